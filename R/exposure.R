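#' Construct an exposure concentration profile
#'
#' An exposure profile is a piecewise-linear concentration time series
#' \eqn{C_w(t)}: strictly increasing times in days starting at 0, and
#' non-negative concentrations in ug/L. Hourly surface-water time series
#' (e.g. TOXSWA output) and constant-exposure toxicity-test treatments are
#' both represented this way; a constant treatment is the two-node profile
#' \code{[(0, c), (t_end, c)]}.
#'
#' @param times numeric vector of times in days; strictly increasing,
#'   first element 0, length >= 2.
#' @param conc numeric vector of concentrations in ug/L, same length as
#'   \code{times}; all finite and >= 0.
#' @param label free-text label.
#' @return An object of class \code{"exposure_profile"}: a list with
#'   elements \code{times}, \code{conc}, \code{label}.
#' @examples
#' p <- exposure_profile(c(0, 1, 2), c(0, 10, 0), label = "pulse")
#' conc_at(p, 0.5)
#' @export
exposure_profile <- function(times, conc, label = "") {
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) < 2L)
    stop("an exposure profile needs at least 2 time nodes")
  if (length(conc) != length(times))
    stop("'times' and 'conc' must have the same length")
  if (anyNA(times) || any(!is.finite(times)))
    stop("times must be finite")
  if (times[1L] != 0)
    stop("the first time node must be 0")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (anyNA(conc) || any(!is.finite(conc)))
    stop("concentrations must be finite")
  if (any(conc < 0))
    stop("concentrations must be non-negative")
  structure(list(times = times, conc = conc, label = as.character(label)[1L]),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("Exposure profile", if (nzchar(x$label)) sQuote(x$label) else "",
      "\n  ", length(x$times), " nodes over [0, ",
      format(max(x$times)), "] days; peak ",
      format(max(x$conc)), " ug/L\n", sep = "")
  invisible(x)
}

#' @export
plot.exposure_profile <- function(x, ...) {
  graphics::plot(x$times, x$conc, type = "l",
                 xlab = "time [d]", ylab = "concentration [ug/L]",
                 main = x$label, ...)
  invisible(x)
}

#' Interpolate an exposure profile
#'
#' Linear interpolation of the concentration between profile nodes; exact at
#' the nodes. No extrapolation: times outside the recorded window are an
#' error, since model predictions are only defined on the profile's support.
#'
#' @param profile an \code{\link{exposure_profile}}.
#' @param t numeric vector of times in days, all inside the profile window.
#' @return Concentrations in ug/L at \code{t}.
#' @export
conc_at <- function(profile, t) {
  stopifnot(inherits(profile, "exposure_profile"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < profile$times[1L]) || any(t > profile$times[length(profile$times)]))
    stop("time outside the profile window [",
         profile$times[1L], ", ", profile$times[length(profile$times)],
         "]; no extrapolation")
  stats::approx(profile$times, profile$conc, xout = t, method = "linear",
                ties = "ordered")$y
}

#' Scale an exposure profile by a multiplication factor
#'
#' Multiplies every concentration by \code{factor}, leaving times unchanged.
#' This is the operation underlying LPx: damage and hence survival respond
#' to \code{scale_profile(p, f)} exactly as to \code{f * Cw(t)}.
#'
#' @param profile an \code{\link{exposure_profile}}.
#' @param factor finite scalar >= 0.
#' @return A new \code{exposure_profile}.
#' @export
scale_profile <- function(profile, factor) {
  stopifnot(inherits(profile, "exposure_profile"))
  factor <- as.numeric(factor)[1L]
  if (!is.finite(factor) || factor < 0)
    stop("'factor' must be finite and >= 0")
  exposure_profile(profile$times, profile$conc * factor, profile$label)
}

#' Read an exposure profile from a delimited text file
#'
#' Two dialects are supported. \code{"two-column-ugL"}: time in days and
#' concentration in ug/L, as written by \code{\link{write_exposure_profile}}.
#' \code{"toxswa-gm3"}: hourly TOXSWA-style rows with time in hours and the
#' water-layer concentration (ConLiqWatLay) in g/m^3; times are converted to
#' days (/24) and concentrations to ug/L (x1000, since 1 g/m^3 = 1000 ug/L).
#' Fields may be comma- or tab-separated; a single (non-numeric) header line
#' is skipped.
#'
#' @param path file path.
#' @param dialect \code{"two-column-ugL"} or \code{"toxswa-gm3"}.
#' @param label profile label; defaults to the file name.
#' @return An \code{\link{exposure_profile}} in days and ug/L.
#' @export
read_exposure_profile <- function(path,
                                  dialect = c("two-column-ugL", "toxswa-gm3"),
                                  label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty profile file: ", path)
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[,\t]+|[[:space:]]+")[[1L]]
    fields <- fields[nzchar(fields)]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[1L])
  start <- 1L
  if (anyNA(first)) start <- 2L  # header line
  if (start > length(lines)) stop("no data rows in ", path)
  rows <- lapply(lines[start:length(lines)], parse_row)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 2L || anyNA(r))
      stop("unparseable row ", i + start - 1L, " in ", path)
  }
  m <- do.call(rbind, rows)
  times <- m[, 1L]
  conc <- m[, 2L]
  if (dialect == "toxswa-gm3") {
    times <- times / 24
    conc <- conc * 1000
  }
  if (any(conc < 0)) stop("negative concentration in ", path)
  if (any(diff(times) <= 0)) stop("times not strictly increasing in ", path)
  if (times[1L] != 0) {
    # re-zero a window that starts later than 0 (TOXSWA windows often do)
    times <- times - times[1L]
  }
  exposure_profile(times, conc, label = label)
}

#' Write an exposure profile as a two-column CSV (days, ug/L)
#'
#' @param profile an \code{\link{exposure_profile}}.
#' @param path output file path.
#' @return \code{path}, invisibly. Round-trips exactly through
#'   \code{\link{read_exposure_profile}} with the \code{"two-column-ugL"}
#'   dialect.
#' @export
write_exposure_profile <- function(profile, path) {
  stopifnot(inherits(profile, "exposure_profile"))
  lines <- c("time_d,conc_ugL",
             paste(format(profile$times, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(profile$conc, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

# constant-exposure treatment profile over [0, t_end]
constant_profile <- function(conc, t_end, label = "") {
  exposure_profile(c(0, t_end), c(conc, conc), label = label)
}
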