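#' Construct a toxicity-test survival dataset
#'
#' Holds survivor counts over time for one study: a shared vector of
#' observation times (days, starting at 0) and one treatment per exposure
#' level. Each treatment carries its exposure as an
#' \code{\link{exposure_profile}} (constant-exposure treatments become
#' two-node profiles) and the integer number of survivors at every
#' observation time, with the count at time 0 equal to the number of
#' organisms at test start.
#'
#' @param times observation times in days; increasing, first element 0.
#' @param treatments a list; each element a list with \code{exposure}
#'   (an \code{exposure_profile} or a single constant concentration in ug/L)
#'   and \code{survivors} (integer counts, one per observation time).
#'   An optional \code{label} defaults to the peak concentration.
#' @param species species label.
#' @param study_type \code{"acute"} or \code{"ELS"}.
#' @param check_monotone require counts to be non-increasing in time (the
#'   prepared state). Raw ELS data may violate this; pass \code{FALSE} and
#'   run \code{\link{prepare_els}}.
#' @return An object of class \code{"survival_dataset"}.
#' @export
survival_dataset <- function(times, treatments, species = "",
                             study_type = c("acute", "ELS"),
                             check_monotone = TRUE) {
  study_type <- match.arg(study_type)
  times <- as.numeric(times)
  if (times[1L] != 0 || any(diff(times) <= 0))
    stop("observation times must start at 0 and increase strictly")
  if (!is.list(treatments) || !length(treatments))
    stop("'treatments' must be a non-empty list")
  treatments <- lapply(treatments, function(tr) {
    if (!is.list(tr) || is.null(tr$exposure) || is.null(tr$survivors))
      stop("each treatment needs 'exposure' and 'survivors'")
    if (!inherits(tr$exposure, "exposure_profile")) {
      conc <- as.numeric(tr$exposure)[1L]
      tr$exposure <- constant_profile(conc, max(times))
    }
    s <- tr$survivors
    if (anyNA(s) || any(s < 0) || any(s != round(s)))
      stop("survivor counts must be non-negative integers")
    if (length(s) != length(times))
      stop("one survivor count per observation time is required")
    if (check_monotone && any(diff(s) > 0))
      stop("survivor counts increase over time; run prepare/enforce_monotone first")
    tr$survivors <- as.integer(round(s))
    if (is.null(tr$label))
      tr$label <- format(max(tr$exposure$conc))
    tr
  })
  if (max(times) > max(vapply(treatments, function(tr) max(tr$exposure$times), 0)))
    stop("exposure profiles must cover the observation window")
  structure(list(times = times, treatments = treatments,
                 species = species, study_type = study_type),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  n0 <- vapply(x$treatments, function(tr) tr$survivors[1L], integer(1))
  cat("Survival dataset (", x$study_type, ")",
      if (nzchar(x$species)) paste0(" for ", x$species), "\n",
      "  ", length(x$treatments), " treatments, ",
      length(x$times), " observation times over ",
      format(max(x$times)), " days, n0 = ",
      paste(n0, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Force survivor counts to be non-increasing in time
#'
#' Caps each observation at the (already capped) value of the previous one:
#' \code{out[i] = min(in[i], out[i-1])}. Apparent resurrections are treated
#' as mis-scored deaths at the earlier time; whenever the final raw count is
#' not above all earlier capped values, the total number of individuals
#' reported at the last observation is preserved. Idempotent.
#'
#' @param survivors non-negative integer vector.
#' @return Integer vector of the same length, non-increasing.
#' @examples
#' enforce_monotone(c(20, 19, 21, 18))  # -> 20 19 19 18
#' @export
enforce_monotone <- function(survivors) {
  s <- as.numeric(survivors)
  if (anyNA(s) || any(s < 0)) stop("survivor counts must be non-negative")
  as.integer(round(cummin(s)))
}

#' Pool replicate or control groups by summing survivors
#'
#' @param groups non-empty list of survivor-count vectors observed at
#'   identical times (equal lengths).
#' @return Element-wise sum as an integer vector.
#' @export
pool_groups <- function(groups) {
  if (!is.list(groups) || !length(groups))
    stop("'groups' must be a non-empty list of survivor sequences")
  len <- vapply(groups, length, integer(1))
  if (any(len != len[1L]))
    stop("groups observed at mismatched numbers of time points")
  as.integer(Reduce(`+`, lapply(groups, as.numeric)))
}

#' Prepare an early-life-stage (ELS) study for calibration
#'
#' Applies, in this order: (1) drop all observations before the hatch day
#' and re-zero time at hatch (GUTS-RED has no egg stage, so the prehatch
#' phase is excluded from calibration); (2) per replicate, force survivor
#' counts non-increasing (\code{\link{enforce_monotone}}); (3) pool
#' replicates within each treatment; (4) pool control groups. The order
#' matters: monotonicity is a per-replicate correction of scoring errors
#' and must precede summation.
#'
#' @param raw a \code{\link{survival_dataset}} with \code{study_type "ELS"}
#'   built with \code{check_monotone = FALSE}; treatments may carry
#'   \code{replicates} (a list of survivor vectors) instead of a pooled
#'   \code{survivors} vector, and a logical \code{is_control} flag.
#' @param hatch_day hatch time in days; must precede the last observation.
#' @return A prepared \code{survival_dataset} (monotone, pooled, re-zeroed).
#' @export
prepare_els <- function(raw, hatch_day) {
  stopifnot(inherits(raw, "survival_dataset"))
  hatch_day <- as.numeric(hatch_day)[1L]
  if (hatch_day >= max(raw$times))
    stop("'hatch_day' must precede the last observation")
  keep <- raw$times >= hatch_day
  if (!any(keep)) stop("no observations at or after 'hatch_day'")
  new_times <- raw$times[keep] - raw$times[keep][1L]
  # steps (1)+(2): truncate, then per-replicate monotonicity
  prepped <- lapply(raw$treatments, function(tr) {
    reps <- if (!is.null(tr$replicates)) tr$replicates else list(tr$survivors)
    reps <- lapply(reps, function(r) enforce_monotone(as.numeric(r)[keep]))
    pooled <- pool_groups(reps)  # step (3)
    list(exposure = truncate_profile(tr$exposure, raw$times[keep][1L]),
         survivors = pooled,
         label = tr$label,
         is_control = isTRUE(tr$is_control) ||
           max(tr$exposure$conc) == 0)
  })
  # step (4): pool controls
  is_ctrl <- vapply(prepped, function(tr) tr$is_control, logical(1))
  if (sum(is_ctrl) > 1L) {
    ctrl <- list(
      exposure = constant_profile(0, max(new_times), label = "control"),
      survivors = pool_groups(lapply(prepped[is_ctrl], `[[`, "survivors")),
      label = "control")
    prepped <- c(list(ctrl), prepped[!is_ctrl])
  }
  prepped <- lapply(prepped, function(tr) { tr$is_control <- NULL; tr })
  survival_dataset(new_times, prepped, species = raw$species,
                   study_type = "ELS")
}

# restrict a profile to [t0, end] and re-zero time at t0
truncate_profile <- function(profile, t0) {
  if (t0 == 0) return(profile)
  t_end <- max(profile$times)
  inner <- profile$times[profile$times > t0 & profile$times < t_end]
  tt <- c(t0, inner, t_end)
  exposure_profile(tt - t0, conc_at(profile, tt), profile$label)
}

#' Read a survival table
#'
#' Format: delimited text (comma or tab), first column the observation time
#' in days, remaining columns one per treatment; the header gives each
#' treatment's exposure concentration in ug/L (the word \code{"control"}
#' means 0); cells are survivor counts.
#'
#' @param path file path.
#' @param species,study_type passed to \code{\link{survival_dataset}}.
#' @param check_monotone see \code{\link{survival_dataset}}.
#' @return A \code{\link{survival_dataset}} with constant-exposure
#'   treatments.
#' @export
read_survival_table <- function(path, species = "", study_type = "acute",
                                check_monotone = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, strip.white = TRUE)
  if (ncol(tab) < 2L) stop("survival table needs a time column and >= 1 treatment")
  times <- as.numeric(tab[[1L]])
  heads <- names(tab)[-1L]
  conc <- ifelse(tolower(trimws(heads)) %in% c("control", "solvent control"),
                 0, suppressWarnings(as.numeric(heads)))
  if (anyNA(conc))
    stop("unparseable treatment concentration in header: ",
         paste(heads[is.na(conc)], collapse = ", "))
  treatments <- lapply(seq_along(conc), function(j) {
    list(exposure = conc[j], survivors = as.numeric(tab[[j + 1L]]),
         label = trimws(heads[j]))
  })
  survival_dataset(times, treatments, species = species,
                   study_type = study_type, check_monotone = check_monotone)
}

#' Write a survival table
#'
#' @param data a \code{\link{survival_dataset}} with constant-exposure
#'   treatments.
#' @param path output path (CSV).
#' @return \code{path}, invisibly. Round-trips exactly through
#'   \code{\link{read_survival_table}}.
#' @export
write_survival_table <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  conc <- vapply(data$treatments, function(tr) max(tr$exposure$conc), 0)
  heads <- ifelse(conc == 0, "control",
                  format(conc, digits = 15, trim = TRUE, scientific = FALSE))
  m <- vapply(data$treatments, function(tr) tr$survivors,
              integer(length(data$times)))
  m <- matrix(m, nrow = length(data$times))
  lines <- c(paste(c("time_d", heads), collapse = ","),
             vapply(seq_along(data$times), function(i) {
               paste(c(format(data$times[i], digits = 15, trim = TRUE,
                              scientific = FALSE), m[i, ]), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
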