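#' Design of a constant-exposure toxicity test
#'
#' @param concentrations exposure concentrations in ug/L; must include 0
#'   (the control) and at least one positive level.
#' @param n0 organisms per treatment at test start.
#' @param times observation times in days (first = 0).
#' @return A list of class \code{"test_design"}.
#' @export
test_design <- function(concentrations, n0 = 40L, times = 0:4) {
  concentrations <- as.numeric(concentrations)
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!any(concentrations == 0)) stop("a control (0 ug/L) is required")
  if (!any(concentrations > 0)) stop("at least one positive level is required")
  if (n0 < 1) stop("n0 must be >= 1")
  times <- as.numeric(times)
  if (times[1L] != 0 || any(diff(times) <= 0))
    stop("observation times must start at 0 and increase")
  structure(list(concentrations = concentrations, n0 = as.integer(n0),
                 times = times, duration = max(times)),
            class = "test_design")
}

#' Simulate a toxicity test with known GUTS-RED parameters
#'
#' Each treatment is a constant-exposure two-node profile; survivors are
#' drawn with \code{\link{simulate_survivors}} under the survival curve of
#' the variant implied by \code{params}. The result satisfies all
#' \code{\link{survival_dataset}} invariants without any post-hoc
#' censoring.
#'
#' @param params \code{\link{sd_params}} or \code{\link{it_params}} (the
#'   true, data-generating values).
#' @param design a \code{\link{test_design}}.
#' @param seed integer seed; the dataset is reproducible.
#' @param species label stored on the dataset.
#' @return A \code{\link{survival_dataset}}.
#' @export
generate_test <- function(params, design, seed = 1L, species = "synthetic") {
  stopifnot(inherits(params, "guts_params"), inherits(design, "test_design"))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, length(design$concentrations))
  treatments <- lapply(seq_along(design$concentrations), function(j) {
    conc <- design$concentrations[j]
    prof <- constant_profile(conc, design$duration)
    curve <- survival_curve(design$times,
                            surv_constant(conc, params, design$times))
    list(exposure = prof,
         survivors = simulate_survivors(curve, design$n0, design$times,
                                        seed = seeds[j]),
         label = if (conc == 0) "control" else format(conc))
  })
  survival_dataset(design$times, treatments, species = species,
                   study_type = "acute")
}

#' Generate a FOCUS-like exposure scenario
#'
#' Parametric idealizations of the characteristic surface-water exposure
#' shapes produced by the FOCUS modelling chain, sampled at hourly nodes,
#' non-negative, starting and ending at 0:
#' \describe{
#'   \item{single-sharp-peak}{triangular pulse, ~1 day rising limb and
#'     ~1 day falling limb (default duration 2 days).}
#'   \item{single-peak-slow-decline}{rise to the peak over the first day,
#'     then exponential decline with half-life \code{decline_halflife}
#'     (default 10 days over a 60-day window; the final node closes to 0).}
#'   \item{multi-peak}{\code{n_peaks} sharp triangular pulses of equal
#'     height, evenly spaced over \code{duration} (default 4 pulses over
#'     30 days).}
#' }
#'
#' @param shape one of the three scenario shapes.
#' @param peak_conc peak concentration, ug/L (> 0); the profile maximum for
#'   every shape.
#' @param duration window length in days (defaults per shape).
#' @param n_peaks number of pulses (multi-peak only, >= 2).
#' @param decline_halflife decline half-life in days (slow-decline only).
#' @return An \code{\link{exposure_profile}} with hourly nodes.
#' @export
generate_scenario <- function(shape = c("single-sharp-peak",
                                        "single-peak-slow-decline",
                                        "multi-peak"),
                              peak_conc = 10, duration = NULL,
                              n_peaks = 4L, decline_halflife = 10) {
  shape <- match.arg(shape)
  if (peak_conc <= 0) stop("peak_conc must be > 0")
  duration <- duration %||% switch(shape,
                                   "single-sharp-peak" = 2,
                                   "single-peak-slow-decline" = 60,
                                   "multi-peak" = 30)
  if (duration <= 0) stop("duration must be > 0")
  tt <- seq(0, duration, by = 1 / 24)
  if (tt[length(tt)] < duration) tt <- c(tt, duration)
  # make sure the peak apexes are exact nodes
  tt <- switch(shape,
               "single-sharp-peak" = sort(unique(c(tt, duration / 2))),
               "single-peak-slow-decline" = sort(unique(c(tt, min(1, duration / 2)))),
               "multi-peak" = sort(unique(c(
                 tt, duration * (seq_len(max(as.integer(n_peaks), 1L)) - 0.5) /
                   max(as.integer(n_peaks), 1L)))))
  conc <- switch(shape,
    "single-sharp-peak" = {
      tp <- duration / 2
      peak_conc * pmax(0, 1 - abs(tt - tp) / tp)
    },
    "single-peak-slow-decline" = {
      if (decline_halflife <= 0) stop("decline_halflife must be > 0")
      tp <- min(1, duration / 2)
      lam <- log(2) / decline_halflife
      cc <- ifelse(tt <= tp, peak_conc * tt / tp,
                   peak_conc * exp(-lam * (tt - tp)))
      cc[length(cc)] <- 0  # close the window
      cc
    },
    "multi-peak" = {
      n_peaks <- as.integer(n_peaks)
      if (n_peaks < 2L) stop("multi-peak needs n_peaks >= 2")
      centers <- duration * (seq_len(n_peaks) - 0.5) / n_peaks
      half <- min(1, duration / (2 * n_peaks) * 0.8)  # non-overlapping
      cc <- numeric(length(tt))
      for (ct in centers)
        cc <- pmax(cc, peak_conc * pmax(0, 1 - abs(tt - ct) / half))
      cc
    })
  exposure_profile(tt, conc, label = shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A synthetic species panel spanning slow to fast toxicokinetics
#'
#' Returns species with dominant rate constants spanning more than two
#' orders of magnitude (0.25 to 100 per day), the range reported for fish.
#' The slow species pairs its low kD with a low threshold, so long-tailed
#' exposure that its damage state integrates over time is what kills it;
#' the fast species pairs a high kD with a higher threshold, so short sharp
#' pulses (which its damage tracks almost instantaneously) are decisive.
#' This construction makes the sensitivity ranking depend on the exposure
#' profile.
#'
#' @param seed kept for interface symmetry with the other generators; the
#'   panel is a fixed deterministic table.
#' @param n_species 2, 3 or 5 species (slow and fast always included).
#' @return A list; each element has \code{label}, \code{sd}
#'   (\code{\link{sd_params}}) and \code{it} (\code{\link{it_params}}).
#' @export
generate_species_panel <- function(seed = 1L, n_species = 5L) {
  panel <- list(
    list(label = "slow-kd",
         sd = sd_params(kD = 0.25, zw = 1.5, bw = 0.15, hb = 0.01),
         it = it_params(kD = 0.25, mw = 4, beta = 3, hb = 0.01)),
    list(label = "slowish-kd",
         sd = sd_params(kD = 1, zw = 2.5, bw = 0.25, hb = 0.01),
         it = it_params(kD = 1, mw = 5, beta = 3.5, hb = 0.01)),
    list(label = "mid-kd",
         sd = sd_params(kD = 5, zw = 4, bw = 0.35, hb = 0.01),
         it = it_params(kD = 5, mw = 6.5, beta = 4, hb = 0.01)),
    list(label = "fastish-kd",
         sd = sd_params(kD = 25, zw = 5, bw = 0.5, hb = 0.01),
         it = it_params(kD = 25, mw = 7, beta = 4.5, hb = 0.01)),
    list(label = "fast-kd",
         sd = sd_params(kD = 100, zw = 6, bw = 0.6, hb = 0.01),
         it = it_params(kD = 100, mw = 8, beta = 5, hb = 0.01)))
  n_species <- as.integer(n_species)
  idx <- switch(as.character(n_species),
                "2" = c(1L, 5L), "3" = c(1L, 3L, 5L), "5" = 1:5,
                stop("n_species must be 2, 3 or 5"))
  panel[idx]
}
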