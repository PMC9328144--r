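#' @export
print.guts_fit <- function(x, ...) {
  cat("GUTS-RED-", x$variant, " fit",
      if (nzchar(x$data$species)) paste0(" (", x$data$species, ")"),
      "\n", sep = "")
  est <- format(signif(as.numeric(x$params), 4))
  flag <- ifelse(x$boundary, " [at bound]", "")
  for (i in seq_along(x$params))
    cat("  ", formatC(names(x$params)[i], width = 5), " = ", est[i],
        flag[i], "\n", sep = "")
  cat("  log-likelihood: ", format(x$logLik, digits = 6),
      if (!x$converged) "  (NOT converged)",
      if (x$n_floored > 0) paste0("  (", x$n_floored,
                                  " floored likelihood cells)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.guts_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' @export
logLik.guts_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$params), class = "logLik")
}

#' Profile-likelihood confidence intervals for a GUTS-RED fit
#'
#' @param object a \code{\link{guts_fit}}.
#' @param parm parameter names (default: all).
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with rows per parameter and columns \code{lower},
#'   \code{upper}; attribute \code{"at_bound"} marks clipped ends.
#' @seealso \code{\link{profile_ci}}
#' @export
confint.guts_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(parm)) parm <- names(object$params)
  cis <- lapply(parm, function(p) profile_ci(object, p, level = level))
  out <- do.call(rbind, lapply(cis, function(ci) as.numeric(ci)))
  dimnames(out) <- list(parm, c("lower", "upper"))
  attr(out, "at_bound") <- do.call(rbind, lapply(cis, attr, "at_bound"))
  out
}

#' @export
summary.guts_fit <- function(object, ci = TRUE, level = 0.95, ...) {
  g <- gof(object)
  cis <- if (ci) confint(object, level = level) else NULL
  structure(list(fit = object, gof = g, ci = cis, level = level),
            class = "summary.guts_fit")
}

#' @export
print.summary.guts_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat("\nProfile-likelihood ", format(100 * x$level),
        "% confidence intervals:\n", sep = "")
    print(signif(x$ci, 4))
    ab <- attr(x$ci, "at_bound")
    if (any(ab)) cat("  (intervals clipped at the search bounds where",
                     "the data carry no information)\n")
  }
  cat("\nGoodness of fit:\n")
  print(x$gof)
  invisible(x)
}

#' Predict survival for a fitted GUTS-RED model
#'
#' @param object a \code{\link{guts_fit}}.
#' @param profile an \code{\link{exposure_profile}}; default: predict for
#'   the calibration treatments at the observation times.
#' @param times evaluation times (days).
#' @param factor multiplication factor applied to the profile.
#' @param ... unused.
#' @return With a \code{profile}: a \code{"survival_curve"}. Without: a
#'   matrix of survival probabilities (times x treatments).
#' @export
predict.guts_fit <- function(object, profile = NULL, times = NULL,
                             factor = 1, ...) {
  if (is.null(profile)) {
    S <- model_survival_matrix(object$params, object$data)
    dimnames(S) <- list(format(object$data$times),
                        vapply(object$data$treatments,
                               function(tr) tr$label, ""))
    return(S)
  }
  p <- if (factor != 1) scale_profile(profile, factor) else profile
  guts_survival(object$params, p, times = times)
}

#' @export
residuals.guts_fit <- function(object, ...) {
  S <- model_survival_matrix(object$params, object$data)
  obs <- vapply(object$data$treatments,
                function(tr) as.numeric(tr$survivors),
                numeric(length(object$data$times)))
  obs <- matrix(obs, nrow = length(object$data$times))
  res <- obs - sweep(S, 2L, obs[1L, ], `*`)
  dimnames(res) <- list(format(object$data$times),
                        vapply(object$data$treatments,
                               function(tr) tr$label, ""))
  res
}

#' Simulate survival datasets from a fitted GUTS-RED model
#'
#' Draws new survivor counts under the fitted parameters and the original
#' test design (conditional-binomial process, matching the likelihood).
#'
#' @param object a \code{\link{guts_fit}}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of \code{\link{survival_dataset}} objects.
#' @export
simulate.guts_fit <- function(object, nsim = 1, seed = NULL, ...) {
  data <- object$data
  S <- model_survival_matrix(object$params, data)
  if (!is.null(seed)) set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, nsim * length(data$treatments))
  k <- 0L
  out <- lapply(seq_len(nsim), function(r) {
    trs <- lapply(seq_along(data$treatments), function(j) {
      tr <- data$treatments[[j]]
      k <<- k + 1L
      curve <- survival_curve(data$times, S[, j])
      tr$survivors <- simulate_survivors(curve, tr$survivors[1L],
                                         data$times, seed = seeds[k])
      tr
    })
    survival_dataset(data$times, trs, species = data$species,
                     study_type = data$study_type)
  })
  if (nsim == 1L) out[[1L]] else out
}

#' Plot observed and fitted survival for a calibrated model
#'
#' One panel: observed survivor fractions (points) and model survival
#' curves (lines) per treatment.
#'
#' @param x a \code{\link{guts_fit}}.
#' @param ... passed to \code{matplot}.
#' @export
plot.guts_fit <- function(x, ...) {
  data <- x$data
  tt <- seq(0, max(data$times), length.out = 101L)
  Sf <- vapply(data$treatments, function(tr) {
    if (is_constant_profile(tr$exposure))
      surv_constant(tr$exposure$conc[1L], x$params, tt)
    else guts_survival(x$params, tr$exposure, times = tt)$survival
  }, numeric(length(tt)))
  cols <- seq_along(data$treatments)
  graphics::matplot(tt, Sf, type = "l", lty = 1, col = cols,
                    ylim = c(0, 1), xlab = "time [d]",
                    ylab = "survival probability",
                    main = paste0("GUTS-RED-", x$variant,
                                  if (nzchar(data$species))
                                    paste0(": ", data$species)), ...)
  for (j in cols) {
    y <- data$treatments[[j]]$survivors
    graphics::points(data$times, y / y[1L], col = j, pch = 16)
  }
  graphics::legend("bottomleft",
                   legend = vapply(data$treatments,
                                   function(tr) tr$label, ""),
                   col = cols, lty = 1, pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}
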