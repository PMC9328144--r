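#' Read a study configuration from a YAML file
#'
#' The configuration drives \code{\link{run_study}}. Keys:
#' \preformatted{
#' seed: 1
#' variants: [SD, IT]
#' x: 50                      # effect level for LPx
#' output_dir: results/       # optional
#' uncertainty: false         # propagate CIs into LPx (slow)
#' species:
#'   - label: carp
#'     table: carp.csv        # survival table (read_survival_table)
#'     study_type: acute
#'   - label: minnow
#'     table: minnow_els.csv
#'     study_type: ELS
#'     hatch_day: 5
#' profiles:
#'   - label: profile-A
#'     path: profileA.csv     # two-column-ugL, or:
#'     dialect: two-column-ugL
#'   - label: pulse
#'     scenario: single-sharp-peak   # generated instead of read
#'     peak_conc: 10
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path YAML file path.
#' @return The configuration list (validated lazily by
#'   \code{\link{run_study}}).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg
}

resolve_path <- function(p, dir) {
  if (is.null(dir) || file.exists(p)) p else file.path(dir, p)
}

#' Run the full calibration-prediction-ranking study
#'
#' For every species and requested variant: load (or take) the survival
#' data, apply ELS preparation where configured, calibrate by maximum
#' likelihood; then compute LP\code{x} for every exposure profile, fit a
#' log-normal SSD per profile and variant, extract HP5, and rank species.
#' A species whose calibration fails is flagged with a warning and dropped
#' from prediction and SSD (which still requires its minimum of 3 species).
#' All randomness derives from \code{config$seed}; re-running with the same
#' configuration reproduces every number.
#'
#' @param config a configuration list (see \code{\link{read_study_config}})
#'   or a path to a YAML file. Species entries may carry a ready
#'   \code{dataset} (a \code{\link{survival_dataset}}) instead of
#'   \code{table}; profile entries a ready \code{profile} instead of
#'   \code{path}/\code{scenario}.
#' @return Object of class \code{"guts_study"}: list with \code{fits}
#'   (species x variant), \code{lp50} (data frame species/profile/variant/
#'   lp50 plus interval columns when uncertainty is on), \code{ssd} (per
#'   profile x variant \code{\link{ssd_fit}}), \code{hp5} (data frame),
#'   \code{ranking} (a \code{\link{rank_species}} result), \code{failed}
#'   (labels of species that did not calibrate), and \code{config}.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  if (is.null(config$species) || !length(config$species))
    stop("config needs at least one species entry")
  if (is.null(config$profiles) || !length(config$profiles))
    stop("config needs at least one profile entry")
  variants <- toupper(config$variants %||% c("SD", "IT"))
  if (!all(variants %in% c("SD", "IT"))) stop("variants must be SD and/or IT")
  seed <- as.integer(config$seed %||% 1L)
  x <- config$x %||% 50
  dir <- config$.dir

  # validate all referenced paths up front
  for (sp in config$species)
    if (!is.null(sp$table) &&
        !file.exists(resolve_path(sp$table, dir)))
      stop("survival table not found: ", sp$table)
  for (pf in config$profiles)
    if (!is.null(pf$path) && !file.exists(resolve_path(pf$path, dir)))
      stop("profile file not found: ", pf$path)

  profiles <- lapply(config$profiles, function(pf) {
    label <- pf$label %||% pf$scenario %||% basename(pf$path)
    p <- if (!is.null(pf$profile)) pf$profile
    else if (!is.null(pf$path))
      read_exposure_profile(resolve_path(pf$path, dir),
                            dialect = pf$dialect %||% "two-column-ugL",
                            label = label)
    else do.call(generate_scenario,
                 c(list(shape = pf$scenario),
                   pf[intersect(names(pf),
                                c("peak_conc", "duration", "n_peaks",
                                  "decline_halflife"))]))
    p$label <- label
    p
  })
  names(profiles) <- vapply(profiles, `[[`, "", "label")

  datasets <- lapply(config$species, function(sp) {
    label <- sp$label %||% sp$table
    d <- if (!is.null(sp$dataset)) sp$dataset
    else read_survival_table(resolve_path(sp$table, dir), species = label,
                             study_type = sp$study_type %||% "acute",
                             check_monotone = is.null(sp$hatch_day))
    if (!is.null(sp$hatch_day)) d <- prepare_els(d, sp$hatch_day)
    d$species <- label
    d
  })
  labels <- vapply(datasets, `[[`, "", "species")
  names(datasets) <- labels

  message("Calibrating ", length(datasets), " species x ",
          length(variants), " variants (seed ", seed, ")")
  fits <- list()
  failed <- character(0)
  for (lab in labels) {
    for (v in variants) {
      f <- tryCatch(
        guts_fit(datasets[[lab]], v, seed = seed),
        error = function(e) e)
      if (inherits(f, "error") || !f$converged) {
        warning("calibration failed for ", lab, " (", v, "): ",
                if (inherits(f, "error")) conditionMessage(f)
                else "not converged")
        failed <- unique(c(failed, paste(lab, v)))
      } else fits[[paste(lab, v, sep = ".")]] <- f
    }
  }

  message("Predicting LP", x, " on ", length(profiles), " profiles")
  want_unc <- isTRUE(config$uncertainty)
  rows <- list()
  for (lab in labels) for (v in variants) {
    f <- fits[[paste(lab, v, sep = ".")]]
    if (is.null(f)) next
    ci_box <- if (want_unc) confint(f)
    for (p in profiles) {
      row <- data.frame(species = lab, profile = p$label, variant = v,
                        lp50 = lpx(f$params, p, x = x),
                        stringsAsFactors = FALSE)
      if (want_unc) {
        u <- lpx_uncertainty(f, p, x = x, seed = seed, ci = ci_box)
        row$lower <- u$ci[["lower"]]; row$upper <- u$ci[["upper"]]
        row$flagged <- u$flagged
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  lp50 <- do.call(rbind, rows)

  ssds <- list(); hp5_rows <- list()
  for (v in variants) for (pl in names(profiles)) {
    vals <- lp50$lp50[lp50$variant == v & lp50$profile == pl]
    if (length(vals) >= 3L && length(unique(vals)) > 1L) {
      s <- suppressWarnings(fit_ssd(vals))
      ssds[[paste(pl, v, sep = ".")]] <- s
      hp5_rows[[length(hp5_rows) + 1L]] <-
        data.frame(profile = pl, variant = v, hp5 = s$hp5,
                   mu = s$mu, sigma = s$sigma, n_species = s$n_species,
                   stringsAsFactors = FALSE)
    } else {
      warning("SSD skipped for ", pl, "/", v,
              ": fewer than 3 calibrated species")
    }
  }
  hp5_tab <- if (length(hp5_rows)) do.call(rbind, hp5_rows)
  else data.frame(profile = character(), variant = character(),
                  hp5 = numeric())

  ranking <- rank_species(lp50)

  out <- structure(list(fits = fits, lp50 = lp50, ssd = ssds,
                        hp5 = hp5_tab, ranking = ranking,
                        failed = failed, profiles = profiles,
                        config = config),
                   class = "guts_study")
  if (!is.null(config$output_dir)) write_study(out, config$output_dir)
  out
}

# per-stage artifacts: delimited tables + JSON fit reports
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$lp50, file.path(out_dir, "lp50_table.csv"),
                   row.names = FALSE)
  utils::write.csv(study$hp5, file.path(out_dir, "hp5_table.csv"),
                   row.names = FALSE)
  utils::write.csv(study$ranking$ranking,
                   file.path(out_dir, "ranking.csv"), row.names = FALSE)
  utils::write.csv(study$ranking$changes,
                   file.path(out_dir, "ranking_changes.csv"),
                   row.names = FALSE)
  reports <- lapply(study$fits, fit_report)
  jsonlite::write_json(reports, file.path(out_dir, "fit_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Plain-list fit report (stable field names for downstream tools)
#'
#' @param fit a \code{\link{guts_fit}}.
#' @param ci optional \code{confint} matrix to include.
#' @return A list: species, variant, estimates, loglik, boundary flags,
#'   convergence, goodness-of-fit metrics (and CIs when supplied).
#' @export
fit_report <- function(fit, ci = NULL) {
  g <- gof(fit)
  rep <- list(species = fit$data$species,
              variant = fit$variant,
              estimate = as.list(coef(fit)),
              loglik = fit$logLik,
              converged = fit$converged,
              boundary = as.list(fit$boundary),
              n_floored = fit$n_floored,
              nrmse = g$nrmse,
              sppe = as.list(g$sppe))
  if (!is.null(ci))
    rep$ci <- apply(ci, 1L, function(r) list(lower = r[[1L]],
                                             upper = r[[2L]]),
                    simplify = FALSE)
  rep
}

#' @export
print.guts_study <- function(x, ...) {
  cat("GUTS-RED study: ", length(unique(x$lp50$species)), " species, ",
      length(x$profiles), " profiles, variants ",
      paste(unique(x$lp50$variant), collapse = "/"), "\n", sep = "")
  if (length(x$failed))
    cat("  failed calibrations:", paste(x$failed, collapse = ", "), "\n")
  cat("\nLP50 table:\n")
  print(x$lp50, digits = 4, row.names = FALSE)
  if (nrow(x$hp5)) {
    cat("\nHP5 per profile:\n")
    print(x$hp5[c("profile", "variant", "hp5")], digits = 4,
          row.names = FALSE)
  }
  cat("\n")
  print(x$ranking)
  invisible(x)
}
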