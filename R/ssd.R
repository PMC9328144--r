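#' Fit a log-normal species sensitivity distribution to LP50 values
#'
#' Maximum-likelihood fit of a log-normal (base 10) distribution to one
#' LP50 per species: \code{mu} is the mean and \code{sigma} the ML standard
#' deviation (n denominator) of the log10 values. The 5% hazard profile is
#' the 5th percentile on the natural scale,
#' \eqn{HP_5 = 10^{\mu + \sigma z_{0.05}}} with
#' \eqn{z_{0.05} = -1.6449}: the multiplication factor at which 5% of
#' species reach 50% mortality.
#'
#' @param lp50 positive numeric vector, one LP50 per species; at least 3
#'   distinct values (a warning is issued below 5, where the fitted tail is
#'   weakly informed).
#' @return Object of class \code{"ssd_fit"}: list with \code{mu},
#'   \code{sigma}, \code{hp5}, \code{n_species}, \code{lp50}.
#' @examples
#' fit_ssd(c(10, 31.6228, 100))$hp5  # 6.7375
#' @export
fit_ssd <- function(lp50) {
  lp50 <- as.numeric(lp50)
  if (anyNA(lp50) || any(lp50 <= 0))
    stop("LP50 values must be positive and non-missing")
  if (length(lp50) < 3L)
    stop("an SSD fit needs at least 3 species")
  if (length(unique(lp50)) == 1L)
    stop("all LP50 values identical: degenerate SSD (sigma = 0)")
  if (length(lp50) < 5L)
    warning("fewer than 5 species: SSD tail weakly informed")
  lx <- log10(lp50)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))  # ML estimate, n denominator
  hp5 <- 10^(mu + sigma * stats::qnorm(0.05))
  structure(list(mu = mu, sigma = sigma, hp5 = hp5,
                 n_species = length(lp50), lp50 = lp50),
            class = "ssd_fit")
}

#' 5% hazard profile of a fitted SSD
#'
#' @param fit an \code{\link{ssd_fit}}.
#' @return The stored 5th percentile (multiplication-factor units).
#' @export
hp5 <- function(fit) {
  stopifnot(inherits(fit, "ssd_fit"))
  fit$hp5
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat("Log-normal SSD over ", x$n_species, " species:\n",
      "  mu = ", format(signif(x$mu, 4)),
      ", sigma = ", format(signif(x$sigma, 4)), " (log10 LP50)\n",
      "  HP5 = ", format(signif(x$hp5, 4)), "\n", sep = "")
  invisible(x)
}

#' Plot an SSD: empirical CDF of LP50 with the fitted log-normal curve
#'
#' @param x an \code{\link{ssd_fit}}.
#' @param ... passed to \code{plot}.
#' @export
plot.ssd_fit <- function(x, ...) {
  v <- sort(x$lp50)
  emp <- (seq_along(v) - 0.5) / length(v)
  grid <- 10^seq(log10(min(v)) - 1, log10(max(v)) + 1, length.out = 200L)
  graphics::plot(grid, stats::pnorm(log10(grid), x$mu, x$sigma),
                 type = "l", log = "x", col = "red",
                 xlab = "LP50 (multiplication factor)",
                 ylab = "fraction of species affected", ...)
  graphics::points(v, emp, pch = 16)
  graphics::abline(v = x$hp5, lty = 2)
  invisible(x)
}

#' Rank species by sensitivity per exposure profile
#'
#' Orders species by ascending LP50 (most sensitive first) within each
#' (profile, variant) cell and reports every species pair whose relative
#' order differs between any two profiles of the same variant — the
#' profile-dependence of sensitivity rankings.
#'
#' @param lp50_table data frame with columns \code{species},
#'   \code{profile}, \code{variant}, \code{lp50}; one row per combination,
#'   complete (an error names missing cells).
#' @return Object of class \code{"ranking_table"}: list with
#'   \code{ranking} (data frame with a \code{rank} column; exact ties share
#'   a rank and are flagged in \code{tie}) and \code{changes} (data frame
#'   of reordered pairs: variant, the two species, and the two profiles on
#'   which their order differs).
#' @export
rank_species <- function(lp50_table) {
  req <- c("species", "profile", "variant", "lp50")
  if (!is.data.frame(lp50_table) || !all(req %in% names(lp50_table)))
    stop("'lp50_table' needs columns ", paste(req, collapse = ", "))
  tb <- lp50_table[req]
  species <- unique(tb$species)
  cells <- expand.grid(species = species,
                       profile = unique(tb$profile),
                       variant = unique(tb$variant),
                       stringsAsFactors = FALSE)
  key <- function(d) paste(d$species, d$profile, d$variant, sep = "\r")
  missing <- !(key(cells) %in% key(tb))
  if (any(missing))
    stop("missing LP50 cells: ",
         paste(apply(cells[missing, ], 1L, paste, collapse = "/"),
               collapse = "; "))
  if (anyNA(tb$lp50) || any(tb$lp50 <= 0))
    stop("LP50 values must be positive")

  pieces <- split(tb, list(tb$profile, tb$variant), drop = TRUE)
  ranking <- do.call(rbind, lapply(pieces, function(d) {
    d <- d[order(d$lp50, d$species), ]
    d$rank <- rank(d$lp50, ties.method = "min")
    d$tie <- duplicated(d$lp50) | duplicated(d$lp50, fromLast = TRUE)
    d
  }))
  rownames(ranking) <- NULL

  changes <- list()
  for (v in unique(tb$variant)) {
    profs <- unique(tb$profile)
    for (a_i in seq_along(profs)) for (b_i in seq_len(a_i - 1L)) {
      pa <- profs[a_i]; pb <- profs[b_i]
      la <- tb$lp50[tb$variant == v & tb$profile == pa][
        match(species, tb$species[tb$variant == v & tb$profile == pa])]
      lb <- tb$lp50[tb$variant == v & tb$profile == pb][
        match(species, tb$species[tb$variant == v & tb$profile == pb])]
      for (i in seq_along(species)) for (j in seq_len(i - 1L)) {
        da <- sign(la[i] - la[j]); db <- sign(lb[i] - lb[j])
        if (da != 0 && db != 0 && da != db)
          changes[[length(changes) + 1L]] <-
            data.frame(variant = v, species_1 = species[j],
                       species_2 = species[i], profile_1 = pb,
                       profile_2 = pa, stringsAsFactors = FALSE)
      }
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
  else data.frame(variant = character(), species_1 = character(),
                  species_2 = character(), profile_1 = character(),
                  profile_2 = character(), stringsAsFactors = FALSE)
  structure(list(ranking = ranking, changes = changes),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("Species sensitivity ranking (ascending LP50, most sensitive first)\n")
  for (v in unique(x$ranking$variant)) {
    for (p in unique(x$ranking$profile)) {
      d <- x$ranking[x$ranking$variant == v & x$ranking$profile == p, ]
      if (!nrow(d)) next
      cat("  [", v, " / ", p, "]  ",
          paste0(d$species, " (", signif(d$lp50, 3),
                 ifelse(d$tie, ", tie", ""), ")", collapse = " < "),
          "\n", sep = "")
    }
  }
  if (nrow(x$changes)) {
    cat("Ranking changes between profiles:\n")
    for (i in seq_len(nrow(x$changes)))
      cat("  ", x$changes$species_1[i], " vs ", x$changes$species_2[i],
          " reorder between ", x$changes$profile_1[i], " and ",
          x$changes$profile_2[i], " (", x$changes$variant[i], ")\n",
          sep = "")
  } else cat("No ranking changes between profiles.\n")
  invisible(x)
}
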