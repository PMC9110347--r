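# Random-null comparison: ensembles of soma-size-constrained random fields
# matched to an observed field, z-score tests of observed statistics
# against the ensemble, and ANOVA/Tukey grouping of regional densities.

#' Simulate a matched random-null ensemble for one cone class
#'
#' Generates `n_replicates` independent hard-core random fields with the
#' observed count of the selected class in the observed window, constrained
#' by that class's soma size, and computes the full set of scalar spatial
#' statistics per replicate: NND mean and regularity index, Voronoi-domain
#' mean and regularity index, and the effective radius of the density
#' recovery profile.
#'
#' @param field Observed [cone_field()].
#' @param cone_class A single cone class present in `field`.
#' @param soma A [soma_sizes()] vector (um).
#' @param n_replicates Number of random fields (>= 2; 20 matches the
#'   standard protocol).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param drp_max_radius,drp_bin_width Autocorrelogram radius and DRP bin
#'   width (um) used for the effective-radius statistic.
#' @return Object of class `null_ensemble`: list with `statistics` (matrix,
#'   replicates x statistics), `null_mean`, `null_sd` (named vectors),
#'   `n_replicates`, `cone_class`, `n_cells`.
#' @examples
#' f <- gen_mixed_triple_field(seed = 5)
#' ne <- simulate_null_ensemble(f, "triple", n_replicates = 5, seed = 11)
#' ne$null_mean
#' @export
simulate_null_ensemble <- function(field, cone_class, soma = soma_sizes(),
                                   n_replicates = 20, seed = 0,
                                   drp_max_radius = 15, drp_bin_width = 1) {
  if (n_replicates < 2L)
    stop("`n_replicates` must be >= 2 (SD undefined otherwise)")
  n_cells <- length(class_index(field, cone_class))
  if (n_cells < 4L)
    stop("class '", cone_class, "' has fewer than 4 cells")
  stat_names <- c("nnd_mean", "nnd_ri", "vd_mean", "vd_ri",
                  "effective_radius")
  stats_mat <- matrix(NA_real_, n_replicates, length(stat_names),
                      dimnames = list(NULL, stat_names))
  counts <- stats::setNames(n_cells, cone_class)
  for (r in seq_len(n_replicates)) {
    rf <- gen_hardcore_random(n = counts, soma = soma,
                              window = field$window, seed = seed + r)
    stats_mat[r, ] <- field_scalar_stats(rf, cone_class, drp_max_radius,
                                         drp_bin_width)
  }
  structure(
    list(statistics = stats_mat,
         null_mean = colMeans(stats_mat),
         null_sd = apply(stats_mat, 2, stats::sd),
         n_replicates = n_replicates, cone_class = cone_class,
         n_cells = n_cells, seed = seed,
         drp_max_radius = drp_max_radius, drp_bin_width = drp_bin_width),
    class = "null_ensemble")
}

#' Scalar spatial statistics of one class of a field
#'
#' The statistic vector used throughout the null comparison: NND mean and
#' regularity index, Voronoi-domain mean and regularity index (interior
#' cells only), and DRP effective radius.
#'
#' @inheritParams simulate_null_ensemble
#' @return Named numeric vector.
#' @export
field_scalar_stats <- function(field, cone_class, drp_max_radius = 15,
                               drp_bin_width = 1) {
  ms <- mosaic_summary(field, cone_class)
  er <- effective_radius(density_recovery_profile(
    autocorrelogram(field, cone_class, drp_max_radius), drp_bin_width))
  c(nnd_mean = ms$nnd$mean, nnd_ri = ms$nnd$regularity_index,
    vd_mean = ms$voronoi$mean, vd_ri = ms$voronoi$regularity_index,
    effective_radius = er)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Random-null ensemble:", x$n_replicates, "hard-core fields of",
      x$n_cells, x$cone_class, "cones\n")
  m <- rbind(mean = x$null_mean, sd = x$null_sd)
  print(round(m, 3))
  invisible(x)
}

#' Compare an observed statistic to a random-null ensemble
#'
#' The observed value is converted to a z-score against the replicate mean
#' and SD; significance is a two-sided normal test. An empirical-rank
#' alternative counts how many replicates are at least as extreme (two
#' sided) and is limited by the replicate count (20 replicates cannot give
#' an empirical p below 2/21).
#'
#' @param observed Observed scalar statistic.
#' @param ensemble A [simulate_null_ensemble()] result.
#' @param statistic Name of the statistic in the ensemble (e.g.
#'   `"nnd_ri"`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param method `"z"` (default) or `"rank"`.
#' @return Object of class `null_comparison`: list with `statistic`,
#'   `observed`, `null_mean`, `null_sd`, `z_score`, `p_value`,
#'   `significant`, `alpha`, `method`.
#' @examples
#' f <- gen_square_mosaic(6, jitter_sd = 0.3, seed = 2)
#' ne <- simulate_null_ensemble(f, "double", n_replicates = 5, seed = 1)
#' compare_to_null(field_scalar_stats(f, "double")[["nnd_ri"]], ne, "nnd_ri")
#' @export
compare_to_null <- function(observed, ensemble, statistic,
                            alpha = 0.05, method = c("z", "rank")) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  method <- match.arg(method)
  if (!statistic %in% colnames(ensemble$statistics))
    stop("unknown statistic '", statistic, "'; available: ",
         paste(colnames(ensemble$statistics), collapse = ", "))
  mu <- ensemble$null_mean[[statistic]]
  sdv <- ensemble$null_sd[[statistic]]
  if (sdv > 0) {
    z <- (observed - mu) / sdv
  } else {
    z <- if (observed == mu) 0 else Inf * sign(observed - mu)
  }
  if (method == "z") {
    p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
    signif <- abs(z) > stats::qnorm(1 - alpha / 2)
  } else {
    vals <- ensemble$statistics[, statistic]
    dev_obs <- abs(observed - mu)
    p <- (sum(abs(vals - mu) >= dev_obs) + 1) /
      (ensemble$n_replicates + 1)
    signif <- p <= alpha
  }
  structure(
    list(statistic = statistic, observed = observed, null_mean = mu,
         null_sd = sdv, z_score = z, p_value = p,
         significant = signif, alpha = alpha, method = method),
    class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: observed %.4g vs null %.4g +/- %.4g  (z = %.3f, p = %.4f) %s\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$z_score, x$p_value,
    if (x$significant) "SIGNIFICANT" else "n.s."))
  invisible(x)
}

#' Compare cone densities (or any statistic) across retinal regions
#'
#' One-way ANOVA followed by Tukey HSD pairwise comparisons at level
#' `alpha`; regions are then grouped with a compact letter display built by
#' insert-and-absorb, so regions sharing a letter are statistically
#' indistinct.
#'
#' @param groups Named list of numeric vectors, one per region, each with
#'   at least 2 values.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `region_comparison`: list with `anova_F`,
#'   `anova_p`, `tukey` (data.frame of pairwise results), and `groups`
#'   (data.frame `region`, `mean`, `sd`, `group_letters`).
#' @examples
#' g <- list(a = c(10, 11, 12), b = c(10.5, 11.5, 12.5), c = c(50, 51, 52))
#' compare_regions(g)$groups
#' @export
compare_regions <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 regions")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named list of regions")
  small <- names(groups)[vapply(groups, length, 1L) < 2L]
  if (length(small))
    stop("region(s) with fewer than 2 values: ",
         paste(small, collapse = ", "))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    region = factor(rep(names(groups), vapply(groups, length, 1L)),
                    levels = names(groups)))
  fit <- stats::aov(value ~ region, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$region
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(region_a = pairs[, 1], region_b = pairs[, 2],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      distinct = tk[, "p adj"] < alpha,
                      row.names = NULL)
  letters_out <- compact_letters(names(groups), tukey)
  res <- data.frame(
    region = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    group_letters = letters_out[names(groups)],
    row.names = NULL)
  structure(
    list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
         tukey = tukey, groups = res, alpha = alpha),
    class = "region_comparison")
}

# Compact letter display (insert-and-absorb): start with one letter
# covering all regions; for each significantly different pair found in a
# letter's set, split that letter into two sets omitting one member each,
# then absorb sets contained in others.
compact_letters <- function(regions, tukey) {
  sets <- list(regions)
  distinct_pairs <- tukey[tukey$distinct, c("region_a", "region_b"),
                          drop = FALSE]
  if (nrow(distinct_pairs)) {
    for (k in seq_len(nrow(distinct_pairs))) {
      a <- distinct_pairs$region_a[k]; b <- distinct_pairs$region_b[k]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets that are subsets of another set
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            !(all(new_sets[[j]] %in% new_sets[[i]]) && i < j))
          keep[i] <- FALSE
      }
      sets <- new_sets[keep]
    }
  }
  out <- stats::setNames(rep("", length(regions)), regions)
  for (i in seq_along(sets))
    for (r in sets[[i]])
      out[r] <- paste0(out[r], letters[i])
  # a region distinct from everything still needs its own letter
  empty <- names(out)[!nzchar(out)]
  for (i in seq_along(empty))
    out[empty[i]] <- letters[length(sets) + i]
  out
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g (alpha = %g)\n",
              x$anova_F, x$anova_p, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
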