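# Statistics for the downstream validation assays: competition-assay
# relative fitness, embryo survival, nematode motility, reprogramming
# conversion metrics and per-cell intensity comparisons.

.check_series <- function(series) {
  req <- c("day", "q94_count", "control_count")
  if (!is.data.frame(series) || !all(req %in% names(series)))
    .fail_param("series needs columns day, q94_count, control_count")
  if (any(series$q94_count < 0) || any(series$control_count < 0))
    .fail_param("counts must be >= 0")
  if (any(series$q94_count + series$control_count == 0))
    .fail_param("each timepoint needs at least one scored cell")
  if (!0 %in% series$day) .fail_param("day 0 must be present")
  if (length(unique(series$day)) < 2)
    .fail_param("need >= 2 distinct timepoints")
  invisible(series)
}

#' Relative-fitness coefficient from a growth-competition time series
#'
#' Models a constant per-day growth-rate difference `s` between the
#' toxic-protein-expressing population and its co-cultured control, under
#' which the expressing fraction decays logistically:
#' `logit(p_t) = logit(p0) - s t`. The fit is weighted least squares on the
#' observed logit proportions with binomial weights
#' `w_t = n_t p_t (1 - p_t)` (the inverse of the large-sample variance of a
#' logit), and the standard error comes from the known-weight information
#' matrix, not the residual mean square - with as few as two or three
#' timepoints a residual-based SE would be uninformative.
#'
#' Proportions of exactly 0 or 1 receive a Haldane continuity correction
#' (half a cell added to each category) and are flagged; noiseless data on
#' the logistic curve are recovered exactly.
#'
#' @param series data.frame `day, q94_count, control_count` (a `condition`
#'   column is carried through if present).
#' @return Object of class `fitness_estimate`: `s` (per day; positive =
#'   expressing fraction declines), `s_se`, `p0_hat`, `logit_residuals`,
#'   `corrected` (logical per timepoint), `condition`.
#' @export
estimate_relative_fitness <- function(series) {
  .check_series(series)
  series <- series[order(series$day), , drop = FALSE]
  q <- series$q94_count; ctl <- series$control_count
  corrected <- q == 0 | ctl == 0
  q <- ifelse(corrected, q + 0.5, q)
  ctl <- ifelse(corrected, ctl + 0.5, ctl)
  n <- q + ctl
  p <- q / n
  if (all(p <= 0) || all(p >= 1))
    .fail_param("proportions degenerate even after continuity correction")
  y <- stats::qlogis(p)
  X <- cbind(1, series$day)
  w <- n * p * (1 - p)
  XtWX <- crossprod(X, X * w)
  if (abs(det(XtWX)) < 1e-12) .fail_param("fitness model is non-identifiable")
  beta <- solve(XtWX, crossprod(X, w * y))
  V <- solve(XtWX)  # dispersion fixed at 1: binomial variance is known
  s <- -beta[2, 1]
  structure(list(
    s = s,
    s_se = sqrt(V[2, 2]),
    p0_hat = stats::plogis(beta[1, 1]),
    logit_residuals = as.numeric(y - X %*% beta),
    corrected = corrected,
    condition = if ("condition" %in% names(series)) series$condition[1] else NA_character_
  ), class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("fitness_estimate%s: s = %.4f / day (SE %.4f), p0_hat = %.3f\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$s, x$s_se, x$p0_hat))
  invisible(x)
}

#' Compare relative fitness across conditions
#'
#' Fits [estimate_relative_fitness()] per condition and forms Wald
#' contrasts of the fitted `s` against a reference condition (the first by
#' default). A rescue is a negative `delta_s` (slower decline than
#' vehicle).
#'
#' @param series_by_condition Named list of competition series data.frames,
#'   or one data.frame with a `condition` column.
#' @param reference Reference condition label (default: first).
#' @return List of class `fitness_comparison`: `fits` (named list of
#'   `fitness_estimate`) and `contrasts` (data.frame `condition, delta_s,
#'   se, z, p_value` vs the reference).
#' @export
compare_fitness <- function(series_by_condition, reference = NULL) {
  if (is.data.frame(series_by_condition)) {
    if (!"condition" %in% names(series_by_condition))
      .fail_param("data.frame input needs a condition column")
    series_by_condition <- split(series_by_condition,
                                 series_by_condition$condition)
  }
  if (length(series_by_condition) < 2)
    .fail_param("need >= 2 conditions to compare")
  if (is.null(names(series_by_condition)))
    .fail_param("conditions must be named")
  fits <- lapply(names(series_by_condition), function(cond) {
    tryCatch(estimate_relative_fitness(series_by_condition[[cond]]),
             error = function(e) stop(sprintf("condition '%s': %s", cond,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  names(fits) <- names(series_by_condition)
  if (is.null(reference)) reference <- names(fits)[1]
  if (!reference %in% names(fits)) .fail_param("unknown reference condition")
  ref <- fits[[reference]]
  others <- setdiff(names(fits), reference)
  contr <- do.call(rbind, lapply(others, function(cond) {
    f <- fits[[cond]]
    d <- f$s - ref$s
    se <- sqrt(f$s_se^2 + ref$s_se^2)
    z <- d / se
    data.frame(condition = cond, reference = reference, delta_s = d,
               se = se, z = z, p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  rownames(contr) <- NULL
  structure(list(fits = fits, contrasts = contr, reference = reference),
            class = "fitness_comparison")
}

#' Compare embryo survival between arms
#'
#' Default is the replicate-level Welch t-test on per-well survival
#' fractions (respecting well-level clustering; works at n = 3 wells); the
#' pooled two-proportion z-test is available as an option. Each arm is
#' contrasted against the first (reference) arm. Both SD and SEM of the
#' per-replicate fractions are reported.
#'
#' @param survival data.frame `arm, replicate, n_total, n_dead`.
#' @param test `"t"` (default) or `"two_proportion"`.
#' @return List of class `survival_comparison`: `arm_summary` (data.frame
#'   `arm, n_replicates, survival_frac, sd, sem`) and `contrasts`
#'   (data.frame `arm, reference, difference, statistic, p_value`),
#'   differences on the survival-fraction scale.
#' @export
compare_survival <- function(survival, test = c("t", "two_proportion")) {
  test <- match.arg(test)
  req <- c("arm", "n_total", "n_dead")
  if (!is.data.frame(survival) || !all(req %in% names(survival)))
    .fail_param("survival needs columns arm, n_total, n_dead")
  if (any(survival$n_dead > survival$n_total) || any(survival$n_dead < 0))
    .fail_param("need 0 <= n_dead <= n_total in every replicate")
  arms <- unique(survival$arm)
  if (length(arms) < 2) .fail_param("need >= 2 arms")
  survival$frac <- 1 - survival$n_dead / survival$n_total

  summ <- do.call(rbind, lapply(arms, function(a) {
    f <- survival$frac[survival$arm == a]
    data.frame(arm = a, n_replicates = length(f), survival_frac = mean(f),
               sd = stats::sd(f), sem = stats::sd(f) / sqrt(length(f)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  ref <- arms[1]
  contr <- do.call(rbind, lapply(arms[-1], function(a) {
    x <- survival[survival$arm == a, , drop = FALSE]
    y <- survival[survival$arm == ref, , drop = FALSE]
    if (test == "t") {
      if (nrow(x) < 2 || nrow(y) < 2)
        .fail_param(paste("the replicate-level t-test needs >= 2 replicates",
                          "per arm; use test = \"two_proportion\""))
      tt <- stats::t.test(x$frac, y$frac)
      data.frame(arm = a, reference = ref,
                 difference = mean(x$frac) - mean(y$frac),
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      pt <- stats::prop.test(c(sum(x$n_dead), sum(y$n_dead)),
                             c(sum(x$n_total), sum(y$n_total)))
      data.frame(arm = a, reference = ref,
                 difference = mean(x$frac) - mean(y$frac),
                 statistic = unname(pt$statistic), p_value = pt$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(contr) <- NULL
  structure(list(arm_summary = summ, contrasts = contr, test = test),
            class = "survival_comparison")
}

#' Compare worm motility (body bends per 30 s) between arms
#'
#' Welch two-sample t-test on per-worm counts by default, Mann-Whitney as
#' the nonparametric option; each arm is contrasted against the first.
#'
#' @param bends data.frame `arm, bends_30s` (one row per worm).
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @param min_worms Minimum worms per arm (default 5).
#' @return List of class `bend_comparison`: `arm_summary` (`arm, n_worms,
#'   mean_bends, sd`) and `contrasts` (`arm, reference, mean_difference,
#'   statistic, p_value`).
#' @export
compare_bends <- function(bends, test = c("t", "wilcoxon"), min_worms = 5L) {
  test <- match.arg(test)
  if (!is.data.frame(bends) || !all(c("arm", "bends_30s") %in% names(bends)))
    .fail_param("bends needs columns arm, bends_30s")
  if (any(bends$bends_30s < 0) || any(bends$bends_30s != round(bends$bends_30s)))
    .fail_param("bend counts must be nonnegative integers")
  arms <- unique(bends$arm)
  if (length(arms) < 2) .fail_param("need >= 2 arms")
  n_by <- table(bends$arm)
  if (any(n_by < min_worms))
    .fail_param("every arm needs >= %d worms", min_worms)

  summ <- do.call(rbind, lapply(arms, function(a) {
    x <- bends$bends_30s[bends$arm == a]
    data.frame(arm = a, n_worms = length(x), mean_bends = mean(x),
               sd = stats::sd(x), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  ref <- arms[1]
  contr <- do.call(rbind, lapply(arms[-1], function(a) {
    x <- bends$bends_30s[bends$arm == a]
    y <- bends$bends_30s[bends$arm == ref]
    ht <- if (test == "t") stats::t.test(x, y)
          else stats::wilcox.test(x, y, exact = FALSE)
    data.frame(arm = a, reference = ref, mean_difference = mean(x) - mean(y),
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(contr) <- NULL
  structure(list(arm_summary = summ, contrasts = contr, test = test),
            class = "bend_comparison")
}

#' Reprogramming purity and efficiency
#'
#' Purity is the fraction of marker-positive (TAU+) cells among all nuclei
#' (DAPI+); efficiency is marker-positive cells per plated fibroblast.
#'
#' @param dapi_count Nuclei counted (> 0).
#' @param tau_count Marker-positive neurons counted (>= 0).
#' @param plated_count Fibroblasts plated (> 0).
#' @param enforce_subset Require `tau_count <= dapi_count` (default TRUE).
#' @return List of class `conversion_metrics`: `purity` in `[0, 1]`,
#'   `efficiency` >= 0.
#' @export
conversion_metrics <- function(dapi_count, tau_count, plated_count,
                               enforce_subset = TRUE) {
  if (dapi_count <= 0) .fail_param("dapi_count must be > 0")
  if (plated_count <= 0) .fail_param("plated_count must be > 0")
  if (tau_count < 0) .fail_param("tau_count must be >= 0")
  if (enforce_subset && tau_count > dapi_count)
    .fail_param("tau_count cannot exceed dapi_count")
  structure(list(purity = tau_count / dapi_count,
                 efficiency = tau_count / plated_count),
            class = "conversion_metrics")
}

#' Compare per-cell intensity distributions between groups
#'
#' Two groups: Welch t-test. More than two: one-way ANOVA with Tukey HSD
#' post-hoc pairwise comparisons.
#'
#' @param groups Named list of numeric per-cell intensity vectors (>= 3
#'   cells each).
#' @return List of class `intensity_comparison`: `group_summary` (`group,
#'   n, mean, sd`), `method` (`"welch_t"` or `"anova_tukey"`), `p_value`
#'   (the t-test or ANOVA F-test p), and `pairwise` (data.frame of
#'   adjusted pairwise p-values for the ANOVA path).
#' @export
compare_intensity <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups)))
    .fail_param("groups must be a named list of >= 2 intensity vectors")
  n_by <- vapply(groups, length, integer(1))
  if (any(n_by < 3)) .fail_param("every group needs >= 3 cells")
  summ <- data.frame(group = names(groups), n = n_by,
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, stats::sd, numeric(1)),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  if (length(groups) == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]])
    return(structure(list(group_summary = summ, method = "welch_t",
                          p_value = tt$p.value, statistic = unname(tt$statistic),
                          pairwise = NULL),
                     class = "intensity_comparison"))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), times = n_by),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pw <- data.frame(contrast = rownames(tk), difference = tk[, "diff"],
                   p_adjusted = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  structure(list(group_summary = summ, method = "anova_tukey",
                 p_value = p, statistic = summary(fit)[[1]][["F value"]][1],
                 pairwise = pw),
            class = "intensity_comparison")
}
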