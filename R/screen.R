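# Plate data model, per-plate percent-of-control normalization, triplicate
# aggregation, 3SD hit calling against dox-only controls, dose-response
# validation and assay QC.

.check_plates <- function(plates, need_norm = FALSE) {
  req <- c("plate_id", "well", "row", "col", "role", "compound_id",
           "dose_uM", "nuclei_count")
  miss <- setdiff(req, names(plates))
  if (length(miss))
    .fail_param("plate table is missing columns: %s",
                paste(miss, collapse = ", "))
  bad <- setdiff(unique(plates$role),
                 c("no_dox_control", "dox_only_control", "compound"))
  if (length(bad))
    .fail_param("unknown well roles: %s", paste(bad, collapse = ", "))
  if (any(plates$nuclei_count < 0)) .fail_param("nuclei counts must be >= 0")
  comp <- plates$role == "compound"
  if (any(comp & plates$compound_id == "") ||
      any(!comp & plates$compound_id != ""))
    .fail_param("compound_id must be nonempty exactly for compound wells")
  if (need_norm && !"norm_count" %in% names(plates))
    .fail_param("plate table has no norm_count column; run normalize_plates() first")
  invisible(plates)
}

#' Normalize well counts to the per-plate dox-only (DMSO) control mean
#'
#' Each well's normalized value is its nuclei count divided by the mean
#' count of that plate's dox-only control wells (the screen's vehicle
#' condition: dox plus DMSO, no compound). Normalization is strictly per
#' plate, which removes any multiplicative plate factor exactly. No-dox
#' controls are not used here; they serve QC (assay window, Z') only.
#'
#' @param plates Plate data.frame (see [simulate_screen()] for columns).
#' @return The same data.frame with a `norm_count` column appended.
#' @export
normalize_plates <- function(plates) {
  .check_plates(plates)
  is_ctrl <- plates$role == "dox_only_control"
  ctrl_n <- tapply(is_ctrl, plates$plate_id, sum)
  if (any(ctrl_n == 0))
    .fail_param("plate(s) without dox-only control wells: %s",
                paste(names(ctrl_n)[ctrl_n == 0], collapse = ", "))
  ctrl_mean <- tapply(ifelse(is_ctrl, plates$nuclei_count, NA_real_),
                      plates$plate_id, mean, na.rm = TRUE)
  if (any(ctrl_mean == 0))
    .fail_param("dox-only control mean is zero on plate(s): %s",
                paste(names(ctrl_mean)[ctrl_mean == 0], collapse = ", "))
  plates$norm_count <- plates$nuclei_count /
    as.numeric(ctrl_mean[plates$plate_id])
  plates
}

#' Summarize normalized compound measurements across replicate plates
#'
#' One summary row per (compound, dose): the unweighted arithmetic mean of
#' the per-replicate normalized values, the single measurement per compound
#' used for hit calling. Missing replicates are averaged over what exists,
#' with the replicate count recorded.
#'
#' @param plates Normalized plate data.frame (from [normalize_plates()]).
#' @return data.frame `compound_id, dose_uM, normalized_mean, n_replicates`
#'   with the long per-replicate table attached as attribute
#'   `"replicates"`.
#' @export
summarize_compounds <- function(plates) {
  .check_plates(plates, need_norm = TRUE)
  cw <- plates[plates$role == "compound", , drop = FALSE]
  if (nrow(cw) == 0) {
    warning("no compound wells to summarize")
    out <- data.frame(compound_id = character(), dose_uM = numeric(),
                      normalized_mean = numeric(), n_replicates = integer())
    attr(out, "replicates") <- cw
    return(out)
  }
  key <- interaction(cw$compound_id, cw$dose_uM, drop = TRUE, lex.order = TRUE)
  mean_v <- tapply(cw$norm_count, key, mean)
  n_v <- tapply(cw$norm_count, key, length)
  first <- !duplicated(key)
  out <- data.frame(compound_id = cw$compound_id[first],
                    dose_uM = cw$dose_uM[first],
                    stringsAsFactors = FALSE)
  k <- as.character(key[first])
  out$normalized_mean <- as.numeric(mean_v[k])
  out$n_replicates <- as.integer(n_v[k])
  out <- out[order(out$compound_id, out$dose_uM), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicates") <- cw
  out
}

#' Location and spread of the normalized dox-only controls
#'
#' Computes the control mean and spread that define the hit threshold
#' `mu + k * sigma`.
#'
#' Two choices matter and are exposed:
#' \describe{
#'   \item{`aggregate`}{`"well"` (default) uses each normalized control
#'     well as one observation. `"replicate_mean"` first averages each
#'     control well position across its replicate plates, so the control
#'     statistic has the same sampling variance as the compound
#'     triplicate-mean statistic (the matched-variance design used for
#'     null calibration).}
#'   \item{`loo`}{With `TRUE`, each control well is normalized by the mean
#'     of the *other* dox-only wells on its plate (leave-one-out), removing
#'     the shrinkage a control inherits from sitting inside its own
#'     normalization denominator. Requires raw counts.}
#' }
#'
#' @param plates Normalized plate data.frame.
#' @param scope `"pooled"` (default): one estimate across all plates;
#'   `"per_plate"`: mean of per-plate means and pooled within-plate spread.
#' @param estimator `"sd"` (sample SD, default) or `"mad"`
#'   (median/MAD, robust).
#' @param aggregate `"well"` or `"replicate_mean"` (see above).
#' @param loo Leave-one-out normalization of control wells (see above).
#' @param k Threshold multiplier carried into [call_hits()] (default 3).
#' @return Object of class `control_stats`: list with `mu`, `sigma`, `n`,
#'   `k` and the option set used.
#' @export
control_stats <- function(plates,
                          scope = c("pooled", "per_plate"),
                          estimator = c("sd", "mad"),
                          aggregate = c("well", "replicate_mean"),
                          loo = FALSE, k = 3) {
  scope <- match.arg(scope); estimator <- match.arg(estimator)
  aggregate <- match.arg(aggregate)
  .check_plates(plates, need_norm = !loo)
  ctrl <- plates[plates$role == "dox_only_control", , drop = FALSE]
  if (nrow(ctrl) < 2) .fail_param("need at least 2 dox-only control wells")
  if (nrow(ctrl) < 8)
    warning("fewer than 8 dox-only control wells in scope")

  if (loo) {
    s <- tapply(ctrl$nuclei_count, ctrl$plate_id, sum)
    n <- tapply(ctrl$nuclei_count, ctrl$plate_id, length)
    if (any(n < 2)) .fail_param("leave-one-out needs >= 2 controls per plate")
    denom <- (as.numeric(s[ctrl$plate_id]) - ctrl$nuclei_count) /
      (as.numeric(n[ctrl$plate_id]) - 1)
    if (any(denom == 0)) .fail_param("leave-one-out control mean is zero")
    vals <- ctrl$nuclei_count / denom
  } else {
    vals <- ctrl$norm_count
  }

  if (aggregate == "replicate_mean") {
    if (!all(c("layout", "replicate") %in% names(ctrl)))
      .fail_param("replicate_mean aggregation needs layout/replicate columns")
    key <- interaction(ctrl$layout, ctrl$well, drop = TRUE)
    vals <- as.numeric(tapply(vals, key, mean))
    plate_key <- as.character(tapply(as.character(ctrl$layout), key,
                                     function(x) x[1]))
  } else {
    plate_key <- as.character(ctrl$plate_id)
  }

  loc <- function(x) if (estimator == "sd") mean(x) else stats::median(x)
  spr <- function(x) if (estimator == "sd") stats::sd(x) else stats::mad(x)

  if (scope == "pooled") {
    mu <- loc(vals); sigma <- spr(vals); n <- length(vals)
  } else {
    mus <- tapply(vals, plate_key, loc)
    sds <- tapply(vals, plate_key, spr)
    mu <- mean(mus)
    sigma <- sqrt(mean(sds^2))
    n <- length(vals)
  }
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 n = as.integer(n), k = k, scope = scope,
                 estimator = estimator, aggregate = aggregate, loo = loo),
            class = "control_stats")
}

#' @export
print.control_stats <- function(x, ...) {
  cat(sprintf(
    "control_stats: mu = %.4f, sigma = %.4f (n = %d, %s/%s%s), k = %g\n",
    x$mu, x$sigma, x$n, x$scope, x$estimator,
    if (x$loo) ", loo" else "", x$k))
  invisible(x)
}

#' Call primary hits with the k-SD rule
#'
#' A compound is a hit when its normalized triplicate mean strictly exceeds
#' `mu + k * sigma` of the dox-only controls (one-sided: increases in
#' nuclei numbers only). The boundary itself is not a hit.
#'
#' @param summaries Compound summaries from [summarize_compounds()].
#' @param stats A [control_stats()] object.
#' @param k Threshold multiplier; defaults to the one stored in `stats`.
#' @return data.frame of class `hit_calls`: `compound_id, dose_uM,
#'   normalized_mean, threshold, margin, is_hit`, sorted by margin
#'   descending (ties by compound id). `sigma = 0` is legal (threshold
#'   collapses to `mu`) and flagged via attribute `"degenerate_sigma"`.
#' @export
call_hits <- function(summaries, stats, k = stats$k) {
  stopifnot(inherits(stats, "control_stats"))
  if (!all(c("compound_id", "normalized_mean") %in% names(summaries)))
    .fail_param("summaries must come from summarize_compounds()")
  threshold <- stats$mu + k * stats$sigma
  out <- data.frame(compound_id = summaries$compound_id,
                    dose_uM = summaries$dose_uM,
                    normalized_mean = summaries$normalized_mean,
                    threshold = threshold,
                    margin = summaries$normalized_mean - threshold,
                    stringsAsFactors = FALSE)
  out$is_hit <- out$margin > 0
  out <- out[order(-out$margin, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_stats") <- stats
  attr(out, "degenerate_sigma") <- stats$sigma == 0 && k > 0
  class(out) <- c("hit_calls", class(out))
  out
}

#' Validate candidates across doses by ANOVA with control contrasts
#'
#' For each candidate compound, normalized well values at every dose are
#' compared against the plate set's dox-only control wells: a one-way
#' ANOVA across (control, dose 1, ..., dose d), followed by per-dose
#' comparisons to control with multiplicity adjustment (single-step
#' Dunnett by default, Holm-adjusted Welch t-tests as fallback). A dose is
#' significant when its adjusted p is below `alpha` *and* its mean exceeds
#' the control mean (direction gate); a compound is validated when
#' significant at >= 2 doses.
#'
#' @param plates Validation plate data.frame (raw or normalized; raw input
#'   is normalized internally).
#' @param alpha Significance level for adjusted per-dose p-values.
#' @param method `"dunnett"` or `"holm"`.
#' @param min_significant_doses Doses required for validation (default 2).
#' @return List of class `dose_response_result` with
#'   `per_dose` (data.frame `compound_id, dose_uM, normalized_mean,
#'   p_adjusted, significant`) and `per_compound` (data.frame
#'   `compound_id, anova_p, n_significant_doses, validated`).
#' @export
validate_dose_response <- function(plates, alpha = 0.05,
                                   method = c("dunnett", "holm"),
                                   min_significant_doses = 2L) {
  method <- match.arg(method)
  if (nrow(plates) == 0)
    return(structure(list(
      per_dose = data.frame(compound_id = character(), dose_uM = numeric(),
                            normalized_mean = numeric(),
                            p_adjusted = numeric(), significant = logical()),
      per_compound = data.frame(compound_id = character(), anova_p = numeric(),
                                n_significant_doses = integer(),
                                validated = logical())),
      class = "dose_response_result"))
  if (!"norm_count" %in% names(plates)) plates <- normalize_plates(plates)
  .check_plates(plates, need_norm = TRUE)
  ctrl <- plates$norm_count[plates$role == "dox_only_control"]
  if (length(ctrl) < 2)
    .fail_param("validation plate set has no usable dox-only control arm")
  ctrl_mean <- mean(ctrl)
  cw <- plates[plates$role == "compound", , drop = FALSE]
  compounds <- sort(unique(cw$compound_id))

  per_dose <- list(); per_comp <- list()
  for (cmp in compounds) {
    w <- cw[cw$compound_id == cmp, , drop = FALSE]
    doses <- sort(unique(w$dose_uM))
    nrep <- tapply(w$norm_count, w$dose_uM, length)
    if (length(doses) < 2 || any(nrep < 2))
      .fail_param("compound %s needs >= 2 doses with >= 2 replicates each", cmp)
    arm <- factor(c(rep("control", length(ctrl)),
                    paste0("d", match(w$dose_uM, doses))),
                  levels = c("control", paste0("d", seq_along(doses))))
    value <- c(ctrl, w$norm_count)
    fit <- stats::aov(value ~ arm)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    dose_means <- as.numeric(tapply(w$norm_count, w$dose_uM, mean))

    if (method == "dunnett") {
      ## single-step Dunnett p-values involve randomized multivariate-t
      ## integration; pin a deterministic substream so results reproduce
      padj <- with_substream(0L, paste0("dunnett:", cmp), {
        gl <- multcomp::glht(fit, linfct = multcomp::mcp(arm = "Dunnett"))
        as.numeric(summary(gl)$test$pvalues)
      })
    } else {
      praw <- vapply(doses, function(d) {
        stats::t.test(w$norm_count[w$dose_uM == d], ctrl)$p.value
      }, numeric(1))
      padj <- stats::p.adjust(praw, method = "holm")
    }
    sig <- padj < alpha & dose_means > ctrl_mean
    per_dose[[cmp]] <- data.frame(compound_id = cmp, dose_uM = doses,
                                  normalized_mean = dose_means,
                                  p_adjusted = padj, significant = sig,
                                  stringsAsFactors = FALSE)
    per_comp[[cmp]] <- data.frame(compound_id = cmp, anova_p = anova_p,
                                  n_significant_doses = sum(sig),
                                  validated = sum(sig) >= min_significant_doses,
                                  stringsAsFactors = FALSE)
  }
  structure(list(per_dose = do.call(rbind, c(per_dose, list(make.row.names = FALSE))),
                 per_compound = do.call(rbind, c(per_comp, list(make.row.names = FALSE)))),
            class = "dose_response_result")
}

#' @export
print.dose_response_result <- function(x, ...) {
  cat(sprintf("dose_response_result: %d compounds, %d validated\n",
              nrow(x$per_compound), sum(x$per_compound$validated)))
  invisible(x)
}

#' Z' factor of a plate's control separation
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mu_pos - mu_neg|`, with no-dox controls
#' as the positive-growth population and dox-only controls as the negative.
#' Z' <= 1 always; values near 1 indicate a wide, tight assay window.
#' Plates whose control means coincide get `NA` with a flag.
#'
#' @param plates Plate data.frame (raw counts are used; Z' is invariant to
#'   the per-plate normalization scale).
#' @return data.frame `plate_id, zprime, undefined`.
#' @export
zprime <- function(plates) {
  .check_plates(plates)
  out <- lapply(split(plates, plates$plate_id), function(p) {
    pos <- p$nuclei_count[p$role == "no_dox_control"]
    neg <- p$nuclei_count[p$role == "dox_only_control"]
    if (length(pos) < 2 || length(neg) < 2)
      .fail_param("plate %s needs >= 2 control wells of each role",
                  p$plate_id[1])
    sep <- abs(mean(pos) - mean(neg))
    if (sep == 0)
      data.frame(plate_id = p$plate_id[1], zprime = NA_real_,
                 undefined = TRUE, stringsAsFactors = FALSE)
    else
      data.frame(plate_id = p$plate_id[1],
                 zprime = 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / sep,
                 undefined = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$plate_id), , drop = FALSE]
}

#' Assay QC report for a plate set
#'
#' Per-plate Z' factors, control coefficients of variation, and an
#' edge-effect diagnostic (mean normalized count of border compound wells
#' over interior compound wells).
#'
#' @param plates Normalized plate data.frame.
#' @return List of class `qc_report` with `zprime` (data.frame),
#'   `control_cv` (data.frame `plate_id, role, cv`) and `edge_ratio`
#'   (single number; `NA` when a plate set has no border compound wells).
#' @export
qc_report <- function(plates) {
  .check_plates(plates, need_norm = TRUE)
  zp <- zprime(plates)
  ctrl <- plates[plates$role != "compound", , drop = FALSE]
  key <- interaction(ctrl$plate_id, ctrl$role, drop = TRUE)
  cv <- tapply(ctrl$nuclei_count, key,
               function(x) stats::sd(x) / mean(x))
  first <- !duplicated(key)
  control_cv <- data.frame(plate_id = ctrl$plate_id[first],
                           role = ctrl$role[first],
                           cv = as.numeric(cv[as.character(key[first])]),
                           stringsAsFactors = FALSE)
  control_cv <- control_cv[order(control_cv$plate_id, control_cv$role), ]
  rownames(control_cv) <- NULL

  nrw <- max(plates$row); ncl <- max(plates$col)
  cw <- plates[plates$role == "compound", , drop = FALSE]
  on_edge <- cw$row == 1 | cw$row == nrw | cw$col == 1 | cw$col == ncl
  edge_ratio <- if (any(on_edge) && any(!on_edge))
    mean(cw$norm_count[on_edge]) / mean(cw$norm_count[!on_edge])
  else NA_real_
  structure(list(zprime = zp, control_cv = control_cv,
                 edge_ratio = edge_ratio),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: median Z' = %.3f over %d plates; edge ratio %.3f\n",
              stats::median(x$zprime$zprime, na.rm = TRUE),
              nrow(x$zprime), x$edge_ratio))
  invisible(x)
}
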