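# Transcriptional signature extraction and connectivity-based drug
# matching: BH adjustment, top-N up/down signature construction, a
# two-sided unweighted Kolmogorov-Smirnov connectivity score against
# reference drug rankings, and hypergeometric class enrichment.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min_{j: p_(j) >= p_(i)} p_(j) * m /
#' rank_j`, clipped at 1, returned in the input order. A thin validating
#' wrapper over [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .fail_param("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Extract an up/down transcriptional signature from a DE table
#'
#' The signature is the top `n` up-regulated and top `n` down-regulated
#' genes among those passing the BH-adjusted significance cutoff, ranked by
#' log2 fold-change (up: LFC descending; down: ascending). LFC ties break
#' by smaller raw p-value, then lexicographic gene id, so extraction is
#' deterministic and stable under row permutation of the input.
#'
#' @param de data.frame with columns `gene, lfc, pvalue` and optionally
#'   `padj` (computed with [bh_adjust()] when absent).
#' @param n Signature size per direction (default 150).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param rank_by `"lfc"` (default) or `"pvalue"` (rank the significant set
#'   by significance instead of effect size).
#' @return Object of class `gene_signature`: list with ordered character
#'   vectors `up` and `down` plus the `n`/`alpha` used. Either side may be
#'   shorter than `n` (or empty) if fewer genes qualify.
#' @export
extract_signature <- function(de, n = 150L, alpha = 0.05,
                              rank_by = c("lfc", "pvalue")) {
  rank_by <- match.arg(rank_by)
  req <- c("gene", "lfc", "pvalue")
  if (!is.data.frame(de) || nrow(de) == 0 || !all(req %in% names(de)))
    .fail_param("de must be a nonempty data.frame with gene, lfc, pvalue")
  if (anyDuplicated(de$gene)) .fail_param("gene ids must be unique")
  if (!"padj" %in% names(de)) de$padj <- bh_adjust(de$pvalue)
  sig <- de[de$padj < alpha, , drop = FALSE]
  pick <- function(rows, decreasing) {
    if (nrow(rows) == 0) return(character(0))
    key <- if (rank_by == "lfc") rows$lfc else -rows$pvalue
    if (!decreasing) key <- -key
    o <- order(-key, rows$pvalue, rows$gene)
    utils::head(rows$gene[o], n)
  }
  up <- pick(sig[sig$lfc > 0, , drop = FALSE], decreasing = TRUE)
  down <- pick(sig[sig$lfc < 0, , drop = FALSE], decreasing = FALSE)
  structure(list(up = up, down = down, n = as.integer(n), alpha = alpha),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up, %d down (n = %d, alpha = %g)\n",
              length(x$up), length(x$down), x$n, x$alpha))
  invisible(x)
}

#' Construct a signature directly from one reference ranking
#'
#' Takes the `n` most up-ranked genes as `up` and the `n` most down-ranked
#' as `down`; useful for building a query from a reference drug (or for
#' planting a reference drug that should match a query).
#'
#' @param ranking Named integer vector: gene -> rank (1 = most
#'   up-regulated), a permutation of `1..N`.
#' @param n Genes per direction.
#' @return A `gene_signature`.
#' @export
signature_from_ranking <- function(ranking, n = 150L) {
  .check_ranking(ranking)
  if (2 * n > length(ranking))
    .fail_param("2n must not exceed the gene universe")
  o <- names(sort(ranking))
  structure(list(up = o[seq_len(n)], down = rev(o)[seq_len(n)],
                 n = as.integer(n), alpha = NA_real_),
            class = "gene_signature")
}

.check_ranking <- function(ranking) {
  if (is.null(names(ranking)) || !is.numeric(ranking))
    .fail_param("ranking must be a named numeric vector of gene ranks")
  if (!setequal(ranking, seq_along(ranking)))
    .fail_param("ranking must be a permutation of 1..N")
  invisible(ranking)
}

# Signed KS enrichment of a gene set's positions within a ranking of N
# genes: the running hit (+1/n) vs miss (-1/(N-n)) walk's maximal
# deviation, signed by its direction; ties in |deviation| resolve positive.
.ks_enrichment <- function(positions, N) {
  n <- length(positions)
  if (n == 0 || n >= N) .fail_param("gene set must be nonempty and proper")
  p <- sort.int(positions)
  j <- seq_len(n)
  d_hit <- j / n - (p - j) / (N - n)        # walk value just after hit j
  d_before <- (j - 1) / n - (p - j) / (N - n) # value just before hit j
  es_pos <- max(d_hit)
  es_neg <- min(d_before)
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Connectivity of a query signature with one reference drug ranking
#'
#' Bidirectional unweighted Kolmogorov-Smirnov statistic: `es_up` is the
#' signed enrichment of the query's up genes in the drug's ranking, and
#' `es_down` likewise for the down genes. The combined score is
#' `tau = (es_up - es_down) / 2` when the two enrichments point in opposite
#' directions (concordant or anti-concordant profile) and 0 otherwise.
#' `tau = 1` means the drug ranks the query's up genes at the very top and
#' down genes at the very bottom; `tau = -1` the exact reverse.
#'
#' @param sig A `gene_signature` (both sides nonempty genes drawn from the
#'   ranking's universe).
#' @param ranking Named rank vector (1 = most up-regulated), a permutation
#'   of `1..N` over the gene universe.
#' @return List of class `connectivity_result`: `es_up`, `es_down`, `tau`.
#' @export
connectivity_score <- function(sig, ranking) {
  stopifnot(inherits(sig, "gene_signature"))
  if (length(sig$up) == 0 && length(sig$down) == 0)
    .fail_param("signature is empty")
  .check_ranking(ranking)
  miss <- setdiff(c(sig$up, sig$down), names(ranking))
  if (length(miss))
    .fail_param("signature genes missing from ranking: %s",
                paste(utils::head(miss, 5), collapse = ", "))
  N <- length(ranking)
  es_up <- if (length(sig$up)) .ks_enrichment(unname(ranking[sig$up]), N) else 0
  es_down <- if (length(sig$down)) .ks_enrichment(unname(ranking[sig$down]), N) else 0
  tau <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
  structure(list(es_up = es_up, es_down = es_down, tau = tau),
            class = "connectivity_result")
}

#' Rank all reference drugs by connectivity with a query signature
#'
#' @param sig A `gene_signature`.
#' @param refmat A `reference_matrix` (see [simulate_reference_matrix()]
#'   or [read_reference_matrix()]).
#' @param ignore_missing Drop signature genes absent from the reference
#'   universe (recorded in attribute `"n_dropped"`) instead of erroring.
#' @return data.frame of class `connectivity_table`: `drug_id, class,
#'   es_up, es_down, tau, rank`, sorted by `tau` descending with ties
#'   broken by drug id.
#' @export
rank_drugs <- function(sig, refmat, ignore_missing = FALSE) {
  stopifnot(inherits(sig, "gene_signature"), inherits(refmat, "reference_matrix"))
  genes <- rownames(refmat$ranks)
  drugs <- colnames(refmat$ranks)
  if (length(drugs) == 0) {
    out <- data.frame(drug_id = character(), class = character(),
                      es_up = numeric(), es_down = numeric(),
                      tau = numeric(), rank = integer())
    class(out) <- c("connectivity_table", class(out))
    return(out)
  }
  miss <- setdiff(c(sig$up, sig$down), genes)
  n_dropped <- 0L
  if (length(miss)) {
    if (!ignore_missing)
      .fail_param("signature genes missing from reference universe: %s%s",
                  paste(utils::head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
    sig$up <- setdiff(sig$up, miss)
    sig$down <- setdiff(sig$down, miss)
    n_dropped <- length(miss)
    if (length(sig$up) == 0 && length(sig$down) == 0)
      .fail_param("no signature genes left after dropping missing ones")
  }
  res <- vapply(drugs, function(d) {
    r <- refmat$ranks[, d]
    names(r) <- genes
    cs <- connectivity_score(sig, r)
    c(cs$es_up, cs$es_down, cs$tau)
  }, numeric(3))
  out <- data.frame(drug_id = drugs,
                    class = as.character(refmat$classes[drugs]),
                    es_up = res[1, ], es_down = res[2, ], tau = res[3, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$tau, out$drug_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("connectivity_table", class(out))
  out
}

#' Drug-class enrichment among the top connectivity matches
#'
#' Counts members of a class among the `top_k` drugs by connectivity and
#' computes the one-sided hypergeometric over-representation p-value.
#'
#' @param results A `connectivity_table` from [rank_drugs()].
#' @param class_label The class to test (must occur among the drugs).
#' @param top_k Number of top drugs considered; defaults to 5% of the
#'   reference, at least 1.
#' @return List of class `class_enrichment`: `class_label`, `top_k`,
#'   `overlap`, `class_size`, `n_drugs`, `p_value`.
#' @export
class_enrichment <- function(results, class_label,
                             top_k = max(1L, round(0.05 * nrow(results)))) {
  stopifnot(inherits(results, "connectivity_table"))
  n <- nrow(results)
  if (top_k < 1 || top_k > n) .fail_param("top_k must be in 1..n_drugs")
  cls <- results$class
  K <- sum(cls == class_label, na.rm = TRUE)
  if (K == 0) .fail_param("unknown class label: %s", class_label)
  top <- results[order(results$rank), , drop = FALSE][seq_len(top_k), ]
  overlap <- sum(top$class == class_label, na.rm = TRUE)
  p <- stats::phyper(overlap - 1, K, n - K, top_k, lower.tail = FALSE)
  structure(list(class_label = class_label, top_k = as.integer(top_k),
                 overlap = as.integer(overlap), class_size = as.integer(K),
                 n_drugs = as.integer(n), p_value = p),
            class = "class_enrichment")
}

#' @export
print.class_enrichment <- function(x, ...) {
  cat(sprintf(
    "class_enrichment: %d/%d '%s' drugs in top %d of %d (hypergeometric p = %.3g)\n",
    x$overlap, x$class_size, x$class_label, x$top_k, x$n_drugs, x$p_value))
  invisible(x)
}
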