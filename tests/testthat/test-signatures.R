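# BH adjustment, signature extraction, connectivity scoring and class
# enrichment.

test_that("BH adjustment matches the hand-worked step-up examples", {
  ## m = 4, p = (0.01, 0.02, 0.03, 0.04): p * 4 / rank = 0.04 everywhere
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ## m = 1 identity
  expect_equal(bh_adjust(0.5), 0.5)
  ## all equal p: min over j >= i of p * m / j is attained at j = m
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force oracle and is monotone", {
  set.seed(42)
  for (i in 1:50) {
    m <- sample(1:80, 1)
    p <- stats::runif(m)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    ## monotone nondecreasing in sorted-p order
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("signature extraction takes significant LFC extremes, deterministically", {
  set.seed(7)
  de <- data.frame(gene = sprintf("G%04d", 1:400),
                   lfc = c(seq(0.5, 3, length.out = 150),
                           seq(-3, -0.5, length.out = 150),
                           stats::rnorm(100, 0, 0.05)),
                   pvalue = c(rep(1e-8, 300), stats::runif(100, 0.5, 1)))
  sig <- extract_signature(de, n = 150, alpha = 0.05)
  expect_length(sig$up, 150)
  expect_length(sig$down, 150)
  expect_length(intersect(sig$up, sig$down), 0)
  ## up sorted by LFC descending, down ascending
  lfc <- setNames(de$lfc, de$gene)
  expect_true(all(diff(lfc[sig$up]) <= 0))
  expect_true(all(diff(lfc[sig$down]) >= 0))
  ## stability under row permutation
  sig2 <- extract_signature(de[sample(nrow(de)), ], n = 150)
  expect_identical(sig$up, sig2$up)
  expect_identical(sig$down, sig2$down)

  ## truncation: fewer significant genes than n
  de_small <- de[c(1:40, 301:400), ]
  s3 <- extract_signature(de_small, n = 150)
  expect_length(s3$up, 40)
  expect_length(s3$down, 0)

  ## a strongly induced gene always lands in `up`
  de$lfc[5] <- 5; de$pvalue[5] <- 1e-12
  expect_true("G0005" %in% extract_signature(de)$up)
})

test_that("planted DE truth flows through extraction", {
  d <- simulate_de_table(n_genes = 1000, n_up = 50, n_down = 50, seed = 3)
  sig <- extract_signature(d$de, n = 50)
  expect_setequal(sig$up, d$truth$up_genes)
  expect_setequal(sig$down, d$truth$down_genes)
})

test_that("connectivity score hits its exact extremes and antisymmetry", {
  N <- 500
  rk <- stats::setNames(1:N, sprintf("G%04d", 1:N))
  sig <- structure(list(up = names(rk)[1:40], down = names(rk)[(N - 39):N],
                        n = 40L, alpha = NA_real_), class = "gene_signature")
  cs <- connectivity_score(sig, rk)
  expect_equal(cs$es_up, 1)
  expect_equal(cs$es_down, -1)
  expect_equal(cs$tau, 1)

  swapped <- structure(list(up = sig$down, down = sig$up, n = 40L,
                            alpha = NA_real_), class = "gene_signature")
  expect_equal(connectivity_score(swapped, rk)$tau, -1)

  ## antisymmetry under up/down swap on arbitrary rankings
  set.seed(5)
  for (i in 1:20) {
    r <- stats::setNames(sample(N), names(rk))
    a <- connectivity_score(sig, r)$tau
    b <- connectivity_score(swapped, r)$tau
    expect_equal(b, -a)
  }

  expect_error(connectivity_score(
    structure(list(up = character(), down = character(), n = 0L,
                   alpha = NA_real_), class = "gene_signature"), rk),
    "empty")
  expect_error(connectivity_score(
    structure(list(up = "NOPE", down = "G0002", n = 1L, alpha = NA_real_),
              class = "gene_signature"), rk), "missing")
})

test_that("permutation null of tau is centred at zero", {
  N <- 400
  genes <- sprintf("G%04d", 1:N)
  sig <- structure(list(up = genes[1:30], down = genes[31:60], n = 30L,
                        alpha = NA_real_), class = "gene_signature")
  set.seed(11)
  taus <- vapply(1:1000, function(i) {
    connectivity_score(sig, stats::setNames(sample(N), genes))$tau
  }, numeric(1))
  expect_lt(abs(mean(taus)), 3 * stats::sd(taus) / sqrt(1000))
})

test_that("a reference drug generated from the query signature ranks first", {
  set.seed(9)
  rm <- simulate_reference_matrix(n_drugs = 60, n_genes = 500,
                                  class_concordance = 0, seed = 9)
  genes <- rownames(rm$ranks)
  sig <- structure(list(up = genes[1:50], down = genes[451:500], n = 50L,
                        alpha = NA_real_), class = "gene_signature")
  ## overwrite one drug's ranking with one generated from the signature:
  ## up genes at the very top, down at the very bottom
  self_rank <- c(1:50, sample(51:450), 451:500)
  rm$ranks[, "DRUG0030"] <- self_rank
  conn <- rank_drugs(sig, rm)
  expect_equal(conn$drug_id[1], "DRUG0030")
  expect_equal(conn$tau[1], 1)
  ## ranks are 1..n and sorted by tau descending
  expect_identical(conn$rank, seq_len(nrow(conn)))
  expect_true(all(diff(conn$tau) <= 0))
})

test_that("rank_drugs handles empty matrices and missing genes", {
  rm0 <- simulate_reference_matrix(n_drugs = 0, n_genes = 50, seed = 1)
  sig <- structure(list(up = "GENE00001", down = "GENE00002", n = 1L,
                        alpha = NA_real_), class = "gene_signature")
  expect_equal(nrow(rank_drugs(sig, rm0)), 0L)

  rm <- simulate_reference_matrix(n_drugs = 5, n_genes = 50, seed = 1)
  bad <- structure(list(up = c("GENE00001", "ABSENT1"), down = "GENE00002",
                        n = 2L, alpha = NA_real_), class = "gene_signature")
  expect_error(rank_drugs(bad, rm), "ABSENT1")
  ok <- rank_drugs(bad, rm, ignore_missing = TRUE)
  expect_equal(attr(ok, "n_dropped"), 1L)
  expect_equal(nrow(ok), 5L)
})

test_that("class enrichment reproduces hypergeometric closed forms", {
  ## build a ranked table by hand: 20 drugs, class of 5
  mk <- function(order_classes) {
    structure(data.frame(drug_id = sprintf("D%02d", seq_along(order_classes)),
                         class = order_classes,
                         es_up = 0, es_down = 0,
                         tau = seq(1, 0, length.out = length(order_classes)),
                         rank = seq_along(order_classes),
                         stringsAsFactors = FALSE),
              class = c("connectivity_table", "data.frame"))
  }
  ## all 5 class members occupy the top 5: p = 1 / C(20, 5)
  tab <- mk(c(rep("ppar", 5), rep(NA, 15)))
  e <- class_enrichment(tab, "ppar", top_k = 5)
  expect_equal(e$overlap, 5L)
  expect_equal(e$p_value, 1 / choose(20, 5))

  ## class absent from the top k: tail >= 0.5 when frequency matches
  tab2 <- mk(c(rep(NA, 15), rep("ppar", 5)))
  e2 <- class_enrichment(tab2, "ppar", top_k = 5)
  expect_equal(e2$overlap, 0L)
  expect_gte(e2$p_value, 0.5)

  ## top_k = n: overlap = class size, p = 1
  e3 <- class_enrichment(tab, "ppar", top_k = 20)
  expect_equal(e3$overlap, 5L)
  expect_equal(e3$p_value, 1)

  expect_error(class_enrichment(tab, "nonexistent"), "unknown class")
  expect_error(class_enrichment(tab, "ppar", top_k = 0), "top_k")
})

test_that("signature and reference files round-trip", {
  d <- simulate_de_table(n_genes = 200, n_up = 20, n_down = 20, seed = 2)
  f_de <- tempfile(fileext = ".tsv")
  write_de_tsv(d$de, f_de)
  expect_equal(read_de_tsv(f_de), d$de, tolerance = 1e-12)

  sig <- extract_signature(d$de, n = 20)
  f_sig <- tempfile(fileext = ".json")
  write_signature_json(sig, f_sig)
  back <- read_signature_json(f_sig)
  expect_identical(back$up, sig$up)
  expect_identical(back$down, sig$down)

  rm <- simulate_reference_matrix(n_drugs = 6, n_genes = 100,
                                  class_labels = c("a", "a", NA, NA, NA, NA),
                                  seed = 4)
  f_rm <- tempfile(fileext = ".tsv"); f_cl <- tempfile(fileext = ".tsv")
  write_reference_matrix(rm, f_rm, f_cl)
  back_rm <- read_reference_matrix(f_rm, f_cl)
  expect_identical(back_rm$ranks, rm$ranks)
  expect_identical(back_rm$classes, rm$classes)
})
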