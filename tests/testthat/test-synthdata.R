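# Generators: determinism, truth consistency, parameter validation and
# distributional structure.

test_that("screen simulation is deterministic and echoes planted truth", {
  cfg <- screen_sim_config(n_compounds = 50L, n_active = 4L,
                           rescue_effects = 1.5, n_toxic = 3L, seed = 7L)
  sim1 <- simulate_screen(cfg)
  sim2 <- simulate_screen(cfg)
  expect_identical(sim1$plates, sim2$plates)
  expect_identical(sim1$truth, sim2$truth)

  expect_length(sim1$truth$active_ids, 4L)
  expect_true(all(sim1$truth$effect_by_compound[sim1$truth$active_ids] == 1.5))
  ## every planted id exists in the generated dataset
  expect_true(all(sim1$truth$active_ids %in% sim1$plates$compound_id))
  expect_true(all(sim1$truth$toxic_ids %in% sim1$plates$compound_id))
  ## each compound appears once per replicate plate
  tab <- table(sim1$plates$compound_id[sim1$plates$role == "compound"])
  expect_true(all(tab == cfg$n_replicate_plates))
  ## scattered controls: >= 8 of each role per plate, interior positions
  ctrl <- sim1$plates[sim1$plates$role != "compound", ]
  per_plate <- table(ctrl$plate_id, ctrl$role)
  expect_true(all(per_plate >= 8))
  expect_true(all(ctrl$row > 1 & ctrl$row < 16 & ctrl$col > 1 & ctrl$col < 24))
})

test_that("all-null screen has one shared mean and compound means near 1", {
  cfg <- screen_sim_config(n_compounds = 300L, n_active = 0L, n_toxic = 0L,
                           dox_effect = 1, plate_factor_sd = 0, seed = 3L)
  sim <- simulate_screen(cfg)
  pl <- normalize_plates(sim$plates)
  sm <- summarize_compounds(pl)
  expect_equal(mean(sm$normalized_mean), 1, tolerance = 0.02)
  ## dox_effect = 1: no-dox and dox-only wells share the mean
  ctrl_means <- tapply(sim$plates$nuclei_count,
                       sim$plates$role, mean)
  expect_equal(unname(ctrl_means["no_dox_control"]),
               unname(ctrl_means["dox_only_control"]), tolerance = 0.05 * 2000)
})

test_that("null compound wells are indistinguishable from dox-only controls", {
  pass <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    cfg <- screen_sim_config(n_compounds = 100L, n_replicate_plates = 1L,
                             n_active = 0L, n_toxic = 0L, seed = s)
    sim <- simulate_screen(cfg)
    pl <- normalize_plates(sim$plates)
    p <- stats::t.test(pl$norm_count[pl$role == "compound"],
                       pl$norm_count[pl$role == "dox_only_control"])$p.value
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass / n_seeds, 0.95)
})

test_that("invalid screen configurations are rejected", {
  expect_error(screen_sim_config(n_compounds = -1), "n_compounds")
  expect_error(screen_sim_config(dox_effect = 0), "dox_effect")
  expect_error(screen_sim_config(dox_effect = 1.2), "dox_effect")
  expect_error(screen_sim_config(n_active = 10, n_toxic = 1300), "n_active")
  expect_error(screen_sim_config(rescue_effects = -2), "rescue_effects")
  expect_error(screen_sim_config(toxic_effects = 1.5), "toxic_effects")
  expect_error(screen_sim_config(n_controls_per_role = 4), "control")
  expect_error(screen_sim_config(baseline_count = 0), "baseline_count")
})

test_that("nuclei image generator places disjoint in-bounds nuclei reproducibly", {
  im0 <- simulate_nuclei_image(0, seed = 1)
  expect_equal(nrow(im0$truth$centers), 0L)
  expect_true(all(im0$image >= 0 & im0$image <= 1))

  im <- simulate_nuclei_image(10, shape = c(96, 96), seed = 2)
  ctr <- im$truth$centers
  expect_equal(nrow(ctr), 10L)
  expect_true(all(ctr$row > 0 & ctr$row <= 96 & ctr$col > 0 & ctr$col <= 96))
  d <- as.matrix(stats::dist(ctr[, c("row", "col")]))
  diag(d) <- Inf
  expect_true(all(d > ctr$radius[1] + ctr$radius[2]))

  im2 <- simulate_nuclei_image(10, shape = c(96, 96), seed = 2)
  expect_identical(im$image, im2$image)

  expect_error(simulate_nuclei_image(200, shape = c(48, 48)), "disjoint")
  expect_error(simulate_nuclei_image(1, shape = c(8, 8)), "shape")
})

test_that("DE table generator plants its truth and keeps nulls uniform", {
  d <- simulate_de_table(n_genes = 500, n_up = 20, n_down = 15,
                         lfc_magnitude = 2, seed = 9)
  expect_setequal(c(d$truth$up_genes, d$truth$down_genes),
                  d$de$gene[abs(d$de$lfc) >= 2])
  expect_true(all(d$de$lfc[d$de$gene %in% d$truth$up_genes] >= 2))
  expect_true(all(d$de$lfc[d$de$gene %in% d$truth$down_genes] <= -2))
  expect_true(all(d$de$pvalue[d$de$gene %in% d$truth$up_genes] < 1e-5))

  ## single planted gene tops the LFC ranking
  d1 <- simulate_de_table(n_genes = 50, n_up = 1, n_down = 0, seed = 4)
  expect_equal(d1$de$gene[which.max(d1$de$lfc)], d1$truth$up_genes)

  ## all-null tables: BH at 0.05 rarely rejects anything
  any_rej <- vapply(1:100, function(s) {
    dn <- simulate_de_table(n_genes = 200, n_up = 0, n_down = 0, seed = s)
    any(bh_adjust(dn$de$pvalue) < 0.05)
  }, logical(1))
  expect_lte(mean(any_rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("reference matrix: valid permutations, concordance limits, empty case", {
  rm <- simulate_reference_matrix(n_drugs = 12, n_genes = 300,
                                  class_labels = c(rep("a", 6), rep(NA, 6)),
                                  class_concordance = 0, seed = 5)
  expect_true(all(apply(rm$ranks, 2, function(r) setequal(r, 1:300))))
  ## concordance 0: within-class rank correlations are null
  cors <- stats::cor(rm$ranks[, 1:6], method = "spearman")
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.05)

  ## concordance 1: class members share one ranking exactly
  rm1 <- simulate_reference_matrix(n_drugs = 2, n_genes = 100,
                                   class_labels = c("a", "a"),
                                   class_concordance = 1, seed = 5)
  expect_identical(rm1$ranks[, 1], rm1$ranks[, 2])

  rm0 <- simulate_reference_matrix(n_drugs = 0, n_genes = 10, seed = 1)
  expect_equal(ncol(rm0$ranks), 0L)
  expect_error(simulate_reference_matrix(class_concordance = 2), "concordance")
})

test_that("competition generator follows the logistic decline", {
  ## closed form: p0 = 0.5, s = 0.2, t = 5 -> e^-1 / (e^-1 + 1)
  p5 <- 0.5 * exp(-1) / (0.5 * exp(-1) + 0.5)
  expect_equal(p5, exp(-1) / (exp(-1) + 1))
  sim <- simulate_competition(p0 = 0.5, s = 0.2, days = c(0, 5),
                              n_cells_sampled = 1e6, seed = 1)
  obs <- sim$series$q94_count / 1e6
  expect_equal(obs[2], p5, tolerance = 3 * sqrt(p5 * (1 - p5) / 1e6) / p5)

  ## s = 0: proportion stays at p0 in expectation
  s0 <- simulate_competition(p0 = 0.3, s = 0, days = c(0, 5, 15),
                             n_cells_sampled = 1e6, seed = 2)
  expect_equal(s0$series$q94_count / 1e6, rep(0.3, 3), tolerance = 0.01)

  ## s > 0: expressing fraction declines
  sd <- simulate_competition(p0 = 0.5, s = 0.2, days = c(0, 5, 15),
                             n_cells_sampled = 1e5, seed = 3)
  expect_true(all(diff(sd$series$q94_count) < 0))
  expect_identical(sd$truth$s, 0.2)

  expect_error(simulate_competition(p0 = 0), "p0")
  expect_error(simulate_competition(days = c(1, 5)), "days")
})

test_that("survival and bend generators respect their degenerate limits", {
  s0 <- simulate_survival(c(a = 0, b = 1), n_eggs = 20, n_replicates = 3,
                          seed = 1)
  expect_true(all(s0$survival$n_dead[s0$survival$arm == "a"] == 0))
  expect_true(all(s0$survival$n_dead[s0$survival$arm == "b"] == 20))
  expect_equal(sum(s0$survival$arm == "a"), 3L)

  b0 <- simulate_bends(c(x = 0), n_worms = 10, seed = 1)
  expect_true(all(b0$bends$bends_30s == 0))
  ## CLT: sample mean within 3 SEs of the Poisson rate
  b <- simulate_bends(c(x = 12), n_worms = 2000, seed = 2)
  expect_lt(abs(mean(b$bends$bends_30s) - 12), 3 * sqrt(12 / 2000))
  b2 <- simulate_bends(c(x = 12), n_worms = 2000, seed = 2)
  expect_identical(b$bends, b2$bends)

  expect_error(simulate_survival(c(a = 1.5)), "death_prob")
  expect_error(simulate_bends(c(a = -1)), "mean_bends")
})

test_that("substreams are independent and stable under a shared master seed", {
  s1 <- substream_seed(42, "screen")
  expect_identical(s1, substream_seed(42, "screen"))
  expect_false(s1 == substream_seed(42, "bends"))
  expect_false(s1 == substream_seed(43, "screen"))
  expect_true(s1 >= 0 && s1 < 2^31)
})
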