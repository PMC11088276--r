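# Plate normalization, control statistics, hit calling, dose-response
# validation and QC.

test_that("normalization divides by the plate's dox-only control mean", {
  pl <- tiny_plate(ctrl_counts = rep(200, 8), compound_counts = c(260, 150))
  norm <- normalize_plates(pl)
  expect_equal(norm$norm_count[norm$compound_id == "CMP0001"], 1.30)
  ## control definition: mean normalized dox-only value is exactly 1
  expect_equal(mean(norm$norm_count[norm$role == "dox_only_control"]), 1)

  ## scale invariance: multiplying a whole plate by c changes nothing
  pl2 <- pl; pl2$nuclei_count <- pl2$nuclei_count * 7.3
  expect_equal(normalize_plates(pl2)$norm_count, norm$norm_count)

  ## degenerate plate: zero control mean
  pl0 <- tiny_plate(ctrl_counts = rep(0, 8), compound_counts = 100)
  expect_error(normalize_plates(pl0), "zero")
})

test_that("normalization is strictly per plate", {
  a <- tiny_plate(rep(100, 8), c(110, 120), plate_id = "P001_R1")
  b <- tiny_plate(rep(400, 8), c(440, 480), plate_id = "P001_R2")
  b$replicate <- 2L
  norm <- normalize_plates(rbind(a, b))
  ## same relative effect on both plates despite 4x raw difference
  expect_equal(norm$norm_count[norm$role == "compound"],
               c(1.1, 1.2, 1.1, 1.2))
})

test_that("compound summaries are unweighted means over replicates", {
  a <- tiny_plate(rep(100, 8), c(120, 150), plate_id = "P001_R1")
  b <- tiny_plate(rep(100, 8), c(130, 150), plate_id = "P001_R2")
  c3 <- tiny_plate(rep(100, 8), c(140, 150), plate_id = "P001_R3")
  b$replicate <- 2L; c3$replicate <- 3L
  sm <- summarize_compounds(normalize_plates(rbind(a, b, c3)))
  expect_equal(sm$normalized_mean[sm$compound_id == "CMP0001"], 1.3)
  expect_equal(sm$normalized_mean[sm$compound_id == "CMP0002"], 1.5)
  expect_equal(sm$n_replicates, c(3L, 3L))

  ## single replicate passes through with n = 1
  sm1 <- summarize_compounds(normalize_plates(a))
  expect_equal(sm1$normalized_mean, c(1.2, 1.5))
  expect_equal(sm1$n_replicates, c(1L, 1L))
})

test_that("control statistics match hand-computed values", {
  pl <- suppressWarnings(normalize_plates(
    tiny_plate(ctrl_counts = c(90, 110), compound_counts = 100)))
  cs <- suppressWarnings(control_stats(pl))
  expect_equal(cs$mu, 1)
  expect_equal(cs$sigma, sqrt(((0.9 - 1)^2 + (1.1 - 1)^2) / 1) / 1,
               tolerance = 1e-12)  # sample SD of {0.9, 1.1} = 0.1414...
  expect_equal(cs$sigma, 0.1414214, tolerance = 1e-6)

  ## all controls equal: sigma 0
  pl0 <- normalize_plates(tiny_plate(rep(100, 8), 100))
  cs0 <- control_stats(pl0)
  expect_equal(cs0$mu, 1)
  expect_equal(cs0$sigma, 0)

  ## MAD resists a planted outlier where the SD does not
  counts <- c(95, 97, 99, 100, 101, 103, 105, 400)
  pln <- normalize_plates(tiny_plate(counts, 100))
  s_sd <- control_stats(pln, estimator = "sd")$sigma
  s_mad <- control_stats(pln, estimator = "mad")$sigma
  expect_lt(s_mad, s_sd)

  expect_error(control_stats(normalize_plates(
    tiny_plate(rep(100, 8), 100))[1, ]), "control")
})

test_that("hit calls use a strict one-sided threshold with sorted margins", {
  pl <- normalize_plates(tiny_plate(rep(100, 8), c(135, 130, 128, 60)))
  cs <- control_stats(pl)
  cs$mu <- 1.0; cs$sigma <- 0.1  # pin exact stats for arithmetic check
  hits <- call_hits(summarize_compounds(pl), cs)
  expect_equal(unique(hits$threshold), 1.3)
  expect_identical(hits$is_hit, c(TRUE, FALSE, FALSE, FALSE))
  ## exactly at threshold: not a hit (strict inequality)
  expect_equal(hits$normalized_mean[2], 1.30)
  expect_false(hits$is_hit[2])
  ## margins sorted descending
  expect_true(all(diff(hits$margin) <= 0))
  ## strong decrease can never be a hit (one-sided rule)
  expect_false(hits$is_hit[hits$normalized_mean == 0.6])

  ## sigma = 0 is legal and flagged: threshold collapses to mu
  cs0 <- cs; cs0$sigma <- 0
  h0 <- call_hits(summarize_compounds(pl), cs0)
  expect_true(attr(h0, "degenerate_sigma"))
  expect_equal(unique(h0$threshold), 1.0)
})

test_that("plate-factor immunity: multiplicative plate factors change no call", {
  cfg <- screen_sim_config(n_compounds = 200L, seed = 5L)
  sim <- simulate_screen(cfg)
  base <- sim$plates
  hits0 <- call_hits(summarize_compounds(normalize_plates(base)),
                     control_stats(normalize_plates(base)))
  set.seed(99)
  factors <- exp(stats::rnorm(length(unique(base$plate_id)), 0, 0.3))
  names(factors) <- unique(base$plate_id)
  warped <- base
  warped$nuclei_count <- base$nuclei_count * factors[base$plate_id]
  hitsw <- call_hits(summarize_compounds(normalize_plates(warped)),
                     control_stats(normalize_plates(warped)))
  expect_identical(hits0$compound_id[hits0$is_hit],
                   hitsw$compound_id[hitsw$is_hit])
})

test_that("dose-response validation applies the >=2-significant-doses rule", {
  cfg <- screen_sim_config(n_compounds = 20L, n_active = 2L,
                           rescue_effects = 1.6, n_toxic = 2L,
                           toxic_effects = 0.5, seed = 13L)
  sim <- simulate_screen(cfg)
  cand <- c(sim$truth$active_ids, sim$truth$toxic_ids,
            setdiff(sim$plates$compound_id[sim$plates$role == "compound"],
                    c(sim$truth$active_ids, sim$truth$toxic_ids))[1])
  vsim <- simulate_validation_screen(cfg, cand, sim$truth)
  res <- validate_dose_response(vsim$plates)
  pc <- res$per_compound
  ## strong rescuers validate; nulls and toxics do not (direction gate)
  expect_true(all(pc$validated[pc$compound_id %in% sim$truth$active_ids]))
  expect_false(any(pc$validated[pc$compound_id %in% sim$truth$toxic_ids]))
  ## toxic compounds decrease counts at every dose, so no dose counts as
  ## a significant increase
  tox <- res$per_dose[res$per_dose$compound_id %in% sim$truth$toxic_ids, ]
  expect_false(any(tox$significant))
  ## per-dose table covers all four doses per compound
  expect_equal(sort(unique(res$per_dose$dose_uM)), c(0.5, 1, 3, 10))

  ## Holm fallback (per-dose Welch t vs control, Holm-adjusted) also
  ## rejects the toxic compounds; with only 3 wells per dose it has less
  ## power than the pooled-variance Dunnett contrasts, so agreement on
  ## every rescuer is not asserted
  res_h <- validate_dose_response(vsim$plates, method = "holm")
  pch <- res_h$per_compound
  expect_false(any(pch$validated[pch$compound_id %in% sim$truth$toxic_ids]))
  expect_identical(pch$compound_id, pc$compound_id)
})

test_that("a compound significant at exactly one dose is not validated", {
  ## construct validation wells directly: effect only at the highest dose
  mk <- function(dose, vals, id = "CMP0001") {
    n <- length(vals)
    data.frame(plate_id = sprintf("P001_R%d", seq_len(n)), layout = 1L,
               replicate = seq_len(n), well = "B02", row = 2L, col = 2L,
               role = "compound", compound_id = id, dose_uM = dose,
               nuclei_count = vals, stringsAsFactors = FALSE)
  }
  set.seed(1)
  ctrl <- do.call(rbind, lapply(1:3, function(r) {
    p <- tiny_plate(round(stats::rnorm(10, 100, 3)), numeric(0),
                    plate_id = sprintf("P001_R%d", r))
    p$replicate <- r
    p
  }))
  jitter <- function(m, n = 3) round(stats::rnorm(n, m, 3))
  wells <- rbind(ctrl,
                 mk(0.5, jitter(100)), mk(1, jitter(101)),
                 mk(3, jitter(99)), mk(10, jitter(160)))
  res <- validate_dose_response(wells)
  expect_equal(res$per_compound$n_significant_doses, 1L)
  expect_false(res$per_compound$validated)
})

test_that("Z' factor matches its formula and flags degenerate plates", {
  ## exact formula case: means 2 and 1, both SDs 0.1 -> Z' = 0.4
  mk_ctrl <- function(role, vals) {
    n <- length(vals)
    data.frame(plate_id = "P1", layout = 1L, replicate = 1L,
               well = sprintf("C%02d", seq_len(n) + 1), row = 3L,
               col = seq_len(n) + 1, role = role, compound_id = "",
               dose_uM = NA_real_, nuclei_count = vals,
               stringsAsFactors = FALSE)
  }
  ## two-point samples with exact mean/SD: mean +- sd/sqrt(2)... use
  ## {m - s, m + s} which has sample SD = s * sqrt(2); pick s accordingly
  s <- 0.1 / sqrt(2)
  pl <- rbind(mk_ctrl("no_dox_control", c(2 - s, 2 + s) * 100),
              mk_ctrl("dox_only_control", c(1 - s, 1 + s) * 100))
  z <- zprime(pl)
  expect_equal(z$zprime, 1 - 3 * (0.1 + 0.1) / 1, tolerance = 1e-12)
  expect_false(z$undefined)

  ## perfect separation with zero spread: Z' = 1
  pl1 <- rbind(mk_ctrl("no_dox_control", rep(200, 4)),
               mk_ctrl("dox_only_control", rep(100, 4)))
  expect_equal(zprime(pl1)$zprime, 1)

  ## identical control distributions: undefined, flagged
  pl2 <- rbind(mk_ctrl("no_dox_control", c(100, 110, 90)),
               mk_ctrl("dox_only_control", c(100, 110, 90)))
  z2 <- zprime(pl2)
  expect_true(z2$undefined)
  expect_true(is.na(z2$zprime))
})

test_that("QC report surfaces a planted edge artifact", {
  cfg <- screen_sim_config(n_compounds = 340L, edge_effect = 0.8,
                           n_active = 0L, n_toxic = 0L, seed = 8L)
  sim <- simulate_screen(cfg)
  qc <- qc_report(normalize_plates(sim$plates))
  expect_equal(qc$edge_ratio, 0.8, tolerance = 0.05)
  expect_true(all(qc$zprime$zprime <= 1, na.rm = TRUE))
  ## clean assay: ratio near 1
  cfg1 <- screen_sim_config(n_compounds = 340L, edge_effect = 1,
                            n_active = 0L, n_toxic = 0L, seed = 8L)
  qc1 <- qc_report(normalize_plates(simulate_screen(cfg1)$plates))
  expect_equal(qc1$edge_ratio, 1, tolerance = 0.05)
})

test_that("plate CSV round-trips including empty compound ids", {
  sim <- simulate_screen(screen_sim_config(n_compounds = 30L, seed = 2L))
  f <- tempfile(fileext = ".csv")
  write_plate_csv(sim$plates, f)
  back <- read_plate_csv(f)
  expect_equal(back, sim$plates)
})
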