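# Seeded generators for every input the screening pipeline consumes, each
# returning the generated dataset together with a ground-truth record so
# recovery can be tested.

.fail_param <- function(...) stop(sprintf(...), call. = FALSE)

#' Configuration for a simulated Htt-Q94 suppressor screen
#'
#' Describes the geometry and noise model of an image-based viability screen
#' in multiwell plates: an inducible toxic protein (dox-dependent) reduces
#' well-level nuclei counts; library compounds may rescue (multiplicative
#' effect > 1) or add toxicity (< 1). Controls of both roles (no-dox, and
#' dox-only without compound) are scattered across interior wells of every
#' plate. Counts are negative-binomial around a multiplicative mean
#' structure: `baseline * dox_effect^[dox] * effect * plate_factor *
#' edge_factor`.
#'
#' The defaults emulate the screen design this package targets: 1216
#' compounds (1122 approved drugs plus 94 epigenetic compounds) in
#' triplicate 384-well plates at a single 1 uM dose, roughly 10% coefficient
#' of variation in dox-only control wells.
#'
#' @param n_compounds Number of library compounds.
#' @param n_replicate_plates Replicate plates per layout (triplicate by
#'   default; the compound summary is the mean across these).
#' @param plate_format Wells per plate, 96 or 384.
#' @param doses Numeric vector of doses in uM; each compound occupies one
#'   well per dose per replicate plate.
#' @param baseline_count Expected nuclei in a no-dox control well after the
#'   growth period.
#' @param dox_effect Multiplicative viability factor in (0, 1] applied to
#'   every dox-exposed well (the toxic-protein effect).
#' @param n_active,rescue_effects Number of planted rescuers and their
#'   multiplicative effects (scalar or length `n_active`), each in
#'   (0, 1/dox_effect].
#' @param n_toxic,toxic_effects Number of planted extra-toxic compounds and
#'   their multiplicative effects in (0, 1).
#' @param plate_factor_sd SD (log scale) of the per-plate log-normal
#'   multiplicative factor.
#' @param edge_effect Multiplicative factor applied to border wells
#'   (evaporation-style growth penalty; controls are interior by design).
#'   Default 1 (clean assay); set below 1 to plant the classic edge
#'   artifact and exercise the QC edge diagnostic.
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param noise_model `"negbin"` (default; overdispersed counts, the
#'   realistic choice after a week of growth) or `"gaussian"` (symmetric
#'   well noise with SD `gaussian_cv * mean`, rounded to integer counts -
#'   the idealized model under which the k-SD rule's null tail is exactly
#'   the normal tail).
#' @param gaussian_cv Coefficient of variation of the Gaussian noise model.
#' @param n_controls_per_role Scattered control wells of each role per
#'   plate (minimum 8).
#' @param compound_ids Optional explicit compound identifiers (length
#'   `n_compounds`).
#' @param active_ids Optional explicit identities for the planted rescuers;
#'   sampled from the library when `NULL`.
#' @param effect_overrides Optional named numeric vector of per-compound
#'   multiplicative effects that overrides the planted assignment (used to
#'   carry primary-screen truth into a validation screen).
#' @param seed Integer master RNG seed.
#' @return An object of class `screen_sim_config` (a validated list).
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_compounds = 1216L,
                              n_replicate_plates = 3L,
                              plate_format = 384L,
                              doses = 1,
                              baseline_count = 2000,
                              dox_effect = 0.5,
                              n_active = 4L,
                              rescue_effects = 1.5,
                              n_toxic = 10L,
                              toxic_effects = 0.5,
                              plate_factor_sd = 0.1,
                              edge_effect = 1,
                              dispersion = 111.1,
                              noise_model = c("negbin", "gaussian"),
                              gaussian_cv = 0.1,
                              n_controls_per_role = 16L,
                              compound_ids = NULL,
                              active_ids = NULL,
                              effect_overrides = NULL,
                              seed = 1L) {
  if (!plate_format %in% c(96L, 384L))
    .fail_param("plate_format must be 96 or 384, got %s", plate_format)
  if (n_compounds < 1) .fail_param("n_compounds must be >= 1")
  if (n_replicate_plates < 1) .fail_param("n_replicate_plates must be >= 1")
  if (length(doses) < 1 || any(doses <= 0))
    .fail_param("doses must be positive concentrations in uM")
  if (baseline_count <= 0) .fail_param("baseline_count must be > 0")
  if (dox_effect <= 0 || dox_effect > 1)
    .fail_param("dox_effect must be in (0, 1]")
  if (n_active < 0 || n_toxic < 0 || n_active + n_toxic > n_compounds)
    .fail_param("need n_active + n_toxic <= n_compounds, both nonnegative")
  if (n_active > 0 && (any(rescue_effects <= 0) ||
                       any(rescue_effects > 1 / dox_effect + 1e-12)))
    .fail_param("rescue_effects must lie in (0, 1/dox_effect]")
  if (n_toxic > 0 && (any(toxic_effects <= 0) || any(toxic_effects >= 1)))
    .fail_param("toxic_effects must lie in (0, 1)")
  if (plate_factor_sd < 0) .fail_param("plate_factor_sd must be >= 0")
  if (edge_effect <= 0) .fail_param("edge_effect must be > 0")
  if (is.na(dispersion) || dispersion <= 0)
    .fail_param("dispersion must be > 0 (Inf for Poisson)")
  noise_model <- match.arg(noise_model)
  if (gaussian_cv <= 0) .fail_param("gaussian_cv must be > 0")
  if (n_controls_per_role < 8)
    .fail_param("scattered-control design needs >= 8 control wells per role")
  if (!is.null(compound_ids) && length(compound_ids) != n_compounds)
    .fail_param("compound_ids must have length n_compounds")
  if (!is.null(active_ids) && length(active_ids) != n_active)
    .fail_param("active_ids must have length n_active")

  nr <- if (plate_format == 384L) 16L else 8L
  nc <- if (plate_format == 384L) 24L else 12L
  if (2L * n_controls_per_role >= (nr - 2L) * (nc - 2L))
    .fail_param("too many control wells for the plate interior")

  structure(list(
    n_compounds = as.integer(n_compounds),
    n_replicate_plates = as.integer(n_replicate_plates),
    plate_format = as.integer(plate_format),
    plate_rows = nr, plate_cols = nc,
    doses = as.numeric(doses),
    baseline_count = baseline_count,
    dox_effect = dox_effect,
    n_active = as.integer(n_active),
    rescue_effects = rescue_effects,
    n_toxic = as.integer(n_toxic),
    toxic_effects = toxic_effects,
    plate_factor_sd = plate_factor_sd,
    edge_effect = edge_effect,
    dispersion = dispersion,
    noise_model = noise_model,
    gaussian_cv = gaussian_cv,
    n_controls_per_role = as.integer(n_controls_per_role),
    compound_ids = compound_ids,
    active_ids = active_ids,
    effect_overrides = effect_overrides,
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat(sprintf(
    "screen_sim_config: %d compounds x %d dose(s), %d-well plates x %d replicates\n",
    x$n_compounds, length(x$doses), x$plate_format, x$n_replicate_plates))
  cat(sprintf("  planted: %d rescuers, %d toxic; dox effect %.2f; seed %d\n",
              x$n_active, x$n_toxic, x$dox_effect, x$seed))
  invisible(x)
}

.well_label <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Simulate a plate-based suppressor screen with planted ground truth
#'
#' Generates well-level nuclei counts for a complete screen. Compounds (at
#' every dose) are laid out across as many plate layouts as needed, each
#' layout replicated `n_replicate_plates` times; scattered interior control
#' wells of both roles are placed per layout at seed-determined positions.
#' Counts are drawn from a negative binomial with mean
#' `baseline_count * dox_effect^[dox] * effect_c * plate_factor *
#' edge_factor`.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements:
#'   \describe{
#'     \item{plates}{data.frame with columns `plate_id, layout, replicate,
#'       well, row, col, role, compound_id, dose_uM, nuclei_count`. Roles
#'       are `no_dox_control`, `dox_only_control`, `compound`;
#'       `compound_id` is `""` for controls.}
#'     \item{truth}{`sim_truth` record: `active_ids`, `toxic_ids`,
#'       `effect_by_compound` (named vector over the whole library).}
#'   }
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  cfg <- config
  nr <- cfg$plate_rows; nc <- cfg$plate_cols
  wp <- nr * nc
  nctrl <- cfg$n_controls_per_role
  per_layout <- wp - 2L * nctrl
  n_doses <- length(cfg$doses)
  slots_needed <- cfg$n_compounds * n_doses
  n_layouts <- ceiling(slots_needed / per_layout)

  ids <- cfg$compound_ids
  if (is.null(ids)) ids <- sprintf("CMP%04d", seq_len(cfg$n_compounds))
  if (anyDuplicated(ids)) .fail_param("compound identifiers must be unique")

  row_of <- rep(seq_len(nr), times = nc)
  col_of <- rep(seq_len(nc), each = nr)
  interior <- which(row_of > 1L & row_of < nr & col_of > 1L & col_of < nc)

  with_substream(cfg$seed, "screen", {
    ## planted effects over the library
    effects <- rep(1, cfg$n_compounds)
    names(effects) <- ids
    if (!is.null(cfg$active_ids)) {
      if (!all(cfg$active_ids %in% ids))
        .fail_param("active_ids must be drawn from the compound library")
      active <- cfg$active_ids
    } else {
      active <- if (cfg$n_active > 0) sample(ids, cfg$n_active) else character()
    }
    toxic_pool <- setdiff(ids, active)
    toxic <- if (cfg$n_toxic > 0) sample(toxic_pool, cfg$n_toxic) else character()
    if (length(active)) effects[active] <- rep(cfg$rescue_effects, length.out = length(active))
    if (length(toxic)) effects[toxic] <- rep(cfg$toxic_effects, length.out = length(toxic))
    if (!is.null(cfg$effect_overrides)) {
      ov <- cfg$effect_overrides
      if (is.null(names(ov)) || !all(names(ov) %in% ids))
        .fail_param("effect_overrides must be named by library compound ids")
      effects[names(ov)] <- ov
    }

    ## per-layout well assignment (shared by that layout's replicate plates)
    lay_layout <- lay_well <- vector("list", n_layouts)
    lay_role <- lay_slot <- vector("list", n_layouts)
    slot_cursor <- 0L
    for (l in seq_len(n_layouts)) {
      ctrl_pos <- sample(interior, 2L * nctrl)
      comp_pos <- setdiff(seq_len(wp), ctrl_pos)
      k <- min(per_layout, slots_needed - slot_cursor)
      comp_pos <- comp_pos[seq_len(k)]
      lay_layout[[l]] <- rep.int(l, 2L * nctrl + k)
      lay_well[[l]] <- c(ctrl_pos, comp_pos)
      lay_role[[l]] <- c(rep("dox_only_control", nctrl),
                         rep("no_dox_control", nctrl),
                         rep("compound", k))
      lay_slot[[l]] <- c(rep.int(NA_integer_, 2L * nctrl),
                         slot_cursor + seq_len(k))
      slot_cursor <- slot_cursor + k
    }
    layout <- unlist(lay_layout); wellpos <- unlist(lay_well)
    role <- unlist(lay_role); slot <- unlist(lay_slot)

    comp_idx <- ifelse(is.na(slot), NA_integer_, (slot - 1L) %/% n_doses + 1L)
    dose_idx <- ifelse(is.na(slot), NA_integer_, (slot - 1L) %% n_doses + 1L)
    compound_id <- ifelse(is.na(comp_idx), "", ids[comp_idx])
    dose <- ifelse(is.na(dose_idx), NA_real_, cfg$doses[dose_idx])

    ## replicate the layouts into physical plates
    nrep <- cfg$n_replicate_plates
    n_base <- length(wellpos)
    rep_id <- rep(seq_len(nrep), each = n_base)
    layout_r <- rep(layout, times = nrep)
    wellpos_r <- rep(wellpos, times = nrep)
    role_r <- rep(role, times = nrep)
    compound_r <- rep(compound_id, times = nrep)
    dose_r <- rep(dose, times = nrep)

    plate_factor <- matrix(
      exp(stats::rnorm(n_layouts * nrep, 0, cfg$plate_factor_sd)),
      nrow = n_layouts)
    pf <- plate_factor[cbind(layout_r, rep_id)]

    rw <- row_of[wellpos_r]; cl <- col_of[wellpos_r]
    on_edge <- rw == 1L | rw == nr | cl == 1L | cl == nc
    ef <- ifelse(on_edge, cfg$edge_effect, 1)

    eff <- rep(1, length(role_r))
    is_comp <- role_r == "compound"
    eff[is_comp] <- effects[compound_r[is_comp]]
    doxed <- role_r != "no_dox_control"
    mu <- cfg$baseline_count * ifelse(doxed, cfg$dox_effect, 1) * eff * pf * ef

    counts <- switch(cfg$noise_model,
      negbin = if (is.infinite(cfg$dispersion)) stats::rpois(length(mu), mu)
               else stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu),
      gaussian = pmax(round(stats::rnorm(length(mu), mu, cfg$gaussian_cv * mu)), 0))

    plates <- data.frame(
      plate_id = sprintf("P%03d_R%d", layout_r, rep_id),
      layout = layout_r,
      replicate = rep_id,
      well = .well_label(rw, cl),
      row = rw, col = cl,
      role = role_r,
      compound_id = compound_r,
      dose_uM = dose_r,
      nuclei_count = counts,
      stringsAsFactors = FALSE
    )
    o <- order(plates$layout, plates$replicate, plates$row, plates$col)
    plates <- plates[o, , drop = FALSE]
    rownames(plates) <- NULL

    truth <- structure(list(
      active_ids = sort(active),
      toxic_ids = sort(toxic),
      effect_by_compound = effects
    ), class = "sim_truth")
    structure(list(plates = plates, truth = truth, config = cfg),
              class = "screen_sim")
  })
}

#' Simulate the dose-response validation stage for a set of candidates
#'
#' Convenience wrapper building a multi-dose screen restricted to candidate
#' compounds, carrying forward their true effects from a primary-screen
#' truth record. Uses an RNG substream distinct from the primary screen so
#' the two stages are independent draws under one master seed.
#'
#' @param config The primary [screen_sim_config()] (supplies the noise
#'   model and seed).
#' @param compound_ids Candidates to re-test.
#' @param truth The primary screen's `sim_truth` (source of true effects).
#' @param doses Validation doses in uM.
#' @return A `screen_sim` list, as [simulate_screen()].
#' @export
simulate_validation_screen <- function(config, compound_ids, truth,
                                       doses = c(0.5, 1, 3, 10)) {
  stopifnot(inherits(config, "screen_sim_config"),
            inherits(truth, "sim_truth"))
  if (length(compound_ids) == 0)
    return(structure(list(
      plates = data.frame(), truth = truth, config = config),
      class = "screen_sim"))
  eff <- truth$effect_by_compound[compound_ids]
  vcfg <- screen_sim_config(
    n_compounds = length(compound_ids),
    n_replicate_plates = config$n_replicate_plates,
    plate_format = config$plate_format,
    doses = doses,
    baseline_count = config$baseline_count,
    dox_effect = config$dox_effect,
    n_active = 0L, n_toxic = 0L,
    plate_factor_sd = config$plate_factor_sd,
    edge_effect = config$edge_effect,
    dispersion = config$dispersion,
    noise_model = config$noise_model,
    gaussian_cv = config$gaussian_cv,
    n_controls_per_role = config$n_controls_per_role,
    compound_ids = compound_ids,
    effect_overrides = eff,
    seed = substream_seed(config$seed, "validation")
  )
  sim <- simulate_screen(vcfg)
  sim$truth$active_ids <- intersect(truth$active_ids, compound_ids)
  sim$truth$toxic_ids <- intersect(truth$toxic_ids, compound_ids)
  sim
}

#' Simulate a nuclear-stain image with known nuclei positions
#'
#' Renders Gaussian-profile nuclei on a noisy background, emulating a
#' Hoechst-stained field. Under the `"disjoint"` overlap policy all pairwise
#' centre distances exceed the sum of the two nuclei's radii and every
#' nucleus lies fully inside the image with a safety margin.
#'
#' @param n_nuclei Number of nuclei to place (may be 0).
#' @param shape Integer length-2 image size (rows, cols), each >= 16.
#' @param intensity_params List with elements `amplitude` (peak intensity,
#'   0-1 scale), `radius` (nominal nucleus radius, px), `background` (mean
#'   background level), `noise_sd` (additive Gaussian noise SD).
#' @param overlap_policy `"disjoint"` (default) or `"free"`.
#' @param seed Integer RNG seed.
#' @return List with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (`sim_truth` holding a `centers` data.frame: `row, col, radius`).
#' @export
simulate_nuclei_image <- function(n_nuclei,
                                  shape = c(96L, 96L),
                                  intensity_params = list(),
                                  overlap_policy = c("disjoint", "free"),
                                  seed = 1L) {
  overlap_policy <- match.arg(overlap_policy)
  if (n_nuclei < 0) .fail_param("n_nuclei must be >= 0")
  if (length(shape) != 2 || any(shape < 16))
    .fail_param("shape must be two dimensions, each >= 16")
  p <- utils::modifyList(
    list(amplitude = 0.7, radius = 5, background = 0.08, noise_sd = 0.015),
    intensity_params)
  if (p$radius <= 0 || p$amplitude <= 0)
    .fail_param("radius and amplitude must be > 0")

  nrw <- as.integer(shape[1]); ncl <- as.integer(shape[2])
  margin <- 2 * p$radius + 1
  if (n_nuclei > 0 && (nrw - 2 * margin < 1 || ncl - 2 * margin < 1))
    .fail_param("image shape %dx%d too small for nuclei of radius %.1f",
                nrw, ncl, p$radius)

  with_substream(seed, "nuclei_image", {
    centers <- matrix(numeric(0), ncol = 2)
    if (n_nuclei > 0) {
      max_tries <- 5000L * n_nuclei
      tries <- 0L
      while (nrow(centers) < n_nuclei) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop(sprintf(
            "could not place %d disjoint nuclei of radius %.1f in a %dx%d image",
            n_nuclei, p$radius, nrw, ncl), call. = FALSE)
        cand <- c(stats::runif(1, margin, nrw - margin),
                  stats::runif(1, margin, ncl - margin))
        ok <- TRUE
        if (overlap_policy == "disjoint" && nrow(centers) > 0) {
          d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2
          ok <- all(d2 > (2 * p$radius)^2)
        }
        if (ok) centers <- rbind(centers, cand)
      }
    }
    img <- matrix(p$background, nrw, ncl)
    sigma <- p$radius / 2
    if (n_nuclei > 0) {
      half <- ceiling(3 * sigma)
      for (i in seq_len(nrow(centers))) {
        cr <- centers[i, 1]; cc <- centers[i, 2]
        rs <- max(1L, floor(cr - half)):min(nrw, ceiling(cr + half))
        cs <- max(1L, floor(cc - half)):min(ncl, ceiling(cc + half))
        g <- outer(exp(-(rs - cr)^2 / (2 * sigma^2)),
                   exp(-(cs - cc)^2 / (2 * sigma^2)))
        img[rs, cs] <- img[rs, cs] + p$amplitude * g
      }
    }
    img <- img + matrix(stats::rnorm(nrw * ncl, 0, p$noise_sd), nrw, ncl)
    img <- pmin(pmax(img, 0), 1)
    truth <- structure(list(
      centers = data.frame(row = centers[, 1], col = centers[, 2],
                           radius = rep(p$radius, n_nuclei))
    ), class = "sim_truth")
    list(image = img, truth = truth)
  })
}

#' Simulate a differential-expression result table
#'
#' Emulates the output of a count-model DE analysis (the DE fit itself is
#' out of scope): null genes get near-zero log2 fold-changes and uniform
#' p-values, planted genes get `|LFC| >= lfc_magnitude` and very small
#' p-values.
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param lfc_magnitude Minimum absolute LFC of planted genes.
#' @param seed Integer RNG seed.
#' @return List with `de` (data.frame `gene, lfc, pvalue`) and `truth`
#'   (`sim_truth` with `up_genes`, `down_genes`).
#' @export
simulate_de_table <- function(n_genes = 5000L, n_up = 300L, n_down = 300L,
                              lfc_magnitude = 2, seed = 1L) {
  if (n_up + n_down > n_genes)
    .fail_param("n_up + n_down must not exceed n_genes")
  if (lfc_magnitude <= 0) .fail_param("lfc_magnitude must be > 0")
  with_substream(seed, "de_table", {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    lfc <- stats::rnorm(n_genes, 0, 0.15)
    pval <- stats::runif(n_genes)
    planted <- if (n_up + n_down > 0) sample(n_genes, n_up + n_down) else integer()
    up <- planted[seq_len(n_up)]
    down <- planted[n_up + seq_len(n_down)]
    if (n_up > 0) {
      lfc[up] <- lfc_magnitude + stats::rexp(n_up, 2)
      pval[up] <- 10^-stats::runif(n_up, 6, 12)
    }
    if (n_down > 0) {
      lfc[down] <- -(lfc_magnitude + stats::rexp(n_down, 2))
      pval[down] <- 10^-stats::runif(n_down, 6, 12)
    }
    truth <- structure(list(up_genes = sort(genes[up]),
                            down_genes = sort(genes[down])),
                       class = "sim_truth")
    list(de = data.frame(gene = genes, lfc = lfc, pvalue = pval,
                         stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate a reference drug-signature rank matrix
#'
#' Desk-scale emulation of a drug transcriptional-signature database: each
#' drug carries a full ranking of the gene universe (rank 1 = most
#' up-regulated). Drugs sharing a class label draw on a shared latent
#' gene-score vector; `class_concordance` in `[0, 1]` sets the fraction of
#' score variance coming from the class latent (0 = independent rankings).
#' Unlabelled drugs (`NA` class) are always independent.
#'
#' An `anchor_signature` ties one class's latent scores to a query
#' signature (its up genes score high, down genes low), planting a drug
#' class whose members genuinely resemble that signature.
#'
#' @param n_drugs Number of reference drugs.
#' @param genes Character gene universe, or `NULL` to generate
#'   `n_genes` synthetic identifiers.
#' @param n_genes Size of the generated universe when `genes` is `NULL`.
#' @param class_labels Character vector of length `n_drugs` (NA =
#'   unlabelled); default all unlabelled.
#' @param class_concordance Within-class ranking concordance in `[0, 1]`.
#' @param anchor_signature Optional [gene_signature] anchoring
#'   `anchor_class`.
#' @param anchor_class Label of the class tied to `anchor_signature`.
#' @param seed Integer RNG seed.
#' @return A `reference_matrix`: list with `ranks` (genes x drugs integer
#'   matrix, each column a permutation of `1:n_genes`) and `classes`
#'   (named character vector).
#' @export
simulate_reference_matrix <- function(n_drugs = 200L,
                                      genes = NULL, n_genes = 1000L,
                                      class_labels = NULL,
                                      class_concordance = 0.7,
                                      anchor_signature = NULL,
                                      anchor_class = NULL,
                                      seed = 1L) {
  if (class_concordance < 0 || class_concordance > 1)
    .fail_param("class_concordance must be in [0, 1]")
  if (is.null(genes)) genes <- sprintf("GENE%05d", seq_len(n_genes))
  n_genes <- length(genes)
  if (is.null(class_labels)) class_labels <- rep(NA_character_, n_drugs)
  if (length(class_labels) != n_drugs)
    .fail_param("class_labels must have length n_drugs")
  if (!is.null(anchor_signature) && is.null(anchor_class))
    .fail_param("anchor_class must name the class tied to anchor_signature")

  with_substream(seed, "reference_matrix", {
    drugs <- sprintf("DRUG%04d", seq_len(n_drugs))
    names(class_labels) <- drugs
    ranks <- matrix(0L, n_genes, n_drugs, dimnames = list(genes, drugs))
    if (n_drugs > 0) {
      latents <- list()
      for (cl in unique(stats::na.omit(class_labels))) {
        z <- stats::rnorm(n_genes)
        if (!is.null(anchor_class) && identical(cl, anchor_class)) {
          z[match(anchor_signature$up, genes)] <- 3 + abs(stats::rnorm(length(anchor_signature$up)))
          z[match(anchor_signature$down, genes)] <- -3 - abs(stats::rnorm(length(anchor_signature$down)))
        }
        latents[[cl]] <- z
      }
      rho <- class_concordance
      for (j in seq_len(n_drugs)) {
        eps <- stats::rnorm(n_genes)
        cl <- class_labels[j]
        score <- if (is.na(cl)) eps
                 else sqrt(rho) * latents[[cl]] + sqrt(1 - rho) * eps
        ranks[, j] <- as.integer(rank(-score, ties.method = "first"))
      }
    }
    structure(list(ranks = ranks, classes = class_labels),
              class = "reference_matrix")
  })
}

#' Simulate a growth-competition time series
#'
#' Two populations seeded 1:1 (or at `p0`) grow with a constant per-day
#' growth-rate difference `s`; the toxic-protein-expressing fraction then
#' follows a logistic decay
#' `p_t = p0 e^{-s t} / (p0 e^{-s t} + (1 - p0))`, and at each sampling day
#' `n_cells_sampled` cells are scored by marker colour, giving binomial
#' counts.
#'
#' @param p0 Initial expressing fraction in (0, 1).
#' @param s Per-day relative-fitness deficit (s > 0 means the expressing
#'   fraction declines).
#' @param days Sampling days, sorted ascending, first = 0.
#' @param n_cells_sampled Cells scored per timepoint.
#' @param condition Condition label carried into the output.
#' @param seed Integer RNG seed.
#' @return List with `series` (data.frame `condition, day, q94_count,
#'   control_count`) and `truth` (`sim_truth` with `s`, `p0`).
#' @export
simulate_competition <- function(p0 = 0.5, s = 0.15, days = c(0, 5, 15),
                                 n_cells_sampled = 4e4,
                                 condition = "condition", seed = 1L) {
  if (p0 <= 0 || p0 >= 1) .fail_param("p0 must be in (0, 1)")
  if (is.unsorted(days, strictly = TRUE) || days[1] != 0)
    .fail_param("days must be strictly ascending and start at 0")
  if (n_cells_sampled < 1) .fail_param("n_cells_sampled must be >= 1")
  with_substream(seed, paste0("competition:", condition), {
    pt <- p0 * exp(-s * days) / (p0 * exp(-s * days) + (1 - p0))
    q <- stats::rbinom(length(days), n_cells_sampled, pt)
    truth <- structure(list(s = s, p0 = p0), class = "sim_truth")
    list(series = data.frame(condition = condition, day = days,
                             q94_count = q,
                             control_count = n_cells_sampled - q,
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate an embryo-survival experiment
#'
#' Per-replicate dead counts are binomial with an arm-specific death
#' probability, emulating microinjected eggs split over replicate wells and
#' scored for death.
#'
#' @param death_prob Named numeric vector of per-arm death probabilities in
#'   `[0, 1]` (names become arm labels).
#' @param n_eggs Eggs per replicate well.
#' @param n_replicates Replicate wells per arm (triplicate by default).
#' @param seed Integer RNG seed.
#' @return List with `survival` (data.frame `arm, replicate, n_total,
#'   n_dead`) and `truth` (`sim_truth` with `death_prob`).
#' @export
simulate_survival <- function(death_prob, n_eggs = 50L, n_replicates = 3L,
                              seed = 1L) {
  if (any(death_prob < 0 | death_prob > 1))
    .fail_param("death_prob values must be in [0, 1]")
  if (is.null(names(death_prob)))
    names(death_prob) <- sprintf("arm%d", seq_along(death_prob))
  if (n_eggs < 1 || n_replicates < 1)
    .fail_param("n_eggs and n_replicates must be >= 1")
  with_substream(seed, "survival", {
    arms <- names(death_prob)
    df <- data.frame(
      arm = rep(arms, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(arms)),
      n_total = n_eggs,
      n_dead = stats::rbinom(length(arms) * n_replicates, n_eggs,
                             rep(death_prob, each = n_replicates)),
      stringsAsFactors = FALSE)
    truth <- structure(list(death_prob = death_prob), class = "sim_truth")
    list(survival = df, truth = truth)
  })
}

#' Simulate a nematode body-bend assay
#'
#' Per-worm bend counts over a 30 s observation window, Poisson by default
#' or negative-binomial when a finite `dispersion` (size) is given.
#'
#' @param mean_bends Named numeric vector of per-arm mean bends per 30 s
#'   (>= 0; names become arm labels).
#' @param n_worms Worms scored per arm.
#' @param dispersion NB size parameter; `Inf` (default) gives Poisson.
#' @param seed Integer RNG seed.
#' @return List with `bends` (data.frame `arm, worm_id, bends_30s`) and
#'   `truth` (`sim_truth` with `mean_bends`).
#' @export
simulate_bends <- function(mean_bends, n_worms = 30L, dispersion = Inf,
                           seed = 1L) {
  if (any(mean_bends < 0)) .fail_param("mean_bends must be >= 0")
  if (is.null(names(mean_bends)))
    names(mean_bends) <- sprintf("arm%d", seq_along(mean_bends))
  if (n_worms < 1) .fail_param("n_worms must be >= 1")
  if (is.na(dispersion) || dispersion <= 0)
    .fail_param("dispersion must be > 0 (Inf for Poisson)")
  with_substream(seed, "bends", {
    arms <- names(mean_bends)
    mu <- rep(mean_bends, each = n_worms)
    counts <- if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
              else stats::rnbinom(length(mu), size = dispersion, mu = mu)
    df <- data.frame(arm = rep(arms, each = n_worms),
                     worm_id = rep(seq_len(n_worms), times = length(arms)),
                     bends_30s = counts, stringsAsFactors = FALSE)
    truth <- structure(list(mean_bends = mean_bends), class = "sim_truth")
    list(bends = df, truth = truth)
  })
}
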