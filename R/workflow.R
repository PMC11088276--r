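# Orchestration: a single validated configuration drives the synthetic
# two-stage screen, optional imaging, signature/connectivity analysis and
# the downstream phenotype statistics, with plain-file handoff between
# stages and a reproducible run report.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "polyqscreen_run",
    stages = list(imaging = TRUE, signatures = TRUE, phenotypes = TRUE),
    screen = list(n_compounds = 1216L, n_replicate_plates = 3L,
                  plate_format = 384L, doses = 1,
                  baseline_count = 2000, dox_effect = 0.5,
                  n_active = 4L, rescue_effects = 1.5,
                  n_toxic = 10L, toxic_effects = 0.5,
                  plate_factor_sd = 0.1, edge_effect = 1,
                  dispersion = 111.1, n_controls_per_role = 16L),
    hit_calling = list(k = 3, scope = "pooled", estimator = "sd",
                       aggregate = "well", loo = FALSE),
    validation = list(doses = c(0.5, 1, 3, 10), alpha = 0.05,
                      method = "dunnett", min_significant_doses = 2L),
    imaging = list(n_images = 4L, n_nuclei = 12L, shape = c(96L, 96L)),
    de = list(n_genes = 2000L, n_up = 200L, n_down = 200L,
              lfc_magnitude = 2),
    signature = list(n = 150L, alpha = 0.05),
    reference = list(n_drugs = 200L, class_size = 10L,
                     class_label = "ppar_agonist",
                     class_concordance = 0.7, top_k = 10L),
    competition = list(conditions = c(vehicle = 0.15, cfz = 0.02, tzd = 0.04),
                       p0 = 0.5, days = c(0, 5, 15), n_cells_sampled = 4e4),
    survival = list(death_prob = c(q94_vehicle = 0.6, q94_cfz = 0.3,
                                   uninjected = 0.05),
                    n_eggs = 50L, n_replicates = 3L),
    bends = list(mean_bends = c(vehicle = 8, cfz = 14), n_worms = 30L),
    intensity = list(means = c(no_dox = 1.0, dox = 0.7, dox_cfz = 0.95),
                     cv = 0.25, n_cells = 500L)
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (a triplicate 1216-compound 384-well
#' screen with four planted rescuers, followed by dose-response
#' validation, signature/connectivity analysis against a 200-drug
#' reference with one planted agonist class, and the downstream phenotype
#' assays) and applies the supplied overrides. Unknown keys at either
#' level are rejected.
#'
#' @param ... Named overrides; section arguments (e.g. `screen`,
#'   `hit_calling`) take named lists merged into the section defaults.
#' @return A validated list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, screen = list(n_compounds = 100))
#' @export
pipeline_config <- function(...) {
  defaults <- .pipeline_defaults()
  user <- list(...)
  if (length(user) && is.null(names(user)))
    .fail_param("pipeline_config overrides must be named")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .fail_param("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        .fail_param("config section '%s' must be a named list", key)
      bad <- setdiff(names(user[[key]]), names(defaults[[key]]))
      if (length(bad))
        .fail_param("unknown keys in config section '%s': %s", key,
                    paste(bad, collapse = ", "))
      cfg[[key]] <- utils::modifyList(defaults[[key]], user[[key]])
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .fail_param("config file not found: %s", path)
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  ## YAML drops vector names into maps; coerce sections back
  x <- lapply(x, function(v) if (is.list(v) && length(v) &&
                                 all(vapply(v, is.numeric, logical(1))) &&
                                 !any(vapply(v, is.list, logical(1))))
                               v else v)
  do.call(pipeline_config, x)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[polyqscreen] stage %-12s %6.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full synthetic screen-to-phenotype pipeline
#'
#' Executes, in order: screen simulation, optional nuclei-image
#' segmentation, per-plate normalization and 3SD hit calling with QC,
#' dose-response validation of the primary hits, signature extraction and
#' connectivity/class-enrichment analysis, and the phenotype statistics
#' (competition fitness, survival, bends, per-cell intensity). Each stage
#' writes plain files (CSV/TSV/JSON) into `out_dir` and later stages read
#' only those files' contents. Reruns with the same configuration produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The run report (invisibly), as [make_report()] plus provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  path <- function(f) file.path(out_dir, f)

  provenance <- list(config_hash = config_hash(unclass(config)),
                     seed = seed,
                     package_version = as.character(utils::packageVersion("polyqscreen")))
  .write_json(c(list(config = unclass(config)), provenance), path("config.json"))

  ## --- stage: simulate + primary screen -------------------------------
  sim <- .stage("simulate", {
    scfg <- do.call(screen_sim_config, c(config$screen, list(seed = seed)))
    simulate_screen(scfg)
  })
  write_plate_csv(sim$plates, path("plates.csv"))
  .write_json(list(active_ids = sim$truth$active_ids,
                   toxic_ids = sim$truth$toxic_ids,
                   effect_by_compound = as.list(sim$truth$effect_by_compound)),
              path("truth.json"))

  if (isTRUE(config$stages$imaging)) {
    .stage("imaging", {
      icfg <- config$imaging
      counts <- do.call(rbind, lapply(seq_len(icfg$n_images), function(i) {
        im <- simulate_nuclei_image(icfg$n_nuclei, shape = icfg$shape,
                                    seed = substream_seed(seed, paste0("img", i)))
        mask <- segment_nuclei(im$image)
        data.frame(image = i, true_nuclei = nrow(im$truth$centers),
                   counted = nrow(mask$objects))
      }))
      utils::write.csv(counts, path("image_counts.csv"), row.names = FALSE)
    })
  }

  hits <- .stage("hit_calling", {
    plates <- normalize_plates(read_plate_csv(path("plates.csv")))
    hc <- config$hit_calling
    stats <- control_stats(plates, scope = hc$scope, estimator = hc$estimator,
                           aggregate = hc$aggregate, loo = hc$loo, k = hc$k)
    calls <- call_hits(summarize_compounds(plates), stats)
    utils::write.csv(as.data.frame(calls), path("hits.csv"), row.names = FALSE)
    qc <- qc_report(plates)
    .write_json(list(zprime = qc$zprime, control_cv = qc$control_cv,
                     edge_ratio = qc$edge_ratio,
                     control_stats = unclass(stats)), path("qc.json"))
    calls
  })

  validation <- .stage("validation", {
    hit_ids <- hits$compound_id[hits$is_hit]
    vsim <- simulate_validation_screen(
      do.call(screen_sim_config, c(config$screen, list(seed = seed))),
      hit_ids, sim$truth, doses = config$validation$doses)
    if (nrow(vsim$plates)) write_plate_csv(vsim$plates, path("validation_plates.csv"))
    vres <- validate_dose_response(vsim$plates,
                                   alpha = config$validation$alpha,
                                   method = config$validation$method,
                                   min_significant_doses = config$validation$min_significant_doses)
    utils::write.csv(vres$per_dose, path("validation_doses.csv"), row.names = FALSE)
    utils::write.csv(vres$per_compound, path("validation.csv"), row.names = FALSE)
    vres
  })

  if (isTRUE(config$stages$signatures)) {
    .stage("signatures", {
      d <- config$de
      det <- simulate_de_table(d$n_genes, d$n_up, d$n_down, d$lfc_magnitude,
                               seed = substream_seed(seed, "de"))
      write_de_tsv(det$de, path("de.tsv"))
      de <- read_de_tsv(path("de.tsv"))
      sig <- extract_signature(de, n = config$signature$n,
                               alpha = config$signature$alpha)
      write_signature_json(sig, path("signature.json"))

      r <- config$reference
      labels <- c(rep(r$class_label, r$class_size),
                  rep(NA_character_, r$n_drugs - r$class_size))
      refmat <- simulate_reference_matrix(
        n_drugs = r$n_drugs, genes = de$gene, class_labels = labels,
        class_concordance = r$class_concordance,
        anchor_signature = sig, anchor_class = r$class_label,
        seed = substream_seed(seed, "refmat"))
      write_reference_matrix(refmat, path("refmat.tsv"), path("refmat_classes.tsv"))

      sig2 <- read_signature_json(path("signature.json"))
      ref2 <- read_reference_matrix(path("refmat.tsv"), path("refmat_classes.tsv"))
      conn <- rank_drugs(sig2, ref2)
      utils::write.csv(as.data.frame(conn), path("connectivity.csv"),
                       row.names = FALSE)
      enr <- class_enrichment(conn, r$class_label, top_k = r$top_k)
      .write_json(unclass(enr), path("enrichment.json"))
    })
  }

  if (isTRUE(config$stages$phenotypes)) {
    .stage("phenotypes", {
      cc <- config$competition
      sims <- lapply(names(cc$conditions), function(cond)
        simulate_competition(p0 = cc$p0, s = cc$conditions[[cond]],
                             days = cc$days,
                             n_cells_sampled = cc$n_cells_sampled,
                             condition = cond, seed = seed))
      series <- do.call(rbind, lapply(sims, `[[`, "series"))
      utils::write.csv(series, path("competition.csv"), row.names = FALSE)
      fc <- compare_fitness(utils::read.csv(path("competition.csv"),
                                            stringsAsFactors = FALSE))
      fitness_df <- do.call(rbind, lapply(fc$fits, function(f)
        data.frame(condition = f$condition, s = f$s, s_se = f$s_se,
                   p0_hat = f$p0_hat, stringsAsFactors = FALSE)))
      utils::write.csv(fitness_df, path("fitness.csv"), row.names = FALSE)

      sv <- config$survival
      ssim <- simulate_survival(sv$death_prob, sv$n_eggs, sv$n_replicates,
                                seed = seed)
      utils::write.csv(ssim$survival, path("survival.csv"), row.names = FALSE)
      scomp <- compare_survival(utils::read.csv(path("survival.csv"),
                                                stringsAsFactors = FALSE))

      bd <- config$bends
      bsim <- simulate_bends(bd$mean_bends, bd$n_worms, seed = seed)
      utils::write.csv(bsim$bends, path("bends.csv"), row.names = FALSE)
      bcomp <- compare_bends(utils::read.csv(path("bends.csv"),
                                             stringsAsFactors = FALSE))

      it <- config$intensity
      groups <- with_substream(seed, "intensity", {
        g <- lapply(it$means, function(m)
          stats::rnorm(it$n_cells, m, it$cv * m))
        names(g) <- names(it$means)
        g
      })
      icomp <- compare_intensity(groups)

      .write_json(list(fitness_contrasts = fc$contrasts,
                       survival = list(arm_summary = scomp$arm_summary,
                                       contrasts = scomp$contrasts),
                       bends = list(arm_summary = bcomp$arm_summary,
                                    contrasts = bcomp$contrasts),
                       intensity = list(group_summary = icomp$group_summary,
                                        method = icomp$method,
                                        p_value = icomp$p_value,
                                        pairwise = icomp$pairwise)),
                  path("contrasts.json"))
    })
  }

  report <- make_report(out_dir)
  report$provenance <- provenance
  .write_json(.report_as_list(report), path("report.json"))
  invisible(report)
}

.report_as_list <- function(report) {
  list(funnel = report$funnel, recovery = report$recovery,
       qc = report$qc, gaps = report$gaps, provenance = report$provenance)
}

#' Summarize a completed run directory
#'
#' Re-derives the screen funnel (library size, primary hits, validated
#' compounds), truth recovery and headline QC from the files a pipeline
#' run left on disk. Missing stage files are reported as explicit gaps
#' rather than errors, so partial runs can still be inspected.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of class `run_report` with `funnel`, `recovery`, `qc`,
#'   `gaps`, `complete`.
#' @export
make_report <- function(run_dir) {
  if (!dir.exists(run_dir)) .fail_param("run directory not found: %s", run_dir)
  p <- function(f) file.path(run_dir, f)
  gaps <- character()
  funnel <- list(n_compounds = NA_integer_, n_hits = NA_integer_,
                 n_validated = NA_integer_)
  recovery <- list(); qc <- list()

  if (file.exists(p("plates.csv"))) {
    plates <- read_plate_csv(p("plates.csv"))
    funnel$n_compounds <- length(unique(plates$compound_id[plates$role == "compound"]))
  } else gaps <- c(gaps, "plates.csv")

  hits <- NULL
  if (file.exists(p("hits.csv"))) {
    hits <- utils::read.csv(p("hits.csv"), stringsAsFactors = FALSE)
    funnel$n_hits <- sum(hits$is_hit)
  } else gaps <- c(gaps, "hits.csv")

  if (file.exists(p("validation.csv"))) {
    val <- utils::read.csv(p("validation.csv"), stringsAsFactors = FALSE)
    funnel$n_validated <- if (nrow(val)) sum(val$validated) else 0L
    if (!is.null(hits)) {
      hit_ids <- hits$compound_id[hits$is_hit]
      if (nrow(val) && !all(val$compound_id[val$validated] %in% hit_ids))
        warning("validated compounds are not a subset of primary hits")
    }
  } else gaps <- c(gaps, "validation.csv")

  if (file.exists(p("truth.json")) && !is.null(hits)) {
    truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    hit_ids <- hits$compound_id[hits$is_hit]
    recovery <- list(
      planted_rescuers = length(truth$active_ids),
      rescuers_hit = length(intersect(truth$active_ids, hit_ids)),
      toxic_false_positives = length(intersect(truth$toxic_ids, hit_ids)))
    if (file.exists(p("validation.csv"))) {
      val <- utils::read.csv(p("validation.csv"), stringsAsFactors = FALSE)
      recovery$rescuers_validated <-
        length(intersect(truth$active_ids,
                         val$compound_id[val$validated]))
    }
  }

  if (file.exists(p("qc.json"))) {
    q <- jsonlite::read_json(p("qc.json"), simplifyVector = TRUE)
    qc <- list(median_zprime = stats::median(q$zprime$zprime, na.rm = TRUE),
               edge_ratio = q$edge_ratio)
  } else gaps <- c(gaps, "qc.json")

  if (file.exists(p("enrichment.json"))) {
    e <- jsonlite::read_json(p("enrichment.json"), simplifyVector = TRUE)
    qc$class_enrichment_p <- e$p_value
  }

  structure(list(funnel = funnel, recovery = recovery, qc = qc,
                 gaps = gaps, complete = length(gaps) == 0),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("polyqscreen run report\n")
  cat(sprintf("  funnel: %s compounds -> %s primary hits -> %s validated\n",
              x$funnel$n_compounds, x$funnel$n_hits, x$funnel$n_validated))
  if (length(x$recovery))
    cat(sprintf("  truth recovery: %d/%d planted rescuers hit, %d validated, %d toxic false positives\n",
                x$recovery$rescuers_hit, x$recovery$planted_rescuers,
                x$recovery$rescuers_validated %||% NA_integer_,
                x$recovery$toxic_false_positives))
  if (length(x$qc))
    cat(sprintf("  QC: median Z' = %.3f, edge ratio = %.3f%s\n",
                x$qc$median_zprime, x$qc$edge_ratio,
                if (!is.null(x$qc$class_enrichment_p))
                  sprintf(", class enrichment p = %.3g", x$qc$class_enrichment_p)
                else ""))
  if (length(x$gaps))
    cat("  INCOMPLETE - missing:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}
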