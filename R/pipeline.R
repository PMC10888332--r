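#' Pipeline run configuration
#'
#' One structured configuration drives the full desk pipeline
#' (phantom -> simulate -> estimate -> classify -> evaluate). Every
#' stochastic stage receives a seed derived deterministically from the
#' global seed, so a run is a pure function of its configuration.
#'
#' @param stages subset of `c("phantom", "simulate", "estimate",
#'   "cohort", "classify", "evaluate")`, executed in this order.
#' @param seed global seed.
#' @param out_dir output directory (created if absent).
#' @param phantom list: `layers`, `lesion` (a [lesion_spec()] or NULL),
#'   `grid`.
#' @param probe a [probe_config()].
#' @param estimator list: `windows`, `candidate_speeds`, reference
#'   properties.
#' @param cohort list: `n_benign`, `n_malignant`.
#' @param stats list: `n_boot`.
#' @param verbose print stage progress.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("phantom", "simulate", "estimate",
                                  "cohort", "classify", "evaluate"),
                       seed = 1L, out_dir = tempfile("quantus_run_"),
                       phantom = list(), probe = probe_config(),
                       estimator = list(), cohort = list(),
                       stats = list(), verbose = FALSE) {
  known <- c("phantom", "simulate", "estimate", "cohort", "classify",
             "evaluate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(stages = known[known %in% stages], seed = as.integer(seed),
                 out_dir = out_dir, phantom = phantom, probe = probe,
                 estimator = estimator, cohort = cohort, stats = stats,
                 verbose = verbose),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  # deterministic per-stage seeds, kept well below 2^31
  config$seed * 1000L +
    match(stage, c("phantom", "simulate", "estimate", "cohort",
                   "classify", "evaluate"))
}

#' Execute the desk QUS pipeline
#'
#' Runs the requested stages in order, persisting artifacts under the
#' configured output directory and recording every input, output, seed
#' and headline metric in a JSON manifest. A stage that needs an
#' artifact from a stage that was not run and is not on disk fails with
#' an error naming the stage.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pathof <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (config$verbose) message(...)
  manifest <- list(package_version = as.character(utils::packageVersion("quantus")),
                   seed = config$seed, stages = config$stages,
                   artifacts = list(), seeds = list(), metrics = list(),
                   parameters = list())
  need <- function(file, stage, producer) {
    p <- pathof(file)
    if (!file.exists(p))
      stop("stage '", stage, "' requires '", file,
           "' produced by stage '", producer, "'")
    readRDS(p)
  }

  for (stage in config$stages) {
    s_seed <- stage_seed(config, stage)
    manifest$seeds[[stage]] <- s_seed
    say("stage ", stage, " (seed ", s_seed, ")")
    if (stage == "phantom") {
      ph <- generate_phantom(layers = config$phantom$layers %||%
                               default_layers(),
                             lesion = config$phantom$lesion,
                             rng_seed = s_seed,
                             grid = config$phantom$grid %||% phantom_grid())
      saveRDS(ph, pathof("phantom.rds"))
      export_png(ph$ac_map, pathof("phantom_ac.png"), "AC map (dB/cm/MHz)")
      manifest$artifacts$phantom <- "phantom.rds"
    } else if (stage == "simulate") {
      ph <- need("phantom.rds", "simulate", "phantom")
      rf <- simulate_rf(ph, config$probe, rng_seed = s_seed)
      saveRDS(rf, pathof("rf.rds"))
      bf <- beamform_das(rf)
      export_png(bf$envelope, pathof("bmode.png"), "B-mode", db = 50)
      manifest$artifacts$rf <- "rf.rds"
      manifest$parameters$probe <- config$probe[c(
        "n_elements", "center_freq_hz", "pitch_mm", "sampling_rate_hz",
        "n_samples", "c_ref")]
      manifest$parameters$steering_angles_deg <-
        config$probe$steering_angles_deg
    } else if (stage == "estimate") {
      ph <- need("phantom.rds", "estimate", "phantom")
      rf <- need("rf.rds", "estimate", "simulate")
      est <- config$estimator
      ref <- reference_rf(config$probe, ph$grid,
                          ac = est$ref_ac %||% 0.5,
                          sos = est$ref_sos %||% 1540,
                          esd = est$ref_esd %||% 85,
                          esc = est$ref_esc %||% 2,
                          rng_seed = s_seed + 500L)
      w <- est$windows %||% analysis_windows(
        z_max_mm = ph$grid$roi_mm[["depth"]] - 2)
      ac_img <- estimate_ac(rf, w, ref)
      sos_img <- estimate_sos(rf, est$candidate_speeds %||%
                                seq(1440, 1640, by = 4))
      ee <- estimate_esd_esc(rf, w, ref, ac_image = ac_img,
                             sos_mps = sos_img$values[1, 1])
      maps <- list(AC = ac_img, SoS = sos_img, ESD = ee$ESD, ESC = ee$ESC)
      saveRDS(maps, pathof("qus_maps.rds"))
      for (p in names(maps))
        export_png(maps[[p]]$values, pathof(paste0("qus_", tolower(p), ".png")),
                   paste(p, "(", maps[[p]]$units, ")"))
      row <- lesion_measurement(maps, ph, id = "run_lesion",
                                label = if (ph$lesion_class %in%
                                            c("benign", "malignant"))
                                  ph$lesion_class else NA_character_)
      utils::write.csv(row, pathof("lesion_measurement.csv"),
                       row.names = FALSE)
      manifest$artifacts$qus_maps <- "qus_maps.rds"
      manifest$artifacts$lesion_measurement <- "lesion_measurement.csv"
      manifest$metrics$lesion <- as.list(row[1, c("ac", "sos", "esd", "esc")])
    } else if (stage == "cohort") {
      co <- sample_cohort(config$cohort$n_benign %||% 32L,
                          config$cohort$n_malignant %||% 23L,
                          seed = s_seed)
      utils::write.csv(co, pathof("cohort.csv"), row.names = FALSE)
      manifest$artifacts$cohort <- "cohort.csv"
    } else if (stage == "classify") {
      cp <- pathof("cohort.csv")
      if (!file.exists(cp))
        stop("stage 'classify' requires 'cohort.csv' produced by stage 'cohort'")
      co <- utils::read.csv(cp)
      cl <- classify_lesions(co)
      utils::write.csv(cl, pathof("classified.csv"), row.names = FALSE)
      manifest$artifacts$classified <- "classified.csv"
      manifest$metrics$n_called_malignant <-
        sum(cl$predicted == "malignant")
    } else if (stage == "evaluate") {
      cp <- pathof("classified.csv")
      if (!file.exists(cp))
        stop("stage 'evaluate' requires 'classified.csv' produced by stage 'classify'")
      cl <- utils::read.csv(cp)
      roc <- roc_auc(cl$probability, cl$label,
                     n_boot = config$stats$n_boot %||% 2000L,
                     seed = s_seed)
      mw <- lapply(c("ac", "sos", "esd", "esc"), function(p)
        mann_whitney(cl[[p]][cl$label == "benign"],
                     cl[[p]][cl$label == "malignant"])$p)
      names(mw) <- c("ac", "sos", "esd", "esc")
      acc <- mean((cl$probability >= 0.5) == (cl$label == "malignant"))
      cp_ci <- clopper_pearson(round(acc * nrow(cl)), nrow(cl))
      manifest$metrics$auc <- roc$auc
      manifest$metrics$auc_ci <- roc$ci
      manifest$metrics$mann_whitney_p <- mw
      manifest$metrics$accuracy <- acc
      manifest$metrics$accuracy_ci <- as.list(cp_ci)
    }
  }
  write_manifest(manifest, pathof("manifest.json"))
  invisible(manifest)
}
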