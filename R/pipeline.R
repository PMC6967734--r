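#' End-to-end pipeline configuration
#'
#' Single object carrying every stage's parameters; defaults equal the
#' analysis constants (30-s/10-s/2-s windows, nw = 2 with 3 tapers, 0.5-35
#' Hz grid, k = 5 states on 5 components with 100 replicates, 20 surrogate
#' permutations, family alpha 0.05, FDR q 0.20).
#'
#' @param cohort a [cohort_config()] (simulation stage).
#' @param grid a [window_grid()].
#' @param spectral a [spectral_config()].
#' @param k,n_components,n_replicates state-model parameters.
#' @param n_perm surrogate permutations per window.
#' @param family_alpha,fdr_q statistics thresholds.
#' @param seed master seed; per-stage, per-subject seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), grid = window_grid(),
                            spectral = spectral_config(), k = 5,
                            n_components = 5, n_replicates = 100,
                            n_perm = 20, family_alpha = 0.05, fdr_q = 0.20,
                            seed = 1) {
  structure(list(cohort = cohort, grid = grid, spectral = spectral, k = k,
                 n_components = n_components, n_replicates = n_replicates,
                 n_perm = n_perm, family_alpha = family_alpha,
                 fdr_q = fdr_q, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> maintenance extraction -> connectivity features -> state
#' model -> state sequences -> dynamics -> statistics. Stage outputs are
#' written under `out_dir` with a manifest (config echo, seeds, row counts,
#' content hashes). Existing stage outputs are reused unless `force`;
#' subjects whose epoch is too short are excluded and logged, leaving the
#' rest unaffected.
#'
#' @param cfg a [pipeline_config].
#' @param out_dir run directory (created if needed).
#' @param cohort optional pre-built cohort (list with `recordings`,
#'   `metas`); by default one is simulated from `cfg$cohort`.
#' @param force recompute even when stage outputs exist.
#' @param verbose print per-stage progress.
#' @return invisibly, a list with `features`, `model`, `sequences`,
#'   `dynamics`, `meta`, `report`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir, cohort = NULL, force = FALSE,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_file <- function(name) file.path(out_dir, name)

  if (is.null(cohort)) {
    say("stage simulate: %d subjects", cfg$cohort$n_subjects)
    cohort <- generate_cohort(cfg$cohort)
  }
  meta <- meta_table(cohort$metas)
  utils::write.csv(meta, stage_file("meta.csv"), row.names = FALSE)

  feat_path <- stage_file("features.csv")
  excluded <- character()
  if (!force && file.exists(feat_path)) {
    say("stage connectivity: reusing %s", feat_path)
    features <- utils::read.csv(feat_path, check.names = FALSE)
  } else {
    feats <- list()
    for (i in seq_along(cohort$recordings)) {
      rec <- cohort$recordings[[i]]
      sid <- rec$subject_id
      ep <- tryCatch(
        extract_maintenance(rec, "incision", "maintenance_end",
                            start_offset = 0),
        error = function(e) e)
      if (inherits(ep, "error")) {
        say("stage connectivity: excluding %s (%s)", sid,
            conditionMessage(ep))
        excluded <- c(excluded, sid)
        next
      }
      say("stage connectivity: %s (%d/%d)", sid, i, length(cohort$recordings))
      feats[[sid]] <- connectivity_features(
        ep, cfg$grid, cfg$spectral, n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, sid, "surrogate"))
    }
    if (!length(feats)) stopf("pipeline error: no subject survived stage connectivity")
    features <- do.call(rbind, feats)
    utils::write.csv(features, feat_path, row.names = FALSE)
  }

  say("stage states: fitting k = %d on %d windows", cfg$k, nrow(features))
  model <- fit_state_model(features, k = cfg$k,
                           n_components = cfg$n_components,
                           n_replicates = cfg$n_replicates,
                           seed = derive_seed(cfg$seed, "states"),
                           f_grid = cfg$spectral$f_grid)
  write_state_model(model, stage_file("state_model.json"))

  seqs <- lapply(split(features, features$subject_id),
                 function(f) assign_states(model, f))
  seq_df <- do.call(rbind, seqs)
  utils::write.csv(seq_df, stage_file("state_sequences.csv"),
                   row.names = FALSE)

  say("stage dynamics: %d subjects", length(seqs))
  dyn <- cohort_dynamics(seqs)
  utils::write.csv(dyn, stage_file("dynamics.csv"), row.names = FALSE)

  say("stage stats")
  report <- run_statistics(dyn, meta, family_alpha = cfg$family_alpha,
                           fdr_q = cfg$fdr_q)
  report_df <- rbind(report$gtp, report$occurrence, report$transitions)
  utils::write.csv(report_df, stage_file("stats_report.csv"),
                   row.names = FALSE)

  outputs <- c("meta.csv", "features.csv", "state_model.json",
               "state_sequences.csv", "dynamics.csv", "stats_report.csv")
  manifest <- list(
    seed = cfg$seed,
    config = list(n_subjects = cfg$cohort$n_subjects,
                  epoch_duration = cfg$cohort$epoch_duration,
                  fs = cfg$cohort$fs, k = cfg$k,
                  n_components = cfg$n_components,
                  n_replicates = cfg$n_replicates, n_perm = cfg$n_perm,
                  family_alpha = cfg$family_alpha, fdr_q = cfg$fdr_q),
    excluded_subjects = excluded,
    rows = list(subjects = nrow(meta), windows = nrow(features),
                sequences = nrow(seq_df), dynamics = nrow(dyn)),
    files = lapply(stats::setNames(nm = outputs), function(f)
      list(path = f, md5 = unname(tools::md5sum(stage_file(f))))))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, model = model, sequences = seqs,
                 dynamics = dyn, meta = meta, report = report,
                 manifest = manifest))
}

#' Serialize a state model to JSON
#' @param model a `state_model`.
#' @param path output path.
#' @export
write_state_model <- function(model, path) {
  jsonlite::write_json(
    list(mean_vector = model$mean_vector,
         pca_basis = model$pca_basis,
         explained_variance = model$explained_variance,
         centroids = model$centroids, k = model$k,
         state_names = model$state_names, f_grid = model$f_grid),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized state model
#' @param path JSON path written by [write_state_model()].
#' @return a `state_model`.
#' @export
read_state_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_vector = as.numeric(j$mean_vector),
                 pca_basis = as.matrix(j$pca_basis),
                 explained_variance = as.numeric(j$explained_variance),
                 centroids = as.matrix(j$centroids), k = j$k,
                 state_names = as.character(j$state_names),
                 f_grid = as.numeric(j$f_grid)),
            class = "state_model")
}
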