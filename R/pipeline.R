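# End-to-end orchestration: synth -> extract -> reduce -> fit-plsr ->
# fit-nn -> contributions -> compare -> report, with a JSON run manifest.

emotion_scales <- c("valence", "tension", "energy")

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; synthesis, rating, fold and initialization seeds
#'   are derived from it deterministically.
#' @param config stimulus configuration data frame.
#' @param effect planted rating mapping.
#' @param n_participants simulated raters.
#' @param threshold collinearity pruning cutoff.
#' @param learning_rate,epochs network training controls; `epochs` is a
#'   named vector per emotion scale (tension conventionally gets the longer
#'   schedule).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("timbral_run_"), seed = 1L,
                            config = default_stimulus_config(),
                            effect = default_planted_effect(),
                            n_participants = 40L, threshold = 0.905,
                            learning_rate = 0.2,
                            epochs = c(valence = 700L, tension = 1000L,
                                       energy = 700L)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 config = config, effect = effect,
                 n_participants = as.integer(n_participants),
                 threshold = threshold, learning_rate = learning_rate,
                 epochs = epochs),
            class = "pipeline_config")
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_upstream <- function(cfg, files, stage) {
  paths <- vapply(files, function(f) stage_path(cfg, f), character(1))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("stage '", stage, "' is missing upstream artifact(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(paths)
}

#' Run one pipeline stage
#'
#' Stages: `synth` (tones, WAVs, metadata, simulated ratings), `extract`
#' (descriptor CSV from the WAVs), `reduce` (pruning + adequacy report),
#' `fit-plsr`, `fit-nn`, `contributions`, `compare`, `report`. Each stage
#' reads its inputs from `out_dir` and errors if an upstream artifact is
#' missing.
#'
#' @param name stage name.
#' @param cfg a [pipeline_config()].
#' @return stage output (also written to `out_dir`), invisibly.
#' @export
run_stage <- function(name, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(
    name,
    "synth" = {
      set <- generate_stimulus_set(cfg$config, seed = cfg$seed,
                                   dir = stage_path(cfg, "audio"))
      utils::write.csv(set$metadata, stage_path(cfg, "stimuli.csv"),
                       row.names = FALSE)
      ratings <- generate_ratings(set$metadata, cfg$effect,
                                  cfg$n_participants, seed = cfg$seed + 1L)
      utils::write.csv(ratings, stage_path(cfg, "ratings.csv"),
                       row.names = FALSE)
      invisible(set)
    },
    "extract" = {
      require_upstream(cfg, "stimuli.csv", name)
      meta <- utils::read.csv(stage_path(cfg, "stimuli.csv"))
      clips <- lapply(meta$stimulus_id, function(id) {
        wav <- read_wav(file.path(stage_path(cfg, "audio"),
                                  paste0(id, ".wav")))
        structure(list(samples = wav$samples,
                       sample_rate = wav$sample_rate),
                  class = "audio_clip")
      })
      names(clips) <- meta$stimulus_id
      desc <- extract_descriptor_matrix(clips)
      utils::write.csv(desc, stage_path(cfg, "descriptors.csv"),
                       row.names = FALSE)
      invisible(desc)
    },
    "reduce" = {
      require_upstream(cfg, "descriptors.csv", name)
      desc <- utils::read.csv(stage_path(cfg, "descriptors.csv"))
      C <- correlation_matrix(desc)
      pruned <- prune_collinear(C, threshold = cfg$threshold)
      retained <- desc[c("stimulus_id", pruned$retained)]
      utils::write.csv(retained, stage_path(cfg, "retained.csv"),
                       row.names = FALSE)
      report <- list(retained = pruned$retained, removed = pruned$removed,
                     kmo = kmo_index(desc[pruned$retained]),
                     kmo_full = tryCatch(kmo_index(desc[-1]),
                                         error = function(e) NA_real_),
                     merge_heights = cluster_descriptors(C)$height,
                     threshold = cfg$threshold)
      jsonlite::write_json(report, stage_path(cfg, "reduction.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      invisible(report)
    },
    "fit-plsr" = {
      require_upstream(cfg, c("retained.csv", "ratings.csv"), name)
      retained <- utils::read.csv(stage_path(cfg, "retained.csv"))
      means <- mean_rating_matrix(aggregate_ratings(
        utils::read.csv(stage_path(cfg, "ratings.csv"))))
      means <- means[match(retained$stimulus_id, means$stimulus_id), ]
      rows <- list()
      for (sc in emotion_scales) {
        rep <- crossvalidate_plsr(retained, means[[sc]],
                                  seed = cfg$seed + 2L)
        utils::write.csv(
          data.frame(descriptor = rownames(rep$loadings), rep$loadings),
          stage_path(cfg, paste0("plsr_loadings_", sc, ".csv")),
          row.names = FALSE)
        imp <- plsr_importance(rep)
        utils::write.csv(
          data.frame(descriptor = names(imp), importance = unname(imp)),
          stage_path(cfg, paste0("plsr_importance_", sc, ".csv")),
          row.names = FALSE)
        rows[[sc]] <- data.frame(scale = sc,
                                 metric = c("r2", "q2", "rmse"),
                                 value = c(rep$r2, rep$q2, rep$rmse),
                                 n_components = rep$n_components)
      }
      out <- do.call(rbind, rows)
      utils::write.csv(out, stage_path(cfg, "plsr_metrics.csv"),
                       row.names = FALSE)
      invisible(out)
    },
    "fit-nn" = {
      require_upstream(cfg, c("retained.csv", "ratings.csv"), name)
      retained <- utils::read.csv(stage_path(cfg, "retained.csv"))
      X <- range_normalize(retained)
      Xm <- as_descriptor_matrix(X)
      means <- mean_rating_matrix(aggregate_ratings(
        utils::read.csv(stage_path(cfg, "ratings.csv"))))
      means <- means[match(retained$stimulus_id, means$stimulus_id), ]
      plan <- make_fold_plan(retained$stimulus_id, seed = cfg$seed + 3L)
      rows <- list()
      folds <- list()
      for (sc in emotion_scales) {
        y <- stats::setNames(means[[sc]], means$stimulus_id)
        conf <- mlp_config(n_inputs = ncol(Xm),
                           learning_rate = cfg$learning_rate,
                           epochs = cfg$epochs[[sc]],
                           seed = cfg$seed + 4L)
        cv <- crossvalidate_mlp(Xm, y, plan, conf)
        met <- mlp_cv_metrics(cv, Xm, y)
        rows[[sc]] <- data.frame(scale = sc,
                                 metric = c("r2", "q2", "rmse"),
                                 value = unname(met))
        folds[[sc]] <- data.frame(scale = sc, fold = 1:5,
                                  rmse = cv$fold_rmse)
        contrib <- cv_contributions(cv)
        utils::write.csv(
          data.frame(descriptor = names(contrib),
                     contribution_pct = unname(contrib)),
          stage_path(cfg, paste0("nn_contributions_", sc, ".csv")),
          row.names = FALSE)
      }
      utils::write.csv(do.call(rbind, folds),
                       stage_path(cfg, "nn_fold_rmse.csv"),
                       row.names = FALSE)
      out <- do.call(rbind, rows)
      utils::write.csv(out, stage_path(cfg, "nn_metrics.csv"),
                       row.names = FALSE)
      invisible(out)
    },
    "contributions" = {
      require_upstream(cfg, paste0("nn_contributions_", emotion_scales,
                                   ".csv"), name)
      tabs <- lapply(emotion_scales, function(sc) {
        d <- utils::read.csv(stage_path(cfg,
                                        paste0("nn_contributions_", sc,
                                               ".csv")))
        cbind(scale = sc,
              top_k_table(stats::setNames(d$contribution_pct,
                                          d$descriptor)))
      })
      out <- do.call(rbind, tabs)
      utils::write.csv(out, stage_path(cfg, "nn_ranks.csv"),
                       row.names = FALSE)
      invisible(out)
    },
    "compare" = {
      require_upstream(cfg, c("plsr_metrics.csv", "nn_metrics.csv"), name)
      plsr <- utils::read.csv(stage_path(cfg, "plsr_metrics.csv"))
      nn <- utils::read.csv(stage_path(cfg, "nn_metrics.csv"))
      out <- comparison_table(plsr[c("scale", "metric", "value")],
                              nn[c("scale", "metric", "value")])
      utils::write.csv(out, stage_path(cfg, "comparison.csv"),
                       row.names = FALSE)
      invisible(out)
    },
    "report" = {
      require_upstream(cfg, c("comparison.csv", "nn_ranks.csv"), name)
      plsr_ranks <- lapply(emotion_scales, function(sc) {
        f <- stage_path(cfg, paste0("plsr_importance_", sc, ".csv"))
        d <- utils::read.csv(f)
        cbind(scale = sc, method = "plsr",
              top_k_table(stats::setNames(d$importance, d$descriptor)))
      })
      nn_ranks <- utils::read.csv(stage_path(cfg, "nn_ranks.csv"))
      nn_ranks <- cbind(scale = nn_ranks$scale, method = "nn",
                        nn_ranks[c("descriptor", "value", "rank")])
      ranks <- rbind(do.call(rbind, plsr_ranks), nn_ranks)
      utils::write.csv(ranks, stage_path(cfg, "ranks.csv"),
                       row.names = FALSE)
      write_manifest(cfg)
      invisible(ranks)
    },
    stop("unknown stage: ", name)
  )
}

write_manifest <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "\\.(csv|json)$",
                      full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("timbral")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    n_participants = cfg$n_participants,
    threshold = cfg$threshold,
    learning_rate = cfg$learning_rate,
    epochs = as.list(cfg$epochs),
    checksums = as.list(tools::md5sum(files))
  )
  tmp <- tempfile(tmpdir = cfg$out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, stage_path(cfg, "manifest.json"))
  invisible(manifest)
}

#' Run the full pipeline
#'
#' @param cfg a [pipeline_config()].
#' @param stages stage subset, in order.
#' @return named list of stage outputs, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("synth", "extract", "reduce",
                                    "fit-plsr", "fit-nn", "contributions",
                                    "compare", "report")) {
  out <- lapply(stages, function(s) {
    message("[timbral] stage: ", s)
    run_stage(s, cfg)
  })
  names(out) <- stages
  invisible(out)
}
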