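#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed and a cohort
#' layout. Per-subject and per-stage seeds are fanned out deterministically
#' from the global seed by a counter scheme, so a run is a pure function of
#' (config, seed). The `"desk"` preset is the CPU-scale synthetic study used
#' by the package's tests and acceptance script: 96 x 96 mm sheets (~9.2k
#' vertices, 3 blocks per hemisphere), 3 subjects (2 train / 1 test), the
#' desk-scale SE-Unet. The `"reference"` preset mirrors the full study scale
#' (576 x 576 sheets = 331,776 vertices = 81 blocks per hemisphere, 5-level
#' SE-Unet with 64 base channels).
#'
#' @param preset `"desk"` or `"reference"`.
#' @param seed global integer seed.
#' @param n_subjects,n_train cohort size and training-subject count.
#' @param gender_effect mm ridge-height shift for gender 1 (see
#'   [generate_cohort()]).
#' @param synth,labeling,features,model,meanshift optional stage config
#'   overrides ([synth_config()], [labeling_config()], [feature_config()],
#'   [model_config()], [meanshift_config()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("desk", "reference"), seed = 1L,
                            n_subjects = NULL, n_train = NULL,
                            gender_effect = 0,
                            synth = NULL, labeling = NULL, features = NULL,
                            model = NULL, meanshift = NULL) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "desk") {
    n_subjects <- n_subjects %||% 3L
    n_train <- n_train %||% 2L
    synth <- synth %||% synth_config(seed = derive_seed(seed, 1L),
                                     grid_shape = c(96L, 96L), n_cells = 6L,
                                     margin = 8)
    model <- model %||% model_config(preset = "desk", epochs = 12L,
                                     seed = derive_seed(seed, 3L))
  } else {
    n_subjects <- n_subjects %||% 1000L
    n_train <- n_train %||% 900L
    synth <- synth %||% synth_config(seed = derive_seed(seed, 1L),
                                     grid_shape = c(576L, 576L),
                                     n_cells = 200L)
    model <- model %||% model_config(preset = "reference",
                                     seed = derive_seed(seed, 3L))
  }
  assert_that(n_train >= 1 && n_train < n_subjects,
              "need 1 <= n_train < n_subjects")
  labeling <- labeling %||% labeling_config()
  features <- features %||% feature_config()
  meanshift <- meanshift %||% meanshift_config()
  model$feature_names <- model$feature_names %||% features$feature_names
  model$n_features <- length(features$feature_names)
  if (model$n_features > 1L) model$variant <- "se_unet_fusion"
  structure(list(preset = preset, seed = seed, n_subjects = n_subjects,
                 n_train = as.integer(n_train), gender_effect = gender_effect,
                 synth = synth, labeling = labeling, features = features,
                 model = model, meanshift = meanshift),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("generate", "label", "features", "train", "predict",
                     "centroids", "evaluate")

stage_done <- function(out, stage, hash) {
  f <- file.path(out, stage, "stage.json")
  if (!file.exists(f)) return(FALSE)
  m <- tryCatch(jsonlite::read_json(f), error = function(e) NULL)
  identical(m$config_hash, hash)
}

mark_stage <- function(out, stage, hash, files) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, files = as.character(files)),
    file.path(out, stage, "stage.json"), auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop_hinge3(sprintf(
      "stage '%s' needs missing artifact '%s' (run stage '%s' first)",
      needed_by, path, stage), "hinge3_dependency_error")
  }
  path
}

subject_paths <- function(out, sid, hemi) {
  base <- file.path(out, "generate", sprintf("%s.%s", sid, hemi))
  list(surf = paste0(base, ".surf"),
       morph = stats::setNames(
         paste0(base, ".", c("sulc", "curv", "thick", "area", "vol")),
         c("sulc", "curv", "thick", "area", "vol")),
       two = paste0(base, ".2hinge.txt"),
       three = paste0(base, ".3hinge.txt"),
       truth_centroids = paste0(base, ".truth_centroids.csv"))
}

load_subject <- function(out, sid, hemi, stage = "generate",
                         needed_by = "label") {
  p <- subject_paths(out, sid, hemi)
  require_artifact(p$surf, stage, needed_by)
  surface <- read_surface(p$surf, hemisphere = hemi)
  morph <- lapply(p$morph, read_morph, surface = surface)
  cents <- readr::read_csv(p$truth_centroids, show_col_types = FALSE)
  ann <- hinge_annotation(read_hinge_list(p$two), read_hinge_list(p$three),
                          as.matrix(cents[, c("x", "y", "z")]),
                          surface = surface)
  list(surface = surface, morph = morph_maps(morph, surface),
       annotation = ann)
}

#' Run the 3-hinge identification pipeline
#'
#' Executes the requested stages in order, writing versioned outputs under
#' `out`: `generate` (synthetic cohort surfaces, morph maps and hinge
#' annotations in interchange formats), `label` (expanded binary region
#' labels), `features` (blocked KNN feature tensors), `train` (segmentation
#' network + log), `predict` (per-vertex labels for held-out subjects),
#' `centroids` (mean-shift centroid tables) and `evaluate` (metrics JSON).
#' Each stage records a config hash; rerunning an unchanged stage into the
#' same directory is a no-op unless `force = TRUE`. Requesting a stage whose
#' inputs are missing raises a dependency error naming the absent artifact.
#'
#' @param cfg a [pipeline_config()].
#' @param out output directory.
#' @param stages subset of
#'   `c("generate","label","features","train","predict","centroids","evaluate")`.
#' @param force rerun stages whose outputs are already up to date.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the cohort manifest, the trained model (if
#'   trained) and the final `eval_report` (if evaluated).
#' @export
run_pipeline <- function(cfg, out,
                         stages = PIPELINE_STAGES,
                         force = FALSE, verbose = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  hemis <- c("lh", "rh")
  cohort <- generate_cohort(cfg$n_subjects, cfg$synth, cfg$gender_effect)
  res$cohort <- cohort
  train_ids <- cohort$subject_id[seq_len(cfg$n_train)]
  test_ids <- setdiff(cohort$subject_id, train_ids)

  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    h <- config_hash(list(cfg = unclass(cfg), stage = stage))
    dir.create(file.path(out, stage), recursive = TRUE, showWarnings = FALSE)
    if (!force && stage_done(out, stage, h)) {
      say("stage %s: up to date, skipping", stage)
      return(invisible(NULL))
    }
    say("stage %s: running", stage)
    files <- fn()
    mark_stage(out, stage, h, files)
    invisible(NULL)
  }

  run_stage("generate", function() {
    files <- c()
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort_subject(cohort, i)
      for (hemi in hemis) {
        s <- subj[[hemi]]
        p <- subject_paths(out, cohort$subject_id[i], hemi)
        write_surface(s$surface, p$surf)
        for (nm in names(p$morph)) write_morph(s$morph[[nm]], p$morph[[nm]])
        write_hinge_list(s$annotation$two_hinge_idx, p$two)
        write_hinge_list(s$annotation$three_hinge_idx, p$three)
        cents <- s$annotation$three_hinge_centroids
        readr::write_csv(tibble::tibble(hemisphere = hemi,
                                        x = cents[, 1], y = cents[, 2],
                                        z = cents[, 3]),
                         p$truth_centroids)
        files <- c(files, p$surf)
      }
    }
    readr::write_csv(cohort[, c("subject_id", "gender", "seed",
                                "ridge_height")],
                     file.path(out, "generate", "manifest.csv"))
    files
  })

  run_stage("label", function() {
    files <- c()
    for (sid in cohort$subject_id) {
      for (hemi in hemis) {
        s <- load_subject(out, sid, hemi, needed_by = "label")
        lab <- expand_regions(s$surface, s$annotation, cfg$labeling)
        f <- file.path(out, "label", sprintf("%s.%s.labels.curv", sid, hemi))
        write_morph(as.numeric(lab), f)
        files <- c(files, f)
      }
    }
    files
  })

  run_stage("features", function() {
    files <- c()
    for (sid in cohort$subject_id) {
      for (hemi in hemis) {
        s <- load_subject(out, sid, hemi, needed_by = "features")
        blocks <- compute_feature_blocks(s$surface, s$morph, cfg$features)
        f <- file.path(out, "features", sprintf("%s.%s.blocks.rds", sid, hemi))
        saveRDS(blocks, f)
        files <- c(files, f)
      }
    }
    files
  })

  run_stage("train", function() {
    samples <- list()
    for (sid in train_ids) {
      for (hemi in hemis) {
        bf <- require_artifact(
          file.path(out, "features", sprintf("%s.%s.blocks.rds", sid, hemi)),
          "features", "train")
        lf <- require_artifact(
          file.path(out, "label", sprintf("%s.%s.labels.curv", sid, hemi)),
          "label", "train")
        blocks <- readRDS(bf)
        labels <- read_morph(lf)
        samples <- c(samples, blocks_to_samples(blocks, labels))
      }
    }
    model <- build_model(cfg$model)
    model <- train_model(model, samples, verbose = verbose)
    saveRDS(model, file.path(out, "train", "model.rds"))
    readr::write_csv(model$log, file.path(out, "train", "training_log.csv"))
    res$model <<- model
    file.path(out, "train", c("model.rds", "training_log.csv"))
  })

  run_stage("predict", function() {
    mf <- require_artifact(file.path(out, "train", "model.rds"),
                           "train", "predict")
    model <- readRDS(mf)
    files <- c()
    for (sid in test_ids) {
      for (hemi in hemis) {
        bf <- require_artifact(
          file.path(out, "features", sprintf("%s.%s.blocks.rds", sid, hemi)),
          "features", "predict")
        pred <- predict_regions(model, readRDS(bf))
        f <- file.path(out, "predict", sprintf("%s.%s.pred.curv", sid, hemi))
        write_morph(as.numeric(pred$label), f)
        write_hinge_list(pred$vertex[pred$label == 1L],
                         file.path(out, "predict",
                                   sprintf("%s.%s.pred.txt", sid, hemi)))
        files <- c(files, f)
      }
    }
    files
  })

  run_stage("centroids", function() {
    files <- c()
    for (sid in test_ids) {
      for (hemi in hemis) {
        pf <- require_artifact(
          file.path(out, "predict", sprintf("%s.%s.pred.curv", sid, hemi)),
          "predict", "centroids")
        s <- load_subject(out, sid, hemi, needed_by = "centroids")
        cents <- find_centroids(read_morph(pf), s$surface, cfg$meanshift)
        f <- file.path(out, "centroids", sprintf("%s.%s.centroids.csv", sid, hemi))
        readr::write_csv(
          cents[, c("hemisphere", "x", "y", "z", "cluster_size")], f)
        files <- c(files, f)
      }
    }
    files
  })

  run_stage("evaluate", function() {
    rows <- list()
    for (sid in test_ids) {
      for (hemi in hemis) {
        s <- load_subject(out, sid, hemi, needed_by = "evaluate")
        truth_lab <- read_morph(require_artifact(
          file.path(out, "label", sprintf("%s.%s.labels.curv", sid, hemi)),
          "label", "evaluate"))
        pred_lab <- read_morph(require_artifact(
          file.path(out, "predict", sprintf("%s.%s.pred.curv", sid, hemi)),
          "predict", "evaluate"))
        cents <- readr::read_csv(require_artifact(
          file.path(out, "centroids", sprintf("%s.%s.centroids.csv", sid, hemi)),
          "centroids", "evaluate"), show_col_types = FALSE)
        rm_ <- region_metrics(pred_lab, truth_lab)
        pre <- if (nrow(s$annotation$three_hinge_centroids) > 0) {
          centroid_pre(cents, s$annotation$three_hinge_centroids)
        } else NA_real_
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(subject_id = sid, hemisphere = hemi), rm_,
          tibble::tibble(pre = pre,
                         n_pred_centroids = nrow(cents),
                         n_truth_centroids =
                           nrow(s$annotation$three_hinge_centroids)))
      }
    }
    per_subject <- dplyr::bind_rows(rows)
    report <- aggregate_subjects(per_subject)
    res$report <<- report
    jsonlite::write_json(
      list(summary = report$summary, per_subject = per_subject),
      file.path(out, "evaluate", "evaluation.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE)
    readr::write_csv(per_subject,
                     file.path(out, "evaluate", "per_subject.csv"))
    file.path(out, "evaluate", c("evaluation.json", "per_subject.csv"))
  })

  invisible(res)
}
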