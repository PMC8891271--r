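# End-to-end pipeline: each stage reads files written by the previous one,
# so stages are independently re-runnable. Artifacts live under
# config$out_dir:
#   slides/          raw synthetic pair images + truth masks (simulate)
#   cohort.csv       slide_id, status, true_purity         (simulate)
#   normalized/      template-normalized H&E images        (normalize)
#   template.json    fitted stain template                 (normalize)
#   registered/      working-scale registered IHC + transforms (register)
#   labels.csv       training-mode tile manifest           (label)
#   labels_eval.csv  evaluation-mode tile manifest         (label)
#   model.json       fitted classifier                     (train)
#   predictions.csv  per-tile cancer probabilities         (predict)
#   eval_report.json accuracy / confusion / AUC            (evaluate)
#   purity.csv       per-slide purity estimates            (purity)

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Every
#' stochastic stage derives its seed from the global `seed`. Unknown keys
#' in any section are rejected.
#'
#' @param out_dir Artifact directory.
#' @param seed Global seed.
#' @param simulate,normalization,registration,labeling,classifier,evaluation
#'   Named lists overriding the per-stage defaults.
#' @param verbosity 0 = quiet, 1 = stage progress messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = list(),
                            normalization = list(), registration = list(),
                            labeling = list(), classifier = list(),
                            evaluation = list(), verbosity = 1L) {
  defaults <- list(
    simulate = list(n_cancer = 2L, n_normal = 1L, purity_grid = 0.5,
                    image_shape = c(1024L, 1024L), rotation_deg = 5,
                    translation_px = c(10, -6), warp_amplitude_px = 0,
                    noise_sd = 0.02),
    normalization = list(method = "vahadane", beta = 0.15, lambda = 0.1,
                         template = "auto"),
    registration = list(downscale = 5L, bins = 50L, maxit = 200L,
                        init_search_px = 30, do_bspline = FALSE,
                        bspline_spacing = 64, bspline_maxit = 15L),
    labeling = list(tile_px = 224L, cancer_fraction_threshold = 0.02,
                    dab_uncertain_low = 0.05, dab_uncertain_high = 0.15,
                    tissue_presence_min = 0.05, train_filter = TRUE),
    classifier = list(backbone = "tiny", hidden = 256L, epochs = 100L,
                      lr = 1e-4, batch_size = 32L, augment = TRUE),
    evaluation = list(threshold = 0.5, balance = TRUE)
  )
  merge_section <- function(name, user) {
    base <- defaults[[name]]
    bad <- setdiff(names(user), names(base))
    if (length(bad)) stop("unknown ", name, " config keys: ",
                          paste(bad, collapse = ", "))
    utils::modifyList(base, user)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), verbosity = verbosity,
    simulate = merge_section("simulate", simulate),
    normalization = merge_section("normalization", normalization),
    registration = merge_section("registration", registration),
    labeling = merge_section("labeling", labeling),
    classifier = merge_section("classifier", classifier),
    evaluation = merge_section("evaluation", evaluation)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching the arguments of
#'   [pipeline_config()].
#' @param out_dir Optional override of the configured artifact directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

say <- function(cfg, ...) if (cfg$verbosity > 0) message("[hemlabel] ", ...)

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", path, "': run the '", stage,
         "' stage first to produce it", call. = FALSE)
  path
}

slide_paths <- function(cfg, id) {
  list(he = file.path(cfg$out_dir, "slides", paste0(id, "_he.png")),
       ihc = file.path(cfg$out_dir, "slides", paste0(id, "_ihc.png")),
       tissue = file.path(cfg$out_dir, "slides", paste0(id, "_tissue.png")),
       cancer = file.path(cfg$out_dir, "slides", paste0(id, "_cancer.png")),
       he_norm = file.path(cfg$out_dir, "normalized", paste0(id, "_he.png")),
       ihc_reg = file.path(cfg$out_dir, "registered", paste0(id, "_ihc.png")),
       transform = file.path(cfg$out_dir, "registered", paste0(id, ".json")))
}

stage_simulate <- function(cfg) {
  dir.create(file.path(cfg$out_dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  s <- cfg$simulate
  coh <- generate_cohort(s$n_cancer, s$n_normal, seed = cfg$seed,
                         purity_grid = s$purity_grid,
                         image_shape = s$image_shape,
                         rotation_deg = s$rotation_deg,
                         translation_px = s$translation_px,
                         warp_amplitude_px = s$warp_amplitude_px,
                         noise_sd = s$noise_sd)
  for (sl in coh$slides) {
    p <- slide_paths(cfg, sl$pair$slide_id)
    write_image(sl$pair$he, p$he)
    write_image(sl$pair$ihc, p$ihc)
    write_mask(sl$truth$tissue_mask, p$tissue)
    write_mask(sl$truth$cancer_mask, p$cancer)
  }
  utils::write.csv(coh$manifest, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)
  say(cfg, "simulate: wrote ", nrow(coh$manifest), " slide pairs")
  invisible(coh$manifest)
}

read_cohort <- function(cfg) {
  utils::read.csv(need_artifact(file.path(cfg$out_dir, "cohort.csv"), "simulate"),
                  stringsAsFactors = FALSE)
}

stage_normalize <- function(cfg) {
  coh <- read_cohort(cfg)
  n <- cfg$normalization
  slides <- lapply(coh$slide_id, function(id)
    read_image(need_artifact(slide_paths(cfg, id)$he, "simulate")))
  ti <- if (identical(n$template, "auto"))
    select_template(slides, coh$status) else match(n$template, coh$slide_id)
  method_fit <- if (n$method == "reinhard") "vahadane" else n$method
  template <- fit_stain_template(slides[[ti]], method_fit, beta = n$beta,
                                 lambda = n$lambda, seed = cfg$seed)
  dir.create(file.path(cfg$out_dir, "normalized"), showWarnings = FALSE)
  for (i in seq_along(slides)) {
    out <- normalize_to_template(slides[[i]], template, n$method,
                                 beta = n$beta, lambda = n$lambda,
                                 seed = cfg$seed)
    write_image(out, slide_paths(cfg, coh$slide_id[i])$he_norm)
  }
  jsonlite::write_json(
    list(template_slide = coh$slide_id[ti], method = n$method,
         S = as.vector(template$S), c99 = template$c99,
         lab_mean = template$lab_mean, lab_sd = template$lab_sd),
    file.path(cfg$out_dir, "template.json"), auto_unbox = TRUE, digits = NA)
  say(cfg, "normalize: template slide ", coh$slide_id[ti])
  invisible(template)
}

stage_register <- function(cfg) {
  coh <- read_cohort(cfg)
  r <- cfg$registration
  dir.create(file.path(cfg$out_dir, "registered"), showWarnings = FALSE)
  reports <- list()
  for (id in coh$slide_id) {
    p <- slide_paths(cfg, id)
    he <- read_image(need_artifact(p$he_norm, "normalize"))
    ihc <- read_image(need_artifact(p$ihc, "simulate"))
    fit <- register_pair(he, ihc, downscale = r$downscale, bins = r$bins,
                         maxit = r$maxit, init_search_px = r$init_search_px,
                         do_bspline = r$do_bspline,
                         bspline_spacing = r$bspline_spacing,
                         bspline_maxit = r$bspline_maxit)
    ihc_small <- downscale_mean(ihc, r$downscale)
    write_image(apply_transform(ihc_small, fit$chain), p$ihc_reg)
    transform_to_json(fit$chain, p$transform)
    reports[[id]] <- data.frame(slide_id = id,
                                mi_before = fit$report$mi_before,
                                mi_after_affine = fit$report$mi_after_affine,
                                mi_after_bspline = fit$report$mi_after_bspline)
    say(cfg, "register ", id, ": MI ",
        sprintf("%.3f -> %.3f", fit$report$mi_before, fit$report$mi_after_bspline))
  }
  mi <- do.call(rbind, reports)
  utils::write.csv(mi, file.path(cfg$out_dir, "mi_report.csv"), row.names = FALSE)
  invisible(mi)
}

labeling_from_cfg <- function(cfg) {
  l <- cfg$labeling
  labeling_config(tile_px = l$tile_px, downscale = cfg$registration$downscale,
                  cancer_fraction_threshold = l$cancer_fraction_threshold,
                  dab_uncertain_low = l$dab_uncertain_low,
                  dab_uncertain_high = l$dab_uncertain_high,
                  tissue_presence_min = l$tissue_presence_min,
                  train_filter = l$train_filter)
}

load_pairs <- function(cfg) {
  coh <- read_cohort(cfg)
  lapply(seq_len(nrow(coh)), function(i) {
    p <- slide_paths(cfg, coh$slide_id[i])
    list(slide_id = coh$slide_id[i],
         he = read_image(need_artifact(p$he_norm, "normalize")),
         ihc_reg = read_image(need_artifact(p$ihc_reg, "register")),
         status = coh$status[i])
  })
}

stage_label <- function(cfg) {
  pairs <- load_pairs(cfg)
  lcfg <- labeling_from_cfg(cfg)
  train_man <- build_dataset(pairs, lcfg, mode = "train")
  eval_man <- build_dataset(pairs, lcfg, mode = "eval")
  write_manifest(train_man, file.path(cfg$out_dir, "labels.csv"))
  write_manifest(eval_man, file.path(cfg$out_dir, "labels_eval.csv"))
  counts <- table(train_man$slide_id, train_man$label)
  jsonlite::write_json(as.data.frame.matrix(counts),
                       file.path(cfg$out_dir, "label_counts.json"))
  say(cfg, "label: ", sum(train_man$label %in% c("cancer", "normal")),
      " kept training tiles of ", nrow(train_man))
  invisible(train_man)
}

normalized_images <- function(cfg) {
  coh <- read_cohort(cfg)
  imgs <- lapply(coh$slide_id, function(id)
    read_image(need_artifact(slide_paths(cfg, id)$he_norm, "normalize")))
  names(imgs) <- coh$slide_id
  imgs
}

stage_train <- function(cfg) {
  man <- read_manifest(need_artifact(file.path(cfg$out_dir, "labels.csv"), "label"))
  c_ <- cfg$classifier
  spec <- classifier_spec(backbone = c_$backbone, hidden = c_$hidden,
                          epochs = c_$epochs, lr = c_$lr,
                          batch_size = c_$batch_size, augment = c_$augment,
                          seed = cfg$seed)
  model <- train_tile_classifier(man, normalized_images(cfg), spec)
  classifier_to_json(model, file.path(cfg$out_dir, "model.json"))
  say(cfg, "train: final BCE loss ", sprintf("%.4f", model$loss[length(model$loss)]))
  invisible(model)
}

stage_predict <- function(cfg) {
  man <- read_manifest(need_artifact(file.path(cfg$out_dir, "labels_eval.csv"), "label"))
  model <- classifier_from_json(need_artifact(file.path(cfg$out_dir, "model.json"), "train"))
  preds <- predict_tiles(model, man, normalized_images(cfg))
  utils::write.csv(preds, file.path(cfg$out_dir, "predictions.csv"), row.names = FALSE)
  say(cfg, "predict: scored ", nrow(preds), " tiles")
  invisible(preds)
}

stage_evaluate <- function(cfg) {
  preds <- utils::read.csv(need_artifact(file.path(cfg$out_dir, "predictions.csv"),
                                         "predict"), stringsAsFactors = FALSE)
  man <- read_manifest(need_artifact(file.path(cfg$out_dir, "labels_eval.csv"), "label"))
  rep <- evaluate_predictions(preds, man, seed = cfg$seed,
                              threshold = cfg$evaluation$threshold,
                              balance = cfg$evaluation$balance)
  jsonlite::write_json(list(accuracy = rep$accuracy,
                            roc_auc = rep$roc_auc,
                            confusion = as.vector(rep$confusion),
                            n_per_class = as.vector(rep$n_per_class),
                            balancing_seed = rep$balancing_seed),
                       file.path(cfg$out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  say(cfg, "evaluate: accuracy ", sprintf("%.3f", rep$accuracy),
      ", AUC ", sprintf("%.3f", rep$roc_auc))
  invisible(rep)
}

stage_purity <- function(cfg) {
  preds <- utils::read.csv(need_artifact(file.path(cfg$out_dir, "predictions.csv"),
                                         "predict"), stringsAsFactors = FALSE)
  man <- read_manifest(need_artifact(file.path(cfg$out_dir, "labels_eval.csv"), "label"))
  j <- merge(preds, man[, c("slide_id", "tile_row", "tile_col", "tissue_fraction_he")],
             by = c("slide_id", "tile_row", "tile_col"))
  j <- j[j$tissue_fraction_he > 0, , drop = FALSE]
  pur <- estimate_purity(j, j$tissue_fraction_he,
                         threshold = cfg$evaluation$threshold)
  coh <- read_cohort(cfg)
  pur <- merge(pur, coh[, c("slide_id", "true_purity")], by = "slide_id",
               all.x = TRUE)
  utils::write.csv(pur, file.path(cfg$out_dir, "purity.csv"), row.names = FALSE)
  say(cfg, "purity: ", nrow(pur), " slides")
  invisible(pur)
}

#' Run the label-transfer pipeline
#'
#' Executes the requested stages in fixed order (`simulate`, `normalize`,
#' `register`, `label`, `train`, `predict`, `evaluate`, `purity`), each
#' reading the artifacts of its predecessors from `config$out_dir` and
#' writing its own. A provenance record (`run_info.json`: config, seed,
#' package version, config hash) is written on every run.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the stage names; defaults to all.
#' @return Named list of the stage results, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "normalize", "register",
                                            "label", "train", "predict",
                                            "evaluate", "purity")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "normalize", "register", "label", "train",
                 "predict", "evaluate", "purity")
  stages <- order_all[order_all %in% match.arg(stages, order_all, several.ok = TRUE)]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_yaml <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(unclass(config), cfg_yaml)
  jsonlite::write_json(list(seed = config$seed,
                            package_version = as.character(utils::packageVersion("hemlabel")),
                            config_md5 = unname(tools::md5sum(cfg_yaml)),
                            stages = stages),
                       file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  runners <- list(simulate = stage_simulate, normalize = stage_normalize,
                  register = stage_register, label = stage_label,
                  train = stage_train, predict = stage_predict,
                  evaluate = stage_evaluate, purity = stage_purity)
  results <- list()
  for (st in stages) results[[st]] <- runners[[st]](config)
  invisible(results)
}
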