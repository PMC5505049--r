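#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis in one validated
#' object. Defaults reproduce the standard setup: parenchymal window
#' -1024..-250 HU, 64 grey levels, four orientations at distance 1, 3 PLS
#' latent variables, scale-free SVM defaults, and a 10000-resample bootstrap
#' screen at alpha 0.05.
#'
#' @param hu_low,hu_high Segmentation window, HU.
#' @param levels Grey levels for quantization.
#' @param orientations GLCM orientations (degrees, as characters).
#' @param distance GLCM pair distance, pixels.
#' @param quantize_mode `"fixed_window"` or `"per_image"`.
#' @param sum_variance_center `"sum_entropy"` or `"sum_average"`.
#' @param n_lv PLS-DA latent variables.
#' @param svm_gamma,svm_cost SVM hyperparameters (`NULL` gamma = 1/p).
#' @param classifier `"plsda"`, `"svm"` or `"both"`.
#' @param boot_resamples,boot_alpha Bootstrap screen settings.
#' @param design A [study_design()] used when the pipeline simulates its own
#'   input; ignored when a manifest is supplied.
#' @param seed Integer seed for the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(hu_low = -1024, hu_high = -250, levels = 64,
                            orientations = c("0", "45", "90", "135"),
                            distance = 1,
                            quantize_mode = "fixed_window",
                            sum_variance_center = "sum_entropy",
                            n_lv = 3, svm_gamma = NULL, svm_cost = 1,
                            classifier = c("both", "plsda", "svm"),
                            boot_resamples = 10000, boot_alpha = 0.05,
                            design = NULL, seed = 1) {
  classifier <- match.arg(classifier)
  check <- function(ok, field, constraint) {
    if (!ok) abort(sprintf("pipeline_config: `%s` %s", field, constraint))
  }
  check(hu_low < hu_high, "hu_low/hu_high", "must satisfy hu_low < hu_high")
  check(levels >= 2, "levels", "must be >= 2")
  check(all(orientations %in% c("0", "45", "90", "135")), "orientations",
        "must be among 0, 45, 90, 135")
  check(distance >= 1, "distance", "must be >= 1")
  check(n_lv >= 1, "n_lv", "must be >= 1")
  check(is.null(svm_gamma) || svm_gamma > 0, "svm_gamma", "must be positive")
  check(svm_cost > 0, "svm_cost", "must be positive")
  check(boot_resamples >= 1, "boot_resamples", "must be >= 1")
  check(boot_alpha > 0 && boot_alpha < 1, "boot_alpha", "must be in (0, 1)")
  if (is.null(design)) design <- study_design(seed = seed)
  stopifnot(inherits(design, "study_design"))
  structure(list(hu_low = hu_low, hu_high = hu_high, levels = levels,
                 orientations = orientations, distance = distance,
                 quantize_mode = quantize_mode,
                 sum_variance_center = sum_variance_center,
                 n_lv = n_lv, svm_gamma = svm_gamma, svm_cost = svm_cost,
                 classifier = classifier,
                 boot_resamples = boot_resamples, boot_alpha = boot_alpha,
                 design = design, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override [pipeline_config()] defaults; a `design:` block
#' overrides [study_design()] defaults. Unknown fields raise an error naming
#' them.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design_args <- raw$design
  raw$design <- NULL
  known <- setdiff(names(formals(pipeline_config)), "design")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(design_args)) {
    seed <- raw$seed %||% formals(study_design)$seed
    design_args$seed <- design_args$seed %||% seed
    raw$design <- do.call(study_design, design_args)
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end texture analysis pipeline
#'
#' Simulates (or ingests) the study, builds the feature table, fits the
#' requested classifiers under leave-one-dog-out cross-validation, computes
#' ROC curves, and runs the diseased-group bootstrap screen. When `out_dir`
#' is given, writes `features.csv`, `cv_report.csv`, `roc_points.csv`,
#' `bootstrap.csv` and a `run.log` accounting for configuration, seed and
#' every excluded slice.
#'
#' @param config A [pipeline_config()].
#' @param manifest Optional path to a slice manifest CSV; when `NULL` the
#'   study is simulated from `config$design`.
#' @param out_dir Optional output directory for the CSV artifacts.
#' @return List: `features`, `reports` (one `cv_report` per classifier),
#'   `roc` (tibble per classifier), `bootstrap`, `excluded`.
#' @export
run_pipeline <- function(config = pipeline_config(), manifest = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  slices <- if (is.null(manifest)) {
    generate_study(config$design)
  } else {
    read_manifest(manifest)
  }
  n_in <- nrow(slices)
  feats <- feature_table(slices, low = config$hu_low, high = config$hu_high,
                         levels = config$levels, distance = config$distance,
                         orientations = config$orientations,
                         quantize_mode = config$quantize_mode,
                         sum_variance_center = config$sum_variance_center)
  excluded <- attr(feats, "excluded")
  stopifnot(nrow(feats) + nrow(excluded) == n_in)

  learners <- switch(config$classifier,
    plsda = list(plsda = plsda_spec(config$n_lv)),
    svm = list(svm = svm_spec(config$svm_gamma, config$svm_cost)),
    both = list(plsda = plsda_spec(config$n_lv),
                svm = svm_spec(config$svm_gamma, config$svm_cost)))
  reports <- lapply(learners, function(sp) leave_one_dog_out(feats, sp))
  roc <- lapply(reports, cv_roc)

  boot <- if (all(c("pte", "no_pte") %in% feats$class_label)) {
    diseased_feature_screen(feats, n_resamples = config$boot_resamples,
                            alpha = config$boot_alpha,
                            seed = config$seed)
  } else NULL

  result <- list(features = feats, reports = reports, roc = roc,
                 bootstrap = boot, excluded = excluded, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  cv <- dplyr::bind_rows(lapply(names(result$reports), function(nm) {
    m <- result$reports[[nm]]$metrics
    m$classifier <- nm
    m
  }))
  write.csv(cv, file.path(out_dir, "cv_report.csv"), row.names = FALSE)
  roc_pts <- dplyr::bind_rows(lapply(names(result$roc), function(nm) {
    purrr::map_dfr(seq_len(nrow(result$roc[[nm]])), function(i) {
      cur <- result$roc[[nm]]$curve[[i]]
      pts <- cur$points
      pts$class <- cur$class
      pts$mode <- result$roc[[nm]]$mode[i]
      pts$classifier <- nm
      pts
    })
  }))
  write.csv(roc_pts, file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  if (!is.null(result$bootstrap)) {
    write.csv(result$bootstrap, file.path(out_dir, "bootstrap.csv"),
              row.names = FALSE)
  }
  cfg <- result$config
  log_lines <- c(
    sprintf("pulmotex %s run at %s", utils::packageVersion("pulmotex"),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d", cfg$seed),
    sprintf("window: [%g, %g] HU; levels: %d; distance: %d; orientations: %s",
            cfg$hu_low, cfg$hu_high, cfg$levels, cfg$distance,
            paste(cfg$orientations, collapse = ",")),
    sprintf("classifier: %s; n_lv: %d; svm_cost: %g", cfg$classifier,
            cfg$n_lv, cfg$svm_cost),
    sprintf("slices in: %d; used: %d; excluded: %d",
            nrow(result$features) + nrow(result$excluded),
            nrow(result$features), nrow(result$excluded)))
  if (nrow(result$excluded) > 0) {
    log_lines <- c(log_lines, "excluded slices:",
                   sprintf("  %s slice %s (%s)", result$excluded$dog_id,
                           result$excluded$slice_index,
                           result$excluded$reason))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
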