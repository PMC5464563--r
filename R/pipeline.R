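# End-to-end orchestration: normalize -> segment -> detect -> features ->
# classify -> evaluate, with a single configuration object and a
# provenance log per run.

#' Pipeline configuration
#'
#' Two operating profiles share one detector: algorithm A uses a low NCC
#' threshold (high sensitivity, more false positives), algorithm B a high
#' one.  All "experimentally determined" knobs live here and are written
#' into every run's provenance log.
#'
#' @param algorithm `"A"` (default) or `"B"`.
#' @param ncc_threshold NCC acceptance threshold; defaults to 0.5 for A
#'   and 0.7 for B.
#' @param template_diameters_mm template bank diameters.
#' @param reference_level normalization target intensity.
#' @param seg_tolerance region-growing intensity tolerance (applied to the
#'   normalized volume).
#' @param seg_sphere_radius SSRG sphere radius in voxels.
#' @param cluster_thresholds morphology thresholds for the clustering
#'   branch (see [cluster_candidates]).
#' @param quant_levels,dilate feature-extraction quantization and region
#'   dilation.
#' @param hit_margin_mm evaluation hit margin.
#' @param cutoff ANN probability cutoff for final detections.
#' @return list of class `cad_config`.
#' @export
cad_config <- function(algorithm = c("A", "B"), ncc_threshold = NULL,
                       template_diameters_mm = c(2, 3, 4),
                       reference_level = 1000, seg_tolerance = 650,
                       seg_sphere_radius = 2,
                       cluster_thresholds = list(min_volume_mm3 = 65,
                                                 min_sphericity = 0.4,
                                                 max_extent_mm = 25),
                       quant_levels = 32, dilate = 1,
                       hit_margin_mm = 1, cutoff = 0.5) {
  algorithm <- match.arg(algorithm)
  if (is.null(ncc_threshold))
    ncc_threshold <- if (algorithm == "A") 0.5 else 0.7
  structure(list(algorithm = algorithm, ncc_threshold = ncc_threshold,
                 template_diameters_mm = template_diameters_mm,
                 reference_level = reference_level,
                 seg_tolerance = seg_tolerance,
                 seg_sphere_radius = seg_sphere_radius,
                 cluster_thresholds = cluster_thresholds,
                 quant_levels = quant_levels, dilate = dilate,
                 hit_margin_mm = hit_margin_mm, cutoff = cutoff),
            class = "cad_config")
}

#' Detect candidates in a segmented volume
#'
#' Runs both detection branches (template matching and clustering) and
#' merges them.
#'
#' @param volume normalized [volume3d].
#' @param mask `brain_mask`.
#' @param config a [cad_config].
#' @return candidate data frame.
#' @export
detect_candidates <- function(volume, mask, config = cad_config()) {
  tpl <- default_templates(volume$spacing_mm, config$template_diameters_mm)
  a <- template_match(volume, mask, tpl, config$ncc_threshold)
  b <- cluster_candidates(volume, mask, config$cluster_thresholds)
  merge_candidates(a, b)
}

#' Run the full CAD pipeline on one case
#'
#' Normalizes the volume at the seed, extracts the brain by SSRG, detects
#' candidates through both branches, extracts the 30-feature vector per
#' candidate and, when a trained model is supplied, converts candidates to
#' probability-scored detections at the configured cutoff.  Identical
#' inputs and configuration give identical output.
#'
#' @param volume a [volume3d].
#' @param seed_point a [seed_point]; `NULL` selects one with [auto_seed].
#' @param config a [cad_config].
#' @param model a trained `ann_model`, or `NULL` to stop after feature
#'   extraction (all candidates returned with probability `NA`).
#' @return list with `detections` (data frame `case_id, x_mm, y_mm, z_mm,
#'   probability`, plus geometry), `candidates`, `features`, `mask`, and
#'   `provenance`.
#' @export
run_case <- function(volume, seed_point = NULL, config = cad_config(),
                     model = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for case ", volume$case_id, ": ",
           conditionMessage(e), call. = FALSE))
  }
  if (is.null(seed_point)) {
    # try ranked automatic seeds until one satisfies the spherical
    # growth condition (a seed can abut an enhancing vessel)
    seeds <- stage("auto_seed", auto_seed_ranked(volume))
    norm <- mask <- NULL
    for (sp in seeds) {
      res <- tryCatch({
        nv <- normalize_intensity(volume, sp, config$reference_level)
        list(norm = nv,
             mask = ssrg(nv, sp, config$seg_tolerance,
                         config$seg_sphere_radius))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        seed_point <- sp; norm <- res$norm; mask <- res$mask
        break
      }
    }
    if (is.null(mask))
      stage("segment",
            stop("no automatic seed satisfied the growth condition"))
  } else {
    norm <- stage("normalize",
                  normalize_intensity(volume, seed_point,
                                      config$reference_level))
    mask <- stage("segment",
                  ssrg(norm, seed_point, config$seg_tolerance,
                       config$seg_sphere_radius))
  }
  timings <- c(segment = proc.time()[["elapsed"]] - t0)
  if (!any(mask$mask)) {
    warning("empty brain mask for case ", volume$case_id,
            ": zero detections")
    cand <- empty_candidates()
  } else {
    cand <- stage("detect", detect_candidates(norm, mask, config))
  }
  timings <- c(timings, detect = proc.time()[["elapsed"]] - t0)
  feats <- stage("features",
                 extract_feature_table(norm, cand, L = config$quant_levels,
                                       dilate = config$dilate))
  timings <- c(timings, features = proc.time()[["elapsed"]] - t0)
  if (!is.null(model) && nrow(cand)) {
    flt <- stage("classify",
                 filter_candidates(cand, model, config$cutoff,
                                   features = feats))
    det <- flt$detections
    scored <- flt$scored
  } else {
    det <- scored <- cbind(cand, probability = rep(NA_real_, nrow(cand)))
  }
  timings <- c(timings, total = proc.time()[["elapsed"]] - t0)
  list(detections = det[, setdiff(names(det), "voxels")],
       scored = scored[, setdiff(names(scored), "voxels")],
       candidates = cand, features = feats, mask = mask,
       provenance = list(case_id = volume$case_id,
                         seed_voxel = seed_point$voxel,
                         seed_kind = seed_point$kind,
                         config = unclass(config),
                         timings_sec = timings))
}

#' Build an ANN training table from phantom cases
#'
#' Runs normalization, segmentation, detection and feature extraction on
#' each case and labels every candidate TP/FP by matching its centroid
#' against the case's ground truth.
#'
#' @param cases list of `list(volume, truth)` (see [phantom_suite]).
#' @param config a [cad_config].
#' @return list with `features` (matrix), `labels` (logical), and
#'   `candidates`.
#' @export
build_training_set <- function(cases, config = cad_config()) {
  feats <- list(); labs <- list(); cands <- list()
  for (cs in cases) {
    run <- run_case(cs$volume, config = config, model = NULL)
    if (!nrow(run$candidates)) next
    tt <- truth_table(cs$truth, cs$volume$spacing_mm)
    marks <- data.frame(case_id = run$candidates$case_id,
                        x_mm = run$candidates$x_mm,
                        y_mm = run$candidates$y_mm,
                        z_mm = run$candidates$z_mm,
                        probability = run$candidates$score)
    m <- match_marks(marks, tt, config$hit_margin_mm)
    feats[[length(feats) + 1L]] <- as.matrix(run$features)
    labs[[length(labs) + 1L]] <- m$marks$is_tp
    cands[[length(cands) + 1L]] <- run$candidates
  }
  list(features = do.call(rbind, feats), labels = unlist(labs),
       candidates = do.call(rbind, cands))
}

#' Compare the A and B operating profiles on the same cases
#'
#' Runs both configurations (which may differ only in their threshold
#' profile) over the case set and reports sensitivity and FP per case for
#' each, together with the expected ordering checks: A is at least as
#' sensitive as B and produces at least as many false positives.
#'
#' @param cases list of `list(volume, truth)`.
#' @param configA,configB the two [cad_config]s.
#' @param model optional `ann_model` applied to both.
#' @param size_floor_mm optional size floor for sensitivity.
#' @return list with per-algorithm metrics and `ordering_holds`.
#' @export
compare_algorithms <- function(cases, configA = cad_config("A"),
                               configB = cad_config("B"), model = NULL,
                               size_floor_mm = NULL) {
  nonthr <- function(cfg) unclass(cfg)[setdiff(names(cfg),
                                               c("algorithm", "ncc_threshold"))]
  if (!identical(nonthr(configA), nonthr(configB)))
    stop("configs must differ only in their threshold profile")
  eval_one <- function(config) {
    marks <- list(); truths <- list(); ids <- character(0)
    for (cs in cases) {
      run <- run_case(cs$volume, config = config, model = model)
      det <- if (is.null(model)) run$scored else run$detections
      det$probability[is.na(det$probability)] <- det$score[is.na(det$probability)]
      marks[[length(marks) + 1L]] <-
        det[, c("case_id", "x_mm", "y_mm", "z_mm", "probability")]
      truths[[length(truths) + 1L]] <- truth_table(cs$truth,
                                                   cs$volume$spacing_mm)
      ids <- c(ids, cs$volume$case_id)
    }
    m <- match_marks(do.call(rbind, marks), do.call(rbind, truths),
                     configA$hit_margin_mm, case_ids = ids)
    sensitivity_fp(m, size_floor_mm)
  }
  a <- eval_one(configA)
  b <- eval_one(configB)
  list(A = a, B = b,
       ordering_holds = a$sensitivity >= b$sensitivity &&
         a$fp_per_case >= b$fp_per_case)
}
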