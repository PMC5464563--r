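# Dual-branch candidate detection: NCC template matching for small
# spheroid nodules, K-means intensity clustering for large or irregular
# (and necrotic) lesions, then a merge of the two branches.

empty_candidates <- function() {
  data.frame(case_id = character(), i = integer(), j = integer(),
             k = integer(), x_mm = numeric(), y_mm = numeric(),
             z_mm = numeric(), radius_mm = numeric(),
             source = character(), score = numeric(),
             voxels = I(list()), stringsAsFactors = FALSE)
}

make_candidates <- function(case_id, centroid, radius_mm, source, score,
                            spacing_mm, voxels = NULL) {
  n <- nrow(centroid)
  if (n == 0L) return(empty_candidates())
  mm <- voxel_to_mm(centroid, spacing_mm)
  if (is.null(voxels)) voxels <- rep(list(NULL), n)
  data.frame(case_id = rep(case_id, n),
             i = as.integer(centroid[, 1]), j = as.integer(centroid[, 2]),
             k = as.integer(centroid[, 3]),
             x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
             radius_mm = radius_mm, source = source, score = score,
             voxels = I(voxels), stringsAsFactors = FALSE)
}

#' Template-matching candidate detection
#'
#' Sweeps each spherical template across the brain volume, computing the
#' normalized cross-correlation at every in-mask voxel where the template
#' window fits.  Voxels whose similarity exceeds `threshold` are labelled
#' under 26-connectivity; each label becomes one candidate whose centroid
#' is the label's (rounded) centre of mass, whose equivalent radius is the
#' template radius, and whose score is the maximum NCC inside the label.
#' Candidates from all templates are pooled.
#'
#' @param volume a [volume3d] (normalized).
#' @param mask a `brain_mask` (or logical array) restricting the search.
#' @param templates list of [make_template] objects; default
#'   [default_templates] at the volume's spacing.
#' @param threshold NCC acceptance threshold in (-1, 1).
#' @return A candidate data frame (one row per candidate; columns
#'   `case_id, i, j, k, x_mm, y_mm, z_mm, radius_mm, source, score,
#'   voxels`).
#' @export
template_match <- function(volume, mask, templates = NULL, threshold = 0.5) {
  if (inherits(mask, "brain_mask")) mask <- mask$mask
  stopifnot(all(dim(mask) == dim(volume$data)))
  if (threshold <= -1 || threshold >= 1)
    stop("`threshold` must lie in (-1, 1)")
  if (is.null(templates)) templates <- default_templates(volume$spacing_mm)
  if (!any(mask)) return(empty_candidates())
  out <- empty_candidates()
  for (tpl in templates) {
    u <- tpl$weights - tpl$t_mean
    nccmap <- ncc_sweep_cpp(volume$data, mask, dim(volume$data),
                            u, dim(tpl$weights), tpl$t_sd)
    hits <- !is.na(nccmap) & nccmap > threshold
    if (!any(hits)) next
    lab <- label_components_cpp(hits, dim(hits), 26L)
    nlab <- max(lab)
    idx <- which(lab > 0L, arr.ind = TRUE)
    labv <- lab[lab > 0L]
    sc <- nccmap[lab > 0L]
    cent <- matrix(0L, nrow = nlab, ncol = 3)
    score <- numeric(nlab)
    for (l in seq_len(nlab)) {
      sel <- labv == l
      cent[l, ] <- as.integer(round(colMeans(idx[sel, , drop = FALSE])))
      score[l] <- max(sc[sel])
    }
    out <- rbind(out, make_candidates(volume$case_id, cent,
                                      tpl$diameter_mm / 2, "template",
                                      score, volume$spacing_mm))
  }
  rownames(out) <- NULL
  out
}

#' One-dimensional K-means clustering of intensities
#'
#' Lloyd iterations on scalar values with deterministic initialization at
#' the `k` evenly spaced quantiles `(1/2k, 3/2k, ..., (2k-1)/2k)`, so
#' identical inputs always give identical clusters.  Points go to the
#' nearest centre (Euclidean distance); within-cluster inertia is
#' non-increasing across iterations; centres are returned sorted ascending
#' with assignments renumbered to match.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of clusters (default 7: enhancing tissue, four tissue /
#'   boundary classes, down to necrotic).
#' @param max_iter,tol iteration cap and relative-inertia convergence
#'   tolerance.
#' @return list with `centers` (sorted), `assignments` (index into
#'   `centers`), `inertia`, `iterations`.
#' @export
kmeans_1d <- function(values, k = 7, max_iter = 300, tol = 1e-6) {
  values <- as.numeric(values)
  if (length(unique(values)) < k)
    stop("need at least ", k, " distinct values, got ",
         length(unique(values)))
  centers <- unname(quantile(values, (2 * seq_len(k) - 1) / (2 * k)))
  # nudge coincident initial centres apart so all k survive
  if (anyDuplicated(centers))
    centers <- centers + seq_len(k) * 1e-9 * max(1, diff(range(values)))
  centers <- sort(centers)
  inertia <- Inf
  assign <- NULL
  for (it in seq_len(max_iter)) {
    bounds <- (head(centers, -1) + centers[-1]) / 2
    assign <- findInterval(values, bounds) + 1L
    means <- tapply(values, factor(assign, levels = seq_len(k)), mean)
    new_centers <- as.numeric(ifelse(is.na(means), centers, means))
    ord <- order(new_centers)
    new_centers <- new_centers[ord]
    new_inertia <- sum((values - new_centers[match(assign, ord)])^2)
    converged <- is.finite(inertia) &&
      (inertia - new_inertia) <= tol * max(inertia, .Machine$double.eps)
    centers <- new_centers
    inertia <- new_inertia
    if (converged) break
  }
  bounds <- (head(centers, -1) + centers[-1]) / 2
  assign <- findInterval(values, bounds) + 1L
  list(centers = centers, assignments = assign,
       inertia = sum((values - centers[assign])^2), iterations = it)
}

# Per-label morphology on a labelled array: volume (mm^3), surface area
# from exposed 6-neighbor faces (mm^2), sphericity, bounding-box extent
# (mm), centroid (voxel).
label_morphology <- function(lab, spacing_mm) {
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  d <- dim(lab)
  vox_vol <- prod(spacing_mm)
  face_area <- c(spacing_mm[2] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  idx <- which(lab > 0L, arr.ind = TRUE)
  labv <- lab[lab > 0L]
  res <- data.frame(label = seq_len(nlab), n_vox = 0L, volume_mm3 = 0,
                    area_mm2 = 0, sphericity = 0, extent_mm = 0,
                    ci = 0, cj = 0, ck = 0)
  pad_shift <- function(arr, axis, by) {
    # value of neighbor at +by along axis, 0 outside
    out <- array(0L, dim = d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { src[[axis]] <- seq_len(d[axis] - 1) + 1
                  dst[[axis]] <- seq_len(d[axis] - 1) }
    else        { src[[axis]] <- seq_len(d[axis] - 1)
                  dst[[axis]] <- seq_len(d[axis] - 1) + 1 }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  # exposed faces per axis direction
  area_by_label <- numeric(nlab)
  for (axis in 1:3) {
    for (by in c(-1L, 1L)) {
      nb <- pad_shift(lab, axis, by)
      exposed <- lab > 0L & nb != lab
      if (any(exposed)) {
        cnt <- tabulate(lab[exposed], nbins = nlab)
        area_by_label <- area_by_label + cnt * face_area[axis]
      }
    }
  }
  for (l in seq_len(nlab)) {
    sel <- labv == l
    pts <- idx[sel, , drop = FALSE]
    nv <- nrow(pts)
    V <- nv * vox_vol
    A <- area_by_label[l]
    ext <- max((apply(pts, 2, max) - apply(pts, 2, min) + 1) * spacing_mm)
    res[l, ] <- list(l, nv, V, A,
                     if (A > 0) pi^(1 / 3) * (6 * V)^(2 / 3) / A else 0,
                     ext, mean(pts[, 1]), mean(pts[, 2]), mean(pts[, 3]))
  }
  res
}

#' Clustering-branch candidate detection
#'
#' Runs [kmeans_1d] (k = 7) on the in-mask intensities and keeps the
#' voxels of the two extreme clusters: the highest-mean cluster captures
#' enhancing lesions, the lowest-mean cluster captures necrotic cores.
#' Each extreme cluster's voxel set is labelled twice under
#' 26-connectivity: as-is, and after a morphological opening (erosion then
#' dilation, radius 1 voxel) that deletes thin vessel-like tubes and so
#' separates lesions a vessel happens to touch.  Each label's volume and
#' sphericity are computed, labels passing all morphology thresholds
#' become candidates with equivalent radius `(3V / 4 pi)^(1/3)`, and the
#' two labelings are deduplicated.  The remaining labels are dropped as
#' false positives.
#'
#' Note the sphericity is computed from the voxelized surface (exposed
#' 6-neighbor faces), which over-counts a smooth surface by roughly 1.5x,
#' so a digitized ball scores about 0.66 rather than 1; the default
#' threshold of 0.4 is calibrated to that convention.
#'
#' @param volume a [volume3d] (normalized).
#' @param mask a `brain_mask` or logical array.
#' @param morpho_thresholds list with `min_volume_mm3` (default 65, about a
#'   5 mm sphere, where the template branch hands over), `min_sphericity`
#'   (default 0.4) and `max_extent_mm` (default 25, rejecting labels far
#'   larger than any plausible lesion).  These are calibration
#'   knobs, not published values.
#' @param k number of intensity clusters (default 7).
#' @return A candidate data frame; cluster-branch rows keep their voxel
#'   sets in the `voxels` list column.
#' @export
cluster_candidates <- function(volume, mask,
                               morpho_thresholds = list(), k = 7) {
  if (inherits(mask, "brain_mask")) mask <- mask$mask
  if (!any(mask)) return(empty_candidates())
  thr <- modifyList(list(min_volume_mm3 = 65, min_sphericity = 0.4,
                         max_extent_mm = 25), morpho_thresholds)
  vals <- volume$data[mask]
  km <- kmeans_1d(vals, k = k)
  d <- dim(volume$data)
  off1 <- sphere_offsets(1)
  label_to_cands <- function(sel) {
    lab <- label_components_cpp(sel, d, 26L)
    morph <- label_morphology(lab, volume$spacing_mm)
    if (is.null(morph)) return(empty_candidates())
    keep <- morph$volume_mm3 >= thr$min_volume_mm3 &
      morph$sphericity >= thr$min_sphericity &
      morph$extent_mm <= thr$max_extent_mm
    morph <- morph[keep, , drop = FALSE]
    if (nrow(morph) == 0L) return(empty_candidates())
    cent <- as.matrix(round(morph[, c("ci", "cj", "ck")]))
    voxels <- lapply(morph$label, function(l)
      which(lab == l, arr.ind = TRUE))
    make_candidates(volume$case_id, cent,
                    (3 * morph$volume_mm3 / (4 * pi))^(1 / 3),
                    "cluster", morph$sphericity, volume$spacing_mm, voxels)
  }
  out <- empty_candidates()
  # label the two extreme clusters separately so a bright lesion embedded
  # in dark tissue never merges with it into one component
  for (cl in c(1L, k)) {
    sel <- array(FALSE, dim = d)
    sel[mask] <- km$assignments == cl
    eroded <- !dilate_mask_cpp(!sel, d, off1)
    dim(eroded) <- d
    opened <- dilate_mask_cpp(eroded, d, off1) & sel
    out <- rbind(out, merge_candidates(label_to_cands(sel),
                                       label_to_cands(opened)))
  }
  rownames(out) <- NULL
  out
}

#' Merge template- and cluster-branch candidates
#'
#' Two candidates are duplicates when their centroids lie within the larger
#' of their two equivalent radii (mm).  Merging keeps the larger-volume
#' candidate's geometry and the maximum score of the group.  Output order
#' is deterministic: sorted by case, then z, y, x.
#'
#' @param a,b candidate data frames (either may be empty).
#' @return A deduplicated candidate data frame.
#' @export
merge_candidates <- function(a, b) {
  all <- rbind(a, b)
  if (nrow(all) <= 1L) return(all)
  ord <- order(-all$radius_mm, -all$score)
  all <- all[ord, ]
  taken <- rep(FALSE, nrow(all))
  keep <- integer(0)
  pos <- as.matrix(all[, c("x_mm", "y_mm", "z_mm")])
  for (i in seq_len(nrow(all))) {
    if (taken[i]) next
    same_case <- all$case_id == all$case_id[i] & !taken
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    dup <- same_case & d <= pmax(all$radius_mm, all$radius_mm[i])
    all$score[i] <- max(all$score[dup])
    taken[dup] <- TRUE
    keep <- c(keep, i)
  }
  out <- all[keep, ]
  out <- out[order(out$case_id, out$k, out$j, out$i), ]
  rownames(out) <- NULL
  out
}

#' Serialize candidates to CSV
#'
#' Writes the candidate table with voxel (0-based) and mm coordinates;
#' the voxel-set list column is dropped.
#'
#' @param candidates candidate data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- candidates[, c("case_id", "i", "j", "k", "x_mm", "y_mm", "z_mm",
                       "radius_mm", "source", "score")]
  names(df)[2:4] <- c("x_vox", "y_vox", "z_vox")
  df$x_vox <- df$x_vox - 1L; df$y_vox <- df$y_vox - 1L
  df$z_vox <- df$z_vox - 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
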