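#' Seed point inside a volume
#'
#' @param voxel integer length-3, 1-based voxel index.
#' @param kind `"manual"` or `"auto"`.
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(voxel, kind = c("manual", "auto")) {
  kind <- match.arg(kind)
  voxel <- as.integer(round(voxel))
  if (length(voxel) != 3L) stop("`voxel` must be a length-3 index")
  structure(list(voxel = voxel, kind = kind), class = "seed_point")
}

check_seed_bounds <- function(seed, volume) {
  d <- dim(volume$data)
  v <- seed$voxel
  if (any(v < 1L) || any(v > d))
    stop("seed voxel (", paste(v, collapse = ","),
         ") lies outside the volume bounds ", paste(d, collapse = "x"))
  invisible(TRUE)
}

#' Median intensity in the 3x3x3 neighborhood of a seed
#'
#' The neighborhood is clamped at the volume border.  Used as the robust
#' local reference statistic for normalization and region growing.
#'
#' @param volume a [volume3d].
#' @param seed a [seed_point].
#' @return scalar median intensity.
#' @export
seed_reference <- function(volume, seed) {
  check_seed_bounds(seed, volume)
  d <- dim(volume$data)
  v <- seed$voxel
  rng <- lapply(1:3, function(a) max(1L, v[a] - 1L):min(d[a], v[a] + 1L))
  median(volume$data[rng[[1]], rng[[2]], rng[[3]]])
}

#' Seed-anchored linear intensity normalization
#'
#' MR signal intensity is relative: the same tissue maps to different
#' numbers across scanners and sessions.  This rescales the whole volume by
#' a single factor so that the median intensity in the 3x3x3 neighborhood
#' of a gray-matter seed equals `reference_level`:
#' `I' = I * reference_level / m`.  Zero maps to zero, ordering is
#' preserved, and the result is invariant to any prior positive scaling of
#' the input.
#'
#' @param volume a [volume3d].
#' @param seed a [seed_point] in gray matter (see [auto_seed]).
#' @param reference_level target intensity for the seed neighborhood
#'   (arbitrary units, default 1000).
#' @return A normalized [volume3d]; the scale factor is attached as
#'   attribute `"scale"`.
#' @export
normalize_intensity <- function(volume, seed, reference_level = 1000) {
  m <- seed_reference(volume, seed)
  if (!is.finite(m) || m <= 0)
    stop("seed neighborhood median is ", format(m),
         "; the seed appears to lie in background")
  out <- volume
  out$data <- volume$data * (reference_level / m)
  attr(out, "scale") <- reference_level / m
  out
}

#' Automatic gray-matter seed selection
#'
#' Thresholds the volume, labels the above-threshold voxels under
#' 26-connectivity, takes the largest connected component (the head/brain),
#' and returns the in-component voxel nearest its centroid among voxels
#' whose intensity lies within the component's interquartile range.  This
#' lands the seed in bulk parenchyma rather than in bright enhancement or
#' dark CSF.
#'
#' @param volume a [volume3d].
#' @param threshold foreground threshold; default is half the 95th
#'   percentile of the volume's intensities.
#' @return A [seed_point] with `kind = "auto"`.
#' @export
auto_seed <- function(volume, threshold = NULL) {
  auto_seed_ranked(volume, threshold, n_max = 1)[[1]]
}

# Ranked fallback seeds: the n_max in-IQR voxels nearest the component
# centroid, thinned so consecutive picks are at least 3 voxels apart.
# Lets the pipeline retry when a seed happens to abut an enhancing
# structure that violates the spherical growth condition.
auto_seed_ranked <- function(volume, threshold = NULL, n_max = 25) {
  if (is.null(threshold))
    threshold <- 0.5 * quantile(volume$data, 0.95, names = FALSE)
  fg <- volume$data > threshold
  if (!any(fg)) stop("empty foreground: no voxels above threshold ",
                     format(threshold))
  lab <- label_components_cpp(fg, dim(volume$data), 26L)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  vals <- volume$data[lab == big]
  q <- quantile(vals, c(0.25, 0.75), names = FALSE)
  centroid <- colMeans(idx)
  ok <- vals >= q[1] & vals <= q[2]
  cand <- idx[ok, , drop = FALSE]
  d2 <- colSums((t(cand) - centroid)^2)
  cand <- cand[order(d2), , drop = FALSE]
  picked <- list()
  for (r in seq_len(nrow(cand))) {
    v <- cand[r, ]
    if (length(picked) &&
        any(vapply(picked, function(p)
          sum((p$voxel - v)^2) < 9, logical(1))))
      next
    picked[[length(picked) + 1L]] <- seed_point(v, kind = "auto")
    if (length(picked) >= n_max) break
  }
  picked
}
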