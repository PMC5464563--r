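# The 30-feature radiomic descriptor computed per candidate: 10 histogram
# features, box-counting fractal dimension, 14 GLCM features and 5 GLRLM
# features.  First-order statistics are computed on the candidate's own
# voxel set; texture and fractal features on the set dilated by one voxel
# so that even 2 mm candidates yield valid voxel pairs.

#' Canonical feature names, in the fixed output order
#' @export
canonical_feature_names <- c(
  "volume", "min", "max", "mean", "standard_deviation", "variance",
  "skewness", "kurtosis", "energy", "entropy", "fractal_dimension",
  "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity", "glcm_asm",
  "glcm_energy", "glcm_probability_max", "glcm_entropy", "glcm_correlation",
  "glcm_mean_reference", "glcm_mean_neighbor", "glcm_variance_reference",
  "glcm_variance_neighbor", "glcm_sd_reference", "glcm_sd_neighbor",
  "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_lgre", "glrlm_hgre")

# The 13 unique unit-distance 3D directions (up to sign).
offsets_13 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(d)
    d[3] > 0 || (d[3] == 0 && (d[2] > 0 || (d[2] == 0 && d[1] > 0))))
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
})

dilate_voxels <- function(vox, dims) {
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- do.call(rbind, lapply(seq_len(nrow(sh)), function(r)
    sweep(vox, 2, sh[r, ], `+`)))
  out <- out[out[, 1] >= 1 & out[, 1] <= dims[1] &
             out[, 2] >= 1 & out[, 2] <= dims[2] &
             out[, 3] >= 1 & out[, 3] <= dims[3], , drop = FALSE]
  unique(out)
}

sphere_voxels <- function(center, radius_mm, spacing_mm, dims) {
  rv <- ceiling(radius_mm / spacing_mm)
  rng <- lapply(1:3, function(a)
    max(1, center[a] - rv[a]):min(dims[a], center[a] + rv[a]))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- sweep(g, 2, center, `-`)
  d2 <- sweep(d2, 2, spacing_mm, `*`)
  g[rowSums(d2^2) <= radius_mm^2, , drop = FALSE]
}

#' Resolve a candidate into a region for feature extraction
#'
#' Template-branch candidates (no stored voxel set) are resolved as the
#' sphere of the candidate's equivalent radius around its centroid;
#' cluster-branch candidates use their stored voxel set.  Intensities are
#' quantized to `L` gray levels by min-max scaling over the dilated voxel
#' set, and both the original and the 1-voxel-dilated sets are kept.
#'
#' @param volume a [volume3d].
#' @param candidate one-row candidate data frame (or list with `i, j, k`,
#'   `radius_mm`, optional `voxels`).
#' @param L number of gray levels (default 32).
#' @param dilate dilation in voxels for the texture region (default 1).
#' @return list with `voxels`, `values`, `qvalues` (candidate set),
#'   `dvoxels`, `dvalues`, `dq` (dilated set), `qarr` (bounding-box array,
#'   levels 0..L-1, -1 outside the dilated set), `L`, `spacing_mm`.
#' @export
candidate_region <- function(volume, candidate, L = 32, dilate = 1) {
  dims <- dim(volume$data)
  vox <- candidate$voxels
  if (is.list(vox) && length(vox) == 1L) vox <- vox[[1]]
  if (is.null(vox))
    vox <- sphere_voxels(c(candidate$i, candidate$j, candidate$k),
                         candidate$radius_mm, volume$spacing_mm, dims)
  vox <- matrix(as.integer(vox), ncol = 3)
  if (nrow(vox) == 0L) stop("candidate region is empty")
  dvox <- vox
  for (d in seq_len(dilate)) dvox <- dilate_voxels(dvox, dims)
  dvals <- volume$data[dvox]
  vals <- volume$data[vox]
  lo <- min(dvals); hi <- max(dvals)
  qz <- function(v) {
    if (hi > lo) pmin(as.integer(floor((v - lo) / (hi - lo) * L)), L - 1L)
    else rep(0L, length(v))
  }
  bb_lo <- apply(dvox, 2, min); bb_hi <- apply(dvox, 2, max)
  qarr <- array(-1L, dim = bb_hi - bb_lo + 1L)
  qarr[sweep(dvox, 2, bb_lo - 1L, `-`)] <- qz(dvals)
  list(voxels = vox, values = vals, qvalues = qz(vals),
       dvoxels = dvox, dvalues = dvals, dq = qz(dvals), qarr = qarr,
       L = as.integer(L), spacing_mm = volume$spacing_mm)
}

#' First-order (histogram) features of a candidate region
#'
#' Volume in mm^3, min/max/mean, population SD and variance, skewness and
#' kurtosis as standardized third and fourth central moments (kurtosis is
#' non-excess, so a Gaussian scores 3), and energy `sum(p^2)` / entropy
#' `-sum(p log2 p)` over the L-level quantized histogram.  A constant (or
#' single-voxel) region gets skewness and kurtosis 0 by convention, with
#' attribute `flat = TRUE`.
#'
#' @param region a [candidate_region].
#' @return named numeric vector of 10 features.
#' @export
histogram_features <- function(region) {
  v <- region$values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  flat <- m2 <= 0
  sk <- if (flat) 0 else mean((v - mu)^3) / m2^1.5
  ku <- if (flat) 0 else mean((v - mu)^4) / m2^2
  p <- tabulate(region$qvalues + 1L, nbins = region$L) / n
  p <- p[p > 0]
  out <- c(volume = n * prod(region$spacing_mm), min = min(v), max = max(v),
           mean = mu, standard_deviation = sqrt(m2), variance = m2,
           skewness = sk, kurtosis = ku, energy = sum(p^2),
           entropy = -sum(p * log2(p)))
  if (flat) attr(out, "flat") <- TRUE
  out
}

#' Gray-level co-occurrence matrix of a quantized region
#'
#' Counts pairs of levels at unit-distance offsets where both voxels
#' belong to the region's (dilated) voxel set, accumulated over the 13
#' unique 3D directions, symmetrized and normalized to probabilities.
#'
#' @param region a [candidate_region], or a quantized array with -1
#'   outside the region.
#' @param L number of gray levels (taken from the region if given one).
#' @param offsets integer matrix of direction offsets (default all 13).
#' @return `L x L` matrix of probabilities summing to 1.
#' @export
glcm <- function(region, L = NULL, offsets = offsets_13) {
  if (is.list(region)) { qarr <- region$qarr; L <- region$L }
  else qarr <- region
  if (is.null(L)) L <- max(qarr) + 1L
  if (L < 2) stop("need at least 2 gray levels")
  d <- dim(qarr)
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    xs <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    ys <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zs <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    a <- qarr[xs, ys, zs, drop = FALSE]
    b <- qarr[xs + o[1], ys + o[2], zs + o[3], drop = FALSE]
    ok <- a >= 0L & b >= 0L
    if (!any(ok)) next
    tab <- tabulate(a[ok] + L * b[ok] + 1L, nbins = L * L)
    counts <- counts + matrix(tab, L, L)
  }
  if (sum(counts) == 0) stop("no valid voxel pairs for GLCM")
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' The 14 GLCM texture features
#'
#' Levels are indexed 0..L-1; `i` is the reference (row) level, `j` the
#' neighbor (column) level.  Correlation with a zero marginal SD is 0 by
#' convention, flagged with attribute `flat_glcm`.
#'
#' @param P normalized (symmetric) co-occurrence matrix.
#' @return named numeric vector of 14 features.
#' @export
glcm_features <- function(P) {
  L <- nrow(P)
  lev <- seq_len(L) - 1
  I <- matrix(lev, L, L)
  J <- t(I)
  pr <- rowSums(P)  # reference marginal
  pn <- colSums(P)  # neighbor marginal
  mu_r <- sum(lev * pr); mu_n <- sum(lev * pn)
  var_r <- sum((lev - mu_r)^2 * pr); var_n <- sum((lev - mu_n)^2 * pn)
  sd_r <- sqrt(var_r); sd_n <- sqrt(var_n)
  pos <- P[P > 0]
  flat <- sd_r <= 0 || sd_n <= 0
  corr <- if (flat) 0 else
    sum(P * (I - mu_r) * (J - mu_n)) / (sd_r * sd_n)
  asm <- sum(P^2)
  out <- c(glcm_contrast = sum(P * (I - J)^2),
           glcm_dissimilarity = sum(P * abs(I - J)),
           glcm_homogeneity = sum(P / (1 + (I - J)^2)),
           glcm_asm = asm, glcm_energy = sqrt(asm),
           glcm_probability_max = max(P),
           glcm_entropy = -sum(pos * log2(pos)),
           glcm_correlation = corr,
           glcm_mean_reference = mu_r, glcm_mean_neighbor = mu_n,
           glcm_variance_reference = var_r, glcm_variance_neighbor = var_n,
           glcm_sd_reference = sd_r, glcm_sd_neighbor = sd_n)
  if (flat) attr(out, "flat_glcm") <- TRUE
  out
}

#' Gray-level run-length matrix of a quantized region
#'
#' Maximal runs of equal level along each of the 13 unique directions,
#' restricted to the region voxel set, accumulated into a matrix `R[g, l]`
#' of run counts by gray level `g` and run length `l`.
#'
#' @param region a [candidate_region] or quantized array (-1 outside).
#' @param L number of gray levels.
#' @param directions integer matrix of directions (default all 13).
#' @return integer matrix `L x max_run_length`.
#' @export
glrlm <- function(region, L = NULL, directions = offsets_13) {
  if (is.list(region)) { qarr <- region$qarr; L <- region$L }
  else qarr <- region
  if (is.null(L)) L <- max(qarr) + 1L
  d <- dim(qarr)
  maxlen <- max(d)
  R <- matrix(0L, nrow = L, ncol = maxlen)
  inb <- function(v) all(v >= 1 & v <= d)
  idx <- which(qarr >= 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    for (s in seq_len(nrow(idx))) {
      v <- idx[s, ]
      g <- qarr[v[1], v[2], v[3]]
      prev <- v - o
      if (inb(prev) && qarr[prev[1], prev[2], prev[3]] == g) next
      len <- 1L
      nxt <- v + o
      while (inb(nxt) && qarr[nxt[1], nxt[2], nxt[3]] == g) {
        len <- len + 1L
        nxt <- nxt + o
      }
      R[g + 1L, len] <- R[g + 1L, len] + 1L
    }
  }
  R
}

#' The 5 GLRLM features
#'
#' Long-run emphasis (LRE), gray-level non-uniformity (GLN), run-length
#' non-uniformity (RLN), low and high gray-level run emphasis (LGRE,
#' HGRE).  Gray levels enter the emphasis terms 1-based (`g+1` for
#' quantized level `g`).
#'
#' @param R run-length matrix from [glrlm].
#' @return named numeric vector of 5 features.
#' @export
glrlm_features <- function(R) {
  Nr <- sum(R)
  if (Nr == 0) stop("empty run-length matrix")
  l <- seq_len(ncol(R))
  g <- seq_len(nrow(R))  # 1-based gray level
  rg <- rowSums(R)
  rl <- colSums(R)
  c(glrlm_lre = sum(t(R) * l^2) / Nr,
    glrlm_gln = sum(rg^2) / Nr,
    glrlm_rln = sum(rl^2) / Nr,
    glrlm_lgre = sum(rg / g^2) / Nr,
    glrlm_hgre = sum(rg * g^2) / Nr)
}

#' Box-counting fractal dimension of a binary 3D mask
#'
#' Counts occupied boxes at sizes 1, 2, 4, ... up to the largest bounding
#' box extent and returns the slope of the least-squares fit of
#' `log N(s)` against `log(1/s)`.  At least three box sizes are required.
#' Scales run to the largest extent so that lower-dimensional sets (a
#' one-voxel-thick line has unit extent on two axes) still expose a
#' scaling range.
#'
#' @param mask logical 3D array (or a [candidate_region], whose dilated
#'   voxel set is used).
#' @return scalar dimension estimate, clamped to `[0, 3]`.
#' @export
fractal_dimension_boxcount <- function(mask) {
  if (is.list(mask)) mask <- mask$qarr >= 0L
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  idx <- sweep(idx, 2, lo - 1L, `-`)  # bbox-anchored, 1-based
  ext <- apply(idx, 2, max)
  sizes <- 1L
  while (2 * sizes[length(sizes)] <= max(ext)) {
    sizes <- c(sizes, 2L * sizes[length(sizes)])
  }
  if (length(sizes) < 3L)
    stop("need at least 3 box sizes; region extent ",
         paste(ext, collapse = "x"), " is too small")
  counts <- vapply(sizes, function(s) {
    boxes <- ceiling(idx / s)
    nrow(unique(boxes))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  min(max(fit$coefficients[2], 0), 3)
}

#' Extract the full 30-feature vector for one candidate
#'
#' Assembles all features in the canonical order given by
#' [canonical_feature_names].  Degenerate regions (constant intensity, too
#' small for a fractal fit) fall back to the documented conventions and
#' the vector carries a `flags` attribute naming them.
#'
#' @param volume a [volume3d].
#' @param candidate one-row candidate data frame.
#' @param L gray levels for quantization (default 32).
#' @param dilate texture-region dilation in voxels (default 1).
#' @return named numeric vector of length 30.
#' @export
extract_features <- function(volume, candidate, L = 32, dilate = 1) {
  region <- candidate_region(volume, candidate, L = L, dilate = dilate)
  flags <- character(0)
  hf <- histogram_features(region)
  if (isTRUE(attr(hf, "flat"))) flags <- c(flags, "flat_region")
  fd <- tryCatch(fractal_dimension_boxcount(region),
                 error = function(e) { flags <<- c(flags, "fractal_degenerate"); 0 })
  P <- tryCatch(glcm(region), error = function(e) NULL)
  if (is.null(P)) {
    flags <- c(flags, "glcm_degenerate")
    gf <- stats::setNames(numeric(14), canonical_feature_names[12:25])
    gf["glcm_homogeneity"] <- 1
  } else {
    gf <- glcm_features(P)
    if (isTRUE(attr(gf, "flat_glcm"))) flags <- c(flags, "flat_glcm")
  }
  rf <- glrlm_features(glrlm(region))
  out <- c(hf, fractal_dimension = unname(fd), gf, rf)
  out <- out[canonical_feature_names]
  stopifnot(length(out) == 30L, !anyNA(out))
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Feature table for a set of candidates
#'
#' @param volume a [volume3d].
#' @param candidates candidate data frame.
#' @param ... passed to [extract_features].
#' @return data frame with one row per candidate and the 30 canonical
#'   feature columns.
#' @export
extract_feature_table <- function(volume, candidates, ...) {
  if (nrow(candidates) == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = 30))
    names(out) <- canonical_feature_names
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(r)
    extract_features(volume, candidates[r, ], ...))
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
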