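# Brain extraction by seed region growing.  Plain SRG floods voxel by
# voxel; the spherical variant (SSRG) only accepts a frontier voxel when
# every voxel of a sphere around it also satisfies the intensity
# condition, which stops single-voxel leaks into neighboring structures
# of similar intensity.

# Voxel offsets within `radius`.  By default distance is measured in
# voxel units (isotropic in index space); with `spacing_mm` given, the
# sphere is measured in physical units of radius * min(spacing), so
# fewer voxels fall inside along coarsely sampled axes.
sphere_offsets <- function(radius, spacing_mm = NULL) {
  r <- as.integer(ceiling(radius))
  if (radius <= 0) return(matrix(0L, nrow = 1, ncol = 3))
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  d2 <- if (is.null(spacing_mm)) rowSums(g^2)
        else rowSums(sweep(g, 2, spacing_mm / min(spacing_mm), `*`)^2)
  g <- g[d2 <= radius^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  unname(g)
}

new_brain_mask <- function(mask, seed, params) {
  structure(list(mask = mask, seed = seed, params = params),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s voxels true of %s (%.1f%%)\n",
              format(sum(x$mask)), format(length(x$mask)),
              100 * mean(x$mask)))
  invisible(x)
}

#' Seed region growing (SRG)
#'
#' Connected flood fill from the seed under 26-connectivity: a voxel joins
#' the region when `|I(v) - I_seed| <= tolerance`, where `I_seed` is the
#' median intensity of the seed's 3x3x3 neighborhood.
#'
#' @param volume a [volume3d].
#' @param seed a [seed_point].
#' @param tolerance non-negative intensity tolerance (same units as the
#'   volume).
#' @param fill_holes post-process the mask by a morphological closing
#'   (dilation, interior-hole filling, erosion) so that enhancing or
#'   necrotic lesions excluded by the intensity condition - and the narrow
#'   exclusion corridors the spherical test carves around vessels - stay
#'   inside the brain mask.  Default `TRUE`; the raw grown region is
#'   returned when `FALSE` (under which the containment and monotonicity
#'   properties of the growth itself hold exactly).
#' @return A `brain_mask` object: logical array `mask` plus the seed and
#'   parameters used.
#' @export
srg <- function(volume, seed, tolerance, fill_holes = TRUE) {
  ssrg(volume, seed, tolerance, sphere_radius_voxels = 0,
       fill_holes = fill_holes)
}

#' Spherical-based seed region growing (SSRG)
#'
#' Like [srg] but a frontier voxel is accepted only if *every* voxel whose
#' centre lies within `sphere_radius_voxels` (Euclidean, in voxel units) of
#' it satisfies the intensity condition.  Sphere voxels falling outside the
#' volume are ignored.  Radius 0 reduces exactly to SRG, and the SSRG mask
#' is always a subset of the SRG mask at equal tolerance.
#'
#' @inheritParams srg
#' @param sphere_radius_voxels sphere radius in voxels (default 2).
#' @param spacing_scaled measure the sphere in physical units
#'   (`radius * min(spacing)`) instead of voxel units, so anisotropic
#'   voxels shrink the sphere along coarse axes.  Default `FALSE`,
#'   matching the per-pixel formulation.
#' @return A `brain_mask` object.
#' @export
ssrg <- function(volume, seed, tolerance, sphere_radius_voxels = 2,
                 fill_holes = TRUE, spacing_scaled = FALSE) {
  check_seed_bounds(seed, volume)
  if (tolerance < 0) stop("`tolerance` must be non-negative")
  ref <- seed_reference(volume, seed)
  off <- sphere_offsets(sphere_radius_voxels,
                        if (spacing_scaled) volume$spacing_mm)
  mask <- region_grow_cpp(volume$data, dim(volume$data),
                          seed$voxel - 1L, ref, tolerance, off)
  if (fill_holes)
    mask <- close_and_fill(mask, radius = sphere_radius_voxels + 1)
  new_brain_mask(mask, seed,
                 list(tolerance = tolerance,
                      sphere_radius_voxels = sphere_radius_voxels,
                      spacing_scaled = spacing_scaled,
                      reference = ref, connectivity = 26,
                      fill_holes = fill_holes))
}

# Morphological closing with interior-hole filling: dilation by a ball
# seals narrow exclusion corridors (the spherical test carves a rind of
# about the sphere radius around off-tolerance structures), hole filling
# recovers enclosed lesions, and the matching erosion restores the outer
# boundary.  The input mask is always a subset of the result.
close_and_fill <- function(mask, radius) {
  d <- dim(mask)
  off <- sphere_offsets(radius)
  dil <- dilate_mask_cpp(mask, d, off)
  dil <- fill_mask_holes(dil)
  eroded <- !dilate_mask_cpp(!dil, d, off)
  dim(eroded) <- d
  eroded | mask
}

# Fill cavities: complement components (6-connectivity) that do not touch
# the volume border are interior holes.
fill_mask_holes <- function(mask) {
  d <- dim(mask)
  lab <- label_components_cpp(!mask, d, 6L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  mask | hole
}
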