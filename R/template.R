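# Spherical matched-filter templates for small metastases.  Two shapes:
# solid spheres for homogeneously enhancing nodules and inner-hole
# (shell) spheres for rim-enhancing necrotic nodules, at diameters of
# 2, 3 and 4 mm by default.

#' Build a spherical detection template
#'
#' The kernel lives on a cubic window whose side (per axis) is the smallest
#' odd voxel count of at least `ceiling(diameter/spacing) + 2`, so a margin
#' of dark surround is always part of the window.  Weights are 1 where the
#' voxel-centre distance from the window centre is at most the radius
#' (`solid`), or between 50% and 100% of the radius (`inner_hole`), and 0
#' elsewhere.  The window mean `t_mean` and population SD `t_sd` are
#' precomputed for normalized cross-correlation.
#'
#' @param diameter_mm template diameter in mm; must be at least the largest
#'   voxel spacing so the sphere spans a voxel on every axis.
#' @param spacing_mm per-axis voxel size in mm.
#' @param kind `"solid"` or `"inner_hole"` (shell thickness 50% of the
#'   radius).
#' @return An object of class `bm_template`.
#' @export
make_template <- function(diameter_mm, spacing_mm = c(1, 1, 1),
                          kind = c("solid", "inner_hole")) {
  kind <- match.arg(kind)
  spacing_mm <- as.numeric(spacing_mm)
  if (diameter_mm < max(spacing_mm))
    stop("diameter ", diameter_mm, " mm is below the resolvable size for spacing ",
         paste(spacing_mm, collapse = "x"), " mm")
  r <- diameter_mm / 2
  side <- vapply(spacing_mm, function(s) {
    n <- ceiling(diameter_mm / s) + 2
    as.integer(if (n %% 2 == 0) n + 1 else n)
  }, integer(1))
  half <- (side - 1L) / 2L
  ax <- lapply(1:3, function(a) (-half[a]:half[a]) * spacing_mm[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  dist <- sqrt(d2)
  w <- if (kind == "solid") {
    (dist <= r) * 1
  } else {
    (dist <= r & dist >= 0.5 * r) * 1
  }
  dim(w) <- side
  n <- length(w)
  t_mean <- mean(w)
  t_sd <- sqrt(mean((w - t_mean)^2))
  if (t_sd <= 0) stop("degenerate template: zero weight variance")
  structure(list(weights = w, diameter_mm = diameter_mm, kind = kind,
                 spacing_mm = spacing_mm, n = n, t_mean = t_mean,
                 t_sd = t_sd),
            class = "bm_template")
}

#' Default template bank
#'
#' Six templates: solid and inner-hole at diameters 2, 3 and 4 mm.
#'
#' @param spacing_mm per-axis voxel size in mm.
#' @param diameters_mm template diameters.
#' @return A list of [make_template] objects.
#' @export
default_templates <- function(spacing_mm = c(1, 1, 1),
                              diameters_mm = c(2, 3, 4)) {
  out <- list()
  for (d in diameters_mm)
    for (k in c("solid", "inner_hole"))
      out[[length(out) + 1L]] <- make_template(d, spacing_mm, k)
  out
}

#' Normalized cross-correlation of a window against a template
#'
#' `ncc = (1/n) * sum((f - fbar) (t - tbar)) / (sigma_f * sigma_t)` with
#' population SDs, i.e. the Pearson correlation of window and kernel.  The
#' value is invariant to any affine intensity change `a*f + b` (a > 0) of
#' the window and bounded in `[-1, 1]`.  A flat window (zero variance) is
#' scored 0 with attribute `flat = TRUE` rather than raising: flat patches
#' are routine in background.
#'
#' @param window numeric array with the same shape as the template window.
#' @param template a [make_template] object.
#' @return scalar similarity in `[-1, 1]`.
#' @export
ncc <- function(window, template) {
  if (!all(dim(window) == dim(template$weights)))
    stop("window shape ", paste(dim(window), collapse = "x"),
         " does not match template window ",
         paste(dim(template$weights), collapse = "x"))
  f <- as.numeric(window)
  n <- template$n
  fbar <- mean(f)
  sf <- sqrt(mean((f - fbar)^2))
  if (sf <= 0) return(structure(0, flat = TRUE))
  sum((f - fbar) * (template$weights - template$t_mean)) /
    (n * sf * template$t_sd)
}
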