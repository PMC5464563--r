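# Synthetic head phantom: an ellipsoidal "brain" of gray/white/CSF-like
# tissue inside a brighter shell, seeded with enhancing spheroid nodules
# (solid or rim-enhancing), tubular vessel-like confounders and additive
# noise.  Every phantom carries exact ground truth, so the whole CAD
# pipeline can be exercised and scored without clinical data.

#' Phantom configuration
#'
#' Defaults emulate the acquisition the pipeline targets: ~1 mm isotropic
#' voxels, nodules of 3-10 mm, a handful of vessel-like enhancing tubes,
#' and additive noise giving a contrast-to-noise ratio of at least 5 for
#' the dimmest nodule against gray matter.
#'
#' @param shape voxels per axis (default `c(96, 96, 96)`).
#' @param spacing_mm per-axis voxel size in mm.
#' @param tissue_levels named intensities (arbitrary units) for
#'   `background`, `csf`, `white`, `gray`, `enhancing`; must satisfy
#'   `enhancing > gray > white > csf`.
#' @param necrotic_level intensity of necrotic rim-lesion cores.
#' @param n_nodules number of nodules.
#' @param nodule_diameter_range_mm min/max nodule diameter.
#' @param rim_fraction fraction of nodules rendered rim-enhancing.
#' @param n_vessels number of tubular enhancing confounders.
#' @param vessel_radius_mm tube radius.
#' @param noise_sigma additive noise SD; `noise_model` selects
#'   `"gaussian"` (default, analytically tractable) or `"rician"`
#'   (MR magnitude noise).
#' @param bias_amplitude amplitude of an optional smooth multiplicative
#'   bias field (coil-inhomogeneity-like, a random linear+quadratic
#'   ramp spanning `1 +/- bias_amplitude`); 0 (default) disables it.
#' @param seed RNG seed; identical configs give bit-identical phantoms.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 96), spacing_mm = c(1, 1, 1),
                           tissue_levels = c(background = 0, csf = 150,
                                             white = 400, gray = 600,
                                             enhancing = 1000),
                           necrotic_level = 200,
                           n_nodules = 5,
                           nodule_diameter_range_mm = c(3, 10),
                           rim_fraction = 0.3,
                           n_vessels = 8, vessel_radius_mm = 0.8,
                           noise_sigma = 20,
                           noise_model = c("gaussian", "rician"),
                           bias_amplitude = 0,
                           seed = 1) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  tl <- tissue_levels
  req <- c("background", "csf", "white", "gray", "enhancing")
  if (!all(req %in% names(tl)))
    stop("tissue_levels must name ", paste(req, collapse = ", "))
  if (!(tl["enhancing"] > tl["gray"] && tl["gray"] > tl["white"] &&
        tl["white"] > tl["csf"]))
    stop("tissue levels must satisfy enhancing > gray > white > csf")
  if (rim_fraction < 0 || rim_fraction > 1)
    stop("rim_fraction must lie in [0, 1]")
  if (nodule_diameter_range_mm[1] < max(spacing_mm))
    stop("nodule diameters must be at least one voxel spacing")
  stopifnot(n_nodules >= 0, n_vessels >= 0, vessel_radius_mm > 0,
            noise_sigma >= 0, bias_amplitude >= 0, bias_amplitude < 1)
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 tissue_levels = tl, necrotic_level = necrotic_level,
                 n_nodules = as.integer(n_nodules),
                 nodule_diameter_range_mm = nodule_diameter_range_mm,
                 rim_fraction = rim_fraction,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_mm = vessel_radius_mm,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# squared normalized ellipsoid coordinate for every voxel:
# e(v) = sum(((v - center) * spacing / semi_axes)^2); e <= 1 is inside.
ellipsoid_field <- function(shape, spacing_mm, center_mm, semi_axes_mm) {
  ax <- lapply(1:3, function(a)
    (((seq_len(shape[a]) - 1) * spacing_mm[a] - center_mm[a]) /
       semi_axes_mm[a])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
}

#' Render a sphere (solid or rim) into a volume
#'
#' Sets every voxel whose centre lies within `diameter_mm / 2` of the
#' centre voxel to `intensity`.  For rim spheres only the outer 50% shell
#' (distance in `[r/2, r]`) takes `intensity`; the interior is set to
#' `necrotic_level`, mirroring the inner-hole template geometry.
#'
#' @param volume a [volume3d].
#' @param center 1-based voxel triple.
#' @param diameter_mm sphere diameter.
#' @param intensity value written into the sphere (shell, for rim).
#' @param rim logical; render as rim-enhancing.
#' @param necrotic_level interior intensity for rim spheres.
#' @return The modified [volume3d].
#' @export
render_sphere <- function(volume, center, diameter_mm, intensity,
                          rim = FALSE, necrotic_level = 0) {
  d <- dim(volume$data)
  sp <- volume$spacing_mm
  r <- diameter_mm / 2
  if (any(center - r / sp < 1) || any(center + r / sp > d))
    stop("sphere of diameter ", diameter_mm, " mm at (",
         paste(center, collapse = ","), ") does not fit inside the volume")
  vox <- sphere_voxels(center, r, sp, d)
  if (rim) {
    dd <- sqrt(rowSums(sweep(sweep(vox, 2, center, `-`), 2, sp, `*`)^2))
    inner <- dd < 0.5 * r
    volume$data[vox[inner, , drop = FALSE]] <- necrotic_level
    volume$data[vox[!inner, , drop = FALSE]] <- intensity
  } else {
    volume$data[vox] <- intensity
  }
  volume
}

# Render a smoothed random-walk tube of enhancing intensity: the minimal
# confounder reproducing the vessel/sinus false-positive mode.
render_vessel <- function(volume, brain_e, radius_mm, intensity) {
  d <- dim(volume$data)
  sp <- volume$spacing_mm
  inside <- which(brain_e <= 0.8^2)
  start <- arrayInd(inside[sample.int(length(inside), 1)], d)
  pos <- as.numeric(start)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  n_steps <- 80L
  rv <- ceiling(radius_mm / sp)
  for (s in seq_len(n_steps)) {
    ctr <- round(pos)
    if (any(ctr - rv < 1) || any(ctr + rv > d)) break
    if (brain_e[ctr[1], ctr[2], ctr[3]] > 0.95^2) break
    vox <- sphere_voxels(ctr, radius_mm, sp, d)
    volume$data[vox] <- intensity
    dir <- dir + 0.35 * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir / sp  # ~1 mm step
  }
  volume
}

#' Generate a synthetic head phantom with ground truth
#'
#' Builds the tissue background (gray-matter ellipsoid with a white-matter
#' core and CSF-like ventricles, surrounded by a detached brighter shell),
#' places the requested nodules by rejection sampling (no nodule-nodule
#' overlap; nodule-vessel contact allowed), draws vessel-like tubes, and
#' finally adds noise.  Nodule intensity is sampled uniformly in
#' `[0.8, 1] * enhancing` so template matches are never degenerate.
#' Identical configurations give bit-identical output.
#'
#' @param config a [phantom_config].
#' @param case_id case identifier.
#' @return list with `volume` (a [volume3d]) and `truth` (a
#'   `ground_truth`: `case_id` plus a nodule table `i, j, k,
#'   diameter_mm, kind`).
#' @export
generate_phantom <- function(config, case_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  d <- config$shape
  sp <- config$spacing_mm
  tl <- config$tissue_levels
  fov <- (d - 1) * sp
  center <- fov / 2
  brain_ax <- fov / 2 * c(0.62, 0.72, 0.62)
  e <- ellipsoid_field(d, sp, center, brain_ax)

  arr <- array(tl[["background"]], dim = d)
  arr[e <= 1] <- tl[["gray"]]
  arr[e <= 0.55^2] <- tl[["white"]]
  # shell (scalp-like), detached from the brain by a dark gap
  arr[e >= 1.08^2 & e <= 1.18^2] <- 0.8 * tl[["enhancing"]]
  # ventricle-like CSF pockets
  for (sgn in c(-1, 1)) {
    vc <- center + c(sgn * 0.18 * brain_ax[1], 0, 0.05 * brain_ax[3])
    ve <- ellipsoid_field(d, sp, vc,
                          c(0.10, 0.30, 0.12) * brain_ax)
    arr[ve <= 1] <- tl[["csf"]]
  }
  vol <- volume3d(arr, spacing_mm = sp, case_id = case_id)

  # --- nodules ---------------------------------------------------------
  n <- config$n_nodules
  drange <- config$nodule_diameter_range_mm
  diam <- if (n) runif(n, drange[1], drange[2]) else numeric(0)
  n_rim <- round(config$rim_fraction * n)
  kind <- rep("solid", n)
  if (n_rim > 0) kind[sample.int(n, n_rim)] <- "rim"
  placed <- matrix(numeric(0), ncol = 4)  # x, y, z (mm), radius
  centers <- matrix(0L, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    r <- diam[i] / 2
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cand <- round(center / sp + 1 +
                      (runif(3, -1, 1) * (brain_ax - r - 2 * max(sp))) / sp)
      cmm <- (cand - 1) * sp
      if (sum(((cmm - center) / (brain_ax - r - 2 * max(sp)))^2) > 1) next
      if (nrow(placed) &&
          any(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cmm)^2)) <
              placed[, 4] + r + 2))
        next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place nodule ", i, " (diameter ",
           round(diam[i], 1), " mm) without overlap after 1000 attempts; ",
           "reduce n_nodules or the diameter range")
    centers[i, ] <- as.integer(cand)
    placed <- rbind(placed, c(cmm, r))
  }
  intens <- runif(n, 0.8, 1) * tl[["enhancing"]]
  for (i in seq_len(n))
    vol <- render_sphere(vol, centers[i, ], diam[i], intens[i],
                         rim = kind[i] == "rim",
                         necrotic_level = config$necrotic_level)

  # --- vessels ---------------------------------------------------------
  for (v in seq_len(config$n_vessels))
    vol <- render_vessel(vol, e, config$vessel_radius_mm,
                         runif(1, 0.8, 1) * tl[["enhancing"]])

  # --- bias field ------------------------------------------------------
  if (config$bias_amplitude > 0) {
    u <- lapply(1:3, function(a) seq_len(d[a]) / d[a] - 0.5)
    co <- runif(6, -1, 1)
    g <- outer(outer(co[1] * u[[1]] + co[4] * u[[1]]^2,
                     co[2] * u[[2]] + co[5] * u[[2]]^2, `+`),
               co[3] * u[[3]] + co[6] * u[[3]]^2, `+`)
    g <- g / max(abs(g)) * config$bias_amplitude
    vol$data <- vol$data * (1 + g)
  }

  # --- noise -----------------------------------------------------------
  if (config$noise_sigma > 0) {
    if (config$noise_model == "gaussian") {
      vol$data <- vol$data + array(rnorm(length(vol$data), 0,
                                         config$noise_sigma), dim = d)
    } else {
      n1 <- rnorm(length(vol$data), 0, config$noise_sigma)
      n2 <- rnorm(length(vol$data), 0, config$noise_sigma)
      vol$data <- array(sqrt((as.numeric(vol$data) + n1)^2 + n2^2), dim = d)
    }
  }

  truth <- structure(
    list(case_id = case_id,
         nodules = data.frame(i = centers[, 1], j = centers[, 2],
                              k = centers[, 3], diameter_mm = diam,
                              kind = kind, stringsAsFactors = FALSE)),
    class = "ground_truth")
  list(volume = vol, truth = truth)
}

#' Generate a suite of phantoms
#'
#' Convenience wrapper producing `n_cases` phantoms with per-case seeds
#' derived from `seed`, plus `n_controls` lesion-free control cases.
#'
#' @param n_cases number of lesion-bearing cases.
#' @param n_controls number of lesion-free control cases.
#' @param seed base seed; case `c` uses `seed * 1000 + c`.
#' @param ... overrides passed to [phantom_config].
#' @return list of `list(volume, truth)` entries.
#' @export
phantom_suite <- function(n_cases, n_controls = 0, seed = 1, ...) {
  args <- list(...)
  out <- vector("list", n_cases + n_controls)
  for (c in seq_len(n_cases + n_controls)) {
    a <- args
    if (c > n_cases) a$n_nodules <- 0
    a$seed <- (seed %% 2000000L) * 1000L + c
    cfg <- do.call(phantom_config, a)
    out[[c]] <- generate_phantom(cfg, case_id = sprintf("case%03d", c))
  }
  out
}

#' Write / read ground truth as JSON
#'
#' Voxel indices are serialized 0-based in (x, y, z) order, the volume's
#' fastest-to-slowest axis order, as recorded in the file header.
#'
#' @param truth a `ground_truth`.
#' @param path JSON path.
#' @return `path` (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  nod <- truth$nodules
  obj <- list(case_id = truth$case_id,
              index_base = 0L, axis_order = "xyz fastest-to-slowest",
              nodules = lapply(seq_len(nrow(nod)), function(r)
                list(center = c(nod$i[r], nod$j[r], nod$k[r]) - 1L,
                     diameter_mm = nod$diameter_mm[r],
                     kind = nod$kind[r])))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nod <- if (length(obj$nodules)) {
    do.call(rbind, lapply(obj$nodules, function(x)
      data.frame(i = x$center[[1]] + 1L, j = x$center[[2]] + 1L,
                 k = x$center[[3]] + 1L, diameter_mm = x$diameter_mm,
                 kind = x$kind, stringsAsFactors = FALSE)))
  } else {
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               diameter_mm = numeric(0), kind = character(0))
  }
  structure(list(case_id = obj$case_id, nodules = nod),
            class = "ground_truth")
}
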