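# The 30-feature descriptor: histogram moments, GLCM, GLRLM, box-counting
# fractal dimension, and the assembled vector.

region_from_qarr <- function(qarr, L, values = NULL) {
  vox <- which(qarr >= 0L, arr.ind = TRUE)
  q <- qarr[qarr >= 0L]
  if (is.null(values)) values <- as.numeric(q)
  list(voxels = vox, values = values, qvalues = q,
       dvoxels = vox, dvalues = values, dq = q, qarr = qarr,
       L = as.integer(L), spacing_mm = c(1, 1, 1))
}

test_that("histogram features honour the documented conventions", {
  qarr <- array(0L, dim = c(3, 3, 3))
  reg <- region_from_qarr(qarr, 32, values = rep(7, 27))
  hf <- histogram_features(reg)
  expect_equal(unname(hf[c("variance", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))
  expect_equal(unname(hf[["energy"]]), 1)
  expect_equal(unname(hf[["volume"]]), 27)

  # two voxels at opposite extremes: 1 bit of entropy, energy 1/2
  q2 <- array(-1L, dim = c(2, 1, 1)); q2[1] <- 0L; q2[2] <- 31L
  reg2 <- region_from_qarr(q2, 32, values = c(0, 100))
  hf2 <- histogram_features(reg2)
  expect_equal(unname(hf2[["entropy"]]), 1)
  expect_equal(unname(hf2[["energy"]]), 0.5)
})

test_that("moments match an arbitrary-precision-style direct computation", {
  set.seed(8)
  vals <- round(runif(27, 0, 1000), 3)
  qarr <- array(0L, dim = c(3, 3, 3))
  reg <- region_from_qarr(qarr, 32, values = vals)
  hf <- histogram_features(reg)
  om <- oracle_moments(vals)
  expect_equal(unname(hf[["mean"]]), unname(om[["mean"]]), tolerance = 1e-12)
  expect_equal(unname(hf[["standard_deviation"]]), unname(om[["sd"]]),
               tolerance = 1e-12)
  expect_equal(unname(hf[["variance"]]), unname(om[["var"]]), tolerance = 1e-12)
  expect_equal(unname(hf[["skewness"]]), unname(om[["skew"]]), tolerance = 1e-12)
  expect_equal(unname(hf[["kurtosis"]]), unname(om[["kurt"]]), tolerance = 1e-12)
  expect_equal(unname(hf[["min"]]), min(vals))
  expect_equal(unname(hf[["max"]]), max(vals))
})

test_that("GLCM handles degenerate and analytic cases", {
  # constant region: single diagonal cell
  qarr <- array(0L, dim = c(3, 3, 3))
  P <- glcm(qarr, L = 4)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  # two-voxel 1D pattern [0, 1] with the single offset (1,0,0)
  q2 <- array(-1L, dim = c(2, 1, 1)); q2[1] <- 0L; q2[2] <- 1L
  P2 <- glcm(q2, L = 2, offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  expect_equal(P2[1, 1] + P2[2, 2], 0)
})

test_that("GLCM equals the brute-force pair-counting oracle", {
  set.seed(12)
  for (rep in 1:10) {
    qarr <- random_qarr(c(4, 4, 4), L = 4)
    if (!any(qarr >= 0)) next
    P <- tryCatch(glcm(qarr, L = 4), error = function(e) NULL)
    if (is.null(P)) next
    expect_equal(P, oracle_glcm(qarr, 4), tolerance = 1e-12)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    # symmetric matrix: reference and neighbor marginals coincide
    expect_equal(rowSums(P), colSums(P), tolerance = 1e-12)
  }
})

test_that("GLCM features match direct summation on a printed toy matrix", {
  P <- matrix(c(0.2, 0.1, 0.0,
                0.1, 0.3, 0.05,
                0.0, 0.05, 0.2), 3, 3, byrow = TRUE)
  f <- glcm_features(P)
  o <- oracle_glcm_features(P)
  expect_equal(unname(f[["glcm_contrast"]]), unname(o[["contrast"]]))
  expect_equal(unname(f[["glcm_dissimilarity"]]), unname(o[["dissimilarity"]]))
  expect_equal(unname(f[["glcm_homogeneity"]]), unname(o[["homogeneity"]]))
  expect_equal(unname(f[["glcm_asm"]]), unname(o[["asm"]]))
  expect_equal(unname(f[["glcm_energy"]]), unname(o[["energy"]]))
  expect_equal(unname(f[["glcm_probability_max"]]), unname(o[["prob_max"]]))
  expect_equal(unname(f[["glcm_entropy"]]), unname(o[["entropy"]]))
  expect_equal(unname(f[["glcm_correlation"]]), unname(o[["correlation"]]))
  expect_equal(unname(f[["glcm_mean_reference"]]), unname(o[["mean_r"]]))
  expect_equal(unname(f[["glcm_mean_neighbor"]]), unname(o[["mean_n"]]))
  expect_equal(unname(f[["glcm_variance_reference"]]), unname(o[["var_r"]]))
  expect_equal(unname(f[["glcm_variance_neighbor"]]), unname(o[["var_n"]]))
  expect_equal(unname(f[["glcm_sd_reference"]]), unname(o[["sd_r"]]))
  expect_equal(unname(f[["glcm_sd_neighbor"]]), unname(o[["sd_n"]]))

  # degenerate single-level matrix: contrast 0, homogeneity 1, correlation 0
  P1 <- matrix(0, 4, 4); P1[2, 2] <- 1
  f1 <- glcm_features(P1)
  expect_equal(unname(f1[c("glcm_contrast", "glcm_homogeneity", "glcm_asm",
                           "glcm_entropy", "glcm_correlation")]),
               c(0, 1, 1, 0, 0))
})

test_that("GLRLM captures analytic run patterns and the brute-force oracle", {
  # a 1 x 1 x N constant line scanned along its own axis: one run, LRE = N^2
  N <- 6
  q <- array(-1L, dim = c(1, 1, N)); q[1, 1, ] <- 3L
  R <- glrlm(q, L = 4, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(sum(R), 1)
  expect_equal(unname(glrlm_features(R)[["glrlm_lre"]]), N^2)

  # alternating levels: all runs of length 1
  q2 <- array(-1L, dim = c(1, 1, 8)); q2[1, 1, ] <- rep(c(0L, 1L), 4)
  R2 <- glrlm(q2, L = 2, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(unname(glrlm_features(R2)[["glrlm_lre"]]), 1)

  set.seed(13)
  for (rep in 1:10) {
    qarr <- random_qarr(c(4, 4, 4), L = 3)
    if (!any(qarr >= 0)) next
    expect_equal(unname(glrlm(qarr, L = 3)), unname(oracle_glrlm(qarr, 3)),
                 tolerance = 0)
  }
})

test_that("box counting recovers known dimensions", {
  cube <- array(TRUE, dim = c(32, 32, 32))
  expect_lt(abs(fractal_dimension_boxcount(cube) - 3), 0.1)

  # a straight 1-voxel line occupies N/s boxes at every scale
  line <- array(FALSE, dim = c(32, 4, 4))
  line[, 2, 2] <- TRUE
  expect_lt(abs(fractal_dimension_boxcount(line) - 1), 0.1)

  # Menger sponge, iteration 2, sampled on a 32^3 grid: dim log20 / log3
  keep1 <- function(v) sum(v == 1) <= 1  # middle-third rule per axis triple
  sponge <- array(FALSE, dim = c(32, 32, 32))
  for (z in 1:32) for (y in 1:32) for (x in 1:32) {
    u <- (c(x, y, z) - 0.5) / 32
    t1 <- floor(u * 3)
    t2 <- floor((u * 3 - t1) * 3)
    sponge[x, y, z] <- keep1(t1) && keep1(t2)
  }
  expect_lt(abs(fractal_dimension_boxcount(sponge) - log(20) / log(3)), 0.15)

  expect_error(fractal_dimension_boxcount(array(TRUE, dim = c(2, 2, 2))),
               "3 box sizes")
})

test_that("extract_features assembles 30 named, finite values", {
  ph <- generate_phantom(phantom_config(shape = c(48, 48, 48), n_nodules = 2,
                                        nodule_diameter_range_mm = c(4, 8),
                                        n_vessels = 1, seed = 44))
  sp <- auto_seed(ph$volume)
  nm <- normalize_intensity(ph$volume, sp)
  mask <- ssrg(nm, sp, 650, 2)
  cand <- detect_candidates(nm, mask, cad_config("A"))
  expect_gt(nrow(cand), 0)
  fv <- extract_features(nm, cand[1, ])
  expect_identical(names(fv), canonical_feature_names)
  expect_identical(length(fv), 30L)
  expect_true(all(is.finite(fv)))

  # constant region: documented conventions in one vector
  flatvol <- make_vol(array(100, dim = c(16, 16, 16)))
  c0 <- metcad:::make_candidates("flat", matrix(c(8, 8, 8), 1), 2.5,
                                 "template", 1, c(1, 1, 1))
  fv0 <- extract_features(flatvol, c0[1, ])
  expect_equal(unname(fv0[c("variance", "skewness", "kurtosis", "entropy",
                            "glcm_contrast", "glcm_correlation")]),
               c(0, 0, 0, 0, 0, 0))
  expect_equal(unname(fv0[c("energy", "glcm_homogeneity", "glcm_asm")]),
               c(1, 1, 1))
  expect_true("flat_region" %in% attr(fv0, "flags"))
})

test_that("features agree with a straight-from-definitions assembly", {
  set.seed(55)
  arr <- array(runif(20^3, 0, 1000), dim = c(20, 20, 20))
  vol <- make_vol(arr)
  cand <- metcad:::make_candidates("x", matrix(c(10, 10, 10), 1), 3,
                                   "template", 1, c(1, 1, 1))
  fv <- extract_features(vol, cand[1, ], L = 32, dilate = 1)
  reg <- candidate_region(vol, cand[1, ], L = 32, dilate = 1)

  om <- oracle_moments(reg$values)
  expect_equal(unname(fv[["mean"]]), unname(om[["mean"]]), tolerance = 1e-12)
  expect_equal(unname(fv[["skewness"]]), unname(om[["skew"]]), tolerance = 1e-12)
  expect_equal(unname(fv[["volume"]]), nrow(reg$voxels))

  P <- oracle_glcm(reg$qarr, 32)
  og <- oracle_glcm_features(P)
  expect_equal(unname(fv[["glcm_contrast"]]), unname(og[["contrast"]]),
               tolerance = 1e-9)
  expect_equal(unname(fv[["glcm_correlation"]]), unname(og[["correlation"]]),
               tolerance = 1e-9)

  R <- oracle_glrlm(reg$qarr, 32)
  or <- oracle_glrlm_features(R)
  expect_equal(unname(fv[["glrlm_lre"]]), unname(or[["lre"]]), tolerance = 1e-9)
  expect_equal(unname(fv[["glrlm_hgre"]]), unname(or[["hgre"]]), tolerance = 1e-9)

  expect_equal(unname(fv[["fractal_dimension"]]),
               min(max(oracle_boxcount(reg$qarr >= 0), 0), 3),
               tolerance = 1e-9)
})

test_that("features are invariant to volume translation", {
  set.seed(66)
  arr <- array(runif(18^3, 0, 500), dim = c(18, 18, 18))
  big <- array(0, dim = c(24, 24, 24))
  big[4:21, 4:21, 4:21] <- arr
  c1 <- metcad:::make_candidates("a", matrix(c(9, 9, 9), 1), 2.5,
                                 "template", 1, c(1, 1, 1))
  c2 <- metcad:::make_candidates("a", matrix(c(12, 12, 12), 1), 2.5,
                                 "template", 1, c(1, 1, 1))
  f1 <- extract_features(make_vol(arr), c1[1, ])
  f2 <- extract_features(make_vol(big), c2[1, ])
  expect_equal(f1, f2, tolerance = 1e-12)
})
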