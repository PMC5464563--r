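# Templates, NCC, template matching, 1D K-means, the clustering branch
# and candidate merging.

test_that("template support matches a brute-force distance scan", {
  tpl <- make_template(2, c(1, 1, 1), "solid")
  d <- dim(tpl$weights)
  ctr <- (d + 1) / 2
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    dist <- sqrt(sum((c(x, y, z) - ctr)^2))
    expect_identical(tpl$weights[x, y, z], as.numeric(dist <= 1))
  }
})

test_that("the inner hole is exactly half the template radius", {
  tpl <- make_template(4, c(1, 1, 1), "inner_hole")
  d <- dim(tpl$weights)
  ctr <- (d + 1) / 2
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    dist <- sqrt(sum((c(x, y, z) - ctr)^2))
    expected <- as.numeric(dist <= 2 && dist >= 1)  # hole radius 1 mm
    expect_identical(tpl$weights[x, y, z], expected)
  }
  # no weight strictly inside 50% of the radius
  expect_identical(tpl$weights[ctr[1], ctr[2], ctr[3]], 0)
})

test_that("templates are mirror symmetric and reject unresolvable sizes", {
  for (dmm in c(2, 3, 4)) for (kind in c("solid", "inner_hole")) {
    w <- make_template(dmm, c(1, 1, 1), kind)$weights
    for (ax in 1:3) {
      idx <- lapply(dim(w), seq_len)
      idx[[ax]] <- rev(idx[[ax]])
      expect_identical(w, w[idx[[1]], idx[[2]], idx[[3]]])
    }
  }
  expect_error(make_template(0.5, c(1, 1, 1)), "resolvable")
  # anisotropic spacing: window side grows along the coarse axis rule
  tpl <- make_template(4, c(1, 1, 2), "solid")
  expect_true(all(dim(tpl$weights) %% 2 == 1))
})

test_that("NCC scores perfect, inverted and formula-oracle cases", {
  tpl <- make_template(3, c(1, 1, 1), "solid")
  # window proportional to the template weights
  expect_equal(ncc(5 + 3 * tpl$weights, tpl), 1.0, tolerance = 1e-12)
  expect_equal(ncc(10 - 2 * tpl$weights, tpl), -1.0, tolerance = 1e-12)
  # fixed 3^3 binary kernel vs entries 1..27
  w <- array(0, dim = c(3, 3, 3)); w[2, 2, 2] <- 1; w[1, 2, 2] <- 1
  k3 <- structure(list(weights = w, n = 27, t_mean = mean(w),
                       t_sd = sqrt(mean((w - mean(w))^2)),
                       diameter_mm = 1, kind = "solid",
                       spacing_mm = c(1, 1, 1)),
                  class = "bm_template")
  win <- array(1:27, dim = c(3, 3, 3))
  expect_equal(ncc(win, k3), oracle_ncc(win, w), tolerance = 1e-14)
  # flat window convention
  flat <- ncc(array(4, dim = dim(tpl$weights)), tpl)
  expect_identical(as.numeric(flat), 0)
  expect_true(attr(flat, "flat"))
})

test_that("NCC is affine-invariant and bounded on random windows", {
  tpl <- make_template(2, c(1, 1, 1), "inner_hole")
  set.seed(5)
  for (rep in 1:50) {
    win <- array(rnorm(prod(dim(tpl$weights))), dim = dim(tpl$weights))
    v <- ncc(win, tpl)
    expect_gte(v, -1); expect_lte(v, 1)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    expect_equal(as.numeric(ncc(a * win + b, tpl)), as.numeric(v),
                 tolerance = 1e-9)
  }
})

test_that("template matching finds a clean nodule and respects thresholds", {
  arr <- array(100, dim = c(32, 32, 32))
  vol <- make_vol(arr)
  vol <- render_sphere(vol, c(16, 16, 16), diameter_mm = 3, intensity = 900)
  mask <- array(TRUE, dim = dim(arr))
  cand <- template_match(vol, mask, threshold = 0.5)
  expect_gt(nrow(cand), 0)
  d <- sqrt((cand$i - 16)^2 + (cand$j - 16)^2 + (cand$k - 16)^2)
  expect_lte(min(d), 1.5)

  # a near-perfect threshold on pure noise yields nothing
  set.seed(9)
  noisy <- make_vol(array(rnorm(24^3), dim = c(24, 24, 24)))
  expect_identical(nrow(template_match(noisy, array(TRUE, dim = c(24, 24, 24)),
                                       threshold = 0.999)), 0L)
  expect_error(template_match(noisy, array(TRUE, dim = c(24, 24, 24)),
                              threshold = 1.2), "threshold")
})

test_that("raising the NCC threshold never adds candidates", {
  ph <- generate_phantom(phantom_config(shape = c(48, 48, 48), n_nodules = 3,
                                        nodule_diameter_range_mm = c(3, 5),
                                        n_vessels = 2, seed = 21))
  sp <- auto_seed(ph$volume)
  nm <- normalize_intensity(ph$volume, sp)
  mask <- ssrg(nm, sp, 650, 2)
  lo <- template_match(nm, mask, threshold = 0.5)
  hi <- template_match(nm, mask, threshold = 0.7)
  expect_lte(nrow(hi), nrow(lo))
  # every high-threshold candidate is covered by a low-threshold one
  if (nrow(hi)) {
    for (r in seq_len(nrow(hi))) {
      d <- sqrt((lo$x_mm - hi$x_mm[r])^2 + (lo$y_mm - hi$y_mm[r])^2 +
                  (lo$z_mm - hi$z_mm[r])^2)
      expect_lte(min(d), hi$radius_mm[r] + max(lo$radius_mm))
    }
  }
})

test_that("1D K-means recovers point masses and the k = 1 mean", {
  vals <- rep(c(10, 20, 30, 40, 50, 60, 70), each = 20)
  km <- kmeans_1d(vals, k = 7)
  expect_equal(km$centers, c(10, 20, 30, 40, 50, 60, 70))
  expect_identical(km$assignments, rep(1:7, each = 20))

  km1 <- kmeans_1d(c(1, 2, 6), k = 1)
  expect_equal(km1$centers, 3)

  # duplicating every point changes nothing
  set.seed(4)
  v <- rnorm(60)
  a <- kmeans_1d(v, 4)
  b <- kmeans_1d(rep(v, 2), 4)
  expect_equal(a$centers, b$centers)

  expect_error(kmeans_1d(c(1, 1, 2, 2), k = 3), "distinct")
})

test_that("1D K-means converges to a Lloyd fixed point matching stats::kmeans", {
  set.seed(14)
  v <- c(rnorm(80, 0), rnorm(80, 6), rnorm(80, 14))
  km <- kmeans_1d(v, 3)
  # assignments follow the nearest-centre rule
  d <- abs(outer(v, km$centers, `-`))
  expect_identical(km$assignments, apply(d, 1, which.min))
  # independent Lloyd implementation agrees on the fixed point
  ref <- stats::kmeans(v, centers = matrix(km$centers), algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(sort(as.numeric(ref$centers)), km$centers, tolerance = 1e-8)
})

test_that("cluster branch sizes a large nodule and audits rim necrosis", {
  cfg <- phantom_config(shape = c(64, 64, 64), n_nodules = 1,
                        nodule_diameter_range_mm = c(10, 10),
                        rim_fraction = 0, n_vessels = 0, noise_sigma = 10,
                        seed = 33)
  ph <- generate_phantom(cfg)
  sp <- auto_seed(ph$volume)
  nm <- normalize_intensity(ph$volume, sp)
  mask <- ssrg(nm, sp, 650, 2)
  cand <- cluster_candidates(nm, mask)
  n <- ph$truth$nodules[1, ]
  d <- sqrt((cand$i - n$i)^2 + (cand$j - n$j)^2 + (cand$k - n$k)^2)
  hit <- which.min(d)
  expect_lte(d[hit], 2)
  expect_lte(abs(cand$radius_mm[hit] - 5), 1)  # within one voxel spacing

  # an impossible volume threshold removes everything
  none <- cluster_candidates(nm, mask,
                             morpho_thresholds = list(min_volume_mm3 = 1e9))
  expect_identical(nrow(none), 0L)

  # necrotic rim cores fall in the lowest-intensity cluster
  cfg2 <- phantom_config(shape = c(64, 64, 64), n_nodules = 1,
                         nodule_diameter_range_mm = c(9, 9),
                         rim_fraction = 1, n_vessels = 0, noise_sigma = 10,
                         seed = 34)
  ph2 <- generate_phantom(cfg2)
  sp2 <- auto_seed(ph2$volume)
  nm2 <- normalize_intensity(ph2$volume, sp2)
  mask2 <- ssrg(nm2, sp2, 650, 2)
  km <- kmeans_1d(nm2$data[mask2$mask], 7)
  asg <- array(NA_integer_, dim = dim(nm2$data))
  asg[mask2$mask] <- km$assignments
  n2 <- ph2$truth$nodules[1, ]
  expect_identical(asg[n2$i, n2$j, n2$k], 1L)  # core in the lowest cluster
})

test_that("merging concatenates disjoint sets and deduplicates overlaps", {
  a <- metcad:::make_candidates("c1", matrix(c(10, 10, 10), 1), 2, "template",
                                0.8, c(1, 1, 1))
  b <- metcad:::make_candidates("c1", matrix(c(30, 30, 30), 1), 2, "cluster",
                                0.5, c(1, 1, 1))
  m <- merge_candidates(a, b)
  expect_identical(nrow(m), 2L)

  expect_identical(nrow(merge_candidates(a, a)), 1L)

  # one voxel apart with 2 mm radii collapses to one, keeping the max score
  c2 <- metcad:::make_candidates("c1", matrix(c(11, 10, 10), 1), 2, "cluster",
                                 0.9, c(1, 1, 1))
  m2 <- merge_candidates(a, c2)
  expect_identical(nrow(m2), 1L)
  expect_equal(m2$score, 0.9)

  # same position in different cases never merges
  d2 <- metcad:::make_candidates("c2", matrix(c(10, 10, 10), 1), 2, "template",
                                 0.8, c(1, 1, 1))
  expect_identical(nrow(merge_candidates(a, d2)), 2L)
})
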