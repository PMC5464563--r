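# Brute-force reference implementations, written straight from the
# definitions with explicit loops.  They are deliberately slow and share
# no code with the package internals they check.

oracle_ncc <- function(window, weights) {
  f <- as.numeric(window)
  t <- as.numeric(weights)
  n <- length(f)
  fbar <- sum(f) / n
  tbar <- sum(t) / n
  sf <- sqrt(sum((f - fbar)^2) / n)
  st <- sqrt(sum((t - tbar)^2) / n)
  s <- 0
  for (m in seq_len(n)) s <- s + (f[m] - fbar) * (t[m] - tbar)
  (1 / n) * s / (sf * st)
}

oracle_moments <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  c(mean = mu, sd = sqrt(m2), var = m2,
    skew = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    kurt = if (m2 > 0) m4 / m2^2 else 0)
}

# all 26 unit offsets split into 13 +/- pairs, matching the canonical set
oracle_directions <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0))))
      out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

# qarr: integer array, -1 outside the region
oracle_glcm <- function(qarr, L) {
  d <- dim(qarr)
  P <- matrix(0, L, L)
  for (o in oracle_directions()) {
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      a <- qarr[x, y, z]
      if (a < 0) next
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      b <- qarr[x2, y2, z2]
      if (b < 0) next
      P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
    }
  }
  P <- P + t(P)
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  out <- c(contrast = 0, dissimilarity = 0, homogeneity = 0, asm = 0,
           energy = 0, prob_max = max(P), entropy = 0, correlation = 0,
           mean_r = 0, mean_n = 0, var_r = 0, var_n = 0, sd_r = 0, sd_n = 0)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    out["contrast"] <- out["contrast"] + p * (i - j)^2
    out["dissimilarity"] <- out["dissimilarity"] + p * abs(i - j)
    out["homogeneity"] <- out["homogeneity"] + p / (1 + (i - j)^2)
    out["asm"] <- out["asm"] + p^2
    if (p > 0) out["entropy"] <- out["entropy"] - p * log2(p)
  }
  out["energy"] <- sqrt(out["asm"])
  pr <- rowSums(P); pn <- colSums(P)
  lev <- 0:(L - 1)
  out["mean_r"] <- sum(lev * pr); out["mean_n"] <- sum(lev * pn)
  out["var_r"] <- sum((lev - out["mean_r"])^2 * pr)
  out["var_n"] <- sum((lev - out["mean_n"])^2 * pn)
  out["sd_r"] <- sqrt(out["var_r"]); out["sd_n"] <- sqrt(out["var_n"])
  if (out["sd_r"] > 0 && out["sd_n"] > 0) {
    for (i in 1:L) for (j in 1:L)
      out["correlation"] <- out["correlation"] +
        P[i, j] * (i - 1 - out["mean_r"]) * (j - 1 - out["mean_n"])
    out["correlation"] <- out["correlation"] / (out["sd_r"] * out["sd_n"])
  }
  out
}

# enumerate maximal runs by walking every line voxel by voxel
oracle_glrlm <- function(qarr, L) {
  d <- dim(qarr)
  R <- matrix(0, L, max(d))
  inb <- function(v) all(v >= 1) && all(v <= d)
  for (o in oracle_directions()) {
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      v <- c(x, y, z)
      g <- qarr[x, y, z]
      if (g < 0) next
      pv <- v - o
      if (inb(pv) && qarr[pv[1], pv[2], pv[3]] == g) next  # not a run start
      len <- 1
      nv <- v + o
      while (inb(nv) && qarr[nv[1], nv[2], nv[3]] == g) {
        len <- len + 1
        nv <- nv + o
      }
      R[g + 1, len] <- R[g + 1, len] + 1
    }
  }
  R
}

oracle_glrlm_features <- function(R) {
  Nr <- sum(R)
  lre <- 0; lgre <- 0; hgre <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    lre <- lre + R[g, l] * l^2
    lgre <- lgre + R[g, l] / g^2
    hgre <- hgre + R[g, l] * g^2
  }
  c(lre = lre / Nr,
    gln = sum(rowSums(R)^2) / Nr,
    rln = sum(colSums(R)^2) / Nr,
    lgre = lgre / Nr, hgre = hgre / Nr)
}

# independent box counting: explicit triple loop over box grid
oracle_boxcount <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  idx <- sweep(idx, 2, lo - 1L, `-`)
  ext <- apply(idx, 2, max)
  sizes <- c()
  s <- 1
  while (2 * s <= max(ext)) { sizes <- c(sizes, s); s <- 2 * s }
  sizes <- c(sizes, s)
  counts <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    occ <- new.env()
    for (r in seq_len(nrow(idx))) {
      key <- paste(ceiling(idx[r, ] / s), collapse = ",")
      assign(key, TRUE, envir = occ)
    }
    counts[si] <- length(ls(occ))
  }
  xs <- log(1 / sizes)
  ys <- log(counts)
  # closed-form least squares
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  b
}

oracle_fom <- function(lesions, nonlesions) {
  s <- 0
  for (a in lesions) for (b in nonlesions)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(lesions) * length(nonlesions))
}

# plain SRG by breadth-first search with an explicit queue
oracle_srg <- function(arr, seed, ref, tol) {
  d <- dim(arr)
  mask <- array(FALSE, dim = d)
  pred <- function(v) abs(arr[v[1], v[2], v[3]] - ref) <= tol
  if (!pred(seed)) return(mask)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]]) next
      if (pred(w)) {
        mask[w[1], w[2], w[3]] <- TRUE
        queue <- c(queue, list(w))
      }
    }
  }
  mask
}

# per-voxel spherical predicate used by the SSRG oracle
oracle_sphere_ok <- function(arr, v, ref, tol, radius) {
  d <- dim(arr)
  r <- ceiling(radius)
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dx^2 + dy^2 + dz^2 > radius^2) next
    w <- v + c(dx, dy, dz)
    if (any(w < 1) || any(w > d)) next
    if (abs(arr[w[1], w[2], w[3]] - ref) > tol) return(FALSE)
  }
  TRUE
}

oracle_ssrg <- function(arr, seed, ref, tol, radius) {
  d <- dim(arr)
  ok <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    ok[x, y, z] <- oracle_sphere_ok(arr, c(x, y, z), ref, tol, radius)
  # flood fill over the acceptable set
  mask <- array(FALSE, dim = d)
  if (!ok[seed[1], seed[2], seed[3]]) return(mask)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]] || !ok[w[1], w[2], w[3]]) next
      mask[w[1], w[2], w[3]] <- TRUE
      queue <- c(queue, list(w))
    }
  }
  mask
}

# small random quantized region inside an array, for texture oracles
random_qarr <- function(dims, L, fill = 0.7) {
  qarr <- array(-1L, dim = dims)
  n <- prod(dims)
  sel <- sample.int(n, ceiling(fill * n))
  qarr[sel] <- sample(0:(L - 1), length(sel), replace = TRUE)
  qarr
}

make_vol <- function(arr, spacing = c(1, 1, 1), id = "test")
  volume3d(arr, spacing_mm = spacing, case_id = id)
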