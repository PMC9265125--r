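# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit voxel-pair enumeration, run
# scanning, BFS flood fill, direct convolution loops) without touching the
# package's computational kernels.

# 13 unique direction vectors at Chebyshev distance 1.
oracle_dirs <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  # keep one of each antipodal pair (first nonzero component positive)
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  as.matrix(d[keep, ])
}

# `lev`: 3D integer array, 0 = outside the VOI.

oracle_glcm_matrix <- function(lev, nbins) {
  dims <- dim(lev)
  M <- matrix(0, nbins, nbins)
  dirs <- oracle_dirs()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    for (d in seq_len(nrow(dirs))) {
      xx <- x + dirs[d, 1]; yy <- y + dirs[d, 2]; zz <- z + dirs[d, 3]
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
          zz < 1 || zz > dims[3]) next
      j <- lev[xx, yy, zz]
      if (j == 0) next
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
    }
  }
  M
}

oracle_glcm_features <- function(lev, nbins) {
  M <- oracle_glcm_matrix(lev, nbins)
  S <- sum(M)
  out <- rep(0, 11)
  if (S > 0) {
    P <- M / S
    ii <- row(P); jj <- col(P)
    px <- rowSums(P)
    mu <- sum(seq_len(nbins) * px)
    v <- sum((seq_len(nbins) - mu)^2 * px)
    ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    psum <- vapply(2:(2 * nbins), function(k) sum(P[ii + jj == k]), 0)
    pdiff <- vapply(0:(nbins - 1), function(k) sum(P[abs(ii - jj) == k]), 0)
    out <- c(sum(P^2),
             ent(P),
             sum(P * (ii - jj)^2),
             sum(P * abs(ii - jj)),
             sum(P / (1 + abs(ii - jj))),
             sum(P / (1 + (ii - jj)^2)),
             if (v > 1e-12) (sum(ii * jj * P) - mu^2) / v else 0,
             sum((ii - mu)^2 * P),
             sum((2:(2 * nbins)) * psum),
             ent(psum),
             ent(pdiff))
  }
  names(out) <- feature_registry()$families$GLCM
  out
}

# Runs: scan every line in every direction for maximal equal-level runs.
oracle_glrlm_matrix <- function(lev, nbins) {
  dims <- dim(lev)
  dirs <- oracle_dirs()
  runs <- list()
  inside <- function(x, y, z) {
    x >= 1 && x <= dims[1] && y >= 1 && y <= dims[2] && z >= 1 && z <= dims[3]
  }
  at <- function(x, y, z) if (inside(x, y, z)) lev[x, y, z] else 0L
  for (d in seq_len(nrow(dirs))) {
    dx <- dirs[d, 1]; dy <- dirs[d, 2]; dz <- dirs[d, 3]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      l <- lev[x, y, z]
      if (l == 0) next
      if (at(x - dx, y - dy, z - dz) == l) next  # not a run start
      len <- 1
      while (at(x + len * dx, y + len * dy, z + len * dz) == l) len <- len + 1
      runs[[length(runs) + 1]] <- c(l, len)
    }
  }
  runs <- do.call(rbind, runs)
  M <- matrix(0, nbins, max(runs[, 2]))
  for (r in seq_len(nrow(runs))) {
    M[runs[r, 1], runs[r, 2]] <- M[runs[r, 1], runs[r, 2]] + 1
  }
  M
}

# 26-connected equal-level zones by BFS.
oracle_glszm_matrix <- function(lev, nbins) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  zones <- list()
  nbrs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    l <- lev[x, y, z]
    queue <- matrix(c(x, y, z), ncol = 3)
    seen[x, y, z] <- TRUE
    size <- 0
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1
      for (d in seq_len(nrow(nbrs))) {
        w <- v + nbrs[d, ]
        if (any(w < 1) || any(w > dims)) next
        if (seen[w[1], w[2], w[3]] || lev[w[1], w[2], w[3]] != l) next
        seen[w[1], w[2], w[3]] <- TRUE
        queue <- rbind(queue, w)
      }
    }
    zones[[length(zones) + 1]] <- c(l, size)
  }
  zones <- do.call(rbind, zones)
  M <- matrix(0, nbins, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) {
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  }
  M
}

# Shared GLRLM/GLSZM feature roster from a (level x size) count matrix.
oracle_rl_sz_features <- function(M, pct_denom, names) {
  tot <- sum(M)
  P <- M / tot
  ii <- row(P); ll <- col(P)
  mi <- rowSums(P); ml <- colSums(P)
  mu_i <- sum(seq_along(mi) * mi)
  mu_l <- sum(seq_along(ml) * ml)
  out <- c(sum(P / ll^2), sum(P * ll^2), sum(P / ii^2), sum(P * ii^2),
           sum(P / (ii^2 * ll^2)), sum(P * ii^2 / ll^2),
           sum(P * ll^2 / ii^2), sum(P * ii^2 * ll^2),
           sum(rowSums(M)^2) / tot, sum(colSums(M)^2) / tot,
           tot / pct_denom,
           sum(P * (ii - mu_i)^2), sum(P * (ll - mu_l)^2))
  names(out) <- names
  out
}

oracle_glrlm_features <- function(lev, nbins, nvoi) {
  oracle_rl_sz_features(oracle_glrlm_matrix(lev, nbins), 13 * nvoi,
                        feature_registry()$families$GLRLM)
}

oracle_glszm_features <- function(lev, nbins, nvoi) {
  oracle_rl_sz_features(oracle_glszm_matrix(lev, nbins), nvoi,
                        feature_registry()$families$GLSZM)
}

# Dependence counts: equal-level 26-neighbors, alpha = 0.
oracle_ngldm_matrix <- function(lev, nbins) {
  dims <- dim(lev)
  M <- matrix(0, nbins, 27)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
          zz < 1 || zz > dims[3]) next
      if (lev[xx, yy, zz] == l) dep <- dep + 1
    }
    M[l, dep + 1] <- M[l, dep + 1] + 1
  }
  M
}

oracle_ngldm_features <- function(lev, nbins) {
  M <- oracle_ngldm_matrix(lev, nbins)
  tot <- sum(M)
  P <- M / tot
  ii <- row(P); jj <- col(P)
  mi <- rowSums(P); mj <- colSums(P)
  mu_i <- sum(seq_along(mi) * mi)
  mu_j <- sum(seq_along(mj) * mj)
  pn0 <- P[P > 0]
  out <- c(sum(P / jj^2), sum(P * jj^2), sum(P / ii^2), sum(P * ii^2),
           sum(P / (ii^2 * jj^2)), sum(P * ii^2 / jj^2),
           sum(P * jj^2 / ii^2), sum(P * ii^2 * jj^2),
           sum(rowSums(M)^2) / tot, sum(rowSums(M)^2) / tot^2,
           sum(colSums(M)^2) / tot, sum(colSums(M)^2) / tot^2,
           sum(P * (ii - mu_i)^2), sum(P * (jj - mu_j)^2),
           -sum(pn0 * log2(pn0)), sum(P^2))
  names(out) <- feature_registry()$families$NGLDM
  out
}

oracle_ngtdm_features <- function(lev, nbins) {
  dims <- dim(lev)
  n <- rep(0, nbins); s <- rep(0, nbins)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
          zz < 1 || zz > dims[3]) next
      if (lev[xx, yy, zz] > 0) vals <- c(vals, lev[xx, yy, zz])
    }
    if (length(vals) == 0) next
    n[l] <- n[l] + 1
    s[l] <- s[l] + abs(l - mean(vals))
  }
  nvc <- sum(n)
  p <- n / nvc
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  coarse <- 1 / max(ps, 1e-6)
  contrast <- 0; busy_den <- 0; cmplx <- 0; strength_num <- 0
  for (i in act) for (j in act) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    cmplx <- cmplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  out <- c(coarse,
           if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s) / nvc else 0,
           if (busy_den > 0) ps / busy_den else 0,
           cmplx / nvc,
           if (sum(s) > 0) strength_num / sum(s) else 0)
  names(out) <- feature_registry()$families$NGTDM
  out
}

oracle_texture_features <- function(lev, nbins) {
  nvoi <- sum(lev > 0)
  c(oracle_glcm_features(lev, nbins),
    oracle_glrlm_features(lev, nbins, nvoi),
    oracle_glszm_features(lev, nbins, nvoi),
    oracle_ngldm_features(lev, nbins),
    oracle_ngtdm_features(lev, nbins))
}

# Direct triple-loop correlation along one axis with half-sample symmetric
# boundary reflection — the wavelet convolution oracle.
oracle_axis_convolve <- function(arr, axis, taps, offset) {
  dims <- dim(arr)
  out <- array(0, dims)
  n <- dims[axis]
  refl <- function(i) {
    while (i < 0 || i >= n) {
      if (i < 0) i <- -1 - i
      if (i >= n) i <- 2 * n - 1 - i
    }
    i
  }
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    acc <- 0
    for (t in seq_along(taps)) {
      pos <- c(x, y, z)
      pos[axis] <- refl(pos[axis] - 1 + (t - 1) - offset) + 1
      acc <- acc + taps[t] * arr[pos[1], pos[2], pos[3]]
    }
    out[x, y, z] <- acc
  }
  out
}
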