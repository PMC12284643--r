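# Independent brute-force oracles used to verify the fast implementations.
# These deliberately share no code with the package internals.

# per-voxel minimum Euclidean distance (mm) to any mask voxel
bruteDistance <- function(mask, sp) {
  idx <- which(mask, arr.ind = TRUE)
  out <- array(0, dim(mask))
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  for (i in seq_len(nrow(all_idx))) {
    dd <- sweep(idx, 2L, all_idx[i, ], `-`)
    dd <- sweep(dd, 2L, sp, `*`)
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# direct (non-separable) 3D correlation with zero padding; valid only on
# interior voxels where the kernel fits entirely inside the volume
bruteConv3 <- function(arr, kx, ky, kz) {
  d <- dim(arr)
  r <- (length(kx) - 1) / 2
  out <- array(NA_real_, d)
  ker <- outer(outer(kx, ky), kz)
  for (i in (r + 1):(d[1] - r))
    for (j in (r + 1):(d[2] - r))
      for (k in (r + 1):(d[3] - r)) {
        blk <- arr[(i - r):(i + r), (j - r):(j + r), (k - r):(k + r)]
        out[i, j, k] <- sum(blk * ker)
      }
  out
}

# 13 Haralick statistics from explicit pair enumeration over a label array
# (levels valued 1..L), using the same 13-direction symmetric accumulation
# convention as the package but written independently in plain R.
bruteHaralick <- function(labels, L, offsets) {
  d <- dim(labels)
  if (length(d) == 2L) {
    d <- c(d, 1L)
    labels <- array(labels, d)
  }
  glcm <- matrix(0, L, L)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      q <- c(x, y, z) + off
      if (any(q < 1) || any(q > d)) next
      l1 <- labels[x, y, z]
      l2 <- labels[q[1], q[2], q[3]]
      if (l1 < 1 || l2 < 1) next
      glcm[l1, l2] <- glcm[l1, l2] + 1
      glcm[l2, l1] <- glcm[l2, l1] + 1
    }
  }
  p <- glcm / sum(glcm)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  mux <- sum(seq_len(L) * px)
  sx2 <- sum((seq_len(L) - mux)^2 * px)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  psum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  sumavg <- sum((2:(2 * L)) * psum)
  dmean <- sum((0:(L - 1)) * pdiff)
  hx <- -sum(xlogx(px))
  pij <- outer(px, px)
  ent <- -sum(xlogx(p))
  hxy1 <- -sum(ifelse(p > 0 & pij > 0, p * log(pij), 0))
  hxy2 <- -sum(xlogx(pij))
  e2 <- 1 - exp(-2 * (hxy2 - ent))
  c(energy = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = if (sx2 > 1e-12) (sum(i * j * p) - mux^2) / sx2 else 0,
    variance = sx2,
    idm = sum(p / (1 + (i - j)^2)),
    sumAverage = sumavg,
    sumVariance = sum(((2:(2 * L)) - sumavg)^2 * psum),
    sumEntropy = -sum(xlogx(psum)),
    entropy = ent,
    differenceVariance = sum(((0:(L - 1)) - dmean)^2 * pdiff),
    differenceEntropy = -sum(xlogx(pdiff)),
    imc1 = if (hx > 1e-12) (ent - hxy1) / hx else 0,
    imc2 = if (e2 > 0) sqrt(e2) else 0)
}

offsets13 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ]
}

# Harrell C-index by exhaustive evaluable-pair enumeration
bruteCindex <- function(time, event, score) {
  conc <- disc <- ties <- 0
  n <- length(time)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    # the pair is evaluable if the shorter time is an event
    ta <- time[a]; tb <- time[b]
    if (ta == tb && event[a] && event[b]) next  # tied times: not evaluable here
    if (ta < tb && !event[a]) next
    if (tb < ta && !event[b]) next
    if (ta == tb) next
    early <- if (ta < tb) a else b
    late <- if (ta < tb) b else a
    if (score[early] > score[late]) conc <- conc + 1
    else if (score[early] < score[late]) disc <- disc + 1
    else ties <- ties + 0.5
  }
  (conc + ties) / (conc + disc + ties)
}

# two-group log-rank chi-square statistic, written directly from the
# hypergeometric formulation (for permutation oracles)
logrankStat <- function(time, event, grp) {
  grp <- as.integer(grp == levels(factor(grp))[2])
  ut <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in ut) {
    at <- time >= t
    n1 <- sum(at & grp == 1)
    n0 <- sum(at & grp == 0)
    d1 <- sum(time == t & event == 1 & grp == 1)
    d <- sum(time == t & event == 1)
    n <- n1 + n0
    if (n < 2) next
    o <- o + d1
    e <- e + d * n1 / n
    v <- v + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o - e)^2 / v
}

# small digital sphere fixture
sphereMask <- function(r, dims = rep(2 * r + 11, 3), spacing = 1) {
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  array(((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2) *
          spacing^2 <= r^2, dims)
}

# tiny in-memory subject for pipeline tests
tinyPhantom <- function(seed, dims = c(24L, 24L, 24L), amplitude = 3,
                        orientation = "outward") {
  generatePhantom(phantomSpec(
    dims = dims, spacing = c(3, 3, 3), brainSemiAxes = c(31, 31, 29),
    tumorCenterOffset = c(0, -6, -5), edemaSemiAxes = c(11, 10, 10),
    amplitude = amplitude, orientation = orientation, seed = seed),
    protocols = "GdT1w")
}
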