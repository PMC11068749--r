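# Shared fixture builders. Everything is generated in code at test time.

# a half-scale phantom: same physical anatomy (mm) on a 0.5 mm grid, about
# 5x fewer voxels than the default — fast enough for unit tests
tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 58L, 52L), spacing = c(0.5, 0.5, 0.5), ...)
}

# small random volume with integer intensities
random_volume <- function(dim = c(6, 5, 4), spacing = c(0.3, 0.3, 0.3),
                          origin = c(0, 0, 0), max_val = 1000L) {
  voxel_volume(array(sample.int(max_val, prod(dim), replace = TRUE), dim),
               spacing, origin)
}

random_mask <- function(dim = c(20, 20, 20), p = 0.5,
                        spacing = c(1, 1, 1)) {
  binary_mask(array(runif(prod(dim)) < p, dim), spacing)
}

# digitized solid ball of radius r voxels in a grid with margin
ball_mask <- function(r, spacing = c(0.3, 0.3, 0.3), margin = 3) {
  d <- rep(2 * r + 2 * margin + 1, 3)
  cc <- r + margin + 1
  ax <- (seq_len(d[1]) - cc)^2
  g <- outer(outer(ax, ax, "+"), ax, "+") <= r^2
  binary_mask(array(g, d), spacing)
}

cube_mask <- function(side, spacing = c(0.3, 0.3, 0.3), margin = 3) {
  d <- rep(side + 2 * margin, 3)
  g <- array(FALSE, d)
  idx <- (margin + 1):(margin + side)
  g[idx, idx, idx] <- TRUE
  binary_mask(g, spacing)
}

# independent exhaustive Kapur criterion scan (the oracle for
# max_entropy_threshold): plain loops, no shared code with the package
oracle_max_entropy <- function(vals, n_bins) {
  rng <- range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (v in vals) {
    b <- 1 + floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins)
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  p <- counts / sum(counts)
  best_crit <- -Inf
  tied <- integer(0)
  for (s in 1:(n_bins - 1)) {
    p0 <- sum(p[1:s])
    p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    h0 <- 0
    for (i in 1:s) if (p[i] > 0) h0 <- h0 - (p[i] / p0) * log(p[i] / p0)
    h1 <- 0
    for (i in (s + 1):n_bins) if (p[i] > 0) h1 <- h1 - (p[i] / p1) * log(p[i] / p1)
    crit <- h0 + h1
    if (crit > best_crit + 1e-12) {
      best_crit <- crit
      tied <- s
    } else if (abs(crit - best_crit) <= 1e-12) {
      tied <- c(tied, s)
    }
  }
  breaks[tied[ceiling(length(tied) / 2)] + 1]
}

# independent voxel tally: per-slice classification via code tabulation,
# a different route than the package's vectorized logical sums
oracle_overlap_tally <- function(pre, post) {
  d <- dim(pre$data)
  vpre <- vpost <- ov <- 0
  for (k in seq_len(d[3])) {
    code <- 2 * pre$data[, , k] + post$data[, , k]  # 0 none, 1 post, 2 pre, 3 both
    tab <- tabulate(code + 1, nbins = 4)
    vpre <- vpre + tab[3] + tab[4]
    vpost <- vpost + tab[2] + tab[4]
    ov <- ov + tab[4]
  }
  list(Vpre = vpre, Vpost = vpost, overlap = ov,
       dV = vpost - vpre, dV_minus = vpre - ov, dV_plus = vpost - ov)
}
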