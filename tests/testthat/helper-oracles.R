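# Shared fixtures and independent oracles for the suite.

breast_protocol <- function() default_breast_protocol()

# Independent exhaustive-permutation two-sided p for the rank-sum test:
# enumerate every assignment of the pooled values to the two groups and
# count assignments at least as extreme (|U - n1 n2 / 2|) as observed.
perm_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    r <- rank(c(pooled[ix], pooled[-ix]))
    sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  }
  mid <- n1 * n2 / 2
  obs <- abs(u_of(seq_len(n1)) - mid)
  devs <- apply(utils::combn(n1 + n2, n1), 2,
                function(ix) abs(u_of(ix) - mid))
  mean(devs >= obs - 1e-9)
}

# Two-region box phantom (no noise): inner box with lesion params, outer
# background, used for map-level and segmentation fixtures.
two_region_volume <- function(grid = c(12, 12, 4),
                              lesion_value = 800, background = 100) {
  vol <- array(background, grid)
  ctr <- round(grid / 2)
  vol[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
      (ctr[3] - 1):(ctr[3] + 1)] <- lesion_value
  vol
}

# Ellipsoid mask helper
ellipsoid_mask <- function(grid, center, semiaxes) {
  ax <- sweep(arrayInd(seq_len(prod(grid)), grid), 2, center)
  array(rowSums(sweep(ax, 2, semiaxes, "/")^2) <= 1, grid)
}
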