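# Independent oracles, deliberately written with different machinery than
# the implementations they check.

# F1 genotype distribution by explicit gamete enumeration: each parent
# contributes each of its two alleles with probability 1/2.
f1_oracle <- function(d1, d2) {
  gam1 <- c(rep(1L, d1), rep(0L, 2L - d1))
  gam2 <- c(rep(1L, d2), rep(0L, 2L - d2))
  offspring <- outer(gam1, gam2, `+`)
  p <- tabulate(as.vector(offspring) + 1L, nbins = 3L) / 4
  stats::setNames(p, c("HOM_REF", "HET", "HOM_ALT"))
}

# Weir & Cockerham (1984) theta for one locus, loop-based from scratch.
# geno: dosage vector; pop: population label per sample.
wc_theta_oracle <- function(geno, pop) {
  pops <- unique(pop)
  n <- p <- h <- numeric(0)
  for (pl in pops) {
    g <- geno[pop == pl]
    g <- g[!is.na(g)]
    if (length(g) >= 2) {
      n <- c(n, length(g))
      p <- c(p, sum(g) / (2 * length(g)))
      h <- c(h, mean(g == 1))
    }
  }
  r <- length(n)
  if (r < 2) return(NA_real_)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  if ((pbar == 0 || pbar == 1) && all(h == 0)) return(NA_real_)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Expected per-locus P_mask by brute-force enumeration of all 3x3 genotype
# pairs weighted by Hardy-Weinberg probabilities.
p_mask_expectation_oracle <- function(q_d, q_r) {
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)  # dosage 0,1,2
  wd <- hwe(q_d); wr <- hwe(q_r)
  weight <- matrix(0, 3, 3)  # [donor dosage + 1, recipient dosage + 1]
  weight[1, 3] <- 1      # donor HOM_REF x recipient HOM_ALT: masked, p = 1
  weight[2, 3] <- 0.5    # donor HET x recipient HOM_ALT
  weight[3, 2] <- -0.5   # donor HOM_ALT x recipient HET: unmasked
  weight[2, 2] <- -0.25  # donor HET x recipient HET
  total <- 0
  for (i in 1:3) for (j in 1:3) total <- total + wd[i] * wr[j] * weight[i, j]
  total
}

# Expected per-locus M_add for one donor genome against a recipient
# population of n_r diploids, by enumeration.
m_add_expectation_oracle <- function(q_d, q_r, n_r) {
  p_donor_carries <- 1 - (1 - q_d)^2
  p_absent_recipients <- (1 - q_r)^(2 * n_r)
  p_donor_carries * p_absent_recipients
}
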