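#' Per-SNP multi-population Weir-Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) theta estimator per biallelic SNP
#' across the analysed populations, from per-population sample sizes, allele
#' frequencies and observed heterozygote frequencies (variance components
#' a, b, c; theta = a / (a + b + c)). Negative estimates are retained, not
#' clamped. At each locus only populations with at least two called
#' genotypes are used; loci with fewer than two usable populations, or
#' monomorphic over the analysed samples, carry an `NA` sentinel and are
#' excluded from downstream distributions.
#'
#' @param table A [variant_table()].
#' @param popmap Popmap tibble.
#' @param pops Population labels to analyse (default: all populations in the
#'   popmap with members in the table); at least two required.
#' @return A tibble with one row per locus: `chrom`, `pos`,
#'   `functional_class`, `adaptive_flag`, `gene`, `fst`, `n_pops_used` and
#'   the total called-genotype count `n_called`.
#' @export
per_snp_fst <- function(table, popmap, pops = NULL) {
  stopifnot(inherits(table, "variant_table"))
  comp <- fst_components(table, popmap, pops)

  tibble(
    chrom = table$loci$chrom, pos = table$loci$pos,
    functional_class = table$loci$functional_class,
    adaptive_flag = table$loci$adaptive_flag,
    gene = table$loci$gene,
    fst = comp$theta,
    n_pops_used = comp$r,
    n_called = comp$n_called
  )
}

# Per-population N/P/H matrices and WC84 components for a table.
fst_components <- function(table, popmap, pops = NULL) {
  pops <- pops %||% unique(popmap$population[popmap$sample %in% table$samples])
  if (length(pops) < 2L) abort("F_ST needs at least two populations")
  nl <- nrow(table$loci)
  npop <- length(pops)
  N <- P <- H <- matrix(NA_real_, nl, npop)
  for (j in seq_along(pops)) {
    s <- intersect(population_samples(popmap, pops[j]), table$samples)
    if (!length(s)) abort(paste0("population has no members in the table: ", pops[j]))
    g <- table$geno[, s, drop = FALSE]
    nj <- rowSums(!is.na(g))
    N[, j] <- nj
    P[, j] <- ifelse(nj > 0, rowSums(g, na.rm = TRUE) / (2 * nj), NA_real_)
    H[, j] <- ifelse(nj > 0, rowSums(g == 1L, na.rm = TRUE) / nj, NA_real_)
  }
  usable <- !is.na(N) & N >= 2
  N[!usable] <- NA_real_
  comp <- wc_theta_components(N, P, H)
  comp$n_called <- as.integer(rowSums(N, na.rm = TRUE))
  comp
}

#' Multi-locus Weir-Cockerham F_ST
#'
#' The standard multi-locus aggregate: variance components are summed over
#' loci before taking the ratio (`sum(a) / sum(a + b + c)`). Unlike the mean
#' of per-SNP theta values, this ratio-of-sums estimator is consistent for
#' the population differentiation parameter and is the quantity to compare
#' against an island-model target.
#'
#' @param table A [variant_table()].
#' @param popmap Popmap tibble.
#' @param pops Population labels to analyse (default: all with members).
#' @param loci Optional logical/integer locus index restricting the
#'   aggregate (e.g., the gene-desert set).
#' @return A single numeric F_ST estimate.
#' @export
multilocus_fst <- function(table, popmap, pops = NULL, loci = NULL) {
  if (!is.null(loci)) table <- subset_variants(table, loci = loci)
  comp <- fst_components(table, popmap, pops)
  ok <- is.finite(comp$theta)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

# Vectorised WC84 variance components over loci. N, P, H are loci x pops
# matrices with NA marking unusable population/locus cells.
wc_theta_components <- function(N, P, H) {
  use <- !is.na(N)
  r <- rowSums(use)
  sumn <- rowSums(N, na.rm = TRUE)
  nbar <- sumn / r
  nc <- (sumn - rowSums(N^2, na.rm = TRUE) / sumn) / (r - 1)
  pbar <- rowSums(N * P, na.rm = TRUE) / sumn
  s2 <- rowSums(N * (P - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(N * H, na.rm = TRUE) / sumn

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc

  theta <- a / denom
  theta[!is.finite(theta)] <- NA_real_
  theta[r < 2] <- NA_real_
  # monomorphic over analysed samples: no variance to partition
  mono <- pbar %in% c(0, 1) & hbar == 0
  theta[mono] <- NA_real_
  list(theta = theta, r = as.integer(r), a = a, b = b, c = cc)
}

#' Empirical percentile of the neutral F_ST distribution
#'
#' Returns the q-th percentile of the defined (non-`NA`) neutral F_ST
#' values, using linear interpolation between order statistics
#' ([stats::quantile()] type 7), so cutoffs are bit-reproducible. Warns when
#' fewer than 20 defined values are available.
#'
#' @param neutral_fst Numeric vector of F_ST values (e.g., the `fst` column
#'   of [per_snp_fst()] restricted to gene-desert loci).
#' @param q Percentile in (0, 100); default 95.
#' @return The percentile cutoff as a single numeric.
#' @export
null_percentile <- function(neutral_fst, q = 95) {
  x <- neutral_fst[is.finite(neutral_fst)]
  if (!length(x)) abort("no defined neutral F_ST values")
  if (length(x) < 20L) {
    warn(sprintf("only %d defined neutral F_ST values; percentile is unstable", length(x)))
  }
  unname(stats::quantile(x, probs = q / 100, type = 7, names = FALSE))
}

#' Flag adaptive loci exceeding the neutral F_ST cutoff
#'
#' A locus is an outlier when its F_ST is strictly greater than the cutoff.
#'
#' @param adaptive_fst Tibble of per-SNP F_ST rows for the test set (from
#'   [per_snp_fst()]); rows with undefined F_ST are dropped.
#' @param cutoff Finite F_ST cutoff (e.g., from [null_percentile()]).
#' @return An `outlier_screen` list: `cutoff`, `n_test`, `n_outliers`,
#'   `outlier_fraction`, the flagged per-locus tibble `loci`, and per-gene
#'   groupings `by_gene`.
#' @export
flag_outliers <- function(adaptive_fst, cutoff) {
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  loci <- adaptive_fst |>
    filter(is.finite(.data$fst)) |>
    mutate(outlier = .data$fst > cutoff)
  by_gene <- loci |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$gene) |>
    summarise(n_loci = n(), n_outliers = sum(.data$outlier),
              max_fst = max(.data$fst), .groups = "drop")
  structure(
    list(
      cutoff = cutoff,
      n_test = nrow(loci),
      n_outliers = sum(loci$outlier),
      outlier_fraction = if (nrow(loci)) mean(loci$outlier) else NA_real_,
      loci = loci,
      by_gene = by_gene
    ),
    class = "outlier_screen"
  )
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf(
    "<outlier_screen> %d/%d test loci above F_ST cutoff %.4f (%.1f%%)\n",
    x$n_outliers, x$n_test, x$cutoff, 100 * x$outlier_fraction
  ))
  invisible(x)
}

#' @export
tidy.outlier_screen <- function(x, ...) x$loci

#' @export
glance.outlier_screen <- function(x, ...) {
  tibble(cutoff = x$cutoff, n_test = x$n_test, n_outliers = x$n_outliers,
         outlier_fraction = x$outlier_fraction)
}

#' Gene-desert-null F_ST outlier screen
#'
#' End-to-end local-adaptation screen: per-SNP Weir-Cockerham F_ST over the
#' analysed populations, the neutral null from gene-desert loci, the
#' percentile cutoff, and outlier flags for the adaptive test set.
#'
#' @param table An annotated [variant_table()].
#' @param popmap Popmap tibble.
#' @param pops Populations to analyse (default: all with members).
#' @param neutral_class Functional class of the null set (default
#'   `GENE_DESERT`).
#' @param test_class Test set: `"ADAPTIVE"` (adaptive-flagged loci, default)
#'   or a functional class.
#' @param percentile Null percentile (default 95).
#' @return An `outlier_screen` (see [flag_outliers()]) with the neutral
#'   per-SNP tibble attached as `$neutral` and `n_neutral` recorded.
#' @export
fst_outlier_screen <- function(table, popmap, pops = NULL,
                               neutral_class = "GENE_DESERT",
                               test_class = "ADAPTIVE",
                               percentile = 95) {
  fst <- per_snp_fst(table, popmap, pops)
  neutral <- fst[class_index_rows(table, neutral_class), , drop = FALSE] |>
    filter(is.finite(.data$fst))
  test <- fst[class_index_rows(table, test_class), , drop = FALSE]
  cutoff <- null_percentile(neutral$fst, q = percentile)
  screen <- flag_outliers(test, cutoff)
  screen$neutral <- neutral
  screen$n_neutral <- nrow(neutral)
  screen
}

class_index_rows <- function(table, class) {
  if (identical(class, "ADAPTIVE")) which(table$loci$adaptive_flag)
  else which(table$loci$functional_class == class)
}
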