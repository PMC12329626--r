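#' Mendelian F1 genotype distribution of a biallelic cross
#'
#' Exact gamete enumeration for two diploid parents: each parent transmits
#' either allele with probability 1/2, so offspring probabilities are
#' multiples of 1/4 (computed in integer quarters, hence exact).
#'
#' @param parent1,parent2 Genotypes as dosage (0/1/2) or state labels
#'   (`"HOM_REF"`, `"HET"`, `"HOM_ALT"`). Missing parents are a fatal error.
#' @return Named numeric vector `c(HOM_REF=, HET=, HOM_ALT=)` summing to 1.
#' @export
f1_genotype_distribution <- function(parent1, parent2) {
  d1 <- state_to_dosage(parent1)
  d2 <- state_to_dosage(parent2)
  if (is.na(d1) || is.na(d2)) {
    abort("F1 distribution undefined for a MISSING parent genotype")
  }
  # d = number of derived alleles = number of derived gametes out of 2
  q_hom_alt <- d1 * d2                 # quarters
  q_hom_ref <- (2L - d1) * (2L - d2)
  q_het <- 4L - q_hom_alt - q_hom_ref
  c(HOM_REF = q_hom_ref, HET = q_het, HOM_ALT = q_hom_alt) / 4
}

#' Probability that a donor masks an exposed deleterious allele
#'
#' For a recipient homozygous for the deleterious allele, the probability
#' that the F1 offspring is heterozygous (the allele is masked): donor
#' homozygous reference gives 1, donor heterozygous 1/2, donor homozygous
#' derived 0.
#'
#' @param donor_gt Donor genotype (dosage or state), vectorised.
#' @param recipient_gt Must be `HOM_ALT` (dosage 2), the exposed state.
#' @return Numeric vector of masking probabilities.
#' @export
masking_probability <- function(donor_gt, recipient_gt = "HOM_ALT") {
  r <- state_to_dosage(recipient_gt)
  if (any(is.na(r)) || any(r != 2L)) {
    abort("masking_probability is defined for recipient HOM_ALT loci only")
  }
  d <- state_to_dosage(donor_gt)
  (2 - d) / 2
}

#' Probability that a donor unmasks a masked deleterious allele
#'
#' For a recipient heterozygous at a deleterious locus, the probability that
#' the F1 offspring is homozygous derived (the allele is exposed): donor
#' homozygous derived gives 1/2, donor heterozygous 1/4, donor homozygous
#' reference 0.
#'
#' @param donor_gt Donor genotype (dosage or state), vectorised.
#' @param recipient_gt Must be `HET` (dosage 1), the masked state.
#' @return Numeric vector of unmasking probabilities.
#' @export
unmasking_probability <- function(donor_gt, recipient_gt = "HET") {
  r <- state_to_dosage(recipient_gt)
  if (any(is.na(r)) || any(r != 1L)) {
    abort("unmasking_probability is defined for recipient HET loci only")
  }
  d <- state_to_dosage(donor_gt)
  d / 4
}

#' Novel functional mutations a donor would add (M_add)
#'
#' Counts class loci at which the donor genome carries at least one derived
#' allele that is absent from the recipient. In `mode = "population"` (the
#' headline definition) absence means derived allele count zero over all
#' called genomes of the recipient population; in `mode = "pairwise"`
#' novelty is judged against a single recipient genome. Loci missing in the
#' donor are skipped and counted; in population mode, loci with no called
#' recipient genotype are skipped as well.
#'
#' @param table An annotated [variant_table()].
#' @param donor_samples Donor sample id(s); one row is returned per donor x
#'   class.
#' @param recipient For `mode = "population"`, a population label resolved
#'   through `popmap`; for `mode = "pairwise"`, a recipient sample id.
#' @param popmap Popmap tibble (required in population mode).
#' @param classes Functional classes (default LoF, damaging missense,
#'   adaptive).
#' @param mode `"population"` (default) or `"pairwise"`.
#' @return A tibble: `donor`, `recipient`, `class`, `m_add`,
#'   `n_skipped_missing`.
#' @export
mutations_added <- function(table, donor_samples, recipient, popmap = NULL,
                            classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE"),
                            mode = c("population", "pairwise")) {
  stopifnot(inherits(table, "variant_table"))
  mode <- match.arg(mode)
  missing <- setdiff(donor_samples, table$samples)
  if (length(missing)) {
    abort(paste0("unknown donor sample(s): ", paste(missing, collapse = ", ")))
  }
  if (mode == "population") {
    if (is.null(popmap)) abort("population mode requires a popmap")
    rec_samples <- intersect(population_samples(popmap, recipient), table$samples)
    if (!length(rec_samples)) {
      abort(paste0("recipient population has no members in the table: ", recipient))
    }
  } else {
    if (!recipient %in% table$samples) {
      abort(paste0("unknown recipient sample: ", recipient))
    }
    rec_samples <- recipient
  }
  purrr::map_dfr(classes, function(cl) {
    g <- class_dosage(table, cl)
    gr <- g[, rec_samples, drop = FALSE]
    rec_called <- rowSums(!is.na(gr)) > 0L
    novel <- rowSums(gr, na.rm = TRUE) == 0L & rec_called
    gd <- g[, donor_samples, drop = FALSE]
    carries <- !is.na(gd) & gd >= 1L
    tibble(
      donor = donor_samples,
      recipient = recipient,
      class = cl,
      m_add = as.integer(colSums(carries & novel)),
      n_skipped_missing = as.integer(colSums(is.na(gd)) +
                                       sum(!rec_called) - colSums(is.na(gd) & !rec_called))
    )
  })
}

# Pairwise genotype-combination counts for one class: for donor set D and
# recipient set R, cross-tabulates (recipient state, donor state) over class
# loci via indicator cross-products. Returns a tibble of all |D| x |R| pairs.
pair_counts_matrix <- function(table, donor_samples, recipient_samples, class) {
  g <- class_dosage(table, class)
  ind <- function(x, k) {
    m <- !is.na(x) & x == k
    storage.mode(m) <- "numeric"
    m
  }
  gd <- g[, donor_samples, drop = FALSE]
  gr <- g[, recipient_samples, drop = FALSE]
  d0 <- ind(gd, 0L); d1 <- ind(gd, 1L); d2 <- ind(gd, 2L)
  r1 <- ind(gr, 1L); r2 <- ind(gr, 2L)
  called_d <- !is.na(gd); storage.mode(called_d) <- "numeric"
  called_r <- !is.na(gr); storage.mode(called_r) <- "numeric"

  xt <- function(a, b) as.integer(crossprod(a, b))  # donors x recipients, flattened
  nd <- length(donor_samples); nr <- length(recipient_samples)
  tibble(
    donor = rep(donor_samples, times = nr),
    recipient = rep(recipient_samples, each = nd),
    class = class,
    n_comparable = xt(called_d, called_r),
    masked_p1 = xt(d0, r2),
    masked_p05 = xt(d1, r2),
    masked_p0 = xt(d2, r2),
    unmasked_p05 = xt(d2, r1),
    unmasked_p025 = xt(d1, r1),
    unmasked_p0 = xt(d0, r1)
  ) |>
    mutate(
      p_mask = 1 * .data$masked_p1 + 0.5 * .data$masked_p05 -
        0.5 * .data$unmasked_p05 - 0.25 * .data$unmasked_p025,
      p_mask_per_locus = if_else(.data$n_comparable > 0L,
                                 .data$p_mask / .data$n_comparable, NA_real_)
    )
}

#' Masking profile of one donor-recipient genome pair
#'
#' Classifies every class locus by the (recipient, donor) genotype pair:
#' recipient homozygous-derived loci masked at probability 1 (donor
#' `HOM_REF`) or 0.5 (donor `HET`); recipient heterozygous loci unmasked at
#' probability 0.5 (donor `HOM_ALT`) or 0.25 (donor `HET`). Zero-probability
#' combinations are tallied for completeness. The masking potential is the
#' cumulative signed score
#' `P_mask = masked_p1 + 0.5 masked_p05 - 0.5 unmasked_p05 - 0.25 unmasked_p025`;
#' positive values mean net masking of exposed deleterious alleles in the
#' F1 generation. Loci missing in either genome are skipped
#' (`n_comparable` counts the rest). A per-comparable-locus normalised score
#' is emitted alongside (`NA` when no locus is comparable).
#'
#' @param table An annotated [variant_table()].
#' @param donor_sample,recipient_sample Sample ids.
#' @param classes Functional classes (default LoF, damaging missense,
#'   adaptive).
#' @return A tibble with one row per class: the four probability-bin counts,
#'   zero-probability tallies, `n_comparable`, `p_mask` and
#'   `p_mask_per_locus`.
#' @export
pair_masking_profile <- function(table, donor_sample, recipient_sample,
                                 classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE")) {
  stopifnot(inherits(table, "variant_table"))
  missing <- setdiff(c(donor_sample, recipient_sample), table$samples)
  if (length(missing)) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(classes, function(cl) {
    pair_counts_matrix(table, donor_sample, recipient_sample, cl)
  })
}

#' Donor-recipient population compatibility summary
#'
#' For each functional class, summarises (i) M_add per donor genome (mean
#' and SD over donors, novelty judged against the recipient population) and
#' its value relative to the number of class loci segregating in the
#' recipient population (as a percentage), and (ii) the masking/unmasking
#' bin counts and the masking potential P_mask (mean and SD over all donor x
#' recipient genome pairs).
#'
#' @param table An annotated [variant_table()].
#' @param popmap Popmap tibble.
#' @param donor_pop,recipient_pop Population labels; sample overlap between
#'   them is a fatal error.
#' @param classes Functional classes (default LoF, damaging missense,
#'   adaptive).
#' @return A `compatibility_result`: a tibble with one row per class and
#'   attributes `donor_pop`, `recipient_pop`, `pairs` (the per-pair tibble)
#'   and `m_add` (the per-donor tibble).
#' @export
population_compatibility <- function(table, popmap, donor_pop, recipient_pop,
                                     classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE")) {
  stopifnot(inherits(table, "variant_table"))
  donors <- intersect(population_samples(popmap, donor_pop), table$samples)
  recips <- intersect(population_samples(popmap, recipient_pop), table$samples)
  if (!length(donors)) abort(paste0("no donor samples in table for ", donor_pop))
  if (!length(recips)) abort(paste0("no recipient samples in table for ", recipient_pop))
  overlap <- intersect(donors, recips)
  if (length(overlap) && donor_pop != recipient_pop) {
    abort(paste0("sample(s) in both populations: ", paste(overlap, collapse = ", ")))
  }

  madd <- mutations_added(table, donors, recipient_pop, popmap,
                          classes = classes, mode = "population")
  pairs <- purrr::map_dfr(classes, function(cl) {
    pair_counts_matrix(table, donors, recips, cl)
  })

  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  seg <- purrr::map_int(classes, function(cl) {
    g <- class_dosage(table, cl)[, recips, drop = FALSE]
    sum(rowSums(g, na.rm = TRUE) >= 1L)
  })

  madd_sum <- madd |>
    group_by(class = .data$class) |>
    summarise(m_add_mean = mean(.data$m_add), m_add_sd = sd_or_na(.data$m_add),
              .groups = "drop")
  pair_sum <- pairs |>
    group_by(class = .data$class) |>
    summarise(
      n_pairs = n(),
      across(c("masked_p1", "masked_p05", "unmasked_p05", "unmasked_p025"),
             list(mean = mean, sd = sd_or_na)),
      p_mask_mean = mean(.data$p_mask),
      p_mask_sd = sd_or_na(.data$p_mask),
      p_mask_sum_per_donor = sum(.data$p_mask) / length(donors),
      p_mask_per_locus_mean = mean(.data$p_mask_per_locus, na.rm = TRUE),
      .groups = "drop"
    )

  out <- tibble(
    donor_pop = donor_pop, recipient_pop = recipient_pop,
    class = classes,
    n_donors = length(donors), n_recipients = length(recips),
    n_segregating_recipient = as.integer(seg)
  ) |>
    left_join(madd_sum, by = "class") |>
    left_join(pair_sum, by = "class") |>
    mutate(relative_m_add_pct = if_else(.data$n_segregating_recipient > 0L,
                                        100 * .data$m_add_mean / .data$n_segregating_recipient,
                                        NA_real_))
  structure(out,
            class = c("compatibility_result", class(out)),
            donor_pop = donor_pop, recipient_pop = recipient_pop,
            pairs = pairs, m_add = madd)
}

#' Per-pair and per-donor detail of a compatibility result
#'
#' @param x A `compatibility_result` from [population_compatibility()].
#' @param ... Unused.
#' @return `tidy()` returns the per donor x recipient pair tibble;
#'   `glance()` a one-row scenario summary.
#' @export
tidy.compatibility_result <- function(x, ...) attr(x, "pairs")

#' @rdname tidy.compatibility_result
#' @export
glance.compatibility_result <- function(x, ...) {
  tibble(
    donor_pop = attr(x, "donor_pop"),
    recipient_pop = attr(x, "recipient_pop"),
    n_donors = x$n_donors[1],
    n_recipients = x$n_recipients[1],
    classes = paste(x$class, collapse = ",")
  )
}

#' Net impact of each donor population across recipient scenarios
#'
#' Averages, per donor population and class, the mean M_add and the mean
#' count of deleterious mutations masked at probability 1 over the recipient
#' populations evaluated, and reports the ratio of deleterious (LoF +
#' damaging missense) to adaptive mean additions.
#'
#' @param results One or more `compatibility_result` objects (or a list of
#'   them, or a pre-bound tibble of their rows).
#' @return A list with `by_class` (tibble: donor_pop x class with across-
#'   recipient mean and SD of `m_add_mean` and `masked_p1_mean`) and
#'   `ratios` (tibble: donor_pop with `deleterious_to_adaptive_ratio`).
#' @export
net_impact_summary <- function(results) {
  if (inherits(results, "compatibility_result")) results <- list(results)
  tab <- if (is.data.frame(results)) as_tibble(results) else {
    purrr::map_dfr(results, as_tibble)
  }
  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  by_class <- tab |>
    group_by(.data$donor_pop, .data$class) |>
    summarise(
      n_recipient_pops = n(),
      m_add_sd = sd_or_na(.data$m_add_mean),
      m_add_mean = mean(.data$m_add_mean),
      masked_p1_sd = sd_or_na(.data$masked_p1_mean),
      masked_p1_mean = mean(.data$masked_p1_mean),
      .groups = "drop"
    )
  ratios <- by_class |>
    group_by(.data$donor_pop) |>
    summarise(
      deleterious_added = sum(.data$m_add_mean[.data$class %in%
                                                 c("LOF", "DAMAGING_MISSENSE")]),
      adaptive_added = sum(.data$m_add_mean[.data$class == "ADAPTIVE"]),
      deleterious_to_adaptive_ratio =
        if_else(.data$adaptive_added > 0,
                .data$deleterious_added / .data$adaptive_added, NA_real_),
      .groups = "drop"
    )
  list(by_class = by_class, ratios = ratios)
}
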