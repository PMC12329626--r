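test_that("F1 distributions match exact Mendelian crosses", {
  expect_equal(f1_genotype_distribution("HET", "HET"),
               c(HOM_REF = 0.25, HET = 0.5, HOM_ALT = 0.25))
  expect_equal(f1_genotype_distribution("HOM_REF", "HOM_ALT"),
               c(HOM_REF = 0, HET = 1, HOM_ALT = 0))
  expect_equal(f1_genotype_distribution("HOM_ALT", "HET"),
               c(HOM_REF = 0, HET = 0.5, HOM_ALT = 0.5))
  expect_error(f1_genotype_distribution("MISSING", "HET"), "MISSING")

  # exact rational arithmetic: probabilities are multiples of 1/4 summing to 1
  for (d1 in 0:2) for (d2 in 0:2) {
    p <- f1_genotype_distribution(d1, d2)
    expect_identical(sum(p), 1)
    expect_true(all(p * 4 == round(p * 4)))
  }
})

test_that("masking and unmasking probabilities equal the F1 enumeration on all 9 genotype pairs", {
  # the four probability bins of the compatibility framework
  expect_identical(masking_probability("HOM_REF"), 1)
  expect_identical(masking_probability("HET"), 0.5)
  expect_identical(masking_probability("HOM_ALT"), 0)
  expect_identical(unmasking_probability("HOM_ALT"), 0.5)
  expect_identical(unmasking_probability("HET"), 0.25)
  expect_identical(unmasking_probability("HOM_REF"), 0)

  for (d in 0:2) {
    expect_equal(masking_probability(d), f1_oracle(d, 2)[["HET"]])
    expect_equal(unmasking_probability(d), f1_oracle(d, 1)[["HOM_ALT"]])
    expect_equal(f1_genotype_distribution(d, 2)[["HET"]], f1_oracle(d, 2)[["HET"]])
    expect_equal(f1_genotype_distribution(d, 1)[["HOM_ALT"]],
                 f1_oracle(d, 1)[["HOM_ALT"]])
    # full distribution agreement for all parent pairs
    for (d2 in 0:2) expect_equal(f1_genotype_distribution(d, d2), f1_oracle(d, d2))
  }

  # contract: defined only for the exposed/masked recipient states
  expect_error(masking_probability("HET", recipient_gt = "HET"), "HOM_ALT")
  expect_error(unmasking_probability("HET", recipient_gt = "HOM_ALT"), "HET")
})

test_that("pair masking profiles match hand-evaluated probability sums", {
  # two loci: (recipient HOM_ALT, donor HOM_REF) and (recipient HET, donor HET)
  vt <- make_table(cbind(d = c(0L, 1L), r = c(2L, 1L)), class = "LOF")
  prof <- pair_masking_profile(vt, "d", "r", classes = "LOF")
  expect_equal(prof$masked_p1, 1L)
  expect_equal(prof$unmasked_p025, 1L)
  expect_equal(prof$p_mask, 1 - 0.25)

  # recipient carries nothing: empty sum
  vt2 <- make_table(cbind(d = c(1L, 2L), r = c(0L, 0L)), class = "LOF")
  prof2 <- pair_masking_profile(vt2, "d", "r", classes = "LOF")
  expect_equal(prof2$p_mask, 0)
  expect_equal(prof2$masked_p1 + prof2$masked_p05 +
                 prof2$unmasked_p05 + prof2$unmasked_p025, 0L)

  # self-cross: shared HOM_ALT loci fall in the zero-probability masking bin
  # and shared HETs unmask at 1/4, so a genome crossed with itself gives
  # P_mask = -0.25 h (h = heterozygous deleterious loci)
  set.seed(31)
  g <- sample(c(0L, 1L, 2L), 60, replace = TRUE)
  vt3 <- make_table(cbind(a = g, b = g), class = "LOF")
  prof3 <- pair_masking_profile(vt3, "a", "b", classes = "LOF")
  h <- sum(g == 1L); m <- sum(g == 2L)
  expect_equal(prof3$masked_p0, m)
  expect_equal(prof3$unmasked_p025, h)
  expect_equal(prof3$p_mask, -0.25 * h)

  # missing genotypes are skipped and counted
  vt4 <- make_table(cbind(d = c(NA, 0L, 1L), r = c(2L, NA, 1L)), class = "LOF")
  prof4 <- pair_masking_profile(vt4, "d", "r", classes = "LOF")
  expect_equal(prof4$n_comparable, 1L)
  expect_equal(prof4$p_mask, -0.25)
})

test_that("P_mask from bin counts equals the locus-by-locus signed-probability sum", {
  set.seed(32)
  for (rep in 1:5) {
    gd <- sample(c(0L, 1L, 2L, NA), 80, replace = TRUE)
    gr <- sample(c(0L, 1L, 2L, NA), 80, replace = TRUE)
    vt <- make_table(cbind(d = gd, r = gr), class = "DAMAGING_MISSENSE")
    prof <- pair_masking_profile(vt, "d", "r", classes = "DAMAGING_MISSENSE")
    ok <- !is.na(gd) & !is.na(gr)
    per_locus <- ifelse(gr[ok] == 2L, (2 - gd[ok]) / 2,
                        ifelse(gr[ok] == 1L, -gd[ok] / 4, 0))
    expect_identical(prof$p_mask, sum(per_locus))
  }
})

test_that("P_mask sign follows the recipient genotype composition", {
  set.seed(33)
  for (rep in 1:10) {
    gd <- sample(0:2, 40, replace = TRUE)
    # no recipient HETs -> only masking terms -> P_mask >= 0
    gr_hom <- sample(c(0L, 2L), 40, replace = TRUE)
    p1 <- pair_masking_profile(make_table(cbind(d = gd, r = gr_hom), class = "LOF"),
                               "d", "r", classes = "LOF")$p_mask
    expect_gte(p1, 0)
    # no recipient HOM_ALTs -> only unmasking terms -> P_mask <= 0
    gr_het <- sample(c(0L, 1L), 40, replace = TRUE)
    p2 <- pair_masking_profile(make_table(cbind(d = gd, r = gr_het), class = "LOF"),
                               "d", "r", classes = "LOF")$p_mask
    expect_lte(p2, 0)
  }
})

test_that("M_add counts donor alleles novel to the recipient population", {
  # donor HET at a locus absent from all recipients contributes 1
  g <- cbind(d1 = c(1L, 0L, 2L, 1L), d2 = c(0L, 0L, 1L, 0L),
             r1 = c(0L, 0L, 0L, 1L), r2 = c(0L, 0L, 0L, 0L))
  vt <- make_table(g, class = "LOF")
  pm <- make_popmap(colnames(g), c("D", "D", "R", "R"))
  out <- mutations_added(vt, c("d1", "d2"), "R", pm, classes = "LOF")
  expect_equal(out$m_add[out$donor == "d1"], 2L)  # loci 1 and 3
  expect_equal(out$m_add[out$donor == "d2"], 1L)  # locus 3

  # donor all HOM_REF adds nothing
  expect_equal(mutations_added(vt, "r2", "D", pm, classes = "LOF")$m_add, 0L)

  # pairwise mode judges novelty against a single genome
  pw <- mutations_added(vt, "d1", "r1", classes = "LOF", mode = "pairwise")
  expect_equal(pw$m_add, 2L)  # locus 4 carried by r1, so not novel pairwise

  # loci missing in the donor are skipped
  g2 <- cbind(d1 = c(NA, 1L), r1 = c(0L, 0L))
  vt2 <- make_table(g2, class = "LOF")
  pm2 <- make_popmap(c("d1", "r1"), c("D", "R"))
  out2 <- mutations_added(vt2, "d1", "R", pm2, classes = "LOF")
  expect_equal(out2$m_add, 1L)
  expect_equal(out2$n_skipped_missing, 1L)
})

test_that("population compatibility matches an exhaustive hand evaluation", {
  g <- cbind(
    d1 = c(0L, 1L, 2L, 0L, 1L, 0L, 2L, 1L),
    d2 = c(0L, 0L, 1L, 1L, 1L, 0L, 2L, 0L),
    r1 = c(2L, 2L, 0L, 1L, 0L, 0L, 2L, 0L),
    r2 = c(1L, 2L, 0L, 1L, 2L, 0L, 0L, NA)
  )
  vt <- make_table(g, class = "LOF")
  pm <- make_popmap(colnames(g), c("D", "D", "R", "R"))
  res <- population_compatibility(vt, pm, "D", "R", classes = "LOF")

  expect_equal(res$m_add_mean, 1.5)            # donors add 2 and 1
  expect_equal(res$m_add_sd, stats::sd(c(2, 1)))
  expect_equal(res$n_segregating_recipient, 5L)
  expect_equal(res$relative_m_add_pct, 100 * 1.5 / 5)

  pairs <- tidy(res)
  expect_equal(nrow(pairs), 4L)
  key <- paste(pairs$donor, pairs$recipient)
  expect_equal(pairs$p_mask[match(c("d1 r1", "d1 r2", "d2 r1", "d2 r2"), key)],
               c(1.5, 1.0, 1.75, 1.25))
  expect_equal(res$p_mask_mean, 1.375)
  expect_equal(res$p_mask_sd, stats::sd(c(1.5, 1.0, 1.75, 1.25)))
  expect_equal(res$masked_p1_mean, 1)
  expect_equal(res$masked_p05_mean, 1)
  expect_equal(res$unmasked_p025_mean, 0.5)
  expect_equal(res$unmasked_p05_mean, 0)
  expect_equal(pairs$n_comparable[match(c("d1 r1", "d1 r2"), key)], c(8L, 7L))

  # population summaries are invariant to swapping donors with identical genomes
  g_swap <- g[, c(2, 1, 3, 4)]
  colnames(g_swap) <- colnames(g)
  res_swap <- population_compatibility(make_table(g_swap, class = "LOF"),
                                       pm, "D", "R", classes = "LOF")
  expect_equal(res_swap$p_mask_mean, res$p_mask_mean)
  expect_equal(res_swap$m_add_mean, res$m_add_mean)

  # a sample assigned to both populations is fatal
  pm_overlap <- pm
  pm_overlap$sample[3] <- "d1"
  expect_error(population_compatibility(vt, pm_overlap, "D", "R", classes = "LOF"),
               "both populations")
})

test_that("self-augmentation adds no novel mutations", {
  set.seed(35)
  g <- matrix(sample(c(0L, 1L, 2L), 300, replace = TRUE), nrow = 30)
  vt <- make_table(g, class = "DAMAGING_MISSENSE")
  pm <- make_popmap(paste0("s", 1:10), rep("P", 10), roles = c(P = "DONOR"))
  res <- population_compatibility(vt, pm, "P", "P", classes = "DAMAGING_MISSENSE")
  expect_equal(res$m_add_mean, 0)
})

test_that("net impact summary averages across recipient populations", {
  set.seed(36)
  cfg <- scenario_config(
    populations = tibble::tibble(
      label = c("Don", "RecA", "RecB", "RecC"),
      role = c("DONOR", "RECIPIENT", "RECIPIENT", "RECIPIENT"),
      n = c(8L, 6L, 6L, 6L)
    ),
    classes = list(
      LOF = list(n_loci = 200L, freq = freq_fixed(0.05, 0.02)),
      DAMAGING_MISSENSE = list(n_loci = 1000L, freq = freq_fixed(0.05, 0.02)),
      ADAPTIVE = list(n_loci = 200L,
                      freq = freq_divergent(freq_fixed(0.25), 0))
    ),
    seed = 36L
  )
  coh <- simulate_cohort(cfg)
  results <- lapply(c("RecA", "RecB", "RecC"), function(r) {
    population_compatibility(coh$table, coh$popmap, "Don", r)
  })
  net <- net_impact_summary(results)
  expect_equal(nrow(net$by_class), 3L)
  expect_equal(unique(net$by_class$n_recipient_pops), 3L)
  # single scenario: summary equals that scenario's values, SD absent
  one <- net_impact_summary(results[[1]])
  expect_true(all(is.na(one$by_class$m_add_sd)))
  expect_equal(one$by_class$m_add_mean,
               results[[1]]$m_add_mean[match(one$by_class$class, results[[1]]$class)])

  # identical recipient frequency profiles: across-recipient SD is small
  # relative to the mean (sampling noise only)
  lof <- net$by_class[net$by_class$class == "LOF", ]
  expect_lt(lof$m_add_sd, 0.5 * lof$m_add_mean)

  # damaging-missense loci are 5x as numerous at the same frequencies, so
  # about 5x as many are added
  ratio <- net$by_class$m_add_mean[net$by_class$class == "DAMAGING_MISSENSE"] /
    net$by_class$m_add_mean[net$by_class$class == "LOF"]
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 6.5)
})
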