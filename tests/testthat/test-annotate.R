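ann_row <- function(pos, effect, gene = "g1", provean = NA_real_) {
  tibble::tibble(chrom = "chr1", pos = pos, alt = "T",
                 effect = effect, gene = gene, provean_score = provean)
}

test_that("effect classification maps terms and resolves conflicts by severity", {
  vt <- make_table(matrix(0L, 5, 2), class = "UNCLASSIFIED")
  ann <- dplyr::bind_rows(
    ann_row(1L, "stop_gained"),
    ann_row(2L, "synonymous_variant"),
    ann_row(3L, "missense_variant", provean = -1),
    ann_row(3L, "intron_variant"),       # second transcript: missense wins
    ann_row(4L, "intergenic_region", gene = NA)
  )
  expect_warning(out <- classify_effects(vt, ann), "multiple effect rows")
  expect_equal(out$loci$functional_class,
               c("LOF", "SILENT", "NEUTRAL_MISSENSE", "INTERGENIC", "UNCLASSIFIED"))

  # every splice/nonsense term in the LoF set maps to LOF
  for (term in lof_effect_terms()) {
    one <- classify_effects(make_table(matrix(0L, 1, 2), class = "UNCLASSIFIED"),
                            ann_row(1L, term))
    expect_equal(one$loci$functional_class, "LOF")
  }
})

test_that("PROVEAN boundary is strict at -2.5", {
  expect_equal(classify_missense(c(-3.0, -2.5, -2.5000001, -1.0, 0)),
               c("DAMAGING", "NEUTRAL", "DAMAGING", "NEUTRAL", "NEUTRAL"))
  expect_true(is.na(classify_missense(NaN)))
  expect_true(is.na(classify_missense(NA_real_)))

  # monotonicity: anything below a damaging score is damaging
  set.seed(3)
  s <- sort(stats::runif(100, -8, 2))
  cls <- classify_missense(s)
  first_neutral <- match("NEUTRAL", cls)
  expect_true(all(cls[seq_len(first_neutral - 1)] == "DAMAGING"))
  expect_true(all(cls[first_neutral:length(cls)] == "NEUTRAL"))
})

test_that("missense reclassification and the deleterious set compose", {
  vt <- make_table(matrix(0L, 15, 2), class = "UNCLASSIFIED")
  ann <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ann_row(.x, "stop_gained")),
    purrr::map_dfr(6:8, ~ann_row(.x, "missense_variant", provean = -4)),
    purrr::map_dfr(9:15, ~ann_row(.x, "missense_variant", provean = -1))
  )
  out <- classify_effects(vt, ann) |> classify_missense_sites()
  counts <- tag_deleterious(out)
  expect_equal(attr(counts, "n_deleterious"), 8L)
  expect_equal(sum(is_deleterious(out)), 8L)
  expect_equal(counts$n_loci[counts$functional_class == "DAMAGING_MISSENSE"], 3L)

  empty <- subset_variants(out, loci = integer(0))
  expect_equal(attr(tag_deleterious(empty), "n_deleterious"), 0L)
})

test_that("adaptive tagging requires non-synonymous effect and gene overlap", {
  gm <- tibble::tibble(gene = "adg", chrom = "chr1",
                       start = 1000L, end = 2000L, strand = "+")
  vt <- make_table(matrix(0L, 4, 2), class = "UNCLASSIFIED",
                   pos = c(1500L, 1600L, 999L, 2001L))
  ann <- dplyr::bind_rows(
    ann_row(1500L, "missense_variant", gene = "adg", provean = -1),
    ann_row(1600L, "synonymous_variant", gene = "adg"),
    ann_row(999L, "missense_variant", gene = "other", provean = -1),
    ann_row(2001L, "missense_variant", gene = "other", provean = -1)
  )
  out <- classify_effects(vt, ann) |>
    classify_missense_sites() |>
    tag_adaptive("adg", gm)
  # missense inside the listed gene is adaptive; silent inside is not;
  # missense 1 bp outside either boundary is not (1-based inclusive ends)
  expect_equal(out$loci$adaptive_flag, c(TRUE, FALSE, FALSE, FALSE))

  expect_warning(tag_adaptive(out, c("adg", "ghost"), gm), "ghost")

  # LoF in a listed gene is included only on request
  ann_lof <- ann_row(1500L, "stop_gained", gene = "adg")
  lofed <- classify_effects(make_table(matrix(0L, 1, 2), pos = 1500L), ann_lof)
  expect_false(tag_adaptive(lofed, "adg", gm)$loci$adaptive_flag)
  expect_true(tag_adaptive(lofed, "adg", gm, include_lof = TRUE)$loci$adaptive_flag)
})

test_that("gene-desert re-classing uses an inclusive distance threshold", {
  gm <- tibble::tibble(gene = "g1", chrom = "chr1",
                       start = 10000L, end = 12000L, strand = "+")
  pos <- c(
    12000L + 250000L,  # far beyond: desert
    12000L + 50000L,   # 50 kb: stays intergenic
    12000L + 100000L,  # exactly at the threshold: desert (inclusive)
    12000L + 99999L    # one base short: intergenic
  )
  vt <- make_table(matrix(0L, 4, 2), class = "INTERGENIC", pos = pos)
  out <- identify_gene_desert_sites(vt, gm, min_distance_bp = 100000L)
  expect_equal(out$loci$functional_class,
               c("GENE_DESERT", "INTERGENIC", "GENE_DESERT", "INTERGENIC"))

  # chromosome without gene models: all intergenic loci qualify, with warning
  vt2 <- make_table(matrix(0L, 2, 2), class = "INTERGENIC", chrom = "chr9")
  expect_warning(out2 <- identify_gene_desert_sites(vt2, gm), "chr9")
  expect_equal(out2$loci$functional_class, rep("GENE_DESERT", 2))
})

test_that("class partition is exhaustive after annotation", {
  cfg <- scenario_config(seed = 9L)
  cfg$classes <- lapply(cfg$classes, function(cl) {
    cl$n_loci <- max(20L, cl$n_loci %/% 50L); cl
  })
  coh <- simulate_cohort(scenario_config(cfg$populations, cfg$classes, seed = 9L))
  redone <- annotate_variants(coh$table, coh$ann, coh$gene_models,
                              coh$adaptive_genes)
  expect_true(all(redone$loci$functional_class %in%
                    setdiff(FUNCTIONAL_CLASSES, "UNCLASSIFIED")))
  got <- table(redone$loci$functional_class)
  truth_cls <- ifelse(coh$truth$class == "ADAPTIVE", "NEUTRAL_MISSENSE",
                      coh$truth$class)
  expect_equal(as.vector(got[names(table(truth_cls))]),
               as.vector(table(truth_cls)))
  expect_equal(sum(redone$loci$adaptive_flag), sum(coh$truth$class == "ADAPTIVE"))
  expect_equal(sum(got), nrow(redone$loci))
})

test_that("DoS follows its closed form and stays within [-1, 1]", {
  expect_equal(compute_dos(10, 10, 5, 5), 0)
  expect_equal(compute_dos(8, 2, 1, 9), 0.7)
  expect_equal(compute_dos(0, 5, 5, 0), -1)
  expect_warning(out <- compute_dos(0, 0, 1, 1), "undefined")
  expect_true(is.na(out))

  set.seed(4)
  dn <- rpois(50, 5); ds <- rpois(50, 5) + 1
  pn <- rpois(50, 5); ps <- rpois(50, 5) + 1
  vals <- compute_dos(dn, ds, pn, ps)
  expect_true(all(vals >= -1 & vals <= 1))
  balanced <- dn / (dn + ds) == pn / (pn + ps)
  expect_true(all(vals[balanced] == 0))
})
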