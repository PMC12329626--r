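#' Allele-frequency models for the synthetic generator
#'
#' Three per-class frequency models:
#' * `freq_fixed()` — one frequency per role (or per population via a named
#'   vector in `by_population`), constant across loci. Used for the
#'   deleterious classes (rare in large donors, drifted upward in small
#'   recipients) and for non-divergent adaptive variants at intermediate
#'   frequency.
#' * `freq_bn()` — island-model differentiation: a per-locus ancestral
#'   frequency drawn uniformly on `ancestral_range`, then per-population
#'   frequencies from the Balding-Nichols Beta distribution with parameter
#'   `fst`. Used for neutral gene-desert loci.
#' * `freq_divergent()` — a base model for most loci, with a fraction of
#'   loci under divergent selection given independent per-population
#'   frequencies drawn uniformly on `divergent_range`.
#'
#' @param donor,recipient,other Frequencies by role for `freq_fixed()`
#'   (`other` defaults to the donor value).
#' @param by_population Optional named frequency vector keyed by population
#'   label, overriding the role-based values.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param ancestral_range Range of the per-locus ancestral frequency.
#' @param base A frequency model for the non-divergent loci.
#' @param divergent_fraction Fraction of loci under divergent selection.
#' @param divergent_range Per-population frequency range for divergent loci.
#' @return A frequency-model specification list.
#' @name freq_models
NULL

#' @rdname freq_models
#' @export
freq_fixed <- function(donor, recipient = donor, other = donor,
                       by_population = NULL) {
  stopifnot(all(c(donor, recipient, other) >= 0),
            all(c(donor, recipient, other) <= 1))
  list(model = "fixed", donor = donor, recipient = recipient, other = other,
       by_population = by_population)
}

#' @rdname freq_models
#' @export
freq_bn <- function(fst = 0.1, ancestral_range = c(0.1, 0.9)) {
  stopifnot(fst > 0, fst < 1, length(ancestral_range) == 2)
  list(model = "balding_nichols", fst = fst, ancestral_range = ancestral_range)
}

#' @rdname freq_models
#' @export
freq_divergent <- function(base, divergent_fraction = 0.1,
                           divergent_range = c(0.05, 0.95)) {
  stopifnot(divergent_fraction >= 0, divergent_fraction <= 1)
  list(model = "divergent", base = base,
       divergent_fraction = divergent_fraction,
       divergent_range = divergent_range)
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Defines a multi-population diploid cohort with class-specific allele-
#' frequency spectra and known truth. The defaults mirror a two-donor,
#' three-recipient design: deleterious alleles rare in the donor
#' populations and drifted upward in the smaller recipients, damaging
#' missense loci five times as numerous as LoF loci, adaptive variants at
#' intermediate frequency, and an abundant neutral gene-desert class under
#' Balding-Nichols differentiation.
#'
#' @param populations Tibble with columns `label`, `role` (`DONOR` /
#'   `RECIPIENT` / `OTHER`) and `n` (diploid individuals).
#' @param classes Named list of class specifications; each element is
#'   `list(n_loci =, freq = <frequency model>)`. Valid names: the
#'   functional classes plus `ADAPTIVE`.
#' @param seed Integer random seed; recorded in all outputs.
#' @param fail_qd_frac Fraction of loci written with a failing `QD` INFO
#'   statistic (planted hard-filter violations; default 0).
#' @param missing_frac Fraction of genotypes set missing at random
#'   (default 0).
#' @param desert_distance Distance (bp) that generated gene-desert loci keep
#'   from every gene model (default 100000, matching the annotation
#'   default).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(populations = default_populations(),
                            classes = default_classes(),
                            seed = 1L,
                            fail_qd_frac = 0,
                            missing_frac = 0,
                            desert_distance = 100000L) {
  populations <- as_tibble(populations)
  stopifnot(all(c("label", "role", "n") %in% names(populations)))
  populations$role <- toupper(populations$role)
  stopifnot(all(populations$role %in% c("DONOR", "RECIPIENT", "OTHER")),
            all(populations$n >= 1))
  if (anyDuplicated(populations$label)) abort("duplicate population labels")
  bad <- setdiff(names(classes), c(FUNCTIONAL_CLASSES, "ADAPTIVE"))
  if (length(bad)) abort(paste0("unknown class(es): ", paste(bad, collapse = ", ")))
  for (nm in names(classes)) {
    if (is.null(classes[[nm]]$n_loci) || classes[[nm]]$n_loci < 1) {
      abort(paste0("class ", nm, " needs n_loci >= 1"))
    }
    m <- classes[[nm]]$freq$model
    if (is.null(m)) abort(paste0("class ", nm, " needs a frequency model"))
    if (m %in% c("balding_nichols", "divergent") && nrow(populations) < 2) {
      abort("differentiation models need at least 2 populations")
    }
  }
  structure(
    list(populations = populations, classes = classes, seed = as.integer(seed),
         fail_qd_frac = fail_qd_frac, missing_frac = missing_frac,
         desert_distance = as.integer(desert_distance)),
    class = "scenario_config"
  )
}

#' @rdname scenario_config
#' @export
default_populations <- function() {
  tibble(
    label = c("D1", "D2", "R1", "R2", "R3"),
    role = c("DONOR", "DONOR", "RECIPIENT", "RECIPIENT", "RECIPIENT"),
    n = c(15L, 15L, 10L, 10L, 10L)
  )
}

#' @rdname scenario_config
#' @export
default_classes <- function() {
  list(
    LOF = list(n_loci = 300L, freq = freq_fixed(donor = 0.03, recipient = 0.10)),
    DAMAGING_MISSENSE = list(n_loci = 1500L, freq = freq_fixed(donor = 0.03, recipient = 0.10)),
    NEUTRAL_MISSENSE = list(n_loci = 1000L, freq = freq_fixed(donor = 0.20, recipient = 0.20)),
    SILENT = list(n_loci = 1500L, freq = freq_fixed(donor = 0.25, recipient = 0.25)),
    INTRON = list(n_loci = 1000L, freq = freq_fixed(donor = 0.25, recipient = 0.25)),
    INTERGENIC = list(n_loci = 500L, freq = freq_fixed(donor = 0.25, recipient = 0.25)),
    GENE_DESERT = list(n_loci = 5000L, freq = freq_bn(fst = 0.1)),
    ADAPTIVE = list(n_loci = 300L,
                    freq = freq_divergent(base = freq_fixed(donor = 0.25, recipient = 0.25),
                                          divergent_fraction = 0))
  )
}

# Draw the per-locus x per-population truth frequency matrix for one class.
draw_class_freqs <- function(spec, populations) {
  npop <- nrow(populations)
  L <- spec$n_loci
  fm <- spec$freq
  divergent <- rep(FALSE, L)
  draw <- function(fm) {
    switch(fm$model,
      fixed = {
        by_role <- c(DONOR = fm$donor, RECIPIENT = fm$recipient, OTHER = fm$other)
        q <- by_role[populations$role]
        if (!is.null(fm$by_population)) {
          hit <- populations$label %in% names(fm$by_population)
          q[hit] <- fm$by_population[populations$label[hit]]
        }
        matrix(rep(q, each = L), nrow = L)
      },
      balding_nichols = {
        anc <- stats::runif(L, fm$ancestral_range[1], fm$ancestral_range[2])
        f <- fm$fst
        shape_scale <- (1 - f) / f
        vapply(seq_len(npop), function(j) {
          stats::rbeta(L, anc * shape_scale, (1 - anc) * shape_scale)
        }, numeric(L))
      },
      abort(paste0("unknown frequency model: ", fm$model))
    )
  }
  if (fm$model == "divergent") {
    Q <- draw(fm$base)
    n_div <- round(fm$divergent_fraction * L)
    if (n_div > 0) {
      idx <- sample.int(L, n_div)
      divergent[idx] <- TRUE
      Q[idx, ] <- matrix(
        stats::runif(n_div * npop, fm$divergent_range[1], fm$divergent_range[2]),
        nrow = n_div
      )
    }
  } else {
    Q <- draw(fm)
  }
  if (L == 1L) Q <- matrix(Q, nrow = 1L)
  list(freq = Q, divergent = divergent)
}

#' Simulate a multi-population diploid cohort with known truth
#'
#' Generates genotypes independently per locus and individual under
#' Hardy-Weinberg equilibrium at each population's true allele frequency,
#' lays out a genome (genes hosting the exonic and intronic loci, intergenic
#' loci in the gaps between genes, gene-desert loci beyond the configured
#' distance from every gene), and builds the matching annotation table
#' (effect terms and PROVEAN scores consistent with the class labels:
#' damaging missense scores drawn on [-10, -2.6], neutral missense on
#' [-2.4, 5]), adaptive-gene list and truth table. Runs are deterministic
#' under a fixed seed.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_cohort` list: `table` (truth-annotated
#'   [variant_table()]), `popmap`, `ann` (annotation tibble), `gene_models`,
#'   `adaptive_genes`, `truth` (per-locus class, per-population true
#'   frequency, divergent-selection and planted-QD-failure flags) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  pops <- config$populations
  npop <- nrow(pops)
  samples <- unlist(lapply(seq_len(npop), function(j) {
    sprintf("%s_%02d", pops$label[j], seq_len(pops$n[j]))
  }))
  sample_pop <- rep(pops$label, times = pops$n)
  popmap <- tibble(sample = samples, population = sample_pop,
                   role = rep(pops$role, times = pops$n))

  class_names <- names(config$classes)
  drawn <- lapply(config$classes, draw_class_freqs, populations = pops)

  # genotypes: per class, per population, HWE binomial draws
  geno_blocks <- lapply(seq_along(class_names), function(i) {
    Q <- drawn[[i]]$freq
    L <- nrow(Q)
    g <- matrix(NA_integer_, L, length(samples))
    for (j in seq_len(npop)) {
      cols <- which(sample_pop == pops$label[j])
      g[, cols] <- stats::rbinom(L * length(cols), 2L, rep(Q[, j], times = length(cols)))
    }
    g
  })
  geno <- do.call(rbind, geno_blocks)
  total_l <- nrow(geno)
  if (config$missing_frac > 0) {
    drop <- which(stats::runif(length(geno)) < config$missing_frac)
    geno[drop] <- NA_integer_
  }

  layout <- layout_genome(class_names, vapply(drawn, function(d) nrow(d$freq), 0L),
                          config$desert_distance)
  loci <- layout$loci
  truth_class <- loci$truth_class

  # INFO statistics from passing ranges; planted QD failures
  qd <- stats::runif(total_l, 5, 30)
  qd_fail <- rep(FALSE, total_l)
  if (config$fail_qd_frac > 0) {
    n_fail <- round(config$fail_qd_frac * total_l)
    idx <- sample.int(total_l, n_fail)
    qd[idx] <- stats::runif(n_fail, 0.1, 1.9)
    qd_fail[idx] <- TRUE
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total_l, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  provean <- rep(NA_real_, total_l)
  provean[truth_class == "DAMAGING_MISSENSE"] <-
    stats::runif(sum(truth_class == "DAMAGING_MISSENSE"), -10, -2.6)
  n_neut <- sum(truth_class %in% c("NEUTRAL_MISSENSE", "ADAPTIVE"))
  provean[truth_class %in% c("NEUTRAL_MISSENSE", "ADAPTIVE")] <-
    stats::runif(n_neut, -2.4, 5)

  effect <- dplyr::case_when(
    truth_class == "LOF" ~ "stop_gained",
    truth_class %in% c("DAMAGING_MISSENSE", "NEUTRAL_MISSENSE", "ADAPTIVE") ~
      "missense_variant",
    truth_class == "SILENT" ~ "synonymous_variant",
    truth_class == "INTRON" ~ "intron_variant",
    TRUE ~ "intergenic_region"
  )

  loci_tbl <- tibble(
    chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt,
    QD = qd,
    MQ = stats::runif(total_l, 40, 60),
    MQRankSum = stats::runif(total_l, -1, 1),
    ReadPosRankSum = stats::runif(total_l, -1, 1),
    SOR = stats::runif(total_l, 0.5, 2),
    functional_class = if_else(truth_class == "ADAPTIVE",
                               "NEUTRAL_MISSENSE", truth_class),
    adaptive_flag = truth_class == "ADAPTIVE",
    provean_score = provean,
    gene = loci$gene
  )

  freq_all <- do.call(rbind, lapply(drawn, `[[`, "freq"))
  colnames(freq_all) <- paste0("freq_", pops$label)
  truth <- dplyr::bind_cols(
    tibble(
      chrom = loci$chrom, pos = loci$pos,
      class = truth_class,
      gene = loci$gene,
      divergent = unlist(lapply(drawn, `[[`, "divergent"), use.names = FALSE),
      qd_fail = qd_fail
    ),
    as_tibble(freq_all)
  )

  ann <- tibble(
    chrom = loci$chrom, pos = loci$pos, alt = alt,
    effect = effect, gene = loci$gene, provean_score = provean
  )

  structure(
    list(
      table = variant_table(loci_tbl, geno, samples),
      popmap = popmap,
      ann = ann,
      gene_models = layout$gene_models,
      adaptive_genes = layout$adaptive_genes,
      truth = truth,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

# Genome layout: genes of width 2 kb separated by 10 kb gaps on chr1; genic
# loci sit inside genes (adaptive loci in dedicated genes, so the adaptive
# gene list is a clean subset), intergenic loci in the gaps, and gene-desert
# loci start desert_distance past the last gene.
layout_genome <- function(class_names, n_loci, desert_distance) {
  gene_size <- 2000L
  gap <- 10000L
  loci_per_gene <- 20L

  genic <- c("LOF", "DAMAGING_MISSENSE", "NEUTRAL_MISSENSE", "SILENT", "INTRON")
  n_genic <- sum(n_loci[class_names %in% genic])
  n_adapt <- sum(n_loci[class_names == "ADAPTIVE"])
  n_genes_reg <- max(1L, ceiling(n_genic / loci_per_gene))
  n_genes_ad <- if (n_adapt > 0) max(1L, ceiling(n_adapt / loci_per_gene)) else 0L
  n_genes <- n_genes_reg + n_genes_ad

  gene_start <- gap + (seq_len(n_genes) - 1L) * (gene_size + gap) + 1L
  gene_models <- tibble(
    gene = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chr1",
    start = gene_start,
    end = gene_start + gene_size - 1L,
    strand = "+"
  )
  reg_genes <- gene_models[seq_len(n_genes_reg), , drop = FALSE]
  ad_genes <- if (n_genes_ad > 0) {
    gene_models[n_genes_reg + seq_len(n_genes_ad), , drop = FALSE]
  } else gene_models[0, ]

  place_in_genes <- function(n, genes) {
    if (n == 0L) return(tibble(pos = integer(), gene = character()))
    gene_idx <- rep(seq_len(nrow(genes)), length.out = n)
    # consecutive offsets within each gene keep positions unique
    off <- stats::ave(seq_len(n), gene_idx, FUN = seq_along)
    stopifnot(max(off) <= gene_size)
    tibble(pos = genes$start[gene_idx] + off - 1L, gene = genes$gene[gene_idx])
  }

  genic_placed <- place_in_genes(n_genic, reg_genes)
  adapt_placed <- place_in_genes(n_adapt, ad_genes)

  # intergenic loci in the middle of the gaps (well inside desert_distance)
  n_inter <- sum(n_loci[class_names == "INTERGENIC"])
  inter_pos <- if (n_inter > 0) {
    gap_mid <- gene_models$end + gap %/% 2L
    gap_idx <- rep(seq_len(n_genes), length.out = n_inter)
    off <- stats::ave(seq_len(n_inter), gap_idx, FUN = seq_along)
    stopifnot(max(off) <= 1000L)
    gap_mid[gap_idx] + off - 1L
  } else integer()

  n_desert <- sum(n_loci[class_names == "GENE_DESERT"])
  desert_start <- max(gene_models$end) + desert_distance
  desert_pos <- if (n_desert > 0) desert_start + (seq_len(n_desert) - 1L) * 10L else integer()

  # assemble in class order
  gi <- ai <- 1L
  out <- vector("list", length(class_names))
  genic_i <- 0L; inter_i <- 0L
  for (k in seq_along(class_names)) {
    cl <- class_names[k]
    L <- n_loci[k]
    if (cl %in% genic) {
      rows <- genic_placed[genic_i + seq_len(L), , drop = FALSE]
      genic_i <- genic_i + L
      out[[k]] <- tibble(chrom = "chr1", pos = rows$pos, gene = rows$gene,
                         truth_class = cl)
    } else if (cl == "ADAPTIVE") {
      rows <- adapt_placed[seq_len(L), , drop = FALSE]
      out[[k]] <- tibble(chrom = "chr1", pos = rows$pos, gene = rows$gene,
                         truth_class = cl)
    } else if (cl == "INTERGENIC") {
      pos <- inter_pos[inter_i + seq_len(L)]
      inter_i <- inter_i + L
      out[[k]] <- tibble(chrom = "chr1", pos = pos, gene = NA_character_,
                         truth_class = cl)
    } else if (cl == "GENE_DESERT") {
      out[[k]] <- tibble(chrom = "chr1", pos = desert_pos[seq_len(L)],
                         gene = NA_character_, truth_class = cl)
    } else {
      abort(paste0("no layout rule for class ", cl))
    }
  }
  loci <- dplyr::bind_rows(out)
  stopifnot(!anyDuplicated(loci$pos))
  list(loci = loci, gene_models = gene_models, adaptive_genes = ad_genes$gene)
}

#' Closed-form expectations for a simulated cohort
#'
#' Computes, from the truth frequencies alone, the Hardy-Weinberg
#' expectations of every downstream metric: per population and class the
#' expected masked load `E[L_mask] = sum_l 2 q (1 - q)` and realised load
#' `E[L_realised] = sum_l q^2`; per donor-recipient population pair and
#' class the expected novel mutations per donor genome
#' `E[M_add] = sum_l (1 - (1 - q_D)^2) (1 - q_R)^(2 n_R)` and the expected
#' masking potential per genome pair
#' `E[P_mask] = sum_l q_R^2 (1 - q_D) - (1 - q_R) q_R q_D`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @return A list of tibbles: `load` (population x class) and `pairs`
#'   (donor population x recipient population x class).
#' @export
closed_form_expectations <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  pops <- cohort$config$populations
  truth <- cohort$truth
  classes <- unique(truth$class)

  qmat <- as.matrix(truth[paste0("freq_", pops$label)])

  load <- purrr::map_dfr(classes, function(cl) {
    rows <- truth$class == cl
    purrr::map_dfr(seq_len(nrow(pops)), function(j) {
      q <- qmat[rows, j]
      tibble(population = pops$label[j], class = cl,
             e_l_mask = sum(2 * q * (1 - q)),
             e_l_realised = sum(q^2),
             e_carried = sum(2 * q * (1 - q)) + sum(q^2))
    })
  })

  donors <- which(pops$role == "DONOR")
  recips <- which(pops$role == "RECIPIENT")
  pairs <- purrr::map_dfr(classes, function(cl) {
    rows <- truth$class == cl
    purrr::map_dfr(donors, function(di) {
      purrr::map_dfr(recips, function(ri) {
        qd <- qmat[rows, di]
        qr <- qmat[rows, ri]
        n_r <- pops$n[ri]
        tibble(
          donor_pop = pops$label[di], recipient_pop = pops$label[ri],
          class = cl,
          e_m_add = sum((1 - (1 - qd)^2) * (1 - qr)^(2 * n_r)),
          e_p_mask = sum(qr^2 * (1 - qd) - (1 - qr) * qr * qd)
        )
      })
    })
  })
  list(load = load, pairs = pairs)
}

#' Write a simulated cohort to disk in the formats the tool consumes
#'
#' Emits an uncompressed VCF (GT fields plus the QD/MQ/MQRankSum/
#' ReadPosRankSum/SOR INFO statistics), the popmap TSV, the annotation TSV,
#' a BED file of gene models, the adaptive-gene list (one id per line) and
#' a JSON truth table carrying the seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    adaptive_genes = file.path(out_dir, "adaptive_genes.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_vcf(cohort$table, paths$vcf)
  readr::write_tsv(cohort$popmap, paths$popmap, col_names = FALSE)
  readr::write_tsv(cohort$ann, paths$annotation)
  bed <- cohort$gene_models |>
    mutate(start0 = .data$start - 1L, score = 0L) |>
    select("chrom", "start0", "end", "gene", "score", "strand")
  readr::write_tsv(bed, paths$genes, col_names = FALSE)
  writeLines(cohort$adaptive_genes, paths$adaptive_genes)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         populations = cohort$config$populations,
         truth = cohort$truth),
    paths$truth, digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' Write a variant table as an uncompressed VCF
#'
#' @param table A [variant_table()].
#' @param path Output `.vcf` path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  loci <- table$loci
  info_keys <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  have <- intersect(info_keys, names(loci))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", have, have),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  info <- if (length(have)) {
    parts <- lapply(have, function(k) sprintf("%s=%.6g", k, loci[[k]]))
    do.call(paste, c(parts, sep = ";"))
  } else rep(".", nrow(loci))
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[table$geno + 1L],
                   nrow = nrow(table$geno))
  gt_chr[is.na(gt_chr)] <- "./."
  body <- paste(
    loci$chrom, loci$pos, ".", loci$ref, loci$alt, ".", "PASS", info, "GT",
    apply(gt_chr, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
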