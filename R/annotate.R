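#' Effect terms treated as loss of function
#'
#' The default set covers nonsense and splice-disrupting consequences; it
#' can be extended per call.
#'
#' @return Character vector of SnpEff-style effect terms.
#' @export
lof_effect_terms <- function() {
  c("stop_gained", "stop_lost", "start_lost",
    "splice_acceptor_variant", "splice_donor_variant", "frameshift_variant")
}

#' Read a per-variant functional annotation table
#'
#' Expects a TSV with header columns `chrom`, `pos`, `alt`, `effect`,
#' `gene`, `provean_score` (effect terms as produced by SnpEff; PROVEAN
#' scores may be empty for non-missense rows).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble keyed by (chrom, pos, alt).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read annotation table: ", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           alt = readr::col_character(),
                           effect = readr::col_character(),
                           gene = readr::col_character(),
                           provean_score = readr::col_double()
                         ))
  need <- c("chrom", "pos", "alt", "effect")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    abort(paste0("annotation table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"gene" %in% names(ann)) ann$gene <- NA_character_
  if (!"provean_score" %in% names(ann)) ann$provean_score <- NA_real_
  ann
}

effect_severity <- function(effect, lof_terms) {
  dplyr::case_when(
    effect %in% lof_terms ~ 5L,
    effect == "missense_variant" ~ 4L,
    effect == "synonymous_variant" ~ 3L,
    effect == "intron_variant" ~ 2L,
    effect %in% c("intergenic_region", "intergenic_variant") ~ 1L,
    TRUE ~ 0L
  )
}

#' Assign functional classes from effect annotations
#'
#' Maps effect terms onto the locus classes: LoF terms to `LOF`, missense to
#' `NEUTRAL_MISSENSE` (pending PROVEAN reclassification via
#' [classify_missense_sites()]), synonymous to `SILENT`, intron/intergenic
#' terms to `INTRON`/`INTERGENIC`. Loci without a matching annotation row
#' stay `UNCLASSIFIED`. When a locus has several annotation rows (e.g., two
#' transcripts) the highest-severity term wins, with a warning.
#'
#' @param table A [variant_table()].
#' @param ann Annotation tibble from [read_annotation()].
#' @param lof_terms Effect terms counted as LoF ([lof_effect_terms()]).
#' @return The table with `functional_class`, `gene` and `provean_score`
#'   filled in.
#' @export
classify_effects <- function(table, ann, lof_terms = lof_effect_terms()) {
  stopifnot(inherits(table, "variant_table"))
  ann <- ann |>
    mutate(.sev = effect_severity(.data$effect, lof_terms))
  n_conflict <- ann |>
    count(.data$chrom, .data$pos, .data$alt) |>
    filter(.data$n > 1L) |>
    nrow()
  if (n_conflict > 0L) {
    warn(sprintf(
      "%d locus/alt key(s) have multiple effect rows; keeping highest severity",
      n_conflict
    ))
  }
  best <- ann |>
    arrange(dplyr::desc(.data$.sev)) |>
    distinct(.data$chrom, .data$pos, .data$alt, .keep_all = TRUE)

  loci <- table$loci |>
    select(-dplyr::any_of(c("effect", ".sev"))) |>
    left_join(best |> select("chrom", "pos", "alt", "effect", ".sev",
                             ann_gene = "gene", ann_provean = "provean_score"),
              by = c("chrom", "pos", "alt"))
  loci <- loci |>
    mutate(
      functional_class = dplyr::case_when(
        is.na(.data$effect) ~ "UNCLASSIFIED",
        .data$.sev == 5L ~ "LOF",
        .data$.sev == 4L ~ "NEUTRAL_MISSENSE",
        .data$.sev == 3L ~ "SILENT",
        .data$.sev == 2L ~ "INTRON",
        .data$.sev == 1L ~ "INTERGENIC",
        TRUE ~ "UNCLASSIFIED"
      ),
      gene = if_else(is.na(.data$ann_gene), .data$gene, .data$ann_gene),
      provean_score = if_else(is.na(.data$ann_provean), .data$provean_score,
                              .data$ann_provean)
    ) |>
    select(-".sev", -"effect", -"ann_gene", -"ann_provean")
  variant_table(loci, table$geno, table$samples)
}

#' Classify a missense variant by its PROVEAN score
#'
#' Strict threshold: a score below `threshold` (default -2.5) is
#' `DAMAGING`; a score at or above it is `NEUTRAL`. Non-finite scores give
#' `NA` (the locus stays outside the deleterious set).
#'
#' @param provean_score Numeric vector of PROVEAN scores.
#' @param threshold Decision boundary (default -2.5).
#' @return Character vector over `DAMAGING` / `NEUTRAL` / `NA`.
#' @export
classify_missense <- function(provean_score, threshold = -2.5) {
  out <- rep(NA_character_, length(provean_score))
  ok <- is.finite(provean_score)
  out[ok & provean_score < threshold] <- "DAMAGING"
  out[ok & provean_score >= threshold] <- "NEUTRAL"
  out
}

#' Reclassify missense loci using PROVEAN scores
#'
#' Missense loci (`NEUTRAL_MISSENSE` or `DAMAGING_MISSENSE`) are re-labelled
#' by [classify_missense()]; missense loci with a non-finite score keep the
#' neutral label and are counted.
#'
#' @param table A [variant_table()] after [classify_effects()].
#' @param threshold PROVEAN decision boundary (default -2.5).
#' @return The table with missense classes resolved.
#' @export
classify_missense_sites <- function(table, threshold = -2.5) {
  stopifnot(inherits(table, "variant_table"))
  loci <- table$loci
  is_mis <- loci$functional_class %in% c("NEUTRAL_MISSENSE", "DAMAGING_MISSENSE")
  cls <- classify_missense(loci$provean_score[is_mis], threshold)
  new <- if_else(is.na(cls), "NEUTRAL_MISSENSE",
                 if_else(cls == "DAMAGING", "DAMAGING_MISSENSE", "NEUTRAL_MISSENSE"))
  loci$functional_class[is_mis] <- new
  n_unscored <- sum(is.na(cls))
  out <- variant_table(loci, table$geno, table$samples)
  attr(out, "n_unscored_missense") <- n_unscored
  out
}

#' Summarise the deleterious variant set
#'
#' Deleterious = LoF plus damaging missense.
#'
#' @param table An annotated [variant_table()].
#' @return A tibble of per-class locus counts with a `deleterious` flag and
#'   the total deleterious count as attribute `"n_deleterious"`.
#' @export
tag_deleterious <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  counts <- table$loci |>
    count(.data$functional_class, name = "n_loci") |>
    mutate(deleterious = .data$functional_class %in% c("LOF", "DAMAGING_MISSENSE"))
  attr(counts, "n_deleterious") <- sum(counts$n_loci[counts$deleterious])
  counts
}

#' Loci in the deleterious set
#'
#' @param table An annotated [variant_table()].
#' @return Logical vector over loci: `TRUE` for LoF or damaging missense.
#' @export
is_deleterious <- function(table) {
  table$loci$functional_class %in% c("LOF", "DAMAGING_MISSENSE")
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input keeps `gene`-type features (1-based inclusive coordinates);
#' BED input is converted by \pkg{rtracklayer} to 1-based.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read gene models: ", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  gr <- if (ext == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    g <- rtracklayer::import(path, format = "GFF3")
    g[tolower(as.character(g$type)) == "gene"]
  }
  ids <- if (!is.null(gr$Name) && !all(is.na(gr$Name))) {
    as.character(gr$Name)
  } else if (!is.null(gr$name)) {
    as.character(gr$name)
  } else if (!is.null(gr$ID)) {
    as.character(gr$ID)
  } else if (!is.null(gr$gene_id)) {
    as.character(gr$gene_id)
  } else {
    paste0("gene", seq_along(gr))
  }
  tibble(
    gene = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

gene_models_granges <- function(gene_models) {
  stopifnot(all(gene_models$start <= gene_models$end))
  GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = gene_models$start, end = gene_models$end),
    gene = gene_models$gene
  )
}

loci_granges <- function(table) {
  GenomicRanges::GRanges(
    seqnames = table$loci$chrom,
    ranges = IRanges::IRanges(start = table$loci$pos, width = 1L)
  )
}

#' Flag adaptive variants inside positively selected genes
#'
#' Sets `adaptive_flag` for non-synonymous loci (missense classes; LoF too
#' when `include_lof = TRUE`) whose position falls within a listed gene's
#' interval (1-based inclusive).
#'
#' @param table An annotated [variant_table()].
#' @param adaptive_genes Character vector of gene ids under positive
#'   selection.
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @param include_lof Also flag LoF loci in listed genes (default `FALSE`:
#'   missense only).
#' @return The table with `adaptive_flag` set.
#' @export
tag_adaptive <- function(table, adaptive_genes, gene_models,
                         include_lof = FALSE) {
  stopifnot(inherits(table, "variant_table"))
  missing_models <- setdiff(adaptive_genes, gene_models$gene)
  if (length(missing_models)) {
    warn(paste0("adaptive gene(s) without a gene model, skipped: ",
                paste(missing_models, collapse = ", ")))
  }
  gm <- gene_models |> filter(.data$gene %in% adaptive_genes)
  loci <- table$loci
  loci$adaptive_flag <- FALSE
  if (nrow(gm)) {
    hits <- GenomicRanges::findOverlaps(loci_granges(table), gene_models_granges(gm))
    in_gene <- rep(FALSE, nrow(loci))
    in_gene[S4Vectors_queryHits(hits)] <- TRUE
    nonsyn_classes <- c("NEUTRAL_MISSENSE", "DAMAGING_MISSENSE",
                        if (include_lof) "LOF")
    loci$adaptive_flag <- in_gene & loci$functional_class %in% nonsyn_classes
  }
  variant_table(loci, table$geno, table$samples)
}

# thin indirection so the S4Vectors generic is resolved once
S4Vectors_queryHits <- function(hits) S4Vectors::queryHits(hits)

#' Re-class intergenic loci far from genes as gene-desert sites
#'
#' Intergenic loci whose distance to the nearest gene interval on the same
#' chromosome is at least `min_distance_bp` become `GENE_DESERT` — the
#' neutral reference set for the F_ST outlier screen. Distance is the
#' base-pair offset from the locus to the closest gene boundary (a locus
#' one base past a gene end is at distance 1); the boundary itself is
#' inclusive (distance exactly `min_distance_bp` qualifies).
#'
#' @param table An annotated [variant_table()].
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @param min_distance_bp Minimum distance to any gene (default 100000).
#' @return The table with qualifying loci re-classed `GENE_DESERT`.
#' @export
identify_gene_desert_sites <- function(table, gene_models,
                                       min_distance_bp = 100000L) {
  stopifnot(inherits(table, "variant_table"))
  loci <- table$loci
  inter <- which(loci$functional_class == "INTERGENIC")
  if (!length(inter)) return(table)
  lg <- loci_granges(table)[inter]
  gg <- gene_models_granges(gene_models)
  no_genes_chroms <- setdiff(unique(as.character(GenomicRanges::seqnames(lg))),
                             unique(gene_models$chrom))
  if (length(no_genes_chroms)) {
    warn(paste0("no gene models on chromosome(s) ",
                paste(no_genes_chroms, collapse = ", "),
                "; all intergenic loci there qualify as gene desert"))
  }
  # seqlevel mismatches are handled explicitly above, so the GenomeInfoDb
  # "no sequence levels in common" warning is redundant here
  d <- suppressWarnings(GenomicRanges::distanceToNearest(lg, gg))
  dist_bp <- rep(Inf, length(lg))  # chromosomes without genes: infinitely far
  qh <- S4Vectors_queryHits(d)
  # IRanges gap distance is 0 for adjacent ranges; +1 converts to bp offset
  dist_bp[qh] <- S4Vectors::mcols(d)$distance + 1L
  ov <- suppressWarnings(GenomicRanges::countOverlaps(lg, gg)) > 0L
  dist_bp[ov] <- 0
  desert <- dist_bp >= min_distance_bp
  loci$functional_class[inter[desert]] <- "GENE_DESERT"
  variant_table(loci, table$geno, table$samples)
}

#' Full annotation pipeline
#'
#' Chains [classify_effects()], [classify_missense_sites()],
#' [tag_adaptive()] and [identify_gene_desert_sites()].
#'
#' @param table A [variant_table()].
#' @param ann Annotation tibble.
#' @param gene_models Gene-model tibble (optional; required for adaptive
#'   tagging and gene-desert identification).
#' @param adaptive_genes Character vector of gene ids (optional).
#' @param provean_threshold PROVEAN decision boundary (default -2.5).
#' @param desert_distance Gene-desert distance in bp (default 100000).
#' @param include_lof_adaptive Count LoF loci in adaptive genes as adaptive
#'   (default `FALSE`).
#' @return An annotated [variant_table()].
#' @export
annotate_variants <- function(table, ann, gene_models = NULL,
                              adaptive_genes = NULL,
                              provean_threshold = -2.5,
                              desert_distance = 100000L,
                              include_lof_adaptive = FALSE) {
  out <- classify_effects(table, ann)
  out <- classify_missense_sites(out, provean_threshold)
  if (!is.null(gene_models) && !is.null(adaptive_genes)) {
    out <- tag_adaptive(out, adaptive_genes, gene_models,
                        include_lof = include_lof_adaptive)
  }
  if (!is.null(gene_models)) {
    out <- identify_gene_desert_sites(out, gene_models, desert_distance)
  }
  out
}

#' Direction of Selection statistic
#'
#' `DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)` from divergent (D) and polymorphic (P)
#' nonsynonymous/synonymous counts. Positive values indicate adaptive
#' protein evolution; the statistic lies in `[-1, 1]`.
#'
#' @param dn,ds Divergent nonsynonymous / synonymous counts.
#' @param pn,ps Polymorphic nonsynonymous / synonymous counts.
#' @return Numeric vector of DoS values; `NA` with a warning where a
#'   denominator is zero.
#' @export
compute_dos <- function(dn, ds, pn, ps) {
  stopifnot(all(c(dn, ds, pn, ps) >= 0, na.rm = TRUE))
  denom_d <- dn + ds
  denom_p <- pn + ps
  bad <- denom_d == 0 | denom_p == 0
  if (any(bad, na.rm = TRUE)) {
    warn("DoS undefined where Dn+Ds or Pn+Ps is zero; returning NA")
  }
  out <- dn / denom_d - pn / denom_p
  out[bad] <- NA_real_
  out
}
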