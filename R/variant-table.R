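#' @importFrom rlang .data `%||%` abort warn
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join bind_rows n across count distinct pull rename if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Functional classes a locus can carry after annotation. ADAPTIVE is an
# orthogonal flag (adaptive_flag), not a member of this partition.
FUNCTIONAL_CLASSES <- c(
  "LOF", "DAMAGING_MISSENSE", "NEUTRAL_MISSENSE", "SILENT",
  "INTRON", "INTERGENIC", "GENE_DESERT", "UNCLASSIFIED"
)

GENOTYPE_STATES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

#' Build a variant table
#'
#' A `variant_table` holds the loci-by-samples diploid genotype matrix of a
#' biallelic SNP cohort together with per-locus annotations. Genotypes are
#' stored as derived-allele dosage: 0 (homozygous reference), 1
#' (heterozygous), 2 (homozygous derived), `NA` (missing or half-called).
#' The ALT allele is treated as the derived allele throughout; see
#' [read_vcf()] for optional ancestral-allele polarisation.
#'
#' @param loci Tibble with one row per locus. Must contain `chrom`, `pos`,
#'   `ref`, `alt`; annotation columns (`functional_class`, `adaptive_flag`,
#'   `provean_score`, `gene`, INFO statistics) are added if absent.
#' @param geno Integer matrix, `nrow(loci)` x `length(samples)`, values in
#'   `c(0L, 1L, 2L, NA)`.
#' @param samples Character vector of sample identifiers (column names).
#'
#' @return An object of class `variant_table`: a list with elements `loci`
#'   (tibble), `samples` (character) and `geno` (integer matrix).
#' @export
variant_table <- function(loci, geno, samples = colnames(geno)) {
  loci <- as_tibble(loci)
  stopifnot(is.matrix(geno))
  if (is.null(samples)) abort("`samples` must be supplied or geno must have colnames")
  samples <- as.character(samples)
  storage.mode(geno) <- "integer"
  if (nrow(loci) != nrow(geno)) {
    abort(sprintf("loci (%d rows) and geno (%d rows) disagree", nrow(loci), nrow(geno)))
  }
  if (length(samples) != ncol(geno)) {
    abort("length(samples) must equal ncol(geno)")
  }
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(loci))
  if (length(miss)) abort(paste0("loci is missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(loci[c("chrom", "pos")])) abort("duplicate (chrom, pos) loci")
  if (nrow(loci) && any(loci$pos < 1L)) abort("pos must be >= 1")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  if (!"functional_class" %in% names(loci)) loci$functional_class <- "UNCLASSIFIED"
  if (!"adaptive_flag" %in% names(loci)) loci$adaptive_flag <- FALSE
  if (!"provean_score" %in% names(loci)) loci$provean_score <- NA_real_
  if (!"gene" %in% names(loci)) loci$gene <- NA_character_
  colnames(geno) <- samples
  structure(
    list(loci = loci, samples = samples, geno = geno),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "<variant_table> %d biallelic loci x %d samples\n",
    nrow(x$loci), length(x$samples)
  ))
  cls <- table(factor(x$loci$functional_class, levels = FUNCTIONAL_CLASSES))
  cls <- cls[cls > 0]
  if (length(cls)) {
    cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  }
  if (any(x$loci$adaptive_flag)) {
    cat("  adaptive-flagged loci:", sum(x$loci$adaptive_flag), "\n")
  }
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$loci), length(x$samples))

#' Number of loci in a variant table
#' @param table A [variant_table()].
#' @return Integer count of loci.
#' @export
n_loci <- function(table) nrow(table$loci)

#' Subset a variant table by locus and/or sample
#'
#' @param table A [variant_table()].
#' @param loci Logical or integer index over loci (default: keep all).
#' @param samples Character vector of sample ids, or index (default: all).
#' @return A `variant_table` restricted to the selection.
#' @export
subset_variants <- function(table, loci = NULL, samples = NULL) {
  stopifnot(inherits(table, "variant_table"))
  li <- loci %||% seq_len(nrow(table$loci))
  if (is.character(samples)) {
    miss <- setdiff(samples, table$samples)
    if (length(miss)) {
      abort(paste0("samples not present: ", paste(miss, collapse = ", ")))
    }
  }
  si <- samples %||% table$samples
  variant_table(table$loci[li, , drop = FALSE],
                table$geno[li, si, drop = FALSE])
}

#' Genotype dosage matrix of a class subset
#'
#' Selects loci of a functional class (or the adaptive set) and returns the
#' dosage matrix. Class `"ADAPTIVE"` selects `adaptive_flag` loci; any other
#' value matches `functional_class`.
#'
#' @param table A [variant_table()].
#' @param class One of the functional classes or `"ADAPTIVE"`.
#' @return Integer dosage matrix (loci of that class x samples).
#' @export
class_dosage <- function(table, class) {
  stopifnot(inherits(table, "variant_table"))
  table$geno[class_index(table, class), , drop = FALSE]
}

class_index <- function(table, class) {
  if (identical(class, "ADAPTIVE")) {
    which(table$loci$adaptive_flag)
  } else {
    which(table$loci$functional_class == class)
  }
}

#' Convert dosages to genotype state labels
#'
#' @param dosage Integer vector of dosages (0/1/2/NA).
#' @return Character vector over `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`.
#' @export
genotype_state <- function(dosage) {
  out <- rep("MISSING", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "HOM_REF"
  out[!is.na(dosage) & dosage == 1L] <- "HET"
  out[!is.na(dosage) & dosage == 2L] <- "HOM_ALT"
  out
}

state_to_dosage <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(!is.na(x) & (x < 0L | x > 2L))) abort("dosage must be 0, 1 or 2")
    return(x)
  }
  m <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L, MISSING = NA_integer_)
  if (!all(x %in% names(m))) abort("unknown genotype state")
  unname(m[x])
}

#' Tidy a variant table into long format
#'
#' One row per locus x sample with the dosage and state; locus annotation
#' columns are carried along.
#'
#' @param x A [variant_table()].
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `dosage`, `state`
#'   plus locus annotations.
#' @export
tidy.variant_table <- function(x, ...) {
  long <- tibble(
    locus = rep(seq_len(nrow(x$loci)), times = length(x$samples)),
    sample = rep(x$samples, each = nrow(x$loci)),
    dosage = as.integer(x$geno)
  )
  long$state <- genotype_state(long$dosage)
  dplyr::bind_cols(x$loci[long$locus, , drop = FALSE], long[-1]) |>
    select("chrom", "pos", "ref", "alt", "sample", "dosage", "state",
           dplyr::everything())
}

#' One-row summary of a variant table
#'
#' @param x A [variant_table()].
#' @param ... Unused.
#' @return A tibble with locus/sample counts, missing-genotype fraction and
#'   per-class locus counts.
#' @export
glance.variant_table <- function(x, ...) {
  cls <- table(factor(x$loci$functional_class, levels = FUNCTIONAL_CLASSES))
  out <- tibble(
    n_loci = nrow(x$loci),
    n_samples = length(x$samples),
    missing_frac = if (length(x$geno)) mean(is.na(x$geno)) else 0,
    n_adaptive = sum(x$loci$adaptive_flag)
  )
  dplyr::bind_cols(out, as_tibble(as.list(setNames(as.integer(cls), paste0("n_", tolower(names(cls)))))))
}

#' Per-locus allele summaries for a sample subset
#'
#' @param table A [variant_table()].
#' @param samples Sample ids (default all).
#' @return A tibble with per-locus counts over the chosen samples: called
#'   genotypes (`n_called`), missing genotypes (`n_missing`), derived allele
#'   count (`ac`) and derived allele frequency (`af`, `NA` when no calls).
#' @export
allele_summary <- function(table, samples = NULL) {
  g <- if (is.null(samples)) table$geno else {
    subset_variants(table, samples = samples)$geno
  }
  called <- !is.na(g)
  ac <- rowSums(g, na.rm = TRUE)
  nc <- rowSums(called)
  tibble(
    chrom = table$loci$chrom, pos = table$loci$pos,
    n_called = as.integer(nc), n_missing = as.integer(ncol(g) - nc),
    ac = as.integer(ac),
    af = if_else(nc > 0L, ac / (2 * nc), NA_real_)
  )
}
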