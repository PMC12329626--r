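#' Read a multi-sample VCF into a variant table
#'
#' Ingests a VCF 4.x file (plain or bgzipped) via \pkg{vcfR}, keeping only
#' biallelic SNP records. Multiallelic and non-SNP records are dropped and
#' counted in the ingest report. Diploid GT fields are mapped to derived-
#' allele dosage; half-called or missing genotypes become `NA`.
#'
#' The INFO statistics used by the GATK-style hard filters (`QD`, `MQ`,
#' `MQRankSum`, `ReadPosRankSum`, `SOR`) are extracted as numeric locus
#' columns when present. With `polarize = TRUE`, loci whose `AA` INFO key
#' equals the ALT allele are flipped (dosage `2 - d`) so dosage always counts
#' the derived allele.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param samples Optional character vector restricting the sample set;
#'   unknown names are a fatal error.
#' @param polarize Use the `AA` (ancestral allele) INFO key to polarise
#'   dosage (default `FALSE`: ALT is assumed derived).
#' @return A [variant_table()]. The ingest report (records in, excluded
#'   multiallelic / non-SNP counts, records out) is attached as attribute
#'   `"ingest"` and available via [ingest_report()].
#' @export
read_vcf <- function(path, samples = NULL, polarize = FALSE) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF ", path, ": ", conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) abort("VCF contains no variant records")

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & !is.na(alt) & alt %in% c("A", "C", "G", "T") &
    ref %in% c("A", "C", "G", "T")
  non_snp <- !multi & !snp
  keep <- which(snp)

  gt_all <- vcfR::extract.gt(v, element = "GT")
  if (is.null(colnames(gt_all))) abort("VCF has no sample genotype columns")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt_all))
    if (length(missing)) {
      abort(paste0("samples not in VCF: ", paste(missing, collapse = ", ")))
    }
    gt_all <- gt_all[, samples, drop = FALSE]
  }
  gt <- gt_all[keep, , drop = FALSE]

  geno <- gt_to_dosage(gt)

  info_keys <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  info <- lapply(info_keys, function(k) {
    val <- extract_info_field(fix$INFO[keep], k)
    suppressWarnings(as.numeric(val))
  })
  names(info) <- info_keys

  loci <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep]
  )
  for (k in info_keys) loci[[k]] <- info[[k]]

  if (isTRUE(polarize)) {
    aa <- extract_info_field(fix$INFO[keep], "AA")
    flip <- !is.na(aa) & aa == loci$alt
    if (any(flip)) {
      geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
      tmp <- loci$ref[flip]
      loci$ref[flip] <- loci$alt[flip]
      loci$alt[flip] <- tmp
    }
  }

  out <- variant_table(loci, geno, colnames(gt))
  attr(out, "ingest") <- tibble(
    records_in = n_in,
    excluded_multiallelic = sum(multi),
    excluded_non_snp = sum(non_snp),
    records_out = length(keep)
  )
  out
}

#' Ingest report of a variant table read from VCF
#'
#' @param table A [variant_table()] produced by [read_vcf()].
#' @return The ingest-report tibble, or `NULL` if the table was built in
#'   memory.
#' @export
ingest_report <- function(table) attr(table, "ingest")

# "0/0" -> 0, "0/1"/"1|0" -> 1, "1/1" -> 2, anything containing "." -> NA.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  core <- substr(gt, 1L, 3L)
  sep_norm <- chartr("|", "/", core)
  d[sep_norm %in% c("0/0")] <- 0L
  d[sep_norm %in% c("0/1", "1/0")] <- 1L
  d[sep_norm %in% c("1/1")] <- 2L
  d
}

extract_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)
  out
}

#' Read a population map
#'
#' Parses a tab-separated population map with columns sample, population,
#' role (an optional header row is tolerated). Roles must be `DONOR`,
#' `RECIPIENT` or `OTHER` (case-insensitive).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample`, `population`, `role`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read popmap: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("popmap has no assignments")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("popmap line %d does not have 3 tab-separated fields", bad[1]))
  }
  df <- tibble(
    sample = vapply(fields, `[[`, "", 1L),
    population = vapply(fields, `[[`, "", 2L),
    role = toupper(vapply(fields, `[[`, "", 3L)),
    line = seq_along(fields)
  )
  if (df$sample[1] %in% c("sample", "SAMPLE") && df$role[1] == "ROLE") {
    df <- df[-1, , drop = FALSE]
  }
  if (!nrow(df)) abort("popmap has no assignments")
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup)) {
    abort(paste0("duplicated sample id(s) in popmap: ", paste(unique(dup), collapse = ", ")))
  }
  bad_role <- df$role[!df$role %in% c("DONOR", "RECIPIENT", "OTHER")]
  if (length(bad_role)) {
    ln <- df$line[!df$role %in% c("DONOR", "RECIPIENT", "OTHER")][1]
    abort(sprintf("unknown role token '%s' at popmap line %d", bad_role[1], ln))
  }
  pm <- df[c("sample", "population", "role")]
  incons <- pm |>
    distinct(.data$population, .data$role) |>
    count(.data$population) |>
    filter(.data$n > 1L)
  if (nrow(incons)) {
    abort(paste0("population assigned more than one role: ",
                 paste(incons$population, collapse = ", ")))
  }
  pm
}

#' Samples belonging to a population
#'
#' @param popmap Popmap tibble from [read_popmap()].
#' @param population Population label(s).
#' @return Character vector of sample ids.
#' @export
population_samples <- function(popmap, population) {
  unknown <- setdiff(population, popmap$population)
  if (length(unknown)) {
    abort(paste0("unknown population(s): ", paste(unknown, collapse = ", ")))
  }
  popmap$sample[popmap$population %in% population]
}
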