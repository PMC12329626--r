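# In-code fixture builders shared across the suite.

# Variant table from a dosage matrix given as rows = loci.
make_table <- function(dosage, samples = NULL, class = "LOF",
                       adaptive = FALSE, chrom = "chr1", pos = NULL,
                       info = NULL) {
  dosage <- as.matrix(dosage)
  samples <- samples %||% colnames(dosage) %||% paste0("s", seq_len(ncol(dosage)))
  colnames(dosage) <- samples
  nl <- nrow(dosage)
  loci <- tibble::tibble(
    chrom = chrom,
    pos = pos %||% seq_len(nl),
    ref = "A", alt = "T",
    functional_class = rep_len(class, nl),
    adaptive_flag = rep_len(adaptive, nl)
  )
  if (!is.null(info)) for (k in names(info)) loci[[k]] <- info[[k]]
  variant_table(loci, dosage, samples)
}

make_popmap <- function(samples, populations, roles = NULL) {
  pops <- unique(populations)
  roles <- roles %||% stats::setNames(
    rep(c("DONOR", "RECIPIENT"), length.out = length(pops)), pops
  )
  tibble::tibble(
    sample = samples,
    population = populations,
    role = unname(roles[populations])
  )
}

write_popmap_file <- function(popmap, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(popmap$sample, popmap$population, popmap$role, sep = "\t"),
             path)
  path
}

# Minimal hand-written VCF with 4 biallelic SNPs and 1 triallelic record.
write_mixed_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ind1", "ind2", "ind3"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50\tPASS\tQD=25\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG\t50\tPASS\tQD=25\tGT\t./.\t0/1\t0/0",
    "chr1\t300\t.\tG\tA,C\t50\tPASS\tQD=25\tGT\t1/2\t0/1\t0/0",
    "chr1\t400\t.\tT\tC\t50\tPASS\tQD=25\tGT\t0|1\t1|1\t0/0",
    "chr1\t500\t.\tA\tG\t50\tPASS\tQD=25\tGT\t0/1\t0/.\t1/1"
  )
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x
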