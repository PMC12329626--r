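#' Per-individual mutation-load profiles
#'
#' For every sample and functional class, counts the heterozygous class
#' loci (`l_mask`, the masked load), the homozygous-derived loci
#' (`l_realised`, the realised or expressed load), their sum (`carried`,
#' loci with at least one derived allele), the allele-dosage sum and the
#' number of missing genotypes. Missing genotypes contribute to no count;
#' counts are absolute per genome.
#'
#' @param table An annotated [variant_table()].
#' @param samples Sample ids to profile (default: all).
#' @param classes Functional classes to profile; `"ADAPTIVE"` selects
#'   adaptive-flagged loci (default the three classes of interest:
#'   `LOF`, `DAMAGING_MISSENSE`, `ADAPTIVE`).
#' @return A tibble with one row per sample x class: `l_mask`,
#'   `l_realised`, `carried`, `dosage_sum`, `n_missing`, `n_loci`.
#' @export
load_profiles <- function(table, samples = NULL,
                          classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE")) {
  stopifnot(inherits(table, "variant_table"))
  samples <- samples %||% table$samples
  missing <- setdiff(samples, table$samples)
  if (length(missing)) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(classes, function(cl) {
    g <- class_dosage(table, cl)[, samples, drop = FALSE]
    tibble(
      sample = samples,
      class = cl,
      n_loci = nrow(g),
      l_mask = as.integer(colSums(g == 1L, na.rm = TRUE)),
      l_realised = as.integer(colSums(g == 2L, na.rm = TRUE)),
      dosage_sum = as.integer(colSums(g, na.rm = TRUE)),
      n_missing = as.integer(colSums(is.na(g)))
    ) |>
      mutate(carried = .data$l_mask + .data$l_realised) |>
      select("sample", "class", "l_mask", "l_realised", "carried",
             "dosage_sum", "n_missing", "n_loci")
  })
}

#' Load profile of a single individual
#'
#' @param table An annotated [variant_table()].
#' @param sample A sample id present in the table.
#' @param classes Functional classes (see [load_profiles()]).
#' @return A one-row-per-class tibble; see [load_profiles()].
#' @export
individual_load <- function(table, sample,
                            classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE")) {
  if (length(sample) != 1L) abort("`sample` must be a single id")
  load_profiles(table, samples = sample, classes = classes)
}

#' Population-level mutation load
#'
#' Mean and sample (n-1) standard deviation over member individuals of each
#' load component; the mean individual load estimates the population level
#' of mutation load. SD is reported as `NA` for single-member populations.
#'
#' @param table An annotated [variant_table()].
#' @param popmap Popmap tibble ([read_popmap()]).
#' @param classes Functional classes (see [load_profiles()]).
#' @param populations Populations to summarise (default: all in the popmap
#'   that have members in the table).
#' @return A tibble with one row per population x class: `n_ind` plus mean
#'   and SD of `l_mask`, `l_realised` and `carried`.
#' @export
population_load <- function(table, popmap,
                            classes = c("LOF", "DAMAGING_MISSENSE", "ADAPTIVE"),
                            populations = NULL) {
  stopifnot(inherits(table, "variant_table"))
  populations <- populations %||% unique(popmap$population)
  prof_all <- purrr::map_dfr(populations, function(p) {
    s <- intersect(population_samples(popmap, p), table$samples)
    if (!length(s)) abort(paste0("population has no members in the table: ", p))
    load_profiles(table, samples = s, classes = classes) |>
      mutate(population = p)
  })
  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  prof_all |>
    group_by(.data$population, .data$class) |>
    summarise(
      n_ind = n(),
      across(c("l_mask", "l_realised", "carried"),
             list(mean = mean, sd = sd_or_na)),
      .groups = "drop"
    )
}
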