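#' Default GATK-style hard-filter thresholds
#'
#' A locus fails when `QD < 2.0`, `MQ < 20.0`, `|MQRankSum| > 3.0`,
#' `|ReadPosRankSum| > 3.0` or `SOR > 5.0`.
#'
#' @return Named list of the five thresholds.
#' @export
hard_filter_thresholds <- function() {
  list(QD = 2.0, MQ = 20.0, MQRankSum = 3.0, ReadPosRankSum = 3.0, SOR = 5.0)
}

#' Apply hard quality filters to a variant table
#'
#' Removes loci failing any of the five site-quality rules. A locus lacking
#' an INFO statistic is not evaluated against that rule (counted in the
#' report). In the report, each removed locus is attributed to the first
#' rule that fires, in the order QD, MQ, MQRankSum, ReadPosRankSum, SOR, so
#' per-rule removals sum to the total; raw fire counts per rule are also
#' given.
#'
#' @param table A [variant_table()].
#' @param thresholds Named list overriding [hard_filter_thresholds()].
#' @return A list with elements `table` (filtered [variant_table()]) and
#'   `report` (a [filter_report] tibble).
#' @export
apply_hard_filters <- function(table, thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(table, "variant_table"))
  thr <- utils::modifyList(hard_filter_thresholds(), as.list(thresholds))
  loci <- table$loci
  nl <- nrow(loci)

  stat <- function(key) {
    if (!key %in% names(loci)) return(rep(NA_real_, nl))
    val <- loci[[key]]
    if (!is.numeric(val)) {
      warn(paste0("INFO field ", key, " is non-numeric; rule skipped where unparseable"))
      val <- suppressWarnings(as.numeric(val))
    }
    val
  }
  fires <- list(
    QD = stat("QD") < thr$QD,
    MQ = stat("MQ") < thr$MQ,
    MQRankSum = abs(stat("MQRankSum")) > thr$MQRankSum,
    ReadPosRankSum = abs(stat("ReadPosRankSum")) > thr$ReadPosRankSum,
    SOR = stat("SOR") > thr$SOR
  )
  not_eval <- vapply(fires, function(f) sum(is.na(f)), 0L)
  fired <- lapply(fires, function(f) !is.na(f) & f)
  any_fired <- Reduce(`|`, fired)

  # first-firing-rule attribution
  attribution <- rep(NA_character_, nl)
  for (rule in rev(names(fired))) attribution[fired[[rule]]] <- rule

  kept <- !any_fired
  report <- tibble(
    stage = "hard_filter",
    rule = names(fired),
    n_in = nl,
    n_fired = unname(vapply(fired, sum, 0L)),
    n_removed = unname(vapply(names(fired), function(r) sum(attribution == r, na.rm = TRUE), 0L)),
    n_not_evaluated = unname(as.integer(not_eval)),
    n_out = sum(kept)
  )
  list(table = subset_variants(table, loci = kept), report = report)
}

#' Apply site-level filters: missingness, singletons, private doubletons
#'
#' Removes loci with genotype missingness strictly above `max_missing`
#' (fraction of the table's samples), loci with derived allele count 1
#' (singletons) and private doubletons. A private doubleton is a locus with
#' derived allele count 2 where both copies sit in a single individual (a
#' homozygous singleton); with `private_scope = "population"` the two copies
#' need only share a population (requires `popmap`).
#'
#' All three rules are per-locus predicates evaluated on the input table, so
#' the surviving set does not depend on rule order; report attribution
#' follows the order missingness, singleton, private doubleton.
#'
#' @param table A [variant_table()].
#' @param max_missing Maximum tolerated missing-genotype fraction
#'   (default 0.20; a fraction of exactly `max_missing` is kept).
#' @param drop_singletons,drop_private_doubletons Toggles for the allele-
#'   count rules (default `TRUE`).
#' @param private_scope `"individual"` (default) or `"population"`.
#' @param popmap Popmap tibble; required for `private_scope = "population"`.
#' @return A list with `table` and `report`, as [apply_hard_filters()].
#' @export
apply_site_filters <- function(table, max_missing = 0.20,
                               drop_singletons = TRUE,
                               drop_private_doubletons = TRUE,
                               private_scope = c("individual", "population"),
                               popmap = NULL) {
  stopifnot(inherits(table, "variant_table"))
  private_scope <- match.arg(private_scope)
  g <- table$geno
  nl <- nrow(g)
  ns <- ncol(g)

  if (nl == 0L) {
    report <- tibble(
      stage = "site_filter",
      rule = c("missingness", "singleton", "private_doubleton"),
      n_in = 0L, n_fired = 0L, n_removed = 0L, n_out = 0L
    )
    return(list(table = table, report = report))
  }

  miss_frac <- rowMeans(is.na(g))
  ac <- rowSums(g, na.rm = TRUE)

  f_miss <- miss_frac > max_missing
  f_single <- if (drop_singletons) ac == 1L else rep(FALSE, nl)
  f_double <- rep(FALSE, nl)
  if (drop_private_doubletons) {
    is_double <- ac == 2L
    if (private_scope == "individual") {
      # both copies in one individual <=> some sample is HOM_ALT
      f_double <- is_double & (rowSums(g == 2L, na.rm = TRUE) > 0L)
    } else {
      if (is.null(popmap)) abort("private_scope = 'population' requires a popmap")
      pops <- unique(popmap$population)
      per_pop_ac <- vapply(pops, function(p) {
        s <- intersect(population_samples(popmap, p), table$samples)
        if (!length(s)) return(rep(0, nl))
        rowSums(g[, s, drop = FALSE], na.rm = TRUE)
      }, numeric(nl))
      if (nl == 1L) per_pop_ac <- matrix(per_pop_ac, nrow = 1L)
      f_double <- is_double & apply(per_pop_ac, 1L, max) == 2
    }
  }

  fired <- list(missingness = f_miss, singleton = f_single,
                private_doubleton = f_double)
  attribution <- rep(NA_character_, nl)
  for (rule in rev(names(fired))) attribution[fired[[rule]]] <- rule
  kept <- !Reduce(`|`, fired)

  report <- tibble(
    stage = "site_filter",
    rule = names(fired),
    n_in = nl,
    n_fired = unname(vapply(fired, sum, 0L)),
    n_removed = unname(vapply(names(fired), function(r) sum(attribution == r, na.rm = TRUE), 0L)),
    n_out = sum(kept)
  )
  list(table = subset_variants(table, loci = kept), report = report)
}

#' Check the accounting identity of a filter report
#'
#' For every stage, sites in minus total removed must equal sites out.
#'
#' @param report A filter-report tibble.
#' @return `TRUE` invisibly; aborts if the identity is violated.
#' @export
check_filter_report <- function(report) {
  ok <- report |>
    group_by(.data$stage) |>
    summarise(ok = dplyr::first(.data$n_in) - sum(.data$n_removed) ==
                dplyr::first(.data$n_out), .groups = "drop")
  if (!all(ok$ok)) abort("filter report accounting identity violated")
  invisible(TRUE)
}
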