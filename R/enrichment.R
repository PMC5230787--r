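#' Summarise annotation features for one gene group
#'
#' Builds one row of the group-comparison table: counts (and percentages,
#' rounded half-up to integers) of distal-in-operon genes (denominator =
#' genes listed in the feature annotation), of genes with an intergenic
#' distance below `intergenic_threshold` (denominator = all genes in the
#' group; overlapping genes have negative distances and count as below the
#' threshold), leaderless counts at the strict and relaxed thresholds, and
#' the mean 5'-UTR length over genes with known UTRs (genes with two mapped
#' 5' ends contribute the mean of their lengths; leaderless calls use the
#' shorter end).
#'
#' @param records Tibble of gene feature records (columns
#'   `listed_in_annotation`, `operon_position`, `intergenic_distance`,
#'   `utr_length`, `utr_length_alt`).
#' @param group Label stored in the output.
#' @param config An [analysis_config()].
#' @return One-row tibble.
#' @export
summarize_group <- function(records, group = "all",
                            config = analysis_config()) {
  n_total <- nrow(records)
  if (n_total == 0) {
    return(tibble::tibble(
      group = group, n_total = 0L, n_listed = 0L, n_single_or_first = 0L,
      n_distal = 0L, pct_distal = NA_integer_, n_short_intergenic = 0L,
      pct_short_intergenic = NA_integer_, n_leaderless_strict = 0L,
      n_leaderless_relaxed = 0L, mean_utr_length = NA_real_))
  }
  listed <- records$listed_in_annotation %in% TRUE
  n_listed <- sum(listed)
  n_distal <- sum(listed & records$operon_position == "distal")
  n_sf <- sum(listed & records$operon_position %in% c("single", "first"))
  short <- is.finite(records$intergenic_distance) &
    records$intergenic_distance < config$intergenic_threshold
  n_short <- sum(short)

  alt <- if ("utr_length_alt" %in% names(records)) {
    records$utr_length_alt
  } else {
    rep(NA_real_, n_total)
  }
  utr_pair <- cbind(records$utr_length, alt)
  known <- rowSums(is.finite(utr_pair)) > 0
  gene_mean <- rowMeans(utr_pair, na.rm = TRUE)[known]
  gene_min <- suppressWarnings(apply(utr_pair, 1, min, na.rm = TRUE))[known]
  ll <- classify_leaderless(gene_min, config)

  pct <- function(count, denom) {
    if (denom == 0) NA_integer_ else as.integer(floor(100 * count / denom + 0.5))
  }
  tibble::tibble(
    group = group,
    n_total = n_total,
    n_listed = n_listed,
    n_single_or_first = n_sf,
    n_distal = n_distal,
    pct_distal = pct(n_distal, n_listed),
    n_short_intergenic = n_short,
    pct_short_intergenic = pct(n_short, n_total),
    n_leaderless_strict = sum(ll$leaderless_strict),
    n_leaderless_relaxed = sum(ll$leaderless_relaxed),
    mean_utr_length = if (any(known)) mean(gene_mean) else NA_real_
  )
}

#' Group-comparison feature table
#'
#' Applies [summarize_group()] to each sensitivity class present in the
#' records (using their `class` column, e.g. merged in from
#' [kev_analysis()] output).
#'
#' @param records Gene feature records with a `class` column.
#' @param groups Classes to summarise (default sensitive and resistant).
#' @param config An [analysis_config()].
#' @return Tibble with one row per group.
#' @export
summarize_groups <- function(records, groups = c("sensitive", "resistant"),
                             config = analysis_config()) {
  dplyr::bind_rows(lapply(groups, function(g) {
    summarize_group(records[records$class %in% g, , drop = FALSE], g, config)
  }))
}

#' Association between group membership and a binary feature
#'
#' Two-sided Fisher's exact test on a 2x2 contingency table, plus the sample
#' odds ratio (with 0.5 added to every cell when any cell is zero).
#'
#' @param table 2x2 matrix of non-negative integer counts, features in rows
#'   and groups in columns.
#' @return List with `odds_ratio`, `p_value`, `table`.
#' @export
#' @examples
#' association_test(matrix(c(12, 61, 46, 59), 2))
association_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  ct <- if (any(table == 0)) table + 0.5 else table
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p_value = p, table = table)
}

#' Feature-association tests between two groups
#'
#' Tests whether distal-in-operon position (among genes listed in the
#' annotation) and a short intergenic distance (among all genes) are
#' associated with group membership.
#'
#' @param records Gene feature records with a `class` column.
#' @param groups Two classes to contrast.
#' @param config An [analysis_config()].
#' @return Tibble with one row per feature: counts, odds ratio, p-value.
#' @export
enrichment_tests <- function(records, groups = c("sensitive", "resistant"),
                             config = analysis_config()) {
  stopifnot(length(groups) == 2L)
  s <- lapply(groups, function(g) {
    summarize_group(records[records$class %in% g, , drop = FALSE], g, config)
  })
  mk <- function(feature, yes, denom) {
    tab <- matrix(c(yes[1], denom[1] - yes[1],
                    yes[2], denom[2] - yes[2]), nrow = 2)
    at <- association_test(tab)
    tibble::tibble(
      feature = feature,
      group_1 = groups[1], yes_1 = yes[1], n_1 = denom[1],
      group_2 = groups[2], yes_2 = yes[2], n_2 = denom[2],
      odds_ratio = at$odds_ratio, p_value = at$p_value
    )
  }
  dplyr::bind_rows(
    mk("distal_in_operon",
       c(s[[1]]$n_distal, s[[2]]$n_distal),
       c(s[[1]]$n_listed, s[[2]]$n_listed)),
    mk(sprintf("intergenic_lt_%d", config$intergenic_threshold),
       c(s[[1]]$n_short_intergenic, s[[2]]$n_short_intergenic),
       c(s[[1]]$n_total, s[[2]]$n_total))
  )
}
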