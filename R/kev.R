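#' Translational efficiency of one replicate
#'
#' TE is the quotient of the polysomal (ribosome-bound) over the free mRNA
#' signal. Non-positive or missing inputs yield `NA`: the replicate is
#' recorded as missing, never as zero.
#'
#' @param polysomal_intensity,free_intensity Numeric vectors (recycled).
#' @return Numeric vector of TEs with `NA` where undefined.
#' @export
#' @examples
#' translational_efficiency(3.0, 1.5) # 2
translational_efficiency <- function(polysomal_intensity, free_intensity) {
  te <- polysomal_intensity / free_intensity
  bad <- !is.finite(polysomal_intensity) | !is.finite(free_intensity) |
    polysomal_intensity <= 0 | free_intensity <= 0
  te[bad] <- NA_real_
  te
}

#' Summarise replicate TEs for one gene in one condition
#'
#' Computes the mean, sample standard deviation and coefficient of variation
#' (sd/mean) of the retained replicate TEs. If the CV reaches
#' `cv_threshold` and at least four values are available, the single value
#' whose removal reduces the CV the most is excluded, provided it deviates
#' from the mean of the remaining values by more than `outlier_k` times
#' their standard deviation — a reproducible stand-in for the visual
#' outlier inspection the QC rule formalises. The rule is applied at most
#' once and never leaves fewer than two values.
#'
#' @param te_values Numeric vector of replicate TEs (`NA` = missing
#'   replicate). Names, if present, identify replicates in exclusion records.
#' @param config An [analysis_config()].
#' @return List with `te_values` (retained, named), `n_used`, `mean_te`,
#'   `sd_te`, `cv`, `excluded` (tibble: replicate, value, reason), `usable`,
#'   `high_cv`.
#' @export
#' @examples
#' summarize_condition(c(1.0, 1.1, 0.9, 10.0))
summarize_condition <- function(te_values, config = analysis_config()) {
  if (is.null(names(te_values))) {
    names(te_values) <- as.character(seq_along(te_values))
  }
  missing <- !is.finite(te_values) | te_values <= 0
  excluded <- tibble::tibble(
    replicate = names(te_values)[missing],
    value = unname(te_values[missing]),
    reason = rep("missing", sum(missing))
  )
  vals <- te_values[!missing]

  stat <- function(v) {
    m <- mean(v)
    s <- if (length(v) >= 2) stats::sd(v) else NA_real_
    list(mean = m, sd = s, cv = if (is.na(s)) NA_real_ else s / m)
  }

  if (length(vals) == 0) {
    return(list(te_values = vals, n_used = 0L, mean_te = NA_real_,
                sd_te = NA_real_, cv = NA_real_, excluded = excluded,
                usable = FALSE, high_cv = FALSE))
  }

  st <- stat(vals)
  if (!is.na(st$cv) && st$cv >= config$cv_threshold && length(vals) >= 4) {
    cv_wo <- vapply(seq_along(vals),
                    function(i) stat(vals[-i])$cv, numeric(1))
    i <- which.min(cv_wo)
    others <- vals[-i]
    if (abs(vals[i] - mean(others)) > config$outlier_k * stats::sd(others)) {
      excluded <- rbind(excluded, tibble::tibble(
        replicate = names(vals)[i], value = unname(vals[i]),
        reason = "outlier"))
      vals <- vals[-i]
      st <- stat(vals)
    }
  }

  list(te_values = vals,
       n_used = length(vals),
       mean_te = st$mean,
       sd_te = st$sd,
       cv = st$cv,
       excluded = excluded,
       usable = TRUE,
       high_cv = !is.na(st$cv) && st$cv >= config$cv_threshold)
}

#' Replicate filter
#'
#' A gene is analysed only if it yielded usable TEs in at least
#' `min_replicates` replicates in the untreated as well as the treated
#' culture (counted after outlier exclusion).
#'
#' @param summary_untreated,summary_treated Outputs of
#'   [summarize_condition()].
#' @param config An [analysis_config()].
#' @return `TRUE` if the gene passes.
#' @export
replicate_filter <- function(summary_untreated, summary_treated,
                             config = analysis_config()) {
  summary_untreated$n_used >= config$min_replicates &&
    summary_treated$n_used >= config$min_replicates
}

#' Compute normalized Kasugamycin effect values
#'
#' The raw per-gene ratio is the mean treated TE divided by the mean
#' untreated TE. Because two-channel intensities carry arbitrary global
#' scales, the log2 ratios are median-centred across all passing genes, so
#' that a KEV of 1 represents the average drug effect by construction; the
#' KEV is 2 to the centred value.
#'
#' @param gene_summaries Tibble with columns `gene_id`, `mean_te_untreated`,
#'   `mean_te_treated` (one row per passing gene).
#' @return The input with added columns `raw_log2_ratio`, `log2_kev`, `kev`.
#' @export
#' @examples
#' compute_kevs(tibble::tibble(gene_id = c("a", "b", "c"),
#'                             mean_te_untreated = c(1, 1, 1),
#'                             mean_te_treated = c(0.5, 1, 4)))
compute_kevs <- function(gene_summaries) {
  stopifnot(all(c("gene_id", "mean_te_untreated", "mean_te_treated") %in%
                  names(gene_summaries)))
  if (nrow(gene_summaries) == 0) stop("no genes passed the replicate filter",
                                      call. = FALSE)
  if (any(gene_summaries$mean_te_untreated <= 0 |
            gene_summaries$mean_te_treated <= 0)) {
    stop("mean TEs must be positive; exclude such genes upstream",
         call. = FALSE)
  }
  raw <- log2(gene_summaries$mean_te_treated /
                gene_summaries$mean_te_untreated)
  centred <- raw - stats::median(raw)
  gene_summaries$raw_log2_ratio <- raw
  gene_summaries$log2_kev <- centred
  gene_summaries$kev <- 2^centred
  gene_summaries
}

#' Classify a KEV
#'
#' Sensitive if the KEV is at or below `sensitive_max` (default 0.5, i.e. at
#' least twofold stronger inhibition than average), resistant at or above
#' `resistant_min` (default 2.0); otherwise average. Both boundaries are
#' inclusive. Non-finite values are classified "excluded".
#'
#' @param kev Numeric vector of KEVs.
#' @param config An [analysis_config()].
#' @return Character vector in {sensitive, average, resistant, excluded}.
#' @export
#' @examples
#' classify_kev(c(0.25, 1.44, 5.21))
classify_kev <- function(kev, config = analysis_config()) {
  out <- rep("excluded", length(kev))
  ok <- is.finite(kev) & kev > 0
  out[ok & kev <= config$sensitive_max] <- "sensitive"
  out[ok & kev >= config$resistant_min] <- "resistant"
  out[ok & kev > config$sensitive_max & kev < config$resistant_min] <-
    "average"
  out
}

#' Per-gene significance of the drug effect
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on the log2 TEs of
#' the retained replicates; TEs are ratios, so the log scale is the natural
#' one, and replicates are not paired across conditions.
#'
#' @param te_untreated,te_treated Numeric vectors of retained replicate TEs.
#' @return p-value in `[0, 1]`, or `NA` if fewer than two values in either
#'   condition or the data are constant.
#' @export
kev_test <- function(te_untreated, te_treated) {
  x <- log2(te_untreated[is.finite(te_untreated) & te_untreated > 0])
  y <- log2(te_treated[is.finite(te_treated) & te_treated > 0])
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Histogram of log2 KEVs
#'
#' Bins the log2 KEVs into bins of width `hist_binwidth` centred on integer
#' multiples of the bin width (so 0 sits at a bin centre and a symmetric
#' distribution yields a symmetric histogram).
#'
#' @param log2_kev Numeric vector of log2 KEVs (or a KEV results tibble with
#'   a `log2_kev` column).
#' @param config An [analysis_config()].
#' @return Tibble with `bin_mid`, `bin_left`, `bin_right`, `count`; counts
#'   sum to the number of finite inputs.
#' @export
kev_distribution <- function(log2_kev, config = analysis_config()) {
  if (is.data.frame(log2_kev)) log2_kev <- log2_kev$log2_kev
  x <- log2_kev[is.finite(log2_kev)]
  if (length(x) == 0) stop("no finite log2 KEVs to bin", call. = FALSE)
  bw <- config$hist_binwidth
  k <- floor(x / bw + 0.5)
  tab <- table(k)
  kk <- as.integer(names(tab))
  tibble::tibble(
    bin_mid = kk * bw,
    bin_left = kk * bw - bw / 2,
    bin_right = kk * bw + bw / 2,
    count = as.integer(tab)
  )
}

#' Full KEV analysis of a measurement table
#'
#' Runs the complete translatome stage: per-replicate TEs, per-condition
#' summaries with CV-triggered outlier exclusion, the
#' at-least-`min_replicates`-per-condition filter, median-centred KEVs,
#' classification and per-gene Welch tests. Every input gene appears exactly
#' once in the result with either a class or an exclusion reason.
#'
#' @param measurements Tibble with columns gene_id, condition
#'   ("untreated"/"treated"), fraction ("free"/"polysomal"), replicate,
#'   intensity (see [read_measurements()]).
#' @param config An [analysis_config()].
#' @return Tibble with one row per gene: replicate counts, means, sds, CVs,
#'   exclusion records, `kev`, `log2_kev`, `class`, `p_value`, `pass` and
#'   `disposition`; list columns `te_untreated`/`te_treated` hold the
#'   retained replicate TEs.
#' @export
kev_analysis <- function(measurements, config = analysis_config()) {
  check_measurements(measurements)

  wide <- tidyr::pivot_wider(measurements,
                             id_cols = c("gene_id", "condition", "replicate"),
                             names_from = "fraction",
                             values_from = "intensity")
  if (!all(c("free", "polysomal") %in% names(wide))) {
    wide$free <- wide$free %||% NA_real_
    wide$polysomal <- wide$polysomal %||% NA_real_
  }
  wide$te <- translational_efficiency(wide$polysomal, wide$free)

  summaries <- lapply(split(wide, wide$gene_id), function(g) {
    out <- list()
    for (cond in c("untreated", "treated")) {
      gc <- g[g$condition == cond, ]
      te <- stats::setNames(gc$te, as.character(gc$replicate))
      out[[cond]] <- summarize_condition(te, config)
    }
    out
  })

  gene_id <- names(summaries)
  fmt_excl <- function(s) {
    e <- s$excluded
    if (nrow(e) == 0) NA_character_ else
      paste(sprintf("%s:%s", e$replicate, e$reason), collapse = ",")
  }
  res <- tibble::tibble(
    gene_id = gene_id,
    n_untreated = vapply(summaries, function(s) s$untreated$n_used,
                         integer(1)),
    n_treated = vapply(summaries, function(s) s$treated$n_used, integer(1)),
    mean_te_untreated = vapply(summaries, function(s) s$untreated$mean_te,
                               numeric(1)),
    mean_te_treated = vapply(summaries, function(s) s$treated$mean_te,
                             numeric(1)),
    sd_te_untreated = vapply(summaries, function(s) s$untreated$sd_te,
                             numeric(1)),
    sd_te_treated = vapply(summaries, function(s) s$treated$sd_te,
                           numeric(1)),
    cv_untreated = vapply(summaries, function(s) s$untreated$cv, numeric(1)),
    cv_treated = vapply(summaries, function(s) s$treated$cv, numeric(1)),
    exclusions_untreated = vapply(summaries, function(s)
      fmt_excl(s$untreated), character(1)),
    exclusions_treated = vapply(summaries, function(s) fmt_excl(s$treated),
                                character(1)),
    te_untreated = lapply(summaries, function(s) s$untreated$te_values),
    te_treated = lapply(summaries, function(s) s$treated$te_values)
  )
  res$pass <- res$n_untreated >= config$min_replicates &
    res$n_treated >= config$min_replicates &
    is.finite(res$mean_te_untreated) & res$mean_te_untreated > 0 &
    is.finite(res$mean_te_treated) & res$mean_te_treated > 0

  res$raw_log2_ratio <- NA_real_
  res$log2_kev <- NA_real_
  res$kev <- NA_real_
  if (any(res$pass)) {
    kevs <- compute_kevs(res[res$pass, c("gene_id", "mean_te_untreated",
                                         "mean_te_treated")])
    idx <- match(kevs$gene_id, res$gene_id)
    res$raw_log2_ratio[idx] <- kevs$raw_log2_ratio
    res$log2_kev[idx] <- kevs$log2_kev
    res$kev[idx] <- kevs$kev
  }
  res$class <- ifelse(res$pass, classify_kev(res$kev, config), "excluded")
  res$p_value <- NA_real_
  res$p_value[res$pass] <- mapply(kev_test,
                                  res$te_untreated[res$pass],
                                  res$te_treated[res$pass])
  res$disposition <- ifelse(res$pass, res$class, "insufficient_replicates")
  res
}

#' Write KEV results as TSV
#'
#' Mirrors a per-gene results table: one row per gene with per-replicate TEs
#' spread into columns (`te_untreated_1` ...), summary statistics, exclusion
#' records, KEV, log2 KEV, class and p-value. Decimal separator is ".".
#'
#' @param records Output of [kev_analysis()].
#' @param path Output file.
#' @param n_replicates Number of replicate columns to write per condition.
#' @return Invisibly, `path`.
#' @export
write_kev_results <- function(records, path, n_replicates = 5L) {
  spread_te <- function(values_list, cond) {
    cols <- lapply(seq_len(n_replicates), function(r) {
      vapply(values_list, function(v) {
        x <- v[as.character(r)]
        if (length(x) == 0 || is.na(names(x)[1])) NA_real_ else unname(x)
      }, numeric(1))
    })
    names(cols) <- sprintf("te_%s_%d", cond, seq_len(n_replicates))
    tibble::as_tibble(cols)
  }
  flat <- dplyr::bind_cols(
    records[, setdiff(names(records), c("te_untreated", "te_treated"))],
    spread_te(records$te_untreated, "untreated"),
    spread_te(records$te_treated, "treated")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
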