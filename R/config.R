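#' Analysis configuration
#'
#' Bundles every tunable constant of the translatome analysis. Defaults are
#' the values used throughout: a CV of 60% triggers outlier inspection, KEVs
#' of 0.5 or lower are sensitive and 2.0 or higher resistant, genes must
#' yield at least three of five replicates in both conditions, and start
#' regions span 40 nt upstream plus the first 40 nt of the ORF with the
#' start codon removed.
#'
#' @param cv_threshold Coefficient of variation (sd/mean of replicate TEs)
#'   at or above which the outlier rule is applied. Default 0.60.
#' @param sensitive_max KEV at or below which a transcript is called
#'   sensitive. Default 0.5.
#' @param resistant_min KEV at or above which a transcript is called
#'   resistant. Default 2.0.
#' @param min_replicates Minimum number of usable replicate TEs required in
#'   each condition. Default 3.
#' @param total_replicates Replicates per condition in the design. Default 5.
#' @param outlier_k A value is excluded as an outlier only if it deviates
#'   from the mean of the remaining values by more than `outlier_k` times
#'   their standard deviation. Default 2.
#' @param leaderless_strict,leaderless_relaxed 5'-UTR lengths (nt) at or
#'   below which a transcript is called leaderless under the strict / relaxed
#'   convention. Defaults 4 and 7.
#' @param intergenic_threshold Intergenic distance (nt) below which a gene is
#'   flagged as likely part of a polycistronic transcript. Default 15.
#' @param end_tolerance Two mapped 5' ends within this many nt are treated as
#'   the same transcription start. Default 3.
#' @param sd_consensus Shine-Dalgarno consensus (DNA alphabet). Default
#'   "TAAGGAGG".
#' @param sd_min_matches,sd_min_run A candidate site is SD-positive if it has
#'   at least `sd_min_matches` position-wise matches to the consensus or a
#'   consecutive run of at least `sd_min_run` matches. Defaults 5 and 4.
#' @param sd_scan_range Interval (nt) of allowed distances between a
#'   candidate site's 3' end and the A of the start codon when scanning a
#'   sequence. Default `c(2, 12)`.
#' @param window_up,window_down nt retrieved upstream of the start codon and
#'   from the start of the ORF (the 3-nt codon itself is removed, so the
#'   stored downstream part has `window_down - 3` nt). Defaults 40 and 40.
#' @param hist_binwidth Bin width (log2 units) of the KEV distribution
#'   histogram. Default 0.25.
#' @param logo_pseudocount Count added to each base per logo column and to
#'   the pooled background counts. Default 0.5.
#'
#' @return A list of class `ksg_analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$sensitive_max
analysis_config <- function(cv_threshold = 0.60,
                            sensitive_max = 0.5,
                            resistant_min = 2.0,
                            min_replicates = 3L,
                            total_replicates = 5L,
                            outlier_k = 2.0,
                            leaderless_strict = 4L,
                            leaderless_relaxed = 7L,
                            intergenic_threshold = 15L,
                            end_tolerance = 3L,
                            sd_consensus = "TAAGGAGG",
                            sd_min_matches = 5L,
                            sd_min_run = 4L,
                            sd_scan_range = c(2L, 12L),
                            window_up = 40L,
                            window_down = 40L,
                            hist_binwidth = 0.25,
                            logo_pseudocount = 0.5) {
  cfg <- list(
    cv_threshold = cv_threshold,
    sensitive_max = sensitive_max,
    resistant_min = resistant_min,
    min_replicates = as.integer(min_replicates),
    total_replicates = as.integer(total_replicates),
    outlier_k = outlier_k,
    leaderless_strict = as.integer(leaderless_strict),
    leaderless_relaxed = as.integer(leaderless_relaxed),
    intergenic_threshold = as.integer(intergenic_threshold),
    end_tolerance = as.integer(end_tolerance),
    sd_consensus = toupper(sd_consensus),
    sd_min_matches = as.integer(sd_min_matches),
    sd_min_run = as.integer(sd_min_run),
    sd_scan_range = as.integer(sd_scan_range),
    window_up = as.integer(window_up),
    window_down = as.integer(window_down),
    hist_binwidth = hist_binwidth,
    logo_pseudocount = logo_pseudocount
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "ksg_analysis_config")
}

validate_analysis_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) {
    stop("analysis config contains non-finite parameters", call. = FALSE)
  }
  if (!(cfg$sensitive_max > 0 && cfg$sensitive_max < 1 &&
        cfg$resistant_min > 1)) {
    stop("thresholds must satisfy 0 < sensitive_max < 1 < resistant_min",
         call. = FALSE)
  }
  if (cfg$min_replicates > cfg$total_replicates) {
    stop("min_replicates must not exceed total_replicates", call. = FALSE)
  }
  if (cfg$cv_threshold <= 0 || cfg$outlier_k <= 0) {
    stop("cv_threshold and outlier_k must be positive", call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", cfg$sd_consensus)) {
    stop("sd_consensus must be an unambiguous DNA string", call. = FALSE)
  }
  if (length(cfg$sd_scan_range) != 2L ||
      cfg$sd_scan_range[1] > cfg$sd_scan_range[2] ||
      cfg$sd_scan_range[1] < 0L) {
    stop("sd_scan_range must be a non-empty non-negative interval",
         call. = FALSE)
  }
  if (cfg$window_up < 1L || cfg$window_down < 4L) {
    stop("window_up must be >= 1 and window_down >= 4", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulation configuration
#'
#' Parameters of the synthetic translatome generator. Defaults reproduce the
#' design of the emulated experiment: 2801 analysable genes measured in five
#' biological replicates (two dye-swapped), sensitive and resistant
#' transcripts planted at the observed rates, start-region base composition
#' at the midpoints of the genome-wide fractions, SD motifs planted 3-7 nt
#' upstream of the start codon, and distal-in-operon fractions of 16% / 30% /
#' 44% for sensitive / average / resistant genes.
#'
#' @param n_genes Number of simulated genes. Default 2801.
#' @param n_replicates Biological replicates per condition. Default 5.
#' @param frac_sensitive,frac_resistant Fractions of genes planted with a
#'   sensitive / resistant effect. Defaults 102/2801 and 137/2801.
#' @param log2_kev_sd Standard deviation of the true log2 KEV of "average"
#'   genes (drawn from a normal distribution centred on 0). Default 0.35,
#'   so that with the default measurement noise the bulk of genes stays
#'   within the twofold thresholds and the planted classes dominate the
#'   tails.
#' @param effect_log2 Magnitude of the planted shift for sensitive
#'   (`-effect_log2`) and resistant (`+effect_log2`) genes. Default 2.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (log-normal) measurement noise applied to every intensity. Default 0.3.
#' @param missing_prob Per-measurement dropout probability. Default 0.18.
#' @param outlier_prob Probability that a measurement is a gross outlier.
#'   Default 0.01.
#' @param outlier_factor Factor by which an outlier measurement is multiplied
#'   or divided (direction random). Default 8.
#' @param seed RNG seed used by the generator functions. Default 1.
#' @param base_composition Named probabilities of A, C, G, T in start-region
#'   background sequence. Default `c(A=.29, C=.22, G=.23, T=.26)`.
#' @param sd_plant_prob Probability that a gene receives a planted SD site.
#'   Default 0.65.
#' @param sd_spacer_range Interval of planted SD-to-AUG distances (nt).
#'   Default `c(3, 7)`.
#' @param sd_plant_mismatches Integer vector of mismatch counts sampled for
#'   planted sites (0 = exact consensus). Default `0:2`.
#' @param utr_meanlog,utr_sdlog Log-normal parameters of simulated 5'-UTR
#'   lengths for leadered genes. Defaults `log(60)` and 0.8.
#' @param leaderless_frac Fraction of genes simulated leaderless (5'-UTR
#'   drawn uniformly from 0-7 nt). Default 0.017.
#' @param operon_config List with `frac_distal` (named fractions of distal
#'   genes per class), `frac_single` (fraction of non-distal genes that are
#'   single rather than first-in-operon), `distal_distance_mean` and
#'   `other_distance_meanlog`/`other_distance_sdlog` (intergenic-distance
#'   models for distal and non-distal genes).
#' @return A list of class `ksg_simulation_config`.
#' @export
simulation_config <- function(n_genes = 2801L,
                              n_replicates = 5L,
                              frac_sensitive = 102 / 2801,
                              frac_resistant = 137 / 2801,
                              log2_kev_sd = 0.35,
                              effect_log2 = 2.0,
                              noise_cv = 0.3,
                              missing_prob = 0.18,
                              outlier_prob = 0.01,
                              outlier_factor = 8,
                              seed = 1L,
                              base_composition = c(A = 0.29, C = 0.22,
                                                   G = 0.23, T = 0.26),
                              sd_plant_prob = 0.65,
                              sd_spacer_range = c(3L, 7L),
                              sd_plant_mismatches = 0:2,
                              utr_meanlog = log(60),
                              utr_sdlog = 0.8,
                              leaderless_frac = 0.017,
                              operon_config = list()) {
  op_default <- list(
    frac_distal = c(sensitive = 0.16, average = 0.30, resistant = 0.44),
    frac_single = 0.6,
    distal_distance_mean = 12,
    distal_distance_shift = -4L,
    other_distance_meanlog = log(120),
    other_distance_sdlog = 0.7
  )
  operon_config <- utils::modifyList(op_default, operon_config)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    frac_sensitive = frac_sensitive,
    frac_resistant = frac_resistant,
    log2_kev_sd = log2_kev_sd,
    effect_log2 = effect_log2,
    noise_cv = noise_cv,
    missing_prob = missing_prob,
    outlier_prob = outlier_prob,
    outlier_factor = outlier_factor,
    seed = as.integer(seed),
    base_composition = base_composition,
    sd_plant_prob = sd_plant_prob,
    sd_spacer_range = as.integer(sd_spacer_range),
    sd_plant_mismatches = as.integer(sd_plant_mismatches),
    utr_meanlog = utr_meanlog,
    utr_sdlog = utr_sdlog,
    leaderless_frac = leaderless_frac,
    operon_config = operon_config
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "ksg_simulation_config")
}

validate_simulation_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))], use.names = FALSE)
  num <- c(num, unlist(cfg$operon_config, use.names = FALSE))
  if (any(!is.finite(num))) {
    stop("simulation config contains non-finite parameters", call. = FALSE)
  }
  probs <- c(cfg$frac_sensitive, cfg$frac_resistant, cfg$missing_prob,
             cfg$outlier_prob, cfg$sd_plant_prob, cfg$leaderless_frac,
             cfg$base_composition, cfg$operon_config$frac_distal,
             cfg$operon_config$frac_single)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_sensitive + cfg$frac_resistant > 1) {
    stop("frac_sensitive + frac_resistant must not exceed 1", call. = FALSE)
  }
  if (abs(sum(cfg$base_composition) - 1) > 1e-8) {
    stop("base_composition must sum to 1", call. = FALSE)
  }
  if (!identical(sort(names(cfg$base_composition)), c("A", "C", "G", "T"))) {
    stop("base_composition must be named A, C, G, T", call. = FALSE)
  }
  if (cfg$n_replicates < 1L) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  if (length(cfg$sd_spacer_range) != 2L ||
      cfg$sd_spacer_range[1] > cfg$sd_spacer_range[2]) {
    stop("sd_spacer_range must be a non-empty interval", call. = FALSE)
  }
  if (cfg$noise_cv < 0 || cfg$outlier_factor <= 1) {
    stop("noise_cv must be >= 0 and outlier_factor > 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' The file may contain `analysis:` and `simulation:` sections whose entries
#' override the package defaults; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return List with elements `analysis` (`ksg_analysis_config`) and
#'   `simulation` (`ksg_simulation_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop("unknown ", section, " config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  a <- raw$analysis %||% list()
  s <- raw$simulation %||% list()
  check_keys(a, names(formals(analysis_config)), "analysis")
  check_keys(s, names(formals(simulation_config)), "simulation")
  if (!is.null(s$base_composition)) {
    s$base_composition <- unlist(s$base_composition)
  }
  list(analysis = do.call(analysis_config, a),
       simulation = do.call(simulation_config, s))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
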