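#' Simulate a polysome-fractionation translatome experiment
#'
#' Generates per-replicate fluorescence intensities for two RNA fractions
#' (free, polysomal) in untreated and antibiotic-treated cultures, together
#' with the ground truth needed for recovery tests.
#'
#' Per gene, a baseline abundance and a baseline translational efficiency
#' (polysomal/free ratio) are drawn log-normally; the treated-culture
#' efficiency is the untreated one multiplied by `2^true_log2_kev`. True
#' log2 KEVs are drawn normal(0, `log2_kev_sd`) for average genes and
#' shifted by `-effect_log2` / `+effect_log2` for the planted sensitive and
#' resistant classes, then median-centred across genes: a KEV is defined
#' relative to the average drug effect, so the centred value is the
#' recoverable estimand and ground-truth class labels are taken from it.
#' Every intensity carries multiplicative log-normal noise with coefficient
#' of variation `noise_cv`, is dropped with probability `missing_prob`, and
#' with probability `outlier_prob` is multiplied or divided (at random) by
#' `outlier_factor`. Dye-swap metadata is recorded for the last two
#' replicates but does not alter values.
#'
#' @param config A [simulation_config()].
#' @return List with `measurements` (tibble: gene_id, condition, fraction,
#'   replicate, dye, intensity) and `truth` (tibble: gene_id, planted_class,
#'   true_log2_kev, true_kev, class).
#' @export
#' @examples
#' sim <- simulate_translatome(simulation_config(n_genes = 50, seed = 7))
#' head(sim$measurements)
simulate_translatome <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  n_sens <- round(config$frac_sensitive * n)
  n_res <- round(config$frac_resistant * n)
  planted <- sample(rep(c("sensitive", "resistant", "average"),
                        c(n_sens, n_res, n - n_sens - n_res)))
  shift <- c(sensitive = -config$effect_log2, average = 0,
             resistant = config$effect_log2)[planted]
  raw <- shift + stats::rnorm(n, 0, config$log2_kev_sd)
  true_log2_kev <- raw - stats::median(raw)
  class <- classify_kev(2^true_log2_kev)

  base_abund <- stats::rlnorm(n, meanlog = log(1000), sdlog = 1)
  base_te <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

  grid <- tidyr::expand_grid(
    gene_id = gene_id,
    condition = c("untreated", "treated"),
    fraction = c("free", "polysomal"),
    replicate = seq_len(config$n_replicates)
  )
  idx <- match(grid$gene_id, gene_id)
  te <- base_te[idx] *
    ifelse(grid$condition == "treated", 2^true_log2_kev[idx], 1)
  # treated arrays carry their own global scale; KEVs must be invariant to it
  expected <- base_abund[idx] *
    ifelse(grid$fraction == "polysomal", te, 1) *
    ifelse(grid$condition == "treated", 1.2, 1)

  m <- nrow(grid)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- stats::rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    noise <- rep(1, m)
  }
  out_flag <- stats::runif(m) < config$outlier_prob
  out_dir <- sample(c(config$outlier_factor, 1 / config$outlier_factor),
                    m, replace = TRUE)
  intensity <- expected * noise * ifelse(out_flag, out_dir, 1)
  keep <- stats::runif(m) >= config$missing_prob

  dye <- ifelse(grid$replicate > config$n_replicates - 2L, "swap", "normal")
  measurements <- tibble::tibble(
    gene_id = grid$gene_id,
    condition = grid$condition,
    fraction = grid$fraction,
    replicate = as.integer(grid$replicate),
    dye = dye,
    intensity = intensity
  )[keep, ]

  truth <- tibble::tibble(
    gene_id = gene_id,
    planted_class = planted,
    true_log2_kev = true_log2_kev,
    true_kev = 2^true_log2_kev,
    class = class
  )
  list(measurements = measurements, truth = truth)
}

#' Simulate start-codon region sequences
#'
#' Draws, per gene, a 77-nt start-region window (40 nt upstream of the start
#' codon plus the first 37 nt of the ORF after the codon, matching the
#' window convention of [extract_start_windows()]) from the background base
#' composition. With probability `sd_plant_prob` a Shine-Dalgarno site — the
#' consensus TAAGGAGG carrying 0-2 random mismatches — is written into the
#' upstream part with its 3' end `spacer` nt upstream of the start codon,
#' where `spacer` is sampled from `sd_spacer_range`.
#'
#' @param config A [simulation_config()].
#' @param consensus SD consensus planted; default TAAGGAGG.
#' @return List with `windows` (tibble: gene_id, upstream_seq, downstream_seq)
#'   and `truth` (tibble: gene_id, sd_planted, sd_spacer, sd_mismatches,
#'   sd_site_seq).
#' @export
simulate_start_regions <- function(config = simulation_config(),
                                   consensus = "TAAGGAGG") {
  validate_simulation_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_genes
  up_len <- 40L
  down_len <- 37L
  gene_id <- sprintf("g%05d", seq_len(n))
  bases <- names(config$base_composition)
  draw <- function(len) {
    matrix(sample(bases, n * len, replace = TRUE,
                  prob = config$base_composition), nrow = n)
  }
  up <- draw(up_len)
  down <- draw(down_len)

  cons <- strsplit(consensus, "")[[1]]
  k <- length(cons)
  planted <- stats::runif(n) < config$sd_plant_prob
  spacer <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)
  site_seq <- rep(NA_character_, n)
  sp_lo <- config$sd_spacer_range[1]
  sp_hi <- config$sd_spacer_range[2]
  for (i in which(planted)) {
    d <- if (sp_lo == sp_hi) sp_lo else sample(sp_lo:sp_hi, 1L)
    m <- if (length(config$sd_plant_mismatches) == 1L) {
      config$sd_plant_mismatches
    } else {
      sample(config$sd_plant_mismatches, 1L)
    }
    site <- cons
    if (m > 0L) {
      pos <- sample(k, m)
      for (p in pos) site[p] <- sample(setdiff(bases, cons[p]), 1L)
    }
    stopifnot(up_len - d - k + 1L >= 1L)
    up[i, (up_len - d - k + 1L):(up_len - d)] <- site
    spacer[i] <- d
    mism[i] <- m
    site_seq[i] <- paste(site, collapse = "")
  }

  windows <- tibble::tibble(
    gene_id = gene_id,
    upstream_seq = apply(up, 1, paste, collapse = ""),
    downstream_seq = apply(down, 1, paste, collapse = "")
  )
  truth <- tibble::tibble(
    gene_id = gene_id,
    sd_planted = planted,
    sd_spacer = spacer,
    sd_mismatches = mism,
    sd_site_seq = site_seq
  )
  list(windows = windows, truth = truth)
}

#' Assemble simulated start regions into a synthetic genome
#'
#' Concatenates the simulated windows (with an ATG start codon re-inserted
#' between the upstream and downstream parts) into a single chromosome,
#' placing alternate genes on the reverse strand, and returns the genome
#' with a matching coordinate annotation. Extracting windows back from this
#' genome with [extract_start_windows()] reproduces the input exactly, which
#' is the round-trip used to validate coordinate and strand arithmetic.
#'
#' @param windows Tibble from [simulate_start_regions()].
#' @param spacer_len nt of random sequence inserted between genes.
#' @param seed RNG seed for the spacer sequence.
#' @param strands Optional character vector of "+"/"-" per gene; default
#'   alternates.
#' @return List with `genome` (a [Biostrings::DNAStringSet] of one record)
#'   and `annotation` (tibble: gene_id, seqid, strand, start_codon — the
#'   1-based coordinate of the A of the start codon on the forward strand).
#' @export
assemble_genome <- function(windows, spacer_len = 20L, seed = 1L,
                            strands = NULL) {
  n <- nrow(windows)
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n)
  stopifnot(length(strands) == n, all(strands %in% c("+", "-")))
  set.seed(seed)
  pieces <- character(2L * n + 1L)
  pieces[1] <- paste(sample(c("A", "C", "G", "T"), spacer_len, TRUE),
                     collapse = "")
  start_codon <- integer(n)
  offset <- spacer_len
  for (i in seq_len(n)) {
    up <- windows$upstream_seq[i]
    down <- windows$downstream_seq[i]
    piece <- paste0(up, "ATG", down)
    len <- nchar(piece)
    a_pos <- nchar(up) + 1L
    if (strands[i] == "+") {
      start_codon[i] <- offset + a_pos
    } else {
      piece <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(piece)))
      start_codon[i] <- offset + (len - a_pos + 1L)
    }
    pieces[2L * i] <- piece
    pieces[2L * i + 1L] <- paste(sample(c("A", "C", "G", "T"), spacer_len,
                                        TRUE), collapse = "")
    offset <- offset + len + spacer_len
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(pieces, collapse = ""), "chr1"))
  annotation <- tibble::tibble(
    gene_id = windows$gene_id,
    seqid = "chr1",
    strand = strands,
    start_codon = start_codon
  )
  list(genome = genome, annotation = annotation)
}

#' Simulate a gene-feature annotation table
#'
#' Emits per-gene operon position (single / first / distal), intergenic
#' distance to the upstream gene, 5'-UTR length(s) and strand — the feature
#' set summarised group-wise by [summarize_group()]. When class labels are
#' supplied, the fraction of distal genes follows
#' `operon_config$frac_distal[class]`, so group contrasts in operon position
#' are planted with known effect size. Distal genes draw short intergenic
#' distances (possibly negative, i.e. overlapping); other genes draw long
#' ones. A small fraction of genes is leaderless (5'-UTR 0-7 nt) and some
#' genes receive a second, longer 5' end, emulating dual promoters.
#'
#' @param config A [simulation_config()].
#' @param classes Optional character vector ("sensitive"/"average"/
#'   "resistant") per gene, e.g. from [simulate_translatome()] truth.
#' @param listed_prob Probability a gene is listed in the feature annotation
#'   (distal calls are only defined for listed genes).
#' @param second_end_prob Probability of a second 5' end.
#' @return Tibble with gene_id, class, listed_in_annotation, operon_position,
#'   intergenic_distance, utr_length, utr_length_alt, strand.
#' @export
simulate_annotation <- function(config = simulation_config(),
                                classes = NULL,
                                listed_prob = 0.74,
                                second_end_prob = 0.15) {
  validate_simulation_config(config)
  set.seed(config$seed + 2L)
  n <- if (is.null(classes)) config$n_genes else length(classes)
  if (is.null(classes)) classes <- rep("average", n)
  stopifnot(all(classes %in% c("sensitive", "average", "resistant")))
  oc <- config$operon_config
  gene_id <- sprintf("g%05d", seq_len(n))

  listed <- stats::runif(n) < listed_prob
  p_distal <- oc$frac_distal[classes]
  distal <- listed & stats::runif(n) < p_distal
  single <- !distal & stats::runif(n) < oc$frac_single
  operon_position <- ifelse(!listed, "unknown",
                            ifelse(distal, "distal",
                                   ifelse(single, "single", "first")))

  dist_distal <- round(stats::rexp(n, rate = 1 / oc$distal_distance_mean)) +
    oc$distal_distance_shift
  dist_other <- round(stats::rlnorm(n, oc$other_distance_meanlog,
                                    oc$other_distance_sdlog))
  intergenic_distance <- as.integer(ifelse(distal, dist_distal, dist_other))

  leaderless <- stats::runif(n) < config$leaderless_frac
  utr <- as.integer(pmax(8, round(stats::rlnorm(n, config$utr_meanlog,
                                                config$utr_sdlog))))
  utr[leaderless] <- sample(0:7, sum(leaderless), replace = TRUE)
  second <- stats::runif(n) < second_end_prob & !leaderless
  utr_alt <- rep(NA_integer_, n)
  utr_alt[second] <- utr[second] +
    as.integer(round(stats::rlnorm(sum(second), log(100), 0.5)))

  strand <- sample(c("+", "-"), n, replace = TRUE)
  # a distal gene is co-transcribed with its upstream neighbour, so it must
  # share that neighbour's strand
  for (i in which(distal)) if (i > 1L) strand[i] <- strand[i - 1L]

  tibble::tibble(
    gene_id = gene_id,
    class = classes,
    listed_in_annotation = listed,
    operon_position = operon_position,
    intergenic_distance = intergenic_distance,
    utr_length = utr,
    utr_length_alt = utr_alt,
    strand = strand
  )
}

#' Write simulated measurements, sequences and truth to disk
#'
#' Measurements and ground truth are written as TSV; start-region windows as
#' FASTA whose headers carry the gene id and the planted-SD truth as
#' `key=value` comments.
#'
#' @param sim Output of [simulate_translatome()].
#' @param regions Output of [simulate_start_regions()] (optional).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, regions = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.tsv"),
             truth = file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$measurements, paths[["measurements"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  if (!is.null(regions)) {
    paths <- c(paths,
               windows = file.path(dir, "start_regions.fasta"),
               region_truth = file.path(dir, "start_region_truth.tsv"))
    hdr <- with(regions$truth, sprintf(
      "%s sd_planted=%s spacer=%s", gene_id, sd_planted,
      ifelse(is.na(sd_spacer), "NA", sd_spacer)))
    seqs <- Biostrings::DNAStringSet(stats::setNames(
      paste0(regions$windows$upstream_seq, regions$windows$downstream_seq),
      hdr))
    Biostrings::writeXStringSet(seqs, paths[["windows"]])
    readr::write_tsv(regions$truth, paths[["region_truth"]])
  }
  invisible(paths)
}
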