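#' Extract start-codon-centred sequence windows
#'
#' Retrieves, for every annotated gene, `window_up` nt upstream of the start
#' codon and the first `window_down` nt of the open reading frame, removes
#' the 3-nt start codon, and stores the two parts separately (so the default
#' 40/40 window holds 40 + 37 = 77 nt). Reverse-strand genes are extracted
#' from the mirrored coordinates and reverse-complemented, so windows always
#' read 5' to 3' on the coding strand. Windows running off a sequence end
#' are padded with `N` and flagged.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param annotation Tibble with columns `gene_id`, `seqid`, `strand`
#'   ("+"/"-") and `start_codon` — the 1-based forward-strand coordinate of
#'   the A of the start codon (for "-" genes, the highest coordinate of the
#'   codon).
#' @param config An [analysis_config()].
#' @return Tibble with `gene_id`, `seqid`, `strand`, `upstream_seq`,
#'   `downstream_seq`, `codon` (with a warning when not ATG/GTG/TTG),
#'   `padded`, and 1-based inclusive forward-strand source coordinates
#'   `up_start`, `up_end`, `down_start`, `down_end`.
#' @export
extract_start_windows <- function(genome, annotation,
                                  config = analysis_config()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  need <- c("gene_id", "seqid", "strand", "start_codon")
  stopifnot(all(need %in% names(annotation)))
  missing_seq <- setdiff(unique(annotation$seqid), names(genome))
  if (length(missing_seq)) {
    stop("annotation references sequences absent from the genome: ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  up_len <- config$window_up
  down_len <- config$window_down - 3L

  fetch <- function(seqid, lo, hi, revcomp) {
    full_len <- Biostrings::width(genome[seqid])
    clo <- max(lo, 1L)
    chi <- min(hi, full_len)
    core <- if (clo > chi) "" else
      as.character(Biostrings::subseq(genome[[seqid]], clo, chi))
    pad_l <- strrep("N", max(0L, clo - lo))
    pad_r <- strrep("N", max(0L, hi - chi))
    s <- paste0(pad_l, core, pad_r)
    if (revcomp) {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    s
  }

  n <- nrow(annotation)
  out <- vector("list", n)
  bad_codons <- character(0)
  for (i in seq_len(n)) {
    g <- annotation[i, ]
    s <- as.integer(g$start_codon)
    if (g$strand == "+") {
      up_rng <- c(s - up_len, s - 1L)
      codon_rng <- c(s, s + 2L)
      down_rng <- c(s + 3L, s + 2L + down_len)
    } else {
      up_rng <- c(s + 1L, s + up_len)
      codon_rng <- c(s - 2L, s)
      down_rng <- c(s - 2L - down_len, s - 3L)
    }
    rc <- g$strand == "-"
    up <- fetch(g$seqid, up_rng[1], up_rng[2], rc)
    codon <- fetch(g$seqid, codon_rng[1], codon_rng[2], rc)
    down <- fetch(g$seqid, down_rng[1], down_rng[2], rc)
    if (!codon %in% c("ATG", "GTG", "TTG")) {
      bad_codons <- c(bad_codons, sprintf("%s (%s)", g$gene_id, codon))
    }
    out[[i]] <- tibble::tibble(
      gene_id = g$gene_id, seqid = g$seqid, strand = g$strand,
      upstream_seq = up, downstream_seq = down, codon = codon,
      padded = grepl("N", paste0(up, down), fixed = TRUE),
      up_start = up_rng[1], up_end = up_rng[2],
      down_start = down_rng[1], down_end = down_rng[2]
    )
  }
  if (length(bad_codons)) {
    warning("start codon not ATG/GTG/TTG for: ",
            paste(bad_codons, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Score a candidate Shine-Dalgarno site against the consensus
#'
#' Position-wise, ungapped comparison of an 8-mer to the SD consensus.
#' Ambiguity code `N` never counts as a match.
#'
#' @param site_seq Candidate sequence (same length as the consensus).
#' @param consensus SD consensus, default TAAGGAGG.
#' @return List with `total_matches` and `longest_run` (longest stretch of
#'   consecutive matches).
#' @export
#' @examples
#' score_sd_site("TGAGGACA") # 5 matches, run of 4
score_sd_site <- function(site_seq, consensus = "TAAGGAGG") {
  a <- strsplit(toupper(site_seq), "")[[1]]
  b <- strsplit(toupper(consensus), "")[[1]]
  if (length(a) != length(b)) {
    stop("site length (", length(a), ") differs from consensus length (",
         length(b), ")", call. = FALSE)
  }
  hit <- a == b & a != "N"
  runs <- rle(hit)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(total_matches = as.integer(sum(hit)), longest_run = as.integer(longest))
}

sd_present <- function(total_matches, longest_run, config) {
  total_matches >= config$sd_min_matches | longest_run >= config$sd_min_run
}

#' SD call for a pre-located candidate site
#'
#' Applies the detection rule — present if at least `sd_min_matches`
#' position-wise matches to the consensus or a consecutive run of at least
#' `sd_min_run` matches — to an already-located candidate 8-mer, e.g. one
#' printed in a table of mapped 5' ends.
#'
#' @param site_seq Candidate 8-mer.
#' @param distance_to_aug nt between the site's 3' end and the A of the
#'   start codon (`NA` allowed).
#' @param config An [analysis_config()].
#' @return One-row tibble: `present`, `site_seq`, `distance_to_aug`,
#'   `total_matches`, `longest_run`.
#' @export
sd_call_from_site <- function(site_seq, distance_to_aug = NA_integer_,
                              config = analysis_config()) {
  sc <- score_sd_site(site_seq, config$sd_consensus)
  tibble::tibble(
    present = sd_present(sc$total_matches, sc$longest_run, config),
    site_seq = toupper(site_seq),
    distance_to_aug = as.integer(distance_to_aug),
    total_matches = sc$total_matches,
    longest_run = sc$longest_run
  )
}

#' Detect a Shine-Dalgarno motif upstream of a start codon
#'
#' Scans every candidate site (of consensus length) whose 3' end lies within
#' `sd_scan_range` nt upstream of the start codon, scores each position-wise
#' against the consensus, and reports the candidate maximising total
#' matches, then longest run, then smallest distance. The motif is called
#' present if the best candidate has at least `sd_min_matches` matches or a
#' run of at least `sd_min_run`.
#'
#' @param upstream_seq Sequence immediately upstream of the start codon
#'   (its last base is position -1), e.g. a 5'-UTR or the upstream part of a
#'   start-region window.
#' @param config An [analysis_config()].
#' @return One-row tibble: `present`, `site_seq`, `distance_to_aug`,
#'   `total_matches`, `longest_run`, `reason` (`NA`, or "too short" when no
#'   candidate fits).
#' @export
#' @examples
#' detect_sd("CCCCCCCCCCCCCCCCCCCCCCCCCCTAAGGAGGCCCCC")
detect_sd <- function(upstream_seq, config = analysis_config()) {
  upstream_seq <- toupper(upstream_seq)
  k <- nchar(config$sd_consensus)
  L <- nchar(upstream_seq)
  d_lo <- config$sd_scan_range[1]
  d_hi <- min(config$sd_scan_range[2], L - k)
  if (d_hi < d_lo) {
    return(tibble::tibble(present = FALSE, site_seq = NA_character_,
                          distance_to_aug = NA_integer_,
                          total_matches = NA_integer_,
                          longest_run = NA_integer_, reason = "too short"))
  }
  best <- NULL
  for (d in d_lo:d_hi) {
    site <- substr(upstream_seq, L - d - k + 1L, L - d)
    sc <- score_sd_site(site, config$sd_consensus)
    cand <- list(site = site, d = d, matches = sc$total_matches,
                 run = sc$longest_run)
    if (is.null(best) ||
        cand$matches > best$matches ||
        (cand$matches == best$matches && cand$run > best$run)) {
      best <- cand
    }
  }
  tibble::tibble(
    present = sd_present(best$matches, best$run, config),
    site_seq = best$site,
    distance_to_aug = as.integer(best$d),
    total_matches = best$matches,
    longest_run = best$run,
    reason = NA_character_
  )
}

#' SD calls for a table of start-region windows
#'
#' @param windows Tibble with `gene_id` and `upstream_seq` (from
#'   [extract_start_windows()] or [simulate_start_regions()]).
#' @param config An [analysis_config()].
#' @return Tibble of per-gene SD calls.
#' @export
detect_sd_windows <- function(windows, config = analysis_config()) {
  calls <- lapply(windows$upstream_seq, detect_sd, config = config)
  dplyr::bind_cols(tibble::tibble(gene_id = windows$gene_id),
                   dplyr::bind_rows(calls))
}

#' Classify a transcript as leaderless
#'
#' Strict call: 5'-UTR of `leaderless_strict` nt or less (default 4);
#' relaxed call: `leaderless_relaxed` nt or less (default 7). A strict call
#' implies a relaxed one.
#'
#' @param utr_length 5'-UTR length(s) in nt (vectorised).
#' @param config An [analysis_config()].
#' @return Tibble with `utr_length`, `leaderless_strict`,
#'   `leaderless_relaxed`.
#' @export
#' @examples
#' classify_leaderless(c(0, 5, 8))
classify_leaderless <- function(utr_length, config = analysis_config()) {
  if (any(is.finite(utr_length) & utr_length < 0)) {
    stop("5'-UTR lengths must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    utr_length = utr_length,
    leaderless_strict = utr_length <= config$leaderless_strict,
    leaderless_relaxed = utr_length <= config$leaderless_relaxed
  )
}

#' Are two mapped 5' ends the same transcription start?
#'
#' Mapped 5' ends whose 5'-UTR lengths differ by at most `end_tolerance` nt
#' (default 3) are regarded as the same transcript end, absorbing the
#' single-nt uncertainty of 5'-end mapping.
#'
#' @param len_a,len_b 5'-UTR lengths in nt (vectorised).
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
#' @examples
#' same_5p_end(31, 28)
same_5p_end <- function(len_a, len_b, config = analysis_config()) {
  if (any(c(len_a, len_b) < 0, na.rm = TRUE)) {
    stop("5'-UTR lengths must be non-negative", call. = FALSE)
  }
  abs(len_a - len_b) <= config$end_tolerance
}
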