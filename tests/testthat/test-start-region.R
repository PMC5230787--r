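make_genome <- function(seq) {
  Biostrings::DNAStringSet(setNames(seq, "chr1"))
}

test_that("forward-strand windows use the documented coordinate arithmetic", {
  set.seed(51)
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, 300, TRUE), collapse = "")
  # plant distinct markers at the window edges around a start at 100
  substr(seq, 60, 67) <- "TTTTAAAA" # upstream starts at 60
  substr(seq, 92, 99) <- "GGGGCCCC" # upstream ends at 99
  substr(seq, 100, 102) <- "ATG"
  substr(seq, 103, 110) <- "CCCCGGGG" # downstream starts at 103
  substr(seq, 132, 139) <- "AAAATTTT" # downstream ends at 139
  ann <- tibble::tibble(gene_id = "g1", seqid = "chr1", strand = "+",
                        start_codon = 100L)
  w <- extract_start_windows(make_genome(seq), ann)
  expect_equal(nchar(w$upstream_seq), 40L)
  expect_equal(nchar(w$downstream_seq), 37L)
  expect_equal(c(w$up_start, w$up_end, w$down_start, w$down_end),
               c(60L, 99L, 103L, 139L))
  expect_equal(substr(w$upstream_seq, 1, 8), "TTTTAAAA")
  expect_equal(substr(w$upstream_seq, 33, 40), "GGGGCCCC")
  expect_equal(w$codon, "ATG")
  expect_equal(substr(w$downstream_seq, 1, 8), "CCCCGGGG")
  expect_equal(substr(w$downstream_seq, 30, 37), "AAAATTTT")
  expect_false(w$padded)
})

test_that("strand handling round-trips through a reverse-complemented genome", {
  sr <- simulate_start_regions(simulation_config(n_genes = 12, seed = 31))
  fwd <- assemble_genome(sr$windows, seed = 4, strands = rep("+", 12))
  rev <- assemble_genome(sr$windows, seed = 4, strands = rep("-", 12))
  w_fwd <- extract_start_windows(fwd$genome, fwd$annotation)
  w_rev <- extract_start_windows(rev$genome, rev$annotation)
  expect_equal(w_fwd$upstream_seq, sr$windows$upstream_seq)
  expect_equal(w_fwd$downstream_seq, sr$windows$downstream_seq)
  expect_equal(w_rev$upstream_seq, sr$windows$upstream_seq)
  expect_equal(w_rev$downstream_seq, sr$windows$downstream_seq)
  # mixed strands via the default alternation
  mix <- assemble_genome(sr$windows, seed = 4)
  w_mix <- extract_start_windows(mix$genome, mix$annotation)
  expect_equal(w_mix$upstream_seq, sr$windows$upstream_seq)
})

test_that("windows near a sequence edge are N-padded and flagged", {
  seq <- paste(rep("ACGT", 40), collapse = "")
  substr(seq, 11, 13) <- "ATG"
  ann <- tibble::tibble(gene_id = "edge", seqid = "chr1", strand = "+",
                        start_codon = 11L)
  w <- extract_start_windows(make_genome(seq), ann)
  expect_true(w$padded)
  expect_equal(substr(w$upstream_seq, 1, 30), strrep("N", 30))
  expect_equal(nchar(w$upstream_seq), 40L)
})

test_that("unknown sequences and odd start codons are reported", {
  seq <- paste(rep("ACGT", 40), collapse = "")
  ann <- tibble::tibble(gene_id = "gX", seqid = "chrMissing", strand = "+",
                        start_codon = 80L)
  expect_error(extract_start_windows(make_genome(seq), ann), "chrMissing")
  ann2 <- tibble::tibble(gene_id = "gY", seqid = "chr1", strand = "+",
                         start_codon = 80L)
  expect_warning(extract_start_windows(make_genome(seq), ann2),
                 "gY")
})

test_that("SD scoring matches published worked examples", {
  s <- score_sd_site("TGAGGACA")
  expect_equal(s$total_matches, 5L)
  expect_equal(s$longest_run, 4L)
  expect_true(sd_call_from_site("TGAGGACA", 5)$present)

  s <- score_sd_site("GCCTGTGG")
  expect_equal(s$total_matches, 3L)
  expect_equal(s$longest_run, 2L)
  expect_false(sd_call_from_site("GCCTGTGG", 3)$present)

  s <- score_sd_site("GATGGAAG")
  expect_equal(s$total_matches, 5L)
  expect_equal(s$longest_run, 3L)
  expect_true(sd_call_from_site("GATGGAAG", 6)$present)

  expect_equal(score_sd_site("TAAGGAGG")$total_matches, 8L)
  # N never matches
  expect_equal(score_sd_site("TAAGGAGN")$total_matches, 7L)
})

test_that("SD scan picks the best candidate within the distance range", {
  up <- paste0(strrep("C", 26), "TAAGGAGG", "CCCCC") # 3' end 5 nt upstream
  call <- detect_sd(up)
  expect_true(call$present)
  expect_equal(call$distance_to_aug, 5L)
  expect_equal(call$total_matches, 8L)
  # a consensus outside the scan range (3' end 20 nt upstream) is not seen
  far <- paste0(strrep("C", 12), "TAAGGAGG", strrep("C", 20))
  expect_false(detect_sd(far)$present)
  # short inputs degrade gracefully (leaderless transcripts)
  short <- detect_sd("ACGT")
  expect_false(short$present)
  expect_equal(short$reason, "too short")
})

test_that("moving a site toward the consensus never loses the call", {
  set.seed(61)
  cfg <- analysis_config()
  cons <- strsplit(cfg$sd_consensus, "")[[1]]
  for (i in 1:200) {
    site <- sample(c("A", "C", "G", "T"), 8, TRUE)
    before <- sd_call_from_site(paste(site, collapse = ""))$present
    off <- which(site != cons)
    if (length(off) == 0) next
    j <- if (length(off) == 1) off else sample(off, 1)
    site[j] <- cons[j]
    after <- sd_call_from_site(paste(site, collapse = ""))$present
    expect_true(!before || after)
  }
})

test_that("leaderless classification applies strict and relaxed thresholds", {
  r <- classify_leaderless(c(0, 4, 5, 7, 8))
  expect_equal(r$leaderless_strict, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$leaderless_relaxed, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(classify_leaderless(-1), "non-negative")
  all_lengths <- classify_leaderless(0:40)
  expect_true(all(!all_lengths$leaderless_strict |
                    all_lengths$leaderless_relaxed))
})

test_that("5'-end equality tolerates small mapping differences", {
  expect_true(same_5p_end(31, 28))
  expect_false(same_5p_end(166, 68))
  expect_true(all(same_5p_end(c(0, 12, 400), c(0, 12, 400))))
  expect_false(same_5p_end(10, 14))
})
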