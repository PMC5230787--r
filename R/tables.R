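#' Experimentally mapped 5' ends of selected transcripts
#'
#' The packaged worked-example dataset: 22 transcripts of 19 genes with
#' experimentally determined 5' ends from untreated and drug-treated
#' cultures, their KEVs, the distance between the candidate SD site's 3' end
#' and the start codon, the published SD yes/no call and the 8-mer at the SD
#' site. Genes with two mapped 5' ends occupy two rows, the second carrying
#' only the alternative UTR lengths. KEVs use decimal commas in the source
#' table and are parsed to numerics here; the `group` column is derived by
#' classifying each gene's KEV with the default thresholds.
#'
#' @param config An [analysis_config()] used to derive the group labels.
#' @return Tibble with b_no, gene, kev, utr_no_ksg, utr_ksg,
#'   distance_to_aug, sd_motif, sd_site_seq, group.
#' @export
#' @examples
#' t1 <- mapped_5p_ends()
#' table(t1$group[!is.na(t1$kev)])
mapped_5p_ends <- function(config = analysis_config()) {
  path <- system.file("extdata", "mapped_5prime_ends.tsv",
                      package = "ksgtome", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  kev <- as.numeric(sub(",", ".", raw$kev, fixed = TRUE))
  # second-end rows inherit the gene's KEV for grouping
  gene_kev <- kev
  for (i in seq_along(gene_kev)) {
    if (is.na(gene_kev[i])) {
      j <- which(raw$b_no == raw$b_no[i] & !is.na(kev))[1]
      gene_kev[i] <- kev[j]
    }
  }
  tibble::tibble(
    b_no = raw$b_no,
    gene = raw$gene,
    kev = kev,
    utr_no_ksg = as.integer(raw$utr_no_ksg),
    utr_ksg = as.integer(raw$utr_ksg),
    distance_to_aug = as.integer(raw$distance_to_aug),
    sd_motif = raw$sd_motif,
    sd_site_seq = raw$sd_site_seq,
    group = classify_kev(gene_kev, config)
  )
}

#' Published group-level feature counts
#'
#' Counts of annotation features for the genome-wide sensitive and resistant
#' transcript groups as tabulated against the feature database: group sizes,
#' genes listed/not listed in the database, single-or-first versus distal
#' operon positions, average 5'-UTR length and the number of genes with an
#' intergenic distance below 15 nt.
#'
#' @return Tibble with columns feature, sensitive, resistant.
#' @export
group_feature_counts <- function() {
  path <- system.file("extdata", "group_feature_counts.tsv",
                      package = "ksgtome", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cii", progress = FALSE)
}
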