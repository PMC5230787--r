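LOGO_BASES <- c("A", "C", "G", "T")

window_matrix <- function(windows) {
  if (is.data.frame(windows)) {
    seqs <- paste0(windows$upstream_seq, windows$downstream_seq)
  } else {
    seqs <- as.character(windows)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- if (is.data.frame(windows)) {
      windows$gene_id[lens != stats::median(lens)]
    } else {
      which(lens != stats::median(lens))
    }
    stop("windows differ in length; offending entries: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Background base frequencies of a window set
#'
#' Pools the base counts over all positions of all windows in a set and
#' converts them to probabilities; these set-derived expectations are what
#' the logo measures deviations from. `N` bases are excluded; a pseudocount
#' (`logo_pseudocount`, default 0.5 per base) keeps every probability
#' positive even in degenerate sets.
#'
#' @param windows Tibble with `upstream_seq`/`downstream_seq` columns, or a
#'   character vector of equal-length sequences.
#' @param config An [analysis_config()].
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @export
background_frequencies <- function(windows, config = analysis_config()) {
  m <- window_matrix(windows)
  counts <- vapply(LOGO_BASES, function(b) sum(m == b), numeric(1)) +
    config$logo_pseudocount
  counts / sum(counts)
}

#' Relative-entropy logo matrix
#'
#' For each alignment position the observed base frequencies `q` are
#' compared to the background `p`; the information content is the relative
#' entropy (Kullback-Leibler divergence) `sum(q * log2(q/p))` in bits, and
#' each base gets a signed letter height `q_b * information`, positive when
#' the base is over-represented (`q_b > p_b`, drawn upright) and negative
#' when under-represented (drawn inverted). The absolute heights at a
#' position sum to its information content. With a uniform background the
#' information reduces to `2 - H(q)`, the classic Shannon logo. Position
#' labels for the default 77-nt start-region windows run -40..-1 and
#' +4..+40 (the start codon is absent).
#'
#' @param windows Tibble with `upstream_seq`/`downstream_seq` columns, or a
#'   character vector of equal-length sequences (at least 2).
#' @param background Named numeric (A, C, G, T) from
#'   [background_frequencies()]; computed from `windows` if omitted.
#' @param config An [analysis_config()].
#' @return Tibble with `position` (label), `q_A` .. `q_T`,
#'   `information_bits`, `height_A` .. `height_T`.
#' @export
logo_matrix <- function(windows, background = NULL,
                        config = analysis_config()) {
  m <- window_matrix(windows)
  if (nrow(m) < 2L) stop("need at least 2 windows", call. = FALSE)
  if (is.null(background)) background <- background_frequencies(windows, config)
  stopifnot(identical(sort(names(background)), LOGO_BASES),
            all(background > 0))
  p <- background[LOGO_BASES]

  L <- ncol(m)
  up <- config$window_up
  down <- config$window_down - 3L
  labels <- if (L == up + down) c(-up:-1, 4:(3 + down)) else seq_len(L)

  pc <- config$logo_pseudocount
  rows <- lapply(seq_len(L), function(j) {
    col <- m[, j]
    counts <- vapply(LOGO_BASES, function(b) sum(col == b), numeric(1)) + pc
    q <- counts / sum(counts)
    terms <- ifelse(q > 0, q * log2(q / p), 0)
    info <- max(0, sum(terms))
    height <- ifelse(q >= p, 1, -1) * q * info
    tibble::tibble(
      position = labels[j],
      q_A = q[["A"]], q_C = q[["C"]], q_G = q[["G"]], q_T = q[["T"]],
      information_bits = info,
      height_A = height[["A"]], height_C = height[["C"]],
      height_G = height[["G"]], height_T = height[["T"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Export a logo matrix as TSV
#'
#' Writes the per-position frequencies, information contents and signed
#' letter heights, preceded by comment lines stating the coordinate
#' convention and the maximum-information position (ties broken by the most
#' upstream position).
#'
#' @param columns Tibble from [logo_matrix()].
#' @param path Output file.
#' @return Invisibly, a list with `path`, `max_position` and `max_bits`.
#' @export
export_logo <- function(columns, path) {
  stopifnot(nrow(columns) >= 1)
  i <- which(columns$information_bits == max(columns$information_bits))[1]
  header <- c(
    "# relative-entropy sequence logo matrix",
    "# positions are relative to the start codon (A = +1); the codon itself (+1..+3) is removed",
    sprintf("# max_information position=%s bits=%.6g",
            columns$position[i], columns$information_bits[i])
  )
  writeLines(header, path)
  readr::write_tsv(columns, path, append = TRUE, col_names = TRUE)
  invisible(list(path = path, max_position = columns$position[i],
                 max_bits = columns$information_bits[i]))
}

#' Read a logo matrix written by [export_logo()]
#'
#' @param path File written by [export_logo()].
#' @return Tibble with the same columns as [logo_matrix()] output.
#' @export
read_logo_matrix <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
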