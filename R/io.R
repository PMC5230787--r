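MEASUREMENT_COLUMNS <- c("gene_id", "condition", "fraction", "replicate",
                         "intensity")

check_measurements <- function(measurements) {
  miss <- setdiff(MEASUREMENT_COLUMNS, names(measurements))
  if (length(miss)) {
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(measurements) == 0) stop("no measurements", call. = FALSE)
  bad_cond <- setdiff(unique(measurements$condition),
                      c("untreated", "treated"))
  bad_frac <- setdiff(unique(measurements$fraction), c("free", "polysomal"))
  if (length(bad_cond) || length(bad_frac)) {
    stop("unexpected condition/fraction levels: ",
         paste(c(bad_cond, bad_frac), collapse = ", "), call. = FALSE)
  }
  key <- paste(measurements$gene_id, measurements$condition,
               measurements$fraction, measurements$replicate, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicated measurement key(s): ",
         paste(utils::head(unique(dup), 5), collapse = "; "), call. = FALSE)
  }
  invisible(measurements)
}

#' Read a measurement table
#'
#' TSV with columns gene_id, condition (untreated/treated), fraction
#' (free/polysomal), replicate, intensity and optionally dye. Duplicate
#' (gene, condition, fraction, replicate) keys, missing columns and
#' non-numeric intensities are rejected with informative errors.
#'
#' @param path Path to a TSV file.
#' @return Tibble of typed measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  miss <- setdiff(MEASUREMENT_COLUMNS, names(raw))
  if (length(miss)) {
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("no measurements", call. = FALSE)
  intensity <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(is.na(intensity) & !(raw$intensity %in% c(NA, "", "NA")))
  if (length(bad)) {
    stop("non-numeric intensity at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = raw$gene_id,
    condition = raw$condition,
    fraction = raw$fraction,
    replicate = as.integer(raw$replicate),
    dye = if ("dye" %in% names(raw)) raw$dye else NA_character_,
    intensity = intensity
  )
  check_measurements(out)
  out
}

#' Read gene annotation (GFF3 or TSV)
#'
#' Returns one record per gene with 1-based inclusive coordinates, strand
#' and the forward-strand coordinate of the A of the start codon (`start`
#' for "+" genes, `end` for "-" genes, assuming the annotated span begins at
#' the start codon). The TSV dialect must provide columns gene_id, seqid,
#' strand, start, end and may carry extra feature columns (utr_length,
#' operon_position, intergenic_distance, ...), which are passed through.
#'
#' @param path Path to the file.
#' @param dialect "gff3", "tsv" or "auto" (by file extension).
#' @return Tibble with gene_id, seqid, strand, start, end, start_codon and
#'   any extra columns.
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (dialect == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) {
                     stop("failed to parse GFF3 '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    d <- as.data.frame(gr)
    d <- d[d$type %in% c("gene", "CDS"), , drop = FALSE]
    if (nrow(d) == 0) stop("no gene/CDS features in ", path, call. = FALSE)
    ids <- as.character(d$ID %||% rep(NA, nrow(d)))
    if ("locus_tag" %in% names(d)) {
      ids <- ifelse(is.na(ids) | ids == "", as.character(d$locus_tag), ids)
    }
    if (anyNA(ids)) stop("GFF3 features without ID/locus_tag", call. = FALSE)
    df <- tibble::tibble(
      gene_id = ids,
      seqid = as.character(d$seqnames),
      strand = as.character(d$strand),
      start = d$start,
      end = d$end
    )
    df <- df[!duplicated(df$gene_id), ]
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "seqid", "strand", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    bad <- which(df$end < df$start)
    if (length(bad)) {
      stop("end < start at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("unknown strand symbol at data row(s): ",
         paste(utils::head(bad_strand, 5), collapse = ", "), call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$start_codon <- ifelse(df$strand == "+", df$start, df$end)
  df
}

#' Run the full translatome pipeline
#'
#' Executes the analysis end to end: KEV stage (TEs, QC, replicate filter,
#' normalized KEVs, classification, per-gene tests), start-region stage
#' (window extraction and SD detection), structure logos for the sensitive
#' and resistant groups, and the feature-enrichment stage, writing every
#' stage's table under `outdir` together with a YAML run summary. Re-running
#' with identical inputs and config reproduces identical outputs.
#'
#' @param measurements Measurement tibble or path to a measurement TSV.
#' @param genome [Biostrings::DNAStringSet] or FASTA path (optional; start
#'   regions and logos are skipped without it).
#' @param annotation Tibble or path with gene coordinates (see
#'   [read_annotation()]); needed for the start-region stage.
#' @param features Gene feature records (tibble or TSV path) for the
#'   enrichment stage; optional.
#' @param config An [analysis_config()].
#' @param outdir Output directory.
#' @param seed Recorded in the run summary (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with `kev`, `sd_calls`, `logos`,
#'   `group_summary`, `tests`, `report` and `paths`.
#' @export
run_pipeline <- function(measurements, genome = NULL, annotation = NULL,
                         features = NULL, config = analysis_config(),
                         outdir = "results", seed = NA_integer_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  report <- list(seed = seed)

  if (is.character(measurements)) {
    measurements <- stage("read", read_measurements(measurements))
  }
  if (is.character(annotation)) {
    annotation <- stage("read", read_annotation(annotation))
  }
  if (is.character(features)) {
    features <- stage("read", readr::read_tsv(features,
                                              show_col_types = FALSE))
  }

  kev <- stage("kev", kev_analysis(measurements, config))
  paths$kev <- file.path(outdir, "kev_results.tsv")
  write_kev_results(kev, paths$kev, config$total_replicates)
  counts <- table(kev$disposition)
  report$genes_in <- nrow(kev)
  report$dispositions <- as.list(stats::setNames(as.integer(counts),
                                                 names(counts)))
  message("kev stage: ", nrow(kev), " genes in; ",
          sum(kev$pass), " passed the replicate filter")

  analyzed <- kev[kev$pass, ]
  if (nrow(analyzed) > 0) {
    hist <- kev_distribution(analyzed$log2_kev, config)
    paths$histogram <- file.path(outdir, "kev_histogram.tsv")
    readr::write_tsv(hist, paths$histogram)
  } else {
    message("no gene passed the replicate filter; downstream stages skipped")
  }

  sd_calls <- NULL
  logos <- list()
  if (!is.null(genome) && !is.null(annotation) && nrow(analyzed) > 0) {
    windows <- stage("start_region", {
      ann <- annotation[annotation$gene_id %in% analyzed$gene_id, ]
      extract_start_windows(genome, ann, config)
    })
    sd_calls <- stage("start_region", detect_sd_windows(windows, config))
    sd_calls$class <- analyzed$class[match(sd_calls$gene_id,
                                           analyzed$gene_id)]
    paths$sd_calls <- file.path(outdir, "sd_calls.tsv")
    readr::write_tsv(sd_calls, paths$sd_calls)
    message("start-region stage: ", nrow(windows), " windows, ",
            sum(sd_calls$present), " SD-positive")

    for (grp in c("sensitive", "resistant")) {
      w <- windows[windows$gene_id %in%
                     analyzed$gene_id[analyzed$class == grp], ]
      if (nrow(w) >= 2) {
        logos[[grp]] <- stage("logo", logo_matrix(w, config = config))
        p <- file.path(outdir, sprintf("logo_%s.tsv", grp))
        info <- export_logo(logos[[grp]], p)
        paths[[paste0("logo_", grp)]] <- p
        report[[paste0("logo_", grp, "_max")]] <-
          list(position = info$max_position, bits = info$max_bits)
        message("logo (", grp, "): max information ",
                signif(info$max_bits, 3), " bits at position ",
                info$max_position)
      } else {
        message("logo (", grp, "): skipped, fewer than 2 windows")
      }
    }
  }

  group_summary <- NULL
  tests <- NULL
  if (!is.null(features) && nrow(analyzed) > 0) {
    feats <- stage("enrichment", {
      f <- features
      f$class <- analyzed$class[match(f$gene_id, analyzed$gene_id)]
      f[!is.na(f$class), ]
    })
    group_summary <- stage("enrichment",
                           summarize_groups(feats, config = config))
    tests <- stage("enrichment", enrichment_tests(feats, config = config))
    paths$group_summary <- file.path(outdir, "group_summary.tsv")
    paths$enrichment_tests <- file.path(outdir, "enrichment_tests.tsv")
    readr::write_tsv(group_summary, paths$group_summary)
    readr::write_tsv(tests, paths$enrichment_tests)
    message("enrichment stage: ",
            paste(sprintf("%s n=%d", group_summary$group,
                          group_summary$n_total), collapse = ", "))
  }

  paths$report <- file.path(outdir, "run_summary.yaml")
  yaml::write_yaml(report, paths$report)
  invisible(list(kev = kev, sd_calls = sd_calls, logos = logos,
                 group_summary = group_summary, tests = tests,
                 report = report, paths = paths))
}
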