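## Column order written and expected for hit tables: the outfmt-6 core
## (qseqid sseqid pident length evalue bitscore) plus subject length,
## kingdom and description extensions.
hit_file_cols <- c(
  "qseqid", "sseqid", "pident", "length", "evalue",
  "bitscore", "slen", "skingdom", "sdesc"
)

hit_tbl_cols <- c(
  "query_id", "subject_accession", "percent_identity", "alignment_length_bp",
  "evalue", "bit_score", "subject_length_bp", "subject_kingdom",
  "subject_description"
)

known_kingdoms <- c("animal", "bacteria", "plant", "fungi")

#' Read assembled contigs from a FASTA file
#'
#' Contig ids are the first whitespace-delimited token of each header. A
#' `stage=<label>` token elsewhere in the header records the library of
#' origin; headers without one give `NA` stages (stage can also be attached
#' later from a count table).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `length_bp`, `stage`,
#'   `sequence`, one row per record (zero rows for an empty file).
#' @export
read_contigs_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(
    contig_id = character(), length_bp = integer(),
    stage = character(), sequence = character()
  )
  if (file.size(path) == 0) {
    return(empty)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(seqs) == 0) {
    return(empty)
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  stage <- stringr::str_match(headers, "stage=([^;]+?)\\s*$")[, 2]
  tibble::tibble(
    contig_id = ids,
    length_bp = as.integer(Biostrings::width(seqs)),
    stage = stage,
    sequence = unname(as.character(seqs))
  )
}

#' Write contigs to FASTA
#'
#' The inverse of [read_contigs_fasta()]: stage labels, when present, are
#' stored as a `stage=` header token so a round trip preserves them.
#'
#' @param contigs Tibble with `contig_id`, `sequence` and optionally `stage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  hdr <- contigs$contig_id
  if ("stage" %in% names(contigs)) {
    has_stage <- !is.na(contigs$stage)
    hdr[has_stage] <- paste0(hdr[has_stage], " stage=", contigs$stage[has_stage])
  }
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Read a BLAST-style tabular hit file
#'
#' Expects a tab-separated file with a header row naming at least the
#' outfmt-6-compatible columns `qseqid`, `sseqid`, `pident`, `length`,
#' `evalue`, `bitscore` plus the extensions `slen` (subject length),
#' `skingdom` (subject kingdom) and `sdesc` (subject description). Extra
#' columns (e.g. alignment coordinates) are ignored. Kingdoms are normalized
#' case-insensitively to animal/bacteria/plant/fungi; anything else becomes
#' `"unknown"`. Duplicate (query, subject) rows are retained — multiple HSPs
#' are legitimate.
#'
#' @param path Path to the TSV file.
#' @param taxonomy_map Optional tibble or TSV path with columns `accession`,
#'   `kingdom`; when given, it overrides (or supplies) the subject kingdom by
#'   accession lookup.
#' @return A tibble of typed hits with columns `query_id`,
#'   `subject_accession`, `percent_identity`, `alignment_length_bp`,
#'   `evalue`, `bit_score`, `subject_length_bp`, `subject_kingdom`,
#'   `subject_description`.
#' @export
read_hits <- function(path, taxonomy_map = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- hit_file_cols
  if (!is.null(taxonomy_map)) required <- setdiff(required, "skingdom")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(
      "hit table ", path, " is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  num <- function(col, what, ge = NULL) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad) > 0 || anyNA(raw[[col]])) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(raw[[col]]))[1]
      stop(
        "non-numeric ", what, " in ", path, " at data row ", row,
        ": '", raw[[col]][row], "'",
        call. = FALSE
      )
    }
    if (!is.null(ge) && any(x < ge)) {
      stop(what, " below ", ge, " in ", path, call. = FALSE)
    }
    x
  }
  kingdom <- if (!is.null(taxonomy_map)) {
    lookup_kingdom(raw$sseqid, taxonomy_map)
  } else {
    normalize_kingdom(raw$skingdom)
  }
  tibble::tibble(
    query_id = raw$qseqid,
    subject_accession = raw$sseqid,
    percent_identity = num("pident", "percent identity", ge = 0),
    alignment_length_bp = as.integer(num("length", "alignment length", ge = 1)),
    evalue = num("evalue", "E-value", ge = 0),
    bit_score = num("bitscore", "bit score"),
    subject_length_bp = as.integer(num("slen", "subject length", ge = 1)),
    subject_kingdom = kingdom,
    subject_description = raw$sdesc
  )
}

#' Write a hit table in the canonical tabular layout
#'
#' @param hits Hit tibble as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  missing <- setdiff(hit_tbl_cols, names(hits))
  if (length(missing) > 0) {
    stop("hit tibble missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- hits[, hit_tbl_cols]
  names(out) <- hit_file_cols
  readr::write_tsv(out, path)
  invisible(path)
}

normalize_kingdom <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("fungus", "fungal")] <- "fungi"
  x[x %in% c("animalia", "metazoa")] <- "animal"
  x[x %in% c("plantae", "viridiplantae")] <- "plant"
  x[!x %in% known_kingdoms] <- "unknown"
  x
}

lookup_kingdom <- function(accessions, taxonomy_map) {
  if (is.character(taxonomy_map) && length(taxonomy_map) == 1) {
    taxonomy_map <- read_taxonomy_map(taxonomy_map)
  }
  stopifnot(all(c("accession", "kingdom") %in% names(taxonomy_map)))
  idx <- match(accessions, taxonomy_map$accession)
  normalize_kingdom(ifelse(is.na(idx), "unknown", taxonomy_map$kingdom[idx]))
}

#' Read an accession-to-kingdom taxonomy map
#'
#' A two-column TSV (`accession`, `kingdom`) used instead of, or on top of,
#' the `skingdom` column of a hit table, for hit files produced without
#' taxonomic annotation.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession`, `kingdom` (normalized).
#' @export
read_taxonomy_map <- function(path) {
  if (!file.exists(path)) stop("taxonomy map not found: ", path, call. = FALSE)
  tm <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("accession", "kingdom"), names(tm))
  if (length(missing) > 0) {
    stop("taxonomy map missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tm$kingdom <- normalize_kingdom(tm$kingdom)
  tm[, c("accession", "kingdom")]
}

#' Read per-stage per-contig mapped-read counts
#'
#' Long-format TSV with columns `contig_id`, `stage`, `reads`. Rows whose
#' `contig_id` is `TOTAL` are optional per-stage totals; when present they are
#' cross-checked against the column sums and a mismatch is an error. A contig
#' absent from a stage simply has no row and is treated as 0 reads wherever
#' counts are consumed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `stage`, `contig_id`, `reads`
#'   (non-negative integers).
#' @seealso [stage_totals()] for total mapped reads per stage.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("contig_id", "stage", "reads"), names(raw))
  if (length(missing) > 0) {
    stop("count table missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  reads <- suppressWarnings(as.numeric(raw$reads))
  if (anyNA(reads)) {
    row <- which(is.na(reads))[1]
    stop("non-numeric read count at data row ", row, ": '", raw$reads[row], "'", call. = FALSE)
  }
  if (any(reads < 0)) {
    stop("negative read count at data row ", which(reads < 0)[1], call. = FALSE)
  }
  counts <- tibble::tibble(
    stage = raw$stage, contig_id = raw$contig_id, reads = as.integer(round(reads))
  )
  totals_rows <- counts$contig_id == "TOTAL"
  stated <- counts[totals_rows, ]
  counts <- counts[!totals_rows, ]
  if (nrow(stated) > 0) {
    observed <- stage_totals(counts)
    chk <- dplyr::left_join(stated, observed, by = "stage", suffix = c("_stated", "_observed"))
    bad <- which(
      is.na(chk$total_mapped_reads) | chk$reads != chk$total_mapped_reads
    )
    if (length(bad) > 0) {
      stop(
        "stated total for stage '", chk$stage[bad[1]], "' (",
        chk$reads[bad[1]], ") does not match the column sum (",
        chk$total_mapped_reads[bad[1]], ")",
        call. = FALSE
      )
    }
  }
  counts
}

#' Write a long-format count table
#'
#' Appends one `TOTAL` row per stage recording total mapped reads so the file
#' self-validates on re-read.
#'
#' @param counts Count tibble (`stage`, `contig_id`, `reads`).
#' @param path Output path.
#' @param totals_row Write the per-stage `TOTAL` rows? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, totals_row = TRUE) {
  stopifnot(all(c("stage", "contig_id", "reads") %in% names(counts)))
  out <- counts[, c("contig_id", "stage", "reads")]
  if (totals_row) {
    tot <- stage_totals(counts)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(contig_id = "TOTAL", stage = tot$stage, reads = tot$total_mapped_reads)
    )
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Total mapped reads per stage library
#'
#' @param counts Count tibble from [read_counts()] or
#'   [simulate_read_counts()].
#' @return A tibble with columns `stage`, `total_mapped_reads`.
#' @export
stage_totals <- function(counts) {
  counts |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(total_mapped_reads = sum(.data$reads), .groups = "drop")
}
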