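#' Keep hits at or below an E-value threshold
#'
#' A match counts as significant when its E-value is less than *or equal to*
#' the threshold (default 0.001), so a hit at exactly the threshold is
#' retained. Row order is preserved.
#'
#' @param hits Hit tibble ([read_hits()] layout).
#' @param threshold Positive E-value cutoff; default 0.001.
#' @return The significant subset of `hits`, in input order.
#' @export
#' @examples
#' h <- tibble::tibble(
#'   query_id = "c1", subject_accession = "g1", percent_identity = 90,
#'   alignment_length_bp = 100L, evalue = 0.001, bit_score = 50,
#'   subject_length_bp = 900L, subject_kingdom = "animal",
#'   subject_description = "catalase isoform 1"
#' )
#' nrow(filter_significant(h)) # retained at the boundary
filter_significant <- function(hits, threshold = 0.001) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  hits[hits$evalue <= threshold, , drop = FALSE]
}

#' Select the best hit per contig
#'
#' One winner per query: minimal E-value, ties broken by maximal bit score,
#' remaining ties by the lexicographically smallest subject accession. The
#' full ordering makes the choice deterministic no matter how input rows are
#' permuted.
#'
#' @param hits Hit tibble, typically already filtered by
#'   [filter_significant()].
#' @return A tibble with one row per distinct `query_id`.
#' @export
select_best_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(hits)
  }
  hits |>
    dplyr::arrange(
      .data$query_id, .data$evalue,
      dplyr::desc(.data$bit_score), .data$subject_accession
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

#' Classify best hits with a keyword ontology
#'
#' Applies the ordered rules of the ontology to each subject description,
#' case-insensitively; the first matching rule assigns `category`, `family`
#' and `subfamily`. Descriptions matching no rule get `category = "none"` —
#' they stay in the dataset but never enter detox tables.
#'
#' @param best_hits Tibble with a `subject_description` column (one row per
#'   contig, e.g. from [select_best_hits()]).
#' @param ontology Rule tibble ([default_ontology()] or [read_ontology()]).
#' @return `best_hits` with `category`, `family`, `subfamily` columns added.
#' @export
classify_hits <- function(best_hits, ontology = default_ontology()) {
  validate_ontology(ontology)
  n <- nrow(best_hits)
  category <- rep("none", n)
  family <- rep("", n)
  subfamily <- rep("", n)
  unassigned <- rep(TRUE, n)
  for (r in seq_len(nrow(ontology))) {
    if (!any(unassigned)) break
    m <- unassigned & grepl(
      ontology$pattern[r], best_hits$subject_description,
      ignore.case = TRUE, perl = TRUE
    )
    category[m] <- ontology$category[r]
    family[m] <- ontology$family[r]
    subfamily[m] <- ontology$subfamily[r]
    unassigned[m] <- FALSE
  }
  dplyr::mutate(
    best_hits,
    category = category, family = family, subfamily = subfamily
  )
}

#' Annotate contigs from a hit table
#'
#' The full annotation stage: filter hits to E-value significance, pick one
#' best hit per contig, classify by the ontology, and flag contigs whose best
#' hit is bacterial, plant or fungal as contaminants. Contigs without any
#' significant hit are kept with `category = "none"` and no subject fields.
#'
#' @param contigs Contig tibble ([read_contigs_fasta()] layout); the
#'   `sequence` column is optional.
#' @param hits Hit tibble.
#' @param ontology Classification rules.
#' @param evalue_max Significance threshold passed to [filter_significant()].
#' @return An annotated tibble, one row per contig, with the contig fields
#'   plus best-hit fields, `category`/`family`/`subfamily`, `has_hit` and
#'   `contaminant`.
#' @export
annotate_contigs <- function(contigs, hits, ontology = default_ontology(),
                             evalue_max = 0.001) {
  best <- hits |>
    filter_significant(threshold = evalue_max) |>
    select_best_hits() |>
    classify_hits(ontology = ontology)
  keep <- c(
    "query_id", "subject_accession", "evalue", "bit_score",
    "percent_identity", "subject_length_bp", "subject_kingdom",
    "subject_description", "category", "family", "subfamily"
  )
  annotated <- contigs |>
    dplyr::left_join(best[, keep], by = c(contig_id = "query_id")) |>
    dplyr::mutate(
      has_hit = !is.na(.data$subject_accession),
      category = dplyr::coalesce(.data$category, "none"),
      family = dplyr::coalesce(.data$family, ""),
      subfamily = dplyr::coalesce(.data$subfamily, ""),
      contaminant = .data$has_hit &
        .data$subject_kingdom %in% c("bacteria", "plant", "fungi")
    )
  annotated
}

#' Remove contaminant contigs and summarise what was removed
#'
#' A contig is a contaminant when its *best* significant hit belongs to
#' bacteria, plants or fungi; lower-ranked hits never decide. The summary
#' reports, per kingdom, the number removed and the removed fraction under
#' both natural denominators — contigs with a significant hit, and all
#' contigs — since either convention is found in transcriptome surveys.
#'
#' @param annotated Annotated tibble from [annotate_contigs()].
#' @return List with `clean` (the annotated tibble minus contaminants) and
#'   `summary` (tibble `kingdom`, `n_removed`, `fraction_of_hits`,
#'   `fraction_of_all`).
#' @export
flag_contaminants <- function(annotated) {
  stopifnot("contaminant" %in% names(annotated))
  n_hits <- sum(annotated$has_hit)
  n_all <- nrow(annotated)
  removed <- annotated[annotated$contaminant, , drop = FALSE]
  summary <- tibble::tibble(kingdom = c("bacteria", "plant", "fungi")) |>
    dplyr::mutate(
      n_removed = purrr::map_int(
        .data$kingdom,
        \(k) sum(removed$subject_kingdom == k)
      ),
      fraction_of_hits = if (n_hits > 0) .data$n_removed / n_hits else 0,
      fraction_of_all = if (n_all > 0) .data$n_removed / n_all else 0
    )
  list(
    clean = annotated[!annotated$contaminant, , drop = FALSE],
    summary = summary
  )
}
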