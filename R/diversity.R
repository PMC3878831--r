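#' Collapse annotated contigs into per-subject gene clusters
#'
#' Contigs whose best significant hit is the same reference gene are grouped
#' into one cluster; the half-length rule ([count_genes()]) then decides how
#' many distinct genes the cluster represents. Rows without a significant
#' best hit are dropped (they cannot be clustered). Clusters inherit
#' category, family and subfamily from their members, which share a subject
#' and therefore a description.
#'
#' @param annotated Annotated contig tibble ([annotate_contigs()] layout),
#'   normally the `clean` element of [flag_contaminants()].
#' @return A tibble with one row per subject accession: subject fields,
#'   list-columns `members`, `member_lengths`, `member_stages`,
#'   `member_sequences`, the inferred gene count, the rule branch taken
#'   (`all_short` or `distinct_contigs`), a `mixed_lengths` audit flag, and
#'   `gene_length_bp` (summed distinct member length capped at the subject
#'   length) for expression normalization.
#' @export
cluster_by_subject <- function(annotated) {
  ann <- annotated[!is.na(annotated$subject_accession), , drop = FALSE]
  if (nrow(ann) == 0) {
    return(tibble::tibble(
      subject_accession = character(), subject_length_bp = integer(),
      category = character(), family = character(), subfamily = character(),
      n_members = integer(), members = list(), member_lengths = list(),
      member_stages = list(), member_sequences = list(),
      inferred_gene_count = integer(), rule_branch = character(),
      mixed_lengths = logical(), gene_length_bp = integer()
    ))
  }
  has_seq <- "sequence" %in% names(ann)
  has_stage <- "stage" %in% names(ann)
  ann |>
    dplyr::arrange(.data$subject_accession, .data$contig_id) |>
    dplyr::group_by(.data$subject_accession) |>
    dplyr::summarise(
      subject_length_bp = .data$subject_length_bp[1],
      category = .data$category[1],
      family = .data$family[1],
      subfamily = .data$subfamily[1],
      n_members = dplyr::n(),
      members = list(.data$contig_id),
      member_lengths = list(.data$length_bp),
      member_stages = list(if (has_stage) stage else rep(NA_character_, dplyr::n())),
      member_sequences = list(if (has_seq) sequence else NULL),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      counted = purrr::pmap(
        list(.data$member_lengths, .data$subject_length_bp, .data$member_sequences),
        function(lens, slen, seqs) count_genes(lens, slen, sequences = seqs, detail = TRUE)
      ),
      inferred_gene_count = purrr::map_int(.data$counted, "count"),
      rule_branch = purrr::map_chr(.data$counted, "branch"),
      mixed_lengths = purrr::map_lgl(.data$counted, "mixed"),
      gene_length_bp = purrr::map_int(.data$counted, "gene_length_bp"),
      gene_length_bp = pmin(.data$gene_length_bp, .data$subject_length_bp),
      counted = NULL
    )
}

#' Count inferred genes in one cluster with the half-length rule
#'
#' Contigs matching the same reference gene are different regions of a single
#' gene when *every* contig is shorter than half the reference length;
#' otherwise each distinct contig sequence is a different gene. Identical
#' sequences (the same contig assembled into several stage libraries) are
#' collapsed before counting when sequences are supplied; without sequences
#' every member is assumed distinct.
#'
#' @param member_lengths Integer vector of member contig lengths (bp).
#' @param subject_length_bp Length of the reference (subject) gene in bp;
#'   required — a cluster without it cannot be resolved.
#' @param sequences Optional character vector of member sequences, parallel
#'   to `member_lengths`, used only to collapse duplicates.
#' @param detail Return a list with the count, the branch taken, a
#'   mixed-length flag and the summed distinct length instead of a bare
#'   integer.
#' @return The inferred gene count (positive integer), or a detail list.
#' @export
#' @examples
#' count_genes(c(300, 400), 1000) # regions of one gene
#' count_genes(c(600, 700), 1000) # two genes
count_genes <- function(member_lengths, subject_length_bp, sequences = NULL,
                        detail = FALSE) {
  if (length(member_lengths) == 0) {
    stop("cluster has no members", call. = FALSE)
  }
  if (is.null(subject_length_bp) || length(subject_length_bp) != 1 ||
    is.na(subject_length_bp) || subject_length_bp <= 0) {
    stop("subject length missing: cluster cannot be resolved", call. = FALSE)
  }
  lens <- as.integer(member_lengths)
  if (!is.null(sequences) && length(sequences) == length(lens) &&
    !anyNA(sequences)) {
    keep <- !duplicated(sequences)
    lens <- lens[keep]
  }
  short <- lens < subject_length_bp / 2
  if (all(short)) {
    res <- list(count = 1L, branch = "all_short", mixed = FALSE)
  } else {
    res <- list(
      count = length(lens),
      branch = "distinct_contigs",
      mixed = any(short)
    )
  }
  res$gene_length_bp <- as.integer(sum(lens))
  if (detail) res else res$count
}

## Which stages is each cluster expressed in? A cluster is expressed in a
## stage when any member contig has >0 reads in that stage's library; when no
## counts are available the member contigs' library-of-origin labels are used.
cluster_stage_membership <- function(clusters, counts = NULL, stages) {
  members <- clusters |>
    dplyr::select("subject_accession", "members", "member_stages") |>
    tidyr::unnest(cols = c("members", "member_stages")) |>
    dplyr::rename(contig_id = "members", origin_stage = "member_stages")
  if (!is.null(counts)) {
    expressed <- counts[counts$reads > 0, c("contig_id", "stage")]
    mem <- members |>
      dplyr::inner_join(expressed, by = "contig_id") |>
      dplyr::select("subject_accession", "stage")
  } else {
    mem <- members |>
      dplyr::filter(!is.na(.data$origin_stage)) |>
      dplyr::select("subject_accession", stage = "origin_stage")
  }
  unknown <- setdiff(unique(mem$stage), stages)
  if (length(unknown) > 0) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(mem)
}

#' Gene-diversity table: inferred genes per stage and category
#'
#' Cell (stage, category) is the sum of inferred gene counts over clusters of
#' that category expressed in that stage. The final `All stages` row is
#' computed over the union of stages — a gene expressed in several stages is
#' counted once — so it is generally less than the column sums. Clusters
#' classified as `none` never enter the table.
#'
#' @param clusters Cluster tibble from [cluster_by_subject()].
#' @param counts Optional count tibble; when `NULL`, membership falls back to
#'   the member contigs' stage labels.
#' @param stages Stage order for the rows.
#' @return A tibble with columns `stage`, one per detox category, and
#'   `total`.
#' @export
diversity_table <- function(clusters, counts = NULL, stages = detox_stages()) {
  cats <- detox_categories()
  detox <- clusters[clusters$category %in% cats, , drop = FALSE]
  skeleton <- tibble::tibble(stage = c(stages, "All stages"))
  if (nrow(detox) == 0) {
    for (cc in cats) skeleton[[cc]] <- 0L
    skeleton$total <- 0L
    return(skeleton)
  }
  mem <- cluster_stage_membership(detox, counts = counts, stages = stages)
  per_stage <- mem |>
    dplyr::left_join(
      detox[, c("subject_accession", "category", "inferred_gene_count")],
      by = "subject_accession"
    )
  union_row <- per_stage |>
    dplyr::distinct(.data$subject_accession, .data$category, .data$inferred_gene_count) |>
    dplyr::mutate(stage = "All stages")
  cells <- dplyr::bind_rows(per_stage, union_row) |>
    dplyr::group_by(.data$stage, .data$category) |>
    dplyr::summarise(n = sum(.data$inferred_gene_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  out <- dplyr::left_join(skeleton, cells, by = "stage")
  for (cc in cats) {
    if (!cc %in% names(out)) out[[cc]] <- 0L
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  out <- out[, c("stage", cats)]
  out$total <- as.integer(rowSums(out[, cats]))
  out
}

#' Check that stage rows of a diversity table are internally consistent
#'
#' Verifies that every row's stated `total` equals the sum of its category
#' cells. Works on pipeline output and on transcribed published tables alike.
#'
#' @param table A tibble with a `stage` column, category count columns and a
#'   `total` column.
#' @return A tibble of violations (`stage`, `stated_total`, `category_sum`);
#'   zero rows means the table is consistent.
#' @export
check_table_consistency <- function(table) {
  empty <- tibble::tibble(
    stage = character(), stated_total = numeric(), category_sum = numeric()
  )
  if (nrow(table) == 0) {
    return(empty)
  }
  stopifnot(all(c("stage", "total") %in% names(table)))
  cat_cols <- setdiff(names(table), c("stage", "total"))
  sums <- rowSums(table[, cat_cols, drop = FALSE])
  bad <- which(sums != table$total)
  if (length(bad) == 0) {
    return(empty)
  }
  tibble::tibble(
    stage = table$stage[bad],
    stated_total = as.numeric(table$total[bad]),
    category_sum = as.numeric(sums[bad])
  )
}

#' Family-level gene counts, with subfamily sub-rows
#'
#' Rows are enzyme families plus sub-rows for the subfamilies tracked by the
#' ontology (CYP4, CYP6, sigma-GST, epsilon-GST); columns are the stages plus
#' an `all_stages` union column. A sub-row counts the subset of its family's
#' clusters carrying that subfamily, so it can never exceed the family row.
#'
#' @inheritParams diversity_table
#' @return A tibble with columns `category`, `family`, `subfamily` (empty
#'   for family-level rows), one column per stage, and `all_stages`.
#' @export
family_table <- function(clusters, counts = NULL, stages = detox_stages()) {
  cats <- detox_categories()
  detox <- clusters[clusters$category %in% cats, , drop = FALSE]
  if (nrow(detox) == 0) {
    return(tibble::tibble(
      category = character(), family = character(), subfamily = character(),
      all_stages = integer()
    ))
  }
  mem <- cluster_stage_membership(detox, counts = counts, stages = stages)
  info <- detox[, c(
    "subject_accession", "category", "family", "subfamily", "inferred_gene_count"
  )]
  long <- dplyr::bind_rows(
    dplyr::left_join(mem, info, by = "subject_accession"),
    dplyr::mutate(info, stage = "all_stages")
  )
  count_rows <- function(df, label) {
    df |>
      dplyr::group_by(.data$category, .data$family, .data$stage) |>
      dplyr::summarise(n = sum(.data$inferred_gene_count), .groups = "drop") |>
      dplyr::mutate(subfamily = label)
  }
  fam_rows <- count_rows(long, "")
  sub_rows <- long |>
    dplyr::filter(.data$subfamily != "") |>
    dplyr::group_by(.data$category, .data$family, .data$subfamily, .data$stage) |>
    dplyr::summarise(n = sum(.data$inferred_gene_count), .groups = "drop")
  wide <- dplyr::bind_rows(fam_rows, sub_rows) |>
    dplyr::mutate(stage = factor(.data$stage, levels = c(stages, "all_stages"))) |>
    tidyr::pivot_wider(
      names_from = "stage", values_from = "n",
      values_fill = 0L, names_expand = TRUE
    ) |>
    dplyr::arrange(
      factor(.data$category, levels = cats), .data$family, .data$subfamily
    )
  wide
}

#' Merge per-species family counts into a comparison table
#'
#' Combines a family table's union column with externally supplied
#' per-species count files (TSV with columns `family`, `count` and optional
#' `subfamily`), 0-filling families a species file lacks, to produce
#' cross-species comparisons of detox family sizes.
#'
#' @param family_counts Output of [family_table()] (or any tibble with
#'   `family`, `subfamily`, `all_stages`).
#' @param species Named list of TSV paths or tibbles, one per species.
#' @param study_label Column name for this study's counts.
#' @return A tibble with `family`, `subfamily` and one count column per
#'   species.
#' @export
merge_species_counts <- function(family_counts, species, study_label = "this_study") {
  out <- family_counts |>
    dplyr::select("family", "subfamily", !!study_label := "all_stages")
  for (sp in names(species)) {
    x <- species[[sp]]
    if (is.character(x) && length(x) == 1) {
      x <- readr::read_tsv(x, col_types = readr::cols(), progress = FALSE)
    }
    if (!all(c("family", "count") %in% names(x))) {
      stop("species table '", sp, "' needs columns family, count", call. = FALSE)
    }
    if (!"subfamily" %in% names(x)) x$subfamily <- ""
    x$subfamily[is.na(x$subfamily)] <- ""
    x <- dplyr::select(x, "family", "subfamily", !!sp := "count")
    out <- dplyr::full_join(out, x, by = c("family", "subfamily"))
  }
  count_cols <- setdiff(names(out), c("family", "subfamily"))
  out |>
    dplyr::mutate(dplyr::across(dplyr::all_of(count_cols), \(v) tidyr::replace_na(v, 0)))
}

#' Flatten clusters into a per-cluster audit table
#'
#' One row per cluster recording the members, their lengths, the rule branch
#' taken and whether the cluster mixed short and long contigs — everything a
#' reviewer needs to audit the half-length collapsing decisions.
#'
#' @param clusters Cluster tibble from [cluster_by_subject()].
#' @return A plain (list-column-free) tibble suitable for writing to TSV.
#' @export
cluster_audit <- function(clusters) {
  clusters |>
    dplyr::transmute(
      subject_accession = .data$subject_accession,
      subject_length_bp = .data$subject_length_bp,
      category = .data$category,
      family = .data$family,
      subfamily = .data$subfamily,
      n_members = .data$n_members,
      members = purrr::map_chr(.data$members, paste, collapse = ";"),
      member_lengths = purrr::map_chr(.data$member_lengths, paste, collapse = ";"),
      rule_branch = .data$rule_branch,
      mixed_lengths = .data$mixed_lengths,
      inferred_gene_count = .data$inferred_gene_count,
      gene_length_bp = .data$gene_length_bp
    )
}
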