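#' RPKM of a single gene
#'
#' Reads per kilobase of gene per million mapped reads:
#' `reads / ((total_mapped_reads / 1e6) * (gene_length_bp / 1000))`.
#' Vectorized over all three arguments.
#'
#' @param reads Non-negative read count(s) for the gene.
#' @param total_mapped_reads Positive total mapped reads of the stage
#'   library.
#' @param gene_length_bp Positive gene length in bp.
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' gene_rpkm(1000, 2e6, 500) # 1000
gene_rpkm <- function(reads, total_mapped_reads, gene_length_bp) {
  if (any(reads < 0)) stop("`reads` must be non-negative", call. = FALSE)
  if (any(total_mapped_reads <= 0)) {
    stop("`total_mapped_reads` must be positive", call. = FALSE)
  }
  if (any(gene_length_bp <= 0)) {
    stop("`gene_length_bp` must be positive", call. = FALSE)
  }
  reads / ((total_mapped_reads / 1e6) * (gene_length_bp / 1000))
}

#' Cumulative RPKM of a group of genes
#'
#' The group statistic divides the group's pooled reads by the *average*
#' gene length of the group (in kb) times the library size in millions:
#' `sum(reads) / ((total_mapped_reads / 1e6) * mean(gene_length_bp / 1000))`.
#' For a single-gene group this reduces to [gene_rpkm()]; for equal-length
#' genes it equals the sum of the members' per-gene RPKMs.
#'
#' @param reads Vector of per-gene read counts (one per group member).
#' @param gene_length_bp Vector of per-gene lengths in bp, parallel to
#'   `reads`.
#' @param total_mapped_reads Positive total mapped reads of the library.
#' @return A single numeric RPKM value.
#' @export
#' @examples
#' group_rpkm(c(100, 100), c(500, 1500), 1e6) # 200
group_rpkm <- function(reads, gene_length_bp, total_mapped_reads) {
  if (length(reads) == 0) stop("group is empty", call. = FALSE)
  if (length(gene_length_bp) != length(reads)) {
    stop("`reads` and `gene_length_bp` must have the same length", call. = FALSE)
  }
  if (any(reads < 0)) stop("`reads` must be non-negative", call. = FALSE)
  if (any(gene_length_bp <= 0)) {
    stop("`gene_length_bp` must be positive", call. = FALSE)
  }
  if (length(total_mapped_reads) != 1 || total_mapped_reads <= 0) {
    stop("`total_mapped_reads` must be a single positive number", call. = FALSE)
  }
  sum(reads) / ((total_mapped_reads / 1e6) * mean(gene_length_bp / 1000))
}

#' Normalized expression profiles per gene, family or category
#'
#' Builds one record per (group, stage). A cluster's reads in a stage are the
#' summed reads of its member contigs in that stage's library; clusters with
#' no reads in a stage contribute 0. Per-gene profiles use [gene_rpkm()] with
#' the cluster's gene length; family and category profiles pool reads and use
#' the group formula of [group_rpkm()] with the group's mean gene length.
#' Total mapped reads per stage are taken over the *whole* library (all
#' contigs in `counts`), not just the detox subset.
#'
#' @param clusters Cluster tibble from [cluster_by_subject()].
#' @param counts Long count tibble (`stage`, `contig_id`, `reads`).
#' @param grouping One of `"gene"`, `"family"`, `"category"`.
#' @param stages Stage order for the output.
#' @return A tibble (`group`, `stage`, `reads`, `length_kb`, `rpkm`) sorted
#'   by group then stage order.
#' @export
expression_profiles <- function(clusters, counts,
                                grouping = c("family", "category", "gene"),
                                stages = detox_stages()) {
  grouping <- match.arg(grouping)
  totals <- stage_totals(counts)
  missing_stage <- setdiff(stages, totals$stage)
  if (length(missing_stage) > 0) {
    stop(
      "count table has no library for stage(s): ",
      paste(missing_stage, collapse = ", "),
      call. = FALSE
    )
  }
  detox <- clusters[clusters$category %in% detox_categories(), , drop = FALSE]
  if (nrow(detox) == 0) {
    return(tibble::tibble(
      group = character(), stage = character(), reads = integer(),
      length_kb = numeric(), rpkm = numeric()
    ))
  }
  members <- detox |>
    dplyr::select("subject_accession", "category", "family", "gene_length_bp", "members") |>
    tidyr::unnest(cols = "members") |>
    dplyr::rename(contig_id = "members")
  cluster_reads <- tidyr::expand_grid(
    subject_accession = detox$subject_accession,
    stage = stages
  ) |>
    dplyr::left_join(
      members |>
        dplyr::inner_join(counts, by = "contig_id") |>
        dplyr::group_by(.data$subject_accession, .data$stage) |>
        dplyr::summarise(reads = sum(.data$reads), .groups = "drop"),
      by = c("subject_accession", "stage")
    ) |>
    dplyr::mutate(reads = tidyr::replace_na(.data$reads, 0L)) |>
    dplyr::left_join(
      detox[, c("subject_accession", "category", "family", "gene_length_bp")],
      by = "subject_accession"
    )
  group_col <- switch(grouping,
    gene = "subject_accession",
    family = "family",
    category = "category"
  )
  out <- cluster_reads |>
    dplyr::group_by(group = .data[[group_col]], .data$stage) |>
    dplyr::summarise(
      reads = sum(.data$reads),
      length_kb = mean(.data$gene_length_bp) / 1000,
      .groups = "drop"
    ) |>
    dplyr::left_join(totals, by = "stage") |>
    dplyr::mutate(
      rpkm = .data$reads / ((.data$total_mapped_reads / 1e6) * .data$length_kb)
    ) |>
    dplyr::select("group", "stage", "reads", "length_kb", "rpkm") |>
    dplyr::arrange(.data$group, factor(.data$stage, levels = stages))
  out
}

#' Bar-profile plot of expression across stages
#'
#' One panel per group, bars in stage order — the usual way stage-resolved
#' normalized expression of enzyme groups is displayed.
#'
#' @param profiles Output of [expression_profiles()].
#' @param stages Stage order for the x axis.
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(profiles, stages = detox_stages()) {
  profiles$stage <- factor(profiles$stage, levels = stages)
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$stage, y = .data$rpkm)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Expression (RPKM)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
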