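#' Configuration for an end-to-end pipeline run
#'
#' Validates paths and options up front so configuration mistakes surface
#' before any computation.
#'
#' @param contigs,hits,counts Paths to the contig FASTA, the hit TSV and the
#'   long-format count TSV. `counts` may be `NULL` (stage membership then
#'   falls back to contig stage labels and no expression table is produced).
#' @param ontology Path to an ontology TSV/YAML, or `NULL` for
#'   [default_ontology()].
#' @param taxonomy_map Optional path to an accession-to-kingdom TSV.
#' @param evalue_max Significance threshold (default 0.001).
#' @param stages Stage order used in all tables.
#' @param out_dir Output directory for the report TSVs.
#' @return A validated list of class `detox_run_config`.
#' @export
run_config <- function(contigs, hits, counts = NULL, ontology = NULL,
                       taxonomy_map = NULL, evalue_max = 0.001,
                       stages = detox_stages(), out_dir = ".") {
  config_error <- function(...) {
    stop(errorCondition(paste0(...), class = "detox_config_error"))
  }
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    config_error("`evalue_max` must be positive")
  }
  for (nm in c("contigs", "hits")) {
    p <- get(nm)
    if (!is.character(p) || !file.exists(p)) {
      config_error("input file for `", nm, "` not found: ", p)
    }
  }
  for (nm in c("counts", "ontology", "taxonomy_map")) {
    p <- get(nm)
    if (!is.null(p) && !file.exists(p)) {
      config_error("input file for `", nm, "` not found: ", p)
    }
  }
  structure(
    list(
      contigs = contigs, hits = hits, counts = counts, ontology = ontology,
      taxonomy_map = taxonomy_map, evalue_max = evalue_max, stages = stages,
      out_dir = out_dir
    ),
    class = "detox_run_config"
  )
}

#' Run the full cataloguing pipeline
#'
#' Reads the inputs, annotates contigs (significance filter, best hit,
#' ontology classification), removes contaminants, collapses contigs into
#' inferred genes, and writes the report files to `config$out_dir`:
#' `annotation.tsv`, `contamination_summary.tsv`, `diversity_table.tsv`,
#' `family_table.tsv`, `cluster_audit.tsv` and (when counts are available)
#' `expression_family.tsv`. Output files are staged in a temporary directory
#' and only moved into place when every stage succeeded, so a failed run
#' leaves no partial outputs. Errors are prefixed with the pipeline stage
#' that raised them.
#'
#' @param config A [run_config()] object.
#' @return A run summary list: input sizes, number of contigs with
#'   significant hits, the fraction of significant best hits with E-value at
#'   or below 1e-05 (a standard annotation-quality diagnostic), per-kingdom
#'   removed-contaminant fractions, the total detox gene count, the tables
#'   themselves, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "detox_run_config"))
  at_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        paste0("[", stage, "] ", conditionMessage(e)),
        class = "detox_stage_error"
      ))
    })
  }
  ontology <- at_stage(
    "config",
    if (is.null(config$ontology)) default_ontology() else read_ontology(config$ontology)
  )
  contigs <- at_stage("read_contigs", read_contigs_fasta(config$contigs))
  hits <- at_stage("read_hits", read_hits(config$hits, taxonomy_map = config$taxonomy_map))
  counts <- at_stage(
    "read_counts",
    if (is.null(config$counts)) NULL else read_counts(config$counts)
  )

  annotated <- at_stage(
    "annotate",
    annotate_contigs(contigs, hits, ontology = ontology, evalue_max = config$evalue_max)
  )
  decon <- at_stage("contaminants", flag_contaminants(annotated))
  clusters <- at_stage("cluster", cluster_by_subject(decon$clean))
  div <- at_stage(
    "diversity",
    diversity_table(clusters, counts = counts, stages = config$stages)
  )
  fam <- at_stage(
    "diversity",
    family_table(clusters, counts = counts, stages = config$stages)
  )
  expr <- if (!is.null(counts)) {
    at_stage(
      "expression",
      expression_profiles(clusters, counts, grouping = "family", stages = config$stages)
    )
  } else {
    NULL
  }

  sig_best <- annotated[annotated$has_hit, , drop = FALSE]
  summary <- list(
    n_contigs = nrow(contigs),
    n_hits = nrow(hits),
    n_contigs_with_significant_hit = nrow(sig_best),
    fraction_evalue_le_1e5 = if (nrow(sig_best) > 0) {
      mean(sig_best$evalue <= 1e-5)
    } else {
      NA_real_
    },
    contamination = decon$summary,
    n_clusters = nrow(clusters),
    total_detox_genes = div$total[div$stage == "All stages"],
    diversity_table = div,
    family_table = fam,
    expression = expr
  )

  staging <- file.path(tempfile("detoxdiv-out-"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  drop_lists <- function(x) x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(drop_lists(annotated), file.path(staging, "annotation.tsv"))
  readr::write_tsv(decon$summary, file.path(staging, "contamination_summary.tsv"))
  readr::write_tsv(div, file.path(staging, "diversity_table.tsv"))
  readr::write_tsv(fam, file.path(staging, "family_table.tsv"))
  readr::write_tsv(cluster_audit(clusters), file.path(staging, "cluster_audit.tsv"))
  if (!is.null(expr)) {
    readr::write_tsv(expr, file.path(staging, "expression_family.tsv"))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- list.files(staging)
  ok <- file.copy(
    file.path(staging, produced), file.path(config$out_dir, produced),
    overwrite = TRUE
  )
  if (!all(ok)) stop("failed to write outputs to ", config$out_dir, call. = FALSE)
  summary$outputs <- file.path(config$out_dir, produced)
  summary
}

#' Mean read length from totals
#'
#' Sequencing-run summaries report a read count and a total base count; the
#' mean read length is their ratio, rounded half-up to the nearest integer
#' base.
#'
#' @param read_count Positive number of reads.
#' @param total_bases Total sequenced bases.
#' @return Integer mean read length.
#' @export
#' @examples
#' summarize_reads(837010, 355789178) # 425
summarize_reads <- function(read_count, total_bases) {
  if (length(read_count) != 1 || is.na(read_count) || read_count <= 0) {
    stop("`read_count` must be a single positive number", call. = FALSE)
  }
  if (length(total_bases) != 1 || is.na(total_bases) || total_bases < 0) {
    stop("`total_bases` must be a single non-negative number", call. = FALSE)
  }
  as.integer(floor(total_bases / read_count + 0.5))
}
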