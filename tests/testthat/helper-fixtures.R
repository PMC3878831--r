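# Shared fixture builders: everything is generated in code, nothing on disk.

make_hit <- function(query = "c1", subject = "g1", evalue = 1e-10,
                     bit_score = 100, kingdom = "animal",
                     description = "catalase isoform 1",
                     subject_length = 1000L, alignment_length = 100L,
                     identity = 90) {
  tibble::tibble(
    query_id = query,
    subject_accession = subject,
    percent_identity = identity,
    alignment_length_bp = as.integer(alignment_length),
    evalue = evalue,
    bit_score = bit_score,
    subject_length_bp = as.integer(subject_length),
    subject_kingdom = kingdom,
    subject_description = description
  )
}

make_contig <- function(id = "c1", length_bp = 500L, stage = "Egg",
                        sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep("ACGT", ceiling(length_bp / 4)), collapse = "")
    sequence <- substr(sequence, 1, length_bp)
  }
  tibble::tibble(
    contig_id = id, length_bp = as.integer(length_bp),
    stage = stage, sequence = sequence
  )
}

# A small but complete simulation configuration; override any field.
small_params <- function(...) {
  defaults <- list(
    n_genes_per_category = c(
      oxidation_reduction = 4, conjugation = 3, hydrolysis = 3,
      other = 2, none = 4
    ),
    contaminant_fraction = 0.2,
    fragmentation_rate = 1.5,
    short_fragment_prob = 0.4,
    read_depth_per_stage = 2e4,
    decoy_rate = 0.5,
    seed = 11L
  )
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
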