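## Families the generator can draw descriptions from, with a sprintf template
## per (family, subfamily) so every emitted description is classifiable by
## default_ontology(). Background ("none") templates deliberately match no rule.
family_catalog <- function() {
  tibble::tribble(
    ~category, ~family, ~subfamily, ~template, ~weight,
    "oxidation_reduction", "cytochrome P450", "CYP4", "cytochrome P450 CYP4G%d", 1,
    "oxidation_reduction", "cytochrome P450", "CYP6", "cytochrome P450 CYP6AS%d", 2,
    "oxidation_reduction", "cytochrome P450", "", "cytochrome P450 306a1-like isoform %d", 1,
    "oxidation_reduction", "aldehyde dehydrogenase", "", "aldehyde dehydrogenase family member %d", 1,
    "oxidation_reduction", "alcohol dehydrogenase", "", "alcohol dehydrogenase class-%d", 1,
    "oxidation_reduction", "catalase", "", "catalase isoform %d", 1,
    "oxidation_reduction", "peroxidase", "", "peroxidase precursor %d", 1,
    "oxidation_reduction", "superoxide dismutase", "", "superoxide dismutase [Cu-Zn] %d", 1,
    "oxidation_reduction", "oxidoreductase", "", "NAD(P)H-dependent oxidoreductase %d", 1,
    "oxidation_reduction", "thioredoxin/glutaredoxin", "", "thioredoxin domain-containing protein %d", 1,
    "conjugation", "glutathione S-transferase", "sigma-GST", "glutathione S-transferase sigma class %d", 1,
    "conjugation", "glutathione S-transferase", "epsilon-GST", "glutathione S-transferase epsilon class %d", 1,
    "conjugation", "glutathione S-transferase", "", "glutathione S-transferase D%d", 2,
    "conjugation", "acetyltransferase", "", "arylamine N-acetyltransferase %d", 1,
    "conjugation", "acyltransferase", "", "acyl-CoA acyltransferase %d", 1,
    "conjugation", "glycosyltransferase", "", "glycosyltransferase family protein %d", 1,
    "conjugation", "methyltransferase", "", "S-adenosylmethionine-dependent methyltransferase %d", 1,
    "conjugation", "sulfotransferase", "", "cytosolic sulfotransferase %d", 1,
    "conjugation", "transaminase", "", "alanine aminotransferase %d", 1,
    "hydrolysis", "carboxylesterase/esterase", "", "carboxylesterase clade %d", 2,
    "hydrolysis", "glycosidase", "", "alpha-glucosidase isoform %d", 1,
    "hydrolysis", "aminopeptidase", "", "membrane alanyl aminopeptidase %d", 1,
    "hydrolysis", "nitrilase", "", "nitrilase homolog %d", 1,
    "hydrolysis", "amidase", "", "fatty acid amidase %d", 1,
    "hydrolysis", "acid/alkaline phosphatase", "", "alkaline phosphatase %d", 1,
    "hydrolysis", "phosphodiesterase", "", "cyclic nucleotide phosphodiesterase %d", 1,
    "other", "ABC transporter", "", "ABC transporter G family member %d", 1,
    "other", "heat shock protein", "", "heat shock protein 70-%d", 2,
    "other", "cadherin", "", "cadherin-like protein %d", 1,
    "other", "isomerase", "", "peptidyl-prolyl cis-trans isomerase %d", 1,
    "other", "lyase", "", "carbon-sulfur lyase %d", 1
  )
}

background_templates <- function() {
  c(
    "ribosomal protein L%d", "actin-related protein %d",
    "elongation factor 1-alpha isoform %d", "tubulin alpha-%d chain",
    "histone H2A variant %d", "ATP synthase subunit %d",
    "cuticular protein %d", "vitellogenin-like protein %d"
  )
}

#' Parameters for the synthetic transcriptome generator
#'
#' Bundles every knob of the simulator with validation. The defaults emulate
#' a pooled bumble-bee life-stage survey: eight stage libraries, 50
#' detoxification genes split across the four categories roughly in the
#' proportions seen in such surveys, a background of housekeeping genes,
#' a ~30% contaminant fraction (bacterial-heavy, then plant, then fungal)
#' among the detox candidates, and stage-specific expression multipliers
#' (GSTs up in immatures and especially pupae, nitrilases and
#' oxidoreductases up in late instars, glycosidases up in adult females,
#' heat shock proteins up in eggs and queens).
#'
#' @param n_genes_per_category Named integer vector of animal gene counts per
#'   category; names from [detox_categories()] plus `"none"` for
#'   non-detox background genes.
#' @param contaminant_fraction Proportion of all reference genes that are
#'   contaminant (non-animal) sources, in `[0, 1)`. Contaminant genes are
#'   generated in addition to `n_genes_per_category` so that the category
#'   counts stay exact: `n_contaminant = round(f / (1 - f) * n_animal)`.
#' @param contaminant_kingdoms Named numeric weights over
#'   `bacteria`/`plant`/`fungi` for contaminant gene kingdoms.
#' @param stages Character vector of stage library labels.
#' @param fragmentation_rate Mean number of contigs per gene (>= 1); each gene
#'   yields `1 + Poisson(rate - 1)` contigs.
#' @param short_fragment_prob Probability that a contig is shorter than half
#'   its source gene.
#' @param read_depth_per_stage Named vector of expected total mapped reads
#'   per stage (a single unnamed value recycles to all stages).
#' @param expression_profile Tibble (`stage`, `family`, `multiplier`) of
#'   relative expression multipliers; unlisted combinations default to 1.
#' @param dispersion Negative-binomial dispersion of counts (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param decoy_rate Mean number of decoy (wrong-subject, worse-E-value) hits
#'   per contig.
#' @param seed Integer seed; all four generators are deterministic given it.
#' @return A validated list of class `detox_sim_params`.
#' @export
#' @examples
#' p <- sim_params(seed = 7)
#' genes <- generate_reference_set(p)
sim_params <- function(n_genes_per_category = c(
                         oxidation_reduction = 17, conjugation = 9,
                         hydrolysis = 12, other = 12, none = 30
                       ),
                       contaminant_fraction = 0.3,
                       contaminant_kingdoms = c(bacteria = 0.463, plant = 0.416, fungi = 0.121),
                       stages = detox_stages(),
                       fragmentation_rate = 2,
                       short_fragment_prob = 0.4,
                       read_depth_per_stage = 1e5,
                       expression_profile = default_expression_profile(stages),
                       dispersion = 0.2,
                       decoy_rate = 1,
                       seed = 1L) {
  bad_names <- setdiff(names(n_genes_per_category), c(detox_categories(), "none"))
  if (is.null(names(n_genes_per_category)) || length(bad_names) > 0) {
    stop("`n_genes_per_category` must be named by category (plus 'none'); bad: ",
      paste(bad_names, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(n_genes_per_category < 0) || sum(n_genes_per_category) < 1) {
    stop("`n_genes_per_category` must be non-negative with a positive total", call. = FALSE)
  }
  if (!is.numeric(contaminant_fraction) || contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("`contaminant_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (is.null(names(contaminant_kingdoms)) ||
    !all(names(contaminant_kingdoms) %in% c("bacteria", "plant", "fungi")) ||
    any(contaminant_kingdoms < 0)) {
    stop("`contaminant_kingdoms` must be non-negative weights named bacteria/plant/fungi",
      call. = FALSE
    )
  }
  if (length(stages) < 1 || anyDuplicated(stages) > 0) {
    stop("`stages` must be a non-empty vector of unique labels", call. = FALSE)
  }
  if (fragmentation_rate < 1) stop("`fragmentation_rate` must be >= 1", call. = FALSE)
  if (short_fragment_prob < 0 || short_fragment_prob > 1) {
    stop("`short_fragment_prob` must be in [0, 1]", call. = FALSE)
  }
  if (length(read_depth_per_stage) == 1 && is.null(names(read_depth_per_stage))) {
    read_depth_per_stage <- stats::setNames(rep(read_depth_per_stage, length(stages)), stages)
  }
  if (!all(stages %in% names(read_depth_per_stage)) || any(read_depth_per_stage <= 0)) {
    stop("`read_depth_per_stage` must give a positive depth for every stage", call. = FALSE)
  }
  if (!all(c("stage", "family", "multiplier") %in% names(expression_profile)) ||
    any(expression_profile$multiplier < 0)) {
    stop("`expression_profile` needs stage/family/multiplier columns with multipliers >= 0",
      call. = FALSE
    )
  }
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (decoy_rate < 0) stop("`decoy_rate` must be >= 0", call. = FALSE)
  structure(
    list(
      n_genes_per_category = n_genes_per_category,
      contaminant_fraction = contaminant_fraction,
      contaminant_kingdoms = contaminant_kingdoms / sum(contaminant_kingdoms),
      stages = stages,
      fragmentation_rate = fragmentation_rate,
      short_fragment_prob = short_fragment_prob,
      read_depth_per_stage = read_depth_per_stage[stages],
      expression_profile = expression_profile,
      dispersion = dispersion,
      decoy_rate = decoy_rate,
      seed = as.integer(seed)
    ),
    class = "detox_sim_params"
  )
}

#' Default stage-by-family expression multipliers
#'
#' Encodes the qualitative stage patterns the simulator emulates: glutathione
#' S-transferases elevated in immatures and highest in pupae (and low in
#' eggs), nitrilases and oxidoreductases elevated in late instars,
#' glycosidases elevated in adult workers and egglaying queens, heat shock
#' proteins elevated in eggs and queens and low in males. All other
#' (stage, family) pairs default to 1.
#'
#' @param stages Stage labels the profile should cover.
#' @return Tibble with columns `stage`, `family`, `multiplier`.
#' @export
default_expression_profile <- function(stages = detox_stages()) {
  prof <- tibble::tribble(
    ~stage, ~family, ~multiplier,
    "Pupa", "glutathione S-transferase", 4,
    "Early instars", "glutathione S-transferase", 2,
    "Late instars", "glutathione S-transferase", 2,
    "Egg", "glutathione S-transferase", 0.3,
    "Late instars", "nitrilase", 3,
    "Late instars", "oxidoreductase", 2,
    "Adult worker", "glycosidase", 3,
    "Egglaying queen", "glycosidase", 3,
    "Egg", "heat shock protein", 3,
    "Diapausing queen", "heat shock protein", 3,
    "Egglaying queen", "heat shock protein", 3,
    "Adult male", "heat shock protein", 0.3
  )
  prof[prof$stage %in% stages, ]
}

#' Generate a synthetic reference gene set
#'
#' Draws animal genes per category exactly as requested in
#' `n_genes_per_category`, then adds contaminant genes (bacterial, plant,
#' fungal, in the configured proportions) so that contaminants make up
#' `contaminant_fraction` of the whole set. Contaminant genes carry
#' detox-family descriptions: they are detox candidates that only taxonomy
#' distinguishes, which is exactly what the contaminant filter must handle.
#'
#' @param params A [sim_params()] object.
#' @return Tibble with columns `accession`, `length_bp`, `kingdom`,
#'   `category`, `family`, `subfamily`, `description`.
#' @export
generate_reference_set <- function(params) {
  stopifnot(inherits(params, "detox_sim_params"))
  withr::with_seed(params$seed, {
    catalog <- family_catalog()
    n_animal <- sum(params$n_genes_per_category)
    f <- params$contaminant_fraction
    n_contaminant <- round(f / (1 - f) * n_animal)
    draw_gene <- function(category, kingdom, serial) {
      if (category == "none") {
        tmpl <- sample(background_templates(), 1)
        fam <- ""
        sub <- ""
      } else {
        rows <- catalog[catalog$category == category, ]
        pick <- rows[sample.int(nrow(rows), 1, prob = rows$weight), ]
        tmpl <- pick$template
        fam <- pick$family
        sub <- pick$subfamily
      }
      tibble::tibble(
        accession = sprintf("REF%05d", serial),
        length_bp = sample(400:3000, 1),
        kingdom = kingdom,
        category = category,
        family = fam,
        subfamily = sub,
        description = sprintf(tmpl, serial)
      )
    }
    serial <- 0
    animal <- purrr::imap_dfr(params$n_genes_per_category, function(n, category) {
      if (n == 0) {
        return(NULL)
      }
      purrr::map_dfr(seq_len(n), function(i) {
        serial <<- serial + 1
        draw_gene(category, "animal", serial)
      })
    })
    contaminant <- NULL
    if (n_contaminant > 0) {
      kingdom_counts <- stats::rmultinom(1, n_contaminant, params$contaminant_kingdoms)[, 1]
      kingdoms <- rep(names(kingdom_counts), kingdom_counts)
      detox_cats <- intersect(names(params$n_genes_per_category), detox_categories())
      if (length(detox_cats) == 0) detox_cats <- detox_categories()
      contaminant <- purrr::map_dfr(kingdoms, function(k) {
        serial <<- serial + 1
        draw_gene(sample(detox_cats, 1), k, serial)
      })
    }
    dplyr::bind_rows(animal, contaminant)
  })
}

#' Fragment reference genes into contigs
#'
#' Each gene yields `1 + Poisson(fragmentation_rate - 1)` contigs. With
#' probability `short_fragment_prob` a contig is drawn shorter than half its
#' gene (a "region" under the half-length collapsing rule), otherwise between
#' half and full gene length. Sequences are uniform-random nucleotides —
#' similarity enters the pipeline through the hit table, not through
#' alignment — and each contig is assigned a stage library of origin.
#'
#' @param genes Reference genes from [generate_reference_set()].
#' @param params A [sim_params()] object.
#' @return List with `contigs` (tibble `contig_id`, `length_bp`, `stage`,
#'   `sequence`) and `map`, the ground-truth tibble (`contig_id`,
#'   `accession`) resolving every contig to its source gene.
#' @export
simulate_contigs <- function(genes, params) {
  stopifnot(inherits(params, "detox_sim_params"))
  if (nrow(genes) == 0) stop("`genes` must be non-empty", call. = FALSE)
  withr::with_seed(params$seed + 1L, {
    n_contigs <- 1L + stats::rpois(nrow(genes), params$fragmentation_rate - 1)
    rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      purrr::map_dfr(seq_len(n_contigs[i]), function(j) {
        short <- stats::runif(1) < params$short_fragment_prob
        half <- ceiling(g$length_bp / 2)
        len <- if (short) {
          sample(100:(half - 1), 1)
        } else {
          sample(half:g$length_bp, 1)
        }
        tibble::tibble(
          accession = g$accession,
          length_bp = as.integer(len),
          stage = sample(params$stages, 1),
          sequence = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
        )
      })
    })
    rows$contig_id <- sprintf("ctg%05d", seq_len(nrow(rows)))
    list(
      contigs = rows[, c("contig_id", "length_bp", "stage", "sequence")],
      map = rows[, c("contig_id", "accession")]
    )
  })
}

#' Simulate a BLAST-style hit table for synthetic contigs
#'
#' Every contig receives one hit against its true source gene with
#' E-value at most 0.001 (log10 E-value uniform on \[-40, -3\], so a little
#' over 94% of true hits fall at or below 1e-05) plus `Poisson(decoy_rate)`
#' decoy hits against other genes with strictly worse E-values and lower bit
#' scores, so best-hit selection is well-defined and the true gene always
#' wins.
#'
#' @param contigs Contig tibble from [simulate_contigs()].
#' @param contig_map Ground-truth `contig_id`/`accession` map.
#' @param genes Reference gene tibble.
#' @param params A [sim_params()] object.
#' @return A hit tibble in the layout of [read_hits()].
#' @export
simulate_hits <- function(contigs, contig_map, genes, params) {
  stopifnot(inherits(params, "detox_sim_params"))
  if (!all(contigs$contig_id %in% contig_map$contig_id)) {
    stop("every contig must be present in `contig_map`", call. = FALSE)
  }
  withr::with_seed(params$seed + 2L, {
    gidx <- match(contig_map$accession[match(contigs$contig_id, contig_map$contig_id)], genes$accession)
    if (anyNA(gidx)) stop("contig map refers to unknown gene accessions", call. = FALSE)
    rows <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
      ctg <- contigs[i, ]
      g <- genes[gidx[i], ]
      aln <- max(50L, as.integer(round(ctg$length_bp * stats::runif(1, 0.7, 1))))
      true_e <- 10^(-stats::runif(1, 3, 40))
      true_bit <- round(aln * stats::runif(1, 1.2, 2.0), 1)
      true_hit <- tibble::tibble(
        query_id = ctg$contig_id,
        subject_accession = g$accession,
        percent_identity = round(stats::runif(1, 75, 100), 2),
        alignment_length_bp = aln,
        evalue = true_e,
        bit_score = true_bit,
        subject_length_bp = g$length_bp,
        subject_kingdom = g$kingdom,
        subject_description = g$description
      )
      n_decoys <- stats::rpois(1, params$decoy_rate)
      n_decoys <- min(n_decoys, nrow(genes) - 1L)
      if (n_decoys == 0) {
        return(true_hit)
      }
      others <- genes[-gidx[i], ][sample.int(nrow(genes) - 1L, n_decoys), ]
      decoys <- purrr::map_dfr(seq_len(n_decoys), function(d) {
        og <- others[d, ]
        daln <- max(40L, as.integer(round(aln * stats::runif(1, 0.4, 0.9))))
        tibble::tibble(
          query_id = ctg$contig_id,
          subject_accession = og$accession,
          percent_identity = round(stats::runif(1, 40, 80), 2),
          alignment_length_bp = daln,
          evalue = min(true_e * 10^stats::runif(1, 2, 10), 10),
          bit_score = round(max(20, true_bit - stats::runif(1, 20, 80)), 1),
          subject_length_bp = og$length_bp,
          subject_kingdom = og$kingdom,
          subject_description = og$description
        )
      })
      dplyr::bind_rows(true_hit, decoys)
    })
    rows
  })
}

#' Simulate per-stage mapped-read counts for synthetic contigs
#'
#' The expected count of contig *c* in stage *s* is
#' `depth[s] * length_kb[c] * multiplier(s, family[c]) / sum(length_kb)`,
#' so expression scales with contig length (longer transcripts collect more
#' reads), doubling a family's multiplier doubles its expected counts, and a
#' multiplier of zero silences the family exactly. Counts are
#' negative-binomial with the configured dispersion (Poisson when 0).
#'
#' @inheritParams simulate_hits
#' @return A long count tibble (`stage`, `contig_id`, `reads`) covering every
#'   stage-contig pair.
#' @export
simulate_read_counts <- function(contigs, contig_map, genes, params) {
  stopifnot(inherits(params, "detox_sim_params"))
  withr::with_seed(params$seed + 3L, {
    fam <- genes$family[match(
      contig_map$accession[match(contigs$contig_id, contig_map$contig_id)],
      genes$accession
    )]
    len_kb <- contigs$length_bp / 1000
    base_scale <- sum(len_kb)
    grid <- tidyr::expand_grid(
      stage = params$stages,
      idx = seq_len(nrow(contigs))
    )
    grid$contig_id <- contigs$contig_id[grid$idx]
    grid$family <- fam[grid$idx]
    grid <- dplyr::left_join(
      grid,
      params$expression_profile,
      by = c("stage", "family")
    )
    grid$multiplier[is.na(grid$multiplier)] <- 1
    mu <- params$read_depth_per_stage[grid$stage] *
      len_kb[grid$idx] * grid$multiplier / base_scale
    reads <- if (params$dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
    }
    reads[mu == 0] <- 0L
    tibble::tibble(
      stage = grid$stage,
      contig_id = grid$contig_id,
      reads = as.integer(reads)
    )
  })
}

#' Generate a complete synthetic dataset, optionally writing it to disk
#'
#' Runs the four generators in sequence and, when `dir` is given, writes the
#' pipeline's input files (`contigs.fasta`, `hits.tsv`, `counts.tsv`,
#' `ontology.tsv`) plus a `truth.yaml` ground-truth manifest recording the
#' reference genes, the contig-to-gene map, and the true per-category gene
#' counts, for recovery tests.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional output directory (created if needed).
#' @return List with `genes`, `contigs`, `map`, `hits`, `counts`, `truth`
#'   and, when written, `paths`.
#' @export
simulate_dataset <- function(params = sim_params(), dir = NULL) {
  genes <- generate_reference_set(params)
  cm <- simulate_contigs(genes, params)
  hits <- simulate_hits(cm$contigs, cm$map, genes, params)
  counts <- simulate_read_counts(cm$contigs, cm$map, genes, params)
  truth <- list(
    n_genes = nrow(genes),
    category_counts = as.list(table(genes$category[genes$kingdom == "animal"])),
    kingdom_counts = as.list(table(genes$kingdom)),
    genes = purrr::pmap(genes, function(...) as.list(list(...))),
    contig_map = stats::setNames(as.list(cm$map$accession), cm$map$contig_id)
  )
  out <- list(
    genes = genes, contigs = cm$contigs, map = cm$map,
    hits = hits, counts = counts, truth = truth
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      contigs = file.path(dir, "contigs.fasta"),
      hits = file.path(dir, "hits.tsv"),
      counts = file.path(dir, "counts.tsv"),
      ontology = file.path(dir, "ontology.tsv"),
      truth = file.path(dir, "truth.yaml")
    )
    write_contigs_fasta(cm$contigs, paths$contigs)
    write_hits(hits, paths$hits)
    write_counts(counts, paths$counts)
    write_ontology(default_ontology(), paths$ontology)
    yaml::write_yaml(truth, paths$truth)
    out$paths <- paths
  }
  out
}
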