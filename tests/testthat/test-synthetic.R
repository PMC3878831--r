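test_that("reference set honours category counts and contamination", {
  p <- sim_params(
    n_genes_per_category = c(oxidation_reduction = 5),
    contaminant_fraction = 0
  )
  genes <- generate_reference_set(p)
  expect_equal(nrow(genes), 5)
  expect_true(all(genes$kingdom == "animal"))
  expect_true(all(genes$category == "oxidation_reduction"))

  p2 <- sim_params(
    n_genes_per_category = c(
      oxidation_reduction = 25, conjugation = 15, hydrolysis = 20, other = 10
    ),
    contaminant_fraction = 0.3
  )
  genes2 <- generate_reference_set(p2)
  expect_equal(nrow(genes2), 100)
  expect_equal(sum(genes2$kingdom != "animal"), 30)
  animal_counts <- table(genes2$category[genes2$kingdom == "animal"])
  expect_equal(animal_counts[["oxidation_reduction"]], 25)
  expect_equal(animal_counts[["conjugation"]], 15)
  expect_equal(animal_counts[["hydrolysis"]], 20)
  expect_equal(animal_counts[["other"]], 10)
})

test_that("every generator is deterministic given the seed", {
  p <- small_params()
  a <- simulate_dataset(p)
  b <- simulate_dataset(p)
  expect_identical(a$genes, b$genes)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$map, b$map)
  expect_identical(a$hits, b$hits)
  expect_identical(a$counts, b$counts)

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_contigs_fasta(a$contigs, f1)
  write_contigs_fasta(b$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parameter validation names the offending field", {
  expect_error(sim_params(contaminant_fraction = 1.2), "contaminant_fraction")
  expect_error(sim_params(fragmentation_rate = 0.5), "fragmentation_rate")
  expect_error(sim_params(short_fragment_prob = -0.1), "short_fragment_prob")
  expect_error(
    sim_params(n_genes_per_category = c(bogus_category = 5)),
    "n_genes_per_category"
  )
  expect_error(sim_params(dispersion = -1), "dispersion")
})

test_that("fragmentation controls contig number and length", {
  p <- small_params(fragmentation_rate = 1, short_fragment_prob = 0)
  genes <- generate_reference_set(p)
  cm <- simulate_contigs(genes, p)
  expect_equal(nrow(cm$contigs), nrow(genes)) # one contig per gene
  joined <- dplyr::left_join(cm$map, genes, by = "accession")
  expect_true(all(cm$contigs$length_bp >= joined$length_bp / 2))
  expect_true(all(cm$contigs$length_bp <= joined$length_bp))

  p1 <- small_params(short_fragment_prob = 1)
  genes1 <- generate_reference_set(p1)
  cm1 <- simulate_contigs(genes1, p1)
  joined1 <- dplyr::left_join(cm1$map, genes1, by = "accession")
  expect_true(all(cm1$contigs$length_bp < joined1$length_bp / 2))
  # every contig resolves to exactly one true gene
  expect_setequal(cm1$contigs$contig_id, cm1$map$contig_id)
  expect_equal(anyDuplicated(cm1$map$contig_id), 0)
})

test_that("the true gene is always the strict best hit", {
  p <- small_params(decoy_rate = 2)
  d <- simulate_dataset(p)
  truth <- setNames(d$map$accession, d$map$contig_id)
  by_query <- split(d$hits, d$hits$query_id)
  for (q in names(by_query)) {
    h <- by_query[[q]]
    true_row <- h[h$subject_accession == truth[[q]], ]
    expect_equal(nrow(true_row), 1)
    expect_lte(true_row$evalue, 0.001)
    decoys <- h[h$subject_accession != truth[[q]], ]
    if (nrow(decoys) > 0) {
      expect_true(all(decoys$evalue > true_row$evalue))
      expect_true(all(decoys$bit_score < true_row$bit_score))
    }
  }
  # emitted table round-trips unchanged through the reader
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(d$hits, f)
  expect_equal(as.data.frame(read_hits(f)), as.data.frame(d$hits), tolerance = 1e-12)
})

test_that("read counts respect the expression profile", {
  p <- small_params(
    expression_profile = tibble::tibble(
      stage = "Pupa", family = "", multiplier = 0
    )
  )
  # multiplier 0 for the background family silences it in that stage
  d <- simulate_dataset(p)
  bg_genes <- d$genes$accession[d$genes$family == ""]
  bg_contigs <- d$map$contig_id[d$map$accession %in% bg_genes]
  pupa <- d$counts[d$counts$stage == "Pupa", ]
  expect_true(all(pupa$reads[pupa$contig_id %in% bg_contigs] == 0))
  expect_gt(sum(pupa$reads[!pupa$contig_id %in% bg_contigs]), 0)

  # per-stage totals are conserved
  tot <- stage_totals(d$counts)
  manual <- tapply(d$counts$reads, d$counts$stage, sum)
  expect_equal(tot$total_mapped_reads, as.integer(manual[tot$stage]), ignore_attr = TRUE)
})

test_that("doubling a family multiplier doubles its mean count", {
  # one gene, 10,000 identical contigs, two stages differing only in the
  # multiplier: the Monte-Carlo mean must scale by 2 within 5%
  n <- 10000
  genes <- tibble::tibble(
    accession = "REF00001", length_bp = 1000L, kingdom = "animal",
    category = "conjugation", family = "glutathione S-transferase",
    subfamily = "", description = "glutathione S-transferase D1"
  )
  contigs <- tibble::tibble(
    contig_id = sprintf("ctg%05d", seq_len(n)),
    length_bp = 1000L, stage = "A", sequence = NA_character_
  )
  map <- tibble::tibble(contig_id = contigs$contig_id, accession = "REF00001")
  p <- sim_params(
    stages = c("A", "B"),
    read_depth_per_stage = c(A = 1e6, B = 1e6),
    expression_profile = tibble::tibble(
      stage = "B", family = "glutathione S-transferase", multiplier = 2
    ),
    seed = 5
  )
  counts <- simulate_read_counts(contigs, map, genes, p)
  mean_a <- mean(counts$reads[counts$stage == "A"])
  mean_b <- mean(counts$reads[counts$stage == "B"])
  expect_gt(mean_b / mean_a, 2 * 0.95)
  expect_lt(mean_b / mean_a, 2 * 1.05)
})
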