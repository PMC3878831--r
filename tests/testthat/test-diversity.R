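# Independent restatement of the collapsing rule, used as the oracle:
# contigs matching one reference gene are one gene when each is shorter than
# half the reference length; otherwise every (distinct) contig is a gene.
oracle_count <- function(lens, subject_len) {
  all_short <- TRUE
  for (l in lens) {
    if (l >= subject_len / 2) all_short <- FALSE
  }
  if (all_short) 1L else length(lens)
}

test_that("half-length rule resolves the canonical cases", {
  expect_equal(count_genes(c(300, 400), 1000), 1L) # regions of one gene
  expect_equal(count_genes(c(600, 700), 1000), 2L) # two genes
  expect_equal(count_genes(600, 1000), 1L) # singleton
  expect_equal(count_genes(c(300, 600), 1000), 2L) # mixed lengths
  expect_equal(count_genes(500, 1000), 1L) # exactly half is not short
  expect_error(count_genes(c(300, 400), NA), "subject length")
  expect_error(count_genes(integer(0), 1000), "no members")
})

test_that("identical-sequence members are collapsed before counting", {
  expect_equal(
    count_genes(c(600, 600, 700), 1000, sequences = c("AAA", "AAA", "CCC")),
    2L
  )
  d <- count_genes(c(300, 600), 1000, detail = TRUE)
  expect_equal(d$branch, "distinct_contigs")
  expect_true(d$mixed)
  expect_equal(count_genes(c(300, 400), 1000, detail = TRUE)$branch, "all_short")
})

test_that("count_genes agrees with the brute-force rule on random clusters", {
  withr::with_seed(42, {
    for (i in 1:2000) {
      slen <- sample(200:3000, 1)
      n <- sample(1:6, 1)
      lens <- sample(100:slen, n, replace = TRUE)
      expect_identical(count_genes(lens, slen), oracle_count(lens, slen))
    }
  })
})

test_that("adding a member never decreases the inferred count", {
  withr::with_seed(7, {
    for (i in 1:500) {
      slen <- sample(400:2000, 1)
      n <- sample(1:5, 1)
      lens <- sample(100:slen, n, replace = TRUE)
      extra <- sample(100:slen, 1)
      expect_gte(count_genes(c(lens, extra), slen), count_genes(lens, slen))
      expect_lte(count_genes(lens, slen), n)
    }
  })
})

test_that("clusters partition contigs by subject and ignore input order", {
  contigs <- dplyr::bind_rows(
    make_contig("c1", 300), make_contig("c2", 400), make_contig("c3", 600)
  )
  hits <- dplyr::bind_rows(
    make_hit("c1", "gA", subject_length = 1000),
    make_hit("c2", "gA", subject_length = 1000),
    make_hit("c3", "gB", subject_length = 1000)
  )
  ann <- annotate_contigs(contigs, hits)
  cl <- cluster_by_subject(ann)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$subject_accession), c("gA", "gB"))
  expect_equal(cl$inferred_gene_count[cl$subject_accession == "gA"], 1L)

  cl2 <- cluster_by_subject(ann[c(3, 1, 2), ])
  expect_equal(as.data.frame(cl2), as.data.frame(cl))

  expect_equal(nrow(cluster_by_subject(ann[0, ])), 0)
})

test_that("diversity table uses union semantics for the all-stages row", {
  # one cluster of 2 inferred genes expressed in every stage
  contigs <- dplyr::bind_rows(
    make_contig("c1", 600, "Egg"), make_contig("c2", 700, "Pupa")
  )
  hits <- dplyr::bind_rows(
    make_hit("c1", "gA", subject_length = 1000),
    make_hit("c2", "gA", subject_length = 1000)
  )
  cl <- cluster_by_subject(annotate_contigs(contigs, hits))
  counts <- tidyr::expand_grid(
    stage = detox_stages(), contig_id = c("c1", "c2")
  ) |> dplyr::mutate(reads = 5L)
  tab <- diversity_table(cl, counts = counts)
  expect_equal(tab$oxidation_reduction, rep(2L, 9))
  expect_equal(tab$total[tab$stage == "All stages"], 2L)
  expect_equal(nrow(check_table_consistency(tab)), 0)

  # expressed in two stages only: counted once in the union row
  counts2 <- counts |>
    dplyr::mutate(reads = ifelse(.data$stage %in% c("Egg", "Pupa"), 5L, 0L))
  tab2 <- diversity_table(cl, counts = counts2)
  expect_equal(tab2$total[tab2$stage == "Egg"], 2L)
  expect_equal(tab2$total[tab2$stage == "Adult male"], 0L)
  expect_equal(tab2$total[tab2$stage == "All stages"], 2L)
  expect_lt(
    tab2$total[tab2$stage == "All stages"],
    sum(tab2$total[tab2$stage != "All stages"])
  )

  empty <- diversity_table(cluster_by_subject(
    annotate_contigs(contigs[0, ], hits[0, ])
  ))
  expect_true(all(empty$total == 0))
})

test_that("fully short or unfragmented simulations recover true gene counts", {
  for (setup in list(
    list(short_fragment_prob = 1, fragmentation_rate = 2),
    list(short_fragment_prob = 0, fragmentation_rate = 1)
  )) {
    p <- small_params(
      short_fragment_prob = setup$short_fragment_prob,
      fragmentation_rate = setup$fragmentation_rate,
      seed = 17
    )
    d <- simulate_dataset(p)
    ann <- annotate_contigs(d$contigs, d$hits)
    cl <- cluster_by_subject(flag_contaminants(ann)$clean)
    tab <- diversity_table(cl, counts = d$counts, stages = p$stages)
    truth <- table(d$genes$category[d$genes$kingdom == "animal"])
    all_row <- tab[tab$stage == "All stages", ]
    for (cc in detox_categories()) {
      expect_equal(all_row[[cc]], as.integer(truth[[cc]]),
        info = paste(cc, "short_fragment_prob =", setup$short_fragment_prob)
      )
    }
  }
})

test_that("family table nests subfamilies under their families", {
  contigs <- dplyr::bind_rows(
    make_contig("c1", 600, "Egg"), make_contig("c2", 650, "Egg"),
    make_contig("c3", 700, "Egg")
  )
  hits <- dplyr::bind_rows(
    make_hit("c1", "gA", subject_length = 1000, description = "cytochrome P450 CYP6AS5"),
    make_hit("c2", "gA", subject_length = 1000, description = "cytochrome P450 CYP6AS5"),
    make_hit("c3", "gA", subject_length = 1000, description = "cytochrome P450 CYP6AS5")
  )
  cl <- cluster_by_subject(annotate_contigs(contigs, hits))
  ft <- family_table(cl)
  fam_row <- ft[ft$family == "cytochrome P450" & ft$subfamily == "", ]
  sub_row <- ft[ft$subfamily == "CYP6", ]
  expect_equal(fam_row$all_stages, 3L)
  expect_equal(sub_row$all_stages, 3L)
  expect_equal(fam_row$Egg, 3L)

  # sub-rows never exceed their family row, across random simulations
  for (seed in c(2, 3, 4)) {
    d <- simulate_dataset(small_params(seed = seed))
    cls <- cluster_by_subject(flag_contaminants(annotate_contigs(d$contigs, d$hits))$clean)
    ftab <- family_table(cls, counts = d$counts)
    subs <- ftab[ftab$subfamily != "", ]
    if (nrow(subs) > 0) {
      fams <- ftab[ftab$subfamily == "", c("family", "all_stages")]
      m <- merge(subs, fams, by = "family", suffixes = c("_sub", "_fam"))
      expect_true(all(m$all_stages_sub <= m$all_stages_fam))
    }
  }
})

test_that("species count merging zero-fills missing families", {
  ft <- tibble::tibble(
    category = "hydrolysis", family = c("nitrilase", "amylase"),
    subfamily = "", all_stages = c(25L, 2L)
  )
  sp <- tibble::tibble(family = "nitrilase", count = 1L)
  merged <- merge_species_counts(ft, list(other_bee = sp))
  expect_equal(merged$other_bee[merged$family == "amylase"], 0)
  expect_equal(merged$other_bee[merged$family == "nitrilase"], 1)
  expect_equal(merged$this_study[merged$family == "nitrilase"], 25)
})

test_that("the shipped reference stage table is internally consistent", {
  ref <- readr::read_tsv(
    system.file("extdata", "bhuntii_stage_gene_counts.tsv", package = "detoxdiv"),
    col_types = readr::cols(stage = readr::col_character(), .default = readr::col_integer())
  )
  expect_equal(nrow(check_table_consistency(ref)), 0)

  corrupt <- ref
  corrupt$conjugation[2] <- corrupt$conjugation[2] + 1L
  v <- check_table_consistency(corrupt)
  expect_equal(nrow(v), 1)
  expect_equal(v$stage, ref$stage[2])

  expect_equal(nrow(check_table_consistency(ref[0, ])), 0)
})
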