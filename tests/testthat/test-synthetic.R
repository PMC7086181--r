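test_that("generate_motif_set honours the stop-codon policy", {
  forbid <- generate_motif_set(84, 6, "forbid", gc = 0.5, seed = 1)
  expect_length(forbid, 84)
  expect_false(anyDuplicated(forbid) > 0)
  expect_false(any(vapply(forbid, motif_contains_stop, logical(1))))

  force <- generate_motif_set(20, 6, "force", gc = 0.4, seed = 2)
  expect_true(all(vapply(force, motif_contains_stop, logical(1))))

  expect_equal(
    generate_motif_set(10, 6, "allow", seed = 3),
    generate_motif_set(10, 6, "allow", seed = 3)
  )
  # 16 distinct dinucleotides cannot supply 100 unique motifs
  expect_error(generate_motif_set(100, 2, "allow", seed = 4), "saturated")
})

test_that("generated motif sets track the GC target", {
  m <- generate_motif_set(200, 6, "allow", gc = 0.5, seed = 5)
  gc <- mean(strsplit(paste(m, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.05)
})

test_that("synthetic_config validates its fields", {
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(gc_content = 1.2), "gc_content")
  expect_error(synthetic_config(exon_count_range = c(3, 2)), "exon_count_range")
  expect_error(synthetic_config(flank_planting_density = 1.5), "densities")
  expect_error(synthetic_config(planted_orf_length = 100), "multiple of 3")
})

test_that("cohorts are reproducible and ground truth matches the sequences", {
  cfg <- synthetic_config(n_genes = 8, seed = 435)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$transcripts, b$transcripts)
  expect_equal(a$ground_truth$ese, b$ground_truth$ese)

  # every recorded interval contains exactly its motif, inside exon bounds
  gt <- a$ground_truth$ese
  expect_gt(nrow(gt), 0)
  for (i in seq_len(nrow(gt))) {
    row <- gt[i, ]
    exon <- a$transcripts$exons[[
      match(row$transcript_id, a$transcripts$transcript_id)
    ]][[row$exon_index]]
    expect_lte(row$end, nchar(exon))
    expect_equal(substring(exon, row$start, row$end), row$motif)
  }
  # planted intervals never overlap within an exon
  by_exon <- split(gt, paste(gt$transcript_id, gt$exon_index))
  for (g in by_exon) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
  }
})

test_that("planted ORFs guarantee a pORF at least as long as requested", {
  cfg <- synthetic_config(
    n_genes = 12, seed = 436,
    flank_planting_density = 0, core_planting_density = 0,
    flank3_planting_density = 0,
    planted_orf_length = 360L
  )
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$ground_truth$orf), 12)
  spl <- spliced_seq(cohort$transcripts)
  lens <- vapply(
    spl, function(s) longest_porf(s)$longest_porf_nt, integer(1)
  )
  expect_true(all(lens >= 360))
})

test_that("unplanted cohort SCD matches an i.i.d. composition oracle", {
  cfg <- synthetic_config(
    n_genes = 60, seed = 437, gc_content = 0.46,
    flank_planting_density = 0, core_planting_density = 0,
    flank3_planting_density = 0
  )
  cohort <- generate_cohort(cfg)
  obs <- pooled_density(spliced_seq(cohort$transcripts), stop_codons())$density
  # Monte-Carlo oracle: same total length of fresh i.i.d. sequence
  total <- sum(nchar(spliced_seq(cohort$transcripts)))
  sims <- withr::with_seed(438, replicate(40, {
    pooled_density(random_seq(total, gc = 0.46), stop_codons())$density
  }))
  expect_lt(abs(obs - mean(sims)), 3 * stats::sd(sims) + 3 * stats::sd(sims) / sqrt(40))
})

test_that("write_cohort round-trips through the readers", {
  cfg <- synthetic_config(n_genes = 4, seed = 439)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort$transcripts, cohort$ground_truth, dir)
  back <- read_transcripts(paths$premrna_fasta, paths$exon_bed)
  expect_equal(back$exons, cohort$transcripts$exons)
  expect_equal(back$introns, cohort$transcripts$introns)
  spl <- Biostrings::readDNAStringSet(paths$spliced_fasta)
  expect_equal(
    unname(as.character(spl)),
    unname(spliced_seq(cohort$transcripts))
  )
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_equal(gt$config$seed, 439)

  # rerunning the generator writes byte-identical FASTA
  dir2 <- withr::local_tempdir()
  cohort2 <- generate_cohort(cfg)
  paths2 <- write_cohort(cohort2$transcripts, cohort2$ground_truth, dir2)
  expect_equal(
    readLines(paths$spliced_fasta),
    readLines(paths2$spliced_fasta)
  )
})
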