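test_that("partition_exon slices 67-nt flanks and core as specified", {
  p <- partition_exon(withr::with_seed(417, random_seq(208)))
  expect_equal(p$start, c(3L, 71L, 140L))
  expect_equal(p$end, c(69L, 137L, 206L))
  expect_true(all(nchar(p$seq) == 67))
  expect_error(partition_exon(withr::with_seed(417, random_seq(207))), "207")
})

test_that("partition regions are disjoint and avoid the terminal dinucleotides", {
  withr::with_seed(418, {
    for (L in c(208, 209, 215, 250, 301, 400)) {
      p <- partition_exon(random_seq(L))
      idx <- unlist(purrr::map2(p$start, p$end, seq))
      expect_false(anyDuplicated(idx) > 0) # disjoint
      expect_false(any(idx %in% c(1, 2, L - 1, L)))
      expect_true(all(nchar(p$seq) == 67))
    }
  })
})

test_that("reverse-complementing an exon mirrors the flanks", {
  ex <- withr::with_seed(419, random_seq(250))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(ex, "")[[1]]), collapse = ""))
  p_fwd <- partition_exon(ex)
  p_rev <- partition_exon(rc)
  rc1 <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(
    p_rev$seq[p_rev$region == "flank5"],
    rc1(p_fwd$seq[p_fwd$region == "flank3"])
  )
  expect_equal(
    p_rev$seq[p_rev$region == "flank3"],
    rc1(p_fwd$seq[p_fwd$region == "flank5"])
  )
})

test_that("region analysis recovers 5'-flank-planted ESE signal", {
  cfg <- synthetic_config(
    n_genes = 40, seed = 420,
    flank_planting_density = 0.35,
    core_planting_density = 0.05,
    flank3_planting_density = 0
  )
  cohort <- generate_cohort(cfg)
  rep <- region_analysis(
    cohort$transcripts, cohort$ground_truth$ese_set,
    n_iterations = 50, seed = 421
  )
  ese <- stats::setNames(rep$ese_density, rep$region)
  expect_gt(ese[["flank5"]], ese[["core"]])
  expect_gt(ese[["flank5"]], ese[["flank3"]])
  # stop-free planting depresses SCD most where planting is densest
  fe <- stats::setNames(rep$fe, rep$region)
  expect_lt(fe[["flank5"]], fe[["core"]])
  expect_true(all(c("o_e", "p_lower", "null_sd") %in% names(rep)))
  expect_error(
    region_analysis(
      transcript_tbl("x", list("ACGTACGT")), "GAAGAA"
    ),
    "207"
  )
})

test_that("exon-intron comparison pairs per gene with ties as failures", {
  # identical exons and introns: all ties, no successes
  tr <- transcript_tbl(
    c("t1", "t2"),
    list(c("GGTGATAACA", "GGTGATAACA"), c("ACGTACGTAC", "ACGTACGTAC")),
    list("GGTGATAACA", "ACGTACGTAC")
  )
  cmp <- compare_exon_intron(tr)
  expect_false(any(cmp$exon_lower))
  expect_equal(glance(cmp)$fraction_exon_lower, 0)

  # deterministic planted contrast: stop-free exons, stop-rich introns
  tr2 <- transcript_tbl(
    c("a", "b", "c"),
    list(
      c(strrep("GGC", 20), strrep("GGC", 20)),
      c(strrep("CCG", 20), strrep("CCG", 20)),
      c(strrep("GCC", 20), strrep("GCC", 20))
    ),
    list(strrep("TAA", 20), strrep("TGA", 20), strrep("TAG", 20))
  )
  cmp2 <- compare_exon_intron(tr2)
  expect_true(all(cmp2$exon_lower))
  expect_equal(glance(cmp2)$fraction_exon_lower, 1)

  # intronless transcripts are excluded with a message
  tr3 <- transcript_tbl(
    c("m", "s"),
    list(c("GGTGATAACA", "ACGTACGTAC"), "ACGTACGTAC"),
    list("ACGTACGTAC", character(0))
  )
  expect_message(cmp3 <- compare_exon_intron(tr3), "intronless")
  expect_equal(nrow(cmp3), 1)
  expect_error(
    compare_exon_intron(transcript_tbl("s", list("ACGT"))),
    "no transcripts"
  )
})

test_that("per-gene FE tables are reproducible and summarised by glance", {
  cfg <- synthetic_config(
    n_genes = 8, seed = 422,
    flank_planting_density = 0, core_planting_density = 0,
    flank3_planting_density = 0
  )
  tr <- generate_cohort(cfg)$transcripts
  a <- per_gene_scd_fe(tr, n_iterations = 30, seed = 423)
  b <- per_gene_scd_fe(tr, n_iterations = 30, seed = 423)
  expect_equal(a, b)
  g <- glance(a)
  expect_equal(g$n, 8)
  expect_equal(g$n_fe_negative, sum(a$fe < 0))
})

test_that("cohort depletion deepens monotonically with planting intensity", {
  fe_at <- vapply(c(0, 0.1, 0.2, 0.3), function(theta) {
    cfg <- synthetic_config(
      n_genes = 40, seed = 424, # same background seed across theta
      flank_planting_density = theta,
      core_planting_density = theta,
      flank3_planting_density = theta
    )
    cohort <- generate_cohort(cfg)
    fold_enrichment(
      cohort_scd_fe(cohort$transcripts, n_iterations = 80, seed = 425)
    )
  }, numeric(1))
  expect_true(all(diff(fe_at) < 0))
  expect_lt(fe_at[4], -0.05)
})

test_that("stop-codon skew reports one FE per stop codon", {
  cfg <- synthetic_config(
    n_genes = 6, seed = 426,
    flank_planting_density = 0, core_planting_density = 0,
    flank3_planting_density = 0
  )
  tr <- generate_cohort(cfg)$transcripts
  sk <- stop_codon_skew(tr, n_iterations = 25, seed = 427)
  expect_equal(sk$codon, c("TAA", "TAG", "TGA"))
  expect_equal(
    sk$observed,
    vapply(
      c("TAA", "TAG", "TGA"),
      function(cd) pooled_density(spliced_seq(tr), cd)$density,
      numeric(1),
      USE.NAMES = FALSE
    )
  )
})
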