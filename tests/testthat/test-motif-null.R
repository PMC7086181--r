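test_that("dinucleotide profile counts all overlapping adjacent pairs", {
  p <- dinucleotide_profile("GAAGTA")
  expect_equal(
    p$dinucleotides[c("GA", "AA", "AG", "GT", "TA")],
    c(GA = 1L, AA = 1L, AG = 1L, GT = 1L, TA = 1L)
  )
  expect_equal(sum(p$dinucleotides), 5L)

  expect_equal(unname(dinucleotide_profile("AAAA")$dinucleotides["AA"]), 3L)
  p2 <- dinucleotide_profile(c("AT", "TA"))
  expect_equal(unname(p2$dinucleotides[c("AT", "TA")]), c(1L, 1L))
  expect_equal(sum(p2$dinucleotides), 2L)

  expect_error(dinucleotide_profile(c("AT", "A")), "length >= 2")
})

test_that("profile totals equal sum of (motif length - 1)", {
  withr::with_seed(406, {
    motifs <- replicate(8, random_seq(sample(2:8, 1)))
    p <- dinucleotide_profile(motifs)
    expect_equal(sum(p$dinucleotides), sum(nchar(motifs) - 1L))
    expect_equal(sum(p$nucleotides), sum(nchar(motifs)))
  })
})

test_that("degenerate profiles force the sampled pseudo-motif", {
  p <- dinucleotide_profile("AAAA") # only AA reachable
  withr::with_seed(407, {
    expect_equal(sample_pseudo_motif(6, p), "AAAAAA")
    expect_equal(sample_pseudo_motif(5, p), "AAAAA")
  })
  # odd-length padding uses the mononucleotide counts
  forced <- structure(
    list(
      dinucleotides = c(AA = 1L),
      nucleotides = c(A = 0L, C = 1L, G = 0L, T = 0L)
    ),
    class = "dinuc_profile"
  )
  withr::with_seed(408, {
    expect_equal(sample_pseudo_motif(5, forced), "AAAAC")
  })
  empty <- structure(
    list(dinucleotides = c(AA = 0L), nucleotides = c(A = 0L)),
    class = "dinuc_profile"
  )
  expect_error(sample_pseudo_motif(6, empty), "degenerate")
})

test_that("pseudo-motif positions are marginally uniform under a uniform profile", {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  uniform <- structure(
    list(
      dinucleotides = stats::setNames(rep(1L, 16), dinucs),
      nucleotides = c(A = 1L, C = 1L, G = 1L, T = 1L)
    ),
    class = "dinuc_profile"
  )
  n <- 4000
  draws <- withr::with_seed(409, replicate(n, sample_pseudo_motif(6, uniform)))
  mat <- do.call(rbind, strsplit(draws, ""))
  freqs <- colMeans(matrix(mat %in% c("G", "C"), nrow = n))
  # each position marginally uniform: GC fraction 0.5 within 3 sigma
  tol <- 3 * sqrt(0.25 / n)
  expect_true(all(abs(freqs - 0.5) < tol))
})

test_that("pseudo-sets preserve size and length multiset, unique per iteration", {
  withr::with_seed(410, {
    for (i in 1:10) {
      true_set <- unique(replicate(sample(3:10, 1), random_seq(sample(4:8, 1))))
      pseudo <- generate_pseudo_set(true_set)
      expect_length(pseudo, length(true_set))
      expect_equal(sort(nchar(pseudo)), sort(nchar(true_set)))
      expect_false(anyDuplicated(pseudo) > 0)
    }
  })
})

test_that("sampling saturates with an explicit error when the profile is too poor", {
  # profile admits only the motif AA; a set of two length-2 motifs cannot
  # be unique within one iteration
  p <- dinucleotide_profile("AAAA")
  withr::with_seed(411, {
    expect_error(
      generate_pseudo_set(c("AC", "GT"), profile = p, max_retries = 50),
      "saturated"
    )
  })
})

test_that("motif null distributions are seed-reproducible", {
  eses <- c("GAAGAA", "CAGAAG", "AAGAAC", "GGAAGA")
  a <- motif_null_distribution(eses, n_iterations = 20, seed = 99)
  b <- motif_null_distribution(eses, n_iterations = 20, seed = 99)
  expect_equal(a$simulants, b$simulants)
  expect_equal(a$observed, pooled_density(eses, stop_codons())$density)
  # query with no occurrences in the true set
  z <- motif_null_distribution(c("CCCCCC", "GGGGGG"),
    query = "AAA",
    n_iterations = 5, seed = 1
  )
  expect_equal(z$observed, 0)
})

test_that("motif sets built without stop avoidance show no stop depletion", {
  # calibration: an unconstrained random motif set should give FE near 0
  motifs <- generate_motif_set(60, 6, "allow", gc = 0.5, seed = 412)
  nd <- motif_null_distribution(motifs, n_iterations = 400, seed = 413)
  fe_sims <- (nd$simulants - mean(nd$simulants)) / mean(nd$simulants)
  expect_lt(
    abs(fold_enrichment(nd)),
    4 * stats::sd(fe_sims)
  )
})
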