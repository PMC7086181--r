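test_that("read_motif_list uppercases, deduplicates and validates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GAAGAA", "GAAGAA", "gaagta", "# comment", ""), f)
  expect_equal(read_motif_list(f), c("GAAGAA", "GAAGTA"))

  writeLines("GAN GTA", f)
  expect_error(read_motif_list(f), "line 1")

  writeLines(character(0), f)
  expect_error(read_motif_list(f), "empty motif set")

  writeLines(c("# only", "# comments"), f)
  expect_error(read_motif_list(f), "empty motif set")
})

write_fasta <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}

test_that("read_transcripts extracts exons and introns from FASTA + BED", {
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fasta("tx1", "ACGTACGTAC", fa)
  writeLines(c("tx1\t0\t4\te1\t0\t+", "tx1\t8\t10\te2\t0\t+"), bed)
  tr <- read_transcripts(fa, bed)
  expect_equal(tr$exons[[1]], c("ACGT", "AC"))
  expect_equal(tr$introns[[1]], "ACGT")

  # no BED: whole record is exon 1
  tr1 <- read_transcripts(fa)
  expect_equal(tr1$exons[[1]], "ACGTACGTAC")
  expect_length(tr1$introns[[1]], 0)

  # out-of-bounds interval names the record
  writeLines("tx1\t5\t20\te1\t0\t+", bed)
  expect_error(read_transcripts(fa, bed), "tx1")

  # overlapping exons rejected
  writeLines(c("tx1\t0\t5\te1\t0\t+", "tx1\t3\t8\te2\t0\t+"), bed)
  expect_error(read_transcripts(fa, bed), "overlapping")
})

test_that("minus-strand records are reverse-complemented to sense strand", {
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  # sense model: exons ACGT, AC with intron ACGT on the plus record
  plus <- "ACGTACGTAC"
  minus <- chartr("ACGT", "TGCA", paste(rev(strsplit(plus, "")[[1]]), collapse = ""))
  write_fasta("tx1", minus, fa)
  # mirror the intervals [0,4) and [8,10) on the reversed record
  writeLines(c("tx1\t0\t2\te2\t0\t-", "tx1\t6\t10\te1\t0\t-"), bed)
  tr <- read_transcripts(fa, bed)
  expect_equal(tr$exons[[1]], c("ACGT", "AC"))
  expect_equal(tr$introns[[1]], "ACGT")
})

test_that("records with noncanonical nucleotides are dropped at ingest", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c("good", "bad"), c("ACGTACGT", "ACGTNCGT"), fa)
  expect_warning(tr <- read_transcripts(fa), "noncanonical")
  expect_equal(tr$transcript_id, "good")
})

test_that("write/read round-trip reproduces transcript models exactly", {
  withr::with_seed(404, {
    tr <- transcript_tbl(
      c("a", "b"),
      list(
        c(random_seq(30), random_seq(20), random_seq(25)),
        random_seq(40)
      ),
      list(c(random_seq(15), random_seq(12)), character(0))
    )
    fa <- withr::local_tempfile(fileext = ".fa")
    bed <- withr::local_tempfile(fileext = ".bed")
    write_transcripts(tr, fa, bed)
    back <- read_transcripts(fa, bed)
    expect_equal(back$exons, tr$exons)
    expect_equal(back$introns, tr$introns)
    # pre-mRNA concatenation reconstructs the span
    pre <- as.character(Biostrings::readDNAStringSet(fa))[["a"]]
    expect_equal(
      pre,
      paste0(
        tr$exons[[1]][1], tr$introns[[1]][1], tr$exons[[1]][2],
        tr$introns[[1]][2], tr$exons[[1]][3]
      )
    )
  })
})

test_that("transcript_tbl enforces exon/intron count invariants", {
  expect_error(
    transcript_tbl("a", list(c("ACGT", "ACGT")), list(c("AA", "CC"))),
    "intron count"
  )
  expect_error(
    transcript_tbl(c("a", "a"), list("ACGT", "ACGT")),
    "unique"
  )
})

test_that("family grouping is component-based and order-invariant", {
  ids <- c("a", "b", "c", "d")
  # no hits: all singletons
  g0 <- group_families(ids, NULL)
  expect_equal(dplyr::n_distinct(g0$family), 4)

  # transitivity through shared members
  g1 <- group_families(c("a", "b", "c"), data.frame(x = c("a", "b"), y = c("b", "c")))
  expect_equal(dplyr::n_distinct(g1$family), 1)

  g2 <- group_families(ids, data.frame(x = "a", y = "b"))
  expect_equal(dplyr::n_distinct(g2$family), 3)
  expect_equal(g2$family[g2$transcript_id == "a"], g2$family[g2$transcript_id == "b"])

  # invariant to pair order and orientation
  h1 <- data.frame(x = c("a", "b"), y = c("b", "c"))
  h2 <- data.frame(x = c("c", "b"), y = c("b", "a"))
  f1 <- group_families(c("a", "b", "c"), h1, seed = 7)
  f2 <- group_families(c("a", "b", "c"), h2, seed = 7)
  expect_equal(f1$family, f2$family)

  expect_error(group_families(c("a", "b"), data.frame(x = "a", y = "z")), "unknown")
})

test_that("random-member representatives are seeded and one per family", {
  ids <- letters[1:6]
  hits <- data.frame(x = c("a", "c"), y = c("b", "d"))
  g1 <- group_families(ids, hits, seed = 11)
  g2 <- group_families(ids, hits, seed = 11)
  expect_equal(g1$representative, g2$representative)
  reps_per_family <- tapply(g1$representative, g1$family, sum)
  expect_true(all(reps_per_family == 1))
  gm <- group_families(ids, hits, representative = "median-aggregate")
  expect_false(any(gm$representative))
})
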