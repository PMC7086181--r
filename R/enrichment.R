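# Cohort-level analyses: per-gene and pooled SCD fold enrichment against
# shuffle nulls, ESE masking, exon-vs-intron pairing, per-stop-codon skew,
# and the exon-region partition (5' flank / core / 3' flank).

scd_stat <- function(motifs) {
  force(motifs)
  function(seqs) pooled_density_value(seqs, motifs)
}

#' Partition an exon into 5' flank, core and 3' flank
#'
#' For exons longer than 207 nucleotides: the 5' flank is nucleotides 3-69
#' (1-based), the 3' flank the mirrored window at the other terminus
#' (L-68 to L-2), and the core the 67 nucleotides centred on the exon
#' midpoint (start biased one nucleotide 5' when the centring is ambiguous).
#' Each region is exactly 67 nt; regions are disjoint and never touch the
#' two terminal dinucleotides.
#'
#' @param exon A single exon sequence, longer than 207 nt.
#' @return Tibble with columns `region` (flank5/core/flank3), `start`,
#'   `end` (1-based inclusive) and `seq`.
#' @export
partition_exon <- function(exon) {
  exon <- check_dna(exon, "exon")
  L <- nchar(exon)
  if (L <= 207L) {
    abort(sprintf("exon too short to partition: %d <= 207", L))
  }
  core_start <- (L - 67L) %/% 2L + 1L
  out <- tibble(
    region = c("flank5", "core", "flank3"),
    start = c(3L, core_start, L - 68L),
    end = c(69L, core_start + 66L, L - 2L)
  )
  out$seq <- substring(exon, out$start, out$end)
  out
}

#' Region-level ESE density and SCD enrichment analysis
#'
#' Partitions every exon longer than 207 nt into 5' flank, core and 3'
#' flank, then per region computes the pooled ESE density, the pooled SCD,
#' and the SCD null from per-region mononucleotide shuffles: fold
#' enrichment, observed/expected ratio, Z and empirical p. A chi-square
#' test of the observed per-region stop-covered counts against the
#' null-expected proportions is attached as the `"chisq"` attribute.
#'
#' @param transcripts A transcript table.
#' @param ese_set Character vector of ESE motifs.
#' @param motifs Query codon set for the density under test (default stop
#'   codons).
#' @param n_iterations Shuffle iterations per region.
#' @param seed Integer master seed.
#' @return Tibble with one row per region, classed `region_report` for
#'   [autoplot.region_report()].
#' @export
region_analysis <- function(transcripts, ese_set, motifs = stop_codons(),
                            n_iterations = 1000L, seed = 1L) {
  ese_set <- check_motifs(ese_set, "ese_set")
  exons <- unlist(transcripts$exons, use.names = FALSE)
  exons <- exons[nchar(exons) > 207L]
  if (length(exons) == 0L) {
    abort("no exons longer than 207 nt; cannot run region analysis")
  }
  parts <- purrr::map(exons, partition_exon)
  regions <- c("flank5", "core", "flank3")
  seeds <- stats::setNames(child_seeds(seed, 3L), regions)
  rows <- purrr::map(regions, function(r) {
    seqs <- purrr::map_chr(parts, function(p) p$seq[p$region == r])
    nd <- sequence_null_distribution(
      seqs, scd_stat(motifs),
      n_iterations = n_iterations, seed = seeds[[r]],
      scope = "whole-transcript"
    )
    td <- tidy(nd)
    tibble(
      region = r,
      n_exons = length(seqs),
      ese_density = pooled_density_value(seqs, ese_set),
      observed = td$observed,
      null_mean = td$null_mean,
      null_sd = td$null_sd,
      fe = td$fe,
      o_e = td$observed / td$null_mean,
      z = td$z,
      p_lower = td$p_lower,
      p_upper = td$p_upper,
      n_iterations = td$n_iterations,
      covered_count = sum(purrr::map_int(
        seqs, function(s) length(covered_positions(s, motifs))
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  expected <- out$null_mean * 67 * out$n_exons
  chisq <- tryCatch(
    chisq.test(out$covered_count, p = expected / sum(expected)),
    error = function(e) NULL
  )
  attr(out, "chisq") <- chisq
  class(out) <- c("region_report", class(out))
  out
}

#' Per-gene SCD fold enrichment against shuffles of the same gene
#'
#' For every transcript, the spliced sequence's pooled density of `motifs`
#' is compared with mononucleotide shuffles of that same sequence (pairwise
#' mode). The cohort-level summary (fraction of genes with FE < 0, binomial
#' tests) is available via [glance()].
#'
#' @inheritParams region_analysis
#' @param motifs Query motif set (default stop codons).
#' @return Tibble with one row per transcript (`transcript_id`, `observed`,
#'   `null_mean`, `null_sd`, `fe`, `z`, `p_lower`, `p_upper`), classed
#'   `pergene_fe`.
#' @export
per_gene_scd_fe <- function(transcripts, motifs = stop_codons(),
                            n_iterations = 1000L, seed = 1L) {
  seqs <- spliced_seq(transcripts)
  seeds <- child_seeds(seed, length(seqs))
  rows <- purrr::imap(seqs, function(s, id) {
    i <- match(id, names(seqs))
    nd <- sequence_null_distribution(
      s, scd_stat(motifs),
      n_iterations = n_iterations, seed = seeds[i],
      scope = "whole-transcript"
    )
    dplyr::bind_cols(tibble(transcript_id = id), tidy(nd))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pergene_fe", class(out))
  out
}

#' @export
glance.pergene_fe <- function(x, ...) {
  n <- nrow(x)
  n_neg <- sum(x$fe < 0, na.rm = TRUE)
  n_sig <- sum(x$fe < 0 & x$p_lower < 0.05, na.rm = TRUE)
  tibble(
    n = n,
    n_fe_negative = n_neg,
    fraction_fe_negative = n_neg / n,
    p_binomial_negative =
      binom.test(n_neg, n, p = 0.5, alternative = "greater")$p.value,
    n_fe_negative_significant = n_sig,
    fraction_fe_negative_significant = n_sig / n,
    p_binomial_significant =
      binom.test(n_sig, n, p = 0.05, alternative = "greater")$p.value
  )
}

#' Cohort-pooled SCD fold enrichment
#'
#' The observed statistic is the pooled density of `motifs` over all spliced
#' transcripts (covered positions and lengths summed before division); each
#' iteration shuffles every transcript within itself and recomputes it.
#'
#' @inheritParams per_gene_scd_fe
#' @param scope Shuffle scope, see [sequence_null_distribution()].
#' @return A [null_distribution()] object.
#' @export
cohort_scd_fe <- function(transcripts, motifs = stop_codons(),
                          n_iterations = 1000L, seed = 1L,
                          scope = "whole-transcript") {
  sequence_null_distribution(
    unname(spliced_seq(transcripts)), scd_stat(motifs),
    n_iterations = n_iterations, seed = seed, scope = scope
  )
}

#' SCD fold enrichment of ESE-masked sequence
#'
#' Removes every position covered by a hit to `ese_set` from each spliced
#' transcript ([mask_and_split()]), keeping the unmatched parts separate,
#' then compares the pooled density of `motifs` in the remaining parts with
#' independent within-part shuffles. If ESEs drive a cohort depletion, the
#' masked remainder should show no depletion.
#'
#' @inheritParams region_analysis
#' @return A [null_distribution()] object. The parts are attached as the
#'   `"parts"` attribute.
#' @export
masked_scd_fe <- function(transcripts, ese_set, motifs = stop_codons(),
                          n_iterations = 1000L, seed = 1L) {
  ese_set <- check_motifs(ese_set, "ese_set")
  parts <- unlist(
    purrr::map(spliced_seq(transcripts), mask_and_split, motifs = ese_set),
    use.names = FALSE
  )
  if (length(parts) == 0L) {
    abort("masking removed all sequence; nothing left to analyse")
  }
  nd <- sequence_null_distribution(
    parts, scd_stat(motifs),
    n_iterations = n_iterations, seed = seed, scope = "whole-transcript"
  )
  attr(nd, "parts") <- parts
  nd
}

#' Per-stop-codon usage skew
#'
#' Computes the fold enrichment of each stop codon separately (singleton
#' query sets TAA, TAG, TGA) against the same whole-transcript shuffle
#' null, reusing one set of shuffles across the three codons.
#'
#' @inheritParams per_gene_scd_fe
#' @return Tibble with one row per stop codon: `codon`, `observed`,
#'   `null_mean`, `fe`, `z`, `p_lower`, `p_upper`.
#' @export
stop_codon_skew <- function(transcripts, n_iterations = 1000L, seed = 1L) {
  seqs <- unname(spliced_seq(transcripts))
  codons <- stop_codons()
  observed <- vapply(codons, function(cd) pooled_density_value(seqs, cd),
    numeric(1),
    USE.NAMES = FALSE
  )
  seeds <- child_seeds(seed, n_iterations)
  sims <- vapply(seq_len(n_iterations), function(i) {
    shuffled <- with_seed(seeds[i], vapply(seqs, shuffle_sequence,
      character(1),
      USE.NAMES = FALSE
    ))
    vapply(codons, function(cd) pooled_density_value(shuffled, cd), numeric(1))
  }, numeric(3))
  purrr::map_dfr(seq_along(codons), function(j) {
    nd <- null_distribution(observed[j], sims[j, ])
    dplyr::bind_cols(
      tibble(codon = codons[j]),
      tidy(nd)[c("observed", "null_mean", "fe", "z", "p_lower", "p_upper")]
    )
  })
}

#' Pairwise exon-versus-intron density comparison
#'
#' For every transcript with intron sequence, compares the pooled exonic
#' density of `motifs` with the pooled intronic density. Ties count as
#' failures for the "exon < intron" success criterion. Intronless
#' transcripts are excluded (with a message). The one-tailed binomial
#' summary is available via [glance()].
#'
#' @inheritParams per_gene_scd_fe
#' @return Tibble with `transcript_id`, `exon_density`, `intron_density`,
#'   `exon_lower`, classed `paired_density`.
#' @export
compare_exon_intron <- function(transcripts, motifs = stop_codons()) {
  has_intron <- purrr::map_lgl(transcripts$introns, function(i) length(i) > 0L)
  if (!all(has_intron)) {
    rlang::inform(sprintf(
      "excluding %d intronless transcript(s) from exon-intron comparison",
      sum(!has_intron)
    ))
  }
  tr <- transcripts[has_intron, ]
  if (nrow(tr) == 0L) {
    abort("no transcripts with intron sequence")
  }
  out <- tibble(
    transcript_id = tr$transcript_id,
    exon_density = purrr::map_dbl(tr$exons, pooled_density_value, motifs = motifs),
    intron_density = purrr::map_dbl(tr$introns, pooled_density_value, motifs = motifs)
  )
  out$exon_lower <- out$exon_density < out$intron_density
  class(out) <- c("paired_density", class(out))
  out
}

#' @export
glance.paired_density <- function(x, ...) {
  n <- nrow(x)
  m <- sum(x$exon_lower)
  wil <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(x$exon_density, x$intron_density, paired = TRUE)$p.value
    ),
    error = function(e) NA_real_
  )
  tibble(
    n = n,
    n_exon_lower = as.integer(m),
    fraction_exon_lower = m / n,
    p_binomial = binom.test(m, n, p = 0.5, alternative = "greater")$p.value,
    p_wilcoxon = wil
  )
}

#' Bar chart of region-level ESE density and SCD fold enrichment
#'
#' @param object A `region_report` from [region_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::select("region", "ese_density", "fe") |>
    tidyr::pivot_longer(c("ese_density", "fe"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(region = factor(.data$region, c("flank5", "core", "flank3")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
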