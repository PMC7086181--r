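# Pseudo-ORF (pORF) statistics: the longest ATG-to-in-frame-stop span in a
# sense-strand transcript, its null distribution under mononucleotide
# shuffles, and the calibration of ORF-length annotation thresholds against
# composition-matched nulls.

# Integer length of the longest pORF (ATG through stop, inclusive) or NA if
# no ATG has a downstream in-frame stop. include_stop = FALSE gives the
# distance up to but excluding the stop codon.
porf_len <- function(seq, include_stop = TRUE) {
  L <- nchar(seq)
  if (L < 6L) {
    return(NA_integer_)
  }
  starts <- seq_len(L - 2L)
  words <- substring(seq, starts, starts + 2L)
  atg <- starts[words == "ATG"]
  stp <- starts[words %in% stop_codons()]
  if (length(atg) == 0L || length(stp) == 0L) {
    return(NA_integer_)
  }
  best <- NA_integer_
  for (f in 0:2) {
    a <- atg[(atg - 1L) %% 3L == f]
    s <- stp[(stp - 1L) %% 3L == f]
    if (length(a) == 0L || length(s) == 0L) next
    # next in-frame stop strictly downstream of each ATG
    idx <- findInterval(a + 2L, s) + 1L
    ok <- idx <= length(s)
    if (!any(ok)) next
    len <- s[idx[ok]] - a[ok] + 3L
    best <- max(best, len, na.rm = TRUE)
  }
  if (is.na(best)) {
    return(NA_integer_)
  }
  if (!include_stop) best - 3L else best
}

#' Longest pseudo-ORF in a sequence
#'
#' Scans every ATG in all three frames of the given (sense) strand and walks
#' in-frame codons to the first stop codon. The recorded length runs from
#' the first base of the ATG through the last base of the stop codon
#' inclusive (minimum 6, always a multiple of 3); set
#' `include_stop = FALSE` for the stop-exclusive convention. Sequences in
#' which no ATG has a downstream in-frame stop have no pORF.
#'
#' @param seq A single DNA sequence.
#' @param include_stop Include the terminating stop codon in the length
#'   (default TRUE).
#' @return One-row tibble with `longest_porf_nt` (NA when absent) and
#'   `has_porf`.
#' @export
#' @examples
#' longest_porf("ATGAAATAA") # 9
#' longest_porf("AAATGA") # no pORF
longest_porf <- function(seq, include_stop = TRUE) {
  seq <- check_dna(seq)
  len <- porf_len(seq, include_stop)
  tibble(longest_porf_nt = len, has_porf = !is.na(len))
}

#' Null distribution of a sequence's longest pORF length
#'
#' The observed value is the longest pORF of the real sequence (which must
#' have one); each iteration shuffles the sequence's nucleotides and records
#' the shuffled longest pORF, scoring 0 when the shuffle has none so the
#' simulant count stays constant. Z scores follow from [z_score()]; a
#' positive Z means the real pORF is longer than composition predicts.
#'
#' @inheritParams longest_porf
#' @param n_iterations Number of shuffles.
#' @param seed Integer master seed.
#' @return A [null_distribution()] object.
#' @export
porf_null <- function(seq, n_iterations = 1000L, seed = 1L,
                      include_stop = TRUE) {
  seq <- check_dna(seq)
  observed <- porf_len(seq, include_stop)
  if (is.na(observed)) {
    abort("sequence has no pORF; excluded from Z analysis")
  }
  seeds <- child_seeds(seed, n_iterations)
  simulants <- vapply(seeds, function(s) {
    shuf <- with_seed(s, shuffle_sequence(seq))
    len <- porf_len(shuf, include_stop)
    if (is.na(len)) 0 else as.numeric(len)
  }, numeric(1))
  null_distribution(as.numeric(observed), simulants)
}

#' Excess of long pORFs over a length-matched shuffle null
#'
#' For each length threshold, counts how many real transcripts have a pORF
#' at least that long, subtracts the mean count in null sets built by
#' [concat_shuffle_extract()] (equal pooled composition and matched
#' lengths), and divides by the number of real transcripts. A locally
#' weighted regression (span 0.75) of excess on threshold, linearly
#' interpolated, locates the smallest threshold at which the excess drops
#' to 5% -- the length cutoff needed to keep composition-driven false
#' positives at that rate.
#'
#' @param transcripts A transcript table (spliced sequences are analysed).
#' @param thresholds Strictly increasing integer vector of nucleotide
#'   thresholds (default 200 to 600 by 10).
#' @param n_iterations Number of null sets.
#' @param seed Integer master seed.
#' @param include_stop Length convention, see [longest_porf()].
#' @return Tibble (`threshold_curve`) with `threshold`, `real_count`,
#'   `null_mean_count`, `excess`; attributes `five_percent_threshold` and
#'   `n_real`.
#' @export
threshold_excess <- function(transcripts, thresholds = seq(200L, 600L, 10L),
                             n_iterations = 1000L, seed = 1L,
                             include_stop = TRUE) {
  if (length(thresholds) == 0L) {
    abort("`thresholds` must be nonempty")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing")
  }
  seqs <- unname(spliced_seq(transcripts))
  n_real <- length(seqs)
  real_len <- vapply(seqs, function(s) {
    l <- porf_len(s, include_stop)
    if (is.na(l)) 0L else l
  }, integer(1))
  real_count <- vapply(thresholds, function(t) sum(real_len >= t), integer(1))
  seeds <- child_seeds(seed, n_iterations)
  null_counts <- vapply(seeds, function(sd) {
    null_seqs <- with_seed(sd, concat_shuffle_extract(seqs))
    lens <- vapply(null_seqs, function(s) {
      l <- porf_len(s, include_stop)
      if (is.na(l)) 0L else l
    }, integer(1))
    vapply(thresholds, function(t) sum(lens >= t), integer(1))
  }, integer(length(thresholds)))
  null_counts <- matrix(null_counts, nrow = length(thresholds))
  null_mean <- rowMeans(null_counts)
  excess <- (real_count - null_mean) / n_real
  out <- tibble(
    threshold = as.integer(thresholds),
    real_count = real_count,
    null_mean_count = null_mean,
    excess = excess
  )
  attr(out, "five_percent_threshold") <-
    five_percent_threshold(out$threshold, out$excess)
  attr(out, "n_real") <- n_real
  class(out) <- c("threshold_curve", class(out))
  out
}

# Smallest threshold at which a loess fit (span 0.75) of excess on
# threshold, linearly interpolated, falls to 0.05. NA when the fit never
# crosses from above.
five_percent_threshold <- function(thresholds, excess, target = 0.05) {
  if (length(thresholds) < 4L) {
    return(NA_real_)
  }
  fit <- tryCatch(
    suppressWarnings(loess(excess ~ thresholds, span = 0.75, degree = 2)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(NA_real_)
  }
  grid <- seq(min(thresholds), max(thresholds), length.out = 500L)
  sm <- suppressWarnings(
    predict(fit, newdata = data.frame(thresholds = grid))
  )
  above <- sm > target
  if (!any(above, na.rm = TRUE)) {
    return(min(thresholds))
  }
  cross <- which(above[-length(above)] & !above[-1])
  if (length(cross) == 0L) {
    return(NA_real_)
  }
  i <- cross[1]
  # linear interpolation between the bracketing grid points
  approx(sm[c(i, i + 1L)], grid[c(i, i + 1L)], xout = target)$y
}

#' Sequence upstream of the 5'-most ATG
#'
#' The prefix strictly before the first ATG occurrence at any position.
#' Absent (NA) when the sequence has no ATG or the first ATG starts at
#' position 1 (empty prefix).
#'
#' @param seq A single DNA sequence.
#' @return Character scalar or NA.
#' @export
upstream_of_first_atg <- function(seq) {
  seq <- check_dna(seq)
  pos <- regexpr("ATG", seq, fixed = TRUE)[1]
  if (pos == -1L || pos == 1L) {
    return(NA_character_)
  }
  substr(seq, 1L, pos - 1L)
}

#' Threshold-excess curve plot
#'
#' @param object A `threshold_curve` from [threshold_excess()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_curve <- function(object, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$threshold, y = .data$excess)
  ) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_smooth(
      method = "loess", span = 0.75,
      se = FALSE, colour = "steelblue", formula = y ~ x
    ) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(
      x = "pORF length threshold (nt)",
      y = "excess fraction over null"
    ) +
    ggplot2::theme_minimal()
  t5 <- attr(object, "five_percent_threshold")
  if (!is.na(t5)) {
    p <- p + ggplot2::geom_vline(
      xintercept = t5,
      colour = "firebrick", linetype = "dotted"
    )
  }
  p
}
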