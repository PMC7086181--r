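# Overlap-once coverage density: the fraction of a sequence's positions
# covered by at least one occurrence of at least one query motif, each
# position counted once no matter how many occurrences overlap it. For the
# stop-codon set {TAA, TAG, TGA} this is the stop codon density (SCD).

# Fast core: 1-based covered positions of `motifs` in `seq`. Scans every
# offset for every motif length via vectorised substring extraction, so
# overlapping self-matches (e.g. GGG in GGGG) are found.
covered_positions <- function(seq, motifs) {
  L <- nchar(seq)
  if (length(motifs) == 0L) {
    return(integer(0))
  }
  covered <- logical(L)
  lens <- nchar(motifs)
  for (k in unique(lens)) {
    if (k < 1L || k > L) next
    mk <- motifs[lens == k]
    starts <- seq_len(L - k + 1L)
    words <- substring(seq, starts, starts + k - 1L)
    hit <- starts[words %in% mk]
    if (length(hit)) {
      covered[rep(hit, each = k) + seq_len(k) - 1L] <- TRUE
    }
  }
  which(covered)
}

#' Find all motif hits in a sequence as a coverage mask
#'
#' Scans `seq` for every occurrence of every motif at every offset (including
#' overlapping self-matches) and returns the union of covered positions. Each
#' position is recorded at most once, so the mask size is bounded by the
#' sequence length.
#'
#' @param seq A single DNA sequence (character scalar over A/C/G/T; case
#'   insensitive).
#' @param motifs Character vector of DNA motifs. Motifs longer than the
#'   sequence simply never match. An empty set yields an empty mask.
#' @return A `coverage_mask` object: list with `sequence_length` and
#'   `covered`, the sorted 1-based covered positions.
#' @export
#' @examples
#' find_hits("AGATAGGGGA", "GGG") # two overlapping hits merge to 4 positions
find_hits <- function(seq, motifs) {
  seq <- check_dna(seq)
  motifs <- check_motifs(motifs)
  structure(
    list(
      sequence_length = nchar(seq),
      covered = covered_positions(seq, motifs)
    ),
    class = "coverage_mask"
  )
}

#' @export
print.coverage_mask <- function(x, ...) {
  cat(sprintf(
    "<coverage_mask> %d of %d positions covered\n",
    length(x$covered), x$sequence_length
  ))
  invisible(x)
}

#' Coverage density of a motif set in a sequence
#'
#' The number of positions covered by at least one motif occurrence, divided
#' by the sequence length. Overlapping occurrences are unioned at the
#' position level before counting, bounding the density by 0 and 1.
#'
#' @inheritParams find_hits
#' @return One-row tibble with `covered_count`, `sequence_length`, `density`.
#' @seealso [pooled_density()] for the aggregate over a sequence set.
#' @export
#' @examples
#' motif_density("AGATAGGGGA", "GGA")$density # 0.3
#' motif_density("GGTGATAACA", stop_codons())$density # SCD = 0.6
motif_density <- function(seq, motifs) {
  seq <- check_dna(seq)
  motifs <- check_motifs(motifs)
  covered <- length(covered_positions(seq, motifs))
  tibble(
    covered_count = covered,
    sequence_length = nchar(seq),
    density = covered / nchar(seq)
  )
}

# Internal: covered count and total length pooled over sequences.
pooled_cov <- function(seqs, motifs) {
  covered <- 0L
  total <- 0L
  for (s in seqs) {
    covered <- covered + length(covered_positions(s, motifs))
    total <- total + nchar(s)
  }
  c(covered = covered, length = total)
}

pooled_density_value <- function(seqs, motifs) {
  x <- pooled_cov(seqs, motifs)
  unname(x[1] / x[2])
}

#' Pooled coverage density over a set of sequences
#'
#' Covered positions and sequence lengths are summed over all sequences
#' before dividing (an aggregate density, not a mean of per-sequence
#' densities), so long sequences weigh proportionally more.
#'
#' @param seqs Character vector of DNA sequences (at least one).
#' @inheritParams find_hits
#' @return One-row tibble with `covered_count`, `sequence_length`, `density`.
#' @export
#' @examples
#' pooled_density(c("AGATAGGGGA", "GGTGATAACA"), "GGA")
pooled_density <- function(seqs, motifs) {
  seqs <- check_dna_vec(seqs)
  motifs <- check_motifs(motifs)
  x <- pooled_cov(seqs, motifs)
  tibble(
    covered_count = unname(x[1]),
    sequence_length = unname(x[2]),
    density = unname(x[1] / x[2])
  )
}

#' Remove motif-matched positions and split the remainder
#'
#' Returns the maximal runs of positions not covered by any motif hit, in
#' order. Parts separated by a hit are kept separate rather than
#' concatenated, which prevents spurious motifs from forming at the joins.
#' Re-scanning the parts with the same motif set finds no hits.
#'
#' @inheritParams find_hits
#' @return Character vector of unmatched sequence parts (possibly empty).
#' @export
#' @examples
#' mask_and_split("ACTACTTTTTAGA", "TTT") # "ACTAC" "AGA"
mask_and_split <- function(seq, motifs) {
  seq <- check_dna(seq)
  motifs <- check_motifs(motifs)
  L <- nchar(seq)
  keep <- rep(TRUE, L)
  keep[covered_positions(seq, motifs)] <- FALSE
  if (!any(keep)) {
    return(character(0))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  substring(seq, starts[r$values], ends[r$values])
}

#' Does a motif contain a stop codon?
#'
#' TRUE if TAA, TAG or TGA occurs at any offset of the motif. Motifs shorter
#' than three nucleotides cannot contain a codon and return FALSE.
#'
#' @param motif A single DNA motif.
#' @return Logical scalar.
#' @export
#' @examples
#' motif_contains_stop("GAAGAA") # FALSE
#' motif_contains_stop("TTGATT") # TRUE (TGA at offset 2)
motif_contains_stop <- function(motif) {
  motif <- check_dna(motif, "motif")
  if (nchar(motif) < 3L) {
    return(FALSE)
  }
  length(covered_positions(motif, stop_codons())) > 0L
}
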