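# Dinucleotide-matched pseudo-motif sets: the motif-level null model. Each
# pseudo-set has exactly the size and length multiset of the true motif set,
# with motifs assembled from dinucleotides sampled at the true set's
# overlapping-dinucleotide frequencies (odd lengths are padded with one
# nucleotide drawn from the true mononucleotide distribution).

#' Dinucleotide profile of a motif set
#'
#' Counts every overlapping adjacent base pair in every motif (the motif
#' GAAGTA contributes GA, AA, AG, GT, TA), plus the mononucleotide counts
#' used for odd-length padding.
#'
#' @param motifs Character vector of motifs, each of length >= 2.
#' @return A `dinuc_profile` object: list with `dinucleotides` (named
#'   integer vector over the 16 dinucleotides) and `nucleotides` (named
#'   integer vector over A/C/G/T).
#' @export
#' @examples
#' dinucleotide_profile("GAAGTA")$dinucleotides[c("GA", "AA", "AG", "GT", "TA")]
dinucleotide_profile <- function(motifs) {
  motifs <- check_dna_vec(motifs, "motifs")
  if (any(nchar(motifs) < 2L)) {
    abort("all motifs must have length >= 2 to define dinucleotides")
  }
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  di_counts <- stats::setNames(integer(16), sort(dinucs))
  nt_counts <- stats::setNames(integer(4), DNA_BASES)
  for (m in motifs) {
    k <- nchar(m)
    pairs <- substring(m, 1:(k - 1L), 2:k)
    tab <- table(pairs)
    di_counts[names(tab)] <- di_counts[names(tab)] + as.integer(tab)
    ch <- table(seq_chars(m))
    nt_counts[names(ch)] <- nt_counts[names(ch)] + as.integer(ch)
  }
  structure(
    list(dinucleotides = di_counts, nucleotides = nt_counts),
    class = "dinuc_profile"
  )
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat(
    "<dinuc_profile>", sum(x$dinucleotides), "dinucleotides,",
    sum(x$nucleotides), "nucleotides\n"
  )
  invisible(x)
}

#' Sample one pseudo-motif from a dinucleotide profile
#'
#' Draws `floor(length / 2)` dinucleotides independently with probabilities
#' proportional to the profile counts and concatenates them; for odd lengths
#' one nucleotide from the mononucleotide counts is appended. Uses the
#' current RNG state (seed at the caller).
#'
#' @param length Target motif length (>= 2).
#' @param profile A [dinucleotide_profile()] object.
#' @return A single DNA motif of the requested length.
#' @export
sample_pseudo_motif <- function(length, profile) {
  stopifnot(inherits(profile, "dinuc_profile"))
  if (length < 2L) {
    abort("pseudo-motif length must be >= 2")
  }
  if (sum(profile$dinucleotides) == 0L) {
    abort("degenerate profile: all dinucleotide counts are zero")
  }
  n_di <- length %/% 2L
  di <- sample(
    names(profile$dinucleotides), n_di,
    replace = TRUE, prob = profile$dinucleotides
  )
  out <- paste(di, collapse = "")
  if (length %% 2L == 1L) {
    if (sum(profile$nucleotides) == 0L) {
      abort("degenerate profile: all nucleotide counts are zero")
    }
    out <- paste0(
      out,
      sample(names(profile$nucleotides), 1L, prob = profile$nucleotides)
    )
  }
  out
}

#' Generate one dinucleotide-matched pseudo-motif set
#'
#' One pseudo-motif per true motif, of the same length. A pseudo-motif that
#' duplicates another already generated in the same iteration is discarded
#' and resampled; uniqueness is enforced only within the iteration
#' (pseudo-motifs equal to true motifs are allowed). Uses the current RNG
#' state.
#'
#' @param true_set Character vector of true motifs (nonempty, lengths >= 2).
#' @param profile Optional precomputed [dinucleotide_profile()]; computed
#'   from `true_set` when missing.
#' @param max_retries Resampling attempts per motif before a saturation
#'   error (the profile may support fewer distinct motifs than the set
#'   size).
#' @return Character vector of pseudo-motifs, same length multiset as
#'   `true_set`.
#' @export
generate_pseudo_set <- function(true_set, profile = NULL, max_retries = 1000L) {
  true_set <- check_dna_vec(true_set, "true_set")
  profile <- profile %||% dinucleotide_profile(true_set)
  out <- character(length(true_set))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(true_set)) {
    len <- nchar(true_set[i])
    tries <- 0L
    repeat {
      cand <- sample_pseudo_motif(len, profile)
      if (!exists(cand, envir = seen, inherits = FALSE)) break
      tries <- tries + 1L
      if (tries >= max_retries) {
        abort(sprintf(
          "pseudo-motif sampling saturated after %d retries: profile supports too few distinct motifs for a set of size %d",
          max_retries, length(true_set)
        ))
      }
    }
    seen[[cand]] <- TRUE
    out[i] <- cand
  }
  out
}

#' Motif-level null distribution of a query set's density
#'
#' The observed value is the pooled coverage density of the query motifs
#' (e.g. the stop codons) across the true motif set, treating each motif as
#' a short sequence. Each iteration generates a dinucleotide-matched
#' pseudo-motif set and records the same pooled density, yielding the null
#' distribution from which fold enrichment and empirical p are computed.
#'
#' @param true_set Character vector of true motifs.
#' @param query Character vector of query motifs (default the stop codons).
#' @param n_iterations Number of pseudo-sets (the reference analyses use
#'   10,000 for motif nulls).
#' @param seed Integer master seed; per-iteration child seeds are derived
#'   from it, so runs are reproducible and order-independent.
#' @param max_retries Passed to [generate_pseudo_set()].
#' @return A [null_distribution()] object.
#' @export
#' @examples
#' eses <- c("GAAGAA", "GAAGAC", "CTGAAG", "AAGAAC")
#' nd <- motif_null_distribution(eses, n_iterations = 50, seed = 1)
#' tidy(nd)
motif_null_distribution <- function(true_set, query = stop_codons(),
                                    n_iterations = 10000L, seed = 1L,
                                    max_retries = 1000L) {
  true_set <- check_dna_vec(true_set, "true_set")
  query <- check_motifs(query, "query")
  if (n_iterations < 1L) {
    abort("`n_iterations` must be >= 1")
  }
  profile <- dinucleotide_profile(true_set)
  observed <- pooled_density_value(true_set, query)
  seeds <- child_seeds(seed, n_iterations)
  simulants <- vapply(seeds, function(s) {
    pseudo <- with_seed(s, generate_pseudo_set(true_set, profile, max_retries))
    pooled_density_value(pseudo, query)
  }, numeric(1))
  null_distribution(observed, simulants)
}
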