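# Enumeration of unordered three-codon sets and compositionally matched
# control groups for the stop-codon set. The stop set has 2 of 9 positions
# G/C (GC = 0.222) and 6 of 9 purines (A/G); matched groups equate one or
# both totals. Used to ask whether a depletion is specific to the stop
# codons or a by-product of their composition.

all_codons <- function() {
  b <- DNA_BASES
  sort(apply(expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1],
    1, paste,
    collapse = ""
  ))
}

count_chars <- function(x, chars) {
  vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) sum(ch %in% chars), integer(1)
  )
}

#' Can two codons overlap?
#'
#' TRUE if some length-1 or length-2 suffix of one codon equals the
#' same-length prefix of the other, in either orientation. A codon may
#' overlap itself (e.g. AAA: suffix AA = prefix AA).
#'
#' @param x,y Codons (3-mers over A/C/G/T).
#' @return Logical scalar.
#' @export
#' @examples
#' codons_can_overlap("TAA", "TAG") # FALSE
#' codons_can_overlap("GAT", "ATG") # TRUE (shared AT)
codons_can_overlap <- function(x, y) {
  x <- check_dna(x, "x")
  y <- check_dna(y, "y")
  if (nchar(x) != 3L || nchar(y) != 3L) {
    abort("`x` and `y` must be codons (length 3)")
  }
  for (k in 1:2) {
    if (substr(x, 4L - k, 3L) == substr(y, 1L, k)) {
      return(TRUE)
    }
    if (substr(y, 4L - k, 3L) == substr(x, 1L, k)) {
      return(TRUE)
    }
  }
  FALSE
}

# 64 x 64 logical matrix of pairwise overlap capability, codon-name indexed.
codon_overlap_matrix <- function() {
  codons <- all_codons()
  pre1 <- substr(codons, 1, 1)
  pre2 <- substr(codons, 1, 2)
  suf1 <- substr(codons, 3, 3)
  suf2 <- substr(codons, 2, 3)
  m <- outer(suf1, pre1, "==") | outer(suf2, pre2, "==")
  m <- m | t(m)
  dimnames(m) <- list(codons, codons)
  m
}

#' Enumerate all unordered sets of three distinct codons
#'
#' All 64 x 63 x 62 = 249,984 ordered triples of distinct codons collapse to
#' 249,984 / 3! = 41,664 unordered sets (stop codons included in the
#' universe). Each set is represented by its lexicographically sorted codon
#' triple with derived composition attributes.
#'
#' @return Tibble with 41,664 rows and columns `codon1`, `codon2`, `codon3`
#'   (sorted), `gc_count` (G/C characters over all nine positions, 0-9),
#'   `purine_count` (A/G characters, 0-9), `contains_stop` (any member is
#'   TAA/TAG/TGA) and `has_internal_overlap` (some pair of *distinct*
#'   members can overlap at offset 1 or 2, in either order).
#' @export
enumerate_tricodon_sets <- function() {
  codons <- all_codons()
  gc <- count_chars(codons, c("G", "C"))
  pu <- count_chars(codons, c("A", "G"))
  is_stop <- codons %in% stop_codons()
  ov <- codon_overlap_matrix()
  idx <- utils::combn(length(codons), 3L)
  i1 <- idx[1, ]
  i2 <- idx[2, ]
  i3 <- idx[3, ]
  tibble(
    codon1 = codons[i1],
    codon2 = codons[i2],
    codon3 = codons[i3],
    gc_count = gc[i1] + gc[i2] + gc[i3],
    purine_count = pu[i1] + pu[i2] + pu[i3],
    contains_stop = is_stop[i1] | is_stop[i2] | is_stop[i3],
    has_internal_overlap =
      ov[cbind(i1, i2)] | ov[cbind(i1, i3)] | ov[cbind(i2, i3)]
  )
}

is_reference_set <- function(sets) {
  ref <- sort(stop_codons())
  sets$codon1 == ref[1] & sets$codon2 == ref[2] & sets$codon3 == ref[3]
}

#' Filter the tricodon enumeration to compositional matches
#'
#' Applies the conjunction of the requested criteria. By default the
#' stop-codon set itself is dropped from the result (`drop_reference =
#' TRUE`): the matched sets serve as *controls* compared against the stop
#' set, which is trivially its own compositional match. Against the full
#' enumeration the canonical control-group sizes are: GC-matched
#' (`gc_match = 2`) 2,879; GC and purine matched (`purine_match = 6`) 473;
#' GC-matched without stop members 2,121; GC-matched without internal
#' overlap 131. The purine-only group is usually quoted with the reference
#' retained (`drop_reference = FALSE`), giving 6,856.
#'
#' @param sets Tibble from [enumerate_tricodon_sets()].
#' @param gc_match,purine_match Optional integers in 0-9: required total
#'   G/C (resp. A/G) character count.
#' @param exclude_stop_members Drop sets containing any stop codon member.
#' @param require_no_overlap Keep only sets whose distinct members cannot
#'   overlap one another.
#' @param drop_reference Drop the stop-codon set itself from the result.
#' @return Filtered tibble.
#' @export
#' @examples
#' sets <- enumerate_tricodon_sets()
#' nrow(filter_sets(sets, gc_match = 2)) # 2879
filter_sets <- function(sets, gc_match = NULL, purine_match = NULL,
                        exclude_stop_members = FALSE,
                        require_no_overlap = FALSE,
                        drop_reference = TRUE) {
  check_match_arg <- function(v, nm) {
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 0 || v > 9)) {
      abort(sprintf("`%s` must be a single integer in [0, 9]", nm))
    }
  }
  check_match_arg(gc_match, "gc_match")
  check_match_arg(purine_match, "purine_match")
  keep <- rep(TRUE, nrow(sets))
  if (!is.null(gc_match)) keep <- keep & sets$gc_count == gc_match
  if (!is.null(purine_match)) keep <- keep & sets$purine_count == purine_match
  if (exclude_stop_members) keep <- keep & !sets$contains_stop
  if (require_no_overlap) keep <- keep & !sets$has_internal_overlap
  if (drop_reference) keep <- keep & !is_reference_set(sets)
  sets[keep, ]
}

#' Compare a target fold enrichment against matched control sets
#'
#' Counts how many matched control sets have FE strictly greater than the
#' target's FE, and tests whether that fraction exceeds one half with a
#' one-tailed exact binomial test (null probability of success 0.5). A large
#' fraction means the target is depleted beyond what its composition
#' predicts.
#'
#' @param matched_fe Numeric vector of FE values for the matched control
#'   sets (nonempty).
#' @param target_fe FE of the target (e.g. stop-codon) set.
#' @return One-row tibble with `n_greater`, `n`, `fraction`, `p_binomial`.
#' @export
compare_against_matched <- function(matched_fe, target_fe) {
  if (length(matched_fe) == 0L) {
    abort("`matched_fe` must be nonempty")
  }
  if (!is.numeric(target_fe) || length(target_fe) != 1L) {
    abort("`target_fe` must be a single numeric value")
  }
  m <- sum(matched_fe > target_fe)
  n <- length(matched_fe)
  tibble(
    n_greater = as.integer(m),
    n = as.integer(n),
    fraction = m / n,
    p_binomial = binom.test(m, n, p = 0.5, alternative = "greater")$p.value
  )
}
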