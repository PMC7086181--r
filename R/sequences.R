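# Internal sequence validation helpers. All sequences in the package are
# plain uppercase character scalars over {A,C,G,T}; validation happens at the
# public boundary so hot internal loops can skip it.

DNA_BASES <- c("A", "C", "G", "T")

#' The stop-codon set
#'
#' The three canonical stop codons, the reference motif set for stop codon
#' density (SCD).
#'
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
#' @examples
#' stop_codons()
stop_codons <- function() c("TAA", "TAG", "TGA")

is_valid_dna <- function(x) {
  length(x) == 1L && !is.na(x) && nzchar(x) &&
    !grepl("[^ACGT]", x)
}

check_dna <- function(x, arg = "seq") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single character string", arg))
  }
  x <- toupper(x)
  if (!nzchar(x)) {
    abort(sprintf("`%s` must be a nonempty sequence", arg))
  }
  if (grepl("[^ACGT]", x)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T}", arg))
  }
  x
}

check_dna_vec <- function(x, arg = "seqs") {
  if (!is.character(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a nonempty character vector", arg))
  }
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x) | !nzchar(x) | is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains invalid sequences at positions: %s",
      arg, paste(which(bad), collapse = ", ")
    ))
  }
  x
}

check_motifs <- function(motifs, arg = "motifs") {
  if (length(motifs) == 0L) {
    return(character(0))
  }
  check_dna_vec(motifs, arg)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

gc_fraction <- function(seq) {
  ch <- seq_chars(seq)
  mean(ch %in% c("G", "C"))
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(seq_chars(seq)), collapse = ""))
}

# Run one expression under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive per-iteration child seeds from one master seed, so iterations are
# order-independent and reproducible.
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
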