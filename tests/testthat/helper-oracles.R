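# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# Every covered position by scanning every (offset, motif) pair directly.
brute_hits <- function(seq, motifs) {
  L <- nchar(seq)
  covered <- integer(0)
  for (m in motifs) {
    k <- nchar(m)
    if (k > L) next
    for (p in seq_len(L - k + 1)) {
      if (substr(seq, p, p + k - 1) == m) {
        covered <- c(covered, p:(p + k - 1))
      }
    }
  }
  sort(unique(covered))
}

# Longest pseudo-ORF by enumerating every substring that starts ATG, has
# length a multiple of 3, ends in a stop codon, and contains no internal
# in-frame stop.
brute_porf <- function(seq) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NA_integer_
  for (i in seq_len(max(L - 5, 0))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= L) {
      codon <- substr(seq, j, j + 2L)
      if (codon %in% stops) {
        len <- j + 2L - i + 1L
        if (is.na(best) || len > best) best <- len
        break
      }
      j <- j + 3L
    }
  }
  best
}

# Independent tricodon enumeration from ordered triples: returns a list of
# per-set data built from string keys, cached across test files.
oracle_env <- new.env(parent = emptyenv())

oracle_tricodons <- function() {
  if (!is.null(oracle_env$sets)) {
    return(oracle_env$sets)
  }
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(
    as.vector(outer(b, b, paste0)), b, paste0
  ))
  og <- expand.grid(
    c1 = codons, c2 = codons, c3 = codons,
    stringsAsFactors = FALSE
  )
  og <- og[og$c1 != og$c2 & og$c1 != og$c3 & og$c2 != og$c3, ]
  stopifnot(nrow(og) == 249984)
  keys <- apply(as.matrix(og), 1, function(x) paste(sort(x), collapse = "|"))
  keys <- unique(keys)
  parts <- strsplit(keys, "|", fixed = TRUE)
  nine <- vapply(parts, paste, character(1), collapse = "")
  gc <- nchar(nine) - nchar(gsub("[GC]", "", nine))
  pu <- nchar(nine) - nchar(gsub("[AG]", "", nine))
  has_stop <- vapply(
    parts, function(p) any(p %in% c("TAA", "TAG", "TGA")), logical(1)
  )
  oracle_env$sets <- list(
    keys = keys, parts = parts, gc = gc, purine = pu, has_stop = has_stop
  )
  oracle_env$sets
}

# Overlap between two distinct codons, written as direct substring checks.
oracle_pair_overlaps <- function(x, y) {
  substr(x, 3, 3) == substr(y, 1, 1) ||
    substr(y, 3, 3) == substr(x, 1, 1) ||
    substr(x, 2, 3) == substr(y, 1, 2) ||
    substr(y, 2, 3) == substr(x, 1, 2)
}

oracle_set_overlaps <- function(p) {
  oracle_pair_overlaps(p[1], p[2]) ||
    oracle_pair_overlaps(p[1], p[3]) ||
    oracle_pair_overlaps(p[2], p[3])
}

random_seq <- function(L, gc = 0.5) {
  paste(
    sample(c("A", "C", "G", "T"), L,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}
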