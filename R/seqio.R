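# Reading and writing the formats the pipeline touches: motif lists (one
# k-mer per line), FASTA + BED6 transcript models, and two-column TSV hit
# lists for paralogous-family grouping. FASTA goes through Biostrings; BED
# coordinates follow the 0-based half-open convention throughout.

#' Read a motif list from a plain-text file
#'
#' One motif per line; lines beginning `#` and blank lines are ignored.
#' Motifs are uppercased and de-duplicated preserving first-seen order.
#'
#' @param path Path to the motif file.
#' @return Character vector of unique uppercase motifs.
#' @export
read_motif_list <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("motif file not found: %s", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- trimws(lines[keep])
  bad <- grepl("[^ACGTacgt]", raw)
  if (any(bad)) {
    abort(sprintf(
      "non-ACGT motif at line %d: '%s'",
      which(keep)[which(bad)[1]], raw[which(bad)[1]]
    ))
  }
  motifs <- unique(toupper(raw))
  if (length(motifs) == 0L) {
    abort("empty motif set")
  }
  motifs
}

#' Build a transcript table
#'
#' The unit all density analyses run over: one row per transcript, with
#' ordered exon and intron sequences as list-columns. All sequences are
#' stored sense-strand. When introns are given their count must be one less
#' than the exon count; single-exon transcripts have zero introns.
#'
#' @param transcript_id Character vector of unique ids.
#' @param exons List of character vectors (one vector of exon sequences per
#'   transcript, in genomic order).
#' @param introns Optional list of character vectors of intron sequences; if
#'   omitted, transcripts carry no intron sequence.
#' @return Tibble with columns `transcript_id`, `exons`, `introns`.
#' @export
transcript_tbl <- function(transcript_id, exons, introns = NULL) {
  if (anyDuplicated(transcript_id)) {
    abort("transcript ids must be unique")
  }
  if (length(exons) != length(transcript_id)) {
    abort("`exons` must have one entry per transcript")
  }
  if (is.null(introns)) {
    introns <- purrr::map(exons, function(e) character(0))
  }
  if (length(introns) != length(transcript_id)) {
    abort("`introns` must have one entry per transcript")
  }
  exons <- purrr::map(exons, check_dna_vec, arg = "exons")
  introns <- purrr::map(introns, function(i) {
    if (length(i) == 0L) character(0) else check_dna_vec(i, arg = "introns")
  })
  ok <- purrr::map2_lgl(exons, introns, function(e, i) {
    length(i) == 0L || length(i) == length(e) - 1L
  })
  if (!all(ok)) {
    abort(sprintf(
      "intron count must be exon count - 1 (or zero) for: %s",
      paste(transcript_id[!ok], collapse = ", ")
    ))
  }
  tibble(
    transcript_id = as.character(transcript_id),
    exons = exons,
    introns = introns
  )
}

#' Spliced (mature) transcript sequences
#'
#' @param transcripts A transcript table from [transcript_tbl()] or
#'   [read_transcripts()].
#' @return Named character vector of exon concatenations, one per transcript.
#' @export
spliced_seq <- function(transcripts) {
  out <- purrr::map_chr(transcripts$exons, paste, collapse = "")
  stats::setNames(out, transcripts$transcript_id)
}

#' Number of exons per transcript
#' @inheritParams spliced_seq
#' @return Integer vector.
#' @export
n_exons <- function(transcripts) {
  purrr::map_int(transcripts$exons, length)
}

#' Read transcript models from FASTA (+ optional exon BED)
#'
#' Without a BED file each FASTA record becomes a single-exon transcript.
#' With a BED6 file, each record is treated as a pre-mRNA span: exons are the
#' 0-based half-open intervals (in ascending order, non-overlapping per
#' record) and introns are the gaps between them. Minus-strand records are
#' reverse-complemented at ingest so all models are sense-strand. Records
#' containing non-ACGT characters are dropped with a warning.
#'
#' @param fasta Path to a FASTA file with unique record ids.
#' @param exon_bed Optional path to a BED file (chrom = FASTA record id,
#'   columns start/end, optional name/score/strand).
#' @return A transcript table (see [transcript_tbl()]).
#' @export
read_transcripts <- function(fasta, exon_bed = NULL) {
  if (!file.exists(fasta)) {
    abort(sprintf("FASTA file not found: %s", fasta))
  }
  recs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort("duplicate FASTA record ids")
  }
  seqs <- toupper(as.character(recs))
  names(seqs) <- ids
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warn(sprintf(
      "dropping %d record(s) containing noncanonical nucleotides: %s",
      sum(bad), paste(head(ids[bad], 5), collapse = ", ")
    ))
    seqs <- seqs[!bad]
    ids <- ids[!bad]
  }
  if (length(seqs) == 0L) {
    abort("no valid FASTA records")
  }

  if (is.null(exon_bed)) {
    return(transcript_tbl(ids, purrr::map(unname(seqs), identity)))
  }

  bed <- read_bed(exon_bed)
  unknown <- setdiff(bed$chrom, ids)
  if (length(unknown)) {
    abort(sprintf(
      "BED references unknown record(s): %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  models <- purrr::map(ids[ids %in% bed$chrom], function(id) {
    b <- dplyr::arrange(bed[bed$chrom == id, ], .data$start)
    s <- seqs[[id]]
    L <- nchar(s)
    if (any(b$start < 0L) || any(b$end > L) || any(b$start >= b$end)) {
      abort(sprintf("BED interval out of bounds for record '%s'", id))
    }
    if (any(b$start[-1] < b$end[-nrow(b)])) {
      abort(sprintf("overlapping exon intervals for record '%s'", id))
    }
    strand <- unique(b$strand)
    if (length(strand) > 1L) {
      abort(sprintf("mixed strands for record '%s'", id))
    }
    if (identical(strand, "-")) {
      # flip to sense strand: reverse-complement the record, mirror intervals
      s <- revcomp(s)
      new_start <- L - b$end
      b$end <- L - b$start
      b$start <- new_start
      b <- dplyr::arrange(b, .data$start)
    }
    exons <- substring(s, b$start + 1L, b$end)
    introns <- if (nrow(b) > 1L) {
      substring(s, b$end[-nrow(b)] + 1L, b$start[-1])
    } else {
      character(0)
    }
    # zero-length gaps (abutting exons) are not representable as introns
    if (any(!nzchar(introns))) {
      abort(sprintf("abutting exon intervals for record '%s'", id))
    }
    list(exons = exons, introns = introns)
  })
  kept <- ids[ids %in% bed$chrom]
  transcript_tbl(
    kept,
    purrr::map(models, "exons"),
    purrr::map(models, "introns")
  )
}

read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path))
  }
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(bed) < 3L) {
    abort("BED file must have at least 3 columns")
  }
  tibble(
    chrom = bed[[1]],
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    name = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
    strand = if (ncol(bed) >= 6) bed[[6]] else "+"
  )
}

#' Write transcript models as pre-mRNA FASTA plus exon BED
#'
#' The inverse of [read_transcripts()]: exons and introns are concatenated in
#' genomic order into one pre-mRNA record per transcript and exon intervals
#' are written as BED6 (0-based half-open, plus strand). Transcripts without
#' intron sequence are written as a single exon interval spanning the record.
#'
#' @inheritParams spliced_seq
#' @param fasta,bed Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_transcripts <- function(transcripts, fasta, bed) {
  rows <- purrr::pmap(transcripts, function(transcript_id, exons, introns) {
    n <- length(exons)
    if (length(introns) == 0L && n > 1L) {
      abort(sprintf(
        "transcript '%s' has multiple exons but no introns; cannot lay out pre-mRNA",
        transcript_id
      ))
    }
    pieces <- character(0)
    starts <- integer(n)
    ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      starts[i] <- pos
      pieces <- c(pieces, exons[i])
      pos <- pos + nchar(exons[i])
      ends[i] <- pos
      if (i < n) {
        pieces <- c(pieces, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    list(
      seq = paste(pieces, collapse = ""),
      bed = tibble(
        chrom = transcript_id, start = starts, end = ends,
        name = paste0(transcript_id, "_exon", seq_len(n)),
        score = 0L, strand = "+"
      )
    )
  })
  pre <- Biostrings::DNAStringSet(purrr::map_chr(rows, "seq"))
  names(pre) <- transcripts$transcript_id
  Biostrings::writeXStringSet(pre, fasta)
  bed_tbl <- dplyr::bind_rows(purrr::map(rows, "bed"))
  readr::write_tsv(bed_tbl, bed, col_names = FALSE)
  invisible(list(fasta = fasta, bed = bed))
}

#' Group transcripts into paralogous families from pairwise hits
#'
#' Families are the connected components of the undirected graph whose edges
#' are the significant pairwise similarity hits; ids with no hits form
#' singleton families. Grouping is invariant to hit order and pair
#' orientation. With `representative = "random-member"` one member per family
#' is flagged (seeded, reproducible); `"median-aggregate"` flags none and
#' downstream statistics should take per-family medians.
#'
#' @param ids Character vector of all transcript ids.
#' @param hits Two-column data frame (or matrix) of id pairs, or a path to a
#'   headerless two-column TSV.
#' @param seed Integer seed for representative sampling.
#' @param representative One of `"random-member"`, `"median-aggregate"`.
#' @return Tibble with `transcript_id`, `family` (integer label) and
#'   `representative` (logical).
#' @export
group_families <- function(ids, hits = NULL, seed = 1L,
                           representative = c("random-member", "median-aggregate")) {
  representative <- match.arg(representative)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    abort("`ids` must be unique")
  }
  if (is.character(hits) && length(hits) == 1L && file.exists(hits)) {
    hits <- readr::read_tsv(
      hits,
      col_names = c("a", "b"), show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  if (is.null(hits) || (is.data.frame(hits) && nrow(hits) == 0L)) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    hits <- as.data.frame(hits)
    if (ncol(hits) < 2L) {
      abort("`hits` must have two columns")
    }
    edges <- cbind(as.character(hits[[1]]), as.character(hits[[2]]))
    unknown <- setdiff(c(edges), ids)
    if (length(unknown)) {
      abort(sprintf(
        "hit pairs reference unknown id(s): %s",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(
    g,
    length(setdiff(ids, igraph::V(g)$name)),
    name = setdiff(ids, igraph::V(g)$name)
  )
  comp <- igraph::components(g)
  fam <- comp$membership[ids]
  # relabel families in order of first appearance for determinism
  fam <- match(fam, unique(fam))
  out <- tibble(transcript_id = ids, family = fam)
  if (representative == "random-member") {
    reps <- with_seed(seed, {
      out |>
        dplyr::group_by(.data$family) |>
        dplyr::slice_sample(n = 1) |>
        dplyr::ungroup() |>
        dplyr::pull(.data$transcript_id)
    })
    out$representative <- out$transcript_id %in% reps
  } else {
    out$representative <- FALSE
  }
  attr(out, "representative_policy") <- representative
  out
}
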