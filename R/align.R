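# Exact local alignment primitive.
#
# All chimera boundary localization, screening and read/contig mapping in
# this package goes through one primitive: the maximum-scoring
# Smith-Waterman local alignment with affine gaps, searched on both strands.
# The heavy lifting is delegated to Biostrings::pairwiseAlignment(), which
# computes the exact optimal score (no heuristics); the test suite checks it
# against an independent brute-force dynamic-programming oracle.
#
# Affine gap convention: a gap of length k costs gap_open + k * gap_extend.

#' Alignment scoring scheme
#'
#' Penalties are stored as non-negative magnitudes.  The defaults are
#' BLASTN-like (match +2, mismatch -3, gap open 5, gap extend 2); with
#' these, the default minimum score of 30 corresponds to roughly 15
#' matched bases, keeping short spurious hits out.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (>= 0).
#' @param gap_open gap opening penalty (>= 0).
#' @param gap_extend gap extension penalty (>= 0), charged per gap base.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = 3, gap_open = 5,
                           gap_extend = 2) {
  if (match <= 0) stop("match reward must be positive")
  if (mismatch < 0 || gap_open < 0 || gap_extend < 0) {
    stop("penalties must be non-negative")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

# Substitution matrix over {A,C,G,T,N}; N scores as a mismatch against
# everything (including N), so N bases can never contribute matches.
.subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", "N"] <- -scoring$mismatch
  m
}

#' Reverse-complement a DNA string
#'
#' @param seq character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements (N maps to N).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
}

.empty_hits <- function() {
  data.frame(read_id = character(), ref_id = character(),
             strand = character(), read_start = integer(),
             read_end = integer(), ref_start = integer(),
             ref_end = integer(), score = numeric(), identity = numeric(),
             aligned_read_frac = numeric(), stringsAsFactors = FALSE)
}

# Vectorized local alignment of many query strings against one reference,
# both strands.  Returns one row per query; queries whose best score falls
# below min_score get NA in every alignment column.
.align_to_ref <- function(bases, read_ids, ref_seq, ref_id, scoring,
                          min_score, both_strands = TRUE) {
  stopifnot(length(bases) == length(read_ids))
  if (!length(bases)) return(.empty_hits())
  mat <- .subst_matrix(scoring)
  pats <- Biostrings::DNAStringSet(bases)
  subj <- if (methods::is(ref_seq, "DNAString")) ref_seq else
    Biostrings::DNAString(as.character(ref_seq))
  align1 <- function(p) {
    Biostrings::pairwiseAlignment(
      p, subj, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  }
  pa_f <- align1(pats)
  sc_f <- Biostrings::score(pa_f)
  if (both_strands) {
    pa_r <- align1(Biostrings::reverseComplement(pats))
    sc_r <- Biostrings::score(pa_r)
  } else {
    pa_r <- NULL
    sc_r <- rep(-Inf, length(bases))
  }
  use_rev <- sc_r > sc_f  # ties go to the + strand
  L <- nchar(bases)
  out <- .empty_hits()[seq_along(bases), , drop = FALSE]
  out$read_id <- read_ids
  out$ref_id <- ref_id
  out$strand <- ifelse(use_rev, "-", "+")
  grab <- function(pa, idx) {
    if (!length(idx)) return(NULL)
    sub <- pa[idx]
    list(rs = Biostrings::start(Biostrings::pattern(sub)) - 1L,
         re = Biostrings::end(Biostrings::pattern(sub)),
         fs = Biostrings::start(Biostrings::subject(sub)) - 1L,
         fe = Biostrings::end(Biostrings::subject(sub)),
         nm = Biostrings::nmatch(sub),
         nc = Biostrings::nchar(sub))
  }
  fwd_idx <- which(!use_rev)
  rev_idx <- which(use_rev)
  g <- grab(pa_f, fwd_idx)
  if (!is.null(g)) {
    out$read_start[fwd_idx] <- g$rs
    out$read_end[fwd_idx] <- g$re
    out$ref_start[fwd_idx] <- g$fs
    out$ref_end[fwd_idx] <- g$fe
    out$score[fwd_idx] <- sc_f[fwd_idx]
    out$identity[fwd_idx] <- g$nm / pmax(g$nc, 1L)
  }
  g <- grab(pa_r, rev_idx)
  if (!is.null(g)) {
    # spans were computed on the reverse-complemented read; mirror back
    out$read_start[rev_idx] <- L[rev_idx] - g$re
    out$read_end[rev_idx] <- L[rev_idx] - g$rs
    out$ref_start[rev_idx] <- g$fs
    out$ref_end[rev_idx] <- g$fe
    out$score[rev_idx] <- sc_r[rev_idx]
    out$identity[rev_idx] <- g$nm / pmax(g$nc, 1L)
  }
  out$aligned_read_frac <- (out$read_end - out$read_start) / L
  below <- out$score < min_score
  nacols <- c("strand", "read_start", "read_end", "ref_start", "ref_end",
              "score", "identity", "aligned_read_frac")
  out[below, nacols] <- NA
  out$ref_id[below] <- NA_character_
  out
}

#' Best local alignments of a set of reads against a reference set
#'
#' For each read, returns the best Smith-Waterman local alignment over all
#' references and both strands, or an all-NA row if no alignment reaches
#' `min_score`.  Co-optimal hits are resolved deterministically: higher
#' score, then earlier reference in `refs`, then smaller read start, then
#' the + strand.
#'
#' @param reads a [read_set()], or a character vector of sequences.
#' @param refs references acceptable to [read_fasta()] output
#'   (named `DNAStringSet` or named character vector).
#' @param scoring a [scoring_scheme()].
#' @param min_score minimum alignment score to report a hit.
#' @param both_strands search the reverse complement as well (default TRUE).
#' @return data.frame with one row per read: `read_id`, `ref_id`, `strand`,
#'   `read_start`, `read_end`, `ref_start`, `ref_end` (0-based half-open),
#'   `score`, `identity`, `aligned_read_frac`.
#' @export
best_hits <- function(reads, refs, scoring = scoring_scheme(),
                      min_score = 30, both_strands = TRUE) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("q", seq_along(reads))
    bases <- toupper(unname(reads))
  } else {
    ids <- reads$read_id
    bases <- reads$bases
  }
  refs <- as_refs(refs)
  if (!length(refs)) stop("reference set is empty")
  best <- NULL
  for (k in seq_along(refs)) {
    hit <- .align_to_ref(bases, ids, refs[[k]], names(refs)[k], scoring,
                         min_score, both_strands)
    if (is.null(best)) {
      best <- hit
    } else {
      # strictly-greater keeps the earlier reference on score ties
      hit_score <- ifelse(is.na(hit$score), -Inf, hit$score)
      best_score <- ifelse(is.na(best$score), -Inf, best$score)
      take <- hit_score > best_score
      best[take, ] <- hit[take, ]
    }
  }
  rownames(best) <- NULL
  best
}

#' Best local alignment of one query against one reference
#'
#' @param query a single sequence (character) or one-row [read_set()].
#' @param ref a single reference sequence (character or `DNAStringSet` of
#'   length 1).
#' @inheritParams best_hits
#' @return a one-row hit data.frame as in [best_hits()], or `NULL` when the
#'   best score is below `min_score`.
#' @export
local_align <- function(query, ref, scoring = scoring_scheme(),
                        min_score = 30, both_strands = TRUE) {
  hit <- best_hits(query, as_refs(ref)[1], scoring, min_score, both_strands)
  if (is.na(hit$score[1])) return(NULL)
  hit[1, , drop = FALSE]
}

#' Best hit of one query over a list of references
#'
#' Convenience single-query wrapper around [best_hits()].
#'
#' @inheritParams local_align
#' @param refs references (named `DNAStringSet` or named character vector).
#' @return a one-row hit data.frame, or `NULL` if nothing reaches
#'   `min_score`.
#' @export
best_hit <- function(query, refs, scoring = scoring_scheme(),
                     min_score = 30, both_strands = TRUE) {
  hit <- best_hits(query, refs, scoring, min_score, both_strands)
  if (is.na(hit$score[1])) return(NULL)
  hit[1, , drop = FALSE]
}
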