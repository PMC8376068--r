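# Screening candidate sequence databases for rRNA contamination.
#
# Two routes to the same report: direct local alignment of the rRNA
# references against each target, or stacking of mock reads generated from
# the rRNA references and mapped onto the targets.  Hits are reported with
# 1-based start, length, supporting identity/read count, and the percentile
# bin of the start position relative to the target length (the x-axis of a
# contamination-position histogram: contamination at sequence extremities
# points to premature assembly termination by chimeric bridge reads).

.hit_percentile <- function(start_1based, target_len) {
  as.integer(floor(100 * (start_1based - 1) / target_len))
}

.empty_contamination <- function() {
  data.frame(target_id = character(), start = integer(), length = integer(),
             percentile = integer(), identity = numeric(),
             n_reads = integer(), stringsAsFactors = FALSE)
}

# Merge raw target-coordinate intervals (0-based half-open) that are within
# merge_gap bases of each other; returns an IRanges.
.merge_target_intervals <- function(starts0, ends0, merge_gap = 10L) {
  ir <- IRanges::IRanges(start = starts0 + 1L, end = ends0)
  IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
}

#' Screen targets for rRNA stretches by direct local alignment
#'
#' For each target, repeatedly finds the best local alignment of each rRNA
#' reference (both strands), masks it, and searches again, collecting every
#' stretch of length at least `min_len` with identity at least
#' `min_identity`.  Stretches from different rRNA references that overlap
#' or lie within `merge_gap` bases are merged into one reported interval.
#'
#' @param rrna_refs rRNA references.
#' @param targets candidate sequences to screen.
#' @param scoring a [scoring_scheme()].
#' @param min_len minimum stretch length to call contamination
#'   (default 50 bp: long enough to exclude the rare natural 15-54 nt
#'   rRNA incorporations while catching assembly-scale contamination).
#' @param min_identity minimum alignment identity (default 0.90).
#' @param merge_gap merge hits within this many bases (default 10).
#' @param max_hits_per_pair iteration cap per (rRNA, target) pair.
#' @return data.frame of contamination hits: `target_id`, `start`
#'   (1-based), `length`, `percentile`, `identity`, `n_reads` (NA for the
#'   direct route).
#' @export
screen_targets_direct <- function(rrna_refs, targets,
                                  scoring = scoring_scheme(),
                                  min_len = 50L, min_identity = 0.90,
                                  merge_gap = 10L, max_hits_per_pair = 20L) {
  rrna_refs <- as_refs(rrna_refs)
  targets <- as_refs(targets)
  if (!length(targets)) stop("no targets to screen")
  min_score <- ceiling(min_len * scoring$match * min_identity / 2)
  sel_cfg <- list(scoring = scoring, boundary_match_run = 5L,
                  min_segment_identity = min_identity,
                  min_score = min_score)
  out <- list()
  for (t in seq_along(targets)) {
    tgt_id <- names(targets)[t]
    tgt_len <- Biostrings::width(targets)[t]
    starts0 <- integer(); ends0 <- integer(); idents <- numeric()
    for (r in seq_along(rrna_refs)) {
      rrna_chr <- as.character(rrna_refs[[r]])
      masked <- as.character(targets[[t]])
      for (it in seq_len(max_hits_per_pair)) {
        hit <- local_align(stats::setNames(rrna_chr, names(rrna_refs)[r]),
                           stats::setNames(masked, tgt_id),
                           scoring = scoring, min_score = min_score)
        if (is.null(hit)) break
        # polish stretch boundaries the same way chimera excision does:
        # keep the best column block anchored in exact-match runs, and
        # take its span on the *target* side
        sel <- .select_segments(
          rrna_chr,
          data.frame(ref_id = tgt_id, strand = hit$strand,
                     seg_start = hit$read_start, seg_end = hit$read_end,
                     stringsAsFactors = FALSE),
          stats::setNames(Biostrings::DNAStringSet(masked), tgt_id),
          sel_cfg)
        if (!sel$ok[1]) break
        span_len <- sel$ref_end[1] - sel$ref_start[1]
        if (span_len < min_len || sel$identity[1] < min_identity) break
        starts0 <- c(starts0, sel$ref_start[1])
        ends0 <- c(ends0, sel$ref_end[1])
        idents <- c(idents, sel$identity[1])
        # mask the found stretch so the next iteration finds other copies
        substr(masked, sel$ref_start[1] + 1L, sel$ref_end[1]) <-
          strrep("N", span_len)
      }
    }
    if (!length(starts0)) next
    merged <- .merge_target_intervals(starts0, ends0, merge_gap)
    for (i in seq_along(merged)) {
      s1 <- IRanges::start(merged)[i]
      covering <- starts0 + 1L <= IRanges::end(merged)[i] &
        ends0 >= s1
      out[[length(out) + 1L]] <- data.frame(
        target_id = tgt_id, start = s1,
        length = IRanges::width(merged)[i],
        percentile = .hit_percentile(s1, tgt_len),
        identity = max(idents[covering]),
        n_reads = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_contamination())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen targets for rRNA stretches with mock reads
#'
#' Generates mock reads from the rRNA references, maps each read onto the
#' targets with [best_hits()], stacks the mapped read intervals per target
#' and reports every merged interval (depth >= 1) as a contamination hit.
#' This emulates probing a database with a simulated sequencing run.
#'
#' @inheritParams screen_targets_direct
#' @param mock_cfg a [mock_config()]; keep `n_reads` modest, these reads
#'   are held in memory.
#' @param min_score minimum mapping score for a read to count.
#' @return data.frame of contamination hits as in
#'   [screen_targets_direct()], with `n_reads` = supporting read count and
#'   `identity` = mean identity of supporting reads.
#' @export
screen_targets_mockreads <- function(rrna_refs, targets,
                                     mock_cfg = mock_config(n_reads = 2000),
                                     scoring = scoring_scheme(),
                                     min_score = 30, merge_gap = 10L) {
  rrna_refs <- as_refs(rrna_refs)
  targets <- as_refs(targets)
  reads <- generate_mock_reads(rrna_refs, mock_cfg)
  hits <- best_hits(reads, targets, scoring = scoring,
                    min_score = min_score)
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  if (!nrow(hits)) return(.empty_contamination())
  out <- list()
  for (tgt_id in unique(hits$ref_id)) {
    sub <- hits[hits$ref_id == tgt_id, , drop = FALSE]
    tgt_len <- Biostrings::width(targets)[names(targets) == tgt_id]
    merged <- .merge_target_intervals(sub$ref_start, sub$ref_end, merge_gap)
    for (i in seq_along(merged)) {
      s1 <- IRanges::start(merged)[i]
      e1 <- IRanges::end(merged)[i]
      covering <- sub$ref_start + 1L <= e1 & sub$ref_end >= s1
      out[[length(out) + 1L]] <- data.frame(
        target_id = tgt_id, start = s1,
        length = IRanges::width(merged)[i],
        percentile = .hit_percentile(s1, tgt_len),
        identity = mean(sub$identity[covering]),
        n_reads = sum(covering), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$target_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Histogram of contamination start percentiles
#'
#' @param hits a contamination hit data.frame (see
#'   [screen_targets_direct()]).
#' @return integer vector of length 100: hit counts per percentile bin
#'   0..99; the sum equals the number of hits.
#' @export
percentile_histogram <- function(hits) {
  counts <- integer(100)
  if (nrow(hits)) {
    tab <- tabulate(hits$percentile + 1L, nbins = 100L)
    counts <- as.integer(tab)
  }
  names(counts) <- 0:99
  counts
}
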