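# Evaluation of cleanup impact: read-overlap (Venn) counts, a toy greedy
# overlap assembler, and contig/genome metrics.
#
# The assembler is deliberately minimal -- exact suffix-prefix overlaps
# only, greedy longest-first merging, deterministic tie-breaking -- and is
# a desk-scale stand-in for a real de novo assembler.  It exists to make
# the chimeric-bridge phenomenon reproducible: a single chimeric read whose
# two moieties overlap an rRNA pile and a virus pile will fuse them into
# one chimeric contig, and removing (or curing) that read separates them.

#' Read-overlap (Venn) counts against two reference sets
#'
#' Each read is assigned to one of four cells by whether its best hit
#' against the rRNA references and against the virus reference(s) clears
#' `min_score`.
#'
#' @param reads a [read_set()].
#' @param rrna_refs rRNA references.
#' @param virus_refs virus reference(s).
#' @param scoring a [scoring_scheme()].
#' @param min_score minimum alignment score to count a mapping.
#' @return named integer vector: `rrna_only`, `virus_only`, `both`
#'   (chimeric), `neither`; sums to `nrow(reads)`.
#' @export
overlap_counts <- function(reads, rrna_refs, virus_refs,
                           scoring = scoring_scheme(), min_score = 30) {
  if (!nrow(reads)) {
    return(c(rrna_only = 0L, virus_only = 0L, both = 0L, neither = 0L))
  }
  r_hit <- !is.na(best_hits(reads, rrna_refs, scoring, min_score)$score)
  v_hit <- !is.na(best_hits(reads, virus_refs, scoring, min_score)$score)
  c(rrna_only = sum(r_hit & !v_hit),
    virus_only = sum(!r_hit & v_hit),
    both = sum(r_hit & v_hit),
    neither = sum(!r_hit & !v_hit))
}

# longest exact suffix(a)-prefix(b) overlap with min_overlap <= k;
# returns 0 when none.
.best_overlap <- function(a, b, min_overlap) {
  kmax <- min(nchar(a), nchar(b))
  la <- nchar(a)
  if (kmax < min_overlap) return(0L)
  for (k in seq(kmax, min_overlap, by = -1L)) {
    if (substr(a, la - k + 1L, la) == substr(b, 1L, k)) return(k)
  }
  0L
}

# best merge between contigs x and y over strand combinations.
# Returns list(k, merged) or NULL.  Orientations tried in fixed order so
# ties resolve deterministically: x+y, y+x, x+rc(y), rc(y)+x.
.best_merge <- function(x, y, min_overlap) {
  ry <- reverse_complement(y)
  cand <- list(c(x, y), c(y, x), c(x, ry), c(ry, x))
  best_k <- 0L; best <- NULL
  for (cb in cand) {
    # containment counts as a full-length overlap
    if (nchar(cb[2]) <= nchar(cb[1]) &&
        grepl(cb[2], cb[1], fixed = TRUE)) {
      k <- nchar(cb[2])
      if (k > best_k) {
        best_k <- k
        best <- cb[1]
      }
      next
    }
    k <- .best_overlap(cb[1], cb[2], min_overlap)
    if (k > best_k) {
      best_k <- k
      best <- paste0(cb[1], substring(cb[2], k + 1L))
    }
  }
  if (best_k < min_overlap) return(NULL)
  list(k = best_k, merged = best)
}

#' Greedy exact-overlap assembly
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bases (both strands;
#' containment counts as a full-length overlap), until no merge is
#' possible.  Ties are broken deterministically by input order and a fixed
#' orientation order.  Mismatches are not tolerated: this suffices for
#' error-free simulated reads and keeps the routine honest about not being
#' a real assembler.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param min_overlap minimum exact overlap (>= 10).
#' @return named character vector of contigs (`contig_1`, ...) sorted by
#'   decreasing length.
#' @export
greedy_assemble <- function(reads, min_overlap = 20L) {
  if (min_overlap < 10) stop("min_overlap must be >= 10")
  seqs <- if (is.character(reads)) toupper(unname(reads)) else reads$bases
  seqs <- seqs[nchar(seqs) > 0]
  n <- length(seqs)
  if (!n) return(stats::setNames(character(), character()))
  alive <- rep(TRUE, n)
  # overlap cache: ov[i, j] = best merge k between i and j (i < j)
  ov <- matrix(0L, n, n)
  pair_k <- function(i, j) {
    bm <- .best_merge(seqs[i], seqs[j], min_overlap)
    if (is.null(bm)) 0L else bm$k
  }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) ov[i, j] <- pair_k(i, j)
  }
  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    sub <- ov[live, live, drop = FALSE]
    kbest <- max(sub)
    if (kbest < min_overlap) break
    w <- which(sub == kbest, arr.ind = TRUE)
    # deterministic: smallest row index, then column
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    i <- live[w[1, 1]]; j <- live[w[1, 2]]
    bm <- .best_merge(seqs[i], seqs[j], min_overlap)
    seqs[i] <- bm$merged
    alive[j] <- FALSE
    for (t in which(alive)) {
      if (t == i) next
      a <- min(i, t); b <- max(i, t)
      ov[a, b] <- pair_k(a, b)
    }
  }
  contigs <- seqs[alive]
  contigs <- contigs[order(-nchar(contigs))]
  stats::setNames(contigs, paste0("contig_", seq_along(contigs)))
}

#' Contig and genome metrics against a reference genome
#'
#' For each contig with a qualifying local alignment on the genome, the
#' contig coverage is the percentage of the contig's bases inside the
#' aligned span.  Metrics: mean length and mean coverage over mapped
#' contigs, percentage of genome bases covered by at least one contig
#' alignment, and (when `reads` is supplied) the number of reads mapping
#' to the genome.
#'
#' @param contigs contigs (named character vector or `DNAStringSet`).
#' @param genome the reference genome (single sequence).
#' @param scoring a [scoring_scheme()].
#' @param min_score minimum alignment score for a contig/read to count.
#' @param reads optional [read_set()] used for the `used_reads` count.
#' @return an `assembly_metrics` list: `mean_contig_length`,
#'   `mean_contig_coverage` (%), `genome_coverage` (%), `used_reads`,
#'   `n_contigs`, `n_contigs_mapped`, `empty` flag.
#' @export
evaluate_contigs <- function(contigs, genome, scoring = scoring_scheme(),
                             min_score = 30, reads = NULL) {
  genome <- as_refs(genome)[1]
  glen <- Biostrings::width(genome)[1]
  used_reads <- NA_integer_
  if (!is.null(reads)) {
    used_reads <- if (nrow(reads)) {
      sum(!is.na(best_hits(reads, genome, scoring, min_score)$score))
    } else 0L
  }
  cseq <- if (is.character(contigs)) contigs else
    stats::setNames(as.character(contigs), names(contigs))
  if (!length(cseq)) {
    return(structure(list(mean_contig_length = 0, mean_contig_coverage = 0,
                          genome_coverage = 0, used_reads = used_reads,
                          n_contigs = 0L, n_contigs_mapped = 0L,
                          empty = TRUE),
                     class = "assembly_metrics"))
  }
  if (is.null(names(cseq))) names(cseq) <- paste0("contig_", seq_along(cseq))
  hits <- best_hits(cseq, genome, scoring, min_score)
  mapped <- !is.na(hits$score)
  clen <- nchar(cseq)
  cov <- 100 * (hits$read_end - hits$read_start) / clen
  gcov <- 0
  if (any(mapped)) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = hits$ref_start[mapped] + 1L, end = hits$ref_end[mapped]))
    gcov <- 100 * sum(IRanges::width(ir)) / glen
  }
  structure(list(
    mean_contig_length = if (any(mapped)) mean(clen[mapped]) else 0,
    mean_contig_coverage = if (any(mapped)) mean(cov[mapped]) else 0,
    genome_coverage = gcov,
    used_reads = used_reads,
    n_contigs = length(cseq),
    n_contigs_mapped = sum(mapped),
    empty = FALSE), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0("assembly metrics: %d contigs (%d mapped), mean ",
                     "length %.1f, mean contig coverage %.2f%%, genome ",
                     "coverage %.2f%%, used reads %s\n"),
              x$n_contigs, x$n_contigs_mapped, x$mean_contig_length,
              x$mean_contig_coverage, x$genome_coverage,
              ifelse(is.na(x$used_reads), "NA", x$used_reads)))
  invisible(x)
}

#' Total rRNA-derived bases detectable in contigs
#'
#' Screens contigs against the rRNA references
#' (via [screen_targets_direct()]) and sums the lengths of the reported
#' stretches.  Used to quantify contamination of an assembly.
#'
#' @param contigs contigs (named character vector or `DNAStringSet`).
#' @param rrna_refs rRNA references.
#' @param min_len minimum stretch length to count (default 30).
#' @param ... passed to [screen_targets_direct()].
#' @return total contaminated bases (integer).
#' @export
contig_rrna_bases <- function(contigs, rrna_refs, min_len = 30L, ...) {
  if (!length(contigs)) return(0L)
  cseq <- if (is.character(contigs)) contigs else
    stats::setNames(as.character(contigs), names(contigs))
  if (is.null(names(cseq))) names(cseq) <- paste0("contig_", seq_along(cseq))
  hits <- screen_targets_direct(rrna_refs, cseq, min_len = min_len, ...)
  as.integer(sum(hits$length))
}

#' Build a deterministic dataset for the three-strategy comparison
#'
#' Constructs a read set in which chimeric reads are essential: clean
#' virus reads tile the genome except for a window that is covered only by
#' the viral moieties of rRNA-virus chimeric reads, plus a pile of pure
#' rRNA reads.  Discarding whole chimeric reads therefore loses the window;
#' curing them recovers it.  Roughly 30% of reads are chimeric.
#'
#' @param rrna_refs rRNA references.
#' @param virus_ref virus reference (single sequence, >= 2 kb advised).
#' @param tile_len clean read length (default 100).
#' @param tile_step tiling step (default 60; overlap = tile_len -
#'   tile_step).
#' @param gap window of the genome left uncovered by clean reads, as a
#'   fraction pair of the genome length (default c(0.45, 0.60)).
#' @param flank_len rRNA moiety length of each chimeric read (default 50).
#' @param chimera_step step between chimeric reads' viral spans
#'   (default 25).
#' @param n_pure_rrna pure rRNA tiling reads (default 7).
#' @param phred constant quality (default 30).
#' @param seed RNG seed (moiety source positions and strands).
#' @return list with `reads` (a [read_set()]) and `truth` (per-read class
#'   data.frame).
#' @export
build_comparison_dataset <- function(rrna_refs, virus_ref, tile_len = 100L,
                                     tile_step = 60L,
                                     gap = c(0.45, 0.60), flank_len = 50L,
                                     chimera_step = 25L, n_pure_rrna = 7L,
                                     phred = 30L, seed = 1L) {
  rrna_refs <- as_refs(rrna_refs)
  rrna_chr <- as.character(rrna_refs[[1]])
  virus_chr <- as.character(as_refs(virus_ref)[[1]])
  G <- nchar(virus_chr)
  qc <- substr(phred_to_string(phred), 1, 1)
  g0 <- as.integer(floor(G * gap[1])); g1 <- as.integer(floor(G * gap[2]))
  ids <- character(); bases <- character(); cls <- character()
  with_seed(seed, {
    # clean tiling left of the gap and right of it
    starts <- c(seq(0L, g0 - tile_len, by = tile_step),
                seq(g1 - (tile_len - tile_step), G - tile_len,
                    by = tile_step), G - tile_len)
    starts <- sort(unique(pmax(starts, 0L)))
    for (i in seq_along(starts)) {
      s <- starts[i]
      ids <- c(ids, paste0("tile_", i))
      bases <- c(bases, substring(virus_chr, s + 1L, s + tile_len))
      cls <- c(cls, "clean_virus")
    }
    # chimeras whose viral moieties span the gap (viral part = tile_len
    # - flank_len + flank_len? keep viral moiety 80 bp for solid overlaps)
    vlen <- 80L
    ch_starts <- seq(g0 - vlen %/% 2L, g1 + vlen %/% 2L - vlen,
                     by = chimera_step)
    for (i in seq_along(ch_starts)) {
      s <- ch_starts[i]
      vpart <- substring(virus_chr, s + 1L, s + vlen)
      rs <- sample.int(nchar(rrna_chr) - flank_len, 1L)
      rpart <- substring(rrna_chr, rs, rs + flank_len - 1L)
      rrna_first <- i %% 2L == 0L
      b <- if (rrna_first) paste0(rpart, vpart) else paste0(vpart, rpart)
      ids <- c(ids, paste0("chim_", i))
      bases <- c(bases, b)
      cls <- c(cls, "chimera")
    }
    # pure rRNA tiling reads
    rr_starts <- seq(0L, by = tile_step, length.out = n_pure_rrna)
    for (i in seq_len(n_pure_rrna)) {
      s <- rr_starts[i]
      ids <- c(ids, paste0("rrna_", i))
      bases <- c(bases, substring(rrna_chr, s + 1L, s + tile_len))
      cls <- c(cls, "pure_rrna")
    }
  })
  list(reads = read_set(ids, bases, strrep(qc, nchar(bases))),
       truth = data.frame(read_id = ids, class = cls,
                          stringsAsFactors = FALSE))
}

#' Compare cure / filter / raw strategies end to end
#'
#' Runs three read-handling strategies on the same read set, assembles each
#' result with [greedy_assemble()] and evaluates the contigs against the
#' virus genome:
#' \describe{
#'   \item{cure}{iterative chimera cleanup ([iterate_cleanup()]): pure
#'     rRNA reads discarded, chimeric reads excised and retained.}
#'   \item{filter}{whole-read discard of everything not classified
#'     `non_rrna` (the behaviour of conventional rRNA read filters).}
#'   \item{raw}{no treatment.}
#' }
#'
#' @param reads a [read_set()].
#' @param rrna_refs rRNA references.
#' @param virus_ref virus genome.
#' @param cfg a [cleanup_config()].
#' @param min_overlap assembler overlap floor.
#' @param min_score alignment score floor for the metrics.
#' @return data.frame with one row per strategy: metrics columns plus
#'   `n_input_reads` and `rrna_bases_in_contigs`.
#' @export
compare_strategies <- function(reads, rrna_refs, virus_ref,
                               cfg = cleanup_config(), min_overlap = 20L,
                               min_score = 30) {
  cure <- iterate_cleanup(reads, rrna_refs, cfg)
  calls <- classify_reads(reads, rrna_refs, cfg)
  sets <- list(
    cure = cure$reads,
    filter = reads[calls$verdict == "non_rrna", , drop = FALSE],
    raw = reads)
  rows <- lapply(names(sets), function(nm) {
    rs <- sets[[nm]]
    contigs <- greedy_assemble(rs, min_overlap)
    met <- evaluate_contigs(contigs, virus_ref, min_score = min_score,
                            reads = rs)
    data.frame(strategy = nm,
               n_input_reads = nrow(rs),
               mean_contig_length = met$mean_contig_length,
               mean_contig_coverage = met$mean_contig_coverage,
               genome_coverage = met$genome_coverage,
               used_reads = met$used_reads,
               n_contigs = met$n_contigs,
               rrna_bases_in_contigs = contig_rrna_bases(contigs, rrna_refs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
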