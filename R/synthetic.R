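# Synthetic data: mock database-probing reads and chimeric read simulation.
#
# Mock reads are exact, error-free substrings of a reference at a constant
# quality -- they emulate a sequencing run for the purpose of probing a
# candidate database for rRNA content, not a realistic error process.  The
# chimera simulator builds total-RNA-seq-like read sets in which reads of
# known class (clean virus / pure rRNA / single- or double-moiety chimera)
# carry recorded junctions, giving every downstream stage a ground truth.

# Run code with a private, seeded RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Mock read generator configuration
#'
#' Defaults emulate a database-probing run: 4 million reads per reference,
#' lengths uniform on 90-150 bp, constant Phred 30 quality.
#'
#' @param n_reads reads to emit per reference (default 4e6).
#' @param len_min,len_max read length bounds (defaults 90 and 150 bp).
#' @param phred constant per-base Phred quality (default 30).
#' @param both_strands sample reads from both strands 50/50 (default TRUE);
#'   FALSE reproduces a forward-only variant.
#' @param seed RNG seed; the output is fully determined by it.
#' @return a `mock_config` list.
#' @export
mock_config <- function(n_reads = 4e6, len_min = 90L, len_max = 150L,
                        phred = 30L, both_strands = TRUE, seed = 1L) {
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (len_min < 1 || len_min > len_max) stop("need 1 <= len_min <= len_max")
  structure(list(n_reads = as.double(n_reads), len_min = as.integer(len_min),
                 len_max = as.integer(len_max), phred = as.integer(phred),
                 both_strands = isTRUE(both_strands),
                 seed = as.integer(seed)),
            class = "mock_config")
}

#' Generate mock reads from reference sequences
#'
#' Emits exactly `cfg$n_reads` reads per reference.  Each read is an exact
#' substring of its reference (or of the reverse complement when
#' `both_strands`), with length uniform on `[len_min, len_max]`, start
#' uniform over valid positions and every base at quality `cfg$phred`.
#'
#' With `out = NULL` the reads are returned as a [read_set()] carrying a
#' `truth` attribute (source reference, span and strand per read).  With an
#' output path, records are streamed to a FASTQ file in chunks -- use this
#' for multi-million-read runs -- and a summary is returned invisibly.
#'
#' @param refs references (named `DNAStringSet` or named character vector).
#' @param cfg a [mock_config()].
#' @param out optional FASTQ output path (streaming mode).
#' @param truth_out optional TSV path for source-span ground truth
#'   (streaming mode only).
#' @param chunk_size records generated per streaming chunk.
#' @return a [read_set()] (in-memory mode) or, invisibly, a summary list
#'   with `n_records`, `len_range`, `qual_chars` (streaming mode).
#' @export
generate_mock_reads <- function(refs, cfg = mock_config(), out = NULL,
                                truth_out = NULL, chunk_size = 250000L) {
  refs <- as_refs(refs)
  if (!length(refs)) stop("reference set is empty")
  widths <- Biostrings::width(refs)
  if (any(widths < cfg$len_min)) {
    stop("reference ", names(refs)[which(widths < cfg$len_min)[1]],
         " is shorter than len_min (", cfg$len_min, ")")
  }
  if (any(widths < cfg$len_max)) {
    stop("reference ", names(refs)[which(widths < cfg$len_max)[1]],
         " is shorter than len_max (", cfg$len_max, ")")
  }
  qual_char <- substr(phred_to_string(cfg$phred), 1, 1)
  con <- NULL
  tcon <- NULL
  if (!is.null(out)) {
    con <- file(out, open = "wt")
    on.exit(close(con), add = TRUE)
    if (!is.null(truth_out)) {
      tcon <- file(truth_out, open = "wt")
      on.exit(close(tcon), add = TRUE)
      writeLines("read_id\tref_id\tstart\tend\tstrand", tcon)
    }
  }
  acc <- list()
  n_records <- 0
  len_lo <- Inf; len_hi <- -Inf
  with_seed(cfg$seed, {
    for (k in seq_along(refs)) {
      ref_chr <- as.character(refs[[k]])
      ref_rc <- reverse_complement(ref_chr)
      L <- nchar(ref_chr)
      remaining <- cfg$n_reads
      idx0 <- 0
      while (remaining > 0) {
        m <- as.integer(min(remaining, chunk_size))
        len <- sample.int(cfg$len_max - cfg$len_min + 1L, m,
                          replace = TRUE) + cfg$len_min - 1L
        start1 <- floor(stats::runif(m) * (L - len + 1)) + 1
        rev <- if (cfg$both_strands) stats::runif(m) < 0.5 else
          rep(FALSE, m)
        bases <- character(m)
        if (any(!rev)) {
          bases[!rev] <- substring(ref_chr, start1[!rev],
                                   start1[!rev] + len[!rev] - 1L)
        }
        if (any(rev)) {
          # sample the span on the forward reference, emit its rc
          bases[rev] <- substring(ref_rc, L - (start1[rev] + len[rev] - 1L) + 1L,
                                  L - start1[rev] + 1L)
        }
        ids <- paste0("mock_", names(refs)[k], "_", idx0 + seq_len(m))
        quals <- strrep(qual_char, len)
        n_records <- n_records + m
        len_lo <- min(len_lo, min(len)); len_hi <- max(len_hi, max(len))
        if (is.null(con)) {
          rs <- read_set(ids, bases, quals)
          attr_truth <- data.frame(read_id = ids, ref_id = names(refs)[k],
                                   start = as.integer(start1 - 1L),
                                   end = as.integer(start1 + len - 1L),
                                   strand = ifelse(rev, "-", "+"),
                                   stringsAsFactors = FALSE)
          acc[[length(acc) + 1L]] <- list(rs = rs, truth = attr_truth)
        } else {
          writeLines(paste0("@", ids, "\n", bases, "\n+\n", quals), con)
          if (!is.null(tcon)) {
            writeLines(paste(ids, names(refs)[k], start1 - 1L,
                             start1 + len - 1L, ifelse(rev, "-", "+"),
                             sep = "\t"), tcon)
          }
        }
        idx0 <- idx0 + m
        remaining <- remaining - m
      }
    }
  })
  if (is.null(con)) {
    reads <- do.call(rbind_read_sets, lapply(acc, `[[`, "rs"))
    truth <- do.call(rbind, lapply(acc, `[[`, "truth"))
    rownames(truth) <- NULL
    attr(reads, "truth") <- truth
    return(reads)
  }
  invisible(list(n_records = n_records,
                 len_range = c(len_lo, len_hi),
                 qual_chars = qual_char))
}

#' Per-base source coverage of mock reads on their reference
#'
#' Depth is computed from the generator's ground-truth spans (not from
#' alignment): `depth[i]` is the number of reads whose source span covers
#' base `i` of `ref`.
#'
#' @param mock_reads a [read_set()] from [generate_mock_reads()] (carrying
#'   the `truth` attribute), or the truth data.frame itself.
#' @param ref the reference the reads were drawn from (single sequence),
#'   or its name when the truth covers several references.
#' @return integer vector of per-base depths along the reference.
#' @export
coverage_profile <- function(mock_reads, ref) {
  truth <- attr(mock_reads, "truth")
  if (is.null(truth) && is.data.frame(mock_reads) &&
      all(c("start", "end", "ref_id") %in% names(mock_reads))) {
    truth <- mock_reads
  }
  if (is.null(truth)) {
    stop("mock_reads must carry generator ground truth (truth attribute)")
  }
  refs <- as_refs(ref)
  L <- Biostrings::width(refs)[1]
  nm <- names(refs)[1]
  sub <- if (nm %in% truth$ref_id) {
    truth[truth$ref_id == nm, , drop = FALSE]
  } else {
    truth  # unnamed reference: use all truth rows
  }
  delta <- integer(L + 1L)
  if (nrow(sub)) {
    starts <- pmax(sub$start, 0L) + 1L
    ends <- pmin(sub$end, L) + 1L
    for (i in seq_len(nrow(sub))) {
      delta[starts[i]] <- delta[starts[i]] + 1L
      delta[ends[i]] <- delta[ends[i]] - 1L
    }
  }
  cumsum(delta)[seq_len(L)]
}

#' Chimera simulation configuration
#'
#' @param n_clean_virus,n_pure_rrna,n_single_chimera,n_double_chimera
#'   read counts per class.
#' @param flank_min minimum length of every moiety in a chimeric read
#'   (default 25 bp): junctions are placed uniformly subject to this floor
#'   on both sides, since 1-bp flanks are unlocalizable in principle.
#' @param duplicate_rate per-read probability of emitting one exact PCR
#'   duplicate (default 0).
#' @param len_min,len_max read length bounds (defaults 90 and 150 bp).
#' @param phred constant per-base quality (default 30).
#' @param seed RNG seed.
#' @return a `chimera_sim_config` list.
#' @export
chimera_sim_config <- function(n_clean_virus = 0L, n_pure_rrna = 0L,
                               n_single_chimera = 0L, n_double_chimera = 0L,
                               flank_min = 25L, duplicate_rate = 0,
                               len_min = 90L, len_max = 150L, phred = 30L,
                               seed = 1L) {
  counts <- c(n_clean_virus, n_pure_rrna, n_single_chimera, n_double_chimera)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0, 1)")
  }
  if (n_double_chimera > 0 && len_min < 3 * flank_min) {
    stop("len_min must be >= 3 * flank_min to fit double-moiety reads")
  }
  if (n_single_chimera > 0 && len_min < 2 * flank_min) {
    stop("len_min must be >= 2 * flank_min to fit chimeric reads")
  }
  structure(list(n_clean_virus = as.integer(n_clean_virus),
                 n_pure_rrna = as.integer(n_pure_rrna),
                 n_single_chimera = as.integer(n_single_chimera),
                 n_double_chimera = as.integer(n_double_chimera),
                 flank_min = as.integer(flank_min),
                 duplicate_rate = duplicate_rate,
                 len_min = as.integer(len_min),
                 len_max = as.integer(len_max),
                 phred = as.integer(phred), seed = as.integer(seed)),
            class = "chimera_sim_config")
}

# uniform integer on [lo, hi], safe against R's sample() scalar expansion
sample_int <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# sample one exact substring (possibly reverse-complemented) of a reference
.sample_fragment <- function(ref_chr, len, both_strands = TRUE) {
  L <- nchar(ref_chr)
  start1 <- sample.int(L - len + 1L, 1L)
  frag <- substring(ref_chr, start1, start1 + len - 1L)
  strand <- "+"
  if (both_strands && stats::runif(1) < 0.5) {
    frag <- reverse_complement(frag)
    strand <- "-"
  }
  list(bases = frag, start = start1 - 1L, end = start1 + len - 1L,
       strand = strand)
}

#' Simulate a chimeric total-RNA-seq read set with ground truth
#'
#' Builds reads of four classes: clean virus substrings, pure rRNA
#' substrings, single-moiety chimeras (rRNA fragment fused to a virus
#' fragment at a recorded junction, order and strands random) and
#' double-moiety chimeras (rRNA + virus + rRNA).  Optional exact PCR
#' duplicates are appended with derived ids.  All reads are error-free at
#' constant quality.
#'
#' @param rrna_refs rRNA references.
#' @param virus_ref virus reference (single sequence).
#' @param cfg a [chimera_sim_config()].
#' @return list with `reads` (a [read_set()]) and `truth` (data.frame:
#'   `read_id`, `class`, `junctions` (semicolon-joined read positions),
#'   `rrna_read_spans`, `virus_read_span` (0-based half-open, semicolon
#'   lists), `rrna_ref`, plus source span columns).
#' @export
simulate_chimeric_dataset <- function(rrna_refs, virus_ref,
                                      cfg = chimera_sim_config()) {
  rrna_refs <- as_refs(rrna_refs)
  virus_chr <- as.character(as_refs(virus_ref)[[1]])
  rrna_chrs <- lapply(seq_along(rrna_refs),
                      function(i) as.character(rrna_refs[[i]]))
  names(rrna_chrs) <- names(rrna_refs)
  qc <- substr(phred_to_string(cfg$phred), 1, 1)

  ids <- character(); bases <- character(); cls <- character()
  junctions <- character(); rrna_spans <- character()
  virus_spans <- character(); rrna_src <- character()

  emit <- function(id, b, class, junc, rspan, vspan, rsrc) {
    ids <<- c(ids, id); bases <<- c(bases, b); cls <<- c(cls, class)
    junctions <<- c(junctions, junc); rrna_spans <<- c(rrna_spans, rspan)
    virus_spans <<- c(virus_spans, vspan); rrna_src <<- c(rrna_src, rsrc)
  }
  span_str <- function(s, e) paste0(s, "-", e)

  with_seed(cfg$seed, {
    rlen <- function() sample_int(cfg$len_min, cfg$len_max)
    for (i in seq_len(cfg$n_clean_virus)) {
      f <- .sample_fragment(virus_chr, rlen())
      emit(paste0("cv_", i), f$bases, "clean_virus", "", "",
           span_str(0L, nchar(f$bases)), "")
    }
    for (i in seq_len(cfg$n_pure_rrna)) {
      k <- sample.int(length(rrna_chrs), 1L)
      f <- .sample_fragment(rrna_chrs[[k]], rlen())
      emit(paste0("rr_", i), f$bases, "pure_rrna", "",
           span_str(0L, nchar(f$bases)), "", names(rrna_chrs)[k])
    }
    for (i in seq_len(cfg$n_single_chimera)) {
      L <- rlen()
      j <- sample_int(cfg$flank_min, L - cfg$flank_min)
      k <- sample.int(length(rrna_chrs), 1L)
      rrna_first <- stats::runif(1) < 0.5
      rlen_frag <- if (rrna_first) j else L - j
      vlen_frag <- L - rlen_frag
      rf <- .sample_fragment(rrna_chrs[[k]], rlen_frag)
      vf <- .sample_fragment(virus_chr, vlen_frag)
      if (rrna_first) {
        b <- paste0(rf$bases, vf$bases)
        rspan <- span_str(0L, j); vspan <- span_str(j, L)
      } else {
        b <- paste0(vf$bases, rf$bases)
        vspan <- span_str(0L, j); rspan <- span_str(j, L)
      }
      emit(paste0("sc_", i), b, "chimera", as.character(j), rspan, vspan,
           names(rrna_chrs)[k])
    }
    for (i in seq_len(cfg$n_double_chimera)) {
      L <- rlen()
      j1 <- sample_int(cfg$flank_min, L - 2L * cfg$flank_min)
      j2 <- sample_int(j1 + cfg$flank_min, L - cfg$flank_min)
      k1 <- sample.int(length(rrna_chrs), 1L)
      k2 <- sample.int(length(rrna_chrs), 1L)
      rf1 <- .sample_fragment(rrna_chrs[[k1]], j1)
      vf <- .sample_fragment(virus_chr, j2 - j1)
      rf2 <- .sample_fragment(rrna_chrs[[k2]], L - j2)
      b <- paste0(rf1$bases, vf$bases, rf2$bases)
      emit(paste0("dc_", i), b, "double_chimera",
           paste(j1, j2, sep = ";"),
           paste(span_str(0L, j1), span_str(j2, L), sep = ";"),
           span_str(j1, j2),
           paste(names(rrna_chrs)[k1], names(rrna_chrs)[k2], sep = ";"))
    }
    if (cfg$duplicate_rate > 0 && length(ids)) {
      dup <- which(stats::runif(length(ids)) < cfg$duplicate_rate)
      for (d in dup) {
        emit(paste0(ids[d], "_dup"), bases[d], cls[d], junctions[d],
             rrna_spans[d], virus_spans[d], rrna_src[d])
      }
    }
  })
  quals <- strrep(qc, nchar(bases))
  truth <- data.frame(read_id = ids, class = cls, junctions = junctions,
                      rrna_read_spans = rrna_spans,
                      virus_read_span = virus_spans,
                      rrna_ref = rrna_src, stringsAsFactors = FALSE)
  list(reads = read_set(ids, bases, quals), truth = truth)
}

# Parse "a-b;c-d" span strings into a two-column matrix of 0-based
# half-open intervals (possibly zero rows).
parse_spans <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("start", "end")
  m
}
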