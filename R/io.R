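# FASTQ / FASTA / SAM input-output.
#
# FASTA goes through Biostrings.  FASTQ is read with a strict 4-line-block
# codec so that malformed records can be reported by record index, which the
# generic readers do not do.  SAM ingestion is read-only and limited to the
# fields the triage step needs (flag, reference, CIGAR, sequence, quality).

#' Read a single-end Phred+33 FASTQ file
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [read_set()] in file order; bases are uppercased.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  # tolerate a trailing blank line
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) return(empty_read_set())
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete (file has ", length(lines), " lines)")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq_ <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ: record ", bad[1], " does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ: record ", bad[1], " has no '+' separator line")
  }
  mism <- which(nchar(seq_) != nchar(qual))
  if (length(mism)) {
    stop("malformed FASTQ: record ", mism[1],
         " sequence and quality lengths differ")
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  read_set(read_id = ids, bases = toupper(seq_), quals = qual)
}

#' Write a read set as Phred+33 FASTQ
#'
#' Read identifiers are written verbatim; cured reads already carry their
#' provenance suffix (`|cut:<start>-<end>/<L|R|M>` per excision).
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$bases, "\n+\n",
                      reads$quals),
               con)
  }
  invisible(path)
}

#' Read a multi-FASTA file of reference sequences
#'
#' @param path path to an uncompressed FASTA file.
#' @return a named `DNAStringSet`; names are the first whitespace-delimited
#'   token of each header.  Duplicate identifiers are an error.
#' @export
read_fasta <- function(path) {
  refs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(refs) <- sub("\\s.*$", "", names(refs))
  dup <- anyDuplicated(names(refs))
  if (dup) stop("duplicate reference id in ", path, ": ", names(refs)[dup])
  if (any(Biostrings::width(refs) == 0L)) {
    stop("empty reference sequence in ", path)
  }
  refs
}

#' Write reference sequences as multi-FASTA (70-column wrapped)
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_refs(seqs), path, width = 70L)
  invisible(path)
}

# --- SAM ingestion ----------------------------------------------------------

.cigar_ops_re <- "([0-9]+)([MIDNSHP=X])"

#' Decompose a CIGAR string into read-coordinate blocks
#'
#' Returns the blocks of read positions consumed by each CIGAR operation,
#' as 0-based half-open intervals.  Operations that consume read bases are
#' M, I, S, = and X; D and N consume reference only and yield zero-width
#' entries.  The returned read-consuming blocks partition
#' `[0, read_length)`.
#'
#' @param cigar a CIGAR string.
#' @return data.frame with columns `op`, `start`, `end` (read coordinates).
#' @export
cigar_read_blocks <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(), start = integer(), end = integer()))
  }
  toks <- regmatches(cigar, gregexpr(.cigar_ops_re, cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar)) {
    stop("invalid CIGAR string: ", cigar)
  }
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- substring(toks, nchar(toks), nchar(toks))
  if (any(ops %in% c("H", "P"))) {
    stop("unsupported CIGAR operation in ", cigar,
         " (hard clips / padding are rejected: bases are unrecoverable)")
  }
  consumes <- ops %in% c("M", "I", "S", "=", "X")
  width <- ifelse(consumes, lens, 0L)
  end <- cumsum(width)
  start <- end - width
  data.frame(op = ops, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Read alignments from a SAM file (triage ingestion)
#'
#' Parses a text SAM file produced by an external aligner run against the
#' rRNA reference.  Secondary (0x100) and supplementary (0x800) records are
#' skipped; hard-clipped records are rejected because their bases cannot be
#' recovered; a mapped record whose reference is missing from the `@SQ`
#' headers is an error.
#'
#' @param path path to a SAM file.
#' @return data.frame with one row per retained record: `read_id`, `flag`,
#'   `mapped`, `ref_id`, `pos` (1-based leftmost mapped position, NA if
#'   unmapped), `cigar`, `bases`, `quals`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- sub("^SN:", "", vapply(strsplit(sq, "\t"), function(f) {
    sn <- f[startsWith(f, "SN:")]
    if (!length(sn)) stop("@SQ header line without SN field")
    sn[1]
  }, character(1)))
  if (!length(body)) {
    return(data.frame(read_id = character(), flag = integer(),
                      mapped = logical(), ref_id = character(),
                      pos = integer(), cigar = character(),
                      bases = character(), quals = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short)) stop("malformed SAM record at line ", short[1])
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  read_id <- vapply(fields, `[`, character(1), 1L)
  rname <- vapply(fields, `[`, character(1), 3L)
  pos <- vapply(fields, function(f) as.integer(f[4]), integer(1))
  cigar <- vapply(fields, `[`, character(1), 6L)
  bases <- toupper(vapply(fields, `[`, character(1), 10L))
  quals <- vapply(fields, `[`, character(1), 11L)
  mapped <- bitwAnd(flag, 0x4L) == 0L
  if (any(grepl("H", cigar[mapped], fixed = TRUE))) {
    bad <- read_id[mapped][grepl("H", cigar[mapped], fixed = TRUE)][1]
    stop("hard-clipped SAM record for read ", bad,
         ": bases are unrecoverable, rerun the aligner with soft clipping")
  }
  missing_sq <- mapped & !(rname %in% sq_names)
  if (any(missing_sq)) {
    stop("mapped SAM record for read ", read_id[missing_sq][1],
         " references '", rname[missing_sq][1], "' with no @SQ header")
  }
  data.frame(read_id = read_id, flag = flag, mapped = mapped,
             ref_id = ifelse(mapped, rname, NA_character_),
             pos = ifelse(mapped, pos, NA_integer_),
             cigar = ifelse(mapped, cigar, NA_character_),
             bases = bases, quals = quals, stringsAsFactors = FALSE)
}

# Summarize one SAM record's read-space structure for triage:
# "unmapped", "full" (no soft clip) or "clipped".
sam_triage_status <- function(sam) {
  status <- character(nrow(sam))
  for (i in seq_len(nrow(sam))) {
    if (!sam$mapped[i]) {
      status[i] <- "unmapped"
    } else {
      blocks <- cigar_read_blocks(sam$cigar[i])
      status[i] <- if (any(blocks$op == "S")) "clipped" else "full"
    }
  }
  status
}

#' Report exact PCR duplicates (informational)
#'
#' PCR duplicates (identical sequence and length) are counted but never
#' collapsed by the cleanup pipeline.
#'
#' @param reads a [read_set()].
#' @return list with `n_reads`, `n_unique_sequences`, `n_duplicate_records`.
#' @export
dedup_report <- function(reads) {
  n <- nrow(reads)
  u <- length(unique(reads$bases))
  list(n_reads = n, n_unique_sequences = u, n_duplicate_records = n - u)
}
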