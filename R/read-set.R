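# Read container and Phred helpers.
#
# Reads are kept in a plain data.frame (class "read_set") with one row per
# read: read_id, bases (uppercase over A/C/G/T/N) and quals stored as the
# Phred+33 ASCII string.  Keeping qualities as the encoded string makes the
# length invariant (nchar(quals) == nchar(bases)) trivial to maintain and
# lets excision slice bases and qualities with the same substring() call.

PHRED_OFFSET <- 33L
PHRED_MAX <- 93L

#' Convert integer Phred scores to a Phred+33 quality string
#'
#' @param q integer vector of Phred scores, each in \[0, 93\].
#' @return a single quality string.
#' @export
phred_to_string <- function(q) {
  q <- as.integer(q)
  if (length(q) && (anyNA(q) || any(q < 0L) || any(q > PHRED_MAX))) {
    stop("Phred scores must be integers in [0, ", PHRED_MAX, "]")
  }
  if (!length(q)) return("")
  intToUtf8(q + PHRED_OFFSET)
}

#' Convert a Phred+33 quality string to integer Phred scores
#'
#' @param s a quality string.
#' @return integer vector of Phred scores.
#' @export
string_to_phred <- function(s) {
  if (!nzchar(s)) return(integer())
  q <- utf8ToInt(s) - PHRED_OFFSET
  if (any(q < 0L) || any(q > PHRED_MAX)) {
    stop("quality string contains characters outside the Phred+33 range")
  }
  as.integer(q)
}

.valid_bases_re <- "^[ACGTN]*$"

#' Construct a read set
#'
#' A `read_set` is a data.frame with columns `read_id`, `bases`, `quals`
#' (Phred+33 encoded string) and `lineage` (provenance of excisions, empty
#' for raw reads).  All coordinates used elsewhere in the package are
#' 0-based half-open.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of uppercase DNA sequences over A/C/G/T/N.
#' @param quals either a character vector of Phred+33 strings or a list of
#'   integer Phred vectors, one per read.
#' @param lineage optional character vector describing applied cuts.
#' @return a `read_set` data.frame.
#' @export
read_set <- function(read_id = character(), bases = character(),
                     quals = character(), lineage = NULL) {
  bases <- toupper(as.character(bases))
  read_id <- as.character(read_id)
  if (is.list(quals)) quals <- vapply(quals, phred_to_string, character(1))
  quals <- as.character(quals)
  if (length(read_id) != length(bases) || length(bases) != length(quals)) {
    stop("read_id, bases and quals must have equal length")
  }
  bad <- !grepl(.valid_bases_re, bases)
  if (any(bad)) {
    stop("read ", read_id[which(bad)[1]], ": bases outside {A,C,G,T,N}")
  }
  mism <- nchar(bases) != nchar(quals)
  if (any(mism)) {
    stop("read ", read_id[which(mism)[1]],
         ": sequence and quality lengths differ")
  }
  if (is.null(lineage)) lineage <- character(length(read_id))
  out <- data.frame(read_id = read_id, bases = bases, quals = quals,
                    lineage = as.character(lineage),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

empty_read_set <- function() read_set()

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads\n")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x), 6)
    show$bases <- ifelse(nchar(show$bases) > 40,
                         paste0(substr(show$bases, 1, 40), "..."), show$bases)
    show$quals <- NULL
    print(show)
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

rbind_read_sets <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (!length(parts)) return(empty_read_set())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

# Normalize a reference argument (DNAStringSet, named character vector, or
# data.frame with ref_id/bases) into a named DNAStringSet.
as_refs <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (is.null(names(x)) || anyNA(names(x)) || !all(nzchar(names(x)))) {
      stop("reference sequences must be named")
    }
    return(x)
  }
  if (is.data.frame(x)) {
    refs <- Biostrings::DNAStringSet(toupper(x$bases))
    names(refs) <- x$ref_id
    return(refs)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("ref", seq_along(x))
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  stop("cannot interpret object of class ", class(x)[1], " as references")
}
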