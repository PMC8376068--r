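# Deterministic synthetic references shared across tests.

make_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

test_rrna_refs <- function() {
  Biostrings::DNAStringSet(c(rrna_18s = make_dna(1500, 101),
                             rrna_28s = make_dna(2200, 102)))
}

test_virus_ref <- function() {
  Biostrings::DNAStringSet(c(virus1 = make_dna(3000, 103)))
}

quick_read_set <- function(bases, ids = NULL, phred = 30L) {
  if (!length(bases)) return(read_set())
  if (is.null(ids)) ids <- paste0("r", seq_along(bases))
  qc <- substr(phred_to_string(phred), 1, 1)
  read_set(ids, bases, strrep(qc, nchar(bases)))
}

# truth-based residual rRNA bases in a final read set, via lineage tracing;
# returns per-read counts of (a) total labelled bases (b) longest run
residual_rrna <- function(final, truth) {
  tot <- integer(nrow(final))
  longest <- integer(nrow(final))
  for (i in seq_len(nrow(final))) {
    tro <- trace_origin(final$read_id[i], nchar(final$bases[i]))
    row <- truth[truth$read_id == tro$source_id, , drop = FALSE]
    if (!nrow(row)) next
    sp <- ribocure:::parse_spans(row$rrna_read_spans[1])
    for (k in seq_len(nrow(sp))) {
      ov <- min(tro$end, sp[k, 2]) - max(tro$start, sp[k, 1])
      if (ov > 0) {
        tot[i] <- tot[i] + ov
        longest[i] <- max(longest[i], ov)
      }
    }
  }
  data.frame(read_id = final$read_id, total = tot, longest = longest)
}

rbind_rs <- function(...) ribocure:::rbind_read_sets(...)
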