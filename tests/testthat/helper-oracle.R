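# Independent brute-force Smith-Waterman oracle (Gotoh affine gaps).
# Deliberately naive O(nm) dynamic programming, kept free of any package
# code path other than reverse_complement (itself property-tested).

sw_oracle_one <- function(a, b, sc) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0 || m == 0) return(0)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  go <- sc$gap_open + sc$gap_extend  # cost of opening a 1-base gap
  ge <- sc$gap_extend
  Hprev <- numeric(m + 1)
  Eprev <- rep(-Inf, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1)
    E <- rep(-Inf, m + 1)
    Fi <- -Inf
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") sc$match else -sc$mismatch
      E[j + 1] <- max(Hprev[j + 1] - go, Eprev[j + 1] - ge)
      Fi <- max(H[j] - go, Fi - ge)
      h <- max(0, Hprev[j] + s, E[j + 1], Fi)
      H[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- H
    Eprev <- E
  }
  best
}

sw_oracle <- function(a, b, sc = scoring_scheme(), both_strands = TRUE) {
  fwd <- sw_oracle_one(a, b, sc)
  if (!both_strands) return(fwd)
  max(fwd, sw_oracle_one(reverse_complement(a), b, sc))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
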