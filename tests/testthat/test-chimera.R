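refs <- test_rrna_refs()
virus <- test_virus_ref()
rrna_chr <- as.character(refs[[1]])
virus_chr <- as.character(virus[[1]])

test_that("classify_reads bins pure rRNA, chimeric and clean reads", {
  pure <- substr(rrna_chr, 201, 320)                       # 120 bp exact
  chim <- paste0(substr(rrna_chr, 1, 50), substr(virus_chr, 501, 570))
  clean <- substr(virus_chr, 1001, 1120)
  rs <- quick_read_set(c(pure, chim, clean), c("p", "c", "v"))
  calls <- classify_reads(rs, refs)
  expect_equal(calls$verdict, c("pure_rrna", "chimeric", "non_rrna"))
  expect_gte(calls$aligned_read_frac[1], 0.9)
  # chimera segment is the rRNA prefix, boundary within +/- 2 bp
  expect_lte(abs(calls$seg_start[2] - 0L), 2)
  expect_lte(abs(calls$seg_end[2] - 50L), 2)
  # non-rRNA row has empty segment (verdict <-> segments invariant)
  expect_true(is.na(calls$seg_start[3]))
})

test_that("excise keeps flanks >= min_retained_length with lineage ids", {
  cfg <- cleanup_config()
  r <- quick_read_set(make_dna(120, 8), "r1")

  out <- excise(r, data.frame(seg_start = 0L, seg_end = 50L), cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "r1|cut:0-50/R")
  expect_equal(out$bases, substr(r$bases, 51, 120))
  expect_equal(nchar(out$quals), 70L)

  out <- excise(r, data.frame(seg_start = 40L, seg_end = 80L), cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(nchar(out$bases), c(40L, 40L))
  expect_equal(out$read_id, c("r1|cut:40-80/L", "r1|cut:40-80/R"))

  r110 <- quick_read_set(make_dna(110, 9), "r2")
  out <- excise(r110, data.frame(seg_start = 0L, seg_end = 100L), cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "dropped_short"), 1L)

  expect_error(excise(r, data.frame(seg_start = 10L, seg_end = 130L)),
               "invalid")
})

test_that("trace_origin inverts the cut-suffix chain", {
  expect_equal(trace_origin("r1", 100)$start, 0L)
  tr <- trace_origin("r1|cut:0-50/R", 70)
  expect_equal(tr$source_id, "r1")
  expect_equal(c(tr$start, tr$end), c(50L, 120L))
  # /R then /L: offsets accumulate only through non-L fragments
  tr <- trace_origin("r1|cut:0-40/R|cut:30-60/L", 30)
  expect_equal(c(tr$start, tr$end), c(40L, 70L))
  tr <- trace_origin("r1|cut:50-80/L", 50)
  expect_equal(c(tr$start, tr$end), c(0L, 50L))
})

test_that("run_round routes reads and satisfies the accounting invariant", {
  cfg <- cleanup_config()
  clean <- quick_read_set(vapply(1:5, function(i) {
    substr(virus_chr, i * 100, i * 100 + 119)
  }, character(1)))
  rr <- run_round(clean, refs, cfg)
  expect_equal(nrow(rr$passthrough), 5L)
  expect_equal(nrow(rr$cured), 0L)
  expect_equal(nrow(rr$discarded), 0L)

  pure <- quick_read_set(vapply(1:5, function(i) {
    substr(rrna_chr, i * 90, i * 90 + 119)
  }, character(1)))
  rr <- run_round(pure, refs, cfg)
  expect_equal(nrow(rr$discarded), 5L)

  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_clean_virus = 15, n_pure_rrna = 12, n_single_chimera = 18,
    flank_min = 30, seed = 301))
  rr <- run_round(sim$reads, refs, cfg)
  s <- rr$stats
  expect_equal(s[["input"]],
               s[["pure_rrna_discarded"]] + s[["chimeric_detected"]] +
                 s[["passthrough"]])
  expect_equal(s[["pure_rrna_discarded"]], 12)
  expect_equal(s[["chimeric_detected"]], 18)
  expect_equal(s[["passthrough"]], 15)
})

test_that("cured reads are exact substrings of their sources", {
  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_single_chimera = 40, n_double_chimera = 10, flank_min = 30,
    seed = 302))
  res <- iterate_cleanup(sim$reads, refs)
  cured <- res$reads[grepl("|cut:", res$reads$read_id, fixed = TRUE), ]
  expect_gt(nrow(cured), 0)
  for (i in seq_len(nrow(cured))) {
    tro <- trace_origin(cured$read_id[i], nchar(cured$bases[i]))
    src <- sim$reads[sim$reads$read_id == tro$source_id, ]
    expect_equal(cured$bases[i],
                 substr(src$bases, tro$start + 1L, tro$end))
    expect_equal(cured$quals[i],
                 substr(src$quals, tro$start + 1L, tro$end))
  }
})

test_that("iterate_cleanup converges and is idempotent at its fixpoint", {
  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_clean_virus = 10, n_single_chimera = 30, flank_min = 30, seed = 303))
  cfg <- cleanup_config(max_rounds = 5)
  res <- iterate_cleanup(sim$reads, refs, cfg)
  # single-moiety chimeras: round 1 cures, a later round cures 0 and stops
  expect_lte(res$n_rounds, 3)
  expect_equal(res$round_stats$cured_emitted[res$n_rounds], 0)
  # cured counts non-increasing across rounds
  expect_true(all(diff(res$round_stats$cured_emitted) <= 0))
  # fixpoint: cleaning the final output cures nothing and discards nothing
  res2 <- iterate_cleanup(res$reads, refs, cfg)
  expect_equal(nrow(res2$reads), nrow(res$reads))
  expect_equal(res2$round_stats$cured_emitted[1], 0)
  expect_equal(res2$round_stats$pure_rrna_discarded[1], 0)
})

test_that("double-moiety reads need the second round", {
  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_double_chimera = 60, flank_min = 30, seed = 304))
  res1 <- iterate_cleanup(sim$reads, refs, cleanup_config(max_rounds = 1))
  res2 <- iterate_cleanup(sim$reads, refs, cleanup_config(max_rounds = 2))
  r1 <- residual_rrna(res1$reads, sim$truth)
  r2 <- residual_rrna(res2$reads, sim$truth)
  # one round leaves whole moieties behind; two rounds leave none
  expect_gt(sum(r1$longest >= 10), 30)
  expect_equal(sum(r2$longest >= 10), 0)
  expect_lt(sum(r2$total), sum(r1$total) / 50)
})

test_that("sam_ingest triage pre-bins reads and converges to the same calls", {
  pure <- substr(rrna_chr, 201, 320)
  chim <- paste0(substr(rrna_chr, 401, 450), substr(virus_chr, 501, 570))
  clean <- substr(virus_chr, 1001, 1120)
  rs <- quick_read_set(c(pure, chim, clean), c("p", "c", "v"))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:rrna_18s\tLN:1500",
    paste("p", 0, "rrna_18s", 201, 60, "120M", "*", 0, 0, pure,
          strrep("?", 120), sep = "\t"),
    paste("c", 0, "rrna_18s", 401, 60, "50M70S", "*", 0, 0, chim,
          strrep("?", 120), sep = "\t"),
    paste("v", 4, "*", 0, 0, "*", "*", 0, 0, clean,
          strrep("?", 120), sep = "\t")), sam)
  cfg <- cleanup_config(triage_mode = "sam_ingest")
  rr <- run_round(rs, refs, cfg, sam = sam)
  expect_equal(rr$calls$verdict, c("pure_rrna", "chimeric", "non_rrna"))
  # the internal-triage flow reaches the same verdicts
  rr_int <- run_round(rs, refs, cleanup_config())
  expect_equal(rr$calls$verdict, rr_int$calls$verdict)
  # and the chimeric excision boundary agrees
  expect_equal(rr$calls$seg_end[2], rr_int$calls$seg_end[2])
})

test_that("cleanup_config validates thresholds", {
  expect_error(cleanup_config(rrna_fraction_threshold = 0), "in \\(0, 1\\]")
  expect_error(cleanup_config(max_rounds = 0), ">= 1")
  expect_error(cleanup_config(min_retained_length = 0), ">= 1")
})
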