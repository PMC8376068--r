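refs <- test_rrna_refs()
virus <- test_virus_ref()

test_that("mock reads respect length, quality and substring contracts", {
  cfg <- mock_config(n_reads = 60, seed = 5)
  reads <- generate_mock_reads(refs[1], cfg)
  expect_equal(nrow(reads), 60L)
  expect_true(all(nchar(reads$bases) >= 90 & nchar(reads$bases) <= 150))
  expect_true(all(strsplit(paste(reads$quals, collapse = ""), "")[[1]] == "?"))
  # every read is a substring of the reference or its reverse complement
  ref_chr <- as.character(refs[[1]])
  ref_rc <- reverse_complement(ref_chr)
  for (b in reads$bases) {
    expect_true(grepl(b, ref_chr, fixed = TRUE) ||
                  grepl(b, ref_rc, fixed = TRUE))
  }
  # truth spans match the emitted sequences
  tr <- attr(reads, "truth")
  for (i in seq_len(nrow(tr))) {
    frag <- substr(ref_chr, tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") frag <- reverse_complement(frag)
    expect_equal(reads$bases[i], frag)
  }
})

test_that("mock generation is seed-deterministic and emits n per reference", {
  a <- generate_mock_reads(refs, mock_config(n_reads = 30, seed = 9))
  b <- generate_mock_reads(refs, mock_config(n_reads = 30, seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 60L)  # 30 per reference
  d <- generate_mock_reads(refs, mock_config(n_reads = 30, seed = 10))
  expect_false(identical(a$bases, d$bases))
})

test_that("streaming and in-memory mock generation agree", {
  f <- withr::local_tempfile(fileext = ".fastq")
  t <- withr::local_tempfile(fileext = ".tsv")
  summary <- generate_mock_reads(refs[1], mock_config(n_reads = 40, seed = 3),
                                 out = f, truth_out = t)
  expect_equal(summary$n_records, 40)
  streamed <- read_fastq(f)
  in_mem <- generate_mock_reads(refs[1], mock_config(n_reads = 40, seed = 3))
  expect_identical(streamed$bases, in_mem$bases)
  expect_identical(streamed$read_id, in_mem$read_id)
  truth_file <- utils::read.delim(t)
  expect_equal(truth_file$start, attr(in_mem, "truth")$start)
})

test_that("mock generator rejects references shorter than the read length", {
  expect_error(
    generate_mock_reads(c(tiny = "ACGTACGT"), mock_config(n_reads = 5)),
    "shorter than")
})

test_that("coverage_profile computes truth-based depth", {
  tr <- data.frame(read_id = "r1", ref_id = "tiny", start = 0L, end = 90L,
                   strand = "+")
  ref <- c(tiny = paste(rep("A", 100), collapse = ""))
  depth <- coverage_profile(tr, ref)
  expect_equal(depth, c(rep(1L, 90), rep(0L, 10)))
  depth0 <- coverage_profile(tr[0, ], ref)
  expect_equal(depth0, rep(0L, 100))

  # many uniform reads cover the whole reference (validation-run intent);
  # edge bases are only covered by reads starting exactly on them, so this
  # needs n well above the ~1400 distinct start positions
  reads <- generate_mock_reads(refs[1],
                               mock_config(n_reads = 20000, seed = 17))
  depth <- coverage_profile(reads, refs[1])
  expect_equal(length(depth), 1500L)
  expect_gt(min(depth), 0)
})

test_that("simulated datasets match their config class counts and junctions", {
  cfg <- chimera_sim_config(n_clean_virus = 5, seed = 1)
  sim <- simulate_chimeric_dataset(refs, virus, cfg)
  expect_equal(nrow(sim$reads), 5L)
  expect_true(all(sim$truth$class == "clean_virus"))
  vch <- as.character(virus[[1]])
  vrc <- reverse_complement(vch)
  for (b in sim$reads$bases) {
    expect_true(grepl(b, vch, fixed = TRUE) || grepl(b, vrc, fixed = TRUE))
  }

  cfg <- chimera_sim_config(n_clean_virus = 7, n_pure_rrna = 8,
                            n_single_chimera = 100, n_double_chimera = 4,
                            flank_min = 25, seed = 2)
  sim <- simulate_chimeric_dataset(refs, virus, cfg)
  expect_equal(as.vector(table(sim$truth$class)[
    c("clean_virus", "pure_rrna", "chimera", "double_chimera")]),
    c(7L, 8L, 100L, 4L))
  single <- sim$truth[sim$truth$class == "chimera", ]
  L <- nchar(sim$reads$bases[match(single$read_id, sim$reads$read_id)])
  j <- as.integer(single$junctions)
  expect_true(all(j >= 25 & j <= L - 25))
  dbl <- sim$truth[sim$truth$class == "double_chimera", ]
  jj <- lapply(strsplit(dbl$junctions, ";"), as.integer)
  expect_true(all(vapply(jj, function(x) x[2] - x[1] >= 25, logical(1))))
})

test_that("chimeric reads are assembled from their recorded moieties", {
  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_single_chimera = 30, flank_min = 25, seed = 6))
  rr <- lapply(seq_along(refs), function(i) as.character(refs[[i]]))
  names(rr) <- names(refs)
  rr_rc <- lapply(rr, reverse_complement)
  vch <- as.character(virus[[1]]); vrc <- reverse_complement(vch)
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    b <- sim$reads$bases[sim$reads$read_id == t$read_id]
    rsp <- ribocure:::parse_spans(t$rrna_read_spans)
    rfrag <- substr(b, rsp[1, 1] + 1L, rsp[1, 2])
    src <- t$rrna_ref
    expect_true(grepl(rfrag, rr[[src]], fixed = TRUE) ||
                  grepl(rfrag, rr_rc[[src]], fixed = TRUE))
    vsp <- ribocure:::parse_spans(t$virus_read_span)
    vfrag <- substr(b, vsp[1, 1] + 1L, vsp[1, 2])
    expect_true(grepl(vfrag, vch, fixed = TRUE) ||
                  grepl(vfrag, vrc, fixed = TRUE))
  }
})

test_that("duplicate_rate appends exact copies with derived ids", {
  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_clean_virus = 200, duplicate_rate = 0.25, seed = 12))
  dups <- grepl("_dup$", sim$reads$read_id)
  expect_gt(sum(dups), 20)
  expect_lt(sum(dups), 80)
  for (i in which(dups)) {
    orig <- sub("_dup$", "", sim$reads$read_id[i])
    expect_equal(sim$reads$bases[i],
                 sim$reads$bases[sim$reads$read_id == orig])
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- chimera_sim_config(n_clean_virus = 10, n_pure_rrna = 10,
                            n_single_chimera = 10, n_double_chimera = 5,
                            flank_min = 30, duplicate_rate = 0.1, seed = 77)
  s1 <- simulate_chimeric_dataset(refs, virus, cfg)
  s2 <- simulate_chimeric_dataset(refs, virus, cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("chimera_sim_config validates geometry", {
  expect_error(chimera_sim_config(n_single_chimera = 1, flank_min = 50),
               "2 \\* flank_min")
  expect_error(chimera_sim_config(n_double_chimera = 1, flank_min = 35),
               "3 \\* flank_min")
  expect_error(chimera_sim_config(duplicate_rate = 1), "duplicate_rate")
})
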