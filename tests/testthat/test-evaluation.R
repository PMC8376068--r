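refs <- test_rrna_refs()
virus <- test_virus_ref()
rrna_chr <- as.character(refs[[1]])
virus_chr <- as.character(virus[[1]])

tile <- function(seq_chr, from, to, len = 100L, step = 50L) {
  starts <- seq(from, to - len, by = step)
  vapply(starts, function(s) substr(seq_chr, s + 1L, s + len), character(1))
}

test_that("overlap_counts recovers a known composition", {
  expect_equal(overlap_counts(quick_read_set(character()), refs, virus),
               c(rrna_only = 0L, virus_only = 0L, both = 0L, neither = 0L))

  one <- quick_read_set(substr(virus_chr, 301, 420))
  expect_equal(unname(overlap_counts(one, refs, virus)["virus_only"]), 1L)

  sim <- simulate_chimeric_dataset(refs, virus, chimera_sim_config(
    n_clean_virus = 9, n_pure_rrna = 6, n_single_chimera = 11,
    flank_min = 25, seed = 401))
  unrelated <- quick_read_set(vapply(1:4, function(i) {
    make_dna(120, 500 + i)
  }, character(1)), paste0("x", 1:4))
  rs <- rbind(sim$reads, unrelated)
  class(rs) <- c("read_set", "data.frame")
  oc <- overlap_counts(rs, refs, virus)
  expect_equal(unname(oc["rrna_only"]), 6L)
  expect_equal(unname(oc["virus_only"]), 9L)
  expect_equal(unname(oc["both"]), 11L)
  expect_equal(unname(oc["neither"]), 4L)
  expect_equal(sum(oc), nrow(rs))
})

test_that("greedy assembly reconstructs a genome from an error-free tiling", {
  genome <- substr(virus_chr, 1001, 1500)  # 500 bp
  reads <- tile(genome, 0L, 500L)
  contigs <- greedy_assemble(quick_read_set(reads), min_overlap = 20)
  expect_equal(length(contigs), 1L)
  expect_equal(unname(contigs[1]), genome)
})

test_that("read sets from disjoint references stay in separate contigs", {
  reads <- c(tile(substr(virus_chr, 1, 300), 0L, 300L),
             tile(substr(rrna_chr, 1, 300), 0L, 300L))
  contigs <- greedy_assemble(quick_read_set(reads), min_overlap = 20)
  expect_equal(length(contigs), 2L)
})

test_that("one chimeric bridge read fuses rRNA and virus piles", {
  vpart <- substr(virus_chr, 1001, 1300)
  rpart <- substr(rrna_chr, 201, 500)
  bridge <- paste0(substr(rpart, 251, 300), substr(vpart, 1, 50))
  reads <- c(tile(vpart, 0L, 300L), tile(rpart, 0L, 300L), bridge)
  contigs <- greedy_assemble(quick_read_set(reads), min_overlap = 20)
  expect_equal(length(contigs), 1L)  # fused chimeric contig
  expect_gt(contig_rrna_bases(contigs, refs), 200L)
  # removing the bridge read yields two clean-by-construction contigs
  contigs2 <- greedy_assemble(quick_read_set(reads[-length(reads)]),
                              min_overlap = 20)
  expect_equal(length(contigs2), 2L)
})

test_that("greedy assembly handles reverse-complemented reads and containment", {
  genome <- substr(virus_chr, 2001, 2400)
  reads <- tile(genome, 0L, 400L)
  reads[2] <- reverse_complement(reads[2])
  reads <- c(reads, substr(genome, 120, 180))  # contained read
  contigs <- greedy_assemble(quick_read_set(reads), min_overlap = 20)
  expect_equal(length(contigs), 1L)
  expect_true(contigs[1] == genome ||
                contigs[1] == reverse_complement(genome))
})

test_that("evaluate_contigs computes the published metric definitions", {
  contig <- substr(virus_chr, 501, 1500)  # exact 1000 bp substring of 3000
  met <- evaluate_contigs(c(c1 = contig), virus)
  expect_equal(met$mean_contig_length, 1000)
  expect_equal(met$mean_contig_coverage, 100)
  expect_equal(met$genome_coverage, 100 * 1000 / 3000)

  # half-chimeric contig: ~50% of its bases align to the genome
  half <- paste0(substr(virus_chr, 501, 1000), substr(rrna_chr, 1, 500))
  met <- evaluate_contigs(c(c1 = half), virus)
  expect_lt(abs(met$mean_contig_coverage - 50), 2)

  met <- evaluate_contigs(character(), virus,
                          reads = quick_read_set(character()))
  expect_true(met$empty)
  expect_equal(met$genome_coverage, 0)
  expect_equal(met$used_reads, 0L)
})

test_that("the three-strategy comparison reproduces the cleanup ordering", {
  ds <- build_comparison_dataset(refs, virus, seed = 42)
  expect_gt(mean(ds$truth$class == "chimera"), 0.2)
  tab <- compare_strategies(ds$reads, refs, virus)
  expect_equal(tab$strategy, c("cure", "filter", "raw"))
  cure <- tab[tab$strategy == "cure", ]
  filt <- tab[tab$strategy == "filter", ]
  raw <- tab[tab$strategy == "raw", ]
  # curing reuses chimeric reads that filtering throws away
  expect_gt(cure$used_reads, filt$used_reads)
  # cured contigs carry no rRNA; raw contigs do
  expect_equal(cure$rrna_bases_in_contigs, 0L)
  expect_gt(raw$rrna_bases_in_contigs, 0L)
  # curing never covers less of the genome than whole-read filtering
  expect_gte(cure$genome_coverage, filt$genome_coverage)
})
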