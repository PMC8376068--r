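# ribocure

Curing rRNA–virus chimeric reads before viral genome assembly.

## The problem

Total-RNA sequencing of virus-bearing samples (mosquito pools, clinical or
environmental specimens) is dominated by host ribosomal RNA, and library
preparation fuses fragments of different molecules into single chimeric
inserts. A fraction of reads therefore carry host rRNA on one side and
viral sequence on the other. Left in, these chimeras bridge the rRNA and
viral read piles during *de novo* assembly and splice rRNA into "viral"
contigs — the mechanism behind rRNA-contaminated virus entries in public
databases. Filtered out whole (the conventional rRNA-removal behaviour),
their viral halves are lost, which is crippling when a low-abundance virus
is represented by only a few hundred reads.

`ribocure` excises just the rRNA moiety. For each read *r* against an rRNA
reference set *R*, it computes the exact maximum-scoring local alignment
(Smith–Waterman, affine gaps, both strands; match +2, mismatch −3, gap of
length *k* costs 5 + 2*k*) and routes the read by the aligned fraction
*f* = |segment| / |r| and identity:

* no credible segment → **passthrough** (the read is not ribosomal);
* *f* ≥ 0.90 → **pure rRNA**, discarded;
* otherwise → **chimeric**: the segment is excised at polished boundaries
  and every flank ≥ 30 bp is kept as a *cured* read
  (id suffix `|cut:<start>-<end>/<L|R|M>` records the provenance).

Cleanup is iterated (default 2 rounds) so triple fusions
(rRNA + virus + rRNA) lose their second moiety too. Companion modules
generate mock probing reads, simulate chimeric datasets with known
junctions, screen candidate databases for rRNA stretches (reported with
1-based start, length and the percentile bin
`floor(100·(start−1)/target_length)`), and quantify assembly impact with a
deterministic greedy overlap assembler and Table-style metrics (mean contig
length, mean % of contig bases aligning to the genome, % genome covered,
reads used).

## Worked example

Synthetic references, a mixed simulated read set, two-round cleanup, and
the three-strategy comparison (cure vs conventional whole-read filtering
vs raw):

```r
library(ribocure)
set.seed(1)
rrna  <- Biostrings::DNAStringSet(c(rrna_18s =
           paste(sample(c("A","C","G","T"), 1800, TRUE), collapse = "")))
virus <- Biostrings::DNAStringSet(c(virus1 =
           paste(sample(c("A","C","G","T"), 3000, TRUE), collapse = "")))

sim <- simulate_chimeric_dataset(rrna, virus, chimera_sim_config(
  n_clean_virus = 40, n_pure_rrna = 40, n_single_chimera = 25,
  n_double_chimera = 5, flank_min = 30, seed = 1))

res <- iterate_cleanup(sim$reads, rrna)
res
#> chimera cleanup: 2 round(s)
#>   round input pure_rrna_discarded chimeric_detected cured_emitted passthrough
#> 1     1   110                  40                30            30          40
#> 2     2    30                   0                 5             4          25
#>   dropped_short
#> 1             0
#> 2             1
#> final read set: 69 reads; 40 pure-rRNA reads discarded
```

Round 1 sorts the 110 reads: 40 pure-rRNA discarded, 40 clean passthrough,
30 chimeras cured. Round 2 re-examines the 30 cured fragments and finds 5
still chimeric — the double-moiety reads — curing 4 (one flank fell below
the 30 bp floor). The final set keeps 69 of the 70 non-pure-rRNA reads.

```r
overlap_counts(sim$reads, rrna, virus)
#>  rrna_only virus_only       both    neither
#>         40         40         30          0

ds  <- build_comparison_dataset(rrna, virus, seed = 1)
compare_strategies(ds$reads, rrna, virus)
#>   strategy n_input_reads mean_contig_length mean_contig_coverage
#> 1     cure            60             1495.0               100.00
#> 2   filter            41             1270.0               100.00
#> 3      raw            67              385.6                59.97
#>   genome_coverage used_reads n_contigs rrna_bases_in_contigs
#> 1           99.67         60         2                     0
#> 2           84.67         41         2                     0
#> 3           99.67         60        13                  1412
```

Curing uses every informative read (60 vs the filter strategy's 41) and
assembles clean contigs covering 99.7% of the genome; whole-read filtering
loses the genome window covered only by chimera flanks (84.7%); raw
assembly reaches the same coverage but its contigs contain 1,412 rRNA
bases and are fragmented by the rRNA pile.

## Command line

A wrapper is installed at `inst/exec/ribocure`; equivalently:

```sh
Rscript -e 'quit(status = ribocure::main())' \
  clean --reads reads.fastq --rrna rrna_db.fa --out-dir out/
```

Subcommands: `mock`, `simulate`, `clean`, `screen`, `evaluate`, `compare`.
Every run writes `manifest.json` (resolved configuration, input MD5s,
package version, seed) next to its outputs; reruns from the same manifest
are byte-identical. Exit codes: 0 success, 1 data error, 2 usage error.
`clean` writes `cured.fastq`, `merged.fastq` (cured + passthrough),
`discarded_rrna.fastq`, `round_stats.tsv` and `calls.tsv`.

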