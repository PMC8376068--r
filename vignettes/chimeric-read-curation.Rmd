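---
title: "Curing rRNA-virus chimeric reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curing rRNA-virus chimeric reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocure)
```

## The problem

Total-RNA sequencing of a virus-bearing host sample is dominated by host
ribosomal RNA. During library preparation, template switching and ligation
artifacts fuse fragments of different molecules into single chimeric
inserts, so a fraction of reads carry host rRNA sequence on one side and
viral sequence on the other. These chimeras are a double hazard for
*de novo* viral genome assembly:

* **Kept**, they act as bridges between the rRNA read pile and the viral
  read pile, seeding contigs that splice rRNA into the assembled "viral"
  genome — the mechanism behind rRNA-contaminated virus entries in public
  sequence databases.
* **Filtered whole** (the behaviour of conventional rRNA removal tools,
  which bin any read that maps to an rRNA reference), their viral half is
  lost. For a low-abundance virus represented by a few hundred reads, that
  loss shortens or breaks the assembly.

`ribocure` takes the third option: locate the rRNA moiety of each chimeric
read precisely and excise *only* that moiety, returning the viral
remainder to the assembly.

## The procedure

For each read, the best local alignment against the rRNA reference set is
computed (exact Smith–Waterman with affine gaps, both strands — see
*Numerical choices*). Reads are routed three ways:

1. **non-rRNA** — no alignment reaches the score floor, or no credible
   rRNA segment exists (identity below `min_segment_identity`): the read
   passes through untouched.
2. **pure rRNA** — the rRNA segment covers at least
   `rrna_fraction_threshold` (default 0.90) of the read: discarded.
   Chimeras are, by definition, reads *partially* mapped to rRNA.
3. **chimeric** — a credible but partial rRNA segment: the segment's bases
   and qualities are excised, and every remaining flank of at least
   `min_retained_length` bases is emitted as a *cured* read carrying a
   `|cut:<start>-<end>/<L|R|M>` provenance suffix on its identifier.

Because an insert can be a triple fusion (rRNA + virus + rRNA), only the
single best rRNA segment is excised per round and the cured output is fed
back for another round (default `max_rounds = 2`). Iteration necessarily
terminates: every cure strictly shortens a read.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rrna_fraction_threshold` | 0.90 | aligned read fraction at or above which a read is discarded as pure rRNA |
| `min_segment_identity` | 0.80 | minimum identity for an rRNA segment to be believed |
| `min_retained_length` | 30 bp | shortest cured fragment worth keeping (below a typical aligner seed length, a fragment cannot inform an assembly) |
| `max_rounds` | 2 | cleanup iterations; round 2 removes second moieties from triple-fusion reads |
| `scoring` | +2/−3, gap 5+2·k | BLASTN-like match/mismatch rewards, affine gap of length k costs open + k·extend |
| `min_score` | 30 | alignment score floor (≈15 matched bases) to call any rRNA hit |
| `boundary_match_run` | 5 | excision boundaries must terminate in this many consecutive exact matches (see below) |

## Numerical choices

**Alignment primitive.** All mapping decisions go through one primitive:
the maximum-scoring local alignment with affine gaps, computed exactly (no
seeding heuristics, both strands searched by aligning the
reverse-complemented query). The implementation is backed by
`Biostrings::pairwiseAlignment`; the test suite verifies score-exact
agreement with an independent brute-force dynamic-programming oracle on
1,000 random sequence pairs. `N` bases score as mismatches against
everything, so they can never contribute evidence.

**Tie-breaking.** Ties between references go to the earlier reference in
input order; ties between strands go to the forward strand. Among
co-optimal alignments within a single reference the backend returns one
deterministically, though not necessarily the smallest-read-start one;
byte-identical reruns are guaranteed and tested.

**Boundary polishing / segment selection.** The maximum-scoring alignment
is not always the right *boundary* evidence. Two failure modes were
observed on simulated data:

* With +2/−3 scoring, a chance extension past the true junction consisting
  of one mismatch followed by two matches gains +1, so the raw optimum
  regularly overshoots the junction by 3 bp or more.
* A read carrying two rRNA moieties that happen to come from nearby
  reference positions can be bridged by a single alignment across the
  viral middle, diluting identity below the believability threshold and
  letting the read escape as non-rRNA with both moieties intact.

Both are cured by one rule, analogous to how a BLAST report would present
separate high-scoring segment pairs: the reported rRNA segment is the
**maximum-scoring contiguous block of alignment columns that starts and
ends with `boundary_match_run` consecutive exact matches** and meets the
identity and score floors. For an ordinary high-identity alignment this
reduces to trimming spurious ends; for a composite alignment it selects
one moiety (the next round catches the other).

**A 1-bp limit on junction exactness.** When a chance extension consumes
the first moiety base as a *gap column*, that single base is
unrecoverable: its sequence is equally consistent with the viral side of
the junction. On simulated double-moiety data this can leave single
residual truth-labelled bases in a small number of reads — material
retention, which we define as ≥10 consecutive rRNA-derived bases (the
shortest stretch that could mislead a seed-based aligner), is zero after
two rounds, as the acceptance suite checks.

**Screening thresholds.** Database screening calls a contamination
stretch at `min_len = 50` bp and `min_identity = 0.90`. The shortest
naturally occurring rRNA incorporations reported in viral genomes are
15–54 nt; 50 bp avoids flagging such biology while catching assembly-scale
contamination. Hits within 10 bp are merged (read-stacking leaves ragged
edges). The reported percentile bin is
`floor(100·(start−1)/target_length)`, using the start position only.

## What the simulator emulates — and what a green test establishes

The generator builds error-free reads: exact substrings of the references
(mock reads for database probing, at constant Phred 30, lengths uniform on
90–150 bp, both strands 50/50), and chimeric reads concatenating an rRNA
fragment and a virus fragment at a junction placed uniformly subject to a
minimum flank (`flank_min`, default 25 bp — a 1-bp flank is unlocalizable
in principle). Triple fusions (rRNA + virus + rRNA) and exact PCR
duplicates (appended, never collapsed — real chimeras were observed as
singletons amplified into duplicates) are available. Every read carries a
ground-truth record of its class, junctions and source spans, so junction
recovery and residual contamination are measured against truth, not
against the method's own output.

Deliberately absent: a sequencing-error model (platform homopolymer
errors included), quality variation, paired-end structure, and real rRNA
secondary-structure-driven chimera hotspots. A green suite therefore
establishes that the algorithm is correct at its boundaries and
conservative in its accounting — not that the 0.80 identity floor is
optimal for any particular sequencing chemistry. On error-free data the
identity floor is simply never exercised; it exists for real reads.

Defaults that mirror the published workflow this package re-implements:
4 million mock reads per reference at 90–150 bp and Phred 30 for database
probing; the 0.90 partial-mapping threshold; and the two-round cleanup.

## Design choices where the design was open

* **Both flanks are kept** when an internal moiety is excised (fragments
  tagged `/L`, `/R`, `/M`). Discarding a flank would waste exactly the
  information this method exists to save; users can lower
  `min_retained_length` tolerance via configuration.
* **One segment per round.** Multi-moiety reads are handled by iteration
  rather than multi-segment excision in one pass; this keeps each round's
  evidence (one best alignment) simple to audit, and matches the
  two-round behaviour of the original workflow.
* **Secondary/supplementary SAM records are skipped** in ingestion mode;
  the primary record carries the read's bases. Hard-clipped records are
  rejected rather than silently truncated, since their bases are
  unrecoverable.
* **PCR duplicates are reported, never collapsed** (`dedup_report`);
  deduplication is a policy decision that belongs upstream.
* **The filter baseline is built in** (`compare_strategies`): discarding
  every read that is not non-rRNA reproduces the behaviour of
  conventional rRNA filters, making the cure/filter/raw comparison a
  one-command regression test.
* **The toy assembler is exact-overlap only.** `greedy_assemble` merges
  longest exact suffix–prefix overlaps (both strands, containment
  counted, deterministic tie-breaks). It exists to reproduce the
  chimeric-bridge phenomenon at desk scale and is explicitly not a
  replacement for a real assembler; with error-free simulated reads,
  exactness is not a restriction.

## Worked example

```{r example, eval = FALSE}
refs <- read_fasta("rrna_db.fa")
reads <- read_fastq("total_rna.fastq")
res <- iterate_cleanup(reads, refs, cleanup_config())
res$round_stats
write_fastq(res$reads, "cured_plus_passthrough.fastq")
```

See the README for a fully reproducible synthetic example with the
numbers it prints.

## Known limitations

* Naturally occurring viral genomes that have recombined with genuine
  rRNA fragments are indistinguishable from artifacts at the read level;
  after curing, such a genome would assemble with a clean break at the
  recombination point rather than a bridged junction.
* Junction localization is exact only up to chance sequence agreement at
  the fusion point (±2 bp for ≥95% of simulated junctions; single
  ambiguous bases can survive, as described above).
* Single-end reads only; the targeted workflow is single-end by nature
  of its sequencing platform.
* Screening at full-database scale is supported procedurally but the
  package ships no database; counts obtained from a public-database
  screen are snapshot-dependent by nature.
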