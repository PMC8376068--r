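Package: ribocure
Title: Detection and Context-Based Excision of rRNA Moieties from Chimeric Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Ribocure", "Maintainers", email = "maintainers@ribocure.dev", role = c("aut", "cre"))
Description: Tools for refining total-RNA-seq read sets prior to viral genome
    assembly. Reads are triaged against a ribosomal RNA (rRNA) reference set;
    reads that are almost entirely ribosomal are discarded, while chimeric
    rRNA-virus reads have their rRNA moiety located by exact local alignment
    and excised, retaining the informative flank(s) for assembly. The package
    also generates mock reads from reference sequences to screen candidate
    sequence databases for rRNA contamination, simulates chimeric read sets
    with known junctions for validation, and quantifies the downstream effect
    of read curation with contig and genome-coverage metrics computed over a
    deterministic greedy overlap assembler.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    IRanges,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
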