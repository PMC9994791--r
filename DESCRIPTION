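Package: pgarc
Title: Compressed, Random-Access Archives of Assembled Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based compression for collections of assembled genomes of
    one species. A designated reference genome is scanned for unique k-mers, a
    spaced subset of which ("splitters") delimits every contig of every sample
    into segments. Segments sharing terminating splitters are grouped, each
    group keeps its first segment as a reference, and the remaining members are
    stored as LZSS match/literal descriptions against it, concatenated into
    fixed-size blocks and xz-compressed. The resulting single-file archive
    supports random access to any sample, contig or base range without
    decompressing the rest of the collection, in-place appending of new
    samples, and an adaptive mode that extends the splitter set from divergent
    samples. A synthetic pangenome simulator is included for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
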