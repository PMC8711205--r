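Package: chromintegrate
Title: Integrative Analysis of Chromatin Accessibility, CUT&RUN Histone
    Acetylation, and Linker Histone Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chromatin remodelling during histone
    deacetylase inhibitor induced differentiation of embryonic stem cells:
    sparse-enrichment (SEACR-style) peak calling from CUT&RUN bedGraph
    coverage with half-mean filtering, replicate consensus and
    condition-unique peak extraction; exact-test differential chromatin
    accessibility classification for ATAC-seq region counts; gene, promoter
    and transposable-element annotation; joint accessibility x H3K56ac
    classification at transcription start sites; and reverse-phase HPLC
    chromatogram quantification of linker histone H1 to nucleosome
    stoichiometry. Ships seeded synthetic-data generators with truth
    manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
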