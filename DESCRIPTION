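Package: hemivox
Title: Hemispheric Lateralization of Cortical Transcriptomes and Mouse
    Vocal Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multi-stage analysis toolkit for studying hemispheric
    lateralization of speech-related cortical gene expression and its
    behavioral correlates.  Provides donor-paired differential expression
    with multi-level false-discovery-rate control, lateralization summary
    statistics (significant-gene count maps, delta/Jaccard dumbbells,
    disease-set overlap), leave-one-donor-out probabilistic handedness
    inference, a GWAS-to-LD-to-eQTL-to-enhancer variant integration
    cascade (sentinel selection, r-squared LD expansion, genomic-region
    annotation, super-enhancer colocalization with McNemar's exact test,
    position-weight-matrix allele scoring), and an ultrasonic-vocalization
    pipeline (spectrogram detection, acoustic feature extraction, contour
    clustering, group comparisons).  Ships synthetic-data generators with
    known ground truth for every stage so the full workflow is testable
    without restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    signal,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
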