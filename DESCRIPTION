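Package: mosaicscan
Title: Somatic SNV Burden, Mutational Signatures and Gene-Set Enrichment
    in Case-Control Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for low-allele-fraction somatic
    single-nucleotide variants (sSNVs) detected by deep exome sequencing of
    paired tissues (neuronal and non-neuronal nuclei plus a non-brain
    reference) from case and control donors. Implements two-caller consensus
    calling with a conservative eight-rule cross-tissue quality-control
    cascade, outlier-specimen exclusion and donor identity-concordance
    checks; per-specimen mutational-burden testing with a
    single-random-intercept Gaussian mixed model and Satterthwaite degrees
    of freedom; 96-trinucleotide-context spectrum construction, Ti/Tv
    ratios, maximum-likelihood KL non-negative matrix factorisation with
    BIC rank selection and correlation-based clustering against a reference
    signature catalog; and MEGA-V-style case/control gene-set mutation
    enrichment (exact Wilcoxon rank-sum, Benjamini-Hochberg FDR, donor
    bootstrap, Haldane-Anscombe odds ratios). A synthetic-data module
    simulates donor tissue trios, planted somatic variants with read-level
    evidence and two noisy pseudo-callers so the full pipeline can be
    exercised and calibrated without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    vcfR
Suggests:
    lme4,
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
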