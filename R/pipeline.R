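#' Synthetic reference-signature catalog
#'
#' A stand-in catalog of 96-channel signature profiles for exercising the
#' clustering step when no published catalog file is at hand. Entirely
#' synthetic: the first three columns are recognisable archetypes (a
#' deamination-like C>T profile peaked at 3'-G flanks, a C>A-heavy
#' oxidative-damage-like profile, and a flat clock-like profile); the
#' remainder are random sparse profiles.
#'
#' @param n_signatures total columns (>= 3).
#' @param seed RNG seed.
#' @return column-stochastic 96 x `n_signatures` matrix named
#'   `SYNREF01`...
#' @export
synthetic_signature_catalog <- function(n_signatures = 30, seed = 1) {
  set.seed(seed)
  labels <- sbs_channels()
  m <- matrix(0, 96, n_signatures,
              dimnames = list(labels,
                              sprintf("SYNREF%02d", seq_len(n_signatures))))
  deam <- rep(0.02 / 80, 96)
  ct <- grep("\\[C>T\\]", labels)
  deam[ct] <- 0.98 * 0.4 / 12
  deam[ct[substr(labels[ct], 7, 7) == "G"]] <- 0.98 * 0.6 / 4
  m[, 1] <- deam / sum(deam)
  oxo <- rep(0.05 / 80, 96)
  oxo[grep("\\[C>A\\]", labels)] <- 0.95 / 16
  m[, 2] <- oxo / sum(oxo)
  clock <- rep(0.2 / 64, 96)
  clock[grep("\\[T>C\\]", labels)] <- 0.5 / 16
  clock[ct] <- 0.3 / 16
  m[, 3] <- clock / sum(clock)
  for (j in seq(4, n_signatures)) {
    w <- stats::rgamma(96, shape = 0.3)
    m[, j] <- w / sum(w)
  }
  m
}

#' Summary metrics of the packaged published call set
#'
#' Recomputes, from the shipped final call-set and cohort fixtures, the
#' headline quantities of the analysis: per-donor burden rates (all and
#' NS+LoF), Ti/Tv ratios by diagnosis, the allele-fraction summary,
#' unique affected genes per cohort, per-class counts, and the
#' BH re-adjustment of the published enrichment p values.
#'
#' @return named list of metrics.
#' @export
published_callset_metrics <- function() {
  cs <- read_final_callset()
  cohort <- read_final_cohort()
  # cohort sheet: one neuronal + one non-neuronal specimen per donor
  specimens <- data.frame(
    specimen_id = paste(rep(cohort$donor_id, each = 2),
                        c("neuronal", "non_neuronal"), sep = "_"),
    donor_id = rep(cohort$donor_id, each = 2),
    tissue = rep(c("neuronal", "non_neuronal"), nrow(cohort)),
    excluded = FALSE, exclude_reason = "",
    stringsAsFactors = FALSE)
  burden <- build_burden_table(cs, specimens, cohort)
  rates <- list(
    case_all = group_rate(burden, cohort, "case", "all"),
    control_all = group_rate(burden, cohort, "control", "all"),
    case_ns_lof = group_rate(burden, cohort, "case", "ns_lof"),
    control_ns_lof = group_rate(burden, cohort, "control", "ns_lof"))
  is_case <- cs$diagnosis == "case"
  titv_case <- titv_ratio(cs$ref[is_case], cs$alt[is_case])
  titv_control <- titv_ratio(cs$ref[!is_case], cs$alt[!is_case])
  vafs <- summarize_vaf(cs$vaf)
  vtest <- vaf_group_test(cs$vaf, cs$diagnosis)
  enr <- read_enrichment_table()
  list(
    n_variants = nrow(cs),
    n_case_variants = sum(is_case),
    n_control_variants = sum(!is_case),
    n_case_ns_lof = sum(is_case & cs$functional_class %in%
                          c("exonic_nonsynonymous", "exonic_lof")),
    n_control_ns_lof = sum(!is_case & cs$functional_class %in%
                             c("exonic_nonsynonymous", "exonic_lof")),
    rates = rates,
    titv_case = titv_case, titv_control = titv_control,
    vaf_mean_pct = 100 * vafs$mean,
    vaf_min_pct = 100 * vafs$min,
    vaf_max_pct = 100 * vafs$max,
    vaf_test = vtest,
    unique_case_genes = length(unique(cs$gene[is_case])),
    unique_control_genes = length(unique(cs$gene[!is_case])),
    enrichment_fdr_recomputed = stats::setNames(bh_adjust(enr$p_value),
                                                enr$gene_set))
}

#' Reconstruct the published hypothesis-driven gene sets
#'
#' Builds stand-in gene sets with the published set sizes whose overlap
#' with the final call set's genes matches the published per-set overlap
#' columns: each set contains its published overlapping case genes plus
#' synthetic filler symbols disjoint from every gene in the call set.
#'
#' @return gene-set collection (see [read_gene_sets()]); filler symbols
#'   are clearly synthetic (`FILLER...`).
#' @export
published_genesets_standin <- function() {
  enr <- read_enrichment_table()
  cs <- read_final_callset()
  avoid <- unique(cs$gene)
  filler_pool <- sprintf("FILLER%05d", seq_len(20000))
  used <- 0L
  sets <- list()
  for (i in seq_len(nrow(enr))) {
    core <- strsplit(enr$case_genes[i] %||% "", ";")[[1]]
    core <- core[nzchar(core)]
    if (is.na(enr$case_genes[i])) core <- character()
    n_fill <- enr$set_size[i] - length(core)
    fill <- filler_pool[used + seq_len(n_fill)]
    used <- used + n_fill
    sets[[enr$gene_set[i]]] <- c(core, fill)
  }
  stopifnot(!any(unlist(sets) %in% setdiff(avoid, unlist(sets))))
  list(sets = sets, source = "hypothesis_driven")
}

#' Run the full somatic-variant analysis on a study directory
#'
#' Orchestrates the pipeline end to end on a directory laid out as
#' written by [write_simulation()] (the same formats real inputs would
#' use): two-caller consensus per brain specimen, the eight-rule QC
#' cascade, outlier-specimen exclusion, donor identity concordance,
#' burden table + mixed-model tests, allele-fraction summary and test,
#' 96-channel spectra + signature extraction + catalog clustering, and
#' gene-set enrichment. Writes a report bundle of TSV/JSON files and
#' returns the results invisibly.
#'
#' @param input_dir study directory (sample_sheet.tsv, targets.bed,
#'   annotations.tsv, site_metrics.tsv, vcf/<specimen>__<caller>.vcf;
#'   optional germline.tsv, gene_sets.gmt).
#' @param out_dir report directory (created).
#' @param callers the two expected caller labels (VCF name infix).
#' @param thresholds QC thresholds from [cascade_thresholds()].
#' @param outlier_k MAD multiplier for specimen exclusion.
#' @param k_range,n_restarts signature-extraction controls.
#' @param catalog optional 96 x S reference catalog for clustering.
#' @param B bootstrap replicates for enrichment.
#' @param seed seed for the stochastic stages (NMF restarts, bootstrap).
#' @return list (invisible): `funnel`, `survivors`, `report`,
#'   `excluded_specimens`, `concordance`, `burden`, `rates`, `lmm_all`,
#'   `lmm_ns_lof`, `vaf_summary`, `vaf_test`, `context_counts`,
#'   `signatures`, `clustering`, `enrichment`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         callers = c("mutect_like", "strelka_like"),
                         thresholds = cascade_thresholds(),
                         outlier_k = 5, k_range = 1:2, n_restarts = 10,
                         catalog = NULL, B = 200, seed = 1) {
  req <- file.path(input_dir, c("sample_sheet.tsv", "targets.bed",
                                "annotations.tsv", "site_metrics.tsv"))
  missing <- req[!file.exists(req)]
  if (length(missing) > 0) {
    stop("input directory lacks: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  cohort <- read_sample_sheet(file.path(input_dir, "sample_sheet.tsv"))
  targets <- read_targets(file.path(input_dir, "targets.bed"))
  annos <- read_annotations(file.path(input_dir, "annotations.tsv"))
  metrics <- read_site_metrics(file.path(input_dir, "site_metrics.tsv"))
  brain <- cohort$specimens[cohort$specimens$tissue != "reference", ,
                            drop = FALSE]

  calls <- list()
  for (sp in brain$specimen_id) {
    for (cal in callers) {
      f <- file.path(input_dir, "vcf", paste0(sp, "__", cal, ".vcf"))
      if (!file.exists(f)) {
        stop("call set of caller ", cal, " missing for specimen ", sp,
             call. = FALSE)
      }
      calls[[paste(sp, cal)]] <- read_caller_vcf(f, cal, sp)
    }
  }
  calls <- do.call(rbind, calls)
  n_raw <- nrow(calls)
  consensus <- consensus_intersect(calls, callers = callers)

  # annotate and attach cross-tissue evidence
  consensus$donor_id <- brain$donor_id[match(consensus$specimen_id,
                                             brain$specimen_id)]
  consensus$tissue <- brain$tissue[match(consensus$specimen_id,
                                         brain$specimen_id)]
  akey <- paste(annos$chrom, annos$pos, annos$ref, annos$alt)
  ai <- match(paste(consensus$chrom, consensus$pos, consensus$ref,
                    consensus$alt), akey)
  consensus$gene <- annos$gene[ai]
  consensus$functional_class <- ifelse(is.na(ai), "other",
                                       annos$functional_class[ai])
  consensus$context <- annos$context[ai]
  consensus$pop_af <- ifelse(is.na(ai), 0, annos$pop_af[ai])
  mkey <- paste(metrics$donor_id, metrics$chrom, metrics$pos)
  mi <- match(paste(consensus$donor_id, consensus$chrom, consensus$pos),
              mkey)
  if (anyNA(mi) && nrow(consensus) > 0) {
    stop("site metrics missing for ", sum(is.na(mi)),
         " consensus candidate(s)", call. = FALSE)
  }
  for (col in grep("^(depth|mq|bq)_", names(metrics), value = TRUE)) {
    consensus[[col]] <- metrics[[col]][mi]
  }
  consensus$n_alleles <- ifelse(
    consensus$tissue == "neuronal",
    metrics$n_alleles_neuronal[mi],
    metrics$n_alleles_non_neuronal[mi])

  cascade <- apply_cascade(consensus, targets, thresholds)
  survivors <- cascade$survivors

  counts <- table(factor(survivors$specimen_id,
                         levels = brain$specimen_id))
  excluded <- exclude_outlier_specimens(
    stats::setNames(as.integer(counts), names(counts)), k_mad = outlier_k)
  specimens <- exclude_specimens(cohort$specimens, excluded,
                                 "excess of somatic calls")
  survivors <- survivors[!survivors$specimen_id %in% excluded, ,
                         drop = FALSE]

  concordance <- NULL
  germ_path <- file.path(input_dir, "germline.tsv")
  if (file.exists(germ_path)) {
    germ <- read_tsv_checked(germ_path, required = c("donor_id",
                                                     "specimen_id", "site",
                                                     "genotype"))
    concordance <- do.call(rbind, lapply(unique(germ$donor_id), function(d) {
      g <- germ[germ$donor_id == d, , drop = FALSE]
      gl <- lapply(split(g, g$specimen_id), function(x) {
        stats::setNames(x$genotype, x$site)
      })
      res <- genotype_concordance(gl)
      data.frame(donor_id = d, flag = res$flag,
                 min_concordance = suppressWarnings(
                   min(res$pairs$concordance, na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  }

  burden <- build_burden_table(survivors, specimens, cohort$donors)
  rates <- list(
    case_all = group_rate(burden, cohort$donors, "case", "all"),
    control_all = group_rate(burden, cohort$donors, "control", "all"),
    case_ns_lof = group_rate(burden, cohort$donors, "case", "ns_lof"),
    control_ns_lof = group_rate(burden, cohort$donors, "control",
                                "ns_lof"))
  lmm_all <- tryCatch(fit_burden_lmm(burden, "count_all"),
                      error = function(e) conditionMessage(e))
  lmm_ns <- tryCatch(fit_burden_lmm(burden, "count_ns_lof"),
                     error = function(e) conditionMessage(e))
  vaf_summary <- if (nrow(survivors) > 0) summarize_vaf(survivors$vaf)
  vaf_test <- tryCatch(
    vaf_group_test(survivors$vaf,
                   cohort$donors$diagnosis[match(survivors$donor_id,
                                                 cohort$donors$donor_id)]),
    error = function(e) conditionMessage(e))

  diag_of <- cohort$donors$diagnosis[match(survivors$donor_id,
                                           cohort$donors$donor_id)]
  has_ctx <- !is.na(survivors$context)
  ctx <- context_matrix(survivors$ref[has_ctx], survivors$alt[has_ctx],
                        survivors$context[has_ctx], diag_of[has_ctx])
  ctx <- ctx[, colSums(ctx) > 0, drop = FALSE]
  sigs <- NULL
  clustering <- NULL
  if (ncol(ctx) > 0) {
    sigs <- extract_signatures(ctx, k_range = k_range,
                               n_restarts = n_restarts, seed = seed)
    if (!is.null(catalog)) {
      clustering <- cluster_with_catalog(sigs, catalog)
    }
  }

  enrichment <- NULL
  gmt_path <- file.path(input_dir, "gene_sets.gmt")
  if (file.exists(gmt_path)) {
    sets <- read_gene_sets(gmt_path)
    enrichment <- run_enrichment(survivors, sets, cohort$donors,
                                 mode = "hypothesis_driven", B = B,
                                 seed = seed)
  }

  funnel <- data.frame(
    stage = c("caller_calls", "consensus", "cascade_pass",
              "after_specimen_exclusion"),
    n = c(n_raw, nrow(consensus), nrow(cascade$survivors),
          nrow(survivors)))

  res <- list(funnel = funnel, survivors = survivors,
              report = cascade$report, excluded_specimens = excluded,
              concordance = concordance, burden = burden, rates = rates,
              lmm_all = lmm_all, lmm_ns_lof = lmm_ns,
              vaf_summary = vaf_summary, vaf_test = vaf_test,
              context_counts = ctx, signatures = sigs,
              clustering = clustering, enrichment = enrichment)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  invisible(res)
}

# serialise a pipeline result to TSV/JSON files
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$funnel, file.path(out_dir, "funnel.tsv"))
  write_tsv(res$report, file.path(out_dir, "filter_report.tsv"))
  surv <- res$survivors
  if (nrow(surv) > 0) {
    surv$ssnv <- format_variant_key(surv$chrom, surv$pos, surv$ref,
                                    surv$alt)
  }
  write_tsv(surv, file.path(out_dir, "survivors.tsv"))
  # manual review queue: red-flag columns left empty unless supplied
  queue <- surv[, intersect(c("ssnv", "specimen_id", "vaf", "depth"),
                            names(surv)), drop = FALSE]
  queue$strand_bias <- NA
  queue$near_indel <- NA
  write_tsv(queue, file.path(out_dir, "inspection_queue.tsv"))
  write_tsv(res$burden, file.path(out_dir, "burden.tsv"))
  for (nm in c("lmm_all", "lmm_ns_lof")) {
    if (inherits(res[[nm]], "mosaic_lmm")) {
      write_tsv(res[[nm]]$coefficients, file.path(out_dir,
                                                  paste0(nm, ".tsv")))
    }
  }
  if (!is.null(res$signatures)) {
    P <- as.data.frame(res$signatures$P)
    P <- cbind(channel = rownames(P), P)
    write_tsv(P, file.path(out_dir, "signatures.tsv"))
    E <- as.data.frame(res$signatures$E)
    E <- cbind(signature = rownames(E), E)
    write_tsv(E, file.path(out_dir, "exposures.tsv"))
    write_tsv(res$signatures$bic_table, file.path(out_dir, "bic_by_k.tsv"))
  }
  if (!is.null(res$clustering)) {
    write_signature_tree(res$clustering, file.path(out_dir,
                                                   "signature_tree.nwk"))
    write_tsv(res$clustering$nearest,
              file.path(out_dir, "nearest_reference.tsv"))
  }
  if (!is.null(res$enrichment)) {
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(res$concordance)) {
    write_tsv(res$concordance, file.path(out_dir, "concordance.tsv"))
  }
  summary <- list(
    funnel = stats::setNames(as.list(res$funnel$n), res$funnel$stage),
    rates = res$rates,
    excluded_specimens = res$excluded_specimens,
    vaf = res$vaf_summary,
    selected_k = if (!is.null(res$signatures)) res$signatures$k)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
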