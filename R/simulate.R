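#' Configuration for the synthetic tissue-trio study
#'
#' Defaults encode the emulated study conditions: 9 case and 10 control
#' donors with three specimens each (neuronal, non-neuronal, reference),
#' ~250x brain and ~50x reference depth, somatic allele fractions uniform
#' on 2.2-7.1%, a C>T-dominated substitution spectrum, and sparse
#' per-specimen counts (per-brain-specimen Poisson means 1.39 / 0.35, i.e.
#' per-donor rates of about 2.78 and 0.70 over two brain specimens). Two
#' pseudo-callers detect a variant when its alternate-read count reaches
#' `caller_sensitivity_min_alt_reads` (minus independent Bernoulli
#' dropout), add caller-private false positives, and co-report occasional
#' shared artifacts constructed to violate specific QC-cascade rules so
#' every filter is exercised.
#'
#' @param n_cases,n_controls donors per group.
#' @param mean_somatic_per_case_specimen,mean_somatic_per_control_specimen
#'   Poisson mean of planted sSNVs per brain specimen.
#' @param vaf_range low/high allele-fraction bounds (fractions).
#' @param brain_depth_mean,reference_depth_mean Poisson depth means.
#' @param signature_mixture 96-channel probability vector or the preset
#'   name `"CtoT_heavy"`.
#' @param shared_tissue_prob probability a planted variant is carried by
#'   both brain specimens of its donor (early-developmental variants).
#' @param caller_sensitivity_min_alt_reads minimum alternate reads for a
#'   pseudo-caller to report a variant.
#' @param caller_dropout per-caller Bernoulli miss probability.
#' @param caller_fp_rate Poisson mean of caller-private false positives
#'   per specimen per caller.
#' @param shared_artifact_rate Poisson mean of both-caller artifacts per
#'   specimen (each violating one cascade rule).
#' @param error_rate per-base sequencing error for non-carrier tissues.
#' @param risk_set_size,risk_fraction_case size of the designated risk
#'   gene set and the probability that a case variant's gene is drawn
#'   from it (controls draw uniformly), giving enrichment a known truth.
#' @param n_contigs,n_targets,target_length,n_genes geometry of the
#'   abstract genome and gene universe.
#' @param germline_panel_size germline sites per donor for the identity
#'   concordance check.
#' @param seed master RNG seed; per-specimen sub-streams are derived by
#'   stable hashing of specimen ids.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 9, n_controls = 10,
                       mean_somatic_per_case_specimen = 1.39,
                       mean_somatic_per_control_specimen = 0.35,
                       vaf_range = c(0.022, 0.071),
                       brain_depth_mean = 250, reference_depth_mean = 50,
                       signature_mixture = "CtoT_heavy",
                       shared_tissue_prob = 0.15,
                       caller_sensitivity_min_alt_reads = 5L,
                       caller_dropout = 0.05,
                       caller_fp_rate = 3,
                       shared_artifact_rate = 0.5,
                       error_rate = 0.001,
                       risk_set_size = 500L, risk_fraction_case = 0.5,
                       n_contigs = 3L, n_targets = 500L,
                       target_length = 150L, n_genes = 5000L,
                       germline_panel_size = 300L,
                       seed = 1L) {
  if (is.character(signature_mixture)) {
    signature_mixture <- signature_mixture_preset(signature_mixture)
  }
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              mean_somatic_per_case_specimen = mean_somatic_per_case_specimen,
              mean_somatic_per_control_specimen =
                mean_somatic_per_control_specimen,
              vaf_range = vaf_range,
              brain_depth_mean = brain_depth_mean,
              reference_depth_mean = reference_depth_mean,
              signature_mixture = signature_mixture,
              shared_tissue_prob = shared_tissue_prob,
              caller_sensitivity_min_alt_reads =
                as.integer(caller_sensitivity_min_alt_reads),
              caller_dropout = caller_dropout,
              caller_fp_rate = caller_fp_rate,
              shared_artifact_rate = shared_artifact_rate,
              error_rate = error_rate,
              risk_set_size = as.integer(risk_set_size),
              risk_fraction_case = risk_fraction_case,
              n_contigs = as.integer(n_contigs),
              n_targets = as.integer(n_targets),
              target_length = as.integer(target_length),
              n_genes = as.integer(n_genes),
              germline_panel_size = as.integer(germline_panel_size),
              seed = as.integer(seed))
  rates <- c(cfg$mean_somatic_per_case_specimen,
             cfg$mean_somatic_per_control_specimen, cfg$caller_fp_rate,
             cfg$shared_artifact_rate, cfg$error_rate, cfg$caller_dropout)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (!(cfg$vaf_range[1] > 0 && cfg$vaf_range[1] <= cfg$vaf_range[2] &&
          cfg$vaf_range[2] < 1)) {
    stop("vaf_range must satisfy 0 < low <= high < 1", call. = FALSE)
  }
  if (length(cfg$signature_mixture) != 96 ||
      abs(sum(cfg$signature_mixture) - 1) > 1e-9 ||
      any(cfg$signature_mixture < 0)) {
    stop("signature_mixture must be 96 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Named substitution-spectrum presets
#'
#' `"CtoT_heavy"` puts 70% of its mass on the C>T class (with extra weight
#' on 3'-G flanks, the deamination-like pattern) and spreads the rest
#' uniformly; `"uniform"` is flat over the 96 channels.
#'
#' @param name preset name.
#' @return 96-channel probability vector (named by channel).
#' @export
signature_mixture_preset <- function(name = c("CtoT_heavy", "uniform")) {
  name <- match.arg(name)
  labels <- sbs_channels()
  w <- rep(0.3 / 80, 96)
  if (name == "uniform") {
    w <- rep(1 / 96, 96)
  } else {
    ct <- grep("\\[C>T\\]", labels)
    g3 <- ct[substr(labels[ct], 7, 7) == "G"]
    w[ct] <- 0.7 * (0.6 / 12)
    w[g3] <- 0.7 * 0.1
  }
  names(w) <- labels
  w / sum(w)
}

# channel index -> ref, alt, 3-base context (pyrimidine strand)
channel_parts <- function(idx) {
  lab <- sbs_channels()[idx]
  data.frame(ref = substr(lab, 3, 3), alt = substr(lab, 5, 5),
             context = paste0(substr(lab, 1, 1), substr(lab, 3, 3),
                              substr(lab, 7, 7)),
             stringsAsFactors = FALSE)
}

#' Simulate the cohort skeleton
#'
#' Donors (with sex and two ancestry covariates) and their three
#' specimens, plus the abstract genome: capture targets on a few synthetic
#' contigs and a synthetic gene universe with a designated risk set.
#'
#' @param config `sim_config` object.
#' @return list with `donors`, `specimens`, `targets`, `genes`,
#'   `risk_genes`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  donor_id <- c(sprintf("S%02d", seq_len(config$n_cases)),
                sprintf("C%02d", seq_len(config$n_controls)))
  donors <- data.frame(
    donor_id = donor_id,
    diagnosis = rep(c("case", "control"),
                    c(config$n_cases, config$n_controls)),
    sex = sample(c("male", "female"), length(donor_id), replace = TRUE),
    ancestry1 = round(stats::rnorm(length(donor_id)), 4),
    ancestry2 = round(stats::rnorm(length(donor_id)), 4),
    stringsAsFactors = FALSE)
  tissues <- c("neuronal", "non_neuronal", "reference")
  specimens <- data.frame(
    specimen_id = paste(rep(donor_id, each = 3), tissues, sep = "_"),
    donor_id = rep(donor_id, each = 3),
    tissue = rep(tissues, length(donor_id)),
    excluded = FALSE, exclude_reason = "",
    stringsAsFactors = FALSE)
  contigs <- paste0("c", seq_len(config$n_contigs))
  idx <- seq_len(config$n_targets) - 1L
  targets <- data.frame(
    chrom = contigs[idx %% config$n_contigs + 1L],
    start = (idx %/% config$n_contigs) * 2000L + 1000L,
    stringsAsFactors = FALSE)
  targets$end <- targets$start + config$target_length
  targets <- validate_targets(targets)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  list(donors = donors, specimens = specimens, targets = targets,
       genes = genes, risk_genes = genes[seq_len(config$risk_set_size)])
}

#' Plant somatic variants for one brain specimen
#'
#' Draws a Poisson number of variants for the diagnosis group, placing
#' each uniformly within a random capture target with a substitution
#' channel from the configured spectrum (half are stored on the purine
#' strand to exercise pyrimidine canonicalisation), an allele fraction
#' uniform in `vaf_range`, and a gene from the synthetic universe
#' (case variants drawn into the risk set with `risk_fraction_case`).
#' Uses the current RNG stream.
#'
#' @param specimen_id,tissue,diagnosis specimen identity (brain tissues
#'   only).
#' @param cohort result of [simulate_cohort()].
#' @param config `sim_config`.
#' @return data.frame of planted variants (possibly zero rows).
#' @export
plant_somatic_variants <- function(specimen_id, tissue, diagnosis, cohort,
                                   config) {
  if (!tissue %in% c("neuronal", "non_neuronal")) {
    stop("variants are planted in brain specimens only", call. = FALSE)
  }
  mean_n <- if (diagnosis == "case") {
    config$mean_somatic_per_case_specimen
  } else {
    config$mean_somatic_per_control_specimen
  }
  n <- stats::rpois(1, mean_n)
  if (n == 0) {
    return(data.frame(specimen_id = character(), tissue = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      context = character(), channel = character(),
                      vaf = numeric(), gene = character(),
                      functional_class = character(), shared = logical(),
                      stringsAsFactors = FALSE))
  }
  ti <- sample.int(nrow(cohort$targets), n, replace = TRUE)
  offset <- vapply(ti, function(i) {
    sample.int(cohort$targets$end[i] - cohort$targets$start[i], 1)
  }, integer(1))
  ch <- sample.int(96, n, replace = TRUE, prob = config$signature_mixture)
  parts <- channel_parts(ch)
  flip <- stats::runif(n) < 0.5
  parts$ref[flip] <- chartr("ACGT", "TGCA", parts$ref[flip])
  parts$alt[flip] <- chartr("ACGT", "TGCA", parts$alt[flip])
  parts$context[flip] <- revcomp(parts$context[flip])
  use_risk <- diagnosis == "case" &
    stats::runif(n) < config$risk_fraction_case
  gene <- ifelse(use_risk,
                 sample(cohort$risk_genes, n, replace = TRUE),
                 sample(cohort$genes, n, replace = TRUE))
  classes <- functional_classes()
  class_prob <- c(0.30, 0.08, 0.04, 0.15, 0.35, 0.05, 0.03)
  data.frame(specimen_id = specimen_id, tissue = tissue,
             chrom = cohort$targets$chrom[ti],
             pos = cohort$targets$start[ti] + offset,  # 1-based, in-target
             ref = parts$ref, alt = parts$alt, context = parts$context,
             channel = sbs_channels()[ch],
             vaf = stats::runif(n, config$vaf_range[1], config$vaf_range[2]),
             gene = gene,
             functional_class = sample(classes, n, replace = TRUE,
                                       prob = class_prob),
             shared = stats::runif(n) < config$shared_tissue_prob,
             stringsAsFactors = FALSE)
}

#' Simulate cross-tissue read evidence for one variant site
#'
#' Depth is Poisson around the tissue mean; alternate reads are Binomial
#' at the planted allele fraction in carrier tissues and at the
#' sequencing error rate elsewhere. Site-level qualities for genuine
#' variant sites are drawn comfortably above the QC thresholds.
#'
#' @param vaf planted allele fraction.
#' @param carrier_tissues subset of `c("neuronal", "non_neuronal")`
#'   carrying the variant.
#' @param config `sim_config`.
#' @return one-row data.frame with `depth_`, `alt_`, `mq_`, `bq_` columns
#'   for the three tissues and `n_alleles_` for the brain tissues.
#' @export
simulate_evidence <- function(vaf, carrier_tissues, config) {
  tissues <- c("neuronal", "non_neuronal", "reference")
  out <- list()
  for (t in tissues) {
    mean_dp <- if (t == "reference") config$reference_depth_mean else
      config$brain_depth_mean
    dp <- stats::rpois(1, mean_dp)
    p <- if (t %in% carrier_tissues) vaf else config$error_rate
    alt <- stats::rbinom(1, dp, p)
    out[[paste0("depth_", t)]] <- dp
    out[[paste0("alt_", t)]] <- alt
    out[[paste0("mq_", t)]] <- round(stats::runif(1, 40, 60), 1)
    out[[paste0("bq_", t)]] <- round(stats::runif(1, 28, 38), 1)
    if (t != "reference") {
      out[[paste0("n_alleles_", t)]] <- 1L + as.integer(alt >= 2L)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# artifact generator: both-caller candidates each violating one cascade
# rule, cycling deterministically through the violation types
artifact_types <- c("low_mq", "low_depth_ref", "triallelic", "indel",
                    "proximity_pair", "off_target", "high_pop_af")

make_shared_artifacts <- function(specimen_id, tissue, cohort, config,
                                  type_offset = 0L) {
  n <- stats::rpois(1, config$shared_artifact_rate)
  if (n == 0) return(NULL)
  rows <- list()
  for (i in seq_len(n)) {
    type <- artifact_types[(type_offset + i - 1L) %% length(artifact_types) + 1L]
    ti <- sample.int(nrow(cohort$targets), 1)
    pos <- cohort$targets$start[ti] +
      sample.int(config$target_length, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ev <- simulate_evidence(stats::runif(1, config$vaf_range[1],
                                         config$vaf_range[2]),
                            carrier_tissues = tissue, config = config)
    pop_af <- 0
    if (type == "low_mq") ev[[paste0("mq_", tissue)]] <- 5
    if (type == "low_depth_ref") {
      ev$depth_reference <- sample(3:10, 1)
    }
    if (type == "triallelic") ev[[paste0("n_alleles_", tissue)]] <- 3L
    if (type == "indel") alt <- paste0(alt, "A")
    if (type == "off_target") pos <- cohort$targets$end[ti] + 400L
    if (type == "high_pop_af") pop_af <- 0.01
    base <- data.frame(specimen_id = specimen_id, tissue = tissue,
                       chrom = cohort$targets$chrom[ti], pos = pos,
                       ref = ref, alt = alt,
                       context = paste0("A", substr(ref, 1, 1), "A"),
                       pop_af = pop_af, artifact_type = type,
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(base, ev)
    if (type == "proximity_pair") {
      twin <- base
      twin$pos <- base$pos + 5L
      ev2 <- simulate_evidence(stats::runif(1, config$vaf_range[1],
                                            config$vaf_range[2]),
                               carrier_tissues = tissue, config = config)
      rows[[length(rows) + 1L]] <- cbind(twin, ev2)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete tissue-trio study
#'
#' Generates the cohort, plants somatic variants with cross-tissue read
#' evidence, derives two pseudo-caller call sets (independent dropout,
#' caller-private false positives, shared rule-violating artifacts) and a
#' germline concordance panel. Per-specimen RNG sub-streams are derived
#' from the master seed by stable hashing of specimen ids, so output is
#' reproducible independent of iteration order.
#'
#' @param config `sim_config` object.
#' @return list with `config`, `donors`, `specimens`, `targets`, `genes`,
#'   `risk_genes`, `truth` (planted variants, one row per carrying
#'   specimen, with detection flags per caller), `calls` (per-caller
#'   candidate rows, [read_caller_vcf()] layout), `site_metrics`,
#'   `annotations`, `germline` (named list donor -> specimen -> genotype
#'   vector).
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  donors <- cohort$donors
  specimens <- cohort$specimens
  brain <- specimens[specimens$tissue != "reference", , drop = FALSE]

  truth_rows <- list(); metric_rows <- list(); anno_rows <- list()
  call_rows <- list()
  classes <- functional_classes()

  for (si in seq_len(nrow(brain))) {
    sp <- brain$specimen_id[si]
    tissue <- brain$tissue[si]
    donor <- brain$donor_id[si]
    diag <- donors$diagnosis[match(donor, donors$donor_id)]
    set.seed((config$seed * 1000L + str_hash(sp)) %% 2147483647L)

    planted <- plant_somatic_variants(sp, tissue, diag, cohort, config)
    if (nrow(planted) > 0) {
      other_tissue <- setdiff(c("neuronal", "non_neuronal"), tissue)
      other_sp <- paste(donor, other_tissue, sep = "_")
      for (vi in seq_len(nrow(planted))) {
        v <- planted[vi, ]
        carriers <- if (v$shared) c(tissue, other_tissue) else tissue
        ev <- simulate_evidence(v$vaf, carriers, config)
        carrying_sp <- if (v$shared) c(sp, other_sp) else sp
        for (cs in carrying_sp) {
          cs_tissue <- sub("^.*_(neuronal|non_neuronal)$", "\\1", cs)
          alt_reads <- ev[[paste0("alt_", cs_tissue)]]
          depth <- ev[[paste0("depth_", cs_tissue)]]
          det <- stats::runif(2) > config$caller_dropout &
            alt_reads >= config$caller_sensitivity_min_alt_reads
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            donor_id = donor, specimen_id = cs, tissue = cs_tissue,
            chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
            context = v$context, channel = v$channel, vaf = v$vaf,
            gene = v$gene, functional_class = v$functional_class,
            shared = v$shared, depth = depth, alt_reads = alt_reads,
            detected_mutect_like = det[1], detected_strelka_like = det[2],
            stringsAsFactors = FALSE)
          for (cal in c("mutect_like", "strelka_like")[det]) {
            call_rows[[length(call_rows) + 1L]] <- data.frame(
              chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
              specimen_id = cs, caller = cal, depth = depth,
              alt_reads = alt_reads,
              vaf = if (depth > 0) alt_reads / depth else 0,
              is_snv = TRUE, stringsAsFactors = FALSE)
          }
        }
        metric_rows[[length(metric_rows) + 1L]] <- cbind(
          data.frame(donor_id = donor, chrom = v$chrom, pos = v$pos,
                     stringsAsFactors = FALSE), ev)
        anno_rows[[length(anno_rows) + 1L]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          gene = v$gene, functional_class = v$functional_class,
          context = v$context, pop_af = 0, stringsAsFactors = FALSE)
      }
    }

    # caller-private false positives (removed by consensus)
    for (cal in c("mutect_like", "strelka_like")) {
      n_fp <- stats::rpois(1, config$caller_fp_rate)
      for (k in seq_len(n_fp)) {
        ti <- sample.int(nrow(cohort$targets), 1)
        pos <- cohort$targets$start[ti] + sample.int(config$target_length, 1)
        ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        dp <- stats::rpois(1, config$brain_depth_mean)
        ar <- sample(3:8, 1)
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          chrom = cohort$targets$chrom[ti], pos = pos, ref = ref,
          alt = alt, specimen_id = sp, caller = cal, depth = dp,
          alt_reads = ar,
          vaf = if (dp > 0) ar / dp else 0, is_snv = TRUE,
          stringsAsFactors = FALSE)
      }
    }

    # shared artifacts (pass consensus, each violates one cascade rule)
    art <- make_shared_artifacts(sp, tissue, cohort, config,
                                 type_offset = si)
    if (!is.null(art)) {
      for (ai in seq_len(nrow(art))) {
        a <- art[ai, ]
        alt_reads <- a[[paste0("alt_", tissue)]]
        depth <- a[[paste0("depth_", tissue)]]
        for (cal in c("mutect_like", "strelka_like")) {
          call_rows[[length(call_rows) + 1L]] <- data.frame(
            chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
            specimen_id = sp, caller = cal, depth = depth,
            alt_reads = alt_reads,
            vaf = if (depth > 0) alt_reads / depth else 0,
            is_snv = nchar(a$alt) == 1L, stringsAsFactors = FALSE)
        }
        metric_rows[[length(metric_rows) + 1L]] <- cbind(
          data.frame(donor_id = donor, chrom = a$chrom, pos = a$pos,
                     stringsAsFactors = FALSE),
          a[, grep("^(depth|alt|mq|bq|n_alleles)_", names(a))])
        anno_rows[[length(anno_rows) + 1L]] <- data.frame(
          chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
          gene = sample(cohort$genes, 1),
          functional_class = sample(classes, 1),
          context = a$context, pop_af = a$pop_af,
          stringsAsFactors = FALSE)
      }
    }
  }

  bindrows <- function(rows, proto) {
    if (length(rows) == 0) return(proto)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  truth <- bindrows(truth_rows, data.frame())
  calls <- bindrows(call_rows, data.frame())
  metrics <- bindrows(metric_rows, data.frame())
  annos <- bindrows(anno_rows, data.frame())
  if (nrow(annos) > 0) {
    annos <- annos[!duplicated(paste(annos$chrom, annos$pos, annos$ref,
                                     annos$alt)), , drop = FALSE]
  }
  if (nrow(metrics) > 0) {
    metrics <- metrics[!duplicated(paste(metrics$donor_id, metrics$chrom,
                                         metrics$pos)), , drop = FALSE]
  }

  # germline concordance panel: one genotype vector per donor, copied to
  # each specimen with a small discordance rate
  set.seed((config$seed * 1000L + 999983L) %% 2147483647L)
  sites <- sprintf("gsite%04d", seq_len(config$germline_panel_size))
  afreq <- stats::runif(config$germline_panel_size, 0.1, 0.9)
  germline <- lapply(seq_len(nrow(donors)), function(di) {
    g <- stats::rbinom(config$germline_panel_size, 2, afreq)
    names(g) <- sites
    sps <- specimens$specimen_id[specimens$donor_id == donors$donor_id[di]]
    per_sp <- lapply(sps, function(s) {
      flip <- stats::runif(config$germline_panel_size) < 0.002
      gs <- g
      gs[flip] <- (gs[flip] + 1L) %% 3L
      gs
    })
    names(per_sp) <- sps
    per_sp
  })
  names(germline) <- donors$donor_id

  list(config = config, donors = donors, specimens = specimens,
       targets = cohort$targets, genes = cohort$genes,
       risk_genes = cohort$risk_genes, truth = truth, calls = calls,
       site_metrics = metrics, annotations = annos, germline = germline)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Produces exactly the inputs the analysis consumes: sample sheet TSV,
#' targets BED, annotation and site-metrics TSVs, a truth table TSV, a
#' germline genotype TSV, a GMT with the risk set plus decoy sets, and
#' one VCF per specimen per pseudo-caller under `vcf/`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param n_decoy_sets decoy gene sets written alongside the risk set.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, n_decoy_sets = 5) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  sheet <- merge(sim$specimens[, c("specimen_id", "donor_id", "tissue")],
                 sim$donors, by = "donor_id")
  write_tsv(sheet[order(sheet$specimen_id), ],
            file.path(dir, "sample_sheet.tsv"))
  write_targets(sim$targets, file.path(dir, "targets.bed"))
  write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(sim$site_metrics, file.path(dir, "site_metrics.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  germ <- do.call(rbind, lapply(names(sim$germline), function(d) {
    do.call(rbind, lapply(names(sim$germline[[d]]), function(s) {
      g <- sim$germline[[d]][[s]]
      data.frame(donor_id = d, specimen_id = s, site = names(g),
                 genotype = as.integer(g), stringsAsFactors = FALSE)
    }))
  }))
  write_tsv(germ, file.path(dir, "germline.tsv"))

  set.seed((sim$config$seed * 1000L + 424243L) %% 2147483647L)
  sets <- list(risk_set = sim$risk_genes)
  for (i in seq_len(n_decoy_sets)) {
    sets[[sprintf("decoy_%02d", i)]] <-
      sort(sample(sim$genes, sample(100:1000, 1)))
  }
  write_gene_sets(list(sets = sets, source = "hypothesis_driven"),
                  file.path(dir, "gene_sets.gmt"))

  brain <- sim$specimens$specimen_id[sim$specimens$tissue != "reference"]
  for (sp in brain) {
    for (cal in c("mutect_like", "strelka_like")) {
      cc <- sim$calls[sim$calls$specimen_id == sp &
                        sim$calls$caller == cal, , drop = FALSE]
      write_caller_vcf(cc, file.path(dir, "vcf",
                                     paste0(sp, "__", cal, ".vcf")))
    }
  }
  invisible(dir)
}
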