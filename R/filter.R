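#' Thresholds for the somatic QC cascade
#'
#' All thresholds are strict inequalities, matching how conservative
#' cross-tissue somatic pipelines state them: mapping quality > `mq`, base
#' quality > `bq`, depth > `dp` (each in all three tissues), exactly
#' `n_alleles` alleles observed at the site in the somatic specimen,
#' single-base alleles only, nearest other candidate > `proximity` bp away,
#' distance outside the nearest capture target < `target_dist` bp, and
#' population allele frequency < `max_af`.
#'
#' @param mq,bq,dp per-tissue site-level quality/depth thresholds.
#' @param n_alleles required number of distinct alleles at the site.
#' @param proximity minimum spacing (bp) between candidates of a specimen.
#' @param target_dist maximum distance (bp) outside a capture target.
#' @param max_af maximum population (minor) allele frequency.
#' @return named list of thresholds.
#' @export
cascade_thresholds <- function(mq = 10, bq = 10, dp = 10, n_alleles = 2L,
                               proximity = 10, target_dist = 350,
                               max_af = 0.001) {
  thr <- list(mq = mq, bq = bq, dp = dp, n_alleles = as.integer(n_alleles),
              proximity = proximity, target_dist = target_dist,
              max_af = max_af)
  if (any(vapply(thr[c("mq", "bq", "dp", "proximity", "target_dist")],
                 function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    stop("cascade thresholds must be non-negative scalars", call. = FALSE)
  }
  if (thr$max_af < 0 || thr$max_af > 1) {
    stop("max_af must lie in [0, 1]", call. = FALSE)
  }
  thr
}

#' Retain candidates reported by both callers
#'
#' A candidate survives consensus iff both callers report the same
#' (chrom, pos, ref, alt) in the same specimen. Evidence from both callers
#' is kept; the merged `depth`/`alt_reads`/`vaf` come from the caller
#' reporting the higher depth at the site (the better-powered estimate).
#'
#' @param calls data.frame of per-caller candidates (columns as produced
#'   by [read_caller_vcf()]) for one or more specimens.
#' @param callers the two expected caller labels. When `NULL` (default)
#'   they are inferred from the data, and every specimen must then carry
#'   calls from both callers — a specimen seen through one caller only
#'   indicates a missing call set and is an error. Pass the labels
#'   explicitly when a caller legitimately reported zero candidates for
#'   some specimen.
#' @return data.frame of consensus candidates with per-caller depth columns
#'   (`depth_<caller>`, `alt_reads_<caller>`) plus merged `depth`,
#'   `alt_reads`, `vaf`, and `callers`.
#' @export
consensus_intersect <- function(calls, callers = NULL) {
  infer <- is.null(callers)
  if (infer) callers <- sort(unique(calls$caller))
  if (length(callers) != 2) {
    stop("consensus requires exactly two callers, got: ",
         paste(callers, collapse = ", "), call. = FALSE)
  }
  if (!all(calls$caller %in% callers)) {
    stop("calls from unexpected caller(s): ",
         paste(setdiff(unique(calls$caller), callers), collapse = ", "),
         call. = FALSE)
  }
  if (infer) {
    for (sp in unique(calls$specimen_id)) {
      have <- unique(calls$caller[calls$specimen_id == sp])
      if (length(have) < 2) {
        stop("call set missing for specimen ", sp, " (only ",
             paste(have, collapse = ","), " present)", call. = FALSE)
      }
    }
  }
  key <- paste(calls$specimen_id, calls$chrom, calls$pos, calls$ref,
               calls$alt, sep = "\r")
  a <- calls[calls$caller == callers[1], , drop = FALSE]
  b <- calls[calls$caller == callers[2], , drop = FALSE]
  ka <- key[calls$caller == callers[1]]
  kb <- key[calls$caller == callers[2]]
  shared <- intersect(ka, kb)
  a <- a[match(shared, ka), , drop = FALSE]
  b <- b[match(shared, kb), , drop = FALSE]
  if (length(shared) == 0) {
    out <- a[0, c("chrom", "pos", "ref", "alt", "specimen_id", "is_snv")]
    out$callers <- character()
    out$depth <- integer(); out$alt_reads <- integer(); out$vaf <- numeric()
    return(out)
  }
  use_a <- a$depth >= b$depth
  out <- data.frame(
    chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
    specimen_id = a$specimen_id, is_snv = a$is_snv & b$is_snv,
    callers = paste(callers[1], callers[2], sep = "+"),
    depth = ifelse(use_a, a$depth, b$depth),
    alt_reads = ifelse(use_a, a$alt_reads, b$alt_reads),
    stringsAsFactors = FALSE)
  out$vaf <- ifelse(out$depth > 0, out$alt_reads / out$depth, 0)
  nm <- function(base, cal) paste0(base, "_", cal)
  out[[nm("depth", callers[1])]] <- a$depth
  out[[nm("alt_reads", callers[1])]] <- a$alt_reads
  out[[nm("depth", callers[2])]] <- b$depth
  out[[nm("alt_reads", callers[2])]] <- b$alt_reads
  rownames(out) <- NULL
  out
}

# distance (bp) from a 1-based variant position to the nearest target
# interval of its chromosome; 0 when the variant falls inside a target
target_distance <- function(chrom, pos, targets) {
  chrom <- canonical_chrom(chrom)
  vapply(seq_along(pos), function(i) {
    t <- targets[targets$chrom == chrom[i], , drop = FALSE]
    if (nrow(t) == 0) return(Inf)
    p0 <- pos[i] - 1L  # 0-based coordinate of the base
    inside <- any(t$start <= p0 & p0 < t$end)
    if (inside) return(0)
    min(pmax(t$start - p0, p0 - t$end + 1L))
  }, numeric(1))
}

#' Apply the eight-rule somatic QC cascade
#'
#' Evaluates, for every consensus candidate: (a) mapping quality, (b) base
#' quality and (c) depth above threshold in all three tissues of the
#' donor; (d) exactly two alleles observed at the site in the somatic
#' specimen; (e) both alleles single bases (no indels); (f) no other
#' candidate of the same specimen within `proximity` bp (all members of a
#' close cluster are removed, evaluated on the full consensus set so the
#' outcome does not depend on rule order); (g) distance outside the
#' nearest capture target below `target_dist` bp; and (h) population
#' allele frequency below `max_af`. A candidate survives iff all eight
#' rules hold.
#'
#' @param candidates data.frame of consensus candidates; must carry, per
#'   row, the somatic-site columns (`chrom`, `pos`, `ref`, `alt`,
#'   `specimen_id`, `is_snv`, `n_alleles`, `pop_af`) and cross-tissue
#'   evidence columns `depth_`/`mq_`/`bq_` suffixed with `neuronal`,
#'   `non_neuronal` and `reference`.
#' @param targets capture-target intervals from [read_targets()].
#' @param thresholds list from [cascade_thresholds()].
#' @return list with `survivors` (subset of `candidates`) and `report`, a
#'   per-candidate ledger holding every rule outcome, the measured values
#'   and the first failing rule (`NA` for survivors).
#' @export
apply_cascade <- function(candidates, targets,
                          thresholds = cascade_thresholds()) {
  thr <- thresholds
  tissues <- c("neuronal", "non_neuronal", "reference")
  need <- c("chrom", "pos", "ref", "alt", "specimen_id", "is_snv",
            "n_alleles", "pop_af",
            as.vector(outer(c("depth", "mq", "bq"), tissues, paste,
                            sep = "_")))
  missing <- setdiff(need, names(candidates))
  if (length(missing) > 0) {
    stop("candidates lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(candidates)
  if (n == 0) {
    rep0 <- candidates[, c("specimen_id", "chrom", "pos", "ref", "alt")]
    rep0$first_fail <- character()
    return(list(survivors = candidates, report = rep0))
  }
  ev <- function(base) {
    m <- as.matrix(candidates[, paste(base, tissues, sep = "_")])
    if (anyNA(m)) {
      stop("missing ", base, " evidence for one or more tissues",
           call. = FALSE)
    }
    m
  }
  pass_mq <- rowSums(ev("mq") > thr$mq) == 3L
  pass_bq <- rowSums(ev("bq") > thr$bq) == 3L
  pass_dp <- rowSums(ev("depth") > thr$dp) == 3L
  pass_alleles <- candidates$n_alleles == thr$n_alleles
  pass_snv <- as.logical(candidates$is_snv)

  # (f) nearest-neighbour spacing on the full consensus set, per specimen
  nearest <- rep(Inf, n)
  for (sp in unique(candidates$specimen_id)) {
    i <- which(candidates$specimen_id == sp)
    for (j in i) {
      same <- i[candidates$chrom[i] == candidates$chrom[j] & i != j]
      if (length(same) > 0) {
        nearest[j] <- min(abs(candidates$pos[same] - candidates$pos[j]))
      }
    }
  }
  pass_prox <- nearest > thr$proximity
  tdist <- target_distance(candidates$chrom, candidates$pos, targets)
  pass_target <- tdist < thr$target_dist
  pop_af <- candidates$pop_af
  pop_af[is.na(pop_af)] <- 0
  pass_af <- pop_af < thr$max_af

  rules <- cbind(mapping_quality = pass_mq, base_quality = pass_bq,
                 depth = pass_dp, two_alleles = pass_alleles,
                 snv_only = pass_snv, proximity = pass_prox,
                 near_target = pass_target, pop_af = pass_af)
  all_pass <- rowSums(rules) == ncol(rules)
  first_fail <- apply(rules, 1, function(r) {
    f <- which(!r)
    if (length(f) == 0) NA_character_ else colnames(rules)[f[1]]
  })
  report <- data.frame(
    specimen_id = candidates$specimen_id,
    chrom = candidates$chrom, pos = candidates$pos,
    ref = candidates$ref, alt = candidates$alt,
    rules, nearest_bp = nearest, target_bp = tdist, pop_af = pop_af,
    pass = all_pass, first_fail = first_fail,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  survivors <- candidates[all_pass, , drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors, report = report)
}

#' Flag specimens with an implausible excess of somatic calls
#'
#' A specimen is excluded when its post-cascade candidate count exceeds
#' `median + k_mad * scale` over all specimens, where the scale is the
#' MAD (with the usual 1.4826 normal-consistency factor) floored at one
#' count so the rule stays meaningful for the sparse regime in which most
#' specimens carry 0-3 candidates and the MAD collapses to zero. A robust
#' stand-in for the study-level judgement that a sample with an
#' implausible excess of somatic variants is contaminated or
#' artifact-ridden.
#'
#' @param counts named integer vector, candidate count per specimen.
#' @param k_mad multiplier on the scale (default 5); `Inf` disables.
#' @return character vector of excluded specimen ids (possibly empty).
#' @export
exclude_outlier_specimens <- function(counts, k_mad = 5) {
  if (length(counts) < 4) {
    warning("fewer than 4 specimens; outlier exclusion skipped")
    return(character())
  }
  if (!is.finite(k_mad)) return(character())
  med <- stats::median(counts)
  m <- max(stats::mad(counts), 1)
  cut <- med + k_mad * m
  names(counts)[counts > cut]
}

#' Pairwise germline genotype concordance within a donor
#'
#' Simplified identity check across the three specimens of a donor using a
#' panel of germline genotypes (0/1/2 allele dosages): for every specimen
#' pair, the fraction of identical calls over shared sites. A donor is
#' flagged `"mismatch"` when any pair falls below `threshold` (a biobank
#' swap signature); pairs with fewer than `min_sites` shared sites are
#' `"indeterminate"`, never a pass.
#'
#' @param genotypes named list: specimen id -> named vector of genotype
#'   dosages (site keys as names).
#' @param min_sites minimum shared genotyped sites per pair (default 100).
#' @param threshold concordance below which a pair signals a mismatch.
#' @return list with `pairs` (data.frame: specimen pair, shared sites,
#'   concordance) and `flag` (`"ok"`, `"mismatch"` or `"indeterminate"`).
#' @export
genotype_concordance <- function(genotypes, min_sites = 100,
                                 threshold = 0.80) {
  sp <- names(genotypes)
  if (length(sp) < 2) stop("need at least two specimens", call. = FALSE)
  cmb <- utils::combn(sp, 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ], n_shared = NA_integer_,
                      concordance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    ga <- genotypes[[cmb[1, i]]]
    gb <- genotypes[[cmb[2, i]]]
    shared <- intersect(names(ga), names(gb))
    pairs$n_shared[i] <- length(shared)
    if (length(shared) >= min_sites) {
      pairs$concordance[i] <- mean(ga[shared] == gb[shared])
    }
  }
  flag <- if (any(!is.na(pairs$concordance) &
                  pairs$concordance < threshold)) {
    "mismatch"
  } else if (anyNA(pairs$concordance)) {
    "indeterminate"
  } else {
    "ok"
  }
  list(pairs = pairs, flag = flag)
}
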