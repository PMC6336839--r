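#' Exact tie-aware Wilcoxon rank-sum test
#'
#' For small samples (`n_x + n_y <= 20` by default) the permutation
#' distribution of the rank-sum statistic is enumerated over all
#' assignments of the pooled midranks, so ties (ubiquitous in sparse
#' mutation counts) are handled exactly. Larger samples use the
#' tie-corrected normal approximation.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends
#'   larger) or `"less"`.
#' @param exact force (`TRUE`)/suppress (`FALSE`) the enumeration path;
#'   default chooses by total sample size.
#' @return list with `statistic` (rank sum of `x`), `p`, and `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(2, 2, 0, 0), rep(0, 5), alternative = "greater")
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) stop("both groups must be non-empty",
                               call. = FALSE)
  if (is.null(exact)) exact <- n <= 20
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (exact) {
    combos <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combos], nrow = nx))
    tol <- 1e-9
    p <- switch(alternative,
                greater = mean(ws >= w - tol),
                less = mean(ws <= w + tol),
                two.sided = mean(abs(ws - mu) >= abs(w - mu) - tol))
    return(list(statistic = w, p = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = w, p = 1, method = "normal"))
  z <- (w - mu) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = w, p = min(p, 1), method = "normal")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validating wrapper over the standard step-up adjustment;
#' order-preserving with the input.
#'
#' @param p raw p values in `(0, 1]`.
#' @return adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Donor bootstrap success rate for a rank-sum comparison
#'
#' Resamples each cohort's donors with replacement `B` times and reports
#' the percentage of replicates in which the Wilcoxon comparison rejects
#' at `alpha` (the tie-corrected normal path is used inside the loop;
#' degenerate all-tied replicates count as non-rejections).
#'
#' @param x,y per-donor counts for the two cohorts (length >= 2 each).
#' @param B bootstrap replicates (>= 100).
#' @param alpha rejection level per replicate.
#' @param seed RNG seed.
#' @param alternative passed to [wilcoxon_rank_sum()].
#' @return success rate in percent.
#' @export
bootstrap_success <- function(x, y, B = 1000, alpha = 0.05, seed = 1,
                              alternative = "two.sided") {
  if (length(x) < 2 || length(y) < 2) {
    stop("bootstrap needs at least two donors per cohort", call. = FALSE)
  }
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    xb <- sample(x, replace = TRUE)
    yb <- sample(y, replace = TRUE)
    p <- wilcoxon_rank_sum(xb, yb, alternative = alternative,
                           exact = FALSE)$p
    if (p < alpha) hits <- hits + 1L
  }
  100 * hits / B
}

#' Odds ratio with Haldane-Anscombe correction
#'
#' Computes `(a d) / (b c)` for the 2x2 table (rows = cohort, columns =
#' in-set / not-in-set gene hits). When any cell is zero, 0.5 is added to
#' every cell first (the Haldane-Anscombe correction); tables without
#' zeros are returned uncorrected.
#'
#' @param a,b,c,d non-negative integer cell counts; `a` = case genes in
#'   the set, `b` = case genes outside it, `c`/`d` the control analogues.
#' @return odds ratio (positive numeric).
#' @export
#' @examples
#' haldane_anscombe_or(2, 1, 1, 2)   # 4, no correction
#' haldane_anscombe_or(4, 19, 0, 7)  # corrected
haldane_anscombe_or <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative",
                           call. = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Per-donor mutation counts inside a gene set
#'
#' For every donor, the number of that donor's surviving sSNVs whose gene
#' belongs to the set (variants, not unique genes; both brain specimens
#' of a donor pooled), split into case and control vectors. Donors with
#' no variants contribute zeros.
#'
#' @param survivors data.frame with `donor_id` and `gene` columns.
#' @param gene_set character vector of gene symbols.
#' @param donors donor table with `donor_id`, `diagnosis`.
#' @return list with numeric vectors `cases` and `controls`, named by
#'   donor id.
#' @export
per_individual_set_counts <- function(survivors, gene_set, donors) {
  unknown <- setdiff(survivors$donor_id, donors$donor_id)
  if (length(unknown) > 0) {
    stop("survivor with unknown donor: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hit <- survivors$gene %in% gene_set
  count_for <- function(ids) {
    v <- vapply(ids, function(d) {
      sum(hit & survivors$donor_id == d)
    }, numeric(1))
    names(v) <- ids
    v
  }
  list(cases = count_for(donors$donor_id[donors$diagnosis == "case"]),
       controls = count_for(donors$donor_id[donors$diagnosis == "control"]))
}

#' Case/control gene-set mutation enrichment
#'
#' MEGA-V-style procedure: per gene set, compare the per-donor in-set
#' mutation-count distributions between cases and controls with the
#' Wilcoxon rank-sum test; adjust across the tested family with
#' Benjamini-Hochberg; estimate a donor-bootstrap success rate; and
#' report a Haldane-Anscombe odds ratio on unique affected genes (case
#' universe = all unique case genes, control universe = all unique
#' control genes). In hypothesis-free mode, sets outside
#' `size_range` genes are dropped before testing. Sets meeting
#' `fdr <= 0.1` and bootstrap success `> 99` are flagged significant.
#'
#' @param survivors annotated surviving variants (`donor_id`, `gene`).
#' @param sets gene-set collection from [read_gene_sets()].
#' @param donors donor table.
#' @param mode `"hypothesis_driven"` (test every set) or
#'   `"hypothesis_free"` (apply the size filter).
#' @param size_range inclusive set-size bounds for hypothesis-free mode.
#' @param B,alpha,seed bootstrap controls (see [bootstrap_success()]).
#' @param alternative Wilcoxon alternative; `"two.sided"` default, with
#'   `"greater"` available as a one-sided case-enriched mode.
#' @return data.frame, one row per tested set: `gene_set`, `p_value`,
#'   `fdr`, `bootstrap_pct`, `set_size`, `overlap_case`,
#'   `overlap_control`, `odds_ratio`, `case_genes`, `control_genes`,
#'   `significant`; ordered by p value.
#' @export
run_enrichment <- function(survivors, sets, donors,
                           mode = c("hypothesis_driven", "hypothesis_free"),
                           size_range = c(100, 1000), B = 1000,
                           alpha = 0.05, seed = 1,
                           alternative = "two.sided") {
  mode <- match.arg(mode)
  if (nrow(survivors) == 0 || all(is.na(survivors$gene)) ||
      all(!nzchar(survivors$gene))) {
    stop("survivors carry no gene annotations", call. = FALSE)
  }
  set_list <- sets$sets
  if (mode == "hypothesis_free") {
    sizes <- lengths(set_list)
    set_list <- set_list[sizes >= size_range[1] & sizes <= size_range[2]]
  }
  if (length(set_list) == 0) {
    stop("no gene sets retained for testing", call. = FALSE)
  }
  case_genes_all <- unique(survivors$gene[
    survivors$donor_id %in% donors$donor_id[donors$diagnosis == "case"]])
  ctrl_genes_all <- unique(survivors$gene[
    survivors$donor_id %in% donors$donor_id[donors$diagnosis == "control"]])
  rows <- lapply(names(set_list), function(nm) {
    gs <- set_list[[nm]]
    cnt <- per_individual_set_counts(survivors, gs, donors)
    p <- wilcoxon_rank_sum(cnt$cases, cnt$controls,
                           alternative = alternative)$p
    cg <- intersect(case_genes_all, gs)
    kg <- intersect(ctrl_genes_all, gs)
    or <- haldane_anscombe_or(length(cg),
                              length(case_genes_all) - length(cg),
                              length(kg),
                              length(ctrl_genes_all) - length(kg))
    data.frame(gene_set = nm, p_value = p, set_size = length(gs),
               overlap_case = length(cg), overlap_control = length(kg),
               odds_ratio = or,
               case_genes = paste(sort(cg), collapse = ";"),
               control_genes = paste(sort(kg), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$bootstrap_pct <- vapply(names(set_list), function(nm) {
    cnt <- per_individual_set_counts(survivors, set_list[[nm]], donors)
    bootstrap_success(cnt$cases, cnt$controls, B = B, alpha = alpha,
                      seed = seed + str_hash(nm) %% 100000L,
                      alternative = alternative)
  }, numeric(1))
  out$significant <- out$fdr <= 0.1 & out$bootstrap_pct > 99
  out <- out[order(out$p_value, -out$overlap_case),
             c("gene_set", "p_value", "fdr", "bootstrap_pct", "set_size",
               "overlap_case", "overlap_control", "odds_ratio",
               "case_genes", "control_genes", "significant")]
  rownames(out) <- NULL
  out
}
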