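#' Build the per-specimen mutational burden table
#'
#' One row per included (non-reference, non-excluded) brain specimen with
#' the donor's covariates and two counts: all surviving sSNVs and the
#' non-synonymous + loss-of-function subset.
#'
#' @param survivors data.frame of surviving candidates with
#'   `specimen_id` and `functional_class` columns.
#' @param specimens,donors cohort tables from [read_sample_sheet()].
#' @return data.frame with `specimen_id`, `donor_id`, `diagnosis`,
#'   `cell_type`, `sex`, ancestry columns, `count_all`, `count_ns_lof`.
#' @export
build_burden_table <- function(survivors, specimens, donors) {
  inc <- specimens[!specimens$excluded & specimens$tissue != "reference", ,
                   drop = FALSE]
  unknown <- setdiff(survivors$specimen_id, specimens$specimen_id)
  if (length(unknown) > 0) {
    stop("survivor references specimen(s) absent from the sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ns_lof <- c("exonic_nonsynonymous", "exonic_lof")
  tab <- data.frame(
    specimen_id = inc$specimen_id,
    donor_id = inc$donor_id,
    cell_type = inc$tissue,
    count_all = vapply(inc$specimen_id, function(s) {
      sum(survivors$specimen_id == s)
    }, integer(1)),
    count_ns_lof = vapply(inc$specimen_id, function(s) {
      sum(survivors$specimen_id == s &
            survivors$functional_class %in% ns_lof)
    }, integer(1)),
    stringsAsFactors = FALSE)
  di <- match(tab$donor_id, donors$donor_id)
  if (anyNA(di)) {
    stop("specimen with donor absent from donor table", call. = FALSE)
  }
  tab$diagnosis <- donors$diagnosis[di]
  tab$sex <- donors$sex[di]
  for (ac in grep("^ancestry", names(donors), value = TRUE)) {
    tab[[ac]] <- donors[[ac]][di]
  }
  rownames(tab) <- NULL
  tab
}

#' Group burden rate: variants per donor
#'
#' Total surviving variant count in a diagnosis group divided by the
#' number of donors in that group (donors with zero variants count in the
#' denominator).
#'
#' @param burden_table table from [build_burden_table()].
#' @param donors donor table (supplies the denominator).
#' @param group `"case"` or `"control"`.
#' @param class_filter `"all"` or `"ns_lof"`.
#' @return variants-per-donor rate (numeric scalar).
#' @export
group_rate <- function(burden_table, donors, group = c("case", "control"),
                       class_filter = c("all", "ns_lof")) {
  group <- match.arg(group)
  class_filter <- match.arg(class_filter)
  n_donors <- sum(donors$diagnosis == group)
  if (n_donors == 0) stop("no donors in group ", group, call. = FALSE)
  col <- if (class_filter == "all") "count_all" else "count_ns_lof"
  sum(burden_table[[col]][burden_table$diagnosis == group]) / n_donors
}

#' Case/control mutational-burden mixed model
#'
#' Models the per-specimen count with fixed effects for diagnosis, cell
#' type, their interaction, sex and any ancestry covariates, and a random
#' intercept per donor; fit by REML with Satterthwaite t tests (see
#' [fit_lmm()]). Unbalanced data (donors with a single included brain
#' specimen) are handled by simply omitting the missing rows. A Poisson
#' generalised mixed model is available behind `family = "poisson"`
#' (delegated to `lme4::glmer`, Wald z tests); the Gaussian fit on
#' untransformed counts is the default.
#'
#' @param burden_table table from [build_burden_table()].
#' @param response `"count_all"` or `"count_ns_lof"`.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return `mosaic_lmm` object (Gaussian) or a coefficient table
#'   (Poisson).
#' @export
fit_burden_lmm <- function(burden_table, response = c("count_all",
                                                      "count_ns_lof"),
                           family = c("gaussian", "poisson")) {
  response <- match.arg(response)
  family <- match.arg(family)
  tab <- burden_table
  for (g in c("case", "control")) {
    if (length(unique(tab$donor_id[tab$diagnosis == g])) < 2) {
      stop("need at least two donors per diagnosis group", call. = FALSE)
    }
  }
  tab$diagnosis <- factor(tab$diagnosis, levels = c("control", "case"))
  tab$cell_type <- factor(tab$cell_type,
                          levels = c("neuronal", "non_neuronal"))
  rhs <- "diagnosis * cell_type"
  if (length(unique(tab$sex[!is.na(tab$sex)])) > 1) {
    tab$sex <- factor(tab$sex)
    rhs <- paste(rhs, "+ sex")
  }
  anc <- grep("^ancestry", names(tab), value = TRUE)
  anc <- anc[vapply(anc, function(a) !anyNA(tab[[a]]), logical(1))]
  if (length(anc) > 0) rhs <- paste(rhs, "+", paste(anc, collapse = " + "))
  form <- stats::as.formula(paste(response, "~", rhs))
  if (family == "poisson") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("the Poisson variant requires the lme4 package", call. = FALSE)
    }
    gform <- stats::as.formula(paste(response, "~", rhs, "+ (1 | donor_id)"))
    fit <- lme4::glmer(gform, data = tab, family = stats::poisson())
    sm <- summary(fit)$coefficients
    return(data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL))
  }
  X <- stats::model.matrix(form, tab)
  fit_lmm(tab[[response]], X, tab$donor_id)
}

#' Welch t-test of allele fractions between case and control variants
#'
#' @param vaf numeric allele fractions, one per surviving variant.
#' @param diagnosis matching `"case"`/`"control"` labels.
#' @return list with `t`, `p`, `mean_case`, `mean_control`.
#' @export
vaf_group_test <- function(vaf, diagnosis) {
  x <- vaf[diagnosis == "case"]
  y <- vaf[diagnosis == "control"]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two allele fractions per group", call. = FALSE)
  }
  if (stats::var(x) + stats::var(y) < .Machine$double.eps) {
    # both groups constant: degenerate Welch limit
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (same) 0 else Inf * sign(mean(x) - mean(y)),
                p = if (same) 1 else 0,
                mean_case = mean(x), mean_control = mean(y)))
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_case = mean(x), mean_control = mean(y))
}

#' Mean and range of variant allele fractions
#' @param vaf numeric allele fractions (non-empty).
#' @return list with `mean`, `min`, `max` (fractions).
#' @export
summarize_vaf <- function(vaf) {
  if (length(vaf) == 0) stop("no allele fractions supplied", call. = FALSE)
  list(mean = mean(vaf), min = min(vaf), max = max(vaf))
}
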