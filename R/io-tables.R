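#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty sets are rejected.
#'
#' @param path GMT file.
#' @param source either `"hypothesis_driven"` or `"hypothesis_free"`,
#'   attached as per-collection metadata.
#' @return list with `sets` (named list of character vectors) and `source`.
#' @export
read_gene_sets <- function(path,
                           source = c("hypothesis_driven", "hypothesis_free")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line with no genes: ", substr(ln, 1, 40), call. = FALSE)
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop("empty gene set: ", parts[1], call. = FALSE)
    }
    sets[[parts[1]]] <- genes
  }
  list(sets = sets, source = source)
}

#' Write gene sets to a GMT file
#' @param collection list as returned by [read_gene_sets()].
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read capture-target intervals from a BED3 file
#'
#' Intervals are 0-based half-open as in the BED convention; conversion to
#' 1-based variant coordinates happens only where distances to targets are
#' computed. Chromosome names are canonicalised (any `chr` prefix removed).
#'
#' @param path BED file (first three columns used).
#' @return data.frame `chrom`, `start`, `end`, sorted, with `end > start`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  validate_targets(df)
}

validate_targets <- function(df) {
  df$chrom <- canonical_chrom(df$chrom)
  if (any(df$start < 0)) stop("negative BED start", call. = FALSE)
  if (any(df$end <= df$start)) {
    stop("BED interval with end <= start", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

write_targets <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 96-channel reference signature catalog
#'
#' Expects a TSV whose first column holds the 96 channel labels in the
#' canonical order of [sbs_channels()] and whose remaining columns are
#' reference signatures. Every signature column must sum to one.
#'
#' @param path TSV file.
#' @return numeric 96 x S matrix, channels as rownames.
#' @export
read_signature_catalog <- function(path) {
  df <- read_tsv_checked(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_signature_catalog(m)
}

validate_signature_catalog <- function(m) {
  if (nrow(m) != 96) {
    stop("signature catalog must have exactly 96 rows, got ", nrow(m),
         call. = FALSE)
  }
  if (!identical(rownames(m), sbs_channels())) {
    stop("catalog channel labels are not in canonical order", call. = FALSE)
  }
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("catalog column(s) do not sum to 1: ",
         paste(colnames(m)[abs(cs - 1) > 1e-9], collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Read the per-site cross-tissue metrics table
#'
#' One row per (donor, site): depth, alt reads, mapping and base quality
#' for each of the three tissues, plus the number of distinct alleles
#' observed in each brain specimen. This is how read-level evidence enters
#' the pipeline (no BAM pileups are computed here).
#'
#' @param path TSV file.
#' @return data.frame keyed by `donor_id`, `chrom`, `pos`.
#' @export
read_site_metrics <- function(path) {
  need <- c("donor_id", "chrom", "pos",
            as.vector(outer(c("depth", "alt", "mq", "bq"),
                            c("neuronal", "non_neuronal", "reference"),
                            paste, sep = "_")),
            "n_alleles_neuronal", "n_alleles_non_neuronal")
  df <- read_tsv_checked(path, required = need)
  df$chrom <- canonical_chrom(df$chrom)
  df
}

#' Read the variant annotation table
#'
#' Keyed by (chrom, pos, ref, alt); carries gene symbol, functional class,
#' trinucleotide context and population allele frequency. A missing
#' population frequency is treated as 0 (absent from the population
#' database = novel).
#'
#' @param path TSV file.
#' @return data.frame with canonical chromosome names and numeric `pop_af`.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, required = c("chrom", "pos", "ref", "alt",
                                            "gene", "functional_class",
                                            "context", "pop_af"))
  df$chrom <- canonical_chrom(df$chrom)
  df$pop_af <- as.numeric(df$pop_af)
  df$pop_af[is.na(df$pop_af)] <- 0
  bad <- !df$functional_class %in% functional_classes()
  if (any(bad)) {
    stop("unknown functional class: ",
         paste(unique(df$functional_class[bad]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Functional consequence classes used throughout the pipeline
#' @return character vector of valid class tokens.
#' @export
functional_classes <- function() {
  c("intronic", "utr3", "utr5", "exonic_synonymous",
    "exonic_nonsynonymous", "exonic_lof", "other")
}

# map printed consequence strings to class tokens
map_printed_class <- function(x) {
  key <- c("Intronic" = "intronic",
           "UTR3" = "utr3",
           "UTR5" = "utr5",
           "Exonic (synonymous)" = "exonic_synonymous",
           "Exonic (non-synonymous)" = "exonic_nonsynonymous",
           "Exonic (loss-of-function)" = "exonic_lof")
  out <- unname(key[x])
  if (any(is.na(out))) {
    stop("unknown printed consequence: ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Load the packaged final sSNV call-set fixture
#'
#' The published final call set of 32 sSNVs (case and control donors, both
#' brain cell types) shipped as a plain TSV, with variant keys, read
#' counts, allele fractions, consequence classes and gene symbols.
#'
#' @return data.frame with one row per sSNV; parsed coordinate columns,
#'   `vaf` as a fraction, `functional_class` tokens, and `diagnosis` in
#'   `case`/`control` form.
#' @export
read_final_callset <- function() {
  path <- system.file("extdata", "published_ssnv_callset.tsv", package = "mosaicscan")
  df <- read_tsv_checked(path, required = c("ssnv", "sample_id", "diagnosis",
                                            "cell_type", "gnomad_af",
                                            "n_reads", "vaf_pct", "type",
                                            "gene"))
  key <- parse_variant_key(df$ssnv)
  out <- data.frame(
    chrom = key$chrom, pos = key$pos, ref = key$ref, alt = key$alt,
    donor_id = df$sample_id,
    specimen_id = paste(df$sample_id,
                        normalize_tissue(df$cell_type, df$sample_id),
                        sep = "_"),
    tissue = normalize_tissue(df$cell_type, df$sample_id),
    diagnosis = normalize_diagnosis(df$diagnosis, df$sample_id),
    pop_af = as.numeric(df$gnomad_af),
    depth = as.integer(df$n_reads),
    vaf = as.numeric(df$vaf_pct) / 100,
    functional_class = map_printed_class(df$type),
    gene = df$gene,
    stringsAsFactors = FALSE)
  out$alt_reads <- as.integer(round(out$depth * out$vaf))
  out
}

#' Load the packaged cohort roster behind the final call set
#'
#' Donor ids with diagnosis for the analysis cohort (9 cases, 10
#' controls). The roster is reconstructed from the published cohort counts
#' (sex/ancestry are not public and are set to `unknown`); it supplies the
#' per-group denominators for burden rates.
#'
#' @return data.frame `donor_id`, `diagnosis`, `sex`.
#' @export
read_final_cohort <- function() {
  path <- system.file("extdata", "published_cohort.tsv", package = "mosaicscan")
  df <- read_tsv_checked(path, required = c("donor_id", "diagnosis", "sex"))
  df$diagnosis <- normalize_diagnosis(df$diagnosis, df$donor_id)
  df
}

#' Load the packaged hypothesis-driven enrichment table fixture
#'
#' The published hypothesis-driven gene-set enrichment results (8 sets):
#' raw p, FDR, bootstrap success, set size, per-cohort overlaps, odds
#' ratio and the overlapping case genes.
#'
#' @return data.frame, one row per gene set.
#' @export
read_enrichment_table <- function() {
  path <- system.file("extdata", "published_enrichment.tsv",
                      package = "mosaicscan")
  read_tsv_checked(path, required = c("gene_set", "p_value", "fdr",
                                      "bootstrap_pct", "set_size",
                                      "overlap_case", "overlap_control",
                                      "odds_ratio", "case_genes"))
}
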