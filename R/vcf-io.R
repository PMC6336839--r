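#' Read one caller's candidate somatic calls from a VCF
#'
#' Consumes tumor/normal-style caller output (one genotyped sample per
#' file). Per-site depth and alternate-read counts are taken from the
#' `AD` FORMAT field (total depth = sum over allele depths, matching how
#' allele fractions are normally recomputed from printed read counts).
#' Multi-allelic records are split into one candidate per ALT allele;
#' indel records are retained but flagged `is_snv = FALSE` so the QC
#' cascade can reject them explicitly.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @param caller_name label recorded in the `caller` column.
#' @param specimen_id specimen the calls belong to.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `specimen_id`, `caller`, `depth`, `alt_reads`, `vaf`, `is_snv`.
#' @export
read_caller_vcf <- function(path, caller_name, specimen_id) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF ", basename(path),
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), specimen_id = character(),
                      caller = character(), depth = integer(),
                      alt_reads = integer(), vaf = numeric(),
                      is_snv = logical(), stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0) return(empty)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    stop("VCF ", basename(path), " has no genotyped sample (need AD field)",
         call. = FALSE)
  }
  fmt <- strsplit(gt[, 1], ":")
  smp <- strsplit(gt[, 2], ":")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    ad_idx <- match("AD", fmt[[i]])
    if (is.na(ad_idx) || ad_idx > length(smp[[i]])) {
      stop("record ", fix$CHROM[i], ":", fix$POS[i], " in ", basename(path),
           " lacks the AD depth field", call. = FALSE)
    }
    ad <- suppressWarnings(as.integer(strsplit(smp[[i]][ad_idx], ",")[[1]]))
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    if (any(is.na(ad)) || length(ad) < 1 + length(alts)) {
      stop("unparsable AD field at ", fix$CHROM[i], ":", fix$POS[i],
           call. = FALSE)
    }
    depth <- sum(ad)
    data.frame(chrom = canonical_chrom(fix$CHROM[i]),
               pos = as.integer(fix$POS[i]),
               ref = fix$REF[i],
               alt = alts,
               specimen_id = specimen_id,
               caller = caller_name,
               depth = depth,
               alt_reads = ad[seq_along(alts) + 1L],
               vaf = if (depth > 0) ad[seq_along(alts) + 1L] / depth else 0,
               is_snv = nchar(fix$REF[i]) == 1L & nchar(alts) == 1L &
                 alts %in% c("A", "C", "G", "T"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write candidate calls as a minimal VCF 4.2 file
#'
#' Inverse of [read_caller_vcf()] at the field level: site, alleles, total
#' depth and alternate-read count survive a write/read round trip.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_reads` columns.
#' @param path output path.
#' @param sample_name sample column name in the VCF.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, sample_name = "SOMATIC") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    ad <- paste(calls$depth - calls$alt_reads, calls$alt_reads, sep = ",")
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", ".", "GT:AD:DP",
                  paste("0/1", ad, calls$depth, sep = ":"), sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
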