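#' Canonical 96-channel trinucleotide substitution labels
#'
#' Channels follow the standard pyrimidine-centric ordering used by COSMIC
#' signature matrices: six substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G), each expanded over the 16 flanking-base pairs with the 5' base
#' varying slowest and bases ordered A < C < G < T. Labels look like
#' `"A[C>T]G"`.
#'
#' @return Character vector of length 96 in canonical order.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(classes, function(cl) {
    as.vector(t(outer(bases, bases,
                      function(f, t) paste0(f, "[", cl, "]", t))))
  }))
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T).
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
#' (C<->T) exchanges; all other substitutions are transversions.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classify_substitution("C", "T")   # transition
#' classify_substitution("C", "G")   # transversion
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok)) stop("invalid base(s) in substitution", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt bases must differ", call. = FALSE)
  ifelse((ref %in% c("A", "G") & alt %in% c("A", "G")) |
         (ref %in% c("C", "T") & alt %in% c("C", "T")),
         "transition", "transversion")
}

#' Map a substitution and its trinucleotide context to a channel
#'
#' Canonicalises to the pyrimidine strand: when the reference base is a
#' purine, the reference, alternate and context are reverse-complemented
#' before lookup, so a `G>A` at `TGT` and a `C>T` at `ACA` land on the same
#' channel.
#'
#' @param ref,alt single bases; `ref` must equal the middle base of
#'   `context`.
#' @param context 3-base string around the variant (5' base, ref, 3' base).
#' @return integer channel index in `1:96` named with the channel label
#'   (see [sbs_channels()]).
#' @export
#' @examples
#' context_channel("C", "T", "ACA")
#' context_channel("G", "A", "TGT")  # same channel by strand symmetry
context_channel <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  n <- max(length(ref), length(alt), length(context))
  if (n == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); context <- rep_len(context, n)
  if (any(nchar(context) != 3L)) {
    stop("context must be a 3-base string", call. = FALSE)
  }
  if (any(substr(context, 2, 2) != ref)) {
    stop("context middle base does not match the reference base",
         call. = FALSE)
  }
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  cls <- match(paste0(ref, ">", alt), classes)
  if (any(is.na(cls))) stop("invalid substitution", call. = FALSE)
  i5 <- match(substr(context, 1, 1), bases)
  i3 <- match(substr(context, 3, 3), bases)
  if (any(is.na(i5) | is.na(i3))) stop("invalid context base", call. = FALSE)
  idx <- (cls - 1L) * 16L + (i5 - 1L) * 4L + i3
  names(idx) <- sbs_channels()[idx]
  idx
}

#' Ratio of transitions to transversions
#'
#' @param ref,alt vectors of single-base reference/alternate alleles.
#' @return A list with counts `n_ti`, `n_tv` and `ratio`
#'   (`Inf` with `infinite = TRUE` when no transversion is present).
#' @export
#' @examples
#' titv_ratio(c("C", "C", "G"), c("T", "A", "A"))
titv_ratio <- function(ref, alt) {
  if (length(ref) == 0) stop("no variants supplied", call. = FALSE)
  cls <- classify_substitution(ref, alt)
  n_ti <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  list(n_ti = n_ti, n_tv = n_tv,
       ratio = if (n_tv == 0) Inf else n_ti / n_tv,
       infinite = n_tv == 0)
}

#' Tally variants into a 96-channel context matrix
#'
#' @param ref,alt,context per-variant substitution and trinucleotide
#'   context (see [context_channel()]).
#' @param group grouping label per variant (e.g. diagnosis); one matrix
#'   column per group.
#' @return 96 x G integer matrix with canonical channel rownames; column
#'   sums equal the number of contributing variants per group.
#' @export
context_matrix <- function(ref, alt, context, group) {
  idx <- context_channel(ref, alt, context)
  group <- as.factor(group)
  m <- vapply(levels(group), function(g) {
    tabulate(idx[group == g], nbins = 96L)
  }, integer(96))
  m <- matrix(m, nrow = 96, dimnames = list(sbs_channels(), levels(group)))
  storage.mode(m) <- "integer"
  m
}
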