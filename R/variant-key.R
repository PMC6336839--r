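#' Parse a compact variant key
#'
#' Variant keys use the layout `chrom:pos|REF>ALT`, e.g.
#' `"9:130263483|C>T"`. Positions are 1-based.
#'
#' @param key character vector of keys.
#' @return data.frame with columns `chrom`, `pos` (integer), `ref`, `alt`.
#' @export
#' @examples
#' parse_variant_key("9:130263483|C>T")
parse_variant_key <- function(key) {
  pat <- "^([0-9XYMT]+|[A-Za-z0-9_.]+):([0-9]+)\\|([ACGT])>([ACGT])$"
  ok <- grepl(pat, key)
  if (any(!ok)) {
    stop("malformed variant key: ", paste(key[!ok], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    chrom = sub(pat, "\\1", key),
    pos = as.integer(sub(pat, "\\2", key)),
    ref = sub(pat, "\\3", key),
    alt = sub(pat, "\\4", key),
    stringsAsFactors = FALSE
  )
}

#' Format variants as compact keys
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return character vector `chrom:pos|REF>ALT`.
#' @export
format_variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, "|", ref, ">", alt)
}
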