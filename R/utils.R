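# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# stable 32-bit hash of a string; used to derive per-specimen RNG sub-streams
# so simulation output does not depend on iteration order
str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647L
  as.integer(h)
}

# read a TSV with strict column checking
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# strip "chr" prefixes so mixed chromosome dialects compare equal
canonical_chrom <- function(chrom) sub("^chr", "", as.character(chrom))
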