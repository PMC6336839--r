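#' Read and validate a cohort sample sheet
#'
#' The sample sheet is a TSV with one row per specimen and required columns
#' `donor_id`, `diagnosis`, `sex`, `tissue`, `specimen_id`. Any columns
#' whose names start with `ancestry` are carried as numeric ancestry
#' covariates. Each donor contributes at most one specimen per tissue
#' (neuronal, non-neuronal brain, and a non-brain reference).
#'
#' @param path path to the TSV sample sheet.
#' @return A list with two data.frames:
#'   * `donors`: `donor_id`, `diagnosis` (`case`/`control`), `sex`,
#'     plus ancestry covariate columns;
#'   * `specimens`: `specimen_id`, `donor_id`, `tissue`
#'     (`neuronal`/`non_neuronal`/`reference`), `excluded`, `exclude_reason`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, required = c("donor_id", "diagnosis", "sex",
                                            "tissue", "specimen_id"))
  if (nrow(df) == 0) {
    return(list(
      donors = data.frame(donor_id = character(), diagnosis = character(),
                          sex = character(), stringsAsFactors = FALSE),
      specimens = data.frame(specimen_id = character(), donor_id = character(),
                             tissue = character(), excluded = logical(),
                             exclude_reason = character(),
                             stringsAsFactors = FALSE)))
  }
  diagnosis <- normalize_diagnosis(df$diagnosis, df$donor_id)
  tissue <- normalize_tissue(df$tissue, df$specimen_id)
  sex <- tolower(df$sex)
  bad_sex <- !sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop("unknown sex token in row(s): ",
         paste(which(bad_sex), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste(df$donor_id, tissue))
  if (any(dup)) {
    stop("duplicate donor/tissue pair(s): ",
         paste(unique(paste(df$donor_id[dup], tissue[dup])), collapse = "; "),
         call. = FALSE)
  }
  if (anyDuplicated(df$specimen_id)) {
    stop("duplicate specimen_id in sample sheet", call. = FALSE)
  }
  anc_cols <- grep("^ancestry", names(df), value = TRUE)
  donors <- unique(data.frame(donor_id = df$donor_id, diagnosis = diagnosis,
                              sex = sex, stringsAsFactors = FALSE))
  if (anyDuplicated(donors$donor_id)) {
    stop("inconsistent diagnosis/sex across specimens of one donor",
         call. = FALSE)
  }
  for (ac in anc_cols) {
    v <- tapply(as.numeric(df[[ac]]), df$donor_id, function(x) x[1])
    donors[[ac]] <- as.numeric(v[donors$donor_id])
  }
  specimens <- data.frame(specimen_id = df$specimen_id,
                          donor_id = df$donor_id,
                          tissue = tissue,
                          excluded = FALSE,
                          exclude_reason = "",
                          stringsAsFactors = FALSE)
  list(donors = donors, specimens = specimens)
}

normalize_diagnosis <- function(x, label) {
  out <- tolower(x)
  out[out %in% c("case", "scz", "affected")] <- "case"
  out[out %in% c("control", "ctrl")] <- "control"
  bad <- !out %in% c("case", "control")
  if (any(bad)) {
    stop("unknown diagnosis token '", x[bad][1], "' for ", label[bad][1],
         call. = FALSE)
  }
  out
}

normalize_tissue <- function(x, label) {
  out <- tolower(gsub("[ -]", "_", x))
  out[out %in% c("neuronal", "neun+", "neuron")] <- "neuronal"
  out[out %in% c("non_neuronal", "neun_", "non_neuron")] <- "non_neuronal"
  out[out %in% c("reference", "muscle", "temporal_muscle")] <- "reference"
  bad <- !out %in% c("neuronal", "non_neuronal", "reference")
  if (any(bad)) {
    stop("unknown tissue token '", x[bad][1], "' for ", label[bad][1],
         call. = FALSE)
  }
  out
}

#' Mark specimens as excluded
#' @param specimens specimen data.frame from [read_sample_sheet()].
#' @param specimen_ids ids to exclude.
#' @param reason free-text reason recorded alongside the flag.
#' @return updated specimen data.frame.
#' @export
exclude_specimens <- function(specimens, specimen_ids, reason) {
  hit <- specimens$specimen_id %in% specimen_ids
  specimens$excluded[hit] <- TRUE
  specimens$exclude_reason[hit] <- reason
  specimens
}
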