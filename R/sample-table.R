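#' Sample annotation table
#'
#' Per-sample annotations used throughout the pipeline. Mandatory columns are
#' `sample_id` and `tissue_class` (`"tumor"` or `"normal"`); the optional
#' columns `cohort`, `cluster`, `group` (`"NL"`/`"OT"`), `grade`
#' (`"G2"`/`"G3"`/`"G4"`), `histology`, `survival_months` and `event` are
#' populated when present. Any further columns are kept as free categorical
#' covariates. Empty strings and `"Unknown"` are mapped to `NA` (unset).
#'
#' @param df a data frame with at least `sample_id` and `tissue_class`.
#' @return a validated data frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "tissue_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("tissue_class", "cohort", "cluster", "group",
                          "grade", "histology"), names(df))) {
    v <- as.character(df[[col]])
    v[v == "" | v == "Unknown" | v == "NA"] <- NA_character_
    df[[col]] <- v
  }
  if (!all(df$tissue_class %in% c("tumor", "normal"))) {
    stop("tissue_class must be 'tumor' or 'normal'", call. = FALSE)
  }
  if ("group" %in% names(df) &&
      !all(is.na(df$group) | df$group %in% c("NL", "OT"))) {
    stop("group must be 'NL' or 'OT' when assigned", call. = FALSE)
  }
  if ("grade" %in% names(df) &&
      !all(is.na(df$grade) | df$grade %in% c("G2", "G3", "G4"))) {
    stop("grade must be one of G2, G3, G4", call. = FALSE)
  }
  if ("survival_months" %in% names(df)) {
    df$survival_months <- as.numeric(df$survival_months)
    if (!"event" %in% names(df)) {
      stop("survival_months present without an event column", call. = FALSE)
    }
    if (any(df$survival_months < 0, na.rm = TRUE)) {
      stop("survival_months must be non-negative", call. = FALSE)
    }
  }
  if ("event" %in% names(df)) {
    df$event <- as.integer(df$event)
    if (!all(is.na(df$event) | df$event %in% 0:1)) {
      stop("event must be 0 or 1", call. = FALSE)
    }
    if ("survival_months" %in% names(df) &&
        any(!is.na(df$survival_months) & is.na(df$event))) {
      stop("event must be present whenever survival_months is present",
           call. = FALSE)
    }
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample annotation table from tab-separated text
#'
#' @param path file path to a TSV with columns named as in [sample_table()].
#' @return a `sample_table` data frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_table(df)
}

#' Write a sample annotation table as tab-separated text
#'
#' @param x a `sample_table` (or plain data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
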