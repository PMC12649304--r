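.arm_cols <- c("study_id", "arm_id", "drug_id", "dose_ug", "ee_dose_ug",
               "endpoint", "observed", "n_subjects", "cavg_ng_ml")

#' Read and validate a trial-arm table
#'
#' Comma-separated, UTF-8, "." decimal, header required and case-sensitive.
#' Columns: `study_id`, `arm_id`, `drug_id`, `dose_ug`, `ee_dose_ug`,
#' `endpoint` (PI or OR), `observed`, `n_subjects`, `cavg_ng_ml`. All
#' offending rows are listed in the validation error.
#'
#' @param path CSV path.
#' @return Validated trial-arm data frame.
#' @export
read_arms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.arm_cols, names(tab))
  if (length(missing))
    stop("arms table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("arms table is empty")
    return(tab[, .arm_cols])
  }
  bad <- character(0)
  chk <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) bad <<- c(bad, paste0("row ", rows, ": ", msg))
  }
  chk(!tab$endpoint %in% c("PI", "OR"), "endpoint must be PI or OR")
  chk(!is.finite(tab$n_subjects) | tab$n_subjects < 1, "n_subjects must be >= 1")
  chk(!is.finite(tab$observed), "observed must be numeric")
  chk(!is.finite(tab$cavg_ng_ml) | tab$cavg_ng_ml <= 0,
      "cavg_ng_ml must be > 0")
  if (length(bad))
    stop("invalid arms table:\n", paste(bad, collapse = "\n"))
  tab[, .arm_cols]
}

#' @rdname read_arms
#' @param arms Trial-arm data frame.
#' @export
write_arms <- function(arms, path) {
  write.csv(arms[, .arm_cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Plain CSV writer with stable column order and no row names, used for the
#' DDI summary and simulated-pair outputs.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @export
write_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
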