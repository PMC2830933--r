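record_columns <- c("record_id", "sire_id", "mgs_id", "herd_year_id",
                    "sex", "age_class", "year_season",
                    "gl_days", "cd_score", "sb_score")

# validate a record table; returns it with integer-typed score columns
validate_records <- function(records, C_cd = 3L, gl_window = c(240L, 310L),
                             check_window = FALSE) {
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) stop("no records")
  bad_row <- function(ok, what) {
    if (!all(ok))
      stop(what, " in row(s) ", paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  gl <- records$gl_days
  bad_row(is.finite(gl) & gl == round(gl), "non-integer or missing gl_days")
  if (check_window)
    bad_row(gl >= gl_window[1] & gl <= gl_window[2],
            "gl_days outside the plausible window")
  cd <- records$cd_score
  bad_row(!is.na(cd) & cd %in% seq_len(C_cd),
          paste0("cd_score outside 1..", C_cd))
  sb <- records$sb_score
  bad_row(!is.na(sb) & sb %in% c(1L, 2L), "sb_score outside {1, 2}")
  for (col in c("sex", "age_class", "year_season"))
    bad_row(!is.na(records[[col]]), paste("missing", col))
  records$gl_days <- as.integer(gl)
  records$cd_score <- as.integer(cd)
  records$sb_score <- as.integer(sb)
  records
}

#' Read calving records from CSV
#'
#' Reads and validates a record table with the documented header
#' (\code{record_id, sire_id, mgs_id, herd_year_id, sex, age_class,
#' year_season, gl_days, cd_score, sb_score}). Validation errors name the
#' offending rows.
#'
#' @param path CSV file path.
#' @param C_cd number of calving-difficulty categories.
#' @return data.frame of validated records, row order preserved.
#' @export
read_records <- function(path, C_cd = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stop("empty input: ", path)
  validate_records(records, C_cd = C_cd)
}

#' Write calving records to CSV
#'
#' @param records record data.frame.
#' @param path output CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records[, intersect(record_columns, names(records))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
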