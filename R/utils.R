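#' @importFrom data.table as.data.table data.table setkey setkeyv setorder
#'   setorderv fread fwrite rbindlist setnames copy uniqueN year :=
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "person_id", "concept_id", "concept_name",
  "domain", "event_date", "unit_id", "window_start", "window_end",
  "gender", "birth_year", "e1", "e2", "n_pair", "gap", "index_date",
  "i.event_date", "i.index_date", "x.j", "i.rid", "rid", "j", "ps",
  "iy", "bin", "d2", "n_units", "n_patients", "trajectory",
  "i.unit_id", "cohort_start_date", "cohort_end_date", "N", "d1",
  "entry_date", "exit_date", "k", "x.unit_id", "i.person_id",
  "i.concept_id", "i.concept_name", "i.domain", "ref", "y",
  "age_bin", "index_year", "age_at_index", "pad_", "priorN", "n"
))

ctLog <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[ClinicalTrajectories] ", ...)
  invisible(NULL)
}

#' Mask small counts for privacy
#'
#' Counts that are positive but below the privacy threshold are replaced by
#' the string `"<k"`; zero, `NA` and counts at or above the threshold are
#' printed as-is. Mirrors the convention of hiding event counts below a
#' minimum in published trajectory outputs.
#'
#' @param x numeric vector of counts.
#' @param k privacy threshold.
#' @return Character vector of the same length.
#' @examples maskCounts(c(0, 5, 19, 20, 120), 20)
#' @export
maskCounts <- function(x, k) {
  out <- as.character(x)
  hide <- !is.na(x) & x > 0 & x < k
  out[hide] <- paste0("<", k)
  out
}

# strict ISO date parsing; returns Date, collects failures
parseDateColumn <- function(x, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(trimws(as.character(x))))
  blank <- which(is.na(x) | !nzchar(trimws(as.character(x))))
  bad <- sort(unique(c(bad, blank)))
  if (length(bad)) {
    stop(sprintf("column '%s': %d unparseable date(s) at row(s) %s",
                 column, length(bad),
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  d
}

checkColumns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

attritionRow <- function(stage, nIn, nKept) {
  data.frame(stage = stage, n_in = as.integer(nIn),
             n_kept = as.integer(nKept),
             n_dropped = as.integer(nIn - nKept),
             stringsAsFactors = FALSE)
}

yearOf <- function(d) as.integer(format(d, "%Y"))
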