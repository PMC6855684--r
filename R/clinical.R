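#' Load a clinical table
#'
#' Reads a subject-level clinical CSV with the schema of the packaged study
#' table (`somatomap_table1()`): one row per subject with group membership
#' (`control`, `left-CRPS`, `right-CRPS`), age, gender, CRPS duration in
#' years (blank for controls), pain ratings on a 0-10 Likert scale (during
#' the scan, and averaged over the preceding 2 and 7 days), left/right-hand
#' pressure pain thresholds (PPT, kg/cm^2), the Edinburgh laterality score in
#' `[-100, 100]`, and an optional upper-limb disability score. Missing values
#' are blank cells and come back as `NA`.
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `clinical_table`, with `group` as a factor.
#' @export
load_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty clinical table: ", path)
  required <- c("id", "group", "age_yr", "gender", "crps_duration_yr",
                "pain_scan", "pain_2d", "pain_7d", "ppt_left", "ppt_right",
                "laterality")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  if (!"disability_score" %in% names(df)) df$disability_score <- NA_real_
  groups <- c("control", "left-CRPS", "right-CRPS")
  bad <- which(!df$group %in% groups)
  if (length(bad)) {
    stop("unknown group in rows ", paste(bad, collapse = ", "),
         " (expected control/left-CRPS/right-CRPS)")
  }
  df$group <- factor(df$group, levels = groups)
  check_range <- function(col, lo, hi, what) {
    x <- df[[col]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad)) {
      stop(what, " out of range [", lo, ", ", hi, "] in rows: ",
           paste(bad, collapse = ", "))
    }
  }
  check_range("pain_scan", 0, 10, "pain_scan Likert rating")
  check_range("pain_2d", 0, 10, "pain_2d Likert rating")
  check_range("pain_7d", 0, 10, "pain_7d Likert rating")
  check_range("laterality", -100, 100, "laterality score")
  for (col in c("ppt_left", "ppt_right")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) stop(col, " must be > 0; offending rows: ",
                          paste(bad, collapse = ", "))
  }
  is_pat <- df$group != "control"
  bad <- which(is_pat & (is.na(df$crps_duration_yr) | df$crps_duration_yr < 0))
  if (length(bad)) stop("patients need nonnegative crps_duration_yr; rows: ",
                        paste(bad, collapse = ", "))
  bad <- which(!is_pat & !is.na(df$crps_duration_yr))
  if (length(bad)) stop("controls must have missing crps_duration_yr; rows: ",
                        paste(bad, collapse = ", "))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Packaged study clinical table
#'
#' Loads the demographic/clinical table shipped with the package: 17 healthy
#' controls, 8 patients with CRPS to the left hand and 10 with CRPS to the
#' right hand (35 subjects). Per-subject disability scores are not publicly
#' tabulated and are carried as missing.
#'
#' @return a `clinical_table` data frame with 35 rows.
#' @export
somatomap_table1 <- function() {
  load_clinical_table(system.file("extdata", "table1.csv",
                                  package = "somatomap", mustWork = TRUE))
}
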