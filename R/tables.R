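# Packaged per-night study tables.
#
# The package ships four plain-text fixtures transcribing the published
# per-night results of the pilot study the pipeline was developed on:
#   table2.csv - 14 in-clinic attended polysomnography studies (patient 2's
#                study failed: 0.00 h, all results missing; the row is kept
#                so cohort accounting matches the study flow chart);
#   table3.csv - 22 home study-nights with concurrent HSAT sensors;
#   table4.csv - 24 home study-nights with load cells only (no gold
#                standard; predictions only);
#   table5.csv - deployability / comfort survey response percentages.
# AHI cells printed as "<5" are censored: the study was graded normal and no
# numeric AHI is reported. They parse to NA with `*_censored = TRUE`.

.table_md5 <- c(
  table2.csv = "316168b07ba7236c6edd88c75152494f",
  table3.csv = "f532ee92ee2ee7d01276bd7c2cb37d5c",
  table4.csv = "6733186f9f073fcb7708e4eddb170e1c",
  table5.csv = "da69073d6579d9ffafa299828d269855"
)

parse_censored_ahi <- function(x) {
  x <- trimws(as.character(x))
  censored <- !is.na(x) & x == "<5"
  missing <- is.na(x) | x == "-" | x == ""
  value <- suppressWarnings(as.numeric(x))
  value[censored | missing] <- NA_real_
  if (any(!is.na(value) & value < 0))
    stop_lcosa("AHI values must be non-negative", "lcosa_data_error")
  list(value = value, censored = censored)
}

normalize_category <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("-", "")] <- NA
  out <- tolower(x)
  if (!all(is.na(out) | out %in% category_levels))
    stop_lcosa("unknown clinical category label", "lcosa_data_error")
  factor(out, levels = category_levels)
}

normalize_severity <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("-", "")] <- NA
  map <- c(normal = "normal", mild = "mild", moderate = "moderate_severe",
           severe = "moderate_severe", "moderate/severe" = "moderate_severe")
  out <- unname(map[tolower(x)])
  factor(out, levels = severity_levels)
}

#' Load the packaged per-night study tables
#'
#' Returns the transcribed study tables as tidy data frames with normalized
#' columns: `subject` (character), `night`, `setting`, `duration_h`,
#' `actual_category` / `predicted_category` (factors `normal`/`abnormal`),
#' `actual_ahi` / `predicted_ahi` (events/h; `NA` where censored or missing),
#' `predicted_censored` (logical, `TRUE` where the source prints `<5`), and
#' the printed severities collapsed to `normal` / `mild` / `moderate_severe`.
#' Printed severity appears once per patient in the home tables; rows without
#' a printed severity carry `NA` (per-night severity is derived from AHI by
#' [severity_from_ahi()] when scoring).
#'
#' File integrity is verified against packaged MD5 checksums.
#'
#' @return A list with data frames `clinic_psg`, `home_hsat`, `home_lc_only`
#'   and `survey`.
#' @export
#' @examples
#' tabs <- load_study_tables()
#' nrow(tabs$home_hsat)  # 22 study-nights
load_study_tables <- function() {
  dir <- system.file("extdata", package = "lcosa")
  files <- names(.table_md5)
  paths <- file.path(dir, files)
  if (!all(file.exists(paths)))
    stop_lcosa("packaged study tables are missing", "lcosa_packaging_error")
  sums <- tools::md5sum(paths)
  if (!all(sums == .table_md5))
    stop_lcosa("packaged study tables failed checksum verification",
               "lcosa_packaging_error")

  t2 <- read.csv(paths[1L], check.names = FALSE, colClasses = "character")
  t3 <- read.csv(paths[2L], check.names = FALSE, colClasses = "character")
  t4 <- read.csv(paths[3L], check.names = FALSE, colClasses = "character")
  t5 <- read.csv(paths[4L], check.names = FALSE)

  shape <- function(df, setting, night = NULL, duration = TRUE,
                    actual = TRUE) {
    pred <- parse_censored_ahi(df$predicted_ahi)
    out <- data.frame(
      subject = as.character(df$patient),
      night = if (is.null(night)) as.integer(df$night) else night,
      setting = setting,
      stringsAsFactors = FALSE
    )
    out$duration_h <- if (duration) as.numeric(ifelse(df$duration_h %in%
      c("-", ""), NA, df$duration_h)) else NA_real_
    if (actual) {
      act <- parse_censored_ahi(df$actual_ahi)
      out$actual_category <- normalize_category(df$actual_category)
      out$actual_ahi <- act$value
      out$actual_severity <- normalize_severity(df$actual_severity)
    }
    out$predicted_category <- normalize_category(df$predicted_category)
    out$predicted_ahi <- pred$value
    out$predicted_censored <- pred$censored
    out$predicted_severity <- normalize_severity(df$predicted_severity)
    out
  }

  list(
    clinic_psg = shape(t2, "clinic_psg", night = 1L),
    home_hsat = shape(t3, "home_hsat"),
    home_lc_only = shape(t4, "home_lc_only", duration = FALSE,
                         actual = FALSE),
    survey = t5
  )
}
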