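#' Published factor-detector q-values for the Yellow River Basin study
#'
#' The q-value table reported for the 50-city Yellow River Basin LAI
#' analysis (years 1980, 1990, 2000, 2010, 2019; fifteen drivers across the
#' natural, social, economic and policy dimensions), shipped as a worked
#' example for [dimension_average_q()]. The policy driver (GRGR) is missing
#' before 2000, when the Grain-for-Green program had not started; those
#' cells are `NA`, never zero.
#'
#' @return data.frame `year`, `factor`, `q`, `stars` (significance marks:
#'   `"**"` p < 0.01, `"*"` p < 0.05).
#' @export
published_q_table <- function() {
  path <- system.file("extdata", "q_values_published.csv", package = "vegdrivers",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c("integer", "character", "numeric", "character"))
  df$stars[is.na(df$stars)] <- ""
  df
}
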