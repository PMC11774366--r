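#' Published level summaries for the Queensland lung-cancer study geography
#'
#' Descriptive summary of the five-level Queensland statistical geography
#' and the simulated state-wide lung-cancer dataset commonly used to study
#' aggregation effects: the number of areas per level (mesh block through
#' SA4, after excluding zero-population areas), the published mean and
#' median cases per area, and the state-wide case total (20,700 over ten
#' years).  Shipped as a plain-text table; used for arithmetic consistency
#' checks (mean cases per area must equal the state total divided by the
#' area count) and as the scale template the synthetic scenario emulates.
#'
#' @return Data frame with columns `level`, `n_areas`, `mean_count`,
#'   `median_count`, `total_cases`.
#' @export
qld_level_summaries <- function() {
  utils::read.csv(system.file("extdata", "qld_levels.csv",
                              package = "maupbym"))
}
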