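# Packaged transcriptions of the published Hainan result tables.
#
# The underlying yearbook panel (15 cities/counties x 2016-2020) is not
# machine-readable anywhere, so the published result tables themselves are
# shipped as fixtures: they exercise the aggregation and classification
# logic (means, effectiveness counts, below-average counts) against known
# printed values. The numbers are the printed 3-decimal values and are
# never recomputed.

.fixture_files <- c(
  "static-efficiency" = "static_efficiency.csv",
  "interval-indices"  = "interval_indices.csv",
  "dmu-indices"       = "dmu_indices.csv"
)

#' Load a packaged result-table fixture
#'
#' Three fixtures are shipped, transcribing published summary tables for
#' the 15-city Hainan health-resource panel (2016-2020):
#' \describe{
#'   \item{`static-efficiency`}{Super-efficiency SBM comprehensive
#'     efficiency per region and year, plus the printed Mean row/column.}
#'   \item{`interval-indices`}{Malmquist component means (EFFCH, TECH,
#'     PECH, SECH, TFP) per adjacent-year interval, plus the Mean row.}
#'   \item{`dmu-indices`}{Malmquist component means per region over all
#'     intervals, plus the Mean row.}
#' }
#' Each table includes its printed `Mean` row; drop it (e.g.
#' `subset(tab, region != "Mean")`) before re-aggregating.
#'
#' @param name One of `"static-efficiency"`, `"interval-indices"`,
#'   `"dmu-indices"`.
#' @return A data frame with attribute `fixture_name`; values are the
#'   printed 3-decimal numbers.
#' @examples
#' tab <- load_fixture("static-efficiency")
#' tab[tab$region == "Haikou City", "2016"]  # 1.248
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(.fixture_files)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(.fixture_files), collapse = ", "))
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "sbmdea",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(tab, "fixture_name") <- name
  tab
}
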