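#' Published marginal counts of the 2018 VIGITEL analytic sample
#'
#' The published sample-characteristics table of the 2018 VIGITEL survey
#' (respondents aged 20+ with a leisure-time physical-activity response)
#' reports, for each gender, age group, and state, the number of
#' respondents below ("inactive") and at or above ("active") 150 minutes
#' per week of leisure-time physical activity, with column percentages.
#' This function returns those counts and recomputes the percentages from
#' them, as count / column total x 100 using the published column sample
#' sizes (31,917 insufficiently active; 19,098 sufficiently active).
#'
#' The published state-level counts contain minor internal inconsistencies
#' (the inactive state block sums to 32,245, not the column total 31,917);
#' recomputation against the published column totals reproduces the
#' published gender and state percentages.
#'
#' @param variable which marginal block to return: \code{"gender"},
#'   \code{"age_group"}, \code{"unit"} (state), or \code{"all"}.
#' @return A data frame with columns \code{variable}, \code{level},
#'   \code{inactive}, \code{active} (counts), \code{pct_inactive},
#'   \code{pct_active} (recomputed column percentages).
#' @examples
#' pa_margins("gender")
#' @export
pa_margins <- function(variable = c("all", "gender", "age_group", "unit")) {
  variable <- match.arg(variable)
  path <- system.file("extdata", "vigitel2018_margins.csv",
                      package = "mrpstrat", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  totals <- df[df$variable == "total", ]
  df <- df[df$variable != "total", ]
  df$pct_inactive <- 100 * df$inactive / totals$inactive
  df$pct_active <- 100 * df$active / totals$active
  if (variable != "all") df <- df[df$variable == variable, ]
  row.names(df) <- NULL
  df
}
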