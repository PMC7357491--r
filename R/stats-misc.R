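#' Siderophore units from CAS absorbance
#'
#' Converts a blank-zeroed absorbance at 630 nm from the chrome azurol S
#' (CAS) liquid assay into percent siderophore units by multiplying by 100,
#' clipped to `[0, 100]` with a warning when the raw product exceeds 100.
#' The conventional CAS formula `(Ar - As) / Ar * 100` (reference absorbance
#' `Ar`, sample absorbance `As`) is available via `method = "reference"`;
#' the literal x100 rule is the default because it is what the screening
#' protocol states.
#'
#' @param absorbance_630 Non-negative absorbance(s); for
#'   `method = "reference"`, the sample absorbance `As`.
#' @param method `"times100"` (default) or `"reference"`.
#' @param reference Reference (uninoculated) absorbance `Ar`, required for
#'   `method = "reference"`.
#'
#' @return Percent siderophore units in `[0, 100]`.
#' @export
#' @examples
#' siderophore_percent(0.594) # 59.4
siderophore_percent <- function(absorbance_630,
                                method = c("times100", "reference"),
                                reference = NULL) {
  method <- match.arg(method)
  if (any(absorbance_630 < 0, na.rm = TRUE)) {
    abort_rhz("Absorbance must be >= 0.", "domain_error")
  }
  pct <- if (method == "times100") {
    100 * absorbance_630
  } else {
    if (is.null(reference) || reference <= 0) {
      abort_rhz("method = 'reference' needs a positive reference absorbance.",
                "domain_error")
    }
    (reference - absorbance_630) / reference * 100
  }
  if (any(pct > 100, na.rm = TRUE)) {
    warn("siderophore_percent(): value(s) above 100% clipped to 100.")
  }
  pmin(pmax(pct, 0), 100)
}

#' Iron-capture contrast between strains
#'
#' Mean of a group's capture percentages minus a reference strain's
#' percentage, in percentage points.
#'
#' @param percents_group Numeric vector of percentages in `[0, 100]`.
#' @param percent_ref Single reference percentage in `[0, 100]`.
#' @return The difference `mean(percents_group) - percent_ref`.
#' @export
#' @examples
#' capture_contrast(c(86.1, 88.4), 59.4) # 27.85, i.e. 28% after rounding
capture_contrast <- function(percents_group, percent_ref) {
  if (length(percents_group) == 0) {
    abort_rhz("Empty group of capture percentages.", "domain_error")
  }
  vals <- c(percents_group, percent_ref)
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    abort_rhz("Capture percentages must lie in [0, 100].", "domain_error")
  }
  mean(percents_group) - percent_ref
}

#' Homogeneity-of-variance check (Brown-Forsythe Levene test)
#'
#' Median-centered Levene test of equal variances across the levels of one
#' factor, the standard assumption check for the linear models fitted here.
#' Implemented via `car::leveneTest(center = median)`.
#'
#' @param table A data frame of observations.
#' @param response Name of the numeric response column.
#' @param factor Name of the grouping column.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`.
#' @export
levene_check <- function(table, response, factor) {
  tbl <- as_tibble(table)
  if (!all(c(response, factor) %in% names(tbl))) {
    abort_rhz("response/factor column not found.", "schema_error")
  }
  g <- base::factor(as.character(tbl[[factor]]))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort_rhz("Levene test needs >= 2 groups with >= 2 observations each.",
              "design_error")
  }
  lt <- car::leveneTest(tbl[[response]], g, center = median)
  tibble(statistic = lt$`F value`[1], df1 = lt$Df[1], df2 = lt$Df[2],
         p_value = lt$`Pr(>F)`[1])
}
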