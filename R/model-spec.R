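#' Declare a model structure for an assay
#'
#' A `model_spec` captures the only model structures the pipeline needs:
#' fixed categorical factors, continuous covariates, pairwise interactions,
#' an optional random intercept over an experimental-unit column (the plate
#' or tube carrying repeated measures), and an optional `log1p` response
#' transform. Factors are coded with treatment contrasts; the alphabetically
#' first level is the reference.
#'
#' @param response Name of the response column.
#' @param fixed_factors Character vector of categorical predictor columns.
#' @param covariates Character vector of continuous predictor columns.
#' @param interactions List of length-2 character vectors, each an interaction
#'   between two declared predictors (factor x factor or factor x covariate).
#' @param random_intercept Optional grouping column for a random intercept;
#'   must not also be a fixed factor.
#' @param transform `"none"` or `"log1p"` (natural log of value + 1).
#'
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("value", fixed_factors = c("strain", "condition"),
#'            interactions = list(c("strain", "condition")),
#'            transform = "log1p")
model_spec <- function(response, fixed_factors = character(),
                       covariates = character(), interactions = list(),
                       random_intercept = NULL,
                       transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  if (!is.null(random_intercept) && random_intercept %in% fixed_factors) {
    abort_rhz("random_intercept must not also be a fixed factor.", "design_error")
  }
  declared <- c(fixed_factors, covariates)
  for (ia in interactions) {
    if (length(ia) != 2 || !all(ia %in% declared)) {
      abort_rhz("Each interaction must pair two declared predictors.", "design_error")
    }
  }
  structure(
    list(response = response, fixed_factors = fixed_factors,
         covariates = covariates, interactions = interactions,
         random_intercept = random_intercept, transform = transform),
    class = "model_spec"
  )
}

# RHS formula string for a model_spec ("1" for intercept-only).
spec_rhs <- function(spec) {
  terms <- c(spec$fixed_factors, spec$covariates,
             vapply(spec$interactions, paste, "", collapse = ":"))
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}
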