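#' Carbon-source degradation velocities from OD time series
#'
#' For every (strain, substrate) cell, fits optical density against time in
#' hours with a random intercept per plate (the repeated-measures unit) and
#' extracts the slope in OD/h: the degradation velocity. A velocity counts as
#' real degradation only when the slope is statistically significant *and*
#' positive; otherwise it is set to zero and flagged `gated_to_zero`. A
#' significant negative slope is not degradation.
#'
#' @param table An [assay_table()] of OD measurements; `condition` holds the
#'   substrate, `unit` the plate.
#' @param alpha Two-sided significance level for the slope test (default 0.05).
#' @param min_timepoints Minimum distinct time points per cell (default 3).
#'
#' @return A tibble of class `velocity_matrix`: `strain`, `substrate`,
#'   `slope`, `se`, `df`, `p_value`, `velocity` (>= 0, OD/h) and `flag`
#'   (`significant_slope` or `gated_to_zero`).
#' @export
degradation_velocities <- function(table, alpha = 0.05, min_timepoints = 3) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_rhz("alpha must lie in (0, 1).", "domain_error")
  }
  tbl <- as_tibble(table)
  cells <- dplyr::group_split(group_by(tbl, .data$strain, .data$condition))
  res <- purrr::map_dfr(cells, function(cell) {
    nt <- length(unique(cell$time_h))
    if (nt < min_timepoints) {
      abort_rhz(paste0("Fewer than ", min_timepoints, " time points for strain ",
                       cell$strain[1], ", substrate ", cell$condition[1], "."),
                "insufficient_data_error")
    }
    spec <- if (length(unique(cell$unit)) >= 2) {
      model_spec("value", covariates = "time_h", random_intercept = "unit")
    } else {
      model_spec("value", covariates = "time_h")
    }
    fit <- fit_assay_model(cell, spec)
    idx <- which(names(fit$coefficients) == "time_h")
    slope <- fit$coefficients[[idx]]
    se <- sqrt(fit$vcov[idx, idx])
    Lrow <- as.numeric(seq_along(fit$coefficients) == idx)
    df <- contrast_df(fit, Lrow)
    # numerically exact fits: a slope below measurement precision is flat
    tol <- 1e-12 * max(1, max(abs(cell$value)))
    if (abs(slope) <= tol) slope <- 0
    p <- if (se > tol) 2 * pt(abs(slope) / se, df, lower.tail = FALSE)
         else if (slope == 0) 1 else 0
    tibble(strain = cell$strain[1], substrate = cell$condition[1],
           slope = slope, se = se, df = df, p_value = p)
  })
  res <- mutate(res,
    significant = .data$p_value < alpha & .data$slope > 0,
    velocity = ifelse(.data$significant, .data$slope, 0),
    flag = ifelse(.data$significant, "significant_slope", "gated_to_zero")
  )
  res$significant <- NULL
  class(res) <- c("velocity_matrix", class(res))
  attr(res, "alpha") <- alpha
  res
}
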