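#' Score a performance matrix with exponential value functions
#'
#' Applies each attribute's exponential single-attribute value function to
#' every strain's performance value, yielding the 0-1 score matrix. The
#' curvature of each function is solved once per attribute from its midpoint
#' anchor. Per-cell provenance records whether the raw value had to be
#' clamped to the anchor interval.
#'
#' @param perf A [build_performance_matrix()] result (or any tibble with
#'   `strain`, `attribute`, `value`).
#' @param specs An [attribute_specs()] tibble covering every attribute in
#'   `perf`.
#'
#' @return A tibble of class `score_matrix`: `strain`, `attribute`,
#'   `criterion`, `value`, `score` (in `[0, 1]`), `clamped`.
#' @export
score_matrix <- function(perf, specs) {
  perf <- as_tibble(perf)
  specs <- attribute_specs(specs)
  missing_specs <- setdiff(unique(perf$attribute), specs$attribute)
  if (length(missing_specs) > 0) {
    abort_rhz(paste0("No attribute spec for: ",
                     paste(missing_specs, collapse = ", ")), "completeness_error")
  }
  rho <- purrr::pmap_dbl(specs[c("v_min", "v_mid", "v_max")], solve_curvature)
  specs$`.rho` <- rho
  out <- inner_join(perf[c("strain", "attribute", "value")], specs,
                    by = "attribute")
  out <- mutate(out,
    clamped = .data$value < .data$v_min | .data$value > .data$v_max,
    score = purrr::pmap_dbl(
      list(.data$value, .data$v_min, .data$v_mid, .data$v_max,
           .data$direction, .data$.rho),
      function(x, lo, mid, hi, dir, r) savf_score(x, lo, mid, hi, dir, rho = r)
    )
  )
  out <- out[c("strain", "attribute", "criterion", "value", "score", "clamped")]
  class(out) <- c("score_matrix", class(out))
  out
}

#' Per-attribute weights implied by a scenario
#'
#' Splits each criterion's normalized weight equally among the attributes
#' assigned to that criterion, so the attribute weights sum to 1. A criterion
#' given positive weight but owning no attribute is a configuration error.
#'
#' @param scenario Either a named numeric vector of criterion weights or one
#'   scenario's rows from a [scenario_weights()] tibble.
#' @param specs An [attribute_specs()] tibble.
#'
#' @return A tibble `attribute`, `criterion`, `weight`, summing to 1.
#' @export
#' @examples
#' attribute_weights(c(plant_growth = 2, colonization = 1, persistence = 1),
#'                   default_attribute_specs())
attribute_weights <- function(scenario, specs) {
  specs <- attribute_specs(specs)
  if (is.data.frame(scenario)) {
    w <- setNames(scenario$weight, scenario$criterion)
  } else {
    w <- scenario
  }
  if (any(w < 0) || sum(w) <= 0) {
    abort_rhz("Criterion weights must be >= 0 with a positive sum.", "domain_error")
  }
  w <- w / sum(w)
  counts <- table(specs$criterion)
  empty <- names(w)[w > 0 & !(names(w) %in% names(counts))]
  if (length(empty) > 0) {
    abort_rhz(paste0("Criterion with positive weight but no attributes: ",
                     paste(empty, collapse = ", ")), "config_error")
  }
  out <- tibble(attribute = specs$attribute, criterion = specs$criterion)
  out$weight <- as.numeric(w[out$criterion]) / as.numeric(counts[out$criterion])
  out$weight[is.na(out$weight)] <- 0
  out
}

#' Aggregate scores into weighted totals and ranks
#'
#' The total score of a strain is the linear weighted sum of its attribute
#' scores; per-criterion weighted subtotals are returned alongside (they sum
#' to the total). Strains are ranked by descending total; exact ties share
#' the order implied by strain id (lexicographic) and are flagged.
#'
#' @param scores A [score_matrix()].
#' @param weights Attribute weights from [attribute_weights()]; must cover
#'   exactly the scored attributes and sum to 1 (tolerance 1e-9).
#' @param scenario Scenario id to stamp on the result (default `"S"`).
#'
#' @return A tibble of class `ranking_result`: `scenario`, `strain`, one
#'   `sub_<criterion>` column per criterion, `total`, `rank`, `tied`.
#' @export
total_scores <- function(scores, weights, scenario = "S") {
  scores <- as_tibble(scores)
  weights <- as_tibble(weights)
  if (!setequal(unique(scores$attribute), weights$attribute)) {
    abort_rhz("Score and weight attribute sets differ.", "completeness_error")
  }
  if (abs(sum(weights$weight) - 1) > 1e-9) {
    abort_rhz("Attribute weights must sum to 1.", "domain_error")
  }
  joined <- inner_join(scores[c("strain", "attribute", "criterion", "score")],
                       weights[c("attribute", "weight")], by = "attribute")
  subtot <- joined %>%
    group_by(.data$strain, .data$criterion) %>%
    summarise(subtotal = sum(.data$score * .data$weight), .groups = "drop")
  wide <- tidyr::pivot_wider(subtot, names_from = "criterion",
                             values_from = "subtotal", names_prefix = "sub_")
  wide$total <- rowSums(wide[setdiff(names(wide), "strain")])
  wide <- arrange(wide, desc(.data$total), .data$strain)
  wide$rank <- seq_len(nrow(wide))
  wide$tied <- duplicated(wide$total) | duplicated(wide$total, fromLast = TRUE)
  out <- dplyr::bind_cols(tibble(scenario = scenario), wide)
  class(out) <- c("ranking_result", class(out))
  out
}

#' Rank strains under every scenario
#'
#' Convenience wrapper: scores a performance matrix once and aggregates it
#' under each scenario's weights.
#'
#' @param perf A [build_performance_matrix()] result.
#' @param specs An [attribute_specs()] tibble.
#' @param scenarios A [scenario_weights()] tibble (default scenarios when
#'   `NULL`).
#'
#' @return A `ranking_result` tibble with one row per (scenario, strain).
#' @export
rank_strains <- function(perf, specs, scenarios = NULL) {
  specs <- attribute_specs(specs)
  scenarios <- scenario_weights(scenarios)
  scores <- score_matrix(perf, specs)
  out <- purrr::map_dfr(split(scenarios, scenarios$scenario), function(s) {
    total_scores(scores, attribute_weights(s, specs), scenario = s$scenario[1])
  })
  class(out) <- c("ranking_result", class(out))
  attr(out, "scores") <- scores
  out
}

#' Compare rankings across scenarios
#'
#' Tabulates totals and ranks per scenario and flags rank reversals between
#' every scenario pair: a pair of strains whose order flips, and in
#' particular a change of the top-ranked strain.
#'
#' @param results A `ranking_result` covering one or more scenarios over the
#'   same strain set.
#'
#' @return A tibble of class `scenario_comparison`: `scenario_a`,
#'   `scenario_b`, `top_a`, `top_b`, `top_changed`, `n_reversed_pairs`,
#'   `reversal`. The per-scenario totals/ranks table is attached as the
#'   `totals` attribute.
#' @export
compare_scenarios <- function(results) {
  results <- as_tibble(results)
  scen <- unique(results$scenario)
  strain_sets <- lapply(split(results$strain, results$scenario), sort)
  if (length(unique(lapply(strain_sets, paste, collapse = "|"))) > 1) {
    abort_rhz("Scenarios cover different strain sets.", "integrity_error")
  }
  totals <- tidyr::pivot_wider(results[c("scenario", "strain", "total", "rank")],
                               names_from = "scenario",
                               values_from = c("total", "rank"))
  if (length(scen) < 2) {
    out <- tibble(scenario_a = character(), scenario_b = character(),
                  top_a = character(), top_b = character(),
                  top_changed = logical(), n_reversed_pairs = integer(),
                  reversal = logical())
  } else {
    prs <- utils::combn(scen, 2)
    out <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
      a <- filter(results, .data$scenario == prs[1, j]) %>% arrange(.data$strain)
      b <- filter(results, .data$scenario == prs[2, j]) %>% arrange(.data$strain)
      n <- nrow(a)
      rev_pairs <- 0L
      if (n >= 2) {
        cmb <- utils::combn(n, 2)
        for (k in seq_len(ncol(cmb))) {
          i1 <- cmb[1, k]; i2 <- cmb[2, k]
          if (sign(a$rank[i1] - a$rank[i2]) * sign(b$rank[i1] - b$rank[i2]) < 0) {
            rev_pairs <- rev_pairs + 1L
          }
        }
      }
      top_a <- a$strain[a$rank == 1][1]
      top_b <- b$strain[b$rank == 1][1]
      tibble(scenario_a = prs[1, j], scenario_b = prs[2, j],
             top_a = top_a, top_b = top_b,
             top_changed = !identical(top_a, top_b),
             n_reversed_pairs = rev_pairs,
             reversal = rev_pairs > 0L)
    })
  }
  class(out) <- c("scenario_comparison", class(out))
  attr(out, "totals") <- totals
  out
}

#' Tidy a ranking result
#'
#' @param x A `ranking_result`.
#' @param ... Unused.
#' @return Long tibble: `scenario`, `strain`, `criterion`, `subtotal`,
#'   `total`, `rank`, `tied`.
#' @export
tidy.ranking_result <- function(x, ...) {
  x <- as_tibble(x)
  tidyr::pivot_longer(x, dplyr::starts_with("sub_"),
                      names_to = "criterion", values_to = "subtotal",
                      names_prefix = "sub_")
}

#' Glance at a ranking result
#'
#' @param x A `ranking_result`.
#' @param ... Unused.
#' @return One row per scenario: `scenario`, `n_strains`, `top_strain`,
#'   `top_total`, `any_tie`.
#' @export
glance.ranking_result <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$scenario) %>%
    summarise(
      n_strains = n(),
      top_strain = .data$strain[.data$rank == 1][1],
      top_total = max(.data$total),
      any_tie = any(.data$tied),
      .groups = "drop"
    )
}

#' Write / read ranking results
#'
#' @param x A `ranking_result`.
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path, json_path = NULL) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as_tibble(x), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    scenario = readr::col_character(), strain = readr::col_character(),
    tied = readr::col_logical(), rank = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  class(out) <- c("ranking_result", class(out))
  out
}
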