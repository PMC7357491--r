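#' Attribute specifications for utility scoring
#'
#' Validates a table of attribute specs: one row per phenotypic attribute with
#' its selection criterion (`plant_growth`, `colonization` or `persistence`),
#' preference `direction` (`increasing`/`decreasing`; a decreasing direction
#' only flags reversed preference — anchors stay on the measurement scale) and
#' the `v_min`/`v_mid`/`v_max` anchors of its exponential value function.
#'
#' @param x A data frame with columns `attribute`, `criterion`, `direction`,
#'   `v_min`, `v_mid`, `v_max`.
#' @return A tibble of class `attribute_specs`.
#' @export
attribute_specs <- function(x) {
  x <- as_tibble(x)
  need <- c("attribute", "criterion", "direction", "v_min", "v_mid", "v_max")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort_rhz(paste0("Missing attribute-spec column(s): ",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (anyDuplicated(x$attribute)) {
    abort_rhz("Duplicate attribute ids in specs.", "integrity_error")
  }
  bad_crit <- setdiff(unique(x$criterion),
                      c("plant_growth", "colonization", "persistence"))
  if (length(bad_crit) > 0) {
    abort_rhz(paste0("Unknown criterion: ", paste(bad_crit, collapse = ", ")),
              "domain_error")
  }
  if (!all(x$direction %in% c("increasing", "decreasing"))) {
    abort_rhz("direction must be 'increasing' or 'decreasing'.", "domain_error")
  }
  purrr::pwalk(x[c("v_min", "v_mid", "v_max")],
               function(v_min, v_mid, v_max) check_anchors(v_min, v_mid, v_max))
  class(x) <- c("attribute_specs", class(x))
  x
}

#' Scenario weights over the three selection criteria
#'
#' A scenario assigns a non-negative importance weight to each criterion;
#' weights are normalized to sum to 1. The default scenarios encode the three
#' selection postures the framework compares: S1 emphasizes plant-growth
#' phenotypes (0.5/0.25/0.25); S2 weights plant growth and colonization
#' equally and persistence less (0.4/0.4/0.2); S3 is indifferent (equal
#' thirds).
#'
#' @param x A data frame with columns `scenario`, `criterion`, `weight`
#'   (long), or `NULL` for the defaults.
#' @return A tibble of class `scenario_weights` with normalized weights.
#' @export
scenario_weights <- function(x = NULL) {
  if (is.null(x)) x <- default_scenarios_raw()
  x <- as_tibble(x)
  need <- c("scenario", "criterion", "weight")
  if (!all(need %in% names(x))) {
    abort_rhz("Scenario table needs columns scenario, criterion, weight.",
              "schema_error")
  }
  if (any(x$weight < 0)) abort_rhz("Weights must be >= 0.", "domain_error")
  x <- x %>%
    group_by(.data$scenario) %>%
    mutate(total = sum(.data$weight)) %>%
    ungroup()
  if (any(x$total <= 0)) {
    abort_rhz("Each scenario needs at least one positive weight.", "domain_error")
  }
  x <- mutate(x, weight = .data$weight / .data$total, total = NULL)
  class(x) <- c("scenario_weights", class(x))
  x
}

default_scenarios_raw <- function() {
  tibble(
    scenario = rep(c("S1", "S2", "S3"), each = 3),
    criterion = rep(c("plant_growth", "colonization", "persistence"), 3),
    weight = c(0.5, 0.25, 0.25,
               0.4, 0.4, 0.2,
               1 / 3, 1 / 3, 1 / 3)
  )
}

#' Default attribute specs of the synthetic study
#'
#' The 38 attributes of the calibrated synthetic study: 8 phosphate
#' solubilization attributes (3 halo media, 5 broths), siderophore synthesis,
#' swimming, surface spreading, ROS sensitivity (decreasing: a smaller
#' inhibition halo means a more resistant strain), 4 biofilm conditions and
#' 22 Eco-plate carbon sources. Anchors are declared elicitation choices of
#' the package (see the methods vignette), not measured quantities: halo
#' areas use a concave function (any clear halo is already informative),
#' everything else is linear between 0 and a plausible upper bound.
#'
#' @return An [attribute_specs()] tibble with 38 rows.
#' @export
default_attribute_specs <- function() {
  base <- dplyr::tribble(
    ~attribute, ~criterion, ~direction, ~v_min, ~v_mid, ~v_max,
    "Pca",  "plant_growth", "increasing", 0, 0.5,  5,
    "Pfe",  "plant_growth", "increasing", 0, 0.5,  5,
    "Prk",  "plant_growth", "increasing", 0, 0.5,  5,
    "PMY",  "plant_growth", "increasing", 0, 40,   80,
    "PMN",  "plant_growth", "increasing", 0, 40,   80,
    "PGN",  "plant_growth", "increasing", 0, 40,   80,
    "PSN",  "plant_growth", "increasing", 0, 40,   80,
    "PFN",  "plant_growth", "increasing", 0, 40,   80,
    "Sph",  "plant_growth", "increasing", 0, 50,   100,
    "Sw",   "colonization", "increasing", 0, 1.25, 2.5,
    "Ss",   "colonization", "increasing", 0, 2,    4,
    "ros",  "colonization", "decreasing", 0, 1,    2,
    "BfM",  "persistence",  "increasing", 0, 0.3,  0.6,
    "BfpH", "persistence",  "increasing", 0, 0.3,  0.6,
    "BfT",  "persistence",  "increasing", 0, 0.3,  0.6,
    "Bfrk", "persistence",  "increasing", 0, 0.3,  0.6
  )
  subs <- eco_substrates()
  subs <- subs[subs$scored, ]
  sub_specs <- tibble(
    attribute = subs$substrate, criterion = "persistence",
    direction = "increasing", v_min = 0, v_mid = 0.006, v_max = 0.012
  )
  attribute_specs(bind_rows(base, sub_specs))
}

#' Read / write a MAUT configuration (attributes + scenarios) as YAML
#'
#' One YAML file holds both the attribute specs and the scenarios:
#' `attributes:` is a list of `{id, criterion, direction, min, mid, max}`
#' maps and `scenarios:` a list of `{id, weights: {criterion: weight}}` maps.
#'
#' @param path YAML file path.
#' @return For `read_maut_config()`: a list with elements `attributes`
#'   ([attribute_specs()]) and `scenarios` ([scenario_weights()]).
#' @export
read_maut_config <- function(path) {
  if (!file.exists(path)) abort_rhz(paste0("File not found: ", path), "io_error")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes) || is.null(cfg$scenarios)) {
    abort_rhz("YAML config needs 'attributes' and 'scenarios' blocks.",
              "schema_error")
  }
  specs <- purrr::map_dfr(cfg$attributes, function(a) {
    tibble(attribute = a$id, criterion = a$criterion,
           direction = a$direction %||% "increasing",
           v_min = a$min, v_mid = a$mid, v_max = a$max)
  })
  scen <- purrr::map_dfr(cfg$scenarios, function(s) {
    tibble(scenario = s$id, criterion = names(s$weights),
           weight = as.numeric(unlist(s$weights)))
  })
  list(attributes = attribute_specs(specs), scenarios = scenario_weights(scen))
}

#' @rdname read_maut_config
#' @param specs An [attribute_specs()] tibble.
#' @param scenarios A [scenario_weights()] tibble.
#' @export
write_maut_config <- function(specs, scenarios, path) {
  specs <- attribute_specs(specs)
  scenarios <- scenario_weights(scenarios)
  attrs <- purrr::pmap(specs, function(attribute, criterion, direction,
                                       v_min, v_mid, v_max, ...) {
    list(id = attribute, criterion = criterion, direction = direction,
         min = v_min, mid = v_mid, max = v_max)
  })
  scen <- purrr::map(split(scenarios, scenarios$scenario), function(s) {
    list(id = s$scenario[1],
         weights = as.list(setNames(s$weight, s$criterion)))
  })
  yaml::write_yaml(list(attributes = attrs, scenarios = unname(scen)), path)
  invisible(path)
}
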