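# Fit a model for one assay and return marginal means for `by`, dropping any
# requested factor that has a single level in the data (e.g. `strain` in a
# single-strain study) and re-attaching it as a constant column afterwards.
mm_for <- function(data, factors, by, covariates = character(),
                   interactions = list(), random = NULL, transform = "none") {
  data <- as_tibble(data)
  single <- factors[vapply(factors, function(f) length(unique(data[[f]])) < 2, TRUE)]
  factors2 <- setdiff(factors, single)
  interactions2 <- purrr::keep(interactions,
                               function(ia) all(ia %in% c(factors2, covariates)))
  by2 <- setdiff(by, single)
  spec <- model_spec("value", fixed_factors = factors2, covariates = covariates,
                     interactions = interactions2, random_intercept = random,
                     transform = transform)
  fit <- fit_assay_model(data, spec)
  mm <- marginal_means(fit, if (length(by2) > 0) by2 else NULL)
  for (f in intersect(single, by)) mm[[f]] <- unique(data[[f]])
  list(fit = fit, mm = as_tibble(mm))
}

biofilm_attr_map <- c(MMS = "BfM", acidic_pH = "BfpH",
                      phosphorus_fertilizer = "Bfrk",
                      high_temperature = "BfT")

#' Estimate the performance matrix from assay tables
#'
#' Runs the per-assay statistical models and assembles the strain x attribute
#' performance matrix that feeds the utility scoring:
#'
#' * halo solubilization areas, swimming/spreading colony areas and
#'   H2O2-inhibition halos are fitted on the log1p scale and their adjusted
#'   means back-transformed with `expm1`;
#' * the spreading model uses time as a continuous covariate interacting
#'   with strain, with a random intercept per plate;
#' * siderophore performance is the x100 rule applied to the adjusted mean
#'   CAS absorbance;
#' * biofilm absorbances are fitted untransformed (strain x condition);
#' * Eco-plate substrates contribute their gated degradation velocities.
#'
#' @param tables Named list of [assay_table()]s with elements `halo`,
#'   `broth`, `cas`, `motility`, `ros`, `biofilm`, `ecoplate` (as produced by
#'   [generate_full_study()]).
#' @param specs An [attribute_specs()] declaring the attribute set (defaults
#'   to [default_attribute_specs()]); completeness is checked against it.
#' @param alpha Significance level for velocity gating.
#' @param detail If `TRUE`, also return the fitted models and Tukey letter
#'   tables per assay.
#'
#' @return A [build_performance_matrix()] tibble, or (with `detail = TRUE`)
#'   a list with `performance`, `fits`, `letters`, `velocities`.
#' @export
estimate_performance <- function(tables, specs = default_attribute_specs(),
                                 alpha = 0.05, detail = FALSE) {
  needed <- c("halo", "broth", "cas", "motility", "ros", "biofilm", "ecoplate")
  missing_tbl <- setdiff(needed, names(tables))
  if (length(missing_tbl) > 0) {
    abort_rhz(paste0("Missing assay table(s): ", paste(missing_tbl, collapse = ", ")),
              "completeness_error")
  }
  specs <- attribute_specs(specs)
  strains <- sort(unique(unlist(lapply(tables, function(t) unique(t$strain)))))
  fits <- list()

  halo <- add_halo_area(tables$halo)
  halo$time_f <- as.character(halo$time_h)
  halo_res <- mm_for(halo, factors = c("strain", "condition", "time_f"),
                     by = c("strain", "condition"),
                     interactions = list(c("strain", "condition")),
                     transform = "log1p")
  fits$halo <- halo_res$fit
  halo_perf <- tibble(strain = halo_res$mm$strain,
                      attribute = halo_res$mm$condition,
                      value = expm1(halo_res$mm$estimate),
                      source = "halo_nbrip")

  broth_res <- mm_for(tables$broth, factors = c("strain", "condition"),
                      by = c("strain", "condition"),
                      interactions = list(c("strain", "condition")),
                      transform = "log1p")
  fits$broth <- broth_res$fit
  broth_perf <- tibble(strain = broth_res$mm$strain,
                       attribute = broth_res$mm$condition,
                       value = expm1(broth_res$mm$estimate),
                       source = "phosphate_broth")

  cas_res <- mm_for(tables$cas, factors = "strain", by = "strain")
  fits$cas <- cas_res$fit
  cas_perf <- tibble(strain = cas_res$mm$strain, attribute = "Sph",
                     value = siderophore_percent(pmax(cas_res$mm$estimate, 0)),
                     source = "cas")

  swim <- filter(as_tibble(tables$motility), .data$assay == "swimming")
  swim$time_f <- as.character(swim$time_h)
  swim_res <- mm_for(swim, factors = c("strain", "time_f"), by = "strain",
                     transform = "log1p")
  fits$swimming <- swim_res$fit
  swim_perf <- tibble(strain = swim_res$mm$strain, attribute = "Sw",
                      value = expm1(swim_res$mm$estimate), source = "swimming")

  spread <- filter(as_tibble(tables$motility), .data$assay == "surface_spreading")
  spread_res <- mm_for(spread, factors = "strain", by = "strain",
                       covariates = "time_h",
                       interactions = list(c("strain", "time_h")),
                       random = "unit", transform = "log1p")
  fits$spreading <- spread_res$fit
  spread_perf <- tibble(strain = spread_res$mm$strain, attribute = "Ss",
                        value = expm1(spread_res$mm$estimate),
                        source = "surface_spreading")

  ros <- as_tibble(tables$ros)
  ros$conc <- as.numeric(sub("mM$", "", ros$condition))
  ros_res <- mm_for(ros, factors = "strain", by = "strain",
                    covariates = "conc", transform = "log1p")
  fits$ros <- ros_res$fit
  ros_perf <- tibble(strain = ros_res$mm$strain, attribute = "ros",
                     value = expm1(ros_res$mm$estimate), source = "ros")

  bf_res <- mm_for(tables$biofilm, factors = c("strain", "condition"),
                   by = c("strain", "condition"),
                   interactions = list(c("strain", "condition")))
  fits$biofilm <- bf_res$fit
  bf_perf <- tibble(strain = bf_res$mm$strain,
                    attribute = unname(biofilm_attr_map[bf_res$mm$condition]),
                    value = pmax(bf_res$mm$estimate, 0), source = "biofilm")

  vel <- degradation_velocities(tables$ecoplate, alpha = alpha)
  eco_attrs <- intersect(unique(vel$substrate), specs$attribute)
  eco_perf <- vel %>%
    filter(.data$substrate %in% eco_attrs) %>%
    mutate(attribute = .data$substrate, value = .data$velocity,
           source = "ecoplate") %>%
    select("strain", "attribute", "value", "source")

  perf <- build_performance_matrix(
    halo_perf, broth_perf, cas_perf, swim_perf, spread_perf, ros_perf,
    bf_perf, eco_perf,
    attributes = specs$attribute, strains = strains
  )
  if (!detail) return(perf)

  letters <- list()
  if (length(strains) > 1) {
    letters$halo_strain <- cld_letters(tukey_pairwise(fits$halo, "strain", alpha))
    letters$halo_source <- cld_letters(tukey_pairwise(fits$halo, "condition", alpha))
    letters$cas <- cld_letters(tukey_pairwise(fits$cas, "strain", alpha))
    letters$spreading <- cld_letters(tukey_pairwise(fits$spreading, "strain", alpha))
    letters$biofilm <- cld_letters(
      tukey_pairwise(fits$biofilm, c("strain", "condition"), alpha))
  }
  list(performance = perf, fits = fits, letters = letters, velocities = vel)
}

#' Run the full selection pipeline on a synthetic study
#'
#' Simulate, estimate, score and rank in one call: the end-to-end analogue of
#' the screening framework. All randomness flows from the config seed, so a
#' fixed config yields byte-identical outputs.
#'
#' @param cfg A [synthetic_config()].
#' @param alpha Significance level used throughout (default 0.05).
#'
#' @return A list of class `pgpr_run`: `study`, `performance`, `scores`,
#'   `ranking`, `comparison`.
#' @export
run_full_study <- function(cfg = synthetic_config(), alpha = 0.05) {
  study <- generate_full_study(cfg)
  perf <- estimate_performance(study$tables, specs = study$attributes,
                               alpha = alpha)
  ranking <- rank_strains(perf, study$attributes, study$scenarios)
  structure(
    list(study = study, performance = perf,
         scores = attr(ranking, "scores"),
         ranking = ranking, comparison = compare_scenarios(ranking)),
    class = "pgpr_run"
  )
}

#' @export
print.pgpr_run <- function(x, ...) {
  cat("<pgpr_run> strains:", paste(unique(x$ranking$strain), collapse = ", "), "\n")
  g <- glance(x$ranking)
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s: top strain %s (total %.3f)\n",
                g$scenario[i], g$top_strain[i], g$top_total[i]))
  }
  invisible(x)
}

#' Write the outputs of a pipeline run
#'
#' Performance matrix (wide CSV + JSON with provenance), ranking (CSV +
#' JSON), and scenario comparison (CSV). Every file is re-readable by the
#' package's own readers.
#'
#' @param run A [run_full_study()] result.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pgpr_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    performance = file.path(dir, "performance_matrix.csv"),
    ranking = file.path(dir, "ranking.csv"),
    comparison = file.path(dir, "scenario_comparison.csv")
  )
  write_performance_matrix(run$performance, paths["performance"],
                           json_path = file.path(dir, "performance_matrix.json"))
  write_ranking(run$ranking, paths["ranking"],
                json_path = file.path(dir, "ranking.json"))
  readr::write_csv(as_tibble(run$comparison), paths["comparison"],
                   progress = FALSE)
  invisible(paths)
}
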