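#' Configuration of the synthetic assay study
#'
#' Defines the study conditions the generators emulate: three *Rhizobium*-like
#' strains, three replicates per experiment, and per-assay true effects
#' calibrated to the printed results of the screening study the package
#' models — mean halo solubilization areas of 1.5 / 2.03 / 2.09 cm^2 at 48 h,
#' a top rock-phosphate solubilization of 72.6 mg/L for the B02-like strain
#' in mannitol/ammonium broth, CAS absorbances 0.861 / 0.884 / 0.594
#' (i.e. 86.1 / 88.4 / 59.4 percent siderophore units), biofilm means and
#' standard errors per condition, and an Eco-plate usability pattern with
#' 17 / 15 / 13 usable carbon sources (13 unusable by every strain).
#' Noise is additive Gaussian on the analysis scale (log1p for areas and
#' concentrations, raw for absorbances and OD), truncated at zero; replicate
#' standard deviations for the biofilm assay derive from the printed standard
#' errors times sqrt(3).
#'
#' Each assay draws from its own random stream, derived from the master seed
#' by a stable hash of the assay id, so adding one assay never perturbs the
#' others and a fixed seed yields byte-identical tables.
#'
#' @param seed Master seed (integer).
#' @param n_strains Number of strains (default 3; calibration templates are
#'   recycled beyond 3).
#' @param n_replicates Replicates per experiment (default 3).
#' @param noise_sd Named list of per-assay residual noise standard deviations;
#'   any entry can be overridden (set to 0 for noiseless generation).
#' @param plate_sd Named list of random-intercept (plate/tube) standard
#'   deviations.
#' @param ecoplate_timepoints Hours at which Eco-plate OD is read.
#' @param usable_pattern Logical strains x 31 matrix of substrate usability;
#'   defaults to the calibrated 17/15/13 pattern.
#' @param calibration Named list of overrides for the per-assay true effects
#'   (see the `calibration` element of the returned object for names and
#'   shapes, which overrides must match).
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 11, n_strains = 3, n_replicates = 3,
                             noise_sd = list(), plate_sd = list(),
                             ecoplate_timepoints = c(12, 24, 36, 48, 60, 72, 84),
                             usable_pattern = NULL, calibration = list()) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    abort_rhz("seed must be a single integer.", "config_error")
  }
  if (n_strains < 1) abort_rhz("n_strains must be >= 1.", "config_error")
  if (n_replicates < 1) abort_rhz("n_replicates must be >= 1.", "config_error")
  base_strains <- c("B02", "L3", "Sp20")
  strains <- if (n_strains <= 3) base_strains[seq_len(n_strains)] else
    c(base_strains, sprintf("SYN%d", 4:n_strains))
  idx <- ((seq_len(n_strains) - 1) %% 3) + 1  # calibration template per strain

  noise <- utils::modifyList(list(
    halo = 0.05, broth = 0.05, cas = 0.01, motility = 0.05, ros = 0.05,
    biofilm = NULL, ecoplate = 0.005
  ), noise_sd)
  plate <- utils::modifyList(list(
    halo = 0.02, spreading = 0.05, ecoplate = 0.02
  ), plate_sd)
  for (v in c(noise[!vapply(noise, is.null, TRUE)], plate)) {
    if (any(unlist(v) < 0)) abort_rhz("Noise sds must be >= 0.", "config_error")
  }
  if (is.null(usable_pattern)) {
    usable_pattern <- default_usable_pattern(strains)
  }
  if (ncol(usable_pattern) != 31) {
    abort_rhz("usable_pattern must cover exactly 31 substrates.", "config_error")
  }

  cal <- list(
    halo_mean48 = c(1.5, 2.03, 2.09)[idx],
    halo_source_rel = c(Pca = 2.1403, Pfe = 0.3851, Prk = 0.4746),
    halo_time_factor = c(`24` = 0.5, `48` = 1),
    broth_means = rbind(
      c(PMY = 1.2, PMN = 72.6, PGN = 48, PSN = 36, PFN = 42),
      c(PMY = 1.0, PMN = 26, PGN = 12, PSN = 9, PFN = 13),
      c(PMY = 0.8, PMN = 20, PGN = 10, PSN = 7, PFN = 8)
    )[idx, , drop = FALSE],
    cas_abs = c(0.861, 0.884, 0.594)[idx],
    swim_area48 = c(2.0, 2.1, 2.0)[idx],
    swim_time_factor = c(`24` = 0.6, `48` = 1),
    spread_intercept = 0.1,
    spread_slope = c(0.010, 0.020, 0.011)[idx],
    spread_times = c(24, 48, 72, 96),
    ros_intercept = c(0.30, 0.70, 0.65)[idx],
    ros_conc_slope = 0.05,
    ros_concs = c(2, 3, 5, 8, 10),
    biofilm_means = rbind(
      c(MMS = 0.46, acidic_pH = 0.22, phosphorus_fertilizer = 0.22,
        high_temperature = 0.18),
      c(MMS = 0.53, acidic_pH = 0.21, phosphorus_fertilizer = 0.24,
        high_temperature = 0.58),
      c(MMS = 0.54, acidic_pH = 0.22, phosphorus_fertilizer = 0.23,
        high_temperature = 0.42)
    )[idx, , drop = FALSE],
    biofilm_se = rbind(
      c(0.03, 0.01, 0.02, 0.01),
      c(0.03, 0.01, 0.02, 0.02),
      c(0.04, 0.02, 0.02, 0.04)
    )[idx, , drop = FALSE],
    eco_base_slope = 0.01,
    eco_strain_mult = c(0.95, 1.2, 0.7)[idx],
    eco_baseline_od = 0.05
  )
  rownames(cal$broth_means) <- rownames(cal$biofilm_means) <-
    rownames(cal$biofilm_se) <- strains
  colnames(cal$biofilm_se) <- colnames(cal$biofilm_means)
  cal <- utils::modifyList(cal, calibration)
  names(cal$halo_mean48) <- names(cal$cas_abs) <- names(cal$swim_area48) <-
    names(cal$spread_slope) <- names(cal$ros_intercept) <-
    names(cal$eco_strain_mult) <- strains

  structure(list(seed = as.integer(seed), n_strains = n_strains,
                 n_replicates = n_replicates, strains = strains,
                 noise_sd = noise, plate_sd = plate,
                 ecoplate_timepoints = ecoplate_timepoints,
                 usable_pattern = usable_pattern, calibration = cal),
            class = "synthetic_config")
}

# Deterministic per-assay stream: a stable polynomial hash of the assay id
# folded into the master seed, so streams are independent of generation order.
stable_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

assay_seed <- function(cfg, assay_id) {
  as.integer((as.numeric(cfg$seed) * 48271 + stable_hash(assay_id)) %% 2147483647)
}

with_stream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncate physically non-negative draws at zero, flagging affected rows.
truncate0 <- function(x) {
  flag <- x < 0
  list(value = pmax(x, 0), truncated = flag)
}

#' Generate the phosphate-solubilization halo assay
#'
#' Halo observations (paired perpendicular radii) on three phosphorus
#' sources at 24 and 48 h, with strain effects calibrated so the 48-h mean
#' areas are 1.5 / 2.03 / 2.09 cm^2 and source effects proportional to the
#' printed per-source solubilization. Noise is Gaussian on the log1p(area)
#' scale; both read times of a plate share a unit (random intercept).
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] with `r1_cm`/`r2_cm` halo rows.
#' @export
generate_halo_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "halo_nbrip"), {
    grid <- tidyr::expand_grid(
      strain = cfg$strains,
      condition = names(cal$halo_source_rel),
      replicate = seq_len(cfg$n_replicates),
      time_h = as.numeric(names(cal$halo_time_factor))
    )
    grid <- arrange(grid, .data$strain, .data$condition, .data$replicate, .data$time_h)
    grid$unit <- paste(grid$strain, grid$condition, grid$replicate, sep = "_")
    la_true <- log1p(cal$halo_mean48[grid$strain] *
                       cal$halo_source_rel[grid$condition] *
                       cal$halo_time_factor[as.character(grid$time_h)])
    units <- unique(grid$unit)
    b <- setNames(rnorm(length(units), 0, cfg$plate_sd$halo), units)
    la <- la_true + b[grid$unit] + rnorm(nrow(grid), 0, cfg$noise_sd$halo)
    area <- truncate0(expm1(la))
    r <- sqrt(area$value)
    assay_table(tibble(
      strain = grid$strain, assay = "halo_nbrip", condition = grid$condition,
      unit = grid$unit, replicate = grid$replicate, time_h = grid$time_h,
      r1_cm = r, r2_cm = r, value_kind = "diameter_cm",
      truncated = area$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the broth phosphate-solubilization assay
#'
#' Endpoint solubilized-phosphate concentrations (mg/L) in five broths
#' (mannitol/yeast and four sugar/ammonium media); the B02-like strain's
#' mannitol/ammonium mean is the calibrated maximum, 72.6 mg/L. Gaussian
#' noise on the log1p scale, truncated at zero.
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] of `concentration_mg_per_L` rows at `time_h = 0`.
#' @export
generate_broth_solubilization <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "phosphate_broth"), {
    grid <- tidyr::expand_grid(
      strain = cfg$strains,
      condition = colnames(cal$broth_means),
      replicate = seq_len(cfg$n_replicates)
    )
    grid <- arrange(grid, .data$strain, .data$condition, .data$replicate)
    mu <- cal$broth_means[cbind(grid$strain, grid$condition)]
    la <- log1p(mu) + rnorm(nrow(grid), 0, cfg$noise_sd$broth)
    val <- truncate0(expm1(la))
    assay_table(tibble(
      strain = grid$strain, assay = "phosphate_broth", condition = grid$condition,
      unit = paste(grid$strain, grid$condition, grid$replicate, sep = "_"),
      replicate = grid$replicate, time_h = 0, value = val$value,
      value_kind = "concentration_mg_per_L", truncated = val$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the CAS siderophore assay
#'
#' Blank-zeroed absorbances at 630 nm calibrated to 0.861 / 0.884 / 0.594, so
#' the x100 rule reproduces capture percentages of 86.1 / 88.4 / 59.4.
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] of absorbance rows.
#' @export
generate_cas_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "cas"), {
    grid <- tidyr::expand_grid(strain = cfg$strains,
                               replicate = seq_len(cfg$n_replicates))
    mu <- cal$cas_abs[grid$strain]
    val <- truncate0(mu + rnorm(nrow(grid), 0, cfg$noise_sd$cas))
    assay_table(tibble(
      strain = grid$strain, assay = "cas", condition = "IDM",
      unit = paste(grid$strain, grid$replicate, sep = "_"),
      replicate = grid$replicate, time_h = 0, value = pmin(val$value, 4),
      value_kind = "absorbance", truncated = val$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the motility assays (swimming and surface spreading)
#'
#' Swimming halo areas at 24/48 h with near-equal strain means (the assay
#' discriminates motility presence, not strain differences), and surface
#' spreading areas at 24/48/72/96 h growing linearly in time on the log1p
#' scale with a strain-specific rate — the L3-like strain spreads fastest.
#' Spreading plates carry repeated measures (random intercept per plate).
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] with assays `swimming` and `surface_spreading`.
#' @export
generate_motility_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "motility"), {
    swim <- tidyr::expand_grid(
      strain = cfg$strains, replicate = seq_len(cfg$n_replicates),
      time_h = as.numeric(names(cal$swim_time_factor))
    )
    swim <- arrange(swim, .data$strain, .data$replicate, .data$time_h)
    la <- log1p(cal$swim_area48[swim$strain] *
                  cal$swim_time_factor[as.character(swim$time_h)]) +
      rnorm(nrow(swim), 0, cfg$noise_sd$motility)
    sw_val <- truncate0(expm1(la))
    swim_tbl <- tibble(
      strain = swim$strain, assay = "swimming", condition = "BM",
      unit = paste("sw", swim$strain, swim$replicate, sep = "_"),
      replicate = swim$replicate, time_h = swim$time_h, value = sw_val$value,
      value_kind = "area_cm2", truncated = sw_val$truncated
    )
    spread <- tidyr::expand_grid(
      strain = cfg$strains, replicate = seq_len(cfg$n_replicates),
      time_h = cal$spread_times
    )
    spread <- arrange(spread, .data$strain, .data$replicate, .data$time_h)
    spread$unit <- paste("ss", spread$strain, spread$replicate, sep = "_")
    units <- unique(spread$unit)
    b <- setNames(rnorm(length(units), 0, cfg$plate_sd$spreading), units)
    la <- cal$spread_intercept + cal$spread_slope[spread$strain] * spread$time_h +
      b[spread$unit] + rnorm(nrow(spread), 0, cfg$noise_sd$motility)
    sp_val <- truncate0(expm1(la))
    spread_tbl <- tibble(
      strain = spread$strain, assay = "surface_spreading", condition = "MMS",
      unit = spread$unit, replicate = spread$replicate, time_h = spread$time_h,
      value = sp_val$value, value_kind = "area_cm2", truncated = sp_val$truncated
    )
    assay_table(bind_rows(swim_tbl, spread_tbl), strains = cfg$strains)
  })
}

#' Generate the hydrogen-peroxide sensitivity assay
#'
#' Growth-inhibition halo areas at five H2O2 concentrations, increasing with
#' concentration on the log1p scale; the B02-like strain has the smallest
#' halos (most resistant). The concentration in mM is encoded in `condition`
#' (e.g. `"5mM"`).
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] of inhibition-halo areas at 48 h.
#' @export
generate_ros_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "ros"), {
    grid <- tidyr::expand_grid(
      strain = cfg$strains, conc = cal$ros_concs,
      replicate = seq_len(cfg$n_replicates)
    )
    grid <- arrange(grid, .data$strain, .data$conc, .data$replicate)
    la <- cal$ros_intercept[grid$strain] + cal$ros_conc_slope * grid$conc +
      rnorm(nrow(grid), 0, cfg$noise_sd$ros)
    val <- truncate0(expm1(la))
    assay_table(tibble(
      strain = grid$strain, assay = "ros", condition = sprintf("%gmM", grid$conc),
      unit = paste("ros", grid$strain, grid$conc, grid$replicate, sep = "_"),
      replicate = grid$replicate, time_h = 48, value = val$value,
      value_kind = "area_cm2", truncated = val$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the biofilm formation assay
#'
#' Endpoint crystal-violet absorbances per condition (control MMS, acidic pH,
#' phosphorus fertilizer, high temperature), calibrated cell-by-cell to the
#' printed condition means; replicate noise is the printed standard error
#' times sqrt(3). Only the B02-like strain loses biofilm at high temperature.
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] of absorbance rows.
#' @export
generate_biofilm_assay <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  with_stream(assay_seed(cfg, "biofilm"), {
    grid <- tidyr::expand_grid(
      strain = cfg$strains, condition = colnames(cal$biofilm_means),
      replicate = seq_len(cfg$n_replicates)
    )
    grid <- arrange(grid, .data$strain, .data$condition, .data$replicate)
    mu <- cal$biofilm_means[cbind(grid$strain, grid$condition)]
    sd_cell <- if (is.null(cfg$noise_sd$biofilm)) {
      cal$biofilm_se[cbind(grid$strain, grid$condition)] * sqrt(3)
    } else {
      rep(cfg$noise_sd$biofilm, nrow(grid))
    }
    val <- truncate0(mu + rnorm(nrow(grid), 0, sd_cell))
    assay_table(tibble(
      strain = grid$strain, assay = "biofilm", condition = grid$condition,
      unit = paste("bf", grid$strain, grid$condition, grid$replicate, sep = "_"),
      replicate = grid$replicate, time_h = 0, value = pmin(val$value, 4),
      value_kind = "absorbance", truncated = val$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the Biolog Eco-plate assay
#'
#' Per-substrate OD time series, linear in time with a per-(strain,
#' substrate) true slope: zero for unusable substrates, and for usable ones
#' the base slope (0.01 OD/h) scaled by a strain multiplier — the L3-like
#' strain degrades fastest. Each strain has `n_replicates` plates with a
#' shared random intercept; reads at 12-h intervals to 72 h plus 84 h.
#'
#' @param cfg A [synthetic_config()].
#' @return An [assay_table()] of OD rows, one series per plate x substrate.
#' @export
generate_ecoplate <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cal <- cfg$calibration
  pattern <- cfg$usable_pattern
  with_stream(assay_seed(cfg, "ecoplate"), {
    grid <- tidyr::expand_grid(
      strain = cfg$strains, plate = seq_len(cfg$n_replicates),
      substrate = colnames(pattern), time_h = cfg$ecoplate_timepoints
    )
    grid <- arrange(grid, .data$strain, .data$plate, .data$substrate, .data$time_h)
    grid$unit <- paste("eco", grid$strain, grid$plate, sep = "_")
    usable <- pattern[cbind(grid$strain, grid$substrate)]
    slope <- ifelse(usable,
                    cal$eco_base_slope * cal$eco_strain_mult[grid$strain], 0)
    units <- unique(grid$unit)
    b <- setNames(rnorm(length(units), 0, cfg$plate_sd$ecoplate), units)
    od <- cal$eco_baseline_od + b[grid$unit] + slope * grid$time_h +
      rnorm(nrow(grid), 0, cfg$noise_sd$ecoplate)
    val <- truncate0(od)
    assay_table(tibble(
      strain = grid$strain, assay = "ecoplate", condition = grid$substrate,
      unit = grid$unit, replicate = grid$plate, time_h = grid$time_h,
      value = pmin(val$value, 4), value_kind = "od", truncated = val$truncated
    ), strains = cfg$strains)
  })
}

#' Generate the complete synthetic study
#'
#' One call produces every assay table plus the matching attribute specs and
#' scenario weights, so the full pipeline (estimate, score, rank) runs
#' end-to-end with no external inputs.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_study`: `tables` (named list of
#'   [assay_table()]s), `attributes`, `scenarios`, `config`.
#' @export
generate_full_study <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tables <- list(
    halo = generate_halo_assay(cfg),
    broth = generate_broth_solubilization(cfg),
    cas = generate_cas_assay(cfg),
    motility = generate_motility_assay(cfg),
    ros = generate_ros_assay(cfg),
    biofilm = generate_biofilm_assay(cfg),
    ecoplate = generate_ecoplate(cfg)
  )
  structure(list(tables = tables, attributes = default_attribute_specs(),
                 scenarios = scenario_weights(), config = cfg),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes one long CSV per assay, the MAUT YAML config, and a JSON manifest
#' recording the seed, the configuration summary and an md5 checksum per
#' file (so identical seeds are verifiably byte-identical).
#'
#' @param study A [generate_full_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(study$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_assay_table(study$tables[[nm]], p)
    paths[nm] <- p
  }
  cfg_path <- file.path(dir, "maut_config.yaml")
  write_maut_config(study$attributes, study$scenarios, cfg_path)
  paths["maut_config"] <- cfg_path
  manifest <- list(
    seed = study$config$seed,
    n_strains = study$config$n_strains,
    n_replicates = study$config$n_replicates,
    strains = study$config$strains,
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  paths["manifest"] <- mpath
  invisible(paths)
}

#' Simulate and write a study in one step
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
simulate_study <- function(cfg = synthetic_config(), dir) {
  write_study(generate_full_study(cfg), dir)
}
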