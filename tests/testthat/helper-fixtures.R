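# Shared fixtures and independent oracles, built in code at test time.

# Closed-form OLS via the normal equations: the independent oracle for the
# package's least-squares path.
ols_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Unbalanced two-factor fixture (<= 50 rows) with known cell means.
two_factor_fixture <- function(seed = 402) {
  set.seed(seed)
  cells <- expand.grid(f = c("a", "b"), g = c("c", "d"),
                       stringsAsFactors = FALSE)
  cells$mu <- c(1, 3, 2, 7)
  cells$n <- c(2, 4, 4, 2)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(f = cells$f[i], g = cells$g[i],
               value = cells$mu[i] + rnorm(cells$n[i], sd = 0.3))
  }))
  tibble::as_tibble(rows)
}

# Random-intercept fixture with known variance components.
lmm_fixture <- function(seed = 7, n_units = 30, n_per = 5,
                        sigma2_b = 0.5, sigma2_e = 0.1) {
  set.seed(seed)
  u <- rep(sprintf("u%02d", seq_len(n_units)), each = n_per)
  b <- rep(rnorm(n_units, 0, sqrt(sigma2_b)), each = n_per)
  x <- rep(seq_len(n_per), n_units)
  tibble::tibble(u = u, x = x,
                 value = 1 + 0.5 * x + b + rnorm(length(u), 0, sqrt(sigma2_e)))
}

# One Eco-plate style OD series: n_plates units measured at `times`,
# slope * t + plate intercept + noise.
od_series <- function(slope, times = c(12, 24, 36, 48, 60, 72, 84),
                      n_plates = 3, noise_sd = 0, plate_sd = 0,
                      baseline = 0.05, seed = NULL,
                      strain = "X", substrate = "sub") {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(plate = seq_len(n_plates), time_h = times)
  b <- rnorm(n_plates, 0, plate_sd)
  od <- baseline + b[grid$plate] + slope * grid$time_h +
    rnorm(nrow(grid), 0, noise_sd)
  assay_table(tibble::tibble(
    strain = strain, assay = "ecoplate", condition = substrate,
    unit = paste0("p", grid$plate), replicate = grid$plate,
    time_h = grid$time_h, value = pmax(od, 0), value_kind = "od"
  ))
}

# Synthetic config with every noise source switched off.
noiseless_config <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    noise_sd = list(halo = 0, broth = 0, cas = 0, motility = 0, ros = 0,
                    biofilm = 0, ecoplate = 0),
    plate_sd = list(halo = 0, spreading = 0, ecoplate = 0),
    ...
  )
}

# Random valid attribute-spec anchors for property tests.
random_anchor <- function() {
  v_min <- runif(1, -5, 5)
  range <- runif(1, 0.5, 10)
  frac <- runif(1, 0.05, 0.95)
  list(v_min = v_min, v_mid = v_min + frac * range, v_max = v_min + range)
}
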