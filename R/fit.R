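#' Fit a linear or random-intercept mixed model to an assay table
#'
#' Ordinary least squares when the [model_spec()] has no random intercept;
#' otherwise a Gaussian random-intercept model estimated by REML, profiled
#' down to a one-dimensional optimization over the variance ratio
#' `lambda = sigma_b^2 / sigma_e^2`. With a single grouping term the marginal
#' covariance is `sigma_e^2 (I + lambda Z Z')`, whose inverse and determinant
#' have closed forms in the group sizes, so each profile evaluation is cheap.
#'
#' Inference on fixed-effect contrasts uses the residual t distribution for
#' OLS and a Satterthwaite-style approximation for mixed fits: the degrees of
#' freedom of a contrast `c'beta` are `2 f^2 / Var(f)` where
#' `f = Var(c'beta)` as a function of the variance components and `Var(f)` is
#' obtained by the delta method from the inverse curvature of the REML
#' deviance. When the grouping variance collapses to zero the fit degrades
#' gracefully to the OLS answer.
#'
#' @param data A data frame (typically an [assay_table()]).
#' @param spec A [model_spec()].
#'
#' @return An object of class `assay_fit` with elements `coefficients`,
#'   `vcov`, `sigma2`, `group_variance`, `residual_df`, `n_obs`, and the
#'   design information needed by [marginal_means()] and [tukey_pairwise()].
#' @export
fit_assay_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as_tibble(data)
  needed <- c(spec$response, spec$fixed_factors, spec$covariates,
              spec$random_intercept)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort_rhz(paste0("Column(s) not in data: ", paste(missing_cols, collapse = ", ")),
              "schema_error")
  }
  df <- data[needed]
  for (f in spec$fixed_factors) {
    lv <- sort(unique(as.character(df[[f]])))
    if (length(lv) < 2) {
      abort_rhz(paste0("Fixed factor '", f, "' has fewer than 2 levels."),
                "design_error")
    }
    df[[f]] <- factor(as.character(df[[f]]), levels = lv)
  }
  y <- df[[spec$response]]
  if (!is.numeric(y)) abort_rhz("Response must be numeric.", "schema_error")
  if (spec$transform == "log1p") y <- log1p_transform(y)

  mt <- delete.response(terms(as.formula(paste("~", spec_rhs(spec)))))
  X <- model.matrix(mt, df)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort_rhz("More coefficients than observations.", "design_error")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort_rhz(paste0("Rank-deficient design; aliased term(s): ",
                     paste(aliased, collapse = ", ")), "singular_error")
  }

  xlevels <- lapply(df[spec$fixed_factors], levels)
  names(xlevels) <- spec$fixed_factors
  cov_means <- vapply(spec$covariates, function(cv) mean(df[[cv]]), 0)

  fit <- list(spec = spec, terms = mt, xlevels = xlevels,
              cov_means = cov_means, X = X, y = y, n_obs = n)

  if (is.null(spec$random_intercept)) {
    beta <- qr.coef(qrX, y)
    r <- y - X %*% beta
    rss <- sum(r^2)
    if (rss < 1e-20 * max(1, sum(y^2))) rss <- 0  # numerically exact fit
    sigma2 <- rss / (n - p)
    XtXinv <- chol2inv(qr.R(qrX))
    dimnames(XtXinv) <- list(colnames(X), colnames(X))
    fit <- c(fit, list(
      coefficients = setNames(as.numeric(beta), colnames(X)),
      vcov = sigma2 * XtXinv, sigma2 = sigma2, group_variance = NULL,
      lambda = NULL, group = NULL, residual_df = n - p
    ))
  } else {
    g <- factor(as.character(df[[spec$random_intercept]]))
    gi <- as.integer(g)
    res <- reml_random_intercept(y, X, gi)
    fit <- c(fit, list(
      coefficients = setNames(res$beta, colnames(X)),
      vcov = res$vcov, sigma2 = res$sigma2, group_variance = res$sigma2_b,
      lambda = res$lambda, group = gi, residual_df = n - p
    ))
    dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  }
  structure(fit, class = "assay_fit")
}

# ---- REML machinery ---------------------------------------------------------

# Multiply V0(lambda)^{-1} = (I + lambda Z Z')^{-1} by a matrix, using the
# Woodbury identity specialized to indicator Z: only group sums are needed.
v0inv_mult <- function(A, gi, ng, lambda) {
  ZA <- rowsum(A, gi)
  w <- lambda / (1 + lambda * ng)
  A - (w * ZA)[gi, , drop = FALSE]
}

reml_random_intercept <- function(y, X, gi) {
  n <- length(y)
  p <- ncol(X)
  ng <- tabulate(gi)
  Y <- cbind(y)

  pieces <- function(lambda) {
    ViX <- v0inv_mult(X, gi, ng, lambda)
    XtViX <- crossprod(X, ViX)
    beta <- solve(XtViX, crossprod(ViX, y))
    r <- as.numeric(y - X %*% beta)
    q <- sum(r * v0inv_mult(cbind(r), gi, ng, lambda))
    list(XtViX = XtViX, beta = as.numeric(beta), q = q)
  }
  crit <- function(loglam) {
    lambda <- exp(loglam)
    pc <- pieces(lambda)
    sig2 <- pc$q / (n - p)
    (n - p) * log(sig2) + sum(log1p(lambda * ng)) +
      as.numeric(determinant(pc$XtViX, logarithm = TRUE)$modulus)
  }

  # Exact-fit guard: a noiseless response makes the profile degenerate.
  ols <- qr(X)
  r0 <- y - X %*% qr.coef(ols, y)
  if (sum(r0^2) / max(1, n - p) < 1e-20) {
    XtXinv <- chol2inv(qr.R(ols))
    return(list(beta = as.numeric(qr.coef(ols, y)), vcov = 0 * XtXinv,
                sigma2 = 0, sigma2_b = 0, lambda = 0))
  }

  opt <- optimize(crit, c(-15, 15), tol = 1e-9)
  lambda <- exp(opt$minimum)
  if (opt$minimum <= -14.5) lambda <- 0  # boundary: no grouping variance
  pc <- pieces(lambda)
  sigma2 <- pc$q / (n - p)
  vcov <- sigma2 * solve(pc$XtViX)
  list(beta = pc$beta, vcov = vcov, sigma2 = sigma2,
       sigma2_b = lambda * sigma2, lambda = lambda)
}

# -2 REML log-likelihood (up to an additive constant) as a function of
# theta = (sigma_e^2, sigma_b^2); used for the Satterthwaite curvature.
reml_m2ll_theta <- function(theta, y, X, gi, ng) {
  n <- length(y)
  p <- ncol(X)
  lambda <- theta[2] / theta[1]
  ViX <- v0inv_mult(X, gi, ng, lambda)
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- as.numeric(y - X %*% beta)
  q <- sum(r * v0inv_mult(cbind(r), gi, ng, lambda))
  (n - p) * log(theta[1]) + sum(log1p(lambda * ng)) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + q / theta[1]
}

# Var(c'beta) as a function of theta, for the delta-method gradient.
contrast_var_theta <- function(theta, L, X, gi, ng) {
  lambda <- theta[2] / theta[1]
  ViX <- v0inv_mult(X, gi, ng, lambda)
  XtViX <- crossprod(X, ViX)
  as.numeric(theta[1] * (L %*% solve(XtViX, L)))
}

# Satterthwaite-style degrees of freedom for a single contrast row L.
contrast_df <- function(fit, L) {
  if (is.null(fit$group)) return(fit$residual_df)
  th <- c(fit$sigma2, fit$group_variance)
  if (th[1] <= 0) return(fit$residual_df)
  if (th[2] <= 1e-10 * th[1]) return(fit$residual_df)
  gi <- fit$group
  ng <- tabulate(gi)
  X <- fit$X
  y <- fit$y
  f0 <- contrast_var_theta(th, L, X, gi, ng)
  h <- pmax(abs(th) * 1e-4, 1e-10)
  grad <- numeric(2)
  H <- matrix(0, 2, 2)
  m2 <- function(t2) reml_m2ll_theta(t2, y, X, gi, ng)
  f <- function(t2) contrast_var_theta(t2, L, X, gi, ng)
  e <- diag(2)
  m0 <- m2(th)
  for (i in 1:2) {
    tp <- th + h[i] * e[, i]; tm <- pmax(th - h[i] * e[, i], th * 1e-3)
    hi <- tp[i] - tm[i]
    grad[i] <- (f(tp) - f(tm)) / hi
    H[i, i] <- (m2(tp) - 2 * m0 + m2(tm)) / ((hi / 2)^2)
  }
  tpp <- th + h; tpm <- th + c(h[1], -h[2]); tmp <- th + c(-h[1], h[2]); tmm <- th - h
  H[1, 2] <- H[2, 1] <- (m2(tpp) - m2(tpm) - m2(tmp) + m2(tmm)) / (4 * h[1] * h[2])
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A)) return(fit$residual_df)
  denom <- as.numeric(t(grad) %*% A %*% grad)
  if (!is.finite(denom) || denom <= 0) return(fit$residual_df)
  df <- 2 * f0^2 / denom
  min(max(df, 1), fit$residual_df)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.assay_fit <- function(x, ...) {
  kind <- if (is.null(x$group)) "linear model (OLS)" else "random-intercept mixed model (REML)"
  cat("<assay_fit> ", kind, "\n", sep = "")
  cat("  response: ", x$spec$response,
      if (x$spec$transform == "log1p") " (log1p scale)" else "", "\n", sep = "")
  cat("  n = ", x$n_obs, ", coefficients = ", length(x$coefficients), "\n", sep = "")
  if (!is.null(x$group_variance)) {
    cat("  sigma2 = ", signif(x$sigma2, 4), ", group variance = ",
        signif(x$group_variance, 4), "\n", sep = "")
  } else {
    cat("  sigma2 = ", signif(x$sigma2, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an assay model fit
#'
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald t/z), `p.value`.
#' @export
tidy.assay_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- ifelse(se > 0, x$coefficients / se,
                 ifelse(x$coefficients == 0, 0, Inf))
  df <- x$residual_df
  tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = se,
    statistic = stat,
    p.value = 2 * pt(abs(stat), df, lower.tail = FALSE)
  )
}

#' Glance at an assay model fit
#'
#' @param x An `assay_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_obs`, `df.residual`, `sigma2`,
#'   `group_variance`, `transform`.
#' @export
glance.assay_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    df.residual = x$residual_df,
    sigma2 = x$sigma2,
    group_variance = x$group_variance %||% NA_real_,
    transform = x$spec$transform
  )
}
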