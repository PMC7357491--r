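#' Estimated marginal (adjusted) means
#'
#' Model-based means for the levels of one factor, or for the cell
#' combinations of several factors, averaging over the levels of every other
#' fixed factor with equal weight and holding continuous covariates at their
#' observed means. These are the "adjusted means" used as performance values
#' downstream. Standard errors come from the coefficient covariance; degrees
#' of freedom are the residual df for OLS fits and the Satterthwaite-style
#' approximation for mixed fits.
#'
#' @param fit An [fit_assay_model()] result.
#' @param factors Character vector of fixed factors defining the levels
#'   (`NULL` for the overall adjusted mean). All must be in the fitted design.
#'
#' @return A tibble of class `marginal_means`: one row per level
#'   (combination), columns `level`, one column per requested factor,
#'   `estimate` (model scale), `se`, `df`.
#' @export
marginal_means <- function(fit, factors = NULL) {
  stopifnot(inherits(fit, "assay_fit"))
  Linfo <- mm_contrasts(fit, factors)
  L <- Linfo$L
  est <- as.numeric(L %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((L %*% fit$vcov) * L)))
  df <- vapply(seq_len(nrow(L)), function(i) contrast_df(fit, L[i, ]), 0)
  out <- dplyr::bind_cols(
    tibble(level = Linfo$labels),
    Linfo$level_cols,
    tibble(estimate = est, se = se, df = df)
  )
  class(out) <- c("marginal_means", class(out))
  attr(out, "factors") <- factors
  attr(out, "L") <- L
  out
}

# Build the averaging contrast matrix for marginal means: one row per level
# (combination) of `factors`, averaging the full reference grid.
mm_contrasts <- function(fit, factors) {
  factors <- factors %||% character()
  unknown <- setdiff(factors, names(fit$xlevels))
  if (length(unknown) > 0) {
    abort_rhz(paste0("Factor(s) not in the fitted design: ",
                     paste(unknown, collapse = ", ")), "key_error")
  }
  grid_vars <- fit$xlevels
  grid <- if (length(grid_vars) == 0) {
    data.frame(row.names = 1)
  } else {
    expand.grid(grid_vars, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  for (f in names(fit$xlevels)) {
    grid[[f]] <- factor(grid[[f]], levels = fit$xlevels[[f]])
  }
  for (cv in names(fit$cov_means)) grid[[cv]] <- fit$cov_means[[cv]]
  Xg <- model.matrix(fit$terms, grid, xlev = fit$xlevels)

  if (length(factors) == 0) {
    L <- matrix(colMeans(Xg), nrow = 1, dimnames = list(NULL, colnames(Xg)))
    return(list(L = L, labels = "(overall)", level_cols = NULL))
  }
  combos <- expand.grid(lapply(fit$xlevels[factors], identity),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  labels <- do.call(paste, c(combos, sep = ":"))
  L <- matrix(0, nrow(combos), ncol(Xg), dimnames = list(labels, colnames(Xg)))
  for (i in seq_len(nrow(combos))) {
    keep <- rep(TRUE, nrow(grid))
    for (f in factors) keep <- keep & grid[[f]] == combos[i, f]
    L[i, ] <- colMeans(Xg[keep, , drop = FALSE])
  }
  names(combos) <- factors
  list(L = L, labels = labels, level_cols = as_tibble(combos))
}

#' Tukey all-pairs comparisons with compact letters
#'
#' All pairwise differences between the marginal means of a factor (or cell
#' combinations of several factors), with studentized-range adjusted p-values
#' (`ptukey` over `k` means) and a compact letter display at `alpha`: levels
#' sharing a letter do not differ significantly. With `k = 2` the adjusted
#' p-value coincides with the pooled two-sided t-test. Letters are built by
#' the insertion-absorption algorithm over the significant-pair graph, with
#' ties broken by level order, so the display is deterministic.
#'
#' @inheritParams marginal_means
#' @param alpha Significance level in (0, 1), default 0.05.
#'
#' @return A tibble of class `tukey_pairwise`: `level_a`, `level_b`,
#'   `difference`, `se`, `statistic` (t), `df`, `p_adjusted`. The letter
#'   display is available via [cld_letters()] (also stored as the `letters`
#'   attribute).
#' @export
tukey_pairwise <- function(fit, factors, alpha = 0.05) {
  stopifnot(inherits(fit, "assay_fit"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_rhz("alpha must lie in (0, 1).", "domain_error")
  }
  mm <- marginal_means(fit, factors)
  L <- attr(mm, "L")
  k <- nrow(mm)
  if (k < 2) abort_rhz("Need at least 2 levels for pairwise comparisons.", "design_error")
  pairs <- utils::combn(k, 2)
  tol <- 1e-10 * max(1, max(abs(mm$estimate)))
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    Ld <- L[i1, ] - L[i2, ]
    diff <- sum(Ld * fit$coefficients)
    se <- sqrt(max(0, as.numeric(t(Ld) %*% fit$vcov %*% Ld)))
    df <- contrast_df(fit, Ld)
    tstat <- if (se > tol) diff / se else if (abs(diff) <= tol) 0 else
      sign(diff) * Inf
    p <- if (is.infinite(tstat)) 0 else
      ptukey(sqrt(2) * abs(tstat), nmeans = k, df = df, lower.tail = FALSE)
    tibble(level_a = mm$level[i1], level_b = mm$level[i2],
           difference = diff, se = se, statistic = tstat, df = df,
           p_adjusted = p)
  })
  sig <- which(res$p_adjusted < alpha)
  letters_tbl <- tibble(
    level = mm$level,
    estimate = mm$estimate,
    letters = cld_insert_absorb(k, pairs[, sig, drop = FALSE])
  )
  class(res) <- c("tukey_pairwise", class(res))
  attr(res, "letters") <- letters_tbl
  attr(res, "alpha") <- alpha
  res
}

#' Compact letter display of a Tukey comparison
#'
#' @param x A [tukey_pairwise()] result.
#' @return A tibble with `level`, `estimate` (model scale) and `letters`.
#' @export
cld_letters <- function(x) {
  stopifnot(inherits(x, "tukey_pairwise"))
  attr(x, "letters")
}

# Insertion-absorption compact letter display. `sig` is a 2 x m matrix of
# significantly different level index pairs. Returns one letter string per
# level; levels sharing a letter are not significantly different.
cld_insert_absorb <- function(k, sig) {
  cols <- list(seq_len(k))
  if (ncol(sig) > 0) {
    for (j in seq_len(ncol(sig))) {
      i1 <- sig[1, j]; i2 <- sig[2, j]
      nxt <- list()
      for (col in cols) {
        if (i1 %in% col && i2 %in% col) {
          nxt <- c(nxt, list(setdiff(col, i1), setdiff(col, i2)))
        } else {
          nxt <- c(nxt, list(col))
        }
      }
      nxt <- nxt[lengths(nxt) > 0]
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(nxt))
      for (a in seq_along(nxt)) {
        for (b in seq_along(nxt)) {
          if (a != b && keep[a] && keep[b] && all(nxt[[a]] %in% nxt[[b]]) &&
              (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- nxt[keep]
    }
  }
  ord <- order(vapply(cols, min, 0L), vapply(cols, paste, "", collapse = ","))
  cols <- cols[ord]
  lab <- make_letter_labels(length(cols))
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- paste(lab[vapply(cols, function(cl) i %in% cl, TRUE)], collapse = "")
  }
  out
}

make_letter_labels <- function(m) {
  if (m <= 26) return(LETTERS[seq_len(m)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(m)]
}
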