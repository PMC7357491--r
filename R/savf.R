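#' Solve the curvature of an exponential single-attribute value function
#'
#' The exponential single-attribute value function (SAVF) used to homogenize
#' performance values into 0-1 scores is
#' \deqn{v(x) = \frac{1 - e^{-(x - v_{min})/\rho}}{1 - e^{-(v_{max} - v_{min})/\rho}}}
#' with curvature constant \eqn{\rho} elicited from a midpoint anchor: \eqn{\rho}
#' is the value for which \eqn{v(v_{mid}) = 0.5}. Positive \eqn{\rho} gives a
#' concave (diminishing-returns) function, negative \eqn{\rho} a convex one.
#' When the midpoint sits exactly halfway between the anchors the function is
#' linear, which corresponds to \eqn{|\rho| \to \infty}; that limit is
#' returned as `Inf`.
#'
#' The curvature is found by bisection on the signed ratio
#' `(v_max - v_min) / rho` over `[1e-6, 1e6]`, to a midpoint tolerance of
#' 1e-10.
#'
#' @param v_min,v_mid,v_max Anchors on the measurement scale; must satisfy
#'   `v_min < v_mid < v_max`.
#' @param tol Relative tolerance on `v_mid` for declaring the linear limit
#'   (default 1e-8 of the anchor range).
#'
#' @return The curvature `rho` (nonzero real), or `Inf` for the linear limit.
#' @export
#' @examples
#' solve_curvature(0, 0.5, 1) # Inf: linear
#' rho <- solve_curvature(0, 0.25, 1) # concave
solve_curvature <- function(v_min, v_mid, v_max, tol = 1e-8) {
  check_anchors(v_min, v_mid, v_max)
  range <- v_max - v_min
  m <- (v_mid - v_min) / range
  if (abs(m - 0.5) < tol) return(Inf)
  # g(R) = normalized value at the midpoint minus 0.5, R = range / rho.
  gfun <- function(R) (1 - exp(-m * R)) / (1 - exp(-R)) - 0.5
  solve_R <- function(lo, hi) {
    flo <- gfun(lo)
    for (i in 1:300) {
      mid <- (lo + hi) / 2
      fm <- gfun(mid)
      if (abs(fm) < 1e-13 || (hi - lo) < 1e-15 * max(1, abs(mid))) return(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    mid
  }
  if (m < 0.5) {
    R <- solve_R(1e-6, 1e6)   # concave: rho > 0
  } else {
    # convex case via the mirror symmetry v(x; R) = 1 - v(1 - x; -R)
    m2 <- 1 - m
    gfun <- function(R) (1 - exp(-m2 * R)) / (1 - exp(-R)) - 0.5
    R <- -solve_R(1e-6, 1e6)
  }
  range / R
}

check_anchors <- function(v_min, v_mid, v_max) {
  if (!(v_min < v_max) || !(v_min < v_mid) || !(v_mid < v_max)) {
    abort_rhz("Anchors must satisfy v_min < v_mid < v_max.", "domain_error")
  }
  invisible(TRUE)
}

#' Score a performance value with an exponential SAVF
#'
#' Evaluates the exponential single-attribute value function defined by the
#' min/mid/max anchors (see [solve_curvature()]) at `x`, returning a score in
#' `[0, 1]`. For `direction = "increasing"` the score rises from 0 at `v_min`
#' to 1 at `v_max` through 0.5 at `v_mid`; for `direction = "decreasing"` the
#' preference is reversed by evaluating the same function at
#' `v_min + v_max - x` (anchors stay on the measurement scale). Performance
#' values outside `[v_min, v_max]` are clamped to the interval before
#' evaluation: the anchors are elicited bounds and extrapolation beyond them
#' is undefined.
#'
#' @param x Numeric performance value(s).
#' @param v_min,v_mid,v_max Anchors, as in [solve_curvature()].
#' @param direction `"increasing"` (default) or `"decreasing"`.
#' @param rho Optional pre-solved curvature (from [solve_curvature()] with the
#'   same anchors); solved on the fly when `NULL`.
#'
#' @return Scores in `[0, 1]`.
#' @export
#' @examples
#' savf_score(c(0, 0.5, 1), 0, 0.5, 1) # 0, 0.5, 1 (linear)
savf_score <- function(x, v_min, v_mid, v_max,
                       direction = c("increasing", "decreasing"), rho = NULL) {
  direction <- match.arg(direction)
  check_anchors(v_min, v_mid, v_max)
  if (is.null(rho)) rho <- solve_curvature(v_min, v_mid, v_max)
  x <- pmin(pmax(x, v_min), v_max)
  if (direction == "decreasing") x <- v_min + v_max - x
  if (is.infinite(rho)) {
    (x - v_min) / (v_max - v_min)
  } else {
    (1 - exp(-(x - v_min) / rho)) / (1 - exp(-(v_max - v_min) / rho))
  }
}
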