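# Uniform cubic B-spline curves: the fixed cubic basis, segment evaluators
# (polynomial and matrix forms, which must agree to 1e-12), and iterative
# least-squares fitting with chord-length parameterisation.

#' Uniform cubic B-spline basis
#'
#' The four cubic basis polynomials
#' `R0 = (-p^3 + 3p^2 - 3p + 1)/6`, `R1 = (3p^3 - 6p^2 + 4)/6`,
#' `R2 = (-3p^3 + 3p^2 + 3p + 1)/6`, `R3 = p^3/6`, which form a partition
#' of unity on `[0, 1]`.
#'
#' @param p parameter value(s) in `[0, 1]`.
#' @return a `length(p)` x 4 matrix of basis values.
#' @export
basis_3 <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  cbind(R0 = (-p^3 + 3 * p^2 - 3 * p + 1) / 6,
        R1 = (3 * p^3 - 6 * p^2 + 4) / 6,
        R2 = (-3 * p^3 + 3 * p^2 + 3 * p + 1) / 6,
        R3 = p^3 / 6)
}

# Coefficient matrix of the segment's matrix form:
# O_j3(p) = (1/6) [1 p p^2 p^3] M [O_j .. O_j+3]^T
BSPLINE_M <- matrix(c(1, 4, 1, 0,
                      -3, 0, 3, 0,
                      3, -6, 3, 0,
                      -1, 3, -3, 1), 4L, 4L, byrow = TRUE)

#' Construct a uniform cubic B-spline curve
#'
#' @param control m x d matrix of control points (`m >= 4`, `d` = 2 or 3).
#' @param closed whether the curve wraps (control indices taken modulo `m`).
#' @export
bspline_curve <- function(control, closed = FALSE) {
  control <- as.matrix(control)
  storage.mode(control) <- "double"
  if (nrow(control) < 4L) stop("need at least 4 control points")
  structure(list(control = control, degree = 3L, closed = closed),
            class = "bspline_curve")
}

#' @export
print.bspline_curve <- function(x, ...) {
  cat(sprintf("<bspline_curve: %d control points, degree 3, %s>\n",
              nrow(x$control), if (x$closed) "closed" else "open"))
  invisible(x)
}

n_segments <- function(curve) {
  m <- nrow(curve$control)
  if (curve$closed) m else m - 3L
}

segment_control <- function(curve, j) {
  m <- nrow(curve$control)
  if (curve$closed) {
    idx <- ((j - 1L + 0:3) %% m) + 1L
  } else {
    if (j < 1L || j > m - 3L) stop("segment index out of range on open curve")
    idx <- j:(j + 3L)
  }
  curve$control[idx, , drop = FALSE]
}

#' Evaluate one segment of a cubic B-spline (basis form)
#'
#' @param curve a [bspline_curve()].
#' @param j segment index (1-based).
#' @param p parameter value(s) in `[0, 1]`.
#' @export
eval_segment <- function(curve, j, p) {
  basis_3(p) %*% segment_control(curve, j)
}

#' Evaluate one segment via the matrix form
#'
#' `(1/6) [1 p p^2 p^3] M [O_j .. O_j+3]^T`; agrees with [eval_segment()]
#' to 1e-12.
#' @inheritParams eval_segment
#' @export
eval_segment_matrix <- function(curve, j, p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  P <- cbind(1, p, p^2, p^3)
  (P %*% BSPLINE_M %*% segment_control(curve, j)) / 6
}

#' Evaluate a curve at global parameters
#'
#' The parameter `t` in `[0, 1]` spans all segments; on a closed curve `t`
#' wraps modulo 1.
#'
#' @param curve a [bspline_curve()].
#' @param t numeric vector of global parameters.
#' @export
eval_curve <- function(curve, t) {
  t <- as.numeric(t)
  ns <- n_segments(curve)
  u <- if (curve$closed) (t %% 1) * ns else pmin(pmax(t, 0), 1) * ns
  j <- pmin(floor(u), ns - 1L)
  p <- u - j
  out <- matrix(0, length(t), ncol(curve$control))
  for (jj in unique(j)) {
    sel <- which(j == jj)
    out[sel, ] <- eval_segment(curve, jj + 1L, p[sel])
  }
  out
}

# Derivatives of the cubic basis with respect to p.
basis_3_d1 <- function(p) {
  cbind((-3 * p^2 + 6 * p - 3) / 6,
        (9 * p^2 - 12 * p) / 6,
        (-9 * p^2 + 6 * p + 3) / 6,
        3 * p^2 / 6)
}

basis_3_d2 <- function(p) {
  cbind(1 - p, 3 * p - 2, 1 - 3 * p, p)
}

# Design matrix mapping control points to curve points (or their first or
# second parameter derivatives) at global params t.
curve_design <- function(t, m, closed, deriv = 0L) {
  ns <- if (closed) m else m - 3L
  u <- if (closed) (t %% 1) * ns else pmin(pmax(t, 0), 1) * ns
  j <- pmin(floor(u), ns - 1L)
  B <- switch(deriv + 1L, basis_3(u - j), basis_3_d1(u - j),
              basis_3_d2(u - j)) * ns^deriv
  A <- matrix(0, length(t), m)
  for (k in 0:3) {
    col <- if (closed) ((j + k) %% m) + 1L else j + k + 1L
    A[cbind(seq_along(t), col)] <- A[cbind(seq_along(t), col)] + B[, k + 1L]
  }
  A
}

# Finite-difference penalty on the control polygon. Order 2 (default)
# shrinks toward straight polygons; order 3 shrinks toward locally
# quadratic ones, i.e. it continues the surrounding curvature across data
# gaps -- the right prior when bridging holes in a ring.
diff_penalty <- function(m, closed, order = 2L) {
  w <- if (order == 2L) c(1, -2, 1) else c(1, -3, 3, -1)
  k <- length(w)
  if (closed) {
    D <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(k)) D[i, ((i + j - 2L) %% m) + 1L] <- w[j]
    }
  } else {
    if (m < k) return(matrix(0, m, m))
    D <- matrix(0, m - k + 1L, m)
    for (i in seq_len(m - k + 1L)) D[i, i + seq_len(k) - 1L] <- w
  }
  crossprod(D)
}

#' Least-squares fit of a uniform cubic B-spline
#'
#' Data points are parameterised by normalised chord length; `iterations`
#' rounds of parameter correction (foot-point reassignment against a dense
#' curve sampling) alternate with linear least-squares refits. The residual
#' RMS is guaranteed non-increasing: a correction round that fails to
#' improve it is rolled back and iteration stops.
#'
#' @param points n x d matrix of ordered data points (`n >= 4`); order along
#'   the curve (by angle about the centroid for closed slices, by the
#'   secondary axis for open profiles) is the caller's contract.
#' @param n_control requested number of control points; reduced (with a
#'   warning) when the data has fewer points.
#' @param iterations parameter-correction rounds.
#' @param closed fit a closed (wrapping) curve.
#' @param lambda relative weight of the control-polygon difference penalty
#'   (scaled by `mean(diag(A'A))`). It stabilises control points that fall
#'   in data gaps, where the least-squares problem alone is singular;
#'   gap-bridging fits (hole repair) should use a larger value than dense
#'   fits.
#' @param params optional initial data parameters in `[0, 1]` (e.g. the
#'   normalised polar angle of ring slabs); `NULL` = normalised chord
#'   length.
#' @param penalty_order 2 (shrink toward straight control polygons) or
#'   3 (shrink toward continued curvature; use for hole bridging).
#' @return a [bspline_curve()] with attributes `"rms"` (residual RMS) and
#'   `"params"` (final data parameters).
#' @export
fit_curve <- function(points, n_control, iterations = 10, closed = FALSE,
                      lambda = 1e-6, params = NULL, penalty_order = 2L) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 points to fit a cubic B-spline")
  if (n_control > n) {
    warning("reducing control count from ", n_control, " to ", n,
            " (fewer data points than controls)")
    n_control <- n
  }
  n_control <- max(4L, as.integer(n_control))
  if (is.null(params)) {
    # chord-length parameterisation
    seg <- sqrt(rowSums((P[-1L, , drop = FALSE] -
                           P[-n, , drop = FALSE])^2))
    if (closed) seg <- c(seg, sqrt(sum((P[1L, ] - P[n, ])^2)))
    total <- sum(seg)
    if (total <= 0) stop("degenerate data: zero total chord length")
    t <- if (closed) c(0, cumsum(seg))[seq_len(n)] / total
    else c(0, cumsum(seg)) / total
  } else {
    if (length(params) != n) stop("params must match the number of points")
    t <- as.numeric(params)
  }

  Pen <- diff_penalty(n_control, closed, as.integer(penalty_order))
  solve_fit <- function(t) {
    A <- curve_design(t, n_control, closed)
    AtA <- crossprod(A)
    sc <- mean(diag(AtA))
    X <- solve(AtA + lambda * sc * Pen + 1e-12 * sc * diag(n_control),
               crossprod(A, P))
    res <- A %*% X - P
    list(X = X, rms = sqrt(mean(rowSums(res^2))))
  }
  fit <- solve_fit(t)
  dense_n <- max(400L, 10L * n_control)
  ts <- if (closed) seq(0, 1, length.out = dense_n + 1L)[-(dense_n + 1L)]
  else seq(0, 1, length.out = dense_n)
  # foot-point correction: coarse localisation on a dense sampling, then a
  # few Newton steps on |C(t) - p|^2 to beat the sampling quantisation
  foot_points <- function(X, t0) {
    tv <- t0
    for (s in 1:5) {
      C0 <- curve_design(tv, n_control, closed) %*% X - P
      C1 <- curve_design(tv, n_control, closed, 1L) %*% X
      C2 <- curve_design(tv, n_control, closed, 2L) %*% X
      g <- rowSums(C1 * C0)
      h <- rowSums(C1 * C1) + rowSums(C2 * C0)
      step <- ifelse(h > 1e-12, g / h, 0)
      tv <- tv - pmax(pmin(step, 0.5 / n_control), -0.5 / n_control)
      tv <- if (closed) tv %% 1 else pmin(pmax(tv, 0), 1)
    }
    tv
  }
  sqd <- function(X, tv) {
    rowSums((curve_design(tv, n_control, closed) %*% X - P)^2)
  }
  for (it in seq_len(max(0L, iterations))) {
    # two candidate corrections: Newton warm-started from the current
    # parameters (quadratic local convergence) and Newton seeded from the
    # dense-grid nearest neighbour (escapes wrong local foot points);
    # keep whichever is closer, per point
    t_warm <- foot_points(fit$X, t)
    curve <- bspline_curve(fit$X, closed = closed)
    Cs <- eval_curve(curve, ts)
    t_grid <- foot_points(fit$X, ts[cpp_nn1(P, Cs)$idx])
    t_new <- ifelse(sqd(fit$X, t_warm) <= sqd(fit$X, t_grid),
                    t_warm, t_grid)
    fit_new <- solve_fit(t_new)
    if (fit_new$rms >= fit$rms - 1e-15) break
    fit <- fit_new
    t <- t_new
  }
  out <- bspline_curve(fit$X, closed = closed)
  attr(out, "rms") <- fit$rms
  attr(out, "params") <- t
  out
}

#' Length of a curve's control polygon
#'
#' On a closed curve the closing edge is included; this is the chest
#' circumference estimator ("the length of the approximate polygon composed
#' of the curve control points").
#' @param curve a [bspline_curve()].
#' @export
control_polygon_length <- function(curve) {
  ctl <- curve$control
  n <- nrow(ctl)
  len <- sum(sqrt(rowSums((ctl[-1L, , drop = FALSE] -
                             ctl[-n, , drop = FALSE])^2)))
  if (curve$closed) len <- len + sqrt(sum((ctl[1L, ] - ctl[n, ])^2))
  len
}
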