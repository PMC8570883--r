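# Body-parameter computation from key points plus the symmetry model and
# ground plane, chest circumference from a closed cross-section fit, and
# MAE/MRE evaluation against reference measurements.

PARAM_NAMES <- c("diagonal_length", "horizontal_length", "shoulder_width",
                 "abdominal_width", "height", "depth")

#' Construct a body-parameter record
#'
#' @param diagonal_length,horizontal_length,shoulder_width,abdominal_width,height,depth
#'   the six body parameters in metres.
#' @param circumference optional chest circumference in metres.
#' @export
body_parameters <- function(diagonal_length, horizontal_length,
                            shoulder_width, abdominal_width, height, depth,
                            circumference = NA_real_) {
  vals <- c(diagonal_length = as.numeric(diagonal_length),
            horizontal_length = as.numeric(horizontal_length),
            shoulder_width = as.numeric(shoulder_width),
            abdominal_width = as.numeric(abdominal_width),
            height = as.numeric(height), depth = as.numeric(depth))
  if (any(vals < 0, na.rm = TRUE)) stop("body parameters must be >= 0")
  if (is.finite(vals["diagonal_length"]) &&
      vals["diagonal_length"] < vals["horizontal_length"] - 1e-9) {
    stop("diagonal length cannot be shorter than horizontal length")
  }
  structure(c(as.list(vals), list(circumference = circumference)),
            class = "body_parameters")
}

#' @export
print.body_parameters <- function(x, ...) {
  cat("<body_parameters (m)>\n")
  for (nm in c(PARAM_NAMES, "circumference")) {
    cat(sprintf("  %-17s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else sprintf("%.4f", x[[nm]])))
  }
  invisible(x)
}

#' Compute the six body parameters
#'
#' Diagonal length = Euclidean distance P4-P5; horizontal length =
#' `|a4 - a5|`; shoulder and abdominal width = twice the top-view distance
#' of P4 (resp. P1) to the symmetry line `c = mu0 + mu1 a`; height =
#' point-plane distance of P6 to the ground; depth = `b(PU) - b(PD)`.
#'
#' @param keypts a [locate_keypoints()] result (or any `keypoints` list).
#' @param model a [symmetry_plane()] result.
#' @param ground the [ground_plane()].
#' @export
measure_body <- function(keypts, model, ground) {
  for (nm in c("P1", "P4", "P5", "P6", "PU", "PD")) {
    if (is.null(keypts[[nm]]) || any(!is.finite(keypts[[nm]]))) {
      stop("missing key point: ", nm)
    }
  }
  P1 <- keypts$P1; P4 <- keypts$P4; P5 <- keypts$P5; P6 <- keypts$P6
  width_of <- function(P) {
    2 * abs(model$mu1 * P[1L] - P[3L] + model$mu0) / sqrt(model$mu1^2 + 1)
  }
  body_parameters(
    diagonal_length = sqrt(sum((P4 - P5)^2)),
    horizontal_length = abs(P4[1L] - P5[1L]),
    shoulder_width = width_of(P4),
    abdominal_width = width_of(P1),
    height = plane_distance(ground, matrix(P6, 1L), signed = FALSE),
    depth = keypts$PU[2L] - keypts$PD[2L])
}

#' Chest circumference from a cross-section slab
#'
#' Extracts the points within `a_center +/- half_width` by passthrough
#' filter, projects them onto the `(b, c)` plane, orders them by polar
#' angle about the section centroid, fits a closed uniform cubic (order-4)
#' B-spline, and returns the perimeter of the closed control-point polygon.
#' The fitting defaults (order 4, 50 iterations, 100 control points) follow
#' the interactive chest-girth procedure.
#'
#' @param cloud a [point_cloud()] holding a closed cross-section at
#'   `a_center` (mirror/repair first if the capture is one-sided).
#' @param a_center longitudinal station of the measurement in metres.
#' @param half_width slab half-width in metres.
#' @param n_control control points of the closed fit.
#' @param iterations parameter-correction rounds.
#' @param lambda smoothing weight (see [fit_curve()]); keeps the control
#'   polygon from zigzagging when the slab is noisy.
#' @return circumference in metres.
#' @export
chest_circumference <- function(cloud, a_center, half_width = 0.005,
                                n_control = 100, iterations = 50,
                                lambda = 1e-2) {
  slab <- passthrough_filter(cloud, "a", a_center - half_width,
                             a_center + half_width)
  if (n_points(slab) < 20L) {
    stop("chest slab holds ", n_points(slab),
         " points; widen half_width or repair/mirror the cloud first")
  }
  p2 <- slab$points[, c(2L, 3L)]
  ctr <- circle_center(p2)
  theta <- atan2(p2[, 2L] - ctr[2L], p2[, 1L] - ctr[1L]) %% (2 * pi)
  # closed-section check: every 20-degree sector must be populated
  sect <- table(factor(floor(theta / (2 * pi / 18)), levels = 0:17))
  if (any(sect == 0L)) {
    stop("cross-section at a = ", format(a_center), " is not closed ",
         "(empty angular sectors); mirror or repair the cloud first")
  }
  # thin to angular-bin centroids: a mirrored/stitched slab carries nearly
  # coincident double surfaces whose interleaving would zigzag the fit
  ar <- angular_representatives(p2, n_bins = max(48L, 2L * n_control))
  curve <- fit_curve(ar$representatives, n_control = n_control,
                     iterations = iterations, closed = TRUE,
                     lambda = lambda)
  control_polygon_length(curve)
}

#' Evaluate measurements against reference values
#'
#' Per-parameter mean absolute error and mean relative error (in percent)
#' over one or more frames; MRE is `NA` where the reference value is zero.
#'
#' @param measured a `body_parameters` or a list of them (frames).
#' @param truth a `body_parameters` or a list matching `measured`.
#' @return data frame with columns `parameter`, `mae`, `mre_pct`.
#' @export
evaluate_measurements <- function(measured, truth) {
  as_frames <- function(x) {
    if (inherits(x, "body_parameters")) list(x) else x
  }
  m <- as_frames(measured); tr <- as_frames(truth)
  if (length(m) != length(tr)) stop("measured and truth frame counts differ")
  nms <- c(PARAM_NAMES, "circumference")
  rows <- lapply(nms, function(nm) {
    mv <- vapply(m, function(f) as.numeric(f[[nm]] %||% NA_real_), 0)
    tv <- vapply(tr, function(f) as.numeric(f[[nm]] %||% NA_real_), 0)
    ok <- is.finite(mv) & is.finite(tv)
    if (!any(ok)) return(NULL)
    abs_err <- abs(mv[ok] - tv[ok])
    rel <- ifelse(tv[ok] == 0, NA_real_, abs_err / abs(tv[ok]) * 100)
    data.frame(parameter = nm, mae = mean(abs_err),
               mre_pct = if (all(is.na(rel))) NA_real_
               else mean(rel, na.rm = TRUE))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
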