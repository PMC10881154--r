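#' Local tangent direction of a basement-membrane trace
#'
#' Returns the direction of the polyline segment nearest to a query point,
#' measured by perpendicular (point-to-segment) distance. The basement
#' membrane curves, so division angles are measured against the membrane
#' direction local to each division rather than a single global horizontal.
#'
#' @param trace a two-column matrix or data frame of ordered polyline vertices
#'   (x, y) in micrometres, with at least two distinct points.
#' @param point numeric length-2 query point (x, y) in micrometres.
#' @return unit-length numeric vector of length 2 giving the segment
#'   direction. Ties between equidistant segments resolve to the first
#'   segment in trace order, so the result is deterministic.
#' @export
local_tangent <- function(trace, point) {
  pts <- as.matrix(trace)
  if (ncol(pts) != 2L || nrow(pts) < 2L)
    stop("trace must have >= 2 points with columns (x, y)", call. = FALSE)
  storage.mode(pts) <- "double"
  seg <- diff(pts)
  len2 <- rowSums(seg^2)
  if (all(len2 == 0)) stop("degenerate trace: all points identical", call. = FALSE)
  keep <- len2 > 0
  a <- pts[-nrow(pts), , drop = FALSE][keep, , drop = FALSE]
  d <- seg[keep, , drop = FALSE]
  l2 <- len2[keep]
  rel <- sweep(-a, 2, -as.double(point)) # point - a, per segment
  t <- pmin(1, pmax(0, (rel[, 1] * d[, 1] + rel[, 2] * d[, 2]) / l2))
  dx <- rel[, 1] - t * d[, 1]
  dy <- rel[, 2] - t * d[, 2]
  i <- which.min(dx^2 + dy^2)
  v <- d[i, ]
  v / sqrt(sum(v^2))
}

#' Spindle-orientation angle relative to the basal layer
#'
#' The division axis is the line through the two spindle poles; the angle
#' reported is the acute angle between that axis and the basal reference
#' direction, folded into `[0, 90]` degrees. The result is invariant to
#' swapping the poles, negating the reference direction, and rigid motions
#' of all coordinates.
#'
#' @param pole_a,pole_b numeric length-2 spindle-pole coordinates (x, y), µm.
#' @param reference optional explicit reference direction (length-2 vector
#'   along the basal layer); if `NULL`, `trace` must be given.
#' @param trace optional basement-membrane polyline; the reference is then
#'   [local_tangent()] at the midpoint of the pole axis.
#' @return angle in degrees on `[0, 90]`.
#' @export
spindle_angle <- function(pole_a, pole_b, reference = NULL, trace = NULL) {
  pole_a <- as.double(pole_a); pole_b <- as.double(pole_b)
  v <- pole_b - pole_a
  if (sum(v^2) == 0) stop("coincident spindle poles", call. = FALSE)
  if (is.null(reference)) {
    if (is.null(trace)) stop("either `reference` or `trace` must be given", call. = FALSE)
    reference <- local_tangent(trace, (pole_a + pole_b) / 2)
  }
  r <- as.double(reference)
  if (sum(r^2) == 0) stop("reference direction must be non-zero", call. = FALSE)
  cosang <- abs(sum(v * r)) / sqrt(sum(v^2) * sum(r^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Classify a division angle into the three orientation bins
#'
#' Divisions are planar ("parallel") at angles at or below 30 degrees,
#' perpendicular at or above 60 degrees, and oblique strictly in between.
#' Both boundary values belong to the outer bins.
#'
#' @param angle numeric vector of angles in degrees, each on `[0, 90]`.
#' @return factor with levels `parallel`, `oblique`, `perpendicular`.
#' @export
bin_angle <- function(angle) {
  if (!is.numeric(angle) || anyNA(angle) || any(angle < 0 | angle > 90))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  out <- ifelse(angle <= 30, "parallel", ifelse(angle >= 60, "perpendicular", "oblique"))
  factor(out, levels = c("parallel", "oblique", "perpendicular"))
}

#' Construct a labelled angle sample
#'
#' @param angles numeric vector of division angles in degrees on `[0, 90]`.
#' @param condition label for the experimental condition.
#' @return an object of class `angle_sample` with fields `condition`,
#'   `angles` and `n`.
#' @export
angle_sample <- function(angles, condition = "unlabelled") {
  if (length(angles) < 1L) stop("angle sample must contain at least one angle", call. = FALSE)
  if (!is.numeric(angles) || anyNA(angles) || any(angles < 0 | angles > 90))
    stop("angles must lie in [0, 90] degrees", call. = FALSE)
  structure(list(condition = as.character(condition),
                 angles = as.double(angles),
                 n = length(angles)),
            class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf("angle_sample '%s': n = %d, median = %.1f deg\n",
              x$condition, x$n, stats::median(x$angles)))
  invisible(x)
}

#' Orientation-bin percentages and quartiles of an angle sample
#'
#' Percentages are computed on the unrounded bin counts; quartiles use the
#' linear-interpolation convention (R quantile type 7). The three bin
#' percentages always sum to 100 before any rounding.
#'
#' @param sample an [angle_sample()] or bare numeric vector of angles.
#' @return an object of class `bin_summary`: percentages `pct_parallel`,
#'   `pct_oblique`, `pct_perpendicular`, quartiles `q25`, `median`, `q75`,
#'   sample size `n` and the `condition` label.
#' @export
distribution_summary <- function(sample) {
  if (!inherits(sample, "angle_sample")) sample <- angle_sample(sample)
  tab <- table(bin_angle(sample$angles))
  pct <- 100 * as.double(tab) / sample$n
  q <- stats::quantile(sample$angles, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(condition = sample$condition, n = sample$n,
                 pct_parallel = pct[[1]], pct_oblique = pct[[2]],
                 pct_perpendicular = pct[[3]],
                 q25 = q[[1]], median = q[[2]], q75 = q[[3]]),
            class = "bin_summary")
}

#' @export
print.bin_summary <- function(x, ...) {
  cat(sprintf("'%s' (n = %d): parallel %.1f%% | oblique %.1f%% | perpendicular %.1f%%\n",
              x$condition, x$n, x$pct_parallel, x$pct_oblique, x$pct_perpendicular))
  cat(sprintf("  median %.1f deg [IQR %.1f-%.1f]\n", x$median, x$q25, x$q75))
  invisible(x)
}

#' Per-division angles and orientation classes from annotation tables
#'
#' Resolves each division's basal reference — an explicit per-division
#' direction when the annotation provides one, otherwise the local tangent of
#' the linked basement-membrane trace at the pole-axis midpoint — and returns
#' a tidy table of angles and bins.
#'
#' @param annotations data frame with columns `division_id`, `condition`,
#'   `mouse_id`, `ax`, `ay`, `bx`, `by` and either `ref_dx`/`ref_dy` or
#'   `trace_id`.
#' @param traces optional data frame of trace vertices with columns
#'   `trace_id`, `point_index`, `x`, `y`.
#' @return data frame with one row per division: identifiers, `angle_deg`
#'   and `orientation`.
#' @export
compute_division_angles <- function(annotations, traces = NULL) {
  ann <- as.data.frame(annotations)
  need <- c("division_id", "condition", "mouse_id", "ax", "ay", "bx", "by")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  has_ref <- all(c("ref_dx", "ref_dy") %in% names(ann))
  has_trace <- "trace_id" %in% names(ann)
  trace_list <- NULL
  if (!is.null(traces)) {
    tr <- as.data.frame(traces)
    tr <- tr[order(tr$trace_id, tr$point_index), ]
    trace_list <- split(tr[, c("x", "y")], tr$trace_id)
  }
  angle <- vapply(seq_len(nrow(ann)), function(i) {
    a <- c(ann$ax[i], ann$ay[i]); b <- c(ann$bx[i], ann$by[i])
    ref <- NULL; trc <- NULL
    if (has_ref && is.finite(ann$ref_dx[i]) && is.finite(ann$ref_dy[i])) {
      ref <- c(ann$ref_dx[i], ann$ref_dy[i])
    } else if (has_trace && !is.na(ann$trace_id[i])) {
      trc <- trace_list[[as.character(ann$trace_id[i])]]
      if (is.null(trc))
        abort_rows(sprintf("unknown trace_id '%s'", ann$trace_id[i]), i)
    } else {
      abort_rows("division has neither an explicit reference nor a trace link", i)
    }
    spindle_angle(a, b, reference = ref, trace = trc)
  }, 0)
  data.frame(division_id = ann$division_id, condition = ann$condition,
             mouse_id = ann$mouse_id, angle_deg = angle,
             orientation = bin_angle(angle))
}
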