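#' Explant roundness time series
#'
#' @param explant_id Explant identifier.
#' @param group Genotype/condition label.
#' @param hpf Strictly increasing time grid, hpf.
#' @param roundness Roundness per frame, in (0, 1]; NA marks missing
#'   frames.
#' @param source `"mask"` or `"direct"`.
#' @return A `shape_series` data frame.
#' @export
shape_series <- function(explant_id, group, hpf, roundness,
                         source = "direct") {
  if (any(diff(hpf) <= 0))
    stop_field("hpf", "time grid must be strictly increasing")
  ok <- is.na(roundness) | (roundness > 0 & roundness <= 1)
  if (!all(ok))
    stop_field("roundness", "values must lie in (0, 1] or be NA")
  structure(data.frame(explant_id = explant_id, group = group, hpf = hpf,
                       roundness = roundness),
            source = source, class = c("shape_series", "data.frame"))
}

# Area and moments-ellipse major axis from pixel index coordinates.
region_moments <- function(xy) {
  n <- nrow(xy)
  mu <- colMeans(xy)
  d <- sweep(xy, 2, mu)
  cov <- crossprod(d) / n
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  list(area = n, major = 4 * sqrt(max(ev[1], 0)),
       minor = 4 * sqrt(max(ev[2], 0)))
}

#' Roundness of a labeled mask region
#'
#' Computes the standard shape descriptor `4 * Area / (pi * MajorAxis^2)`,
#' where MajorAxis is the major-axis length of the ellipse with the same
#' second central moments as the region. A perfect circle scores 1;
#' elongation drives the value toward 0. The result is clipped to (0, 1].
#'
#' @param mask Integer/numeric matrix; zero is background.
#' @param label Region label to measure. May be omitted when the mask
#'   contains a single non-zero label.
#' @param min_area Minimum region area in pixels.
#' @return Roundness value in (0, 1].
#' @export
roundness_from_mask <- function(mask, label = NULL, min_area = 50) {
  labs <- sort(unique(mask[mask != 0]))
  if (is.null(label)) {
    if (length(labs) == 0)
      stop("mask contains no labeled region", call. = FALSE)
    if (length(labs) > 1)
      stop("mask contains multiple labels; supply `label`", call. = FALSE)
    label <- labs
  }
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(sprintf("label %s not present in mask", label), call. = FALSE)
  if (nrow(idx) < min_area)
    stop(sprintf("region area %d px below minimum %d", nrow(idx),
                 min_area), call. = FALSE)
  mo <- region_moments(idx)
  if (mo$major == 0)
    stop("degenerate region: zero major axis", call. = FALSE)
  min(4 * mo$area / (pi * mo$major^2), 1)
}

# Area and second central moments of a closed polygon (Green's theorem).
polygon_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  ixx <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  iyy <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  s <- sign(a); a <- abs(a)
  # central second moments per unit area
  mxx <- s * iyy / a - cx^2
  myy <- s * ixx / a - cy^2
  mxy <- s * ixy / a - cx * cy
  cov <- matrix(c(mxx, mxy, mxy, myy), 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  list(area = a, major = 4 * sqrt(max(ev[1], 0)),
       minor = 4 * sqrt(max(ev[2], 0)))
}

#' Roundness of a boundary polygon
#'
#' Same descriptor as [roundness_from_mask()], computed from exact polygon
#' moments rather than pixel membership.
#'
#' @param xy Two-column matrix of boundary vertices (ordered, closed
#'   implicitly).
#' @return Roundness value in (0, 1].
#' @export
roundness_from_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("polygon needs >= 3 vertices", call. = FALSE)
  mo <- polygon_moments(xy)
  if (mo$area <= 0 || mo$major == 0)
    stop("degenerate polygon", call. = FALSE)
  min(4 * mo$area / (pi * mo$major^2), 1)
}

#' Inclusion rule for explant shape series
#'
#' Explant extension is variable and not every explant extends; only
#' explants whose roundness drops below `cutoff_roundness` by
#' `cutoff_time_hpf` are included in timing analyses.
#'
#' @param series A [shape_series()].
#' @param cutoff_roundness Threshold (default 0.5).
#' @param cutoff_time_hpf Deadline in hpf (default 12).
#' @return List with `include` (TRUE/FALSE/NA for indeterminate) and
#'   `reason`.
#' @export
include_explant <- function(series, cutoff_roundness = 0.5,
                            cutoff_time_hpf = 12) {
  obs <- series[!is.na(series$roundness), , drop = FALSE]
  if (!nrow(obs) || max(obs$hpf) < cutoff_time_hpf) {
    warning("series ends before cutoff time; decision indeterminate",
            call. = FALSE)
    return(list(include = NA, reason = "series ends before cutoff time"))
  }
  mn <- min(obs$roundness[obs$hpf <= cutoff_time_hpf])
  if (mn < cutoff_roundness)
    list(include = TRUE,
         reason = sprintf("min roundness %.3f < %.2f by %g hpf", mn,
                          cutoff_roundness, cutoff_time_hpf))
  else
    list(include = FALSE,
         reason = sprintf("min roundness %.3f >= %.2f by %g hpf", mn,
                          cutoff_roundness, cutoff_time_hpf))
}

#' Automated extension-onset call from a roundness series
#'
#' Surrogate for the visual "first visible tip" call: onset is the first
#' time roundness falls below the pre-extension plateau mean by more than
#' `drop_fraction` and stays below for `sustain_frames` consecutive frames.
#'
#' @param series A [shape_series()].
#' @param drop_fraction Fractional drop below the plateau mean (default
#'   0.05).
#' @param sustain_frames Consecutive frames the drop must persist.
#' @param plateau_frames Number of initial frames defining the plateau.
#' @return Onset hpf, or `NA` when roundness never drops.
#' @export
extension_onset_from_series <- function(series, drop_fraction = 0.05,
                                        sustain_frames = 3,
                                        plateau_frames = 6) {
  r <- series$roundness
  t <- series$hpf
  if (length(r) < plateau_frames)
    stop("series shorter than plateau window", call. = FALSE)
  plateau <- mean(r[seq_len(plateau_frames)], na.rm = TRUE)
  thresh <- plateau * (1 - drop_fraction)
  below <- !is.na(r) & r < thresh
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run == sustain_frames) return(t[i - sustain_frames + 1L])
  }
  NA_real_
}

#' Length/width ratio morphometry
#'
#' Arc length of the midline polyline (accounting for curvature) divided by
#' the length of the maximal-width perpendicular segment.
#'
#' @param midline Two-column matrix of >= 2 midline points.
#' @param width_segment Two-column matrix of the 2 endpoints of the width
#'   segment.
#' @return List of class `morphometry_result`: `length`, `width`, `ratio`.
#' @export
length_width_ratio <- function(midline, width_segment) {
  midline <- as.matrix(midline)
  width_segment <- as.matrix(width_segment)
  if (nrow(midline) < 2)
    stop("midline polyline needs >= 2 points", call. = FALSE)
  if (nrow(width_segment) != 2)
    stop("width segment needs exactly 2 points", call. = FALSE)
  seglen <- sqrt(rowSums(diff(midline)^2))
  len <- sum(seglen)
  wid <- sqrt(sum((width_segment[2, ] - width_segment[1, ])^2))
  if (len == 0) stop("midline has zero length", call. = FALSE)
  if (wid == 0) stop("width segment has zero length", call. = FALSE)
  structure(list(length = len, width = wid, ratio = len / wid),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("length %.4g / width %.4g = ratio %.4g\n", x$length,
              x$width, x$ratio))
  invisible(x)
}
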