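#' Nuclear track table
#'
#' One row per cell per frame with positions in micrometers. Time is
#' `t0_hpf + frame * frame_interval / 60` unless an explicit `t_hpf`
#' column is supplied.
#'
#' @param df Data frame with columns `track_id`, `frame`, `x`, `y` and
#'   optionally `t_hpf`.
#' @param frame_interval Minutes between frames (default 5).
#' @param midline_x Dorsal midline x position, um.
#' @param t0_hpf Time of frame 0 in hpf (used when `t_hpf` is absent).
#' @return A `track_table` data frame sorted by (track, frame).
#' @export
track_table <- function(df, frame_interval = 5, midline_x = 0,
                        t0_hpf = 0) {
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("df", paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) && any(!is.finite(df$x) | !is.finite(df$y)))
    stop_field("df", "coordinates must be finite")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup))
    stop(sprintf("duplicated (track, frame) rows, e.g. track %s frame %s",
                 df$track_id[dup][1], df$frame[dup][1]), call. = FALSE)
  if (!"t_hpf" %in% names(df))
    df$t_hpf <- t0_hpf + df$frame * frame_interval / 60
  rownames(df) <- NULL
  structure(df[, c("track_id", "frame", "t_hpf", "x", "y")],
            frame_interval = frame_interval, midline_x = midline_x,
            class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("track_table: %d tracks, %d observations, %g-min frames, midline x = %g um\n",
              length(unique(x$track_id)), nrow(x),
              attr(x, "frame_interval"), attr(x, "midline_x")))
  invisible(x)
}

# Longest run of consecutive frames within one track.
longest_consecutive_run <- function(frames) {
  if (!length(frames)) return(integer(0))
  brk <- cumsum(c(0L, diff(frames) != 1L))
  runs <- split(seq_along(frames), brk)
  runs[[which.max(lengths(runs))]]
}

#' Filter tracks for kinetics analysis
#'
#' Applies the midline-exclusion rule (observations within
#' `exclusion_radius_um` of the midline are removed, because convergence is
#' reduced where extension dominates) and the minimum-duration rule
#' (tracks must span at least `min_frames` consecutive frames, i.e. 15
#' minutes at 5-min frames). With `midline_policy = "observation"`
#' (default, conservative) the exclusion removes individual observations
#' and the duration rule is then re-applied to the longest remaining
#' consecutive run; with `"track"` a track is removed only when all of its
#' observations fall inside the exclusion zone.
#'
#' @param table A [track_table()].
#' @param min_frames Minimum consecutive frames per track.
#' @param exclusion_radius_um Half-width of the midline exclusion zone.
#' @param midline_policy `"observation"` or `"track"`.
#' @return Filtered `track_table` with attribute `filter_counts` (rows
#'   removed per rule). Empty input or no survivors yields an empty table
#'   with a warning, not an error.
#' @export
filter_tracks <- function(table, min_frames = 3,
                          exclusion_radius_um = 100,
                          midline_policy = c("observation", "track")) {
  midline_policy <- match.arg(midline_policy)
  mid <- attr(table, "midline_x")
  if (is.null(mid)) stop("track table has no midline_x", call. = FALSE)
  n0 <- nrow(table)
  near <- abs(table$x - mid) <= exclusion_radius_um
  if (midline_policy == "observation") {
    kept <- table[!near, , drop = FALSE]
  } else {
    all_near <- tapply(near, table$track_id, all)
    kept <- table[!table$track_id %in%
                    names(all_near)[all_near], , drop = FALSE]
  }
  n_mid <- n0 - nrow(kept)
  pieces <- lapply(split(kept, kept$track_id), function(d) {
    run <- longest_consecutive_run(d$frame)
    if (length(run) >= min_frames) d[run, , drop = FALSE] else NULL
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- kept[0, , drop = FALSE]
  n_short <- nrow(kept) - nrow(out)
  if (!nrow(out))
    warning("no tracks survive filtering", call. = FALSE)
  rownames(out) <- NULL
  structure(out, frame_interval = attr(table, "frame_interval"),
            midline_x = mid,
            filter_counts = c(midline_exclusion = n_mid,
                              min_frames = n_short),
            class = c("track_table", "data.frame"))
}

#' Per-frame mean signed mediolateral displacement
#'
#' For each step between consecutive frames of a track the signed ML
#' displacement is `|x_t - midline| - |x_(t+1) - midline|`, so movement
#' toward the midline (convergence) is positive. Steps are attributed to
#' the later frame and averaged across cells per frame.
#'
#' @param table A (filtered) [track_table()].
#' @return Data frame `ml_curve`: `frame`, `t_hpf`, `mean_ml` (um/frame),
#'   `se`, `n_cells` (NA mean at frames with zero cells).
#' @export
ml_displacement_curve <- function(table) {
  mid <- attr(table, "midline_x")
  steps <- do.call(rbind, lapply(split(table, table$track_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    dd <- abs(d$x - mid)
    data.frame(frame = d$frame[-1], t_hpf = d$t_hpf[-1],
               ml = dd[-nrow(d)] - dd[-1])
  }))
  if (is.null(steps))
    return(structure(data.frame(frame = integer(0), t_hpf = numeric(0),
                                mean_ml = numeric(0), se = numeric(0),
                                n_cells = integer(0)),
                     class = c("ml_curve", "data.frame")))
  frames <- sort(unique(steps$frame))
  agg <- lapply(frames, function(f) {
    v <- steps$ml[steps$frame == f]
    data.frame(frame = f, t_hpf = steps$t_hpf[steps$frame == f][1],
               mean_ml = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_,
               n_cells = length(v))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, class = c("ml_curve", "data.frame"))
}

#' Sliding-window moving average
#'
#' Trailing-aligned moving average with shrinking windows at the start of
#' the series (the first value averages one point, the second two, ...),
#' switchable to centered alignment. Missing values are omitted
#' window-wise.
#'
#' @param curve Numeric vector (or an `ml_curve`, smoothing `mean_ml`).
#' @param window Window length in points (default 4).
#' @param align `"trailing"` (default) or `"centered"`.
#' @return Smoothed vector (or `ml_curve` with `mean_ml` replaced and the
#'   raw curve kept as `raw_ml`).
#' @export
smooth_curve <- function(curve, window = 4,
                         align = c("trailing", "centered")) {
  align <- match.arg(align)
  if (inherits(curve, "ml_curve")) {
    out <- curve
    out$raw_ml <- curve$mean_ml
    out$mean_ml <- smooth_curve(curve$mean_ml, window, align)
    return(out)
  }
  check_count(window, "window", lower = 1)
  n <- length(curve)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (align == "trailing") max(1, i - window + 1):i
    else max(1, i - floor((window - 1) / 2)):
      min(n, i + ceiling((window - 1) / 2))
    v <- curve[idx]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

# Best continuous two-segment (hinge) least-squares fit over a breakpoint
# grid at frame resolution. Model: y = a + b t + c (t - brk)_+ .
hinge_search <- function(t, y, min_seg = 3) {
  n <- length(t)
  cand <- t[seq(min_seg, n - min_seg)]
  best <- NULL
  for (b in cand) {
    X <- cbind(1, t, pmax(t - b, 0))
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(breakpoint = b, sse = sse, coef = fit$coefficients)
  }
  best
}

#' Convergence-onset changepoint from an ML displacement curve
#'
#' Fits a continuous two-segment piecewise-linear (hinge) model over a
#' breakpoint grid at frame resolution and reports the SSE-minimizing
#' breakpoint as the onset -- but only when the hinge beats the single-line
#' fit by an extra sum-of-squares F test at `alpha` (the breakpoint counts
#' as an estimated parameter: F with 2 and n - 4 df) and the post-break
#' slope exceeds the pre-break slope. With `cumulative = TRUE` the hinge is
#' fitted to the cumulative sum of the curve, appropriate when convergence
#' adds a roughly constant per-frame displacement after onset (a step in
#' the per-frame curve is a hinge in the cumulative curve).
#'
#' @param curve Numeric vector of per-frame mean ML displacement (or an
#'   `ml_curve`).
#' @param t_grid Times (hpf) matching `curve`; taken from an `ml_curve`
#'   automatically.
#' @param alpha F-test gate level.
#' @param min_points Minimum number of non-missing points.
#' @param min_seg Minimum points in each segment.
#' @param cumulative Fit the hinge to the cumulative curve?
#' @return List of class `onset_estimate`: `onset_hpf` (NA when no onset),
#'   `p_value`, `F`, `breakpoint_grid_n`, `reason`.
#' @export
convergence_onset <- function(curve, t_grid = NULL, alpha = 0.05,
                              min_points = 10, min_seg = 3,
                              cumulative = FALSE) {
  if (inherits(curve, "ml_curve")) {
    t_grid <- curve$t_hpf
    curve <- curve$mean_ml
  }
  ok <- !is.na(curve) & !is.na(t_grid)
  if (!any(ok)) stop("curve is all-missing", call. = FALSE)
  y <- curve[ok]; t <- t_grid[ok]
  if (length(y) < min_points)
    stop(sprintf("need >= %d non-missing points", min_points),
         call. = FALSE)
  if (cumulative) y <- cumsum(y)
  none <- function(reason)
    structure(list(onset_hpf = NA_real_, p_value = NA_real_, F = NA_real_,
                   breakpoint_grid_n = NA_integer_, reason = reason),
              class = "onset_estimate")
  # single-line null fit
  X0 <- cbind(1, t)
  f0 <- stats::lm.fit(X0, y)
  sse0 <- sum(f0$residuals^2)
  hinge <- hinge_search(t, y, min_seg)
  n <- length(y)
  df2 <- n - 4
  if (df2 <= 0) return(none("too few points for hinge test"))
  scale0 <- mean(y^2) + 1
  if (hinge$sse / n < 1e-24 * scale0 && sse0 / n < 1e-24 * scale0)
    return(none("degenerate: both models fit exactly"))
  Fst <- ((sse0 - hinge$sse) / 2) / (hinge$sse / df2)
  if (!is.finite(Fst)) Fst <- Inf  # exact hinge, noiseless
  p <- stats::pf(Fst, 2, df2, lower.tail = FALSE)
  slope_change <- hinge$coef[3]
  if (p < alpha && slope_change > 0)
    structure(list(onset_hpf = hinge$breakpoint, p_value = p, F = Fst,
                   breakpoint_grid_n = length(t) - 2 * min_seg + 1,
                   reason = "hinge significant"),
              class = "onset_estimate")
  else none(if (slope_change <= 0) "post-break slope not greater"
            else "hinge not significantly better than line")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (is.na(x$onset_hpf))
    cat(sprintf("no onset (%s)\n", x$reason))
  else
    cat(sprintf("onset %.3f hpf (F = %.3g, p = %.3g)\n", x$onset_hpf,
                x$F, x$p_value))
  invisible(x)
}

#' Persistence of a single track
#'
#' Ratio of the linear (straight-line) distance traveled to the total path
#' length; 1 for straight monotone motion, 0 for a closed loop.
#'
#' @param track Data frame with columns `x`, `y` ordered by frame.
#' @return Persistence in `[0, 1]`; a zero-length path is defined as 0
#'   (with attribute `degenerate = TRUE`).
#' @export
track_persistence <- function(track) {
  if (nrow(track) < 2) stop("need >= 2 observations", call. = FALSE)
  p <- as.matrix(track[, c("x", "y")])
  path <- sum(sqrt(rowSums(diff(p)^2)))
  if (path == 0) return(structure(0, degenerate = TRUE))
  net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  min(net / path, 1)
}

#' Straight-line speed and instantaneous velocities of a track
#'
#' Straight-line speed is the total linear displacement divided by the
#' total tracking time; instantaneous velocity is the displacement between
#' consecutive frames divided by the frame interval. Both in um/min.
#'
#' @param track Data frame with columns `x`, `y` ordered by frame.
#' @param frame_interval Minutes between frames (default 5).
#' @return List: `straight_line_speed` (um/min), `instantaneous` (um/min
#'   per step), `mean_instantaneous`.
#' @export
track_speeds <- function(track, frame_interval = 5) {
  if (nrow(track) < 2) stop("need >= 2 observations", call. = FALSE)
  p <- as.matrix(track[, c("x", "y")])
  steps <- sqrt(rowSums(diff(p)^2))
  total_time <- (nrow(p) - 1) * frame_interval
  list(straight_line_speed = sqrt(sum((p[nrow(p), ] - p[1, ])^2)) /
         total_time,
       instantaneous = steps / frame_interval,
       mean_instantaneous = mean(steps / frame_interval))
}

#' Convergence kinetics summary for a track table
#'
#' Filters tracks, computes the per-frame mean ML displacement curve and
#' its 4-point smoothed version, estimates the convergence onset (hinge
#' changepoint on the cumulative displacement curve), and tabulates
#' per-track persistence and speeds.
#'
#' @param table A [track_table()].
#' @param window Smoothing window (points).
#' @param alpha Onset F-test gate level.
#' @param filter Apply [filter_tracks()] first?
#' @param ... Passed to [filter_tracks()].
#' @return List of class `kinetics_summary`: `curve` (with raw and
#'   smoothed ML displacement), `onset`, `per_track` (persistence and
#'   speeds), `n_tracks`.
#' @export
kinetics_summary <- function(table, window = 4, alpha = 0.05,
                             filter = TRUE, ...) {
  tab <- if (filter) filter_tracks(table, ...) else table
  curve <- ml_displacement_curve(tab)
  sm <- smooth_curve(curve, window = window)
  onset <- if (nrow(curve) >= 10)
    convergence_onset(curve$mean_ml, curve$t_hpf, alpha = alpha,
                      cumulative = TRUE)
  else structure(list(onset_hpf = NA_real_, p_value = NA_real_,
                      F = NA_real_, breakpoint_grid_n = NA_integer_,
                      reason = "curve too short"),
                 class = "onset_estimate")
  fi <- attr(tab, "frame_interval")
  per_track <- do.call(rbind, lapply(split(tab, tab$track_id),
                                     function(d) {
    if (nrow(d) < 2) return(NULL)
    sp <- track_speeds(d, fi)
    data.frame(track_id = d$track_id[1], n_frames = nrow(d),
               persistence = as.numeric(track_persistence(d)),
               straight_line_speed = sp$straight_line_speed,
               mean_instantaneous = sp$mean_instantaneous)
  }))
  rownames(per_track) <- NULL
  structure(list(curve = sm, onset = onset, per_track = per_track,
                 n_tracks = length(unique(tab$track_id))),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("kinetics_summary: %d tracks, %d frames\n", x$n_tracks,
              nrow(x$curve)))
  print(x$onset)
  if (!is.null(x$per_track))
    cat(sprintf("median persistence %.3f, median straight-line speed %.3g um/min\n",
                stats::median(x$per_track$persistence),
                stats::median(x$per_track$straight_line_speed)))
  invisible(x)
}

#' @export
`[.track_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("track_id", "frame") %in% names(out))) {
    attr(out, "frame_interval") <- attr(x, "frame_interval")
    attr(out, "midline_x") <- attr(x, "midline_x")
    class(out) <- class(x)
  }
  out
}
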