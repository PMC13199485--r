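#' Default seven-stage developmental grid
#'
#' Stage labels with hours-post-fertilization (hpf) values spanning late
#' blastula through the end of gastrulation, matching a seven-stage
#' peri-gastrulation RNA-seq design. The pre-gastrulation window runs
#' sphere -> 50% epiboly; shield (6 hpf) marks gastrulation onset.
#'
#' @return Named numeric vector of hpf values, ordered by hpf.
#' @export
default_stage_grid <- function() {
  c(sphere = 4.0, dome = 4.3, epi50 = 5.3, shield = 6.0,
    epi75 = 8.0, epi90 = 9.0, bud = 10.0)
}

#' Specification for a synthetic stage-resolved expression panel
#'
#' Describes genes x stages x conditions TPM trajectories with a set of
#' planted "trigger" genes: flat (within noise) across the pre-gastrulation
#' window, then elevated by `trigger_effect` from the trigger stage onward in
#' every condition. Non-planted genes follow a documented mixture of flat,
#' monotone-decreasing and late-rising patterns so that screen specificity is
#' exercised against plausible confounders.
#'
#' @param n_genes Number of genes.
#' @param stage_hpf Named numeric vector mapping stage labels to hpf,
#'   strictly increasing. Default [default_stage_grid()].
#' @param conditions Character vector of condition labels (default three
#'   explant conditions).
#' @param planted_triggers Integer indices of genes given the trigger
#'   pattern.
#' @param trigger_stage Stage label at which planted genes rise (default
#'   `"shield"`).
#' @param trigger_effect Fold increase at the trigger stage (> 1).
#' @param baseline_meanlog,baseline_sdlog Lognormal location/scale of
#'   per-gene baseline TPM.
#' @param noise_cv Coefficient of variation of mean-preserving lognormal
#'   replicate noise (>= 0).
#' @param n_replicates Replicates per (gene, stage, condition).
#' @param mixture Length-3 numeric (flat, decreasing, late-rise) proportions
#'   for non-planted genes; must sum to 1.
#' @param decay_factor Per-stage multiplicative decline of "decreasing"
#'   genes.
#' @param seed Master integer seed; per-gene substreams are derived by a
#'   documented counter scheme (see the methods vignette).
#' @return An object of class `sim_expression_spec`.
#' @export
sim_expression_spec <- function(n_genes = 200,
                                stage_hpf = default_stage_grid(),
                                conditions = c("uninjected", "acvr1b", "ndr2"),
                                planted_triggers = integer(0),
                                trigger_stage = "shield",
                                trigger_effect = 3,
                                baseline_meanlog = log(50),
                                baseline_sdlog = 1,
                                noise_cv = 0.2,
                                n_replicates = 3,
                                mixture = c(flat = 0.7, decreasing = 0.15,
                                            late_rise = 0.15),
                                decay_factor = 0.7,
                                seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", lower = 0)
  if (is.null(names(stage_hpf)) || any(names(stage_hpf) == ""))
    stop_field("stage_hpf", "must be a named vector of hpf values")
  if (any(diff(stage_hpf) <= 0))
    stop_field("stage_hpf", "hpf values must be strictly increasing")
  if (!length(conditions)) stop_field("conditions", "must be non-empty")
  planted_triggers <- as.integer(planted_triggers)
  if (length(planted_triggers) &&
      (any(planted_triggers < 1) || any(planted_triggers > n_genes)))
    stop_field("planted_triggers", "indices must lie in 1..n_genes")
  check_number(trigger_effect, "trigger_effect")
  if (trigger_effect <= 1) stop_field("trigger_effect", "must be > 1")
  if (!trigger_stage %in% names(stage_hpf))
    stop_field("trigger_stage", "not a stage label in stage_hpf")
  if (match(trigger_stage, names(stage_hpf)) < 2)
    stop_field("trigger_stage", "must have at least one earlier stage")
  check_number(noise_cv, "noise_cv", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 1)
  if (length(mixture) != 3 || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop_field("mixture", "must be 3 non-negative proportions summing to 1")
  check_number(decay_factor, "decay_factor", lower = 0, upper = 1)
  structure(list(n_genes = n_genes, stage_hpf = stage_hpf,
                 conditions = conditions,
                 planted_triggers = sort(unique(planted_triggers)),
                 trigger_stage = trigger_stage,
                 trigger_effect = trigger_effect,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 mixture = mixture, decay_factor = decay_factor,
                 seed = as.integer(seed)),
            class = "sim_expression_spec")
}

# Stage-mean TPM trajectory for one gene given its pattern.
sim_gene_means <- function(pattern, baseline, spec) {
  n_stage <- length(spec$stage_hpf)
  k <- match(spec$trigger_stage, names(spec$stage_hpf))
  m <- rep(baseline, n_stage)
  if (pattern == "trigger") {
    m[k:n_stage] <- baseline * spec$trigger_effect
  } else if (pattern == "decreasing") {
    m <- baseline * spec$decay_factor^(seq_len(n_stage) - 1)
  } else if (pattern == "late_rise") {
    j <- min(k + 2L, n_stage)
    m[j:n_stage] <- baseline * spec$trigger_effect
  }
  m
}

#' Generate a synthetic expression panel
#'
#' Draws per-gene baselines from a lognormal distribution, builds
#' stage-resolved mean trajectories according to each gene's pattern, and
#' adds mean-preserving lognormal replicate noise independently per
#' (condition, replicate). Reproducible: the per-gene random stream depends
#' only on `spec$seed` and the gene index.
#'
#' @param spec A [sim_expression_spec()].
#' @return An `expression_panel` (long data frame with columns `gene`,
#'   `stage`, `hpf`, `condition`, `replicate`, `tpm`) with attributes
#'   `stage_hpf`, `conditions`, and `truth` (the planted pattern per gene).
#' @export
gen_expression_panel <- function(spec) {
  stopifnot(inherits(spec, "sim_expression_spec"))
  n <- spec$n_genes
  stages <- names(spec$stage_hpf)
  genes <- sprintf("g%04d", seq_len(n))
  patterns <- character(n)
  if (n > 0) {
    pool <- c("flat", "decreasing", "late_rise")
    # Deterministic mixture assignment for non-planted genes.
    non <- setdiff(seq_len(n), spec$planted_triggers)
    counts <- floor(spec$mixture * length(non))
    counts[1] <- length(non) - sum(counts[-1])
    patterns[non] <- rep(pool, times = counts)
    patterns[spec$planted_triggers] <- "trigger"
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- with_seed(substream_seed(spec$seed, i), {
      baseline <- stats::rlnorm(1, spec$baseline_meanlog, spec$baseline_sdlog)
      m <- sim_gene_means(patterns[i], baseline, spec)
      nn <- length(m) * length(spec$conditions) * spec$n_replicates
      df <- expand.grid(stage = stages, condition = spec$conditions,
                        replicate = seq_len(spec$n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      df$tpm <- rep(m, times = length(spec$conditions) * spec$n_replicates) *
        lognormal_noise(nn, spec$noise_cv)
      df
    })
  }
  out <- if (n > 0) do.call(rbind, Map(function(g, df) {
    df$gene <- g
    df
  }, genes, rows)) else
    data.frame(stage = character(0), condition = character(0),
               replicate = integer(0), tpm = numeric(0), gene = character(0))
  out$hpf <- unname(spec$stage_hpf[out$stage])
  out <- out[, c("gene", "stage", "hpf", "condition", "replicate", "tpm")]
  rownames(out) <- NULL
  expression_panel(out, stage_hpf = spec$stage_hpf,
                   truth = stats::setNames(patterns, genes))
}

#' Specification for synthetic nuclear tracks
#'
#' Cells perform an unbiased 2-D random walk before `onset_hpf` and gain a
#' constant per-frame bias of `convergence_speed` toward `midline_x`
#' afterwards, emulating the onset of convergence movements. Boundaries are
#' reflecting so cells stay in the imaged field.
#'
#' @param n_cells Number of tracks.
#' @param frame_interval Minutes between frames (default 5).
#' @param t_start,t_end Movie span in hpf.
#' @param onset_hpf Planted convergence onset; must lie strictly inside
#'   `(t_start, t_end)`.
#' @param convergence_speed Post-onset bias toward the midline, um per
#'   frame.
#' @param diffusion_sd Isotropic per-frame noise, um.
#' @param midline_x Dorsal midline x position, um.
#' @param field_half_width Half-width of the field about the midline, um.
#' @param dead_zone_um Initial positions avoid `|x - midline| <
#'   dead_zone_um`.
#' @param field_height Extent of y positions, um.
#' @param seed Master seed (per-cell substreams).
#' @return An object of class `sim_track_spec`.
#' @export
sim_track_spec <- function(n_cells = 200, frame_interval = 5,
                           t_start = 6.5, t_end = 11, onset_hpf = 8,
                           convergence_speed = 1, diffusion_sd = 2,
                           midline_x = 0, field_half_width = 400,
                           dead_zone_um = 120, field_height = 400,
                           seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", lower = 0)
  check_number(frame_interval, "frame_interval")
  if (frame_interval <= 0) stop_field("frame_interval", "must be > 0")
  check_number(diffusion_sd, "diffusion_sd", lower = 0)
  check_number(convergence_speed, "convergence_speed", lower = 0)
  if (!(t_start < onset_hpf && onset_hpf < t_end))
    stop_field("onset_hpf", "must lie strictly between t_start and t_end")
  if (dead_zone_um < 0 || dead_zone_um >= field_half_width)
    stop_field("dead_zone_um", "must be in [0, field_half_width)")
  structure(list(n_cells = n_cells, frame_interval = frame_interval,
                 t_start = t_start, t_end = t_end, onset_hpf = onset_hpf,
                 convergence_speed = convergence_speed,
                 diffusion_sd = diffusion_sd, midline_x = midline_x,
                 field_half_width = field_half_width,
                 dead_zone_um = dead_zone_um, field_height = field_height,
                 seed = as.integer(seed)),
            class = "sim_track_spec")
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate synthetic nuclear tracks
#'
#' @param spec A [sim_track_spec()].
#' @return A [track_table()] with one row per cell per frame.
#' @export
gen_tracks <- function(spec) {
  stopifnot(inherits(spec, "sim_track_spec"))
  dt <- spec$frame_interval / 60
  t_grid <- seq(spec$t_start, spec$t_end, by = dt)
  n_fr <- length(t_grid)
  xs <- vector("list", spec$n_cells)
  lo <- spec$midline_x - spec$field_half_width
  hi <- spec$midline_x + spec$field_half_width
  for (i in seq_len(spec$n_cells)) {
    xs[[i]] <- with_seed(substream_seed(spec$seed, i), {
      side <- if (stats::runif(1) < 0.5) -1 else 1
      x0 <- spec$midline_x +
        side * stats::runif(1, spec$dead_zone_um, spec$field_half_width)
      y0 <- stats::runif(1, 0, spec$field_height)
      x <- numeric(n_fr); y <- numeric(n_fr)
      x[1] <- x0; y[1] <- y0
      for (f in 2:n_fr) {
        bias <- if (t_grid[f - 1] >= spec$onset_hpf)
          sign(spec$midline_x - x[f - 1]) * spec$convergence_speed else 0
        x[f] <- reflect_into(x[f - 1] + bias +
                               stats::rnorm(1, 0, spec$diffusion_sd), lo, hi)
        y[f] <- reflect_into(y[f - 1] +
                               stats::rnorm(1, 0, spec$diffusion_sd),
                             0, spec$field_height)
      }
      data.frame(track_id = i, frame = seq_len(n_fr) - 1L,
                 t_hpf = t_grid, x = x, y = y)
    })
  }
  df <- if (spec$n_cells > 0) do.call(rbind, xs) else
    data.frame(track_id = integer(0), frame = integer(0),
               t_hpf = numeric(0), x = numeric(0), y = numeric(0))
  track_table(df, frame_interval = spec$frame_interval,
              midline_x = spec$midline_x)
}

#' Specification for synthetic explant roundness series
#'
#' Roundness decays along a Boltzmann sigmoid
#' `bottom + (top - bottom) / (1 + exp((t - v50_hpf) / slope))` (decreasing
#' form; positive slope means decreasing roundness over time) plus Gaussian
#' noise, clipped to (0, 1].
#'
#' @param n_explants Number of series.
#' @param bottom,top Roundness asymptotes, `0 < bottom < top <= 1`.
#' @param v50_hpf Midpoint of the roundness change, hpf.
#' @param slope Sigmoid width parameter, hpf.
#' @param noise_sd Gaussian noise on roundness.
#' @param frame_interval Minutes between frames (default 10).
#' @param t_start,t_end Series span in hpf.
#' @param seed Master seed (per-explant substreams).
#' @return An object of class `sim_shape_spec`.
#' @export
sim_shape_spec <- function(n_explants = 1, bottom = 0.3, top = 0.95,
                           v50_hpf = 9, slope = 0.5, noise_sd = 0.03,
                           frame_interval = 10, t_start = 6, t_end = 12,
                           seed = 1L) {
  n_explants <- check_count(n_explants, "n_explants", lower = 0)
  check_number(bottom, "bottom"); check_number(top, "top")
  if (!(0 < bottom && bottom < top && top <= 1))
    stop_field("bottom", "need 0 < bottom < top <= 1")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(frame_interval, "frame_interval")
  if (frame_interval <= 0) stop_field("frame_interval", "must be > 0")
  if (t_start >= t_end) stop_field("t_start", "must be < t_end")
  structure(list(n_explants = n_explants, bottom = bottom, top = top,
                 v50_hpf = v50_hpf, slope = slope, noise_sd = noise_sd,
                 frame_interval = frame_interval, t_start = t_start,
                 t_end = t_end, seed = as.integer(seed)),
            class = "sim_shape_spec")
}

#' Generate synthetic explant roundness series (optionally with masks)
#'
#' When `masks = TRUE` each frame is also rendered as a rasterized ellipse
#' label mask whose axes are chosen so that the analytic roundness of the
#' ellipse (minor/major axis ratio for the moments-equivalent ellipse)
#' equals the series value at that frame.
#'
#' @param spec A [sim_shape_spec()].
#' @param masks Emit per-frame elliptical label masks?
#' @param mask_area_px Target ellipse area in pixels when `masks = TRUE`.
#' @return List of `shape_series` data frames (columns `explant_id`,
#'   `group`, `hpf`, `roundness`); with `masks = TRUE` each series carries a
#'   `masks` attribute (list of integer matrices) and an `ellipse_axes`
#'   attribute (per-frame major/minor axis lengths, px).
#' @export
gen_shape_series <- function(spec, masks = FALSE, mask_area_px = 4000) {
  stopifnot(inherits(spec, "sim_shape_spec"))
  t_grid <- seq(spec$t_start, spec$t_end, by = spec$frame_interval / 60)
  out <- vector("list", spec$n_explants)
  for (i in seq_len(spec$n_explants)) {
    r <- boltzmann(t_grid, spec$bottom, spec$top, spec$v50_hpf, spec$slope)
    if (spec$noise_sd > 0)
      r <- r + with_seed(substream_seed(spec$seed, i),
                         stats::rnorm(length(t_grid), 0, spec$noise_sd))
    r <- pmin(pmax(r, 1e-6), 1)
    ser <- shape_series(explant_id = sprintf("ex%03d", i), group = "sim",
                        hpf = t_grid, roundness = r)
    if (masks) {
      a <- sqrt(mask_area_px / (pi * r))   # semi-major: area = pi a b, b = r a
      b <- r * a
      ms <- Map(rasterize_ellipse, a, b)
      attr(ser, "masks") <- ms
      attr(ser, "ellipse_axes") <- data.frame(hpf = t_grid,
                                              major = 2 * a, minor = 2 * b)
    }
    out[[i]] <- ser
  }
  out
}

# Axis-aligned filled ellipse as an integer label mask (label 1).
rasterize_ellipse <- function(a, b, angle = 0) {
  half <- ceiling(max(a, b)) + 2L
  n <- 2L * half + 1L
  cx <- half + 1
  xs <- matrix(rep(seq_len(n) - cx, each = n), n, n)
  ys <- matrix(rep(seq_len(n) - cx, times = n), n, n)
  if (angle != 0) {
    xr <- cos(angle) * xs + sin(angle) * ys
    yr <- -sin(angle) * xs + cos(angle) * ys
    xs <- xr; ys <- yr
  }
  m <- matrix(0L, n, n)
  m[(xs / a)^2 + (ys / b)^2 <= 1] <- 1L
  m
}
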