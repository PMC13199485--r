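#' Boltzmann sigmoid (decreasing form)
#'
#' `r(t) = bottom + (top - bottom) / (1 + exp((t - v50) / slope))`. With
#' `slope > 0` the curve decreases from `top` (early) to `bottom` (late);
#' `v50` is the time of the curve midpoint `(top + bottom) / 2`, i.e. the
#' time at which 50% of the total change has occurred.
#'
#' @param t Time, hpf.
#' @param bottom,top Asymptotes.
#' @param v50 Midpoint time, hpf.
#' @param slope Width parameter, hpf.
#' @return Model values at `t`.
#' @export
boltzmann <- function(t, bottom, top, v50, slope) {
  bottom + (top - bottom) / (1 + exp((t - v50) / slope))
}

# Pull (t, r) points out of the accepted input forms: a shape_series, a
# data frame with hpf/roundness columns, or a list of either (pooled).
series_points <- function(x) {
  if (is.data.frame(x)) {
    tc <- intersect(c("hpf", "t"), names(x))[1]
    rc <- intersect(c("roundness", "r", "value"), names(x))[1]
    if (is.na(tc) || is.na(rc))
      stop("data frame must have hpf/roundness columns", call. = FALSE)
    ok <- !is.na(x[[rc]])
    return(list(t = x[[tc]][ok], r = x[[rc]][ok]))
  }
  if (is.list(x)) {
    pts <- lapply(x, series_points)
    return(list(t = unlist(lapply(pts, `[[`, "t")),
                r = unlist(lapply(pts, `[[`, "r"))))
  }
  stop("unsupported series input", call. = FALSE)
}

# Documented initialization: top = max r, bottom = min r, v50 = time of the
# point closest to midrange, slope = time range / 10; plus deterministic
# jittered restarts to escape poor basins.
boltzmann_starts <- function(t, r, n_extra = 5) {
  top0 <- max(r); bot0 <- min(r)
  mid <- (top0 + bot0) / 2
  v0 <- t[which.min(abs(r - mid))]
  s0 <- diff(range(t)) / 10
  base <- c(bottom = bot0, top = top0, v50 = v0, slope = s0)
  jit <- rbind(c(1, 1, 1, 1),
               c(0.8, 1.05, 0.9, 0.5),
               c(1.2, 0.95, 1.1, 2),
               c(1, 1, 0.8, 0.25),
               c(1, 1, 1.2, 4),
               c(0.5, 1, 1, 1))[seq_len(n_extra + 1), , drop = FALSE]
  lapply(seq_len(nrow(jit)), function(i) base * jit[i, ])
}

fit_boltzmann_xy <- function(t, r, n_starts = 6) {
  resid_fn <- function(p) r - boltzmann(t, p[1], p[2], p[3], p[4])
  best <- NULL
  for (start in boltzmann_starts(t, r, n_starts - 1)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-14)
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
  }
  best
}

#' Fit a Boltzmann sigmoid to roundness data
#'
#' Least-squares fit of the decreasing Boltzmann model by
#' Levenberg-Marquardt with a documented multi-start initialization. A list
#' of series is pooled: one curve is fitted to all points (as when fitting
#' a single curve per genotype).
#'
#' @param x A [shape_series()], a data frame with `hpf`/`roundness`
#'   columns, or a list of either (pooled fit).
#' @param min_points Minimum number of points (default 6).
#' @param min_range Minimum dynamic range of the response; below this the
#'   series is refused as flat.
#' @return An object of class `sigmoid_fit`: `coefficients` (bottom, top,
#'   v50, slope), `sse`, `df` (`n - 4`), `n`, `converged`, `fitted`.
#' @export
fit_boltzmann <- function(x, min_points = 6, min_range = 0.05) {
  pts <- series_points(x)
  t <- pts$t; r <- pts$r
  if (length(t) < min_points)
    stop(sprintf("need >= %d points to fit", min_points), call. = FALSE)
  if (diff(range(r)) < min_range)
    stop(sprintf("flat series: dynamic range %.3g below minimum %.3g",
                 diff(range(r)), min_range), call. = FALSE)
  best <- fit_boltzmann_xy(t, r)
  if (is.null(best))
    stop("Boltzmann fit failed from every start", call. = FALSE)
  p <- best$par
  if (p[1] > p[2]) {  # normalize: bottom < top, flip sign convention
    p <- c(p[2], p[1], p[3], -p[4])
    names(p) <- c("bottom", "top", "v50", "slope")
  }
  structure(list(coefficients = stats::setNames(as.numeric(p),
                                                c("bottom", "top", "v50",
                                                  "slope")),
                 sse = best$sse, df = length(t) - 4L, n = length(t),
                 converged = best$converged,
                 fitted = boltzmann(t, p[1], p[2], p[3], p[4]), t = t,
                 r = r),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(paste0("Boltzmann sigmoid fit (n = %d, df = %d%s)\n",
                     "  bottom %.4f  top %.4f  V50 %.4f hpf  ",
                     "slope %.4f hpf\n  SSE %.6g\n"),
              x$n, x$df, if (x$converged) "" else ", NOT converged",
              co["bottom"], co["top"], co["v50"], co["slope"], x$sse))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$t
  co <- object$coefficients
  boltzmann(t, co["bottom"], co["top"], co["v50"], co["slope"])
}

# Fit groups with a subset of parameters shared (pooled model).
fit_shared <- function(pts_list, share, starts) {
  pars <- c("bottom", "top", "v50", "slope")
  free <- setdiff(pars, share)
  g <- length(pts_list)
  # parameter vector layout: shared params once, then free params per group
  p0 <- c(vapply(share, function(nm)
    mean(vapply(starts, `[[`, 0, nm)), 0),
    unlist(lapply(starts, function(s) s[free])))
  unpack <- function(p) {
    lapply(seq_len(g), function(i) {
      out <- numeric(4); names(out) <- pars
      if (length(share)) out[share] <- p[seq_along(share)]
      if (length(free))
        out[free] <- p[length(share) + (i - 1) * length(free) +
                         seq_along(free)]
      out
    })
  }
  resid_fn <- function(p) {
    ps <- unpack(p)
    unlist(lapply(seq_len(g), function(i) {
      pt <- pts_list[[i]]
      pt$r - boltzmann(pt$t, ps[[i]]["bottom"], ps[[i]]["top"],
                       ps[[i]]["v50"], ps[[i]]["slope"])
    }))
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-13))
  list(sse = sum(fit$fvec^2), n_par = length(p0),
       params = unpack(fit$par), converged = fit$info %in% 1:4)
}

#' Compare Boltzmann fits between groups by the extra sum-of-squares F test
#'
#' Fits a pooled model in which `share` parameters are common to all groups
#' against separate per-group fits, and compares the nested models:
#' `F = ((SSE_pooled - SSE_separate) / (df_pooled - df_separate)) /
#' (SSE_separate / df_separate)`.
#'
#' @param group_series Named list (>= 2 groups); each element is a series
#'   input accepted by [fit_boltzmann()].
#' @param share Parameters shared in the pooled model (default all four).
#' @return An object of class `f_test_result`: `F`, `df1`, `df2`,
#'   `p_value`, `sse_pooled`, `sse_separate`, and both nested fits.
#' @export
compare_fits_f_test <- function(group_series,
                                share = c("bottom", "top", "v50",
                                          "slope")) {
  if (length(group_series) < 2)
    stop("need >= 2 groups", call. = FALSE)
  share <- match.arg(share, c("bottom", "top", "v50", "slope"),
                     several.ok = TRUE)
  nms <- names(group_series) %||% paste0("group", seq_along(group_series))
  pts <- lapply(group_series, series_points)
  sep <- vector("list", length(pts))
  for (i in seq_along(pts)) {
    sep[[i]] <- tryCatch(fit_boltzmann(data.frame(hpf = pts[[i]]$t,
                                                  roundness = pts[[i]]$r)),
                         error = function(e)
                           stop(sprintf("separate fit failed in group `%s`: %s",
                                        nms[i], conditionMessage(e)),
                                call. = FALSE))
  }
  n <- sum(vapply(pts, function(p) length(p$t), 0))
  sse_sep <- sum(vapply(sep, `[[`, 0, "sse"))
  df_sep <- n - 4L * length(pts)
  pooled <- fit_shared(pts, share,
                       lapply(sep, function(f) as.list(f$coefficients)))
  df_pool <- n - pooled$n_par
  sse_pool <- max(pooled$sse, sse_sep)  # nested: pooled cannot beat separate
  Fst <- ((sse_pool - sse_sep) / (df_pool - df_sep)) / (sse_sep / df_sep)
  Fst <- max(Fst, 0)
  p <- stats::pf(Fst, df_pool - df_sep, df_sep, lower.tail = FALSE)
  structure(list(F = Fst, df1 = df_pool - df_sep, df2 = df_sep,
                 p_value = p, sse_pooled = sse_pool,
                 sse_separate = sse_sep, shared = share,
                 separate_fits = stats::setNames(sep, nms),
                 pooled_params = stats::setNames(pooled$params, nms)),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf(paste0("Extra sum-of-squares F test (shared: %s)\n",
                     "  F(%d, %d) = %.4g, p = %.4g\n",
                     "  SSE pooled %.6g, SSE separate %.6g\n"),
              paste(x$shared, collapse = ", "), x$df1, x$df2, x$F,
              x$p_value, x$sse_pooled, x$sse_separate))
  invisible(x)
}
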