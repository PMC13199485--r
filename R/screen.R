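#' Stage-resolved expression panel
#'
#' A replicate-aware long table of TPM values per (gene, stage, condition,
#' replicate), the substrate of the trigger-gene screen. Stages are ordered
#' by hpf via the `stage_hpf` attribute.
#'
#' @param df Data frame with columns `gene`, `stage`, `hpf`, `condition`,
#'   `replicate`, `tpm`.
#' @param stage_hpf Named numeric vector mapping stage labels to hpf
#'   (strictly increasing).
#' @param truth Optional named character vector of planted patterns
#'   (generator provenance).
#' @return An object of class `expression_panel` (a data frame).
#' @export
expression_panel <- function(df, stage_hpf, truth = NULL) {
  need <- c("gene", "stage", "hpf", "condition", "replicate", "tpm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_field("df", paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(diff(stage_hpf) <= 0))
    stop_field("stage_hpf", "hpf values must be strictly increasing")
  bad <- setdiff(unique(df$stage), names(stage_hpf))
  if (length(bad))
    stop_field("df", paste("stages not in stage_hpf:",
                           paste(bad, collapse = ", ")))
  if (nrow(df) && any(!is.finite(df$tpm) | df$tpm < 0))
    stop_field("tpm", "TPM values must be finite and >= 0")
  structure(df, stage_hpf = stage_hpf,
            conditions = unique(df$condition), truth = truth,
            class = c("expression_panel", "data.frame"))
}

#' @export
print.expression_panel <- function(x, ...) {
  sh <- attr(x, "stage_hpf")
  cat(sprintf("expression_panel: %d genes x %d stages x %d conditions\n",
              length(unique(x$gene)), length(sh),
              length(attr(x, "conditions"))))
  cat("stages:", paste(sprintf("%s(%g hpf)", names(sh), sh),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Criteria defining a "trigger" expression pattern
#'
#' Operationalizes the screen for genes whose expression remains unchanged
#' across the pre-gastrulation window but increases at the trigger stage
#' (gastrulation onset, shield) and beyond. The confirmation filters carry
#' the published cutoffs: a sharp increase Delta > `delta_min` (a 50%
#' increase by default) from 50% epiboly to shield and at least `tpm_min`
#' (5) TPM at shield stage in the confirmation (intact-embryo) series.
#'
#' @param pre_window Character pair of stage labels bounding the unchanged
#'   window; `NULL` (default) means from the first stage through the stage
#'   immediately before `trigger_stage`.
#' @param trigger_stage Stage at which the increase must begin.
#' @param unchanged_max_fc Max tolerated fold-change magnitude inside the
#'   pre-window (>= 1).
#' @param increase_min_fc Min fold-change at the trigger stage vs the
#'   pre-window end (> 1).
#' @param sustained Require expression to stay near the trigger level at
#'   all later stages?
#' @param retention Fraction of the trigger-stage level that later stages
#'   must retain when `sustained`.
#' @param delta_min Min fractional increase (Delta) from pre-window end to
#'   trigger stage in the confirmation series.
#' @param tpm_min Min TPM at the trigger stage in the confirmation series.
#' @param significance_mode `"fold_only"` (default) or `"replicate_test"`
#'   (one-sided Welch test on log2(TPM + pseudocount) replicates).
#' @param alpha Significance level in `replicate_test` mode.
#' @param pseudocount TPM pseudocount applied before any log or ratio.
#' @param p_adjust Apply Benjamini-Hochberg across genes in
#'   `replicate_test` mode?
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(pre_window = NULL, trigger_stage = "shield",
                            unchanged_max_fc = 1.25, increase_min_fc = 1.5,
                            sustained = TRUE, retention = 0.8,
                            delta_min = 0.5, tpm_min = 5,
                            significance_mode = c("fold_only",
                                                  "replicate_test"),
                            alpha = 0.05, pseudocount = 0.1,
                            p_adjust = FALSE) {
  check_number(unchanged_max_fc, "unchanged_max_fc", lower = 1)
  check_number(increase_min_fc, "increase_min_fc")
  if (increase_min_fc <= 1) stop_field("increase_min_fc", "must be > 1")
  check_number(delta_min, "delta_min")
  if (delta_min <= 0) stop_field("delta_min", "must be > 0")
  if (!is.numeric(tpm_min) || length(tpm_min) != 1 || is.na(tpm_min) ||
      tpm_min < 0)
    stop_field("tpm_min", "must be a single number >= 0 (Inf allowed)")
  check_number(retention, "retention", lower = 0, upper = 1)
  check_number(pseudocount, "pseudocount", lower = 0)
  structure(list(pre_window = pre_window, trigger_stage = trigger_stage,
                 unchanged_max_fc = unchanged_max_fc,
                 increase_min_fc = increase_min_fc, sustained = sustained,
                 retention = retention, delta_min = delta_min,
                 tpm_min = tpm_min,
                 significance_mode = match.arg(significance_mode),
                 alpha = alpha, pseudocount = pseudocount,
                 p_adjust = p_adjust),
            class = "screen_criteria")
}

# Resolve pre-window / trigger stage labels to indices in a stage grid.
resolve_stages <- function(stage_hpf, criteria) {
  labs <- names(stage_hpf)
  if (!criteria$trigger_stage %in% labs)
    stop(sprintf("stage `%s` missing from panel", criteria$trigger_stage),
         call. = FALSE)
  k <- match(criteria$trigger_stage, labs)
  if (is.null(criteria$pre_window)) {
    pre <- seq_len(k - 1L)
  } else {
    miss <- setdiff(criteria$pre_window, labs)
    if (length(miss))
      stop(sprintf("stage `%s` missing from panel", miss[1]), call. = FALSE)
    idx <- match(criteria$pre_window, labs)
    pre <- seq(idx[1], idx[2])
  }
  if (!length(pre) || max(pre) >= k)
    stop("pre-window must end before the trigger stage", call. = FALSE)
  list(pre = pre, trigger = k, later = if (k < length(labs))
    seq(k + 1L, length(labs)) else integer(0))
}

#' Classify one gene's stage series as trigger / not-trigger
#'
#' A gene is a trigger when (a) its expression is unchanged across the
#' pre-window (the fold change between the window's start and end stages
#' has magnitude at most `unchanged_max_fc`), (b) it increases by at least
#' `increase_min_fc` at the trigger
#' stage relative to the pre-window end (in `replicate_test` mode a
#' one-sided Welch test on log2 replicates must also reject), and (c) when
#' `sustained`, its mean at every later stage retains at least `retention`
#' of the trigger-stage level.
#'
#' @param gene_series Data frame with columns `stage`, `tpm` (one row per
#'   replicate) for a single gene and condition.
#' @param criteria A [screen_criteria()].
#' @param stage_hpf Named hpf vector ordering the stages; defaults to a
#'   `stage_hpf` attribute on `gene_series` or [default_stage_grid()].
#' @return A one-row data frame (class `trigger_call`): `verdict`,
#'   `failing` (first failing criterion or `""`), `pre_fc` (pre-window
#'   end-vs-start fold-change magnitude), `trigger_fc`, `p_value`.
#' @export
classify_trigger_pattern <- function(gene_series, criteria = screen_criteria(),
                                     stage_hpf = NULL) {
  stage_hpf <- stage_hpf %||% attr(gene_series, "stage_hpf") %||%
    default_stage_grid()
  st <- resolve_stages(stage_hpf, criteria)
  miss <- setdiff(names(stage_hpf), unique(gene_series$stage))
  if (length(miss))
    stop(sprintf("stage `%s` missing from gene series", miss[1]),
         call. = FALSE)
  pc <- criteria$pseudocount
  m <- tapply(gene_series$tpm, gene_series$stage, mean)[names(stage_hpf)]
  p_value <- NA_real_
  failing <- ""
  if (pc == 0 && m[st$pre[length(st$pre)]] == 0) {
    failing <- "below detection"
  } else {
    # unchanged = fold change across the pre-window pair (end vs start)
    pre_fc <- exp(abs(log((m[st$pre[length(st$pre)]] + pc) /
                            (m[st$pre[1]] + pc))))
    trig_fc <- (m[st$trigger] + pc) / (m[st$pre[length(st$pre)]] + pc)
    if (pre_fc > criteria$unchanged_max_fc) {
      failing <- "pre-window unchanged"
    } else if (trig_fc < criteria$increase_min_fc) {
      failing <- "trigger-stage increase"
    } else if (criteria$significance_mode == "replicate_test") {
      a <- log2(gene_series$tpm[gene_series$stage ==
                                  names(stage_hpf)[st$trigger]] + pc)
      b <- log2(gene_series$tpm[gene_series$stage ==
                                  names(stage_hpf)[st$pre[length(st$pre)]]] +
                  pc)
      p_value <- if (length(a) > 1 && length(b) > 1 &&
                     (stats::sd(a) > 0 || stats::sd(b) > 0))
        stats::t.test(a, b, alternative = "greater")$p.value else
          as.numeric(mean(a) <= mean(b))
      if (!is.na(p_value) && p_value > criteria$alpha)
        failing <- "replicate test"
    }
    if (failing == "" && criteria$sustained &&
        length(st$later) &&
        any(m[st$later] < criteria$retention * m[st$trigger]))
      failing <- "sustained"
  }
  pre_fc <- if (exists("pre_fc", inherits = FALSE)) pre_fc else NA_real_
  trig_fc <- if (exists("trig_fc", inherits = FALSE)) trig_fc else NA_real_
  structure(data.frame(verdict = failing == "", failing = failing,
                       pre_fc = unname(pre_fc),
                       trigger_fc = unname(trig_fc), p_value = p_value),
            class = c("trigger_call", "data.frame"))
}

# Stage-mean TPM matrix (genes x stages) for one condition of a panel.
stage_mean_matrix <- function(panel, condition) {
  sub <- panel[panel$condition == condition, , drop = FALSE]
  sh <- attr(panel, "stage_hpf")
  m <- tapply(sub$tpm, list(sub$gene, sub$stage), mean)
  m[, names(sh), drop = FALSE]
}

# Vectorized trigger calls from a stage-mean matrix.
calls_from_means <- function(m, stage_hpf, criteria) {
  st <- resolve_stages(stage_hpf, criteria)
  pc <- criteria$pseudocount
  pre <- m[, st$pre, drop = FALSE] + pc
  pre_fc <- exp(abs(log(pre[, ncol(pre)] / pre[, 1])))
  trig_fc <- (m[, st$trigger] + pc) / (m[, st$pre[length(st$pre)]] + pc)
  ok <- pre_fc <= criteria$unchanged_max_fc &
    trig_fc >= criteria$increase_min_fc
  if (criteria$sustained && length(st$later)) {
    lev <- criteria$retention * m[, st$trigger]
    ok <- ok & apply(m[, st$later, drop = FALSE] >= lev, 1, all)
  }
  if (pc == 0) ok <- ok & m[, st$pre[length(st$pre)]] > 0
  data.frame(gene = rownames(m), verdict = unname(ok),
             pre_fc = unname(pre_fc), trigger_fc = unname(trig_fc))
}

# Replicate-test p-values (one-sided Welch on log2(TPM + pc)) per gene for
# the pre-window end -> trigger stage contrast.
replicate_test_p <- function(panel, condition, criteria) {
  sh <- attr(panel, "stage_hpf")
  st <- resolve_stages(sh, criteria)
  lab_a <- names(sh)[st$trigger]
  lab_b <- names(sh)[st$pre[length(st$pre)]]
  sub <- panel[panel$condition == condition &
                 panel$stage %in% c(lab_a, lab_b), , drop = FALSE]
  sapply(split(sub, sub$gene), function(d) {
    a <- log2(d$tpm[d$stage == lab_a] + criteria$pseudocount)
    b <- log2(d$tpm[d$stage == lab_b] + criteria$pseudocount)
    if (length(a) > 1 && length(b) > 1 && (stats::sd(a) > 0 ||
                                           stats::sd(b) > 0))
      stats::t.test(a, b, alternative = "greater")$p.value
    else as.numeric(mean(a) <= mean(b))
  })
}

#' Run the tiered trigger-gene screen
#'
#' Tier 1: genes called trigger in every explant condition. Tier 2: tier-1
#' genes whose expression also increases from the pre-window end to the
#' trigger stage in the confirmation (intact-embryo) panel. Tier 3: tier-2
#' genes passing the sharp-increase filter (Delta > `delta_min`) and the
#' expression filter (trigger-stage TPM > `tpm_min`) in the confirmation
#' panel. Gene universes are reconciled by inner join on gene id, with the
#' number of dropped ids reported.
#'
#' @param explant_panels List of [expression_panel()]s (one or more
#'   conditions each); every (panel, condition) pair is screened.
#' @param embryo_panel Confirmation [expression_panel()] (single condition
#'   used; the first if several).
#' @param criteria A [screen_criteria()].
#' @return An object of class `candidate_set`: tiers (`tier1`, `tier2`,
#'   `tier3` gene vectors), `counts`, a per-gene `audit` table, and
#'   `dropped_genes`.
#' @export
run_screen <- function(explant_panels, embryo_panel,
                       criteria = screen_criteria()) {
  if (inherits(explant_panels, "expression_panel"))
    explant_panels <- list(explant_panels)
  universes <- c(lapply(explant_panels, function(p) unique(p$gene)),
                 list(unique(embryo_panel$gene)))
  genes <- Reduce(intersect, universes)
  if (!length(genes))
    stop("gene universes are disjoint across panels", call. = FALSE)
  dropped <- length(unique(unlist(universes))) - length(genes)
  verdicts <- list()
  for (pi in seq_along(explant_panels)) {
    p <- explant_panels[[pi]]
    sh <- attr(p, "stage_hpf")
    for (cond in attr(p, "conditions")) {
      m <- stage_mean_matrix(p, cond)[genes, , drop = FALSE]
      calls <- calls_from_means(m, sh, criteria)
      if (criteria$significance_mode == "replicate_test") {
        pv <- replicate_test_p(p, cond, criteria)[genes]
        if (criteria$p_adjust) pv <- stats::p.adjust(pv, "BH")
        calls$verdict <- calls$verdict & pv <= criteria$alpha
      }
      nm <- if (length(explant_panels) > 1)
        sprintf("panel%d.%s", pi, cond) else cond
      verdicts[[nm]] <- stats::setNames(calls$verdict, calls$gene)
    }
  }
  vmat <- do.call(cbind, verdicts)
  tier1 <- genes[rowSums(vmat) == ncol(vmat)]

  sh_e <- attr(embryo_panel, "stage_hpf")
  st <- resolve_stages(sh_e, criteria)
  cond_e <- attr(embryo_panel, "conditions")[1]
  me <- stage_mean_matrix(embryo_panel, cond_e)[genes, , drop = FALSE]
  pc <- criteria$pseudocount
  fc_e <- (me[, st$trigger] + pc) / (me[, st$pre[length(st$pre)]] + pc)
  inc_e <- fc_e >= criteria$increase_min_fc
  if (criteria$significance_mode == "replicate_test") {
    pv <- replicate_test_p(embryo_panel, cond_e, criteria)[genes]
    if (criteria$p_adjust) pv <- stats::p.adjust(pv, "BH")
    inc_e <- inc_e & pv <= criteria$alpha
  }
  tier2 <- intersect(tier1, genes[inc_e])
  delta <- fc_e - 1
  tpm_trig <- me[, st$trigger]
  tier3 <- intersect(tier2,
                     genes[delta > criteria$delta_min &
                             tpm_trig > criteria$tpm_min])
  audit <- data.frame(gene = genes, vmat, embryo_fc = unname(fc_e),
                      delta = unname(delta),
                      trigger_tpm = unname(tpm_trig),
                      tier1 = genes %in% tier1, tier2 = genes %in% tier2,
                      tier3 = genes %in% tier3, row.names = NULL,
                      check.names = FALSE)
  structure(list(tier1 = tier1, tier2 = tier2, tier3 = tier3,
                 counts = c(tier1 = length(tier1), tier2 = length(tier2),
                            tier3 = length(tier3)),
                 audit = audit, dropped_genes = dropped,
                 criteria = criteria),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Tiered trigger-gene candidate set\n")
  cat(sprintf("  tier 1 (all explant conditions): %d genes\n",
              x$counts["tier1"]))
  cat(sprintf("  tier 2 (+ embryo-confirmed):     %d genes\n",
              x$counts["tier2"]))
  cat(sprintf("  tier 3 (+ Delta/TPM filters):    %d genes\n",
              x$counts["tier3"]))
  if (x$dropped_genes)
    cat(sprintf("  (%d gene ids dropped in universe intersection)\n",
                x$dropped_genes))
  invisible(x)
}

#' Fold-change and ratio trajectory for a gene pair
#'
#' Computes per-stage replicate-mean expression of two genes in one
#' condition, their fold changes relative to the first stage, and the
#' per-stage numerator/denominator ratio, locating the ratio peak (earliest
#' stage attaining the maximum) and the inversion point: the first
#' up-crossing of ratio = 1, linearly interpolated in hpf.
#'
#' @param panel An [expression_panel()].
#' @param gene_numerator,gene_denominator Gene ids.
#' @param condition Condition label (default: first condition).
#' @param pseudocount TPM pseudocount for ratios.
#' @return An object of class `ratio_trajectory`: data frame `trajectory`
#'   (`stage`, `hpf`, `fc_numerator`, `fc_denominator`, `ratio`),
#'   `peak_stage`, `peak_hpf`, `inversion_hpf` (NA when the ratio never
#'   up-crosses 1).
#' @export
ratio_trajectory <- function(panel, gene_numerator, gene_denominator,
                             condition = NULL, pseudocount = 0.1) {
  condition <- condition %||% attr(panel, "conditions")[1]
  sh <- attr(panel, "stage_hpf")
  for (g in c(gene_numerator, gene_denominator))
    if (!g %in% panel$gene)
      stop(sprintf("gene `%s` not in panel", g), call. = FALSE)
  m <- stage_mean_matrix(panel, condition)
  num <- m[gene_numerator, ]
  den <- m[gene_denominator, ]
  if (all(den == 0)) stop("ratio undefined: denominator gene has zero ",
                          "expression at all stages", call. = FALSE)
  num_p <- num + pseudocount
  den_p <- den + pseudocount
  ratio <- num_p / den_p
  traj <- data.frame(stage = names(sh), hpf = unname(sh),
                     fc_numerator = unname(num_p / num_p[1]),
                     fc_denominator = unname(den_p / den_p[1]),
                     ratio = unname(ratio), row.names = NULL)
  peak <- which.max(traj$ratio)   # which.max takes the earliest tie
  inv <- NA_real_
  up <- which(traj$ratio[-1] > 1 & traj$ratio[-nrow(traj)] <= 1)
  if (length(up)) {
    i <- up[1]
    r0 <- traj$ratio[i]; r1 <- traj$ratio[i + 1]
    inv <- traj$hpf[i] + (1 - r0) / (r1 - r0) *
      (traj$hpf[i + 1] - traj$hpf[i])
  } else if (traj$ratio[1] > 1) {
    inv <- NA_real_   # starts above 1: no up-crossing
  }
  structure(list(trajectory = traj, peak_stage = traj$stage[peak],
                 peak_hpf = traj$hpf[peak], inversion_hpf = inv,
                 gene_numerator = gene_numerator,
                 gene_denominator = gene_denominator,
                 condition = condition),
            class = "ratio_trajectory")
}

#' @export
print.ratio_trajectory <- function(x, ...) {
  cat(sprintf("%s / %s ratio trajectory (%s)\n", x$gene_numerator,
              x$gene_denominator, x$condition))
  print(x$trajectory, row.names = FALSE)
  cat(sprintf("peak at %s (%g hpf); inversion at %s hpf\n", x$peak_stage,
              x$peak_hpf,
              if (is.na(x$inversion_hpf)) "none" else
                format(x$inversion_hpf, digits = 4)))
  invisible(x)
}

#' @export
`[.expression_panel` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("gene", "stage", "tpm") %in% names(out))) {
    attr(out, "stage_hpf") <- attr(x, "stage_hpf")
    attr(out, "conditions") <- unique(out$condition)
    attr(out, "truth") <- attr(x, "truth")
    class(out) <- class(x)
  }
  out
}

#' Simulated operating characteristics of the trigger screen
#'
#' Generates explant and confirmation panels with planted trigger genes
#' over `n_seeds` independent seeds, runs the tiered screen, and pools
#' tier-1 true/false positives against the generator's ground truth.
#'
#' @param n_seeds Number of seeded replicates.
#' @param n_genes,n_planted Panel size and number of planted triggers.
#' @param noise_cv Replicate noise CV.
#' @param n_replicates Replicates per design cell.
#' @param criteria A [screen_criteria()].
#' @param seed Base seed; replicate s uses `seed + s`.
#' @return List: `sensitivity`, `specificity` (pooled over seeds),
#'   `per_seed` data frame.
#' @export
screen_performance <- function(n_seeds = 50, n_genes = 200,
                               n_planted = 20, noise_cv = 0.2,
                               n_replicates = 3,
                               criteria = screen_criteria(), seed = 1L) {
  per <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    spec <- sim_expression_spec(n_genes = n_genes,
                                planted_triggers = seq_len(n_planted),
                                noise_cv = noise_cv,
                                n_replicates = n_replicates,
                                seed = seed + s)
    panel <- gen_expression_panel(spec)
    espec <- spec
    espec$conditions <- "embryo"
    espec$seed <- substream_seed(spec$seed, 999983L)
    embryo <- gen_expression_panel(espec)
    cs <- run_screen(list(panel), embryo, criteria)
    truth <- names(attr(panel, "truth"))[attr(panel, "truth") == "trigger"]
    tp <- length(intersect(cs$tier1, truth))
    fp <- length(setdiff(cs$tier1, truth))
    per[[s]] <- data.frame(seed = seed + s, tp = tp, fp = fp,
                           fn = length(truth) - tp,
                           tn = n_genes - length(truth) - fp)
  }
  per <- do.call(rbind, per)
  list(sensitivity = sum(per$tp) / sum(per$tp + per$fn),
       specificity = sum(per$tn) / sum(per$tn + per$fp),
       per_seed = per)
}
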