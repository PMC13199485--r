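# Independent brute-force oracles, deliberately written as plain loops from
# the rule statements so they share no code path with the package.

# Per-gene trigger verdict from stage-mean TPM values (single condition).
# Rules: pre-window end/start fold change within unchanged_max_fc; trigger
# stage at least increase_min_fc over pre-window end; every later stage at
# least retention * trigger-stage mean.
oracle_trigger_verdict <- function(means, trigger_idx,
                                   unchanged_max_fc = 1.25,
                                   increase_min_fc = 1.5,
                                   retention = 0.8, pseudocount = 0.1) {
  pre_start <- means[1] + pseudocount
  pre_end <- means[trigger_idx - 1] + pseudocount
  trig <- means[trigger_idx] + pseudocount
  fc_pre <- pre_end / pre_start
  if (fc_pre > unchanged_max_fc || fc_pre < 1 / unchanged_max_fc)
    return(FALSE)
  if (trig / pre_end < increase_min_fc) return(FALSE)
  if (trigger_idx < length(means))
    for (j in (trigger_idx + 1):length(means))
      if (means[j] < retention * means[trigger_idx]) return(FALSE)
  TRUE
}

# Tier-1 oracle over a panel: a gene passes when it passes in every
# condition; means computed with plain loops.
oracle_tier1 <- function(panel, trigger_stage = "shield") {
  sh <- attr(panel, "stage_hpf")
  trigger_idx <- match(trigger_stage, names(sh))
  genes <- unique(panel$gene)
  conds <- unique(panel$condition)
  out <- character(0)
  for (g in genes) {
    ok <- TRUE
    for (cond in conds) {
      means <- numeric(length(sh))
      for (k in seq_along(sh)) {
        v <- panel$tpm[panel$gene == g & panel$condition == cond &
                         panel$stage == names(sh)[k]]
        means[k] <- sum(v) / length(v)
      }
      if (!oracle_trigger_verdict(means, trigger_idx)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, g)
  }
  out
}

# Score a gapped alignment (equal-length character vectors) under a
# substitution matrix with affine gaps costing open + (len - 1) * extend.
# Any pair involving X scores 0.
oracle_score_alignment <- function(ca, cb, mat, open, extend) {
  stopifnot(length(ca) == length(cb))
  total <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" && cb[k] == "-") stop("gap-gap column")
    if (ca[k] == "-") {
      total <- total - if (in_gap_a) extend else open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      total <- total - if (in_gap_b) extend else open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      total <- total + if (ca[k] == "X" || cb[k] == "X") 0 else
        mat[ca[k], cb[k]]
      in_gap_a <- in_gap_b <- FALSE
    }
  }
  total
}

# Exhaustive optimal global alignment score by enumerating every monotone
# alignment path (exponential; for short sequences only).
oracle_best_alignment_score <- function(a, b, mat, open, extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, cols_a, cols_b) {
    if (i > length(ca) && j > length(cb)) {
      s <- oracle_score_alignment(cols_a, cols_b, mat, open, extend)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1, j + 1, c(cols_a, ca[i]), c(cols_b, cb[j]))
    if (i <= length(ca))
      recurse(i + 1, j, c(cols_a, ca[i]), c(cols_b, "-"))
    if (j <= length(cb))
      recurse(i, j + 1, c(cols_a, "-"), c(cols_b, cb[j]))
    invisible()
  }
  recurse(1, 1, character(0), character(0))
  best
}

# Noiseless decreasing-sigmoid series on a regular grid.
make_sigmoid_series <- function(bottom = 0.3, top = 0.95, v50 = 9,
                                slope = 0.5, t = seq(6, 12, by = 1 / 6),
                                noise_sd = 0, seed = NULL) {
  r <- boltzmann(t, bottom, top, v50, slope)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + rnorm(length(t), 0, noise_sd)
  }
  data.frame(hpf = t, roundness = pmin(pmax(r, 1e-6), 1))
}

blosum62 <- cetime:::blosum62_matrix
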