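#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged per (sample, gene); the
#' delta-Ct of the target gene against the reference (housekeeping) gene is
#' referenced to the calibrator sample, and relative expression is
#' `2^-ddCt`.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct` (one row
#'   per technical replicate).
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id.
#' @param calibrator Calibrator sample id.
#' @return Data frame of class `ddct_result`: per sample, mean/SD Ct of
#'   target and reference, `dct`, `ddct`, `fold_change`.
#' @export
ddct <- function(ct_table, target, reference, calibrator) {
  need <- c("sample", "gene", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop_field("ct_table",
               paste("missing columns:", paste(miss, collapse = ", ")))
  bad <- !is.finite(ct_table$ct)
  if (any(bad)) {
    warning(sprintf("dropping %d non-finite Ct rows", sum(bad)),
            call. = FALSE)
    ct_table <- ct_table[!bad, , drop = FALSE]
  }
  samples <- unique(ct_table$sample)
  if (!calibrator %in% samples)
    stop(sprintf("calibrator sample `%s` not present", calibrator),
         call. = FALSE)
  for (s in samples) for (g in c(target, reference))
    if (!any(ct_table$sample == s & ct_table$gene == g))
      stop(sprintf("gene `%s` missing in sample `%s`", g, s),
           call. = FALSE)
  agg <- function(g, fun) sapply(samples, function(s)
    fun(ct_table$ct[ct_table$sample == s & ct_table$gene == g]))
  mt <- agg(target, mean); mr <- agg(reference, mean)
  st <- agg(target, stats::sd); sr <- agg(reference, stats::sd)
  dct <- mt - mr
  ddct <- dct - dct[samples == calibrator]
  structure(data.frame(sample = samples, ct_target_mean = unname(mt),
                       ct_target_sd = unname(st),
                       ct_reference_mean = unname(mr),
                       ct_reference_sd = unname(sr), dct = unname(dct),
                       ddct = unname(ddct),
                       fold_change = unname(2^-ddct), row.names = NULL),
            target = target, reference = reference,
            calibrator = calibrator,
            class = c("ddct_result", "data.frame"))
}

hs_disaccharide_codes <- c("D0A0", "D0S0", "D0A6", "D0S6",
                           "D2A0", "D2S0", "D2A6", "D2S6")

#' Internal-standard quantification of HS disaccharides
#'
#' Each disaccharide is quantified against its isotopically labeled
#' internal standard: `amount = (light area / heavy area) * standard_pmol`.
#' Amounts are optionally normalized to total protein and expressed as a
#' percentage of the summed quantified species.
#'
#' @param peak_table Data frame with columns `code`, `area_light`,
#'   `area_heavy`.
#' @param standard_pmol Spiked standard amount per disaccharide (default
#'   20 pmol).
#' @param protein_ug Total protein (BCA), ug; optional.
#' @return Data frame of class `disaccharide_table`: `code`, areas,
#'   `amount_pmol`, `pmol_per_ug` (when protein given), `percent`,
#'   `quantifiable`.
#' @export
quantify_disaccharides <- function(peak_table, standard_pmol = 20,
                                   protein_ug = NULL) {
  need <- c("code", "area_light", "area_heavy")
  miss <- setdiff(need, names(peak_table))
  if (length(miss))
    stop_field("peak_table",
               paste("missing columns:", paste(miss, collapse = ", ")))
  check_number(standard_pmol, "standard_pmol", lower = 0)
  if (!is.null(protein_ug)) {
    check_number(protein_ug, "protein_ug")
    if (protein_ug <= 0) stop_field("protein_ug", "must be > 0")
  }
  if (any(peak_table$area_light < 0 | peak_table$area_heavy < 0))
    stop_field("peak_table", "peak areas must be >= 0")
  unknown <- setdiff(peak_table$code, hs_disaccharide_codes)
  if (length(unknown))
    warning(sprintf("unknown disaccharide code(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  quant <- peak_table$area_heavy > 0
  if (!any(quant))
    stop("no quantifiable disaccharides (all heavy-channel areas zero)",
         call. = FALSE)
  amount <- ifelse(quant,
                   peak_table$area_light / peak_table$area_heavy *
                     standard_pmol, NA_real_)
  total <- sum(amount[quant])
  percent <- ifelse(quant,
                    if (total > 0) 100 * amount / total else 0, NA_real_)
  out <- data.frame(code = peak_table$code,
                    area_light = peak_table$area_light,
                    area_heavy = peak_table$area_heavy,
                    amount_pmol = amount, percent = percent,
                    quantifiable = quant)
  if (!is.null(protein_ug)) out$pmol_per_ug <- amount / protein_ug
  structure(out, standard_pmol = standard_pmol,
            protein_ug = protein_ug %||% NA_real_,
            class = c("disaccharide_table", "data.frame"))
}

amino_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

check_protein <- function(seq, field, allow_gaps = FALSE) {
  if (!nzchar(seq)) stop_field(field, "sequence is empty")
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- amino_alphabet
  if (allow_gaps) ok <- c(ok, "-")
  bad <- which(!ch %in% ok)
  if (length(bad))
    stop_field(field, sprintf("unknown character `%s` at position %d",
                              ch[bad[1]], bad[1]))
  ch
}

# Pair score: BLOSUM62 with any pair involving X scored 0.
pair_score <- function(a, b, mat) {
  s <- mat[cbind(a, b)]
  s[a == "X" | b == "X"] <- 0
  s
}

#' Global pairwise alignment with affine gaps (Needleman-Wunsch/Gotoh)
#'
#' Dynamic-programming global alignment under a substitution matrix with
#' affine gap penalties: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param seq_a,seq_b Protein sequences (20-letter alphabet plus X, which
#'   scores 0 against everything).
#' @param substitution Substitution matrix (default the built-in
#'   BLOSUM62), or the string `"BLOSUM62"`.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List: `aligned_a`, `aligned_b` (gapped strings), `score`.
#' @export
align_global <- function(seq_a, seq_b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  mat <- if (is.character(substitution) &&
             identical(substitution, "BLOSUM62")) blosum62_matrix
  else as.matrix(substitution)
  a <- check_protein(seq_a, "seq_a")
  b <- check_protein(seq_b, "seq_b")
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in seq_b (a residue vs -)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in seq_a (- vs b residue)
  M[1, 1] <- 0
  if (n >= 1) Ix[2:(n + 1), 1] <- -gap_open - (0:(n - 1)) * gap_extend
  if (m >= 1) Iy[1, 2:(m + 1)] <- -gap_open - (0:(m - 1)) * gap_extend
  for (i in seq_len(n)) {
    srow <- pair_score(a[i], b, mat)
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + srow[j]
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open,
                              Iy[i, j + 1] - gap_open,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open,
                              Ix[i + 1, j] - gap_open,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  # traceback
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1],
                       Iy[n + 1, m + 1]))
  score <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])[state]
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  eps <- 1e-9
  while (i > 0 || j > 0) {
    if (state == 1) {
      s <- pair_score(a[i], b[j], mat)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which(abs(prev + s - M[i + 1, j + 1]) < eps)[1]
      ra <- c(a[i], ra); rb <- c(b[j], rb)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      cur <- Ix[i + 1, j + 1]
      cand <- c(M[i, j + 1] - gap_open, Ix[i, j + 1] - gap_extend,
                Iy[i, j + 1] - gap_open)
      state <- c(1, 2, 3)[which(abs(cand - cur) < eps)[1]]
      ra <- c(a[i], ra); rb <- c("-", rb)
      i <- i - 1
    } else {
      cur <- Iy[i + 1, j + 1]
      cand <- c(M[i + 1, j] - gap_open, Ix[i + 1, j] - gap_open,
                Iy[i + 1, j] - gap_extend)
      state <- c(1, 2, 3)[which(abs(cand - cur) < eps)[1]]
      ra <- c("-", ra); rb <- c(b[j], rb)
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- 3
    if (j == 0 && i > 0) state <- 2
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""), score = score)
}

#' Percent identity and similarity of a protein pair
#'
#' Aligns two sequences globally (unless `prealigned`) and reports percent
#' identity (identical columns) and percent similarity (columns whose
#' residue pair has a positive substitution score, identities included).
#' The default denominator is the number of columns where both sequences
#' have residues (gaps excluded); `denominator = "any_residue"` counts
#' columns with at least one residue instead.
#'
#' @param seq_a,seq_b Protein sequences; with `prealigned = TRUE`, gapped
#'   aligned strings of equal length.
#' @param prealigned Are the inputs already aligned?
#' @param substitution Substitution matrix or `"BLOSUM62"`.
#' @param gap_open,gap_extend Gap penalties for the alignment step.
#' @param denominator `"both_residues"` (default) or `"any_residue"`.
#' @return List of class `alignment_stats`: `identity`, `similarity`
#'   (percent), `alignment_length`, `gap_count`, `aligned_a`, `aligned_b`,
#'   `score` (NA when prealigned).
#' @export
pairwise_identity_similarity <- function(seq_a, seq_b, prealigned = FALSE,
                                         substitution = "BLOSUM62",
                                         gap_open = 10, gap_extend = 0.5,
                                         denominator = c("both_residues",
                                                         "any_residue")) {
  denominator <- match.arg(denominator)
  mat <- if (is.character(substitution) &&
             identical(substitution, "BLOSUM62")) blosum62_matrix
  else as.matrix(substitution)
  if (prealigned) {
    ca <- check_protein(seq_a, "seq_a", allow_gaps = TRUE)
    cb <- check_protein(seq_b, "seq_b", allow_gaps = TRUE)
    if (length(ca) != length(cb))
      stop("prealigned sequences must have equal length", call. = FALSE)
    score <- NA_real_
  } else {
    aln <- align_global(seq_a, seq_b, substitution = mat,
                        gap_open = gap_open, gap_extend = gap_extend)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    score <- aln$score
  }
  both <- ca != "-" & cb != "-"
  any_res <- ca != "-" | cb != "-"
  denom <- if (denominator == "both_residues") sum(both) else sum(any_res)
  if (denom == 0) stop("alignment has no residue columns", call. = FALSE)
  ident <- both & ca == cb
  simil <- ident
  if (any(both)) {
    sc <- pair_score(ca[both], cb[both], mat)
    simil[both] <- simil[both] | sc > 0
  }
  structure(list(identity = 100 * sum(ident) / denom,
                 similarity = 100 * sum(simil) / denom,
                 alignment_length = length(ca),
                 gap_count = sum(!both), aligned_a = paste(ca, collapse = ""),
                 aligned_b = paste(cb, collapse = ""), score = score),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("identity %.1f%%, similarity %.1f%% over %d columns (%d gap columns)\n",
              x$identity, x$similarity, x$alignment_length, x$gap_count))
  invisible(x)
}
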