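# Expression deregulation ranking: the R statistic (patient-versus-control
# outlier ratio), ranked gene lists, target-set enrichment against an
# expected background rate, and a delta-delta-Ct relative-expression utility
# with multiple endogenous controls.

#' Deregulation ratio of a patient value against controls
#'
#' R is the distance from the patient expression value P to the closest
#' control value C, divided by the expression range within controls:
#' R = |P - C| / (Cmax - Cmin).  R is 0 iff P equals some control value, and
#' is invariant under affine transforms of the expression scale.  Ties in
#' the closest-control selection take the larger control value.
#'
#' @param P Patient expression value.
#' @param controls Numeric vector of at least two control values.
#' @return R >= 0, or NA (with a warning) when the controls have zero range.
#' @examples
#' deregulation_ratio(10, c(2, 4, 6))  # 1
#' @export
deregulation_ratio <- function(P, controls) {
  stopifnot(is.numeric(P), length(P) == 1L, is.numeric(controls))
  if (length(controls) < 2L) stop("at least two control values required")
  if (any(!is.finite(c(P, controls)))) stop("values must be finite")
  rng <- max(controls) - min(controls)
  if (rng <= 0) {
    warning("control range is zero; R undefined", call. = FALSE)
    return(NA_real_)
  }
  d <- abs(controls - P)
  dmin <- min(d)
  dmin / rng
}

#' Rank genes by expression deregulation
#'
#' Computes R per gene with the patient column against all remaining columns
#' and sorts genes by R, descending; ties (including the all-zero case where
#' every patient value sits on a control value) keep the input order.  Genes
#' with an undefined R (zero control range) are placed last and flagged.
#'
#' @param mat Numeric matrix or data.frame of expression values, genes in
#'   rows (rownames or a `gene` column), samples in columns.
#' @param patient Name of the patient column.
#' @param flags Optional data.frame (gene, ...) of upstream prefilter flags
#'   (e.g. differential-expression significance) carried through to the
#'   output; the flags are inputs, not recomputed here.
#' @param r_threshold Threshold defining the deregulated subset.
#' @return data.frame gene, R, deregulated (R >= threshold), rank, plus any
#'   flag columns.
#' @export
rank_deregulated <- function(mat, patient, flags = NULL, r_threshold = 0.9) {
  if (is.data.frame(mat) && "gene" %in% names(mat)) {
    genes <- mat$gene
    mat <- as.matrix(mat[, setdiff(names(mat), "gene"), drop = FALSE])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(mat)
    genes <- rownames(mat)
  }
  if (!patient %in% colnames(mat)) stop("patient column not found")
  ctrl <- mat[, setdiff(colnames(mat), patient), drop = FALSE]
  if (ncol(ctrl) < 2L) stop("at least two control samples required")
  R <- vapply(seq_len(nrow(mat)), function(i)
    suppressWarnings(deregulation_ratio(mat[i, patient], ctrl[i, ])),
    numeric(1))
  ord <- order(-R, na.last = TRUE)   # stable: ties keep input order
  out <- data.frame(gene = genes[ord], R = R[ord],
                    deregulated = !is.na(R[ord]) & R[ord] >= r_threshold,
                    undefined_R = is.na(R[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  if (!is.null(flags)) out <- merge(out, flags, by = "gene", sort = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Enrichment of predicted targets in a gene set
#'
#' Compares the observed proportion of predicted-target genes in a set
#' against an expected background rate with an exact one-sided binomial test
#' (alternative: greater).
#'
#' @param genes Character vector of genes in the set.
#' @param targets Character vector of predicted-target genes (or a logical
#'   vector along `genes`).
#' @param expected_rate Background target rate in (0, 1).
#' @return List: n, n_targets, proportion, percent, expected_rate, p_value.
#' @examples
#' target_enrichment(paste0("g", 1:31), paste0("g", 1:21), 0.30)$percent
#' @export
target_enrichment <- function(genes, targets, expected_rate) {
  if (!length(genes)) stop("gene set is empty")
  stopifnot(expected_rate > 0, expected_rate < 1)
  x <- if (is.logical(targets)) sum(targets) else sum(genes %in% targets)
  n <- length(genes)
  bt <- stats::binom.test(x, n, p = expected_rate, alternative = "greater")
  list(n = n, n_targets = x, proportion = x / n, percent = 100 * x / n,
       expected_rate = expected_rate, p_value = unname(bt$p.value))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalises a target gene's Ct values against the mean Ct of one or more
#' endogenous control genes per replicate (arithmetic mean of Ct values,
#' i.e. the geometric mean of the linear expression of the controls), then
#' against a calibrator sample: fold = 2^-(ddCt).  The per-sample dispersion
#' is the standard deviation of the per-replicate fold changes.
#'
#' @param ct data.frame with columns sample, gene, replicate, ct.
#' @param target Target gene name.
#' @param controls Character vector of endogenous control gene names.
#' @param calibrator Sample whose ddCt is defined as 0.
#' @return data.frame sample, n_rep, dct, ddct, fold, fold_sd.  Samples with
#'   a missing control Ct are skipped with a warning.
#' @export
relative_expression <- function(ct, target, controls, calibrator) {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct)),
            length(controls) >= 1)
  samples <- unique(ct$sample)
  per_sample <- lapply(samples, function(s) {
    d <- ct[ct$sample == s, , drop = FALSE]
    reps <- sort(unique(d$replicate[d$gene == target]))
    dcts <- vapply(reps, function(r) {
      tg <- d$ct[d$gene == target & d$replicate == r]
      cc <- vapply(controls, function(g) {
        v <- d$ct[d$gene == g & d$replicate == r]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
      if (!length(tg) || any(is.na(cc))) return(NA_real_)
      tg[1] - mean(cc)
    }, numeric(1))
    dcts <- dcts[!is.na(dcts)]
    if (!length(dcts)) {
      warning("sample ", s, " skipped: missing control Ct", call. = FALSE)
      return(NULL)
    }
    data.frame(sample = s, n_rep = length(dcts), dct = mean(dcts),
               dct_reps = I(list(dcts)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_sample)
  if (is.null(res) || !calibrator %in% res$sample)
    stop("calibrator sample has no usable Ct values")
  cal <- res$dct[res$sample == calibrator]
  res$ddct <- res$dct - cal
  res$fold <- 2^(-res$ddct)
  res$fold_sd <- vapply(seq_len(nrow(res)), function(i) {
    folds <- 2^(-(res$dct_reps[[i]] - cal))
    if (length(folds) > 1L) stats::sd(folds) else NA_real_
  }, numeric(1))
  res$dct_reps <- NULL
  rownames(res) <- NULL
  res
}
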