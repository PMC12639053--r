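#' Invert the log transform to a pseudo-count matrix
#'
#' The count-based negative-binomial tests (edgeR, DESeq2) need integer
#' input, so the log2 quantities are transformed back to the linear scale
#' (`2^x - 1`, the exact inverse of the `log2(x + 1)` transform), clipped
#' at 0 (batch correction can push log2 values slightly negative), scaled
#' by 10000 and rounded up (ceiling).
#'
#' @param m a log2-scale `QuantMatrix` (complete).
#' @return integer matrix with the same dimnames.
#' @export
counts_from_log <- function(m) {
  x <- if (inherits(m, "QuantMatrix")) m$values else m
  counts <- ceiling(pmax(2^x - 1, 0) * 10000)
  storage.mode(counts) <- "double"  # values can exceed .Machine$integer.max
  counts
}

#' Differential expression test between two sample groups
#'
#' Runs one of seven per-protein two-group tests on a (complete,
#' batch-corrected) log2 matrix:
#'
#' * `Welch`: Welch's unequal-variance t-test (vectorized).
#' * `Wilcox`: Wilcoxon-Mann-Whitney rank-sum test (exact for small
#'   tie-free groups, normal approximation otherwise).
#' * `ModT_Trend`: limma linear model with empirical-Bayes variance
#'   moderation towards an intensity-dependent trend (`trend = TRUE`).
#' * `ModT_Voom`: limma-voom; observation-level precision weights from the
#'   fitted mean-variance trend, then moderated t. Runs on
#'   [counts_from_log()] output, as voom expects counts.
#' * `NB_QLF` / `NB_LRT`: edgeR negative-binomial GLM with quasi-likelihood
#'   F-test / likelihood-ratio test on [counts_from_log()] output.
#' * `NB_Wald_Shrink`: DESeq2 negative-binomial Wald test on
#'   [counts_from_log()] output.
#'
#' For every method `log2fc` is reported uniformly as the difference of
#' group means of the log2 quantities (group `a` minus group `b`), which is
#' what the ground-truth confusion labeling uses; the model's own
#' coefficient for the count-based tests is kept in `model_log2fc`.
#' P-values are BH-adjusted across proteins.
#'
#' @param m a log2-scale `QuantMatrix` without missing values.
#' @param ann a `SampleAnnotation`.
#' @param comparison character vector `c(group_a, group_b)`.
#' @param method test registry label.
#' @return a `data.frame` (`DEResult`) with columns `protein_id`, `log2fc`,
#'   `model_log2fc`, `statistic`, `p`, `p_adj`, `method`.
#' @export
run_test <- function(m, ann, comparison,
                     method = c("Welch", "Wilcox", "ModT_Trend", "ModT_Voom",
                                "NB_QLF", "NB_LRT", "NB_Wald_Shrink")) {
  method <- match.arg(method)
  ann <- sample_annotation(ann, m)
  a <- comparison[1]; b <- comparison[2]
  if (!all(c(a, b) %in% ann$group)) stop("comparison group missing from annotation")
  sel <- ann$group %in% c(a, b)
  v <- m$values[, sel, drop = FALSE]
  grp <- factor(ann$group[sel], levels = c(b, a))  # coefficient = a vs b
  if (min(table(grp)) < 2L) stop("each comparison group needs >= 2 samples")
  ia <- grp == a; ib <- grp == b
  lfc <- rowMeans(v[, ia, drop = FALSE]) - rowMeans(v[, ib, drop = FALSE])

  res <- switch(method,
    Welch = welch_rows(v, ia, ib),
    Wilcox = wilcox_rows(v, ia, ib),
    ModT_Trend = {
      design <- stats::model.matrix(~grp)
      fit <- limma::eBayes(limma::lmFit(v, design), trend = TRUE)
      tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
      list(stat = tt$t, p = tt$P.Value, model_lfc = tt$logFC)
    },
    ModT_Voom = {
      design <- stats::model.matrix(~grp)
      counts <- counts_from_log(qm_update(m, v))
      vw <- limma::voom(counts, design)
      fit <- limma::eBayes(limma::lmFit(vw, design))
      tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
      list(stat = tt$t, p = tt$P.Value, model_lfc = tt$logFC)
    },
    NB_QLF = edger_rows(v, grp, m, use_qlf = TRUE),
    NB_LRT = edger_rows(v, grp, m, use_qlf = FALSE),
    NB_Wald_Shrink = deseq_rows(v, grp, m))

  p <- res$p
  out <- data.frame(protein_id = rownames(v),
                    log2fc = unname(lfc),
                    model_log2fc = unname(res$model_lfc),
                    statistic = unname(res$stat),
                    p = unname(p),
                    p_adj = unname(bh_adjust(p)),
                    method = method,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

welch_rows <- function(v, ia, ib) {
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(v[, ia, drop = FALSE]); mb <- rowMeans(v[, ib, drop = FALSE])
  va <- apply(v[, ia, drop = FALSE], 1L, stats::var)
  vb <- apply(v[, ib, drop = FALSE], 1L, stats::var)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  zero <- se2 == 0
  stat[zero & (ma == mb)] <- 0
  p[zero & (ma == mb)] <- 1
  p[zero & (ma != mb)] <- NaN  # zero variance, nonzero difference: undefined
  list(stat = stat, p = p, model_lfc = ma - mb)
}

wilcox_rows <- function(v, ia, ib) {
  res <- apply(v, 1L, function(r) {
    w <- suppressWarnings(stats::wilcox.test(r[ia], r[ib], exact = NULL, correct = TRUE))
    c(w$statistic, w$p.value)
  })
  list(stat = res[1, ], p = res[2, ],
       model_lfc = rowMeans(v[, ia, drop = FALSE]) - rowMeans(v[, ib, drop = FALSE]))
}

edger_rows <- function(v, grp, m, use_qlf = TRUE) {
  counts <- counts_from_log(qm_update(m, v))
  design <- stats::model.matrix(~grp)
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "none")
  y <- edgeR::estimateDisp(y, design)
  if (use_qlf) {
    fit <- edgeR::glmQLFit(y, design)
    tst <- edgeR::glmQLFTest(fit, coef = 2)
  } else {
    fit <- edgeR::glmFit(y, design)
    tst <- edgeR::glmLRT(fit, coef = 2)
  }
  tab <- tst$table
  stat <- if (use_qlf) tab$F else tab$LR
  list(stat = stat, p = tab$PValue, model_lfc = tab$logFC)
}

deseq_rows <- function(v, grp, m) {
  counts <- counts_from_log(qm_update(m, v))
  # DESeq2 stores counts as 32-bit integers; very intense matrices are
  # globally rescaled by a power of 10 (absorbed by the size factors)
  if (max(counts) >= .Machine$integer.max) {
    scale <- 10^ceiling(log10(max(counts) / (.Machine$integer.max - 1)))
    counts <- ceiling(counts / scale)
  }
  storage.mode(counts) <- "integer"
  coldata <- data.frame(group = grp)
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = counts, colData = coldata, design = ~group))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE, fitType = "parametric",
                                        sfType = "ratio", minReplicatesForReplace = Inf))
  res <- DESeq2::results(dds, contrast = c("group", levels(grp)[2], levels(grp)[1]),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  list(stat = res$stat, p = res$pvalue, model_lfc = res$log2FoldChange)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` that passes `NaN`/`NA`
#' entries through untouched.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out[is.nan(p)] <- NaN
  out
}

#' Cohen's d standardized effect size
#'
#' `(mean(a) - mean(b)) / pooled SD`; `NaN` when the pooled SD is 0.
#'
#' @param a,b numeric vectors with at least two values each.
#' @return scalar effect size.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) return(NaN)
  (mean(a) - mean(b)) / sqrt(sp2)
}
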