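#' Method registries for the five workflow steps
#'
#' The default benchmarking grid spans 4 sparsity-reduction x 7 imputation
#' x 5 normalization x 5 batch-correction x 7 differential-test methods
#' (4900 combinations).
#'
#' @return named list of character vectors, one per step, in pipeline order.
#' @export
method_registries <- function() {
  list(
    sparsity = c("NoSR", "SR66", "SR75", "SR90"),
    imputation = c("Zero", "HalfRowMin", "RowMean", "RowMedian", "KNN",
                   "IterativeSVD", "SoftImpute"),
    normalization = c("Unnorm", "Median", "Sum", "QN", "TRQN"),
    batch_correction = c("NoBC", "RegressOut", "ComBatP", "ComBatNP",
                         "ScanoramaAdapter"),
    test = c("Welch", "Wilcox", "ModT_Trend", "ModT_Voom", "NB_QLF",
             "NB_LRT", "NB_Wald_Shrink"))
}

sparsity_fraction <- function(label) {
  switch(label, NoSR = 0, SR66 = 0.66, SR75 = 0.75, SR90 = 0.90,
         stop("unknown sparsity label: ", label))
}

#' Sparsity reduction: drop proteins below a data-completeness floor
#'
#' Retains proteins observed (non-missing) in at least
#' `min_completeness * n_samples` samples; "at least p%" of n samples is
#' read as `count >= ceiling(p * n - 1e-9)`, so e.g. 75% of 4 samples
#' means at least 3. The sample set is unchanged.
#'
#' @param m a `QuantMatrix`.
#' @param min_completeness fraction in `[0, 1]`; 0 keeps everything (NoSR).
#'   A registry label (`"SR75"` etc.) is also accepted.
#' @return the filtered `QuantMatrix`.
#' @export
sparsity_reduce <- function(m, min_completeness) {
  if (is.character(min_completeness))
    min_completeness <- sparsity_fraction(min_completeness)
  stopifnot(min_completeness >= 0, min_completeness <= 1)
  if (nrow(m$values) == 0L) stop("empty matrix")
  need <- ceiling(min_completeness * ncol(m$values) - 1e-9)
  keep <- rowSums(!is.na(m$values)) >= need
  if (!any(keep)) warning("sparsity reduction removed all proteins")
  m[keep, ]
}

#' Missing-value imputation
#'
#' Seven methods spanning constant, row-statistic and matrix-completion
#' families. Rows are proteins. The four simple methods (`Zero`,
#' `HalfRowMin`, `RowMean`, `RowMedian`) never alter an observed entry;
#' `KNN`, `IterativeSVD` and `SoftImpute` also restore observed entries
#' exactly, imputing only the missing positions from the completed fit.
#'
#' * `KNN`: per protein with missing entries, the `k` nearest protein rows
#'   (Euclidean distance on mutually observed columns, scaled to the full
#'   column count) supply a distance-weighted mean of their values in the
#'   missing column.
#' * `IterativeSVD`: iterative low-rank SVD completion (hard-thresholded
#'   rank-`rank` reconstruction, iterated to convergence).
#' * `SoftImpute`: soft-thresholded SVD completion; the shrinkage value
#'   defaults to `max(singular value)/50` of the zero-filled matrix.
#'
#' @param m a `QuantMatrix` (raw scale).
#' @param method imputation registry label.
#' @param k neighbors for KNN.
#' @param rank target rank for IterativeSVD.
#' @param max_iter,tol iteration controls for the SVD methods.
#' @param shrinkage soft threshold for SoftImpute (`NULL` = heuristic).
#' @return a complete `QuantMatrix` (no `NA`).
#' @export
impute <- function(m, method = c("Zero", "HalfRowMin", "RowMean", "RowMedian",
                                 "KNN", "IterativeSVD", "SoftImpute"),
                   k = 5L, rank = 10L, max_iter = 200L, tol = 1e-4,
                   shrinkage = NULL) {
  method <- match.arg(method)
  v <- m$values
  miss <- is.na(v)
  if (!any(miss)) return(m)
  if (method %in% c("HalfRowMin", "RowMean", "RowMedian", "KNN")) {
    empty <- rowSums(!miss) == 0L
    if (any(empty))
      stop("protein(s) with no observed value under ", method,
           "; apply sparsity reduction first: ",
           paste(utils::head(rownames(v)[empty], 3), collapse = ", "))
  }
  out <- switch(method,
    Zero = { v[miss] <- 0; v },
    HalfRowMin = impute_row_stat(v, function(r) min(r, na.rm = TRUE) / 2),
    RowMean = impute_row_stat(v, function(r) mean(r, na.rm = TRUE)),
    RowMedian = impute_row_stat(v, function(r) stats::median(r, na.rm = TRUE)),
    KNN = impute_knn(v, k = k),
    IterativeSVD = impute_iterative_svd(v, rank = rank, max_iter = max_iter, tol = tol),
    SoftImpute = impute_soft(v, shrinkage = shrinkage, max_iter = max_iter, tol = 1e-5))
  out[out < 0] <- 0  # matrix completion may undershoot; abundances stay non-negative
  out[!miss] <- v[!miss]
  qm_update(m, out)
}

impute_row_stat <- function(v, f) {
  fill <- apply(v, 1L, f)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- fill[idx[, 1L]]
  v
}

impute_knn <- function(v, k = 5L) {
  miss <- is.na(v)
  rows_missing <- which(rowSums(miss) > 0L)
  n <- nrow(v)
  for (i in rows_missing) {
    xi <- v[i, ]
    shared <- !is.na(xi) & t(!miss)         # samples x proteins: mutually observed
    d2 <- colSums((xi - t(v))^2 * shared, na.rm = TRUE)
    n_shared <- colSums(shared)
    d <- sqrt(d2 / pmax(n_shared, 1L) * ncol(v))  # rescale to full column count
    d[n_shared == 0L] <- Inf
    d[i] <- Inf
    for (j in which(miss[i, ])) {
      cand <- which(!miss[, j] & is.finite(d))
      if (!length(cand)) next
      nb <- cand[order(d[cand], rownames(v)[cand])][seq_len(min(k, length(cand)))]
      w <- 1 / pmax(d[nb], 1e-12)
      v[i, j] <- sum(w * v[nb, j]) / sum(w)
    }
    # neighbors may not cover a column at all; fall back to the row mean
    still <- is.na(v[i, ])
    if (any(still)) v[i, still] <- mean(xi, na.rm = TRUE)
  }
  v
}

# iterate: fill -> rank-r SVD reconstruction of the fill -> refill
impute_iterative_svd <- function(v, rank = 10L, max_iter = 200L, tol = 1e-4) {
  miss <- is.na(v)
  r <- min(rank, nrow(v) - 1L, ncol(v) - 1L)
  fill <- v
  col_means <- colMeans(v, na.rm = TRUE)
  col_means[is.nan(col_means)] <- mean(v, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  fill[idx] <- col_means[idx[, 2L]]
  for (it in seq_len(max_iter)) {
    s <- svd(fill, nu = r, nv = r)
    recon <- s$u %*% (s$d[seq_len(r)] * t(s$v))
    new <- v
    new[miss] <- recon[miss]
    delta <- sqrt(sum((new - fill)^2)) / max(sqrt(sum(fill^2)), 1e-12)
    fill <- new
    if (delta < tol) break
  }
  fill
}

# soft-thresholded SVD completion
impute_soft <- function(v, shrinkage = NULL, max_iter = 200L, tol = 1e-5) {
  miss <- is.na(v)
  fill <- v
  fill[miss] <- 0
  if (is.null(shrinkage)) shrinkage <- svd(fill, nu = 0, nv = 0)$d[1] / 50
  for (it in seq_len(max_iter)) {
    s <- svd(fill)
    d <- pmax(s$d - shrinkage, 0)
    keep <- d > 0
    recon <- if (any(keep))
      s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
    else matrix(0, nrow(v), ncol(v))
    new <- v
    new[miss] <- recon[miss]
    delta <- sqrt(sum((new - fill)^2)) / max(sqrt(sum(fill^2)), 1e-12)
    fill <- new
    if (delta < tol) break
  }
  fill
}

#' Sample-level normalization of raw quantities
#'
#' Operates on raw (pre-log) quantities, before [log_transform()]:
#'
#' * `Sum`: columns scaled so every column sum equals the mean original
#'   column sum.
#' * `Median`: columns scaled so every column median equals the mean
#'   original column median.
#' * `QN`: quantile normalization; each column's order statistics are
#'   replaced by the across-column mean order statistics (ties averaged).
#' * `TRQN`: tail-robust QN; QN is applied, then the top `tail_fraction`
#'   of each column (by original rank) is rescaled back towards the
#'   original scale by the column's median original/QN ratio over that
#'   tail, so extreme high-abundance proteins are not forced onto the
#'   common quantile grid.
#' * `Unnorm`: strict identity.
#'
#' @param m a `QuantMatrix`; complete (no `NA`) for `QN`/`TRQN`.
#' @param method normalization registry label.
#' @param tail_fraction fraction of top values treated robustly by TRQN.
#' @return the normalized `QuantMatrix`.
#' @export
normalize_quant <- function(m, method = c("Unnorm", "Median", "Sum", "QN", "TRQN"),
                            tail_fraction = 0.05) {
  method <- match.arg(method)
  v <- m$values
  if (method == "Unnorm") return(m)
  if (method %in% c("QN", "TRQN") && anyNA(v))
    stop(method, " requires a complete matrix; impute first")
  out <- switch(method,
    Sum = {
      cs <- colSums(v, na.rm = TRUE)
      if (any(cs == 0)) stop("zero column sum in sample ", colnames(v)[which(cs == 0)[1]])
      sweep(v, 2L, cs / mean(cs), "/")
    },
    Median = {
      cm <- apply(v, 2L, stats::median, na.rm = TRUE)
      if (any(cm == 0)) stop("zero column median in sample ", colnames(v)[which(cm == 0)[1]])
      sweep(v, 2L, cm / mean(cm), "/")
    },
    QN = quantile_normalize(v),
    TRQN = {
      qn <- quantile_normalize(v)
      out <- qn
      n_tail <- max(1L, ceiling(tail_fraction * nrow(v)))
      for (j in seq_len(ncol(v))) {
        tail_idx <- order(v[, j], decreasing = TRUE)[seq_len(n_tail)]
        ratio <- stats::median(v[tail_idx, j] / pmax(qn[tail_idx, j], 1e-12))
        out[tail_idx, j] <- qn[tail_idx, j] * ratio
      }
      out
    })
  qm_update(m, out)
}

# classic QN; ties within a column receive the average of their target
# order statistics (limma::normalizeQuantiles with ties=TRUE semantics)
quantile_normalize <- function(v) {
  limma::normalizeQuantiles(v, ties = TRUE)
}

#' Log2 transform with a pseudocount of 1
#'
#' `x -> log2(x + 1)`, applied after normalization so zero stays zero.
#'
#' @param m a `QuantMatrix` of non-negative values.
#' @return the transformed `QuantMatrix` (log2 scale).
#' @export
log_transform <- function(m) {
  if (any(m$values[!is.na(m$values)] < 0)) stop("negative value in log_transform input")
  qm_update(m, log2(m$values + 1), log2_scale = TRUE)
}
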