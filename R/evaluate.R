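#' Direction-aware confusion counts against species ground truth
#'
#' A protein is "called" when its (adjusted) p-value is below `p0` and its
#' `|log2fc|` exceeds `t0`. Ground-truth positives (species with a nonzero
#' design ratio) count as TP only when called in the expected direction
#' (`expected_positive_down` needs `log2fc < -t0`, `expected_positive_up`
#' needs `log2fc > t0`); a positive called in the wrong direction or not
#' called is FN. Ground-truth negatives (constant species) are FP when
#' called in either direction, TN otherwise. Proteins with undefined
#' p-values are excluded and reported in `n_untested`.
#'
#' @param de a `DEResult` from [run_test()].
#' @param truth named label vector from [truth_labels()].
#' @param p0 p-value threshold.
#' @param t0 absolute log2 fold-change threshold (>= 0).
#' @param use_adjusted use BH-adjusted p-values (default) or raw.
#' @return list with `tp`, `fp`, `tn`, `fn`, `n_untested`.
#' @export
confusion_counts <- function(de, truth, p0 = 0.05, t0 = log2(1.2),
                             use_adjusted = TRUE) {
  stopifnot(t0 >= 0)
  lab <- truth[de$protein_id]
  if (anyNA(lab)) stop("tested protein without a truth label")
  p <- if (use_adjusted) de$p_adj else de$p
  tested <- !is.na(p)
  p <- p[tested]; lab <- lab[tested]; lfc <- de$log2fc[tested]
  sig <- p < p0
  called_up <- sig & lfc > t0
  called_down <- sig & lfc < -t0
  tp <- sum((lab == "expected_positive_up" & called_up) |
            (lab == "expected_positive_down" & called_down))
  fn <- sum(lab %in% c("expected_positive_up", "expected_positive_down")) - tp
  fp <- sum(lab == "expected_negative" & (called_up | called_down))
  tn <- sum(lab == "expected_negative") - fp
  list(tp = tp, fp = fp, tn = tn, fn = fn, n_untested = sum(!tested))
}

#' ROC curve and partial AUC below an FPR ceiling
#'
#' Scores are `-log10` (adjusted) p-values with the same direction gate as
#' [confusion_counts()]: a ground-truth positive whose fold change points
#' the wrong way can never become a true positive, at any threshold. The
#' ROC curve sweeps the score threshold; the partial AUC is the unnormalized
#' trapezoidal area over FPR in `[0, fpr_max]` (maximum `fpr_max`, i.e. 0.1
#' at the default: the value of a perfect classifier).
#'
#' @param de a `DEResult`.
#' @param truth named label vector from [truth_labels()].
#' @param fpr_max FPR ceiling (default 0.1).
#' @param use_adjusted use BH-adjusted p-values for scores.
#' @return list with `roc` (data.frame of fpr, tpr) and `pauc`.
#' @export
roc_pauc <- function(de, truth, fpr_max = 0.1, use_adjusted = TRUE) {
  lab <- truth[de$protein_id]
  if (anyNA(lab)) stop("tested protein without a truth label")
  p <- if (use_adjusted) de$p_adj else de$p
  tested <- !is.na(p)
  p <- p[tested]; lab <- lab[tested]; lfc <- de$log2fc[tested]
  is_pos <- lab %in% c("expected_positive_up", "expected_positive_down")
  n_pos <- sum(is_pos); n_neg <- sum(lab == "expected_negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined metric: need both ground-truth positives and negatives")
  score <- -log10(pmax(p, 1e-300))
  wrong_dir <- (lab == "expected_positive_up" & lfc <= 0) |
               (lab == "expected_positive_down" & lfc >= 0)
  score[wrong_dir] <- -Inf
  pauc_from_scores(score, is_pos, fpr_max = fpr_max)
}

# threshold sweep + clipped trapezoid; scores of -Inf never pass
pauc_from_scores <- function(score, is_pos, fpr_max = 0.1) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- is_pos[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one ROC point per distinct score
  finite <- is.finite(s[last])
  tpr <- c(0, (tp[last] / n_pos)[finite])
  fpr <- c(0, (fp[last] / n_neg)[finite])
  # clip at fpr_max with linear interpolation
  above <- fpr > fpr_max
  if (any(above)) {
    i <- which(above)[1]
    t_at <- tpr[i - 1] + (tpr[i] - tpr[i - 1]) *
      (fpr_max - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    fpr <- c(fpr[seq_len(i - 1)], fpr_max)
    tpr <- c(tpr[seq_len(i - 1)], t_at)
  } else if (utils::tail(fpr, 1) < fpr_max) {
    # wrong-direction positives never enter; curve is flat to fpr_max
    fpr <- c(fpr, fpr_max); tpr <- c(tpr, utils::tail(tpr, 1))
  }
  pauc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), pauc = pauc)
}

#' Optimize the p-value and fold-change thresholds for recall at a
#' precision floor
#'
#' Searches the p-value grid (0.1, 0.05, 0.01, 0.001 by default) crossed
#' with every distinct observed `|log2fc|` (plus 0) as the fold-change
#' threshold, and picks the pair maximizing recall subject to
#' `precision >= precision_floor`. Ties prefer the smaller `t0`, then the
#' larger `p0` (favoring sensitivity). When the floor is unattainable the
#' maximum-precision point is returned with `floor_met = FALSE`.
#'
#' @param de a `DEResult`.
#' @param truth named label vector.
#' @param p0_grid candidate p-value thresholds.
#' @param precision_floor required precision (default 0.95).
#' @param use_adjusted use BH-adjusted p-values.
#' @return list with `p0_opt`, `t0_opt`, `floor_met`, and the confusion /
#'   derived metrics (`tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `accuracy`, `f1`) at the optimum.
#' @export
optimize_thresholds <- function(de, truth, p0_grid = c(0.1, 0.05, 0.01, 0.001),
                                precision_floor = 0.95, use_adjusted = TRUE) {
  t0_grid <- sort(unique(c(0, abs(de$log2fc))))
  t0_grid <- t0_grid[is.finite(t0_grid)]
  best <- NULL; best_any <- NULL
  for (p0 in sort(p0_grid, decreasing = TRUE)) {
    for (t0 in t0_grid) {
      cc <- confusion_counts(de, truth, p0 = p0, t0 = t0, use_adjusted = use_adjusted)
      met <- derive_metrics(cc)
      cand <- c(list(p0_opt = p0, t0_opt = t0), cc, met)
      if (is.null(best_any) || met$precision > best_any$precision) best_any <- cand
      if (met$precision >= precision_floor) {
        if (is.null(best) ||
            met$recall > best$recall ||
            (met$recall == best$recall && t0 < best$t0_opt) ||
            (met$recall == best$recall && t0 == best$t0_opt && p0 > best$p0_opt))
          best <- cand
      }
    }
  }
  if (is.null(best)) {
    best <- best_any
    best$floor_met <- FALSE
  } else best$floor_met <- TRUE
  best
}

derive_metrics <- function(cc) {
  with(cc, {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    accuracy <- (tp + tn) / max(tp + tn + fp + fn, 1L)
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
  })
}

#' Adjusted Rand index (pair-counting form)
#'
#' Over all sample pairs, let `a` = same true label and same cluster, `b` =
#' same label, different cluster, `c` = different label, same cluster, `d` =
#' different label, different cluster. Then
#' `ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))`. 1 means a perfect match;
#' 0 is the expectation under random clustering.
#'
#' @param labels_a,labels_b two partitions of the same items.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2L)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  c_ <- sum(choose(colSums(tab), 2)) - a
  d <- choose(n, 2) - a - b - c_
  denom <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (denom == 0) return(1)  # both partitions trivial and identical in pair structure
  2 * (a * d - b * c_) / denom
}

#' Graph-based sample clustering (PCA -> SNN -> Louvain)
#'
#' Principal components of the (protein-centered) log2 matrix feed a
#' shared-nearest-neighbor graph (Jaccard edge weights over `k_snn`-nearest
#' neighbor sets, pruned below 1/15), whose Louvain communities are the
#' discovered clusters. Deterministic under the fixed `seed`.
#'
#' @param m a `QuantMatrix` (log2 scale, complete).
#' @param n_pcs number of principal components (lowered with a warning when
#'   there are fewer samples).
#' @param k_snn neighbors for the SNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the community search.
#' @return integer cluster label per sample (named).
#' @export
cluster_samples <- function(m, n_pcs = 10L, k_snn = 5L, resolution = 0.8, seed = 0L) {
  v <- m$values
  n <- ncol(v)
  if (n < 3L) stop("need >= 3 samples to cluster")
  n_pcs_eff <- min(n_pcs, n - 1L, nrow(v))
  if (n_pcs_eff < n_pcs) warning("n_pcs lowered to ", n_pcs_eff)
  k_eff <- min(k_snn, n - 1L)
  pcs <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs_eff), drop = FALSE]
  d <- as.matrix(stats::dist(pcs))
  nn <- apply(d, 1L, function(row) order(row)[2:(k_eff + 1L)])  # k x n, excludes self
  nn_sets <- lapply(seq_len(n), function(i) c(i, nn[, i]))
  edges <- NULL; weights <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(nn_sets[[i]], nn_sets[[j]]))
    w <- shared / (2L * (k_eff + 1L) - shared)
    if (w > 1 / 15) { edges <- c(edges, i, j); weights <- c(weights, w) }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges, weight = weights)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(igraph::membership(comm), colnames(v))
}

#' Aggregate per-metric ranks into a total rank
#'
#' Each metric is ranked descending (higher is better, ties averaged; `NaN`
#' gets the worst rank). The total rank is the rank of the summed metric
#' ranks, with residual ties broken by input order (stable).
#'
#' @param records data.frame with columns `ari`, `pauc`, `f1` (one row per
#'   method combination).
#' @return the data.frame with `rank_ari`, `rank_pauc`, `rank_f1`,
#'   `total_rank` columns added.
#' @export
aggregate_rank <- function(records) {
  stopifnot(nrow(records) >= 1L)
  rank_desc <- function(x) {
    x[is.na(x)] <- -Inf  # NaN metric ranks worst
    rank(-x, ties.method = "average")
  }
  records$rank_ari <- rank_desc(records$ari)
  records$rank_pauc <- rank_desc(records$pauc)
  records$rank_f1 <- rank_desc(records$f1)
  total <- records$rank_ari + records$rank_pauc + records$rank_f1
  records$total_rank <- rank(total, ties.method = "first")
  records
}
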