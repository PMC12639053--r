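ranker_steps <- function(include_sparsity = FALSE) {
  steps <- c("imputation", "normalization", "batch_correction", "test")
  if (include_sparsity) c("sparsity", steps) else steps
}

encode_records <- function(records, steps) {
  reg <- method_registries()
  X <- vapply(steps, function(s) as.numeric(match(records[[s]], reg[[s]]) - 1L),
              numeric(nrow(records)))
  X <- matrix(X, nrow = nrow(records), dimnames = list(NULL, steps))
  if (anyNA(X)) stop("record contains a method label outside the registries")
  X
}

#' Fit a learning-to-rank model on benchmark metrics records
#'
#' The method labels of each combination are ordinal-encoded as categorical
#' features and the aggregated total rank is the target of an XGBoost
#' gradient-boosted tree ensemble with the pairwise ranking objective
#' (`rank:pairwise`, all records in a single ranking group); the model is
#' trained so that a higher predicted score means a better (lower) total
#' rank. By default the ranker is trained within one sparsity stratum and
#' sparsity is not a feature; set `include_sparsity = TRUE` to add it.
#'
#' @param records metrics data.frame from [run_grid()] (rows with
#'   `status != "ok"` or missing `total_rank` are dropped).
#' @param seed RNG seed for the booster.
#' @param include_sparsity add the sparsity label as a fifth feature.
#' @param nrounds,max_depth,eta booster hyperparameters.
#' @return an object of class `scp_ranker`.
#' @export
fit_ranker <- function(records, seed = 0L, include_sparsity = FALSE,
                       nrounds = 200L, max_depth = 4L, eta = 0.1) {
  records <- records[!is.na(records$total_rank), , drop = FALSE]
  if ("status" %in% names(records))
    records <- records[records$status == "ok", , drop = FALSE]
  if (nrow(records) < 20L) stop("need >= 20 scored records to fit a ranker")
  if (length(unique(records$total_rank)) < 2L) stop("all ranks tied; nothing to learn")
  steps <- ranker_steps(include_sparsity)
  X <- encode_records(records, steps)
  relevance <- max(records$total_rank) - records$total_rank  # higher = better
  dtrain <- xgboost::xgb.DMatrix(X, label = relevance)
  xgboost::setinfo(dtrain, "group", nrow(X))
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "rank:pairwise", max_depth = max_depth, eta = eta,
                  nthread = 1L, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, steps = steps, records = records),
            class = "scp_ranker")
}

#' Predicted ranking scores
#' @param object an `scp_ranker`.
#' @param newdata records data.frame (defaults to the training records).
#' @param ... ignored.
#' @return numeric scores, higher = predicted better.
#' @export
predict.scp_ranker <- function(object, newdata = object$records, ...) {
  stats::predict(object$booster, encode_records(newdata, object$steps))
}

#' Feature importance of the fitted ranker
#' @param model an `scp_ranker`.
#' @return data.frame of per-step gain importance.
#' @export
ranker_importance <- function(model) {
  as.data.frame(xgboost::xgb.importance(model = model$booster))
}

#' SHAP explanation of the high-performing combinations
#'
#' Computes exact tree-SHAP attributions and pairwise SHAP interaction
#' values for the top fraction (default 25%) of combinations by total
#' rank, then aggregates: mean absolute SHAP per step, the per-method SHAP
#' distribution with its 5th percentile (the conservative "value at risk"
#' summary used downstream), mean absolute interaction per step pair, and
#' the per-method-pair interaction distribution with its 5th percentile.
#'
#' @param model an `scp_ranker`.
#' @param records records to explain (defaults to training records).
#' @param top_fraction fraction of best combinations explained.
#' @return a `ShapSummary` list with elements `step_importance`,
#'   `method_shap`, `step_pair_interaction`, `method_pair_interaction`,
#'   `top_fraction`, `n_top`, plus the raw per-record matrices.
#' @export
shap_explain <- function(model, records = model$records, top_fraction = 0.25) {
  records <- records[!is.na(records$total_rank), , drop = FALSE]
  n_top <- max(1L, floor(top_fraction * nrow(records)))
  top <- records[order(records$total_rank), , drop = FALSE][seq_len(n_top), , drop = FALSE]
  X <- encode_records(top, model$steps)
  contrib <- stats::predict(model$booster, X, predcontrib = TRUE)
  inter <- stats::predict(model$booster, X, predinteraction = TRUE)
  steps <- model$steps
  K <- length(steps)

  step_importance <- data.frame(
    step = steps,
    mean_abs_shap = vapply(seq_len(K), function(k) mean(abs(contrib[, k])), numeric(1)),
    stringsAsFactors = FALSE)

  p5 <- function(x) unname(stats::quantile(x, 0.05, type = 7))
  method_shap <- do.call(rbind, lapply(seq_len(K), function(k) {
    do.call(rbind, lapply(unique(top[[steps[k]]]), function(mth) {
      vals <- contrib[top[[steps[k]]] == mth, k]
      data.frame(step = steps[k], method = mth, n = length(vals),
                 mean_shap = mean(vals), p5 = p5(vals), stringsAsFactors = FALSE)
    }))
  }))
  rownames(method_shap) <- NULL

  # interaction between features i and j of one record: symmetric halves summed
  pair_val <- function(i, j) inter[, i, j] + inter[, j, i]
  pairs <- which(upper.tri(matrix(TRUE, K, K)), arr.ind = TRUE)
  step_pair_interaction <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    data.frame(step_a = steps[i], step_b = steps[j],
               mean_abs_interaction = mean(abs(pair_val(i, j))),
               stringsAsFactors = FALSE)
  }))

  method_pair_interaction <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    v <- pair_val(i, j)
    combos <- unique(top[, c(steps[i], steps[j])])
    do.call(rbind, lapply(seq_len(nrow(combos)), function(q) {
      sel <- top[[steps[i]]] == combos[q, 1] & top[[steps[j]]] == combos[q, 2]
      data.frame(step_a = steps[i], method_a = combos[q, 1],
                 step_b = steps[j], method_b = combos[q, 2],
                 n = sum(sel), mean_interaction = mean(v[sel]), p5 = p5(v[sel]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(method_pair_interaction) <- NULL

  structure(list(step_importance = step_importance,
                 method_shap = method_shap,
                 step_pair_interaction = step_pair_interaction,
                 method_pair_interaction = method_pair_interaction,
                 top_fraction = top_fraction, n_top = n_top,
                 contrib = contrib, interaction = inter, top_records = top,
                 steps = steps),
            class = c("ShapSummary", "list"))
}

# additive surrogate score of a full/partial combination under a ShapSummary
surrogate_score <- function(s, steps, methods) {
  ms <- s$method_shap; mp <- s$method_pair_interaction
  total <- 0
  for (k in seq_along(steps)) {
    row <- ms[ms$step == steps[k] & ms$method == methods[k], ]
    total <- total + if (nrow(row)) row$p5 else 0
    if (k > 1L) for (l in seq_len(k - 1L)) {
      pr <- mp[(mp$step_a == steps[l] & mp$method_a == methods[l] &
                  mp$step_b == steps[k] & mp$method_b == methods[k]) |
               (mp$step_a == steps[k] & mp$method_a == methods[k] &
                  mp$step_b == steps[l] & mp$method_b == methods[l]), ]
      if (nrow(pr)) total <- total + sum(pr$p5)
    }
  }
  total
}

#' Conservative beam-search selection of recommended workflows
#'
#' Steps are ordered by descending mean absolute SHAP value. Within each
#' step, candidate methods are those appearing at least `min_n` times in
#' the explained top set (rarer methods are excluded and flagged). Partial
#' combinations are scored additively by the 5th percentiles of the
#' per-method SHAP distributions plus the 5th percentiles of the pairwise
#' interaction distributions with the methods already chosen (a
#' "value at risk" style conservative score); only the best `W` partial
#' combinations survive each expansion. Ties are broken lexicographically
#' by method label.
#'
#' @param s a `ShapSummary`.
#' @param W beam width (default 12).
#' @param min_n minimum occurrences in the top set for a method to be a
#'   candidate.
#' @return a `BeamSelection`: `selection` data.frame (rank, one column per
#'   step in pipeline order, `score`), `step_order`, `excluded` methods,
#'   and `W`.
#' @export
beam_select <- function(s, W = 12L, min_n = 3L) {
  steps <- s$step_importance$step[order(-s$step_importance$mean_abs_shap)]
  ms <- s$method_shap
  candidates <- lapply(steps, function(st) {
    rows <- ms[ms$step == st, ]
    sort(rows$method[rows$n >= min_n])
  })
  names(candidates) <- steps
  excluded <- do.call(rbind, lapply(steps, function(st) {
    rows <- ms[ms$step == st & ms$n < min_n, ]
    if (nrow(rows)) data.frame(step = st, method = rows$method, n = rows$n,
                               stringsAsFactors = FALSE) else NULL
  }))
  if (any(!lengths(candidates)))
    stop("a step has no candidate method with n >= ", min_n)

  beam <- list(list(methods = character(0), score = 0))
  for (k in seq_along(steps)) {
    expanded <- list()
    for (partial in beam) for (mth in candidates[[k]]) {
      methods <- c(partial$methods, mth)
      expanded[[length(expanded) + 1L]] <-
        list(methods = methods,
             score = surrogate_score(s, steps[seq_len(k)], methods))
    }
    scores <- vapply(expanded, `[[`, numeric(1), "score")
    keys <- vapply(expanded, function(e) paste(e$methods, collapse = "|"), character(1))
    ord <- order(-scores, keys)  # ties: lexicographic by method labels
    beam <- expanded[ord[seq_len(min(W, length(expanded)))]]
  }

  sel <- do.call(rbind, lapply(seq_along(beam), function(i) {
    row <- as.data.frame(as.list(stats::setNames(beam[[i]]$methods, steps)),
                         stringsAsFactors = FALSE)
    row$score <- beam[[i]]$score
    row$rank <- i
    row
  }))
  pipeline_order <- intersect(c("sparsity", "imputation", "normalization",
                                "batch_correction", "test"), steps)
  sel <- sel[, c("rank", pipeline_order, "score")]
  structure(list(selection = sel, step_order = steps, excluded = excluded, W = W),
            class = c("BeamSelection", "list"))
}

#' Export a beam selection as a Graphviz decision tree
#'
#' Nodes are `step: method` choices along the beam's step order; edge
#' order (and an `order` edge attribute) encodes the conditional priority
#' given by the best surrogate score below each branch.
#'
#' @param b a `BeamSelection`.
#' @return a single string of DOT digraph text.
#' @export
export_tree <- function(b) {
  sel <- b$selection
  steps <- b$step_order
  if (!nrow(sel)) stop("empty selection")
  nodes <- c("root [label=\"start\"];")
  edges <- character(0)
  seen <- character(0)
  # order branches by the best score among selections passing through them
  for (k in seq_along(steps)) {
    prefixes <- unique(sel[, steps[seq_len(k)], drop = FALSE])
    best <- apply(prefixes, 1L, function(pref) {
      match_rows <- rep(TRUE, nrow(sel))
      for (l in seq_len(k)) match_rows <- match_rows & sel[[steps[l]]] == pref[[l]]
      max(sel$score[match_rows])
    })
    prefixes <- prefixes[order(-best), , drop = FALSE]
    for (r in seq_len(nrow(prefixes))) {
      id <- paste0("n_", gsub("[^A-Za-z0-9]", "_",
                              paste(prefixes[r, ], collapse = "__")))
      if (!id %in% seen) {
        seen <- c(seen, id)
        nodes <- c(nodes, sprintf("%s [label=\"%s: %s\"];", id,
                                  steps[k], prefixes[r, k]))
        parent <- if (k == 1L) "root" else
          paste0("n_", gsub("[^A-Za-z0-9]", "_",
                            paste(prefixes[r, seq_len(k - 1L)], collapse = "__")))
        edges <- c(edges, sprintf("%s -> %s [order=%d];", parent, id, length(edges) + 1L))
      }
    }
  }
  paste0("digraph beam_selection {\n  rankdir=LR;\n  ",
         paste(c(nodes, edges), collapse = "\n  "), "\n}\n")
}
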