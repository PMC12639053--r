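#' Specification of a method-combination grid run
#'
#' @param registries named list of method label vectors per step (defaults
#'   to the full registries of [method_registries()]: 4 x 7 x 5 x 5 x 7 =
#'   4900 combinations).
#' @param comparison two group names for the differential test.
#' @param p0,t0 fixed significance / fold-change thresholds used for the
#'   reported fixed-threshold confusion metrics (ranking uses the optimized
#'   F1, see [optimize_thresholds()]).
#' @param precision_floor precision floor for threshold optimization.
#' @param use_adjusted use BH-adjusted p-values for scoring.
#' @param covariates pass group covariates to the batch correctors.
#' @param cluster_params list(n_pcs, k_snn, resolution) for [cluster_samples()].
#' @param seed seed for the clustering stage.
#' @param adapter_command external corrector command (`NULL` = adapter slot
#'   disabled; such combinations are recorded as skipped).
#' @return a `GridSpec` list.
#' @export
grid_spec <- function(registries = method_registries(),
                      comparison = c("S4", "S2"),
                      p0 = 0.05, t0 = log2(1.2),
                      precision_floor = 0.95,
                      use_adjusted = TRUE,
                      covariates = TRUE,
                      cluster_params = list(n_pcs = 10L, k_snn = 5L, resolution = 0.8),
                      seed = 0L,
                      adapter_command = NULL) {
  full <- method_registries()
  for (step in names(registries)) {
    if (!step %in% names(full)) stop("unknown grid step: ", step)
    bad <- setdiff(registries[[step]], full[[step]])
    if (length(bad)) stop("unknown method(s) for step ", step, ": ", paste(bad, collapse = ", "))
  }
  reg <- utils::modifyList(full, registries)
  structure(list(registries = reg, comparison = comparison, p0 = p0, t0 = t0,
                 precision_floor = precision_floor, use_adjusted = use_adjusted,
                 covariates = covariates, cluster_params = cluster_params,
                 seed = as.integer(seed), adapter_command = adapter_command),
            class = c("GridSpec", "list"))
}

#' Enumerate all method combinations of a grid
#'
#' Cartesian product of the step registries in deterministic lexicographic
#' order of the pipeline step order (sparsity varies slowest, test fastest).
#'
#' @param g a `GridSpec`.
#' @return data.frame with one row per combination and one column per step.
#' @export
enumerate_grid <- function(g) {
  r <- g$registries
  if (any(!lengths(r))) stop("empty registry")
  combos <- expand.grid(test = r$test,
                        batch_correction = r$batch_correction,
                        normalization = r$normalization,
                        imputation = r$imputation,
                        sparsity = r$sparsity,
                        stringsAsFactors = FALSE)
  combos <- combos[, c("sparsity", "imputation", "normalization",
                       "batch_correction", "test")]
  rownames(combos) <- NULL
  combos
}

#' Execute the full benchmarking grid
#'
#' For every method combination: sparsity reduction -> imputation ->
#' normalization -> log2 transform -> batch correction -> clustering/ARI ->
#' differential test -> ground-truth scoring (pAUC, fixed-threshold and
#' optimized confusion metrics), with shared-prefix caching (a prefix is
#' recomputed once and reused by every combination extending it; results
#' are identical to an uncached run). Failing combinations are recorded
#' with a skip reason, never aborting the grid.
#'
#' @param m a raw-scale `QuantMatrix` with species labels.
#' @param ann a `SampleAnnotation`.
#' @param truth a `GroundTruth` from [simulate_matrix()] or a named label
#'   vector from [truth_labels()].
#' @param g a `GridSpec`.
#' @param verbose print one line per prefix.
#' @return a `data.frame` of `MetricsRecord` rows: the five method labels,
#'   `ari`, `pauc`, confusion counts and derived metrics at the fixed
#'   thresholds, optimized thresholds (`p0_opt`, `t0_opt`) with their `f1`,
#'   ranks from [aggregate_rank()], `status` and `elapsed` seconds.
#' @export
run_grid <- function(m, ann, truth, g = grid_spec(), verbose = FALSE) {
  ann <- sample_annotation(ann, m)
  labels <- if (inherits(truth, "GroundTruth"))
    truth_labels(truth, g$comparison) else truth
  reg <- g$registries
  group_truth <- stats::setNames(ann$group, ann$sample_id)
  records <- list()

  for (sr in reg$sparsity) {
    m_sr <- tryCatch(sparsity_reduce(m, sr), error = function(e) e)
    for (imp in reg$imputation) {
      m_imp <- if (inherits(m_sr, "error")) m_sr else
        tryCatch(impute(m_sr, imp), error = function(e) e)
      for (nm in reg$normalization) {
        m_log <- if (inherits(m_imp, "error")) m_imp else
          tryCatch(log_transform(normalize_quant(m_imp, nm)), error = function(e) e)
        for (bc in reg$batch_correction) {
          t_bc <- Sys.time()
          bc_out <- if (inherits(m_log, "error")) m_log else
            tryCatch(suppressWarnings(
              batch_correct(m_log, ann, bc, covariates = g$covariates,
                            adapter_command = g$adapter_command)),
              error = function(e) e)
          ari <- NA_real_
          if (!inherits(bc_out, "error")) {
            cl <- tryCatch(cluster_samples(
              bc_out, n_pcs = g$cluster_params$n_pcs, k_snn = g$cluster_params$k_snn,
              resolution = g$cluster_params$resolution, seed = g$seed),
              error = function(e) e, warning = function(w) suppressWarnings(
                cluster_samples(bc_out, n_pcs = g$cluster_params$n_pcs,
                                k_snn = g$cluster_params$k_snn,
                                resolution = g$cluster_params$resolution, seed = g$seed)))
            if (!inherits(cl, "error"))
              ari <- adjusted_rand(group_truth[names(cl)], cl)
          }
          if (verbose)
            message(sprintf("[%s|%s|%s|%s] %s", sr, imp, nm, bc,
                            if (inherits(bc_out, "error")) conditionMessage(bc_out)
                            else sprintf("ARI=%.3f", ari)))
          for (tst in reg$test) {
            rec <- data.frame(sparsity = sr, imputation = imp, normalization = nm,
                              batch_correction = bc, test = tst,
                              ari = ari, pauc = NA_real_,
                              tp = NA_integer_, fp = NA_integer_,
                              tn = NA_integer_, fn = NA_integer_,
                              tpr = NA_real_, fpr = NA_real_,
                              precision = NA_real_, recall = NA_real_,
                              accuracy = NA_real_, f1_fixed = NA_real_,
                              p0_opt = NA_real_, t0_opt = NA_real_, f1 = NA_real_,
                              status = "ok", elapsed = NA_real_,
                              stringsAsFactors = FALSE)
            t0c <- Sys.time()
            if (inherits(bc_out, "error")) {
              rec$status <- if (inherits(bc_out, "skip_combination"))
                conditionMessage(bc_out) else paste0("skipped:", conditionMessage(bc_out))
            } else {
              de <- tryCatch(run_test(bc_out, ann, g$comparison, tst),
                             error = function(e) e)
              if (inherits(de, "error")) {
                rec$status <- paste0("skipped:", conditionMessage(de))
              } else {
                cc <- confusion_counts(de, labels, p0 = g$p0, t0 = g$t0,
                                       use_adjusted = g$use_adjusted)
                met <- derive_metrics(cc)
                rp <- tryCatch(roc_pauc(de, labels, use_adjusted = g$use_adjusted),
                               error = function(e) NULL)
                opt <- optimize_thresholds(de, labels,
                                           precision_floor = g$precision_floor,
                                           use_adjusted = g$use_adjusted)
                rec$pauc <- if (is.null(rp)) NA_real_ else rp$pauc
                rec$tp <- cc$tp; rec$fp <- cc$fp; rec$tn <- cc$tn; rec$fn <- cc$fn
                rec$tpr <- met$recall
                rec$fpr <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_
                rec$precision <- met$precision; rec$recall <- met$recall
                rec$accuracy <- met$accuracy; rec$f1_fixed <- met$f1
                rec$p0_opt <- opt$p0_opt; rec$t0_opt <- opt$t0_opt; rec$f1 <- opt$f1
              }
            }
            rec$elapsed <- as.numeric(difftime(Sys.time(), t0c, units = "secs")) +
              if (tst == reg$test[1]) as.numeric(difftime(t0c, t_bc, units = "secs")) else 0
            records[[length(records) + 1L]] <- rec
          }
        }
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  ok <- out$status == "ok"
  if (any(ok)) {
    ranked <- aggregate_rank(out[ok, , drop = FALSE])
    out$rank_ari <- out$rank_pauc <- out$rank_f1 <- out$total_rank <- NA_real_
    out[ok, c("rank_ari", "rank_pauc", "rank_f1", "total_rank")] <-
      ranked[, c("rank_ari", "rank_pauc", "rank_f1", "total_rank")]
  }
  out
}
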