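#' Batch-effect correction by linear-model residualization
#'
#' Fits, per protein, a linear model with batch indicator columns (and the
#' biological group design as covariates when `covariates = TRUE`, so real
#' group differences are not absorbed into the batch term) and subtracts
#' only the fitted batch component, preserving the grand mean. This is the
#' `removeBatchEffect` approach of the limma package, which performs the
#' fit here.
#'
#' @param m a log2-scale `QuantMatrix`.
#' @param ann a `SampleAnnotation` covering the samples of `m`.
#' @param covariates logical; include group as a covariate (default TRUE).
#' @return the corrected `QuantMatrix` (same shape and ids).
#' @export
regress_out_batch <- function(m, ann, covariates = TRUE) {
  ann <- sample_annotation(ann, m)
  if (length(unique(ann$batch)) < 2L) {
    warning("single batch; regress_out_batch is the identity")
    return(m)
  }
  check_confounded(ann, covariates)
  design <- if (covariates) stats::model.matrix(~factor(ann$group)) else matrix(1, nrow(ann), 1)
  corrected <- limma::removeBatchEffect(m$values, batch = factor(ann$batch),
                                        design = design)
  qm_update(m, corrected)
}

check_confounded <- function(ann, covariates) {
  if (!covariates) return(invisible(TRUE))
  tab <- table(ann$batch, ann$group)
  # batch nested in group (each batch sees one group) makes the design singular
  if (all(rowSums(tab > 0) == 1L))
    stop("batch is confounded with group (each batch contains a single group); ",
         "cannot separate batch from biology with covariates on")
  invisible(TRUE)
}

#' Empirical-Bayes location/scale batch correction (ComBat)
#'
#' Standardizes each protein (removing the covariate fit and pooled
#' variance), estimates per-batch location (gamma) and scale (delta^2)
#' effects, shrinks them via empirical Bayes -- conjugate normal /
#' inverse-gamma updates in parametric mode, Monte-Carlo weighted
#' posteriors in non-parametric mode -- then adjusts and back-transforms.
#' Delegates to `sva::ComBat`; biological group is supplied as a model
#' covariate when `covariates = TRUE`.
#'
#' @param m a log2-scale `QuantMatrix`.
#' @param ann a `SampleAnnotation`.
#' @param mode `"parametric"` or `"nonparametric"` prior.
#' @param covariates logical; include group in the model matrix.
#' @return the corrected `QuantMatrix`.
#' @export
combat_correct <- function(m, ann, mode = c("parametric", "nonparametric"),
                           covariates = TRUE) {
  mode <- match.arg(mode)
  ann <- sample_annotation(ann, m)
  if (length(unique(ann$batch)) < 2L) {
    warning("single batch; combat_correct is the identity")
    return(m)
  }
  if (any(table(ann$batch) < 2L)) stop("every batch needs >= 2 samples for scale estimation")
  check_confounded(ann, covariates)
  v <- m$values
  # sva::ComBat drops rows with zero within-batch variance from estimation;
  # proteins that are globally constant are left unadjusted with a warning
  const <- apply(v, 1L, function(r) stats::var(r) == 0 || !is.finite(stats::var(r)))
  if (any(const)) warning(sum(const), " zero-variance protein(s) left unadjusted")
  mod <- if (covariates) stats::model.matrix(~factor(ann$group)) else NULL
  corrected <- v
  # sva reports progress on stdout; keep grid runs quiet
  utils::capture.output(adj <- suppressMessages(
    sva::ComBat(dat = v[!const, , drop = FALSE], batch = factor(ann$batch),
                mod = mod, par.prior = (mode == "parametric"),
                prior.plots = FALSE)))
  corrected[!const, ] <- adj
  qm_update(m, corrected)
}

#' Adapter slot for an external batch-correction tool
#'
#' Runs a user-declared external command with a matrix-in/matrix-out
#' contract: the command receives the matrix TSV and annotation TSV paths
#' as its two trailing arguments plus an output path, and must write a
#' corrected matrix TSV of identical shape and identifiers. The adapter
#' ships disabled: when `command` is `NULL` the combination is marked
#' skipped rather than silently substituted.
#'
#' @param m a log2-scale `QuantMatrix`.
#' @param ann a `SampleAnnotation`.
#' @param command character vector: the executable and any leading
#'   arguments, or `NULL` (not configured).
#' @return the corrected `QuantMatrix`, or a `skip_combination` condition
#'   when the adapter is unavailable.
#' @export
external_corrector_adapter <- function(m, ann, command = NULL) {
  if (is.null(command) || !nzchar(command[1]))
    stop(skip_condition("skipped:adapter (no external corrector configured)"))
  if (Sys.which(command[1]) == "" && !file.exists(command[1]))
    stop(skip_condition(paste0("skipped:adapter (command not found: ", command[1], ")")))
  ann <- sample_annotation(ann, m)
  tmp_in <- tempfile(fileext = ".tsv"); tmp_ann <- tempfile(fileext = ".tsv")
  tmp_out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_in, tmp_ann, tmp_out)), add = TRUE)
  write_quant_tsv(m, tmp_in)
  utils::write.table(ann, tmp_ann, sep = "\t", quote = FALSE, row.names = FALSE)
  status <- system2(command[1], c(command[-1], tmp_in, tmp_ann, tmp_out))
  if (status != 0L || !file.exists(tmp_out))
    stop("external corrector failed with status ", status)
  out <- read_quant_tsv(tmp_out)
  if (!identical(dim(out$values), dim(m$values)) ||
      !identical(rownames(out$values), qm_proteins(m)) ||
      !identical(colnames(out$values), qm_samples(m)))
    stop("external corrector violated the matrix contract (shape or ids changed)")
  qm_update(m, out$values)
}

skip_condition <- function(msg) {
  structure(class = c("skip_combination", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Apply a batch-correction registry label
#'
#' @param m log2-scale `QuantMatrix`.
#' @param ann `SampleAnnotation`.
#' @param method registry label (`NoBC`, `RegressOut`, `ComBatP`,
#'   `ComBatNP`, `ScanoramaAdapter`).
#' @param covariates passed to the native correctors.
#' @param adapter_command command for `ScanoramaAdapter` (default `NULL`,
#'   i.e. the slot is disabled and such combinations are skipped).
#' @return corrected `QuantMatrix`.
#' @export
batch_correct <- function(m, ann, method, covariates = TRUE, adapter_command = NULL) {
  switch(method,
    NoBC = m,
    RegressOut = regress_out_batch(m, ann, covariates = covariates),
    ComBatP = combat_correct(m, ann, mode = "parametric", covariates = covariates),
    ComBatNP = combat_correct(m, ann, mode = "nonparametric", covariates = covariates),
    ScanoramaAdapter = external_corrector_adapter(m, ann, command = adapter_command),
    stop("unknown batch correction method: ", method))
}
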