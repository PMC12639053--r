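#' Descriptive quality-control metrics for a quantification matrix
#'
#' Computes the standard report-level QC panel: per-run protein counts,
#' the data-completeness curve (number of proteins quantified in at least
#' a given fraction of runs), per-protein coefficients of variation within
#' replicate groups (SD/mean of raw quantities), and, when a reference
#' group is given, per-species median log2 fold changes of group means
#' against the reference together with their deviation from the design
#' values, plus Welch p and Cohen's d comparing each species' fold-change
#' distribution against the constant (human) background.
#'
#' @param m a raw-scale `QuantMatrix` with species labels.
#' @param ann a `SampleAnnotation`; `group` defines the replicate groups.
#' @param reference_group optional group name used as fold-change reference.
#' @param completeness_grid fractions for the completeness curve.
#' @return list with `per_run_counts`, `completeness`, `cv`, and (with a
#'   reference) `fold_changes`.
#' @export
qc_metrics <- function(m, ann, reference_group = NULL,
                       completeness_grid = seq(0, 1, by = 0.1)) {
  ann <- sample_annotation(ann, m)
  v <- m$values
  obs <- !is.na(v)

  per_run_counts <- data.frame(sample_id = colnames(v),
                               n_proteins = colSums(obs),
                               stringsAsFactors = FALSE)

  frac_obs <- rowMeans(obs)
  completeness <- data.frame(
    min_fraction = completeness_grid,
    n_proteins = vapply(completeness_grid,
                        function(f) sum(frac_obs >= f - 1e-9), integer(1)))

  cv_rows <- lapply(unique(ann$group), function(g) {
    sub <- v[, ann$group == g, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdev <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    ok <- rowSums(!is.na(sub)) >= 2L & mu > 0
    data.frame(group = g, protein_id = rownames(v)[ok],
               cv = (sdev / mu)[ok], stringsAsFactors = FALSE)
  })
  cv <- do.call(rbind, cv_rows); rownames(cv) <- NULL

  out <- list(per_run_counts = per_run_counts, completeness = completeness, cv = cv)

  if (!is.null(reference_group)) {
    sp <- qm_species(m)
    ref_mean <- rowMeans(v[, ann$group == reference_group, drop = FALSE], na.rm = TRUE)
    rows <- list()
    for (g in setdiff(unique(ann$group), reference_group)) {
      gm <- rowMeans(v[, ann$group == g, drop = FALSE], na.rm = TRUE)
      lfc <- log2(gm / ref_mean)
      ok <- is.finite(lfc)
      human_lfc <- lfc[ok & sp == "human"]
      for (s in unique(sp)) {
        sl <- lfc[ok & sp == s]
        if (!length(sl)) next
        wp <- if (s != "human" && length(human_lfc) >= 2L && length(sl) >= 2L)
          tryCatch(stats::t.test(sl, human_lfc)$p.value, error = function(e) NA_real_)
        else NA_real_
        cd <- if (s != "human" && length(human_lfc) >= 2L && length(sl) >= 2L)
          cohens_d(sl, human_lfc) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, species = s, n = length(sl),
          median_log2fc = stats::median(sl),
          welch_p_vs_human = wp, cohens_d_vs_human = cd,
          stringsAsFactors = FALSE)
      }
    }
    out$fold_changes <- do.call(rbind, rows)
    rownames(out$fold_changes) <- NULL
  }
  out
}

#' Entrapment (wrong-organism) summary
#'
#' For each sample, counts proteins whose species is not in the sample's
#' allowed-species set yet which carry an observed quantity -- the
#' entrapment hits that co-searching organism-specific samples produces --
#' and summarizes their quantity distribution. Additionally reports, per
#' data-completeness threshold, how many wrong-organism proteins a
#' completeness filter would retain, quantifying how sparsity reduction
#' suppresses spurious transfers.
#'
#' @param m a raw-scale `QuantMatrix` with species labels.
#' @param allowed_species named list: sample id -> character vector of
#'   species genuinely present in that sample.
#' @param completeness_grid completeness thresholds for the retention curve.
#' @return list with `per_sample` (sample, entrapment count, median
#'   quantity) and `retention` (threshold, wrong-organism proteins kept).
#' @export
entrapment_summary <- function(m, allowed_species,
                               completeness_grid = c(0, 0.5, 0.66, 0.75, 0.9)) {
  v <- m$values
  sp <- qm_species(m)
  missing_ann <- setdiff(colnames(v), names(allowed_species))
  if (length(missing_ann))
    stop("samples without an allowed-species set: ", paste(missing_ann, collapse = ", "))
  per_sample <- do.call(rbind, lapply(colnames(v), function(s) {
    wrong <- !(sp %in% allowed_species[[s]])
    hit <- wrong & !is.na(v[, s])
    data.frame(sample_id = s, n_entrapment = sum(hit),
               median_quantity = if (any(hit)) stats::median(v[hit, s]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # a protein is "wrong-organism" if absent from any sample where it appears
  wrong_any <- vapply(rownames(v), function(pid) {
    present_in <- colnames(v)[!is.na(v[pid, ])]
    any(!sp[[pid]] %in% unlist(allowed_species[present_in])) &&
      any(vapply(present_in, function(s) !(sp[[pid]] %in% allowed_species[[s]]), logical(1)))
  }, logical(1))
  frac_obs <- rowMeans(!is.na(v))
  retention <- data.frame(
    min_fraction = completeness_grid,
    n_wrong_retained = vapply(completeness_grid, function(f)
      sum(wrong_any & frac_obs >= f - 1e-9), integer(1)))
  list(per_sample = per_sample, retention = retention)
}
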