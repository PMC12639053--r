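#' Read a DIA search-engine report into a canonical precursor table
#'
#' Supports the three tabular dialects produced by the mainstream DIA
#' software: DIA-NN long-format main reports, Spectronaut long-format
#' exports, and PEAKS wide protein/peptide area tables (one `Area <sample>`
#' column per run, melted into long rows). The result is a canonical
#' long-format table with one row per precursor (or protein-group entry) per
#' run; q-value columns absent from a dialect are filled with 0 so that
#' downstream q-value filtering is a no-op for them.
#'
#' @param path delimited text file (TSV or CSV, sniffed by `fread`).
#' @param dialect one of `"diann"`, `"spectronaut"`, `"peaks"`.
#' @return a `data.frame` with columns `run_id`, `protein_group`,
#'   `stripped_sequence`, `precursor_id`, `precursor_quantity`, `q_value`,
#'   `lib_q_value`, `pg_q_value`, `lib_pg_q_value`.
#' @export
read_precursor_report <- function(path, dialect = c("diann", "spectronaut", "peaks")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("report file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("empty report: ", path)
  cols <- names(dt)

  need_col <- function(nm) {
    if (!nm %in% cols) stop(sprintf("report is missing mandatory column '%s' for dialect '%s'", nm, dialect))
    dt[[nm]]
  }

  if (dialect == "diann") {
    out <- data.frame(
      run_id = as.character(need_col("Run")),
      protein_group = as.character(need_col("Protein.Group")),
      stripped_sequence = as.character(need_col("Stripped.Sequence")),
      precursor_id = if ("Precursor.Id" %in% cols) as.character(dt$Precursor.Id)
                     else paste0(dt$Stripped.Sequence, ".", seq_len(nrow(dt))),
      precursor_quantity = as.numeric(need_col("Precursor.Quantity")),
      q_value = as.numeric(need_col("Q.Value")),
      lib_q_value = as.numeric(need_col("Lib.Q.Value")),
      pg_q_value = as.numeric(need_col("PG.Q.Value")),
      lib_pg_q_value = as.numeric(need_col("Lib.PG.Q.Value")),
      stringsAsFactors = FALSE)
  } else if (dialect == "spectronaut") {
    out <- data.frame(
      run_id = as.character(if ("R.FileName" %in% cols) dt$R.FileName else need_col("Run")),
      protein_group = as.character(need_col("PG.ProteinAccessions")),
      stripped_sequence = as.character(need_col("PEP.StrippedSequence")),
      precursor_id = if ("EG.PrecursorId" %in% cols) as.character(dt$EG.PrecursorId)
                     else paste0(dt$PEP.StrippedSequence, ".", seq_len(nrow(dt))),
      precursor_quantity = as.numeric(if ("PEP.Quantity" %in% cols) dt$PEP.Quantity
                                      else need_col("PG.Quantity")),
      q_value = if ("EG.Qvalue" %in% cols) as.numeric(dt$EG.Qvalue) else 0,
      lib_q_value = 0,
      pg_q_value = if ("PG.Qvalue" %in% cols) as.numeric(dt$PG.Qvalue) else 0,
      lib_pg_q_value = 0,
      stringsAsFactors = FALSE)
  } else { # peaks: wide table, one "Area <sample>" column per run
    acc <- as.character(need_col("Accession"))
    area_cols <- grep("^Area ", cols, value = TRUE)
    if (!length(area_cols)) stop("report is missing mandatory column 'Area <SampleName>' for dialect 'peaks'")
    top <- if ("Top" %in% cols) dt$Top else rep(TRUE, nrow(dt))
    grp <- if ("Protein Group" %in% cols) as.character(dt[["Protein Group"]]) else acc
    pep <- if ("Peptide" %in% cols) as.character(dt$Peptide) else acc
    pieces <- lapply(area_cols, function(ac) {
      data.frame(run_id = sub("^Area ", "", ac),
                 protein_group = acc,
                 stripped_sequence = pep,
                 precursor_id = paste0(pep, ".1"),
                 precursor_quantity = as.numeric(dt[[ac]]),
                 q_value = 0, lib_q_value = 0, pg_q_value = 0, lib_pg_q_value = 0,
                 peaks_top = as.logical(top),
                 peaks_group = grp,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[!is.na(out$precursor_quantity), , drop = FALSE]
    rownames(out) <- NULL
  }
  qcols <- c("q_value", "lib_q_value", "pg_q_value", "lib_pg_q_value")
  for (qc in qcols) {
    bad <- !is.na(out[[qc]]) & (out[[qc]] < 0 | out[[qc]] > 1)
    if (any(bad)) stop("q-value column ", qc, " outside [0,1]")
  }
  if (any(!nzchar(out$run_id))) stop("empty run_id in report")
  attr(out, "dialect") <- dialect
  out
}

#' Filter a precursor report by run- and protein-level q-values
#'
#' Retains only rows passing all four q-value thresholds: precursor-level
#' run-specific and library q-values at 0.01, protein-group q-value at 0.05
#' and library protein-group q-value at 0.01 by default. Row order is
#' preserved and the operation is idempotent.
#'
#' @param r a precursor report from [read_precursor_report()].
#' @param thresholds named list/vector with elements `q`, `lib_q`, `pg_q`,
#'   `lib_pg_q`.
#' @return the filtered report.
#' @export
filter_report <- function(r, thresholds = list(q = 0.01, lib_q = 0.01, pg_q = 0.05, lib_pg_q = 0.01)) {
  th <- unlist(thresholds)
  if (any(th < 0 | th > 1)) stop("q-value thresholds must lie in [0,1]")
  keep <- r$q_value <= th[["q"]] &
    r$lib_q_value <= th[["lib_q"]] &
    r$pg_q_value <= th[["pg_q"]] &
    r$lib_pg_q_value <= th[["lib_pg_q"]]
  keep[is.na(keep)] <- FALSE
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dialect") <- attr(r, "dialect")
  out
}

#' Aggregate precursors to peptide-level quantities
#'
#' Per (stripped sequence, run), the peptide quantity is the sum of the
#' `top_n` largest precursor quantities (ties at the cutoff resolved by
#' stable descending sort, so the result is deterministic and equals the
#' maximal attainable sum of `top_n` values).
#'
#' @param r a (filtered) precursor report.
#' @param top_n number of top precursors summed per peptide (default 3).
#' @return a `QuantMatrix` of peptides x runs.
#' @export
aggregate_peptides <- function(r, top_n = 3L) {
  stopifnot(top_n >= 1L)
  dt <- data.table::as.data.table(r)
  # stable ordering: quantity descending, precursor_id ascending for ties
  data.table::setorder(dt, stripped_sequence, run_id, -precursor_quantity, precursor_id)
  agg <- dt[, list(quantity = sum(utils::head(precursor_quantity, top_n))),
            by = c("stripped_sequence", "run_id")]
  wide <- data.table::dcast(agg, stripped_sequence ~ run_id, value.var = "quantity")
  vals <- as.matrix(wide[, -1, with = FALSE])
  rownames(vals) <- wide$stripped_sequence
  vals <- vals[order(rownames(vals)), sort(colnames(vals)), drop = FALSE]
  QuantMatrix(vals)
}

#' Build a protein-level quantification matrix from a report
#'
#' Rolls a long report up to one row per protein-group representative and
#' one column per run, with `NA` where a protein was not observed in a run.
#' For the PEAKS dialect the representative is the accession flagged `Top`
#' within its protein group; for DIA-NN/Spectronaut groups the first
#' accession of the (sorted) group string is used. Multiple rows mapping to
#' the same representative in the same run are summed.
#'
#' @param r a (filtered) precursor report.
#' @param dedup protein-group deduplication rule; only `"top_of_group"` is
#'   defined.
#' @return a `QuantMatrix` of proteins x runs.
#' @export
to_protein_matrix <- function(r, dedup = "top_of_group") {
  dedup <- match.arg(dedup, "top_of_group")
  dt <- data.table::as.data.table(r)
  if (!is.null(dt$peaks_top)) {
    dt <- dt[dt$peaks_top %in% TRUE]
    dt[, "protein_id" := protein_group]
  } else {
    # normalize accession order within the group string, take the first
    dt[, "protein_id" := vapply(strsplit(protein_group, ";", fixed = TRUE),
                                function(a) sort(trimws(a))[1], character(1))]
  }
  agg <- dt[, list(quantity = sum(precursor_quantity)), by = c("protein_id", "run_id")]
  if (anyDuplicated(agg[, c("protein_id", "run_id")]))
    stop("duplicate protein id after deduplication")
  wide <- data.table::dcast(agg, protein_id ~ run_id, value.var = "quantity")
  vals <- as.matrix(wide[, -1, with = FALSE])
  rownames(vals) <- wide$protein_id
  vals <- vals[order(rownames(vals)), sort(colnames(vals)), drop = FALSE]
  QuantMatrix(vals)
}
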