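#' Protein x sample quantification matrix with species labels
#'
#' `QuantMatrix` is the canonical container passed between all pipeline
#' stages: a numeric proteins x samples matrix (raw, i.e. linear-scale,
#' non-negative abundances unless a stage documents otherwise) with `NA` as
#' the explicit missing-value marker, plus a species label per protein.
#' Zero is a legal measured value; missingness is always `NA`.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; must
#'   have unique, non-empty dimnames.
#' @param species character vector of species labels, one per protein, from
#'   `c("human", "yeast", "ecoli", "other")`; may be named by protein id.
#' @param log2_scale logical; `TRUE` marks a log2-transformed matrix, on
#'   which negative values are legal (e.g. after batch correction).
#' @return an object of class `QuantMatrix`.
#' @export
QuantMatrix <- function(values, species = NULL, log2_scale = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("QuantMatrix requires protein ids as rownames")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("QuantMatrix requires sample ids as colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids in QuantMatrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in QuantMatrix")
  if (!log2_scale && any(values[!is.na(values)] < 0))
    stop("QuantMatrix values must be non-negative (missing entries are NA)")
  if (is.null(species)) {
    species <- rep("other", nrow(values))
    names(species) <- rownames(values)
  } else {
    if (!is.null(names(species))) {
      if (!all(rownames(values) %in% names(species)))
        stop("species map does not cover all protein ids")
      species <- species[rownames(values)]
    } else {
      if (length(species) != nrow(values))
        stop("species vector length must match protein count")
      names(species) <- rownames(values)
    }
  }
  structure(list(values = values,
                 species = as.character(stats::setNames(species, names(species))),
                 log2_scale = isTRUE(log2_scale)),
            class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("QuantMatrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  tab <- table(x$species)
  cat("species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$values)

#' Extract the numeric matrix from a QuantMatrix
#' @param m a `QuantMatrix`.
#' @return numeric matrix with dimnames.
#' @export
qm_values <- function(m) m$values

#' Extract the named species vector from a QuantMatrix
#' @param m a `QuantMatrix`.
#' @return character vector named by protein id.
#' @export
qm_species <- function(m) stats::setNames(m$species, rownames(m$values))

#' Protein and sample identifiers
#' @param m a `QuantMatrix`.
#' @return character vector of ids.
#' @export
qm_proteins <- function(m) rownames(m$values)

#' @rdname qm_proteins
#' @export
qm_samples <- function(m) colnames(m$values)

#' Subset a QuantMatrix by proteins and/or samples
#'
#' @param x a `QuantMatrix`.
#' @param i,j protein / sample index (logical, integer, or character).
#' @param ... ignored.
#' @return a `QuantMatrix`.
#' @export
`[.QuantMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  QuantMatrix(x$values[i, j, drop = FALSE],
              qm_species(x)[rownames(x$values[i, , drop = FALSE])],
              log2_scale = x$log2_scale)
}

# replace the value slot, keeping species and scale; used by transforms
qm_update <- function(m, values, log2_scale = m$log2_scale) {
  QuantMatrix(values, qm_species(m)[rownames(values)], log2_scale = log2_scale)
}

#' Attach species labels to a QuantMatrix
#'
#' Species labels drive the ground-truth TP/FP labeling of differential
#' expression results. Labels come either from organism suffixes in the
#' protein identifiers (UniProt style, e.g. `ALBU_HUMAN`, `ADH1_YEAST`,
#' `LACY_ECOLI`) or from an explicit protein -> species map. Unmapped
#' proteins get `"other"`.
#'
#' @param m a `QuantMatrix`.
#' @param map_source `"suffix"` or `"explicit"`.
#' @param map named character vector (protein id -> species) for
#'   `map_source = "explicit"`.
#' @return the `QuantMatrix` with its species field populated.
#' @export
assign_species <- function(m, map_source = c("suffix", "explicit"), map = NULL) {
  map_source <- match.arg(map_source)
  ids <- qm_proteins(m)
  if (map_source == "suffix") {
    sp <- rep("other", length(ids))
    sp[grepl("_HUMAN$", ids)] <- "human"
    sp[grepl("_(YEAST|YEAS[0-9A-Z])$", ids)] <- "yeast"
    sp[grepl("_(ECOLI|ECOL[0-9A-Z])$", ids)] <- "ecoli"
  } else {
    if (is.null(map)) stop("explicit map_source requires a map")
    sp <- unname(map[ids])
    sp[is.na(sp)] <- "other"
  }
  QuantMatrix(m$values, stats::setNames(sp, ids), log2_scale = m$log2_scale)
}

#' Read / write the canonical matrix TSV
#'
#' The canonical on-disk form is a TSV whose first column (`protein_id`)
#' holds protein identifiers followed by one column per sample; empty cells
#' are missing values. An optional `species` column is restored into the
#' species field on read.
#'
#' @param path file path.
#' @param m a `QuantMatrix`.
#' @return `read_quant_tsv` returns a `QuantMatrix`; `write_quant_tsv`
#'   returns `path` invisibly.
#' @export
read_quant_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
  ids <- as.character(dt[[1]])
  species <- NULL
  if ("species" %in% names(dt)) {
    species <- stats::setNames(as.character(dt$species), ids)
    dt[, "species" := NULL]
  }
  vals <- as.matrix(dt[, -1, with = FALSE])
  rownames(vals) <- ids
  QuantMatrix(vals, species)
}

#' @rdname read_quant_tsv
#' @export
write_quant_tsv <- function(m, path) {
  dt <- data.table::data.table(protein_id = qm_proteins(m),
                               species = unname(qm_species(m)))
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Per-sample annotation table
#'
#' Validates and normalizes a sample annotation `data.frame` with columns
#' `sample_id`, `group`, `batch` and optionally `replicate`.
#'
#' @param df data.frame of per-sample metadata.
#' @param m optional `QuantMatrix`; when given, every sample of `m` must be
#'   annotated and rows are reordered to match.
#' @return a `data.frame` with class `SampleAnnotation` prepended.
#' @export
sample_annotation <- function(df, m = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotation")
  if (!"replicate" %in% names(df)) df$replicate <- seq_len(nrow(df))
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$batch <- as.character(df$batch)
  if (!is.null(m)) {
    missing_samples <- setdiff(qm_samples(m), df$sample_id)
    if (length(missing_samples))
      stop("samples without annotation: ", paste(missing_samples, collapse = ", "))
    df <- df[match(qm_samples(m), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("SampleAnnotation", "data.frame")
  df
}
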