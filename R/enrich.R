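#' Over-representation analysis of differential proteins
#'
#' One-sided Fisher's exact test per annotation term on the 2x2 table of
#' (differential vs background) x (in-term vs not), BH-adjusted across
#' terms; terms with adjusted p < `alpha` are kept. Each kept term carries
#' its up/down-regulated differential protein counts and the regulation
#' Z-score of [regulation_z()] (proteins in `diff_up` count up; those in
#' the differential set but not in `diff_up` count down).
#'
#' @param diff_proteins character vector of differential protein ids
#'   (subset of `background`).
#' @param background character vector of all tested protein ids.
#' @param annotation named list: term id -> character vector of protein ids
#'   (or a two-column data.frame `protein_id`, `term_id`).
#' @param diff_up subset of `diff_proteins` that is up-regulated.
#' @param alpha adjusted-p cutoff for keeping terms (default 0.05).
#' @return an `EnrichmentProfile` data.frame: `term_id`, `n_diff`,
#'   `n_term`, `p`, `p_adj`, `count_up`, `count_down`, `z`.
#' @export
ora_test <- function(diff_proteins, background, annotation,
                     diff_up = character(0), alpha = 0.05) {
  if (is.data.frame(annotation))
    annotation <- split(annotation$protein_id, annotation$term_id)
  if (!length(annotation)) stop("empty annotation map")
  extra <- setdiff(diff_proteins, background)
  if (length(extra)) stop("differential proteins outside the background: ",
                          paste(utils::head(extra, 3), collapse = ", "))
  n_bg <- length(background); n_diff <- length(diff_proteins)
  if (n_diff == 0L) return(empty_profile())
  rows <- lapply(names(annotation), function(term) {
    in_term <- intersect(annotation[[term]], background)
    k <- length(intersect(in_term, diff_proteins))
    tab <- matrix(c(k, length(in_term) - k,
                    n_diff - k, n_bg - length(in_term) - (n_diff - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    up <- length(intersect(in_term, diff_up))
    down <- k - up
    data.frame(term_id = term, n_diff = k, n_term = length(in_term), p = p,
               count_up = up, count_down = down, stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  prof$p_adj <- bh_adjust(prof$p)
  prof <- prof[prof$p_adj < alpha & prof$n_diff > 0L, , drop = FALSE]
  prof$z <- mapply(regulation_z, prof$count_up, prof$count_down)
  rownames(prof) <- NULL
  class(prof) <- c("EnrichmentProfile", "data.frame")
  prof
}

empty_profile <- function() {
  prof <- data.frame(term_id = character(0), n_diff = integer(0),
                     n_term = integer(0), p = numeric(0), count_up = integer(0),
                     count_down = integer(0), p_adj = numeric(0), z = numeric(0),
                     stringsAsFactors = FALSE)
  class(prof) <- c("EnrichmentProfile", "data.frame")
  prof
}

#' Regulation Z-score of an enriched term
#'
#' `Z = (count_up - count_down) / sqrt(count_up + count_down)`; positive
#' values indicate up-regulation, negative down-regulation.
#'
#' @param count_up,count_down non-negative counts of up-/down-regulated
#'   differential proteins annotated to the term (not both 0).
#' @return scalar Z-score.
#' @export
regulation_z <- function(count_up, count_down) {
  stopifnot(count_up >= 0, count_down >= 0)
  total <- count_up + count_down
  if (total == 0) stop("undefined Z-score: no differential proteins in term")
  (count_up - count_down) / sqrt(total)
}

#' Signed Jaccard similarity between two enrichment profiles
#'
#' `J = |agreeing shared terms| / (|A| + |B| - |agreeing shared terms|)`,
#' where a shared term agrees when its Z-score signs coincide (a Z of 0
#' agrees with either sign). The corresponding distance is `1 - J`. Two
#' empty profiles get distance 0 with a warning.
#'
#' @param a,b `EnrichmentProfile` data.frames over the same annotation
#'   universe.
#' @return list with `jaccard` and `distance`.
#' @export
signed_jaccard <- function(a, b) {
  if (!nrow(a) && !nrow(b)) {
    warning("both profiles empty; distance defined as 0")
    return(list(jaccard = 1, distance = 0))
  }
  shared <- intersect(a$term_id, b$term_id)
  za <- stats::setNames(a$z, a$term_id)[shared]
  zb <- stats::setNames(b$z, b$term_id)[shared]
  agree <- sum(za * zb >= 0)
  j <- agree / (nrow(a) + nrow(b) - agree)
  list(jaccard = j, distance = 1 - j)
}

#' Hierarchical clustering of workflows by signed-Jaccard distance
#'
#' Average-linkage agglomerative clustering on the pairwise signed-Jaccard
#' distance matrix of the profiles. Leaf order is made deterministic by
#' ordering tied merges by label.
#'
#' @param profiles named list of `EnrichmentProfile`s (names = workflow ids).
#' @return list with `dist` (matrix), `hclust`, and `leaf_order`.
#' @export
cluster_workflows <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("wf", seq_along(profiles))
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- suppressWarnings(signed_jaccard(profiles[[i]], profiles[[j]])$distance)
    d[i, j] <- d[j, i] <- dij
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(dist = d, hclust = hc, leaf_order = ids[hc$order])
}

#' Write a dendrogram as Newick text
#'
#' @param hc an `hclust` object.
#' @return single Newick string (branch lengths = merge heights).
#' @export
hclust_to_newick <- function(hc) {
  lab <- hc$labels
  build <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_h))
    h <- hc$height[i]
    sprintf("(%s,%s):%g", build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
            parent_h - h)
  }
  n <- length(hc$height)
  paste0("(", build(hc$merge[n, 1], hc$height[n]), ",",
         build(hc$merge[n, 2], hc$height[n]), ");")
}
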