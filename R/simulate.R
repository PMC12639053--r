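#' Default benchmark designs for ground-truth mixed-proteome simulations
#'
#' Two designs mirror the benchmark layouts this framework targets:
#'
#' * `mixed_s1s5`: five mixed-proteome groups S1-S5 with human held constant
#'   and yeast / E. coli abundance ratios spanning 0.4-1.6 in reciprocal
#'   pairs (yeast 1.6, 1.3, 1.0, 0.7, 0.4; E. coli 0.4, 0.7, 1.0, 1.3, 1.6
#'   relative to the S3 reference, which is 50% human / 25% yeast /
#'   25% E. coli), three batches, six replicates per group.
#' * `spikein_1y2e_2y1e`: two single-cell spike-in groups, C1Y2E (20 pg
#'   yeast + 40 pg E. coli) vs C2Y1E (40 pg yeast + 20 pg E. coli), so the
#'   expected log2 fold change C2Y1E/C1Y2E is +1 for yeast and -1 for
#'   E. coli, with a per-sample human cell-size factor.
#'
#' @param kind `"mixed_s1s5"` or `"spikein_1y2e_2y1e"`.
#' @param seed integer seed stored in the design.
#' @return a `DesignSpec` list understood by [simulate_matrix()].
#' @export
default_design <- function(kind = c("mixed_s1s5", "spikein_1y2e_2y1e"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "mixed_s1s5") {
    groups <- data.frame(
      name = c("S1", "S2", "S3", "S4", "S5"),
      human = 1,
      yeast = c(1.6, 1.3, 1.0, 0.7, 0.4),
      ecoli = c(0.4, 0.7, 1.0, 1.3, 1.6),
      stringsAsFactors = FALSE)
    spec <- list(
      kind = kind,
      groups = groups,
      samples_per_group_per_batch = 2L,
      batches = data.frame(name = c("B1", "B2", "B3"),
                           location_sd = 0.5, scale_shape = 30,
                           stringsAsFactors = FALSE),
      n_proteins = c(human = 1000L, yeast = 1000L, ecoli = 1000L),
      base_mean_log2 = 12, base_sd_log2 = 2,
      noise_sd_log2 = 0.25, depth_sd_log2 = 0.15,
      cell_size_sd = 0,
      mnar = list(threshold_log2 = 10.0, slope = 0.8),
      mcar_rate = 0.02,
      seed = as.integer(seed))
  } else {
    groups <- data.frame(
      name = c("C1Y2E", "C2Y1E"),
      human = 1,
      yeast = c(1, 2),
      ecoli = c(2, 1),
      stringsAsFactors = FALSE)
    spec <- list(
      kind = kind,
      groups = groups,
      samples_per_group_per_batch = 10L,
      batches = data.frame(name = c("B1", "B2", "B3"),
                           location_sd = 0.5, scale_shape = 30,
                           stringsAsFactors = FALSE),
      n_proteins = c(human = 600L, yeast = 300L, ecoli = 300L),
      base_mean_log2 = 12, base_sd_log2 = 2,
      noise_sd_log2 = 0.3, depth_sd_log2 = 0.15,
      cell_size_sd = 0.3,
      mnar = list(threshold_log2 = 10.0, slope = 0.8),
      mcar_rate = 0.02,
      seed = as.integer(seed))
  }
  class(spec) <- c("DesignSpec", "list")
  spec
}

validate_design <- function(d) {
  stopifnot(is.data.frame(d$groups), nrow(d$groups) >= 1)
  species <- setdiff(names(d$groups), "name")
  if (any(as.matrix(d$groups[species]) <= 0)) stop("ratios must be positive")
  if (any(d$n_proteins < 1)) stop("degenerate design: no proteins")
  if (d$samples_per_group_per_batch < 1) stop("degenerate design: no samples")
  if (d$mcar_rate < 0 || d$mcar_rate >= 1) stop("mcar_rate must lie in [0,1)")
  if (any(d$batches$location_sd < 0)) stop("location_sd must be >= 0")
  invisible(TRUE)
}

# independent seed substream per simulation stage, so e.g. adding proteins
# does not perturb the sample-level draws
substream <- function(seed, stage) {
  offsets <- c(proteins = 101L, samples = 211L, batch = 307L,
               noise = 401L, missing = 503L)
  (abs(as.integer(seed)) %% 1000000L) * 1009L + offsets[[stage]]
}

#' Simulate a ground-truth mixed-proteome quantification matrix
#'
#' Generates, on the log2 scale, `x_ij = mu_i + log2(ratio[s, g(j)]) +
#' depth_j + gamma_ib + delta_ib * eps_ij` where `mu_i` is the protein base
#' abundance, `gamma_ib ~ N(0, location_sd^2)` and `delta_ib` (a positive
#' inverse-gamma multiplier with mean 1, shape `scale_shape`) are per
#' protein x batch location/scale batch effects of the kind ComBat models,
#' `depth_j` is a per-sample loading factor, and `eps` is technical noise.
#' Human proteins additionally receive a per-sample cell-size shift with SD
#' `cell_size_sd`. An entry is observed with probability
#' `plogis(slope * (x_ij - threshold))` (intensity-dependent MNAR dropout;
#' `slope = 0` or `threshold = -Inf` disables this channel) and then kept
#' with probability `1 - mcar_rate` (random MCAR dropout). Emitted values
#' are `2^x` with `NA` for missing entries.
#'
#' @param d a `DesignSpec`, e.g. from [default_design()].
#' @return list with elements `matrix` (`QuantMatrix`), `annotation`
#'   (`SampleAnnotation`) and `truth` (`GroundTruth`).
#' @export
simulate_matrix <- function(d) {
  validate_design(d)
  species_names <- setdiff(names(d$groups), "name")
  n_prot <- d$n_proteins[species_names]
  species <- rep(species_names, times = n_prot)
  prot_ids <- unlist(lapply(species_names, function(s)
    sprintf("%s%04d_%s", toupper(substr(s, 1, 2)), seq_len(n_prot[[s]]), toupper(s))))
  names(species) <- prot_ids
  G <- nrow(d$groups); B <- nrow(d$batches); R <- d$samples_per_group_per_batch

  ann <- expand.grid(replicate = seq_len(R), batch = d$batches$name,
                     group = d$groups$name, stringsAsFactors = FALSE)
  ann$replicate <- as.integer(ann$replicate +
    R * (match(ann$batch, d$batches$name) - 1L))
  ann$sample_id <- sprintf("%s_%s_r%02d", ann$group, ann$batch, ann$replicate)
  ann <- ann[, c("sample_id", "group", "batch", "replicate")]
  n_s <- nrow(ann); n_p <- length(prot_ids)

  set.seed(substream(d$seed, "proteins"))
  mu <- stats::rnorm(n_p, d$base_mean_log2, d$base_sd_log2)

  set.seed(substream(d$seed, "samples"))
  depth <- stats::rnorm(n_s, 0, d$depth_sd_log2)
  cell_size <- if (d$cell_size_sd > 0) stats::rnorm(n_s, 0, d$cell_size_sd) else numeric(n_s)

  set.seed(substream(d$seed, "batch"))
  gamma <- matrix(0, n_p, B); delta <- matrix(1, n_p, B)
  for (b in seq_len(B)) {
    lsd <- d$batches$location_sd[b]; shp <- d$batches$scale_shape[b]
    if (lsd > 0) gamma[, b] <- stats::rnorm(n_p, 0, lsd)
    if (is.finite(shp)) {
      if (shp <= 1) stop("scale_shape must exceed 1 (or be Inf to disable)")
      delta[, b] <- (shp - 1) / stats::rgamma(n_p, shape = shp, rate = 1)
    }
  }

  set.seed(substream(d$seed, "noise"))
  eps <- matrix(stats::rnorm(n_p * n_s, 0, d$noise_sd_log2), n_p, n_s)

  ratio_mat <- as.matrix(d$groups[species_names])       # group x species
  rownames(ratio_mat) <- d$groups$name
  g_idx <- match(ann$group, d$groups$name)
  b_idx <- match(ann$batch, d$batches$name)
  log2ratio <- t(log2(ratio_mat[g_idx, species, drop = FALSE]))  # protein x sample
  is_human <- species == "human"

  x <- mu + log2ratio +
    matrix(depth, n_p, n_s, byrow = TRUE) +
    gamma[, b_idx, drop = FALSE] +
    delta[, b_idx, drop = FALSE] * eps
  if (any(cell_size != 0))
    x[is_human, ] <- x[is_human, , drop = FALSE] +
      matrix(cell_size, sum(is_human), n_s, byrow = TRUE)

  set.seed(substream(d$seed, "missing"))
  slope <- d$mnar$slope; thr <- d$mnar$threshold_log2
  p_obs <- if (is.null(slope) || slope == 0 || thr == -Inf) matrix(1, n_p, n_s)
           else stats::plogis(slope * (x - thr))
  obs <- matrix(stats::runif(n_p * n_s) < p_obs, n_p, n_s)
  if (d$mcar_rate > 0)
    obs <- obs & (matrix(stats::runif(n_p * n_s), n_p, n_s) >= d$mcar_rate)

  vals <- 2^x
  vals[!obs] <- NA_real_
  dimnames(vals) <- list(prot_ids, ann$sample_id)

  truth <- structure(list(species = species, ratios = ratio_mat), class = "GroundTruth")
  list(matrix = QuantMatrix(vals, species),
       annotation = sample_annotation(ann),
       truth = truth)
}

#' Expected log2 fold change between two groups for each species
#'
#' @param gt a `GroundTruth`.
#' @param group_a,group_b group names; the fold change is `a` over `b`.
#' @return named numeric vector over species.
#' @export
expected_log2fc <- function(gt, group_a, group_b) {
  if (!all(c(group_a, group_b) %in% rownames(gt$ratios)))
    stop("unknown group in comparison")
  log2(gt$ratios[group_a, ] / gt$ratios[group_b, ])
}

#' Ground-truth differential labels for a two-group comparison
#'
#' Maps every protein to `expected_positive_up`, `expected_positive_down`
#' (its species has a nonzero expected log2 fold change between the two
#' groups, with the sign giving the direction) or `expected_negative`
#' (constant species, e.g. human in the constant-human designs).
#'
#' @param gt a `GroundTruth`.
#' @param comparison character vector `c(group_a, group_b)`.
#' @param fc_threshold minimum `|expected log2 FC|` for a species to count
#'   as positive (default 0, i.e. any nonzero design ratio).
#' @return named character vector, one label per protein.
#' @export
truth_labels <- function(gt, comparison, fc_threshold = 0) {
  efc <- expected_log2fc(gt, comparison[1], comparison[2])
  lab_by_species <- ifelse(abs(efc) > fc_threshold,
                           ifelse(efc > 0, "expected_positive_up", "expected_positive_down"),
                           "expected_negative")
  stats::setNames(unname(lab_by_species[gt$species]), names(gt$species))
}

#' Write / read a DesignSpec as JSON
#'
#' @param d a `DesignSpec`.
#' @param path file path.
#' @return `read_design` returns a `DesignSpec`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(d, path) {
  d <- unclass(d)
  d$n_proteins <- as.list(d$n_proteins)  # keep species names in JSON
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$groups <- as.data.frame(d$groups, stringsAsFactors = FALSE)
  d$batches <- as.data.frame(d$batches, stringsAsFactors = FALSE)
  d$n_proteins <- unlist(d$n_proteins)
  d$samples_per_group_per_batch <- as.integer(d$samples_per_group_per_batch)
  d$seed <- as.integer(d$seed)
  class(d) <- c("DesignSpec", "list")
  d
}
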