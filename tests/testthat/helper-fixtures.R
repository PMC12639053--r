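# shared fixtures and independent oracles; simulations are memoized so the
# suite builds each one once per session

fixture_path <- function(name) {
  system.file("extdata", name, package = "scpbench", mustWork = TRUE)
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small mixed-design simulation used across modules
sim_small <- function(seed = 11L, n = c(human = 120L, yeast = 60L, ecoli = 60L)) {
  memo(paste0("sim_small_", seed, "_", paste(n, collapse = "_")), {
    d <- default_design("mixed_s1s5", seed = seed)
    d$n_proteins <- n
    simulate_matrix(d)
  })
}

# complete (no missing), batch-free simulation for deterministic stages
sim_clean <- function(seed = 5L) {
  memo(paste0("sim_clean_", seed), {
    d <- default_design("mixed_s1s5", seed = seed)
    d$n_proteins <- c(human = 80L, yeast = 40L, ecoli = 40L)
    d$batches$location_sd <- 0
    d$batches$scale_shape <- Inf
    d$mnar$slope <- 0
    d$mcar_rate <- 0
    simulate_matrix(d)
  })
}

# fully deterministic simulation: no noise, no depth, no batch, no dropout
sim_noisefree <- function(seed = 5L) {
  memo(paste0("sim_noisefree_", seed), {
    d <- default_design("mixed_s1s5", seed = seed)
    d$n_proteins <- c(human = 40L, yeast = 20L, ecoli = 20L)
    d$noise_sd_log2 <- 0
    d$depth_sd_log2 <- 0
    d$batches$location_sd <- 0
    d$batches$scale_shape <- Inf
    d$mnar$slope <- 0
    d$mcar_rate <- 0
    simulate_matrix(d)
  })
}

# hand-built log2 QuantMatrix
toy_qm <- function(values, species = NULL, log2_scale = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  QuantMatrix(values, species, log2_scale = log2_scale)
}

# independent pair-counting ARI oracle: loop over all item pairs
ari_oracle <- function(la, lb) {
  n <- length(la)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- la[i] == la[j]; sc <- lb[i] == lb[j]
    if (st && sc) a <- a + 1
    else if (st && !sc) b <- b + 1
    else if (!st && sc) c_ <- c_ + 1
    else d <- d + 1
  }
  den <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (den == 0) return(1)
  2 * (a * d - b * c_) / den
}

# synthetic metrics table where the winning methods are planted; used by
# the recommender tests
planted_records <- function(seed = 1L) {
  memo(paste0("planted_records_", seed), {
    set.seed(seed)
    reg <- method_registries()
    rec <- expand.grid(test = reg$test, batch_correction = reg$batch_correction,
                       normalization = reg$normalization, imputation = reg$imputation,
                       sparsity = "SR75", stringsAsFactors = FALSE)
    score <- 2 * (rec$test == "NB_Wald_Shrink") +
      1 * (rec$normalization == "Sum") +
      0.5 * (rec$batch_correction %in% c("ComBatP", "ComBatNP")) +
      0.5 * (rec$test == "NB_Wald_Shrink" & rec$normalization == "Sum") +
      stats::rnorm(nrow(rec), 0, 0.05)
    rec$ari <- rec$pauc <- rec$f1 <- score
    rec$status <- "ok"
    rec$total_rank <- rank(-score, ties.method = "first")
    rec
  })
}
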