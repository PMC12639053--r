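fake_de <- function(protein_id, log2fc, p) {
  data.frame(protein_id = protein_id, log2fc = log2fc, model_log2fc = log2fc,
             statistic = 0, p = p, p_adj = p, method = "Welch",
             stringsAsFactors = FALSE)
}

test_that("confusion labeling is direction-aware and conserves totals", {
  truth <- c(H1 = "expected_negative", Y1 = "expected_positive_down",
             Y2 = "expected_positive_down", E1 = "expected_positive_up")
  de <- fake_de(names(truth), log2fc = c(0.1, -1, 1, 1),
                p = c(0.5, 0.001, 0.001, 0.001))
  cc <- confusion_counts(de, truth, p0 = 0.05, t0 = log2(1.2))
  expect_equal(cc$tn, 1)   # human p=0.5
  expect_equal(cc$tp, 2)   # Y1 down-called, E1 up-called
  expect_equal(cc$fn, 1)   # Y2 significant but wrong direction
  expect_equal(cc$fp, 0)
  expect_equal(cc$tp + cc$fn, sum(truth != "expected_negative"))
  expect_equal(cc$fp + cc$tn, sum(truth == "expected_negative"))
})

test_that("perfect separation yields the maximum pAUC of 0.1", {
  n <- 50
  truth <- setNames(rep(c("expected_positive_up", "expected_negative"), each = n),
                    paste0("P", seq_len(2 * n)))
  de <- fake_de(names(truth), log2fc = rep(c(2, 0.01), each = n),
                p = c(runif(n, 1e-10, 1e-6), runif(n, 0.2, 1)))
  expect_equal(roc_pauc(de, truth)$pauc, 0.1)
})

test_that("random scores approach the chance pAUC of 0.005", {
  set.seed(10)
  n <- 5000
  truth <- setNames(sample(c("expected_positive_up", "expected_negative"), 2 * n, TRUE),
                    paste0("P", seq_len(2 * n)))
  de <- fake_de(names(truth),
                log2fc = ifelse(truth == "expected_positive_up", 1, 0),
                p = runif(2 * n))
  expect_lt(abs(roc_pauc(de, truth)$pauc - 0.005), 0.001)
})

test_that("the 4-point toy ROC matches the hand trapezoid", {
  truth <- c(A = "expected_positive_up", B = "expected_negative",
             C = "expected_positive_up", D = "expected_negative")
  de <- fake_de(names(truth), log2fc = c(1, 1, 1, 1),
                p = 10^(-c(4, 3, 2, 1)))
  # thresholds sweep: (0,0) (0,.5) (.5,.5) (.5,1) (1,1); clipped at fpr 0.1
  # the only area is the rectangle 0..0.1 at tpr 0.5
  expect_equal(roc_pauc(de, truth)$pauc, 0.05)
  expect_error(roc_pauc(de, truth[0]), "label")
  truth_all_pos <- setNames(rep("expected_positive_up", 4), names(truth))
  expect_error(roc_pauc(fake_de(names(truth), rep(1, 4), rep(0.01, 4)),
                        truth_all_pos), "undefined")
})

test_that("threshold optimization maximizes recall at the precision floor", {
  # perfectly separated toy
  truth <- c(Y1 = "expected_positive_down", Y2 = "expected_positive_down",
             H1 = "expected_negative", H2 = "expected_negative")
  de <- fake_de(names(truth), log2fc = c(-1, -1.2, 0.05, -0.02),
                p = c(0.001, 0.002, 0.9, 0.8))
  opt <- optimize_thresholds(de, truth)
  expect_true(opt$floor_met)
  expect_equal(opt$recall, 1)
  expect_equal(opt$precision, 1)
  expect_equal(opt$f1, 1)
})

test_that("optimization agrees with an exhaustive grid-search oracle", {
  set.seed(12)
  n <- 60
  truth <- setNames(sample(c("expected_positive_up", "expected_negative"), n, TRUE),
                    paste0("P", seq_len(n)))
  de <- fake_de(names(truth),
                log2fc = rnorm(n, ifelse(truth == "expected_positive_up", 0.8, 0), 0.5),
                p = ifelse(truth == "expected_positive_up",
                           10^-runif(n, 0.5, 4), runif(n)))
  opt <- optimize_thresholds(de, truth, precision_floor = 0.95)
  # independent oracle: exhaustive loop, same tie rules
  best <- NULL
  for (p0 in c(0.1, 0.05, 0.01, 0.001)) for (t0 in sort(unique(c(0, abs(de$log2fc))))) {
    sig <- de$p_adj < p0
    tp <- sum(truth == "expected_positive_up" & sig & de$log2fc > t0)
    fp <- sum(truth == "expected_negative" & sig & abs(de$log2fc) > t0)
    fn <- sum(truth == "expected_positive_up") - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec >= 0.95 &&
        (is.null(best) || rec > best$rec ||
         (rec == best$rec && t0 < best$t0) ||
         (rec == best$rec && t0 == best$t0 && p0 > best$p0)))
      best <- list(p0 = p0, t0 = t0, rec = rec)
  }
  expect_equal(opt$p0_opt, best$p0)
  expect_equal(opt$t0_opt, best$t0)
  expect_equal(opt$recall, best$rec)
})

test_that("F1 follows its closed form from the confusion counts", {
  met <- scpbench:::derive_metrics(list(tp = 9, fp = 1, tn = 0, fn = 1))
  expect_equal(met$precision, 0.9)
  expect_equal(met$recall, 0.9)
  expect_equal(met$f1, 0.9)
})

test_that("pair-count ARI matches the brute-force oracle on random partitions", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)  # relabeling
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 2, 2)),
               ari_oracle(c(1, 1, 2, 2), c(1, 2, 2, 2)))
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    la <- sample(1:3, n, TRUE); lb <- sample(1:4, n, TRUE)
    expect_equal(adjusted_rand(la, lb), ari_oracle(la, lb), tolerance = 1e-12)
  }
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    la <- sample(1:4, n, TRUE); lb <- sample(1:4, n, TRUE)
    expect_equal(adjusted_rand(la, lb), mclust::adjustedRandIndex(la, lb),
                 tolerance = 1e-12)
  }
})

test_that("SNN-Louvain separates well-separated blobs and is deterministic", {
  set.seed(20)
  v <- cbind(matrix(rnorm(50 * 15, 0, 0.1), 50, 15),
             matrix(rnorm(50 * 15, 10, 0.1), 50, 15))
  dimnames(v) <- list(paste0("P", 1:50), paste0("S", 1:30))
  m <- QuantMatrix(v, log2_scale = TRUE)
  cl <- cluster_samples(m, seed = 0)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(adjusted_rand(rep(1:2, each = 15), cl), 1)
  expect_identical(cl, cluster_samples(m, seed = 0))
  # identical samples collapse to one community
  same <- QuantMatrix(matrix(5, 20, 6, dimnames = list(paste0("P", 1:20), paste0("S", 1:6))),
                      log2_scale = TRUE)
  expect_equal(length(unique(suppressWarnings(cluster_samples(same, seed = 0)))), 1L)
})

test_that("rank aggregation follows the nested-rank formula and its invariances", {
  rec <- data.frame(ari = c(0.9, 0.5, 0.7), pauc = c(0.09, 0.01, 0.05),
                    f1 = c(0.95, 0.60, 0.80))
  out <- aggregate_rank(rec)
  # hand computation: combo 1 ranks (1,1,1)=3 -> 1; combo 3 (2,2,2)=6 -> 2; combo 2 -> 3
  expect_equal(out$total_rank, c(1, 3, 2))
  single <- aggregate_rank(data.frame(ari = 0.2, pauc = 0.01, f1 = 0.3))
  expect_equal(single$total_rank, 1)
  # invariant to record order and monotone metric transforms
  perm <- c(3, 1, 2)
  out_perm <- aggregate_rank(rec[perm, ])
  expect_equal(out_perm$total_rank, out$total_rank[perm])
  rec2 <- rec; rec2$pauc <- rec2$pauc^3  # strictly monotone
  expect_equal(aggregate_rank(rec2)$total_rank, out$total_rank)
  # NaN metric gets the worst rank
  rec3 <- rec; rec3$ari[1] <- NaN
  expect_equal(aggregate_rank(rec3)$rank_ari[1], 3)
})

test_that("QC metrics report CV, completeness and fold-change accuracy", {
  sim <- sim_noisefree()
  qc <- qc_metrics(sim$matrix, sim$annotation, reference_group = "S3")
  # noise-free: CV within replicate groups is 0 up to depth=0 -> exactly 0
  expect_lt(max(qc$cv$cv), 1e-12)
  # completeness at 100% equals the shared-in-all-runs count
  expect_equal(qc$completeness$n_proteins[qc$completeness$min_fraction == 1],
               sum(rowSums(!is.na(qm_values(sim$matrix))) == 30))
  fc <- qc$fold_changes
  for (i in seq_len(nrow(fc))) {
    expect_equal(fc$median_log2fc[i],
                 unname(expected_log2fc(sim$truth, fc$group[i], "S3")[fc$species[i]]),
                 tolerance = 1e-9)
  }
})

test_that("entrapment counts wrong-organism hits and their completeness response", {
  v <- matrix(1, 5, 4, dimnames = list(
    c("H1_HUMAN", "H2_HUMAN", "E1_ECOLI", "E2_ECOLI", "E3_ECOLI"),
    paste0("S", 1:4)))
  # E2/E3 sporadic: observed in one run only
  v["E2_ECOLI", 2:4] <- NA
  v["E3_ECOLI", c(1, 3, 4)] <- NA
  m <- assign_species(QuantMatrix(v), "suffix")
  allowed <- setNames(rep(list("human"), 4), paste0("S", 1:4))
  es <- entrapment_summary(m, allowed)
  expect_equal(es$per_sample$n_entrapment, c(2, 2, 1, 1))  # ecoli hits per sample
  # all 3 ecoli proteins are wrong-organism; only E1 survives 75% completeness
  expect_equal(es$retention$n_wrong_retained[es$retention$min_fraction == 0], 3L)
  expect_equal(es$retention$n_wrong_retained[es$retention$min_fraction == 0.75], 1L)
  clean <- assign_species(QuantMatrix(v[1:2, ]), "suffix")
  expect_equal(sum(entrapment_summary(clean, allowed)$per_sample$n_entrapment), 0L)
})
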