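test_that("the ranker needs enough records and is reproducible", {
  rec <- planted_records()
  expect_error(fit_ranker(rec[1:10, ]), ">= 20")
  m1 <- fit_ranker(rec, seed = 4L)
  m2 <- fit_ranker(rec, seed = 4L)
  expect_equal(predict(m1), predict(m2), tolerance = 1e-12)
  tied <- rec; tied$total_rank <- 1
  expect_error(fit_ranker(tied), "tied")
})

test_that("a planted dominant step surfaces as the top feature importance", {
  model <- fit_ranker(planted_records(), seed = 1L)
  imp <- ranker_importance(model)
  expect_equal(imp$Feature[which.max(imp$Gain)], "test")
  # predictions track the planted ordering: best combos score highest
  rec <- model$records
  expect_gt(cor(predict(model), -rec$total_rank, method = "spearman"), 0.8)
})

test_that("SHAP attributions satisfy local accuracy and interaction symmetry", {
  model <- fit_ranker(planted_records(), seed = 1L)
  s <- shap_explain(model, top_fraction = 0.25)
  expect_equal(s$n_top, floor(0.25 * nrow(model$records)))
  pred_top <- predict(model, s$top_records)
  expect_equal(unname(rowSums(s$contrib)), unname(pred_top), tolerance = 1e-5)
  for (r in c(1L, 5L)) {  # xgboost computes in single precision
    expect_lt(max(abs(s$interaction[r, , ] - t(s$interaction[r, , ]))), 1e-5)
  }
  # planted signal: the test step carries the largest mean |SHAP|
  expect_equal(s$step_importance$step[which.max(s$step_importance$mean_abs_shap)],
               "test")
  ms <- s$method_shap
  expect_gt(ms$mean_shap[ms$step == "test" & ms$method == "NB_Wald_Shrink"],
            max(ms$mean_shap[ms$step == "test" & ms$method != "NB_Wald_Shrink"], na.rm = TRUE))
})

test_that("beam search returns W combinations and matches exhaustive argmax", {
  model <- fit_ranker(planted_records(), seed = 1L)
  s <- shap_explain(model, top_fraction = 0.25)
  b <- beam_select(s, W = 12L)
  expect_equal(nrow(b$selection), 12L)
  expect_true(all(diff(b$selection$score) <= 1e-12))
  # recommended combos carry the planted winners up front
  expect_equal(b$selection$test[1], "NB_Wald_Shrink")

  # exhaustive oracle on the candidate space (W >= all combinations)
  ms <- s$method_shap; mp <- s$method_pair_interaction
  cand <- lapply(b$step_order, function(st)
    sort(ms$method[ms$step == st & ms$n >= 3]))
  names(cand) <- b$step_order
  combos <- expand.grid(cand, stringsAsFactors = FALSE)
  score_one <- function(methods) {
    tot <- 0
    for (k in seq_along(b$step_order)) {
      row <- ms[ms$step == b$step_order[k] & ms$method == methods[[k]], ]
      tot <- tot + row$p5
      if (k > 1) for (l in seq_len(k - 1)) {
        pr <- mp[(mp$step_a == b$step_order[l] & mp$method_a == methods[[l]] &
                    mp$step_b == b$step_order[k] & mp$method_b == methods[[k]]) |
                 (mp$step_a == b$step_order[k] & mp$method_a == methods[[k]] &
                    mp$step_b == b$step_order[l] & mp$method_b == methods[[l]]), ]
        if (nrow(pr)) tot <- tot + sum(pr$p5)
      }
    }
    tot
  }
  oracle_scores <- apply(combos, 1L, function(row) score_one(as.list(row)))
  keys <- apply(combos, 1L, paste, collapse = "|")
  oracle_order <- order(-oracle_scores, keys)
  b_full <- beam_select(s, W = nrow(combos) + 10L)
  got_keys <- apply(b_full$selection[, b$step_order], 1L, paste, collapse = "|")
  expect_equal(got_keys, keys[oracle_order])
  expect_equal(b_full$selection$score, oracle_scores[oracle_order], tolerance = 1e-12)
  # the top-W of the exhaustive ordering equals the beam result
  top12 <- apply(b$selection[, b$step_order], 1L, paste, collapse = "|")
  expect_equal(top12, keys[oracle_order][1:12])
})

test_that("a hand-set two-step summary is beam-traced as on paper", {
  # step1 (norm): A p5=2, B p5=1; step2 (test): X p5=0.5, Y p5=0
  # interaction: (A,X)=-3 -> A+X = 2+0.5-3 = -0.5; A+Y=2; B+X=1.5; B+Y=1
  ms <- data.frame(step = c("normalization", "normalization", "test", "test"),
                   method = c("A", "B", "X", "Y"), n = 5,
                   mean_shap = c(2, 1, 0.5, 0), p5 = c(2, 1, 0.5, 0),
                   stringsAsFactors = FALSE)
  mp <- data.frame(step_a = "normalization", method_a = "A",
                   step_b = "test", method_b = "X", n = 5,
                   mean_interaction = -3, p5 = -3, stringsAsFactors = FALSE)
  s <- structure(list(
    step_importance = data.frame(step = c("normalization", "test"),
                                 mean_abs_shap = c(2, 1), stringsAsFactors = FALSE),
    method_shap = ms, method_pair_interaction = mp,
    step_pair_interaction = data.frame(step_a = "normalization", step_b = "test",
                                       mean_abs_interaction = 3),
    top_fraction = 0.25, n_top = 20, steps = c("normalization", "test")),
    class = c("ShapSummary", "list"))
  b <- beam_select(s, W = 2L)
  # hand trace: beam keeps A(2), B(1); expansions A+Y=2, B+X=1.5, B+Y=1, A+X=-0.5
  expect_equal(nrow(b$selection), 2L)
  expect_equal(b$selection$normalization, c("A", "B"))
  expect_equal(b$selection$test, c("Y", "X"))
  expect_equal(b$selection$score, c(2, 1.5))
  # width 1 collapses to the greedy-but-hedged single path
  b1 <- beam_select(s, W = 1L)
  expect_equal(b1$selection$score, 2)
})

test_that("the exported decision tree is valid DOT with one node per choice", {
  model <- fit_ranker(planted_records(), seed = 1L)
  b <- beam_select(shap_explain(model), W = 4L)
  dot <- export_tree(b)
  expect_match(dot, "^digraph")
  expect_match(dot, "rankdir=LR")
  # every selected method appears as a node label
  for (st in b$step_order) for (mth in unique(b$selection[[st]]))
    expect_match(dot, paste0(st, ": ", mth), fixed = TRUE)
  # edges = nodes - root (a tree)
  n_nodes <- length(gregexpr("label=", dot)[[1]])
  n_edges <- length(gregexpr("->", dot)[[1]])
  expect_equal(n_edges, n_nodes - 1L)
  single <- b
  single$selection <- b$selection[1, ]
  expect_equal(length(gregexpr("->", export_tree(single))[[1]]), length(b$step_order))
})
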