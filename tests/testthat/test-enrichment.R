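test_that("feature tables compose per-sample log-likelihoods", {
  sc <- gen_scenario(n_nodes = 6, n_extra_cycle_edges = 0, n_pairs = 10,
                     delta = 0, seed = 4)
  expr <- gen_expression(sc)
  bn <- fit_gaussian_bn(sc$truth, expr)
  ft <- build_feature_table(list(pw1 = bn), expr)
  expect_equal(names(ft), c("sample", "pair", "condition", "split", "pw1"))
  expect_equal(ft$pw1, bn_loglik(bn, expr))

  # duplicated sample rows give duplicated feature rows
  ft2 <- build_feature_table(list(pw1 = bn), dplyr::bind_rows(expr[1, ], expr[1, ]))
  expect_equal(ft2$pw1[1], ft2$pw1[2])

  missing_gene <- expr[, setdiff(names(expr), "g03")]
  expect_error(build_feature_table(list(pw1 = bn), missing_gene), "g03")
})

test_that("perturbed samples score lower under the control-trained network", {
  sc <- gen_scenario(n_nodes = 8, n_extra_cycle_edges = 0, n_pairs = 100,
                     n_perturb = 3, delta = 2, seed = 13)
  expr <- gen_expression(sc)
  bn <- fit_gaussian_bn(sc$truth, expr)  # control training samples only
  ft <- build_feature_table(list(pw = bn), expr)
  test_rows <- ft[ft$split == "test", ]
  m_ctl <- mean(test_rows$pw[test_rows$condition == "non_tumor"])
  m_tum <- mean(test_rows$pw[test_rows$condition == "tumor"])
  expect_gt(m_ctl, m_tum)
})

test_that("AUC and MCC threshold behave on canonical inputs", {
  # perfectly separated scores
  expect_equal(pathwaybn:::auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(pathwaybn:::auc_score(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(pathwaybn:::auc_score(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)

  th <- pathwaybn:::mcc_threshold(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1))
  expect_equal(th$mcc, 1)
  expect_equal(th$accuracy, 1)
  expect_equal(th$threshold, 0.5)
})

test_that("grid search returns the best OOB cell with deterministic tie-breaks", {
  ft <- toy_feature_table(n_pairs = 30, shift = 4, seed = 2)
  ft <- pathwaybn:::paired_split(ft, 0.75, seed = 1)
  # single-cell grid -> that cell
  g1 <- grid_search_rf(ft, ntree_grid = 100, mtry_grid = 1, seed = 1)
  expect_equal(g1$ntree, 100)
  expect_equal(g1$mtry, 1)
  # separable features: every cell perfect, tie-break -> smallest cell
  g2 <- grid_search_rf(ft, ntree_grid = c(100, 200), mtry_grid = c(1, 2), seed = 1)
  expect_true(all(g2$grid$oob_auc == 1))
  expect_equal(g2$ntree, 100)
  expect_equal(g2$mtry, 1)
  # reproducible under the same seed
  g3 <- grid_search_rf(ft, ntree_grid = c(100, 200), mtry_grid = c(1, 2), seed = 1)
  expect_identical(g2$grid, g3$grid)

  ft_one <- ft[ft$condition == "tumor", ]
  expect_error(grid_search_rf(ft_one, 100, 1), "single class")
})

test_that("separable features give perfect repeated-split classification", {
  ft <- toy_feature_table(n_pairs = 40, shift = 6, seed = 3)
  res <- train_eval_rf(ft, ntree = 100, mtry = 1, seed = 1, repeats = 5)
  g <- glance(res)
  expect_equal(g$accuracy_mean, 1)
  expect_equal(g$precision_mean, 1)
  expect_equal(g$recall_mean, 1)
  expect_equal(g$f1_mean, 1)
  expect_equal(g$auc_mean, 1)
  # the separating pathway dominates the importance ranking
  expect_equal(tidy(res)$pathway[1], "pwA")
  expect_true(all(tidy(res)$mdg >= 0))
})

test_that("label shuffles drive AUC to chance", {
  ft <- toy_feature_table(n_pairs = 100, shift = 0, seed = 5)  # no signal at all
  res <- train_eval_rf(ft, ntree = 200, mtry = 1, seed = 7, repeats = 10)
  expect_gt(glance(res)$auc_mean, 0.4)
  expect_lt(glance(res)$auc_mean, 0.6)
})

test_that("rankings compare across strategies", {
  ft <- toy_feature_table(n_pairs = 30, shift = 4, seed = 6)
  resA <- train_eval_rf(ft, ntree = 100, mtry = 1, seed = 1, repeats = 3)
  resB <- train_eval_rf(ft, ntree = 100, mtry = 1, seed = 1, repeats = 3)
  cmp <- compare_rankings(list(a = resA, b = resB))
  expect_equal(nrow(cmp$ranks), 4)
  expect_equal(cmp$spearman$spearman, 1)

  # importances {P1: 5, P2: 3} -> ranks {1, 2}
  fake <- structure(list(
    metrics = resA$metrics,
    importance = tibble::tibble(pathway = c("P1", "P2"), mdg = c(5, 3)) |>
      dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(mdg))),
    hyperparams = list(ntree = 1, mtry = 1), repeats = 1),
    class = "enrichment_result")
  expect_equal(rank_pathways(fake)$rank, c(1, 2))

  resC <- resA
  resC$importance$pathway <- c("zz", "yy")
  expect_error(compare_rankings(list(a = resA, c = resC)), "different pathway")
})

test_that("train_eval_rf is reproducible and respects pairing", {
  ft <- toy_feature_table(n_pairs = 24, shift = 2, seed = 8)
  r1 <- train_eval_rf(ft, ntree = 100, mtry = 1, seed = 3, repeats = 4)
  r2 <- train_eval_rf(ft, ntree = 100, mtry = 1, seed = 3, repeats = 4)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$importance, r2$importance)
  # a redrawn split always keeps pair members together
  sp <- pathwaybn:::paired_split(ft, 0.75, seed = 11)
  agg <- tapply(sp$split, sp$pair, function(s) length(unique(s)))
  expect_true(all(agg == 1))
})
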