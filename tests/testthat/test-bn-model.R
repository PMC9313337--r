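# Build a tiny expression tibble around a value matrix.
as_expr <- function(vals, condition = "non_tumor", split = "train") {
  n <- nrow(vals)
  dplyr::bind_cols(
    tibble::tibble(sample = sprintf("s%03d", seq_len(n)),
                   pair = sprintf("p%03d", seq_len(n)),
                   condition = condition, split = split),
    tibble::as_tibble(vals))
}

test_that("maximum-likelihood fits recover hand-computable parameters", {
  # root node with training values {1, 3}: mean 2, MLE variance 1
  dag <- pathway_graph(tibble::tibble(source = character(), target = character()),
                       nodes = tibble::tibble(id = "R"))
  expr <- as_expr(tibble::tibble(R = c(1, 3)))
  bn <- fit_gaussian_bn(dag, expr)
  expect_equal(bn$params$R$beta0, 2)
  expect_equal(bn$params$R$sigma2, 1)  # divide by n, not n-1

  # exact interpolation: Y = 1 + 2X with zero noise -> variance at the floor
  dag2 <- pathway_graph(tibble::tibble(source = "X", target = "Y"))
  x <- c(0, 1, 2, 3)
  expr2 <- as_expr(tibble::tibble(X = x, Y = 1 + 2 * x))
  bn2 <- fit_gaussian_bn(dag2, expr2)
  expect_equal(bn2$params$Y$beta0, 1)
  expect_equal(unname(bn2$params$Y$beta["X"]), 2)
  expect_equal(bn2$params$Y$sigma2, 1e-8)

  expect_error(fit_gaussian_bn(dag2, as_expr(tibble::tibble(X = 1, Y = 1))),
               "at least")
})

test_that("coefficients are recovered consistently as n grows", {
  sc <- gen_scenario(n_nodes = 6, n_extra_cycle_edges = 0, n_pairs = 10,
                     delta = 0, seed = 42)
  truth_bn <- pathwaybn:::scenario_bn(sc, "non_tumor")
  errs <- vapply(c(100, 1000, 5000), function(n) {
    sc_n <- sc
    sc_n$n_pairs <- n
    expr <- gen_expression(sc_n)
    bn <- fit_gaussian_bn(sc$truth, expr, split = NULL)
    max(abs(tidy(bn)$estimate[tidy(bn)$term != "(Intercept)"] -
              tidy(truth_bn)$estimate[tidy(truth_bn)$term != "(Intercept)"]))
  }, 0)
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) < 0))
})

test_that("the factorised log-likelihood equals the joint Gaussian density", {
  # single standard-normal root at its mean
  dag <- pathway_graph(tibble::tibble(source = character(), target = character()),
                       nodes = tibble::tibble(id = "R"))
  bn <- structure(list(dag = dag,
                       params = list(R = list(beta0 = 0, beta = setNames(numeric(0), character(0)),
                                              sigma2 = 1)),
                       n_train = 10L), class = "gaussian_bn")
  expect_equal(bn_loglik(bn, c(R = 0)), -0.5 * log(2 * pi))

  # random DAG/parameter/sample triples against the closed-form MVN oracle
  for (seed in 1:30) {
    sc <- gen_scenario(n_nodes = 3 + seed %% 6, n_extra_cycle_edges = 0,
                       n_pairs = 5, delta = 0, seed = seed)
    bn2 <- pathwaybn:::scenario_bn(sc, "non_tumor")
    mv <- bn_joint_mvn(bn2)
    x <- withr::with_seed(seed, rnorm(length(mv$mean), mv$mean, 2))
    names(x) <- names(mv$mean)
    d <- x - mv$mean
    ll_mvn <- -0.5 * (length(x) * log(2 * pi) +
                        as.numeric(determinant(mv$cov)$modulus) +
                        as.numeric(t(d) %*% solve(mv$cov) %*% d))
    expect_equal(bn_loglik(bn2, x), ll_mvn, tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("log-likelihood is deterministic and order-invariant", {
  sc <- gen_scenario(n_nodes = 7, n_extra_cycle_edges = 0, n_pairs = 20,
                     delta = 0, seed = 9)
  expr <- gen_expression(sc)
  bn <- fit_gaussian_bn(sc$truth, expr)
  x <- expr[3, ]
  expect_identical(bn_loglik(bn, x), bn_loglik(bn, x))
  # shuffling node order in the DAG leaves the likelihood unchanged
  sh <- sc$truth
  perm <- withr::with_seed(4, sample.int(nrow(sh$nodes)))
  sh$nodes <- sh$nodes[perm, ]
  bn_sh <- fit_gaussian_bn(sh, expr)
  expect_equal(bn_loglik(bn_sh, x), bn_loglik(bn, x), tolerance = 1e-12)
})

test_that("BIC penalises density and prefers the true sparse model", {
  sc <- gen_scenario(n_nodes = 5, n_extra_cycle_edges = 0, n_pairs = 500,
                     delta = 0, seed = 17)
  expr <- gen_expression(sc)
  bn_true <- fit_gaussian_bn(sc$truth, expr)

  # same loglik, one extra parameter -> strictly worse BIC
  k_pen <- function(bn) sum(vapply(bn$params, function(p) length(p$beta) + 2, 0))
  n_tr <- sum(expr$condition == "non_tumor" & expr$split == "train")
  expect_equal(bn_bic(bn_true, expr),
               k_pen(bn_true) * log(n_tr) -
                 2 * sum(bn_loglik(bn_true, pathwaybn:::expr_subset(expr, "non_tumor", "train"))))

  # saturated DAG (all forward pairs) loses to the generating structure
  ids <- sc$truth$nodes$id
  sat_edges <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids)) |>
    dplyr::filter(i < j) |>
    dplyr::transmute(source = ids[i], target = ids[j])
  sat <- pathway_graph(sat_edges, nodes = sc$truth$nodes)
  bn_sat <- fit_gaussian_bn(sat, expr)
  expect_gt(bn_bic(bn_sat, expr), bn_bic(bn_true, expr))

  expect_error(bn_bic(bn_true, expr, condition = "nope"), "no samples")
})

test_that("BIC ranks aggregate across pathways", {
  tbl <- tibble::tibble(
    strategy = rep(c("a", "b"), each = 3),
    pathway = rep(c("p1", "p2", "p3"), 2),
    bic = c(10, 10, 10, 20, 20, 5))
  r <- rank_bic(tbl)
  expect_equal(r$strategy, c("a", "b"))
  expect_equal(r$mean_rank, c((1 + 1 + 2) / 3, (2 + 2 + 1) / 3))
})

test_that("rank-deficient parent matrices fall back to the pseudo-inverse", {
  dag <- pathway_graph(tibble::tibble(source = c("A", "B"), target = c("C", "C")))
  a <- c(1, 2, 3, 4, 5)
  expr <- as_expr(tibble::tibble(A = a, B = 2 * a, C = 3 * a + 1))
  expect_warning(bn <- fit_gaussian_bn(dag, expr), "rank-deficient")
  mu <- bn$params$C$beta0 + as.numeric(cbind(a, 2 * a) %*% bn$params$C$beta)
  expect_equal(mu, 3 * a + 1, tolerance = 1e-6)
})
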