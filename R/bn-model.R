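SIGMA2_FLOOR <- 1e-8

#' Fit a linear-Gaussian Bayesian network by maximum likelihood
#'
#' Each node Y with parents X1..Xk follows Y = b0 + sum(bi Xi) + eps,
#' eps ~ N(0, sigma^2). Parameters are the ordinary-least-squares estimates
#' (the MLE under Gaussian noise) fitted per node on the requested samples —
#' by default the control ("non_tumor") training samples, so the network
#' describes unperturbed regulation. The residual variance is the MLE
#' (divide by n), floored at 1e-8 so degenerate, exactly-interpolated fits
#' keep a finite density.
#'
#' @param dag An acyclic `pathway_graph`.
#' @param expr Expression tibble covering all `dag` genes.
#' @param condition Condition label to fit on (default `"non_tumor"`).
#' @param split Split label (default `"train"`; `NULL` for all samples of
#'   the condition).
#' @return An object of class `gaussian_bn`: list with `dag`, `params`
#'   (per node: `beta0`, named coefficient vector `beta`, `sigma2`) and
#'   `n_train`.
#' @export
fit_gaussian_bn <- function(dag, expr, condition = "non_tumor",
                            split = "train") {
  stopifnot(is_acyclic(dag))
  dat <- expr_subset(expr, condition, split)
  if (nrow(dat) == 0) dat <- expr_subset(expr, condition, NULL)
  genes <- expression_genes(dat)
  missing <- setdiff(dag$nodes$id, genes)
  if (length(missing) > 0) {
    stop("gene(s) absent from expression data: ",
         paste(head(missing, 5), collapse = ", "))
  }
  max_indeg <- if (nrow(dag$edges) > 0) max(table(dag$edges$target)) else 0
  if (nrow(dat) < max_indeg + 2) {
    stop("need at least ", max_indeg + 2, " samples to fit (have ",
         nrow(dat), ")")
  }
  n <- nrow(dat)
  params <- list()
  for (node in dag$nodes$id) {
    parents <- dag$edges$source[dag$edges$target == node]
    y <- dat[[node]]
    if (length(parents) == 0) {
      beta0 <- mean(y)
      beta <- setNames(numeric(0), character(0))
      res <- y - beta0
    } else {
      X <- cbind(`(Intercept)` = 1, as.matrix(dat[, parents, drop = FALSE]))
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        warning("rank-deficient parent matrix for node '", node,
                "'; using pseudo-inverse")
        co <- as.numeric(MASS_ginv(X) %*% y)
      } else {
        co <- qr.coef(qrX, y)
      }
      beta0 <- co[1]
      beta <- setNames(co[-1], parents)
      res <- y - as.numeric(X %*% co)
    }
    params[[node]] <- list(beta0 = unname(beta0), beta = beta,
                           sigma2 = max(mean(res^2), SIGMA2_FLOOR))
  }
  structure(list(dag = dag, params = params, n_train = n),
            class = "gaussian_bn")
}

# Moore-Penrose pseudo-inverse via SVD (MASS is not a declared dependency).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.gaussian_bn <- function(x, ...) {
  cat(sprintf("<gaussian_bn> %d nodes, %d edges, fitted on %d samples\n",
              nrow(x$dag$nodes), nrow(x$dag$edges), x$n_train))
  invisible(x)
}

#' Tidy a fitted Gaussian BN
#'
#' One row per parameter: node, term (`(Intercept)` or parent id), estimate,
#' plus the node's residual variance.
#'
#' @param x A `gaussian_bn`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gaussian_bn <- function(x, ...) {
  purrr::map_dfr(names(x$params), function(node) {
    p <- x$params[[node]]
    tibble::tibble(node = node,
                   term = c("(Intercept)", names(p$beta)),
                   estimate = c(p$beta0, unname(p$beta)),
                   sigma2 = p$sigma2)
  })
}

#' Per-sample Bayesian-network log-likelihood
#'
#' The joint log-density factorises over the DAG:
#' log P(x1..xn) = sum_i log P(xi | parents(xi)), each term a conditional
#' Gaussian density (natural log). Accepts one named sample vector or an
#' expression tibble and is vectorised over rows.
#'
#' @param bn A `gaussian_bn`.
#' @param newdata Named numeric vector over genes, or an expression/plain
#'   tibble with one column per gene.
#' @return Numeric vector of log-likelihoods, one per sample.
#' @export
bn_loglik <- function(bn, newdata) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- tibble::as_tibble(as.list(newdata))
  }
  nodes <- names(bn$params)
  missing <- setdiff(nodes, names(newdata))
  if (length(missing) > 0) {
    stop("sample is missing gene(s): ", paste(head(missing, 5), collapse = ", "))
  }
  n <- nrow(newdata)
  ll <- numeric(n)
  for (node in nodes) {
    p <- bn$params[[node]]
    mu <- rep(p$beta0, n)
    if (length(p$beta) > 0) {
      mu <- mu + as.numeric(as.matrix(newdata[, names(p$beta), drop = FALSE]) %*%
                              unname(p$beta))
    }
    ll <- ll + dnorm(newdata[[node]], mean = mu, sd = sqrt(p$sigma2), log = TRUE)
  }
  ll
}

#' Bayesian information criterion of a fitted BN on a sample set
#'
#' BIC = k * ln(n) - 2 * sum(loglik), where k counts one intercept, one
#' residual variance and one coefficient per parent for every node
#' (k = sum(|parents| + 2)). Lower is better: the criterion balances fit
#' against the number of edges the reconstruction kept.
#'
#' @param bn A `gaussian_bn`.
#' @param expr Expression tibble.
#' @param condition,split Sample filters (defaults: control training data,
#'   the set the fit itself used).
#' @return BIC value (numeric scalar).
#' @export
bn_bic <- function(bn, expr, condition = "non_tumor", split = "train") {
  dat <- expr_subset(expr, condition, split)
  if (nrow(dat) == 0) stop("no samples match the requested condition/split")
  k <- sum(vapply(bn$params, function(p) length(p$beta) + 2, 0))
  n <- nrow(dat)
  k * log(n) - 2 * sum(bn_loglik(bn, dat))
}

#' Average BIC ranks of strategies across pathways
#'
#' Given BIC values per (strategy, pathway), ranks strategies within each
#' pathway (rank 1 = lowest BIC = best penalized fit) and averages the ranks
#' per strategy across pathways — the model-fitness league table for the
#' reconstruction strategies.
#'
#' @param bic_table Tibble with columns `strategy`, `pathway`, `bic`.
#' @return Tibble with columns `strategy`, `mean_rank`, sorted best first.
#' @export
rank_bic <- function(bic_table) {
  stopifnot(all(c("strategy", "pathway", "bic") %in% names(bic_table)))
  bic_table |>
    dplyr::group_by(.data$pathway) |>
    dplyr::mutate(rank = rank(.data$bic)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(mean_rank = mean(rank), .groups = "drop") |>
    dplyr::arrange(.data$mean_rank)
}

#' Closed-form joint distribution of a linear-Gaussian system
#'
#' The implied joint over all nodes is multivariate normal with
#' mu = (I - B)^-T applied to intercepts and Sigma = (I - B)^-T D (I - B)^-1,
#' where B[i, j] is the coefficient of parent i in child j's equation and D
#' the diagonal of residual variances. Used as the independent oracle for
#' [bn_loglik()] and for the synthetic generator's covariance checks.
#'
#' @param bn A `gaussian_bn`.
#' @return List with `mean` (named vector) and `cov` (matrix).
#' @export
bn_joint_mvn <- function(bn) {
  nodes <- names(bn$params)
  k <- length(nodes)
  B <- matrix(0, k, k, dimnames = list(nodes, nodes))
  b0 <- setNames(numeric(k), nodes)
  D <- setNames(numeric(k), nodes)
  for (node in nodes) {
    p <- bn$params[[node]]
    b0[node] <- p$beta0
    D[node] <- p$sigma2
    if (length(p$beta) > 0) B[names(p$beta), node] <- unname(p$beta)
  }
  A <- solve(diag(k) - t(B))        # x = A %*% (b0 + eps)
  mu <- as.numeric(A %*% b0)
  Sigma <- A %*% diag(D, k) %*% t(A)
  list(mean = setNames(mu, nodes), cov = Sigma)
}
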