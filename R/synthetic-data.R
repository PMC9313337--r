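#' Generate a synthetic annotated pathway graph with known ground truth
#'
#' Builds a random DAG on a seed-fixed topological order (the acyclic
#' "truth"), annotates compartments consistently with depth (early nodes at
#' the membrane, deep nodes in the nucleus) and then adds back-edges from
#' deep to shallow nodes (interaction `inhibition` or `expression`) to
#' create the directed cycles typical of curated signalling pathways. The
#' observed cyclic graph and the truth it was built from are both returned,
#' so reconstruction strategies can be scored against the generating DAG.
#'
#' @param n_nodes Number of genes (>= 3).
#' @param n_extra_cycle_edges Number of cycle-creating back-edges.
#' @param seed Integer seed.
#' @param annotate Annotate compartments by depth (default `TRUE`); when
#'   `FALSE` all compartments are `unknown`.
#' @param p_edge Forward-edge density of the truth DAG (default 0.3).
#' @param name Graph name prefix.
#' @return List with `observed` (cyclic `pathway_graph`), `truth` (acyclic
#'   `pathway_graph`) and `back_edges` (tibble).
#' @export
gen_pathway <- function(n_nodes, n_extra_cycle_edges = 2, seed = 1L,
                        annotate = TRUE, p_edge = 0.3, name = "synthetic") {
  stopifnot(n_nodes >= 3)
  ids <- sprintf("g%02d", seq_len(n_nodes))
  withr::with_seed(seed, {
    pairs <- t(combn(seq_len(n_nodes), 2))  # i < j: forward in topological order
    pick <- runif(nrow(pairs)) < p_edge
    # keep the backbone connected: ensure every non-root has >= 1 parent
    for (j in 2:n_nodes) {
      if (!any(pick & pairs[, 2] == j)) {
        cand <- which(pairs[, 2] == j)
        pick[cand[sample.int(length(cand), 1)]] <- TRUE
      }
    }
    fwd <- pairs[pick, , drop = FALSE]
    interactions <- sample(c("activation", "binding", "state_transition"),
                           nrow(fwd), replace = TRUE,
                           prob = c(0.6, 0.2, 0.2))
    edges <- tibble::tibble(source = ids[fwd[, 1]], target = ids[fwd[, 2]],
                            interaction = interactions)
    # back-edges: deep -> strictly shallower node, creating cycles
    back_cand <- pairs
    # a back-edge j -> i only creates a cycle if a forward path i ->..-> j
    # exists, so restrict candidates to reachable pairs
    adj_fwd <- split(fwd[, 2], factor(fwd[, 1], levels = seq_len(n_nodes)))
    reachable <- function(i, j) {  # path i -> j through fwd edges?
      adj <- adj_fwd
      stack <- c(i)
      seen <- logical(n_nodes)
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (v == j) return(TRUE)
        for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
      FALSE
    }
    ok <- vapply(seq_len(nrow(back_cand)),
                 function(r) reachable(back_cand[r, 1], back_cand[r, 2]),
                 TRUE)
    back_cand <- back_cand[ok, , drop = FALSE]
    if (annotate) {
      # back-edges must run strictly against the compartment axis so that
      # they are exactly the anti-flux edges the biological rules remove
      tert <- function(i) ceiling(3 * i / n_nodes)
      strict <- tert(back_cand[, 2]) > tert(back_cand[, 1])
      back_cand <- back_cand[strict, , drop = FALSE]
    }
    if (nrow(back_cand) < n_extra_cycle_edges) {
      stop("cannot place ", n_extra_cycle_edges, " cycle-creating back-edges; ",
           "increase p_edge or n_nodes")
    }
    sel <- back_cand[sample.int(nrow(back_cand), n_extra_cycle_edges), ,
                     drop = FALSE]
    back <- tibble::tibble(source = ids[sel[, 2]], target = ids[sel[, 1]],
                           interaction = sample(c("inhibition", "expression"),
                                                n_extra_cycle_edges,
                                                replace = TRUE))
  })
  depth <- seq_len(n_nodes) / n_nodes
  compartment <- if (annotate) {
    ifelse(depth <= 1 / 3, "membrane",
           ifelse(depth <= 2 / 3, "cytoplasm", "nucleus"))
  } else "unknown"
  nodes <- tibble::tibble(id = ids, compartment = compartment)
  truth <- pathway_graph(edges, nodes, name = paste0(name, "_truth"))
  observed <- pathway_graph(dplyr::bind_rows(edges, back), nodes, name = name)
  list(observed = observed, truth = truth, back_edges = back)
}

#' Assemble a full synthetic scenario
#'
#' A scenario bundles the observed cyclic graph, its acyclic truth, the
#' linear-Gaussian generating parameters (coefficients uniform on
#' +/-[0.5, 2], residual sd 1, root means around 5-9 so values land on a
#' nonnegative log2(n+1)-like scale) and a tumor-condition perturbation:
#' an additive delta applied to the coefficients of a chosen subset of truth
#' edges.
#'
#' @inheritParams gen_pathway
#' @param n_pairs Number of tumor/control sample pairs.
#' @param n_perturb Number of truth edges perturbed in the tumor condition.
#' @param delta Additive coefficient perturbation (0 = null scenario).
#' @param noise_sd Residual standard deviation (default 1).
#' @return An object of class `bn_scenario`.
#' @export
gen_scenario <- function(n_nodes = 12, n_extra_cycle_edges = 3, n_pairs = 60,
                         n_perturb = 3, delta = 1.5, seed = 1L,
                         noise_sd = 1, p_edge = 0.3, name = "synthetic") {
  gp <- gen_pathway(n_nodes, n_extra_cycle_edges,
                    seed = derive_seed(seed, "graph"), p_edge = p_edge,
                    name = name)
  truth <- gp$truth
  withr::with_seed(derive_seed(seed, "params"), {
    coefs <- (2 * (runif(nrow(truth$edges)) < 0.5) - 1) *
      runif(nrow(truth$edges), 0.5, 2.0)
    roots <- setdiff(truth$nodes$id, truth$edges$target)
    beta0 <- setNames(rep(1, n_nodes), truth$nodes$id)
    beta0[roots] <- runif(length(roots), 5, 9)
    n_perturb <- min(n_perturb, nrow(truth$edges))
    perturb_idx <- sample.int(nrow(truth$edges), n_perturb)
  })
  structure(list(observed = gp$observed, truth = truth,
                 back_edges = gp$back_edges,
                 coefs = coefs, beta0 = beta0, noise_sd = noise_sd,
                 perturb_idx = perturb_idx, delta = delta,
                 n_pairs = n_pairs, seed = seed, name = name),
            class = "bn_scenario")
}

#' @export
print.bn_scenario <- function(x, ...) {
  cat(sprintf(
    "<bn_scenario> %s: %d nodes, %d truth edges (+%d back-edges), %d pairs, delta=%.2f on %d edge(s)\n",
    x$name, nrow(x$truth$nodes), nrow(x$truth$edges), nrow(x$back_edges),
    x$n_pairs, x$delta, length(x$perturb_idx)))
  invisible(x)
}

# Scenario parameters as a gaussian_bn (condition-specific coefficients).
scenario_bn <- function(scenario, condition = c("non_tumor", "tumor")) {
  condition <- match.arg(condition)
  coefs <- scenario$coefs
  if (condition == "tumor") {
    coefs[scenario$perturb_idx] <- coefs[scenario$perturb_idx] + scenario$delta
  }
  params <- list()
  for (node in scenario$truth$nodes$id) {
    at <- which(scenario$truth$edges$target == node)
    params[[node]] <- list(
      beta0 = unname(scenario$beta0[node]),
      beta = setNames(coefs[at], scenario$truth$edges$source[at]),
      sigma2 = scenario$noise_sd^2)
  }
  structure(list(dag = scenario$truth, params = params, n_train = NA_integer_),
            class = "gaussian_bn")
}

# Ancestral sampling of n draws from a gaussian_bn; returns samples x genes.
sample_bn <- function(bn, n, noise_sd = NULL) {
  ord_ig <- igraph::topo_sort(as_igraph(bn$dag), mode = "out")
  ord <- names(ord_ig)
  out <- matrix(0, n, length(bn$params),
                dimnames = list(NULL, names(bn$params)))
  for (node in ord) {
    p <- bn$params[[node]]
    mu <- rep(p$beta0, n)
    if (length(p$beta) > 0) {
      mu <- mu + out[, names(p$beta), drop = FALSE] %*% unname(p$beta)
    }
    sdv <- if (is.null(noise_sd)) sqrt(p$sigma2) else noise_sd
    out[, node] <- mu + rnorm(n, 0, sdv)
  }
  out
}

#' Generate paired two-condition expression data for a scenario
#'
#' Ancestral sampling over the truth DAG: control samples use the scenario's
#' coefficients, tumor samples the perturbed ones. Each of the `n_pairs`
#' pair ids contributes one sample per condition; a paired 75/25 train/test
#' split is assigned (both members of a pair on the same side). Values stay
#' on the generator's nonnegative log2-like scale — no clamping, so the
#' closed-form covariance of the linear system holds exactly.
#'
#' @param scenario A `bn_scenario` from [gen_scenario()].
#' @param repeat_index Which of the split randomizations to assign (the
#'   split seed derives from `scenario$seed` and this index, so the study protocol's
#'   ten repeated splits are independently reproducible).
#' @return An expression tibble (see [read_expression()]).
#' @export
gen_expression <- function(scenario, repeat_index = 1L) {
  n <- scenario$n_pairs
  ctl <- scenario_bn(scenario, "non_tumor")
  tum <- scenario_bn(scenario, "tumor")
  vals <- withr::with_seed(derive_seed(scenario$seed, "expr"), {
    rbind(sample_bn(ctl, n), sample_bn(tum, n))
  })
  # deterministic per-gene shift onto a nonnegative log2(n+1)-like scale:
  # a constant offset (same in both conditions) leaves all covariances and
  # regression coefficients untouched
  mv_c <- bn_joint_mvn(ctl)
  mv_t <- bn_joint_mvn(tum)
  off <- pmax(0, 4 * sqrt(diag(mv_c$cov)) - mv_c$mean,
              4 * sqrt(diag(mv_t$cov)) - mv_t$mean)
  offset <- setNames(off, names(mv_c$mean))
  vals <- sweep(vals, 2, offset[colnames(vals)], "+")
  pair_ids <- sprintf("p%03d", seq_len(n))
  meta <- tibble::tibble(
    sample = c(paste0(pair_ids, "_N"), paste0(pair_ids, "_T")),
    pair = rep(pair_ids, 2),
    condition = rep(c("non_tumor", "tumor"), each = n),
    split = "train")
  expr <- dplyr::bind_cols(meta, tibble::as_tibble(vals))
  resplit_expression(expr, seed = derive_seed(scenario$seed,
                                              paste0("split", repeat_index)))
}

#' Redraw the paired 75/25 train/test split
#'
#' @param expr Expression tibble.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return The expression tibble with a fresh `split` column; both members
#'   of each pair share the assignment.
#' @export
resplit_expression <- function(expr, fraction = 0.75, seed = 1L) {
  paired_split(expr, fraction = fraction, seed = seed)
}
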