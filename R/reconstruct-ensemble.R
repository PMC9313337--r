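# --- TrueSkill node ranking -------------------------------------------------
# Each node is a player (Gaussian skill belief, mu = 25, sigma = 25/3); each
# edge u -> v is a match won by v. Standard two-player update without draws:
#   c^2 = 2*beta^2 + sigma_w^2 + sigma_l^2,  t = (mu_w - mu_l)/c
#   v(t) = phi(t)/Phi(t),  w(t) = v(t)*(v(t)+t)
#   mu_w += sigma_w^2/c * v;   mu_l -= sigma_l^2/c * v
#   sigma^2 *= (1 - sigma^2/c^2 * w)
# Edges are processed once in a seed-shuffled order; the final ranking score
# is the posterior mean, higher = more downstream.
trueskill_rank <- function(edges, nodes, seed = 1L,
                           mu0 = 25, sigma0 = 25 / 3) {
  beta <- sigma0 / 2
  mu <- setNames(rep(mu0, length(nodes)), nodes)
  s2 <- setNames(rep(sigma0^2, length(nodes)), nodes)
  ord <- withr::with_seed(seed, sample.int(nrow(edges)))
  for (i in ord) {
    w <- edges$target[i]  # winner: the regulated node ranks higher
    l <- edges$source[i]
    c2 <- 2 * beta^2 + s2[w] + s2[l]
    cc <- sqrt(c2)
    t <- (mu[w] - mu[l]) / cc
    vt <- dnorm(t) / pnorm(t)
    if (!is.finite(vt)) vt <- -t  # extreme tail fallback
    wt <- vt * (vt + t)
    mu[w] <- mu[w] + s2[w] / cc * vt
    mu[l] <- mu[l] - s2[l] / cc * vt
    s2[w] <- s2[w] * max(1 - s2[w] / c2 * wt, 1e-6)
    s2[l] <- s2[l] * max(1 - s2[l] / c2 * wt, 1e-6)
  }
  mu
}

# --- Social agony ranking ---------------------------------------------------
# Integer labels r minimising sum over edges u->v of max(0, r[u] - r[v] + 1).
# Exact exhaustive search over labelings 1..k for k <= exact_max nodes;
# seeded coordinate-descent relabeling (labels restricted to 1..k) above.
agony_of <- function(r, src_idx, tgt_idx) {
  sum(pmax(0, r[src_idx] - r[tgt_idx] + 1))
}

agony_rank <- function(edges, nodes, seed = 1L, exact_max = 5L) {
  k <- length(nodes)
  src <- match(edges$source, nodes)
  tgt <- match(edges$target, nodes)
  n_forward <- function(r) sum(r[src] < r[tgt])
  # objective: minimise agony; among minimal labelings prefer the hierarchy
  # explaining the most edges (max strictly-forward edges)
  score <- function(r) agony_of(r, src, tgt) - n_forward(r) / (length(src) + 1)
  if (k <= exact_max) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    sc <- apply(grid, 1, score)
    best <- grid[which.min(sc), ]
  } else {
    # coordinate descent on node labels; only edges incident to the node
    # being relabelled contribute to the score change, so each step is local
    out_e <- lapply(seq_len(k), function(i) which(src == i & tgt != i))
    in_e <- lapply(seq_len(k), function(i) which(tgt == i & src != i))
    wt <- 1 / (length(src) + 1)
    best <- withr::with_seed(seed, sample.int(k))
    local_score <- function(i, lab) {
      rv <- best[tgt[out_e[[i]]]]
      ru <- best[src[in_e[[i]]]]
      sum(pmax(0, lab - rv + 1)) + sum(pmax(0, ru - lab + 1)) -
        (sum(lab < rv) + sum(ru < lab)) * wt
    }
    repeat {
      improved <- FALSE
      for (i in seq_len(k)) {
        vals <- vapply(seq_len(k), function(lab) local_score(i, lab), 0)
        pick <- which.min(vals)
        if (vals[pick] < local_score(i, best[i]) - 1e-12) {
          best[i] <- pick
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  setNames(as.numeric(best), nodes)
}

# --- Decycling heuristics ---------------------------------------------------
# Given a ranking (higher = more downstream), a "violating" edge u -> v has
# rank gap r[u] - r[v] >= 0: it points against the hierarchy. Each heuristic
# returns the indices (into `edges`) it removes; each guarantees the residual
# subgraph acyclic because removing *all* violating edges leaves only
# strictly rank-increasing edges.
edges_acyclic <- function(edges, nodes, drop_idx) {
  alive <- rep(TRUE, nrow(edges))
  alive[drop_idx] <- FALSE
  edges_acyclic_cpp(match(edges$source, nodes), match(edges$target, nodes),
                    alive, length(nodes))
}

decycle_heuristic <- function(edges, nodes, ranks,
                              heuristic = c("forward", "backward", "greedy")) {
  heuristic <- match.arg(heuristic)
  gap <- ranks[edges$source] - ranks[edges$target]
  viol <- which(gap >= 0)
  if (edges_acyclic(edges, nodes, integer())) return(integer())
  if (heuristic == "forward") {
    ord <- viol[order(-gap[viol])]  # descending gap, stable
    removed <- integer()
    for (i in ord) {
      removed <- c(removed, i)
      if (edges_acyclic(edges, nodes, removed)) break
    }
    removed
  } else if (heuristic == "backward") {
    ord <- viol[order(gap[viol])]  # ascending gap
    # smallest suffix (largest-gap tail) whose removal breaks all cycles;
    # acyclicity is monotone in the suffix, so scan for the turning point
    lo <- 1L
    while (lo < length(ord) &&
           edges_acyclic(edges, nodes, ord[(lo + 1L):length(ord)])) {
      lo <- lo + 1L
    }
    ord[lo:length(ord)]
  } else {
    removed <- integer()
    repeat {
      if (edges_acyclic(edges, nodes, removed)) break
      left <- setdiff(viol, removed)
      if (length(left) == 0) {  # ranking left a cycle of negative-gap edges: impossible
        left <- setdiff(seq_len(nrow(edges)), removed)
      }
      pick <- left[which.max(gap[left])]
      removed <- c(removed, pick)
    }
    removed
  }
}

#' Hierarchy-preserving ensemble reconstruction
#'
#' Breaks cycles while preserving the graph's hierarchy as much as possible.
#' Within each nontrivial strongly connected component two node rankings are
#' computed — TrueSkill (every edge u -> v is a match won by v; Gaussian
#' skill beliefs updated by the standard two-player rule; rank = posterior
#' mean) and social agony (integer labelling minimising
#' sum max(0, r(u) - r(v) + 1) over edges) — and each ranking is paired with
#' three removal heuristics (forward, backward, greedy scans over
#' hierarchy-violating edges), yielding six decycling methods. Each method
#' votes on every edge (remove = 1); the final DAG inserts edges in ascending
#' vote order (stable ties), skipping cycle-creators, so the edges most often
#' tagged for removal are the ones sacrificed.
#'
#' @param g A `pathway_graph`.
#' @param seed Integer seed (TrueSkill match order, agony restarts).
#' @return A `bn_reconstruction` with `strategy = "ensemble"`; removed edges
#'   carry their vote score (0-6) as evidence.
#' @export
ensemble_reconstruct <- function(g, seed = 1L) {
  sl <- remove_self_loops(g)
  edges <- sl$graph$edges
  votes <- rep(0, nrow(edges))
  keys <- edge_keys(edges)
  sccs <- nontrivial_sccs(sl$graph)
  if (length(sccs) > 0) {
    # hierarchy is inferred on the whole graph (upstream/downstream context
    # outside an SCC informs which of its edges are feedbacks); decycling
    # then runs per SCC
    all_nodes <- g$nodes$id
    rankings <- list(
      trueskill = trueskill_rank(edges, all_nodes,
                                 seed = derive_seed(seed, "trueskill")),
      agony = agony_rank(edges, all_nodes, seed = derive_seed(seed, "agony")))
    for (members in sccs) {
      idx <- which(edges$source %in% members & edges$target %in% members)
      sub <- edges[idx, ]
      for (rk in rankings) {
        for (h in c("forward", "backward", "greedy")) {
          rem <- decycle_heuristic(sub, members, rk[members], h)
          votes[idx[rem]] <- votes[idx[rem]] + 1
        }
      }
    }
  }
  ord <- order(votes)  # ascending votes, stable input order on ties
  res <- greedy_acyclic_insert(g$nodes, edges[ord, ])
  kept_keys <- edge_keys(res$kept)
  keep <- keys %in% kept_keys
  dag <- g
  dag$edges <- edges[keep, ]
  removed <- dplyr::bind_rows(
    removed_tbl(sl$removed, "self_loop"),
    removed_tbl(edges[!keep, ], "vote", votes[!keep]))
  new_reconstruction("ensemble", dag, removed, seed = seed,
                     details = list(votes = setNames(votes, keys)))
}

#' The six ensemble decycling methods
#'
#' Enumerates the (ranking metric, removal heuristic) pairs that make up the
#' ensemble vote.
#'
#' @return A tibble with columns `metric` and `heuristic` (6 rows).
#' @export
ensemble_members <- function() {
  tidyr::expand_grid(metric = c("trueskill", "agony"),
                     heuristic = c("forward", "backward", "greedy"))
}
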