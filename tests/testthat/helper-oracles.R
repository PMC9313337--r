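# Independent oracles used across the suite. Each is deliberately naive
# (reachability matrices, exhaustive enumeration) so it shares no code with
# the implementation it checks.

# Random directed graph as a pathway_graph; may contain cycles/self-loops.
random_graph <- function(n_nodes, p_edge, seed, self_loops = FALSE) {
  withr::with_seed(seed, {
    ids <- LETTERS[seq_len(n_nodes)]
    grid <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
    if (!self_loops) grid <- grid[grid$source != grid$target, ]
    sel <- grid[runif(nrow(grid)) < p_edge, ]
    if (nrow(sel) == 0) sel <- grid[1, ]
    pathway_graph(sel, nodes = tibble::tibble(id = ids), name = "random")
  })
}

# Boolean reachability closure by repeated matrix multiplication.
reach_matrix <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  simple <- g$edges[g$edges$source != g$edges$target, ]
  A[cbind(simple$source, simple$target)] <- TRUE
  R <- A
  for (i in seq_len(n)) R <- R | (R %*% A > 0)
  R
}

# SCC partition from mutual reachability (nontrivial: size >= 2 or self-loop).
brute_sccs <- function(g) {
  R <- reach_matrix(g)
  ids <- g$nodes$id
  mutual <- R & t(R)
  diag(mutual) <- TRUE
  groups <- unique(apply(mutual, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  groups <- strsplit(groups, ",")
  keep <- vapply(groups, length, 0L) >= 2
  loops <- unique(g$edges$source[g$edges$source == g$edges$target])
  nontrivial <- c(groups[keep],
                  as.list(setdiff(loops, unlist(groups[keep]))))
  lapply(nontrivial, sort)
}

# All simple cycles by brute-force DFS over node sequences.
brute_simple_cycles <- function(g) {
  simple <- g$edges[g$edges$source != g$edges$target, ]
  adj <- split(simple$target, factor(simple$source, levels = g$nodes$id))
  cycles <- list()
  extend <- function(path) {
    for (w in adj[[path[length(path)]]]) {
      if (w == path[1] && length(path) >= 2) {
        if (path[1] == min(path)) cycles[[length(cycles) + 1]] <<- path
      } else if (!(w %in% path) && w > path[1]) {
        extend(c(path, w))
      }
    }
  }
  for (v in sort(g$nodes$id)) extend(v)
  key <- vapply(cycles, function(cy) paste(cy, collapse = "->"), "")
  cycles[order(nchar(key), key)]
}

# Exhaustive social-agony minimisation over integer labelings 1..k.
brute_agony <- function(edges, nodes) {
  k <- length(nodes)
  src <- match(edges$source, nodes)
  tgt <- match(edges$target, nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  ag <- apply(grid, 1, function(r) sum(pmax(0, r[src] - r[tgt] + 1)))
  list(min_agony = min(ag), ranking = setNames(grid[which.min(ag), ], nodes))
}

# Small two-pathway feature scenario helper for enrichment tests.
toy_feature_table <- function(n_pairs = 40, shift = 3, seed = 1) {
  withr::with_seed(seed, {
    pair <- sprintf("p%02d", seq_len(n_pairs))
    tibble::tibble(
      sample = c(paste0(pair, "_N"), paste0(pair, "_T")),
      pair = rep(pair, 2),
      condition = rep(c("non_tumor", "tumor"), each = n_pairs),
      split = "train",
      pwA = c(rnorm(n_pairs), rnorm(n_pairs) - shift),
      pwB = rnorm(2 * n_pairs))
  })
}
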