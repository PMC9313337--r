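STRATEGIES <- c("props", "clipper", "bnrich", "bpa", "ensemble")

# Common result container for all five DAG-reconstruction strategies.
# removed: tibble(source, target, interaction, provenance, reason, evidence)
# added:   tibble of edges with provenance "added" (BPA only)
new_reconstruction <- function(strategy, dag, removed, added = NULL,
                               seed = NULL, details = list()) {
  if (is.null(added)) {
    added <- dag$edges[0, ]
  }
  stopifnot(strategy %in% STRATEGIES)
  structure(list(strategy = strategy, dag = dag, removed = removed,
                 added = added, seed = seed, details = details),
            class = "bn_reconstruction")
}

empty_removed <- function() {
  tibble::tibble(source = character(), target = character(),
                 interaction = character(), provenance = character(),
                 reason = character(), evidence = double())
}

removed_tbl <- function(edges, reason, evidence = NA_real_) {
  if (nrow(edges) == 0) return(empty_removed())
  tibble::tibble(source = edges$source, target = edges$target,
                 interaction = edges$interaction,
                 provenance = edges$provenance,
                 reason = reason,
                 evidence = rep_len(evidence, nrow(edges)))
}

#' @export
print.bn_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<bn_reconstruction> strategy=%s: %d nodes, %d edges kept, %d removed (%d self-loops), %d added\n",
    x$strategy, nrow(x$dag$nodes), nrow(x$dag$edges),
    nrow(x$removed), sum(x$removed$reason == "self_loop"), nrow(x$added)))
  invisible(x)
}

#' Tidy a reconstruction into a per-edge ledger
#'
#' One row per original or added edge with its fate (`kept`, `removed`,
#' `added`), the removal reason code and the numeric evidence (p-value,
#' vote score, ...) where the strategy produces one.
#'
#' @param x A `bn_reconstruction`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bn_reconstruction <- function(x, ...) {
  kept <- x$dag$edges[x$dag$edges$provenance == "original", ]
  out <- dplyr::bind_rows(
    dplyr::mutate(kept, status = "kept", reason = NA_character_,
                  evidence = NA_real_),
    dplyr::mutate(x$removed, status = "removed"),
    if (nrow(x$added) > 0)
      dplyr::mutate(x$added, status = "added", reason = NA_character_,
                    evidence = NA_real_)
  )
  dplyr::mutate(out, strategy = x$strategy, .before = 1)
}

#' Random-insertion DAG reconstruction (PROPS-style)
#'
#' Starts from an empty graph and re-inserts the pathway's edges in a
#' seed-determined uniform random order, skipping any edge whose insertion
#' would create a directed cycle. Self-loops are stripped first. Every
#' rejected edge would re-create a cycle if added back to the final DAG.
#'
#' @param g A `pathway_graph` (may be cyclic).
#' @param seed Integer seed controlling the insertion order.
#' @return A `bn_reconstruction` with `strategy = "props"`.
#' @export
props_reconstruct <- function(g, seed = 1L) {
  sl <- remove_self_loops(g)
  edges <- sl$graph$edges
  ord <- withr::with_seed(seed, sample.int(nrow(edges)))
  perm <- edges[ord, ]
  res <- greedy_acyclic_insert(g$nodes, perm)
  kept_keys <- edge_keys(res$kept)
  dag <- g
  dag$edges <- edges[edge_keys(edges) %in% kept_keys, ]  # original stable order
  removed <- dplyr::bind_rows(removed_tbl(sl$removed, "self_loop"),
                              removed_tbl(res$rejected, "cycle"))
  new_reconstruction("props", dag, removed, seed = seed)
}

# Insert edges in the given order, skipping cycle-creating ones.
# Returns kept and rejected edge tibbles (in visit order).
greedy_acyclic_insert <- function(nodes, edges_in_order) {
  keep <- greedy_insert_cpp(match(edges_in_order$source, nodes$id),
                            match(edges_in_order$target, nodes$id),
                            nrow(nodes))
  list(kept = edges_in_order[keep, ], rejected = edges_in_order[!keep, ])
}

#' Cyclegroup rewiring reconstruction (BPA-style)
#'
#' Groups of cycles sharing nodes ("cyclegroups", realised as nontrivial
#' strongly connected components) are handled together: every edge between
#' two group members is deleted, the members are numbered by a seeded random
#' permutation, an edge i -> j is added for every ordered member pair with
#' number(i) < number(j) (a complete acyclic tournament, k(k-1)/2 edges), and
#' every external parent of any member is connected to every member it does
#' not already point to. Added edges carry `provenance = "added"`.
#'
#' @param g A `pathway_graph`.
#' @param seed Integer seed controlling the member numbering.
#' @return A `bn_reconstruction` with `strategy = "bpa"`.
#' @export
bpa_reconstruct <- function(g, seed = 1L) {
  sl <- remove_self_loops(g)
  edges <- sl$graph$edges
  groups <- nontrivial_sccs(sl$graph)
  removed <- removed_tbl(sl$removed, "self_loop")
  added <- edges[0, ]
  keep <- rep(TRUE, nrow(edges))
  withr::with_seed(seed, {
    for (members in groups) {
      internal <- edges$source %in% members & edges$target %in% members
      removed <- dplyr::bind_rows(removed,
                                  removed_tbl(edges[internal, ], "cyclegroup"))
      keep[internal] <- FALSE
      number <- sample.int(length(members))
      ord <- members[order(number)]
      pairs <- if (length(ord) >= 2) t(combn(seq_along(ord), 2)) else matrix(0, 0, 2)
      tour <- tibble::tibble(source = ord[pairs[, 1]], target = ord[pairs[, 2]],
                             interaction = "unknown", provenance = "added")
      ext <- edges$target %in% members & !(edges$source %in% members)
      parents <- unique(edges$source[ext])
      fan <- tidyr::expand_grid(source = parents, target = members)
      if (nrow(fan) > 0) {
        have <- edge_keys(edges[ext, ])
        fan <- fan[!(paste(fan$source, fan$target, sep = "\r") %in% have), ]
        fan <- dplyr::mutate(fan, interaction = "unknown", provenance = "added")
      }
      added <- dplyr::bind_rows(added, tour, fan)
    }
  })
  dag <- g
  dag$edges <- dplyr::bind_rows(edges[keep, ], added)
  res <- new_reconstruction("bpa", dag, removed, added = added, seed = seed)
  stopifnot(is_acyclic(res$dag))
  res
}
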