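# Closed-form simple linear regression slope test: child ~ parent.
# Returns the two-sided p-value of H0: slope = 0 (t distribution, n-2 df).
# Zero-variance parent (or child) -> p = 1 with a warning, per contract.
edge_slope_pvalue <- function(parent, child) {
  n <- length(parent)
  if (n < 3) stop("need at least 3 samples for the slope test")
  if (var(parent) == 0 || var(child) == 0) {
    warning("zero-variance gene in slope test; p-value set to 1")
    return(1)
  }
  r <- cor(parent, child)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Significance-ranked DAG reconstruction (Clipper-style)
#'
#' Uses the strength of linear association between connected genes to decide
#' which cyclic edges to sacrifice. For every edge a simple linear regression
#' of the child on the parent is fitted on control training samples; the
#' two-sided p-value of the slope t-test is the edge's evidence. Edges are
#' then re-inserted into an empty graph in ascending-p order (most
#' significant first; ties broken by stable input order), skipping any edge
#' that would create a cycle, so the removed edges are those with the weakest
#' expression support.
#'
#' @param g A `pathway_graph`.
#' @param expr Expression tibble covering all graph genes.
#' @param condition Condition label whose samples drive the regressions
#'   (default `"non_tumor"`, the control group).
#' @param split Split label to use (default `"train"`); `NULL` uses all
#'   samples of the condition.
#' @return A `bn_reconstruction` with `strategy = "clipper"`; removed edges
#'   carry their p-values as evidence.
#' @export
clipper_reconstruct <- function(g, expr, condition = "non_tumor",
                                split = "train") {
  sub <- expr_subset(expr, condition, split)
  if (nrow(sub) == 0 && !is.null(split)) {
    sub <- expr_subset(expr, condition, NULL)
  }
  if (nrow(sub) < 3) stop("need >= 3 samples of condition '", condition, "'")
  sl <- remove_self_loops(g)
  edges <- sl$graph$edges
  genes <- expression_genes(sub)
  missing <- setdiff(unique(c(edges$source, edges$target)), genes)
  if (length(missing) > 0) {
    stop("gene(s) absent from expression data: ",
         paste(head(missing, 5), collapse = ", "))
  }
  pvals <- vapply(seq_len(nrow(edges)), function(i) {
    edge_slope_pvalue(sub[[edges$source[i]]], sub[[edges$target[i]]])
  }, 0)
  ord <- order(pvals)  # stable: ties keep input edge order
  res <- greedy_acyclic_insert(g$nodes, edges[ord, ])
  kept_keys <- edge_keys(res$kept)
  dag <- g
  keep <- edge_keys(edges) %in% kept_keys
  dag$edges <- edges[keep, ]
  removed <- dplyr::bind_rows(
    removed_tbl(sl$removed, "self_loop"),
    removed_tbl(edges[!keep, ], "cycle", pvals[!keep]))
  new_reconstruction("clipper", dag, removed,
                     details = list(p_values = setNames(pvals, edge_keys(edges))))
}
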