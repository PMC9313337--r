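COMPARTMENT_RANK <- c(extracellular = 1, membrane = 2, cytoplasm = 3,
                      nucleus = 4, unknown = NA_real_)

#' Biological-rule DAG reconstruction (BNrich-style, rule stage)
#'
#' Removes cyclic structure using prior knowledge instead of data or
#' randomness: signalling flows from the cell membrane towards the nucleus,
#' so edges running against that axis inside a cyclic region are feedbacks
#' and are eliminated. Ordered rules, each applied only to edges whose two
#' endpoints lie in the same nontrivial strongly connected component, with
#' SCCs recomputed after each rule:
#'
#' * **R1** (anti-flux): source compartment strictly deeper than target on
#'   the axis extracellular < membrane < cytoplasm < nucleus.
#' * **R2** (nuclear feedback output): `expression` / `state_transition`
#'   edges leaving a nucleus node towards any shallower compartment.
#' * **R3** (negative feedback): `inhibition` edges inside a remaining SCC.
#'
#' If cycles survive all three rules, `fallback` decides: `"error"` lists the
#' surviving cycles, `"clipper"` delegates the residual graph to
#' [clipper_reconstruct()].
#'
#' @param g A `pathway_graph` with compartment annotations (`unknown`
#'   allowed, but such edges never match R1/R2).
#' @param fallback `"error"` (default) or `"clipper"`.
#' @param expr,condition Passed to [clipper_reconstruct()] when
#'   `fallback = "clipper"`.
#' @return A `bn_reconstruction` with `strategy = "bnrich"`; removed edges
#'   carry their rule id (`self_loop`, `R1`, `R2`, `R3`, `fallback_clipper`)
#'   as the reason code.
#' @export
bnrich_rules <- function(g, fallback = c("error", "clipper"), expr = NULL,
                         condition = "non_tumor") {
  fallback <- match.arg(fallback)
  sl <- remove_self_loops(g)
  cur <- sl$graph
  comp <- setNames(g$nodes$compartment, g$nodes$id)
  rank_of <- function(ids) unname(COMPARTMENT_RANK[comp[ids]])
  removed <- removed_tbl(sl$removed, "self_loop")

  rules <- list(
    R1 = function(e) {
      rs <- rank_of(e$source); rt <- rank_of(e$target)
      !is.na(rs) & !is.na(rt) & rs > rt
    },
    R2 = function(e) {
      rs <- rank_of(e$source); rt <- rank_of(e$target)
      e$interaction %in% c("expression", "state_transition") &
        comp[e$source] == "nucleus" & !is.na(rt) & rt < COMPARTMENT_RANK[["nucleus"]]
    },
    R3 = function(e) e$interaction == "inhibition"
  )
  for (rid in names(rules)) {
    sccs <- nontrivial_sccs(cur)
    in_scc <- rep(FALSE, nrow(cur$edges))
    for (m in sccs) {
      in_scc <- in_scc | (cur$edges$source %in% m & cur$edges$target %in% m)
    }
    if (!any(in_scc)) break
    hit <- in_scc & rules[[rid]](cur$edges)
    if (any(hit)) {
      removed <- dplyr::bind_rows(removed, removed_tbl(cur$edges[hit, ], rid))
      cur$edges <- cur$edges[!hit, ]
    }
  }
  if (!is_acyclic(cur)) {
    if (fallback == "error") {
      cr <- find_sccs(cur, max_cycles = 5L)
      cyc <- vapply(head(cr$simple_cycles, 5),
                    function(cy) paste(c(cy, cy[1]), collapse = "->"), "")
      stop("cycles survive the rule stage: ", paste(cyc, collapse = "; "),
           " (use fallback = \"clipper\" or annotate compartments)")
    }
    if (is.null(expr)) stop("fallback = \"clipper\" requires expression data")
    sub <- clipper_reconstruct(cur, expr, condition = condition)
    cur <- sub$dag
    resid <- sub$removed[sub$removed$reason != "self_loop", ]
    if (nrow(resid) > 0) {
      resid$reason <- "fallback_clipper"
      removed <- dplyr::bind_rows(removed, resid)
    }
  }
  new_reconstruction("bnrich", cur, removed)
}

#' LASSO edge simplification (BNrich-style, shrinkage stage)
#'
#' Simplifies an already-acyclic pathway graph by L1-penalised regression.
#' For every child node one LASSO fit per condition is made with all parents
#' as predictors; the penalty is chosen per fit by K-fold cross-validation
#' using the one-standard-error rule anchored at the minimal mean squared
#' error (the largest penalty within 1 SE of the CV minimum, the standard
#' parsimony convention). An edge is removed only when its coefficient
#' is shrunk exactly to zero in *both* the tumor and the control fit — a
#' relationship present in either condition is kept. Removal only: the
#' result stays acyclic.
#'
#' @param dag An acyclic `pathway_graph`.
#' @param expr Expression tibble containing both condition labels; training
#'   samples are used.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param split Split label (default `"train"`; `NULL` for all samples).
#' @return A `bn_reconstruction` with `strategy = "bnrich"`; removed edges
#'   have reason `"lasso_zero"`.
#' @export
bnrich_lasso_simplify <- function(dag, expr, nfolds = 5, seed = 1L,
                                  split = "train") {
  stopifnot(is_acyclic(dag))
  conds <- unique(expr$condition)
  if (length(conds) < 2) stop("LASSO stage needs both condition labels")
  sub <- expr_subset(expr, NULL, split)
  if (nrow(sub) == 0) sub <- expr
  genes <- expression_genes(sub)
  missing <- setdiff(dag$nodes$id, genes)
  if (length(missing) > 0) {
    stop("gene(s) absent from expression data: ",
         paste(head(missing, 5), collapse = ", "))
  }
  drop_keys <- character()
  children <- unique(dag$edges$target)
  for (child in children) {
    parents <- dag$edges$source[dag$edges$target == child]
    zero_in <- rep(TRUE, length(parents))
    names(zero_in) <- parents
    for (cond in conds) {
      dat <- sub[sub$condition == cond, ]
      y <- dat[[child]]
      X <- as.matrix(dat[, parents, drop = FALSE])
      ok <- apply(X, 2, sd) > 0
      if (any(!ok)) {
        warning("zero-variance parent(s) of '", child, "'; edge(s) retained")
        zero_in[!ok] <- FALSE
      }
      if (sum(ok) == 0) next
      foldid <- withr::with_seed(
        derive_seed(seed, paste0(child, cond)),
        sample(rep_len(seq_len(nfolds), nrow(X))))
      fit <- cd_lasso_cv(X[, ok, drop = FALSE], y, as.integer(foldid),
                         100L, 1e-4)
      zero_in[ok] <- zero_in[ok] & (fit$coef == 0)
    }
    if (any(zero_in)) {
      drop_keys <- c(drop_keys,
                     paste(names(zero_in)[zero_in], child, sep = "\r"))
    }
  }
  keep <- !(edge_keys(dag$edges) %in% drop_keys)
  out <- dag
  out$edges <- dag$edges[keep, ]
  removed <- removed_tbl(dag$edges[!keep, ], "lasso_zero")
  new_reconstruction("bnrich", out, removed)
}

#' Full BNrich-style reconstruction (rules then LASSO)
#'
#' Convenience wrapper running [bnrich_rules()] followed by
#' [bnrich_lasso_simplify()] and merging the removal ledgers.
#'
#' @inheritParams bnrich_rules
#' @inheritParams bnrich_lasso_simplify
#' @return A `bn_reconstruction` with `strategy = "bnrich"`.
#' @export
bnrich_reconstruct <- function(g, expr, fallback = c("error", "clipper"),
                               condition = "non_tumor", nfolds = 5, seed = 1L) {
  stage1 <- bnrich_rules(g, fallback = fallback, expr = expr,
                         condition = condition)
  stage2 <- bnrich_lasso_simplify(stage1$dag, expr, nfolds = nfolds, seed = seed)
  new_reconstruction("bnrich", stage2$dag,
                     dplyr::bind_rows(stage1$removed, stage2$removed))
}
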