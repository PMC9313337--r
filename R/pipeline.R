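#' Run a reconstruction strategy by name
#'
#' Thin dispatcher used by [run_pipeline()] and the comparison reports.
#'
#' @param strategy One of `"props"`, `"clipper"`, `"bnrich"`, `"bpa"`,
#'   `"ensemble"`.
#' @param g A `pathway_graph`.
#' @param expr Expression tibble (required for clipper and bnrich).
#' @param seed Integer seed (used by the stochastic strategies).
#' @param condition Control-condition label for the data-driven strategies.
#' @param bnrich_fallback Fallback for [bnrich_rules()] residual cycles.
#' @return A `bn_reconstruction`.
#' @export
reconstruct_dag <- function(strategy, g, expr = NULL, seed = 1L,
                            condition = "non_tumor",
                            bnrich_fallback = "clipper") {
  strategy <- match.arg(strategy, STRATEGIES)
  switch(strategy,
    props = props_reconstruct(g, seed = seed),
    bpa = bpa_reconstruct(g, seed = seed),
    ensemble = ensemble_reconstruct(g, seed = seed),
    clipper = {
      if (is.null(expr)) stop("clipper requires expression data")
      clipper_reconstruct(g, expr, condition = condition)
    },
    bnrich = {
      if (is.null(expr)) stop("bnrich requires expression data")
      bnrich_reconstruct(g, expr, fallback = bnrich_fallback,
                         condition = condition, seed = seed)
    })
}

#' Reconstruction accounting report
#'
#' Per-strategy edge bookkeeping (self-loop removals, cycle-driven removals,
#' additions, percent edge loss relative to the original edge count) plus
#' pairwise comparisons: Jaccard overlap of the removed sets, of the kept
#' original edges, and of the full reconstructed edge sets including added
#' edges (`dag_jaccard`, the superimposition analysis for strategies that
#' rewire rather than only delete).
#'
#' @param results List of `bn_reconstruction` objects for the same original
#'   graph; names default to strategies.
#' @param original The original `pathway_graph`.
#' @return An object of class `reconstruction_report`: list of tibbles
#'   `per_strategy` and `pairwise`.
#' @export
reconstruction_report <- function(results, original) {
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- vapply(results, function(r) r$strategy, "")
  }
  n_orig <- nrow(original$edges)
  orig_keys <- edge_keys(original$edges)
  for (r in results) {
    rr <- r$removed
    known <- c(edge_keys(r$dag$edges[r$dag$edges$provenance == "original", ]),
               paste(rr$source, rr$target, sep = "\r"))
    if (!setequal(known, orig_keys)) {
      stop("result for strategy '", r$strategy,
           "' does not derive from the given original graph")
    }
  }
  per_strategy <- purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(
      strategy = nm,
      n_original = n_orig,
      n_self_loop = sum(r$removed$reason == "self_loop"),
      n_cycle_removed = sum(r$removed$reason != "self_loop"),
      n_added = nrow(r$added),
      n_kept = nrow(r$dag$edges),
      pct_loss = 100 * nrow(r$removed) / n_orig)
  })
  nms <- names(results)
  pairs <- if (length(nms) >= 2) t(combn(nms, 2)) else matrix(character(), 0, 2)
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(1)
    length(intersect(a, b)) / u
  }
  pairwise <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- results[[pairs[i, 1]]]
    b <- results[[pairs[i, 2]]]
    rem_a <- paste(a$removed$source, a$removed$target, sep = "\r")
    rem_b <- paste(b$removed$source, b$removed$target, sep = "\r")
    kept_a <- edge_keys(a$dag$edges[a$dag$edges$provenance == "original", ])
    kept_b <- edge_keys(b$dag$edges[b$dag$edges$provenance == "original", ])
    tibble::tibble(strategy_a = pairs[i, 1], strategy_b = pairs[i, 2],
                   removed_jaccard = jaccard(rem_a, rem_b),
                   kept_jaccard = jaccard(kept_a, kept_b),
                   dag_jaccard = jaccard(edge_keys(a$dag$edges),
                                         edge_keys(b$dag$edges)))
  })
  structure(list(per_strategy = per_strategy, pairwise = pairwise),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("<reconstruction_report>\n")
  print(x$per_strategy)
  if (nrow(x$pairwise) > 0) print(x$pairwise)
  invisible(x)
}

#' @export
tidy.reconstruction_report <- function(x, ...) x$per_strategy

default_config <- function() {
  list(strategies = STRATEGIES, seed = 1L, repeats = 10, fraction = 0.75,
       n_pathways = 6, n_nodes = 12, n_extra_cycle_edges = 3, n_pairs = 60,
       n_perturb = 3, delta = 1.5, perturb_pathway = 1,
       ntree_grid = c(200, 500), mtry_grid = NULL, lasso_folds = 5,
       grid_search = FALSE, ntree = 500, mtry = NULL)
}

#' Run the full comparison pipeline on synthetic data
#'
#' End-to-end orchestration of the study design: simulate a universe of
#' cyclic pathways in which one pathway is perturbed in the tumor condition,
#' reconstruct each pathway with every requested strategy, fit a Gaussian BN
#' per (strategy, pathway) on control training samples, build the pathway
#' log-likelihood feature table, classify tumor vs control with the Random
#' Forest, and rank pathways by importance. All artifacts (per-strategy
#' enrichment JSON, reconstruction report TSV, ranking comparison TSV, BIC
#' rank TSV, seed log) are written under `out_dir`; identical configuration
#' and seed give identical outputs.
#'
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param config Named list overriding the defaults: `strategies`, `seed`,
#'   `repeats`, `fraction`, `n_pathways`, `n_nodes`, `n_extra_cycle_edges`,
#'   `n_pairs`, `n_perturb`, `delta` (perturbation size; 0 = null scenario),
#'   `perturb_pathway` (index of the perturbed pathway, NA = none),
#'   `ntree`, `mtry`, `grid_search`, `ntree_grid`, `mtry_grid`,
#'   `lasso_folds`.
#' @return List with `scenarios`, `reconstructions`, `report`, `bns`,
#'   `features`, `enrichment` (per strategy), `comparison`, `bic_ranks`,
#'   `config`.
#' @export
run_pipeline <- function(out_dir = NULL, config = list()) {
  cfg <- modifyList(default_config(), config)
  stopifnot(cfg$fraction > 0, cfg$fraction < 1, cfg$repeats >= 1)
  cfg$strategies <- match.arg(cfg$strategies, STRATEGIES, several.ok = TRUE)

  # -- simulate ---------------------------------------------------------------
  scenarios <- lapply(seq_len(cfg$n_pathways), function(i) {
    gen_scenario(
      n_nodes = cfg$n_nodes, n_extra_cycle_edges = cfg$n_extra_cycle_edges,
      n_pairs = cfg$n_pairs, n_perturb = cfg$n_perturb,
      delta = if (!is.na(cfg$perturb_pathway) && i == cfg$perturb_pathway)
        cfg$delta else 0,
      seed = derive_seed(cfg$seed, paste0("scenario", i)),
      name = sprintf("pw%02d", i))
  })
  names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  exprs <- lapply(scenarios, gen_expression)
  # one shared sample frame: gene columns get a pathway prefix
  merged <- exprs[[1]][, EXPR_META]
  for (nm in names(exprs)) {
    genes <- expression_genes(exprs[[nm]])
    block <- exprs[[nm]][, genes]
    names(block) <- paste0(nm, ".", genes)
    merged <- dplyr::bind_cols(merged, block)
  }

  prefixed <- function(g, nm) {  # rename graph genes to the merged columns
    g$nodes$id <- paste0(nm, ".", g$nodes$id)
    g$edges$source <- paste0(nm, ".", g$edges$source)
    g$edges$target <- paste0(nm, ".", g$edges$target)
    g
  }

  # -- reconstruct / fit / score ----------------------------------------------
  reconstructions <- list()
  bns <- list()
  bic_rows <- list()
  for (strategy in cfg$strategies) {
    reconstructions[[strategy]] <- list()
    strat_bns <- list()
    for (nm in names(scenarios)) {
      g <- prefixed(scenarios[[nm]]$observed, nm)
      rec <- reconstruct_dag(strategy, g, expr = merged,
                             seed = derive_seed(cfg$seed,
                                                paste0(strategy, nm)))
      reconstructions[[strategy]][[nm]] <- rec
      bn <- fit_gaussian_bn(rec$dag, merged)
      strat_bns[[nm]] <- bn
      bic_rows[[length(bic_rows) + 1]] <- tibble::tibble(
        strategy = strategy, pathway = nm,
        bic = bn_bic(bn, merged))
    }
    bns[[strategy]] <- strat_bns
  }

  # -- enrich -----------------------------------------------------------------
  # per repeat the split is redrawn and the BNs refitted on that split's
  # control training samples (run_enrichment), so test samples never leak
  # into network fitting; the grid search, if requested, uses the initial
  # split's out-of-bag AUC only to pick hyperparameters
  enrichment <- list()
  for (strategy in cfg$strategies) {
    hp <- if (isTRUE(cfg$grid_search)) {
      grid_search_rf(build_feature_table(bns[[strategy]], merged),
                     ntree_grid = cfg$ntree_grid, mtry_grid = cfg$mtry_grid,
                     seed = derive_seed(cfg$seed, paste0("grid", strategy)))
    } else {
      list(ntree = cfg$ntree,
           mtry = if (is.null(cfg$mtry))
             max(1, round(sqrt(cfg$n_pathways))) else cfg$mtry)
    }
    dags <- lapply(reconstructions[[strategy]], function(r) r$dag)
    enrichment[[strategy]] <- run_enrichment(
      dags, merged, ntree = hp$ntree, mtry = hp$mtry,
      seed = derive_seed(cfg$seed, paste0("rf", strategy)),
      repeats = cfg$repeats, fraction = cfg$fraction)
  }
  comparison <- compare_rankings(enrichment)
  bic_ranks <- rank_bic(dplyr::bind_rows(bic_rows))
  report <- NULL
  if (length(cfg$strategies) >= 1) {
    nm1 <- names(scenarios)[1]
    report <- reconstruction_report(
      lapply(reconstructions, function(rs) rs[[nm1]]),
      prefixed(scenarios[[nm1]]$observed, nm1))
  }

  out <- list(scenarios = scenarios, reconstructions = reconstructions,
              report = report, bns = bns, features = NULL,
              enrichment = enrichment, comparison = comparison,
              bic_ranks = bic_ranks, config = cfg)

  # -- write artifacts --------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (strategy in names(enrichment)) {
      res <- enrichment[[strategy]]
      jsonlite::write_json(
        list(strategy = strategy,
             metrics = glance(res),
             per_repeat = res$metrics,
             importance = res$importance,
             hyperparams = res$hyperparams),
        file.path(out_dir, paste0("enrichment_", strategy, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    readr::write_tsv(report$per_strategy,
                     file.path(out_dir, "reconstruction_report.tsv"),
                     progress = FALSE)
    readr::write_tsv(comparison$ranks,
                     file.path(out_dir, "ranking_comparison.tsv"),
                     progress = FALSE)
    readr::write_tsv(bic_ranks, file.path(out_dir, "bic_ranks.tsv"),
                     progress = FALSE)
    log <- c(sprintf("master_seed\t%d", cfg$seed),
             sprintf("strategy_seeds\t%s",
                     paste(vapply(cfg$strategies, function(s)
                       sprintf("%s=%d", s, derive_seed(cfg$seed, paste0("rf", s))),
                       ""), collapse = ",")))
    writeLines(log, file.path(out_dir, "run_log.tsv"))
  }
  out
}
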