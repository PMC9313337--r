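FEATURE_META <- c("sample", "pair", "condition", "split")

#' Build the pathway log-likelihood feature table
#'
#' For every sample and every pathway, the feature is the sample's
#' log-likelihood under that pathway's fitted Bayesian network. Because the
#' networks are trained only on control training samples, tumor samples —
#' whose regulatory relationships deviate from the control model — score
#' systematically lower, which is the signal the classifier exploits.
#'
#' @param bns Named list of `gaussian_bn` objects (names = pathway ids).
#' @param expr Expression tibble covering every gene of every network.
#' @return A tibble with columns `sample`, `pair`, `condition`, `split` and
#'   one numeric column per pathway.
#' @export
build_feature_table <- function(bns, expr) {
  stopifnot(length(bns) > 0, !is.null(names(bns)))
  out <- expr[, FEATURE_META]
  genes <- expression_genes(expr)
  for (pw in names(bns)) {
    missing <- setdiff(names(bns[[pw]]$params), genes)
    if (length(missing) > 0) {
      stop("pathway '", pw, "' needs gene(s) absent from expression data: ",
           paste(head(missing, 5), collapse = ", "))
    }
    out[[pw]] <- bn_loglik(bns[[pw]], expr)
  }
  out
}

feature_pathways <- function(ft) setdiff(names(ft), FEATURE_META)

# Split a feature/expression table's rows into train/test by pair id,
# keeping both members of a pair on the same side.
paired_split <- function(tbl, fraction = 0.75, seed = 1L) {
  pairs <- unique(tbl$pair)
  n_train <- round(length(pairs) * fraction)
  tr <- withr::with_seed(seed, sample(pairs, n_train))
  dplyr::mutate(tbl, split = ifelse(.data$pair %in% tr, "train", "test"))
}

rf_matrices <- function(ft, rows) {
  X <- as.matrix(ft[rows, feature_pathways(ft), drop = FALSE])
  y <- as.integer(ft$condition[rows] == "tumor")
  list(X = X, y = y)
}

#' Grid search for Random-Forest hyperparameters
#'
#' Evaluates every (ntree, mtry) cell by out-of-bag AUC on the training
#' rows and returns the best; ties prefer the smaller ntree, then the
#' smaller mtry.
#'
#' @param ft Feature table from [build_feature_table()].
#' @param ntree_grid,mtry_grid Candidate values. `mtry_grid` defaults to
#'   `sqrt(p)`, `p/3` and `p` (rounded, deduplicated) for p pathways.
#' @param seed Integer seed.
#' @return List with `ntree`, `mtry` and the search table (`grid`).
#' @export
grid_search_rf <- function(ft, ntree_grid = c(200, 500, 1000),
                           mtry_grid = NULL, seed = 1L) {
  p <- length(feature_pathways(ft))
  if (is.null(mtry_grid)) {
    mtry_grid <- sort(unique(pmax(1, round(c(sqrt(p), p / 3, p)))))
  }
  tr <- rf_matrices(ft, ft$split == "train")
  if (length(unique(tr$y)) < 2) stop("training split has a single class")
  grid <- tidyr::expand_grid(ntree = sort(ntree_grid), mtry = sort(mtry_grid))
  grid$oob_auc <- purrr::map2_dbl(grid$ntree, grid$mtry, function(nt, mt) {
    fit <- withr::with_seed(
      derive_seed(seed, paste0("grid", nt, "_", mt)),
      rf_fit_predict(tr$X, tr$y, tr$X[0, , drop = FALSE], nt, mt, 1L))
    ok <- !is.na(fit$oob_prob)
    auc_score(fit$oob_prob[ok], tr$y[ok])
  })
  best <- grid[order(-grid$oob_auc, grid$ntree, grid$mtry), ][1, ]
  list(ntree = best$ntree, mtry = best$mtry, grid = grid)
}

#' Train and evaluate the Random-Forest pathway classifier
#'
#' Repeats the published evaluation protocol: a paired 75/25 train/test split is
#' redrawn per repeat (both members of a tumor/control pair stay on the same
#' side), a forest is fitted on the training rows, test samples are scored,
#' the decision threshold is chosen to maximise the Matthews correlation
#' coefficient over midpoints of the sorted unique test scores, and
#' accuracy/precision/recall/F1 at that threshold plus threshold-free AUC
#' are recorded. Feature importances are mean decrease in Gini impurity,
#' averaged over repeats.
#'
#' @param ft Feature table from [build_feature_table()].
#' @param ntree,mtry Forest hyperparameters (see [grid_search_rf()]).
#' @param seed Master seed; repeat r uses a derived seed.
#' @param repeats Number of random splits (default 10).
#' @param fraction Training fraction (default 0.75).
#' @param resplit If `FALSE`, the table's own `split` column is used for
#'   every repeat instead of redrawing.
#' @return An object of class `enrichment_result`: list with `metrics`
#'   (tibble, one row per repeat), `importance` (tibble pathway/mdg/rank),
#'   `hyperparams` and `repeats`.
#' @export
train_eval_rf <- function(ft, ntree = 500, mtry = NULL, seed = 1L,
                          repeats = 10, fraction = 0.75, resplit = TRUE) {
  pw <- feature_pathways(ft)
  if (is.null(mtry)) mtry <- max(1, round(sqrt(length(pw))))
  metrics <- list()
  imp <- matrix(0, nrow = 0, ncol = length(pw), dimnames = list(NULL, pw))
  for (r in seq_len(repeats)) {
    tbl <- if (resplit) {
      paired_split(ft, fraction, seed = derive_seed(seed, paste0("split", r)))
    } else ft
    one <- eval_one_split(tbl, ntree, mtry,
                          seed = derive_seed(seed, paste0("rf", r)),
                          repeat_id = r)
    if (is.null(one)) next
    metrics[[length(metrics) + 1]] <- one$metrics
    imp <- rbind(imp, one$importance)
  }
  finish_enrichment(metrics, imp, pw, ntree, mtry, repeats)
}

# Fit/score one train/test split; NULL when a side is single-class.
eval_one_split <- function(tbl, ntree, mtry, seed, repeat_id) {
  tr <- rf_matrices(tbl, tbl$split == "train")
  te <- rf_matrices(tbl, tbl$split == "test")
  if (length(unique(te$y)) < 2 || length(unique(tr$y)) < 2) {
    warning("repeat ", repeat_id, " skipped: single-class train or test fold")
    return(NULL)
  }
  fit <- withr::with_seed(
    seed,
    rf_fit_predict(tr$X, tr$y, te$X, as.integer(ntree), as.integer(mtry), 1L))
  th <- mcc_threshold(fit$test_prob, te$y)
  list(metrics = tibble::tibble(
         repeat_id = repeat_id, accuracy = th$accuracy,
         precision = th$precision, recall = th$recall, f1 = th$f1,
         auc = auc_score(fit$test_prob, te$y),
         threshold = th$threshold, mcc = th$mcc),
       importance = as.numeric(fit$importance))
}

finish_enrichment <- function(metrics, imp, pw, ntree, mtry, repeats) {
  if (length(metrics) == 0) stop("every repeat was degenerate")
  importance <- tibble::tibble(pathway = pw, mdg = colMeans(imp)) |>
    dplyr::arrange(dplyr::desc(.data$mdg)) |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$mdg)))
  structure(list(metrics = dplyr::bind_rows(metrics),
                 importance = importance,
                 hyperparams = list(ntree = ntree, mtry = mtry),
                 repeats = repeats),
            class = "enrichment_result")
}

#' Leak-free repeated enrichment over fresh splits
#'
#' The full per-split protocol: for every repeat a fresh paired 75/25 split
#' is drawn, the Bayesian networks are refitted on that split's control
#' training samples only, the feature table is rebuilt, and the forest is
#' trained and evaluated. Unlike [train_eval_rf()] on a fixed feature table,
#' no test sample of any repeat was ever seen during that repeat's network
#' fitting, so a null scenario scores at chance.
#'
#' @param dags Named list of acyclic `pathway_graph` objects (pathways).
#' @param expr Expression tibble covering all pathway genes.
#' @param ntree,mtry Forest hyperparameters.
#' @param seed Master seed.
#' @param repeats Number of random splits (default 10).
#' @param fraction Training fraction (default 0.75).
#' @param condition Control condition label used for network fitting.
#' @return An `enrichment_result`.
#' @export
run_enrichment <- function(dags, expr, ntree = 500, mtry = NULL, seed = 1L,
                           repeats = 10, fraction = 0.75,
                           condition = "non_tumor") {
  stopifnot(length(dags) > 0, !is.null(names(dags)))
  pw <- names(dags)
  if (is.null(mtry)) mtry <- max(1, round(sqrt(length(pw))))
  metrics <- list()
  imp <- matrix(0, nrow = 0, ncol = length(pw), dimnames = list(NULL, pw))
  for (r in seq_len(repeats)) {
    expr_r <- resplit_expression(expr, fraction,
                                 seed = derive_seed(seed, paste0("split", r)))
    bns <- lapply(dags, fit_gaussian_bn, expr = expr_r, condition = condition)
    ft <- build_feature_table(bns, expr_r)
    one <- eval_one_split(ft, ntree, mtry,
                          seed = derive_seed(seed, paste0("rf", r)),
                          repeat_id = r)
    if (is.null(one)) next
    metrics[[length(metrics) + 1]] <- one$metrics
    imp <- rbind(imp, one$importance)
  }
  finish_enrichment(metrics, imp, pw, ntree, mtry, repeats)
}

#' @export
print.enrichment_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<enrichment_result> %d repeat(s); AUC %.3f +/- %.3f; top pathway: %s\n",
    nrow(x$metrics), g$auc_mean, g$auc_sd, x$importance$pathway[1]))
  invisible(x)
}

#' Tidy / summarise an enrichment result
#'
#' `tidy()` returns the per-pathway importance table (mean decrease Gini and
#' rank); `glance()` returns one row of mean +/- sd classification metrics
#' over the repeats.
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.enrichment_result <- function(x, ...) x$importance

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_repeats = nrow(m),
    accuracy_mean = mean(m$accuracy), accuracy_sd = sd(m$accuracy),
    precision_mean = mean(m$precision), precision_sd = sd(m$precision),
    recall_mean = mean(m$recall), recall_sd = sd(m$recall),
    f1_mean = mean(m$f1), f1_sd = sd(m$f1),
    auc_mean = mean(m$auc), auc_sd = sd(m$auc),
    ntree = x$hyperparams$ntree, mtry = x$hyperparams$mtry)
}

#' Rank pathways by importance
#'
#' Dense ranks by descending mean-decrease-Gini importance (rank 1 = most
#' important for separating tumor from control).
#'
#' @param result An `enrichment_result`.
#' @return Tibble with columns `pathway`, `mdg`, `rank`.
#' @export
rank_pathways <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  result$importance
}

#' Compare pathway rankings across reconstruction strategies
#'
#' @param results Named list of `enrichment_result` objects (names =
#'   strategies) over the same pathway universe.
#' @return List with `ranks` (long tibble: pathway, strategy, rank, mdg —
#'   bump-chart data) and `spearman` (tibble of pairwise Spearman rank
#'   correlations between strategies).
#' @export
compare_rankings <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  sets <- lapply(results, function(r) sort(r$importance$pathway))
  if (length(unique(lapply(sets, paste, collapse = "|"))) != 1) {
    stop("strategies rank different pathway sets")
  }
  ranks <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::mutate(r$importance, strategy = nm, .before = 1)
  })
  nms <- names(results)
  pairs <- if (length(nms) >= 2) t(combn(nms, 2)) else matrix(character(), 0, 2)
  spearman <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- results[[pairs[i, 1]]]$importance
    b <- results[[pairs[i, 2]]]$importance
    b <- b[match(a$pathway, b$pathway), ]
    tibble::tibble(strategy_a = pairs[i, 1], strategy_b = pairs[i, 2],
                   spearman = cor(a$mdg, b$mdg, method = "spearman"))
  })
  list(ranks = ranks, spearman = spearman)
}
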