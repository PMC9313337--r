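# Expression tables are plain tibbles with four metadata columns
# (sample, pair, condition, split) followed by one numeric column per gene.
EXPR_META <- c("sample", "pair", "condition", "split")

#' Gene columns of an expression table
#' @param expr Expression tibble (see [read_expression()]).
#' @return Character vector of gene ids.
#' @export
expression_genes <- function(expr) setdiff(names(expr), EXPR_META)

validate_expression <- function(expr) {
  stopifnot(all(EXPR_META %in% names(expr)))
  genes <- expression_genes(expr)
  bad <- genes[!vapply(expr[genes], is.numeric, TRUE)]
  if (length(bad) > 0) {
    stop("non-numeric expression column(s): ", paste(head(bad, 3), collapse = ", "))
  }
  if (anyNA(expr[genes])) stop("expression table contains missing values")
  tab <- table(expr$pair)
  if (nrow(expr) > 0 && any(tab != 2)) {
    stop("each pair id must appear exactly twice (one sample per condition)")
  }
  invisible(expr)
}

# Subset helper: condition/split filters, NULL = keep all.
expr_subset <- function(expr, condition = NULL, split = NULL) {
  if (!is.null(condition)) expr <- expr[expr$condition %in% condition, ]
  if (!is.null(split)) expr <- expr[expr$split %in% split, ]
  expr
}

#' Read / write an expression table
#'
#' TSV with columns `sample`, `pair`, `condition`, `split` followed by one
#' numeric column per gene; values are on a log2(n+1)-like scale. Round-trips
#' exactly (up to floating-point text representation).
#'
#' @param path File path.
#' @return `read_expression()` returns the expression tibble.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(EXPR_META, names(df))
  if (length(missing) > 0) {
    stop("expression file missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(EXPR_META), as.character))
  genes <- expression_genes(df)
  for (gcol in genes) {
    if (nrow(df) == 0) {
      df[[gcol]] <- double()
      next
    }
    if (!is.numeric(df[[gcol]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[gcol]]))))[1]
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   bad, gcol))
    }
  }
  validate_expression(df)
}

#' @rdname read_expression
#' @param expr Expression tibble.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Per-gene permutation shuffle control
#'
#' Independently permutes each gene's values across all samples, leaving
#' labels, pairs and splits untouched. Marginal distributions are preserved
#' exactly while all gene-gene and gene-label associations are destroyed —
#' the negative control used to show that data-driven reconstruction reacts
#' to real co-expression structure.
#'
#' @param expr Expression tibble.
#' @param seed Integer seed.
#' @return The shuffled expression tibble.
#' @export
shuffle_expression <- function(expr, seed = 1L) {
  genes <- expression_genes(expr)
  n <- nrow(expr)
  withr::with_seed(seed, {
    for (gcol in genes) {
      expr[[gcol]] <- expr[[gcol]][sample.int(n)]
    }
  })
  expr
}
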