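#' @useDynLib pathwaybn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats coef cor dnorm pnorm pt rnorm runif sd setNames var
#' @importFrom utils combn head modifyList
"_PACKAGE"

COMPARTMENTS <- c("extracellular", "membrane", "cytoplasm", "nucleus", "unknown")
INTERACTIONS <- c("activation", "inhibition", "binding", "expression",
                  "state_transition", "unknown")

#' Construct a pathway graph
#'
#' A pathway graph is a directed, possibly cyclic gene-regulatory network:
#' a node table (gene id plus subcellular compartment) and an ordered edge
#' table (source, target, interaction class, provenance). Edge order is
#' stable and defines default tie-breaking throughout the package.
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `interaction` (activation, inhibition, binding, expression,
#'   state_transition, unknown) and `provenance` (original/added).
#' @param nodes Optional data frame with columns `id` and `compartment`
#'   (extracellular, membrane, cytoplasm, nucleus, unknown). Nodes appearing
#'   only in `edges` are induced with compartment `"unknown"`.
#' @param name Graph name.
#' @return An object of class `pathway_graph` with tibble components `nodes`
#'   and `edges`.
#' @export
pathway_graph <- function(edges, nodes = NULL, name = "pathway") {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0 && !all(c("source", "target") %in% names(edges))) {
    edges <- tibble::tibble(source = character(), target = character())
  }
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (!"interaction" %in% names(edges)) edges$interaction <- "unknown"
  if (!"provenance" %in% names(edges)) edges$provenance <- "original"
  edges <- dplyr::mutate(edges,
    source = as.character(.data$source),
    target = as.character(.data$target),
    interaction = ifelse(is.na(.data$interaction) | .data$interaction == "",
                         "unknown", as.character(.data$interaction)),
    provenance = as.character(.data$provenance)
  )
  edges <- edges[, c("source", "target", "interaction", "provenance")]
  bad <- setdiff(unique(edges$interaction), INTERACTIONS)
  if (length(bad) > 0) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  }
  dup <- duplicated(edges[, c("source", "target")])
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed to first occurrence")
    edges <- edges[!dup, ]
  }
  ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = ids, compartment = "unknown")
  } else {
    nodes <- tibble::as_tibble(nodes)
    stopifnot("id" %in% names(nodes))
    if (!"compartment" %in% names(nodes)) nodes$compartment <- "unknown"
    nodes <- dplyr::mutate(nodes,
      id = as.character(.data$id),
      compartment = ifelse(is.na(.data$compartment), "unknown",
                           as.character(.data$compartment)))
    nodes <- nodes[!duplicated(nodes$id), c("id", "compartment")]
    missing <- setdiff(ids, nodes$id)
    if (length(missing) > 0) {
      nodes <- dplyr::bind_rows(
        nodes, tibble::tibble(id = missing, compartment = "unknown"))
    }
  }
  bad <- setdiff(unique(nodes$compartment), COMPARTMENTS)
  if (length(bad) > 0) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges (%d added)\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$provenance == "added")))
  invisible(x)
}

#' @export
format.pathway_graph <- function(x, ...) {
  sprintf("<pathway_graph> %s: %d nodes, %d edges",
          x$name, nrow(x$nodes), nrow(x$edges))
}

#' Number of nodes / edges
#' @param g A `pathway_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

edge_keys <- function(edges) paste(edges$source, edges$target, sep = "\r")

#' Convert a pathway graph to an igraph object
#'
#' Node and edge annotations are carried as igraph attributes.
#'
#' @param g A `pathway_graph`.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(g$edges), directed = TRUE,
    vertices = as.data.frame(g$nodes))
  ig
}

#' Read a pathway graph from an edge-list TSV
#'
#' The native exchange format: a tab-separated file with header columns
#' `source`, `target` and optionally `interaction`, `source_compartment`,
#' `target_compartment`. Nodes are induced from edge endpoints; an optional
#' node table can supply compartments for isolated genes.
#'
#' @param path Path to the edge-list TSV.
#' @param node_path Optional path to a node-table TSV with columns `id`,
#'   `compartment`.
#' @param name Graph name; defaults to the file stem.
#' @return A `pathway_graph`.
#' @export
read_edgelist <- function(path, node_path = NULL, name = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("source", "target") %in% names(df))) {
    stop("edge-list file must have 'source' and 'target' columns: ", path)
  }
  nodes <- NULL
  if (all(c("source_compartment", "target_compartment") %in% names(df)) &&
      nrow(df) > 0) {
    nodes <- dplyr::bind_rows(
      tibble::tibble(id = df$source, compartment = df$source_compartment),
      tibble::tibble(id = df$target, compartment = df$target_compartment))
    nodes <- nodes[!duplicated(nodes$id), ]
  }
  if (!is.null(node_path)) {
    nt <- readr::read_tsv(node_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    stopifnot("id" %in% names(nt))
    nodes <- dplyr::bind_rows(tibble::as_tibble(nt),
                              if (is.null(nodes)) NULL else nodes)
    nodes <- nodes[!duplicated(nodes$id), ]
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pathway_graph(df[, intersect(c("source", "target", "interaction"), names(df))],
                nodes = nodes, name = name)
}

#' Write a pathway graph
#'
#' `write_edgelist()` writes the native edge-list TSV (round-trips through
#' [read_edgelist()] up to edge order); `write_graphml()` exports GraphML with
#' node attribute `compartment` and edge attributes `interaction`,
#' `provenance`.
#'
#' @param g A `pathway_graph`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edgelist <- function(g, path) {
  comp <- setNames(g$nodes$compartment, g$nodes$id)
  out <- dplyr::mutate(g$edges,
                       source_compartment = unname(comp[.data$source]),
                       target_compartment = unname(comp[.data$target]))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' The seven-gene worked-example network
#'
#' A hypothetical gene network of 7 nodes and 9 edges containing three
#' directed cycles (\{A,B,D\}, \{A,C,D\} and \{D,E\}), used throughout the
#' package as the canonical small fixture. Edges are numbered 1-9 in their
#' stored order: 1 A->C, 2 A->B, 3 D->A, 4 B->D, 5 C->D, 6 E->D, 7 D->E,
#' 8 E->F, 9 E->G. Compartments are annotated so that the two feedback edges
#' (3: D->A, 6: E->D) run against the membrane-to-nucleus signalling axis and
#' are exactly the ones removed by [bnrich_rules()].
#'
#' @return A `pathway_graph`.
#' @export
fixture_fig2 <- function() {
  edges <- tibble::tribble(
    ~source, ~target, ~interaction,
    "A", "C", "activation",
    "A", "B", "activation",
    "D", "A", "inhibition",
    "B", "D", "activation",
    "C", "D", "activation",
    "E", "D", "inhibition",
    "D", "E", "activation",
    "E", "F", "activation",
    "E", "G", "expression"
  )
  nodes <- tibble::tribble(
    ~id, ~compartment,
    "A", "membrane",
    "B", "cytoplasm",
    "C", "cytoplasm",
    "D", "cytoplasm",
    "E", "nucleus",
    "F", "unknown",
    "G", "unknown"
  )
  pathway_graph(edges, nodes, name = "fig2_example")
}

#' Remove self-loop edges
#'
#' Self-loops (edges with identical endpoints) cannot appear in a Bayesian
#' network and are stripped before every reconstruction strategy.
#'
#' @param g A `pathway_graph`.
#' @return A list with elements `graph` (self-loop-free `pathway_graph`) and
#'   `removed` (tibble of the dropped edges).
#' @export
remove_self_loops <- function(g) {
  loop <- g$edges$source == g$edges$target
  out <- g
  out$edges <- g$edges[!loop, ]
  list(graph = out, removed = g$edges[loop, ])
}

#' Is the graph acyclic?
#'
#' @param g A `pathway_graph`.
#' @return Logical scalar; self-loops count as cycles.
#' @export
is_acyclic <- function(g) {
  if (any(g$edges$source == g$edges$target)) return(FALSE)
  if (nrow(g$edges) == 0) return(TRUE)
  igraph::is_dag(as_igraph(g))
}

# Adjacency list (targets per source) for fast reachability on small graphs.
adjacency_list <- function(edges, nodes) {
  adj <- split(edges$target, factor(edges$source, levels = nodes))
  lapply(adj, as.character)
}

# TRUE iff `to` is reachable from `from` in the adjacency list.
reaches <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- new.env(parent = emptyenv())
  stack <- from
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (w == to) return(TRUE)
      if (is.null(seen[[w]])) {
        seen[[w]] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

#' Would adding an edge create a cycle?
#'
#' For an acyclic graph `g`, adding source -> target creates a cycle iff a
#' directed path target -> source already exists.
#'
#' @param g An acyclic `pathway_graph`.
#' @param source,target Node ids of the candidate edge.
#' @return Logical scalar.
#' @export
would_create_cycle <- function(g, source, target) {
  if (!is_acyclic(g)) {
    stop("would_create_cycle() requires an acyclic graph")
  }
  if (source == target) return(TRUE)
  if (!(source %in% g$nodes$id) || !(target %in% g$nodes$id)) return(FALSE)
  adj <- adjacency_list(g$edges, g$nodes$id)
  reaches(adj, target, source)
}

#' Strongly connected components and simple cycles
#'
#' Computes the nontrivial strongly connected components (two or more nodes,
#' or a single node with a self-loop) and enumerates every simple directed
#' cycle with a Johnson-style search. Each cycle is reported once, rotated to
#' start at its lexicographically smallest node; self-loops are listed
#' separately as length-1 cycles.
#'
#' @param g A `pathway_graph`.
#' @param max_cycles Safety cap on the number of enumerated cycles.
#' @return An object of class `cycle_report`: list with `scc_list` (list of
#'   character vectors, each sorted), `simple_cycles` (list of node-id
#'   sequences) and `self_loops` (tibble of self-loop edges).
#' @export
find_sccs <- function(g, max_cycles = 100000L) {
  self_loops <- g$edges[g$edges$source == g$edges$target, ]
  simple <- g$edges[g$edges$source != g$edges$target, ]
  nodes <- g$nodes$id
  scc_list <- list()
  if (nrow(simple) > 0) {
    ig <- igraph::graph_from_data_frame(as.data.frame(simple[, 1:2]),
                                        directed = TRUE,
                                        vertices = data.frame(id = nodes))
    comp <- igraph::components(ig, mode = "strong")
    memb <- split(names(comp$membership), comp$membership)
    scc_list <- Filter(function(m) length(m) >= 2, memb)
    scc_list <- lapply(scc_list, function(m) sort(m))
    # stable order: by smallest member
    if (length(scc_list) > 0) {
      scc_list <- scc_list[order(vapply(scc_list, `[`, "", 1))]
      names(scc_list) <- NULL
    }
  }
  loopers <- unique(self_loops$source)
  for (v in setdiff(loopers, unlist(scc_list))) {
    scc_list <- c(scc_list, list(v))
  }
  names(scc_list) <- NULL
  cycles <- enumerate_simple_cycles(simple, scc_list, max_cycles)
  structure(list(scc_list = scc_list, simple_cycles = cycles,
                 self_loops = self_loops),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> %d nontrivial SCC(s), %d simple cycle(s), %d self-loop(s)\n",
              length(x$scc_list), length(x$simple_cycles), nrow(x$self_loops)))
  invisible(x)
}

# Membership-only nontrivial SCC computation (no cycle enumeration); the
# workhorse for the reconstruction strategies, where enumerating simple
# cycles would be combinatorially explosive on dense components.
nontrivial_sccs <- function(g) {
  simple <- g$edges[g$edges$source != g$edges$target, ]
  out <- list()
  if (nrow(simple) > 0) {
    ig <- igraph::graph_from_data_frame(as.data.frame(simple[, 1:2]),
                                        directed = TRUE,
                                        vertices = data.frame(id = g$nodes$id))
    comp <- igraph::components(ig, mode = "strong")
    memb <- split(names(comp$membership), comp$membership)
    out <- Filter(function(m) length(m) >= 2, memb)
    out <- lapply(out, sort)
    if (length(out) > 0) out <- out[order(vapply(out, `[`, "", 1))]
    names(out) <- NULL
  }
  out
}

# Johnson-style simple-cycle enumeration restricted to each nontrivial SCC.
# Cycles are emitted in canonical rotation (start at lexicographically
# smallest node) and sorted for a deterministic report.
enumerate_simple_cycles <- function(edges, scc_list, max_cycles) {
  cycles <- list()
  multi <- Filter(function(m) length(m) >= 2, scc_list)
  for (members in multi) {
    sub <- edges[edges$source %in% members & edges$target %in% members, ]
    adj <- adjacency_list(sub, members)
    # DFS from each start node, only visiting nodes >= start (lexicographic)
    for (start in sort(members)) {
      stack_path <- character()
      res <- new.env(parent = emptyenv())
      dfs <- function(v) {
        if (length(cycles) >= max_cycles) return()
        stack_path <<- c(stack_path, v)
        for (w in adj[[v]]) {
          if (length(cycles) >= max_cycles) break
          if (w < start) next
          if (w == start) {
            cycles[[length(cycles) + 1L]] <<- stack_path
          } else if (!(w %in% stack_path)) {
            dfs(w)
          }
        }
        stack_path <<- stack_path[-length(stack_path)]
      }
      dfs(start)
    }
  }
  if (length(cycles) > 1) {
    key <- vapply(cycles, function(cy) paste(cy, collapse = "->"), "")
    cycles <- cycles[order(nchar(key), key)]
  }
  cycles
}

#' Graph equality up to edge order
#' @param a,b `pathway_graph` objects.
#' @return Logical scalar.
#' @export
graph_equal <- function(a, b) {
  na <- dplyr::arrange(a$nodes, .data$id)
  nb <- dplyr::arrange(b$nodes, .data$id)
  ea <- dplyr::arrange(a$edges, .data$source, .data$target)
  eb <- dplyr::arrange(b$edges, .data$source, .data$target)
  identical(as.data.frame(na), as.data.frame(nb)) &&
    identical(as.data.frame(ea), as.data.frame(eb))
}

#' Tidy a pathway graph into its edge table
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @return The edge tibble with compartments joined on.
#' @export
tidy.pathway_graph <- function(x, ...) {
  comp <- setNames(x$nodes$compartment, x$nodes$id)
  dplyr::mutate(x$edges,
                source_compartment = unname(comp[.data$source]),
                target_compartment = unname(comp[.data$target]))
}
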