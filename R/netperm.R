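#' Build a gene-interaction graph from an edge list
#'
#' Constructs an undirected simple graph: duplicate edges and reversed
#' duplicates are merged, self-loops dropped (their count is reported as an
#' attribute `n_loops_dropped`).
#'
#' @param edges two-column data frame or matrix of gene-id pairs.
#' @return an [igraph] undirected simple graph.
#' @export
build_graph <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2 || nrow(edges) == 0) {
    stopf("`edges` must be a non-empty two-column edge list")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  g <- igraph::graph_from_data_frame(data.frame(a[!loops], b[!loops]),
                                     directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "n_loops_dropped", sum(loops))
  g
}

#' Extract bridged candidate subnetworks from a global interaction graph
#'
#' Builds the subgraph induced by the mapped candidate genes plus every
#' *bridge* gene: a non-candidate adjacent to at least two mapped candidates
#' ("one missing gene in between"). Retained edges are candidate-candidate
#' and candidate-bridge edges of the global graph; bridge-bridge edges are
#' excluded, since a path through two consecutive non-candidates would
#' exceed the one-gene allowance. Connected components are returned with
#' isolated candidates kept as size-1 components.
#'
#' @param graph global interaction graph ([build_graph()]).
#' @param candidates character vector of candidate gene ids; ids absent from
#'   the graph are dropped (their count is reported).
#' @return list of class `subnetwork_set`:
#'   \describe{
#'     \item{components}{list of components, each with `nodes`, `candidate`
#'       (logical per node), `bridges`, `edges` (two-column matrix), `size`,
#'       `n_edges`.}
#'     \item{largest}{the winning component under the reporting tie-break
#'       (larger edge count, then lexicographically smallest node set).}
#'     \item{largest_size}{node count of the largest component.}
#'     \item{n_candidates_mapped}{candidates found in the graph.}
#'     \item{n_candidates_dropped}{candidates absent from the graph.}
#'   }
#' @export
bridged_subnetworks <- function(graph, candidates) {
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) stopf("`candidates` must be nonempty")
  vnames <- igraph::V(graph)$name
  mapped <- intersect(candidates, vnames)
  if (length(mapped) == 0) {
    stopf("no candidate gene maps to the interaction graph")
  }
  comp <- bridged_components_fast(graph, match(mapped, vnames))
  components <- lapply(comp$groups, function(grp) {
    nodes <- vnames[grp$nodes]
    is_cand <- grp$nodes %in% comp$cand_idx
    edges <- if (nrow(grp$edges)) {
      cbind(vnames[grp$edges[, 1]], vnames[grp$edges[, 2]])
    } else {
      matrix(character(), ncol = 2)
    }
    list(nodes = nodes, candidate = is_cand,
         bridges = nodes[!is_cand], edges = edges,
         size = length(nodes), n_edges = nrow(grp$edges))
  })
  sizes <- vapply(components, `[[`, numeric(1), "size")
  win <- pick_largest(components)
  structure(list(
    components = components,
    largest = components[[win]],
    largest_size = max(sizes),
    n_candidates_mapped = length(mapped),
    n_candidates_dropped = length(candidates) - length(mapped)
  ), class = "subnetwork_set")
}

# Core construction on integer vertex indices; shared with the permutation
# loop. Returns candidate indices and per-component node/edge index sets.
bridged_components_fast <- function(graph, cand_idx, prep = NULL) {
  if (is.null(prep)) prep <- prep_graph(graph)
  is_cand <- logical(prep$n)
  is_cand[cand_idx] <- TRUE
  # candidate-neighbour counts for every vertex
  cn <- tabulate(c(prep$el[is_cand[prep$el[, 2]], 1],
                   prep$el[is_cand[prep$el[, 1]], 2]), nbins = prep$n)
  is_bridge <- !is_cand & cn >= 2
  keep_edge <- (is_cand[prep$el[, 1]] | is_cand[prep$el[, 2]]) &
    (is_cand[prep$el[, 1]] | is_bridge[prep$el[, 1]]) &
    (is_cand[prep$el[, 2]] | is_bridge[prep$el[, 2]])
  el <- prep$el[keep_edge, , drop = FALSE]
  nodes <- sort(unique(c(cand_idx, as.vector(el))))
  comp_id <- union_find_components(nodes, el)
  groups <- lapply(split(seq_along(nodes), comp_id), function(ii) {
    nd <- nodes[ii]
    in_comp <- logical(prep$n)
    in_comp[nd] <- TRUE
    list(nodes = nd,
         edges = el[in_comp[el[, 1]] & in_comp[el[, 2]], , drop = FALSE])
  })
  list(groups = unname(groups), cand_idx = cand_idx)
}

prep_graph <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  list(n = igraph::vcount(graph), el = el)
}

# Union-find over the kept nodes; returns a component id per node.
union_find_components <- function(nodes, el) {
  idx <- integer(max(c(nodes, 1L)))
  idx[nodes] <- seq_along(nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      ra <- find(idx[el[e, 1]])
      rb <- find(idx[el[e, 2]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_along(nodes), find, integer(1))
}

# Reporting tie-break: size, then edge count, then smallest node set.
pick_largest <- function(components) {
  sizes <- vapply(components, `[[`, numeric(1), "size")
  top <- which(sizes == max(sizes))
  if (length(top) > 1) {
    ne <- vapply(components[top], `[[`, numeric(1), "n_edges")
    top <- top[ne == max(ne)]
    if (length(top) > 1) {
      keys <- vapply(components[top], function(cc) {
        paste(sort(cc$nodes), collapse = "|")
      }, character(1))
      top <- top[order(keys)]
    }
  }
  top[1]
}

#' Size of the largest bridged subnetwork
#'
#' @param subnetworks a `subnetwork_set` from [bridged_subnetworks()], or a
#'   bare list of components with `size` fields.
#' @return largest node count (candidates plus bridges).
#' @export
largest_size <- function(subnetworks) {
  comps <- if (inherits(subnetworks, "subnetwork_set")) {
    subnetworks$components
  } else {
    subnetworks
  }
  if (length(comps) == 0) stopf("no components supplied")
  max(vapply(comps, `[[`, numeric(1), "size"))
}

#' Permutation test for the largest bridged-subnetwork size
#'
#' Repeatedly samples `n` distinct genes uniformly from the graph's
#' mappable universe, rebuilds the bridged subnetworks, and records the
#' largest size. With `A` the number of permutations whose largest size is
#' greater than or equal to the observed size, the p-value is
#' `p = (A + 1) / (N_perm + 1)` (so 1000 permutations give the classic
#' (A + 1)/1001).
#'
#' @param graph global interaction graph.
#' @param n number of genes to draw per permutation (the number of mapped
#'   candidate genes).
#' @param observed_size observed largest subnetwork size.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for reproducibility.
#' @return list of class `perm_test`: `n`, `observed_size`, `n_perm`, `A`,
#'   `p_value`, `seed`, `perm_sizes` (all permutation statistics).
#' @export
permutation_test <- function(graph, n, observed_size, n_perm = 1000,
                             seed = 1L) {
  n_univ <- igraph::vcount(graph)
  if (!is_count(n) || n > n_univ) {
    stopf("`n` must be a positive count <= mappable universe (%d)", n_univ)
  }
  if (!is_count(n_perm)) stopf("`n_perm` must be >= 1")
  prep <- prep_graph(graph)
  sizes <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      cand <- sample.int(n_univ, n)
      comp <- bridged_components_fast(graph, cand, prep)
      max(vapply(comp$groups, function(g) length(g$nodes), numeric(1)))
    }, numeric(1))
  })
  A <- sum(sizes >= observed_size)
  structure(list(
    n = n, observed_size = observed_size, n_perm = n_perm, A = A,
    p_value = (A + 1) / (n_perm + 1), seed = as.integer(seed),
    perm_sizes = sizes
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> observed largest size %d with n = %d candidates: A = %d of %d permutations >= observed, p = (A+1)/(N+1) = %.4g\n",
              x$observed_size, x$n, x$A, x$n_perm, x$p_value))
  invisible(x)
}

#' Classify hub genes within a subnetwork component
#'
#' A gene is a hub when it has more than ten connections to other genes in
#' the network (degree >= 11); "non-hub" genes have ten or fewer.
#' Degrees are counted within the component by default; set
#' `scope = "global"` (and supply `graph`) to count connections in the
#' global interaction graph instead.
#'
#' @param component one component from [bridged_subnetworks()] (list with
#'   `nodes` and `edges`).
#' @param scope `"subnetwork"` (default) or `"global"`.
#' @param graph global graph, required for `scope = "global"`.
#' @param hub_threshold hub if degree strictly greater (default 10).
#' @return data frame: `gene_id`, `degree`, `hub`.
#' @export
classify_hubs <- function(component, scope = c("subnetwork", "global"),
                          graph = NULL, hub_threshold = 10) {
  scope <- match.arg(scope)
  nodes <- component$nodes
  if (length(nodes) == 0) stopf("component has no nodes")
  if (scope == "subnetwork") {
    deg <- stats::setNames(integer(length(nodes)), nodes)
    if (!is.null(component$edges) && nrow(component$edges)) {
      tab <- table(factor(c(component$edges[, 1], component$edges[, 2]),
                          levels = nodes))
      deg[names(tab)] <- as.integer(tab)
    }
  } else {
    if (is.null(graph)) stopf("global scope requires `graph`")
    deg <- igraph::degree(graph, v = nodes)
  }
  data.frame(gene_id = nodes, degree = as.integer(deg),
             hub = as.integer(deg) > hub_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
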