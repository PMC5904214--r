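# ---- deterministic graph helpers -------------------------------------------
# All tie-breaking in this module is lexicographic by node label: adjacency
# lists are sorted, BFS visits neighbours in sorted order, Kruskal sorts
# edges by (weight, node, node).  Outputs are therefore platform-independent.

ordered_adjacency <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  adj <- split(c(el[, 2], el[, 1]), factor(c(el[, 1], el[, 2]),
                                           levels = nodes))
  lapply(adj, function(v) sort(unique(v)))
}

# BFS shortest-path tree from `src`; parent of each node is the first
# (lexicographically smallest at its depth) neighbour that discovered it.
bfs_tree <- function(adj, src) {
  nodes <- names(adj)
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- character(length(nodes))
  queue[1] <- src
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (!is.finite(dist[[w]])) {
        dist[[w]] <- dist[[v]] + 1
        parent[[w]] <- v
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  list(parent = parent, dist = dist)
}

bfs_path <- function(tree, src, dst) {
  if (!is.finite(tree$dist[[dst]]))
    stop("no path to '", dst, "'")
  path <- dst
  while (path[1] != src) path <- c(tree$parent[[path[1]]], path)
  path
}

path_edges <- function(path) {
  if (length(path) < 2) return(NULL)
  cbind(path[-length(path)], path[-1])
}

normalize_edges <- function(el) {
  if (is.null(el) || nrow(el) == 0)
    return(matrix(character(), 0, 2))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- unique(el)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  dimnames(el) <- NULL
  el
}

# Kruskal MST with union-find; `edges` is a data frame with columns
# a, b, w, pre-sorted by (w, a, b).  Returns the row indices kept.
kruskal <- function(edges, nodes) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$a[i]); rb <- find(edges$b[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      keep[i] <- TRUE
    }
  }
  which(keep)
}

# Iteratively remove non-terminal leaves (pruning fixpoint).
prune_leaves <- function(el, terminals) {
  repeat {
    if (nrow(el) == 0) break
    deg <- table(c(el[, 1], el[, 2]))
    leaves <- setdiff(names(deg)[deg == 1], terminals)
    if (!length(leaves)) break
    el <- el[!(el[, 1] %in% leaves | el[, 2] %in% leaves), , drop = FALSE]
  }
  el
}

# ---- solution container ----------------------------------------------------

#' Steiner tree solutions
#'
#' A `SteinerSolution` records the extracted tree: its edges and nodes, the
#' terminals it was asked to connect, the imputed (Steiner) nodes — tree
#' nodes that are not terminals, interpreted as mediator genes — the cost
#' (edge count), the method used, and any terminals dropped because they
#' were absent from the network.  The constructor verifies the tree
#' invariant `|edges| = |nodes| - 1` with connectivity.
#'
#' @param tree_edges Two-column character matrix of undirected edges.
#' @param terminals Character vector of requested terminals found in the
#'   network.
#' @param method `"exact"` or `"heuristic"`.
#' @param dropped_terminals Terminals absent from the network.
#' @return An object of class `SteinerSolution`.
#' @export
steiner_solution <- function(tree_edges, terminals,
                             method = c("exact", "heuristic"),
                             dropped_terminals = character()) {
  method <- match.arg(method)
  tree_edges <- normalize_edges(tree_edges)
  tree_nodes <- sort(unique(c(as.vector(tree_edges), terminals)))
  if (nrow(tree_edges) != length(tree_nodes) - 1)
    stop("internal error: solution is not a tree (|E| != |V| - 1)")
  if (nrow(tree_edges) > 0) {
    g <- igraph::graph_from_edgelist(tree_edges, directed = FALSE)
    if (!igraph::is_connected(g))
      stop("internal error: solution is not connected")
  }
  structure(list(tree_edges = tree_edges,
                 tree_nodes = tree_nodes,
                 terminals = sort(terminals),
                 imputed_nodes = sort(setdiff(tree_nodes, terminals)),
                 cost = nrow(tree_edges),
                 method = method,
                 dropped_terminals = sort(dropped_terminals)),
            class = "SteinerSolution")
}

#' @export
print.SteinerSolution <- function(x, ...) {
  cat(sprintf("SteinerSolution (%s): cost %d, %d terminal(s), %d imputed\n",
              x$method, x$cost, length(x$terminals),
              length(x$imputed_nodes)))
  if (length(x$dropped_terminals))
    cat("  dropped terminals:",
        paste(x$dropped_terminals, collapse = ", "), "\n")
  invisible(x)
}

# Common front matter for both solvers: drop absent terminals with a
# warning, deduplicate, check mutual reachability.
prepare_terminals <- function(network, terminals) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop("network nodes must be named")
  terminals <- unique(as.character(terminals))
  dropped <- setdiff(terminals, nodes)
  if (length(dropped))
    warning(length(dropped), " terminal(s) absent from the network dropped: ",
            paste(head(dropped, 10), collapse = ", "))
  terms <- sort(intersect(terminals, nodes))
  if (!length(terms)) stop("no terminals present in the network")
  comp <- igraph::components(network)
  mem <- comp$membership[terms]
  if (length(unique(mem)) > 1) {
    tab <- split(terms, mem)
    main <- which.max(lengths(tab))
    stop("terminals lie in disconnected components; unreachable: ",
         paste(unlist(tab[-main]), collapse = ", "))
  }
  list(terms = terms, dropped = dropped)
}

# ---- operations ------------------------------------------------------------

#' Largest connected component
#'
#' Induced subgraph on the largest connected component; if several
#' components tie for size, the one containing the lexicographically
#' smallest node wins.
#'
#' @param network An `igraph` graph with named nodes.
#' @return The induced subgraph.
#' @export
largest_component <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty graph")
  comp <- igraph::components(network)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k)
      min(igraph::V(network)$name[comp$membership == k]), character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(network,
                           which(comp$membership == best))
}

#' Exact minimum Steiner tree (Dreyfus-Wagner)
#'
#' Dynamic program over terminal subsets: `S[D, v]` is the minimum edge
#' count of a tree spanning terminal subset `D` plus node `v`, built by
#' alternating subset merges at a node with shortest-path relaxations over
#' the hop-distance metric.  The returned cost is globally optimal.  The
#' `3^L * n` term keeps this desk-scale only for modest terminal counts,
#' hence `exact_terminal_limit` (default 12); beyond it use
#' [steiner_heuristic()].
#'
#' Ties among optimal trees are broken deterministically by scanning
#' candidate nodes and submasks in lexicographic order during
#' reconstruction.
#'
#' @param network Connected undirected `igraph` graph with named nodes.
#' @param terminals Character vector of terminal labels; terminals absent
#'   from the network are dropped with a warning.
#' @param exact_terminal_limit Refuse instances with more terminals.
#' @return A [steiner_solution()] with `method = "exact"`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' steiner_exact(g, c("a", "c"))$cost  # 2, imputed node "b"
#' @export
steiner_exact <- function(network, terminals, exact_terminal_limit = 12) {
  prep <- prepare_terminals(network, terminals)
  terms <- prep$terms
  L <- length(terms)
  if (L > exact_terminal_limit)
    stop("too many terminals for the exact solver (", L, " > ",
         exact_terminal_limit, "); use steiner_heuristic()")
  if (L == 1)
    return(steiner_solution(matrix(character(), 0, 2), terms, "exact",
                            prep$dropped))
  nodes <- sort(igraph::V(network)$name)
  D <- igraph::distances(network)[nodes, nodes]
  adj <- ordered_adjacency(network)
  bfs_cache <- new.env(parent = emptyenv())
  get_tree <- function(src) {
    if (is.null(bfs_cache[[src]])) bfs_cache[[src]] <- bfs_tree(adj, src)
    bfs_cache[[src]]
  }
  root <- terms[1]
  others <- terms[-1]
  L2 <- L - 1
  n_masks <- bitwShiftL(1L, L2) - 1L
  n <- length(nodes)
  S <- matrix(Inf, n_masks, n, dimnames = list(NULL, nodes))
  M <- matrix(Inf, n_masks, n, dimnames = list(NULL, nodes))
  bit_of <- bitwShiftL(1L, seq_len(L2) - 1L)
  popcount <- vapply(seq_len(n_masks), function(m)
    sum(bitwAnd(m, bit_of) > 0), numeric(1))
  for (mask in order(popcount)) {
    if (popcount[mask] == 1) {
      ti <- others[which(bitwAnd(mask, bit_of) > 0)]
      M[mask, ] <- Inf
      M[mask, ti] <- 0
    } else {
      sub <- bitwAnd(mask - 1L, mask)
      while (sub > 0L) {
        other <- bitwAnd(mask, bitwNot(sub))
        if (sub < other)  # each unordered split once
          M[mask, ] <- pmin(M[mask, ], S[sub, ] + S[other, ])
        sub <- bitwAnd(sub - 1L, mask)
      }
    }
    S[mask, ] <- apply(M[mask, ] + D, 2, min)
  }
  full <- n_masks
  opt <- S[full, root]
  # Reconstruction mirrors the DP, taking the first minimum in scan order.
  edges <- list()
  rec_S <- function(mask, v) {
    u <- nodes[which.min(M[mask, ] + D[, v])]
    if (u != v)
      edges[[length(edges) + 1]] <<- path_edges(bfs_path(get_tree(u), u, v))
    rec_M(mask, u)
  }
  rec_M <- function(mask, u) {
    if (popcount[mask] == 1) return(invisible())
    best <- Inf; best_sub <- NULL
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      other <- bitwAnd(mask, bitwNot(sub))
      if (sub < other) {
        val <- S[sub, u] + S[other, u]
        if (val < best) { best <- val; best_sub <- sub }
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
    rec_S(best_sub, u)
    rec_S(bitwAnd(mask, bitwNot(best_sub)), u)
  }
  rec_S(full, root)
  el <- normalize_edges(do.call(rbind, edges))
  # Guard against shared sub-paths in the reconstruction: re-extract a
  # spanning tree of the edge union and prune, then check optimality.
  if (nrow(el) > 0) {
    edf <- data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
    edf <- edf[order(edf$a, edf$b), ]
    keep <- kruskal(edf, unique(c(edf$a, edf$b)))
    el <- prune_leaves(as.matrix(edf[keep, c("a", "b")]), terms)
  }
  stopifnot(nrow(el) == opt)
  steiner_solution(el, terms, "exact", prep$dropped)
}

#' Approximate Steiner tree (Kou-Markowsky-Berman)
#'
#' Metric-closure approximation: build the complete graph on terminals
#' weighted by hop shortest-path distance, take its minimum spanning tree,
#' expand each closure edge to an actual shortest path, take a spanning
#' tree of the union and prune non-terminal leaves to a fixpoint.  The
#' cost is within `2 (1 - 1/L)` of optimal for `L` terminals.  All path
#' and spanning-tree ties are broken lexicographically, so repeated runs
#' return identical edge sets.
#'
#' @inheritParams steiner_exact
#' @return A [steiner_solution()] with `method = "heuristic"`.
#' @export
steiner_heuristic <- function(network, terminals) {
  prep <- prepare_terminals(network, terminals)
  terms <- prep$terms
  if (length(terms) == 1)
    return(steiner_solution(matrix(character(), 0, 2), terms, "heuristic",
                            prep$dropped))
  adj <- ordered_adjacency(network)
  trees <- setNames(lapply(terms, function(t) bfs_tree(adj, t)), terms)
  # metric closure on terminals
  pairs <- t(utils::combn(terms, 2))       # combn of sorted: a < b
  closure <- data.frame(a = pairs[, 1], b = pairs[, 2],
                        w = mapply(function(a, b) trees[[a]]$dist[[b]],
                                   pairs[, 1], pairs[, 2]),
                        stringsAsFactors = FALSE)
  closure <- closure[order(closure$w, closure$a, closure$b), ]
  mst_rows <- kruskal(closure, terms)
  # expand closure MST edges along BFS paths from the smaller endpoint
  expanded <- lapply(mst_rows, function(i)
    path_edges(bfs_path(trees[[closure$a[i]]], closure$a[i], closure$b[i])))
  el <- normalize_edges(do.call(rbind, expanded))
  edf <- data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
  edf <- edf[order(edf$a, edf$b), ]
  keep <- kruskal(edf, unique(c(edf$a, edf$b)))
  el <- prune_leaves(as.matrix(edf[keep, c("a", "b")]), terms)
  steiner_solution(el, terms, "heuristic", prep$dropped)
}

#' @rdname steiner_exact
#' @param mode `"auto"` (exact when the terminal count allows, else
#'   heuristic with a log note), `"exact"`, or `"heuristic"`.
#' @export
steiner_tree <- function(network, terminals, mode = c("auto", "exact",
                                                      "heuristic"),
                         exact_terminal_limit = 12) {
  mode <- match.arg(mode)
  if (mode == "exact")
    return(steiner_exact(network, terminals, exact_terminal_limit))
  if (mode == "heuristic")
    return(steiner_heuristic(network, terminals))
  n_present <- length(intersect(unique(as.character(terminals)),
                                igraph::V(network)$name))
  if (n_present <= exact_terminal_limit) {
    steiner_exact(network, terminals, exact_terminal_limit)
  } else {
    log_msg("steiner_tree", n_present, " terminals > exact limit ",
            exact_terminal_limit, "; using the heuristic")
    steiner_heuristic(network, terminals)
  }
}

#' Imputed mediator genes of a Steiner solution
#'
#' The non-terminal nodes the tree had to pass through, in lexicographic
#' order — directly usable as a gene signature for a follow-up survival
#' stratification.
#'
#' @param solution A [steiner_solution()].
#' @return Character vector (possibly empty).
#' @export
extract_imputed <- function(solution) {
  stopifnot(inherits(solution, "SteinerSolution"))
  solution$imputed_nodes
}
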