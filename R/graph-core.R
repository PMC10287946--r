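# Graph and tree containers built on igraph, plus edge-list / GraphML I/O.
#
# A "gene graph" is a plain igraph object whose vertices carry gene
# identifiers in the `name` attribute and whose edges optionally carry a
# numeric `weight`.  Node matching against expression columns is exact and
# case-sensitive throughout the package.

#' Construct a gene graph
#'
#' Builds a simple igraph object from an edge table. Self-loops and duplicate
#' edges are dropped (duplicates of an undirected edge are detected regardless
#' of endpoint order); counts of dropped records are reported as a warning.
#'
#' @param from,to character vectors of endpoint gene identifiers.
#' @param weight optional numeric edge weights (finite).
#' @param nodes optional character vector of node identifiers; allows isolated
#'   nodes not incident to any edge.
#' @param directed logical; build a directed graph.
#' @return an igraph object with vertex attribute `name` and, when `weight`
#'   is given, edge attribute `weight`.
#' @export
gene_graph <- function(from, to, weight = NULL, nodes = NULL, directed = FALSE) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to))
    validation_error("'from' and 'to' must have equal length")
  if (!is.null(weight)) {
    if (length(weight) != length(from))
      validation_error("'weight' length must match the number of edges")
    if (anyNA(weight) || any(!is.finite(weight)))
      validation_error("edge weights must be finite (no NA/NaN/Inf)")
  }

  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    from <- from[!loops]; to <- to[!loops]
    if (!is.null(weight)) weight <- weight[!loops]
  }
  key <- if (directed) paste(from, to, sep = "\r") else edge_key(from, to)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)), call. = FALSE)
    from <- from[!dup]; to <- to[!dup]
    if (!is.null(weight)) weight <- weight[!dup]
  }

  verts <- unique(c(nodes, from, to))
  if (length(verts) == 0L) validation_error("empty graph")
  # canonical storage: undirected endpoints ordered, rows sorted
  if (!directed && length(from)) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  if (length(from)) {
    o <- order(from, to)
    from <- from[o]; to <- to[o]
    if (!is.null(weight)) weight <- weight[o]
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(weight)) data.frame(from = from, to = to, stringsAsFactors = FALSE)
    else data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE),
    directed = directed, vertices = sort(verts))
  g
}

#' Validate a gene graph
#'
#' Checks the structural invariants assumed by all algorithms: named
#' vertices, no self-loops, no duplicate edges, finite weights.
#'
#' @param g igraph object.
#' @return `g`, invisibly.
#' @export
validate_gene_graph <- function(g) {
  if (!igraph::is_igraph(g)) validation_error("not an igraph object")
  if (is.null(igraph::V(g)$name)) validation_error("graph vertices must be named")
  if (any(igraph::which_loop(g))) validation_error("graph contains self-loops")
  if (any(igraph::which_multiple(g))) validation_error("graph contains duplicate edges")
  w <- igraph::E(g)$weight
  if (!is.null(w) && (anyNA(w) || any(!is.finite(w))))
    validation_error("graph has non-finite edge weights")
  invisible(g)
}

#' Read a gene graph from edge-list TSV or GraphML
#'
#' The format is auto-detected from the file extension: `.graphml` is parsed
#' as GraphML (edge attribute key `weight`), anything else as a headerless
#' edge list with two node columns and an optional third numeric weight
#' column, `#` comment lines allowed. Isolated nodes survive only in GraphML.
#'
#' @param path file path.
#' @param directed logical; interpret edges as directed (edge-list input
#'   only; GraphML carries its own directedness).
#' @return an igraph object.
#' @export
read_gene_graph <- function(path, directed = FALSE) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    # igraph warns when a written file already carries an 'id' attribute
    g <- withCallingHandlers(
      igraph::read_graph(path, format = "graphml"),
      warning = function(w) {
        if (grepl("'id' vertex attribute", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.null(igraph::V(g)$name)) {
      id <- igraph::vertex_attr(g, "id")
      if (!is.null(id)) igraph::V(g)$name <- id
      else validation_error("GraphML vertices carry no identifiers")
    }
    nl <- sum(igraph::which_loop(g)); nm <- sum(igraph::which_multiple(g))
    if (nl + nm > 0) {
      message(sprintf("dropping %d self-loop(s) and %d multi-edge(s)", nl, nm))
      g <- igraph::simplify(g, edge.attr.comb = list(weight = "min", "ignore"))
    }
    if (igraph::vcount(g) == 0L) validation_error("empty graph")
    w <- igraph::E(g)$weight
    if (!is.null(w) && (anyNA(w) || any(!is.finite(w))))
      validation_error("GraphML contains non-finite edge weights")
    return(g)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) validation_error("empty graph")
  fields <- strsplit(trimws(lines[idx]), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    validation_error(sprintf("malformed edge on line %d: expected 2 or 3 columns, got %d",
                             idx[bad[1L]], nf[bad[1L]]))
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- NULL
  if (any(nf == 3L)) {
    if (!all(nf == 3L))
      validation_error(sprintf("line %d: weight column present on some lines but not others",
                               idx[which(nf != 3L)[1L]]))
    weight <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    badw <- which(is.na(weight) | !is.finite(weight))
    if (length(badw))
      validation_error(sprintf("non-finite or unparseable weight on line %d", idx[badw[1L]]))
  }
  gene_graph(from, to, weight = weight, directed = directed)
}

#' Write a gene graph to edge-list TSV or GraphML
#'
#' Edge-list output is canonical: undirected endpoints sorted within each
#' row, rows sorted lexicographically, so serialization is deterministic.
#'
#' @param g igraph object.
#' @param path output file; `.graphml` selects GraphML.
#' @return `path`, invisibly.
#' @export
write_gene_graph <- function(g, path) {
  validate_gene_graph(g)
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  if (nrow(el)) {
    if (!igraph::is_directed(g)) {
      swap <- el[, 1L] > el[, 2L]
      el[swap, ] <- el[swap, c(2L, 1L)]
    }
    o <- order(el[, 1L], el[, 2L])
    el <- el[o, , drop = FALSE]
    if (!is.null(w)) w <- w[o]
  }
  out <- if (is.null(w)) cbind(el)
         else cbind(el, format(w, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest (weakly, if directed) connected
#' component. Size ties are broken in favour of the component containing the
#' lexicographically smallest node label.
#'
#' @param g igraph object.
#' @return induced subgraph.
#' @export
largest_component <- function(g) {
  validate_gene_graph(g)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(best, function(k) min(igraph::V(g)$name[comp$membership == k]), "")
    best <- best[order(mins)][1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Tree / arborescence structure check
#'
#' A tree is a connected graph with `|E| = |V| - 1` (connectivity taken in
#' the weak sense for directed input). An arborescence additionally has a
#' single zero-in-degree root from which every node is reachable by directed
#' paths.
#'
#' @param g igraph object.
#' @return list with `is_tree`, `is_arborescence`, `root` (`NA` unless an
#'   arborescence).
#' @export
check_tree <- function(g) {
  validate_gene_graph(g)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  connected <- igraph::is_connected(g, mode = "weak")
  is_tree <- connected && m == n - 1L
  is_arb <- FALSE; root <- NA_character_
  if (is_tree && igraph::is_directed(g)) {
    indeg <- igraph::degree(g, mode = "in")
    r <- which(indeg == 0L)
    if (length(r) == 1L && all(indeg[-r] == 1L)) {
      reach <- igraph::subcomponent(g, r, mode = "out")
      if (length(reach) == n) {
        is_arb <- TRUE
        root <- igraph::V(g)$name[r]
      }
    }
  }
  list(is_tree = is_tree, is_arborescence = is_arb, root = root)
}

# ---------------------------------------------------------------------------
# directed_tree: arborescence as a parent map

#' Construct a directed tree (arborescence)
#'
#' @param parent named character vector mapping each node to its parent;
#'   exactly one entry is `NA` (the root).
#' @param edge_weights optional numeric vector named by child node, one entry
#'   per non-root node.
#' @return object of class `directed_tree` with fields `nodes`, `root`,
#'   `parent`, `edge_weights`, `total_weight`.
#' @export
directed_tree <- function(parent, edge_weights = NULL) {
  nodes <- names(parent)
  if (is.null(nodes) || anyDuplicated(nodes))
    validation_error("'parent' must be uniquely named by child node")
  root <- nodes[is.na(parent)]
  if (length(root) != 1L)
    validation_error(sprintf("exactly one root required, found %d", length(root)))
  kids <- nodes[!is.na(parent)]
  if (!all(parent[kids] %in% nodes))
    validation_error("some parents are not in the node set")
  if (any(parent[kids] == kids))
    validation_error("self-loop in parent map")
  # reachability from root <=> no cycles given the unique-parent structure
  depth <- rep(NA_integer_, length(nodes)); names(depth) <- nodes
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- kids[parent[kids] %in% frontier & is.na(depth[kids])]
    if (length(nxt)) depth[nxt] <- depth[[frontier[1L]]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth))
    validation_error(sprintf("cycle detected: node(s) %s unreachable from root",
                             paste(nodes[is.na(depth)], collapse = ", ")))
  if (is.null(edge_weights)) {
    edge_weights <- rep(NA_real_, length(kids)); names(edge_weights) <- kids
  } else {
    if (is.null(names(edge_weights)) || !setequal(names(edge_weights), kids))
      validation_error("'edge_weights' must be named by the non-root nodes")
    edge_weights <- edge_weights[kids]
  }
  total <- if (anyNA(edge_weights)) NA_real_ else sum(edge_weights)
  structure(list(nodes = nodes, root = root, parent = parent,
                 edge_weights = edge_weights, total_weight = total),
            class = "directed_tree")
}

#' @export
print.directed_tree <- function(x, ...) {
  cat(sprintf("directed tree: %d nodes, root '%s', total weight %s\n",
              length(x$nodes), x$root,
              if (is.na(x$total_weight)) "NA" else format(x$total_weight)))
  invisible(x)
}

#' Convert a directed tree to an igraph object
#'
#' @param t a `directed_tree`.
#' @return directed igraph with edge attribute `weight` when available.
#' @export
tree_as_igraph <- function(t) {
  stopifnot(inherits(t, "directed_tree"))
  kids <- t$nodes[t$nodes != t$root]
  w <- t$edge_weights[kids]
  gene_graph(from = unname(t$parent[kids]), to = kids,
             weight = if (anyNA(w)) NULL else unname(w),
             nodes = t$nodes, directed = TRUE)
}

#' Convert an igraph arborescence to a directed tree
#'
#' @param g directed igraph passing the arborescence check.
#' @return a `directed_tree`.
#' @export
tree_from_igraph <- function(g) {
  chk <- check_tree(g)
  if (!chk$is_arborescence) validation_error("graph is not an arborescence")
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  parent <- rep(NA_character_, length(nodes)); names(parent) <- nodes
  parent[el[, 2L]] <- el[, 1L]
  w <- igraph::E(g)$weight
  ew <- NULL
  if (!is.null(w)) { ew <- w; names(ew) <- el[, 2L] }
  directed_tree(parent, ew)
}

#' All directed source-sink paths of an arborescence
#'
#' For an arborescence there is exactly one directed path per
#' (ancestor, descendant) pair; `K` is the number of such pairs.
#'
#' @param t a `directed_tree`.
#' @return list with `paths` (list of records `source`, `sink`,
#'   `node_sequence`, `edge_sequence`) and the count `K`.
#' @export
directed_paths <- function(t) {
  stopifnot(inherits(t, "directed_tree"))
  paths <- list()
  for (j in t$nodes) {
    if (j == t$root) next
    chain <- j
    a <- t$parent[[j]]
    while (!is.na(a)) {
      chain <- c(a, chain)           # chain runs ancestor ... j
      seqn <- chain
      paths[[length(paths) + 1L]] <- list(
        source = a, sink = j, node_sequence = seqn,
        edge_sequence = paste(seqn[-length(seqn)], seqn[-1L], sep = "->"))
      a <- t$parent[[a]]
    }
  }
  list(paths = paths, K = length(paths))
}
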