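#' Directed gene network
#'
#' A `gene_network` is a directed graph over gene identifiers. Each edge is an
#' ordered (parent, child) pair carrying a `confidence` in \[0, 1\] -- for
#' consensus networks this is the fraction of structure-learning runs in which
#' the edge appeared. Self-edges are forbidden.
#'
#' @param edges A data frame (or NULL for an edgeless network) with columns
#'   `parent`, `child` and optionally `confidence` (default 1). Duplicate
#'   (parent, child) pairs collapse to a single edge keeping the maximum
#'   confidence.
#' @param nodes Optional character vector of node identifiers; the final node
#'   set is the union of `nodes` and all edge endpoints, so isolated genes can
#'   be declared explicitly.
#' @return An object of class `gene_network` with elements `nodes` (character),
#'   `edges` (data frame `parent`, `child`, `confidence`) and `is_dag`
#'   (logical).
#' @examples
#' net <- gene_network(data.frame(parent = c("A", "B"), child = c("B", "C")))
#' net$is_dag
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("parent", "child") %in% names(edges)))
      stop("edges must have 'parent' and 'child' columns")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    if (is.null(edges$confidence)) edges$confidence <- 1
    edges$confidence <- as.numeric(edges$confidence)
    if (anyNA(edges$parent) || anyNA(edges$child))
      stop("edge endpoints must not be missing")
    if (any(edges$parent == edges$child))
      stop("self-edges are not allowed: ",
           paste(unique(edges$parent[edges$parent == edges$child]),
                 collapse = ", "))
    if (anyNA(edges$confidence) ||
        any(edges$confidence < 0) || any(edges$confidence > 1))
      stop("edge confidence must lie in [0, 1]")
    key <- paste(edges$parent, edges$child, sep = "\r")
    if (anyDuplicated(key)) {
      conf <- tapply(edges$confidence, key, max)
      first <- !duplicated(key)
      edges <- edges[first, c("parent", "child"), drop = FALSE]
      edges$confidence <- as.numeric(conf[paste(edges$parent, edges$child,
                                                sep = "\r")])
    }
    edges <- edges[, c("parent", "child", "confidence")]
  }
  nodes <- sort(unique(c(as.character(nodes), edges$parent, edges$child)))
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges, is_dag = NA),
                   class = "gene_network")
  net$is_dag <- igraph::is_dag(as_igraph(net))
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges, %s\n",
              length(x$nodes), nrow(x$edges),
              if (isTRUE(x$is_dag)) "acyclic" else "contains cycles"))
  invisible(x)
}

#' Number of nodes and edges
#' @param net A `gene_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# igraph view of a gene_network (keeps isolated vertices)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Read a directed network from an edge-list file
#'
#' Canonical interchange format: whitespace- or tab-delimited lines
#' `parent child [confidence]`. Lines starting with `#` and blank lines are
#' ignored. A header line (third field non-numeric, or first two fields equal
#' to "parent"/"child") is skipped. Duplicate edges collapse keeping the
#' maximum confidence; a missing confidence column defaults to 1.
#'
#' @param path File to read.
#' @param nodes_path Optional file declaring the node universe (one identifier
#'   per line, `#` comments), so genes without edges are retained.
#' @return A [gene_network()].
#' @seealso [write_edge_list()], [read_gene_set()]
#' @export
read_edge_list <- function(path, nodes_path = NULL) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(gene_network(nodes = if (is.null(nodes_path)) NULL
                        else read_gene_set(nodes_path)$members))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed edge-list line %d in '%s': '%s'",
                 lineno[bad[1]], path, lines[bad[1]]))
  f1 <- fields[[1]]
  is_header <- (length(f1) == 3L && is.na(suppressWarnings(as.numeric(f1[3])))) ||
    (length(f1) == 2L && all(tolower(f1) %in% c("parent", "child", "from", "to")))
  if (is_header) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  if (length(fields) == 0L)
    return(gene_network(nodes = if (is.null(nodes_path)) NULL
                        else read_gene_set(nodes_path)$members))
  parent <- vapply(fields, `[`, character(1), 1L)
  child <- vapply(fields, `[`, character(1), 2L)
  conf <- vapply(fields, function(f)
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3])) else 1, numeric(1))
  if (anyNA(conf)) {
    i <- which(is.na(conf))[1]
    stop(sprintf("non-numeric confidence on line %d", lineno[i]))
  }
  self <- parent == child
  if (any(self))
    stop(sprintf("self-edge '%s' on line %d", parent[which(self)[1]],
                 lineno[which(self)[1]]))
  extra <- if (is.null(nodes_path)) NULL else read_gene_set(nodes_path)$members
  gene_network(data.frame(parent = parent, child = child, confidence = conf,
                          stringsAsFactors = FALSE), nodes = extra)
}

#' Write a network as an edge list
#'
#' @param net A `gene_network`.
#' @param path Output file.
#' @param header Write a `parent child confidence` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("parent\tchild\tconfidence", con)
  if (nrow(net$edges))
    writeLines(sprintf("%s\t%s\t%g", net$edges$parent, net$edges$child,
                       net$edges$confidence), con)
  invisible(path)
}

#' Named gene set
#'
#' @param members Character vector of unique gene identifiers.
#' @param name Label for the set.
#' @return Object of class `gene_set` with fields `name` and `members`.
#' @export
gene_set <- function(members, name = "geneset") {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Read / write a gene-set file (one identifier per line, `#` comments)
#'
#' @param path File to read or write.
#' @param name Set label; defaults to the file name.
#' @return [gene_set()] for the reader; `path` invisibly for the writer.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(sub("#.*$", "", raw))
  gene_set(raw[nzchar(raw)], name = name)
}

#' @rdname read_gene_set
#' @param set A `gene_set` (or character vector) to write.
#' @export
write_gene_set <- function(set, path) {
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  writeLines(members, path)
  invisible(path)
}

# single-source directed shortest-path distances (Inf if unreachable)
node_distances <- function(net, gene) {
  if (!gene %in% net$nodes) stop("unknown gene: ", gene)
  d <- igraph::distances(as_igraph(net), v = gene, mode = "out")[1, ]
  d[net$nodes]
}

#' Downstream genes at an exact shortest-path distance
#'
#' Genes whose directed shortest-path distance from `gene` is exactly `d`
#' (breadth-first search semantics); the focal gene itself is excluded.
#'
#' @param net A `gene_network`.
#' @param gene Focal gene identifier (must be a node).
#' @param d Distance in edges, `d >= 1`.
#' @return Character vector of gene identifiers (possibly empty).
#' @examples
#' net <- gene_network(data.frame(parent = c("A", "B"), child = c("B", "C")))
#' downstream_at_distance(net, "A", 2)  # "C"
#' @export
downstream_at_distance <- function(net, gene, d) {
  stopifnot(length(d) == 1L, d >= 1)
  dist <- node_distances(net, gene)
  names(dist)[!is.infinite(dist) & dist == d]
}

#' Downstream neighborhood within a radius
#'
#' All genes reachable from `gene` along directed edges in at most `radius`
#' steps, excluding `gene` itself. With `radius = 4` this is the downstream
#' "neighborhood" used for type-2 key-driver enrichment.
#'
#' @inheritParams downstream_at_distance
#' @param radius Maximum shortest-path distance, `>= 1`.
#' @return Character vector of gene identifiers.
#' @export
downstream_within <- function(net, gene, radius = 4) {
  stopifnot(length(radius) == 1L, radius >= 1)
  dist <- node_distances(net, gene)
  names(dist)[!is.infinite(dist) & dist >= 1 & dist <= radius]
}
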