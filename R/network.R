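#' Construct a simple undirected network
#'
#' Builds the package's central network object from an edge list. Networks are
#' simple (no self-loops, no multi-edges), undirected and unweighted; node
#' identifiers are 0-based contiguous integers, the convention of most public
#' edge-list corpora. The adjacency matrix `A` is stored dense with a zero
#' diagonal, together with per-node degrees and sorted neighbour lists.
#'
#' @param edges two-column matrix (or data frame) of integer node ids, one
#'   edge per row. Duplicate rows and reversed duplicates are collapsed;
#'   self-loops are dropped with a warning (or an error when `strict = TRUE`).
#' @param n number of nodes. Defaults to `max(edges) + 1`; may be larger to
#'   include isolated nodes, never smaller.
#' @param strict error instead of warn on self-loops.
#'
#' @return An object of class `walk_network` with fields `n`, `edges`
#'   (m x 2 matrix, each row `i < j`), `adj` (0/1 integer matrix), `deg`,
#'   `nbr` (list of ascending neighbour vectors, 0-based ids), `k_av`,
#'   `k_max`.
#' @examples
#' p3 <- network(rbind(c(0, 1), c(1, 2)))
#' p3$deg
#' @export
network <- function(edges, n = NULL, strict = FALSE) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    if (is.null(n)) stop("no edges and no node count given")
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edge list must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("non-integer or missing node id in edge list")
  if (nrow(edges) > 0L && min(edges) < 0L) stop("node ids must be >= 0")

  n_seen <- if (nrow(edges) > 0L) max(edges) + 1L else 0L  # loops count as nodes
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    msg <- sprintf("%d self-loop(s) in edge list", sum(loops))
    if (strict) stop(msg) else warning(msg, "; dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation + dedup
  e <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]

  n_min <- n_seen
  if (is.null(n)) n <- n_min
  n <- as.integer(n)
  if (n < n_min) stop("node count smaller than largest node id + 1")
  if (n < 1L) stop("network must have at least one node")

  adj <- matrix(0L, n, n)
  if (nrow(e) > 0L) {
    adj[cbind(e[, 1L] + 1L, e[, 2L] + 1L)] <- 1L
    adj[cbind(e[, 2L] + 1L, e[, 1L] + 1L)] <- 1L
  }
  deg <- as.integer(rowSums(adj))
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L) - 1L)

  structure(
    list(
      n = n, edges = e, adj = adj, deg = deg, nbr = nbr,
      k_av = 2 * nrow(e) / n, k_max = if (n > 0L) max(deg) else 0L
    ),
    class = "walk_network"
  )
}

#' @export
print.walk_network <- function(x, ...) {
  cat(sprintf(
    "walk_network: N = %d, |E| = %d, k_av = %.3f, k_max = %d\n",
    x$n, nrow(x$edges), x$k_av, x$k_max
  ))
  invisible(x)
}

#' Coerce a walk_network to an igraph object
#' @param network a `walk_network`.
#' @return An undirected [igraph::graph] on `network$n` vertices.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "walk_network"))
  igraph::graph_from_adjacency_matrix(network$adj, mode = "undirected")
}

#' Read a network from a whitespace-delimited edge list
#'
#' One edge per line as two integer tokens; blank lines and lines starting
#' with `#` are skipped, except for an optional header comment `# N=<int>`
#' which fixes the node count (so trailing isolated nodes survive a
#' round-trip).
#'
#' @param path file path.
#' @param strict error (rather than warn-and-drop) on self-loops.
#' @return A [network()] object.
#' @export
read_edge_list <- function(path, strict = FALSE) {
  lines <- readLines(path)
  n_override <- NULL
  hdr <- grep("^\\s*#\\s*N\\s*=\\s*[0-9]+", lines, value = TRUE)
  if (length(hdr) > 0L) {
    n_override <- as.integer(sub("^\\s*#\\s*N\\s*=\\s*([0-9]+).*$", "\\1", hdr[1L]))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L && is.null(n_override)) stop("no edges in ", path)
  ends <- matrix(NA_integer_, length(body), 2L)
  for (k in seq_along(body)) {
    tok <- strsplit(trimws(body[k]), "\\s+")[[1L]]
    v <- suppressWarnings(as.integer(tok))
    if (length(v) != 2L || anyNA(v)) {
      stop(sprintf("malformed edge on line %d of %s: '%s'", lineno[k], path, body[k]))
    }
    ends[k, ] <- v
  }
  network(ends, n = n_override, strict = strict)
}

#' Write a network as an edge list
#'
#' Inverse of [read_edge_list()]: emits a `# N=<n>` header followed by one
#' `i j` line per edge with `i < j`.
#'
#' @param network a `walk_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "walk_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d", network$n), con)
  if (nrow(network$edges) > 0L) {
    writeLines(sprintf("%d %d", network$edges[, 1L], network$edges[, 2L]), con)
  }
  invisible(path)
}

#' Build a network from an adjacency matrix
#' @param adj square symmetric 0/1 matrix with zero diagonal.
#' @return A [network()] object.
#' @export
network_from_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  if (!all(adj %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency matrix must be symmetric")
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  network(cbind(idx[, 1L] - 1L, idx[, 2L] - 1L), n = nrow(adj))
}

#' Good-link mask G = J - (A + I)
#'
#' The 0/1 matrix marking the ordered node pairs that are useful for link
#' prediction: `G_ij = 1` exactly when `A_ij = 0` and `i != j`. Together with
#' `A + I` it partitions all ordered pairs into good and bad.
#'
#' @param network a `walk_network`.
#' @return An `n x n` 0/1 integer matrix.
#' @examples
#' good_link_matrix(network(rbind(c(0, 1), c(1, 2))))
#' @export
good_link_matrix <- function(network) {
  stopifnot(inherits(network, "walk_network"))
  g <- 1L - network$adj
  diag(g) <- 0L
  g
}
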