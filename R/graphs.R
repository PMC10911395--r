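#' Environment graphs
#'
#' An environment graph is an undirected, unweighted graph whose nodes are the
#' discrete places an agent can occupy and whose edges are the moves available
#' in one step. Node indices are 0-based and contiguous, which matches the way
#' labyrinth nodes are conventionally numbered; matrices derived from a graph
#' (adjacency, distances, resolvent, ...) are ordinary R matrices whose row
#' `r` corresponds to node `r - 1`, with node ids as dimnames so that e.g.
#' `D["4", "11"]` works.
#'
#' Adjacency matrices are always zero on the diagonal: the built-in critical
#' gains of the standard graphs are the reciprocals of the spectral radius of
#' the loop-free adjacency, and the learning rule never potentiates a synapse
#' from a map cell onto itself. [adjacency_matrix()] can add the diagonal for
#' sensitivity experiments.
#'
#' @param n_nodes Number of nodes (positive integer).
#' @param edges Two-column integer matrix of 0-based node pairs, one row per
#'   undirected edge.
#' @param labels Optional character vector of per-node labels.
#' @param end_nodes Optional integer vector (0-based) of nodes flagged as
#'   end nodes (leaves), used by patrol coverage metrics.
#' @return An object of class `endo_graph` with fields `n_nodes`, `edges`
#'   (canonical ordering: smaller id first, rows sorted), `labels`,
#'   `end_nodes`.
#' @export
env_graph <- function(n_nodes, edges, labels = NULL, end_nodes = integer(0)) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L)
    stop("`n_nodes` must be a single positive integer")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 0L) || any(edges >= n_nodes))
      stop("edge endpoints must be valid 0-based node indices")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed in an environment graph")
    edges <- t(apply(edges, 1L, sort))
    edges <- matrix(as.integer(edges), ncol = 2L)
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
    if (anyDuplicated(edges))
      stop("duplicate edges are not allowed")
  }
  if (!is.null(labels) && length(labels) != n_nodes)
    stop("`labels` must have one entry per node")
  end_nodes <- sort(unique(as.integer(end_nodes)))
  if (length(end_nodes) && (any(end_nodes < 0L) || any(end_nodes >= n_nodes)))
    stop("`end_nodes` must be valid node indices")
  structure(
    list(n_nodes = n_nodes, edges = edges, labels = labels,
         end_nodes = end_nodes),
    class = "endo_graph")
}

#' @export
print.endo_graph <- function(x, ...) {
  cat(sprintf("<endo_graph> %d nodes, %d edges", x$n_nodes, nrow(x$edges)))
  if (length(x$end_nodes)) cat(sprintf(", %d end nodes", length(x$end_nodes)))
  cat("\n")
  invisible(x)
}

#' @export
`==.endo_graph` <- function(e1, e2) {
  e1$n_nodes == e2$n_nodes && identical(e1$edges, e2$edges)
}

#' Adjacency matrix of an environment graph
#'
#' @param graph An [env_graph()].
#' @param self_loops Add ones on the diagonal (off by default; the standard
#'   theory quantities all use the zero-diagonal adjacency).
#' @return A symmetric 0/1 matrix with node ids as dimnames.
#' @export
adjacency_matrix <- function(graph, self_loops = FALSE) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    idx <- graph$edges + 1L
    A[idx] <- 1
    A[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (self_loops) diag(A) <- 1
  ids <- as.character(0:(n - 1L))
  dimnames(A) <- list(ids, ids)
  A
}

# igraph view of an endo_graph (internal)
as_igraph <- function(graph) {
  igraph::make_graph(as.vector(t(graph$edges + 1L)), n = graph$n_nodes,
                     directed = FALSE)
}

# neighbor lists, 1-based (internal)
neighbor_list <- function(graph) {
  n <- graph$n_nodes
  nb <- vector("list", n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1L] + 1L
    j <- graph$edges[r, 2L] + 1L
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(x) sort(unique(x)))
}

#' Ring graph
#'
#' Cycle graph with `n` nodes (0 ... n-1), node `i` adjacent to
#' `(i ± 1) mod n`, plus optional chords. A chord is an extra edge between two
#' non-adjacent ring nodes, used to model a shortcut appearing across the
#' environment.
#'
#' @param n Number of nodes, at least 3.
#' @param chords Optional list of length-2 integer vectors (0-based node
#'   pairs), or a two-column matrix.
#' @return An `endo_graph`.
#' @examples
#' g <- build_ring(50)
#' critical_gain(g)  # 0.5
#' @export
build_ring <- function(n, chords = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("a ring needs at least 3 nodes")
  edges <- cbind(0:(n - 1L), c(1:(n - 1L), 0L))
  if (!is.null(chords)) {
    if (is.list(chords)) chords <- do.call(rbind, chords)
    chords <- matrix(as.integer(chords), ncol = 2L)
    ring <- env_graph(n, edges)
    A <- adjacency_matrix(ring)
    for (r in seq_len(nrow(chords))) {
      i <- chords[r, 1L]; j <- chords[r, 2L]
      if (A[i + 1L, j + 1L] == 1)
        stop(sprintf("chord (%d,%d) duplicates an existing edge", i, j))
      A[i + 1L, j + 1L] <- 1
    }
    edges <- rbind(edges, chords)
  }
  env_graph(n, edges)
}

#' Complete binary tree ("labyrinth") graph
#'
#' Complete binary tree of depth `levels`, rooted at node 0 (the entrance),
#' numbered breadth-first so node `i` has children `2i + 1` and `2i + 2`.
#' The leaves are flagged as end nodes. With `levels = 6` this is the
#' 127-node labyrinth used in rodent maze experiments: 126 edges, 64 end
#' nodes, diameter 12.
#'
#' @param levels Tree depth, at least 1.
#' @return An `endo_graph` with `end_nodes` set to the leaves.
#' @export
build_binary_tree <- function(levels) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop("`levels` must be at least 1")
  n <- 2L^(levels + 1L) - 1L
  parents <- 0:(2L^levels - 2L)
  edges <- cbind(rep(parents, each = 2L),
                 as.integer(c(rbind(2L * parents + 1L, 2L * parents + 2L))))
  leaves <- (2L^levels - 1L):(n - 1L)
  labels <- c("entrance", rep(NA_character_, n - 1L))
  labels[leaves + 1L] <- paste0("leaf-", leaves)
  env_graph(n, edges, labels = labels, end_nodes = leaves)
}

# enumerate Hanoi states: a state assigns each disk (1 = smallest) to a peg
# in 1:3. Ordered so that state index is the base-3 expansion with disk 1 as
# the least significant digit.
hanoi_states <- function(n_disks) {
  as.matrix(expand.grid(rep(list(1:3), n_disks)))
}

#' Tower-of-Hanoi state graph
#'
#' One node per legal configuration of `n_disks` disks on 3 pegs (3^n
#' states); an edge for every legal single-disk move (move the top disk of
#' one peg onto a peg whose top disk is larger, or which is empty). The start
#' node has all disks on the center peg (peg 2); the two configurations with
#' all disks on peg 1 or peg 3 are the solution nodes, flagged as end nodes.
#' Node labels record the peg of each disk, smallest first, e.g. `"(2,2,2,2)"`.
#'
#' @param n_disks Number of disks, at least 1.
#' @return An `endo_graph`. The start node id is in
#'   `attr(graph, "start_node")`, solution ids in `attr(graph, "solutions")`.
#' @export
build_hanoi <- function(n_disks) {
  n_disks <- as.integer(n_disks)
  if (is.na(n_disks) || n_disks < 1L) stop("`n_disks` must be at least 1")
  states <- hanoi_states(n_disks)
  n <- nrow(states)
  key <- apply(states, 1L, paste, collapse = ",")
  edges <- NULL
  for (s in seq_len(n)) {
    st <- states[s, ]
    for (d in seq_len(n_disks)) {
      p <- st[d]
      if (d > 1L && any(st[seq_len(d - 1L)] == p)) next  # not top of its peg
      for (q in setdiff(1:3, p)) {
        if (d > 1L && any(st[seq_len(d - 1L)] == q)) next  # smaller disk on q
        st2 <- st; st2[d] <- q
        s2 <- match(paste(st2, collapse = ","), key)
        if (s < s2) edges <- rbind(edges, c(s - 1L, s2 - 1L))
      }
    }
  }
  start <- match(paste(rep(2L, n_disks), collapse = ","), key) - 1L
  sols <- c(match(paste(rep(1L, n_disks), collapse = ","), key),
            match(paste(rep(3L, n_disks), collapse = ","), key)) - 1L
  g <- env_graph(n, edges, labels = paste0("(", key, ")"), end_nodes = sols)
  attr(g, "start_node") <- start
  attr(g, "solutions") <- sols
  g
}

#' Shortest graph distances
#'
#' Hop counts between every pair of nodes (breadth-first search), or from a
#' subset of source nodes.
#'
#' @param graph An `endo_graph`; must be connected.
#' @param from Optional 0-based source node(s); default all nodes.
#' @return Matrix of distances (`length(from)` x n) with node ids as
#'   dimnames; symmetric when `from` is omitted.
#' @export
shortest_distances <- function(graph, from = NULL) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    small <- which(comp$membership == which.min(comp$csize))
    stop(sprintf(
      "graph is disconnected (infinite distances); smallest component: {%s}",
      paste(sort(small - 1L), collapse = ", ")))
  }
  v <- if (is.null(from)) igraph::V(g) else as.integer(from) + 1L
  D <- igraph::distances(g, v = v, algorithm = "unweighted")
  ids <- as.character(0:(graph$n_nodes - 1L))
  dimnames(D) <- list(if (is.null(from)) ids else as.character(from), ids)
  D
}

#' Critical gain of a graph
#'
#' The map network's goal signal encodes graph distance only while the neuron
#' gain stays below the critical gain, the reciprocal of the largest absolute
#' eigenvalue of the (zero-diagonal) adjacency matrix. Above it the recurrent
#' network computation diverges.
#'
#' @param graph An `endo_graph`.
#' @param self_loops Use the adjacency with ones on the diagonal instead
#'   (sensitivity experiments only).
#' @return The critical gain, a positive number.
#' @examples
#' critical_gain(build_ring(50))        # 0.5
#' critical_gain(build_binary_tree(6))  # ~0.383
#' @export
critical_gain <- function(graph, self_loops = FALSE) {
  A <- adjacency_matrix(graph, self_loops = self_loops)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  1 / max(abs(ev))
}

#' Add or remove a link
#'
#' Modify the environment by adding or removing one undirected edge,
#' modelling e.g. a shortcut opening up or a corridor caving in. Removing a
#' cut edge leaves a disconnected graph; that is allowed (navigation is still
#' defined on the reachable set) but a warning is issued.
#'
#' @param graph An `endo_graph`.
#' @param i,j Distinct 0-based node indices.
#' @return The modified `endo_graph`.
#' @export
add_link <- function(graph, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("cannot link a node to itself")
  A <- adjacency_matrix(graph)
  if (A[i + 1L, j + 1L] == 1) stop(sprintf("edge (%d,%d) already exists", i, j))
  env_graph(graph$n_nodes, rbind(graph$edges, c(i, j)),
            labels = graph$labels, end_nodes = graph$end_nodes)
}

#' @rdname add_link
#' @export
remove_link <- function(graph, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  e <- sort(c(i, j))
  hit <- which(graph$edges[, 1L] == e[1L] & graph$edges[, 2L] == e[2L])
  if (!length(hit)) stop(sprintf("edge (%d,%d) does not exist", i, j))
  out <- env_graph(graph$n_nodes, graph$edges[-hit, , drop = FALSE],
                   labels = graph$labels, end_nodes = graph$end_nodes)
  if (igraph::components(as_igraph(out))$no > 1L)
    warning(sprintf("removing edge (%d,%d) disconnects the graph", i, j))
  out
}

#' Read / write tab-separated edge lists
#'
#' Plain-text exchange format: one edge per line as `i<TAB>j` with 0-based
#' node indices; lines starting with `#` are comments. Writing uses the
#' canonical ordering (smaller index first, rows sorted), so
#' write-then-read is an identity.
#'
#' @param path File path.
#' @param n_nodes Optional node count for `read_edgelist` (defaults to
#'   `max(index) + 1`, which drops trailing isolated nodes).
#' @return `read_edgelist` returns an `endo_graph`; `write_edgelist` returns
#'   `path` invisibly.
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  edges <- NULL
  for (ln in which(keep)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) != 2L)
      stop(sprintf("line %d: expected two whitespace-separated tokens", ln))
    ij <- suppressWarnings(as.integer(tok))
    if (any(is.na(ij)))
      stop(sprintf("line %d: non-integer token", ln))
    if (ij[1L] == ij[2L])
      stop(sprintf("line %d: self-loop %d-%d rejected", ln, ij[1L], ij[2L]))
    edges <- rbind(edges, ij)
  }
  if (is.null(edges)) stop("no edges found in ", path)
  if (is.null(n_nodes)) n_nodes <- max(edges) + 1L
  env_graph(n_nodes, edges)
}

#' @rdname read_edgelist
#' @param graph An `endo_graph` to write.
#' @export
write_edgelist <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d", graph$edges[, 1L], graph$edges[, 2L]), con)
  invisible(path)
}

#' @rdname read_edgelist
#' @export
write_adjacency_csv <- function(graph, path) {
  A <- adjacency_matrix(graph)
  if (!is.null(graph$labels)) {
    lab <- ifelse(is.na(graph$labels), colnames(A), graph$labels)
    dimnames(A) <- list(lab, lab)
  }
  utils::write.csv(A, path, row.names = TRUE)
  invisible(path)
}
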