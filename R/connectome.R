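# Synthetic structural connectomes. The analyses downstream need two things
# from the substrate: degree heterogeneity (designated hubs) for the
# degree-amplitude topography, and millimetre-scale inter-node distances for
# conduction delays. Nodes are embedded in a 3-D box and edges sampled with
# hub-weighted preference, then repaired to guarantee connectivity and the
# hub-degree contract.

#' Generate a hub-heterogeneous spatially embedded connectome
#'
#' Builds a symmetric binary adjacency matrix with a designated set of hub
#' nodes whose degree is at least twice the median degree, plus Euclidean
#' distances (mm) from uniform node positions in a cubic volume.
#'
#' @param n_nodes number of nodes (>= 10).
#' @param density fraction of the `n_nodes*(n_nodes-1)/2` possible edges,
#'   in (0, 1).
#' @param hub_fraction fraction of nodes designated as hubs, in (0, 0.5).
#' @param seed integer seed; generation is fully reproducible.
#' @param box_mm side length of the embedding cube in millimetres.
#' @param max_retries number of fresh edge draws attempted before the
#'   connectivity repair step gives up with an error.
#' @return an object of class `connectome`: list with `n_nodes`, `adjacency`
#'   (symmetric 0/1, zero diagonal), `distances` (symmetric, mm, zero
#'   diagonal), `labels`, `hubs` (logical), and `coords` (n x 3, mm).
#' @export
generate_connectome <- function(n_nodes, density, hub_fraction, seed,
                                box_mm = 150, max_retries = 50L) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 10L)
  check_fraction(density, "density")
  check_fraction(hub_fraction, "hub_fraction", 0, 0.5)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)

  coords <- matrix(runif(n_nodes * 3L, 0, box_mm), ncol = 3L)
  dist_mat <- unname(as.matrix(stats::dist(coords)))
  n_hub <- max(1L, round(hub_fraction * n_nodes))
  hubs <- logical(n_nodes)
  hubs[sample.int(n_nodes, n_hub)] <- TRUE

  n_pairs <- n_nodes * (n_nodes - 1L) / 2L
  n_edges <- max(n_nodes - 1L, round(density * n_pairs))
  pair_idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)))
  rowcol <- arrayInd(pair_idx, c(n_nodes, n_nodes))
  w_node <- ifelse(hubs, 4, 1)
  w_pair <- w_node[rowcol[, 1L]] * w_node[rowcol[, 2L]]

  adj <- NULL
  for (try in seq_len(max_retries)) {
    a <- matrix(0L, n_nodes, n_nodes)
    chosen <- sample.int(n_pairs, n_edges, prob = w_pair)
    a[pair_idx[chosen]] <- 1L
    a <- a + t(a)
    a <- .connect_components(a)
    a <- .boost_hubs(a, hubs)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(g)) {
      adj <- a
      break
    }
  }
  if (is.null(adj))
    stop("failed to generate a connected connectome after ", max_retries,
         " retries")
  dimnames(adj) <- NULL
  structure(
    list(n_nodes = n_nodes, adjacency = adj, distances = dist_mat,
         labels = sprintf("node%03d", seq_len(n_nodes)), hubs = hubs,
         coords = coords),
    class = "connectome"
  )
}

# join disconnected components by linking a random node of each smaller
# component to a random node of the largest
.connect_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    big <- which.max(comp$csize)
    other <- which(comp$membership != big)
    from <- other[sample.int(length(other), 1L)]
    inbig <- which(comp$membership == big)
    to <- inbig[sample.int(length(inbig), 1L)]
    adj[from, to] <- adj[to, from] <- 1L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
  }
  adj
}

# add edges from under-connected hubs until every hub has degree
# >= 2 * median degree of the final graph
.boost_hubs <- function(adj, hubs) {
  repeat {
    deg <- rowSums(adj)
    target <- 2L * ceiling(median(deg))
    lacking <- which(hubs & deg < target)
    if (length(lacking) == 0L) return(adj)
    h <- lacking[1L]
    cand <- which(adj[h, ] == 0L & seq_along(hubs) != h)
    if (length(cand) == 0L) return(adj)  # hub already saturated
    k <- cand[sample.int(length(cand), 1L)]
    adj[h, k] <- adj[k, h] <- 1L
  }
}

#' @export
print.connectome <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  cat(sprintf("connectome: %d nodes, %d edges (density %.3f)\n",
              x$n_nodes, sum(x$adjacency) / 2,
              sum(x$adjacency) / (x$n_nodes * (x$n_nodes - 1))))
  cat(sprintf("  degree: median %d, max %d; %d hub nodes\n",
              as.integer(median(deg)), max(deg), sum(x$hubs)))
  cat(sprintf("  distances: %.1f-%.1f mm\n",
              min(x$distances[x$distances > 0]), max(x$distances)))
  invisible(x)
}

#' Generate natural frequencies for an oscillator network
#'
#' Samples node natural frequencies from Normal(`mean_hz`, `sd_hz`) in Hz,
#' redrawing any non-positive values (preserving approximate normality), and
#' converts to angular frequency (rad/s).
#'
#' @param n_nodes number of oscillators.
#' @param mean_hz mean frequency in Hz (default 10, the dominant rhythm of
#'   resting human EEG).
#' @param sd_hz standard deviation in Hz (default 0.5).
#' @param seed integer seed.
#' @return object of class `frequency_set`: list with `omega` (rad/s),
#'   `hz`, and `seed`.
#' @export
generate_frequencies <- function(n_nodes, mean_hz = 10, sd_hz = 0.5, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  stopifnot(mean_hz > 0, sd_hz >= 0)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  hz <- rnorm(n_nodes, mean_hz, sd_hz)
  while (any(hz <= 0)) {
    bad <- hz <= 0
    hz[bad] <- rnorm(sum(bad), mean_hz, sd_hz)
  }
  structure(list(omega = 2 * pi * hz, hz = hz, seed = seed),
            class = "frequency_set")
}

#' Validate a connectome object
#'
#' Checks the structural invariants: symmetry, 0/1 entries, zero diagonal,
#' non-negative symmetric distances that are positive wherever an edge
#' exists, and a single connected component.
#'
#' @param conn a `connectome`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_connectome <- function(conn) {
  a <- conn$adjacency
  d <- conn$distances
  stopifnot(isSymmetric(a), all(a %in% c(0L, 1L)), all(diag(a) == 0))
  stopifnot(isSymmetric(unname(d)), all(d >= 0), all(diag(d) == 0))
  if (any(a == 1 & d <= 0))
    stop("distances must be positive wherever an edge exists")
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (!igraph::is_connected(g)) stop("connectome graph is not connected")
  invisible(TRUE)
}

#' Write / read a connectome as plain-text matrices
#'
#' Writes `<prefix>_adjacency.txt` and `<prefix>_distances.txt`
#' (whitespace-delimited square matrices) plus `<prefix>_labels.txt` (one
#' label per line); `read_connectome` reverses the operation.
#'
#' @param conn a `connectome`.
#' @param prefix path prefix for the three files.
#' @return `write_connectome` the prefix invisibly; `read_connectome` a
#'   `connectome` (without coordinates or hub designations).
#' @export
write_connectome <- function(conn, prefix) {
  write.table(conn$adjacency, paste0(prefix, "_adjacency.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(conn$distances, paste0(prefix, "_distances.txt"),
              row.names = FALSE, col.names = FALSE)
  writeLines(conn$labels, paste0(prefix, "_labels.txt"))
  invisible(prefix)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(prefix) {
  adj <- as.matrix(read.table(paste0(prefix, "_adjacency.txt")))
  dst <- as.matrix(read.table(paste0(prefix, "_distances.txt")))
  labels <- readLines(paste0(prefix, "_labels.txt"))
  dimnames(adj) <- dimnames(dst) <- NULL
  conn <- structure(
    list(n_nodes = nrow(adj), adjacency = adj, distances = dst,
         labels = labels, hubs = NULL, coords = NULL),
    class = "connectome"
  )
  validate_connectome(conn)
  conn
}
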