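#' MCODE parameter set
#'
#' Parameters of the molecular-complex-detection algorithm. The defaults are
#' the standard published settings: degree cutoff 2, node score cutoff 0.2,
#' K-core 2, maximum depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff Minimum simple degree for a vertex to receive a
#'   nonzero weight.
#' @param node_score_cutoff Fraction of the seed weight below which a
#'   neighbour is not recruited (in \[0, 1\]).
#' @param k_core Complexes lacking a k-core of this order are dropped.
#' @param max_depth Maximum breadth-first distance from the seed.
#' @param haircut Remove degree-1 members from a finished complex.
#' @param fluff Not supported; must be `FALSE`.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100,
                         haircut = TRUE, fluff = FALSE) {
  stopifnot(degree_cutoff >= 0, node_score_cutoff >= 0, node_score_cutoff <= 1,
            k_core >= 0, max_depth >= 1)
  if (isTRUE(fluff)) stop("fluff post-processing is not supported")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = FALSE),
            class = "mcode_params")
}

simple_graph <- function(net) {
  g <- as_igraph(net, simple = TRUE)
  g
}

graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' Weights every vertex by the local density of its neighbourhood: vertices
#' with simple degree below `degree_cutoff` get weight 0; every other vertex
#' gets \eqn{k \times} density of the highest-\eqn{k}-core of its closed
#' neighbourhood (the induced subgraph on the vertex and its neighbours,
#' self-loops ignored), where \eqn{k} is the order of that core.
#'
#' @param net An [interaction_network()].
#' @param params An [mcode_params()] object.
#' @return Named numeric vector of weights, one per node.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "interaction_network"), inherits(params, "mcode_params"))
  g <- simple_graph(net)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- setNames(numeric(length(ids)), ids)
  for (v in seq_along(ids)) {
    if (deg[v] < params$degree_cutoff || deg[v] == 0) next
    nb <- igraph::neighbors(g, v)
    h <- igraph::induced_subgraph(g, c(v, nb))
    core <- igraph::coreness(h)
    kmax <- max(core)
    if (kmax == 0) next
    hc <- igraph::induced_subgraph(h, which(core >= kmax))
    w[v] <- kmax * graph_density_simple(hc)
  }
  w
}

#' Find molecular complexes with the MCODE procedure
#'
#' Greedy seeded complex growth on the simple undirected view of a typed
#' network: seeds are taken in decreasing vertex-weight order (ties broken
#' by lexicographic node id); from each unassigned seed, neighbours whose
#' weight is at least `seed_weight * (1 - node_score_cutoff)` are recruited
#' breadth-first to at most `max_depth` steps, each node joining at most
#' one complex. Finished complexes lacking a `k_core`-core are dropped;
#' with `haircut`, degree-1 members (within the complex) are removed. Each
#' complex is scored by its density times its size and the list is
#' returned sorted by decreasing score.
#'
#' @param net An [interaction_network()].
#' @param params An [mcode_params()] object.
#' @return List of complexes; each is a list with `members` (sorted node
#'   ids), `seed` and `score`.
#' @export
mcode_find_complexes <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "interaction_network"), inherits(params, "mcode_params"))
  g <- simple_graph(net)
  nv <- igraph::vcount(g)
  if (nv == 0) return(list())
  ids <- igraph::V(g)$name
  w <- mcode_vertex_weights(net, params)
  w <- w[ids]
  order_idx <- order(-w, ids)
  assigned <- rep(FALSE, nv)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)

  complexes <- list()
  for (s in order_idx) {
    if (assigned[s] || w[s] <= 0) next
    threshold <- w[s] * (1 - params$node_score_cutoff)
    members <- s
    in_cpx <- rep(FALSE, nv); in_cpx[s] <- TRUE
    frontier <- s
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!in_cpx[u] && !assigned[u] && w[u] >= threshold) {
            in_cpx[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- sort(nxt)
      depth <- depth + 1
    }
    if (length(members) < 2) next
    h <- igraph::induced_subgraph(g, members)
    if (params$k_core > 0 && max(igraph::coreness(h)) < params$k_core) next
    final_names <- igraph::V(h)$name
    if (params$haircut) {
      keep <- igraph::degree(h) >= 2
      if (sum(keep) < 2) next
      h <- igraph::induced_subgraph(h, which(keep))
      final_names <- igraph::V(h)$name
    }
    assigned[match(final_names, ids)] <- TRUE
    assigned[s] <- TRUE
    complexes[[length(complexes) + 1]] <-
      list(members = sort(final_names), seed = ids[s],
           score = graph_density_simple(h) * igraph::vcount(h))
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord]
}

#' Write a complex list as TSV
#'
#' One row per complex: id, score, seed, semicolon-joined members.
#'
#' @param complexes Result of [mcode_find_complexes()].
#' @param path Output path.
#' @export
write_complexes <- function(complexes, path) {
  df <- data.frame(
    complex = seq_along(complexes),
    score = vapply(complexes, `[[`, numeric(1), "score"),
    seed = vapply(complexes, `[[`, character(1), "seed"),
    n_members = vapply(complexes, function(x) length(x$members), integer(1)),
    members = vapply(complexes, function(x) paste(x$members, collapse = ";"),
                     character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
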