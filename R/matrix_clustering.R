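#' Binary interaction matrix of a network
#'
#' Symmetric node-by-node 0/1 matrix in lexicographic node order: cell
#' (i, j) is 1 exactly when an interaction of any type exists between the
#' two nodes; the diagonal is 1 only at self-interacting genes.
#'
#' @param net A non-empty [interaction_network()].
#' @return A base 0/1 matrix with node ids as dimnames.
#' @export
build_binary_matrix <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$nodes) == 0) stop("cannot build a matrix from an empty network")
  m <- as.matrix(neighbor_matrix(net))
  storage.mode(m) <- "double"
  m
}

#' Uncentered correlation of two vectors
#'
#' \eqn{\sum x_i y_i / (\sqrt{\sum x_i^2}\,\sqrt{\sum y_i^2})}: the cosine
#' of the raw (non-mean-centred) vectors, the "uncentered correlation" of
#' classic expression-clustering tools. Defined as 0 when either vector is
#' all-zero.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Numeric similarity in \[-1, 1\] (in \[0, 1\] for binary data).
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

uncentered_similarity_matrix <- function(mat) {
  cp <- tcrossprod(mat)
  nrm <- sqrt(diag(cp))
  s <- cp / outer(nrm, nrm)
  s[!is.finite(s)] <- 0
  s
}

#' Average-linkage hierarchical clustering on uncentered correlation
#'
#' Agglomerative clustering of the rows of a binary interaction matrix.
#' Row-row similarity is the uncentered correlation; cluster-cluster
#' similarity is the unweighted mean of all cross-pair similarities
#' (average linkage, maintained by the Lance-Williams update). At every
#' step the most similar pair of clusters merges; exact ties are broken by
#' the lexicographically smallest member id (then the second-smallest),
#' which makes the agglomeration deterministic. Rows with no interactions
#' (all-zero, undefined similarity) are excluded.
#'
#' @param mat Matrix from [build_binary_matrix()] (rows named).
#' @return An object of class `merge_tree`: list with `merge` (hclust-style
#'   merge matrix), `similarity` (merge similarities, non-increasing),
#'   `labels`, and `n_leaves`.
#' @export
average_linkage <- function(mat) {
  stopifnot(is.matrix(mat))
  keep <- rowSums(mat != 0) > 0
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 rows with interactions to cluster")
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  s <- uncentered_similarity_matrix(mat)
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minlab <- labels                    # lexicographically smallest member id
  node_id <- -seq_len(n)              # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  sims <- numeric(n - 1)
  diag(s) <- -Inf
  s[!active, ] <- -Inf

  for (step in seq_len(n - 1)) {
    # inactive rows/columns and the diagonal are held at -Inf
    best <- max(s)
    cand <- which(s >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    lab2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(lab1, lab2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    merge[step, ] <- c(node_id[i], node_id[j])
    sims[step] <- s[i, j]
    # Lance-Williams update for unweighted average linkage
    newrow <- (size[i] * s[i, ] + size[j] * s[j, ]) / (size[i] + size[j])
    s[i, ] <- newrow
    s[, i] <- newrow
    s[i, i] <- -Inf
    active[j] <- FALSE
    s[j, ] <- -Inf
    s[, j] <- -Inf
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    node_id[i] <- step
  }
  structure(list(merge = merge, similarity = sims, labels = labels,
                 n_leaves = n),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("merge_tree:", x$n_leaves, "leaves,", nrow(x$merge), "merges, similarity range [",
      sprintf("%.3f", min(x$similarity)), ",", sprintf("%.3f", max(x$similarity)), "]\n")
  invisible(x)
}

# Leaves under each merge node, as indices into tree$labels.
merge_leaves <- function(tree) {
  n <- tree$n_leaves
  out <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- tree$merge[k, ]
    leaves <- integer()
    for (c in kids) {
      leaves <- c(leaves, if (c < 0) -c else out[[c]])
    }
    out[[k]] <- leaves
  }
  out
}

#' Cut a merge tree at a similarity threshold
#'
#' Extracts the maximal subtrees whose internal merges all have similarity
#' at or above the threshold; each such subtree's leaves form one cluster.
#' Only clusters with at least 2 nodes are reported (a merge subtree always
#' has at least 2 leaves, so singleton leaves are never clusters).
#'
#' @param tree A [average_linkage()] merge tree.
#' @param threshold Similarity threshold in \[0, 1\].
#' @return An object of class `dendrogram_cut`: list with `threshold`,
#'   `clusters` (list of sorted node-id vectors), `n_clusters`, `min_size`,
#'   `max_size`.
#' @export
cut_at_similarity <- function(tree, threshold) {
  stopifnot(inherits(tree, "merge_tree"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  n <- tree$n_leaves
  nm <- n - 1
  good <- logical(nm)
  for (k in seq_len(nm)) {
    kids <- tree$merge[k, ]
    kids_ok <- all(vapply(kids, function(c) c < 0 || good[c], logical(1)))
    good[k] <- kids_ok && tree$similarity[k] >= threshold
  }
  parent_good <- logical(nm)
  for (k in seq_len(nm)) {
    for (c in tree$merge[k, ]) {
      if (c > 0 && good[k]) parent_good[c] <- TRUE
    }
  }
  roots <- which(good & !parent_good)
  leaves <- merge_leaves(tree)
  clusters <- lapply(roots, function(k) sort(tree$labels[leaves[[k]]]))
  sizes <- lengths(clusters)
  structure(list(threshold = threshold, clusters = clusters,
                 n_clusters = length(clusters),
                 min_size = if (length(sizes)) min(sizes) else 0L,
                 max_size = if (length(sizes)) max(sizes) else 0L),
            class = "dendrogram_cut")
}

#' @export
print.dendrogram_cut <- function(x, ...) {
  cat(sprintf("dendrogram_cut at %.2f: %d clusters (sizes %d-%d)\n",
              x$threshold, x$n_clusters, x$min_size, x$max_size))
  invisible(x)
}

#' Clustered-node count across a threshold grid
#'
#' For each threshold, the total number of leaves belonging to clusters of
#' size at least 2 at that cut. The count is non-increasing in the
#' threshold.
#'
#' @param tree A [average_linkage()] merge tree.
#' @param thresholds Non-empty numeric grid in \[0, 1\].
#' @return Data frame with columns `threshold`, `n_clustered_nodes`.
#' @export
clustered_node_curve <- function(tree, thresholds) {
  if (length(thresholds) == 0) stop("threshold grid must be non-empty")
  thresholds <- sort(thresholds)
  counts <- vapply(thresholds, function(t)
    sum(lengths(cut_at_similarity(tree, t)$clusters)), numeric(1))
  data.frame(threshold = thresholds, n_clustered_nodes = counts)
}

#' Detect inflection thresholds of a clustered-node curve
#'
#' Smooths the curve with a 3-point moving average, takes the discrete
#' second difference, and identifies curvature episodes: maximal runs of
#' grid points with a constant nonzero second-difference sign. Each episode
#' is reported at its central grid point, so a single knee in a
#' piecewise-linear curve is located at the knee itself.
#'
#' @param curve Data frame from [clustered_node_curve()] (at least 5 rows).
#' @return Numeric vector of inflection thresholds (possibly empty).
#' @export
detect_inflections <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("threshold", "n_clustered_nodes") %in% names(curve)))
  if (nrow(curve) < 5) stop("curve must have at least 5 points")
  curve <- curve[order(curve$threshold), , drop = FALSE]
  y <- curve$n_clustered_nodes
  n <- length(y)
  # full 3-point windows only: partial end windows would fabricate curvature
  s <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3   # s[k] smooths index k+1
  m <- length(s)
  d2 <- s[3:m] - 2 * s[2:(m - 1)] + s[1:(m - 2)]    # d2[k] at grid index k+2
  eps <- 1e-9 * max(abs(y), 1)
  sg <- ifelse(d2 > eps, 1L, ifelse(d2 < -eps, -1L, 0L))
  out <- numeric()
  i <- 1
  while (i <= length(sg)) {
    if (sg[i] != 0) {
      j <- i
      while (j < length(sg) && sg[j + 1] == sg[i]) j <- j + 1
      centre <- floor((i + j) / 2)
      out <- c(out, curve$threshold[centre + 2])    # +2: d2 index -> grid index
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Export a clustered data table and tree file
#'
#' Writes the dendrogram-viewer text formats: `export_gtr()` writes the
#' gene-tree file (one line per merge: node id, two child ids, similarity)
#' and `export_cdt()` the clustered data table with rows in dendrogram
#' order.
#'
#' @param tree A [average_linkage()] merge tree.
#' @param mat The binary matrix the tree was built from.
#' @param path Output path.
#' @export
export_gtr <- function(tree, path) {
  stopifnot(inherits(tree, "merge_tree"))
  idname <- function(c) if (c < 0) sprintf("GENE%dX", -c) else sprintf("NODE%dX", c)
  lines <- vapply(seq_len(nrow(tree$merge)), function(k) {
    paste(sprintf("NODE%dX", k), idname(tree$merge[k, 1]),
          idname(tree$merge[k, 2]), format(tree$similarity[k], digits = 10),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Dendrogram leaf order: left-to-right traversal of the final merge.
tree_leaf_order <- function(tree) {
  walk <- function(c) {
    if (c < 0) return(-c)
    unlist(lapply(tree$merge[c, ], walk))
  }
  walk(nrow(tree$merge))
}

#' @rdname export_gtr
#' @export
export_cdt <- function(tree, mat, path) {
  stopifnot(inherits(tree, "merge_tree"), is.matrix(mat))
  ord <- tree_leaf_order(tree)
  labs <- tree$labels[ord]
  m <- mat[labs, , drop = FALSE]
  header <- paste(c("GID", "UNIQID", "NAME", colnames(m)), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", rep("1", ncol(m))), collapse = "\t")
  rows <- vapply(seq_along(labs), function(i) {
    paste(c(sprintf("GENE%dX", ord[i]), labs[i], labs[i],
            format(m[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, rows), path)
  invisible(path)
}

#' Write a dendrogram cut as a cluster-list TSV
#'
#' @param cut A [cut_at_similarity()] result.
#' @param path Output path.
#' @export
write_cut <- function(cut, path) {
  df <- data.frame(cluster = seq_along(cut$clusters),
                   threshold = cut$threshold,
                   n_members = lengths(cut$clusters),
                   members = vapply(cut$clusters, paste, character(1),
                                    collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
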