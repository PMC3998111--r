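#' @importFrom stats wilcox.test
NULL

# Sparse symmetric neighbour-indicator matrix: row v is the 0/1 indicator of
# N(v); the diagonal is 1 exactly where a self-interaction exists.
neighbor_matrix <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  ids <- net$nodes$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  i <- idx[net$edges$a]; j <- idx[net$edges$b]
  m <- Matrix::sparseMatrix(i = c(i, j[i != j]), j = c(j, i[i != j]),
                            x = 1, dims = c(n, n), dimnames = list(ids, ids))
  m@x[] <- 1  # collapse any accidental multiplicity
  m
}

#' Neighbour set of a node
#'
#' All nodes that interact with the given node; the node itself is a member
#' exactly when it has a self-interaction.
#'
#' @param net An [interaction_network()].
#' @param node A node id present in the network.
#' @return Character vector of neighbour ids (possibly empty).
#' @export
neighbor_set <- function(net, node) {
  stopifnot(inherits(net, "interaction_network"))
  if (!node %in% net$nodes$id) stop("unknown node: ", node)
  e <- net$edges
  # a self-loop (node, node) contributes `node` itself; ordinary edges never do
  sort(unique(c(e$b[e$a == node], e$a[e$b == node])))
}

#' Jaccard similarity of two nodes' neighbour sets
#'
#' \eqn{|N(a) \cap N(b)| / |N(a) \cup N(b)|}, where each neighbour set
#' includes the node itself when a self-interaction exists. Defined as 0
#' when both sets are empty.
#'
#' @param net An [interaction_network()].
#' @param a,b Node ids present in the network.
#' @return Numeric in \[0, 1\].
#' @export
jaccard_coefficient <- function(net, a, b) {
  na <- neighbor_set(net, a)
  nb <- neighbor_set(net, b)
  u <- length(union(na, nb))
  if (u == 0) return(0)
  length(intersect(na, nb)) / u
}

# Dense all-pairs Jaccard matrix (named, symmetric). Intended for networks
# of up to a few thousand nodes.
jaccard_matrix <- function(net) {
  m <- neighbor_matrix(net)
  inter <- as.matrix(m %*% m)  # m symmetric: (m m)[a,b] = |N(a) /\ N(b)|
  sizes <- Matrix::rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  j <- ifelse(un > 0, inter / un, 0)
  dimnames(j) <- dimnames(m)
  j
}

pair_code_from_kinds <- function(ka, kb) {
  k1 <- pmin(ka, kb); k2 <- pmax(ka, kb)
  ifelse(k1 == "chemical" & k2 == "chemical", "CC",
  ifelse(k1 == "gene" & k2 == "gene", "GG",
  ifelse(k1 == "disease" & k2 == "disease", "DD",
  ifelse(k1 == "chemical" & k2 == "gene", "CG",
  ifelse(k1 == "disease" & k2 == "gene", "DG", "DC")))))
}

#' All-pairs Jaccard table
#'
#' Computes the Jaccard coefficient for every unordered pair of distinct
#' nodes (optionally restricted to the requested pair classes), labelled
#' with the pair class (DG, DC, CG, GG, CC, DD) and whether the pair is an
#' edge of the network.
#'
#' @param net An [interaction_network()].
#' @param classes Optional character vector of pair-class codes to keep.
#' @return Data frame with columns `a`, `b`, `pair_class`, `linked`,
#'   `coefficient`.
#' @export
jaccard_table <- function(net, classes = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  n <- nrow(net$nodes)
  if (n < 2) {
    return(data.frame(a = character(), b = character(), pair_class = character(),
                      linked = logical(), coefficient = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- net$nodes$id
  kinds <- net$nodes$kind
  jm <- jaccard_matrix(net)
  ut <- which(upper.tri(jm), arr.ind = TRUE)
  df <- data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
                   pair_class = pair_code_from_kinds(kinds[ut[, 1]], kinds[ut[, 2]]),
                   coefficient = jm[ut], stringsAsFactors = FALSE)
  ek <- edge_key(net$edges$a, net$edges$b)
  df$linked <- edge_key(df$a, df$b) %in% ek
  if (!is.null(classes)) df <- df[df$pair_class %in% classes, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("a", "b", "pair_class", "linked", "coefficient")]
}

#' Compare Jaccard similarity of linked and unlinked node pairs
#'
#' For each requested pair class, splits the all-pairs Jaccard coefficients
#' by linked status and performs a one-sided Mann-Whitney U test (normal
#' approximation with tie and continuity correction) of the alternative
#' that linked pairs are stochastically more similar than unlinked pairs.
#'
#' @param net An [interaction_network()].
#' @param classes Pair-class codes, by default the three disease-related
#'   classes `DG`, `DC`, `CG`.
#' @return Data frame with one row per class: `pair_class`, `n_linked`,
#'   `n_unlinked`, `median_linked`, `median_unlinked`, `u_statistic`,
#'   `p_value`.
#' @export
compare_linked_unlinked <- function(net, classes = c("DG", "DC", "CG")) {
  tab <- jaccard_table(net, classes)
  out <- lapply(classes, function(cl) {
    x <- tab[tab$pair_class == cl, , drop = FALSE]
    if (nrow(x) == 0) stop("no node pairs of class ", cl)
    linked <- x$coefficient[x$linked]
    unlinked <- x$coefficient[!x$linked]
    if (length(linked) == 0 || length(unlinked) == 0) {
      stop("class ", cl, " is degenerate: needs at least one linked and one unlinked pair")
    }
    wt <- suppressWarnings(wilcox.test(linked, unlinked, alternative = "greater",
                                       exact = FALSE, correct = TRUE))
    data.frame(pair_class = cl, n_linked = length(linked),
               n_unlinked = length(unlinked),
               median_linked = median(linked),
               median_unlinked = median(unlinked),
               u_statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentile rank of a pair's similarity within a sub-network
#'
#' Ranks the Jaccard coefficient of a node pair against the coefficients of
#' all *other* unordered pairs of the sub-network, as a mid-rank percentile
#' (fraction of other coefficients strictly smaller, plus half the ties,
#' times 100), and assigns the band: lower25 for percentiles in \[0, 25\],
#' middle for (25, 75\], upper25 for (75, 100\].
#'
#' @param subnet An [interaction_network()] with at least 3 nodes.
#' @param a,b Node ids inside the sub-network.
#' @return List with `rank_percentile` and `band`.
#' @export
subnetwork_percentile <- function(subnet, a, b) {
  stopifnot(inherits(subnet, "interaction_network"))
  if (nrow(subnet$nodes) < 3) stop("sub-network must have at least 3 nodes")
  if (!all(c(a, b) %in% subnet$nodes$id)) {
    stop("pair (", a, ", ", b, ") is not inside the sub-network")
  }
  tab <- jaccard_table(subnet)
  key <- edge_key(tab$a, tab$b)
  target_key <- edge_key(a, b)
  hit <- key == target_key
  if (!any(hit)) stop("pair (", a, ", ", b, ") is not a valid unordered pair")
  x <- tab$coefficient[hit][1]
  others <- tab$coefficient[!hit]
  pct <- 100 * (sum(others < x) + 0.5 * sum(others == x)) / length(others)
  band <- if (pct <= 25) "lower25" else if (pct <= 75) "middle" else "upper25"
  list(rank_percentile = pct, band = band)
}

#' Mean similarity of each node to its sub-network
#'
#' For every node of the sub-network, the mean of its Jaccard coefficients
#' to all other sub-network nodes -- a scalar expressing how similar the
#' node is to the sub-network as a whole.
#'
#' @param subnet An [interaction_network()] with at least 2 nodes.
#' @return Named numeric vector (one mean per node).
#' @export
node_mean_similarity <- function(subnet) {
  stopifnot(inherits(subnet, "interaction_network"))
  n <- nrow(subnet$nodes)
  if (n < 2) stop("sub-network must have at least 2 nodes")
  jm <- jaccard_matrix(subnet)
  diag(jm) <- 0
  rowSums(jm) / (n - 1)
}

#' Calibration of the linked-versus-unlinked test under a permutation null
#'
#' Repeatedly permutes the linked/unlinked labels of one pair class and
#' re-runs the one-sided Mann-Whitney test, estimating the type-I error
#' rate of [compare_linked_unlinked()] at level `alpha`. Under the null the
#' rejection rate should be close to (and not exceed, beyond Monte-Carlo
#' error) `alpha`.
#'
#' @param net An [interaction_network()].
#' @param pair_class One pair-class code.
#' @param n_perm Number of label permutations.
#' @param alpha Nominal test level.
#' @param seed Integer seed.
#' @return List with `rejection_rate`, `alpha`, `n_perm` and the vector of
#'   permutation `p_values`.
#' @export
calibrate_linked_test <- function(net, pair_class = "CG", n_perm = 500,
                                  alpha = 0.01, seed = 1) {
  tab <- jaccard_table(net, pair_class)
  coef <- tab$coefficient
  n_linked <- sum(tab$linked)
  if (n_linked == 0 || n_linked == length(coef)) {
    stop("class ", pair_class, " is degenerate for permutation")
  }
  set.seed(seed)
  p <- vapply(seq_len(n_perm), function(i) {
    lab <- sample.int(length(coef), n_linked)
    suppressWarnings(wilcox.test(coef[lab], coef[-lab], alternative = "greater",
                                 exact = FALSE, correct = TRUE))$p.value
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), alpha = alpha, n_perm = n_perm,
       p_values = p)
}
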