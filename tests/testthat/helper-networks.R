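# Small constructors and independent oracles shared across test files.

# kinds: named character vector id -> kind; edges: data frame or list of
# c(a, b) pairs (raw_types optional third element).
make_net <- function(kinds, edges = NULL) {
  nodes <- data.frame(id = if (length(kinds)) names(kinds) else character(),
                      kind = unname(kinds), stringsAsFactors = FALSE)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(a = e[[1]], b = e[[2]],
                 raw_types = if (length(e) >= 3) e[[3]] else "",
                 stringsAsFactors = FALSE)
    }))
  }
  interaction_network(nodes, edges)
}

gene_clique <- function(n, prefix = "g") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  prs <- t(combn(ids, 2))
  make_net(setNames(rep("gene", n), ids),
           data.frame(a = prs[, 1], b = prs[, 2], stringsAsFactors = FALSE))
}

# two gene K4s joined through one low-weight bridge node
two_k4_bridge <- function() {
  ids <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4), "x1")
  e <- rbind(t(combn(sprintf("a%d", 1:4), 2)),
             t(combn(sprintf("b%d", 1:4), 2)),
             c("a1", "x1"), c("b1", "x1"))
  make_net(setNames(rep("gene", 9), ids),
           data.frame(a = e[, 1], b = e[, 2], stringsAsFactors = FALSE))
}

# independent brute-force Jaccard from explicit neighbour sets
oracle_jaccard <- function(net, a, b) {
  nb <- function(v) {
    e <- net$edges
    sort(unique(c(e$b[e$a == v], e$a[e$b == v])))
  }
  na <- nb(a); nbv <- nb(b)
  u <- length(union(na, nbv))
  if (u == 0) 0 else length(intersect(na, nbv)) / u
}

# random small gene/chemical/disease network for property tests
random_net <- function(n_nodes = 8, p = 0.4, seed = 1) {
  set.seed(seed)
  kinds <- sample(c("gene", "chemical", "disease"), n_nodes, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  ids <- sprintf("n%02d", seq_len(n_nodes))
  names(kinds) <- ids
  prs <- t(combn(ids, 2))
  ok <- !(kinds[prs[, 1]] == "disease" & kinds[prs[, 2]] == "disease")
  prs <- prs[ok & runif(nrow(prs)) < p, , drop = FALSE]
  make_net(kinds, if (nrow(prs)) data.frame(a = prs[, 1], b = prs[, 2],
                                            stringsAsFactors = FALSE))
}

# exhaustive average-linkage agglomeration oracle: recomputes every
# cluster-cluster similarity as the mean over cross pairs of the ORIGINAL
# similarity matrix, with the lexicographic tie-break on smallest member id.
oracle_average_linkage <- function(s, labels) {
  clusters <- as.list(seq_along(labels))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cs <- mean(s[clusters[[i]], clusters[[j]], drop = FALSE])
      mi <- min(labels[clusters[[i]]]); mj <- min(labels[clusters[[j]]])
      cand <- list(i = i, j = j, sim = cs, l1 = min(mi, mj), l2 = max(mi, mj))
      if (is.null(best) || cs > best$sim + 1e-12 ||
          (abs(cs - best$sim) <= 1e-12 &&
           (cand$l1 < best$l1 || (cand$l1 == best$l1 && cand$l2 < best$l2)))) {
        best <- cand
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(labels[c(clusters[[best$i]], clusters[[best$j]])]),
           similarity = best$sim)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# cluster sets at a cut, independent of merge order: leaves of each merge
merge_member_sets <- function(tree) {
  n <- tree$n_leaves
  out <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- tree$merge[k, ]
    leaves <- integer()
    for (c in kids) leaves <- c(leaves, if (c < 0) -c else out[[c]])
    out[[k]] <- leaves
  }
  lapply(out, function(i) sort(tree$labels[i]))
}

set_jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

write_triples_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
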