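test_that("binary matrix mirrors the adjacency with self-loops on the diagonal", {
  tri <- gene_clique(3)
  m <- build_binary_matrix(tri)
  expect_equal(sum(m) - sum(diag(m)), 6)
  expect_equal(unname(diag(m)), rep(0, 3))

  loop <- make_net(c(g1 = "gene", g2 = "gene"),
                   list(c("g1", "g1"), c("g1", "g2")))
  ml <- build_binary_matrix(loop)
  expect_equal(ml["g1", "g1"], 1)
  expect_equal(ml["g2", "g2"], 0)
  expect_identical(ml, t(ml))

  b <- generate_bundle(synthesis_config(seed = 13, n_genes = 30,
                                        n_chemicals = 30, n_diseases = 10,
                                        n_planted_clusters = 1,
                                        planted_cluster_size = 5))
  net <- bundle_network(b)
  mm <- build_binary_matrix(net)
  degs <- vapply(rownames(mm), function(v) length(neighbor_set(net, v)), 1)
  expect_equal(unname(rowSums(mm)), unname(degs))
  expect_error(build_binary_matrix(make_net(character())), "empty")
})

test_that("uncentered correlation matches hand arithmetic", {
  expect_equal(uncentered_correlation(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(uncentered_correlation(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(uncentered_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(uncentered_correlation(c(0, 0), c(1, 1)), 0)
  expect_error(uncentered_correlation(1:3, 1:4), "equal length")
  # self-similarity is 1 unless all-zero
  for (seed in 1:5) {
    set.seed(seed)
    v <- rbinom(10, 1, 0.5)
    if (sum(v)) expect_equal(uncentered_correlation(v, v), 1)
  }
})

test_that("agglomeration matches the exhaustive oracle on small matrices", {
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(4:8, 1)
    mat <- matrix(rbinom(n * 12, 1, 0.4), n, 12)
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
    if (nrow(mat) < 3) next
    rownames(mat) <- sprintf("r%02d", seq_len(nrow(mat)))
    storage.mode(mat) <- "double"
    tree <- average_linkage(mat)
    s <- outer(seq_len(nrow(mat)), seq_len(nrow(mat)),
               Vectorize(function(i, j) uncentered_correlation(mat[i, ], mat[j, ])))
    oracle <- oracle_average_linkage(s, rownames(mat))
    trees <- merge_member_sets(tree)
    for (k in seq_along(oracle)) {
      expect_equal(trees[[k]], oracle[[k]]$members)
      expect_equal(tree$similarity[k], oracle[[k]]$similarity, tolerance = 1e-10)
    }
    # merge similarities are non-increasing
    expect_true(all(diff(tree$similarity) <= 1e-10))
    # independent cross-check of merge heights against stats::hclust
    hc <- stats::hclust(stats::as.dist(1 - s), method = "average")
    expect_equal(sort(tree$similarity), sort(1 - hc$height), tolerance = 1e-10)
  }
})

test_that("identical rows merge first and row permutation does not change cuts", {
  mat <- rbind(r1 = c(1, 1, 0, 0), r2 = c(1, 1, 0, 0), r3 = c(0, 0, 1, 1))
  tree <- average_linkage(mat)
  expect_equal(tree$similarity[1], 1)
  expect_setequal(merge_member_sets(tree)[[1]], c("r1", "r2"))

  set.seed(7)
  mat2 <- matrix(rbinom(60, 1, 0.5), 6, 10)
  rownames(mat2) <- sprintf("x%d", 1:6)
  mat2 <- mat2[rowSums(mat2) > 0, , drop = FALSE]
  storage.mode(mat2) <- "double"
  tree_a <- average_linkage(mat2)
  perm <- sample(nrow(mat2))
  tree_b <- average_linkage(mat2[perm, , drop = FALSE])
  for (t in c(0.2, 0.5, 0.8)) {
    ca <- cut_at_similarity(tree_a, t)$clusters
    cb <- cut_at_similarity(tree_b, t)$clusters
    expect_setequal(lapply(ca, paste, collapse = ","),
                    lapply(cb, paste, collapse = ","))
  }
  expect_error(average_linkage(mat2[1, , drop = FALSE]), "at least 2")
})

test_that("threshold cuts return maximal subtrees of high-similarity merges", {
  mat <- rbind(a1 = c(1, 1, 1, 0, 0, 0), a2 = c(1, 1, 0, 0, 0, 0),
               b1 = c(0, 0, 0, 1, 1, 1), b2 = c(0, 0, 0, 1, 1, 0),
               c1 = c(1, 0, 0, 1, 0, 0))
  tree <- average_linkage(mat)
  cut_hi <- cut_at_similarity(tree, 0.75)
  expect_setequal(lapply(cut_hi$clusters, paste, collapse = ","),
                  list("a1,a2", "b1,b2"))
  expect_equal(cut_hi$min_size, 2)
  # a threshold above the top merge yields no clusters
  cut_top <- cut_at_similarity(tree, max(tree$similarity) + 1e-9)
  expect_equal(cut_top$n_clusters, 0)
  # threshold 0 clusters everything into the root's components
  cut0 <- cut_at_similarity(tree, 0)
  expect_equal(sum(lengths(cut0$clusters)), tree$n_leaves)
  expect_error(cut_at_similarity(tree, 1.2), "\\[0, 1\\]")
})

test_that("clustered-node curve is monotone and matches per-threshold cuts", {
  b <- generate_bundle(synthesis_config(seed = 29, n_genes = 30,
                                        n_chemicals = 40, n_diseases = 12,
                                        n_planted_clusters = 2,
                                        planted_cluster_size = 6))
  tree <- average_linkage(build_binary_matrix(bundle_network(b)))
  grid <- seq(0, 1, by = 0.1)
  curve <- clustered_node_curve(tree, grid)
  expect_true(all(diff(curve$n_clustered_nodes) <= 0))
  for (i in seq_along(grid)) {
    expect_equal(curve$n_clustered_nodes[i],
                 sum(lengths(cut_at_similarity(tree, grid[i])$clusters)))
  }
  expect_error(clustered_node_curve(tree, numeric()), "non-empty")
})

test_that("planted blocks are recovered by the 0.4-threshold cut", {
  cfg <- synthesis_config(seed = 37, n_planted_clusters = 3,
                          planted_cluster_size = 8,
                          planted_within_density = 0.9, reference_overlap = 0,
                          density = c(CG = 0.005, GG = 0.005,
                                      DG = 0.005, DC = 0.005))
  b <- generate_bundle(cfg)
  net <- bundle_network(b)
  tree <- average_linkage(build_binary_matrix(net))
  cut <- cut_at_similarity(tree, 0.4)
  for (block in b$truth$clusters) {
    block <- intersect(block, net$nodes$id)
    best <- max(vapply(cut$clusters, function(s) set_jaccard(s, block), 1))
    expect_gte(best, 0.8)
  }
})

test_that("inflection detection finds constructed knees and ignores lines", {
  grid <- seq(0, 1, by = 0.05)
  linear <- data.frame(threshold = grid,
                       n_clustered_nodes = 200 - 150 * grid)
  expect_length(detect_inflections(linear), 0)

  # single knee at 0.4: steep before, shallow after
  y1 <- ifelse(grid <= 0.4, 200 - 400 * grid, 40 - 40 * (grid - 0.4))
  knee1 <- detect_inflections(data.frame(threshold = grid, n_clustered_nodes = y1))
  expect_equal(knee1, 0.4)

  # two knees at 0.3 and 0.7
  y2 <- ifelse(grid <= 0.3, 300 - 500 * grid,
        ifelse(grid <= 0.7, 150 - 50 * (grid - 0.3), 130 - 300 * (grid - 0.7)))
  knee2 <- detect_inflections(data.frame(threshold = grid, n_clustered_nodes = y2))
  expect_equal(knee2, c(0.3, 0.7))

  expect_error(detect_inflections(linear[1:4, ]), "at least 5")
})

test_that("CDT and GTR exports are well-formed text artifacts", {
  mat <- rbind(a = c(1, 1, 0), b = c(1, 1, 1), c = c(0, 1, 1))
  colnames(mat) <- c("a", "b", "c")
  tree <- average_linkage(mat)
  gtr <- tempfile(fileext = ".gtr"); cdt <- tempfile(fileext = ".cdt")
  export_gtr(tree, gtr)
  export_cdt(tree, mat, cdt)
  glines <- readLines(gtr)
  expect_length(glines, 2)
  expect_match(glines[1], "^NODE1X\t")
  clines <- readLines(cdt)
  expect_length(clines, 2 + 3)
  expect_match(clines[1], "^GID\t")
})
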