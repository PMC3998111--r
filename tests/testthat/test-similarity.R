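test_that("neighbour sets include self only through self-interactions", {
  net <- make_net(c(g1 = "gene", g2 = "gene", g3 = "gene", g4 = "gene"),
                  list(c("g1", "g1"), c("g1", "g2"), c("g1", "g3")))
  expect_setequal(neighbor_set(net, "g1"), c("g1", "g2", "g3"))
  expect_equal(neighbor_set(net, "g2"), "g1")
  expect_equal(neighbor_set(net, "g4"), character())
  expect_error(neighbor_set(net, "nope"), "unknown node")

  star <- make_net(c(h = "gene", l1 = "gene", l2 = "gene", l3 = "gene",
                     l4 = "gene", l5 = "gene"),
                   lapply(paste0("l", 1:5), function(l) c("h", l)))
  expect_setequal(neighbor_set(star, "h"), paste0("l", 1:5))
})

test_that("Jaccard coefficient matches hand arithmetic and the brute-force oracle", {
  # N(a)={x,y,z}, N(b)={y,z,w} -> 2/4
  net <- make_net(c(a = "gene", b = "gene", x = "gene", y = "gene",
                    z = "gene", w = "gene"),
                  list(c("a", "x"), c("a", "y"), c("a", "z"),
                       c("b", "y"), c("b", "z"), c("b", "w")))
  expect_equal(jaccard_coefficient(net, "a", "b"), 0.5)
  # identical nonempty sets -> 1; disjoint -> 0
  expect_equal(jaccard_coefficient(net, "y", "z"), 1)
  expect_equal(jaccard_coefficient(net, "x", "w"), 0)

  for (seed in 1:6) {
    rnet <- random_net(10, 0.35, seed)
    tab <- jaccard_table(rnet)
    for (i in sample(nrow(tab), 12)) {
      expect_equal(tab$coefficient[i], oracle_jaccard(rnet, tab$a[i], tab$b[i]))
    }
    # symmetry
    expect_equal(jaccard_coefficient(rnet, tab$a[1], tab$b[1]),
                 jaccard_coefficient(rnet, tab$b[1], tab$a[1]))
  }
})

test_that("jaccard table classifies pairs and flags linked ones", {
  net <- make_net(c(g1 = "gene", c1 = "chemical", d1 = "disease"),
                  list(c("g1", "c1"), c("g1", "d1")))
  tab <- jaccard_table(net)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$pair_class, c("CG", "DG", "DC"))
  expect_equal(tab$linked[tab$pair_class == "DC"], FALSE)
  expect_true(all(tab$linked[tab$pair_class != "DC"]))
})

test_that("linked pairs separate from unlinked in the extreme case", {
  # two self-interacting gene cliques: within-clique (linked) pairs have
  # identical neighbour sets (coefficient 1), cross-clique (unlinked) pairs
  # share nothing (coefficient 0)
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  kinds <- setNames(rep("gene", 10), ids)
  cl <- function(v) c(lapply(v, function(x) c(x, x)),
                      apply(combn(v, 2), 2, identity, simplify = FALSE))
  net <- make_net(kinds, c(cl(ids[1:5]), cl(ids[6:10])))
  cmp <- compare_linked_unlinked(net, "GG")
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$median_linked, 1)
  expect_equal(cmp$median_unlinked, 0)
  expect_error(compare_linked_unlinked(net, "DG"), "DG")
})

test_that("type-I error of the linked/unlinked test is near nominal under permutation", {
  b <- generate_bundle(synthesis_config(seed = 5, n_genes = 60, n_chemicals = 80,
                                        n_diseases = 20, n_planted_clusters = 2,
                                        planted_cluster_size = 6))
  net <- bundle_network(b)
  cal <- calibrate_linked_test(net, "CG", n_perm = 200, alpha = 0.05, seed = 9)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(cal$rejection_rate, 0.05 + 3 * se)
})

test_that("sub-network percentile ranking uses mid-rank against the other pairs", {
  # 6-node sub-network, brute-force ranking of all 15 pairs
  set.seed(3)
  sn <- random_net(6, 0.5, seed = 3)
  tab <- jaccard_table(sn)
  for (i in seq_len(nrow(tab))) {
    r <- subnetwork_percentile(sn, tab$a[i], tab$b[i])
    others <- tab$coefficient[-i]
    expect_equal(r$rank_percentile,
                 100 * (sum(others < tab$coefficient[i]) +
                          0.5 * sum(others == tab$coefficient[i])) / length(others))
  }
  # unique maximum -> percentile 100, upper band
  star <- make_net(c(h = "gene", l1 = "gene", l2 = "gene", l3 = "gene"),
                   list(c("h", "l1"), c("h", "l2"), c("h", "l3")))
  # leaves share exactly {h}: coefficient 1, all ties; hub-leaf pairs are 0
  r <- subnetwork_percentile(star, "l1", "l2")
  expect_equal(r$band, "upper25")
  # all-coefficients-equal network -> percentile 50, middle band
  tri <- gene_clique(3)
  r2 <- subnetwork_percentile(tri, "g01", "g02")
  expect_equal(r2$rank_percentile, 50)
  expect_equal(r2$band, "middle")
  expect_error(subnetwork_percentile(tri, "g01", "zz"), "not inside")
})

test_that("node mean similarity averages over all other sub-network nodes", {
  # K1,4 star: leaf-leaf coefficient 1 (identical sets {hub}), hub-leaf 0
  star <- make_net(c(h = "gene", l1 = "gene", l2 = "gene", l3 = "gene",
                     l4 = "gene"),
                   lapply(paste0("l", 1:4), function(l) c("h", l)))
  ms <- node_mean_similarity(star)
  expect_equal(unname(ms["h"]), 0)
  expect_equal(unname(ms[paste0("l", 1:4)]), rep(0.75, 4))

  # self-interacting clique: identical neighbour sets, every coefficient 1
  ids <- sprintf("k%d", 1:5)
  k5 <- make_net(setNames(rep("gene", 5), ids),
                 c(lapply(ids, function(x) c(x, x)),
                   apply(combn(ids, 2), 2, identity, simplify = FALSE)))
  expect_equal(unname(node_mean_similarity(k5)), rep(1, 5))

  # random sub-network equals brute-force averaging
  rn <- random_net(8, 0.4, seed = 12)
  ms2 <- node_mean_similarity(rn)
  for (v in names(ms2)) {
    others <- setdiff(rn$nodes$id, v)
    expect_equal(unname(ms2[v]),
                 mean(vapply(others, function(u) oracle_jaccard(rn, v, u), 1)))
  }
  expect_error(node_mean_similarity(make_net(c(a = "gene"))), "at least 2")
})

test_that("adding an edge never shrinks neighbourhood intersections", {
  for (seed in 1:4) {
    net <- random_net(9, 0.3, seed)
    tab <- jaccard_table(net)
    open <- tab[!tab$linked, , drop = FALSE]
    if (nrow(open) == 0) next
    pick <- open[1, ]
    nodes <- net$nodes
    edges2 <- rbind(net$edges[, c("a", "b", "raw_types")],
                    data.frame(a = pick$a, b = pick$b, raw_types = ""))
    net2 <- interaction_network(nodes, edges2)
    m1 <- as.matrix(tripnet:::neighbor_matrix(net))
    m2 <- as.matrix(tripnet:::neighbor_matrix(net2))
    inter1 <- m1 %*% m1
    inter2 <- m2 %*% m2
    expect_true(all(inter2 >= inter1))
  }
})
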