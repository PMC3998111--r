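# hand-built 6-row raw fixture used by the filter rule traces
fixture_tables <- function() {
  raw_tables(
    chem_gene = data.frame(
      chemical = c("c1", "c2", "c3"),
      gene = c("g1", "g2", "g1"),
      interaction_text = c("c1 results in increased expression of g1",
                           "c2 affects the reaction of g2", ""),
      raw_types = c("increases", "affects", "decreases"),
      stringsAsFactors = FALSE),
    chem_disease = data.frame(
      chemical = c("c1", "c3"),
      disease = c("d1", "d9"),
      direct_evidence = c("therapeutic", "marker/mechanism"),
      stringsAsFactors = FALSE),
    gene_disease = data.frame(
      gene = c("g1", "g3"),
      disease = c("d1", "d1"),
      direct_evidence = c("marker/mechanism", "marker/mechanism"),
      stringsAsFactors = FALSE),
    ppi = data.frame(gene_a = c("g1", "g2", "g3"),
                     gene_b = c("g3", "g4", "g4"),
                     stringsAsFactors = FALSE))
}

test_that("disease-context filtering keeps only entities within two steps of a disease", {
  t <- fixture_tables()
  f <- filter_to_disease_context(t, "d1")
  # c3-d9: d9 not in context -> dropped; c3 keeps its chem_gene row via g1
  expect_equal(nrow(f$chem_disease), 1)
  expect_equal(f$chem_disease$chemical, "c1")
  # g2 has no disease link and its chemical c2 has none either -> row dropped
  expect_false("c2" %in% f$chem_gene$chemical)
  # c3-g1 retained through g1's direct disease link
  expect_true(any(f$chem_gene$chemical == "c3"))
  # PPI: g1-g3 kept (both retained, both direct); g2-g4 and g3-g4 dropped
  expect_equal(nrow(f$ppi), 1)
  expect_equal(sort(c(f$ppi$gene_a, f$ppi$gene_b)), c("g1", "g3"))
  expect_error(filter_to_disease_context(t, character()), "non-empty")
})

test_that("filtering is the identity when every entity is disease-linked", {
  t <- raw_tables(
    chem_gene = data.frame(chemical = "c1", gene = "g1",
                           interaction_text = "", raw_types = "increases"),
    chem_disease = data.frame(chemical = "c1", disease = "d1",
                              direct_evidence = "therapeutic"),
    gene_disease = data.frame(gene = "g1", disease = "d1",
                              direct_evidence = "marker/mechanism"),
    ppi = data.frame(gene_a = "g1", gene_b = "g1"))
  f <- filter_to_disease_context(t, "d1")
  expect_identical(f$chem_gene, t$chem_gene)
  expect_identical(f$ppi, t$ppi)
})

test_that("bidirectional deduplication merges orientations and is idempotent", {
  rows <- data.frame(
    chemical = c("c1", "c1", "c2", "c2", "c3", "c4"),
    gene = c("g1", "g1", "g2", "g2", "g3", "g4"),
    raw_types = c("increases", "decreases", "affects", "affects", "", "therapeutic"),
    stringsAsFactors = FALSE)
  dd <- dedup_bidirectional(rows)
  expect_equal(dd$report$n_directed_chem_gene, 6)
  expect_equal(dd$report$n_unique_after_dedup, 4)
  expect_equal(dd$edges$raw_types[dd$edges$chemical == "c1"],
               "decreases;increases")
  again <- dedup_bidirectional(dd$edges)
  expect_identical(again$edges, dd$edges)
  expect_equal(again$report$n_directed_chem_gene,
               again$report$n_unique_after_dedup)

  empty <- dedup_bidirectional(rows[0, ])
  expect_equal(empty$report$n_unique_after_dedup, 0)
})

test_that("chemical co-occurrence mentions yield typed chemical-chemical edges", {
  rows <- data.frame(
    chemical = c("aspirinX", "chemB", "chemC"),
    gene = c("G", "G", "H"),
    interaction_text = c("aspirinX inhibits reaction of chemB with G",
                         "chemB binds G", ""),
    raw_types = c("decreases", "increases", "affects"),
    stringsAsFactors = FALSE)
  cc <- infer_chemical_chemical(rows, c("aspirinX", "chemB", "chemC"))
  expect_equal(nrow(cc), 1)
  expect_equal(cc$a, "aspirinX")
  expect_equal(cc$b, "chemB")
  expect_equal(cc$raw_types, "decreases")

  # no secondary mentions
  expect_equal(nrow(infer_chemical_chemical(rows[3, ], c("chemB", "chemC"))), 0)

  # conflicting types on the same inferred pair merge to mixed polarity
  rows2 <- data.frame(
    chemical = c("ca", "ca"), gene = c("g1", "g2"),
    interaction_text = c("ca promotes cb with g1", "ca blocks cb with g2"),
    raw_types = c("increases", "decreases"), stringsAsFactors = FALSE)
  cc2 <- infer_chemical_chemical(rows2, c("ca", "cb"))
  expect_equal(nrow(cc2), 1)
  expect_equal(cc2$raw_types, "decreases;increases")
  expect_equal(classify_polarity(cc2$raw_types), "mixed")

  # word-boundary matching: substrings of longer names do not fire
  rows3 <- data.frame(chemical = "cx", gene = "g",
                      interaction_text = "cx interacts with chemBase complex",
                      raw_types = "affects", stringsAsFactors = FALSE)
  expect_equal(nrow(infer_chemical_chemical(rows3, c("cx", "chemB"))), 0)
})

test_that("whole network composes the stages and carries no chemical-chemical edges", {
  b <- generate_bundle(synthesis_config(seed = 7, n_genes = 20, n_chemicals = 30,
                                        n_diseases = 5, n_planted_clusters = 1,
                                        planted_cluster_size = 6,
                                        cooccurrence_rate = 0.3))
  net <- build_whole_network(b$tables, b$diseases)
  s <- network_summary(net)
  expect_equal(s$link_counts[["chemical-chemical"]], 0)

  # independent recount from the filtered tables
  f <- filter_to_disease_context(b$tables, b$diseases)
  dd <- dedup_bidirectional(f$chem_gene)
  expect_equal(s$link_counts[["gene-chemical"]], nrow(dd$edges))
  gg_pairs <- unique(paste(pmin(f$ppi$gene_a, f$ppi$gene_b),
                           pmax(f$ppi$gene_a, f$ppi$gene_b)))
  expect_equal(s$link_counts[["gene-gene"]], length(gg_pairs))
  expect_equal(s$link_counts[["disease-chemical"]],
               length(unique(paste(f$chem_disease$chemical, f$chem_disease$disease))))

  expect_error(build_whole_network(b$tables, character()), "non-empty")
})

test_that("therapeutic construction applies the chemical and gene inclusion rules", {
  t <- raw_tables(
    chem_gene = data.frame(
      chemical = c("cT", "cM", "cT2", "cT"),
      gene = c("g1", "g2", "g3", "g3"),
      interaction_text = c("", "", "cT2 enhances cT binding of g3", ""),
      raw_types = c("increases", "decreases", "increases", "affects"),
      stringsAsFactors = FALSE),
    chem_disease = data.frame(
      chemical = c("cT", "cM", "cT2"),
      disease = c("d1", "d1", "d1"),
      direct_evidence = c("therapeutic", "marker/mechanism", "both"),
      stringsAsFactors = FALSE),
    gene_disease = data.frame(gene = "g2", disease = "d1",
                              direct_evidence = "marker/mechanism",
                              stringsAsFactors = FALSE),
    ppi = data.frame(gene_a = character(), gene_b = character(),
                     stringsAsFactors = FALSE))
  net <- build_therapeutic_network(t, "d1")
  chems <- net$nodes$id[net$nodes$kind == "chemical"]
  genes <- net$nodes$id[net$nodes$kind == "gene"]
  # marker/mechanism-only chemical excluded; "both" counts as therapeutic
  expect_setequal(chems, c("cT", "cT2"))
  # g2 linked only to the excluded chemical -> excluded despite disease link
  expect_setequal(genes, c("g1", "g3"))
  # co-occurrence between two retained chemicals -> one chemical-chemical edge
  s <- network_summary(net)
  expect_equal(s$link_counts[["chemical-chemical"]], 1)
  expect_equal(attr(net, "build_report")$n_chem_chem_inferred, 1)
})

test_that("therapeutic network is a subgraph of the whole network except added CC edges", {
  b <- generate_bundle(synthesis_config(seed = 11, n_genes = 30, n_chemicals = 40,
                                        n_diseases = 10, n_planted_clusters = 1,
                                        planted_cluster_size = 6,
                                        cooccurrence_rate = 0.2))
  whole <- build_whole_network(b$tables, b$diseases)
  ther <- build_therapeutic_network(b$tables, b$diseases)
  expect_true(all(ther$nodes$id %in% whole$nodes$id))
  non_cc <- ther$edges[ther$edges$class != "chemical-chemical", ]
  whole_keys <- paste(whole$edges$a, whole$edges$b)
  expect_true(all(paste(non_cc$a, non_cc$b) %in% whole_keys))
})

test_that("raw tables survive a disk round trip", {
  t <- fixture_tables()
  d <- tempfile()
  write_raw_tables(t, d)
  back <- read_raw_tables(d)
  for (nm in names(unclass(t))) expect_identical(back[[nm]], t[[nm]])
  lp <- file.path(d, "diseases.txt")
  write_disease_list(c("d1", "d2"), lp)
  expect_equal(read_disease_list(lp), c("d1", "d2"))
})
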