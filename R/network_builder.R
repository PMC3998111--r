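#' Bundle raw curated association tables
#'
#' Container for the four input tables of the network-construction pipeline,
#' in the dialect of curated toxicogenomics databases:
#' \describe{
#'   \item{chem_gene}{`chemical`, `gene`, `interaction_text` (free text that
#'     may mention secondary chemicals), `raw_types` (semicolon-joined
#'     interaction types).}
#'   \item{chem_disease}{`chemical`, `disease`, `direct_evidence` in
#'     \{therapeutic, marker/mechanism, both, none\}.}
#'   \item{gene_disease}{`gene`, `disease`, `direct_evidence`.}
#'   \item{ppi}{`gene_a`, `gene_b` protein-protein interaction pairs
#'     (self-pairs permitted).}
#' }
#'
#' @param chem_gene,chem_disease,gene_disease,ppi Data frames as above.
#' @return An object of class `raw_tables`.
#' @export
raw_tables <- function(chem_gene, chem_disease, gene_disease, ppi) {
  chem_gene <- as.data.frame(chem_gene, stringsAsFactors = FALSE)
  chem_disease <- as.data.frame(chem_disease, stringsAsFactors = FALSE)
  gene_disease <- as.data.frame(gene_disease, stringsAsFactors = FALSE)
  ppi <- as.data.frame(ppi, stringsAsFactors = FALSE)
  stopifnot(all(c("chemical", "gene") %in% names(chem_gene)),
            all(c("chemical", "disease", "direct_evidence") %in% names(chem_disease)),
            all(c("gene", "disease", "direct_evidence") %in% names(gene_disease)),
            all(c("gene_a", "gene_b") %in% names(ppi)))
  if (!"interaction_text" %in% names(chem_gene)) chem_gene$interaction_text <- ""
  if (!"raw_types" %in% names(chem_gene)) chem_gene$raw_types <- ""
  ev <- c(chem_disease$direct_evidence, gene_disease$direct_evidence)
  bad <- setdiff(unique(ev), c("therapeutic", "marker/mechanism", "both", "none"))
  if (length(bad)) stop("unknown direct_evidence value: ", paste(bad, collapse = ", "))
  all_names <- c(chem_gene$chemical, chem_gene$gene,
                 chem_disease$chemical, chem_disease$disease,
                 gene_disease$gene, gene_disease$disease,
                 ppi$gene_a, ppi$gene_b)
  if (any(!nzchar(trimws(all_names)))) stop("raw tables contain empty entity names")
  structure(list(chem_gene = chem_gene, chem_disease = chem_disease,
                 gene_disease = gene_disease, ppi = ppi),
            class = "raw_tables")
}

#' @export
print.raw_tables <- function(x, ...) {
  cat("raw_tables:",
      nrow(x$chem_gene), "chem-gene,",
      nrow(x$chem_disease), "chem-disease,",
      nrow(x$gene_disease), "gene-disease,",
      nrow(x$ppi), "PPI rows\n")
  invisible(x)
}

#' Read and write raw association tables
#'
#' `read_raw_tables()` reads `chem_gene.tsv`, `chem_disease.tsv`,
#' `gene_disease.tsv` and `ppi.tsv` from a directory; `write_raw_tables()`
#' writes them. A disease list (`diseases.txt`, one name per line) is
#' handled by `read_disease_list()` / `write_disease_list()`.
#'
#' @param dir Directory containing or receiving the four TSV files.
#' @return `read_raw_tables()`: a [raw_tables()] object.
#' @export
read_raw_tables <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                                      colClasses = "character", comment.char = "#")
  raw_tables(rd("chem_gene.tsv"), rd("chem_disease.tsv"),
             rd("gene_disease.tsv"), rd("ppi.tsv"))
}

#' @rdname read_raw_tables
#' @param tables A [raw_tables()] object.
#' @export
write_raw_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "raw_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wr(tables$chem_gene, "chem_gene.tsv")
  wr(tables$chem_disease, "chem_disease.tsv")
  wr(tables$gene_disease, "gene_disease.tsv")
  wr(tables$ppi, "ppi.tsv")
  invisible(dir)
}

#' @rdname read_raw_tables
#' @param path Path of the disease list file.
#' @export
read_disease_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_raw_tables
#' @param diseases Character vector of disease names.
#' @export
write_disease_list <- function(diseases, path) {
  writeLines(diseases, path)
  invisible(path)
}

#' Restrict raw tables to a disease context
#'
#' Implements the disease-context filter of the construction pipeline: an
#' entity (gene or chemical) is *directly linked* when it has at least one
#' association row to a disease in `diseases`. Disease-association rows to
#' unlisted diseases are dropped. A chemical-gene row is retained when at
#' least one of its endpoints is directly linked (so every retained entity
#' has a path of length at most 2 to a listed disease). A PPI row is
#' retained when both genes are retained and at least one of the pair is
#' directly disease-linked.
#'
#' @param tables A [raw_tables()] object.
#' @param diseases Non-empty character vector of disease names.
#' @return A filtered [raw_tables()] object.
#' @export
filter_to_disease_context <- function(tables, diseases) {
  stopifnot(inherits(tables, "raw_tables"))
  diseases <- unique(trimws(as.character(diseases)))
  diseases <- diseases[nzchar(diseases)]
  if (length(diseases) == 0) stop("disease set must be non-empty")

  cd <- tables$chem_disease[tables$chem_disease$disease %in% diseases, , drop = FALSE]
  gd <- tables$gene_disease[tables$gene_disease$disease %in% diseases, , drop = FALSE]
  direct_chems <- unique(cd$chemical)
  direct_genes <- unique(gd$gene)

  cg <- tables$chem_gene
  keep_cg <- cg$chemical %in% direct_chems | cg$gene %in% direct_genes
  cg <- cg[keep_cg, , drop = FALSE]

  retained_genes <- union(direct_genes, cg$gene)
  ppi <- tables$ppi
  keep_ppi <- ppi$gene_a %in% retained_genes & ppi$gene_b %in% retained_genes &
    (ppi$gene_a %in% direct_genes | ppi$gene_b %in% direct_genes)
  ppi <- ppi[keep_ppi, , drop = FALSE]

  rownames(cg) <- rownames(cd) <- rownames(gd) <- rownames(ppi) <- NULL
  raw_tables(cg, cd, gd, ppi)
}

#' Collapse directed chemical-gene rows to undirected edges
#'
#' Batch queries in both orientations (chemical-gene and gene-chemical)
#' produce duplicate records of the same underlying interaction. This
#' collapses the rows to one undirected edge per unordered
#' (chemical, gene) pair, taking the union of interaction types across
#' orientations, and reports the before/after counts.
#'
#' @param chem_gene Data frame with columns `chemical`, `gene`, `raw_types`
#'   (and optionally `interaction_text`).
#' @return A list with `edges` (one row per unique pair, `interaction_text`
#'   values concatenated with `" | "`) and `report` (a list:
#'   `n_directed_chem_gene`, `n_unique_after_dedup`).
#' @export
dedup_bidirectional <- function(chem_gene) {
  chem_gene <- as.data.frame(chem_gene, stringsAsFactors = FALSE)
  if (!"raw_types" %in% names(chem_gene))
    chem_gene$raw_types <- rep("", nrow(chem_gene))
  if (!"interaction_text" %in% names(chem_gene))
    chem_gene$interaction_text <- rep("", nrow(chem_gene))
  n_in <- nrow(chem_gene)
  if (n_in == 0) {
    return(list(edges = chem_gene,
                report = list(n_directed_chem_gene = 0L, n_unique_after_dedup = 0L)))
  }
  key <- paste(chem_gene$chemical, chem_gene$gene, sep = "\r")
  grp <- split(seq_len(n_in), key)
  idx <- vapply(grp, `[`, integer(1), 1L)
  # keep first-seen row order for determinism
  ord <- order(idx)
  grp <- grp[ord]; idx <- idx[ord]
  edges <- chem_gene[idx, , drop = FALSE]
  edges$raw_types <- vapply(grp, function(i)
    join_semi(list(unlist(split_semi(chem_gene$raw_types[i])))), character(1))
  edges$interaction_text <- vapply(grp, function(i) {
    tx <- unique(chem_gene$interaction_text[i])
    paste(tx[nzchar(tx)], collapse = " | ")
  }, character(1))
  rownames(edges) <- NULL
  list(edges = edges,
       report = list(n_directed_chem_gene = n_in,
                     n_unique_after_dedup = nrow(edges)))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Infer chemical-chemical links from co-occurrence in interaction text
#'
#' A secondary chemical *co-occurs* with a chemical-gene interaction when
#' its name appears (word-boundary delimited, case-insensitive) in the
#' interaction's free-text description. Each co-occurrence yields an
#' undirected chemical-chemical edge between the host chemical and the
#' secondary chemical, typed with the interaction types of the hosting
#' chemical-gene row; duplicate pairs merge by union of types.
#'
#' @param chem_gene Data frame with columns `chemical`, `gene`,
#'   `interaction_text`, `raw_types`.
#' @param vocabulary Character vector of known chemical names to match.
#' @return Data frame of inferred edges: `a`, `b`, `raw_types`.
#' @export
infer_chemical_chemical <- function(chem_gene, vocabulary) {
  chem_gene <- as.data.frame(chem_gene, stringsAsFactors = FALSE)
  vocabulary <- unique(as.character(vocabulary))
  empty <- data.frame(a = character(), b = character(), raw_types = character(),
                      stringsAsFactors = FALSE)
  if (nrow(chem_gene) == 0 || length(vocabulary) == 0) return(empty)
  txt <- chem_gene$interaction_text
  if (is.null(txt)) return(empty)
  # match longer names first so that a name contained in a longer synonym
  # is not double-reported for the same span
  vocabulary <- vocabulary[order(-nchar(vocabulary), vocabulary)]
  has_text <- which(!is.na(txt) & nzchar(txt))
  if (length(has_text) == 0) return(empty)
  out_a <- character(); out_b <- character(); out_t <- character()
  for (v in vocabulary) {
    pat <- paste0("\\b", escape_regex(v), "\\b")
    m <- has_text[grepl(pat, txt[has_text], ignore.case = TRUE, perl = TRUE)]
    m <- m[chem_gene$chemical[m] != v]
    if (length(m)) {
      out_a <- c(out_a, chem_gene$chemical[m])
      out_b <- c(out_b, rep(v, length(m)))
      out_t <- c(out_t, chem_gene$raw_types[m])
    }
  }
  if (length(out_a) == 0) return(empty)
  p <- canonical_pair(out_a, out_b)
  key <- paste(p$a, p$b, sep = "\r")
  grp <- split(seq_along(key), key)
  df <- data.frame(
    a = vapply(grp, function(i) p$a[i[1]], character(1)),
    b = vapply(grp, function(i) p$b[i[1]], character(1)),
    raw_types = vapply(grp, function(i)
      join_semi(list(unlist(split_semi(out_t[i])))), character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

evidence_to_types <- function(ev) {
  ifelse(ev == "both", "marker/mechanism;therapeutic",
  ifelse(ev == "none", "", ev))
}

assemble_network <- function(cg_edges, cd, gd, ppi, cc = NULL, diseases = NULL) {
  nd <- function(ids, kind) data.frame(id = ids, kind = rep(kind, length(ids)),
                                       stringsAsFactors = FALSE)
  ed <- function(a, b, types) data.frame(a = a, b = b,
                                         raw_types = rep_len(types, length(a)),
                                         stringsAsFactors = FALSE)
  nodes <- unique(rbind(
    nd(cg_edges$chemical, "chemical"), nd(cg_edges$gene, "gene"),
    nd(cd$chemical, "chemical"), nd(cd$disease, "disease"),
    nd(gd$gene, "gene"), nd(gd$disease, "disease"),
    nd(c(ppi$gene_a, ppi$gene_b), "gene"),
    if (!is.null(cc)) nd(c(cc$a, cc$b), "chemical"),
    if (!is.null(diseases)) nd(diseases, "disease")))
  edges <- rbind(
    ed(cg_edges$chemical, cg_edges$gene, cg_edges$raw_types),
    ed(cd$chemical, cd$disease, evidence_to_types(cd$direct_evidence)),
    ed(gd$gene, gd$disease, evidence_to_types(gd$direct_evidence)),
    ed(ppi$gene_a, ppi$gene_b, ""),
    if (!is.null(cc)) ed(cc$a, cc$b, cc$raw_types))
  interaction_network(nodes, edges)
}

#' Build the whole disease-context network
#'
#' Composes the construction stages: disease-context filtering,
#' bidirectional deduplication of chemical-gene rows, and the merge of
#' disease-association and PPI edges. The whole network carries no
#' chemical-chemical edges (those are specific to the therapeutic subset).
#' A build report (directed/unique chemical-gene counts and node counts per
#' kind) is attached as attribute `"build_report"`.
#'
#' @param tables A [raw_tables()] object.
#' @param diseases Non-empty character vector of context diseases.
#' @return An [interaction_network()].
#' @export
build_whole_network <- function(tables, diseases) {
  ft <- filter_to_disease_context(tables, diseases)
  dd <- dedup_bidirectional(ft$chem_gene)
  net <- assemble_network(dd$edges, ft$chem_disease, ft$gene_disease, ft$ppi)
  rep <- dd$report
  rep$n_chem_chem_inferred <- 0L
  nk <- table(factor(net$nodes$kind, levels = node_kinds()))
  rep$filtered_node_counts <- setNames(as.integer(nk), names(nk))
  attr(net, "build_report") <- rep
  net
}

#' Build the therapeutic network
#'
#' The therapeutic subset of the disease-context network: chemicals are
#' retained only when they carry at least one therapeutic disease
#' association (`direct_evidence` therapeutic or both); genes are retained
#' only when linked to a retained chemical by a chemical-gene edge; all
#' context diseases of the whole network are kept. Chemical-chemical edges
#' inferred from co-occurrence mentions among the retained chemicals are
#' added ([infer_chemical_chemical()]).
#'
#' @inheritParams build_whole_network
#' @return An [interaction_network()] with attribute `"build_report"`.
#' @export
build_therapeutic_network <- function(tables, diseases) {
  ft <- filter_to_disease_context(tables, diseases)
  cd <- ft$chem_disease
  ther_chems <- unique(cd$chemical[cd$direct_evidence %in% c("therapeutic", "both")])

  dd <- dedup_bidirectional(ft$chem_gene)
  cg <- dd$edges[dd$edges$chemical %in% ther_chems, , drop = FALSE]
  ther_genes <- unique(cg$gene)

  cd <- cd[cd$chemical %in% ther_chems, , drop = FALSE]
  gd <- ft$gene_disease[ft$gene_disease$gene %in% ther_genes, , drop = FALSE]
  ppi <- ft$ppi[ft$ppi$gene_a %in% ther_genes & ft$ppi$gene_b %in% ther_genes,
                , drop = FALSE]
  cc <- infer_chemical_chemical(cg, ther_chems)
  cc <- cc[cc$a %in% ther_chems & cc$b %in% ther_chems, , drop = FALSE]

  all_diseases <- unique(c(ft$chem_disease$disease, ft$gene_disease$disease))
  net <- assemble_network(cg, cd, gd, ppi, cc,
                          diseases = all_diseases)
  rep <- dd$report
  rep$n_chem_chem_inferred <- nrow(cc)
  nk <- table(factor(net$nodes$kind, levels = node_kinds()))
  rep$filtered_node_counts <- setNames(as.integer(nk), names(nk))
  attr(net, "build_report") <- rep
  net
}

#' Recompute printed network statistics from deposited triple files
#'
#' Given the whole-network and therapeutic-network edge-triple files (the
#' format of [save_triples()]), reloads both networks and recomputes the
#' publication-style statistics block: node/link totals, mean neighbours,
#' link probability, the MCODE complex count at the standard parameters,
#' matrix-cluster counts at the 0.7 and 0.4 similarity thresholds with the
#' maximum cluster size at 0.4, the linked disease-gene median Jaccard
#' coefficient, and the linked-versus-unlinked Mann-Whitney p-values for
#' the DG/DC/CG classes of the therapeutic network.
#'
#' @param whole_path,therapeutic_path Paths to the two triple TSV files.
#' @return A named list of computed statistics.
#' @export
reproduce_printed_statistics <- function(whole_path, therapeutic_path) {
  whole <- load_triples(whole_path)
  ther <- load_triples(therapeutic_path)
  sw <- network_summary(whole)
  st <- network_summary(ther)
  cmp <- compare_linked_unlinked(ther, c("DG", "DC", "CG"))
  complexes <- mcode_find_complexes(ther, mcode_params())
  bm <- build_binary_matrix(ther)
  tree <- average_linkage(bm)
  cut07 <- cut_at_similarity(tree, 0.7)
  cut04 <- cut_at_similarity(tree, 0.4)
  list(
    whole_total_nodes = sw$total_nodes,
    whole_total_links = sw$total_links,
    therapeutic_total_nodes = st$total_nodes,
    therapeutic_total_links = st$total_links,
    therapeutic_link_probability = st$link_probability,
    therapeutic_mean_neighbors = st$mean_neighbors,
    n_mcode_complexes = length(complexes),
    n_clusters_0.7 = cut07$n_clusters,
    n_clusters_0.4 = cut04$n_clusters,
    max_cluster_size_0.4 = cut04$max_size,
    median_linked_DG = cmp$median_linked[cmp$pair_class == "DG"],
    mw_p_values = setNames(cmp$p_value, cmp$pair_class))
}
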