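#' @importFrom stats median setNames complete.cases
#' @importFrom utils write.table head
NULL

#' Controlled vocabularies for edge annotations
#'
#' Interaction-type labels and protein-modification tags used on edges of a
#' tripartite gene-chemical-disease network. `tripnet_raw_types()` returns the
#' five curated interaction-type labels; `tripnet_modifications()` returns the
#' twelve protein modifications a chemical can impart on a protein.
#'
#' @return Character vector of allowed labels.
#' @export
tripnet_raw_types <- function() {
  c("therapeutic", "marker/mechanism", "increases", "decreases", "affects")
}

#' @rdname tripnet_raw_types
#' @export
tripnet_modifications <- function() {
  c("ubiquitination", "phosphorylation", "oxidation", "cleavage",
    "methylation", "hydrolysis", "hydroxylation", "glycosylation",
    "glucuronidation", "acetylation", "nitrosation", "ribosylation")
}

node_kinds <- function() c("gene", "chemical", "disease")

# Edge classes permitted in the model; disease-disease is not a valid class.
edge_classes <- function() {
  c("gene-gene", "gene-chemical", "chemical-chemical",
    "disease-gene", "disease-chemical")
}

# Two-letter pair-class codes used by the similarity module.
pair_class_codes <- function() c("DG", "DC", "CG", "GG", "CC")

#' Derive the edge class from two node kinds
#'
#' @param kind_a,kind_b Node kinds (`"gene"`, `"chemical"` or `"disease"`).
#' @return Character vector of edge classes, e.g. `"disease-gene"`.
#' @export
edge_class <- function(kind_a, kind_b) {
  ka <- pmin(kind_a, kind_b)
  kb <- pmax(kind_a, kind_b)
  cls <- ifelse(ka == "chemical" & kb == "chemical", "chemical-chemical",
         ifelse(ka == "gene" & kb == "gene", "gene-gene",
         ifelse(ka == "chemical" & kb == "gene", "gene-chemical",
         ifelse(ka == "disease" & kb == "gene", "disease-gene",
         ifelse(ka == "chemical" & kb == "disease", "disease-chemical",
                NA_character_)))))
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1]
    stop("invalid edge class for node kinds '", kind_a[bad], "' and '",
         kind_b[bad], "' (disease-disease links are not permitted)")
  }
  cls
}

# Map an edge class to its two-letter code (DG, DC, CG, GG, CC).
class_to_code <- function(cls) {
  codes <- c("gene-gene" = "GG", "gene-chemical" = "CG",
             "chemical-chemical" = "CC", "disease-gene" = "DG",
             "disease-chemical" = "DC")
  unname(codes[cls])
}

split_semi <- function(x) {
  if (length(x) == 0) return(list())
  lapply(strsplit(x, ";", fixed = TRUE), function(v) sort(unique(v[nzchar(v)])))
}

join_semi <- function(x) vapply(x, function(v) paste(sort(unique(v)), collapse = ";"),
                                character(1))

#' Classify edge polarity from its interaction types
#'
#' An edge is `positive` when all its interaction types are drawn from
#' \{therapeutic, increases\}, `negative` when all are drawn from
#' \{marker/mechanism, decreases\}, and `mixed` otherwise (including the
#' neutral `affects` label, conflicting evidence such as therapeutic together
#' with marker/mechanism, and edges that carry no interaction-type label at
#' all, e.g. protein-protein interaction rows).
#'
#' @param raw_types Character vector of semicolon-joined interaction types
#'   (one element per edge), or a list of character vectors.
#' @return Character vector: `"positive"`, `"negative"` or `"mixed"`.
#' @export
classify_polarity <- function(raw_types) {
  if (!is.list(raw_types)) raw_types <- split_semi(as.character(raw_types))
  vapply(raw_types, function(tt) {
    if (length(tt) == 0) return("mixed")
    if (all(tt %in% c("therapeutic", "increases"))) return("positive")
    if (all(tt %in% c("marker/mechanism", "decreases"))) return("negative")
    "mixed"
  }, character(1))
}

canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

edge_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "\r")
}

#' Construct a typed tripartite interaction network
#'
#' The container for all analyses in the package: a set of typed nodes
#' (gene / chemical / disease) and undirected annotated edges. Edges are
#' canonicalised to an unordered pair; duplicate pairs are merged by taking
#' the union of their interaction types and modifications, and polarity is
#' recomputed from the merged type set. Self-loops are permitted for
#' gene-gene records only (a protein interacting with itself);
#' disease-disease edges are rejected.
#'
#' @param nodes Data frame with columns `id` and `kind`.
#' @param edges Data frame with columns `a`, `b` and optionally `raw_types`
#'   and `modifications` (semicolon-joined strings).
#' @return An object of class `interaction_network` with components `nodes`
#'   (data frame `id`, `kind`) and `edges` (data frame `a`, `b`, `class`,
#'   `raw_types`, `modifications`, `polarity`).
#' @export
interaction_network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(nodes)))
  nodes$id <- trimws(as.character(nodes$id))
  nodes$kind <- as.character(nodes$kind)
  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty")
  bad_kind <- setdiff(unique(nodes$kind), node_kinds())
  if (length(bad_kind)) stop("unknown node kind: ", paste(bad_kind, collapse = ", "))
  nodes <- unique(nodes[, c("id", "kind")])
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    stop("node id '", dup, "' declared with more than one kind")
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(a = character(), b = character(), class = character(),
                        raw_types = character(), modifications = character(),
                        polarity = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b") %in% names(edges)))
    edges$a <- trimws(as.character(edges$a))
    edges$b <- trimws(as.character(edges$b))
    if (!"raw_types" %in% names(edges)) edges$raw_types <- ""
    if (!"modifications" %in% names(edges)) edges$modifications <- ""
    edges$raw_types[is.na(edges$raw_types)] <- ""
    edges$modifications[is.na(edges$modifications)] <- ""

    missing_nodes <- setdiff(c(edges$a, edges$b), nodes$id)
    if (length(missing_nodes)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(head(missing_nodes, 5), collapse = ", "))
    }
    kind_of <- setNames(nodes$kind, nodes$id)
    cls <- edge_class(kind_of[edges$a], kind_of[edges$b])
    self <- edges$a == edges$b
    if (any(self & cls != "gene-gene")) {
      stop("self-interactions are only permitted for gene-gene edges")
    }

    rt_bad <- setdiff(unlist(split_semi(edges$raw_types)), tripnet_raw_types())
    if (length(rt_bad)) stop("unknown interaction type: ", paste(rt_bad, collapse = ", "))
    mod_bad <- setdiff(unlist(split_semi(edges$modifications)), tripnet_modifications())
    if (length(mod_bad)) stop("unknown protein modification: ",
                              paste(mod_bad, collapse = ", "))

    p <- canonical_pair(edges$a, edges$b)
    edges$a <- p$a; edges$b <- p$b
    key <- paste(edges$a, edges$b, sep = "\r")
    if (anyDuplicated(key)) {
      grp <- split(seq_len(nrow(edges)), key)
      idx <- vapply(grp, `[`, integer(1), 1L)
      rt <- vapply(grp, function(i) join_semi(list(unlist(split_semi(edges$raw_types[i])))),
                   character(1))
      md <- vapply(grp, function(i) join_semi(list(unlist(split_semi(edges$modifications[i])))),
                   character(1))
      edges <- edges[idx, , drop = FALSE]
      edges$raw_types <- rt
      edges$modifications <- md
    } else {
      edges$raw_types <- join_semi(split_semi(edges$raw_types))
      edges$modifications <- join_semi(split_semi(edges$modifications))
    }
    edges$class <- edge_class(kind_of[edges$a], kind_of[edges$b])
    edges$polarity <- classify_polarity(edges$raw_types)
    edges <- edges[order(edges$a, edges$b),
                   c("a", "b", "class", "raw_types", "modifications", "polarity")]
    rownames(edges) <- NULL
  }

  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  nk <- table(factor(x$nodes$kind, levels = node_kinds()))
  cat("interaction_network:", nrow(x$nodes), "nodes (",
      paste(sprintf("%d %s", as.integer(nk), names(nk)), collapse = ", "),
      "), ", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read an interaction network from an edge-triple TSV file
#'
#' Expects a UTF-8 tab-separated file with a header row and columns
#' `node_a`, `node_b`, `kind_a`, `kind_b`, `raw_types`, `modifications`
#' (the last two semicolon-joined, possibly empty). Lines starting with `#`
#' are ignored. Duplicate rows for the same unordered pair collapse to one
#' edge with merged interaction types.
#'
#' @param path Path to the triple file.
#' @return An [interaction_network()].
#' @seealso [save_triples()]
#' @export
load_triples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("triple file has no header row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  required <- c("node_a", "node_b", "kind_a", "kind_b")
  if (!all(required %in% header)) {
    stop("triple file header must contain columns ",
         paste(required, collapse = ", "), ": ", path)
  }
  ncol_expected <- length(header)
  body <- fields[-1]
  body_lines <- line_no[-1]
  if (length(body) == 0) {
    return(interaction_network(data.frame(id = character(), kind = character())))
  }
  nf <- lengths(body)
  # trailing empty fields are dropped by strsplit; pad them back
  short_ok <- nf >= 4 & nf <= ncol_expected
  if (any(!short_ok)) {
    bad <- which(!short_ok)[1]
    stop("malformed row at line ", body_lines[bad], " of ", path,
         ": expected ", ncol_expected, " tab-separated fields, found ", nf[bad])
  }
  body <- lapply(body, function(v) c(v, rep("", ncol_expected - length(v))))
  m <- do.call(rbind, body)
  colnames(m) <- header
  df <- as.data.frame(m, stringsAsFactors = FALSE)

  bad_kind <- !(df$kind_a %in% node_kinds()) | !(df$kind_b %in% node_kinds())
  if (any(bad_kind)) {
    bad <- which(bad_kind)[1]
    stop("unknown node kind at line ", body_lines[bad], " of ", path, ": '",
         df$kind_a[bad], "' / '", df$kind_b[bad], "'")
  }
  dd <- df$kind_a == "disease" & df$kind_b == "disease"
  if (any(dd)) {
    stop("disease-disease link at line ", body_lines[which(dd)[1]], " of ",
         path, ": class not permitted")
  }
  nodes <- unique(data.frame(
    id = c(df$node_a, df$node_b),
    kind = c(df$kind_a, df$kind_b),
    stringsAsFactors = FALSE))
  edges <- data.frame(a = df$node_a, b = df$node_b,
                      raw_types = if ("raw_types" %in% header) df$raw_types else "",
                      modifications = if ("modifications" %in% header) df$modifications else "",
                      stringsAsFactors = FALSE)
  interaction_network(nodes, edges)
}

#' Write an interaction network as an edge-triple TSV file
#'
#' Inverse of [load_triples()]: the written file reloads to an identical
#' network provided the network has no isolated nodes (an edge list cannot
#' represent degree-zero nodes; use [export_sif()] when they must survive a
#' round trip).
#'
#' @param net An [interaction_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_triples <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  df <- data.frame(node_a = net$edges$a, node_b = net$edges$b,
                   kind_a = unname(kind_of[net$edges$a]),
                   kind_b = unname(kind_of[net$edges$b]),
                   raw_types = net$edges$raw_types,
                   modifications = net$edges$modifications,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Convert a network to an igraph graph
#'
#' @param net An [interaction_network()].
#' @param simple If `TRUE`, drop self-loops (used by degree-based
#'   algorithms that operate on the simple undirected view).
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net, simple = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::graph_from_data_frame(
    d = net$edges[, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes)
  if (simple) g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}

#' Extract the induced sub-network on a set of nodes
#'
#' Keeps the named nodes and every edge with both endpoints among them
#' (including gene self-loops).
#'
#' @param net An [interaction_network()].
#' @param ids Character vector of node ids; all must exist in `net`.
#' @return An [interaction_network()].
#' @export
induced_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "interaction_network"))
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, net$nodes$id)
  if (length(missing)) stop("unknown node(s): ", paste(head(missing, 5), collapse = ", "))
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  keep <- net$edges$a %in% ids & net$edges$b %in% ids
  interaction_network(nodes, net$edges[keep, , drop = FALSE])
}

#' Link probability of a network with given totals
#'
#' The probability that two random nodes are linked:
#' \eqn{L / \binom{N}{2}}.
#'
#' @param n_nodes,n_links Node and link totals.
#' @return Numeric probability (NaN for fewer than two nodes).
#' @export
link_probability <- function(n_nodes, n_links) {
  if (n_nodes < 2) return(NaN)
  n_links / (n_nodes * (n_nodes - 1) / 2)
}

#' Mean number of neighbours implied by network totals
#'
#' \eqn{2L/N}, the mean degree of a loop-free undirected graph.
#'
#' @inheritParams link_probability
#' @return Numeric (NaN for an empty network).
#' @export
mean_neighbors <- function(n_nodes, n_links) {
  if (n_nodes < 1) return(NaN)
  2 * n_links / n_nodes
}

#' Summary statistics of an interaction network
#'
#' Computes the printed-statistics block for a network: node counts per kind,
#' link counts per edge class, the mean neighbour count (mean of the
#' neighbour-set size |N(v)|, a self-loop contributing one), the link
#' probability \eqn{L/\binom{N}{2}}, and the characteristic path length
#' (mean shortest-path length over unordered node pairs of the largest
#' connected component).
#'
#' @param net An [interaction_network()].
#' @return An object of class `network_summary`: a list with
#'   `node_counts`, `link_counts`, `total_nodes`, `total_links`,
#'   `mean_neighbors`, `link_probability`, `characteristic_path_length`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  node_counts <- table(factor(net$nodes$kind, levels = node_kinds()))
  node_counts <- setNames(as.integer(node_counts), names(node_counts))
  link_counts <- table(factor(net$edges$class, levels = edge_classes()))
  link_counts <- setNames(as.integer(link_counts), names(link_counts))
  n <- nrow(net$nodes); l <- nrow(net$edges)
  if (n == 0) {
    out <- list(node_counts = node_counts, link_counts = link_counts,
                total_nodes = 0L, total_links = 0L,
                mean_neighbors = NaN, link_probability = NaN,
                characteristic_path_length = NaN)
    return(structure(out, class = "network_summary"))
  }
  self <- sum(net$edges$a == net$edges$b)
  mean_nb <- (2 * (l - self) + self) / n
  lp <- link_probability(n, l)
  g <- as_igraph(net, simple = TRUE)
  comp <- igraph::components(g)
  cpl <- NaN
  if (n >= 2) {
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    cpl <- if (igraph::vcount(sub) >= 2) igraph::mean_distance(sub, directed = FALSE) else NaN
  }
  structure(list(node_counts = node_counts, link_counts = link_counts,
                 total_nodes = n, total_links = l,
                 mean_neighbors = mean_nb, link_probability = lp,
                 characteristic_path_length = cpl),
            class = "network_summary")
}

#' @export
summary.interaction_network <- function(object, ...) network_summary(object)

#' @export
print.network_summary <- function(x, ...) {
  cat("Nodes:", x$total_nodes,
      sprintf("(%s)", paste(sprintf("%s %d", names(x$node_counts), x$node_counts),
                            collapse = ", ")), "\n")
  cat("Links:", x$total_links,
      sprintf("(%s)", paste(sprintf("%s %d", names(x$link_counts), x$link_counts),
                            collapse = ", ")), "\n")
  cat(sprintf("Mean neighbors: %.2f  Link probability: %.4g  Characteristic path length: %.2f\n",
              x$mean_neighbors, x$link_probability, x$characteristic_path_length))
  invisible(x)
}

#' Export a network in SIF format with attribute tables
#'
#' Writes `<prefix>.sif` (source, edge-class relation, target), a node
#' attribute table `<prefix>.nodes.tsv` (id, kind) and an edge attribute
#' table `<prefix>.edges.tsv` (a, b, raw_types, modifications, polarity).
#' [import_sif()] reconstructs an identical network, including isolated
#' nodes (present in the node table but absent from the SIF body).
#'
#' @param net An [interaction_network()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
export_sif <- function(net, prefix) {
  stopifnot(inherits(net, "interaction_network"))
  sif_path <- paste0(prefix, ".sif")
  node_path <- paste0(prefix, ".nodes.tsv")
  edge_path <- paste0(prefix, ".edges.tsv")
  sif <- if (nrow(net$edges)) {
    paste(net$edges$a, net$edges$class, net$edges$b, sep = "\t")
  } else character()
  tryCatch({
    writeLines(sif, sif_path)
  }, error = function(e) stop("cannot write SIF file '", sif_path, "': ",
                              conditionMessage(e)))
  write.table(net$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$edges[, c("a", "b", "raw_types", "modifications", "polarity")],
              edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif = sif_path, nodes = node_path, edges = edge_path))
}

#' @rdname export_sif
#' @export
import_sif <- function(prefix) {
  node_path <- paste0(prefix, ".nodes.tsv")
  edge_path <- paste0(prefix, ".edges.tsv")
  if (!file.exists(node_path)) stop("missing node attribute table: ", node_path)
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  edges$raw_types[is.na(edges$raw_types)] <- ""
  edges$modifications[is.na(edges$modifications)] <- ""
  interaction_network(nodes, edges)
}
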