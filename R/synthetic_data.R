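#' Configuration of the synthetic-data generator
#'
#' Describes a synthetic gene-chemical-disease study: node counts at about
#' a quarter of the published network scale, sparse per-class background
#' edge densities (roughly 1.5% of node pairs linked overall), planted
#' dense mixed-kind clusters, the fraction of chemical-disease rows with
#' therapeutic evidence, the rate of secondary-chemical co-occurrence
#' mentions in chemical-gene interaction text, and the fraction of planted
#' gene-gene edges withheld into a reference validation network.
#'
#' @param n_genes,n_chemicals,n_diseases Node counts per kind.
#' @param density Named per-class background edge probabilities with names
#'   `CG`, `GG`, `DG`, `DC` (chemical-chemical links are never generated
#'   directly; they arise from co-occurrence inference).
#' @param n_planted_clusters,planted_cluster_size Number and size (>= 3) of
#'   planted dense blocks.
#' @param planted_within_density Edge probability inside a planted block
#'   (over admissible pairs; should far exceed the background).
#' @param therapeutic_fraction Probability that a chemical-disease row
#'   carries therapeutic evidence (`therapeutic` or `both`).
#' @param cooccurrence_rate Fraction of chemical-gene rows whose
#'   interaction text names a secondary chemical.
#' @param reference_overlap Fraction of planted gene-gene edges withheld
#'   from the tables and placed in the reference network.
#' @param reference_noise Reference noise edges, as a fraction of the
#'   withheld-edge count (random unlinked gene pairs).
#' @param duplicate_fraction Fraction of chemical-gene pairs also emitted
#'   in the reverse query orientation (bidirectional duplicates).
#' @param self_loop_rate Fraction of genes given a PPI self-interaction.
#' @param degree_sdlog Log-normal sd of the per-node degree propensity
#'   (unit mean, so expected densities stay at their configured values);
#'   0 disables degree heterogeneity.
#' @param seed Integer seed; the same configuration and seed always yield
#'   byte-identical output.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(n_genes = 100, n_chemicals = 150, n_diseases = 60,
                             density = c(CG = 0.012, GG = 0.015,
                                         DG = 0.015, DC = 0.02),
                             n_planted_clusters = 3, planted_cluster_size = 8,
                             planted_within_density = 0.9,
                             therapeutic_fraction = 0.7,
                             cooccurrence_rate = 0.05,
                             reference_overlap = 0.15,
                             reference_noise = 0.25,
                             duplicate_fraction = 0.95,
                             self_loop_rate = 0.05,
                             degree_sdlog = 0.75,
                             seed = 1) {
  stopifnot(n_genes >= 0, n_chemicals >= 0, n_diseases >= 0,
            all(c("CG", "GG", "DG", "DC") %in% names(density)),
            all(density >= 0 & density <= 1),
            n_planted_clusters >= 0, planted_cluster_size >= 3,
            planted_within_density >= 0, planted_within_density <= 1,
            therapeutic_fraction >= 0, therapeutic_fraction <= 1,
            cooccurrence_rate >= 0, cooccurrence_rate <= 1,
            reference_overlap >= 0, reference_overlap <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            self_loop_rate >= 0, self_loop_rate <= 1,
            degree_sdlog >= 0)
  cfg <- list(n_genes = as.integer(n_genes), n_chemicals = as.integer(n_chemicals),
              n_diseases = as.integer(n_diseases), density = density,
              n_planted_clusters = as.integer(n_planted_clusters),
              planted_cluster_size = as.integer(planted_cluster_size),
              planted_within_density = planted_within_density,
              therapeutic_fraction = therapeutic_fraction,
              cooccurrence_rate = cooccurrence_rate,
              reference_overlap = reference_overlap,
              reference_noise = reference_noise,
              duplicate_fraction = duplicate_fraction,
              self_loop_rate = self_loop_rate,
              degree_sdlog = degree_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "synthesis_config"
  cfg
}

# Sample undirected pairs between two disjoint node sets (or within one set
# when b is NULL) with per-pair probability p * w_a * w_b capped at 0.98.
sample_pairs <- function(a, b = NULL, p, w) {
  if (p <= 0) return(data.frame(a = character(), b = character(),
                                stringsAsFactors = FALSE))
  if (is.null(b)) {
    if (length(a) < 2) return(data.frame(a = character(), b = character()))
    idx <- which(upper.tri(matrix(0, length(a), length(a))), arr.ind = TRUE)
    x <- a[idx[, 1]]; y <- a[idx[, 2]]
  } else {
    g <- expand.grid(ai = seq_along(a), bi = seq_along(b))
    x <- a[g$ai]; y <- b[g$bi]
  }
  pr <- pmin(p * w[x] * w[y], 0.98)
  keep <- stats::runif(length(x)) < pr
  data.frame(a = x[keep], b = y[keep], stringsAsFactors = FALSE)
}

sample_types <- function(n) {
  sample(c("increases", "decreases", "affects"), n, replace = TRUE,
         prob = c(0.4, 0.4, 0.2))
}

#' Generate a synthetic study bundle
#'
#' Draws a full set of raw association tables with planted structure: sparse
#' Bernoulli background edges per class (with log-normal per-node degree
#' propensities emulating hub dominance), dense planted mixed-kind blocks,
#' interaction types from the closed vocabulary, therapeutic evidence at
#' the configured rate, secondary-chemical co-occurrence mentions in a
#' fraction of the chemical-gene interaction texts, bidirectional duplicate
#' chemical-gene rows, gene self-interactions, and a reference gene-gene
#' network containing the withheld planted edges plus noise. The output is
#' deterministic in the seed.
#'
#' @param config A [synthesis_config()].
#' @return An object of class `synthetic_bundle`: list with `tables`
#'   ([raw_tables()]), `diseases`, `truth` (planted cluster memberships and
#'   withheld edges) and `reference_net` (an [interaction_network()]).
#' @export
generate_bundle <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  total <- config$n_genes + config$n_chemicals + config$n_diseases
  if (config$n_planted_clusters * config$planted_cluster_size > total) {
    stop("infeasible config: planted clusters need more nodes than exist")
  }
  set.seed(config$seed)
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  chems <- sprintf("C%03d", seq_len(config$n_chemicals))
  diseases <- sprintf("D%03d", seq_len(config$n_diseases))

  # unit-mean log-normal propensities: hub-dominated degrees while keeping
  # the expected class density equal to the configured probability
  w <- stats::rlnorm(total, meanlog = -config$degree_sdlog^2 / 2,
                     sdlog = config$degree_sdlog)
  names(w) <- c(genes, chems, diseases)

  d <- config$density
  cg <- sample_pairs(chems, genes, d[["CG"]], w)      # a = chemical, b = gene
  gg <- sample_pairs(genes, NULL, d[["GG"]], w)
  dg <- sample_pairs(diseases, genes, d[["DG"]], w)   # a = disease, b = gene
  dc <- sample_pairs(diseases, chems, d[["DC"]], w)   # a = disease, b = chemical

  # planted dense blocks: gene-dominant mixed-kind blocks (one chemical and
  # one disease each) so that almost every within-block pair is admissible
  # and the block's realised density stays close to planted_within_density
  clusters <- list()
  used_g <- used_c <- used_d <- character()
  planted_gg <- data.frame(a = character(), b = character())
  if (config$n_planted_clusters > 0) {
    sz <- config$planted_cluster_size
    nc <- 1L; nd <- 1L; ng <- sz - nc - nd
    for (k in seq_len(config$n_planted_clusters)) {
      gpool <- setdiff(genes, used_g); cpool <- setdiff(chems, used_c)
      dpool <- setdiff(diseases, used_d)
      if (length(gpool) < ng || length(cpool) < nc || length(dpool) < nd) {
        stop("infeasible config: not enough unused nodes for planted cluster ", k)
      }
      bg <- sort(sample(gpool, ng)); bc <- sort(sample(cpool, nc))
      bd <- sort(sample(dpool, nd))
      used_g <- c(used_g, bg); used_c <- c(used_c, bc); used_d <- c(used_d, bd)
      members <- c(bg, bc, bd)
      clusters[[k]] <- sort(members)
      pw <- config$planted_within_density
      # enumerate admissible within-block pairs
      prs <- utils::combn(members, 2)
      kind_of <- function(v) ifelse(v %in% genes, "gene",
                             ifelse(v %in% chems, "chemical", "disease"))
      for (ii in seq_len(ncol(prs))) {
        u <- prs[1, ii]; v <- prs[2, ii]
        ku <- kind_of(u); kv <- kind_of(v)
        # disease-disease is not a valid class; chemical-chemical links have
        # no raw-table representation (they arise from co-occurrence only)
        if (ku == "disease" && kv == "disease") next
        if (ku == "chemical" && kv == "chemical") next
        if (stats::runif(1) >= pw) next
        if (ku == "gene" && kv == "gene") {
          gg <- rbind(gg, data.frame(a = min(u, v), b = max(u, v)))
          planted_gg <- rbind(planted_gg, data.frame(a = min(u, v), b = max(u, v)))
        } else if (ku == "chemical" && kv == "gene") {
          cg <- rbind(cg, data.frame(a = u, b = v))
        } else if (ku == "gene" && kv == "chemical") {
          cg <- rbind(cg, data.frame(a = v, b = u))
        } else if (ku == "disease" && kv == "gene") {
          dg <- rbind(dg, data.frame(a = u, b = v))
        } else if (ku == "gene" && kv == "disease") {
          dg <- rbind(dg, data.frame(a = v, b = u))
        } else if (ku == "disease" && kv == "chemical") {
          dc <- rbind(dc, data.frame(a = u, b = v))
        } else {
          dc <- rbind(dc, data.frame(a = v, b = u))
        }
      }
      # every planted block member is anchored to at least one block disease
      # (or, failing that, a global disease) so context filtering keeps it
      anchor <- if (nd > 0) bd[1] else diseases[1]
      for (g1 in bg) dg <- rbind(dg, data.frame(a = anchor, b = g1))
      for (c1 in bc) dc <- rbind(dc, data.frame(a = anchor, b = c1))
    }
  }

  dedup2 <- function(df) {
    if (nrow(df) == 0) return(df)
    df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  cg <- dedup2(cg); gg <- dedup2(gg); dg <- dedup2(dg); dc <- dedup2(dc)
  gg <- gg[gg$a != gg$b, , drop = FALSE]

  # withhold a fraction of planted gene-gene edges into the reference net
  planted_gg <- dedup2(planted_gg)
  n_withheld <- round(config$reference_overlap * nrow(planted_gg))
  withheld <- planted_gg[seq_len(0), , drop = FALSE]
  if (n_withheld > 0) {
    take <- sort(sample(nrow(planted_gg), n_withheld))
    withheld <- planted_gg[take, , drop = FALSE]
    wkey <- paste(withheld$a, withheld$b, sep = "\r")
    gg <- gg[!(paste(gg$a, gg$b, sep = "\r") %in% wkey), , drop = FALSE]
  }

  # self-interacting genes
  selfs <- genes[stats::runif(length(genes)) < config$self_loop_rate]

  # chemical-gene table with interaction text and co-occurrence mentions
  n_cg <- nrow(cg)
  types <- if (n_cg) sample_types(n_cg) else character()
  txt <- character(n_cg)
  if (n_cg) {
    verbs <- c(increases = "results in increased expression of",
               decreases = "results in decreased activity of",
               affects = "affects the reaction of")
    txt <- paste(cg$a, unname(verbs[types]), cg$b)
    co <- stats::runif(n_cg) < config$cooccurrence_rate
    if (any(co) && length(chems) > 1) {
      second <- vapply(which(co), function(i)
        sample(setdiff(chems, cg$a[i]), 1), character(1))
      txt[co] <- paste0(cg$a[co], " inhibits the reaction of ", second,
                        " with ", cg$b[co])
    }
  }
  chem_gene <- data.frame(chemical = cg$a, gene = cg$b,
                          interaction_text = txt, raw_types = types,
                          stringsAsFactors = FALSE)
  # bidirectional duplicates from the reverse query orientation
  if (n_cg && config$duplicate_fraction > 0) {
    dup <- which(stats::runif(n_cg) < config$duplicate_fraction)
    chem_gene <- rbind(chem_gene, chem_gene[dup, , drop = FALSE])
  }

  ev_cd <- function(n) {
    u <- stats::runif(n)
    tf <- config$therapeutic_fraction
    ifelse(u < tf * 0.9, "therapeutic",
    ifelse(u < tf, "both", "marker/mechanism"))
  }
  chem_disease <- data.frame(chemical = dc$b, disease = dc$a,
                             direct_evidence = ev_cd(nrow(dc)),
                             stringsAsFactors = FALSE)
  gene_disease <- data.frame(gene = dg$b, disease = dg$a,
                             direct_evidence = sample(
                               c("marker/mechanism", "therapeutic"),
                               nrow(dg), replace = TRUE, prob = c(0.8, 0.2)),
                             stringsAsFactors = FALSE)
  ppi <- rbind(data.frame(gene_a = gg$a, gene_b = gg$b, stringsAsFactors = FALSE),
               data.frame(gene_a = selfs, gene_b = selfs, stringsAsFactors = FALSE))

  # reference network: withheld planted edges plus random noise pairs
  ref_edges <- withheld
  n_noise <- round(config$reference_noise * nrow(withheld))
  if (n_noise > 0) {
    gg_key <- c(paste(gg$a, gg$b, sep = "\r"), paste(withheld$a, withheld$b, sep = "\r"))
    tries <- 0
    noise <- data.frame(a = character(), b = character())
    while (nrow(noise) < n_noise && tries < 50 * n_noise) {
      u <- sample(genes, 2)
      a1 <- min(u); b1 <- max(u)
      k <- paste(a1, b1, sep = "\r")
      if (!(k %in% gg_key)) {
        noise <- rbind(noise, data.frame(a = a1, b = b1))
        gg_key <- c(gg_key, k)
      }
      tries <- tries + 1
    }
    ref_edges <- rbind(ref_edges, noise)
  }
  ref_nodes <- data.frame(id = genes, kind = "gene", stringsAsFactors = FALSE)
  reference_net <- interaction_network(ref_nodes,
                                       if (nrow(ref_edges)) ref_edges else NULL)

  structure(list(
    tables = raw_tables(chem_gene, chem_disease, gene_disease, ppi),
    diseases = diseases,
    truth = list(clusters = clusters, withheld = withheld),
    reference_net = reference_net,
    config = config), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", x$config$n_genes, "genes,", x$config$n_chemicals,
      "chemicals,", x$config$n_diseases, "diseases;",
      length(x$truth$clusters), "planted clusters,",
      nrow(x$truth$withheld), "withheld reference edges\n")
  invisible(x)
}

#' Observed edge density per class of a synthetic bundle
#'
#' Counts the unique undirected pairs present in each raw table and divides
#' by the number of possible pairs of that class; in expectation this
#' matches the configured background density (planted blocks and anchors
#' add a small excess).
#'
#' @param bundle A [generate_bundle()] result.
#' @return Named numeric vector with elements `CG`, `GG`, `DG`, `DC`.
#' @export
empirical_density <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  cfg <- bundle$config
  t <- bundle$tables
  cg_pairs <- unique(paste(t$chem_gene$chemical, t$chem_gene$gene, sep = "\r"))
  gg <- t$ppi[t$ppi$gene_a != t$ppi$gene_b, , drop = FALSE]
  gg_pairs <- unique(paste(pmin(gg$gene_a, gg$gene_b),
                           pmax(gg$gene_a, gg$gene_b), sep = "\r"))
  dg_pairs <- unique(paste(t$gene_disease$gene, t$gene_disease$disease, sep = "\r"))
  dc_pairs <- unique(paste(t$chem_disease$chemical, t$chem_disease$disease, sep = "\r"))
  safe_div <- function(num, den) if (den > 0) num / den else 0
  c(CG = safe_div(length(cg_pairs), cfg$n_chemicals * cfg$n_genes),
    GG = safe_div(length(gg_pairs), choose(cfg$n_genes, 2)),
    DG = safe_div(length(dg_pairs), cfg$n_diseases * cfg$n_genes),
    DC = safe_div(length(dc_pairs), cfg$n_diseases * cfg$n_chemicals))
}

#' Write a synthetic bundle to disk
#'
#' Writes the four raw tables ([write_raw_tables()]), the disease list, the
#' reference network triple file and a JSON truth manifest (planted cluster
#' memberships, withheld edges, configuration).
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_raw_tables(bundle$tables, dir)
  write_disease_list(bundle$diseases, file.path(dir, "diseases.txt"))
  save_triples(bundle$reference_net, file.path(dir, "reference_net.tsv"))
  manifest <- list(config = unclass(bundle$config),
                   clusters = bundle$truth$clusters,
                   withheld = bundle$truth$withheld)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Whole-context network of a synthetic bundle
#'
#' Convenience composition: [build_whole_network()] on the bundle's tables
#' with its full disease list.
#'
#' @param bundle A [generate_bundle()] result.
#' @return An [interaction_network()].
#' @export
bundle_network <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  build_whole_network(bundle$tables, bundle$diseases)
}
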