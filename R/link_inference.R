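#' Sample candidate novel links from complex co-membership
#'
#' Non-connected node pairs inside highly interconnected sub-networks are
#' refined starting points for inferring novel interactions. This collects
#' every unlinked within-complex pair, samples `n_sample` of them uniformly
#' without replacement (seeded), and annotates each with its Jaccard
#' coefficient, its mid-rank percentile among all pairs of the hosting
#' sub-network, and the percentile band (lower25 / middle / upper25). An
#' empty `evidence` column is provided for manual literature annotation.
#'
#' @param net An [interaction_network()].
#' @param complexes Complex list from [mcode_find_complexes()].
#' @param n_sample Number of pairs to draw (>= 1). When fewer unlinked
#'   pairs exist, all are returned and the attribute
#'   `"insufficient_pairs"` is set to `TRUE`.
#' @param seed Integer seed for the draw.
#' @return Data frame with columns `a`, `b`, `subnet_id`, `jaccard`,
#'   `percentile`, `band`, `evidence`.
#' @export
candidate_pairs <- function(net, complexes, n_sample = 23, seed = 1) {
  stopifnot(inherits(net, "interaction_network"), n_sample >= 1)
  ek <- edge_key(net$edges$a, net$edges$b)
  pool <- list()
  for (k in seq_along(complexes)) {
    members <- complexes[[k]]$members
    if (length(members) < 2) next
    prs <- utils::combn(sort(members), 2)
    keys <- edge_key(prs[1, ], prs[2, ])
    open <- which(!(keys %in% ek))
    if (length(open)) {
      pool[[length(pool) + 1]] <- data.frame(
        a = prs[1, open], b = prs[2, open], subnet_id = k,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(a = character(), b = character(), subnet_id = integer(),
                      jaccard = numeric(), percentile = numeric(),
                      band = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  if (length(pool) == 0) return(empty)
  pool <- do.call(rbind, pool)
  insufficient <- nrow(pool) < n_sample
  if (insufficient) {
    warning("only ", nrow(pool), " unlinked within-complex pairs available (",
            n_sample, " requested); returning all")
    take <- seq_len(nrow(pool))
  } else {
    set.seed(seed)
    take <- sort(sample.int(nrow(pool), n_sample))
  }
  out <- pool[take, , drop = FALSE]
  subnets <- lapply(complexes, function(x) induced_subnetwork(net, x$members))
  ann <- lapply(seq_len(nrow(out)), function(i) {
    sn <- subnets[[out$subnet_id[i]]]
    pr <- subnetwork_percentile(sn, out$a[i], out$b[i])
    data.frame(jaccard = jaccard_coefficient(net, out$a[i], out$b[i]),
               percentile = pr$rank_percentile, band = pr$band,
               stringsAsFactors = FALSE)
  })
  out <- cbind(out, do.call(rbind, ann))
  out$evidence <- ""
  rownames(out) <- NULL
  attr(out, "insufficient_pairs") <- insufficient
  out
}

mid_rank_percentile <- function(x, ref) {
  n <- length(ref)
  vapply(x, function(v) 100 * (sum(ref < v) + 0.5 * sum(ref == v)) / n,
         numeric(1))
}

#' Validate similarity-based link prediction against a reference network
#'
#' The validation set consists of the reference network's gene-gene edges
#' whose two genes are both present in the study network but whose
#' interaction is absent from it; self-interactions are excluded from both
#' the validation set and the background. The background is every unlinked
#' gene-gene pair of the study network. A one-sided Mann-Whitney test of
#' the alternative that validation pairs are more similar than the
#' background is reported, together with a decile histogram of mid-rank
#' Jaccard percentiles (computed against the background distribution) for
#' both sets; percentile values falling on a bin boundary are assigned to
#' the lower bin, so heavy coefficient ties distort the background away
#' from 10% per bin.
#'
#' @param net Study [interaction_network()].
#' @param reference_net Reference [interaction_network()] sharing gene ids
#'   with `net`.
#' @return List with `n_validation_pairs`, `u_p_value` and
#'   `decile_histogram` (data frame: `decile`, `background_fraction`,
#'   `validation_fraction`).
#' @export
validate_against_reference <- function(net, reference_net) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(reference_net, "interaction_network"))
  genes <- net$nodes$id[net$nodes$kind == "gene"]
  gg <- jaccard_table(net, "GG")           # distinct pairs only; no self
  bg <- gg[!gg$linked, , drop = FALSE]
  if (nrow(bg) == 0) stop("study network has no unlinked gene-gene pairs")

  re <- reference_net$edges[reference_net$edges$class == "gene-gene", , drop = FALSE]
  re <- re[re$a != re$b, , drop = FALSE]
  re <- re[re$a %in% genes & re$b %in% genes, , drop = FALSE]
  ek <- edge_key(net$edges$a, net$edges$b)
  re <- re[!(edge_key(re$a, re$b) %in% ek), , drop = FALSE]
  if (nrow(re) == 0) {
    stop("empty validation set: no reference gene-gene edge is absent from the network")
  }
  bg_key <- edge_key(bg$a, bg$b)
  val_idx <- match(edge_key(re$a, re$b), bg_key)
  val <- bg$coefficient[val_idx]

  wt <- suppressWarnings(wilcox.test(val, bg$coefficient, alternative = "greater",
                                     exact = FALSE, correct = TRUE))
  bg_pct <- mid_rank_percentile(bg$coefficient, bg$coefficient)
  val_pct <- mid_rank_percentile(val, bg$coefficient)
  to_bin <- function(p) pmin(pmax(ceiling(p / 10), 1L), 10L)
  hist_frac <- function(p) {
    b <- factor(to_bin(p), levels = 1:10)
    as.numeric(table(b)) / length(p)
  }
  list(n_validation_pairs = nrow(re),
       u_p_value = wt$p.value,
       decile_histogram = data.frame(
         decile = 1:10,
         background_fraction = hist_frac(bg_pct),
         validation_fraction = hist_frac(val_pct)))
}
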