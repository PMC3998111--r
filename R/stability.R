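#' @importFrom stats ks.test
NULL

jaccard_from_indicator <- function(m) {
  inter <- as.matrix(m %*% m)
  sizes <- Matrix::rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

upper_values <- function(j) j[upper.tri(j)]

#' Single-edge-addition stability of the Jaccard distribution
#'
#' For every admissible missing edge of a sub-network (every unordered
#' non-adjacent pair of distinct nodes that would not create a
#' disease-disease link), adds that one edge, recomputes the full Jaccard
#' coefficient distribution over all node pairs, and compares it to the
#' unperturbed distribution with a two-sample two-sided Kolmogorov-Smirnov
#' test. Large p-values indicate that single missing interactions barely
#' move the similarity distribution, i.e. that the Jaccard coefficient is
#' stable to small amounts of missing data.
#'
#' The exact small-sample KS p-value is used when the sub-network has fewer
#' than 25 node pairs, the asymptotic approximation otherwise.
#'
#' @param subnet An [interaction_network()] with at least 3 nodes and at
#'   least one admissible missing edge.
#' @param subnet_id Optional identifier copied into the report.
#' @return An object of class `stability_report`: list with `subnet_id`,
#'   `n_perturbations`, `p_values`, `mean_p`, `min_p`.
#' @export
perturb_and_test <- function(subnet, subnet_id = NA_character_) {
  stopifnot(inherits(subnet, "interaction_network"))
  n <- nrow(subnet$nodes)
  if (n < 3) stop("sub-network must have at least 3 nodes")
  ids <- subnet$nodes$id
  kinds <- subnet$nodes$kind
  m <- neighbor_matrix(subnet)
  base <- upper_values(jaccard_from_indicator(m))

  adj <- as.matrix(m) > 0
  cand <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
  if (nrow(cand)) {
    dd <- kinds[cand[, 1]] == "disease" & kinds[cand[, 2]] == "disease"
    cand <- cand[!dd, , drop = FALSE]
  }
  if (nrow(cand) == 0) stop("sub-network has no admissible missing edge to perturb")

  n_pairs <- length(base)
  use_exact <- n_pairs < 25
  p <- vapply(seq_len(nrow(cand)), function(k) {
    m2 <- m
    i <- cand[k, 1]; j <- cand[k, 2]
    m2[i, j] <- 1; m2[j, i] <- 1
    pert <- upper_values(jaccard_from_indicator(m2))
    suppressWarnings(ks.test(base, pert, exact = use_exact))$p.value
  }, numeric(1))

  structure(list(subnet_id = subnet_id, n_perturbations = nrow(cand),
                 p_values = p, mean_p = mean(p), min_p = min(p)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report%s: %d perturbations, mean p = %.3f, min p = %.3f\n",
              if (is.na(x$subnet_id)) "" else paste0(" [", x$subnet_id, "]"),
              x$n_perturbations, x$mean_p, x$min_p))
  invisible(x)
}

#' Write a stability report as TSV
#'
#' @param report A `stability_report`.
#' @param path Output path.
#' @export
write_stability_report <- function(report, path) {
  df <- data.frame(subnet_id = report$subnet_id,
                   perturbation = seq_along(report$p_values),
                   p_value = report$p_values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
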