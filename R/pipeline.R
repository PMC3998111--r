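#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. All stages write their TSV
#' artifacts under `out_dir`; downstream stages read the artifacts of the
#' stages they depend on from the same directory.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used by every stochastic stage.
#' @param input_dir Directory with raw tables and `diseases.txt`; defaults
#'   to the `bundle` sub-directory written by the simulate stage.
#' @param mcode An [mcode_params()] object.
#' @param thresholds Similarity thresholds for matrix-cluster extraction.
#' @param grid_step Step of the threshold grid of the clustered-node curve.
#' @param synthesis A [synthesis_config()] for the simulate stage (its
#'   `seed` is overridden by `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, input_dir = NULL,
                            mcode = mcode_params(),
                            thresholds = c(0.4, 0.7), grid_step = 0.05,
                            synthesis = synthesis_config()) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1), grid_step > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_dir = input_dir, mcode = mcode,
                 thresholds = thresholds, grid_step = grid_step,
                 synthesis = synthesis),
            class = "pipeline_config")
}

config_digest <- function(config) {
  # digest the scientific configuration only: where artifacts live must not
  # change what they contain
  x <- unclass(config)
  x$out_dir <- NULL
  x$input_dir <- NULL
  x <- x[order(names(x))]
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(x, unclass), f, version = 2)
  unname(tools::md5sum(f))
}

write_artifact <- function(df, path, digest) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#config_digest=", digest), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run stage '", stage,
         "' first", call. = FALSE)
  }
  path
}

log_stage <- function(config, stage, artifacts, n_rows) {
  log_path <- file.path(config$out_dir, "pipeline_log.tsv")
  row <- data.frame(stage = stage, artifact = basename(artifacts),
                    rows = n_rows, config_digest = config_digest(config),
                    seed = config$seed)
  utils::write.table(row, log_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(log_path),
                     append = file.exists(log_path))
}

#' Run a pipeline stage
#'
#' Orchestrates the analysis stages in construction order:
#' `simulate` (synthetic bundle), `build` (whole and therapeutic
#' networks), `stats` (summary statistics), `jaccard` (linked/unlinked
#' comparison), `mcode` (complex detection), `stability` (single-edge
#' perturbation KS tests of the largest complexes), `hac` (binary-matrix
#' hierarchical clustering, threshold cuts, clustered-node curve and
#' inflection points), `infer` (candidate pairs and reference validation),
#' or `all` to chain everything. Every artifact embeds the configuration
#' digest in a leading comment line and the run is appended to
#' `pipeline_log.tsv`.
#'
#' @param stage One of the stage names above.
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths of the artifacts written by the stage.
#' @export
run_pipeline <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "build", "stats", "jaccard", "mcode", "stability",
              "hac", "infer")
  stage <- match.arg(stage, c(stages, "all"))
  if (stage == "all") {
    out <- unlist(lapply(stages, run_pipeline, config = config))
    return(invisible(out))
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  digest <- config_digest(config)
  out <- file.path(config$out_dir, "")
  input_dir <- if (is.null(config$input_dir))
    file.path(config$out_dir, "bundle") else config$input_dir
  ther_path <- file.path(config$out_dir, "therapeutic_network.tsv")
  whole_path <- file.path(config$out_dir, "whole_network.tsv")

  paths <- switch(stage,
    simulate = {
      cfg <- config$synthesis
      cfg$seed <- config$seed
      bundle <- generate_bundle(cfg)
      write_bundle(bundle, file.path(config$out_dir, "bundle"))
      file.path(config$out_dir, "bundle")
    },
    build = {
      if (!dir.exists(input_dir)) {
        stop("missing input tables at '", input_dir,
             "': run stage 'simulate' first or set input_dir", call. = FALSE)
      }
      tables <- read_raw_tables(input_dir)
      diseases <- read_disease_list(file.path(input_dir, "diseases.txt"))
      whole <- build_whole_network(tables, diseases)
      ther <- build_therapeutic_network(tables, diseases)
      save_triples(whole, whole_path)
      save_triples(ther, ther_path)
      c(whole_path, ther_path)
    },
    stats = {
      require_artifact(ther_path, "build")
      nets <- list(whole = load_triples(whole_path),
                   therapeutic = load_triples(ther_path))
      df <- do.call(rbind, lapply(names(nets), function(nm) {
        s <- network_summary(nets[[nm]])
        data.frame(network = nm, total_nodes = s$total_nodes,
                   total_links = s$total_links,
                   mean_neighbors = s$mean_neighbors,
                   link_probability = s$link_probability,
                   characteristic_path_length = s$characteristic_path_length)
      }))
      p <- file.path(config$out_dir, "network_summary.tsv")
      write_artifact(df, p, digest)
      p
    },
    jaccard = {
      require_artifact(ther_path, "build")
      net <- load_triples(ther_path)
      cmp <- compare_linked_unlinked(net)
      p <- file.path(config$out_dir, "linked_unlinked.tsv")
      write_artifact(cmp, p, digest)
      p
    },
    mcode = {
      require_artifact(ther_path, "build")
      net <- load_triples(ther_path)
      complexes <- mcode_find_complexes(net, config$mcode)
      p <- file.path(config$out_dir, "mcode_complexes.tsv")
      write_complexes(complexes, p)
      p
    },
    stability = {
      cpath <- require_artifact(file.path(config$out_dir, "mcode_complexes.tsv"),
                                "mcode")
      net <- load_triples(require_artifact(ther_path, "build"))
      cx <- utils::read.delim(cpath, stringsAsFactors = FALSE, comment.char = "#")
      cx <- cx[order(-cx$n_members), , drop = FALSE]
      cx <- utils::head(cx[cx$n_members >= 5, , drop = FALSE], 3)
      if (nrow(cx) == 0) stop("no complex of size >= 5 to perturb", call. = FALSE)
      reports <- lapply(seq_len(nrow(cx)), function(i) {
        sn <- induced_subnetwork(net, strsplit(cx$members[i], ";")[[1]])
        # complete complexes (no admissible missing edge) have nothing to test
        r <- tryCatch(perturb_and_test(sn, subnet_id = as.character(cx$complex[i])),
                      error = function(e) NULL)
        if (is.null(r)) return(NULL)
        data.frame(subnet_id = r$subnet_id, n_perturbations = r$n_perturbations,
                   mean_p = r$mean_p, min_p = r$min_p)
      })
      reports <- reports[!vapply(reports, is.null, logical(1))]
      if (length(reports) == 0) {
        stop("no perturbable complex: all candidates are complete", call. = FALSE)
      }
      p <- file.path(config$out_dir, "stability.tsv")
      write_artifact(do.call(rbind, reports), p, digest)
      p
    },
    hac = {
      net <- load_triples(require_artifact(ther_path, "build"))
      mat <- build_binary_matrix(net)
      tree <- average_linkage(mat)
      export_gtr(tree, file.path(config$out_dir, "therapeutic.gtr"))
      export_cdt(tree, mat, file.path(config$out_dir, "therapeutic.cdt"))
      cut_paths <- vapply(config$thresholds, function(t) {
        cp <- file.path(config$out_dir, sprintf("clusters_%.2f.tsv", t))
        write_cut(cut_at_similarity(tree, t), cp)
        cp
      }, character(1))
      curve <- clustered_node_curve(tree, seq(0, 1, by = config$grid_step))
      curve_path <- file.path(config$out_dir, "clustered_node_curve.tsv")
      write_artifact(curve, curve_path, digest)
      infl <- detect_inflections(curve)
      infl_path <- file.path(config$out_dir, "inflections.tsv")
      write_artifact(data.frame(threshold = infl), infl_path, digest)
      c(cut_paths, curve_path, infl_path)
    },
    infer = {
      cpath <- require_artifact(file.path(config$out_dir, "mcode_complexes.tsv"),
                                "mcode")
      net <- load_triples(require_artifact(ther_path, "build"))
      cx <- utils::read.delim(cpath, stringsAsFactors = FALSE, comment.char = "#")
      complexes <- lapply(seq_len(nrow(cx)), function(i)
        list(members = strsplit(cx$members[i], ";")[[1]],
             seed = cx$seed[i], score = cx$score[i]))
      cands <- suppressWarnings(
        candidate_pairs(net, complexes, n_sample = 23, seed = config$seed))
      cand_path <- file.path(config$out_dir, "candidates.tsv")
      write_artifact(cands, cand_path, digest)
      paths <- cand_path
      ref_path <- file.path(input_dir, "reference_net.tsv")
      if (file.exists(ref_path)) {
        val <- validate_against_reference(net, load_triples(ref_path))
        val_path <- file.path(config$out_dir, "validation.tsv")
        write_artifact(data.frame(n_validation_pairs = val$n_validation_pairs,
                                  u_p_value = val$u_p_value), val_path, digest)
        hist_path <- file.path(config$out_dir, "validation_histogram.tsv")
        write_artifact(val$decile_histogram, hist_path, digest)
        paths <- c(paths, val_path, hist_path)
      }
      paths
    })
  n_rows <- vapply(paths, function(p) {
    if (dir.exists(p) || !file.exists(p)) return(NA_integer_)
    length(readLines(p, warn = FALSE))
  }, integer(1))
  log_stage(config, stage, paths, n_rows)
  invisible(paths)
}
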