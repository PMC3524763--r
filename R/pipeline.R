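# End-to-end pipeline: preprocess -> redundancy matrix -> k-sweep ->
# cluster tree -> patterns for representative clusters. Each stage writes its
# artifacts to the output directory; timestamps live only in the log so that
# two runs with the same config and seed are byte-identical elsewhere.

#' Assemble a pipeline configuration
#'
#' @param input Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param out_dir Output directory (created if missing).
#' @param max_gap_fraction Column gap-fraction threshold (default 0.20).
#' @param dedup Collapse duplicate sequences (default TRUE).
#' @param drop_insert_columns See [read_msa()].
#' @param site_offset Integer added to 1..N to produce reference site labels.
#' @param alpha Significance level of the pairwise dependency test.
#' @param cutoff Adjusted-residual cutoff for patterns (default 3.29).
#' @param confidence Optional confidence level overriding `cutoff`.
#' @param span,allow_gaps See [enumerate_patterns()].
#' @param k_max,k_min,restarts,max_iter See [sweep_k()].
#' @param rep_tolerance,min_interlace,min_shared See [build_cluster_tree()].
#' @param seed Master seed for the sweep.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, format = "fasta",
                       out_dir = "coevclust_run",
                       max_gap_fraction = 0.20, dedup = TRUE,
                       drop_insert_columns = NULL, site_offset = 0,
                       alpha = 0.05, cutoff = 3.29, confidence = NULL,
                       span = "full", allow_gaps = TRUE,
                       k_max = NULL, k_min = 2, restarts = 1,
                       max_iter = 100, rep_tolerance = 0.05,
                       min_interlace = 1, min_shared = 2, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_gap_fraction >= 0, cfg$max_gap_fraction <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$k_min >= 2,
            cfg$restarts >= 1, cfg$max_iter >= 1)
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns the `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

pipeline_stages <- c("preprocess", "rmatrix", "cluster", "tree", "patterns")

#' Run the full analysis pipeline
#'
#' Executes the stages `preprocess` (read + gap filter + dedup),
#' `rmatrix` (pairwise redundancies + dependency test), `cluster` (k-sweep),
#' `tree` (cluster tree) and `patterns` (pattern discovery on representative
#' clusters), writing each stage's artifacts under `config$out_dir`:
#' `preprocess.json`, `filtered.fasta`, `rmatrix.tsv`, `pairs.tsv`,
#' `clusters_k<k>.tsv`, `clusters.json`, `tree.json`, `tree.dot`,
#' `branches.tsv`, `patterns.tsv` and `log.txt`. A failing stage aborts with
#' a stage-named error.
#'
#' @param config A [run_config()].
#' @param through Last stage to execute (default `"patterns"` = all).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, through = "patterns") {
  stopifnot(inherits(config, "run_config"))
  through <- match.arg(through, pipeline_stages)
  wanted <- pipeline_stages[seq_len(match(through, pipeline_stages))]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("coevclust ",
                        as.character(utils::packageVersion("coevclust")),
                        " | R ", getRversion()),
                 paste0("seed: ", config$seed),
                 paste0("started: ", format(Sys.time(), usetz = TRUE)))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    if (!(name %in% wanted)) return(NULL)
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
    log_lines <<- c(log_lines,
                    sprintf("stage %-10s done at +%.1fs", name,
                            as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))))
    res
  }
  out <- function(f) file.path(config$out_dir, f)

  aln <- stage("preprocess", {
    if (is.null(config$input) || !file.exists(config$input)) {
      abort(paste0("input file not found: ", config$input %||% "<missing>"))
    }
    raw <- read_msa(config$input, format = config$format,
                    drop_insert_columns = config$drop_insert_columns)
    pp <- preprocess_msa(raw, config$max_gap_fraction, config$dedup)
    if (config$site_offset != 0) {
      pp <- relabel_sites(pp, pp$site_labels + config$site_offset)
    }
    write_json_artifact(preprocess_report(pp), out("preprocess.json"))
    write_msa(pp, out("filtered.fasta"))
    pp
  })

  rmat <- stage("rmatrix", {
    rm <- redundancy_matrix(aln)
    wide <- as.data.frame(rm$R)
    readr::write_tsv(cbind(site = rm$labels, wide), out("rmatrix.tsv"))
    readr::write_tsv(dependency_test(rm, alpha = config$alpha),
                     out("pairs.tsv"))
    rm
  })

  sweep <- stage("cluster", {
    k_max <- config$k_max %||% (length(rmat$labels) - 1)
    sw <- sweep_k(rmat, k_max = k_max, k_min = config$k_min,
                  seed = config$seed, restarts = config$restarts,
                  max_iter = config$max_iter)
    for (cfg_k in sw$configs) {
      readr::write_tsv(tidy(cfg_k),
                       out(sprintf("clusters_k%d.tsv", cfg_k$k)))
    }
    write_json_artifact(glance(sw), out("clusters.json"))
    sw
  })

  tree <- stage("tree", {
    tr <- build_cluster_tree(sweep, min_interlace = config$min_interlace,
                             min_shared = config$min_shared,
                             rep_tolerance = config$rep_tolerance)
    write_json_artifact(list(nodes = tidy(tr), edges = tr$edges,
                             branch_types = tr$branch_types,
                             modules = tr$modules,
                             representatives = tr$representatives),
                        out("tree.json"))
    export_tree_dot(tr, out("tree.dot"))
    readr::write_tsv(dplyr::left_join(tr$branch_types, tr$modules,
                                      by = "branch"),
                     out("branches.tsv"))
    tr
  })

  pats <- stage("patterns", {
    reps <- tree$representatives
    res <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
      sites <- as.integer(strsplit(reps$sites[i], ",")[[1]])
      found <- enumerate_patterns(aln, sites, cutoff = config$cutoff,
                                  confidence = config$confidence,
                                  span = config$span,
                                  allow_gaps = config$allow_gaps)
      if (nrow(found) == 0) return(NULL)
      dplyr::mutate(found, branch = reps$branch[i], .before = 1)
    })
    if (nrow(res) == 0) {
      res <- tibble(branch = integer(), sites = character(),
                    symbols = character(), order = integer(),
                    observed = integer(), expected = numeric(),
                    residual = numeric(), variance = numeric(),
                    adjusted_residual = numeric())
    }
    readr::write_tsv(res, out("patterns.tsv"))
    res
  })

  log_lines <- c(log_lines, paste0("finished: ", format(Sys.time(),
                                                        usetz = TRUE)))
  writeLines(log_lines, out("log.txt"))
  invisible(list(aln = aln, rmat = rmat, sweep = sweep, tree = tree,
                 patterns = pats))
}
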