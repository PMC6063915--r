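# End-to-end orchestration: simulate fixtures, run the full inference chain
# (collapse -> SNR -> GSEA -> perturbed genes -> network filters ->
# candidate links -> MCMC -> thresholded process network) from a single
# JSON configuration, with a manifest recording seeds and file hashes.

#' Read a pipeline configuration from JSON
#'
#' Recognized top-level keys: `expression` (GCT/TSV path), `format`,
#' `cls`, `gmt`, `network`, `probe_map` (optional TSV probe_id/gene),
#' `impute_group` (optional member pair to mean-impute), `outdir`, `seed`,
#' plus nested `gsea` and `bpn` objects overriding [gsea_config()] /
#' [bpn_config()] defaults and an optional `synthetic` object passed to
#' [synthetic_config()].
#'
#' @param path JSON file path.
#' @return A list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(cfg)
}

#' Validate a pipeline configuration list
#'
#' @param cfg Named list (see [read_pipeline_config()]).
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(cfg) {
  if (is.null(cfg$outdir)) stop("pipeline config is missing key: outdir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  gsea_args <- cfg$gsea %||% list()
  cfg$gsea_config <- do.call(gsea_config,
                             c(gsea_args,
                               if (is.null(gsea_args$rng_seed))
                                 list(rng_seed = cfg$seed)))
  bpn_args <- cfg$bpn %||% list()
  cfg$bpn_config <- do.call(bpn_config,
                            c(bpn_args,
                              if (is.null(bpn_args$rng_seed))
                                list(rng_seed = cfg$seed)))
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    if (is.null(syn$rng_seed)) syn$rng_seed <- cfg$seed
    if (!is.null(syn$planted_links) &&
        (is.data.frame(syn$planted_links) || is.matrix(syn$planted_links)))
      syn$planted_links <- lapply(seq_len(nrow(syn$planted_links)),
                                  function(i)
                                    as.list(syn$planted_links[i, ]))
    cfg$synthetic_config <- do.call(synthetic_config, syn)
  }
  structure(cfg, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(outdir, seed, files) {
  files <- files[file.exists(files) & basename(files) != "manifest.json"]
  manifest <- list(seed = seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f)
                                    list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates the configured synthetic dataset and writes GCT + TSV
#' expression, CLS labels, GMT gene sets, edge-list TSV, truth JSON, and a
#' manifest with the seed and per-file MD5 hashes. Regeneration with the
#' same configuration is byte-identical (the manifest's timestamp aside).
#'
#' @param config A `PipelineConfig` with a `synthetic` section, or a
#'   `SyntheticConfig`.
#' @param outdir Output directory (created if needed); defaults to the
#'   pipeline config's `outdir`.
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config, outdir = NULL) {
  if (inherits(config, "SyntheticConfig")) {
    syn <- config
    if (is.null(outdir)) stop("cmd_simulate needs an output directory")
  } else {
    syn <- config$synthetic_config
    if (is.null(syn)) stop("pipeline config is missing key: synthetic")
    outdir <- outdir %||% config$outdir
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_synthetic_dataset(syn)
  paths <- file.path(outdir, c("expression.gct", "expression.tsv",
                               "classes.cls", "gene_sets.gmt",
                               "network.tsv", "truth.json"))
  write_expression(ds$matrix, paths[[1L]], "gct")
  write_expression(ds$matrix, paths[[2L]], "tsv")
  write_cls(ds$matrix$samples$group, paths[[3L]])
  write_gmt(ds$gene_sets, paths[[4L]])
  write_network(ds$network, paths[[5L]], header = FALSE)
  jsonlite::write_json(
    list(planted_de_set_names = ds$truth$planted_de_set_names,
         planted_up_or_down = as.list(ds$truth$planted_up_or_down),
         planted_link_pairs = ds$truth$planted_link_pairs,
         de_gene_list = ds$truth$de_gene_list),
    paths[[6L]], auto_unbox = TRUE, pretty = TRUE)
  write_manifest(outdir, syn$rng_seed, paths)
  invisible(paths)
}

#' Run the full inference chain
#'
#' Stages: load expression (or simulate when a `synthetic` section is
#' given and no `expression` path), optional probe collapse and
#' mean-replicate imputation, SNR ranking + GSEA, perturbed-gene union,
#' interaction-network confidence and universe filters, candidate link
#' construction, Metropolis sampling, posterior thresholding. Writes the
#' enrichment TSV, perturbed gene list, link probability TSV, process
#' network SIF + GraphML, per-link support reports (JSON), dendrogram
#' Newick files, and a manifest. Filter counts are logged via `message()`.
#'
#' @param config A `PipelineConfig`.
#' @return Invisibly, a list with the in-memory results (`results`,
#'   `perturbed`, `bpn`, `process_network`, `outdir`).
#' @export
cmd_run <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$expression)) {
    mat <- step("load_expression",
                load_expression(config$expression,
                                config$format %||% "gct"))
    if (!is.null(config$cls)) {
      labels <- read_cls(config$cls)
      mat$samples$group <- labels
    }
    collection <- step("read_gmt", read_gmt(config$gmt))
    net_raw <- step("load_interactions",
                    load_interactions(config$network,
                                      config$score_min %||% 500L))
    truth <- NULL
  } else if (!is.null(config$synthetic_config)) {
    ds <- step("simulate", generate_synthetic_dataset(config$synthetic_config))
    mat <- ds$matrix
    collection <- ds$gene_sets
    net_raw <- ds$network
    truth <- ds$truth
  } else {
    stop("pipeline config needs either an expression path or a synthetic ",
         "section")
  }

  if (!is.null(config$probe_map)) {
    map <- read.delim(config$probe_map, stringsAsFactors = FALSE)
    mat <- step("collapse_probes", collapse_probes(mat, map))
  }
  if (!is.null(config$impute_group)) {
    grp <- sample_group("short_group", unlist(config$impute_group))
    mat <- step("impute_mean_replicate", impute_mean_replicate(mat, grp))
  }

  groups <- unique(mat$samples$group)
  if (length(groups) != 2L)
    stop("stage [contrast] failed: need exactly 2 sample classes, got ",
         length(groups))
  contr <- contrast(
    sample_group(groups[[2L]],
                 mat$samples$sample_id[mat$samples$group == groups[[2L]]]),
    sample_group(groups[[1L]],
                 mat$samples$sample_id[mat$samples$group == groups[[1L]]]))

  tree <- step("cluster_samples", cluster_samples(mat))
  writeLines(as_newick(tree), file.path(outdir, "dendrogram.nwk"))

  results <- step("run_gsea",
                  run_gsea(mat, contr, collection, config$gsea_config))
  write_enrichment(results, file.path(outdir, "enrichment.tsv"))
  write_enrichment_json(results, file.path(outdir, "enrichment.json"))
  q_thr <- config$gsea_config$q_threshold
  sig <- results[results$q <= q_thr, , drop = FALSE]
  message(nrow(sig), " of ", nrow(results),
          " tested gene sets significant at q <= ", q_thr)

  perturbed <- leading_edge_union(results, q_thr)
  writeLines(perturbed, file.path(outdir, "perturbed_genes.txt"))

  net <- step("restrict_to_measured",
              restrict_to_measured(net_raw, rownames(mat$values)))

  out <- list(results = results, perturbed = perturbed, truth = truth,
              bpn = NULL, process_network = NULL, outdir = outdir)
  candidates <- build_candidate_links(sig, perturbed, net)
  if (!length(candidates)) {
    warning("no candidate links between significant gene sets; ",
            "writing an empty process network")
    writeLines(character(0), file.path(outdir, "bpn.sif"))
  } else {
    fit <- step("mcmc_bpn", mcmc_bpn(candidates, config$bpn_config))
    write_links(fit, file.path(outdir, "link_probabilities.tsv"))
    pn <- threshold_bpn(fit, results = results)
    write_sif(pn, file.path(outdir, "bpn.sif"))
    write_graphml(pn, file.path(outdir, "bpn.graphml"), results = results)
    reports <- lapply(candidates, function(l) {
      r <- link_report(l)
      list(set_a = r$set_a, set_b = r$set_b, n_support = r$n_support,
           n_leading_edge_support = r$n_leading_edge_support,
           support = r$support)
    })
    jsonlite::write_json(reports, file.path(outdir, "link_reports.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message(nrow(pn$links), " links retained at tau = ", pn$tau, " among ",
            nrow(pn$nodes), " gene sets (", pn$n_components,
            " components)")
    out$bpn <- fit
    out$process_network <- pn
  }
  write_manifest(outdir, config$seed,
                 list.files(outdir, full.names = TRUE))
  invisible(out)
}
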