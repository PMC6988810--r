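#' Pipeline configuration
#'
#' One structured configuration (plus one master seed) drives the
#' whole analysis; every randomized stage receives a seed derived
#' deterministically from the master seed, so identical configurations
#' yield identical outputs.
#'
#' @param depth_policy rarefaction depth: `"second_lowest"` (default;
#'   the conventional choice when the shallowest sample is meant to be
#'   dropped), `"lowest"`, or a fixed positive integer.
#' @param clam a [clam_params].
#' @param clam_stations optional station subset for the two-habitat
#'   comparison (default: all stations).
#' @param mic a [mic_params].
#' @param null_model,n_random,min_degree network-stage settings: the
#'   random-graph null (`"same_n_m"` or `"degree_preserving"`), the
#'   number of random replicates, and the hub degree threshold.
#' @param trophic_rules a `trophic_rules` table (default: the shipped
#'   group-level conventions).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth_policy = "second_lowest",
                            clam = clam_params(),
                            clam_stations = NULL,
                            mic = mic_params(),
                            null_model = "same_n_m",
                            n_random = 100L,
                            min_degree = 20L,
                            trophic_rules = NULL,
                            seed = 1L) {
  cfg <- list(depth_policy = depth_policy, clam = clam,
              clam_stations = clam_stations, mic = mic,
              null_model = match.arg(null_model,
                                     c("same_n_m", "degree_preserving")),
              n_random = as.integer(n_random),
              min_degree = as.integer(min_degree),
              trophic_rules = trophic_rules,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-habitat analysis pipeline
#'
#' Replicate pooling, singleton removal, rarefying, alpha-diversity and
#' the shared/exclusive habitat partition, CLAM classification on
#' depth-equalized habitat pools, trophic annotation and composition,
#' and MIC network inference with topology, random-null comparison and
#' hubs.  A manifest records every parameter, derived seed and
#' intermediate shape; rerunning with the same inputs and seed
#' reproduces every output bit-identically.
#'
#' @param table an [otu_table] (raw counts, replicates as columns).
#' @param metadata a [sample_metadata].
#' @param taxonomy optional `taxonomy_table`.
#' @param config a [pipeline_config].
#' @param outdir optional directory; when given, writes per-stage TSV
#'   and JSON outputs, a GraphML export and `manifest.json`.
#' @return list of class `pipeline_result` with elements `pooled`,
#'   `rarefied`, `diversity`, `venn`, `clam`, `trophic`,
#'   `trophic_composition`, `edges`, `network`, `network_stats`,
#'   `hubs`, `habitat_edges`, `manifest`.
#' @export
run_pipeline <- function(table, metadata, taxonomy = NULL,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(rarefy = derive_seed(config$seed, "rarefy"),
                clam_pool = derive_seed(config$seed, "clam_pool"),
                mic = derive_seed(config$seed, "mic"),
                null = derive_seed(config$seed, "null"))

  log_stage("pool", "input %d OTUs x %d samples", nrow(table), ncol(table))
  pooled <- pool_replicates(table, metadata)
  log_stage("pool", "pooled to %d samples", ncol(pooled$table))

  nosing <- remove_singletons(pooled$table)
  log_stage("singletons", "%d of %d OTUs retained",
            nrow(nosing), nrow(pooled$table))

  depth <- resolve_depth(nosing, config$depth_policy)
  rarefied <- rarefy_table(nosing, depth, seed = seeds$rarefy)
  rarefied <- rarefied[rowSums(rarefied) > 0, , drop = FALSE]
  log_stage("rarefy", "depth %d; %d OTUs x %d samples retained",
            depth, nrow(rarefied), ncol(rarefied))
  rmeta <- pooled$metadata[pooled$metadata$sample_id %in%
                             colnames(rarefied), , drop = FALSE]

  div <- diversity_summary(rarefied)
  venn <- venn_partition(rarefied, rmeta)

  pools <- pool_by_habitat(nosing, pooled$metadata,
                           stations = config$clam_stations,
                           seed = seeds$clam_pool)
  clam <- clam_classify(pools$count_A, pools$count_B, config$clam)
  log_stage("clam", "habitat depth %d; classes: %s", pools$depth,
            paste(names(table(clam$class)), as.integer(table(clam$class)),
                  sep = "=", collapse = ", "))

  trophic <- NULL; tcomp <- NULL
  if (!is.null(taxonomy)) {
    rules <- config$trophic_rules %||% default_trophic_rules()
    trophic <- assign_trophic(taxonomy, rules)
    tcomp <- trophic_composition(rarefied, rmeta,
                                 trophic[rownames(rarefied)])
  }

  mp <- config$mic
  mp$seed <- seeds$mic
  filtered <- filter_min_total(rarefied, mp$min_total_reads)
  log_stage("mic", "%d OTUs with >= %d reads; %d pairs",
            nrow(filtered), mp$min_total_reads, choose(nrow(filtered), 2))
  edges <- build_edge_set(filtered, mp)

  totals <- rowSums(rarefied)
  net <- build_network(edges, clam = clam, taxonomy = taxonomy,
                       trophic = trophic, total_reads = totals)
  nstats <- if (igraph::vcount(net) > 0L)
    network_stats(net, n_random = config$n_random,
                  model = config$null_model, seed = seeds$null)
  else NULL
  hubs <- if (!is.null(nstats)) identify_hubs(nstats, config$min_degree)
          else data.frame(otu_id = character(), degree = integer())
  hedges <- if (igraph::vcount(net) > 0L) habitat_edge_summary(net) else NULL
  if (!is.null(nstats))
    log_stage("network", "%d nodes, %d edges, C = %.3f, L = %.3f, %d hubs",
              nstats$n_nodes, nstats$n_edges, nstats$C, nstats$L, nrow(hubs))

  manifest <- list(
    seed = config$seed, derived_seeds = seeds,
    depth_policy = config$depth_policy, depth = depth,
    clam = unclass(config$clam), clam_stations = config$clam_stations,
    clam_habitat_depth = pools$depth,
    mic = unclass(mp), null_model = config$null_model,
    n_random = config$n_random, min_degree = config$min_degree,
    shapes = list(input = dim(table), pooled = dim(pooled$table),
                  singleton_filtered = dim(nosing),
                  rarefied = dim(rarefied), mic_input = dim(filtered),
                  n_edges = nrow(edges)))

  result <- list(pooled = pooled, rarefied = rarefied, diversity = div,
                 venn = venn, clam = clam, trophic = trophic,
                 trophic_composition = tcomp, edges = edges, network = net,
                 network_stats = nstats, hubs = hubs,
                 habitat_edges = hedges, manifest = manifest)
  class(result) <- "pipeline_result"
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Two-habitat protist community analysis\n")
  cat(sprintf("  rarefied table: %d OTUs x %d samples (depth %d)\n",
              nrow(x$rarefied), ncol(x$rarefied), x$manifest$depth))
  print(x$venn)
  print(x$clam)
  if (!is.null(x$network_stats)) print(x$network_stats)
  invisible(x)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(outdir, name)
  counts <- data.frame(otu_id = rownames(result$rarefied),
                       as.data.frame(unclass(result$rarefied)),
                       check.names = FALSE)
  write_tsv(counts, fp("rarefied_counts.tsv"))
  write_tsv(result$diversity, fp("diversity.tsv"))
  jsonlite::write_json(unclass(result$venn), fp("venn.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(as.data.frame(result$clam), fp("clam.tsv"))
  jsonlite::write_json(summary(result$clam), fp("clam_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$trophic_composition))
    write_tsv(result$trophic_composition, fp("trophic_composition.tsv"))
  write_tsv(as.data.frame(result$edges), fp("edges.tsv"))
  if (igraph::vcount(result$network) > 0L)
    export_network(result$network, graphml = fp("network.graphml"))
  if (!is.null(result$network_stats)) {
    st <- result$network_stats
    jsonlite::write_json(
      list(n_nodes = st$n_nodes, n_edges = st$n_edges, C = st$C, L = st$L,
           L_largest_component = st$L_largest_component, Cr = st$Cr,
           Lr = st$Lr, null_model = st$null_model, n_random = st$n_random,
           hubs = result$hubs$otu_id),
      fp("network_summary.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(result$hubs, fp("hubs.tsv"))
    write_tsv(result$habitat_edges, fp("habitat_edges.tsv"))
  }
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
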