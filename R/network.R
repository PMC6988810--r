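#' Build the co-occurrence network from a significant edge set
#'
#' Simple undirected graph on the OTUs incident to at least one
#' significant edge (isolated OTUs are excluded).  Node attributes
#' carry taxonomy group, CLAM class, trophic class and total reads when
#' the corresponding tables are supplied; missing annotations become
#' `"unknown"`.  Exact duplicate pairs are deduplicated with a warning;
#' duplicates with conflicting attributes are an error.
#'
#' @param edges a `mic_edge_set` (or data.frame with `otu_a`, `otu_b`,
#'   `mic`, `sign`).
#' @param clam optional `clam_result` for node classes.
#' @param taxonomy optional `taxonomy_table` for node groups.
#' @param trophic optional named vector of trophic categories.
#' @param total_reads optional named vector of per-OTU totals.
#' @return an [igraph::igraph] object.
#' @export
build_network <- function(edges, clam = NULL, taxonomy = NULL,
                          trophic = NULL, total_reads = NULL) {
  if (nrow(edges) == 0L) {
    warning("empty edge list: returning an empty network", call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  key <- paste(pmin(edges$otu_a, edges$otu_b),
               pmax(edges$otu_a, edges$otu_b), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    chk <- split(paste(signif(edges$mic, 12), edges$sign), key[dup])
    if (any(vapply(chk, function(v) length(unique(v)) > 1L, logical(1))))
      stop("conflicting duplicate edges in the edge list", call. = FALSE)
    warning("deduplicating repeated edge pair(s)", call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (any(edges$otu_a == edges$otu_b))
    stop("self-loop in the edge list", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_a", "otu_b",
              intersect(c("mic", "pearson_r", "nonlinearity", "p_value",
                          "sign"), names(edges)))],
    directed = FALSE)
  ids <- igraph::V(g)$name
  lookup <- function(map, default = "unknown") {
    v <- map[ids]
    v[is.na(v)] <- default
    unname(v)
  }
  if (!is.null(clam))
    igraph::V(g)$clam_class <- lookup(
      stats::setNames(as.character(clam$class), clam$otu_id))
  if (!is.null(taxonomy))
    igraph::V(g)$group <- lookup(
      stats::setNames(taxonomy$group, taxonomy$otu_id))
  if (!is.null(trophic)) {
    tv <- as.character(trophic[ids]); tv[is.na(tv)] <- "unknown"
    igraph::V(g)$trophic <- unname(tv)
  }
  if (!is.null(total_reads)) {
    tr <- total_reads[ids]; tr[is.na(tr)] <- 0
    igraph::V(g)$total_reads <- unname(as.numeric(tr))
  }
  g
}

#' Network topology statistics
#'
#' Degree per node; `C`, the mean local clustering coefficient with
#' degree-below-2 nodes contributing 0; and `L`, the mean shortest-path
#' length over all connected ordered pairs (disconnected pairs are
#' excluded and their number reported).  `L_largest_component` gives
#' the same average restricted to the largest connected component.
#'
#' @param net an igraph network.
#' @return list of class `network_stats` with `n_nodes`, `n_edges`,
#'   `degree`, `C`, `L`, `L_largest_component`,
#'   `n_disconnected_pairs`.
#' @export
topology <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1L) stop("network has no nodes", call. = FALSE)
  deg <- igraph::degree(net)
  C <- if (igraph::ecount(net) == 0L) 0
       else igraph::transitivity(net, type = "localaverage",
                                 isolates = "zero")
  d <- igraph::distances(net)
  finite <- is.finite(d) & upper.tri(d)
  L <- if (any(finite)) mean(d[finite]) else NA_real_
  comp <- igraph::components(net)
  lcc <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  Llcc <- if (igraph::vcount(lcc) > 1L)
    igraph::mean_distance(lcc, unconnected = FALSE) else NA_real_
  out <- list(n_nodes = n, n_edges = igraph::ecount(net),
              degree = deg, C = C, L = L,
              L_largest_component = Llcc,
              n_disconnected_pairs = sum(!is.finite(d) & upper.tri(d)))
  class(out) <- "network_stats"
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  C = %.4f, L = %.4f (%d disconnected pairs excluded)\n",
              x$C, x$L, x$n_disconnected_pairs))
  if (!is.null(x$Cr))
    cat(sprintf("  random null (%s, n = %d): Cr = %.4f, Lr = %.4f\n",
                x$null_model, x$n_random, x$Cr, x$Lr))
  invisible(x)
}

#' Random-graph null comparison
#'
#' Compares the observed network against random replicates: either
#' uniform simple graphs with the same node and edge counts
#' (`same_n_m`, the G(n, m) model) or degree-preserving edge-swap
#' randomizations (at least `10 * |E|` successful swaps).  Returns the
#' mean clustering coefficient and characteristic path length over
#' replicates together with the raw distributions.
#'
#' @param net an igraph network.
#' @param n_random number of replicates (conventionally 100).
#' @param model `"same_n_m"` or `"degree_preserving"`.
#' @param seed integer seed.
#' @return list with `Cr`, `Lr`, `C_dist`, `L_dist`, `model`,
#'   `n_random`.
#' @export
random_null <- function(net, n_random = 100L,
                        model = c("same_n_m", "degree_preserving"),
                        seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_random >= 1)
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  set.seed(as.integer(seed))
  cs <- numeric(n_random); ls <- numeric(n_random)
  for (r in seq_len(n_random)) {
    g <- if (model == "same_n_m") igraph::sample_gnm(n, m)
         else igraph::rewire(net, igraph::keeping_degseq(niter = 10L * m))
    st <- topology(g)
    cs[r] <- st$C; ls[r] <- st$L
  }
  list(Cr = mean(cs), Lr = mean(ls), C_dist = cs, L_dist = ls,
       model = model, n_random = as.integer(n_random))
}

#' Full network statistics with the random null attached
#'
#' @inheritParams random_null
#' @return `network_stats` with `Cr`, `Lr`, `null_model`, `n_random`
#'   fields added.
#' @export
network_stats <- function(net, n_random = 100L,
                          model = c("same_n_m", "degree_preserving"),
                          seed = 1L) {
  st <- topology(net)
  nul <- random_null(net, n_random = n_random, model = model, seed = seed)
  st$Cr <- nul$Cr; st$Lr <- nul$Lr
  st$null_model <- nul$model; st$n_random <- nul$n_random
  st
}

#' Identify hub nodes
#'
#' Nodes with degree at least `min_degree`, sorted by decreasing
#' degree with ties broken by node id.
#'
#' @param stats a `network_stats` (or any list with a named `degree`
#'   vector).
#' @param min_degree integer threshold (default 20).
#' @return data.frame with `otu_id` and `degree`.
#' @export
identify_hubs <- function(stats, min_degree = 20L) {
  deg <- stats$degree
  keep <- deg >= min_degree
  ids <- names(deg)[keep]
  dg <- unname(deg[keep])
  o <- order(-dg, ids)
  data.frame(otu_id = ids[o], degree = as.integer(dg[o]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge summary by habitat class of the endpoints
#'
#' Tallies edges by the CLAM classes at their endpoints --
#' specialist_A--specialist_A, specialist_B--specialist_B,
#' specialist_A--specialist_B, generalist-involving, and other (a
#' too_rare or unknown endpoint) -- with the fraction of negative
#' edges overall and within each category.
#'
#' @param net an igraph network whose nodes carry `clam_class` and
#'   whose edges carry `sign`.
#' @return data.frame with `category`, `n_edges`, `negative_fraction`,
#'   plus an `"overall"` row.
#' @export
habitat_edge_summary <- function(net) {
  if (is.null(igraph::V(net)$clam_class))
    stop("nodes lack clam_class annotation", call. = FALSE)
  ends <- igraph::as_edgelist(net)
  cls <- stats::setNames(igraph::V(net)$clam_class, igraph::V(net)$name)
  c1 <- cls[ends[, 1L]]; c2 <- cls[ends[, 2L]]
  cat_of <- function(a, b) {
    ifelse(a == "specialist_A" & b == "specialist_A", "A-A",
    ifelse(a == "specialist_B" & b == "specialist_B", "B-B",
    ifelse((a == "specialist_A" & b == "specialist_B") |
           (a == "specialist_B" & b == "specialist_A"), "A-B",
    ifelse(a == "generalist" | b == "generalist", "generalist", "other"))))
  }
  category <- cat_of(c1, c2)
  sgn <- igraph::E(net)$sign
  if (is.null(sgn)) sgn <- rep("positive", length(category))
  levs <- c("A-A", "B-B", "A-B", "generalist", "other")
  rows <- lapply(levs, function(lv) {
    sel <- category == lv
    data.frame(category = lv, n_edges = sum(sel),
               negative_fraction = if (any(sel))
                 mean(sgn[sel] == "negative") else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(category = "overall", n_edges = length(category),
                        negative_fraction = if (length(category))
                          mean(sgn == "negative") else NA_real_,
                        stringsAsFactors = FALSE))
}

#' Export a network to GraphML and edge-list TSV
#'
#' @param net an igraph network.
#' @param graphml,edges_tsv output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(net, graphml, format = "graphml")
  if (!is.null(edges_tsv)) {
    el <- igraph::as_edgelist(net)
    df <- data.frame(otu_a = el[, 1L], otu_b = el[, 2L],
                     stringsAsFactors = FALSE)
    for (at in igraph::edge_attr_names(net))
      df[[at]] <- igraph::edge_attr(net, at)
    utils::write.table(df, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphml, edges_tsv = edges_tsv))
}
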