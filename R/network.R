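#' Build a thresholded co-occurrence network
#'
#' Keeps an undirected edge for every taxon pair with `|r| > r_cut` and
#' `p < p_cut` (strict inequalities, so a correlation of exactly 0.7 is
#' excluded). Isolated nodes are retained with degree zero; edges carry the
#' correlation, its sign, and the pseudo p-value.
#'
#' @param res result of [sparcc_bootstrap_p()] (or a list with matrices `r`
#'   and `p`).
#' @param r_cut absolute-correlation threshold (default 0.7).
#' @param p_cut p-value threshold (default 0.05).
#' @param node_groups optional named vector mapping taxon id to an
#'   enrichment-group attribute.
#' @return an `igraph` graph with vertex attribute `group` (when given) and
#'   edge attributes `r`, `sign`, `p`; graph attributes record the
#'   thresholds.
#' @export
build_network <- function(res, r_cut = 0.7, p_cut = 0.05, node_groups = NULL) {
  r <- res$r; p <- res$p
  taxa <- colnames(r)
  sel <- which(abs(r) > r_cut & p < p_cut & upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(
    from = taxa[sel[, 1L]], to = taxa[sel[, 2L]],
    r = r[sel], sign = ifelse(r[sel] > 0, "positive", "negative"),
    p = p[sel], stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = taxa))
  if (!is.null(node_groups)) {
    igraph::V(g)$group <- unname(node_groups[igraph::V(g)$name])
  }
  g <- igraph::set_graph_attr(g, "r_cut", r_cut)
  igraph::set_graph_attr(g, "p_cut", p_cut)
}

#' Topology metrics of a co-occurrence network
#'
#' Standard unweighted metrics on the simple undirected graph: node/edge
#' counts, global clustering (mean local clustering over nodes of degree
#' >= 2), average shortest path length on the largest connected component,
#' average degree, density, and graph-level mean betweenness and degree
#' centrality.
#'
#' @param net an `igraph` graph.
#' @return named list of metrics.
#' @export
topology <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n == 0L || e == 0L) {
    warning("empty graph: all metrics reported as 0")
    return(list(node_number = n, edge_number = e, clustering_coefficient = 0,
                average_path_length = 0, average_degree = if (n > 0) 0 else 0,
                graph_density = 0, betweenness_centrality = 0,
                degree_centrality = 0))
  }
  deg <- igraph::degree(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  eligible <- deg >= 2
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(net, which(comp$membership ==
                                                 which.max(comp$csize)))
  list(
    node_number = n,
    edge_number = e,
    clustering_coefficient = if (any(eligible)) mean(loc[eligible]) else 0,
    average_path_length = igraph::mean_distance(giant, directed = FALSE),
    average_degree = 2 * e / n,
    graph_density = igraph::edge_density(net),
    betweenness_centrality = mean(igraph::betweenness(net, directed = FALSE,
                                                      normalized = TRUE)),
    degree_centrality = mean(deg / (n - 1))
  )
}

#' Compare two networks by bootstrapped node attributes
#'
#' For each node attribute (degree, closeness centrality, betweenness
#' centrality, and transitivity centrality, i.e. the local clustering
#' coefficient), the two networks' node-level vectors are compared with a
#' two-sample Kolmogorov-Smirnov test; in addition the vectors are resampled
#' with replacement `n_boot` times and the median bootstrap KS p-value is
#' reported alongside the original-vector test.
#'
#' @param net_a,net_b `igraph` graphs.
#' @param attributes which node attributes to compare.
#' @param n_boot bootstrap rounds (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per attribute: `ks_statistic`, `ks_p`
#'   (original vectors), `boot_median_p`.
#' @export
compare_networks_ks <- function(net_a, net_b,
                                attributes = c("degree", "closeness",
                                               "betweenness", "transitivity"),
                                n_boot = 10000, seed = 1) {
  attributes <- match.arg(attributes, several.ok = TRUE)
  if (igraph::vcount(net_a) == 0L || igraph::vcount(net_b) == 0L) {
    stop("both networks must be nonempty")
  }
  node_attr <- function(g, what) {
    switch(what,
      degree = igraph::degree(g),
      closeness = {
        v <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
        v[!is.finite(v)] <- 0
        v
      },
      betweenness = igraph::betweenness(g, directed = FALSE, normalized = TRUE),
      transitivity = igraph::transitivity(g, type = "local", isolates = "zero")
    )
  }
  rows <- list()
  for (what in attributes) {
    va <- node_attr(net_a, what); vb <- node_attr(net_b, what)
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) == 0L || length(vb) == 0L ||
        (length(unique(c(va, vb))) == 1L && what == "transitivity" &&
         all(c(va, vb) == 0))) {
      warning("attribute '", what, "' undefined for all nodes; skipped")
      next
    }
    orig <- suppressWarnings(stats::ks.test(va, vb))
    boot_p <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        suppressWarnings(stats::ks.test(
          sample(va, length(va), replace = TRUE),
          sample(vb, length(vb), replace = TRUE)
        )$p.value)
      }, numeric(1))
    })
    rows[[what]] <- data.frame(
      attribute = what,
      ks_statistic = unname(orig$statistic),
      ks_p = orig$p.value,
      boot_median_p = stats::median(boot_p),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edge overlap between two networks
#'
#' Set algebra on unordered node-pair keys: edges shared by both networks
#' and edges specific to each.
#'
#' @param net_a,net_b `igraph` graphs over comparable node id spaces.
#' @return list with `shared`, `a_specific`, `b_specific` (character vectors
#'   of `"u|v"` keys) and `counts` (named integer vector).
#' @export
edge_overlap <- function(net_a, net_b) {
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0L) return(character(0))
    apply(el, 1L, function(e) paste(sort(e), collapse = "|"))
  }
  ka <- key(net_a); kb <- key(net_b)
  shared <- intersect(ka, kb)
  list(
    shared = shared,
    a_specific = setdiff(ka, kb),
    b_specific = setdiff(kb, ka),
    counts = c(shared = length(shared),
               a_specific = length(setdiff(ka, kb)),
               b_specific = length(setdiff(kb, ka)))
  )
}
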