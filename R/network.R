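#' Build a signed association network
#'
#' Keeps the significant edges of one association table that belong to the
#' requested network (synchronous = delay 0, time-shifted = nonzero
#' delay) and assembles an undirected igraph with signed edge weights.
#' Isolated nodes are dropped by construction (nodes enter via their
#' edges).
#'
#' @param assoc association table from [pairwise_associations()].
#' @param which `"synchronous"` or `"time_shifted"`.
#' @param node_attrs optional data.frame with column `otu_id` plus node
#'   attributes (e.g. `domain`, `core`, `preferred_season`) to attach.
#' @return undirected [igraph::igraph] with edge attributes `weight`
#'   (signed), `abs_weight`, `type`, `delay`, `sign`.
#' @export
build_network <- function(assoc, which = c("synchronous", "time_shifted"),
                          node_attrs = NULL) {
  which <- match.arg(which)
  ed <- assoc[assoc$significant & assoc$network == which, , drop = FALSE]
  if (nrow(ed) == 0) {
    warning("no significant ", which, " edges; returning empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$otu_a, to = ed$otu_b,
               weight = ed$weight, abs_weight = abs(ed$weight),
               type = ed$edge_type, delay = ed$delay,
               sign = ifelse(ed$weight >= 0, "+", "-"),
               stringsAsFactors = FALSE),
    directed = FALSE)
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(g)$name, node_attrs$otu_id)
    for (col in setdiff(names(node_attrs), "otu_id"))
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
  }
  g
}

#' Topology summary of an association network
#'
#' @param net an igraph network from [build_network()].
#' @return list: `nodes`, `edges`, `density` (2E / V(V-1); 0 with
#'   `density_defined = FALSE` when V <= 1), `mean_degree`,
#'   `n_positive`, `n_negative`, `n_by_type` (named table).
#' @export
network_properties <- function(net) {
  V <- igraph::vcount(net)
  E <- igraph::ecount(net)
  dens_def <- V > 1
  w <- if (E > 0) igraph::E(net)$weight else numeric(0)
  ty <- if (E > 0) igraph::E(net)$type else character(0)
  list(nodes = V, edges = E,
       density = if (dens_def) 2 * E / (V * (V - 1)) else 0,
       density_defined = dens_def,
       mean_degree = if (V > 0) 2 * E / V else 0,
       n_positive = sum(w > 0), n_negative = sum(w < 0),
       n_by_type = table(ty))
}

#' Weighted topological importance (WI^n)
#'
#' Node importance combining direct and up-to-`n`-step indirect
#' interaction effects. With \eqn{D_i = \sum_j |w_{ij}|}, the one-step
#' effect of node j on its neighbour i is \eqn{a_{ij} = |w_{ij}| / D_i}
#' (each node divides its attention among neighbours in proportion to
#' interaction strength), m-step effects are the matrix power
#' \eqn{A^m} (walks may revisit nodes), the total m-step effect spread by
#' node j is \eqn{\sigma_{m,j} = \sum_{i \ne j} (A^m)_{ij}} (self-effects
#' excluded at every step), and
#' \eqn{WI^n_j = (\sum_{m=1}^n \sigma_{m,j}) / n}. Edge signs are
#' ignored here (absolute weights); direction of a node's interactions is
#' classified separately by [keystone_sign()]. WI is invariant to
#' rescaling all weights.
#'
#' @param net igraph network with a `weight` edge attribute (signed
#'   weights allowed).
#' @param steps maximum number of steps `n`, default 3 (the WI^3 used
#'   for keystone identification).
#' @return data.frame with `otu_id`, `sigma_1..sigma_n`, `wi`, and
#'   logical `isolated` (WI = 0).
#' @export
topological_importance <- function(net, steps = 3) {
  V <- igraph::vcount(net)
  ids <- igraph::V(net)$name
  if (is.null(ids)) ids <- as.character(seq_len(V))
  if (V == 0)
    return(data.frame(otu_id = character(), wi = numeric()))
  W <- abs(igraph::as_adjacency_matrix(net, attr = "weight",
                                       sparse = FALSE))
  Di <- rowSums(W)
  isolated <- Di == 0
  A <- W
  A[!isolated, ] <- W[!isolated, , drop = FALSE] / Di[!isolated]
  sig <- matrix(0, nrow = V, ncol = steps,
                dimnames = list(ids, paste0("sigma_", seq_len(steps))))
  Am <- diag(V)
  for (m in seq_len(steps)) {
    Am <- Am %*% A
    sig[, m] <- colSums(Am) - diag(Am)
  }
  out <- data.frame(otu_id = ids, sig, wi = rowSums(sig) / steps,
                    isolated = isolated, stringsAsFactors = FALSE)
  out$wi[isolated] <- 0
  rownames(out) <- NULL
  out
}

#' Keystone OTU selection from WI^3 values
#'
#' Keystones are the nodes with `WI^3 > 1`; if fewer than `expand_below`
#' (default 6) nodes qualify, the selection is expanded to `WI^3 >= 1`.
#'
#' @param wi named numeric vector of WI^3 values (names = OTU ids), or
#'   the data.frame from [topological_importance()].
#' @param expand_below expand the rule when fewer keystones than this.
#' @return character vector of keystone OTU ids.
#' @export
call_keystones <- function(wi, expand_below = 6) {
  if (is.data.frame(wi)) wi <- stats::setNames(wi$wi, wi$otu_id)
  ks <- names(wi)[wi > 1]
  if (length(ks) < expand_below) ks <- names(wi)[wi >= 1]
  ks
}

#' Interaction-direction class of a node
#'
#' A keystone is *positive* when the sum of its signed incident edge
#' weights is positive (richly connected via positive associations),
#' *negative* when the sum is negative, *unspecified* on an exact
#' balance.
#'
#' @param net igraph network with signed `weight`.
#' @param node node (OTU id) present in the network.
#' @return `"positive"`, `"negative"` or `"unspecified"`.
#' @export
keystone_sign <- function(net, node) {
  if (!node %in% igraph::V(net)$name) stop("node '", node, "' not in network")
  inc <- igraph::incident(net, node)
  s <- sum(igraph::E(net)$weight[as.integer(inc)])
  if (abs(s) < 1e-12) "unspecified" else if (s > 0) "positive" else "negative"
}

#' Preferred season of an abundance series
#'
#' Two published rules are implemented. `method = "relabund"` (network
#' node colouring): a season is preferred when the difference between the
#' mean relative abundance in that season and the mean over the whole
#' study exceeds the (population) standard deviation over the whole
#' study. `method = "zscore"` (keystone heatmaps): the preferred season
#' is the one with positive mean z-score-transformed abundance. Under
#' either rule, no qualifying season gives `"none"` and more than one
#' gives `"unspecified"`.
#'
#' @param values abundance values at the present occasions (relative
#'   abundances for `"relabund"`).
#' @param season_labels season of each value.
#' @param method `"relabund"` or `"zscore"`.
#' @return single season label, `"none"`, or `"unspecified"`; seasons
#'   without present samples are skipped and listed in the
#'   `skipped_seasons` attribute.
#' @export
preferred_season <- function(values, season_labels,
                             method = c("relabund", "zscore")) {
  method <- match.arg(method)
  if (length(values) != length(season_labels))
    stop("values and season_labels differ in length")
  seasons <- unique(season_labels)
  n <- length(values)
  qualifying <- character(0)
  if (method == "relabund") {
    mu <- mean(values)
    sd_pop <- sqrt(mean((values - mu)^2))
    for (s in seasons) {
      vs <- values[season_labels == s]
      if (mean(vs) - mu > sd_pop) qualifying <- c(qualifying, s)
    }
  } else {
    sdv <- stats::sd(values)
    z <- if (sdv == 0) rep(0, n) else (values - mean(values)) / sdv
    for (s in seasons)
      if (mean(z[season_labels == s]) > 0) qualifying <- c(qualifying, s)
  }
  out <- if (length(qualifying) == 0) "none"
  else if (length(qualifying) > 1) "unspecified"
  else qualifying
  structure(out, skipped_seasons = character(0))
}

#' Keystone report for one lake
#'
#' Joins keystone calls with their WI^3 values, interaction-direction
#' class, core-membership label, domain tag and preferred season under
#' both season rules, for the synchronous and time-shifted networks of a
#' lake. Sorted by WI^3 descending within network.
#'
#' @param networks named list with elements `synchronous` and/or
#'   `time_shifted` (igraph networks).
#' @param table the lake's [otutab] (counts) used for season profiles.
#' @param metadata the lake's metadata (`sample_id`, `time_index`,
#'   `season`, `missing`).
#' @param core character vector of core OTU ids (e.g. from
#'   [partition_core()]).
#' @param domains optional named character vector otu_id -> domain tag.
#' @param steps WI steps, default 3.
#' @return data.frame: `network`, `otu_id`, `wi`, `sign_class`, `core`,
#'   `domain`, `season_relabund`, `season_zscore`.
#' @export
keystone_report <- function(networks, table, metadata, core,
                            domains = NULL, steps = 3) {
  md <- metadata[!metadata$missing, , drop = FALSE]
  md <- md[md$sample_id %in% rownames(table), , drop = FALSE]
  md <- md[order(md$time_index), , drop = FALSE]
  fr <- unclass(relative_abundance(table))[md$sample_id, , drop = FALSE]
  rows <- list()
  for (which in names(networks)) {
    net <- networks[[which]]
    if (igraph::vcount(net) == 0) next
    ti <- topological_importance(net, steps = steps)
    ks <- call_keystones(ti)
    if (length(ks) == 0) next
    wi <- stats::setNames(ti$wi, ti$otu_id)[ks]
    rec <- data.frame(
      network = which, otu_id = ks, wi = unname(wi),
      sign_class = vapply(ks, function(o) keystone_sign(net, o), ""),
      core = ifelse(ks %in% core, "core", "non-core"),
      domain = if (is.null(domains)) "unknown" else
        unname(domains[ks]),
      season_relabund = vapply(ks, function(o)
        if (o %in% colnames(fr))
          as.character(preferred_season(fr[, o], md$season, "relabund"))
        else NA_character_, ""),
      season_zscore = vapply(ks, function(o)
        if (o %in% colnames(fr))
          as.character(preferred_season(fr[, o], md$season, "zscore"))
        else NA_character_, ""),
      stringsAsFactors = FALSE
    )
    rows[[which]] <- rec[order(-rec$wi), ]
  }
  if (!length(rows))
    return(data.frame(network = character(), otu_id = character(),
                      wi = numeric(), sign_class = character(),
                      core = character(), domain = character(),
                      season_relabund = character(),
                      season_zscore = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML (plus optional edge-list TSV)
#'
#' @param net igraph network.
#' @param path GraphML output path.
#' @param edge_tsv optional path for a plain edge-list TSV.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, edge_tsv = NULL) {
  igraph::write_graph(net, path, format = "graphml")
  if (!is.null(edge_tsv)) {
    if (igraph::ecount(net) > 0) {
      el <- igraph::as_data_frame(net, what = "edges")
    } else {
      el <- data.frame(from = character(), to = character())
    }
    utils::write.table(el, edge_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
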