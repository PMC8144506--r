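#' Sponge-network assembly and hub selection
#'
#' Final sponge edges are called from candidate pairs by the significance
#' of their Pearson correlation on the shared transformed expression
#' matrix: the correlation p-value comes from the Fisher z-transform (the
#' corPvalueFisher convention of co-expression toolkits), is BH-adjusted
#' across the whole candidate family, and edges with adjusted p below the
#' cutoff (optionally restricted to positive correlation and to causal
#' effect summaries above a floor) form a bipartite lncRNA-mRNA network.
#' Hub lncRNAs are the top fraction of lncRNA nodes by degree.
#'
#' @name network
#' @keywords internal
NULL

#' Fisher z-transform correlation p-value
#'
#' Two-sided p for a Pearson correlation r at sample size n, from
#' z = sqrt(n - 3) * atanh(r) against the standard normal. Symmetric in
#' the sign of r; p(0) = 1; |r| = 1 saturates at p = 0.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param n sample size (>= 4).
#' @return p-value(s) in `[0, 1]`.
#' @export
cor_pvalue_fisher <- function(r, n) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  if (any(n < 4)) stop("n must be >= 4")
  z <- sqrt(n - 3) * atanh(r)
  p <- 2 * stats::pnorm(-abs(z))
  p[abs(r) >= 1] <- 0
  p
}

new_sponge_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  lnc_degree <- if (nrow(edges)) table(edges$lnc_id) else table(character())
  mrna_degree <- if (nrow(edges)) table(edges$mrna_id) else table(character())
  structure(list(
    edges = edges,
    lnc_degree = sort(stats::setNames(as.integer(lnc_degree), names(lnc_degree)), decreasing = TRUE),
    mrna_degree = sort(stats::setNames(as.integer(mrna_degree), names(mrna_degree)), decreasing = TRUE)
  ), class = "sponge_network")
}

#' @export
print.sponge_network <- function(x, ...) {
  cat("sponge_network:", nrow(x$edges), "edges,",
      length(x$lnc_degree), "lncRNAs,", length(x$mrna_degree), "mRNAs\n")
  invisible(x)
}

#' Call sponge edges from candidate pairs
#'
#' Computes each candidate pair's Pearson correlation and Fisher-z p-value
#' on the supplied (transformed) expression matrix, BH-adjusts the
#' p-values jointly across all candidates, and retains pairs with
#' `q_cor < q_max`, `effect_summary > effect_min`, and positive
#' correlation when `require_positive_r` (ceRNA co-regulation predicts
#' positive lncRNA-mRNA correlation). Degrees are recomputed from the
#' retained edge set.
#'
#' @param data transformed expression matrix (same one the causal stage
#'   used) containing all pair genes.
#' @param pairs candidate-pair data frame (needs `lnc_id`, `mrna_id`,
#'   `k_shared`).
#' @param effects effect data frame from [estimate_pair_effects()], keyed
#'   on the same (lnc_id, mrna_id) pairs.
#' @param q_max BH-adjusted correlation significance cutoff in (0, 1].
#' @param effect_min causal-effect floor; `-Inf` (the default) disables
#'   the causal gate and effects annotate the edges.
#' @param require_positive_r keep only positively correlated pairs.
#' @return A `sponge_network`.
#' @export
call_edges <- function(data, pairs, effects, q_max = 0.05,
                       effect_min = -Inf, require_positive_r = TRUE) {
  validate_expression(data)
  stopifnot(is.data.frame(pairs), is.data.frame(effects))
  if (!is.numeric(q_max) || q_max <= 0 || q_max > 1) stop("q_max must lie in (0, 1]")
  key_p <- paste(pairs$lnc_id, pairs$mrna_id, sep = "\r")
  key_e <- paste(effects$lnc_id, effects$mrna_id, sep = "\r")
  orphans <- c(setdiff(key_p, key_e), setdiff(key_e, key_p))
  if (length(orphans)) {
    stop("pairs and effects are not aligned; orphan key(s): ",
         paste(gsub("\r", "/", utils::head(orphans, 5L)), collapse = ", "))
  }
  eff <- effects$effect_summary[match(key_p, key_e)]
  empty <- data.frame(lnc_id = character(), mrna_id = character(),
                      r = numeric(), p_cor = numeric(), q_cor = numeric(),
                      effect_summary = numeric(), k_shared = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(new_sponge_network(empty))
  absent <- setdiff(unique(c(pairs$lnc_id, pairs$mrna_id)), rownames(data))
  if (length(absent)) stop("pair gene(s) missing from expression: ",
                           paste(utils::head(absent, 10L), collapse = ", "))
  n <- ncol(data)
  r <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(data[pairs$lnc_id[i], ], data[pairs$mrna_id[i], ]), 0)
  p_cor <- cor_pvalue_fisher(r, n)
  q_cor <- bh_adjust(p_cor)
  keep <- q_cor < q_max & eff > effect_min
  if (require_positive_r) keep <- keep & r > 0
  edges <- data.frame(
    lnc_id = pairs$lnc_id, mrna_id = pairs$mrna_id,
    r = r, p_cor = p_cor, q_cor = q_cor,
    effect_summary = eff,
    k_shared = if ("k_shared" %in% names(pairs)) pairs$k_shared else NA_integer_,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(edges) <- NULL
  new_sponge_network(edges)
}

#' Select hub lncRNAs by degree
#'
#' Sorts lncRNA nodes by degree (descending, ties broken by id ascending)
#' and takes the top `max(1, floor(fraction * L))`, L the number of lncRNA
#' nodes in the network. With 24 lncRNA nodes and the default fraction of
#' 0.2 this yields 4 hubs.
#'
#' @param net a `sponge_network` with at least one edge.
#' @param fraction fraction of lncRNA nodes to keep, in (0, 1].
#' @return A `hub_set` list: `hubs` (ordered ids), `degree` (their
#'   degrees), `fraction`.
#' @export
select_hubs <- function(net, fraction = 0.2) {
  stopifnot(inherits(net, "sponge_network"))
  if (!nrow(net$edges)) stop("cannot select hubs from an empty network")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  deg <- net$lnc_degree
  ord <- order(-deg, names(deg), method = "radix")
  n_hub <- max(1L, floor(fraction * length(deg)))
  structure(list(
    hubs = names(deg)[ord][seq_len(n_hub)],
    degree = unname(deg[ord][seq_len(n_hub)]),
    fraction = fraction), class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat("hub_set (top ", format(100 * x$fraction), "% by degree): ",
      paste(x$hubs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Degree table of a sponge network
#'
#' @param net a `sponge_network`.
#' @return Data frame with columns `node_id`, `class`
#'   (`lncRNA`/`mRNA`) and `degree`, one row per node.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "sponge_network"))
  df <- rbind(
    data.frame(node_id = names(net$lnc_degree), class = "lncRNA",
               degree = unname(net$lnc_degree), stringsAsFactors = FALSE),
    data.frame(node_id = names(net$mrna_degree), class = "mRNA",
               degree = unname(net$mrna_degree), stringsAsFactors = FALSE))
  df <- df[order(-df$degree, df$node_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write the sponge edge table
#'
#' Tab-separated lnc_id, mrna_id, r, p_cor, q_cor, effect_summary,
#' k_shared, sorted by (q_cor, lnc_id, mrna_id).
#'
#' @param net a `sponge_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "sponge_network"))
  e <- net$edges
  if (nrow(e)) {
    e <- e[order(e$q_cor, e$lnc_id, e$mrna_id, method = "radix"), , drop = FALSE]
    e$r <- signif(e$r, 6L); e$p_cor <- signif(e$p_cor, 6L)
    e$q_cor <- signif(e$q_cor, 6L); e$effect_summary <- signif(e$effect_summary, 6L)
  }
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the hub list
#' @param hubs a `hub_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hubs <- function(hubs, path) {
  stopifnot(inherits(hubs, "hub_set"))
  utils::write.table(
    data.frame(lnc_id = hubs$hubs, degree = hubs$degree, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sponge network to GraphML
#'
#' Bipartite graph with node attribute `class` (lncRNA/mRNA) and the edge
#' attributes r, p_cor, q_cor, effect_summary, k_shared.
#'
#' @param net a `sponge_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "sponge_network"))
  e <- net$edges
  vertices <- data.frame(
    name = c(names(net$lnc_degree), names(net$mrna_degree)),
    class = rep(c("lncRNA", "mRNA"),
                c(length(net$lnc_degree), length(net$mrna_degree))),
    stringsAsFactors = FALSE)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = e$lnc_id, to = e$mrna_id, r = e$r, p_cor = e$p_cor,
                   q_cor = e$q_cor, effect_summary = e$effect_summary,
                   k_shared = e$k_shared, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
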