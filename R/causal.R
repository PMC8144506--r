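#' Constraint-based causal-effect estimation for sponge pairs
#'
#' The causal stage estimates lncRNA -> mRNA effects from observational
#' expression with the standard two-step recipe: (1) learn the Markov
#' equivalence class of the data-generating DAG as a CPDAG with the
#' order-independent PC-stable algorithm, using Fisher-z Gaussian
#' conditional-independence tests; (2) for each pair, run local IDA
#' ("intervention calculus when the DAG is absent"): enumerate the
#' adjustment sets compatible with the CPDAG around the lncRNA and collect
#' the multiset of regression-based total effects, summarized by the
#' signed minimum-absolute element (the conventional IDA lower bound).
#' Causal sufficiency is assumed, as the method requires; in sponge data
#' miRNAs are latent confounders, so effects are screening scores, not
#' unbiased estimates.
#'
#' A CPDAG is held as an adjacency-mark matrix `amat` with
#' `amat[i, j] == 1 && amat[j, i] == 0` meaning a directed edge i -> j and
#' both entries 1 meaning an undirected edge.
#'
#' @name causal
#' @keywords internal
NULL

#' Conditional-independence test configuration
#'
#' @param alpha per-test significance level in (0, 1); an edge survives a
#'   test when p <= alpha.
#' @param max_cond_size largest conditioning-set size the skeleton search
#'   explores (`Inf` for unbounded).
#' @return A `ci_cfg` list.
#' @export
ci_cfg <- function(alpha = 0.01, max_cond_size = 3L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!(is.infinite(max_cond_size) && max_cond_size > 0)) {
    stopifnot(max_cond_size >= 0, max_cond_size == floor(max_cond_size))
  }
  structure(list(alpha = alpha, max_cond_size = max_cond_size), class = "ci_cfg")
}

# partial correlation from a precomputed correlation matrix
.pcor_from_cor <- function(C, i, j, S) {
  if (!length(S)) {
    r <- C[i, j]
  } else {
    idx <- c(i, j, S)
    P <- tryCatch(solve(C[idx, idx, drop = FALSE]),
                  error = function(e) stop("collinear conditioning set: ",
                                           conditionMessage(e), call. = FALSE))
    r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  }
  # numeric tolerance: |r| may exceed 1 by rounding
  max(-1, min(1, r))
}

.resolve_nodes <- function(data, ids) {
  if (is.character(ids)) {
    idx <- match(ids, rownames(data))
    if (anyNA(idx)) stop("gene(s) not in matrix: ", paste(ids[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(ids)
}

#' Partial correlation of two genes given a conditioning set
#'
#' rho(i, j | S) computed by inversion of the corresponding submatrix of
#' the sample correlation matrix.
#'
#' @param data expression matrix (genes x samples).
#' @param i,j gene ids or row indices (distinct, not in `S`).
#' @param S conditioning genes (possibly empty); needs
#'   `length(S) <= ncol(data) - 4`.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(data, i, j, S = character()) {
  validate_expression(data)
  i <- .resolve_nodes(data, i); j <- .resolve_nodes(data, j)
  S <- if (length(S)) .resolve_nodes(data, S) else integer()
  if (i == j) stop("i and j must be distinct genes")
  if (i %in% S || j %in% S) stop("i and j must not be in the conditioning set")
  if (length(S) > ncol(data) - 4L) stop("conditioning set too large for the sample size")
  C <- stats::cor(t(data[unique(c(i, j, S)), , drop = FALSE]))
  map <- match(c(i, j, S), unique(c(i, j, S)))
  .pcor_from_cor(C, map[1L], map[2L], if (length(S)) map[-(1:2)] else integer())
}

.fisher_z_p <- function(r, n, s_size) {
  if (abs(r) >= 1) return(c(z = sign(r) * Inf, p = 0))
  z <- sqrt(n - s_size - 3) * atanh(r)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fisher-z conditional-independence test
#'
#' Tests rho(i, j | S) = 0 via z = sqrt(n - |S| - 3) * atanh(rho) against
#' the standard normal. A perfectly correlated pair saturates at p = 0 and
#' is declared dependent.
#'
#' @inheritParams partial_correlation
#' @param cfg a [ci_cfg()] (supplies alpha).
#' @return List with `statistic` (z), `p` and `independent` (p > alpha).
#' @export
ci_test <- function(data, i, j, S = character(), cfg = ci_cfg()) {
  validate_expression(data)
  n <- ncol(data)
  s_size <- length(S)
  if (n - s_size - 3 < 1) stop("too few samples for a conditioning set of size ", s_size)
  r <- partial_correlation(data, i, j, S)
  zp <- .fisher_z_p(r, n, s_size)
  list(statistic = unname(zp["z"]), p = unname(zp["p"]),
       independent = unname(zp["p"]) > cfg$alpha)
}

# ---- CPDAG container ---------------------------------------------------

new_cpdag <- function(amat) {
  stopifnot(is.matrix(amat), nrow(amat) == ncol(amat),
            !is.null(rownames(amat)), identical(rownames(amat), colnames(amat)))
  diag(amat) <- 0L
  structure(list(nodes = rownames(amat), amat = amat), class = "cpdag")
}

#' Construct a CPDAG from edge lists
#'
#' @param nodes character vector of node names.
#' @param directed two-column matrix/data frame of directed edges
#'   (from, to), or NULL.
#' @param undirected two-column matrix/data frame of undirected edges, or
#'   NULL.
#' @return A `cpdag` object.
#' @export
cpdag <- function(nodes, directed = NULL, undirected = NULL) {
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  add <- function(e, both) {
    if (is.null(e) || !NROW(e)) return()
    e <- as.matrix(e)
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1L]; j <- e[r, 2L]
      amat[i, j] <<- 1L
      if (both) amat[j, i] <<- 1L
    }
  }
  add(directed, both = FALSE)
  add(undirected, both = TRUE)
  g <- new_cpdag(amat)
  .validate_cpdag(g)
  g
}

.validate_cpdag <- function(g) {
  a <- g$amat
  if (any(diag(a) != 0)) stop("cpdag has a self-loop")
  invisible(g)
}

#' @export
print.cpdag <- function(x, ...) {
  cat("cpdag:", length(x$nodes), "nodes,",
      nrow(directed_edges(x)), "directed and",
      nrow(undirected_edges(x)), "undirected edges\n")
  invisible(x)
}

#' Directed edges of a CPDAG
#' @param g a `cpdag`.
#' @return Two-column character matrix (from, to).
#' @export
directed_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  m <- cbind(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Undirected edges of a CPDAG
#' @param g a `cpdag`.
#' @return Two-column character matrix with each edge once (a < b).
#' @export
undirected_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  m <- cbind(a = g$nodes[pmin(idx[, 1L], idx[, 2L])],
             b = g$nodes[pmax(idx[, 1L], idx[, 2L])])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

.parents_of <- function(amat, x) which(amat[, x] == 1L & amat[x, ] == 0L)
.siblings_of <- function(amat, x) which(amat[, x] == 1L & amat[x, ] == 1L)
.adjacent <- function(amat, i, j) (amat[i, j] + amat[j, i]) > 0L

# ---- PC-stable ---------------------------------------------------------

# Level-wise PC-stable skeleton. Adjacency sets are frozen at the start of
# each level; for an adjacent pair every candidate subset from both sides
# is tested and, if any separates, the edge is removed with the
# maximum-p-value separating set recorded (ties broken by the subset's
# sorted node names). Testing exhaustively instead of stopping at the
# first separator makes the recorded sepsets -- and hence the v-structures
# -- invariant to the order genes arrive in, not just the skeleton.
.skeleton_pc_stable <- function(C, n, nodes, alpha, max_cond_size) {
  p <- length(nodes)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p)
  for (i in seq_len(p)) sepset[[i]] <- vector("list", p)
  subset_key <- function(S) paste(sort(nodes[S]), collapse = "\r")
  lev <- 0L
  max_lev <- min(max_cond_size, p - 2L, n - 4L)
  repeat {
    if (lev > max_lev) break
    frozen <- lapply(seq_len(p), function(i) which(adj[i, ]))
    if (!any(vapply(frozen, length, 1L) - 1L >= lev)) break
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        if (!adj[i, j]) next
        combos <- list()
        for (side in list(setdiff(frozen[[i]], j), setdiff(frozen[[j]], i))) {
          if (length(side) < lev) next
          combos <- c(combos,
                      if (lev == 0L) list(integer())
                      else if (length(side) == lev) list(side)  # combn scalar trap
                      else utils::combn(side, lev, simplify = FALSE))
        }
        if (!length(combos)) next
        combos <- combos[!duplicated(vapply(combos, subset_key, ""))]
        best_p <- -1; best_S <- NULL; best_key <- ""
        for (S in combos) {
          r <- .pcor_from_cor(C, i, j, S)
          p_val <- unname(.fisher_z_p(r, n, length(S))["p"])
          key <- subset_key(S)
          if (p_val > best_p || (p_val == best_p && key < best_key)) {
            best_p <- p_val; best_S <- S; best_key <- key
          }
        }
        if (best_p > alpha) {
          adj[i, j] <- adj[j, i] <- FALSE
          sepset[[i]][[j]] <- sepset[[j]][[i]] <- best_S
        }
      }
    }
    lev <- lev + 1L
  }
  list(adj = adj, sepset = sepset)
}

.orient_v_structures <- function(adj, sepset, nodes) {
  p <- nrow(adj)
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  # collect candidate colliders, then apply in node-name order so the
  # conflict guard cannot depend on the input ordering of the genes
  triples <- list()
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (adj[i, j]) next
      ks <- which(adj[i, ] & adj[j, ])
      S <- sepset[[i]][[j]]
      for (k in ks) {
        if (!k %in% S) triples[[length(triples) + 1L]] <- c(i, j, k)
      }
    }
  }
  if (length(triples)) {
    key <- vapply(triples, function(t) {
      ends <- sort(nodes[t[1:2]])
      paste(ends[1L], ends[2L], nodes[t[3L]])
    }, "")
    for (t in triples[order(key)]) {
      i <- t[1L]; j <- t[2L]; k <- t[3L]
      # orient i -> k <- j unless an earlier collider already claimed an
      # arm in the opposite direction (first in canonical order wins)
      if (amat[i, k] == 1L) amat[k, i] <- 0L
      if (amat[j, k] == 1L) amat[k, j] <- 0L
    }
  }
  amat
}

# Meek orientation rules R1-R3, applied to a fixpoint. With orientations
# arising solely from v-structures these three rules are complete.
.meek_closure <- function(amat) {
  p <- nrow(amat)
  is_dir <- function(a, b) amat[a, b] == 1L && amat[b, a] == 0L
  is_und <- function(a, b) amat[a, b] == 1L && amat[b, a] == 1L
  adj <- function(a, b) (amat[a, b] + amat[b, a]) > 0L
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) {
      for (c_ in seq_len(p)) {
        if (b == c_ || !is_und(b, c_)) next
        oriented <- FALSE
        # R1: a -> b - c, a and c nonadjacent  =>  b -> c
        for (a in seq_len(p)) {
          if (a == b || a == c_) next
          if (is_dir(a, b) && !adj(a, c_)) { oriented <- TRUE; break }
        }
        # R2: b -> d -> c with b - c  =>  b -> c
        if (!oriented) {
          for (d in seq_len(p)) {
            if (d == b || d == c_) next
            if (is_dir(b, d) && is_dir(d, c_)) { oriented <- TRUE; break }
          }
        }
        # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 nonadjacent
        if (!oriented) {
          ds <- which(vapply(seq_len(p), function(d)
            d != b && d != c_ && is_und(b, d) && is_dir(d, c_), TRUE))
          if (length(ds) >= 2L) {
            for (u in seq_along(ds)) {
              for (v in seq_along(ds)) {
                if (u < v && !adj(ds[u], ds[v])) { oriented <- TRUE; break }
              }
              if (oriented) break
            }
          }
        }
        if (oriented) { amat[c_, b] <- 0L; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  amat
}

#' Estimate a CPDAG with the PC-stable algorithm
#'
#' Level-wise skeleton search with adjacency sets frozen at the start of
#' each level (the order-independent "stable" variant), Fisher-z Gaussian
#' conditional-independence tests, v-structure orientation from recorded
#' separating sets, and Meek-rule closure.
#'
#' @param data expression matrix (>= 2 genes x >= 10 samples).
#' @param cfg a [ci_cfg()].
#' @return A `cpdag`.
#' @export
pc_stable_cpdag <- function(data, cfg = ci_cfg()) {
  validate_expression(data)
  stopifnot(inherits(cfg, "ci_cfg"))
  p <- nrow(data); n <- ncol(data)
  if (p < 2L) stop("need at least two genes")
  if (n < 10L) stop("need at least 10 samples for skeleton estimation")
  C <- stats::cor(t(data))
  sk <- .skeleton_pc_stable(C, n, rownames(data), cfg$alpha, cfg$max_cond_size)
  amat <- .orient_v_structures(sk$adj, sk$sepset, rownames(data))
  amat <- .meek_closure(amat)
  dimnames(amat) <- list(rownames(data), rownames(data))
  g <- new_cpdag(amat)
  attr(g, "sepset") <- sk$sepset
  g
}

#' CPDAG of a DAG
#'
#' Maps a DAG to the completed partially directed graph representing its
#' Markov equivalence class: keep the skeleton, orient the v-structures,
#' close under the Meek rules.
#'
#' @param dag square 0/1 adjacency matrix with `dag[i, j] == 1` meaning
#'   i -> j; must be acyclic, with identical row/column names.
#' @return A `cpdag`.
#' @export
dag_to_cpdag <- function(dag) {
  stopifnot(is.matrix(dag), nrow(dag) == ncol(dag))
  if (is.null(rownames(dag))) {
    rownames(dag) <- colnames(dag) <- paste0("v", seq_len(nrow(dag)))
  }
  p <- nrow(dag)
  if (any(dag == 1L & t(dag) == 1L)) stop("dag has a 2-cycle")
  # acyclicity via repeated sink elimination
  left <- seq_len(p)
  while (length(left)) {
    sinks <- which(rowSums(dag[left, left, drop = FALSE]) == 0)
    if (!length(sinks)) stop("graph is cyclic")
    left <- left[-sinks[1L]]
  }
  adj <- (dag + t(dag)) > 0
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  for (k in seq_len(p)) {
    pa <- which(dag[, k] == 1L)
    if (length(pa) < 2L) next
    for (u in seq_along(pa)) {
      for (v in seq_along(pa)) {
        if (u < v && !adj[pa[u], pa[v]]) {
          amat[k, pa[u]] <- 0L
          amat[k, pa[v]] <- 0L
        }
      }
    }
  }
  amat <- .meek_closure(amat)
  dimnames(amat) <- dimnames(dag)
  new_cpdag(amat)
}

# ---- local IDA ---------------------------------------------------------

# subsets of a set ordered by (size, lexicographic over sorted members)
.ordered_subsets <- function(members) {
  members <- sort(members)
  out <- list(integer())
  for (size in seq_len(length(members))) {
    out <- c(out, if (size == length(members)) list(members)
             else utils::combn(members, size, simplify = FALSE))
  }
  out
}

.ols_coef_x <- function(y_vec, X) {
  fit <- stats::lm.fit(cbind(1, X), y_vec)
  if (fit$rank < ncol(X) + 1L) return(NULL)   # rank-deficient: caller flags
  unname(fit$coefficients[2L])
}

#' Local IDA: possible causal effects of one gene on another
#'
#' For gene x with CPDAG parents pa(x) and undirected neighbors sib(x),
#' every subset S of sib(x) that is locally valid (orienting S into x
#' creates no new v-structure at x, i.e. each member of S is adjacent to
#' every other member of S and to every parent) yields one candidate
#' adjustment set pa(x) U S and one total-effect estimate: the coefficient
#' of x in the least-squares regression of y on x and the adjustment set.
#' If y itself lies in the adjustment set the effect is 0 (y is then a
#' cause of x in the corresponding DAGs). The summary is the
#' minimum-absolute effect carrying the sign of the attaining member; ties
#' are broken toward the smaller, then lexicographically earlier, sibling
#' subset.
#'
#' @param data expression matrix containing x, y and all their CPDAG
#'   neighbors.
#' @param g a `cpdag` over (a superset of) the genes of interest.
#' @param x,y distinct node names in `g`.
#' @return A `causal_effect` list with fields `x`, `y`, `effects`
#'   (multiset, one per valid sibling subset), `summary`,
#'   `n_parent_sets`.
#' @export
ida_local <- function(data, g, x, y) {
  validate_expression(data)
  stopifnot(inherits(g, "cpdag"))
  if (identical(x, y)) stop("x and y must differ")
  ix <- match(x, g$nodes); iy <- match(y, g$nodes)
  if (is.na(ix) || is.na(iy)) stop("x or y not a node of the cpdag")
  a <- g$amat
  pa <- .parents_of(a, ix)
  sib <- .siblings_of(a, ix)
  effects <- numeric()
  kept_sets <- list()
  any_rank_fail <- FALSE
  for (S in .ordered_subsets(sib)) {
    others <- c(S, pa)
    valid <- TRUE
    for (u in S) {
      for (v in others) {
        if (u != v && !.adjacent(a, u, v)) { valid <- FALSE; break }
      }
      if (!valid) break
    }
    if (!valid) next
    adjust <- g$nodes[c(pa, S)]
    if (y %in% adjust) {
      eff <- 0
    } else {
      X <- t(data[c(x, adjust), , drop = FALSE])
      eff <- .ols_coef_x(data[y, ], X)
      if (is.null(eff)) { any_rank_fail <- TRUE; next }
    }
    effects <- c(effects, eff)
    kept_sets <- c(kept_sets, list(adjust))
  }
  if (!length(effects)) {
    stop("no usable adjustment set for (", x, ", ", y, ")",
         if (any_rank_fail) " (all regressions rank-deficient)" else "")
  }
  best <- which.min(abs(effects))   # subsets pre-ordered by (size, lex)
  structure(list(x = x, y = y, effects = effects,
                 summary = effects[best],
                 n_parent_sets = length(effects),
                 parent_sets = kept_sets),
            class = "causal_effect")
}

#' @export
print.causal_effect <- function(x, ...) {
  cat("causal effect ", x$x, " -> ", x$y, ": summary ",
      signif(x$summary, 4L), " over ", x$n_parent_sets,
      " adjustment set(s)\n", sep = "")
  invisible(x)
}

#' Estimate causal effects for a list of candidate pairs
#'
#' Builds one CPDAG over the union of all genes appearing in the candidate
#' pairs (not the whole transcriptome) and runs [ida_local()] for each
#' pair. The CPDAG is read-only after construction, so pairs are
#' independent of each other; evaluation order cannot change the result.
#'
#' @param data expression matrix containing all pair genes.
#' @param pairs data frame with columns `lnc_id` and `mrna_id` (typically
#'   from [enumerate_candidates()]); extra columns are ignored.
#' @param cfg a [ci_cfg()].
#' @return Data frame aligned with `pairs`: `lnc_id`, `mrna_id`,
#'   `effect_summary`, `n_parent_sets`, and list-column `effects`; the
#'   estimated `cpdag` is attached as attribute `"cpdag"`.
#' @export
estimate_pair_effects <- function(data, pairs, cfg = ci_cfg()) {
  validate_expression(data)
  stopifnot(is.data.frame(pairs), all(c("lnc_id", "mrna_id") %in% names(pairs)))
  genes <- unique(c(pairs$lnc_id, pairs$mrna_id))
  if (!nrow(pairs)) {
    out <- data.frame(lnc_id = character(), mrna_id = character(),
                      effect_summary = numeric(), n_parent_sets = integer(),
                      stringsAsFactors = FALSE)
    out$effects <- list()
    return(out)
  }
  absent <- setdiff(genes, rownames(data))
  if (length(absent)) stop("pair gene(s) missing from expression: ",
                           paste(utils::head(absent, 10L), collapse = ", "))
  sub <- data[genes, , drop = FALSE]
  g <- pc_stable_cpdag(sub, cfg)
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    ida_local(sub, g, pairs$lnc_id[r], pairs$mrna_id[r])
  })
  out <- data.frame(
    lnc_id = pairs$lnc_id, mrna_id = pairs$mrna_id,
    effect_summary = vapply(res, function(e) e$summary, 0),
    n_parent_sets = vapply(res, function(e) e$n_parent_sets, 0L),
    stringsAsFactors = FALSE)
  out$effects <- lapply(res, function(e) e$effects)
  attr(out, "cpdag") <- g
  out
}

#' Write a causal-effect table
#'
#' Tab-separated columns lnc_id, mrna_id, effect_summary, n_parent_sets,
#' effects (semicolon-joined, 6 significant digits).
#'
#' @param effects data frame from [estimate_pair_effects()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  stopifnot(is.data.frame(effects))
  df <- data.frame(
    lnc_id = effects$lnc_id, mrna_id = effects$mrna_id,
    effect_summary = signif(effects$effect_summary, 6L),
    n_parent_sets = effects$n_parent_sets,
    effects = vapply(effects$effects, function(e)
      paste(signif(e, 6L), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a CPDAG to GraphML
#'
#' Writes the mixed graph with an edge attribute `directed` in
#' \{true, false\}.
#'
#' @param g a `cpdag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpdag_graphml <- function(g, path) {
  stopifnot(inherits(g, "cpdag"))
  de <- directed_edges(g)
  ue <- undirected_edges(g)
  edges <- rbind(de, ue)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = edges[, 1L], to = edges[, 2L],
                   directed = rep(c("true", "false"), c(nrow(de), nrow(ue))),
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
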