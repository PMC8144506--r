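#' Ground-truth sponge-system simulation
#'
#' The generator builds a linear-Gaussian structural equation model in
#' which latent miRNA regulators are exogenous and repress both lncRNAs
#' and mRNAs. A lncRNA-mRNA pair that shares miRNA regulators acquires a
#' positive expression correlation -- the ceRNA signature -- without any
#' direct coupling; optional direct lncRNA -> mRNA edges add genuinely
#' causal pairs. The emitted expression matrix contains only lncRNA and
#' mRNA rows: miRNAs stay latent, mirroring rRNA-depleted long-RNA
#' sequencing in which the confounders are unobserved. Interaction
#' evidence tables are derived from the true miRNA -> target edges and
#' corrupted with configurable false-positive/false-negative rates.
#'
#' All outputs are pure functions of the spec (including its seed); the
#' global RNG state is left untouched.
#'
#' @name synthetic-data
#' @keywords internal
NULL

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sharing matrices
#'
#' `sharing_none()` is the all-zero matrix; `sharing_diagonal()` places
#' `counts` (recycled) on the (lnc_i, mrna_i) diagonal, giving a sparse
#' background of sponge pairs with graded sharing.
#'
#' @param n_lnc,n_mrna matrix dimensions.
#' @param counts sharing counts recycled along the diagonal.
#' @return Integer matrix n_lnc x n_mrna.
#' @export
sharing_none <- function(n_lnc, n_mrna) {
  matrix(0L, n_lnc, n_mrna)
}

#' @rdname sharing_none
#' @export
sharing_diagonal <- function(n_lnc, n_mrna, counts = 0:5) {
  m <- sharing_none(n_lnc, n_mrna)
  d <- min(n_lnc, n_mrna)
  m[cbind(seq_len(d), seq_len(d))] <- rep_len(as.integer(counts), d)
  m
}

#' Specify a synthetic sponge system
#'
#' Defaults describe the package's reference system: 30 miRNAs, 12
#' lncRNAs, 20 mRNAs observed over 22 samples (the sample count of a
#' typical patient-tissue design), a diagonal background of sponge pairs
#' sharing 0-5 miRNAs, miRNA -> target coefficients around -0.8, unit
#' noise, and 5% false-positive/false-negative evidence corruption.
#'
#' @param n_mirna,n_lnc,n_mrna node counts (positive).
#' @param n_samples samples to simulate (>= 10).
#' @param sharing_matrix integer n_lnc x n_mrna matrix of planned shared
#'   regulator counts; default [sharing_diagonal()].
#' @param repression_strength mean miRNA -> target coefficient (< 0).
#' @param coef_sd standard deviation of the coefficients around the mean.
#' @param direct_effect coefficient of direct lncRNA -> mRNA edges.
#' @param direct_pairs two-column matrix of (lnc index, mrna index) pairs
#'   receiving a direct edge, or NULL.
#' @param private_per_gene private (unshared) miRNA regulators per
#'   transcript, drawn without replacement from the leftover pool.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param fp_rate,fn_rate evidence corruption rates in `[0, 1)`.
#' @param seed integer seed; every generator output is deterministic in it.
#' @return A `sponge_spec` list.
#' @export
sponge_system_spec <- function(n_mirna = 30L, n_lnc = 12L, n_mrna = 20L,
                               n_samples = 22L, sharing_matrix = NULL,
                               repression_strength = -0.8, coef_sd = 0.1,
                               direct_effect = 0, direct_pairs = NULL,
                               private_per_gene = 0L, noise_sd = 1,
                               fp_rate = 0.05, fn_rate = 0.05, seed = 1L) {
  stopifnot(n_mirna >= 1, n_lnc >= 1, n_mrna >= 1, n_samples >= 10,
            repression_strength < 0, coef_sd >= 0, noise_sd > 0,
            private_per_gene >= 0,
            fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate < 1)
  if (is.null(sharing_matrix)) sharing_matrix <- sharing_diagonal(n_lnc, n_mrna)
  sharing_matrix <- matrix(as.integer(sharing_matrix), n_lnc, n_mrna)
  if (any(sharing_matrix < 0)) stop("sharing counts must be non-negative")
  if (!is.null(direct_pairs)) {
    direct_pairs <- matrix(as.integer(direct_pairs), ncol = 2L)
    stopifnot(all(direct_pairs[, 1L] >= 1L), all(direct_pairs[, 1L] <= n_lnc),
              all(direct_pairs[, 2L] >= 1L), all(direct_pairs[, 2L] <= n_mrna))
  }
  structure(list(
    n_mirna = as.integer(n_mirna), n_lnc = as.integer(n_lnc),
    n_mrna = as.integer(n_mrna), n_samples = as.integer(n_samples),
    sharing_matrix = sharing_matrix,
    repression_strength = repression_strength, coef_sd = coef_sd,
    direct_effect = direct_effect, direct_pairs = direct_pairs,
    private_per_gene = as.integer(private_per_gene), noise_sd = noise_sd,
    fp_rate = fp_rate, fn_rate = fn_rate, seed = as.integer(seed)
  ), class = "sponge_spec")
}

#' Plant strong sponge pairs into a spec
#'
#' Replaces the sharing matrix with exactly `n_pairs` diagonal
#' (lnc_i, mrna_i) pairs sharing `n_shared` miRNAs each -- the planted
#' ground truth used for recovery studies. Background sharing is cleared
#' so the planted pairs and the miRNA pool budget are unambiguous.
#'
#' @param spec a `sponge_spec`.
#' @param n_pairs number of planted pairs.
#' @param n_shared shared regulators per planted pair.
#' @return The modified `sponge_spec`.
#' @export
plant_sponge_pairs <- function(spec, n_pairs = 3L, n_shared = 8L) {
  stopifnot(inherits(spec, "sponge_spec"),
            n_pairs >= 1, n_pairs <= min(spec$n_lnc, spec$n_mrna), n_shared >= 1)
  m <- sharing_none(spec$n_lnc, spec$n_mrna)
  m[cbind(seq_len(n_pairs), seq_len(n_pairs))] <- as.integer(n_shared)
  spec$sharing_matrix <- m
  spec
}

.mirna_ids <- function(n) sprintf("miR%03d", seq_len(n))
.lnc_ids <- function(n) sprintf("lnc%02d", seq_len(n))
.mrna_ids <- function(n) sprintf("mRNA%02d", seq_len(n))

#' Generate the ground-truth sponge DAG
#'
#' Builds the weighted acyclic graph of the system: exogenous miRNAs,
#' shared miRNA parents per sponge pair (drawn without replacement across
#' pairs, so sponging pools are disjoint and the true sponge pairs are
#' exactly the support of the sharing matrix), private miRNA parents per
#' transcript (also without replacement), and optional direct
#' lncRNA -> mRNA edges.
#'
#' @param spec a `sponge_spec`.
#' @return A `sponge_truth` list: node id vectors, `edges` (from, to,
#'   coef), `true_sponge_pairs`, `true_direct_pairs`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "sponge_spec"))
  total_shared <- sum(spec$sharing_matrix)
  if (total_shared > spec$n_mirna) {
    stop("sharing demand (", total_shared, ") exceeds n_mirna (", spec$n_mirna, ")")
  }
  n_private <- spec$private_per_gene * (spec$n_lnc + spec$n_mrna)
  if (total_shared + n_private > spec$n_mirna) {
    stop("private-regulator demand exceeds the leftover miRNA pool (need ",
         total_shared + n_private, ", have ", spec$n_mirna, ")")
  }
  mirna <- .mirna_ids(spec$n_mirna)
  lnc <- .lnc_ids(spec$n_lnc)
  mrna <- .mrna_ids(spec$n_mrna)
  .with_seed(spec$seed, {
    pool <- sample(mirna)          # shuffled assignment order
    ptr <- 0L
    take <- function(k) {
      out <- pool[ptr + seq_len(k)]
      ptr <<- ptr + k
      out
    }
    from <- character(); to <- character()
    sponge <- list()
    for (i in seq_len(spec$n_lnc)) {
      for (j in seq_len(spec$n_mrna)) {
        s <- spec$sharing_matrix[i, j]
        if (s > 0L) {
          shared <- take(s)
          from <- c(from, shared, shared)
          to <- c(to, rep(lnc[i], s), rep(mrna[j], s))
          sponge[[length(sponge) + 1L]] <-
            data.frame(lnc_id = lnc[i], mrna_id = mrna[j], n_shared = s,
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (spec$private_per_gene > 0L) {
      for (g in c(lnc, mrna)) {
        priv <- take(spec$private_per_gene)
        from <- c(from, priv)
        to <- c(to, rep(g, spec$private_per_gene))
      }
    }
    coef <- stats::rnorm(length(from), spec$repression_strength, spec$coef_sd)
    edges <- data.frame(from = from, to = to, coef = coef,
                        stringsAsFactors = FALSE)
    direct <- data.frame(lnc_id = character(), mrna_id = character(),
                         coef = numeric(), stringsAsFactors = FALSE)
    if (!is.null(spec$direct_pairs) && nrow(spec$direct_pairs) && spec$direct_effect != 0) {
      direct <- data.frame(lnc_id = lnc[spec$direct_pairs[, 1L]],
                           mrna_id = mrna[spec$direct_pairs[, 2L]],
                           coef = spec$direct_effect, stringsAsFactors = FALSE)
      edges <- rbind(edges, data.frame(from = direct$lnc_id, to = direct$mrna_id,
                                       coef = direct$coef, stringsAsFactors = FALSE))
    }
    truth <- structure(list(
      mirna_ids = mirna, lnc_ids = lnc, mrna_ids = mrna,
      edges = edges,
      true_sponge_pairs = if (length(sponge)) do.call(rbind, sponge) else
        data.frame(lnc_id = character(), mrna_id = character(),
                   n_shared = integer(), stringsAsFactors = FALSE),
      true_direct_pairs = direct
    ), class = "sponge_truth")
    truth
  })
}

#' @export
print.sponge_truth <- function(x, ...) {
  cat("sponge_truth:", length(x$mirna_ids), "miRNAs,", length(x$lnc_ids),
      "lncRNAs,", length(x$mrna_ids), "mRNAs;", nrow(x$edges), "edges;",
      nrow(x$true_sponge_pairs), "true sponge pair(s),",
      nrow(x$true_direct_pairs), "direct pair(s)\n")
  invisible(x)
}

#' Simulate expression from a sponge truth
#'
#' Topological-order sampling of the linear-Gaussian SEM: each node equals
#' the coefficient-weighted sum of its parents plus Gaussian noise. The
#' returned matrix holds only the lncRNA and mRNA rows (miRNAs are
#' latent), on the Gaussian scale; downstream stages should use transform
#' mode `"none"`.
#'
#' @param truth a `sponge_truth`.
#' @param spec the `sponge_spec` it was generated from.
#' @return Expression matrix (n_lnc + n_mrna) x n_samples.
#' @export
simulate_expression <- function(truth, spec) {
  stopifnot(inherits(truth, "sponge_truth"), inherits(spec, "sponge_spec"))
  n <- spec$n_samples
  nodes <- c(truth$mirna_ids, truth$lnc_ids, truth$mrna_ids)  # topological
  .with_seed(spec$seed + 1L, {
    vals <- matrix(0, length(nodes), n, dimnames = list(nodes, sprintf("S%02d", seq_len(n))))
    for (v in nodes) {
      x <- stats::rnorm(n, 0, spec$noise_sd)
      pe <- truth$edges[truth$edges$to == v, , drop = FALSE]
      if (nrow(pe)) {
        x <- x + colSums(vals[pe$from, , drop = FALSE] * pe$coef)
      }
      vals[v, ] <- x
    }
    vals[c(truth$lnc_ids, truth$mrna_ids), , drop = FALSE]
  })
}

#' Emit corrupted interaction-evidence tables
#'
#' One record per true miRNA -> target edge, each deleted independently
#' with probability `fn_rate`, plus `round(fp_rate * n_true)` spurious
#' records per target class drawn uniformly (without replacement) from the
#' non-edges of that class.
#'
#' @param truth a `sponge_truth`.
#' @param spec its `sponge_spec`.
#' @return List with elements `lncrna` and `mrna`: record data frames in
#'   the interaction dialect (source column `"synthetic"` for true
#'   records, `"synthetic_fp"` for spurious ones).
#' @export
emit_evidence <- function(truth, spec) {
  stopifnot(inherits(truth, "sponge_truth"), inherits(spec, "sponge_spec"))
  mirna_edges <- truth$edges[truth$edges$from %in% truth$mirna_ids, , drop = FALSE]
  .with_seed(spec$seed + 2L, {
    one_class <- function(targets, class) {
      tru <- mirna_edges[mirna_edges$to %in% targets, , drop = FALSE]
      keep <- stats::runif(nrow(tru)) >= spec$fn_rate
      rec <- data.frame(mirna_id = tru$from[keep], target_id = tru$to[keep],
                        target_class = class, source = "synthetic",
                        stringsAsFactors = FALSE)
      n_fp <- round(spec$fp_rate * nrow(tru))
      if (n_fp > 0L) {
        all_pairs <- expand.grid(mirna_id = truth$mirna_ids, target_id = targets,
                                 KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        is_edge <- paste(all_pairs$mirna_id, all_pairs$target_id) %in%
          paste(tru$from, tru$to)
        non_edges <- all_pairs[!is_edge, , drop = FALSE]
        pick <- non_edges[sample(nrow(non_edges), min(n_fp, nrow(non_edges))), , drop = FALSE]
        rec <- rbind(rec, data.frame(mirna_id = pick$mirna_id,
                                     target_id = pick$target_id,
                                     target_class = class,
                                     source = "synthetic_fp",
                                     stringsAsFactors = FALSE))
      }
      rec
    }
    list(lncrna = one_class(truth$lnc_ids, "lncRNA"),
         mrna = one_class(truth$mrna_ids, "mRNA"))
  })
}

#' Write a complete synthetic input bundle
#'
#' Writes expression, annotation, the two evidence tables, the truth edge
#' list (with coefficients), the true sponge-pair table, and a ready-made
#' pipeline configuration (Gaussian scale: `min_total = 0`,
#' `transform = none`). Byte-identical across calls with the same spec.
#'
#' @param spec a `sponge_spec`.
#' @param dir output directory (created if needed).
#' @return Named list of file paths (invisible), including `config`.
#' @export
end_to_end_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "sponge_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(spec)
  expr <- simulate_expression(truth, spec)
  ev <- emit_evidence(truth, spec)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    evidence_lncrna = file.path(dir, "evidence_lncrna.tsv"),
    evidence_mrna = file.path(dir, "evidence_mrna.tsv"),
    truth_edges = file.path(dir, "truth_edges.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    config = file.path(dir, "config.txt"))
  write_expression(expr, paths$expression)
  anno <- stats::setNames(rep(c("lncRNA", "mRNA"),
                              c(length(truth$lnc_ids), length(truth$mrna_ids))),
                          c(truth$lnc_ids, truth$mrna_ids))
  write_annotation(anno, paths$annotation)
  write_interactions(interaction_set(ev$lncrna), paths$evidence_lncrna)
  write_interactions(interaction_set(ev$mrna), paths$evidence_mrna)
  utils::write.table(truth$edges, paths$truth_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$true_sponge_pairs, paths$truth_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(
    paste0("expression = ", paths$expression),
    paste0("annotation = ", paths$annotation),
    paste0("evidence_lncrna = ", paths$evidence_lncrna),
    paste0("evidence_mrna = ", paths$evidence_mrna),
    paste0("out_dir = ", file.path(dir, "out")),
    "min_total = 0",
    "transform = none",
    paste0("seed = ", spec$seed)), paths$config)
  invisible(paths)
}

#' Score a called network against the generating truth
#'
#' @param net a `sponge_network` (or its edge data frame).
#' @param truth a `sponge_truth`, or a data frame with columns `lnc_id`,
#'   `mrna_id` of true pairs.
#' @return List: `n_edges`, `tp`, `fp`, `fn`, `recall`, `precision`.
#' @export
score_network <- function(net, truth) {
  edges <- if (inherits(net, "sponge_network")) net$edges else net
  true_pairs <- if (inherits(truth, "sponge_truth")) truth$true_sponge_pairs else truth
  key_e <- paste(edges$lnc_id, edges$mrna_id)
  key_t <- paste(true_pairs$lnc_id, true_pairs$mrna_id)
  tp <- sum(key_e %in% key_t)
  list(n_edges = nrow(edges), tp = tp, fp = nrow(edges) - tp,
       fn = length(key_t) - tp,
       recall = if (length(key_t)) tp / length(key_t) else NA_real_,
       precision = if (nrow(edges)) tp / nrow(edges) else NA_real_)
}
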