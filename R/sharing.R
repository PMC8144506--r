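#' Shared-miRNA enrichment of candidate sponge pairs
#'
#' A lncRNA and an mRNA are candidate ceRNA partners when they share
#' significantly more miRNA interaction evidence than expected by chance.
#' With N miRNAs in the evidence universe, K of them targeting the mRNA and
#' n targeting the lncRNA, the number shared under random draws is
#' Hypergeometric(N, K, n); enrichment is the upper-tail probability
#' P(X >= k), corrected across all pairs by Benjamini-Hochberg.
#'
#' @name sharing
#' @keywords internal
NULL

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n) (N universe size, K successes,
#' n draws), evaluated through the survival function so extreme tails are
#' computed in a numerically stable way. Optionally returns log p for
#' overlaps whose p-value underflows double precision; the package never
#' reports an exact zero for k < n.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param n number of draws (miRNAs targeting the lncRNA).
#' @param K number of successes in the universe (miRNAs targeting the mRNA).
#' @param N universe size (>= 1).
#' @param log.p return log(p) instead of p.
#' @return Probability in `[0, 1]` (or its log).
#' @export
hypergeom_upper_tail <- function(k, n, K, N, log.p = FALSE) {
  stopifnot(length(k) == length(n) || length(n) == 1L,
            length(k) == length(K) || length(K) == 1L,
            length(k) == length(N) || length(N) == 1L)
  if (any(N < 1)) stop("precondition violated: N >= 1")
  if (any(k < 0)) stop("precondition violated: k >= 0")
  if (any(n < 0) || any(K < 0)) stop("precondition violated: n >= 0 and K >= 0")
  if (any(n > N) || any(K > N)) stop("precondition violated: max(n, K) <= N")
  if (any(k > pmin(n, K))) stop("precondition violated: k <= min(n, K)")
  # P(X >= k) = P(X > k - 1); phyper's 'm' = successes, 'n' = failures
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE, log.p = log.p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j,
#' clipped at 1, returned in the original input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Enumerate candidate lncRNA-mRNA sponge pairs
#'
#' Forms every (lncRNA, mRNA) combination whose shared-miRNA count reaches
#' `min_shared`, scores it with [hypergeom_upper_tail()] against the pooled
#' miRNA universe of the evidence set, and BH-adjusts the p-values across
#' the enumerated family.
#'
#' @param s merged `interaction_set` (both target classes).
#' @param lnc_ids lncRNA ids; must be lncRNA-class targets in `s`.
#' @param mrna_ids mRNA ids; must be mRNA-class targets in `s`.
#' @param min_shared minimum shared-miRNA count (>= 1).
#' @return Data frame of candidate pairs with columns `lnc_id`, `mrna_id`,
#'   `k_shared`, `n_lnc`, `K_mrna`, `N_universe`, `p_hyper`, `q_hyper`.
#'   May have zero rows.
#' @export
enumerate_candidates <- function(s, lnc_ids, mrna_ids, min_shared = 1L) {
  stopifnot(inherits(s, "interaction_set"))
  if (min_shared < 1L) stop("min_shared must be >= 1")
  lnc_ids <- unique(as.character(lnc_ids))
  mrna_ids <- unique(as.character(mrna_ids))
  rec <- s$records
  lnc_targets <- unique(rec$target_id[rec$target_class == "lncRNA"])
  mrna_targets <- unique(rec$target_id[rec$target_class == "mRNA"])
  unknown_l <- setdiff(lnc_ids, lnc_targets)
  unknown_m <- setdiff(mrna_ids, mrna_targets)
  if (length(unknown_l)) stop("unknown lncRNA id(s): ", paste(utils::head(unknown_l, 5L), collapse = ", "))
  if (length(unknown_m)) stop("unknown mRNA id(s): ", paste(utils::head(unknown_m, 5L), collapse = ", "))
  N <- length(unique(rec$mirna_id))
  sets <- split(rec$mirna_id, rec$target_id)
  sets <- lapply(sets, unique)
  out <- vector("list", length(lnc_ids) * length(mrna_ids))
  idx <- 0L
  for (l in lnc_ids) {
    ml <- sets[[l]]
    for (m in mrna_ids) {
      mm <- sets[[m]]
      k <- length(intersect(ml, mm))
      if (k >= min_shared) {
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          lnc_id = l, mrna_id = m, k_shared = k,
          n_lnc = length(ml), K_mrna = length(mm), N_universe = N,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!idx) {
    return(data.frame(lnc_id = character(), mrna_id = character(),
                      k_shared = integer(), n_lnc = integer(),
                      K_mrna = integer(), N_universe = integer(),
                      p_hyper = numeric(), q_hyper = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, out[seq_len(idx)])
  pairs$p_hyper <- hypergeom_upper_tail(pairs$k_shared, pairs$n_lnc,
                                        pairs$K_mrna, pairs$N_universe)
  pairs$q_hyper <- bh_adjust(pairs$p_hyper)
  rownames(pairs) <- NULL
  pairs
}

#' Filter candidate pairs on adjusted sharing significance
#'
#' Retains pairs with `q_hyper < q_max` (strict), preserving input order.
#'
#' @param pairs candidate-pair data frame from [enumerate_candidates()].
#' @param q_max significance cutoff in (0, 1].
#' @return Filtered data frame.
#' @export
filter_candidates <- function(pairs, q_max = 0.05) {
  stopifnot(is.data.frame(pairs), "q_hyper" %in% names(pairs))
  if (!is.numeric(q_max) || length(q_max) != 1L || q_max <= 0 || q_max > 1) {
    stop("q_max must lie in (0, 1]")
  }
  pairs[pairs$q_hyper < q_max, , drop = FALSE]
}

#' Write a candidate-pair table
#'
#' Tab-separated, deterministically sorted by (q_hyper, lnc_id, mrna_id).
#'
#' @param pairs candidate-pair data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(pairs, path) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$q_hyper, pairs$lnc_id, pairs$mrna_id,
                         method = "radix"), , drop = FALSE]
  }
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
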