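# Independent brute-force oracles and small simulation helpers shared by
# the unit, property and acceptance tests. Everything here deliberately
# avoids the package's own computational paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-tail hypergeometric by direct summation of exact binomial terms
oracle_hyper_upper <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, 0)) / choose(N, n)
}

# naive Benjamini-Hochberg step-up, double loop
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# all DAG adjacency matrices on p labeled nodes (0/1, a[i,j]=1 means i->j)
enumerate_dags <- function(p) {
  pairs <- t(utils::combn(p, 2))
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    a <- matrix(0L, p, p)
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) a[pairs[k, 1L], pairs[k, 2L]] <- 1L
      if (s == 2) a[pairs[k, 2L], pairs[k, 1L]] <- 1L
    }
    if (is_acyclic(a)) out[[length(out) + 1L]] <- a
  }
  out
}

is_acyclic <- function(a) {
  left <- seq_len(nrow(a))
  while (length(left)) {
    sinks <- which(rowSums(a[left, left, drop = FALSE]) == 0)
    if (!length(sinks)) return(FALSE)
    left <- left[-sinks[1L]]
  }
  TRUE
}

# Markov-equivalence-class key: skeleton + v-structures
dag_class_key <- function(a) {
  p <- nrow(a)
  adj <- (a + t(a)) > 0
  vs <- character()
  for (k in seq_len(p)) {
    pa <- which(a[, k] == 1L)
    if (length(pa) >= 2L) {
      for (u in seq_along(pa)) for (v in seq_along(pa)) {
        if (u < v && !adj[pa[u], pa[v]]) {
          vs <- c(vs, paste(pa[u], pa[v], k, sep = ":"))
        }
      }
    }
  }
  paste(paste(which(adj & upper.tri(adj)), collapse = ","),
        paste(sort(vs), collapse = ";"), sep = "|")
}

# CPDAG of an equivalence class given as a list of member DAGs: an edge is
# directed iff every member orients it the same way. Independent of the
# package's Meek machinery.
class_to_cpdag <- function(members, nodes) {
  p <- length(nodes)
  const <- matrix(TRUE, p, p)
  for (a in members) const <- const & (a == members[[1L]])
  a1 <- members[[1L]]
  adj <- (a1 + t(a1)) > 0
  de <- NULL; ue <- NULL
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j && adj[i, j]) {
      if (const[i, j] && const[j, i]) {
        if (a1[i, j] == 1L) de <- rbind(de, c(nodes[i], nodes[j]))
        else de <- rbind(de, c(nodes[j], nodes[i]))
      } else {
        ue <- rbind(ue, c(nodes[i], nodes[j]))
      }
    }
  }
  cpdag(nodes, directed = de, undirected = ue)
}

# canonical string form of a cpdag, for equality checks
cpdag_key <- function(g) {
  de <- directed_edges(g); ue <- undirected_edges(g)
  paste(paste(sort(paste(de[, 1L], de[, 2L], sep = ">")), collapse = ","),
        paste(sort(paste(ue[, 1L], ue[, 2L], sep = "-")), collapse = ","),
        sep = "|")
}

# simulate a linear-Gaussian SEM given a weighted adjacency matrix B
# (B[i, j] = coefficient of i in the equation of j), unit noise
sim_sem <- function(B, n, seed, noise_sd = 1) {
  set.seed(seed)
  p <- nrow(B)
  nodes <- rownames(B)
  stopifnot(is_acyclic((B != 0) + 0L))
  x <- matrix(0, p, n, dimnames = list(nodes, paste0("s", seq_len(n))))
  left <- seq_len(p)
  order_ <- integer()
  while (length(left)) {  # topological order by source elimination
    src <- which(colSums(B[left, left, drop = FALSE] != 0) == 0)
    order_ <- c(order_, left[src[1L]])
    left <- left[-src[1L]]
  }
  for (v in order_) {
    x[v, ] <- rnorm(n, 0, noise_sd)
    pa <- which(B[, v] != 0)
    if (length(pa)) x[v, ] <- x[v, ] + colSums(x[pa, , drop = FALSE] * B[pa, v])
  }
  x
}

# small interaction-record data frame builder
make_records <- function(mirna, target, class, source = "db") {
  data.frame(mirna_id = mirna, target_id = target, target_class = class,
             source = source, stringsAsFactors = FALSE)
}
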