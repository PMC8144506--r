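make_pair_data <- function(n = 40, seed = 61) {
  # three correlated (sponge-like) pairs and three independent pairs
  set.seed(seed)
  d <- matrix(rnorm(12 * n), 12, n,
              dimnames = list(c(sprintf("L%d", 1:6), sprintf("M%d", 1:6)),
                              sprintf("s%02d", seq_len(n))))
  for (i in 1:3) d[sprintf("M%d", i), ] <- d[sprintf("L%d", i), ] + 0.4 * rnorm(n)
  pairs <- data.frame(lnc_id = sprintf("L%d", 1:6), mrna_id = sprintf("M%d", 1:6),
                      k_shared = 3L, stringsAsFactors = FALSE)
  effects <- data.frame(lnc_id = pairs$lnc_id, mrna_id = pairs$mrna_id,
                        effect_summary = 1, n_parent_sets = 1L,
                        stringsAsFactors = FALSE)
  effects$effects <- as.list(rep(1, 6))
  list(data = d, pairs = pairs, effects = effects)
}

test_that("Fisher correlation p-values follow the z transform exactly", {
  expect_equal(cor_pvalue_fisher(0, 22), 1)
  expect_equal(cor_pvalue_fisher(1, 22), 0)
  expect_equal(cor_pvalue_fisher(0.87, 22), 6.2190092267905e-09, tolerance = 1e-8)
  expect_equal(cor_pvalue_fisher(-0.87, 22), cor_pvalue_fisher(0.87, 22))
  # strictly decreasing in |r| at fixed n, and in n at fixed r
  p_r <- cor_pvalue_fisher(seq(0.05, 0.95, by = 0.05), 22)
  expect_true(all(diff(p_r) < 0))
  p_n <- vapply(5:40, function(n) cor_pvalue_fisher(0.5, n), 0)
  expect_true(all(diff(p_n) < 0))
  expect_error(cor_pvalue_fisher(1.2, 22), "<= 1")
  expect_error(cor_pvalue_fisher(0.5, 3), ">= 4")
})

test_that("edge calling gates on q, sign and effect floor, and conserves degree", {
  env <- make_pair_data()
  net <- call_edges(env$data, env$pairs, env$effects, q_max = 0.05)
  expect_true(all(net$edges$lnc_id %in% sprintf("L%d", 1:3)))
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$r > 0))
  expect_equal(sum(net$lnc_degree), nrow(net$edges))
  expect_equal(sum(net$mrna_degree), nrow(net$edges))
  # r is the plain Pearson correlation on the supplied matrix
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$r[i],
                 cor(env$data[net$edges$lnc_id[i], ],
                     env$data[net$edges$mrna_id[i], ]), tolerance = 1e-12)
  }
  expect_equal(net$edges$q_cor[order(net$edges$lnc_id)],
               oracle_bh(cor_pvalue_fisher(
                 vapply(1:6, function(i) cor(env$data[sprintf("L%d", i), ],
                                             env$data[sprintf("M%d", i), ]), 0),
                 ncol(env$data)))[1:3], tolerance = 1e-12)
})

test_that("the no-filter limit returns every candidate as an edge", {
  env <- make_pair_data()
  net <- call_edges(env$data, env$pairs, env$effects, q_max = 1,
                    effect_min = -Inf, require_positive_r = FALSE)
  expect_equal(nrow(net$edges), nrow(env$pairs))
})

test_that("mismatched pair and effect keys are reported as orphans", {
  env <- make_pair_data()
  expect_error(call_edges(env$data, env$pairs, env$effects[-1L, ], q_max = 0.5),
               "orphan")
})

test_that("edge filters are monotone in their thresholds", {
  env <- make_pair_data(seed = 62)
  env$effects$effect_summary <- seq(-1, 1.5, length.out = 6)
  n_edges <- function(q, emin) nrow(call_edges(env$data, env$pairs, env$effects,
                                               q_max = q, effect_min = emin,
                                               require_positive_r = FALSE)$edges)
  qs <- c(0.01, 0.05, 0.2, 1)
  expect_true(all(diff(vapply(qs, n_edges, 0, emin = -Inf)) >= 0))
  emins <- c(-Inf, -0.5, 0, 0.5, 1.4)
  expect_true(all(diff(vapply(emins, function(e) n_edges(1, e), 0)) <= 0))
})

test_that("hub selection takes the top degree fraction with stable ties", {
  # 24 lncRNAs at fraction 0.2 -> exactly 4 hubs
  edges <- data.frame(
    lnc_id = rep(sprintf("lnc%02d", 1:24), times = c(rep(3, 4), rep(1, 20))),
    mrna_id = sprintf("m%02d", seq_len(4 * 3 + 20)),
    r = 0.8, p_cor = 1e-4, q_cor = 1e-3, effect_summary = 1, k_shared = 2L,
    stringsAsFactors = FALSE)
  net <- spongenet:::new_sponge_network(edges)
  hubs <- select_hubs(net, 0.2)
  expect_length(hubs$hubs, 4L)
  expect_setequal(hubs$hubs, sprintf("lnc%02d", 1:4))
  expect_true(min(hubs$degree) >= max(net$lnc_degree[setdiff(names(net$lnc_degree), hubs$hubs)]))
  # fraction 1 returns everything, degree-sorted
  all_h <- select_hubs(net, 1)
  expect_length(all_h$hubs, 24L)
  expect_true(all(diff(all_h$degree) <= 0))
  # random degrees vs brute-force sort-and-slice
  set.seed(63)
  deg <- sample(1:5, 30, TRUE)
  edges2 <- data.frame(
    lnc_id = rep(sprintf("x%02d", 1:30), times = deg),
    mrna_id = sprintf("m%03d", seq_len(sum(deg))),
    r = 0.5, p_cor = 0.01, q_cor = 0.01, effect_summary = 1, k_shared = 1L,
    stringsAsFactors = FALSE)
  net2 <- spongenet:::new_sponge_network(edges2)
  hubs2 <- select_hubs(net2, 0.3)
  ids <- sprintf("x%02d", 1:30)
  expected <- ids[order(-deg, ids)][seq_len(max(1, floor(0.3 * 30)))]
  expect_equal(hubs2$hubs, expected)
  # permutation invariance w.r.t. edge order
  perm <- sample(nrow(edges2))
  hubs2b <- select_hubs(spongenet:::new_sponge_network(edges2[perm, ]), 0.3)
  expect_equal(hubs2b$hubs, hubs2$hubs)
  expect_error(select_hubs(spongenet:::new_sponge_network(edges2[0, ]), 0.2), "empty")
  expect_error(select_hubs(net2, 0), "\\(0, 1\\]")
})

test_that("the degree table matches brute-force incidence counting", {
  edges <- data.frame(lnc_id = c("L1", "L1", "L1"), mrna_id = c("M1", "M2", "M3"),
                      r = 0.9, p_cor = 1e-5, q_cor = 1e-4, effect_summary = 1,
                      k_shared = 2L, stringsAsFactors = FALSE)
  tab <- degree_table(spongenet:::new_sponge_network(edges))
  expect_equal(tab$degree[tab$node_id == "L1"], 3L)
  expect_equal(sort(tab$degree[tab$class == "mRNA"]), c(1L, 1L, 1L))
  set.seed(64)
  e2 <- unique(data.frame(lnc_id = sample(sprintf("L%d", 1:8), 40, TRUE),
                          mrna_id = sample(sprintf("M%d", 1:8), 40, TRUE),
                          stringsAsFactors = FALSE))
  e2[c("r", "p_cor", "q_cor", "effect_summary", "k_shared")] <-
    list(0.5, 0.01, 0.02, 1, 1L)
  tab2 <- degree_table(spongenet:::new_sponge_network(e2))
  for (i in seq_len(nrow(tab2))) {
    side <- if (tab2$class[i] == "lncRNA") e2$lnc_id else e2$mrna_id
    expect_equal(tab2$degree[i], sum(side == tab2$node_id[i]))
  }
})

test_that("network writers emit sorted tables and valid GraphML", {
  env <- make_pair_data()
  net <- call_edges(env$data, env$pairs, env$effects, q_max = 1,
                    require_positive_r = FALSE)
  path <- withr::local_tempfile()
  write_edges(net, path)
  tab <- read.delim(path)
  expect_equal(tab$q_cor, sort(tab$q_cor))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_match(paste(readLines(gml), collapse = ""), "lncRNA")
  hubs <- select_hubs(net, 0.5)
  hpath <- withr::local_tempfile()
  write_hubs(hubs, hpath)
  expect_equal(read.delim(hpath)$lnc_id, hubs$hubs)
})
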