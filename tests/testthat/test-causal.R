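test_that("partial correlation matches Pearson at S = {} and a residual oracle", {
  set.seed(41)
  n <- 5000
  i <- rnorm(n); s <- 0.9 * i + rnorm(n); j <- 0.9 * s + rnorm(n)
  d <- rbind(i = i, s = s, j = j)
  colnames(d) <- paste0("c", seq_len(n))
  expect_equal(partial_correlation(d, "i", "j"), cor(i, j), tolerance = 1e-12)
  # chain: conditioning on the mediator kills the correlation
  p_cond <- partial_correlation(d, "i", "j", "s")
  expect_lt(abs(p_cond), 3 / sqrt(n))
  # oracle: correlation of regression residuals
  expect_equal(p_cond,
               cor(resid(lm(i ~ s)), resid(lm(j ~ s))), tolerance = 1e-10)
  # duplicated conditioning gene makes the system singular
  d2 <- rbind(d, s2 = s)
  expect_error(partial_correlation(d2, "i", "j", c("s", "s2")), "collinear")
})

test_that("the Fisher z test matches its closed form and flips with alpha", {
  set.seed(42)
  d <- rbind(a = rnorm(22), b = rnorm(22))
  colnames(d) <- paste0("s", 1:22)
  # engineer an exact r = 0 pair via orthogonalization
  b_orth <- resid(lm(d["b", ] ~ d["a", ]))
  d0 <- rbind(a = d["a", ], b = b_orth)
  colnames(d0) <- colnames(d)
  res0 <- ci_test(d0, "a", "b")
  expect_equal(res0$statistic, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-10)
  expect_true(res0$independent)
  # r = 0.87 at n = 22 (the scale of a strong sponge-pair correlation)
  r <- 0.87; n <- 22
  z <- sqrt(n - 3) * 0.5 * log((1 + r) / (1 - r))
  expect_equal(z, 5.81075938953977, tolerance = 1e-10)
  expect_equal(2 * pnorm(-abs(z)), 6.2190092267905e-09, tolerance = 1e-6)
  # the decision flips monotonically in alpha around the observed p
  dd <- rbind(x = rnorm(50))
  dd <- rbind(dd, y = 0.3 * dd["x", ] + rnorm(50))
  colnames(dd) <- paste0("s", 1:50)
  p_obs <- ci_test(dd, "x", "y", cfg = ci_cfg(0.5))$p
  alphas <- sort(c(p_obs * 0.5, p_obs * 2, 0.9999) / 2)
  dec <- vapply(alphas, function(a)
    ci_test(dd, "x", "y", cfg = ci_cfg(a))$independent, TRUE)
  expect_true(all(diff(as.integer(dec)) <= 0))
})

test_that("PC-stable recovers the independence pattern of small systems", {
  n <- 5000
  # three mutually independent genes: no edges at alpha = 0.01
  set.seed(43)
  d <- rbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  colnames(d) <- paste0("s", 1:n)
  g <- pc_stable_cpdag(d, ci_cfg(0.01, 3))
  expect_equal(nrow(directed_edges(g)) + nrow(undirected_edges(g)), 0L)
  # collider x -> z <- y
  set.seed(44)
  x <- rnorm(n); y <- rnorm(n); z <- x + y + rnorm(n)
  dc <- rbind(x = x, y = y, z = z); colnames(dc) <- paste0("s", 1:n)
  gc_ <- pc_stable_cpdag(dc, ci_cfg(0.01, 3))
  expect_equal(cpdag_key(gc_), "x>z,y>z|")
  # chain x -> y -> z stays undirected (its Markov equivalence class)
  set.seed(45)
  x2 <- rnorm(n); y2 <- x2 + rnorm(n); z2 <- y2 + rnorm(n)
  dch <- rbind(x = x2, y = y2, z = z2); colnames(dch) <- paste0("s", 1:n)
  gch <- pc_stable_cpdag(dch, ci_cfg(0.01, 3))
  expect_equal(cpdag_key(gch), "|x-y,y-z")
})

test_that("PC-stable output is invariant to the gene input order", {
  set.seed(46)
  B <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  B["a", "c"] <- 0.9; B["b", "c"] <- 0.8
  B["c", "d"] <- 0.8; B["d", "e"] <- 0.9
  d <- sim_sem(B, 3000, seed = 46)
  g1 <- pc_stable_cpdag(d, ci_cfg(0.01, 3))
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    g2 <- pc_stable_cpdag(d[sample(5), , drop = FALSE], ci_cfg(0.01, 3))
    expect_equal(cpdag_key(g2), cpdag_key(g1))
  }
})

test_that("dag_to_cpdag reproduces known equivalence classes", {
  # collider stays fully oriented
  a <- matrix(0L, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  a["x", "z"] <- 1L; a["y", "z"] <- 1L
  expect_equal(cpdag_key(dag_to_cpdag(a)), "x>z,y>z|")
  # chain loses all orientations
  b <- matrix(0L, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  b["x", "y"] <- 1L; b["y", "z"] <- 1L
  expect_equal(cpdag_key(dag_to_cpdag(b)), "|x-y,y-z")
  # cyclic input is rejected
  cy <- matrix(0L, 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  cy["u", "v"] <- 1L; cy["v", "u"] <- 1L
  expect_error(dag_to_cpdag(cy), "2-cycle")
})

test_that("local IDA recovers a known effect and the no-effect case", {
  n <- 5000
  set.seed(47)
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.7 * z1 + 0.7 * z2 + rnorm(n)
  y <- 2 * x + rnorm(n)
  d <- rbind(z1 = z1, z2 = z2, x = x, y = y); colnames(d) <- paste0("s", 1:n)
  g <- pc_stable_cpdag(d, ci_cfg(0.01, 3))
  e <- ida_local(d, g, "x", "y")
  expect_equal(e$n_parent_sets, 1L)
  expect_equal(e$summary, 2, tolerance = 5 / sqrt(n))
  # y d-separated from z1 given x: effect of z1 on... use a null pair
  e0 <- ida_local(d, g, "z1", "z2")
  expect_lt(abs(e0$summary), 5 / sqrt(n))
  expect_error(ida_local(d, g, "x", "x"), "differ")
})

test_that("local IDA enumerates valid sibling subsets on a hand-built CPDAG", {
  # x - z (undirected), x - y (undirected), z and y nonadjacent:
  # S = {z, y} would create a new collider at x, so the valid subsets are
  # {}, {z}, {y}; y in the adjustment set forces a zero effect.
  set.seed(48)
  n <- 400
  common <- rnorm(n)
  d <- rbind(x = common + rnorm(n), y = common + rnorm(n), z = common + rnorm(n))
  colnames(d) <- paste0("s", 1:n)
  g <- cpdag(c("x", "y", "z"), undirected = rbind(c("x", "z"), c("x", "y")))
  e <- ida_local(d, g, "x", "y")
  expect_equal(e$n_parent_sets, 3L)
  expect_equal(sum(e$effects == 0), 1L)  # exactly the S containing y
  # oracle: coefficients from the two estimable adjustment sets
  beta_empty <- unname(coef(lm(d["y", ] ~ d["x", ]))[2L])
  beta_z <- unname(coef(lm(d["y", ] ~ d["x", ] + d["z", ]))[2L])
  expect_setequal(round(setdiff(e$effects, 0), 10),
                  round(c(beta_empty, beta_z), 10))
})

test_that("pair-effect estimation is pure and aligned with its input", {
  set.seed(49)
  n <- 300
  x <- rnorm(n); y <- 1.5 * x + rnorm(n)
  d <- rbind(L1 = x, M1 = y); colnames(d) <- paste0("s", 1:n)
  pairs <- data.frame(lnc_id = c("L1", "L1"), mrna_id = c("M1", "M1"),
                      stringsAsFactors = FALSE)
  eff <- estimate_pair_effects(d, pairs, ci_cfg(0.01, 3))
  expect_equal(nrow(eff), 2L)
  # duplicate input pairs give duplicate identical outputs
  expect_identical(eff$effects[[1L]], eff$effects[[2L]])
  expect_equal(eff$effect_summary[1L], eff$effect_summary[2L])
  expect_s3_class(attr(eff, "cpdag"), "cpdag")
  expect_error(estimate_pair_effects(d, data.frame(lnc_id = "L9", mrna_id = "M1")),
               "missing from expression")
  # empty candidate list passes through as an empty result
  e0 <- estimate_pair_effects(d, pairs[0, , drop = FALSE])
  expect_equal(nrow(e0), 0L)
})

test_that("cpdag graphml export writes both edge kinds", {
  g <- cpdag(c("a", "b", "c"), directed = rbind(c("a", "b")),
             undirected = rbind(c("b", "c")))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_cpdag_graphml(g, path)
  doc <- paste(readLines(path), collapse = "\n")
  expect_match(doc, "graphml")
  expect_match(doc, "true")
  expect_match(doc, "false")
})
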