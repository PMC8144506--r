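test_that("truth generation is deterministic and honors the sharing plan", {
  spec <- sponge_system_spec(seed = 5L)
  t1 <- generate_truth(spec)
  t2 <- generate_truth(spec)
  expect_identical(t1, t2)
  # diagonal default: counts 0:5 recycled along (i, i); zero entries absent
  plan <- sharing_diagonal(12, 20)[cbind(1:12, 1:12)]
  expect_equal(t1$true_sponge_pairs$n_shared, plan[plan > 0])
  expect_equal(t1$true_sponge_pairs$lnc_id, sprintf("lnc%02d", which(plan > 0)))
  # construction check: a planted pair has exactly its planned common parents
  spec3 <- plant_sponge_pairs(sponge_system_spec(seed = 6L), 1, 3)
  t3 <- generate_truth(spec3)
  e <- t3$edges
  common <- intersect(e$from[e$to == "lnc01"], e$from[e$to == "mRNA01"])
  expect_length(common, 3L)
  # all-zero sharing with no privates: no sponge pairs, no direct pairs
  spec0 <- sponge_system_spec(sharing_matrix = sharing_none(12, 20), seed = 7L)
  t0 <- generate_truth(spec0)
  expect_equal(nrow(t0$true_sponge_pairs), 0L)
  expect_equal(nrow(t0$true_direct_pairs), 0L)
})

test_that("sharing demand beyond the miRNA pool is rejected", {
  spec <- sponge_system_spec(n_mirna = 10L,
                             sharing_matrix = sharing_diagonal(12, 20, counts = 3))
  expect_error(generate_truth(spec), "sharing demand")
  spec2 <- sponge_system_spec(n_mirna = 30L, private_per_gene = 2L)
  expect_error(generate_truth(spec2), "private-regulator demand")
})

test_that("simulated expression matches the closed-form sponge correlation", {
  # one pair sharing s miRNAs with equal coefficients b and unit noise has
  # population correlation s b^2 / (s b^2 + 1)
  for (s in c(1L, 4L)) {
    spec <- sponge_system_spec(
      n_mirna = 10L, n_lnc = 1L, n_mrna = 1L, n_samples = 2000L,
      sharing_matrix = matrix(s, 1, 1), repression_strength = -0.8,
      coef_sd = 0, fp_rate = 0, fn_rate = 0, seed = 100L + s)
    truth <- generate_truth(spec)
    x <- simulate_expression(truth, spec)
    rho <- s * 0.64 / (s * 0.64 + 1)
    expect_equal(cor(x["lnc01", ], x["mRNA01", ]), rho, tolerance = 3 / sqrt(2000))
  }
  # miRNA-only background: unrelated transcripts stay uncorrelated
  spec0 <- sponge_system_spec(n_mirna = 35L, n_lnc = 3L, n_mrna = 3L,
                              n_samples = 2000L,
                              sharing_matrix = sharing_none(3, 3),
                              private_per_gene = 1L, seed = 11L)
  x0 <- simulate_expression(generate_truth(spec0), spec0)
  cors <- cor(t(x0))
  expect_lt(max(abs(cors[upper.tri(cors)])), 3 / sqrt(2000))
})

test_that("a direct lncRNA->mRNA edge is recovered by the causal stage", {
  spec <- sponge_system_spec(
    n_mirna = 10L, n_lnc = 1L, n_mrna = 1L, n_samples = 5000L,
    sharing_matrix = matrix(0L, 1, 1), direct_effect = 1.2,
    direct_pairs = cbind(1L, 1L), fp_rate = 0, fn_rate = 0, seed = 13L)
  truth <- generate_truth(spec)
  expect_equal(nrow(truth$true_direct_pairs), 1L)
  x <- simulate_expression(truth, spec)
  # with no confounding the OLS slope is the direct coefficient
  slope <- unname(coef(lm(x["mRNA01", ] ~ x["lnc01", ]))[2L])
  expect_equal(slope, 1.2, tolerance = 5 / sqrt(5000))
})

test_that("evidence corruption applies the planned fp/fn draws", {
  spec <- sponge_system_spec(seed = 21L)   # 30 true miRNA->target edge pairs
  truth <- generate_truth(spec)
  # fp = fn = 0: records biject with the miRNA->target edges
  spec0 <- spec; spec0$fp_rate <- 0; spec0$fn_rate <- 0
  ev0 <- emit_evidence(truth, spec0)
  rec0 <- rbind(ev0$lncrna, ev0$mrna)
  expect_equal(sort(paste(rec0$mirna_id, rec0$target_id)),
               sort(paste(truth$edges$from, truth$edges$to)))
  # with corruption: spurious count is exact, deletions only remove truths
  ev <- emit_evidence(truth, spec)
  for (class_ in c("lncrna", "mrna")) {
    rec <- ev[[class_]]
    targets <- if (class_ == "lncrna") truth$lnc_ids else truth$mrna_ids
    tru <- truth$edges[truth$edges$to %in% targets, ]
    true_keys <- paste(tru$from, tru$to)
    got_keys <- paste(rec$mirna_id, rec$target_id)
    n_fp <- sum(!got_keys %in% true_keys)
    expect_equal(n_fp, round(spec$fp_rate * nrow(tru)))
    expect_equal(rec$source[!got_keys %in% true_keys],
                 rep("synthetic_fp", n_fp))
    expect_true(all(got_keys[rec$source == "synthetic"] %in% true_keys))
  }
  expect_identical(emit_evidence(truth, spec), ev)
})

test_that("fixture bundles are byte-identical per seed and feed the pipeline", {
  spec <- plant_sponge_pairs(sponge_system_spec(seed = 31L), 3, 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- end_to_end_fixture(spec, d1)
  p2 <- end_to_end_fixture(spec, d2)
  for (key in c("expression", "annotation", "evidence_lncrna", "evidence_mrna",
                "truth_edges", "truth_pairs")) {
    expect_identical(readLines(p1[[key]]), readLines(p2[[key]]))
  }
  res <- suppressMessages(run_pipeline(p1$config, out_dir = file.path(d1, "out")))
  expect_gt(nrow(res$network$edges), 0L)
  sc <- score_network(res$network, generate_truth(spec))
  expect_equal(sc$n_edges, sc$tp + sc$fp)
})
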