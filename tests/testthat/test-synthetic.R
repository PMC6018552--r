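test_that("generate_planted_network honours its cardinality contract", {
  net <- generate_planted_network(3, 12, 20, effect_size = 1, seed = 42)
  expect_length(net$tf_ids, 3)
  expect_length(net$target_ids, 12)
  expect_length(net$null_ids, 20)
  # every target regulated by >= 1 TF, every edge endpoint legal
  expect_setequal(unique(net$edges$target), net$target_ids)
  expect_true(all(net$edges$tf %in% net$tf_ids))
  expect_true(all(net$edges$weight != 0 & is.finite(net$edges$weight)))
  expect_length(intersect(net$null_ids, c(net$tf_ids, net$target_ids)), 0)
  expect_gte(sum(net$edges$sign < 0), 1)

  minimal <- generate_planted_network(1, 1, 0, effect_size = 1, seed = 7)
  expect_equal(nrow(minimal$edges), 1)
  expect_true(minimal$edges$sign %in% c(-1, 1))
  expect_identical(minimal, generate_planted_network(1, 1, 0, effect_size = 1, seed = 7))
  expect_identical(generate_planted_network(3, 12, 20, seed = 5),
                   generate_planted_network(3, 12, 20, seed = 5))
  expect_error(generate_planted_network(0, 3, 1), "positive")
  expect_error(generate_planted_network(1, 1, 0, effect_size = 0), "effect_size")
})

test_that("simulate_expression is the stated linear model", {
  # degenerate: zero noise and zero effects -> every sample at baseline
  cfg <- noiseless_config(seed = 3)
  net <- generate_planted_network(1, 2, 1, effect_size = 1, seed = 3)
  net0 <- net
  net0$tf_region_effect$effect <- 0
  expr <- simulate_expression(net0, cfg)
  expect_true(all(apply(expr, 1, function(x) diff(range(x)) == 0)))

  # linearity: one +1 edge, effect 1, zero noise -> L-S difference = weight
  expr1 <- simulate_expression(net, cfg)
  samples <- attr(expr1, "samples")
  lmask <- region_class(samples$region) == "L"
  pos_target <- net$edges$target[net$edges$sign > 0][1]
  neg_target <- net$edges$target[net$edges$sign < 0][1]
  dpos <- mean(expr1[pos_target, lmask]) - mean(expr1[pos_target, !lmask])
  expect_equal(dpos, net$edges$weight[net$edges$sign > 0][1], tolerance = 1e-12)
  dneg <- mean(expr1[neg_target, lmask]) - mean(expr1[neg_target, !lmask])
  expect_equal(dneg, -1, tolerance = 1e-12)
  # null genes receive no TF term
  expect_equal(unname(diff(range(expr1["nl01", ]))), 0)
})

test_that("planted L-S effects are recovered on average across seeds", {
  # Monte-Carlo mean of the per-target L-S contrast vs the planted value
  diffs <- unlist(lapply(1:20, function(s) {
    w <- make_world(seed = s, n_tfs = 2, n_targets = 4, n_nulls = 2)
    samples <- attr(w$expr, "samples")
    lmask <- region_class(samples$region) == "L"
    pos <- w$net$edges$target[w$net$edges$sign > 0]
    vapply(pos, function(g) {
      mean(w$expr[g, lmask]) - mean(w$expr[g, !lmask])
    }, numeric(1))
  }))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1), 3 * se)
})

test_that("expression_to_cq inverts the quantification model", {
  cfg <- noiseless_config(seed = 9)
  net <- generate_planted_network(1, 2, 1, effect_size = 1, seed = 9)
  expr <- simulate_expression(net, cfg)
  plate <- expression_to_cq(expr, cfg)
  expect_s3_class(plate, "cq_plate")
  # doubling expression lowers Cq by exactly 1 at zero noise
  expr2 <- expr + 1
  attr(expr2, "samples") <- attr(expr, "samples")
  plate2 <- expression_to_cq(expr2, cfg)
  tgt <- !plate$is_reference
  expect_equal(plate2$cq[tgt], plate$cq[tgt] - 1, tolerance = 1e-12)
  # reference genes unaffected by target expression
  expect_equal(plate2$cq[!tgt], plate$cq[!tgt], tolerance = 1e-12)

  # round trip: noiseless plate through quantification recovers ratios
  rq <- relative_quantities(plate, c("ref1", "ref2"))
  g <- net$target_ids[1]
  sub <- rq[rq$gene == g, ]
  key <- sample_key(sub$fin, sub$region, sub$stage, sub$replicate)
  samples <- attr(expr, "samples")
  ekey <- sample_key(samples$fin, samples$region, samples$stage, samples$replicate)
  e <- expr[g, match(key, ekey)]
  expect_equal(sub$rq / sub$rq[1], 2^(e - e[1]), tolerance = 1e-9)
})

test_that("RQ estimates of planted 2-fold effects are calibrated at default noise", {
  med <- vapply(1:20, function(s) {
    w <- make_world(seed = s, n_tfs = 2, n_targets = 4, n_nulls = 1)
    rq <- relative_quantities(w$plate, c("ref1", "ref2"))
    pos <- w$net$edges$target[w$net$edges$sign > 0]
    folds <- vapply(pos, function(g) {
      sub <- rq[rq$gene == g, ]
      2^(mean(sub$log_rq[region_class(sub$region) == "L"]) -
           mean(sub$log_rq[region_class(sub$region) == "S"]))
    }, numeric(1))
    median(folds)
  }, numeric(1))
  expect_gte(median(med), 1.8)
  expect_lte(median(med), 2.2)
})

test_that("synthetic generators are deterministic given the seed", {
  w1 <- make_world(seed = 11, n_tfs = 2, n_targets = 4, n_nulls = 3)
  w2 <- make_world(seed = 11, n_tfs = 2, n_targets = 4, n_nulls = 3)
  expect_identical(w1$plate, w2$plate)
  db1 <- build_coexpression_db(w1$net, w1$cfg)
  db2 <- build_coexpression_db(w2$net, w2$cfg)
  expect_identical(db1, db2)
  lib <- generate_pwm_library(4, c(8, 8), seed = 11, tf_ids = w1$net$tf_ids)
  p1 <- generate_promoters(w1$net, lib, w1$cfg)
  p2 <- generate_promoters(w2$net, lib, w2$cfg)
  expect_identical(p1, p2)
  # and byte-identical on disk
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(p1, f1); write_fasta(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("coexpression db ranks, bounds supportability, and separates signal", {
  w <- make_world(seed = 4, n_tfs = 2, n_targets = 6, n_nulls = 6,
                  compendium_noise_sd = 0.3)
  db <- build_coexpression_db(w$net, w$cfg)
  expect_true(all(db$supportability <= w$cfg$n_batches))
  expect_true(all(db$gene != db$neighbor))
  # ranks strictly by descending correlation
  for (g in unique(db$gene)[1:4]) {
    nb <- db_neighbors(db, g)
    expect_true(all(diff(nb$correlation) <= 1e-12))
  }
  # co-targets of the same TF with equal signs support each other
  ed <- w$net$edges
  tf1 <- ed$target[ed$tf == "tf01" & ed$sign > 0]
  pair <- db[db$gene == tf1[1] & db$neighbor == tf1[2], ]
  expect_gt(pair$correlation, 0.3)
  expect_gte(pair$supportability, 1)
  expect_error(build_coexpression_db(w$net, simulation_config(compendium_size = 10)),
               "compendium_size")
})
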