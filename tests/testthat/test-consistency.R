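test_that("paired_lvs_tests matches the hand-computed example", {
  # d = [0.5, 0.6, 0.7]; mean 0.6, sd 0.1; t = 0.6/(0.1/sqrt(3)) = 10.392
  rq <- make_rq_pairs(l = c(1.0, 1.2, 1.4), s = c(0.5, 0.6, 0.7))
  sig <- paired_lvs_tests(rq)
  expect_equal(sig$t, 10.392305, tolerance = 1e-6)
  expect_equal(sig$df, 2)
  expect_equal(sig$p, 0.0091328, tolerance = 1e-4)
  expect_equal(sig$direction, "higher-L")

  # null identity and label-swap symmetry
  same <- paired_lvs_tests(make_rq_pairs(l = c(1, 2, 3), s = c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  swapped <- paired_lvs_tests(make_rq_pairs(l = c(0.5, 0.6, 0.7),
                                            s = c(1.0, 1.2, 1.4)))
  expect_equal(swapped$p, sig$p)
  expect_equal(swapped$direction, "higher-S")

  # zero-variance nonzero differences: degenerate flag, p = 0
  deg <- paired_lvs_tests(make_rq_pairs(l = c(2, 3, 4), s = c(1, 2, 3)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("paired t equals the stats::t.test oracle on random data", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    l <- rnorm(n); s <- rnorm(n)
    sig <- paired_lvs_tests(make_rq_pairs(l = l, s = s))
    oracle <- t.test(l, s, paired = TRUE)
    expect_equal(sig$t, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(sig$p, oracle$p.value, tolerance = 1e-9)
  }
})

test_that("pairing violations and tiny designs are rejected", {
  rq <- make_rq_pairs(l = c(1, 2, 3), s = c(0, 1, 2))
  broken <- rq[!(rq$region == "dS" & rq$replicate == 3), ]
  class(broken) <- class(rq)
  expect_error(paired_lvs_tests(broken), "unpaired")
  one <- rq[rq$replicate == 1, ]
  class(one) <- class(rq)
  expect_error(paired_lvs_tests(one), ">= 2 replicate")
})

test_that("consistency_call implements the two-stages-of-two-fins rule", {
  # dorsal stages 0,1 and anal stages 1,2 higher-L -> consistent
  sig <- as_sig(
    sig_row("g", "dorsal", "dL", 0, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 1, 0.02, "higher-L"),
    sig_row("g", "dorsal", "dL", 2, 0.50, "higher-L"),
    sig_row("g", "anal", "aL", 1, 0.01, "higher-L"),
    sig_row("g", "anal", "aL", 2, 0.03, "higher-L"))
  expect_equal(consistency_call(sig)$verdict, "consistent-higher-L")

  # three stages of a single fin: fails min_fins
  sig1 <- as_sig(
    sig_row("g", "dorsal", "dL", 0, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 1, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 2, 0.01, "higher-L"))
  expect_equal(consistency_call(sig1)$verdict, "inconsistent")

  # opposing directions in different fins: inconsistent
  sig2 <- as_sig(
    sig_row("g", "dorsal", "dL", 0, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 1, 0.01, "higher-L"),
    sig_row("g", "anal", "aL", 0, 0.01, "higher-S"),
    sig_row("g", "anal", "aL", 1, 0.01, "higher-S"))
  expect_equal(consistency_call(sig2)$verdict, "inconsistent")
})

test_that("caudal cells require both L regions under the default rule", {
  mk <- function(p_vcl) as_sig(
    sig_row("g", "caudal", "dcL", 0, 0.01, "higher-L"),
    sig_row("g", "caudal", "vcL", 0, p_vcl, "higher-L"),
    sig_row("g", "caudal", "dcL", 1, 0.01, "higher-L"),
    sig_row("g", "caudal", "vcL", 1, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 0, 0.01, "higher-L"),
    sig_row("g", "dorsal", "dL", 1, 0.01, "higher-L"),
    sig_row("g", "anal", "aL", 0, 0.01, "higher-L"),
    sig_row("g", "anal", "aL", 1, 0.01, "higher-L"))
  expect_equal(consistency_call(mk(0.01))$verdict, "consistent-higher-L")
  # one caudal L region not significant: the stage-0 cell drops out
  expect_equal(consistency_call(mk(0.5))$verdict, "consistent-higher-L")
  rep_any <- consistency_call(mk(0.5), caudal_rule = "any")
  rep_all <- consistency_call(mk(0.5))
  expect_gt(rep_any$n_cells, rep_all$n_cells)
})

test_that("verdicts are invariant to fin/stage relabelling and monotone in alpha", {
  set.seed(99)
  for (i in 1:20) {
    rows <- list()
    dir <- sample(c("higher-L", "higher-S"), 1)  # conflict-free by design
    for (f in c("dorsal", "anal")) {
      lr <- fin_layout()[[f]]$L
      for (st in 0:2) {
        rows[[length(rows) + 1]] <- sig_row("g", f, lr, st, runif(1), dir)
      }
    }
    sig <- do.call(as_sig, rows)
    v1 <- consistency_call(sig)$verdict
    # permute stage labels and swap fins
    sig2 <- sig
    sig2$stage <- (sig2$stage + 1) %% 3
    sig2$fin <- ifelse(sig2$fin == "dorsal", "anal", "dorsal")
    sig2$l_region <- ifelse(sig2$fin == "dorsal", "dL", "aL")
    expect_identical(consistency_call(sig2)$verdict, v1)
    # monotonicity on conflict-free matrices
    v_strict <- consistency_call(sig, alpha = 0.01)$verdict
    if (startsWith(v_strict, "consistent")) expect_identical(v1, v_strict)
  }
})

test_that("region model detects a planted effect and applies Bonferroni", {
  # Bonferroni arithmetic: p = 0.002 in a 23-gene batch -> 0.046
  expect_equal(min(1, 0.002 * 23), 0.046)
  w <- make_world(seed = 2, n_tfs = 1, n_targets = 2, n_nulls = 1,
                  effect_size = 1.5, noise_sd_cq = 0.25)
  rq <- relative_quantities(w$plate, c("ref1", "ref2"))
  fit <- fit_region_model(rq)
  expect_equal(fit$p_region_adj, pmin(1, fit$p_region * nrow(fit)))
  pos <- w$net$edges$target[w$net$edges$sign > 0][1]
  expect_lt(fit$p_region[fit$gene == pos], 0.05)
  expect_gt(fit$p_region[fit$gene == "nl01"], 0.05)
})

test_that("region model power and type-I behaviour match the simulation oracle", {
  # power: planted effect 1.5, Cq noise 0.25 -> adjusted p < 0.05 in >= 90%
  # of seeds (scaled to 25 seeds to stay within the test budget)
  hits <- vapply(1:25, function(s) {
    w <- make_world(seed = s, n_tfs = 1, n_targets = 1, n_nulls = 0,
                    effect_size = 1.5, noise_sd_cq = 0.25)
    rq <- relative_quantities(w$plate, c("ref1", "ref2"))
    fit <- fit_region_model(rq, genes = w$net$target_ids[1], interactions = FALSE)
    fit$p_region_adj < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # type-I: null-gene region p approximately uniform (scaled to 120 genes)
  w <- make_world(seed = 1234, n_tfs = 1, n_targets = 1, n_nulls = 120)
  rq <- relative_quantities(w$plate, c("ref1", "ref2"))
  fit <- fit_region_model(rq, genes = w$net$null_ids, interactions = FALSE)
  rate <- mean(fit$p_region < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)
})
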