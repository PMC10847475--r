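test_that("collapse_burden takes the max carried weight and zero otherwise", {
  variants <- make_variants(
    list(variant_id = "v1", gene = "A"), list(variant_id = "v2", gene = "A"),
    list(variant_id = "v3", gene = "B")
  )
  variants$weight <- c(0.2, 0.9, 0.5)
  carriers <- data.frame(
    variant_id = c("v1", "v2", "v3", "v3"),  # duplicate row = hom carrier
    sample_id = c("S1", "S1", "S2", "S2")
  )
  b <- collapse_burden(variants, carriers, c("S1", "S2", "S3"))
  expect_equal(b["S1", "A"], 0.9)
  expect_equal(b["S1", "B"], 0)
  expect_equal(b["S2", "B"], 0.5)   # het/hom carrier status identical
  expect_equal(Matrix::rowSums(b)[["S3"]], 0)
  expect_error(collapse_burden(variants,
                               data.frame(variant_id = "nope", sample_id = "S1"),
                               c("S1")), "unknown variant")
})

test_that("eligible_genes requires min_qualified distinct weight-nonzero variants", {
  variants <- data.table::rbindlist(list(
    # gene A: exactly 10 qualified
    do.call(make_variants, lapply(1:10, function(i) list(variant_id = sprintf("a%02d", i), gene = "A"))),
    # gene B: 9 qualified + 5 zero-weight
    do.call(make_variants, lapply(1:14, function(i) list(variant_id = sprintf("b%02d", i), gene = "B")))
  ))
  variants$weight <- c(rep(0.5, 10), rep(0.5, 9), rep(0, 5))
  expect_equal(eligible_genes(variants, 10), "A")
  empty <- variants[0, ]
  expect_equal(eligible_genes(empty, 10), character(0))
})

test_that("fisher_exact_2x2 matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(3, 7, 1, 9), fisher_oracle(3, 7, 1, 9), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 80, 0, 89), 1)
  # symmetry: transposing the table leaves p unchanged
  expect_equal(fisher_exact_2x2(3, 7, 1, 9), fisher_exact_2x2(3, 1, 7, 9))
  # random tables against stats::fisher.test
  withr::with_seed(42, {
    for (i in 1:25) {
      cells <- rpois(4, 6)
      expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                   stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-10)
    }
  })
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  # mid-p subtracts half the observed (and tied) point mass
  p_exact <- fisher_exact_2x2(3, 7, 1, 9)
  p_mid <- fisher_exact_2x2(3, 7, 1, 9, midp = TRUE)
  expect_lt(p_mid, p_exact)
})

test_that("cauchy_combine reproduces high-precision reference values", {
  # references computed with 60-digit arbitrary-precision arithmetic at the
  # binary-exact double inputs
  cases <- list(
    list(p = c(0.01, 0.10, 0.50), w = NULL, expect = 0.02729618663946214698),
    list(p = c(1e-12, 0.5), w = NULL, expect = 1.99999999999999996e-12),
    list(p = c(0.2, 0.4, 0.6, 0.8), w = NULL, expect = 0.5),
    list(p = c(0.01, 0.2, 0.9), w = c(1, 2, 3), expect = 0.07400574738459998683),
    list(p = c(0.999999, 0.5), w = NULL, expect = 0.99999799999999996223),
    list(p = c(1e-12, 1e-12, 0.9999), w = NULL, expect = 1.50000000749999976e-12),
    list(p = c(0.03, 0.04, 0.05), w = c(5, 1, 1), expect = 0.03307524607059264516)
  )
  for (cs in cases) {
    expect_equal(cauchy_combine(cs$p, cs$w), cs$expect, tolerance = 1e-12)
  }
  # a cancelling pair of near-boundary inputs: the two tangent terms are
  # ~3.2e9 and nearly annihilate, so double precision carries ~3e-12 of
  # intrinsic conditioning error; checked at a tolerance that reflects it
  expect_equal(cauchy_combine(c(1e-10, 1 - 1e-10)), 0.002417153439235785544,
               tolerance = 5e-9)
})

test_that("cauchy_combine has the documented fixed points and invariances", {
  expect_equal(cauchy_combine(0.5), 0.5)
  for (x in c(0.001, 0.05, 0.3, 0.5, 0.77, 0.999)) {
    expect_equal(cauchy_combine(rep(x, 3)), x, tolerance = 1e-9)
  }
  # invariant to rescaling all weights
  p <- c(0.02, 0.4, 0.77)
  expect_equal(cauchy_combine(p, c(1, 2, 3)), cauchy_combine(p, c(10, 20, 30)))
  expect_error(cauchy_combine(numeric(0)), "empty")
  expect_error(cauchy_combine(c(0.5, 0.5), c(1, -1)), "positive")
})

test_that("odds_ratio computes the cross-product with Haldane-Anscombe fallback", {
  expect_equal(odds_ratio(2, 98, 1, 199), (2 * 199) / (98 * 1), tolerance = 1e-12)
  expect_equal(odds_ratio(5, 95, 0, 200), (5.5 * 200.5) / (95.5 * 0.5), tolerance = 1e-12)
  expect_equal(odds_ratio(7, 13, 7, 13), 1)
  expect_equal(odds_ratio(3, 3, 3, 3), 1)
})

test_that("qvalues_storey follows the step-down formula with single-lambda pi0", {
  p <- c(0.01, 0.02, 0.03, 0.8, 0.9)
  q <- qvalues_storey(p, lambda0 = 0.5)
  expect_equal(attr(q, "pi0"), 0.8)
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.04, 0.72, 0.72), tolerance = 1e-12)

  expect_equal(as.numeric(qvalues_storey(rep(1, 4))), rep(1, 4))

  # pi0 = 1 reduces exactly to Benjamini-Hochberg
  withr::with_seed(7, {
    p_null <- runif(200)  # mean(p > 0.5) ~ 0.5 so pi0 caps at 1 often; force it
    p_null <- c(p_null, rep(0.99, 250))
    q2 <- qvalues_storey(p_null, lambda0 = 0.5)
    expect_equal(attr(q2, "pi0"), 1)
    expect_equal(as.numeric(q2), stats::p.adjust(p_null, method = "BH"), tolerance = 1e-12)
  })

  # monotone along sorted p and bounded by 1
  withr::with_seed(8, {
    p3 <- runif(500)^2
    q3 <- qvalues_storey(p3)
    o <- order(p3)
    expect_true(all(diff(q3[o]) >= -1e-12))
    expect_true(all(q3 <= 1 & q3 >= 0))
  })
  expect_error(qvalues_storey(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("genomic inflation factor is calibrated, monotone, and matches a frozen oracle", {
  m <- 10000
  expect_equal(genomic_inflation_lambda((1:m) / (m + 1)), 1, tolerance = 0.02)
  p <- c(0.01, 0.2, 0.6, 0.9)
  expect_gt(genomic_inflation_lambda(p / 2), genomic_inflation_lambda(p))
  # frozen value from an independent chi-square quantile implementation
  expect_equal(genomic_inflation_lambda(c(0.01, 0.5, 0.9)), 1.0, tolerance = 1e-9)
  expect_error(genomic_inflation_lambda(numeric(0)), "zero p-values")
})

test_that("gene_burden_test reduces to the single Fisher p when all weights are 1", {
  samples <- sprintf("S%04d", 1:200)
  entries <- data.frame(sample = samples[c(1:6, 21:28)], gene = "G1", burden = 1)
  b <- burden_matrix(entries, samples, "G1")
  labels <- case_control_labels(20, 180)
  res <- gene_burden_test(b, labels, midp = FALSE)
  a <- sum(entries$sample %in% labels$sample_id[labels$status == "case"])
  cc <- nrow(entries) - a
  expect_equal(res$p_combined, fisher_exact_2x2(a, 20 - a, cc, 180 - cc), tolerance = 1e-12)
  expect_equal(res$case_carriers, a)
  expect_equal(res$control_carriers, cc)
})

test_that("gene_burden_test handles degenerate genes and label errors", {
  samples <- sprintf("S%04d", 1:100)
  b <- burden_matrix(data.frame(sample = "S0001", gene = "G2", burden = 0.5),
                     samples, c("G1", "G2"))
  labels <- case_control_labels(10, 90)
  res <- gene_burden_test(b, labels)
  expect_equal(res[res$gene == "G1", ]$p_combined, 1)  # zero carriers
  all_case <- data.frame(sample_id = samples, status = "case")
  expect_error(gene_burden_test(b, all_case), "case and one control")
})

test_that("the exact conditional null of the combined statistic is calibrated", {
  # small enough to verify the lookup's null distribution directly: the
  # exact p-values, weighted by their own null probabilities, must be
  # super-uniform (exact tail) with mean 0.5 under the mid-p correction
  lk <- urvburden:::exact_combined_lookup(c(4L, 6L, 3L), n_case = 30, n_control = 120,
                                          midp = TRUE)
  K_cls <- c(4L, 6L, 3L)
  grid <- expand.grid(ka = 0:4, kb = 0:6, kc = 0:3)
  rest <- 150 - sum(K_cls)
  kr <- 30 - (grid$ka + grid$kb + grid$kc)
  logp <- lchoose(4, grid$ka) + lchoose(6, grid$kb) + lchoose(3, grid$kc) +
    ifelse(kr >= 0 & kr <= rest, lchoose(rest, kr), -Inf) - lchoose(150, 30)
  prob <- exp(logp)
  pv <- lk$p
  keep <- prob > 0
  expect_true(all(is.finite(pv[keep])))
  expect_equal(sum(prob), 1, tolerance = 1e-12)
  expect_equal(sum(pv[keep] * prob[keep]), 0.5, tolerance = 1e-9)  # mid-p mean
  # exact-tail version dominates uniform: P(p <= alpha) <= alpha
  lk2 <- urvburden:::exact_combined_lookup(K_cls, 30, 120, midp = FALSE)
  for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
    expect_lte(sum(prob[keep][lk2$p[keep] <= alpha]), alpha + 1e-12)
  }
})

test_that("a planted risk gene is recovered with high power", {
  hits <- 0L; n_seed <- 15L
  for (s in seq_len(n_seed)) {
    cfg <- simulation_config(n_cases = 750, n_controls = 3750, n_genes = 60,
                             variants_per_gene = 80, seed = 1000 + s,
                             risk_genes = data.frame(gene = "RISK1", odds_ratio = 4),
                             risk_p0 = 0.01)
    sim <- simulate_cohort(cfg)
    v <- assign_weights(filter_urv(select_canonical(sim$variants)), "functional")
    keep <- v$gene %in% eligible_genes(v)
    vv <- v[keep, ]
    b <- collapse_burden(vv, sim$carriers[sim$carriers$variant_id %in%
                                            vv$variant_id[vv$weight > 0], ],
                         sim$labels$sample_id)
    res <- gene_burden_test(b, sim$labels)
    if (res[res$gene == "RISK1", ]$p_combined < 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 13L)  # ~95% power with binomial slack at n = 15
})
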