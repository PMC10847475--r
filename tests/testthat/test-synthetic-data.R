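test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  bad_props <- c(pLoF = 0.5, inframe_indel = 0.1, missense = 0.2,
                 synonymous = 0.1, other = 0.05)  # sums to 0.95
  expect_error(simulation_config(consequence_props = bad_props), "sum to 1")
  expect_error(simulation_config(n_cases = 0), "positive")
  expect_error(simulation_config(risk_genes = data.frame(gene = "G", odds_ratio = -1)),
               "positive")
  expect_error(simulation_config(carrier_freq = 0), "carrier_freq")
})

test_that("simulate_cohort is deterministic given the seed", {
  cfg <- simulation_config(n_cases = 40, n_controls = 160, n_genes = 15,
                           variants_per_gene = 25, seed = 99,
                           risk_genes = data.frame(gene = "R1", odds_ratio = 3),
                           risk_p0 = 0.05)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$carriers, s2$carriers)
  expect_identical(s1$labels, s2$labels)
  # different seed differs
  s3 <- simulate_cohort(simulation_config(n_cases = 40, n_controls = 160,
                                          n_genes = 15, variants_per_gene = 25,
                                          seed = 100))
  expect_false(identical(s1$carriers, s3$carriers))
})

test_that("a null cohort has no systematic case/control carrier difference", {
  cfg <- simulation_config(n_cases = 400, n_controls = 400, n_genes = 50,
                           variants_per_gene = 40, seed = 5)
  sim <- simulate_cohort(cfg)
  merged <- merge(sim$carriers, sim$labels, by = "sample_id")
  rate_case <- nrow(merged[merged$status == "case", ]) / 400
  rate_ctrl <- nrow(merged[merged$status == "control", ]) / 400
  # carried variants per individual; equal in expectation under the null
  expect_lt(abs(rate_case - rate_ctrl) / rate_ctrl, 0.15)
})

test_that("risk genes realize the configured carrier odds ratio", {
  # closed form: p1 = R * p0 / (1 - p0 + R * p0) = 0.0388... for p0 = 0.01, R = 4
  p1 <- case_carrier_prob(0.01, 4)
  expect_equal(p1, 0.0388349514563107, tolerance = 1e-12)
  # a 1% gene-level URV carrier rate in 25k individuals needs a realistically
  # deep variant pool to stay within cohort AC <= 3 per variant
  cfg <- simulation_config(n_cases = 5000, n_controls = 20000, n_genes = 5,
                           variants_per_gene = 600, seed = 31,
                           risk_genes = data.frame(gene = "R1", odds_ratio = 4),
                           risk_p0 = 0.01)
  sim <- simulate_cohort(cfg)
  v <- assign_weights(filter_urv(select_canonical(sim$variants)), "functional")
  vq <- v[v$weight > 0, ]
  b <- collapse_burden(vq, sim$carriers[sim$carriers$variant_id %in% vq$variant_id, ],
                       sim$labels$sample_id)
  case_ids <- sim$labels$sample_id[sim$labels$status == "case"]
  frac <- mean(b[case_ids, "R1"] > 0)
  se <- sqrt(p1 * (1 - p1) / length(case_ids))
  expect_lt(abs(frac - p1), 3 * se)
})

test_that("simulate_genesets plants a set verbatim and is reproducible", {
  universe <- sprintf("G%03d", 1:100)
  planted <- c("G001", "G002", "G003")
  sets <- simulate_genesets(5, 10, universe, planted = planted, seed = 4)
  expect_identical(sets[["PLANTED"]], planted)
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
  sets2 <- simulate_genesets(5, 10, universe, planted = planted, seed = 4)
  expect_identical(sets, sets2)
  expect_error(simulate_genesets(1, 10, character(0)), "empty")
  expect_error(simulate_genesets(1, 200, universe), "exceeds")
})

test_that("simulate_expression is deterministic and realizes the planted fold", {
  planted <- sprintf("G%04d", 1:50)
  cfg <- expression_sim_config(n_genes = 300, cells_per_type_stage = 200,
                               cell_types = c("target", "other1", "other2"),
                               stages = "s1", baseline_mean = 2, dispersion = 0.4,
                               planted_sets = list(list(genes = planted,
                                                        cell_type = "target",
                                                        fold = 8)),
                               seed = 12)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(as.matrix(e1$counts), as.matrix(e2$counts))

  meta <- e1$cells
  tgt <- as.matrix(e1$counts[planted, meta$cell_id[meta$cell_type == "target"]])
  oth <- as.matrix(e1$counts[planted, meta$cell_id[meta$cell_type != "target"]])
  ratio <- mean(tgt) / mean(oth)
  # delta-method SE of the ratio of means from the observed data
  se <- ratio * sqrt(var(as.vector(tgt)) / (mean(tgt)^2 * length(tgt)) +
                     var(as.vector(oth)) / (mean(oth)^2 * length(oth)))
  expect_lt(abs(ratio - 8), 3 * se)
})

test_that("expression config rejects unknown planted references and bad folds", {
  expect_error(expression_sim_config(n_genes = 10,
                                     planted_sets = list(list(genes = "NOPE",
                                                              cell_type = "notochord",
                                                              fold = 2))),
               "unknown gene")
  expect_error(expression_sim_config(n_genes = 10,
                                     planted_sets = list(list(genes = "G0001",
                                                              cell_type = "nope",
                                                              fold = 2))),
               "unknown cell type")
  expect_error(expression_sim_config(n_genes = 10,
                                     planted_sets = list(list(genes = "G0001",
                                                              cell_type = "notochord",
                                                              fold = 0.5))),
               "fold")
})

test_that("simulate_probands reproduces the requested marginal counts", {
  pr <- simulate_probands(n = 100, n_female = 40,
                          class_counts = c(failure_of_formation = 30,
                                           segmentation_defect = 20, mixed = 50),
                          n_diagnosed = 10,
                          anomaly_counts = c(cardiac = 15), seed = 3)
  expect_equal(nrow(pr), 100)
  expect_equal(sum(pr$sex == "female"), 40)
  expect_equal(sum(pr$diagnosed), 10)
  expect_equal(sum(pr$cardiac), 15)
  expect_equal(as.integer(table(pr$malformation_class)[c("failure_of_formation",
                                                         "segmentation_defect", "mixed")]),
               c(30L, 20L, 50L))
  expect_error(simulate_probands(n = 10, class_counts = c(failure_of_formation = 5,
                                                          segmentation_defect = 1,
                                                          mixed = 1)),
               "sum to")
})
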