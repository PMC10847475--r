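# Small end-to-end pipeline fixture: a seeded cohort with two planted risk
# genes, gene sets containing them, and a labeled expression bundle.
pipeline_fixture <- function(dir, seed = 21) {
  rg <- data.frame(gene = c("RISK1", "RISK2"), odds_ratio = 5)
  sim <- simulate_cohort(simulation_config(n_cases = 150, n_controls = 750,
                                           n_genes = 80, variants_per_gene = 50,
                                           seed = seed, risk_genes = rg,
                                           risk_p0 = 0.03))
  paths <- write_cohort(sim, dir)
  gs <- simulate_genesets(15, 12, universe = sort(unique(sim$variants$gene)),
                          planted = c("RISK1", "RISK2", sprintf("G%04d", 1:8)),
                          seed = 2)
  gmt <- file.path(dir, "sets.gmt")
  write_gmt(gs, gmt)
  expr <- simulate_expression(expression_sim_config(n_genes = 100,
                                                    cell_types = c("a", "b", "c"),
                                                    stages = c("s1", "s2"),
                                                    cells_per_type_stage = 25,
                                                    seed = 4))
  epaths <- write_expression(expr, dir)
  pipeline_config(variants = paths[["variants"]], carriers = paths[["carriers"]],
                  labels = paths[["labels"]], genesets = gmt,
                  expression_mtx = epaths[["mtx"]], expression_genes = epaths[["genes"]],
                  expression_cells = epaths[["cells"]], n_perm = 50, n_boot = 200,
                  seed = 5)
}
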