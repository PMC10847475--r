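#' Write a simulated cohort to disk
#'
#' Writes `variants.tsv`, `carriers.tsv` and `labels.tsv` (tab-separated)
#' into `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             carriers = file.path(dir, "carriers.tsv"),
             labels = file.path(dir, "labels.tsv"))
  fwrite(sim$variants, paths[["variants"]], sep = "\t")
  fwrite(sim$carriers, paths[["carriers"]], sep = "\t")
  fwrite(sim$labels, paths[["labels"]], sep = "\t")
  invisible(paths)
}

#' Write a simulated expression bundle to disk
#'
#' Writes `matrix.mtx`, `genes.tsv` and `cells.tsv` into `dir`.
#'
#' @param expr Output of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cells.tsv"))
  Matrix::writeMM(expr$counts, paths[["mtx"]])
  writeLines(rownames(expr$counts), paths[["genes"]])
  fwrite(expr$cells, paths[["cells"]], sep = "\t")
  invisible(paths)
}

#' Default pipeline configuration
#'
#' Returns the full parameter list of [run_pipeline()] with defaults filled
#' in; pass overrides as named arguments or a list (e.g. parsed from YAML).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    variants = NULL, carriers = NULL, labels = NULL,
    genesets = NULL,
    expression_mtx = NULL, expression_genes = NULL, expression_cells = NULL,
    outdir = NULL,
    weight_table = "functional",
    popmax_max = 1e-4, ac_max = 3L, min_qualified = 10L,
    thresholds = c(1e-8, 0.5, 1),
    n_perm = 1000L, lambda_storey = 0.5, alpha_hits = 0.05,
    n_boot = 1000L, seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) && is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop_config("unknown pipeline config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, overrides)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A named list of pipeline parameters.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  pipeline_config(yaml::read_yaml(path))
}

stage_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full burden-analysis pipeline
#'
#' Executes, in order: variant reading, canonical-transcript selection,
#' cohort allele counting, the ultra-rare-variant filter, weight assignment,
#' gene eligibility, per-individual burden collapsing, the per-gene
#' Fisher/ACAT burden test, label-permutation expected p-values,
#' Storey-Tibshirani q-values, and (when inputs are provided) hypergeometric
#' pathway enrichment of nominally significant genes and expression-weighted
#' cell-type enrichment. Results are written as TSVs plus a JSON run
#' manifest; re-running with the same config reproduces identical files.
#'
#' @param config A [pipeline_config()] list or the path to a YAML file.
#' @return Invisibly, a list with `results`, `qq`, `pathway`, `ewce`
#'   (data.tables or NULL) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- pipeline_config(config)
  for (key in c("variants", "carriers", "labels")) {
    if (is.null(config[[key]])) stop_config("pipeline config lacks required input '%s'", key)
  }
  input_keys <- c("variants", "carriers", "labels", "genesets",
                  "expression_mtx", "expression_genes", "expression_cells")
  for (key in input_keys) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) stop_config("input file for '%s' not found: %s", key, p)
  }
  if (is.null(config$outdir)) stop_config("pipeline config lacks an output directory ('outdir')")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  stage_log("reading inputs")
  variants <- read_variant_table(config$variants)
  carriers <- read_carrier_table(config$carriers)
  labels <- read_label_table(config$labels)
  n_variants_input <- uniqueN(variants$variant_id)

  stage_log("selecting canonical transcript annotations")
  variants <- select_canonical(variants)
  if (!"cohort_ac" %in% names(variants) || anyNA(variants$cohort_ac)) {
    variants <- add_cohort_ac(variants, carriers)
  }

  stage_log("applying ultra-rare-variant filter (popmax <= %g, AC <= %d)",
            config$popmax_max, as.integer(config$ac_max))
  urv <- filter_urv(variants, popmax_max = config$popmax_max, ac_max = config$ac_max)

  wt <- resolve_weight_table(config$weight_table)
  stage_log("assigning weights (table '%s')", wt$name)
  urv <- assign_weights(urv, wt)

  elig <- eligible_genes(urv, min_qualified = config$min_qualified)
  stage_log("%d of %d genes eligible (>= %d qualified variants)",
            length(elig), uniqueN(urv$gene), as.integer(config$min_qualified))
  if (length(elig) == 0L) stop_config("no gene passes the eligibility filter")
  urv_elig <- urv[urv$gene %in% elig, ]
  nq <- qualified_variant_counts(urv_elig)

  stage_log("collapsing burdens for %d samples", nrow(labels))
  carriers_elig <- carriers[carriers$variant_id %in% urv_elig$variant_id, ]
  burden <- collapse_burden(urv_elig, carriers_elig, labels$sample_id)

  stage_log("testing %d genes", ncol(burden))
  results <- gene_burden_test(burden, labels, thresholds = config$thresholds,
                              n_qualified = nq)
  q <- qvalues_storey(results$p_combined, lambda0 = config$lambda_storey)
  results[, q_value := as.numeric(q)]
  setorder(results, p_combined, gene)
  lambda <- genomic_inflation_lambda(results$p_combined)

  stage_log("permutation null (n_perm = %d)", as.integer(config$n_perm))
  qq <- permute_expected_pvalues(burden, labels, thresholds = config$thresholds,
                                 n_perm = config$n_perm, seed = config$seed)
  qq[, observed_p := sort(results$p_combined)]

  hits <- results[p_combined < config$alpha_hits, gene]
  stage_log("%d nominally significant genes (p < %g), lambda = %.3f",
            length(hits), config$alpha_hits, lambda)

  pathway <- NULL
  if (!is.null(config$genesets) && length(hits) > 0L) {
    stage_log("pathway enrichment against %s", config$genesets)
    pathway <- hypergeometric_enrichment(hits, config$genesets, universe = elig)
  }

  ewce <- NULL
  if (!is.null(config$expression_mtx) && length(hits) > 0L) {
    stage_log("cell-type enrichment (n_boot = %d)", as.integer(config$n_boot))
    expr <- read_expression_mtx(config$expression_mtx, config$expression_genes,
                                config$expression_cells)
    spec <- compute_specificity(expr$counts, expr$cells)
    present <- intersect(hits, rownames(spec))
    if (length(present) > 0L) {
      ewce <- ewce_bootstrap(present, spec, n_boot = config$n_boot, seed = config$seed)
    } else {
      stage_log("no hit gene present in the expression matrix; skipping enrichment")
    }
  }

  manifest <- list(
    parameters = config[c("weight_table", "popmax_max", "ac_max", "min_qualified",
                          "thresholds", "n_perm", "lambda_storey", "alpha_hits",
                          "n_boot", "seed")],
    counts = list(
      n_samples = nrow(labels),
      n_cases = sum(labels$status == "case"),
      n_controls = sum(labels$status == "control"),
      n_variants_input = n_variants_input,
      n_variants_urv = uniqueN(urv$variant_id),
      n_qualified_variants = uniqueN(urv[urv$weight > 0, ]$variant_id),
      n_genes_annotated = uniqueN(variants$gene),
      n_genes_eligible = length(elig),
      n_hits_nominal = length(hits),
      n_genes_q_lt_0.05 = sum(results$q_value < 0.05)
    ),
    statistics = list(
      lambda_gc = lambda,
      pi0 = as.numeric(attr(q, "pi0"))
    )
  )
  manifest$parameters$weight_table <- wt$name

  stage_log("writing results to %s", config$outdir)
  fwrite(results, file.path(config$outdir, "results.tsv"), sep = "\t")
  fwrite(qq, file.path(config$outdir, "qq.tsv"), sep = "\t")
  if (!is.null(pathway)) fwrite(pathway, file.path(config$outdir, "pathway.tsv"), sep = "\t")
  if (!is.null(ewce)) fwrite(ewce, file.path(config$outdir, "ewce.tsv"), sep = "\t")
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(results = results, qq = qq, pathway = pathway, ewce = ewce,
                 manifest = manifest))
}
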