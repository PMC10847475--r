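#' Configuration for the synthetic case-control cohort generator
#'
#' Defaults emulate the statistical shape of a large rare-disease burden
#' study: ~750 undiagnosed cases against ~3740 screened controls, thousands
#' of genes each carrying on the order of a hundred distinct ultra-rare
#' variants (most observed in one or two individuals), a heavy-tailed
#' population allele-frequency spectrum with a point mass at zero (novel
#' variants) and a log-uniform component spanning both sides of the
#' ultra-rare threshold, and a handful of planted risk genes with carrier
#' odds ratios in the 3-6 range.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_genes Number of genes.
#' @param variants_per_gene Mean of the per-gene Poisson variant count
#'   (floored at 1).
#' @param consequence_props Named proportions over
#'   `r paste(CONSEQUENCE_CLASSES, collapse = ", ")`; must sum to 1.
#' @param popmax_zero_prob Probability a variant is absent from the
#'   reference population (popmax AF 0).
#' @param popmax_range Range of the log-uniform popmax AF component.
#' @param carrier_freq Per-variant probability that a given individual
#'   carries the variant (background rate; drives cohort allele counts).
#' @param risk_genes `data.frame(gene, odds_ratio)` of planted risk genes.
#'   For a risk gene with baseline (control) gene-level carrier probability
#'   `p0` and odds ratio `R`, cases carry with probability
#'   `p1 = R * p0 / (1 - p0 + R * p0)`.
#' @param risk_p0 Optional gene-level baseline carrier probability for risk
#'   genes; when `NULL` it is aggregated from `carrier_freq` over the gene's
#'   functional variants.
#' @param annotation_dup_frac Fraction of variants that also receive a
#'   non-canonical transcript annotation row (exercises canonical selection).
#' @param seed Integer seed; all outputs are deterministic given the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 744L,
                              n_controls = 3740L,
                              n_genes = 2500L,
                              variants_per_gene = 120,
                              consequence_props = c(pLoF = 0.08,
                                                    inframe_indel = 0.04,
                                                    missense = 0.45,
                                                    synonymous = 0.35,
                                                    other = 0.08),
                              popmax_zero_prob = 0.3,
                              popmax_range = c(1e-7, 1e-2),
                              carrier_freq = 2.5e-4,
                              risk_genes = NULL,
                              risk_p0 = NULL,
                              annotation_dup_frac = 0.05,
                              seed = 1L) {
  if (is.null(risk_genes)) {
    risk_genes <- data.frame(gene = character(), odds_ratio = numeric())
  }
  risk_genes <- as.data.frame(risk_genes)
  if (nrow(risk_genes) > 0L) check_columns(risk_genes, c("gene", "odds_ratio"), "risk_genes")
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes), variants_per_gene = variants_per_gene,
              consequence_props = consequence_props,
              popmax_zero_prob = popmax_zero_prob, popmax_range = popmax_range,
              carrier_freq = carrier_freq, risk_genes = risk_genes,
              risk_p0 = risk_p0, annotation_dup_frac = annotation_dup_frac,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_cases <= 0L || n_controls <= 0L || n_genes <= 0L || variants_per_gene <= 0) {
      stop_config("cohort sizes, gene count and variant rate must be positive")
    }
    if (is.null(names(consequence_props)) ||
        !setequal(names(consequence_props), CONSEQUENCE_CLASSES)) {
      stop_config("consequence_props must be named over: %s",
                  paste(CONSEQUENCE_CLASSES, collapse = ", "))
    }
    if (abs(sum(consequence_props) - 1) > 1e-9) {
      stop_config("consequence proportions must sum to 1 (got %.12f)", sum(consequence_props))
    }
    if (any(consequence_props < 0)) stop_config("consequence proportions must be nonnegative")
    if (popmax_zero_prob < 0 || popmax_zero_prob > 1) {
      stop_config("popmax_zero_prob must lie in [0, 1]")
    }
    if (length(popmax_range) != 2L || popmax_range[1L] <= 0 ||
        popmax_range[1L] >= popmax_range[2L] || popmax_range[2L] > 1) {
      stop_config("popmax_range must be an increasing pair within (0, 1]")
    }
    if (carrier_freq <= 0 || carrier_freq >= 1) stop_config("carrier_freq must lie in (0, 1)")
    if (nrow(risk_genes) > 0L && any(risk_genes$odds_ratio <= 0)) {
      stop_config("risk gene odds ratios must be positive")
    }
    if (!is.null(risk_p0) && (risk_p0 <= 0 || risk_p0 >= 1)) {
      stop_config("risk_p0 must lie in (0, 1)")
    }
  })
  invisible(cfg)
}

#' Case carrier probability implied by an odds ratio
#'
#' For baseline carrier probability `p0` and carrier odds ratio `R`,
#' `p1 = R * p0 / (1 - p0 + R * p0)`.
#'
#' @param p0 Baseline (control) carrier probability.
#' @param odds_ratio Carrier odds ratio.
#' @return Case carrier probability.
#' @export
case_carrier_prob <- function(p0, odds_ratio) {
  odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
}

# Consequence classes whose carriers constitute planted risk signal (the
# classes that receive nonzero weight under the functional table).
FUNCTIONAL_CLASSES <- c("pLoF", "inframe_indel", "missense")

#' Simulate an annotated case-control cohort
#'
#' Generates an annotated variant table, a long carrier table and a sample
#' label table with known ground truth. Background carriers are drawn per
#' variant at `carrier_freq` regardless of status; for each planted risk
#' gene, a gene-level carrier indicator is drawn per individual (probability
#' `p0` in controls, `p1` from the configured odds ratio in cases) and
#' redistributed uniformly over the gene's functional variants, matching the
#' collapsed unit the burden test operates on. Synonymous/other variants are
#' always background, so a synonymous-only calibration run stays null even
#' in risk genes. Carrier status is binary (het and hom are both "carrier")
#' and `cohort_ac` counts one allele per carrier.
#'
#' @param config A [simulation_config()].
#' @return List with `variants` (annotation table, one row per
#'   variant-transcript), `carriers` (`variant_id`, `sample_id`), `labels`
#'   (`sample_id`, `status`) and `truth` (per risk gene: `gene`,
#'   `odds_ratio`, `p0`, `p1`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_total <- cfg$n_cases + cfg$n_controls
  samples <- sprintf("S%05d", seq_len(n_total))
  labels <- data.table(sample_id = samples,
                       status = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)))

  risk_names <- cfg$risk_genes$gene
  if (length(risk_names) > cfg$n_genes) stop_config("more risk genes than genes")
  genes <- c(risk_names,
             sprintf("G%04d", seq_len(cfg$n_genes - length(risk_names))))

  nv <- pmax(1L, rpois(cfg$n_genes, cfg$variants_per_gene))
  V <- sum(nv)
  gene_of <- rep(genes, nv)
  gene_idx <- rep(seq_len(cfg$n_genes), nv)
  chrom_of_gene <- sample(as.character(1:22), cfg$n_genes, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  pos <- sample.int(240000000L, V, replace = FALSE)
  chrom <- chrom_of_gene[gene_idx]
  variant_id <- paste(chrom, pos, ref, alt, sep = "-")

  consequence <- sample(names(cfg$consequence_props), V, replace = TRUE,
                        prob = cfg$consequence_props)
  dmg <- integer(V)
  mis <- consequence == "missense"
  dmg[mis] <- sample(0:3, sum(mis), replace = TRUE, prob = c(0.35, 0.30, 0.20, 0.15))
  popmax <- numeric(V)
  nonzero <- runif(V) >= cfg$popmax_zero_prob
  lr <- log10(cfg$popmax_range)
  popmax[nonzero] <- 10^runif(sum(nonzero), lr[1L], lr[2L])

  variants <- data.table(
    variant_id = variant_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene_of,
    transcript = sprintf("ENST%06d", gene_idx * 10L + 1L),
    canonical = TRUE,
    consequence = consequence,
    damaging_prediction_count = dmg,
    gnomad_popmax_af = popmax
  )

  # Background carriers: vectorized with-replacement draw, deduplicated
  # (carrier status is binary, so a duplicate draw is a no-op).
  is_risk <- gene_of %in% risk_names
  planted <- is_risk & consequence %in% FUNCTIONAL_CLASSES
  bg_idx <- which(!planted)
  k_bg <- rbinom(length(bg_idx), n_total, cfg$carrier_freq)
  carriers_bg <- data.table(
    variant_id = rep(variants$variant_id[bg_idx], k_bg),
    sample_id = samples[sample.int(n_total, sum(k_bg), replace = TRUE)]
  )

  # Planted risk carriers: gene-level indicator redistributed over the
  # gene's qualifying variants (functional class, ultra-rare popmax), dealt
  # in near-balanced fashion so the planted variants remain singletons or
  # doubletons and the gene-level carrier probability survives the
  # ultra-rare-variant filter intact.
  truth_rows <- list(); carriers_risk <- list()
  case_ids <- samples[seq_len(cfg$n_cases)]
  control_ids <- samples[cfg$n_cases + seq_len(cfg$n_controls)]
  for (i in seq_along(risk_names)) {
    rg <- risk_names[i]
    R <- cfg$risk_genes$odds_ratio[i]
    qual <- which(gene_of == rg & planted & popmax <= 1e-4)
    if (length(qual) == 0L) stop_config("risk gene '%s' drew no qualifying functional variants; increase variants_per_gene", rg)
    p0 <- cfg$risk_p0 %||% (1 - (1 - cfg$carrier_freq)^length(qual))
    p1 <- case_carrier_prob(p0, R)
    car_case <- case_ids[runif(cfg$n_cases) < p1]
    car_ctrl <- control_ids[runif(cfg$n_controls) < p0]
    car <- c(car_case, car_ctrl)
    if (length(car) > 0L) {
      pool <- if (length(qual) > 1L) sample(qual) else qual
      carriers_risk[[rg]] <- data.table(
        variant_id = variants$variant_id[rep_len(pool, length(car))],
        sample_id = car
      )
    }
    truth_rows[[rg]] <- data.table(gene = rg, odds_ratio = R, p0 = p0, p1 = p1)
  }

  carriers <- unique(rbindlist(c(list(carriers_bg), carriers_risk)))
  setorder(carriers, variant_id, sample_id)

  variants <- add_cohort_ac(variants, carriers)

  # Extra non-canonical annotation rows on a fraction of variants.
  if (cfg$annotation_dup_frac > 0) {
    dup <- which(runif(V) < cfg$annotation_dup_frac)
    if (length(dup) > 0L) {
      extra <- variants[dup]
      extra[, `:=`(transcript = sprintf("ENST%06d", gene_idx[dup] * 10L + 2L),
                   canonical = FALSE,
                   consequence = sample(CONSEQUENCE_CLASSES, length(dup), replace = TRUE))]
      variants <- rbind(variants, extra)
    }
  }
  setorder(variants, chrom, pos, variant_id, transcript)

  list(variants = variants[], carriers = carriers[], labels = labels[],
       truth = rbindlist(truth_rows))
}

#' Simulate gene sets in GMT form
#'
#' Draws `n_sets` sets of `set_size` genes uniformly without replacement
#' from the universe; when `planted` is given, the first set is exactly the
#' planted gene set.
#'
#' @param n_sets Number of sets.
#' @param set_size Genes per (random) set.
#' @param universe Gene universe to draw from.
#' @param planted Optional character vector: a set included verbatim.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-ready; see [write_gmt()]).
#' @export
simulate_genesets <- function(n_sets, set_size, universe, planted = NULL, seed = 1L) {
  if (length(universe) == 0L) stop_config("gene universe is empty")
  if (set_size > length(universe)) stop_config("set_size exceeds the universe size")
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    if (!is.null(planted)) {
      sets[[1L]] <- unique(planted)
      names(sets)[1L] <- "PLANTED"
    }
    sets
  })
}

#' Configuration for the synthetic single-cell expression generator
#'
#' Emulates a labeled developmental single-nucleus atlas: a dozen cell types
#' observed across five gestational stages, negative-binomial counts at a
#' common baseline, and planted gene sets whose mean expression is multiplied
#' by a fold factor in one target cell type (at every stage).
#'
#' @param n_genes Number of genes (`G0001`...).
#' @param cell_types Character vector of cell-type labels.
#' @param stages Character vector of stage labels.
#' @param cells_per_type_stage Cells simulated per (cell type, stage).
#' @param baseline_mean Negative-binomial mean per gene per cell.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + mu^2 * dispersion`); 0 gives Poisson counts.
#' @param planted_sets List of `list(genes, cell_type, fold)` entries;
#'   `fold >= 1` multiplies the target type's mean for those genes.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000L,
                                  cell_types = c("notochord", "sclerotome",
                                                 "chondrocyte_progenitor", "osteoblast",
                                                 "myoblast", "myocyte",
                                                 "neural_progenitor", "neuron",
                                                 "fibroblast", "endothelium",
                                                 "immune", "erythroid"),
                                  stages = c("wk05", "wk06", "wk07", "wk08", "wk17"),
                                  cells_per_type_stage = 200L,
                                  baseline_mean = 0.5,
                                  dispersion = 0.5,
                                  planted_sets = list(),
                                  seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types, stages = stages,
              cells_per_type_stage = as.integer(cells_per_type_stage),
              baseline_mean = baseline_mean, dispersion = dispersion,
              planted_sets = planted_sets, seed = as.integer(seed))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (cfg$n_genes <= 0L || cfg$cells_per_type_stage <= 0L) {
    stop_config("gene and cell counts must be positive")
  }
  if (cfg$baseline_mean <= 0) stop_config("baseline_mean must be positive")
  if (cfg$dispersion < 0) stop_config("dispersion must be nonnegative")
  if (length(cfg$cell_types) < 2L) stop_config("need at least two cell types")
  for (ps in cfg$planted_sets) {
    if (!all(c("genes", "cell_type", "fold") %in% names(ps))) {
      stop_config("each planted set needs fields genes, cell_type, fold")
    }
    if (ps$fold < 1) stop_config("planted fold factors must be >= 1")
    if (!ps$cell_type %in% cfg$cell_types) {
      stop_config("planted set targets unknown cell type '%s'", ps$cell_type)
    }
    unknown <- setdiff(ps$genes, genes)
    if (length(unknown) > 0L) {
      stop_config("planted set references unknown gene(s), e.g. %s",
                  paste(utils::head(unknown, 3L), collapse = ", "))
    }
  }
  structure(cfg, class = "expression_sim_config")
}

#' Simulate a labeled single-cell count matrix
#'
#' Draws negative-binomial counts for every (gene, cell); genes in a planted
#' set have their mean multiplied by the fold factor in the target cell type
#' (all stages). Deterministic given the config seed.
#'
#' @param config An [expression_sim_config()].
#' @return List with `counts` (sparse dgCMatrix, genes x cells) and `cells`
#'   (`cell_id`, `cell_type`, `stage`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  withr::with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mu <- matrix(cfg$baseline_mean, nrow = cfg$n_genes, ncol = length(cfg$cell_types),
               dimnames = list(genes, cfg$cell_types))
  for (ps in cfg$planted_sets) {
    mu[ps$genes, ps$cell_type] <- mu[ps$genes, ps$cell_type] * ps$fold
  }
  blocks <- list(); meta <- list(); cell_counter <- 0L
  for (st in cfg$stages) {
    for (tp in cfg$cell_types) {
      nc <- cfg$cells_per_type_stage
      mu_vec <- rep(mu[, tp], nc)
      draws <- if (cfg$dispersion == 0) {
        stats::rpois(length(mu_vec), mu_vec)
      } else {
        rnbinom(length(mu_vec), mu = mu_vec, size = 1 / cfg$dispersion)
      }
      blocks[[paste(st, tp)]] <- matrix(draws, nrow = cfg$n_genes, ncol = nc)
      meta[[paste(st, tp)]] <- data.table(
        cell_id = sprintf("C%06d", cell_counter + seq_len(nc)),
        cell_type = tp, stage = st)
      cell_counter <- cell_counter + nc
    }
  }
  cells <- rbindlist(meta)
  counts <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
  dimnames(counts) <- list(genes, cells$cell_id)
  list(counts = counts, cells = cells[])
}
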