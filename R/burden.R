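#' Collapse weighted variants to a per-individual gene burden matrix
#'
#' The burden of a gene in an individual is the maximum weight among the
#' qualifying (weight > 0) ultra-rare variants the individual carries in that
#' gene, or 0 when none is carried. Carrier status is binary, so het and hom
#' carriers of a variant receive the same burden.
#'
#' @param variants Variant table with `weight` assigned (one row per
#'   (variant, gene); run [select_canonical()] first).
#' @param carriers Long carrier table (`variant_id`, `sample_id`).
#' @param samples Character vector of all sample ids (defines row order; a
#'   sample carrying nothing still gets a row of zeros).
#' @return A sparse `dgCMatrix`, samples x genes, entries in \[0, 1\].
#' @export
collapse_burden <- function(variants, carriers, samples) {
  vdt <- as.data.table(variants)
  check_columns(vdt, c("variant_id", "gene", "weight"), "variant table")
  cdt <- as.data.table(carriers)
  unknown <- setdiff(unique(cdt$variant_id), vdt$variant_id)
  if (length(unknown) > 0L) {
    stop_config("carrier table references unknown variant(s), e.g. %s",
                paste(utils::head(unknown, 3L), collapse = ", "))
  }
  genes <- sort(unique(vdt$gene))
  qual <- vdt[weight > 0, .(variant_id, gene, weight)]
  hits <- qual[cdt, on = "variant_id", nomatch = NULL]
  hits <- hits[sample_id %in% samples]
  agg <- hits[, .(burden = max(weight)), by = .(sample_id, gene)]
  Matrix::sparseMatrix(
    i = match(agg$sample_id, samples),
    j = match(agg$gene, genes),
    x = agg$burden,
    dims = c(length(samples), length(genes)),
    dimnames = list(samples, genes)
  )
}

#' Genes eligible for the burden test
#'
#' A gene enters the test only if at least `min_qualified` distinct qualifying
#' variants (weight != 0) were observed in it across the cohort.
#'
#' @param variants Variant table with `weight` assigned.
#' @param min_qualified Minimum number of distinct qualified variants.
#' @return Character vector of gene symbols, sorted.
#' @export
eligible_genes <- function(variants, min_qualified = 10L) {
  dt <- as.data.table(variants)
  check_columns(dt, c("variant_id", "gene", "weight"), "variant table")
  counts <- dt[weight > 0, .(n = uniqueN(variant_id)), by = gene]
  sort(counts[n >= min_qualified, gene])
}

#' Count distinct qualified variants per gene
#'
#' @param variants Variant table with `weight` assigned.
#' @return Named integer vector, gene -> number of weight-nonzero variants.
#' @export
qualified_variant_counts <- function(variants) {
  dt <- as.data.table(variants)
  counts <- dt[weight > 0, .(n = uniqueN(variant_id)), by = gene]
  setNames(counts$n, counts$gene)
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Vectorized over tables `[a, b; c, d]`. The two-sided p-value is the sum of
#' hypergeometric point probabilities (at the observed margins) not exceeding
#' the probability of the observed table, the convention of
#' [stats::fisher.test()]; a relative tolerance of 1e-7 absorbs floating-point
#' ties.
#'
#' @param a,b,c,d Nonnegative integer vectors (recycled to a common length);
#'   rows are e.g. case/control, columns carrier/non-carrier.
#' @param midp If `TRUE`, apply the mid-p correction: only half the
#'   probability of the observed table (and of tables tied with it) is
#'   counted. The mid-p value is less conservative under discreteness and is
#'   never exactly 0 or 1 for a non-degenerate table.
#' @return Numeric vector of p-values in (0, 1\].
#' @export
fisher_exact_2x2 <- function(a, b, c, d, midp = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(is.na(cells))) stop_config("cell counts must be nonnegative integers")
  if (any(cells != floor(cells))) stop_config("cell counts must be integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  key <- paste(r1, r2, c1, sep = ",")
  p <- numeric(n)
  for (g in split(seq_len(n), key)) {
    i1 <- g[1L]
    p[g] <- fisher_p_by_k(r1[i1], r2[i1], c1[i1], midp = midp)[a[g] + 1L - max(0, c1[i1] - r2[i1])]
  }
  p
}

# Two-sided Fisher p for every achievable top-left cell value given margins:
# row totals r1 (cases) and r2 (controls), first-column total c1 (carriers).
# Returns the p-value vector over the support, indexed from k = max(0, c1-r2).
# A relative tolerance of 1e-7 absorbs floating-point ties (fisher.test
# convention); with midp, tied tables (including the observed one) count half.
fisher_p_by_k <- function(r1, r2, c1, midp = FALSE) {
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p <- vapply(seq_along(probs), function(i) {
    inc <- probs <= probs[i] * (1 + 1e-7)
    if (midp) {
      tie <- inc & probs >= probs[i] * (1 - 1e-7)
      sum(probs[inc]) - 0.5 * sum(probs[tie])
    } else {
      sum(probs[inc])
    }
  }, numeric(1L))
  pmin(p, 1)
}

#' Combine p-values with the aggregated Cauchy association test (ACAT)
#'
#' The statistic is `T = sum(w_i * tan((0.5 - p_i) * pi)) / sum(w_i)` and the
#' combined p-value is the upper-tail standard-Cauchy probability of `T`,
#' i.e. `0.5 - atan(T) / pi`. The combination is invariant to rescaling all
#' weights by a constant and equals `x` when every input is `x`. Inputs are
#' clipped to `[1e-16, 1 - 1e-16]` so the tangent stays finite.
#'
#' @param p Numeric vector of p-values in (0, 1).
#' @param weights Positive weights, recycled; equal by default.
#' @return A single combined p-value in (0, 1).
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (length(p) == 0L) stop_config("cannot combine an empty set of p-values")
  if (is.null(weights)) weights <- rep(1, length(p))
  weights <- rep_len(weights, length(p))
  if (any(weights <= 0)) stop_config("Cauchy combination weights must be positive")
  stat <- sum(weights * acat_tan_term(p)) / sum(weights)
  out <- pcauchy(stat, lower.tail = FALSE)
  min(max(out, .Machine$double.xmin), 1 - 1e-16)
}

# tan((0.5 - p) * pi) evaluated without cancellation: near the poles
# (p close to 0 or 1) the subtraction 0.5 - p rounds at 2^-53 and destroys
# relative precision, so the identity tan((0.5 - p) * pi) = 1 / tan(p * pi)
# is used there instead. Inputs are clipped to [1e-16, 1 - 1e-16].
acat_tan_term <- function(p) {
  p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
  out <- numeric(length(p))
  lo <- p <= 0.25
  hi <- p >= 0.75
  mid <- !lo & !hi
  out[mid] <- tanpi(0.5 - p[mid])
  out[lo] <- 1 / tanpi(p[lo])
  out[hi] <- -1 / tanpi(1 - p[hi])  # 1 - p is exact for p near 1
  out
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a*d) / (b*c)`; when any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to every cell of that table. Vectorized.
#'
#' @param a,b,c,d Nonnegative counts (a = case carriers, b = case
#'   non-carriers, c = control carriers, d = control non-carriers).
#' @return Numeric vector of odds-ratio estimates.
#' @export
odds_ratio <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
  (a * d) / (b * c)
}

# Shared internals ------------------------------------------------------------

# Cumulative carrier indicator matrices (samples x genes, numeric sparse),
# one per threshold: entry 1 iff burden >= t. Sorted ascending thresholds
# give nested indicators whose successive differences are the disjoint
# weight-class indicators.
threshold_indicators <- function(burden, thresholds) {
  lapply(sort(thresholds), function(t) {
    methods::as(burden >= t, "dMatrix")
  })
}

# Convert cumulative (burden >= t_j) per-gene counts to disjoint class counts
# [t_1, t_2), [t_2, t_3), ..., [t_J, Inf). Input genes x thresholds.
cumulative_to_class <- function(mat) {
  J <- ncol(mat)
  if (J == 1L) return(mat)
  cbind(mat[, -J, drop = FALSE] - mat[, -1L, drop = FALSE], mat[, J, drop = FALSE])
}

# Case labels as a 0/1 vector aligned with rownames(burden).
case_vector <- function(burden, labels) {
  ldt <- as.data.table(labels)
  check_columns(ldt, c("sample_id", "status"), "label table")
  status <- ldt$status[match(rownames(burden), ldt$sample_id)]
  if (anyNA(status)) stop_config("labels missing for %d sample(s) in the burden matrix",
                                 sum(is.na(status)))
  if (!any(status == "case") || !any(status == "control")) {
    stop_config("labels must contain at least one case and one control")
  }
  as.numeric(status == "case")
}

# The combined statistic: equal-weight Cauchy (ACAT) transform of the
# nested per-threshold mid-p Fisher p-values. `t_list` holds, per threshold
# j, the tangent term tanpi(0.5 - p_j(k_j)) as a vector over the cumulative
# case-carrier count k_j = 0..K_j; degenerate thresholds (K_j = 0 or N) are
# NULL and dropped. Returns a function of the cumulative counts.
acat_tangent_vectors <- function(K_cum, n_case, n_control, midp = TRUE) {
  n_total <- n_case + n_control
  lapply(K_cum, function(K) {
    if (K <= 0 || K >= n_total) return(NULL)
    pv <- fisher_p_by_k(n_case, n_control, K, midp = midp)
    lo <- max(0, K - n_control)
    # index by k = 0..K; below-support entries are impossible (prob 0)
    full <- rep(NA_real_, K + 1L)
    full[(lo:min(K, n_case)) + 1L] <- acat_tan_term(pv)
    full
  })
}

# Exact conditional null of the combined ACAT statistic for one gene.
#
# Under case/control label permutation the total carrier count of each
# disjoint weight class is fixed; the case share (k_a, k_b, k_c, ...) of the
# classes follows a multivariate hypergeometric law. The per-threshold
# (cumulative, nested) mid-p Fisher p-values and their Cauchy combination
# statistic T are deterministic functions of those counts, so the exact
# permutation p-value of T -- P(T >= T_obs), or the mid-p version
# P(T > T_obs) + 0.5 * P(T = T_obs) -- is computed by full enumeration.
# Returns a flat array over the class-count grid (index ka + kb*(Ka+1) + ...)
# holding the combined p for every achievable configuration (NA where the
# configuration has probability zero).
exact_combined_lookup <- function(K_cls, n_case, n_control, midp = TRUE) {
  J <- length(K_cls)
  n_total <- n_case + n_control
  rest <- n_total - sum(K_cls)
  dims <- K_cls + 1L
  grids <- lapply(seq_len(J), function(j) 0:K_cls[j])
  # log-binomial contribution of each class, combined by outer sums
  lchoose_cls <- lapply(seq_len(J), function(j) lchoose(K_cls[j], grids[[j]]))
  lp <- lchoose_cls[[1L]]
  ksum <- grids[[1L]]
  for (j in seq_len(J)[-1L]) {
    lp <- outer(lp, lchoose_cls[[j]], `+`)
    ksum <- outer(ksum, grids[[j]], `+`)
  }
  lp <- as.vector(lp); ksum <- as.vector(ksum)
  krest <- n_case - ksum
  ok <- krest >= 0 & krest <= rest
  logp <- rep(-Inf, length(lp))
  logp[ok] <- lp[ok] + lchoose(rest, krest[ok]) - lchoose(n_total, n_case)
  prob <- exp(logp)

  # cumulative counts k_J, k_{J-1}+k_J, ..., as vectors over the grid
  K_cum <- rev(cumsum(rev(K_cls)))
  tv <- acat_tangent_vectors(K_cum, n_case, n_control, midp = midp)
  # cumulative count j = sum of class counts j..J
  cum_counts <- vector("list", J)
  acc <- 0
  for (j in rev(seq_len(J))) {
    reps_before <- prod(dims[seq_len(j - 1L)])
    reps_after <- prod(dims[seq_len(J)[-seq_len(j)]])
    acc <- acc + rep(rep(grids[[j]], each = reps_before), times = reps_after)
    cum_counts[[j]] <- acc
  }
  tsum <- numeric(length(prob)); n_live <- 0L
  for (j in seq_len(J)) {
    if (is.null(tv[[j]])) next
    tsum <- tsum + tv[[j]][cum_counts[[j]] + 1L]
    n_live <- n_live + 1L
  }
  p_out <- rep(NA_real_, length(prob))
  feas <- which(ok & prob > 0)
  if (n_live == 0L || length(feas) == 0L) {
    p_out[ok] <- 1
    return(list(p = p_out, dims = dims))
  }
  stat <- tsum[feas] / n_live
  o <- order(stat, decreasing = TRUE)
  st <- stat[o]; pr <- prob[feas][o]
  # group exact ties of the statistic (tolerance absorbs float noise)
  tol <- 1e-9 * pmax(1, abs(st))
  new_grp <- c(TRUE, diff(st) < -tol[-1L])
  grp <- cumsum(new_grp)
  grp_p <- rowsum(pr, grp)[, 1L]
  cum_after <- cumsum(grp_p)
  cum_before <- cum_after - grp_p
  p_grp <- if (midp) cum_before + 0.5 * grp_p else cum_after
  pv <- numeric(length(st))
  pv[o] <- pmin(pmax(p_grp[grp], .Machine$double.xmin), 1)
  p_out[feas] <- pv
  list(p = p_out, dims = dims)
}

# Build per-gene exact-null lookups for all genes. `K_cls_mat` is genes x
# classes (disjoint class carrier totals). Genes whose enumeration grid
# exceeds `combo_limit` cells fall back to the analytic Cauchy CDF (flagged
# type "analytic"); for ultra-rare variation this is not normally reached.
build_exact_lookups <- function(K_cls_mat, n_case, n_control, midp = TRUE,
                                combo_limit = 3e5) {
  lapply(seq_len(nrow(K_cls_mat)), function(g) {
    K_cls <- as.integer(K_cls_mat[g, ])
    if (prod(K_cls + 1) > combo_limit) {
      K_cum <- rev(cumsum(rev(K_cls)))
      return(list(type = "analytic",
                  tv = acat_tangent_vectors(K_cum, n_case, n_control, midp = midp)))
    }
    c(list(type = "exact"), exact_combined_lookup(K_cls, n_case, n_control, midp = midp))
  })
}

# Flatten per-gene exact lookups into one vector with offsets and strides so
# a whole permutation resolves with a single indexed read per gene.
flatten_lookups <- function(lookups) {
  m <- length(lookups)
  J <- NULL
  exact <- vapply(lookups, function(lk) lk$type == "exact", logical(1L))
  sizes <- integer(m)
  for (g in which(exact)) sizes[g] <- length(lookups[[g]]$p)
  offset <- cumsum(c(0L, sizes[-m]))
  flat_p <- numeric(sum(sizes))
  stride <- NULL
  for (g in which(exact)) {
    lk <- lookups[[g]]
    if (is.null(stride)) stride <- matrix(0, m, length(lk$dims))
    flat_p[offset[g] + seq_len(sizes[g])] <- lk$p
    stride[g, ] <- cumprod(c(1L, lk$dims[-length(lk$dims)]))
  }
  list(p = flat_p, offset = offset, stride = stride, exact = exact,
       analytic = lookups[!exact], analytic_idx = which(!exact))
}

# Combined p for all genes given disjoint class case counts (genes x classes)
# and the flattened lookups.
combined_p_from_lookups <- function(k_cls_mat, flat) {
  m <- nrow(k_cls_mat)
  out <- rep(1, m)
  if (any(flat$exact)) {
    idx <- flat$offset + rowSums(k_cls_mat * flat$stride) + 1L
    ge <- which(flat$exact)
    out[ge] <- flat$p[idx[ge]]
  }
  for (i in seq_along(flat$analytic_idx)) {
    g <- flat$analytic_idx[i]
    lk <- flat$analytic[[i]]
    tsum <- 0; n_live <- 0L
    kcum <- rev(cumsum(rev(k_cls_mat[g, ])))
    for (j in seq_along(lk$tv)) {
      if (is.null(lk$tv[[j]])) next
      tsum <- tsum + lk$tv[[j]][kcum[j] + 1L]
      n_live <- n_live + 1L
    }
    out[g] <- if (n_live == 0L) 1 else
      min(max(pcauchy(tsum / n_live, lower.tail = FALSE), .Machine$double.xmin), 1)
  }
  out
}

#' Gene-based weighted burden test
#'
#' Each sorted threshold `t_j` dichotomizes the per-individual burden (the
#' maximum carried variant weight) into a nested 2x2 case/control x
#' (burden >= t_j)/(burden < t_j) table; the default thresholds
#' `{1e-8, 0.5, 1}` realize the carrier tests at burden > 0, >= 0.5 and = 1.
#' Each table is scored with the two-sided mid-p Fisher exact test and the
#' per-threshold p-values are combined into the equal-weight aggregated
#' Cauchy association (ACAT) statistic `T = mean(tan((0.5 - p_j) * pi))`.
#'
#' The reported `p_combined` is the *exact conditional (permutation) tail
#' probability* of `T`: given the burden matrix, the carrier totals of the
#' disjoint weight classes `[t_1, t_2), ..., [t_J, Inf)` are fixed under
#' case/control label permutation and the case shares follow a multivariate
#' hypergeometric law, so `P(T >= T_obs)` is computed by full enumeration
#' per gene. This keeps the combination calibrated -- the analytic Cauchy
#' CDF is exact only for independent or perfectly dependent components,
#' and the nested threshold tables are strongly dependent. With
#' `midp = TRUE` (default) the tail is mid-p corrected
#' (`P(T > T_obs) + 0.5 * P(T = T_obs)`), which centers the null
#' distribution of `p_combined` despite its discreteness; `midp = FALSE`
#' gives the classical conservative exact tail, and then a gene in which
#' every threshold yields the identical table reports exactly the single
#' two-sided Fisher p of that table. Degenerate thresholds (no carriers, or
#' everyone a carrier) are uninformative and are dropped; a gene with no
#' carriers at all reports `p_combined = 1`. Carrier counts and the odds
#' ratio are reported at burden > 0.
#'
#' @param burden Burden matrix from [collapse_burden()] (samples x genes).
#' @param labels Label table (`sample_id`, `status`).
#' @param thresholds Numeric dichotomization thresholds in (0, 1\].
#' @param n_qualified Optional named vector (gene -> qualified variant count)
#'   used to fill the `n_qualified_variants` column.
#' @param midp Use the mid-p corrections (recommended; see Details).
#' @return A `data.table` with one row per gene: `gene`,
#'   `n_qualified_variants`, `case_carriers`, `control_carriers`,
#'   `odds_ratio`, `p_combined`.
#' @export
gene_burden_test <- function(burden, labels, thresholds = c(1e-8, 0.5, 1),
                             n_qualified = NULL, midp = TRUE) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  case01 <- case_vector(burden, labels)
  n_case <- sum(case01); n_control <- length(case01) - n_case
  ind <- threshold_indicators(burden, thresholds)
  K_mat <- vapply(ind, Matrix::colSums, numeric(ncol(burden)))
  k_mat <- vapply(ind, function(m) as.numeric(Matrix::crossprod(m, case01)),
                  numeric(ncol(burden)))
  if (ncol(burden) == 1L) { K_mat <- rbind(K_mat); k_mat <- rbind(k_mat) }
  lookups <- build_exact_lookups(cumulative_to_class(K_mat), n_case, n_control,
                                 midp = midp)
  p_comb <- combined_p_from_lookups(cumulative_to_class(k_mat),
                                    flatten_lookups(lookups))
  a <- k_mat[, 1L]; cc <- K_mat[, 1L] - a
  res <- data.table(
    gene = colnames(burden),
    n_qualified_variants = if (is.null(n_qualified)) NA_integer_ else
      as.integer(n_qualified[colnames(burden)]),
    case_carriers = as.integer(a),
    control_carriers = as.integer(cc),
    odds_ratio = odds_ratio(a, n_case - a, cc, n_control - cc),
    p_combined = p_comb
  )
  res[]
}

#' Permutation null of the burden test p-value order statistics
#'
#' Case/control labels are shuffled (preserving the case count), the full
#' per-gene burden test is re-run for each permutation, and the expected
#' p-value at rank i is the mean over permutations of the i-th order
#' statistic. Used to draw calibration QQ plots against an empirical null.
#'
#' @param burden Burden matrix (samples x genes).
#' @param labels Label table.
#' @param thresholds Weight-class boundaries, as in [gene_burden_test()].
#' @param n_perm Number of label permutations.
#' @param seed Integer seed; the permutation stream is reproducible.
#' @param perm_fun Permutation generator `function(case01)` returning a
#'   permuted 0/1 vector; defaults to a uniform shuffle. Exposed for
#'   degenerate-case testing.
#' @param midp Use mid-p Fisher components, as in [gene_burden_test()];
#'   must match the setting used for the observed p-values.
#' @return A `data.table` with columns `rank`, `expected_p`.
#' @export
permute_expected_pvalues <- function(burden, labels, thresholds = c(1e-8, 0.5, 1),
                                     n_perm = 1000L, seed = 1L,
                                     perm_fun = NULL, midp = TRUE) {
  stopifnot(n_perm >= 1L)
  case01 <- case_vector(burden, labels)
  n_case <- sum(case01); n_control <- length(case01) - n_case
  ind <- threshold_indicators(burden, thresholds)
  K_mat <- vapply(ind, Matrix::colSums, numeric(ncol(burden)))
  if (ncol(burden) == 1L) K_mat <- rbind(K_mat)
  flat <- flatten_lookups(build_exact_lookups(cumulative_to_class(K_mat),
                                              n_case, n_control, midp = midp))
  m <- ncol(burden)
  acc <- numeric(m)
  if (is.null(perm_fun)) perm_fun <- function(x) sample(x)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- perm_fun(case01)
      k_mat <- vapply(ind, function(mm) as.numeric(Matrix::crossprod(mm, perm)),
                      numeric(m))
      if (m == 1L) k_mat <- rbind(k_mat)
      p <- combined_p_from_lookups(cumulative_to_class(k_mat), flat)
      acc <- acc + sort(p)
    }
  })
  data.table(rank = seq_len(m), expected_p = acc / n_perm)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower = FALSE)) / qchisq(0.5, 1)`.
#' Values near 1 indicate a calibrated test; values well above 1 indicate
#' inflation.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return The inflation factor lambda.
#' @export
genomic_inflation_lambda <- function(p) {
  if (length(p) == 0L) stop_config("cannot compute lambda from zero p-values")
  stopifnot(all(p > 0 & p <= 1))
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Storey-Tibshirani q-values
#'
#' The null proportion is estimated from the p-value histogram above a single
#' tuning point `lambda0`: `pi0 = min(1, mean(p > lambda0) / (1 - lambda0))`,
#' falling back to the conservative `pi0 = 1` (Benjamini-Hochberg equivalent)
#' when the estimate is not positive. The q-value of the i-th smallest p is
#' `min over j >= i of pi0 * m * p_(j) / j`, which is monotone along the
#' sorted p-values and never exceeds 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda0 Tuning parameter in (0, 1) for the pi0 estimate.
#' @return Numeric vector of q-values in the original order of `p`.
#' @export
qvalues_storey <- function(p, lambda0 = 0.5) {
  if (any(p < 0 | p > 1 | is.na(p))) stop_config("p-values must lie in [0, 1]")
  stopifnot(lambda0 > 0, lambda0 < 1)
  m <- length(p)
  pi0 <- mean(p > lambda0) / (1 - lambda0)
  if (pi0 <= 0) pi0 <- 1
  pi0 <- min(pi0, 1)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}
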