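#' Read a MatrixMarket single-cell count matrix with cell metadata
#'
#' Expects `matrix.mtx` (genes x cells), `genes.tsv` (one gene symbol per
#' line, or a first column of symbols) and `cells.tsv` (columns `cell_id`,
#' `cell_type`, `stage`).
#'
#' @param mtx,genes,cells Paths to the three files.
#' @return List with `counts` (sparse dgCMatrix, genes x cells, dimnames set)
#'   and `cells` (data.table of cell metadata).
#' @export
read_expression_mtx <- function(mtx, genes, cells) {
  for (p in c(mtx, genes, cells)) {
    if (!file.exists(p)) stop_config("expression input not found: %s", p)
  }
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  gene_ids <- fread(genes, header = FALSE)[[1L]]
  meta <- fread(cells)
  check_columns(meta, c("cell_id", "cell_type", "stage"), sprintf("cell table '%s'", cells))
  if (nrow(counts) != length(gene_ids)) {
    stop_format("gene file lists %d genes but matrix has %d rows",
                length(gene_ids), nrow(counts))
  }
  if (ncol(counts) != nrow(meta)) {
    stop_format("cell table lists %d cells but matrix has %d columns",
                nrow(meta), ncol(counts))
  }
  dimnames(counts) <- list(gene_ids, meta$cell_id)
  list(counts = counts, cells = meta[])
}

#' Cell-type specificity matrix from labeled single-cell counts
#'
#' Counts are depth-normalized per cell (divided by the cell's total and
#' rescaled by the median cell total), averaged per cell type within the
#' requested developmental stage, and each gene's per-type means are divided
#' by their sum across the stage's cell types. A gene's specificity row thus
#' sums to 1 within the stage; genes with zero mean everywhere get 0 and are
#' flagged unexpressed (excluded from bootstrap backgrounds). Specificity is
#' computed per stage independently; pass `stage = NULL` to get the
#' column-concatenated matrix over all stages.
#'
#' @param counts Count matrix (genes x cells), dense or sparse, with
#'   dimnames.
#' @param cells Cell metadata (`cell_id`, `cell_type`, `stage`) aligned with
#'   `colnames(counts)`.
#' @param stage A single stage label, or `NULL` for all stages.
#' @return Numeric matrix, genes x groups. Column names are `cell_type` for a
#'   single stage and `cell_type|stage` otherwise; attributes `groups`
#'   (data.frame: column, cell_type, stage) and `expressed` (named logical
#'   per gene, any stage) describe it.
#' @export
compute_specificity <- function(counts, cells, stage = NULL) {
  meta <- as.data.table(cells)
  check_columns(meta, c("cell_id", "cell_type", "stage"), "cell metadata")
  if (is.null(colnames(counts)) || !all(meta$cell_id %in% colnames(counts))) {
    stop_config("cell metadata does not match the count matrix columns")
  }
  stages <- if (is.null(stage)) sort(unique(meta$stage)) else stage
  if (!all(stages %in% meta$stage)) {
    stop_config("unknown stage(s): %s", paste(setdiff(stages, meta$stage), collapse = ", "))
  }
  blocks <- list(); groups <- list()
  for (st in stages) {
    sub <- meta[meta$stage == st, ]
    types <- sort(unique(sub$cell_type))
    if (length(types) < 2L) {
      stop_config("stage '%s' has a single cell type; specificity needs at least two", st)
    }
    cm <- counts[, sub$cell_id, drop = FALSE]
    depth <- Matrix::colSums(cm)
    if (any(depth == 0)) depth[depth == 0] <- 1
    norm <- cm %*% Matrix::Diagonal(x = median(depth) / depth)
    means <- vapply(types, function(tp) {
      idx <- which(sub$cell_type == tp)
      as.numeric(Matrix::rowSums(norm[, idx, drop = FALSE])) / length(idx)
    }, numeric(nrow(counts)))
    tot <- rowSums(means)
    spec <- means / ifelse(tot > 0, tot, 1)
    spec[tot == 0, ] <- 0
    cn <- if (is.null(stage)) paste(types, st, sep = "|") else types
    colnames(spec) <- cn
    blocks[[st]] <- spec
    groups[[st]] <- data.frame(column = cn, cell_type = types, stage = st,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(counts)
  attr(out, "groups") <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  attr(out, "expressed") <- setNames(rowSums(out) > 0, rownames(counts))
  out
}

#' Expression-weighted cell-type enrichment bootstrap
#'
#' Tests whether a target gene set is more specifically expressed in each
#' (cell type, stage) group than random gene sets of the same size. The
#' observed statistic per group is the sum of the target genes' specificity;
#' each bootstrap draws the same number of genes uniformly without
#' replacement from the expressed background and recomputes the sums. The
#' one-sided p-value is `(1 + #{bootstrap >= observed}) / (1 + n_boot)`
#' (add-one corrected, so never 0), and the z-score is the observed sum
#' standardized by the bootstrap moments. Groups with zero bootstrap
#' variance report `z = NA` and `p = 1`.
#'
#' @param target Character vector of target genes.
#' @param spec Specificity matrix from [compute_specificity()].
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed for the bootstrap stream.
#' @return `data.table`: `stage, cell_type, n_target, observed, boot_mean,
#'   boot_sd, z, p`.
#' @export
ewce_bootstrap <- function(target, spec, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  expressed <- attr(spec, "expressed")
  if (is.null(expressed)) expressed <- setNames(rowSums(spec) > 0, rownames(spec))
  bg <- rownames(spec)[expressed]
  target_in <- intersect(unique(target), bg)
  if (length(target_in) == 0L) {
    stop_config("no target gene is present (and expressed) in the specificity matrix")
  }
  nt <- length(target_in)
  observed <- colSums(spec[target_in, , drop = FALSE])
  boot_sums <- withr::with_seed(seed, {
    idx <- replicate(n_boot, sample(bg, nt, replace = FALSE))
    sampled <- spec[as.vector(idx), , drop = FALSE]
    rs <- rowsum(sampled, group = rep(seq_len(n_boot), each = nt), reorder = FALSE)
    rs
  })
  boot_mean <- colMeans(boot_sums)
  boot_sd <- apply(boot_sums, 2L, stats::sd)
  # ">= observed" up to float noise from summing the same specificities in a
  # different order (a degenerate target equal to the whole background must
  # tie every bootstrap)
  exceed <- colSums(sweep(boot_sums, 2L, observed - 1e-9, `>=`))
  p <- (1 + exceed) / (1 + n_boot)
  z <- ifelse(boot_sd > 0, (observed - boot_mean) / boot_sd, NA_real_)
  p[boot_sd == 0] <- 1
  grp <- attr(spec, "groups")
  if (is.null(grp)) {
    grp <- data.frame(column = colnames(spec), cell_type = colnames(spec),
                      stage = NA_character_)
  }
  out <- data.table(
    stage = grp$stage[match(colnames(spec), grp$column)],
    cell_type = grp$cell_type[match(colnames(spec), grp$column)],
    n_target = nt,
    observed = as.numeric(observed),
    boot_mean = as.numeric(boot_mean),
    boot_sd = as.numeric(boot_sd),
    z = as.numeric(z),
    p = as.numeric(p)
  )
  out[]
}
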