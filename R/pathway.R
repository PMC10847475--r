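#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set id, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set id -> member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_config("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param genesets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set ids).
#' @export
write_gmt <- function(genesets, path, descriptions = NULL) {
  if (is.null(names(genesets)) || any(names(genesets) == "")) {
    stop_config("gene sets must be a named list")
  }
  if (is.null(descriptions)) descriptions <- names(genesets)
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the hit list overlaps it more than
#' expected by chance within the gene universe. With `N` universe genes, `K`
#' of them in the set, `n` hits and `k` hits inside the set, the one-sided
#' upper-tail p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, and
#' the fold enrichment is `(k/n) / (K/N)` — the hit rate inside the set
#' relative to the set's share of the universe. Set members outside the
#' universe are dropped before testing; hits outside the universe raise an
#' error. No multiple-testing adjustment is applied by default (an optional
#' Benjamini-Hochberg column can be requested).
#'
#' @param hits Character vector of hit genes (must lie in `universe`).
#' @param genesets Named list of character vectors, or a GMT path.
#' @param universe Character vector: the tested gene universe (e.g. all genes
#'   that entered the burden test).
#' @param adjust If `TRUE`, append a Benjamini-Hochberg `p_adjust` column.
#' @return `data.table` sorted by p: `pathway_id, k, K, n, N, fold, p`.
#' @export
hypergeometric_enrichment <- function(hits, genesets, universe, adjust = FALSE) {
  if (is.character(genesets) && length(genesets) == 1L) genesets <- read_gmt(genesets)
  universe <- unique(universe)
  hits <- unique(hits)
  if (length(universe) == 0L) stop_config("gene universe is empty")
  if (length(hits) == 0L) stop_config("hit list is empty")
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    stop_config("%d hit gene(s) outside the universe, e.g. %s", length(outside),
                paste(utils::head(outside, 3L), collapse = ", "))
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(genesets), function(id) {
    set <- intersect(unique(genesets[[id]]), universe)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.table(pathway_id = id, k = k, K = K, n = n, N = N,
               fold = if (K == 0L) 0 else (k / n) / (K / N),
               p = min(p, 1))
  })
  out <- rbindlist(rows)
  setorder(out, p, pathway_id)
  if (adjust) out[, p_adjust := stats::p.adjust(p, method = "BH")]
  out[]
}
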