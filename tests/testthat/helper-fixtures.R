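# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

make_variants <- function(...) {
  rows <- list(...)
  defaults <- list(chrom = "1", pos = 100L, ref = "A", alt = "T",
                   transcript = "ENST000001", canonical = TRUE,
                   consequence = "missense", damaging_prediction_count = 0L,
                   gnomad_popmax_af = 0, cohort_ac = 1L)
  data.table::rbindlist(lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(defaults, rows[[i]])
    r$variant_id <- r$variant_id %||% sprintf("v%03d", i)
    r$gene <- r$gene %||% "GENE1"
    data.table::as.data.table(r)
  }), use.names = TRUE, fill = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_tmp <- function(dt, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  data.table::fwrite(dt, path, sep = "\t")
  path
}

# Independent two-sided Fisher oracle: direct summation of hypergeometric
# point masses computed from log-binomial coefficients (lchoose route,
# independent of the package's dhyper-based implementation).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  probs <- exp(logp)
  pobs <- probs[x == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric oracle by direct summation.
hyper_upper_oracle <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# A small burden matrix with explicit entries.
burden_matrix <- function(entries, samples, genes) {
  m <- Matrix::sparseMatrix(i = match(entries$sample, samples),
                            j = match(entries$gene, genes),
                            x = entries$burden,
                            dims = c(length(samples), length(genes)),
                            dimnames = list(samples, genes))
  m
}

case_control_labels <- function(n_case, n_control) {
  data.frame(sample_id = sprintf("S%04d", seq_len(n_case + n_control)),
             status = rep(c("case", "control"), c(n_case, n_control)))
}
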