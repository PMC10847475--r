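#' Read an annotated variant table
#'
#' The table is tab-separated with header columns `variant_id, chrom, pos,
#' ref, alt, gene, transcript, canonical, consequence,
#' damaging_prediction_count, gnomad_popmax_af, cohort_ac`. `cohort_ac` is
#' optional and, when absent, is computed later from the carrier table. A
#' missing (empty or NA) `gnomad_popmax_af` is interpreted as 0: a variant
#' absent from the reference population is novel, hence maximally rare.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` of typed variant records, one row per
#'   (variant, transcript) annotation.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop_config("variant table not found: %s", path)
  required <- c("variant_id", "chrom", "pos", "ref", "alt", "gene", "transcript",
                "canonical", "consequence", "damaging_prediction_count",
                "gnomad_popmax_af")
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"),
              na.strings = c("", "NA"))
  check_columns(dt, required, sprintf("variant table '%s'", path))
  as_variant_table(dt, what = sprintf("variant table '%s'", path))
}

# Validate/coerce a raw variant table; errors cite 1-based data row numbers.
as_variant_table <- function(dt, what = "variant table") {
  dt <- as.data.table(dt)
  coerce_num <- function(col, integerish = FALSE, allow_na = FALSE) {
    raw <- dt[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !is.na(raw)
    if (!allow_na) bad <- bad | (is.na(raw) & !allow_na & col %in% c("pos"))
    if (any(bad)) {
      stop_format("%s: unparseable '%s' in row(s) %s", what, col,
                  paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    if (integerish) as.integer(val) else val
  }
  dt[, pos := coerce_num("pos", integerish = TRUE)]
  if (anyNA(dt$pos)) {
    stop_format("%s: unparseable 'pos' in row(s) %s", what,
                paste(utils::head(which(is.na(dt$pos)), 5L), collapse = ", "))
  }
  dt[, damaging_prediction_count := coerce_num("damaging_prediction_count",
                                               integerish = TRUE, allow_na = TRUE)]
  dt[is.na(damaging_prediction_count), damaging_prediction_count := 0L]
  dt[, gnomad_popmax_af := coerce_num("gnomad_popmax_af", allow_na = TRUE)]
  dt[is.na(gnomad_popmax_af), gnomad_popmax_af := 0]
  if (any(dt$gnomad_popmax_af < 0 | dt$gnomad_popmax_af > 1)) {
    stop_format("%s: gnomad_popmax_af outside [0, 1]", what)
  }
  if (is.character(dt$canonical)) {
    dt[, canonical := toupper(canonical) %in% c("TRUE", "T", "YES", "1")]
  } else {
    dt[, canonical := as.logical(canonical)]
  }
  unknown <- setdiff(unique(dt$consequence), CONSEQUENCE_CLASSES)
  if (length(unknown) > 0L) {
    stop_format("%s: unknown consequence class(es): %s", what,
                paste(unknown, collapse = ", "))
  }
  if ("cohort_ac" %in% names(dt)) {
    dt[, cohort_ac := coerce_num("cohort_ac", integerish = TRUE, allow_na = TRUE)]
  }
  dt[]
}

#' Read a long carrier table
#'
#' Two tab-separated columns, `variant_id` and `sample_id`; one row per
#' carried variant per individual. Heterozygous and homozygous carriers are
#' recorded identically (carrier status is binary).
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with columns `variant_id`, `sample_id`.
#' @export
read_carrier_table <- function(path) {
  if (!file.exists(path)) stop_config("carrier table not found: %s", path)
  dt <- fread(path, sep = "\t")
  check_columns(dt, c("variant_id", "sample_id"), sprintf("carrier table '%s'", path))
  unique(dt[, .(variant_id = as.character(variant_id), sample_id = as.character(sample_id))])
}

#' Read a case/control label table
#'
#' Tab-separated columns `sample_id` and `status`, with status `case` or
#' `control`.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with columns `sample_id`, `status`.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop_config("label table not found: %s", path)
  dt <- fread(path, sep = "\t")
  check_columns(dt, c("sample_id", "status"), sprintf("label table '%s'", path))
  bad <- setdiff(unique(dt$status), c("case", "control"))
  if (length(bad) > 0L) {
    stop_format("label table '%s': status must be 'case' or 'control' (found: %s)",
                path, paste(bad, collapse = ", "))
  }
  dt[, .(sample_id = as.character(sample_id), status = as.character(status))]
}

#' Read genotype carriers from a VCF
#'
#' Parses a VCF v4.x file (plain text or bgzipped), splits multi-allelic
#' sites into one biallelic record per alternate allele, and returns site
#' records keyed by `variant_id = chrom-pos-ref-alt` together with a long
#' carrier table. Any genotype containing the alternate allele (het or hom)
#' makes the sample a carrier. Functional annotation is expected separately
#' as a TSV keyed on the same `variant_id`.
#'
#' @param path Path to a VCF file with GT fields.
#' @return A list with elements `sites` (data.table: variant_id, chrom, pos,
#'   ref, alt) and `carriers` (data.table: variant_id, sample_id).
#' @export
read_vcf_cohort <- function(path) {
  if (!file.exists(path)) stop_config("VCF not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || !startsWith(lines[1L], "#CHROM")) {
    stop_format("'%s' does not look like a VCF (missing #CHROM header)", path)
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  samples <- header[-(1:9)]
  if (length(samples) == 0L) stop_format("VCF '%s' carries no sample genotypes", path)
  body <- lines[-1L]
  sites_list <- vector("list", length(body))
  carr_list <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop_format("VCF '%s': record %d lacks a GT field", path, i)
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1L), gt_idx)
    alleles <- strsplit(gts, "[/|]")
    ids <- paste(f[1L], f[2L], f[4L], alts, sep = "-")
    sites_list[[i]] <- data.table(variant_id = ids, chrom = f[1L],
                                  pos = as.integer(f[2L]), ref = f[4L], alt = alts)
    hits <- lapply(seq_along(alts), function(k) {
      carrier <- vapply(alleles, function(a) as.character(k) %in% a, logical(1L))
      if (any(carrier)) data.table(variant_id = ids[k], sample_id = samples[carrier])
    })
    carr_list[[i]] <- rbindlist(hits)
  }
  list(sites = rbindlist(sites_list), carriers = unique(rbindlist(carr_list)))
}

#' Select one transcript annotation per (variant, gene)
#'
#' When a variant is annotated on several transcripts of the same gene, the
#' transcript flagged canonical is kept. Ties among several canonical rows go
#' to the lexicographically smallest transcript identifier; if no row is
#' flagged canonical, the most severe consequence wins
#' (pLoF > inframe_indel > missense > synonymous > other), then again the
#' smallest transcript identifier.
#'
#' @param variants Variant table (one row per annotation).
#' @return Variant table with exactly one row per (variant_id, gene).
#' @export
select_canonical <- function(variants) {
  dt <- as.data.table(variants)
  sev <- match(dt$consequence, CONSEQUENCE_CLASSES)
  dt[, `:=`(.canon_rank = !canonical, .sev_rank = sev)]
  setorder(dt, variant_id, gene, .canon_rank, .sev_rank, transcript)
  out <- dt[, .SD[1L], by = .(variant_id, gene)]
  out[, c(".canon_rank", ".sev_rank") := NULL]
  out[]
}

#' Compute cohort allele counts from a carrier table
#'
#' Each carrier contributes one counted allele (carrier status is binary,
#' so homozygotes are not double-counted).
#'
#' @param variants Variant table.
#' @param carriers Long carrier table (`variant_id`, `sample_id`).
#' @return Variant table with a `cohort_ac` column.
#' @export
add_cohort_ac <- function(variants, carriers) {
  dt <- as.data.table(variants)
  ac <- as.data.table(carriers)[, .(cohort_ac = .N), by = variant_id]
  if ("cohort_ac" %in% names(dt)) dt[, cohort_ac := NULL]
  dt[ac, cohort_ac := i.cohort_ac, on = "variant_id"]
  dt[is.na(cohort_ac), cohort_ac := 0L]
  dt[]
}

#' Retain ultra-rare variants
#'
#' A variant is ultra-rare when its gnomAD control population-max allele
#' frequency is at most `popmax_max` (default 0.01%) and its cohort allele
#' count is at most `ac_max` (default 3). Both thresholds are inclusive, and
#' a missing popmax frequency counts as 0. The filter is idempotent.
#'
#' @param variants Variant table with `gnomad_popmax_af` and `cohort_ac`.
#' @param popmax_max Maximum gnomAD popmax allele frequency (inclusive).
#' @param ac_max Maximum cohort allele count (inclusive).
#' @return The retained subset of `variants`.
#' @export
filter_urv <- function(variants, popmax_max = 1e-4, ac_max = 3L) {
  stopifnot(popmax_max >= 0, ac_max >= 0)
  dt <- as.data.table(variants)
  check_columns(dt, c("gnomad_popmax_af", "cohort_ac"), "variant table")
  af <- dt$gnomad_popmax_af
  af[is.na(af)] <- 0
  dt[af <= popmax_max & cohort_ac <= ac_max]
}

#' Assign collapsing weights to variants
#'
#' Each variant gets a weight in \[0, 1\] determined solely by its consequence
#' class and, for tiered classes, its damaging-prediction count. Variants
#' with weight 0 are not qualified and never contribute to gene burdens.
#'
#' @param variants Variant table.
#' @param table A [weight_table()], built-in table name, or YAML path.
#' @return Variant table with a `weight` column.
#' @export
assign_weights <- function(variants, table = default_weight_table("functional")) {
  table <- resolve_weight_table(table)
  dt <- as.data.table(variants)
  unknown <- setdiff(unique(dt$consequence), names(table$classes))
  if (length(unknown) > 0L) {
    stop_config("weight table '%s' has no entry for class(es): %s",
                table$name, paste(unknown, collapse = ", "))
  }
  w <- numeric(nrow(dt))
  for (cls in unique(dt$consequence)) {
    idx <- which(dt$consequence == cls)
    w[idx] <- class_weight(table$classes[[cls]], dt$damaging_prediction_count[idx])
  }
  dt[, weight := w]
  dt[]
}
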