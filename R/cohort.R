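#' Summarize a proband cohort table
#'
#' Produces descriptive counts and percentages in the style of a clinical
#' cohort table: sex, malformation class (failure_of_formation,
#' segmentation_defect, mixed), any logical anomaly-flag columns, and the
#' molecular diagnostic yield (`diagnosed` column). Percentages are
#' count / total x 100, rounded half-up to one decimal, matching printed
#' clinical-table precision.
#'
#' @param records Proband data.frame with at least `proband_id`; recognized
#'   columns: `sex` (label, "female"/"male"), `malformation_class`,
#'   `diagnosed` (logical), plus arbitrary logical flag columns.
#' @return `data.table` with columns `category`, `group`, `count`, `percent`.
#' @export
summarize_cohort <- function(records) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) stop_config("cannot summarize an empty cohort")
  total <- nrow(dt)
  pct <- function(k) round_half_up(k / total * 100, 1)
  rows <- list(data.table(category = "cohort", group = "n_probands",
                          count = total, percent = 100))
  if ("sex" %in% names(dt)) {
    k <- sum(dt$sex == "female")
    rows <- c(rows, list(data.table(category = "sex", group = "female",
                                    count = k, percent = pct(k))))
  }
  if ("malformation_class" %in% names(dt)) {
    known <- c("failure_of_formation", "segmentation_defect", "mixed")
    bad <- setdiff(unique(dt$malformation_class), known)
    if (length(bad) > 0L) {
      stop_format("unknown malformation_class value(s): %s", paste(bad, collapse = ", "))
    }
    for (cls in known) {
      k <- sum(dt$malformation_class == cls)
      rows <- c(rows, list(data.table(category = "malformation_class", group = cls,
                                      count = k, percent = pct(k))))
    }
  }
  flag_cols <- names(dt)[vapply(dt, is.logical, logical(1L))]
  flag_cols <- setdiff(flag_cols, "diagnosed")
  for (fc in flag_cols) {
    k <- sum(dt[[fc]], na.rm = TRUE)
    rows <- c(rows, list(data.table(category = "anomaly", group = fc,
                                    count = k, percent = pct(k))))
  }
  if ("diagnosed" %in% names(dt)) {
    k <- sum(dt$diagnosed, na.rm = TRUE)
    rows <- c(rows, list(data.table(category = "diagnostic_yield", group = "diagnosed",
                                    count = k, percent = pct(k))))
  }
  rbindlist(rows)
}

#' Simulate a proband record table
#'
#' Deterministically (given `seed`) builds a per-proband table whose marginal
#' counts equal the requested values; used to exercise [summarize_cohort()]
#' on cohorts with a known composition. Defaults emulate a large surgical
#' congenital-vertebral-malformation cohort: 873 probands, 448 female,
#' malformation classes 301/123/449, 105 molecularly diagnosed, and typical
#' intraspinal/extra-spinal anomaly frequencies.
#'
#' @param n Number of probands.
#' @param n_female Number of females.
#' @param class_counts Named counts over the three malformation classes
#'   (must sum to `n`).
#' @param n_diagnosed Number of probands with a molecular diagnosis.
#' @param anomaly_counts Named counts of logical anomaly flags.
#' @param seed Integer seed controlling which probands get which attribute.
#' @return Proband `data.table` suitable for [summarize_cohort()].
#' @export
simulate_probands <- function(n = 873L,
                              n_female = 448L,
                              class_counts = c(failure_of_formation = 301L,
                                               segmentation_defect = 123L,
                                               mixed = 449L),
                              n_diagnosed = 105L,
                              anomaly_counts = c(diastematomyelia = 135L,
                                                 syringomyelia = 81L,
                                                 tethered_cord = 47L,
                                                 cardiovascular = 95L,
                                                 genitourinary = 65L,
                                                 digestive = 62L),
                              seed = 1L) {
  if (sum(class_counts) != n) {
    stop_config("malformation class counts sum to %d, not n = %d", sum(class_counts), n)
  }
  if (n_female > n || n_diagnosed > n || any(anomaly_counts > n)) {
    stop_config("attribute counts cannot exceed the cohort size")
  }
  withr::with_seed(seed, {
    dt <- data.table(
      proband_id = sprintf("P%04d", seq_len(n)),
      sex = sample(rep(c("female", "male"), c(n_female, n - n_female))),
      age_at_diagnosis = round(pmax(0, stats::rnorm(n, mean = 5.1, sd = 6.0)), 1),
      malformation_class = sample(rep(names(class_counts), class_counts)),
      diagnosed = sample(rep(c(TRUE, FALSE), c(n_diagnosed, n - n_diagnosed)))
    )
    for (fc in names(anomaly_counts)) {
      dt[, (fc) := sample(rep(c(TRUE, FALSE), c(anomaly_counts[[fc]], n - anomaly_counts[[fc]])))]
    }
    dt[]
  })
}
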