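#' Variant consequence classes, ordered from most to least severe
#'
#' Severity order used when breaking ties between transcript annotations that
#' lack a canonical flag: predicted loss-of-function first, then inframe
#' indels, missense, synonymous, and everything else.
#'
#' @export
CONSEQUENCE_CLASSES <- c("pLoF", "inframe_indel", "missense", "synonymous", "other")

#' Construct a variant weight table
#'
#' A weight table maps a variant's consequence class (and, for missense
#' variants, the number of concordant in-silico damaging predictions) to a
#' weight in \[0, 1\]. Variants with weight 0 are "not qualified" and are
#' ignored by the collapsing burden test; the per-individual gene burden is
#' the maximum weight among carried qualifying variants.
#'
#' @param classes Named list. Each consequence class maps either to a single
#'   numeric weight, or (for prediction-tiered classes such as missense) to a
#'   data.frame with columns `min_predictions` and `weight`: a variant gets
#'   the weight of the tier with the largest `min_predictions` not exceeding
#'   its damaging-prediction count.
#' @param name Label for the table.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(classes, name = "custom") {
  stopifnot(is.list(classes), length(classes) > 0L)
  for (cls in names(classes)) {
    entry <- classes[[cls]]
    if (is.data.frame(entry)) {
      check_columns(entry, c("min_predictions", "weight"), sprintf("tier table for class '%s'", cls))
      w <- entry$weight
    } else {
      if (!is.numeric(entry) || length(entry) != 1L) {
        stop_config("weight for class '%s' must be a single number or a tier data.frame", cls)
      }
      w <- entry
    }
    if (any(w < 0 | w > 1)) stop_config("weights for class '%s' fall outside [0, 1]", cls)
  }
  structure(list(name = name, classes = classes), class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table '%s'>\n", x$name))
  for (cls in names(x$classes)) {
    entry <- x$classes[[cls]]
    if (is.data.frame(entry)) {
      tiers <- paste(sprintf(">=%d preds: %.2g", entry$min_predictions, entry$weight),
                     collapse = "; ")
      cat(sprintf("  %-14s %s\n", cls, tiers))
    } else {
      cat(sprintf("  %-14s %.2g\n", cls, entry))
    }
  }
  invisible(x)
}

#' Built-in weight tables
#'
#' `"functional"` is the default analysis table: pLoF variants get the maximum
#' weight 1, inframe indels 0.8, missense variants a tier by damaging
#' in-silico prediction count (>=2 predictions: 0.8; exactly 1: 0.5;
#' none: 0.2), synonymous and other variants weight 0 (not qualified).
#' `"synonymous_calibration"` inverts the design for an empirical-null run:
#' only synonymous variants qualify (weight 1), which should carry no real
#' case-control signal and so probes the calibration of the whole pipeline.
#'
#' @param name One of `"functional"`, `"synonymous_calibration"`.
#' @return A [weight_table()].
#' @export
default_weight_table <- function(name = c("functional", "synonymous_calibration")) {
  name <- match.arg(name)
  if (name == "functional") {
    weight_table(list(
      pLoF          = 1.0,
      inframe_indel = 0.8,
      missense      = data.frame(min_predictions = c(2L, 1L, 0L),
                                 weight          = c(0.8, 0.5, 0.2)),
      synonymous    = 0.0,
      other         = 0.0
    ), name = "functional")
  } else {
    weight_table(list(
      pLoF          = 0.0,
      inframe_indel = 0.0,
      missense      = 0.0,
      synonymous    = 1.0,
      other         = 0.0
    ), name = "synonymous_calibration")
  }
}

#' Read a weight table from YAML
#'
#' Expected layout: a top-level `name` and a `classes` mapping; each class is
#' either a scalar weight or a list of `{min_predictions, weight}` tiers.
#'
#' @param path Path to a YAML file.
#' @return A [weight_table()].
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop_config("weight table file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$classes)) stop_format("weight table YAML lacks a 'classes' mapping: %s", path)
  classes <- lapply(y$classes, function(entry) {
    if (is.list(entry)) {
      tiers <- do.call(rbind, lapply(entry, function(t) {
        data.frame(min_predictions = as.integer(t$min_predictions),
                   weight = as.numeric(t$weight))
      }))
      tiers[order(-tiers$min_predictions), , drop = FALSE]
    } else {
      as.numeric(entry)
    }
  })
  weight_table(classes, name = y$name %||% tools::file_path_sans_ext(basename(path)))
}

#' Resolve a weight table from a name or a file path
#'
#' @param x A `weight_table`, the name of a built-in table, or a YAML path.
#' @return A [weight_table()].
#' @export
resolve_weight_table <- function(x) {
  if (inherits(x, "weight_table")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("functional", "synonymous_calibration")) return(default_weight_table(x))
    return(read_weight_table(x))
  }
  stop_config("cannot interpret weight table specification")
}

# Weight for one class given a vector of damaging-prediction counts.
class_weight <- function(entry, pred_counts) {
  if (is.data.frame(entry)) {
    tiers <- entry[order(-entry$min_predictions), , drop = FALSE]
    w <- rep(NA_real_, length(pred_counts))
    for (i in seq_len(nrow(tiers))) {
      hit <- is.na(w) & pred_counts >= tiers$min_predictions[i]
      w[hit] <- tiers$weight[i]
    }
    w[is.na(w)] <- tiers$weight[nrow(tiers)]
    w
  } else {
    rep(entry, length(pred_counts))
  }
}
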