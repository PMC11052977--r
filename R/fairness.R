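#' Bundle predictions with outcomes and protected groups
#'
#' The substrate of every fairness metric: true binary outcomes `Y`
#' (1 = death within 24 h of admission in the ICU setting), predicted
#' positive-class probabilities, thresholded hard labels, and the
#' protected-attribute group of each record.
#'
#' @param y_true Binary (0/1) vector of observed outcomes.
#' @param y_score Numeric vector of positive-class probabilities in
#'   \eqn{[0,1]}.
#' @param group Character or factor vector of protected-group labels.
#' @param y_pred Optional binary vector of hard predictions; defaults to
#'   thresholding `y_score` at `threshold`.
#' @param threshold Classification threshold on `y_score` (default 0.5).
#' @return A `prediction_set` tibble with columns `y_true`, `y_score`,
#'   `y_pred`, `group`.
#' @export
prediction_set <- function(y_true, y_score, group, y_pred = NULL,
                           threshold = 0.5) {
  if (is.null(y_pred)) y_pred <- as.integer(y_score >= threshold)
  n <- length(y_true)
  if (n < 1L || length(y_score) != n || length(y_pred) != n ||
      length(group) != n) {
    stop("y_true, y_score, y_pred and group must share a positive length.",
         call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("y_true and y_pred must be binary 0/1.", call. = FALSE)
  }
  if (any(!is.finite(y_score)) || any(y_score < 0) || any(y_score > 1)) {
    stop("y_score must lie in [0, 1].", call. = FALSE)
  }
  out <- tibble::tibble(
    y_true = as.integer(y_true),
    y_score = as.numeric(y_score),
    y_pred = as.integer(y_pred),
    group = as.character(group)
  )
  class(out) <- c("prediction_set", class(out))
  out
}

as_prediction_set <- function(p) {
  if (inherits(p, "prediction_set")) return(p)
  stopifnot(is.data.frame(p),
            all(c("y_true", "y_score", "y_pred", "group") %in% names(p)))
  prediction_set(p$y_true, p$y_score, p$group, y_pred = p$y_pred)
}

#' Per-group confusion counts
#'
#' Exact TP/TN/FP/FN counts for each protected group present in the
#' data.
#'
#' @param p A [prediction_set()].
#' @return Tibble with one row per group: `group`, `n`, `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_by_group <- function(p) {
  p <- as_prediction_set(p)
  p |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      tp = sum(.data$y_true == 1L & .data$y_pred == 1L),
      tn = sum(.data$y_true == 0L & .data$y_pred == 0L),
      fp = sum(.data$y_true == 0L & .data$y_pred == 1L),
      fn = sum(.data$y_true == 1L & .data$y_pred == 0L),
      .groups = "drop"
    )
}

#' Demographic parity difference
#'
#' Largest pairwise absolute gap in positive-prediction rates
#' \eqn{P(\hat Y = 1 \mid A = a)} across protected groups. Zero means
#' parity; larger values mean the classifier's positive rate depends on
#' group membership.
#'
#' @param p A [prediction_set()] with at least two groups.
#' @return Single non-negative number in \eqn{[0,1]}.
#' @export
demographic_parity_difference <- function(p) {
  rates <- positive_rate_by_group(p)
  if (nrow(rates) < 2L) {
    stop("Demographic parity needs at least two groups.", call. = FALSE)
  }
  max(rates$positive_rate) - min(rates$positive_rate)
}

positive_rate_by_group <- function(p) {
  p <- as_prediction_set(p)
  p |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(positive_rate = mean(.data$y_pred == 1L),
                     .groups = "drop")
}

#' Error-rate parity: per-group FPR/FNR and their worst-case gaps
#'
#' Per-group false positive rate \eqn{FP/(FP+TN)} and false negative
#' rate \eqn{FN/(FN+TP)}, with the maximum pairwise absolute gap per
#' error type. A group with no negatives (respectively no positives) has
#' an undefined FPR (FNR); it is reported as `NA`, excluded from the
#' gap, and flagged with a warning.
#'
#' @param p A [prediction_set()] with at least two groups.
#' @return List with `rates` (tibble: `group`, `fpr`, `fnr`),
#'   `fpr_difference`, `fnr_difference`.
#' @export
error_rate_parity <- function(p) {
  cm <- confusion_by_group(p)
  if (nrow(cm) < 2L) {
    stop("Error-rate parity needs at least two groups.", call. = FALSE)
  }
  rates <- cm |>
    dplyr::mutate(
      fpr = dplyr::if_else(.data$fp + .data$tn > 0L,
                           .data$fp / (.data$fp + .data$tn), NA_real_),
      fnr = dplyr::if_else(.data$fn + .data$tp > 0L,
                           .data$fn / (.data$fn + .data$tp), NA_real_)
    ) |>
    dplyr::select("group", "fpr", "fnr")
  for (col in c("fpr", "fnr")) {
    bad <- rates$group[is.na(rates[[col]])]
    if (length(bad) > 0L) {
      warning("Group(s) ", paste(bad, collapse = ", "), " have an ",
              "undefined ", toupper(col),
              " (degenerate denominator); excluded from the parity gap.",
              call. = FALSE)
    }
    if (all(is.na(rates[[col]]))) {
      stop("All groups have an undefined ", toupper(col), ".",
           call. = FALSE)
    }
  }
  list(
    rates = rates,
    fpr_difference = diff(range(rates$fpr, na.rm = TRUE)),
    fnr_difference = diff(range(rates$fnr, na.rm = TRUE))
  )
}

#' Mann-Whitney AUC
#'
#' Probability that a randomly drawn positive outscores a randomly drawn
#' negative, ties counted one half. Computed from rank sums (midranks),
#' which equals explicit pair counting.
#'
#' @param y_true Binary 0/1 vector.
#' @param y_score Numeric score vector.
#' @return AUC in \eqn{[0,1]}, or `NA` if either class is absent.
#' @export
mann_whitney_auc <- function(y_true, y_score) {
  pos <- y_true == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(y_score, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-group ROC AUC
#'
#' @param p A [prediction_set()].
#' @return Tibble with `group` and `auc`; groups lacking a positive or a
#'   negative record get `NA`.
#' @export
auc_by_group <- function(p) {
  p <- as_prediction_set(p)
  p |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(auc = mann_whitney_auc(.data$y_true, .data$y_score),
                     .groups = "drop")
}

#' Full group-fairness report
#'
#' Assembles per-group positive-prediction rates, FPR, FNR, accuracy and
#' AUC together with the headline parity gaps (worst-case pairwise
#' absolute differences) and overall accuracy.
#'
#' @param p A [prediction_set()] with at least two groups.
#' @return A `fairness_report` object: list with `by_group` (tibble:
#'   `group`, `n`, `positive_rate`, `fpr`, `fnr`, `accuracy`, `auc`),
#'   `demographic_parity_difference`, `fpr_parity_difference`,
#'   `fnr_parity_difference`, `accuracy_spread`, `auc_spread`,
#'   `overall_accuracy`, `overall_auc`.
#' @export
fairness_report <- function(p) {
  p <- as_prediction_set(p)
  cm <- confusion_by_group(p)
  if (nrow(cm) < 2L) {
    stop("A fairness report needs at least two groups.", call. = FALSE)
  }
  erp <- error_rate_parity(p)
  by_group <- cm |>
    dplyr::mutate(
      positive_rate = (.data$tp + .data$fp) / .data$n,
      accuracy = (.data$tp + .data$tn) / .data$n
    ) |>
    dplyr::left_join(erp$rates, by = "group") |>
    dplyr::left_join(auc_by_group(p), by = "group") |>
    dplyr::select("group", "n", "positive_rate", "fpr", "fnr",
                  "accuracy", "auc")

  structure(
    list(
      by_group = by_group,
      demographic_parity_difference = demographic_parity_difference(p),
      fpr_parity_difference = erp$fpr_difference,
      fnr_parity_difference = erp$fnr_difference,
      accuracy_spread = diff(range(by_group$accuracy)),
      auc_spread = diff(range(by_group$auc, na.rm = TRUE)),
      overall_accuracy = mean(p$y_true == p$y_pred),
      overall_auc = mann_whitney_auc(p$y_true, p$y_score)
    ),
    class = "fairness_report"
  )
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report>\n")
  print(x$by_group)
  cat(sprintf("demographic parity difference: %.4f\n",
              x$demographic_parity_difference))
  cat(sprintf("FPR / FNR parity differences : %.4f / %.4f\n",
              x$fpr_parity_difference, x$fnr_parity_difference))
  cat(sprintf("accuracy: overall %.4f, per-group spread %.4f\n",
              x$overall_accuracy, x$accuracy_spread))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-group fairness metrics
#'
#' @param x A `fairness_report`.
#' @param ... Unused.
#' @return Long tibble: `group`, `metric`, `value`.
#' @export
tidy.fairness_report <- function(x, ...) {
  x$by_group |>
    tidyr::pivot_longer(-c("group", "n"), names_to = "metric",
                        values_to = "value") |>
    dplyr::select("group", "metric", "value")
}

#' One-row fairness summary
#'
#' @param x A `fairness_report`.
#' @param ... Unused.
#' @return One-row tibble of the headline gaps and overall metrics.
#' @export
glance.fairness_report <- function(x, ...) {
  tibble::tibble(
    demographic_parity_difference = x$demographic_parity_difference,
    fpr_parity_difference = x$fpr_parity_difference,
    fnr_parity_difference = x$fnr_parity_difference,
    accuracy_spread = x$accuracy_spread,
    auc_spread = x$auc_spread,
    overall_accuracy = x$overall_accuracy,
    overall_auc = x$overall_auc
  )
}

#' Plot per-group fairness metrics
#'
#' @param object A `fairness_report`.
#' @param ... Unused.
#' @return A ggplot: per-group bars, one facet per metric.
#' @export
autoplot.fairness_report <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "protected group", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a fairness report to CSV and JSON
#'
#' @param x A `fairness_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_fairness_report <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(tidy(x), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      c(list(by_group = x$by_group), glance(x)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  invisible(x)
}
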