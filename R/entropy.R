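#' Shannon entropy of a feature (log base 10)
#'
#' \eqn{H = -\sum_b p_b \log_{10} p_b} over non-empty bins. Clinical
#' score features are integer-valued on \eqn{[0, 22]}, so integer input
#' is tallied with one bin per integer value; continuous input (such as
#' post-transform features) is discretized into `n_bins` equal-width
#' bins over its observed range. Empty bins contribute zero
#' (\eqn{0 \log 0 = 0}).
#'
#' @param values Non-empty finite numeric vector.
#' @param n_bins Number of equal-width bins for continuous input
#'   (default 23, matching the 0-22 score cardinality).
#' @return Non-negative entropy in log10 units; at most
#'   \eqn{\log_{10}}(number of bins).
#' @export
#' @examples
#' shannon_entropy(rep(1:10, each = 5)) # uniform over 10 values -> 1
shannon_entropy <- function(values, n_bins = 23L) {
  if (length(values) == 0L) {
    stop("`values` must be non-empty.", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite.", call. = FALSE)
  }
  if (n_bins < 1L) stop("`n_bins` must be >= 1.", call. = FALSE)
  counts <- bin_counts(values, n_bins)
  p <- counts[counts > 0] / length(values)
  -sum(p * log10(p))
}

bin_counts <- function(values, n_bins) {
  if (all(values == round(values))) {
    return(as.integer(table(values)))
  }
  rng <- range(values)
  if (rng[2] - rng[1] <= 0) return(length(values))
  bin <- pmin(floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins),
              n_bins - 1L)
  as.integer(table(bin))
}

#' Per-feature entropy profile of a feature matrix
#'
#' Columnwise [shannon_entropy()] plus the spread (max minus min), the
#' uniformity diagnostic used to compare a cohort before and after
#' spectral equalization.
#'
#' @param x Numeric matrix or data frame of features (cohort tibbles are
#'   accepted; their `feature_*` columns are used).
#' @param n_bins Bins for continuous features (default 23).
#' @return An `entropy_profile` tibble (`feature`, `entropy`) with
#'   attributes `spread` and `n_bins`.
#' @export
entropy_profile <- function(x, n_bins = 23L) {
  if (is.data.frame(x)) {
    feats <- feature_columns(x)
    if (length(feats) > 0L) x <- x[feats]
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  }
  h <- apply(x, 2L, shannon_entropy, n_bins = n_bins)
  out <- tibble::tibble(feature = colnames(x), entropy = unname(h))
  attr(out, "spread") <- max(out$entropy) - min(out$entropy)
  attr(out, "n_bins") <- as.integer(n_bins)
  class(out) <- c("entropy_profile", class(out))
  out
}

#' Spread of an entropy profile
#'
#' @param profile An [entropy_profile()].
#' @return `max(entropy) - min(entropy)`.
#' @export
entropy_spread <- function(profile) {
  attr(profile, "spread")
}

#' Compare entropy profiles before and after a transform
#'
#' @param pre,post [entropy_profile()]s over the same feature set.
#' @return List with `by_feature` (tibble: `feature`, `entropy_pre`,
#'   `entropy_post`, `delta`), `spread_pre`, `spread_post`, and
#'   `uniformized` (`TRUE` when the post spread is strictly smaller).
#' @export
compare_entropy <- function(pre, post) {
  if (!setequal(pre$feature, post$feature) ||
      nrow(pre) != nrow(post)) {
    stop("Profiles cover different feature sets.", call. = FALSE)
  }
  by_feature <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(pre), entropy_pre = "entropy"),
    dplyr::rename(tibble::as_tibble(post), entropy_post = "entropy"),
    by = "feature"
  ) |>
    dplyr::mutate(delta = .data$entropy_post - .data$entropy_pre)
  structure(
    list(
      by_feature = by_feature,
      spread_pre = entropy_spread(pre),
      spread_post = entropy_spread(post),
      uniformized = entropy_spread(post) < entropy_spread(pre)
    ),
    class = "entropy_comparison"
  )
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat("<entropy_comparison> ", nrow(x$by_feature), " features\n", sep = "")
  cat(sprintf("  spread pre %.4f -> post %.4f (%s)\n",
              x$spread_pre, x$spread_post,
              if (x$uniformized) "uniformized" else "not uniformized"))
  invisible(x)
}

#' Plot pre/post entropy profiles
#'
#' @param object An `entropy_comparison` from [compare_entropy()].
#' @param ... Unused.
#' @return A ggplot of per-feature entropies before and after.
#' @export
autoplot.entropy_comparison <- function(object, ...) {
  object$by_feature |>
    tidyr::pivot_longer(c("entropy_pre", "entropy_post"),
                        names_to = "stage", names_prefix = "entropy_",
                        values_to = "entropy") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$feature, y = .data$entropy,
                                 fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Shannon entropy (log10)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write an entropy comparison to CSV and JSON
#'
#' @param x An `entropy_comparison`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_entropy_comparison <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(x$by_feature, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(spread_pre = x$spread_pre, spread_post = x$spread_post,
           uniformized = x$uniformized),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(x)
}
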