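#' Monte-Carlo permutation-sampling Shapley attribution
#'
#' Estimates each feature's Shapley value for every instance by
#' averaging marginal contributions over random feature orderings.
#' Features absent from the growing coalition are imputed from a
#' background row drawn uniformly (one per sampled ordering), the
#' standard interventional value function. Per ordering the marginal
#' contributions telescope, so the per-instance attribution sum equals
#' the model output at the instance minus the mean output over the
#' sampled background rows exactly; against the full-background mean it
#' holds within Monte-Carlo error.
#'
#' @param predict_fn Function mapping a numeric matrix (rows =
#'   instances) to a numeric vector or a matrix of class probabilities
#'   (one column per class).
#' @param background Numeric matrix of background rows used for
#'   imputation.
#' @param instances Numeric matrix of rows to explain.
#' @param n_samples Number of sampled orderings per instance
#'   (default 50).
#' @param seed Integer seed; estimates are seed-reproducible.
#' @return An `attribution_report`: list with `values` (tibble:
#'   `instance`, `feature`, `class`, `attribution`, `se` — the
#'   per-feature Monte-Carlo standard error), `summary` (tibble:
#'   `feature`, `class`, `mean_abs_attribution`, `rank`),
#'   `uniformity` (tibble: `class`, `uniformity_index`), `efficiency`
#'   (tibble per instance and class: attribution sum, prediction gap,
#'   Monte-Carlo standard error), and bookkeeping fields.
#' @export
shapley_attribution <- function(predict_fn, background, instances,
                                n_samples = 50L, seed = 1L) {
  background <- as_feature_matrix(background)
  instances <- as_feature_matrix(instances)
  if (nrow(background) == 0L) stop("`background` is empty.", call. = FALSE)
  if (ncol(background) != ncol(instances)) {
    stop("`background` and `instances` must share features.", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("`n_samples` must be >= 1.", call. = FALSE)
  d <- ncol(instances)
  feat_names <- colnames(instances)

  out_probe <- as_prediction_matrix(predict_fn(instances[1, , drop = FALSE]))
  n_class <- ncol(out_probe)
  class_names <- colnames(out_probe)

  rows <- list()
  eff <- list()
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(instances))) {
      x <- instances[i, ]
      perms <- replicate(n_samples, sample.int(d), simplify = FALSE)
      bg_idx <- sample.int(nrow(background), n_samples, replace = TRUE)
      # Build every coalition row for all orderings, evaluate in one call
      coal <- matrix(0, nrow = n_samples * (d + 1L), ncol = d)
      for (s in seq_len(n_samples)) {
        b <- background[bg_idx[s], ]
        row0 <- (s - 1L) * (d + 1L)
        current <- b
        coal[row0 + 1L, ] <- current
        for (pos in seq_len(d)) {
          j <- perms[[s]][pos]
          current[j] <- x[j]
          coal[row0 + pos + 1L, ] <- current
        }
      }
      colnames(coal) <- feat_names
      preds <- as_prediction_matrix(predict_fn(coal), n_class)

      contrib <- array(0, dim = c(d, n_class, n_samples))
      for (s in seq_len(n_samples)) {
        row0 <- (s - 1L) * (d + 1L)
        delta <- preds[row0 + 1L + seq_len(d), , drop = FALSE] -
          preds[row0 + seq_len(d), , drop = FALSE]
        contrib[perms[[s]], , s] <- delta
      }
      phi <- apply(contrib, c(1L, 2L), mean)
      phi_se <- apply(contrib, c(1L, 2L), stats::sd) / sqrt(n_samples)

      fx <- as_prediction_matrix(predict_fn(instances[i, , drop = FALSE]),
                                 n_class)
      fb <- as_prediction_matrix(predict_fn(background), n_class)
      base_rows <- preds[(seq_len(n_samples) - 1L) * (d + 1L) + 1L, ,
                         drop = FALSE]
      for (c_idx in seq_len(n_class)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          instance = i,
          feature = feat_names,
          class = class_names[c_idx],
          attribution = phi[, c_idx],
          se = phi_se[, c_idx]
        )
        eff[[length(eff) + 1L]] <- tibble::tibble(
          instance = i,
          class = class_names[c_idx],
          attribution_sum = sum(phi[, c_idx]),
          prediction_gap = fx[1L, c_idx] - mean(fb[, c_idx]),
          mc_se = stats::sd(base_rows[, c_idx]) / sqrt(n_samples)
        )
      }
    }
  })

  build_attribution_report(
    dplyr::bind_rows(rows), dplyr::bind_rows(eff),
    n_samples = n_samples, seed = as.integer(seed),
    estimator = "permutation-sampling"
  )
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  }
  x
}

as_prediction_matrix <- function(pred, n_class = NULL) {
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1L)
  pred <- as.matrix(pred)
  if (!is.null(n_class) && ncol(pred) != n_class) {
    stop("predict_fn returned an inconsistent number of classes.",
         call. = FALSE)
  }
  if (is.null(colnames(pred))) {
    colnames(pred) <- if (ncol(pred) == 1L) "output" else
      paste0("class_", seq_len(ncol(pred)) - 1L)
  }
  pred
}

build_attribution_report <- function(values, efficiency, n_samples, seed,
                                     estimator) {
  summary <- values |>
    dplyr::group_by(.data$feature, .data$class) |>
    dplyr::summarise(mean_abs_attribution = mean(abs(.data$attribution)),
                     .groups = "drop") |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(rank = rank(-.data$mean_abs_attribution,
                              ties.method = "first")) |>
    dplyr::ungroup()
  uniformity <- summary |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      uniformity_index = 1 - gini_coefficient(.data$mean_abs_attribution),
      .groups = "drop"
    )
  structure(
    list(values = values, summary = summary, uniformity = uniformity,
         efficiency = efficiency, n_samples = n_samples, seed = seed,
         estimator = estimator),
    class = "attribution_report"
  )
}

# Gini coefficient of a non-negative attribution mass; 0 for a uniform
# distribution, -> 1 when one feature carries everything.
gini_coefficient <- function(w) {
  if (any(w < 0)) stop("Gini needs non-negative mass.", call. = FALSE)
  n <- length(w)
  if (n <= 1L || sum(w) == 0) return(0)
  w <- sort(w)
  sum((2 * seq_len(n) - n - 1L) * w) / (n * sum(w))
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> ", x$estimator, ", ",
      dplyr::n_distinct(x$values$instance), " instances, ",
      dplyr::n_distinct(x$values$feature), " features\n", sep = "")
  print(x$uniformity)
  invisible(x)
}

#' Tidy per-feature attribution summary
#'
#' @param x An `attribution_report`.
#' @param ... Unused.
#' @return Tibble: `feature`, `class`, `mean_abs_attribution`, `rank`.
#' @export
tidy.attribution_report <- function(x, ...) {
  x$summary
}

#' One-row attribution summary (uniformity per class)
#'
#' @param x An `attribution_report`.
#' @param ... Unused.
#' @return Wide one-row tibble of uniformity indices.
#' @export
glance.attribution_report <- function(x, ...) {
  x$uniformity |>
    tidyr::pivot_wider(names_from = "class",
                       values_from = "uniformity_index",
                       names_prefix = "uniformity_")
}

#' Plot mean absolute attributions per feature and class
#'
#' @param object An `attribution_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attribution_report <- function(object, ...) {
  object$summary |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$feature, .data$mean_abs_attribution),
      y = .data$mean_abs_attribution
    )) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = NULL, y = "mean |Shapley value|") +
    ggplot2::theme_minimal()
}

#' Exact Shapley values by subset enumeration
#'
#' Reference enumerator for small feature counts: computes
#' \eqn{\phi_j = \sum_S \frac{|S|!(d-|S|-1)!}{d!}[v(S \cup j) - v(S)]}
#' with the interventional value function
#' \eqn{v(S) =} mean over background rows of the prediction with
#' features in `S` taken from the instance and the rest from the
#' background row. Averaging over all orderings and over the background
#' gives the same quantity the Monte-Carlo estimator converges to.
#'
#' @param predict_fn As in [shapley_attribution()].
#' @param background Numeric background matrix.
#' @param instance Single row (vector or 1-row matrix) to explain.
#' @return Matrix of exact Shapley values, features x classes.
#' @export
exact_shapley <- function(predict_fn, background, instance) {
  background <- as_feature_matrix(background)
  instance <- as_feature_matrix(instance)
  stopifnot(nrow(instance) == 1L)
  d <- ncol(background)
  if (d > 10L) {
    stop("exact_shapley enumerates 2^d coalitions; d must be <= 10.",
         call. = FALSE)
  }
  n_bg <- nrow(background)
  x <- instance[1L, ]

  # v(S) for all 2^d subsets, averaged over background rows
  n_sub <- 2L^d
  v <- NULL
  for (mask in seq_len(n_sub) - 1L) {
    in_s <- as.logical(bitwAnd(mask, 2L^(seq_len(d) - 1L)))
    rows <- background
    rows[, in_s] <- matrix(x[in_s], n_bg, sum(in_s), byrow = TRUE)
    pred <- as_prediction_matrix(predict_fn(rows))
    vals <- colMeans(pred)
    if (is.null(v)) {
      v <- matrix(0, n_sub, length(vals),
                  dimnames = list(NULL, names(vals)))
    }
    v[mask + 1L, ] <- vals
  }

  phi <- matrix(0, d, ncol(v),
                dimnames = list(colnames(background), colnames(v)))
  fact <- factorial(0:d)
  for (j in seq_len(d)) {
    bit_j <- 2L^(j - 1L)
    for (mask in seq_len(n_sub) - 1L) {
      if (bitwAnd(mask, bit_j) != 0L) next
      s <- sum(as.logical(bitwAnd(mask, 2L^(seq_len(d) - 1L))))
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[j, ] <- phi[j, ] + w * (v[mask + bit_j + 1L, ] - v[mask + 1L, ])
    }
  }
  phi
}

#' Compare benchmark and transform attribution reports
#'
#' @param benchmark,gs `attribution_report`s over the same features and
#'   classes.
#' @param zero_tol Attributions with absolute mean below this count as
#'   zero-contribution features (default 1e-12).
#' @return List with per-class tibble `by_class` (`uniformity_benchmark`,
#'   `uniformity_gs`, `uniformity_delta`, `kendall_tau`,
#'   `zero_features_benchmark`, `zero_features_gs`, `more_equalized`).
#' @export
compare_attributions <- function(benchmark, gs, zero_tol = 1e-12) {
  sb <- benchmark$summary
  sg <- gs$summary
  if (!setequal(sb$feature, sg$feature) ||
      !setequal(sb$class, sg$class)) {
    stop("Reports cover different features or classes.", call. = FALSE)
  }
  joined <- dplyr::inner_join(sb, sg, by = c("feature", "class"),
                              suffix = c("_benchmark", "_gs"))
  ub <- benchmark$uniformity |>
    dplyr::rename(uniformity_benchmark = "uniformity_index")
  ug <- gs$uniformity |> dplyr::rename(uniformity_gs = "uniformity_index")
  by_class <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      kendall_tau = stats::cor(.data$rank_benchmark, .data$rank_gs,
                               method = "kendall"),
      zero_features_benchmark =
        sum(.data$mean_abs_attribution_benchmark < zero_tol),
      zero_features_gs = sum(.data$mean_abs_attribution_gs < zero_tol),
      .groups = "drop"
    ) |>
    dplyr::inner_join(ub, by = "class") |>
    dplyr::inner_join(ug, by = "class") |>
    dplyr::mutate(
      uniformity_delta = .data$uniformity_gs - .data$uniformity_benchmark,
      more_equalized = .data$uniformity_delta > 0
    )
  structure(list(by_class = by_class), class = "attribution_comparison")
}

#' @export
print.attribution_comparison <- function(x, ...) {
  cat("<attribution_comparison>\n")
  print(x$by_class)
  invisible(x)
}

#' Write an attribution report to CSV and JSON
#'
#' @param x An `attribution_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_attribution_report <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(x$summary, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(uniformity = x$uniformity, n_samples = x$n_samples,
           seed = x$seed, estimator = x$estimator),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(x)
}
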