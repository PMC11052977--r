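#' Configuration of the paired benchmark-versus-transform experiment
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohorts.
#' @param gs A [gs_config()] for the spectral-equalization transform.
#' @param mlp An [mlp_spec()]; its `input_dim` must match the cohort's
#'   feature count.
#' @param split_fractions Train/validation/test fractions, positive and
#'   summing to one (default `c(0.7, 0.15, 0.15)`).
#' @param n_cohorts Number of cohort replicates (default 3).
#' @param n_repetitions Repetitions per cohort (default 5); each
#'   repetition re-randomizes both the split and the model
#'   initialization through its derived seed.
#' @param threshold Classification threshold (default 0.5).
#' @param transform_when `"before_split"` (default; the transform sees
#'   the full cohort and the subsets are carved out of its output) or
#'   `"after_split"` (each subset transformed separately, provided for
#'   methodological comparison).
#' @param seed Master seed; repetition seeds are
#'   `seed + 100 * cohort_index + repetition`.
#' @param attribution_instances,attribution_samples Size of the pooled
#'   Shapley comparison (instances explained, orderings per instance).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              gs = gs_config(),
                              mlp = NULL,
                              split_fractions = c(0.7, 0.15, 0.15),
                              n_cohorts = 3L,
                              n_repetitions = 5L,
                              threshold = 0.5,
                              transform_when = c("before_split",
                                                 "after_split"),
                              seed = 1L,
                              attribution_instances = 15L,
                              attribution_samples = 30L) {
  if (length(split_fractions) != 3L || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    stop("`split_fractions` must be three positive numbers summing to 1.",
         call. = FALSE)
  }
  if (is.null(mlp)) mlp <- mlp_spec(input_dim = cohort$n_features)
  if (mlp$input_dim != cohort$n_features) {
    stop("mlp input_dim (", mlp$input_dim, ") must equal the cohort's ",
         "n_features (", cohort$n_features, ").", call. = FALSE)
  }
  structure(
    list(
      cohort = cohort, gs = gs, mlp = mlp,
      split_fractions = split_fractions,
      n_cohorts = as.integer(n_cohorts),
      n_repetitions = as.integer(n_repetitions),
      threshold = threshold,
      transform_when = match.arg(transform_when),
      seed = as.integer(seed),
      attribution_instances = as.integer(attribution_instances),
      attribution_samples = as.integer(attribution_samples)
    ),
    class = "experiment_config"
  )
}

repetition_seed <- function(config, cohort_index, repetition) {
  config$seed + 100L * cohort_index + repetition
}

#' Group-stratified train/validation/test split
#'
#' Rows are allocated within each protected group by largest-remainder
#' arithmetic on the fractions, after a seeded within-group shuffle, so
#' every subset mirrors the cohort's group composition to within one row
#' per stratum. The protected attribute travels with each subset as a
#' metadata column but is never among the feature columns.
#'
#' @param cohort A cohort tibble.
#' @param fractions Train/validation/test fractions summing to one.
#' @param seed Seed for the within-group shuffles.
#' @return A list with integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
split_data <- function(cohort, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    stop("`fractions` must be positive and sum to 1.", call. = FALSE)
  }
  groups <- as.character(cohort$group)
  small <- names(which(table(groups) < 3L))
  if (length(small) > 0L) {
    warning("Group(s) ", paste(small, collapse = ", "), " have fewer ",
            "than 3 rows; best-effort allocation.", call. = FALSE)
  }
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  withr::with_seed(as.integer(seed), {
    for (g in unique(groups)) {
      idx <- sample(which(groups == g))
      n_g <- length(idx)
      sizes <- fraction_allocation(n_g, fractions)
      parts$train <- c(parts$train, idx[seq_len(sizes[1L])])
      parts$val <- c(parts$val,
                     idx[sizes[1L] + seq_len(sizes[2L])])
      parts$test <- c(parts$test,
                      idx[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
    }
  })
  lapply(parts, sort)
}

# Largest-remainder allocation of n rows to fractions.
fraction_allocation <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  remainder <- n - sum(base)
  frac <- exact - base
  order_idx <- order(frac, decreasing = TRUE)
  if (remainder > 0L) {
    base[order_idx[seq_len(remainder)]] <-
      base[order_idx[seq_len(remainder)]] + 1L
  }
  as.integer(base)
}

#' Run one arm (benchmark or transform) of a paired comparison
#'
#' Both arms of a (cohort, repetition) pair share the repetition seed,
#' hence identical split indices and identical model initialization;
#' the only difference is whether the feature matrix passes through the
#' spectral-equalization transform first (by default before the split,
#' matching the protocol that distributes information across all
#' subsequent subsets). The protected attribute is excluded from the
#' model inputs in both arms.
#'
#' @param cohort A cohort tibble.
#' @param config An [experiment_config()].
#' @param arm `"benchmark"` or `"gs"`.
#' @param seed Repetition seed (controls split, transform phase init,
#'   and model training).
#' @return List with `model` (a `gs_mlp`), `predictions` (a
#'   [prediction_set()] on the test subset), `split` (the index lists),
#'   and `arm`.
#' @export
run_arm <- function(cohort, config, arm = c("benchmark", "gs"),
                    seed = config$seed) {
  arm <- match.arg(arm)
  split <- split_data(cohort, config$split_fractions, seed = seed)

  working <- cohort
  if (arm == "gs" && config$transform_when == "before_split") {
    gs_cfg <- config$gs
    gs_cfg$seed <- seed
    working <- gs_transform_cohort(working, gs_cfg)
  }
  feats <- feature_columns(working)
  subsets <- lapply(split, function(idx) working[idx, , drop = FALSE])
  if (arm == "gs" && config$transform_when == "after_split") {
    gs_cfg <- config$gs
    gs_cfg$seed <- seed
    subsets <- lapply(subsets, gs_transform_cohort, config = gs_cfg)
  }

  mlp <- config$mlp
  mlp$seed <- seed
  model <- train_mlp(
    mlp,
    as.matrix(subsets$train[feats]), subsets$train$outcome,
    as.matrix(subsets$val[feats]), subsets$val$outcome
  )
  scores <- predict_proba(model, as.matrix(subsets$test[feats]))[, "class_1"]
  preds <- prediction_set(
    y_true = subsets$test$outcome,
    y_score = scores,
    group = subsets$test$group,
    threshold = config$threshold
  )
  list(model = model, predictions = preds, split = split, arm = arm)
}

#' Run the full paired experiment
#'
#' Executes `n_cohorts x n_repetitions x 2` model runs (default
#' 3 x 5 x 2 = 30, i.e. 15 repetitions per arm): for each cohort
#' replicate and repetition, the benchmark and transform arms are run
#' with shared seeds and split indices, and their fairness reports are
#' collected. One pooled entropy comparison (training features before
#' versus after the transform) and one pooled attribution comparison
#' (Shapley profiles of the two arms' models on shared test instances)
#' are computed on the first cohort's first repetition.
#'
#' @param config An [experiment_config()].
#' @param output_dir Optional directory; per-run metrics (CSV), the
#'   comparison summaries (JSON) and a run log are written there.
#' @return An `experiment_report`: list with `runs` (one-row-per-run
#'   tibble of fairness metrics), `entropy`, `attribution`, `config`,
#'   and `log` (per-run seeds and timings).
#' @export
run_experiment <- function(config = experiment_config(),
                           output_dir = NULL) {
  cohorts <- make_cohort_replicates(config$cohort, config$n_cohorts)
  runs <- list()
  group_rows <- list()
  log <- list()
  entropy_cmp <- NULL
  attribution_cmp <- NULL

  for (ci in seq_len(config$n_cohorts)) {
    cohort <- cohorts[[ci]]
    for (rep_i in seq_len(config$n_repetitions)) {
      seed <- repetition_seed(config, ci, rep_i)
      arms <- list()
      for (arm in c("benchmark", "gs")) {
        t0 <- proc.time()[["elapsed"]]
        res <- run_arm(cohort, config, arm = arm, seed = seed)
        elapsed <- proc.time()[["elapsed"]] - t0
        fr <- fairness_report(res$predictions)
        runs[[length(runs) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(cohort = ci, repetition = rep_i, arm = arm,
                         seed = seed),
          glance(fr)
        )
        group_rows[[length(group_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(cohort = ci, repetition = rep_i, arm = arm),
          confusion_by_group(res$predictions)
        )
        log[[length(log) + 1L]] <- tibble::tibble(
          cohort = ci, repetition = rep_i, arm = arm, seed = seed,
          n_train = length(res$split$train),
          n_val = length(res$split$val),
          n_test = length(res$split$test),
          epochs = nrow(res$model$history),
          gs_before_split = arm == "gs" &&
            config$transform_when == "before_split",
          group_in_features = "group" %in%
            feature_columns(cohort),
          elapsed_s = elapsed
        )
        arms[[arm]] <- res
      }

      if (ci == 1L && rep_i == 1L) {
        feats <- feature_columns(cohort)
        gs_cfg <- config$gs
        gs_cfg$seed <- seed
        transformed <- gs_transform_cohort(cohort, gs_cfg)
        tr_idx <- arms$benchmark$split$train
        entropy_cmp <- compare_entropy(
          entropy_profile(cohort[tr_idx, feats]),
          entropy_profile(transformed[tr_idx, feats])
        )
        attribution_cmp <- pooled_attribution_comparison(
          arms, cohort, transformed, config, seed
        )
      }
    }
  }

  report <- structure(
    list(
      runs = dplyr::bind_rows(runs),
      group_confusions = dplyr::bind_rows(group_rows),
      log = dplyr::bind_rows(log),
      entropy = entropy_cmp,
      attribution = attribution_cmp,
      config = config
    ),
    class = "experiment_report"
  )
  if (!is.null(output_dir)) write_experiment_report(report, output_dir)
  report
}

pooled_attribution_comparison <- function(arms, cohort, transformed,
                                          config, seed) {
  feats <- feature_columns(cohort)
  test_idx <- arms$benchmark$split$test
  train_idx <- arms$benchmark$split$train
  n_inst <- min(config$attribution_instances, length(test_idx))
  n_bg <- min(100L, length(train_idx))
  inst_idx <- test_idx[seq_len(n_inst)]
  bg_idx <- train_idx[seq_len(n_bg)]

  explain <- function(model, data) {
    shapley_attribution(
      function(m) predict_proba(model, m),
      background = as.matrix(data[bg_idx, feats]),
      instances = as.matrix(data[inst_idx, feats]),
      n_samples = config$attribution_samples,
      seed = seed
    )
  }
  compare_attributions(
    explain(arms$benchmark$model, cohort),
    explain(arms$gs$model, transformed)
  )
}

#' Pooled per-group performance across all repetitions of an arm
#'
#' Sums the per-repetition confusion counts of every run of an arm, so
#' each group's accuracy and positive-prediction rate are estimated on
#' all of its test rows at once — the mean-performance-per-group view
#' (one bar per group per arm), far less noisy for the small minority
#' groups than any single repetition's test subset.
#'
#' @param report An `experiment_report`.
#' @return Tibble: `arm`, `group`, pooled `n`, `accuracy`,
#'   `positive_rate`.
#' @export
pooled_group_metrics <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  report$group_confusions |>
    dplyr::group_by(.data$arm, .data$group) |>
    dplyr::summarise(dplyr::across(c("n", "tp", "tn", "fp", "fn"), sum),
                     .groups = "drop") |>
    dplyr::mutate(
      accuracy = (.data$tp + .data$tn) / .data$n,
      positive_rate = (.data$tp + .data$fp) / .data$n
    ) |>
    dplyr::select("arm", "group", "n", "accuracy", "positive_rate")
}

#' Pooled per-group accuracy spread and rate gap per arm
#'
#' @param report An `experiment_report`.
#' @return Tibble: `arm`, `accuracy_spread`, `demographic_parity_difference`
#'   computed on the pooled per-group estimates of
#'   [pooled_group_metrics()].
#' @export
pooled_group_spreads <- function(report) {
  pooled_group_metrics(report) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      accuracy_spread = diff(range(.data$accuracy)),
      demographic_parity_difference = diff(range(.data$positive_rate)),
      .groups = "drop"
    )
}

#' Aggregate a paired experiment into an arm-comparison table
#'
#' @param report An `experiment_report`.
#' @return An `arm_comparison`: tibble with one row per metric —
#'   benchmark mean, transform-arm mean, delta, and a label
#'   (`improvement` when the transform arm moved the metric in its
#'   desirable direction, `regression` otherwise). For parity gaps and
#'   spreads smaller is better; for accuracies and AUC larger is
#'   better.
#' @export
compare_arms <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  expected <- report$config$n_cohorts * report$config$n_repetitions * 2L
  if (nrow(report$runs) != expected) {
    stop("Incomplete report: ", nrow(report$runs), " of ", expected,
         " runs recorded.", call. = FALSE)
  }
  smaller_better <- c("demographic_parity_difference",
                      "fpr_parity_difference", "fnr_parity_difference",
                      "accuracy_spread", "auc_spread")
  long <- report$runs |>
    tidyr::pivot_longer(-c("cohort", "repetition", "arm", "seed"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric, .data$arm) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  wide <- long |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("mean", "sd")) |>
    dplyr::mutate(
      delta = .data$mean_gs - .data$mean_benchmark,
      direction = dplyr::if_else(.data$metric %in% smaller_better,
                                 "smaller_better", "larger_better"),
      label = dplyr::case_when(
        .data$delta == 0 ~ "unchanged",
        .data$direction == "smaller_better" & .data$delta < 0 ~ "improvement",
        .data$direction == "larger_better" & .data$delta > 0 ~ "improvement",
        .default = "regression"
      )
    )
  structure(wide, class = c("arm_comparison", class(wide)))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", x$config$n_cohorts, " cohorts x ",
      x$config$n_repetitions, " repetitions x 2 arms = ",
      nrow(x$runs), " runs\n", sep = "")
  print(compare_arms(x))
  invisible(x)
}

#' Tidy per-run experiment metrics
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-run metric tibble.
#' @export
tidy.experiment_report <- function(x, ...) {
  x$runs
}

#' One-row experiment summary
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return One-row tibble: per-arm mean demographic-parity difference,
#'   accuracy spread, overall accuracy, plus entropy spreads.
#' @export
glance.experiment_report <- function(x, ...) {
  cmp <- compare_arms(x)
  pick <- function(metric, col) {
    cmp[[col]][cmp$metric == metric]
  }
  tibble::tibble(
    n_runs = nrow(x$runs),
    dp_benchmark = pick("demographic_parity_difference", "mean_benchmark"),
    dp_gs = pick("demographic_parity_difference", "mean_gs"),
    accuracy_spread_benchmark = pick("accuracy_spread", "mean_benchmark"),
    accuracy_spread_gs = pick("accuracy_spread", "mean_gs"),
    overall_accuracy_benchmark = pick("overall_accuracy", "mean_benchmark"),
    overall_accuracy_gs = pick("overall_accuracy", "mean_gs"),
    entropy_spread_pre = x$entropy$spread_pre,
    entropy_spread_post = x$entropy$spread_post
  )
}

#' Plot per-arm distributions of the fairness metrics
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot: one facet per metric, boxplots by arm.
#' @export
autoplot.experiment_report <- function(object, ...) {
  object$runs |>
    tidyr::pivot_longer(-c("cohort", "repetition", "arm", "seed"),
                        names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$arm, y = .data$value,
                                 fill = .data$arm)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write an experiment report to disk
#'
#' Per-run metrics and the run log as CSV, the arm comparison, entropy
#' and attribution summaries as JSON.
#'
#' @param report An `experiment_report`.
#' @param output_dir Directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_experiment_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$runs, file.path(output_dir, "runs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$log, file.path(output_dir, "run_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    compare_arms(report), file.path(output_dir, "arm_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(report$entropy)) {
    write_entropy_comparison(
      report$entropy,
      csv_path = file.path(output_dir, "entropy_by_feature.csv"),
      json_path = file.path(output_dir, "entropy_summary.json")
    )
  }
  if (!is.null(report$attribution)) {
    jsonlite::write_json(
      report$attribution$by_class,
      file.path(output_dir, "attribution_comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(output_dir)
}
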