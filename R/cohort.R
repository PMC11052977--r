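#' Default racio-ethnic group proportions
#'
#' Proportions of the five regrouped ancestry labels in the reference
#' ICU cohort of 13,980 patients: European American (9814), African
#' American (1690), East-Asian American (346), Hispanic American (641),
#' Others/unreported (1489).
#'
#' @return Named numeric vector over `EA`, `AA`, `EAA`, `HA`, `OTH`,
#'   summing to one.
#' @export
default_group_proportions <- function() {
  counts <- c(EA = 9814, AA = 1690, EAA = 346, HA = 641, OTH = 1489)
  counts / sum(counts)
}

#' Specification of a synthetic biased ICU cohort
#'
#' Describes a cohort that emulates the structure of the reference ICU
#' mortality dataset: five racio-ethnic groups at heavily imbalanced
#' proportions, integer clinical-score features on \eqn{[0, 22]}, a
#' binary 24-hour mortality outcome, and built-in representation bias —
#' the features that carry the mortality signal differ between the
#' majority group and the minority groups, so a classifier trained on
#' the pooled data learns the majority's signal preferentially.
#'
#' @param n_patients Cohort size (default 2000; the reference cohort has
#'   13,980).
#' @param group_proportions Named proportions over the group labels
#'   (default [default_group_proportions()]); must sum to one.
#' @param n_features Number of integer score features (default 35).
#' @param feature_range Inclusive integer score range (default
#'   `c(0, 22)`).
#' @param base_mortality_rate Target marginal outcome rate
#'   (default 0.15); the logistic intercept is calibrated by bisection
#'   to hit it.
#' @param effect_size Logistic coefficient magnitude on the informative
#'   (standardized) features (default 1.2).
#' @param group_risk_offsets Named per-group additive logit offsets on
#'   the mortality risk (default: elevated baseline risk for the
#'   minority groups, the documented-disparity pattern in ICU
#'   mortality); groups absent from the vector get 0.
#' @param missing_rate Default cell-missingness rate used by
#'   [inject_missing()] (default 0.02; generation itself is complete).
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 2000L,
                        group_proportions = default_group_proportions(),
                        n_features = 35L,
                        feature_range = c(0L, 22L),
                        base_mortality_rate = 0.15,
                        effect_size = 1.2,
                        group_risk_offsets = c(EA = 0, AA = 0.8,
                                               EAA = 0.5, HA = 0.65,
                                               OTH = 0.4),
                        missing_rate = 0.02,
                        seed = 1L) {
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    stop("`group_proportions` must sum to 1.", call. = FALSE)
  }
  if (is.null(names(group_proportions))) {
    stop("`group_proportions` must be named.", call. = FALSE)
  }
  if (n_features < 20L) {
    stop("Need at least 20 features for the bias mechanism's layout ",
         "(two informative blocks plus demographic-correlate columns).",
         call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      group_proportions = group_proportions,
      n_features = as.integer(n_features),
      feature_range = as.integer(feature_range),
      base_mortality_rate = base_mortality_rate,
      effect_size = effect_size,
      group_risk_offsets = group_risk_offsets,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic biased cohort
#'
#' Draws group labels from a multinomial at the spec proportions,
#' integer score features from discretized normals truncated to the
#' score range, and the binary outcome from a logistic model whose
#' informative features depend on the group. The feature panel is
#' heterogeneous by design: the majority group's risk signal sits in
#' broadly dispersed scores, the minority groups' in coarsely
#' quantized near-constant ones whose raw-scale variation a pooled
#' model barely exploits, a dispersion gradient across background
#' columns spreads the per-feature entropies, and a few near-constant
#' columns carry group-mean offsets (demographic correlates).
#' Coefficient magnitudes are equal across groups; the majority's
#' advantage comes from representation share plus the raw-scale
#' visibility of its features. Minority groups additionally carry an
#' elevated baseline risk (`group_risk_offsets`), which a pooled model
#' can only express by conditioning on the demographic-correlate
#' columns. The logistic
#' intercept is calibrated by bisection so the expected mortality rate
#' matches `base_mortality_rate` to within 1e-6 before the Bernoulli
#' draw.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort tibble: columns `feature_1..feature_d` (integer
#'   scores), `outcome` (0/1), `group`; the generating spec and seed are
#'   attached as attribute `"cohort_spec"`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$n_features
  n <- spec$n_patients
  lo <- spec$feature_range[1L]
  hi <- spec$feature_range[2L]
  labels <- names(spec$group_proportions)
  majority <- labels[which.max(spec$group_proportions)]

  withr::with_seed(spec$seed, {
    group <- sample(labels, n, replace = TRUE,
                    prob = spec$group_proportions)

    # Heterogeneous integer scores laid out by role. Real severity
    # panels mix broadly dispersed scores (near-uniform over 0-22)
    # with coarsely quantized, almost constant ones, so per-feature
    # Shannon entropies span a wide band:
    #   cols 1-5              majority-informative, broad (sd 3.5)
    #   cols 6 .. d-15        background, dispersion gradient 4 -> 0.25
    #   cols d-14 .. d-10     minority-informative, near-constant
    #                         (sd 0.3): coarsely quantized scores whose
    #                         raw-scale variation is too small for the
    #                         pooled model to exploit
    #   cols d-9 .. d         demographic correlates, near-constant
    #                         (sd 0.4) with a +2 group-mean offset on
    #                         each group's pair of columns
    layout <- cohort_layout(d)
    feat_sd <- rep(1, d)
    feat_sd[layout$block_major] <- 3.5
    feat_sd[layout$background] <-
      exp(seq(log((hi - lo) / 5.5), log(0.25),
              length.out = length(layout$background)))
    feat_sd[layout$block_minor] <- 0.3
    feat_sd[layout$markers] <- 0.4
    feat_mean <- lo + (hi - lo) * (0.25 + 0.5 * ((seq_len(d) * 7L) %% d) / d)
    mu <- matrix(feat_mean, length(labels), d, byrow = TRUE,
                 dimnames = list(labels, NULL))
    for (g_idx in seq_along(labels)) {
      shift_cols <- layout$markers[(g_idx - 1L) * 2L %% length(layout$markers) +
                                     seq_len(2L)]
      mu[g_idx, shift_cols] <- mu[g_idx, shift_cols] + 2
    }
    x <- matrix(0L, n, d)
    for (j in seq_len(d)) {
      raw <- stats::rnorm(n, mean = mu[group, j], sd = feat_sd[j])
      x[, j] <- pmin(pmax(as.integer(round(raw)), lo), hi)
    }
    colnames(x) <- paste0("feature_", seq_len(d))

    # Group-dependent informative blocks on standardized (quantized)
    # scores; the standardization makes the latent risk strength equal
    # across groups -- only the raw-scale visibility of the columns
    # and the groups' representation shares differ.
    xs <- scale(x)
    xs[is.nan(xs)] <- 0
    beta_major <- numeric(d)
    beta_major[layout$block_major] <- spec$effect_size
    beta_minor <- numeric(d)
    beta_minor[layout$block_minor] <- spec$effect_size
    offsets <- spec$group_risk_offsets[group]
    offsets[is.na(offsets)] <- 0
    lin <- ifelse(group == majority,
                  as.numeric(xs %*% beta_major),
                  as.numeric(xs %*% beta_minor)) + unname(offsets)

    intercept <- calibrate_intercept(lin, spec$base_mortality_rate)
    p_death <- plogis(intercept + lin)
    outcome <- stats::rbinom(n, 1L, p_death)
  })

  out <- tibble::as_tibble(as.data.frame(x))
  out$outcome <- as.integer(outcome)
  out$group <- group
  attr(out, "cohort_spec") <- spec
  out
}

# Column roles for the synthetic score panel (d >= 20).
cohort_layout <- function(d) {
  list(
    block_major = 1:5,
    background = 6:(d - 15L),
    block_minor = (d - 14L):(d - 10L),
    markers = (d - 9L):d
  )
}

# Bisection on the logistic intercept so mean(plogis(c + lin)) hits the
# target rate.
calibrate_intercept <- function(lin, target, tol = 1e-6) {
  f <- function(c0) mean(stats::plogis(c0 + lin)) - target
  lower <- -30; upper <- 30
  for (i in seq_len(200L)) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) upper <- mid else lower <- mid
    if (upper - lower < tol * 1e-2) break
  }
  (lower + upper) / 2
}

#' Inject missing cells at random
#'
#' Each feature cell goes missing independently with probability
#' `missing_rate`; outcome and group columns stay complete. Exercises
#' the complete-case filter.
#'
#' @param cohort A cohort tibble.
#' @param missing_rate Per-cell missingness probability in \eqn{[0, 1)}.
#' @param seed Seed.
#' @return The cohort with `NA`s injected into feature columns.
#' @export
inject_missing <- function(cohort, missing_rate = 0.02, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1).", call. = FALSE)
  }
  if (missing_rate == 0) return(cohort)
  feats <- feature_columns(cohort)
  x <- as.matrix(cohort[feats])
  withr::with_seed(as.integer(seed), {
    mask <- matrix(stats::runif(length(x)) < missing_rate,
                   nrow(x), ncol(x))
  })
  x[mask] <- NA
  cohort[feats] <- as.data.frame(x)
  cohort
}

#' Complete-case filter
#'
#' Keeps exactly the rows with no missing values, in their original
#' order — the preprocessing rule applied to the reference cohort.
#'
#' @param cohort A cohort tibble (or any data frame).
#' @return The filtered tibble.
#' @export
filter_complete_cases <- function(cohort) {
  keep <- stats::complete.cases(cohort)
  if (!any(keep)) {
    stop("No complete cases remain after filtering.", call. = FALSE)
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "cohort_spec") <- attr(cohort, "cohort_spec")
  out
}

#' Cohort replicates from one patient pool
#'
#' Emulates running the experiment on several cohorts constructed from
#' the same patients under different sampling settings: one patient
#' pool is generated from the spec's seed, and each replicate is a
#' distinct seeded re-arrangement (permutation) of its rows, so
#' downstream stratified splits differ across replicates while the
#' patients do not.
#'
#' @param spec A [cohort_spec()].
#' @param n_cohorts Number of replicates (default 3).
#' @return List of cohort tibbles.
#' @export
make_cohort_replicates <- function(spec = cohort_spec(), n_cohorts = 3L) {
  if (n_cohorts < 1L) stop("`n_cohorts` must be >= 1.", call. = FALSE)
  pool <- generate_cohort(spec)
  lapply(seq_len(n_cohorts), function(r) {
    perm <- withr::with_seed(spec$seed + r, sample.int(nrow(pool)))
    out <- pool[perm, , drop = FALSE]
    attr(out, "cohort_spec") <- spec
    attr(out, "replicate") <- r
    out
  })
}

#' Write / read a cohort as CSV with a JSON spec sidecar
#'
#' @param cohort A cohort tibble.
#' @param path CSV path; the spec echo goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  spec <- attr(cohort, "cohort_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  out$group <- as.character(out$group)
  out
}
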