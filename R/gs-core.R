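#' Two-dimensional discrete Fourier transform
#'
#' Unnormalized forward 2-D DFT,
#' \eqn{F[u,v] = \sum_n \sum_m x[n,m] e^{-i 2\pi (un/N + vm/M)}}.
#' The inverse [idft2()] carries the \eqn{1/(NM)} factor, so
#' `idft2(dft2(x))` recovers `x`.
#'
#' @param x Numeric or complex matrix (patients in rows, features in
#'   columns). Must be non-empty with finite entries.
#' @return Complex matrix of the same dimensions.
#' @seealso [idft2()], [gs_transform()]
#' @export
#' @examples
#' dft2(matrix(c(1, 3, 2, 4), 2, 2))
dft2 <- function(x) {
  x <- as_spectral_matrix(x)
  stats::fft(x)
}

#' Two-dimensional inverse discrete Fourier transform
#'
#' Inverse of [dft2()]; carries the \eqn{1/(NM)} normalization so the
#' round trip is the identity.
#'
#' @param f Complex (or numeric) matrix.
#' @return Complex matrix of the same dimensions.
#' @export
idft2 <- function(f) {
  f <- as_spectral_matrix(f)
  stats::fft(f, inverse = TRUE) / length(f)
}

as_spectral_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (nrow(x) < 1L || ncol(x) < 1L || length(x) == 0L) {
    stop("`", arg, "` must be a non-empty matrix.", call. = FALSE)
  }
  if (!is.complex(x)) {
    if (!is.numeric(x)) {
      stop("`", arg, "` must be numeric or complex.", call. = FALSE)
    }
    storage.mode(x) <- "double"
  }
  x
}

check_finite_matrix <- function(x, arg = deparse(substitute(x))) {
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x)))) {
    stop(
      "`", arg, "` contains NA/NaN/Inf values; apply complete-case ",
      "filtering (see `filter_complete_cases()`) before transforming.",
      call. = FALSE
    )
  }
  invisible(x)
}

#' Seeded uniform random phase matrix
#'
#' Initial hologram-plane phases: i.i.d. angles drawn uniformly on
#' \eqn{[0, 2\pi)}. The global RNG state is left untouched.
#'
#' @param n_rows,n_cols Positive integer dimensions.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return Numeric `n_rows` x `n_cols` matrix of angles in radians.
#' @export
init_phase <- function(n_rows, n_cols, seed) {
  if (n_rows < 1L || n_cols < 1L) {
    stop("Phase matrix dimensions must be positive.", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    matrix(stats::runif(n_rows * n_cols, 0, 2 * pi), n_rows, n_cols)
  })
}

wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

#' Gerchberg-Saxton iteration between image and frequency planes
#'
#' Runs the classical error-reduction cycle: form the image-plane field
#' from the source magnitudes and the current hologram phase, transform
#' forward, keep the phase while imposing the target magnitudes, transform
#' back, and keep the new image-plane phase for the next cycle. The error
#' trace records, per cycle, the mean squared mismatch between the
#' achieved spectral magnitudes and the target magnitudes.
#'
#' @param source_magnitudes Non-negative numeric matrix `|f|` (image
#'   plane).
#' @param target_magnitudes Non-negative numeric matrix of the same shape
#'   (frequency plane); for spectral equalization this is all ones.
#' @param cycles Number of iterations (default 50).
#' @param seed Seed for the random initial phase.
#' @return A `gs_state` object: list with `k` (cycles run),
#'   `phase_hologram` and `phase_target` (radian matrices in
#'   \eqn{[0, 2\pi)}), `error_trace` (length-`k` non-increasing vector),
#'   and `source_magnitudes`.
#' @export
gs_iterate <- function(source_magnitudes, target_magnitudes, cycles = 50L,
                       seed = 1L) {
  src <- as_spectral_matrix(source_magnitudes)
  tgt <- as_spectral_matrix(target_magnitudes)
  check_finite_matrix(src, "source_magnitudes")
  check_finite_matrix(tgt, "target_magnitudes")
  src <- Re(src); tgt <- Re(tgt)
  if (!identical(dim(src), dim(tgt))) {
    stop("source and target magnitude matrices must share a shape.",
         call. = FALSE)
  }
  if (any(src < 0) || any(tgt < 0)) {
    stop("Magnitudes must be non-negative.", call. = FALSE)
  }
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) {
    stop("`cycles` must be a positive integer.", call. = FALSE)
  }

  phase_h <- init_phase(nrow(src), ncol(src), seed)
  phase_t <- matrix(0, nrow(src), ncol(src))
  err <- numeric(cycles)
  for (k in seq_len(cycles)) {
    field <- src * exp(1i * phase_h)
    spectrum <- dft2(field)
    err[k] <- mean((Mod(spectrum) - tgt)^2)
    phase_t <- wrap_angle(Arg(spectrum))
    constrained <- tgt * exp(1i * phase_t)
    back <- idft2(constrained)
    phase_h <- wrap_angle(Arg(back))
  }

  structure(
    list(
      k = cycles,
      phase_hologram = phase_h,
      phase_target = phase_t,
      error_trace = err,
      source_magnitudes = src,
      seed = as.integer(seed)
    ),
    class = "gs_state"
  )
}

#' @export
print.gs_state <- function(x, ...) {
  cat("<gs_state> ", nrow(x$source_magnitudes), "x",
      ncol(x$source_magnitudes), " matrix, ", x$k, " cycles\n", sep = "")
  cat("  final magnitude-mismatch error: ",
      format(x$error_trace[x$k], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Configuration for the Gerchberg-Saxton transform
#'
#' @param cycles Number of GS cycles (default 50).
#' @param seed Integer seed for the random phase initialization.
#' @param output_mode How the complex image-plane field is reduced to a
#'   real matrix: `"modulus"` (default) or `"real_part"`.
#' @param rescale Post-transform rescaling: `"minmax01"` (default,
#'   min-max over the whole matrix to \eqn{[0,1]}) or `"none"`.
#' @param batch_size Rows per stratified batch for cohort-level
#'   transforms, or `"all"` (default) for a single full-matrix transform.
#' @return A `gs_config` list.
#' @export
gs_config <- function(cycles = 50L, seed = 1L,
                      output_mode = c("modulus", "real_part"),
                      rescale = c("minmax01", "none"),
                      batch_size = "all") {
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1L) {
    stop("`cycles` must be a positive integer.", call. = FALSE)
  }
  if (!identical(batch_size, "all")) {
    batch_size <- as.integer(batch_size)
    if (is.na(batch_size) || batch_size < 1L) {
      stop("`batch_size` must be a positive integer or \"all\".",
           call. = FALSE)
    }
  }
  structure(
    list(
      cycles = cycles,
      seed = as.integer(seed),
      output_mode = match.arg(output_mode),
      rescale = match.arg(rescale),
      batch_size = batch_size
    ),
    class = "gs_config"
  )
}

#' Gerchberg-Saxton spectral-equalization transform
#'
#' Maps a real feature matrix to its bias-mitigated counterpart: the GS
#' iteration is run with the matrix's absolute values as source
#' magnitudes and an all-ones target spectrum, the retrieved target-plane
#' phase is placed on a unit-magnitude spectrum, and the inverse
#' transform of that flat spectrum is the complex output field `z`
#' (which satisfies \eqn{|\mathrm{dft2}(z)| \equiv 1}). The returned real
#' matrix is `z` reduced per `output_mode` and rescaled per `rescale`.
#'
#' @param x Real feature matrix (or data frame); finite entries only.
#' @param config A [gs_config()].
#' @return List with `values` (real matrix, same shape as `x`),
#'   `field` (the complex image-plane field `z`), and `state`
#'   (the [gs_iterate()] `gs_state`).
#' @export
#' @examples
#' out <- gs_transform(matrix(runif(32, 0, 22), 8, 4), gs_config(seed = 7))
#' range(out$values)
gs_transform <- function(x, config = gs_config()) {
  x <- as_spectral_matrix(x)
  check_finite_matrix(x, "x")
  x <- Re(x)

  state <- gs_iterate(abs(x), matrix(1, nrow(x), ncol(x)),
                      cycles = config$cycles, seed = config$seed)
  z <- idft2(exp(1i * state$phase_target))
  values <- switch(config$output_mode,
    modulus = Mod(z),
    real_part = Re(z)
  )
  if (config$rescale == "minmax01") {
    values <- rescale_minmax(values)
  }
  dimnames(values) <- dimnames(x)
  list(values = values, field = z, state = state)
}

rescale_minmax <- function(values) {
  rng <- range(values)
  if (rng[2] - rng[1] <= 0) {
    # degenerate constant matrix: midpoint of the unit interval
    return(matrix(0.5, nrow(values), ncol(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Group-balanced batches for large-cohort transforms
#'
#' Partitions cohort rows into batches in which every protected group is
#' represented in near-cohort proportion (largest-remainder allocation:
#' each group's rows are shuffled and dealt across batches so that any
#' batch's group count differs from the proportional share by at most one
#' row). Spectral equalization acts within a batch only, so equitable
#' batches are what lets a batched transform approximate a full-matrix
#' one.
#'
#' @param cohort A cohort tibble with a `group` column (see
#'   [generate_cohort()]), or any data frame with a `group` column.
#' @param batch_size Target rows per batch, or `"all"` for one batch.
#' @param seed Seed for the within-group shuffling.
#' @return List of integer row-index vectors: disjoint, exhaustive.
#' @export
stratified_batches <- function(cohort, batch_size = "all", seed = 1L) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  n <- nrow(cohort)
  groups <- as.character(cohort$group)
  if (identical(batch_size, "all")) {
    return(list(seq_len(n)))
  }
  batch_size <- as.integer(batch_size)
  n_groups <- length(unique(groups))
  if (batch_size < n_groups) {
    stop("`batch_size` (", batch_size, ") is smaller than the number of ",
         "groups (", n_groups, "); every batch must be able to hold each ",
         "group.", call. = FALSE)
  }
  n_batches <- max(1L, ceiling(n / batch_size))

  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) batches[[b]] <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (g in unique(groups)) {
      idx <- sample(which(groups == g))
      sizes <- largest_remainder(length(idx), n_batches)
      start <- 1L
      for (b in seq_len(n_batches)) {
        if (sizes[b] > 0L) {
          batches[[b]] <- c(batches[[b]], idx[start:(start + sizes[b] - 1L)])
          start <- start + sizes[b]
        }
      }
    }
  })
  lapply(batches, sort)
}

# Split `total` into `parts` integers summing to total, each equal to the
# proportional share rounded down plus at most one remainder unit.
largest_remainder <- function(total, parts) {
  share <- total / parts
  base <- floor(rep(share, parts))
  remainder <- total - sum(base)
  frac <- rep(share, parts) - base
  order_idx <- order(frac, seq_len(parts), decreasing = c(TRUE, FALSE),
                     method = "radix")
  if (remainder > 0L) {
    base[order_idx[seq_len(remainder)]] <- base[order_idx[seq_len(remainder)]] + 1L
  }
  as.integer(base)
}

#' Apply the GS transform to a cohort's feature columns
#'
#' Convenience wrapper used by the experiment pipeline: transforms the
#' feature columns of a cohort tibble (optionally in group-stratified
#' batches per `config$batch_size`) and returns the cohort with features
#' replaced by their transformed values. Outcome and group columns are
#' untouched. When batching, min-max rescaling is applied once over the
#' assembled matrix so batches share a scale.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (columns
#'   `feature_*`, `outcome`, `group`).
#' @param config A [gs_config()].
#' @return The cohort tibble with transformed features; the per-batch
#'   `gs_state` diagnostics are attached as attribute `"gs_states"`.
#' @export
gs_transform_cohort <- function(cohort, config = gs_config()) {
  feats <- feature_columns(cohort)
  x <- as.matrix(cohort[feats])
  batches <- stratified_batches(cohort, config$batch_size,
                                seed = config$seed)
  inner <- config
  inner$rescale <- "none"
  out <- matrix(NA_real_, nrow(x), ncol(x))
  states <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    res <- gs_transform(x[idx, , drop = FALSE], inner)
    out[idx, ] <- res$values
    states[[b]] <- res$state
  }
  if (config$rescale == "minmax01") out <- rescale_minmax(out)
  cohort[feats] <- as.data.frame(out)
  attr(cohort, "gs_states") <- states
  cohort
}

feature_columns <- function(cohort) {
  grep("^feature_", names(cohort), value = TRUE)
}
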