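#' Specification of the feed-forward mortality classifier
#'
#' A small fully connected network with a reversed-pyramid hidden stack
#' (64, 32, 16 rectified-linear units), a two-unit softmax output, the
#' Adam optimizer, class-weighted cross-entropy and early stopping on
#' validation loss — the architecture used identically for benchmark and
#' transformed data so any metric difference is attributable to the
#' data.
#'
#' @param input_dim Number of input features (default 35).
#' @param hidden_sizes Strictly decreasing hidden-layer widths
#'   (default `c(64, 32, 16)`).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed for initialization and shuffling.
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(input_dim = 35L, hidden_sizes = c(64L, 32L, 16L),
                     max_epochs = 200L, patience = 10L, batch_size = 64L,
                     learning_rate = 1e-3, seed = 1L) {
  if (input_dim < 1L) stop("`input_dim` must be positive.", call. = FALSE)
  if (length(hidden_sizes) > 1L && any(diff(hidden_sizes) >= 0)) {
    stop("`hidden_sizes` must be strictly decreasing (reversed pyramid).",
         call. = FALSE)
  }
  structure(
    list(
      input_dim = as.integer(input_dim),
      hidden_sizes = as.integer(hidden_sizes),
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      seed = as.integer(seed)
    ),
    class = "mlp_spec"
  )
}

#' Balanced class weights
#'
#' Inverse-frequency weights \eqn{w_c = n / (2 n_c)} so each class
#' carries equal total mass in the loss.
#'
#' @param y Binary 0/1 label vector with both classes present.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
#' @examples
#' class_weights(c(rep(0, 90), rep(1, 10)))
class_weights <- function(y) {
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1.", call. = FALSE)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  if (n0 == 0L || n1 == 0L) {
    stop("Both classes must be present to balance weights.", call. = FALSE)
  }
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Train the feed-forward classifier
#'
#' Minibatch gradient training with Adam and class-weighted softmax
#' cross-entropy. After each epoch the class-weighted validation loss is
#' evaluated; when it fails to improve for `patience` consecutive
#' epochs, training stops and the best-epoch parameters are restored.
#' With a fixed seed (initialization and shuffling) training is
#' reproducible under single-threaded execution.
#'
#' @param spec An [mlp_spec()].
#' @param x_train,y_train Training features (matrix, `input_dim`
#'   columns) and binary labels (both classes required).
#' @param x_val,y_val Validation set monitored for early stopping.
#' @return A `gs_mlp` model: parameters, per-epoch `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`), `best_epoch`, the spec, and
#'   the class weights used.
#' @export
train_mlp <- function(spec, x_train, y_train, x_val, y_val) {
  x_train <- as_feature_matrix(x_train)
  x_val <- as_feature_matrix(x_val)
  if (ncol(x_train) != spec$input_dim) {
    stop("x_train has ", ncol(x_train), " columns; spec expects ",
         spec$input_dim, ".", call. = FALSE)
  }
  if (any(!is.finite(x_train)) || any(!is.finite(x_val))) {
    stop("Features must be finite.", call. = FALSE)
  }
  w <- class_weights(y_train)   # errors on single-class labels

  # inputs mapped to [0,1] by one global train min/max (not
  # per-column): training is kept numerically well-scaled while the
  # relative variance of the columns -- the information distribution
  # the spectral transform acts on -- is preserved
  center <- min(x_train)
  scale_rng <- max(x_train) - center
  if (scale_rng <= 0) scale_rng <- 1
  x_train <- (x_train - center) / scale_rng
  x_val <- (x_val - center) / scale_rng

  sizes <- c(spec$input_dim, spec$hidden_sizes, 2L)
  n_layers <- length(sizes) - 1L

  withr::with_seed(spec$seed, {
    params <- lapply(seq_len(n_layers), function(l) {
      # He initialization for rectified-linear stacks
      list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                sd = sqrt(2 / sizes[l])),
                   sizes[l], sizes[l + 1L]),
        b = rep(0, sizes[l + 1L])
      )
    })
    adam <- lapply(params, function(p) {
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    })
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L

    n <- nrow(x_train)
    sw_train <- unname(w[as.character(y_train)])
    sw_val <- unname(w[as.character(y_val)])
    history <- matrix(NA_real_, spec$max_epochs, 2L)
    best_val <- Inf
    best_params <- params
    best_epoch <- 0L
    stall <- 0L

    for (epoch in seq_len(spec$max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      epoch_loss <- 0
      for (st in starts) {
        rows <- idx[st:min(st + spec$batch_size - 1L, n)]
        xb <- x_train[rows, , drop = FALSE]
        yb <- y_train[rows]
        swb <- sw_train[rows]

        fw <- mlp_forward(params, xb)
        probs <- fw$probs
        m <- length(rows)
        loss <- -sum(swb * log(pmax(probs[cbind(seq_len(m), yb + 1L)],
                                    1e-12))) / sum(swb)
        epoch_loss <- epoch_loss + loss * m

        # backprop: weighted softmax cross-entropy gradient
        dz <- probs
        dz[cbind(seq_len(m), yb + 1L)] <-
          dz[cbind(seq_len(m), yb + 1L)] - 1
        dz <- dz * (swb / sum(swb))
        grads <- mlp_backward(params, fw, dz)

        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (l in seq_len(n_layers)) {
          adam[[l]]$mW <- beta1 * adam[[l]]$mW + (1 - beta1) * grads[[l]]$W
          adam[[l]]$vW <- beta2 * adam[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
          adam[[l]]$mb <- beta1 * adam[[l]]$mb + (1 - beta1) * grads[[l]]$b
          adam[[l]]$vb <- beta2 * adam[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
          params[[l]]$W <- params[[l]]$W - spec$learning_rate *
            (adam[[l]]$mW / corr1) / (sqrt(adam[[l]]$vW / corr2) + eps)
          params[[l]]$b <- params[[l]]$b - spec$learning_rate *
            (adam[[l]]$mb / corr1) / (sqrt(adam[[l]]$vb / corr2) + eps)
        }
      }

      val_probs <- mlp_forward(params, x_val)$probs
      val_loss <- -sum(sw_val *
                         log(pmax(val_probs[cbind(seq_along(y_val),
                                                  y_val + 1L)], 1e-12))) /
        sum(sw_val)
      history[epoch, ] <- c(epoch_loss / n, val_loss)

      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$patience) break
      }
    }
  })

  ran <- which(!is.na(history[, 1L]))
  structure(
    list(
      params = best_params,
      history = tibble::tibble(
        epoch = ran,
        train_loss = history[ran, 1L],
        val_loss = history[ran, 2L]
      ),
      best_epoch = best_epoch,
      best_val_loss = best_val,
      class_weights = w,
      center = center,
      scale = scale_rng,
      spec = spec
    ),
    class = "gs_mlp"
  )
}

mlp_forward <- function(params, x) {
  acts <- vector("list", length(params) + 1L)
  acts[[1L]] <- x
  a <- x
  for (l in seq_along(params)) {
    z <- sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, `+`)
    a <- if (l < length(params)) pmax(z, 0) else z
    acts[[l + 1L]] <- a
  }
  # row-wise softmax, max-shifted for stability
  z <- acts[[length(acts)]]
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(acts = acts, probs = probs)
}

mlp_backward <- function(params, fw, dz) {
  n_layers <- length(params)
  grads <- vector("list", n_layers)
  delta <- dz
  for (l in rev(seq_len(n_layers))) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$W)) * (fw$acts[[l]] > 0)
    }
  }
  grads
}

#' Class-probability predictions from a trained classifier
#'
#' @param model A `gs_mlp` from [train_mlp()].
#' @param x Feature matrix with `input_dim` columns.
#' @return Numeric matrix, one row per input row, columns
#'   `class_0`/`class_1` summing to one (softmax simplex).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "gs_mlp"))
  x <- as_feature_matrix(x)
  if (ncol(x) != model$spec$input_dim) {
    stop("Input has ", ncol(x), " columns; model expects ",
         model$spec$input_dim, ".", call. = FALSE)
  }
  x <- (x - model$center) / model$scale
  probs <- mlp_forward(model$params, x)$probs
  colnames(probs) <- c("class_0", "class_1")
  probs
}

#' @export
predict.gs_mlp <- function(object, newdata, type = c("prob", "class"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  probs <- predict_proba(object, newdata)
  if (type == "prob") return(probs)
  as.integer(probs[, "class_1"] >= threshold)
}

#' @export
print.gs_mlp <- function(x, ...) {
  cat("<gs_mlp> ", x$spec$input_dim, " -> ",
      paste(x$spec$hidden_sizes, collapse = " -> "),
      " -> 2 (softmax)\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best epoch ",
      x$best_epoch, " (val loss ", format(x$best_val_loss, digits = 5),
      ")\n", sep = "")
  invisible(x)
}

#' Per-epoch training history
#'
#' @param x A `gs_mlp`.
#' @param ... Unused.
#' @return Tibble: `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.gs_mlp <- function(x, ...) {
  x$history
}

#' One-row training summary
#'
#' @param x A `gs_mlp`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, best epoch, best validation loss.
#' @export
glance.gs_mlp <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    early_stopped = nrow(x$history) < x$spec$max_epochs
  )
}
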