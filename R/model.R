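#' Training hyperparameters for the fusion network
#'
#' Full-batch gradient descent with momentum on mean-squared error, early
#' stopping on a held-out validation split of the training minutes.
#'
#' @param learning_rate Step size (default 0.1; full-batch gradients on
#'   \[0,1\]-scaled targets are small, so larger steps than the textbook 0.01
#'   are needed to converge in a few thousand epochs).
#' @param momentum Momentum coefficient (default 0.9).
#' @param max_epochs Maximum training epochs (default 10000).
#' @param patience Early-stopping patience in epochs (default 500).
#' @param val_fraction Fraction of training rows held out for the stopping
#'   criterion (default 0.1).
#' @param hidden Hidden-layer sizes, default `c(4, 7)` (the 4-4-7-1 network).
#' @return An `ann_control` list.
#' @export
ann_control <- function(learning_rate = 0.1, momentum = 0.9,
                        max_epochs = 10000, patience = 500,
                        val_fraction = 0.1, hidden = c(4, 7)) {
  structure(list(
    learning_rate = learning_rate, momentum = momentum,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    val_fraction = val_fraction, hidden = as.integer(hidden)
  ), class = "ann_control")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Validate and assemble the design matrix; drops degenerate-flagged minutes.
prepare_training <- function(features, targets, feature_names = NULL) {
  stopifnot(is.data.frame(features))
  if (is.data.frame(targets)) targets <- targets$value %||% targets[[2]]
  targets <- as.numeric(targets)
  if (nrow(features) != length(targets)) {
    abort("`features` and `targets` must have the same number of rows.")
  }
  feature_names <- feature_names %||% intersect(doa_features(), names(features))
  if (!length(feature_names)) abort("no feature columns found.")
  keep <- rep(TRUE, nrow(features))
  if ("flags" %in% names(features)) {
    flagged <- !is.na(features$flags) & nzchar(features$flags)
    if (any(flagged)) {
      message(sprintf("excluding %d degenerate-flagged minute(s) from training.",
                      sum(flagged)))
      keep <- keep & !flagged
    }
  }
  X <- as.matrix(features[keep, feature_names, drop = FALSE])
  y <- targets[keep]
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(rowSums(X)))[1]
    mins <- features$minute[keep] %||% seq_len(nrow(X))
    abort(sprintf("non-finite feature value at minute %s.", mins[bad]))
  }
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100)) {
    abort("targets must be finite and within [0, 100].")
  }
  list(X = X, y = y, feature_names = feature_names)
}

scale_fit <- function(X) {
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  list(center = center, scale = scl)
}

scale_apply <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

ann_forward <- function(Ws, bs, X) {
  A <- list(X)
  for (l in seq_along(Ws)) {
    A[[l + 1]] <- sigmoid(A[[l]] %*% Ws[[l]] +
                            matrix(bs[[l]], nrow(X), length(bs[[l]]), byrow = TRUE))
  }
  A
}

#' Train the feedforward fusion network
#'
#' Fits the 4-4-7-1 multilayer perceptron (logistic activations throughout,
#' output rescaled to 0-100) by full-batch backpropagation against the
#' per-minute reference index. Inputs are z-scored with training statistics;
#' targets are scaled to \[0,1\]. Training is deterministic given `seed`.
#'
#' @param features Tibble with columns among `pe`, `br`, `sef95`, `sfs` (plus
#'   optional `minute`, `flags`); degenerate-flagged minutes are excluded.
#' @param targets Numeric reference-index values in \[0,100\] (or a tibble
#'   with a `value` column), one per feature row.
#' @param hyper An [ann_control()].
#' @param seed Integer seed for weight initialization and the validation split.
#' @param feature_names Optional explicit feature subset.
#' @return A `doa_model` (kind `"ann"`).
#' @export
train_doa_ann <- function(features, targets, hyper = ann_control(), seed = 1,
                          feature_names = NULL) {
  prep <- prepare_training(features, targets, feature_names)
  if (nrow(prep$X) < 20) abort("need at least 20 aligned (feature, target) rows.")
  scaler <- scale_fit(prep$X)
  X <- scale_apply(prep$X, scaler)
  y <- prep$y / 100
  n <- nrow(X)
  sizes <- c(ncol(X), hyper$hidden, 1L)

  with_seed(seed, {
    n_val <- max(1L, round(hyper$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

    Ws <- list(); bs <- list(); vW <- list(); vb <- list()
    for (l in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[l]
      Ws[[l]] <- matrix(runif(fan_in * sizes[l + 1], -1, 1) / sqrt(fan_in),
                        fan_in, sizes[l + 1])
      bs[[l]] <- numeric(sizes[l + 1])
      vW[[l]] <- Ws[[l]] * 0
      vb[[l]] <- bs[[l]] * 0
    }

    best <- list(val = Inf, Ws = Ws, bs = bs, epoch = 0L)
    stall <- 0L
    hist_tr <- numeric(0); hist_va <- numeric(0)
    ntr <- nrow(Xtr)
    for (epoch in seq_len(hyper$max_epochs)) {
      A <- ann_forward(Ws, bs, Xtr)
      out <- A[[length(A)]][, 1]
      err <- out - ytr
      # backprop: delta at output for MSE with sigmoid
      delta <- (2 / ntr) * err * out * (1 - out)
      delta <- matrix(delta, ncol = 1)
      for (l in rev(seq_along(Ws))) {
        gW <- t(A[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          Al <- A[[l]]
          delta <- (delta %*% t(Ws[[l]])) * Al * (1 - Al)
        }
        vW[[l]] <- hyper$momentum * vW[[l]] - hyper$learning_rate * gW
        vb[[l]] <- hyper$momentum * vb[[l]] - hyper$learning_rate * gb
        Ws[[l]] <- Ws[[l]] + vW[[l]]
        bs[[l]] <- bs[[l]] + vb[[l]]
      }
      tr_mse <- mean(err^2)
      va_out <- ann_forward(Ws, bs, Xva)
      va_mse <- mean((va_out[[length(va_out)]][, 1] - yva)^2)
      hist_tr <- c(hist_tr, tr_mse); hist_va <- c(hist_va, va_mse)
      if (va_mse < best$val - 1e-12) {
        best <- list(val = va_mse, Ws = Ws, bs = bs, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hyper$patience) break
      }
    }

    structure(
      list(
        kind = "ann",
        layer_sizes = sizes,
        weights = best$Ws, biases = best$bs,
        input_scaler = scaler,
        feature_names = prep$feature_names,
        output_range = c(0, 100),
        train_seed = as.integer(seed),
        hyper = hyper,
        n_train = n,
        epochs_run = length(hist_tr),
        best_epoch = best$epoch,
        loss_history = tibble::tibble(
          epoch = seq_along(hist_tr), train_mse = hist_tr, val_mse = hist_va
        )
      ),
      class = "doa_model"
    )
  })
}

#' Train the linear epsilon-SVR baseline
#'
#' Linear support-vector regression of the reference index on the z-scored
#' features (libsvm epsilon-regression). The primal weight vector is
#' recovered from the support coefficients (`w = sum(beta_n x_n)`).
#'
#' @inheritParams train_doa_ann
#' @param C Box penalty (default 10).
#' @param epsilon Tube half-width in index units (default 2).
#' @return A `doa_model` (kind `"svr"`).
#' @export
train_doa_svr <- function(features, targets, C = 10, epsilon = 2,
                          feature_names = NULL) {
  prep <- prepare_training(features, targets, feature_names)
  scaler <- scale_fit(prep$X)
  X <- scale_apply(prep$X, scaler)
  fit <- e1071::svm(X, prep$y, type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(
    list(
      kind = "svr",
      fit = fit,
      w = w, b = -fit$rho,
      C = C, epsilon = epsilon,
      input_scaler = scaler,
      feature_names = prep$feature_names,
      output_range = c(0, 100),
      n_train = nrow(X)
    ),
    class = "doa_model"
  )
}

#' Predict the 0-100 DoA index
#'
#' @param model A `doa_model` from [train_doa_ann()] or [train_doa_svr()].
#' @param features Tibble with the model's feature columns (and optionally
#'   `minute`, `flags`).
#' @return Tibble with columns `minute` and `index` (clipped to \[0,100\]);
#'   degenerate flags are carried through in `flags` when present.
#' @export
predict_index <- function(model, features) {
  stopifnot(inherits(model, "doa_model"))
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  if (any(!is.finite(X))) abort("non-finite feature values in prediction input.")
  X <- scale_apply(X, model$input_scaler)
  raw <- if (model$kind == "ann") {
    A <- ann_forward(model$weights, model$biases, X)
    A[[length(A)]][, 1] * 100
  } else {
    drop(X %*% model$w) + model$b
  }
  out <- tibble::tibble(
    minute = features$minute %||% (seq_len(nrow(X)) - 1L),
    index = pmin(100, pmax(0, raw))
  )
  if ("flags" %in% names(features)) out$flags <- features$flags
  out
}

#' @export
predict.doa_model <- function(object, newdata, ...) {
  predict_index(object, newdata)$index
}

#' @export
print.doa_model <- function(x, ...) {
  if (x$kind == "ann") {
    cat(sprintf("<doa_model: ann %s> %d training minutes, %d epochs (best %d)\n",
                paste(x$layer_sizes, collapse = "-"), x$n_train,
                x$epochs_run, x$best_epoch))
  } else {
    cat(sprintf("<doa_model: linear svr> C=%g eps=%g, %d training minutes\n",
                x$C, x$epsilon, x$n_train))
  }
  invisible(x)
}

#' Hidden-node count heuristic
#'
#' The simple additive rule `d = a + b + c` used to enumerate candidate
#' hidden-layer widths from the input count `a`, output count `b` and a
#' regulation constant `c` in 1..10. It documents the search that produced
#' the 7-node second hidden layer; the concrete 4-4-7-1 architecture is
#' fixed independently.
#'
#' @param a Number of input nodes (>= 1).
#' @param b Number of output nodes (>= 1).
#' @param c Regulation constant in 1..10 (may be a vector).
#' @return Candidate hidden-node counts.
#' @export
hidden_nodes_heuristic <- function(a, b, c) {
  if (a < 1 || b < 1) abort("`a` and `b` must be >= 1.")
  if (any(c < 1 | c > 10)) abort("`c` must lie in 1..10.")
  as.integer(a + b + c)
}

#' @export
tidy.doa_model <- function(x, ...) {
  if (x$kind == "svr") {
    return(tibble::tibble(
      term = c(x$feature_names, "(intercept)"),
      estimate = c(x$w, x$b)
    ))
  }
  rows <- purrr::imap(x$weights, function(W, l) {
    from <- if (l == 1) x$feature_names else paste0("h", l - 1, "_", seq_len(nrow(W)))
    to <- if (l == length(x$weights)) "index" else paste0("h", l, "_", seq_len(ncol(W)))
    dplyr::bind_rows(
      tidyr::expand_grid(from = from, to = to) |>
        dplyr::mutate(layer = l, estimate = as.vector(t(W))) |>
        dplyr::select("layer", "from", "to", "estimate"),
      tibble::tibble(layer = l, from = "(bias)", to = to,
                     estimate = x$biases[[l]])
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
glance.doa_model <- function(x, ...) {
  if (x$kind == "svr") {
    tibble::tibble(
      kind = "svr", n_train = x$n_train,
      n_features = length(x$feature_names),
      C = x$C, epsilon = x$epsilon,
      n_support = nrow(x$fit$SV)
    )
  } else {
    tibble::tibble(
      kind = "ann", n_train = x$n_train,
      n_features = length(x$feature_names),
      epochs_run = x$epochs_run, best_epoch = x$best_epoch,
      train_mse = tail(x$loss_history$train_mse, 1),
      val_mse = min(x$loss_history$val_mse)
    )
  }
}

#' Serialize a fitted model to JSON
#'
#' @param model A `doa_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_doa_model <- function(model, path) {
  stopifnot(inherits(model, "doa_model"))
  obj <- if (model$kind == "ann") {
    list(
      kind = "ann", layer_sizes = model$layer_sizes,
      weights = model$weights,
      biases = model$biases,
      scaler = model$input_scaler, feature_names = model$feature_names,
      train_seed = model$train_seed, n_train = model$n_train
    )
  } else {
    list(
      kind = "svr", w = as.list(model$w), b = model$b,
      C = model$C, epsilon = model$epsilon,
      scaler = model$input_scaler, feature_names = model$feature_names,
      n_train = model$n_train
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model back
#'
#' @param path JSON path written by [write_doa_model()].
#' @return A `doa_model` usable with [predict_index()] (SVR models are
#'   restored in linear `w, b` form).
#' @export
read_doa_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- list(center = unlist(obj$scaler$center),
                 scale = unlist(obj$scaler$scale))
  names(scaler$center) <- obj$feature_names
  names(scaler$scale) <- obj$feature_names
  if (obj$kind == "ann") {
    structure(list(
      kind = "ann", layer_sizes = obj$layer_sizes,
      weights = lapply(obj$weights, function(W) {
        if (is.matrix(W)) W else matrix(unlist(W), nrow = length(W), byrow = TRUE)
      }),
      biases = lapply(obj$biases, as.numeric),
      input_scaler = scaler, feature_names = obj$feature_names,
      output_range = c(0, 100), train_seed = obj$train_seed,
      n_train = obj$n_train, epochs_run = NA_integer_,
      best_epoch = NA_integer_, loss_history = tibble::tibble()
    ), class = "doa_model")
  } else {
    structure(list(
      kind = "svr", fit = NULL, w = unlist(obj$w), b = obj$b,
      C = obj$C, epsilon = obj$epsilon, input_scaler = scaler,
      feature_names = obj$feature_names, output_range = c(0, 100),
      n_train = obj$n_train
    ), class = "doa_model")
  }
}
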