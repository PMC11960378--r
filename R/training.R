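#' Training configuration
#'
#' Defaults encode the training regime of the detection pipeline: focal
#' binary cross-entropy for the severe class imbalance (alpha 0.25,
#' gamma 2), the adaptive-moment (Adam) optimizer as the adaptive learning
#' rate method, L2 regularization on convolution and dense weights,
#' dropout in the recurrent/dense head, and keep-best-by-validation-F1
#' checkpointing over (by default) 100 epochs.
#'
#' @param epochs Number of passes over the training stream (>= 1).
#' @param batch_size Examples per optimization step.
#' @param focal_gamma Focusing exponent (>= 0).
#' @param focal_alpha Positive-class weight in (0, 1).
#' @param learning_rate Initial Adam step size.
#' @param l2_weight L2 coefficient on convolution and dense kernel weights.
#' @param dropout_rate Dropout fraction in the head during training.
#' @param seed Integer seed; fixes shuffling, dropout and (if the model is
#'   rebuilt) initialization.
#' @param early_stop_f1 Optional validation frame-F1 at which training
#'   stops early (checkpointing stays keep-best regardless); `NULL`
#'   disables.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, focal_gamma = 2,
                         focal_alpha = 0.25, learning_rate = 1e-3,
                         l2_weight = 1e-4, dropout_rate = 0.3, seed = 1L,
                         early_stop_f1 = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, focal_gamma >= 0,
            focal_alpha > 0, focal_alpha < 1, learning_rate > 0,
            l2_weight >= 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 learning_rate = learning_rate, l2_weight = l2_weight,
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 early_stop_f1 = early_stop_f1,
                 checkpoint_policy = "keep-best-by-validation-F1"),
            class = "train_config")
}

#' Focal binary cross-entropy
#'
#' For a per-frame probability `p` and binary label `y`:
#' label 1 contributes `-alpha * (1 - p)^gamma * log(p)`, label 0
#' contributes `-(1 - alpha) * p^gamma * log(1 - p)`. Probabilities are
#' clipped to `[eps, 1 - eps]`; masked frames contribute nothing; the
#' batch loss is the mean over unmasked frames. With `gamma = 0` and
#' `alpha = 0.5` this is exactly half the ordinary binary cross-entropy.
#'
#' @param prob Numeric array of probabilities.
#' @param label Binary labels, same shape.
#' @param alpha Positive-class weight.
#' @param gamma Focusing exponent.
#' @param mask Optional 0/1 array; frames with 0 are excluded.
#' @param eps Clipping constant.
#' @return Scalar mean loss over unmasked frames.
#' @export
focal_loss <- function(prob, label, alpha = 0.25, gamma = 2, mask = NULL,
                       eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  l <- ifelse(label > 0.5,
              -alpha * (1 - p)^gamma * log(p),
              -(1 - alpha) * p^gamma * log(1 - p))
  if (is.null(mask)) return(mean(l))
  m <- sum(mask > 0)
  if (m == 0L) return(0)
  sum(l[mask > 0]) / m
}

# gradient of the mean focal loss w.r.t. the probability (before the
# activation jacobian); prob clipped as in the loss, with zero gradient
# through the clamp
focal_grad_p <- function(prob, label, alpha, gamma, mask, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  pos <- label > 0.5
  dl_dp <- ifelse(pos,
                  alpha * (gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) -
                             (1 - p)^gamma / p),
                  (1 - alpha) * (p^gamma / (1 - p) -
                                   gamma * p^(pmax(gamma - 1, 0)) *
                                   log(1 - p)))
  dl_dp[prob < eps | prob > 1 - eps] <- 0
  m <- sum(mask > 0)
  if (m == 0L) return(dl_dp * 0)
  dl_dp * (mask > 0) / m
}

# chain through the output activation: d(loss)/dz
focal_grad_z <- function(prob, z, label, alpha, gamma, mask, activation,
                         eps = 1e-7) {
  dp <- focal_grad_p(prob, label, alpha, gamma, mask, eps)
  if (activation == "sigmoid") dp * prob * (1 - prob) else dp * (z > 0)
}

# elementwise tree operations over nested parameter lists
tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

# walk two parameter trees in parallel; match children by name (gradient
# trees are assembled in reverse layer order)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    key <- names(a)
    out <- lapply(seq_along(a), function(i) {
      bi <- if (!is.null(key) && !is.null(names(b))) b[[key[i]]] else b[[i]]
      tree_map2(f, a[[i]], bi)
    })
    names(out) <- key
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                     opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   opt$m, opt$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, opt = opt)
}

# add L2 gradients on convolution and dense kernel weights only (names
# "w" under conv*/proj/dense* nodes; recurrent and normalization
# parameters are not penalized)
add_l2 <- function(grads, params, l2) {
  if (l2 <= 0) return(grads)
  rec <- function(g, p, path) {
    if (is.list(g)) {
      out <- lapply(names(g), function(nm) rec(g[[nm]], p[[nm]],
                                               c(path, nm)))
      names(out) <- names(g)
      return(out)
    }
    leaf <- path[length(path)]
    parent <- if (length(path) >= 2L) path[length(path) - 1L] else ""
    penalized <- leaf == "w" &&
      grepl("^(conv|proj|dense)", parent)
    if (penalized) g + l2 * p else g
  }
  rec(grads, params, character())
}

# L2 penalty value matching add_l2 (0.5 * l2 * sum w^2 over penalized)
l2_penalty <- function(params, l2) {
  if (l2 <= 0) return(0)
  total <- 0
  rec <- function(p, path) {
    if (is.list(p)) {
      for (nm in names(p)) rec(p[[nm]], c(path, nm))
      return(invisible())
    }
    leaf <- path[length(path)]
    parent <- if (length(path) >= 2L) path[length(path) - 1L] else ""
    if (leaf == "w" && grepl("^(conv|proj|dense)", parent)) {
      total <<- total + sum(p * p)
    }
  }
  rec(params, character())
  0.5 * l2 * total
}

# frame-level confusion at a 0.5 threshold over unmasked frames
frame_f1 <- function(prob, label, mask) {
  sel <- mask > 0
  pred <- prob[sel] >= 0.5
  truth <- label[sel] > 0.5
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

gather_labels <- function(examples) {
  list(y = t(vapply(examples, `[[`, numeric(length(examples[[1]]$y)), "y")),
       mask = t(vapply(examples, `[[`,
                       numeric(length(examples[[1]]$mask)), "mask")))
}

#' Train a model on feature-example streams
#'
#' Mini-batch Adam on the focal loss, with L2 regularization on
#' convolution and dense kernels, dropout active in the head during
#' training only, and per-epoch validation frame-F1 logging. The returned
#' model carries the weights of the epoch with the best validation F1
#' (ties broken toward the earlier epoch). Fully reproducible given
#' `cfg$seed` (single-threaded BLAS assumed for bit identity).
#'
#' @param model A `swd_model` from [build_variant()].
#' @param train_stream List of feature examples for optimization; must
#'   contain at least one positive frame.
#' @param val_stream List of feature examples for validation.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `swd_fit`: `model` (best checkpoint),
#'   `history` (tibble: epoch, train_loss, val_loss, val_f1), `best_epoch`,
#'   `config`.
#' @export
train_model <- function(model, train_stream, val_stream,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "swd_model"), inherits(cfg, "train_config"))
  if (length(train_stream) == 0L || length(val_stream) == 0L) {
    stop("training and validation streams must be non-empty", call. = FALSE)
  }
  ytr <- gather_labels(train_stream)
  if (sum(ytr$y[ytr$mask > 0]) == 0) {
    stop("degenerate training data: no positive frames", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  model$cfg$dropout_rate <- cfg$dropout_rate
  model$cfg$l2_weight <- cfg$l2_weight
  yva <- gather_labels(val_stream)
  opt <- adam_init(model$params)
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_loss = numeric(), val_f1 = numeric())
  best <- list(f1 = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  n_tr <- length(train_stream)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    ep_n <- 0L
    for (bi in batches) {
      xb <- stack_examples(train_stream[bi])
      yb <- matrix(ytr$y[bi, ], nrow = length(bi))
      mb <- matrix(ytr$mask[bi, ], nrow = length(bi))
      fw <- model_forward(model, xb, training = TRUE)
      model$state <- fw$state
      loss <- focal_loss(fw$prob, yb, cfg$focal_alpha, cfg$focal_gamma, mb) +
        l2_penalty(model$params, cfg$l2_weight)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      }
      dz <- focal_grad_z(fw$prob, fw$z, yb, cfg$focal_alpha,
                         cfg$focal_gamma, mb, model$cfg$output_activation)
      grads <- model_backward(model, fw$cache, dz)
      grads <- add_l2(grads, model$params, cfg$l2_weight)
      st <- adam_step(model$params, grads, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$opt
      ep_loss <- ep_loss + loss * length(bi)
      ep_n <- ep_n + length(bi)
    }
    vp <- predict(model, val_stream, batch_size = cfg$batch_size)
    v_loss <- focal_loss(vp, yva$y, cfg$focal_alpha, cfg$focal_gamma,
                         yva$mask)
    v_f1 <- frame_f1(vp, yva$y, yva$mask)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = v_loss,
      val_f1 = v_f1))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val F1 %.3f",
                      epoch, ep_loss / ep_n, v_loss, v_f1))
    }
    if (is.finite(v_f1) && v_f1 > best$f1) {
      best <- list(f1 = v_f1, params = model$params, state = model$state,
                   epoch = epoch)
    }
    if (!is.null(cfg$early_stop_f1) && is.finite(v_f1) &&
        v_f1 >= cfg$early_stop_f1) break
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_f1 = best$f1,
                 config = cfg),
            class = "swd_fit")
}

#' @export
print.swd_fit <- function(x, ...) {
  cat(sprintf("<swd_fit '%s': %d epoch(s), best val F1 %.3f at epoch %d>\n",
              x$model$variant, nrow(x$history), x$best_val_f1,
              x$best_epoch))
  invisible(x)
}

#' Tidy method for a training fit: the per-epoch history
#' @param x A `swd_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, train_loss, val_loss, val_f1.
#' @export
tidy.swd_fit <- function(x, ...) x$history

#' One-row summary of a training fit
#' @param x A `swd_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.swd_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$variant, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_f1 = x$best_val_f1,
                 final_train_loss = utils::tail(x$history$train_loss, 1))
}

#' Training-history plot
#' @param object A `swd_fit`.
#' @param ... Unused.
#' @return A ggplot object: losses and validation F1 per epoch.
#' @export
autoplot.swd_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
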