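#' Model configuration for the four compared architectures
#'
#' The canonical input is one 64-frame example of 256 features over 19
#' channels. Variants: `resnet_bigru` (residual CNN encoder + bidirectional
#' GRU head — the full model), `cnn_gru` (shortcut-free conv stack + GRU
#' head), `cnn_only` (shortcut-free conv stack + per-frame dense head),
#' `gru_only` (per-frame flatten of the raw features + GRU head).
#'
#' @param variant One of `"cnn_only"`, `"gru_only"`, `"cnn_gru"`,
#'   `"resnet_bigru"`.
#' @param input_shape Frames x features x channels; fixed at
#'   `c(64, 256, 19)` for the canonical build.
#' @param gru_units Units per GRU direction.
#' @param dense_units Width of the per-frame dense layer.
#' @param dropout_rate Dropout fraction in the head (training only).
#' @param l2_weight L2 penalty coefficient on convolution and dense
#'   weights.
#' @param output_activation `"sigmoid"` (default: per-frame seizure
#'   probability) or `"relu"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("resnet_bigru", "cnn_only", "gru_only",
                                     "cnn_gru"),
                         input_shape = c(64L, 256L, 19L), gru_units = 128L,
                         dense_units = 128L, dropout_rate = 0.3,
                         l2_weight = 1e-4,
                         output_activation = c("sigmoid", "relu")) {
  variant <- match.arg(variant)
  output_activation <- match.arg(output_activation)
  stopifnot(length(input_shape) == 3, all(input_shape > 0))
  structure(list(variant = variant, input_shape = as.integer(input_shape),
                 gru_units = as.integer(gru_units),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, l2_weight = l2_weight,
                 output_activation = output_activation),
            class = "model_config")
}

# channel plan of the four conv stages
ENC_PLAN <- c(32L, 64L, 128L, 64L)

# Table-consistent parameter counts asserted at construction time:
# per block (projection, main conv1, main conv2)
ENC_EXPECTED <- list(
  b1 = c(proj = 640, conv1 = 5472, conv2 = 9216),
  b2 = c(proj = 2112, conv1 = 18432, conv2 = 36864),
  b3 = c(proj = 8320, conv1 = 73728, conv2 = 147456),
  b4 = c(proj = 8256, conv1 = 73728, conv2 = 36864)
)
BIGRU1_EXPECTED <- 886272L

conv_n_params <- function(p) length(p$w) + length(p$b)
gru_pair_n_params <- function(pf, pb) {
  sum(vapply(c(pf, pb), length, 0L))
}

shape_str <- function(...) paste(c(...), collapse = " x ")

report_row <- function(layer, name, activation, output_size, kernel_size,
                       filters, parameters) {
  tibble::tibble(layer = layer, name = name, activation = activation,
                 output_size = output_size, kernel_size = kernel_size,
                 filters = filters, parameters = parameters)
}

# build the 4-stage conv encoder; resnet = TRUE adds 1x1 projection
# shortcuts and the elementwise Add. Bias convention forced by the
# parameter-count targets: 3x3 convolutions bias-free (batch norm absorbs
# the bias), 1x1 projections carry bias.
build_encoder <- function(cfg, resnet) {
  Tn <- cfg$input_shape[1]; Fn <- cfg$input_shape[2]
  cin <- cfg$input_shape[3]
  params <- list()
  state <- list()
  rows <- report_row(NA_integer_, "input", "-",
                     shape_str(Tn, Fn, cin), "-", NA_integer_, 0L)
  li <- 0L
  fdim <- Fn
  for (k in seq_along(ENC_PLAN)) {
    cout <- ENC_PLAN[k]
    blk <- list(
      conv1 = init_conv(3L, 3L, cin, cout, bias = FALSE),
      bn1 = init_bn(cout),
      conv2 = init_conv(3L, 3L, cout, cout, bias = FALSE),
      bn2 = init_bn(cout)
    )
    if (resnet) blk$proj <- init_conv(1L, 1L, cin, cout, bias = TRUE)
    if (resnet) {
      exp_k <- ENC_EXPECTED[[k]]
      got <- c(proj = conv_n_params(blk$proj),
               conv1 = conv_n_params(blk$conv1),
               conv2 = conv_n_params(blk$conv2))
      if (!all(got == exp_k)) {
        stop("encoder block ", k, " parameter counts ",
             paste(got, collapse = "/"), " differ from the reference ",
             paste(exp_k, collapse = "/"), call. = FALSE)
      }
    }
    params[[paste0("b", k)]] <- blk
    state[[paste0("b", k)]] <- list(bn1 = bn_new_state(cout),
                                    bn2 = bn_new_state(cout))
    sh <- shape_str(Tn, fdim, cout)
    main_rows <- dplyr::bind_rows(
      report_row(li + 1L, sprintf("conv2d_%d", 3L * (k - 1L) + 1L), "RELU",
                 sh, "3 x 3", cout, conv_n_params(blk$conv1)),
      report_row(NA_integer_, sprintf("batch_normalization_%d", 2L * k - 1L),
                 "-", sh, "-", cout, 2L * cout),
      report_row(li + 2L, sprintf("conv2d_%d", 3L * (k - 1L) + 2L), "-", sh,
                 "3 x 3", cout, conv_n_params(blk$conv2)),
      report_row(NA_integer_, sprintf("batch_normalization_%d", 2L * k), "-",
                 sh, "-", cout, 2L * cout)
    )
    if (resnet) {
      proj_row <- report_row(li + 3L,
                             if (k == 1L) "conv2d"
                             else sprintf("conv2d_%d", 3L * (k - 1L)),
                             "-", sh, "1 x 1", cout,
                             conv_n_params(blk$proj))
      # Table 2 lists block 1's projection after the main path and later
      # blocks' projection first; computation is order-independent
      block_rows <- if (k == 1L) {
        dplyr::bind_rows(main_rows, proj_row)
      } else {
        dplyr::bind_rows(proj_row, main_rows)
      }
      # renumber the numbered rows to match table order
      block_rows$layer[!is.na(block_rows$layer)] <- li + 1:3
      block_rows <- dplyr::bind_rows(
        block_rows,
        report_row(li + 4L, "Add+RELU", "RELU", sh, "-", NA_integer_, 0L),
        report_row(li + 5L, "Max_pooling", "-",
                   shape_str(Tn, fdim %/% 2L, cout), "-", NA_integer_, 0L))
      li <- li + 5L
    } else {
      block_rows <- dplyr::bind_rows(
        main_rows,
        report_row(li + 3L, "RELU", "RELU", sh, "-", NA_integer_, 0L),
        report_row(li + 4L, "Max_pooling", "-",
                   shape_str(Tn, fdim %/% 2L, cout), "-", NA_integer_, 0L))
      block_rows$layer[!is.na(block_rows$layer)] <- li + 1:4
      li <- li + 4L
    }
    rows <- dplyr::bind_rows(rows, block_rows)
    cin <- cout
    fdim <- fdim %/% 2L
  }
  list(params = params, state = state, report = rows,
       out_shape = c(Tn, fdim, cin))
}

# bidirectional-GRU sequence head over the flattened encoder output
build_head_bigru <- function(cfg, in_width, assert_count = FALSE) {
  U <- cfg$gru_units
  ph <- list(
    gru1f = init_gru(in_width, U), gru1b = init_gru(in_width, U),
    gru2f = init_gru(2L * U, U), gru2b = init_gru(2L * U, U),
    dense1 = init_dense(2L * U, cfg$dense_units),
    dense2 = init_dense(cfg$dense_units, 1L)
  )
  n1 <- gru_pair_n_params(ph$gru1f, ph$gru1b)
  if (assert_count && n1 != BIGRU1_EXPECTED) {
    stop("first bidirectional GRU parameter count ", n1,
         " differs from the reference ", BIGRU1_EXPECTED, call. = FALSE)
  }
  Tn <- cfg$input_shape[1]
  rows <- dplyr::bind_rows(
    report_row(NA_integer_, "Reshape", "-", shape_str(Tn, in_width), "-",
               NA_integer_, 0L),
    report_row(NA_integer_, "Bidirectional", "tanh",
               shape_str(Tn, 2L * U), "-", U, n1),
    report_row(NA_integer_, "Bidirectional_1", "tanh",
               shape_str(Tn, 2L * U), "-", U,
               gru_pair_n_params(ph$gru2f, ph$gru2b)),
    report_row(NA_integer_, "Time_distributed", "RELU",
               shape_str(Tn, cfg$dense_units), "-", cfg$dense_units,
               length(ph$dense1$w) + length(ph$dense1$b)),
    report_row(NA_integer_, "Time_distributed_1", "-", shape_str(Tn, 1L),
               "-", 1L, length(ph$dense2$w) + length(ph$dense2$b)),
    report_row(NA_integer_, "Output", toupper(cfg$output_activation),
               shape_str(Tn, 1L), "-", NA_integer_, 0L)
  )
  list(params = ph, report = rows)
}

# per-frame dense head (no recurrence) for the cnn_only variant
build_head_dense <- function(cfg, in_width) {
  ph <- list(dense1 = init_dense(in_width, cfg$dense_units),
             dense2 = init_dense(cfg$dense_units, 1L))
  Tn <- cfg$input_shape[1]
  rows <- dplyr::bind_rows(
    report_row(NA_integer_, "Reshape", "-", shape_str(Tn, in_width), "-",
               NA_integer_, 0L),
    report_row(NA_integer_, "Time_distributed", "RELU",
               shape_str(Tn, cfg$dense_units), "-", cfg$dense_units,
               length(ph$dense1$w) + length(ph$dense1$b)),
    report_row(NA_integer_, "Time_distributed_1", "-", shape_str(Tn, 1L),
               "-", 1L, length(ph$dense2$w) + length(ph$dense2$b)),
    report_row(NA_integer_, "Output", toupper(cfg$output_activation),
               shape_str(Tn, 1L), "-", NA_integer_, 0L)
  )
  list(params = ph, report = rows)
}

new_swd_model <- function(cfg, params, state, report) {
  structure(list(variant = cfg$variant, cfg = cfg, params = params,
                 state = state, report = report),
            class = "swd_model")
}

#' Build the residual CNN encoder
#'
#' Four residual blocks with channel plan 19 -> 32 -> 64 -> 128 -> 64.
#' Each block: 3x3 conv / batch norm / ReLU / 3x3 conv / batch norm on the
#' main path, a biased 1x1 projection on the identity path, elementwise
#' Add + ReLU, then (1, 2) max pooling that halves only the feature axis —
#' the 64-frame sequence axis is preserved throughout, giving output
#' shape (64, 16, 64). Construction fails if any convolution's parameter
#' count differs from the reference table.
#'
#' @param cfg A [model_config()] (variant is ignored).
#' @param seed Optional RNG seed for weight initialization.
#' @return An object of class `swd_encoder` with elements `params`,
#'   `state`, `report` (a [layer_report()] tibble) and `out_shape`.
#' @export
build_resnet_encoder <- function(cfg = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enc <- build_encoder(cfg, resnet = TRUE)
  structure(enc, class = "swd_encoder")
}

#' Build the bidirectional GRU head
#'
#' Flattens the encoder output (64, 16, 64) to a 64 x 1024 frame sequence,
#' applies two sequence-returning bidirectional GRU layers (128 units per
#' direction, dual-bias gate formulation), then per-frame dense layers
#' 256 -> 128 (ReLU) -> 1 with the configured output activation. The first
#' bidirectional layer must count exactly 886,272 parameters.
#'
#' @param cfg A [model_config()].
#' @param in_shape Encoder output shape, default `c(64, 16, 64)`.
#' @param seed Optional RNG seed.
#' @return List with `params` and `report`.
#' @export
build_bigru_head <- function(cfg = model_config(), in_shape = c(64, 16, 64),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build_head_bigru(cfg, as.integer(in_shape[2] * in_shape[3]),
                   assert_count = TRUE)
}

#' Build one of the four compared architectures
#'
#' @param cfg A [model_config()]; `cfg$variant` selects the architecture.
#' @param seed Optional RNG seed for reproducible initialization.
#' @return An object of class `swd_model`.
#' @export
build_variant <- function(cfg = model_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- cfg$input_shape[1]
  if (cfg$variant %in% c("resnet_bigru", "cnn_gru", "cnn_only")) {
    enc <- build_encoder(cfg, resnet = cfg$variant == "resnet_bigru")
    in_width <- enc$out_shape[2] * enc$out_shape[3]
    head <- if (cfg$variant == "cnn_only") {
      build_head_dense(cfg, in_width)
    } else {
      build_head_bigru(cfg, in_width,
                       assert_count = cfg$variant == "resnet_bigru")
    }
    params <- list(enc = enc$params, head = head$params)
    state <- enc$state
    report <- dplyr::bind_rows(enc$report, head$report)
  } else if (cfg$variant == "gru_only") {
    in_width <- cfg$input_shape[2] * cfg$input_shape[3]
    head <- build_head_bigru(cfg, in_width)
    params <- list(head = head$params)
    state <- list()
    report <- dplyr::bind_rows(
      report_row(NA_integer_, "input", "-",
                 shape_str(cfg$input_shape), "-", NA_integer_, 0L),
      head$report)
  } else {
    stop("unknown variant: ", cfg$variant, call. = FALSE)
  }
  new_swd_model(cfg, params, state, report)
}

#' Per-layer report of a built model
#'
#' One row per layer in forward order with the reference table's column
#' semantics: `layer` (table row number where applicable), `name`,
#' `activation`, `output_size`, `kernel_size`, `filters`, `parameters`
#' (exact trainable parameter count).
#'
#' @param model A `swd_model` or `swd_encoder`.
#' @return A tibble.
#' @export
layer_report <- function(model) {
  stopifnot(inherits(model, "swd_model") || inherits(model, "swd_encoder"))
  model$report
}

#' Write a layer report to CSV
#' @param report Tibble from [layer_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layer_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Total trainable parameter count of a model
#' @param model A `swd_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' @export
print.swd_model <- function(x, ...) {
  cat(sprintf("<swd_model '%s': input %s, %s trainable parameters>\n",
              x$variant, shape_str(x$cfg$input_shape),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Tidy method for a built model: its layer report
#' @param x A `swd_model`.
#' @param ... Unused.
#' @return The [layer_report()] tibble.
#' @export
tidy.swd_model <- function(x, ...) layer_report(x)

#' @export
glance.swd_model <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_params = n_params(x),
                 n_layers = nrow(x$report),
                 input_shape = shape_str(x$cfg$input_shape))
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

# encoder forward over tensor (T, F, C, B)
enc_forward <- function(params, state, x, training, resnet) {
  caches <- vector("list", length(params))
  for (k in seq_along(params)) {
    blk <- params[[k]]
    st <- state[[k]]
    c1 <- conv_fw(x, blk$conv1)
    bn1 <- bn_fw(c1, blk$bn1, training, st$bn1)
    r1 <- relu_fw(bn1$y)
    c2 <- conv_fw(r1$y, blk$conv2)
    bn2 <- bn_fw(c2, blk$bn2, training, st$bn2)
    pre <- if (resnet) bn2$y + conv_fw(x, blk$proj) else bn2$y
    r2 <- relu_fw(pre)
    pool <- maxpool12_fw(r2$y)
    caches[[k]] <- list(x = x, bn1 = bn1$cache, m1 = r1$mask, h1 = r1$y,
                        bn2 = bn2$cache, m2 = r2$mask, pool = pool[-1L])
    state[[k]] <- list(bn1 = bn1$run, bn2 = bn2$run)
    x <- pool$y
  }
  list(y = x, caches = caches, state = state)
}

enc_backward <- function(params, caches, dy, resnet) {
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  for (k in rev(seq_along(params))) {
    blk <- params[[k]]
    ca <- caches[[k]]
    d <- maxpool12_bw(dy, ca$pool)
    d <- relu_bw(d, ca$m2)
    g <- list()
    if (resnet) {
      gp <- conv_bw(ca$x, blk$proj, d)
      g$proj <- list(w = gp$dw, b = gp$db)
      dx_proj <- gp$dx
    }
    b2 <- bn_bw(d, blk$bn2, ca$bn2)
    g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
    g2 <- conv_bw(ca$h1, blk$conv2, b2$dx)
    g$conv2 <- list(w = g2$dw)
    d1 <- relu_bw(g2$dx, ca$m1)
    b1 <- bn_bw(d1, blk$bn1, ca$bn1)
    g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
    g1 <- conv_bw(ca$x, blk$conv1, b1$dx)
    g$conv1 <- list(w = g1$dw)
    dy <- if (resnet) g1$dx + dx_proj else g1$dx
    grads[[k]] <- g
  }
  list(dx = dy, grads = grads)
}

# (T, F2, C2, B) tensor -> (B, T, F2*C2) frame sequence
flatten_frames <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(4L, 1L, 2L, 3L))
  dim(xp) <- c(d[4], d[1], d[2] * d[3])
  xp
}

unflatten_frames <- function(dX, dims) {
  dim(dX) <- c(dims[4], dims[1], dims[2], dims[3])
  aperm(dX, c(2L, 3L, 4L, 1L))
}

out_activation_fw <- function(z, kind) {
  if (kind == "sigmoid") sigmoid(z) else pmax(z, 0)
}

head_bigru_forward <- function(ph, X, training, rate, act) {
  g1 <- bigru_fw(X, ph$gru1f, ph$gru1b)
  d1 <- dropout_fw(g1$h, rate, training)
  g2 <- bigru_fw(d1$y, ph$gru2f, ph$gru2b)
  d2 <- dropout_fw(g2$h, rate, training)
  t1 <- tdense_fw(d2$y, ph$dense1)
  r1 <- relu_fw(t1)
  d3 <- dropout_fw(r1$y, rate, training)
  z <- tdense_fw(d3$y, ph$dense2)
  prob <- out_activation_fw(z, act)
  list(prob = prob[, , 1L], z = z[, , 1L],
       cache = list(X = X, g1 = g1$cache, d1m = d1$mask, h1 = d1$y,
                    g2 = g2$cache, d2m = d2$mask, h2 = d2$y,
                    m_r1 = r1$mask, h3 = d3$y, d3m = d3$mask, zdim = dim(z)))
}

head_bigru_backward <- function(ph, cache, dz) {
  dim(dz) <- cache$zdim
  g <- list()
  td2 <- tdense_bw(cache$h3, ph$dense2, dz)
  g$dense2 <- list(w = td2$dw, b = td2$db)
  d <- dropout_bw(td2$dx, cache$d3m)
  d <- relu_bw(d, cache$m_r1)
  td1 <- tdense_bw(cache$h2, ph$dense1, d)
  g$dense1 <- list(w = td1$dw, b = td1$db)
  d <- dropout_bw(td1$dx, cache$d2m)
  b2 <- bigru_bw(ph$gru2f, ph$gru2b, cache$g2, d)
  g$gru2f <- b2$fwd[c("dw", "du", "db_in", "db_rec")]
  g$gru2b <- b2$bwd[c("dw", "du", "db_in", "db_rec")]
  names(g$gru2f) <- names(g$gru2b) <- c("w", "u", "b_in", "b_rec")
  d <- dropout_bw(b2$dX, cache$d1m)
  b1 <- bigru_bw(ph$gru1f, ph$gru1b, cache$g1, d)
  g$gru1f <- b1$fwd[c("dw", "du", "db_in", "db_rec")]
  g$gru1b <- b1$bwd[c("dw", "du", "db_in", "db_rec")]
  names(g$gru1f) <- names(g$gru1b) <- c("w", "u", "b_in", "b_rec")
  list(dX = b1$dX, grads = g)
}

head_dense_forward <- function(ph, X, training, rate, act) {
  t1 <- tdense_fw(X, ph$dense1)
  r1 <- relu_fw(t1)
  d1 <- dropout_fw(r1$y, rate, training)
  z <- tdense_fw(d1$y, ph$dense2)
  prob <- out_activation_fw(z, act)
  list(prob = prob[, , 1L], z = z[, , 1L],
       cache = list(X = X, m_r1 = r1$mask, h1 = d1$y, d1m = d1$mask,
                    zdim = dim(z)))
}

head_dense_backward <- function(ph, cache, dz) {
  dim(dz) <- cache$zdim
  g <- list()
  td2 <- tdense_bw(cache$h1, ph$dense2, dz)
  g$dense2 <- list(w = td2$dw, b = td2$db)
  d <- dropout_bw(td2$dx, cache$d1m)
  d <- relu_bw(d, cache$m_r1)
  td1 <- tdense_bw(cache$X, ph$dense1, d)
  g$dense1 <- list(w = td1$dw, b = td1$db)
  list(dX = td1$dx, grads = g)
}

# full-model forward on a batch tensor (T, F, C, B).
# Returns per-frame probabilities (B, T) and, when training, the caches
# needed for model_backward.
model_forward <- function(model, xb, training = FALSE, keep_cache = training) {
  cfg <- model$cfg
  act <- cfg$output_activation
  rate <- if (training) cfg$dropout_rate else 0
  variant <- model$variant
  cache <- list()
  if (variant == "gru_only") {
    X <- flatten_frames(xb)
    hd <- head_bigru_forward(model$params$head, X, training, rate, act)
    cache <- list(head = hd$cache)
    enc_state <- model$state
  } else {
    enc <- enc_forward(model$params$enc, model$state, xb, training,
                       resnet = variant == "resnet_bigru")
    enc_state <- enc$state
    X <- flatten_frames(enc$y)
    hd <- if (variant == "cnn_only") {
      head_dense_forward(model$params$head, X, training, rate, act)
    } else {
      head_bigru_forward(model$params$head, X, training, rate, act)
    }
    cache <- list(enc = enc$caches, head = hd$cache,
                  enc_out_dims = dim(enc$y))
  }
  list(prob = hd$prob, z = hd$z, cache = if (keep_cache) cache,
       state = enc_state)
}

# backward from d(loss)/d(z) (B, T); returns gradients mirroring params
model_backward <- function(model, cache, dz) {
  variant <- model$variant
  if (variant == "gru_only") {
    hb <- head_bigru_backward(model$params$head, cache$head, dz)
    return(list(head = hb$grads))
  }
  hb <- if (variant == "cnn_only") {
    head_dense_backward(model$params$head, cache$head, dz)
  } else {
    head_bigru_backward(model$params$head, cache$head, dz)
  }
  dy <- unflatten_frames(hb$dX, cache$enc_out_dims)
  eb <- enc_backward(model$params$enc, cache$enc, dy,
                     resnet = variant == "resnet_bigru")
  list(enc = eb$grads, head = hb$grads)
}

# stack a list of feature examples into a batch tensor (T, F, C, B)
stack_examples <- function(examples) {
  d <- dim(examples[[1]]$x)
  array(unlist(lapply(examples, `[[`, "x"), use.names = FALSE),
        c(d, length(examples)))
}

#' Per-frame seizure probabilities for feature examples
#'
#' @param object A `swd_model`.
#' @param examples List of feature examples ([make_examples()] /
#'   [normalize_examples()]).
#' @param batch_size Examples per forward batch.
#' @param ... Unused.
#' @return Matrix `length(examples)` x frames of probabilities.
#' @export
predict.swd_model <- function(object, examples, batch_size = 8L, ...) {
  stopifnot(length(examples) > 0L)
  Tn <- object$cfg$input_shape[1]
  out <- matrix(0, length(examples), Tn)
  idx <- split(seq_along(examples),
               ceiling(seq_along(examples) / batch_size))
  for (ii in idx) {
    fw <- model_forward(object, stack_examples(examples[ii]),
                        training = FALSE, keep_cache = FALSE)
    out[ii, ] <- fw$prob
  }
  out
}
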