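# The DysDiTect architecture family.
#
# A model is assembled from four switchable stages around a shared CNN
# encoder: sinusoidal positional encoding (P), a 2-layer bidirectional LSTM
# (L), multi-head self-attention (A), and a grade input neuron (G). Any
# subset of {P, L, A, G} yields one of 16 named variants.

#' Configure a DysDiTect model variant
#'
#' @param use_P,use_L,use_A,use_G logical stage switches: positional
#'   encoding, Bi-LSTM, self-attention, grade input.
#' @param backbone `"small_cnn"` (a compact conv/pool encoder that trains on
#'   CPU) or `"resnet50_transfer"` (requires an externally supplied
#'   pretrained weight bundle; none is distributed with the package).
#' @param cnn_out_dim per-character feature width produced by the CNN.
#' @param lstm_hidden hidden state size of each LSTM direction.
#' @param lstm_layers number of stacked Bi-LSTM layers.
#' @param attn_heads number of self-attention heads.
#' @param dropout dropout rate applied to LSTM, attention, and condensed
#'   layers during training.
#' @param seq_len number of characters per participant.
#' @param image_px side length of the square input images (multiple of 32).
#' @param attn_residual add a residual connection around the attention block
#'   (off by default; the attention output dimensionality is unchanged
#'   either way).
#' @return A `dysditect_config` object (a named list).
#' @export
model_config <- function(use_P = TRUE, use_L = TRUE, use_A = TRUE, use_G = TRUE,
                         backbone = c("small_cnn", "resnet50_transfer"),
                         cnn_out_dim = 32L, lstm_hidden = 128L,
                         lstm_layers = 2L, attn_heads = 4L, dropout = 0.2,
                         seq_len = 96L, image_px = 128L,
                         attn_residual = FALSE) {
  backbone <- match.arg(backbone)
  if (image_px %% 32 != 0)
    stop("image_px must be a multiple of 32, got ", image_px)
  cfg <- list(use_P = isTRUE(use_P), use_L = isTRUE(use_L),
              use_A = isTRUE(use_A), use_G = isTRUE(use_G),
              backbone = backbone, cnn_out_dim = as.integer(cnn_out_dim),
              lstm_hidden = as.integer(lstm_hidden),
              lstm_layers = as.integer(lstm_layers),
              attn_heads = as.integer(attn_heads), dropout = dropout,
              seq_len = as.integer(seq_len), image_px = as.integer(image_px),
              attn_residual = isTRUE(attn_residual))
  if (cfg$use_A) {
    d_attn <- attention_dim(cfg)
    if (d_attn %% cfg$attn_heads != 0)
      stop("attention feature dimension (", d_attn,
           ") is not divisible by attn_heads (", cfg$attn_heads, ")")
  }
  structure(cfg, class = "dysditect_config")
}

# Feature width entering the attention block: Bi-LSTM output when L is on,
# otherwise the raw CNN feature width.
attention_dim <- function(cfg) {
  if (cfg$use_L) 2L * cfg$lstm_hidden else cfg$cnn_out_dim
}

# Feature width entering the condensation layer.
condense_dim <- function(cfg) {
  if (cfg$use_L || cfg$use_A) attention_dim(cfg) else cfg$cnn_out_dim
}

#' Variant name of a configuration
#'
#' `"DysDiTect_"` followed by the enabled stage letters in P, L, A, G order
#' (the empty suffix names the bare CNN + classifier model).
#'
#' @param config a `dysditect_config`.
#' @return A string.
#' @export
variant_name <- function(config) {
  paste0("DysDiTect_",
         paste0(c("P", "L", "A", "G")[c(config$use_P, config$use_L,
                                        config$use_A, config$use_G)],
                collapse = ""))
}

#' Configuration for a named variant
#'
#' @param name e.g. `"DysDiTect_PLA"` or `"DysDiTect_"`.
#' @param ... further arguments passed to [model_config()].
#' @return A `dysditect_config`.
#' @export
variant_config <- function(name, ...) {
  flags <- sub("^DysDiTect_", "", name)
  if (!grepl("^DysDiTect_", name) || !grepl("^P?L?A?G?$", flags))
    stop("unknown variant name '", name, "'; valid names are: ",
         paste(enumerate_variants()$name, collapse = ", "))
  model_config(use_P = grepl("P", flags), use_L = grepl("L", flags),
               use_A = grepl("A", flags), use_G = grepl("G", flags), ...)
}

#' Enumerate the 16 ablation variants
#'
#' All subsets of the {P, L, A, G} switches, ordered with P outermost and G
#' innermost (the reporting order of the ablation table).
#'
#' @param ... passed to [model_config()] for every variant (e.g. a smaller
#'   `lstm_hidden` for quick experiments).
#' @return A tibble with the variant `name`, the four logical flags, and a
#'   `config` list-column.
#' @export
enumerate_variants <- function(...) {
  grid <- expand.grid(use_G = c(TRUE, FALSE), use_A = c(TRUE, FALSE),
                      use_L = c(TRUE, FALSE), use_P = c(TRUE, FALSE))
  grid <- grid[order(-grid$use_P, -grid$use_L, -grid$use_A, -grid$use_G), ]
  out <- purrr::pmap(grid, function(use_G, use_A, use_L, use_P) {
    model_config(use_P = use_P, use_L = use_L, use_A = use_A, use_G = use_G, ...)
  })
  tibble::tibble(name = vapply(out, variant_name, character(1)),
                 use_P = grid$use_P, use_L = grid$use_L,
                 use_A = grid$use_A, use_G = grid$use_G,
                 config = out)
}

#' Build a model with freshly initialized weights
#'
#' Weight initialization draws from the current RNG stream; seed it (or use
#' [train_model()], which derives a seed) for reproducible builds.
#'
#' @param config a `dysditect_config`.
#' @return A `dysditect_model`: the config, a flat named parameter list, and
#'   the positional-encoding table.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "dysditect_config"))
  if (config$backbone == "resnet50_transfer")
    stop("backbone 'resnet50_transfer' needs an ImageNet-pretrained ",
         "weight bundle, which is not distributed with this package; ",
         "use backbone = 'small_cnn'")
  p <- c(init_conv(3L, 3L, 8L, "cnn.conv1"),
         init_conv(3L, 8L, 16L, "cnn.conv2"),
         init_conv(3L, 16L, 32L, "cnn.conv3"),
         init_linear(32L, config$cnn_out_dim, "cnn.fc"))
  if (config$use_L) {
    d_in <- config$cnn_out_dim
    for (l in seq_len(config$lstm_layers)) {
      p <- c(p,
             init_lstm_dir(d_in, config$lstm_hidden, sprintf("lstm.l%d.fwd", l)),
             init_lstm_dir(d_in, config$lstm_hidden, sprintf("lstm.l%d.bwd", l)))
      d_in <- 2L * config$lstm_hidden
    }
  }
  if (config$use_A) {
    d <- attention_dim(config)
    for (s in c("wq", "wk", "wv", "wo"))
      p <- c(p, init_linear(d, d, paste0("attn.", s)))
  }
  p <- c(p, init_linear(condense_dim(config), 1L, "cond"),
         init_linear(config$seq_len + as.integer(config$use_G), 1L, "head"))
  structure(list(config = config, params = p,
                 pe = positional_encoding_table(config$seq_len,
                                                config$cnn_out_dim)),
            class = "dysditect_model")
}

#' @export
print.dysditect_model <- function(x, ...) {
  cat(variant_name(x$config), " (", x$config$backbone, "), ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# Names of parameters held fixed under the frozen fine-tuning policy:
# every CNN block except the last conv block and the CNN projection head.
frozen_param_names <- function(model) {
  nms <- names(model$params)
  nms[grepl("^cnn\\.conv[12]\\.", nms)]
}

## ---- stage-wise encoders (the documented dataflow) -------------------------

# convert the (seq_len, 3, px, px) input contract to internal (px, px, 3, T)
to_internal_images <- function(images, cfg) {
  d <- dim(images)
  if (length(d) == 4 && d[1] == cfg$seq_len && d[2] == 3L)
    return(aperm(images, c(3, 4, 2, 1)))
  if (length(d) == 4 && d[3] == 3L && d[4] == cfg$seq_len)
    return(images)
  stop("expected an image array of shape (", cfg$seq_len, ", 3, ",
       cfg$image_px, ", ", cfg$image_px, ")")
}

#' Encode a character sequence with the shared CNN
#'
#' The same CNN (shared weights) is applied to each image independently,
#' so permuting the inputs permutes the output rows identically.
#'
#' @param model a `dysditect_model`.
#' @param images array `(seq_len, 3, px, px)` of binarized images.
#' @return A `(seq_len, cnn_out_dim)` feature matrix, stage `"post_cnn"`.
#' @export
cnn_encode <- function(model, images) {
  x <- to_internal_images(images, model$config)
  out <- small_cnn_fw(x, model$params, model$config$cnn_out_dim)$out
  structure(out, stage = "post_cnn")
}

#' Add the fixed sinusoidal positional encoding
#'
#' @param model a `dysditect_model`.
#' @param fm a `(seq_len, cnn_out_dim)` feature matrix.
#' @return The encoded matrix, same shape, stage `"post_pe"`.
#' @export
positional_encode <- function(model, fm) {
  stopifnot(all(dim(fm) == dim(model$pe)))
  structure(fm + model$pe, stage = "post_pe")
}

#' Encode the sequence with the 2-layer bidirectional LSTM
#'
#' Per-timestep outputs of the top layer; forward and backward hidden
#' states are concatenated, so the feature width is `2 * lstm_hidden`.
#'
#' @param model a `dysditect_model` built with `use_L = TRUE`.
#' @param fm a `(seq_len, cnn_out_dim)` feature matrix.
#' @param train apply dropout between layers and on the output.
#' @return A `(seq_len, 2 * lstm_hidden)` matrix, stage `"post_lstm"`.
#' @export
bilstm_encode <- function(model, fm, train = FALSE) {
  stopifnot(model$config$use_L)
  res <- bilstm_chain_fw(fm, model$params, model$config, train)
  structure(res$out, stage = "post_lstm")
}

bilstm_chain_fw <- function(fm, p, cfg, train) {
  caches <- list()
  x <- fm
  for (l in seq_len(cfg$lstm_layers)) {
    bl <- bilstm_layer_fw(x, p, sprintf("lstm.l%d", l))
    dr <- dropout_fw(bl$out, cfg$dropout, train)
    caches[[l]] <- list(layer = bl$cache, mask = dr$mask)
    x <- dr$y
  }
  list(out = x, caches = caches)
}

bilstm_chain_bw <- function(caches, dY, cfg) {
  grads <- list()
  for (l in rev(seq_len(cfg$lstm_layers))) {
    dY <- dropout_bw(caches[[l]]$mask, dY)
    res <- bilstm_layer_bw(caches[[l]]$layer, dY, sprintf("lstm.l%d", l))
    grads <- acc_grads(grads, res$grads)
    dY <- res$dX
  }
  list(dX = dY, grads = grads)
}

#' Multi-head self-attention over the sequence
#'
#' Standard scaled dot-product self-attention without a causal mask; the
#' output has the same shape as the input, and the per-head row-stochastic
#' weight matrices are returned for analysis.
#'
#' @param model a `dysditect_model` built with `use_A = TRUE`.
#' @param fm a `(seq_len, D)` feature matrix with `D` divisible by the
#'   number of heads.
#' @param train apply dropout to the attention output.
#' @return A list: `out` (same shape as `fm`, stage `"post_attn"`) and
#'   `weights`, an `(heads, seq_len, seq_len)` array.
#' @export
self_attend <- function(model, fm, train = FALSE) {
  stopifnot(model$config$use_A)
  if (ncol(fm) %% model$config$attn_heads != 0)
    stop("feature dimension not divisible by the number of heads")
  at <- attention_fw(fm, model$params, model$config$attn_heads)
  out <- if (model$config$attn_residual) fm + at$out else at$out
  dr <- dropout_fw(out, model$config$dropout, train)
  list(out = structure(dr$y, stage = "post_attn"), weights = at$weights)
}

#' Condense per-character embeddings and classify
#'
#' A linear map shared across timesteps condenses each character embedding
#' into one neuron; with `use_G` the scaled grade (grade / 6) is appended,
#' and a final linear layer plus sigmoid yields the probability that the
#' participant has developmental dyslexia.
#'
#' @param model a `dysditect_model`.
#' @param fm a `(seq_len, D)` feature matrix from any stage.
#' @param grade integer school grade (2-6); required iff `use_G`.
#' @return A list with `prob` and `logit`.
#' @export
condense_classify <- function(model, fm, grade = NULL) {
  cfg <- model$config
  if (cfg$use_G && is.null(grade))
    stop("this variant uses grade information; supply `grade`")
  p <- model$params
  cvec <- drop(fm %*% p[["cond.w"]]) + p[["cond.b"]]
  hin <- if (cfg$use_G) c(cvec, grade / 6) else cvec
  logit <- sum(hin * p[["head.w"]]) + p[["head.b"]]
  list(prob = sigmoid(logit), logit = logit)
}

## ---- full forward / backward ----------------------------------------------

# Internal forward on (px, px, 3, seq_len) image arrays. Returns caches
# sufficient for backprop.
model_fw <- function(model, x_int, grade, train = FALSE, s0 = NULL) {
  cfg <- model$config; p <- model$params
  cnn <- small_cnn_fw(x_int, p, cfg$cnn_out_dim, s0 = s0)
  X <- cnn$out
  if (cfg$use_P) X <- X + model$pe
  lstm_cache <- NULL
  if (cfg$use_L) {
    bl <- bilstm_chain_fw(X, p, cfg, train)
    lstm_cache <- bl$caches
    X <- bl$out
  }
  attn <- NULL; attn_cache <- NULL; attn_mask <- NULL; attn_in <- NULL
  if (cfg$use_A) {
    attn_in <- X
    at <- attention_fw(X, p, cfg$attn_heads)
    attn <- at$weights
    attn_cache <- at$cache
    out <- if (cfg$attn_residual) X + at$out else at$out
    dr <- dropout_fw(out, cfg$dropout, train)
    attn_mask <- dr$mask
    X <- dr$y
  }
  drc <- dropout_fw(drop(X %*% p[["cond.w"]]) + p[["cond.b"]], cfg$dropout, train)
  cvec <- drc$y
  hin <- if (cfg$use_G) c(cvec, grade / 6) else cvec
  logit <- sum(hin * p[["head.w"]]) + p[["head.b"]]
  list(prob = sigmoid(logit), logit = logit, attention = attn,
       cache = list(cnn = cnn$cache, lstm = lstm_cache,
                    attn = attn_cache, attn_mask = attn_mask,
                    attn_in = attn_in, cond_in = X, cond_mask = drc$mask,
                    hin = hin))
}

model_bw <- function(model, fwd, dlogit) {
  cfg <- model$config; p <- model$params; cache <- fwd$cache
  grads <- list()
  grads[["head.w"]] <- matrix(cache$hin * dlogit, ncol = 1)
  grads[["head.b"]] <- dlogit
  dhin <- drop(p[["head.w"]]) * dlogit
  dcvec <- dropout_bw(cache$cond_mask, dhin[seq_len(cfg$seq_len)])
  X <- cache$cond_in
  grads[["cond.w"]] <- crossprod(X, dcvec)
  grads[["cond.b"]] <- sum(dcvec)
  dX <- dcvec %o% drop(p[["cond.w"]])
  if (cfg$use_A) {
    dX <- dropout_bw(cache$attn_mask, dX)
    ab <- attention_bw(cache$attn, dX, p)
    grads <- acc_grads(grads, ab$grads)
    dX <- if (cfg$attn_residual) dX + ab$dX else ab$dX
  }
  if (cfg$use_L) {
    lb <- bilstm_chain_bw(cache$lstm, dX, cfg)
    grads <- acc_grads(grads, lb$grads)
    dX <- lb$dX
  }
  # positional encoding is additive: gradient passes through unchanged
  cb <- small_cnn_bw(cache$cnn, dX, p)
  acc_grads(grads, cb$grads)
}

#' Run a full forward pass
#'
#' Dataflow: CNN, then positional encoding (if P), Bi-LSTM (if L),
#' self-attention (if A), condensation and classification (with grade
#' iff G). Deterministic in evaluation mode (`train = FALSE`).
#'
#' @param model a `dysditect_model`.
#' @param images array `(seq_len, 3, px, px)`.
#' @param grade school grade 2-6 (required iff the variant uses G).
#' @param train apply dropout (training mode).
#' @return A list: `prob`, `logit`, and `attention` (an
#'   `(heads, seq_len, seq_len)` array, `NULL` unless the variant uses A).
#' @export
model_forward <- function(model, images, grade = NULL, train = FALSE) {
  cfg <- model$config
  if (cfg$use_G && is.null(grade))
    stop("this variant uses grade information; supply `grade`")
  x <- to_internal_images(images, cfg)
  out <- model_fw(model, x, grade, train = train)
  out$cache <- NULL
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.dysditect_model <- function(x, ...) {
  tibble::tibble(variant = variant_name(x$config),
                 backbone = x$config$backbone,
                 n_parameters = n_parameters(x),
                 seq_len = x$config$seq_len,
                 attention_dim = if (x$config$use_A) attention_dim(x$config) else NA_integer_)
}

#' @export
tidy.dysditect_model <- function(x, ...) {
  tibble::tibble(parameter = names(x$params),
                 dims = vapply(x$params, function(p)
                   paste(dim(p) %||% length(p), collapse = "x"), character(1)),
                 n = vapply(x$params, length, integer(1)))
}
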