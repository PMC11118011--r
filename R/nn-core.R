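# Parameter containers and the Adam optimizer.
#
# Model parameters live in a flat named list of numeric arrays
# ("cnn.conv1.w", "lstm.l1.fwd.Wx", ...). Keeping the container flat makes
# optimizer state, parameter counting and freeze masks one-liners.

#' @keywords internal
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  x <- stats::runif(prod(dims), -bound, bound)
  if (length(dims) > 1) dim(x) <- dims
  x
}

# Linear and conv layers: uniform He-style weights, zero biases. Zero
# biases matter here: an all-blank (zero) character image then maps to an
# exactly-zero feature vector, so response-type differences are not buried
# under a constant activation offset when training from scratch.
init_linear <- function(d_in, d_out, prefix) {
  out <- list(init_uniform(c(d_in, d_out), d_in),
              numeric(d_out))
  names(out) <- paste0(prefix, c(".w", ".b"))
  out
}

init_conv <- function(k, c_in, c_out, prefix) {
  fan_in <- k * k * c_in
  w <- array(stats::runif(k * k * c_in * c_out, -sqrt(6 / fan_in),
                          sqrt(6 / fan_in)),
             dim = c(k, k, c_in, c_out))
  out <- list(w, numeric(c_out))
  names(out) <- paste0(prefix, c(".w", ".b"))
  out
}

init_lstm_dir <- function(d_in, hidden, prefix) {
  out <- list(init_uniform(c(d_in, 4 * hidden), hidden),
              init_uniform(c(hidden, 4 * hidden), hidden),
              init_uniform(4 * hidden, hidden))
  names(out) <- paste0(prefix, c(".Wx", ".Wh", ".b"))
  out
}

#' Count free parameters of a model
#'
#' @param model a `dysditect_model` object.
#' @return Integer scalar: total number of scalar weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

zero_like <- function(params) lapply(params, function(p) {
  z <- numeric(length(p))
  if (!is.null(dim(p))) dim(z) <- dim(p)
  z
})

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# PyTorch-style Adam: L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     frozen = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise accumulate: a + b over matching names
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
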