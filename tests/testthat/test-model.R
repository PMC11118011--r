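# Architecture family: variant enumeration, stage contracts, wiring, and
# gradient correctness against finite differences.

test_that("variant enumeration covers all 16 subsets in reporting order", {
  ev <- enumerate_variants()
  expect_equal(nrow(ev), 16)
  expect_equal(anyDuplicated(ev$name), 0)
  expect_true(all(c("DysDiTect_PLAG", "DysDiTect_") %in% ev$name))
  for (flag in c("use_P", "use_L", "use_A", "use_G"))
    expect_equal(sum(ev[[flag]]), 8)
  # same order as the published ablation table
  expect_equal(ev$name, reference_ablation()$variant)
  expect_equal(vapply(ev$config, variant_name, character(1)), ev$name)
})

test_that("variant names parse back to their flag sets", {
  cfg <- variant_config("DysDiTect_PG")
  expect_true(cfg$use_P && cfg$use_G)
  expect_false(cfg$use_L || cfg$use_A)
  expect_error(variant_config("DysDiTect_GP"), "unknown variant")
  expect_error(variant_config("Dys_PLAG"), "unknown variant")
})

test_that("positional encoding matches the sinusoid formula everywhere", {
  pe <- positional_encoding_table(96, 32)
  expect_equal(dim(pe), c(96, 32))
  # position 0: sin terms 0, cos terms 1
  expect_equal(pe[1, seq(1, 31, 2)], rep(0, 16))
  expect_equal(pe[1, seq(2, 32, 2)], rep(1, 16))
  # brute-force evaluation of the formula
  for (pos in c(0, 1, 17, 95)) {
    for (d in c(1, 2, 15, 32)) {
      i2 <- if (d %% 2 == 1) d - 1 else d - 2
      ref <- if (d %% 2 == 1) sin(pos / 10000^(i2 / 32)) else
        cos(pos / 10000^(i2 / 32))
      expect_equal(pe[pos + 1, d], ref)
    }
  }
})

test_that("the CNN encoder is shared across items (equivariance) and sized right", {
  set.seed(42)
  cfg <- tiny_variant("DysDiTect_", seq_len = 6)
  m <- build_model(cfg)
  x <- array(as.double(runif(6 * 3 * 32 * 32) < 0.1), dim = c(6, 3, 32, 32))
  f <- cnn_encode(m, x)
  expect_equal(dim(f), c(6, cfg$cnn_out_dim))
  perm <- c(3, 1, 6, 2, 5, 4)
  f_perm <- cnn_encode(m, x[perm, , , , drop = FALSE])
  expect_equal(unclass(f_perm), unclass(f)[perm, ], ignore_attr = TRUE)
  # identical inputs give identical rows
  x0 <- array(0, dim = c(6, 3, 32, 32))
  f0 <- cnn_encode(m, x0)
  expect_true(all(abs(sweep(f0, 2, f0[1, ])) < 1e-12))
  expect_true(all(is.finite(f0)))
})

test_that("CNN output is 32 features per item on full-size input", {
  set.seed(1)
  m <- build_model(model_config(use_L = FALSE, use_A = FALSE, use_G = FALSE,
                                use_P = FALSE, seq_len = 4L, image_px = 128L))
  x <- array(as.double(runif(4 * 3 * 128 * 128) < 0.07),
             dim = c(4, 3, 128, 128))
  expect_equal(dim(cnn_encode(m, x)), c(4, 32))
})

test_that("Bi-LSTM encoding concatenates both directions and is reversible", {
  set.seed(7)
  cfg <- model_config(use_P = FALSE, use_A = FALSE, use_G = FALSE,
                      cnn_out_dim = 8L, lstm_hidden = 16L, lstm_layers = 2L,
                      seq_len = 12L, image_px = 32L, dropout = 0)
  m <- build_model(cfg)
  X <- matrix(rnorm(12 * 8), 12, 8)
  out <- bilstm_encode(m, X)
  expect_equal(dim(out), c(12, 32))
  expect_equal(unclass(bilstm_encode(m, X)), unclass(out),
               ignore_attr = TRUE)  # eval-mode determinism

  # default dimensions: 256 features per timestep
  m256 <- with_seed_build(model_config(use_P = FALSE, use_A = FALSE,
                                       use_G = FALSE, seq_len = 5L,
                                       image_px = 32L))
  expect_equal(ncol(bilstm_encode(m256, matrix(rnorm(5 * 32), 5, 32))), 256)
})

test_that("swapping direction weights and reversing input reverses the output", {
  set.seed(11)
  p1 <- c(dysditect:::init_lstm_dir(5L, 7L, "lstm.l1.fwd"),
          dysditect:::init_lstm_dir(5L, 7L, "lstm.l1.bwd"))
  p2 <- p1
  for (s in c("Wx", "Wh", "b")) {
    p2[[paste0("lstm.l1.fwd.", s)]] <- p1[[paste0("lstm.l1.bwd.", s)]]
    p2[[paste0("lstm.l1.bwd.", s)]] <- p1[[paste0("lstm.l1.fwd.", s)]]
  }
  X <- matrix(rnorm(9 * 5), 9, 5)
  out1 <- dysditect:::bilstm_layer_fw(X, p1, "lstm.l1")$out
  out2 <- dysditect:::bilstm_layer_fw(X[9:1, ], p2, "lstm.l1")$out
  expect_equal(out2, out1[9:1, c(8:14, 1:7)], tolerance = 1e-12)
})

test_that("self-attention is row-stochastic, shape-preserving, and uniform on constant input", {
  set.seed(13)
  cfg <- model_config(use_P = FALSE, use_L = FALSE, use_G = FALSE,
                      cnn_out_dim = 8L, attn_heads = 2L, seq_len = 10L,
                      image_px = 32L, dropout = 0)
  m <- build_model(cfg)
  X <- matrix(rnorm(10 * 8), 10, 8)
  at <- self_attend(m, X)
  expect_equal(dim(at$out), c(10, 8))
  expect_equal(dim(at$weights), c(2, 10, 10))
  expect_true(all(abs(apply(at$weights, c(1, 2), sum) - 1) < 1e-5))
  expect_true(all(at$weights >= 0))
  # identical token features at every position -> uniform rows
  Xc <- matrix(rep(rnorm(8), each = 10), 10, 8)
  atc <- self_attend(m, Xc)
  expect_true(all(abs(atc$weights - 1 / 10) < 1e-12))
})

test_that("condensation uses 96 + grade inputs and sigmoid output", {
  set.seed(17)
  mg <- with_seed_build(tiny_variant("DysDiTect_G"))
  expect_equal(nrow(mg$params[["head.w"]]), 97L)
  m0 <- with_seed_build(tiny_variant("DysDiTect_"))
  expect_equal(nrow(m0$params[["head.w"]]), 96L)
  X <- matrix(rnorm(96 * 8), 96, 8)
  out <- condense_classify(mg, X, grade = 4)
  expect_gt(out$prob, 0); expect_lt(out$prob, 1)
  expect_error(condense_classify(mg, X), "grade")
  # doubling the final-layer weights preserves probability ordering
  X2 <- matrix(rnorm(96 * 8), 96, 8)
  p1 <- condense_classify(m0, X)$prob
  p2 <- condense_classify(m0, X2)$prob
  m2 <- m0
  m2$params[["head.w"]] <- 2 * m2$params[["head.w"]]
  m2$params[["head.b"]] <- 2 * m2$params[["head.b"]]
  q1 <- condense_classify(m2, X)$prob
  q2 <- condense_classify(m2, X2)$prob
  expect_equal(p1 > p2, q1 > q2)
})

test_that("all 16 variants run a forward pass and match their stage wiring", {
  set.seed(23)
  x <- array(as.double(runif(8 * 3 * 32 * 32) < 0.1), dim = c(8, 3, 32, 32))
  ev <- enumerate_variants(cnn_out_dim = 8L, lstm_hidden = 6L,
                           attn_heads = 2L, seq_len = 8L, image_px = 32L,
                           dropout = 0)
  for (i in seq_len(nrow(ev))) {
    cfg <- ev$config[[i]]
    m <- build_model(cfg)
    out <- model_forward(m, x, grade = if (cfg$use_G) 3 else NULL)
    expect_gt(out$prob, 0); expect_lt(out$prob, 1)
    # parameter blocks exist iff the stage is enabled
    nms <- names(m$params)
    expect_equal(any(grepl("^lstm\\.", nms)), cfg$use_L, info = ev$name[i])
    expect_equal(any(grepl("^attn\\.", nms)), cfg$use_A, info = ev$name[i])
    expect_equal(is.null(out$attention), !cfg$use_A, info = ev$name[i])
    if (cfg$use_A) {
      d_attn <- if (cfg$use_L) 2 * cfg$lstm_hidden else cfg$cnn_out_dim
      expect_equal(nrow(m$params[["attn.wq.w"]]), d_attn, info = ev$name[i])
    }
    expect_equal(nrow(m$params[["head.w"]]),
                 cfg$seq_len + as.integer(cfg$use_G), info = ev$name[i])
    # forward pass equals the manually chained stages
    f <- cnn_encode(m, x)
    if (cfg$use_P) f <- positional_encode(m, f)
    if (cfg$use_L) f <- bilstm_encode(m, f)
    att <- NULL
    if (cfg$use_A) {
      sa <- self_attend(m, f)
      f <- sa$out; att <- sa$weights
    }
    manual <- condense_classify(m, f, grade = if (cfg$use_G) 3 else NULL)
    expect_equal(out$prob, manual$prob, tolerance = 1e-12, info = ev$name[i])
    if (cfg$use_A) expect_equal(out$attention, att, info = ev$name[i])
  }
})

test_that("enabling the LSTM strictly increases the parameter count", {
  set.seed(29)
  for (base in c("DysDiTect_", "DysDiTect_PA", "DysDiTect_PAG")) {
    m0 <- with_seed_build(tiny_variant(base))
    with_l <- sub("_(P?)(A?)(G?)$", "_\\1L\\2\\3", base)
    m1 <- with_seed_build(tiny_variant(with_l))
    expect_gt(n_parameters(m1), n_parameters(m0))
  }
})

test_that("positional encoding breaks permutation equivariance of the input", {
  set.seed(31)
  cfg <- tiny_variant("DysDiTect_P", seq_len = 8)
  m <- build_model(cfg)
  x <- array(as.double(runif(8 * 3 * 32 * 32) < 0.1), dim = c(8, 3, 32, 32))
  perm <- 8:1
  f <- positional_encode(m, cnn_encode(m, x))
  f_perm <- positional_encode(m, cnn_encode(m, x[perm, , , ]))
  expect_gt(max(abs(unclass(f_perm) - unclass(f)[perm, ])), 1e-6)
})

test_that("analytic gradients agree with finite differences across variants", {
  set.seed(37)
  x <- array(runif(5 * 3 * 32 * 32), dim = c(32, 32, 3, 5))
  eps <- 1e-6
  for (vname in c("DysDiTect_PLAG", "DysDiTect_PA", "DysDiTect_LG",
                  "DysDiTect_")) {
    cfg <- do.call(variant_config,
                   c(list(name = vname, seq_len = 5L, dropout = 0),
                     tiny_model_opts))
    m <- build_model(cfg)
    grade <- if (cfg$use_G) 4 else NULL
    fw <- dysditect:::model_fw(m, x, grade)
    grads <- dysditect:::model_bw(m, fw, fw$prob - 1)
    loss_at <- function(params) {
      m2 <- m; m2$params <- params
      dysditect:::bce_from_logit(dysditect:::model_fw(m2, x, grade)$logit, 1)
    }
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_lt(abs(num - grads[[nm]][i]),
                  1e-6 + 1e-3 * (abs(num) + abs(grads[[nm]][i])))
      }
    }
  }
})

test_that("evaluation mode is deterministic; training mode applies dropout", {
  set.seed(41)
  cfg <- tiny_variant("DysDiTect_L", seq_len = 6, dropout = 0.5)
  m <- build_model(cfg)
  x <- array(as.double(runif(6 * 3 * 32 * 32) < 0.1), dim = c(6, 3, 32, 32))
  a <- model_forward(m, x)$prob
  b <- model_forward(m, x)$prob
  expect_identical(a, b)
  set.seed(1); tr1 <- model_forward(m, x, train = TRUE)$prob
  set.seed(2); tr2 <- model_forward(m, x, train = TRUE)$prob
  expect_false(identical(tr1, tr2))
})

test_that("the transfer backbone demands an external weight bundle", {
  expect_error(build_model(model_config(backbone = "resnet50_transfer")),
               "pretrained")
})
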