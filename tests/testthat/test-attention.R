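# Attained-weight distributions, entropy, summaries, heatmap scaling, and
# ICC(3,k) against ANOVA oracles.

test_that("attained distributions renormalize columns of the head average", {
  t_len <- 96L
  uni <- array(1 / t_len, dim = c(4, t_len, t_len))
  att <- attained_distributions(uni)
  expect_equal(att, matrix(1 / t_len, t_len, t_len))

  eye <- array(0, dim = c(2, 5, 5))
  for (h in 1:2) eye[h, , ] <- diag(5)
  att_eye <- attained_distributions(eye)
  expect_equal(att_eye, diag(5))   # token j attained only by row j

  rnd <- random_attention(heads = 4L, t_len = 30L)
  att_rnd <- attained_distributions(rnd)
  expect_true(all(abs(colSums(att_rnd) - 1) < 1e-9))
  att_raw <- attained_distributions(rnd, renorm = FALSE)
  expect_equal(att_raw, apply(rnd, c(2, 3), mean) / 30)
})

test_that("entropy honours its closed forms and bounds", {
  expect_equal(entropy_bits(rep(1 / 96, 96)), log2(96))
  expect_equal(entropy_bits(c(1, rep(0, 95))), 0)
  expect_equal(entropy_bits(rep(c(1 / 48, 0), 48)), log2(48))
  expect_error(entropy_bits(c(-0.1, 1.1)), "non-negative")
  expect_error(entropy_bits(c(0.5, 0.4)), "sum to 1")
  set.seed(2)
  for (i in 1:20) {
    p <- rexp(96); p <- p / sum(p)
    h <- entropy_bits(p)
    expect_gte(h, 0)
    expect_lte(h, log2(96) + 1e-12)
  }
})

test_that("entropy summaries match an independent aggregation oracle", {
  set.seed(8)
  n <- 1000
  rec <- tibble::tibble(
    participant_id = sample(sprintf("P%02d", 1:20), n, replace = TRUE),
    status = sample(c("TD", "DD"), n, replace = TRUE),
    position_index = sample(0:95, n, replace = TRUE),
    entropy_bits = runif(n, 0, log2(96)),
    response = sample(c("correct", "wrong"), n, replace = TRUE))
  out <- entropy_summary(rec)
  for (i in seq_len(nrow(out))) {
    sel <- rec$status == out$status[i] & rec$response == out$response[i]
    expect_equal(out$K[i], sum(sel))
    expect_equal(out$M[i], mean(rec$entropy_bits[sel]))
    expect_equal(out$SD[i], sd(rec$entropy_bits[sel]))
  }
})

test_that("entropy summary conventions for empty and singleton cells hold", {
  one <- tibble::tibble(participant_id = "P01", status = "TD",
                        position_index = 0L, entropy_bits = 3.2,
                        response = "correct")
  out <- entropy_summary(one)
  expect_equal(out$K[out$status == "TD" & out$response == "correct"], 1L)
  expect_equal(out$M[out$status == "TD" & out$response == "correct"], 3.2)
  expect_true(is.na(out$SD[out$status == "TD" & out$response == "correct"]))
  expect_equal(out$K[out$status == "DD" & out$response == "wrong"], 0L)
  expect_true(is.na(out$M[out$status == "DD" & out$response == "wrong"]))
})

test_that("heatmap scaling multiplies by sequence length and clips", {
  t_len <- 96L
  uni <- array(1 / t_len, dim = c(4, t_len, t_len))
  expect_equal(scale_for_heatmap(uni, c(0, 2)),
               matrix(1, t_len, t_len))
  rnd <- random_attention(4L, 20L)
  sc <- scale_for_heatmap(rnd, c(0, 2))
  expect_true(all(sc >= 0 & sc <= 2))
  # one dominant column displays above 1
  M <- matrix(0.3 / 19, 20, 20); M[, 7] <- 0.7; M <- M / rowSums(M)
  sc2 <- scale_for_heatmap(M, c(0, 2))
  expect_true(all(sc2[, 7] > 1))
  expect_error(scale_for_heatmap(rnd, c(2, 1)), "lo < hi")
})

# independent oracle: mean squares from a two-way ANOVA fit
icc3k_aov <- function(ratings) {
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(nrow(ratings)), ncol(ratings))),
                   rater = factor(rep(seq_len(ncol(ratings)),
                                      each = nrow(ratings))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  ms_r <- tab["subj", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  (ms_r - ms_e) / ms_r
}

test_that("icc3k equals the two-way ANOVA oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    base <- rnorm(n)
    ratings <- cbind(base + rnorm(n, sd = 0.5), base + rnorm(n, sd = 0.5))
    expect_equal(icc3k(ratings)$icc, icc3k_aov(ratings), tolerance = 1e-8)
  }
})

test_that("icc3k worked example: a hand-computed 4x2 table", {
  ratings <- matrix(c(1, 2, 3, 4,
                      2, 2, 4, 5), ncol = 2)
  # explicit sums of squares
  grand <- mean(ratings)
  ss_rows <- 2 * sum((rowMeans(ratings) - grand)^2)
  ss_cols <- 4 * sum((colMeans(ratings) - grand)^2)
  ss_err <- sum((ratings - grand)^2) - ss_rows - ss_cols
  expected <- (ss_rows / 3 - ss_err / 3) / (ss_rows / 3)
  res <- icc3k(ratings)
  expect_equal(res$icc, expected, tolerance = 1e-10)
  expect_equal(res$icc, icc3k_aov(ratings), tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(3, 3))
})

test_that("icc3k degenerate and null behaviour", {
  x <- rnorm(10)
  ident <- icc3k(cbind(x, x))
  expect_equal(ident$icc, 1)
  expect_equal(ident$ci_lower, 1)
  set.seed(99)
  null <- icc3k(cbind(rnorm(1e4), rnorm(1e4)))
  expect_lt(abs(null$icc), 0.05)
  expect_error(icc3k(cbind(1:2, 3:4)), "at least 3")
  expect_error(icc3k(cbind(c(1, 2, NA), 1:3)), "finite")
})

test_that("the F statistic implies the ICC and its confidence bounds", {
  # consistency between the reported F and interval endpoints:
  # icc = 1 - 1/F, bounds from the F quantiles on (N-1, N-1) df at k = 2
  set.seed(4)
  base <- rnorm(92)
  ratings <- cbind(base + rnorm(92), base + rnorm(92))
  res <- icc3k(ratings)
  expect_equal(res$icc, 1 - 1 / res$F, tolerance = 1e-12)
  expect_equal(res$ci_lower, 1 - qf(0.975, res$df1, res$df2) / res$F,
               tolerance = 1e-12)
})
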