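# Cohort generator: ability calibration, the discontinuation rule, the
# renderer, and reproducibility.

test_that("sampled abilities match the calibration moments", {
  cfg <- cohort_config()
  set.seed(101)
  # Grade 2 TD: mean score 42.9/96 = 0.447
  a <- sample_ability(2, "TD", cfg, n = 1e4)
  expect_lt(abs(mean(a) - 42.9 / 96), 0.01)
  # Grade 6 DD: sd 17.4/96 = 0.181
  b <- sample_ability(6, "DD", cfg, n = 1e4)
  expect_lt(abs(sd(b) - 17.4 / 96), 0.02)
  expect_true(all(a > 0 & a < 1))
})

test_that("degenerate and infeasible Beta moments are handled", {
  ap <- tibble::tibble(grade = 3L, status = "TD",
                       mean_correct = 48, sd_correct = 0.5)
  cfg <- cohort_config(counts = tibble::tibble(grade = 3L, status = "TD", n = 1L),
                       accuracy_params = ap)
  set.seed(5)
  draws <- sample_ability(3, "TD", cfg, n = 200)
  expect_true(all(abs(draws - 0.5) < 0.05))
  ap_bad <- tibble::tibble(grade = 3L, status = "TD",
                           mean_correct = 48, sd_correct = 50)
  cfg_bad <- cohort_config(counts = cfg$counts, accuracy_params = ap_bad)
  expect_error(sample_ability(3, "TD", cfg_bad), "infeasible")
  expect_error(sample_ability(2, "XX", cfg), "no accuracy parameters")
})

test_that("the discontinuation rule blanks everything after 8 failed words", {
  # all 16 first characters wrong -> the rest is blank
  labels <- discontinue_labels(rep(FALSE, 96))
  expect_equal(labels[1:16], rep("wrong", 16))
  expect_equal(labels[17:96], rep("blank", 80))
  # a fully correct run never blanks
  expect_equal(discontinue_labels(rep(TRUE, 96)), rep("correct", 96))
  # one wrong character makes the word incorrect, but a correct word
  # resets the run
  ok <- rep(TRUE, 96)
  ok[seq(1, 13, 2)] <- FALSE            # words 1-7 incorrect, word 8 correct
  lab <- discontinue_labels(ok)
  expect_false(any(lab == "blank"))
  ok2 <- rep(TRUE, 96)
  ok2[seq(1, 16, 2)] <- FALSE           # words 1-8 incorrect
  lab2 <- discontinue_labels(ok2)
  expect_equal(lab2[17:96], rep("blank", 80))
  expect_equal(lab2[1:16], rep(c("wrong", "correct"), 8))
})

test_that("blanks always form a (possibly empty) suffix", {
  cfg <- cohort_config()
  set.seed(7)
  for (p in runif(60, 0.02, 0.98)) {
    resp <- simulate_responses(p, cfg)$response
    blanks <- which(resp == "blank")
    if (length(blanks) > 0)
      expect_equal(blanks, seq(min(blanks), 96))
  }
})

test_that("mean blank count is non-increasing in ability", {
  cfg <- cohort_config()
  set.seed(17)
  grid <- seq(0.1, 0.9, by = 0.1)
  mean_blanks <- vapply(grid, function(p) {
    mean(replicate(500, sum(simulate_responses(p, cfg)$response == "blank")))
  }, numeric(1))
  expect_true(all(diff(mean_blanks) < 1))   # monotone up to MC noise
  expect_gt(mean_blanks[1], mean_blanks[9])
})

test_that("per-cell mean scores land on the calibration targets", {
  cfg <- cohort_config()
  norms <- dictation_norms()
  set.seed(23)
  for (r in seq_len(nrow(norms))) {
    ab <- sample_ability(norms$grade[r], norms$status[r], cfg, n = 1000)
    cnt <- vapply(ab, function(p)
      sum(simulate_responses(p, cfg)$response == "correct"), numeric(1))
    expect_lt(abs(mean(cnt) - norms$mean_correct[r]), 1.5)
  }
})

test_that("synthetic TD outscores DD within every grade", {
  cfg <- cohort_config()
  set.seed(29)
  for (g in 2:6) {
    td <- mean(sample_ability(g, "TD", cfg, n = 1000))
    dd <- mean(sample_ability(g, "DD", cfg, n = 1000))
    expect_gt(td, dd)
  }
})

test_that("rendering respects the response type", {
  cfg <- cohort_config(counts = tibble::tibble(grade = 2L, status = "TD", n = 1L),
                       render = tiny_render(128L))
  tpl <- dysditect:::char_templates(cfg)
  set.seed(31)
  blank <- render_response("blank", tpl[[1]], cfg)
  expect_lt(mean(blank), 0.005)
  fracs <- vapply(1:300, function(i)
    mean(render_response("correct", tpl[[(i %% 96) + 1]], cfg)), numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.20)
  for (i in 1:20) {
    cor_img <- render_response("correct", tpl[[i]], cfg)
    wrong_img <- render_response("wrong", tpl[[i]], cfg)
    expect_gt(sum(cor_img != wrong_img), 0)
  }
})

test_that("cohort generation is reproducible and respects the counts", {
  counts <- tibble::tibble(grade = c(2L, 5L), status = c("TD", "DD"),
                           n = c(3L, 2L))
  cfg <- cohort_config(counts = counts, render = tiny_render(32L), seed = 77L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(nrow(a$participants), 5)
  expect_equal(length(a$images), 5)
  expect_identical(a$images, b$images)
  expect_identical(a$responses, b$responses)
  c2 <- generate_cohort(cohort_config(counts = counts,
                                      render = tiny_render(32L), seed = 78L))
  expect_false(identical(a$images, c2$images))
  # empty cohort
  empty <- generate_cohort(cohort_config(
    counts = tibble::tibble(grade = 2L, status = "TD", n = 0L),
    render = tiny_render(32L)))
  expect_equal(nrow(empty$participants), 0)
  expect_equal(length(empty$images), 0)
})

test_that("cohorts round-trip through PNG files and a manifest", {
  coh <- test_cohort(n_per_cell = 1L, grades = 2L, px = 32L, seed = 3L)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_equal(nrow(man), 2 * 96)
  expect_true(all(file.exists(man$path)))
  back <- load_cohort(file.path(dir, "manifest.csv"))
  for (id in names(coh$images))
    expect_identical(as.integer(back$images[[id]]),
                     as.integer(coh$images[[id]]))
  expect_equal(back$participants$n_correct, coh$participants$n_correct)
})
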