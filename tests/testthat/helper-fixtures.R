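# Shared fixtures: small render settings, balanced cohorts and tiny model
# dimensions keep the suite fast while exercising the full pipeline.

tiny_render <- function(px = 32L, ...) {
  utils::modifyList(list(image_px = as.integer(px), stroke_range = c(4L, 9L),
                         jitter = 0.012, stroke_width = 3,
                         scribble_prob = 0, mark_prob = 0),
                    list(...))
}

# balanced cohort with enough participants per stratum for an 8:1:1 split
test_cohort <- function(n_per_cell = 8L, grades = c(2L, 4L), px = 32L,
                        seed = 5L, render = TRUE) {
  counts <- tidyr::expand_grid(grade = grades, status = c("TD", "DD"))
  counts$n <- as.integer(n_per_cell)
  cfg <- cohort_config(counts = counts, render = tiny_render(px), seed = seed)
  generate_cohort(cfg, render = render)
}

# strongly separated cohort (non-overlapping ability distributions)
separable_cohort <- function(n_per_cell = 10L, px = 32L, seed = 9L) {
  counts <- tibble::tibble(grade = c(3L, 3L), status = c("TD", "DD"),
                           n = as.integer(n_per_cell))
  ap <- tibble::tibble(grade = c(3L, 3L), status = c("TD", "DD"),
                       mean_correct = c(88, 10), sd_correct = c(3, 3))
  cfg <- cohort_config(counts = counts, accuracy_params = ap,
                       render = tiny_render(px), seed = seed)
  generate_cohort(cfg)
}

tiny_model_opts <- list(cnn_out_dim = 8L, lstm_hidden = 6L, lstm_layers = 2L,
                        attn_heads = 2L, image_px = 32L)

tiny_variant <- function(name, seq_len = 96L, dropout = 0.2) {
  do.call(variant_config,
          c(list(name = name, seq_len = as.integer(seq_len),
                 dropout = dropout), tiny_model_opts))
}

with_seed_build <- function(cfg, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  m <- build_model(cfg)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  m
}

# random row-stochastic attention array
random_attention <- function(heads = 4L, t_len = 96L) {
  a <- array(stats::rexp(heads * t_len * t_len), dim = c(heads, t_len, t_len))
  for (h in seq_len(heads)) a[h, , ] <- a[h, , ] / rowSums(a[h, , ])
  a
}
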