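# Attention-map analyses: attained-weight distributions per character,
# Shannon entropy of those distributions, group/response summaries, the
# display scaling used for heatmaps, and ICC(3,k) agreement.

#' Attained-weight distributions
#'
#' Heads are averaged into a single row-stochastic matrix; the attained
#' weights of character `j` are column `j` (the attention assigned *to* it
#' by all tokens), renormalized to sum to one. With `renorm = FALSE` the
#' column is divided by the sequence length instead.
#'
#' @param weights `(heads, T, T)` attention array (rows row-stochastic), or
#'   a `(T, T)` matrix.
#' @param renorm renormalize each column to sum 1.
#' @return A `T x T` matrix whose column `j` is the attained-weight
#'   distribution of token `j`.
#' @export
attained_distributions <- function(weights, renorm = TRUE) {
  M <- head_average(weights)
  cs <- colSums(M)
  if (any(cs <= 0)) stop("degenerate attention: a column sums to zero")
  if (renorm) sweep(M, 2, cs, "/") else M / nrow(M)
}

head_average <- function(weights) {
  if (length(dim(weights)) == 3) apply(weights, c(2, 3), mean)
  else as.matrix(weights)
}

#' Shannon entropy in bits
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention. Entries must be
#' non-negative and sum to 1 (within 1e-6).
#'
#' @param dist a probability vector.
#' @return Entropy in bits, in `[0, log2(length(dist))]`.
#' @export
entropy_bits <- function(dist) {
  if (any(dist < 0)) stop("probabilities must be non-negative")
  if (abs(sum(dist) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- dist[dist > 0]
  -sum(nz * log2(nz))
}

#' Per-character attention entropy records
#'
#' Extracts a participant's attention weights, forms the attained-weight
#' distribution of every character, and returns its entropy alongside the
#' response code.
#'
#' @param fit a `dysditect_fit` or `dysditect_model` whose variant uses
#'   attention.
#' @param cohort a rendered `dictation_cohort`.
#' @param ids participant ids (default: all).
#' @param renorm see [attained_distributions()].
#' @return A tibble: `participant_id`, `status`, `position_index`,
#'   `entropy_bits`, `response`.
#' @export
attention_entropy <- function(fit, cohort, ids = NULL, renorm = TRUE) {
  model <- if (inherits(fit, "dysditect_fit")) fit$model else fit
  if (!model$config$use_A)
    stop("variant ", variant_name(model$config), " has no attention module")
  if (is.null(ids)) ids <- cohort$participants$participant_id
  purrr::map_dfr(ids, function(id) {
    rec <- participant_internal(cohort, id)
    fw <- model_fw(model, rec$x, rec$grade, train = FALSE, s0 = rec$s0)
    att <- attained_distributions(fw$attention, renorm = renorm)
    resp <- cohort$responses[cohort$responses$participant_id == id, ]
    part <- cohort$participants[cohort$participants$participant_id == id, ]
    tibble::tibble(participant_id = id, status = part$status,
                   position_index = resp$position_index,
                   entropy_bits = apply(att, 2, entropy_bits),
                   response = resp$response)
  })
}

#' Summarize entropy by group and response
#'
#' @param records a tibble from [attention_entropy()] (columns `status`,
#'   `response`, `entropy_bits`).
#' @param responses response categories to tabulate.
#' @return A tibble with one row per group-by-response cell: `status`,
#'   `response`, `K` (count), `M` (mean), `SD`. Empty cells keep `K = 0`
#'   with `M`/`SD` absent (`NA`); singleton cells have `SD = NA`.
#' @export
entropy_summary <- function(records, responses = c("correct", "wrong")) {
  grid <- tidyr::expand_grid(status = c("TD", "DD"), response = responses)
  agg <- records |>
    dplyr::filter(.data$response %in% responses) |>
    dplyr::group_by(.data$status, .data$response) |>
    dplyr::summarise(K = dplyr::n(), M = mean(.data$entropy_bits),
                     SD = sd(.data$entropy_bits), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = c("status", "response"))
  out$K[is.na(out$K)] <- 0L
  out
}

#' Display scaling of an attention map
#'
#' The head-averaged matrix is multiplied by the sequence length (so a
#' uniform map displays as 1 everywhere) and clipped to `[lo, hi]`.
#'
#' @param weights `(heads, T, T)` array or `(T, T)` matrix.
#' @param clip length-2 numeric `(lo, hi)`, `lo < hi`.
#' @return A `T x T` matrix with values in `[lo, hi]`.
#' @export
scale_for_heatmap <- function(weights, clip = c(0, 2)) {
  if (clip[1] >= clip[2]) stop("clip must satisfy lo < hi")
  M <- head_average(weights) * nrow(head_average(weights))
  pmin(pmax(M, clip[1]), clip[2])
}

#' Heatmap of an attention map
#'
#' @param weights `(heads, T, T)` array or `(T, T)` matrix.
#' @param clip display clip window, see [scale_for_heatmap()].
#' @return A ggplot raster: rows = attending token (top first), columns =
#'   attended token.
#' @export
plot_attention <- function(weights, clip = c(0, 2)) {
  M <- scale_for_heatmap(weights, clip)
  df <- tidyr::expand_grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  df$value <- M[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red",
                                  midpoint = 1, limits = clip) +
    ggplot2::labs(x = "attended token", y = "attending token",
                  fill = "scaled\nweight")
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects model, consistency definition, average of k
#' ratings: `ICC(3,k) = (MS_rows - MS_error) / MS_rows` from the two-way
#' ANOVA decomposition, with `F = MS_rows / MS_error` on
#' `(N-1, (N-1)(k-1))` degrees of freedom and an F-based 95% confidence
#' interval.
#'
#' @param ratings numeric matrix, `N` subjects by `k` raters/measures
#'   (typically k = 2).
#' @param conf_level confidence level for the interval.
#' @return A one-row tibble: `icc`, `ci_lower`, `ci_upper`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
icc3k <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 columns")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  ms_r <- ss_rows / df1
  ms_e <- ss_err / df2
  if (ms_e <= .Machine$double.eps * max(1, ms_r)) {
    return(tibble::tibble(icc = 1, ci_lower = 1, ci_upper = 1,
                          F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  Fobs <- ms_r / ms_e
  alpha <- 1 - conf_level
  fl <- Fobs / qf(1 - alpha / 2, df1, df2)
  fu <- Fobs * qf(1 - alpha / 2, df2, df1)
  tibble::tibble(icc = (ms_r - ms_e) / ms_r,
                 ci_lower = 1 - 1 / fl, ci_upper = 1 - 1 / fu,
                 F = Fobs, df1 = df1, df2 = df2,
                 p = pf(Fobs, df1, df2, lower.tail = FALSE))
}

#' Pair per-participant entropy with accuracy for agreement analysis
#'
#' Builds the two-column rating matrix (per-participant mean attained-weight
#' entropy, z-scored, against per-participant proportion correct, z-scored)
#' fed to [icc3k()]. The pairing is configurable because the published
#' analysis leaves it open.
#'
#' @param records tibble from [attention_entropy()].
#' @param cohort the matching `dictation_cohort`.
#' @return A list with the `ratings` matrix (N x 2) and the participant ids.
#' @export
entropy_accuracy_ratings <- function(records, cohort) {
  ent <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(entropy = mean(.data$entropy_bits), .groups = "drop")
  acc <- cohort$participants[, c("participant_id", "n_correct")]
  m <- dplyr::inner_join(ent, acc, by = "participant_id")
  z <- function(x) (x - mean(x)) / sd(x)
  list(ratings = cbind(entropy = z(m$entropy),
                       accuracy = z(m$n_correct / cohort$config$n_items)),
       participant_id = m$participant_id)
}
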