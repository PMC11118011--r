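# Synthetic dictation cohorts.
#
# The study's handwriting dataset is private, so this module generates
# desk-scale cohorts carrying the statistical structure the classifier
# exploits: group- and grade-dependent accuracy calibrated to the published
# norms, a discontinuation rule that produces blank runs late in the
# sequence, and rendered pseudo-character images whose response type
# (correct / wrong / blank) is visible in the pixels.

#' Published group norms for the encoded dictation task
#'
#' Per grade-by-status cell: number of participants and the mean / SD of the
#' number of correctly written characters (out of 96) reported for the
#' encoded subsample (N = 869) of the original DysDiTect study.
#'
#' @return A tibble with columns `grade`, `status`, `n`, `mean_correct`,
#'   `sd_correct`.
#' @export
dictation_norms <- function() {
  tibble::tibble(
    grade = rep(2:6, 2),
    status = rep(c("TD", "DD"), each = 5),
    n = c(165L, 111L, 102L, 56L, 31L, 162L, 101L, 54L, 62L, 25L),
    mean_correct = c(42.9, 53.1, 68.1, 76.3, 83.0,
                     20.9, 32.6, 38.3, 48.9, 56.3),
    sd_correct = c(15.4, 16.7, 13.6, 13.0, 10.3,
                   12.4, 16.2, 16.5, 18.9, 17.4))
}

#' Grade-by-status composition of the full study cohort
#'
#' The 1064-participant composition (483 DD, 581 TD) of the original study.
#'
#' @return A tibble with columns `grade`, `status`, `n`.
#' @export
study_cohort_counts <- function() {
  tibble::tibble(grade = rep(2:6, 2),
                 status = rep(c("DD", "TD"), each = 5),
                 n = c(172L, 110L, 101L, 72L, 28L,
                       174L, 158L, 143L, 62L, 44L))
}

#' Configure a synthetic dictation cohort
#'
#' @param counts tibble (`grade`, `status`, `n`): participants per cell.
#' @param accuracy_params tibble (`grade`, `status`, `mean_correct`,
#'   `sd_correct`): per-cell moments of the number-correct score out of
#'   `n_items`; defaults to [dictation_norms()].
#' @param n_items characters per participant (48 two-character words).
#' @param discontinuation list: testing stops once `window_words`
#'   consecutive words (of `chars_per_word` characters) are incorrect.
#' @param item_difficulty list: `enabled` and `slope`. When enabled, word
#'   difficulties rise linearly from `-slope` to `+slope` logits across the
#'   sequence (the task's incremental-difficulty design) and each
#'   participant's latent ability is solved so that the expected
#'   number-correct *under the stop rule* equals `n_items` times the
#'   sampled ability. Without the gradient, low-ability participants hit
#'   the stop rule almost immediately and per-cell mean scores fall far
#'   below the calibration targets.
#' @param render list of rendering parameters: `image_px` (square side,
#'   multiple of 32), `stroke_range` (strokes per template), `jitter`
#'   (endpoint jitter, unit-box coordinates), `stroke_width` (line width in
#'   pixels at 128 px, rescaled with `image_px`), `scribble_prob`
#'   (probability a blank is replaced by a cross-out scribble), `mark_prob`
#'   (probability of overlaying a scoring tick/cross on a non-blank).
#' @param template_seed fixed seed for the 96 character templates (the same
#'   dictation materials are presented to every participant, so templates
#'   do not vary with the cohort seed).
#' @param seed cohort seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(counts = study_cohort_counts(),
                          accuracy_params = dictation_norms(),
                          n_items = 96L,
                          discontinuation = list(window_words = 8L,
                                                 chars_per_word = 2L),
                          item_difficulty = list(enabled = TRUE, slope = 4),
                          render = list(image_px = 128L,
                                        stroke_range = c(4L, 9L),
                                        jitter = 0.012,
                                        stroke_width = 3,
                                        scribble_prob = 0,
                                        mark_prob = 0),
                          template_seed = 96L,
                          seed = 42L) {
  stopifnot(all(counts$n >= 0),
            all(accuracy_params$mean_correct >= 0),
            all(accuracy_params$mean_correct <= n_items),
            all(accuracy_params$sd_correct > 0))
  structure(list(counts = counts, accuracy_params = accuracy_params,
                 n_items = as.integer(n_items),
                 discontinuation = discontinuation,
                 item_difficulty = item_difficulty, render = render,
                 template_seed = template_seed, seed = seed),
            class = "cohort_config")
}

#' Desk-scale cohort configuration
#'
#' The full-cohort composition scaled down proportionally (largest
#' remainder) to `n_total` participants, keeping every grade-by-status cell
#' represented; all other settings as [cohort_config()].
#'
#' @param n_total total participants.
#' @param ... passed on to [cohort_config()].
#' @export
desk_cohort_config <- function(n_total = 120L, ...) {
  counts <- study_cohort_counts()
  quota <- counts$n * n_total / sum(counts$n)
  n <- floor(quota)
  short <- n_total - sum(n)
  ord <- order(quota - n, decreasing = TRUE)
  n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1L
  counts$n <- as.integer(n)
  cohort_config(counts = counts, ...)
}

# run expr under a temporary RNG seed, restoring caller RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-component seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Sample participant abilities for one cohort cell
#'
#' Ability is the per-character probability of a correct response, drawn
#' from a Beta distribution moment-matched to the cell's score mean / 96
#' and SD / 96, clipped to (0.01, 0.99). Draws come from the current RNG
#' stream.
#'
#' @param grade school grade (2-6).
#' @param status `"TD"` or `"DD"`.
#' @param config a `cohort_config`.
#' @param n number of draws.
#' @return Numeric vector of abilities in (0, 1).
#' @export
sample_ability <- function(grade, status, config, n = 1L) {
  ap <- config$accuracy_params
  row <- ap[ap$grade == grade & ap$status == status, ]
  if (nrow(row) != 1)
    stop("no accuracy parameters for grade ", grade, " status ", status)
  m <- row$mean_correct / config$n_items
  s <- row$sd_correct / config$n_items
  if (s^2 >= m * (1 - m))
    stop("infeasible Beta moments for grade ", grade, " ", status,
         ": sd^2 >= mean * (1 - mean)")
  k <- m * (1 - m) / s^2 - 1
  pmin(0.99, pmax(0.01, stats::rbeta(n, m * k, (1 - m) * k)))
}

# Word difficulties (logits), rising linearly across the sequence.
word_difficulties <- function(config) {
  n_words <- config$n_items %/% config$discontinuation$chars_per_word
  if (!isTRUE(config$item_difficulty$enabled)) return(rep(0, n_words))
  s <- config$item_difficulty$slope
  s * (seq_len(n_words) - (n_words + 1) / 2) / ((n_words - 1) / 2)
}

# Expected number of correct characters under the stop rule, given
# per-word character success probabilities. Exact dynamic program over the
# consecutive-incorrect run length (a word is correct iff both characters
# are, so the word-level success probability is p_w^cpw).
expected_correct <- function(p_word, window, cpw) {
  state <- c(1, numeric(window - 1))       # P(run length = 0..window-1)
  total <- 0
  for (w in seq_along(p_word)) {
    reach <- sum(state)
    if (reach < 1e-14) break
    total <- total + reach * cpw * p_word[w]
    q <- p_word[w]^cpw                     # word fully correct
    new_state <- numeric(window)
    new_state[1] <- reach * q
    new_state[2:window] <- state[1:(window - 1)] * (1 - q)
    state <- new_state                     # mass reaching run = window stops
  }
  total
}

# Solve the latent ability location so that the expected number of correct
# characters, *including* the truncation caused by the stop rule, equals
# n_items * p. This is what makes per-cell mean scores land on the
# calibration targets.
solve_theta <- function(p, diffs, window, cpw) {
  n_items <- length(diffs) * cpw
  f <- function(theta)
    expected_correct(stats::plogis(theta - diffs), window, cpw) - p * n_items
  stats::uniroot(f, c(-60, 60), tol = 1e-9)$root
}

#' Apply the discontinuation rule to character outcomes
#'
#' Characters are grouped into words of `cpw`; a word is incorrect iff any
#' of its characters is wrong. Once `window` consecutive words are
#' incorrect (checked on word boundaries), every remaining character is
#' blank; the characters of the triggering words keep their labels.
#'
#' @param char_ok logical vector (TRUE = character written correctly),
#'   length a multiple of `cpw`.
#' @param window consecutive incorrect words that stop testing.
#' @param cpw characters per word.
#' @return Character vector over `"correct"`, `"wrong"`, `"blank"`.
#' @export
discontinue_labels <- function(char_ok, window = 8L, cpw = 2L) {
  stopifnot(length(char_ok) %% cpw == 0)
  n_words <- length(char_ok) %/% cpw
  resp <- character(length(char_ok))
  run <- 0L; stopped <- FALSE
  for (w in seq_len(n_words)) {
    idx <- ((w - 1L) * cpw + 1L):(w * cpw)
    if (stopped) { resp[idx] <- "blank"; next }
    ok <- char_ok[idx]
    resp[idx] <- ifelse(ok, "correct", "wrong")
    run <- if (all(ok)) 0L else run + 1L
    if (run >= window) stopped <- TRUE
  }
  resp
}

#' Simulate one participant's response sequence
#'
#' Characters are drawn independently given the participant's ability (with
#' the per-word difficulty gradient when enabled); a word is incorrect iff
#' either of its characters is wrong; after `window_words` consecutive
#' incorrect words, every remaining character is blank.
#'
#' @param ability per-character probability of a correct response, in (0,1).
#' @param config a `cohort_config`.
#' @return A tibble with `position_index` (0-based), `word` (1-based), and
#'   `response` (`"correct"`, `"wrong"` or `"blank"`).
#' @export
simulate_responses <- function(ability, config) {
  stopifnot(ability > 0, ability < 1)
  cpw <- config$discontinuation$chars_per_word
  window <- config$discontinuation$window_words
  n_words <- config$n_items %/% cpw
  diffs <- word_difficulties(config)
  p_word <- if (isTRUE(config$item_difficulty$enabled))
    stats::plogis(solve_theta(ability, diffs, window, cpw) - diffs)
  else rep(ability, n_words)
  char_ok <- unlist(lapply(seq_len(n_words), function(w)
    stats::rbinom(cpw, 1L, p_word[w]) == 1L))
  resp <- discontinue_labels(char_ok, window = window, cpw = cpw)
  tibble::tibble(position_index = 0:(config$n_items - 1L),
                 word = rep(seq_len(n_words), each = cpw),
                 response = resp)
}

## ---- rendering -------------------------------------------------------------

# 96 fixed pseudo-character templates: per item, a set of polyline strokes
# in unit-box coordinates. The same materials go to every participant.
char_templates <- function(config) {
  with_local_seed(config$template_seed, {
    lapply(seq_len(config$n_items), function(i) {
      n_strokes <- sample(config$render$stroke_range[1]:config$render$stroke_range[2], 1)
      lapply(seq_len(n_strokes), function(s) {
        n_pts <- sample(2:4, 1)
        pts <- cbind(runif(n_pts, 0.15, 0.85), runif(n_pts, 0.15, 0.85))
        cbind(pts[-n_pts, 1], pts[-n_pts, 2], pts[-1, 1], pts[-1, 2])
      })
    })
  })
}

# flatten a template (list of per-stroke segment matrices) to one segment
# matrix in pixel coordinates, with endpoint jitter
template_segments <- function(strokes, px, jitter) {
  segs <- do.call(rbind, strokes)
  if (is.null(segs) || nrow(segs) == 0) return(matrix(0, 0, 4))
  segs + matrix(rnorm(length(segs), 0, jitter), nrow(segs), 4)
}

perturb_template <- function(strokes, config) {
  ops <- c("remove", "extra", "displace")
  op <- sample(ops, 1)
  if (op == "remove" && length(strokes) > 1) {
    strokes[[sample(length(strokes), 1)]] <- NULL
  } else if (op == "displace") {
    k <- sample(length(strokes), 1)
    off <- runif(2, -0.18, 0.18)
    strokes[[k]][, c(1, 3)] <- strokes[[k]][, c(1, 3)] + off[1]
    strokes[[k]][, c(2, 4)] <- strokes[[k]][, c(2, 4)] + off[2]
  } else {
    pts <- cbind(runif(2, 0.1, 0.9), runif(2, 0.1, 0.9))
    strokes[[length(strokes) + 1]] <- cbind(pts[1, 1], pts[1, 2],
                                            pts[2, 1], pts[2, 2])
  }
  strokes
}

#' Render one character response as a binary image
#'
#' Correct responses render the item's fixed template with small endpoint
#' jitter; wrong responses perturb the template (a stroke removed, added,
#' or displaced); blanks are empty (optionally a cross-out scribble).
#'
#' @param response `"correct"`, `"wrong"` or `"blank"`.
#' @param template one element of the fixed template list (a list of
#'   per-stroke segment matrices in unit coordinates).
#' @param config a `cohort_config`.
#' @return An `image_px` x `image_px` integer matrix with values in {0, 1}.
#' @export
render_response <- function(response, template, config) {
  px <- config$render$image_px
  hw <- max(0.5, config$render$stroke_width / 2 * px / 128)
  if (response == "blank") {
    if (runif(1) < config$render$scribble_prob) {
      segs <- rbind(c(0.2, 0.3, 0.8, 0.7), c(0.2, 0.7, 0.8, 0.3)) * px
      return(raster_segments(px, px, segs, hw))
    }
    return(matrix(0L, px, px))
  }
  strokes <- if (response == "wrong") perturb_template(template, config) else template
  segs <- template_segments(strokes, px, config$render$jitter) * px
  img <- raster_segments(px, px, segs, hw)
  if (config$render$mark_prob > 0 && runif(1) < config$render$mark_prob) {
    mark <- if (response == "correct")
      rbind(c(0.72, 0.85, 0.8, 0.95), c(0.8, 0.95, 0.95, 0.72)) * px
    else rbind(c(0.72, 0.72, 0.95, 0.95), c(0.72, 0.95, 0.95, 0.72)) * px
    img <- pmax(img, raster_segments(px, px, mark, hw))
  }
  img
}

#' Generate a synthetic dictation cohort
#'
#' Samples abilities per cell, simulates response sequences under the
#' discontinuation rule, and renders the character images. Fully
#' reproducible from `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a `cohort_config`.
#' @param render render images (set `FALSE` for response-level analyses).
#' @return A `dictation_cohort`: list with `participants` (tibble:
#'   `participant_id`, `grade`, `status`, `ability`, `n_correct`),
#'   `responses` (long tibble: `participant_id`, `position_index`, `word`,
#'   `response`), `images` (named list of `(px, px, n_items)` raw arrays,
#'   values 0/1), and `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  templates <- if (render) char_templates(config) else NULL
  px <- config$render$image_px
  with_local_seed(derive_seed(config$seed, "cohort"), {
    cells <- dplyr::filter(config$counts, .data$n > 0)
    parts <- list(); resps <- list(); images <- list()
    k <- 0L
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      abilities <- sample_ability(cell$grade, cell$status, config, cell$n)
      for (j in seq_len(cell$n)) {
        k <- k + 1L
        id <- sprintf("P%04d", k)
        rs <- simulate_responses(abilities[j], config)
        rs$participant_id <- id
        parts[[k]] <- tibble::tibble(
          participant_id = id, grade = cell$grade, status = cell$status,
          ability = abilities[j],
          n_correct = sum(rs$response == "correct"))
        resps[[k]] <- rs
        if (render) {
          arr <- array(as.raw(0), dim = c(px, px, config$n_items))
          for (i in seq_len(config$n_items))
            arr[, , i] <- as.raw(render_response(rs$response[i],
                                                 templates[[i]], config))
          images[[id]] <- arr
        }
      }
    }
    resp_tbl <- if (length(resps) == 0)
      tibble::tibble(participant_id = character(0),
                     position_index = integer(0), word = integer(0),
                     response = character(0))
    else dplyr::bind_rows(resps)[, c("participant_id", "position_index",
                                     "word", "response")]
    part_tbl <- if (length(parts) == 0)
      tibble::tibble(participant_id = character(0), grade = integer(0),
                     status = character(0), ability = numeric(0),
                     n_correct = integer(0))
    else dplyr::bind_rows(parts)
    structure(list(participants = part_tbl,
                   responses = resp_tbl,
                   images = if (render) images else NULL,
                   config = config,
                   cache = new.env(parent = emptyenv())),
              class = "dictation_cohort")
  })
}

#' @export
print.dictation_cohort <- function(x, ...) {
  cat("dictation cohort:", nrow(x$participants), "participants,",
      x$config$n_items, "items each",
      if (!is.null(x$images)) sprintf("(%d rendered images at %d px)",
        length(x$images) * x$config$n_items, x$config$render$image_px)
      else "(responses only)", "\n")
  invisible(x)
}

#' Per-participant image array in model input layout
#'
#' @param cohort a `dictation_cohort` with rendered images.
#' @param participant_id one id.
#' @return Array `(n_items, 3, px, px)`: the binary image replicated across
#'   three channels.
#' @export
participant_images <- function(cohort, participant_id) {
  arr <- cohort$images[[participant_id]]
  if (is.null(arr)) stop("no rendered images for ", participant_id)
  internal_to_input(internal_images(arr))
}

# raw (px, px, T) -> double (px, px, 3, T), the internal model layout
internal_images <- function(raw_arr) {
  d <- dim(raw_arr)
  x <- array(0, dim = c(d[1], d[2], 3L, d[3]))
  plane <- array(as.double(as.integer(raw_arr)), dim = d)
  for (c in 1:3) x[, , c, ] <- plane
  x
}

internal_to_input <- function(x_int) aperm(x_int, c(4, 3, 1, 2))

#' Write a cohort to disk as PNG files plus a manifest
#'
#' One PNG per character named `{participant}_{index}.png` and a
#' `manifest.csv` with columns `participant_id`, `grade`, `status`,
#' `position_index`, `response_code`, `blank_flag`, `path`.
#'
#' @param cohort a rendered `dictation_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in names(cohort$images)) {
    arr <- cohort$images[[id]]
    part <- cohort$participants[cohort$participants$participant_id == id, ]
    resp <- cohort$responses[cohort$responses$participant_id == id, ]
    for (i in seq_len(dim(arr)[3])) {
      img <- as.integer(arr[, , i])
      path <- file.path(dir, sprintf("%s_%02d.png", id, i - 1L))
      png::writePNG(matrix(as.double(img), dim(arr)[1], dim(arr)[2]), path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = id, grade = part$grade, status = part$status,
        position_index = i - 1L, response_code = resp$response[i],
        blank_flag = mean(img) < 0.005, path = path)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' Accepts manifests written by [write_cohort()] or by the page
#' preprocessing pipeline.
#'
#' @param manifest_path path to a `manifest.csv`.
#' @return A `dictation_cohort` (without abilities).
#' @export
load_cohort <- function(manifest_path) {
  man <- tibble::as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  ids <- unique(man$participant_id)
  first <- png::readPNG(man$path[1])
  px <- nrow(first)
  n_items <- max(man$position_index) + 1L
  images <- list()
  parts <- list(); resps <- list()
  for (id in ids) {
    sub <- man[man$participant_id == id, ]
    sub <- sub[order(sub$position_index), ]
    arr <- array(as.raw(0), dim = c(px, px, n_items))
    for (i in seq_len(nrow(sub)))
      arr[, , sub$position_index[i] + 1L] <-
        as.raw(round(png::readPNG(sub$path[i])))
    images[[id]] <- arr
    parts[[id]] <- tibble::tibble(
      participant_id = id, grade = sub$grade[1], status = sub$status[1],
      ability = NA_real_,
      n_correct = if ("response_code" %in% names(sub))
        sum(sub$response_code == "correct") else NA_integer_)
    resps[[id]] <- tibble::tibble(
      participant_id = id, position_index = sub$position_index,
      word = sub$position_index %/% 2L + 1L,
      response = if ("response_code" %in% names(sub)) sub$response_code
                 else NA_character_)
  }
  cfg <- cohort_config(render = list(image_px = px, stroke_range = c(4L, 9L),
                                     jitter = 0.012, stroke_width = 3,
                                     scribble_prob = 0, mark_prob = 0),
                       n_items = n_items)
  structure(list(participants = dplyr::bind_rows(parts),
                 responses = dplyr::bind_rows(resps),
                 images = images, config = cfg,
                 cache = new.env(parent = emptyenv())),
            class = "dictation_cohort")
}
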