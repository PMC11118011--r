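# Participant-level dataset assembly: the stratified train/validation/test
# partition and conversion to model input tensors.

# Largest-remainder allocation of n units to ratios, surplus preference
# test > val > train.
allocate_stratum <- function(n, ratios) {
  pref <- c(train = 3L, val = 2L, test = 1L)   # lower = earlier for surplus
  quota <- n * ratios / sum(ratios)
  base <- floor(quota)
  rem <- n - sum(base)
  ord <- order(-(quota - base), pref[names(ratios)])
  out <- base
  if (rem > 0) out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  as.integer(out)
}

#' Stratified train/validation/test split
#'
#' Within each grade-by-status stratum, participants are allocated to the
#' three partitions by largest remainder against the ratio quotas (surplus
#' units preferring test, then val, then train) and shuffled by the seed.
#' Deterministic given the seed; different seeds change within-stratum
#' membership but not the counts.
#'
#' @param participants tibble with `participant_id`, `grade`, `status`
#'   (e.g. `cohort$participants`), or a `dictation_cohort`.
#' @param ratios length-3 numeric, train/val/test proportions.
#' @param seed shuffling seed.
#' @return A tibble (`participant_id`, `grade`, `status`, `partition`) with
#'   attributes `seed` and `ratios`.
#' @export
stratified_split <- function(participants, ratios = c(8, 1, 1), seed = 42L) {
  if (inherits(participants, "dictation_cohort"))
    participants <- participants$participants
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be three non-negative numbers with a positive sum")
  names(ratios) <- c("train", "val", "test")
  strata <- dplyr::group_split(dplyr::group_by(participants,
                                               .data$grade, .data$status))
  out <- with_local_seed(derive_seed(seed, "split"), {
    purrr::map(strata, function(s) {
      if (nrow(s) == 0) return(NULL)
      counts <- allocate_stratum(nrow(s), ratios)
      ids <- sample(s$participant_id)
      tibble::tibble(participant_id = ids,
                     grade = s$grade[1], status = s$status[1],
                     partition = rep(c("train", "val", "test"), counts))
    })
  })
  res <- dplyr::bind_rows(out)
  res <- res[match(participants$participant_id, res$participant_id), ]
  attr(res, "seed") <- seed
  attr(res, "ratios") <- ratios
  res
}

#' Convert one participant record to model input
#'
#' @param cohort a rendered `dictation_cohort`.
#' @param participant_id one id.
#' @return A list: `images` array `(n_items, 3, px, px)` (the binary image
#'   replicated across 3 channels), `grade` (integer), and `label`
#'   (1 = DD, 0 = TD).
#' @export
to_model_input <- function(cohort, participant_id) {
  part <- cohort$participants[cohort$participants$participant_id ==
                                participant_id, ]
  if (nrow(part) != 1) stop("unknown participant ", participant_id)
  arr <- cohort$images[[participant_id]]
  if (is.null(arr)) stop("no rendered images for ", participant_id)
  d <- dim(arr)
  if (length(d) != 3 || d[3] != cohort$config$n_items || d[1] != d[2])
    stop("malformed image array for ", participant_id)
  list(images = internal_to_input(internal_images(arr)),
       grade = as.integer(part$grade),
       label = as.integer(part$status == "DD"))
}

#' Write / read a split assignment
#'
#' @param split a split tibble from [stratified_split()].
#' @param path CSV path.
#' @export
write_split <- function(split, path) {
  write.csv(split[, c("participant_id", "partition")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
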