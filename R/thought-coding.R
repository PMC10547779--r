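#' Validate a thought-probe table
#'
#' Schema checks for one participant's probe responses: categories in 1-6,
#' contemplation and consistency in 1-3 and present exactly when the category
#' is 1-5 (when category 6, absent-mindedness, is reported the follow-up
#' probes are not shown, so both must be absent), and exactly
#' `n_trials_per_block` rows for each of the two blocks.
#'
#' @param probes A data frame with columns `trial`, `block` (`"non_vib"` /
#'   `"vib"`), `category`, `contemplation`, `consistency`.
#' @param n_trials_per_block Expected rows per block (design default 20).
#' @return The validated table, invisibly unchanged.
#' @export
validate_probe_table <- function(probes, n_trials_per_block = 20) {
  req <- c("trial", "block", "category", "contemplation", "consistency")
  missing_cols <- setdiff(req, names(probes))
  if (length(missing_cols) > 0) {
    stop("probe table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(probes$block %in% c("non_vib", "vib"))) {
    stop("block must be 'non_vib' or 'vib'", call. = FALSE)
  }
  tab <- table(factor(probes$block, levels = c("non_vib", "vib")))
  if (any(tab != n_trials_per_block)) {
    stop("each block must have exactly ", n_trials_per_block, " probe rows; ",
         "got ", paste(tab, collapse = "/"), call. = FALSE)
  }
  if (any(!probes$category %in% 1:6)) {
    stop("category codes must be in 1..6", call. = FALSE)
  }
  is6 <- probes$category == 6
  if (any(!is.na(probes$contemplation[is6])) ||
      any(!is.na(probes$consistency[is6]))) {
    stop("category-6 rows must have absent contemplation/consistency",
         call. = FALSE)
  }
  ok_level <- function(x) !is.na(x) & x %in% 1:3
  if (any(!ok_level(probes$contemplation[!is6])) ||
      any(!ok_level(probes$consistency[!is6]))) {
    stop("categories 1-5 require contemplation and consistency in 1..3",
         call. = FALSE)
  }
  invisible(probes)
}

#' Count continuations of thought categories within a block
#'
#' A continuation is an adjacent pair of trials reporting the same category.
#' Counted for the core categories 1, 2, 4 and 5 only; any pair involving
#' category 3 (peripheral stimuli, too rarely reported) or 6
#' (absent-mindedness, no verbal content) is dropped, and an excluded
#' category never bridges a pair (1, 6, 1 yields no continuation of 1).
#'
#' @param categories Integer vector of one block's category sequence in trial
#'   order.
#' @return Named integer vector with elements `"1"`, `"2"`, `"4"`, `"5"`.
#' @export
count_continuations <- function(categories) {
  a <- categories[-length(categories)]
  b <- categories[-1]
  keep <- !(a %in% c(3, 6)) & !(b %in% c(3, 6))
  out <- vapply(c(1, 2, 4, 5),
                function(c) sum(keep & a == c & b == c), numeric(1))
  stats::setNames(as.integer(out), c("1", "2", "4", "5"))
}

#' Count transitions between task focus and mind-wandering
#'
#' Transitions are adjacent pairs reporting different categories, anchored on
#' category 1 (task-focused). Grouped counts pool categories 2, 4, 5 into one
#' mind-wandering state (pairs 1 to MW and MW to 1); per-category counts
#' split the same pairs by the non-1 category. Pairs touching categories 3 or
#' 6 are dropped.
#'
#' @inheritParams count_continuations
#' @return A list with `grouped` (named integer vector `to_mw`, `from_mw`)
#'   and `percat` (named integer vector `1->2`, `1->4`, `1->5`, `2->1`,
#'   `4->1`, `5->1`).
#' @export
count_transitions <- function(categories) {
  a <- categories[-length(categories)]
  b <- categories[-1]
  keep <- !(a %in% c(3, 6)) & !(b %in% c(3, 6))
  mw <- c(2, 4, 5)
  percat <- c(
    vapply(mw, function(c) sum(keep & a == 1 & b == c), numeric(1)),
    vapply(mw, function(c) sum(keep & a == c & b == 1), numeric(1))
  )
  names(percat) <- c(paste0("1->", mw), paste0(mw, "->1"))
  grouped <- c(to_mw = sum(percat[1:3]), from_mw = sum(percat[4:6]))
  list(grouped = as.integer(grouped) |> stats::setNames(names(grouped)),
       percat = as.integer(percat) |> stats::setNames(names(percat)))
}

#' Count highly contemplated and highly consistent Category-5 reports
#'
#' Over one block's rows with category 5 (self-referential, task-unrelated
#' thought): high contemplation is a response of 2 or 3 to the contemplation
#' probe; high consistency is a response of 1 to the consistency probe.
#'
#' @param block_rows Data frame of one block's probe rows (`category`,
#'   `contemplation`, `consistency`).
#' @return Named integer vector `highly_contemplated_5`,
#'   `highly_consistent_5`.
#' @export
count_high_flags <- function(block_rows) {
  r5 <- block_rows[block_rows$category == 5, ]
  c(highly_contemplated_5 = sum(r5$contemplation %in% c(2, 3)),
    highly_consistent_5 = sum(r5$consistency == 1))
}

#' Per-block thought-state counts for one participant
#'
#' Applies [count_continuations()], [count_transitions()] and
#' [count_high_flags()] within each block (the pair spanning the
#' between-block break is never counted).
#'
#' @param probes A validated probe table for one participant.
#' @param participant_id Identifier copied into the output.
#' @param n_trials_per_block Passed to [validate_probe_table()].
#' @return A tibble with one row per block: continuation counts
#'   `continuation_1/2/4/5`, grouped and per-category transition counts,
#'   `highly_contemplated_5`, `highly_consistent_5`.
#' @export
thought_counts <- function(probes, participant_id = NA_character_,
                           n_trials_per_block = 20) {
  validate_probe_table(probes, n_trials_per_block)
  rows <- lapply(c("non_vib", "vib"), function(b) {
    blk <- probes[probes$block == b, ]
    blk <- blk[order(blk$trial), ]
    cont <- count_continuations(blk$category)
    tr <- count_transitions(blk$category)
    high <- count_high_flags(blk)
    tibble::tibble(
      participant_id = participant_id, block = b,
      vibration = as.integer(b == "vib"),
      continuation_1 = cont[["1"]], continuation_2 = cont[["2"]],
      continuation_4 = cont[["4"]], continuation_5 = cont[["5"]],
      transition_to_mw = tr$grouped[["to_mw"]],
      transition_from_mw = tr$grouped[["from_mw"]],
      transition_1_2 = tr$percat[["1->2"]],
      transition_1_4 = tr$percat[["1->4"]],
      transition_1_5 = tr$percat[["1->5"]],
      transition_2_1 = tr$percat[["2->1"]],
      transition_4_1 = tr$percat[["4->1"]],
      transition_5_1 = tr$percat[["5->1"]],
      highly_contemplated_5 = high[["highly_contemplated_5"]],
      highly_consistent_5 = high[["highly_consistent_5"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply participant-level exclusion rules
#'
#' A participant is excluded when any rule fires: they noticed the vibration
#' stimuli; they answered correctly on no more than half of the trials
#' ("more than half" read strictly, so exactly 50% correct is excluded);
#' they never reported any of the core categories 1, 2, 4, 5 across the
#' whole task; or their pulse data could not be measured.
#'
#' @param participants Cohort tibble with logical columns
#'   `noticed_vibration` and `bad_pulse_data` (others optional).
#' @param probes Probe tables for all participants, with `participant_id`.
#' @param responses Response logs for all participants, with
#'   `participant_id` and logical `correct`.
#' @return A tibble `participant_id`, `excluded`, `reasons` (comma-joined,
#'   empty when retained).
#' @export
apply_exclusions <- function(participants, probes, responses) {
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant_id[i]
    pr <- probes[probes$participant_id == pid, ]
    rs <- responses[responses$participant_id == pid, ]
    reasons <- character(0)
    if (isTRUE(participants$noticed_vibration[i])) {
      reasons <- c(reasons, "noticed_vibration")
    }
    if (nrow(rs) > 0 && mean(rs$correct) <= 0.5) {
      reasons <- c(reasons, "low_correct_response")
    }
    if (nrow(pr) > 0 && !any(pr$category %in% c(1, 2, 4, 5))) {
      reasons <- c(reasons, "no_core_categories")
    }
    if (isTRUE(participants$bad_pulse_data[i])) {
      reasons <- c(reasons, "bad_pulse_data")
    }
    tibble::tibble(participant_id = pid, excluded = length(reasons) > 0,
                   reasons = paste(reasons, collapse = ","))
  })
  dplyr::bind_rows(rows)
}
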