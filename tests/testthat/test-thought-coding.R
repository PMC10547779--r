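make_probes <- function(categories_nonvib, categories_vib) {
  mk <- function(cats, block, offset) {
    tibble::tibble(
      trial = seq_along(cats) + offset, block = block, category = cats,
      contemplation = ifelse(cats == 6, NA_integer_, 2L),
      consistency = ifelse(cats == 6, NA_integer_, 1L))
  }
  dplyr::bind_rows(mk(categories_nonvib, "non_vib", 0),
                   mk(categories_vib, "vib", length(categories_nonvib)))
}

test_that("probe-table validation enforces the category-6 and row-count rules", {
  good <- make_probes(rep(c(1L, 5L), 10), rep(c(2L, 6L), 10))
  expect_no_error(validate_probe_table(good))

  bad6 <- good
  bad6$contemplation[bad6$category == 6][1] <- 2L
  expect_error(validate_probe_table(bad6), "category-6")

  expect_error(validate_probe_table(good[-1, ]), "exactly 20")
  bad_code <- good
  bad_code$category[1] <- 7L
  expect_error(validate_probe_table(bad_code), "1..6")
  bad_na <- good
  bad_na$contemplation[1] <- NA_integer_
  expect_error(validate_probe_table(bad_na), "require contemplation")
})

test_that("continuation counting follows the non-bridging rule", {
  expect_equal(count_continuations(rep(5L, 20))[["5"]], 19L)
  expect_equal(count_continuations(c(5, 5, 5, 1, 5))[["5"]], 2L)
  expect_equal(count_continuations(c(1, 6, 1))[["1"]], 0L)
  expect_equal(count_continuations(c(1, 3, 1))[["1"]], 0L)
  expect_equal(unname(count_continuations(c(1, 1, 2, 2, 4, 4, 5, 5))),
               rep(1L, 4))
  # total continuations can never exceed 19 pairs per 20-trial block
  set.seed(3)
  for (rep in 1:50) {
    cats <- sample(1:6, 20, replace = TRUE)
    expect_lte(sum(count_continuations(cats)), 19)
  }
})

test_that("transition counting is anchored on the task-focused category", {
  tr <- count_transitions(c(1, 5, 1, 2))
  expect_equal(tr$grouped[["to_mw"]], 2L)
  expect_equal(tr$grouped[["from_mw"]], 1L)
  expect_equal(tr$percat[["1->5"]], 1L)
  expect_equal(tr$percat[["1->2"]], 1L)
  expect_equal(tr$percat[["5->1"]], 1L)
  expect_equal(tr$percat[["1->4"]], 0L)

  expect_true(all(count_transitions(rep(4L, 20))$percat == 0))
  expect_true(all(count_transitions(c(2, 4, 2, 4))$grouped == 0))

  # reversal symmetry: 1->MW of a sequence equals MW->1 of its reversal
  set.seed(8)
  for (rep in 1:50) {
    cats <- sample(1:6, 20, replace = TRUE)
    expect_equal(count_transitions(cats)$grouped[["to_mw"]],
                 count_transitions(rev(cats))$grouped[["from_mw"]])
  }
})

test_that("high contemplation/consistency flags count Category-5 rows only", {
  rows <- tibble::tibble(category = c(5, 5, 2),
                         contemplation = c(3, 1, 3),
                         consistency = c(1, 1, 1))
  flags <- count_high_flags(rows)
  expect_equal(flags[["highly_contemplated_5"]], 1)
  expect_equal(flags[["highly_consistent_5"]], 2)
  expect_equal(unname(count_high_flags(rows[rows$category == 1, ])), c(0, 0))
  all5 <- tibble::tibble(category = rep(5, 20), contemplation = rep(2, 20),
                         consistency = rep(1, 20))
  expect_equal(unname(count_high_flags(all5)), c(20, 20))
})

test_that("thought counts never count the pair spanning the block break", {
  probes <- make_probes(rep(5L, 20), rep(5L, 20))
  tc <- thought_counts(probes)
  expect_equal(tc$continuation_5, c(19L, 19L)) # not 20 on the vib block
})

test_that("exclusion rules reproduce the designed cohort attrition", {
  cfg <- cohort_config(n_participants = 100, seed = 6)
  co <- generate_cohort(cfg)
  probes <- list(); responses <- list()
  for (i in seq_len(100)) {
    p <- co[i, ]
    sched <- generate_event_schedule(cfg, seed = p$stream_seed)
    probes[[i]] <- dplyr::bind_cols(participant_id = p$participant_id,
                                    generate_probe_table(p, sched, cfg))
    responses[[i]] <- dplyr::bind_cols(
      participant_id = p$participant_id,
      generate_response_log(p, sched, cfg)[, c("trial", "correct")])
  }
  ex <- apply_exclusions(co, dplyr::bind_rows(probes),
                         dplyr::bind_rows(responses))
  expect_equal(sum(!ex$excluded), 80)
  expect_equal(sum(ex$excluded), 20)
  reasons <- unlist(strsplit(ex$reasons[ex$excluded], ","))
  expect_equal(sum(reasons == "noticed_vibration"), 9)
  expect_equal(sum(reasons == "low_correct_response"), 3)
  expect_equal(sum(reasons == "no_core_categories"), 6)
  expect_equal(sum(reasons == "bad_pulse_data"), 2)
})

test_that("exactly half-correct responding is excluded (strict majority rule)", {
  co <- tibble::tibble(participant_id = "P1", noticed_vibration = FALSE,
                       bad_pulse_data = FALSE)
  probes <- tibble::tibble(participant_id = "P1", category = c(1L, 5L))
  resp <- tibble::tibble(participant_id = "P1",
                         correct = rep(c(TRUE, FALSE), 20))
  ex <- apply_exclusions(co, probes, resp)
  expect_true(ex$excluded)
  expect_match(ex$reasons, "low_correct_response")

  resp$correct[2] <- TRUE # 21/40 correct: retained
  expect_false(apply_exclusions(co, probes, resp)$excluded)
})
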