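# Response-log reading and path replay.

test_that("a simulated cohort log round-trips through the file dialect", {
  case <- make_demo_case(3, 8)
  sim <- simulate_cohort(case, 54, seed = 11)
  for (ext in c(".csv", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_cohort(sim, f, case)
    recs <- read_responses(f, case)
    expect_length(recs, 54)
    expect_identical(lapply(recs, `[[`, "answers"),
                     lapply(sim$records, `[[`, "answers"))
    expect_identical(vapply(recs, `[[`, "", "user_id"),
                     vapply(sim$records, `[[`, "", "user_id"))
    # and replay recovers every ground-truth path exactly
    paths <- replay_cohort(case, recs)
    expect_identical(lapply(paths, `[[`, "nodes"),
                     lapply(sim$paths, `[[`, "nodes"))
    expect_true(all(vapply(paths, `[[`, TRUE, "complete")))
  }
})

test_that("header-only logs, sparse rows, and missing columns behave as specified", {
  case <- make_demo_case(2, 4)
  qkeys <- case$nodes$question_key[!is.na(case$nodes$question_key)]
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(paste(c("user_id", "group", "role", qkeys), collapse = ","), f)
  expect_length(read_responses(f, case), 0)

  # one row answering only the first question
  first_opt <- case$edges$option[case$edges$from == case$start][1]
  row <- c("u1", "", "", ifelse(qkeys == "q_T1", first_opt, ""))
  writeLines(c(paste(c("user_id", "group", "role", qkeys), collapse = ","),
               paste(shQuote(row, "cmd"), collapse = ",")), f)
  recs <- read_responses(f, case)
  expect_length(recs, 1)
  expect_identical(names(recs[[1]]$answers), "q_T1")

  # missing user-id column
  writeLines(paste(qkeys, collapse = ","), f)
  expect_error(read_responses(f, case), "user-id column")

  # question key with no matching column
  writeLines(paste(c("user_id", qkeys[-1]), collapse = ","), f)
  expect_error(read_responses(f, case), qkeys[1], fixed = TRUE)
})

test_that("duplicate user ids are kept separately with a suffix", {
  case <- make_demo_case(1, 3)
  sim <- simulate_cohort(case, 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(list(sim$records[[1]], sim$records[[1]]), f, case)
  expect_warning(recs <- read_responses(f, case), "duplicate")
  expect_identical(vapply(recs, `[[`, "", "user_id"),
                   c("U0001", "U0001#2"))
})

test_that("expert answers replay onto the expert route with no anomalies", {
  case <- make_demo_case(4, 8)
  rec <- expert_record(case, "exp1")
  p <- replay_path(case, rec)
  expect_identical(p$nodes, case$expert_route)
  expect_true(p$complete)
  expect_identical(nrow(p$anomalies), 0L)
})

test_that("an incorrect first-menu answer terminates at that option's endpoint", {
  case <- make_demo_case(5, 8)
  rec <- strategy_record(case, "inc1", pick_class_at(case$start, "incorrect"))
  p <- replay_path(case, rec)
  inc_edge <- case$edges[case$edges$from == case$start &
                           case$edges$class == "incorrect", ][1, ]
  expect_identical(p$terminal, inc_edge$to)
  expect_identical(p$nodes, c(case$start, inc_edge$to))
  expect_true(p$complete)
})

test_that("replay anomalies: orphan, missing and multiple answers", {
  case <- make_demo_case(3, 8)
  rec <- expert_record(case, "u1")

  # an answer for a question the route never visits (back-button artifact)
  off_key <- "q_M1"
  orec <- rec
  orec$answers[[off_key]] <- case$edges$option[case$edges$from == "M1"][1]
  p <- replay_path(case, orec)
  expect_identical(p$nodes, case$expert_route)
  expect_identical(p$anomalies$code, "ORPHAN_ANSWER")
  expect_identical(p$anomalies$question_key, off_key)

  # no answer at the second checkpoint: incomplete, frozen at that node
  mrec <- rec
  mrec$answers[["q_H1"]] <- NULL
  p <- replay_path(case, mrec)
  expect_false(p$complete)
  expect_identical(p$terminal, "H1")
  expect_true("MISSING_ANSWER" %in% p$anomalies$code)

  # two recorded values for one visited question: the last wins
  drec <- rec
  tol_opt <- case$edges$option[case$edges$from == "H1" &
                                 case$edges$class == "tolerable"][1]
  drec$answers[["q_H1"]] <- c(tol_opt, drec$answers[["q_H1"]])
  p <- replay_path(case, drec)
  expect_identical(p$nodes, case$expert_route)
  expect_true("MULTI_ANSWER" %in% p$anomalies$code)

  # an answer matching no option is a hard error naming the node
  brec <- rec
  brec$answers[["q_T1"]] <- "not on the menu"
  expect_error(replay_path(case, brec), "UNMATCHED_OPTION")
})

test_that("whitespace in recorded answers is normalized before matching", {
  case <- make_demo_case(1, 3)
  rec <- expert_record(case, "u1")
  rec$answers[["q_T1"]] <- paste0("  ", gsub(" ", "   ", rec$answers[["q_T1"]]), " ")
  p <- replay_path(case, rec)
  expect_identical(p$nodes, case$expert_route)
})

test_that("replayed paths match the exhaustive-enumeration oracle", {
  case <- make_demo_case(2, 5)
  expect_lte(length(enumerate_paths(case)), 200)
  sim <- simulate_cohort(case, 40, seed = 21,
                         profile = behavior_profile(0.5, 0.3, 0.2))
  for (i in seq_along(sim$records)) {
    consistent <- oracle_consistent_paths(case, sim$records[[i]])
    expect_length(consistent, 1)
    p <- replay_path(case, sim$records[[i]])
    expect_identical(p$edges, case$edges[consistent[[1]], , drop = FALSE])
    # and every consecutive pair is a declared edge
    for (j in seq_len(nrow(p$edges)))
      expect_true(any(case$edges$from == p$edges$from[j] &
                        case$edges$to == p$edges$to[j] &
                        case$edges$option == p$edges$option[j]))
  }
})

test_that("xlsx convenience reader matches the csv reader", {
  skip_if_not_installed("readxl")
  # readxl reads but does not write; go through a minimal xml writer is out
  # of scope, so exercise the dispatch path only via extension errors
  expect_error(read_responses("nope.xlsx", make_demo_case(1, 3)), "not found")
})
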