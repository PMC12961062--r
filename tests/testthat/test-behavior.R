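# Cumulative checkpoint classification and cohort tables.

test_that("a fully expert path is expert at every checkpoint", {
  case <- make_demo_case(5, 8)
  p <- replay_path(case, expert_record(case, "e1"))
  st <- classify_user(case, p)
  expect_identical(unique(st$status), "expert")
  expect_identical(st$checkpoint_index, 0:10)
  expect_identical(st$node_id, case$expert_route)
})

test_that("a tolerable deviation at the first menu never becomes incorrect", {
  case <- make_demo_case(5, 8)
  # deviate at T1 to the detour, then expert ever after (rejoins at T2)
  rec <- strategy_record(case, "t1", pick_class_at("T1", "tolerable"))
  p <- replay_path(case, rec)
  expect_identical(p$terminal, case$finish)
  st <- classify_user(case, p)$status
  expect_identical(st[1], "expert")                 # k = 0: no decision yet
  expect_identical(unique(st[-1]), "tolerable_only")
  expect_identical(st, oracle_classify(case, p))
})

test_that("an incorrect choice is absorbing and freezes at the terminal", {
  case <- make_demo_case(5, 8)
  rec <- strategy_record(case, "i1", pick_class_at("T3", "incorrect"))
  p <- replay_path(case, rec)
  st <- classify_user(case, p)$status
  # expert through T1,H1,T2,H2 (4 decisions), incorrect from T3's row on
  expect_identical(st, c(rep("expert", 5), rep("incorrect", 6)))
  expect_identical(st, oracle_classify(case, p))
})

test_that("classification agrees with the brute-force rescan across mixtures", {
  case <- make_demo_case(3, 6)
  for (mix in list(c(1, 0, 0), c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))) {
    sim <- simulate_cohort(case, 30, seed = 5 + round(100 * mix[1]),
                           profile = behavior_profile(mix[1], mix[2], mix[3]))
    for (p in sim$paths)
      expect_identical(classify_user(case, p)$status, oracle_classify(case, p))
  }
})

test_that("classifying a path from another case is refused", {
  a <- make_demo_case(2, 4)
  b <- make_demo_case(3, 4)
  p <- replay_path(a, expert_record(a, "u"))
  expect_error(classify_user(b, p), "replayed from case")
})

test_that("an all-expert cohort tabulates as (N, 100.0, N, 100.0, 0, 0.0)", {
  case <- make_demo_case(4, 8)
  paths <- replay_cohort(case, lapply(1:7, function(i)
    expert_record(case, paste0("u", i))))
  tbl <- behavior_table(case, paths)
  expect_true(all(tbl$n_tolerable == 7 & tbl$pct_tolerable == 100 &
                    tbl$n_expert == 7 & tbl$pct_expert == 100 &
                    tbl$n_incorrect == 0 & tbl$pct_incorrect == 0))
})

test_that("a single user crossing an incorrect edge flips the whole tail", {
  case <- make_demo_case(3, 8)
  p <- replay_path(case, strategy_record(case, "u",
                                         pick_class_at("T1", "incorrect")))
  tbl <- behavior_table(case, list(p))
  expect_identical(tbl$n_incorrect, c(0L, rep(1L, 6)))
  expect_identical(tbl$pct_incorrect, c(0, rep(100, 6)))
  expect_identical(tbl$n_tolerable + tbl$n_incorrect, rep(1L, 7))
})

test_that("empty cohorts produce an N = 0 table with a warning", {
  case <- make_demo_case(1, 3)
  expect_warning(tbl <- behavior_table(case, list()), "empty cohort")
  expect_identical(attr(tbl, "cohort_size"), 0L)
  expect_true(all(tbl$pct_tolerable == 0 & tbl$pct_expert == 0))
})

test_that("incomplete paths freeze at their last classified status", {
  case <- make_demo_case(3, 8)
  rec <- expert_record(case, "u1")
  rec$answers[["q_T2"]] <- NULL            # stops expert-like at T2
  p <- replay_path(case, rec)
  expect_false(p$complete)
  st <- classify_user(case, p)$status
  # expert while checkpoints are covered by actual decisions, then frozen
  expect_identical(st, c("expert", "expert", "expert",
                         rep("tolerable_only", 4)))
})

test_that("tallies match hand-computed values on a hand-built cohort", {
  case <- make_demo_case(2, 6)
  recs <- list(
    expert_record(case, "a"),
    expert_record(case, "b"),
    strategy_record(case, "c", pick_class_at("T1", "tolerable")),
    strategy_record(case, "d", pick_class_at("T2", "incorrect")),
    strategy_record(case, "e", pick_class_at("H2", "incorrect")))
  paths <- replay_cohort(case, recs)

  ep <- endpoint_distribution(paths)
  expect_identical(ep$count[ep$node_id == case$finish], 3L)
  expect_identical(ep$count[ep$node_id == "E2"], 2L)

  nv <- nodes_visited(paths)
  expect_identical(nv$n_nodes[nv$user_id == "a"],
                   length(case$expert_route))
  expect_identical(nv$n_nodes[nv$user_id == "d"], 4L)  # T1,H1,T2,E2

  rf <- route_frequency(paths)
  expect_identical(sum(rf$count), 5L)
  expect_identical(rf$count[1], 2L)  # the two identical expert routes
  expect_identical(rf$route[1], paste(case$expert_route, collapse = " -> "))
})

test_that("group tables are additive and partition the cohort", {
  case <- make_demo_case(3, 8)
  sim <- simulate_cohort(case, 54, seed = 9,
                         profile = behavior_profile(0.7, 0.2, 0.1),
                         group_labels = c("SOC", "MTX"))
  labs <- vapply(sim$records, `[[`, "", "group")
  names(labs) <- vapply(sim$records, `[[`, "", "user_id")
  out <- compare_groups(case, sim$paths, labs)
  expect_named(out, c("MTX", "SOC"))
  expect_identical(attr(out$SOC$table, "cohort_size"), 27L)
  expect_identical(attr(out$MTX$table, "cohort_size"), 27L)

  whole <- behavior_table(case, sim$paths)
  for (col in c("n_tolerable", "n_expert", "n_incorrect"))
    expect_identical(out$SOC$table[[col]] + out$MTX$table[[col]], whole[[col]])
  expect_identical(out$SOC$usage$count + out$MTX$usage$count,
                   edge_usage(case, sim$paths)$count)

  # one label for everyone reproduces the whole-cohort table
  one <- compare_groups(case, sim$paths,
                        setNames(rep("all", 54), names(labs)))
  expect_identical(as.data.frame(one$all$table), as.data.frame(whole))

  # a user missing from the grouping is an error
  expect_error(compare_groups(case, sim$paths, labs[-1]), "no group label")
})

test_that("three-way role split covers the whole cohort", {
  case <- make_demo_case(2, 8)
  roles <- c(rep("medical student", 36), rep("pharmacy resident", 8),
             rep("nurse", 10))
  sim <- simulate_cohort(case, 54, seed = 13, role_labels = roles)
  labs <- vapply(sim$records, `[[`, "", "role")
  names(labs) <- vapply(sim$records, `[[`, "", "user_id")
  out <- compare_groups(case, sim$paths, labs)
  expect_identical(sum(vapply(out, function(g)
    attr(g$table, "cohort_size"), integer(1))), 54L)
})

test_that("percentages are rounded half-up to one decimal", {
  # 14/54 and 28/54 land on .92... and .85..., exercising the half-up rule
  expect_identical(branchmap:::pct_round(14, 54), 25.9)
  expect_identical(branchmap:::pct_round(28, 54), 51.9)
  expect_identical(branchmap:::pct_round(53, 54), 98.1)
  expect_identical(branchmap:::pct_round(1, 16), 6.3)   # 6.25 rounds up
})
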