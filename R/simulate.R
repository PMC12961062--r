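# Synthetic branched cases and stochastic respondent cohorts, so every
# pipeline stage is testable without human participant data.

#' Behavior profile for simulated respondents
#'
#' At every decision node a simulated user draws a choice class from the
#' mixture `(p_expert, p_tolerable, p_incorrect)` and then picks uniformly
#' among that node's options of the drawn class. At nodes lacking a class
#' (e.g. a menu with no incorrect option) the mixture is renormalized over
#' the classes present. Per-node overrides replace the global mixture at
#' named nodes.
#'
#' @param p_expert,p_tolerable,p_incorrect mixture over choice classes;
#'   must be in `[0, 1]` and sum to 1 (tolerance 1e-9). The defaults
#'   emulate a moderately skilled learner cohort: mostly expert choices,
#'   occasional harmless detours, rare harmful choices.
#' @param overrides optional named list: node id -> numeric vector with
#'   names `expert`, `tolerable`, `incorrect`.
#' @return an object of class `behavior_profile`.
#' @export
behavior_profile <- function(p_expert = 0.85, p_tolerable = 0.08,
                             p_incorrect = 0.07, overrides = list()) {
  check_mix <- function(m, what) {
    if (any(m < 0 | m > 1)) stop(what, ": probabilities must be in [0, 1]")
    if (abs(sum(m) - 1) > 1e-9) stop(what, ": mixture must sum to 1")
    m
  }
  mix <- check_mix(c(expert = p_expert, tolerable = p_tolerable,
                     incorrect = p_incorrect), "behavior profile")
  overrides <- lapply(overrides, function(m)
    check_mix(m[c("expert", "tolerable", "incorrect")], "node override"))
  structure(list(mixture = mix, overrides = overrides),
            class = "behavior_profile")
}

# per-user seed derived from the cohort seed by a fixed affine map, so a
# cohort is reproducible and earlier users do not reshuffle when n grows
derive_user_seed <- function(seed, i) {
  as.integer(((as.double(seed) %% 2147483629) * 1000003 + i * 10007) %%
               2147483629)
}

#' Build a demonstration branched case
#'
#' Constructs a valid case shaped like a multi-day chemotherapy-monitoring
#' scenario: an expert spine alternating treatment menus (circles) and
#' hydration prompts (diamonds) at 6-hour-grid timepoints, tolerable
#' detour menus that rejoin the spine at the next timepoint, incorrect
#' options collapsing onto per-stage adverse endpoints, and a single
#' FINISH node. With the default five treatment stages the expert route
#' has 11 checkpoints (five treatment, five hydration, FINISH), matching
#' the published scenario's checkpoint table.
#'
#' @param n_treatment_stages number of expert-spine treatment menus
#'   (>= 1; default 5).
#' @param options_per_menu options per treatment menu (>= 3 so each class
#'   is represented; default 8, the lower end of the published menus'
#'   8-14 range).
#' @return a valid `case_graph`.
#' @export
make_demo_case <- function(n_treatment_stages = 5, options_per_menu = 8) {
  S <- as.integer(n_treatment_stages)
  m <- as.integer(options_per_menu)
  if (is.na(S) || S < 1) stop("n_treatment_stages must be >= 1")
  if (is.na(m) || m < 3) stop("options_per_menu must be >= 3")

  tp <- function(i) if (i == 1L) 24 else 30 + 6 * i   # 24, 42, 48, 54, ...
  tps <- vapply(seq_len(S), tp, 0)
  t_fin <- 30 + 6 * (S + 1)

  nodes <- list()
  edges <- list()
  add_node <- function(id, label, kind, t, qk, tier)
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, label = label, kind = kind, timepoint_hours = t,
      question_key = qk, tier = tier, stringsAsFactors = FALSE)
  add_edge <- function(from, option, to, class)
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, option = option, to = to, class = class,
      stringsAsFactors = FALSE)

  n_tol <- pmax(1L, (m - 1L) %/% 2L)
  n_inc <- m - 1L - n_tol

  tx_options <- function(t_next, t_now) {
    exp <- paste0("Obtain the next methotrexate level at ", t_next, " h")
    # earlier-than-expert recheck times, skipping the expert time itself
    tol_t <- setdiff(t_now + 6 * seq_len(n_tol + 1L), t_next)[seq_len(n_tol)]
    tol <- paste0("Obtain the next methotrexate level at ", tol_t, " h")
    inc_pool <- c("Administer leucovorin 100 mg/m2 now",
                  "Discharge the patient",
                  "Discontinue level monitoring",
                  "Administer leucovorin 1000 mg/m2 now")
    inc <- c(inc_pool, paste0("Defer all evaluation (variant ",
                              seq_len(max(0L, n_inc - length(inc_pool))), ")"))
    list(exp = exp, tol = tol, inc = inc[seq_len(n_inc)])
  }

  for (i in seq_len(S)) {
    t_i <- tps[i]
    nxt <- if (i < S) paste0("T", i + 1L) else "FINISH"
    t_next <- if (i < S) tps[i + 1L] else t_fin
    Ti <- paste0("T", i); Hi <- paste0("H", i)
    Mi <- paste0("M", i); Ei <- paste0("E", i)

    add_node(Ti, paste0(t_i, "Hr"), "treatment", t_i,
             paste0("q_", Ti), "expert_row")
    add_node(Hi, paste0(t_i, "Hr fluid"), "hydration", t_i,
             paste0("q_", Hi), "expert_row")
    add_node(Mi, paste0(t_i + 6, "Hr (detour)"), "treatment", t_i + 6,
             paste0("q_", Mi), "middle")
    add_node(Ei, paste0("End", i), "endpoint", NA, NA, "endpoint_row")

    op <- tx_options(t_next, t_i)
    add_edge(Ti, op$exp, Hi, "expert")
    for (o in op$tol) add_edge(Ti, o, Mi, "tolerable")
    for (o in op$inc) add_edge(Ti, o, Ei, "incorrect")

    add_edge(Hi, "Maintain the current fluid rate", nxt, "expert")
    add_edge(Hi, "Increase intravenous fluids", nxt, "tolerable")
    add_edge(Hi, "Decrease intravenous fluids", Ei, "incorrect")

    opm <- tx_options(t_next, t_i + 6)
    add_edge(Mi, opm$exp, nxt, "expert")
    for (o in opm$tol) add_edge(Mi, o, nxt, "tolerable")
    for (o in opm$inc) add_edge(Mi, o, Ei, "incorrect")
  }
  add_node("FINISH", paste0(t_fin, "Hr"), "endpoint", t_fin, NA, "expert_row")

  case_graph(case_id = paste0("demo_mtx_s", S, "m", m),
             title = "High-dose methotrexate monitoring (demo case)",
             start = "T1",
             nodes = do.call(rbind, nodes), edges = do.call(rbind, edges))
}

#' Simulate a cohort of respondents
#'
#' Each simulated user walks the case from the start node; at every
#' decision node a choice class is drawn from the behavior profile
#' (renormalized over the classes present at that node) and an option of
#' that class is drawn uniformly. The chosen option text is recorded under
#' the node's question key, exactly as a branching form would log it. The
#' walk ends at an endpoint, so every ground-truth path is complete.
#'
#' Reproducibility: each user's draws come from a private RNG stream
#' seeded by a fixed affine map of `(seed, user index)`, so the same
#' `(case, n_users, seed, profile)` always yields byte-identical logs and
#' increasing `n_users` never reshuffles earlier users.
#'
#' @param case a valid `case_graph`.
#' @param n_users cohort size (>= 1).
#' @param seed integer cohort seed.
#' @param profile a [behavior_profile()].
#' @param group_labels,role_labels optional character vectors recycled
#'   across users in order (e.g. `c("SOC", "MTX")` alternates arms).
#' @param user_prefix prefix for generated user ids.
#' @return a `cohort_sim`: list with `records` (list of
#'   `response_record`) and `paths` (list of ground-truth `user_path`).
#' @export
simulate_cohort <- function(case, n_users, seed,
                            profile = behavior_profile(),
                            group_labels = NULL, role_labels = NULL,
                            user_prefix = "U") {
  assert_valid_case(case)
  stopifnot(inherits(profile, "behavior_profile"))
  n_users <- as.integer(n_users)
  if (is.na(n_users) || n_users < 1) stop("n_users must be >= 1")
  nodes <- case$nodes
  edges <- case$edges
  groups <- if (is.null(group_labels)) rep(NA_character_, n_users)
    else rep_len(as.character(group_labels), n_users)
  roles <- if (is.null(role_labels)) rep(NA_character_, n_users)
    else rep_len(as.character(role_labels), n_users)

  records <- vector("list", n_users)
  paths <- vector("list", n_users)
  for (i in seq_len(n_users)) {
    uid <- sprintf("%s%04d", user_prefix, i)
    set.seed(derive_user_seed(seed, i))
    cur <- case$start
    path_nodes <- cur
    taken <- integer(0)
    answers <- list()
    repeat {
      ni <- match(cur, nodes$id)
      if (nodes$kind[ni] == "endpoint") break
      out <- which(edges$from == cur)
      present <- sort(unique(edges$class[out]))
      mix <- if (!is.null(profile$overrides[[cur]]))
        profile$overrides[[cur]] else profile$mixture
      mass <- mix[present]
      if (sum(mass) <= 0)
        stop("node '", cur, "': every class present has zero mixture mass",
             call. = FALSE)
      cls <- present[sample.int(length(present), 1L, prob = mass / sum(mass))]
      cand <- out[edges$class[out] == cls]
      pick <- cand[sample.int(length(cand), 1L)]
      answers[[nodes$question_key[ni]]] <- edges$option[pick]
      taken <- c(taken, pick)
      cur <- edges$to[pick]
      path_nodes <- c(path_nodes, cur)
    }
    records[[i]] <- response_record(uid, answers, group = groups[i],
                                    role = roles[i])
    paths[[i]] <- structure(list(
      user_id = uid, nodes = path_nodes,
      edges = edges[taken, , drop = FALSE],
      terminal = path_nodes[length(path_nodes)], complete = TRUE,
      anomalies = data.frame(code = character(), question_key = character(),
                             stringsAsFactors = FALSE),
      case_id = case$case_id), class = "user_path")
  }
  structure(list(records = records, paths = paths, case_id = case$case_id,
                 seed = seed), class = "cohort_sim")
}

#' Inject back-button artifacts into simulated records
#'
#' Emulates the form's non-disableable "go back" button: with probability
#' `p` a user gains one extra recorded answer for a question their actual
#' route never visited. Replaying such a record reports one
#' `ORPHAN_ANSWER` anomaly per injection.
#'
#' @param sim a `cohort_sim`.
#' @param case the `case_graph` the cohort was simulated from.
#' @param p per-user injection probability.
#' @param seed integer seed for the injection draws.
#' @return the modified `cohort_sim`; the number of injected answers is
#'   stored in attribute `n_injected`.
#' @export
inject_backtracks <- function(sim, case, p, seed) {
  stopifnot(inherits(sim, "cohort_sim"))
  assert_valid_case(case)
  nodes <- case$nodes
  edges <- case$edges
  decision_keys <- nodes$question_key[nodes$kind != "endpoint"]
  set.seed(as.integer(seed) %% 2147483629L)
  n_injected <- 0L
  for (i in seq_along(sim$records)) {
    if (stats::runif(1) >= p) next
    rec <- sim$records[[i]]
    unused <- setdiff(decision_keys, names(rec$answers))
    if (length(unused) == 0) next
    qk <- unused[sample.int(length(unused), 1L)]
    nid <- nodes$id[match(qk, nodes$question_key)]
    opts <- edges$option[edges$from == nid]
    rec$answers[[qk]] <- opts[sample.int(length(opts), 1L)]
    sim$records[[i]] <- rec
    n_injected <- n_injected + 1L
  }
  attr(sim, "n_injected") <- n_injected
  sim
}

#' Write a cohort's response log
#'
#' Writes the wide response-log dialect read by [read_responses()]:
#' columns `user_id`, `group`, `role`, then one column per case question
#' key (repeated when any record holds several values for a key). Reading
#' the file back recovers the records exactly.
#'
#' @param records a `cohort_sim` or a list of `response_record`.
#' @param path output path (`.csv` or `.tsv`).
#' @param case the `case_graph` defining the question-key columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, case) {
  if (inherits(records, "cohort_sim")) records <- records$records
  assert_valid_case(case)
  qkeys <- case$nodes$question_key[!is.na(case$nodes$question_key)]
  width <- vapply(qkeys, function(qk)
    max(1L, vapply(records, function(r) length(r$answers[[qk]]), integer(1))),
    integer(1))
  cols <- list(
    user_id = vapply(records, function(r) r$user_id, character(1)),
    group = vapply(records, function(r)
      if (is.na(r$group)) "" else r$group, character(1)),
    role = vapply(records, function(r)
      if (is.na(r$role)) "" else r$role, character(1)))
  headers <- c("user_id", "group", "role")
  for (k in seq_along(qkeys)) {
    qk <- qkeys[k]
    for (j in seq_len(width[k])) {
      cols[[length(cols) + 1L]] <- vapply(records, function(r) {
        v <- r$answers[[qk]]
        if (length(v) >= j) v[j] else ""
      }, character(1))
      headers <- c(headers, qk)
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- headers
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt"))
    "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}
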