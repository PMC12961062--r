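# Cumulative behavior classification at expert-route checkpoints.
#
# Status semantics ("tolerable" in reported tables = expert OR
# tolerable_only): a user is expert at checkpoint k while their first k
# decisions are exactly the first k expert-route edges; crossing any
# incorrect-classified edge is absorbing. Users who stop early (incomplete
# replay or early endpoint) are frozen at their terminal classification.

# round half up to `digits` decimals (matches how the published tables
# print 53/54 -> 98.1 and 28/54 -> 51.9, where round-half-even would not)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

pct_round <- function(n, total) {
  if (total == 0) return(0)
  round_half_up(100 * n / total, 1)
}

#' Classify one user's cumulative behavior at every checkpoint
#'
#' At checkpoint index `k` (0-based along the expert route) the status is
#' computed from the user's first `min(k, D)` decisions, where `D` is their
#' total decision count: `incorrect` if any of those edges is classified
#' incorrect; `expert` if they are exactly the first `k` expert-route
#' edges; otherwise `tolerable_only`. At `k = 0` every user is expert (no
#' decision made yet). Users are frozen at their terminal classification
#' for checkpoints beyond their last decision.
#'
#' @param case a valid `case_graph`.
#' @param path a `user_path` replayed from the same case.
#' @return data frame with columns `user_id`, `checkpoint_index` (0-based),
#'   `node_id`, `status` (one of `expert`, `tolerable_only`, `incorrect`).
#' @export
classify_user <- function(case, path) {
  assert_valid_case(case)
  stopifnot(inherits(path, "user_path"))
  if (!identical(path$case_id, case$case_id))
    stop("path was replayed from case '", path$case_id,
         "', not from '", case$case_id, "'", call. = FALSE)

  route <- case$expert_route
  K <- length(route)
  D <- nrow(path$edges)
  # does decision j coincide with expert-route edge j?
  exp_steps <- min(D, K - 1L)
  on_exp <- logical(D)
  if (exp_steps > 0) {
    j <- seq_len(exp_steps)
    on_exp[j] <- path$edges$from[j] == route[j] &
      path$edges$to[j] == route[j + 1L] &
      path$edges$class[j] == "expert"
  }
  exp_prefix <- if (D > 0) cumsum(!on_exp) == 0 else logical(0)
  inc_prefix <- if (D > 0) cumsum(path$edges$class == "incorrect") > 0 else logical(0)

  status <- character(K)
  for (k in seq_len(K) - 1L) {
    m <- min(k, D)
    status[k + 1L] <- if (m > 0 && inc_prefix[m]) "incorrect"
    else if (m == k && (k == 0L || exp_prefix[k])) "expert"
    else "tolerable_only"
  }
  data.frame(user_id = path$user_id, checkpoint_index = seq_len(K) - 1L,
             node_id = route, status = status, stringsAsFactors = FALSE)
}

#' Tabulate cohort behavior at every expert-route checkpoint
#'
#' One row per checkpoint with counts and percentages of tolerable
#' (expert and/or unharmful so far), expert (only expert choices so far)
#' and incorrect (crossed a harmful choice) users. By construction
#' `n_tolerable + n_incorrect = N` on every row, `n_expert <= n_tolerable`,
#' `n_expert` is non-increasing and `n_incorrect` non-decreasing down the
#' rows. Percentages are rounded half-up to one decimal.
#'
#' @param case a valid `case_graph`.
#' @param paths list of `user_path` from the same case.
#' @return a `behavior_table`: data frame with columns `node_id`, `label`,
#'   `n_tolerable`, `pct_tolerable`, `n_expert`, `pct_expert`,
#'   `n_incorrect`, `pct_incorrect`; attribute `cohort_size`.
#' @export
behavior_table <- function(case, paths) {
  assert_valid_case(case)
  N <- length(paths)
  if (N == 0)
    warning("empty cohort: behavior table computed with N = 0", call. = FALSE)
  cps <- expert_checkpoints(case)
  K <- nrow(cps)
  n_exp <- n_inc <- integer(K)
  for (p in paths) {
    st <- classify_user(case, p)$status
    n_exp <- n_exp + as.integer(st == "expert")
    n_inc <- n_inc + as.integer(st == "incorrect")
  }
  n_tol <- N - n_inc
  out <- data.frame(
    node_id = cps$node_id, label = cps$label,
    n_tolerable = n_tol, pct_tolerable = vapply(n_tol, pct_round, 0, total = N),
    n_expert = n_exp, pct_expert = vapply(n_exp, pct_round, 0, total = N),
    n_incorrect = n_inc, pct_incorrect = vapply(n_inc, pct_round, 0, total = N),
    stringsAsFactors = FALSE)
  structure(out, cohort_size = N, class = c("behavior_table", "data.frame"))
}

#' @export
print.behavior_table <- function(x, ...) {
  cat("Cohort behavior at", nrow(x), "checkpoints (N =",
      attr(x, "cohort_size"), "users)\n")
  y <- as.data.frame(x)
  for (cc in grep("^pct_", names(y))) y[[cc]] <- sprintf("%.1f", y[[cc]])
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a behavior table as CSV or TSV
#'
#' Fixed column order; percentages printed with exactly one decimal.
#'
#' @param x a `behavior_table`.
#' @param path output path; `.tsv`/`.tab`/`.txt` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(x, path) {
  stopifnot(inherits(x, "behavior_table"))
  y <- as.data.frame(x)
  for (cc in grep("^pct_", names(y))) y[[cc]] <- sprintf("%.1f", y[[cc]])
  write_delim_ext(y, path)
}

write_delim_ext <- function(df, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt"))
    "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Cohort tallies: endpoints, nodes visited, route frequencies
#'
#' Straightforward descriptive tallies over the replayed cohort.
#' `endpoint_distribution` and `route_frequency` consider complete paths
#' only; `nodes_visited` covers every path.
#'
#' @param paths list of `user_path`.
#' @return `endpoint_distribution`: data frame `node_id`, `count` (sorted
#'   by count descending, then id); `nodes_visited`: data frame `user_id`,
#'   `n_nodes`; `route_frequency`: data frame `route` (node ids joined by
#'   `" -> "`), `count`, sorted by count descending then lexicographically.
#' @export
endpoint_distribution <- function(paths) {
  term <- vapply(Filter(function(p) p$complete, paths),
                 function(p) p$terminal, character(1))
  if (length(term) == 0)
    return(data.frame(node_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(term)
  out <- data.frame(node_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$node_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname endpoint_distribution
#' @export
nodes_visited <- function(paths) {
  data.frame(user_id = vapply(paths, function(p) p$user_id, character(1)),
             n_nodes = vapply(paths, function(p) length(p$nodes), integer(1)),
             stringsAsFactors = FALSE)
}

#' @rdname endpoint_distribution
#' @export
route_frequency <- function(paths) {
  complete <- Filter(function(p) p$complete, paths)
  if (length(complete) == 0)
    return(data.frame(route = character(), count = integer(),
                      stringsAsFactors = FALSE))
  routes <- vapply(complete, function(p) paste(p$nodes, collapse = " -> "),
                   character(1))
  tab <- table(routes)
  out <- data.frame(route = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$route, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare behavior between groups of users
#'
#' Splits the cohort by a user label (study arm, professional role, ...)
#' and computes a behavior table and per-edge usage for each group. Group
#' counts are additive: summing per-group counts over a partition of the
#' cohort reproduces the whole-cohort table.
#'
#' @param case a valid `case_graph`.
#' @param paths list of `user_path`.
#' @param grouping named character vector (or factor) mapping `user_id` to
#'   a group label; every user in `paths` must be present. Factor levels
#'   with no users yield empty tables with a warning.
#' @return named list, one entry per label: `list(table = behavior_table,
#'   usage = edge_usage)`.
#' @export
compare_groups <- function(case, paths, grouping) {
  assert_valid_case(case)
  labs <- as.character(grouping)
  names(labs) <- names(grouping)
  uids <- vapply(paths, function(p) p$user_id, character(1))
  missing <- setdiff(uids, names(labs))
  if (length(missing))
    stop("no group label for user(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  levels <- if (is.factor(grouping)) levels(grouping) else
    sort(unique(labs[names(labs) %in% uids]), method = "radix")
  out <- list()
  for (lab in levels) {
    sub <- paths[labs[uids] == lab]
    if (length(sub) == 0)
      warning("group '", lab, "' has no users", call. = FALSE)
    out[[lab]] <- list(table = suppressWarnings(behavior_table(case, sub)),
                       usage = edge_usage(case, sub))
  }
  out
}
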