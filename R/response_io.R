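#' Read a branching-form response log
#'
#' Reads the wide spreadsheet dialect exported by branching survey forms:
#' one row per submission, one column per form question, most cells blank
#' because each respondent only sees the questions on their own branch.
#' Columns are matched to the case's `question_key` values by exact header;
#' duplicate headers (the same question answered more than once, e.g. via
#' the form's back button) are kept as multiple values in column order.
#'
#' @param path CSV (`.csv`), TSV (`.tsv`/`.tab`/`.txt`) or, when the
#'   `readxl` package is available, XLSX response log with a header row.
#' @param case the `case_graph` whose question keys identify the columns.
#' @param id_col name of the respondent-identifier column.
#' @param group_col,role_col optional names of group/role label columns;
#'   silently skipped when absent from the file.
#' @return list of `response_record` objects, each with fields `user_id`,
#'   `group`, `role` and `answers` (named list: question_key -> character
#'   vector of recorded values in submission order). Duplicate user ids get
#'   a `#2`, `#3`, ... suffix with a warning.
#' @export
read_responses <- function(path, case, id_col = "user_id",
                           group_col = "group", role_col = "role") {
  stopifnot(inherits(case, "case_graph"))
  tab <- read_wide_table(path)
  hdr <- names(tab)
  if (!id_col %in% hdr)
    stop("response log '", path, "' has no user-id column '", id_col, "'",
         call. = FALSE)
  qkeys <- case$nodes$question_key[!is.na(case$nodes$question_key)]
  missing <- setdiff(qkeys, hdr)
  if (length(missing))
    stop("response log '", path, "' has no column for question key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  ids <- as.character(tab[[which(hdr == id_col)[1L]]])
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0)
    warning(n_dup, " duplicate user id(s) in '", path,
            "'; rows kept separately with a '#k' suffix", call. = FALSE)
  seen <- list()
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    uid <- ids[i]
    if (is.null(seen[[uid]])) seen[[uid]] <- 0L
    seen[[uid]] <- seen[[uid]] + 1L
    if (seen[[uid]] > 1L) uid <- paste0(uid, "#", seen[[uid]])
    answers <- list()
    for (qk in qkeys) {
      vals <- unlist(tab[i, which(hdr == qk)], use.names = FALSE)
      vals <- as.character(vals[!is.na(vals) & trimws(vals) != ""])
      if (length(vals)) answers[[qk]] <- vals
    }
    grab <- function(col) {
      if (!is.null(col) && col %in% hdr) {
        v <- as.character(tab[i, which(hdr == col)[1L]])
        if (!is.na(v) && v != "") v else NA_character_
      } else NA_character_
    }
    records[[i]] <- response_record(uid, answers, group = grab(group_col),
                                    role = grab(role_col))
  }
  records
}

#' @rdname read_responses
#' @param user_id respondent identifier (nonempty).
#' @param answers named list mapping question_key to recorded value(s).
#' @param group,role optional labels.
#' @export
response_record <- function(user_id, answers = list(), group = NA_character_,
                            role = NA_character_) {
  user_id <- as.character(user_id)
  if (length(user_id) != 1L || is.na(user_id) || !nzchar(user_id))
    stop("user_id must be a nonempty string")
  answers <- lapply(answers, as.character)
  if (length(answers))  # canonical key order, so round trips compare equal
    answers <- answers[order(names(answers), method = "radix")]
  structure(list(user_id = user_id, group = as.character(group),
                 role = as.character(role), answers = answers),
            class = "response_record")
}

read_wide_table <- function(path) {
  if (!file.exists(path)) stop("response log not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx logs requires the 'readxl' package", call. = FALSE)
    tab <- readxl::read_excel(path, col_types = "text", .name_repair = "minimal")
    return(as.data.frame(tab, stringsAsFactors = FALSE, check.names = FALSE))
  }
  sep <- if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8-BOM", comment.char = "",
                    stringsAsFactors = FALSE)
}

norm_ws <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Replay one respondent's answers into a path through the case
#'
#' Starting from the case's start node, the recorded answer at each visited
#' decision node selects the outgoing edge whose option text matches (exact
#' match after whitespace normalization). Replay stops at an endpoint
#' (`complete = TRUE`) or at the first decision node with no recorded
#' answer (`complete = FALSE`, anomaly `MISSING_ANSWER`). Answers for
#' questions the replayed route never visits are flagged `ORPHAN_ANSWER`
#' (typically back-button artifacts); if a visited question holds several
#' recorded values the last one is used (`MULTI_ANSWER`).
#'
#' @param case a valid `case_graph`.
#' @param record a `response_record`.
#' @return a `user_path`: list with `user_id`, `nodes` (ordered ids),
#'   `edges` (data frame of traversed edges), `terminal`, `complete`,
#'   `anomalies` (data frame `code`, `question_key`) and `case_id`.
#' @export
replay_path <- function(case, record) {
  assert_valid_case(case)
  stopifnot(inherits(record, "response_record"))
  nodes <- case$nodes
  edges <- case$edges
  anomalies <- list()
  add_anom <- function(code, qk)
    anomalies[[length(anomalies) + 1L]] <<- data.frame(
      code = code, question_key = qk, stringsAsFactors = FALSE)

  cur <- case$start
  path_nodes <- cur
  taken <- integer(0)
  visited_keys <- character(0)
  repeat {
    ni <- match(cur, nodes$id)
    if (nodes$kind[ni] == "endpoint") break
    qk <- nodes$question_key[ni]
    visited_keys <- c(visited_keys, qk)
    vals <- record$answers[[qk]]
    if (is.null(vals) || length(vals) == 0L) {
      add_anom("MISSING_ANSWER", qk)
      break
    }
    if (length(vals) > 1L) add_anom("MULTI_ANSWER", qk)
    ans <- norm_ws(vals[length(vals)])
    out <- which(edges$from == cur)
    hit <- out[norm_ws(edges$option[out]) == ans]
    if (length(hit) == 0L)
      stop("UNMATCHED_OPTION: answer '", ans, "' matches no option at node '",
           cur, "' (user ", record$user_id, ")", call. = FALSE)
    hit <- hit[1L]  # duplicate option text: first declared edge wins
    taken <- c(taken, hit)
    cur <- edges$to[hit]
    path_nodes <- c(path_nodes, cur)
  }
  for (qk in setdiff(names(record$answers), visited_keys))
    add_anom("ORPHAN_ANSWER", qk)

  terminal <- path_nodes[length(path_nodes)]
  complete <- nodes$kind[match(terminal, nodes$id)] == "endpoint"
  empty <- data.frame(code = character(), question_key = character(),
                      stringsAsFactors = FALSE)
  structure(list(
    user_id = record$user_id,
    nodes = path_nodes,
    edges = edges[taken, , drop = FALSE],
    terminal = terminal,
    complete = complete,
    anomalies = if (length(anomalies)) do.call(rbind, anomalies) else empty,
    case_id = case$case_id), class = "user_path")
}

#' Replay a whole cohort of records
#'
#' @param case a valid `case_graph`.
#' @param records list of `response_record`.
#' @param strict drop incomplete paths (respondents who never reached an
#'   endpoint) instead of retaining them.
#' @return list of `user_path`.
#' @export
replay_cohort <- function(case, records, strict = FALSE) {
  paths <- lapply(records, function(r) replay_path(case, r))
  if (strict) paths <- Filter(function(p) p$complete, paths)
  paths
}

#' @export
print.user_path <- function(x, ...) {
  cat("User path [", x$user_id, "]: ",
      paste(x$nodes, collapse = " -> "),
      if (x$complete) "  (complete)" else "  (incomplete)", "\n", sep = "")
  if (nrow(x$anomalies))
    cat("  anomalies:", paste(x$anomalies$code, collapse = ", "), "\n")
  invisible(x)
}
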