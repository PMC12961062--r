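#' Construct a branched-case graph
#'
#' A `case_graph` holds the full structure of a branched ("choose your own
#' adventure" style) clinical case: decision nodes, classified choice edges,
#' the start node, and the expert route. The expert route is derived by
#' following the unique expert-classified edge out of each decision node,
#' starting at `start`, until an endpoint is reached; its last node is the
#' FINISH node.
#'
#' @param case_id short stable case identifier.
#' @param title display title.
#' @param start node id where every user path begins.
#' @param nodes data frame with columns `id`, `label`, `kind`
#'   (`"treatment"`, `"hydration"` or `"endpoint"`), `timepoint_hours`
#'   (numeric, `NA` allowed for endpoints), `question_key` (`NA` for
#'   endpoints) and `tier` (`"expert_row"`, `"middle"` or `"endpoint_row"`).
#' @param edges data frame with columns `from`, `option` (verbatim answer
#'   text), `to` and `class` (`"expert"`, `"tolerable"` or `"incorrect"`).
#' @param check if `TRUE` (default) structural defects that make the expert
#'   route underivable raise an error; with `FALSE` a best-effort object is
#'   returned so that [validate_case()] can report the defects.
#'
#' @return an object of class `case_graph` with fields `case_id`, `title`,
#'   `start`, `nodes`, `edges`, `expert_route` and `finish`.
#' @seealso [load_case()], [validate_case()], [expert_checkpoints()]
#' @export
case_graph <- function(case_id, title, start, nodes, edges, check = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("id", "label", "kind", "timepoint_hours", "question_key", "tier")
  need_e <- c("from", "option", "to", "class")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  nodes <- nodes[, need_n]
  edges <- edges[, need_e]
  for (cc in c("id", "label", "kind", "question_key", "tier"))
    nodes[[cc]] <- as.character(nodes[[cc]])
  nodes$timepoint_hours <- as.numeric(nodes$timepoint_hours)
  for (cc in need_e) edges[[cc]] <- as.character(edges[[cc]])

  # canonical, locale-independent ordering => stable serialization
  nodes <- nodes[order(nodes$id, method = "radix"), , drop = FALSE]
  edges <- edges[order(edges$from, edges$option, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL

  route <- derive_expert_route(start, nodes, edges, strict = check)
  x <- structure(
    list(case_id = as.character(case_id), title = as.character(title),
         start = as.character(start), nodes = nodes, edges = edges,
         expert_route = route, finish = route[length(route)]),
    class = "case_graph")
  if (check) {
    rep <- validate_case(x)
    if (nrow(rep$errors) > 0L)
      stop("invalid case graph:\n", format_report(rep), call. = FALSE)
    attr(x, "validated") <- TRUE
  }
  x
}

# Follow the unique expert edge from `start` until an endpoint is reached.
derive_expert_route <- function(start, nodes, edges, strict = TRUE) {
  route <- start
  cur <- start
  is_endpoint <- function(id) {
    k <- nodes$kind[match(id, nodes$id)]
    !is.na(k) && k == "endpoint"
  }
  for (step in seq_len(nrow(nodes) + 1L)) {
    if (!cur %in% nodes$id || is_endpoint(cur)) break
    out <- edges[edges$from == cur & edges$class == "expert", , drop = FALSE]
    if (nrow(out) != 1L) {
      if (strict)
        stop("node '", cur, "' has ", nrow(out),
             " expert edges (exactly 1 required)", call. = FALSE)
      break
    }
    cur <- out$to[1L]
    if (cur %in% route) {  # cycle on the expert route
      if (strict) stop("expert route revisits node '", cur, "'", call. = FALSE)
      break
    }
    route <- c(route, cur)
  }
  route
}

#' Load a case-definition file
#'
#' Reads a structured-text (YAML) case definition with top-level keys
#' `case_id`, `title`, `start`, `nodes` and `edges`, builds the
#' [case_graph()] and rejects it if validation finds any error.
#'
#' @param path path to a case-definition file.
#' @return a validated `case_graph`.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed case file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  for (key in c("case_id", "title", "start", "nodes", "edges"))
    if (is.null(doc[[key]]))
      stop("malformed case file '", path, "': missing section '", key, "'",
           call. = FALSE)
  pick <- function(rec, field) {
    v <- rec[[field]]
    if (is.null(v)) NA else v
  }
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
    if (is.null(n$id)) stop("malformed case file: node without 'id' in ",
                            "section 'nodes'", call. = FALSE)
    data.frame(id = as.character(n$id), label = as.character(pick(n, "label")),
               kind = as.character(pick(n, "kind")),
               timepoint_hours = as.numeric(pick(n, "timepoint_hours")),
               question_key = as.character(pick(n, "question_key")),
               tier = as.character(pick(n, "tier")),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(doc$edges, function(e) {
    for (f in c("from", "option", "to", "class"))
      if (is.null(e[[f]]))
        stop("malformed case file: edge without '", f,
             "' in section 'edges'", call. = FALSE)
    data.frame(from = as.character(e$from), option = as.character(e$option),
               to = as.character(e$to), class = as.character(e$class),
               stringsAsFactors = FALSE)
  }))
  x <- case_graph(doc$case_id, doc$title, doc$start, nodes, edges,
                  check = FALSE)
  rep <- validate_case(x)
  if (nrow(rep$errors) > 0L)
    stop("case file '", path, "' failed validation:\n", format_report(rep),
         call. = FALSE)
  attr(x, "validated") <- TRUE
  x
}

#' Serialize a case graph to a case-definition file
#'
#' Writes the YAML dialect read by [load_case()]. Output is byte-stable:
#' nodes and edges are emitted in canonical sorted order with a fixed field
#' order, so `load_case(write_case(x))` round-trips to an identical object.
#'
#' @param case a `case_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "case_graph"))
  strip_na <- function(lst) lst[!vapply(lst, function(v) is.na(v), logical(1))]
  doc <- list(
    case_id = case$case_id,
    title = case$title,
    start = case$start,
    nodes = lapply(seq_len(nrow(case$nodes)), function(i) {
      n <- case$nodes[i, ]
      strip_na(list(id = n$id, label = n$label, kind = n$kind,
                    timepoint_hours = n$timepoint_hours,
                    question_key = n$question_key, tier = n$tier))
    }),
    edges = lapply(seq_len(nrow(case$edges)), function(i) {
      e <- case$edges[i, ]
      list(from = e$from, option = e$option, to = e$to, class = e$class)
    }))
  yaml::write_yaml(doc, path, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' Validate a case graph
#'
#' Structural checks on a `case_graph`. Errors (any one makes the case
#' unusable downstream): unknown node references, endpoints with outgoing
#' edges or question keys, decision nodes without exactly one expert edge or
#' without outgoing edges, unreachable nodes, directed cycles, a broken
#' expert-route chain, bad `kind`/`class`/`tier` values, negative
#' timepoints. Warnings: treatment menus outside the expected 8-14 option
#' range (`MENU_SIZE`), duplicate option text at one node (`DUP_OPTION`).
#'
#' @param case a `case_graph`.
#' @return a `validation_report`: list with data frames `errors` and
#'   `warnings`, each with columns `code`, `ref`, `message`.
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "case_graph"))
  errs <- list()
  warns <- list()
  add <- function(store, code, ref, msg) {
    store[[length(store) + 1L]] <- data.frame(code = code, ref = ref,
                                              message = msg,
                                              stringsAsFactors = FALSE)
    store
  }
  nodes <- case$nodes
  edges <- case$edges
  ids <- nodes$id

  dup <- unique(ids[duplicated(ids)])
  for (d in dup) errs <- add(errs, "DUP_NODE_ID", d, "duplicate node id")

  if (!case$start %in% ids)
    errs <- add(errs, "START_MISSING", case$start,
                "start node is not in the node set")

  bad_kind <- nodes$id[!nodes$kind %in% c("treatment", "hydration", "endpoint")]
  for (b in bad_kind) errs <- add(errs, "BAD_KIND", b, "unknown node kind")
  bad_tier <- nodes$id[!nodes$tier %in% c("expert_row", "middle", "endpoint_row")]
  for (b in bad_tier) errs <- add(errs, "BAD_TIER", b, "unknown node tier")
  bad_tp <- nodes$id[!is.na(nodes$timepoint_hours) & nodes$timepoint_hours < 0]
  for (b in bad_tp) errs <- add(errs, "BAD_TIMEPOINT", b,
                                "negative timepoint_hours")
  bad_cls <- which(!edges$class %in% c("expert", "tolerable", "incorrect"))
  for (b in bad_cls)
    errs <- add(errs, "BAD_CLASS", edge_ref(edges[b, ]),
                paste0("unknown edge class '", edges$class[b], "'"))

  miss_to <- which(!edges$to %in% ids)
  for (b in miss_to)
    errs <- add(errs, "DANGLING_DEST", edge_ref(edges[b, ]),
                paste0("destination '", edges$to[b], "' is not a known node"))
  miss_from <- which(!edges$from %in% ids)
  for (b in miss_from)
    errs <- add(errs, "DANGLING_SOURCE", edge_ref(edges[b, ]),
                paste0("source '", edges$from[b], "' is not a known node"))

  is_ep <- nodes$kind == "endpoint"
  n_out <- vapply(ids, function(id) sum(edges$from == id), integer(1))
  for (id in ids[is_ep & n_out > 0])
    errs <- add(errs, "ENDPOINT_OUTGOING", id, "endpoint has outgoing edges")
  for (id in ids[is_ep & !is.na(nodes$question_key)])
    errs <- add(errs, "ENDPOINT_QUESTION", id, "endpoint has a question_key")
  for (id in ids[!is_ep & n_out == 0])
    errs <- add(errs, "NO_OUTGOING", id,
                "decision node has no outgoing edges")

  n_exp <- vapply(ids, function(id)
    sum(edges$from == id & edges$class == "expert"), integer(1))
  for (id in ids[!is_ep & n_exp != 1])
    errs <- add(errs, "EXPERT_EDGE_COUNT", id,
                paste0("decision node has ", n_exp[match(id, ids)],
                       " expert edges (exactly 1 required)"))

  # graph-level checks on the well-formed part of the edge set
  ok_e <- edges$from %in% ids & edges$to %in% ids
  if (length(ids) > 0 && !anyDuplicated(ids) && case$start %in% ids) {
    g <- igraph::graph_from_data_frame(
      edges[ok_e, c("from", "to"), drop = FALSE], directed = TRUE,
      vertices = data.frame(name = ids))
    reach <- igraph::subcomponent(g, case$start, mode = "out")$name
    for (id in setdiff(ids, reach))
      errs <- add(errs, "UNREACHABLE", id,
                  "node is not reachable from the start node")
    if (!igraph::is_dag(g))
      errs <- add(errs, "CYCLE", case$case_id,
                  "case graph contains a directed cycle")
  }

  # expert route chain: start -> ... -> endpoint via expert edges
  rt <- case$expert_route
  broken <- rt[1L] != case$start
  if (!broken && length(rt) >= 2) {
    for (i in seq_len(length(rt) - 1L)) {
      hit <- edges$from == rt[i] & edges$to == rt[i + 1L] &
        edges$class == "expert"
      if (!any(hit)) { broken <- TRUE; break }
    }
  }
  last <- rt[length(rt)]
  if (!broken && (!last %in% ids || nodes$kind[match(last, ids)] != "endpoint"))
    broken <- TRUE
  if (broken)
    errs <- add(errs, "EXPERT_ROUTE_BROKEN",
                paste(rt, collapse = " -> "),
                "expert route does not run from start to an endpoint via expert edges")

  # warnings
  for (id in ids[nodes$kind == "treatment"]) {
    m <- n_out[match(id, ids)]
    if (m > 0 && (m < 8 || m > 14))
      warns <- add(warns, "MENU_SIZE", id,
                   paste0("treatment menu has ", m,
                          " options (expected 8 to 14)"))
  }
  key <- paste(edges$from, edges$option, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    warns <- add(warns, "DUP_OPTION", parts[1L],
                 paste0("duplicate option text '", parts[2L], "'"))
  }

  empty <- data.frame(code = character(), ref = character(),
                      message = character(), stringsAsFactors = FALSE)
  structure(list(errors = if (length(errs)) do.call(rbind, errs) else empty,
                 warnings = if (length(warns)) do.call(rbind, warns) else empty),
            class = "validation_report")
}

edge_ref <- function(e) paste0(e$from, " --[", e$option, "]--> ", e$to)

format_report <- function(rep) {
  fmt <- function(df, tag)
    if (nrow(df)) paste0("  ", tag, " ", df$code, " (", df$ref, "): ",
                         df$message, collapse = "\n") else NULL
  paste(c(fmt(rep$errors, "error"), fmt(rep$warnings, "warning")),
        collapse = "\n")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Case validation:", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors) + nrow(x$warnings) > 0) cat(format_report(x), "\n")
  invisible(x)
}

# Downstream operations refuse invalid cases. Cases built or loaded
# through the checking constructors carry a validation flag so repeated
# calls stay cheap.
assert_valid_case <- function(case) {
  stopifnot(inherits(case, "case_graph"))
  if (isTRUE(attr(case, "validated"))) return(invisible(case))
  rep <- validate_case(case)
  if (nrow(rep$errors) > 0L)
    stop("refusing to operate on an invalid case graph:\n",
         format_report(rep), call. = FALSE)
  invisible(case)
}

#' Expert-route checkpoints
#'
#' The ordered nodes of the expert route. These checkpoints are the rows of
#' the cohort behavior table: the uppermost line of the case map, from the
#' first decision point through the FINISH node.
#'
#' @param case a valid `case_graph`.
#' @return data frame with columns `node_id` and `label`, in traversal order.
#' @export
expert_checkpoints <- function(case) {
  assert_valid_case(case)
  idx <- match(case$expert_route, case$nodes$id)
  data.frame(node_id = case$expert_route, label = case$nodes$label[idx],
             stringsAsFactors = FALSE)
}

#' @export
print.case_graph <- function(x, ...) {
  n_ep <- sum(x$nodes$kind == "endpoint")
  cat("Branched case '", x$case_id, "': ", x$title, "\n", sep = "")
  cat("  ", nrow(x$nodes), " nodes (", n_ep, " endpoints), ",
      nrow(x$edges), " classified edges\n", sep = "")
  cat("  expert route (", length(x$expert_route), " checkpoints): ",
      paste(x$expert_route, collapse = " -> "), "\n", sep = "")
  invisible(x)
}
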