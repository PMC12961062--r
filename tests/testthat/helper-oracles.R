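# Independent oracles and fixture builders. Everything here recomputes
# expected values by brute force, separately from the package's own code
# paths, so tests compare two independent routes to the same answer.

# --- exhaustive enumeration -------------------------------------------------

# all root-to-leaf edge paths of a case, by depth-first recursion over the
# raw edge table (never uses replay_path)
enumerate_paths <- function(case, limit = 10000L) {
  edges <- case$edges
  is_ep <- function(id) case$nodes$kind[match(id, case$nodes$id)] == "endpoint"
  out <- list()
  recurse <- function(node, idx) {
    if (length(out) >= limit) stop("path enumeration limit exceeded")
    if (is_ep(node)) {
      out[[length(out) + 1L]] <<- idx
      return(invisible(NULL))
    }
    for (i in which(edges$from == node)) recurse(edges$to[i], c(idx, i))
  }
  recurse(case$start, integer(0))
  out  # list of edge-row index vectors
}

# the unique enumerated complete path consistent with a record's answers:
# every traversed edge's option must equal the recorded answer (last value)
# at its source node's question key
oracle_consistent_paths <- function(case, record) {
  edges <- case$edges
  qk_of <- function(id) case$nodes$question_key[match(id, case$nodes$id)]
  norm <- function(x) gsub("[[:space:]]+", " ", trimws(x))
  Filter(function(idx) {
    all(vapply(idx, function(i) {
      vals <- record$answers[[qk_of(edges$from[i])]]
      !is.null(vals) && norm(vals[length(vals)]) == norm(edges$option[i])
    }, logical(1)))
  }, enumerate_paths(case))
}

# --- brute-force cumulative classification ----------------------------------

# recompute a user's status at one checkpoint from scratch, with a plain
# re-scan of the first min(k, D) decisions (no shared state with
# classify_user's vectorized prefix logic)
oracle_status_at <- function(case, path, k) {
  route <- case$expert_route
  D <- nrow(path$edges)
  m <- min(k, D)
  if (m > 0) {
    for (j in seq_len(m))
      if (path$edges$class[j] == "incorrect") return("incorrect")
  }
  if (m < k) return("tolerable_only")
  if (k == 0) return("expert")
  for (j in seq_len(k)) {
    ok <- path$edges$from[j] == route[j] &&
      path$edges$to[j] == route[j + 1L] &&
      path$edges$class[j] == "expert"
    if (!ok) return("tolerable_only")
  }
  "expert"
}

oracle_classify <- function(case, path) {
  K <- length(case$expert_route)
  vapply(seq_len(K) - 1L, function(k) oracle_status_at(case, path, k),
         character(1))
}

# --- naive per-edge tally ---------------------------------------------------

oracle_edge_counts <- function(case, paths) {
  key <- paste(case$edges$from, case$edges$option, case$edges$to, sep = "\r")
  counts <- setNames(integer(length(key)), key)
  for (p in paths) {
    if (nrow(p$edges) == 0) next
    for (j in seq_len(nrow(p$edges))) {
      k <- paste(p$edges$from[j], p$edges$option[j], p$edges$to[j], sep = "\r")
      counts[k] <- counts[k] + 1L
    }
  }
  unname(counts)
}

# --- fixture builders -------------------------------------------------------

# build a response_record by walking the case with a per-node chooser;
# pick(node_id, out_edges_df) must return one row index into out_edges_df
strategy_record <- function(case, uid, pick) {
  nodes <- case$nodes
  edges <- case$edges
  cur <- case$start
  answers <- list()
  repeat {
    ni <- match(cur, nodes$id)
    if (nodes$kind[ni] == "endpoint") break
    out <- edges[edges$from == cur, , drop = FALSE]
    j <- pick(cur, out)
    answers[[nodes$question_key[ni]]] <- out$option[j]
    cur <- out$to[j]
  }
  response_record(uid, answers)
}

pick_class <- function(class, fallback = "expert") {
  function(node_id, out) {
    j <- which(out$class == class)
    if (length(j) == 0) j <- which(out$class == fallback)
    j[1L]
  }
}

# expert everywhere except one chosen class at one node
pick_class_at <- function(node, class) {
  function(node_id, out) {
    want <- if (node_id == node) class else "expert"
    j <- which(out$class == want)
    if (length(j) == 0) j <- which(out$class == "expert")
    j[1L]
  }
}

expert_record <- function(case, uid) strategy_record(case, uid, pick_class("expert"))

# --- minimal DOT subset parser ----------------------------------------------

# grammar-level parse of the renderer's DOT dialect: digraph header, graph/
# node/edge default attributes, rank groups, quoted node statements, quoted
# edge statements with attribute lists, one optional key subgraph, balanced
# braces. Returns the parsed structure or stops on any unrecognized line.
parse_dot <- function(dot) {
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines[nzchar(trimws(lines))])
  qs <- '"(\\\\.|[^"\\\\])*"'   # quoted string with escapes
  unq <- function(x) {
    x <- substr(x, 2, nchar(x) - 1)
    gsub("\\\\(.)", "\\1", x)
  }
  stopifnot(grepl(paste0("^digraph ", qs, " \\{$"), lines[1]))
  stopifnot(lines[length(lines)] == "}")
  body <- lines[-c(1, length(lines))]

  nodes <- list(); edges <- list(); ranks <- list(); depth <- 0L
  re_rank <- paste0("^\\{ rank=(min|max|same); (", qs, "; )+\\}$")
  re_node <- paste0("^(", qs, ") \\[(.*)\\];$")
  re_edge <- paste0("^(", qs, ") -> (", qs, ") \\[(.*)\\];$")
  re_attr <- "^(graph|node|edge) \\[.*\\];$"
  parse_attrs <- function(s) {
    m <- gregexpr(paste0("([a-z]+)=(", qs, "|[0-9.]+)"), s)[[1]]
    parts <- regmatches(s, list(m))[[1]]
    kv <- strsplit(parts, "=", fixed = FALSE)
    out <- lapply(kv, function(p) {
      v <- paste(p[-1], collapse = "=")
      if (startsWith(v, '"')) unq(v) else as.numeric(v)
    })
    names(out) <- vapply(kv, `[[`, "", 1)
    out
  }
  for (ln in body) {
    if (grepl(re_rank, ln)) {
      kind <- sub("^\\{ rank=([a-z]+);.*$", "\\1", ln)
      ids <- regmatches(ln, gregexpr(qs, ln))[[1]]
      ranks[[length(ranks) + 1L]] <- list(rank = kind,
                                          ids = vapply(ids, unq, ""))
    } else if (grepl(re_edge, ln)) {
      from <- unq(sub(re_edge, "\\1", ln))
      to <- unq(sub(re_edge, "\\3", ln))
      edges[[length(edges) + 1L]] <-
        c(list(from = from, to = to),
          parse_attrs(sub(re_edge, "\\5", ln)))
    } else if (grepl(re_node, ln)) {
      id <- unq(sub(re_node, "\\1", ln))
      nodes[[length(nodes) + 1L]] <- c(list(id = id),
                                       parse_attrs(sub(re_node, "\\3", ln)))
    } else if (grepl(re_attr, ln)) {
    } else if (grepl("^subgraph [A-Za-z0-9_]+ \\{$", ln)) {
      depth <- depth + 1L
    } else if (ln == "}") {
      depth <- depth - 1L
      stopifnot(depth >= 0L)
    } else {
      stop("unparseable DOT line: ", ln)
    }
  }
  stopifnot(depth == 0L)
  list(nodes = nodes, edges = edges, ranks = ranks)
}
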