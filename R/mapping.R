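# Deterministic Graphviz DOT emission of the case map, with cohort traffic
# superimposed: the expert route runs along the top row, incorrect
# endpoints sit on the bottom row, edge width scales with the fraction of
# the cohort traversing the edge, and color encodes the edge taxonomy.

#' Map style for DOT rendering
#'
#' Visual conventions of the case map: treatment prompts are circles,
#' hydration prompts diamonds, endpoints squares; edge colors distinguish
#' untraveled, expert, deviation (off the expert path but harmless),
#' rejoin (returning to the expert path) and incorrect edges; edge pen
#' width grows linearly from `w_min` to `w_max` with the fraction of the
#' cohort traversing the edge.
#'
#' @param shapes named character: node kind -> DOT shape.
#' @param palette named character: style class -> color.
#' @param w_min,w_max pen-width range (`w_min > 0`, `w_max >= w_min`).
#' @param rank_expert,rank_endpoints emit rank constraints pinning the
#'   expert route to the top row and incorrect endpoints to the bottom row.
#' @param legend emit a key subgraph naming each node.
#' @return an object of class `map_style`.
#' @export
map_style <- function(shapes = c(treatment = "circle", hydration = "diamond",
                                 endpoint = "box"),
                      palette = c(untraveled = "gray70", expert = "black",
                                  deviation = "orange", rejoin = "teal",
                                  incorrect = "magenta"),
                      w_min = 1, w_max = 8,
                      rank_expert = TRUE, rank_endpoints = TRUE,
                      legend = TRUE) {
  if (!is.numeric(w_min) || w_min <= 0) stop("w_min must be > 0")
  if (!is.numeric(w_max) || w_max < w_min) stop("w_max must be >= w_min")
  need <- c("untraveled", "expert", "deviation", "rejoin", "incorrect")
  if (!all(need %in% names(palette)))
    stop("palette must name colors for: ", paste(need, collapse = ", "))
  structure(list(shapes = shapes, palette = palette, w_min = w_min,
                 w_max = w_max, rank_expert = isTRUE(rank_expert),
                 rank_endpoints = isTRUE(rank_endpoints),
                 legend = isTRUE(legend)),
            class = "map_style")
}

#' Per-edge cohort traffic and style taxonomy
#'
#' Counts how many users traverse each declared edge and assigns the style
#' class used by the renderer: `incorrect` for harmful choices, `expert`
#' for the expert-route edges, `rejoin` for edges returning from an
#' off-route node to the expert route, `deviation` otherwise; any edge no
#' user traversed is `untraveled` regardless of taxonomy.
#'
#' @param case a valid `case_graph`.
#' @param paths list of `user_path` replayed from the case.
#' @return an `edge_usage` data frame: `from`, `option`, `to`, `class`,
#'   `count`, `fraction` (count / cohort size), `style_class`; attribute
#'   `cohort_size`.
#' @export
edge_usage <- function(case, paths) {
  assert_valid_case(case)
  edges <- case$edges
  key <- paste(edges$from, edges$option, edges$to, sep = "\r")
  count <- integer(nrow(edges))
  for (p in paths) {
    if (nrow(p$edges) == 0) next
    pk <- paste(p$edges$from, p$edges$option, p$edges$to, sep = "\r")
    idx <- match(pk, key)
    if (anyNA(idx))
      stop("path for user ", p$user_id, " uses edges not in this case",
           call. = FALSE)
    tab <- table(idx)
    count[as.integer(names(tab))] <- count[as.integer(names(tab))] +
      as.integer(tab)
  }
  N <- length(paths)
  route <- case$expert_route
  pair <- paste(route[-length(route)], route[-1L], sep = "\r")
  on_route <- edges$from %in% route
  to_route <- edges$to %in% route
  is_exp <- paste(edges$from, edges$to, sep = "\r") %in% pair &
    edges$class == "expert"
  style <- ifelse(edges$class == "incorrect", "incorrect",
           ifelse(is_exp, "expert",
           ifelse(!on_route & to_route, "rejoin", "deviation")))
  style[count == 0L] <- "untraveled"
  out <- cbind(edges,
               data.frame(count = count,
                          fraction = if (N > 0) count / N else rep(0, length(count)),
                          style_class = style, stringsAsFactors = FALSE))
  structure(out, cohort_size = N, class = c("edge_usage", "data.frame"))
}

dot_quote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

#' Render the case map as Graphviz DOT text
#'
#' Emits deterministic DOT describing the case map: the expert route
#' pinned to the top rank in route order, incorrect endpoints pinned to
#' the bottom rank, node shapes by kind, and — when `usage` is supplied —
#' edge colors by style class and pen widths
#' `w_min + (w_max - w_min) * fraction`. Without `usage` the base map is
#' drawn with every edge in the untraveled style. Identical inputs produce
#' byte-identical output (sorted node and edge emission, fixed number
#' formatting).
#'
#' @param case a valid `case_graph`.
#' @param usage optional `edge_usage` from [edge_usage()].
#' @param style a [map_style()].
#' @param title_suffix optional text appended to the graph title (used to
#'   label group maps in side-by-side comparisons).
#' @return a single string of DOT source.
#' @export
render_dot <- function(case, usage = NULL, style = map_style(),
                       title_suffix = NULL) {
  assert_valid_case(case)
  stopifnot(inherits(style, "map_style"))
  if (style$w_max < style$w_min) stop("w_max must be >= w_min")
  nodes <- case$nodes
  edges <- case$edges
  if (!is.null(usage)) {
    stopifnot(inherits(usage, "edge_usage"))
    key_c <- paste(edges$from, edges$option, edges$to, sep = "\r")
    key_u <- paste(usage$from, usage$option, usage$to, sep = "\r")
    idx <- match(key_c, key_u)
    if (anyNA(idx)) stop("usage does not cover this case's edges")
    fraction <- usage$fraction[idx]
    style_class <- usage$style_class[idx]
    count <- usage$count[idx]
  } else {
    fraction <- rep(0, nrow(edges))
    style_class <- rep("untraveled", nrow(edges))
    count <- rep(0L, nrow(edges))
  }

  title <- case$title
  if (!is.null(title_suffix)) title <- paste0(title, " - ", title_suffix)
  L <- c(
    paste0("digraph ", dot_quote(case$case_id), " {"),
    paste0("  graph [label=", dot_quote(title),
           ", labelloc=\"t\", fontsize=18, nodesep=0.3, ranksep=0.55];"),
    "  node [fontsize=11, style=\"filled\", fillcolor=\"white\"];",
    "  edge [arrowsize=0.7];")

  if (style$rank_expert) {
    L <- c(L, paste0("  { rank=min; ",
                     paste(dot_quote(case$expert_route), collapse = "; "),
                     "; }"))
  }
  if (style$rank_endpoints) {
    bottom <- nodes$id[nodes$tier == "endpoint_row"]
    bottom <- sort(setdiff(bottom, case$finish), method = "radix")
    if (length(bottom))
      L <- c(L, paste0("  { rank=max; ",
                       paste(dot_quote(bottom), collapse = "; "), "; }"))
  }

  for (i in order(nodes$id, method = "radix")) {
    shape <- style$shapes[[nodes$kind[i]]]
    fill <- if (nodes$kind[i] == "endpoint" && nodes$id[i] != case$finish)
      "gray80" else "white"
    L <- c(L, paste0("  ", dot_quote(nodes$id[i]),
                     " [label=", dot_quote(nodes$id[i]),
                     ", shape=\"", shape, "\", fillcolor=\"", fill, "\"];"))
  }

  wspan <- style$w_max - style$w_min
  for (i in order(edges$from, edges$option, edges$to, method = "radix")) {
    w <- style$w_min + wspan * fraction[i]
    L <- c(L, paste0(
      "  ", dot_quote(edges$from[i]), " -> ", dot_quote(edges$to[i]),
      " [color=\"", style$palette[[style_class[i]]], "\"",
      ", penwidth=", sprintf("%.3f", w),
      ", tooltip=", dot_quote(paste0(edges$option[i], " (n=", count[i], ")")),
      "];"))
  }

  if (style$legend) {
    idx <- order(nodes$id, method = "radix")
    key <- paste0(nodes$id[idx], ": ", nodes$label[idx], "\\l",
                  collapse = "")
    L <- c(L,
           "  subgraph cluster_key {",
           "    graph [label=\"Key\", fontsize=12];",
           paste0("    \"__key__\" [shape=\"plaintext\", style=\"\", label=",
                  dot_quote_raw(key), "];"),
           "  }")
  }
  L <- c(L, "}")
  paste0(paste(L, collapse = "\n"), "\n")
}

# quote a label that already contains DOT escape sequences (\l)
dot_quote_raw <- function(x) paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")

#' Render one map per group with a shared layout
#'
#' Each group's traffic is rendered on the same node set with identical
#' rank constraints and node ordering, so the maps are directly comparable
#' side by side; only the title and the edge styling differ.
#'
#' @param case a valid `case_graph`.
#' @param usages named list (two or more entries) of `edge_usage`, one per
#'   group label.
#' @param style a [map_style()].
#' @return named list of DOT strings.
#' @export
render_comparison <- function(case, usages, style = map_style()) {
  if (length(usages) == 0) stop("no group usages supplied", call. = FALSE)
  if (length(usages) < 2)
    stop("comparison needs at least two groups", call. = FALSE)
  if (is.null(names(usages)) || any(!nzchar(names(usages))))
    stop("usages must be a named list", call. = FALSE)
  out <- lapply(names(usages), function(lab)
    render_dot(case, usages[[lab]], style, title_suffix = lab))
  names(out) <- names(usages)
  out
}
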