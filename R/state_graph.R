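#' Multistate transition graphs and their block decompositions
#'
#' A unidirectional (acyclic) multistate process is described by its state
#' space and the set of permitted direct transitions. Two canonical
#' decompositions of such a graph drive the blockwise inference strategies:
#' one competing-risk block per non-absorbing state (all transitions leaving
#' that state, treated as competing causes), and one single-transition block
#' per permitted transition.
#'
#' @name state_graph
NULL

#' Construct a transition graph
#'
#' @param transitions two-column integer matrix (or data.frame) of permitted
#'   direct transitions, one `(from, to)` pair per row, or a list of length-2
#'   integer vectors. States are nonnegative integer labels.
#' @param states optional integer vector of state labels; defaults to the
#'   states appearing in `transitions`. Supplying extra labels allows states
#'   that are only reachable in principle (they yield empty blocks, with a
#'   warning at validation).
#' @param labels optional character vector of display names, parallel to
#'   `states`.
#'
#' @return An object of class `transition_graph` with elements `states`,
#'   `transitions` (ordered two-column matrix) and `labels`. The graph is
#'   validated on construction (see [validate_graph()]).
#' @examples
#' g <- transition_graph(rbind(c(0, 1), c(0, 2), c(1, 2)))
#' competing_risk_blocks(g)
#' @export
transition_graph <- function(transitions, states = NULL, labels = NULL) {
  if (is.list(transitions) && !is.data.frame(transitions)) {
    transitions <- do.call(rbind, lapply(transitions, as.integer))
  }
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L) {
    stop("`transitions` must have two columns (from, to)", call. = FALSE)
  }
  storage.mode(transitions) <- "integer"
  if (anyNA(transitions) || any(transitions < 0L)) {
    stop("transitions must be nonnegative integer state labels", call. = FALSE)
  }
  if (anyDuplicated(paste(transitions[, 1], transitions[, 2]))) {
    stop("duplicate transitions supplied", call. = FALSE)
  }
  if (is.null(states)) states <- sort(unique(as.vector(transitions)))
  states <- sort(unique(as.integer(states)))
  if (!is.null(labels) && length(labels) != length(states)) {
    stop("`labels` must be parallel to `states`", call. = FALSE)
  }
  # deterministic ordering: ascending from-state, then to-state
  ord <- order(transitions[, 1], transitions[, 2])
  transitions <- transitions[ord, , drop = FALSE]
  colnames(transitions) <- c("from", "to")
  g <- structure(
    list(states = states, transitions = transitions, labels = labels),
    class = "transition_graph"
  )
  validate_graph(g)
}

#' Validate a transition graph
#'
#' Checks that every transition references a known state, that no state maps
#' to itself, that the directed graph is acyclic (unidirectional process) and
#' that at least one state is absorbing (no outgoing transitions). States with
#' no incident transitions are accepted with a warning; they produce empty
#' blocks downstream.
#'
#' @param graph a `transition_graph`.
#' @return The graph, invisibly unchanged, with attribute `validated = TRUE`.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  tr <- graph$transitions
  if (!all(tr %in% graph$states)) {
    stop("transition references a state not in the state set", call. = FALSE)
  }
  if (any(tr[, 1] == tr[, 2])) {
    stop("self-transitions are not permitted", call. = FALSE)
  }
  if (!is_acyclic(graph$states, tr)) {
    stop("transition graph contains a cycle: the multistate process must be unidirectional",
      call. = FALSE
    )
  }
  absorbing <- setdiff(graph$states, unique(tr[, 1]))
  if (length(absorbing) == 0L) {
    stop("graph has no absorbing state", call. = FALSE)
  }
  unreachable <- setdiff(graph$states, unique(as.vector(tr)))
  if (length(unreachable) > 0L) {
    warning(
      "states with no incident transitions: ",
      paste(unreachable, collapse = ", "), " (they yield empty blocks)",
      call. = FALSE
    )
  }
  attr(graph, "validated") <- TRUE
  invisible(graph)
}

# Kahn's algorithm; TRUE if the directed edge set is acyclic.
is_acyclic <- function(states, tr) {
  if (nrow(tr) == 0L) return(TRUE)
  edges <- tr
  repeat {
    sources <- setdiff(unique(edges[, 1]), unique(edges[, 2]))
    if (length(sources) == 0L) return(FALSE)
    edges <- edges[!(edges[, 1] %in% sources), , drop = FALSE]
    if (nrow(edges) == 0L) return(TRUE)
  }
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", length(x$states), "states,",
      nrow(x$transitions), "permitted transitions\n")
  cat("  states:", paste(x$states, collapse = " "), "\n")
  cat("  transitions:",
      paste(sprintf("%d->%d", x$transitions[, 1], x$transitions[, 2]),
            collapse = ", "), "\n")
  abs_states <- absorbing_states(x)
  cat("  absorbing:", paste(abs_states, collapse = " "), "\n")
  invisible(x)
}

#' Absorbing states of a graph
#' @param graph a `transition_graph`.
#' @return Integer vector of states with no outgoing transition.
#' @export
absorbing_states <- function(graph) {
  setdiff(graph$states, unique(graph$transitions[, 1]))
}

#' Competing-risk block decomposition
#'
#' Decomposes the transition set into one block per non-absorbing state: the
#' block with initial state `j` contains every permitted transition out of
#' `j`, whose target states act as competing causes. The decomposition is
#' unique and partitions the transition set.
#'
#' @param graph a validated `transition_graph`.
#' @return A list of `competing_risk_block` objects, ordered by ascending
#'   initial-state label; each has fields `initial_state` and
#'   `terminal_states` (ascending).
#' @export
competing_risk_blocks <- function(graph) {
  graph <- validate_graph(graph)
  tr <- graph$transitions
  initials <- sort(unique(tr[, 1]))
  lapply(initials, function(j) {
    structure(
      list(
        initial_state = j,
        terminal_states = sort(tr[tr[, 1] == j, 2])
      ),
      class = "competing_risk_block"
    )
  })
}

#' Single-transition block decomposition
#'
#' One block per permitted transition; used by the JM-ST strategy, which fits
#' an independent joint longitudinal-survival model per transition.
#'
#' @param graph a validated `transition_graph`.
#' @return A list of `transition_block` objects ordered by ascending
#'   `(from, to)`; each has fields `from_state` and `to_state`.
#' @export
single_transition_blocks <- function(graph) {
  graph <- validate_graph(graph)
  tr <- graph$transitions
  lapply(seq_len(nrow(tr)), function(i) {
    structure(
      list(from_state = tr[i, 1], to_state = tr[i, 2]),
      class = "transition_block"
    )
  })
}

#' @export
print.competing_risk_block <- function(x, ...) {
  cat(sprintf(
    "Competing-risk block: %d -> {%s}\n",
    x$initial_state, paste(x$terminal_states, collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.transition_block <- function(x, ...) {
  cat(sprintf("Single-transition block: %d -> %d\n", x$from_state, x$to_state))
  invisible(x)
}

transition_id <- function(from, to) sprintf("%d->%d", from, to)

#' Export a graph as an edge-list text file
#'
#' Writes one `j -> k` pair per line, the same format accepted in config
#' files; intended for provenance alongside simulation or fit outputs.
#'
#' @param graph a `transition_graph`.
#' @param path output file path.
#' @export
write_graph <- function(graph, path) {
  writeLines(
    sprintf("%d -> %d", graph$transitions[, 1], graph$transitions[, 2]),
    path
  )
  invisible(path)
}

#' Read a graph from an edge-list text file or character vector
#' @param x path to a file of `j -> k` lines, or a character vector of them.
#' @return A validated `transition_graph`.
#' @export
parse_graph <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([0-9]+)\\s*->\\s*([0-9]+)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("cannot parse transition line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  tr <- t(vapply(parts, function(p) as.integer(p[2:3]), integer(2)))
  transition_graph(tr)
}

#' The five-state progressive graph of the multimorbidity case study
#'
#' States 0 (single condition at entry), 1 and 2 (one additional condition),
#' 3 (both additional conditions) and 4 (death, absorbing), with the eight
#' permitted transitions 0->1, 0->2, 0->4, 1->3, 1->4, 2->3, 2->4, 3->4.
#' This graph has four competing-risk blocks and eight single-transition
#' blocks.
#'
#' @return A validated `transition_graph`.
#' @export
illness_death_graph <- function() {
  transition_graph(rbind(
    c(0L, 1L), c(0L, 2L), c(0L, 4L),
    c(1L, 3L), c(1L, 4L),
    c(2L, 3L), c(2L, 4L),
    c(3L, 4L)
  ))
}

#' The extended ten-transition progressive graph
#'
#' Adds transitions 0->3 and 1->2 to [illness_death_graph()], giving the
#' ten-transition structure used for the nonlinear-trajectory simulation
#' preset: four competing-risk blocks and ten single-transition blocks.
#'
#' @return A validated `transition_graph`.
#' @export
extended_graph <- function() {
  transition_graph(rbind(
    c(0L, 1L), c(0L, 2L), c(0L, 3L), c(0L, 4L),
    c(1L, 2L), c(1L, 3L), c(1L, 4L),
    c(2L, 3L), c(2L, 4L),
    c(3L, 4L)
  ))
}
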