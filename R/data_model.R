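#' Subject-level joint data and block datasets
#'
#' Joint data couple, per subject, a longitudinal biomarker record
#' (measurement times and values plus baseline covariates) with an observed
#' multistate path (sequence of visited states with entry times) under right
#' censoring. Blockwise inference conditions each block on a block dataset:
#' the risk set of subjects entering the block's initial state, a per-subject
#' longitudinal index set (historical or concurrent), and the block-specific
#' event view.
#'
#' @name data_model
NULL

#' Construct one subject record
#'
#' @param id subject identifier (scalar).
#' @param obs_times strictly increasing measurement times (study time).
#' @param obs_values biomarker values, parallel to `obs_times`.
#' @param w named numeric vector of baseline covariates (possibly empty).
#' @param path two-column matrix/data.frame `(state, entry_time)`, first row
#'   `(initial state, 0)`, entry times strictly increasing.
#' @param censor_time right-censoring / end-of-follow-up time `C`; must be at
#'   least the last path entry time and at least the last measurement time.
#' @param graph optional `transition_graph`; when supplied, consecutive path
#'   states are checked to be permitted transitions.
#' @return A `subject_record` object.
#' @export
subject_record <- function(id, obs_times, obs_values, w = numeric(0),
                           path, censor_time, graph = NULL) {
  obs_times <- as.numeric(obs_times)
  obs_values <- as.numeric(obs_values)
  if (length(obs_times) != length(obs_values)) {
    stop("obs_times and obs_values must be parallel", call. = FALSE)
  }
  if (length(obs_times) == 0L) {
    stop("subject ", id, " has no longitudinal measurements; at least one is required",
         call. = FALSE)
  }
  if (is.unsorted(obs_times, strictly = TRUE)) {
    stop("obs_times must be strictly increasing", call. = FALSE)
  }
  path <- as.matrix(path)
  if (ncol(path) != 2L) stop("path must have columns (state, entry_time)", call. = FALSE)
  colnames(path) <- c("state", "entry_time")
  if (path[1, 2] != 0) stop("path must start at time 0", call. = FALSE)
  if (nrow(path) > 1L && is.unsorted(path[, 2], strictly = TRUE)) {
    stop("path entry times must be strictly increasing", call. = FALSE)
  }
  censor_time <- as.numeric(censor_time)
  if (censor_time < path[nrow(path), 2]) {
    stop("censor_time precedes the last transition", call. = FALSE)
  }
  if (!is.null(graph)) {
    if (nrow(path) > 1L) {
      key <- paste(graph$transitions[, 1], graph$transitions[, 2])
      steps <- paste(path[-nrow(path), 1], path[-1, 1])
      if (!all(steps %in% key)) {
        stop("subject ", id, ": observed path uses a transition not permitted by the graph",
             call. = FALSE)
      }
    }
    # follow-up effectively ends on entering an absorbing state; normalize so
    # that records round-trip through the counting-process file format
    if (path[nrow(path), 1] %in% absorbing_states(graph)) {
      censor_time <- unname(path[nrow(path), 2])
    }
  }
  if (any(obs_times > censor_time)) {
    stop("measurement after the censoring time", call. = FALSE)
  }
  structure(
    list(
      id = id, obs_times = obs_times, obs_values = obs_values,
      w = w, path = path, censor_time = censor_time
    ),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "Subject %s: %d measurements, path %s, C = %.3g\n",
    as.character(x$id), length(x$obs_times),
    paste(x$path[, 1], collapse = "->"), x$censor_time
  ))
  invisible(x)
}

#' Bundle subject records with their graph
#'
#' @param subjects list of `subject_record`s.
#' @param graph the `transition_graph` against which the paths are valid.
#' @return A `joint_data` object (list with `subjects`, `graph`).
#' @export
joint_data <- function(subjects, graph) {
  stopifnot(inherits(graph, "transition_graph"))
  if (!all(vapply(subjects, inherits, TRUE, "subject_record"))) {
    stop("subjects must be a list of subject_record objects", call. = FALSE)
  }
  structure(list(subjects = subjects, graph = graph), class = "joint_data")
}

#' @export
print.joint_data <- function(x, ...) {
  n <- length(x$subjects)
  nobs <- sum(vapply(x$subjects, function(s) length(s$obs_times), 1L))
  ntr <- sum(vapply(x$subjects, function(s) nrow(s$path) - 1L, 1L))
  cat(sprintf(
    "Joint dataset: %d subjects, %d measurements, %d observed transitions\n",
    n, nobs, ntr
  ))
  print(x$graph)
  invisible(x)
}

#' Read joint data from long-format CSV files
#'
#' The longitudinal file has columns `id,time,value` plus any covariate
#' columns; covariates must be constant within subject. The event file is in
#' counting-process long format with columns `id,from,to,tstart,tstop,status`:
#' one row per at-risk transition interval, `status = 1` on the realized
#' transition. A subject's path is reconstructed from the `status = 1` rows;
#' the censoring time is the largest `tstop`.
#'
#' @param longitudinal_file,event_file CSV paths.
#' @param graph `transition_graph` used to check the reconstructed paths.
#' @return A `joint_data` object.
#' @export
read_joint_data <- function(longitudinal_file, event_file, graph) {
  long <- utils::read.csv(longitudinal_file)
  ev <- utils::read.csv(event_file)
  need_long <- c("id", "time", "value")
  need_ev <- c("id", "from", "to", "tstart", "tstop", "status")
  if (!all(need_long %in% names(long))) {
    stop("longitudinal file must have columns id,time,value", call. = FALSE)
  }
  if (!all(need_ev %in% names(ev))) {
    stop("event file must have columns id,from,to,tstart,tstop,status", call. = FALSE)
  }
  covar_cols <- setdiff(names(long), need_long)
  ids <- unique(ev$id)
  subjects <- lapply(ids, function(i) {
    li <- long[long$id == i, , drop = FALSE]
    li <- li[order(li$time), , drop = FALSE]
    ei <- ev[ev$id == i, , drop = FALSE]
    ei <- ei[order(ei$tstart, ei$to), , drop = FALSE]
    w <- numeric(0)
    if (length(covar_cols) > 0L) {
      if (nrow(li) > 0L) {
        wmat <- unique(li[covar_cols])
        if (nrow(wmat) != 1L) {
          stop("subject ", i, ": covariates vary within subject", call. = FALSE)
        }
        w <- unlist(wmat[1, , drop = TRUE])
        names(w) <- covar_cols
      }
    }
    hits <- ei[ei$status == 1, , drop = FALSE]
    hits <- hits[order(hits$tstop), , drop = FALSE]
    start_state <- ei$from[which.min(ei$tstart)]
    path <- rbind(
      c(start_state, 0),
      if (nrow(hits) > 0L) cbind(hits$to, hits$tstop)
    )
    censor_time <- max(ei$tstop)
    subject_record(
      id = i, obs_times = li$time, obs_values = li$value, w = w,
      path = path, censor_time = censor_time, graph = graph
    )
  })
  joint_data(subjects, graph)
}

#' Write joint data as long-format CSV files
#'
#' Emits the same two-file format read by [read_joint_data()]: the
#' longitudinal file (`id,time,value,<covariates>`) and the event file in
#' counting-process long format with one row per transition at risk during
#' each sojourn interval.
#'
#' @param data a `joint_data` object.
#' @param longitudinal_file,event_file output CSV paths.
#' @export
write_joint_data <- function(data, longitudinal_file, event_file) {
  subjects <- data$subjects
  tr <- data$graph$transitions
  long <- do.call(rbind, lapply(subjects, function(s) {
    d <- data.frame(id = s$id, time = s$obs_times, value = s$obs_values)
    for (nm in names(s$w)) d[[nm]] <- s$w[[nm]]
    d
  }))
  ev <- do.call(rbind, lapply(subjects, function(s) {
    iv <- sojourn_intervals(s)
    do.call(rbind, lapply(seq_len(nrow(iv)), function(l) {
      from <- iv$state[l]
      outs <- tr[tr[, 1] == from, 2]
      if (length(outs) == 0L) return(NULL)
      data.frame(
        id = s$id, from = from, to = outs,
        tstart = iv$start[l], tstop = iv$stop[l],
        status = as.integer(!is.na(iv$next_state[l]) & outs == iv$next_state[l])
      )
    }))
  }))
  utils::write.csv(long, longitudinal_file, row.names = FALSE)
  utils::write.csv(ev, event_file, row.names = FALSE)
  invisible(list(longitudinal = longitudinal_file, event = event_file))
}

# Sojourn intervals of a subject: one row per occupied non-absorbing interval,
# with the interval bounds and the state transitioned to (NA when censored).
sojourn_intervals <- function(subject) {
  path <- subject$path
  n <- nrow(path)
  starts <- path[, 2]
  stops <- c(if (n > 1) path[-1, 2], subject$censor_time)
  nxt <- c(if (n > 1) path[-1, 1], NA_integer_)
  out <- data.frame(
    state = path[, 1], start = starts, stop = stops, next_state = nxt
  )
  # the final row is the absorbing state (zero-length exposure) when the
  # subject was absorbed exactly at censor time bookkeeping; drop rows with
  # no exposure
  out[out$stop > out$start | !is.na(out$next_state), , drop = FALSE]
}

#' Longitudinal data-assignment strategy for a block
#'
#' `historical` uses every measurement taken up to the subject's exit from
#' the block (from study start); `concurrent` uses only measurements taken
#' during the time spent in the block, falling back to the historical set for
#' subjects with no in-block measurement.
#'
#' @param mode `"historical"` or `"concurrent"`.
#' @return A `longitudinal_strategy` object.
#' @export
longitudinal_strategy <- function(mode = c("historical", "concurrent")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "longitudinal_strategy")
}

#' Build the dataset conditioning one competing-risk block
#'
#' Members are the subjects whose path visits the block's initial state. Each
#' member's event view runs from their entry into that state to the earlier
#' of their next transition out of it and their censoring time; the event
#' target is the state transitioned to, or censored. The longitudinal index
#' set follows `strategy`: historical keeps all measurement indices `j` with
#' `t_ij <= exit`; concurrent keeps `entry < t_ij <= exit` (a measurement at
#' exactly the entry time belongs to the state being exited), falling back to
#' the historical set when empty.
#'
#' @param data a `joint_data` object.
#' @param block a `competing_risk_block` from the same graph.
#' @param strategy a [longitudinal_strategy()] (default historical).
#' @param entry_adjusted character vector of covariate names to which the
#'   block entry time is added (e.g. age measured at study entry becoming age
#'   at entry to the current state), after scaling by `entry_scale`.
#' @param entry_scale divisor applied to the entry time before adding it to
#'   `entry_adjusted` covariates (e.g. 10 for age in decades with time in
#'   years).
#' @return A `block_dataset`: fields `block`, `members` (subject indices into
#'   `data$subjects`), `entry`, `exit`, `event_target` (integer or NA for
#'   censored), `long_index` (list of measurement index vectors), `W`
#'   (covariate matrix, entry-adjusted where requested), `strategy`.
#' @export
build_block_dataset <- function(data, block,
                                strategy = longitudinal_strategy("historical"),
                                entry_adjusted = character(0),
                                entry_scale = 1) {
  stopifnot(inherits(data, "joint_data"), inherits(block, "competing_risk_block"))
  tr <- data$graph$transitions
  block_tr <- tr[tr[, 1] == block$initial_state, 2]
  if (!setequal(block_tr, block$terminal_states)) {
    stop("block does not match the dataset's graph", call. = FALSE)
  }
  subjects <- data$subjects
  members <- integer(0); entry <- numeric(0); exit <- numeric(0)
  target <- integer(0); long_index <- list(); Wl <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    pos <- match(block$initial_state, s$path[, 1])
    if (is.na(pos)) next
    ent <- unname(s$path[pos, 2])
    if (pos < nrow(s$path)) {
      ext <- unname(s$path[pos + 1, 2])
      tgt <- unname(as.integer(s$path[pos + 1, 1]))
    } else {
      ext <- s$censor_time
      tgt <- NA_integer_
    }
    if (ext <= ent) next # zero exposure (absorbed/censored instantly)
    hist_idx <- which(s$obs_times <= ext)
    idx <- if (strategy$mode == "concurrent") {
      conc <- which(s$obs_times > ent & s$obs_times <= ext)
      if (length(conc) > 0L) conc else hist_idx
    } else {
      hist_idx
    }
    if (length(idx) == 0L) next # no usable longitudinal data for this block
    members <- c(members, i); entry <- c(entry, ent); exit <- c(exit, ext)
    target <- c(target, tgt); long_index <- c(long_index, list(idx))
    w <- s$w
    if (length(entry_adjusted) > 0L) {
      w[entry_adjusted] <- w[entry_adjusted] + ent / entry_scale
    }
    Wl <- c(Wl, list(w))
  }
  W <- if (length(Wl) > 0L) do.call(rbind, Wl) else matrix(0, 0, 0)
  structure(
    list(
      block = block, members = members, entry = entry, exit = exit,
      event_target = target, long_index = long_index, W = W,
      strategy = strategy, data = data
    ),
    class = "block_dataset"
  )
}

#' @export
print.block_dataset <- function(x, ...) {
  nev <- sum(!is.na(x$event_target))
  cat(sprintf(
    "Block dataset %d -> {%s}: %d subjects at risk, %d events, strategy %s\n",
    x$block$initial_state,
    paste(x$block$terminal_states, collapse = ","),
    length(x$members), nev, x$strategy$mode
  ))
  invisible(x)
}

#' Single-transition view of a competing-risk block dataset
#'
#' Identical members, exposure intervals and longitudinal index sets; the
#' event indicator is 1 only for subjects whose realized target equals
#' `target_state` — subjects who transition to a competing state or are
#' censored are both treated as censored at the same exit time.
#'
#' @param block_dataset a `block_dataset` built by [build_block_dataset()].
#' @param target_state one of the block's terminal states.
#' @return A `block_dataset` whose `block` is a `transition_block` and whose
#'   `event` field is the 0/1 indicator for the target transition.
#' @export
single_transition_view <- function(block_dataset, target_state) {
  b <- block_dataset$block
  if (!inherits(b, "competing_risk_block")) {
    stop("single_transition_view expects a competing-risk block dataset", call. = FALSE)
  }
  if (!(target_state %in% b$terminal_states)) {
    stop("target_state ", target_state, " is not a terminal state of the block",
         call. = FALSE)
  }
  out <- block_dataset
  out$block <- structure(
    list(from_state = b$initial_state, to_state = as.integer(target_state)),
    class = "transition_block"
  )
  out$event <- as.integer(!is.na(block_dataset$event_target) &
                            block_dataset$event_target == target_state)
  out
}
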