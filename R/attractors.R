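# State-transition-graph and attractor analysis.
#
# Under deterministic synchronous updates with a fixed input level, every
# state has exactly one successor, so the state space is a functional graph:
# each connected component contains exactly one terminal cycle (an attractor;
# length 1 = fixed point) and every state has a unique path into it.

cs_state_keys <- function(M) {
  apply(M, 1, paste, collapse = ",")
}

#' Build the synchronous state-transition graph
#'
#' Enumerates every level-state at a fixed injury level and records its
#' unique synchronous successor.
#'
#' @param model A `cs_model` whose inputs are covered by `fixed`.
#' @param injury Level for the input variable `I` (other inputs, if any, can
#'   be supplied through `fixed`).
#' @param fixed Optional named levels for input variables; defaults to
#'   `list(I = injury)`.
#' @return An object of class `cs_stg`: list with `states` (level matrix),
#'   `succ` (integer vector of successor row indices) and `fixed`.
#' @export
build_stg <- function(model, injury = NULL, fixed = NULL) {
  if (is.null(fixed)) {
    fixed <- stats::setNames(as.list(as.integer(injury)),
                             cs_input_vars(model))
  }
  states <- enumerate_initial_states(model, fixed)
  nxt <- cs_step_matrix(model, states, clamps = NULL)
  idx <- match(cs_state_keys(nxt), cs_state_keys(states))
  if (anyNA(idx)) stop("successor outside enumerated space", call. = FALSE)
  structure(list(states = states, succ = idx, fixed = fixed),
            class = "cs_stg")
}

#' Enumerate attractors of a state-transition graph
#'
#' @param stg A `cs_stg` from [build_stg()].
#' @return List of attractors sorted by basin size (descending), each a list
#'   with `states` (matrix of cycle states in transition order), `length`
#'   and `basin` (number of states, including the cycle, that reach it).
#' @export
attractors <- function(stg) {
  succ <- stg$succ
  n <- length(succ)
  # color: 0 unvisited, 1 on current walk, 2 done
  color <- integer(n)
  on_cycle <- logical(n)
  comp <- integer(n)  # attractor id per state
  atts <- list()
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- succ[v]
    }
    if (color[v] == 1L) {
      # new cycle discovered along this walk
      cyc_start <- match(v, path)
      cyc <- path[cyc_start:length(path)]
      on_cycle[cyc] <- TRUE
      aid <- length(atts) + 1L
      atts[[aid]] <- cyc
      comp[path] <- aid
    } else {
      comp[path] <- comp[v]
    }
    color[path] <- 2L
  }
  basin <- tabulate(comp, nbins = length(atts))
  out <- lapply(seq_along(atts), function(a) {
    cyc <- atts[[a]]
    list(states = stg$states[cyc, , drop = FALSE],
         length = length(cyc), basin = basin[[a]])
  })
  out[order(-basin)]
}

#' Steps until each initial state first enters its attractor
#'
#' Exact step counts computed by memoized walking of the successor map: a
#' state already on its attractor has time 0, otherwise time is one more
#' than its successor's.
#'
#' @param model A `cs_model` (used when `stg` is not supplied).
#' @param injury Injury level (as in [build_stg()]).
#' @param stg Optionally a prebuilt `cs_stg`.
#' @return Data frame with one row per initial state: the state levels plus
#'   `time` (integer steps).
#' @export
time_to_attractor <- function(model, injury = NULL, stg = NULL) {
  if (is.null(stg)) stg <- build_stg(model, injury)
  succ <- stg$succ
  n <- length(succ)
  on_cycle <- logical(n)
  for (a in cs_cycle_indices(stg)) on_cycle[a] <- TRUE
  time <- rep(NA_integer_, n)
  time[on_cycle] <- 0L
  for (s in seq_len(n)) {
    if (!is.na(time[s])) next
    path <- integer(0)
    v <- s
    while (is.na(time[v])) {
      path <- c(path, v)
      v <- succ[v]
    }
    base <- time[v]
    time[rev(path)] <- base + seq_along(path)
  }
  out <- as.data.frame(stg$states)
  out$time <- time
  out
}

cs_cycle_indices <- function(stg) {
  succ <- stg$succ
  n <- length(succ)
  color <- integer(n)
  cyc <- integer(0)
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- succ[v]
    }
    if (color[v] == 1L) cyc <- c(cyc, path[match(v, path):length(path)])
    color[path] <- 2L
  }
  cyc
}

#' Pseudo-Kaplan-Meier curve of time to steady state
#'
#' Fraction of initial states that have not yet entered their attractor as a
#' function of the time step, weighting every initial state equally.
#'
#' @param table Data frame from [time_to_attractor()] (needs a `time`
#'   column), or a bare integer vector of times.
#' @return Data frame with columns `step` and `surviving` (fraction with
#'   time-to-attractor strictly greater than `step`); non-increasing and 0 at
#'   the maximum time.
#' @export
km_curve <- function(table) {
  times <- if (is.data.frame(table)) table$time else as.integer(table)
  if (length(times) == 0) stop("empty time-to-attractor table", call. = FALSE)
  steps <- 0:max(times)
  surviving <- vapply(steps, function(t) mean(times > t), numeric(1))
  data.frame(step = steps, surviving = surviving)
}

#' Export a state-transition graph as an edge list
#'
#' @param stg A `cs_stg`.
#' @param path Optional CSV path.
#' @return Data frame with `from` / `to` columns (states serialized as
#'   comma-separated level tuples in variable declaration order).
#' @export
stg_edgelist <- function(stg, path = NULL) {
  keys <- cs_state_keys(stg$states)
  df <- data.frame(from = keys, to = keys[stg$succ],
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
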