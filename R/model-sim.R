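# Simulation engine: synchronous updates on integer level-states.
#
# A level-state is a named integer vector (one level per variable); ensembles
# are integer matrices with one row per state and one column per variable.
# Rule expressions are evaluated in an environment that exposes, for every
# variable, its level under its own name plus (for three-level variables) the
# `_low` / `_high` bits, so both bit literals and level comparisons work.

cs_check_state <- function(model, state) {
  nm <- model$vars$name
  missing <- setdiff(nm, names(state))
  if (length(missing) > 0) {
    stop(sprintf("state is missing variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lv <- as.integer(state[nm])
  bad <- which(lv < 0L | lv > model$vars$arity - 1L | is.na(lv))
  if (length(bad) > 0) {
    stop(sprintf("level out of range for variable(s): %s",
                 paste(nm[bad], collapse = ", ")), call. = FALSE)
  }
  stats::setNames(lv, nm)
}

#' Encode a level-state into low/high bits
#'
#' Three-level variables are represented by two binary variables: level 0 is
#' (low = 0, high = 0), level 1 is canonically (low = 1, high = 0) and level 2
#' is (low = 1, high = 1).  Two-level variables map to a single bit.
#'
#' @param state Named integer vector of levels.
#' @param model A `cs_model`.
#' @return Named integer vector of bits.
#' @seealso [decode_state()] for the inverse (which accepts the
#'   non-canonical (0, 1) encoding of level 1 as well, since the level is
#'   defined as the sum of the two bits).
#' @export
encode_state <- function(state, model) {
  lv <- cs_check_state(model, state)
  bits <- integer(0)
  for (i in seq_len(nrow(model$vars))) {
    nm <- model$vars$name[i]
    if (model$vars$arity[i] == 2L) {
      bits[[nm]] <- lv[[nm]]
    } else {
      bits[[paste0(nm, "_low")]] <- as.integer(lv[[nm]] >= 1L)
      bits[[paste0(nm, "_high")]] <- as.integer(lv[[nm]] == 2L)
    }
  }
  bits
}

#' Decode a bit-state back to levels
#'
#' The level of a three-level variable is the sum of its two bits, so the
#' non-canonical bit pattern (low = 0, high = 1) also decodes to level 1.
#'
#' @param bits Named integer vector of bits.
#' @param model A `cs_model`.
#' @return Named integer vector of levels.
#' @export
decode_state <- function(bits, model) {
  out <- integer(0)
  for (i in seq_len(nrow(model$vars))) {
    nm <- model$vars$name[i]
    if (model$vars$arity[i] == 2L) {
      out[[nm]] <- as.integer(bits[[nm]])
    } else {
      out[[nm]] <- as.integer(bits[[paste0(nm, "_low")]]) +
        as.integer(bits[[paste0(nm, "_high")]])
    }
  }
  cs_check_state(model, out)
}

# Evaluation environment for a level matrix (n states x variables).
cs_eval_env <- function(model, L) {
  env <- vector("list", 0)
  for (i in seq_len(nrow(model$vars))) {
    nm <- model$vars$name[i]
    col <- L[, nm]
    env[[nm]] <- col
    if (model$vars$arity[i] == 3L) {
      env[[paste0(nm, "_low")]] <- as.integer(col >= 1L)
      env[[paste0(nm, "_high")]] <- as.integer(col == 2L)
    }
  }
  env
}

cs_check_clamps <- function(model, clamps) {
  if (is.null(clamps) || length(clamps) == 0) return(invisible(NULL))
  unknown <- setdiff(names(clamps), model$vars$name)
  if (length(unknown) > 0) {
    stop(sprintf("clamp for undeclared variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(clamps)) {
    ar <- cs_arity(model, nm)
    if (any(clamps[[nm]] < 0L | clamps[[nm]] > ar - 1L)) {
      stop(sprintf("clamp level out of range for '%s'", nm), call. = FALSE)
    }
  }
  invisible(NULL)
}

# One synchronous step applied to every row of a level matrix.  `clamps` is a
# named list of scalar levels applied to the *output* state; input variables
# keep their previous level unless clamped.
cs_step_matrix <- function(model, L, clamps = NULL) {
  env <- cs_eval_env(model, L)
  n <- nrow(L)
  out <- L
  for (i in seq_len(nrow(model$vars))) {
    nm <- model$vars$name[i]
    if (!is.null(clamps) && nm %in% names(clamps)) {
      out[, nm] <- as.integer(clamps[[nm]])
      next
    }
    if (model$vars$role[i] == "input") next  # inputs persist
    if (model$vars$arity[i] == 2L) {
      v <- eval(model$rules[[nm]], env)
      out[, nm] <- as.integer(rep_len(as.logical(v), n))
    } else {
      lo <- as.integer(rep_len(as.logical(
        eval(model$rules[[paste0(nm, "_low")]], env)), n))
      hi <- as.integer(rep_len(as.logical(
        eval(model$rules[[paste0(nm, "_high")]], env)), n))
      out[, nm] <- lo + hi
    }
  }
  out
}

#' Apply one synchronous update
#'
#' Every non-input, non-clamped bit simultaneously takes the value of its rule
#' evaluated on the *previous* state; input and clamped variables take their
#' fixed level.
#'
#' @param model A `cs_model`.
#' @param state Named integer vector of levels.
#' @param clamps Optional named list/vector of levels to clamp.
#' @return The successor level-state.
#' @export
step_state <- function(model, state, clamps = NULL) {
  lv <- cs_check_state(model, state)
  cs_check_clamps(model, clamps)
  L <- matrix(lv, nrow = 1, dimnames = list(NULL, names(lv)))
  out <- cs_step_matrix(model, L, clamps)
  stats::setNames(as.integer(out[1, ]), colnames(out))
}

# Normalize a clamp schedule: named list whose elements are either a scalar
# (constant across steps) or a vector of length `steps + 1` giving the level
# at steps 0..steps.
cs_clamp_at <- function(clamps, step_index, steps) {
  if (is.null(clamps) || length(clamps) == 0) return(NULL)
  out <- list()
  for (nm in names(clamps)) {
    v <- clamps[[nm]]
    if (length(v) == 1L) {
      out[[nm]] <- as.integer(v)
    } else {
      if (length(v) < steps + 1L) {
        stop(sprintf("clamp schedule for '%s' is shorter than the simulation (%d < %d)",
                     nm, length(v), steps + 1L), call. = FALSE)
      }
      out[[nm]] <- as.integer(v[[step_index + 1L]])
    }
  }
  out
}

#' Simulate a trajectory of synchronous updates
#'
#' @param model A `cs_model`.
#' @param init Named integer vector: the state at step 0.
#' @param steps Number of synchronous updates (>= 0).
#' @param clamps Optional named list: each element a scalar level held fixed
#'   for the whole run (applied at step 0 as well), or a vector of length
#'   `steps + 1` giving a per-step clamp schedule.
#' @param stop_at_fixpoint If `TRUE`, once two consecutive states are equal
#'   (and all clamps are constant) the trailing rows repeat the fixed point
#'   without further rule evaluation.
#' @return Integer matrix of class `cs_trajectory` with `steps + 1` rows
#'   (step 0 first) and one column per variable.
#' @export
simulate_model <- function(model, init, steps, clamps = NULL,
                           stop_at_fixpoint = FALSE) {
  stopifnot(steps >= 0)
  cs_check_clamps(model, clamps)
  lv <- cs_check_state(model, init)
  c0 <- cs_clamp_at(clamps, 0L, steps)
  for (nm in names(c0)) lv[[nm]] <- c0[[nm]]
  traj <- matrix(NA_integer_, nrow = steps + 1L, ncol = length(lv),
                 dimnames = list(as.character(0:steps), names(lv)))
  traj[1, ] <- lv
  constant_clamps <- is.null(clamps) ||
    all(vapply(clamps, function(v) length(v) == 1L, logical(1)))
  if (steps > 0) {
    cur <- matrix(lv, nrow = 1, dimnames = list(NULL, names(lv)))
    for (t in seq_len(steps)) {
      ct <- cs_clamp_at(clamps, t, steps)
      nxt <- cs_step_matrix(model, cur, ct)
      traj[t + 1L, ] <- nxt[1, ]
      if (stop_at_fixpoint && constant_clamps && all(nxt == cur) && t < steps) {
        traj[(t + 2L):(steps + 1L), ] <- matrix(nxt[1, ], nrow = steps - t,
                                                ncol = ncol(nxt), byrow = TRUE)
        break
      }
      cur <- nxt
    }
  }
  structure(traj, class = c("cs_trajectory", class(traj)))
}

#' Simulate a whole ensemble of initial states at once
#'
#' Vectorized companion of [simulate_model()]: all rows advance through the
#' same clamp schedule simultaneously.
#'
#' @param model A `cs_model`.
#' @param inits Integer matrix of initial states (rows) by variables (columns).
#' @param steps Number of synchronous updates.
#' @param clamps As in [simulate_model()].
#' @return A list of `steps + 1` level matrices, one per step.
#' @export
simulate_ensemble <- function(model, inits, steps, clamps = NULL) {
  stopifnot(steps >= 0, is.matrix(inits))
  cs_check_clamps(model, clamps)
  inits <- inits[, model$vars$name, drop = FALSE]
  c0 <- cs_clamp_at(clamps, 0L, steps)
  for (nm in names(c0)) inits[, nm] <- c0[[nm]]
  out <- vector("list", steps + 1L)
  out[[1]] <- inits
  cur <- inits
  for (t in seq_len(steps)) {
    cur <- cs_step_matrix(model, cur, cs_clamp_at(clamps, t, steps))
    out[[t + 1L]] <- cur
  }
  names(out) <- as.character(0:steps)
  out
}

#' Enumerate all initial level-states
#'
#' Exhaustive, duplicate-free Cartesian product over the levels of all
#' non-input variables, in deterministic lexicographic order (the first
#' declared variable varies slowest).  Input variables are fixed at the
#' supplied levels.
#'
#' @param model A `cs_model`.
#' @param fixed Named vector/list of levels covering every input variable.
#' @return Integer matrix, one row per state, columns in declaration order.
#' @export
enumerate_initial_states <- function(model, fixed = NULL) {
  inputs <- cs_input_vars(model)
  missing <- setdiff(inputs, names(fixed))
  if (length(missing) > 0) {
    stop(sprintf("fixed levels required for input variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  internal <- cs_internal_vars(model)
  lev <- lapply(internal, function(nm) 0:(cs_arity(model, nm) - 1L))
  names(lev) <- internal
  # first declared variable most significant: reverse for expand.grid
  grid <- do.call(expand.grid, c(rev(lev), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, internal, drop = FALSE]
  M <- matrix(NA_integer_, nrow = nrow(grid), ncol = nrow(model$vars),
              dimnames = list(NULL, model$vars$name))
  for (nm in internal) M[, nm] <- as.integer(grid[[nm]])
  for (nm in inputs) M[, nm] <- as.integer(fixed[[nm]])
  cs_check_clamps(model, as.list(stats::setNames(
    as.integer(fixed[inputs]), inputs)))
  M
}

#' Per-step mean and standard error over an ensemble of trajectories
#'
#' @param trajectories Either a list of `cs_trajectory` matrices of equal
#'   length, or the per-step list returned by [simulate_ensemble()].
#' @return A list with matrices `mean` and `se` (steps x variables) and the
#'   ensemble size `n`.  The standard error is sd / sqrt(n) and is zero when
#'   all members agree.
#' @export
ensemble_summary <- function(trajectories) {
  if (length(trajectories) == 0) stop("empty ensemble", call. = FALSE)
  if (is.matrix(trajectories[[1]]) &&
      !inherits(trajectories[[1]], "cs_trajectory") &&
      !is.null(names(trajectories)) &&
      identical(names(trajectories)[1], "0")) {
    # simulate_ensemble output: list of per-step level matrices
    steps <- length(trajectories)
    vars <- colnames(trajectories[[1]])
    n <- nrow(trajectories[[1]])
    mn <- se <- matrix(NA_real_, nrow = steps, ncol = length(vars),
                       dimnames = list(names(trajectories), vars))
    for (t in seq_len(steps)) {
      M <- trajectories[[t]]
      mn[t, ] <- colMeans(M)
      se[t, ] <- apply(M, 2, stats::sd) / sqrt(n)
    }
    return(list(mean = mn, se = se, n = n))
  }
  lens <- vapply(trajectories, nrow, integer(1))
  if (length(unique(lens)) != 1) {
    stop("trajectories have mismatched lengths", call. = FALSE)
  }
  vars <- colnames(trajectories[[1]])
  n <- length(trajectories)
  arr <- array(unlist(trajectories),
               dim = c(lens[1], length(vars), n),
               dimnames = list(rownames(trajectories[[1]]), vars, NULL))
  mn <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(n)
  list(mean = mn, se = se, n = n)
}

#' Write a trajectory as long-format CSV
#'
#' @param traj A `cs_trajectory`.
#' @param path Output CSV path (columns step, variable, level).
#' @return The long-format data frame, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(
    step = rep(as.integer(rownames(traj)), times = ncol(traj)),
    variable = rep(colnames(traj), each = nrow(traj)),
    level = as.integer(traj),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
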