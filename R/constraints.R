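# Behavioral constraint suite for the chemokine switch.
#
# Each constraint transcribes one qualitative dynamic claim about the switch
# into an executable predicate decided by exhaustive simulation of the finite
# state space.  The suite, not any particular ruleset, is the specification
# of record: any candidate ruleset can be checked against it.

cs_switch_vars <- c("I", "X", "MIG", "MCP1", "IP10", "IL6")

# Shared exhaustive dynamics for one model: per injury level, the enumerated
# ensemble trajectory (as a per-step list of level matrices), the successor
# map, attractors and time-to-attractor; plus zero-init trajectories.
cs_switch_dynamics <- function(model, steps = 20L, zero_steps = 12L) {
  dyn <- list(steps = steps)
  for (inj in c(1L, 2L)) {
    states <- enumerate_initial_states(model, fixed = list(I = inj))
    ens <- simulate_ensemble(model, states, steps)
    stg <- structure(list(
      states = states,
      succ = match(cs_state_keys(ens[[2]]), cs_state_keys(states)),
      fixed = list(I = inj)), class = "cs_stg")
    atts <- attractors(stg)
    tta <- time_to_attractor(model, stg = stg)
    dyn[[as.character(inj)]] <- list(states = states, ens = ens,
                                     stg = stg, attractors = atts,
                                     times = tta$time)
  }
  dyn$zero <- lapply(stats::setNames(0:2, 0:2), function(inj) {
    simulate_model(model, zero_state(model, inj), zero_steps)
  })
  dyn
}

cs_first_at <- function(traj, var, level) {
  hit <- which(traj[, var] == level)
  if (length(hit) == 0) NA_integer_ else as.integer(rownames(traj))[hit[1]]
}

# does IP10 reach level 2 and hold it through `through`?
cs_reaches_and_holds <- function(traj, var, level, through) {
  steps <- as.integer(rownames(traj))
  keep <- steps <= through
  v <- traj[keep, var]
  first <- which(v == level)
  length(first) > 0 && all(v[first[1]:length(v)] == level)
}

cs_ens_levels <- function(ens, var) {
  # states x steps matrix of one variable's level across the ensemble
  vapply(ens, function(M) M[, var], numeric(nrow(ens[[1]])))
}

#' Behavioral constraint suite for the chemokine switch
#'
#' Returns the machine-checkable constraints encoding the switch's required
#' qualitative dynamics (B1-B10) plus two soft, reported-only checks
#' (B11-B12).  Every predicate is decided by exhaustive simulation over the
#' 108 initial mediator states at fixed injury severity.
#'
#' @return List of constraints; each has `id`, `description`, `anchor` (the
#'   behavioral claim the constraint encodes), `severity` (`"required"` or
#'   `"soft"`) and `predicate` (a function of the model and precomputed
#'   dynamics returning `list(pass, counterexample)`).
#' @export
constraint_suite <- function() {
  mk <- function(id, description, anchor, severity, predicate) {
    list(id = id, description = description, anchor = anchor,
         severity = severity, predicate = predicate)
  }
  list(
    mk("B1", "all-zero state is a fixed point under mild injury",
       "with every element initialized to zero and mild injury, all variables remain at zero",
       "required",
       function(model, dyn) {
         z <- zero_state(model, 0L)
         ok <- all(step_state(model, z) == z)
         list(pass = ok, counterexample = if (!ok) step_state(model, z))
       }),
    mk("B2", "moderate injury from rest: IP-10 saturates, others stay at zero",
       "under moderate injury from a resting start IP-10 rises to its highest level while MIG, MCP-1 and IL-6 remain at zero",
       "required",
       function(model, dyn) {
         tr <- dyn$zero[["1"]]
         ok <- cs_reaches_and_holds(tr, "IP10", 2L, max(as.integer(rownames(tr)))) &&
           all(tr[, c("MIG", "MCP1", "IL6")] == 0L)
         list(pass = ok, counterexample = if (!ok) tr)
       }),
    mk("B3", "severe injury from rest: transient MCP-1 then IL-6 peaks, moderate steady state",
       "under severe injury from a resting start IP-10 saturates and MCP-1 and then IL-6 peak at their highest levels before settling at a moderate level",
       "required",
       function(model, dyn) {
         tr <- dyn$zero[["2"]]
         n <- nrow(tr)
         t_mcp <- cs_first_at(tr, "MCP1", 2L)
         t_il6 <- cs_first_at(tr, "IL6", 2L)
         ok <- !is.na(cs_first_at(tr, "IP10", 2L)) &&
           !is.na(t_mcp) && !is.na(t_il6) && t_mcp < t_il6 &&
           all(tr[n, ] == tr[n - 1, ]) &&
           tr[n, "MCP1"] == 1L && tr[n, "IL6"] == 1L
         list(pass = ok, counterexample = if (!ok) tr)
       }),
    mk("B4", "MCP-1 never reaches its high level under moderate injury",
       "over every initial state, moderate injury never drives MCP-1 to its highest level at any step after the start",
       "required",
       function(model, dyn) {
         lv <- cs_ens_levels(dyn[["1"]]$ens, "MCP1")[, -1, drop = FALSE]
         bad <- which(apply(lv == 2L, 1, any))
         list(pass = length(bad) == 0,
              counterexample = if (length(bad) > 0)
                dyn[["1"]]$states[bad[1], ])
       }),
    mk("B5", "MCP-1 stays at least moderate under severe injury",
       "under severe injury MCP-1 is at least at its moderate level at every step after the start, from every initial state",
       "required",
       function(model, dyn) {
         lv <- cs_ens_levels(dyn[["2"]]$ens, "MCP1")[, -1, drop = FALSE]
         bad <- which(apply(lv < 1L, 1, any))
         list(pass = length(bad) == 0,
              counterexample = if (length(bad) > 0)
                dyn[["2"]]$states[bad[1], ])
       }),
    mk("B6", "a single attractor per injury severity",
       "moderate and severe injury each have exactly one steady state irrespective of initial conditions",
       "required",
       function(model, dyn) {
         n1 <- length(dyn[["1"]]$attractors)
         n2 <- length(dyn[["2"]]$attractors)
         ce <- NULL
         if (n1 > 1) ce <- dyn[["1"]]$attractors[[2]]$states[1, ]
         if (n2 > 1) ce <- dyn[["2"]]$attractors[[2]]$states[1, ]
         list(pass = n1 == 1 && n2 == 1, counterexample = ce)
       }),
    mk("B7", "attractors are fixed points, not cycles",
       "every attractor under moderate and severe injury is a steady state of period one",
       "required",
       function(model, dyn) {
         lens <- c(vapply(dyn[["1"]]$attractors, `[[`, integer(1), "length"),
                   vapply(dyn[["2"]]$attractors, `[[`, integer(1), "length"))
         list(pass = all(lens == 1L),
              counterexample = if (any(lens != 1L)) lens)
       }),
    mk("B8", "the intermediate node X delays IP-10 induction",
       "with X present, IP-10 first saturates strictly later after injury than in the variant where injury drives IP-10 directly",
       "required",
       function(model, dyn) {
         nox <- cs_without_x_variant(model)
         ok <- TRUE
         ce <- NULL
         for (inj in c(1L, 2L)) {
           with_x <- cs_first_at(dyn$zero[[as.character(inj)]], "IP10", 2L)
           tr0 <- simulate_model(nox, zero_state(nox, inj), 12L)
           without <- cs_first_at(tr0, "IP10", 2L)
           if (is.na(with_x) || is.na(without) || !(with_x > without)) {
             ok <- FALSE
             ce <- c(injury = inj, with_x = with_x, without_x = without)
           }
         }
         list(pass = ok, counterexample = ce)
       }),
    mk("B9", "sustained X is required to hold IP-10 at its high level",
       "a one-step spike of X fails to bring IP-10 to its highest level and hold it through step 10 under moderate injury, whereas a sustained step of X does",
       "required",
       function(model, dyn) {
         z <- zero_state(model, 1L)
         spike <- simulate_model(model, z, 10L,
                                 clamps = list(I = 1L,
                                               X = clamp_profile("spike", 11L)))
         stepc <- simulate_model(model, z, 10L,
                                 clamps = list(I = 1L,
                                               X = clamp_profile("step", 11L)))
         spike_holds <- cs_reaches_and_holds(spike, "IP10", 2L, 10L)
         step_holds <- cs_reaches_and_holds(stepc, "IP10", 2L, 10L)
         list(pass = !spike_holds && step_holds,
              counterexample = if (spike_holds || !step_holds)
                list(spike = spike, step = stepc))
       }),
    mk("B10", "low initial MCP-1 separates moderate from severe injury",
       "starting from moderate MCP-1 alone, MCP-1 stays low and resolves under moderate injury but peaks high and settles at a moderate level under severe injury",
       "required",
       function(model, dyn) {
         init <- zero_state(model, 0L)
         init[["MCP1"]] <- 1L
         tr1 <- simulate_model(model, init, 12L, clamps = list(I = 1L))
         tr2 <- simulate_model(model, init, 12L, clamps = list(I = 2L))
         ok <- max(tr1[, "MCP1"]) == 1L && tr1[nrow(tr1), "MCP1"] == 0L &&
           max(tr2[, "MCP1"]) == 2L && tr2[nrow(tr2), "MCP1"] == 1L
         list(pass = ok, counterexample = if (!ok)
           list(moderate = tr1, severe = tr2))
       }),
    mk("B11", "ensemble-mean MIG decays after step 2 at either severity",
       "the ensemble-mean MIG trajectory is non-increasing after step 2 under both moderate and severe injury",
       "soft",
       function(model, dyn) {
         ok <- TRUE
         for (inj in c("1", "2")) {
           mn <- colMeans(cs_ens_levels(dyn[[inj]]$ens, "MIG"))
           tail_mn <- mn[-(1:2)]  # means at steps 2, 3, ...
           if (any(diff(tail_mn) > 1e-12)) ok <- FALSE
         }
         list(pass = ok, counterexample = NULL)
       }),
    mk("B12", "severe injury takes at least as long to settle",
       "the median time to reach the steady state over all initial states is at least as large for severe as for moderate injury",
       "soft",
       function(model, dyn) {
         m1 <- stats::median(dyn[["1"]]$times)
         m2 <- stats::median(dyn[["2"]]$times)
         list(pass = m2 >= m1, counterexample = c(moderate = m1, severe = m2))
       })
  )
}

#' Check a logical model against a constraint suite
#'
#' Evaluates every constraint predicate by exhaustive simulation of the
#' model's finite state space; deterministic.
#'
#' @param model A `cs_model` declaring the six switch variables
#'   (`I`, `X`, `MIG`, `MCP1`, `IP10`, `IL6`).
#' @param suite List of constraints, as from [constraint_suite()].
#' @param dynamics Optional precomputed [cs_switch_dynamics] (internal reuse).
#' @return Object of class `cs_constraint_report`: a data frame (`id`,
#'   `severity`, `description`, `pass`) with a `witness` attribute holding
#'   each failed constraint's counterexample.
#' @export
check_constraints <- function(model, suite = constraint_suite(),
                              dynamics = NULL) {
  stopifnot(inherits(model, "cs_model"))
  missing <- setdiff(cs_switch_vars, model$vars$name)
  if (length(missing) > 0) {
    stop(sprintf("model is missing switch variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(suite) == 0) {
    out <- data.frame(id = character(0), severity = character(0),
                      description = character(0), pass = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "witness") <- list()
    class(out) <- c("cs_constraint_report", class(out))
    return(out)
  }
  if (is.null(dynamics)) dynamics <- cs_switch_dynamics(model)
  rows <- lapply(suite, function(con) {
    res <- con$predicate(model, dynamics)
    list(id = con$id, severity = con$severity,
         description = con$description, pass = isTRUE(res$pass),
         counterexample = res$counterexample)
  })
  out <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    severity = vapply(rows, `[[`, character(1), "severity"),
    description = vapply(rows, `[[`, character(1), "description"),
    pass = vapply(rows, `[[`, logical(1), "pass"),
    stringsAsFactors = FALSE)
  wit <- lapply(rows, `[[`, "counterexample")
  names(wit) <- out$id
  attr(out, "witness") <- wit
  class(out) <- c("cs_constraint_report", class(out))
  out
}

#' @export
print.cs_constraint_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Constraint report: empty suite\n")
    return(invisible(x))
  }
  req <- x$severity == "required"
  cat(sprintf("Constraint report: %d/%d required passed, %d/%d soft passed\n",
              sum(x$pass[req]), sum(req),
              sum(x$pass[!req]), sum(!req)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-4s %s: %s\n",
                if (x$pass[i]) "ok" else "FAIL",
                x$id[i], x$severity[i], x$description[i]))
  }
  invisible(x)
}

#' Write a constraint report as CSV
#'
#' @param report A `cs_constraint_report`.
#' @param path Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_constraint_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report)[, c("id", "severity",
                                             "description", "pass")],
                   path, row.names = FALSE)
  invisible(report)
}
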