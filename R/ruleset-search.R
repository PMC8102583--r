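# Ruleset-space uncertainty search.
#
# The network topology (who regulates whom) is held fixed; the space permutes
# the free choices a logical encoding leaves open: the sign of every edge,
# the injury literal (at-least-moderate vs severe-only) for edges from the
# three-level injury input, and a per-target AND/OR combiner applied over the
# same-sign groups.  Rule shape: injury literals are never gated by mediator
# inhibition (injury acts upstream of the mediator cross-regulation), i.e.
#
#   target* = C( inj_act..., C(med_act...) and not C(inh...) )
#
# with C the target's combiner.  Every rule of the reference ruleset is
# expressible in this shape, so the reference model is a member of its own
# variant space.

#' Regulator topology of the chemokine switch
#'
#' The fixed regulator sets per target bit, as inferred for the switch motif
#' (chemokine self- and cross-regulation, injury inputs, the intermediate
#' node X, and IL-6 as output).
#'
#' @return Named list: for each target bit, a character vector of regulators
#'   (bit names, or the injury input `I`).
#' @export
switch_topology <- function() {
  list(
    X         = c("I"),
    IP10_low  = c("X", "IP10_high"),
    IP10_high = c("IP10_low", "MIG", "MCP1_low"),
    MIG       = c("MIG", "IP10_low"),
    MCP1_low  = c("I", "MCP1_low", "IP10_high"),
    MCP1_high = c("I", "MCP1_low", "IP10_high"),
    IL6_low   = c("MIG", "MCP1_low"),
    IL6_high  = c("IL6_low", "MCP1_low", "IP10_high")
  )
}

# Option table for one target: a data frame with one row per variant choice.
# `lit3` names the regulators that are three-level variables referenced by
# level comparison, which carry a free threshold literal (>= 1 vs == 2).
cs_target_options <- function(target, regulators, lit3 = character(0)) {
  per_edge <- lapply(seq_along(regulators), function(i) {
    if (regulators[i] %in% lit3) {
      c("act_ge1", "act_eq2", "inh_ge1", "inh_eq2")
    } else {
      c("act", "inh")
    }
  })
  names(per_edge) <- paste0("edge", seq_along(regulators))
  opts <- c(per_edge,
            if (length(regulators) >= 2) list(combiner = c("or", "and")))
  grid <- do.call(expand.grid,
                  c(rev(opts), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  if (!"combiner" %in% names(grid)) grid$combiner <- "or"
  grid
}

cs_build_variant_rule <- function(regulators, choices, lit3 = character(0),
                                  inputs = character(0)) {
  comb_op <- if (choices$combiner == "and") "&" else "|"
  combine <- function(exprs) Reduce(function(a, b) call(comb_op, a, b), exprs)
  lit <- function(reg, tag) {
    if (reg %in% lit3) {
      if (grepl("eq2$", tag)) call("==", as.name(reg), 2L)
      else call(">=", as.name(reg), 1L)
    } else {
      as.name(reg)
    }
  }
  inj_act <- list(); med_act <- list(); inh <- list()
  for (i in seq_along(regulators)) {
    tag <- choices[[paste0("edge", i)]]
    e <- lit(regulators[i], tag)
    if (grepl("^act", tag)) {
      if (regulators[i] %in% inputs) inj_act <- c(inj_act, list(e))
      else med_act <- c(med_act, list(e))
    } else {
      inh <- c(inh, list(e))
    }
  }
  core <- NULL
  if (length(med_act) > 0 && length(inh) > 0) {
    core <- call("&", combine(med_act), call("!", combine(inh)))
  } else if (length(med_act) > 0) {
    core <- combine(med_act)
  } else if (length(inh) > 0) {
    core <- call("!", combine(inh))
  }
  terms <- c(inj_act, if (!is.null(core)) list(core))
  if (length(terms) == 0) return(0L)
  combine(terms)
}

#' Variant space of logical rulesets over a fixed topology
#'
#' @param topology Named list of regulator sets per target bit (see
#'   [switch_topology()]).
#' @param base A `cs_model` providing the variable declarations and the rules
#'   of any target bits not being permuted.
#' @param free Character vector of target bits whose rules are permuted;
#'   defaults to all targets in the topology.
#' @return Object of class `cs_variant_space` with the per-target option
#'   tables, the total variant count `count` (closed-form product) and the
#'   base model.
#' @export
variant_space <- function(topology, base = reference_model(),
                          free = names(topology)) {
  stopifnot(all(free %in% names(topology)))
  for (tgt in names(topology)) {
    if (length(topology[[tgt]]) == 0) {
      stop(sprintf("empty regulator set for target '%s'", tgt), call. = FALSE)
    }
  }
  lit3 <- base$vars$name[base$vars$arity == 3L]
  inputs <- cs_input_vars(base)
  opts <- lapply(free, function(tgt)
    cs_target_options(tgt, topology[[tgt]], lit3))
  names(opts) <- free
  sizes <- vapply(opts, nrow, integer(1))
  # closed form: per target, combiner (if >=2 regulators) x per-edge options
  closed <- prod(vapply(free, function(tgt) {
    regs <- topology[[tgt]]
    per_edge <- ifelse(regs %in% lit3, 4, 2)
    prod(per_edge) * if (length(regs) >= 2) 2 else 1
  }, numeric(1)))
  stopifnot(closed == prod(as.numeric(sizes)))
  structure(list(topology = topology, base = base, free = free,
                 options = opts, sizes = sizes, count = closed,
                 lit3 = lit3, inputs = inputs),
            class = "cs_variant_space")
}

#' Materialize one variant of a ruleset space
#'
#' Decodes a variant id (1-based mixed-radix index over the free targets'
#' option tables, first free target most significant) into a full logical
#' model.
#'
#' @param space A `cs_variant_space`.
#' @param id Variant id in `1..space$count`.
#' @return A `cs_model`.
#' @export
variant_model <- function(space, id) {
  stopifnot(id >= 1, id <= space$count)
  idx <- cs_unrank(id, space$sizes)
  model <- space$base
  for (k in seq_along(space$free)) {
    tgt <- space$free[k]
    choices <- space$options[[tgt]][idx[k], , drop = FALSE]
    expr <- cs_build_variant_rule(space$topology[[tgt]], as.list(choices),
                                  space$lit3, space$inputs)
    model$rules[[tgt]] <- expr
    model$rule_text[[tgt]] <- cs_deparse_rule(expr)
  }
  model
}

# mixed-radix unranking, first digit most significant
cs_unrank <- function(id, sizes) {
  rem <- id - 1
  idx <- integer(length(sizes))
  for (k in rev(seq_along(sizes))) {
    idx[k] <- rem %% sizes[k] + 1
    rem <- rem %/% sizes[k]
  }
  idx
}

cs_rank <- function(idx, sizes) {
  id <- 0
  for (k in seq_along(sizes)) id <- id * sizes[k] + (idx[k] - 1)
  id + 1
}

# render an expression back to the model grammar
cs_deparse_rule <- function(e) {
  if (is.numeric(e)) return(as.character(e))
  if (is.name(e)) return(as.character(e))
  op <- as.character(e[[1]])
  switch(op,
         "|" = sprintf("%s or %s", cs_deparse_rule(e[[2]]),
                       cs_deparse_rule(e[[3]])),
         "&" = sprintf("%s and %s", cs_paren(e[[2]], "|"),
                       cs_paren(e[[3]], "|")),
         "!" = sprintf("not %s", cs_paren(e[[2]], c("|", "&"))),
         ">=" = sprintf("%s >= %s", as.character(e[[2]]), e[[3]]),
         "==" = sprintf("%s == %s", as.character(e[[2]]), e[[3]]),
         "(" = cs_deparse_rule(e[[2]]),
         stop(sprintf("cannot render operator '%s'", op), call. = FALSE))
}

cs_paren <- function(e, weaker_ops) {
  txt <- cs_deparse_rule(e)
  if (is.call(e) && as.character(e[[1]]) %in% weaker_ops) {
    sprintf("(%s)", txt)
  } else {
    txt
  }
}

#' Locate a model inside a variant space
#'
#' Returns the variant id whose decoded rules are semantically identical to
#' the given model on every state (checked by exhaustive truth-table
#' comparison of each free target's rule), or `NA` if absent.
#'
#' @param space A `cs_variant_space`.
#' @param model A `cs_model`.
#' @return Integer variant id or `NA`.
#' @export
variant_id_of <- function(space, model) {
  idx <- integer(length(space$free))
  for (k in seq_along(space$free)) {
    tgt <- space$free[k]
    opts <- space$options[[tgt]]
    target_expr <- model$rules[[tgt]]
    hit <- NA_integer_
    for (r in seq_len(nrow(opts))) {
      cand <- cs_build_variant_rule(space$topology[[tgt]],
                                    as.list(opts[r, , drop = FALSE]),
                                    space$lit3, space$inputs)
      if (cs_exprs_equivalent(cand, target_expr, space$base)) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) return(NA_integer_)
    idx[k] <- hit
  }
  as.integer(cs_rank(idx, space$sizes))
}

# semantic equality of two rule expressions over the full state space
cs_exprs_equivalent <- function(e1, e2, model) {
  vars <- model$vars
  lev <- lapply(seq_len(nrow(vars)), function(i) 0:(vars$arity[i] - 1L))
  names(lev) <- vars$name
  grid <- do.call(expand.grid, c(lev, KEEP.OUT.ATTRS = FALSE))
  L <- as.matrix(grid)
  env <- cs_eval_env(model, L)
  n <- nrow(L)
  v1 <- rep_len(as.logical(eval(e1, env)), n)
  v2 <- rep_len(as.logical(eval(e2, env)), n)
  all(v1 == v2)
}

#' Score a candidate ruleset against the constraint suite
#'
#' @param model Candidate `cs_model`.
#' @param suite Constraint suite (see [constraint_suite()]).
#' @param reference Reference model supplying the target trajectories for the
#'   distance term.
#' @param distance_steps Steps of the zero-init trajectories compared.
#' @return List with `required` and `soft` pass counts, `distance` (mean
#'   absolute level difference between the candidate's and the reference's
#'   zero-init moderate/severe trajectories) and the full `report`.
#' @export
score_ruleset <- function(model, suite = constraint_suite(),
                          reference = reference_model(),
                          distance_steps = 10L) {
  report <- check_constraints(model, suite)
  vars <- setdiff(cs_internal_vars(reference), character(0))
  dist <- 0
  cnt <- 0
  for (inj in c(1L, 2L)) {
    tr_c <- simulate_model(model, zero_state(model, inj), distance_steps)
    tr_r <- simulate_model(reference, zero_state(reference, inj),
                           distance_steps)
    dist <- dist + sum(abs(tr_c[, vars] - tr_r[, vars]))
    cnt <- cnt + length(tr_r[, vars])
  }
  req <- report$severity == "required"
  list(required = sum(report$pass[req]),
       soft = sum(report$pass[!req]),
       distance = dist / cnt,
       report = report)
}

#' Search a ruleset variant space
#'
#' Scores variants against the behavioral constraint suite and ranks them
#' lexicographically: more required constraints passed, then more soft
#' constraints, then smaller trajectory distance to the reference.  With a
#' budget at least the size of the space the search is exhaustive; otherwise
#' it scores a uniform random subsample of variant ids drawn without
#' replacement under `seed`.
#'
#' @param space A `cs_variant_space`.
#' @param suite Constraint suite.
#' @param budget Maximum number of variants to score (>= 1).
#' @param seed Integer seed for the subsample (ignored when exhaustive).
#' @param reference Reference model for the distance term.
#' @return Data frame (best first): `id`, `required`, `soft`, `distance`.
#' @export
search_rulesets <- function(space, suite = constraint_suite(), budget,
                            seed = 1L, reference = reference_model()) {
  stopifnot(budget >= 1)
  if (budget >= space$count) {
    ids <- seq_len(space$count)
  } else {
    set.seed(seed)
    ids <- sort(sample.int(space$count, budget))
  }
  res <- vapply(ids, function(id) {
    sc <- score_ruleset(variant_model(space, id), suite, reference)
    c(sc$required, sc$soft, sc$distance)
  }, numeric(3))
  out <- data.frame(id = ids, required = res[1, ], soft = res[2, ],
                    distance = res[3, ])
  out[order(-out$required, -out$soft, out$distance, out$id), , drop = FALSE]
}
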