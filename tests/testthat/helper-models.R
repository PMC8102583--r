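# Shared fixtures: tiny models and an independent rule interpreter.

identity_model <- function() {
  parse_model(c("var A:2", "rule A = A"))
}

two_bit_model <- function() {
  parse_model(c("var A:2", "var B:2", "rule A = B", "rule B = A"))
}

# Independent scalar rule interpreter used as the synchronicity oracle: walks
# the parsed AST directly on a single level-state, with its own bit logic.
naive_eval <- function(expr, levels, model) {
  ev <- function(e) {
    if (is.numeric(e)) return(e != 0)
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% model$vars$name) return(levels[[nm]] != 0)
      base <- sub("_(low|high)$", "", nm)
      lv <- levels[[base]]
      if (grepl("_low$", nm)) return(lv >= 1)
      return(lv == 2)
    }
    op <- as.character(e[[1]])
    switch(op,
           "&" = ev(e[[2]]) && ev(e[[3]]),
           "|" = ev(e[[2]]) || ev(e[[3]]),
           "!" = !ev(e[[2]]),
           ">=" = levels[[as.character(e[[2]])]] >= e[[3]],
           "==" = levels[[as.character(e[[2]])]] == e[[3]],
           stop("unknown operator ", op))
  }
  ev(expr)
}

# One synchronous step computed bit-by-bit with the naive interpreter.
naive_step <- function(model, levels) {
  out <- levels
  for (i in seq_len(nrow(model$vars))) {
    nm <- model$vars$name[i]
    if (model$vars$role[i] == "input") next
    if (model$vars$arity[i] == 2L) {
      out[[nm]] <- as.integer(naive_eval(model$rules[[nm]], levels, model))
    } else {
      lo <- naive_eval(model$rules[[paste0(nm, "_low")]], levels, model)
      hi <- naive_eval(model$rules[[paste0(nm, "_high")]], levels, model)
      out[[nm]] <- as.integer(lo) + as.integer(hi)
    }
  }
  out
}

ref_fixed_point <- function(injury) {
  if (injury == 1L) {
    c(I = 1L, X = 1L, MIG = 0L, MCP1 = 0L, IP10 = 2L, IL6 = 0L)
  } else {
    c(I = 2L, X = 1L, MIG = 0L, MCP1 = 1L, IP10 = 2L, IL6 = 1L)
  }
}

# Reference model with the MIG suppression term removed (self-loop only):
# known to create a second fixed point under moderate injury.
mig_selfloop_model <- function() {
  txt <- write_model(reference_model())
  txt <- sub("^rule MIG = .*$", "rule MIG = MIG", txt)
  parse_model(txt)
}
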