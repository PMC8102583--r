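# The reference chemokine-switch ruleset.
#
# Variables: I = injury severity (input; mild = 0, moderate = 1, severe = 2),
# X = latent intermediate upstream of IP-10 (step-like, IFN-gamma-like),
# MIG = CXCL9, MCP1 = CCL2, IP10 = CXCL10, IL6.  MCP-1, IP-10 and IL-6 are
# three-level; their level is the sum of the low and high bits.

cs_reference_text <- function() {
  c("# chemokine-switch reference ruleset",
    "var I:3 input",
    "var X:2",
    "var MIG:2",
    "var MCP1:3",
    "var IP10:3",
    "var IL6:3",
    "rule X = I >= 1",
    "rule IP10_low = X or IP10_high",
    "rule IP10_high = IP10_low and not (MIG and MCP1_low)",
    "rule MIG = MIG and not IP10_low",
    "rule MCP1_low = I == 2 or (MCP1_low and not IP10_high)",
    "rule MCP1_high = I == 2 and MCP1_low and not IP10_high",
    "rule IL6_low = MIG or MCP1_low",
    "rule IL6_high = IL6_low and MCP1_low and not IP10_high")
}

#' The reference chemokine-switch model
#'
#' Returns the canonical ruleset for the injury -> X -> IP-10/MCP-1/MIG -> IL-6
#' switch: each chemokine feeds back on itself and cross-inhibits the others,
#' MCP-1 is driven directly by severe injury, IP-10 induction is delayed
#' through the intermediate node X, and IL-6 integrates MIG and MCP-1 with
#' high output gated by MCP-1 activity and the absence of high IP-10.
#'
#' Key dynamic properties (all machine-checked by [constraint_suite()]):
#' under mild injury the all-zero state is a fixed point; under moderate
#' injury IP-10 rises to its top level while the other mediators stay at
#' zero from a resting start; under severe injury MCP-1 and then IL-6
#' transiently peak before settling at a moderate level.
#'
#' @return A `cs_model`.
#' @export
reference_model <- function() {
  parse_model(cs_reference_text())
}

#' Zero-mediator initial state for a switch-type model
#'
#' @param model A `cs_model` (defaults to the reference model).
#' @param injury Injury level for the input variable `I`.
#' @return Named integer level-state with every internal variable at 0.
#' @export
zero_state <- function(model = reference_model(), injury = 0L) {
  st <- stats::setNames(integer(nrow(model$vars)), model$vars$name)
  for (nm in cs_input_vars(model)) st[[nm]] <- as.integer(injury)
  st
}

#' Clamp schedule for the intermediate node X
#'
#' Encodes the two candidate dynamics examined for the latent node upstream
#' of IP-10: a single-step spike (0 at step 0, 1 at step 1, 0 thereafter) or
#' a sustained step rise (0 at step 0, 1 from step 1 onward).
#'
#' @param shape `"spike"` or `"step"`.
#' @param length Schedule length in steps (>= 2); element `t + 1` is the
#'   clamped level at step `t`.
#' @return Integer vector of levels usable as `clamps = list(X = ...)`.
#' @export
clamp_profile <- function(shape = c("spike", "step"), length) {
  shape <- match.arg(shape)
  if (length < 2) stop("clamp profile needs length >= 2", call. = FALSE)
  out <- integer(length)
  if (shape == "spike") out[2] <- 1L else out[2:length] <- 1L
  out
}

# Variant with the delay node bypassed: IP-10 low bit is driven directly by
# injury.  X (if present) keeps its rule but no longer feeds IP-10; from a
# zero start the IP-10 trajectory equals that of outright X deletion.
cs_without_x_variant <- function(model) {
  txt <- write_model(model)
  txt <- sub("^rule IP10_low = .*$", "rule IP10_low = I >= 1 or IP10_high",
             txt)
  parse_model(txt)
}
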