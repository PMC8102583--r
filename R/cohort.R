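# Synthetic trauma cohort generator.
#
# Discrete switch-model trajectories are mapped to pg/ml concentrations on a
# clinical sampling schedule: level l of mediator m becomes
# baseline_m * fold_m^l * exp(eps), eps ~ N(0, sigma^2), independently per
# sample (multiplicative lognormal noise, as Luminex panel concentrations are
# positive and right-skewed).  IFN-gamma is emitted tracking the latent X
# trajectory; bystander mediators are pure baseline noise and give the
# network-inference stage true-negative edges to reject.

#' Default mediator concentration map
#'
#' Baselines (pg/ml), per-level fold changes and log-scale noise sigma for
#' the emitted mediator panel.  The fold choices keep the discrete levels
#' separable under the clinical MCP-1 outcome cutoffs: MCP-1 level 1 maps to
#' 600 pg/ml (below the 1000 pg/ml low-MCP-1 cutoff) and level 2 to 3600
#' pg/ml (above 1500 pg/ml).  These are declared stand-ins, not estimates of
#' any measured panel.
#'
#' @param sigma Log-scale lognormal noise sigma applied to every mediator.
#' @return Data frame with columns `mediator`, `source` (the model variable
#'   tracked, or `"noise"` for bystanders), `baseline`, `fold`, `sigma`.
#' @export
default_mediator_map <- function(sigma = 0.3) {
  data.frame(
    mediator = c("MCP1", "MIG", "IP10", "IL6", "IFNg",
                 "TNFa", "IL1b", "IL10"),
    source   = c("MCP1", "MIG", "IP10", "IL6", "X",
                 "noise", "noise", "noise"),
    baseline = c(100, 200, 150, 5, 10, 20, 10, 15),
    fold     = c(6, 5, 5, 10, 4, 1, 1, 1),
    sigma    = sigma,
    stringsAsFactors = FALSE)
}

#' Clinical sampling schedule
#'
#' One synchronous model step is taken as 8 h, so steps 1-3 span the first
#' 24 h and step 21 is 168 h (day 7).  The default schedule takes the
#' admission draw at time 0 plus samples at 8 and 16 h, then daily samples
#' from 24 h through 168 h.
#'
#' @param hours_per_step Hours represented by one synchronous step.
#' @param times_h Sample times in hours post-injury (must lie on the step
#'   grid).
#' @return List with `times_h`, `steps` (model step per sample) and
#'   `hours_per_step`.
#' @export
default_schedule <- function(hours_per_step = 8,
                             times_h = c(0, 8, 16, seq(24, 168, by = 24))) {
  stopifnot(all(diff(times_h) > 0))
  steps <- times_h / hours_per_step
  if (any(steps != round(steps))) {
    stop("sample times must be multiples of hours_per_step", call. = FALSE)
  }
  list(times_h = times_h, steps = as.integer(steps),
       hours_per_step = hours_per_step)
}

cs_emit_concentrations <- function(levels_by_step, map, schedule) {
  # levels_by_step: steps x variables trajectory matrix (step 0 first)
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    src <- map$source[i]
    lv <- if (src == "noise") {
      rep(0L, length(schedule$steps))
    } else {
      levels_by_step[schedule$steps + 1L, src]
    }
    mu <- map$baseline[i] * map$fold[i]^lv
    eps <- stats::rnorm(length(mu), 0, map$sigma[i])
    out[[i]] <- data.frame(time_h = schedule$times_h,
                           mediator = map$mediator[i],
                           value_pg_ml = mu * exp(eps),
                           latent_level = lv,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate one synthetic patient
#'
#' Draws a random initial mediator state (uniform over the exhaustive
#' enumeration), simulates the switch model at fixed injury severity, and
#' emits noisy concentrations on the sampling schedule.
#'
#' @param model The switch `cs_model`.
#' @param injury Injury level (0 mild, 1 moderate, 2 severe).
#' @param mediator_map Data frame as from [default_mediator_map()].
#' @param schedule Sampling schedule from [default_schedule()].
#' @param seed Integer seed; identical seeds reproduce the patient exactly.
#' @param patient_id Identifier recorded in the output rows.
#' @param init Optional fixed initial level-state (overrides the random
#'   draw).
#' @return List of class `cs_patient`: `id`, `group`, `trajectory` (latent
#'   levels) and `data` (long-format concentrations).
#' @export
simulate_patient <- function(model, injury, mediator_map = default_mediator_map(),
                             schedule = default_schedule(), seed,
                             patient_id = "p1", init = NULL) {
  known <- c(model$vars$name, "noise")
  bad <- setdiff(mediator_map$source, known)
  if (length(bad) > 0) {
    stop(sprintf("mediator map references unknown source(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  if (is.null(init)) {
    states <- enumerate_initial_states(model, fixed = list(I = injury))
    init <- states[sample.int(nrow(states), 1L), ]
  }
  steps <- max(schedule$steps)
  traj <- simulate_model(model, init, steps, clamps = list(I = injury))
  data <- cs_emit_concentrations(traj, mediator_map, schedule)
  structure(list(id = patient_id,
                 group = c("mild", "moderate", "severe")[injury + 1L],
                 trajectory = traj, data = data),
            class = "cs_patient")
}

#' Generate a synthetic trauma cohort
#'
#' Independent patients per injury group, each with a per-patient seed
#' derived deterministically from the master seed, plus a healthy-reference
#' pseudo-patient group whose latent levels are held at zero throughout.
#'
#' @param n_mild,n_moderate,n_severe Patients per injury group (the study
#'   design uses 48/47/47).
#' @param seed Master seed.
#' @param mediator_map,schedule See [simulate_patient()].
#' @param n_healthy Healthy-reference pseudo-patients (latent level 0).
#' @param model The switch model.
#' @return Long-format data frame of class `cs_cohort`: columns
#'   `patient_id`, `group`, `time_h`, `mediator`, `value_pg_ml`,
#'   `latent_level`.
#' @export
generate_cohort <- function(n_mild = 48L, n_moderate = 47L, n_severe = 47L,
                            seed = 1L,
                            mediator_map = default_mediator_map(),
                            schedule = default_schedule(),
                            n_healthy = 10L,
                            model = reference_model()) {
  stopifnot(n_mild >= 0, n_moderate >= 0, n_severe >= 0, n_healthy >= 0)
  groups <- rep(c(0L, 1L, 2L), c(n_mild, n_moderate, n_severe))
  n_all <- length(groups) + n_healthy
  set.seed(seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_all)
  rows <- vector("list", n_all)
  zero <- NULL
  for (k in seq_along(groups)) {
    pid <- sprintf("pt%03d", k)
    pat <- simulate_patient(model, groups[k], mediator_map, schedule,
                            seed = patient_seeds[k], patient_id = pid)
    rows[[k]] <- cbind(patient_id = pid, group = pat$group,
                       pat$data, stringsAsFactors = FALSE)
  }
  if (n_healthy > 0) {
    zero_traj <- matrix(0L, nrow = max(schedule$steps) + 1L,
                        ncol = nrow(model$vars),
                        dimnames = list(as.character(0:max(schedule$steps)),
                                        model$vars$name))
    for (h in seq_len(n_healthy)) {
      k <- length(groups) + h
      pid <- sprintf("hv%03d", h)
      set.seed(patient_seeds[k])
      data <- cs_emit_concentrations(zero_traj, mediator_map, schedule)
      rows[[k]] <- cbind(patient_id = pid, group = "healthy",
                         data, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), group = character(0),
                      time_h = numeric(0), mediator = character(0),
                      value_pg_ml = numeric(0), latent_level = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[, c("patient_id", "group", "time_h", "mediator",
                 "value_pg_ml", "latent_level")]
  rownames(out) <- NULL
  class(out) <- c("cs_cohort", class(out))
  out
}

#' Retain patients with low first-sample MCP-1
#'
#' Keeps patients whose MCP-1 concentration at their earliest sampled time is
#' below the threshold (1000 pg/ml by default, the clinical low-MCP-1
#' cutoff).  Idempotent.
#'
#' @param cohort A `cs_cohort`.
#' @param threshold Concentration cutoff in pg/ml.
#' @return Filtered `cs_cohort`.
#' @export
subgroup_low_mcp1 <- function(cohort, threshold = 1000) {
  if (nrow(cohort) == 0) return(cohort)
  mcp <- cohort[cohort$mediator == "MCP1", , drop = FALSE]
  if (nrow(mcp) == 0) stop("cohort has no MCP-1 measurements", call. = FALSE)
  first <- stats::aggregate(time_h ~ patient_id, data = mcp, FUN = min)
  key <- paste(mcp$patient_id, mcp$time_h)
  first$value <- mcp$value_pg_ml[match(paste(first$patient_id, first$time_h),
                                       key)]
  keep <- first$patient_id[first$value < threshold]
  out <- cohort[cohort$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group means and standard errors per mediator and time
#'
#' Arithmetic mean and standard error on the raw pg/ml scale.
#'
#' @param cohort A `cs_cohort`.
#' @return Data frame: `group`, `mediator`, `time_h`, `n`, `mean`, `se`.
#' @export
group_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  agg <- stats::aggregate(value_pg_ml ~ group + mediator + time_h,
                          data = cohort,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(group = agg$group, mediator = agg$mediator,
                    time_h = agg$time_h,
                    n = agg$value_pg_ml[, "n"],
                    mean = agg$value_pg_ml[, "mean"],
                    se = ifelse(agg$value_pg_ml[, "n"] > 1,
                                agg$value_pg_ml[, "sd"] /
                                  sqrt(agg$value_pg_ml[, "n"]), 0),
                    stringsAsFactors = FALSE)
  out[order(out$group, out$mediator, out$time_h), , drop = FALSE]
}

#' Decode latent levels from noise-free concentrations
#'
#' Inverts the concentration map (`log(conc / baseline) / log(fold)`); exact
#' for sigma = 0 cohorts.
#'
#' @param cohort A `cs_cohort`.
#' @param mediator_map The map used to generate it.
#' @return The cohort with a `decoded_level` column appended.
#' @export
decode_levels <- function(cohort, mediator_map = default_mediator_map()) {
  m <- match(cohort$mediator, mediator_map$mediator)
  base <- mediator_map$baseline[m]
  fold <- mediator_map$fold[m]
  lv <- ifelse(fold > 1, log(cohort$value_pg_ml / base) / log(fold), 0)
  cohort$decoded_level <- as.integer(round(lv))
  cohort
}
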