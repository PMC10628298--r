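#' Parameters of the two-state branching process
#'
#' A cell is either drug-susceptible (S) or primed (P). S cells divide at
#' rate `r_S` per day and die at rate `d_S`; P cells at `r_P` and `d_P`.
#' At each division, each daughter independently switches to the other
#' state with probability `p_on` (S mother) or `p_off` (P mother) -- the
#' per-daughter convention, under which "one switching event every N
#' divisions" corresponds to a per-daughter probability of `1 / (2 N)`.
#' `gamma` optionally couples S->P switching to the lineage's current
#' primed fraction: `p_on_eff = p_on * (1 + gamma * primed_fraction)`.
#'
#' @param r_S,r_P division rates per day (`r_S > 0`).
#' @param d_S,d_P death rates per day.
#' @param p_on per-daughter S->P switch probability.
#' @param p_off per-daughter P->S switch probability.
#' @param gamma lineage-coupling coefficient (default 0, no coupling).
#' @return object of class `two_state_params`.
#' @export
two_state_params <- function(r_S = 1, r_P = 0.5, d_S = 0, d_P = 0,
                             p_on = 0, p_off = 0, gamma = 0) {
  stopifnot(r_S > 0, r_P >= 0, d_S >= 0, d_P >= 0,
            p_on >= 0, p_on <= 1, p_off >= 0, p_off <= 1, gamma >= 0)
  structure(list(r_S = r_S, r_P = r_P, d_S = d_S, d_P = d_P,
                 p_on = p_on, p_off = p_off, gamma = gamma),
            class = "two_state_params")
}

#' Convert between divisions-per-event and per-daughter probability
#'
#' Under the per-daughter convention, one switching event every `N`
#' divisions corresponds to a per-daughter switch probability `1 / (2 N)`,
#' since each division draws two daughters.
#'
#' @param divisions divisions per switching event.
#' @return per-daughter probability.
#' @export
divisions_to_prob <- function(divisions) 1 / (2 * divisions)

#' @rdname divisions_to_prob
#' @param prob per-daughter probability.
#' @export
prob_to_divisions <- function(prob) 1 / (2 * prob)

.as_founders <- function(founders) {
  # accepts c(S = n, P = m) or a character vector of states
  if (is.character(founders)) {
    states <- ifelse(founders == "P", 1L, 0L)
  } else {
    n_s <- as.integer(founders["S"] %||% 0)
    n_s <- if (is.na(n_s)) 0L else n_s
    n_p <- if (!is.na(founders["P"])) as.integer(founders["P"]) else 0L
    states <- c(rep(0L, n_s), rep(1L, n_p))
  }
  stopifnot(length(states) >= 1)
  states
}

.stop_duration <- function(stop, params) {
  if (!is.null(stop$duration)) return(stop$duration)
  if (!is.null(stop$target_doublings))
    return(stop$target_doublings * log(2) / params$r_S)
  stop("stop must specify duration or target_doublings")
}

#' Simulate a two-state branching population
#'
#' Exact event-driven (Gillespie) simulation: each cell divides at its
#' state's rate and dies at its state's rate; at a division each daughter
#' independently switches state with the per-daughter probability (or, in
#' `"continuous"` mode, switching is an independent per-cell event at the
#' per-time equivalent rate). Lineage ids are inherited; each founder
#' starts its own lineage. Reproducible given a seed.
#'
#' @param params a [two_state_params()].
#' @param founders founder composition: `c(S = n, P = m)` or a character
#'   vector of founder states.
#' @param stop list with `duration` (days) or `target_doublings`
#'   (doublings of the susceptible state: duration
#'   `doublings * log(2) / r_S`).
#' @param seed optional integer seed.
#' @param switch_mode `"division"` (per-daughter, default) or
#'   `"continuous"`.
#' @param max_cells hard cap on population size.
#' @return object of class `simulated_population`: list with `cells`
#'   (data.frame: `cell_id`, `lineage_id`, `state`, `birth_time`),
#'   `events`, `founder_states`, `time`, `extinct`, `params`, `seed`.
#' @export
simulate_population <- function(params, founders, stop, seed = NULL,
                                switch_mode = c("division", "continuous"),
                                max_cells = 5e6) {
  switch_mode <- match.arg(switch_mode)
  .check_seed(seed)
  fstates <- .as_founders(founders)
  duration <- .stop_duration(stop, params)
  res <- sim_twostate_cpp(fstates, seq_along(fstates),
                          params$r_S, params$r_P, params$d_S, params$d_P,
                          params$p_on, params$p_off, params$gamma,
                          duration, as.integer(max_cells),
                          if (switch_mode == "continuous") 1L else 0L)
  if (res$truncated)
    warning("population hit max_cells before the stop condition")
  cells <- data.frame(
    cell_id = sprintf("cell%07d", seq_along(res$state)),
    lineage_id = res$lineage,
    state = ifelse(res$state == 1L, "P", "S"),
    birth_time = res$birth_time,
    stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 events = res$events,
                 founder_states = setNames(ifelse(fstates == 1L, "P", "S"),
                                           as.character(seq_along(fstates))),
                 time = res$time,
                 extinct = res$extinct,
                 params = params,
                 seed = seed),
            class = "simulated_population")
}

#' Deterministic steady-state primed fraction
#'
#' Fixed point of the primed fraction `f = P / (S + P)` under the
#' deterministic (mean-field) limit of the two-state model. With the
#' per-daughter convention the mean-field flows are
#' `S' = (r_S (1 - 2 p_on) - d_S) S + 2 p_off r_P P` and
#' `P' = 2 p_on r_S S + (r_P (1 - 2 p_off) - d_P) P`
#' (per-time switching `2 p_on r_S`, one draw per daughter). The fixed
#' point solves a quadratic in `f`; the stable root in `[0, 1]` is
#' returned. Lineage coupling (`gamma`) is ignored here (population-level
#' limit).
#'
#' @param params a [two_state_params()].
#' @return the stable steady-state primed fraction in `[0, 1]`.
#' @export
steady_state_fraction <- function(params) {
  a <- params$r_S * (1 - 2 * params$p_on) - params$d_S
  b <- 2 * params$p_off * params$r_P
  cc <- 2 * params$p_on * params$r_S
  e <- params$r_P * (1 - 2 * params$p_off) - params$d_P
  # g(f) = A f^2 + B f + C, roots are fixed points; stable where g'(f) < 0
  A <- -(b + e - a - cc)
  B <- e - a - 2 * cc
  C <- cc
  eps <- 1e-12
  if (abs(A) < eps) {
    if (abs(B) < eps) stop("degenerate parameters: no unique fixed point")
    f <- -C / B
    if (f < -1e-9 || f > 1 + 1e-9 || B >= 0)
      stop("no stable fixed point in [0, 1]")
    return(min(max(f, 0), 1))
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no real fixed point (parameter pathology)")
  roots <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  inside <- roots[roots >= -1e-9 & roots <= 1 + 1e-9]
  stable <- inside[2 * A * inside + B < 0]
  if (length(stable) == 0) stop("no stable fixed point in [0, 1]")
  min(max(stable[1], 0), 1)
}

#' Subsample captured cells with imperfect barcode detection
#'
#' Uniform sampling without replacement of `n` cells from a simulated
#' population; each sampled cell keeps its lineage id with probability
#' `detection`, otherwise the lineage is NA (barcode not recovered).
#'
#' @param pop a [simulate_population()] result.
#' @param n cells to sample (must not exceed the population size).
#' @param detection barcode detection probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return cell table data.frame with `cell_id`, `lineage_id` (NA when
#'   undetected), `state`, `true_lineage`.
#' @export
sample_cells <- function(pop, n, detection = 1, seed = NULL) {
  .check_seed(seed)
  cells <- pop$cells
  if (n > nrow(cells)) stop("cannot sample more cells than the population")
  idx <- sample.int(nrow(cells), n)
  out <- cells[idx, c("cell_id", "lineage_id", "state"), drop = FALSE]
  out$true_lineage <- out$lineage_id
  if (detection < 1)
    out$lineage_id[runif(n) >= detection] <- NA
  rownames(out) <- NULL
  out
}

#' Design of an expand/split/treat lineage-tracing experiment
#'
#' @param founders founder composition, `c(S = n, P = m)`.
#' @param expansion_doublings susceptible-state doublings during barcode
#'   expansion before the split.
#' @param plates named list of per-condition parameter overrides (each a
#'   named list of [two_state_params()] fields, or NULL for no change).
#' @param treatment_days duration of the per-plate treatment phase.
#' @param capture cells captured per plate (`Inf` = all).
#' @param barcode_detection_rate probability a captured cell's barcode is
#'   recovered (default 0.60, the typical recovered fraction in droplet
#'   experiments with a transcribed barcode).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(founders, expansion_doublings,
                              plates = list(untreated = NULL),
                              treatment_days = 0,
                              capture = Inf,
                              barcode_detection_rate = 0.60) {
  stopifnot(length(plates) >= 1, expansion_doublings >= 0,
            barcode_detection_rate >= 0, barcode_detection_rate <= 1)
  structure(list(founders = founders,
                 expansion_doublings = expansion_doublings,
                 plates = plates,
                 treatment_days = treatment_days,
                 capture = capture,
                 barcode_detection_rate = barcode_detection_rate),
            class = "experiment_design")
}

.apply_overrides <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0) return(params)
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  class(params) <- "two_state_params"
  params
}

# internal fast path: expansion + optional split/treatment of one plate,
# returning raw integer vectors (state: 0/1, lineage) after capture.
.sim_design_plate <- function(base_params, design, plate_params,
                              n_plates = length(design$plates),
                              switch_mode = "division") {
  fstates <- .as_founders(design$founders)
  dur <- design$expansion_doublings * log(2) / base_params$r_S
  mode_i <- if (switch_mode == "continuous") 1L else 0L
  res <- sim_twostate_cpp(fstates, seq_along(fstates),
                          base_params$r_S, base_params$r_P,
                          base_params$d_S, base_params$d_P,
                          base_params$p_on, base_params$p_off,
                          base_params$gamma, dur, 5e6L, mode_i)
  state <- res$state
  lineage <- res$lineage
  if (length(state) == 0)
    return(list(state = integer(0), lineage = integer(0),
                founder_states = fstates, extinct = TRUE))
  if (n_plates > 1) {
    keep <- sample.int(n_plates, length(state), replace = TRUE) == 1L
    state <- state[keep]
    lineage <- lineage[keep]
  }
  if (design$treatment_days > 0 && length(state) > 0) {
    p <- plate_params
    res <- sim_twostate_cpp(state, lineage,
                            p$r_S, p$r_P, p$d_S, p$d_P,
                            p$p_on, p$p_off, p$gamma,
                            design$treatment_days, 5e6L, mode_i)
    state <- res$state
    lineage <- res$lineage
  }
  n <- length(state)
  if (is.finite(design$capture) && design$capture < n) {
    idx <- sample.int(n, design$capture)
    state <- state[idx]
    lineage <- lineage[idx]
  }
  det <- design$barcode_detection_rate
  obs_lineage <- lineage
  if (det < 1 && n > 0)
    obs_lineage[runif(length(obs_lineage)) >= det] <- NA_integer_
  list(state = state, lineage = obs_lineage, true_lineage = lineage,
       founder_states = fstates, extinct = (n == 0))
}

#' Simulate a full expand/split/treat experiment
#'
#' Expands barcoded founders under the base parameters, distributes the
#' resulting cells multinomially across the design's plates, continues
#' each plate under its (optionally overridden) parameters for the
#' treatment phase, then captures cells and masks lineage barcodes at the
#' detection rate. Ground-truth lineages and founder states are retained.
#'
#' @param design an [experiment_design()].
#' @param base_params a [two_state_params()] used for expansion and as the
#'   default for every plate.
#' @param seed optional integer seed.
#' @param switch_mode passed to the simulator.
#' @return list with `tables` (named list of per-condition cell tables:
#'   `cell_id`, `condition`, `lineage_id`, `state`, `true_lineage`) and
#'   `founder_states` (named vector lineage id -> founder state).
#' @export
simulate_experiment <- function(design, base_params, seed = NULL,
                                switch_mode = c("division", "continuous")) {
  switch_mode <- match.arg(switch_mode)
  .check_seed(seed)
  fstates <- .as_founders(design$founders)
  dur <- design$expansion_doublings * log(2) / base_params$r_S
  mode_i <- if (switch_mode == "continuous") 1L else 0L
  res <- sim_twostate_cpp(fstates, seq_along(fstates),
                          base_params$r_S, base_params$r_P,
                          base_params$d_S, base_params$d_P,
                          base_params$p_on, base_params$p_off,
                          base_params$gamma, dur, 5e6L, mode_i)
  n_plates <- length(design$plates)
  assign_plate <- sample.int(n_plates, length(res$state), replace = TRUE)
  tables <- list()
  for (k in seq_len(n_plates)) {
    cond <- names(design$plates)[k]
    st <- res$state[assign_plate == k]
    li <- res$lineage[assign_plate == k]
    if (design$treatment_days > 0 && length(st) > 0) {
      p <- .apply_overrides(base_params, design$plates[[k]])
      r2 <- sim_twostate_cpp(st, li, p$r_S, p$r_P, p$d_S, p$d_P,
                             p$p_on, p$p_off, p$gamma,
                             design$treatment_days, 5e6L, mode_i)
      st <- r2$state
      li <- r2$lineage
    }
    n <- length(st)
    cap <- design$capture
    if (is.finite(cap) && cap > n) {
      warning("capture larger than plate population for ", cond,
              "; capped at ", n)
      cap <- n
    }
    if (is.finite(cap) && cap < n) {
      idx <- sample.int(n, cap)
      st <- st[idx]
      li <- li[idx]
      n <- cap
    }
    obs <- li
    if (design$barcode_detection_rate < 1 && n > 0)
      obs[runif(n) >= design$barcode_detection_rate] <- NA_integer_
    tables[[cond]] <- data.frame(
      cell_id = sprintf("%s_cell%07d", cond, seq_len(n)),
      condition = cond,
      lineage_id = obs,
      state = ifelse(st == 1L, "P", "S"),
      true_lineage = li,
      stringsAsFactors = FALSE)
  }
  list(tables = tables,
       founder_states = setNames(ifelse(fstates == 1L, "P", "S"),
                                 as.character(seq_along(fstates))),
       params = base_params, design = design, seed = seed)
}
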