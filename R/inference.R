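.CATEGORIES <- c("PURE_S", "PURE_P", "S_TO_P", "P_TO_S")

.STAT_NAMES <- c(
  "percent_primed",
  paste0("cat_", .CATEGORIES),
  paste0("size_S_q", c(25, 50, 75)),
  paste0("size_P_q", c(25, 50, 75)),
  paste0("pf_bin", 1:10))

# fast core shared by summary_stats() and the grid fitter: takes a state
# indicator (1 = primed), lineage ids (NA = no barcode) and founder states
# ("S"/"P") indexed by lineage id.
.stats_core <- function(is_p, lineage, founder_states) {
  out <- numeric(21)
  names(out) <- .STAT_NAMES
  out["percent_primed"] <- mean(is_p)
  ok <- !is.na(lineage)
  lin <- as.character(lineage[ok])
  ids <- unique(lin)
  if (length(ids) == 0) return(out)
  f <- factor(lin, levels = ids)
  size <- tabulate(f, nbins = length(ids))
  n_p <- tabulate(f[is_p[ok] == 1], nbins = length(ids))
  founder <- unname(founder_states[ids])
  cat <- ifelse(founder == "S",
                ifelse(n_p == 0, "PURE_S", "S_TO_P"),
                ifelse(n_p == size, "PURE_P", "P_TO_S"))
  ct <- table(factor(cat, levels = .CATEGORIES))
  out[paste0("cat_", .CATEGORIES)] <- as.numeric(ct) / length(ids)
  q <- function(x) if (length(x)) unname(quantile(x, c(.25, .5, .75))) else c(0, 0, 0)
  out[paste0("size_S_q", c(25, 50, 75))] <- q(size[founder == "S"])
  out[paste0("size_P_q", c(25, 50, 75))] <- q(size[founder == "P"])
  pf <- n_p / size
  bins <- tabulate(pmin(floor(pf * 10), 9) + 1L, nbins = 10L)
  out[paste0("pf_bin", 1:10)] <- bins / length(ids)
  out
}

#' Summary statistics of a lineage-annotated cell table
#'
#' The statistic vector compared between observed and simulated data
#' during inference: overall primed fraction (computed over all cells,
#' including those without a recovered barcode), the fractions of the four
#' lineage memory categories, lineage-size quartiles per founder state,
#' and a 10-bin histogram of per-lineage primed fractions. Cells without a
#' lineage contribute only to the primed fraction.
#'
#' @param table cell table with `state` and `lineage_id` (NA allowed).
#' @param classes a [classify_lineages()] result for the same table (used
#'   for founder states).
#' @return named numeric vector of class `summary_stats` (21 components;
#'   category fractions and the histogram each sum to 1).
#' @export
summary_stats <- function(table, classes) {
  stopifnot(nrow(classes) >= 1)
  founder_states <- setNames(classes$founder_state,
                             as.character(classes$lineage_id))
  lineage <- as.character(table$lineage_id)
  lineage[!lineage %in% names(founder_states)] <- NA
  out <- .stats_core(as.integer(table$state == "P"), lineage, founder_states)
  class(out) <- c("summary_stats", "numeric")
  out
}

# simulate one replicate of `design` (plate 1) under `params` and return
# the statistic vector
.sim_stats_once <- function(params, design, switch_mode = "division") {
  sim <- .sim_design_plate(params, design, params,
                           n_plates = length(design$plates),
                           switch_mode = switch_mode)
  if (sim$extinct) return(NULL)
  founder_states <- setNames(ifelse(sim$founder_states == 1L, "P", "S"),
                             as.character(seq_along(sim$founder_states)))
  .stats_core(sim$state, sim$lineage, founder_states)
}

.grid_axes <- function(free_params, grid_size, log_spaced = TRUE) {
  lapply(free_params, function(rg) {
    stopifnot(length(rg) == 2, all(rg > 0), rg[2] > rg[1])
    if (log_spaced) exp(seq(log(rg[1]), log(rg[2]), length.out = grid_size))
    else seq(rg[1], rg[2], length.out = grid_size)
  })
}

#' Fit two-state parameters to observed summary statistics on a grid
#'
#' Simulation-based (ABC-style) inference: over a (log-spaced) grid of the
#' free parameters, each point simulates `sims_per_point` replicates of
#' the experimental design, averages their summary statistics, and is
#' scored by Euclidean distance to the observed statistics with each
#' component standardized by its replicate spread (estimated once from
#' pilot replicates at the grid midpoint; zero-spread components are
#' standardized by 1). Returns the minimizing point and the accepted set
#' (best `accept_frac` of points), a crude uncertainty region rather than
#' a posterior.
#'
#' @param observed observed [summary_stats()] vector.
#' @param free_params named list of `c(min, max)` ranges for the
#'   parameters to fit (names must be [two_state_params()] fields).
#' @param fixed a [two_state_params()] providing all other parameters.
#' @param design an [experiment_design()] describing how the observed data
#'   were generated.
#' @param grid_size grid points per axis.
#' @param sims_per_point simulation replicates per grid point.
#' @param seed optional integer seed.
#' @param accept_frac fraction of grid points in the accepted set.
#' @param vary_phase `"all"`: free parameters apply to expansion and
#'   treatment alike; `"treatment"`: only to the treatment phase (the
#'   expansion runs under `fixed`).
#' @param switch_mode passed to the simulator.
#' @param spread optional precomputed standardization spread (one value
#'   per statistic component); when supplied the pilot step is skipped.
#'   [scenario_selection()] uses this to score all scenarios on a common
#'   scale.
#' @return object of class `inference_result`: list with `best_params`,
#'   `best_point`, `grid` (data.frame of points and distances),
#'   `accepted`, `n_simulations`, `spread`, `seed`.
#' @export
fit_grid <- function(observed, free_params, fixed, design,
                     grid_size = 20L, sims_per_point = 10L, seed = NULL,
                     accept_frac = 0.01,
                     vary_phase = c("all", "treatment", "paired"),
                     switch_mode = "division", spread = NULL) {
  vary_phase <- match.arg(vary_phase)
  .check_seed(seed)
  axes <- .grid_axes(free_params, grid_size)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(free_params)

  sim_one <- function(overrides) {
    switch(vary_phase,
           all = .sim_stats_once(.apply_overrides(fixed, overrides),
                                 design, switch_mode),
           treatment = .sim_stats_treated(fixed, overrides, design,
                                          switch_mode),
           paired = .sim_stats_paired(fixed, overrides, design, switch_mode))
  }

  if (is.null(spread)) {
    # pilot replicates at the grid midpoint give the standardization spread
    mid <- lapply(axes, function(v) exp(mean(log(range(v)))))
    pilot <- lapply(seq_len(max(sims_per_point, 5L)), function(i) sim_one(mid))
    pilot <- do.call(cbind, pilot[!vapply(pilot, is.null, TRUE)])
    if (is.null(pilot)) {
      spread <- rep(1, length(observed))
    } else {
      spread <- apply(pilot, 1, sd)
      spread[spread < .Machine$double.eps] <- 1
    }
  }

  n_sim <- 0L
  dist <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ov <- as.list(grid[i, , drop = FALSE])
    acc <- NULL
    n_ok <- 0L
    for (s in seq_len(sims_per_point)) {
      st <- sim_one(ov)
      n_sim <- n_sim + 1L
      if (!is.null(st)) {
        acc <- if (is.null(acc)) st else acc + st
        n_ok <- n_ok + 1L
      }
    }
    if (n_ok == 0L) {
      dist[i] <- Inf
    } else {
      mu <- acc / n_ok
      dist[i] <- sqrt(sum(((mu - observed) / spread)^2))
    }
  }
  grid$distance <- dist
  best <- which.min(dist)
  n_acc <- max(1L, ceiling(accept_frac * nrow(grid)))
  accepted <- grid[order(dist)[seq_len(n_acc)], , drop = FALSE]
  best_point <- as.list(grid[best, names(free_params), drop = FALSE])
  structure(list(
    best_params = .apply_overrides(fixed, best_point),
    best_point = unlist(best_point),
    grid = grid,
    accepted = accepted,
    n_simulations = n_sim,
    spread = spread,
    seed = seed), class = "inference_result")
}

# treatment-phase-only variation: expansion under `fixed`, treatment under
# the overridden parameters
.sim_stats_treated <- function(fixed, overrides, design, switch_mode) {
  plate_params <- .apply_overrides(fixed, overrides)
  sim <- .sim_design_plate(fixed, design, plate_params,
                           n_plates = length(design$plates),
                           switch_mode = switch_mode)
  if (sim$extinct) return(NULL)
  founder_states <- setNames(ifelse(sim$founder_states == 1L, "P", "S"),
                             as.character(seq_along(sim$founder_states)))
  .stats_core(sim$state, sim$lineage, founder_states)
}

# paired split-plate simulation: one expansion under `fixed`, an untreated
# plate continued under `fixed` and a treated plate under the overrides;
# returns the treated per-plate statistics concatenated with the
# matched-lineage statistics against the untreated twin plate
.sim_stats_paired <- function(fixed, overrides, design, switch_mode) {
  plate_params <- .apply_overrides(fixed, overrides)
  fstates <- .as_founders(design$founders)
  dur <- design$expansion_doublings * log(2) / fixed$r_S
  mode_i <- if (switch_mode == "continuous") 1L else 0L
  res <- sim_twostate_cpp(fstates, seq_along(fstates),
                          fixed$r_S, fixed$r_P, fixed$d_S, fixed$d_P,
                          fixed$p_on, fixed$p_off, fixed$gamma,
                          dur, 5e6L, mode_i)
  if (length(res$state) == 0) return(NULL)
  n_plates <- max(2L, length(design$plates))
  assign <- sample.int(n_plates, length(res$state), replace = TRUE)
  one_plate <- function(k, p) {
    st <- res$state[assign == k]
    li <- res$lineage[assign == k]
    if (design$treatment_days > 0 && length(st) > 0) {
      r2 <- sim_twostate_cpp(st, li, p$r_S, p$r_P, p$d_S, p$d_P,
                             p$p_on, p$p_off, p$gamma,
                             design$treatment_days, 5e6L, mode_i)
      st <- r2$state
      li <- r2$lineage
    }
    n <- length(st)
    if (is.finite(design$capture) && design$capture < n) {
      idx <- sample.int(n, design$capture)
      st <- st[idx]
      li <- li[idx]
      n <- design$capture
    }
    if (design$barcode_detection_rate < 1 && n > 0)
      li[runif(n) >= design$barcode_detection_rate] <- NA_integer_
    list(state = st, lineage = li)
  }
  u <- one_plate(1L, fixed)
  t <- one_plate(2L, plate_params)
  if (length(t$state) == 0) return(NULL)
  founder_states <- setNames(ifelse(fstates == 1L, "P", "S"),
                             as.character(seq_along(fstates)))
  c(.stats_core(t$state, t$lineage, founder_states),
    .paired_core(u$state, u$lineage, t$state, t$lineage))
}

#' Rank single-parameter scenarios explaining a treatment effect
#'
#' A treatment that changes the primed-cell percentage can in principle be
#' explained by several single-parameter changes (faster primed growth,
#' selective killing, or state switching). Each named scenario fits only
#' its designated parameter to the treated summary statistics via
#' [fit_grid()] (expansion runs under the base parameters; the scenario
#' parameter applies to the treatment phase only); scenarios are ranked by
#' their best fit distance. Ties are broken toward the smallest relative
#' change from the base parameter (the null modification).
#'
#' @param untreated untreated [summary_stats()] (recorded for reference).
#' @param treated treated [summary_stats()] to fit.
#' @param scenarios named list; each element is
#'   `list(param = "<field>", range = c(min, max))`.
#' @param base a [two_state_params()] fitting the untreated data.
#' @param design an [experiment_design()] with a treatment phase.
#' @param seed optional integer seed.
#' @param grid_size,sims_per_point passed to [fit_grid()].
#' @param switch_mode passed to the simulator.
#' @param paired_observed optional [paired_lineage_stats()] vector for the
#'   observed untreated/treated pair. When supplied, each scenario is
#'   fitted against the treated statistics concatenated with the
#'   matched-lineage statistics, simulated from a paired split-plate
#'   design; this is what separates state switching from selective
#'   killing, which look alike in per-plate summaries.
#' @return data.frame ranked best-first: `scenario`, `param`,
#'   `fitted_value`, `base_value`, `distance`.
#' @export
scenario_selection <- function(untreated, treated, scenarios, base, design,
                               seed = NULL, grid_size = 10L,
                               sims_per_point = 5L,
                               switch_mode = "division",
                               paired_observed = NULL) {
  if (length(scenarios) < 2) stop("need at least 2 scenarios")
  .check_seed(seed)
  paired <- !is.null(paired_observed)
  observed <- if (paired) c(unclass(treated), paired_observed)
              else unclass(treated)
  phase <- if (paired) "paired" else "treatment"
  sim_null <- function(i) {
    if (paired) .sim_stats_paired(base, list(), design, switch_mode)
    else .sim_stats_treated(base, list(), design, switch_mode)
  }
  # a common standardization spread, estimated under the null modification,
  # keeps the scenario distances comparable
  pilot <- lapply(seq_len(max(sims_per_point, 8L)), sim_null)
  pilot <- do.call(cbind, pilot[!vapply(pilot, is.null, TRUE)])
  spread <- if (is.null(pilot)) rep(1, length(observed)) else apply(pilot, 1, sd)
  spread[spread < .Machine$double.eps] <- 1
  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    fit <- fit_grid(observed,
                    free_params = setNames(list(sc$range), sc$param),
                    fixed = base, design = design,
                    grid_size = grid_size, sims_per_point = sims_per_point,
                    seed = NULL, vary_phase = phase,
                    switch_mode = switch_mode, spread = spread)
    base_val <- base[[sc$param]]
    data.frame(scenario = nm, param = sc$param,
               fitted_value = unname(fit$best_point[1]),
               base_value = base_val,
               distance = min(fit$grid$distance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  null_dev <- abs(log(pmax(out$fitted_value, 1e-12) /
                        pmax(out$base_value, 1e-12)))
  out <- out[order(out$distance, null_dev), , drop = FALSE]
  rownames(out) <- NULL
  out
}
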