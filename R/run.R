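## Simulation drivers: the compiled engine (default) and the reference
## engine behind one interface, returning `ccr_trajectory` objects.

## Flat integer/real encoding of a model consumed by the compiled engine.
model_arrays <- function(spec, mode) {
  sl <- spec$slats
  rr <- mode_rates(spec, mode)
  list(
    type_is_growth = as.integer(sl$is_growth),
    type_copies = as.integer(ifelse(sl$is_growth, 1L, sl$copies)),
    type_half = as.integer(ifelse(is.na(sl$half), -1L, ifelse(sl$half == "A", 0L, 1L))),
    tsite_owner = match(spec$sites$slat, sl$slat) - 1L,
    pair_i = spec$compat$site_i - 1L,
    pair_j = spec$compat$site_j - 1L,
    pair_gg = as.integer(spec$compat$kind == "growth"),
    pair_wobble = as.integer(spec$compat$wobble),
    pair_toehold = as.integer(spec$compat$kind == "toehold"),
    k_off = rr$k_off, k_on_inter = rr$k_on_inter, k_on_intra = rr$k_on_intra,
    wobble_on = spec$config$wobble_on_factor,
    wobble_off = spec$config$wobble_off_factor)
}

#' Run one scission simulation
#'
#' Simulates the model from its initial state (intact ribbon; cut slats free
#' in solution, or one copy per type toehold-bound in prebound mode) by the
#' exact Gillespie algorithm until scission, `t_max`, `event_max`, or
#' candidate exhaustion. Time is in units of `1 / k_off`. The trajectory
#' records a sample whenever the tracked-complex size, the number of
#' complexes, the largest-complex size, or the number of half-bridging
#' complexes changes. Deterministic given `(spec, mode, seed)` for a fixed
#' engine.
#'
#' @param spec A `ccr_model`.
#' @param mode `"standard"` or `"prebound"`.
#' @param seed Integer seed for the replicate.
#' @param t_max Simulation horizon (default 3000 time units, several times
#'   the typical scission time of the default geometry, so that censoring is
#'   rare).
#' @param event_max Cap on applied events.
#' @param stop_on_scission Stop as soon as no complex contains growth slats
#'   of both ribbon halves (default `TRUE`).
#' @param engine `"compiled"` (fast, default) or `"reference"` (pure R,
#'   full re-enumeration each step; small models only).
#' @param log_events Keep the full event log (time, kind, site pair).
#' @param audit If `TRUE` (or an integer interval), the compiled engine
#'   verifies after every (or every nth) event that a full rebuild of the
#'   propensity set, the complex partition, site occupancy, degrees and
#'   per-type copy conservation all match the incrementally maintained
#'   state, and errors on any violation.
#' @param displaced_growth What happens to a growth slat that loses its last
#'   bond: `"recycle"` (free monomer, may rebind at intercomplex rates;
#'   default) or `"delete"` (removed from the system).
#' @return A `ccr_trajectory`.
#' @export
run_scission <- function(spec, mode = c("standard", "prebound"), seed = 1L,
                         t_max = 3000, event_max = 5e6,
                         stop_on_scission = TRUE,
                         engine = c("compiled", "reference"),
                         log_events = FALSE, audit = FALSE,
                         displaced_growth = c("recycle", "delete")) {
  stopifnot(inherits(spec, "ccr_model"))
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  displaced_growth <- match.arg(displaced_growth)
  audit_interval <- if (isTRUE(audit)) 1L else if (is.numeric(audit) && audit > 0) as.integer(audit) else 0L

  if (engine == "compiled") {
    set.seed(seed)
    raw <- ccr_run_cpp(model_arrays(spec, mode), mode == "prebound",
                       t_max, event_max, stop_on_scission,
                       log_events || audit_interval > 0L, audit_interval,
                       displaced_growth == "recycle")
    traj <- new_trajectory(spec, mode, seed, engine, raw)
  } else {
    traj <- run_reference(spec, mode, seed, t_max, event_max,
                          stop_on_scission, log_events)
  }
  traj
}

new_trajectory <- function(spec, mode, seed, engine, raw) {
  inst_map <- data.frame(
    inst = seq_along(raw$inst_type),
    type = spec$slats$slat[raw$inst_type],
    copy = raw$inst_copy,
    is_growth = spec$slats$is_growth[raw$inst_type],
    half = spec$slats$half[raw$inst_type])
  fb <- raw$final_bonds
  translate <- function(is) {
    data.frame(inst = raw$isite_inst[is],
               slat = inst_map$type[raw$isite_inst[is]],
               copy = inst_map$copy[raw$isite_inst[is]],
               site = spec$sites$name[raw$isite_tsite[is]])
  }
  final_bonds <- if (nrow(fb)) {
    a <- translate(fb$isite_i); b <- translate(fb$isite_j)
    names(a) <- paste0(names(a), "_i"); names(b) <- paste0(names(b), "_j")
    cbind(a, b)
  } else NULL
  events <- raw$events
  if (!is.null(events) && nrow(events)) {
    events$kind <- c("bind_inter", "bind_intra", "unbind")[events$kind]
    events$inst_i <- raw$isite_inst[events$isite_i]
    events$inst_j <- raw$isite_inst[events$isite_j]
    events$tsite_i <- raw$isite_tsite[events$isite_i]
    events$tsite_j <- raw$isite_tsite[events$isite_j]
  }
  fc <- raw$final_complexes
  fc$growth <- fc$growth_a + fc$growth_b
  structure(
    list(samples = raw$samples, events = events,
         termination = raw$termination, t_end = raw$t_end,
         n_events = raw$n_events, n_null = raw$n_null,
         initial_total_propensity = raw$initial_total_propensity,
         final_complexes = fc[order(-fc$size), , drop = FALSE],
         final_pool = stats::setNames(raw$pool, spec$slats$slat),
         inst_map = inst_map, final_bonds = final_bonds,
         n_growth_initial = sum(spec$slats$is_growth),
         seed = seed, mode = mode, engine = engine,
         condition = list(L = spec$config$L, E = spec$config$E,
                          R = spec$config$R,
                          n_wobble = if (is.null(spec$config$wobble_layout)) 0L
                                     else nrow(spec$config$wobble_layout))),
    class = "ccr_trajectory")
}

run_reference <- function(spec, mode, seed, t_max, event_max,
                          stop_on_scission, log_events) {
  state <- initial_state(spec, mode, seed)
  obs <- state_observables(state)
  samples <- list(data.frame(time = 0, tracked_complex_size = obs$tracked,
                             n_complexes = obs$n_complexes,
                             largest_complex_size = obs$largest,
                             bridging = obs$bridging))
  events <- list()
  termination <- "t_max"
  n_events <- 0L
  cand0 <- enumerate_candidates(state, spec)
  initial_total <- sum(cand0$propensity)
  if (stop_on_scission && obs$bridging == 0L) termination <- "scission"
  else repeat {
    cand <- if (n_events == 0L) cand0 else enumerate_candidates(state, spec)
    if (nrow(cand) == 0L) { termination <- "no_events"; break }
    total <- sum(cand$propensity)
    tau <- stats::rexp(1L, total)
    if (state$t + tau > t_max) { state$t <- t_max; termination <- "t_max"; break }
    u <- stats::runif(1L) * total
    k <- min(findInterval(u, cumsum(cand$propensity), left.open = TRUE) + 1L, nrow(cand))
    ev <- cand[k, ]
    state$t <- state$t + tau
    state <- apply_event(state, ev)
    n_events <- n_events + 1L
    if (log_events) { ev$time <- state$t; events[[length(events) + 1L]] <- ev }
    obs <- state_observables(state)
    last <- samples[[length(samples)]]
    if (obs$tracked != last$tracked_complex_size ||
        obs$largest != last$largest_complex_size ||
        obs$n_complexes != last$n_complexes || obs$bridging != last$bridging)
      samples[[length(samples) + 1L]] <- data.frame(
        time = state$t, tracked_complex_size = obs$tracked,
        n_complexes = obs$n_complexes, largest_complex_size = obs$largest,
        bridging = obs$bridging)
    if (stop_on_scission && obs$bridging == 0L) { termination <- "scission"; break }
    if (n_events >= event_max) { termination <- "event_max"; break }
  }
  samples <- do.call(rbind, samples)
  if (samples$time[nrow(samples)] != state$t)
    samples <- rbind(samples, data.frame(
      time = state$t, tracked_complex_size = obs$tracked,
      n_complexes = obs$n_complexes, largest_complex_size = obs$largest,
      bridging = obs$bridging))

  ## final complexes from scratch
  comp <- state_components(state)
  memb <- comp$membership
  keep <- comp$csize[memb] >= 2L
  fc <- if (any(keep)) {
    tab <- split(seq_len(nrow(state$inst))[keep], memb[keep])
    do.call(rbind, lapply(tab, function(ii) data.frame(
      size = length(ii),
      growth_a = sum(state$inst$is_growth[ii] & state$inst$half[ii] %in% "A"),
      growth_b = sum(state$inst$is_growth[ii] & state$inst$half[ii] %in% "B"))))
  } else data.frame(size = integer(), growth_a = integer(), growth_b = integer())
  fc$growth <- fc$growth_a + fc$growth_b
  bonded <- which(!is.na(state$partner) & seq_along(state$partner) < state$partner)
  mk_side <- function(is) data.frame(
    inst = state$isite$inst[is],
    slat = state$inst$type[state$isite$inst[is]],
    copy = state$inst$copy[state$isite$inst[is]],
    site = state$isite$name[is])
  final_bonds <- if (length(bonded)) {
    a <- mk_side(bonded); b <- mk_side(state$partner[bonded])
    names(a) <- paste0(names(a), "_i"); names(b) <- paste0(names(b), "_j")
    cbind(a, b)
  } else NULL
  deg <- inst_degree(state)
  pool_tab <- table(state$inst$type[!state$inst$is_growth & deg == 0L])
  structure(
    list(samples = samples,
         events = if (length(events)) do.call(rbind, events) else NULL,
         termination = termination, t_end = state$t,
         n_events = n_events, n_null = 0L,
         initial_total_propensity = initial_total,
         final_complexes = fc[order(-fc$size), , drop = FALSE],
         final_pool = pool_tab,
         inst_map = state$inst, final_bonds = final_bonds,
         n_growth_initial = sum(state$inst$is_growth),
         seed = seed, mode = mode, engine = "reference",
         condition = list(L = spec$config$L, E = spec$config$E,
                          R = spec$config$R,
                          n_wobble = if (is.null(spec$config$wobble_layout)) 0L
                                     else nrow(spec$config$wobble_layout))),
    class = "ccr_trajectory")
}

#' Run an ensemble of independent replicates
#'
#' Replicate `r` uses seed `base_seed + r`, so the ensemble is reproducible
#' from `(spec, mode, n, base_seed)` and replicates are independent.
#'
#' @inheritParams run_scission
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base seed; replicate seeds are `base_seed + 1:n`.
#' @param ... Passed on to [run_scission()].
#' @return List of `ccr_trajectory` objects, in replicate order.
#' @export
run_ensemble <- function(spec, mode = "standard", n_replicates = 100L,
                         base_seed = 0L, ...) {
  stopifnot(n_replicates >= 1L)
  lapply(seq_len(n_replicates), function(r)
    run_scission(spec, mode = mode, seed = base_seed + r, ...))
}

#' @export
print.ccr_trajectory <- function(x, ...) {
  cat(sprintf("Scission trajectory (%s engine, %s mode, seed %d)\n",
              x$engine, x$mode, x$seed))
  cat(sprintf("  L = %d, E = %d, R = %d, %d wobbles; %d growth slats\n",
              x$condition$L, x$condition$E, x$condition$R,
              x$condition$n_wobble, x$n_growth_initial))
  cat(sprintf("  %s after %.4g time units, %d events (%d null), %d samples\n",
              x$termination, x$t_end, as.integer(x$n_events),
              as.integer(x$n_null), nrow(x$samples)))
  fc <- x$final_complexes
  if (nrow(fc))
    cat(sprintf("  final complexes (size/growth A+B): %s\n",
                paste(sprintf("%d (%d+%d)", fc$size, fc$growth_a, fc$growth_b)[seq_len(min(4L, nrow(fc)))],
                      collapse = ", ")))
  invisible(x)
}

#' Plot the complex-size time course of a trajectory
#'
#' @param x A `ccr_trajectory`.
#' @param ... Passed to [plot()].
#' @export
plot.ccr_trajectory <- function(x, ...) {
  s <- x$samples
  plot(s$time, s$largest_complex_size, type = "s",
       xlab = sprintf("time (1/k_off units)"),
       ylab = "largest complex size (slats)", ...)
  graphics::lines(s$time, s$tracked_complex_size, type = "s", col = "grey50", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2), col = c("black", "grey50"),
                   legend = c("largest complex", "tracked complex"))
  invisible(x)
}
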