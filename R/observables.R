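#' Detect ribbon scission in a trajectory
#'
#' Primary (`half_label`) detector: scission is the first sampled time at
#' which no complex contains growth slats of both ribbon halves — the
#' ground-truth event, available because the model labels every growth slat
#' A or B. Secondary (`size_drop`) detector: the first sample at which the
#' largest complex size falls to at most `(1 - f)` times its running
#' maximum, the operational "sharp decrease in the maximum complex size"
#' criterion one would use without labels. Both are reported; when the spec
#' lacks half labels only `size_drop` is available.
#'
#' @param trajectory A `ccr_trajectory`.
#' @param spec The `ccr_model` it was simulated from (optional; used only
#'   to confirm half labels exist).
#' @param f Fractional size-drop threshold (default 0.3).
#' @return A one-row data frame of class `ccr_scission`: `scission_time`
#'   (primary; `NA` if censored), `censored`, `time_half_label`,
#'   `time_size_drop`, `detectors_agree` (within one sampled event),
#'   `product1`, `product2` (growth-slat counts of the two largest final
#'   complexes), `comparable` (both products >= 25% of the initial
#'   growth-slat count), `seed`, `t_end`, `termination`.
#' @export
detect_scission <- function(trajectory, spec = NULL, f = 0.3) {
  stopifnot(inherits(trajectory, "ccr_trajectory"))
  s <- trajectory$samples
  have_halves <- is.null(spec) || any(!is.na(spec$slats$half))

  ## half-label detector
  t_half <- NA_real_
  if (have_halves) {
    i <- which(s$bridging == 0L)[1]
    if (!is.na(i)) t_half <- s$time[i]
  }

  ## size-drop detector, with the index of the triggering sample
  runmax <- cummax(s$largest_complex_size)
  j <- which(s$largest_complex_size <= (1 - f) * runmax)[1]
  t_drop <- if (is.na(j)) NA_real_ else s$time[j]

  primary <- if (have_halves) t_half else t_drop
  censored <- is.na(primary)

  agree <- NA
  if (!is.na(t_half) && !is.na(t_drop)) {
    i <- which(s$bridging == 0L)[1]
    agree <- abs(i - j) <= 1L
  }

  fc <- trajectory$final_complexes
  growth <- sort(fc$growth, decreasing = TRUE)
  p1 <- if (length(growth) >= 1L) growth[1] else 0L
  p2 <- if (length(growth) >= 2L) growth[2] else 0L
  ng <- trajectory$n_growth_initial
  out <- data.frame(
    scission_time = primary, censored = censored,
    time_half_label = t_half, time_size_drop = t_drop,
    detectors_agree = agree,
    product1 = p1, product2 = p2,
    comparable = !censored && p1 >= 0.25 * ng && p2 >= 0.25 * ng,
    seed = trajectory$seed, t_end = trajectory$t_end,
    termination = trajectory$termination)
  class(out) <- c("ccr_scission", "data.frame")
  out
}

#' Scission results for an ensemble of trajectories
#'
#' @param trajectories List of `ccr_trajectory` (e.g. from
#'   [run_ensemble()]).
#' @param spec The `ccr_model`.
#' @param f Size-drop threshold, see [detect_scission()].
#' @return Data frame with one row per replicate.
#' @export
scission_results <- function(trajectories, spec = NULL, f = 0.3) {
  out <- do.call(rbind, lapply(trajectories, detect_scission, spec = spec, f = f))
  out$replicate <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize scission ensembles per condition
#'
#' Mean scission time is computed over detected (non-censored) replicates
#' only; censored replicates are counted and reported, never imputed. The
#' standard error is the sample standard deviation over the square root of
#' the detected count. With `normalize_to`, each condition mean (and SE) is
#' divided by the reference condition's mean, as in reporting mean time to
#' scission normalized to a reference slat length.
#'
#' @param results A data frame of per-replicate results carrying a
#'   `condition` column (see [sweep_conditions()]), or a list of such data
#'   frames named by condition, or a single [scission_results()] table
#'   (treated as one condition).
#' @param normalize_to Optional condition name whose mean becomes 1.
#' @return Data frame of class `ccr_summary`: `condition`, `n`, `detected`,
#'   `censored`, `mean_scission_time`, `se`, and, when normalizing,
#'   `normalized_mean` and `normalized_se`.
#' @export
summarize_ensemble <- function(results, normalize_to = NULL) {
  if (is.data.frame(results)) {
    if (is.null(results$condition)) results$condition <- "condition"
    results <- split(results, results$condition)
  } else if (is.null(names(results))) {
    names(results) <- paste0("condition_", seq_along(results))
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    det <- r[!r$censored, , drop = FALSE]
    data.frame(
      condition = nm, n = nrow(r), detected = nrow(det),
      censored = sum(r$censored),
      mean_scission_time = if (nrow(det)) mean(det$scission_time) else NA_real_,
      se = if (nrow(det) > 1L) stats::sd(det$scission_time) / sqrt(nrow(det)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  ## preserve the order conditions were supplied in
  out <- out[match(names(results), out$condition), , drop = FALSE]
  if (!is.null(normalize_to)) {
    if (!normalize_to %in% out$condition)
      stop("`normalize_to` names an unknown condition: ", normalize_to, call. = FALSE)
    ref <- out$mean_scission_time[out$condition == normalize_to]
    if (is.na(ref)) stop("Reference condition is all-censored; cannot normalize.", call. = FALSE)
    out$normalized_mean <- out$mean_scission_time / ref
    out$normalized_se <- out$se / ref
  }
  rownames(out) <- NULL
  class(out) <- c("ccr_summary", "data.frame")
  out
}

#' @export
print.ccr_summary <- function(x, digits = 4, ...) {
  cat("Scission ensemble summary\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Parameter sweep over model conditions
#'
#' Builds one model per grid row, runs an ensemble in the given mode, and
#' summarizes scission per condition. Every condition of one sweep uses the
#' same `base_seed` (replicate `r` of every condition runs with seed
#' `base_seed + r`), so the whole sweep is reproducible from
#' `(grid, base_seed)` and conditions are compared under common replicate
#' seeds. Invalid grid points are recorded as failed conditions and the
#' sweep continues.
#'
#' @param grid Data frame (or list coercible to one) whose columns may
#'   include `L`, `E`, `mode`, `include_cut_x`, `include_cut_y`,
#'   `n_wobble`, `wobble_arrangement` (see [wobble_arrangement()]), and a
#'   `wobble_layout` list-column of explicit layouts overriding `n_wobble`.
#'   Unspecified columns fall back to `base_config`.
#' @param base_config A [build_config()] supplying defaults for fields
#'   absent from the grid.
#' @param mode Default simulation mode for rows lacking a `mode` column.
#' @param n Replicates per condition.
#' @param base_seed Base seed shared by all conditions.
#' @param ... Passed to [run_scission()] (e.g. `t_max`).
#' @return A `ccr_summary` with one row per grid row (grid order), plus
#'   columns echoing the grid and `failed`/`message` for invalid points.
#'   The per-replicate tables are attached as `attr(, "results")`.
#' @export
sweep_conditions <- function(grid, base_config = build_config(L = 10),
                             mode = "standard", n = 100L, base_seed = 0L, ...) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("Empty sweep grid.", call. = FALSE)
  results <- list()
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    pick <- function(field, default) if (!is.null(row[[field]]) && !is.na(row[[field]][[1]])) row[[field]][[1]] else default
    cond_mode <- pick("mode", mode)
    label <- if (!is.null(row$condition)) as.character(row$condition) else {
      paste0("L", pick("L", base_config$L), "_E", pick("E", base_config$E),
             "_w", if (!is.null(row$wobble_layout)) nrow(row$wobble_layout[[1]]) else pick("n_wobble", 0L),
             "_", cond_mode,
             if (!isTRUE(pick("include_cut_x", base_config$include_cut_x))) "_noCX" else "",
             if (!isTRUE(pick("include_cut_y", base_config$include_cut_y))) "_noCY" else "")
    }
    res <- tryCatch({
      Lg <- pick("L", base_config$L)
      wl <- if (!is.null(row$wobble_layout)) row$wobble_layout[[1]]
            else if (!is.null(row$n_wobble) && !is.na(row$n_wobble) && row$n_wobble > 0L)
              wobble_arrangement(Lg, base_config$R, row$n_wobble,
                                 arrangement = pick("wobble_arrangement", "spread"))
            else base_config$wobble_layout
      cfg <- build_config(
        L = Lg, E = pick("E", base_config$E), R = pick("R", base_config$R),
        wobble_layout = wl,
        wobble_on_factor = pick("wobble_on_factor", base_config$wobble_on_factor),
        wobble_off_factor = pick("wobble_off_factor", base_config$wobble_off_factor),
        cut_excess = pick("cut_excess", base_config$cut_excess),
        include_cut_x = pick("include_cut_x", base_config$include_cut_x),
        include_cut_y = pick("include_cut_y", base_config$include_cut_y),
        rates = base_config$rates)
      spec <- build_scission_model(cfg)
      trajs <- run_ensemble(spec, mode = cond_mode, n_replicates = n,
                            base_seed = base_seed, ...)
      r <- scission_results(trajs, spec)
      r$condition <- label
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[g]] <- data.frame(condition = label, n = 0L, detected = 0L,
                              censored = 0L, mean_scission_time = NA_real_,
                              se = NA_real_, failed = TRUE,
                              message = conditionMessage(res))
    } else {
      results[[label]] <- res
      sm <- summarize_ensemble(stats::setNames(list(res), label))
      sm$failed <- FALSE
      sm$message <- ""
      rows[[g]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ccr_summary", "data.frame")
  attr(out, "results") <- results
  out
}
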