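#' Parameters of the coarse growth-and-cut population model
#'
#' The coarse model abstracts the full site-graph dynamics into two
#' ingredients: ribbons elongate deterministically and continuously at rate
#' `v` per growing end (one growing end per ribbon; a cut creates one new
#' growth front), and cut sites spaced every `Delta` length units along a
#' ribbon fire as independent single stochastic events. A cut site arms
#' once the repeat distal to it is complete — the ribbon must reach length
#' `(k+1)*Delta` for the site at `k*Delta` — and then fires after an
#' exponential waiting time with rate `lambda` (`Inf` means it fires the
#' moment it arms). Firing splits the ribbon at the site into two
#' independently growing ribbons.
#'
#' @param v Growth rate (length units per time per growing end), > 0.
#' @param Delta Spacing between consecutive cut sites (length units), > 0.
#' @param lambda Per-site cut hazard (1/time), >= 0; `Inf` for
#'   instantaneous cutting.
#' @param t_max Simulation horizon.
#' @param ell0 Initial length of the single seeded ribbon (default 0).
#' @return An object of class `ccr_coarse_params`.
#' @export
coarse_params <- function(v = 1, Delta = 1, lambda = 1, t_max = 10, ell0 = 0) {
  if (!isTRUE(v > 0)) stop("`v` (growth rate) must be > 0.", call. = FALSE)
  if (!isTRUE(Delta > 0)) stop("`Delta` (cut interval) must be > 0.", call. = FALSE)
  if (!isTRUE(lambda >= 0)) stop("`lambda` (cut hazard) must be >= 0.", call. = FALSE)
  if (!isTRUE(t_max > 0)) stop("`t_max` must be > 0.", call. = FALSE)
  structure(list(v = v, Delta = Delta, lambda = lambda,
                 t_max = t_max, ell0 = ell0),
            class = "ccr_coarse_params")
}

#' Simulate the coarse growth-and-cut population model
#'
#' Exact event-driven simulation: between events every ribbon's length
#' increases linearly at rate `v`; events are cut-site formations
#' (deterministic times) and cut-site firings (exponential clocks drawn
#' when a site arms). A firing splits the ribbon exactly at the site, so
#' fragment lengths always sum to the parent length. Deterministic given
#' `seed`.
#'
#' @param params A [coarse_params()] object.
#' @param seed Integer seed.
#' @return An object of class `ccr_population`: list with `times` (event
#'   times, starting at 0), `counts` (ribbon count), `mass` (total length),
#'   `lengths` (list of per-ribbon length vectors at each sampled time),
#'   `cuts` (data frame of cut events: time, parent length, child lengths),
#'   and `params`.
#' @export
simulate_population <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ccr_coarse_params"))
  set.seed(seed)
  v <- params$v; Delta <- params$Delta; lam <- params$lambda
  t_max <- params$t_max

  ## per-ribbon state: length at time `t0`, number of armed sites, fire
  ## times of armed-but-unfired sites (absolute), all positions relative to
  ## the ribbon's non-growing origin
  len <- params$ell0
  armed <- list(numeric(0))     # absolute fire time per armed site position
  pos <- list(numeric(0))       # site positions (multiples of Delta)
  lens <- len
  t <- 0
  n_sites_armed <- floor(max(0, lens / Delta) - 1 + 1e-12)  # sites with distal repeat complete
  draw_fire <- function(now, n = 1L) {
    if (is.infinite(lam)) rep(now, n)
    else if (lam == 0) rep(Inf, n)
    else now + stats::rexp(n, lam)
  }
  if (n_sites_armed > 0) {
    pos[[1]] <- Delta * seq_len(n_sites_armed)
    armed[[1]] <- draw_fire(t, n_sites_armed)
  }

  times <- 0; counts <- 1L; mass <- lens
  lengths <- list(lens)
  cuts <- list()

  repeat {
    ## next arming per ribbon: ribbon i arms site k_i+1 (at (k_i+1)*Delta)
    ## when its length reaches (k_i+2)*Delta
    n <- length(lens)
    next_arm <- (lengths_needed <- (vapply(pos, length, 0L) + 2) * Delta)
    t_arm <- t + (next_arm - lens) / v
    t_fire <- vapply(armed, function(a) if (length(a)) min(a) else Inf, 0)
    i_arm <- which.min(t_arm); i_fire <- which.min(t_fire)
    t_next <- min(t_arm[i_arm], t_fire[i_fire])
    if (t_next > t_max || !is.finite(t_next)) {
      dt <- t_max - t
      lens <- lens + v * dt
      t <- t_max
      times <- c(times, t); counts <- c(counts, length(lens))
      mass <- c(mass, sum(lens)); lengths[[length(lengths) + 1L]] <- lens
      break
    }
    dt <- t_next - t
    lens <- lens + v * dt
    t <- t_next
    if (t_arm[i_arm] <= t_fire[i_fire]) {
      ## arm a new site on ribbon i_arm
      i <- i_arm
      k <- length(pos[[i]]) + 1L
      pos[[i]] <- c(pos[[i]], k * Delta)
      armed[[i]] <- c(armed[[i]], draw_fire(t))
    } else {
      ## fire the earliest armed site: split ribbon i at position x
      i <- i_fire
      j <- which.min(armed[[i]])
      x <- pos[[i]][j]
      parent <- lens[i]
      ## child A = [0, x): keeps origin, gains a fresh growth front
      ## child B = [x, parent): keeps the original growth front
      lenA <- x; lenB <- parent - x
      keepB <- pos[[i]] > x
      posB <- pos[[i]][keepB] - x
      armB <- armed[[i]][keepB]
      posA <- pos[[i]][pos[[i]] < x]
      armA <- armed[[i]][pos[[i]] < x]
      ## arming rule re-checked: a site is armed iff length >= pos + Delta;
      ## carried clocks are redrawn implicitly by keeping their old draws
      ## (memorylessness) but must be dropped if the distal repeat is now
      ## incomplete (can happen only for B's largest positions)
      okA <- lenA >= posA + Delta - 1e-9
      posA <- posA[okA]; armA <- armA[okA]
      okB <- lenB >= posB + Delta - 1e-9
      posB <- posB[okB]; armB <- armB[okB]
      lens[i] <- lenA; pos[[i]] <- posA; armed[[i]] <- armA
      lens <- c(lens, lenB); pos[[length(pos) + 1L]] <- posB
      armed[[length(armed) + 1L]] <- armB
      cuts[[length(cuts) + 1L]] <- data.frame(time = t, parent = parent,
                                              child1 = lenA, child2 = lenB)
      times <- c(times, t); counts <- c(counts, length(lens))
      mass <- c(mass, sum(lens)); lengths[[length(lengths) + 1L]] <- lens
    }
  }
  structure(
    list(times = times, counts = counts, mass = mass, lengths = lengths,
         cuts = if (length(cuts)) do.call(rbind, cuts) else
           data.frame(time = numeric(), parent = numeric(),
                      child1 = numeric(), child2 = numeric()),
         params = params, seed = seed),
    class = "ccr_population")
}

#' @export
print.ccr_population <- function(x, ...) {
  p <- x$params
  cat(sprintf("Coarse growth/cut population: v = %g, Delta = %g, lambda = %g\n",
              p$v, p$Delta, p$lambda))
  cat(sprintf("  t = %.4g: %d ribbons, total mass %.4g, %d cuts\n",
              x$times[length(x$times)], x$counts[length(x$counts)],
              x$mass[length(x$mass)], nrow(x$cuts)))
  invisible(x)
}

#' @export
plot.ccr_population <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$times, x$counts, type = "s", log = "y",
       xlab = "time", ylab = "ribbon count", ...)
  fin <- x$lengths[[length(x$lengths)]]
  graphics::hist(fin, breaks = seq(0, max(fin) + x$params$Delta / 4, by = x$params$Delta / 4),
                 main = "", xlab = "fragment length")
  invisible(x)
}

#' Amplification metrics of a population trajectory
#'
#' Fits the doubling time by least squares of `log2(count)` against time
#' over the exponential phase (samples with count >= 2), and bins the final
#' fragment lengths with bin width `Delta / 4`. With fewer than three
#' doublings the estimate is flagged low-confidence; with no cuts at all
#' (`lambda = 0`) the doubling time is undefined.
#'
#' @param traj A `ccr_population`.
#' @return List with `doubling_time` (`NA` if undefined), `low_confidence`,
#'   `n_doublings`, `final_lengths`, `histogram` (counts per bin of width
#'   `Delta/4`), `bin_breaks`.
#' @export
amplification_metrics <- function(traj) {
  stopifnot(inherits(traj, "ccr_population"))
  counts <- traj$counts; times <- traj$times
  n_doubl <- log2(max(counts))
  keep <- counts >= 2L
  doubling <- NA_real_
  if (sum(keep) >= 2L && max(counts) > min(counts[keep])) {
    fit <- stats::lm.fit(cbind(1, times[keep]), log2(counts[keep]))
    slope <- fit$coefficients[2]
    if (is.finite(slope) && slope > 0) doubling <- 1 / slope
  }
  fin <- traj$lengths[[length(traj$lengths)]]
  bw <- traj$params$Delta / 4
  breaks <- seq(0, (floor(max(fin) / bw) + 1) * bw, by = bw)
  h <- graphics::hist(fin, breaks = breaks, plot = FALSE)
  list(doubling_time = unname(doubling),
       low_confidence = n_doubl < 3,
       n_doublings = n_doubl,
       final_lengths = fin,
       histogram = h$counts,
       bin_breaks = breaks)
}
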