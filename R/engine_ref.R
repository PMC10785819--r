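## Reference simulation engine: a direct, unoptimized transcription of the
## event semantics. Every cut-slat copy is instantiated concretely and the
## candidate set is re-enumerated from scratch at each step, so this path is
## practical only for small models; run_scission() uses the compiled engine
## by default and this one serves as its semantic cross-check.

mode_rates <- function(spec, mode = c("standard", "prebound")) {
  mode <- match.arg(mode)
  r <- spec$rates
  if (mode == "standard") {
    list(k_off = r$k_off, k_on_inter = r$k_on_inter, k_on_intra = r$k_on_intra)
  } else {
    list(k_off = r$prebound_k_off, k_on_inter = r$prebound_k_on_inter,
         k_on_intra = r$alpha * r$prebound_k_on_inter)
  }
}

#' Initial simulation state
#'
#' Instantiates the dynamic state of a model: in standard mode the intact
#' ribbon with every cut-slat copy free in solution; in prebound mode
#' additionally one copy of each cut-slat type bound to the ribbon by all
#' `E` of its toeholds, with the prebound rate set (off 0.8, inter on 0.05,
#' intra on `alpha * 0.05`).
#'
#' @param spec A `ccr_model`.
#' @param mode `"standard"` or `"prebound"`.
#' @param seed Integer seed; stored in the state and used to initialize the
#'   generator for subsequent [gillespie_step()] draws.
#' @return An object of class `ccr_state`.
#' @export
initial_state <- function(spec, mode = c("standard", "prebound"), seed = 1L) {
  stopifnot(inherits(spec, "ccr_model"))
  mode <- match.arg(mode)
  sl <- spec$slats
  copies <- ifelse(sl$is_growth, 1L, sl$copies)
  inst <- data.frame(
    inst = seq_len(sum(copies)),
    type = rep(sl$slat, copies),
    copy = unlist(lapply(copies, seq_len)),
    is_growth = rep(sl$is_growth, copies),
    half = rep(sl$half, copies))

  nsites_of_type <- table(spec$sites$slat)[inst$type]
  isite <- data.frame(
    inst = rep(inst$inst, nsites_of_type),
    tsite = unlist(lapply(inst$type, function(ty)
      spec$sites$site[spec$sites$slat == ty]), use.names = FALSE))
  isite$role <- spec$sites$role[isite$tsite]
  isite$name <- spec$sites$name[isite$tsite]
  isite$isite <- seq_len(nrow(isite))

  ## instance-level expansion of the template compatibility map
  tsite_owner <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
  tsite_owner_j <- spec$sites$slat[match(spec$compat$site_j, spec$sites$site)]
  ikey <- paste(isite$inst, isite$tsite)
  inst_by_type <- split(inst$inst, inst$type)
  ipair_list <- lapply(seq_len(nrow(spec$compat)), function(p) {
    row <- spec$compat[p, ]
    g <- expand.grid(a = inst_by_type[[tsite_owner[p]]],
                     b = inst_by_type[[tsite_owner_j[p]]])
    data.frame(tpair = row$pair,
               isite_i = isite$isite[match(paste(g$a, row$site_i), ikey)],
               isite_j = isite$isite[match(paste(g$b, row$site_j), ikey)],
               kind = row$kind, wobble = row$wobble, cross = row$cross)
  })
  ipairs <- do.call(rbind, ipair_list)
  ipairs$ipair <- seq_len(nrow(ipairs))
  rownames(ipairs) <- NULL

  partner <- rep(NA_integer_, nrow(isite))
  bond_tpair <- rep(NA_integer_, nrow(isite))
  bind_pair <- function(p) {
    partner[ipairs$isite_i[p]] <<- ipairs$isite_j[p]
    partner[ipairs$isite_j[p]] <<- ipairs$isite_i[p]
    bond_tpair[ipairs$isite_i[p]] <<- ipairs$tpair[p]
    bond_tpair[ipairs$isite_j[p]] <<- ipairs$tpair[p]
  }
  for (p in which(ipairs$kind == "growth")) bind_pair(p)
  if (mode == "prebound") {
    ## first copy of each cut type engages all its toeholds
    first_copy <- inst$inst[!inst$is_growth & inst$copy == 1L]
    is_toe <- ipairs$kind == "toehold"
    cut_side <- ifelse(isite$role[ipairs$isite_i] == "toehold",
                       isite$inst[ipairs$isite_i], isite$inst[ipairs$isite_j])
    for (p in which(is_toe & cut_side %in% first_copy)) bind_pair(p)
  }

  state <- structure(
    list(inst = inst, isite = isite, ipairs = ipairs,
         partner = partner, bond_tpair = bond_tpair,
         removed = rep(FALSE, nrow(inst)),
         t = 0, mode = mode, seed = as.integer(seed),
         rates = mode_rates(spec, mode),
         wobble_on = spec$config$wobble_on_factor,
         wobble_off = spec$config$wobble_off_factor),
    class = "ccr_state")
  set.seed(seed)
  state
}

inst_degree <- function(state) {
  bonded <- !is.na(state$partner)
  tabulate(state$isite$inst[bonded], nbins = nrow(state$inst))
}

## adjacency list instance -> bonded partner instances (with multiplicity)
inst_adjacency <- function(state) {
  bonded <- which(!is.na(state$partner))
  from <- state$isite$inst[bonded]
  to <- state$isite$inst[state$partner[bonded]]
  split(to, factor(from, levels = state$inst$inst))
}

## TRUE iff a bond path of <= `hops` bonds joins instances a and b
path_within <- function(adj, a, b, hops = 3L) {
  if (a == b) return(TRUE)
  frontier <- a
  seen <- a
  for (d in seq_len(hops)) {
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
    if (b %in% frontier) return(TRUE)
    frontier <- setdiff(frontier, seen)
    if (!length(frontier)) return(FALSE)
    seen <- c(seen, frontier)
  }
  FALSE
}

#' Three-point locality constraint
#'
#' Two slats of one complex are "local" iff the bond graph joins them
#' through at most two intermediate slats (a path of at most three bonds),
#' the graph proxy for physical proximity that gates every intracomplex
#' binding event.
#'
#' @param state A `ccr_state`.
#' @param inst_a,inst_b Instance ids of two slats in the same complex.
#' @return `TRUE` or `FALSE`. Slats in different complexes are rejected
#'   with an error, since the constraint is defined within one complex.
#' @export
locality_satisfied <- function(state, inst_a, inst_b) {
  stopifnot(inherits(state, "ccr_state"))
  adj <- inst_adjacency(state)
  comp <- state_components(state)$membership
  if (comp[inst_a] != comp[inst_b])
    stop("Slats are in different complexes; locality is undefined across complexes.", call. = FALSE)
  path_within(adj, inst_a, inst_b, 3L)
}

state_components <- function(state) {
  bonded <- which(!is.na(state$partner) & seq_along(state$partner) < state$partner)
  n <- nrow(state$inst)
  g <- igraph::graph_from_edgelist(
    cbind(state$isite$inst[bonded], state$isite$inst[state$partner[bonded]]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)
}

#' Enumerate event candidates in the current state
#'
#' Builds the complete candidate set: one unbind candidate per bond
#' (propensity `k_off`, scaled by the wobble off-factor for wobbled
#' growth-growth bonds); intercomplex binds between a free site on a free
#' monomer and a free site on an in-complex slat (propensity `k_on_inter`
#' per free copy, wobble on-factor applied to wobbled growth bonds); and
#' intracomplex binds between free compatible sites of two in-complex slats
#' that satisfy the three-point locality constraint (`k_on_intra`, same
#' wobble scaling). Binding between two free monomers and between two
#' distinct complexes is excluded: the system is one ribbon plus free slats.
#'
#' @param state A `ccr_state`.
#' @param spec The `ccr_model` the state was built from.
#' @return Data frame with columns `kind` (`bind_inter`, `bind_intra`,
#'   `unbind`), `isite_i`, `isite_j`, `tpair`, `propensity`.
#' @export
enumerate_candidates <- function(state, spec) {
  stopifnot(inherits(state, "ccr_state"))
  r <- state$rates
  ip <- state$ipairs
  deg <- inst_degree(state)
  removed <- state$removed
  own_i <- state$isite$inst[ip$isite_i]
  own_j <- state$isite$inst[ip$isite_j]

  bonded <- !is.na(state$partner[ip$isite_i]) &
    state$partner[ip$isite_i] == ip$isite_j
  out <- list()
  if (any(bonded)) {
    w <- ip$wobble[bonded] & ip$kind[bonded] == "growth"
    out$unbind <- data.frame(
      kind = "unbind", isite_i = ip$isite_i[bonded], isite_j = ip$isite_j[bonded],
      tpair = ip$tpair[bonded],
      propensity = r$k_off * ifelse(w, state$wobble_off, 1))
  }

  free_pair <- is.na(state$partner[ip$isite_i]) & is.na(state$partner[ip$isite_j]) &
    !removed[own_i] & !removed[own_j]
  cand <- which(free_pair)
  if (length(cand)) {
    di <- deg[own_i[cand]]; dj <- deg[own_j[cand]]
    won <- ifelse(ip$wobble[cand] & ip$kind[cand] == "growth", state$wobble_on, 1)
    inter <- xor(di == 0L, dj == 0L)
    if (any(inter)) {
      out$inter <- data.frame(
        kind = "bind_inter",
        isite_i = ip$isite_i[cand[inter]], isite_j = ip$isite_j[cand[inter]],
        tpair = ip$tpair[cand[inter]],
        propensity = r$k_on_inter * won[inter])
    }
    intra <- di > 0L & dj > 0L
    if (any(intra)) {
      adj <- inst_adjacency(state)
      keep <- vapply(cand[intra], function(p)
        path_within(adj, own_i[p], own_j[p], 3L), logical(1))
      ii <- cand[intra][keep]
      if (length(ii)) {
        out$intra <- data.frame(
          kind = "bind_intra", isite_i = ip$isite_i[ii], isite_j = ip$isite_j[ii],
          tpair = ip$tpair[ii],
          propensity = r$k_on_intra * won[intra][keep])
      }
    }
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res))
    res <- data.frame(kind = character(), isite_i = integer(), isite_j = integer(),
                      tpair = integer(), propensity = numeric())
  rownames(res) <- NULL
  res
}

#' One exact Gillespie step
#'
#' Draws the waiting time to the next event from an exponential with rate
#' equal to the total propensity, selects the event proportionally to its
#' propensity, and applies it. Draws come from R's global generator, so a
#' state initialized with a given seed evolves deterministically.
#'
#' @param state A `ccr_state`.
#' @param spec The `ccr_model`.
#' @param candidates Optionally, a precomputed [enumerate_candidates()]
#'   table for this state.
#' @return A list with `state` (updated) and `event` (a one-row data frame,
#'   or `NULL` when the candidate set is empty, which signals `no_events`
#'   termination).
#' @export
gillespie_step <- function(state, spec, candidates = NULL) {
  if (is.null(candidates)) candidates <- enumerate_candidates(state, spec)
  if (nrow(candidates) == 0L)
    return(list(state = state, event = NULL))
  total <- sum(candidates$propensity)
  tau <- stats::rexp(1L, rate = total)
  u <- stats::runif(1L) * total
  k <- findInterval(u, cumsum(candidates$propensity), left.open = TRUE) + 1L
  k <- min(k, nrow(candidates))
  ev <- candidates[k, ]
  state$t <- state$t + tau
  state <- apply_event(state, ev)
  ev$time <- state$t
  list(state = state, event = ev)
}

apply_event <- function(state, ev) {
  if (ev$kind == "unbind") {
    state$partner[c(ev$isite_i, ev$isite_j)] <- NA_integer_
    state$bond_tpair[c(ev$isite_i, ev$isite_j)] <- NA_integer_
  } else {
    state$partner[ev$isite_i] <- ev$isite_j
    state$partner[ev$isite_j] <- ev$isite_i
    state$bond_tpair[c(ev$isite_i, ev$isite_j)] <- ev$tpair
  }
  state
}

## Observables of the current state, computed from scratch.
state_observables <- function(state) {
  comp <- state_components(state)
  sizes <- comp$csize
  in_complex <- sizes[comp$membership] >= 2L
  memb <- ifelse(in_complex, comp$membership, NA_integer_)
  cs <- table(memb[!is.na(memb)])
  gA <- tapply(state$inst$is_growth & state$inst$half %in% "A", memb, sum)
  gB <- tapply(state$inst$is_growth & state$inst$half %in% "B", memb, sum)
  bridging <- sum(gA > 0 & gB > 0, na.rm = TRUE)
  tracked_comp <- memb[1L]  # complex holding the first growth slat (GX1-side anchor)
  list(
    n_complexes = length(cs),
    largest = if (length(cs)) max(cs) else 0L,
    bridging = bridging,
    tracked = if (is.na(tracked_comp)) 1L else sum(memb == tracked_comp, na.rm = TRUE))
}
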