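## Independent continuous-time Markov chain oracle for tiny models.
##
## The event semantics are re-implemented here directly from their
## definition (site occupancy, monomer/complex molecularity, three-point
## locality), deliberately sharing no code with the engines. States are
## bond subsets (valid only for cut_excess = 1, where instance level equals
## template level); the chain is enumerated exhaustively and mean first
## passage to scission is obtained from the linear first-step equations.

oracle_env <- function(spec) {
  cpt <- spec$compat
  slat_i <- spec$sites$slat[match(cpt$site_i, spec$sites$site)]
  slat_j <- spec$sites$slat[match(cpt$site_j, spec$sites$site)]
  growth <- spec$slats$slat[spec$slats$is_growth]
  half <- setNames(spec$slats$half, spec$slats$slat)
  rates <- crisscut:::mode_rates(spec, "standard")
  list(cpt = cpt, slat_i = slat_i, slat_j = slat_j,
       growth = growth, half = half, rates = rates,
       initial = cpt$pair[cpt$kind == "growth"])
}

## is the state (a set of bonded template pairs) past scission?
oracle_absorbed <- function(env, bonds) {
  if (!length(bonds)) return(TRUE)
  ed <- cbind(env$slat_i[bonds], env$slat_j[bonds])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  for (c in seq_len(comp$no)) {
    mem <- names(comp$membership)[comp$membership == c]
    h <- env$half[intersect(mem, env$growth)]
    if (any(h %in% "A") && any(h %in% "B")) return(FALSE)
  }
  TRUE
}

## all outgoing transitions of a transient state: list of (bonds', rate)
oracle_transitions <- function(env, bonds) {
  cpt <- env$cpt
  out <- list()
  for (b in bonds)
    out[[length(out) + 1L]] <- list(bonds = setdiff(bonds, b), rate = env$rates$k_off)

  used_sites <- c(cpt$site_i[bonds], cpt$site_j[bonds])
  deg <- table(c(env$slat_i[bonds], env$slat_j[bonds]))
  degree_of <- function(s) if (s %in% names(deg)) deg[[s]] else 0L

  ## slat-level adjacency for the locality search
  adj <- split(c(env$slat_j[bonds], env$slat_i[bonds]),
               c(env$slat_i[bonds], env$slat_j[bonds]))
  within3 <- function(a, b) {
    f <- a
    for (d in 1:3) {
      f <- unique(unlist(adj[f], use.names = FALSE))
      if (b %in% f) return(TRUE)
      if (!length(f)) return(FALSE)
    }
    FALSE
  }
  for (p in setdiff(cpt$pair, bonds)) {
    if (cpt$site_i[p] %in% used_sites || cpt$site_j[p] %in% used_sites) next
    da <- degree_of(env$slat_i[p]); db <- degree_of(env$slat_j[p])
    rate <- if (da == 0L && db == 0L) 0
            else if (da == 0L || db == 0L) env$rates$k_on_inter
            else if (within3(env$slat_i[p], env$slat_j[p])) env$rates$k_on_intra
            else 0
    if (rate > 0)
      out[[length(out) + 1L]] <- list(bonds = sort(c(bonds, p)), rate = rate)
  }
  out
}

state_key <- function(bonds) paste(bonds, collapse = ",")

## enumerate the reachable chain and solve the first-step equations for the
## mean first-passage time from the initial state to the marked set
## (default: scission)
oracle_mfpt <- function(spec, max_states = 50000L, absorbed_fn = NULL) {
  env <- oracle_env(spec)
  if (is.null(absorbed_fn)) absorbed_fn <- function(env, bonds) oracle_absorbed(env, bonds)
  init <- sort(env$initial)
  keys <- state_key(init)
  states <- list(init)
  frontier <- 1L
  trans <- list()
  absorbed <- logical(0)
  while (length(frontier)) {
    nxt <- integer(0)
    for (si in frontier) {
      bonds <- states[[si]]
      if (absorbed_fn(env, bonds)) { absorbed[si] <- TRUE; trans[[si]] <- list(); next }
      absorbed[si] <- FALSE
      tr <- oracle_transitions(env, bonds)
      ids <- integer(length(tr))
      for (k in seq_along(tr)) {
        key <- state_key(tr[[k]]$bonds)
        id <- match(key, keys)
        if (is.na(id)) {
          states[[length(states) + 1L]] <- tr[[k]]$bonds
          keys <- c(keys, key)
          id <- length(states)
          nxt <- c(nxt, id)
        }
        ids[k] <- id
      }
      trans[[si]] <- Map(function(t, id) list(id = id, rate = t$rate), tr, ids)
    }
    frontier <- nxt
    if (length(states) > max_states) stop("oracle state space too large")
  }
  n <- length(states)
  tidx <- which(!absorbed)
  m <- length(tidx)
  pos <- match(seq_len(n), tidx)
  A <- matrix(0, m, m)
  for (r in seq_len(m)) {
    si <- tidx[r]
    tot <- 0
    for (tr in trans[[si]]) {
      tot <- tot + tr$rate
      if (!absorbed[tr$id]) A[r, pos[tr$id]] <- A[r, pos[tr$id]] + tr$rate
    }
    A[r, r] <- A[r, r] - tot
  }
  h <- solve(-A, rep(1, m))
  list(mfpt = h[pos[1L]], n_states = n, n_transient = m)
}
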