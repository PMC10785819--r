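#' Build configuration for a crisscross scission model
#'
#' Collects the handful of integers and reals that fully determine a
#' site-graph model of a two-half crisscross ribbon with a cut interface:
#' the core slat length (ribbon width), the number of toehold segments per
#' cut slat, the repeat count, the wobble layout and strength, the kinetic
#' rate constants, and the cut-slat stoichiometry.
#'
#' @param L Core slat length: number of core binding sites per growth slat
#'   (the ribbon width). Must be an integer >= 2; a single-site slat admits
#'   no cross-interface bonds.
#' @param E Extension length: number of toehold segments per cut slat
#'   (integer >= 0, at most `L + 2`).
#' @param R Number of repeat units of growth slats in the ribbon (>= 1).
#' @param wobble_layout Growth-bond positions whose growth-side binding is
#'   weakened: a two-column data frame (or matrix) with columns `x` and `y`
#'   naming the X- and Y-slat indices of each wobbled bond, or `NULL` for
#'   none. See [cross_interface_layout()] for the canonical cut-interface
#'   positions.
#' @param wobble_on_factor Multiplier applied to growth-bond on-rates at
#'   wobble positions (default 2/3).
#' @param wobble_off_factor Multiplier applied to growth-bond off-rates at
#'   wobble positions (default 1.5).
#' @param cut_excess Free copies of each cut-slat type per single ribbon
#'   (default 100, i.e. a 100-fold excess over the one ribbon).
#' @param include_cut_x,include_cut_y Whether to include the cut-x and/or
#'   cut-y slat families (default both `TRUE`).
#' @param rates Kinetic rate constants, from [rate_params()].
#'
#' @return An object of class `ccr_config`.
#' @seealso [build_scission_model()], [rate_params()]
#' @export
build_config <- function(L, E = 5L, R = 2L,
                         wobble_layout = NULL,
                         wobble_on_factor = 2 / 3,
                         wobble_off_factor = 1.5,
                         cut_excess = 100L,
                         include_cut_x = TRUE,
                         include_cut_y = TRUE,
                         rates = rate_params()) {
  L <- as.integer(L); E <- as.integer(E); R <- as.integer(R)
  cut_excess <- as.integer(cut_excess)
  if (is.na(L) || L < 2L)
    stop("`L` must be an integer >= 2: a width-1 ribbon has no cross-interface bonds (L*(L-1)/2 = 0) and cannot be cut.", call. = FALSE)
  if (is.na(E) || E < 0L)
    stop("`E` (extension length) must be a non-negative integer.", call. = FALSE)
  if (E > L + 2L)
    stop("`E` must be <= L + 2: toehold host addressing runs off the ribbon for longer extensions.", call. = FALSE)
  if (is.na(R) || R < 1L)
    stop("`R` (repeat count) must be an integer >= 1.", call. = FALSE)
  if (!isTRUE(wobble_on_factor > 0) || !isTRUE(wobble_off_factor > 0))
    stop("Wobble factors must be positive reals.", call. = FALSE)
  if (is.na(cut_excess) || cut_excess < 1L)
    stop("`cut_excess` must be an integer >= 1.", call. = FALSE)
  if (!is.null(wobble_layout)) {
    wobble_layout <- as.data.frame(wobble_layout)
    if (!all(c("x", "y") %in% names(wobble_layout)))
      stop("`wobble_layout` needs columns `x` and `y` (growth-bond slat indices).", call. = FALSE)
    wobble_layout <- data.frame(x = as.integer(wobble_layout$x),
                                y = as.integer(wobble_layout$y))
  }
  stopifnot(inherits(rates, "ccr_rates"))
  structure(
    list(L = L, E = E, R = R,
         wobble_layout = wobble_layout,
         wobble_on_factor = wobble_on_factor,
         wobble_off_factor = wobble_off_factor,
         cut_excess = cut_excess,
         include_cut_x = isTRUE(include_cut_x),
         include_cut_y = isTRUE(include_cut_y),
         rates = rates),
    class = "ccr_config")
}

#' Kinetic rate constants for the scission model
#'
#' Off-rates define the time unit (`k_off = 1`). The intracomplex on-rate is
#' tied to the intercomplex on-rate through `alpha`, the ratio of intra- to
#' intercomplex on-rate at unit reference concentration, which encodes the
#' positional-entropy loss upon capture of a free monomer from solution.
#' The `prebound_*` constants parameterize runs started with cut slats
#' already toehold-bound, where binding must be weak enough to exchange but
#' strong enough that cut slats remain engaged.
#'
#' @param k_off Off-rate of any bond (default 1; sets the time unit).
#' @param k_on_inter Intercomplex on-rate per free monomer copy (default 0.04).
#' @param alpha Intra/intercomplex on-rate ratio at unit concentration
#'   (default 1000).
#' @param k_on_intra Intracomplex on-rate; defaults to `alpha * k_on_inter`
#'   and must equal it if both are given.
#' @param prebound_k_on_inter,prebound_k_off Rates used in prebound mode
#'   (defaults 0.05 and 0.8). The prebound intracomplex on-rate is
#'   `alpha * prebound_k_on_inter`.
#' @return An object of class `ccr_rates`.
#' @export
rate_params <- function(k_off = 1, k_on_inter = 0.04, alpha = 1000,
                        k_on_intra = alpha * k_on_inter,
                        prebound_k_on_inter = 0.05, prebound_k_off = 0.8) {
  vals <- c(k_off = k_off, k_on_inter = k_on_inter, alpha = alpha,
            k_on_intra = k_on_intra,
            prebound_k_on_inter = prebound_k_on_inter,
            prebound_k_off = prebound_k_off)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("All rate constants must be positive finite reals.", call. = FALSE)
  if (abs(k_on_intra - alpha * k_on_inter) > 1e-9 * k_on_intra)
    stop("Inconsistent rates: `k_on_intra` must equal `alpha * k_on_inter`.", call. = FALSE)
  structure(as.list(vals), class = "ccr_rates")
}

## Diagonal bond rule of the canonical stagger-1 parallelogram: growth slats
## X_i (i = 1..N, N = R*L) and Y_j (j = 1..N+L-1); bond (X_i, Y_j) exists iff
## 0 <= j - i <= L - 1. Returns the full (unpruned) layout.
full_bond_layout <- function(L, R) {
  N <- R * L
  i <- rep(seq_len(N), each = L)
  j <- i + rep(0:(L - 1L), times = N)
  keep <- j <= N + L - 1L
  data.frame(x = i[keep], y = j[keep])
}

#' Canonical cut-interface bond positions for a ribbon geometry
#'
#' Enumerates the growth bonds that join the A half (slat indices `<=
#' floor(N/2)`, `N = R*L`) to the B half, in canonical order (by X index,
#' then Y index). These are the bonds severed at scission, and the positions
#' eligible for wobble placement in the provided sweep utilities.
#'
#' @param L Core slat length.
#' @param R Repeat count.
#' @return Data frame with integer columns `x` and `y`.
#' @export
cross_interface_layout <- function(L, R = 2L) {
  lay <- full_bond_layout(as.integer(L), as.integer(R))
  n2 <- (as.integer(R) * as.integer(L)) %/% 2L
  out <- lay[lay$x <= n2 & lay$y > n2, , drop = FALSE]
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick a wobble layout on the cut interface
#'
#' Convenience selector of `n` cross-interface bonds to weaken. The
#' `"spread"` arrangement spaces the wobbles evenly along the canonical
#' cross-bond order; `"block"` takes a contiguous run starting at `offset`;
#' `"random"` samples positions uniformly (reproducible via `seed`).
#'
#' @param L,R Ribbon geometry, as in [cross_interface_layout()].
#' @param n Number of wobble positions.
#' @param arrangement One of `"spread"`, `"block"`, `"random"`.
#' @param offset Start position (1-based) for the `"block"` arrangement.
#' @param seed Seed for the `"random"` arrangement.
#' @return A wobble layout data frame usable as `wobble_layout` in
#'   [build_config()].
#' @export
wobble_arrangement <- function(L, R = 2L, n = 5L,
                               arrangement = c("spread", "block", "random"),
                               offset = 1L, seed = NULL) {
  arrangement <- match.arg(arrangement)
  xb <- cross_interface_layout(L, R)
  m <- nrow(xb)
  n <- as.integer(n)
  if (n < 0L || n > m)
    stop(sprintf("Cannot place %d wobbles on %d cross-interface bonds.", n, m), call. = FALSE)
  if (n == 0L) return(xb[integer(0), , drop = FALSE])
  idx <- switch(arrangement,
    spread = unique(round(seq(1L, m, length.out = n))),
    block = {
      if (offset < 1L || offset + n - 1L > m)
        stop("`block` arrangement runs past the interface.", call. = FALSE)
      seq(offset, offset + n - 1L)
    },
    random = {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(seed)
      }
      sort(sample.int(m, n))
    })
  out <- xb[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

clamp_int <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Build the site-graph model of a crisscross ribbon with a cut interface
#'
#' Programmatically generates the full static description of a scission
#' simulation system: one intact ribbon of `R*L` X growth slats and the
#' matching Y slats (diagonal bond rule `0 <= j - i <= L - 1`, terminal
#' slats with fewer than two bonds pruned), split into halves A and B at
#' `floor(N/2)`; one cut-y slat type per B-half Y slat holding cross-bonds
#' and one cut-x type per A-half X slat holding cross-bonds, each carrying
#' competed sites that mirror the cross-bond sites it invades plus `E`
#' dedicated toehold sites bound to extension-host sites on the half it
#' will cap; and the full site-compatibility map and initial bond set.
#'
#' Toehold `k` of cut-y slat `CY_j` is hosted on `X_{j-L+k-1}` and toehold
#' `k` of cut-x slat `CX_i` on `Y_{i+L-1+k}`, each host index clamped to the
#' kept slats of the half the cut slat caps (extensions pile up on the
#' boundary or terminal slat). The clamp keeps every extension host in
#' range for any `E <= L + 2` and guarantees that no cut slat can ever
#' bond growth slats of both halves — cut slats must cap a half, not
#' bridge the interface.
#'
#' @param config A [build_config()] object.
#' @return An object of class `ccr_model`: a list with elements `config`,
#'   `rates`, `slats`, `sites`, `compat` (all compatible site pairs, with
#'   growth/competed/toehold kind, wobble and cross-interface flags),
#'   `initial_bonds` (the intact ribbon), and `n_half` (the half
#'   coordination number `floor(L/2)`).
#' @examples
#' m <- build_scission_model(build_config(L = 4, E = 2))
#' m
#' nrow(cross_interface_bonds(m))  # L*(L-1)/2 = 6
#' @export
build_scission_model <- function(config) {
  stopifnot(inherits(config, "ccr_config"))
  L <- config$L; E <- config$E; R <- config$R
  N <- R * L
  n2 <- N %/% 2L

  lay <- full_bond_layout(L, R)
  ## single-pass pruning of slats with < 2 bonds in the full layout
  xb_deg <- tabulate(lay$x, nbins = N)
  yb_deg <- tabulate(lay$y, nbins = N + L - 1L)
  kept_x <- which(xb_deg >= 2L)
  kept_y <- which(yb_deg >= 2L)
  lay <- lay[lay$x %in% kept_x & lay$y %in% kept_y, , drop = FALSE]
  if (nrow(lay) == 0L) stop("Degenerate ribbon: no growth bonds survive pruning.", call. = FALSE)

  half_of <- function(idx) ifelse(idx <= n2, "A", "B")
  cross <- lay$x <= n2 & lay$y > n2
  if (!any(cross))
    stop("Degenerate ribbon: no cross-interface bonds (increase L).", call. = FALSE)

  ## wobble flags on growth bonds
  wob <- rep(FALSE, nrow(lay))
  wl <- config$wobble_layout
  if (!is.null(wl) && nrow(wl)) {
    key <- paste(lay$x, lay$y)
    wkey <- paste(wl$x, wl$y)
    missing <- setdiff(wkey, key)
    if (length(missing))
      stop("wobble_layout names growth bonds absent from the ribbon: ",
           paste(missing, collapse = ", "), call. = FALSE)
    wob <- key %in% wkey
  }

  ## cut types
  cy_idx <- if (config$include_cut_y) sort(unique(lay$y[cross])) else integer(0)
  cx_idx <- if (config$include_cut_x) sort(unique(lay$x[cross])) else integer(0)

  slats <- rbind(
    data.frame(slat = paste0("GX", kept_x), orientation = "GROWTH_X",
               index = kept_x, half = half_of(kept_x), copies = 1L),
    data.frame(slat = paste0("GY", kept_y), orientation = "GROWTH_Y",
               index = kept_y, half = half_of(kept_y), copies = 1L),
    if (length(cy_idx))
      data.frame(slat = paste0("CY", cy_idx), orientation = "CUT_Y",
                 index = cy_idx, half = NA_character_, copies = config$cut_excess),
    if (length(cx_idx))
      data.frame(slat = paste0("CX", cx_idx), orientation = "CUT_X",
                 index = cx_idx, half = NA_character_, copies = config$cut_excess))
  slats$is_growth <- slats$orientation %in% c("GROWTH_X", "GROWTH_Y")
  rownames(slats) <- NULL

  ## --- sites ------------------------------------------------------------
  ## core sites: position p on X_i pairs with Y_{i+p-1}; position q on Y_j
  ## pairs with X_{j-L+q}. Only positions with a kept partner bond exist.
  sites <- list()
  add_sites <- function(slat, role, site_index, name) {
    sites[[length(sites) + 1L]] <<- data.frame(
      slat = slat, role = role, site_index = as.integer(site_index), name = name)
  }
  add_sites(paste0("GX", lay$x), "core", lay$y - lay$x + 1L,
            paste0("c", lay$y - lay$x + 1L))
  add_sites(paste0("GY", lay$y), "core", lay$x - lay$y + L,
            paste0("c", lay$x - lay$y + L))

  ## cut-slat competed sites mirror the cross-bond sites they invade
  cross_lay <- lay[cross, , drop = FALSE]
  if (length(cy_idx)) {
    add_sites(paste0("CY", cross_lay$y), "competed", cross_lay$x,
              paste0("m", cross_lay$x))
  }
  if (length(cx_idx)) {
    add_sites(paste0("CX", cross_lay$x), "competed", cross_lay$y,
              paste0("m", cross_lay$y))
  }

  ## toeholds + dedicated extension hosts. Host indices are clamped to the
  ## kept slats of the half the cut slat caps (A-half X hosts for cut-y,
  ## B-half Y hosts for cut-x): a cut slat must never itself bridge the two
  ## halves, or it would hold the ribbon together after full displacement.
  toe <- NULL
  if (E > 0L) {
    mk_toe <- function(cut_prefix, cut_indices, host_fun, host_prefix, host_range) {
      if (!length(cut_indices)) return(NULL)
      g <- expand.grid(idx = cut_indices, k = seq_len(E))
      g$host <- clamp_int(host_fun(g$idx, g$k), min(host_range), max(host_range))
      data.frame(cut = paste0(cut_prefix, g$idx),
                 k = g$k,
                 host = paste0(host_prefix, g$host))
    }
    toe <- rbind(
      mk_toe("CY", cy_idx, function(j, k) j - L + k - 1L, "GX", kept_x[kept_x <= n2]),
      mk_toe("CX", cx_idx, function(i, k) i + L - 1L + k, "GY", kept_y[kept_y > n2]))
    if (!is.null(toe) && nrow(toe)) {
      add_sites(toe$cut, "toehold", toe$k, paste0("t", toe$k))
      add_sites(toe$host, "extension_host", seq_len(nrow(toe)),
                paste0("h", toe$cut, "t", toe$k))
    }
  }
  sites <- do.call(rbind, sites)
  sites <- sites[order(match(sites$slat, slats$slat), sites$role, sites$site_index), ]
  sites$site <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites <- sites[, c("site", "slat", "role", "site_index", "name")]

  site_id <- function(slat, name) {
    key <- paste(sites$slat, sites$name)
    m <- match(paste(slat, name), key)
    if (anyNA(m)) stop("internal: unresolved site address")
    sites$site[m]
  }

  ## --- compatibility map ------------------------------------------------
  gx_site <- site_id(paste0("GX", lay$x), paste0("c", lay$y - lay$x + 1L))
  gy_site <- site_id(paste0("GY", lay$y), paste0("c", lay$x - lay$y + L))
  compat <- data.frame(site_i = gx_site, site_j = gy_site, kind = "growth",
                       wobble = wob, cross = cross, x = lay$x, y = lay$y)

  if (length(cy_idx)) {
    cyl <- cross_lay
    compat <- rbind(compat, data.frame(
      site_i = site_id(paste0("GX", cyl$x), paste0("c", cyl$y - cyl$x + 1L)),
      site_j = site_id(paste0("CY", cyl$y), paste0("m", cyl$x)),
      kind = "competed", wobble = FALSE, cross = FALSE, x = cyl$x, y = cyl$y))
  }
  if (length(cx_idx)) {
    cxl <- cross_lay
    compat <- rbind(compat, data.frame(
      site_i = site_id(paste0("GY", cxl$y), paste0("c", cxl$x - cxl$y + L)),
      site_j = site_id(paste0("CX", cxl$x), paste0("m", cxl$y)),
      kind = "competed", wobble = FALSE, cross = FALSE, x = cxl$x, y = cxl$y))
  }
  if (!is.null(toe) && nrow(toe)) {
    compat <- rbind(compat, data.frame(
      site_i = site_id(toe$host, paste0("h", toe$cut, "t", toe$k)),
      site_j = site_id(toe$cut, paste0("t", toe$k)),
      kind = "toehold", wobble = FALSE, cross = FALSE,
      x = NA_integer_, y = NA_integer_))
  }
  ## canonical unordered pairs: site_i < site_j
  swap <- compat$site_i > compat$site_j
  tmp <- compat$site_i[swap]
  compat$site_i[swap] <- compat$site_j[swap]
  compat$site_j[swap] <- tmp
  compat <- compat[order(compat$site_i, compat$site_j), ]
  rownames(compat) <- NULL
  compat$pair <- seq_len(nrow(compat))

  initial_bonds <- compat[compat$kind == "growth",
                          c("pair", "site_i", "site_j", "x", "y", "cross", "wobble")]
  rownames(initial_bonds) <- NULL

  structure(
    list(config = config, rates = config$rates, slats = slats, sites = sites,
         compat = compat, initial_bonds = initial_bonds,
         n_half = L %/% 2L, n2 = n2),
    class = "ccr_model")
}

#' Cross-interface bonds of a built model
#'
#' Returns exactly the initial growth bonds that join an A-half slat to a
#' B-half slat; removing them disconnects the growth slats into the two
#' ribbon halves. For an `R = 2` ribbon there are `L*(L-1)/2` of them.
#'
#' @param spec A `ccr_model`.
#' @return Data frame of bond positions (columns `pair`, `site_i`, `site_j`,
#'   `x`, `y`).
#' @export
cross_interface_bonds <- function(spec) {
  stopifnot(inherits(spec, "ccr_model"))
  out <- spec$initial_bonds[spec$initial_bonds$cross, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ccr_model <- function(x, ...) {
  cfg <- x$config
  ng <- sum(x$slats$is_growth)
  nc <- sum(!x$slats$is_growth)
  cat(sprintf("Crisscross scission model: L = %d, E = %d, R = %d\n",
              cfg$L, cfg$E, cfg$R))
  cat(sprintf("  %d growth slats (%d A-half, %d B-half), %d cut-slat types x %d copies\n",
              ng, sum(x$slats$half == "A", na.rm = TRUE),
              sum(x$slats$half == "B", na.rm = TRUE), nc, cfg$cut_excess))
  cat(sprintf("  %d sites, %d compatible pairs, %d initial bonds (%d cross-interface)\n",
              nrow(x$sites), nrow(x$compat), nrow(x$initial_bonds),
              sum(x$initial_bonds$cross)))
  nw <- if (is.null(cfg$wobble_layout)) 0L else nrow(cfg$wobble_layout)
  if (nw) cat(sprintf("  %d wobble-sites (on x %.3g, off x %.3g)\n",
                      nw, cfg$wobble_on_factor, cfg$wobble_off_factor))
  invisible(x)
}

#' Validate a scission model
#'
#' Runs every structural invariant of the model container and returns a
#' report rather than failing: every initial bond is in the compatibility
#' map; no site appears in two initial bonds; deleting the cross-interface
#' bonds splits the growth slats into exactly two connected components;
#' every toehold site has exactly one compatible partner (its dedicated
#' extension host); every competed site targets a site that is growth-bound
#' in the initial state; wobble positions name existing initial bonds.
#'
#' @param spec A `ccr_model`.
#' @return A data frame of class `ccr_validation` with columns `check`,
#'   `pass`, `detail`.
#' @export
validate_model <- function(spec) {
  stopifnot(inherits(spec, "ccr_model"))
  checks <- list()
  note <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass, detail = detail)
  }
  pair_key <- function(d) paste(pmin(d$site_i, d$site_j), pmax(d$site_i, d$site_j))

  ib <- spec$initial_bonds
  note("initial_bonds_in_compatibility",
       all(pair_key(ib) %in% pair_key(spec$compat)))

  occ <- c(ib$site_i, ib$site_j)
  dup <- occ[duplicated(occ)]
  note("site_occupancy_unique", length(dup) == 0L,
       if (length(dup)) paste("sites bonded twice:", paste(unique(dup), collapse = ",")) else "")

  ## halves disconnect when cross bonds removed
  gsl <- spec$slats$slat[spec$slats$is_growth]
  keep <- !ib$cross
  owner <- spec$sites$slat[match(c(ib$site_i[keep], ib$site_j[keep]), spec$sites$site)]
  ed <- matrix(owner, ncol = 2L)
  g <- igraph::graph_from_data_frame(as.data.frame(ed), directed = FALSE,
                                     vertices = data.frame(name = gsl))
  comp <- igraph::components(g)
  two <- comp$no == 2L
  halves_ok <- FALSE
  if (two) {
    memb <- comp$membership[gsl]
    lab <- spec$slats$half[match(gsl, spec$slats$slat)]
    halves_ok <- length(unique(paste(memb, lab))) == 2L
  }
  note("cross_bond_removal_splits_two_components", two,
       sprintf("%d components", comp$no))
  note("components_match_half_labels", isTRUE(halves_ok))

  ## toehold sites: exactly one compatible partner, an extension_host
  toes <- spec$sites$site[spec$sites$role == "toehold"]
  if (length(toes)) {
    cnt <- tabulate(factor(c(spec$compat$site_i, spec$compat$site_j),
                           levels = spec$sites$site), nbins = nrow(spec$sites))
    ok_cnt <- all(cnt[toes] == 1L)
    partner <- function(s) {
      p <- c(spec$compat$site_j[spec$compat$site_i == s],
             spec$compat$site_i[spec$compat$site_j == s])
      p
    }
    roles <- vapply(toes, function(s) {
      p <- partner(s)
      if (length(p) != 1L) return("multiple")
      spec$sites$role[match(p, spec$sites$site)]
    }, character(1))
    note("toehold_partner_unique_extension_host",
         ok_cnt && all(roles == "extension_host"))
    hosts <- spec$sites$site[spec$sites$role == "extension_host"]
    note("extension_host_exclusive", all(cnt[hosts] == 1L))
  } else {
    note("toehold_partner_unique_extension_host", TRUE, "no toeholds (E = 0)")
    note("extension_host_exclusive", TRUE, "no toeholds (E = 0)")
  }

  ## competed sites target initially growth-bound sites
  comp_pairs <- spec$compat[spec$compat$kind == "competed", , drop = FALSE]
  if (nrow(comp_pairs)) {
    role_i <- spec$sites$role[match(comp_pairs$site_i, spec$sites$site)]
    target <- ifelse(role_i == "core", comp_pairs$site_i, comp_pairs$site_j)
    bound <- target %in% c(ib$site_i, ib$site_j)
    in_one <- vapply(target, function(s) sum(ib$site_i == s | ib$site_j == s), integer(1)) == 1L
    note("competed_targets_growth_bound", all(bound) && all(in_one))
  } else {
    note("competed_targets_growth_bound", TRUE, "no cut slats")
  }

  ## every cut slat touches growth slats of exactly one half
  cut_slats <- spec$slats$slat[!spec$slats$is_growth]
  if (length(cut_slats)) {
    owner_i <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
    owner_j <- spec$sites$slat[match(spec$compat$site_j, spec$sites$site)]
    half_of_slat <- spec$slats$half[match(spec$slats$slat, spec$slats$slat)]
    names(half_of_slat) <- spec$slats$slat
    ok <- vapply(cut_slats, function(cs) {
      touch <- c(owner_j[owner_i == cs], owner_i[owner_j == cs])
      length(unique(stats::na.omit(half_of_slat[touch]))) <= 1L
    }, logical(1))
    note("cut_slats_engage_single_half", all(ok),
         if (!all(ok)) paste("bridging cut slats:", paste(cut_slats[!ok], collapse = ",")) else "")
  } else {
    note("cut_slats_engage_single_half", TRUE, "no cut slats")
  }

  ## wobble layout names existing initial bonds
  wl <- spec$config$wobble_layout
  if (!is.null(wl) && nrow(wl)) {
    note("wobble_bonds_exist",
         all(paste(wl$x, wl$y) %in% paste(ib$x, ib$y)))
  } else {
    note("wobble_bonds_exist", TRUE, "no wobbles")
  }

  ## bond rule is a function: each (x, y) position appears at most once
  note("bond_rule_function", !anyDuplicated(paste(ib$x, ib$y)))

  out <- do.call(rbind, checks)
  class(out) <- c("ccr_validation", "data.frame")
  out
}

#' @export
print.ccr_validation <- function(x, ...) {
  status <- ifelse(x$pass, "PASS", "FAIL")
  cat(sprintf("Model validation: %d/%d checks pass\n", sum(x$pass), nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s%s\n", status[i], x$check[i],
                if (nzchar(x$detail[i])) paste0(" (", x$detail[i], ")") else ""))
  invisible(x)
}
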