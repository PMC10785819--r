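## Kappa (KaSim 4 dialect) export of generated models, plus a bundled
## structural reader. The reader validates syntax and counts and supports an
## exact round trip (export -> parse -> re-export is byte-identical); running
## KaSim itself is never required.

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

## slat-level adjacency of the template compatibility map: for each
## unordered slat pair, the template pairs connecting them
slat_pair_index <- function(spec) {
  owner_i <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
  owner_j <- spec$sites$slat[match(spec$compat$site_j, spec$sites$site)]
  key <- ifelse(owner_i < owner_j, paste(owner_i, owner_j), paste(owner_j, owner_i))
  split(seq_len(nrow(spec$compat)), key)
}

slat_neighbors <- function(spec) {
  owner_i <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
  owner_j <- spec$sites$slat[match(spec$compat$site_j, spec$sites$site)]
  adj <- split(c(owner_j, owner_i), c(owner_i, owner_j))
  lapply(adj, unique)
}

## Enumerate the three-point-constraint traversal templates for one
## compatible site pair: all simple slat paths of 1..3 potential bonds from
## the pair's first owner to its second, with a concrete choice of template
## site pair per path edge, no site used twice, and the rule's own two
## sites excluded from the context. Returns a list of integer vectors of
## template pair ids (the context bonds, in path order).
intra_traversals <- function(spec, pair_id, spi = slat_pair_index(spec),
                             nb = slat_neighbors(spec)) {
  cp <- spec$compat[pair_id, ]
  sa <- cp$site_i; sb <- cp$site_j
  A <- spec$sites$slat[match(sa, spec$sites$site)]
  B <- spec$sites$slat[match(sb, spec$sites$site)]
  owner_i <- spec$sites$slat[match(spec$compat$site_i, spec$sites$site)]
  pairs_between <- function(u, v) {
    k <- if (u < v) paste(u, v) else paste(v, u)
    spi[[k]]
  }
  ## site of pair p on slat u
  site_on <- function(p, u) {
    ifelse(owner_i[p] == u, spec$compat$site_i[p], spec$compat$site_j[p])
  }
  out <- list()
  ## length 1: a second bond directly joining A and B
  for (p in setdiff(pairs_between(A, B), pair_id)) {
    if (site_on(p, A) == sa || site_on(p, B) == sb) next
    out[[length(out) + 1L]] <- p
  }
  ## length 2: A - C - B
  for (C in setdiff(intersect(nb[[A]], nb[[B]]), c(A, B))) {
    for (p1 in pairs_between(A, C)) {
      if (site_on(p1, A) == sa) next
      for (p2 in pairs_between(C, B)) {
        if (site_on(p2, B) == sb) next
        if (site_on(p2, C) == site_on(p1, C)) next
        out[[length(out) + 1L]] <- c(p1, p2)
      }
    }
  }
  ## length 3: A - C - D - B
  for (C in setdiff(nb[[A]], c(A, B))) {
    for (D in setdiff(intersect(nb[[C]], nb[[B]]), c(A, B, C))) {
      for (p1 in pairs_between(A, C)) {
        if (site_on(p1, A) == sa) next
        for (p2 in pairs_between(C, D)) {
          if (site_on(p2, C) == site_on(p1, C)) next
          for (p3 in pairs_between(D, B)) {
            if (site_on(p3, B) == sb) next
            if (site_on(p3, D) == site_on(p2, D)) next
            out[[length(out) + 1L]] <- c(p1, p2, p3)
          }
        }
      }
    }
  }
  out
}

#' Export a model as Kappa (KaSim 4 dialect) text
#'
#' Emits one agent declaration per slat type with named sites; one
#' unbinding and one intercomplex binding rule per compatible site pair;
#' one intracomplex binding rule per traversal template of the three-point
#' constraint (the left-hand side spells out a chain of at most three
#' context bonds placing the two slats within two intermediates, as
#' enumerated by conditional traversal of the compatibility map); an init
#' block with the intact ribbon complex (plus prebound cut slats in
#' prebound mode) and the free cut-slat copies; and rate constants taken
#' from the engine's propensity coefficients (wobble-scaled where flagged).
#' A largest-complex observable is noted as a comment, since complex-size
#' tracking is engine-specific.
#'
#' @param spec A `ccr_model`.
#' @param mode `"standard"` or `"prebound"`: selects the rate set and the
#'   initial mixture.
#' @return A `ccr_kappa` object; `render_kappa()` turns it into text and
#'   `print()` shows a summary.
#' @export
export_kappa <- function(spec, mode = c("standard", "prebound")) {
  stopifnot(inherits(spec, "ccr_model"))
  ok <- validate_model(spec)
  if (!all(ok$pass))
    stop("Refusing to export an invalid model; see validate_model().", call. = FALSE)
  mode <- match.arg(mode)
  rr <- mode_rates(spec, mode)
  cfg <- spec$config

  header <- c(
    model = "crisscross ribbon scission",
    L = as.character(cfg$L), E = as.character(cfg$E), R = as.character(cfg$R),
    mode = mode,
    wobbles = as.character(if (is.null(cfg$wobble_layout)) 0L else nrow(cfg$wobble_layout)),
    cut_excess = as.character(cfg$cut_excess))

  sites_by_slat <- split(spec$sites$name, spec$sites$slat)
  agents <- data.frame(
    name = spec$slats$slat,
    sites = vapply(spec$slats$slat, function(s)
      paste(sites_by_slat[[s]], collapse = ","), character(1)))

  vars <- data.frame(
    name = c("k_off", "k_on_inter", "k_on_intra", "wobble_on", "wobble_off"),
    value = fmt_num(c(rr$k_off, rr$k_on_inter, rr$k_on_intra,
                      cfg$wobble_on_factor, cfg$wobble_off_factor)))

  sl_of <- function(s) spec$sites$slat[match(s, spec$sites$site)]
  nm_of <- function(s) spec$sites$name[match(s, spec$sites$site)]
  pat <- function(s, link) sprintf("%s(%s[%s])", sl_of(s), nm_of(s), link)

  rules <- list()
  add_rule <- function(name, lhs, rhs, rate) {
    rules[[length(rules) + 1L]] <<- data.frame(name = name, lhs = lhs, rhs = rhs, rate = rate)
  }
  cpt <- spec$compat
  for (p in seq_len(nrow(cpt))) {
    sa <- cpt$site_i[p]; sb <- cpt$site_j[p]
    wob <- cpt$wobble[p] && cpt$kind[p] == "growth"
    tag <- sprintf("%s.%s__%s.%s", sl_of(sa), nm_of(sa), sl_of(sb), nm_of(sb))
    add_rule(sprintf("u_%s", tag),
             paste(pat(sa, 1), pat(sb, 1), sep = ", "),
             paste(pat(sa, "."), pat(sb, "."), sep = ", "),
             fmt_num(rr$k_off * if (wob) cfg$wobble_off_factor else 1))
    add_rule(sprintf("b_inter_%s", tag),
             paste(pat(sa, "."), pat(sb, "."), sep = ", "),
             paste(pat(sa, 1), pat(sb, 1), sep = ", "),
             fmt_num(rr$k_on_inter * if (wob) cfg$wobble_on_factor else 1))
  }
  ## intracomplex rules with explicit three-point context
  spi <- slat_pair_index(spec)
  nb <- slat_neighbors(spec)
  owner_i_all <- spec$sites$slat[match(cpt$site_i, spec$sites$site)]
  for (p in seq_len(nrow(cpt))) {
    sa <- cpt$site_i[p]; sb <- cpt$site_j[p]
    wob <- cpt$wobble[p] && cpt$kind[p] == "growth"
    tag <- sprintf("%s.%s__%s.%s", sl_of(sa), nm_of(sa), sl_of(sb), nm_of(sb))
    trs <- intra_traversals(spec, p, spi, nb)
    for (ti in seq_along(trs)) {
      path <- trs[[ti]]
      ## assemble agent patterns along the path A, C, D, ..., B
      slat_seq <- sl_of(sa)
      for (q in path) {
        u <- slat_seq[length(slat_seq)]
        v <- if (owner_i_all[q] == u) sl_of(cpt$site_j[q]) else sl_of(cpt$site_i[q])
        slat_seq <- c(slat_seq, v)
      }
      ## per-agent site/link lists: link 1 is the new bond, 2.. the context
      mk <- function(bound_link_for_new) {
        segs <- character(length(slat_seq))
        for (ai in seq_along(slat_seq)) {
          u <- slat_seq[ai]
          parts <- character(0)
          if (ai == 1L) parts <- c(parts, sprintf("%s[%s]", nm_of(sa), bound_link_for_new))
          if (ai == length(slat_seq)) parts <- c(parts, sprintf("%s[%s]", nm_of(sb), bound_link_for_new))
          if (ai > 1L) { # incoming context bond path[ai-1]
            q <- path[ai - 1L]
            su <- if (owner_i_all[q] == u) cpt$site_i[q] else cpt$site_j[q]
            parts <- c(parts, sprintf("%s[%d]", nm_of(su), ai))
          }
          if (ai < length(slat_seq)) { # outgoing context bond path[ai]
            q <- path[ai]
            su <- if (owner_i_all[q] == u) cpt$site_i[q] else cpt$site_j[q]
            parts <- c(parts, sprintf("%s[%d]", nm_of(su), ai + 1L))
          }
          segs[ai] <- sprintf("%s(%s)", u, paste(parts, collapse = ", "))
        }
        paste(segs, collapse = ", ")
      }
      add_rule(sprintf("b_intra_%s__t%d", tag, ti), mk("."), mk("1"),
               fmt_num(rr$k_on_intra * if (wob) cfg$wobble_on_factor else 1))
    }
  }
  rules <- do.call(rbind, rules)

  ## init block: the intact ribbon as one bound complex
  ib <- spec$initial_bonds
  prebound_cuts <- if (mode == "prebound") {
    toe <- cpt[cpt$kind == "toehold", , drop = FALSE]
    toe
  } else cpt[0, ]
  bond_label <- stats::setNames(seq_len(nrow(ib) + nrow(prebound_cuts)),
                                c(paste(ib$site_i, ib$site_j),
                                  if (nrow(prebound_cuts)) paste(prebound_cuts$site_i, prebound_cuts$site_j)))
  lab_of_site <- integer(nrow(spec$sites))
  for (b in seq_len(nrow(ib))) {
    lab_of_site[ib$site_i[b]] <- b
    lab_of_site[ib$site_j[b]] <- b
  }
  if (nrow(prebound_cuts)) for (b in seq_len(nrow(prebound_cuts))) {
    lab_of_site[prebound_cuts$site_i[b]] <- nrow(ib) + b
    lab_of_site[prebound_cuts$site_j[b]] <- nrow(ib) + b
  }
  complex_slats <- spec$slats$slat[spec$slats$is_growth]
  if (mode == "prebound") complex_slats <- spec$slats$slat
  ribbon_expr <- paste(vapply(complex_slats, function(s) {
    ss <- spec$sites[spec$sites$slat == s, ]
    bound <- ss[lab_of_site[ss$site] > 0L, , drop = FALSE]
    sprintf("%s(%s)", s, paste(sprintf("%s[%d]", bound$name, lab_of_site[bound$site]),
                               collapse = ", "))
  }, character(1)), collapse = ", ")
  free_copies <- spec$slats$copies[!spec$slats$is_growth] -
    (if (mode == "prebound") 1L else 0L)
  inits <- rbind(
    data.frame(count = "1", expr = ribbon_expr),
    if (any(!spec$slats$is_growth))
      data.frame(count = as.character(free_copies),
                 expr = sprintf("%s()", spec$slats$slat[!spec$slats$is_growth])))

  km <- structure(
    list(header = header, agents = agents, vars = vars, rules = rules,
         inits = inits,
         obs_note = "observable: largest complex size (engine-specific; in KaSim track complexes via snapshots)"),
    class = "ccr_kappa")
  km
}

#' Render a Kappa model object to text
#'
#' Deterministic canonical rendering; rendering, parsing and re-rendering
#' is a byte-identical fixed point.
#'
#' @param km A `ccr_kappa` object.
#' @return A single character scalar of KaSim-4-style text.
#' @export
render_kappa <- function(km) {
  stopifnot(inherits(km, "ccr_kappa"))
  lines <- c(
    "## kappa model generated by crisscut",
    sprintf("## %s: %s", names(km$header), km$header),
    "",
    sprintf("%%agent: %s(%s)", km$agents$name, km$agents$sites),
    "",
    sprintf("%%var: '%s' %s", km$vars$name, km$vars$value),
    "",
    "## rules",
    sprintf("'%s' %s -> %s @ %s", km$rules$name, km$rules$lhs, km$rules$rhs, km$rules$rate),
    "",
    "## init",
    sprintf("%%init: %s %s", km$inits$count, km$inits$expr),
    "",
    sprintf("## %s", km$obs_note))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse KaSim-4-style text produced by the exporter
#'
#' A structural reader: it recovers agents, variables, rules, inits and the
#' header metadata, validating line syntax. It does not execute Kappa
#' semantics.
#'
#' @param text Character scalar (or vector of lines).
#' @return A `ccr_kappa` object.
#' @export
parse_kappa <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  header <- character(0)
  agents <- list(); vars <- list(); rules <- list(); inits <- list()
  obs_note <- NULL
  for (ln in lines) {
    if (ln == "" || ln == "## kappa model generated by crisscut" || ln == "## rules" || ln == "## init") next
    if (grepl("^## observable", ln)) { obs_note <- sub("^## ", "", ln); next }
    if (grepl("^## [^:]+: ", ln)) {
      kv <- sub("^## ([^:]+): (.*)$", "\\1\x01\\2", ln)
      kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
      header[kv[1]] <- kv[2]
      next
    }
    if (grepl("^%agent:", ln)) {
      m <- regmatches(ln, regexec("^%agent: ([A-Za-z0-9_]+)\\(([^)]*)\\)$", ln))[[1]]
      if (length(m) != 3L) stop("Malformed agent declaration: ", ln, call. = FALSE)
      agents[[length(agents) + 1L]] <- data.frame(name = m[2], sites = m[3])
      next
    }
    if (grepl("^%var:", ln)) {
      m <- regmatches(ln, regexec("^%var: '([^']+)' (.+)$", ln))[[1]]
      if (length(m) != 3L) stop("Malformed var: ", ln, call. = FALSE)
      vars[[length(vars) + 1L]] <- data.frame(name = m[2], value = m[3])
      next
    }
    if (grepl("^%init:", ln)) {
      m <- regmatches(ln, regexec("^%init: ([0-9]+) (.+)$", ln))[[1]]
      if (length(m) != 3L) stop("Malformed init: ", ln, call. = FALSE)
      inits[[length(inits) + 1L]] <- data.frame(count = m[2], expr = m[3])
      next
    }
    if (grepl("^'", ln)) {
      m <- regmatches(ln, regexec("^'([^']+)' (.+) -> (.+) @ ([-0-9.eE]+)$", ln))[[1]]
      if (length(m) != 5L) stop("Malformed rule: ", ln, call. = FALSE)
      rules[[length(rules) + 1L]] <- data.frame(name = m[2], lhs = m[3], rhs = m[4], rate = m[5])
      next
    }
    stop("Unrecognized line in kappa text: ", ln, call. = FALSE)
  }
  structure(
    list(header = header,
         agents = do.call(rbind, agents),
         vars = do.call(rbind, vars),
         rules = do.call(rbind, rules),
         inits = do.call(rbind, inits),
         obs_note = obs_note),
    class = "ccr_kappa")
}

#' @export
print.ccr_kappa <- function(x, ...) {
  cat("Kappa model text (KaSim 4 dialect)\n")
  cat(sprintf("  %s\n", paste(sprintf("%s=%s", names(x$header), x$header), collapse = " ")))
  nb <- sum(grepl("^b_inter_", x$rules$name))
  nu <- sum(grepl("^u_", x$rules$name))
  ni <- sum(grepl("^b_intra_", x$rules$name))
  cat(sprintf("  %d agents, %d rules (%d unbind, %d intercomplex, %d intracomplex traversal templates), %d inits\n",
              nrow(x$agents), nrow(x$rules), nu, nb, ni, nrow(x$inits)))
  invisible(x)
}
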