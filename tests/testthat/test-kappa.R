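## Independent enumeration of three-point traversal templates, built on
## igraph simple paths plus explicit site-choice counting (a different
## algorithm from the exporter's nested conditional traversal).
count_traversals_igraph <- function(spec) {
  cpt <- spec$compat
  owner_i <- spec$sites$slat[match(cpt$site_i, spec$sites$site)]
  owner_j <- spec$sites$slat[match(cpt$site_j, spec$sites$site)]
  g <- igraph::simplify(igraph::graph_from_data_frame(
    unique(data.frame(a = owner_i, b = owner_j)), directed = FALSE,
    vertices = data.frame(name = spec$slats$slat)))
  pair_rows <- function(u, v) which((owner_i == u & owner_j == v) | (owner_i == v & owner_j == u))
  site_on <- function(p, u) ifelse(owner_i[p] == u, cpt$site_i[p], cpt$site_j[p])
  total <- 0L
  for (p0 in seq_len(nrow(cpt))) {
    A <- owner_i[p0]; B <- owner_j[p0]
    sa <- cpt$site_i[p0]; sb <- cpt$site_j[p0]
    paths <- igraph::all_simple_paths(g, from = A, to = B, cutoff = 3)
    for (pa in paths) {
      nodes <- names(pa)
      k <- length(nodes) - 1L
      ## site choices per consecutive edge, honoring exclusions
      choices <- lapply(seq_len(k), function(e) pair_rows(nodes[e], nodes[e + 1L]))
      combos <- expand.grid(choices)
      n_ok <- 0L
      for (r in seq_len(nrow(combos))) {
        ps <- as.integer(combos[r, ])
        if (k == 1L && ps[1] == p0) next
        ok <- site_on(ps[1], A) != sa && site_on(ps[k], B) != sb
        if (ok && k > 1L) for (e in seq_len(k - 1L)) {
          if (site_on(ps[e], nodes[e + 1L]) == site_on(ps[e + 1L], nodes[e + 1L])) { ok <- FALSE; break }
        }
        if (ok) n_ok <- n_ok + 1L
      }
      total <- total + n_ok
    }
  }
  total
}

test_that("export parses back and agent count equals the slat-type count", {
  m <- build_scission_model(toy_config(E = 1, cut_excess = 100L))
  km <- export_kappa(m, "standard")
  txt <- render_kappa(km)
  km2 <- parse_kappa(txt)
  expect_identical(nrow(km2$agents), nrow(m$slats))
  expect_identical(nrow(km2$rules), nrow(km$rules))
  expect_identical(km2$header[["L"]], "2")
})

test_that("export -> parse -> re-export is a byte-identical fixed point", {
  w <- cross_interface_layout(3, 2)[1, ]
  specs <- list(
    build_scission_model(toy_config(E = 1)),
    build_scission_model(build_config(L = 3, E = 2, wobble_layout = w)))
  for (m in specs) for (mode in c("standard", "prebound")) {
    txt <- render_kappa(export_kappa(m, mode))
    txt2 <- render_kappa(parse_kappa(txt))
    expect_identical(txt2, txt)
  }
})

test_that("rule count equals the independent traversal-template enumeration", {
  for (cfg in list(toy_config(E = 1), build_config(L = 3, E = 2),
                   build_config(L = 4, E = 2, include_cut_x = FALSE))) {
    m <- build_scission_model(cfg)
    km <- export_kappa(m, "standard")
    n_pairs <- nrow(m$compat)
    expected <- 2L * n_pairs + count_traversals_igraph(m)
    expect_identical(nrow(km$rules), expected,
                     info = sprintf("L=%d E=%d", cfg$L, cfg$E))
  }
})

test_that("exported rates equal the engine's propensity coefficients, wobble-scaled", {
  w <- cross_interface_layout(3, 2)[2, , drop = FALSE]
  m <- build_scission_model(build_config(L = 3, E = 1, wobble_layout = w))
  km <- export_kappa(m, "standard")
  rr <- crisscut:::mode_rates(m, "standard")
  rates <- as.numeric(km$rules$rate)
  expect_true(all(vapply(rates, function(x)
    any(abs(x - c(rr$k_off, rr$k_off * 1.5, rr$k_on_inter, rr$k_on_inter * 2 / 3,
                  rr$k_on_intra, rr$k_on_intra * 2 / 3)) < 1e-9), logical(1))))
  ## the wobbled bond prints off-rate 1.5 and intra on-rate 40 * 2/3
  wp <- m$compat$pair[m$compat$wobble]
  sl <- function(s) m$sites$slat[match(s, m$sites$site)]
  nm <- function(s) m$sites$name[match(s, m$sites$site)]
  tag <- sprintf("%s.%s__%s.%s", sl(m$compat$site_i[wp]), nm(m$compat$site_i[wp]),
                 sl(m$compat$site_j[wp]), nm(m$compat$site_j[wp]))
  expect_equal(as.numeric(km$rules$rate[km$rules$name == paste0("u_", tag)]), 1.5)
  intra_w <- km$rules$rate[grepl(paste0("^b_intra_", tag, "__"), km$rules$name)]
  expect_true(length(intra_w) > 0)
  expect_equal(unique(as.numeric(intra_w)), 40 * 2 / 3)
  ## prebound export carries the prebound rate set
  kmp <- export_kappa(m, "prebound")
  vp <- setNames(as.numeric(kmp$vars$value), kmp$vars$name)
  expect_identical(vp[["k_off"]], 0.8)
  expect_identical(vp[["k_on_inter"]], 0.05)
  expect_identical(vp[["k_on_intra"]], 50)
})

test_that("prebound init mixture binds one copy per cut type and frees the rest", {
  m <- build_scission_model(build_config(L = 3, E = 2, cut_excess = 7))
  km <- export_kappa(m, "prebound")
  ## the complex init line mentions every cut type; free counts are excess - 1
  expect_true(all(vapply(m$slats$slat[!m$slats$is_growth], grepl,
                         logical(1), x = km$inits$expr[1], fixed = TRUE)))
  expect_identical(unique(km$inits$count[-1]), "6")
})

test_that("an invalidated model is refused by the exporter", {
  m <- build_scission_model(build_config(L = 3, E = 1))
  ## duplicate an initial bond: the shared sites now appear in two bonds
  m$initial_bonds <- rbind(m$initial_bonds, m$initial_bonds[1, ])
  expect_false(all(validate_model(m)$pass))
  expect_error(export_kappa(m), "invalid")
})
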