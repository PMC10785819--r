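test_that("standard initial state has the full free cut-slat pool and one ribbon complex", {
  m <- build_scission_model(default_config())
  st <- initial_state(m, "standard", seed = 1)
  deg <- crisscut:::inst_degree(st)
  cut <- !st$inst$is_growth
  expect_identical(sum(cut), 18L * 100L)
  expect_true(all(deg[st$inst$inst[cut]] == 0L))         # all copies free
  expect_identical(as.vector(table(st$inst$type[cut])), rep(100L, 18L))
  comp <- crisscut:::state_components(st)
  expect_equal(max(comp$csize), 47)                 # one growth complex
  expect_equal(sum(comp$csize >= 2L), 1)
})

test_that("prebound initial state binds one copy of each cut type by all its toeholds", {
  m <- build_scission_model(default_config())
  st <- initial_state(m, "prebound", seed = 1)
  deg <- crisscut:::inst_degree(st)
  bound_cut <- which(!st$inst$is_growth & deg > 0L)
  expect_identical(length(bound_cut), 18L)
  expect_true(all(deg[bound_cut] == 5L))                 # E toehold bonds each
  expect_true(all(st$inst$copy[bound_cut] == 1L))
  comp <- crisscut:::state_components(st)
  expect_equal(max(comp$csize), 65)
  ## prebound rate set
  expect_identical(st$rates$k_off, 0.8)
  expect_identical(st$rates$k_on_inter, 0.05)
  expect_identical(st$rates$k_on_intra, 50)
})

test_that("identical seeds give bit-identical states and trajectories", {
  m <- build_scission_model(build_config(L = 4, E = 2, cut_excess = 5))
  expect_identical(initial_state(m, "standard", 7), initial_state(m, "standard", 7))
  t1 <- run_scission(m, "standard", seed = 11, log_events = TRUE)
  t2 <- run_scission(m, "standard", seed = 11, log_events = TRUE)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$t_end, t2$t_end)
  r1 <- run_scission(m, "standard", seed = 5, engine = "reference", t_max = 3)
  r2 <- run_scission(m, "standard", seed = 5, engine = "reference", t_max = 3)
  expect_identical(r1$samples, r2$samples)
  ## different seeds diverge (misuse of equal seeds is detectable)
  t3 <- run_scission(m, "standard", seed = 12, log_events = TRUE)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("three-point locality is a bonded path of at most three bonds", {
  ## cut-free L=2 ribbon is the chain X1-Y2-X2-Y3-X3-Y4-X4
  m <- build_scission_model(build_config(L = 2, E = 0,
                                         include_cut_x = FALSE, include_cut_y = FALSE))
  st <- initial_state(m, "standard", 1)
  id <- function(s) st$inst$inst[st$inst$type == s]
  expect_true(locality_satisfied(st, id("GX1"), id("GY2")))   # 1 bond
  expect_true(locality_satisfied(st, id("GX1"), id("GX2")))   # 2 bonds
  expect_true(locality_satisfied(st, id("GX1"), id("GY3")))   # 3 bonds
  expect_false(locality_satisfied(st, id("GX1"), id("GX3")))  # 4 bonds
  expect_false(locality_satisfied(st, id("GX1"), id("GX4")))
  ## across complexes the question is rejected
  cand <- enumerate_candidates(st, m)
  xb <- cross_interface_bonds(m)
  br <- cand[cand$kind == "unbind" & cand$tpair == xb$pair[1], ]  # break the cross bond
  st2 <- crisscut:::apply_event(st, br)
  expect_error(locality_satisfied(st2, id("GX1"), id("GX4")), "different complexes")
})

test_that("candidate enumeration applies rates, wobble factors and occupancy exclusion", {
  xb <- cross_interface_layout(6, 2)
  m <- build_scission_model(build_config(L = 6, E = 3, wobble_layout = xb[2, ]))
  st <- initial_state(m, "standard", 1)
  cand <- enumerate_candidates(st, m)
  wp <- m$compat$pair[m$compat$wobble]
  plain <- m$initial_bonds$pair[!m$initial_bonds$pair %in% wp][1]
  expect_identical(unique(cand$propensity[cand$kind == "unbind" & cand$tpair == plain]), 1)
  expect_identical(unique(cand$propensity[cand$kind == "unbind" & cand$tpair == wp]), 1.5)
  ## bound sites contribute no bind candidates
  gp <- st$ipairs[st$ipairs$tpair %in% m$initial_bonds$pair, ]
  bonded_sites <- c(gp$isite_i, gp$isite_j)
  binds <- cand[cand$kind != "unbind", ]
  expect_false(any(c(binds$isite_i, binds$isite_j) %in% bonded_sites))
  ## intercomplex binds are toehold recruitments at k_on_inter per free copy
  expect_true(all(binds$kind == "bind_inter"))
  expect_identical(unique(binds$propensity), 0.04)
  ## after breaking the wobble bond its re-formation carries 40 * 2/3
  br <- cand[cand$kind == "unbind" & cand$tpair == wp, ]
  st2 <- crisscut:::apply_event(st, br)
  c2 <- enumerate_candidates(st2, m)
  expect_equal(unique(c2$propensity[c2$tpair == wp & c2$kind == "bind_intra"]),
               40 * (2 / 3), tolerance = 1e-12)
})

test_that("reference and compiled engines enumerate identical initial candidate sets", {
  configs <- list(
    toy_config(E = 2),
    build_config(L = 6, E = 3, cut_excess = 4,
                 wobble_layout = cross_interface_layout(6, 2)[c(1, 5), ]))
  for (cfg in configs) {
    m <- build_scission_model(cfg)
    for (mode in c("standard", "prebound")) {
      st <- initial_state(m, mode, 1)
      rc <- enumerate_candidates(st, m)
      rc$kindcode <- match(rc$kind, c("bind_inter", "bind_intra", "unbind"))
      ragg <- aggregate(propensity ~ tpair + kindcode, rc, sum)
      cc <- crisscut:::ccr_candidates_cpp(crisscut:::model_arrays(m, mode),
                                          mode == "prebound", TRUE)
      cagg <- aggregate(list(propensity = cc$propensity),
                        list(tpair = cc$pair, kindcode = cc$kind), sum)
      ragg <- ragg[order(ragg$tpair, ragg$kindcode), ]
      cagg <- cagg[order(cagg$tpair, cagg$kindcode), ]
      expect_equal(ragg$tpair, cagg$tpair, info = mode)
      expect_equal(ragg$kindcode, cagg$kindcode, info = mode)
      expect_equal(ragg$propensity, cagg$propensity, tolerance = 1e-12, info = mode)
    }
  }
})

test_that("frozen-state event statistics follow the propensities", {
  m <- build_scission_model(toy_config(E = 2, cut_excess = 2))
  st <- initial_state(m, "standard", seed = 99)
  cand <- enumerate_candidates(st, m)
  n <- 10000L
  set.seed(123)
  picks <- integer(n)
  taus <- numeric(n)
  for (i in seq_len(n)) {
    step <- gillespie_step(st, m, candidates = cand)  # state discarded: frozen
    ev <- step$event
    picks[i] <- which(cand$isite_i == ev$isite_i & cand$isite_j == ev$isite_j &
                        cand$kind == ev$kind)
    taus[i] <- step$state$t - st$t
  }
  total <- sum(cand$propensity)
  ## waiting times are exponential with the total propensity
  expect_lt(abs(mean(taus) - 1 / total), 3 * stats::sd(taus) / sqrt(n))
  ## choice frequencies match propensity proportions
  obs <- tabulate(picks, nbins = nrow(cand))
  keep <- cand$propensity * n / total >= 5
  chi <- stats::chisq.test(obs[keep], p = cand$propensity[keep] / sum(cand$propensity[keep]))
  expect_gt(chi$p.value, 0.01)
})

test_that("a cut-free ribbon is stable: no scission within the horizon", {
  m <- build_scission_model(build_config(L = 4, E = 0,
                                         include_cut_x = FALSE, include_cut_y = FALSE))
  tr <- run_scission(m, "standard", seed = 3, t_max = 30)
  expect_identical(tr$termination, "t_max")
  expect_identical(tail(tr$samples$bridging, 1), 1L)
  sc <- detect_scission(tr, m)
  expect_true(sc$censored)
})

test_that("default standard trajectories show capture growth followed by a sharp size drop", {
  m <- build_scission_model(default_config())
  tr <- run_scission(m, "standard", seed = 21)
  expect_identical(tr$termination, "scission")
  s <- tr$samples
  expect_gt(max(s$largest_complex_size), 47)                 # cut-slat capture
  expect_lt(tail(s$largest_complex_size, 1), 0.7 * max(s$largest_complex_size))
  expect_true(all(diff(s$time) >= 0))
  expect_identical(s$time[1], 0)
  expect_identical(s$largest_complex_size[1], 47L)
})

test_that("ensembles use base_seed + r and are order-stable", {
  m <- build_scission_model(build_config(L = 3, E = 1, cut_excess = 10))
  ens <- run_ensemble(m, "standard", n_replicates = 4, base_seed = 100, t_max = 5)
  expect_identical(vapply(ens, function(x) x$seed, 0), c(101, 102, 103, 104))
  solo <- run_scission(m, "standard", seed = 103, t_max = 5)
  expect_identical(ens[[3]]$samples, solo$samples)
})

test_that("displaced growth slats can be deleted instead of recycled", {
  m <- build_scission_model(default_config())
  tr <- run_scission(m, "standard", seed = 5, displaced_growth = "delete",
                     log_events = TRUE)
  expect_identical(tr$termination, "scission")
  ## replay per-slat degrees: once a growth slat reaches degree 0 it is
  ## deleted and must never appear in a later event
  ev <- tr$events
  im <- tr$inst_map
  owner_of_site <- m$sites$slat[match(c(m$initial_bonds$site_i, m$initial_bonds$site_j), m$sites$site)]
  deg <- setNames(rep(0L, nrow(im)), im$inst)
  init_deg <- table(match(owner_of_site, im$type))  # growth instance = first of type
  deg[names(init_deg)] <- as.integer(init_deg)
  dead <- rep(FALSE, nrow(im))
  violated <- FALSE
  for (e in seq_len(nrow(ev))) {
    for (g in c(ev$inst_i[e], ev$inst_j[e])) {
      if (im$is_growth[g] && dead[g]) violated <- TRUE
    }
    d <- if (ev$kind[e] == "unbind") -1L else 1L
    deg[ev$inst_i[e]] <- deg[ev$inst_i[e]] + d
    deg[ev$inst_j[e]] <- deg[ev$inst_j[e]] + d
    for (g in c(ev$inst_i[e], ev$inst_j[e]))
      if (im$is_growth[g] && deg[g] == 0L) dead[g] <- TRUE
  }
  expect_false(violated)
})

test_that("internal audit mode passes on standard, prebound and wobbled runs", {
  w <- wobble_arrangement(6, 2, 3, "spread")
  m <- build_scission_model(build_config(L = 6, E = 3, wobble_layout = w))
  expect_no_error(run_scission(m, "standard", seed = 2, audit = TRUE))
  expect_no_error(run_scission(m, "prebound", seed = 2, audit = TRUE))
})
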