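test_that("cross-interface bond count matches brute-force enumeration for L = 2..12", {
  for (L in 2:12) {
    m <- build_scission_model(build_config(L = L, E = min(5L, L)))
    expect_identical(nrow(cross_interface_bonds(m)), brute_cross_count(L),
                     info = paste("L =", L))
    ## closed form for R = 2
    expect_identical(nrow(cross_interface_bonds(m)), as.integer(L * (L - 1) / 2))
  }
  ## a different repeat count
  m3 <- build_scission_model(build_config(L = 4, E = 2, R = 3))
  expect_identical(nrow(cross_interface_bonds(m3)), brute_cross_count(4, 3))
})

test_that("default geometry has 45 cross bonds and 9 + 9 cut-slat types", {
  m <- build_scission_model(default_config())
  expect_identical(nrow(cross_interface_bonds(m)), 45L)
  expect_identical(sum(m$slats$orientation == "CUT_Y"), 9L)
  expect_identical(sum(m$slats$orientation == "CUT_X"), 9L)
  expect_identical(m$n_half, 5L)
  ## terminal one-bond Y slats are pruned, nothing else
  expect_false(any(c("GY1", "GY29") %in% m$slats$slat))
  expect_identical(sum(m$slats$is_growth), 47L)
})

test_that("smallest valid model is L = 2 with a single cross bond", {
  m <- build_scission_model(build_config(L = 2, E = 1))
  expect_identical(nrow(cross_interface_bonds(m)), 1L)
  expect_true(all(validate_model(m)$pass))
})

test_that("degenerate and out-of-range configurations are rejected with clear errors", {
  expect_error(build_config(L = 1), "cross-interface")
  expect_error(build_config(L = 10, E = 13), "L \\+ 2")
  expect_error(build_config(L = 10, R = 0), "repeat")
  expect_error(build_config(L = 10, wobble_on_factor = 0), "positive")
  expect_error(build_config(L = 10, cut_excess = 0), ">= 1")
  expect_error(build_config(L = 4, wobble_layout = data.frame(a = 1, b = 2)), "columns")
  ## wobble naming a non-existent bond fails at build time
  expect_error(
    build_scission_model(build_config(L = 4, wobble_layout = data.frame(x = 1, y = 8))),
    "absent")
})

test_that("toehold hosts are in range and single-half for every E up to L + 2", {
  for (L in c(2L, 4L, 7L, 10L)) {
    m <- build_scission_model(build_config(L = L, E = L + 2L))
    rep <- validate_model(m)
    expect_true(all(rep$pass), info = paste("L =", L))
    ## each toehold has a dedicated host on the half its cut slat caps
    hosts <- m$sites[m$sites$role == "extension_host", ]
    half <- m$slats$half[match(hosts$slat, m$slats$slat)]
    cut_kind <- ifelse(grepl("^hCY", hosts$name), "CY", "CX")
    expect_true(all(half[cut_kind == "CY"] == "A"))
    expect_true(all(half[cut_kind == "CX"] == "B"))
  }
})

test_that("removing the cross-interface bonds disconnects the growth slats into the two halves", {
  for (L in c(3L, 6L, 10L)) {
    m <- build_scission_model(build_config(L = L, E = 2))
    xb <- cross_interface_bonds(m)
    keep <- !m$initial_bonds$pair %in% xb$pair
    owner <- m$sites$slat[match(c(m$initial_bonds$site_i[keep], m$initial_bonds$site_j[keep]),
                                m$sites$site)]
    g <- igraph::graph_from_data_frame(
      as.data.frame(matrix(owner, ncol = 2)), directed = FALSE,
      vertices = data.frame(name = m$slats$slat[m$slats$is_growth]))
    comp <- igraph::components(g)
    expect_equal(comp$no, 2)
    memb <- comp$membership
    half <- m$slats$half[match(names(memb), m$slats$slat)]
    expect_identical(length(unique(paste(memb, half))), 2L)
  }
})

test_that("validate_model flags constructed violations", {
  m <- build_scission_model(build_config(L = 4, E = 2))
  expect_true(all(validate_model(m)$pass))

  ## a toehold given a second compatible partner breaks host exclusivity
  bad <- m
  toe <- bad$sites$site[bad$sites$role == "toehold"][1]
  core <- bad$sites$site[bad$sites$role == "core"][1]
  extra <- data.frame(site_i = min(toe, core), site_j = max(toe, core),
                      kind = "toehold", wobble = FALSE, cross = FALSE,
                      x = NA_integer_, y = NA_integer_, pair = nrow(bad$compat) + 1L)
  bad$compat <- rbind(bad$compat, extra)
  rep <- validate_model(bad)
  expect_false(rep$pass[rep$check == "toehold_partner_unique_extension_host"])

  ## a wobble position whose bond was deleted from initial_bonds
  xb <- cross_interface_layout(4, 2)
  m2 <- build_scission_model(build_config(L = 4, E = 2, wobble_layout = xb[1, ]))
  m2$initial_bonds <- m2$initial_bonds[
    !(m2$initial_bonds$x == xb$x[1] & m2$initial_bonds$y == xb$y[1]), ]
  rep2 <- validate_model(m2)
  expect_false(rep2$pass[rep2$check == "wobble_bonds_exist"])
})

test_that("each bond position appears once and interior slats carry L bonds", {
  m <- build_scission_model(build_config(L = 6, E = 3))
  ib <- m$initial_bonds
  expect_false(anyDuplicated(paste(ib$x, ib$y)) > 0)
  ## interior (unpruned-neighbour) slats have exactly L growth bonds
  owner <- m$sites$slat[match(c(ib$site_i, ib$site_j), m$sites$site)]
  deg <- table(owner)
  interior_x <- paste0("GX", 2:11)  # N = 12; X_1 and X_N lose a pruned partner
  expect_true(all(deg[interior_x] == 6L))
})

test_that("wobble_arrangement selects valid cross-interface layouts", {
  w <- wobble_arrangement(10, 2, 5, "spread")
  expect_identical(nrow(w), 5L)
  xb <- cross_interface_layout(10, 2)
  expect_true(all(paste(w$x, w$y) %in% paste(xb$x, xb$y)))
  wb <- wobble_arrangement(10, 2, 5, "block", offset = 3)
  expect_identical(nrow(wb), 5L)
  expect_error(wobble_arrangement(10, 2, 46), "Cannot place")
  expect_error(wobble_arrangement(10, 2, 5, "block", offset = 44), "past the interface")
  wr1 <- wobble_arrangement(10, 2, 5, "random", seed = 9)
  wr2 <- wobble_arrangement(10, 2, 5, "random", seed = 9)
  expect_identical(wr1, wr2)
  ## the model accepts any of them
  expect_true(all(validate_model(
    build_scission_model(build_config(L = 10, wobble_layout = wb)))$pass))
})

test_that("rate parameter consistency is enforced", {
  expect_error(rate_params(k_on_inter = 0.04, alpha = 1000, k_on_intra = 10),
               "alpha")
  r <- rate_params()
  expect_identical(r$k_off, 1)
  expect_identical(r$k_on_inter, 0.04)
  expect_identical(r$k_on_intra, 40)
  expect_identical(r$prebound_k_on_inter, 0.05)
  expect_identical(r$prebound_k_off, 0.8)
})
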