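## Synthetic trajectory with a known split inserted at t = 7.5
scripted_trajectory <- function() {
  samples <- data.frame(
    time = c(0, 2, 5, 7.5, 9),
    tracked_complex_size = c(47L, 50L, 60L, 30L, 30L),
    n_complexes = c(1L, 1L, 1L, 2L, 2L),
    largest_complex_size = c(47L, 50L, 60L, 31L, 31L),
    bridging = c(1L, 1L, 1L, 0L, 0L))
  structure(
    list(samples = samples, events = NULL, termination = "scission",
         t_end = 9, n_events = 10L, n_null = 0L,
         final_complexes = data.frame(size = c(31L, 30L), growth_a = c(0L, 19L),
                                      growth_b = c(28L, 0L), growth = c(28L, 19L)),
         final_pool = NULL, inst_map = NULL, final_bonds = NULL,
         n_growth_initial = 47L, seed = 1L, mode = "standard",
         engine = "scripted",
         condition = list(L = 10L, E = 5L, R = 2L, n_wobble = 0L)),
    class = "ccr_trajectory")
}

test_that("both detectors recover a scripted split at t = 7.5 and agree", {
  tr <- scripted_trajectory()
  sc <- detect_scission(tr)
  expect_identical(sc$time_half_label, 7.5)
  expect_identical(sc$time_size_drop, 7.5)   # 31 <= 0.7 * 60
  expect_identical(sc$scission_time, 7.5)
  expect_true(sc$detectors_agree)
  expect_false(sc$censored)
  expect_identical(sc$product1, 28L)
  expect_identical(sc$product2, 19L)
  expect_true(sc$comparable)
})

test_that("a run without scission is censored, never imputed", {
  tr <- scripted_trajectory()
  tr$samples$bridging <- 1L
  tr$samples$largest_complex_size <- c(47L, 50L, 60L, 62L, 62L)
  tr$termination <- "t_max"
  sc <- detect_scission(tr)
  expect_true(sc$censored)
  expect_true(is.na(sc$scission_time))
  sm <- summarize_ensemble(list(cond = rbind(sc, sc)))
  expect_identical(sm$censored, 2L)
  expect_true(is.na(sm$mean_scission_time))
})

test_that("ensemble summaries normalize correctly and report SE = sd/sqrt(n)", {
  mk <- function(times, cond) {
    data.frame(scission_time = times, censored = FALSE, condition = cond)
  }
  res <- rbind(mk(c(2, 2, 2), "a"), mk(c(4, 4, 4), "b"))
  sm <- summarize_ensemble(res, normalize_to = "a")
  expect_identical(sm$normalized_mean[sm$condition == "a"], 1)
  expect_identical(sm$normalized_mean[sm$condition == "b"], 2)

  set.seed(1)
  x <- rexp(100, 1 / 5)
  sm2 <- summarize_ensemble(mk(x, "c"))
  expect_equal(sm2$mean_scission_time, mean(x))
  expect_equal(sm2$se, sd(x) / sqrt(100))
  ## bootstrap cross-check of the standard error
  set.seed(2)
  boot <- replicate(2000, mean(sample(x, replace = TRUE)))
  expect_lt(abs(sd(boot) - sm2$se) / sm2$se, 0.15)
})

test_that("a single-point sweep equals run_ensemble plus summarize", {
  cfg <- build_config(L = 4, E = 2, cut_excess = 20)
  m <- build_scission_model(cfg)
  trajs <- run_ensemble(m, "standard", n_replicates = 12, base_seed = 7, t_max = 100)
  direct <- summarize_ensemble(list(cond = scission_results(trajs, m)))
  sw <- sweep_conditions(data.frame(L = 4), base_config = cfg, mode = "standard",
                         n = 12, base_seed = 7, t_max = 100)
  expect_equal(sw$mean_scission_time, direct$mean_scission_time)
  expect_equal(sw$se, direct$se)
  expect_identical(sw$detected, direct$detected)
})

test_that("invalid grid points are recorded as failed conditions and the sweep continues", {
  sw <- sweep_conditions(data.frame(L = c(4, 1, 3)),
                         base_config = build_config(L = 4, E = 2, cut_excess = 10),
                         n = 3, base_seed = 1, t_max = 20)
  expect_identical(nrow(sw), 3L)
  expect_identical(sw$failed, c(FALSE, TRUE, FALSE))
  expect_match(sw$message[2], "cross-interface")
  expect_false(anyNA(sw$mean_scission_time[!sw$failed]))
})

test_that("cut-y-only and cut-x-only designs both run to completion and report means", {
  grid <- data.frame(include_cut_x = c(FALSE, TRUE),
                     include_cut_y = c(TRUE, FALSE),
                     condition = c("cut_y_only", "cut_x_only"))
  sw <- sweep_conditions(grid, base_config = build_config(L = 4, E = 2),
                         n = 15, base_seed = 3, t_max = 500)
  expect_false(any(sw$failed))
  expect_true(all(is.finite(sw$mean_scission_time)))
  expect_identical(sw$condition, c("cut_y_only", "cut_x_only"))
})

test_that("scission of the default model yields two comparable halves", {
  m <- build_scission_model(default_config())
  trajs <- run_ensemble(m, "standard", n_replicates = 10, base_seed = 40)
  res <- scission_results(trajs, m)
  expect_true(all(!res$censored))
  expect_true(all(res$product1 + res$product2 <= res$product1[1] + res$product2[1] + 47))
  expect_true(mean(res$comparable) >= 0.9)
})
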