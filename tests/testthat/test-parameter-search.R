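test_that("kinetic-order sampling respects the intervals and the seed", {
  t <- bl_topo
  g1 <- sample_kinetic_orders(t, seed = 123)
  g2 <- sample_kinetic_orders(t, seed = 123)
  expect_identical(g1, g2)
  efflux <- c("E1", "E2", "E3", "E4")
  expect_true(all(g1[efflux] >= 0 & g1[efflux] <= 4))
  other <- setdiff(names(g1), efflux)
  expect_true(all(g1[other] >= 0 & g1[other] <= 1))
})

test_that("admissibility bands implement the plus/minus 25 percent rule", {
  t <- bl_topo
  obs <- bl_gt$observations["control"]
  feeds <- bl_gt$feeds["control"]
  crit <- admissibility_criteria(obs, feeds)
  b <- crit$scenarios$control$bands
  g_row <- b[b$observable == "G", ]
  expect_equal(g_row$lo, 0.75 * g_row$mean)
  expect_equal(g_row$hi, 1.25 * g_row$mean)
  wall_row <- b[b$observable == "wall_pCA", ]
  expect_equal(wall_row$lo, 0.5 * wall_row$mean)   # relaxed wall band

  # simulated 120 vs target 100 passes, 130 fails
  fake <- obs
  fake$control$totals["G"] <- g_row$mean * 1.2
  expect_equal(evaluate_admissibility(fake, crit)$margins$violation[
    crit$scenarios$control$bands$observable == "G"], 0)
  fake$control$totals["G"] <- g_row$mean * 1.3
  v <- evaluate_admissibility(fake, crit)
  expect_false(v$pass)
  expect_gt(v$score, 0)

  # noise-free self-evaluation: all margins zero
  self <- evaluate_admissibility(obs, crit)
  expect_true(self$pass)
  expect_equal(max(abs(self$margins$margin)), 0, tolerance = 1e-12)

  expect_error(evaluate_admissibility(list(), crit), "missing scenario")
})

test_that("explore-and-exploit recovers admissible sets on synthetic targets", {
  t <- bl_topo
  crit <- generate_observations(bl_gt, noise_model(0, 0, 1), seed = 2)$criteria
  static_ens <- sample_steady_state_fluxes(t, crit, n = 3, seed = 5)
  ens40 <- explore_exploit_search(t, static_ens, crit, budget = 40, seed = 9)
  expect_s3_class(ens40, "admissible_ensemble")
  expect_gte(length(ens40), 1)

  # monotone accumulation on the same seed stream
  ens15 <- explore_exploit_search(t, static_ens, crit, budget = 15, seed = 9)
  expect_gte(length(ens40), length(ens15))

  # idempotence: every member re-passes admissibility when re-simulated
  rec <- ens40[[1]]
  obs <- lapply(stats::setNames(names(crit$scenarios), names(crit$scenarios)),
                function(k)
    simulate_scenario(t, rec$params,
                      make_scenario(k, t, feed = crit$scenarios[[k]]$feed))$observations)
  expect_true(evaluate_admissibility(obs, crit)$pass)

  # provenance and reproducibility
  ens40b <- explore_exploit_search(t, static_ens, crit, budget = 40, seed = 9)
  expect_equal(length(ens40), length(ens40b))
  expect_equal(ens40[[1]]$params$a, ens40b[[1]]$params$a)

  # zero budget: explicitly empty
  ens0 <- explore_exploit_search(t, static_ens, crit, budget = 0, seed = 9)
  expect_length(ens0, 0)
})
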