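test_that("sampled flux distributions are mass balanced and labeled sanely", {
  t <- bl_topo
  ens <- sample_steady_state_fluxes(t, targets = NULL, n = 4, seed = 3)
  for (f in ens) {
    expect_lt(max(abs(mass_balance_residual(t, f))), 1e-9)
    for (fd in names(f$label_fields)) {
      lf <- f$label_fields[[fd]]
      expect_true(all(lf[!is.na(lf)] >= 0 & lf[!is.na(lf)] <= 1))
    }
  }
})

test_that("noise-free targets from a known flux vector are feasible; impossible targets are not", {
  t <- bl_topo
  f <- bl_fix$f
  obs <- list(control = readouts_from_fluxes(t, f$values,
                static_label_field(t, f, feed_spec()), f$r),
              phe_label = readouts_from_fluxes(t, f$values,
                static_label_field(t, f, feed_spec(phe_label = 1)), f$r))
  feeds <- list(control = feed_spec(), phe_label = feed_spec(phe_label = 1))
  crit <- admissibility_criteria(obs, feeds)
  ens <- sample_steady_state_fluxes(t, crit, n = 2, seed = 42)
  expect_gte(length(ens), 1)

  # G-monomer total far above the total carbon influx: conservation bound
  bad <- obs
  bad$control$totals["G"] <- 1e4
  bad$control$totals["total"] <- 1e4
  badcrit <- admissibility_criteria(bad, feeds)
  expect_error(sample_steady_state_fluxes(t, badcrit, n = 1, seed = 1,
                                          max_draws = 150),
               class = "bl_infeasible_targets")
})

test_that("label propagation is a flux-weighted convex combination", {
  t <- bl_topo
  f <- bl_fix$f
  feed <- feed_spec(phe_label = 1)
  lf <- propagate_label_fractions(t, f, feed)
  # saturation / annihilation
  lf1 <- propagate_label_fractions(t, f, feed_spec(phe_label = 1, tyr_label = 1))
  lf0 <- propagate_label_fractions(t, f, feed_spec())
  expect_true(all(abs(lf1[!is.na(lf1)] - 1) < 1e-9))
  expect_true(all(abs(lf0[!is.na(lf0)]) < 1e-12))
  # zero-throughput ER pools of the cytosol-only sinapyl tail are flagged
  expect_setequal(attr(lf, "flagged"), c("Y14", "Y15"))
})

test_that("two-stream merge yields the hand-computed flux-weighted label", {
  # labeled stream (rate 2) and unlabeled stream (rate 3) merge at the
  # cytosolic pCA pool: L = 2/5 = 0.4
  f <- bl_merge_fixture()
  lf <- propagate_label_fractions(bl_topo, f, feed_spec(phe_label = 1))
  expect_equal(unname(lf[["X4"]]), 0.4, tolerance = 1e-12)
  expect_equal(unname(lf[["Y4"]]), 1.0, tolerance = 1e-12)
})

test_that("solve_diffusion_link reproduces the frozen example and signals degeneracy", {
  sol <- solve_diffusion_link(D = 10, D_L = 8, L_X = 0.6, L_Y = 0.2, r = 0.9)
  expect_equal(sol$X_ss, 750 / 7, tolerance = 1e-9)   # 107.142857...
  expect_equal(sol$Y_ss, 250 / 7, tolerance = 1e-9)   # 35.714285...
  expect_equal(sol$d, 10 / (750 / 7 - 250 / 7), tolerance = 1e-9)  # 0.14
  expect_equal(0.9 * sol$X_ss + 0.1 * sol$Y_ss, 100, tolerance = 1e-10)

  expect_error(solve_diffusion_link(10, 5, 0.5, 0.5), class = "bl_degenerate_pool")
  expect_error(solve_diffusion_link(0, 0, 0.6, 0.2), class = "bl_degenerate_pool")
  # labeled flow equal to total flow out of a partially labeled pool
  # forces a nonpositive concentration
  expect_error(solve_diffusion_link(-5, -5, 0.2, 1, r = 0.9),
               class = "bl_infeasible_labeling")
})

test_that("diffusion solver inverts 1000 random feasible forward problems", {
  # independent oracle: generate (d, X, Y) forward, compute (D, D_L),
  # require exact recovery
  set.seed(99)
  r <- 0.9
  for (i in 1:1000) {
    X <- runif(1, 1, 110.9)
    Y <- (100 - r * X) / (1 - r)
    if (abs(X - Y) < 1e-3) next
    d <- exp(runif(1, log(1e-3), log(10)))
    L <- sort(runif(2))
    L_X <- L[2]; L_Y <- L[1]
    if (abs(L_X - L_Y) < 1e-6) next
    D <- d * (X - Y)
    D_L <- d * (L_X * X - L_Y * Y)
    sol <- tryCatch(solve_diffusion_link(D, D_L, L_X, L_Y, r = r),
                    bl_error = function(e) NULL)
    expect_false(is.null(sol))
    expect_equal(sol$X_ss, X, tolerance = 1e-9)
    expect_equal(sol$Y_ss, Y, tolerance = 1e-9)
    expect_equal(sol$d, d, tolerance = 1e-9)
  }
})

test_that("diffusion solver agrees with a brute-force numeric 3x3 solve", {
  set.seed(7)
  r <- 0.9
  for (i in 1:20) {
    D <- runif(1, -20, 20)
    if (abs(D) < 0.5) next
    L_X <- runif(1); L_Y <- runif(1)
    if (abs(L_X - L_Y) < 0.05) next
    rho <- runif(1, 0.25, 0.75)
    b <- abs(D) * rho / (1 - rho)
    D_L <- if (D > 0) (abs(D) + b) * L_X - b * L_Y else
      -((abs(D) + b) * L_Y - b * L_X)
    sol <- solve_diffusion_link(D, D_L, L_X, L_Y, r = r)
    # oracle: substitute Y(X) from the normalization into the ratio of the
    # two diffusion equations and root-find in X alone
    Yof <- function(X) (100 - r * X) / (1 - r)
    h <- function(X) D_L * (X - Yof(X)) - D * (L_X * X - L_Y * Yof(X))
    lo <- 1e-9; hi <- 100 / r - 1e-9
    if (h(lo) * h(hi) > 0) next   # no interior root: infeasible combination
    root <- uniroot(h, c(lo, hi), tol = 1e-13)$root
    expect_equal(root, sol$X_ss, tolerance = 1e-7)
    expect_equal(Yof(root), sol$Y_ss, tolerance = 1e-7)
    expect_equal(D / (root - Yof(root)), sol$d, tolerance = 1e-7)
  }
})

test_that("degenerate pools are exactly the four dictated by the stoichiometry", {
  t <- bl_topo
  for (f in list(bl_fix$f, bl_gt$flux)) {
    lf <- propagate_label_fractions(t, f, feed_spec(phe_label = 1))
    expect_setequal(detect_degenerate_pools(t, lf),
                    c(2L, 9L, 16L, 17L))
    # same set under the Tyr feed: degeneracy is structural
    lft <- propagate_label_fractions(t, f, feed_spec(tyr_label = 1))
    expect_setequal(detect_degenerate_pools(t, lft), c(2L, 9L, 16L, 17L))
  }
  # tol = 1 saturates the bound: every defined pair is reported
  lf <- propagate_label_fractions(t, bl_fix$f, feed_spec(phe_label = 1))
  paired_defined <- detect_degenerate_pools(t, lf, tol = 1)
  expect_length(paired_defined, 15)  # 17 paired minus the two flagged NA
})

test_that("degenerate-pool sampling respects direction, normalization and seed", {
  t <- bl_topo
  f <- bl_fix$f
  lf <- propagate_label_fractions(t, f, feed_spec(phe_label = 1))
  ids <- detect_degenerate_pools(t, lf)
  s1 <- sample_degenerate_steady_states(t, f, ids, r = 0.9, seed = 5)
  s2 <- sample_degenerate_steady_states(t, f, ids, r = 0.9, seed = 5)
  expect_identical(s1, s2)
  for (k in seq_len(nrow(s1))) {
    row <- s1[k, ]
    expect_equal(0.9 * row$X_ss + 0.1 * row$Y_ss, 100, tolerance = 1e-9)
    D <- f$values[[paste0("D", row$metabolite)]]
    # Eq. 1 holds exactly with the distribution's net diffusion flux
    expect_equal(row$d * (row$X_ss - row$Y_ss), D, tolerance = 1e-9)
    # the receiving pool is below 100, its partner above
    recv <- if (row$receiver == "er") row$Y_ss else row$X_ss
    part <- if (row$receiver == "er") row$X_ss else row$Y_ss
    expect_lt(recv, 100); expect_gt(part, 100)
  }
})

test_that("flux ensemble summary behaves", {
  f <- bl_fix$f
  ens <- list(f, f, f)
  sm <- flux_ensemble_summary(ens)
  tot <- sm[sm$component == "total", ]
  expect_true(all(tot$q75 - tot$q25 == 0))
  # median of a 3-member spread
  f2 <- f; f2$values <- f$values * 2
  f3 <- f; f3$values <- f$values * 3
  sm2 <- flux_ensemble_summary(list(f, f2, f3))
  tot2 <- sm2[sm2$component == "total", ]
  expect_equal(tot2$median, 2 * tot$median, tolerance = 1e-12)
  # permutation invariance
  sm3 <- flux_ensemble_summary(list(f3, f, f2))
  expect_equal(sm2, sm3)
  expect_error(flux_ensemble_summary(list()), "empty")
})
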