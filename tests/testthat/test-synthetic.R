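test_that("ground truth is self-consistent, channeled and reproducible", {
  t <- bl_topo
  gt <- bl_gt
  # simulating the truth under its control feed: derivatives vanish
  fr <- pooled_rhs(t, gt$params)
  expect_lt(max(abs(fr(gt$params$conc))), 1e-9)
  # enforced channeling signature
  expect_gt(gt$observations$phe_label$incorporation[["G"]],
            gt$observations$phe_label$incorporation[["S"]])
  expect_gt(gt$observations$tyr_label$incorporation[["S"]],
            gt$observations$tyr_label$incorporation[["G"]])
  # fixed seed reproduces the truth exactly
  gt2 <- generate_ground_truth(t, seed = 1)
  expect_equal(gt2$params$a, gt$params$a)
  expect_equal(gt2$params$conc, gt$params$conc)
})

test_that("emitted observations conserve mass and respect bounds", {
  gt <- bl_gt
  for (obs in gt$observations) {
    inc <- obs$incorporation
    expect_true(all(inc[!is.na(inc)] >= 0 & inc[!is.na(inc)] <= 1))
  }
  # at steady state the total sink accumulation rate equals the total
  # carbon influx (mass conservation of the generator)
  v <- gt$flux$values
  r <- gt$params$r
  sink_abs <- r * (v[["TH"]] + v[["TG"]] + v[["TS"]] + v[["E1"]] + v[["E3"]]) +
    (1 - r) * (v[["E2"]] + v[["E4"]])
  influx_abs <- r * (v[["V1"]] + v[["V2"]])
  expect_equal(sink_abs, influx_abs, tolerance = 1e-9)
})

test_that("noise model: zero noise is exact, replicate mean obeys the LLN", {
  gt <- bl_gt
  clean <- generate_observations(gt, noise_model(0, 0, 1), seed = 4)
  expect_equal(clean$observations$control$totals,
               gt$observations$control$totals, tolerance = 1e-12)
  # 10,000 lognormal replicates at sd = 0.1: mean within ~1% of truth
  noisy <- generate_observations(gt, noise_model(0.1, 0.03, 10000), seed = 4)
  rel <- noisy$observations$control$totals[["G"]] /
    gt$observations$control$totals[["G"]]
  expect_lt(abs(rel - 1), 0.01)
  # all emitted fractions clipped to [0, 1]
  for (obs in noisy$observations) {
    inc <- obs$incorporation
    expect_true(all(inc[!is.na(inc)] >= 0 & inc[!is.na(inc)] <= 1))
  }
})

test_that("recovery experiment: truth admissible, ensemble recovered", {
  rep <- recovery_experiment(seed = 1, budget = 40, n_static = 3)
  expect_true(rep$truth_admissible)
  expect_equal(rep$truth_score, 0)
  expect_gte(rep$n_admissible, 1)
  expect_true(rep$sg_within_band)
  expect_output(print(rep), "truth admissible")
})
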