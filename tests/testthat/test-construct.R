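test_that("rate-constant back-calculation inverts the rate law", {
  t <- bl_topo
  # V = 50, pooled substrate = 100, g = 0.5, enzyme = 100 -> a = 0.05
  f <- bl_fix$f
  f$values[] <- 0
  f$values["V3"] <- 50
  conc <- stats::setNames(rep(100, 34), t$pools$pool)
  g <- bl_fix$g; g["V3"] <- 0.5
  a <- back_calculate_rate_constants(t, f, conc, g)
  expect_equal(unname(a[["V3"]]), 50 / (sqrt(100) * 100))
  expect_true(all(a[setdiff(names(a), "V3")] == 0))
  # doubling the enzyme level halves a, leaving the flux unchanged
  e2 <- enzyme_profile(t); e2[] <- 2
  a2 <- back_calculate_rate_constants(t, f, conc, g, e = e2)
  expect_equal(unname(a2[["V3"]]), unname(a[["V3"]]) / 2)
  # zero concentration feeding a nonzero flux is a named error
  conc0 <- conc; conc0["X4"] <- 0
  expect_error(back_calculate_rate_constants(t, f, conc0, g),
               class = "bl_domain_error")
})

test_that("constructed parameter sets reproduce their flux distribution exactly", {
  t <- bl_topo
  f <- bl_fix$f
  p <- bl_fix$p
  # steady-state reconstruction: residual below 1e-10
  fr <- pooled_rhs(t, p)
  expect_lt(max(abs(fr(p$conc))), 1e-10)
  # flux values at the steady state equal the sampled distribution
  v <- flux_values_at(t, p, p$conc)
  expect_equal(v[names(f$values)], f$values, tolerance = 1e-9)
  # Eq. 3: volume-weighted totals are 100 for every metabolite
  w <- ifelse(t$pools$compartment == "cytosol", p$r, 1 - p$r)
  totals <- tapply(w * p$conc, t$pools$metabolite, sum)
  expect_equal(as.vector(totals), rep(100, 17), tolerance = 1e-9)
})

test_that("construction agrees with the algebraic diffusion-link solve", {
  t <- bl_topo
  f <- bl_fix$f
  p <- bl_fix$p
  lf <- propagate_label_fractions(t, f, feed_spec(phe_label = 1))
  deg <- detect_degenerate_pools(t, lf)
  for (m in setdiff(t$diffusion$metabolite, deg)) {
    if (abs(f$values[[paste0("D", m)]]) < 1e-9) next
    chk <- cross_check_diffusion_link(t, f, p, m)
    expect_equal(chk$algebraic$X_ss, unname(chk$constructed$X_ss),
                 tolerance = 1e-8)
    expect_equal(chk$algebraic$Y_ss, unname(chk$constructed$Y_ss),
                 tolerance = 1e-8)
    expect_equal(chk$algebraic$d, unname(chk$constructed$d),
                 tolerance = 1e-8)
  }
})

test_that("the degenerate receiving pools are those of the Eq-8 array", {
  # diffusion pours into [Y2, X9, X16, X17]: ER side for cinnamic acid,
  # cytosolic side for the three ER-gated products
  t <- bl_topo
  f <- bl_fix$f
  expect_gt(f$values[["D2"]], 0)    # X2 -> Y2
  expect_lt(f$values[["D9"]], 0)    # Y9 -> X9
  expect_lt(f$values[["D16"]], 0)
  expect_lt(f$values[["D17"]], 0)
  deg <- bl_fix$p$meta$degenerate
  expect_setequal(deg$receiver[deg$metabolite == 2], "er")
  expect_setequal(deg$receiver[deg$metabolite %in% c(9, 16, 17)], "cytosol")
})
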