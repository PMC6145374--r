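test_that("gma_flux evaluates the power law and is label-blind", {
  t <- bl_topo
  p <- bl_fix$p
  p$a["V3"] <- 2; p$g["V3"] <- 0.5
  st <- build_wild_type_state(t, p)
  i4 <- match("X4", t$pools$pool)
  st$labeled[i4] <- 30; st$unlabeled[i4] <- 70
  expect_equal(gma_flux(t, "V3", st, p), 2 * sqrt(100) * 100)  # 2000
  # swapping the label split leaves the flux unchanged
  st2 <- st; st2$labeled[i4] <- 70; st2$unlabeled[i4] <- 30
  expect_equal(gma_flux(t, "V3", st2, p), gma_flux(t, "V3", st, p))
  # zero orders: sink flux with g = 0 and no enzyme factor reduces to a
  p$a["TG"] <- 3.25; p$g["TG"] <- 0
  expect_equal(gma_flux(t, "TG", st, p), 3.25)
  expect_error(gma_flux(t, "nope", st, p), "unknown flux")
})

test_that("split_flux is proportional and exactly additive", {
  expect_equal(split_flux(20, 30, 100), c(V_L = 6, V_UL = 14))
  expect_equal(split_flux(7, 0, 50), c(V_L = 0, V_UL = 7))
  expect_equal(split_flux(7, 50, 50), c(V_L = 7, V_UL = 0))
  expect_equal(split_flux(0, 0, 0), c(V_L = 0, V_UL = 0))
  expect_error(split_flux(1, 0, 0), class = "bl_domain_error")
  set.seed(1)
  for (i in 1:50) {
    V <- runif(1, 0, 100); tot <- runif(1, 1e-6, 200); lab <- runif(1, 0, tot)
    s <- split_flux(V, lab, tot)
    expect_identical(unname(s[1] + s[2]), V)
  }
})

test_that("assembled RHS vanishes at the constructed wild-type steady state", {
  t <- bl_topo
  p <- bl_fix$p
  rhs <- assemble_rhs(t, p)
  y <- pack_state(build_wild_type_state(t, p))
  expect_lt(max(abs(rhs(0, y)[1:68])), 1e-9)
  # the labeled stationary field under the Phe feed is stationary too
  lf <- static_label_field(t, bl_fix$f, feed_spec(phe_label = 1))
  st <- labeled_state(t, labeled = lf * p$conc, unlabeled = (1 - lf) * p$conc)
  rhs_phe <- assemble_rhs(t, p, feed = feed_spec(phe_label = 1))
  expect_lt(max(abs(rhs_phe(0, pack_state(st))[1:68])), 1e-9)
})

test_that("pooled dynamics are invariant under label redistribution", {
  t <- bl_topo
  p <- bl_fix$p
  rhs <- assemble_rhs(t, p, feed = feed_spec(phe_label = 1))
  set.seed(2)
  conc <- p$conc * runif(34, 0.5, 1.5)
  u <- runif(34); u2 <- runif(34)
  y1 <- pack_state(labeled_state(t, labeled = u * conc, unlabeled = (1 - u) * conc))
  y2 <- pack_state(labeled_state(t, labeled = u2 * conc, unlabeled = (1 - u2) * conc))
  d1 <- rhs(0, y1); d2 <- rhs(0, y2)
  pooled1 <- d1[1:34] + d1[35:68]
  pooled2 <- d2[1:34] + d2[35:68]
  expect_equal(pooled1, pooled2, tolerance = 1e-10)
})

test_that("volume-weighted mass production equals the total feed influx", {
  t <- bl_topo
  p <- bl_fix$p
  feed <- feed_spec(phe_label = 1, ca_influx = 5, pca_influx = 3)
  rhs <- assemble_rhs(t, p, feed = feed)
  set.seed(3)
  conc <- p$conc * runif(34, 0.6, 1.4)
  u <- runif(34)
  st <- labeled_state(t, labeled = u * conc, unlabeled = (1 - u) * conc)
  dy <- rhs(0, pack_state(st))
  w <- ifelse(t$pools$compartment == "cytosol", p$r, 1 - p$r)
  dmass <- sum(w * (dy[1:34] + dy[35:68])) + sum(dy[69:78])
  influx <- p$r * (p$a[["V1"]] * 100^p$g[["V1"]] * 100 +
                   p$a[["V2"]] * 100^p$g[["V2"]] * 100) +
    p$r * (feed$ca_influx + feed$pca_influx)
  expect_equal(dmass, unname(influx), tolerance = 1e-8)
})

test_that("integrator contracts hold", {
  t <- bl_topo
  p <- bl_fix$p
  # zero feed, zero initial state: identically zero trajectory
  rhs0 <- assemble_rhs(t, p, feed = feed_spec(phe_scale = 0, tyr_scale = 0))
  tr <- integrate_gma(rhs0, rep(0, 78), t_end = 5, n_out = 5)
  expect_true(all(tr$states == 0))
  # steady-state initial condition stays constant
  rhs <- assemble_rhs(t, p)
  y0 <- pack_state(build_wild_type_state(t, p))
  tr2 <- integrate_gma(rhs, y0, t_end = 20, n_out = 5,
                       rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(tr2$final[1:68] - y0[1:68])), 1e-5)
  # label split of a fixed total does not affect the pooled trajectory
  rhs_phe <- assemble_rhs(t, p, feed = feed_spec(phe_label = 1))
  mk <- function(u) pack_state(labeled_state(t, labeled = u * p$conc,
                                             unlabeled = (1 - u) * p$conc))
  trA <- integrate_gma(rhs_phe, mk(0.2), t_end = 10, n_out = 3,
                       rtol = 1e-9, atol = 1e-11)
  trB <- integrate_gma(rhs_phe, mk(0.8), t_end = 10, n_out = 3,
                       rtol = 1e-9, atol = 1e-11)
  pooledA <- trA$final[1:34] + trA$final[35:68]
  pooledB <- trB$final[1:34] + trB$final[35:68]
  expect_equal(pooledA, pooledB, tolerance = 1e-6)
})

test_that("find_steady_state recovers and knockdown states are stable", {
  t <- bl_topo
  p <- bl_gt$params
  rhs <- assemble_rhs(t, p)
  y0 <- pack_state(build_wild_type_state(t, p))
  res <- find_steady_state(rhs, y0, t)
  expect_lt(res$residual, 1e-9)
  expect_equal(res$state[1:68], y0[1:68], tolerance = 1e-6)

  # 50% CCR knockdown: new pooled steady state exists, differs from the
  # wild type, and long-horizon relaxation (oracle) lands on it
  e <- enzyme_profile(t, CCR = 0.5)
  fr <- pooled_rhs(t, p, e)
  seqc <- sequential_steady_state(t, p, e, feed_spec())
  expect_lt(max(abs(fr(seqc))), 1e-6)
  expect_gt(max(abs(seqc - p$conc) / p$conc), 0.05)
  rhs_p <- function(time, y) fr(y)
  tr <- integrate_gma(rhs_p, p$conc, t_end = 2000, rtol = 1e-8, atol = 1e-10,
                      n_out = 3, quiescent_tol = 1e-9)
  expect_equal(unname(tr$final), unname(seqc), tolerance = 1e-3)

  # local stability: perturbation relaxes back (Jacobian eigenvalues)
  n <- 34
  J <- matrix(0, n, n)
  f0 <- fr(seqc); h <- pmax(1e-6 * seqc, 1e-8)
  for (j in 1:n) { x <- seqc; x[j] <- x[j] + h[j]; J[, j] <- (fr(x) - f0) / h[j] }
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 1e-8)
})
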