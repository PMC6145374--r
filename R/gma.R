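# --- Parameter sets, labeled states and the 68-equation GMA system -------

#' Construct a kinetic parameter set
#'
#' Bundles everything that turns the topology into a concrete GMA model:
#' rate constants `a_j` for every enzymatic reaction and sink flux, kinetic
#' orders `g_j` (one per flux: every reaction has a single substrate),
#' diffusion rate constants `d_j`, the cytosolic volume fraction `r`, and
#' the compartmental steady-state concentrations the rate constants were
#' back-calculated at. Enzyme orders `h_{i,j}` are structural: 1 for the
#' catalyzing enzyme of an enzymatic reaction, 0 otherwise, so they are not
#' stored. The volume ratio `R = r/(1-r)` is always derived, never stored.
#'
#' @param t a `lignin_topology`
#' @param a named rate constants over reaction and sink flux ids
#' @param g named kinetic orders over the same ids
#' @param d named diffusion constants over link ids
#' @param r cytosolic volume fraction (default 0.9)
#' @param conc named steady-state pool concentrations (34 pools)
#' @param meta free-form provenance list
#' @return object of class `parameter_set`
#' @export
parameter_set <- function(t, a, g, d, r = 0.9, conc, meta = list()) {
  ids <- c(t$reactions$id, t$sinks$id)
  stopifnot(all(ids %in% names(a)), all(ids %in% names(g)),
            all(t$diffusion$id %in% names(d)),
            all(t$pools$pool %in% names(conc)),
            r > 0, r < 1, all(a[ids] >= 0), all(d[t$diffusion$id] >= 0))
  structure(list(a = a[ids], g = g[ids], d = d[t$diffusion$id], r = r,
                 conc = conc[t$pools$pool], meta = meta),
            class = "parameter_set")
}

#' Enzyme activity profile
#'
#' Activity multipliers relative to wild type (1 = wild type; on the
#' normalized scale the wild-type enzyme level is 100). Shared between
#' compartments for the same enzyme.
#'
#' @param t a `lignin_topology`
#' @param ... named multipliers, e.g. `PTAL = 0.2`
#' @return named numeric vector over all pathway enzymes
#' @export
enzyme_profile <- function(t, ...) {
  e <- stats::setNames(rep(1, length(t$enzymes)), t$enzymes)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), t$enzymes)
    if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
    e[names(dots)] <- as.numeric(dots)
  }
  stopifnot(all(e >= 0))
  e
}

#' Labeled model state
#'
#' @param t a `lignin_topology`
#' @param labeled,unlabeled named numeric vectors over pools (>= 0)
#' @param sinks_labeled,sinks_unlabeled accumulators for the five sinks
#'   (wall_pCA, wall_FA, H, G, S)
#' @return object of class `labeled_state`
#' @export
labeled_state <- function(t, labeled, unlabeled,
                          sinks_labeled = NULL, sinks_unlabeled = NULL) {
  sn <- sink_names()
  if (is.null(sinks_labeled)) sinks_labeled <- stats::setNames(rep(0, 5), sn)
  if (is.null(sinks_unlabeled)) sinks_unlabeled <- stats::setNames(rep(0, 5), sn)
  stopifnot(length(labeled) == nrow(t$pools), length(unlabeled) == nrow(t$pools),
            all(labeled >= 0), all(unlabeled >= 0))
  structure(list(labeled = stats::setNames(as.numeric(labeled), t$pools$pool),
                 unlabeled = stats::setNames(as.numeric(unlabeled), t$pools$pool),
                 sinks_labeled = sinks_labeled[sn],
                 sinks_unlabeled = sinks_unlabeled[sn]),
            class = "labeled_state")
}

sink_names <- function() c("wall_pCA", "wall_FA", "H", "G", "S")

# state vector layout: [L pools | UL pools | L sinks | UL sinks]
pack_state <- function(s) {
  c(s$labeled, s$unlabeled, s$sinks_labeled, s$sinks_unlabeled)
}

unpack_state <- function(t, y) {
  np <- nrow(t$pools)
  labeled_state(
    t,
    labeled = y[seq_len(np)],
    unlabeled = y[np + seq_len(np)],
    sinks_labeled = stats::setNames(y[2 * np + 1:5], sink_names()),
    sinks_unlabeled = stats::setNames(y[2 * np + 5 + 1:5], sink_names())
  )
}

#' Wild-type steady state as a labeled state
#'
#' All mass unlabeled, sinks empty; pool totals are the parameter set's
#' back-calculated compartmental concentrations, so the volume-weighted
#' total of every metabolite is 100.
#'
#' @param t a `lignin_topology`
#' @param p a `parameter_set`
#' @return a `labeled_state`
#' @export
build_wild_type_state <- function(t, p) {
  labeled_state(t, labeled = rep(0, nrow(t$pools)), unlabeled = p$conc)
}

# Precomputed index structure for fast flux evaluation.
.flux_plan <- function(t, p, e, feed) {
  rs <- rbind(
    data.frame(id = t$reactions$id, enzyme = t$reactions$enzyme,
               substrate = t$reactions$substrate,
               compartment = t$reactions$compartment,
               product = t$reactions$product, h = 1,
               stringsAsFactors = FALSE),
    data.frame(id = t$sinks$id, enzyme = NA_character_,
               substrate = t$sinks$source, compartment = t$sinks$compartment,
               product = NA_integer_, h = 0, stringsAsFactors = FALSE)
  )
  srcids <- t$metabolites$id[t$metabolites$is_source]
  is_src <- rs$substrate %in% srcids
  isub <- ifelse(is_src, NA_integer_,
                 pool_index(t, rs$substrate, rs$compartment))
  iprod <- ifelse(is.na(rs$product), NA_integer_,
                  pool_index(t, rs$product, rs$compartment))
  enzfac <- ifelse(rs$h == 1, 100 * e[rs$enzyme], 1)
  src_conc <- ifelse(is_src, vapply(rs$substrate, function(m)
    if (m %in% srcids) source_level(feed, m) else NA_real_, 0), NA_real_)
  src_lab <- ifelse(is_src, vapply(rs$substrate, function(m)
    if (m %in% srcids) source_label(feed, m) else NA_real_, 0), NA_real_)
  list(ids = rs$id, isub = isub, iprod = iprod, is_src = is_src,
       a = p$a[rs$id], g = p$g[rs$id], enzfac = as.numeric(enzfac),
       src_conc = src_conc, src_lab = src_lab,
       comp = rs$compartment,
       n_rx = nrow(t$reactions), n_sink = nrow(t$sinks))
}

#' Evaluate one GMA flux
#'
#' Power-law rate law on the pooled (labeled + unlabeled) substrate: the
#' enzymes are blind to labels, so
#' `V_j = a_j (X_L + X_UL)^g_j * (100 * activity)^h_j`,
#' with the ER pool substituted when the reaction lives in the ER
#' compartment, and the source concentration when the substrate is a
#' boundary amino acid.
#'
#' @param t a `lignin_topology`
#' @param j flux id (reaction or sink)
#' @param state a `labeled_state`
#' @param p a `parameter_set`
#' @param e enzyme activity profile (multipliers, 1 = wild type)
#' @param feed a `feed_spec` (source levels)
#' @return nonnegative rate
#' @export
gma_flux <- function(t, j, state, p, e = enzyme_profile(t),
                     feed = feed_spec()) {
  plan <- .flux_plan(t, p, e, feed)
  k <- match(j, plan$ids)
  if (is.na(k)) stop("unknown flux id: ", j)
  pooled <- if (plan$is_src[k]) plan$src_conc[k] else
    state$labeled[[plan$isub[k]]] + state$unlabeled[[plan$isub[k]]]
  if (pooled == 0 && plan$g[k] < 0)
    bl_stop("bl_domain_error", "zero pooled substrate with negative kinetic order")
  plan$a[[k]] * pooled^plan$g[[k]] * plan$enzfac[[k]]
}

#' Split a flux into labeled and unlabeled portions
#'
#' The split is proportional to how label-rich the substrate pool is:
#' `V_L = V * labeled / total`, `V_UL = V - V_L` (exactly additive).
#'
#' @param V total flux (>= 0)
#' @param substrate_labeled labeled substrate concentration
#' @param substrate_total pooled substrate concentration
#' @return numeric c(V_L, V_UL)
#' @export
split_flux <- function(V, substrate_labeled, substrate_total) {
  stopifnot(substrate_labeled >= 0, substrate_labeled <= substrate_total + 1e-12)
  if (substrate_total <= 0) {
    if (V > 0) bl_stop("bl_domain_error",
                       "positive flux from an empty substrate pool")
    return(c(V_L = 0, V_UL = 0))
  }
  vl <- V * substrate_labeled / substrate_total
  c(V_L = vl, V_UL = V - vl)
}

#' Assemble the labeled/unlabeled ODE right-hand side
#'
#' Builds the derivative function of the 68 metabolite equations (labeled
#' and unlabeled pools) plus the ten sink accumulators. Fluxes follow the
#' GMA law on pooled substrates and are split by substrate label richness;
#' diffusion enters cytosolic equations as `-d_j (X - Y)` and ER equations
#' as `+R d_j (X - Y)` with `R = r/(1-r)`; medium additions are zero-order
#' unlabeled influxes; sink accumulators integrate the absolute
#' (volume-weighted) sink fluxes.
#'
#' @inheritParams gma_flux
#' @return `function(time, y)` returning the derivative of the packed state
#' @export
assemble_rhs <- function(t, p, e = enzyme_profile(t), feed = feed_spec()) {
  plan <- .flux_plan(t, p, e, feed)
  np <- nrow(t$pools)
  r <- p$r
  R <- r / (1 - r)
  px <- pool_index(t, t$diffusion$metabolite, "cytosol")
  py <- pool_index(t, t$diffusion$metabolite, "er")
  dvec <- p$d[t$diffusion$id]
  inx <- medium_influxes(feed)
  influx_pool <- pool_index(t, as.integer(names(inx)), "cytosol")
  influx_rate <- as.numeric(inx)
  # sink accumulator weights: absolute mass = volfrac * local flux
  sid <- t$sinks$id
  sink_target <- match(t$sinks$target, sink_names())
  sink_w <- ifelse(t$sinks$compartment == "cytosol", r, 1 - r)
  ksink <- match(sid, plan$ids)
  nf <- length(plan$ids)
  live_sub <- which(!plan$is_src)
  prod_k <- which(!is.na(plan$iprod))

  function(time, y) {
    L <- y[seq_len(np)]
    UL <- y[np + seq_len(np)]
    pooled_pools <- pmax(L + UL, 0)
    sub <- numeric(nf)
    sub[plan$is_src] <- plan$src_conc[plan$is_src]
    sub[live_sub] <- pooled_pools[plan$isub[live_sub]]
    V <- plan$a * sub^plan$g * plan$enzfac
    frac <- numeric(nf)
    frac[plan$is_src] <- plan$src_lab[plan$is_src]
    ok <- live_sub[sub[live_sub] > 0]
    frac[ok] <- pmax(pmin(L[plan$isub[ok]] / sub[ok], 1), 0)
    VL <- V * frac
    VUL <- V - VL

    dL <- numeric(np); dUL <- numeric(np)
    for (k in live_sub) {
      i <- plan$isub[k]
      dL[i] <- dL[i] - VL[k]; dUL[i] <- dUL[i] - VUL[k]
    }
    for (k in prod_k) {
      i <- plan$iprod[k]
      dL[i] <- dL[i] + VL[k]; dUL[i] <- dUL[i] + VUL[k]
    }
    # diffusion cross-talk
    DfL <- dvec * (L[px] - L[py])
    DfUL <- dvec * (UL[px] - UL[py])
    dL[px] <- dL[px] - DfL;      dUL[px] <- dUL[px] - DfUL
    dL[py] <- dL[py] + R * DfL;  dUL[py] <- dUL[py] + R * DfUL
    # unlabeled medium additions
    dUL[influx_pool] <- dUL[influx_pool] + influx_rate

    dSinkL <- numeric(5); dSinkUL <- numeric(5)
    for (s in seq_along(ksink)) {
      j <- ksink[s]; tg <- sink_target[s]; w <- sink_w[s]
      dSinkL[tg] <- dSinkL[tg] + w * VL[j]
      dSinkUL[tg] <- dSinkUL[tg] + w * VUL[j]
    }
    c(dL, dUL, dSinkL, dSinkUL)
  }
}

# Pooled (label-free) subsystem: because enzymes are label-blind, the pooled
# concentrations obey an autonomous 34-dim GMA system. Used for fast
# steady-state computation after perturbations.
pooled_rhs <- function(t, p, e = enzyme_profile(t), feed = feed_spec()) {
  plan <- .flux_plan(t, p, e, feed)
  np <- nrow(t$pools)
  r <- p$r; R <- r / (1 - r)
  px <- pool_index(t, t$diffusion$metabolite, "cytosol")
  py <- pool_index(t, t$diffusion$metabolite, "er")
  dvec <- p$d[t$diffusion$id]
  inx <- medium_influxes(feed)
  influx_pool <- pool_index(t, as.integer(names(inx)), "cytosol")
  influx_rate <- as.numeric(inx)
  live_sub <- which(!plan$is_src)
  prod_k <- which(!is.na(plan$iprod))
  function(conc) {
    conc <- pmax(conc, 0)
    sub <- numeric(length(plan$ids))
    sub[plan$is_src] <- plan$src_conc[plan$is_src]
    sub[live_sub] <- conc[plan$isub[live_sub]]
    V <- plan$a * sub^plan$g * plan$enzfac
    dx <- numeric(np)
    for (k in live_sub) dx[plan$isub[k]] <- dx[plan$isub[k]] - V[k]
    for (k in prod_k) dx[plan$iprod[k]] <- dx[plan$iprod[k]] + V[k]
    Df <- dvec * (conc[px] - conc[py])
    dx[px] <- dx[px] - Df
    dx[py] <- dx[py] + R * Df
    dx[influx_pool] <- dx[influx_pool] + influx_rate
    dx
  }
}

# All reaction/sink flux values plus net diffusion fluxes at a pooled state.
flux_values_at <- function(t, p, conc, e = enzyme_profile(t),
                           feed = feed_spec()) {
  plan <- .flux_plan(t, p, e, feed)
  sub <- numeric(length(plan$ids))
  sub[plan$is_src] <- plan$src_conc[plan$is_src]
  live <- which(!plan$is_src)
  sub[live] <- pmax(conc[plan$isub[live]], 0)
  V <- stats::setNames(plan$a * sub^plan$g * plan$enzfac, plan$ids)
  px <- pool_index(t, t$diffusion$metabolite, "cytosol")
  py <- pool_index(t, t$diffusion$metabolite, "er")
  D <- stats::setNames(p$d[t$diffusion$id] * (conc[px] - conc[py]),
                       t$diffusion$id)
  c(V, D)
}

#' Integrate the dynamic model
#'
#' Adaptive embedded Runge-Kutta (Cash-Karp 4(5)) integrator with step-size
#' control, written for this package because no ODE solver is available in
#' the dependency closure. Steps are accepted when the embedded error
#' estimate satisfies the mixed tolerance; negative undershoots beyond
#' `-atol` are clipped-and-flagged. Optionally stops early once the state is
#' quiescent (max |dy/dt| below `quiescent_tol`).
#'
#' @param rhs derivative function `f(time, y)`
#' @param y0 initial state vector (nonnegative)
#' @param t_end finite time horizon
#' @param rtol,atol relative/absolute tolerances
#' @param n_out number of equally spaced output times (>= 2)
#' @param quiescent_tol if finite, stop when `max(abs(dy))` falls below it
#' @param max_steps step budget before failure is reported
#' @return list of class `gma_trajectory`: `time` vector, `states` matrix
#'   (rows = times), `final`, `steps`, `quiescent`
#' @export
integrate_gma <- function(rhs, y0, t_end, rtol = 1e-8, atol = 1e-10,
                          n_out = 21, quiescent_tol = Inf,
                          max_steps = 200000L) {
  stopifnot(is.finite(t_end), t_end > 0, all(y0 >= -atol))
  # Cash-Karp tableau
  A <- list(c(1/5),
            c(3/40, 9/40),
            c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  tout <- seq(0, t_end, length.out = max(2L, n_out))
  out <- matrix(NA_real_, length(tout), length(y0))
  out[1, ] <- y0
  iout <- 2L
  tcur <- 0; y <- y0
  h <- t_end / 100
  nstep <- 0L
  quiescent <- FALSE
  while (tcur < t_end && iout <= length(tout)) {
    nstep <- nstep + 1L
    if (nstep > max_steps)
      bl_stop("bl_integration_failure",
              sprintf("step budget exhausted at t = %.4g (step size %.3g)", tcur, h))
    h <- min(h, t_end - tcur)
    k1 <- rhs(tcur, y)
    if (any(!is.finite(k1)))
      bl_stop("bl_integration_failure", sprintf("non-finite derivative at t = %.4g", tcur))
    k2 <- rhs(tcur + h / 5, y + h * A[[1]][1] * k1)
    k3 <- rhs(tcur + 3 * h / 10, y + h * (A[[2]][1] * k1 + A[[2]][2] * k2))
    k4 <- rhs(tcur + 3 * h / 5, y + h * (A[[3]][1] * k1 + A[[3]][2] * k2 + A[[3]][3] * k3))
    k5 <- rhs(tcur + h, y + h * (A[[4]][1] * k1 + A[[4]][2] * k2 + A[[4]][3] * k3 + A[[4]][4] * k4))
    k6 <- rhs(tcur + 7 * h / 8,
              y + h * (A[[5]][1] * k1 + A[[5]][2] * k2 + A[[5]][3] * k3 +
                         A[[5]][4] * k4 + A[[5]][5] * k5))
    y5 <- y + h * (c5[1] * k1 + c5[3] * k3 + c5[4] * k4 + c5[6] * k6)
    y4 <- y + h * (c4[1] * k1 + c4[3] * k3 + c4[4] * k4 + c4[5] * k5 + c4[6] * k6)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (is.na(err) || err > 1) {
      h <- h * max(0.2, 0.9 * err^(-0.25))
      if (h < 1e-14 * t_end)
        bl_stop("bl_integration_failure",
                sprintf("step-size collapse at t = %.4g", tcur))
      next
    }
    tnew <- tcur + h
    if (any(y5 < -atol * 100)) {
      # severe undershoot: retry with a smaller step
      h <- h / 2
      if (h < 1e-14 * t_end)
        bl_stop("bl_integration_failure", "persistent negative undershoot")
      next
    }
    y5[y5 < 0] <- 0
    while (iout <= length(tout) && tout[iout] <= tnew + 1e-12) {
      # linear interpolation within the accepted step (output only)
      th <- (tout[iout] - tcur) / h
      out[iout, ] <- y + th * (y5 - y)
      iout <- iout + 1L
    }
    y <- y5; tcur <- tnew
    if (is.finite(quiescent_tol) && max(abs(k1)) < quiescent_tol) {
      quiescent <- TRUE
      if (iout <= length(tout)) {
        idx <- iout:length(tout)
        out[idx, ] <- matrix(y, length(idx), length(y), byrow = TRUE)
      }
      iout <- length(tout) + 1L
      break
    }
    h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
  }
  structure(list(time = tout, states = out, final = y, steps = nstep,
                 quiescent = quiescent),
            class = "gma_trajectory")
}

# Damped Newton iteration with numerical Jacobian. With `positive = TRUE`
# the iteration runs in log-concentration space, which enforces positivity
# and copes with steady states many orders of magnitude from the starting
# point (sublinear kinetic orders can push perturbed steady states very
# far on the concentration scale).
newton_steady_state <- function(f, x0, tol = 1e-10, max_iter = 60L,
                                lower = 0, positive = FALSE) {
  n <- length(x0)
  if (positive) {
    z <- log(pmax(x0, 1e-9))
    fz <- f(exp(z))
    for (it in seq_len(max_iter)) {
      nrm <- max(abs(fz))
      if (nrm < tol) break
      J <- matrix(0, n, n)
      h <- 1e-6
      for (j in seq_len(n)) {
        zp <- z; zp[j] <- zp[j] + h
        J[, j] <- (f(exp(zp)) - fz) / h
      }
      step <- tryCatch(solve(J, -fz), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(pmax(step, -4), 4)  # trust region on the log scale
      lam <- 1
      repeat {
        zn <- z + lam * step
        fn <- f(exp(zn))
        if (max(abs(fn)) < nrm || lam < 1e-5) break
        lam <- lam / 2
      }
      if (max(abs(fn)) >= nrm) break
      z <- zn; fz <- fn
    }
    return(list(x = exp(z), residual = max(abs(fz)),
                converged = max(abs(fz)) < tol))
  }
  x <- x0
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    nrm <- max(abs(fx))
    if (nrm < tol) break
    J <- matrix(0, n, n)
    hh <- pmax(1e-7 * abs(x), 1e-9)
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + hh[j]
      J[, j] <- (f(xp) - fx) / hh[j]
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, lower)
      fn <- f(xn)
      if (max(abs(fn)) < nrm || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(fn)) >= nrm) break  # stalled
    x <- xn; fx <- fn
  }
  list(x = x, residual = max(abs(fx)), converged = max(abs(fx)) < tol)
}

# Exact steady state by forward substitution along the pathway DAG.
# The default network has no regulatory feedback, so metabolites can be
# processed in topological order: for each metabolite the two compartmental
# pools satisfy a 2x2 system (mass balance of the pair under known absolute
# inflows), solved by Newton on the log scale. Works for arbitrarily
# perturbed enzyme activities and medium influxes, where the new steady
# state can be many orders of magnitude from the wild type.
sequential_steady_state <- function(t, p, e = enzyme_profile(t),
                                    feed = feed_spec()) {
  paired <- t$metabolites$id[t$metabolites$has_er_pool]
  srcids <- t$metabolites$id[t$metabolites$is_source]
  rx <- rbind(
    data.frame(id = t$reactions$id, sub = t$reactions$substrate,
               prod = t$reactions$product, comp = t$reactions$compartment,
               enz = t$reactions$enzyme, stringsAsFactors = FALSE),
    data.frame(id = t$sinks$id, sub = t$sinks$source, prod = NA_integer_,
               comp = t$sinks$compartment, enz = NA_character_,
               stringsAsFactors = FALSE))
  rx$a <- p$a[rx$id]
  rx$g <- p$g[rx$id]
  rx$ef <- ifelse(is.na(rx$enz), 1, 100 * e[rx$enz])
  # topological order over paired metabolites
  edges <- rx[!is.na(rx$prod) & rx$sub %in% paired, c("sub", "prod")]
  indeg <- stats::setNames(rep(0L, length(paired)), paired)
  for (pr in edges$prod) if (as.character(pr) %in% names(indeg))
    indeg[as.character(pr)] <- indeg[as.character(pr)] + 1L
  order_ <- integer(0)
  queue <- paired[indeg[as.character(paired)] == 0L]
  indeg2 <- indeg
  while (length(queue)) {
    m <- queue[1]; queue <- queue[-1]
    order_ <- c(order_, m)
    for (pr in edges$prod[edges$sub == m]) {
      key <- as.character(pr)
      if (key %in% names(indeg2)) {
        indeg2[key] <- indeg2[key] - 1L
        if (indeg2[key] == 0L) queue <- c(queue, pr)
      }
    }
  }
  if (length(order_) != length(paired)) return(NULL)  # cycle: caller falls back
  r <- p$r
  conc <- stats::setNames(rep(NA_real_, nrow(t$pools)), t$pools$pool)
  in_abs <- stats::setNames(rep(0, nrow(t$pools)), t$pools$pool)
  # source-driven entry fluxes and medium influxes
  for (k in which(rx$sub %in% srcids)) {
    v <- rx$a[k] * source_level(feed, rx$sub[k])^rx$g[k] * rx$ef[k]
    ip <- pool_index(t, rx$prod[k], rx$comp[k])
    in_abs[ip] <- in_abs[ip] + (if (rx$comp[k] == "cytosol") r else 1 - r) * v
  }
  inx <- medium_influxes(feed)
  for (mm in names(inx)) if (inx[[mm]] > 0) {
    ip <- pool_index(t, as.integer(mm), "cytosol")
    in_abs[ip] <- in_abs[ip] + r * inx[[mm]]
  }
  for (m in order_) {
    px <- pool_index(t, m, "cytosol"); py <- pool_index(t, m, "er")
    kx <- which(rx$sub == m & rx$comp == "cytosol")
    ky <- which(rx$sub == m & rx$comp == "er")
    d <- p$d[[paste0("D", m)]]
    ix <- in_abs[px]; iy <- in_abs[py]
    # residuals of the pair in absolute units. Unknowns are (log Y, Delta)
    # with X = Y + Delta, so the diffusion flux r*d*Delta never suffers
    # cancellation even when both pools are huge and nearly equal.
    fpair <- function(z) {
      Y <- exp(z[1]); X <- Y + z[2]
      if (X <= 0) return(c(Inf, Inf))
      ox <- if (length(kx)) sum(r * rx$a[kx] * X^rx$g[kx] * rx$ef[kx]) else 0
      oy <- if (length(ky)) sum((1 - r) * rx$a[ky] * Y^rx$g[ky] * rx$ef[ky]) else 0
      D <- r * d * z[2]
      c(ix - ox - D, iy - oy + D)
    }
    jpair <- function(z) {
      Y <- exp(z[1]); X <- Y + z[2]
      dox <- if (length(kx)) sum(r * rx$a[kx] * rx$g[kx] * X^(rx$g[kx] - 1) * rx$ef[kx]) else 0
      doy <- if (length(ky)) sum((1 - r) * rx$a[ky] * rx$g[ky] * Y^(rx$g[ky] - 1) * rx$ef[ky]) else 0
      matrix(c(-dox * Y, -doy * Y,
               -dox - r * d, r * d), 2, 2)
    }
    z <- c(log(max(p$conc[py], 1e-9)), p$conc[px] - p$conc[py])
    fz <- fpair(z)
    scale_ <- max(1, ix + iy)
    for (it in 1:300) {
      if (max(abs(fz)) < 1e-12 * scale_) break
      step <- tryCatch(solve(jpair(z), -fz), error = function(err) NULL)
      if (is.null(step)) break
      step[1] <- min(max(step[1], -3), 3)
      lam <- 1
      repeat {
        zn <- z + lam * step
        fn <- fpair(zn)
        if (max(abs(fn)) < max(abs(fz)) || lam < 1e-8) break
        lam <- lam / 2
      }
      if (max(abs(fn)) >= max(abs(fz))) break
      z <- zn; fz <- fn
    }
    Y <- exp(z[1]); X <- Y + z[2]
    conc[px] <- X; conc[py] <- Y
    for (k in kx) if (!is.na(rx$prod[k])) {
      ip <- pool_index(t, rx$prod[k], rx$comp[k])
      in_abs[ip] <- in_abs[ip] + r * rx$a[k] * X^rx$g[k] * rx$ef[k]
    }
    for (k in ky) if (!is.na(rx$prod[k])) {
      ip <- pool_index(t, rx$prod[k], rx$comp[k])
      in_abs[ip] <- in_abs[ip] + (1 - r) * rx$a[k] * Y^rx$g[k] * rx$ef[k]
    }
  }
  conc
}

#' Find a steady state of the dynamic model
#'
#' Damped Newton iteration (numerical Jacobian) on the metabolite equations,
#' globalized by long-horizon relaxation with the integrator when Newton
#' stalls. Sink accumulators grow linearly and are excluded from the root
#' condition.
#'
#' @param rhs assembled derivative function from [assemble_rhs()]
#' @param guess a `labeled_state` or packed state vector
#' @param t a `lignin_topology` (for the state layout)
#' @param tol residual tolerance
#' @return list with `state` (packed vector), `residual`, `converged`
#' @export
find_steady_state <- function(rhs, guess, t, tol = 1e-9) {
  y0 <- if (inherits(guess, "labeled_state")) pack_state(guess) else guess
  np2 <- 2L * nrow(t$pools)
  f <- function(x) rhs(0, c(x, numeric(10)))[seq_len(np2)]
  res <- newton_steady_state(f, y0[seq_len(np2)], tol = tol)
  if (!res$converged) {
    traj <- tryCatch(
      integrate_gma(rhs, c(res$x, numeric(10)), t_end = 500,
                    rtol = 1e-7, atol = 1e-9, quiescent_tol = tol / 10),
      error = function(e) NULL)
    if (!is.null(traj)) {
      res2 <- newton_steady_state(f, traj$final[seq_len(np2)], tol = tol)
      if (res2$residual <= res$residual) res <- res2
    }
  }
  list(state = c(res$x, y0[np2 + 1:10]), residual = res$residual,
       converged = res$converged)
}

#' Volume-weighted total mass of a state
#'
#' The conserved quantity of the two-compartment formulation: cytosolic
#' pools and cytosol-side sink accumulators weigh `r`, ER-side ones `1-r`
#' (sink accumulators are already stored in absolute units).
#'
#' @param t a `lignin_topology`
#' @param state a `labeled_state`
#' @param r cytosolic volume fraction
#' @param component "total", "labeled" or "unlabeled"
#' @return scalar mass
#' @export
total_mass <- function(t, state, r = 0.9, component = "total") {
  w <- ifelse(t$pools$compartment == "cytosol", r, 1 - r)
  pools <- switch(component,
    total = state$labeled + state$unlabeled,
    labeled = state$labeled,
    unlabeled = state$unlabeled)
  sinks <- switch(component,
    total = state$sinks_labeled + state$sinks_unlabeled,
    labeled = state$sinks_labeled,
    unlabeled = state$sinks_unlabeled)
  sum(w * pools) + sum(sinks)
}
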