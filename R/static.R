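# --- Static model: route-based steady-state flux sampling ----------------
#
# Admissible steady-state flux distributions are sampled on a positive basis
# of source-to-sink routes through the two-compartment network. Every route
# carries absolute (volume-weighted) mass from PAL/PTAL entry to one of the
# seven absorbing sinks, so any nonnegative combination balances exactly;
# sampling route weights is equivalent to sampling the free fluxes of the
# null-space within box bounds, but never leaves the feasible cone.
# Diffusion gross backflows are sampled alongside, which fixes a consistent
# stationary label field and (later) the compartmental concentration splits.

.bl_route_catalog <- function() {
  pfx <- c("V1", "+D2", "V18")                 # Phe -> CA -> (ER) -> Y4
  list(
    # Phe-derived mass
    p_g   = c(pfx, "V25", "V26", "V23", "-D9", "V9", "V10", "V11", "V13", "TG"),
    p_s   = c(pfx, "V25", "V26", "V23", "V24", "V27", "V28", "V32", "-D16", "V15", "V16", "TS"),
    p_h   = c(pfx, "V25", "V31", "V30", "-D19", "TH"),
    p_cc  = c(pfx, "V19", "V21", "V27", "V28", "V29", "-D13", "TG"),
    p_e2  = c(pfx, "E2"),
    p_e4  = c(pfx, "V19", "V20", "E4"),
    p_x_g = c(pfx, "-D4", "V3", "V8", "+D8", "V23", "-D9", "V9", "V10", "V11", "V13", "TG"),
    p_x_s = c(pfx, "-D4", "V4", "V5", "+D7", "V22", "V28", "V32", "-D16", "V15", "V16", "TS"),
    # Tyr-derived mass
    t_g   = c("V2", "V3", "V8", "+D8", "V23", "-D9", "V9", "V10", "V11", "V13", "TG"),
    t_s   = c("V2", "V4", "V5", "+D7", "V22", "V28", "V32", "-D16", "V15", "V16", "TS"),
    t_s2  = c("V2", "V4", "V5", "+D7", "V22", "V28", "V29", "V33", "-D17", "V17", "TS"),
    t_fc  = c("V2", "V4", "V5", "V7", "V11", "V13", "TG"),
    t_cc  = c("V2", "V4", "V6", "V10", "V11", "V13", "TG"),
    t_h   = c("V2", "V3", "V12", "V14", "TH"),
    t_h2  = c("V2", "V3", "+D5", "V31", "V30", "-D19", "TH"),
    t_e1  = c("V2", "E1"),
    t_e3  = c("V2", "V4", "V5", "E3")
  )
}

# Baseline absolute route flows: the stated world of the generator. Chosen
# once for a G-rich grass stem (H ~ 8%, G ~ 58%, S ~ 35% of monomer flux,
# S/G ~ 0.6, substantial wall-bound pCA, moderate wall-bound FA) with the
# channeling pattern built in: the dominant Phe route reaches G-lignin
# through the ER shikimate gate, the dominant Tyr route reaches S-lignin by
# crossing into the ER ferulate channel.
.bl_route_base <- function() {
  c(p_g = 28, p_s = 4, p_h = 2, p_cc = 3, p_e2 = 6, p_e4 = 4,
    p_x_g = 4, p_x_s = 2,
    t_g = 5, t_s = 16, t_s2 = 5, t_fc = 3, t_cc = 2, t_h = 2.5,
    t_h2 = 1.5, t_e1 = 6, t_e3 = 4)
}

# Convert absolute route flows into local-unit flux values.
.routes_to_fluxes <- function(t, weights, r = 0.9) {
  cat_ <- .bl_route_catalog()
  ids <- flux_ids(t)
  v <- stats::setNames(numeric(length(ids)), ids)
  comp <- stats::setNames(c(t$reactions$compartment, t$sinks$compartment),
                          c(t$reactions$id, t$sinks$id))
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (w == 0) next
    for (step in cat_[[nm]]) {
      if (startsWith(step, "+D")) {
        id <- substring(step, 2); v[id] <- v[id] + w / r
      } else if (startsWith(step, "-D")) {
        id <- substring(step, 2); v[id] <- v[id] - w / r
      } else {
        vf <- if (comp[[step]] == "cytosol") r else 1 - r
        v[step] <- v[step] + w / vf
      }
    }
  }
  v
}

# Sample gross diffusion backflows (absolute units). rho is the
# receiver-to-donor gross ratio; the receiving pool's share of the
# metabolite grows with rho.
.sample_gross_back <- function(t, values, r, rho_range = c(0.2, 0.8),
                               dead_back = c(0.5, 3)) {
  ids <- t$diffusion$id
  out <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    Dabs <- r * abs(values[[id]])
    if (Dabs > 1e-12) {
      rho <- stats::runif(1, rho_range[1], rho_range[2])
      out[id] <- Dabs * rho / (1 - rho)
    } else {
      out[id] <- stats::runif(1, dead_back[1], dead_back[2])
    }
  }
  out
}

# Stationary label field of a route sample under a feed, using the sampled
# gross diffusion flows.
static_label_field <- function(t, f, feed) {
  gb <- f$gross_back
  fwd <- stats::setNames(f$r * abs(f$values[t$diffusion$id]) + gb, t$diffusion$id)
  terms <- .inflow_terms(t, f, feed,
                         gross_flows = list(fwd = fwd, back = gb))
  .solve_label_balance(t, terms, feed)
}

#' Observation set: the measurable surface of one scenario
#'
#' @param totals named numeric: `H`, `G`, `S`, `total`, `S_over_G`,
#'   `wall_pCA`, `wall_FA` (absolute normalized mass flux into each sink)
#' @param incorporation named numeric label-incorporation fractions for
#'   `H`, `G`, `S`, `total`, `wall_pCA`, `wall_FA`
#' @return object of class `observation_set`
#' @export
observation_set <- function(totals, incorporation) {
  stopifnot(all(c("H", "G", "S", "total", "S_over_G") %in% names(totals)))
  inc <- incorporation[!is.na(incorporation)]
  if (length(inc) && (any(inc < -1e-9) || any(inc > 1 + 1e-9)))
    stop("incorporation fractions must lie in [0,1]")
  if (any(totals[c("H", "G", "S", "total")] < 0))
    stop("monomer totals must be nonnegative")
  structure(list(totals = totals, incorporation = incorporation),
            class = "observation_set")
}

# Readouts implied by a flux distribution and a label field (quasi-steady
# incorporation endpoint).
readouts_from_fluxes <- function(t, values, lf, r = 0.9) {
  H <- r * values[["TH"]]; G <- r * values[["TG"]]; S <- r * values[["TS"]]
  e1 <- r * values[["E1"]]; e2 <- (1 - r) * values[["E2"]]
  e3 <- r * values[["E3"]]; e4 <- (1 - r) * values[["E4"]]
  wall_pca <- e1 + e2; wall_fa <- e3 + e4
  lig <- H + G + S
  sinks <- t$sinks
  lab_of <- function(id) {
    s <- sinks[sinks$id == id, ]
    lf[[pool_index(t, s$source, s$compartment)]]
  }
  iH <- lab_of("TH"); iG <- lab_of("TG"); iS <- lab_of("TS")
  itot <- if (lig > 0) (H * iH + G * iG + S * iS) / lig else NA_real_
  ipca <- if (wall_pca > 0) (e1 * lab_of("E1") + e2 * lab_of("E2")) / wall_pca else NA_real_
  ifa <- if (wall_fa > 0) (e3 * lab_of("E3") + e4 * lab_of("E4")) / wall_fa else NA_real_
  observation_set(
    totals = c(H = H, G = G, S = S, total = lig,
               S_over_G = if (G > 0) S / G else NA_real_,
               wall_pCA = wall_pca, wall_FA = wall_fa),
    incorporation = c(H = iH, G = iG, S = iS, total = itot,
                      wall_pCA = ipca, wall_FA = ifa)
  )
}

# Static readouts of a sampled flux distribution for the three
# influx-free scenarios.
static_readouts <- function(t, f) {
  feeds <- list(control = feed_spec(),
                phe_label = feed_spec(phe_label = 1),
                tyr_label = feed_spec(tyr_label = 1))
  lapply(feeds, function(fd) {
    lf <- static_label_field(t, f, fd)
    readouts_from_fluxes(t, f$values, lf, f$r)
  })
}

in_band <- function(value, lo, hi) !is.na(value) && value >= lo && value <= hi

# check a scenario's observation set against one band table
.check_bands <- function(obs, bands) {
  ok <- TRUE
  for (k in seq_len(nrow(bands))) {
    b <- bands[k, ]
    v <- if (b$type == "total") obs$totals[[b$observable]] else
      obs$incorporation[[b$observable]]
    if (!in_band(v, b$lo, b$hi)) ok <- FALSE
  }
  ok
}

#' Sample admissible steady-state flux distributions
#'
#' Rejection sampler over the route-weight cone: route flows are drawn
#' uniformly within box bounds around the baseline flows, gross diffusion
#' backflows are sampled per link, the stationary label fields for the
#' labeled-Phe and labeled-Tyr feeds are solved, and the sample is accepted
#' when its static readouts fall within the target bands for the control
#' and both labeling scenarios (dilution scenarios involve a perturbed
#' steady state and are checked dynamically during parameterization).
#'
#' @param t a `lignin_topology`
#' @param targets an `admissibility_criteria` object, or NULL to accept
#'   every mass-balanced sample
#' @param n number of distributions to return
#' @param seed integer seed
#' @param r cytosolic volume fraction
#' @param spread multiplicative half-width of the uniform route-weight
#'   boxes (bounds are `base * (1 -/+ spread)`)
#' @param max_draws rejection budget
#' @return list of `flux_distribution` (class `flux_ensemble`) with
#'   attribute `acceptance_rate`; raises `bl_infeasible_targets` when the
#'   budget is exhausted before any sample is accepted
#' @export
sample_steady_state_fluxes <- function(t, targets = NULL, n = 10, seed = 1,
                                       r = 0.9, spread = 0.5,
                                       max_draws = 200 * n) {
  set.seed(seed)
  base <- .bl_route_base()
  lo <- base * (1 - spread); hi <- base * (1 + spread)
  out <- list()
  draws <- 0L
  while (length(out) < n && draws < max_draws) {
    draws <- draws + 1L
    w <- stats::runif(length(base), lo, hi)
    names(w) <- names(base)
    v <- .routes_to_fluxes(t, w, r)
    f <- flux_distribution(v, r = r)
    f$gross_back <- .sample_gross_back(t, v, r)
    f$route_weights <- w
    lf_phe <- static_label_field(t, f, feed_spec(phe_label = 1))
    lf_tyr <- static_label_field(t, f, feed_spec(tyr_label = 1))
    f$label_fields <- list(phe_label = lf_phe, tyr_label = lf_tyr)
    f$labeled_fraction <- list(
      phe_label = flux_label_fractions(t, f, lf_phe, feed_spec(phe_label = 1)),
      tyr_label = flux_label_fractions(t, f, lf_tyr, feed_spec(tyr_label = 1)))
    if (!is.null(targets)) {
      obs <- static_readouts(t, f)
      ok <- TRUE
      for (sc in c("control", "phe_label", "tyr_label")) {
        if (!sc %in% names(targets$scenarios)) next
        if (!.check_bands(obs[[sc]], targets$scenarios[[sc]]$bands)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      f$static_observations <- obs
    }
    out[[length(out) + 1L]] <- f
  }
  if (length(out) == 0 && !is.null(targets))
    bl_stop("bl_infeasible_targets",
            sprintf("no admissible flux distribution found in %d draws", draws))
  if (length(out) < n)
    warning(sprintf("only %d of %d requested distributions found in budget",
                    length(out), n))
  structure(out, class = "flux_ensemble",
            acceptance_rate = length(out) / draws)
}
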