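# --- From a static flux sample to a full kinetic parameter set -----------

#' Back-calculate GMA rate constants at a steady state
#'
#' Inverts the GMA rate law at the steady state:
#' `a_j = V_j / (pooled_substrate^g_j * (100 * activity)^h_j)`, so the given
#' flux distribution is an exact steady-state flux vector of the resulting
#' model. Fluxes with value zero get `a_j = 0`.
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution`
#' @param conc named steady-state pool concentrations
#' @param g named kinetic orders (reactions and sinks)
#' @param e wild-type enzyme activity profile
#' @param feed reference feed (source levels; default wild type)
#' @return named vector of rate constants
#' @export
back_calculate_rate_constants <- function(t, f, conc, g,
                                          e = enzyme_profile(t),
                                          feed = feed_spec()) {
  ids <- c(t$reactions$id, t$sinks$id)
  comp <- c(t$reactions$compartment, t$sinks$compartment)
  subm <- c(t$reactions$substrate, t$sinks$source)
  enz <- c(t$reactions$enzyme, rep(NA_character_, nrow(t$sinks)))
  srcids <- t$metabolites$id[t$metabolites$is_source]
  a <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    v <- f$values[[ids[k]]]
    if (v == 0) { a[k] <- 0; next }
    s <- if (subm[k] %in% srcids) source_level(feed, subm[k]) else
      conc[[pool_index(t, subm[k], comp[k])]]
    if (s <= 0)
      bl_stop("bl_domain_error",
              sprintf("zero steady-state concentration of pool %s feeding flux %s",
                      paste0(if (comp[k] == "cytosol") "X" else "Y", subm[k]),
                      ids[k]))
    ef <- if (is.na(enz[k])) 1 else 100 * e[[enz[k]]]
    a[k] <- v / (s^g[[ids[k]]] * ef)
  }
  a
}

#' Construct a full parameter set from a static flux sample
#'
#' Solves the compartmental concentration split and diffusion constant of
#' every link from the sampled net and gross diffusion flows (equivalently,
#' from the net flux, its labeled portion and the two label levels via the
#' three algebraic equations), samples the four label-degenerate pools on
#' the receiving side of their diffusion links, and back-calculates the
#' rate constants so that the flux distribution is an exact steady state.
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution` from [sample_steady_state_fluxes()]
#'   (carries gross backflows and label fields)
#' @param g named kinetic orders from [sample_kinetic_orders()]
#' @param r cytosolic volume fraction
#' @param seed optional seed for the degenerate-pool draws
#' @param deg_draws optional data frame (from
#'   [sample_degenerate_steady_states()]) to reuse instead of sampling
#' @param d_max reject solutions whose diffusion constants exceed this cap
#'   (keeps the ODE system integrable; see the methods vignette)
#' @return a `parameter_set`
#' @export
construct_parameter_set <- function(t, f, g, r = 0.9, seed = NULL,
                                    deg_draws = NULL, d_max = 50) {
  # degeneracy is detected on the net-donor field, where pools whose only
  # exchange is gross (zero net diffusion) are flagged NA and skipped:
  # those need no Eq-8 sampling, their split is pinned at X = Y = 100
  lf_net <- propagate_label_fractions(t, f, feed_spec(phe_label = 1))
  deg <- detect_degenerate_pools(t, lf_net, tol = 1e-9)
  if (is.null(deg_draws)) {
    deg_draws <- sample_degenerate_steady_states(t, f, deg, r = r, seed = seed)
  }
  conc <- stats::setNames(rep(NA_real_, nrow(t$pools)), t$pools$pool)
  dvec <- stats::setNames(numeric(nrow(t$diffusion)), t$diffusion$id)
  for (k in seq_len(nrow(t$diffusion))) {
    m <- t$diffusion$metabolite[k]
    id <- t$diffusion$id[k]
    px <- pool_index(t, m, "cytosol"); py <- pool_index(t, m, "er")
    Dloc <- f$values[[id]]
    if (m %in% deg) {
      row <- deg_draws[deg_draws$metabolite == m, ]
      conc[px] <- row$X_ss; conc[py] <- row$Y_ss; dvec[id] <- row$d
      next
    }
    Dabs <- r * abs(Dloc)
    b <- f$gross_back[[id]]
    if (Dabs <= 1e-12) {
      # no net transfer: pools split evenly, d from the gross exchange
      conc[px] <- 100; conc[py] <- 100
      dvec[id] <- (b / r) / 100
      next
    }
    # donor : receiver gross ratio fixes the concentration split
    ratio <- (Dabs + b) / b          # donor conc / receiver conc
    if (Dloc > 0) {                  # cytosol is the donor
      Y <- 100 / (r * ratio + (1 - r)); X <- ratio * Y
    } else {
      X <- 100 / (r + (1 - r) * ratio); Y <- ratio * X
    }
    conc[px] <- X; conc[py] <- Y
    dvec[id] <- Dloc / (X - Y)
  }
  if (any(dvec < 0))
    bl_stop("bl_infeasible_labeling", "negative diffusion constant")
  if (any(dvec > d_max))
    bl_stop("bl_infeasible_labeling",
            sprintf("diffusion constant above cap %.3g", d_max))
  a <- back_calculate_rate_constants(t, f, conc, g)
  parameter_set(t, a = a, g = g, d = dvec, r = r, conc = conc,
                meta = list(degenerate = deg_draws,
                            route_weights = f$route_weights))
}

#' Verify a diffusion-link solution against the label equations
#'
#' Convenience wrapper used in tests: recomputes (d, X, Y) for one link of
#' a constructed parameter set through [solve_diffusion_link()] from the
#' net flux, its labeled portion and the label levels, and returns both
#' solutions.
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution` with label fields
#' @param p a `parameter_set`
#' @param metabolite metabolite id of the link
#' @param feed feed whose label field is used
#' @return list with `algebraic` (from [solve_diffusion_link()]) and
#'   `constructed` (from the parameter set)
#' @export
cross_check_diffusion_link <- function(t, f, p, metabolite,
                                       feed = feed_spec(phe_label = 1)) {
  id <- paste0("D", metabolite)
  lf <- static_label_field(t, f, feed)
  px <- pool_index(t, metabolite, "cytosol")
  py <- pool_index(t, metabolite, "er")
  D <- f$values[[id]]
  # labeled portion of the net diffusion implied by the gross flows
  b <- f$gross_back[[id]] / p$r   # local units
  fwd <- abs(D) + b
  DL <- if (D >= 0) fwd * lf[[px]] - b * lf[[py]] else
    -(fwd * lf[[py]] - b * lf[[px]])
  alg <- solve_diffusion_link(D, DL, lf[[px]], lf[[py]], r = p$r)
  list(algebraic = alg,
       constructed = list(d = p$d[[id]], X_ss = p$conc[[px]],
                          Y_ss = p$conc[[py]]))
}
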