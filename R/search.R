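# --- Monte Carlo parameterization and the explore-and-exploit search -----

#' Kinetic-order sampling ranges
#'
#' Substrate/activator orders are drawn from [0, 1]; the four wall-phenolic
#' efflux orders from [0, 4]; inhibitor orders (none in the default model)
#' from [-4, 0].
#'
#' @param substrate,efflux,inhibitor length-2 intervals
#' @return list of class `sampling_ranges`
#' @export
sampling_ranges <- function(substrate = c(0, 1), efflux = c(0, 4),
                            inhibitor = c(-4, 0)) {
  structure(list(substrate = substrate, efflux = efflux,
                 inhibitor = inhibitor), class = "sampling_ranges")
}

#' Sample kinetic orders
#'
#' One uniform draw per flux (every reaction and sink in the GMA form has a
#' single substrate): substrate range for enzymatic reactions and monolignol
#' transports, efflux range for E1--E4.
#'
#' @param t a `lignin_topology`
#' @param ranges a `sampling_ranges`
#' @param seed optional integer seed
#' @return named numeric vector of kinetic orders
#' @export
sample_kinetic_orders <- function(t, ranges = sampling_ranges(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(t$reactions$id, t$sinks$id)
  efflux <- t$sinks$id[t$sinks$kind == "wall_phenolic"]
  g <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    rg <- if (id %in% efflux) ranges$efflux else ranges$substrate
    g[id] <- stats::runif(1, rg[1], rg[2])
  }
  g
}

# band rows for one scenario kind
.scenario_band_rows <- function(kind) {
  switch(kind,
    control = data.frame(
      type = "total",
      observable = c("H", "G", "S", "total", "S_over_G", "wall_pCA", "wall_FA"),
      wall = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
    phe_label = ,
    tyr_label = ,
    pca_dilution_phe = ,
    pca_dilution_tyr = data.frame(
      type = "incorporation",
      observable = c("H", "G", "S", "total", "wall_pCA", "wall_FA"),
      wall = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
    ca_dilution_phe = ,
    ca_dilution_tyr = data.frame(
      type = "incorporation",
      observable = c("H", "G", "S", "total"),
      wall = FALSE),
    data.frame(type = "incorporation",
               observable = c("H", "G", "S", "total"), wall = FALSE))
}

#' Build admissibility criteria from per-scenario observations
#'
#' A simulation matches an observable when it falls within the band
#' `mean * (1 -/+ tol)`: `lignin_tol` (default 25%) for lignin totals,
#' composition and monomer label incorporations, and the more relaxed
#' `wall_tol` (default 50%) for wall-bound phenolics. Incorporation bands
#' additionally get a small absolute floor (`inc_floor`) so that
#' near-zero fractions do not produce empty bands.
#'
#' @param observations named list of `observation_set` per scenario kind
#' @param feeds named list of `feed_spec` per scenario kind
#' @param lignin_tol,wall_tol fractional half-widths
#' @param inc_floor absolute half-width floor for incorporation fractions
#' @return object of class `admissibility_criteria`
#' @export
admissibility_criteria <- function(observations, feeds,
                                   lignin_tol = 0.25, wall_tol = 0.5,
                                   inc_floor = 0.02) {
  stopifnot(identical(sort(names(observations)), sort(names(feeds))))
  scenarios <- lapply(stats::setNames(names(observations), names(observations)),
                      function(kind) {
    obs <- observations[[kind]]
    rows <- .scenario_band_rows(kind)
    rows$mean <- NA_real_; rows$lo <- NA_real_; rows$hi <- NA_real_
    for (k in seq_len(nrow(rows))) {
      v <- if (rows$type[k] == "total") obs$totals[[rows$observable[k]]] else
        obs$incorporation[[rows$observable[k]]]
      tol <- if (rows$wall[k]) wall_tol else lignin_tol
      half <- abs(v) * tol
      if (rows$type[k] == "incorporation") half <- max(half, inc_floor)
      rows$mean[k] <- v
      rows$lo[k] <- v - half
      rows$hi[k] <- min(v + half, if (rows$type[k] == "incorporation") 1 else Inf)
      rows$lo[k] <- max(rows$lo[k], 0)
    }
    list(feed = feeds[[kind]], bands = rows)
  })
  structure(list(scenarios = scenarios,
                 lignin_tol = lignin_tol, wall_tol = wall_tol),
            class = "admissibility_criteria")
}

#' Evaluate admissibility of simulated observations
#'
#' @param observations named list of `observation_set`, one per scenario in
#'   the criteria (a missing scenario is an error, never a pass)
#' @param criteria an `admissibility_criteria`
#' @return list with `pass`, `margins` (data frame of signed fractional
#'   deviations and band violations) and `score` (sum of squared fractional
#'   band violations; 0 iff strictly admissible)
#' @export
evaluate_admissibility <- function(observations, criteria) {
  missing <- setdiff(names(criteria$scenarios), names(observations))
  if (length(missing))
    stop("missing scenario(s): ", paste(missing, collapse = ", "))
  margins <- list()
  for (sc in names(criteria$scenarios)) {
    bands <- criteria$scenarios[[sc]]$bands
    obs <- observations[[sc]]
    for (k in seq_len(nrow(bands))) {
      b <- bands[k, ]
      v <- if (b$type == "total") obs$totals[[b$observable]] else
        obs$incorporation[[b$observable]]
      denom <- max(abs(b$mean), 1e-6)
      margin <- if (is.na(v)) NA_real_ else (v - b$mean) / denom
      viol <- if (is.na(v)) 1 else if (v < b$lo) (b$lo - v) / denom else
        if (v > b$hi) (v - b$hi) / denom else 0
      margins[[length(margins) + 1L]] <- data.frame(
        scenario = sc, type = b$type, observable = b$observable,
        value = v, mean = b$mean, lo = b$lo, hi = b$hi,
        margin = margin, violation = viol)
    }
  }
  margins <- do.call(rbind, margins)
  list(pass = all(margins$violation == 0),
       margins = margins,
       score = sum(margins$violation^2))
}

# Evaluate one candidate (static member + kinetic orders + degenerate
# draws) against the criteria, scenario by scenario in the staged order,
# stopping at the first violated stage.
.evaluate_candidate <- function(t, f, g, deg_draws, criteria, r,
                                stage_order, d_max = 50) {
  p <- tryCatch(
    construct_parameter_set(t, f, g, r = r, deg_draws = deg_draws,
                            d_max = d_max),
    bl_error = function(e) NULL)
  if (is.null(p))
    return(list(params = NULL, stages_passed = -1L, score = Inf,
                observations = NULL))
  obs <- list()
  stages <- 0L
  total_score <- 0
  for (sc in stage_order) {
    scn <- criteria$scenarios[[sc]]
    sim <- tryCatch(
      simulate_scenario(t, p, make_scenario(sc, t, feed = scn$feed)),
      bl_error = function(e) NULL, error = function(e) NULL)
    if (is.null(sim)) { total_score <- Inf; break }
    obs[[sc]] <- sim$observations
    part <- evaluate_admissibility(obs[sc],
      structure(list(scenarios = criteria$scenarios[sc]),
                class = "admissibility_criteria"))
    total_score <- total_score + part$score
    if (part$score > 0) break
    stages <- stages + 1L
  }
  list(params = p, stages_passed = stages, score = total_score,
       observations = obs)
}

#' Explore-and-exploit parameter search
#'
#' Parameterizes the dynamic model against the admissibility criteria.
#' Exploration draws fresh Monte Carlo candidates (a static-ensemble
#' member, kinetic orders within the sampling ranges, degenerate-pool
#' steady states on the receiving side of their links); exploitation
#' perturbs the best-scoring candidate within a neighborhood that halves
#' after every improvement and resets after a stall. Scenarios are
#' evaluated one at a time in the staged order (control, then the two
#' labeling feeds, then the dilutions), with a candidate's score
#' accumulating until its first violated stage; admissible candidates
#' pass every scenario jointly.
#'
#' @param t a `lignin_topology`
#' @param static_ens a `flux_ensemble` from [sample_steady_state_fluxes()]
#' @param criteria an `admissibility_criteria`
#' @param budget number of candidate evaluations
#' @param seed integer seed
#' @param epsilon exploration probability during exploitation phases
#' @param stall evaluations without improvement before a restart
#' @param sigma0 initial relative neighborhood radius
#' @param ranges a `sampling_ranges`
#' @param r cytosolic volume fraction
#' @param d_max diffusion-constant cap passed to the constructor
#' @return object of class `admissible_ensemble`: list of records
#'   (`params`, `margins`, `provenance`), with attributes `diagnostics`
#'   (best margins seen) and `n_evaluated`
#' @export
explore_exploit_search <- function(t, static_ens, criteria, budget = 500,
                                   seed = 1, epsilon = 0.2, stall = 500,
                                   sigma0 = 0.3, ranges = sampling_ranges(),
                                   r = 0.9, d_max = 50) {
  stopifnot(budget >= 0, length(static_ens) >= 1)
  set.seed(seed)
  stage_order <- intersect(
    c("control", "phe_label", "tyr_label",
      "ca_dilution_phe", "ca_dilution_tyr",
      "pca_dilution_phe", "pca_dilution_tyr", "knockdown"),
    names(criteria$scenarios))
  efflux <- t$sinks$id[t$sinks$kind == "wall_phenolic"]
  gwidth <- stats::setNames(
    ifelse(c(t$reactions$id, t$sinks$id) %in% efflux,
           diff(ranges$efflux), diff(ranges$substrate)),
    c(t$reactions$id, t$sinks$id))
  glo <- stats::setNames(
    ifelse(names(gwidth) %in% efflux, ranges$efflux[1], ranges$substrate[1]),
    names(gwidth))
  ghi <- glo + gwidth

  fresh <- function() {
    midx <- sample.int(length(static_ens), 1)
    f <- static_ens[[midx]]
    g <- sample_kinetic_orders(t, ranges)
    lf <- f$label_fields$phe_label
    deg <- detect_degenerate_pools(t, lf)
    dd <- sample_degenerate_steady_states(t, f, deg, r = r)
    list(member = midx, f = f, g = g, deg = dd)
  }
  perturb <- function(cand, sigma) {
    g <- cand$g + stats::rnorm(length(cand$g), 0, sigma) * gwidth
    g <- pmin(pmax(g, glo), ghi)
    names(g) <- names(cand$g)
    dd <- cand$deg
    if (!is.null(dd) && nrow(dd)) {
      for (k in seq_len(nrow(dd))) {
        if (!dd$identifiable[k]) next
        recv <- if (identical(dd$receiver[k], "er")) dd$Y_ss[k] else dd$X_ss[k]
        recv <- min(max(recv * exp(stats::rnorm(1, 0, sigma)), 1e-3), 99.99)
        D <- cand$f$values[[paste0("D", dd$metabolite[k])]]
        if (D > 0) {
          dd$Y_ss[k] <- recv; dd$X_ss[k] <- (100 - (1 - r) * recv) / r
        } else {
          dd$X_ss[k] <- recv; dd$Y_ss[k] <- (100 - r * recv) / (1 - r)
        }
        dd$d[k] <- D / (dd$X_ss[k] - dd$Y_ss[k])
      }
    }
    list(member = cand$member, f = cand$f, g = g, deg = dd)
  }

  records <- list()
  best <- NULL; best_key <- c(-Inf, Inf)  # (stages passed, -score)
  best_margins <- NULL
  sigma <- sigma0
  since_improvement <- 0L
  for (it in seq_len(budget)) {
    exploit <- !is.null(best) && stats::runif(1) > epsilon
    cand <- if (exploit) perturb(best$cand, sigma) else fresh()
    ev <- .evaluate_candidate(t, cand$f, cand$g, cand$deg, criteria, r,
                              stage_order, d_max = d_max)
    key <- c(ev$stages_passed, -ev$score)
    improved <- key[1] > best_key[1] ||
      (key[1] == best_key[1] && key[2] > best_key[2])
    if (improved) {
      best <- list(cand = cand, ev = ev)
      best_key <- key
      sigma <- max(sigma / 2, 0.02)
      since_improvement <- 0L
      if (!is.null(ev$observations) && length(ev$observations))
        best_margins <- tryCatch(
          evaluate_admissibility(ev$observations,
            structure(list(scenarios =
              criteria$scenarios[names(ev$observations)]),
              class = "admissibility_criteria"))$margins,
          error = function(e) NULL)
    } else {
      since_improvement <- since_improvement + 1L
      if (since_improvement >= stall) {
        sigma <- sigma0
        best <- NULL; best_key <- c(-Inf, Inf)
        since_improvement <- 0L
      }
    }
    if (ev$stages_passed == length(stage_order)) {
      verdict <- evaluate_admissibility(ev$observations, criteria)
      records[[length(records) + 1L]] <- list(
        params = ev$params,
        margins = verdict$margins,
        observations = ev$observations,
        provenance = list(seed = seed, iteration = it,
                          mode = if (exploit) "exploit" else "explore",
                          static_member = cand$member))
    }
  }
  structure(records, class = "admissible_ensemble",
            diagnostics = list(best_margins = best_margins,
                               best_stages = best_key[1]),
            n_evaluated = budget)
}
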