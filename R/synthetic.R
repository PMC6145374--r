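# --- Synthetic ground truth and pseudo-observations ----------------------
#
# Stands in for the study's raw measurements: a self-consistent kinetic
# model with the qualitative channeling signature (labeled Phe incorporates
# preferentially into G-lignin, labeled Tyr into S-lignin), plus noisy
# replicate observations in exactly the format the fitting pipeline reads.

#' Noise model for pseudo-observations
#'
#' Multiplicative lognormal noise on totals and additive truncated-Gaussian
#' noise on incorporation fractions, averaged over replicates. Defaults are
#' plausible assay-level noise; they are a harness choice, not a measured
#' property.
#'
#' @param total_sd lognormal sigma on totals
#' @param fraction_sd Gaussian sd on fractions
#' @param replicates replicate count
#' @return object of class `noise_model`
#' @export
noise_model <- function(total_sd = 0.1, fraction_sd = 0.03, replicates = 3) {
  stopifnot(total_sd >= 0, fraction_sd >= 0, replicates >= 1)
  structure(list(total_sd = total_sd, fraction_sd = fraction_sd,
                 replicates = replicates), class = "noise_model")
}

.gt_scenario_kinds <- c("control", "phe_label", "tyr_label",
                        "ca_dilution_phe", "ca_dilution_tyr",
                        "pca_dilution_phe", "pca_dilution_tyr")

#' Generate a synthetic ground-truth model
#'
#' Draws a mass-balanced steady-state flux distribution from the route
#' sampler (whose baseline is biased so that the ER coniferaldehyde channel
#' funnels Phe-derived carbon toward G and the ferulate crossing funnels
#' Tyr-derived carbon toward S), verifies the channeling signature on the
#' static label fields, samples kinetic orders from the study's ranges,
#' back-calculates rate constants, and checks local stability of the
#' resulting steady state (eigenvalues of the numerical Jacobian). Unstable
#' or infeasible draws are rejected and redrawn.
#'
#' @param t a `lignin_topology`
#' @param seed integer seed
#' @param r cytosolic volume fraction
#' @param max_tries rejection budget
#' @param ca_influx,pca_influx medium influx magnitudes used by the
#'   dilution scenarios of the truth
#' @return object of class `ground_truth`: topology, flux distribution,
#'   `parameter_set`, feeds and exact noise-free observations per scenario
#' @export
generate_ground_truth <- function(t, seed = 1, r = 0.9, max_tries = 25,
                                  ca_influx = 22, pca_influx = 22) {
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    f <- sample_steady_state_fluxes(t, targets = NULL, n = 1,
                                    seed = sample.int(2^30, 1), r = r)[[1]]
    # channeling signature on the quasi-steady incorporation fields
    obs_phe <- readouts_from_fluxes(t, f$values, f$label_fields$phe_label, r)
    obs_tyr <- readouts_from_fluxes(t, f$values, f$label_fields$tyr_label, r)
    if (!(obs_phe$incorporation[["G"]] > obs_phe$incorporation[["S"]] &&
          obs_tyr$incorporation[["S"]] > obs_tyr$incorporation[["G"]])) next
    g <- sample_kinetic_orders(t)
    p <- tryCatch(construct_parameter_set(t, f, g, r = r),
                  bl_error = function(e) NULL)
    if (is.null(p)) next
    # local stability of the pooled steady state
    fr <- pooled_rhs(t, p)
    n <- length(p$conc)
    J <- matrix(0, n, n)
    f0 <- fr(p$conc)
    h <- pmax(1e-6 * p$conc, 1e-8)
    for (j in seq_len(n)) {
      x <- p$conc; x[j] <- x[j] + h[j]
      J[, j] <- (fr(x) - f0) / h[j]
    }
    ev <- eigen(J, only.values = TRUE)$values
    if (max(Re(ev)) > 1e-8) next

    feeds <- list(
      control = feed_spec(),
      phe_label = feed_spec(phe_label = 1),
      tyr_label = feed_spec(tyr_label = 1),
      ca_dilution_phe = feed_spec(phe_label = 1, ca_influx = ca_influx),
      ca_dilution_tyr = feed_spec(tyr_label = 1, ca_influx = ca_influx),
      pca_dilution_phe = feed_spec(phe_label = 1, pca_influx = pca_influx),
      pca_dilution_tyr = feed_spec(tyr_label = 1, pca_influx = pca_influx))
    observations <- tryCatch(
      lapply(stats::setNames(names(feeds), names(feeds)), function(kind) {
        sc <- make_scenario(kind, t, feed = feeds[[kind]])
        simulate_scenario(t, p, sc)$observations
      }),
      bl_error = function(e) NULL)
    if (is.null(observations)) next  # dilution steady state unusable
    return(structure(list(topology = t, flux = f, params = p, g = g,
                          feeds = feeds, observations = observations,
                          seed = seed, tries = i),
                     class = "ground_truth"))
  }
  bl_stop("bl_generation_failure",
          sprintf("no stable channeling ground truth found in %d tries", max_tries))
}

#' Generate noisy pseudo-observations and admissibility bands
#'
#' Applies the noise model to the truth's exact observations (lognormal on
#' totals, truncated Gaussian on fractions, replicate means) and wraps the
#' noisy means in the band machinery of the fitting pipeline (25% lignin
#' bands, relaxed wall-phenolic bands).
#'
#' @param gt a `ground_truth`
#' @param nm a `noise_model`
#' @param seed integer seed
#' @param lignin_tol,wall_tol band half-widths passed to
#'   [admissibility_criteria()]
#' @return list with `observations` (noisy means per scenario) and
#'   `criteria` (an `admissibility_criteria`)
#' @export
generate_observations <- function(gt, nm = noise_model(), seed = 1,
                                  lignin_tol = 0.25, wall_tol = 0.5) {
  set.seed(seed)
  noisy <- lapply(gt$observations, function(obs) {
    tot <- obs$totals; inc <- obs$incorporation
    tot_mean <- tot * 0; inc_mean <- inc * 0
    for (rep in seq_len(nm$replicates)) {
      tr <- tot * exp(stats::rnorm(length(tot), 0, nm$total_sd))
      ir <- pmin(pmax(inc + stats::rnorm(length(inc), 0, nm$fraction_sd), 0), 1)
      tot_mean <- tot_mean + tr / nm$replicates
      inc_mean <- inc_mean + ir / nm$replicates
    }
    tot_mean[["S_over_G"]] <- tot_mean[["S"]] / tot_mean[["G"]]
    tot_mean[["total"]] <- sum(tot_mean[c("H", "G", "S")])
    observation_set(tot_mean, inc_mean)
  })
  list(observations = noisy,
       criteria = admissibility_criteria(noisy, gt$feeds,
                                         lignin_tol = lignin_tol,
                                         wall_tol = wall_tol))
}

#' End-to-end parameter-recovery experiment
#'
#' Truth, pseudo-observations, static ensemble, explore-and-exploit search;
#' reports whether the truth is admissible against its own targets, the
#' size of the recovered ensemble, and the spread of key predictions.
#'
#' @param seed integer seed
#' @param budget dynamic-search candidate budget
#' @param n_static static ensemble size
#' @param nm noise model (use `noise_model(0, 0, 1)` for the noise-free
#'   harness)
#' @param t topology (default built-in)
#' @return list of class `recovery_report`
#' @export
recovery_experiment <- function(seed = 1, budget = 300, n_static = 8,
                                nm = noise_model(0, 0, 1),
                                t = build_brachypodium_topology()) {
  gt <- generate_ground_truth(t, seed = seed)
  obs <- generate_observations(gt, nm, seed = seed + 1)
  criteria <- obs$criteria

  # sanity floor: the generating parameter set must be admissible
  truth_obs <- lapply(stats::setNames(names(gt$feeds), names(gt$feeds)),
                      function(kind)
    simulate_scenario(t, gt$params,
                      make_scenario(kind, t, feed = gt$feeds[[kind]]))$observations)
  truth_verdict <- evaluate_admissibility(truth_obs, criteria)

  static_ens <- sample_steady_state_fluxes(t, targets = criteria,
                                           n = n_static, seed = seed + 2)
  ens <- explore_exploit_search(t, static_ens, criteria, budget = budget,
                                seed = seed + 3)
  sg <- if (length(ens))
    stats::median(vapply(ens, function(rec)
      rec$observations$control$totals[["S_over_G"]], 0)) else NA_real_
  truth_sg <- gt$observations$control$totals[["S_over_G"]]
  structure(list(
    seed = seed,
    truth_admissible = truth_verdict$pass,
    truth_score = truth_verdict$score,
    static_acceptance = attr(static_ens, "acceptance_rate"),
    n_admissible = length(ens),
    median_S_over_G = sg,
    truth_S_over_G = truth_sg,
    sg_within_band = !is.na(sg) &&
      abs(sg - truth_sg) <= 0.25 * truth_sg,
    ensemble = ens,
    ground_truth = gt,
    criteria = criteria
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report (seed", x$seed, ")\n")
  cat(sprintf("  truth admissible against own targets: %s (score %.3g)\n",
              x$truth_admissible, x$truth_score))
  cat(sprintf("  static acceptance rate: %.3f\n", x$static_acceptance))
  cat(sprintf("  admissible parameter sets found: %d\n", x$n_admissible))
  cat(sprintf("  S/G: truth %.3f, ensemble median %.3f (within 25%%: %s)\n",
              x$truth_S_over_G, x$median_S_over_G, x$sg_within_band))
  invisible(x)
}
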