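# --- Scenario construction and readout computation ------------------------

.scenario_kinds <- c("control", "phe_label", "tyr_label",
                     "ca_dilution_phe", "ca_dilution_tyr",
                     "pca_dilution_phe", "pca_dilution_tyr", "knockdown")

#' Construct an experimental scenario
#'
#' Bundles a feeding condition, an enzyme activity profile and a horizon.
#' Labeling scenarios set the named source's label fraction to 1 and all
#' others to 0; dilution scenarios additionally add the unlabeled medium
#' influx of cinnamic or *p*-coumaric acid (magnitude estimated by the
#' static model, passed via `ca_influx`/`pca_influx`).
#'
#' @param kind one of control, phe_label, tyr_label, ca_dilution_phe,
#'   ca_dilution_tyr, pca_dilution_phe, pca_dilution_tyr, knockdown
#' @param t a `lignin_topology` (for the default activity profile)
#' @param feed optional `feed_spec` overriding the kind's default
#' @param activity optional enzyme activity profile (knockdown scenarios)
#' @param ca_influx,pca_influx unlabeled medium influx rates for the
#'   dilution kinds
#' @param horizon integration horizon for trajectory-based readouts
#' @return object of class `lignin_scenario`
#' @export
make_scenario <- function(kind, t, feed = NULL, activity = NULL,
                          ca_influx = 22, pca_influx = 22, horizon = 400) {
  if (!kind %in% .scenario_kinds)
    stop("unknown scenario kind: ", kind)
  if (is.null(feed)) {
    feed <- switch(kind,
      control = feed_spec(),
      phe_label = feed_spec(phe_label = 1),
      tyr_label = feed_spec(tyr_label = 1),
      ca_dilution_phe = feed_spec(phe_label = 1, ca_influx = ca_influx),
      ca_dilution_tyr = feed_spec(tyr_label = 1, ca_influx = ca_influx),
      pca_dilution_phe = feed_spec(phe_label = 1, pca_influx = pca_influx),
      pca_dilution_tyr = feed_spec(tyr_label = 1, pca_influx = pca_influx),
      knockdown = feed_spec(tyr_label = 1))
  }
  if (is.null(activity)) activity <- enzyme_profile(t)
  structure(list(kind = kind, feed = feed, activity = activity,
                 horizon = horizon),
            class = "lignin_scenario")
}

# TRUE when the scenario leaves the wild-type pooled steady state intact
# (pure labeling switch): enzymes at wild type, no medium influx, source
# levels at wild type.
.is_wildtype_conditions <- function(scenario) {
  all(scenario$activity == 1) &&
    scenario$feed$ca_influx == 0 && scenario$feed$pca_influx == 0 &&
    scenario$feed$phe_scale == 1 && scenario$feed$tyr_scale == 1
}

#' Simulate a scenario to its quasi-steady readouts
#'
#' Computes the pooled steady state under the scenario's feed and activity
#' profile (the wild-type state when nothing but the labeling changed,
#' otherwise by damped Newton with integration fallback from the wild-type
#' state), then solves the exact stationary label field and derives the
#' observation set. This is the quasi-steady endpoint of the labeling
#' experiment: sink incorporation fractions converge to these values.
#'
#' @param t a `lignin_topology`
#' @param p a `parameter_set`
#' @param scenario a `lignin_scenario`
#' @param conc_cap reject steady states whose largest pool exceeds this
#'   (numerically unusable parameter sets; see the methods vignette)
#' @return list with `observations` (an `observation_set`), `conc`,
#'   `fluxes`, `label_field`, `residual`
#' @export
simulate_scenario <- function(t, p, scenario, conc_cap = 1e6) {
  e <- scenario$activity
  feed <- scenario$feed
  if (.is_wildtype_conditions(scenario)) {
    conc <- p$conc
    residual <- max(abs(pooled_rhs(t, p, e, feed)(conc)))
  } else {
    fr <- pooled_rhs(t, p, e, feed)
    sol <- NULL
    seqc <- sequential_steady_state(t, p, e, feed)
    if (!is.null(seqc)) {
      # the sequential solve is exact on the feedforward network: a
      # non-finite or out-of-range result means the steady state is
      # numerically unusable, so fail fast instead of relaxing for long
      if (!all(is.finite(seqc)) || max(seqc) > conc_cap)
        bl_stop("bl_integration_failure",
                sprintf("steady state out of numerical range for scenario %s (max pool %.3g)",
                        scenario$kind, suppressWarnings(max(seqc))))
      res <- max(abs(fr(seqc)))
      if (res < 1e-6) sol <- list(x = seqc, residual = res, converged = TRUE)
    }
    if (is.null(sol)) {
      guess <- if (!is.null(seqc) && all(is.finite(seqc))) seqc else p$conc
      sol <- newton_steady_state(fr, guess, tol = 1e-9, positive = TRUE)
      if (!sol$converged) {
        rhs2 <- function(time, y) fr(y)
        traj <- tryCatch(
          integrate_gma(rhs2, sol$x, t_end = scenario$horizon,
                        rtol = 1e-6, atol = 1e-8, quiescent_tol = 1e-8,
                        max_steps = 20000L),
          error = function(e) NULL)
        if (!is.null(traj)) {
          sol2 <- newton_steady_state(fr, traj$final, tol = 1e-9,
                                      positive = TRUE)
          if (sol2$residual < sol$residual) sol <- sol2
        }
      }
    }
    conc <- stats::setNames(sol$x, t$pools$pool)
    residual <- sol$residual
    if (residual > 1e-4)
      bl_stop("bl_integration_failure",
              sprintf("no steady state found for scenario %s (residual %.3g)",
                      scenario$kind, residual))
    if (max(conc) > conc_cap)
      bl_stop("bl_integration_failure",
              sprintf("steady state out of numerical range for scenario %s (max pool %.3g)",
                      scenario$kind, max(conc)))
  }
  values <- flux_values_at(t, p, conc, e, feed)
  f2 <- flux_distribution(values, r = p$r)
  lf <- steady_state_label_field(t, f2, conc, p$d, feed)
  obs <- readouts_from_fluxes(t, values, lf, p$r)
  list(observations = obs, conc = conc, fluxes = values,
       label_field = lf, residual = residual)
}

#' Compute readouts from an integrated trajectory
#'
#' Monomer totals are labeled + unlabeled sink accumulation over the
#' trajectory window; incorporation fractions are labeled / total per sink;
#' total-lignin incorporation is mass-weighted over H, G and S. Empty sinks
#' yield `NA` fractions and are listed in the `flagged` attribute.
#'
#' @param traj a `gma_trajectory` from [integrate_gma()]
#' @param t a `lignin_topology`
#' @return an `observation_set` with attribute `flagged`
#' @export
compute_readouts <- function(traj, t) {
  np <- nrow(t$pools)
  final <- traj$final
  sl <- stats::setNames(final[2 * np + 1:5], sink_names())
  su <- stats::setNames(final[2 * np + 5 + 1:5], sink_names())
  tot <- sl + su
  frac <- ifelse(tot > 0, sl / tot, NA_real_)
  H <- tot[["H"]]; G <- tot[["G"]]; S <- tot[["S"]]
  lig <- H + G + S
  itot <- if (lig > 0)
    (H * frac[["H"]] + G * frac[["G"]] + S * frac[["S"]]) / lig else NA_real_
  obs <- observation_set(
    totals = c(H = H, G = G, S = S, total = lig,
               S_over_G = if (G > 0) S / G else NA_real_,
               wall_pCA = tot[["wall_pCA"]], wall_FA = tot[["wall_FA"]]),
    incorporation = c(H = frac[["H"]], G = frac[["G"]], S = frac[["S"]],
                      total = itot, wall_pCA = frac[["wall_pCA"]],
                      wall_FA = frac[["wall_FA"]]))
  attr(obs, "flagged") <- sink_names()[tot <= 0]
  obs
}

#' Simulate an enzyme knockdown to its new steady state
#'
#' Scales enzyme activities by the given profile, relaxes the pooled system
#' to its new steady state (long-horizon integration from the wild-type
#' state with Newton polishing, to land on the stable branch), and reports
#' the readouts plus lignin composition relative to wild type for each
#' feeding condition.
#'
#' @param t a `lignin_topology`
#' @param p a `parameter_set`
#' @param e enzyme activity profile (multipliers relative to wild type)
#' @param feeds named list of `feed_spec`
#' @return named list per feed with `observations`, `relative_totals`
#'   (knockdown / wild type), `conc`
#' @export
simulate_knockdown <- function(t, p, e, feeds) {
  wt <- lapply(feeds, function(fd) {
    sc <- make_scenario("knockdown", t, feed = fd, activity = enzyme_profile(t))
    simulate_scenario(t, p, sc)
  })
  lapply(stats::setNames(names(feeds), names(feeds)), function(nm) {
    sc <- make_scenario("knockdown", t, feed = feeds[[nm]], activity = e)
    sim <- simulate_scenario(t, p, sc)
    wt_tot <- wt[[nm]]$observations$totals
    rel <- sim$observations$totals / wt_tot
    list(observations = sim$observations, relative_totals = rel,
         conc = sim$conc)
  })
}

#' Transcript bounds for knockdown validation
#'
#' Enzyme activity intervals bounded between the wild type (1) and the
#' measured transcript fold change of the knockdown line.
#'
#' @param t a `lignin_topology`
#' @param ... named transcript fold changes relative to wild type,
#'   e.g. `PTAL = 0.1`
#' @return data frame with enzyme, lower, upper
#' @export
transcript_bounds <- function(t, ...) {
  tr <- stats::setNames(rep(1, length(t$enzymes)), t$enzymes)
  dots <- list(...)
  bad <- setdiff(names(dots), t$enzymes)
  if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
  tr[names(dots)] <- as.numeric(dots)
  data.frame(enzyme = t$enzymes,
             lower = pmin(tr, 1), upper = pmax(tr, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcript-bounded knockdown validation
#'
#' Randomly generates `n` altered enzyme activity profiles, each bounded
#' elementwise between the wild type and the transcript level of the
#' knockdown line, together with a carbon-influx scaling factor
#' (log-uniform on `influx_range`, applied to both amino-acid supplies).
#' Every profile is simulated with the dynamic model for every feed in the
#' target bands; profiles whose readouts fall within all bands are
#' retained. Reports per-enzyme retained ranges and the retained
#' influx-change distribution.
#'
#' @param t a `lignin_topology`
#' @param ens an admissible ensemble (list of records with `$params`), or a
#'   single `parameter_set`
#' @param tb transcript bounds from [transcript_bounds()]
#' @param targets an `admissibility_criteria` whose scenarios describe the
#'   knockdown observations (feeds + bands)
#' @param n number of profiles (the study default is 20000)
#' @param seed integer seed
#' @param influx_range range of the carbon-influx scaling factor
#' @return list with `retained` (data frame of profiles), `n_retained`,
#'   `enzyme_summary`, `influx_summary`, and `nearest_miss` diagnostics
#'   when nothing is retained
#' @export
bdptal_validation <- function(t, ens, tb, targets, n = 20000, seed = 1,
                              influx_range = c(0.5, 1)) {
  if (inherits(ens, "parameter_set")) ens <- list(list(params = ens))
  if (length(ens) == 0) stop("empty ensemble")
  set.seed(seed)
  rows <- list()
  best_score <- Inf; best_row <- NULL
  scn <- names(targets$scenarios)
  for (i in seq_len(n)) {
    u <- stats::runif(nrow(tb), tb$lower, tb$upper)
    names(u) <- tb$enzyme
    s <- exp(stats::runif(1, log(influx_range[1]), log(influx_range[2])))
    p <- ens[[(i - 1L) %% length(ens) + 1L]]$params
    e <- enzyme_profile(t)
    e[names(u)] <- u
    obs <- list()
    feasible <- TRUE
    for (sc in scn) {
      fd <- targets$scenarios[[sc]]$feed
      fd$phe_scale <- fd$phe_scale * s
      fd$tyr_scale <- fd$tyr_scale * s
      sim <- tryCatch(
        simulate_scenario(t, p, make_scenario("knockdown", t, feed = fd,
                                              activity = e)),
        error = function(err) NULL)
      if (is.null(sim)) { feasible <- FALSE; break }
      obs[[sc]] <- sim$observations
    }
    if (!feasible) next
    verdict <- evaluate_admissibility(obs, targets)
    row <- data.frame(profile = i, t(u), influx_scale = s,
                      score = verdict$score, check.names = FALSE)
    if (verdict$pass) {
      rows[[length(rows) + 1L]] <- row
    } else if (verdict$score < best_score) {
      best_score <- verdict$score
      best_row <- list(row = row, margins = verdict$margins)
    }
  }
  retained <- if (length(rows)) do.call(rbind, rows) else NULL
  enzyme_summary <- NULL; influx_summary <- NULL
  if (!is.null(retained)) {
    qs <- function(x) stats::quantile(x, c(0, .25, .5, .75, 1))
    enzyme_summary <- do.call(rbind, lapply(tb$enzyme, function(en)
      data.frame(enzyme = en, t(qs(retained[[en]])), check.names = FALSE)))
    influx_summary <- qs(retained$influx_scale)
  }
  list(retained = retained, n_retained = length(rows),
       enzyme_summary = enzyme_summary, influx_summary = influx_summary,
       nearest_miss = if (length(rows) == 0) best_row else NULL)
}
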