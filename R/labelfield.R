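#' Construct a steady-state flux distribution
#'
#' Fluxes are stored in compartment-local normalized units (the units of the
#' GMA rate laws and of the diffusion law `D_j = d_j (X_i - Y_i)`, positive =
#' net cytosol-to-ER transfer). Mass balance therefore holds with respect to
#' the volume-weighted balance matrix, in which diffusion enters ER rows with
#' the volume-ratio multiplier R = r/(1-r).
#'
#' @param values named numeric vector over all flux ids of the topology
#'   (reactions `V*`, sinks `E*`/`T*`, diffusion `D*`)
#' @param r cytosolic volume fraction
#' @param labeled_fraction optional named list (per feeding condition) of
#'   per-flux labeled fractions
#' @return object of class `flux_distribution`
#' @export
flux_distribution <- function(values, r = 0.9, labeled_fraction = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)), r > 0, r < 1)
  structure(list(values = values, r = r, labeled_fraction = labeled_fraction),
            class = "flux_distribution")
}

#' Mass-balance residual of a flux distribution
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution`
#' @return numeric vector of net absolute-mass production per pool
#' @export
mass_balance_residual <- function(t, f) {
  Sb <- balance_matrix(t, f$r)
  v <- f$values[colnames(Sb)]
  drop(Sb %*% v)
}

# Inflow bookkeeping shared by both label-balance conventions.
# Returns, for every pool, lists of (weight, source) pairs where source is a
# pool index, or a negative metabolite id for boundary sources, or 0 for an
# unlabeled medium influx. Weights are absolute (volume-weighted) flux
# magnitudes so cytosol and ER contributions are commensurable.
.inflow_terms <- function(t, f, feed, gross = FALSE, conc = NULL, d = NULL,
                          gross_flows = NULL) {
  np <- nrow(t$pools)
  r <- f$r
  w <- list(i = integer(0), src = integer(0), wt = numeric(0))
  add <- function(pool, src, wt) {
    w$i <<- c(w$i, pool); w$src <<- c(w$src, src); w$wt <<- c(w$wt, wt)
  }
  volfrac <- c(cytosol = r, er = 1 - r)
  srcids <- t$metabolites$id[t$metabolites$is_source]
  for (k in seq_len(nrow(t$reactions))) {
    rx <- t$reactions[k, ]
    v <- f$values[[rx$id]]
    if (v == 0) next
    pprod <- pool_index(t, rx$product, rx$compartment)
    if (rx$substrate %in% srcids) {
      add(pprod, -rx$substrate, v * volfrac[[rx$compartment]])
    } else {
      psub <- pool_index(t, rx$substrate, rx$compartment)
      add(pprod, psub, v * volfrac[[rx$compartment]])
    }
  }
  inx <- medium_influxes(feed)
  for (m in names(inx)) {
    if (inx[[m]] > 0) add(pool_index(t, as.integer(m), "cytosol"), 0L, r * inx[[m]])
  }
  for (k in seq_len(nrow(t$diffusion))) {
    m <- t$diffusion$metabolite[k]
    px <- pool_index(t, m, "cytosol"); py <- pool_index(t, m, "er")
    if (!is.null(gross_flows)) {
      id <- t$diffusion$id[k]
      D <- f$values[[id]]
      fwd <- gross_flows$fwd[[id]]; back <- gross_flows$back[[id]]
      if (D >= 0) {  # donor = cytosol
        if (fwd > 0) add(py, px, fwd)
        if (back > 0) add(px, py, back)
      } else {       # donor = ER
        if (fwd > 0) add(px, py, fwd)
        if (back > 0) add(py, px, back)
      }
    } else if (gross) {
      dk <- d[[t$diffusion$id[k]]]
      if (dk > 0) {
        add(py, px, r * dk * conc[px])  # gross cytosol -> ER carries L_X
        add(px, py, r * dk * conc[py])
      }
    } else {
      D <- f$values[[t$diffusion$id[k]]]
      if (D > 0) add(py, px, r * D) else if (D < 0) add(px, py, r * (-D))
    }
  }
  w
}

# Solve the linear label balance given inflow terms; pools with zero total
# inflow get NA ("zero throughput": label undefined there).
.solve_label_balance <- function(t, terms, feed) {
  np <- nrow(t$pools)
  A <- matrix(0, np, np)
  b <- numeric(np)
  tot <- numeric(np)
  for (k in seq_along(terms$i)) {
    p <- terms$i[k]; s <- terms$src[k]; wt <- terms$wt[k]
    tot[p] <- tot[p] + wt
    if (s > 0) {
      A[p, s] <- A[p, s] - wt
    } else if (s < 0) {
      b[p] <- b[p] + wt * source_label(feed, -s)
    } # s == 0: unlabeled influx, contributes weight only
  }
  diag(A) <- diag(A) + tot
  live <- tot > 1e-12
  L <- rep(NA_real_, np)
  if (any(live)) {
    L[live] <- solve(A[live, live, drop = FALSE], b[live])
    # clip solver noise
    L[live] <- pmin(pmax(L[live], 0), 1)
  }
  names(L) <- t$pools$pool
  structure(L, class = "label_field", feed = feed,
            flagged = t$pools$pool[!live])
}

#' Propagate steady-state label fractions through a flux distribution
#'
#' Solves the linear label-balance system of the static model: for every
#' pool, the flux-weighted average of the labels of its inflows equals its
#' own label. Net diffusion fluxes are treated as directed flows carrying the
#' donor pool's label, so no compartmental concentrations are needed. Pools
#' with zero throughput are flagged and get `NA`.
#'
#' @param t a `lignin_topology`
#' @param f a mass-balanced `flux_distribution`
#' @param feed a `feed_spec` giving the source label fractions
#' @return a `label_field`: named vector of label levels in [0,1] per pool,
#'   with attribute `flagged` listing zero-throughput pools
#' @export
propagate_label_fractions <- function(t, f, feed) {
  terms <- .inflow_terms(t, f, feed, gross = FALSE)
  .solve_label_balance(t, terms, feed)
}

#' Exact stationary label field of the dynamic model
#'
#' Unlike [propagate_label_fractions()], which uses the net-donor convention
#' of the static model, this solves the gross-exchange balance in which a
#' diffusion link transports `d X_i` cytosol-to-ER and `d Y_i` back, each
#' carrying its donor's label. Given the compartmental steady-state
#' concentrations and diffusion constants this is the label distribution the
#' 68-equation ODE system relaxes to under the feed.
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution`
#' @param conc named numeric vector of steady-state pool concentrations
#' @param d named numeric vector of diffusion rate constants (by link id)
#' @param feed a `feed_spec`
#' @return a `label_field`
#' @export
steady_state_label_field <- function(t, f, conc, d, feed) {
  terms <- .inflow_terms(t, f, feed, gross = TRUE, conc = conc, d = d)
  .solve_label_balance(t, terms, feed)
}

#' Labeled fraction of every flux under a label field
#'
#' Reaction and sink fluxes carry the label of their substrate pool (or of
#' the source under the feed); net diffusion fluxes carry the donor pool's
#' label.
#'
#' @inheritParams propagate_label_fractions
#' @param lf a `label_field`
#' @return named numeric vector of labeled fractions per flux id
#' @export
flux_label_fractions <- function(t, f, lf, feed) {
  out <- stats::setNames(rep(NA_real_, length(flux_ids(t))), flux_ids(t))
  srcids <- t$metabolites$id[t$metabolites$is_source]
  for (k in seq_len(nrow(t$reactions))) {
    rx <- t$reactions[k, ]
    out[rx$id] <- if (rx$substrate %in% srcids) source_label(feed, rx$substrate)
      else lf[[pool_index(t, rx$substrate, rx$compartment)]]
  }
  for (k in seq_len(nrow(t$sinks))) {
    s <- t$sinks[k, ]
    out[s$id] <- lf[[pool_index(t, s$source, s$compartment)]]
  }
  for (k in seq_len(nrow(t$diffusion))) {
    m <- t$diffusion$metabolite[k]
    D <- f$values[[t$diffusion$id[k]]]
    donor <- if (D >= 0) pool_index(t, m, "cytosol") else pool_index(t, m, "er")
    out[t$diffusion$id[k]] <- lf[[donor]]
  }
  out
}

#' Solve one diffusion link for (d, X, Y) from label data
#'
#' Given the net diffusion flux `D`, its labeled portion `D_L`, and the label
#' incorporation levels of the two pools, solves the algebraic system
#' \deqn{d (X - Y) = D, \quad d (L_X X - L_Y Y) = D_L, \quad
#'       r X + (1 - r) Y = 100}
#' for the diffusion rate constant and the compartmental steady-state
#' concentrations. When `L_X = L_Y` the first two equations are linearly
#' dependent (the degenerate case) and a classed condition
#' `bl_degenerate_pool` is raised; the caller must sample the pools instead.
#' A solution with a nonpositive pool raises `bl_infeasible_labeling`.
#'
#' @param D net diffusion flux (nonzero; cytosol-local units)
#' @param D_L labeled portion of the net diffusion flux
#' @param L_X,L_Y label incorporation levels of the cytosolic and ER pool
#' @param r cytosolic volume fraction
#' @param tol relative tolerance for degeneracy detection
#' @return list with elements `d`, `X_ss`, `Y_ss`
#' @export
solve_diffusion_link <- function(D, D_L, L_X, L_Y, r = 0.9, tol = 1e-9) {
  stopifnot(is.finite(D), is.finite(D_L))
  if (D == 0) bl_stop("bl_degenerate_pool", "zero net diffusion flux: d unidentifiable")
  if (abs(L_X - L_Y) <= tol * max(1, abs(L_X), abs(L_Y))) {
    bl_stop("bl_degenerate_pool",
            sprintf("label levels coincide (L_X = %.6g, L_Y = %.6g): degenerate pool",
                    L_X, L_Y))
  }
  # Eliminate d: D_L * (X - Y) = D * (L_X X - L_Y Y), plus the normalization.
  A <- rbind(c(D_L - D * L_X, -D_L + D * L_Y),
             c(r, 1 - r))
  rhs <- c(0, 100)
  if (abs(det(A)) < 1e-12 * max(1, abs(D), abs(D_L))) {
    bl_stop("bl_degenerate_pool", "linearly dependent label equations")
  }
  sol <- solve(A, rhs)
  X <- sol[1]; Y <- sol[2]
  if (!is.finite(X) || !is.finite(Y) || X <= 0 || Y <= 0) {
    bl_stop("bl_infeasible_labeling",
            sprintf("nonpositive compartmental concentration (X = %.4g, Y = %.4g)", X, Y),
            list(X_ss = X, Y_ss = Y))
  }
  if (abs(X - Y) < 1e-12) {
    bl_stop("bl_degenerate_pool", "X = Y: diffusion constant unidentifiable")
  }
  list(d = D / (X - Y), X_ss = X, Y_ss = Y)
}

#' Detect label-degenerate metabolites
#'
#' Returns the metabolites whose cytosolic and ER pools carry the same label
#' incorporation level, so that the diffusion-link equations are linearly
#' dependent and the compartmental steady states cannot be solved
#' algebraically. Pools with undefined label (zero throughput) are skipped.
#'
#' @param t a `lignin_topology`
#' @param lf a `label_field`
#' @param tol relative tolerance on `|L_X - L_Y|`
#' @return integer vector of metabolite ids
#' @export
detect_degenerate_pools <- function(t, lf, tol = 1e-9) {
  paired <- t$metabolites$id[t$metabolites$has_er_pool]
  out <- integer(0)
  for (m in paired) {
    lx <- lf[[pool_index(t, m, "cytosol")]]
    ly <- lf[[pool_index(t, m, "er")]]
    if (is.na(lx) || is.na(ly)) next
    if (abs(lx - ly) <= tol * max(1, abs(lx), abs(ly))) out <- c(out, m)
  }
  out
}

#' Sample steady states of degenerate pools
#'
#' For each label-degenerate metabolite the receiving pool (the one the net
#' diffusion flux pours into at steady state) is sampled uniformly in
#' (0, 100); its partner follows from the volume-weighted normalization
#' `r X + (1-r) Y = 100`, and the diffusion constant from `d = D / (X - Y)`.
#' A link with zero net diffusion is flagged and its rate constant drawn from
#' a log-uniform prior (default `[1e-3, 10]`), with `X = Y = 100`.
#'
#' @param t a `lignin_topology`
#' @param f a `flux_distribution` (fixes each link's net diffusion)
#' @param ids metabolite ids to sample (from [detect_degenerate_pools()])
#' @param r cytosolic volume fraction
#' @param seed integer seed (optional; uses current RNG state if NULL)
#' @param d_prior length-2 prior range for unidentifiable rate constants
#' @return data frame with metabolite, X_ss, Y_ss, d, receiver, identifiable
#' @export
sample_degenerate_steady_states <- function(t, f, ids, r = 0.9, seed = NULL,
                                            d_prior = c(1e-3, 10)) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(ids, function(m) {
    D <- f$values[[paste0("D", m)]]
    if (D == 0) {
      d <- exp(stats::runif(1, log(d_prior[1]), log(d_prior[2])))
      return(data.frame(metabolite = m, X_ss = 100, Y_ss = 100, d = d,
                        receiver = NA_character_, identifiable = FALSE))
    }
    v <- stats::runif(1, 0, 100)
    if (D > 0) {           # pours into the ER pool
      Y <- v; X <- (100 - (1 - r) * v) / r
      receiver <- "er"
    } else {               # pours into the cytosolic pool
      X <- v; Y <- (100 - r * v) / (1 - r)
      receiver <- "cytosol"
    }
    data.frame(metabolite = m, X_ss = X, Y_ss = Y, d = D / (X - Y),
               receiver = receiver, identifiable = TRUE)
  })
  do.call(rbind, res)
}

#' Quantile summary of a flux ensemble
#'
#' @param ens nonempty list of `flux_distribution` objects
#' @return data frame with per-flux median, quartiles and range (total
#'   fluxes), plus one block per feeding condition for labeled portions when
#'   the distributions carry them
#' @export
flux_ensemble_summary <- function(ens) {
  if (length(ens) == 0) stop("empty ensemble")
  ids <- names(ens[[1]]$values)
  tot <- sapply(ens, function(f) f$values[ids])
  qs <- t(apply(tot, 1, stats::quantile, probs = c(0, .25, .5, .75, 1)))
  out <- data.frame(flux = ids, component = "total",
                    min = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                    q75 = qs[, 4], max = qs[, 5], row.names = NULL)
  feeds <- unique(unlist(lapply(ens, function(f) names(f$labeled_fraction))))
  for (fd in feeds) {
    lab <- sapply(ens, function(f) f$values[ids] * f$labeled_fraction[[fd]][ids])
    qs <- t(apply(lab, 1, stats::quantile, probs = c(0, .25, .5, .75, 1), na.rm = TRUE))
    out <- rbind(out, data.frame(flux = ids, component = paste0("labeled_", fd),
                                 min = qs[, 1], q25 = qs[, 2], median = qs[, 3],
                                 q75 = qs[, 4], max = qs[, 5], row.names = NULL))
  }
  out
}
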