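# --- Configuration, serialization, CLI surface and SBML export -----------

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' Read a run configuration
#'
#' JSON configuration with schema validation; unknown keys are reported
#' with their paths. Every run writes its resolved configuration next to
#' its outputs.
#'
#' @param path JSON file
#' @return named list of class `run_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "out_dir", "c3h", "r", "scenario", "ca_influx",
             "pca_influx", "parameter_file", "target_file", "budget",
             "n_static", "lignin_tol", "wall_tol", "epsilon", "stall",
             "sigma0", "ensemble_file", "transcript_bounds", "n_profiles",
             "influx_range", "noise", "horizon", "activity", "d_max",
             "spread")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(seed = 1L, out_dir = ".", c3h = TRUE, r = 0.9,
                   budget = 500L, n_static = 8L, lignin_tol = 0.25,
                   wall_tol = 0.5, n_profiles = 200L,
                   influx_range = c(0.5, 1), d_max = 50, spread = 0.5)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

.resolve_outputs <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_json(unclass(cfg), file.path(cfg$out_dir, "resolved_config.json"))
}

# ---- parameter set / criteria serialization ------------------------------

#' Write / read a parameter set as JSON
#' @param p a `parameter_set`
#' @param path file path
#' @export
write_parameter_set <- function(p, path) {
  .write_json(list(a = as.list(p$a), g = as.list(p$g), d = as.list(p$d),
                   r = p$r, conc = as.list(p$conc)), path)
  invisible(path)
}

#' @rdname write_parameter_set
#' @param t a `lignin_topology`
#' @export
read_parameter_set <- function(t, path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parameter_set(t, a = unlist(x$a), g = unlist(x$g), d = unlist(x$d),
                r = x$r, conc = unlist(x$conc))
}

#' Write / read admissibility criteria (target file)
#' @param criteria an `admissibility_criteria`
#' @param path file path
#' @export
write_criteria <- function(criteria, path) {
  out <- lapply(criteria$scenarios, function(sc)
    list(feed = unclass(sc$feed), bands = sc$bands))
  .write_json(list(scenarios = out, lignin_tol = criteria$lignin_tol,
                   wall_tol = criteria$wall_tol), path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenarios <- lapply(x$scenarios, function(sc) {
    fd <- do.call(feed_spec, sc$feed)
    list(feed = fd, bands = as.data.frame(sc$bands))
  })
  structure(list(scenarios = scenarios, lignin_tol = x$lignin_tol,
                 wall_tol = x$wall_tol),
            class = "admissibility_criteria")
}

# observation set <-> flat list
.obs_to_list <- function(obs)
  list(totals = as.list(obs$totals), incorporation = as.list(obs$incorporation))

# ---- CLI operations ------------------------------------------------------

#' Run one scenario from a configuration (CLI `simulate`)
#'
#' Requires `parameter_file` and `scenario` in the config; writes a tidy
#' trajectory CSV (time, pool, labeled, unlabeled), a JSON readout file and
#' the resolved configuration into `out_dir`.
#'
#' @param config path to a JSON `run_config`, or a `run_config`
#' @return invisibly, the output file paths
#' @export
cli_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  if (is.null(cfg$parameter_file) || !file.exists(cfg$parameter_file))
    stop("parameter_file missing or not found")
  if (is.null(cfg$scenario)) stop("scenario missing from config")
  t <- build_brachypodium_topology(c3h = isTRUE(cfg$c3h))
  p <- read_parameter_set(t, cfg$parameter_file)
  set.seed(cfg$seed)
  act <- enzyme_profile(t)
  if (!is.null(cfg$activity)) act[names(cfg$activity)] <- unlist(cfg$activity)
  sc <- make_scenario(cfg$scenario, t,
                      ca_influx = if (is.null(cfg$ca_influx)) 22 else cfg$ca_influx,
                      pca_influx = if (is.null(cfg$pca_influx)) 22 else cfg$pca_influx,
                      activity = act)
  .resolve_outputs(cfg)
  # trajectory of the labeling experiment from the unlabeled steady state
  sim <- simulate_scenario(t, p, sc)
  y0 <- pack_state(labeled_state(t, labeled = rep(0, nrow(t$pools)),
                                 unlabeled = sim$conc))
  rhs <- assemble_rhs(t, p, sc$activity, sc$feed)
  horizon <- if (is.null(cfg$horizon)) 400 else cfg$horizon
  traj <- integrate_gma(rhs, y0, t_end = horizon, rtol = 1e-7, atol = 1e-9,
                        n_out = 41)
  np <- nrow(t$pools)
  tidy <- do.call(rbind, lapply(seq_along(traj$time), function(i)
    data.frame(time = traj$time[i], pool = t$pools$pool,
               labeled = traj$states[i, seq_len(np)],
               unlabeled = traj$states[i, np + seq_len(np)])))
  traj_file <- file.path(cfg$out_dir, "trajectory.csv")
  utils::write.csv(tidy, traj_file, row.names = FALSE)
  readout_file <- file.path(cfg$out_dir, "readouts.json")
  .write_json(list(scenario = cfg$scenario, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("brachylignin")),
                   quasi_steady = .obs_to_list(sim$observations),
                   trajectory_endpoint = .obs_to_list(compute_readouts(traj, t))),
              readout_file)
  invisible(c(trajectory = traj_file, readouts = readout_file))
}

#' Fit an admissible ensemble from a target file (CLI `fit`)
#'
#' Runs the static flux-ensemble sampler against the targets, then the
#' explore-and-exploit dynamic search; writes a JSON-lines ensemble file,
#' a margin report CSV and a JSON summary.
#'
#' @inheritParams cli_simulate
#' @return invisibly, the output file paths
#' @export
cli_fit <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  if (is.null(cfg$target_file) || !file.exists(cfg$target_file))
    stop("target_file missing or not found")
  t <- build_brachypodium_topology(c3h = isTRUE(cfg$c3h))
  criteria <- read_criteria(cfg$target_file)
  .resolve_outputs(cfg)
  ens_file <- file.path(cfg$out_dir, "ensemble.jsonl")
  margin_file <- file.path(cfg$out_dir, "margins.csv")
  summary_file <- file.path(cfg$out_dir, "summary.json")
  if (cfg$budget == 0) {
    writeLines(character(0), ens_file)
    .write_json(list(n_admissible = 0,
                     note = "budget = 0: no candidates evaluated"),
                summary_file)
    return(invisible(c(ensemble = ens_file, summary = summary_file)))
  }
  static_ens <- sample_steady_state_fluxes(t, targets = criteria,
                                           n = cfg$n_static, seed = cfg$seed,
                                           r = cfg$r, spread = cfg$spread)
  ens <- explore_exploit_search(
    t, static_ens, criteria, budget = cfg$budget, seed = cfg$seed + 1,
    epsilon = if (is.null(cfg$epsilon)) 0.2 else cfg$epsilon,
    stall = if (is.null(cfg$stall)) 500 else cfg$stall,
    sigma0 = if (is.null(cfg$sigma0)) 0.3 else cfg$sigma0,
    r = cfg$r, d_max = cfg$d_max)
  lines <- vapply(ens, function(rec)
    jsonlite::toJSON(list(a = as.list(rec$params$a), g = as.list(rec$params$g),
                          d = as.list(rec$params$d), r = rec$params$r,
                          conc = as.list(rec$params$conc),
                          provenance = rec$provenance),
                    auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, ens_file)
  margins <- if (length(ens))
    do.call(rbind, lapply(seq_along(ens), function(i)
      cbind(member = i, ens[[i]]$margins))) else
    data.frame()
  utils::write.csv(margins, margin_file, row.names = FALSE)
  .write_json(list(n_admissible = length(ens),
                   static_acceptance = attr(static_ens, "acceptance_rate"),
                   budget = cfg$budget, seed = cfg$seed,
                   note = if (length(ens) == 0)
                     "no admissible parameter set found in budget" else NULL),
              summary_file)
  invisible(c(ensemble = ens_file, margins = margin_file,
              summary = summary_file))
}

#' Knockdown validation from config (CLI `validate`)
#'
#' Requires `ensemble_file` (JSON-lines from [cli_fit()]),
#' `transcript_bounds` (named fold changes) and `target_file` (knockdown
#' observation bands); writes the retained profiles and the influx-change
#' distribution.
#'
#' @inheritParams cli_simulate
#' @return invisibly, the output file paths
#' @export
cli_validate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  if (is.null(cfg$ensemble_file) || !file.exists(cfg$ensemble_file))
    stop("ensemble_file missing or not found")
  t <- build_brachypodium_topology(c3h = isTRUE(cfg$c3h))
  lines <- readLines(cfg$ensemble_file)
  if (length(lines) == 0) stop("empty ensemble file")
  ens <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    list(params = parameter_set(t, a = unlist(x$a), g = unlist(x$g),
                                d = unlist(x$d), r = x$r,
                                conc = unlist(x$conc)))
  })
  targets <- read_criteria(cfg$target_file)
  tb <- do.call(transcript_bounds, c(list(t), as.list(cfg$transcript_bounds)))
  .resolve_outputs(cfg)
  res <- bdptal_validation(t, ens, tb, targets, n = cfg$n_profiles,
                           seed = cfg$seed,
                           influx_range = as.numeric(cfg$influx_range))
  retained_file <- file.path(cfg$out_dir, "retained_profiles.csv")
  utils::write.csv(if (is.null(res$retained)) data.frame() else res$retained,
                   retained_file, row.names = FALSE)
  summary_file <- file.path(cfg$out_dir, "validation_summary.json")
  .write_json(list(seed = cfg$seed, n_profiles = cfg$n_profiles,
                   n_retained = res$n_retained,
                   influx_summary = as.list(res$influx_summary)),
              summary_file)
  invisible(c(retained = retained_file, summary = summary_file))
}

#' Generate synthetic targets from config (CLI `synth`)
#'
#' @inheritParams cli_simulate
#' @return invisibly, the output file paths
#' @export
cli_synth <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  t <- build_brachypodium_topology(c3h = isTRUE(cfg$c3h))
  .resolve_outputs(cfg)
  gt <- generate_ground_truth(t, seed = cfg$seed, r = cfg$r)
  nm <- if (is.null(cfg$noise)) noise_model() else
    do.call(noise_model, as.list(cfg$noise))
  obs <- generate_observations(gt, nm, seed = cfg$seed + 1,
                               lignin_tol = cfg$lignin_tol,
                               wall_tol = cfg$wall_tol)
  target_file <- file.path(cfg$out_dir, "targets.json")
  write_criteria(obs$criteria, target_file)
  param_file <- file.path(cfg$out_dir, "truth_parameters.json")
  write_parameter_set(gt$params, param_file)
  invisible(c(targets = target_file, truth = param_file))
}

#' Command-line entry point
#'
#' `Rscript -e 'brachylignin::bl_cli()' simulate config.json` style
#' dispatcher over the subcommands simulate, fit, validate, synth, export.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`)
#' @return exit status, invisibly
#' @export
bl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: <simulate|fit|validate|synth|export> <config.json|args>")
    return(invisible(1L))
  }
  cmd <- args[1]
  out <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(args[2]),
      fit = cli_fit(args[2]),
      validate = cli_validate(args[2]),
      synth = cli_synth(args[2]),
      export = {
        t <- build_brachypodium_topology()
        export_sbml(t, p = NULL, path = args[2])
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(out)
}

# ---- SBML export / import ------------------------------------------------

#' Export the model as an SBML Level 3 document
#'
#' Species are the 34 compartmental pools (plus the five absorbing sink
#' species in a `wall` compartment); reactions are the enzymatic fluxes,
#' sink fluxes and (reversible) diffusion links. When a parameter set is
#' supplied, GMA kinetic laws are embedded as MathML power products.
#'
#' @param t a `lignin_topology`
#' @param p optional `parameter_set`
#' @param path output file
#' @return the path, invisibly
#' @export
export_sbml <- function(t, p = NULL, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "brachypodium_lignin")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in c("cytosol", "er", "wall")) {
    sz <- switch(cid, cytosol = if (is.null(p)) 0.9 else p$r,
                 er = if (is.null(p)) 0.1 else 1 - p$r, wall = 1)
    xml2::xml_add_child(comps, "compartment", id = cid,
                        size = format(sz), constant = "true")
  }
  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (k in seq_len(nrow(t$pools))) {
    xml2::xml_add_child(sp, "species", id = t$pools$pool[k],
      name = t$metabolites$name[match(t$pools$metabolite[k], t$metabolites$id)],
      compartment = t$pools$compartment[k],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  for (s in sink_names()) {
    xml2::xml_add_child(sp, "species", id = paste0("sink_", s),
                        compartment = "wall",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "true", constant = "false")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  srcids <- t$metabolites$id[t$metabolites$is_source]
  add_ref <- function(parent, tag, species) {
    lst <- xml2::xml_add_child(parent, tag)
    xml2::xml_add_child(lst, "speciesReference", species = species,
                        stoichiometry = "1", constant = "true")
  }
  add_kinetic <- function(rx, terms) {
    # terms: named list value -> exponent (NULL exponent = plain factor)
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
      xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    for (nm in names(terms)) {
      ex <- terms[[nm]]
      if (is.null(ex)) {
        if (suppressWarnings(!is.na(as.numeric(nm)))) {
          xml2::xml_add_child(ap, "cn", nm)
        } else xml2::xml_add_child(ap, "ci", nm)
      } else {
        pw <- xml2::xml_add_child(ap, "apply")
        xml2::xml_add_child(pw, "power")
        xml2::xml_add_child(pw, "ci", nm)
        xml2::xml_add_child(pw, "cn", format(ex))
      }
    }
  }
  for (k in seq_len(nrow(t$reactions))) {
    r <- t$reactions[k, ]
    rx <- xml2::xml_add_child(rxs, "reaction", id = r$id,
                              name = paste0(r$enzyme, "_", r$compartment),
                              reversible = "false")
    xs <- if (r$compartment == "cytosol") "X" else "Y"
    if (!r$substrate %in% srcids)
      add_ref(rx, "listOfReactants", paste0(xs, r$substrate))
    add_ref(rx, "listOfProducts", paste0(xs, r$product))
    if (!is.null(p)) {
      sub <- paste0(xs, r$substrate)
      terms <- list()
      terms[[format(p$a[[r$id]] * 100)]] <- NULL  # a_j * enzyme baseline
      if (!r$substrate %in% srcids) terms[[sub]] <- p$g[[r$id]]
      add_kinetic(rx, terms)
    }
  }
  for (k in seq_len(nrow(t$sinks))) {
    s <- t$sinks[k, ]
    rx <- xml2::xml_add_child(rxs, "reaction", id = s$id,
                              reversible = "false")
    xs <- if (s$compartment == "cytosol") "X" else "Y"
    add_ref(rx, "listOfReactants", paste0(xs, s$source))
    add_ref(rx, "listOfProducts", paste0("sink_", s$target))
    if (!is.null(p)) {
      terms <- list()
      terms[[format(p$a[[s$id]])]] <- NULL
      terms[[paste0(xs, s$source)]] <- p$g[[s$id]]
      add_kinetic(rx, terms)
    }
  }
  for (k in seq_len(nrow(t$diffusion))) {
    m <- t$diffusion$metabolite[k]
    rx <- xml2::xml_add_child(rxs, "reaction", id = t$diffusion$id[k],
                              name = "diffusion", reversible = "true")
    add_ref(rx, "listOfReactants", paste0("X", m))
    add_ref(rx, "listOfProducts", paste0("Y", m))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import an exported SBML document
#'
#' @param path SBML file from [export_sbml()]
#' @return list with `species` (data frame) and `S` (stoichiometric matrix
#'   over non-boundary species and reactions)
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    compartment = xml2::xml_attr(spn, "compartment"),
    boundary = xml2::xml_attr(spn, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  rxn <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rids <- xml2::xml_attr(rxn, "id")
  pool_sp <- species$id[!species$boundary]
  S <- matrix(0L, length(pool_sp), length(rids),
              dimnames = list(pool_sp, rids))
  for (i in seq_along(rxn)) {
    for (ref in xml2::xml_find_all(rxn[[i]], ".//s:listOfReactants/s:speciesReference", ns)) {
      id <- xml2::xml_attr(ref, "species")
      if (id %in% pool_sp) S[id, rids[i]] <- S[id, rids[i]] - 1L
    }
    for (ref in xml2::xml_find_all(rxn[[i]], ".//s:listOfProducts/s:speciesReference", ns)) {
      id <- xml2::xml_attr(ref, "species")
      if (id %in% pool_sp) S[id, rids[i]] <- S[id, rids[i]] + 1L
    }
  }
  list(species = species, S = S)
}

#' Structural consistency checks for an SBML export
#'
#' No external SBML validator is available offline; these are the package's
#' own checks: unique ids, every species reference resolves, every
#' non-boundary species participates in at least one reaction, and
#' conversion reactions are stoichiometrically balanced.
#'
#' @param path SBML file
#' @return TRUE (invisibly) or a character vector of problems
#' @export
check_sbml_consistency <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  ids <- xml2::xml_attr(spn, "id")
  problems <- character(0)
  if (anyDuplicated(ids)) problems <- c(problems, "duplicate species ids")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference", ns), "species")
  if (!all(refs %in% ids))
    problems <- c(problems, "unresolved species reference")
  rids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:reaction", ns), "id")
  if (anyDuplicated(rids)) problems <- c(problems, "duplicate reaction ids")
  boundary <- ids[xml2::xml_attr(spn, "boundaryCondition") == "true"]
  used <- unique(refs)
  orphan <- setdiff(setdiff(ids, boundary), used)
  if (length(orphan))
    problems <- c(problems, paste("orphan species:", paste(orphan, collapse = ", ")))
  if (length(problems)) problems else invisible(TRUE)
}
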