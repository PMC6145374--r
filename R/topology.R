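# Canonical metabolite table for the Brachypodium monolignol pathway.
# Ids follow the X_i / Y_i subscript convention; the two amino-acid sources
# have no ER pool (they are boundary variables fixed by the feeding regime),
# leaving 17 metabolites with pools in both compartments (34 pools in all).
.bl_metabolites <- function() {
  data.frame(
    id = 1:19,
    name = c(
      "phenylalanine", "cinnamic acid", "tyrosine", "p-coumaric acid",
      "p-coumaroyl-CoA", "caffeic acid", "ferulic acid",
      "p-coumaroyl shikimate", "caffeoyl shikimate", "caffeoyl-CoA",
      "feruloyl-CoA", "coniferaldehyde", "coniferyl alcohol",
      "sinapaldehyde", "sinapyl alcohol", "5-OH-coniferaldehyde",
      "5-OH-coniferyl alcohol", "p-coumaraldehyde", "p-coumaryl alcohol"
    ),
    symbol = c(
      "Phe", "CA", "Tyr", "pCA", "pCA-CoA", "CaffA", "FA", "pC-shik",
      "Caff-shik", "Caff-CoA", "Fer-CoA", "ConifALD", "ConifOH",
      "SinALD", "SinOH", "5OH-ConifALD", "5OH-ConifOH", "pC-ALD", "pC-OH"
    ),
    is_source = c(TRUE, FALSE, TRUE, rep(FALSE, 16)),
    has_er_pool = c(FALSE, TRUE, FALSE, rep(TRUE, 16)),
    is_degenerate_candidate = c(
      FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE
    ),
    stringsAsFactors = FALSE
  )
}

# Enzymatic reactions. Compartment placement encodes the biology the model
# rests on: the P450s C4H, C3'H and F5H are bound to the outer ER surface and
# exist only there; PAL/PTAL act on the cytosolic source pools; the sinapyl
# tail downstream of the two F5H products runs in the cytosol (which is what
# confines label degeneracy to the four pools the pathway stoichiometry
# dictates); all other soluble-enzyme steps are instantiated in both activity
# centers. V25/V26/V31 are deliberate: they are the ER-compartment 4CL, HCT
# and CCR reactions on p-coumaroyl-CoA, so the canonical indices match the
# published example equations for Y5.
.bl_reactions <- function() {
  rx <- function(id, enzyme, sub, prod, comp) {
    data.frame(id = id, enzyme = enzyme, substrate = sub, product = prod,
               compartment = comp, stringsAsFactors = FALSE)
  }
  rbind(
    rx("V1",  "PAL",     1,  2,  "cytosol"),
    rx("V2",  "PTAL",    3,  4,  "cytosol"),
    rx("V3",  "4CL",     4,  5,  "cytosol"),
    rx("V4",  "C3H",     4,  6,  "cytosol"),
    rx("V5",  "COMT",    6,  7,  "cytosol"),
    rx("V6",  "4CL",     6,  10, "cytosol"),
    rx("V7",  "4CL",     7,  11, "cytosol"),
    rx("V8",  "HCT",     5,  8,  "cytosol"),
    rx("V9",  "HCT",     9,  10, "cytosol"),
    rx("V10", "CCoAOMT", 10, 11, "cytosol"),
    rx("V11", "CCR",     11, 12, "cytosol"),
    rx("V12", "CCR",     5,  18, "cytosol"),
    rx("V13", "CAD",     12, 13, "cytosol"),
    rx("V14", "CAD",     18, 19, "cytosol"),
    rx("V15", "COMT",    16, 14, "cytosol"),
    rx("V16", "CAD",     14, 15, "cytosol"),
    rx("V17", "COMT",    17, 15, "cytosol"),
    rx("V18", "C4H",     2,  4,  "er"),
    rx("V19", "C3H",     4,  6,  "er"),
    rx("V20", "COMT",    6,  7,  "er"),
    rx("V21", "4CL",     6,  10, "er"),
    rx("V22", "4CL",     7,  11, "er"),
    rx("V23", "C3pH",    8,  9,  "er"),
    rx("V24", "HCT",     9,  10, "er"),
    rx("V25", "4CL",     4,  5,  "er"),
    rx("V26", "HCT",     5,  8,  "er"),
    rx("V27", "CCoAOMT", 10, 11, "er"),
    rx("V28", "CCR",     11, 12, "er"),
    rx("V29", "CAD",     12, 13, "er"),
    rx("V30", "CAD",     18, 19, "er"),
    rx("V31", "CCR",     5,  18, "er"),
    rx("V32", "F5H",     12, 16, "er"),
    rx("V33", "F5H",     13, 17, "er")
  )
}

.bl_sinks <- function(fa_source = 7L) {
  data.frame(
    id = c("E1", "E2", "E3", "E4", "TH", "TG", "TS"),
    target = c("wall_pCA", "wall_pCA", "wall_FA", "wall_FA", "H", "G", "S"),
    source = c(4L, 4L, fa_source, fa_source, 19L, 13L, 15L),
    compartment = c("cytosol", "er", "cytosol", "er",
                    "cytosol", "cytosol", "cytosol"),
    kind = c(rep("wall_phenolic", 4), rep("lignin_monomer", 3)),
    stringsAsFactors = FALSE
  )
}

#' Build the two-compartment Brachypodium lignin pathway topology
#'
#' Constructs the fixed reaction network of monolignol biosynthesis in
#' *Brachypodium distachyon*, distributed over two activity centers: the
#' cytosol (pools `X_i`) and the outer ER surface (pools `Y_i`). The three
#' cytochrome-P450 steps (C4H, C3'H, F5H) exist only in the ER compartment;
#' phenylalanine and tyrosine enter via cytosolic PAL/PTAL; each of the 17
#' intermediate metabolites has one pool in each compartment connected by a
#' diffusion link; absorbing sinks collect the three lignin monomers (H, G, S)
#' and the wall-bound *p*-coumaric and ferulic acid effluxes (E1--E4).
#'
#' There is no CSE reaction (caffeoyl shikimate to caffeic acid) and no
#' CCR step on caffeoyl-CoA: both are absent in *Brachypodium*. The direct
#' C3H hydroxylation of *p*-coumaric acid (with the caffeic/ferulic acid
#' branch it opens) is part of the default network; `c3h = FALSE` removes it,
#' which shrinks the network to 15 paired metabolites and reroutes the
#' wall-bound ferulate effluxes to feruloyl-CoA.
#'
#' @param c3h logical; include the C3H route via free caffeic/ferulic acid.
#' @return An object of class `lignin_topology`: a list with data frames
#'   `metabolites`, `reactions`, `sinks`, `diffusion`, the pool table
#'   `pools`, enzyme list, channel annotations, and the paper-symbol alias
#'   table.
#' @export
build_brachypodium_topology <- function(c3h = TRUE) {
  mets <- .bl_metabolites()
  rxns <- .bl_reactions()
  if (c3h) {
    sinks <- .bl_sinks(7L)
  } else {
    drop_m <- c(6L, 7L)
    mets <- mets[!mets$id %in% drop_m, , drop = FALSE]
    keep <- !(rxns$substrate %in% drop_m | rxns$product %in% drop_m)
    rxns <- rxns[keep, , drop = FALSE]
    sinks <- .bl_sinks(11L)
  }
  paired <- mets$id[mets$has_er_pool]
  diffusion <- data.frame(
    id = paste0("D", paired),
    metabolite = paired,
    rate_constant_symbol = paste0("d_", paired),
    stringsAsFactors = FALSE
  )
  pools <- data.frame(
    pool = c(paste0("X", paired), paste0("Y", paired)),
    metabolite = c(paired, paired),
    compartment = rep(c("cytosol", "er"), each = length(paired)),
    stringsAsFactors = FALSE
  )
  topo <- structure(list(
    metabolites = mets,
    reactions = rxns,
    sinks = sinks,
    diffusion = diffusion,
    pools = pools,
    enzymes = sort(unique(rxns$enzyme)),
    channel_annotations = list(
      er_shikimate_channel = list(
        fluxes = intersect(c("V25", "V26", "V23", "V24"), rxns$id),
        compartment = "er"),
      er_coniferaldehyde_channel = list(
        fluxes = c("V28", "V29", "V32", "V33"),
        compartment = "er")
    ),
    aliases = data.frame(
      paper = c("V25", "V26", "V31", "d9"),
      canonical = c("V25", "V26", "V31", "D5"),
      meaning = c("ER 4CL: Y4 -> Y5", "ER HCT: Y5 -> Y8",
                  "ER CCR: Y5 -> Y18",
                  "diffusion link of p-coumaroyl-CoA (X5 <-> Y5)"),
      stringsAsFactors = FALSE
    ),
    c3h = c3h
  ), class = "lignin_topology")
  topo
}

#' @export
print.lignin_topology <- function(x, ...) {
  cat("Two-compartment lignin pathway topology (Brachypodium)\n")
  cat(sprintf("  metabolites: %d (%d paired -> %d pools; %d sources)\n",
              nrow(x$metabolites), sum(x$metabolites$has_er_pool),
              nrow(x$pools), sum(x$metabolites$is_source)))
  cat(sprintf("  enzymatic reactions: %d (%d cytosol, %d ER)\n",
              nrow(x$reactions), sum(x$reactions$compartment == "cytosol"),
              sum(x$reactions$compartment == "er")))
  cat(sprintf("  sinks: %d, diffusion links: %d, state equations: %d\n",
              nrow(x$sinks), nrow(x$diffusion), n_state_equations(x)))
  invisible(x)
}

#' Number of dynamic state equations (labeled + unlabeled pools)
#' @param t a `lignin_topology`
#' @return integer; 68 for the built-in default topology
#' @export
n_state_equations <- function(t) 2L * nrow(t$pools)

# Index of the pool (met, compartment) in the canonical pool ordering.
pool_index <- function(t, metabolite, compartment) {
  i <- match(paste(metabolite, compartment),
             paste(t$pools$metabolite, t$pools$compartment))
  i
}

# All flux ids in canonical column order: reactions, sinks, diffusion.
flux_ids <- function(t) c(t$reactions$id, t$sinks$id, t$diffusion$id)

#' Stoichiometric matrix of the pathway
#'
#' Entry (i, j) is the net stoichiometric coefficient of pool i in flux j.
#' Diffusion columns carry -1 on the cytosolic pool and +1 on the ER pool of
#' the linked metabolite (positive flux = net cytosol-to-ER transfer); the
#' ER-row volume scaling by R = r/(1-r) is applied at ODE assembly time, not
#' here. Source uptake reactions (PAL, PTAL) have no substrate row because
#' the sources are boundary variables; sink columns have a single -1.
#'
#' @param t a `lignin_topology`
#' @return integer matrix, pools x fluxes, with dimnames
#' @export
stoichiometric_matrix <- function(t) {
  np <- nrow(t$pools)
  ids <- flux_ids(t)
  S <- matrix(0L, np, length(ids), dimnames = list(t$pools$pool, ids))
  src <- t$metabolites$id[t$metabolites$is_source]
  for (k in seq_len(nrow(t$reactions))) {
    r <- t$reactions[k, ]
    if (!r$substrate %in% src) {
      S[pool_index(t, r$substrate, r$compartment), r$id] <- -1L
    }
    S[pool_index(t, r$product, r$compartment), r$id] <- 1L
  }
  for (k in seq_len(nrow(t$sinks))) {
    s <- t$sinks[k, ]
    S[pool_index(t, s$source, s$compartment), s$id] <- -1L
  }
  for (k in seq_len(nrow(t$diffusion))) {
    m <- t$diffusion$metabolite[k]
    S[pool_index(t, m, "cytosol"), t$diffusion$id[k]] <- -1L
    S[pool_index(t, m, "er"), t$diffusion$id[k]] <- 1L
  }
  S
}

# Steady-state balance matrix in absolute (volume-weighted) units: local
# fluxes multiplied by their compartment volume fraction so that S_abs %*% v
# (v in local units) gives d/dt of r*X / (1-r)*Y. Used by the static sampler.
balance_matrix <- function(t, r = 0.9) {
  S <- stoichiometric_matrix(t)
  w <- ifelse(t$pools$compartment == "cytosol", r, 1 - r)
  # local reaction/sink fluxes scale with their own compartment volume;
  # a diffusion flux D (cytosol-local units) moves absolute mass r*D.
  Sb <- S * 0
  for (j in colnames(S)) {
    if (startsWith(j, "D")) {
      Sb[, j] <- S[, j] * r  # -r*D on X row, +r*D on Y row (abs units)
    } else {
      Sb[, j] <- S[, j] * w
    }
  }
  Sb
}

#' Validate a pathway topology
#'
#' Structural checks: duplicate flux ids, pools unreachable from the sources,
#' and dead-end metabolites (non-source metabolites with no consuming
#' reaction or sink in either compartment; diffusion alone cannot drain a
#' pool at steady state). The built-in topology yields an empty report.
#'
#' @param t a `lignin_topology`
#' @return a list of class `topology_validation` with character vectors
#'   `duplicate_flux_ids`, `unreachable_pools`, `dead_end_metabolites`;
#'   `ok` is TRUE when all are empty.
#' @export
validate_topology <- function(t) {
  ids <- flux_ids(t)
  dup <- unique(ids[duplicated(ids)])

  # reachability over reactions (sub -> prod), diffusion (both ways)
  src <- t$metabolites$id[t$metabolites$is_source]
  reach <- src
  repeat {
    nxt <- unique(c(reach, t$reactions$product[t$reactions$substrate %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  unreachable <- setdiff(t$metabolites$id[!t$metabolites$is_source], reach)
  unreachable_pools <- t$pools$pool[t$pools$metabolite %in% unreachable]

  nonsrc <- t$metabolites$id[!t$metabolites$is_source]
  consumed <- unique(c(t$reactions$substrate, t$sinks$source))
  dead <- setdiff(nonsrc, consumed)
  dead_names <- t$metabolites$name[match(dead, t$metabolites$id)]

  out <- list(
    duplicate_flux_ids = dup,
    unreachable_pools = unreachable_pools,
    dead_end_metabolites = dead_names,
    ok = length(dup) == 0 && length(unreachable_pools) == 0 && length(dead) == 0
  )
  class(out) <- "topology_validation"
  out
}

#' @export
print.topology_validation <- function(x, ...) {
  if (x$ok) {
    cat("topology valid: no problems found\n")
  } else {
    if (length(x$duplicate_flux_ids))
      cat("duplicate flux ids:", paste(x$duplicate_flux_ids, collapse = ", "), "\n")
    if (length(x$unreachable_pools))
      cat("unreachable pools:", paste(x$unreachable_pools, collapse = ", "), "\n")
    if (length(x$dead_end_metabolites))
      cat("dead-end metabolites:", paste(x$dead_end_metabolites, collapse = ", "), "\n")
  }
  invisible(x)
}
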