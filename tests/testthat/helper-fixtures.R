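# Shared fixtures, built once per test run (everything is generated in
# code; no data files). Seeds are fixed so all tests are deterministic.

bl_topo <- build_brachypodium_topology()

# one untargeted static flux sample + kinetic orders + constructed model
bl_fix <- local({
  f <- sample_steady_state_fluxes(bl_topo, targets = NULL, n = 1,
                                  seed = 42)[[1]]
  g <- sample_kinetic_orders(bl_topo, seed = 7)
  p <- construct_parameter_set(bl_topo, f, g, seed = 11)
  list(f = f, g = g, p = p)
})

# synthetic ground truth (channeling pattern + stable + all 7 scenarios)
bl_gt <- generate_ground_truth(bl_topo, seed = 1)

# hand-built flux distribution: two labeled/unlabeled streams merging at
# the cytosolic pCA pool (used for the label-propagation oracle)
bl_merge_fixture <- function(r = 0.9) {
  ids <- c(bl_topo$reactions$id, bl_topo$sinks$id, bl_topo$diffusion$id)
  v <- stats::setNames(numeric(length(ids)), ids)
  v["V1"] <- 2 / r      # labeled Phe entry, 2 absolute units
  v["D2"] <- 2 / r      # cinnamic acid crosses into the ER
  v["V18"] <- 2 / (1 - r)  # C4H into the ER pCA pool
  v["D4"] <- -2 / r     # pCA diffuses back into the cytosol
  v["V2"] <- 3 / r      # unlabeled Tyr entry, 3 absolute units
  v["E1"] <- 5 / r      # combined efflux out of the cytosolic pCA pool
  flux_distribution(v, r = r)
}
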