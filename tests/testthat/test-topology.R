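test_that("built-in topology has the published structure", {
  t <- bl_topo
  expect_equal(nrow(t$pools), 34)                    # 17 paired metabolites
  expect_equal(n_state_equations(t), 68)             # labeled + unlabeled
  expect_equal(sum(t$metabolites$is_source), 2)      # Phe and Tyr
  expect_false(any(t$metabolites$has_er_pool[t$metabolites$is_source]))

  # the three P450s exist only at the ER surface
  for (enz in c("C4H", "C3pH", "F5H")) {
    expect_true(all(t$reactions$compartment[t$reactions$enzyme == enz] == "er"))
  }
  # absent in Brachypodium: CSE (caffeoyl shikimate -> caffeic acid) and
  # the CCR step on caffeoyl-CoA
  caffeoyl_shik <- 9L; caffeoyl_coa <- 10L; caffeic <- 6L
  cons9 <- t$reactions[t$reactions$substrate == caffeoyl_shik, ]
  expect_false(caffeic %in% cons9$product)
  expect_false(any(t$reactions$substrate == caffeoyl_coa &
                     t$reactions$enzyme == "CCR"))

  # anchor indices: ER 4CL / HCT / CCR on the p-coumaroyl-CoA node
  rx <- t$reactions
  expect_equal(rx$enzyme[rx$id == "V25"], "4CL")
  expect_equal(rx$compartment[rx$id == "V25"], "er")
  expect_equal(rx$substrate[rx$id == "V25"], 4)
  expect_equal(rx$product[rx$id == "V25"], 5)
  expect_equal(rx$substrate[rx$id == "V26"], 5)
  expect_equal(rx$product[rx$id == "V26"], 8)
  expect_equal(rx$substrate[rx$id == "V31"], 5)
  expect_equal(rx$product[rx$id == "V31"], 18)
  expect_equal(t$aliases$canonical[t$aliases$paper == "d9"], "D5")

  # every diffusion link connects the two pools of one metabolite
  expect_equal(sort(t$diffusion$metabolite),
               sort(t$metabolites$id[t$metabolites$has_er_pool]))
})

test_that("stoichiometric matrix is conservative", {
  t <- bl_topo
  S <- stoichiometric_matrix(t)
  expect_equal(dim(S), c(34L, length(flux_ids(t))))
  # pool-to-pool conversion columns sum to zero
  src <- t$metabolites$id[t$metabolites$is_source]
  conv <- t$reactions$id[!t$reactions$substrate %in% src]
  expect_true(all(colSums(S[, conv]) == 0))
  # sink columns: exactly one -1, no +1
  for (id in t$sinks$id) {
    expect_equal(sum(S[, id] == -1L), 1)
    expect_equal(sum(S[, id] == 1L), 0)
  }
  # diffusion columns: -1 on X row, +1 on Y row of the same metabolite
  for (k in seq_len(nrow(t$diffusion))) {
    cl <- S[, t$diffusion$id[k]]
    expect_equal(sum(cl != 0), 2)
    expect_equal(sum(cl), 0)
  }
})

test_that("validation flags structural defects", {
  t <- bl_topo
  expect_true(validate_topology(t)$ok)

  broken <- t
  broken$sinks <- broken$sinks[broken$sinks$id != "TH", ]
  rep1 <- validate_topology(broken)
  expect_false(rep1$ok)
  expect_true("p-coumaryl alcohol" %in% rep1$dead_end_metabolites)

  dup <- t
  dup$reactions$id[2] <- "V1"
  expect_true("V1" %in% validate_topology(dup)$duplicate_flux_ids)
})

test_that("sinks remain reachable from Phe alone without PTAL", {
  t <- bl_topo
  noptal <- t
  noptal$reactions <- noptal$reactions[noptal$reactions$enzyme != "PTAL", ]
  # restrict sources to Phe and check reachability of the monomer precursors
  noptal$metabolites$is_source[noptal$metabolites$id == 3] <- FALSE
  rep <- validate_topology(noptal)
  expect_length(rep$unreachable_pools, 0)
})

test_that("the C3H flag removes the free-acid branch", {
  t2 <- build_brachypodium_topology(c3h = FALSE)
  expect_equal(sum(t2$metabolites$has_er_pool), 15)
  expect_false(any(t2$reactions$enzyme == "C3H"))
  # wall-FA effluxes rerouted to feruloyl-CoA
  expect_equal(unique(t2$sinks$source[t2$sinks$target == "wall_FA"]), 11L)
  expect_true(validate_topology(t2)$ok)
})
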