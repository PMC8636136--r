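test_that("the 12-10 well has the prescribed shape", {
  expect_equal(go_contact_energy(5, 5, 1.2), -1.2)
  expect_lt(abs(go_contact_energy(500, 5, 1.2)), 1e-18)
  # zero crossing at r0 * sqrt(5/6)
  rc <- 5 * sqrt(5 / 6)
  expect_lt(abs(go_contact_energy(rc, 5, 1.2)), 1e-12)
  expect_gt(go_contact_energy(rc - 1e-3, 5, 1.2), 0)
  expect_lt(go_contact_energy(rc + 1e-3, 5, 1.2), 0)
  # finite at r -> 0 (overflow guard)
  expect_true(is.finite(go_contact_energy(1e-12, 5, 1.2)))
})

test_that("screened electrostatics follow the Debye-Hueckel form", {
  p <- energy_params(salt = 200, temperature = 300, dielectric = 78)
  expect_equal(debye_length(200, 300, 78), 6.8, tolerance = 0.01)
  expect_equal(debye_huckel_energy(5, 0, 1, p), 0)
  e <- debye_huckel_energy(seq(3, 20, by = 0.5), 1, -1, p)
  expect_true(all(e <= 0))
  expect_true(all(diff(e) >= 0))     # monotone toward 0
  expect_equal(debye_huckel_energy(p$dh_cutoff + 1, 1, -1, p), 0)
})

test_that("pairing wells scale A:T shallower than G:C by the set ratio", {
  p <- energy_params()
  gc <- build_bdna("GGGGGG")
  at <- build_bdna("AAAAAA")
  e_gc <- dna_energy(gc$coords, gc, p)[["dna_pair"]]
  e_at <- dna_energy(at$coords, at, p)[["dna_pair"]]
  expect_equal(e_at / e_gc, p$at_gc_ratio, tolerance = 1e-10)
})

test_that("pairing energy is local to the separated pair", {
  d <- small_duplex()
  p <- energy_params()
  e0 <- dna_energy(d$coords, d, p)[["dna_pair"]]
  # pull one interior pair's bases 10 A apart along the pair axis
  k <- 5
  i <- d$wc_pairs$i[k]; j <- d$wc_pairs$j[k]
  u <- (d$coords[j, ] - d$coords[i, ])
  u <- u / sqrt(sum(u^2))
  X <- d$coords
  X[i, ] <- X[i, ] - 5 * u; X[j, ] <- X[j, ] + 5 * u
  e1 <- dna_energy(X, d, p)[["dna_pair"]]
  eps_k <- ifelse(d$wc_pairs$pair_class[k] == "GC", p$eps_bp,
                  p$eps_bp * p$at_gc_ratio)
  # that pair's well is emptied (it contributed -eps, now ~0);
  # neighbouring pairs' bases were not moved
  expect_equal(e1 - e0, eps_k, tolerance = 0.05 * eps_k)
})

test_that("non-complementary pairing requests are topology errors", {
  d <- small_duplex()
  bad <- d
  bad$beads$identity[bad$wc_pairs$i[1]] <- "C"  # opposite still pairs with T
  expect_error(derive_bonded_terms(
    cg_topology(bad$beads, bad$coords, bad$chain_table, bad$promoter),
    wc_pairs = cbind(bad$wc_pairs$i, bad$wc_pairs$j)), "non-complementary")
})

test_that("energies are invariant under rigid motion", {
  toy <- toy_system()
  X <- toy$refset$coords$oc
  e0 <- total_energy_forces(X, toy$topology, toy$contacts)$breakdown
  e1 <- total_energy_forces(sweep(X, 2, c(-11, 4, 30)), toy$topology,
                            toy$contacts)$breakdown
  expect_equal(e1, e0, tolerance = 1e-10)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e2 <- total_energy_forces(X %*% R, toy$topology, toy$contacts)$breakdown
  expect_equal(e2, e0, tolerance = 1e-8)
  # net force vanishes (no external field)
  f <- total_energy_forces(X, toy$topology, toy$contacts)$forces
  expect_lt(max(abs(colSums(f))), 1e-8)
})

test_that("with charges and contacts removed, a protein chain is a pure Go model", {
  toy <- toy_system()
  top <- toy$topology
  prot <- which(top$beads$kind == "CA")
  # neutralize and isolate the protein
  top$beads$identity[prot] <- "A"
  keep <- top$beads$kind == "CA"
  top2 <- top
  top2$beads <- top$beads[keep, , drop = FALSE]
  top2$coords <- top$coords[keep, , drop = FALSE]
  top2$chain_table <- top$chain_table[1, , drop = FALSE]
  top2$wc_pairs <- top2$wc_pairs[0, ]; top2$stacks <- top2$stacks[0, ]
  keepb <- top$bonds$i %in% prot & top$bonds$j %in% prot
  top2$bonds <- top$bonds[keepb, , drop = FALSE]
  top2$angles <- top$angles[top$angles$i %in% prot & top$angles$k %in% prot, ]
  top2$dihedrals <- top$dihedrals[top$dihedrals$i %in% prot &
                                    top$dihedrals$l %in% prot, ]
  ef <- total_energy_forces(top2$coords, top2, NULL)
  expect_equal(ef$breakdown[["electrostatic"]], 0)
  expect_equal(ef$breakdown[["go_protein_dna"]], 0)
  expect_equal(ef$breakdown[["dna_pair"]], 0)
  # the reference structure is (near) the minimum: tiny gradient except
  # the excluded-volume background
  expect_lt(abs(ef$breakdown[["protein_local"]]), 1e-8)
  expect_equal(ef$breakdown[["go_protein"]],
               -nrow(top2$go_intra) * energy_params()$eps_go_intra *
                 (1 + (5 * 0.5^12 - 6 * 0.5^10)), tolerance = 1e-6)
})

test_that("energy parameters round-trip through YAML", {
  p <- energy_params(eps_bp = 7.5, salt = 150, ev_radii = c(CA = 2.2, P = 2,
                                                            S = 2, B = 1.4))
  f <- tempfile(fileext = ".yml")
  write_energy_params(p, f)
  q <- read_energy_params(f)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  writeLines("nonsense: 1", f)
  expect_error(read_energy_params(f), "unknown parameter")
})
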