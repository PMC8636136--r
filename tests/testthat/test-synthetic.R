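test_that("a one-base-pair duplex has two nucleotides and one pair", {
  d <- build_bdna("G")
  expect_equal(nrow(d$beads), 4)  # S+B per strand, no 5' phosphates
  expect_equal(nrow(d$wc_pairs), 1)
  expect_equal(d$wc_pairs$pair_class, "GC")
})

test_that("built duplexes are fully paired under the break criterion", {
  for (sd in 1:3) {
    d <- build_bdna(.random_seq <- paste(sample(c("A", "C", "G", "T"), 12,
                                                replace = TRUE), collapse = ""))
    expect_equal(bubble_size(d$coords, d, break_threshold = 6.2), 0)
  }
})

test_that("helix geometry follows the rise/twist parameters", {
  d <- build_bdna("ACGTACGTAC", rise = 3.38, twist = 34.3)
  # axial extent between first and last base pair equals 9 steps of rise
  zb <- d$coords[d$beads$kind == "B" & d$beads$chain_id == "T", 3]
  expect_equal(max(zb) - min(zb), 9 * 3.38, tolerance = 1e-10)
  # all pair distances equal by construction
  wd <- wc_distances(d$coords, d)
  expect_lt(diff(range(wd)), 1e-8)
})

test_that("the built geometry is the DNA bonded-energy minimum", {
  d <- small_duplex()
  e <- dna_energy(d$coords, d)
  expect_lt(abs(e[["dna_bonded"]]), 1e-8)
  # stacking and pairing sit at their well minima: total equals -sum(eps)
  p <- energy_params()
  eps_wc <- ifelse(d$wc_pairs$pair_class == "GC", p$eps_bp,
                   p$eps_bp * p$at_gc_ratio)
  expect_equal(e[["dna_pair"]], -sum(eps_wc), tolerance = 1e-6)
  expect_equal(e[["dna_stack"]], -nrow(d$stacks) * p$eps_stack,
               tolerance = 1e-6)
})

test_that("invalid sequences are rejected", {
  expect_error(build_bdna("ACGU"), "invalid base")
  expect_error(build_bdna(""), "non-empty")
})

test_that("toy system prescriptions are met exactly", {
  toy <- toy_system()
  cs <- toy$contacts
  expect_equal(length(cs$cc_specific), 92)
  expect_equal(length(cs$oc_set), 22)
  expect_equal(length(cs$itc_unique), 99)
  expect_equal(unname(cs$overlap["oc_in_itc"]), 19)
  # CC contacts are disjoint from all others
  u <- cs$union_set
  expect_equal(sum(u$in_cc & (u$in_oc | u$in_itc)), 0)
})

test_that("toy generation is seed-deterministic with seed-varying geometry", {
  a <- build_toy_pic(seed = 3)
  b <- build_toy_pic(seed = 3)
  expect_identical(a$refset$coords, b$refset$coords)
  expect_identical(a$contacts$union_set, b$contacts$union_set)
  c2 <- build_toy_pic(seed = 4)
  expect_false(identical(a$refset$coords$cc, c2$refset$coords$cc))
  expect_equal(length(c2$contacts$cc_specific), 92)
  expect_equal(length(c2$contacts$itc_unique), 99)
})

test_that("unsatisfiable contact prescriptions raise a spec error", {
  sp <- toy_system_spec(clamp_size = 45, contact_sizes = c(cc = 5000, oc = 22,
                                                           itc = 118))
  expect_error(build_toy_pic(sp, seed = 1), "unsatisfiable")
  expect_error(toy_system_spec(oc_itc_overlap = 30), "cannot exceed")
})

test_that("single-state specs degenerate to the full set", {
  # with n_states collapsed the state-specific set is the whole list
  cs <- build_contact_sets(cc = data.frame(bead_i = 1:4, bead_j = 5:8,
                                           r0 = rep(5, 4)))
  expect_equal(length(cs$cc_specific), 4)
  expect_equal(nrow(cs$union_set), 4)
})

test_that("perturbed frames satisfy the generator contract", {
  toy <- toy_system()
  cs <- toy$contacts
  sets <- list(cc = cs$cc_specific, oc = cs$oc_set, itc = cs$itc_unique)
  for (s in names(sets)) {
    fr <- perturb_to_state(toy$refset, s, noise = 0.3, seed = 7)
    expect_gte(contact_fraction(fr, cs, sets[[s]]), 0.9)
    for (o in setdiff(names(sets), s)) {
      # contacts exclusive to the other state (not shared with state s)
      u <- cs$union_set
      excl <- which(u[[paste0("in_", o)]] & !u[[paste0("in_", s)]])
      expect_lt(contact_fraction(fr, cs, excl), 0.1)
    }
  }
  # zero noise reproduces the reference exactly
  fr0 <- perturb_to_state(toy$refset, "cc", noise = 0, seed = 1)
  expect_equal(contact_fraction(fr0, cs, cs$cc_specific), 1.0)
  expect_error(perturb_to_state(toy$refset, "nope"), "unknown state")
})

test_that("contact fractions decay monotonically with noise on average", {
  toy <- toy_system()
  cs <- toy$contacts
  noise <- c(0, 1, 2.5, 5, 10)
  fr <- vapply(noise, function(nz) {
    mean(vapply(1:8, function(sd)
      contact_fraction(perturb_to_state(toy$refset, "itc", nz, sd),
                       cs, cs$itc_unique), 1.0))
  }, 1.0)
  expect_true(all(diff(fr) <= 0.02))  # non-increasing up to MC noise
  expect_equal(fr[1], 1.0)
  expect_lt(fr[length(fr)], 0.5)
})
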