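test_that("bead-level detection matches a brute-force scan", {
  for (sd in 1:10) {
    top <- random_cg_instance(n_prot = sample(3:8, 1), n_dna_res = sample(2:5, 1),
                              seed = sd)
    cutoff <- runif(1, 4, 9)
    got <- detect_native_contacts(top, cutoff = cutoff)
    # independent oracle: exhaustive double loop
    bd <- top$beads
    prot <- which(bd$kind == "CA")
    dna <- which(bd$kind != "CA")
    exp_rows <- list()
    for (i in prot) for (j in dna) {
      r <- sqrt(sum((top$coords[i, ] - top$coords[j, ])^2))
      if (r < cutoff)
        exp_rows[[length(exp_rows) + 1L]] <- data.frame(bead_i = i, bead_j = j,
                                                        r0 = r)
    }
    want <- if (length(exp_rows)) do.call(rbind, exp_rows) else
      data.frame(bead_i = integer(0), bead_j = integer(0), r0 = numeric(0))
    want <- want[order(want$bead_i, want$bead_j), ]
    rownames(want) <- rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("distant chains yield no contacts; missing chains error", {
  top <- random_cg_instance(5, 3, seed = 1, spread = 5)
  far <- top
  dna <- which(far$beads$kind != "CA")
  far$coords[dna, ] <- far$coords[dna, ] + 500
  expect_equal(nrow(detect_native_contacts(far, cutoff = 10)), 0)

  prot_only <- top
  prot_only$beads <- prot_only$beads[prot_only$beads$kind == "CA", ]
  prot_only$coords <- top$coords[top$beads$kind == "CA", ]
  prot_only$chain_table <- prot_only$chain_table[1, , drop = FALSE]
  expect_error(detect_native_contacts(prot_only, cutoff = 10), "both")
})

test_that("heavy-atom detection records one contact per bead pair", {
  f <- tempfile(fileext = ".pdb")
  # one glycine 4 A from a nucleotide base: within a 6.5 A heavy-atom cutoff
  nuc <- readLines(write_nucleotide_pdb(tempfile(fileext = ".pdb")))
  gly <- c(
    "ATOM     30  N   GLY A   1       8.000   5.000   6.000  1.00  0.00           N",
    "ATOM     31  CA  GLY A   1       9.000   5.000   6.000  1.00  0.00           C",
    "ATOM     32  C   GLY A   1      10.000   5.000   6.000  1.00  0.00           C")
  writeLines(c(nuc[-length(nuc)], gly, "END"), f)
  m <- read_structure(f)
  got <- detect_native_contacts(m, cutoff = 6.5)
  expect_gte(nrow(got), 1)
  # each (protein bead, DNA bead) pair appears at most once
  expect_false(any(duplicated(paste(got$bead_i, got$bead_j))))
})

test_that("set algebra of union and state-specific subsets", {
  same <- data.frame(bead_i = 1:5, bead_j = 11:15, r0 = rep(5, 5))
  cs <- build_contact_sets(cc = same, oc = same, itc = same)
  expect_equal(nrow(cs$union_set), 5)
  expect_equal(length(cs$cc_specific), 0)
  expect_equal(length(cs$itc_unique), 0)
  expect_equal(length(cs$oc_set), 5)

  cc <- data.frame(bead_i = 1:3, bead_j = 21:23, r0 = 5)
  oc <- data.frame(bead_i = 4:5, bead_j = 24:25, r0 = 5)
  itc <- data.frame(bead_i = 6:9, bead_j = 26:29, r0 = 5)
  cs2 <- build_contact_sets(cc = cc, oc = oc, itc = itc)
  expect_equal(nrow(cs2$union_set), 9)
  expect_equal(length(cs2$cc_specific), 3)
  expect_equal(length(cs2$itc_unique), 4)
  # |union| = |cc_specific| + |non-CC contacts|
  expect_equal(nrow(cs2$union_set),
               length(cs2$cc_specific) + sum(!cs2$union_set$in_cc))
})

test_that("r0 conflicts across states warn and follow priority", {
  cc <- data.frame(bead_i = 1, bead_j = 2, r0 = 5)
  itc <- data.frame(bead_i = 1, bead_j = 2, r0 = 9)
  expect_warning(cs <- build_contact_sets(cc = cc, itc = itc), "differing")
  expect_equal(cs$union_set$r0, 5)  # CC wins
})

test_that("weakening scales selected wells only, out of place", {
  toy <- toy_system()
  cs <- toy$contacts
  sel <- toy$groups$ewing[1:3]
  w <- weaken_contacts(cs, sel, 0.5)
  expect_equal(w$union_set$epsilon[sel], cs$union_set$epsilon[sel] * 0.5)
  expect_equal(w$union_set$epsilon[-sel], cs$union_set$epsilon[-sel])
  expect_equal(cs$union_set$epsilon, rep(1.2, nrow(cs$union_set)))  # untouched
  expect_identical(weaken_contacts(cs, sel, 1)$union_set, cs$union_set)
  expect_warning(weaken_contacts(cs, integer(0), 0.5), "empty")
})

test_that("zeroing a subset removes exactly its well energy", {
  toy <- toy_system()
  cs <- toy$contacts
  sel <- toy$groups$ewing
  fr <- toy$refset$coords$oc
  e_full <- total_energy_forces(fr, toy$topology, cs)$breakdown[["go_protein_dna"]]
  e_weak <- total_energy_forces(fr, toy$topology,
                                weaken_contacts(cs, sel, 0))$breakdown[["go_protein_dna"]]
  # independent oracle: truncated-shifted 12-10 well energy of the subset
  u <- cs$union_set[sel, ]
  r <- sqrt(rowSums((fr[u$bead_i, , drop = FALSE] - fr[u$bead_j, , drop = FALSE])^2))
  well <- function(r, r0, eps)
    ifelse(r >= 2 * r0, 0,
           go_contact_energy(r, r0, eps) - go_contact_energy(2 * r0, r0, eps))
  expect_equal(e_full - e_weak, sum(well(r, u$r0, u$epsilon)), tolerance = 1e-8)
})

test_that("the calibration scan brackets the survival threshold", {
  # a clean two-body probe: one protein bead bound to one nucleotide through a
  # single contact well; shallow wells lose the contact within the probe run,
  # deep wells keep it, so the scan's survival curve crosses the 50% criterion
  # inside the candidate range
  beads <- data.frame(bead_id = 1:3, chain_id = c("A", "T", "T"),
                      residue_index = c(1, 1, 1), kind = c("CA", "S", "B"),
                      identity = c("A", "A", "A"), stringsAsFactors = FALSE)
  X <- rbind(c(0, 0, 0), c(5, 0, 0), c(7, 0, 0))
  top <- cg_topology(beads, X, data.frame(chain_id = c("A", "T"),
                                          role = c("protein", "template"),
                                          stringsAsFactors = FALSE))
  top <- derive_bonded_terms(top)
  cs <- build_contact_sets(oc = data.frame(bead_i = 1, bead_j = 2, r0 = 5))
  sys <- list(topology = top, contacts = cs, refset = list(coords = list(oc = X)))
  probes <- list(calibration_probe("oc", 1L, "maintained"))
  cands <- c(0.1, 0.5, 1.5, 3, 6)
  cal <- calibrate_epsilon(sys, candidates = cands, probes = probes,
                           seeds = 1:3, n_steps = 20000, save_interval = 200)
  rep <- cal$report
  # deepest well binds, shallowest does not: the threshold is bracketed
  expect_lt(rep$survival[1], 0.5)
  expect_gte(rep$survival[nrow(rep)], 0.5)
  # returned value is the smallest candidate whose probe passed
  expect_equal(cal$eps_go, min(rep$eps[rep$ok]))
  # survival grows with well depth (Monte-Carlo averaged)
  expect_true(all(diff(rep$survival) >= -0.1))
  expect_gt(cor(rep$eps, rep$survival), 0.8)

  # an enormous well depth cannot satisfy a loss-requiring probe
  probes_bad <- list(calibration_probe("oc", 1L, "lost"))
  expect_error(calibrate_epsilon(sys, candidates = 60, probes = probes_bad,
                                 seeds = 1, n_steps = 5000,
                                 save_interval = 200),
               "calibration failure")
})

test_that("charge-flip mutations delete the residue's DNA contacts", {
  toy <- toy_system()
  mut <- apply_charge_flip(toy$topology, toy$contacts, toy$groups$ewing_beads)
  expect_true(all(mut$topology$beads$identity[toy$groups$ewing_beads] == "E"))
  expect_equal(bead_charges(mut$topology)[toy$groups$ewing_beads],
               rep(-1, length(toy$groups$ewing_beads)))
  expect_false(any(mut$contacts$union_set$bead_i %in% toy$groups$ewing_beads))
  expect_lt(nrow(mut$contacts$union_set), nrow(toy$contacts$union_set))
})

test_that("contact sets round-trip through the TSV sidecar", {
  toy <- toy_system()
  cs <- weaken_contacts(toy$contacts, toy$groups$ewing, 0.5)
  f <- tempfile(fileext = ".tsv")
  write_contact_sets(cs, f)
  back <- read_contact_sets(f)
  expect_equal(length(back$cc_specific), length(cs$cc_specific))
  expect_equal(length(back$itc_unique), length(cs$itc_unique))
  key <- function(x) paste(x$union_set$bead_i, x$union_set$bead_j)
  m <- match(key(cs), key(back))
  expect_equal(back$union_set$epsilon[m], cs$union_set$epsilon,
               tolerance = 1e-10)
  expect_equal(back$union_set$r0[m], cs$union_set$r0, tolerance = 1e-10)
})

test_that("toy fixtures write a CG-PDB per state plus the contact table", {
  toy <- toy_system()
  pre <- tempfile("toy")
  paths <- write_toy_pic(toy, pre)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  back <- read_cg_pdb(paste0(pre, "_itc.pdb"))
  expect_equal(nrow(back$beads), nrow(toy$topology$beads))
  expect_equal(back$coords, round(unname(toy$refset$coords$itc), 3))
})
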