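test_that("identical seeds give bit-identical trajectories", {
  d <- small_duplex()
  cfg <- sim_config(n_steps = 2000, seed = 42, save_interval = 100)
  t1 <- run_langevin(d$coords, d, NULL, energy_params(), cfg)
  t2 <- run_langevin(d$coords, d, NULL, energy_params(), cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  t3 <- run_langevin(d$coords, d, NULL, energy_params(),
                     sim_config(n_steps = 2000, seed = 43, save_interval = 100))
  expect_false(identical(t1$final_coords, t3$final_coords))
})

test_that("frame bookkeeping matches the save interval", {
  d <- small_duplex()
  tr <- run_langevin(d$coords, d, NULL, energy_params(),
                     sim_config(n_steps = 1000, seed = 1, save_interval = 300))
  expect_equal(dim(tr$frames)[1], floor(1000 / 300) + 1)
  expect_equal(tr$steps, c(0, 300, 600, 900))
  expect_true(all(is.finite(as.matrix(tr$energies))))
})

test_that("a minimum-energy structure at 0 K stays put", {
  d <- small_duplex()
  tr <- run_langevin(d$coords, d, NULL, energy_params(),
                     sim_config(n_steps = 1000, seed = 1, save_interval = 500,
                                temperature = 0),
                     velocities = matrix(0, nrow(d$coords), 3))
  drift <- max(abs(tr$final_coords - d$coords))
  expect_lt(drift, 0.2)  # only the weak excluded-volume background relaxes
})

test_that("zero friction conserves energy on a two-body contact system", {
  beads <- data.frame(bead_id = 1:2, chain_id = "A", residue_index = 1:2,
                      kind = "CA", identity = c("A", "A"),
                      stringsAsFactors = FALSE)
  X <- rbind(c(0, 0, 0), c(5.5, 0, 0))
  top <- cg_topology(beads, X, data.frame(chain_id = "A", role = "protein",
                                          stringsAsFactors = FALSE))
  top$go_intra <- data.frame(i = 1, j = 2, r0 = 5.0)
  v0 <- rbind(c(0.02, 0, 0), c(-0.02, 0, 0))
  tr <- run_langevin(X, top, NULL, energy_params(),
                     sim_config(n_steps = 20000, timestep = 0.05, friction = 0,
                                seed = 1, save_interval = 100),
                     velocities = v0)
  e <- tr$energies$total
  expect_lt(max(e) - min(e), 1e-4 * max(abs(e)) + 1e-4)
})

test_that("a constant annealing schedule degenerates to a plain run", {
  d <- small_duplex()
  tr1 <- anneal(d$coords, d, NULL, energy_params(),
                schedule = rbind(c(0, 300), c(2000, 300)),
                seed = 9, save_interval = 200)
  tr2 <- run_langevin(d$coords, d, NULL, energy_params(),
                      sim_config(n_steps = 2000, temperature = 300, seed = 9,
                                 save_interval = 200))
  expect_identical(tr1$frames, tr2$frames)
})

test_that("quenching reduces fluctuations and drains velocities", {
  d <- small_duplex()
  # equilibrate, quench to 1 K, then hold: the low-temperature segment
  # fluctuates less than the hot segment
  tr <- anneal(d$coords, d, NULL, energy_params(),
               schedule = rbind(c(0, 300), c(10000, 300), c(20000, 1)),
               n_steps = 30000, seed = 2, save_interval = 200)
  rmsf_seg <- function(frames) {
    mu <- apply(frames, c(2, 3), mean)
    mean(sqrt(apply(sweep(frames, c(2, 3), mu)^2, 1, mean)))
  }
  hot <- tr$frames[10:50, , ]
  cold <- tr$frames[110:151, , ]
  expect_lt(rmsf_seg(cold), rmsf_seg(hot) / 2)

  tr0 <- anneal(d$coords, d, NULL, energy_params(),
                schedule = rbind(c(0, 300), c(5000, 0)), n_steps = 8000,
                seed = 3, save_interval = 500)
  expect_lt(max(abs(tr0$final_velocities)), 0.02)
})

test_that("temperature estimates track the schedule", {
  d <- small_duplex()
  kB <- 0.0019872041
  ndof <- 3 * nrow(d$beads)
  tr <- run_langevin(d$coords, d, NULL, energy_params(),
                     sim_config(n_steps = 30000, timestep = 0.05, seed = 4,
                                save_interval = 100, temperature = 300))
  t_est <- mean(tail(tr$energies$kinetic, 200)) * 2 / (ndof * kB)
  expect_equal(t_est, 300, tolerance = 0.05)
})

test_that("mismatch introduction and revert are exact inverses", {
  toy <- toy_system()
  top <- toy$topology
  top_m <- apply_mismatch(top)
  expect_equal(sum(!top_m$wc_pairs$enabled), 15)
  # non-template window bases equal the opposing template base (never WC)
  mm <- top_m$mismatch
  tpl_b <- top_m$beads$identity[top_m$wc_pairs$i[mm$wc_rows]]
  nt_b <- top_m$beads$identity[top_m$wc_pairs$j[mm$wc_rows]]
  expect_true(all(tpl_b == nt_b))
  # coordinates untouched
  expect_identical(top_m$coords, top$coords)
  # revert restores everything
  top_r <- revert_mismatch(top_m)
  expect_identical(top_r$beads, top$beads)
  expect_identical(top_r$wc_pairs, top$wc_pairs)
  expect_null(top_r$mismatch)
  # revert without mismatch warns, identity
  expect_warning(top_r2 <- revert_mismatch(top_r), "no mismatch")
  expect_identical(top_r2$beads, top_r$beads)
  # double application refused; empty region refused
  expect_error(apply_mismatch(top_m), "already active")
  expect_error(apply_mismatch(top, region = c(900, 950)), "outside")
  # explicit mismatch strings must be non-complementary: offering the true
  # Watson-Crick complement of the window is rejected
  ps <- top$promoter
  tidx <- tss_interval_index(ps, ps$mismatch_region)
  wc_str <- paste(vapply(strsplit(ps$template, "")[[1]][tidx],
                         cgpic:::complement_base, ""), collapse = "")
  expect_error(apply_mismatch(top, mismatch_bases = wc_str), "complementary")
})

test_that("an explicit mismatch string is respected", {
  toy <- toy_system()
  ps <- toy$topology$promoter
  tidx <- tss_interval_index(ps, ps$mismatch_region)
  tpl <- strsplit(ps$template, "")[[1]][tidx]
  # same-as-template is one valid explicit choice
  top_m <- apply_mismatch(toy$topology, mismatch_bases = paste(tpl, collapse = ""))
  expect_equal(sum(!top_m$wc_pairs$enabled), 15)
})

test_that("diverging runs report the failing step", {
  d <- small_duplex()
  X <- d$coords
  X[5, ] <- X[6, ] + 0.01  # deep overlap with huge bonded strain
  expect_error(
    run_langevin(X, d, NULL, energy_params(),
                 sim_config(n_steps = 5000, timestep = 5, seed = 1,
                            save_interval = 100)),
    "divergence at step")
})
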