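test_that("bubble size counts pairs beyond the threshold", {
  d <- small_duplex()
  expect_equal(bubble_size(d$coords, d), 0)
  # displace k pairs to 10 A -> exactly k
  for (k in c(1, 3, 7)) {
    X <- d$coords
    rows <- seq_len(k)
    for (r in rows) {
      i <- d$wc_pairs$i[r]; j <- d$wc_pairs$j[r]
      u <- (X[j, ] - X[i, ]); u <- u / sqrt(sum(u^2))
      X[j, ] <- X[i, ] + 10 * u
    }
    expect_equal(bubble_size(X, d), k)
  }
})

test_that("bubble size is monotone under pair-distance increases", {
  d <- small_duplex()
  X <- d$coords
  sizes <- integer(0)
  for (step in 1:6) {
    r <- sample(nrow(d$wc_pairs), 1)
    j <- d$wc_pairs$j[r]; i <- d$wc_pairs$i[r]
    u <- (X[j, ] - X[i, ]); u <- u / sqrt(sum(u^2))
    X[j, ] <- X[j, ] + runif(1, 0.5, 3) * u   # only ever increases distances
    sizes <- c(sizes, bubble_size(X, d))
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("threshold calibration inverts a known distance distribution", {
  d <- small_duplex()
  # build a fake trajectory whose pair distances are draws from a known set
  set.seed(31)
  nf <- 60
  frames <- array(0, c(nf, nrow(d$coords), 3))
  draws <- matrix(rexp(nf * nrow(d$wc_pairs), rate = 0.5) + 4,
                  nf, nrow(d$wc_pairs))
  for (f in seq_len(nf)) {
    X <- d$coords
    for (r in seq_len(nrow(d$wc_pairs))) {
      i <- d$wc_pairs$i[r]; j <- d$wc_pairs$j[r]
      u <- (X[j, ] - X[i, ]); u <- u / sqrt(sum(u^2))
      X[j, ] <- X[i, ] + draws[f, r] * u
    }
    frames[f, , ] <- X
  }
  fake <- structure(list(frames = frames, topology = d,
                         steps = seq_len(nf)), class = "cg_trajectory")
  grid <- seq(4, 12, by = 0.1)
  target <- 0.05
  th <- calibrate_break_threshold(fake, target_rate = target, grid = grid,
                                  burn_in = 0)
  # oracle: smallest grid value with empirical exceed-rate <= target
  rates <- vapply(grid, function(g) mean(draws > g), 1.0)
  expect_equal(as.numeric(th), grid[which(rates <= target)[1]])
  # feeding the threshold back reproduces a rate at or below target
  expect_lte(attr(th, "rate"), target)
  # a 100% target returns the grid minimum
  expect_equal(as.numeric(calibrate_break_threshold(fake, 1, grid, burn_in = 0)),
               grid[1])
  expect_error(calibrate_break_threshold(fake, target_rate = -1, grid = grid,
                                         burn_in = 0), "calibration failure")
})

test_that("contact fractions follow the formation criterion", {
  cs <- data.frame(bead_i = 1:4, bead_j = 5:8, r0 = 5)
  X <- matrix(0, 8, 3)
  X[5:8, 1] <- c(5, 5, 15, 15)    # two at r0, two at 3*r0
  expect_equal(contact_fraction(X, cs), 0.5)
  X[5:8, 1] <- 1000
  expect_equal(contact_fraction(X, cs), 0)
  expect_error(contact_fraction(X, cs[0, ]), "empty")
  toy <- toy_system()
  expect_equal(contact_fraction(toy$refset$coords$itc, toy$contacts,
                                toy$contacts$itc_unique), 1.0)
})

test_that("state labels follow the fraction cutoffs", {
  f <- data.frame(f_cc = c(0.9, 0.1, 0.05, 0, 0.02, 0, 0),
                  f_oc = c(0.05, 0.4, 0.85, 0.2, 0.3, 0.1, 0),
                  f_itc = c(0, 0.05, 0.1, 0.9, 0.4, 0.5, 0))
  lab <- assign_state(f, ewing_formed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                                          TRUE))
  expect_equal(as.character(lab),
               c("CC", "pre-OC", "OC", "ITC", "I1", "I2", "unassigned"))
})

test_that("a staged CC -> pre-OC -> OC fixture labels monotonically", {
  stages <- data.frame(
    f_cc = c(0.95, 0.9, 0.7, 0.25, 0.1, 0.05, 0.02),
    f_oc = c(0.0, 0.05, 0.1, 0.35, 0.5, 0.75, 0.9),
    f_itc = 0)
  lab <- assign_state(stages)
  ord <- c(CC = 1, `pre-OC` = 2, OC = 3)
  seen <- ord[as.character(lab[lab != "unassigned"])]
  expect_true(all(diff(seen) >= 0))  # no backward skips
  expect_equal(as.character(lab[1]), "CC")
  expect_equal(as.character(lab[length(lab)]), "OC")
})

test_that("gate distance is the Euclidean distance of group centroids", {
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(10, 0, 0), c(12, 0, 0))
  expect_equal(gate_distance(X, list(1:2, 3:4)), 10)
  expect_equal(gate_distance(X, list(1, 1)), 0)
  expect_equal(gate_distance(X, list(2, 3)), 8)
  expect_error(gate_distance(X, list(integer(0), 1)), "non-empty")
  expect_error(gate_distance(X, list(1, 99)), "missing beads")
})

test_that("the moving average is centered with truncated edges", {
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  r <- 0:10
  ma <- moving_average(r, 3)
  expect_equal(ma[2:10], r[2:10])          # interior of a ramp is unchanged
  expect_equal(ma[1], mean(r[1:2]))        # truncated edge window
  expect_error(moving_average(r, 4), "odd")
  expect_error(moving_average(r, 13), "longer")
})

test_that("Kabsch RMSD agrees with an independent superposition", {
  set.seed(8)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_equal(kabsch_rmsd(A, A), 0)
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_lt(kabsch_rmsd(A, A %*% R + 3), 1e-8)
  # against bio3d as an independent oracle on random pairs
  for (sd in 1:3) {
    set.seed(sd)
    B <- A + matrix(rnorm(60, sd = 0.8), 20, 3)
    ours <- kabsch_rmsd(A, B)
    fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(A)), as.vector(t(B))))
    ref <- sqrt(mean(colSums(matrix((as.vector(t(A)) - fit)^2, nrow = 3))))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
  # one displaced bead contributes ~ d/sqrt(N)
  N <- 400
  set.seed(9)
  A2 <- matrix(rnorm(N * 3, sd = 20), N, 3)
  B2 <- A2; B2[1, ] <- B2[1, ] + c(6, 0, 0)
  expect_equal(kabsch_rmsd(A2, B2), 6 / sqrt(N), tolerance = 0.05)
  expect_error(kabsch_rmsd(A2[1:5, ], B2[1:4, ]), "differ")
})

test_that("state traces combine fractions, flags and gate distances", {
  toy <- toy_system()
  tr <- run_langevin(toy$refset$coords$itc, toy$topology, toy$contacts,
                     energy_params(),
                     sim_config(n_steps = 3000, seed = 2, save_interval = 500))
  st <- state_trace(tr, toy$contacts, toy$groups)
  expect_true(all(st$f_itc >= 0 & st$f_itc <= 1))
  expect_true(all(as.character(st$label) %in%
                    c("CC", "pre-OC", "OC", "I1", "I2", "ITC", "unassigned")))
  expect_true(all(is.finite(st$gate)))
  expect_equal(as.character(st$label[1]), "ITC")
})

test_that("state traces export to TSV with bubble column", {
  toy <- toy_system()
  tr <- run_langevin(toy$refset$coords$cc, toy$topology, toy$contacts,
                     energy_params(),
                     sim_config(n_steps = 1000, seed = 3, save_interval = 500))
  st <- state_trace(tr, toy$contacts, toy$groups)
  bt <- bubble_trace(tr)
  f <- tempfile(fileext = ".tsv")
  write_state_trace_tsv(st, f, bubble = bt)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(st))
  expect_equal(back$bubble, bt$bubble)
  expect_equal(back$f_cc, st$f_cc, tolerance = 1e-10)
})
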