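# Langevin dynamics driver and the run protocols that manipulate the duplex
# sequence: mismatch introduction (pre-melting) and sequence revert.

#' Simulation configuration
#'
#' @param n_steps Number of integrator steps.
#' @param timestep Integration step, reduced time units. Default 0.2.
#' @param friction Langevin friction, 1/time. Default 0.25. Zero gives
#'   microcanonical (velocity-Verlet) propagation.
#' @param temperature Thermostat temperature, K (ignored if `anneal_schedule`
#'   given).
#' @param seed Integer seed; trajectories are bit-reproducible per seed.
#' @param save_interval Steps between saved frames.
#' @param anneal_schedule Optional matrix/data frame `(step, temperature)`,
#'   step-ordered, temperatures >= 0; piecewise-linear in between, constant
#'   after the last knot.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 10000, timestep = 0.2, friction = 0.25,
                       temperature = 300, seed = 1, save_interval = 100,
                       anneal_schedule = NULL) {
  stopifnot(timestep > 0, n_steps >= 0, friction >= 0, save_interval >= 1)
  if (!is.null(anneal_schedule)) {
    anneal_schedule <- as.matrix(anneal_schedule)
    stopifnot(ncol(anneal_schedule) == 2, all(anneal_schedule[, 2] >= 0),
              !is.unsorted(anneal_schedule[, 1]))
  } else {
    stopifnot(temperature >= 0)
  }
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 seed = as.integer(seed),
                 save_interval = as.integer(save_interval),
                 anneal_schedule = anneal_schedule), class = "sim_config")
}

#' Run Langevin dynamics
#'
#' Propagates the system with a BAOAB-splitting Langevin integrator. The
#' trajectory is bit-reproducible for a given seed. Initial velocities are
#' drawn from the Maxwell-Boltzmann distribution at the starting temperature
#' unless supplied.
#'
#' @param coords Starting `n x 3` coordinates, Angstrom.
#' @param topology A `cg_topology`.
#' @param contacts Optional [contact_sets()].
#' @param params An [energy_params()].
#' @param config A [sim_config()].
#' @param velocities Optional starting velocities (`n x 3`).
#' @return Object of class `cg_trajectory`: `frames` (array
#'   `n_frames x n x 3`), `energies` (data frame, one row per frame),
#'   `steps`, `final_coords`, `final_velocities`, `config`, `topology`.
#' @export
run_langevin <- function(coords, topology, contacts = NULL,
                         params = energy_params(), config = sim_config(),
                         velocities = NULL) {
  sys <- build_system(topology, contacts, params)
  sched <- config$anneal_schedule %||%
    matrix(c(0, config$temperature), 1, 2)
  out <- .cpp_run_langevin(as.matrix(coords), sys, config$n_steps,
                           config$timestep, config$friction,
                           as.matrix(sched), config$seed,
                           config$save_interval, velocities)
  structure(list(frames = out$frames,
                 energies = as.data.frame(out$energies),
                 steps = out$steps,
                 final_coords = out$final_coords,
                 final_velocities = out$final_velocities,
                 config = config, topology = topology), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory: ", dim(x$frames)[1], " frames x ", dim(x$frames)[2],
      " beads; ", x$config$n_steps, " steps (seed ", x$config$seed, ")\n",
      sep = "")
  e <- x$energies$total
  cat("  total energy: start ", round(e[1], 2), ", end ",
      round(e[length(e)], 2), " kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
plot.cg_trajectory <- function(x, term = "total", ...) {
  plot(x$steps, x$energies[[term]], type = "l", xlab = "MD step",
       ylab = paste(term, "energy (kcal/mol)"), ...)
  invisible(x)
}

#' Annealing run
#'
#' Convenience wrapper over [run_langevin()] with a temperature schedule, e.g.
#' a quench from 300 K to 1 K followed by a low-temperature segment to obtain
#' a low-fluctuation structure suitable for export.
#'
#' @inheritParams run_langevin
#' @param schedule Matrix/data frame `(step, temperature)`.
#' @param n_steps Total steps (default: last schedule step).
#' @param ... Passed to [sim_config()].
#' @return A `cg_trajectory`.
#' @export
anneal <- function(coords, topology, contacts = NULL, params = energy_params(),
                   schedule, n_steps = NULL, ...) {
  schedule <- as.matrix(schedule)
  n_steps <- n_steps %||% schedule[nrow(schedule), 1]
  run_langevin(coords, topology, contacts, params,
               sim_config(n_steps = n_steps, anneal_schedule = schedule, ...))
}

#' Introduce a sequence mismatch (disable pairing in a window)
#'
#' Replaces each non-template base in the window with the identity of the
#' opposing template base (guaranteeing non-complementarity) and flags the
#' window's Watson-Crick pairs as non-pairing, so their pairing wells
#' contribute nothing. Coordinates are untouched; melting must occur
#' dynamically. The original identities are stored so [revert_mismatch()]
#' restores the topology exactly.
#'
#' @param topology A `cg_topology` with an attached promoter sequence.
#' @param region Half-open TSS-relative interval `c(start, end)`; default the
#'   promoter's recorded `mismatch_region`.
#' @param mismatch_bases Optional explicit replacement string for the window's
#'   non-template bases (5'->3' along the template window).
#' @return Modified topology (class unchanged).
#' @export
apply_mismatch <- function(topology, region = NULL, mismatch_bases = NULL) {
  ps <- topology$promoter
  if (is.null(ps)) stop("topology carries no promoter sequence")
  region <- region %||% ps$mismatch_region
  if (is.null(region)) stop("no mismatch region given or recorded")
  tidx <- tss_interval_index(ps, region)
  if (!length(tidx)) stop("mismatch region outside the promoter")
  if (!is.null(topology$mismatch))
    stop("a mismatch is already active; revert first")
  bd <- topology$beads
  L <- nchar(ps$template)
  tb <- strsplit(ps$template, "")[[1]]
  nt_res <- L + 1 - tidx
  new_base <- if (!is.null(mismatch_bases)) {
    mb <- strsplit(toupper(mismatch_bases), "")[[1]]
    if (length(mb) != length(tidx))
      stop("mismatch_bases length must equal the window size")
    comp <- mb == vapply(tb[tidx], complement_base, "")
    if (any(comp))
      stop("mismatch_bases complementary to the template at window offsets: ",
           paste(which(comp), collapse = ", "))
    mb
  } else tb[tidx]  # same-as-template rule: never complementary

  wc_rows <- which(topology$wc_pairs$i %in%
                     bd$bead_id[bd$residue_index %in% tidx & bd$kind == "B" &
                                  .role_of(topology, bd$chain_id) == "template"])
  nt_beads <- which(.role_of(topology, bd$chain_id) == "non_template" &
                      bd$residue_index %in% nt_res)
  old_ident <- bd$identity[nt_beads]
  ord <- match(bd$residue_index[nt_beads], nt_res)
  topology$beads$identity[nt_beads] <- new_base[ord]
  topology$wc_pairs$enabled[wc_rows] <- FALSE
  topology$mismatch <- list(region = region, wc_rows = wc_rows,
                            nt_beads = nt_beads, old_identity = old_ident)
  ps$mismatch_region <- region
  topology$promoter <- ps
  topology
}

.role_of <- function(topology, chain_ids) {
  setNames(topology$chain_table$role, topology$chain_table$chain_id)[chain_ids]
}

#' Revert a mismatch to the native sequence
#'
#' Restores the original non-template base identities and re-enables the
#' pairing wells at all window positions. Coordinates are untouched:
#' re-pairing of a melted window happens dynamically in the subsequent run.
#' Idempotent; warns when no mismatch is active.
#'
#' @param topology A `cg_topology`.
#' @return The restored topology.
#' @export
revert_mismatch <- function(topology) {
  mm <- topology$mismatch
  if (is.null(mm)) {
    warning("no mismatch present; topology returned unchanged")
    return(topology)
  }
  topology$beads$identity[mm$nt_beads] <- mm$old_identity
  topology$wc_pairs$enabled[mm$wc_rows] <- TRUE
  topology$mismatch <- NULL
  topology
}

#' Restrain a bead group at its native position
#'
#' Pins a group (e.g. the gate loop) to its native conformation by adding
#' stiff harmonic bonds from each group bead to its `n_anchors` nearest
#' non-group protein beads, with native rest lengths. Used to hold the gate
#' loop shut in control simulations.
#'
#' @param topology A `cg_topology`.
#' @param beads Bead ids to restrain.
#' @param k Force constant, kcal/mol/A^2.
#' @param n_anchors Anchor bonds per restrained bead.
#' @return Topology with the extra bonds appended (column `k` marks
#'   per-bond force constants).
#' @export
restrain_group <- function(topology, beads, k = 50, n_anchors = 3) {
  bd <- topology$beads; X <- topology$coords
  prot <- which(bd$kind == "CA" & !(seq_len(nrow(bd)) %in% beads))
  extra <- list()
  for (b in beads) {
    d <- sqrt(colSums((t(X[prot, , drop = FALSE]) - X[b, ])^2))
    near <- prot[order(d)[seq_len(n_anchors)]]
    for (a in near)
      extra[[length(extra) + 1L]] <-
        data.frame(i = b, j = a, r0 = sqrt(sum((X[b, ] - X[a, ])^2)),
                   term = 0L, k = k)
  }
  bonds <- topology$bonds
  if (!"k" %in% names(bonds)) bonds$k <- NA_real_
  topology$bonds <- rbind(bonds, do.call(rbind, extra))
  topology
}

#' Export trajectory coordinates and energies as TSV
#'
#' Writes `<prefix>_energies.tsv` (per-frame energy breakdown) and, when
#' `coords = TRUE`, `<prefix>_frames.tsv` (long format: frame, bead, x, y, z).
#'
#' @param trajectory A `cg_trajectory`.
#' @param prefix Output path prefix.
#' @param coords Also write coordinates (default `FALSE`; can be large).
#' @return Invisibly, the paths written.
#' @export
write_trajectory_tsv <- function(trajectory, prefix, coords = FALSE) {
  ep <- paste0(prefix, "_energies.tsv")
  df <- cbind(step = trajectory$steps, trajectory$energies)
  write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- ep
  if (coords) {
    fp <- paste0(prefix, "_frames.tsv")
    fr <- trajectory$frames
    nf <- dim(fr)[1]; nb <- dim(fr)[2]
    long <- data.frame(frame = rep(seq_len(nf), each = nb),
                       bead = rep(seq_len(nb), nf),
                       x = as.vector(t(fr[, , 1])),
                       y = as.vector(t(fr[, , 2])),
                       z = as.vector(t(fr[, , 3])))
    write.table(long, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
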