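# Force-field constants, closed-form energy functions, and the packing of a
# cg_topology (+ contact sets) into the flat arrays the C++ kernel consumes.

#' Force-field parameters for the coarse-grained model
#'
#' All constants of the energy function in one validated object. Defaults are
#' the model's study conditions: protein-DNA contact wells of 1.2 kcal/mol,
#' 200 mM monovalent salt, 300 K. The Watson-Crick well depth `eps_bp` (the
#' G:C value; A:T wells are scaled by `at_gc_ratio`) is the single calibration
#' knob of the DNA model: its default was fixed with
#' [calibrate_pairing_strength()] so that a free 20-bp duplex at the default
#' solvent condition shows a per-pair base-pair opening rate of 0.3% under the
#' 6.2 Angstrom criterion.
#'
#' @param eps_go Protein-DNA native-contact well depth, kcal/mol.
#' @param salt Monovalent salt concentration, mM.
#' @param temperature Reference temperature, K.
#' @param dielectric Relative permittivity of the solvent.
#' @param dh_cutoff Electrostatics cutoff, Angstrom; default 3.5 Debye lengths
#'   (must be at least 3).
#' @param eps_bp G:C Watson-Crick well depth, kcal/mol (calibrated).
#' @param at_gc_ratio A:T/G:C well-depth ratio (two vs three hydrogen bonds).
#' @param bp_angle_width Width (rad) of the Gaussian orientation factor on the
#'   pairing well.
#' @param eps_stack Nearest-neighbour stacking well depth, kcal/mol.
#' @param eps_go_intra Intra-protein native-contact well depth, kcal/mol.
#' @param k_bond,k_angle,k_dih1,k_dih3 Bonded force constants
#'   (kcal/mol/A^2, kcal/mol/rad^2, kcal/mol, kcal/mol).
#' @param ev_eps Excluded-volume prefactor, kcal/mol.
#' @param ev_radii Named per-kind excluded-volume radii, Angstrom.
#' @param phosphate_charge Phosphate bead charge, e.
#' @return Object of class `energy_params`.
#' @export
energy_params <- function(eps_go = 1.2, salt = 200, temperature = 300,
                          dielectric = 78, dh_cutoff = NULL,
                          eps_bp = 9.25, at_gc_ratio = 2 / 3,
                          bp_angle_width = 0.35, eps_stack = 1.2,
                          eps_go_intra = 0.6,
                          k_bond = 100, k_angle = 20, k_dih1 = 1.0, k_dih3 = 0.5,
                          ev_eps = 0.2,
                          ev_radii = c(CA = 2.0, P = 2.0, S = 2.0, B = 1.5),
                          phosphate_charge = -0.6) {
  lam <- debye_length(salt, temperature, dielectric)
  if (is.null(dh_cutoff)) dh_cutoff <- 3.5 * lam
  if (dh_cutoff < 3 * lam)
    stop("dh_cutoff must be at least 3 Debye lengths (", round(3 * lam, 2), " A)")
  p <- list(eps_go = eps_go, salt = salt, temperature = temperature,
            dielectric = dielectric, dh_cutoff = dh_cutoff,
            debye_length = lam, eps_bp = eps_bp, at_gc_ratio = at_gc_ratio,
            bp_angle_width = bp_angle_width, eps_stack = eps_stack,
            eps_go_intra = eps_go_intra, k_bond = k_bond, k_angle = k_angle,
            k_dih1 = k_dih1, k_dih3 = k_dih3, ev_eps = ev_eps,
            ev_radii = ev_radii, phosphate_charge = phosphate_charge)
  num <- unlist(p[c("eps_go", "salt", "temperature", "dielectric", "dh_cutoff",
                    "eps_bp", "eps_stack", "k_bond", "k_angle", "ev_eps")])
  if (any(num <= 0)) stop("energy parameters must be positive")
  structure(p, class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("energy_params: eps_go ", x$eps_go, " kcal/mol, eps_bp(GC) ", x$eps_bp,
      " kcal/mol, salt ", x$salt, " mM, T ", x$temperature,
      " K, Debye length ", round(x$debye_length, 2), " A\n", sep = "")
  invisible(x)
}

#' Debye screening length
#'
#' \eqn{\lambda_D \approx 3.04 \sqrt{\epsilon_r T / (78.5 \cdot 298)} / \sqrt{I}}
#' Angstrom with the ionic strength \eqn{I} in mol/L; about 6.8 A at 200 mM,
#' 300 K, relative permittivity 78.
#'
#' @param salt Monovalent salt, mM.
#' @param temperature K.
#' @param dielectric Relative permittivity.
#' @return Length in Angstrom.
#' @export
debye_length <- function(salt, temperature = 300, dielectric = 78) {
  I <- salt / 1000
  3.04 * sqrt(dielectric * temperature / (78.5 * 298)) / sqrt(I)
}

#' Structure-based 12-10 contact energy
#'
#' \eqn{E(r) = \epsilon [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]}: minimum of depth
#' \eqn{-\epsilon} at \eqn{r = r_0}, zero crossing at
#' \eqn{r = r_0\sqrt{5/6}}, zero at infinity. Below \eqn{0.3 r_0} the energy
#' continues linearly so it stays finite as \eqn{r \to 0} (overflow guard,
#' matching the simulation kernel).
#'
#' @param r Distance(s), Angstrom.
#' @param r0 Native distance, Angstrom.
#' @param eps Well depth, kcal/mol.
#' @return Energy, kcal/mol (vectorized over `r`).
#' @export
go_contact_energy <- function(r, r0, eps) {
  stopifnot(all(r > 0), r0 > 0, eps > 0)
  rmin <- 0.3 * r0
  e110 <- function(rr) {
    x <- r0 / rr
    eps * (5 * x^12 - 6 * x^10)
  }
  slope0 <- {
    x <- r0 / rmin
    60 * eps * x^10 * (1 - x^2) / rmin
  }
  ifelse(r < rmin, e110(rmin) + slope0 * (r - rmin), e110(r))
}

#' Debye-Hueckel screened electrostatic energy
#'
#' \eqn{E(r) = 332.0637\, q_1 q_2 \exp(-r/\lambda_D) / (\epsilon_r r)}
#' kcal/mol, truncated at `params$dh_cutoff` and shifted to continuity there.
#'
#' @param r Distance(s), Angstrom.
#' @param q1,q2 Charges, elementary units.
#' @param params An [energy_params()] object.
#' @return Energy, kcal/mol (vectorized over `r`).
#' @export
debye_huckel_energy <- function(r, q1, q2, params = energy_params()) {
  stopifnot(all(r > 0))
  if (q1 == 0 || q2 == 0) return(rep(0, length(r)))
  pref <- 332.0637 * q1 * q2 / params$dielectric
  lam <- params$debye_length
  rc <- params$dh_cutoff
  e <- pref * exp(-r / lam) / r - pref * exp(-rc / lam) / rc
  ifelse(r >= rc, 0, e)
}

# ---- system packing ---------------------------------------------------------

.empty_mat <- function(nc) matrix(numeric(0), ncol = nc)

#' Pack a topology and contact sets into the simulation kernel's system form
#'
#' Applies force constants and well depths from `params` to the topology's
#' native tables, computes per-bead charges/masses/radii, and returns the flat
#' list the C++ kernel consumes. Called internally by [total_energy_forces()]
#' and [run_langevin()]; exposed for advanced use.
#'
#' @param topology A `cg_topology` with bonded tables filled.
#' @param contacts Optional [contact_sets()] supplying protein-DNA wells.
#' @param params An [energy_params()].
#' @return A plain list (`n`, `bonds`, `angles`, `dihedrals`, `pairs`, `wc`,
#'   `charge`, `ev_radius`, `mass`, ...).
#' @export
build_system <- function(topology, contacts = NULL, params = energy_params()) {
  top <- topology
  n <- nrow(top$beads)
  bm <- if (is.null(top$bonds) || !nrow(top$bonds)) .empty_mat(5) else {
    kb <- if ("k" %in% names(top$bonds))
      ifelse(is.na(top$bonds$k), params$k_bond, top$bonds$k) else params$k_bond
    cbind(top$bonds$i, top$bonds$j, top$bonds$r0, kb, top$bonds$term)
  }
  am <- if (is.null(top$angles) || !nrow(top$angles)) .empty_mat(6) else
    cbind(top$angles$i, top$angles$j, top$angles$k, top$angles$th0,
          params$k_angle, top$angles$term)
  dm <- if (is.null(top$dihedrals) || !nrow(top$dihedrals)) .empty_mat(8) else
    cbind(top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l,
          top$dihedrals$phi0, params$k_dih1, params$k_dih3, top$dihedrals$term)
  pr <- list()
  if (!is.null(top$stacks) && nrow(top$stacks))
    pr[[length(pr) + 1L]] <- cbind(top$stacks$i, top$stacks$j, top$stacks$r0,
                                   params$eps_stack, 2)
  if (!is.null(top$go_intra) && nrow(top$go_intra))
    pr[[length(pr) + 1L]] <- cbind(top$go_intra$i, top$go_intra$j,
                                   top$go_intra$r0, params$eps_go_intra, 4)
  if (!is.null(contacts)) {
    u <- contacts$union_set
    if (nrow(u))
      pr[[length(pr) + 1L]] <- cbind(u$bead_i, u$bead_j, u$r0, u$epsilon, 5)
  }
  pm <- if (length(pr)) do.call(rbind, pr) else .empty_mat(5)
  wm <- if (is.null(top$wc_pairs) || !nrow(top$wc_pairs)) .empty_mat(9) else {
    wc <- top$wc_pairs
    eps <- ifelse(wc$enabled,
                  params$eps_bp * ifelse(wc$pair_class == "GC", 1, params$at_gc_ratio),
                  0)
    cbind(wc$i, wc$j, wc$s_i, wc$s_j, wc$r0, eps, wc$th1_0, wc$th2_0,
          params$bp_angle_width)
  }
  list(n = n, bonds = bm, angles = am, dihedrals = dm, pairs = pm, wc = wm,
       charge = bead_charges(top, params$phosphate_charge),
       ev_radius = unname(params$ev_radii[top$beads$kind]),
       mass = bead_masses(top$beads$kind),
       ev_eps = params$ev_eps,
       dh_pref = 332.0637 / params$dielectric,
       dh_lambda = params$debye_length,
       dh_cutoff = params$dh_cutoff)
}

#' Total energy and analytic forces
#'
#' Evaluates every term of the coarse-grained energy function and its exact
#' analytic gradient at the given configuration.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param topology A `cg_topology`.
#' @param contacts Optional [contact_sets()].
#' @param params An [energy_params()].
#' @return List: `breakdown` (named per-term energies plus `total`, kcal/mol)
#'   and `forces` (`n x 3`, kcal/mol/A).
#' @export
total_energy_forces <- function(coords, topology, contacts = NULL,
                                params = energy_params()) {
  sys <- build_system(topology, contacts, params)
  out <- .cpp_energy_forces(as.matrix(coords), sys)
  list(breakdown = c(out$terms, total = out$total), forces = out$forces)
}

#' DNA-model energy terms of a configuration
#'
#' The DNA slice of the energy breakdown: backbone bonded terms, stacking and
#' Watson-Crick pairing (orientation-modulated, disabled pairs contribute 0).
#'
#' @inheritParams total_energy_forces
#' @return Named numeric: `dna_bonded`, `dna_stack`, `dna_pair`.
#' @export
dna_energy <- function(coords, topology, params = energy_params()) {
  ef <- total_energy_forces(coords, topology, contacts = NULL, params = params)
  ef$breakdown[c("dna_bonded", "dna_stack", "dna_pair")]
}

#' Read / write energy parameters as YAML
#'
#' Serializes every constant of an [energy_params()] object to a YAML file,
#' and restores a validated object from one (unknown fields are rejected;
#' missing fields take the defaults).
#'
#' @param params An [energy_params()].
#' @param path File path.
#' @return `write_energy_params()` the path, invisibly;
#'   `read_energy_params()` an [energy_params()].
#' @export
write_energy_params <- function(params, path) {
  stopifnot(inherits(params, "energy_params"))
  x <- unclass(params)
  x$debye_length <- NULL  # derived
  x$ev_radii <- as.list(x$ev_radii)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_energy_params
#' @export
read_energy_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$ev_radii)) x$ev_radii <- unlist(x$ev_radii)
  known <- names(formals(energy_params))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown parameter fields: ", paste(bad, collapse = ", "))
  do.call(energy_params, x)
}
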