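# Synthetic systems: idealized B-form duplex DNA and seeded perturbations.
# These generators define the desk-scale study conditions; every pipeline
# stage is testable on them without external structure downloads.

#' Build an idealized B-form DNA duplex
#'
#' Constructs a coarse-grained double helix with fiber-diffraction B-DNA
#' parameters (rise 3.38 A, twist 34.3 deg/bp by default). Each strand
#' contributes P/S/B beads per nucleotide with the 5'-terminal phosphate
#' absent; all Watson-Crick base-base distances are equal by construction and
#' all native bonded values are taken from the built geometry, so the built
#' configuration is the minimum of the DNA bonded energy.
#'
#' The helical axis is the z axis; base pair `t` sits at `z = (t-1) * rise`.
#'
#' @param sequence Template strand, 5'->3', A/C/G/T only.
#' @param rise Helical rise per base pair, Angstrom.
#' @param twist Helical twist per base pair, degrees.
#' @param tss_index 1-based template index taken as the +1 site (for
#'   TSS-relative annotation); default the middle of the duplex.
#' @param mismatch_region Optional TSS-relative half-open interval recorded on
#'   the attached [promoter_sequence()] (the geometry is always built paired;
#'   use [apply_mismatch()] to disable pairing).
#' @return A `cg_topology` with reference coordinates and an attached
#'   `promoter_sequence`.
#' @examples
#' dna <- build_bdna("ACGTACGTAC")
#' nrow(dna$beads)  # 10*2*3 - 2
#' @export
build_bdna <- function(sequence, rise = 3.38, twist = 34.3,
                       tss_index = NULL, mismatch_region = NULL) {
  seq_ <- toupper(sequence)
  if (!is.character(seq_) || length(seq_) != 1L || !nchar(seq_))
    stop("sequence must be a non-empty string")
  if (grepl("[^ACGT]", seq_)) stop("invalid base in sequence")
  L <- nchar(seq_)
  tb <- strsplit(seq_, "")[[1]]
  if (is.null(tss_index)) tss_index <- ceiling((L + 1) / 2)
  ps <- promoter_sequence(seq_, tss_index = tss_index,
                          mismatch_region = mismatch_region)

  tw <- twist * pi / 180
  rP <- 8.9; rS <- 6.9; rB <- 2.2
  phiS <- 0.9; phiB <- 0.3
  cyl <- function(r, th, z) c(r * cos(th), r * sin(th), z)

  beads <- list(); xyz <- list()
  add <- function(chain, resi, kind, ident, pos) {
    beads[[length(beads) + 1L]] <<- data.frame(
      chain_id = chain, residue_index = resi, kind = kind, identity = ident,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  theta <- function(t) (t - 1) * tw
  zz <- function(t) (t - 1) * rise

  for (t in seq_len(L)) {   # template, 5'->3' along +z
    if (t >= 2) add("T", t, "P", tb[t], cyl(rP, theta(t) - tw / 2 + phiS, zz(t) - rise / 2))
    add("T", t, "S", tb[t], cyl(rS, theta(t) + phiS, zz(t)))
    add("T", t, "B", tb[t], cyl(rB, theta(t) + phiB, zz(t)))
  }
  nb <- vapply(rev(tb), complement_base, "")   # non-template 5'->3'
  for (u in seq_len(L)) {
    t <- L + 1 - u
    if (u >= 2) add("N", u, "P", nb[u], cyl(rP, theta(t) + tw / 2 + pi - phiS, zz(t) + rise / 2))
    add("N", u, "S", nb[u], cyl(rS, theta(t) + pi - phiS, zz(t)))
    add("N", u, "B", nb[u], cyl(rB, theta(t) + pi - phiB, zz(t)))
  }
  bd <- do.call(rbind, beads)
  bd$bead_id <- seq_len(nrow(bd))
  bd <- bd[, c("bead_id", "chain_id", "residue_index", "kind", "identity")]
  X <- do.call(rbind, xyz)
  top <- cg_topology(bd, X,
                     chain_table = data.frame(
                       chain_id = c("T", "N"), role = c("template", "non_template"),
                       stringsAsFactors = FALSE),
                     promoter = ps)
  bid <- function(chain, resi, kind)
    bd$bead_id[bd$chain_id == chain & bd$residue_index == resi & bd$kind == kind]
  wc <- cbind(vapply(seq_len(L), function(t) bid("T", t, "B"), 1L),
              vapply(seq_len(L), function(t) bid("N", L + 1 - t, "B"), 1L))
  derive_bonded_terms(top, wc_pairs = wc)
}

#' Specification of a toy clamp + promoter system
#'
#' Describes the download-free stand-in for the pre-initiation complex used in
#' tests and desk-scale protocol runs: an idealized duplex, a clamp-shaped toy
#' protein with a gate loop across its cleft mouth, three labeled reference
#' poses of the duplex (closed-complex-like: outside the cleft; open-complex-
#' like: at the cleft mouth with the mismatch window melted; initially-
#' transcribing-like: threaded on the clamp axis past the gate loop), and
#' prescribed state-specific contact-set sizes with the subset structure the
#' analysis assumes (the CC-like set disjoint from the others, the OC-like set
#' mostly contained in the ITC-like contacts).
#'
#' @param duplex_length Duplex length, bp.
#' @param sequence Template strand or `NULL` for a seeded random sequence.
#' @param clamp_size Residue count of the toy clamp protein.
#' @param contact_sizes Named integer vector `c(cc=, oc=, itc=)` of state
#'   contact-set sizes; defaults to the three-state sizes 92/22/118.
#' @param oc_itc_overlap How many OC-like contacts are shared with the
#'   ITC-like pose (default 19 of 22).
#' @param gate_loop_size Residues in the gate loop.
#' @param mismatch_window TSS-relative half-open interval of the melted /
#'   mismatched region (default `c(-13, 3)`: 15 positions).
#' @return Object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(duplex_length = 24, sequence = NULL,
                            clamp_size = 110,
                            contact_sizes = c(cc = 92, oc = 22, itc = 118),
                            oc_itc_overlap = 19, gate_loop_size = 9,
                            mismatch_window = c(-13, 3)) {
  stopifnot(duplex_length >= 4, clamp_size >= 40,
            all(c("cc", "oc", "itc") %in% names(contact_sizes)))
  if (oc_itc_overlap > contact_sizes[["oc"]] ||
      oc_itc_overlap > contact_sizes[["itc"]])
    stop("oc_itc_overlap cannot exceed the OC or ITC set size")
  structure(list(duplex_length = as.integer(duplex_length), sequence = sequence,
                 clamp_size = as.integer(clamp_size),
                 contact_sizes = contact_sizes,
                 oc_itc_overlap = as.integer(oc_itc_overlap),
                 gate_loop_size = as.integer(gate_loop_size),
                 mismatch_window = mismatch_window),
            class = "toy_system_spec")
}

#' Perturb reference coordinates toward a labeled state
#'
#' Returns the target state's reference coordinates with isotropic Gaussian
#' noise, for ground-truth frames in state-assignment tests: at moderate noise
#' the returned configuration forms at least 90% of the target state's
#' contacts and fewer than 10% of contacts exclusive to the other states.
#'
#' @param refset A `reference_set` (e.g. from [build_toy_pic()]).
#' @param state State name present in `refset$coords`.
#' @param noise Gaussian displacement s.d. per coordinate, Angstrom.
#' @param seed Integer seed.
#' @return `n x 3` coordinate matrix.
#' @export
perturb_to_state <- function(refset, state, noise = 0.3, seed = 1) {
  if (!state %in% names(refset$coords))
    stop("unknown state: ", state, " (have ",
         paste(names(refset$coords), collapse = ", "), ")")
  X <- refset$coords[[state]]
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  X + matrix(rnorm(length(X), sd = noise), nrow(X), 3)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Seeded random sequence with balanced composition.
.random_sequence <- function(L, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
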