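# Toy pre-initiation-complex stand-in: a solenoidal clamp protein with a
# flexible gate loop across its cleft mouth, plus an ideal duplex posed in
# three labeled reference states (CC-like outside the cleft, OC-like at the
# mouth with a melted mismatch window, ITC-like threaded on the clamp axis).
# Contact sets of prescribed sizes and overlap structure are selected from the
# pose geometry so that every analysis-stage contract can be tested against
# generator ground truth.

.clamp_geometry <- function(clamp_size, gate_loop_size, seed) {
  n_body <- clamp_size - gate_loop_size
  n_layers <- 6L
  radius <- 13; z_span <- 24
  mouth_half <- 50 * pi / 180        # mouth opening: |angle| < 50 deg
  per <- rep(n_body %/% n_layers, n_layers)
  extra <- n_body %% n_layers
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  zs <- seq(-z_span / 2, z_span / 2, length.out = n_layers)
  xyz <- list(); arc_end <- logical(0); layer_of <- integer(0)
  for (l in seq_len(n_layers)) {
    a0 <- mouth_half; a1 <- 2 * pi - mouth_half
    ang <- seq(a0, a1, length.out = per[l])
    if (l %% 2 == 0) ang <- rev(ang)     # serpentine: alternate direction
    for (k in seq_along(ang)) {
      xyz[[length(xyz) + 1L]] <- c(radius * cos(ang[k]), radius * sin(ang[k]), zs[l])
      arc_end <- c(arc_end, k == 1L || k == length(ang))
      layer_of <- c(layer_of, l)
    }
  }
  # gate loop: chain terminus arcing from the upper mouth edge across the
  # mouth interior (apex near the channel axis) toward the lower mouth edge;
  # the far end is free, so the shut conformation is held by local terms only.
  A <- c(radius * cos(mouth_half), radius * sin(mouth_half), z_span / 2)
  B <- c(radius * cos(mouth_half), -radius * sin(mouth_half), -z_span / 2)
  Cc <- c(3.5, 0, 0)
  # stop the arc short of B so the free end does not overlap the ring start
  tt <- seq(0, 0.88, length.out = gate_loop_size + 1L)[-1L]
  gate <- t(vapply(tt, function(s)
    (1 - s)^2 * A + 2 * s * (1 - s) * Cc + s^2 * B, numeric(3)))
  body <- do.call(rbind, xyz)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  jit <- matrix(rnorm((nrow(body) + nrow(gate)) * 3, sd = 0.25), ncol = 3)
  coords <- rbind(body, gate) + jit
  is_gate <- c(rep(FALSE, nrow(body)), rep(TRUE, nrow(gate)))
  # open-gate conformation (used by the ITC reference pose): same Bezier with
  # the control point swung outward, clearing the channel.
  Co <- c(22, 0, 0)
  gate_open <- t(vapply(tt, function(s)
    (1 - s)^2 * A + 2 * s * (1 - s) * Co + s^2 * B, numeric(3))) +
    jit[(nrow(body) + 1L):nrow(jit), , drop = FALSE]
  # residue identities: channel-facing lysines every 4th body residue
  ident <- rep(c("A", "K", "L", "S"), length.out = nrow(body))
  ident <- c(ident, rep(c("G", "S"), length.out = nrow(gate)))
  list(coords = coords, gate_open = gate_open, is_gate = is_gate,
       identity = ident, arc_end = c(arc_end, rep(FALSE, nrow(gate))),
       layer = c(layer_of, rep(NA_integer_, nrow(gate))),
       radius = radius, mouth_half = mouth_half)
}

# Smoothly tapered radial melt of the mismatch window (OC-like pose):
# non-template beads of window residues are pushed outward along their local
# radial direction; template bases tuck slightly inward.
.melt_window <- function(coords, top, window_tidx) {
  bd <- top$beads
  L <- nchar(top$promoter$template)
  w <- sort(window_tidx)
  taper <- function(t) {
    edge <- min(t - (min(w) - 1), (max(w) + 1) - t)
    min(1, edge / 3)
  }
  X <- coords
  for (t in w) {
    f <- taper(t)
    nt_res <- L + 1 - t
    for (b in which(bd$chain_id == "N" & bd$residue_index == nt_res)) {
      r <- X[b, ]; rad <- c(abs(r[1]), r[2], 0)  # bulge away from the clamp
      n <- sqrt(sum(rad^2)); if (n < 1e-6) next
      X[b, ] <- r + (rad / n) * 4.0 * f
    }
    for (b in which(bd$chain_id == "T" & bd$residue_index == t & bd$kind == "B")) {
      r <- X[b, ]; rad <- c(r[1], r[2], 0)
      n <- sqrt(sum(rad^2)); if (n < 1e-6) next
      X[b, ] <- r - (rad / n) * 0.8 * f
    }
  }
  X
}

#' Build the toy clamp + promoter three-state system
#'
#' Constructs the full testbed: combined clamp + duplex topology (native
#' bonded terms from the built geometry; the clamp's shut-gate conformation is
#' the protein reference, and gate-loop residues carry local terms only so the
#' gate can fluctuate open), per-state coordinates, and contact sets with
#' exactly the prescribed sizes and overlap structure. State poses displace
#' the duplex both laterally (into the cleft) and axially (toward the "active
#' site"), so that each state's specific contacts are broken in the other
#' states.
#'
#' @param spec A [toy_system_spec()].
#' @param seed Integer seed (jitter and random sequence).
#' @param pose_dx,pose_dz Named lateral/axial duplex offsets per state, Angstrom.
#' @param contact_cap Maximum native distance for a selected contact, Angstrom.
#' @param approach_n Number of ITC-unique contacts drawn from the approach
#'   band (wells reaching toward the OC pose); sets the strength of the
#'   OC -> ITC driving force.
#' @return Object of class `toy_pic`: list with `topology`, `refset`
#'   (a `reference_set` with states cc/oc/itc), `contacts` (a
#'   [contact_sets()]), `state_lists` (per-state contact data frames),
#'   `groups` (bead-index sets: `gate_loop`, `gate_anchor`, `ewing_beads`,
#'   and `ewing` = union-set row indices of the E-wing-analog contacts),
#'   `spec`, `seed`.
#' @export
build_toy_pic <- function(spec = toy_system_spec(), seed = 1,
                          pose_dx = c(cc = 16, oc = 14, itc = 0),
                          pose_dz = c(cc = 22, oc = 0, itc = -12),
                          contact_cap = 19, approach_n = 70L) {
  L <- spec$duplex_length
  seq_ <- spec$sequence %||% .random_sequence(L, seed)
  tss <- ceiling(L * 0.72)
  dna <- build_bdna(seq_, tss_index = tss, mismatch_region = spec$mismatch_window)
  ndna <- nrow(dna$beads)
  dna_local <- sweep(dna$coords, 2, c(0, 0, (L - 1) * 3.38 / 2))  # center axis

  cl <- .clamp_geometry(spec$clamp_size, spec$gate_loop_size, seed)
  np <- nrow(cl$coords)
  pb <- data.frame(bead_id = seq_len(np), chain_id = "C",
                   residue_index = seq_len(np), kind = "CA",
                   identity = cl$identity, stringsAsFactors = FALSE)
  db <- dna$beads
  db$bead_id <- db$bead_id + np
  beads <- rbind(pb, db)

  pose <- function(state, melted = FALSE) {
    X <- dna_local
    if (melted) {
      wt <- tss_interval_index(dna$promoter, spec$mismatch_window)
      X <- .melt_window(X, dna, wt)
    }
    X <- sweep(X, 2, c(-pose_dx[[state]], 0, -pose_dz[[state]]))
    prot <- if (state == "itc") {
      Xp <- cl$coords; Xp[cl$is_gate, ] <- cl$gate_open; Xp
    } else cl$coords
    rbind(prot, X)
  }
  X_cc <- pose("cc"); X_oc <- pose("oc", melted = TRUE); X_itc <- pose("itc")

  top <- cg_topology(beads, X_cc,
                     chain_table = data.frame(
                       chain_id = c("C", "T", "N"),
                       role = c("protein:clamp", "template", "non_template"),
                       stringsAsFactors = FALSE),
                     promoter = dna$promoter)
  wc <- cbind(dna$wc_pairs$i + np, dna$wc_pairs$j + np)
  top <- derive_bonded_terms(top, wc_pairs = wc)
  gate_beads <- which(c(cl$is_gate, rep(FALSE, ndna)))
  keep <- !(top$go_intra$i %in% gate_beads | top$go_intra$j %in% gate_beads)
  top$go_intra <- top$go_intra[keep, , drop = FALSE]

  # ---- contact selection with prescribed sizes/overlaps ---------------------
  prot_idx <- setdiff(seq_len(np), gate_beads)
  dna_idx <- np + seq_len(ndna)
  pd <- function(X) {
    # n_prot x n_dna distance matrix
    P <- X[prot_idx, , drop = FALSE]; D <- X[dna_idx, , drop = FALSE]
    outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
  }
  d_cc <- sqrt(pmax(pd(X_cc), 0)); d_oc <- sqrt(pmax(pd(X_oc), 0))
  d_itc <- sqrt(pmax(pd(X_itc), 0))
  pick <- function(score, ok, n, taken) {
    cand <- which(ok & !taken & score >= 3.2)
    cand <- cand[order(score[cand])]
    if (length(cand) < n)
      stop("toy contact prescription unsatisfiable: need ", n,
           " candidates, have ", length(cand),
           " (adjust poses/sizes in the spec)")
    cand[seq_len(n)]
  }
  taken <- matrix(FALSE, nrow(d_cc), ncol(d_cc))
  shared <- pick(d_oc, d_oc <= contact_cap & d_itc <= 1.2 * d_oc &
                   abs(d_itc - d_oc) <= 2 & d_cc > 2.1 * d_oc,
                 spec$oc_itc_overlap, taken)
  taken[shared] <- TRUE
  oc_only <- pick(d_oc, d_oc <= contact_cap & d_itc > 2.1 * d_oc &
                    d_cc > 2.1 * d_oc,
                  spec$contact_sizes[["oc"]] - spec$oc_itc_overlap, taken)
  taken[oc_only] <- TRUE
  # ITC-unique pairs must be unformed at OC (margin past the 1.2 formation
  # criterion). A first tranche is taken from the "approach band" - pairs
  # whose wells already reach toward the OC pose (d_oc inside the well's
  # capture range): their attraction is the driving force of the OC -> ITC
  # transition once the E-wing hold is released. The remainder are the
  # snuggest channel pairs, far out of range at OC.
  n_itc_only <- spec$contact_sizes[["itc"]] - spec$oc_itc_overlap
  n_approach <- min(as.integer(approach_n), n_itc_only)
  ok_itc <- d_itc <= contact_cap & d_cc > 2.1 * d_itc
  approach <- pick(d_itc, ok_itc & d_oc > 1.35 * d_itc & d_oc < 1.7 * d_itc,
                   n_approach, taken)
  taken[approach] <- TRUE
  itc_rest <- pick(d_itc, ok_itc & d_oc > 1.35 * d_itc,
                   n_itc_only - n_approach, taken)
  itc_only <- c(approach, itc_rest)
  taken[itc_only] <- TRUE
  cc_only <- pick(d_cc, d_cc <= contact_cap & d_oc > 2.1 * d_cc &
                    d_itc > 2.1 * d_cc, spec$contact_sizes[["cc"]], taken)

  as_list <- function(cells, dmat) {
    ij <- arrayInd(cells, dim(dmat))
    data.frame(bead_i = prot_idx[ij[, 1]], bead_j = dna_idx[ij[, 2]],
               r0 = dmat[cells])
  }
  cc_list <- as_list(cc_only, d_cc)
  oc_list <- as_list(c(shared, oc_only), d_oc)
  itc_list <- as_list(c(shared, itc_only), d_itc)

  contacts <- build_contact_sets(cc = cc_list, oc = oc_list, itc = itc_list)

  state_top <- function(X) { t2 <- top; t2$coords <- X; t2 }
  refset <- build_reference_set(cc = state_top(X_cc), oc = state_top(X_oc),
                                itc = state_top(X_itc))
  refset$topology <- top

  ew_beads <- which(c(cl$arc_end, rep(FALSE, ndna)))
  ew_rows <- which(contacts$union_set$bead_i %in% ew_beads &
                     seq_len(nrow(contacts$union_set)) %in% contacts$oc_set)
  if (!length(ew_rows)) {
    oc_rows <- contacts$oc_set
    ew_rows <- oc_rows[order(contacts$union_set$r0[oc_rows])][1:min(5, length(oc_rows))]
  }
  anchor <- which(beads$kind == "CA" & !seq_len(nrow(beads)) %in% gate_beads &
                    top$coords[, 1] < -12.5)
  structure(list(
    topology = top, refset = refset, contacts = contacts,
    state_lists = list(cc = cc_list, oc = oc_list, itc = itc_list),
    groups = list(gate_loop = gate_beads, gate_anchor = anchor,
                  ewing_beads = ew_beads, ewing = ew_rows),
    spec = spec, seed = seed), class = "toy_pic")
}

#' @export
print.toy_pic <- function(x, ...) {
  sz <- x$spec$contact_sizes
  cat("toy_pic: clamp ", x$spec$clamp_size, " residues + ",
      x$spec$duplex_length, "-bp duplex; contact sets cc/oc/itc = ",
      sz[["cc"]], "/", sz[["oc"]], "/", sz[["itc"]],
      " (", x$spec$oc_itc_overlap, " shared oc-itc)\n", sep = "")
  print(x$refset)
  invisible(x)
}

#' Write toy-system fixtures to disk
#'
#' Emits one CG-PDB per reference state (`<prefix>_cc.pdb`, `_oc.pdb`,
#' `_itc.pdb`) plus the sidecar contact-set table (`<prefix>_contacts.tsv`).
#'
#' @param toy A [build_toy_pic()] result.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_toy_pic <- function(toy, prefix) {
  paths <- character(0)
  for (s in names(toy$refset$coords)) {
    p <- paste0(prefix, "_", s, ".pdb")
    write_cg_pdb(toy$topology, p, coords = toy$refset$coords[[s]])
    paths <- c(paths, p)
  }
  ct <- paste0(prefix, "_contacts.tsv")
  write_contact_sets(toy$contacts, ct)
  invisible(c(paths, ct))
}
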