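# Native protein-DNA contacts: detection, union/state-specific set algebra,
# the eps_go calibration protocol, and targeted contact weakening.

#' Detect native protein-DNA contacts in one state structure
#'
#' Given an atomic model, two residue groups are in contact when any pair of
#' their heavy atoms lies within `cutoff`; the contact is recorded per
#' coarse-grained bead pair (the protein residue's CA bead against the
#' nucleotide group's P/S/B bead) with `r0` equal to the bead-bead distance in
#' that state. Given a coarse-grained topology, detection runs directly on
#' bead-bead distances against `cutoff`.
#'
#' @param x An `atomic_model` or a `cg_topology`.
#' @param cutoff Contact cutoff, Angstrom. Default 6.5 (heavy-atom convention;
#'   for bead-level detection pass a bead-scale cutoff explicitly).
#' @param coords Coordinates for a `cg_topology` (default: its reference).
#' @return Data frame `bead_i` (protein), `bead_j` (DNA), `r0` (Angstrom).
#' @export
detect_native_contacts <- function(x, cutoff = 6.5, coords = NULL) {
  if (inherits(x, "atomic_model")) {
    top <- coarse_grain(x, derive = FALSE)
    at <- x$atoms
    heavy <- at[!grepl("^H", at$elety), , drop = FALSE]
    roles <- setNames(top$chain_table$role, top$chain_table$chain_id)
    bd <- top$beads
    is_prot_chain <- startsWith(roles[heavy$chain], "protein")
    if (!any(is_prot_chain) || all(is_prot_chain))
      stop("structure must contain both protein and DNA chains")
    group_of <- function(a) {
      if (is_prot_chain[a]) return("CA")
      e <- heavy$elety[a]
      if (e %in% .phos_atoms) "P" else if (e %in% .sugar_atoms) "S"
      else if (e %in% .base_ring ||
               e %in% c("O2", "N2", "O4", "N4", "O6", "N6", "C7")) "B"
      else NA_character_
    }
    grp <- vapply(seq_len(nrow(heavy)), group_of, "")
    keep <- !is.na(grp) & !(grp == "CA" & !is_prot_chain)
    # protein side: use all heavy atoms of the residue for detection
    keep[is_prot_chain] <- TRUE
    grp[is_prot_chain] <- "CA"
    heavy <- heavy[keep, , drop = FALSE]; grp <- grp[keep]
    key <- paste(heavy$chain, heavy$resno, grp)
    bead_key <- paste(bd$chain_id, bd$residue_index, bd$kind)
    bead_of <- match(key, bead_key)
    ok <- !is.na(bead_of)
    heavy <- heavy[ok, , drop = FALSE]; bead_of <- bead_of[ok]
    pa <- which(is_prot_chain[ok])
    da <- which(!is_prot_chain[ok])
    A <- as.matrix(heavy[pa, c("x", "y", "z")])
    B <- as.matrix(heavy[da, c("x", "y", "z")])
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (!nrow(hit))
      return(data.frame(bead_i = integer(0), bead_j = integer(0), r0 = numeric(0)))
    pairs <- unique(data.frame(bead_i = bead_of[pa][hit[, 1]],
                               bead_j = bead_of[da][hit[, 2]]))
    pairs$r0 <- sqrt(rowSums((top$coords[pairs$bead_i, , drop = FALSE] -
                              top$coords[pairs$bead_j, , drop = FALSE])^2))
    rownames(pairs) <- NULL
    return(pairs[order(pairs$bead_i, pairs$bead_j), ])
  }
  if (inherits(x, "cg_topology")) {
    X <- coords %||% x$coords
    roles <- setNames(x$chain_table$role, x$chain_table$chain_id)
    prot <- which(x$beads$kind == "CA")
    dna <- which(roles[x$beads$chain_id] %in% c("template", "non_template"))
    if (!length(prot) || !length(dna))
      stop("topology must contain both protein and DNA beads")
    P <- X[prot, , drop = FALSE]; D <- X[dna, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    out <- data.frame(bead_i = prot[hit[, 1]], bead_j = dna[hit[, 2]],
                      r0 = sqrt(pmax(d2[hit], 0)))
    rownames(out) <- NULL
    return(out[order(out$bead_i, out$bead_j), ])
  }
  stop("x must be an atomic_model or a cg_topology")
}

#' Build union and state-specific contact sets
#'
#' Merges per-state contact lists into the union set used by the contact
#' potential and computes the analysis subsets: contacts specific to the first
#' state (CC-like), the full second-state (OC) set, and contacts unique to the
#' third state (ITC). When states disagree on `r0` for a shared pair, the
#' earlier state wins (priority CC > OC > ITC); disagreements above 2 Angstrom
#' raise a warning.
#'
#' @param cc,oc,itc Data frames `bead_i`, `bead_j`, `r0` (any may be empty).
#' @param epsilon Well depth assigned to every record, kcal/mol.
#' @return Object of class `contact_sets`: `union_set` (data frame with
#'   `bead_i`, `bead_j`, `r0`, `epsilon`, `in_cc`, `in_oc`, `in_itc`),
#'   `cc_specific`, `oc_set`, `itc_unique` (row indices), `overlap`
#'   (named counts).
#' @export
build_contact_sets <- function(cc = NULL, oc = NULL, itc = NULL, epsilon = 1.2) {
  empty <- data.frame(bead_i = integer(0), bead_j = integer(0), r0 = numeric(0))
  states <- list(cc = cc %||% empty, oc = oc %||% empty, itc = itc %||% empty)
  if (all(vapply(states, nrow, 1L) == 0))
    stop("at least one state contact list must be non-empty")
  key <- function(df) paste(df$bead_i, df$bead_j)
  all_keys <- unique(unlist(lapply(states, key)))
  u <- data.frame(do.call(rbind, lapply(strsplit(all_keys, " "), as.integer)))
  names(u) <- c("bead_i", "bead_j")
  r0 <- rep(NA_real_, nrow(u))
  flags <- matrix(FALSE, nrow(u), 3, dimnames = list(NULL, c("cc", "oc", "itc")))
  for (s in c("cc", "oc", "itc")) {
    m <- match(all_keys, key(states[[s]]))
    hit <- !is.na(m)
    flags[hit, s] <- TRUE
    conflict <- hit & !is.na(r0) & abs(states[[s]]$r0[m] - r0) > 2
    if (any(conflict))
      warning(sum(conflict), " contacts with r0 differing by >2 A across ",
              "states; keeping the higher-priority value")
    r0[hit & is.na(r0)] <- states[[s]]$r0[m[hit & is.na(r0)]]
  }
  u$r0 <- r0
  u$epsilon <- epsilon
  u$in_cc <- flags[, "cc"]; u$in_oc <- flags[, "oc"]; u$in_itc <- flags[, "itc"]
  structure(list(
    union_set = u,
    cc_specific = which(u$in_cc & !u$in_oc & !u$in_itc),
    oc_set = which(u$in_oc),
    itc_unique = which(u$in_itc & !u$in_oc & !u$in_cc),
    overlap = c(oc_in_itc = sum(u$in_oc & u$in_itc),
                cc_shared = sum(u$in_cc & (u$in_oc | u$in_itc)))
  ), class = "contact_sets")
}

#' @export
print.contact_sets <- function(x, ...) {
  u <- x$union_set
  cat("contact_sets: union ", nrow(u), " (cc ", sum(u$in_cc), ", oc ",
      sum(u$in_oc), ", itc ", sum(u$in_itc), "); cc-specific ",
      length(x$cc_specific), ", itc-unique ", length(x$itc_unique),
      ", oc-in-itc overlap ", x$overlap[["oc_in_itc"]], "/", sum(u$in_oc),
      "\n", sep = "")
  invisible(x)
}

#' Weaken a subset of contact wells
#'
#' Multiplies the well depth of the selected union-set records by `factor`,
#' leaving all other records (and the input object) untouched.
#'
#' @param contacts A [contact_sets()].
#' @param subset Integer row indices into `contacts$union_set`.
#' @param factor Multiplier in `[0, 1]`.
#' @return A modified copy of `contacts`.
#' @export
weaken_contacts <- function(contacts, subset, factor) {
  stopifnot(inherits(contacts, "contact_sets"), factor >= 0, factor <= 1)
  if (!length(subset)) {
    warning("empty contact selection; nothing weakened")
    return(contacts)
  }
  stopifnot(all(subset >= 1), all(subset <= nrow(contacts$union_set)))
  contacts$union_set$epsilon[subset] <- contacts$union_set$epsilon[subset] * factor
  contacts
}

#' Charge-flip mutation of protein residues
#'
#' Models a Lys/Arg/Thr -> Glu style mutation at the coarse-grained level:
#' the residues' bead identities are set to `"E"` (charge +1/0 -> -1) and all
#' their native contacts to DNA are removed from the contact set (CG beads
#' carry no side-chain geometry, so the contact loss is imposed).
#'
#' @param topology A `cg_topology`.
#' @param contacts A [contact_sets()].
#' @param beads Protein bead ids to mutate.
#' @return List `topology`, `contacts` with the mutation applied.
#' @export
apply_charge_flip <- function(topology, contacts, beads) {
  stopifnot(all(topology$beads$kind[beads] == "CA"))
  topology$beads$identity[beads] <- "E"
  drop <- contacts$union_set$bead_i %in% beads
  if (any(drop)) {
    u <- contacts$union_set[!drop, , drop = FALSE]
    contacts <- build_contact_sets(
      cc = u[u$in_cc, c("bead_i", "bead_j", "r0")],
      oc = u[u$in_oc, c("bead_i", "bead_j", "r0")],
      itc = u[u$in_itc, c("bead_i", "bead_j", "r0")],
      epsilon = contacts$union_set$epsilon[1])
  }
  list(topology = topology, contacts = contacts)
}

#' Define a calibration probe for [calibrate_epsilon()]
#'
#' @param state Reference state the probe run starts from.
#' @param subset Union-set row indices of the probed contacts.
#' @param outcome `"maintained"` or `"lost"`.
#' @param mutate_beads Optional protein bead ids receiving a charge-flip
#'   mutation (with contact deletion) before the run.
#' @return A `calibration_probe`.
#' @export
calibration_probe <- function(state, subset, outcome = c("maintained", "lost"),
                              mutate_beads = NULL) {
  outcome <- match.arg(outcome)
  structure(list(state = state, subset = subset, outcome = outcome,
                 mutate_beads = mutate_beads), class = "calibration_probe")
}

#' Calibrate the protein-DNA contact strength eps_go
#'
#' Scans candidate well depths; for each, runs a short equilibrium Langevin
#' simulation per probe (starting from the probe's reference state, with any
#' charge-flip mutation applied) and scores the probe's mean contact-survival
#' fraction over the run. A probe requiring `"maintained"` passes when the
#' mean survival is at least `survival_threshold`; one requiring `"lost"`
#' passes when it is below. The smallest candidate satisfying every probe is
#' returned.
#'
#' This is the protocol used with the three-state complex to fix the default
#' of 1.2 kcal/mol: (1) CC keeps the DNA / E-wing contact, (2) OC keeps the
#' template-strand contacts near the active site, (3) OC and ITC keep the
#' upstream-DNA / TFIIE contacts, (4) the triple charge-flip mutant loses
#' them.
#'
#' @param system List with `topology`, `refset`, `contacts` (e.g. a
#'   [build_toy_pic()] result).
#' @param candidates Increasing vector of candidate eps_go values, kcal/mol.
#' @param probes List of [calibration_probe()] objects.
#' @param seeds One integer seed per probe replicate (replicates are averaged).
#' @param n_steps,save_interval Probe run length and sampling stride.
#' @param params Base [energy_params()] (its `eps_go` is overridden per
#'   candidate).
#' @param survival_threshold Maintained/lost decision boundary.
#' @return List: `eps_go` (chosen value), `report` (data frame of per-probe
#'   survival fractions per candidate).
#' @export
calibrate_epsilon <- function(system, candidates, probes, seeds = 1:2,
                              n_steps = 20000, save_interval = 200,
                              params = energy_params(),
                              survival_threshold = 0.5) {
  stopifnot(length(candidates) >= 1, !is.unsorted(candidates))
  report <- list()
  chosen <- NA_real_
  for (eps in candidates) {
    all_ok <- TRUE
    for (pi in seq_along(probes)) {
      pr <- probes[[pi]]
      top <- system$topology
      cs <- system$contacts
      cs$union_set$epsilon[] <- eps
      if (!is.null(pr$mutate_beads)) {
        keys0 <- paste(cs$union_set$bead_i, cs$union_set$bead_j)[pr$subset]
        mut <- apply_charge_flip(top, cs, pr$mutate_beads)
        top <- mut$topology; cs <- mut$contacts
        cs$union_set$epsilon[] <- eps
        keys1 <- paste(cs$union_set$bead_i, cs$union_set$bead_j)
        subset <- match(keys0, keys1)
        subset <- subset[!is.na(subset)]
      } else subset <- pr$subset
      surv <- vapply(seeds, function(sd) {
        tr <- run_langevin(system$refset$coords[[pr$state]], top, cs, params,
                           sim_config(n_steps = n_steps,
                                      save_interval = save_interval,
                                      temperature = params$temperature,
                                      seed = sd))
        if (!length(subset)) return(0)
        nf <- dim(tr$frames)[1]
        use <- seq(floor(nf / 2) + 1, nf)  # equilibrated trailing half
        mean(vapply(use, function(fr)
          contact_fraction(tr$frames[fr, , ], cs, subset), 1.0))
      }, 1.0)
      s <- mean(surv)
      ok <- if (pr$outcome == "maintained") s >= survival_threshold
            else s < survival_threshold
      report[[length(report) + 1L]] <- data.frame(
        eps = eps, probe = pi, state = pr$state, outcome = pr$outcome,
        survival = s, ok = ok)
      if (!ok) all_ok <- FALSE
    }
    if (all_ok && is.na(chosen)) chosen <- eps
  }
  report <- do.call(rbind, report)
  if (is.na(chosen)) {
    bad <- report[!report$ok, ]
    stop("calibration failure: no candidate satisfies all probes ",
         "(first violated probe at largest eps: probe ",
         bad$probe[nrow(bad)], ", outcome ", bad$outcome[nrow(bad)], ")")
  }
  list(eps_go = chosen, report = report)
}

#' Read / write contact sets as TSV
#'
#' Columns: `bead_i`, `bead_j`, `r0`, `epsilon`, and the three state flags
#' `in_cc`, `in_oc`, `in_itc`.
#'
#' @param contacts A [contact_sets()].
#' @param path File path.
#' @return `write_contact_sets()` the path, invisibly;
#'   `read_contact_sets()` a [contact_sets()] rebuilt from the flags.
#' @export
write_contact_sets <- function(contacts, path) {
  write.table(contacts$union_set, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_sets
#' @export
read_contact_sets <- function(path) {
  u <- read.table(path, header = TRUE, sep = "\t")
  need <- c("bead_i", "bead_j", "r0", "epsilon", "in_cc", "in_oc", "in_itc")
  if (!all(need %in% names(u))) stop("malformed contact-set table: ", path)
  cs <- build_contact_sets(
    cc = u[u$in_cc, c("bead_i", "bead_j", "r0")],
    oc = u[u$in_oc, c("bead_i", "bead_j", "r0")],
    itc = u[u$in_itc, c("bead_i", "bead_j", "r0")])
  # restore per-record well depths (matched by pair key)
  key_in <- paste(u$bead_i, u$bead_j)
  key_out <- paste(cs$union_set$bead_i, cs$union_set$bead_j)
  cs$union_set$epsilon <- u$epsilon[match(key_out, key_in)]
  cs
}
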