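# Coarse-grained topology: beads, bonded terms with native values, Watson-Crick
# pairing table, chain roles. Built either from an atomic model (coarse_grain)
# or by the synthetic generators; native values always come from the geometry
# the topology was built from.

#' Construct a coarse-grained topology
#'
#' Low-level constructor. Most users will obtain topologies from
#' [coarse_grain()] or [build_bdna()] / [build_toy_pic()], which derive all
#' bonded terms from the source geometry via [derive_bonded_terms()].
#'
#' @param beads Data frame with columns `bead_id`, `chain_id`,
#'   `residue_index`, `kind` (one of `"CA"`, `"P"`, `"S"`, `"B"`),
#'   `identity` (amino-acid or base one-letter code).
#' @param coords Numeric `n x 3` matrix of reference coordinates (Angstrom).
#' @param chain_table Data frame `chain_id`, `role` with role one of
#'   `"protein"`, `"template"`, `"non_template"` (protein roles may carry a
#'   subunit name suffix, e.g. `"protein:Rpb2"`).
#' @param promoter Optional [promoter_sequence()] attached for bookkeeping.
#' @return Object of class `cg_topology`.
#' @export
cg_topology <- function(beads, coords, chain_table, promoter = NULL) {
  stopifnot(is.data.frame(beads), nrow(beads) == nrow(coords), ncol(coords) == 3)
  need <- c("bead_id", "chain_id", "residue_index", "kind", "identity")
  if (!all(need %in% names(beads)))
    stop("beads must have columns: ", paste(need, collapse = ", "))
  if (!all(beads$kind %in% c("CA", "P", "S", "B")))
    stop("bead kind must be CA, P, S or B")
  prot_chains <- chain_table$chain_id[startsWith(chain_table$role, "protein")]
  bad <- (beads$kind == "CA") != (beads$chain_id %in% prot_chains)
  if (any(bad)) stop("CA beads must occur exactly on protein chains")
  structure(list(
    beads = beads, coords = unname(as.matrix(coords)),
    chain_table = chain_table, promoter = promoter,
    bonds = NULL, angles = NULL, dihedrals = NULL,
    stacks = NULL, wc_pairs = NULL, go_intra = NULL,
    mismatch = NULL
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  nk <- table(x$beads$kind)
  cat("cg_topology: ", nrow(x$beads), " beads (",
      paste(names(nk), nk, sep = ":", collapse = ", "), "), ",
      length(unique(x$beads$chain_id)), " chains\n", sep = "")
  cat("  bonds ", nrow(x$bonds %||% data.frame()),
      ", angles ", nrow(x$angles %||% data.frame()),
      ", dihedrals ", nrow(x$dihedrals %||% data.frame()),
      ", stacks ", nrow(x$stacks %||% data.frame()),
      ", wc pairs ", nrow(x$wc_pairs %||% data.frame()),
      ", intra-protein contacts ", nrow(x$go_intra %||% data.frame()), "\n", sep = "")
  if (!is.null(x$mismatch))
    cat("  mismatch active at ", length(x$mismatch$wc_rows), " pairs\n", sep = "")
  invisible(x)
}

# --- geometry helpers (R side, used for native values and analysis) ----------

.vnorm <- function(v) sqrt(sum(v * v))

.vangle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cth <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(pmin(1, pmax(-1, cth)))
}

.vdihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m <- pracma_cross(n1, n2)
  atan2(sum(m * b2) / .vnorm(b2), sum(n1 * n2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Derive bonded terms and native values from reference geometry
#'
#' Builds the bond/angle/dihedral tables, intra-strand stacking pairs,
#' Watson-Crick pairing geometry and intra-protein native contacts, taking all
#' native values (distances, angles, dihedrals) from `topology$coords`. For
#' protein chains, consecutive residues give virtual bonds/angles/dihedrals and
#' residue pairs separated by at least `go_min_seq` with C-alpha distance below
#' `go_cutoff` give native contacts. For DNA strands (5'->3' residue order) the
#' backbone is P(i)-S(i)-B(i) with S(i)-P(i+1) linkage.
#'
#' @param topology A `cg_topology`.
#' @param wc_pairs Optional two-column matrix of base-bead ids to treat as
#'   Watson-Crick partners; if `NULL`, pairs are detected from geometry and
#'   base complementarity (base beads of complementary identity on strands of
#'   opposite role within `wc_detect_cutoff`).
#' @param go_cutoff C-alpha distance cutoff (Angstrom) for intra-protein
#'   native contacts. Default 8.
#' @param go_min_seq Minimum sequence separation for intra-protein contacts.
#' @param wc_detect_cutoff Base-bead distance cutoff for pairing detection.
#' @return The topology with bonded tables filled in.
#' @export
derive_bonded_terms <- function(topology, wc_pairs = NULL, go_cutoff = 8,
                                go_min_seq = 4, wc_detect_cutoff = 7) {
  top <- topology
  bd <- top$beads; X <- top$coords
  bonds <- list(); angles <- list(); dihs <- list(); stacks <- list()
  goi <- list()

  dist_ij <- function(i, j) .vnorm(X[i, ] - X[j, ])
  add_bond <- function(i, j, term) list(i = i, j = j, r0 = dist_ij(i, j), term = term)
  add_ang <- function(i, j, k, term)
    list(i = i, j = j, k = k, th0 = .vangle(X[i, ], X[j, ], X[k, ]), term = term)
  add_dih <- function(i, j, k, l, term)
    list(i = i, j = j, k = k, l = l,
         phi0 = .vdihedral(X[i, ], X[j, ], X[k, ], X[l, ]), term = term)

  for (ch in unique(bd$chain_id)) {
    role <- top$chain_table$role[top$chain_table$chain_id == ch]
    rows <- which(bd$chain_id == ch)
    rows <- rows[order(bd$residue_index[rows])]
    if (startsWith(role, "protein")) {
      n <- length(rows)
      if (n >= 2) for (t in 1:(n - 1))
        bonds[[length(bonds) + 1L]] <- add_bond(rows[t], rows[t + 1], 0L)
      if (n >= 3) for (t in 1:(n - 2))
        angles[[length(angles) + 1L]] <- add_ang(rows[t], rows[t + 1], rows[t + 2], 0L)
      if (n >= 4) for (t in 1:(n - 3))
        dihs[[length(dihs) + 1L]] <- add_dih(rows[t], rows[t + 1], rows[t + 2], rows[t + 3], 0L)
      if (n >= go_min_seq + 1) {
        for (a in 1:(n - go_min_seq)) for (b in (a + go_min_seq):n) {
          r <- dist_ij(rows[a], rows[b])
          if (r < go_cutoff)
            goi[[length(goi) + 1L]] <- list(i = rows[a], j = rows[b], r0 = r)
        }
      }
    } else {
      # DNA strand: group rows by residue, in 5'->3' order
      res <- sort(unique(bd$residue_index[rows]))
      get <- function(ri, kind) {
        w <- rows[bd$residue_index[rows] == ri & bd$kind[rows] == kind]
        if (length(w)) w else NA_integer_
      }
      n <- length(res)
      for (t in seq_len(n)) {
        P <- get(res[t], "P"); S <- get(res[t], "S"); B <- get(res[t], "B")
        if (!is.na(P)) bonds[[length(bonds) + 1L]] <- add_bond(P, S, 1L)
        bonds[[length(bonds) + 1L]] <- add_bond(S, B, 1L)
        if (!is.na(P)) angles[[length(angles) + 1L]] <- add_ang(P, S, B, 1L)
        if (t < n) {
          P2 <- get(res[t + 1], "P"); S2 <- get(res[t + 1], "S"); B2 <- get(res[t + 1], "B")
          if (!is.na(P2)) {
            bonds[[length(bonds) + 1L]] <- add_bond(S, P2, 1L)
            angles[[length(angles) + 1L]] <- add_ang(B, S, P2, 1L)
            angles[[length(angles) + 1L]] <- add_ang(S, P2, S2, 1L)
            if (!is.na(P))
              angles[[length(angles) + 1L]] <- add_ang(P, S, P2, 1L)
            dihs[[length(dihs) + 1L]] <- add_dih(S, P2, S2, B2, 1L)
            if (!is.na(P))
              dihs[[length(dihs) + 1L]] <- add_dih(P, S, P2, S2, 1L)
            if (t < n - 0 && t + 2 <= n) {
              P3 <- get(res[t + 2], "P")
              if (!is.na(P3))
                dihs[[length(dihs) + 1L]] <- add_dih(S, P2, S2, P3, 1L)
            }
          }
          stacks[[length(stacks) + 1L]] <-
            list(i = B, j = B2, r0 = dist_ij(B, B2))
        }
      }
    }
  }

  top$bonds <- .bind_rows_list(bonds)
  top$angles <- .bind_rows_list(angles)
  top$dihedrals <- .bind_rows_list(dihs)
  top$stacks <- .bind_rows_list(stacks)
  top$go_intra <- .bind_rows_list(goi)

  # Watson-Crick pairs: each pair stores its base beads, the flanking sugar
  # beads used by the orientation factor, native distance and native angles.
  if (is.null(wc_pairs)) wc_pairs <- .detect_wc_pairs(top, wc_detect_cutoff)
  if (!is.null(wc_pairs) && nrow(wc_pairs) > 0) {
    sug <- function(b) {
      w <- which(top$beads$chain_id == top$beads$chain_id[b] &
                 top$beads$residue_index == top$beads$residue_index[b] &
                 top$beads$kind == "S")
      if (!length(w)) stop("paired base bead ", b, " has no sugar bead")
      w
    }
    si <- vapply(wc_pairs[, 1], sug, 1L)
    sj <- vapply(wc_pairs[, 2], sug, 1L)
    pair_class <- ifelse(top$beads$identity[wc_pairs[, 1]] %in% c("G", "C"), "GC", "AT")
    wc <- data.frame(
      i = wc_pairs[, 1], j = wc_pairs[, 2], s_i = si, s_j = sj,
      r0 = vapply(seq_len(nrow(wc_pairs)),
                  function(r) dist_ij(wc_pairs[r, 1], wc_pairs[r, 2]), 1.0),
      th1_0 = vapply(seq_len(nrow(wc_pairs)), function(r)
        .vangle(X[si[r], ], X[wc_pairs[r, 1], ], X[wc_pairs[r, 2], ]), 1.0),
      th2_0 = vapply(seq_len(nrow(wc_pairs)), function(r)
        .vangle(X[wc_pairs[r, 1], ], X[wc_pairs[r, 2], ], X[sj[r], ]), 1.0),
      pair_class = pair_class, enabled = TRUE,
      stringsAsFactors = FALSE)
    # basic sanity: complementary identities where pairing is requested
    idi <- top$beads$identity[wc$i]; idj <- top$beads$identity[wc$j]
    ok <- vapply(seq_along(idi), function(r) complement_base(idi[r]) == idj[r], TRUE)
    if (!all(ok))
      stop("non-complementary wc_pair requested at rows: ",
           paste(which(!ok), collapse = ", "))
    top$wc_pairs <- wc
  } else {
    top$wc_pairs <- data.frame(i = integer(0), j = integer(0), s_i = integer(0),
                               s_j = integer(0), r0 = numeric(0), th1_0 = numeric(0),
                               th2_0 = numeric(0), pair_class = character(0),
                               enabled = logical(0))
  }
  top
}

.bind_rows_list <- function(lst) {
  if (!length(lst)) return(NULL)
  do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
}

# Detect Watson-Crick partners: complementary base beads on template vs
# non-template strands, mutually nearest within cutoff.
.detect_wc_pairs <- function(top, cutoff) {
  bd <- top$beads
  roles <- setNames(top$chain_table$role, top$chain_table$chain_id)
  tb <- which(bd$kind == "B" & roles[bd$chain_id] == "template")
  nb <- which(bd$kind == "B" & roles[bd$chain_id] == "non_template")
  if (!length(tb) || !length(nb)) return(NULL)
  out <- list()
  for (i in tb) {
    d <- sqrt(colSums((t(top$coords[nb, , drop = FALSE]) - top$coords[i, ])^2))
    comp <- vapply(bd$identity[nb], function(b) b == complement_base(bd$identity[i]), TRUE)
    cand <- which(d < cutoff & comp)
    if (!length(cand)) next
    j <- nb[cand[which.min(d[cand])]]
    out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  # enforce one-to-one: keep the closest claim per non-template base
  keep <- !duplicated(m[, 2])
  m[keep, , drop = FALSE]
}

#' Bead masses (amu) by bead kind
#' @param kind Character vector of bead kinds.
#' @return Numeric vector of masses.
#' @export
bead_masses <- function(kind) {
  unname(c(CA = 110, P = 95, S = 83, B = 110)[kind])
}

#' Per-bead charges under the fixed-charge convention
#'
#' Protein: +1 e on Lys/Arg, -1 e on Asp/Glu, 0 elsewhere. DNA: the phosphate
#' bead carries `phosphate_charge` (default -0.6 e, a counterion-condensation
#' convention); sugar and base are neutral.
#'
#' @param topology A `cg_topology`.
#' @param phosphate_charge Charge on each phosphate bead, units e.
#' @return Numeric vector, one charge per bead.
#' @export
bead_charges <- function(topology, phosphate_charge = -0.6) {
  bd <- topology$beads
  q <- numeric(nrow(bd))
  q[bd$kind == "P"] <- phosphate_charge
  q[bd$kind == "CA" & bd$identity %in% c("K", "R")] <- 1
  q[bd$kind == "CA" & bd$identity %in% c("D", "E")] <- -1
  q
}
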