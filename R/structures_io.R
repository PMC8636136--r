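# Structure input: atomic models from PDB/mmCIF (via bio3d), coarse-graining
# to the CA + three-sites-per-nucleotide representation, CG-PDB round trip,
# and multi-state reference sets.

.protein_res <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                  "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                  "MSE","SEC","PYL")
.nucleic_res <- c("DA","DT","DG","DC","A","T","G","C","U","DU",
                  "DA5","DT5","DG5","DC5","DA3","DT3","DG3","DC3")

.aa3to1 <- c(ALA="A",ARG="R",ASN="N",ASP="D",CYS="C",GLN="Q",GLU="E",GLY="G",
             HIS="H",ILE="I",LEU="L",LYS="K",MET="M",PHE="F",PRO="P",SER="S",
             THR="T",TRP="W",TYR="Y",VAL="V",MSE="M",SEC="U",PYL="O")

.phos_atoms <- c("P","OP1","OP2","O1P","O2P","O5'")
.sugar_atoms <- c("C1'","C2'","C3'","C4'","C5'","O4'")
.base_ring <- c("N1","C2","N3","C4","C5","C6","N7","C8","N9")

#' Read an atomic structure from a PDB or mmCIF file
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] that normalizes
#' the atom table: alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by altloc label), atom names use the prime
#' convention, and per-chain gaps in residue numbering are reported as missing
#' residues (they are never rebuilt).
#'
#' @param file Path to a `.pdb`, `.ent` or `.cif` file.
#' @return Object of class `atomic_model`: list with `atoms` (data frame:
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`), `missing` (data frame
#'   of chain/resno gaps) and `source`.
#' @export
read_structure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  ext <- tolower(tools::file_ext(file))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(file) else bio3d::read.pdb(file),
    error = function(e) stop("unparseable structure file ", file, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & at$resid %in%
             c(.protein_res, .nucleic_res), , drop = FALSE]
  if (!nrow(at)) stop("empty model: no protein or nucleic residues in ", file)
  at$elety <- gsub("\\*", "'", at$elety)
  if (!"o" %in% names(at) || all(is.na(at$o))) at$o <- 1
  at$alt[is.na(at$alt)] <- ""
  # resolve altlocs: keep, per (chain, resno, elety), the highest occupancy
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)[ord]), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]

  miss <- list()
  for (ch in unique(at$chain)) {
    rn <- sort(unique(at$resno[at$chain == ch]))
    gaps <- setdiff(seq(min(rn), max(rn)), rn)
    if (length(gaps))
      miss[[length(miss) + 1L]] <- data.frame(chain = ch, resno = gaps)
  }
  miss <- if (length(miss)) do.call(rbind, miss) else
    data.frame(chain = character(0), resno = integer(0))
  if (nrow(miss))
    message("read_structure: ", nrow(miss),
            " missing residues (gaps in numbering); excluded from the model")
  structure(list(
    atoms = data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                       elety = at$elety, x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE),
    missing = miss, source = file), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("atomic_model: ", nrow(x$atoms), " atoms, chains ",
      paste(unique(x$atoms$chain), collapse = ","),
      "; ", nrow(x$missing), " missing residues\n", sep = "")
  invisible(x)
}

#' Coarse-grain an atomic model
#'
#' Maps each protein residue to one bead at its C-alpha position and each
#' nucleotide to three beads: P at the phosphate-group centroid
#' (P, OP1, OP2, O5'), S at the sugar-ring centroid (C1'-C5', O4') and B at
#' the base-ring centroid (purine/pyrimidine ring heavy atoms). The
#' 5'-terminal nucleotide of a strand has no P bead when the source structure
#' lacks the phosphate group. Bonded terms and Watson-Crick pairs are then
#' derived from the mapped geometry with [derive_bonded_terms()].
#'
#' @param model An `atomic_model` from [read_structure()].
#' @param chain_roles Optional named character vector mapping chain ids to
#'   roles (`"protein"`, `"template"`, `"non_template"`). By default protein /
#'   nucleic chains are classified by residue names and the first nucleic
#'   chain is taken as the template strand.
#' @param derive If `TRUE` (default), fill bonded terms from the geometry.
#' @param ... Passed to [derive_bonded_terms()].
#' @return A `cg_topology` with reference coordinates.
#' @export
coarse_grain <- function(model, chain_roles = NULL, derive = TRUE, ...) {
  at <- model$atoms
  beads <- list(); xyz <- list()
  roles <- character(0)
  nuc_seen <- 0L
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    is_prot <- any(ca$resid %in% .protein_res)
    role <- if (!is.null(chain_roles) && ch %in% names(chain_roles)) {
      chain_roles[[ch]]
    } else if (is_prot) "protein" else {
      nuc_seen <- nuc_seen + 1L
      if (nuc_seen == 1L) "template" else "non_template"
    }
    roles[ch] <- role
    for (rn in unique(ca$resno)) {
      rr <- ca[ca$resno == rn, , drop = FALSE]
      resid <- rr$resid[1]
      if (resid %in% .protein_res) {
        w <- which(rr$elety == "CA")
        if (!length(w))
          stop("coarse_grain: residue ", resid, " ", rn, " chain ", ch,
               " has no CA atom")
        beads[[length(beads) + 1L]] <- data.frame(
          chain_id = ch, residue_index = rn, kind = "CA",
          identity = unname(.aa3to1[resid]), stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <- as.numeric(rr[w[1], c("x", "y", "z")])
      } else {
        base1 <- sub("^D", "", sub("[35]$", "", resid))
        grp <- function(names_) {
          w <- which(rr$elety %in% names_)
          if (!length(w)) return(NULL)
          colMeans(rr[w, c("x", "y", "z"), drop = FALSE])
        }
        p <- grp(.phos_atoms); s <- grp(.sugar_atoms); b <- grp(.base_ring)
        if (is.null(s) && is.null(b))
          stop("coarse_grain: nucleotide ", resid, " ", rn, " chain ", ch,
               " has no mappable atoms")
        if (is.null(s) || is.null(b))
          stop("coarse_grain: nucleotide ", resid, " ", rn, " chain ", ch,
               " is missing its ", if (is.null(s)) "sugar" else "base", " group")
        for (kb in list(list("P", p), list("S", s), list("B", b))) {
          if (is.null(kb[[2]])) next
          beads[[length(beads) + 1L]] <- data.frame(
            chain_id = ch, residue_index = rn, kind = kb[[1]],
            identity = base1, stringsAsFactors = FALSE)
          xyz[[length(xyz) + 1L]] <- as.numeric(kb[[2]])
        }
      }
    }
  }
  beads <- do.call(rbind, beads)
  beads$bead_id <- seq_len(nrow(beads))
  beads <- beads[, c("bead_id", "chain_id", "residue_index", "kind", "identity")]
  coords <- do.call(rbind, xyz)
  top <- cg_topology(beads, coords,
                     chain_table = data.frame(chain_id = names(roles),
                                              role = unname(roles),
                                              stringsAsFactors = FALSE))
  if (derive) top <- derive_bonded_terms(top, ...)
  top
}

#' Write a coarse-grained structure as a pseudo-atom PDB file
#'
#' One ATOM record per bead; the bead kind goes in the atom-name field, the
#' residue identity in the residue-name field. Coordinates are written at the
#' standard 3-decimal PDB precision, so a write/read round trip preserves them
#' to that precision exactly.
#'
#' @param topology A `cg_topology`.
#' @param path Output file.
#' @param coords Coordinates to write (default: the topology's reference).
#' @export
write_cg_pdb <- function(topology, path, coords = topology$coords) {
  bd <- topology$beads
  stopifnot(nrow(bd) == nrow(coords))
  ch <- substr(bd$chain_id, 1, 1)
  res3 <- ifelse(bd$kind == "CA", "ALA", paste0("D", bd$identity))
  res3 <- ifelse(bd$kind == "CA",
                 names(.aa3to1)[match(bd$identity, .aa3to1)], res3)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    bd$bead_id %% 100000L, bd$kind, res3, ch, bd$residue_index %% 10000L,
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a coarse-grained pseudo-atom PDB written by [write_cg_pdb()]
#'
#' @param path File path.
#' @return List with `beads` and `coords` (no bonded terms; pass through
#'   [cg_topology()] + [derive_bonded_terms()] to rebuild a full topology).
#' @export
read_cg_pdb <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[startsWith(ln, "ATOM")]
  if (!length(ln)) stop("no ATOM records in ", path)
  kind <- trimws(substr(ln, 13, 16))
  res3 <- trimws(substr(ln, 18, 20))
  identity <- ifelse(kind == "CA", unname(.aa3to1[res3]), sub("^D", "", res3))
  beads <- data.frame(
    bead_id = seq_along(ln),
    chain_id = substr(ln, 22, 22),
    residue_index = as.integer(substr(ln, 23, 26)),
    kind = kind, identity = identity, stringsAsFactors = FALSE)
  coords <- cbind(as.numeric(substr(ln, 31, 38)),
                  as.numeric(substr(ln, 39, 46)),
                  as.numeric(substr(ln, 47, 54)))
  list(beads = beads, coords = coords)
}

#' Assemble a multi-state reference set (CC / OC / ITC)
#'
#' Establishes a common bead ordering across the states of a complex, stores
#' per-state coordinates, and reports pairwise protein-only RMSDs after Kabsch
#' superposition (DNA is excluded from the RMSD, since the DNA differs
#' qualitatively between states). The protein composition must agree across
#' states.
#'
#' @param ... Named `cg_topology` objects (e.g. `cc = `, `oc = `, `itc = `),
#'   each carrying its own reference coordinates.
#' @return Object of class `reference_set`: `topology` (the first state's,
#'   used as the common reference), `coords` (named list per state),
#'   `rmsd` (matrix of pairwise protein RMSDs, Angstrom).
#' @export
build_reference_set <- function(...) {
  states <- list(...)
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("states must be named, e.g. build_reference_set(cc = ..., oc = ...)")
  ref <- states[[1]]
  prot <- which(ref$beads$kind == "CA")
  for (nm in names(states)[-1]) {
    s <- states[[nm]]
    if (nrow(s$beads) != nrow(ref$beads))
      stop("state ", nm, ": bead count differs from reference")
    pi <- which(s$beads$kind == "CA")
    if (length(pi) != length(prot) ||
        any(s$beads$identity[pi] != ref$beads$identity[prot]))
      stop("state ", nm, ": protein composition differs from reference")
  }
  nst <- length(states)
  rm <- matrix(0, nst, nst, dimnames = list(names(states), names(states)))
  for (a in seq_len(nst)) for (b in seq_len(nst)) if (a < b) {
    r <- kabsch_rmsd(states[[a]]$coords, states[[b]]$coords, selection = prot)
    rm[a, b] <- rm[b, a] <- r
  }
  structure(list(
    topology = ref,
    coords = lapply(states, function(s) s$coords),
    rmsd = rm), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set with states: ", paste(names(x$coords), collapse = ", "),
      "\nprotein-only pairwise RMSD (A):\n", sep = "")
  print(round(x$rmsd, 3))
  invisible(x)
}
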