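# Trajectory statistics: DNA bubble size and its threshold calibration,
# state-specific contact fractions and discrete state assignment, gate
# distances, moving averages, Kabsch RMSD.

#' Analysis parameters
#'
#' @param break_threshold Base-base distance above which a Watson-Crick pair
#'   counts as broken, Angstrom. Default 6.2 (calibrated so a free duplex at
#'   300 K / 200 mM shows a 0.3% per-pair break rate).
#' @param ma_window Moving-average window, frames (odd). Default 11.
#' @param formation_criterion A contact is formed when `r <= criterion * r0`.
#'   Default 1.2.
#' @param state_thresholds Named cutoffs for [assign_state()]; see Details.
#' @param gate_open_distance Gate distance above which the gate counts open,
#'   Angstrom, or `NULL` to estimate from the trajectory (closed-state mean +
#'   2 SD over the first decile of frames).
#'
#' @details Default state cutoffs: CC when `f_cc >= 0.6`; pre-OC when
#' `f_cc <= 0.3` and `0.25 <= f_oc < 0.7`; OC when `f_oc >= 0.7` and
#' `f_itc < 0.25`; I1/I2 when `0.25 <= f_itc < 0.7`, split by the E-wing
#' contact flag (I1 formed, I2 lost); ITC when `f_itc >= 0.7`; otherwise
#' unassigned.
#' @return Object of class `analysis_params`.
#' @export
analysis_params <- function(break_threshold = 6.2, ma_window = 11,
                            formation_criterion = 1.2,
                            state_thresholds = c(cc_hi = 0.6, cc_lo = 0.3,
                                                 oc_lo = 0.25, oc_hi = 0.7,
                                                 itc_lo = 0.25, itc_hi = 0.7),
                            gate_open_distance = NULL) {
  stopifnot(break_threshold > 0, ma_window %% 2 == 1)
  structure(list(break_threshold = break_threshold, ma_window = ma_window,
                 formation_criterion = formation_criterion,
                 state_thresholds = state_thresholds,
                 gate_open_distance = gate_open_distance),
            class = "analysis_params")
}

#' DNA bubble size of one frame
#'
#' Counts the Watson-Crick pairs whose base-bead distance exceeds the break
#' threshold; the sum of broken base pairs is the bubble size.
#'
#' @param frame `n x 3` coordinates.
#' @param topology A `cg_topology` with `wc_pairs`.
#' @param break_threshold Angstrom; default 6.2.
#' @param window Optional TSS-relative half-open interval restricting the
#'   counted pairs (default: all pairs).
#' @return Integer count of broken pairs.
#' @export
bubble_size <- function(frame, topology, break_threshold = 6.2, window = NULL) {
  d <- wc_distances(frame, topology, window)
  sum(d > break_threshold)
}

#' Base-base distances of the Watson-Crick pairs
#' @inheritParams bubble_size
#' @return Numeric vector, one distance per (selected) pair.
#' @export
wc_distances <- function(frame, topology, window = NULL) {
  wc <- topology$wc_pairs
  if (is.null(wc) || !nrow(wc)) stop("topology has no wc_pairs")
  if (!is.null(window)) {
    ps <- topology$promoter
    if (is.null(ps)) stop("window given but topology has no promoter")
    tidx <- tss_interval_index(ps, window)
    bd <- topology$beads
    tb <- bd$bead_id[bd$kind == "B" & bd$residue_index %in% tidx &
                       .role_of(topology, bd$chain_id) == "template"]
    wc <- wc[wc$i %in% tb, , drop = FALSE]
  }
  sqrt(rowSums((frame[wc$i, , drop = FALSE] - frame[wc$j, , drop = FALSE])^2))
}

#' Per-frame bubble trace of a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param break_threshold Angstrom.
#' @param window Optional TSS-relative interval restriction.
#' @return Object of class `bubble_trace`: data frame `step`, `bubble`, plus
#'   attributes `mask` (frames x pairs logical) and the threshold.
#' @export
bubble_trace <- function(trajectory, break_threshold = 6.2, window = NULL) {
  nf <- dim(trajectory$frames)[1]
  top <- trajectory$topology
  mask <- t(vapply(seq_len(nf), function(f)
    wc_distances(trajectory$frames[f, , ], top, window) > break_threshold,
    logical(length(wc_distances(trajectory$frames[1, , ], top, window)))))
  out <- data.frame(step = trajectory$steps, bubble = rowSums(mask))
  attr(out, "mask") <- mask
  attr(out, "break_threshold") <- break_threshold
  class(out) <- c("bubble_trace", "data.frame")
  out
}

#' Summarize a bubble trace over a frame range
#' @param trace A [bubble_trace()].
#' @param frames Frame indices entering the statistics (default all).
#' @return Named numeric `mean`, `sd`.
#' @export
bubble_stats <- function(trace, frames = seq_len(nrow(trace))) {
  c(mean = mean(trace$bubble[frames]), sd = sd(trace$bubble[frames]))
}

#' Calibrate the base-pair break threshold
#'
#' Scans a threshold grid against the pooled base-base distances of a fully
#' paired duplex trajectory and returns the smallest threshold whose
#' empirical exceed-rate is at most the target (the observed quantile of the
#' breathing distribution). With the calibrated DNA model and the 0.3% target
#' this reproduces the 6.2 Angstrom criterion.
#'
#' @param trajectory A `cg_trajectory` of a duplex (or list of trajectories).
#' @param target_rate Target exceed-rate (e.g. 0.003).
#' @param grid Candidate thresholds, Angstrom.
#' @param burn_in Fraction of initial frames discarded.
#' @return Threshold, Angstrom; attribute `"rate"` carries the achieved rate.
#' @export
calibrate_break_threshold <- function(trajectory, target_rate = 0.003,
                                      grid = seq(4, 10, by = 0.1),
                                      burn_in = 0.1) {
  trajs <- if (inherits(trajectory, "cg_trajectory")) list(trajectory) else trajectory
  dists <- unlist(lapply(trajs, function(tr) {
    nf <- dim(tr$frames)[1]
    use <- seq(floor(burn_in * nf) + 1, nf)
    unlist(lapply(use, function(f) wc_distances(tr$frames[f, , ], tr$topology)))
  }))
  rates <- vapply(grid, function(th) mean(dists > th), 1.0)
  ok <- which(rates <= target_rate)
  if (!length(ok))
    stop("calibration failure: no grid threshold reaches rate <= ", target_rate)
  th <- grid[ok[1]]
  attr(th, "rate") <- rates[ok[1]]
  th
}

#' Fraction of formed contacts in one frame
#'
#' A contact is formed when its bead-bead distance is at most
#' `criterion * r0`.
#'
#' @param frame `n x 3` coordinates.
#' @param contacts A [contact_sets()] (or a data frame with `bead_i`,
#'   `bead_j`, `r0`).
#' @param subset Union-set row indices (default: all records).
#' @param criterion Formation criterion; default 1.2.
#' @return Fraction in `[0, 1]`.
#' @export
contact_fraction <- function(frame, contacts, subset = NULL, criterion = 1.2) {
  u <- if (inherits(contacts, "contact_sets")) contacts$union_set else contacts
  if (!is.null(subset)) u <- u[subset, , drop = FALSE]
  if (!nrow(u)) stop("contact subset is empty; fraction undefined")
  d <- sqrt(rowSums((frame[u$bead_i, , drop = FALSE] -
                     frame[u$bead_j, , drop = FALSE])^2))
  mean(d <= criterion * u$r0)
}

#' Per-frame state-specific contact fractions and discrete labels
#'
#' Computes, for every frame, the fraction of formed contacts in each
#' state-characterizing subset (CC-specific, OC, ITC-unique), the E-wing
#' contact flag and gate distance when the groups are supplied, and the
#' discrete state label via [assign_state()].
#'
#' @param trajectory A `cg_trajectory`.
#' @param contacts A [contact_sets()].
#' @param groups Optional list with `ewing` (union-set rows) and `gate_loop` /
#'   `gate_anchor` (bead ids), as returned by [build_toy_pic()].
#' @param params An [analysis_params()].
#' @return Object of class `state_trace`: data frame `step`, `f_cc`, `f_oc`,
#'   `f_itc`, `ewing`, `gate`, `label`.
#' @export
state_trace <- function(trajectory, contacts, groups = NULL,
                        params = analysis_params()) {
  nf <- dim(trajectory$frames)[1]
  crit <- params$formation_criterion
  safe_frac <- function(frame, subset) {
    if (!length(subset)) return(NA_real_)
    contact_fraction(frame, contacts, subset, crit)
  }
  rows <- lapply(seq_len(nf), function(f) {
    fr <- trajectory$frames[f, , ]
    data.frame(
      step = trajectory$steps[f],
      f_cc = safe_frac(fr, contacts$cc_specific),
      f_oc = safe_frac(fr, contacts$oc_set),
      f_itc = safe_frac(fr, contacts$itc_unique),
      ewing = if (!is.null(groups$ewing) && length(groups$ewing))
        contact_fraction(fr, contacts, groups$ewing, crit) else NA_real_,
      gate = if (!is.null(groups$gate_loop))
        gate_distance(fr, groups[c("gate_loop", "gate_anchor")]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  gate_open <- params$gate_open_distance
  if (is.null(gate_open) && !all(is.na(out$gate))) {
    dec <- out$gate[seq_len(max(2, floor(nf / 10)))]
    gate_open <- mean(dec) + 2 * sd(dec)
  }
  out$label <- assign_state(out, params,
                            ewing_formed = !is.na(out$ewing) & out$ewing >= 0.5,
                            gate_open = if (all(is.na(out$gate))) NULL
                                        else out$gate > (gate_open %||% Inf))
  class(out) <- c("state_trace", "data.frame")
  attr(out, "gate_open_distance") <- gate_open
  out
}

#' Assign discrete state labels from contact fractions
#'
#' Deterministic labeling from the three state fractions (with optional
#' E-wing/gate auxiliary flags): CC when the CC-specific fraction is high;
#' pre-OC when CC-specific contacts are largely lost and an intermediate
#' fraction of OC contacts has formed; OC when the OC fraction is high and
#' ITC-unique contacts are absent; I1/I2 at intermediate ITC-unique fractions
#' (split by whether the E-wing contact persists); ITC when the ITC-unique
#' fraction is high; otherwise unassigned.
#'
#' @param fractions Data frame with `f_cc`, `f_oc`, `f_itc` columns (NA
#'   fractions are treated as 0).
#' @param params An [analysis_params()] (cutoffs in `state_thresholds`).
#' @param ewing_formed Optional logical per frame: E-wing contact present.
#' @param gate_open Optional logical per frame: gate open.
#' @return Factor with levels CC, pre-OC, OC, I1, I2, ITC, unassigned.
#' @export
assign_state <- function(fractions, params = analysis_params(),
                         ewing_formed = NULL, gate_open = NULL) {
  th <- params$state_thresholds
  f_cc <- ifelse(is.na(fractions$f_cc), 0, fractions$f_cc)
  f_oc <- ifelse(is.na(fractions$f_oc), 0, fractions$f_oc)
  f_itc <- ifelse(is.na(fractions$f_itc), 0, fractions$f_itc)
  n <- length(f_cc)
  if (is.null(ewing_formed)) ewing_formed <- rep(TRUE, n)
  lab <- rep("unassigned", n)
  lab[f_itc >= th[["itc_hi"]]] <- "ITC"
  mid_itc <- f_itc >= th[["itc_lo"]] & f_itc < th[["itc_hi"]] & lab == "unassigned"
  lab[mid_itc & ewing_formed] <- "I1"
  lab[mid_itc & !ewing_formed] <- "I2"
  oc <- f_oc >= th[["oc_hi"]] & f_itc < th[["itc_lo"]] & lab == "unassigned"
  lab[oc] <- "OC"
  pre <- f_cc <= th[["cc_lo"]] & f_oc >= th[["oc_lo"]] & f_oc < th[["oc_hi"]] &
    f_itc < th[["itc_lo"]] & lab == "unassigned"
  lab[pre] <- "pre-OC"
  lab[f_cc >= th[["cc_hi"]] & lab == "unassigned"] <- "CC"
  factor(lab, levels = c("CC", "pre-OC", "OC", "I1", "I2", "ITC", "unassigned"))
}

#' Distance between the centers of mass of two bead groups
#'
#' Used for the fork-loop-1 / B-linker gate coordinate: the Euclidean
#' distance between the centers of mass of the two groups.
#'
#' @param frame `n x 3` coordinates.
#' @param gate_groups List of two bead-id vectors (e.g. `gate_loop`,
#'   `gate_anchor`).
#' @return Distance, Angstrom.
#' @export
gate_distance <- function(frame, gate_groups) {
  g1 <- gate_groups[[1]]; g2 <- gate_groups[[2]]
  if (!length(g1) || !length(g2)) stop("gate groups must be non-empty")
  if (any(c(g1, g2) > nrow(frame))) stop("gate group references missing beads")
  c1 <- colMeans(frame[g1, , drop = FALSE])
  c2 <- colMeans(frame[g2, , drop = FALSE])
  sqrt(sum((c1 - c2)^2))
}

#' Centered moving average with truncated edges
#'
#' @param series Numeric vector.
#' @param window Odd window length, at most `length(series)`.
#' @return Smoothed vector of the same length; near the edges the window is
#'   truncated to the available points.
#' @export
moving_average <- function(series, window) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window > length(series)) stop("window longer than the series")
  h <- (window - 1) / 2
  n <- length(series)
  vapply(seq_len(n), function(i)
    mean(series[max(1, i - h):min(n, i + h)]), 1.0)
}

#' Minimal RMSD under rigid superposition (Kabsch)
#'
#' Superposes `coordsB` onto `coordsA` over the selection by the Kabsch
#' algorithm (optimal rotation after centroid removal, with reflection
#' correction) and returns the root-mean-square deviation over that selection.
#'
#' @param coordsA,coordsB `n x 3` coordinate matrices.
#' @param selection Row indices used for both fitting and the RMSD
#'   (default: all rows).
#' @return RMSD, Angstrom.
#' @export
kabsch_rmsd <- function(coordsA, coordsB, selection = NULL) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]; B <- B[selection, , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) stop("selection sizes differ")
  if (nrow(A) < 3) stop("need at least 3 points")
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A - B %*% t(R))^2)))
}

#' Write a per-frame state trace as TSV
#'
#' One row per frame: step, bubble size (when supplied), the three state
#' fractions, E-wing fraction, gate distance and discrete label.
#'
#' @param trace A [state_trace()] data frame.
#' @param path Output file.
#' @param bubble Optional [bubble_trace()] merged in by step.
#' @return The path, invisibly.
#' @export
write_state_trace_tsv <- function(trace, path, bubble = NULL) {
  out <- as.data.frame(trace)
  if (!is.null(bubble))
    out$bubble <- bubble$bubble[match(out$step, bubble$step)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
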