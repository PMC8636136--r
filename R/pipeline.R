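# End-to-end protocols: the mismatch-melt / revert route from the closed to
# the open complex, the open-to-initially-transcribing route with optional
# E-wing weakening and gate restraint, duplex break-rate calibration, and
# ensemble reports.

.run_safe <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = conditionMessage(e)))
}

.terminal_label <- function(trace, tail_frac = 0.1) {
  n <- nrow(trace)
  use <- seq(max(1, n - max(1, floor(tail_frac * n)) + 1), n)
  tab <- table(trace$label[use])
  names(tab)[which.max(tab)]
}

#' Closed-to-open protocol: mismatch melt, pause detection, sequence revert
#'
#' Per run: introduce the mismatch into the promoter window, simulate
#' `steps_melt` steps from the closed-complex pose, detect the pre-OC/OC pause
#' (the state label must be stable over the trailing `dwell_frac` of the melt
#' segment), revert to the native sequence, and simulate `steps_revert`
#' further steps. Reports per-run terminal labels and post-revert bubble
#' statistics.
#'
#' @param system A [build_toy_pic()] result (or compatible list with
#'   `topology`, `refset`, `contacts`, `groups`).
#' @param n_runs Number of independent runs.
#' @param steps_melt,steps_revert Steps per segment.
#' @param seeds Integer vector of per-run seeds (default `1:n_runs`).
#' @param params,anal_params Energy and analysis parameter objects.
#' @param save_interval Frame stride.
#' @param dwell_frac Fraction of the melt segment over which the label must be
#'   stable to count as a pause.
#' @param bubble_window TSS-relative interval for bubble counting (default
#'   the system's mismatch window).
#' @return Object of class `ensemble_summary`; `$runs` holds per-run traces.
#' @export
protocol_cc_to_oc <- function(system, n_runs = 5, steps_melt = 120000,
                              steps_revert = 60000, seeds = seq_len(n_runs),
                              params = energy_params(),
                              anal_params = analysis_params(),
                              save_interval = 200, dwell_frac = 0.1,
                              bubble_window = NULL) {
  stopifnot(length(seeds) == n_runs)
  bubble_window <- bubble_window %||% system$spec$mismatch_window
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- .run_safe({
      top_m <- apply_mismatch(system$topology)
      tr1 <- run_langevin(system$refset$coords$cc, top_m, system$contacts,
                          params, sim_config(n_steps = steps_melt, seed = seeds[r],
                                             save_interval = save_interval,
                                             temperature = params$temperature))
      st1 <- state_trace(tr1, system$contacts, system$groups, anal_params)
      bt1 <- bubble_trace(tr1, anal_params$break_threshold, bubble_window)
      n1 <- nrow(st1)
      dwell <- seq(max(1, n1 - max(1, floor(dwell_frac * n1)) + 1), n1)
      paused <- length(unique(st1$label[dwell])) == 1L
      top_r <- revert_mismatch(top_m)
      tr2 <- run_langevin(tr1$final_coords, top_r, system$contacts, params,
                          sim_config(n_steps = steps_revert,
                                     seed = seeds[r] + 1000L,
                                     save_interval = save_interval,
                                     temperature = params$temperature),
                          velocities = tr1$final_velocities)
      st2 <- state_trace(tr2, system$contacts, system$groups, anal_params)
      bt2 <- bubble_trace(tr2, anal_params$break_threshold, bubble_window)
      half <- seq(floor(nrow(bt2) / 2) + 1, nrow(bt2))
      list(seed = seeds[r], paused = paused,
           pause_label = .terminal_label(st1, dwell_frac),
           terminal_label = .terminal_label(st2, dwell_frac),
           melt_bubble = bubble_stats(bt1, seq(floor(nrow(bt1) / 2) + 1, nrow(bt1))),
           revert_bubble = bubble_stats(bt2, half),
           melt_trace = st1, revert_trace = st2,
           melt_bubble_trace = bt1, revert_bubble_trace = bt2)
    })
    runs[[r]] <- res
  }
  .summarize_ensemble(runs, protocol = "cc_to_oc", n_runs = n_runs)
}

#' Open-to-ITC protocol: long runs, optional E-wing weakening, gate restraint
#'
#' Per run: start from the open-complex pose (native sequence), optionally
#' weaken the E-wing-analog contact wells by `weaken_factor`, optionally
#' restrain the gate loop shut, simulate `n_steps`, and label the terminal
#' state. Gate-opening events (upward crossings of the gate-open distance)
#' and I2 dwell frames are extracted from the traces.
#'
#' @inheritParams protocol_cc_to_oc
#' @param n_steps Steps per run.
#' @param weaken_factor Multiplier on the E-wing-analog well depths
#'   (`NULL` = untouched control).
#' @param restrain_gate If `TRUE`, pin the gate loop at its native (shut)
#'   conformation.
#' @return An `ensemble_summary`.
#' @export
protocol_oc_to_itc <- function(system, n_runs = 5, n_steps = 60000,
                               weaken_factor = NULL, restrain_gate = FALSE,
                               seeds = seq_len(n_runs),
                               params = energy_params(),
                               anal_params = analysis_params(),
                               save_interval = 200) {
  stopifnot(length(seeds) == n_runs)
  contacts <- system$contacts
  if (!is.null(weaken_factor))
    contacts <- weaken_contacts(contacts, system$groups$ewing, weaken_factor)
  top <- system$topology
  if (restrain_gate)
    top <- restrain_group(top, system$groups$gate_loop)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- .run_safe({
      tr <- run_langevin(system$refset$coords$oc, top, contacts, params,
                         sim_config(n_steps = n_steps, seed = seeds[r],
                                    save_interval = save_interval,
                                    temperature = params$temperature))
      st <- state_trace(tr, contacts, system$groups, anal_params)
      bt <- bubble_trace(tr, anal_params$break_threshold)
      gate_open_d <- anal_params$gate_open_distance %||%
        attr(st, "gate_open_distance")
      open <- !is.na(st$gate) & st$gate > gate_open_d
      events <- which(diff(c(FALSE, open)) == 1)
      list(seed = seeds[r], terminal_label = .terminal_label(st),
           i2_dwell_frames = sum(st$label == "I2"),
           gate_opening_steps = st$step[events],
           bubble = bubble_stats(bt, seq(floor(nrow(bt) / 2) + 1, nrow(bt))),
           trace = st, bubble_trace = bt)
    })
    runs[[r]] <- res
  }
  .summarize_ensemble(runs, protocol = "oc_to_itc", n_runs = n_runs,
                      weaken_factor = weaken_factor,
                      restrain_gate = restrain_gate)
}

.summarize_ensemble <- function(runs, protocol, n_runs, ...) {
  ok <- vapply(runs, function(r) r$ok, TRUE)
  good <- lapply(runs[ok], function(r) r$value)
  labels <- vapply(good, function(r) r$terminal_label, "")
  counts <- table(factor(labels,
                         levels = c("CC", "pre-OC", "OC", "I1", "I2", "ITC",
                                    "unassigned")))
  bub <- lapply(good, function(r) r[[grep("bubble$|revert_bubble", names(r))[1]]])
  per_state <- tapply(seq_along(labels), labels, function(ix) {
    m <- vapply(ix, function(i) bub[[i]][["mean"]], 1.0)
    c(mean = mean(m), sd = if (length(m) > 1) sd(m) else 0)
  })
  failed <- which(!ok)
  if (length(failed))
    message("ensemble: ", length(failed), " run(s) diverged and were excluded: ",
            paste(vapply(runs[failed], function(r) r$error, ""), collapse = "; "))
  structure(list(protocol = protocol, n_runs = n_runs,
                 n_completed = sum(ok), terminal_counts = counts,
                 terminal_labels = labels, bubble_by_state = per_state,
                 runs = good, failed = failed, options = list(...)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary [", x$protocol, "]: ", x$n_completed, "/", x$n_runs,
      " runs completed\n", sep = "")
  tc <- x$terminal_counts[x$terminal_counts > 0]
  cat("  terminal states: ",
      paste(names(tc), tc, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a machine- and human-readable ensemble report
#'
#' Emits `summary.json` (counts, per-run terminal labels, bubble statistics)
#' and, when `plots = TRUE`, PNG time-course plots (bubble size, state
#' fractions, gate distance with its moving average) into `dir`. Re-running
#' on the same summary reproduces identical JSON.
#'
#' @param summary An `ensemble_summary`.
#' @param dir Output directory (created if needed).
#' @param plots Also write plots.
#' @param ma_window Moving-average window for the gate-distance plot.
#' @return Invisibly, the path to `summary.json`.
#' @export
report_ensemble <- function(summary, dir, plots = FALSE, ma_window = 11) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    protocol = summary$protocol,
    package_version = as.character(utils::packageVersion("cgpic")),
    seeds = as.list(vapply(summary$runs, function(r) as.integer(r$seed), 1L)),
    n_runs = summary$n_runs,
    n_completed = summary$n_completed,
    terminal_counts = as.list(summary$terminal_counts),
    terminal_labels = as.list(unname(summary$terminal_labels)),
    bubble_by_state = lapply(summary$bubble_by_state, as.list),
    options = summary$options)
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots && length(summary$runs)) {
    r1 <- summary$runs[[1]]
    tr <- r1$trace %||% r1$revert_trace
    bt <- r1$bubble_trace %||% r1$revert_bubble_trace
    grDevices::png(file.path(dir, "timecourses.png"), width = 900, height = 900)
    par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
    plot(bt$step, bt$bubble, type = "l", xlab = "MD step",
         ylab = "bubble size (bp)")
    lines(bt$step, moving_average(bt$bubble, min(ma_window,
      nrow(bt) - (1 - nrow(bt) %% 2))), col = "blue")
    plot(tr$step, tr$f_cc, type = "l", col = "red", ylim = c(0, 1),
         xlab = "MD step", ylab = "contact fraction")
    lines(tr$step, tr$f_oc, col = "darkgreen")
    lines(tr$step, tr$f_itc, col = "purple")
    legend("topright", c("CC", "OC", "ITC"), lty = 1,
           col = c("red", "darkgreen", "purple"))
    if (!all(is.na(tr$gate))) {
      plot(tr$step, tr$gate, type = "l", xlab = "MD step",
           ylab = "gate distance (A)")
      lines(tr$step, moving_average(tr$gate, min(ma_window,
        nrow(tr) - (1 - nrow(tr) %% 2))), col = "blue")
    }
    dev.off()
  }
  invisible(path)
}

#' Per-pair base-pair break rate of a free duplex
#'
#' Builds an idealized duplex, runs equilibrium Langevin dynamics at the given
#' conditions (one run per seed), and returns the fraction of (frame, pair)
#' events with base-base distance above the threshold, pooled over runs after
#' discarding the burn-in.
#'
#' @param sequence Duplex template sequence.
#' @param n_steps Steps per run.
#' @param seeds Integer seeds.
#' @param params An [energy_params()].
#' @param threshold Break threshold, Angstrom (default 6.2).
#' @param save_interval Frame stride.
#' @param burn_in Fraction of frames discarded.
#' @return Break rate (fraction); attributes `n_events`, `n_broken`.
#' @export
duplex_break_rate <- function(sequence = "ACGTACGTACGTACGTACGT",
                              n_steps = 4e5, seeds = 1:3,
                              params = energy_params(), threshold = 6.2,
                              save_interval = 100, burn_in = 0.1) {
  dna <- build_bdna(sequence)
  broken <- 0; events <- 0
  for (sd in seeds) {
    tr <- run_langevin(dna$coords, dna, NULL, params,
                       sim_config(n_steps = n_steps, seed = sd,
                                  save_interval = save_interval,
                                  temperature = params$temperature))
    nf <- dim(tr$frames)[1]
    use <- seq(floor(burn_in * nf) + 1, nf)
    for (f in use) {
      d <- wc_distances(tr$frames[f, , ], dna)
      broken <- broken + sum(d > threshold)
      events <- events + length(d)
    }
  }
  rate <- broken / events
  attr(rate, "n_events") <- events
  attr(rate, "n_broken") <- broken
  rate
}

#' Calibrate the Watson-Crick well depth against the duplex break rate
#'
#' Scans candidate G:C well depths; for each, measures the free-duplex break
#' rate with [duplex_break_rate()] and returns the depth whose log-rate
#' interpolates to the target (rates decrease monotonically with depth). This
#' is the procedure that fixed the `eps_bp` default in [energy_params()].
#'
#' @param candidates Increasing vector of candidate depths, kcal/mol.
#' @param target_rate Target break rate (default 0.003).
#' @param ... Passed to [duplex_break_rate()].
#' @return List: `eps_bp` (interpolated), `table` (depth vs measured rate).
#' @export
calibrate_pairing_strength <- function(candidates = seq(3, 5, by = 0.25),
                                       target_rate = 0.003, ...) {
  rates <- vapply(candidates, function(e) {
    p <- energy_params(eps_bp = e)
    r <- duplex_break_rate(params = p, ...)
    # floor at half an event so a break-free scan can still be interpolated
    max(as.numeric(r), 0.5 / attr(r, "n_events"))
  }, 1.0)
  tab <- data.frame(eps_bp = candidates, rate = rates)
  if (all(rates > target_rate) || all(rates < target_rate))
    stop("target rate not bracketed by the candidate depths; measured range ",
         signif(min(rates), 3), " - ", signif(max(rates), 3))
  i <- max(which(rates > target_rate))
  # log-linear interpolation between the bracketing candidates
  lr <- log(rates[c(i, i + 1)])
  w <- (log(target_rate) - lr[1]) / (lr[2] - lr[1])
  list(eps_bp = candidates[i] + w * (candidates[i + 1] - candidates[i]),
       table = tab)
}
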