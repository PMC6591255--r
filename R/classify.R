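#' Classification configuration
#'
#' Thresholds used to assign a discrete dynamical regime to a simulated EEG
#' trace.  The regimes are: low/high saturated steady states (LS/HS), tonic
#' oscillations (TO, high-frequency low-amplitude), m-spike-and-wave
#' discharges (m-SWD, spikes riding a slow wave) and clonic oscillations
#' (CO, large slow cycles without narrow spikes).
#'
#' Defaults are calibrated against reference simulations: `ls_hs_split` is
#' the midpoint of the two saturated EEG levels at (c_tr, c_te) =
#' (0.15, 2.3) (LS, y = 0.174) and (0.15, 3) (HS, y = 0.528);
#' `to_freq_min = 10` Hz sits in the empty band between the fastest
#' non-tonic cycle (9.5 Hz) and the slowest tonic oscillation (14 Hz);
#' `spike_prominence = 0.008` keeps the faintest spike of the 4- and
#' 5-spike SWD patterns (prominence about 0.01) while rejecting sub-0.003
#' ripple.  A spike is a prominent local maximum whose width at half
#' prominence is below `spike_width_frac` of the fundamental period
#' (measured spikes are ~50 ms wide at half prominence versus wave crests
#' covering 40-85% of the cycle).
#'
#' @param steady_amplitude_tol peak-to-peak EEG threshold below which the
#'   tail of a trace counts as steady (default 1e-3).
#' @param ls_hs_split EEG level separating LS from HS steady states
#'   (default 0.351).
#' @param to_freq_min dominant-frequency floor (Hz) for tonic oscillations
#'   (default 10).
#' @param spike_prominence peak prominence threshold used when counting
#'   spikes per cycle (default 0.008).
#' @param spike_width_frac maximum width at half prominence of a spike,
#'   as a fraction of the fundamental period (default 0.25).
#' @param transient_discard initial transient discarded before analysis
#'   (s, default 5).
#' @return a `classification_config` object.
#' @export
classification_config <- function(steady_amplitude_tol = 1e-3,
                                  ls_hs_split = 0.351,
                                  to_freq_min = 10,
                                  spike_prominence = 0.008,
                                  spike_width_frac = 0.25,
                                  transient_discard = 5) {
  stopifnot(steady_amplitude_tol > 0, to_freq_min > 0, spike_prominence > 0,
            spike_width_frac > 0, transient_discard > 0)
  structure(list(steady_amplitude_tol = steady_amplitude_tol,
                 ls_hs_split = ls_hs_split, to_freq_min = to_freq_min,
                 spike_prominence = spike_prominence,
                 spike_width_frac = spike_width_frac,
                 transient_discard = transient_discard),
            class = "classification_config")
}

#' State label
#'
#' Discrete dynamical regime of a trace: one of `TO`, `LS`, `HS`, `SWD`,
#' `CO`, or `UNRESOLVED` when a trace cannot be labelled unambiguously
#' (e.g. an oscillation still dying out).  `m` (spike count per cycle) is
#' defined only for SWD.
#'
#' @param kind one of `"TO","LS","HS","SWD","CO","UNRESOLVED"`.
#' @param m integer spike count per cycle (SWD only).
#' @param dominant_frequency Hz; 0 for steady states.
#' @return a `state_label` object.
#' @export
state_label <- function(kind, m = NA_integer_, dominant_frequency = 0) {
  kind <- match.arg(kind, c("TO", "LS", "HS", "SWD", "CO", "UNRESOLVED"))
  if (kind == "SWD") {
    if (is.na(m) || m < 1) stop("SWD labels require a spike count m >= 1")
  } else if (!is.na(m)) {
    stop("m is defined only for SWD labels")
  }
  structure(list(kind = kind, m = as.integer(m),
                 dominant_frequency = dominant_frequency),
            class = "state_label")
}

#' Compact text form of a state label ("2-SWD", "LS", ...)
#' @param lab a [state_label()].
#' @return character scalar.
#' @export
format_label <- function(lab) {
  stopifnot(inherits(lab, "state_label"))
  if (lab$kind == "SWD") paste0(lab$m, "-SWD") else lab$kind
}

#' @export
print.state_label <- function(x, ...) {
  cat(format_label(x))
  if (x$dominant_frequency > 0)
    cat(sprintf(" (%.2f Hz)", x$dominant_frequency))
  cat("\n")
  invisible(x)
}

#' Dominant frequency of a trace
#'
#' Discards the initial transient, removes the mean and returns the
#' frequency of the largest FFT spectral peak.  A trace whose post-transient
#' peak-to-peak amplitude is below `steady_tol` is steady and returns 0.
#'
#' @param y numeric series.
#' @param dt sampling step (s).
#' @param transient_discard initial span to discard (s).
#' @param steady_tol steadiness peak-to-peak threshold.
#' @return dominant frequency in Hz (0 for steady traces).
#' @export
dominant_frequency <- function(y, dt, transient_discard = 5,
                               steady_tol = 1e-3) {
  n_keep <- length(y) - round(transient_discard / dt)
  if (n_keep * dt < 4)
    stop("series must extend at least 4 s beyond the discarded transient")
  v <- y[(length(y) - n_keep + 1):length(y)]
  if (diff(range(v)) < steady_tol) return(0)
  v <- v - mean(v)
  n <- length(v)
  spec <- Mod(stats::fft(v))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) / (n * dt)
  freqs[which.max(spec)]
}

#' Local extreme values of a trace
#'
#' All strict local maxima and minima values after the transient; a steady
#' trace returns its single level.  Used for one-parameter bifurcation-style
#' extrema sweeps.
#'
#' @inheritParams dominant_frequency
#' @return numeric vector of extreme values (sorted, unique).
#' @export
signal_extrema <- function(y, dt, transient_discard = 5,
                           steady_tol = 1e-3) {
  n_keep <- length(y) - round(transient_discard / dt)
  if (n_keep < 3) stop("series too short after transient discard")
  v <- y[(length(y) - n_keep + 1):length(y)]
  if (diff(range(v)) < steady_tol) return(mean(v))
  n <- length(v)
  core <- v[2:(n - 1)]
  is_max <- core > v[1:(n - 2)] & core > v[3:n]
  is_min <- core < v[1:(n - 2)] & core < v[3:n]
  sort(unique(core[is_max | is_min]))
}

# local maxima with topographic prominence and width at half prominence;
# returns a data.frame(index, prominence, width) (width in samples)
peak_census <- function(v, min_prominence) {
  n <- length(v)
  empty <- data.frame(index = integer(0), prominence = numeric(0),
                      width = integer(0))
  if (n < 3) return(empty)
  core <- v[2:(n - 1)]
  cand <- which(core > v[1:(n - 2)] & core >= v[3:n]) + 1L
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(i) {
    h <- v[i]
    left <- v[1:(i - 1)]
    right <- v[(i + 1):n]
    higher_l <- which(left > h)
    base_l <- min(left[if (length(higher_l)) (max(higher_l) + 1):(i - 1)
                       else seq_along(left)])
    higher_r <- which(right > h)
    base_r <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1)
                        else seq_along(right)])
    prom <- h - max(base_l, base_r)
    if (prom < min_prominence) return(NULL)
    half <- h - prom / 2
    wl <- i; while (wl > 1 && v[wl] > half) wl <- wl - 1L
    wr <- i; while (wr < n && v[wr] > half) wr <- wr + 1L
    data.frame(index = i, prominence = prom, width = wr - wl)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Spikes per cycle of an oscillatory trace
#'
#' Counts sharp spikes riding the slow wave: prominent local maxima whose
#' width at half prominence is below `width_frac` of the fundamental
#' period (the broad wave crest itself is excluded by this width test).
#' The trace is segmented into fundamental periods phase-anchored at the
#' tallest spike and the modal per-period count is returned — the `m` of
#' an m-SWD pattern.  Returns 0 when no narrow spike exists (clonic or
#' tonic cycles).
#'
#' @param y numeric series (analysed as given; discard transients first).
#' @param dt sampling step (s).
#' @param fundamental fundamental frequency (Hz), > 0.
#' @param prominence peak prominence threshold.
#' @param width_frac maximum spike width at half prominence as a fraction
#'   of the period.
#' @return integer modal spike count per cycle (0 if none).
#' @export
count_spikes_per_cycle <- function(y, dt, fundamental, prominence = 0.008,
                                   width_frac = 0.25) {
  stopifnot(fundamental > 0)
  period <- round(1 / (fundamental * dt))
  if (length(y) < 3 * period)
    stop("need at least 3 complete periods to count spikes per cycle")
  pk <- peak_census(y, prominence)
  spikes <- pk$index[pk$width <= width_frac * period]
  if (!length(spikes)) return(0L)
  anchor <- spikes[which.max(y[spikes])]
  start <- ((anchor - period %/% 4 - 1L) %% period) + 1L
  edges <- seq(start, length(y), by = period)
  if (length(edges) < 4)
    stop("need at least 3 complete periods to count spikes per cycle")
  counts <- vapply(seq_len(length(edges) - 1), function(k) {
    sum(spikes >= edges[k] & spikes < edges[k + 1])
  }, integer(1))
  counts <- counts[counts > 0]
  if (!length(counts)) return(0L)
  tb <- table(counts)
  as.integer(names(tb)[which.max(tb)])
}

# classify a raw EEG series (noise-free probe) given its sampling step
classify_series <- function(y, dt, cfg = classification_config()) {
  stopifnot(inherits(cfg, "classification_config"))
  n_keep <- length(y) - round(cfg$transient_discard / dt)
  if (n_keep < round(2 / dt))
    stop("trace too short for classification (need >= 2 s after transient)")
  v <- y[(length(y) - n_keep + 1):length(y)]
  tail_n <- min(length(v), round(5 / dt))
  tail_v <- v[(length(v) - tail_n + 1):length(v)]
  if (diff(range(tail_v)) < cfg$steady_amplitude_tol) {
    lvl <- mean(tail_v)
    return(state_label(if (lvl < cfg$ls_hs_split) "LS" else "HS"))
  }
  # a decaying oscillation (second half much smaller than the first) is
  # reported as UNRESOLVED rather than silently guessed
  half <- length(v) %/% 2
  if (diff(range(v[(half + 1):length(v)])) <
        0.3 * diff(range(v[1:half])))
    return(state_label("UNRESOLVED"))
  freq <- dominant_frequency(y, dt, transient_discard = cfg$transient_discard,
                             steady_tol = cfg$steady_amplitude_tol)
  if (freq >= cfg$to_freq_min)
    return(state_label("TO", dominant_frequency = freq))
  m <- tryCatch(count_spikes_per_cycle(v, dt, freq, cfg$spike_prominence,
                                       cfg$spike_width_frac),
                error = function(e) NA_integer_)
  if (is.na(m)) return(state_label("UNRESOLVED"))
  if (m >= 1L) return(state_label("SWD", m = m, dominant_frequency = freq))
  state_label("CO", dominant_frequency = freq)
}

#' Classify the dynamical regime of a trajectory
#'
#' Assigns one of LS, HS, TO, m-SWD, CO to a noise-free probe trajectory:
#' steady tails are split into LS/HS by their level; oscillations at or
#' above `to_freq_min` are TO; slow oscillations with narrow spikes riding
#' the wave are m-SWD (m = modal spike count per fundamental period);
#' remaining slow spike-free oscillations are CO.  Ambiguous traces (e.g.
#' a decaying oscillation) return an explicit `UNRESOLVED` label.
#'
#' @param traj a `tc_trajectory` (>= 10 s, noise-free).
#' @param cfg a [classification_config()].
#' @return a [state_label()].
#' @export
classify_state <- function(traj, cfg = classification_config()) {
  stopifnot(inherits(traj, "tc_trajectory"))
  classify_series(traj$y, traj$dt, cfg)
}
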