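#' Simulation configuration for a pulse-chase cytometry time course
#'
#' Builds and validates the parameter set for [simulate_time_course()]. The
#' defaults describe a fast-cycling root-meristem-like population: S phase of
#' 2.7 h inside a 7.2 h cycle, a 30 min label pulse, hourly chase sampling,
#' division with return of labeled 2C nuclei, a small residual-incorporation
#' rate producing the weakly labeled "arm", and multiplicative measurement
#' noise typical of good DNA-stain histograms.
#'
#' @param t_g1,t_s,t_g2m Phase durations in hours (G1, S, G2+M). All > 0.
#' @param pulse_len Label pulse length in hours (>= 0). A pulse of exactly 0
#'   marks cells in S at pulse end with one unit of label (instantaneous
#'   pulse idealization); a positive pulse accrues label in proportion to
#'   DNA synthesized during the pulse window.
#' @param chase_times Sorted chase sampling times in hours; must start at 0.
#' @param n_cells Number of (non-debris) nuclei per replicate at pulse start.
#' @param n_replicates Number of biological replicates to simulate.
#' @param dapi_gain DNA-stain channel gain (arbitrary units per C).
#' @param dapi_cv Coefficient of variation of the DNA-stain measurement.
#' @param label_gain Label channel gain (arbitrary units per unit of label,
#'   where 1 unit corresponds to a full genome replication's worth of
#'   synthesis under labeling).
#' @param label_cv Coefficient of variation of the label measurement.
#' @param label_background Additive label background (arbitrary units).
#' @param residual_rate Fraction of the pulse incorporation rate that
#'   persists at chase start (imperfect chase); 0 disables the residual arm.
#' @param residual_decay Exponential time constant (hours) of the residual
#'   incorporation rate during the chase.
#' @param noncycling_fraction Proportion of nuclei from non-proliferating
#'   cells (differentiated tissue in a root segment): fixed at 2C or 4C,
#'   never labeled, keeping the unlabeled reference peaks populated
#'   throughout the chase.
#' @param slow_fraction Proportion of cells with a prolonged S phase.
#' @param slow_factor Multiplier (>= 1) on the slow subpopulation's S
#'   duration, applied to chase-phase progression (cells synthesize
#'   normally during the brief pulse, then slow down); `Inf` encodes
#'   arrest (cells freeze at their current replicated fraction).
#' @param debris_fraction Proportion of recorded events that are sub-2C
#'   debris.
#' @param age_distribution `"uniform"` (default; cell-cycle ages uniform over
#'   the cycle, which makes the 0 h relative movement exactly 0.5 in
#'   expectation) or `"exponential_growth"` (age density proportional to
#'   `2^(-a / T_C)`, the steady state of an exponentially growing culture).
#' @param divide_labeled Should cells finishing G2/M divide into two 2C
#'   daughter nuclei (each carrying half the parent label) that re-enter G1
#'   and may start a second round of synthesis? If `FALSE`, cells
#'   accumulate at 4C.
#' @param daughter_cycling Probability that a daughter nucleus continues
#'   cycling after division; the rest park in G1 at 2C (a steady-state
#'   meristem sheds about half of each generation into the elongation
#'   zone). Only continuing daughters can start a second round of
#'   synthesis.
#' @param phase_cv Cell-to-cell coefficient of variation of the phase
#'   durations (lognormal, mean preserved). Desynchronizes division and
#'   re-entry so that labeled 2C return and any second round of synthesis
#'   build up gradually, as observed in real time courses; 0 gives fully
#'   deterministic kinetics (used by the analytic oracles).
#' @param seed Integer seed for the single pseudo-random stream driving the
#'   whole time course.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_time_course()], [closed_form_rm()]
#' @export
sim_config <- function(t_g1 = 1.0, t_s = 2.7, t_g2m = 4.5,
                       pulse_len = 0.5,
                       chase_times = 0:7,
                       n_cells = 20000L,
                       n_replicates = 1L,
                       dapi_gain = 100,
                       dapi_cv = 0.04,
                       label_gain = 5000,
                       label_cv = 0.10,
                       label_background = 10,
                       residual_rate = 0.02,
                       residual_decay = 1,
                       noncycling_fraction = 0.3,
                       slow_fraction = 0.3,
                       slow_factor = 6,
                       debris_fraction = 0.05,
                       age_distribution = c("uniform", "exponential_growth"),
                       divide_labeled = TRUE,
                       daughter_cycling = 0.35,
                       phase_cv = 0.25,
                       seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  cfg <- list(
    t_g1 = t_g1, t_s = t_s, t_g2m = t_g2m, pulse_len = pulse_len,
    chase_times = as.numeric(chase_times),
    n_cells = as.integer(n_cells), n_replicates = as.integer(n_replicates),
    dapi_gain = dapi_gain, dapi_cv = dapi_cv,
    label_gain = label_gain, label_cv = label_cv,
    label_background = label_background,
    residual_rate = residual_rate, residual_decay = residual_decay,
    noncycling_fraction = noncycling_fraction,
    slow_fraction = slow_fraction, slow_factor = slow_factor,
    debris_fraction = debris_fraction,
    age_distribution = age_distribution,
    divide_labeled = isTRUE(divide_labeled),
    daughter_cycling = daughter_cycling,
    phase_cv = phase_cv,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num_ok <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
  pos <- function(name) {
    x <- cfg[[name]]
    if (!num_ok(x) || !is.finite(x) || x <= 0)
      stop("sim_config: `", name, "` must be a finite positive number",
           call. = FALSE)
  }
  for (nm in c("t_g1", "t_s", "t_g2m", "dapi_gain", "label_gain",
               "residual_decay"))
    pos(nm)
  nonneg <- function(name, allow_inf = FALSE) {
    x <- cfg[[name]]
    if (!num_ok(x) || x < 0 || (!allow_inf && !is.finite(x)))
      stop("sim_config: `", name, "` must be a finite non-negative number",
           call. = FALSE)
  }
  for (nm in c("pulse_len", "dapi_cv", "label_cv", "label_background",
               "residual_rate", "phase_cv"))
    nonneg(nm)
  for (nm in c("slow_fraction", "debris_fraction", "noncycling_fraction",
               "daughter_cycling")) {
    nonneg(nm)
    if (cfg[[nm]] > 1)
      stop("sim_config: `", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  if (!num_ok(cfg$slow_factor) || is.na(cfg$slow_factor) ||
      cfg$slow_factor < 1)
    stop("sim_config: `slow_factor` must be >= 1 (Inf encodes arrest)",
         call. = FALSE)
  ct <- cfg$chase_times
  if (length(ct) < 1L || any(!is.finite(ct)) || is.unsorted(ct, strictly = TRUE) ||
      ct[1] != 0)
    stop("sim_config: `chase_times` must be strictly increasing and start at 0",
         call. = FALSE)
  if (cfg$n_cells < 1L || cfg$n_replicates < 1L)
    stop("sim_config: `n_cells` and `n_replicates` must be positive integers",
         call. = FALSE)
  invisible(cfg)
}

#' Theoretical relative movement of an ideal labeled cohort
#'
#' For a cohort labeled instantaneously while spread uniformly across S phase,
#' synthesizing DNA at a constant rate and never dividing, the mean replicated
#' fraction at scaled chase time `u = t / t_s` is `0.5 + u - u^2 / 2`: each
#' cell at initial replicated fraction `f` sits at `min(f + u, 1)`, and
#' averaging over `f ~ U(0, 1)` gives the closed form. The relative movement
#' equals this mean fraction, rising from 0.5 at pulse end to 1.0 when the
#' whole cohort has finished replication.
#'
#' @param u Scaled chase time `t / t_s`, in `[0, 1]`.
#' @return The relative-movement value `0.5 + u - u^2/2`.
#' @export
closed_form_rm <- function(u) {
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("closed_form_rm: `u` must lie in [0, 1]", call. = FALSE)
  0.5 + u - u^2 / 2
}

# Internal cell-population state: parallel vectors.
#   phase 1 = G1, 2 = S, 3 = G2M
#   pos    = time spent in current phase (h), for G1/G2M
#   sfrac  = replicated fraction, for S
#   s_dur  = per-cell S duration (h); Inf = arrested
#   label  = accumulated label (1 = a full replication's worth)
#   divided = has this nucleus been produced by a division during the chase
rdur <- function(n, mean_h, cv) {
  if (cv <= 0) return(rep(mean_h, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_h) - sdlog^2 / 2, sdlog = sdlog)
}

new_population <- function(cfg) {
  n <- cfg$n_cells
  g1_dur <- rdur(n, cfg$t_g1, cfg$phase_cv)
  s_dur <- rdur(n, cfg$t_s, cfg$phase_cv)
  g2m_dur <- rdur(n, cfg$t_g2m, cfg$phase_cv)
  # the slow/arrest multiplier applies once the chase starts (see
  # simulate_time_course); cycling history and the pulse use base rates
  slow <- stats::runif(n) < cfg$slow_fraction
  s_mult <- ifelse(slow, cfg$slow_factor, 1)
  t_c <- g1_dur + s_dur + g2m_dur
  u <- stats::runif(n)
  a <- switch(cfg$age_distribution,
    uniform = u * t_c,
    exponential_growth = -t_c * log2(1 - u / 2)
  )
  in_g1 <- a < g1_dur
  in_s <- !in_g1 & a < g1_dur + s_dur
  phase <- ifelse(in_g1, 1L, ifelse(in_s, 2L, 3L))
  pos <- numeric(n)
  sfrac <- numeric(n)
  pos[phase == 1L] <- a[phase == 1L]
  sfrac[phase == 2L] <- (a[phase == 2L] - g1_dur[phase == 2L]) /
    s_dur[phase == 2L]
  pos[phase == 3L] <- a[phase == 3L] - g1_dur[phase == 3L] -
    s_dur[phase == 3L]
  frozen <- stats::runif(n) < cfg$noncycling_fraction
  if (any(frozen)) {
    # non-proliferating nuclei: parked at 2C (mostly) or 4C, never labeled
    at_4c <- frozen & stats::runif(n) < 1 / 3
    phase[frozen] <- 1L
    phase[at_4c] <- 3L
    pos[frozen] <- 0
    sfrac[frozen] <- 0
  }
  list(phase = phase, pos = pos, sfrac = sfrac,
       g1_dur = g1_dur, s_dur = s_dur, g2m_dur = g2m_dur, s_mult = s_mult,
       label = numeric(n), divided = rep(FALSE, n), frozen = frozen)
}

# Advance every cell by `dt` hours starting at absolute chase time `t_start`
# (pulse end = 0). `avail` gives the label-precursor availability relative to
# the pulse: "none", "const" (pulse window), or "residual"
# (residual_rate * exp(-t / residual_decay) during the chase). Label accrues
# as availability times replicated-fraction increment. Cells finishing G2/M
# either divide into two G1 daughters with half the label each
# (divide_labeled) or stay parked at 4C.
advance_population <- function(pop, dt, t_start, avail, cfg) {
  remaining <- rep(dt, length(pop$phase))
  remaining[pop$frozen] <- 0
  repeat {
    act <- which(remaining > 1e-12)
    if (length(act) == 0L) break

    ph <- pop$phase[act]
    tau <- t_start + dt - remaining[act]  # per-cell absolute time

    # time left in current phase
    tleft <- numeric(length(act))
    g1 <- ph == 1L; s <- ph == 2L; g2 <- ph == 3L
    tleft[g1] <- pop$g1_dur[act[g1]] - pop$pos[act[g1]]
    tleft[s] <- (1 - pop$sfrac[act[s]]) * pop$s_dur[act[s]]
    tleft[g2] <- pop$g2m_dur[act[g2]] - pop$pos[act[g2]]
    tleft <- pmax(tleft, 0)

    step <- pmin(remaining[act], tleft)
    # arrested cells (infinite S): consume the whole step without progress
    arrested <- s & !is.finite(pop$s_dur[act])
    step[arrested] <- remaining[act][arrested]

    # progress
    i_g1 <- act[g1]; i_s <- act[s]; i_g2 <- act[g2]
    pop$pos[i_g1] <- pop$pos[i_g1] + step[g1]
    ds <- numeric(sum(s))
    fin <- is.finite(pop$s_dur[i_s])
    ds[fin] <- step[s][fin] / pop$s_dur[i_s][fin]
    pop$sfrac[i_s] <- pop$sfrac[i_s] + ds
    pop$pos[i_g2] <- pop$pos[i_g2] + step[g2]

    # label accrual during S
    if (avail != "none" && any(s)) {
      inc <- switch(avail,
        const = ds,
        residual = {
          td <- cfg$residual_decay
          tt <- tau[s]
          integ <- cfg$residual_rate * td *
            (exp(-tt / td) - exp(-(tt + step[s]) / td))
          out <- numeric(sum(s))
          out[fin] <- integ[fin] / pop$s_dur[i_s][fin]
          out
        })
      pop$label[i_s] <- pop$label[i_s] + inc
    }

    remaining[act] <- remaining[act] - step

    # phase transitions for cells that exhausted their phase with time left
    done <- act[step >= tleft - 1e-12 & remaining[act] > 1e-12 & !arrested]
    if (length(done)) {
      d_g1 <- done[pop$phase[done] == 1L]
      d_s <- done[pop$phase[done] == 2L]
      d_g2 <- done[pop$phase[done] == 3L]
      if (length(d_g1)) {
        pop$phase[d_g1] <- 2L
        pop$sfrac[d_g1] <- 0
      }
      if (length(d_s)) {
        pop$phase[d_s] <- 3L
        pop$sfrac[d_s] <- 1
        pop$pos[d_s] <- 0
      }
      if (length(d_g2)) {
        if (cfg$divide_labeled) {
          pop$phase[d_g2] <- 1L
          pop$pos[d_g2] <- 0
          pop$label[d_g2] <- pop$label[d_g2] / 2
          pop$divided[d_g2] <- TRUE
          # second daughter: duplicate rows, sharing the remaining time
          k <- length(d_g2)
          for (f in c("phase", "pos", "sfrac", "g1_dur", "s_dur",
                      "g2m_dur", "s_mult", "label", "divided", "frozen"))
            pop[[f]] <- c(pop[[f]], pop[[f]][d_g2])
          remaining <- c(remaining, remaining[d_g2])
          # a fraction of daughters leaves the proliferating pool at 2C
          if (cfg$daughter_cycling < 1) {
            dd <- c(d_g2, seq.int(length(pop$phase) - k + 1L,
                                  length(pop$phase)))
            exit <- dd[stats::runif(length(dd)) >= cfg$daughter_cycling]
            if (length(exit)) {
              pop$frozen[exit] <- TRUE
              remaining[exit] <- 0
            }
          }
        } else {
          pop$pos[d_g2] <- pop$g2m_dur[d_g2]
          remaining[d_g2] <- 0
        }
      }
    }
  }
  pop
}

# DNA content in C units per cell (2C in G1, 2C..4C in S, 4C in G2/M)
population_dna <- function(pop) {
  dna <- rep(2, length(pop$phase))
  s <- pop$phase == 2L
  dna[s] <- 2 * (1 + pop$sfrac[s])
  dna[pop$phase == 3L] <- 4
  dna
}

# Measure one snapshot: multiplicative Gaussian noise per channel, debris
# events appended below 2C.
measure_population <- function(pop, cfg, time_h, replicate) {
  n <- length(pop$phase)
  dna <- population_dna(pop)
  dapi <- cfg$dapi_gain * dna * (1 + stats::rnorm(n, 0, cfg$dapi_cv))
  label <- cfg$label_background +
    cfg$label_gain * pop$label * (1 + stats::rnorm(n, 0, cfg$label_cv))
  ssc <- exp(stats::rnorm(n, log(1000), 0.4))
  if (cfg$debris_fraction > 0) {
    nd <- round(n * cfg$debris_fraction / (1 - cfg$debris_fraction))
    if (nd > 0) {
      d_dapi <- cfg$dapi_gain * 2 * stats::runif(nd, 0.1, 0.9) *
        (1 + stats::rnorm(nd, 0, cfg$dapi_cv))
      d_label <- cfg$label_background * (1 + stats::rnorm(nd, 0, cfg$label_cv))
      d_ssc <- exp(stats::rnorm(nd, log(300), 0.6))
      dapi <- c(dapi, d_dapi)
      label <- c(label, d_label)
      ssc <- c(ssc, d_ssc)
    }
  }
  event_table(dapi = dapi, label = pmax(label, 0), ssc = ssc,
              sample = sprintf("sim_t%g_r%d", time_h, replicate),
              time_h = time_h, replicate = replicate)
}

#' Simulate a pulse-chase flow cytometry time course
#'
#' Generates one event table per chase time and replicate from a single
#' simulated population trajectory per replicate (the same labeled cohort is
#' followed through the chase, as in a real pulse-chase). Cells progress
#' through G1, S and G2/M at constant within-phase rates; cells in S during
#' the pulse window accumulate label in proportion to the DNA they
#' synthesize while the precursor is available; during the chase a residual
#' incorporation rate (decaying exponentially) produces weakly labeled
#' "arm" events; cells completing G2/M divide into two 2C daughter nuclei
#' carrying half the parent label each, traverse G1 and may re-enter S.
#' An optional slow or arrested subpopulation prolongs or freezes S-phase
#' progression. Measurement applies channel-specific multiplicative Gaussian
#' noise and appends sub-2C debris events.
#'
#' @param config A [sim_config()] object.
#' @return A `time_course` object (see [time_course()]): one
#'   [event_table()] per `(chase time, replicate)`.
#' @export
simulate_time_course <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  entries <- list()
  for (rep_id in seq_len(config$n_replicates)) {
    pop <- new_population(config)
    if (config$pulse_len > 0) {
      pop <- advance_population(pop, config$pulse_len,
                                t_start = -config$pulse_len,
                                avail = "const", cfg = config)
    } else {
      # instantaneous pulse: mark cells currently in S with a unit of label
      pop$label[pop$phase == 2L] <- 1
    }
    # slow or arrested progression takes effect for the chase
    pop$s_dur <- pop$s_dur * pop$s_mult
    t_prev <- 0
    for (t in config$chase_times) {
      if (t > t_prev) {
        avail <- if (config$residual_rate > 0) "residual" else "none"
        pop <- advance_population(pop, t - t_prev, t_start = t_prev,
                                  avail = avail, cfg = config)
        t_prev <- t
      }
      entries[[length(entries) + 1L]] <-
        measure_population(pop, config, time_h = t, replicate = rep_id)
    }
  }
  time_course(entries)
}

#' Write a simulated time course to per-sample files plus a manifest
#'
#' One CSV (or minimal FCS 3.1) file per `(time, replicate)` sample and a
#' YAML or JSON manifest listing `time_h`, `replicate`, `path` for each.
#'
#' @param tc A `time_course`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"fcs"`.
#' @param manifest_format `"yaml"` (default) or `"json"`.
#' @return The manifest path, invisibly.
#' @export
write_time_course <- function(tc, dir, format = c("csv", "fcs"),
                              manifest_format = c("yaml", "json")) {
  stopifnot(inherits(tc, "time_course"))
  format <- match.arg(format)
  manifest_format <- match.arg(manifest_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(tc$entries, function(et) {
    meta <- event_meta(et)
    fn <- sprintf("events_t%s_r%s.%s",
                  gsub("[^0-9a-zA-Z.]", "_", format(meta$time_h)),
                  meta$replicate, format)
    path <- file.path(dir, fn)
    if (format == "csv") write_events_csv(et, path) else write_fcs(et, path)
    list(time_h = meta$time_h, replicate = meta$replicate, path = fn)
  })
  mpath <- file.path(dir, paste0("manifest.", manifest_format))
  if (manifest_format == "yaml") {
    yaml::write_yaml(list(samples = rows), mpath)
  } else {
    jsonlite::write_json(list(samples = rows), mpath, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(mpath)
}
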