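#' Relative movement of the labeled cohort
#'
#' `RM = (F_L - F_G1) / (F_G2/M - F_G1)`: the labeled cohort's mean
#' DNA-stain fluorescence normalized between the unlabeled G1 and G2/M
#' means. Under ideal kinetics RM is 0.5 immediately after the pulse
#' (cohort spread uniformly between 2C and 4C) and reaches 1.0 when every
#' labeled nucleus has finished replication. Values slightly outside
#' [0, 1] can occur under measurement noise and are returned unclamped.
#'
#' @param stats A `population_stats` object from [gated_stats()], or any
#'   list with `f_l`, `f_g1`, `f_g2m`.
#' @return The RM value (dimensionless), or `NA` if the labeled gate was
#'   empty.
#' @export
relative_movement <- function(stats) {
  if (stats$f_g2m <= stats$f_g1)
    stop("relative_movement: degenerate populations (F_G2/M <= F_G1)",
         call. = FALSE)
  (stats$f_l - stats$f_g1) / (stats$f_g2m - stats$f_g1)
}

#' Assemble the pooled RM-versus-time series of a time course
#'
#' Gates are taken once per replicate from its 0 h sample and reused for
#' all of that replicate's time points; each sample contributes one
#' `(time, RM)` point. Points from all replicates are pooled into a single
#' series (the default, preserving replicate scatter for the regression);
#' `pooling = "averaged"` instead averages RM per time point across
#' replicates.
#'
#' @param tc A [time_course()].
#' @param gates Either a single `gate_set` applied to every replicate or a
#'   named list of gate sets keyed by replicate id; `NULL` (default) runs
#'   [auto_gates()] on each replicate's 0 h sample.
#' @param pooling `"pooled"` (default) or `"averaged"`.
#' @param ... Passed to [auto_gates()] when gates are derived here.
#' @return A `data.frame` of class `rm_series` with columns `time_h`,
#'   `rm`, `replicate`, `n_labeled`, `n_g1`, `n_g2m`. Samples with an
#'   empty labeled gate are dropped with a warning.
#' @export
assemble_series <- function(tc, gates = NULL, pooling = c("pooled", "averaged"),
                            ...) {
  stopifnot(inherits(tc, "time_course"))
  pooling <- match.arg(pooling)
  reps <- unique(tc$samples$replicate)
  if (is.null(gates)) {
    gates <- lapply(stats::setNames(reps, reps), function(r) {
      i <- which(tc$samples$replicate == r & tc$samples$time_h == 0)
      if (!length(i))
        stop("assemble_series: replicate ", r, " has no 0 h sample to gate on",
             call. = FALSE)
      auto_gates(tc$entries[[i[1]]], ...)
    })
  } else if (inherits(gates, "gate_set")) {
    gates <- lapply(stats::setNames(reps, reps), function(r) gates)
  }
  rows <- lapply(seq_along(tc$entries), function(i) {
    et <- tc$entries[[i]]
    meta <- event_meta(et)
    g <- gates[[as.character(meta$replicate)]]
    st <- gated_stats(et, g, is_t0 = meta$time_h == 0)
    if (st$missing_labeled) {
      warning(sprintf(
        "assemble_series: empty labeled gate at t=%g h replicate %s; point omitted",
        meta$time_h, as.character(meta$replicate)), call. = FALSE)
      return(NULL)
    }
    data.frame(time_h = meta$time_h, rm = relative_movement(st),
               replicate = as.character(meta$replicate),
               n_labeled = st$n_labeled, n_g1 = st$n_g1, n_g2m = st$n_g2m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (pooling == "averaged") {
    agg <- stats::aggregate(cbind(rm, n_labeled, n_g1, n_g2m) ~ time_h, out,
                            mean)
    out <- data.frame(time_h = agg$time_h, rm = agg$rm,
                      replicate = "averaged",
                      n_labeled = round(agg$n_labeled),
                      n_g1 = round(agg$n_g1), n_g2m = round(agg$n_g2m),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("rm_series", "data.frame")
  attr(out, "gates") <- gates
  out
}

#' Build an RM series from raw vectors
#'
#' Convenience constructor for fitting published or externally computed
#' `(time, RM)` observations.
#'
#' @param time_h Chase times in hours.
#' @param rm RM values.
#' @param replicate Optional replicate ids (recycled).
#' @return An `rm_series` data frame.
#' @export
rm_series <- function(time_h, rm, replicate = "1") {
  stopifnot(length(time_h) == length(rm), all(is.finite(time_h)),
            all(is.finite(rm)), all(time_h >= 0))
  out <- data.frame(time_h = as.numeric(time_h), rm = as.numeric(rm),
                    replicate = as.character(replicate),
                    n_labeled = NA_integer_, n_g1 = NA_integer_,
                    n_g2m = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("rm_series", "data.frame")
  out
}

#' Write an RM series as TSV
#' @param series An `rm_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rm_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
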