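#' Round half away from zero
#'
#' Reporting convention for durations (one decimal hour) and RM values
#' (two decimals): exact halves round up, unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' S-phase duration estimates from a segmented fit
#'
#' Two estimates are derived from the two-line model of the RM-versus-time
#' relationship: the breakpoint itself (`t_lower`, the chase time at which
#' the main labeled cohort has essentially completed replication) and the
#' extrapolation of the first segment to the theoretical RM of 1.0
#' (`t_upper = (1 - b0) / b1`, accounting for more slowly progressing
#' nuclei). The RM value at the breakpoint, `b0 + b1 psi`, indicates how
#' far below 1.0 the series plateaus (lowered by re-replicating or
#' arrested subpopulations).
#'
#' @param fit A `segmented_fit` from [fit_segmented()], or any list with
#'   `beta0`, `beta1`, `psi`.
#' @return An object of class `duration_estimate`: `t_lower`, `t_upper`,
#'   `rm_at_breakpoint` at full precision, plus `rounded` (durations to
#'   one decimal hour, RM to two decimals, half up).
#' @export
estimate_duration <- function(fit) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged) && is.null(fit$psi))
    stop("estimate_duration: no usable fit", call. = FALSE)
  if (fit$beta1 <= 0)
    stop("estimate_duration: first-segment slope <= 0; cohort not progressing",
         call. = FALSE)
  t_lower <- fit$psi
  t_upper <- (1 - fit$beta0) / fit$beta1
  rm_bp <- fit$beta0 + fit$beta1 * fit$psi
  structure(list(
    t_lower = t_lower, t_upper = t_upper, rm_at_breakpoint = rm_bp,
    rounded = list(t_lower = round_half_up(t_lower, 1),
                   t_upper = round_half_up(t_upper, 1),
                   rm_at_breakpoint = round_half_up(rm_bp, 2))),
    class = "duration_estimate")
}

#' @export
print.duration_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<duration_estimate> S-phase duration %.1f h (breakpoint) / %.1f h",
    " (extrapolated); RM at breakpoint %.2f\n"),
    x$rounded$t_lower, x$rounded$t_upper, x$rounded$rm_at_breakpoint))
  invisible(x)
}

#' Run the full estimation pipeline on a time-course manifest
#'
#' Loads the manifest, derives gates per replicate from the 0 h samples,
#' computes per-sample population statistics and RM values, pools them
#' into an RM series, fits the segmented two-line model, and converts it
#' into the pair of S-phase duration estimates. Writes a JSON report, the
#' RM series as TSV, and (optionally) an RM plot with both fitted
#' segments, the extrapolated first segment and the RM = 1.0 reference.
#' Rerunning on identical inputs produces a byte-identical report.
#'
#' @param manifest Path to a YAML/JSON time-course manifest (see
#'   [load_manifest()]).
#' @param out_dir Output directory, created if needed; `NULL` writes no
#'   files.
#' @param channel_map Passed to [read_events()].
#' @param pooling `"pooled"` (default) or `"averaged"` RM series assembly.
#' @param plot Write `rm_plot.pdf` (default TRUE when `out_dir` is set).
#' @param ... Passed to [auto_gates()].
#' @return A list with `series`, `gates`, `fit`, `duration`, `report`
#'   (the report also lands in `out_dir/report.json`).
#' @export
run_pipeline <- function(manifest, out_dir = NULL, channel_map = NULL,
                         pooling = "pooled", plot = !is.null(out_dir), ...) {
  tc <- load_manifest(manifest, channel_map = channel_map)
  if (length(unique(tc$samples$time_h)) < 4)
    stop("run_pipeline: need at least 4 distinct time points for the ",
         "segmented fit", call. = FALSE)
  series <- assemble_series(tc, pooling = pooling, ...)
  fit <- fit_segmented(series)
  dur <- estimate_duration(fit)
  gates <- attr(series, "gates")
  report <- list(
    schema = "rmphase/report/1",
    input = list(manifest = basename(manifest),
                 md5 = unname(tools::md5sum(manifest)),
                 n_samples = length(tc$entries)),
    gates = lapply(gates, unclass),
    rm_series = as.data.frame(series),
    fit = unclass(fit)[c("beta0", "beta1", "beta2", "psi", "slope1",
                         "slope2", "slope1_ci", "slope2_ci", "r2", "rss",
                         "davies_p", "n", "converged", "boundary")],
    duration = list(t_lower = dur$t_lower, t_upper = dur$t_upper,
                    rm_at_breakpoint = dur$rm_at_breakpoint,
                    rounded = dur$rounded))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_rm_series(series, file.path(out_dir, "rm_series.tsv"))
    if (plot) {
      grDevices::pdf(file.path(out_dir, "rm_plot.pdf"), width = 6,
                     height = 4.5)
      print(plot_rm_fit(series, fit, dur))
      grDevices::dev.off()
    }
  }
  list(series = series, gates = gates, fit = fit, duration = dur,
       report = report)
}

#' Plot an RM series with its segmented fit
#'
#' Mirrors the standard presentation of labeled-cohort kinetics: pooled
#' replicate points, the two fitted segments, the first segment
#' extrapolated (dashed) to the theoretical RM of 1.0 (dotted reference),
#' and a downward arrow at the breakpoint.
#'
#' @param series An `rm_series`.
#' @param fit A `segmented_fit`.
#' @param dur Optional `duration_estimate` (recomputed if missing).
#' @return A ggplot object.
#' @export
plot_rm_fit <- function(series, fit, dur = NULL) {
  if (is.null(dur)) dur <- estimate_duration(fit)
  t_max <- max(series$time_h)
  seg1 <- data.frame(x = c(min(series$time_h), fit$psi))
  seg1$y <- fit$beta0 + fit$beta1 * seg1$x
  seg2 <- data.frame(x = c(fit$psi, t_max))
  seg2$y <- fit$beta0 + fit$beta1 * seg2$x + fit$beta2 * (seg2$x - fit$psi)
  ext <- data.frame(x = c(fit$psi, min(dur$t_upper, t_max * 1.05)))
  ext$y <- fit$beta0 + fit$beta1 * ext$x
  rm_bp <- dur$rm_at_breakpoint
  ggplot2::ggplot(as.data.frame(series),
                  ggplot2::aes(x = .data$time_h, y = .data$rm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$replicate), size = 2) +
    ggplot2::geom_line(data = seg1, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.7) +
    ggplot2::geom_line(data = seg2, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.7) +
    ggplot2::geom_line(data = ext, ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = "dashed") +
    ggplot2::annotate("segment", x = fit$psi, xend = fit$psi,
                      y = rm_bp + 0.12, yend = rm_bp + 0.03,
                      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::labs(x = "Chase time (h)", y = "Relative movement (RM)",
                  shape = "Replicate") +
    ggplot2::theme_classic()
}

#' Bivariate cytogram of one sample
#'
#' Label fluorescence (log scale) versus DNA-stain fluorescence (linear),
#' optionally overlaid with gate boxes.
#'
#' @param et An [event_table()].
#' @param gates Optional `gate_set` to draw.
#' @param max_events Subsample cap for plotting.
#' @return A ggplot object.
#' @export
plot_cytogram <- function(et, gates = NULL, max_events = 20000) {
  df <- as.data.frame(et)
  if (nrow(df) > max_events)
    df <- df[sort(sample.int(nrow(df), max_events)), ]
  df$label_pos <- pmax(df$label, 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dapi,
                                        y = .data$label_pos)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "DNA-stain fluorescence (linear)",
                  y = "Label fluorescence (log)") +
    ggplot2::theme_classic()
  if (!is.null(gates)) {
    thr <- max(gates$full_label_threshold, 1)
    boxes <- data.frame(
      xmin = c(gates$g1_box[1], gates$g2m_box[1]),
      xmax = c(gates$g1_box[2], gates$g2m_box[2]),
      ymin = 1, ymax = max(gates$label_threshold, 1))
    p <- p +
      ggplot2::geom_rect(data = boxes,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = .data$ymin, ymax = .data$ymax),
                         inherit.aes = FALSE, fill = NA, colour = "black") +
      ggplot2::geom_hline(yintercept = thr, colour = "red",
                          linetype = "dashed")
  }
  p
}
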