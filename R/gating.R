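#' Derive a gate set from a 0 h sample
#'
#' Automates the bivariate gating used to follow a pulse-labeled cohort:
#' the two dominant modes of the DNA-stain distribution locate the
#' unlabeled G1 (2C) and G2/M (4C) peaks (their ratio must be 2 within
#' `mode_ratio_tol`); boxes of half-width `k` estimated CVs are drawn
#' around each; a label threshold separating labeled from unlabeled events
#' is set at the `label_quantile` quantile of label values inside the G1
#' box; a "fully labeled" threshold for excluding the residually labeled
#' low-intensity arm is set at `arm_factor` times the median label of the
#' 0 h labeled cohort; and a debris floor at half the G1 mode removes
#' sub-2C fragments.
#'
#' @param t0_events [event_table()] of the 0 h sample (both unlabeled
#'   peaks must be present).
#' @param k Gate half-width in estimated CVs (default 3, capturing > 99%
#'   of a Gaussian peak without bridging 2C and 4C).
#' @param mode_ratio_tol Allowed deviation of the G2/M-to-G1 mode ratio
#'   from 2 (default 0.2, i.e. accepted range 1.8-2.2).
#' @param label_quantile Quantile of G1-box label values defining the
#'   labeled/unlabeled threshold (default 0.995).
#' @param arm_factor Fraction of the 0 h labeled-cohort median label below
#'   which an event counts as residually labeled (default 0.1, encoding a
#'   10- to 100-fold dimmer arm).
#' @return An object of class `gate_set`: list with `g1_box`, `g2m_box`
#'   (numeric length-2 intervals on the DNA-stain axis), `label_threshold`,
#'   `full_label_threshold`, `debris_floor`, `g1_mode`, `g2m_mode`,
#'   `cv_hat`, `k`.
#' @export
auto_gates <- function(t0_events, k = 3, mode_ratio_tol = 0.2,
                       label_quantile = 0.995, arm_factor = 0.1) {
  dapi <- t0_events$dapi
  label <- t0_events$label
  modes <- find_two_modes(dapi)
  g1_mode <- modes[1]; g2m_mode <- modes[2]
  ratio <- g2m_mode / g1_mode
  if (ratio < 2 - mode_ratio_tol || ratio > 2 + mode_ratio_tol)
    stop(sprintf(
      "auto_gates: G2/M-to-G1 mode ratio %.3f outside [%.1f, %.1f]",
      ratio, 2 - mode_ratio_tol, 2 + mode_ratio_tol), call. = FALSE)

  # refine centers and spread on the events themselves (density mode
  # locations drift under smoothing); median/MAD are robust to the flat
  # S-phase arc crossing each window
  refine <- function(m) {
    w <- dapi[dapi >= 0.9 * m & dapi <= 1.1 * m]
    c(center = stats::median(w), spread = stats::mad(w))
  }
  g1 <- refine(g1_mode); g2m <- refine(g2m_mode)
  cv_hat <- unname(g1["spread"] / g1["center"])
  g1_box <- unname(g1["center"] * c(1 - k * cv_hat, 1 + k * cv_hat))
  g2m_box <- unname(g2m["center"] * c(1 - k * cv_hat, 1 + k * cv_hat))
  if (g1_box[2] >= g2m_box[1])
    stop("auto_gates: G1 and G2/M boxes overlap; peaks unresolved",
         call. = FALSE)
  debris_floor <- 0.5 * unname(g1["center"])
  in_g1 <- dapi >= g1_box[1] & dapi <= g1_box[2]
  if (!any(in_g1))
    stop("auto_gates: empty G1 box", call. = FALSE)
  # robust location/scale version of the G1-box label quantile: the box also
  # catches labeled nuclei that entered S just before sampling, so a raw
  # percentile would land among labeled values; median + z*MAD targets the
  # same quantile of the unlabeled (majority) label distribution
  zq <- stats::qnorm(label_quantile)
  lab_g1 <- label[in_g1]
  label_threshold <- stats::median(lab_g1) + zq * stats::mad(lab_g1)
  labeled0 <- label > label_threshold & dapi >= debris_floor &
    dapi >= g1_box[1] & dapi <= g2m_box[2]
  if (!any(labeled0))
    stop("auto_gates: no labeled events found in the 0 h sample",
         call. = FALSE)
  full_label_threshold <- max(arm_factor * stats::median(label[labeled0]),
                              label_threshold)
  structure(list(
    g1_box = g1_box, g2m_box = g2m_box,
    label_threshold = label_threshold,
    full_label_threshold = full_label_threshold,
    debris_floor = debris_floor,
    g1_mode = unname(g1["center"]), g2m_mode = unname(g2m["center"]),
    cv_hat = cv_hat, k = k), class = "gate_set")
}

# Two dominant, well-separated modes of a DNA-stain distribution, found on
# a Gaussian kernel density (Silverman-rule bandwidth). Modes closer than
# `min_sep` (ratio) to a taller mode are absorbed into it.
find_two_modes <- function(x, min_sep = 1.4) {
  if (length(unique(x)) < 2L)
    stop("auto_gates: DNA-stain values are degenerate", call. = FALSE)
  d <- stats::density(x, n = 1024)
  i <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (!length(i)) i <- which.max(d$y)
  peaks <- data.frame(x = d$x[i], y = d$y[i])
  peaks <- peaks[order(-peaks$y), , drop = FALSE]
  kept <- peaks[1, , drop = FALSE]
  for (j in seq_len(nrow(peaks))[-1]) {
    if (all(pmax(peaks$x[j] / kept$x, kept$x / peaks$x[j]) >= min_sep))
      kept <- rbind(kept, peaks[j, ])
    if (nrow(kept) == 2L) break
  }
  if (nrow(kept) < 2L)
    stop("auto_gates: fewer than two detectable DNA-content modes",
         call. = FALSE)
  sort(kept$x)
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<gate_set> G1 [%.4g, %.4g]  G2/M [%.4g, %.4g]\n",
    "  label > %.4g (labeled), >= %.4g (fully labeled); debris < %.4g\n"),
    x$g1_box[1], x$g1_box[2], x$g2m_box[1], x$g2m_box[2],
    x$label_threshold, x$full_label_threshold, x$debris_floor))
  invisible(x)
}

#' Serialize / deserialize a gate set as JSON
#' @param gates A `gate_set`.
#' @param path JSON file path.
#' @return `write_gates`: `path` invisibly; `read_gates`: a `gate_set`.
#' @export
write_gates <- function(gates, path) {
  jsonlite::write_json(unclass(gates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(g, class = "gate_set")
}

#' Per-gate population statistics for one sample
#'
#' Computes the mean DNA-stain fluorescence of the unlabeled G1 and G2/M
#' populations and of the labeled S-phase cohort, applying the cohort
#' exclusion rules: residually labeled events (below the fully-labeled
#' threshold) are never counted, and after 0 h the cohort's lower
#' DNA-stain bound moves from the G1 box's lower edge up to its upper
#' edge so that labeled nuclei that divided and returned to 2C are
#' excluded.
#'
#' @param events An [event_table()].
#' @param gates A `gate_set` from [auto_gates()] (computed once per
#'   replicate from its 0 h sample and reused across time points).
#' @param is_t0 Is this the 0 h sample? Controls the returned-G1 exclusion.
#' @return An object of class `population_stats`: list with `f_l`, `f_g1`,
#'   `f_g2m` (mean DNA-stain per gate; `f_l` is `NA` with
#'   `missing_labeled = TRUE` when the cohort gate is empty), and counts
#'   `n_labeled`, `n_g1`, `n_g2m`, `n_events`, `n_debris`.
#' @export
gated_stats <- function(events, gates, is_t0) {
  stopifnot(inherits(gates, "gate_set"))
  dapi <- events$dapi
  label <- events$label
  keep <- dapi >= gates$debris_floor
  unl <- label <= gates$label_threshold & keep
  in_g1 <- unl & dapi >= gates$g1_box[1] & dapi <= gates$g1_box[2]
  in_g2m <- unl & dapi >= gates$g2m_box[1] & dapi <= gates$g2m_box[2]
  if (!any(in_g1) || !any(in_g2m))
    stop("gated_stats: empty unlabeled G1 or G2/M gate", call. = FALSE)
  lower <- if (isTRUE(is_t0)) gates$g1_box[1] else gates$g1_box[2]
  coh <- keep & label > gates$label_threshold &
    label >= gates$full_label_threshold &
    dapi >= lower & dapi <= gates$g2m_box[2]
  f_g1 <- mean(dapi[in_g1])
  f_g2m <- mean(dapi[in_g2m])
  if (f_g1 >= f_g2m)
    stop("gated_stats: G1 mean not below G2/M mean", call. = FALSE)
  f_l <- if (any(coh)) mean(dapi[coh]) else NA_real_
  structure(list(
    f_l = f_l, f_g1 = f_g1, f_g2m = f_g2m,
    n_labeled = sum(coh), n_g1 = sum(in_g1), n_g2m = sum(in_g2m),
    n_events = length(dapi), n_debris = sum(!keep),
    missing_labeled = !any(coh)), class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(
    "<population_stats> F_L=%.4g (n=%d)  F_G1=%.4g (n=%d)  F_G2/M=%.4g (n=%d)\n",
    x$f_l, x$n_labeled, x$f_g1, x$n_g1, x$f_g2m, x$n_g2m))
  invisible(x)
}
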