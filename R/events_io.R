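#' Construct an event table
#'
#' An event table holds per-nucleus fluorescence measurements for one
#' sample: linear DNA-stain values (`dapi`), linear label values (`label`;
#' conventionally displayed on a log scale), and optional side scatter
#' (`ssc`), with sample metadata attached as attributes.
#'
#' @param dapi,label Numeric vectors of equal length; finite, `dapi > 0`.
#' @param ssc Optional numeric vector of side-scatter values.
#' @param sample Sample label.
#' @param time_h Chase time in hours (>= 0).
#' @param replicate Replicate identifier.
#' @return A `data.frame` of class `event_table` with columns `dapi`,
#'   `label` and (if given) `ssc`.
#' @export
event_table <- function(dapi, label, ssc = NULL, sample = "",
                        time_h = NA_real_, replicate = NA) {
  if (length(dapi) != length(label))
    stop("event_table: `dapi` and `label` must have the same length",
         call. = FALSE)
  if (any(!is.finite(dapi)) || any(!is.finite(label)))
    stop("event_table: fluorescence values must be finite", call. = FALSE)
  if (!is.na(time_h) && time_h < 0)
    stop("event_table: chase time must be >= 0", call. = FALSE)
  df <- data.frame(dapi = as.numeric(dapi), label = as.numeric(label))
  if (!is.null(ssc)) {
    if (length(ssc) != length(dapi))
      stop("event_table: `ssc` length mismatch", call. = FALSE)
    df$ssc <- as.numeric(ssc)
  }
  attr(df, "sample") <- sample
  attr(df, "time_h") <- as.numeric(time_h)
  attr(df, "replicate") <- replicate
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  m <- event_meta(x)
  cat(sprintf("<event_table> %d events  sample=%s  t=%g h  replicate=%s\n",
              nrow(x), m$sample, m$time_h, as.character(m$replicate)))
  invisible(x)
}

#' Metadata of an event table
#' @param et An `event_table`.
#' @return A list with `sample`, `time_h`, `replicate`.
#' @export
event_meta <- function(et) {
  list(sample = attr(et, "sample"), time_h = attr(et, "time_h"),
       replicate = attr(et, "replicate"))
}

#' Construct a time course from event tables
#'
#' @param entries List of [event_table()] objects, each carrying `time_h`
#'   and `replicate` metadata. Entries are sorted by time then replicate.
#' @param require_t0 Require a 0 h entry for every replicate (default TRUE).
#' @return An object of class `time_course`: a list with `entries` and an
#'   index data frame `samples` (`time_h`, `replicate`).
#' @export
time_course <- function(entries, require_t0 = TRUE) {
  times <- vapply(entries, function(e) event_meta(e)$time_h, numeric(1))
  reps <- vapply(entries, function(e) as.character(event_meta(e)$replicate),
                 character(1))
  ord <- order(times, reps)
  entries <- entries[ord]
  times <- times[ord]; reps <- reps[ord]
  if (anyDuplicated(paste(times, reps)))
    stop("time_course: duplicate (time, replicate) pair", call. = FALSE)
  if (require_t0) {
    no_t0 <- setdiff(unique(reps), reps[times == 0])
    if (length(no_t0))
      stop("time_course: replicate(s) without a 0 h sample: ",
           paste(no_t0, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries,
                 samples = data.frame(time_h = times, replicate = reps,
                                      stringsAsFactors = FALSE)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %d samples, %d time points, %d replicate(s)\n",
              length(x$entries), length(unique(x$samples$time_h)),
              length(unique(x$samples$replicate))))
  invisible(x)
}

#' Write an event table as CSV
#'
#' Fixed dialect: comma-separated, header row, UTF-8, '.' decimal, full
#' double precision.
#'
#' @param et An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(et, path) {
  df <- as.data.frame(et)
  for (cl in names(df)) df[[cl]] <- format(df[[cl]], digits = 17, trim = TRUE,
                                           scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

default_channel_map <- c(dapi = "dapi", label = "label", ssc = "ssc")

# Heuristic channel detection on FCS/CSV channel names: DNA stain from
# "DAPI"/"460", label from "488"/"FITC"/"530"/"AF", scatter from "SSC".
auto_channel_map <- function(names_avail) {
  find1 <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, names_avail, ignore.case = TRUE, value = TRUE)
      if (length(hit)) return(hit[1])
    }
    NA_character_
  }
  c(dapi = find1(c("^dapi$", "dapi", "460", "dna")),
    label = find1(c("^label$", "488", "fitc", "530", "\\baf\\b", "edu")),
    ssc = find1(c("^ssc", "side")))
}

resolve_channels <- function(names_avail, channel_map) {
  if (is.null(channel_map)) channel_map <- auto_channel_map(names_avail)
  need <- c("dapi", "label")
  for (ch in need) {
    nm <- channel_map[[ch]]
    if (is.null(nm) || is.na(nm) || !(nm %in% names_avail))
      stop("read_events: cannot resolve channel `", ch,
           "`; available channels: ", paste(names_avail, collapse = ", "),
           call. = FALSE)
  }
  channel_map
}

#' Read an event table from CSV or FCS
#'
#' CSV files are parsed by column header; FCS 3.0/3.1 list-mode files are
#' parsed from their TEXT and DATA segments, and log-amplified channels
#' (`$PnE` with a positive first parameter) are converted back to the
#' linear scale. With no `channel_map`, channels are auto-detected from
#' names containing "DAPI"/"460" (DNA stain), "488"/"FITC"/"530" (label)
#' and "SSC" (scatter).
#'
#' @param path File path (`.csv` or `.fcs`; FCS also detected by magic).
#' @param channel_map Named character vector mapping `dapi`, `label` and
#'   optionally `ssc` to channel names in the file, or `NULL` to
#'   auto-detect.
#' @param sample,time_h,replicate Metadata attached to the result.
#' @return An [event_table()].
#' @export
read_events <- function(path, channel_map = NULL, sample = basename(path),
                        time_h = NA_real_, replicate = NA) {
  if (!file.exists(path))
    stop("read_events: file not found: ", path, call. = FALSE)
  is_fcs <- grepl("\\.fcs$", path, ignore.case = TRUE) ||
    identical(substr(readChar(path, 6L, useBytes = TRUE), 1, 3), "FCS")
  if (is_fcs) {
    raw <- read_fcs(path)
  } else {
    raw <- tryCatch(
      utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop("read_events: malformed CSV: ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  cm <- resolve_channels(names(raw), channel_map)
  ssc_name <- if ("ssc" %in% names(cm)) cm[["ssc"]] else NA_character_
  ssc <- if (!is.na(ssc_name) && ssc_name %in% names(raw))
    raw[[ssc_name]] else NULL
  event_table(dapi = raw[[cm[["dapi"]]]], label = raw[[cm[["label"]]]],
              ssc = ssc, sample = sample, time_h = time_h,
              replicate = replicate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a time-course manifest
#'
#' A manifest (YAML or JSON) lists one record per sample with fields
#' `time_h`, `replicate` and `path` (relative to the manifest directory),
#' either at top level or under a `samples` key. All referenced event files
#' are loaded and assembled into a time-sorted [time_course()].
#'
#' @param path Manifest path (`.yaml`/`.yml` or `.json`).
#' @param channel_map Passed to [read_events()].
#' @param allow_missing_t0 Proceed (with a warning) when a replicate lacks a
#'   0 h sample; default `FALSE` (error).
#' @return A `time_course`.
#' @export
load_manifest <- function(path, channel_map = NULL,
                          allow_missing_t0 = FALSE) {
  if (!file.exists(path))
    stop("load_manifest: file not found: ", path, call. = FALSE)
  m <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  samples <- m$samples %||% m
  if (!length(samples))
    stop("load_manifest: no samples listed in ", path, call. = FALSE)
  base <- dirname(path)
  key <- vapply(samples, function(s) paste(s$time_h, s$replicate),
                character(1))
  if (anyDuplicated(key))
    stop("load_manifest: duplicate (time, replicate) pair: ",
         key[duplicated(key)][1], call. = FALSE)
  entries <- lapply(samples, function(s) {
    p <- s$path
    if (!file.exists(p)) p <- file.path(base, s$path)
    if (!file.exists(p))
      stop("load_manifest: referenced file not found: ", s$path,
           call. = FALSE)
    read_events(p, channel_map = channel_map, sample = basename(p),
                time_h = as.numeric(s$time_h), replicate = s$replicate)
  })
  times <- vapply(entries, function(e) event_meta(e)$time_h, numeric(1))
  reps <- vapply(entries, function(e) as.character(event_meta(e)$replicate),
                 character(1))
  no_t0 <- setdiff(unique(reps), reps[times == 0])
  if (length(no_t0)) {
    warning("load_manifest: replicate(s) without a 0 h sample: ",
            paste(no_t0, collapse = ", "), call. = FALSE)
    if (!allow_missing_t0)
      stop("load_manifest: missing 0 h sample(s); pass ",
           "`allow_missing_t0 = TRUE` to proceed", call. = FALSE)
  }
  time_course(entries, require_t0 = FALSE)
}

## ---- minimal FCS 3.1 list-mode support ------------------------------------

#' Write an event table as a minimal FCS 3.1 file
#'
#' List mode, one dataset, single-precision float data (`$DATATYPE F`),
#' little-endian, linear amplification (`$PnE 0,0`).
#'
#' @param et An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(et, path) {
  df <- as.data.frame(et)
  chan <- names(df)
  npar <- length(chan)
  ntot <- nrow(df)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$NEXTDATA", "0",
          "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  for (i in seq_len(npar)) {
    rng <- as.character(ceiling(max(df[[i]], 1)))
    kw <- c(kw, sprintf("$P%dN", i), chan[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), rng)
  }
  # data offsets depend on TEXT length; pad BEGINDATA/ENDDATA to fixed width
  delim <- "/"
  build_text <- function(bd, ed) {
    paste0(delim,
           paste(c(kw, "$BEGINDATA", sprintf("%10d", bd),
                   "$ENDDATA", sprintf("%10d", ed)),
                 collapse = delim),
           delim)
  }
  header_len <- 58L
  probe <- build_text(0L, 0L)
  text_start <- header_len
  text_end <- text_start + nchar(probe, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_len <- 4L * npar * ntot
  data_end <- data_start + data_len - 1L
  text <- build_text(data_start, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(probe, type = "bytes"))
  hdr_off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   hdr_off(text_start), hdr_off(text_end),
                   if (data_end <= 99999999) hdr_off(data_start) else hdr_off(0),
                   if (data_end <= 99999999) hdr_off(data_end) else hdr_off(0),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  mat <- t(as.matrix(df))
  writeBin(as.vector(mat), con, size = 4L, endian = "little")
  invisible(path)
}

# Parse a minimal FCS 3.0/3.1 file: header offsets, TEXT keywords, list-mode
# DATA of type F (float32), D (float64) or I (unsigned int, byte-aligned
# $PnB). Log-amplified channels ($PnE = "d,r", d > 0) are de-logged to
# r * 10^(d * x / $PnR).
read_fcs <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!grepl("^FCS3", header))
    stop("read_fcs: not an FCS 3.x file: ", path, call. = FALSE)
  off <- function(i) {
    suppressWarnings(as.integer(trimws(substr(header, 11 + 8 * (i - 1),
                                              10 + 8 * i))))
  }
  ts <- off(1); te <- off(2); ds <- off(3); de <- off(4)
  if (any(is.na(c(ts, te))) || te <= ts || te > sz)
    stop("read_fcs: malformed header in ", path, call. = FALSE)
  seek(con, ts)
  text <- readChar(con, te - ts + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  kw <- stats::setNames(vals, keys)
  gv <- function(k, default = NA) {
    if (k %in% names(kw)) kw[[k]] else default
  }
  npar <- as.integer(gv("$PAR"))
  ntot <- as.integer(gv("$TOT"))
  dtype <- gv("$DATATYPE", "F")
  mode <- gv("$MODE", "L")
  byteord <- gv("$BYTEORD", "1,2,3,4")
  if (is.na(npar) || is.na(ntot) || mode != "L")
    stop("read_fcs: only list-mode files with $PAR/$TOT are supported",
         call. = FALSE)
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (is.na(ds) || ds == 0) ds <- as.integer(gv("$BEGINDATA"))
  if (is.na(de) || de == 0) de <- as.integer(gv("$ENDDATA"))
  if (is.na(ds) || is.na(de) || de <= ds)
    stop("read_fcs: cannot locate DATA segment in ", path, call. = FALSE)
  seek(con, ds)
  bits <- vapply(seq_len(npar),
                 function(i) as.integer(gv(sprintf("$P%dB", i), "32")),
                 integer(1))
  n_values <- npar * ntot
  if (dtype == "F") {
    x <- readBin(con, "numeric", n = n_values, size = 4L, endian = endian)
  } else if (dtype == "D") {
    x <- readBin(con, "numeric", n = n_values, size = 8L, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !(bits[1] %in% c(8L, 16L, 32L)))
      stop("read_fcs: integer data requires uniform $PnB of 8/16/32",
           call. = FALSE)
    x <- readBin(con, "integer", n = n_values, size = bits[1] / 8L,
                 signed = bits[1] > 16L, endian = endian)
    x <- as.numeric(x)
    x[x < 0] <- x[x < 0] + 2^bits[1]  # undo sign wrap for 32-bit
  } else {
    stop("read_fcs: unsupported $DATATYPE ", dtype, call. = FALSE)
  }
  if (length(x) < n_values)
    stop("read_fcs: truncated DATA segment in ", path, call. = FALSE)
  mat <- matrix(x, nrow = npar, ncol = ntot)
  cn <- vapply(seq_len(npar), function(i) {
    nm <- gv(sprintf("$P%dN", i), NA)
    if (is.na(nm) || nm == "") nm <- gv(sprintf("$P%dS", i),
                                        sprintf("P%d", i))
    nm
  }, character(1))
  out <- as.data.frame(t(mat))
  names(out) <- cn
  # de-log amplified channels
  for (i in seq_len(npar)) {
    pe <- strsplit(gv(sprintf("$P%dE", i), "0,0"), ",")[[1]]
    d <- suppressWarnings(as.numeric(pe[1]))
    r0 <- suppressWarnings(as.numeric(pe[2]))
    if (!is.na(d) && d > 0) {
      rng <- as.numeric(gv(sprintf("$P%dR", i), "1024"))
      if (is.na(r0) || r0 == 0) r0 <- 1
      out[[i]] <- r0 * 10^(d * out[[i]] / rng)
    }
  }
  out
}
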