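make_events <- function(n = 100, seed = 1) {
  set.seed(seed)
  event_table(dapi = runif(n, 100, 450), label = runif(n, 0, 1000),
              ssc = runif(n, 10, 5000), sample = "s", time_h = 1,
              replicate = "r1")
}

test_that("event tables validate their inputs", {
  expect_error(event_table(dapi = 1:3, label = 1:2), "same length")
  expect_error(event_table(dapi = c(1, NA), label = c(1, 2)), "finite")
  expect_error(event_table(dapi = 1, label = 1, time_h = -1), ">= 0")
})

test_that("CSV round trip preserves counts exactly and values to 1e-6", {
  et <- make_events(257)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(et, path)
  et2 <- read_events(path, time_h = 1, replicate = "r1")
  expect_identical(nrow(et2), nrow(et))
  for (cl in c("dapi", "label", "ssc"))
    expect_equal(et2[[cl]], et[[cl]], tolerance = 1e-6)
})

test_that("a plain dapi,label,ssc CSV parses directly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dapi,label,ssc", "200,10,1000", "300,500,1200",
               "400,12,900"), path)
  et <- read_events(path)
  expect_identical(nrow(et), 3L)
  expect_equal(et$dapi, c(200, 300, 400))
})

test_that("missing channels produce a resolution error naming what exists", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dapi,ssc", "200,1000"), path)
  err <- expect_error(
    read_events(path, channel_map = c(dapi = "dapi", label = "label")),
    "cannot resolve channel `label`")
  expect_match(conditionMessage(err), "dapi, ssc")
})

test_that("channels are auto-detected from instrument-style names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("DAPI-460/50-A,AF488-530/40-A,SSC-A",
               "200,10,1000", "300,500,1200"), path)
  et <- read_events(path)
  expect_equal(et$dapi, c(200, 300))
  expect_equal(et$label, c(10, 500))
})

test_that("FCS round trip recovers the table within float precision", {
  et <- make_events(300, seed = 2)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(et, path)
  et2 <- read_events(path, time_h = 1, replicate = "r1")
  expect_identical(nrow(et2), nrow(et))
  for (cl in c("dapi", "label", "ssc"))
    expect_equal(et2[[cl]], et[[cl]], tolerance = 1e-6)
})

test_that("log-amplified integer FCS channels are restored to linear scale", {
  # hand-built FCS 3.1 file: 2 parameters, 3 events, 16-bit integers,
  # channel 2 log-amplified over 4 decades ($P2E = 4,1, $P2R = 1024)
  path <- withr::local_tempfile(fileext = ".fcs")
  raw_vals <- c(100L, 256L, 200L, 512L, 300L, 1023L)  # interleaved d,l
  kw <- paste0("/$BEGINANALYSIS/0/$ENDANALYSIS/0/$BEGINSTEXT/0/$ENDSTEXT/0",
               "/$NEXTDATA/0/$MODE/L/$DATATYPE/I/$BYTEORD/1,2,3,4",
               "/$PAR/2/$TOT/3",
               "/$P1N/DAPI-A/$P1B/16/$P1E/0,0/$P1R/1024",
               "/$P2N/FITC-A/$P2B/16/$P2E/4,1/$P2R/1024")
  text_start <- 58L
  # reserve space for the data offsets appended below
  probe <- paste0(kw, "/$BEGINDATA/", sprintf("%8d", 0),
                  "/$ENDDATA/", sprintf("%8d", 0), "/")
  text_end <- text_start + nchar(probe) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 2L * length(raw_vals) - 1L
  text <- paste0(kw, "/$BEGINDATA/", sprintf("%8d", data_start),
                 "/$ENDDATA/", sprintf("%8d", data_end), "/")
  con <- file(path, "wb")
  writeChar(sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_start, text_end,
                    data_start, data_end, 0L, 0L),
            con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(raw_vals, con, size = 2L, endian = "little")
  close(con)
  et <- read_events(path)
  expect_equal(et$dapi, c(100, 200, 300))
  expect_equal(et$label, 10^(4 * c(256, 512, 1023) / 1024),
               tolerance = 1e-12)
})

write_manifest_fixture <- function(dir, times, reps = "1",
                                   format = "yaml") {
  rows <- list()
  for (r in reps) for (t in times) {
    et <- event_table(dapi = c(200, 300, 400), label = c(0, 500, 0),
                      sample = "x", time_h = t, replicate = r)
    fn <- sprintf("e_%s_%s.csv", t, r)
    write_events_csv(et, file.path(dir, fn))
    rows[[length(rows) + 1L]] <- list(time_h = t, replicate = r, path = fn)
  }
  mpath <- file.path(dir, paste0("manifest.", format))
  if (format == "yaml") yaml::write_yaml(list(samples = rows), mpath)
  else jsonlite::write_json(list(samples = rows), mpath, auto_unbox = TRUE)
  mpath
}

test_that("manifests load complete, time-sorted courses (yaml and json)", {
  for (fmt in c("yaml", "json")) {
    dir <- withr::local_tempdir()
    mpath <- write_manifest_fixture(dir, times = c(3, 0, 7, 1, 2, 5, 4, 6),
                                    format = fmt)
    tc <- load_manifest(mpath)
    expect_identical(length(tc$entries), 8L)
    expect_identical(tc$samples$time_h, as.numeric(0:7))
  }
})

test_that("manifest error paths: duplicates, missing files, missing 0 h", {
  dir <- withr::local_tempdir()
  mpath <- write_manifest_fixture(dir, times = c(0, 1))
  m <- yaml::read_yaml(mpath)
  m$samples[[2]]$time_h <- 0
  yaml::write_yaml(m, mpath)
  expect_error(load_manifest(mpath), "duplicate")

  mpath2 <- write_manifest_fixture(dir, times = c(0, 1))
  m <- yaml::read_yaml(mpath2)
  m$samples[[2]]$path <- "nope.csv"
  yaml::write_yaml(m, mpath2)
  expect_error(load_manifest(mpath2), "nope.csv")

  dir3 <- withr::local_tempdir()
  mpath3 <- write_manifest_fixture(dir3, times = c(1, 2))
  expect_error(suppressWarnings(load_manifest(mpath3)), "0 h")
  expect_warning(tc <- load_manifest(mpath3, allow_missing_t0 = TRUE),
                 "without a 0 h")
  expect_identical(length(tc$entries), 2L)
})
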