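test_that("delimited traces are read with unit conversion and dialect guessing", {
  dir <- withr::local_tempdir()
  t_ms <- seq(0.01, 1200, length.out = 118)
  f <- 500 + 1500 * (1 - exp(-t_ms / 50))

  tsv <- file.path(dir, "trace_ms.tsv")
  readr::write_tsv(tibble::tibble(time = t_ms, fluor = f), tsv)
  tr <- read_transient(tsv, time_unit = "ms", group = "mock")
  expect_equal(nrow(tr), 118)
  expect_equal(tr$time_us, t_ms * 1e3)
  expect_equal(tr$label, rep("trace_ms", 118))

  csv <- file.path(dir, "trace_us.csv")
  writeLines(paste(t_ms * 1e3, f, sep = ","), csv) # no header, comma dialect
  tr2 <- read_transient(csv, time_unit = "us")
  expect_equal(tr2$time_us, tr$time_us)
  expect_equal(tr2$fluor, tr$fluor)
})

test_that("write/read round-trips at full numeric precision", {
  dir <- withr::local_tempdir()
  tr <- simulate_ojip(ojip_scenario(noise_sd = 0.02), seed = 11,
                      label = "rt", group = "g")
  path <- file.path(dir, "rt.tsv")
  write_transient(tr, path, time_unit = "us")
  back <- read_transient(path, time_unit = "us", label = "rt", group = "g")
  expect_identical(back$time_us, tr$time_us)
  expect_identical(back$fluor, tr$fluor)

  mr <- simulate_mr(noise_sd = 0.01, seed = 3, label = "mr", group = "g")
  mpath <- file.path(dir, "mr.tsv")
  write_transient(mr, mpath, time_unit = "ms")
  mback <- read_mr_trace(mpath, time_unit = "ms", label = "mr", group = "g")
  expect_identical(mback$time_ms, mr$time_ms)
  expect_identical(mback$refl, mr$refl)
})

test_that("malformed rows are dropped with a count and bad time axes are hard errors", {
  dir <- withr::local_tempdir()
  t_ms <- seq(0.01, 500, length.out = 118)
  f <- as.character(500 + 3 * seq_along(t_ms))
  f[c(5, 50, 100)] <- "NA"
  path <- file.path(dir, "holes.tsv")
  writeLines(c("time\tsignal", paste(t_ms, f, sep = "\t")), path)
  expect_warning(tr <- read_transient(path, time_unit = "ms"),
                 "3 rows dropped")
  expect_equal(nrow(tr), 115)

  dup <- file.path(dir, "dup.tsv")
  t_bad <- t_ms
  t_bad[8] <- t_bad[7] # duplicated time stamp
  writeLines(paste(t_bad, 1:118, sep = "\t"), dup)
  expect_error(read_transient(dup, time_unit = "ms"), "row 8")

  short <- file.path(dir, "short.tsv")
  writeLines(paste(t_ms[1:6], 1:6, sep = "\t"), short)
  expect_error(read_transient(short, time_unit = "ms"), "fewer than 10")

  expect_error(read_transient(file.path(dir, "nope.tsv")), "not found")
})

test_that("transient validation enforces the time-axis and signal invariants", {
  tm <- c(10, 20, 50, 100, 200, 300, 500, 1000, 2000, 5000)
  expect_error(as_transient(tm[1:9], 1:9), "at least 10")
  expect_error(as_transient(tm + 100, 1:10), "before 50")
  expect_error(as_transient(tm, c(1:9, -5)), "non-negative")
  expect_error(as_mr_trace(c(1, 2, 3), c(1, 1, 1)), "0.7 ms")
  expect_error(as_mr_trace(c(0.5, 1, 2), c(1, 0, 1)), "positive")
})

test_that("interpolation is exact on samples, monotone between them, and matches closed forms", {
  tr <- as_transient(c(10, 30, 60, 100, 200, 400, 800, 1500, 3000, 6000),
                     c(100, 300, 420, 500, 640, 800, 980, 1200, 1500, 1800))
  # exact at a sample point
  expect_identical(fluor_at(tr, 60), 420)
  # linear rule midpoint of (10,100)-(30,300)
  expect_equal(fluor_at(tr, 20), 200)
  # log-time rule still exact at samples and lies between the brackets
  expect_equal(fluor_at(tr, 30, rule = "log-time"), 300)
  lt <- fluor_at(tr, 20, rule = "log-time")
  expect_gt(lt, 100)
  expect_lt(lt, 300)
  # monotone between ordered samples
  probes <- seq(10, 30, by = 1)
  expect_true(all(diff(fluor_at(tr, probes)) >= 0))
  # outside the sampled range
  expect_error(fluor_at(tr, 9), "outside")

  # dense exponential against the closed form
  dense <- exp_transient(0.3) # tau = 300 us
  expect_equal(fluor_at(dense, 300), 500 + 2000 * (1 - exp(-1)),
               tolerance = 1e-3)
})
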