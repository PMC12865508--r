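test_that("read_traps builds the operation matrix from deployment dates", {
  window <- as.Date(c("2023-02-15", "2023-05-16"))  # 91 days
  path <- write_trap_csv(52, window)
  traps <- read_traps(path, window, occasion_length = 1)
  expect_s3_class(traps, "trap_array")
  expect_equal(n_traps(traps), 52)
  expect_equal(n_occasions(traps), 91)
  expect_equal(effort(traps), 52 * 91)  # = 4732 trap-days

  # station retrieved before the window starts: all-zero row plus warning
  setup <- rep(window[1], 3)
  retr <- c(window[2], window[2], window[1] - 5)
  path2 <- write_trap_csv(3, window, setup = setup, retrieval = retr)
  expect_warning(t2 <- read_traps(path2, window), "outside the survey window")
  expect_equal(unname(rowSums(t2$operation)), c(91, 91, 0))

  # dates beyond the window are clipped with a warning
  path3 <- write_trap_csv(2, window, setup = rep(window[1] - 10, 2),
                          retrieval = rep(window[2] + 10, 2))
  expect_warning(t3 <- read_traps(path3, window), "clipped")
  expect_equal(effort(t3), 2 * 91)
})

test_that("read_traps validates its input", {
  window <- as.Date(c("2023-02-15", "2023-02-24"))
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(station = c("A", "A"), x = c(0, 1), y = c(0, 1),
                       setup_date = window[1], retrieval_date = window[2]),
            path, row.names = FALSE)
  expect_error(read_traps(path, window), "duplicate station")
  write.csv(data.frame(station = c("A", "B"), x = c(0, NA), y = c(0, 1),
                       setup_date = window[1], retrieval_date = window[2]),
            path, row.names = FALSE)
  expect_error(read_traps(path, window), "missing trap coordinates")
})

test_that("multi-day occasions bin operation days correctly", {
  window <- as.Date(c("2023-02-15", "2023-02-24"))  # 10 days
  path <- write_trap_csv(2, window)
  traps <- read_traps(path, window, occasion_length = 3)
  expect_equal(n_occasions(traps), 4)  # 3+3+3+1 days
  expect_true(all(traps$operation == 1))
})

test_that("build_capture_data deduplicates and bins a record table", {
  window <- as.Date(c("2023-03-01", "2023-03-10"))
  path <- write_trap_csv(4, window)
  traps <- read_traps(path, window)

  # two photos of one individual 40 s apart collapse into one event
  rec <- data.frame(
    station = c("S01", "S01", "S02"),
    datetime = as.POSIXct(c("2023-03-02 10:00:00", "2023-03-02 10:00:40",
                            "2023-03-03 09:00:00"), tz = "UTC"),
    individual = c("JF01", "JF01", "JF02"), stringsAsFactors = FALSE)
  cap <- build_capture_data(rec, traps)
  expect_equal(sum(cap$y_id), 2)
  expect_equal(unname(apply(cap$y_id, 1, sum)), c(1, 1))
  expect_equal(sum(cap$n_noid), 0)

  # one unidentifiable photo lands in the unidentified matrix at day 3
  rec2 <- data.frame(station = "S01",
                     datetime = as.POSIXct("2023-03-03 12:00:00", tz = "UTC"),
                     individual = NA_character_, stringsAsFactors = FALSE)
  cap2 <- build_capture_data(rec2, traps)
  expect_equal(cap2$n_noid[1, 3], 1L)
  expect_equal(sum(cap2$n_noid), 1L)
  expect_equal(dim(cap2$y_id)[1], 0)
})

test_that("a mixed 10-record fixture reproduces the hand enumeration", {
  # Hand enumeration with a 30-min window, chained within station/individual:
  #  JA at S01: 10:00, 10:20, 10:45 -> one chained event (gaps 20, 25 min)
  #  JA at S01 day 4: 09:00          -> second event
  #  JA at S02: 11:00                -> third event
  #  JB at S01: 10:10                -> one event (different individual)
  #  noID at S03: 08:00, 08:29      -> one chained event
  #  noID at S03: 09:30              -> second event (61 min after 08:29)
  #  noID at S04: 23:50              -> one event
  # totals: y_id 4 events (JA 3, JB 1), n_noid 3 events
  window <- as.Date(c("2023-03-01", "2023-03-10"))
  traps <- read_traps(write_trap_csv(4, window), window)
  dt <- function(x) as.POSIXct(x, tz = "UTC")
  rec <- data.frame(
    station = c("S01", "S01", "S01", "S01", "S02", "S01", "S03", "S03",
                "S03", "S04"),
    datetime = dt(c("2023-03-02 10:00:00", "2023-03-02 10:20:00",
                    "2023-03-02 10:45:00", "2023-03-04 09:00:00",
                    "2023-03-02 11:00:00", "2023-03-02 10:10:00",
                    "2023-03-05 08:00:00", "2023-03-05 08:29:00",
                    "2023-03-05 09:30:00", "2023-03-06 23:50:00")),
    individual = c("JA", "JA", "JA", "JA", "JA", "JB", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  cap <- build_capture_data(rec, traps, dedup_window = 30)
  expect_equal(unname(apply(cap$y_id, 1, sum)), c(3, 1))  # JA, JB
  expect_equal(cap$y_id[1, 1, 2], 1L)  # JA chained burst at S01 day 2
  expect_equal(cap$y_id[1, 1, 4], 1L)
  expect_equal(cap$y_id[1, 2, 2], 1L)
  expect_equal(sum(cap$n_noid), 3L)
  expect_equal(cap$n_noid[3, 5], 2L)
  expect_equal(cap$n_noid[4, 6], 1L)
  # total deduplicated events = identified + unidentified
  expect_equal(sum(cap$y_id) + sum(cap$n_noid), 7)
})

test_that("records at inactive station-occasions are dropped or activated", {
  window <- as.Date(c("2023-03-01", "2023-03-10"))
  path <- write_trap_csv(2, window,
                         setup = c(window[1], as.Date("2023-03-05")),
                         retrieval = rep(window[2], 2))
  traps <- read_traps(path, window)
  rec <- data.frame(station = "S02",
                    datetime = as.POSIXct("2023-03-02 10:00:00", tz = "UTC"),
                    individual = "JX", stringsAsFactors = FALSE)
  expect_warning(cap <- build_capture_data(rec, traps), "dropped")
  expect_equal(sum(cap$y_id), 0)
  expect_warning(cap2 <- build_capture_data(rec, traps,
                                            on_inactive = "activate"),
                 "activated")
  expect_equal(sum(cap2$y_id), 1)
  expect_equal(unname(attr(cap2, "traps")$operation[2, 2]), 1)
})

test_that("capture_data enforces count invariants against the traps", {
  traps <- tiny_traps(K = 3)
  y <- array(0L, c(1, 4, 3)); y[1, 1, 1] <- 1L
  n <- matrix(0L, 4, 3)
  expect_s3_class(capture_data(y, n, "A", traps = traps), "capture_data")
  traps$operation[1, 1] <- 0
  expect_error(capture_data(y, n, "A", traps = traps), "inactive")
  y[1, 1, 1] <- 0L
  expect_error(capture_data(y, n, "A", traps = traps),
               "at least one detection")
  y[1, 1, 1] <- -1L
  expect_error(capture_data(y, n, "A"), "nonnegative")
})

test_that("state space geometry and area arithmetic", {
  # traps spanning 10 x 20 km with a 9150-m buffer: 28.3 x 38.3 km rectangle
  traps <- trap_array(c("A", "B"), rbind(c(0, 0), c(10000, 20000)),
                      matrix(1, 2, 1))
  ss <- build_state_space(traps, 9150)
  expect_equal(ss$area_km2, 28.3 * 38.3)  # 1083.89 km2
  expect_equal(ss$bounds, c(-9150, 19150, -9150, 29150))

  # zero buffer reduces to the trap bounding box
  ss0 <- build_state_space(traps, 0)
  expect_equal(ss0$area_km2, 10 * 20)
  expect_error(build_state_space(traps, -1), ">= 0")

  # polygon mask: area by the shoelace formula; excluded traps are an error
  tri <- rbind(c(-1000, -1000), c(25000, -1000), c(-1000, 45000))
  ss_tri <- build_state_space(traps, 0, mask = tri)
  expect_equal(ss_tri$area_km2, 0.5 * 26 * 46)
  expect_true(all(in_state_space(ss_tri, traps$xy[, 1], traps$xy[, 2])))
  small <- rbind(c(-100, -100), c(100, -100), c(100, 100), c(-100, 100))
  expect_error(build_state_space(traps, 0, mask = small), "excludes trap")
})

test_that("trap and capture tables round-trip through CSV", {
  window <- as.Date(c("2023-03-01", "2023-03-10"))
  traps <- read_traps(write_trap_csv(4, window), window)
  traps$operation[2, 5] <- 0
  path <- tempfile(fileext = ".csv")
  write_traps(traps, path)
  traps2 <- read_traps(path, window)
  expect_equal(unname(traps2$operation), unname(traps$operation))
  expect_equal(unname(traps2$xy), unname(traps$xy))

  y <- array(0L, c(2, 4, 10))
  y[1, 1, 2] <- 2L; y[1, 3, 7] <- 1L; y[2, 4, 10] <- 1L
  n <- matrix(0L, 4, 10); n[2, 1] <- 3L
  cap <- capture_data(y, n, c("JA", "JB"))
  path2 <- tempfile(fileext = ".csv")
  write_capture_data(cap, path2)
  cap2 <- read_capture_data(path2)
  expect_equal(cap2$y_id, cap$y_id)
  expect_equal(cap2$n_noid, cap$n_noid)
  expect_equal(cap2$individual_ids, cap$individual_ids)
})

test_that("scr_dataset checks dimensional consistency", {
  traps <- tiny_traps(K = 3)
  ss <- build_state_space(traps, 500)
  y <- array(0L, c(1, 4, 3)); y[1, 1, 1] <- 1L
  cap <- capture_data(y, matrix(0L, 4, 3), "A")
  expect_s3_class(scr_dataset(traps, cap, ss), "scr_dataset")
  cap_bad <- capture_data(array(1L, c(1, 3, 3)), matrix(0L, 3, 3), "A")
  expect_error(scr_dataset(traps, cap_bad, ss), "number of detectors")
})
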