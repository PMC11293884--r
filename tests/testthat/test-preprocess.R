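write_fix_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("ingest sorts, de-duplicates and parses ISO timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fix_csv(data.frame(
    animal_id = "A",
    timestamp = c(
      "2023-01-01T08:00:00", "2023-01-01T00:00:00", "2023-01-01T08:00:00"
    ),
    x = c(3, 1, 99), y = c(30, 10, 99)
  ), path)
  out <- ingest_fixes(path)
  expect_equal(nrow(out), 2) # duplicate timestamp collapsed to first kept
  expect_true(all(diff(as.numeric(out$t)) > 0)) # sorted
  expect_equal(out$x, c(1, 3))
})

test_that("bad rows are rejected with a warning, majority-bad is an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fix_csv(data.frame(
    animal_id = "A",
    timestamp = c(
      "2023-01-01T00:00:00", "not a time",
      "2023-01-01T08:00:00", "2023-01-01T12:00:00"
    ),
    x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)
  ), path)
  expect_warning(out <- ingest_fixes(path), "rejected")
  expect_equal(nrow(out), 3)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fix_csv(data.frame(
    animal_id = "A",
    timestamp = c("nope", "also nope", "2023-01-01T08:00:00"),
    x = 1:3, y = 1:3
  ), path2)
  expect_error(suppressWarnings(ingest_fixes(path2)), "50%")
})

test_that("an empty file warns and returns an empty result", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("animal_id,timestamp,x,y", path)
  expect_warning(out <- ingest_fixes(path), "no fixes")
  expect_equal(nrow(out), 0)
})

test_that("resampling 60-min fixes to 240 +/- 10 keeps every 4th fix", {
  trk <- make_regular_track(41, step_m = 100, interval_min = 60)
  out <- resample_track(trk, 240, 10)
  expect_equal(length(unique(out$burst_id)), 1)
  expect_equal(nrow(out), 11)
  expect_true(all(diff(as.numeric(out$t)) == 240 * 60))
})

test_that("a gap beyond the window splits the track into two bursts", {
  trk <- make_regular_track(20, interval_min = 240)
  trk$t[11:20] <- trk$t[11:20] + 3600 # one 300-min gap
  out <- resample_track(trk, 240, 10)
  expect_equal(length(unique(out$burst_id)), 2)
  expect_equal(as.vector(table(out$burst_id)), c(10, 10))
})

test_that("a fix 247 min after the anchor is accepted", {
  t0 <- as.POSIXct("2023-01-01", tz = "UTC")
  trk <- tibble::tibble(
    animal_id = "A",
    t = t0 + c(0, 247, 487, 727) * 60,
    x = 1:4, y = 0
  )
  out <- resample_track(trk, 240, 10)
  expect_equal(nrow(out), 4)
  expect_equal(length(unique(out$burst_id)), 1)
})

test_that("resampling an already-regular burst is the identity", {
  trk <- make_regular_track(25, interval_min = 240)
  out <- resample_track(trk, 240, 10)
  expect_equal(out$t, trk$t)
  expect_equal(out$x, trk$x)
  out2 <- resample_track(out[, names(trk)], 240, 10)
  expect_equal(out2$t, out$t)
})

test_that("cluster detection follows the fix-count and buffer rules", {
  t0 <- as.POSIXct("2023-01-01", tz = "UTC")
  # 4 identical fixes over 16 h: one cluster
  f1 <- tibble::tibble(t = t0 + (0:3) * 16 / 3 * 3600, x = 500, y = 500)
  expect_equal(nrow(detect_clusters(f1)), 1)
  # 3rd fix 30 h after the 2nd: temporal buffer violated, no cluster
  f2 <- f1
  f2$t <- t0 + c(0, 4, 34, 38) * 3600
  expect_equal(nrow(detect_clusters(f2)), 0)
  # only 3 members: below the minimum fix count
  f3 <- f1[1:3, ]
  expect_equal(nrow(detect_clusters(f3)), 0)
  # 4 fixes pairwise >= 200 m apart: nothing within the 150 m buffer
  f4 <- tibble::tibble(
    t = t0 + (0:3) * 3600,
    x = c(0, 200, 0, 200), y = c(0, 0, 200, 200)
  )
  expect_equal(nrow(detect_clusters(f4)), 0)
})

test_that("three injected clusters amid wide movement are all found", {
  trk <- make_regular_track(60, step_m = 1200)
  attr(trk, "extent") <- c(xmin = -1e6, xmax = 1e6, ymin = -1e6, ymax = 1e6)
  for (q in c(0.25, 0.5, 0.75)) {
    at <- trk$t[ceiling(nrow(trk) * q)]
    ctr <- c(trk$x[ceiling(nrow(trk) * q)], 5000)
    trk <- inject_cluster(trk, ctr, radius_m = 60, n_fixes = 5,
      duration_h = 20, at_time = at, seed = round(q * 100))
  }
  cl <- detect_clusters(trk)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$n >= 4))
})

test_that("cluster removal keeps boundary fixes and splits the burst", {
  trk <- make_regular_track(10)
  trk$burst_id <- 1L
  clusters <- tibble::tibble(
    cluster_id = 1L, n = 4L, cx = 0, cy = 0,
    t_start = trk$t[4], t_end = trk$t[7], members = list(4:7)
  )
  out <- remove_clusters(trk, clusters)
  expect_equal(out$x, trk$x[c(1:4, 7:10)])
  expect_equal(unique(out$burst_id[1:4]), 1L)
  expect_equal(unique(out$burst_id[5:8]), 2L)
  # no clusters: unchanged
  expect_identical(remove_clusters(trk, detect_clusters(trk)), trk)
})

test_that("a cluster at the burst start leaves only the trailing burst usable", {
  trk <- make_regular_track(8)
  trk$burst_id <- 1L
  clusters <- tibble::tibble(
    cluster_id = 1L, n = 4L, cx = 0, cy = 0,
    t_start = trk$t[1], t_end = trk$t[4], members = list(1:4)
  )
  out <- remove_clusters(trk, clusters)
  expect_equal(out$x, trk$x[c(1, 4:8)])
  # the leading remnant is a singleton; the trailing burst starts at the
  # cluster's last fix
  expect_equal(sum(out$burst_id == max(out$burst_id)), 5)
  expect_equal(out$x[out$burst_id == max(out$burst_id)][1], trk$x[4])
  # out-of-range member indices are rejected
  bad <- clusters
  bad$members <- list(7:11)
  expect_error(remove_clusters(trk, bad), "range")
})

test_that("transition trimming drops the window and re-bursts", {
  trk <- make_regular_track(10 * 6, interval_min = 240) # 10 days
  trk$burst_id <- 1L
  seg_start <- trk$t[1]
  out <- trim_transition(trk, seg_start, trim_days = 3)
  expect_equal(nrow(out), 60 - 18)
  expect_true(min(out$t) >= seg_start + 3 * 86400)
  # trim starting mid-burst splits it in two
  out2 <- trim_transition(trk, trk$t[1] + 4 * 86400, trim_days = 3)
  expect_equal(length(unique(out2$burst_id)), 2)
  # trim longer than the data warns and returns nothing
  short <- make_regular_track(12, interval_min = 240)
  short$burst_id <- 1L
  expect_warning(out3 <- trim_transition(short, short$t[1], trim_days = 3),
    "removed all")
  expect_equal(nrow(out3), 0)
})

test_that("every preprocessing step emits at most as many fixes as it takes", {
  trk <- make_regular_track(50, interval_min = 240)
  out <- resample_track(trk, 240, 10)
  expect_lte(nrow(out), nrow(trk))
  cl <- detect_clusters(out)
  out2 <- remove_clusters(out, cl)
  expect_lte(nrow(out2), nrow(out))
  out3 <- suppressWarnings(trim_transition(out2, out2$t[1], 3))
  expect_lte(nrow(out3), nrow(out2))
})
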