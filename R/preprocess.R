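# per-element ISO-8601 parsing: each row gets the first format that fits, so
# one malformed row cannot poison the whole column
parse_iso_times <- function(x, tz = "UTC") {
  fmts <- c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  )
  out <- rep(NA_real_, length(x))
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    p <- as.numeric(as.POSIXct(strptime(x[todo], f, tz = tz)))
    out[todo] <- ifelse(is.na(p), NA_real_, p)
  }
  as.POSIXct(out, origin = "1970-01-01", tz = tz)
}

#' Ingest GPS fixes from delimited text
#'
#' Reads one row per fix, resolves columns through `column_map`, parses
#' ISO-8601 timestamps (UTC), sorts by time within animal and collapses
#' exact-duplicate timestamps to the first occurrence. Unparseable rows are
#' rejected with a warning naming their row numbers; more than 50% rejects is
#' an error. An empty file yields an empty result with a warning.
#'
#' @param path delimited text file.
#' @param column_map named character vector mapping the required names
#'   `animal_id`, `t`, `x`, `y` to columns in the file.
#' @param sep field separator (default comma).
#' @return tibble with columns `animal_id, t, x, y`, time-sorted per animal.
#' @export
ingest_fixes <- function(path,
                         column_map = c(
                           animal_id = "animal_id", t = "timestamp",
                           x = "x", y = "y"
                         ),
                         sep = ",") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path,
    header = TRUE, sep = sep,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (nrow(raw) == 0L) {
    warning("no fixes in ", path)
    return(tibble::tibble(
      animal_id = character(), t = as.POSIXct(character(), tz = "UTC"),
      x = numeric(), y = numeric()
    ))
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  tt <- parse_iso_times(as.character(raw[[column_map[["t"]]]]))
  xx <- suppressWarnings(as.numeric(raw[[column_map[["x"]]]]))
  yy <- suppressWarnings(as.numeric(raw[[column_map[["y"]]]]))
  bad <- is.na(tt) | !is.finite(xx) | !is.finite(yy)
  if (any(bad)) {
    warning(
      sum(bad), " row(s) rejected (bad timestamp/coordinate): rows ",
      paste(utils::head(which(bad), 20), collapse = ", ")
    )
    if (mean(bad) > 0.5) stop("more than 50% of rows rejected in ", path)
  }
  out <- tibble::tibble(
    animal_id = as.character(raw[[column_map[["animal_id"]]]])[!bad],
    t = tt[!bad], x = xx[!bad], y = yy[!bad]
  )
  out <- dplyr::arrange(out, .data$animal_id, .data$t)
  out <- dplyr::distinct(out, .data$animal_id, .data$t, .keep_all = TRUE)
  out
}

#' Resample a track to a target fix rate
#'
#' Greedy forward pass per animal: from the current anchor fix, the earliest
#' subsequent fix whose gap from the anchor lies within
#' `target_interval_min` +/- `tolerance_min` is accepted and becomes the new
#' anchor; fixes arriving too soon are skipped; a gap overrunning the window
#' closes the burst and the overrunning fix seeds the next one. Bursts
#' shorter than `min_burst` fixes are discarded (3 fixes = one full step with
#' a turning angle).
#'
#' @param fixes tibble with `animal_id, t, x, y` (extra columns carried
#'   through), time-sorted.
#' @param target_interval_min target fix interval (min), default 240.
#' @param tolerance_min half-width of the acceptance window (min), default 10.
#' @param min_burst minimum fixes per burst, default 3.
#' @return tibble of retained fixes with a `burst_id` column (unique across
#'   animals).
#' @export
resample_track <- function(fixes, target_interval_min = 240,
                           tolerance_min = 10, min_burst = 3) {
  stopifnot(target_interval_min > 0, tolerance_min > 0)
  lo <- (target_interval_min - tolerance_min) * 60
  hi <- (target_interval_min + tolerance_min) * 60
  out <- vector("list", 0L)
  burst_counter <- 0L
  for (aid in unique(fixes$animal_id)) {
    f <- fixes[fixes$animal_id == aid, , drop = FALSE]
    ts <- as.numeric(f$t)
    n <- nrow(f)
    keep <- integer(0)
    bid <- integer(0)
    burst_counter <- burst_counter + 1L
    anchor <- 1L
    keep <- anchor
    bid <- burst_counter
    j <- 2L
    while (j <= n) {
      gap <- ts[j] - ts[anchor]
      if (gap < lo) {
        j <- j + 1L # too soon: skip
      } else if (gap <= hi) {
        keep <- c(keep, j)
        bid <- c(bid, burst_counter)
        anchor <- j
        j <- j + 1L
      } else {
        # window overrun: close burst, this fix seeds a new one
        burst_counter <- burst_counter + 1L
        anchor <- j
        keep <- c(keep, j)
        bid <- c(bid, burst_counter)
        j <- j + 1L
      }
    }
    res <- f[keep, , drop = FALSE]
    res$burst_id <- bid
    out[[length(out) + 1L]] <- res
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(res)
  sizes <- table(res$burst_id)
  res <- res[res$burst_id %in% as.integer(names(sizes)[sizes >= min_burst]), ,
    drop = FALSE
  ]
  res
}

#' Detect stationary (kill-site) GPS clusters
#'
#' Sequential scan over time-sorted fixes of one animal: a candidate cluster
#' opens at a seed fix; a later fix joins if it lies within
#' `spatial_buffer_m` of the running centroid (recomputed as members join)
#' and within `temporal_buffer_h` of the cluster's last member; fixes farther
#' away are skipped without closing the candidate (the animal may leave and
#' revisit). A candidate is emitted iff it gathered at least `min_fix_count`
#' members; emitted clusters are non-overlapping (the scan resumes after the
#' last member).
#'
#' @param fixes time-sorted tibble with `t, x, y` for one animal.
#' @param min_fix_count minimum members, default 4.
#' @param spatial_buffer_m centroid buffer (m), default 150.
#' @param temporal_buffer_h maximum gap between consecutive members (h),
#'   default 24.
#' @return tibble with one row per cluster: `cluster_id, n, cx, cy, t_start,
#'   t_end` and list-column `members` (row indices into `fixes`).
#' @export
detect_clusters <- function(fixes, min_fix_count = 4, spatial_buffer_m = 150,
                            temporal_buffer_h = 24) {
  n <- nrow(fixes)
  ts <- as.numeric(fixes$t)
  xs <- fixes$x
  ys <- fixes$y
  max_gap <- temporal_buffer_h * 3600
  clusters <- list()
  i <- 1L
  while (i <= n) {
    members <- i
    cx <- xs[i]
    cy <- ys[i]
    j <- i + 1L
    while (j <= n) {
      if (ts[j] - ts[members[length(members)]] > max_gap) break
      if (sqrt((xs[j] - cx)^2 + (ys[j] - cy)^2) <= spatial_buffer_m) {
        members <- c(members, j)
        cx <- mean(xs[members])
        cy <- mean(ys[members])
      }
      j <- j + 1L
    }
    if (length(members) >= min_fix_count) {
      clusters[[length(clusters) + 1L]] <- tibble::tibble(
        cluster_id = length(clusters) + 1L,
        n = length(members), cx = cx, cy = cy,
        t_start = fixes$t[members[1]],
        t_end = fixes$t[members[length(members)]],
        members = list(members)
      )
      i <- members[length(members)] + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(clusters) == 0L) {
    return(tibble::tibble(
      cluster_id = integer(), n = integer(), cx = numeric(), cy = numeric(),
      t_start = as.POSIXct(character(), tz = "UTC"),
      t_end = as.POSIXct(character(), tz = "UTC"), members = list()
    ))
  }
  dplyr::bind_rows(clusters)
}

#' Remove cluster interiors from a burst
#'
#' Interior cluster fixes are dropped; the cluster's first fix terminates the
#' incoming burst (conclusion of the incoming step) and its last fix begins
#' the outgoing burst (start of the departure step), so no step ever spans a
#' cluster interior.
#'
#' @param fixes tibble with a `burst_id` column (e.g. from
#'   [resample_track()]).
#' @param clusters result of [detect_clusters()] on the same `fixes`.
#' @return tibble of fixes with re-assigned `burst_id`.
#' @export
remove_clusters <- function(fixes, clusters) {
  n <- nrow(fixes)
  if (nrow(clusters) == 0L) return(fixes)
  all_members <- unlist(clusters$members)
  if (any(all_members < 1L | all_members > n)) {
    stop("cluster member indices out of range")
  }
  drop <- rep(FALSE, n)
  cut_after <- rep(FALSE, n) # burst boundary after this fix
  for (k in seq_len(nrow(clusters))) {
    m <- clusters$members[[k]]
    first <- m[1]
    last <- m[length(m)]
    # drop everything strictly between first and last member (members and
    # skipped interlopers alike: they fall inside the stationary interval)
    if (last > first + 1L) drop[(first + 1L):(last - 1L)] <- TRUE
    cut_after[first] <- TRUE
  }
  keep_idx <- which(!drop)
  out <- fixes[keep_idx, , drop = FALSE]
  # new burst ids: split at original burst boundaries and at cluster cuts
  ob <- fixes$burst_id[keep_idx]
  k <- length(keep_idx)
  new_burst <- cumsum(
    c(TRUE, ob[-1] != ob[-k] | cut_after[keep_idx[-k]])
  )
  out$burst_id <- new_burst
  out
}

#' Trim a state-transition period and re-burst
#'
#' Drops fixes in `[segment start, start + trim_days)` and re-assigns burst
#' ids so no step spans the trimmed window (a new step burst begins at the
#' state boundary).
#'
#' @param fixes tibble with `burst_id, t` columns.
#' @param segment_start POSIXct start of the state segment.
#' @param trim_days length of the transition period (days), default 3.
#' @param target_interval_min,tolerance_min fix-rate window used to decide
#'   where re-bursting must split (a gap outside the window splits).
#' @param min_burst bursts shorter than this are discarded.
#' @return tibble of retained fixes with re-assigned `burst_id`; empty (with
#'   a warning) if the trim swallows all data.
#' @export
trim_transition <- function(fixes, segment_start, trim_days = 3,
                            target_interval_min = 240, tolerance_min = 10,
                            min_burst = 3) {
  t0 <- as.numeric(segment_start)
  t1 <- t0 + trim_days * 86400
  ts <- as.numeric(fixes$t)
  keep <- !(ts >= t0 & ts < t1)
  out <- fixes[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("transition trim removed all fixes")
    return(out)
  }
  hi <- (target_interval_min + tolerance_min) * 60
  ts2 <- as.numeric(out$t)
  n2 <- nrow(out)
  split <- c(
    TRUE,
    out$burst_id[-1] != out$burst_id[-n2] | diff(ts2) > hi
  )
  out$burst_id <- cumsum(split)
  sizes <- table(out$burst_id)
  out[out$burst_id %in% as.integer(names(sizes)[sizes >= min_burst]), ,
    drop = FALSE
  ]
}
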