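#' Peak-calling thresholds
#'
#' @param a_dt minimum smoothed height for a primary peak (default 0.1).
#' @param v_t minimum secondary deviation to open/close a secondary peak
#'   during scanning (default 0.1); recoveries must exceed `v_t` strictly.
#' @param m smoothing half-width in windows (default 4); `m = 0` disables
#'   smoothing.
#' @return list of class `sibsam_thresholds`.
#' @export
thresholds <- function(a_dt = 0.1, v_t = 0.1, m = 4) {
  stopifnot(a_dt > 0, v_t > 0, m >= 0)
  structure(list(a_dt = a_dt, v_t = v_t, m = as.integer(m)),
            class = "sibsam_thresholds")
}

#' Smooth an ancestry-difference profile
#'
#' Weighted moving average with triangular weights: the focal window gets
#' weight `m + 1`, each neighbour at distance `d` gets `m + 1 - d`, out to
#' the `m`th window with weight 1. Smoothing never crosses a chromosome
#' boundary; at chromosome edges the missing flank windows are dropped and
#' the weights renormalized over the available windows.
#'
#' @param ad per-window values.
#' @param chrom_index integer chromosome index per window (same order);
#'   a single-chromosome profile may omit it.
#' @param m smoothing half-width; `m = 0` returns `ad` unchanged.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(ad, chrom_index = NULL, m = 4) {
  if (m == 0) return(ad)
  if (is.null(chrom_index)) chrom_index <- rep(1L, length(ad))
  w <- c(seq_len(m), m + 1, rev(seq_len(m)))
  out <- numeric(length(ad))
  for (ci in unique(chrom_index)) {
    sel <- which(chrom_index == ci)
    x <- ad[sel]
    n <- length(x)
    xp <- c(rep(0, m), x, rep(0, m))
    ip <- c(rep(0, m), rep(1, n), rep(0, m))
    num <- stats::filter(xp, w, sides = 2)[(m + 1):(m + n)]
    den <- stats::filter(ip, w, sides = 2)[(m + 1):(m + n)]
    out[sel] <- as.numeric(num / den)
  }
  out
}

#' Find primary peaks on a smoothed profile
#'
#' A primary peak is the maximum of a maximal run of consecutive windows
#' with value > 0 (runs never span chromosomes), kept only if that maximum
#' exceeds `a_dt`. Argmax ties go to the lowest window index.
#'
#' @param sp smoothed per-window values.
#' @param chrom_index integer chromosome index per window (optional for a
#'   single chromosome).
#' @param thr a [thresholds()] object.
#' @return data frame with one row per primary peak: `peak_id`, `chrom`
#'   (index), `window` (genome-order index), `height`, `run_start`,
#'   `run_end` (genome-order bounds of the positive run).
#' @export
find_primary_peaks <- function(sp, chrom_index = NULL, thr = thresholds()) {
  if (is.null(chrom_index)) chrom_index <- rep(1L, length(sp))
  out <- list()
  for (ci in unique(chrom_index)) {
    sel <- which(chrom_index == ci)
    x <- sp[sel]
    pos <- x > 0
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      seg <- x[i0:i1]
      h <- max(seg)
      if (h > thr$a_dt) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ci,
          window = sel[i0 + which.max(seg) - 1L],
          height = h,
          run_start = sel[i0], run_end = sel[i1])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(peak_id = integer(), chrom = integer(),
                      window = integer(), height = numeric(),
                      run_start = integer(), run_end = integer()))
  res <- do.call(rbind, out)
  res <- res[order(-res$height), , drop = FALSE]
  res <- data.frame(peak_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

# Scan one flank of a primary peak for secondary peaks using the
# open/close rule: moving away from the primary, a recovery strictly
# beyond v_t from the running minimum since the last peak opens a new
# secondary peak; a drop strictly beyond v_t below its running maximum
# closes it. A peak still open when the run ends is recorded as well.
scan_flank <- function(sp, idx_seq, v_t) {
  peaks <- list()
  run_min <- Inf
  open <- FALSE
  cur_max <- -Inf
  cur_idx <- NA_integer_
  for (i in idx_seq) {
    x <- sp[i]
    if (!open) {
      if (x < run_min) run_min <- x
      if (x - run_min > v_t) {
        open <- TRUE
        cur_max <- x
        cur_idx <- i
      }
    } else {
      if (x > cur_max) { cur_max <- x; cur_idx <- i }
      if (cur_max - x > v_t) {
        peaks[[length(peaks) + 1]] <- list(window = cur_idx, height = cur_max)
        open <- FALSE
        run_min <- x
      }
    }
  }
  if (open)
    peaks[[length(peaks) + 1]] <- list(window = cur_idx, height = cur_max)
  peaks
}

#' Find secondary peaks of one primary peak
#'
#' Scans outward from the primary window on each side within the
#' primary's positive run, applying the recovery/drop rule with threshold
#' `v_t`, then assigns each secondary its deviation `v` under the
#' taller-first priority rule (see [secondary_deviations()]).
#'
#' @param sp smoothed per-window values (genome order).
#' @param primary one row of [find_primary_peaks()] output.
#' @param thr a [thresholds()] object.
#' @return data frame with one row per secondary peak: `window`, `height`,
#'   `side` (-1 left of primary, +1 right), `v`.
#' @export
find_secondary_peaks <- function(sp, primary, thr = thresholds()) {
  pw <- primary$window
  left <- if (pw > primary$run_start) seq(pw - 1L, primary$run_start) else integer()
  right <- if (pw < primary$run_end) seq(pw + 1L, primary$run_end) else integer()
  res <- list()
  for (side in c(-1L, 1L)) {
    found <- scan_flank(sp, if (side < 0) left else right, thr$v_t)
    for (p in found)
      res[[length(res) + 1]] <- data.frame(window = p$window,
                                           height = p$height, side = side)
  }
  if (length(res) == 0)
    return(data.frame(window = integer(), height = numeric(),
                      side = integer(), v = numeric()))
  sec <- do.call(rbind, res)
  sec$v <- secondary_deviations(sp, pw, sec$window, sec$height)
  sec[order(-sec$v), , drop = FALSE]
}

#' Secondary deviations under the taller-first priority rule
#'
#' The tallest secondary peak on a side of the primary takes
#' `v = height - min(profile between it and the primary)`, ignoring any
#' shorter peaks in between. A shorter secondary lying between two taller
#' peaks (the primary counts as taller) takes `v = height - max(valley on
#' either side)`, where each valley is the profile minimum between the
#' peak and the nearest strictly taller peak in that direction. Taller
#' peaks are evaluated first so that a shorter inner peak can never
#' out-rank a taller outer one.
#'
#' @param sp smoothed per-window values.
#' @param primary_window genome-order window index of the primary peak.
#' @param windows,heights secondary peak windows and heights.
#' @return numeric vector of deviations `v`, aligned with `windows`.
#' @export
secondary_deviations <- function(sp, primary_window, windows, heights) {
  n <- length(windows)
  if (n == 0) return(numeric())
  all_w <- c(primary_window, windows)
  all_h <- c(sp[primary_window], heights)
  v <- numeric(n)
  for (i in seq_len(n)) {
    wi <- windows[i]; hi <- heights[i]
    taller <- all_w[all_h > hi]
    # nearest strictly taller peak on each side of this one
    lt <- taller[taller < wi]
    rt <- taller[taller > wi]
    vals <- numeric()
    if (length(lt) > 0) {
      b <- max(lt)
      vals <- c(vals, min(sp[b:wi]))
    }
    if (length(rt) > 0) {
      b <- min(rt)
      vals <- c(vals, min(sp[wi:b]))
    }
    # the primary is taller than every secondary, so vals is non-empty
    v[i] <- hi - max(vals)
  }
  v
}

#' Full peak call on an ancestry-difference profile
#'
#' Smooths the profile, identifies all primary peaks, and attaches each
#' primary's secondary peaks with adjusted deviations.
#'
#' @param ad raw per-window ancestry differences (genome order).
#' @param gmap a [genome_map()] (used for chromosome boundaries and
#'   coordinates); alternatively pass `chrom_index`.
#' @param thr a [thresholds()] object.
#' @param chrom_index integer chromosome index per window, if no `gmap`.
#' @return list of class `peak_set`: `smoothed` profile, `primary` data
#'   frame, and `secondary` (list indexed by primary `peak_id`).
#' @export
find_peaks <- function(ad, gmap = NULL, thr = thresholds(),
                       chrom_index = NULL) {
  if (!is.null(gmap)) chrom_index <- window_midpoints(gmap)$chrom_index
  sp <- smooth_profile(ad, chrom_index, thr$m)
  prim <- find_primary_peaks(sp, chrom_index, thr)
  secs <- lapply(seq_len(nrow(prim)), function(i)
    find_secondary_peaks(sp, prim[i, ], thr))
  names(secs) <- prim$peak_id
  structure(list(smoothed = sp, primary = prim, secondary = secs,
                 thresholds = thr),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", nrow(x$primary), "primary peak(s)\n")
  if (nrow(x$primary) > 0) {
    n_sec <- vapply(x$secondary, nrow, integer(1))
    for (i in seq_len(nrow(x$primary)))
      cat(sprintf("  peak %d: chrom %d window %d height %.3f (%d secondary)\n",
                  x$primary$peak_id[i], x$primary$chrom[i],
                  x$primary$window[i], x$primary$height[i], n_sec[i]))
  }
  invisible(x)
}
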