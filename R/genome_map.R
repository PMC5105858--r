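#' @useDynLib sibsam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma rnorm quantile median rbinom rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Construct a windowed genome map
#'
#' A `genome_map` holds an ordered set of genomic windows per chromosome,
#' each with physical (bp) and genetic (cM) coordinates. Windows are
#' half-open `[start, end)` in both coordinate systems; the last window of
#' a chromosome is closed on the right. At most one chromosome may be
#' flagged as the X (hemizygous in males, no paternal transmission to
#' sons).
#'
#' @param windows data frame with columns `chrom`, `phys_start`,
#'   `phys_end`, `cm_start`, `cm_end`, ordered by chromosome then
#'   `cm_start`.
#' @param x_chrom label of the X chromosome, or `NA` for none.
#' @return An object of class `genome_map` with elements `chrom` (one row
#'   per chromosome: `chrom`, `is_x`, `total_cm`, `n_windows`) and
#'   `windows` (per-window table with a within-chromosome `index`).
#' @export
genome_map <- function(windows, x_chrom = "X") {
  req <- c("chrom", "phys_start", "phys_end", "cm_start", "cm_end")
  miss <- setdiff(req, names(windows))
  if (length(miss) > 0)
    stop("window table lacks columns: ", paste(miss, collapse = ", "))
  windows$chrom <- as.character(windows$chrom)
  labs <- unique(windows$chrom)
  win <- NULL
  chrom_rows <- list()
  for (lab in labs) {
    w <- windows[windows$chrom == lab, req, drop = FALSE]
    validate_chrom_windows(w, lab)
    w$index <- seq_len(nrow(w))
    win <- rbind(win, w)
    chrom_rows[[lab]] <- data.frame(
      chrom = lab,
      is_x = identical(lab, as.character(x_chrom)),
      total_cm = w$cm_end[nrow(w)],
      n_windows = nrow(w),
      stringsAsFactors = FALSE
    )
  }
  chrom <- do.call(rbind, chrom_rows)
  rownames(chrom) <- rownames(win) <- NULL
  if (sum(chrom$is_x) > 1) stop("at most one chromosome can be the X")
  structure(list(chrom = chrom, windows = win), class = "genome_map")
}

validate_chrom_windows <- function(w, lab) {
  if (nrow(w) == 0) stop("chromosome ", lab, " has zero windows")
  bad <- which(w$phys_end <= w$phys_start)
  if (length(bad) > 0)
    stop("chromosome ", lab, ": phys_end <= phys_start at window row ", bad[1])
  bad <- which(w$cm_end < w$cm_start)
  if (length(bad) > 0)
    stop("chromosome ", lab, ": cm_end < cm_start at window row ", bad[1])
  if (nrow(w) > 1) {
    d <- w$cm_start[-1] - w$cm_end[-nrow(w)]
    bad <- which(abs(d) > 1e-6)
    if (length(bad) > 0)
      stop("chromosome ", lab, ": windows not contiguous in cM at window row ",
           bad[1] + 1, " (cm_start must equal previous cm_end)")
  }
  if (abs(w$cm_start[1]) > 1e-9)
    stop("chromosome ", lab, ": first window must start at 0 cM")
  invisible(TRUE)
}

#' Default Drosophila-like chromosome configuration
#'
#' Genetic lengths approximating the D. melanogaster map (X about 73 cM,
#' chromosome 2 about 108 cM, chromosome 3 about 110 cM) with physical
#' sizes on the scale of the major chromosomes. These are configurable
#' conventions, not measured constants.
#'
#' @return data frame with columns `chrom`, `cm`, `bp`, `is_x`.
#' @export
drosophila_chroms <- function() {
  data.frame(
    chrom = c("X", "2", "3"),
    cm = c(73, 108, 110),
    bp = c(22.5e6, 48e6, 52e6),
    is_x = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic windowed genome map
#'
#' Draws per-window centimorgan widths as symmetric Dirichlet shares of
#' each chromosome's total genetic length, emulating windows of variable
#' cM length (heterogeneous local recombination) without external map
#' data. Physical spans are proportional to the cM widths with
#' multiplicative log-normal jitter.
#'
#' @param n_windows integer vector of windows per chromosome (recycled).
#' @param chroms chromosome table as from [drosophila_chroms()].
#' @param concentration Dirichlet concentration for window cM shares;
#'   larger values give more uniform windows.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return A [genome_map()].
#' @export
make_synthetic_map <- function(n_windows = 500,
                               chroms = drosophila_chroms(),
                               concentration = 3,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_windows <- rep_len(as.integer(n_windows), nrow(chroms))
  if (any(n_windows < 1)) stop("each chromosome needs at least one window")
  win <- NULL
  for (i in seq_len(nrow(chroms))) {
    n <- n_windows[i]
    g <- rgamma(n, shape = concentration, rate = 1)
    share <- g / sum(g)
    cm_w <- share * chroms$cm[i]
    cm_end <- cumsum(cm_w)
    cm_end[n] <- chroms$cm[i]  # kill accumulated rounding
    cm_start <- c(0, cm_end[-n])
    raw_bp <- cm_w * exp(rnorm(n, 0, 0.3))
    bp_w <- pmax(1, round(raw_bp / sum(raw_bp) * chroms$bp[i]))
    bp_end <- cumsum(bp_w)
    bp_start <- c(0, bp_end[-n])
    win <- rbind(win, data.frame(
      chrom = chroms$chrom[i],
      phys_start = bp_start, phys_end = bp_end,
      cm_start = cm_start, cm_end = cm_end,
      stringsAsFactors = FALSE
    ))
  }
  x_lab <- if (any(chroms$is_x)) chroms$chrom[chroms$is_x][1] else NA
  genome_map(win, x_chrom = x_lab)
}

#' Locate the window containing a genetic position
#'
#' Windows are half-open `[cm_start, cm_end)`; the last window of the
#' chromosome is closed on the right so `cm_pos = total_cm` is valid.
#'
#' @param gmap a [genome_map()].
#' @param chrom chromosome label.
#' @param cm_pos position in cM, in `[0, total_cm]`.
#' @return 1-based window index within the chromosome.
#' @export
window_at <- function(gmap, chrom, cm_pos) {
  ci <- match(as.character(chrom), gmap$chrom$chrom)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  total <- gmap$chrom$total_cm[ci]
  if (any(cm_pos < 0 | cm_pos > total))
    stop("cm_pos outside [0, ", total, "] on chromosome ", chrom)
  w <- gmap$windows[gmap$windows$chrom == gmap$chrom$chrom[ci], ]
  idx <- findInterval(cm_pos, w$cm_start)
  pmin(idx, nrow(w))
}

#' Window cM midpoints in genome order
#'
#' @param gmap a [genome_map()].
#' @return list with `chrom_index` (integer per window) and `mid` (cM).
#' @export
window_midpoints <- function(gmap) {
  w <- gmap$windows
  ci <- match(w$chrom, gmap$chrom$chrom)
  list(chrom_index = ci, mid = (w$cm_start + w$cm_end) / 2)
}

#' Write a window table with an ancestry profile
#'
#' The on-disk format is a TSV with a header; BSA tables carry columns
#' `chrom phys_start phys_end cm_start cm_end ad depth_high depth_low`,
#' IM tables `chrom phys_start phys_end cm_start cm_end ap depth`.
#' Comment lines start with `#`. Physical coordinates are written 1-based.
#'
#' @param gmap a [genome_map()].
#' @param path output file.
#' @param ad,ap per-window statistic (exactly one of the two).
#' @param depth_high,depth_low,depth informative read depths per window.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(gmap, path, ad = NULL, ap = NULL,
                               depth_high = NULL, depth_low = NULL,
                               depth = NULL) {
  w <- gmap$windows
  fmt <- function(x) sprintf("%.17g", x)
  if (!is.null(ad)) {
    if (is.null(depth_high)) depth_high <- rep(0L, nrow(w))
    if (is.null(depth_low)) depth_low <- rep(0L, nrow(w))
    tab <- data.frame(chrom = w$chrom,
                      phys_start = w$phys_start + 1L, phys_end = w$phys_end,
                      cm_start = fmt(w$cm_start), cm_end = fmt(w$cm_end),
                      ad = fmt(ad), depth_high = depth_high,
                      depth_low = depth_low, stringsAsFactors = FALSE)
  } else if (!is.null(ap)) {
    if (is.null(depth)) depth <- rep(0L, nrow(w))
    tab <- data.frame(chrom = w$chrom,
                      phys_start = w$phys_start + 1L, phys_end = w$phys_end,
                      cm_start = fmt(w$cm_start), cm_end = fmt(w$cm_end),
                      ap = fmt(ap), depth = depth, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(chrom = w$chrom,
                      phys_start = w$phys_start + 1L, phys_end = w$phys_end,
                      cm_start = fmt(w$cm_start), cm_end = fmt(w$cm_end),
                      ad = fmt(rep(0, nrow(w))),
                      depth_high = rep(0L, nrow(w)),
                      depth_low = rep(0L, nrow(w)), stringsAsFactors = FALSE)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a window table
#'
#' Reads the TSV format written by [write_window_table()]: genome map plus
#' the observed ancestry profile (`ad` with two pool depths for BSA, `ap`
#' with one depth for IM). Windows must be sorted and contiguous in cM
#' within each chromosome; violations raise an error naming the row.
#'
#' @param path input file.
#' @param x_chrom label of the X chromosome, or `NA`.
#' @return list with `gmap` (a [genome_map()]), `profile` (numeric vector
#'   of `ad` or `ap` in window order), `mode` (`"bsa"` or `"im"`), and the
#'   depth column(s).
#' @export
load_window_table <- function(path, x_chrom = "X") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("chrom", "phys_start", "phys_end", "cm_start", "cm_end")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("malformed window table ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  num <- c("phys_start", "phys_end", "cm_start", "cm_end")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop("malformed window table ", path, ": non-numeric ", cn,
           " at line ", which(is.na(v))[1] + 1L)
    tab[[cn]] <- v
  }
  win <- tab[req]
  win$phys_start <- win$phys_start - 1  # back to 0-based half-open
  gmap <- genome_map(win, x_chrom = x_chrom)
  if ("ad" %in% names(tab)) {
    list(gmap = gmap, profile = as.numeric(tab$ad), mode = "bsa",
         depth_high = as.numeric(tab$depth_high),
         depth_low = as.numeric(tab$depth_low))
  } else if ("ap" %in% names(tab)) {
    list(gmap = gmap, profile = as.numeric(tab$ap), mode = "im",
         depth = as.numeric(tab$depth))
  } else {
    stop("window table ", path, " has neither an 'ad' nor an 'ap' column")
  }
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chrom), "chromosomes,",
      nrow(x$windows), "windows\n")
  for (i in seq_len(nrow(x$chrom)))
    cat(sprintf("  %s%s: %d windows, %.1f cM\n", x$chrom$chrom[i],
                if (x$chrom$is_x[i]) " (X)" else "",
                x$chrom$n_windows[i], x$chrom$total_cm[i]))
  invisible(x)
}
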