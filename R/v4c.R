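#' Virtual-4C profile from a contact matrix viewpoint
#'
#' Sums the matrix rows of the bins overlapped by the viewpoint interval
#' and applies a centred moving average of width `smooth_window` with
#' truncated edges (a window of 1 leaves the row untouched). Viewpoint
#' bins are reported, not zeroed, and flagged via `viewpoint_bins`.
#'
#' @param matrix a `contact_matrix`.
#' @param viewpoint bp interval, either `c(start, end)` or
#'   `"chrS:start-end"`; must lie inside the region and overlap >= 1 bin.
#' @param smooth_window odd integer >= 1.
#' @return object of class `viewpoint_profile`: `values` (smoothed signal,
#'   one per bin), `values_raw`, `viewpoint`, `viewpoint_bins` (0-based),
#'   `smooth_window`, `bin_size`, `n_bins`, `chrom`.
#' @export
virtual_4c <- function(matrix, viewpoint, smooth_window = 3L) {
  stopifnot(inherits(matrix, "contact_matrix"))
  sw <- as.integer(smooth_window)
  if (sw < 1L || sw %% 2L == 0L) stop("smooth_window must be an odd integer >= 1")
  iv <- parse_interval(viewpoint)
  n <- matrix$n_bins
  bs <- matrix$bin_size
  if (iv[1] < 0 || iv[2] > n * bs) stop("viewpoint outside region")
  bins <- which((seq_len(n) - 1L) * bs < iv[2] & seq_len(n) * bs > iv[1])
  if (!length(bins)) stop("viewpoint overlaps no bin")

  M <- cm_dense(matrix)
  raw <- colSums(M[bins, , drop = FALSE])
  if (sw == 1L) {
    sm <- raw
  } else {
    h <- sw %/% 2L
    cs <- c(0, cumsum(raw))
    lo <- pmax(1L, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  structure(
    list(values = sm, values_raw = raw, viewpoint = iv,
         viewpoint_bins = bins - 1L, smooth_window = sw,
         bin_size = bs, n_bins = n, chrom = "chrS"),
    class = "viewpoint_profile"
  )
}

#' @export
print.viewpoint_profile <- function(x, ...) {
  cat(sprintf("<viewpoint_profile> chrS:%g-%g (%d bins), window %d, mass %.6g\n",
              x$viewpoint[1], x$viewpoint[2], length(x$viewpoint_bins),
              x$smooth_window, sum(x$values)))
  invisible(x)
}

#' Fraction of profile mass on the viewpoint's side of a boundary
#'
#' Splits the region at `boundary_bp` (bins are assigned by midpoint) and
#' returns the share of profile mass on the side holding the viewpoint,
#' excluding the viewpoint bins themselves. This is the quantity behind the
#' observation that a viewpoint downstream of a domain boundary interacts
#' almost exclusively downstream.
#'
#' @param profile a `viewpoint_profile`.
#' @param boundary_bp boundary position in bp.
#' @param use_raw use the unsmoothed signal (default) or the smoothed one.
#' @return fraction in `[0, 1]`.
#' @export
side_mass_fraction <- function(profile, boundary_bp, use_raw = TRUE) {
  stopifnot(inherits(profile, "viewpoint_profile"))
  v <- if (use_raw) profile$values_raw else profile$values
  mids <- (seq_len(profile$n_bins) - 0.5) * profile$bin_size
  own_side <- sign(mids - boundary_bp) ==
    sign(mean(mids[profile$viewpoint_bins + 1L]) - boundary_bp)
  v[profile$viewpoint_bins + 1L] <- 0
  tot <- sum(v)
  if (tot == 0) return(NA_real_)
  sum(v[own_side]) / tot
}

#' Export a viewpoint profile as bedGraph
#'
#' Four-column bedGraph with a track header; one line per nonzero bin,
#' 0-based half-open bin intervals, full-precision values.
#' @param profile a `viewpoint_profile`.
#' @param path output file.
#' @param name track name.
#' @param use_raw export the unsmoothed signal instead of the smoothed one.
#' @return the path, invisibly.
#' @export
export_bedgraph <- function(profile, path, name = "virtual4C",
                            use_raw = FALSE) {
  stopifnot(inherits(profile, "viewpoint_profile"))
  v <- if (use_raw) profile$values_raw else profile$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", name), con)
  nz <- which(v != 0)
  if (length(nz)) {
    start <- (nz - 1L) * profile$bin_size
    writeLines(paste(profile$chrom,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(start + profile$bin_size, scientific = FALSE, trim = TRUE),
                     fmt_num(v[nz])), con)
  }
  invisible(path)
}

#' Read a bedGraph file written by [export_bedgraph()]
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  tab <- utils::read.table(text = lines, header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           stringsAsFactors = FALSE)
  tab
}
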