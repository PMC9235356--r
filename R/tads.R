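#' Call first-level TAD boundaries by spectral segmentation
#'
#' Sliding windows along the matrix diagonal are segmented by spectral
#' clustering of the windowed contact graph: the degree-normalized
#' Laplacian is eigendecomposed (eigenvector signs fixed by a
#' first-nonzero-positive convention so results are reproducible), bins are
#' embedded in the leading eigenvectors, and a contiguity-respecting
#' dynamic-programming segmentation into k groups is scored by the mean
#' silhouette width for k in 1..`k_max` (k = 1 wins whenever no split
#' reaches `min_silhouette`). Window-level cuts are consolidated into
#' first-level boundaries by majority voting over the windows covering each
#' position, and boundaries closer than `min_tad` are resolved in favour of
#' the better-supported cut. The call is deterministic for a fixed matrix
#' and invariant to positive rescaling of the counts.
#'
#' @param matrix a `contact_matrix` (typically coarsened to ~25 kb bins
#'   with [coarsen()]).
#' @param window sliding-window width in bins (>= 2 * `min_tad`).
#' @param k_max largest number of groups tried per window.
#' @param min_tad smallest admissible TAD size in bins.
#' @param min_silhouette smallest mean silhouette a split must reach.
#' @param dist_cap contacts farther than this many bins are ignored when
#'   building window graphs.
#' @return object of class `tad_segmentation`: `resolution` (bp),
#'   `n_bins`, `boundaries` (interior cut bins, each the start of a TAD),
#'   `tads` (data frame `start`, `end`, `score`; half-open bin intervals
#'   tiling the region), and `chrom`.
#' @export
call_tads <- function(matrix, window = 40L, k_max = 5L, min_tad = 4L,
                      min_silhouette = 0.15, dist_cap = 200L) {
  stopifnot(inherits(matrix, "contact_matrix"))
  window <- as.integer(window); k_max <- as.integer(k_max)
  min_tad <- as.integer(min_tad)
  if (min_tad < 1L) stop("min_tad must be >= 1")
  if (window < 2L * min_tad) stop("window must be >= 2 * min_tad")
  n <- matrix$n_bins

  if (cm_mass(matrix) == 0) {
    warning("all-zero contact matrix: returning a single TAD")
    return(new_tad_segmentation(integer(0), n, matrix, numeric(0)))
  }

  M <- cm_dense(matrix)
  diag(M) <- 0
  if (n > dist_cap) {
    idx <- abs(row(M) - col(M)) > dist_cap
    M[idx] <- 0
  }

  win <- min(window, n)
  starts <- if (n <= window) 0L else {
    unique(c(seq.int(0L, n - win, by = max(1L, win %/% 2L)), n - win))
  }
  votes <- integer(n + 1L)     # votes[b + 1] = support for a cut before bin b
  cover <- integer(n + 1L)
  for (ws in starts) {
    rng <- (ws + 1L):(ws + win)
    cuts <- spectral_segment(M[rng, rng, drop = FALSE], k_max, min_tad,
                             min_silhouette)
    interior <- (ws + 2L):(ws + win)        # cuts strictly inside the window
    cover[interior] <- cover[interior] + 1L
    if (length(cuts)) votes[ws + cuts + 1L] <- votes[ws + cuts + 1L] + 1L
  }
  keep <- which(votes > 0 & votes >= ceiling(cover / 2))[] - 1L
  keep <- keep[keep > 0 & keep < n]

  # enforce the minimum TAD size against region edges and neighbours,
  # dropping the less-supported cut (later position on ties)
  keep <- sort(keep)
  repeat {
    gaps <- diff(c(0L, keep, n))
    bad <- which(gaps < min_tad)
    if (!length(gaps) || !length(bad)) break
    g <- bad[1]
    cand <- unique(c(if (g > 1L) keep[g - 1L], if (g <= length(keep)) keep[g]))
    v <- votes[cand + 1L]
    drop_at <- cand[order(v, -cand)][1]
    keep <- setdiff(keep, drop_at)
  }

  seg <- new_tad_segmentation(keep, n, matrix, NULL)
  seg$tads$score <- tad_scores(M, seg$tads)
  seg
}

new_tad_segmentation <- function(boundaries, n, matrix, scores) {
  edges <- c(0L, boundaries, n)
  tads <- data.frame(start = edges[-length(edges)], end = edges[-1L])
  tads$score <- if (length(scores)) scores else rep(NA_real_, nrow(tads))
  structure(
    list(resolution = matrix$bin_size, n_bins = n,
         boundaries = as.integer(boundaries), tads = tads, chrom = "chrS"),
    class = "tad_segmentation"
  )
}

# within/cross contact contrast per TAD (log2 ratio of mean counts)
tad_scores <- function(M, tads) {
  n <- nrow(M)
  vapply(seq_len(nrow(tads)), function(t) {
    rng <- (tads$start[t] + 1L):tads$end[t]
    within <- M[rng, rng, drop = FALSE]
    w_mean <- mean(within[upper.tri(within)])
    out <- setdiff(seq_len(n), rng)
    c_mean <- if (length(out)) mean(M[rng, out, drop = FALSE]) else NA_real_
    if (is.na(c_mean) || length(rng) < 2L) return(NA_real_)
    log2((w_mean + 1e-9) / (c_mean + 1e-9))
  }, numeric(1))
}

#' @export
print.tad_segmentation <- function(x, ...) {
  cat(sprintf("<tad_segmentation> %d TADs over %d bins at %g bp; interior boundaries: %s\n",
              nrow(x$tads), x$n_bins, x$resolution,
              if (length(x$boundaries)) paste(x$boundaries, collapse = ", ") else "none"))
  invisible(x)
}

# Spectral segmentation of one windowed contact graph.
# Returns interior cut positions in 1..(L-1): a cut at c puts local bins
# (0-based) 0..c-1 and c..L-1 in different groups.
spectral_segment <- function(A, k_max, min_tad, min_silhouette) {
  L <- nrow(A)
  k_cap <- min(k_max, L %/% min_tad)
  if (k_cap < 2L || all(A == 0)) return(integer(0))
  deg <- rowSums(A)
  dd <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Lsym <- diag(L) - (dd * A) * rep(dd, each = L)
  Lsym <- (Lsym + t(Lsym)) / 2
  E <- eigen(Lsym, symmetric = TRUE)
  vecs <- E$vectors[, L:1, drop = FALSE]          # ascending eigenvalues
  # reproducible sign: first non-negligible entry positive
  for (c in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, c]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, c] < 0) vecs[, c] <- -vecs[, c]
  }

  best_sil <- -Inf
  best_cuts <- integer(0)
  for (k in 2:k_cap) {
    X <- vecs[, seq_len(k), drop = FALSE]
    rn <- sqrt(rowSums(X^2))
    X <- X / pmax(rn, 1e-12)
    cuts <- dp_segment(X, k, min_tad)
    if (length(cuts) != k - 1L) next
    labels <- findInterval(seq_len(L) - 1L, cuts) + 1L
    sil <- mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
    if (sil > best_sil + 1e-12) {
      best_sil <- sil
      best_cuts <- cuts
    }
  }
  if (best_sil >= min_silhouette) best_cuts else integer(0)
}

# Optimal contiguous k-segmentation of the rows of X (minimum total
# within-segment sum of squares), each segment at least min_len rows.
dp_segment <- function(X, k, min_len) {
  n <- nrow(X)
  cs <- rbind(0, apply(X, 2L, cumsum))
  cs2 <- rbind(0, apply(X^2, 2L, cumsum))
  segcost <- function(a, b) {       # rows a..b inclusive, 1-based
    len <- b - a + 1L
    s <- cs[b + 1L, ] - cs[a, ]
    q <- cs2[b + 1L, ] - cs2[a, ]
    sum(q - s^2 / len)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in min_len:n) D[1L, j] <- segcost(1L, j)
  if (k >= 2L) {
    for (t in 2:k) {
      for (j in (t * min_len):n) {
        lo <- (t - 1L) * min_len
        hi <- j - min_len
        if (hi < lo) next
        prev <- D[t - 1L, lo:hi]
        costs <- vapply(lo:hi, function(m) segcost(m + 1L, j), numeric(1))
        tot <- prev + costs
        m_best <- which.min(tot)       # first minimum: deterministic ties
        D[t, j] <- tot[m_best]
        B[t, j] <- lo + m_best - 1L
      }
    }
  }
  if (!is.finite(D[k, n])) return(integer(0))
  cuts <- integer(0)
  j <- n
  for (t in k:2) {
    m <- B[t, j]
    cuts <- c(m, cuts)
    j <- m
  }
  cuts
}

#' Annotate TAD boundaries against region features
#'
#' Labels every interior boundary (and the two region edges) with the
#' features its coarse bin overlaps, using 0-based half-open interval
#' intersection in bp. Features may be a [build_layout()] object (genes
#' plus individual duplication copies) or any data frame with `name`,
#' `start`, `end` columns in bp.
#'
#' @param seg a `tad_segmentation`.
#' @param features a `region_layout` or a bp-coordinate feature frame.
#' @return data frame `boundary_bp`, `coarse_bin`, `label`, `score`; one
#'   row per boundary including the region edges.
#' @export
annotate_boundaries <- function(seg, features) {
  stopifnot(inherits(seg, "tad_segmentation"))
  if (inherits(features, "region_layout")) {
    if (features$region_length != seg$n_bins * seg$resolution) {
      stop("coordinate mismatch: layout region length does not match the segmentation")
    }
    feats <- rbind(
      features$genes[, c("name", "start", "end")],
      dup_copy_intervals(features)[, c("name", "start", "end")]
    )
  } else {
    feats <- as.data.frame(features)
    if (!all(c("name", "start", "end") %in% names(feats))) {
      stop("features must carry bp columns name, start, end")
    }
    if (nrow(feats) && max(feats$end) <= seg$n_bins) {
      stop("features look bin-indexed, not bp: supply bp coordinates")
    }
  }
  res <- seg$resolution
  bnd <- c(0L, seg$boundaries, seg$n_bins)
  is_edge <- bnd == 0L | bnd == seg$n_bins
  labels <- vapply(seq_along(bnd), function(i) {
    if (is_edge[i]) return("region edge")
    b <- bnd[i]
    lo <- b * res
    hi <- (b + 1L) * res
    hit <- feats$name[feats$start < hi & feats$end > lo]
    if (length(hit)) paste(hit, collapse = ",") else
      if (nrow(feats)) "intergenic" else "unannotated"
  }, character(1))
  score <- c(NA_real_, seg$tads$score[match(seg$boundaries, seg$tads$start)],
             NA_real_)
  data.frame(boundary_bp = bnd * res, coarse_bin = bnd, label = labels,
             score = score)
}

#' Write TAD intervals as BED and the boundary report as TSV
#' @param seg a `tad_segmentation`.
#' @param bed_path,report_path output files; `NULL` skips either one.
#' @param features passed to [annotate_boundaries()] for the report.
#' @return invisibly, the boundary report data frame (or `NULL`).
#' @export
write_tads <- function(seg, bed_path = NULL, report_path = NULL,
                       features = NULL) {
  stopifnot(inherits(seg, "tad_segmentation"))
  if (!is.null(bed_path)) {
    write_bed(data.frame(chrom = seg$chrom,
                         start = seg$tads$start * seg$resolution,
                         end = seg$tads$end * seg$resolution,
                         name = paste0("TAD_", seq_len(nrow(seg$tads))),
                         score = ifelse(is.na(seg$tads$score), 0,
                                        round(pmin(pmax(seg$tads$score, 0), 10) * 100))),
              bed_path)
  }
  rep_df <- NULL
  if (!is.null(report_path)) {
    rep_df <- if (!is.null(features)) annotate_boundaries(seg, features) else {
      bnd <- c(0L, seg$boundaries, seg$n_bins)
      data.frame(boundary_bp = bnd * seg$resolution, coarse_bin = bnd,
                 label = "unannotated", score = NA_real_)
    }
    con <- file(report_path, "w")
    writeLines("boundary_bp\tcoarse_bin\tlabel\tscore", con)
    writeLines(paste(format(rep_df$boundary_bp, scientific = FALSE, trim = TRUE),
                     rep_df$coarse_bin, rep_df$label,
                     ifelse(is.na(rep_df$score), "NA", fmt_num(rep_df$score)),
                     sep = "\t"), con)
    close(con)
  }
  invisible(rep_df)
}
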