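#' Sparse symmetric binned contact matrix
#'
#' The central container of the package: a cis contact map over `n_bins`
#' genomic bins of width `bin_size`, stored as upper-triangular sparse
#' triplets with non-negative (possibly fractional) counts. Duplicate
#' triplets are aggregated and entries are kept in canonical (i <= j,
#' sorted) order, so the representation never depends on insertion order.
#'
#' @param bin_i,bin_j integer bin indices in `[0, n_bins)`; pairs are
#'   symmetrised so the stored entry always has `bin_i <= bin_j`.
#' @param count non-negative counts (fractional counts are allowed).
#' @param n_bins number of bins in the region.
#' @param bin_size bin width in bp.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bin_i, bin_j, count, n_bins, bin_size) {
  stopifnot(length(bin_i) == length(bin_j), length(count) == length(bin_i))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (bin_size <= 0) stop("bin_size must be > 0")
  bin_i <- as.integer(bin_i)
  bin_j <- as.integer(bin_j)
  count <- as.numeric(count)
  if (length(bin_i) > 0L) {
    if (anyNA(bin_i) || anyNA(bin_j) ||
        any(bin_i < 0L | bin_j < 0L | bin_i >= n_bins | bin_j >= n_bins)) {
      stop("bin index out of range [0, n_bins)")
    }
    if (any(!is.finite(count)) || any(count < 0)) {
      stop("counts must be finite and non-negative")
    }
    ii <- pmin(bin_i, bin_j)
    jj <- pmax(bin_i, bin_j)
    key <- as.numeric(ii) * n_bins + jj
    agg <- rowsum(count, key)            # sorted by key
    keys <- as.numeric(rownames(agg))
    cnt <- agg[, 1L]
    keep <- cnt != 0
    keys <- keys[keep]
    cnt <- unname(cnt[keep])
    bin_i <- as.integer(keys %/% n_bins)
    bin_j <- as.integer(keys %% n_bins)
    count <- cnt
  } else {
    bin_i <- integer(0)
    bin_j <- integer(0)
    count <- numeric(0)
  }
  structure(
    list(bin_i = bin_i, bin_j = bin_j, count = count,
         n_bins = n_bins, bin_size = as.numeric(bin_size)),
    class = "contact_matrix"
  )
}

#' Total mass of a contact matrix
#' @param x a `contact_matrix`.
#' @return sum of all (upper-triangular) counts.
#' @export
cm_mass <- function(x) {
  stopifnot(inherits(x, "contact_matrix"))
  sum(x$count)
}

#' Dense symmetric view of a contact matrix
#'
#' Off-diagonal entries are mirrored; the diagonal is not double-counted.
#' Intended for region-scale matrices (a few hundred bins).
#' @param x a `contact_matrix`.
#' @return an `n_bins` x `n_bins` numeric matrix.
#' @export
cm_dense <- function(x) {
  stopifnot(inherits(x, "contact_matrix"))
  n <- x$n_bins
  M <- matrix(0, n, n)
  if (length(x$count)) {
    M[cbind(x$bin_i + 1L, x$bin_j + 1L)] <- x$count
    off <- x$bin_i != x$bin_j
    M[cbind(x$bin_j[off] + 1L, x$bin_i[off] + 1L)] <- x$count[off]
  }
  M
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins x %g bp, %d non-zero entries, mass %.6g\n",
              x$n_bins, x$bin_size, length(x$count), cm_mass(x)))
  invisible(x)
}

#' Write a contact matrix as sparse triplet text
#'
#' Format: comment header naming `bin_size` and `n_bins`, then a
#' tab-separated table `bin_i  bin_j  count` (upper triangle only).
#' Numeric formatting is deterministic so identical matrices produce
#' byte-identical files.
#' @param x a `contact_matrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_contact_matrix <- function(x, path) {
  stopifnot(inherits(x, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_size=%s", fmt_num(x$bin_size)),
               sprintf("# n_bins=%d", x$n_bins),
               "bin_i\tbin_j\tcount"), con)
  if (length(x$count)) {
    writeLines(paste(x$bin_i, x$bin_j, fmt_num(x$count), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sparse triplet contact matrix
#' @param path file written by [write_contact_matrix()].
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  head <- readLines(path, n = 10L)
  bs <- sub("^# bin_size=", "", grep("^# bin_size=", head, value = TRUE)[1])
  nb <- sub("^# n_bins=", "", grep("^# n_bins=", head, value = TRUE)[1])
  if (is.na(bs) || is.na(nb)) stop("missing bin_size/n_bins header in ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  contact_matrix(tab$bin_i, tab$bin_j, tab$count,
                 n_bins = as.integer(nb), bin_size = as.numeric(bs))
}

#' Sum-pool a contact matrix to coarser bins
#'
#' Fine bins are grouped `factor` at a time; when `factor` does not divide
#' `n_bins`, the trailing partial group is absorbed into the last coarse
#' bin. Total mass is preserved exactly.
#' @param x a `contact_matrix`.
#' @param factor integer pooling factor (>= 1).
#' @return a `contact_matrix` at `bin_size * factor` resolution.
#' @export
coarsen <- function(x, factor) {
  stopifnot(inherits(x, "contact_matrix"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(x)
  n_coarse <- x$n_bins %/% factor
  if (n_coarse < 1L) stop("factor larger than n_bins")
  ci <- pmin(x$bin_i %/% factor, n_coarse - 1L)
  cj <- pmin(x$bin_j %/% factor, n_coarse - 1L)
  contact_matrix(ci, cj, x$count, n_bins = n_coarse,
                 bin_size = x$bin_size * factor)
}
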