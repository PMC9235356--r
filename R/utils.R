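# Internal helpers shared across modules.

# Deterministic numeric formatting: shortest representation that
# round-trips a double (17 significant digits, trimmed by %g).
fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, format = "g", digits = 17)
    gsub(" ", "", s)
  }, character(1))
}

# Clipped box-filter sum: S[i, j] = sum of M over rows i-w..i+w and
# columns j-w..j+w, truncated at the matrix edge.
boxsum <- function(M, w) {
  n <- nrow(M)
  if (w == 0L) return(M)
  P <- matrix(0, n + 1L, n + 1L)
  P[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  lo <- pmax(1L, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w)
  P[hi + 1L, hi + 1L] - P[lo, hi + 1L] - P[hi + 1L, lo] + P[lo, lo]
}

# parse "chrS:START-END" or pass through a numeric (start, end) pair;
# returns c(start, end) in bp (0-based half-open).
parse_interval <- function(x) {
  if (is.numeric(x) && length(x) == 2L) {
    iv <- as.numeric(x)
  } else if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^(?:[^:]+:)?([0-9]+)-([0-9]+)$", x))[[1]]
    if (length(m) != 3L) stop("cannot parse interval: ", x)
    iv <- as.numeric(m[2:3])
  } else {
    stop("interval must be c(start, end) or 'chr:start-end'")
  }
  if (iv[2] <= iv[1]) stop("interval end must exceed start")
  iv
}

# Minimal deterministic BED writer. `df` may carry chrom, start, end and
# optionally name, score, strand columns; missing trailing columns are
# dropped, intervals are 0-based half-open.
write_bed <- function(df, path, header = NULL) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  use <- cols[cols %in% names(df)]
  # BED columns are positional: stop at the first absent one
  k <- match(FALSE, cols %in% use, nomatch = length(cols) + 1L) - 1L
  use <- cols[seq_len(k)]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(df)) {
    fields <- lapply(use, function(cl) {
      v <- df[[cl]]
      if (is.numeric(v) && cl %in% c("start", "end", "score")) {
        format(v, scientific = FALSE, trim = TRUE)
      } else as.character(v)
    })
    writeLines(do.call(paste, c(fields, sep = "\t")), con)
  }
  invisible(path)
}

read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    return(out)
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- cols[seq_len(ncol(tab))]
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
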