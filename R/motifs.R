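#' Construct a motif model from a count or probability matrix
#'
#' @param mat 4 x width numeric matrix with rows A, C, G, T (JASPAR-like).
#'   Count matrices are detected automatically and normalized per column
#'   after adding `pseudocount` to every cell.
#' @param background base composition of the background model (sums to 1).
#' @param threshold log-odds score cutoff in bits.
#' @param pseudocount added per cell when normalizing counts.
#' @return object of class `motif_model` with the probability matrix,
#'   log-odds matrix (bits), background, width and threshold.
#' @export
motif_model <- function(mat, background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                        threshold = 8, pseudocount = 0.25) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("motif matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stop("motif width must be >= 4")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) stop("motif matrix entries must be non-negative")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 1e-6)) {         # counts: normalize
    mat <- sweep(mat + pseudocount, 2L, csums + 4 * pseudocount, "/")
  }
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("columns must sum to 1")
  lo <- log2(mat / background)
  structure(
    list(prob = mat, logodds = lo, background = background,
         width = ncol(mat), threshold = threshold,
         max_score = sum(apply(lo, 2L, max))),
    class = "motif_model"
  )
}

#' Read a tab-separated motif matrix
#'
#' Accepts JASPAR-like tables: 4 tab-separated rows of counts or
#' probabilities, optionally prefixed by the base letter and with a `>`
#' header line.
#' @param path file path.
#' @param ... passed to [motif_model()].
#' @return a `motif_model`.
#' @export
read_motif <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[>#]", lines) & nzchar(lines)]
  if (length(lines) != 4L) stop("expected 4 matrix rows in ", path)
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (grepl("^[ACGTacgt]$", f[1])) f <- f[-1]
    as.numeric(f)
  })
  motif_model(do.call(rbind, rows), ...)
}

#' Consensus sequence of a motif model
#' @param model a `motif_model`.
#' @return character string; ties resolved in A, C, G, T order.
#' @export
consensus_sequence <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  paste(rownames(model$prob)[apply(model$prob, 2L, which.max)], collapse = "")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, consensus %s, threshold %g bits (max %.2f)\n",
              x$width, consensus_sequence(x), x$threshold, x$max_score))
  invisible(x)
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Scan a sequence for motif hits on both strands
#'
#' Scores every window with the summed per-position log2 odds
#' (`sum log2(p(base) / q(base))`, in bits); the reverse strand is scored
#' on the reverse complement of the window and reported at the same
#' forward-strand start coordinate. Windows containing N are skipped.
#' Both strands are reported independently when both pass the threshold;
#' hits are sorted by position, then strand ("+" before "-").
#'
#' @param sequence character string over A, C, G, T, N (or a
#'   `Biostrings::DNAString`).
#' @param model a `motif_model`.
#' @param threshold optional override of the model threshold (bits).
#' @return data frame `position` (0-based start), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, model, threshold = NULL) {
  stopifnot(inherits(model, "motif_model"))
  thr <- threshold %||% model$threshold
  seq_chr <- toupper(as.character(sequence))
  bases <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  w <- model$width
  n <- length(bases)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < w) {
    warning("sequence shorter than motif width: no windows to scan")
    return(empty)
  }
  code <- match(bases, c("A", "C", "G", "T"))   # N and others -> NA
  if (anyNA(code) && !all(bases[is.na(code)] == "N")) {
    stop("sequence must be over A, C, G, T, N")
  }
  n_win <- n - w + 1L
  lo_f <- model$logodds
  # scanning the forward strand with the reverse-complemented matrix is
  # equivalent to scoring the reverse complement of each window
  lo_r <- model$logodds[4:1, w:1, drop = FALSE]
  score_f <- numeric(n_win)
  score_r <- numeric(n_win)
  for (k in seq_len(w)) {
    b <- code[k:(n_win + k - 1L)]
    score_f <- score_f + lo_f[cbind(b, k)]
    score_r <- score_r + lo_r[cbind(b, k)]
  }
  keep_f <- which(!is.na(score_f) & score_f >= thr)
  keep_r <- which(!is.na(score_r) & score_r >= thr)
  hits <- rbind(
    data.frame(position = keep_f - 1L,
               strand = rep("+", length(keep_f)),
               score = score_f[keep_f]),
    data.frame(position = keep_r - 1L,
               strand = rep("-", length(keep_r)),
               score = score_r[keep_r])
  )
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify TAD anchor orientation from motif hits
#'
#' A TAD is `convergent` when at least one "+" hit lies within
#' `anchor_window` of its left boundary and at least one "-" hit within
#' `anchor_window` of its right boundary (the loop-extrusion
#' configuration); `divergent` is the mirror image, `tandem` has
#' same-strand hits at both anchors, and `unanchored` anything else.
#' Convergent takes precedence when several predicates hold.
#'
#' @param hits data frame from [scan_pwm()] with bp positions in the same
#'   coordinates as the segmentation.
#' @param seg a `tad_segmentation`.
#' @param anchor_window window around each boundary in bp; defaults to
#'   2 coarse bins.
#' @return data frame, one row per TAD: boundaries in bp, hit counts per
#'   strand at each anchor, and the orientation `label`.
#' @export
classify_anchor_orientation <- function(hits, seg,
                                        anchor_window = 2 * seg$resolution) {
  stopifnot(inherits(seg, "tad_segmentation"))
  res <- seg$resolution
  out <- lapply(seq_len(nrow(seg$tads)), function(t) {
    lb <- seg$tads$start[t] * res
    rb <- seg$tads$end[t] * res
    near_l <- abs(hits$position - lb) <= anchor_window
    near_r <- abs(hits$position - rb) <= anchor_window
    npl <- sum(near_l & hits$strand == "+")
    nml <- sum(near_l & hits$strand == "-")
    npr <- sum(near_r & hits$strand == "+")
    nmr <- sum(near_r & hits$strand == "-")
    label <- if (npl > 0 && nmr > 0) "convergent"
      else if (nml > 0 && npr > 0) "divergent"
      else if ((npl > 0 && npr > 0) || (nml > 0 && nmr > 0)) "tandem"
      else "unanchored"
    data.frame(tad = t, start_bp = lb, end_bp = rb,
               n_plus_left = npl, n_minus_left = nml,
               n_plus_right = npr, n_minus_right = nmr,
               label = label)
  })
  do.call(rbind, out)
}

#' Write motif hits as extended BED6 + exact score
#'
#' BED6 with the integer score column scaled to 0-1000 relative to the
#' motif's maximum attainable score, plus the exact log-odds score (bits)
#' in column 7.
#' @param hits data frame from [scan_pwm()].
#' @param model the `motif_model` used for scanning.
#' @param path output file.
#' @param chrom chromosome name.
#' @return the path, invisibly.
#' @export
write_motif_hits <- function(hits, model, path, chrom = "chrS") {
  stopifnot(inherits(model, "motif_model"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits)) {
    scaled <- round(pmin(1000, pmax(0, 1000 * hits$score / model$max_score)))
    writeLines(paste(chrom,
                     format(hits$position, scientific = FALSE, trim = TRUE),
                     format(hits$position + model$width, scientific = FALSE,
                            trim = TRUE),
                     paste0("ctcf_hit_", seq_len(nrow(hits))),
                     scaled, hits$strand, fmt_num(hits$score),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Synthesize the region sequence implied by a layout
#'
#' Random background sequence with the motif consensus planted at every
#' CTCF site (reverse-complemented on "-" sites); the first duplication
#' unit is then copied verbatim onto the remaining copies, so the repeat
#' copies are exact duplicates carrying the same motifs.
#'
#' @param layout a [build_layout()] object.
#' @param model motif model whose consensus is planted.
#' @param seed RNG seed.
#' @param gc background GC content.
#' @return character string of length `region_length`.
#' @export
synth_region_sequence <- function(layout, model, seed = 1L, gc = 0.4) {
  stopifnot(inherits(layout, "region_layout"), inherits(model, "motif_model"))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), layout$region_length, replace = TRUE, prob = p)
  cons <- strsplit(consensus_sequence(model), "", fixed = TRUE)[[1]]
  rc <- rev(unname(DNA_COMP[cons]))
  for (s in seq_len(nrow(layout$ctcf_sites))) {
    pos <- layout$ctcf_sites$position[s]
    motif <- if (layout$ctcf_sites$strand[s] == "+") cons else rc
    if (pos + length(motif) <= layout$region_length) {
      bases[(pos + 1L):(pos + length(motif))] <- motif
    }
  }
  if (layout$dup_copies >= 2L) {
    u0 <- layout$dup_unit
    unit <- bases[(u0[1] + 1L):(u0[2])]
    for (k in seq_len(layout$dup_copies - 1L)) {
      off <- u0[1] + k * layout$dup_unit_length
      bases[(off + 1L):(off + layout$dup_unit_length)] <- unit
    }
  }
  paste(bases, collapse = "")
}

#' Write / read the synthetic region FASTA
#' @param sequence character string.
#' @param path output FASTA path.
#' @param name sequence name.
#' @return the path, invisibly.
#' @export
write_region_fasta <- function(sequence, path, name = "chrS") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_region_fasta
#' @export
read_region_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}
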