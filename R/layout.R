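#' Blueprint of the synthetic duplicated locus
#'
#' Builds the layout every downstream stage is exercised against: a ~1 Mb
#' region holding seven tandem genes, an intragenic tandem segmental
#' duplication whose copies make reads ambiguous, CTCF sites (one
#' reverse-orientation site per duplication copy, convergent sites at the
#' outer domain edges), and the planted TAD boundary truth. Defaults mirror
#' the biology the package targets: a 1 Mb region binned at 5 kb, an 18 kb
#' duplication unit repeated twice inside the fifth gene, and a boundary
#' planted at the midpoint of the second copy.
#'
#' @param region_length region size in bp; must be a multiple of `bin_size`.
#' @param bin_size bin width in bp.
#' @param dup_unit_length length of one duplication unit in bp
#'   (>= 2 * `bin_size`).
#' @param dup_copies number of tandem copies (>= 1).
#' @param dup_start start of the first copy in bp.
#' @param boundary_positions planted TAD boundaries in bp; `NULL` plants a
#'   single boundary at the midpoint of copy `min(2, dup_copies)`.
#' @param ctcf_spec optional data frame with columns `position`, `strand`
#'   giving the full CTCF site list; `NULL` builds the default set
#'   (convergent outer anchors, one "-" site per duplication copy, one "+"
#'   site just downstream of the duplicated block).
#' @param genes optional data frame (`name`, `start`, `end`, `strand`);
#'   `NULL` uses the default seven-gene arrangement.
#' @param seed unused; accepted for interface symmetry with the stochastic
#'   generators (layout construction is deterministic).
#' @return an object of class `region_layout`.
#' @examples
#' layout <- build_layout()
#' layout$dup_block
#' @export
build_layout <- function(region_length = 1e6, bin_size = 5000,
                         dup_unit_length = 18000, dup_copies = 2,
                         dup_start = 450000,
                         boundary_positions = NULL,
                         ctcf_spec = NULL, genes = NULL, seed = NULL) {
  region_length <- as.numeric(region_length)
  bin_size <- as.numeric(bin_size)
  dup_copies <- as.integer(dup_copies)
  if (region_length <= 0 || bin_size <= 0) stop("region_length and bin_size must be > 0")
  if (region_length %% bin_size != 0) {
    stop("region_length must be an integer multiple of bin_size")
  }
  if (dup_unit_length < 2 * bin_size) {
    stop("dup_unit_length must be >= 2 * bin_size")
  }
  if (dup_copies < 1L) stop("dup_copies must be >= 1")
  dup_block <- c(dup_start, dup_start + dup_unit_length * dup_copies)
  if (dup_block[1] < 0 || dup_block[2] > region_length) {
    stop("duplication block must lie fully inside the region")
  }

  if (is.null(boundary_positions)) {
    copy_for_boundary <- min(2L, dup_copies)
    boundary_positions <- dup_start +
      (copy_for_boundary - 1L) * dup_unit_length + dup_unit_length / 2
  }
  boundary_positions <- sort(as.numeric(boundary_positions))
  if (anyDuplicated(boundary_positions)) stop("duplicate boundary positions")
  if (any(boundary_positions <= 0 | boundary_positions >= region_length)) {
    stop("boundaries must lie strictly inside (0, region_length)")
  }
  if (dup_copies >= 2L &&
      !any(boundary_positions > dup_block[1] & boundary_positions < dup_block[2])) {
    stop("with dup_copies >= 2 at least one boundary must lie inside the duplicated block")
  }

  if (is.null(genes)) {
    genes <- data.frame(
      name = c("C4BPB", "C4BPA", "CD55", "CR2", "CR1", "CR1L", "CD46"),
      start = c(40000, 90000, 200000, 300000, 400000, 600000, 700000),
      end = c(80000, 130000, 240000, 335000, 540000, 650000, 745000),
      strand = "+",
      stringsAsFactors = FALSE
    )
  }
  if (any(genes$start < 0 | genes$end > region_length | genes$end <= genes$start)) {
    stop("gene intervals must be valid and inside the region")
  }

  copy_starts <- dup_start + (seq_len(dup_copies) - 1L) * dup_unit_length
  if (is.null(ctcf_spec)) {
    ctcf_spec <- data.frame(
      position = c(2000, copy_starts + 5000, dup_block[2] + 2000,
                   region_length - 2000),
      strand = c("+", rep("-", dup_copies), "+", "-"),
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("position", "strand") %in% names(ctcf_spec))) {
    stop("ctcf_spec needs columns position, strand")
  }
  if (!all(ctcf_spec$strand %in% c("+", "-"))) stop("CTCF strand must be '+' or '-'")
  if (any(ctcf_spec$position < 0 | ctcf_spec$position >= region_length)) {
    stop("CTCF positions must lie inside the region")
  }
  ctcf_spec <- ctcf_spec[order(ctcf_spec$position, ctcf_spec$strand), , drop = FALSE]
  rownames(ctcf_spec) <- NULL
  # repeat invariant: every duplication copy carries >= 1 reverse site
  for (cs in copy_starts) {
    inside <- ctcf_spec$position >= cs & ctcf_spec$position < cs + dup_unit_length
    if (!any(inside & ctcf_spec$strand == "-")) {
      stop("every duplication copy must contain at least one '-' CTCF site")
    }
  }

  structure(
    list(region_length = region_length,
         bin_size = bin_size,
         n_bins = as.integer(region_length %/% bin_size),
         genes = genes,
         dup_unit = c(dup_start, dup_start + dup_unit_length),
         dup_unit_length = dup_unit_length,
         dup_copies = dup_copies,
         dup_block = dup_block,
         ctcf_sites = ctcf_spec,
         tad_boundaries_truth = boundary_positions),
    class = "region_layout"
  )
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("<region_layout> %g bp / %g bp bins (%d bins)\n",
              x$region_length, x$bin_size, x$n_bins))
  cat(sprintf("  genes: %s\n", paste(x$genes$name, collapse = ", ")))
  cat(sprintf("  duplication: %g bp unit x %d copies at [%g, %g)\n",
              x$dup_unit_length, x$dup_copies, x$dup_block[1], x$dup_block[2]))
  cat(sprintf("  planted boundaries (bp): %s\n",
              paste(x$tad_boundaries_truth, collapse = ", ")))
  invisible(x)
}

# bp intervals of the individual duplication copies, 0-based half-open
dup_copy_intervals <- function(layout) {
  starts <- layout$dup_unit[1] +
    (seq_len(layout$dup_copies) - 1L) * layout$dup_unit_length
  data.frame(name = paste0("dup_copy_", seq_len(layout$dup_copies)),
             start = starts, end = starts + layout$dup_unit_length,
             stringsAsFactors = FALSE)
}

# indices of bins fully contained in the duplicated block (0-based)
dup_interior_bins <- function(layout) {
  b <- seq_len(layout$n_bins) - 1L
  bs <- layout$bin_size
  b[b * bs >= layout$dup_block[1] & (b + 1) * bs <= layout$dup_block[2]]
}
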