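#' Simulate Hi-C read pairs over a synthetic duplicated region
#'
#' Draws cis read pairs whose true bin pair follows a power-law distance
#' decay attenuated across planted TAD boundaries, then derives each
#' read's candidate alignments: a read end falling inside the duplicated
#' block is ambiguous among the homologous positions in every copy, so its
#' candidates are the binned images of the bp position shifted by whole
#' duplication units. Self-pairs (distance 0 bins) are excluded; reads with
#' more than one distinct candidate bin pair are multireads.
#'
#' The sampling weight of a true bin pair (i, j), i < j, is
#' `(d + 1)^(-decay_alpha) * insulation^b` with `d = j - i` in bins and `b`
#' the number of planted boundaries between the two bin midpoints.
#'
#' @param layout a [build_layout()] object.
#' @param n_reads number of read pairs to draw (>= 1).
#' @param decay_alpha power-law decay exponent (> 0); 1.0 is the canonical
#'   contact-probability decay at the sub-Mb scale.
#' @param insulation cross-boundary attenuation in (0, 1]; 1 means no
#'   boundary effect.
#' @param seed RNG seed; identical `(layout, arguments, seed)` reproduce
#'   identical output (Mersenne-Twister, R's default generator).
#' @return list with elements `reads` (data frame, one row per candidate:
#'   `read_id`, `bin_i`, `bin_j`, `n_candidates`, `is_true`), `truth`
#'   (a `contact_matrix` of true bin pairs) and the echoed parameters.
#' @export
simulate_contacts <- function(layout, n_reads, decay_alpha = 1.0,
                              insulation = 0.2, seed = 1L) {
  stopifnot(inherits(layout, "region_layout"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (!is.finite(decay_alpha) || decay_alpha <= 0) stop("decay_alpha must be > 0")
  if (!is.finite(insulation) || insulation <= 0 || insulation > 1) {
    stop("insulation must lie in (0, 1]")
  }
  n <- layout$n_bins
  bs <- layout$bin_size

  up <- which(upper.tri(matrix(0, n, n)))          # column-major upper triangle
  pi0 <- (up - 1L) %% n                             # 0-based row (= smaller bin)
  pj0 <- (up - 1L) %/% n                            # 0-based col (= larger bin)
  d <- pj0 - pi0
  mid <- (seq_len(n) - 0.5) * bs
  rgn <- findInterval(mid, layout$tad_boundaries_truth)
  straddle <- abs(rgn[pj0 + 1L] - rgn[pi0 + 1L])
  wgt <- (d + 1)^(-decay_alpha) * insulation^straddle

  set.seed(seed)
  draw <- sample.int(length(wgt), n_reads, replace = TRUE, prob = wgt)
  ti <- pi0[draw]
  tj <- pj0[draw]
  bp1 <- ti * bs + (sample.int(bs, n_reads, replace = TRUE) - 1)
  bp2 <- tj * bs + (sample.int(bs, n_reads, replace = TRUE) - 1)

  blk <- layout$dup_block
  ul <- layout$dup_unit_length
  copies <- layout$dup_copies
  in1 <- copies >= 2L & bp1 >= blk[1] & bp1 < blk[2]
  in2 <- copies >= 2L & bp2 >= blk[1] & bp2 < blk[2]
  c1 <- ifelse(in1, copies, 1L)
  c2 <- ifelse(in2, copies, 1L)

  nrep <- c1 * c2
  ridx <- rep.int(seq_len(n_reads), nrep)
  t_in_read <- sequence(nrep) - 1L
  c2rep <- rep.int(c2, nrep)
  k1 <- t_in_read %/% c2rep
  k2 <- t_in_read %% c2rep
  a1 <- ifelse(in1, blk[1] + (bp1 - blk[1]) %% ul, bp1)
  a2 <- ifelse(in2, blk[1] + (bp2 - blk[1]) %% ul, bp2)
  e1 <- rep.int(a1, nrep) + k1 * ul
  e2 <- rep.int(a2, nrep) + k2 * ul
  b1 <- e1 %/% bs
  b2 <- e2 %/% bs
  bi <- pmin(b1, b2)
  bj <- pmax(b1, b2)

  key <- ridx * (as.numeric(n) * n) + bi * n + bj
  keep <- !duplicated(key)
  ridx <- ridx[keep]; bi <- bi[keep]; bj <- bj[keep]
  nc <- tabulate(ridx, nbins = n_reads)
  is_true <- bi == ti[ridx] & bj == tj[ridx]

  reads <- data.frame(read_id = ridx,
                      bin_i = as.integer(bi),
                      bin_j = as.integer(bj),
                      n_candidates = nc[ridx],
                      is_true = is_true)
  truth <- contact_matrix(ti, tj, rep(1, n_reads), n_bins = n, bin_size = bs)
  list(reads = reads, truth = truth, layout = layout,
       params = list(n_reads = n_reads, decay_alpha = decay_alpha,
                     insulation = insulation, seed = seed))
}

#' Write simulation fixtures to plain-text files
#'
#' Emits the read-pair candidate table (tab-delimited: `read_id`, `bin_i`,
#' `bin_j`, `n_candidates`), the true origin pairs, truth boundaries, genes
#' and stranded CTCF sites as 0-based half-open BED, and a YAML layout
#' manifest. All writers are byte-deterministic. The files round-trip
#' losslessly through [read_fixture()].
#'
#' @param reads candidate table as produced by [simulate_contacts()] (the
#'   full simulation list is also accepted).
#' @param layout the [build_layout()] object the reads were simulated from.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(reads, layout, out_dir) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads <- reads$reads
  }
  stopifnot(inherits(layout, "region_layout"), is.data.frame(reads))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(out_dir, "reads.tsv"),
    truth_pairs = file.path(out_dir, "truth_pairs.tsv"),
    boundaries = file.path(out_dir, "truth_boundaries.bed"),
    genes = file.path(out_dir, "genes.bed"),
    ctcf = file.path(out_dir, "ctcf_sites.bed"),
    manifest = file.path(out_dir, "layout.yml")
  )

  con <- file(paths[["reads"]], "w")
  writeLines("read_id\tbin_i\tbin_j\tn_candidates", con)
  if (nrow(reads)) {
    writeLines(paste(reads$read_id, reads$bin_i, reads$bin_j,
                     reads$n_candidates, sep = "\t"), con)
  }
  close(con)

  con <- file(paths[["truth_pairs"]], "w")
  writeLines("read_id\tbin_i\tbin_j", con)
  tr <- reads[isTRUE_col(reads$is_true), , drop = FALSE]
  if (nrow(tr)) {
    writeLines(paste(tr$read_id, tr$bin_i, tr$bin_j, sep = "\t"), con)
  }
  close(con)

  bnd <- layout$tad_boundaries_truth
  write_bed(data.frame(chrom = "chrS", start = bnd, end = bnd + 1,
                       name = paste0("boundary_", seq_along(bnd))),
            paths[["boundaries"]])
  write_bed(data.frame(chrom = "chrS", start = layout$genes$start,
                       end = layout$genes$end, name = layout$genes$name,
                       score = 0, strand = layout$genes$strand),
            paths[["genes"]])
  write_bed(data.frame(chrom = "chrS", start = layout$ctcf_sites$position,
                       end = layout$ctcf_sites$position + 1,
                       name = paste0("ctcf_", seq_len(nrow(layout$ctcf_sites))),
                       score = 0, strand = layout$ctcf_sites$strand),
            paths[["ctcf"]])

  yaml::write_yaml(list(
    region_length = layout$region_length,
    bin_size = layout$bin_size,
    dup_start = layout$dup_unit[1],
    dup_unit_length = layout$dup_unit_length,
    dup_copies = layout$dup_copies,
    files = as.list(basename(paths))
  ), paths[["manifest"]])

  invisible(paths)
}

isTRUE_col <- function(x) if (is.null(x)) logical(0) else x

#' Read fixtures written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with `layout` (a `region_layout`) and `reads` (candidate
#'   table with `n_candidates` and `is_true` restored).
#' @export
read_fixture <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "layout.yml"))
  bnd <- read_bed(file.path(dir, "truth_boundaries.bed"))
  genes <- read_bed(file.path(dir, "genes.bed"))
  ctcf <- read_bed(file.path(dir, "ctcf_sites.bed"))
  layout <- build_layout(
    region_length = man$region_length, bin_size = man$bin_size,
    dup_unit_length = man$dup_unit_length, dup_copies = man$dup_copies,
    dup_start = man$dup_start,
    boundary_positions = bnd$start,
    ctcf_spec = data.frame(position = ctcf$start, strand = ctcf$strand,
                           stringsAsFactors = FALSE),
    genes = data.frame(name = genes$name, start = genes$start,
                       end = genes$end, strand = genes$strand,
                       stringsAsFactors = FALSE)
  )
  reads <- read_pairs(file.path(dir, "reads.tsv"))
  tp <- file.path(dir, "truth_pairs.tsv")
  if (file.exists(tp)) {
    truth <- utils::read.table(tp, header = TRUE, sep = "\t")
    key <- paste(reads$read_id, reads$bin_i, reads$bin_j)
    reads$is_true <- key %in% paste(truth$read_id, truth$bin_i, truth$bin_j)
  }
  list(layout = layout, reads = reads)
}

#' Read a candidate read-pair table
#'
#' Tab-delimited, one line per candidate alignment: `read_id`, `bin_i`,
#' `bin_j`, `n_candidates`. A missing `n_candidates` column is rebuilt from
#' the per-read line counts.
#' @param path file path.
#' @return data frame of candidates.
#' @export
read_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("read_id", "bin_i", "bin_j") %in% names(tab))) {
    stop("read-pair table needs columns read_id, bin_i, bin_j")
  }
  if (is.null(tab$n_candidates)) {
    cnt <- table(tab$read_id)
    tab$n_candidates <- as.integer(cnt[as.character(tab$read_id)])
  }
  tab
}
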