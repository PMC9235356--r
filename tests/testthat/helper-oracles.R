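# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (loops, direct formula evaluation)
# and shares no code with the package internals it checks.

DNA_COMP_H <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# brute-force PWM scan: score every window on both strands by direct
# per-position lookup; returns one row per window with forward and
# reverse-complement scores (NA where the window contains N)
naive_scan <- function(sequence, model) {
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  w <- model$width
  n <- length(b)
  if (n < w) return(data.frame(position = integer(0)))
  out <- lapply(seq_len(n - w + 1L), function(p) {
    win <- b[p:(p + w - 1L)]
    if (any(win == "N")) {
      return(data.frame(position = p - 1L, fwd = NA_real_, rev = NA_real_))
    }
    fs <- sum(vapply(seq_len(w), function(k) model$logodds[win[k], k],
                     numeric(1)))
    rcw <- rev(unname(DNA_COMP_H[win]))
    rs <- sum(vapply(seq_len(w), function(k) model$logodds[rcw[k], k],
                     numeric(1)))
    data.frame(position = p - 1L, fwd = fs, rev = rs)
  })
  do.call(rbind, out)
}

# direct evaluation of one posterior sweep over uni-read counts only:
# posterior_k proportional to P(d_k) * (L_k + pseudocount) with L_k the
# clipped (2w+1)^2 neighbourhood sum, computed with explicit loops
naive_posterior_sweep <- function(reads, uni_matrix, prior, w, pseudocount) {
  U <- cm_dense(uni_matrix)
  n <- nrow(U)
  multi <- reads[reads$n_candidates > 1L, , drop = FALSE]
  res <- numeric(nrow(multi))
  for (id in unique(multi$read_id)) {
    rows <- which(multi$read_id == id)
    wt <- vapply(rows, function(r) {
      i <- multi$bin_i[r] + 1L
      j <- multi$bin_j[r] + 1L
      L <- 0
      for (a in max(1, i - w):min(n, i + w)) {
        for (b in max(1, j - w):min(n, j + w)) L <- L + U[a, b]
      }
      prior_prob(prior, multi$bin_j[r] - multi$bin_i[r]) * (L + pseudocount)
    }, numeric(1))
    res[rows] <- if (sum(wt) > 0) wt / sum(wt) else 1 / length(rows)
  }
  data.frame(read_id = multi$read_id, bin_i = multi$bin_i,
             bin_j = multi$bin_j, posterior = res)
}

# analytic multiread probability for a simulated layout: a read is
# ambiguous iff either end's bp falls in the duplicated block, so
# P(multi) = sum over true pairs of p(i,j) * (1 - (1-f_i)(1-f_j)) with f_b
# the fraction of bin b covered by the block
expected_multiread_fraction <- function(layout, decay_alpha, insulation) {
  n <- layout$n_bins
  bs <- layout$bin_size
  blk <- layout$dup_block
  f <- vapply(seq_len(n) - 1L, function(b) {
    if (layout$dup_copies < 2L) return(0)
    max(0, min((b + 1) * bs, blk[2]) - max(b * bs, blk[1])) / bs
  }, numeric(1))
  mid <- (seq_len(n) - 0.5) * bs
  rgn <- findInterval(mid, layout$tad_boundaries_truth)
  tot_w <- 0
  tot_m <- 0
  for (i in 0:(n - 2L)) {
    j <- (i + 1L):(n - 1L)
    d <- j - i
    wgt <- (d + 1)^(-decay_alpha) * insulation^abs(rgn[j + 1L] - rgn[i + 1L])
    pm <- 1 - (1 - f[i + 1L]) * (1 - f[j + 1L])
    tot_w <- tot_w + sum(wgt)
    tot_m <- tot_m + sum(wgt * pm)
  }
  tot_m / tot_w
}

# random candidate-table instance for posterior-oracle equivalence tests
random_rescue_instance <- function(seed) {
  set.seed(seed)
  n <- sample(15:35, 1)
  bs <- 1000
  n_uni <- sample(20:50, 1)
  ui <- sample(0:(n - 1), n_uni, replace = TRUE)
  uj <- sample(0:(n - 1), n_uni, replace = TRUE)
  uni <- contact_matrix(ui, uj, rep(1, n_uni), n_bins = n, bin_size = bs)
  # power-law-filled matrix so the spline prior always has support
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  d <- up[, 2] - up[, 1]
  pm <- contact_matrix(up[, 1], up[, 2], 5 * (d + 1)^-1,
                       n_bins = n, bin_size = bs)
  prior <- fit_distance_prior(pm, min_d = 1L, spline_df = 4)
  n_multi <- sample(1:10, 1)
  rows <- lapply(seq_len(n_multi), function(r) {
    k <- sample(2:4, 1)
    repeat {
      ci <- sample(0:(n - 1), k, replace = TRUE)
      cj <- sample(0:(n - 1), k, replace = TRUE)
      bi <- pmin(ci, cj); bj <- pmax(ci, cj)
      if (!anyDuplicated(paste(bi, bj)) && all(bj > bi)) break
    }
    data.frame(read_id = 1000 + r, bin_i = bi, bin_j = bj, n_candidates = k)
  })
  reads <- do.call(rbind, rows)
  list(reads = reads, uni = uni, prior = prior,
       w = sample(0:3, 1), pseudocount = sample(c(0, 0.5, 2), 1))
}

# single-window contact matrix with two perfectly separated blocks
two_block_matrix <- function(n = 20L, split = 10L, value = 1) {
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  same <- (up[, 1] < split) == (up[, 2] < split)
  contact_matrix(up[same, 1], up[same, 2], rep(value, sum(same)),
                 n_bins = n, bin_size = 5000)
}

constant_matrix <- function(n = 20L, value = 1) {
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  contact_matrix(up[, 1], up[, 2], rep(value, nrow(up)),
                 n_bins = n, bin_size = 5000)
}

# small high-information test motif built in code (width 6)
toy_motif <- function(threshold = 5) {
  m <- matrix(0.02, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("C", "A", "C", "G", "T", "G")
  for (k in seq_along(cons)) m[cons[k], k] <- 0.94
  motif_model(m, threshold = threshold)
}

reverse_complement_chr <- function(x) {
  paste(rev(unname(DNA_COMP_H[strsplit(toupper(x), "")[[1]]])), collapse = "")
}
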