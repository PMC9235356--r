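#' Bin uniquely mapping reads into a contact matrix
#'
#' Keeps only reads with exactly one candidate bin pair; the resulting
#' matrix mass equals the number of unique reads.
#' @param reads candidate table ([read_pairs()] / [simulate_contacts()]).
#' @param n_bins,bin_size matrix geometry.
#' @return a `contact_matrix` of uni-read counts.
#' @export
bin_uni_reads <- function(reads, n_bins, bin_size) {
  stopifnot(is.data.frame(reads))
  if (is.null(reads$n_candidates)) {
    cnt <- table(reads$read_id)
    reads$n_candidates <- as.integer(cnt[as.character(reads$read_id)])
  }
  uni <- reads[reads$n_candidates == 1L, , drop = FALSE]
  contact_matrix(uni$bin_i, uni$bin_j, rep(1, nrow(uni)),
                 n_bins = n_bins, bin_size = bin_size)
}

#' Fit the distance-decay contact prior
#'
#' Estimates the background probability that two bins contact as a smooth
#' function of their separation: the mean count per admissible bin pair is
#' computed at every distance `d >= min_d`, smoothed by a univariate spline
#' fit in log(d)-log(mean) space, exponentiated, floored at a small
#' positive epsilon, and normalized over the distance grid.
#'
#' @param matrix a `contact_matrix` (typically uni-reads only).
#' @param min_d smallest distance (in bins) used; shorter-range pairs are
#'   excluded as self/adjacent-bin artefacts.
#' @param spline_df equivalent degrees of freedom of the spline.
#' @param eps floor applied to the smoothed curve before normalization so
#'   the prior stays positive at unobserved distances.
#' @return object of class `distance_prior` with fields `distances`,
#'   `probabilities` (summing to 1), the spline `fit`, `min_d` and the
#'   normalized floor `eps_prob`.
#' @export
fit_distance_prior <- function(matrix, min_d = 2L, spline_df = 6,
                               eps = 1e-12) {
  stopifnot(inherits(matrix, "contact_matrix"))
  n <- matrix$n_bins
  if (n - 1L < min_d) stop("matrix too small for min_d")
  d_grid <- seq.int(min_d, n - 1L)
  dd <- matrix$bin_j - matrix$bin_i
  use <- dd >= min_d
  tot <- numeric(length(d_grid))
  if (any(use)) {
    agg <- rowsum(matrix$count[use], dd[use])
    tot[match(as.integer(rownames(agg)), d_grid)] <- agg[, 1L]
  }
  n_pairs <- n - d_grid
  mean_c <- tot / n_pairs
  pos <- mean_c > 0
  need <- max(4, ceiling(spline_df))
  if (sum(pos) < need) {
    stop(sprintf(paste0("insufficient distance support for the spline prior: ",
                        "%d distances with positive mean counts at d >= %d, ",
                        "need at least %d"), sum(pos), min_d, need))
  }
  fit <- stats::smooth.spline(log(d_grid[pos]), log(mean_c[pos]), df = spline_df)
  pred <- exp(stats::predict(fit, log(d_grid))$y)
  pred <- pmax(pred, eps)
  z <- sum(pred)
  structure(
    list(distances = d_grid, probabilities = pred / z, fit = fit,
         min_d = as.integer(min_d), eps_prob = eps / z),
    class = "distance_prior"
  )
}

#' Evaluate the distance prior at integer bin distances
#'
#' Distances outside the supported grid (including those below `min_d`)
#' receive the normalized floor, so every candidate distance is evaluable.
#' @param prior a `distance_prior`.
#' @param d integer distances in bins.
#' @return probabilities, one per element of `d`.
#' @export
prior_prob <- function(prior, d) {
  stopifnot(inherits(prior, "distance_prior"))
  idx <- match(as.integer(d), prior$distances)
  p <- prior$probabilities[idx]
  p[is.na(p)] <- prior$eps_prob
  p
}

#' Log-log slope of a fitted distance prior
#'
#' Ordinary least-squares slope of `log(P(d))` on `log(d)` over the prior's
#' grid; -1 for an ideal `1/d` decay.
#' @param prior a `distance_prior`.
#' @return the slope (a single number).
#' @export
prior_loglog_slope <- function(prior) {
  stopifnot(inherits(prior, "distance_prior"))
  unname(stats::coef(stats::lm(log(prior$probabilities) ~ log(prior$distances)))[2])
}

#' @export
print.distance_prior <- function(x, ...) {
  cat(sprintf("<distance_prior> d in [%d, %d] bins, log-log slope %.3f\n",
              min(x$distances), max(x$distances), prior_loglog_slope(x)))
  invisible(x)
}

#' Allocate multireads over their candidate bin pairs
#'
#' Iteratively computes, for every multiread, the posterior probability of
#' each candidate bin pair: `posterior_k` is proportional to
#' `P(d_k) * (L_k + pseudocount)`, where `P` is the distance prior and
#' `L_k` the summed current contact count (uni-reads plus the current
#' fractional multiread mass) in the `(2w+1) x (2w+1)` bin-pair
#' neighbourhood centred on candidate `k`, clipped at the matrix edge.
#' Posteriors are renormalized per read; fractional counts are refreshed
#' synchronously from the new posteriors after each sweep (Jacobi-style,
#' so the result is independent of read order), and sweeps continue until
#' the largest absolute posterior change drops below `tol` or `max_iter`
#' is reached. The first sweep sees uni-read counts only.
#'
#' @param reads candidate table; rows with `n_candidates == 1` are carried
#'   through with posterior exactly 1 and take no part in the iteration.
#' @param matrix uni-read `contact_matrix` ([bin_uni_reads()]).
#' @param prior a `distance_prior` covering the candidate distances.
#' @param w neighbourhood half-width in bins (>= 0).
#' @param pseudocount added to every local count so zero-coverage
#'   candidates retain prior-driven mass (>= 0).
#' @param tol convergence tolerance on the max posterior change (> 0).
#' @param max_iter sweep cap.
#' @return a `posterior_table`: data frame (`read_id`, `bin_i`, `bin_j`,
#'   `posterior`, `is_multi`) with attributes `iterations` and `converged`.
#' @export
allocate_multireads <- function(reads, matrix, prior, w = 2L,
                                pseudocount = 0.5, tol = 1e-4,
                                max_iter = 50L) {
  stopifnot(is.data.frame(reads), inherits(matrix, "contact_matrix"),
            inherits(prior, "distance_prior"))
  if (w < 0) stop("w must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  n <- matrix$n_bins
  if (is.null(reads$n_candidates)) {
    cnt <- table(reads$read_id)
    reads$n_candidates <- as.integer(cnt[as.character(reads$read_id)])
  }
  if (nrow(reads) &&
      (max(reads$bin_j) >= n || min(reads$bin_i) < 0)) {
    stop("candidate bin index out of range for this matrix")
  }

  multi <- reads$n_candidates > 1L
  out_uni <- reads[!multi, c("read_id", "bin_i", "bin_j"), drop = FALSE]
  if (nrow(out_uni)) out_uni$posterior <- 1
  mt <- reads[multi, , drop = FALSE]

  iterations <- 0L
  converged <- TRUE
  post <- numeric(0)
  if (nrow(mt)) {
    rid <- match(mt$read_id, unique(mt$read_id))
    ci <- mt$bin_i
    cj <- mt$bin_j
    pv <- prior_prob(prior, cj - ci)
    U <- cm_dense(matrix)
    lin_at <- cbind(ci + 1L, cj + 1L)
    # linear indices for symmetric fractional refresh
    up_idx <- (cj) * n + ci + 1L
    lo_idx <- (ci) * n + cj + 1L
    Fm <- matrix(0, n, n)
    post_old <- NULL
    converged <- FALSE
    for (t in seq_len(max_iter)) {
      S <- boxsum(U + Fm, w)
      L <- S[lin_at]
      wt <- pv * (L + pseudocount)
      den <- rowsum(wt, rid)[, 1L]
      den_r <- den[rid]
      post <- ifelse(den_r > 0, wt / den_r, 1 / mt$n_candidates)
      iterations <- t
      if (!is.null(post_old) && max(abs(post - post_old)) < tol) {
        converged <- TRUE
        break
      }
      post_old <- post
      Fm[] <- 0
      acc <- rowsum(post, up_idx)
      Fm[as.numeric(rownames(acc))] <- acc[, 1L]
      off <- ci != cj
      if (any(off)) {
        acc2 <- rowsum(post[off], lo_idx[off])
        Fm[as.numeric(rownames(acc2))] <- acc2[, 1L]
      }
    }
  }

  out_multi <- mt[, c("read_id", "bin_i", "bin_j"), drop = FALSE]
  if (nrow(out_multi)) out_multi$posterior <- post
  out <- rbind(out_uni, out_multi)
  out$is_multi <- rep(c(FALSE, TRUE), c(nrow(out_uni), nrow(out_multi)))
  out <- out[order(out$read_id, out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, iterations = iterations, converged = converged,
            class = c("posterior_table", "data.frame"))
}

#' Accumulate posteriors as fractional contact counts
#'
#' Adds each multiread's posterior mass at its candidate bin pairs to the
#' uni-read matrix, so the output mass equals the number of unique reads
#' plus the number of multireads.
#' @param matrix uni-read `contact_matrix`.
#' @param posteriors a `posterior_table` from [allocate_multireads()].
#' @return a `contact_matrix` with fractional counts.
#' @export
accumulate_fractional <- function(matrix, posteriors) {
  stopifnot(inherits(matrix, "contact_matrix"),
            inherits(posteriors, "posterior_table"))
  mp <- posteriors[posteriors$is_multi, , drop = FALSE]
  contact_matrix(c(matrix$bin_i, mp$bin_i),
                 c(matrix$bin_j, mp$bin_j),
                 c(matrix$count, mp$posterior),
                 n_bins = matrix$n_bins, bin_size = matrix$bin_size)
}

#' Stringent whole-read allocation at a posterior threshold
#'
#' A multiread is assigned wholly (count 1) to its maximum-posterior
#' candidate if and only if that posterior reaches the threshold
#' (ties at exactly the threshold are kept); all other multireads are
#' discarded.
#' @param posteriors a `posterior_table`.
#' @param threshold posterior cutoff in (0.5, 1]; defaults to the
#'   0.99-stringent mode.
#' @return list with `assignments` (data frame `read_id`, `bin_i`,
#'   `bin_j`, `posterior` of kept multireads), `n_kept`, `n_dropped`.
#' @export
apply_stringent_filter <- function(posteriors, threshold = 0.99) {
  stopifnot(inherits(posteriors, "posterior_table"))
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]; below 0.5 the argmax is not unique in general")
  }
  mp <- posteriors[posteriors$is_multi, , drop = FALSE]
  if (!nrow(mp)) {
    return(list(assignments = mp[, c("read_id", "bin_i", "bin_j", "posterior")],
                n_kept = 0L, n_dropped = 0L))
  }
  ord <- order(mp$read_id, -mp$posterior, mp$bin_i, mp$bin_j)
  mp <- mp[ord, , drop = FALSE]
  best <- mp[!duplicated(mp$read_id), , drop = FALSE]
  kept <- best[best$posterior >= threshold,
               c("read_id", "bin_i", "bin_j", "posterior"), drop = FALSE]
  rownames(kept) <- NULL
  list(assignments = kept,
       n_kept = nrow(kept),
       n_dropped = length(unique(mp$read_id)) - nrow(kept))
}

#' Add whole-read assignments to a contact matrix
#' @param matrix uni-read `contact_matrix`.
#' @param assignments `assignments` element of [apply_stringent_filter()].
#' @return a `contact_matrix` with one count added per kept read.
#' @export
add_assignments <- function(matrix, assignments) {
  stopifnot(inherits(matrix, "contact_matrix"))
  contact_matrix(c(matrix$bin_i, assignments$bin_i),
                 c(matrix$bin_j, assignments$bin_j),
                 c(matrix$count, rep(1, nrow(assignments))),
                 n_bins = matrix$n_bins, bin_size = matrix$bin_size)
}

#' Full multiread rescue: prior fit, allocation, count accumulation
#'
#' Convenience wrapper chaining [bin_uni_reads()], [fit_distance_prior()],
#' [allocate_multireads()] and either [accumulate_fractional()]
#' (`mode = "fractional"`) or [apply_stringent_filter()] plus
#' [add_assignments()] (`mode = "stringent"`).
#'
#' @param reads candidate table.
#' @param n_bins,bin_size matrix geometry.
#' @param mode `"fractional"` or `"stringent"`.
#' @param threshold stringent-mode posterior cutoff.
#' @param w,pseudocount,tol,max_iter passed to [allocate_multireads()].
#' @param min_d,spline_df passed to [fit_distance_prior()].
#' @return list of class `rescue_result`: `matrix` (rescued counts),
#'   `uni_matrix`, `prior`, `posteriors`, `mode` and a `stats` list
#'   (`n_uni`, `n_multi`, `n_kept`, `n_dropped`).
#' @export
rescue_reads <- function(reads, n_bins, bin_size,
                         mode = c("fractional", "stringent"),
                         threshold = 0.99, w = 2L, pseudocount = 0.5,
                         tol = 1e-4, max_iter = 50L,
                         min_d = 2L, spline_df = 6) {
  mode <- match.arg(mode)
  uni <- bin_uni_reads(reads, n_bins = n_bins, bin_size = bin_size)
  prior <- fit_distance_prior(uni, min_d = min_d, spline_df = spline_df)
  post <- allocate_multireads(reads, uni, prior, w = w,
                              pseudocount = pseudocount, tol = tol,
                              max_iter = max_iter)
  n_multi <- length(unique(post$read_id[post$is_multi]))
  if (mode == "fractional") {
    mat <- accumulate_fractional(uni, post)
    stats <- list(n_uni = cm_mass(uni), n_multi = n_multi,
                  n_kept = n_multi, n_dropped = 0L)
  } else {
    filt <- apply_stringent_filter(post, threshold = threshold)
    mat <- add_assignments(uni, filt$assignments)
    stats <- list(n_uni = cm_mass(uni), n_multi = n_multi,
                  n_kept = filt$n_kept, n_dropped = filt$n_dropped)
  }
  structure(list(matrix = mat, uni_matrix = uni, prior = prior,
                 posteriors = post, mode = mode, stats = stats),
            class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("<rescue_result> mode=%s, uni=%g, multi=%d, kept=%g, mass=%.6g\n",
              x$mode, x$stats$n_uni, x$stats$n_multi, x$stats$n_kept,
              cm_mass(x$matrix)))
  invisible(x)
}
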