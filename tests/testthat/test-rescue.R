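uni_reads_df <- function(i, j) {
  data.frame(read_id = seq_along(i), bin_i = i, bin_j = j,
             n_candidates = 1L)
}

test_that("uni-read binning counts exactly the single-candidate reads", {
  r <- uni_reads_df(c(4, 4, 4), c(10, 10, 10))
  m <- bin_uni_reads(r, 20, 5000)
  expect_equal(cm_dense(m)[5, 11], 3)
  expect_equal(cm_mass(m), 3)

  multi <- data.frame(read_id = c(1, 1, 2, 2), bin_i = c(0, 5, 1, 6),
                      bin_j = c(3, 8, 4, 9), n_candidates = 2L)
  expect_equal(cm_mass(bin_uni_reads(multi, 20, 5000)), 0)

  mixed <- rbind(uni_reads_df(c(2, 3), c(7, 9)), multi)
  expect_equal(cm_mass(bin_uni_reads(mixed, 20, 5000)),
               sum(mixed$n_candidates == 1))
  expect_error(bin_uni_reads(uni_reads_df(0, 25), 20, 5000), "out of range")
})

test_that("the spline prior recovers an exact power law and normalizes", {
  n <- 101L
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  d <- up[, 2] - up[, 1]
  pm <- contact_matrix(up[, 1], up[, 2], 3 * d^-1, n_bins = n,
                       bin_size = 1000)
  prior <- fit_distance_prior(pm, min_d = 1L, spline_df = 4)
  expect_lt(abs(prior_loglog_slope(prior) - (-1)), 0.02)
  expect_equal(sum(prior$probabilities), 1, tolerance = 1e-9)

  flat <- contact_matrix(up[, 1], up[, 2], rep(2, nrow(up)), n_bins = n,
                         bin_size = 1000)
  pf <- fit_distance_prior(flat, min_d = 1L, spline_df = 4)
  expect_equal(pf$probabilities,
               rep(1 / length(pf$distances), length(pf$distances)),
               tolerance = 1e-6)
  expect_equal(sum(pf$probabilities), 1, tolerance = 1e-12)
})

test_that("insufficient distance support fails with a named deficit", {
  m <- contact_matrix(c(0, 0), c(5, 7), c(1, 1), 20, 1000)
  expect_error(fit_distance_prior(m, min_d = 2, spline_df = 6),
               "2 distances with positive mean counts")
})

test_that("posterior updates follow the prior-times-local-counts formula", {
  n <- 40L
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  d <- up[, 2] - up[, 1]
  pm <- contact_matrix(up[, 1], up[, 2], 5 * (d + 1)^-1, n, 1000)
  prior <- fit_distance_prior(pm, min_d = 1, spline_df = 4)

  # single candidate: posterior exactly 1 whatever prior and counts hold
  single <- data.frame(read_id = 1L, bin_i = 3L, bin_j = 9L,
                       n_candidates = 1L)
  uni0 <- contact_matrix(integer(0), integer(0), numeric(0), n, 1000)
  p1 <- allocate_multireads(single, uni0, prior)
  expect_identical(p1$posterior, 1)

  # symmetric candidates at identical distance and local counts: 0.5/0.5
  uni_sym <- contact_matrix(c(2, 22), c(8, 28), c(4, 4), n, 1000)
  sym <- data.frame(read_id = 7L, bin_i = c(2L, 22L), bin_j = c(8L, 28L),
                    n_candidates = 2L)
  ps <- allocate_multireads(sym, uni_sym, prior, w = 2, pseudocount = 0.5)
  expect_equal(ps$posterior, c(0.5, 0.5), tolerance = 1e-12)

  # equal distance, local uni counts 5 vs 15, pseudocount 0, one sweep:
  # posteriors must be exactly 1/4 and 3/4
  uni53 <- contact_matrix(c(2, 22), c(8, 28), c(5, 15), n, 1000)
  rd <- data.frame(read_id = 9L, bin_i = c(2L, 22L), bin_j = c(8L, 28L),
                   n_candidates = 2L)
  pa <- allocate_multireads(rd, uni53, prior, w = 2, pseudocount = 0,
                            max_iter = 1L)
  expect_equal(pa$posterior, c(0.25, 0.75), tolerance = 1e-12)
  expect_error(allocate_multireads(rd, uni53, prior, w = -1), "w must")
  expect_error(allocate_multireads(rd, uni53, prior, tol = 0), "tol")
})

test_that("one sweep matches the direct formula on random instances", {
  for (s in 1:20) {
    inst <- random_rescue_instance(s)
    got <- allocate_multireads(inst$reads, inst$uni, inst$prior,
                               w = inst$w, pseudocount = inst$pseudocount,
                               max_iter = 1L)
    want <- naive_posterior_sweep(inst$reads, inst$uni, inst$prior,
                                  inst$w, inst$pseudocount)
    got <- got[got$is_multi, ]
    key_g <- paste(got$read_id, got$bin_i, got$bin_j)
    key_w <- paste(want$read_id, want$bin_i, want$bin_j)
    expect_equal(got$posterior[order(key_g)], want$posterior[order(key_w)],
                 tolerance = 1e-12)
  }
})

test_that("posteriors form a simplex per read and converge on real input", {
  lay <- build_layout()
  sim <- simulate_contacts(lay, 40000, seed = 13)
  res <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size)
  post <- res$posteriors
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
  sums <- tapply(post$posterior, post$read_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(attr(post, "converged"))
})

test_that("raising a candidate's local uni count never lowers its posterior", {
  n <- 60L
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  d <- up[, 2] - up[, 1]
  pm <- contact_matrix(up[, 1], up[, 2], 5 * (d + 1)^-1, n, 1000)
  prior <- fit_distance_prior(pm, min_d = 1, spline_df = 4)
  rd <- data.frame(read_id = 1L, bin_i = c(2L, 30L), bin_j = c(10L, 45L),
                   n_candidates = 2L)
  last <- -Inf
  for (cnt in c(0, 1, 3, 8, 20)) {
    uni <- contact_matrix(c(2, 30), c(10, 45), c(cnt, 5), n, 1000)
    p <- allocate_multireads(rd, uni, prior, w = 2, pseudocount = 0.5,
                             max_iter = 1L)
    val <- p$posterior[p$bin_i == 2]
    expect_gte(val, last)
    last <- val
  }
})

test_that("fractional accumulation adds exactly the posterior mass", {
  lay <- build_layout()
  sim <- simulate_contacts(lay, 30000, seed = 17)
  uni <- bin_uni_reads(sim$reads, lay$n_bins, lay$bin_size)
  prior <- fit_distance_prior(uni)
  post <- allocate_multireads(sim$reads, uni, prior)
  out <- accumulate_fractional(uni, post)
  n_multi <- length(unique(post$read_id[post$is_multi]))
  expect_equal(cm_mass(out), cm_mass(uni) + n_multi, tolerance = 1e-9)

  # no multireads: identity
  only_uni <- sim$reads[sim$reads$n_candidates == 1, ]
  p2 <- allocate_multireads(only_uni, uni, prior)
  expect_equal(accumulate_fractional(uni, p2), uni)

  # hand case: posteriors (0.25, 0.75) land exactly at the candidates
  n <- 40L
  uni53 <- contact_matrix(c(2, 22), c(8, 28), c(5, 15), n, 1000)
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
  pm <- contact_matrix(up[, 1], up[, 2],
                       5 * (up[, 2] - up[, 1] + 1)^-1, n, 1000)
  pr <- fit_distance_prior(pm, min_d = 1, spline_df = 4)
  rd <- data.frame(read_id = 9L, bin_i = c(2L, 22L), bin_j = c(8L, 28L),
                   n_candidates = 2L)
  pa <- allocate_multireads(rd, uni53, pr, w = 2, pseudocount = 0,
                            max_iter = 1L)
  acc <- accumulate_fractional(uni53, pa)
  expect_equal(cm_dense(acc)[3, 9], 5.25, tolerance = 1e-12)
  expect_equal(cm_dense(acc)[23, 29], 15.75, tolerance = 1e-12)
})

test_that("stringent filtering keeps only high-confidence whole reads", {
  tab <- data.frame(
    read_id = c(1L, 1L, 2L, 2L, 3L),
    bin_i = c(2L, 12L, 3L, 13L, 5L),
    bin_j = c(8L, 18L, 9L, 19L, 11L),
    posterior = c(0.995, 0.005, 0.90, 0.10, 1),
    is_multi = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  class(tab) <- c("posterior_table", "data.frame")
  filt <- apply_stringent_filter(tab, 0.99)
  expect_equal(filt$n_kept, 1L)
  expect_equal(filt$n_dropped, 1L)
  expect_equal(filt$assignments$bin_i, 2L)
  # a posterior exactly at the threshold is kept (>=)
  tab$posterior[1:2] <- c(0.99, 0.01)
  expect_equal(apply_stringent_filter(tab, 0.99)$n_kept, 1L)
  expect_error(apply_stringent_filter(tab, 0.4), "0.5")
  expect_error(apply_stringent_filter(tab, 1.2), "0.5")
})

test_that("with no multireads stringent and fractional matrices coincide", {
  lay <- build_layout(dup_copies = 1)
  sim <- simulate_contacts(lay, 20000, seed = 3)
  rf <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size, mode = "fractional")
  rs <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size, mode = "stringent")
  expect_equal(rf$matrix, rs$matrix)
  expect_equal(cm_mass(rf$matrix), 20000)
})

test_that("rescue restores coverage over the duplication interior", {
  lay <- build_layout()
  sim <- simulate_contacts(lay, 100000, seed = 19)
  res <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size)
  di <- dupHiC:::dup_interior_bins(lay) + 1L
  U <- cm_dense(res$uni_matrix)
  R <- cm_dense(res$matrix)
  expect_equal(sum(U[di, ]), 0)
  expect_true(all(rowSums(R[di, , drop = FALSE]) > 0))
  # conservation in both modes
  expect_equal(cm_mass(res$matrix),
               res$stats$n_uni + res$stats$n_multi, tolerance = 1e-9)
  st <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size, mode = "stringent")
  expect_equal(cm_mass(st$matrix), st$stats$n_uni + st$stats$n_kept)
})
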