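#' Comparative-Ct relative expression
#'
#' `2^-(ct_target - ct_reference)`: the relative abundance of a target
#' transcript against a reference gene measured in the same sample.
#' Fold change versus a control sample is the ratio of two such values
#' (`2^-ddCt`).
#' @param ct_target,ct_reference threshold cycles (finite).
#' @return relative expression (vectorized).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' ddCt fold change of a sample against a control
#' @param dct_sample,dct_control delta-Ct values (target minus reference).
#' @return `2^-(dct_sample - dct_control)`.
#' @export
fold_change_ddct <- function(dct_sample, dct_control) {
  2^(-(dct_sample - dct_control))
}

#' ChIP enrichment by the percent-input method
#'
#' The input Ct is first adjusted for its dilution
#' (`ct_input - log2(1 / input_fraction)`), then enrichment is
#' `100 * 2^(adjusted_input - ct_ip)`.
#' @param ct_ip immunoprecipitate Ct.
#' @param ct_input input-chromatin Ct.
#' @param input_fraction fraction of chromatin kept as input, in (0, 1).
#' @return percent of input recovered.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (any(input_fraction <= 0) || any(input_fraction >= 1)) {
    stop("input_fraction must lie in (0, 1)")
  }
  adj <- ct_input - log2(1 / input_fraction)
  100 * 2^(adj - ct_ip)
}

# fraction of template surviving nuclease digestion at one locus
retained_fraction <- function(ct_dig, ct_undig) {
  stopifnot(all(is.finite(ct_dig)), all(is.finite(ct_undig)))
  2^(-(ct_dig - ct_undig))
}

#' Chromatin accessibility from nuclease-protection qPCR
#'
#' Retained fraction at a locus is `2^-(ct_digested - ct_undigested)`;
#' accessibility is `1 - retained(target) / retained(control)`, clipped to
#' `[0, 1]` (the control is an inaccessible reference locus, so a target
#' more protected than the control is reported as 0 with a warning).
#' @param ct_dig_t,ct_undig_t digested / undigested Ct at the target.
#' @param ct_dig_c,ct_undig_c digested / undigested Ct at the control
#'   locus.
#' @return accessibility in `[0, 1]`; 1 means fully accessible.
#' @export
chart_accessibility <- function(ct_dig_t, ct_undig_t, ct_dig_c, ct_undig_c) {
  rt <- retained_fraction(ct_dig_t, ct_undig_t)
  rc <- retained_fraction(ct_dig_c, ct_undig_c)
  if (any(rc == 0)) stop("retained fraction at the control locus is zero")
  acc <- 1 - rt / rc
  if (any(acc < 0)) {
    warning("negative accessibility clipped to 0 (target more retained than control)")
  }
  pmin(pmax(acc, 0), 1)
}

#' Nucleosome occupancy from MNase-protection qPCR
#'
#' Occupancy is `retained(target) / retained(control)`, clipped to
#' `[0, 1]`: 1.0 represents completely compacted nucleosomes, lower values
#' reduced occupancy.
#' @inheritParams chart_accessibility
#' @return occupancy in `[0, 1]`.
#' @export
mnase_occupancy <- function(ct_dig_t, ct_undig_t, ct_dig_c, ct_undig_c) {
  rt <- retained_fraction(ct_dig_t, ct_undig_t)
  rc <- retained_fraction(ct_dig_c, ct_undig_c)
  if (any(rc == 0)) stop("retained fraction at the control locus is zero")
  occ <- rt / rc
  if (any(occ > 1)) {
    warning("occupancy above 1 clipped to 1")
  }
  pmin(pmax(occ, 0), 1)
}

#' Dual-luciferase relative activity
#'
#' Firefly readings are normalized to the co-transfected Renilla control,
#' then to the empty-vector control construct:
#' `(firefly_s / renilla_s) / (firefly_ctrl / renilla_ctrl)`.
#' @param firefly_s,renilla_s construct readings (> 0).
#' @param firefly_ctrl,renilla_ctrl control-vector readings (> 0).
#' @return relative activity; 1.0 means no enhancer effect.
#' @export
luciferase_relative <- function(firefly_s, renilla_s,
                                firefly_ctrl, renilla_ctrl) {
  vals <- c(firefly_s, renilla_s, firefly_ctrl, renilla_ctrl)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("luminescence readings must be positive")
  }
  (firefly_s / renilla_s) / (firefly_ctrl / renilla_ctrl)
}

#' Student's unpaired two-sided t-test (pooled variance)
#'
#' Wraps `stats::t.test(var.equal = TRUE)` with explicit handling of the
#' degenerate zero-variance cases: identical constant groups give
#' `t = 0, p = 1`; constant groups with different means have no defined
#' pooled-variance statistic and raise an error.
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list `t`, `df` (`n_a + n_b - 2`), `p`, `significant`
#'   (at p < 0.05).
#' @export
unpaired_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    stop("groups must be finite")
  }
  df <- length(group_a) + length(group_b) - 2L
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = df, p = 1, significant = FALSE))
    }
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < 0.05)
}

#' Aggregate a Ct plate table over replicates
#'
#' Replicates are averaged on the Ct scale (before any exponentiation);
#' the SEM of the mean Ct is propagated to the `2^-Ct` scale by the delta
#' method (`sem_transformed = ln(2) * 2^-mean * sem_ct`).
#' @param ct_table data frame with columns `sample`, `target`, and `ct`
#'   (plus optional `condition`).
#' @return data frame, one row per sample/target (and condition, when
#'   present) group with
#'   `mean_ct`, `sem_ct`, `n`.
#' @export
summarise_ct <- function(ct_table) {
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table needs columns sample, target, ct")
  }
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  keys <- c("sample", "target", intersect("condition", names(ct_table)))
  grp <- interaction(ct_table[keys], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(ct_table, grp), function(g) {
    out <- g[1L, keys, drop = FALSE]
    out$mean_ct <- mean(g$ct)
    out$sem_ct <- if (nrow(g) > 1L) stats::sd(g$ct) / sqrt(nrow(g)) else NA_real_
    out$n <- nrow(g)
    out
  }))
  rownames(agg) <- NULL
  agg
}
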