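# Expression filter cascade and clustering of significant probe sets.

# Control/treated column indices for an expression matrix.
expr_groups <- function(samples, control = NULL) {
  trts <- unique(samples$treatment)
  if (length(trts) != 2) stopf("expected exactly two treatment groups")
  if (is.null(control)) control <- trts[1]
  treated <- setdiff(trts, control)
  idx_c <- which(samples$treatment == control)
  idx_t <- which(samples$treatment == treated)
  if (length(idx_c) == 0 || length(idx_t) == 0) stopf("empty treatment group")
  list(control = idx_c, treated = idx_t)
}

#' Filter probe sets by minimum expression
#'
#' A probe set is excluded only when its average signal is below the
#' threshold in *both* groups, i.e. retained iff its mean is `>= threshold`
#' in at least one group (inclusive boundary).  This avoids large fold
#' changes in genes that are not expressed under either condition.
#'
#' @param signal probe sets x samples matrix of positive linear-scale
#'   signals.
#' @param samples sample metadata with a `treatment` column.
#' @param threshold minimum group-mean signal (default 50).
#' @param control control-group label (default: first level encountered).
#' @return logical vector, `TRUE` for retained probe sets.
#' @export
filter_expressed <- function(signal, samples, threshold = 50,
                             control = NULL) {
  g <- expr_groups(samples, control)
  m_c <- rowMeans(signal[, g$control, drop = FALSE])
  m_t <- rowMeans(signal[, g$treated, drop = FALSE])
  m_c >= threshold | m_t >= threshold
}

#' Filter probe sets by fold change
#'
#' Retains probe sets whose linear fold change (treated mean over control
#' mean) is at least `fc`-fold in either direction (inclusive):
#' `FC >= fc` or `FC <= 1/fc`.
#'
#' @inheritParams filter_expressed
#' @param fc minimum fold change (default 1.5).
#' @return logical vector, `TRUE` for retained probe sets.
#' @export
filter_fold_change <- function(signal, samples, fc = 1.5, control = NULL) {
  g <- expr_groups(samples, control)
  m_c <- rowMeans(signal[, g$control, drop = FALSE])
  m_t <- rowMeans(signal[, g$treated, drop = FALSE])
  if (any(m_c <= 0)) stopf("non-positive control group mean")
  ratio <- m_t / m_c
  ratio >= fc | ratio <= 1 / fc
}

#' Filter probe sets by t-test p-value
#'
#' Two-sample t-test (pooled variance by default) on the linear signals per
#' probe set; retained iff `p <= alpha`.
#'
#' @inheritParams filter_expressed
#' @param alpha significance threshold (default 0.001).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return list with `p` (per probe set) and `pass` (logical); probe sets
#'   with zero variance in both groups get `NA` p and fail.
#' @export
filter_pvalue <- function(signal, samples, alpha = 0.001, control = NULL,
                          var_equal = TRUE) {
  g <- expr_groups(samples, control)
  if (length(g$control) < 2 || length(g$treated) < 2) {
    stopf("at least 2 samples per group required for the t-test")
  }
  tt <- row_t_test(signal, g$control, g$treated, var_equal = var_equal)
  list(p = tt$p, t = tt$t, pass = !is.na(tt$p) & tt$p <= alpha,
       undefined = tt$undefined)
}

#' Run the expression filter cascade
#'
#' Applies, in order, the minimum-expression filter, the fold-change filter
#' and the t-test p-value filter, recording per-stage pass flags.  The
#' cascade is monotone: raising any threshold never adds probe sets.
#'
#' @inheritParams filter_expressed
#' @param min_signal,min_fc,alpha cascade thresholds (defaults 50, 1.5,
#'   0.001).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return a `data.frame` per probe set: group means, linear `fold_change`,
#'   `p`, and `pass_expressed`, `pass_fc`, `pass_p`, `pass_final` flags.
#' @export
expression_cascade <- function(signal, samples, min_signal = 50,
                               min_fc = 1.5, alpha = 0.001, control = NULL,
                               var_equal = TRUE) {
  g <- expr_groups(samples, control)
  m_c <- rowMeans(signal[, g$control, drop = FALSE])
  m_t <- rowMeans(signal[, g$treated, drop = FALSE])
  pass_expressed <- filter_expressed(signal, samples, min_signal, control)
  pass_fc <- filter_fold_change(signal, samples, min_fc, control)
  pv <- filter_pvalue(signal, samples, alpha, control, var_equal)
  res <- data.frame(
    probe_set_id = rownames(signal) %||%
      as.character(seq_len(nrow(signal))),
    mean_control = m_c, mean_treated = m_t, fold_change = m_t / m_c,
    t = pv$t, p = pv$p,
    pass_expressed = pass_expressed,
    pass_fc = pass_expressed & pass_fc,
    pass_p = pass_expressed & pass_fc & pv$pass,
    stringsAsFactors = FALSE
  )
  res$pass_final <- res$pass_p
  message(sprintf(
    "expression cascade: %d probe sets -> %d expressed -> %d fold change -> %d significant",
    nrow(res), sum(res$pass_expressed), sum(res$pass_fc),
    sum(res$pass_final)))
  rownames(res) <- NULL
  res
}

#' Cluster significant probe sets and samples
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of the final-pass probe sets and of the samples, on per-probe
#' z-scored log2 signals.  With planted effects dominating noise, the two
#' top-level sample branches separate control from treated animals.
#'
#' @param signal probe sets x samples matrix restricted to the probe sets to
#'   cluster (>= 2 rows).
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `probe_hclust`, `sample_hclust`, `probe_order`,
#'   `sample_order`, and the z-scored matrix `z`.
#' @export
cluster_significant <- function(signal, method = "average") {
  if (nrow(signal) < 2) stopf("at least 2 passing probe sets required")
  lz <- log2(signal)
  mu <- rowMeans(lz)
  s <- sqrt(row_vars(lz))
  s[s == 0] <- 1  # constant probes carry no clustering information
  z <- (lz - mu) / s
  probe_hclust <- stats::hclust(stats::dist(z), method = method)
  sample_hclust <- stats::hclust(stats::dist(t(z)), method = method)
  list(probe_hclust = probe_hclust, sample_hclust = sample_hclust,
       probe_order = probe_hclust$order, sample_order = sample_hclust$order,
       z = z)
}
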