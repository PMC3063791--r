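# Expression-methylation integration: symbol pairing, donor-level
# correlation, the ranked gene table and CpG classification.

#' Pair expression probe sets with methylation regions by gene symbol
#'
#' One pair is emitted per (expression probe set, region) sharing a symbol; a
#' gene with several expression probe sets gets one methylation value
#' associated with each expression value.  Matching is case-sensitive after
#' whitespace stripping.  Symbols present on only one platform are dropped
#' (counts logged); symbols with several regions have all regions paired and
#' are flagged.
#'
#' @param probe_map expression annotation: `probe_set_id`, `symbol`.
#' @param regions methylation annotation: `region_id`, `symbol`.
#' @return a `data.frame` of pairs (`symbol`, `probe_set_id`, `region_id`,
#'   `multi_region` flag).
#' @export
map_by_symbol <- function(probe_map, regions) {
  pm <- probe_map[!is.na(probe_map$symbol), , drop = FALSE]
  rg <- regions[!is.na(regions$symbol), , drop = FALSE]
  pm$symbol <- trimws(pm$symbol)
  rg$symbol <- trimws(rg$symbol)
  common <- intersect(pm$symbol, rg$symbol)
  n_expr_only <- length(setdiff(pm$symbol, common))
  n_meth_only <- length(setdiff(rg$symbol, common))
  if (length(common) == 0) {
    warning("no shared gene symbols between platforms", call. = FALSE)
    return(data.frame(symbol = character(), probe_set_id = character(),
                      region_id = character(), multi_region = logical(),
                      stringsAsFactors = FALSE))
  }
  pm <- pm[pm$symbol %in% common, , drop = FALSE]
  rg <- rg[rg$symbol %in% common, , drop = FALSE]
  pairs <- merge(pm[, c("probe_set_id", "symbol")],
                 rg[, c("region_id", "symbol")], by = "symbol")
  dup <- names(which(table(rg$symbol) > 1))
  pairs$multi_region <- pairs$symbol %in% dup
  message(sprintf(
    "map_by_symbol: %d pairs over %d shared symbols (%d expression-only, %d methylation-only symbols dropped)",
    nrow(pairs), length(common), n_expr_only, n_meth_only))
  pairs[order(pairs$symbol, pairs$probe_set_id, pairs$region_id), ,
        drop = FALSE]
}

#' Correlation test from a correlation coefficient
#'
#' Two-sided test of `r` via the t transform `t = r*sqrt(n-2)/sqrt(1-r^2)`
#' with `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return list with `r`, `n`, `t`, `df` and two-sided `p`.
#' @export
cor_test_r <- function(r, n) {
  if (any(n < 3)) stopf("at least 3 paired observations required")
  df <- n - 2
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(r = r, n = n, t = t, df = df, p = p)
}

#' Donor-level expression-methylation correlation
#'
#' Pearson correlation between per-donor expression (log2 signal) and
#' promoter methylation (M-value), pooled across both treatment groups
#' (default n = 20: 10 control plus 10 treated donors), with the two-sided p
#' from the t transform at `n - 2` degrees of freedom.
#'
#' @param expression per-donor expression values (linear signal; log2 is
#'   taken internally when `log2_expression = TRUE`).
#' @param methylation per-donor methylation M-values, paired by position.
#' @param log2_expression correlate log2 signals (default) or linear.
#' @return list as [cor_test_r()]; zero variance in either vector yields
#'   `NA` statistics with a warning.
#' @export
correlate <- function(expression, methylation, log2_expression = TRUE) {
  ok <- is.finite(expression) & is.finite(methylation)
  x <- expression[ok]
  y <- methylation[ok]
  n <- length(x)
  if (n < 3) stopf("at least 3 complete pairs required (got %d)", n)
  if (log2_expression) x <- log2(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one of the vectors; correlation undefined",
            call. = FALSE)
    return(list(r = NA_real_, n = n, t = NA_real_, df = n - 2, p = NA_real_))
  }
  cor_test_r(stats::cor(x, y), n)
}

#' Build the ranked gene integration table
#'
#' Combines the expression cascade, the differential-methylation records and
#' the donor-level correlations into one row per gene.  For genes with
#' several expression probe sets the representative probe set is the one
#' with the highest control-group mean signal.  Genes are ranked by linear
#' fold change (descending for `direction = "up"`, ascending for `"down"`),
#' ties broken alphabetically by symbol, and the top `top_n` rows are
#' returned.
#'
#' @param de expression cascade results ([expression_cascade()]).
#' @param dm differential-methylation records
#'   ([differential_methylation()]).
#' @param correlations per-pair correlation results: `data.frame` with
#'   `probe_set_id`, `region_id`, `corr`, `corr_p` (see
#'   [integrate_methylation_expression()]).
#' @param pairs symbol pairing table ([map_by_symbol()]).
#' @param regions region annotation table (for the CpG class).
#' @param top_n number of rows (default 30).
#' @param direction `"up"` or `"down"`.
#' @param min_signal only genes whose representative probe set has a group
#'   mean above this value are eligible (default 50, as for the cascade).
#' @return a `data.frame` with columns `symbol`, `probe_set_id`,
#'   `region_id`, `fold_change`, `p_expression`, `delta_meth`,
#'   `p_methylation`, `corr`, `p_corr`, `cpg_class`.
#' @export
build_gene_table <- function(de, dm, correlations, pairs, regions,
                             top_n = 30, direction = c("up", "down"),
                             min_signal = 50) {
  direction <- match.arg(direction)
  if (nrow(de) == 0 || nrow(dm) == 0 || nrow(pairs) == 0) {
    stopf("empty inputs to build_gene_table")
  }
  de <- de[, setdiff(names(de), "symbol"), drop = FALSE]  # pairs carry it
  tab <- merge(pairs, de, by = "probe_set_id")
  tab <- merge(tab, dm[, c("region_id", "delta", "p")], by = "region_id",
               suffixes = c("", "_meth"))
  tab <- merge(tab, correlations, by = c("probe_set_id", "region_id"),
               all.x = TRUE)
  tab <- tab[pmax(tab$mean_control, tab$mean_treated) >= min_signal, ,
             drop = FALSE]
  # representative probe set per gene: highest control-group mean
  tab <- tab[order(tab$symbol, -tab$mean_control, tab$probe_set_id), ,
             drop = FALSE]
  tab <- tab[!duplicated(tab$symbol), , drop = FALSE]
  ord <- if (direction == "up") {
    order(-tab$fold_change, tab$symbol)
  } else {
    order(tab$fold_change, tab$symbol)
  }
  tab <- tab[ord, , drop = FALSE]
  tab <- utils::head(tab, top_n)
  out <- data.frame(
    symbol = tab$symbol, probe_set_id = tab$probe_set_id,
    region_id = tab$region_id, fold_change = tab$fold_change,
    p_expression = tab$p, delta_meth = tab$delta,
    p_methylation = tab$p_meth, corr = tab$corr, p_corr = tab$corr_p,
    cpg_class = regions$cpg_class[match(tab$region_id, regions$region_id)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Correlate every expression-methylation pair at donor level
#'
#' For each (probe set, region) pair, aligns the expression samples and the
#' target-organ donor methylation values by donor and computes the pooled
#' donor-level correlation.
#'
#' @param expression an `expression_set` (or list with `signal`, `samples`).
#' @param donor donor-level methylation: list `values`, `samples` as from
#'   [average_technical_replicates()].
#' @param pairs pairing table from [map_by_symbol()].
#' @param organ organ of the methylation values to use.
#' @param log2_expression correlate log2 signals (default).
#' @return `data.frame`: `probe_set_id`, `region_id`, `corr`, `corr_t`,
#'   `corr_n`, `corr_p`.
#' @export
integrate_methylation_expression <- function(expression, donor, pairs,
                                             organ,
                                             log2_expression = TRUE) {
  msel <- donor$samples$organ == organ
  mvals <- donor$values[, msel, drop = FALSE]
  mdon <- donor$samples$donor_id[msel]
  edon <- expression$samples$donor_id
  common <- intersect(edon, mdon)
  if (length(common) < 3) stopf("fewer than 3 shared donors across platforms")
  E <- expression$signal[, match(common, edon), drop = FALSE]
  Mv <- mvals[, match(common, mdon), drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    e <- E[pairs$probe_set_id[k], ]
    m <- Mv[pairs$region_id[k], ]
    ok <- is.finite(e) & is.finite(m)
    if (sum(ok) < 3 || stats::sd(m[ok]) == 0) {
      return(data.frame(corr = NA_real_, corr_t = NA_real_,
                        corr_n = sum(ok), corr_p = NA_real_))
    }
    ct <- correlate(e[ok], m[ok], log2_expression = log2_expression)
    data.frame(corr = ct$r, corr_t = ct$t, corr_n = ct$n, corr_p = ct$p)
  })
  cbind(pairs[, c("probe_set_id", "region_id")],
        data.table::setDF(data.table::rbindlist(res)))
}

#' Classify a promoter sequence into a CpG class
#'
#' Sliding 500-nt window classification by GC content and observed/expected
#' CpG ratio (`o/e = n_CpG * L / (n_C * n_G)`): *strong* if some window has
#' GC > 0.55 and o/e > 0.75; *poor* if no window reaches o/e 0.48; *weak*
#' otherwise.  Sequences with more than 10% ambiguous bases are
#' unclassified (`NA` with a warning).
#'
#' @param sequence a single DNA string (A/C/G/T; case-insensitive).
#' @param window window length in nt (default 500; sequence must be at least
#'   this long).
#' @param strong_gc,strong_oe,poor_oe class thresholds.
#' @return `"strong"`, `"weak"`, `"poor"`, or `NA_character_`.
#' @export
classify_cpg <- function(sequence, window = 500, strong_gc = 0.55,
                         strong_oe = 0.75, poor_oe = 0.48) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < window) stopf("sequence length %d is below the window size %d",
                        n, window)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ambiguous <- !(ch %in% c("A", "C", "G", "T"))
  if (mean(ambiguous) > 0.10) {
    warning("more than 10% ambiguous bases; sequence unclassified",
            call. = FALSE)
    return(NA_character_)
  }
  isC <- cumsum(c(0, ch == "C"))
  isG <- cumsum(c(0, ch == "G"))
  cg <- cumsum(c(0, ch[-n] == "C" & ch[-1] == "G", 0))
  starts <- seq_len(n - window + 1)
  ends <- starts + window - 1
  nC <- isC[ends + 1] - isC[starts]
  nG <- isG[ends + 1] - isG[starts]
  # CpG dinucleotides fully inside the window (start position <= end-1)
  nCG <- cg[ends] - cg[starts]
  gc <- (nC + nG) / window
  oe <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
  if (any(gc > strong_gc & oe > strong_oe)) return("strong")
  if (all(oe < poor_oe)) return("poor")
  "weak"
}
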