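# Methylome processing: probe-level two-colour intensities to normalized
# per-region methylation values and differential-methylation calls.

#' Compute M- and A-values from two-colour intensities
#'
#' `M = log2(Cy5/Cy3)` (IP over input; the methylation read-out) and
#' `A = (log2 Cy5 + log2 Cy3)/2` (mean log intensity; the abscissa for
#' dye-bias correction).  Non-positive intensities are rejected: the affected
#' entries become `NA` with a warning.
#'
#' @param cy5,cy3 numeric vectors or matrices (probes x arrays) of raw IP and
#'   input channel intensities.
#' @return list with components `M` and `A`, same shape as the input.
#' @export
compute_m_values <- function(cy5, cy3) {
  stopifnot(length(cy5) == length(cy3))
  bad <- !is.finite(cy5) | !is.finite(cy3) | cy5 <= 0 | cy3 <= 0
  if (any(bad)) {
    warning(sprintf("%d probe value(s) with non-positive intensity rejected",
                    sum(bad)), call. = FALSE)
    cy5[bad] <- NA_real_
    cy3[bad] <- NA_real_
  }
  l5 <- log2(cy5); l3 <- log2(cy3)
  list(M = l5 - l3, A = (l5 + l3) / 2)
}

#' Exclude saturated probes
#'
#' Probes whose raw input (Cy3) signal is strictly greater than the ceiling
#' are considered completely saturated and excluded per array; a Cy3 exactly
#' at the ceiling is retained.
#'
#' @param x either a data.frame with a `cy3` column (one array) or a numeric
#'   matrix of Cy3 intensities (probes x arrays).
#' @param threshold saturation ceiling (default 15,000; must be positive).
#' @return for a data.frame, the retained rows; for a matrix, a logical
#'   matrix that is `TRUE` where the probe is retained.
#' @export
filter_saturated <- function(x, threshold = 15000) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("saturation threshold must be positive")
  }
  if (is.data.frame(x)) {
    keep <- !(x$cy3 > threshold)
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      message(sprintf("filter_saturated: excluded %d of %d probes (Cy3 > %s)",
                      n_drop, length(keep), format(threshold)))
    }
    x[keep, , drop = FALSE]
  } else {
    !(x > threshold)
  }
}

#' Per-array loess dye-bias correction
#'
#' Fits a robust degree-1 local regression of M on A independently per array
#' and subtracts the fit: `M_corrected = M - loess(A)`.  This removes
#' intensity-dependent dye bias (and residual saturation trend) while leaving
#' the per-probe deviations that carry the methylation signal.
#'
#' @param M,A numeric vectors or matrices (probes x arrays) as produced by
#'   [compute_m_values()]; `NA` probes (e.g. saturated) are ignored in the
#'   fit and remain `NA`.
#' @param span loess span (fraction of probes in the local window).
#' @param iterations robustness iterations (total fits; 4 = initial fit plus
#'   3 reweighted fits).
#' @param min_probes minimum finite probes required per array.
#' @return corrected M values, same shape as `M`.
#' @export
loess_normalize <- function(M, A, span = 0.3, iterations = 4L,
                            min_probes = 50L) {
  vec <- is.null(dim(M))
  M <- as.matrix(M); A <- as.matrix(A)
  stopifnot(all(dim(M) == dim(A)))
  out <- M
  for (j in seq_len(ncol(M))) {
    idx <- which(is.finite(M[, j]) & is.finite(A[, j]))
    label <- colnames(M)[j] %||% as.character(j)
    if (length(idx) < min_probes) {
      stopf("array %s: %d usable probes; at least %d required for loess",
            label, length(idx), min_probes)
    }
    if (stats::sd(A[idx, j]) == 0) {
      stopf("array %s: degenerate A values (all equal); cannot fit loess",
            label)
    }
    fit <- limma::loessFit(y = M[idx, j], x = A[idx, j], span = span,
                           iterations = iterations)
    out[idx, j] <- M[idx, j] - fit$fitted
  }
  if (vec) out <- drop(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map probes to (region, TSS) windows.  The window is measured along
# transcription direction: for a plus-strand TSS the genomic window is
# [TSS + w1, TSS + w2]; for a minus-strand TSS it is mirrored to
# [TSS - w2, TSS - w1].  Probes are assigned by midpoint, closed interval.
window_map <- function(annotation, window = c(-800, 100)) {
  regions <- annotation$regions
  probes <- annotation$probes
  mid <- (probes$start + probes$end) / 2
  tss_list <- strsplit(regions$tss, ",", fixed = TRUE)
  n_tss <- lengths(tss_list)
  reg_idx <- rep(seq_len(nrow(regions)), n_tss)
  tss_pos <- as.numeric(unlist(tss_list))
  tss_id <- sequence(n_tss)
  plus <- regions$strand[reg_idx] == "+"
  lo <- ifelse(plus, tss_pos + window[1], tss_pos - window[2])
  hi <- ifelse(plus, tss_pos + window[2], tss_pos - window[1])
  # candidate probes are restricted to the TSS's own region
  probe_reg <- match(probes$region_id, regions$region_id)
  by_region <- split(seq_along(probe_reg), probe_reg)
  maps <- lapply(seq_along(reg_idx), function(k) {
    cand <- by_region[[as.character(reg_idx[k])]]
    if (is.null(cand)) return(NULL)
    i <- cand[mid[cand] >= lo[k] & mid[cand] <= hi[k]]
    if (length(i) == 0) return(NULL)
    data.frame(probe_idx = i, region_id = regions$region_id[reg_idx[k]],
               tss_id = tss_id[k], stringsAsFactors = FALSE)
  })
  data.table::setDF(data.table::rbindlist(maps))
}

#' Aggregate probe M-values into per-region TSS-window signals
#'
#' For each transcription start site the mean M-value of the probes whose
#' midpoint lies within the -800..+100 nt window (along transcription
#' direction) is computed; for regions with alternative TSSs the median over
#' the per-TSS means is taken.  Regions with no in-window probes on an array
#' yield `NA` (logged).
#'
#' @param M numeric vector (one array) or matrix (probes x arrays) of probe
#'   M-values, rows ordered as `annotation$probes`.
#' @param annotation a `region_annotation`.
#' @param window window in nt relative to the TSS, `c(upstream, downstream)`
#'   with upstream negative (default `c(-800, 100)`).
#' @return per-region values: a vector or matrix (regions x arrays) with
#'   rownames `region_id`, in annotation order.
#' @export
aggregate_promoter_window <- function(M, annotation, window = c(-800, 100)) {
  vec <- is.null(dim(M))
  M <- as.matrix(M)
  probes <- annotation$probes
  regions <- annotation$regions
  if (nrow(M) != nrow(probes)) {
    stopf("M has %d rows but the annotation describes %d probes",
          nrow(M), nrow(probes))
  }
  map <- window_map(annotation, window)
  out <- matrix(NA_real_, nrow(regions), ncol(M),
                dimnames = list(regions$region_id, colnames(M)))
  if (nrow(map) > 0) {
    grp <- factor(paste(map$region_id, map$tss_id, sep = "@"))
    Msub <- M[map$probe_idx, , drop = FALSE]
    ok <- !is.na(Msub)
    sums <- rowsum(ifelse(ok, Msub, 0), grp)
    cnts <- rowsum(ok + 0, grp)
    tss_means <- sums / cnts          # NaN where a TSS has no usable probes
    tss_means[cnts == 0] <- NA_real_
    reg_of_grp <- sub("@.*$", "", rownames(tss_means))
    dt <- data.table::data.table(region_id = reg_of_grp, tss_means)
    med <- dt[, lapply(.SD, stats::median, na.rm = TRUE), by = region_id]
    med_mat <- as.matrix(med[, -1])
    med_mat[is.nan(med_mat)] <- NA_real_
    out[med$region_id, ] <- med_mat
  }
  n_missing <- sum(rowSums(!is.na(out)) == 0)
  if (n_missing > 0) {
    message(sprintf(
      "aggregate_promoter_window: %d region(s) with no in-window probes",
      n_missing))
  }
  if (vec) out <- drop(out)
  out
}

#' Median-centre and bring arrays to a common scale
#'
#' Subtracts the per-array median M-value, then rescales every array so its
#' median absolute deviation equals the across-array mean MAD (a robust
#' interpretation of "bringing all chips to the same scale").
#'
#' @param mat regions x arrays matrix of per-region M-values.
#' @return matrix of the same shape; every column has median 0 and the common
#'   MAD.
#' @export
center_and_scale <- function(mat) {
  if (ncol(mat) < 2) stopf("center_and_scale requires at least 2 arrays")
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  centred <- sweep(mat, 2, med)
  mads <- apply(centred, 2, stats::mad, na.rm = TRUE)
  if (any(!is.finite(mads) | mads == 0)) {
    stopf("array %s has zero median absolute deviation; cannot scale",
          paste(colnames(mat)[which(mads == 0 | !is.finite(mads))],
                collapse = ", "))
  }
  target <- mean(mads)
  sweep(centred, 2, target / mads, "*")
}

#' Average technical replicate arrays into donor-level values
#'
#' Since the technical (within-donor) variation is low relative to the
#' biological (between-donor) variation, replicate arrays of the same
#' donor-organ sample are averaged; the default design collapses 80 arrays
#' into 40 donor-organ units.
#'
#' @param mat regions x arrays matrix.
#' @param arrays array metadata with columns `array_id`, `organ`,
#'   `treatment`, `donor_id` matching the columns of `mat`.
#' @return list with `values` (regions x donor-organ units) and `samples`
#'   (unit metadata: `sample_id`, `organ`, `treatment`, `donor_id`,
#'   `n_reps`).
#' @export
average_technical_replicates <- function(mat, arrays) {
  if (!all(colnames(mat) == arrays$array_id)) {
    stopf("column names of `mat` do not match `arrays$array_id`")
  }
  unit <- sprintf("%s_%s_%s", arrays$organ, arrays$treatment, arrays$donor_id)
  f <- factor(unit, levels = unique(unit))
  ok <- !is.na(mat)
  sums <- t(rowsum(t(ifelse(ok, mat, 0)), f))
  cnts <- t(rowsum(t(ok + 0), f))
  values <- sums / cnts
  values[cnts == 0] <- NA_real_
  first <- !duplicated(unit)
  samples <- data.frame(
    sample_id = unit[first], organ = arrays$organ[first],
    treatment = arrays$treatment[first], donor_id = arrays$donor_id[first],
    n_reps = as.integer(table(f)[unique(unit)]), stringsAsFactors = FALSE
  )
  list(values = values, samples = samples)
}

#' Call differential methylation in one organ
#'
#' Two-sample t-test of treated versus control donor-level region M-values,
#' with `delta` the treated-minus-control mean difference (log2 units).  A
#' region is significant when `p <= p_threshold` *and*
#' `|delta| >= delta_threshold`; volcano-style class labels are `up`, `down`
#' or `ns`.  Regions with missing values are excluded listwise within groups;
#' regions with zero variance in both groups are flagged `undefined`.
#'
#' @param values regions x samples matrix of donor-level M-values.
#' @param samples sample metadata (`organ`, `treatment` columns).
#' @param organ organ to test.
#' @param p_threshold,delta_threshold significance thresholds
#'   (defaults 0.01 and 0.2).
#' @param control control-treatment label; defaults to the first level
#'   encountered.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return a `data.frame` (one row per region): group means, `delta`, `t`,
#'   `df`, `p`, `significant`, `class`, `undefined`.
#' @export
differential_methylation <- function(values, samples, organ,
                                     p_threshold = 0.01,
                                     delta_threshold = 0.2,
                                     control = NULL, var_equal = TRUE) {
  sel <- samples$organ == organ
  if (!any(sel)) stopf("no samples for organ '%s'", organ)
  values <- values[, sel, drop = FALSE]
  samples <- samples[sel, , drop = FALSE]
  trts <- unique(samples$treatment)
  if (length(trts) != 2) stopf("expected exactly two treatment groups")
  if (is.null(control)) control <- trts[1]
  treated <- setdiff(trts, control)
  idx_c <- which(samples$treatment == control)
  idx_t <- which(samples$treatment == treated)
  if (length(idx_c) < 2 || length(idx_t) < 2) {
    stopf("at least 2 donors per treatment group required")
  }
  tt <- row_t_test(values, idx_c, idx_t, var_equal = var_equal)
  sig <- !is.na(tt$p) & tt$p <= p_threshold &
    abs(tt$delta) >= delta_threshold
  res <- data.frame(
    region_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    mean_control = tt$mean1, mean_treated = tt$mean2, delta = tt$delta,
    t = tt$t, df = tt$df, p = tt$p, significant = sig,
    class = ifelse(sig, ifelse(tt$delta > 0, "up", "down"), "ns"),
    undefined = tt$undefined, stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Split-plot ANOVA with donor as a random effect
#'
#' Per region, fits the model with organ and treatment main effects, their
#' interaction, and donor as a random (whole-plot) effect.  Treatment is
#' tested against the donor-within-treatment mean square; organ and the
#' organ-by-treatment interaction are tested against the residual.  Donor and
#' residual variance components are reported; with technical replicates in
#' the input the residual estimates the technical variance.
#'
#' @param values regions x observations matrix (array-level, or donor-level
#'   after replicate averaging).
#' @param samples observation metadata (`organ`, `treatment`, `donor_id`).
#' @param alpha significance threshold for the reported flags (default
#'   0.001).
#' @return a `data.frame` per region: F and p for organ, treatment and
#'   interaction, significance flags at `alpha`, and variance components
#'   `var_donor`, `var_residual`.
#' @export
split_plot_anova <- function(values, samples, alpha = 0.001) {
  organs <- unique(samples$organ)
  trts <- unique(samples$treatment)
  donors <- unique(samples$donor_id)
  o <- length(organs); t_ <- length(trts); nd <- length(donors)
  N <- nrow(samples)
  # balance checks: every donor in exactly one treatment, measured in every
  # organ with a constant replicate count
  tab <- table(samples$donor_id, samples$organ)
  if (length(unique(as.vector(tab))) != 1 || any(tab == 0)) {
    stopf(paste0("unbalanced design: every donor must be measured in every",
                 " organ with the same number of replicates"))
  }
  dt_tab <- table(samples$donor_id, samples$treatment)
  if (any(rowSums(dt_tab > 0) != 1)) {
    stopf("unbalanced design: a donor appears in more than one treatment")
  }
  a <- nd / t_
  if (a != round(a)) stopf("unbalanced design: unequal donors per treatment")
  r <- N / (nd * o)

  complete <- rowSums(is.na(values)) == 0
  Y <- values[complete, , drop = FALSE]

  gm <- function(f) {
    # group by integer level codes so column order equals factor-level order
    s <- t(rowsum(t(Y), as.integer(f)))
    sweep(s, 2, as.vector(table(f)), "/")
  }
  f_trt <- factor(samples$treatment, levels = trts)
  f_org <- factor(samples$organ, levels = organs)
  f_don <- factor(samples$donor_id, levels = donors)
  f_cell <- factor(paste(samples$treatment, samples$organ, sep = "|"),
                   levels = as.vector(outer(trts, organs, paste, sep = "|")))

  M_trt <- gm(f_trt); M_org <- gm(f_org); M_don <- gm(f_don)
  M_cell <- gm(f_cell)
  grand <- rowMeans(Y)

  trt_of_donor <- samples$treatment[match(donors, samples$donor_id)]
  cell_trt <- rep(trts, times = o)
  cell_org <- rep(organs, each = t_)

  SS_T <- (N / t_) * rowSums((M_trt - grand)^2)
  SS_D <- (o * r) * rowSums((M_don - M_trt[, match(trt_of_donor, trts),
                                           drop = FALSE])^2)
  SS_O <- (N / o) * rowSums((M_org - grand)^2)
  SS_TO <- (a * r) * rowSums((M_cell -
                                M_trt[, match(cell_trt, trts), drop = FALSE] -
                                M_org[, match(cell_org, organs),
                                      drop = FALSE] + grand)^2)
  SS_tot <- rowSums((Y - grand)^2)
  SS_E <- pmax(SS_tot - SS_T - SS_D - SS_O - SS_TO, 0)

  df_T <- t_ - 1; df_D <- t_ * (a - 1); df_O <- o - 1
  df_TO <- (t_ - 1) * (o - 1)
  df_E <- N - 1 - df_T - df_D - df_O - df_TO
  MS_D <- SS_D / df_D; MS_E <- SS_E / df_E

  fp <- function(SS, df, MS_err, df_err) {
    f <- (SS / df) / MS_err
    f[SS == 0] <- 0
    p <- stats::pf(f, df, df_err, lower.tail = FALSE)
    p[SS == 0] <- 1
    list(F = f, p = p)
  }
  trt <- fp(SS_T, df_T, MS_D, df_D)
  org <- fp(SS_O, df_O, MS_E, df_E)
  int <- fp(SS_TO, df_TO, MS_E, df_E)

  fill <- function(x) {
    out <- rep(NA_real_, nrow(values)); out[complete] <- x; out
  }
  res <- data.frame(
    region_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    F_organ = fill(org$F), p_organ = fill(org$p),
    F_treatment = fill(trt$F), p_treatment = fill(trt$p),
    F_interaction = fill(int$F), p_interaction = fill(int$p),
    var_donor = fill(pmax((MS_D - MS_E) / (o * r), 0)),
    var_residual = fill(MS_E), stringsAsFactors = FALSE
  )
  res$sig_organ <- !is.na(res$p_organ) & res$p_organ <= alpha
  res$sig_treatment <- !is.na(res$p_treatment) & res$p_treatment <= alpha
  res$sig_interaction <- !is.na(res$p_interaction) &
    res$p_interaction <= alpha
  rownames(res) <- NULL
  res
}

#' Run the full methylome processing chain
#'
#' Saturation filtering, M/A computation, per-array loess correction,
#' TSS-window aggregation, median centering with between-array scaling, and
#' technical-replicate averaging, with per-stage probe bookkeeping.
#'
#' @param arrays a `medip_arrays` object (or compatible list with `cy5`,
#'   `cy3`, `probes`, `arrays`).
#' @param annotation the matching `region_annotation`.
#' @param saturation,window,span,iterations processing parameters (defaults:
#'   ceiling 15,000; window -800..+100; loess span 0.3 with 3 robustness
#'   iterations).
#' @return list with `region_m` (normalized regions x arrays matrix),
#'   `donor` (list `values`, `samples` at donor level), `arrays` metadata and
#'   a `counts` vector of per-stage probe numbers.
#' @export
process_medip <- function(arrays, annotation, saturation = 15000,
                          window = c(-800, 100), span = 0.3,
                          iterations = 4L) {
  keep <- filter_saturated(arrays$cy3, saturation)
  n_sat <- sum(!keep)
  ma <- compute_m_values(arrays$cy5, arrays$cy3)
  M <- ma$M; A <- ma$A
  M[!keep] <- NA_real_
  A[!keep] <- NA_real_
  M_norm <- loess_normalize(M, A, span = span, iterations = iterations)
  region_raw <- aggregate_promoter_window(M_norm, annotation, window)
  region_m <- center_and_scale(region_raw)
  donor <- average_technical_replicates(region_m, arrays$arrays)
  message(sprintf(
    "process_medip: %d probes x %d arrays; %d saturated probe values; %d regions; %d donor-organ units",
    nrow(arrays$cy3), ncol(arrays$cy3), n_sat, nrow(region_m),
    ncol(donor$values)))
  list(region_m = region_m, donor = donor, arrays = arrays$arrays,
       counts = c(probes = nrow(arrays$cy3), arrays = ncol(arrays$cy3),
                  saturated_values = n_sat, regions = nrow(region_m),
                  donor_units = ncol(donor$values)))
}
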