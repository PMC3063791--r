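# Locus-level validation-assay calculators: comparative-Ct qPCR, MeDIP- and
# ChIP-qPCR enrichment, bisulfite clone summarisation, pyrosequencing group
# comparison.  All qPCR arithmetic assumes fixed amplification efficiency 2.

#' Comparative-Ct (delta-delta-Ct) fold changes
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` is the sample dCt
#' minus the mean dCt of the control group; the relative expression fold
#' change is `2^(-ddCt)`.  Group summaries use the geometric mean (fold
#' changes are ratio-scale).
#'
#' @param ct long-format Ct table: `sample_id`, `assay`, `ct`, `group`.
#' @param target,reference assay labels of the target and reference
#'   (housekeeping) assays.
#' @param control_group label of the calibrator group.
#' @return list with `per_sample` (`sample_id`, `group`, `dct`, `ddct`,
#'   `fold`) and `per_group` (`group`, `n`, `fold_geomean`).
#' @export
ddct_fold_change <- function(ct, target, reference, control_group) {
  tg <- ct[ct$assay == target, c("sample_id", "group", "ct")]
  rf <- ct[ct$assay == reference, c("sample_id", "ct")]
  merged <- merge(tg, rf, by = "sample_id", suffixes = c("_target", "_ref"))
  skipped <- setdiff(tg$sample_id, merged$sample_id)
  if (length(skipped) > 0) {
    warning(sprintf("%d sample(s) without reference Ct skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  if (nrow(merged) == 0) stopf("no samples with both target and reference Ct")
  if (!any(merged$group == control_group)) {
    stopf("control group '%s' not present", control_group)
  }
  merged$dct <- merged$ct_target - merged$ct_ref
  cal <- mean(merged$dct[merged$group == control_group])
  merged$ddct <- merged$dct - cal
  merged$fold <- 2^(-merged$ddct)
  per_sample <- merged[, c("sample_id", "group", "dct", "ddct", "fold")]
  per_sample <- per_sample[order(per_sample$group, per_sample$sample_id), ]
  rownames(per_sample) <- NULL
  grp <- split(per_sample$fold, per_sample$group)
  per_group <- data.frame(
    group = names(grp), n = lengths(grp),
    fold_geomean = vapply(grp, function(x) exp(mean(log(x))), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

#' MeDIP-qPCR relative enrichment (IP over input)
#'
#' Per sample and locus, `enrichment = 2^(Ct_input - Ct_IP) * dilution`,
#' where the dilution factor corrects for unequal template amounts in the IP
#' and input reactions.
#'
#' @param ct long-format Ct table: `sample_id`, `locus`, `fraction`
#'   (`"input"` / `"IP"`), `ct`, `group`.
#' @param locus locus (or loci) to evaluate; default all.
#' @param dilution_factor multiplicative dilution correction (default 1).
#' @return `data.frame` of enrichment records: `locus`, `sample_id`,
#'   `group`, `enrichment`.
#' @export
qpcr_enrichment <- function(ct, locus = NULL, dilution_factor = 1) {
  if (!is.null(locus)) ct <- ct[ct$locus %in% locus, , drop = FALSE]
  ip <- ct[ct$fraction == "IP", c("sample_id", "locus", "group", "ct")]
  inp <- ct[ct$fraction == "input", c("sample_id", "locus", "ct")]
  merged <- merge(ip, inp, by = c("sample_id", "locus"),
                  suffixes = c("_ip", "_input"))
  if (nrow(merged) == 0) stopf("no paired IP/input Ct values found")
  merged$enrichment <- 2^(merged$ct_input - merged$ct_ip) * dilution_factor
  out <- merged[order(merged$locus, merged$group, merged$sample_id),
                c("locus", "sample_id", "group", "enrichment")]
  rownames(out) <- NULL
  out
}

#' Percent methylation from a bisulfite clone matrix
#'
#' Overall percentage = methylated calls / non-missing calls x 100, plus the
#' per-CpG percentages; missing calls are excluded from the denominator.
#'
#' @param clones clones x CpG matrix of calls (1 = methylated,
#'   0 = unmethylated, `NA` = missing).
#' @return list with `percent` (overall), `per_cpg` (named vector),
#'   `n_clones`, `n_calls`.
#' @export
percent_methylation <- function(clones) {
  clones <- as.matrix(clones)
  if (nrow(clones) < 1) stopf("at least one clone required")
  n_calls <- sum(!is.na(clones))
  if (n_calls == 0) stopf("all calls are missing")
  per_cpg <- 100 * colMeans(clones, na.rm = TRUE)
  list(percent = 100 * sum(clones, na.rm = TRUE) / n_calls,
       per_cpg = per_cpg, n_clones = nrow(clones), n_calls = n_calls)
}

#' Pyrosequencing group comparison per CpG site
#'
#' Per CpG, the control-minus-treated difference in mean percent methylation
#' (percentage points) with a pooled two-sample t-test.
#'
#' @param pyro long table: `group`, `replicate`, `cpg`, `percent` (0..100);
#'   optionally pre-filtered to one organ.
#' @param control control-group label.
#' @return `data.frame` per CpG: group means, `difference`
#'   (control - treated), `t`, `p`, group sizes.
#' @export
pyro_group_compare <- function(pyro, control = NULL) {
  if (any(pyro$percent < 0 | pyro$percent > 100)) {
    stopf("percent values outside [0, 100]")
  }
  grps <- unique(pyro$group)
  if (length(grps) != 2) stopf("expected exactly two groups")
  if (is.null(control)) control <- grps[1]
  treated <- setdiff(grps, control)
  res <- lapply(unique(pyro$cpg), function(cp) {
    x <- pyro$percent[pyro$cpg == cp & pyro$group == control]
    y <- pyro$percent[pyro$cpg == cp & pyro$group == treated]
    if (length(x) < 2 || length(y) < 2) {
      stopf("at least 2 replicates per group required for CpG %s", cp)
    }
    df <- length(x) + length(y) - 2
    sp2 <- ((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) / df
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    tstat <- if (se == 0) ifelse(mean(x) == mean(y), 0, Inf) else
      (mean(x) - mean(y)) / se
    data.frame(cpg = cp, mean_control = mean(x), mean_treated = mean(y),
               difference = mean(x) - mean(y), t = tstat,
               p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
               n_control = length(x), n_treated = length(y),
               stringsAsFactors = FALSE)
  })
  out <- data.table::setDF(data.table::rbindlist(res))
  rownames(out) <- NULL
  out
}

#' ChIP-qPCR enrichment with IgG control and switch summary
#'
#' Per antibody, locus and replicate, the enrichment relative to input; IgG
#' is reported as a parallel background track (not subtracted).  The switch
#' summary per locus and group is the ratio of the mean enrichment of the
#' active marks to the mean enrichment of the repressive marks; a locus is
#' flagged uninformative in a group when the mean IgG enrichment reaches the
#' smallest specific-antibody mean.
#'
#' @param ct long-format Ct table: `sample_id`, `locus`, `antibody`,
#'   `fraction` (`"input"` / `"IP"`), `ct`, `group`.
#' @param active_marks,repressive_marks antibody labels of the active and
#'   repressive histone marks.
#' @param igg label of the negative-control antibody (must be measured at
#'   every locus).
#' @param dilution_factor multiplicative correction as in
#'   [qpcr_enrichment()].
#' @return list with `records` (per antibody/locus/replicate enrichment) and
#'   `switch_summary` (per locus and group: active and repressive means,
#'   `igg_mean`, `switch_ratio`, `uninformative` flag).
#' @export
chip_enrichment <- function(ct, active_marks = c("H3K4me2", "H3K9ac"),
                            repressive_marks = "H3K27me3", igg = "IgG",
                            dilution_factor = 1) {
  loci <- unique(ct$locus)
  igg_loci <- unique(ct$locus[ct$antibody == igg])
  if (length(setdiff(loci, igg_loci)) > 0) {
    stopf("IgG control missing at locus: %s",
          paste(setdiff(loci, igg_loci), collapse = ", "))
  }
  ip <- ct[ct$fraction == "IP", ]
  inp <- ct[ct$fraction == "input", c("sample_id", "locus", "antibody", "ct")]
  merged <- merge(ip, inp, by = c("sample_id", "locus", "antibody"),
                  suffixes = c("_ip", "_input"))
  merged$enrichment <- 2^(merged$ct_input - merged$ct_ip) * dilution_factor
  records <- merged[order(merged$locus, merged$antibody, merged$group,
                          merged$sample_id),
                    c("locus", "antibody", "group", "sample_id",
                      "enrichment")]
  rownames(records) <- NULL

  agg <- stats::aggregate(enrichment ~ locus + antibody + group,
                          data = records, FUN = mean)
  summ <- lapply(split(agg, list(agg$locus, agg$group), drop = TRUE),
                 function(d) {
    act <- mean(d$enrichment[d$antibody %in% active_marks])
    rep_ <- mean(d$enrichment[d$antibody %in% repressive_marks])
    ig <- mean(d$enrichment[d$antibody == igg])
    specific_min <- min(d$enrichment[d$antibody != igg])
    data.frame(locus = d$locus[1], group = d$group[1], active_mean = act,
               repressive_mean = rep_, igg_mean = ig,
               switch_ratio = act / rep_,
               uninformative = ig >= specific_min, stringsAsFactors = FALSE)
  })
  switch_summary <- data.table::setDF(data.table::rbindlist(summ))
  switch_summary <- switch_summary[order(switch_summary$locus,
                                         switch_summary$group), ]
  rownames(switch_summary) <- NULL
  list(records = records, switch_summary = switch_summary)
}
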