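# Methylome processing: M/A values, saturation, loess, window aggregation,
# centering/scaling, replicate averaging, DM calling, split-plot ANOVA.

test_that("compute_m_values gives exact logs and rejects bad intensities", {
  ma <- compute_m_values(c(200, 100, 100), c(100, 100, 800))
  expect_equal(ma$M, c(1, 0, -3))
  expect_equal(ma$A[1], (log2(200) + log2(100)) / 2)  # = 7.1439
  expect_equal(ma$A[1], 7.1439, tolerance = 1e-4)
  expect_warning(ma2 <- compute_m_values(c(100, -5), c(100, 100)),
                 "non-positive")
  expect_true(is.na(ma2$M[2]) && !is.na(ma2$M[1]))
})

test_that("filter_saturated applies the strictly-greater rule per array", {
  df <- data.frame(probe_id = c("a", "b", "c"),
                   cy5 = c(100, 100, 100), cy3 = c(15000, 15001, 200))
  suppressMessages(kept <- filter_saturated(df))
  expect_equal(kept$probe_id, c("a", "c"))  # 15,000 kept, 15,001 dropped
  below <- data.frame(probe_id = "a", cy5 = 1, cy3 = 14999)
  expect_identical(filter_saturated(below), below)
  m <- matrix(c(15000, 15001), 1)
  expect_equal(filter_saturated(m), matrix(c(TRUE, FALSE), 1))
  expect_error(filter_saturated(df, threshold = 0), "positive")
})

test_that("loess_normalize removes a constant offset exactly", {
  set.seed(42)
  A <- runif(400, 4, 14)
  M0 <- rnorm(400, 0, 0.05)
  base <- loess_normalize(M0, A)
  shifted <- loess_normalize(M0 + 1.5, A)
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("loess_normalize corrects planted bias (decile oracle) and is
           nearly idempotent", {
  # full default probe density (2,000 regions) but a 2-donor design: the
  # decile bound is a property of the per-array probe count
  d <- study_design(n_donors_per_group = 2, seed = 17)
  ann <- generate_annotation(1600, 400, seed = 17)
  tr <- generate_truth(ann, d, n_dm = 20, n_de = 20)
  arr <- simulate_two_color_arrays(d, ann, tr, noise_model())
  ma <- compute_m_values(arr$cy5, arr$cy3)
  keep <- filter_saturated(arr$cy3)
  M <- ma$M; A <- ma$A
  M[!keep] <- NA
  Mn <- loess_normalize(M[, 1], A[, 1])
  ok <- !is.na(Mn)
  dec <- cut(A[ok, 1], quantile(A[ok, 1], 0:10 / 10), include.lowest = TRUE)
  resid <- Mn[ok] - mean(Mn[ok])
  expect_lt(max(abs(tapply(resid, dec, mean))), 0.02)
  # second pass moves probes far less than the noise scale (local smoothers
  # are not idempotent to machine precision, and isolated probes in the
  # sparse intensity tails move most; see the methods vignette)
  M2 <- loess_normalize(Mn, A[, 1])
  dd <- abs(M2 - Mn)
  expect_lt(median(dd, na.rm = TRUE), 0.005)
  expect_lt(quantile(dd, 0.99, na.rm = TRUE), 0.02)
})

test_that("loess_normalize rejects degenerate input", {
  expect_error(loess_normalize(rnorm(10), runif(10)), "at least 50")
  M <- matrix(rnorm(120), dimnames = list(NULL, c("x1", "x2")), ncol = 2)
  A <- matrix(5, 60, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_error(loess_normalize(M, A), "x1")
})

test_that("aggregate_promoter_window matches the brute-force oracle", {
  ann <- manual_annotation()
  set.seed(7)
  M <- rnorm(nrow(ann$probes))
  got <- suppressMessages(aggregate_promoter_window(M, ann))
  expect_equal(got, oracle_aggregate(M, ann))
  # minus-strand TSS at 30,000: genomic window [29,900 .. 30,800]
  mid <- (ann$probes$start + ann$probes$end) / 2
  manual <- mean(M[ann$probes$region_id == "rB" & mid >= 29900 &
                     mid <= 30800])
  expect_equal(unname(got["rB"]), manual)
})

test_that("window aggregation: mean within TSS, median across TSSs", {
  ann <- manual_annotation()
  ann$regions <- ann$regions[1, ]
  ann$regions$tss <- "10000"
  ann$probes <- data.frame(
    probe_id = c("p1", "p2"), region_id = "rA", chrom = "chr1",
    start = c(9500L, 9700L), end = c(9550L, 9750L))
  expect_equal(unname(aggregate_promoter_window(c(0.2, 0.4), ann)["rA"]),
               0.3)
  # two alternative TSSs with window means 0.1 and 0.5 -> median 0.3
  ann2 <- manual_annotation()
  ann2$regions <- ann2$regions[1, ]  # tss "10000,10400"
  ann2$probes <- data.frame(
    probe_id = c("p1", "p2"), region_id = "rA", chrom = "chr1",
    start = c(9300L, 10400L), end = c(9350L, 10450L))
  # probe 1 only in window of TSS1; probe 2 only in window of TSS2
  expect_equal(unname(aggregate_promoter_window(c(0.1, 0.5), ann2)["rA"]),
               0.3)
  # region with no in-window probes -> NA, logged
  ann3 <- ann
  ann3$probes$start <- c(3000L, 3100L); ann3$probes$end <- c(3050L, 3150L)
  expect_message(v <- aggregate_promoter_window(c(1, 2), ann3),
                 "no in-window")
  expect_true(is.na(v["rA"]))
})

test_that("aggregation is linear in the probe values", {
  ann <- manual_annotation()
  set.seed(8)
  M <- rnorm(nrow(ann$probes))
  expect_equal(aggregate_promoter_window(3.7 * M, ann),
               3.7 * aggregate_promoter_window(M, ann))
})

test_that("center_and_scale zeroes medians and equalises MADs", {
  set.seed(9)
  z <- rnorm(101)
  z <- z - median(z)
  mat <- cbind(a1 = z * 0.1 / mad(z), a2 = z * 0.3 / mad(z) + 2)
  out <- center_and_scale(mat)
  expect_equal(unname(apply(out, 2, median)), c(0, 0))
  expect_equal(unname(apply(out, 2, mad)), c(0.2, 0.2))
  # already centred at a common scale: unchanged
  expect_equal(center_and_scale(out), out)
  # rank order within arrays is preserved
  expect_equal(order(out[, 1]), order(mat[, 1]))
  expect_error(center_and_scale(cbind(a = z, b = rep(1, 101))), "b")
  expect_error(center_and_scale(mat[, 1, drop = FALSE]), "at least 2")
})

test_that("average_technical_replicates averages within donor-organ units", {
  mat <- matrix(c(0.1, 0.3, 0.7, 0.7), 1,
                dimnames = list("r1", c("a1", "a2", "a3", "a4")))
  arrays <- data.frame(array_id = c("a1", "a2", "a3", "a4"),
                       organ = c("liver", "liver", "kidney", "kidney"),
                       treatment = "control",
                       donor_id = c("d1", "d1", "d1", "d2"))
  got <- average_technical_replicates(mat, arrays)
  expect_equal(unname(got$values[1, ]), c(0.2, 0.7, 0.7))
  expect_equal(got$samples$n_reps, c(2L, 1L, 1L))
  expect_error(average_technical_replicates(mat[, c(2, 1, 3, 4),
                                                drop = FALSE], arrays),
               "array_id")
  # default design: 80 arrays -> 40 donor-organ units
  m <- small_meth()
  expect_equal(ncol(m$donor$values), 40L)
})

test_that("differential_methylation applies the conjunction rule", {
  # construct donor values with known delta and p
  set.seed(10)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:20), organ = "liver",
    treatment = rep(c("control", "PB"), each = 10),
    donor_id = sprintf("d%02d", 1:20))
  base <- rnorm(10, 0, 0.02)
  vals <- rbind(
    big_clear = c(base, base + 0.25),        # delta 0.25, tiny p
    small_delta = c(base, base + 0.19),      # delta 0.19, tiny p
    identical_groups = rep(1, 20),           # delta 0, undefined variance
    null = rnorm(20, 0, 0.05))
  colnames(vals) <- samples$sample_id
  dm <- differential_methylation(vals, samples, "liver",
                                 control = "control")
  expect_true(dm$significant[dm$region_id == "big_clear"])
  expect_equal(dm$class[dm$region_id == "big_clear"], "up")
  expect_lt(dm$p[dm$region_id == "small_delta"], 0.001)
  expect_false(dm$significant[dm$region_id == "small_delta"])  # delta fails
  row3 <- dm[dm$region_id == "identical_groups", ]
  expect_equal(row3$delta, 0)
  expect_false(row3$significant)
  expect_true(row3$undefined)
})

test_that("differential_methylation matches the sums-based t oracle", {
  set.seed(12)
  x <- rnorm(10, 0.1, 0.2); y <- rnorm(10, 0.4, 0.2)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:20), organ = "liver",
                        treatment = rep(c("control", "PB"), each = 10),
                        donor_id = sprintf("d%02d", 1:20))
  vals <- matrix(c(x, y), 1, dimnames = list("r1", samples$sample_id))
  dm <- differential_methylation(vals, samples, "liver",
                                 control = "control")
  orc <- oracle_pooled_t(x, y)
  expect_equal(dm$t, orc$t)
  expect_equal(dm$p, orc$p)
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(dm$p, tt$p.value)
  expect_error(differential_methylation(vals, samples, "kidney"), "organ")
})

test_that("split_plot_anova matches aov() and the explicit SS oracle", {
  # 4-donor toy design: 2 treatments x 2 donors x 2 organs, single arrays
  set.seed(13)
  samples <- expand.grid(organ = c("liver", "kidney"),
                         donor_id = sprintf("d%d", 1:4),
                         stringsAsFactors = FALSE)
  samples$treatment <- ifelse(samples$donor_id %in% c("d1", "d2"),
                              "control", "PB")
  samples$array_id <- sprintf("a%d", seq_len(nrow(samples)))
  y <- rnorm(8, mean = 1 + 0.5 * (samples$organ == "liver"))
  vals <- matrix(y, 1, dimnames = list("r1", samples$array_id))
  got <- split_plot_anova(vals, samples)
  fit <- summary(aov(y ~ treatment * organ + Error(donor_id),
                     data = cbind(samples, y = y)))
  s1 <- fit[["Error: donor_id"]][[1]]
  s2 <- fit[["Error: Within"]][[1]]
  expect_equal(got$F_treatment, s1["treatment", "F value"])
  expect_equal(got$p_treatment, s1["treatment", "Pr(>F)"])
  expect_equal(got$F_organ, s2["organ", "F value"])
  expect_equal(got$p_organ, s2["organ", "Pr(>F)"])
  expect_equal(got$F_interaction, s2["treatment:organ", "F value"])
  expect_equal(got$p_interaction, s2["treatment:organ", "Pr(>F)"])
  # explicit sums-of-squares oracle for the same toy design
  g <- mean(y)
  m_t <- tapply(y, samples$treatment, mean)
  m_o <- tapply(y, samples$organ, mean)
  m_d <- tapply(y, samples$donor_id, mean)
  m_c <- tapply(y, paste(samples$treatment, samples$organ), mean)
  ss_t <- 4 * sum((m_t - g)^2)
  ss_d <- 2 * sum((m_d - m_t[c("control", "control", "PB", "PB")])^2)
  ss_o <- 4 * sum((m_o - g)^2)
  cells <- expand.grid(o = c("kidney", "liver"), t = c("control", "PB"),
                       stringsAsFactors = FALSE)
  ss_to <- 2 * sum((m_c[paste(cells$t, cells$o)] - m_t[cells$t] -
                      m_o[cells$o] + g)^2)
  ss_e <- sum((y - g)^2) - ss_t - ss_d - ss_o - ss_to
  expect_equal(got$F_treatment, (ss_t / 1) / (ss_d / 2))
  expect_equal(got$F_organ, (ss_o / 1) / (ss_e / 2))
  expect_equal(got$F_interaction, (ss_to / 1) / (ss_e / 2))
})

test_that("split_plot_anova handles degenerate and unbalanced input", {
  samples <- expand.grid(organ = c("liver", "kidney"),
                         donor_id = sprintf("d%d", 1:4),
                         stringsAsFactors = FALSE)
  samples$treatment <- ifelse(samples$donor_id %in% c("d1", "d2"),
                              "control", "PB")
  samples$array_id <- sprintf("a%d", seq_len(nrow(samples)))
  vals <- matrix(1, 1, 8, dimnames = list("r1", samples$array_id))
  got <- split_plot_anova(vals, samples)
  expect_equal(c(got$F_organ, got$F_treatment, got$F_interaction),
               c(0, 0, 0))
  expect_equal(c(got$p_organ, got$p_treatment, got$p_interaction),
               c(1, 1, 1))
  expect_error(split_plot_anova(vals[, -1, drop = FALSE],
                                samples[-1, ]), "unbalanced")
})

test_that("split_plot_anova detects planted organ effects, treatment null", {
  d <- study_design(seed = 31)
  ann <- generate_annotation(320, 80, seed = 31)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0, n_switch = 1,
                       switch_delta_meth = 0, switch_expr_fc = 1,
                       n_organ = 200)
  no <- noise_model(coupling_meth = 0)
  arr <- simulate_two_color_arrays(d, ann, tr, no)
  proc <- suppressMessages(process_medip(arr, ann))
  an <- split_plot_anova(proc$region_m, arr$arrays)
  affected <- tr$organ_delta != 0
  expect_gte(mean(an$p_organ[affected] <= 0.001, na.rm = TRUE), 0.95)
  # treatment was not planted: p approximately uniform on null regions
  p_null <- an$p_treatment[!is.na(an$p_treatment)]
  expect_gt(mean(p_null), 0.4)
  expect_lt(mean(p_null), 0.6)
  expect_lt(mean(p_null <= 0.05), 0.12)
  expect_true(all(an$F_organ >= 0 & an$F_treatment >= 0, na.rm = TRUE))
})
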