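# Synthetic-data generators: geometry, noise-free limits, planted effects,
# determinism.

test_that("generate_annotation lays out 1.8 kb promoters with 16 tiled probes", {
  ann <- generate_annotation(1, seed = 1, alt_tss_frac = 0)
  rg <- ann$regions
  pb <- ann$probes
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$strand, "+")
  expect_equal(rg$tss, "10000")
  # 1,300 nt upstream + 500 nt downstream of the TSS
  expect_equal(c(rg$start, rg$end), c(8700L, 10500L))
  expect_equal(nrow(pb), 16L)
  expect_true(all(pb$start >= 8700 & pb$end <= 10500))
  expect_equal(unique(diff(pb$start)), 100L)
})

test_that("generate_annotation validates counts and is deterministic", {
  expect_error(generate_annotation(0), "n_regions")
  expect_error(generate_annotation(10, n_intergenic = -1), "n_intergenic")
  a1 <- generate_annotation(40, 10, seed = 9)
  a2 <- generate_annotation(40, 10, seed = 9)
  expect_identical(a1, a2)
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv(a1$regions, f1); write_tsv(a2$regions, f2)
  expect_identical(readLines(f1), readLines(f2))
  # intergenic islands have no symbol; promoters do
  expect_true(all(is.na(a1$regions$symbol[a1$regions$region_class ==
                                            "intergenic_cgi"])))
  expect_true(all(!is.na(a1$regions$symbol[a1$regions$region_class ==
                                             "promoter"])))
  expect_true(all(a1$regions$cpg_class %in% c("strong", "weak", "poor")))
})

test_that("alternative TSSs are offset 300-600 nt downstream", {
  ann <- generate_annotation(200, seed = 2, alt_tss_frac = 0.5)
  rg <- ann$regions
  multi <- grepl(",", rg$tss)
  expect_gt(sum(multi), 50)
  tss <- strsplit(rg$tss[multi], ",")
  off <- vapply(seq_along(tss), function(i) {
    d <- diff(as.numeric(tss[[i]]))
    if (rg$strand[multi][i] == "-") -d else d
  }, numeric(1))
  expect_true(all(off >= 300 & off <= 600))
})

test_that("noise-free arrays reproduce planted M exactly and count 80", {
  d <- study_design(n_donors_per_group = 2, seed = 5)
  ann <- generate_annotation(12, 3, seed = 5)
  tr <- generate_truth(ann, d, n_dm = 2, n_de = 2)
  no <- noise_model(sigma_tech = 0, sigma_donor = 0, sigma_probe = 0,
                    dye_bias_coefficients = 0, coupling_meth = 0)
  arr <- simulate_two_color_arrays(d, ann, tr, no)
  M_obs <- log2(arr$cy5 / arr$cy3)
  ridx <- match(arr$probes$region_id, tr$region_id)
  for (j in seq_len(ncol(M_obs))) {
    cell <- paste0("m_", arr$arrays$organ[j], "_", arr$arrays$treatment[j])
    expect_equal(M_obs[, j], setNames(tr[[cell]][ridx],
                                      rownames(M_obs)), tolerance = 1e-12)
  }
  # default design bookkeeping: 2 organs x 20 donors x 2 reps = 80 arrays
  expect_equal(nrow(small_sim()$arrays$arrays), 80L)
})

test_that("simulate_two_color_arrays rejects incomplete truth", {
  s <- small_sim()
  tr_bad <- s$truth[-1, ]
  expect_error(simulate_two_color_arrays(s$design, s$annotation, tr_bad,
                                         s$noise), "missing")
})

test_that("planted dye bias is recovered from the M-A scatter", {
  d <- study_design(n_donors_per_group = 2, seed = 8)
  ann <- generate_annotation(150, seed = 8)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0)
  coefs <- c(0, 0.1, 0.06, 0)  # linear + quadratic bias in standardised A
  no <- noise_model(sigma_tech = 0, sigma_donor = 0, sigma_probe = 0,
                    dye_bias_coefficients = coefs, coupling_meth = 0)
  arr <- simulate_two_color_arrays(d, ann, tr, no)
  j <- 1
  ma <- compute_m_values(arr$cy5[, j], arr$cy3[, j])
  ridx <- match(arr$probes$region_id, tr$region_id)
  cell <- paste0("m_", arr$arrays$organ[j], "_", arr$arrays$treatment[j])
  bias_obs <- ma$M - tr[[cell]][ridx]
  z <- (ma$A - no$dye_bias_center) / no$dye_bias_scale
  fit <- lm(bias_obs ~ z + I(z^2))
  # mild errors-in-variables attenuation (M/2 enters observed A) bounds the
  # agreement at a few percent
  expect_equal(unname(coef(fit))[2:3], coefs[2:3], tolerance = 0.1)
})

test_that("about 1-2% of probes exceed the saturation ceiling", {
  s <- small_sim()
  frac <- mean(s$arrays$cy3 > s$noise$saturation_ceiling)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.03)
})

test_that("expression: noise-free fold changes are exact, seeds reproduce", {
  d <- study_design(n_donors_per_group = 3, seed = 4)
  ann <- generate_annotation(10, seed = 4)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0, n_switch = 1,
                       switch_expr_fc = 1)
  tr$expr_fc[] <- 1
  no <- noise_model(sigma_expr = 0, sigma_expr_donor = 0, coupling_expr = 0)
  ex <- simulate_expression(d, tr, no)
  ctrl <- ex$samples$treatment == d$treatments[1]
  ratio <- rowMeans(ex$signal[, !ctrl]) / rowMeans(ex$signal[, ctrl])
  expect_equal(unname(ratio), rep(1, nrow(ex$signal)), tolerance = 1e-12)
  ex2 <- simulate_expression(d, tr, no)
  expect_identical(ex$signal, ex2$signal)
})

test_that("a strongly coupled switch gene anti-correlates across 20 donors", {
  d <- study_design(seed = 21)
  ann <- generate_annotation(30, seed = 21)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0, n_switch = 1)
  no <- noise_model(coupling_expr = 1, coupling_meth = 0.2)
  ex <- simulate_expression(d, tr, no)
  arr <- simulate_two_color_arrays(d, ann, tr, no)
  proc <- suppressMessages(process_medip(arr, ann))
  sw <- tr$region_id[tr$is_switch]
  sym <- tr$symbol[tr$is_switch]
  msel <- proc$donor$samples$organ == d$organs[1]
  m <- proc$donor$values[sw, msel]
  e <- ex$signal[paste0("ps_", sym, "_1"),
                 match(proc$donor$samples$donor_id[msel],
                       ex$samples$donor_id)]
  r <- cor(log2(e), m)
  expect_lt(r, -0.8)
})

test_that("a fraction of genes carries multiple probe sets", {
  s <- small_sim()
  counts <- table(s$expression$probe_map$symbol)
  expect_gt(mean(counts > 1), 0.05)
  expect_true(all(counts <= 2))
})

test_that("assay generator: noise-free ddCT inverts the planted fold change", {
  d <- study_design(n_donors_per_group = 3, seed = 6)
  ann <- generate_annotation(5, seed = 6)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0, n_switch = 1,
                       switch_expr_fc = 8)
  no <- noise_model(sigma_ct = 0, sigma_pyro = 0)
  as_ <- simulate_assay_data(d, tr, no)
  dd <- ddct_fold_change(as_$expression_ct, "target", "reference",
                         control_group = d$treatments[1])
  treated <- dd$per_sample$group == d$treatments[2]
  expect_equal(unique(round(dd$per_sample$ddct[treated], 10)), -3)
  expect_equal(unique(round(dd$per_sample$fold[treated], 10)), 8)
})

test_that("clone matrices follow the per-CpG probabilities", {
  d <- study_design(seed = 13)
  ann <- generate_annotation(5, seed = 13)
  tr <- generate_truth(ann, d, n_dm = 0, n_de = 0)
  # probability 0 -> all calls unmethylated
  a0 <- simulate_assay_data(d, tr, n_clones = 10, n_cpgs = 7,
                            bis_p_control = rep(0, 7),
                            bis_p_treated = rep(0, 7))
  expect_equal(percent_methylation(a0$clones$control)$percent, 0)
  # planted 72%: observed within binomial error at large clone count
  n_clones <- 400
  a72 <- simulate_assay_data(d, tr, n_clones = n_clones, n_cpgs = 7,
                             bis_p_control = rep(0.72, 7),
                             bis_p_treated = rep(0.5, 7))
  obs <- percent_methylation(a72$clones$control)$percent / 100
  n_calls <- n_clones * 7
  se <- sqrt(0.72 * 0.28 / n_calls)
  expect_lt(abs(obs - 0.72), 4 * se)
})

test_that("all generators are deterministic under a fixed seed", {
  d <- study_design(seed = 99)
  ann <- generate_annotation(20, 5, seed = 99)
  tr1 <- generate_truth(ann, d)
  tr2 <- generate_truth(ann, d)
  expect_identical(tr1, tr2)
  no <- noise_model()
  expect_identical(simulate_two_color_arrays(d, ann, tr1, no)$cy5,
                   simulate_two_color_arrays(d, ann, tr2, no)$cy5)
  expect_identical(simulate_assay_data(d, tr1, no),
                   simulate_assay_data(d, tr1, no))
})

test_that("switch genes couple opposite-signed effects", {
  s <- small_sim()
  tr <- s$truth
  sw <- tr[tr$is_switch, ]
  expect_equal(nrow(sw), 1L)
  expect_true(sign(log2(sw$expr_fc)) == -sign(sw$delta_meth))
  expect_true(all(table(tr$region_id) == 1))
})

test_that("noise model enforces non-negative sigmas", {
  expect_error(noise_model(sigma_tech = -0.1), "non-negative")
  expect_error(noise_model(saturation_ceiling = 0), "positive")
})
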