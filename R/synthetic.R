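# Synthetic-data generators: every pipeline input with the statistical
# structure the study design assumes, plus planted ground truth for
# parameter-recovery tests.

#' Study design for a two-organ, two-treatment microarray experiment
#'
#' Describes the sampling layout: `n_donors_per_group` animals per treatment
#' group, each contributing one sample per organ, each sample hybridised on
#' `tech_reps_per_sample` arrays.  The default design (10 donors/group, two
#' organs, two treatments, duplicate arrays) yields 80 arrays.
#'
#' @param n_donors_per_group animals per treatment group (>= 2).
#' @param organs organ labels; the first is the target organ of the
#'   differential analyses.
#' @param treatments treatment labels; the first is the control group.
#' @param tech_reps_per_sample technical (array) replicates per organ sample.
#' @param seed master seed; fully determines every generated data set.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_donors_per_group = 10, organs = c("liver", "kidney"),
                         treatments = c("control", "PB"),
                         tech_reps_per_sample = 2, seed = 1L) {
  n_donors_per_group <- check_count(n_donors_per_group, "n_donors_per_group", 2L)
  tech_reps_per_sample <- check_count(tech_reps_per_sample,
                                      "tech_reps_per_sample", 1L)
  if (length(treatments) != 2L) stopf("exactly two treatment groups expected")
  n_donors <- n_donors_per_group * length(treatments)
  donors <- data.frame(
    donor_id = sprintf("d%02d", seq_len(n_donors)),
    treatment = rep(treatments, each = n_donors_per_group),
    stringsAsFactors = FALSE
  )
  structure(list(
    n_donors_per_group = n_donors_per_group, organs = organs,
    treatments = treatments, tech_reps_per_sample = tech_reps_per_sample,
    seed = as.integer(seed), donors = donors
  ), class = "study_design")
}

#' Noise model for the synthetic generators
#'
#' Variance defaults are anchored on the study's reported structure: the
#' standard error between donors of a group is about twice the within-donor
#' (technical) error, so `sigma_donor = 2 * sigma_tech`; the magnitudes are
#' chosen so that a planted methylation difference of ~0.3 M-units over 10
#' donors per group reaches the p-values reported for the strongest locus
#' (see the methods vignette for the derivation).
#'
#' @param sigma_tech sd of the within-donor (technical, per-array) region-level
#'   M noise.
#' @param sigma_donor sd of the donor random effect (M units); default twice
#'   `sigma_tech`.
#' @param sigma_probe sd of probe-level measurement noise (M units).
#' @param dye_bias_coefficients polynomial coefficients (constant first) of the
#'   dye bias as a function of standardised mean log2 intensity
#'   `z = (A - dye_bias_center) / dye_bias_scale`; standardisation keeps the
#'   bias bounded (and loess-recoverable) whatever the intensity spread.
#' @param dye_bias_center,dye_bias_scale standardisation of A for the bias
#'   polynomial; defaults track the Cy3 log-normal parameters.
#' @param saturation_ceiling raw input (Cy3) intensity above which a probe is
#'   considered completely saturated.
#' @param cy3_meanlog,cy3_sdlog log-normal parameters of the raw Cy3 draw;
#'   defaults put ~1.5% of probes above the 15,000 ceiling.
#' @param sigma_expr sd (log2) of residual expression noise.
#' @param sigma_expr_donor sd (log2) of the per-gene donor effect on expression.
#' @param coupling_expr,coupling_meth loadings of the shared per-donor latent
#'   activation on switch-gene expression (log2, positive) and promoter
#'   methylation (M units, subtracted), producing the anti-correlation.
#' @param sigma_ct sd (cycles) of qPCR Ct noise.
#' @param sigma_pyro sd (percentage points) of pyrosequencing replicates.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_tech = 0.035, sigma_donor = 2 * sigma_tech,
                        sigma_probe = 0.05,
                        dye_bias_coefficients = c(0, 0.08, 0.03, -0.008),
                        dye_bias_center = cy3_meanlog / log(2),
                        dye_bias_scale = cy3_sdlog / log(2),
                        saturation_ceiling = 15000,
                        cy3_meanlog = 6, cy3_sdlog = 1.7,
                        sigma_expr = 0.5, sigma_expr_donor = 0.25,
                        coupling_expr = 0.5, coupling_meth = 0.05,
                        sigma_ct = 0.15, sigma_pyro = 5) {
  sig <- c(sigma_tech = sigma_tech, sigma_donor = sigma_donor,
           sigma_probe = sigma_probe, sigma_expr = sigma_expr,
           sigma_expr_donor = sigma_expr_donor, sigma_ct = sigma_ct,
           sigma_pyro = sigma_pyro)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    stopf("all noise standard deviations must be non-negative")
  }
  if (saturation_ceiling <= 0) stopf("saturation_ceiling must be positive")
  structure(as.list(environment()), class = "noise_model")
}

#' Generate a promoter / CpG-island tiling annotation
#'
#' Each promoter region spans 1.8 kb around its transcription start site
#' (1,300 bp upstream, 500 bp downstream, along transcription direction) and
#' carries 16 tiled ~50-nt probes at 100-nt spacing.  A configurable fraction
#' of promoters carries a second, alternative TSS offset 300-600 nt
#' downstream of the first.  Intergenic CpG islands have no gene symbol and a
#' pseudo-TSS at the island midpoint for window aggregation.  Intervals are
#' 0-based half-open; a TSS is the 0-based position of the first transcribed
#' base.
#'
#' @param n_regions number of promoter regions (>= 1).
#' @param n_intergenic number of intergenic CpG islands (>= 0).
#' @param seed RNG seed.
#' @param alt_tss_frac fraction of promoters with two alternative TSSs.
#' @param probes_per_region,probe_spacing,probe_length tiling geometry (nt).
#' @param cpg_class_probs sampling weights for the strong/weak/poor CpG
#'   classes.
#' @return an object of class `region_annotation`: a list with elements
#'   `regions` (one row per region: `region_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (comma-joined), `symbol`, `region_class`, `cpg_class`)
#'   and `probes` (one row per probe: `probe_id`, `region_id`, `chrom`,
#'   `start`, `end`).
#' @export
generate_annotation <- function(n_regions, n_intergenic = 0L, seed = 1L,
                                alt_tss_frac = 0.2, probes_per_region = 16L,
                                probe_spacing = 100L, probe_length = 50L,
                                cpg_class_probs = c(strong = 1, weak = 1,
                                                    poor = 1) / 3) {
  n_regions <- check_count(n_regions, "n_regions", 1L)
  n_intergenic <- check_count(n_intergenic, "n_intergenic", 0L)
  n_total <- n_regions + n_intergenic
  withr::with_seed(as.integer(seed), {
    idx <- seq_len(n_total)
    chrom <- sprintf("chr%d", 1L + (idx - 1L) %% 19L)
    pos_on_chrom <- (idx - 1L) %/% 19L
    tss1 <- 10000L + pos_on_chrom * 20000L
    strand <- rep(c("+", "-"), length.out = n_total)
    is_promoter <- idx <= n_regions
    # region interval: 1300 nt upstream, 500 nt downstream of the first TSS
    up <- 1300L; down <- 500L
    start <- ifelse(strand == "+", tss1 - up, tss1 - down)
    end <- start + up + down
    has_alt <- is_promoter & (runif(n_total) < alt_tss_frac)
    alt_off <- as.integer(round(runif(n_total, 300, 600)))
    tss2 <- ifelse(strand == "+", tss1 + alt_off, tss1 - alt_off)
    # intergenic islands: pseudo-TSS at midpoint, no symbol
    tss1[!is_promoter] <- start[!is_promoter] + (up + down) %/% 2L
    tss <- ifelse(has_alt, paste(tss1, tss2, sep = ","), as.character(tss1))
    cpg_class <- sample(names(cpg_class_probs), n_total, replace = TRUE,
                        prob = cpg_class_probs)
    regions <- data.frame(
      region_id = sprintf("r%05d", idx),
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, tss = tss,
      symbol = ifelse(is_promoter, sprintf("g%04d", idx), NA_character_),
      region_class = ifelse(is_promoter, "promoter", "intergenic_cgi"),
      cpg_class = cpg_class, stringsAsFactors = FALSE
    )
    k <- seq_len(probes_per_region) - 1L
    probes <- data.frame(
      probe_id = sprintf("%s_p%02d", rep(regions$region_id,
                                         each = probes_per_region),
                         rep(k + 1L, n_total)),
      region_id = rep(regions$region_id, each = probes_per_region),
      chrom = rep(regions$chrom, each = probes_per_region),
      start = rep(as.integer(start), each = probes_per_region) +
        rep(k * probe_spacing, n_total),
      stringsAsFactors = FALSE
    )
    probes$end <- probes$start + as.integer(probe_length)
    structure(list(regions = regions, probes = probes),
              class = "region_annotation")
  })
}

#' Plant ground truth for a synthetic study
#'
#' Assigns every annotated region its true methylation level per
#' (organ, treatment) cell, plants differential methylation in the target
#' organ, expression fold changes for a subset of genes, organ effects, and
#' designates switch genes whose methylation moves down while expression moves
#' up (driven additionally by a shared per-donor latent factor at simulation
#' time).
#'
#' @param annotation a `region_annotation`.
#' @param design a `study_design`.
#' @param n_dm planted differentially methylated regions (target organ).
#' @param dm_delta absolute planted methylation difference (M units).
#' @param n_de planted differentially expressed genes.
#' @param de_fc_range range of planted linear fold changes (half of the genes
#'   get the reciprocal, i.e. down-regulation).
#' @param n_switch number of switch genes.
#' @param switch_expr_fc,switch_delta_meth planted switch-gene expression fold
#'   change and methylation change; defaults mirror the strongest locus of the
#'   motivating study (fold change ~452, delta M ~ -0.305).
#' @param n_organ regions with a between-organ methylation difference.
#' @param organ_delta absolute planted organ effect (M units).
#' @param base_m_mean,base_m_sd distribution of baseline region M levels.
#' @param expr_base_log2_mean,expr_base_log2_sd distribution of baseline
#'   expression signals (log2).
#' @param seed RNG seed; defaults to a sub-stream of the design seed.
#' @return a `data.frame` of class `truth_table`, one row per region, with
#'   columns `m_<organ>_<treatment>` for every design cell plus the planted
#'   effect bookkeeping (`is_dm`, `delta_meth`, `is_de`, `expr_fc`,
#'   `expr_base`, `is_switch`, `organ_delta`).
#' @export
generate_truth <- function(annotation, design,
                           n_dm = 100L, dm_delta = 0.3,
                           n_de = 100L, de_fc_range = c(4, 16),
                           n_switch = 1L,
                           switch_expr_fc = 451.86, switch_delta_meth = -0.305,
                           n_organ = NULL, organ_delta = 0.5,
                           base_m_mean = 0.3, base_m_sd = 0.4,
                           expr_base_log2_mean = 7.5, expr_base_log2_sd = 1.5,
                           seed = sub_seed(design$seed, 401L)) {
  regions <- annotation$regions
  n <- nrow(regions)
  if (is.null(n_organ)) n_organ <- round(0.15 * n)
  withr::with_seed(as.integer(seed), {
    truth <- regions[, c("region_id", "symbol", "region_class", "cpg_class")]
    truth$base_m <- rnorm(n, base_m_mean, base_m_sd)
    promoter_idx <- which(!is.na(regions$symbol))
    if (n_switch > length(promoter_idx)) {
      stopf("n_switch exceeds the number of annotated promoters")
    }
    switch_idx <- sample(promoter_idx, n_switch)
    pool <- setdiff(seq_len(n), switch_idx)
    dm_idx <- sample(pool, min(n_dm, length(pool)))
    pool_de <- setdiff(intersect(pool, promoter_idx), dm_idx)
    de_idx <- sample(pool_de, min(n_de, length(pool_de)))
    organ_idx <- sample(seq_len(n), min(n_organ, n))

    truth$is_switch <- seq_len(n) %in% switch_idx
    truth$is_dm <- seq_len(n) %in% c(dm_idx, switch_idx)
    truth$is_de <- truth$symbol %in% regions$symbol[c(de_idx, switch_idx)]
    truth$delta_meth <- 0
    truth$delta_meth[dm_idx] <- dm_delta * sample(c(-1, 1), length(dm_idx),
                                                 replace = TRUE)
    truth$delta_meth[switch_idx] <- switch_delta_meth
    truth$expr_fc <- 1
    fc <- exp(runif(length(de_idx), log(de_fc_range[1]), log(de_fc_range[2])))
    down <- runif(length(de_idx)) < 0.5
    fc[down] <- 1 / fc[down]
    truth$expr_fc[de_idx] <- fc
    truth$expr_fc[switch_idx] <- switch_expr_fc
    truth$expr_base <- 2^rnorm(n, expr_base_log2_mean, expr_base_log2_sd)
    truth$organ_delta <- 0
    truth$organ_delta[organ_idx] <- organ_delta *
      sample(c(-1, 1), length(organ_idx), replace = TRUE)

    target <- design$organs[1]
    control <- design$treatments[1]
    for (org in design$organs) {
      for (trt in design$treatments) {
        m <- truth$base_m
        if (org != target) m <- m + truth$organ_delta
        if (org == target && trt != control) m <- m + truth$delta_meth
        truth[[paste0("m_", org, "_", trt)]] <- m
      }
    }
    class(truth) <- c("truth_table", "data.frame")
    truth
  })
}

# Shared per-donor latent activation driving the switch-gene coupling between
# expression (up) and promoter methylation (down).  Deterministic in the
# design seed so the array and expression generators agree.
latent_activation <- function(design) {
  withr::with_seed(sub_seed(design$seed, 77L),
                   rnorm(nrow(design$donors)))
}

# Donor random effects on region methylation, shared across organs and
# technical replicates (the whole-plot error of the split-plot design).
donor_meth_effects <- function(design, n_regions, noise) {
  nd <- nrow(design$donors)
  withr::with_seed(sub_seed(design$seed, 131L),
                   matrix(rnorm(n_regions * nd, 0, noise$sigma_donor),
                          n_regions, nd))
}

# Array layout implied by a design: one row per hybridisation.
array_layout <- function(design) {
  g <- expand.grid(tech_rep = seq_len(design$tech_reps_per_sample),
                   donor_id = design$donors$donor_id,
                   organ = design$organs,
                   stringsAsFactors = FALSE)
  g <- g[order(g$organ, g$donor_id, g$tech_rep), , drop = FALSE]
  g$treatment <- design$donors$treatment[match(g$donor_id,
                                               design$donors$donor_id)]
  g$array_id <- sprintf("%s_%s_%s_r%d", g$organ, g$treatment, g$donor_id,
                        g$tech_rep)
  rownames(g) <- NULL
  g[, c("array_id", "organ", "treatment", "donor_id", "tech_rep")]
}

#' Simulate two-colour MeDIP tiling arrays
#'
#' Per probe and array, the input channel (Cy3) is drawn from a heavy-tailed
#' log-normal distribution (a small fraction exceeds the saturation ceiling);
#' the IP channel is `Cy5 = Cy3 * 2^(M + bias(A))` where `M` combines the
#' planted region methylation for the array's (organ, treatment) cell, the
#' donor random effect, the switch-gene latent coupling, technical (per
#' region-array) noise and probe-level noise, and `bias(A)` is the configured
#' dye-bias polynomial in mean log2 intensity.
#'
#' @param design a `study_design`.
#' @param annotation a `region_annotation`.
#' @param truth a `truth_table` covering every annotated region.
#' @param noise a `noise_model`.
#' @return an object of class `medip_arrays`: list with matrices `cy5`, `cy3`
#'   (probes x arrays), the `probes` table, and the `arrays` metadata
#'   (`array_id`, `organ`, `treatment`, `donor_id`, `tech_rep`).
#' @export
simulate_two_color_arrays <- function(design, annotation, truth,
                                      noise = noise_model()) {
  regions <- annotation$regions
  probes <- annotation$probes
  miss <- setdiff(regions$region_id, truth$region_id)
  if (length(miss) > 0) {
    stopf("truth table is missing %d annotated region(s), e.g. %s",
          length(miss), miss[1])
  }
  truth <- truth[match(regions$region_id, truth$region_id), , drop = FALSE]
  arrays <- array_layout(design)
  na <- nrow(arrays); nr <- nrow(regions); np <- nrow(probes)
  ridx <- match(probes$region_id, regions$region_id)
  didx <- match(arrays$donor_id, design$donors$donor_id)

  D <- donor_meth_effects(design, nr, noise)
  z <- latent_activation(design)
  sw <- which(truth$is_switch)
  if (length(sw) > 0 && noise$coupling_meth != 0) {
    D[sw, ] <- D[sw, , drop = FALSE] -
      noise$coupling_meth * matrix(z, length(sw), length(z), byrow = TRUE)
  }

  m_cols <- paste0("m_", arrays$organ, "_", arrays$treatment)
  M_cell <- vapply(m_cols, function(cl) truth[[cl]], numeric(nr))

  withr::with_seed(sub_seed(design$seed, 211L), {
    E <- matrix(rnorm(nr * na, 0, noise$sigma_tech), nr, na)
    cy3 <- matrix(rlnorm(np * na, noise$cy3_meanlog, noise$cy3_sdlog), np, na)
    P <- matrix(rnorm(np * na, 0, noise$sigma_probe), np, na)
  })
  M_region <- M_cell + D[, didx, drop = FALSE] + E
  M_probe <- M_region[ridx, , drop = FALSE] + P
  A_proxy <- log2(cy3) + M_probe / 2
  bias <- polyval(noise$dye_bias_coefficients,
                  (A_proxy - noise$dye_bias_center) / noise$dye_bias_scale)
  cy5 <- cy3 * 2^(M_probe + bias)
  if (any(cy5 <= 0) || any(cy3 <= 0)) stopf("non-positive intensity generated")
  dimnames(cy5) <- dimnames(cy3) <- list(probes$probe_id, arrays$array_id)
  structure(list(cy5 = cy5, cy3 = cy3, probes = probes, arrays = arrays,
                 design = design, noise = noise),
            class = "medip_arrays")
}

#' Simulate an expression signal matrix
#'
#' Generates positive MAS5-like signals per probe set and animal for the
#' target organ.  Treated-group means equal control means times the planted
#' fold change; switch genes additionally load on the shared per-donor latent
#' activation (expression up) that simultaneously shifts their promoter
#' methylation down in [simulate_two_color_arrays()], producing a strongly
#' negative donor-level correlation.  A fraction of genes receives a second
#' probe set with its own multiplicative affinity.
#'
#' @param design a `study_design`.
#' @param truth a `truth_table` (promoter rows define the gene list).
#' @param noise a `noise_model`.
#' @param organ organ to simulate (default: the design's target organ).
#' @param multi_probe_frac fraction of genes with two probe sets.
#' @param probe_affinity_sd sd (log2) of the fixed per-probe-set affinity.
#' @return an object of class `expression_set`: list with `signal`
#'   (probe sets x samples), `samples` metadata and `probe_map`
#'   (`probe_set_id`, `symbol`).
#' @export
simulate_expression <- function(design, truth, noise = noise_model(),
                                organ = design$organs[1],
                                multi_probe_frac = 0.2,
                                probe_affinity_sd = 0.3) {
  genes <- truth[!is.na(truth$symbol), , drop = FALSE]
  if (nrow(genes) == 0) stopf("truth table contains no annotated genes")
  if (any(genes$expr_base <= 0)) stopf("non-positive baseline signals in truth")
  donors <- design$donors
  nd <- nrow(donors); ng <- nrow(genes)
  treated <- donors$treatment != design$treatments[1]
  z <- latent_activation(design)
  withr::with_seed(sub_seed(design$seed, 307L), {
    extra <- runif(ng) < multi_probe_frac
    n_ps <- 1L + as.integer(extra)
    gidx <- rep(seq_len(ng), n_ps)
    ps_rank <- sequence(n_ps)
    affinity <- rnorm(length(gidx), 0, probe_affinity_sd)
    affinity[ps_rank == 1L] <- 0  # first probe set is the reference assay
    donor_eff <- matrix(rnorm(ng * nd, 0, noise$sigma_expr_donor), ng, nd)
    resid <- matrix(rnorm(length(gidx) * nd, 0, noise$sigma_expr),
                    length(gidx), nd)
  })
  log2_gene <- log2(genes$expr_base) +
    outer(log2(genes$expr_fc), as.numeric(treated)) +
    donor_eff +
    noise$coupling_expr * outer(as.numeric(genes$is_switch), z)
  signal <- 2^(log2_gene[gidx, , drop = FALSE] + affinity + resid)
  probe_map <- data.frame(
    probe_set_id = sprintf("ps_%s_%d", genes$symbol[gidx], ps_rank),
    symbol = genes$symbol[gidx], stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%s", organ, donors$treatment, donors$donor_id),
    organ = organ, treatment = donors$treatment, donor_id = donors$donor_id,
    stringsAsFactors = FALSE
  )
  dimnames(signal) <- list(probe_map$probe_set_id, samples$sample_id)
  structure(list(signal = signal, samples = samples, probe_map = probe_map),
            class = "expression_set")
}

#' Simulate locus-level validation-assay data
#'
#' Generates the inputs of the validation calculators with fixed efficiency-2
#' qPCR chemistry: comparative-Ct expression tables consistent with the
#' planted switch-gene fold change, MeDIP-qPCR Ct pairs for methylated /
#' unmethylated control loci and the demethylating switch locus, ChIP-qPCR Ct
#' tables for active/repressive histone marks with an IgG track, bisulfite
#' clone call matrices with per-CpG methylation probabilities, and
#' pyrosequencing percent tables.
#'
#' @param design a `study_design`.
#' @param truth a `truth_table`; the switch gene's planted fold change drives
#'   the expression Ct table.
#' @param noise a `noise_model` (`sigma_ct`, `sigma_pyro`).
#' @param n_medip_reps biological replicates per group for MeDIP-qPCR.
#' @param n_clones,n_cpgs bisulfite clone matrix dimensions.
#' @param bis_p_control,bis_p_treated per-CpG methylation probabilities
#'   (defaults average 72% and 57%).
#' @param pyro_control,pyro_treated named per-CpG mean methylation percentages
#'   in the target organ (defaults plant 25- and 9-point reductions).
#' @return an object of class `assay_data`: list with `expression_ct`,
#'   `medip_ct`, `chip_ct` (long-format Ct tables), `clones` (list of 0/1/NA
#'   matrices by group), `pyro` (percent table) and `planted` (generator
#'   truth for tests).
#' @export
simulate_assay_data <- function(design, truth, noise = noise_model(),
                                n_medip_reps = 6L, n_clones = 10L, n_cpgs = 7L,
                                bis_p_control = c(0.90, 0.85, 0.75, 0.70,
                                                  0.65, 0.60, 0.60),
                                bis_p_treated = bis_p_control - 0.15,
                                pyro_control = c(CpG1 = 40, CpG2 = 25),
                                pyro_treated = c(CpG1 = 15, CpG2 = 16)) {
  control <- design$treatments[1]
  treatedl <- design$treatments[2]
  stopifnot(length(bis_p_control) == n_cpgs, length(bis_p_treated) == n_cpgs)
  sw_fc <- if (any(truth$is_switch)) truth$expr_fc[truth$is_switch][1] else 1
  withr::with_seed(sub_seed(design$seed, 503L), {
    ## comparative-Ct expression assay: one cDNA sample per donor
    donors <- design$donors
    fc <- ifelse(donors$treatment == control, 1, sw_fc)
    nct <- function(n) rnorm(n, 0, noise$sigma_ct)
    expression_ct <- rbind(
      data.frame(sample_id = donors$donor_id, assay = "target",
                 fraction = "cDNA", ct = 26 - log2(fc) + nct(nrow(donors)),
                 group = donors$treatment, stringsAsFactors = FALSE),
      data.frame(sample_id = donors$donor_id, assay = "reference",
                 fraction = "cDNA", ct = 12 + nct(nrow(donors)),
                 group = donors$treatment, stringsAsFactors = FALSE)
    )

    ## MeDIP-qPCR: methylated / unmethylated controls plus the switch locus
    medip_enrich <- list()
    medip_enrich[[control]] <- c(H19_ICR = 16, IAP = 16, CSa = 1,
                                 Intergenic3 = 1, Hprt = 1, Gapdh = 1,
                                 switch_promoter = 8, switch_intron = 10)
    medip_enrich[[treatedl]] <- medip_enrich[[control]]
    medip_enrich[[treatedl]][c("switch_promoter", "switch_intron")] <- c(3, 2)
    medip_ct <- data.table::rbindlist(lapply(names(medip_enrich), function(g) {
      e <- medip_enrich[[g]]
      grid <- expand.grid(locus = names(e), rep = seq_len(n_medip_reps),
                          stringsAsFactors = FALSE)
      ct_in <- 28 + nct(nrow(grid))
      data.frame(sample_id = sprintf("%s_m%02d", g, grid$rep),
                 locus = grid$locus,
                 fraction = rep(c("input", "IP"), each = nrow(grid)),
                 ct = c(ct_in, 28 - log2(e[grid$locus]) + nct(nrow(grid))),
                 group = g, stringsAsFactors = FALSE)
    }))
    medip_ct <- data.table::setDF(medip_ct)

    ## ChIP-qPCR: epigenetic switch at the target locus, constitutive controls
    chip_enrich <- list()
    chip_enrich[[control]] <- rbind(
      switch_tss = c(IgG = 0.3, H3K4me2 = 1, H3K9ac = 1, H3K27me3 = 8),
      active1    = c(IgG = 0.3, H3K4me2 = 8, H3K9ac = 8, H3K27me3 = 0.8),
      active2    = c(IgG = 0.3, H3K4me2 = 8, H3K9ac = 8, H3K27me3 = 0.8),
      repressed1 = c(IgG = 0.3, H3K4me2 = 0.8, H3K9ac = 0.8, H3K27me3 = 8),
      repressed2 = c(IgG = 0.3, H3K4me2 = 0.8, H3K9ac = 0.8, H3K27me3 = 8))
    chip_enrich[[treatedl]] <- chip_enrich[[control]]
    chip_enrich[[treatedl]]["switch_tss", ] <-
      c(IgG = 0.3, H3K4me2 = 8, H3K9ac = 6, H3K27me3 = 1)
    chip_reps <- c(IgG = 5L, H3K4me2 = 5L, H3K9ac = 3L, H3K27me3 = 5L)
    chip_ct <- data.table::rbindlist(lapply(names(chip_enrich), function(g) {
      e <- chip_enrich[[g]]
      rows <- lapply(colnames(e), function(ab) {
        grid <- expand.grid(locus = rownames(e), rep = seq_len(chip_reps[ab]),
                            stringsAsFactors = FALSE)
        ct_in <- 25 + nct(nrow(grid))
        data.frame(sample_id = sprintf("%s_c%02d", g, grid$rep),
                   locus = grid$locus, antibody = ab,
                   fraction = rep(c("input", "IP"), each = nrow(grid)),
                   ct = c(ct_in,
                          25 - log2(e[grid$locus, ab]) + nct(nrow(grid))),
                   group = g, stringsAsFactors = FALSE)
      })
      data.table::rbindlist(rows)
    }))
    chip_ct <- data.table::setDF(chip_ct)

    ## bisulfite clone matrices: Bernoulli per-CpG calls
    make_clones <- function(p) {
      m <- matrix(rbinom(n_clones * n_cpgs, 1L,
                         rep(p, each = n_clones)), n_clones, n_cpgs,
                  dimnames = list(sprintf("clone%02d", seq_len(n_clones)),
                                  sprintf("CpG%d", seq_len(n_cpgs))))
      m
    }
    clones <- setNames(list(make_clones(bis_p_control),
                            make_clones(bis_p_treated)),
                       c(control, treatedl))

    ## pyrosequencing: per-CpG percentages, target organ changes only
    n <- design$n_donors_per_group
    pyro_means <- list()
    pyro_means[[design$organs[1]]] <- list(pyro_control, pyro_treated)
    for (org in design$organs[-1]) {
      pyro_means[[org]] <- list(pyro_control, pyro_control)
    }
    pyro <- data.table::rbindlist(lapply(names(pyro_means), function(org) {
      mm <- pyro_means[[org]]
      data.table::rbindlist(lapply(seq_along(design$treatments), function(i) {
        grid <- expand.grid(replicate = seq_len(n),
                            cpg = names(pyro_control),
                            stringsAsFactors = FALSE)
        pct <- mm[[i]][grid$cpg] + rnorm(nrow(grid), 0, noise$sigma_pyro)
        data.frame(organ = org, group = design$treatments[i],
                   replicate = grid$replicate, cpg = grid$cpg,
                   percent = pmin(pmax(pct, 0), 100),
                   stringsAsFactors = FALSE)
      }))
    }))
    pyro <- data.table::setDF(pyro)

    structure(list(
      expression_ct = expression_ct, medip_ct = medip_ct, chip_ct = chip_ct,
      clones = clones, pyro = pyro,
      planted = list(expression_fc = sw_fc, medip_enrichment = medip_enrich,
                     chip_enrichment = chip_enrich,
                     bis_p = list(control = bis_p_control,
                                  treated = bis_p_treated),
                     pyro_means = pyro_means)
    ), class = "assay_data")
  })
}
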