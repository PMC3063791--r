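# Shared fixtures, generated in code and cached for the duration of the test
# run.  The "small" study keeps the full default design (10 donors/group, 2
# organs, duplicate arrays = 80 arrays) but fewer regions, so donor-level
# power matches the default world while tests stay fast.

small_config <- function(seed = 11L) {
  pipeline_config(seed = seed, n_regions = 200L, n_intergenic = 50L,
                  n_dm = 20L, n_de = 20L, n_switch = 1L)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small synthetic study (design, annotation, truth, arrays, expression,
# assays)
small_sim <- function() {
  cached("small_sim", suppressMessages({
    d <- study_design(seed = 11L)
    ann <- generate_annotation(200L, 50L, seed = sub_seed_test(11L, 11L))
    tr <- generate_truth(ann, d, n_dm = 20L, n_de = 20L)
    no <- noise_model()
    list(design = d, annotation = ann, truth = tr, noise = no,
         arrays = simulate_two_color_arrays(d, ann, tr, no),
         expression = simulate_expression(d, tr, no),
         assays = simulate_assay_data(d, tr, no))
  }))
}

sub_seed_test <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2000000000L) + as.integer(offset)
}

# processed methylome for the small study
small_meth <- function() {
  cached("small_meth", suppressMessages({
    s <- small_sim()
    process_medip(s$arrays, s$annotation)
  }))
}

# a tiny manual annotation with known geometry: two regions, one with two
# TSSs, one on the minus strand
manual_annotation <- function() {
  regions <- data.frame(
    region_id = c("rA", "rB"),
    chrom = c("chr1", "chr1"),
    start = c(8700L, 29500L),
    end = c(10500L, 31300L),
    strand = c("+", "-"),
    tss = c("10000,10400", "30000"),
    symbol = c("geneA", "geneB"),
    region_class = "promoter",
    cpg_class = c("strong", "poor"),
    stringsAsFactors = FALSE
  )
  k <- 0:15
  probes <- data.frame(
    probe_id = c(sprintf("rA_p%02d", k + 1), sprintf("rB_p%02d", k + 1)),
    region_id = rep(c("rA", "rB"), each = 16),
    chrom = "chr1",
    start = c(8700L + k * 100L, 29500L + k * 100L),
    stringsAsFactors = FALSE
  )
  probes$end <- probes$start + 50L
  structure(list(regions = regions, probes = probes),
            class = "region_annotation")
}

# brute-force window aggregation oracle: explicit loop over probes and TSSs
oracle_aggregate <- function(M, annotation, window = c(-800, 100)) {
  regions <- annotation$regions
  probes <- annotation$probes
  mid <- (probes$start + probes$end) / 2
  out <- setNames(rep(NA_real_, nrow(regions)), regions$region_id)
  for (i in seq_len(nrow(regions))) {
    tss <- as.numeric(strsplit(regions$tss[i], ",")[[1]])
    per_tss <- numeric(0)
    for (tp in tss) {
      if (regions$strand[i] == "+") {
        lo <- tp + window[1]; hi <- tp + window[2]
      } else {
        lo <- tp - window[2]; hi <- tp - window[1]
      }
      vals <- c()
      for (j in seq_len(nrow(probes))) {
        if (probes$region_id[j] == regions$region_id[i] &&
            !is.na(M[j]) && mid[j] >= lo && mid[j] <= hi) {
          vals <- c(vals, M[j])
        }
      }
      per_tss <- c(per_tss, if (length(vals)) mean(vals) else NA_real_)
    }
    if (any(!is.na(per_tss))) out[i] <- median(per_tss, na.rm = TRUE)
  }
  out
}

# closed-form pooled two-sample t oracle (sums-based)
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE))
}
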