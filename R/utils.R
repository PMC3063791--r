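# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed.  Offsets keep the
# generators for annotation, truth, arrays, expression and assays independent
# while remaining fully determined by the master seed (and inside 32-bit range).
sub_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2000000000L) + as.integer(offset)
}

# Row-wise variance of a numeric matrix (two-pass, NA-aware).
row_vars <- function(x, na.rm = FALSE) {
  n <- rowSums(!is.na(x))
  if (!na.rm) n <- ncol(x)
  mu <- rowMeans(x, na.rm = na.rm)
  rowSums((x - mu)^2, na.rm = na.rm) / pmax(n - 1L, 1L)
}

# Pooled two-sample t-test computed row-wise over a matrix split into two
# column groups.  Returns delta (mean2 - mean1), t, df and two-sided p.
# Rows where both groups have zero variance get NA statistics and are flagged.
row_t_test <- function(x, idx1, idx2, var_equal = TRUE) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- row_vars(x1, na.rm = TRUE)
  v2 <- row_vars(x2, na.rm = TRUE)
  delta <- m2 - m1
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / pmax(df, 1L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / pmax(n1 - 1L, 1L) + (v2 / n2)^2 / pmax(n2 - 1L, 1L))
  }
  tstat <- delta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  undefined <- !is.finite(se) | se == 0 | n1 < 2 | n2 < 2
  tstat[undefined] <- NA_real_
  p[undefined] <- NA_real_
  list(
    mean1 = m1, mean2 = m2, delta = delta, t = tstat, df = df, p = p,
    undefined = undefined
  )
}

# Evaluate a polynomial with coefficients ordered constant-first.
polyval <- function(coef, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  }
  as.integer(x)
}

#' Write a table as tab-separated text
#'
#' All tabular outputs of the pipeline use one dialect: tab delimiter, UTF-8,
#' `NA` for missing values, no quoting unless a field contains a delimiter.
#' This keeps outputs byte-identical across runs and diffable in tests.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = "auto", na = "NA",
                     eol = "\n", scipen = 50)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  data.table::setDF(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
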