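# Method-agreement statistics for paired per-image metrics from two imaging
# modalities: Kruskal-Wallis between groups, simple linear regression,
# Bland-Altman bias/limits, intraclass correlation with the usual agreement
# bands, and per-sample maximum percentage difference tables.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic over `k` groups with a chi-square `(k - 1)`
#' degrees-of-freedom p-value. Implemented directly from ranks (average
#' ranks for ties, tie-corrected denominator).
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2))
    stop("need at least 2 groups with at least 2 values each")
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(v)
  r <- rank(v)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  df <- length(groups) - 1
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Ordinary least-squares regression with R-squared
#'
#' @param x,y finite numeric vectors of equal length (>= 3 pairs).
#' @return List with `slope`, `intercept`, `r2`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 (x, y) pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0) stop("zero variance in x")
  f <- lm(y ~ x)
  cf <- coef(f)
  r2 <- if (sd(y) == 0) 1 else stats::cor(x, y)^2
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `b - a` (or, in relative mode, the mean of
#' `100 * (b - a) / a`); limits of agreement are `bias +/- 1.96 * SD` of the
#' differences.
#'
#' @param a,b paired measurements (reference first).
#' @param relative logical; express differences as percent of `a`.
#' @return List with `bias`, `limits` (length 2), `sd_diff`.
#' @export
bland_altman <- function(a, b, relative = FALSE) {
  if (length(a) != length(b) || length(a) < 2) stop("need >= 2 matched pairs")
  d <- if (relative) {
    if (any(a == 0)) stop("zero reference values in relative mode")
    100 * (b - a) / a
  } else b - a
  bias <- mean(d); s <- sd(d)
  list(bias = bias, limits = c(bias - 1.96 * s, bias + 1.96 * s),
       sd_diff = s)
}

#' Intraclass correlation coefficient with agreement band
#'
#' Default model: two-way mixed effects, absolute agreement, single
#' measurement (ICC(A,1) in the McGraw-Wong taxonomy), computed from the
#' two-way mean squares. The consistency form ICC(C,1) is available via
#' `model = "consistency"`. Bands: below 0.5 low, 0.5 to 0.75 good, above
#' 0.75 excellent.
#'
#' @param a,b paired measurements (>= 3 pairs). Rows are subjects, the two
#'   vectors the two raters/modalities.
#' @param model `"agreement"` (default) or `"consistency"`.
#' @return List with `icc`, `band`, `model`.
#' @export
icc <- function(a, b, model = c("agreement", "consistency")) {
  model <- match.arg(model)
  if (length(a) != length(b) || length(a) < 3) stop("need >= 3 matched pairs")
  m <- cbind(a, b)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  val <- if (model == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  else (msr - mse) / (msr + (k - 1) * mse)
  if (!is.finite(val)) val <- 1 # zero total variance: perfect duplication
  band <- if (val < 0.5) "low" else if (val <= 0.75) "good" else "excellent"
  list(icc = val, band = band, model = model)
}

#' Maximum percentage difference over matched pairs
#'
#' `max over pairs of 100 * |b - a| / a`, rounded to an integer percent;
#' the reference modality is the denominator. `NA` pairs (not-detected
#' entries) are dropped pairwise.
#'
#' @param a reference values (e.g. the CT-derived metric).
#' @param b comparison values (e.g. the MR-derived metric).
#' @return Integer percent.
#' @export
max_percent_diff <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) stop("need >= 1 matched pair")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) return(NA_integer_)
  if (any(a == 0)) stop("zero reference value")
  as.integer(round(max(100 * abs(b - a) / a)))
}

#' Pairwise agreement summary for a long-format metrics table
#'
#' Takes a long table `(sample_id, image_id, modality, metric, value)` with
#' exactly two modalities, matches pairs per (sample, image, metric), and
#' reports per-metric Kruskal-Wallis p, OLS R-squared, Bland-Altman relative
#' bias, ICC with band, and max percent difference. `NA`/not-detected values
#' are excluded pairwise with a logged count.
#'
#' @param df data.frame with columns `sample_id`, `image_id`, `modality`,
#'   `metric`, `value`.
#' @param reference modality name used as the reference (denominator).
#' @return data.frame with one row per metric.
#' @export
agreement_summary <- function(df, reference) {
  need <- c("sample_id", "image_id", "modality", "metric", "value")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)),
                                            collapse = ", "))
  mods <- unique(df$modality)
  if (length(mods) != 2 || !(reference %in% mods))
    stop("table must contain exactly two modalities including the reference")
  other <- setdiff(mods, reference)
  out <- lapply(split(df, df$metric), function(dm) {
    wide <- merge(dm[dm$modality == reference,
                     c("sample_id", "image_id", "value")],
                  dm[dm$modality == other,
                     c("sample_id", "image_id", "value")],
                  by = c("sample_id", "image_id"), suffixes = c("_ref", "_cmp"))
    keep <- is.finite(wide$value_ref) & is.finite(wide$value_cmp)
    dropped <- sum(!keep)
    a <- wide$value_ref[keep]; b <- wide$value_cmp[keep]
    kw <- tryCatch(kruskal_wallis(list(a, b)), error = function(e) list(p = NA))
    r2 <- tryCatch(linear_r2(a, b)$r2, error = function(e) NA_real_)
    ba <- tryCatch(bland_altman(a, b, relative = TRUE),
                   error = function(e) list(bias = NA_real_))
    ic <- tryCatch(icc(a, b), error = function(e)
      list(icc = NA_real_, band = NA_character_))
    data.frame(metric = dm$metric[1], n_pairs = length(a),
               n_dropped = dropped, kw_p = kw$p, r2 = r2,
               bias_pct = ba$bias, icc = ic$icc, icc_band = ic$band)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
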