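# -- per-position testing, FDR, contrast/noise, concordance -----------------

# coerce welch_compare input: positions-x-replicates matrix, or the long
# tibble produced by transcriptogram() (one column per sample)
profiles_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (is.data.frame(profiles) && all(c("position", "sample", "value") %in% names(profiles))) {
    wide <- tidyr::pivot_wider(profiles[c("position", "sample", "value")],
                               names_from = "sample", values_from = "value")
    wide <- wide[order(wide$position), ]
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$position
    return(m)
  }
  abort("`profiles` must be a positions-x-replicates matrix or a long transcriptogram tibble")
}

#' Per-position Welch comparison of two classes of transcriptograms
#'
#' At each ordering position, the two groups of replicate transcriptogram
#' values are compared with Welch's two-tailed t-test (unequal variances,
#' Satterthwaite degrees of freedom).  The replicate unit is the sample
#' transcriptogram: technical and biological replicates enter as provided.
#' Multiplicity over the ordering positions is handled three ways at once:
#' a Bonferroni flag at family level `family_alpha` (the per-test threshold
#' is `family_alpha / family_size`), Benjamini-Hochberg q-values, and
#' Storey q-values with estimated pi0.
#'
#' @param profiles_a,profiles_b positions-x-replicates matrices (or long
#'   transcriptogram tibbles) for the two classes; >= 2 replicates each.
#' @param family_alpha family-wise error level for the Bonferroni flag.
#' @param family_size number of simultaneous hypotheses for Bonferroni;
#'   default is the number of non-missing tested positions.  Pass the full
#'   ordering length to correct over all positions regardless of coverage.
#' @param fdr FDR method for the `q_value` column: `"storey"` (default) or
#'   `"bh"`; the other method's q-values are always included too.
#' @return A tibble of class `xgram_comparison` with per-position columns
#'   `position`, `mean_a`, `mean_b`, `diff`, `effect_size` (difference over
#'   pooled standard error), `t`, `df`, `p_value`, `bonferroni`
#'   (logical), `q_bh`, `q_storey`, `q_value`; attributes record
#'   `family_size`, `bonferroni_threshold` and Storey's `pi0`.
#' @export
welch_compare <- function(profiles_a, profiles_b, family_alpha = 0.01,
                          family_size = NULL, fdr = c("storey", "bh")) {
  fdr <- match.arg(fdr)
  a <- profiles_matrix(profiles_a)
  b <- profiles_matrix(profiles_b)
  if (nrow(a) != nrow(b)) abort("profiles are not position-aligned")
  if (ncol(a) < 2 || ncol(b) < 2)
    abort("each group needs >= 2 replicate profiles",
          class = "xgram_insufficient_replication")
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- row_vars(a); v2 <- row_vars(b)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- !is.na(se2) & se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    t_stat[eq] <- 0; p[eq] <- 1; df[eq] <- n1 + n2 - 2
    ne <- degenerate & (m1 != m2)
    t_stat[ne] <- sign(m1 - m2)[ne] * Inf; p[ne] <- 0; df[ne] <- n1 + n2 - 2
  }
  tested <- !is.na(p)
  fam <- family_size %||% sum(tested)
  thr <- family_alpha / fam
  q_bh <- rep(NA_real_, length(p))
  q_bh[tested] <- p.adjust(p[tested], method = "BH")
  st <- storey_qvalue(p[tested])
  q_st <- rep(NA_real_, length(p))
  q_st[tested] <- st$q

  out <- tibble(
    position = seq_along(p),
    mean_a = m1, mean_b = m2, diff = m1 - m2,
    effect_size = t_stat,
    t = t_stat, df = df, p_value = p,
    bonferroni = !is.na(p) & p < thr,
    q_bh = q_bh, q_storey = q_st,
    q_value = if (fdr == "storey") q_st else q_bh
  )
  attr(out, "family_size") <- fam
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "pi0") <- st$pi0
  attr(out, "n_replicates") <- c(n1, n2)
  attr(out, "fdr_method") <- fdr
  class(out) <- c("xgram_comparison", class(out))
  out
}

# Storey pi0: lambda grid + cubic smoother, evaluated at the largest lambda
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) return(list(q = numeric(0), pi0 = NA_real_))
  pi0 <- if (length(p) >= 100) storey_pi0(p, lambda) else 1
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(cummin(q), 1)[ro]
  list(q = q, pi0 = pi0)
}

#' Estimate q-values from a vector of P-values
#'
#' `"bh"` gives Benjamini-Hochberg step-up q-values; `"storey"` additionally
#' estimates the null proportion pi0 on a lambda grid (0.05..0.95, cubic
#' smoother) and scales the q-values by it, which recovers power when many
#' hypotheses are non-null.
#'
#' @param p numeric vector of P-values in [0, 1].
#' @param method `"storey"` or `"bh"`.
#' @return A tibble `p_value`, `q_value`, with attribute `pi0` (Storey) and
#'   `method`.
#' @export
estimate_fdr <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("P-values must lie in [0, 1]", class = "xgram_bad_pvalues")
  if (method == "bh") {
    out <- tibble(p_value = p, q_value = p.adjust(p, method = "BH"))
    attr(out, "pi0") <- NA_real_
  } else {
    st <- storey_qvalue(p)
    out <- tibble(p_value = p, q_value = st$q)
    attr(out, "pi0") <- st$pi0
  }
  attr(out, "method") <- method
  out
}

#' Contrast-to-noise and signal-to-noise of a replicate class
#'
#' The contrast at a position is the absolute deviation of the class mean
#' transcriptogram from the class global average; the noise is the SD of the
#' replicate transcriptograms at that position.  The report aggregates over
#' positions: average noise Omega (mean of per-position SDs),
#' contrast-to-noise omega (position-averaged contrast over Omega) and
#' signal-to-noise SNR (position-averaged mean over Omega).  With
#' `per_position = TRUE`, omega and SNR are instead means of the
#' per-position ratios.
#'
#' @param profiles positions-x-replicates matrix (or long transcriptogram
#'   tibble) of one class; >= 2 replicates.
#' @param per_position use the per-position-ratio aggregation variant.
#' @return An object of class `noise_report`: list with `positions` (tibble
#'   `position`, `mean`, `contrast`, `sd`) and scalars `Omega`, `omega`,
#'   `snr` (Inf when all per-position SDs are zero), `global_mean`.
#' @export
contrast_noise <- function(profiles, per_position = FALSE) {
  m <- profiles_matrix(profiles)
  if (ncol(m) < 2)
    abort("need >= 2 replicate profiles", class = "xgram_insufficient_replication")
  mu <- rowMeans(m)
  g <- mean(mu, na.rm = TRUE)
  contrast <- abs(mu - g)
  sd_i <- sqrt(row_vars(m))
  Omega <- mean(sd_i, na.rm = TRUE)
  if (isTRUE(all.equal(Omega, 0)) || Omega == 0) {
    omega <- Inf; snr <- Inf
  } else if (per_position) {
    ok <- !is.na(sd_i) & sd_i > 0
    omega <- mean(contrast[ok] / sd_i[ok])
    snr <- mean(mu[ok] / sd_i[ok])
  } else {
    omega <- mean(contrast, na.rm = TRUE) / Omega
    snr <- g / Omega
  }
  structure(
    list(positions = tibble(position = seq_along(mu), mean = mu,
                            contrast = contrast, sd = sd_i),
         Omega = Omega, omega = omega, snr = snr, global_mean = g,
         n_replicates = ncol(m), per_position = per_position),
    class = "noise_report"
  )
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> Omega = %.4g, omega = %.4g, SNR = %.4g (%d replicates)\n",
              x$Omega, x$omega, x$snr, x$n_replicates))
  invisible(x)
}

#' Noise and contrast across window radii
#'
#' Convenience sweep: smooths one condition's replicates at each radius and
#' collects the [contrast_noise()] scalars.  On purely random noise the
#' average noise falls as the inverse square root of the window size
#' `w = 2r + 1`.
#'
#' @inheritParams class_profiles
#' @param condition condition label whose replicates are analyzed.
#' @param radii integer vector of window radii.
#' @return A tibble `r`, `w`, `Omega`, `omega`, `snr`.
#' @export
noise_curve <- function(expression, design, ordering, condition,
                        radii = c(5, 10, 20, 40, 80)) {
  design <- validate_design(design)
  cols <- design$sample[design$condition == condition]
  if (!length(cols))
    abort(sprintf("condition '%s' absent from design", condition),
          class = "xgram_invalid_design")
  purrr::map_dfr(radii, function(r) {
    tg <- tg_matrix(expression, ordering, r, quiet = TRUE)
    nr <- contrast_noise(tg$values[, cols, drop = FALSE])
    tibble(r = r, w = 2 * r + 1, Omega = nr$Omega, omega = nr$omega,
           snr = nr$snr)
  })
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two laboratories' per-gene (or per-position) fold
#' changes: `rho_c = 2 s12 / (s1^2 + s2^2 + (mu1 - mu2)^2)` with population
#' (1/n) moments.  Unlike Pearson's r it penalizes location and scale shifts,
#' so `|rho_c| <= |r|` always, with equality only when means and variances
#' agree.
#'
#' @param x,y equal-length aligned numeric vectors (>= 2 entries; pairs with
#'   missing values are dropped).
#' @param moments `"population"` (1/n, the classical definition) or
#'   `"sample"` (1/(n-1)).
#' @return A one-row tibble `rho_c`, `pearson`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `sigma12`, `n`; `rho_c` is `NA` when both inputs are
#'   constant.
#' @export
concordance <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(x) != length(y)) abort("inputs must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) abort("need >= 2 aligned pairs")
  denom_n <- if (moments == "population") n else n - 1
  mu1 <- mean(x); mu2 <- mean(y)
  s1 <- sum((x - mu1)^2) / denom_n
  s2 <- sum((y - mu2)^2) / denom_n
  s12 <- sum((x - mu1) * (y - mu2)) / denom_n
  denom <- s1 + s2 + (mu1 - mu2)^2
  rho_c <- if (denom == 0) NA_real_ else 2 * s12 / denom
  pearson <- if (s1 == 0 || s2 == 0) NA_real_ else s12 / sqrt(s1 * s2)
  tibble(rho_c = rho_c, pearson = pearson, mu1 = mu1, mu2 = mu2,
         sigma1 = sqrt(s1), sigma2 = sqrt(s2), sigma12 = s12, n = n)
}

#' Between-laboratory reproducibility versus window radius
#'
#' For each radius (including `r = 0`, the plain transcriptome), both
#' laboratories' expression tables are smoothed on the same ordering, the
#' per-position log2 fold change between the two conditions is computed in
#' each laboratory (difference of condition mean transcriptograms), and the
#' concordance correlation between the two fold-change vectors is recorded.
#' If `baseline_seed` is given, the same computation is repeated on a seeded
#' random permutation of the ordering, the standard negative control: a
#' random list does not concentrate correlated genes, so windowing there
#' destroys rather than reinforces the shared signal.
#'
#' @param expr_lab1,expr_lab2 expression tibbles from the two laboratories
#'   (same genes, same design).
#' @param design shared design tibble; must contain both `conditions`.
#' @param ordering a [gene_ordering()].
#' @param radii integer vector of radii to evaluate.
#' @param conditions length-2 character vector: fold change is condition 1
#'   minus condition 2 (log2 scale).
#' @param baseline_seed optional seed for the random-ordering control.
#' @return A tibble `r`, `ordering` ("true" or "random"), `rho_c`,
#'   `pearson`.
#' @export
reproducibility_curve <- function(expr_lab1, expr_lab2, design, ordering,
                                  radii = c(0, 10, 20, 40, 80),
                                  conditions, baseline_seed = NULL) {
  design <- validate_design(design)
  if (length(conditions) != 2 || !all(conditions %in% design$condition))
    abort("`conditions` must name two conditions present in the design",
          class = "xgram_invalid_design")
  orderings <- list(true = validate_ordering(ordering))
  if (!is.null(baseline_seed))
    orderings$random <- random_ordering(ordering, seed = baseline_seed)
  purrr::imap_dfr(orderings, function(ord, label) {
    purrr::map_dfr(radii, function(r) {
      fc <- lapply(list(expr_lab1, expr_lab2), function(ex) {
        tg <- tg_matrix(ex, ord, r, quiet = TRUE)
        c1 <- design$sample[design$condition == conditions[1]]
        c2 <- design$sample[design$condition == conditions[2]]
        rowMeans(tg$values[, c1, drop = FALSE]) -
          rowMeans(tg$values[, c2, drop = FALSE])
      })
      cc <- concordance(fc[[1]], fc[[2]])
      tibble(r = r, ordering = label, rho_c = cc$rho_c, pearson = cc$pearson)
    })
  })
}
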