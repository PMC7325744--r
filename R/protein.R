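#' Group fold change with delta-method standard error
#'
#' Fold change of group means, `mean(target) / mean(reference)`, with SE
#' from the first-order delta method. Satisfies reciprocal symmetry:
#' `fold(a, b) * fold(b, a) = 1` for positive means.
#'
#' @param target,reference Numeric vectors of replicate values.
#' @return A `group_comparison` list: group means and SEs, `fold`,
#'   `fold_se`, per-group `n`.
#' @export
fold_change <- function(target, reference) {
  mt <- mean(target); mr <- mean(reference)
  if (mr <= 0) stop("reference mean must be > 0", call. = FALSE)
  se_t <- stats::sd(target) / sqrt(length(target))
  se_r <- stats::sd(reference) / sqrt(length(reference))
  fold <- mt / mr
  fold_se <- if (mt > 0)
    abs(fold) * sqrt((se_t / mt)^2 + (se_r / mr)^2) else se_t / mr
  structure(list(target_mean = mt, target_se = se_t,
                 reference_mean = mr, reference_se = se_r,
                 fold = fold, fold_se = fold_se,
                 n_target = length(target), n_reference = length(reference)),
            class = "group_comparison")
}

#' Lysine as a percentage of total protein
#'
#' @param lysine Lysine content (g / 100 g flour).
#' @param protein Total protein (g / 100 g flour), > 0.
#' @return Percent of total protein that is lysine.
#' @export
lysine_percent_of_protein <- function(lysine, protein) {
  if (any(protein <= 0)) stop("total protein must be > 0", call. = FALSE)
  100 * lysine / protein
}

#' Popping loss and retention of an amino-acid level
#'
#' Loss is `raw - popped` (negative when a residue rises after popping)
#' and retention is `100 * popped / raw`, so
#' `retention/100 * raw + loss == raw` exactly.
#'
#' @param raw,popped Levels (g / 100 g), raw > 0.
#' @return List with `loss`, `retention` (percent), `gain` flag.
#' @export
popping_retention <- function(raw, popped) {
  if (any(raw <= 0)) stop("raw level must be > 0", call. = FALSE)
  loss <- raw - popped
  retention <- 100 * popped / raw
  list(loss = loss, retention = retention, gain = popped > raw)
}

#' Cross-method correlation of amino-acid levels with low-r flags
#'
#' For each residue and each pair of treatments, the Pearson correlation
#' across genotype means is computed; pairs correlating below 0.700 are
#' flagged as method-inconsistent. Pairs with fewer than 3 common
#' genotypes are skipped with a warning.
#'
#' @param aa An `amino_profile` data frame.
#' @param fraction `"protein_bound"` or `"free"`.
#' @param threshold Flagging threshold (default 0.700).
#' @return Data frame: `residue`, `treatment1`, `treatment2`, `n`, `r`,
#'   `flagged`.
#' @export
method_correlations <- function(aa, fraction = "protein_bound",
                                threshold = 0.700) {
  d <- aa[aa$fraction == fraction, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows in fraction ", fraction, call. = FALSE)
  gm <- stats::aggregate(value ~ genotype + residue + treatment, data = d,
                         FUN = mean)
  out <- list()
  skipped <- 0L
  for (res in unique(gm$residue)) {
    g <- gm[gm$residue == res, ]
    trts <- sort(unique(g$treatment))
    if (length(trts) < 2) next
    for (pair in utils::combn(trts, 2, simplify = FALSE)) {
      a <- g[g$treatment == pair[1], c("genotype", "value")]
      b <- g[g$treatment == pair[2], c("genotype", "value")]
      m <- merge(a, b, by = "genotype")
      if (nrow(m) < 3) { skipped <- skipped + 1L; next }
      r <- stats::cor(m$value.x, m$value.y)
      out[[length(out) + 1L]] <- data.frame(
        residue = res, treatment1 = pair[1], treatment2 = pair[2],
        n = nrow(m), r = r, flagged = is.na(r) | r < threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " treatment pair(s) skipped: fewer than 3 common genotypes")
  if (length(out) == 0)
    stop("no treatment pair had 3 or more common genotypes", call. = FALSE)
  do.call(rbind, out)
}

# Welch-style one-sided comparison of a sample mean against a derived
# value with its own SE; df by Welch-Satterthwaite.
welch_above <- function(x, ref_mean, ref_se, ref_df) {
  n <- length(x)
  se_x <- stats::sd(x) / sqrt(n)
  se2 <- se_x^2 + ref_se^2
  if (se2 == 0) return(list(t = NA_real_, p = NA_real_, tied = mean(x) == ref_mean))
  tstat <- (mean(x) - ref_mean) / sqrt(se2)
  df <- se2^2 / (se_x^4 / (n - 1) + if (ref_se > 0) ref_se^4 / ref_df else 0)
  list(t = tstat, p = stats::pt(tstat, df, lower.tail = FALSE), tied = FALSE)
}

#' Classify the inheritance mode of a residue level
#'
#' Two one-sided Welch tests locate the hybrid mean relative to the
#' mid-parent value (SE = half the root-sum-square of the parent SEs) and
#' the high-parent mean: not significantly above mid-parent -> `additive`;
#' above mid-parent but not above the high parent -> `dominant`;
#' significantly above the high parent (and above mid) -> `over_dominant`;
#' conflicting patterns or degenerate exact ties -> `ambiguous`.
#'
#' @param hybrid,maternal,paternal Numeric replicate vectors (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return An `inheritance_call` list with the call, group means,
#'   mid-parent value and both test results.
#' @export
classify_inheritance <- function(hybrid, maternal, paternal, alpha = 0.05) {
  if (length(hybrid) < 2 || length(maternal) < 2 || length(paternal) < 2)
    stop("at least 2 replicates per group are required", call. = FALSE)
  mh <- mean(hybrid); mm <- mean(maternal); mp <- mean(paternal)
  se_m <- stats::sd(maternal) / sqrt(length(maternal))
  se_p <- stats::sd(paternal) / sqrt(length(paternal))
  mid <- (mm + mp) / 2
  mid_se <- 0.5 * sqrt(se_m^2 + se_p^2)
  mid_df <- length(maternal) + length(paternal) - 2
  high <- if (mm >= mp) maternal else paternal
  t_mid <- welch_above(hybrid, mid, mid_se, mid_df)
  t_high <- welch_above(hybrid, mean(high),
                        stats::sd(high) / sqrt(length(high)),
                        length(high) - 1)
  if (is.na(t_mid$p) || is.na(t_high$p)) {
    # zero-variance degenerate groups with exact ties
    call <- "ambiguous"
  } else {
    above_mid <- t_mid$p < alpha
    above_high <- t_high$p < alpha
    call <- if (!above_mid && !above_high) "additive"
    else if (above_mid && !above_high) "dominant"
    else if (above_mid && above_high) "over_dominant"
    else "ambiguous"   # above high parent but not above mid-parent
  }
  structure(list(call = call, hybrid_mean = mh, maternal_mean = mm,
                 paternal_mean = mp, mid_parent = mid,
                 high_parent = mean(high), alpha = alpha,
                 test_mid = t_mid, test_high = t_high),
            class = "inheritance_call")
}

#' Fraction of the daily dietary requirement met by one serving
#'
#' `100 * (level/100 * serving) / requirement`. The requirement is a user
#' input (g/day), never hard-coded.
#'
#' @param level Amino-acid content of the flake (g / 100 g).
#' @param serving Serving size (g).
#' @param requirement Daily requirement (g/day), > 0.
#' @return Percent of the daily requirement.
#' @export
daily_requirement_fraction <- function(level, serving, requirement) {
  if (any(requirement <= 0)) stop("requirement must be > 0", call. = FALSE)
  100 * (level / 100 * serving) / requirement
}
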