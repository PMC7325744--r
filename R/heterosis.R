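#' The five heterosis categories, in order of increasing genetic diversity
#' @return Ordered character vector of category labels.
#' @export
heterosis_levels <- function() {
  c("pseudo_self", "same_popcorn", "same_qpm", "same_pool_hybrid",
    "complete_hybrid")
}

#' Categorize a cross by pedigree distance
#'
#' Rules, applied in order: same QPM donor and same popcorn parent ->
#' `pseudo_self` (sib lines of independent descent); same popcorn parent
#' only -> `same_popcorn` (double back-cross to the popcorn parent makes
#' shared popcorn ancestry dominate); same QPM donor only -> `same_qpm`;
#' all parents distinct but popcorn parents in one heterotic pool ->
#' `same_pool_hybrid`; otherwise `complete_hybrid`. Categorization is
#' symmetric in the two inbreds.
#'
#' @param a,b Single `pedigree` records (one-row data frames) for the two
#'   crossed inbreds.
#' @return One category label from [heterosis_levels()].
#' @export
categorize_cross <- function(a, b) {
  for (r in list(a, b))
    if (!is.data.frame(r) || nrow(r) != 1 ||
        !all(c("qpm_parent", "popcorn_parent", "heterotic_pool") %in% names(r)))
      stop("categorize_cross expects one-row pedigree records", call. = FALSE)
  same_qpm <- a$qpm_parent == b$qpm_parent
  same_pop <- a$popcorn_parent == b$popcorn_parent
  same_pool <- a$heterotic_pool == b$heterotic_pool
  if (same_qpm && same_pop) "pseudo_self"
  else if (same_pop) "same_popcorn"
  else if (same_qpm) "same_qpm"
  else if (same_pool) "same_pool_hybrid"
  else "complete_hybrid"
}

#' Categorize a table of crosses against a pedigree
#'
#' @param ped A `pedigree` data frame.
#' @param crosses Data frame with `maternal` and `paternal` inbred ids
#'   (e.g. from [default_crosses()]).
#' @return `crosses` with a `category` factor column ordered by
#'   [heterosis_levels()].
#' @export
categorize_crosses <- function(ped, crosses) {
  lookup <- function(id) {
    i <- match(id, ped$inbred)
    if (is.na(i)) stop("unknown inbred in pedigree lookup: ", id,
                       call. = FALSE)
    ped[i, , drop = FALSE]
  }
  cat <- vapply(seq_len(nrow(crosses)), function(i)
    categorize_cross(lookup(crosses$maternal[i]),
                     lookup(crosses$paternal[i])), character(1))
  crosses$category <- factor(cat, levels = heterosis_levels(), ordered = TRUE)
  crosses
}

#' Tukey-Kramer honest significant difference test
#'
#' Pairwise comparisons of group means using the studentized-range
#' distribution with the Tukey-Kramer unequal-n adjustment:
#' `q = |mi - mj| / sqrt((s2/2) * (1/ni + 1/nj))`, with p-values from
#' `ptukey(q, k, df)`. Stars follow the usual figure convention
#' (0.001 / 0.01 / 0.05).
#'
#' @param means Named numeric vector of group means.
#' @param ns Group sizes (same order/names as `means`).
#' @param s2 Pooled residual (error) variance.
#' @param df Residual degrees of freedom.
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q`, `p`, `stars`.
#' @export
tukey_hsd <- function(means, ns, s2, df) {
  k <- length(means)
  if (k < 2) stop("at least two groups are required", call. = FALSE)
  if (df < 1) stop("residual df must be >= 1", call. = FALSE)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- means[j] - means[i]
    se <- sqrt((s2 / 2) * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0   # boundary: zero error variance
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    c(diff = unname(diff), q = unname(q), p = unname(p))
  })
  out <- data.frame(group1 = names(means)[pairs[1, ]],
                    group2 = names(means)[pairs[2, ]],
                    t(res), stringsAsFactors = FALSE)
  out$stars <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "NS"))
  rownames(out) <- NULL
  out
}

#' Test the stepwise trait-improvement trend across heterosis categories
#'
#' Fits the two-location model with the pedigree category as the random
#' treatment (Type II SS), runs Tukey-Kramer pairwise comparisons on the
#' category means against the plot-level residual variance, and reports a
#' monotonicity flag over the category order: the flag is cleared only by
#' an adjacent-category mean *decrease* exceeding 0.25 pooled standard
#' errors of the difference (smaller dips are treated as noise).
#'
#' @param plots A `fieldbook` data frame.
#' @param categorized Data frame mapping `genotype` to `category` (from
#'   [categorize_crosses()]).
#' @param trait Trait name.
#' @return A `trend_report` list: per-category `means`/`ns`, `anova_p`,
#'   `tukey` table, `monotone` flag and `violations`.
#' @export
category_trend <- function(plots, categorized, trait) {
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  d$category <- as.character(
    categorized$category[match(d$genotype, categorized$genotype)])
  d <- d[!is.na(d$category), , drop = FALSE]
  present <- heterosis_levels()[heterosis_levels() %in% unique(d$category)]
  if (length(present) < 2)
    stop("at least two heterosis categories must be populated", call. = FALSE)
  fit <- fit_gcbd_anova(d, "category", trait)
  tab <- fit$table
  anova_p <- tab$p[tab$term == "treatment"]
  means <- tapply(d$value, factor(d$category, levels = present), mean)
  ns <- as.vector(table(factor(d$category, levels = present)))
  names(ns) <- present
  tk <- tukey_hsd(means, ns, fit$sigma2_error, fit$residual_df)
  # monotone trend along increasing genetic diversity
  violations <- character(0)
  if (length(present) > 1) {
    for (i in seq_len(length(present) - 1)) {
      a <- present[i]; b <- present[i + 1]
      se_diff <- sqrt(fit$sigma2_error * (1 / ns[a] + 1 / ns[b]))
      if (means[b] - means[a] < -0.25 * se_diff)
        violations <- c(violations, paste(a, "->", b))
    }
  }
  structure(list(trait = trait, categories = present,
                 means = means, ns = ns, anova_p = anova_p,
                 anova_table = tab, tukey = tk,
                 monotone = length(violations) == 0,
                 violations = violations),
            class = "trend_report")
}
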