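#' Per-hybrid, per-trait summaries for ranking
#'
#' Mean and standard deviation of each trait for each hybrid over its
#' replicate row-plots, pooled across locations (one summary measurement
#' per row-plot is assumed).
#'
#' @param plots A `fieldbook` data frame.
#' @param hybrids Optional character vector restricting the genotypes.
#' @return A `trait_summary` data frame: `hybrid`, `trait`, `mean`, `sd`,
#'   `n`.
#' @export
trait_summaries <- function(plots, hybrids = NULL) {
  d <- plots[!is.na(plots$value), , drop = FALSE]
  if (!is.null(hybrids)) d <- d[d$genotype %in% hybrids, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations to summarize", call. = FALSE)
  agg <- stats::aggregate(value ~ genotype + trait, data = d,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(hybrid = agg$genotype, trait = agg$trait,
                    mean = agg$value[, "mean"],
                    sd = ifelse(is.na(agg$value[, "sd"]), 0,
                                agg$value[, "sd"]),
                    n = agg$value[, "n"], stringsAsFactors = FALSE)
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' Orient trait summaries for "bigger is better" ranking
#'
#' Traits whose premium value is a minimum are complemented: a
#' `complement_then_maximize` trait (e.g. rot susceptibility) must be a
#' proportion and its means are mapped `x -> 1 - x` (standard deviations
#' are unchanged by reflection). `maximize` traits pass through; `excluded`
#' traits are dropped.
#'
#' @param summaries A `trait_summary` data frame.
#' @param specs A `trait_spec` data frame.
#' @return The oriented `trait_summary` (excluded traits removed).
#' @export
orient_traits <- function(summaries, specs) {
  specs <- validate_trait_specs(specs)
  s <- summaries[summaries$trait %in%
                   specs$name[specs$orientation != "excluded"], ,
                 drop = FALSE]
  ori <- specs$orientation[match(s$trait, specs$name)]
  comp <- ori == "complement_then_maximize"
  if (any(comp & (s$mean < 0 | s$mean > 1)))
    stop("complement orientation applied to a non-proportion value",
         call. = FALSE)
  s$mean[comp] <- 1 - s$mean[comp]
  class(s) <- c("trait_summary", "data.frame")
  s
}

#' Single-trait contribution to the rank-summation index
#'
#' The contribution of trait i to hybrid h's index is the weighted squared
#' relative deviation from the best hybrid, scaled by the hybrid's
#' relative within-trait variability:
#' `(y/y_max - 1)^2 * I * (sd/sd_max)` (multiplicative variant, default:
#' less homogeneous hybrids are penalized more). The `divisive` variant
#' divides by the sd ratio instead.
#'
#' @param y Oriented trait mean for the hybrid.
#' @param y_max Best oriented mean across hybrids (must be > 0).
#' @param sd,sd_max Hybrid and maximum within-trait standard deviations.
#' @param weight Selection-intensity weight in [0, 1].
#' @param variant `"multiplicative"` or `"divisive"` sd-term placement.
#' @return Nonnegative contribution.
#' @export
#' @examples
#' trait_term(8, 10, sd = 1, sd_max = 2, weight = 0.85)  # 0.017
trait_term <- function(y, y_max, sd, sd_max, weight,
                       variant = c("multiplicative", "divisive")) {
  variant <- match.arg(variant)
  if (y_max <= 0) stop("degenerate trait: y_max must be > 0", call. = FALSE)
  sd_ratio <- if (sd_max > 0) sd / sd_max else 1
  base <- (y / y_max - 1)^2 * weight
  if (variant == "multiplicative") base * sd_ratio
  else if (sd_ratio > 0) base / sd_ratio else base
}

#' Rank hybrids by the weighted rank-summation index
#'
#' Computes each hybrid's index total `X_h` as the sum of per-trait
#' contributions (see [trait_term()]) after orientation, using per-trait
#' maxima taken across the ranked hybrids post-orientation. Smaller totals
#' mark superior hybrids; a hybrid attaining the oriented maximum of every
#' weighted trait scores exactly 0. Degenerate traits (nonpositive
#' oriented maximum) are skipped with a warning. A hybrid missing a
#' weighted trait receives that trait's worst observed contribution
#' (pessimistic imputation) and is flagged. Ties share a rank position;
#' display order among ties puts higher expansion volume first.
#'
#' @param summaries A `trait_summary` data frame covering all hybrids.
#' @param specs A `trait_spec` data frame (defaults to
#'   [default_trait_specs()]).
#' @param variant sd-term placement, see [trait_term()].
#' @return A `rank_result` data frame ordered best-first: `hybrid`,
#'   `total`, `rank`, `imputed`, plus one `contrib_<trait>` column per
#'   weighted trait.
#' @export
rank_hybrids <- function(summaries, specs = default_trait_specs(),
                         variant = c("multiplicative", "divisive")) {
  variant <- match.arg(variant)
  s <- orient_traits(summaries, specs)
  hybrids <- unique(summaries$hybrid)
  if (length(hybrids) == 0) stop("no hybrids to rank", call. = FALSE)
  traits <- intersect(specs$name[specs$orientation != "excluded"],
                      unique(s$trait))
  contrib <- matrix(NA_real_, length(hybrids), length(traits),
                    dimnames = list(hybrids, traits))
  for (tr in traits) {
    st <- s[s$trait == tr, , drop = FALSE]
    y_max <- max(st$mean)
    if (y_max <= 0) {
      warning("degenerate trait '", tr, "' (oriented maximum <= 0): skipped")
      contrib[, tr] <- 0
      next
    }
    sd_max <- max(st$sd)
    w <- specs$weight[specs$name == tr]
    vals <- vapply(seq_len(nrow(st)), function(i)
      trait_term(st$mean[i], y_max, st$sd[i], sd_max, w, variant),
      numeric(1))
    contrib[st$hybrid, tr] <- vals
    # pessimistic imputation for hybrids missing this trait
    miss <- is.na(contrib[, tr])
    if (any(miss)) contrib[miss, tr] <- max(vals)
  }
  imputed <- vapply(hybrids, function(h) {
    !all(traits %in% s$trait[s$hybrid == h])
  }, logical(1))
  total <- rowSums(contrib)
  rk <- rank(total, ties.method = "min")
  out <- data.frame(hybrid = hybrids, total = unname(total),
                    rank = unname(rk), imputed = unname(imputed),
                    stringsAsFactors = FALSE)
  cm <- as.data.frame(contrib)
  names(cm) <- paste0("contrib_", names(cm))
  out <- cbind(out, cm)
  # display order: ascending total; among exact ties, higher oriented EV first
  ev_mean <- rep(NA_real_, length(hybrids))
  if ("ev" %in% s$trait) {
    se <- s[s$trait == "ev", ]
    ev_mean[match(se$hybrid, hybrids)] <- se$mean
  }
  out <- out[order(out$total, -ifelse(is.na(ev_mean), -Inf, ev_mean)), ]
  rownames(out) <- NULL
  class(out) <- c("rank_result", "data.frame")
  out
}
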