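#' Fit the two-location generalized complete block model with Type II SS
#'
#' Fits `value ~ location + treatment + location:treatment` to plot-level
#' observations of one trait and computes Type II sums of squares by
#' model comparison: each term's SS is the residual-SS drop when the term
#' is added to the model containing all other terms of equal or lower
#' order (interactions excluded). This respects marginality and keeps
#' degrees of freedom honest with missing plots; on balanced data it
#' reduces to the textbook sequential two-way ANOVA. Replicate row-plots
#' within a location are absorbed into the error stratum.
#'
#' @param plots A `fieldbook` data frame.
#' @param treatment_factor `"hybrid"` (the genotype id), `"maternal"`,
#'   `"paternal"`, or the name of any column present in `plots` to be used
#'   as the treatment.
#' @param trait Trait name to analyse.
#' @return A `gcbd_anova` object: ANOVA table (`term`, `df`, `ss`, `ms`,
#'   `f`, `p`), grand mean, raw treatment/location/interaction effect
#'   estimates, residual variance, and design counts.
#' @export
fit_gcbd_anova <- function(plots, treatment_factor = "hybrid", trait) {
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait ", trait, call. = FALSE)
  trt <- switch(treatment_factor,
                hybrid = d$genotype,
                maternal = d$maternal,
                paternal = d$paternal,
                {
                  if (!treatment_factor %in% names(d))
                    stop("unknown treatment factor: ", treatment_factor,
                         call. = FALSE)
                  d[[treatment_factor]]
                })
  keep <- !is.na(trt)
  d <- d[keep, , drop = FALSE]; trt <- trt[keep]
  loc <- factor(d$location); trtf <- factor(trt)
  if (nlevels(loc) < 2)
    stop("at least 2 locations are required", call. = FALSE)
  if (nlevels(trtf) < 2)
    stop("at least 2 treatment levels are required", call. = FALSE)
  y <- d$value
  rss <- function(mm) {
    fit <- stats::lm.fit(mm, y)
    list(rss = sum(fit$residuals^2), rank = fit$rank)
  }
  mm_null <- matrix(1, length(y), 1)
  mm_loc <- stats::model.matrix(~loc)
  mm_trt <- stats::model.matrix(~trtf)
  mm_add <- stats::model.matrix(~loc + trtf)
  mm_full <- stats::model.matrix(~loc * trtf)
  f_loc <- rss(mm_loc); f_trt <- rss(mm_trt); f_add <- rss(mm_add)
  f_full <- rss(mm_full)
  # Type II: each main effect adjusted for the other; interaction last
  ss_loc <- f_trt$rss - f_add$rss
  ss_trt <- f_loc$rss - f_add$rss
  ss_int <- f_add$rss - f_full$rss
  df_loc <- f_add$rank - f_trt$rank
  df_trt <- f_add$rank - f_loc$rank
  df_int <- f_full$rank - f_add$rank
  if (df_trt == 0 || df_loc == 0)
    stop("degenerate design: a factor is confounded with another",
         call. = FALSE)
  df_res <- length(y) - f_full$rank
  ss_res <- f_full$rss
  ms_err <- if (df_res > 0) ss_res / df_res else NA_real_
  tab <- data.frame(
    term = c("location", "treatment", "location:treatment", "residual"),
    df = c(df_loc, df_trt, df_int, df_res),
    ss = c(ss_loc, ss_trt, ss_int, ss_res),
    stringsAsFactors = FALSE
  )
  tab$ms <- ifelse(tab$df > 0, tab$ss / tab$df, NA_real_)
  tab$f <- c(tab$ms[1:3] / ms_err, NA_real_)
  tab$p <- c(stats::pf(tab$f[1:3], tab$df[1:3], df_res, lower.tail = FALSE),
             NA_real_)
  # raw effect estimates from cell/marginal means
  gm <- mean(y)
  trt_eff <- tapply(y, trtf, mean) - gm
  loc_eff <- tapply(y, loc, mean) - gm
  cellm <- tapply(y, list(loc, trtf), mean)
  int_eff <- sweep(sweep(cellm - gm, 1, loc_eff, "-"), 2, trt_eff, "-")
  cn <- table(loc, trtf)
  structure(list(
    trait = trait, treatment_factor = treatment_factor, table = tab,
    grand_mean = gm, treatment_effects = trt_eff,
    location_effects = loc_eff, interaction_effects = int_eff,
    sigma2_error = ms_err, residual_df = df_res,
    n_locations = nlevels(loc), n_treatments = nlevels(trtf),
    mean_cell_n = mean(cn[cn > 0]), cell_n = cn, n_obs = length(y)
  ), class = "gcbd_anova")
}

#' @export
print.gcbd_anova <- function(x, ...) {
  cat("GCBD ANOVA (Type II SS) for trait '", x$trait, "', treatment = ",
      x$treatment_factor, "\n", sep = "")
  print(transform(x$table, ss = signif(ss, 6), ms = signif(ms, 6),
                  f = signif(f, 4), p = signif(p, 4)), row.names = FALSE)
  invisible(x)
}

#' Solve variance components from expected mean squares
#'
#' Treating the treatment and location-by-treatment terms as random, the
#' balanced expected mean squares are
#' `E(MS_trt) = s2_e + n*s2_int + n*L*s2_trt`,
#' `E(MS_int) = s2_e + n*s2_int`, `E(MS_err) = s2_e`, with `n` plots per
#' location-by-treatment cell and `L` locations. Components are solved by
#' direct inversion using the Type II mean squares; for mildly unbalanced
#' data `n` is the mean occupied-cell count (Henderson-style moment
#' approximation). Negative solutions are clipped to zero with the
#' pre-clip value retained.
#'
#' @param fit A `gcbd_anova` object.
#' @param clip Clip negative solutions to zero (default `TRUE`).
#' @return A `variance_components` object with `sigma2_treatment`,
#'   `sigma2_interaction`, `sigma2_error`, pre-clip values, and flags.
#' @export
variance_components <- function(fit, clip = TRUE) {
  stopifnot(inherits(fit, "gcbd_anova"))
  if (fit$residual_df <= 0)
    stop("zero residual degrees of freedom: variance components undefined",
         call. = FALSE)
  tab <- fit$table
  ms <- stats::setNames(tab$ms, tab$term)
  n <- fit$mean_cell_n
  L <- fit$n_locations
  s2e <- ms[["residual"]]
  s2i_raw <- (ms[["location:treatment"]] - s2e) / n
  s2t_raw <- (ms[["treatment"]] - ms[["location:treatment"]]) / (n * L)
  clipped <- c(treatment = s2t_raw < 0, interaction = s2i_raw < 0)
  s2i <- if (clip) max(s2i_raw, 0) else s2i_raw
  s2t <- if (clip) max(s2t_raw, 0) else s2t_raw
  structure(list(
    sigma2_treatment = s2t, sigma2_interaction = s2i, sigma2_error = s2e,
    preclip = c(treatment = s2t_raw, interaction = s2i_raw, error = s2e),
    clipped = clipped, treatment_factor = fit$treatment_factor,
    trait = fit$trait
  ), class = "variance_components")
}

#' Broad-sense heritability / genetic repeatability on the plot basis
#'
#' The ratio of treatment (genetic) variance to plot-basis phenotypic
#' variance, `s2_t / (s2_t + s2_int + s2_e)`. With the hybrid as the
#' random treatment this is the genetic repeatability; with a parental
#' role it is that role's broad-sense heritability.
#'
#' @param components A `variance_components` object.
#' @return A `heritability` object with `ratio`, `role` and `basis`.
#' @export
heritability <- function(components) {
  stopifnot(inherits(components, "variance_components"))
  tot <- components$sigma2_treatment + components$sigma2_interaction +
    components$sigma2_error
  if (tot <= 0)
    stop("all variance components are zero: heritability undefined",
         call. = FALSE)
  role <- switch(components$treatment_factor,
                 maternal = "maternal", paternal = "paternal", "hybrid")
  structure(list(ratio = components$sigma2_treatment / tot,
                 role = role, basis = "plot", trait = components$trait),
            class = "heritability")
}
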