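#' Hybrid entry means by trait
#'
#' One value per hybrid per trait: the mean over all of its plots, pooled
#' across locations.
#'
#' @param plots A `fieldbook` data frame.
#' @param traits Optional character vector of traits to keep.
#' @return Numeric matrix, hybrids in rows and traits in columns (NA where
#'   a hybrid lacks a trait).
#' @export
entry_means <- function(plots, traits = NULL) {
  d <- plots[!is.na(plots$value), , drop = FALSE]
  if (!is.null(traits)) d <- d[d$trait %in% traits, , drop = FALSE]
  tapply(d$value, list(d$genotype, d$trait), mean)
}

#' Pairwise Pearson correlation and covariance across traits
#'
#' Pairwise-complete Pearson correlations on hybrid entry means with
#' two-sided t-test p-values and significance stars
#' (`***` p < 0.0001, `**` p < 0.001, `*` p < 0.05, `NS` otherwise).
#' Constant traits yield NA correlations and are flagged.
#'
#' @param em Entry-mean matrix from [entry_means()].
#' @return A `trait_matrix` list: `correlation`, `p`, `stars`,
#'   `covariance`, `variance`, `n`, `flagged_constant`.
#' @export
correlation_matrix <- function(em) {
  em <- as.matrix(em)
  if (nrow(em) < 3)
    stop("at least 3 hybrids with data are required", call. = FALSE)
  tn <- colnames(em)
  k <- length(tn)
  sds <- apply(em, 2, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  R <- suppressWarnings(stats::cor(em, use = "pairwise.complete.obs"))
  V <- stats::cov(em, use = "pairwise.complete.obs")
  N <- crossprod(!is.na(em))
  P <- matrix(NA_real_, k, k, dimnames = dimnames(R))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    n <- N[i, j]; r <- R[i, j]
    if (i == j) { P[i, j] <- 0; next }
    if (is.na(r) || n < 3) next
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    P[i, j] <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  structure(list(correlation = R, p = P, stars = star_map(P),
                 covariance = V, variance = diag(V), n = N,
                 flagged_constant = tn[constant]),
            class = "trait_matrix")
}

#' Map p-values to significance stars
#'
#' Pure threshold map: `***` below 0.0001, `**` below 0.001, `*` below
#' 0.05, otherwise `NS`.
#' @param p Numeric vector/matrix of p-values.
#' @return Character object of the same shape.
#' @export
star_map <- function(p) {
  s <- ifelse(is.na(p), NA_character_,
              ifelse(p < 1e-4, "***",
                     ifelse(p < 1e-3, "**",
                            ifelse(p < 0.05, "*", "NS"))))
  if (is.matrix(p)) dim(s) <- dim(p)
  if (!is.null(dimnames(p))) dimnames(s) <- dimnames(p)
  s
}

#' Standardized path coefficients by correlation-matrix regression
#'
#' Simplified path analysis: the outcome is regressed on the predictors
#' after standardization, so coefficients solve the normal equations
#' `R_xx b = r_xy` built from Pearson correlations. With one predictor
#' the coefficient equals the correlation; with orthogonal predictors
#' each coefficient equals its marginal correlation. The classical path
#' identity `r_xy = b_x + sum_j r_xj b_j` holds exactly.
#'
#' @param em Entry-mean matrix from [entry_means()].
#' @param outcome Outcome trait name.
#' @param predictors Character vector of predictor trait names.
#' @return A `path_model` list: `outcome`, `predictors`, `coefficients`
#'   (standardized), `residual_variance` (1 - R^2).
#' @export
path_coefficients <- function(em, outcome, predictors) {
  em <- as.matrix(em)
  cols <- c(outcome, predictors)
  if (!all(cols %in% colnames(em)))
    stop("traits absent from entry means: ",
         paste(setdiff(cols, colnames(em)), collapse = ", "), call. = FALSE)
  X <- em[stats::complete.cases(em[, cols, drop = FALSE]), cols, drop = FALSE]
  if (nrow(X) < length(predictors) + 2)
    stop("too few complete cases for the path model", call. = FALSE)
  R <- stats::cor(X)
  Rxx <- R[predictors, predictors, drop = FALSE]
  rxy <- R[predictors, outcome]
  if (abs(det(Rxx)) < 1e-12)
    stop("predictor correlation matrix is singular (collinearity)",
         call. = FALSE)
  beta <- solve(Rxx, rxy)
  structure(list(outcome = outcome, predictors = predictors,
                 coefficients = stats::setNames(as.numeric(beta), predictors),
                 residual_variance = as.numeric(1 - crossprod(beta, rxy)),
                 predictor_correlations = Rxx,
                 marginal_correlations = rxy),
            class = "path_model")
}
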