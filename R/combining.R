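#' Per-cross cell means for a diallel trait
#'
#' Averages plot values within each maternal x paternal cross. Cells with
#' no data are flagged missing and excluded from the grand mean and from
#' role marginal means, which are unweighted means of available cell means.
#'
#' @param plots A `fieldbook` data frame with `maternal`/`paternal` ids.
#' @param trait Trait name.
#' @return A `cell_means` object: `mean` and `n` matrices (maternal rows,
#'   paternal columns), `grand_mean`, `maternal_means`, `paternal_means`.
#' @export
hybrid_cell_means <- function(plots, trait) {
  d <- plots[plots$trait == trait & !is.na(plots$value) &
               !is.na(plots$maternal) & !is.na(plots$paternal), ,
             drop = FALSE]
  if (nrow(d) == 0)
    stop("no hybrid observations for trait ", trait, call. = FALSE)
  mf <- factor(d$maternal, levels = sort(unique(d$maternal)))
  pf <- factor(d$paternal, levels = sort(unique(d$paternal)))
  mean_mat <- tapply(d$value, list(mf, pf), mean)
  n_mat <- table(mf, pf)
  structure(list(
    mean = mean_mat, n = unclass(n_mat), trait = trait,
    grand_mean = mean(mean_mat, na.rm = TRUE),
    maternal_means = rowMeans(mean_mat, na.rm = TRUE),
    paternal_means = colMeans(mean_mat, na.rm = TRUE)
  ), class = "cell_means")
}

# Joint additive least-squares fit to available cell means:
#   ybar_kl = mu + g_k + g_l  (sum-to-zero constraints on both roles).
# On a complete grid this reproduces marginal-mean deviations exactly; on
# an incomplete grid (selfs excluded) it adjusts for the missing cells so
# that GCA effects sum to zero and SCA residuals have exact zero row and
# column sums over available cells.
gca_ls_fit <- function(cells) {
  Y <- cells$mean
  av <- which(!is.na(Y), arr.ind = TRUE)
  if (nrow(av) < 2) stop("not enough cells for a GCA fit", call. = FALSE)
  mfac <- factor(rownames(Y)[av[, 1]], levels = rownames(Y))
  pfac <- factor(colnames(Y)[av[, 2]], levels = colnames(Y))
  y <- Y[av]
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ mfac + pfac)
  cf <- stats::coef(fit)
  a <- nlevels(mfac); b <- nlevels(pfac)
  gm_eff <- cf[grep("^mfac", names(cf))]
  gp_eff <- cf[grep("^pfac", names(cf))]
  g_m <- c(gm_eff, -sum(gm_eff))
  g_p <- c(gp_eff, -sum(gp_eff))
  names(g_m) <- rownames(Y); names(g_p) <- colnames(Y)
  list(mu = unname(cf[["(Intercept)"]]), maternal = g_m, paternal = g_p)
}

#' Estimate general combining ability for one parental role
#'
#' GCA effects are deviations of a parent's average hybrid performance
#' from the grand mean, with the sign convention that a positive effect
#' marks an above-average parent. Effects are obtained from a joint
#' additive least-squares fit to the available cell means under
#' sum-to-zero constraints; on a complete balanced grid this equals the
#' marginal-mean formula `g_k = ybar_k. - mu` exactly, and on the
#' selfs-excluded factorial it corrects for the missing diagonal so the
#' zero-sum contract still holds exactly.
#'
#' @param cells A `cell_means` object.
#' @param role `"maternal"` or `"paternal"`.
#' @return A `gca_table` data frame (`parent`, `effect`) with attributes
#'   `mu` (the fitted grand mean), `role` and `trait`.
#' @export
estimate_gca <- function(cells, role = c("maternal", "paternal")) {
  role <- match.arg(role)
  stopifnot(inherits(cells, "cell_means"))
  if (length(if (role == "maternal") rownames(cells$mean)
             else colnames(cells$mean)) < 2)
    stop("at least 2 parents are required in role ", role, call. = FALSE)
  ls <- gca_ls_fit(cells)
  eff <- ls[[role]]
  out <- data.frame(parent = names(eff), effect = unname(eff),
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- ls$mu
  attr(out, "role") <- role
  attr(out, "trait") <- cells$trait
  class(out) <- c("gca_table", "data.frame")
  out
}

#' Estimate specific combining ability
#'
#' SCA effects are the cross-specific deviations left after removing the
#' grand mean and both parental GCA effects:
#' `s_kl = ybar_kl - mu - g_k - g_l`. The reconstruction identity
#' `mu + g_k + g_l + s_kl = ybar_kl` holds exactly for every observed
#' cell, and row/column sums of the SCA matrix over available cells are
#' exactly zero.
#'
#' @param cells A `cell_means` object.
#' @param mgca,pgca `gca_table` objects from [estimate_gca()] on the same
#'   cell means.
#' @return An `sca_matrix` object: matrix of SCA effects (NA for missing
#'   cells) with attributes `mu` and `trait`.
#' @export
estimate_sca <- function(cells, mgca, pgca) {
  stopifnot(inherits(cells, "cell_means"),
            inherits(mgca, "gca_table"), inherits(pgca, "gca_table"))
  Y <- cells$mean
  if (!identical(mgca$parent, rownames(Y)) ||
      !identical(pgca$parent, colnames(Y)))
    stop("GCA tables do not match the cell-mean dimensions", call. = FALSE)
  if (abs(attr(mgca, "mu") - attr(pgca, "mu")) > 1e-8)
    stop("maternal and paternal GCA tables come from different fits",
         call. = FALSE)
  mu <- attr(mgca, "mu")
  S <- Y - mu - outer(mgca$effect, pgca$effect, "+")
  attr(S, "mu") <- mu
  attr(S, "trait") <- cells$trait
  class(S) <- c("sca_matrix", class(S))
  S
}

#' Standard errors of GCA effects or SCA cells by contrast algebra
#'
#' The effect is written as a linear contrast of cell means (marginal-mean
#' definition over available cells); its variance is
#' `sum(c_kl^2 * s2 / n_kl)` with `s2` the residual variance of the
#' plot-level two-location fit with the hybrid as treatment.
#'
#' @param plots A `fieldbook` data frame (used for the residual variance).
#' @param cells The `cell_means` object the effects came from.
#' @param role `"maternal"`, `"paternal"`, or `"sca"`.
#' @return Named vector of standard errors (per parent, or per available
#'   cross for `"sca"`). Parents/cells with insufficient replication are
#'   returned as `NA` with a warning.
#' @export
combining_se <- function(plots, cells, role = c("maternal", "paternal", "sca")) {
  role <- match.arg(role)
  stopifnot(inherits(cells, "cell_means"))
  fit <- fit_gcbd_anova(plots, "hybrid", cells$trait)
  s2 <- fit$sigma2_error
  N <- cells$n
  avail <- !is.na(cells$mean)
  n_cells <- sum(avail)
  var_of <- function(C) {
    # C: contrast weights over the cell grid (0 where missing)
    if (any(C[avail] != 0 & N[avail] < 1)) return(NA_real_)
    sum((C[avail]^2) * s2 / N[avail])
  }
  base <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(cells$mean))
  if (role %in% c("maternal", "paternal")) {
    ids <- if (role == "maternal") rownames(N) else colnames(N)
    se <- vapply(ids, function(k) {
      C <- base
      C[avail] <- -1 / n_cells
      own <- if (role == "maternal") avail[k, ] else avail[, k]
      m <- sum(own)
      if (m == 0) return(NA_real_)
      if (role == "maternal") C[k, own] <- C[k, own] + 1 / m
      else C[own, k] <- C[own, k] + 1 / m
      sqrt(var_of(C))
    }, numeric(1))
  } else {
    cellidx <- which(avail, arr.ind = TRUE)
    se <- apply(cellidx, 1, function(ij) {
      k <- ij[1]; l <- ij[2]
      C <- base
      C[avail] <- C[avail] + 1 / n_cells            # + mu removed twice below
      rown <- sum(avail[k, ]); coln <- sum(avail[, l])
      C[k, avail[k, ]] <- C[k, avail[k, ]] - 1 / rown
      C[avail[, l], l] <- C[avail[, l], l] - 1 / coln
      C[k, l] <- C[k, l] + 1
      sqrt(var_of(C))
    })
    names(se) <- paste(rownames(N)[cellidx[, 1]],
                       colnames(N)[cellidx[, 2]], sep = "x")
  }
  if (anyNA(se)) warning("insufficient replication for some effects; SE = NA")
  se
}

#' Full diallel estimates for one trait
#'
#' Convenience wrapper: cell means, maternal/paternal GCA with standard
#' errors and role heritabilities, SCA matrix with repeatability.
#'
#' @param plots A `fieldbook` data frame.
#' @param trait Trait name.
#' @return A `diallel_estimates` list.
#' @export
diallel_estimates <- function(plots, trait) {
  cells <- hybrid_cell_means(plots, trait)
  mgca <- estimate_gca(cells, "maternal")
  pgca <- estimate_gca(cells, "paternal")
  sca <- estimate_sca(cells, mgca, pgca)
  herit <- function(factor_name) {
    f <- fit_gcbd_anova(plots, factor_name, trait)
    heritability(variance_components(f))$ratio
  }
  structure(list(
    trait = trait, grand_mean = attr(mgca, "mu"), cells = cells,
    mgca = mgca, pgca = pgca, sca = sca,
    se_maternal = combining_se(plots, cells, "maternal"),
    se_paternal = combining_se(plots, cells, "paternal"),
    heritability_maternal = herit("maternal"),
    heritability_paternal = herit("paternal"),
    repeatability_hybrid = herit("hybrid")
  ), class = "diallel_estimates")
}
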