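# Shared fixture builders and independent oracles.

# Balanced plot table: every treatment at every location x block, value =
# mu + loc_eff + trt_eff + int_eff + noise. Treatment ids double as
# genotype ids so the same table feeds fit_gcbd_anova("hybrid", ...).
make_balanced_fb <- function(trt_ids, loc_ids, blocks, mu = 10,
                             loc_eff = NULL, trt_eff = NULL,
                             int_eff = NULL, sd = 0, trait = "el",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loc_eff)) loc_eff <- stats::setNames(rep(0, length(loc_ids)), loc_ids)
  if (is.null(trt_eff)) trt_eff <- stats::setNames(rep(0, length(trt_ids)), trt_ids)
  if (is.null(int_eff))
    int_eff <- matrix(0, length(loc_ids), length(trt_ids),
                      dimnames = list(loc_ids, trt_ids))
  g <- expand.grid(block = paste0("B", seq_len(blocks)), genotype = trt_ids,
                   location = loc_ids, stringsAsFactors = FALSE)
  g$value <- mu + loc_eff[g$location] + trt_eff[g$genotype] +
    int_eff[cbind(g$location, g$genotype)] +
    stats::rnorm(nrow(g), 0, sd)
  data.frame(location = g$location, block = g$block, genotype = g$genotype,
             maternal = NA_character_, paternal = NA_character_,
             trait = trait, value = g$value, stringsAsFactors = FALSE)
}

# Diallel fieldbook with explicit cell means (maternal x paternal matrix,
# NA = missing cross) replicated `reps` times per location, plus noise.
make_diallel_fb <- function(cellmeans, loc_ids = c("L1", "L2"), reps = 2,
                            sd = 0, trait = "el", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  av <- which(!is.na(cellmeans), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nrow(av)), function(i) {
    m <- rownames(cellmeans)[av[i, 1]]; p <- colnames(cellmeans)[av[i, 2]]
    expand.grid(location = loc_ids, block = paste0("B", seq_len(reps)),
                maternal = m, paternal = p, stringsAsFactors = FALSE)
  }))
  rows$genotype <- hybrid_id(rows$maternal, rows$paternal)
  rows$trait <- trait
  rows$value <- cellmeans[cbind(rows$maternal, rows$paternal)] +
    stats::rnorm(nrow(rows), 0, sd)
  rows[, c("location", "block", "genotype", "maternal", "paternal",
           "trait", "value")]
}

# Residual sum of squares by plain QR on a hand-built design matrix.
rss_qr <- function(X, y) sum(qr.resid(qr(X), y)^2)

# Indicator (dummy) columns for a factor, built without model.matrix.
dummies <- function(f) {
  f <- factor(f)
  m <- outer(f, levels(f), `==`) * 1
  colnames(m) <- levels(f)
  m
}

# Brute-force Type II SS oracle: nested least squares with hand-built
# full-rank design matrices (drop-first-level coding).
type2_oracle <- function(loc, trt, y) {
  L <- dummies(loc)[, -1, drop = FALSE]
  T_ <- dummies(trt)[, -1, drop = FALSE]
  inter <- do.call(cbind, lapply(seq_len(ncol(L)), function(i)
    L[, i] * T_))
  one <- rep(1, length(y))
  r_loc <- rss_qr(cbind(one, L), y)
  r_trt <- rss_qr(cbind(one, T_), y)
  r_add <- rss_qr(cbind(one, L, T_), y)
  r_full <- rss_qr(cbind(one, L, T_, inter), y)
  c(location = r_trt - r_add, treatment = r_loc - r_add,
    interaction = r_add - r_full, residual = r_full)
}

# Expected among-hybrid-cell variance induced by exactly centered
# maternal GCA, paternal GCA and SCA draws: tr(C Sigma)/(n-1) with C the
# centering projector over the cross set.
expected_hybrid_variance <- function(crosses, s2m, s2p, s2s) {
  n <- nrow(crosses)
  Zm <- dummies(crosses$maternal)
  Zp <- dummies(crosses$paternal)
  Cm <- diag(ncol(Zm)) - 1 / ncol(Zm)
  Cp <- diag(ncol(Zp)) - 1 / ncol(Zp)
  Cn <- diag(n) - 1 / n
  Sigma <- s2m * Zm %*% Cm %*% t(Zm) + s2p * Zp %*% Cp %*% t(Zp) + s2s * Cn
  sum(diag(Cn %*% Sigma)) / (n - 1)
}

# Hand evaluation of the rank-summation index on oriented summaries.
index_oracle <- function(means, sds, weights) {
  # means, sds: hybrid x trait matrices (already oriented); weights named
  totals <- rep(0, nrow(means))
  for (tr in colnames(means)) {
    ymax <- max(means[, tr]); smax <- max(sds[, tr])
    ratio <- if (smax > 0) sds[, tr] / smax else 1
    totals <- totals + (means[, tr] / ymax - 1)^2 * weights[[tr]] * ratio
  }
  stats::setNames(totals, rownames(means))
}

ref_gca_path <- function() {
  system.file("extdata", "reference_gca.csv", package = "qppdiallel")
}
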