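#' Default simulation parameters for a 4 x 12 popcorn diallel trial
#'
#' The emulated design is the standard pre-screening trial: 4 maternal
#' inbreds crossed to 12 paternal inbreds (selfs excluded, reciprocals
#' distinct; 44 hybrids), grown in a generalized complete block design at
#' 2 locations with 6 replicate row-plots per location. Per-trait variance
#' components (maternal GCA, paternal GCA, SCA, location, location x
#' genotype, plot error) default to magnitudes that place plot-basis
#' heritabilities in the 0.02-0.45 range typical of such trials; the
#' genetic correlation across traits defaults to a two-factor structure in
#' which expansion volume is negatively correlated with yield components
#' and positively with vitreousness and popability.
#'
#' @param maternal,paternal Character vectors of parent inbred ids.
#' @param locations Character vector of location ids.
#' @param blocks Number of replicate row-plots per location.
#' @param traits Character vector of trait names to simulate (must appear
#'   in the rows of `mu` and `varcomp`).
#' @param mu Named numeric vector of per-trait grand means.
#' @param varcomp Numeric matrix, traits x components, columns
#'   `mgca`, `pgca`, `sca`, `location`, `gxe`, `error`.
#' @param genetic_cor Genetic correlation matrix across traits (applied to
#'   GCA/SCA effects only; location, interaction and plot errors are
#'   independent across traits).
#' @param missing_prob Probability that a plot record is missing completely
#'   at random.
#' @param seed Integer RNG seed.
#' @return A `sim_params` list.
#' @export
simulation_params <- function(maternal = paste0("I", c(5, 6, 9, 10)),
                              paternal = paste0("I", 1:12),
                              locations = c("NE", "KS"),
                              blocks = 6,
                              traits = NULL,
                              mu = default_trait_means(),
                              varcomp = default_variance_components(),
                              genetic_cor = default_genetic_correlation(),
                              missing_prob = 0,
                              seed = 20190101L) {
  if (is.null(traits)) traits <- rownames(varcomp)
  p <- list(maternal = maternal, paternal = paternal, locations = locations,
            blocks = as.integer(blocks), traits = traits, mu = mu,
            varcomp = varcomp, genetic_cor = genetic_cor,
            missing_prob = missing_prob, seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

#' @keywords internal
validate_sim_params <- function(p) {
  stopifnot(length(p$maternal) >= 2, length(p$paternal) >= 2,
            length(p$locations) >= 1, p$blocks >= 1)
  if (!all(p$traits %in% rownames(p$varcomp)))
    stop("varcomp lacks rows for some traits", call. = FALSE)
  if (!all(p$traits %in% names(p$mu)))
    stop("mu lacks entries for some traits", call. = FALSE)
  comp <- c("mgca", "pgca", "sca", "location", "gxe", "error")
  if (!all(comp %in% colnames(p$varcomp)))
    stop("varcomp must have columns ", paste(comp, collapse = ", "),
         call. = FALSE)
  if (any(p$varcomp < 0)) stop("variance components must be >= 0", call. = FALSE)
  R <- p$genetic_cor[p$traits, p$traits, drop = FALSE]
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8))
    stop("genetic correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("genetic correlation matrix is not positive semidefinite",
         call. = FALSE)
  if (p$missing_prob < 0 || p$missing_prob >= 1)
    stop("missing_prob must lie in [0, 1)", call. = FALSE)
  p
}

#' Default per-trait grand means
#' @return Named numeric vector over the trait registry.
#' @export
default_trait_means <- function() {
  c(germination = 0.85, dap = 65, rot = 0.10, neh = 12, el = 14, nre = 14,
    ew = 46.6, ks = 67, vit = 5.5, gw100 = 12.5, pa = 0.95, ev = 42)
}

#' Default per-trait variance components
#'
#' Rows are traits, columns `mgca`, `pgca`, `sca`, `location`, `gxe`,
#' `error` on the plot basis (trait units squared).
#' @return Numeric matrix.
#' @export
default_variance_components <- function() {
  m <- rbind(
    germination = c(4e-4, 4e-4, 2e-4, 5e-4, 5e-4, 4e-3),
    dap         = c(0.5, 0.5, 0.3, 2, 0.5, 8),
    rot         = c(2e-4, 1e-4, 1e-4, 1e-4, 3e-4, 5e-3),
    neh         = c(0.2, 0.2, 0.2, 0.5, 0.6, 5),
    el          = c(1.2, 0.6, 0.6, 0.5, 0.3, 3),
    nre         = c(0.5, 0.3, 0.2, 0.2, 0.2, 2),
    ew          = c(30, 15, 15, 20, 10, 100),
    ks          = c(15, 8, 7, 5, 5, 60),
    vit         = c(0.01, 0.05, 0.02, 0.02, 0.05, 0.5),
    gw100       = c(1, 0.4, 0.3, 0.3, 0.5, 3),
    pa          = c(2e-5, 5e-5, 3e-5, 2e-5, 5e-5, 1e-3),
    ev          = c(600, 900, 500, 100, 200, 4000)
  )
  colnames(m) <- c("mgca", "pgca", "sca", "location", "gxe", "error")
  m
}

#' Default genetic correlation matrix across traits
#'
#' Built from a two-factor loading model (an "agronomic" and a "popcorn
#' quality" factor), which guarantees positive semidefiniteness and
#' reproduces the signature negative expansion-volume vs. yield-component
#' correlations alongside positive EV-vitreousness and EV-popability
#' correlations.
#' @return A 12 x 12 correlation matrix over the trait registry.
#' @export
default_genetic_correlation <- function() {
  L <- rbind(
    germination = c(0.3, 0),
    dap         = c(0, 0),
    rot         = c(-0.2, 0),
    neh         = c(0.4, 0),
    el          = c(0.7, -0.1),
    nre         = c(0.6, -0.2),
    ew          = c(0.8, -0.25),
    ks          = c(0.5, -0.3),
    vit         = c(-0.1, 0.5),
    gw100       = c(0.7, -0.3),
    pa          = c(0, 0.6),
    ev          = c(-0.3, 0.8)
  )
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(rownames(L), rownames(L))
  R
}

#' The 44 crosses of the default diallel, in standard numbering
#'
#' Hybrids are numbered in maternal order (I5, I6, I9, I10) and within each
#' maternal parent in paternal order I1..I12, selfs excluded.
#' @param maternal,paternal Parent id vectors.
#' @return Data frame with `hybrid_no`, `maternal`, `paternal`, `genotype`.
#' @export
default_crosses <- function(maternal = paste0("I", c(5, 6, 9, 10)),
                            paternal = paste0("I", 1:12)) {
  rows <- do.call(rbind, lapply(maternal, function(m) {
    pp <- setdiff(paternal, m)
    data.frame(maternal = m, paternal = pp, stringsAsFactors = FALSE)
  }))
  rows$hybrid_no <- seq_len(nrow(rows))
  rows$genotype <- hybrid_id(rows$maternal, rows$paternal)
  rows[, c("hybrid_no", "maternal", "paternal", "genotype")]
}

# Draw an n x T matrix of effects with cross-trait correlation R (applied
# through its eigen square root so PSD matrices with zero eigenvalues are
# accepted), per-trait variances v, exactly centered per column.
draw_effects <- function(n, v, R) {
  Tn <- length(v)
  Z <- matrix(stats::rnorm(n * Tn), n, Tn)
  e <- eigen(R, symmetric = TRUE)
  rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), Tn) %*% t(e$vectors)
  E <- Z %*% rt
  E <- sweep(E, 2, sqrt(v), "*")
  E <- sweep(E, 2, colMeans(E), "-")
  colnames(E) <- names(v)
  E
}

#' Simulate a multi-trait diallel field trial
#'
#' Each plot value is mu + g_m + g_p + s + location + (location x genotype)
#' + plot error, with GCA/SCA effects drawn jointly across traits from the
#' specified genetic correlation and centered to exact zero sum per role.
#' Proportion traits are truncated to [0, 1], the vitreousness score to
#' [1, 7] and counts to >= 0 (negligible at default magnitudes). Output is
#' bit-identical for identical seeds.
#'
#' @param params A `sim_params` object from [simulation_params()].
#' @return List with `fieldbook` (a [read_fieldbook()]-shaped data frame)
#'   and `truth` (class `true_effects`: `mgca`, `pgca`, `sca` effect
#'   matrices with traits in columns, `location` effects, `gxe` effects,
#'   `mu`, `varcomp`, and the `crosses` table).
#' @export
simulate_diallel_trial <- function(params = simulation_params()) {
  params <- validate_sim_params(params)
  set.seed(params$seed)
  tr <- params$traits
  R <- params$genetic_cor[tr, tr, drop = FALSE]
  vc <- params$varcomp[tr, , drop = FALSE]
  crosses <- default_crosses(params$maternal, params$paternal)
  nm <- length(params$maternal); np <- length(params$paternal)
  nc <- nrow(crosses); nl <- length(params$locations)

  vnamed <- function(col) stats::setNames(vc[, col], tr)
  mgca <- draw_effects(nm, vnamed("mgca"), R)
  rownames(mgca) <- params$maternal
  pgca <- draw_effects(np, vnamed("pgca"), R)
  rownames(pgca) <- params$paternal
  sca <- draw_effects(nc, vnamed("sca"), R)
  rownames(sca) <- crosses$genotype
  # environmental terms: independent across traits
  loc_eff <- draw_effects(nl, vnamed("location"), diag(length(tr)))
  rownames(loc_eff) <- params$locations
  gxe <- draw_effects(nl * nc, vnamed("gxe"), diag(length(tr)))
  rownames(gxe) <- paste(rep(params$locations, each = nc),
                         rep(crosses$genotype, nl), sep = ":")

  plots <- expand.grid(block = paste0("B", seq_len(params$blocks)),
                       cross = seq_len(nc),
                       location = params$locations,
                       stringsAsFactors = FALSE)
  ci <- plots$cross
  gi <- paste(plots$location, crosses$genotype[ci], sep = ":")
  reg <- trait_registry()
  out <- vector("list", length(tr))
  for (j in seq_along(tr)) {
    t1 <- tr[j]
    val <- params$mu[[t1]] +
      mgca[crosses$maternal[ci], j] +
      pgca[crosses$paternal[ci], j] +
      sca[ci, j] +
      loc_eff[plots$location, j] +
      gxe[gi, j] +
      stats::rnorm(nrow(plots), 0, sqrt(vc[t1, "error"]))
    kind <- reg$kind[match(t1, reg$name)]
    if (!is.na(kind)) {
      if (kind == "proportion") val <- pmin(pmax(val, 0), 1)
      if (kind == "score") val <- pmin(pmax(val, 1), 7)
      if (kind == "count") val <- pmax(val, 0)
    }
    out[[j]] <- data.frame(
      location = plots$location,
      block = plots$block,
      genotype = crosses$genotype[ci],
      maternal = crosses$maternal[ci],
      paternal = crosses$paternal[ci],
      trait = t1,
      value = val,
      stringsAsFactors = FALSE
    )
  }
  fb <- do.call(rbind, out)
  if (params$missing_prob > 0) {
    keep <- stats::runif(nrow(fb)) >= params$missing_prob
    fb <- fb[keep, , drop = FALSE]
  }
  rownames(fb) <- NULL
  class(fb) <- c("fieldbook", "data.frame")
  truth <- structure(list(mgca = mgca, pgca = pgca, sca = sca,
                          location = loc_eff, gxe = gxe,
                          mu = params$mu[tr], varcomp = vc,
                          crosses = crosses),
                     class = "true_effects")
  list(fieldbook = fb, truth = truth)
}

#' Simulate amino-acid profiles with a known inheritance-mode map
#'
#' For each residue the hybrid level is the mid-parent value (`additive`),
#' the high-parent value (`dominant`), or the high-parent value inflated by
#' `delta` (`over_dominant`), plus multiplicative Gaussian noise. Popped
#' treatments apply per-method multiplicative retention factors to the
#' generating level before noise.
#'
#' @param mode_map Named character vector, residue -> mode.
#' @param parent_levels Named list, residue -> numeric c(maternal, paternal)
#'   raw-kernel levels (g/100 g).
#' @param noise_sd Relative noise standard deviation (fraction of the
#'   generating level).
#' @param replicates Replicates per genotype/treatment.
#' @param seed Integer RNG seed.
#' @param delta Over-dominance inflation above the high parent.
#' @param retention Named numeric vector of per-method retention factors
#'   for the popped treatments.
#' @return An `amino_profile` data frame covering the hybrid and both
#'   parents, raw plus popped treatments.
#' @export
simulate_amino_profiles <- function(mode_map, parent_levels,
                                    noise_sd = 0.05, replicates = 6,
                                    seed = 1L, delta = 0.2,
                                    retention = c(air = 0.95,
                                                  microwave = 0.90,
                                                  oil = 0.85)) {
  bad <- !mode_map %in% c("additive", "dominant", "over_dominant")
  if (any(bad))
    stop("unknown inheritance mode label: ",
         paste(unique(mode_map[bad]), collapse = ", "), call. = FALSE)
  if (!all(names(mode_map) %in% names(parent_levels)))
    stop("parent_levels lacks entries for some residues", call. = FALSE)
  set.seed(as.integer(seed))
  recs <- list()
  for (res in names(mode_map)) {
    lv <- parent_levels[[res]]
    if (length(lv) != 2 || any(lv < 0))
      stop("parent levels must be two nonnegative values (", res, ")",
           call. = FALSE)
    hy <- switch(mode_map[[res]],
                 additive = mean(lv),
                 dominant = max(lv),
                 over_dominant = max(lv) * (1 + delta))
    frac <- if (tolower(res) %in% c("trp", "tryptophan", "cys", "cysteine"))
      "free" else "protein_bound"
    geno <- c(HYB = hy, MAT = lv[1], PAT = lv[2])
    cls <- c(HYB = "QPP_hybrid", MAT = "QPP_inbred", PAT = "QPP_inbred")
    for (g in names(geno)) {
      for (trtm in c("raw", names(retention))) {
        lev <- geno[[g]] * if (trtm == "raw") 1 else retention[[trtm]]
        val <- lev * (1 + stats::rnorm(replicates, 0, noise_sd))
        recs[[length(recs) + 1L]] <- data.frame(
          genotype = g, class = cls[[g]], residue = res, fraction = frac,
          treatment = trtm, replicate = seq_len(replicates),
          value = pmax(val, 0), stringsAsFactors = FALSE)
      }
    }
  }
  validate_amino_profiles(do.call(rbind, recs))
}

#' Default pedigree for the 12 quality-protein popcorn inbreds
#'
#' A synthetic reconstruction of the published pedigree structure: twelve
#' BC2F5 inbreds in six sib pairs of single-seed descent, derived from
#' three QPM donors (CML154Q, K0326Y, Tx807) crossed to four proprietary
#' popcorn parents (P1-P4), with popcorn parents P2 and P3 sharing one
#' heterotic pool. Inbreds I9/I10 are the CML154Q x P1 pair. Under the
#' standard 4 x 12 cross set this pedigree reproduces the published
#' category memberships: pseudo-self hybrids 5, 16, 31, 42 and same-pool
#' hybrids 3, 4, 10, 11, 14, 15, 21, 22.
#'
#' @return A `pedigree` data frame with 12 records.
#' @export
make_default_pedigree <- function() {
  ped <- data.frame(
    inbred = paste0("I", 1:12),
    qpm_parent = c("K0326Y", "K0326Y", "CML154Q", "CML154Q", "Tx807",
                   "Tx807", "K0326Y", "K0326Y", "CML154Q", "CML154Q",
                   "K0326Y", "K0326Y"),
    popcorn_parent = c("P4", "P4", "P3", "P3", "P2", "P2", "P2", "P2",
                       "P1", "P1", "P3", "P3"),
    heterotic_pool = c("PoolC", "PoolC", "PoolB", "PoolB", "PoolB", "PoolB",
                       "PoolB", "PoolB", "PoolA", "PoolA", "PoolB", "PoolB"),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}
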