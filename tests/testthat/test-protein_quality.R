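test_that("fold change arithmetic, symmetry and errors", {
  fc <- fold_change(rep(0.58, 4), rep(0.40, 4))
  expect_equal(fc$fold, 1.45)
  expect_equal(fold_change(1:5, 1:5)$fold, 1)
  expect_equal(fold_change(rep(0, 3), rep(2, 3))$fold, 0)
  # reciprocal symmetry for positive means
  set.seed(2)
  a <- runif(6, 1, 2); b <- runif(6, 2, 3)
  expect_equal(fold_change(a, b)$fold * fold_change(b, a)$fold, 1,
               tolerance = 1e-12)
  expect_error(fold_change(1:3, c(-2, 0, 2)), "reference mean")
  # delta-method SE: zero-variance groups give zero SE
  expect_equal(fold_change(rep(2, 4), rep(4, 4))$fold_se, 0)
})

test_that("lysine share of protein and dietary fractions", {
  expect_equal(lysine_percent_of_protein(0.558, 12), 4.65)
  expect_equal(lysine_percent_of_protein(0, 10), 0)
  expect_equal(lysine_percent_of_protein(10, 10), 100)
  expect_error(lysine_percent_of_protein(0.5, 0), "> 0")
  expect_equal(daily_requirement_fraction(0.40, 47, 2.108),
               100 * 0.40 / 100 * 47 / 2.108)
  expect_equal(daily_requirement_fraction(0, 47, 2.108), 0)
  expect_equal(daily_requirement_fraction(0.40, 94, 2.108),
               2 * daily_requirement_fraction(0.40, 47, 2.108))
  expect_error(daily_requirement_fraction(0.4, 47, 0), "requirement")
})

test_that("popping loss/retention identities", {
  pr <- popping_retention(0.0314, 0.0227)
  expect_equal(pr$loss, 0.0087)
  expect_equal(pr$retention, 100 * 0.0227 / 0.0314)
  expect_equal(pr$retention, 72.3, tolerance = 0.01)
  # exact identity retention/100 * raw + loss = raw
  expect_equal(pr$retention / 100 * 0.0314 + pr$loss, 0.0314,
               tolerance = 1e-15)
  same <- popping_retention(0.5, 0.5)
  expect_equal(same$loss, 0); expect_equal(same$retention, 100)
  gain <- popping_retention(0.5, 0.6)
  expect_true(gain$gain); expect_lt(gain$loss, 0)
  expect_gt(gain$retention, 100)
  expect_error(popping_retention(0, 0.1), "raw")
})

test_that("method correlations flag weakly consistent residues", {
  # construct genotype vectors with known correlation across treatments
  set.seed(5)
  n <- 12
  x <- rnorm(n)
  make_aa <- function(res, yvals) {
    rbind(
      data.frame(genotype = paste0("G", 1:n), class = "QPP_hybrid",
                 residue = res, fraction = "free", treatment = "raw",
                 replicate = 1, value = 5 + x),
      data.frame(genotype = paste0("G", 1:n), class = "QPP_hybrid",
                 residue = res, fraction = "free", treatment = "air",
                 replicate = 1, value = 5 + yvals))
  }
  # target r ~ 0.65 by rotation: y = r*x + sqrt(1-r^2)*z with z orthogonalized
  z <- residuals(lm(rnorm(n) ~ x)); z <- z / sd(z) * sd(x)
  r_target <- 0.65
  y_lo <- r_target * x + sqrt(1 - r_target^2) * z
  aa <- rbind(make_aa("Gly", y_lo), make_aa("Lys", x))
  aa$value <- aa$value - min(aa$value) + 0.01   # keep values nonnegative
  tab <- method_correlations(aa, fraction = "free")
  expect_equal(tab$r[tab$residue == "Lys"], 1, tolerance = 1e-12)
  expect_false(tab$flagged[tab$residue == "Lys"])
  expect_equal(tab$r[tab$residue == "Gly"], 0.65, tolerance = 0.02)
  expect_true(tab$flagged[tab$residue == "Gly"])
  # anti-correlated pair is flagged at r = -1
  aa2 <- make_aa("Val", -x)
  aa2$value <- aa2$value - min(aa2$value) + 0.01
  tab2 <- method_correlations(aa2, fraction = "free")
  expect_equal(tab2$r, -1, tolerance = 1e-12)
  expect_true(tab2$flagged)
  # <3 common genotypes -> pair skipped with warning
  expect_warning(expect_error(
    method_correlations(aa[aa$genotype %in% c("G1", "G2"), ],
                        fraction = "free"), "3 or more"), "skipped")
})

test_that("inheritance classifier nails clear-cut cases", {
  set.seed(6)
  mat <- rnorm(6, 0.30, 0.003); pat <- rnorm(6, 0.46, 0.003)
  mid <- (mean(mat) + mean(pat)) / 2
  add <- classify_inheritance(rnorm(6, mid, 0.003), mat, pat)
  expect_identical(add$call, "additive")
  over <- classify_inheritance(rnorm(6, 0.60, 0.003), mat, pat)
  expect_identical(over$call, "over_dominant")
  dom <- classify_inheritance(rnorm(6, 0.46, 0.003), mat, pat)
  expect_identical(dom$call, "dominant")
  # degenerate zero-variance exact ties -> ambiguous
  tie <- classify_inheritance(rep(0.4, 3), rep(0.4, 3), rep(0.4, 3))
  expect_identical(tie$call, "ambiguous")
  expect_error(classify_inheritance(0.4, rep(0.4, 3), rep(0.4, 3)),
               "2 replicates")
})

test_that("classifier recovers the generator's mode map at default noise", {
  modes <- c(Lys = "additive", His = "over_dominant", Glx = "dominant")
  levels <- list(Lys = c(0.30, 0.46), His = c(0.30, 0.40), Glx = c(2.0, 2.8))
  n_rep <- 150
  hits <- 0L; total <- 0L
  for (i in seq_len(n_rep)) {
    aa <- simulate_amino_profiles(modes, levels, noise_sd = 0.05,
                                  replicates = 6, seed = 1000 + i)
    raw <- aa[aa$treatment == "raw", ]
    for (res in names(modes)) {
      d <- raw[raw$residue == res, ]
      call <- classify_inheritance(d$value[d$genotype == "HYB"],
                                   d$value[d$genotype == "MAT"],
                                   d$value[d$genotype == "PAT"])$call
      hits <- hits + (call == modes[[res]])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
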