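toy_cells <- function(vals = c(10, 14, 12, 16)) {
  matrix(vals, 2, 2, dimnames = list(c("A", "B"), c("C", "D")))
}

test_that("cell means, marginals and grand mean match hand values", {
  fb <- make_diallel_fb(toy_cells(), reps = 1, loc_ids = "L1")
  cm <- hybrid_cell_means(fb, "el")
  expect_equal(cm$grand_mean, 13)
  expect_equal(unname(cm$maternal_means), c(11, 15))
  expect_equal(unname(cm$paternal_means), c(12, 14))
  expect_equal(cm$mean["A", "C"], 10)
  # single plot per cross => cell mean equals the plot value
  expect_equal(as.vector(cm$n), rep(1L, 4))
  expect_error(hybrid_cell_means(fb, "ev"), "no hybrid observations")
})

test_that("one missing cell is flagged and marginals use the rest", {
  Y <- toy_cells(); Y["A", "D"] <- NA
  fb <- make_diallel_fb(Y, reps = 2)
  cm <- hybrid_cell_means(fb, "el")
  expect_true(is.na(cm$mean["A", "D"]))
  expect_equal(unname(cm$maternal_means), c(10, 15))
  expect_equal(cm$grand_mean, mean(c(10, 14, 16)))
})

test_that("GCA/SCA reproduce the hand-computed toys", {
  cm <- hybrid_cell_means(make_diallel_fb(toy_cells(), reps = 1,
                                          loc_ids = "L1"), "el")
  mg <- estimate_gca(cm, "maternal"); pg <- estimate_gca(cm, "paternal")
  expect_equal(mg$effect, c(-2, 2))
  expect_equal(pg$effect, c(-1, 1))
  sca <- estimate_sca(cm, mg, pg)
  expect_equal(max(abs(sca)), 0, tolerance = 1e-12)  # purely additive table

  cm2 <- hybrid_cell_means(make_diallel_fb(toy_cells(c(10, 14, 13, 15)),
                                           reps = 1, loc_ids = "L1"), "el")
  mg2 <- estimate_gca(cm2, "maternal"); pg2 <- estimate_gca(cm2, "paternal")
  s2 <- estimate_sca(cm2, mg2, pg2)
  expect_equal(unclass(s2)[1, ], c(C = -0.5, D = 0.5))
  expect_equal(unclass(s2)[2, ], c(C = 0.5, D = -0.5))
})

test_that("all-equal cell means give all-zero effects", {
  cm <- hybrid_cell_means(make_diallel_fb(toy_cells(rep(7, 4)), reps = 2),
                          "el")
  expect_equal(estimate_gca(cm, "maternal")$effect, c(0, 0))
  expect_equal(estimate_gca(cm, "paternal")$effect, c(0, 0))
})

test_that("zero-sum, reconstruction and translation equivariance hold on the selfs-excluded factorial", {
  sim <- simulate_diallel_trial(simulation_params(seed = 123))
  fb <- sim$fieldbook
  for (shift in c(0, 100)) {
    fb2 <- fb; fb2$value <- fb2$value + shift
    cm <- hybrid_cell_means(fb2, "ew")
    mg <- estimate_gca(cm, "maternal"); pg <- estimate_gca(cm, "paternal")
    expect_lt(abs(sum(mg$effect)), 1e-10)
    expect_lt(abs(sum(pg$effect)), 1e-10)
    sca <- estimate_sca(cm, mg, pg)
    expect_lt(max(abs(rowSums(sca, na.rm = TRUE))), 1e-10)
    expect_lt(max(abs(colSums(sca, na.rm = TRUE))), 1e-10)
    rec <- attr(mg, "mu") + outer(mg$effect, pg$effect, "+") + unclass(sca)
    expect_equal(rec[!is.na(cm$mean)], cm$mean[!is.na(cm$mean)],
                 tolerance = 1e-10)
    if (shift == 0) {
      base_mg <- mg$effect; base_mu <- attr(mg, "mu")
    } else {
      expect_equal(mg$effect, base_mg, tolerance = 1e-9)
      expect_equal(attr(mg, "mu"), base_mu + shift, tolerance = 1e-9)
    }
  }
})

test_that("contrast SEs match a brute-force plot-level oracle", {
  set.seed(9)
  Y <- toy_cells()
  fb <- make_diallel_fb(Y, reps = 3, sd = 1, seed = 9)
  cm <- hybrid_cell_means(fb, "el")
  fit <- fit_gcbd_anova(fb, "hybrid", "el")
  s2 <- fit$sigma2_error
  se <- combining_se(fb, cm, "maternal")
  # oracle: g_A = mean(row A cells) - mean(all cells); each cell mean has
  # variance s2/n; propagate weights directly
  n <- cm$n
  w <- matrix(-1 / 4, 2, 2); w[1, ] <- w[1, ] + 1 / 2
  expect_equal(unname(se["A"]), sqrt(sum(w^2 * s2 / n)), tolerance = 1e-10)
  # SCA cell contrast oracle
  se_sca <- combining_se(fb, cm, "sca")
  w_sca <- matrix(1 / 4, 2, 2)
  w_sca[1, ] <- w_sca[1, ] - 1 / 2; w_sca[, 1] <- w_sca[, 1] - 1 / 2
  w_sca[1, 1] <- w_sca[1, 1] + 1
  expect_equal(unname(se_sca["AxC"]), sqrt(sum(w_sca^2 * s2 / n)),
               tolerance = 1e-10)
})

test_that("SE scaling: zero residual variance and 1/n behaviour", {
  Y <- toy_cells()
  fb0 <- make_diallel_fb(Y, reps = 2, sd = 0)
  cm0 <- hybrid_cell_means(fb0, "el")
  expect_equal(unname(combining_se(fb0, cm0, "paternal")), c(0, 0))
  fb1 <- make_diallel_fb(Y, reps = 3, sd = 1, seed = 4)
  fb2 <- make_diallel_fb(Y, reps = 6, sd = 1, seed = 4)
  cm1 <- hybrid_cell_means(fb1, "el"); cm2 <- hybrid_cell_means(fb2, "el")
  se1 <- combining_se(fb1, cm1, "maternal")
  se2 <- combining_se(fb2, cm2, "maternal")
  # with the residual variance held fixed, doubling replication halves
  # the squared SE: compare after rescaling by the two sigma2 estimates
  f1 <- fit_gcbd_anova(fb1, "hybrid", "el")$sigma2_error
  f2 <- fit_gcbd_anova(fb2, "hybrid", "el")$sigma2_error
  expect_equal(unname(se2["A"]^2 / f2), unname(se1["A"]^2 / f1 / 2),
               tolerance = 1e-10)
})

test_that("GCA requires at least two parents per role", {
  Y <- matrix(c(10, 12), 1, 2, dimnames = list("A", c("C", "D")))
  fb <- make_diallel_fb(Y, reps = 2)
  cm <- hybrid_cell_means(fb, "el")
  expect_error(estimate_gca(cm, "maternal"), "at least 2 parents")
})
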