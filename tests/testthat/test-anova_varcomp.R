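test_that("zero-noise data with no treatment effect gives SS_treatment 0", {
  fb <- make_balanced_fb(paste0("G", 1:4), c("L1", "L2"), 3,
                         loc_eff = c(L1 = -1, L2 = 1))
  fit <- fit_gcbd_anova(fb, "hybrid", "el")
  tab <- fit$table
  expect_equal(tab$ss[tab$term == "treatment"], 0, tolerance = 1e-10)
  expect_gt(tab$ss[tab$term == "location"], 0)
})

test_that("Type II SS match the brute-force oracle, balanced and unbalanced", {
  set.seed(31)
  for (rep in 1:5) {
    t_n <- sample(3:5, 1)
    fb <- make_balanced_fb(paste0("G", seq_len(t_n)), c("L1", "L2"), 3,
                           loc_eff = setNames(rnorm(2), c("L1", "L2")),
                           trt_eff = setNames(rnorm(t_n), paste0("G", seq_len(t_n))),
                           sd = 1)
    # unbalanced variant: drop one treatment entirely at one location,
    # plus a few random plots
    drop <- c(which(fb$genotype == "G1" & fb$location == "L2"),
              sample(nrow(fb), 2))
    for (d in list(fb, fb[-drop, ])) {
      fit <- fit_gcbd_anova(d, "hybrid", "el")
      oracle <- type2_oracle(d$location, d$genotype, d$value)
      got <- setNames(fit$table$ss, fit$table$term)
      for (term in c("location", "treatment", "residual"))
        expect_equal(got[[term]], oracle[[term]],
                     tolerance = 1e-8, label = term)
      expect_equal(got[["location:treatment"]], oracle[["interaction"]],
                   tolerance = 1e-8)
    }
  }
})

test_that("Type II equals Type I term-for-term under balance", {
  set.seed(77)
  for (rep in 1:5) {
    t_n <- sample(3:6, 1)
    fb <- make_balanced_fb(paste0("G", seq_len(t_n)), c("L1", "L2"), 3,
                           trt_eff = setNames(rnorm(t_n), paste0("G", seq_len(t_n))),
                           loc_eff = setNames(rnorm(2), c("L1", "L2")),
                           sd = 1)
    fit <- fit_gcbd_anova(fb, "hybrid", "el")
    seq_tab <- anova(lm(value ~ factor(location) * factor(genotype),
                        data = fb))           # Type I oracle
    expect_equal(fit$table$ss,
                 as.numeric(seq_tab[["Sum Sq"]]), tolerance = 1e-8)
    expect_equal(fit$table$df, as.numeric(seq_tab[["Df"]]))
  }
})

test_that("degenerate designs and thin data raise contract errors", {
  fb <- make_balanced_fb(paste0("G", 1:3), c("L1", "L2"), 2)
  expect_error(fit_gcbd_anova(fb[fb$location == "L1", ], "hybrid", "el"),
               "2 locations")
  one <- fb[fb$genotype == "G1", ]
  expect_error(fit_gcbd_anova(one, "hybrid", "el"), "treatment levels")
  # treatment perfectly confounded with location
  conf <- fb[(fb$genotype == "G1" & fb$location == "L1") |
             (fb$genotype == "G2" & fb$location == "L2"), ]
  expect_error(fit_gcbd_anova(conf, "hybrid", "el"), "confounded")
})

test_that("variance components invert a constructed mean-square table", {
  fb <- make_balanced_fb(paste0("G", 1:6), c("L1", "L2"), 4, sd = 1,
                         seed = 3)
  fit <- fit_gcbd_anova(fb, "hybrid", "el")
  # overwrite the MS column with values generated from known components
  s2t <- 2.5; s2i <- 1.5; s2e <- 0.75; n <- 4; L <- 2
  tab <- fit$table
  tab$ms[tab$term == "residual"] <- s2e
  tab$ms[tab$term == "location:treatment"] <- s2e + n * s2i
  tab$ms[tab$term == "treatment"] <- s2e + n * s2i + n * L * s2t
  fit$table <- tab
  vc <- variance_components(fit)
  expect_equal(vc$sigma2_treatment, s2t, tolerance = 1e-12)
  expect_equal(vc$sigma2_interaction, s2i, tolerance = 1e-12)
  expect_equal(vc$sigma2_error, s2e, tolerance = 1e-12)

  # MS_treatment = MS_interaction => zero treatment variance
  tab$ms[tab$term == "treatment"] <- s2e + n * s2i
  fit$table <- tab
  expect_equal(variance_components(fit)$sigma2_treatment, 0)

  # negative solution clipped with flag, pre-clip value retained
  tab$ms[tab$term == "treatment"] <- 0.1
  fit$table <- tab
  vc <- variance_components(fit)
  expect_equal(vc$sigma2_treatment, 0)
  expect_true(vc$clipped[["treatment"]])
  expect_lt(vc$preclip[["treatment"]], 0)
})

test_that("heritability is the plot-basis variance ratio", {
  base <- structure(list(sigma2_treatment = 1, sigma2_interaction = 1,
                         sigma2_error = 2, treatment_factor = "maternal",
                         trait = "el"), class = "variance_components")
  h <- heritability(base)
  expect_equal(h$ratio, 0.25)
  expect_identical(h$role, "maternal")
  base$sigma2_treatment <- 0
  expect_equal(heritability(base)$ratio, 0)
  base$sigma2_treatment <- 2; base$sigma2_interaction <- 0
  base$sigma2_error <- 0
  expect_equal(heritability(base)$ratio, 1)
  base$sigma2_treatment <- 0
  expect_error(heritability(base), "undefined")
})
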