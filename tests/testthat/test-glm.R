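test_that("noise-free forward-model data are recovered exactly", {
  d <- glm_design(n = 65, seed = 3)
  coefs <- default_coefs(interaction = -0.35)
  d$score <- simulate_behavior(d, coefs, noise_sd = 0)
  fit <- suppressWarnings(interaction_glm(d, "score", "e_glob", standardize = "predictors"))
  got <- coef(fit)
  expect_equal(unname(got["age"]), coefs[["age"]], tolerance = 1e-8)
  expect_equal(unname(got["E"]), coefs[["efficiency"]], tolerance = 1e-8)
  expect_equal(unname(got["sex"]), coefs[["sex"]], tolerance = 1e-8)
  expect_equal(unname(got["edu"]), coefs[["education"]], tolerance = 1e-8)
  expect_equal(unname(got["icv"]), coefs[["icv"]], tolerance = 1e-8)
  expect_equal(unname(got["morph"]), coefs[["morph"]], tolerance = 1e-8)
  expect_equal(unname(got["age:E"]), coefs[["interaction"]], tolerance = 1e-8)
  expect_equal(unname(got["(Intercept)"]), coefs[["intercept"]], tolerance = 1e-8)
})

test_that("degenerate designs are rejected informatively", {
  d <- glm_design(n = 30, seed = 4)
  d$score <- simulate_behavior(d, default_coefs(), noise_sd = 0.5, seed = 1)
  # collinear column: efficiency duplicated as morph covariate
  d2 <- d; d2$morph_global <- 2 * d2$e_glob
  d2 <- within(d2, score <- score)
  fit_err <- tryCatch(interaction_glm(d2, "score", "e_glob"), error = identity)
  expect_s3_class(fit_err, "error")
  expect_match(conditionMessage(fit_err), "collinear|zero variance")
  # zero-variance column
  d3 <- d; d3$education <- 12
  expect_error(interaction_glm(d3, "score", "e_glob"), "zero variance")
  # missing values must be handled by the caller
  d4 <- d; d4$score[3] <- NA
  expect_error(interaction_glm(d4, "score", "e_glob"), "missing values")
})

test_that("flipping the sex code changes only the sex coefficient's sign", {
  d <- glm_design(n = 50, seed = 5)
  d$score <- simulate_behavior(d, default_coefs(), noise_sd = 0.6, seed = 2)
  f1 <- interaction_glm(d, "score", "e_glob")
  d$sex <- 1 - d$sex
  f2 <- interaction_glm(d, "score", "e_glob")
  expect_equal(coef(f2)[["sex"]], -coef(f1)[["sex"]], tolerance = 1e-10)
  keep <- c("age", "E", "edu", "icv", "morph", "age:E")
  expect_equal(coef(f2)[keep], coef(f1)[keep], tolerance = 1e-10)
  expect_equal(f2$interaction$p, f1$interaction$p, tolerance = 1e-12)
})

test_that("fit methods behave like a classic model object", {
  d <- glm_design(n = 60, seed = 6)
  d$score <- simulate_behavior(d, default_coefs(), noise_sd = 0.6, seed = 3)
  fit <- interaction_glm(d, "score", "e_glob")
  expect_s3_class(fit, "interaction_fit")
  expect_output(print(fit), "interaction beta")
  expect_output(print(summary(fit)), "Estimate")
  expect_length(residuals(fit), 60)
  # predictions on the fitting data return the raw behavior scale
  pr <- predict(fit, newdata = d)
  expect_gt(cor(pr, d$score), 0.5)
  expect_equal(mean(pr), mean(d$score), tolerance = 1e-8)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sims), c(60, 2))
  # plot method draws without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("BH-FDR matches the worked example and the step-up oracle", {
  res <- fdr_bh(c(0.001, 0.01, 0.02, 0.4))
  expect_equal(res$q, c(0.004, 0.02, 0.0266667, 0.4), tolerance = 1e-4)
  expect_equal(sum(res$significant), 3L)
  # degenerate families
  expect_equal(fdr_bh(rep(1, 5))$significant, rep(FALSE, 5))
  expect_equal(fdr_bh(0.03)$q, 0.03)
  expect_length(fdr_bh(numeric(0))$q, 0L)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # random families against the step-up definition
  set.seed(321)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    res <- fdr_bh(p)
    expect_equal(res$q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(res$q >= p - 1e-15))
  }
})

test_that("leave-one-out refits once per subject and reports percentages", {
  d <- glm_design(n = 40, seed = 8)
  # strong noise-free interaction: significant in every fold
  d$score <- simulate_behavior(d, default_coefs(interaction = -0.5), noise_sd = 0)
  loo <- loo_reproducibility(d, "score", "e_glob")
  expect_equal(loo$n_folds, 40L)
  expect_length(loo$fold_p, 40L)
  expect_equal(loo$reproducibility_pct, 100)
  # with noise and an impossibly strict alpha no fold is significant
  d$score_noisy <- simulate_behavior(d, default_coefs(), noise_sd = 0.6, seed = 7)
  loo0 <- loo_reproducibility(d, "score_noisy", "e_glob", alpha = 1e-300)
  expect_equal(loo0$reproducibility_pct, 0)
  # noise-free folds all recover identical coefficients (full-sample fit)
  full <- suppressWarnings(interaction_glm(d, "score", "e_glob"))
  expect_true(all(abs(loo$fold_p - loo$fold_p[1]) < 1e-6))
  expect_lt(full$interaction$p, 1e-10)
})

test_that("the scan fits every metric/behavior family with FDR and LOO", {
  set.seed(12)
  d <- glm_design(n = 50, seed = 10)
  d$`e_nodal_A(lh)` <- rnorm(50)
  d$`e_nodal_B(rh)` <- rnorm(50)
  d$`e_local_A(lh)` <- rnorm(50)
  d$`e_local_B(rh)` <- rnorm(50)
  d$s1 <- simulate_behavior(d, default_coefs(interaction = -0.6), noise_sd = 0.3, seed = 4)
  d$s2 <- rnorm(50)
  res <- efficiency_interaction_scan(d, c("s1", "s2"), measure = "area",
                                     loo = "significant")
  # 2 global + 2 metrics x 2 parcels x 2 behaviors
  expect_equal(nrow(res), 2 + 8)
  expect_setequal(unique(res$metric), c("global", "nodal", "local"))
  # q-values are BH within each family
  glob <- res[res$metric == "global", ]
  expect_equal(glob$q, oracle_bh(glob$p), tolerance = 1e-12)
  nod_s1 <- res[res$metric == "nodal" & res$behavior == "s1", ]
  expect_equal(nod_s1$q, oracle_bh(nod_s1$p), tolerance = 1e-12)
  # the planted strong interaction is detected and has LOO attached
  hit <- res[res$metric == "global" & res$behavior == "s1", ]
  expect_true(hit$significant)
  expect_false(is.na(hit$reproducibility_pct))
  # non-significant rows skip LOO under loo = "significant"
  expect_true(all(is.na(res$reproducibility_pct[!res$significant])))
})

test_that("missing behavior values shrink the per-test sample size", {
  d <- glm_design(n = 45, seed = 13)
  d$score <- simulate_behavior(d, default_coefs(), noise_sd = 0.5, seed = 5)
  d$score[1:5] <- NA
  res <- efficiency_interaction_scan(d, "score", measure = "area", loo = "none")
  expect_equal(res$n, 40L)
})
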