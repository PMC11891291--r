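balanced_fit <- function() {
  G <- diag(2); rownames(G) <- colnames(G) <- c("a", "b")
  fit_emreml(c(1, 2, 3, 4), matrix(1, 4, 1, dimnames = list(NULL, "mu")),
             Z = c("a", "a", "b", "b"), G)
}

test_that("balanced one-way layout matches closed-form ANOVA-REML", {
  f <- balanced_fit()
  expect_true(f$converged)
  expect_equal(f$sigma2_e, 0.5, tolerance = 1e-6)
  expect_equal(f$sigma2_g, 1.75, tolerance = 1e-6)
})

test_that("REML log-likelihood trace is non-decreasing on every fit", {
  f1 <- balanced_fit()
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  co <- simulate_cohort(small_config(seed = 41))
  rel <- compute_grm(co$genotypes)
  f2 <- fit_model_suite(co$phenotypes, "synthetica", "GT", "1", rel)$all
  expect_true(all(diff(f2$loglik_trace) > -1e-8))
})

test_that("several balanced designs match closed-form components", {
  set.seed(5)
  for (rep in 1:3) {
    q <- 5; n_per <- 4
    y <- rnorm(q * n_per, rep(rnorm(q, sd = 2), each = n_per))
    acc <- rep(letters[1:q], each = n_per)
    G <- diag(q); rownames(G) <- colnames(G) <- letters[1:q]
    f <- fit_emreml(y, matrix(1, q * n_per, 1), acc, G)
    m <- tapply(y, acc, mean)
    msw <- sum((y - m[acc])^2) / (q * (n_per - 1))
    msb <- n_per * sum((m - mean(y))^2) / (q - 1)
    expect_equal(f$sigma2_e, msw, tolerance = 1e-6)
    expect_equal(f$sigma2_g, max((msb - msw) / n_per, 1e-8),
                 tolerance = 1e-5)
  }
})

test_that("EM fixed point attains the dense-matrix REML maximum", {
  set.seed(6)
  q <- 6; n <- 30
  cfg <- simulation_config(n_accessions = q, n_snps = 150, rng_seed = 8)
  G <- compute_grm(simulate_genotypes(cfg))$G
  ids <- rownames(G)
  acc <- sample(ids, n, replace = TRUE)
  X <- cbind(1, rnorm(n))
  g_true <- drop(crossprod(chol(bend_grm(G)), rnorm(q)))
  y <- X %*% c(2, 1) + g_true[match(acc, ids)] + rnorm(n, sd = 0.8)
  f <- fit_emreml(y, X, acc, G)
  Zm <- incidence(acc, ids)
  ll_em <- dense_reml_ll(f$sigma2_g, f$sigma2_e, y, X, Zm, G)
  opt <- optim(log(c(f$sigma2_g, f$sigma2_e)), function(lp)
    -dense_reml_ll(exp(lp[1]), exp(lp[2]), y, X, Zm, G),
    method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(ll_em - (-opt$value)), 1e-4)
  # and the engine's own log-likelihood agrees with the dense formula
  expect_equal(f$loglik, ll_em, tolerance = 1e-6)
})

test_that("gBLUPs match the direct matrix formula on a small instance", {
  set.seed(7)
  q <- 5; n <- 18
  cfg <- simulation_config(n_accessions = q, n_snps = 120, rng_seed = 9)
  G <- compute_grm(simulate_genotypes(cfg))$G
  ids <- rownames(G)
  acc <- sample(ids, n, replace = TRUE)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, 2) + drop(crossprod(chol(bend_grm(G)), rnorm(q)))[match(acc, ids)]
  f <- fit_emreml(y, X, acc, G)
  Zm <- incidence(acc, ids)
  Gb <- bend_grm(G)
  V <- f$sigma2_e * diag(n) + f$sigma2_g * Zm %*% Gb %*% t(Zm)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u_direct <- f$sigma2_g * Gb %*% t(Zm) %*% Vi %*% (y - X %*% beta)
  expect_equal(unname(extract_gblups(f)), unname(drop(u_direct)),
               tolerance = 1e-6)
})

test_that("accessions without phenotypes are predicted through G", {
  cfg <- simulation_config(n_accessions = 8, n_snps = 200, fst = 0.3,
                           k_pops = 2, rng_seed = 10)
  G <- compute_grm(simulate_genotypes(cfg))$G
  ids <- rownames(G)
  set.seed(8)
  obs_ids <- ids[1:6]
  acc <- rep(obs_ids, each = 5)
  g_true <- drop(crossprod(chol(bend_grm(G)), rnorm(8))) * 2
  y <- 3 + g_true[match(acc, ids)] + rnorm(length(acc), sd = 0.5)
  f <- fit_emreml(y, matrix(1, length(y), 1), acc, G)
  u <- extract_gblups(f)
  expect_length(u, 8)
  expect_true(all(is.finite(u[ids[7:8]])))
  # prediction is nontrivial: correlated with relatives' truth
  expect_gt(cor(u, g_true), 0.5)
})

test_that("noise-free fixed-effect data pins the residual at its bound", {
  G <- diag(3); rownames(G) <- colnames(G) <- letters[1:3]
  X <- cbind(1, c(0, 1, 2, 3, 4, 5))
  y <- drop(X %*% c(1, 2))
  f <- fit_emreml(y, X, rep(letters[1:3], 2), G)
  expect_true(f$boundary)
  expect_lt(f$sigma2_e, 1e-6)
  expect_equal(unname(f$gblups), rep(0, 3), tolerance = 1e-4)
})

test_that("pure-noise data rarely shows apparent heritability", {
  set.seed(11)
  G <- compute_grm(simulate_genotypes(
    simulation_config(n_accessions = 50, n_snps = 400, rng_seed = 12)))$G
  ids <- rownames(G)
  h2 <- replicate(20, {
    acc <- rep(ids, each = 10)
    y <- rnorm(length(acc))
    heritability(fit_emreml(y, matrix(1, length(y), 1), acc, G))
  })
  expect_gte(mean(h2 <= 0.05), 0.9)
})

test_that("heritability is the variance ratio with its boundary cases", {
  f <- balanced_fit()
  expect_equal(heritability(f), f$sigma2_g / (f$sigma2_g + f$sigma2_e))
  f$sigma2_g <- 1; f$sigma2_e <- 3; f$h2 <- 1 / 4
  expect_equal(heritability(f), 0.25)
  f$sigma2_g <- 0; f$h2 <- 0
  expect_equal(heritability(f), 0)
})

test_that("gBLUP variance is bounded by the shrinkage inequality", {
  co <- simulate_cohort(small_config(seed = 44))
  rel <- compute_grm(co$genotypes)
  f <- fit_model_suite(co$phenotypes, "synthetica", "GT", "1", rel)$all
  expect_lte(var(f$gblups), f$sigma2_g * max(diag(rel$G)) + 1e-8)
})

test_that("Wald Z-test matches the normal reference", {
  f <- balanced_fit()
  f$beta <- data.frame(term = c("x1", "x2"), estimate = c(1.96, 0),
                       se = c(1, 1))
  w <- wald_z_test(f, "x1")
  expect_equal(w$p, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_equal(wald_z_test(f, "x2")$p, 1)
  expect_error(wald_z_test(f, "absent"), "absent")
})

test_that("type contrast flips sign when labels are swapped", {
  co <- simulate_cohort(small_config(seed = 45))
  rel <- compute_grm(co$genotypes)
  f1 <- fit_gblup_model(co$phenotypes[co$phenotypes$germinated == 1, ],
                        "gt_hours", c("temperature", "type"), rel)
  sw <- co$phenotypes
  sw$type <- ifelse(sw$type == "wild", "landrace", "wild")
  f2 <- fit_gblup_model(sw[sw$germinated == 1, ], "gt_hours",
                        c("temperature", "type"), rel)
  z1 <- wald_z_test(f1, "typewild")$z
  z2 <- wald_z_test(f2, "typewild")$z
  expect_equal(sign(z1), -sign(z2))
  expect_equal(abs(z1), abs(z2), tolerance = 0.05)
})

test_that("Tukey q follows the k=2 studentized-range identity", {
  co <- simulate_cohort(small_config(seed = 46))
  rel <- compute_grm(co$genotypes)
  f <- fit_gblup_model(co$phenotypes[co$phenotypes$germinated == 1, ],
                       "gt_hours", c("temperature", "type"), rel)
  tk <- tukey_hsd(f, "type")
  expect_equal(tk$q, abs(tk$diff) / (tk$se_diff / sqrt(2)),
               tolerance = 1e-12)
  # for two levels the Tukey p equals the two-sided t-test on the contrast
  p_t <- 2 * pt(-abs(tk$diff / tk$se_diff), df = f$df_residual)
  expect_equal(tk$p, p_t, tolerance = 1e-6)
  # synthetic zero-difference contrast has p = 1
  f$beta$estimate[f$beta$term == "typewild"] <- 0
  tk0 <- tukey_hsd(f, "type")
  expect_equal(tk0$p, 1, tolerance = 1e-9)
  expect_error(tukey_hsd(f, "species"), "not found")
})

test_that("model suites produce the expected number of fits", {
  co <- simulate_cohort(small_config(seed = 47))
  rel <- compute_grm(co$genotypes)
  phen <- add_latent_residuals(co$phenotypes)
  expect_length(fit_model_suite(phen, "synthetica", "GT", "1", rel), 1)
  expect_length(fit_model_suite(phen, "synthetica", "GT", "1b", rel), 2)
  f1c <- fit_model_suite(phen, "synthetica", "GT", "1c", rel)
  expect_length(f1c, 4)
  f3d <- fit_model_suite(phen, "synthetica", "GRA", "3d", rel)$all
  n_countries <- length(unique(co$latitudes$country))
  expect_equal(sum(grepl("^warm:country", f3d$beta$term)), n_countries)
})

test_that("without GxE the per-temperature gBLUP rankings agree", {
  cfg <- simulation_config(n_accessions = 60, n_snps = 500,
                           seeds_per_cell = 50, ge_correlation = 1,
                           latitude_slope = 0, sigma2_g = 60, sigma2_e = 30,
                           rng_seed = 48)
  co <- simulate_cohort(cfg)
  rel <- compute_grm(co$genotypes)
  fits <- fit_model_suite(co$phenotypes, "synthetica", "GT", "1c", rel)
  ty <- stats::setNames(co$latitudes$type, co$latitudes$accession)
  cold <- pool_typewise_gblups(fits, ty, "cold")
  warm <- pool_typewise_gblups(fits, ty, "warm")
  acc <- intersect(names(cold), names(warm))
  expect_gt(cor(cold[acc], warm[acc], method = "spearman"), 0.95)
})

test_that("aliased fixed-effect columns are dropped with a message", {
  G <- diag(3); rownames(G) <- colnames(G) <- letters[1:3]
  X <- cbind(mu = 1, a = c(1, 0, 1, 0, 1, 0), b = c(0, 1, 0, 1, 0, 1))
  expect_message(
    f <- fit_emreml(rnorm(6), X, rep(letters[1:3], 2), G), "aliased")
  expect_equal(nrow(f$beta), 2)
})
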