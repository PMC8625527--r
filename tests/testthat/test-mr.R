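test_that("instrument selection applies a strict genome-wide threshold", {
  g <- tiny_gwas(beta = c(0.3, 0.2, 0.25), se = rep(0.02, 3),
                 pval = c(1e-9, 6e-8, 4.9e-8))
  kept <- select_instruments(g)
  expect_identical(kept$snp, g$snp[c(1, 3)])
  expect_warning(none <- select_instruments(
    tiny_gwas(beta = 0.1, se = 0.1, pval = 0.5)), "no instrument")
  expect_identical(nrow(none), 0L)
  expect_identical(nrow(select_instruments(g, threshold = 1.0)), 3L)
})

test_that("harmonization aligns, flips, complements and excludes correctly", {
  exp <- tiny_gwas(beta = c(0.1, 0.1, 0.1, 0.1), se = rep(0.01, 4),
                   ea = c("A", "A", "A", "A"), oa = c("G", "T", "G", "G"),
                   eaf = c(0.3, 0.5, 0.3, 0.3))
  out <- exp
  out$beta <- c(-0.05, 0.07, 0.02, 0.04)
  out$effect_allele <- c("G", "A", "T", "A")
  out$other_allele  <- c("A", "T", "C", "C")
  out$eaf <- c(0.7, 0.5, 0.3, 0.3)
  expect_message(h <- harmonize(exp, out), "excluded")
  # rs001: swapped alleles -> sign flip
  expect_equal(h$beta_out[h$snp == "rs001"], 0.05)
  expect_true(h$flipped[h$snp == "rs001"])
  expect_equal(h$eaf_out[h$snp == "rs001"], 0.3)
  # rs003: strand complement (T/C is A/G on the other strand) -> kept as is
  expect_equal(h$beta_out[h$snp == "rs003"], 0.02)
  expect_false(h$flipped[h$snp == "rs003"])
  excl <- attr(h, "excluded")
  # rs002: palindromic with EAF 0.5 -> ambiguous
  expect_identical(excl$reason[excl$snp == "rs002"], "ambiguous palindromic")
  # rs004: A/C cannot match A/G on either strand
  expect_identical(excl$reason[excl$snp == "rs004"], "allele mismatch")
  # no shared rsIDs is an error
  out2 <- out; out2$snp <- paste0("x", out2$snp)
  expect_error(harmonize(exp, out2), "no shared instruments")
})

test_that("harmonization of already-harmonized tables is the identity", {
  sim <- simulate_gwas_pair(gwas_sim_config(theta = 0.2, seed = 21,
                                            maf_range = c(0.1, 0.4)))
  h1 <- suppressMessages(harmonize(sim$exposure, sim$outcome))
  # re-express the harmonized outcome on the exposure's alleles and rerun
  out2 <- sim$outcome[match(h1$snp, sim$outcome$snp), ]
  out2$effect_allele <- h1$effect_allele
  out2$other_allele <- h1$other_allele
  out2$beta <- h1$beta_out
  out2$eaf <- h1$eaf_out
  h2 <- harmonize(sim$exposure, out2)
  expect_identical(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))
})

test_that("Wald ratio follows the first-order delta method", {
  p <- make_pairs(beta_exp = 0.1, beta_out = 0.05, se_out = 0.01)
  wr <- wald_ratio(p)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(make_pairs(-0.2, 0, 0.01))$beta, 0)
  expect_error(wald_ratio(make_pairs(0, 0.1, 0.01)), "beta_exp = 0")
})

test_that("IVW reproduces the worked two-SNP example and its Q", {
  p <- make_pairs(beta_exp = c(0.1, 0.2), beta_out = c(0.05, 0.08),
                  se_out = c(0.01, 0.02))
  est <- ivw_estimate(p, model = "fixed")
  expect_equal(est$beta, 0.45, tolerance = 1e-12)
  q <- cochran_q(p)
  expect_equal(q$q_stat, 0.5, tolerance = 1e-12)
  expect_identical(q$df, 1L)
  # homogeneous ratios: beta = c and Q = 0, p = 1
  ph <- make_pairs(beta_exp = c(0.1, 0.2, 0.4),
                   beta_out = 0.3 * c(0.1, 0.2, 0.4),
                   se_out = c(0.01, 0.02, 0.01))
  esth <- ivw_estimate(ph)
  expect_equal(esth$beta, 0.3, tolerance = 1e-12)
  expect_equal(attr(esth, "Q"), 0, tolerance = 1e-12)
  expect_equal(cochran_q(ph)$p_value, 1)
  # doubling every weight doubles Q (halve se_out by sqrt(2))
  p2 <- p; p2$se_out <- p$se_out / sqrt(2)
  expect_equal(cochran_q(p2, center = 0.45)$q_stat,
               2 * cochran_q(p, center = 0.45)$q_stat, tolerance = 1e-12)
  expect_error(ivw_estimate(p[1, ]), ">= 2")
  expect_error(cochran_q(p[1, ]), ">= 2")
  # relaxed single-instrument mode degenerates to the Wald ratio
  single <- ivw_estimate(p[1, ], allow_single = TRUE)
  expect_equal(single$beta, 0.5)
  expect_equal(single$se, 0.1)
})

test_that("IVW weighted mean equals weighted regression through the origin", {
  for (seed in 1:20) {
    p <- random_pairs(15, seed)
    est <- ivw_estimate(p, model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = p, weights = 1 / p$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
    # fixed-effect SE is the regression SE divided by the residual scale
    sm <- summary(fit)
    expect_equal(est$se, unname(sm$coefficients[1, 2] / sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the stated rule and is reproducible", {
  p <- make_pairs(beta_exp = c(1, 1, 1), beta_out = c(0.1, 0.2, 0.3),
                  se_out = c(0.1, 0.1, 0.1))
  wm <- weighted_median_estimate(p, n_boot = 50, seed = 4)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)  # p_2 = 0.5 exactly
  wm2 <- weighted_median_estimate(p, n_boot = 50, seed = 4)
  expect_identical(wm$se, wm2$se)
  # all ratios equal c -> estimate c
  pc <- make_pairs(beta_exp = c(0.1, 0.2, 0.3), beta_out = 0.4 * c(0.1, 0.2, 0.3),
                   se_out = c(0.01, 0.03, 0.02))
  expect_equal(weighted_median_estimate(pc, n_boot = 20, seed = 1)$beta, 0.4,
               tolerance = 1e-12)
  expect_error(weighted_median_estimate(p[1:2, ]), ">= 3")
  # unequal weights: hand evaluation of the interpolation
  pu <- make_pairs(beta_exp = c(1, 2, 1), beta_out = c(0.1, 0.4, 0.3),
                   se_out = c(0.1, 0.1, 0.1))
  w <- c(1, 4, 1) / 6
  # sorted ratios 0.1, 0.2, 0.3 with weights 1/6, 4/6, 1/6
  pk <- cumsum(w) - w / 2  # 1/12, 1/2 ... second position hits 0.5
  expect_equal(weighted_median_estimate(pu, n_boot = 20, seed = 1)$beta, 0.2)
})

test_that("Egger recovers exact linear and affine relations", {
  x <- seq(0.1, 0.5, 0.1)
  p <- make_pairs(beta_exp = x, beta_out = 0.3 * x, se_out = rep(0.01, 5))
  eg <- egger_estimate(p)
  expect_equal(eg$estimate$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$pleiotropy$intercept, 0, tolerance = 1e-10)
  pa <- make_pairs(beta_exp = x, beta_out = 0.02 + 0.3 * x,
                   se_out = rep(0.01, 5))
  ega <- egger_estimate(pa)
  expect_equal(ega$estimate$beta, 0.3, tolerance = 1e-10)
  expect_equal(ega$pleiotropy$intercept, 0.02, tolerance = 1e-10)
  expect_error(egger_estimate(p[1:2, ]), ">= 3")
  pconst <- make_pairs(beta_exp = rep(0.2, 4), beta_out = rnorm(4),
                       se_out = rep(0.01, 4))
  expect_error(egger_estimate(pconst), "not identifiable")
})

test_that("Egger equals the weighted-least-squares oracle on random data", {
  for (seed in 1:20) {
    p <- random_pairs(12, seed + 100)
    eg <- egger_estimate(p)
    s <- ifelse(p$beta_exp < 0, -1, 1)
    fit <- lm(I(s * beta_out) ~ I(s * beta_exp), data = p,
              weights = 1 / p$se_out^2)
    expect_equal(eg$pleiotropy$intercept, unname(coef(fit)[1]),
                 tolerance = 1e-10)
    expect_equal(eg$estimate$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    sm <- summary(fit)
    if (sm$sigma > 1) {  # above the floor our SEs match lm exactly
      expect_equal(eg$estimate$se, unname(sm$coefficients[2, 2]),
                   tolerance = 1e-10)
      expect_equal(eg$pleiotropy$se, unname(sm$coefficients[1, 2]),
                   tolerance = 1e-10)
      expect_equal(eg$pleiotropy$p_value,
                   unname(sm$coefficients[1, 4]), tolerance = 1e-10)
    }
  }
})

test_that("leave-one-out is exhaustive, ordered, and isolates outliers", {
  pc <- make_pairs(beta_exp = c(0.1, 0.2, 0.3, 0.4),
                   beta_out = 0.25 * c(0.1, 0.2, 0.3, 0.4),
                   se_out = rep(0.01, 4))
  loo <- leave_one_out(pc)
  expect_identical(loo$excluded_snp, pc$snp)
  expect_equal(loo$beta, rep(0.25, 4), tolerance = 1e-12)
  # one planted outlier: the record excluding it sits closest to the bulk
  po <- make_pairs(beta_exp = rep(0.2, 5),
                   beta_out = 0.2 * c(0.3, 0.31, 0.29, 0.3, 3.0),
                   se_out = rep(0.01, 5))
  loo_o <- leave_one_out(po)
  dev <- abs(loo_o$beta - median(po$beta_out / po$beta_exp))
  expect_identical(which.min(dev), 5L)
  expect_error(leave_one_out(pc[1:2, ]), ">= 3")
})

test_that("odds-ratio conversion is exp with a 95% Wald interval", {
  expect_equal(to_odds_ratio(0, 1)$or, 1)
  o <- to_odds_ratio(0.1655, 0.02)
  expect_equal(o$or, 1.18, tolerance = 0.005)
  expect_true(o$ci_low < o$or && o$or < o$ci_high)
  expect_equal(o$ci_low, exp(0.1655 - 1.96 * 0.02), tolerance = 1e-12)
  expect_error(to_odds_ratio(0.1, 0), "se must be > 0")
  # MrEstimate invariants hold on a fitted object
  est <- ivw_estimate(make_pairs(c(0.1, 0.2), c(0.05, 0.08), c(0.01, 0.02)))
  expect_equal(est$odds_ratio, exp(est$beta))
  expect_equal(est$ci_low, exp(est$beta - 1.96 * est$se))
})

test_that("estimates are equivariant to exposure scale and allele flips", {
  sim <- simulate_gwas_pair(gwas_sim_config(theta = 0.25, seed = 31,
                                            frac_palindromic = 0))
  h <- harmonize(sim$exposure, sim$outcome)
  k <- 2.5
  hk <- h; hk$beta_exp <- k * h$beta_exp; hk$se_exp <- k * h$se_exp
  expect_equal(ivw_estimate(hk)$beta, ivw_estimate(h)$beta / k,
               tolerance = 1e-12)
  expect_equal(egger_estimate(hk)$estimate$beta,
               egger_estimate(h)$estimate$beta / k, tolerance = 1e-10)
  wm_k <- weighted_median_estimate(hk, n_boot = 50, seed = 6)
  wm_1 <- weighted_median_estimate(h, n_boot = 50, seed = 6)
  expect_equal(wm_k$beta, wm_1$beta / k, tolerance = 1e-12)
  expect_equal(wm_k$se, wm_1$se / k, tolerance = 1e-12)
  # flipping every outcome record (swap alleles, negate beta, complement
  # EAF) leaves the harmonized effects bit-identical
  flip <- sim$outcome
  flip$effect_allele <- sim$outcome$other_allele
  flip$other_allele <- sim$outcome$effect_allele
  flip$beta <- -sim$outcome$beta
  flip$eaf <- 1 - sim$outcome$eaf
  hf <- harmonize(sim$exposure, flip)
  expect_identical(hf$beta_out, h$beta_out)
  expect_identical(ivw_estimate(hf)$beta, ivw_estimate(h)$beta)
})

test_that("two-step mediation multiplies the IVW betas and names failures", {
  tri <- simulate_gwas_triplet(
    gwas_sim_config(theta = 0.4, seed = 41, frac_palindromic = 0),
    gwas_sim_config(theta = 0.5, seed = 42, frac_palindromic = 0))
  ts <- run_two_step(tri$exposure, tri$mediator, tri$outcome,
                     n_boot = 50, seed = 2)
  b1 <- ts$step1$estimates$beta[ts$step1$estimates$method == "ivw"]
  b2 <- ts$step2$estimates$beta[ts$step2$estimates$method == "ivw"]
  expect_equal(ts$mediated_effect, b1 * b2, tolerance = 1e-12)
  expect_named(ts$pleiotropy_flags, c("step1", "step2"))
  # no shared rsIDs between mediator instruments and the outcome table
  tri0 <- simulate_gwas_triplet(
    gwas_sim_config(theta = 0.4, seed = 41, frac_palindromic = 0),
    gwas_sim_config(theta = 0.5, seed = 42, frac_palindromic = 0),
    shared_snps = 0)
  expect_error(run_two_step(tri0$exposure, tri0$mediator, tri0$outcome),
               "step 2.*no shared instruments")
})
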