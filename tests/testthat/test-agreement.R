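test_that("regression metrics follow their definitions", {
  obs <- c(100, 200); est <- c(110, 190)
  m <- regression_metrics(obs, est)
  expect_equal(m$rmse, 10)
  expect_equal(m$bias, 0)
  expect_equal(m$rrmse, 100 * 10 / 150)
  expect_equal(m$re, mean((obs - est) / est))

  id <- regression_metrics(1:10 * 10, 1:10 * 10)
  expect_equal(id$rmse, 0)
  expect_equal(id$bias, 0)
  expect_equal(id$re, 0)
  expect_equal(id$r_squared, 1)
  expect_equal(id$rrmse, 0)

  expect_error(regression_metrics(c(1, 1), c(1, 1.0001)), "undefined")
  expect_error(regression_metrics(c(1, 2), c(1, 0)), "undefined")
})

test_that("rRMSE reproduces printed worked examples and is scale invariant", {
  expect_equal(round(relative_rmse(6.49, 148.62), 2), 4.37)
  set.seed(40)
  obs <- runif(30, 50, 400); est <- obs + rnorm(30, 0, 20)
  r1 <- regression_metrics(obs, est)$rrmse
  r2 <- regression_metrics(7.3 * obs, 7.3 * est)$rrmse
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Bland-Altman limits bracket the mean difference at 1.96 s", {
  ba <- bland_altman(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)       # sample (n - 1) denominator
  expect_equal(ba$uloa, 1.96)
  expect_equal(ba$lloa, -1.96)

  idba <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(c(idba$mean_diff, idba$sd_diff, idba$uloa, idba$lloa),
               c(0, 0, 0, 0))

  # direction convention
  ba2 <- bland_altman(c(10, 10), c(8, 9),
                      agreement_conventions(diff_direction = "obs_minus_est"))
  expect_equal(ba2$mean_diff, 1.5)

  set.seed(41)
  obs <- runif(50, 10, 100); est <- obs + rnorm(50, -2, 5)
  ba3 <- bland_altman(obs, est)
  expect_equal(ba3$uloa - ba3$lloa, 3.92 * ba3$sd_diff)
  expect_equal(ba3$pairs$diff, est - obs)
})

test_that("the concordance correlation matches hand evaluation", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  # rho = 1, population variances 2/3, mean gap 1 -> 2*(2/3)/(4/3 + 1) = 4/7
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  x <- c(1, 2, 3); y <- 2 * x
  n <- 3
  vx <- var(x) * (n - 1) / n; vy <- var(y) * (n - 1) / n
  sxy <- cov(x, y) * (n - 1) / n
  direct <- 2 * sxy / (vx + vy + (mean(x) - mean(y))^2)
  expect_equal(ccc(x, y), direct)
  expect_lt(ccc(x, y), 1)
  expect_error(ccc(c(1, 1), c(1, 2)), "zero variance")
})

test_that("|CCC| never exceeds |Pearson correlation|", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15, 10, 3)
    y <- 0.5 * x + rnorm(15, i / 5, 2)
    expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  # equality iff equal means and variances: construct by exact standardisation
  x <- rnorm(12)
  y0 <- rnorm(12)
  y <- (y0 - mean(y0)) / sd(y0) * sd(x) + mean(x)
  expect_equal(ccc(x, y), cor(x, y))
})

test_that("gauge repeatability decomposes variance components", {
  expect_equal(grr(rbind(c(5, 5, 5), c(9, 9, 9)))$grr_percent, 0)
  expect_equal(grr(rbind(c(4, 6, 5), c(6, 4, 5)))$grr_percent, 100)
  expect_error(grr(list(c(1, 2))), "2 parts")
  expect_error(grr(list(c(1, 2), 3)), "2 replicate")

  # simulation recovery: sigma2_parts = 9, sigma2_repeat = 1 -> GRR = 10%.
  # With only 10 parts the between-part variance estimate is noisy and the
  # ratio estimator carries a finite-sample upward bias of about +2 points,
  # so recovery is asserted within that sampling behaviour.
  set.seed(43)
  g <- replicate(500, {
    truth <- rnorm(10, 100, 3)
    reps <- matrix(rnorm(30, rep(truth, each = 3), 1), nrow = 10, byrow = TRUE)
    grr(reps)$grr_percent
  })
  expect_lt(abs(mean(g) - 10), 2.5)
  expect_lt(abs(median(g) - 10), 2.5)
})

test_that("Kruskal-Wallis matches the reference implementation", {
  for (groups in list(list(c(1, 2, 3), c(4, 5, 6)),
                      list(c(1.2, 5.3, 2), c(4, 4, 6, 8), c(0.5, 9, 3, 3)),
                      list(rnorm(10), rnorm(8, 1), rnorm(12, -0.4)))) {
    kw <- kruskal_wallis(groups)
    ref <- kruskal.test(unlist(groups),
                        factor(rep(seq_along(groups), lengths(groups))))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(kruskal_wallis(list(c(3, 1, 4)))$H, 0)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("Kruskal-Wallis H is invariant to monotone transforms", {
  set.seed(44)
  groups <- list(rnorm(9), rnorm(7, 0.5), rnorm(11, -0.2))
  h0 <- kruskal_wallis(groups)$H
  for (f in list(exp, function(x) x^3, function(x) atan(x) * 5 + 2)) {
    expect_equal(kruskal_wallis(lapply(groups, f))$H, h0, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U follows the rank-sum formula and exact law", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U1, 4)     # R1 = 3, U = 4 + 3 - 3
  expect_equal(mw$U, 0)

  # identical groups: null centre, tie fallback
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(mw2$p, 0.99)

  # U1 + U2 = n1 n2
  set.seed(45)
  g1 <- rnorm(7); g2 <- rnorm(9)
  u1 <- mann_whitney_u(g1, g2)$U1
  u2 <- mann_whitney_u(g2, g1)$U1
  expect_equal(u1 + u2, 63)

  # exact p equals the 70-arrangement enumeration for n1 = n2 = 4
  for (i in 1:5) {
    g1 <- sample(seq(1, 100), 4); g2 <- sample(seq(101, 200) + 0.5, 4)
    g <- sample(c(g1, g2)); g1 <- g[1:4]; g2 <- g[5:8]
    mw3 <- mann_whitney_u(g1, g2)
    expect_equal(mw3$method, "exact")
    expect_equal(mw3$p, mwu_enum_p(g1, g2), tolerance = 1e-12)
  }
})

test_that("build_report assembles overall, per-species and test blocks", {
  tab <- generate_paired_dataset(seed = 46)
  rep <- build_report(tab)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$n, 123L)
  expect_length(rep$per_species, 4L)
  expect_true(is.finite(rep$kw$H))
  expect_equal(nrow(rep$pairwise), 6L)
  expect_true(all(rep$pairwise$p_holm >= rep$pairwise$p))
  expect_equal(rep$overall$uloa - rep$overall$lloa,
               3.92 * rep$overall$sd_diff)
  js <- report_to_json(rep)
  expect_true(jsonlite::validate(js))

  # identity estimates: all error metrics collapse, KW degenerate
  tab2 <- tab
  tab2$estimated_volume <- tab2$reference_volume
  rep2 <- build_report(tab2)
  expect_equal(rep2$overall$rmse, 0)
  expect_equal(rep2$overall$ccc, 1)
  expect_false(is.finite(rep2$kw$H))

  # species with one sample: skipped per-species, kept overall
  tab3 <- rbind(tab, tab[1, ])
  tab3$species[nrow(tab3)] <- "singleton"
  expect_warning(rep3 <- build_report(tab3), "singleton")
  expect_equal(rep3$n, 124L)
  expect_length(rep3$per_species, 4L)
})
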