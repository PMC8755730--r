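test_that("one-way ANOVA matches the direct sums-of-squares oracle", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      k <- sample(2:5, 1)
      groups <- lapply(seq_len(k), function(i)
        rnorm(sample(2:8, 1), mean = runif(1, 0, 10)))
      names(groups) <- paste0("g", seq_len(k))
      res <- suppressWarnings(one_way_anova(groups))
      expect_equal(res$F, oracle_anova_F(groups), tolerance = 1e-9)
      N <- length(unlist(groups))
      expect_identical(unname(res$df), c(k - 1L, N - k))
    }
  })
  ## the fixed worked case
  fixed <- list(a = c(1, 2), b = c(2, 3), c = c(3, 4))
  expect_equal(suppressWarnings(one_way_anova(fixed))$F,
               oracle_anova_F(fixed), tolerance = 1e-12)
})

test_that("ANOVA handles degenerate and small-group inputs per contract", {
  same <- replicate(4, c(1, 2, 3), simplify = FALSE)
  res <- one_way_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  four <- replicate(4, rnorm(6), simplify = FALSE)
  expect_identical(unname(one_way_anova(four)$df), c(3L, 20L))

  bad <- list(a = rnorm(3), b = 1)
  expect_error(one_way_anova(bad), "b")
  expect_warning(one_way_anova(list(a = c(1, 2), b = c(2, 4), c = c(3, 6))),
                 "n = 2")
})

test_that("summary-statistics ANOVA is an exact identity with the raw-data ANOVA", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      k <- sample(2:5, 1)
      ns <- sample(2:9, k, replace = TRUE)
      groups <- lapply(ns, function(n) rnorm(n, runif(1, 0, 5)))
      raw <- suppressWarnings(one_way_anova(groups))
      summ <- anova_from_summary(
        means = vapply(groups, mean, numeric(1)),
        sds = vapply(groups, sd, numeric(1)),
        ns = ns)
      expect_equal(summ$F, raw$F, tolerance = 1e-9)
      expect_equal(summ$p, raw$p, tolerance = 1e-9)
      ## ...and via SEMs
      summ2 <- anova_from_summary(
        means = vapply(groups, mean, numeric(1)),
        sems = vapply(groups, function(g) sd(g) / sqrt(length(g)),
                      numeric(1)),
        ns = ns)
      expect_equal(summ2$F, raw$F, tolerance = 1e-9)
    }
  })
})

test_that("with two groups F equals the squared equal-variance t statistic", {
  withr::with_seed(33, {
    for (rep in 1:8) {
      a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
      F <- one_way_anova(list(a, b))$F
      t <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(F, unname(t$statistic)^2, tolerance = 1e-9)
      expect_equal(one_way_anova(list(a, b))$p, t$p.value, tolerance = 1e-9)
    }
  })
})

test_that("F critical values reproduce the figure-legend constants", {
  expect_equal(f_critical(0.05, 3, 20), 3.098, tolerance = 1e-3)
  expect_equal(f_critical(0.05, 3, 9), 3.862, tolerance = 1e-3)
  ## chi-square(1) limit for one numerator df
  expect_equal(f_critical(0.05, 1, 1e7), qchisq(0.95, 1), tolerance = 1e-4)
  expect_error(f_critical(1.2, 3, 20), "alpha")
  expect_error(f_critical(0.05, 0, 20), "freedom")
})

test_that("Welch t-test follows its formula and symmetry", {
  a <- c(5.1, 4.8, 5.6, 5.0); b <- c(6.2, 5.9, 6.8)
  res <- welch_t(a, b)
  ## direct formula evaluation
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  t_direct <- (mean(a) - mean(b)) / se
  df_direct <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                         (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(res$t, t_direct, tolerance = 1e-9)
  expect_equal(res$df, df_direct, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(t_direct), df_direct), tolerance = 1e-9)

  swapped <- welch_t(b, a)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  ident <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$p, 1)
  expect_error(welch_t(1, c(1, 2)), "length")
})

test_that("simple regression reports slope, r and the slope p-value", {
  x <- c(1, 2, 3, 4, 5)
  res <- linreg(x, -x)
  expect_equal(res$r, -1)
  expect_equal(res$slope, -1, tolerance = 1e-12)

  ## three-point closed form
  r3 <- linreg(c(0, 1, 2), c(1, 3, 4))
  expect_equal(r3$slope, 1.5, tolerance = 1e-12)
  expect_equal(r3$intercept, 7 / 6, tolerance = 1e-9)  # ybar - slope * xbar

  expect_error(linreg(c(1, 1, 1), c(1, 2, 3)), "constant")
  withr::with_seed(17, {
    fit <- linreg(x, -2 * x + rnorm(5, 0, 0.5))
    expect_identical(sign(fit$slope), sign(fit$r))
  })

  ## permutation null: |r| stays small at large n
  withr::with_seed(5, {
    x <- rnorm(500)
    y <- sample(x)
    expect_lt(abs(linreg(x, y)$r), 0.15)
  })
})

test_that("fucosylation and sialylation of simulated O-glycomes are negatively correlated", {
  libO <- builtin_glycan_library("O")
  design <- data.frame(group = "CTX", template = "cortexO", n = 10)
  coh <- simulate_cohort(design, config = sim_config(), seed = 19)
  m <- spectra_category_matrix(coh$spectra, libO)
  res <- linreg(m[, "fucose"], m[, "NeuAc"])
  expect_lt(res$r, 0)
})

test_that("the category summary table mirrors the published layout", {
  withr::with_seed(11, {
    mk <- function(shift = 0)
      cbind(`high-mannose` = rnorm(6, 60 + shift, 1),
            fucose = rnorm(6, 35, 1))
    tab <- summary_table(list(CTX = mk(), CBLM = mk(10)))
    expect_setequal(tab$category, c("high-mannose", "fucose"))
    hm <- tab[tab$category == "high-mannose", ]
    expect_true(hm$significant)
    expect_identical(hm$stars, "***")
    expect_false(tab$significant[tab$category == "fucose"])
    ## significance flag is consistent between F and p
    expect_identical(tab$F > tab$F_crit, tab$p < 0.05)

    single <- summary_table(list(CTX = mk()))
    expect_false("F" %in% names(single))
    expect_true(all(c("CTX_mean", "CTX_sem") %in% names(single)))

    bh <- summary_table(list(CTX = mk(), CBLM = mk(10)), adjust = "BH")
    expect_true(all(bh$p_adj >= bh$p - 1e-12))
  })
})
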