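test_that("log-likelihood is the multinomial kernel over all trees", {
  m <- mpt_model("only")
  # empty data contribute nothing
  expect_equal(log_likelihood(m, c(0.5, 0.5, 0.5, 0.5),
                              single_condition_data(cp = c(0, 0, 0))), 0)
  # certain detection, all mass on the observed cell: ln 1 = 0
  expect_equal(log_likelihood(m, c(1, 0.5, 0.5, 0.5),
                              single_condition_data(cp = c(5, 0, 0))), 0)
  # hand arithmetic on one culprit-present tree
  cc <- 0.16667
  m_cc <- mpt_model("only", guess_split = cc)
  ll <- log_likelihood(m_cc, c(0, 0.9, 0, 0.5),
                       single_condition_data(cp = c(1, 1, 1)))
  expect_equal(ll, log(0.5 * cc) + log(0.5 * (1 - cc)) + log(0.5),
               tolerance = 1e-12)
  expect_equal(ll, log(0.083335) + log(0.416665) + log(0.5), tolerance = 1e-9)
  # impossible cell with positive count
  expect_equal(log_likelihood(m, c(1, 0.5, 0.5, 0.5),
                              single_condition_data(cp = c(5, 1, 0))), -Inf)
})

test_that("saturated models reproduce observed proportions with G2 = 0", {
  # datasets inside the model's range: expected counts (integer-rounded)
  # under interior parameter values, where the four free parameters can
  # reach the observed proportions exactly
  interior <- list(c(dP = 0.30, dA = 0.10, b = 0.06, g = 0.44),
                   c(dP = 0.15, dA = 0.30, b = 0.12, g = 0.60),
                   c(dP = 0.55, dA = 0.05, b = 0.03, g = 0.25))
  m <- mpt_model("only")
  for (pars in interior) {
    cp <- round(2000 * category_probs(pars, "culprit_present"))
    ca <- round(2000 * category_probs(pars, "culprit_absent"))
    dat <- single_condition_data(cp = cp, ca = ca)
    fit <- fit_mpt(m, dat)
    expect_equal(fit$df, 0L)
    expect_lt(fit$G2, 1e-8)
    expect_equal(fit$p_value, 1)
    for (tree in c("culprit_present", "culprit_absent")) {
      n <- dat$count[dat$lineup_type == tree]
      expect_lt(max(abs(fit$fitted[[paste0("only.", tree)]] - n / sum(n))),
                1e-6)
    }
  }
})

test_that("zero degrees of freedom does not guarantee a perfect fit outside the model's range", {
  # with the guessing split fixed, the four free parameters cannot reach
  # every point of the observed simplex pair: this table's exact solution
  # lies outside the unit box, so the boundary MLE keeps G2 > 0 at df = 0
  dat <- single_condition_data(cp = c(284, 180, 300), ca = c(108, 257, 399))
  fit <- suppressWarnings(fit_mpt(mpt_model("only"), dat))
  expect_equal(fit$df, 0L)
  expect_gt(fit$G2, 0.1)
  expect_true(any(fit$boundary))
})

test_that("optimizer matches a brute-force grid search on single-tree problems", {
  m <- mpt_model("only", fixed = list(b = 0, dA = 0.5))
  for (counts in list(c(30, 30, 40), c(5, 80, 15), c(60, 10, 30))) {
    dat <- single_condition_data(cp = counts)
    fit <- fit_mpt(m, dat, se = FALSE)
    oracle <- grid_search_cp(counts, b = 0, cc = m$guess_split)
    expect_equal(unname(fit$estimates["only", "dP"]), oracle$dP,
                 tolerance = 1e-3)
    expect_equal(unname(fit$estimates["only", "g"]), oracle$g,
                 tolerance = 1e-3)
    expect_equal(fit$log_likelihood, oracle$ll, tolerance = 1e-6)
  }
})

test_that("degrees of freedom follow the cells - trees - parameters convention", {
  m2 <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  expect_equal(mpt_df(m2, exp1_frequencies()), 2L)
  m4 <- mpt_model(c("combined_three", "separate_three", "combined_one",
                    "separate_one"), equal = list(b = "all", dA = "all"))
  expect_equal(mpt_df(m4, exp2_frequencies()), 6L)
  expect_equal(mpt_df(mpt_model("only"),
                      single_condition_data(cp = c(1, 1, 1), ca = c(1, 1, 1))),
               0L)
  # a lone culprit-present tree cannot identify four free parameters
  expect_error(mpt_df(mpt_model("only"), single_condition_data(cp = c(1, 1, 1))),
               "overparameterized")
})

test_that("chi-square p-values cover the saturated and null edge cases", {
  expect_equal(gof_p_value(0, 3), 1)
  expect_equal(gof_p_value(5.12, 0), 1)  # saturated: p defined as 1
  expect_equal(gof_p_value(5.12, 2),
               stats::pchisq(5.12, 2, lower.tail = FALSE))
})

test_that("refits from distinct start seeds agree to 1e-8 in log-likelihood", {
  m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  dat <- exp1_frequencies()
  lls <- vapply(1:10, function(s)
    fit_mpt(m, dat, n_starts = 3, start_seed = s, se = FALSE)$log_likelihood,
    numeric(1))
  expect_lt(diff(range(lls)), 1e-8)
  fit <- fit_mpt(m, dat)
  expect_true(fit$converged)
  expect_lt(fit$start_loglik_spread, 1e-6)
})

test_that("estimates recover the truth at very large samples", {
  d <- exp1_design()
  m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  big <- d$design
  big$n_participants <- 500000L  # 1e6 responses per tree
  dat <- simulate_responses(d$truth, big, seed = 99)
  fit <- fit_mpt(m, dat, se = FALSE)
  expect_lt(max(abs(fit$estimates - d$truth[rownames(fit$estimates), ])),
            0.005)
})

test_that("standard errors shrink as 1/sqrt(N) and flag singular information", {
  m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  dat <- exp1_frequencies()
  fit1 <- fit_mpt(m, dat)
  dat4 <- dat
  dat4$count <- dat$count * 4L
  fit4 <- fit_mpt(m, frequency_data(dat4))
  expect_equal(unname(fit4$theta_se), unname(fit1$theta_se) / 2,
               tolerance = 0.05)
  # dA is unidentified when no culprit-absent tree is observed: the
  # information matrix has an exactly-zero row, and SEs must degrade to NA
  # with a warning rather than a failed fit
  cp_only <- single_condition_data(cp = c(30, 30, 40))
  expect_warning(
    se_flat <- standard_errors(mpt_model("only"), cp_only,
                               c(0.3, 0.5, 0.2, 0.4)),
    "singular")
  expect_true(all(is.na(se_flat)))
})

test_that("fit validates data/model agreement and degenerate inputs", {
  m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
  only_one <- single_condition_data(cp = c(1, 1, 1), condition = "combined")
  expect_error(fit_mpt(m, only_one), "no counts for condition")
  extra <- rbind(as.data.frame(exp1_frequencies()),
                 data.frame(condition = "ghost", lineup_type = "culprit_absent",
                            response = "filler", count = 1L))
  expect_error(fit_mpt(m, extra), "absent from the model")
  # zero-count cells are tolerated and contribute nothing to G2
  dat0 <- single_condition_data(cp = c(50, 0, 50), ca = c(10, 40, 50),
                                condition = "only")
  f0 <- suppressWarnings(fit_mpt(mpt_model("only"), dat0, se = FALSE))
  expect_true(is.finite(f0$G2) && f0$G2 >= 0)
})
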