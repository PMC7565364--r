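# Kaplan-Meier, log-rank, Cox regression, Martingale residuals and the
# signature expression categories.

test_that("Kaplan-Meier matches the product-limit arithmetic", {
  km <- kaplan_meier(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(km$step$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)          # first time S <= 0.5
  expect_true(km$median_reached)

  cens <- kaplan_meier(data.frame(time = c(5, 7, 9), event = 0))
  expect_true(all(cens$step$surv == 1))
  expect_false(cens$median_reached)
  expect_true(is.na(cens$median))

  # without censoring the KM curve is the empirical survival function
  withr_seed(3)
  t <- round(rexp(40, 0.1), 2)
  km2 <- kaplan_meier(data.frame(time = t, event = 1))
  emp <- vapply(km2$step$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$step$surv, emp, tolerance = 1e-12)

  expect_error(kaplan_meier(data.frame(time = c(0, 1), event = c(1, 1))),
               "> 0")
})

test_that("log-rank test is symmetric and null on identical groups", {
  rec <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  same <- logrank_test(rec, rec)
  expect_equal(same$chisq, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)

  withr_seed(5)
  a <- data.frame(time = rexp(30, 0.1), event = rbinom(30, 1, 0.8))
  b <- data.frame(time = rexp(30, 0.2), event = rbinom(30, 1, 0.8))
  expect_equal(logrank_test(a, b)[c("chisq", "p")],
               logrank_test(b, a)[c("chisq", "p")])
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)), "no events")
})

test_that("Cox score test equals the log-rank statistic for binary groups", {
  withr_seed(8)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    grp <- sample(rep(c("A", "B"), length.out = n))
    time <- rexp(n, ifelse(grp == "A", 0.08, 0.12)) + runif(n, 0, 1e-4)
    event <- rbinom(n, 1, 0.85)
    if (sum(event) == 0) next
    rec <- data.frame(time = time, event = event, grp = grp)
    lr <- logrank_test(rec[rec$grp == "A", ], rec[rec$grp == "B", ])
    cf <- cox_fit(rec, "grp")
    expect_equal(cf$score_chisq, lr$chisq, tolerance = 1e-6)
  }
})

test_that("Cox fit recovers a known hazard ratio and reports Wald CIs", {
  withr_seed(12)
  hrs <- replicate(100, {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, log(2) / 20 * 2^x)          # true HR = 2 for group B
    cens <- runif(n, 0, 55)
    rec <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
                      grp = ifelse(x == 1, "B", "A"))
    cox_fit(rec, "grp")$coefficients$hr[1]
  })
  expect_gte(mean(hrs), 2 * 0.925)
  expect_lte(mean(hrs), 2 * 1.075)

  rec <- data.frame(time = rexp(200, 0.05), event = 1,
                    grp = sample(rep(c("A", "B"), 100)))
  cf <- cox_fit(rec, "grp")
  expect_true(cf$converged)
  expect_false(cf$separation)
  expect_true(cf$coefficients$ci_lower < cf$coefficients$hr &
                cf$coefficients$hr < cf$coefficients$ci_upper)
  expect_true(all(cf$coefficients$hr > 0))
})

test_that("a covariate independent of survival is rarely flagged", {
  withr_seed(19)
  ok <- replicate(100, {
    n <- 300
    rec <- data.frame(time = rexp(n, 0.07), event = rbinom(n, 1, 0.7),
                      grp = sample(rep(c("A", "B"), n / 2)))
    co <- cox_fit(rec, "grp")$coefficients
    se <- (log(co$ci_upper) - log(co$hr)) / 1.96
    abs(co$beta) < 2 * se
  })
  expect_gte(sum(ok), 93)
})

test_that("reference levels order the Cox coefficients", {
  withr_seed(4)
  rec <- data.frame(time = rexp(120, 0.1), event = 1,
                    grade = sample(c("G2", "G3", "G4"), 120, TRUE))
  cf <- cox_fit(rec, "grade", reference_levels = list(grade = "G2"))
  expect_identical(cf$coefficients$term, c("gradeG3", "gradeG4"))
  cf2 <- cox_fit(rec, "grade", reference_levels = list(grade = "G4"))
  expect_identical(cf2$coefficients$term, c("gradeG2", "gradeG3"))
  expect_error(cox_fit(rec, "grade", reference_levels = list(grade = "G9")),
               "not observed")
  expect_error(cox_fit(rec, "nope"), "not in records")
})

test_that("monotone likelihood is flagged as separation", {
  rec <- data.frame(time = c(1:10, 21:30), event = 1,
                    grp = rep(c("early", "late"), each = 10))
  expect_warning(cf <- cox_fit(rec, "grp"), "separation")
  expect_true(cf$separation)
})

test_that("null-model Martingale residuals follow Nelson-Aalen arithmetic", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 0))
  # H = 1/4 at t=1; +1/2 at t=3
  expect_equal(martingale_residuals_null(rec),
               c(1 - 0.25, -0.25, 1 - 0.75, -0.75), tolerance = 1e-12)

  withr_seed(6)
  rec2 <- data.frame(time = round(rexp(100, 0.1), 1) + 0.1,
                     event = rbinom(100, 1, 0.7))
  r <- martingale_residuals_null(rec2)
  expect_equal(sum(r), 0, tolerance = 1e-9)
  oracle <- residuals(survival::coxph(survival::Surv(time, event) ~ 1,
                                      data = rec2, ties = "breslow"),
                      type = "martingale")
  expect_equal(r, unname(oracle), tolerance = 1e-9)
})

test_that("signature expression categories follow tertile x median binning", {
  withr_seed(10)
  e1 <- runif(300); e2 <- runif(300)
  cat6 <- categorize_signature_expression(e1, e2, c("SIG1", "SIG2"))
  expect_length(levels(cat6), 6)
  t1 <- table(sub("-.*", "", cat6))
  expect_true(all(abs(t1 - 100) <= 1))
  t2 <- table(sub(".*-", "", cat6))
  expect_true(all(abs(t2 - 150) <= 1))

  # value exactly at a threshold goes to the lower bin
  ref <- list(gene1 = c(1, 2, 3, 4, 5, 6), gene2 = c(1, 2, 3, 4))
  q <- stats::quantile(ref$gene1, 1 / 3, names = FALSE)
  catx <- categorize_signature_expression(c(q, q + 1e-9), c(2.5, 2.5),
                                          c("a", "b"), reference = ref)
  expect_identical(as.character(catx), c("a_low-b_low", "a_medium-b_low"))

  expect_error(categorize_signature_expression(rep(1, 10), runif(10)),
               "degenerate")
  expect_error(categorize_signature_expression(1:3, 1:4), "same samples")
})
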