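test_that("confusion matrices tally evaluations by direct count", {
  evals <- data.frame(
    patient_id = letters[1:10], tool = "t",
    eligible = TRUE,
    flagged = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
    outcome_cancer_12m = c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  cm <- confusion_from_evaluations(evals)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1L, 2L, 1L, 6L))
  # all flagged, all outcome
  all_pos <- transform(evals, flagged = TRUE, outcome_cancer_12m = TRUE)
  cm2 <- confusion_from_evaluations(all_pos)
  expect_identical(c(cm2$fp, cm2$fn, cm2$tn), c(0L, 0L, 0L))
  expect_error(confusion_from_evaluations(evals[0, ]), "no evaluations")
  expect_error(confusion_from_evaluations(transform(evals, tool = letters[1:10])),
               "mix")
  # ineligible rows are excluded from the tally
  evals$eligible[1] <- FALSE
  expect_identical(confusion_from_evaluations(evals)$tp, 0L)
})

test_that("PPV reproduces the published arithmetic from printed counts", {
  expect_equal(round(100 * ppv(confusion_matrix(102, 7330, 135, 100))$estimate, 2),
               1.37)
  expect_equal(round(100 * ppv(confusion_matrix(105, 10322, 136, 100))$estimate, 2),
               1.01)
  expect_equal(round(100 * ppv(confusion_matrix(30, 3702, 186, 100))$estimate, 2),
               0.80)
})

test_that("binomial_ci matches independent oracles and is reflective", {
  # Clopper-Pearson against the beta-quantile oracle and binom.test
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    got <- binomial_ci(x, n)
    expect_equal(unname(got), cp_oracle(x, n), tolerance = 1e-12)
    bt <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(got), as.numeric(bt), tolerance = 1e-9)
    # reflection: ci(x, n) = 1 - reverse(ci(n - x, n))
    refl <- binomial_ci(n - x, n)
    expect_equal(unname(got), 1 - unname(rev(refl)), tolerance = 1e-12)
  }
  expect_identical(unname(binomial_ci(0, 10)[1]), 0)
  expect_identical(unname(binomial_ci(10, 10)[2]), 1)
  expect_error(binomial_ci(5, 0), "n > 0")
  expect_error(binomial_ci(11, 10), "successes")
  # alternative methods stay ordered around the point estimate
  for (m in c("wilson", "wald")) {
    ci <- binomial_ci(102, 7432, method = m)
    expect_true(ci[1] <= 102 / 7432 && 102 / 7432 <= ci[2])
  }
})

test_that("Clopper-Pearson is the method that reproduces the printed interval", {
  cp <- 100 * binomial_ci(102, 7432)
  expect_equal(round(unname(cp), 2), c(1.12, 1.66))
  wil <- 100 * binomial_ci(102, 7432, method = "wilson")
  expect_false(isTRUE(all.equal(round(unname(wil), 2), c(1.12, 1.66))))
})

test_that("likelihood ratios follow the identities and the log-method CI", {
  lr <- lr_estimates(0.4304, 0.9605)
  expect_equal(round(unname(lr["lr_plus"]), 1), 10.9)
  expect_equal(round(unname(lr["lr_minus"]), 2), 0.59)
  # CI from a concrete matrix: hand log-method computation
  cm <- confusion_matrix(102, 7330, 135, 178370)
  lrs <- likelihood_ratios(cm)
  sens <- 102 / 237; spec <- 178370 / 185700
  expect_equal(lrs$lr_plus$estimate, sens / (1 - spec))
  se <- sqrt(1 / 102 - 1 / 237 + 1 / 7330 - 1 / 185700)
  expect_equal(lrs$lr_plus$ci_low,
               lrs$lr_plus$estimate * exp(-qnorm(0.975) * se))
  # degenerate cases yield markers
  perfect <- likelihood_ratios(confusion_matrix(10, 0, 0, 10))
  expect_true(is.na(perfect$lr_plus$estimate))
  expect_identical(perfect$lr_minus$estimate, 0)
})

test_that("statistic invariants hold and extra TPs help", {
  cm <- confusion_matrix(5, 20, 3, 72)
  expect_equal(accuracy(cm)$estimate, (5 + 72) / 100)
  for (f in list(ppv, npv, sensitivity, specificity, accuracy)) {
    st <- f(cm)
    expect_true(st$ci_low <= st$estimate && st$estimate <= st$ci_high)
    expect_true(st$estimate >= 0 && st$estimate <= 1)
  }
  cm2 <- confusion_matrix(6, 20, 3, 72)
  expect_gt(ppv(cm2)$estimate, ppv(cm)$estimate)
  expect_gt(sensitivity(cm2)$estimate, sensitivity(cm)$estimate)
  # ppv on (x, n - x) equals the plain binomial point estimate
  expect_equal(ppv(confusion_matrix(7, 13, 0, 0))$estimate, 7 / 20)
  # zero denominator: marker, not error
  expect_true(is.na(ppv(confusion_matrix(0, 0, 3, 7))$estimate))
})

test_that("Clopper-Pearson coverage at p = 0.013 is at least nominal", {
  set.seed(2024)
  p <- 0.013
  n <- 5000
  draws <- rbinom(2000, n, p)
  covered <- vapply(draws, function(x) {
    ci <- binomial_ci(x, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("per-symptom PPV counts presenters and outcomes directly", {
  tls <- c(
    lapply(1:2, function(i) mk_timeline("2012-01-01", "jaundice",
                                        dx = "2012-06-01",
                                        id = paste0("c", i))),
    lapply(1:98, function(i) mk_timeline("2012-01-01", "jaundice",
                                         id = paste0("n", i)))
  )
  st <- per_symptom_ppv(tls, "jaundice")
  expect_equal(st$estimate, 0.02)
  expect_identical(attr(st, "n"), 100L)
  expect_true(is.na(per_symptom_ppv(tls, "vte")$estimate))
  all_pos <- lapply(1:3, function(i) mk_timeline("2012-01-01", "uwl",
                                                 dx = "2012-03-01",
                                                 id = paste0("p", i)))
  expect_equal(per_symptom_ppv(all_pos, "uwl")$estimate, 1)
  # diagnosis beyond follow-up does not count
  late <- list(mk_timeline("2012-01-01", "uwl", dx = "2014-01-01"))
  expect_equal(per_symptom_ppv(late, "uwl")$estimate, 0)
})

test_that("group comparison tests behave and match a permutation oracle", {
  flat <- matrix(c(50, 50, 50, 50), 2)
  expect_equal(compare_proportions(flat)$statistic, 0)
  x <- c(1, 2, 3, 4, 5)
  expect_gt(compare_distributions(x, x)$p_value, 0.99)
  expect_true(is.na(compare_proportions(matrix(c(0, 0, 5, 5), 2))$statistic))

  # chi-square p-value vs permutation null on a small table
  set.seed(88)
  a <- rbinom(40, 1, 0.6) == 1
  b <- rbinom(35, 1, 0.3) == 1
  obs <- compare_proportions(a, b)
  pooled <- c(a, b)
  na <- length(a)
  perm_stat <- replicate(1e5, {
    idx <- sample.int(length(pooled), na)
    pa <- pooled[idx]; pb <- pooled[-idx]
    ea <- c(sum(pa), sum(!pa)); eb <- c(sum(pb), sum(!pb))
    tab <- rbind(ea, eb)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  })
  p_perm <- mean(perm_stat >= obs$statistic - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(obs$p_value - p_perm), max(5 * se, 0.02))
})
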