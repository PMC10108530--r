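toy_matrix <- function() {
  # 10 genomes x 3 modules with a hand-tallied occurrence pattern
  mat <- rbind(
    c(1.00, 0.80, 0.20), c(0.90, 0.75, 0.10), c(0.80, 0.40, 0.00),
    c(1.00, 0.90, 0.74), c(0.75, 0.60, 0.30),
    c(0.20, 0.80, 0.90), c(0.10, 0.75, 1.00), c(0.00, 0.70, 0.80),
    c(0.30, 0.90, 0.76), c(0.25, 0.50, 0.75))
  dimnames(mat) <- list(paste0("g", 1:10),
                        c("M00001", "M00002", "M00003"))
  mat
}

toy_groups <- function() {
  stats::setNames(rep(c("good", "poor"), each = 5), paste0("g", 1:10))
}

test_that("module occurrence counts match a hand tally (inclusive 0.75)", {
  occ <- module_occurrence(toy_matrix(), toy_groups())
  get <- function(m, g) occ$n_present[occ$module_id == m & occ$group == g]
  expect_equal(get("M00001", "good"), 5L) # 0.75 counts as present
  expect_equal(get("M00001", "poor"), 0L)
  expect_equal(get("M00002", "good"), 3L)
  expect_equal(get("M00002", "poor"), 3L)
  expect_equal(get("M00003", "good"), 0L)
  expect_equal(get("M00003", "poor"), 5L)
  expect_true(all(occ$n_total == 5L))
  expect_error(module_occurrence(toy_matrix(), toy_groups()[-1]),
               "without group")
})

test_that("the Rao score statistic has its closed-form values", {
  r <- rao_score_test(c(10, 0), c(10, 10))
  expect_equal(r$score, 20)
  expect_equal(r$p_value, 7.7e-6, tolerance = 1e-2)
  expect_equal(rao_score_test(c(5, 5), c(10, 10))$score, 0)
  expect_equal(rao_score_test(c(5, 5), c(10, 10))$p_value, 1)
  # zero-variance rows return (0, 1) rather than NaN
  expect_equal(rao_score_test(c(10, 10), c(10, 10)),
               list(score = 0, p_value = 1, df = 1L))
  expect_equal(rao_score_test(c(0, 0), c(10, 10))$p_value, 1)
  expect_error(rao_score_test(5, 10), "at least 2 groups")
  expect_error(rao_score_test(c(11, 0), c(10, 10)), "n_present")
})

test_that("for two groups the score equals Pearson chi-square", {
  set.seed(5)
  for (i in 1:300) {
    n <- sample(3:40, 2, replace = TRUE)
    k <- c(rbinom(1, n[1], runif(1)), rbinom(1, n[2], runif(1)))
    r <- rao_score_test(k, n)
    tab <- rbind(k, n - k)
    if (sum(k) == 0 || sum(k) == sum(n)) {
      expect_equal(r$score, 0)
    } else {
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_lt(abs(r$score - unname(cs$statistic)), 1e-9)
      expect_equal(r$p_value, unname(cs$p.value), tolerance = 1e-12)
    }
  }
})

test_that("the score agrees with a binomial-GLM Rao score test", {
  cases <- list(list(k = c(9, 2), n = c(12, 11)),
                list(k = c(15, 14), n = c(20, 20)),
                list(k = c(3, 9, 1), n = c(10, 12, 8)))
  for (cs in cases) {
    g <- factor(seq_along(cs$k))
    fit0 <- stats::glm(cbind(cs$k, cs$n - cs$k) ~ 1, family = binomial())
    fit1 <- stats::glm(cbind(cs$k, cs$n - cs$k) ~ g, family = binomial())
    rao <- stats::anova(fit0, fit1, test = "Rao")$Rao[2]
    # agreement to the IRLS convergence tolerance of glm
    expect_equal(rao_score_test(cs$k, cs$n)$score, rao, tolerance = 1e-4)
  }
})

test_that("the score is invariant under group relabeling", {
  set.seed(6)
  for (i in 1:50) {
    n <- sample(5:30, 3, replace = TRUE)
    k <- rbinom(3, n, 0.4)
    perm <- sample(3)
    expect_equal(rao_score_test(k, n)$score,
                 rao_score_test(k[perm], n[perm])$score)
  }
})

test_that("BH q-values match hand computation and stay ordered", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("enrichment combines the q, completeness and presence criteria", {
  res <- enrichment_test(toy_matrix(), toy_groups())
  expect_equal(nrow(res), 3)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$enrichment_score >= 0))
  m1 <- res[res$module_id == "M00001", ]
  expect_equal(m1$associated_groups, "good")
  expect_true(m1$enriched)
  expect_false(res$enriched[res$module_id == "M00002"])
  sets <- enriched_modules(res, toy_matrix(), toy_groups())
  expect_equal(sets$good, "M00001")
  expect_equal(sets$poor, "M00003")
})

test_that("enrichment boundaries are strict for q, inclusive for presence", {
  rows <- data.frame(module_id = "M00001", enrichment_score = 5,
                     p_value = 0.01, q_value = 0.05,
                     associated_groups = "good",
                     proportion_good = 0.8, proportion_poor = 0.1,
                     mean_completeness_good = 0.9,
                     mean_completeness_poor = 0.2,
                     stringsAsFactors = FALSE)
  mat <- toy_matrix()[, "M00001", drop = FALSE]
  # q exactly at the cutoff is not enriched ("less than 0.05")
  expect_length(enriched_modules(rows, mat, toy_groups())$good, 0)
  rows$q_value <- 0.049
  expect_equal(enriched_modules(rows, mat, toy_groups())$good, "M00001")
  rows$proportion_good <- 0.4 # below the 50% group-presence criterion
  expect_length(enriched_modules(rows, mat, toy_groups())$good, 0)
})
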