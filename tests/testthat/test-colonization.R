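test_that("subpopulation filtering applies the 1% and coverage rules", {
  prof <- data.frame(genome_id = "G1", subpop_id = c("s1", "s2", "s3"),
                     sample_id = "S1", proportion = c(0.985, 0.005, 0.01),
                     stringsAsFactors = FALSE)
  out <- filter_subpopulations(prof)
  # below 1% dropped, exactly 1% retained ("less than 1%" rule)
  expect_setequal(out$subpop_id, c("s1", "s3"))

  cov_ok <- matrix(FALSE, 1, 1, dimnames = list("G1", "S1"))
  expect_equal(nrow(filter_subpopulations(prof, coverage_ok = cov_ok)), 0)
  cov_ok[] <- TRUE
  expect_equal(nrow(filter_subpopulations(prof, coverage_ok = cov_ok)), 2)

  bad <- prof
  bad$proportion <- c(0.8, 0.3, 0.2)
  expect_error(filter_subpopulations(bad), "exceed 1")
})

toy_subpops <- function(pre_det, discr) {
  rows <- list(data.frame(genome_id = "G1",
                          subpop_id = if (discr) c("sA", "sB") else "sA",
                          sample_id = "DS1",
                          proportion = if (discr) c(0.6, 0.4) else 1,
                          stringsAsFactors = FALSE))
  if (pre_det) {
    rows <- c(rows, list(data.frame(genome_id = "G1", subpop_id = "sA",
                                    sample_id = "R1_pre", proportion = 1,
                                    stringsAsFactors = FALSE)))
  }
  rows <- c(rows, list(data.frame(genome_id = "G1",
                                  subpop_id = if (discr) c("sA", "sB")
                                              else "sA",
                                  sample_id = "R1_d030",
                                  proportion = if (discr) c(0.5, 0.5) else 1,
                                  stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

test_that("the phenotype decision tree matches the exhaustive truth table", {
  meta <- toy_meta()
  combos <- expand.grid(donor = c(TRUE, FALSE), pre = c(TRUE, FALSE),
                        post = c(TRUE, FALSE), discr = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    expected <- if (!cb$donor) "not_applicable"
      else if (!cb$post) "not_colonized"
      else if (!cb$pre) "colonized"
      else if (cb$discr) "colonized"
      else "undetermined"
    det <- toy_detection(donor = ifelse(cb$donor, 0.9, 0.02),
                         pre = ifelse(cb$pre, 0.9, 0.02),
                         d007 = 0.9, # boundary day: never post-FMT evidence
                         d030 = ifelse(cb$post, 0.9, 0.02))
    call <- assign_phenotype("G1", "R1", det,
                             toy_subpops(cb$pre, cb$discr), meta)
    expect_equal(call$outcome, expected,
                 label = paste0("donor=", cb$donor, " pre=", cb$pre,
                                " post=", cb$post, " discr=", cb$discr))
  }
})

test_that("a detection only at the day-7 boundary is not colonization", {
  call <- assign_phenotype("G1", "R1",
                           toy_detection(donor = 0.9, d007 = 0.9,
                                         d030 = 0.02),
                           empty_subpops(), toy_meta())
  expect_equal(call$outcome, "not_colonized")
})

test_that("recipients without usable timelines raise named errors", {
  meta <- toy_meta()
  no_pre <- meta[meta$sample_id != "R1_pre", ]
  expect_error(assign_phenotype("G1", "R1", toy_detection(), empty_subpops(),
                                no_pre), "R1.*no pre-FMT")
  no_post <- meta[meta$day_relative_to_fmt <= 7, ]
  expect_error(assign_phenotype("G1", "R1", toy_detection(), empty_subpops(),
                                no_post), "R1.*no post-FMT")
  expect_error(assign_phenotype("G1", "R9", toy_detection(), empty_subpops(),
                                meta), "R9")
})

test_that("good/poor classification follows the all-5 / at-least-3 rules", {
  mk <- function(donor, post) {
    data.frame(recipient_id = paste0("R", seq_along(donor)),
               donor_detected = donor, post7_detected = post)
  }
  expect_equal(classify_good_poor(mk(rep(TRUE, 5), rep(TRUE, 5))), "good")
  expect_equal(classify_good_poor(mk(rep(TRUE, 5),
                                     c(FALSE, FALSE, FALSE, TRUE, TRUE))),
               "poor")
  expect_equal(classify_good_poor(mk(rep(TRUE, 5),
                                     c(FALSE, FALSE, TRUE, TRUE, TRUE))),
               "neither")
  # donor non-detection blocks both labels
  expect_equal(classify_good_poor(mk(c(FALSE, rep(TRUE, 4)), rep(TRUE, 5))),
               "neither")
  expect_equal(classify_good_poor(mk(rep(FALSE, 5), rep(FALSE, 5))),
               "neither")
  expect_error(classify_good_poor(mk(rep(TRUE, 3), rep(TRUE, 3))),
               "at least 5")
})

test_that("no random summary is ever both good and poor", {
  set.seed(3)
  for (i in 1:200) {
    s <- data.frame(recipient_id = paste0("R", 1:5),
                    donor_detected = runif(5) < 0.7,
                    post7_detected = runif(5) < 0.5)
    lab <- classify_good_poor(s)
    expect_true(lab %in% c("good", "poor", "neither"))
  }
})

test_that("representative selection keeps the most prevalent genomes", {
  prev <- c(a = 0.9, b = 0.5, c = 0.7)
  expect_equal(select_representatives(c("a", "b", "c"), prev, 2),
               c("a", "c"))
  # tie at the cutoff: lexicographically smaller id wins
  prev2 <- c(x = 0.9, m = 0.5, b = 0.5)
  expect_equal(select_representatives(c("x", "m", "b"), prev2, 2),
               c("x", "b"))
  expect_equal(select_representatives(c("a", "b"), prev, 2),
               c("a", "b"))
  expect_error(select_representatives(c("a", "b"), prev, 3), "exceeds")
  expect_error(select_representatives(c("a", "z"), prev, 1),
               "no prevalence")
})

test_that("colonization regression recovers a planted prevalence effect", {
  set.seed(11)
  n <- 200
  prev <- runif(n)
  dose <- rlnorm(n, 2, 0.6)
  beta <- 1.5
  y <- rbinom(n, 1, plogis(beta * scale(prev)[, 1]))
  fit <- colonization_regression(y, data.frame(prevalence = prev,
                                               donor_dose = dose))
  prow <- fit[fit$predictor == "prevalence", ]
  expect_gt(prow$slope, 0)
  expect_lt(abs(prow$slope - beta), 2 * prow$se)
  expect_lt(prow$p_value, 0.01)
})

test_that("regression is calibrated under permuted (null) labels", {
  set.seed(12)
  n <- 120
  rejections <- replicate(40, {
    prev <- runif(n)
    y <- sample(rep(0:1, n / 2))
    fit <- colonization_regression(y, data.frame(prevalence = prev))
    fit$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.2)
})

test_that("degenerate regression inputs raise explicit errors", {
  expect_error(colonization_regression(rep(1, 10),
                                       data.frame(x = rnorm(10))),
               "both classes")
  x <- c(1:5, 11:15)
  y <- rep(c(0, 1), each = 5)
  expect_error(colonization_regression(y, data.frame(x = x)),
               class = "mindep_separation_error")
  expect_error(colonization_regression(y, data.frame(x = rep(1, 10))),
               "constant")
})

test_that("planted cohort labels and phenotypes are fully recovered", {
  cfg <- sim_config(seed = 31, n_good_colonizers = 8, n_poor_colonizers = 8,
                    n_neither = 4)
  coh <- gen_fmt_cohort(cfg)
  cls <- classify_cohort(coh$detection, coh$meta)
  truth <- coh$truth$labels
  expect_equal(cls$label[match(truth$genome_id, cls$genome_id)],
               truth$label)
  cov_ok <- coh$detection$scg_coverage >=
    colonization_rules()$scg_coverage_min
  sp <- filter_subpopulations(coh$subpops, coverage_ok = cov_ok)
  calls <- colonization_calls(coh$detection, sp, coh$meta)
  m <- merge(calls, coh$truth$pairs, by = c("genome_id", "recipient_id"),
             suffixes = c("_called", "_truth"))
  expect_equal(m$outcome_called, m$outcome_truth)
})
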