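test_that("motif classes group rotations and reverse complements", {
  expect_setequal(motif_class_members("AC")$members, c("AC", "CA", "GT", "TG"))
  expect_setequal(motif_class_members("AT")$members, c("AT", "TA"))
  expect_setequal(motif_class_members("A")$members, c("A", "T"))
  expect_setequal(motif_class_members("AAC")$members,
                  c("AAC", "ACA", "CAA", "GTT", "TGT", "TTG"))
  expect_equal(motif_class_members("TG")$label, "AC")
  expect_error(motif_class_members("GAGA"), "primitive")

  # partition property: every member maps back to the identical class
  all_dimers <- c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  dimers <- all_dimers[vapply(all_dimers,
                              function(m) primitive_motif(m) == m, logical(1))]
  seen <- list()
  for (m in dimers) {
    cls <- motif_class_members(m)
    expect_true(m %in% cls$members)
    for (mem in cls$members)
      expect_identical(motif_class_members(mem)$members, cls$members)
    expect_true(length(cls$members) %in% c(2L, 4L))
    seen[[cls$label]] <- cls$members
  }
  expect_setequal(unlist(seen), dimers)   # classes partition the dimers
  expect_equal(length(seen), 4L)          # AC, AG, AT, CG
})

test_that("starting-preference test reproduces published class expectations", {
  r <- starting_preference_test(c(TA = 48814, AT = 35558))
  expect_equal(r$expected_rounded, 42186)
  expect_equal(r$df, 1L)
  expect_equal(r$p, 0)   # chi-square ~2083 on 1 df underflows

  r <- starting_preference_test(c(AAT = 4099, ATA = 2260, TAA = 2406,
                                  ATT = 3533, TAT = 2233, TTA = 3093))
  expect_equal(r$expected_rounded, 2937)
  expect_equal(r$df, 5L)
  expect_lt(r$p, 1e-200)
  # statistic matches the direct goodness-of-fit formula
  obs <- c(4099, 2260, 2406, 3533, 2233, 3093)
  expect_equal(r$statistic, sum((obs - mean(obs))^2 / mean(obs)))

  flat <- starting_preference_test(c(AC = 100, CA = 100, GT = 100, TG = 100))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  expect_error(starting_preference_test(c(AC = 0, CA = 0, GT = 0, TG = 0)),
               "zero")
  expect_error(starting_preference_test(c(AC = 5, CA = 5)), "class")
})

test_that("end/middle expectations follow the 2-in-n terminal-unit model", {
  expect_equal(end_middle_expected(5, 3717),
               c(end = 1486.8, middle = 2230.2))
  expect_equal(round_half_up(end_middle_expected(5, 3717)),
               c(end = 1487, middle = 2230))
  expect_equal(end_middle_expected(8, 76), c(end = 19, middle = 57))
  expect_equal(end_middle_expected(2, 100), c(end = 100, middle = 0))
  expect_error(end_middle_expected(1, 10), "repeat_number")

  # expectations always sum to the total
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:40, 1); tot <- sample(0:5000, 1)
    e <- end_middle_expected(n, tot)
    expect_equal(sum(e), tot)
    expect_true(all(e >= 0))
  }
})

test_that("end/middle chi-square test behaves across regimes", {
  r <- end_middle_test(50, 50, 4)   # exactly at expectation
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # strong end excess underflows double precision
  r <- end_middle_test(15005, 50, 3)
  expect_equal(r$method, "chisq")
  expect_equal(r$p, 0)
  exp3 <- end_middle_expected(3, 15055)
  expect_equal(r$statistic,
               (15005 - exp3["end"])^2 / exp3["end"] +
                 (50 - exp3["middle"])^2 / exp3["middle"],
               ignore_attr = TRUE)

  # small expected cells fall back to the exact binomial
  r <- end_middle_test(3, 1, 8)
  expect_equal(r$method, "binomial")
  expect_equal(r$p, exact_binom_p(3, 4, 2 / 8), tolerance = 1e-8)

  # p decreases monotonically along a ray away from expectation
  ps <- vapply(c(0, 10, 20, 30),
               function(k) end_middle_test(200 + k, 400 - k, 6)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(end_middle_test(0, 0, 5), "zero total")
})

test_that("heterozygosity curve fits recover exact generating curves", {
  x <- 4:15
  lin <- fit_het_curve(data.frame(repeat_number = x, het = 2 * x + 1),
                       "linear")
  expect_equal(lin$r2, 1)
  expect_equal(unname(lin$parameters["slope"]), 2)
  expect_equal(unname(lin$parameters["intercept"]), 1)

  ex <- fit_het_curve(data.frame(repeat_number = x, het = 0.5 * exp(0.3 * x)),
                      "exponential")
  expect_equal(ex$r2, 1)
  expect_equal(unname(ex$parameters["rate"]), 0.3)
  expect_equal(unname(ex$parameters["scale"]), 0.5)

  expect_error(fit_het_curve(data.frame(repeat_number = c(3, 3, 3),
                                        het = c(1, 2, 3))), "degenerate")
  expect_error(fit_het_curve(data.frame(repeat_number = 1:2, het = 1:2)),
               "3 points")
  expect_error(fit_het_curve(data.frame(repeat_number = 1:5,
                                        het = c(0, 1, 2, 3, 4)),
                             "exponential"), "positive")

  set.seed(9)
  noisy_exp <- data.frame(repeat_number = x,
                          het = 0.5 * exp(0.3 * x) * exp(rnorm(12, 0, 0.05)))
  expect_equal(select_het_model(noisy_exp)$model, "exponential")
  noisy_lin <- data.frame(repeat_number = x, het = 2 * x + rnorm(12, 0, 0.3))
  expect_equal(select_het_model(noisy_lin)$model, "linear")
  # recovered rate within 2 standard errors of the generating rate
  f <- fit_het_curve(noisy_exp, "exponential")
  se <- summary(f$fit)$coefficients[2, 2]
  expect_lt(abs(f$parameters["rate"] - 0.3), 2 * se)
})

test_that("density/recombination regression matches closed-form least squares", {
  set.seed(21)
  # loci spread over one scaffold; density differs per interval
  starts <- sort(sample(0:999999, 3000))
  loci <- data.frame(seq_id = "s1", start = starts,
                     motif_size = sample(2:4, 3000, replace = TRUE))
  intervals <- data.frame(seq_id = "s1",
                          phys_start = seq(0, 900000, by = 100000),
                          phys_end = seq(100000, 1000000, by = 100000),
                          cm = runif(10, 0.5, 5))
  res <- density_recombination_correlation(loci, intervals)
  x <- res$table$cm_per_mb; y <- res$table$density_per_mb
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$fit$slope, slope)
  expect_equal(res$fit$intercept, mean(y) - slope * mean(x))
  expect_equal(res$fit$r2, cor(x, y)^2)
  expect_true(all(res$table$pred_lo <= res$table$conf_lo))
  expect_true(all(res$table$pred_hi >= res$table$conf_hi))

  # density exactly proportional to cM/Mb -> r2 = 1
  intervals$cm <- (res$table$density_per_mb / 10) * 0.1  # spans are 0.1 Mb
  res2 <- density_recombination_correlation(loci, intervals)
  expect_equal(res2$fit$r2, 1)
  expect_gt(res2$fit$slope, 0)

  # cM/Mb arithmetic: 5 cM over 2 Mb is 2.5 cM/Mb
  one <- data.frame(seq_id = "s1", phys_start = 0, phys_end = 2e6, cm = 5)
  res3 <- density_recombination_correlation(
    loci, rbind(one, intervals[1:2, ]))
  expect_equal(res3$table$cm_per_mb[1], 2.5)

  # intervals outside the assembly are skipped with a warning
  bad <- rbind(intervals,
               data.frame(seq_id = "s2", phys_start = 0, phys_end = 1000,
                          cm = 1))
  expect_warning(
    res4 <- density_recombination_correlation(loci, bad,
                                              seq_lengths = c(s1 = 1e6)),
    "skipping")
  expect_equal(res4$fit$n, 10)
})

test_that("scaffold abundance flags use Bonferroni-corrected binomial tests", {
  set.seed(31)
  sizes <- c(sc1 = 2e5, sc2 = 2e5, sc3 = 2e5)
  # uniform rate: no flags
  loci <- data.frame(
    seq_id = rep(names(sizes), each = 400),
    start = unlist(lapply(1:3, function(i) sort(sample(0:199999, 400)))),
    motif_size = 2L)
  fl <- scaffold_abundance_flags(loci, sizes)
  expect_equal(fl$flag, c("", "", ""))
  expect_equal(fl$expected, rep(400, 3))

  # one scaffold with triple density is flagged +
  extra <- data.frame(seq_id = "sc2", start = sample(0:199999, 800),
                      motif_size = 2L)
  fl2 <- scaffold_abundance_flags(rbind(loci, extra), sizes)
  expect_equal(fl2$flag[fl2$seq_id == "sc2"], "+")

  # p-values match a direct-summation exact binomial on small counts
  tiny <- data.frame(seq_id = c(rep("sc1", 12), rep("sc2", 3)),
                     start = 0L, motif_size = 2L)
  fl3 <- scaffold_abundance_flags(tiny, c(sc1 = 1000, sc2 = 1000))
  expect_equal(fl3$p[1], exact_binom_p(12, 15, 0.5), tolerance = 1e-8)
  expect_equal(fl3$p[2], exact_binom_p(3, 15, 0.5), tolerance = 1e-8)

  expect_error(scaffold_abundance_flags(loci, c(a = 100)), "2 scaffolds")
  expect_error(scaffold_abundance_flags(loci, c(a = 100, b = 0)),
               "zero-length")
})
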