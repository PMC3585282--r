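test_that("electrode aggregation averages within experiments", {
  tab <- experiment_table(data.frame(
    experiment_id = rep("exp01", 4), condition = "control",
    electrode_id = paste0("E", 1:4), value = c(2, 4, 4, 6)))
  agg <- aggregate_electrodes(tab)
  expect_equal(agg$mean_value, 4)
  expect_equal(agg$n_electrodes, 4L)
  # single electrode is the identity
  tab1 <- experiment_table(data.frame(
    experiment_id = "exp01", condition = "control",
    electrode_id = "E1", value = 3.14))
  expect_equal(aggregate_electrodes(tab1)$mean_value, 3.14)
  # permuting rows changes nothing
  tab2 <- experiment_table(data.frame(
    experiment_id = rep(c("a", "b"), each = 4),
    condition = rep(c("x", "y"), each = 4),
    electrode_id = rep(paste0("E", 1:4), 2),
    value = c(1, 2, 3, 4, 10, 20, 30, 40)))
  perm <- tab2[sample(nrow(tab2)), ]
  expect_equal(aggregate_electrodes(experiment_table(perm)),
               aggregate_electrodes(tab2))
})

test_that("one-way ANOVA: degenerate and identity cases", {
  # identical groups: no between-group variance at all
  an <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(an$f, 0)
  expect_equal(an$p, 1)
  # zero within-group variance with unequal means: below-machine marker
  an2 <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_true(an2$p_below_machine)
  expect_equal(an2$f, Inf)
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(anova_oneway(list(1, c(2, 3))), "at least two values")
})

test_that("one-way ANOVA matches the closed-form oracle", {
  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6 (df 2), SSW = 6 (df 6) => F = 3
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  an <- anova_oneway(groups)
  expect_equal(an$f, 3)
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  orc <- oracle_anova(groups)
  expect_equal(an$f, orc$f, tolerance = 1e-12)
  expect_equal(an$p, orc$p, tolerance = 1e-12)
  # two groups: F equals the square of the pooled t statistic
  a <- c(1.2, 0.8, 1.5, 1.1); b <- c(2.0, 1.7, 2.4)
  an2 <- anova_oneway(list(a, b))
  tt <- ttest(a, b, mode = "unpaired")
  expect_equal(an2$f, tt$t^2, tolerance = 1e-12)
})

test_that("t-tests match closed-form oracles and behave symmetrically", {
  # paired: d = {-1,-1,-2,-2}, t = -1.5 / (sd(d)/2) = -3*sqrt(3)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 5, 6)
  tt <- ttest(a, b, mode = "paired")
  expect_equal(tt$t, -3 * sqrt(3), tolerance = 1e-12)
  orc <- oracle_t_paired(a, b)
  expect_equal(tt$t, orc$t, tolerance = 1e-12)
  expect_equal(tt$p, orc$p, tolerance = 1e-12)
  expect_equal(tt$df, 3)
  # swapping the samples flips t and preserves p
  tt_swap <- ttest(b, a, mode = "paired")
  expect_equal(tt_swap$t, -tt$t)
  expect_equal(tt_swap$p, tt$p)
  # unpaired pooled form
  x <- c(5.1, 4.9, 5.3, 5.0); y <- c(5.6, 5.8, 5.5)
  tu <- ttest(x, y, mode = "unpaired")
  orc2 <- oracle_t_pooled(x, y)
  expect_equal(tu$t, orc2$t, tolerance = 1e-12)
  expect_equal(tu$p, orc2$p, tolerance = 1e-12)
  expect_equal(tu$df, 5)
  # identical paired samples have zero-variance differences
  td <- ttest(a, a, mode = "paired")
  expect_true(td$degenerate)
  expect_true(is.na(td$t))
})

test_that("statistics match independent oracles on random fixtures", {
  set.seed(421)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), mean = j))
    an <- anova_oneway(groups)
    orc <- oracle_anova(groups)
    expect_equal(an$f, orc$f, tolerance = 1e-10)
    expect_equal(an$p, orc$p, tolerance = 1e-10)
    n <- sample(3:9, 1)
    a <- rnorm(n); b <- rnorm(n, 0.5)
    tp <- ttest(a, b, "paired"); op <- oracle_t_paired(a, b)
    expect_equal(tp$t, op$t, tolerance = 1e-10)
    expect_equal(tp$p, op$p, tolerance = 1e-10)
    b2 <- rnorm(sample(3:9, 1), 0.5)
    tu <- ttest(a, b2, "unpaired"); ou <- oracle_t_pooled(a, b2)
    expect_equal(tu$t, ou$t, tolerance = 1e-10)
    expect_equal(tu$p, ou$p, tolerance = 1e-10)
  }
})

test_that("A(F;P) annotation renders and parses at stated precision", {
  lab <- format_afp(4.561, 0.01234)
  expect_match(lab, "^A\\(")
  back <- parse_afp(lab)
  expect_equal(unname(back["f"]), 4.561, tolerance = 1e-2)
  expect_equal(unname(back["p"]), 0.01234, tolerance = 1e-2)
  # small p rendered in scientific notation and recoverable
  lab2 <- format_afp(33.2, 2.5e-7)
  expect_match(lab2, "e-0?7")
  expect_equal(unname(parse_afp(lab2)["p"]), 2.5e-7, tolerance = 1e-3)
  expect_error(parse_afp("F(1;2)"), "label")
})

test_that("delta-delta-Ct follows its defining arithmetic", {
  tab <- ct_table(data.frame(
    sample_id = c("s1", "s1", "ref", "ref"),
    gene = c("GOI", "HPRT", "GOI", "HPRT"),
    ct_cycles = c(25, 20, 24, 20)),
    reference_sample_id = "ref")
  d <- ddct(tab)
  s1 <- d[d$sample_id == "s1", ]
  expect_equal(s1$delta_ct, 5)     # 25 - 20
  expect_equal(s1$delta_delta_ct, 1)  # 5 - 4
  expect_equal(s1$fold_change, 0.5)
  # the reference sample against itself is identically zero
  r <- d[d$sample_id == "ref", ]
  expect_equal(r$delta_delta_ct, 0)
  expect_equal(r$fold_change, 1)
})

test_that("delta-delta-Ct is invariant to per-sample Ct offsets", {
  base <- data.frame(
    sample_id = rep(c("s1", "s2", "ref"), each = 3),
    gene = rep(c("g1", "g2", "HPRT"), 3),
    ct_cycles = c(25, 27, 20, 24, 28, 21, 23, 26, 20))
  d0 <- ddct(ct_table(base, reference_sample_id = "ref"))
  shifted <- base
  shifted$ct_cycles[shifted$sample_id == "s1"] <-
    shifted$ct_cycles[shifted$sample_id == "s1"] + 3.7
  d1 <- ddct(ct_table(shifted, reference_sample_id = "ref"))
  expect_equal(d1$delta_delta_ct, d0$delta_delta_ct)
})

test_that("Ct table validation names what is missing", {
  df <- data.frame(sample_id = c("s1", "ref"), gene = c("GOI", "HPRT"),
                   ct_cycles = c(25, 20))
  expect_error(ct_table(df, reference_sample_id = "ref"),
               "lacks the reference gene")
  df2 <- data.frame(sample_id = "s1", gene = "HPRT", ct_cycles = 20)
  expect_error(ct_table(df2, reference_sample_id = "nope"), "not present")
})
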