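# build a synthetic 2x2 crossover dataset with lognormal between-subject
# spread and within-subject CV, true test/reference ratio `ratio`
make_crossover <- function(n = 24, ratio = 1, cv_within = 0.15,
                           cv_between = 0.3, base = 20) {
  sdw <- sqrt(log(1 + cv_within^2))
  sdb <- sqrt(log(1 + cv_between^2))
  subj <- rep(seq_len(n), each = 2)
  seqs <- rep(ifelse(seq_len(n) %% 2 == 1, "TR", "RT"), each = 2)
  period <- rep(1:2, n)
  form <- ifelse((seqs == "TR") == (period == 1), "test", "reference")
  eta <- rep(rnorm(n, 0, sdb), each = 2)
  eps <- rnorm(2 * n, 0, sdw)
  val <- base * exp(eta + eps) * ifelse(form == "test", ratio, 1)
  data.frame(subject = subj, sequence = seqs, period = period,
             formulation = form, cmax = val, auc0t = val, auc0inf = val)
}

test_that("identical test and reference data give GMR 100% and pass", {
  set.seed(1)
  df <- make_crossover(n = 12, ratio = 1, cv_within = 0)
  ds <- be_dataset(df, "crossover_2x2")
  warns <- capture_warnings(rep <- tost_be(ds))
  expect_match(warns, "zero variance", all = TRUE)
  expect_length(warns, 3)   # one degenerate-CI warning per parameter
  expect_equal(rep$gmr, rep(100, 3), tolerance = 1e-9)
  expect_equal(rep$lower, rep$gmr, tolerance = 1e-9)
  expect_true(all(rep$pass))
})

test_that("TOST detects equivalence and inequivalence at the designed rates", {
  set.seed(42)
  pass_at <- function(ratio) {
    mean(vapply(1:200, function(i) {
      ds <- be_dataset(make_crossover(n = 24, ratio = ratio), "crossover_2x2")
      all(tost_be(ds, limits = c(80, 125))$pass)
    }, TRUE))
  }
  expect_gte(pass_at(0.95), 0.95)
  expect_lte(pass_at(0.70), 0.01)
})

test_that("swapping test and reference inverts the GMR", {
  set.seed(7)
  df <- make_crossover(n = 16, ratio = 0.9)
  swapped <- df
  swapped$formulation <- ifelse(df$formulation == "test",
                                "reference", "test")
  swapped$sequence <- ifelse(df$sequence == "TR", "RT", "TR")
  r1 <- tost_be(be_dataset(df, "crossover_2x2"))
  r2 <- tost_be(be_dataset(swapped, "crossover_2x2"))
  expect_equal(r1$gmr * r2$gmr, rep(100^2, 3), tolerance = 1e-9)
})

test_that("widening alpha never widens the confidence interval", {
  set.seed(11)
  ds <- be_dataset(make_crossover(n = 20, ratio = 0.95), "crossover_2x2")
  r05 <- tost_be(ds, alpha = 0.05)
  r10 <- tost_be(ds, alpha = 0.10)
  expect_true(all(r10$lower >= r05$lower))
  expect_true(all(r10$upper <= r05$upper))
})

test_that("parallel-design analysis reports the ANOVA-style p-value", {
  set.seed(5)
  n <- 6
  df <- data.frame(
    subject = 1:(2 * n),
    formulation = rep(c("test", "reference"), each = n),
    cmax = c(rlnorm(n, log(118), 0.1), rlnorm(n, log(128), 0.1)),
    auc0t = c(rlnorm(n, log(718), 0.1), rlnorm(n, log(718), 0.1)),
    auc0inf = c(rlnorm(n, log(722), 0.1), rlnorm(n, log(722), 0.1)))
  rep <- tost_be(be_dataset(df, "parallel"))
  expect_true(all(is.finite(rep$p_anova)))
  expect_true(all(rep$p_anova >= 0 & rep$p_anova <= 1))
  # grossly different arms give a significant formulation effect
  df2 <- df; df2$cmax[df2$formulation == "test"] <- df2$cmax[df2$formulation == "test"] * 3
  rep2 <- tost_be(be_dataset(df2, "parallel"))
  expect_lt(rep2$p_anova[rep2$parameter == "cmax"], 0.05)
  expect_false(rep2$pass[rep2$parameter == "cmax"])
})

test_that("BE datasets validate their structure", {
  df <- make_crossover(n = 4)
  expect_error(be_dataset(df[-1, ], "crossover_2x2"), "exactly one")
  df2 <- df; df2$cmax[1] <- -1
  expect_error(be_dataset(df2, "crossover_2x2"), "positive")
  df3 <- df; df3$formulation[1] <- "generic"
  expect_error(be_dataset(df3, "crossover_2x2"), "formulation")
  path <- tempfile(fileext = ".csv")
  write_be_dataset(be_dataset(df, "crossover_2x2"), path)
  back <- read_be_dataset(path)
  expect_equal(back$data$cmax, df$cmax, tolerance = 1e-9)
})

test_that("virtual BE with identical products is exactly equivalent", {
  pop <- sample_population(population_spec(n = 6, seed = 21))
  suppressWarnings(
    rep <- virtual_be_trial(pop, lev, fast_dis, fast_dis, dose = 1000,
                            t_end = 24, dt = 0.25))
  expect_equal(rep$gmr, rep(100, 3), tolerance = 1e-6)
  expect_true(all(rep$pass))
  tm <- attr(rep, "tmax")
  expect_equal(unname(tm["test"]), unname(tm["reference"]))
})
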