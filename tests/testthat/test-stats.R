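test_that("Mann-Whitney exact p matches the textbook separated-groups case", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
})

test_that("identical groups give p = 1", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
})

test_that("exact Mann-Whitney equals full enumeration for n_a + n_b <= 12", {
  set.seed(61)
  for (rep in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    tied <- rep %% 2 == 0
    a <- if (tied) sample(1:4, na, replace = TRUE) else rnorm(na)
    b <- if (tied) sample(1:4, nb, replace = TRUE) else rnorm(nb)
    r <- mann_whitney_u(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with wilcox.test", {
  set.seed(62)
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney_u(a, b)$p_value,
                 suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("large tied samples fall back to the flagged normal approximation", {
  set.seed(63)
  a <- sample(1:5, 40, replace = TRUE); b <- sample(1:5, 45, replace = TRUE)
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal_approx")
  expect_equal(r$p_value,
               suppressWarnings(wilcox.test(a, b, correct = TRUE)$p.value),
               tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(64)
  for (rep in 1:30) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 0, 0, 1), 2)), "integer")
})

test_that("the test is well powered for the mixed-vs-uniform polarity contrast", {
  set.seed(65)
  rej <- 0
  for (r in 1:100) {
    a <- pmin(pmax(rnorm(20, 0.55, 0.1), 0), 1)
    b <- pmin(pmax(rnorm(20, 0.95, 0.1), 0), 1)
    if (mann_whitney_u(a, b)$p_value <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / 100, 0.9)
})

test_that("the report bundle is complete and rerun-identical", {
  s1 <- data.frame(neurite_id = 1:3, n_out = c(9, 8, 7), n_in = c(1, 2, 3),
                   n_excluded = 0, f_out = c(0.9, 0.8, 0.7),
                   f_in = c(0.1, 0.2, 0.3), defined = TRUE)
  s2 <- s1; s2$f_out <- c(0.5, 0.55, 0.45)
  st <- list(early_vs_late = mann_whitney_u(s1$f_out, s2$f_out))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  f1 <- build_report(list(late = s1, early = s2), st, out_dir = d1)
  f2 <- build_report(list(late = s1, early = s2), st, out_dir = d2)
  expect_true(all(file.exists(f1)))
  stats_csv <- utils::read.csv(file.path(d1, "stats.csv"))
  expect_equal(nrow(stats_csv), 1)
  expect_equal(stats_csv$test, "mann_whitney_u")
  for (f in c("condition_table.csv", "stats.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_error(build_report(list(), out_dir = d1), "missing upstream")
})
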