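table1 <- function() {
  read_norms(system.file("extdata", "iaps_duplicates_table1.csv",
                         package = "affectselect"))
}

test_that("the 24 duplicate rows merge into 12 entries with averaged means", {
  md <- merge_duplicates(table1())
  expect_equal(nrow(md$table), 12L)
  expect_equal(md$report$n_groups, 12L)
  expect_equal(md$report$n_rows_merged, 12L)
  sp <- md$table[md$table$code == "1230", ]
  expect_equal(sp$val_mean, mean(c(4.09, 4.61)))
  expect_equal(sp$aro_mean, mean(c(4.85, 4.03)))
  expect_equal(sp$dom1_mean, mean(c(4.58, 5.60)))
  expect_equal(sp$val_mean, 4.35)
  expect_equal(sp$aro_mean, 4.44)
  expect_equal(sp$dom1_mean, 5.09)
})

test_that("merging is idempotent and a no-op without duplicates", {
  md <- merge_duplicates(table1())
  again <- merge_duplicates(md$table)
  expect_equal(again$report$n_groups, 0L)
  expect_equal(as.data.frame(again$table), as.data.frame(md$table))
})

test_that("merged sd equals the exact combined-sample sd", {
  # oracle: reconstruct two centred raw samples with the stated moments
  # and pool them directly
  mk <- function(n, m, s) {
    x <- scale(stats::rnorm(n))  # exact mean 0, sd 1
    as.numeric(x * s + m)
  }
  set.seed(99)
  x1 <- mk(40, 5.2, 1.3); x2 <- mk(60, 6.0, 0.9)
  tab <- norm_table(code = c("1", "1"),
                    val_mean = c(mean(x1), mean(x2)),
                    val_sd = c(sd(x1), sd(x2)), val_n = c(40, 60),
                    aro_mean = c(4, 4), aro_sd = c(1, 1), aro_n = c(40, 60))
  md <- merge_duplicates(tab, sd_method = "pooled")
  expect_equal(md$table$val_sd, sd(c(x1, x2)), tolerance = 1e-12)
  expect_equal(md$table$val_n, 100)
  md2 <- merge_duplicates(tab, sd_method = "average")
  expect_equal(md2$table$val_sd, mean(c(sd(x1), sd(x2))))
})

test_that("dominance resolution keeps the better-populated variant", {
  tab <- norm_table(code = as.character(1:4),
                    val_mean = rep(5, 4), val_sd = rep(1, 4),
                    val_n = rep(100, 4),
                    aro_mean = rep(4, 4), aro_sd = rep(1, 4),
                    aro_n = rep(100, 4),
                    dom1_mean = c(5, 6, 7, NA),
                    dom2_mean = c(NA, NA, 5, NA))
  rd <- resolve_dominance(tab)
  expect_equal(rd$report$variant, "dom1")
  expect_equal(rd$report$n_dropped, 1L)
  expect_identical(rd$report$codes, "4")
  expect_equal(rd$table$dom_mean, c(5, 6, 7))

  rd2 <- resolve_dominance(tab, policy = "force_dom2")
  expect_equal(rd2$report$n_dropped, 3L)

  full <- norm_table(code = "9", val_mean = 5, val_sd = 1, val_n = 100,
                     aro_mean = 4, aro_sd = 1, aro_n = 100, dom1_mean = 5)
  expect_equal(resolve_dominance(full)$report$n_dropped, 0L)

  none <- norm_table(code = "9", val_mean = 5, val_sd = 1, val_n = 100,
                     aro_mean = 4, aro_sd = 1, aro_n = 100)
  expect_error(resolve_dominance(none), "dominance")
})

test_that("the MAD rule flags exactly the hand-computed outlier", {
  # median 3, raw MAD 1 -> scaled MAD 1.4826, cutoff 3.7065:
  # only 100 deviates by more
  flags <- mad_flags(c(1, 2, 3, 4, 100), cutoff = 2.5, constant = 1.4826)
  expect_identical(as.logical(flags), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(flags, "center"), 3)
  expect_equal(attr(flags, "mad"), 1.4826)
})

test_that("a degenerate scale warns and flags nothing; empty input errors", {
  expect_warning(f <- mad_flags(c(5, 5, 5, 5)), "degenerate")
  expect_false(any(f))
  expect_error(mad_flags(numeric(0)), "finite")
})

test_that("MAD flags are invariant under affine rescaling", {
  set.seed(7)
  for (i in 1:20) {
    x <- stats::rnorm(50, sd = runif(1, 0.5, 3))
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    expect_identical(as.logical(mad_flags(a * x + b)),
                     as.logical(mad_flags(x)))
  }
})

test_that("CI width follows the t margin and the 1-point criterion", {
  expect_equal(ci_width(5, sd = 0, n = 50), 0)
  expect_equal(ci_width(5, sd = 0, n = 5000), 0)
  # independent check against the t quantile table: t_{.975,99} = 1.9842
  expect_equal(ci_width(5, sd = 2.52, n = 100),
               2 * 1.9842 * 2.52 / 10, tolerance = 1e-4)
  expect_gt(ci_width(5, sd = 2.52, n = 100), 1.0)
  expect_lt(ci_width(5, sd = 2.40, n = 100), 1.0)
  # strictly increasing in sd, strictly decreasing in n
  sds <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(ci_width(5, sds, 100)) > 0))
  ns <- seq(10, 500, by = 10)
  expect_true(all(diff(ci_width(5, 1.5, ns)) < 0))
  expect_error(ci_width(5, 1, 1), "n >= 2")
  # z margin is slightly narrower than t
  expect_lt(ci_width(5, 2, 100, method = "z"), ci_width(5, 2, 100))
})

test_that("screening recovers exactly the injected artifact counts", {
  base <- clean_base(500, seed = 21)
  inj <- inject_artifacts(base, n_duplicates = 5, n_outliers = 7,
                          n_wide_ci = 9, seed = 4)
  res <- run_screening(inj$table)
  expect_equal(res$report$n_duplicate_groups, 5L)
  expect_equal(res$report$n_rows_merged, 5L)
  expect_equal(res$report$n_outliers, 7L)
  expect_setequal(res$report$codes_outliers, inj$manifest$outliers)
  expect_equal(res$report$n_wide_ci, 9L)
  expect_setequal(res$report$codes_wide_ci, inj$manifest$wide_ci)
  expect_setequal(res$report$codes_duplicates, inj$manifest$duplicates)
})

test_that("screening a clean table changes nothing", {
  base <- clean_base(400, seed = 8)
  res <- run_screening(base)
  expect_equal(res$report$n_output, res$report$n_input)
  expect_equal(res$report$n_outliers, 0L)
  expect_equal(res$report$n_wide_ci, 0L)
  expect_equal(res$table$code, base$code)
})

test_that("the report reconciliation identity holds on fuzzed inputs", {
  for (s in 1:8) {
    sn <- sample_norms(default_iaps_spec(), 300, seed = s)$table
    # tables carry their natural artifacts plus injected ones; outlier
    # injection is exercised separately on a unimodal base where the
    # displacement always fits the rating scale
    inj <- inject_artifacts(sn, n_duplicates = s %% 4, n_outliers = 0,
                            n_wide_ci = s %% 5, seed = s + 100)
    rep <- suppressWarnings(run_screening(inj$table))$report
    expect_equal(rep$n_output,
                 rep$n_input - rep$n_rows_merged -
                   rep$n_dropped_missing_dominance - rep$n_outliers -
                   rep$n_wide_ci)
    # removal stages touch disjoint code sets
    lists <- list(rep$codes_dropped_dominance, rep$codes_outliers,
                  rep$codes_wide_ci)
    expect_equal(length(unlist(lists)), length(unique(unlist(lists))))
  }
})

test_that("a second screening pass removes no more than the first", {
  sn <- sample_norms(default_iaps_spec(), 500, seed = 3)$table
  first <- suppressWarnings(run_screening(sn))
  tab <- first$table
  tab$dom_mean <- tab$dom_sd <- tab$dom_n <- NULL
  class(tab) <- c("norm_table", "data.frame")
  second <- suppressWarnings(run_screening(tab))
  removed1 <- first$report$n_input - first$report$n_output
  removed2 <- second$report$n_input - second$report$n_output
  expect_lte(removed2, removed1)
})
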