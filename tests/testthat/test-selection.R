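# classification stub with chosen uncertainties/clusters
cl_stub <- function(u, cluster, codes = sprintf("c%03d", seq_along(u))) {
  k <- max(cluster)
  z <- matrix(0, length(u), max(2, k))
  for (i in seq_along(u)) {
    z[i, cluster[i]] <- 1 - u[i]
    spread <- u[i] / (ncol(z) - 1)
    z[i, -cluster[i]] <- spread
  }
  structure(list(codes = codes, z = z, cluster = cluster, uncertainty = u,
                 k = k,
                 summary = data.frame(cluster = seq_len(k),
                                      size = tabulate(cluster, k))),
            class = "gmm_classification")
}

test_that("usability bands follow the interpolated percentile thresholds", {
  u <- c(rep(0, 10), rep(0.5, 6), rep(0.9, 4))
  # independent quantile oracle: sort and interpolate directly
  s <- sort(u)
  q_at <- function(p) {
    h <- p * (length(s) - 1) + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  }
  b <- usability_bands(u)
  th <- attr(b, "thresholds")
  expect_equal(unname(th["ok"]), q_at(0.75))
  expect_equal(unname(th["risky"]), q_at(0.95))
  expect_equal(unname(th["ok"]), 0.5)
  expect_equal(unname(th["risky"]), 0.9)
  expect_identical(unique(b[u == 0]), "ok")
  expect_identical(unique(b[u == 0.5]), "ok")     # at the 75th boundary
  expect_identical(unique(b[u == 0.9]), "risky")  # at the 95th boundary
})

test_that("representative selection ranks by uncertainty with code tie-breaks", {
  u <- c(0.30, 0.10, 0.20, 0.10, 0.05, 0.40, 0.15, 0.25)
  cluster <- c(1, 1, 1, 1, 2, 2, 2, 2)
  codes <- c("b", "a", "c", "A", "z", "y", "x", "w")
  cl <- cl_stub(u, cluster, codes)
  sel <- select_representatives(cl, selection_config(n_per_cluster = 2))
  ex1 <- sel$exemplars[sel$exemplars$cluster == 1, ]
  # ties at u = 0.10 break lexicographically: "A" < "a"
  expect_identical(ex1$code, c("A", "a"))
  ex2 <- sel$exemplars[sel$exemplars$cluster == 2, ]
  expect_identical(ex2$code, c("z", "x"))
  # every selected exemplar beats every non-selected cluster member
  for (g in 1:2) {
    sel_u <- sel$table$uncertainty[sel$table$cluster == g &
                                     sel$table$selected]
    non_u <- sel$table$uncertainty[sel$table$cluster == g &
                                     !sel$table$selected]
    expect_lte(max(sel_u), min(non_u))
  }
})

test_that("n_per_cluster = 1 picks the argmin; short clusters warn", {
  cl <- cl_stub(c(0.3, 0.1, 0.2, 0.4, 0.5), c(1, 1, 1, 2, 2))
  sel <- select_representatives(cl, selection_config(n_per_cluster = 1))
  expect_identical(sel$exemplars$code,
                   c("c002", "c004"))
  expect_warning(
    sel5 <- select_representatives(cl, selection_config(n_per_cluster = 5)),
    "fewer")
  expect_equal(nrow(sel5$exemplars), 5L)  # all members returned
  expect_error(selection_config(n_per_cluster = 0))
  empty <- structure(list(codes = character(0), cluster = integer(0),
                          uncertainty = numeric(0), k = 1L),
                     class = "gmm_classification")
  expect_error(select_representatives(empty), "empty")
})

test_that("banding partitions the sample roughly 75/20/5", {
  set.seed(73)
  u <- stats::runif(400)
  b <- usability_bands(u)
  expect_equal(sum(b == "ok") / 400, 0.75, tolerance = 0.01)
  expect_equal(sum(b == "risky") / 400, 0.20, tolerance = 0.01)
  expect_equal(sum(b == "avoid") / 400, 0.05, tolerance = 0.01)
})

test_that("external code lists are redistributed with full accounting", {
  cl <- cl_stub(c(0.1, 0.1, 0.2, 0.2, 0.3), c(1, 1, 1, 2, 2),
                codes = c("100", "101", "102", "200", "201"))
  report <- structure(list(
    codes_dropped_dominance = c("300"),
    codes_outliers = c("400", "401"),
    codes_wide_ci = c("500")
  ), class = "screening_report")
  rc <- reclassify_codes(c("100", "101", "200", "300", "400", "500",
                           "999"), cl, report)
  expect_equal(unname(rc$per_cluster), c(2L, 1L))
  expect_equal(rc$excluded_missing_dominance, 1L)
  expect_equal(rc$excluded_outlier, 1L)
  expect_equal(rc$excluded_wide_ci, 1L)
  expect_equal(rc$unaccounted, 1L)
  expect_identical(rc$unaccounted_codes, "999")
  # counts always sum to the input length
  total <- sum(rc$per_cluster) + rc$excluded_missing_dominance +
    rc$excluded_outlier + rc$excluded_wide_ci + rc$unaccounted
  expect_equal(total, rc$n)
  # single-cluster list
  rc2 <- reclassify_codes(c("100", "101", "102"), cl)
  expect_equal(unname(rc2$per_cluster), c(3L, 0L))
  expect_equal(rc2$unaccounted, 0L)
})
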