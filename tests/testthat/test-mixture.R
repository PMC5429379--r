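test_that("parameter counts follow the decomposition counting rule", {
  expect_equal(gmm_nparams("VVV", 1), 9L)
  expect_equal(gmm_nparams("VEV", 5), 41L)
  expect_equal(gmm_nparams("EII", 1), 4L)
  # independent counter from the reference mixture implementation
  for (fam in gmm_families()$name) {
    for (k in c(1L, 3L, 5L, 9L)) {
      expect_equal(gmm_nparams(fam, k),
                   as.integer(mclust::nMclustParams(fam, d = 3, G = k)),
                   info = paste(fam, k))
    }
  }
  expect_error(gmm_nparams("ZZZ", 2), "unknown")
})

test_that("k = 1 fits equal the closed-form maximum-likelihood solution", {
  set.seed(5)
  X <- matrix(stats::rnorm(300), ncol = 3) %*%
    matrix(c(1, .3, 0, .3, 1, .2, 0, .2, 1), 3)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)
  fit <- em_fit(X, 1, "VVV")
  expect_equal(as.numeric(fit$mean), mu, tolerance = 1e-10)
  expect_equal(fit$Sigma[[1]], S, tolerance = 1e-10)
  expect_equal(fit$loglik, sum(mvn_loglik_rows(X, mu, S)), tolerance = 1e-10)
  fit_sph <- em_fit(X, 1, "EII")
  expect_equal(fit_sph$Sigma[[1]], diag(mean(diag(S)), 3), tolerance = 1e-10)
})

test_that("the log-likelihood trace is non-decreasing on every fit", {
  blobs <- easy_blobs(50, sd = 0.8, seed = 2)
  for (fam in gmm_families()$name) {
    for (k in 2:4) {
      fit <- em_fit(blobs$X, k, fam)
      expect_true(all(diff(fit$loglik_trace) > -1e-10),
                  info = paste(fam, k))
    }
  }
})

test_that("well-separated blobs are recovered exactly with tight centroids", {
  blobs <- make_blobs(80, rbind(c(0, 0, 0), c(10, 10, 10)), sd = 0.5,
                      seed = 3)
  fit <- em_fit(blobs$X, 2, "EII")
  cl <- classify(fit, blobs$X)
  expect_equal(compare_partitions(cl$cluster, blobs$labels)$ari, 1)
  ord <- order(fit$mean[1, ])
  expect_lt(max(abs(fit$mean[, ord] - cbind(c(0, 0, 0), c(10, 10, 10)))),
            0.1)
})

test_that("fits agree with the reference EM implementation on easy data", {
  withr::local_package("mclust")
  blobs <- easy_blobs(70, sd = 0.5, seed = 11)
  for (fam in c("EII", "VVI", "VEV", "VVV")) {
    fit <- em_fit(blobs$X, 3, fam)
    ref <- mclust::Mclust(blobs$X, G = 3, modelNames = fam,
                          verbose = FALSE)
    expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6,
                 info = fam)
    expect_equal(fit$bic, as.numeric(ref$bic), tolerance = 1e-6,
                 info = fam)
    cl <- classify(fit, blobs$X)
    expect_equal(compare_partitions(cl$cluster,
                                    ref$classification)$ari, 1,
                 info = fam)
  }
})

test_that("flexibility is ordered: looser families never fit worse", {
  blobs <- easy_blobs(80, sd = 0.4, seed = 13)
  for (k in 2:3) {
    ll <- vapply(c(VII = "VII", VEV = "VEV", VVV = "VVV"), function(f) {
      em_fit(blobs$X, k, f)$loglik
    }, 0)
    expect_gte(ll["VVV"], ll["VEV"] - 1e-6)
    expect_gte(ll["VEV"], ll["VII"] - 1e-6)
  }
})

test_that("responsibilities are normalised and uncertainties behave", {
  blobs <- easy_blobs(40, seed = 4)
  fit <- em_fit(blobs$X, 3, "VVI")
  cl <- classify(fit, blobs$X)
  expect_equal(rowSums(cl$z), rep(1, nrow(blobs$X)), tolerance = 1e-12)
  expect_true(all(cl$uncertainty >= 0 & cl$uncertainty <= 1 - 1 / 3))
  expect_equal(sum(cl$summary$size), nrow(blobs$X))

  # symmetric two-component model: the midpoint has uncertainty 1/2,
  # a point 20 sd from all components but one essentially 0
  sym <- .gmm_toy(mu = cbind(c(-10, 0, 0), c(10, 0, 0)))
  mid <- classify(sym, matrix(c(0, 0, 0), 1))
  expect_equal(mid$uncertainty, 0.5, tolerance = 1e-12)
  near <- classify(sym, matrix(c(-10, 0, 0), 1))
  expect_lt(near$uncertainty, 1e-6)
})

test_that("classification errors on dimension mismatch and new data work", {
  blobs <- easy_blobs(30, seed = 6)
  fit <- em_fit(blobs$X, 3, "EII")
  expect_error(classify(fit, blobs$X[, 1:2]), "dimension")
  new <- easy_blobs(10, seed = 60)
  cl <- classify(fit, new$X)
  expect_equal(compare_partitions(cl$cluster, new$labels)$ari, 1)
})

test_that("degenerate inputs raise argument or degeneracy errors", {
  X <- matrix(stats::rnorm(30), ncol = 3)
  expect_error(em_fit(X, 10), "n > k")
  expect_error(em_fit(X, 0), "k must be")
  # duplicated single point in a tiny sample collapses a component
  Xbad <- rbind(matrix(0, 5, 3), matrix(stats::rnorm(15), 5, 3))
  expect_error(em_fit(Xbad, 2, "VVV"),
               class = "affectselect_degenerate_fit")
})

test_that("BIC selection is reproducible and consistent on easy cases", {
  # single spherical Gaussian: one component wins
  set.seed(17)
  X1 <- matrix(stats::rnorm(1500), ncol = 3)
  sel1 <- select_model(X1, k_range = 1:3,
                       families = c("EII", "VEV", "VVV"))
  expect_equal(sel1$best$k, 1L)
  # deterministic: identical surfaces on repeated runs
  blobs <- easy_blobs(60, seed = 19)
  s1 <- select_model(blobs$X, 1:4, c("EII", "VEV"))
  s2 <- select_model(blobs$X, 1:4, c("EII", "VEV"))
  expect_identical(s1$surface, s2$surface)
  expect_equal(s1$best$k, 3L)
  # gmm_bic matches the stored value and the definition
  expect_equal(gmm_bic(s1$best), s1$best$bic)
  expect_equal(gmm_bic(s1$best),
               2 * s1$best$loglik - s1$best$n_params * log(s1$best$n_obs))
})

test_that("the fitted decomposition satisfies the family constraints", {
  blobs <- easy_blobs(70, sd = 0.6, seed = 23)
  fit <- em_fit(blobs$X, 3, "VEV")
  dec <- fit$decomposition
  # det-1 shapes, shared across components (VEV ties the shape)
  shapes <- sapply(dec, function(d) sort(d$shape))
  expect_equal(apply(shapes, 1, function(r) max(r) - min(r)),
               rep(0, 3), tolerance = 1e-6)
  expect_equal(prod(dec[[1]]$shape), 1, tolerance = 1e-8)
  for (d in dec) {
    expect_equal(crossprod(d$orientation), diag(3), tolerance = 1e-8)
  }
  expect_equal(sum(fit$pro), 1, tolerance = 1e-12)
  expect_true(all(fit$pro > 0))
})
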