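# ---- internal: log densities and E-step -------------------------------------

# log N(x | mu, Sigma) for all rows of X; Sigma via Cholesky.
.log_mvn <- function(X, mu, Sigma) {
  d <- ncol(X)
  R <- chol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  Xc <- sweep(X, 2L, mu, "-")
  Z <- forwardsolve(t(R), t(Xc))
  maha <- colSums(Z^2)
  -0.5 * (d * log(2 * pi) + logdet + maha)
}

# responsibilities + loglik from current parameters
.e_step <- function(X, pro, mean, Sigma) {
  k <- length(pro)
  n <- nrow(X)
  logd <- matrix(0, n, k)
  for (g in seq_len(k)) {
    logd[, g] <- log(pro[g]) + .log_mvn(X, mean[, g], Sigma[[g]])
  }
  m <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
  ll_i <- m + log(rowSums(exp(logd - m)))
  z <- exp(logd - ll_i)
  list(z = z, loglik = sum(ll_i))
}

# ---- internal: constrained covariance M-steps -------------------------------

# W: list of k scatter matrices sum_i z_ig (x_i - mu_g)(x_i - mu_g)';
# ng: effective component sizes; n: total observations.
.cov_mstep <- function(family, W, ng, n, inner_tol = 1e-8, inner_max = 100L) {
  d <- nrow(W[[1L]])
  k <- length(W)
  I <- diag(d)
  detd <- function(v) prod(v)^(1 / d)
  switch(family,
    EII = {
      lambda <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
      rep(list(lambda * I), k)
    },
    VII = {
      lapply(seq_len(k), function(g) {
        (sum(diag(W[[g]])) / (ng[g] * d)) * I
      })
    },
    EEI = {
      B <- diag(Reduce(`+`, W))
      lam <- detd(B) / n
      A <- B / detd(B)
      rep(list(lam * diag(A, d)), k)
    },
    VEI = {
      Bg <- lapply(W, diag)
      lambda <- vapply(seq_len(k), function(g) sum(Bg[[g]]) / (ng[g] * d), 0)
      A <- rep(1, d)
      for (it in seq_len(inner_max)) {
        S <- Reduce(`+`, lapply(seq_len(k), function(g) Bg[[g]] / lambda[g]))
        A_new <- S / detd(S)
        lambda_new <- vapply(seq_len(k), function(g) {
          sum(Bg[[g]] / A_new) / (ng[g] * d)
        }, 0)
        done <- max(abs(A_new - A)) < inner_tol &&
          max(abs(lambda_new - lambda) / (abs(lambda) + 1e-300)) < inner_tol
        A <- A_new
        lambda <- lambda_new
        if (done) break
      }
      lapply(seq_len(k), function(g) lambda[g] * diag(A, d))
    },
    EVI = {
      Bg <- lapply(W, diag)
      dets <- vapply(Bg, detd, 0)
      lam <- sum(dets) / n
      lapply(seq_len(k), function(g) lam * diag(Bg[[g]] / dets[g], d))
    },
    VVI = {
      lapply(seq_len(k), function(g) diag(diag(W[[g]]) / ng[g], d))
    },
    EEE = {
      S <- Reduce(`+`, W) / n
      rep(list(S), k)
    },
    EEV = {
      eig <- lapply(W, function(w) eigen(w, symmetric = TRUE))
      Om <- Reduce(`+`, lapply(eig, function(e) pmax(e$values, 0)))
      lam <- detd(Om) / n
      A <- Om / detd(Om)
      lapply(seq_len(k), function(g) {
        D <- eig[[g]]$vectors
        lam * D %*% diag(A, d) %*% t(D)
      })
    },
    VEV = {
      eig <- lapply(W, function(w) eigen(w, symmetric = TRUE))
      Om <- lapply(eig, function(e) pmax(e$values, 0))
      lambda <- vapply(seq_len(k), function(g) sum(Om[[g]]) / (ng[g] * d), 0)
      A <- rep(1, d)
      for (it in seq_len(inner_max)) {
        S <- Reduce(`+`, lapply(seq_len(k), function(g) Om[[g]] / lambda[g]))
        A_new <- S / detd(S)
        lambda_new <- vapply(seq_len(k), function(g) {
          sum(Om[[g]] / A_new) / (ng[g] * d)
        }, 0)
        done <- max(abs(A_new - A)) < inner_tol &&
          max(abs(lambda_new - lambda) / (abs(lambda) + 1e-300)) < inner_tol
        A <- A_new
        lambda <- lambda_new
        if (done) break
      }
      lapply(seq_len(k), function(g) {
        D <- eig[[g]]$vectors
        lambda[g] * D %*% diag(A, d) %*% t(D)
      })
    },
    VVV = {
      lapply(seq_len(k), function(g) W[[g]] / ng[g])
    },
    stop("unknown covariance family: ", family, call. = FALSE)
  )
}

# volume/shape/orientation factors of a fitted covariance list
.decompose_cov <- function(Sigma) {
  lapply(Sigma, function(S) {
    e <- eigen(S, symmetric = TRUE)
    lam <- prod(e$values)^(1 / length(e$values))
    list(volume = lam, shape = e$values / lam, orientation = e$vectors)
  })
}

.degenerate_fit <- function(msg, trace) {
  structure(
    class = c("affectselect_degenerate_fit", "error", "condition"),
    list(message = msg, call = NULL, trace = trace)
  )
}

# ---- user-facing fitting ----------------------------------------------------

#' Fit a Gaussian mixture by EM under a constrained covariance family
#'
#' Maximum-likelihood fit of a \code{k}-component Gaussian mixture to the
#' rows of \code{X}, with the component covariances constrained to one of
#' the ten volume/shape/orientation families (see [gmm_families()]). The
#' E-step computes responsibilities from the current parameters; the M-step
#' updates weights, means and the constrained covariances (families
#' \code{VEI} and \code{VEV} use an inner fixed-point solver for the shared
#' shape). Iteration stops when the relative log-likelihood change falls
#' below \code{tol}.
#'
#' Initialisation defaults to a deterministic Ward-linkage agglomeration of
#' the data cut at \code{k} groups, so repeated fits on the same data give
#' identical results. Pass an integer vector of starting labels via
#' \code{init} to override.
#'
#' @param X Numeric matrix, observations in rows (typically n x 3 PAD
#'   means).
#' @param k Number of components, \code{1 <= k < nrow(X)}.
#' @param family Covariance family name, e.g. \code{"VEV"}.
#' @param init \code{"ward"} (default) or an integer vector of length
#'   \code{nrow(X)} with starting labels in \code{1..k}.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param eigen_floor Relative floor on covariance eigenvalues: a component
#'   whose smallest covariance eigenvalue drops below
#'   \code{eigen_floor * mean(diag(cov(X)))} triggers a degenerate-fit
#'   error, as does a component weight below \code{1/(10 n)}.
#' @return An object of class \code{"gmm_fit"}: a list with elements
#'   \code{k}, \code{family}, \code{pro} (mixing weights), \code{mean}
#'   (d x k), \code{Sigma} (list of covariances), \code{decomposition}
#'   (volume/shape/orientation factors), \code{loglik}, \code{loglik_trace},
#'   \code{n_params}, \code{bic}, \code{n_obs}, \code{iterations},
#'   \code{converged}.
#' @seealso [select_model()], [classify()], [gmm_bic()]
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(150, 0), ncol = 3),
#'            matrix(rnorm(150, 8), ncol = 3))
#' fit <- em_fit(X, k = 2, family = "EII")
#' fit$pro
#' @export
em_fit <- function(X, k, family = "VEV", init = "ward",
                   tol = 1e-8, max_iter = 1000L, eigen_floor = 1e-10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  d <- ncol(X)
  if (!all(is.finite(X))) stop("X must be finite", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k) stop("need more observations than components (n > k)",
                   call. = FALSE)
  fam <- .family_row(family)
  scale_ref <- mean(apply(X, 2L, stats::var))
  eig_floor_abs <- eigen_floor * scale_ref
  w_floor <- 1 / (10 * n)

  if (k == 1L) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu, "-")
    W <- list(crossprod(Xc))
    Sigma <- .cov_mstep(family, W, ng = n, n = n)
    ll <- sum(.log_mvn(X, mu, Sigma[[1L]]))
    return(.gmm_fit_obj(k, family, pro = 1, mean = matrix(mu, d, 1),
                        Sigma = Sigma, loglik = ll, trace = ll, n = n,
                        iterations = 0L, converged = TRUE))
  }

  # starting hard labels
  if (is.character(init) && identical(init, "ward")) {
    labels <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"),
                            k = k)
  } else if (is.numeric(init) && length(init) == n) {
    labels <- as.integer(init)
    if (!all(labels %in% seq_len(k))) {
      stop("init labels must lie in 1..k", call. = FALSE)
    }
  } else {
    stop("init must be \"ward\" or an integer label vector", call. = FALSE)
  }
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), labels)] <- 1

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  pro <- mean_mat <- Sigma <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ng <- colSums(z)
    if (any(ng < w_floor * n)) {
      stop(.degenerate_fit(
        sprintf("component collapsed (weight below 1/(10n)) at iteration %d",
                iter), loglik_trace))
    }
    pro <- ng / n
    mean_mat <- crossprod(X, z)
    mean_mat <- sweep(mean_mat, 2L, ng, "/")
    W <- lapply(seq_len(k), function(g) {
      Xc <- sweep(X, 2L, mean_mat[, g], "-")
      crossprod(Xc * z[, g], Xc)
    })
    Sigma <- .cov_mstep(family, W, ng, n)
    min_eig <- vapply(Sigma, function(S) min(eigen(S, symmetric = TRUE,
                                                   only.values = TRUE)$values),
                      0)
    if (any(min_eig < eig_floor_abs)) {
      stop(.degenerate_fit(
        sprintf("singular component covariance at iteration %d", iter),
        loglik_trace))
    }
    es <- .e_step(X, pro, mean_mat, Sigma)
    z <- es$z
    loglik_trace <- c(loglik_trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  .gmm_fit_obj(k, family, pro, mean_mat, Sigma, loglik = ll_old,
               trace = loglik_trace, n = n, iterations = iter,
               converged = converged)
}

.gmm_fit_obj <- function(k, family, pro, mean, Sigma, loglik, trace, n,
                         iterations, converged) {
  m <- gmm_nparams(family, k, d = nrow(mean))
  structure(list(
    k = as.integer(k),
    family = family,
    pro = as.numeric(pro),
    mean = mean,
    Sigma = Sigma,
    decomposition = .decompose_cov(Sigma),
    loglik = loglik,
    loglik_trace = trace,
    n_params = m,
    n_obs = as.integer(n),
    bic = 2 * loglik - m * log(n),
    iterations = as.integer(iterations),
    converged = converged
  ), class = "gmm_fit")
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' Uses the mixture-modelling sign convention \eqn{2\hat\ell - m \log n},
#' so larger values indicate better models and the BIC is maximised during
#' model selection.
#'
#' @param model A \code{"gmm_fit"} object from [em_fit()].
#' @return The BIC value (numeric scalar).
#' @export
gmm_bic <- function(model) {
  if (!inherits(model, "gmm_fit")) stop("not a fitted mixture", call. = FALSE)
  if (is.null(model$loglik) || !is.finite(model$loglik)) {
    stop("model has no fitted log-likelihood", call. = FALSE)
  }
  2 * model$loglik - model$n_params * log(model$n_obs)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %s, k = %d, n = %d\n",
              x$family, x$k, x$n_obs))
  cat(sprintf("  loglik = %.4f  params = %d  BIC = %.4f\n",
              x$loglik, x$n_params, x$bic))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$pro), collapse = " "),
      "\n")
  invisible(x)
}

#' Select a mixture model by BIC over components and covariance families
#'
#' Fits every combination of component count in \code{k_range} and family
#' in \code{families} with [em_fit()] and returns the fit maximising the
#' BIC, together with the full BIC surface for reporting. Fits that
#' degenerate (collapsing components or singular covariances) are recorded
#' in the surface with \code{NA} BIC and excluded from selection. Ties are
#' broken toward fewer components, then toward the more parsimonious
#' family. With the default deterministic initialisation the result is
#' reproducible run to run.
#'
#' @param X Numeric data matrix (rows = stimuli).
#' @param k_range Integer vector of component counts (default \code{1:9}).
#' @param families Character vector of family names (default all ten).
#' @param ... Passed to [em_fit()].
#' @return A list of class \code{"gmm_selection"} with elements
#'   \code{best} (the winning \code{"gmm_fit"}) and \code{surface} (a data
#'   frame with one row per (k, family): \code{k}, \code{family},
#'   \code{loglik}, \code{n_params}, \code{bic}, \code{error}).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(120, 0), ncol = 3),
#'            matrix(rnorm(120, 6), ncol = 3))
#' sel <- select_model(X, k_range = 1:3, families = c("EII", "VVV"))
#' sel$best$k
#' @export
select_model <- function(X, k_range = 1:9, families = gmm_families()$name,
                         ...) {
  X <- as.matrix(X)
  grid <- expand.grid(k = k_range, family = families,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  surface <- data.frame(k = grid$k, family = grid$family,
                        loglik = NA_real_, n_params = NA_integer_,
                        bic = NA_real_, error = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(em_fit(X, k = grid$k[i], family = grid$family[i], ...),
                    error = function(e) e)
    if (inherits(fit, "gmm_fit")) {
      fits[[i]] <- fit
      surface$loglik[i] <- fit$loglik
      surface$n_params[i] <- fit$n_params
      surface$bic[i] <- fit$bic
    } else {
      surface$error[i] <- conditionMessage(fit)
    }
  }
  ok <- !is.na(surface$bic)
  if (!any(ok)) {
    stop("all mixture fits failed:\n",
         paste(unique(stats::na.omit(surface$error)), collapse = "\n"),
         call. = FALSE)
  }
  # max BIC; ties -> smaller k, then fewer parameters
  cand <- which(ok)
  cand <- cand[order(-surface$bic[cand], surface$k[cand],
                     surface$n_params[cand])]
  best_i <- cand[1L]
  structure(list(best = fits[[best_i]], surface = surface),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat("BIC model selection over", nrow(x$surface), "fits\n")
  cat("Best model:\n")
  print(x$best)
  invisible(x)
}

#' Classify stimuli under a fitted mixture
#'
#' Computes posterior responsibilities \eqn{\tau_{ig}}, hard labels
#' \eqn{\arg\max_g \tau_{ig}} and classification uncertainties
#' \eqn{u_i = 1 - \max_g \tau_{ig}} for the rows of \code{X}, which need
#' not be the data the model was fitted to (so a model fitted to one half
#' of a sample can classify the other half).
#'
#' @param model A \code{"gmm_fit"}.
#' @param X Data matrix with the model's dimension.
#' @param codes Optional character identifiers, one per row of \code{X}.
#' @return Object of class \code{"gmm_classification"}: list with
#'   \code{codes}, \code{z} (n x k responsibilities), \code{cluster} (hard
#'   labels), \code{uncertainty}, \code{summary} (per-cluster size and mean
#'   uncertainty).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(90, 0), ncol = 3),
#'            matrix(rnorm(90, 7), ncol = 3))
#' fit <- em_fit(X, k = 2, family = "EII")
#' cl <- classify(fit, X)
#' table(cl$cluster)
#' @export
classify <- function(model, X, codes = NULL) {
  if (!inherits(model, "gmm_fit")) stop("not a fitted mixture", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$mean)) {
    stop("data dimension does not match the model", call. = FALSE)
  }
  if (is.null(codes)) {
    codes <- rownames(X)
    if (is.null(codes)) codes <- as.character(seq_len(nrow(X)))
  }
  if (length(codes) != nrow(X)) {
    stop("codes length must match nrow(X)", call. = FALSE)
  }
  es <- .e_step(X, model$pro, model$mean, model$Sigma)
  cluster <- max.col(es$z, ties.method = "first")
  uncertainty <- 1 - es$z[cbind(seq_len(nrow(X)), cluster)]
  sizes <- tabulate(cluster, nbins = model$k)
  summary <- data.frame(
    cluster = seq_len(model$k),
    size = sizes,
    mixing_prop = model$pro,
    mean_uncertainty = vapply(seq_len(model$k), function(g) {
      if (sizes[g] == 0) NA_real_ else mean(uncertainty[cluster == g])
    }, 0)
  )
  structure(list(codes = as.character(codes), z = es$z, cluster = cluster,
                 uncertainty = uncertainty, k = model$k, summary = summary,
                 loglik = es$loglik),
            class = "gmm_classification")
}

#' @export
print.gmm_classification <- function(x, ...) {
  cat(sprintf("Classification of %d stimuli into %d clusters\n",
              length(x$cluster), x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Turn a classification into a plain data frame
#'
#' @param x A \code{"gmm_classification"}.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return Data frame with columns \code{code}, \code{cluster},
#'   \code{uncertainty}.
#' @export
as.data.frame.gmm_classification <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(code = x$codes, cluster = x$cluster,
             uncertainty = x$uncertainty, stringsAsFactors = FALSE)
}
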