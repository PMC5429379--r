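# ---- partition agreement -----------------------------------------------------

#' Compare two partitions of the same stimulus set
#'
#' Builds the contingency table of two hard clusterings and derives the
#' agreement measures used to compare clustering solutions:
#' \itemize{
#'   \item Variation of Information \eqn{VI = H(P_1) + H(P_2) - 2 I}, with
#'     natural-log entropies over label proportions -- a metric on
#'     partitions, 0 iff they coincide up to relabeling; normalised here by
#'     its universal bound \eqn{\ln n}.
#'   \item Adjusted Rand Index -- pair-counting agreement corrected for
#'     chance under the permutation model; 1 iff identical up to
#'     relabeling, about 0 for random labelings.
#'   \item Cramér's \eqn{\phi}: \eqn{\sqrt{\chi^2 / (n (\min(r,c) - 1))}}
#'     from the Pearson chi-squared statistic of the contingency table
#'     (no continuity correction; empty rows/columns dropped first).
#' }
#'
#' @param p1,p2 Label vectors (or \code{"partition"} objects) over the same
#'   items, in the same order.
#' @return Object of class \code{"concordance_report"}: contingency table,
#'   entropies, mutual information \code{I}, \code{vi}, \code{nvi},
#'   \code{ari}, \code{phi}, \code{chisq}, \code{n}.
#' @examples
#' compare_partitions(c(1, 1, 2, 2), c(1, 2, 1, 2))$ari # -0.5
#' @export
compare_partitions <- function(p1, p2) {
  if (inherits(p1, "partition")) p1 <- p1$labels
  if (inherits(p2, "partition")) p2 <- p2$labels
  if (inherits(p1, "gmm_classification")) p1 <- p1$cluster
  if (inherits(p2, "gmm_classification")) p2 <- p2$cluster
  if (length(p1) != length(p2)) {
    stop("partitions must cover the same item set", call. = FALSE)
  }
  n <- length(p1)
  tab <- table(p1, p2)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pj <- tab / n
  H1 <- -sum(pr * log(pr))
  H2 <- -sum(pc * log(pc))
  nz <- pj > 0
  I <- sum(pj[nz] * log(pj[nz] / (pr[row(pj)[nz]] * pc[col(pj)[nz]])))
  vi <- max(0, H1 + H2 - 2 * I)
  nvi <- if (n > 1) vi / log(n) else 0

  # adjusted Rand from pair counts
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  ntot <- comb2(n)
  expected <- sum_a * sum_b / ntot
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else
    (sum_ij - expected) / (max_idx - expected)

  # Pearson chi-squared and Cramer's phi
  E <- outer(rowSums(tab), colSums(tab)) / n
  chisq <- sum((tab - E)^2 / E)
  mindim <- min(nrow(tab), ncol(tab))
  phi <- if (mindim >= 2) {
    sqrt(chisq / (n * (mindim - 1)))
  } else if (nrow(tab) == 1L && ncol(tab) == 1L) {
    1   # both partitions are the single all-inclusive cluster: identical
  } else {
    NA_real_   # association with a constant labeling is undefined
  }

  structure(list(contingency = tab, n = n, H1 = H1, H2 = H2, I = I,
                 vi = vi, nvi = nvi, ari = ari, chisq = chisq, phi = phi),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Partition concordance (n = %d): VI = %.4f (normalised %.4f), ARI = %.4f, phi = %.4f\n",
    x$n, x$vi, x$nvi, x$ari, x$phi))
  invisible(x)
}

# ---- stability validation ----------------------------------------------------

.stability_report <- function(mode, reps, seed, full_k = NA_integer_) {
  ks <- reps$k[!is.na(reps$k)]
  modal_k <- if (length(ks)) {
    as.integer(names(sort(table(ks), decreasing = TRUE))[1L])
  } else NA_integer_
  structure(list(mode = mode, reps = reps, modal_k = modal_k,
                 full_k = full_k, seed = seed,
                 summary = c(mean_ari = mean(reps$ari, na.rm = TRUE),
                             mean_nvi = mean(reps$nvi, na.rm = TRUE),
                             mean_phi = mean(reps$phi, na.rm = TRUE))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s stability: %d repetitions, modal k = %s\n", x$mode,
              nrow(x$reps), x$modal_k))
  cat(sprintf("  mean ARI = %.4f, mean normalised VI = %.4f, mean phi = %.4f\n",
              x$summary["mean_ari"], x$summary["mean_nvi"],
              x$summary["mean_phi"]))
  invisible(x)
}

#' Split-half stability of model-based clustering
#'
#' Repeatedly splits the stimuli into two random halves, selects a mixture
#' model on each half independently, and uses each half's model to predict
#' the classification of the other half. Agreement (ARI, normalised VI,
#' Cramér's phi) between the predicted and independently fitted labels of
#' a half measures whether both halves support the same cluster
#' structure; the two directions are averaged per repetition.
#'
#' @param X Data matrix.
#' @param codes Optional stimulus identifiers.
#' @param R Number of repetitions (default 20).
#' @param k_range,families Model search space per half (see
#'   [select_model()]).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A \code{"stability_report"}; \code{reps} holds per-repetition
#'   selected \code{k} (half A), \code{k_b}, and agreement metrics.
#' @export
split_half <- function(X, codes = NULL, R = 20L, k_range = 1:9,
                       families = gmm_families()$name, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * (max(k_range) + 1)) {
    stop("sample too small to split for the requested k range",
         call. = FALSE)
  }
  set.seed(seed)
  reps <- data.frame(rep = seq_len(R), k = NA_integer_, k_b = NA_integer_,
                     ari = NA_real_, nvi = NA_real_, phi = NA_real_)
  for (r in seq_len(R)) {
    idx <- sample.int(n)
    a <- idx[seq_len(floor(n / 2))]
    b <- idx[(floor(n / 2) + 1L):n]
    res <- tryCatch({
      fit_a <- select_model(X[a, , drop = FALSE], k_range, families)$best
      fit_b <- select_model(X[b, , drop = FALSE], k_range, families)$best
      pred_b <- classify(fit_a, X[b, , drop = FALSE])$cluster
      own_b <- classify(fit_b, X[b, , drop = FALSE])$cluster
      pred_a <- classify(fit_b, X[a, , drop = FALSE])$cluster
      own_a <- classify(fit_a, X[a, , drop = FALSE])$cluster
      cb <- compare_partitions(pred_b, own_b)
      ca <- compare_partitions(pred_a, own_a)
      list(k = fit_a$k, k_b = fit_b$k,
           ari = (cb$ari + ca$ari) / 2, nvi = (cb$nvi + ca$nvi) / 2,
           phi = (cb$phi + ca$phi) / 2)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      reps$k[r] <- res$k; reps$k_b[r] <- res$k_b
      reps$ari[r] <- res$ari; reps$nvi[r] <- res$nvi; reps$phi[r] <- res$phi
    }
  }
  .stability_report("split-half", reps, seed)
}

#' Jack-knife stability of model-based clustering
#'
#' Repeatedly deletes a random fraction of the stimuli, re-runs BIC model
#' selection on the remainder, and cross-tabulates the retained stimuli's
#' new labels against the full-data solution. Stable structure shows up as
#' a steady selected \code{k} and high agreement despite the deletions.
#' Fit failures are recorded per repetition, not fatal.
#'
#' @param X Data matrix.
#' @param codes Optional stimulus identifiers.
#' @param fraction Fraction of stimuli deleted per repetition, in
#'   \[0, 1) (default 0.10).
#' @param B Number of repetitions (default 2000, the "few thousand" scale;
#'   use a smaller B for interactive work).
#' @param k_range,families Model search space (see [select_model()]).
#' @param seed Integer seed.
#' @return A \code{"stability_report"} with per-repetition selected
#'   \code{k} and agreement with the full-data solution; \code{full_k}
#'   records the full-data model's k.
#' @export
jackknife <- function(X, codes = NULL, fraction = 0.10, B = 2000L,
                      k_range = 1:9, families = gmm_families()$name,
                      seed = 1L) {
  X <- as.matrix(X)
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  n <- nrow(X)
  set.seed(seed)
  full <- select_model(X, k_range, families)$best
  full_lab <- classify(full, X)$cluster
  n_drop <- floor(fraction * n)
  reps <- data.frame(rep = seq_len(B), k = NA_integer_, ari = NA_real_,
                     nvi = NA_real_, phi = NA_real_,
                     error = NA_character_)
  for (r in seq_len(B)) {
    keep <- if (n_drop > 0) sort(sample.int(n)[-seq_len(n_drop)]) else
      seq_len(n)
    # sample.int draws a permutation; dropping its head is a uniform
    # random deletion of n_drop items
    res <- tryCatch({
      fit <- select_model(X[keep, , drop = FALSE], k_range, families)$best
      lab <- classify(fit, X[keep, , drop = FALSE])$cluster
      cc <- compare_partitions(lab, full_lab[keep])
      list(k = fit$k, ari = cc$ari, nvi = cc$nvi, phi = cc$phi)
    }, error = function(e) conditionMessage(e))
    if (is.list(res)) {
      reps$k[r] <- res$k; reps$ari[r] <- res$ari
      reps$nvi[r] <- res$nvi; reps$phi[r] <- res$phi
    } else {
      reps$error[r] <- res
    }
  }
  .stability_report("jack-knife", reps, seed, full_k = full$k)
}
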