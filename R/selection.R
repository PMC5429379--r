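#' Selection configuration
#'
#' @param p_ok,p_risky Uncertainty percentiles (0-100) bounding the
#'   usability bands: uncertainties at or below the \code{p_ok}-th
#'   percentile are \code{"ok"} stimuli, those between \code{p_ok} and
#'   \code{p_risky} are \code{"risky"} candidates, and those above
#'   \code{p_risky} should be avoided -- the conventional 75/95 split of
#'   classification-uncertainty plots. Must satisfy
#'   \code{0 < p_ok < p_risky < 100}.
#' @param n_per_cluster Number of exemplars to retain per cluster
#'   (default 20).
#' @return A list of class \code{"selection_config"}.
#' @export
selection_config <- function(p_ok = 75, p_risky = 95, n_per_cluster = 20L) {
  stopifnot(p_ok > 0, p_ok < p_risky, p_risky < 100, n_per_cluster > 0)
  structure(list(p_ok = p_ok, p_risky = p_risky,
                 n_per_cluster = as.integer(n_per_cluster)),
            class = "selection_config")
}

#' Band stimuli by classification uncertainty
#'
#' Computes the \code{p_ok}-th and \code{p_risky}-th percentiles of the
#' uncertainties (linear-interpolation quantiles over the full classified
#' sample) and assigns each stimulus a usability band: \code{"ok"} (at or
#' below the first threshold), \code{"risky"}, or \code{"avoid"} (above
#' the second).
#'
#' @param uncertainty Numeric vector of classification uncertainties.
#' @param p_ok,p_risky Percentile thresholds, see [selection_config()].
#' @return Character vector of bands with attribute \code{thresholds}.
#' @export
usability_bands <- function(uncertainty, p_ok = 75, p_risky = 95) {
  if (!length(uncertainty)) {
    return(structure(character(0),
                     thresholds = c(ok = NA_real_, risky = NA_real_)))
  }
  q <- stats::quantile(uncertainty, probs = c(p_ok, p_risky) / 100,
                       names = FALSE, type = 7)
  bands <- ifelse(uncertainty <= q[1L], "ok",
                  ifelse(uncertainty <= q[2L], "risky", "avoid"))
  structure(bands, thresholds = c(ok = q[1L], risky = q[2L]))
}

#' Select uncertainty-ranked representative stimuli per cluster
#'
#' Ranks the members of every cluster by ascending classification
#' uncertainty (ties broken by code, lexicographically, for reproducible
#' output) and retains the first \code{n_per_cluster} of each -- the
#' stimuli that represent their cluster best. All stimuli are additionally
#' banded by the global uncertainty percentiles (see [usability_bands()]).
#' Clusters smaller than \code{n_per_cluster} return all their members
#' with a warning.
#'
#' @param classification A \code{"gmm_classification"} (from
#'   [classify()]).
#' @param config A [selection_config()].
#' @return Object of class \code{"stimulus_selection"}: \code{table} (all
#'   stimuli with \code{code}, \code{cluster}, \code{uncertainty},
#'   \code{usability_band}, \code{rank_in_cluster}, \code{selected}),
#'   \code{exemplars} (the selected subset), \code{thresholds}.
#' @export
select_representatives <- function(classification,
                                   config = selection_config()) {
  if (!inherits(classification, "gmm_classification")) {
    stop("classification must come from classify()", call. = FALSE)
  }
  if (!length(classification$cluster)) {
    stop("empty classification", call. = FALSE)
  }
  bands <- usability_bands(classification$uncertainty,
                           config$p_ok, config$p_risky)
  df <- data.frame(code = classification$codes,
                   cluster = classification$cluster,
                   uncertainty = classification$uncertainty,
                   usability_band = as.character(bands),
                   stringsAsFactors = FALSE)
  ord <- order(df$cluster, df$uncertainty, df$code)
  df <- df[ord, , drop = FALSE]
  df$rank_in_cluster <- stats::ave(seq_len(nrow(df)), df$cluster,
                                   FUN = seq_along)
  df$selected <- df$rank_in_cluster <= config$n_per_cluster
  short <- tapply(df$rank_in_cluster, df$cluster, max)
  short <- names(short)[short < config$n_per_cluster]
  if (length(short)) {
    warning("cluster(s) ", paste(short, collapse = ", "), " have fewer ",
            "than ", config$n_per_cluster, " members; all returned")
  }
  rownames(df) <- NULL
  structure(list(table = df,
                 exemplars = df[df$selected, , drop = FALSE],
                 thresholds = attr(bands, "thresholds"),
                 config = config),
            class = "stimulus_selection")
}

#' @export
print.stimulus_selection <- function(x, ...) {
  cat(sprintf(
    "Stimulus selection: %d exemplars over %d clusters (<= %d per cluster)\n",
    nrow(x$exemplars), length(unique(x$table$cluster)),
    x$config$n_per_cluster))
  cat(sprintf("  uncertainty thresholds: ok <= %.4f, risky <= %.4f\n",
              x$thresholds[1L], x$thresholds[2L]))
  invisible(x)
}

#' Redistribute an external stimulus list over the clustering
#'
#' Takes a list of stimulus codes (e.g. the stimuli another study used as
#' one affective category) and reports where they land under this
#' pipeline: counts per cluster for classified codes, counts excluded at
#' each screening stage (missing dominance, MAD outlier, wide CI), and
#' codes absent from the database altogether ("unaccounted for"). The
#' counts always sum to the input list length.
#'
#' @param codes Character vector of stimulus codes.
#' @param classification A \code{"gmm_classification"}.
#' @param screening_report A \code{"screening_report"} from
#'   [run_screening()]; optional (when omitted, exclusion counts are 0 and
#'   unmatched codes are all unaccounted for).
#' @return List of class \code{"redistribution"}: \code{per_cluster}
#'   (named integer vector), \code{excluded_missing_dominance},
#'   \code{excluded_outlier}, \code{excluded_wide_ci},
#'   \code{unaccounted}, \code{n}.
#' @export
reclassify_codes <- function(codes, classification,
                             screening_report = NULL) {
  codes <- as.character(codes)
  k <- classification$k
  cl <- classification$cluster[match(codes, classification$codes)]
  per_cluster <- vapply(seq_len(k), function(g) sum(cl == g, na.rm = TRUE),
                        0L)
  names(per_cluster) <- paste0("C", seq_len(k))
  rest <- codes[is.na(cl)]
  in_set <- function(set) if (is.null(screening_report)) rep(FALSE,
                                                             length(rest))
    else rest %in% set
  dom <- in_set(screening_report$codes_dropped_dominance)
  out <- in_set(screening_report$codes_outliers) & !dom
  wide <- in_set(screening_report$codes_wide_ci) & !dom & !out
  unacc <- !(dom | out | wide)
  structure(list(per_cluster = per_cluster,
                 excluded_missing_dominance = sum(dom),
                 excluded_outlier = sum(out),
                 excluded_wide_ci = sum(wide),
                 unaccounted = sum(unacc),
                 unaccounted_codes = rest[unacc],
                 n = length(codes)),
            class = "redistribution")
}

#' @export
print.redistribution <- function(x, ...) {
  cat(sprintf("Redistribution of %d stimulus codes\n", x$n))
  cat("  per cluster: ",
      paste(sprintf("%s=%d", names(x$per_cluster), x$per_cluster),
            collapse = " "), "\n")
  cat(sprintf(
    "  excluded: %d missing dominance, %d outlier, %d wide CI; %d unaccounted\n",
    x$excluded_missing_dominance, x$excluded_outlier, x$excluded_wide_ci,
    x$unaccounted))
  invisible(x)
}
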