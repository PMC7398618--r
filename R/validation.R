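# In vivo reporter validation rate as a function of epigenomic rank:
# a smoothing-spline rate curve pinned at effective df = 2, background rates
# from elements the ranked feature set missed, multi-dataset rank
# combination, and cumulative positive curves.

#' Fit the validation-rate curve over rank
#'
#' A cubic smoothing spline of the 0/1 validation outcomes against rank with
#' the smoothing parameter chosen so the smoother's effective degrees of
#' freedom equal \code{effective_df}. Fitted values are clipped to [0, 1] for
#' reporting.
#'
#' @param ranks numeric ranks (1 = best).
#' @param labels 0/1 (or logical) validation outcomes.
#' @param effective_df target effective df (default 2).
#' @return list(rate = function(rank) in [0, 1], fitted, df, constant): a
#'   constant-label input returns a flat fit with \code{constant = TRUE}.
#' @export
fit_validation_curve <- function(ranks, labels, effective_df = 2) {
  labels <- as.numeric(labels)
  stopifnot(length(ranks) >= 10, all(labels %in% c(0, 1)))
  if (length(unique(labels)) == 1) {
    lvl <- labels[1]
    return(list(rate = function(r) rep(lvl, length(r)),
                fitted = rep(lvl, length(ranks)), df = 0, constant = TRUE))
  }
  # smooth.spline's own df solver saturates at its default spar bound for
  # very smooth targets; solve trace(S_lambda) = effective_df over spar
  # explicitly and refit at the root
  fit0 <- smooth.spline(ranks, labels, df = effective_df)
  fit <- fit0
  if (abs(fit0$df - effective_df) > 1e-3) {
    # df(spar) can approach the target asymptotically without crossing it,
    # so minimize the gap rather than root-find
    gap <- function(sp) {
      d <- tryCatch(
        suppressWarnings(smooth.spline(ranks, labels, spar = sp)$df),
        error = function(e) NA_real_)
      if (is.na(d) || d < 1 + 1e-8) return(1e6)
      abs(d - effective_df)
    }
    sp_best <- optimize(gap, c(fit0$spar - 1, fit0$spar + 2))$minimum
    fit <- suppressWarnings(smooth.spline(ranks, labels, spar = sp_best))
  }
  rate <- function(r) pmin(1, pmax(0, predict(fit, r)$y))
  list(rate = rate, fitted = rate(ranks), df = fit$df, constant = FALSE)
}

#' Background validation rate among missed elements
#'
#' The positives among elements not overlapped by the ranked feature set,
#' divided by the number of such elements.
#'
#' @param missed_labels 0/1 labels of the missed elements.
#' @return rate in [0, 1]; NA for an empty set.
#' @export
background_rate <- function(missed_labels) {
  if (length(missed_labels) == 0) return(NA_real_)
  mean(as.numeric(missed_labels))
}

#' Combine replicate rankings by rank sum
#'
#' Elements are re-ranked by the sum of their per-dataset ranks; ties are
#' broken by element coordinate (chrom, start), then element id.
#'
#' @param rank_mat numeric matrix, elements x datasets, of ranks over the
#'   same element universe.
#' @param elements data.frame(element, chrom, start) describing the rows.
#' @return data.frame(element, rank_sum, combined_rank) in combined order.
#' @export
combine_ranks <- function(rank_mat, elements) {
  rank_mat <- as.matrix(rank_mat)
  if (nrow(rank_mat) != nrow(elements))
    stop("rank matrix and element table sizes differ")
  if (anyNA(rank_mat)) stop("mismatched element universes (NA ranks)")
  rs <- rowSums(rank_mat)
  o <- order(rs, elements$chrom, elements$start, elements$element)
  data.frame(element = elements$element[o], rank_sum = rs[o],
             combined_rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Cumulative positives as a function of rank
#'
#' @param ranks numeric ranks (1 = best).
#' @param labels 0/1 outcomes.
#' @return data.frame(rank, cumulative_positives): a non-decreasing step
#'   curve whose endpoint equals the total positives.
#' @export
cumulative_positive_curve <- function(ranks, labels) {
  o <- order(ranks)
  data.frame(rank = ranks[o],
             cumulative_positives = cumsum(as.numeric(labels)[o]))
}
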