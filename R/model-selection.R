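# Choosing the number of chromatin states from a family of emission models.
# Two strategies: (1) median best-match correlation of the full model's states
# against each simpler model; (2) mean Between-SS / Total-SS of k-means over
# the pooled emission rows of all models from both replicate series.

#' Construct an emission model
#'
#' @param emissions n_states x n_marks matrix of emission probabilities in
#'   [0, 1]; column names are histone-mark names.
#' @return object of class \code{emission_model}.
#' @export
emission_model <- function(emissions) {
  emissions <- as.matrix(emissions)
  if (any(emissions < 0 | emissions > 1))
    stop("emission probabilities must lie in [0, 1]")
  if (is.null(colnames(emissions)))
    colnames(emissions) <- paste0("mark", seq_len(ncol(emissions)))
  rownames(emissions) <- as.character(seq_len(nrow(emissions)))
  structure(list(emissions = emissions, n_states = nrow(emissions),
                 marks = colnames(emissions)), class = "emission_model")
}

#' Read/write ChromHMM-style emissions_k.txt tables
#'
#' Tab-separated, first column the state number, remaining columns one per
#' mark.
#'
#' @param path file path.
#' @return emission model.
#' @export
read_emissions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  emission_model(as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_emissions
#' @param model emission model to write.
#' @export
write_emissions <- function(model, path) {
  df <- cbind(data.frame(state = seq_len(model$n_states)),
              as.data.frame(model$emissions))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best-match correlation of each reference state against another model
#'
#' For each state (emission row) of \code{reference}, the Pearson correlation
#' with every state of \code{other}; the maximum is reported. Constant
#' emission rows have undefined correlation and contribute 0.
#'
#' @param reference,other emission models over the same mark set.
#' @return numeric vector, one value per reference state.
#' @export
best_match_correlations <- function(reference, other) {
  if (!identical(reference$marks, other$marks))
    stop("models use different mark sets")
  safe_cor <- function(a, B) {
    if (sd(a) == 0) return(rep(0, nrow(B)))
    apply(B, 1, function(b) if (sd(b) == 0) 0 else cor(a, b))
  }
  unname(apply(reference$emissions, 1, function(row)
    max(safe_cor(row, other$emissions))))
}

#' Median best-match correlation series over a model family
#'
#' @param family named list of emission models; names are the state counts k.
#' @param reference_k the full model's k (default 24).
#' @return data.frame(k, median_correlation), one row per model in the family.
#' @export
median_correlation_series <- function(family, reference_k = 24) {
  ks <- as.integer(names(family))
  if (!(reference_k %in% ks)) stop("reference model k=", reference_k, " missing")
  ref <- family[[as.character(reference_k)]]
  med <- vapply(family, function(m)
    median(best_match_correlations(ref, m)), numeric(1))
  data.frame(k = ks, median_correlation = as.numeric(med), row.names = NULL)
}

# k-means++ seeding: spreads initial centroids; D^2-weighted sampling.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Mean Between-SS / Total-SS separation ratio of k-means
#'
#' All emission rows from all models (both replicate series) are treated as
#' points in mark space. k-means (Lloyd iterations, k-means++ seeding) is run
#' \code{n_realizations} times with fresh seedings; the mean of
#' BetweenSS/TotalSS is returned. Well-separated, cohesive clusters approach 1.
#'
#' @param pooled_emissions numeric matrix of emission rows.
#' @param k number of clusters (<= number of points).
#' @param n_realizations independent clustering restarts (default 100).
#' @param iter_max Lloyd iteration cap.
#' @return mean ratio in [0, 1].
#' @export
separation_ratio <- function(pooled_emissions, k, n_realizations = 100,
                             iter_max = 300) {
  x <- as.matrix(pooled_emissions)
  if (k > nrow(x)) stop("k exceeds the number of points")
  if (k == 1) return(0)
  tot <- sum(scale(x, scale = FALSE)^2)
  if (tot == 0) return(0)
  ratios <- vapply(seq_len(n_realizations), function(i) {
    centers <- .kmeanspp_centers(unique(x), min(k, nrow(unique(x))))
    if (nrow(centers) < k) return(1)  # fewer distinct points than k
    km <- suppressWarnings(kmeans(x, centers = centers, iter.max = iter_max,
                                  algorithm = "Lloyd"))
    km$betweenss / km$totss
  }, numeric(1))
  mean(ratios)
}

#' Select the optimal number of chromatin states
#'
#' Strategy 1 (per replicate series): smallest k whose median best-match
#' correlation against the full model reaches >= \code{threshold} x its value
#' at \code{k_max}. Strategy 2 (both series pooled): smallest k whose mean
#' separation ratio reaches >= \code{threshold} x the ratio at \code{k_max}.
#'
#' @param families list of named model lists, one per replicate series
#'   (names = k as character).
#' @param threshold fraction of the value at k_max (default 0.95).
#' @param n_realizations k-means restarts per k for strategy 2.
#' @param seed optional RNG seed (strategy 2 is stochastic).
#' @return list with \code{strategy1} (k per series), \code{strategy2} (one
#'   k), \code{series1} (median-correlation tables) and \code{series2}
#'   (ratio table).
#' @export
select_state_number <- function(families, threshold = 0.95,
                                n_realizations = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ks <- sort(as.integer(names(families[[1]])))
  k_max <- max(ks)
  smallest_reaching <- function(k, value, target) {
    ok <- ks[value[match(ks, k)] >= target]
    if (length(ok) == 0) { warning("no k reaches threshold; returning k_max"); k_max }
    else min(ok)
  }
  # strategy 1: per replicate series
  series1 <- lapply(families, median_correlation_series, reference_k = k_max)
  strategy1 <- vapply(series1, function(s) {
    ref_val <- s$median_correlation[s$k == k_max]
    smallest_reaching(s$k, s$median_correlation, threshold * ref_val)
  }, numeric(1))
  # strategy 2: pooled emissions from all models of all series
  pooled <- do.call(rbind, unlist(lapply(families, function(fam)
    lapply(fam, function(m) m$emissions)), recursive = FALSE))
  ratios <- vapply(ks, function(k)
    separation_ratio(pooled, k, n_realizations = n_realizations), numeric(1))
  series2 <- data.frame(k = ks, ratio = ratios)
  strategy2 <- smallest_reaching(ks, ratios, threshold * ratios[ks == k_max])
  list(strategy1 = strategy1, strategy2 = strategy2,
       series1 = series1, series2 = series2)
}
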