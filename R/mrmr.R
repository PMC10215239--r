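#' Equal-frequency binning
#'
#' Assigns each value to one of at most `bins` equal-occupancy bins using
#' average ranks, so the binning is exactly invariant under strictly
#' monotone transforms of the input. A constant vector collapses to a
#' single bin.
#'
#' @param x Numeric vector.
#' @param bins Maximum number of bins.
#' @return Integer vector of bin ids in `1..bins`.
#' @export
eqfreq_bin <- function(x, bins) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(r / length(x) * bins)
  pmin(pmax(b, 1L), bins)
}

#' Plug-in mutual information (nats)
#'
#' Histogram estimate of the mutual information between two real vectors
#' after equal-frequency binning of each into `bins` bins. Symmetric in
#' its arguments and non-negative; a constant vector yields 0.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param bins Number of bins per variable.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, bins) {
  n <- length(x)
  if (n != length(y) || n < 2) stop("x and y must have equal length >= 2")
  .mi_binned(eqfreq_bin(x, bins), eqfreq_bin(y, bins), bins)
}

# MI (nats) from pre-binned integer vectors in 1..bins
.mi_binned <- function(bx, by, bins) {
  n <- length(bx)
  joint <- matrix(tabulate((bx - 1L) * bins + by, bins * bins),
                  bins, bins, byrow = TRUE) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  pij <- as.numeric(joint)
  pi_pj <- as.numeric(outer(px, py))
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / pi_pj[nz]))
}

.default_bins <- function(n, cap = 64L) min(cap, ceiling(sqrt(n)))

#' Rank features by minimal-redundancy maximal-relevance
#'
#' Greedy forward MRMR selection: the first pick maximizes relevance
#' (mutual information with the CRM label); each subsequent pick maximizes
#' relevance minus the mean MI with already-selected features (difference
#' scheme) or relevance divided by it (quotient scheme). Ties break by
#' registry order, making rankings fully deterministic.
#'
#' @param table Feature table from [build_table()] (or any data.frame with
#'   a `crm` column and feature columns).
#' @param k Number of features to rank (1..number of features).
#' @param scheme `"difference"` (default) or `"quotient"`.
#' @param bins Histogram bins; default `ceiling(sqrt(n))` capped at 64.
#' @param features Candidate feature names; defaults to all registry
#'   columns present in `table`.
#' @return data.frame of class `crm_ranking` with columns `rank`, `name`,
#'   `score`, `relevance`, `redundancy`.
#' @export
rank_mrmr <- function(table, k = 10L, scheme = c("difference", "quotient"),
                      bins = NULL, features = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(features))
    features <- intersect(feature_registry()$name, names(table))
  if (k <= 0) stop("k must be positive")
  k <- min(k, length(features))
  y <- table$crm
  n <- length(y)
  if (is.null(bins)) bins <- .default_bins(n)
  B <- lapply(features, function(f) eqfreq_bin(table[[f]], bins))
  names(B) <- features
  by_ <- eqfreq_bin(y, bins)
  rel <- vapply(B, function(bx) .mi_binned(bx, by_, bins), numeric(1))
  p <- length(features)
  red_sum <- numeric(p)           # sum of MI with selected features
  selected <- integer(0)
  out <- data.frame(rank = seq_len(k), name = character(k), score = numeric(k),
                    relevance = numeric(k), redundancy = numeric(k),
                    stringsAsFactors = FALSE)
  avail <- rep(TRUE, p)
  for (step in seq_len(k)) {
    if (step == 1) {
      red <- rep(0, p)
      score <- rel
    } else {
      red <- red_sum / (step - 1)
      score <- if (scheme == "difference") rel - red
               else rel / pmax(red, .Machine$double.eps)
    }
    score[!avail] <- -Inf
    pick <- which.max(score)      # first max = registry-order tie-break
    avail[pick] <- FALSE
    selected <- c(selected, pick)
    out$name[step] <- features[pick]
    out$score[step] <- score[pick]
    out$relevance[step] <- rel[pick]
    out$redundancy[step] <- red[pick]
    if (step < k) {
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(j)
        .mi_binned(B[[j]], B[[pick]], bins), numeric(1))
    }
  }
  class(out) <- c("crm_ranking", "data.frame")
  out
}
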