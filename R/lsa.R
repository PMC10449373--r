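#' Percentile-Z (normal scores) normalisation
#'
#' Ranks the series (ties averaged) and maps ranks to standard normal
#' quantiles, \eqn{z_i = \Phi^{-1}(r_i / (n + 1))}. This is the
#' normalisation used before local similarity scoring: it is
#' order-preserving and makes every series marginally near-Gaussian, so
#' scores are comparable across OTUs of very different abundance.
#'
#' @param series numeric vector of length >= 3.
#' @return normalised series; a constant series maps to all zeros with a
#'   warning (such series are excluded from association testing).
#' @export
percentile_z <- function(series) {
  n <- length(series)
  if (n < 3) stop("need at least 3 time points")
  if (anyNA(series)) stop("series contains NA; interpolate first")
  if (stats::sd(series) == 0) {
    warning("constant series: percentile-Z undefined, returning zeros")
    return(numeric(n))
  }
  stats::qnorm(rank(series, ties.method = "average") / (n + 1))
}

#' Fill missing time points of a series
#'
#' Interior gaps (e.g. dry sampling dates) are filled by linear
#' interpolation on the time index; leading/trailing gaps take the nearest
#' observed value. At least two observed points are required.
#'
#' @param series numeric vector with `NA` at missing points, or complete
#'   vector plus a logical `mask`.
#' @param mask optional logical vector, `TRUE` where observed; defaults
#'   to `!is.na(series)`.
#' @return filled series with attribute `n_interpolated`.
#' @export
interpolate_missing <- function(series, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(series)
  if (sum(mask) < 2) stop("need at least two observed points")
  idx <- seq_along(series)
  out <- stats::approx(idx[mask], series[mask], xout = idx,
                       method = "linear", rule = 2)$y
  attr(out, "n_interpolated") <- sum(!mask)
  out
}

#' Local similarity between two time series
#'
#' Dynamic-programming local similarity: the maximal sum of elementwise
#' products (or negated products, for negative association) over a pair of
#' equal-length aligned subintervals whose offset is at most `D` sampling
#' steps, divided by the series length. Unlike a global correlation it
#' detects associations confined to part of the season, and the bounded
#' delay picks up leader/follower dynamics one sampling interval apart.
#'
#' The reported delay is `d = start_x - start_y`: `d = +1` means the
#' window in `x` starts one step after the window in `y` (x lags y).
#' Score ties are resolved towards the smallest `|d|`, then positive
#' sign, then the earliest window.
#'
#' @param x,y numeric series of equal length (normalised with
#'   [percentile_z()] in the standard workflow).
#' @param D delay limit (non-negative integer), default 1.
#' @return list of class `ls_result`: `score` (>= 0), `sign` (`"+"` or
#'   `"-"`), `delay`, `start_x`, `start_y`, `length`.
#' @examples
#' x <- c(3, 1, -2, 0)
#' y <- c(0, 3, 1, -2)  # x delayed by one step
#' local_similarity(x, y, D = 1)  # score 3.5, sign "+", |delay| 1
#' @export
local_similarity <- function(x, y, D = 1) {
  if (length(x) != length(y)) stop("series lengths differ")
  res <- ls_dp_cpp(as.numeric(x), as.numeric(y), as.integer(D))
  structure(list(score = res$score,
                 sign = if (res$sign > 0) "+" else "-",
                 delay = res$delay,
                 start_x = res$start_x, start_y = res$start_y,
                 length = res$length),
            class = "ls_result")
}

#' @export
print.ls_result <- function(x, ...) {
  cat(sprintf("LS = %.4f (%s), delay %d, window x[%d..%d] vs y[%d..%d]\n",
              x$score, x$sign, x$delay, x$start_x,
              x$start_x + x$length - 1, x$start_y,
              x$start_y + x$length - 1))
  invisible(x)
}

#' Permutation p-value for a local similarity score
#'
#' Shuffles the time order of `y` and recomputes the maximal absolute LS
#' score; the p-value follows the add-one rule
#' \eqn{p = (1 + \#\{|LS_{perm}| \ge |LS_{obs}|\}) / (1 + n_{perm})} and
#' is therefore never zero.
#'
#' @inheritParams local_similarity
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(x, y, D = 1, n_perm = 1000, seed = 1L) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (n_perm < 1) stop("n_perm must be >= 1")
  withr::with_seed(as.integer(seed), {
    ls_perm_p_cpp(as.numeric(x), as.numeric(y), as.integer(D),
                  as.integer(n_perm))
  })
}

#' Shifted Spearman rank correlation (SSCC)
#'
#' Spearman correlation of `x[i]` against `y[i - d]` on the overlapping
#' points — the "global" association statistic complementing the local
#' similarity score. Significance by permutation of `y`'s time order
#' (add-one rule).
#'
#' @param x,y numeric series of equal length (raw or rank-preserving
#'   normalised; Spearman only uses ranks).
#' @param d shift, same convention as [local_similarity()] delays.
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed.
#' @return list with `rho` and `p`.
#' @export
spearman_shifted <- function(x, y, d = 0, n_perm = 999, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n - abs(d) < 5) stop("overlap shorter than 5 points")
  rho <- spearman_shift_cpp(as.numeric(x), as.numeric(y), as.integer(d))
  hits <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(b) {
      rp <- spearman_shift_cpp(as.numeric(x), sample(as.numeric(y)),
                               as.integer(d))
      abs(rp) >= abs(rho) - 1e-12
    }, TRUE))
  })
  list(rho = rho, p = (1 + hits) / (1 + n_perm))
}

#' Assemble a normalised time-series set from a table
#'
#' Converts a (filtered, rarefied) per-lake table into OTU-by-time series
#' ready for association testing: missing occasions (dry dates) are
#' linearly interpolated, each series is percentile-Z normalised, and
#' series with too few genuinely observed points or constant values are
#' dropped.
#'
#' @param table an [otutab] whose rows are one lake's present samples.
#' @param metadata metadata with `sample_id`, `time_index`, `missing`
#'   covering occasions `1..T` of that lake.
#' @param min_observed minimum number of non-interpolated points for a
#'   series to be eligible, default 6.
#' @return list of class `timeseries_set`: `otu_ids`, `X` (OTUs x T
#'   normalised), `X_raw`, `observed` (logical length T), `n_interpolated`.
#' @export
timeseries_set <- function(table, metadata, min_observed = 6) {
  md <- metadata[order(metadata$time_index), , drop = FALSE]
  T_ <- max(md$time_index)
  observed <- rep(FALSE, T_)
  m <- unclass(table)
  raw <- matrix(NA_real_, nrow = ncol(m), ncol = T_,
                dimnames = list(colnames(m), NULL))
  for (i in seq_len(nrow(md))) {
    t <- md$time_index[i]
    if (!md$missing[i] && md$sample_id[i] %in% rownames(m)) {
      observed[t] <- TRUE
      raw[, t] <- m[md$sample_id[i], ]
    }
  }
  n_obs <- sum(observed)
  if (n_obs < min_observed)
    stop("only ", n_obs, " observed occasions; need >= ", min_observed)
  filled <- t(apply(raw, 1, interpolate_missing, mask = observed))
  constant <- apply(filled, 1, function(v) stats::sd(v) == 0)
  if (any(constant))
    warning(sum(constant), " constant series excluded")
  keep <- !constant
  X <- t(apply(filled[keep, , drop = FALSE], 1, percentile_z))
  structure(list(otu_ids = rownames(raw)[keep],
                 X = X, X_raw = filled[keep, , drop = FALSE],
                 observed = observed,
                 n_interpolated = T_ - n_obs),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("timeseries_set: %d series x %d occasions (%d interpolated)\n",
              length(x$otu_ids), ncol(x$X), x$n_interpolated))
  invisible(x)
}

#' Test all OTU pairs for local and global associations
#'
#' For every unordered pair of series: the local similarity score (delay
#' limit `D`), its permutation p-value, the shifted Spearman correlation
#' (SSCC) at the LS-optimal delay and its permutation p-value (one shuffle
#' stream serves both statistics). Benjamini-Hochberg q-values are
#' computed separately for the LS and the SSCC p-value families. A pair
#' is a significant edge when at least one family satisfies `p < alpha`
#' and `q < alpha`; its `edge_type` is `"SSCC"` when the global statistic
#' passes (a global association subsumes the local one), `"LS"`
#' otherwise, and it belongs to the `synchronous` network when the delay
#' is 0, to the `time_shifted` network when it is ±1 (or more, up to
#' `D`). The edge weight is the signed score of the typing statistic.
#'
#' @param ts a [timeseries_set()].
#' @param D delay limit, default 1.
#' @param alpha significance level applied to both p and q, default 0.01.
#' @param n_perm permutations per pair, default 1000.
#' @param seed master seed; pair `k` uses stream `seed + k`.
#' @return data.frame (association table), one row per tested pair:
#'   `otu_a`, `otu_b`, `ls`, `ls_sign`, `delay`, `start_x`, `start_y`,
#'   `length`, `ls_p`, `ls_q`, `sscc`, `sscc_p`, `sscc_q`, `significant`,
#'   `edge_type`, `network`, `weight`, `n_interpolated`.
#' @export
pairwise_associations <- function(ts, D = 1, alpha = 0.01, n_perm = 1000,
                                  seed = 1L) {
  k <- length(ts$otu_ids)
  if (k < 2) stop("need at least two eligible series")
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  res <- vector("list", np)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    r <- withr::with_seed(as.integer(seed) + p, {
      ls_assoc_perm_cpp(ts$X[i, ], ts$X[j, ], as.integer(D),
                        as.integer(n_perm))
    })
    res[[p]] <- data.frame(
      otu_a = ts$otu_ids[i], otu_b = ts$otu_ids[j],
      ls = r$score, ls_sign = if (r$sign > 0) "+" else "-",
      delay = r$delay, start_x = r$start_x, start_y = r$start_y,
      length = r$length, ls_p = r$ls_p,
      sscc = r$sscc, sscc_p = r$sscc_p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$ls_q <- stats::p.adjust(out$ls_p, method = "BH")
  out$sscc_q <- stats::p.adjust(out$sscc_p, method = "BH")
  ls_pass <- out$ls_p < alpha & out$ls_q < alpha
  sscc_pass <- out$sscc_p < alpha & out$sscc_q < alpha
  out$significant <- ls_pass | sscc_pass
  out$edge_type <- ifelse(sscc_pass, "SSCC", ifelse(ls_pass, "LS", NA))
  out$network <- ifelse(out$delay == 0, "synchronous", "time_shifted")
  sgn <- ifelse(out$ls_sign == "+", 1, -1)
  out$weight <- ifelse(!is.na(out$edge_type) & out$edge_type == "SSCC",
                       out$sscc, out$ls * sgn)
  out$n_interpolated <- 2L * ts$n_interpolated
  cols <- c("otu_a", "otu_b", "ls", "ls_sign", "delay", "start_x",
            "start_y", "length", "ls_p", "ls_q", "sscc", "sscc_p",
            "sscc_q", "significant", "edge_type", "network", "weight",
            "n_interpolated")
  out[, cols]
}
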