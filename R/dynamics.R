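#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, in \[0, 1\]:
#' 0 for identical communities, 1 for disjoint supports.
#'
#' @param u,v non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(u - v)) / tot
}

#' Bray-Curtis distance matrix of a table
#'
#' Thin wrapper around [vegan::vegdist()] returning a plain symmetric
#' matrix with sample ids.
#'
#' @param table an [otutab].
#' @return symmetric matrix of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(table) {
  d <- as.matrix(vegan::vegdist(unclass(table), method = "bray"))
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Community turnover along a lake's time series
#'
#' Bray-Curtis dissimilarity between consecutive *present* sampling
#' occasions of one lake — the standard proxy of community turnover.
#' Occasions missing from the table (e.g. dry dates) are skipped, so a
#' consecutive pair may span a desiccation gap; both time indices are
#' reported.
#'
#' @param table an [otutab] containing (at least) the lake's samples.
#' @param metadata metadata data.frame with `sample_id`, `lake`,
#'   `time_index`, `missing`.
#' @param lake lake to extract; default uses all metadata rows (assumed
#'   one lake).
#' @return data.frame with columns `lake`, `t1`, `t2`, `bc`.
#' @export
turnover_series <- function(table, metadata, lake = NULL) {
  md <- metadata
  if (!is.null(lake)) md <- md[md$lake == lake, , drop = FALSE]
  md <- md[!md$missing & md$sample_id %in% rownames(table), , drop = FALSE]
  md <- md[order(md$time_index), , drop = FALSE]
  if (nrow(md) < 2) stop("need at least two present samples")
  m <- unclass(table)[md$sample_id, , drop = FALSE]
  n <- nrow(md)
  data.frame(
    lake = md$lake[-n],
    t1 = md$time_index[-n],
    t2 = md$time_index[-1],
    bc = vapply(seq_len(n - 1),
                function(i) bray_curtis(m[i, ], m[i + 1, ]), 0),
    stringsAsFactors = FALSE
  )
}

#' Time distance decay of community dissimilarity
#'
#' All within-lake pairwise Bray-Curtis dissimilarities, grouped by the
#' absolute time-index lag between the two occasions.
#'
#' @inheritParams turnover_series
#' @return data.frame with columns `lake`, `t1`, `t2`, `lag`, `bc`,
#'   ordered by lag.
#' @export
distance_decay <- function(table, metadata, lake = NULL) {
  md <- metadata
  if (!is.null(lake)) md <- md[md$lake == lake, , drop = FALSE]
  md <- md[!md$missing & md$sample_id %in% rownames(table), , drop = FALSE]
  md <- md[order(md$time_index), , drop = FALSE]
  if (nrow(md) < 3) stop("need at least three present samples")
  m <- unclass(table)[md$sample_id, , drop = FALSE]
  n <- nrow(md)
  pairs <- utils::combn(n, 2)
  out <- data.frame(
    lake = md$lake[pairs[1, ]],
    t1 = md$time_index[pairs[1, ]],
    t2 = md$time_index[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  out$lag <- abs(out$t2 - out$t1)
  out$bc <- vapply(seq_len(ncol(pairs)), function(k)
    bray_curtis(m[pairs[1, k], ], m[pairs[2, k], ]), 0)
  out[order(out$lag, out$t1), ]
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' One- or two-way PERMANOVA with sequential (Type I) sums of squares and
#' permutation of raw observations, computed by [vegan::adonis2()] (the
#' `adonis` engine). For two factors the model is `d ~ A * B` (main
#' effects in the order given, then the interaction). Permutations can be
#' given as a count (Monte Carlo, seeded) or as an explicit permutation
#' matrix (rows = permutations of `1:n`), which makes exhaustive
#' enumeration possible for small n.
#'
#' @param d distance matrix (symmetric matrix or `dist`).
#' @param factors data.frame of one or two categorical columns, rows in
#'   the order of `d`'s ids; every level needs >= 2 samples.
#' @param n_perm number of permutations (default 999), or a permutation
#'   matrix.
#' @param seed RNG seed for Monte-Carlo permutations.
#' @return data.frame of terms with columns `term`, `df`, `ss`,
#'   `pseudo_f`, `r2`, `p` (residual and total rows included, p = NA
#'   there), with attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, factors, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  factors <- as.data.frame(factors)
  if (!ncol(factors) %in% 1:2) stop("one or two factors supported")
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2)
      stop("factor '", nm, "' has a single level")
    if (any(table(factors[[nm]]) < 2))
      stop("factor '", nm, "' has a level with fewer than 2 samples")
  }
  fml <- if (ncol(factors) == 1)
    stats::as.formula(paste("d ~", names(factors)[1]))
  else
    stats::as.formula(paste("d ~", names(factors)[1], "*", names(factors)[2]))
  res <- withr::with_seed(as.integer(seed), {
    vegan::adonis2(fml, data = factors, permutations = n_perm, by = "terms")
  })
  out <- data.frame(
    term = rownames(res),
    df = res$Df,
    ss = res$SumOfSqs,
    pseudo_f = res$F,
    r2 = res$R2,
    p = res[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- if (is.matrix(n_perm)) nrow(n_perm) else n_perm
  attr(out, "seed") <- seed
  out
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the corresponding off-diagonal entries with a
#' permutation p-value, via [vegan::mantel()].
#'
#' @param d1,d2 distance matrices over the same ids in the same order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L,
                        method = "pearson") {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  if (length(d1) != length(d2)) stop("distance matrices differ in size")
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("constant distance matrix: correlation undefined")
  res <- withr::with_seed(as.integer(seed), {
    vegan::mantel(d1, d2, method = method, permutations = n_perm)
  })
  list(r = unname(res$statistic), p = res$signif)
}

#' Screen environmental variables for collinearity
#'
#' Flags every unordered pair of variables whose Pearson correlation
#' exceeds the threshold in absolute value (strictly), computed on
#' pairwise-complete observations. Constant variables are dropped with a
#' warning.
#'
#' @param env numeric matrix or data.frame, samples in rows, variables in
#'   columns.
#' @param threshold absolute-correlation cutoff, default 0.7.
#' @return data.frame with columns `var1`, `var2`, `r`.
#' @export
collinearity_screen <- function(env, threshold = 0.7) {
  env <- as.matrix(env)
  sds <- apply(env, 2, stats::sd, na.rm = TRUE)
  constant <- is.na(sds) | sds == 0
  if (any(constant)) {
    warning("constant variable(s) excluded: ",
            paste(colnames(env)[constant], collapse = ", "))
    env <- env[, !constant, drop = FALSE]
  }
  if (ncol(env) < 2)
    return(data.frame(var1 = character(), var2 = character(), r = numeric()))
  cc <- stats::cor(env, use = "pairwise.complete.obs")
  idx <- which(upper.tri(cc) & abs(cc) > threshold, arr.ind = TRUE)
  data.frame(var1 = colnames(env)[idx[, 1]],
             var2 = colnames(env)[idx[, 2]],
             r = cc[idx],
             stringsAsFactors = FALSE)
}

#' Two-group permutation test on the difference of means
#'
#' Two-sided permutation test for a difference in group means (used e.g.
#' to compare turnover between drying and non-drying lakes, where no
#' particular parametric test is assumed). The p-value follows the
#' add-one rule and is never zero.
#'
#' @param values numeric vector.
#' @param labels group labels (exactly two groups, each with >= 2
#'   values).
#' @param n_perm number of label permutations, default 9999.
#' @param seed RNG seed.
#' @return list with `diff` (observed mean difference), `p`.
#' @export
compare_groups <- function(values, labels, n_perm = 9999, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 values")
  g1 <- labels == levels(labels)[1]
  obs <- mean(values[g1]) - mean(values[!g1])
  n1 <- sum(g1)
  hits <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(values), n1)
      d <- mean(values[idx]) - mean(values[-idx])
      abs(d) >= abs(obs) - 1e-12
    }, TRUE))
  })
  list(diff = obs, p = (1 + hits) / (1 + n_perm))
}
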