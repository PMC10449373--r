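# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the LS oracle enumerates all window pairs, the
# WI oracle enumerates walks with explicit loops.

# exhaustive local similarity: all pairs of equal-length windows with
# |start_x - start_y| <= D
ls_brute <- function(x, y, D) {
  n <- length(x)
  best <- list(score = 0, sign = "+", delay = 0L)
  for (d in -D:D) {
    for (sx in 1:n) {
      sy <- sx - d
      if (sy < 1) next
      for (len in 1:n) {
        ex <- sx + len - 1
        ey <- sy + len - 1
        if (ex > n || ey > n) break
        s <- sum(x[sx:ex] * y[sy:ey]) / n
        if (abs(s) > best$score + 1e-15)
          best <- list(score = abs(s), sign = if (s >= 0) "+" else "-",
                       delay = as.integer(d))
      }
    }
  }
  best
}

# walk-enumeration WI^3: sums products of one-step effects over all walks
# of length m (revisits allowed), endpoints distinct; A[i, j] = effect of
# j on i = |w_ij| / sum_k |w_ik|
wi_walk_oracle <- function(A) {
  V <- nrow(A)
  sig <- matrix(0, V, 3)
  for (j in 1:V) {
    for (i in 1:V) {
      if (i == j) next
      sig[j, 1] <- sig[j, 1] + A[i, j]
      for (k in 1:V) {
        sig[j, 2] <- sig[j, 2] + A[i, k] * A[k, j]
        for (l in 1:V) {
          sig[j, 3] <- sig[j, 3] + A[i, k] * A[k, l] * A[l, j]
        }
      }
    }
  }
  list(sigma = sig, wi = rowSums(sig) / 3)
}

# effect matrix from a symmetric signed weight matrix
effect_matrix <- function(W) {
  W <- abs(W)
  D <- rowSums(W)
  A <- W
  ok <- D > 0
  A[ok, ] <- W[ok, , drop = FALSE] / D[ok]
  A
}

# classical distance-based pseudo-F for a one-way design (Anderson's
# partition computed directly from squared distances)
pseudo_f_oracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.factor(labels)
  a <- nlevels(labels)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in 1:n) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small labelled count matrix helper
mk_tab <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  if (is.null(otus)) otus <- paste0("otu", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  otutab(m)
}

# one-lake metadata covering times 1..T
mk_meta <- function(lake = "lake1", T_ = 14, missing = integer(0),
                    seasons = list(spring = 1:4, summer = 5:10,
                                   autumn = 11:14)) {
  season <- character(T_)
  for (s in names(seasons)) season[seasons[[s]]] <- s
  data.frame(sample_id = sprintf("%s_t%02d", lake, 1:T_), lake = lake,
             time_index = 1:T_, season = season,
             missing = (1:T_) %in% missing, stringsAsFactors = FALSE)
}
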