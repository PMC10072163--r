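# Independent oracles, deliberately written as direct transliterations of
# the definitions (closed forms, exhaustive enumeration) rather than
# reusing any package code path.

# Welch two-sided t-test P value from the closed form
# (Welch-Satterthwaite degrees of freedom), with the zero-variance
# degenerate rule.
welch_p_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

oracle_p_matrix <- function(cns_list) {
  k <- length(cns_list)
  P <- matrix(1, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) P[i, j] <- welch_p_oracle(cns_list[[i]], cns_list[[j]])
    }
  }
  P
}

# All 2^(k-1) contiguous partitions of 1..k as lists of index vectors.
all_contiguous_partitions <- function(k) {
  if (k == 1) return(list(list(1L)))
  out <- list()
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)  # cut after band i
    bounds <- c(0L, cuts, k)
    out[[length(out) + 1L]] <- lapply(seq_len(length(bounds) - 1), function(r) {
      seq.int(bounds[r] + 1L, bounds[r + 1L])
    })
  }
  out
}

# Initial regions by brute force: among all contiguous partitions whose
# every region is internally compatible (all pairwise P >= alpha), take the
# one with the lexicographically largest region sizes (longest first
# region, then longest second, ...), which is what left-to-right greedy
# growth produces.
oracle_initial_regions <- function(P, alpha) {
  k <- nrow(P)
  valid <- Filter(function(part) {
    all(vapply(part, function(idx) {
      length(idx) == 1 || all(P[idx, idx][upper.tri(diag(length(idx)))] >= alpha)
    }, logical(1)))
  }, all_contiguous_partitions(k))
  sizes <- lapply(valid, function(p) vapply(p, length, integer(1)))
  best <- 1L
  lex_gt <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] != b[i]) return(a[i] > b[i])
    }
    FALSE
  }
  for (i in seq_along(valid)) {
    if (lex_gt(sizes[[i]], sizes[[best]])) best <- i
  }
  valid[[best]]
}

# Naive merge fixpoint: leftmost adjacent pair satisfying rule (i)
# f > 0.5 or rule (ii) larger side > 7 bands and f > 0.3 merges first;
# repeat from the left until no pair merges.
oracle_merge_regions <- function(regions, P, alpha) {
  repeat {
    did <- FALSE
    i <- 1
    while (i < length(regions)) {
      a <- regions[[i]]; b <- regions[[i + 1]]
      ps <- as.vector(P[a, b, drop = FALSE])
      f <- sum(ps >= alpha) / length(ps)
      big <- max(length(a), length(b))
      if (f > 0.5 || (big > 7 && f > 0.3)) {
        regions <- c(regions[seq_len(i - 1)], list(c(a, b)),
                     regions[seq_along(regions) > i + 1])
        did <- TRUE
        break
      }
      i <- i + 1
    }
    if (!did) return(regions)
  }
}

oracle_segment <- function(cns_list, alpha = 0.1) {
  P <- oracle_p_matrix(cns_list)
  oracle_merge_regions(oracle_initial_regions(P, alpha), P, alpha)
}

# AUC as the literal fraction of (positive, negative) pairs correctly
# ordered, ties counting one half.
oracle_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
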