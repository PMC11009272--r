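# Independent oracles, deliberately written without reference to the package
# internals they check.

# Exhaustive semi-global (free end-gap) alignment oracle: fills the DP table
# for the given linear scoring and enumerates every co-optimal alignment,
# returning the set of percent identities (matches / aligned columns,
# terminal overhangs excluded) those alignments realise. NULL when the best
# alignment is empty.
nw_overlap_identity_set <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  D <- matrix(0, n + 1, m + 1)   # free leading gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (av[i] == bv[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + sub, D[i, j + 1] - gap,
                             D[i + 1, j] - gap)
    }
  }
  ends <- unique(rbind(cbind(n, seq_len(m)), cbind(seq_len(n), m)))
  scores <- D[ends + 1]
  best <- max(scores)
  if (best <= 0) return(NULL)

  idents <- new.env()
  trace <- function(i, j, matches, cols) {
    if (i == 0 || j == 0) {
      if (cols > 0) {
        key <- sprintf("%.9f", 100 * matches / cols)
        assign(key, TRUE, envir = idents)
      }
      return(invisible())
    }
    sub <- if (av[i] == bv[j]) match else mismatch
    if (D[i + 1, j + 1] == D[i, j] + sub) {
      trace(i - 1, j - 1, matches + (av[i] == bv[j]), cols + 1)
    }
    if (D[i + 1, j + 1] == D[i, j + 1] - gap) trace(i - 1, j, matches, cols + 1)
    if (D[i + 1, j + 1] == D[i + 1, j] - gap) trace(i, j - 1, matches, cols + 1)
  }
  for (k in which(scores == best)) {
    trace(ends[k, 1], ends[k, 2], 0, 0)
  }
  as.numeric(ls(envir = idents))
}

# Closed-form integral of the piecewise-linear interpolant through
# (depths, values), written out segment by segment.
analytic_piecewise_linear_integral <- function(values, depths) {
  total <- 0
  for (k in seq_len(length(depths) - 1)) {
    h <- depths[k + 1] - depths[k]
    slope <- (values[k + 1] - values[k]) / h
    # integral of v_k + slope * t over t in [0, h]
    total <- total + values[k] * h + slope * h^2 / 2
  }
  total
}

# Closed-form OLS of y on x.
ols_closed_form <- function(y, x, with_intercept = TRUE) {
  if (with_intercept) {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    fitted <- intercept + slope * x
    r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  } else {
    slope <- sum(x * y) / sum(x^2)
    intercept <- NA_real_
    fitted <- slope * x
    r2 <- 1 - sum((y - fitted)^2) / sum(y^2)  # uncentered convention
  }
  list(slope = slope, intercept = intercept, r_squared = r2)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Introduce k substitutions at the given positions, always to a different base.
mutate_seq <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}
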