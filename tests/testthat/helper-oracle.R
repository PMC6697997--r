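# Brute-force NGTDM oracle, written naively and directly from the matrix
# definition. Kept independent of the package's compiled path: plain loops,
# neighbor values gathered into a vector, mean() for the neighborhood
# average. Both eligibility policies are implemented.

oracle_ngtdm <- function(vals, valid, d = 1, policy = "strict-interior") {
  nr <- nrow(vals)
  nc <- ncol(vals)
  maxb <- max(vals[valid])
  s <- numeric(maxb)
  cnt <- integer(maxb)
  n <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!valid[r, c]) next
      nbr <- numeric(0)
      full <- TRUE
      for (dr in -d:d) {
        for (dc in -d:d) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc || !valid[rr, cc]) {
            full <- FALSE
            next
          }
          nbr <- c(nbr, vals[rr, cc])
        }
      }
      eligible <- if (policy == "strict-interior") full else length(nbr) > 0
      if (!eligible) next
      i <- vals[r, c]
      s[i] <- s[i] + abs(i - mean(nbr))
      cnt[i] <- cnt[i] + 1L
      n <- n + 1L
    }
  }
  list(s = s, cnt = cnt, n = n)
}

oracle_features <- function(tab, eps = 1e-8) {
  if (tab$n == 0)
    return(c(coarseness = NA_real_, contrast = NA_real_, busyness = NA_real_))
  p <- tab$cnt / tab$n
  lev <- which(tab$cnt > 0)
  ng <- length(lev)
  coarse <- 1 / (eps + sum(p * tab$s))
  contr <- 0
  if (ng > 1) {
    acc <- 0
    for (i in lev) for (j in lev) acc <- acc + p[i] * p[j] * (i - j)^2
    contr <- acc / (ng * (ng - 1)) * sum(tab$s) / tab$n
  }
  den <- 0
  for (i in lev) for (j in lev) den <- den + abs(i * p[i] - j * p[j])
  busy <- if (den > 0) sum(p * tab$s) / den else 0
  c(coarseness = coarse, contrast = contr, busyness = busy)
}

random_patch <- function(nr, nc, bins = 8L, p_valid = 1) {
  vals <- matrix(sample.int(bins, nr * nc, replace = TRUE), nr, nc)
  valid <- matrix(runif(nr * nc) < p_valid, nr, nc)
  if (!any(valid)) valid[sample.int(nr * nc, 1)] <- TRUE
  list(vals = vals, valid = valid)
}

# Mann-Whitney AUC by exhaustive pair enumeration (concordant + half ties).
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# A CV-plan seed distinct from, but determined by, the cohort seed.
derive_seed_for_test <- function(seed) 1000L + as.integer(seed) * 3L

# Small dual-time-point cohort for pipeline tests (kept tiny for speed).
small_cohort <- function(n_benign = 5, n_malignant = 7, seed = 11) {
  generate_cohort(n_benign, n_malignant, seed = seed)
}
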