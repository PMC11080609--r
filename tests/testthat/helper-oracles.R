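# Independent oracles and fixture builders. The oracles deliberately use
# naive loop/enumeration implementations so they share no code path with
# the package.

# brute-force expansion index straight from the definition
oracle_ei <- function(cag, height, ref, theta, window = c(-Inf, Inf)) {
  keep <- cag >= window[1] & cag <= window[2]
  cag <- cag[keep]; height <- height[keep]
  h0 <- 0
  for (i in seq_along(cag)) if (cag[i] == ref) h0 <- h0 + height[i]
  ret_h <- numeric(0); ret_d <- numeric(0)
  for (i in seq_along(cag)) {
    d <- cag[i] - ref
    if (d >= 1 && height[i] >= theta * h0) {
      ret_h <- c(ret_h, height[i]); ret_d <- c(ret_d, d)
    }
  }
  S <- h0 + sum(ret_h)
  ei <- 0
  for (i in seq_along(ret_h)) ei <- ei + ret_h[i] / S * ret_d[i]
  ei
}

# ordinary least squares through explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y)) # (intercept, slope)
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(anyDuplicated(c(x, y)) == 0)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ws <- apply(utils::combn(N, n1), 2, sum) - n1 * (n1 + 1) / 2
  m <- n1 * n2 / 2
  p <- if (w_obs > m) 2 * mean(ws >= w_obs) else 2 * mean(ws <= w_obs)
  min(p, 1)
}

# calibration whose lattice is size_bp = 100 + 3 * cag
unit_cal <- function(ref = 45) size_calibration(100 + 3 * ref, ref)

# trace with peaks placed at integer repeat counts on the unit_cal lattice
make_trace <- function(heights_by_cag, ref = NULL, gene = NA_character_,
                       id = "t1", ...) {
  cag <- as.integer(names(heights_by_cag))
  new_trace(id, data.frame(size_bp = 100 + 3 * cag,
                           height = as.numeric(heights_by_cag)),
            gene = gene, ...)
}

# random expanded-allele trace of at most max_peaks peaks around ref,
# with arbitrary (adversarial) height patterns
random_trace <- function(ref = 45, max_peaks = 12) {
  n_extra <- sample(0:(max_peaks - 1), 1)
  deltas <- sort(sample(setdiff(-4:10, 0), n_extra))
  cag <- c(ref, ref + deltas)
  h <- stats::setNames(stats::runif(length(cag), 1, 1000), cag)
  h[as.character(ref)] <- stats::runif(1, 800, 2000) # modal stays tallest
  make_trace(h)
}

# random trace whose expanded tail decays with the offset, the morphology
# of real somatic-expansion profiles (threshold retention then drops the
# farthest peak first, which is what makes EI non-increasing in theta)
decay_trace <- function(ref = 45, max_tail = 10) {
  n_tail <- sample(1:max_tail, 1)
  h0 <- stats::runif(1, 800, 2000)
  tail_h <- h0 * sort(stats::runif(n_tail, 0.005, 0.95), decreasing = TRUE)
  h <- stats::setNames(c(h0, tail_h), c(ref, ref + seq_len(n_tail)))
  make_trace(h)
}
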