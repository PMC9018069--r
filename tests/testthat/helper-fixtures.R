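# Shared fixture builders. Everything is generated in code; no data files.

# Random SPD matrix with eigenvalues bounded away from zero.
rand_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) / p + diag(p) * 0.5
}

# Random symmetric matrix.
rand_sym <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(p * p), p, p)
  (a + t(a)) / 2
}

frob <- function(m) sqrt(sum(m * m))

# Orthonormal p x k frame.
rand_frame <- function(p, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * (k)), p, k)))
}

# Minimal single-subject trial table for behavioral unit tests.
make_trials <- function(error_deg, epoch = "learning", day = 1,
                        rt_s = 0.5, subject = "s1") {
  n <- length(error_deg)
  tibble::tibble(
    subject = subject, group = "FF", day = day, trial = seq_len(n),
    block = (seq_len(n) - 1) %/% 8 + 1, epoch = epoch,
    target_deg = 0, error_deg = error_deg,
    rt_s = rep_len(rt_s, n), valid = TRUE, interpolated = FALSE)
}
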