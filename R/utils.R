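#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Wrap degrees into (-180, 180].
wrap_degrees <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Circular mean of angles in degrees
#'
#' The direction of the resultant vector of the unit vectors at each angle,
#' `atan2(mean(sin), mean(cos))`, mapped to (-180, 180]. Degenerate inputs
#' whose resultant has near-zero length (e.g. two antipodal angles) return
#' the atan2 convention value.
#'
#' @param x numeric vector of angles in degrees.
#' @param na.rm drop missing values first.
#' @return a single angle in degrees in (-180, 180].
#' @examples
#' circular_mean(c(-10, 10))   # 0
#' circular_mean(c(170, -170)) # 180
#' @export
circular_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) abort("circular_mean(): no data.")
  rad <- x * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  wrap_degrees(ang)
}

#' Adjusted Rand index between two partitions
#'
#' Standard contingency-table formula (Hubert & Arabie). Used to score
#' recovery of planted group structure by the learner clustering.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return scalar ARI; 1 for identical partitions (up to label permutation).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("Partitions differ in length.")
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Frobenius norm.
fnorm <- function(m) sqrt(sum(m * m))

# Deterministic child seed: keep within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
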