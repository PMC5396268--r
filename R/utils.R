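`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance matrix between two coordinate sets (rows = atoms).
cross_dist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

rmsd_of <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# population standard deviation (divide by n, not n - 1)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_finite_matrix <- function(x) is.numeric(x) && all(is.finite(x))
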