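# Physical constants and small numeric helpers shared across the package.

#' Boltzmann constant in kcal mol-1 K-1
#'
#' The conventional biomolecular-simulation value 1.987e-3 kcal mol-1 K-1,
#' so that kB*T at 300 K equals 0.5961 kcal/mol.
#' @keywords internal
.kB <- 1.987e-3

#' Thermal energy kB*T
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy in kcal/mol.
#' @examples
#' kBT(300) # 0.5961
#' @export
kBT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}

# Euclidean distances between two sets of points (rows of n x 3 matrices).
.row_dist <- function(a, b) {
  sqrt(rowSums((a - b)^2))
}

# All unordered pairs (i < j) among n indices, as a 2-column matrix.
.all_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, 1L], j = idx[, 2L])
}

# Canonical unordered pair key "i-j" with i < j.
.pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# TRUE when all points lie (numerically) on one line.
.is_collinear <- function(xyz, tol = 1e-8) {
  if (nrow(xyz) < 3L) return(TRUE)
  centered <- sweep(xyz, 2L, colMeans(xyz))
  s <- svd(centered, nu = 0L, nv = 0L)$d
  s[2L] <= tol * max(s[1L], 1)
}
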