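# Spectral statistics of rigidity graphs: eigendecomposition with a
# deterministic sign convention, mode similarity by maximal absolute dot
# product, windowed mean graphs and mean-mode contents, prominent-mode
# selection (Tukey fence on strengths, empirical quantile on contents) and
# mechanical hotspot extraction.

#' Eigendecompose a rigidity graph matrix
#'
#' Modes are sorted by descending eigenvalue (mode index alpha from 1) and
#' sign-fixed so each eigenvector's largest-magnitude component is positive.
#'
#' @param graph A `rigidity_graph`, or a symmetric numeric matrix.
#' @param kind `"K"` (signless Laplacian D + A, default) or `"L"`
#'   (Laplacian D - A); ignored when `graph` is already a matrix.
#' @return Object of class `spectral_result`: list with `values` (descending),
#'   `vectors` (columns are orthonormal modes), `kind`.
#' @export
eigendecompose <- function(graph, kind = c("K", "L")) {
  kind <- match.arg(kind)
  if (inherits(graph, "rigidity_graph")) {
    M <- if (kind == "K") signless_laplacian(graph) else laplacian(graph)
  } else {
    M <- as.matrix(graph)
  }
  if (!all(is.finite(M))) stop("non-finite matrix entries")
  eg <- eigen(M, symmetric = TRUE)
  V <- eg$vectors
  for (a in seq_len(ncol(V))) {
    peak <- which.max(abs(V[, a]))
    if (V[peak, a] < 0) V[, a] <- -V[, a]
  }
  structure(list(values = eg$values, vectors = V, kind = kind),
            class = "spectral_result")
}

#' Mode similarity between two spectra
#'
#' The similarity of the compared graph along mode alpha of the reference is
#' `r_alpha = max_beta |nu_beta . nu_alpha_ref|`, with `beta_max` the
#' maximising compared mode (ties broken towards the smaller index).
#'
#' @param compared,reference `spectral_result` objects of equal dimension.
#' @param alpha Reference mode indices (default: all).
#' @return Data.frame with `alpha`, `r`, `beta_max`.
#' @export
mode_similarity <- function(compared, reference,
                            alpha = seq_along(reference$values)) {
  stopifnot(inherits(compared, "spectral_result"),
            inherits(reference, "spectral_result"))
  if (nrow(compared$vectors) != nrow(reference$vectors)) {
    stop("dimension mismatch between compared and reference spectra")
  }
  M <- abs(crossprod(compared$vectors, reference$vectors[, alpha,
                                                         drop = FALSE]))
  data.frame(
    alpha = alpha,
    r = apply(M, 2L, max),
    beta_max = apply(M, 2L, which.max)
  )
}

#' Mean rigidity graph over trajectory windows
#'
#' @param graphs List of `rigidity_graph` objects with equal residue count.
#' @return A `rigidity_graph` whose adjacency is the entrywise mean, with
#'   `window = "mean"`.
#' @export
mean_graph <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  n <- graphs[[1L]]$n
  for (g in graphs) {
    if (!inherits(g, "rigidity_graph") || g$n != n) {
      stop("all graphs must be rigidity_graphs with the same residue count")
    }
  }
  A <- Reduce(`+`, lapply(graphs, `[[`, "A")) / length(graphs)
  structure(list(A = A, n = n, group = graphs[[1L]]$group,
                 subset = graphs[[1L]]$subset, window = "mean"),
            class = "rigidity_graph")
}

#' Mean-mode contents across trajectory windows
#'
#' For each mean-mode (eigenvector of the mean graph) and each window, the
#' content `r_n` is the largest |dot product| with that window's eigenvectors;
#' averaging over windows gives the averaged mean-mode content.
#'
#' @param graphs List of per-window `rigidity_graph` objects.
#' @param mean_spec Optional `spectral_result` of the mean graph; computed
#'   from `graphs` when omitted.
#' @param kind Matrix kind passed to [eigendecompose()] (default `"K"`).
#' @return Object of class `mean_mode_stats`: list with `mean_graph`,
#'   `spectrum` (of the mean graph), `content` (windows x modes matrix of
#'   r_n), `content_mean` (per-mode average), `n_windows`.
#' @export
mean_mode_content <- function(graphs, mean_spec = NULL, kind = "K") {
  kbar <- mean_graph(graphs)
  if (is.null(mean_spec)) mean_spec <- eigendecompose(kbar, kind)
  r <- t(vapply(graphs, function(g) {
    mode_similarity(eigendecompose(g, kind), mean_spec)$r
  }, numeric(length(mean_spec$values))))
  structure(
    list(mean_graph = kbar, spectrum = mean_spec, content = r,
         content_mean = colMeans(r), n_windows = length(graphs)),
    class = "mean_mode_stats"
  )
}

#' Select prominent modes by strength and content
#'
#' A mean-mode is prominent when its strength exceeds the Tukey upper fence
#' `Q3 + 1.5 * IQR` of the eigenvalue distribution (strict inequality) AND its
#' averaged content lies in the top `1 - content_quantile` of contents.
#' Quartiles use linear interpolation between order statistics (quantile
#' type 7).
#'
#' @param lambda Mean-mode strengths (eigenvalues of the mean graph).
#' @param content Averaged mean-mode contents, same length.
#' @param content_quantile Content quantile threshold: 0.75 keeps the top 25%
#'   (backbone-involving graphs); 0.68 keeps the top 32% (side-chain graphs).
#' @return Object of class `prominent_modes`: list with `modes` (indices),
#'   `fence`, `content_threshold`.
#' @export
select_prominent_modes <- function(lambda, content, content_quantile = 0.75) {
  stopifnot(length(lambda) == length(content))
  if (length(lambda) < 4L) stop("need at least 4 modes to define quartiles")
  q <- stats::quantile(lambda, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  cthr <- stats::quantile(content, content_quantile, type = 7, names = FALSE)
  modes <- which(lambda > fence & content >= cthr)
  structure(list(modes = modes, fence = fence, content_threshold = cthr),
            class = "prominent_modes")
}

#' Hotspot residues of a mode
#'
#' Residues whose squared eigenvector weight reaches `nu_c2`; at the default
#' 0.1 a unit mode can hold at most 10 hotspots.
#'
#' @param v A (unit) eigenvector.
#' @param nu_c2 Squared-weight threshold (default 0.1).
#' @return Integer vector of residue indices.
#' @export
hotspot_residues <- function(v, nu_c2 = 0.1) {
  stopifnot(nu_c2 > 0)
  which(v^2 >= nu_c2)
}

#' @export
print.mean_mode_stats <- function(x, ...) {
  cat("Mean-mode statistics:", x$n_windows, "windows,",
      length(x$spectrum$values), "modes; top strength",
      sprintf("%.4g", x$spectrum$values[1L]), "\n")
  invisible(x)
}

#' @export
print.prominent_modes <- function(x, ...) {
  cat("Prominent modes:", paste(x$modes, collapse = ", "),
      sprintf("(fence %.4g, content >= %.4g)\n", x$fence,
              x$content_threshold))
  invisible(x)
}
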