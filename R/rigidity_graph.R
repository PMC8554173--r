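# Inter-residue rigidity graphs. Edge weights k_IJ sum the bsENM spring
# constants linking the CG sites of residues I and J; the degree k_II is the
# residue's total coupling strength. L = D - A is the Laplacian, K = D + A the
# signless Laplacian. Springs are classified by sequence separation
# (skeleton-1: within a residue or nearest neighbours; skeleton-2: second
# neighbours; the rest are non-skeleton) and by site-class group (BB/BS/SS);
# cysteine Sgamma-Sgamma springs at covalent-bond distance are disulfides and
# excluded from the rigidity analysis.

#' Classify bsENM springs by sequence separation and site-class group
#'
#' @param springs Data.frame with columns `i`, `j` (site indices) and `l0`.
#' @param sites Site table as in a `cg_model` (`residue`, `chain`,
#'   `site_class`, `resid`, `source`).
#' @param ss_cut Rest-length cutoff in Angstrom below which a cysteine
#'   Sgamma-Sgamma spring is a disulfide (default 2.5).
#' @return Data.frame with `category` (`skeleton1`, `skeleton2`,
#'   `nonskeleton`, `disulfide`) and `group` (`BB`, `BS`, `SS`).
#' @export
classify_springs <- function(springs, sites, ss_cut = 2.5) {
  ri <- sites$residue[springs$i]
  rj <- sites$residue[springs$j]
  ci <- sites$chain[springs$i]
  cj <- sites$chain[springs$j]
  same_chain <- ci == cj
  dsep <- abs(ri - rj)

  category <- rep("nonskeleton", nrow(springs))
  category[same_chain & dsep <= 1L] <- "skeleton1"
  category[same_chain & dsep == 2L] <- "skeleton2"

  bb_i <- sites$site_class[springs$i] == "backbone"
  bb_j <- sites$site_class[springs$j] == "backbone"
  group <- ifelse(bb_i & bb_j, "BB", ifelse(!bb_i & !bb_j, "SS", "BS"))

  disulf <- sites$resid[springs$i] == "CYS" & sites$resid[springs$j] == "CYS" &
    sites$source[springs$i] == "SG" & sites$source[springs$j] == "SG" &
    springs$l0 < ss_cut
  category[disulf] <- "disulfide"

  data.frame(category = category, group = group)
}

# Spring row filter for a group/subset request.
.select_springs <- function(springs, group, subset) {
  keep <- switch(subset,
    nonskeleton = springs$category == "nonskeleton",
    skeleton = springs$category %in% c("skeleton1", "skeleton2"),
    all = springs$category != "disulfide",
    stop("unknown subset: ", subset)
  )
  if (group != "ALL") keep <- keep & springs$group == group
  keep
}

#' Build an inter-residue rigidity graph from a bsENM
#'
#' @param model A `bsenm`.
#' @param group Interaction group: `"ALL"`, `"BB"`, `"BS"` or `"SS"`.
#' @param subset Spring subset: `"nonskeleton"` (default; disulfides always
#'   excluded), `"skeleton"` (skeleton-1 and skeleton-2), or `"all"`
#'   (everything except disulfides).
#' @param window Optional window label carried in the result.
#' @return Object of class `rigidity_graph`: list with `A` (N x N symmetric
#'   non-negative matrix, zero diagonal), `n`, `group`, `subset`, `window`.
#'   Intra-residue springs never contribute (the diagonal of A is zero by
#'   definition; degrees come from row sums).
#' @export
residue_graph <- function(model, group = "ALL",
                          subset = c("nonskeleton", "skeleton", "all"),
                          window = NA) {
  stopifnot(inherits(model, "bsenm"))
  group <- match.arg(group, c("ALL", "BB", "BS", "SS"))
  subset <- match.arg(subset)
  n <- max(model$sites$residue)
  sp <- model$springs
  keep <- .select_springs(sp, group, subset)
  A <- matrix(0, n, n)
  if (any(keep)) {
    ri <- model$sites$residue[sp$i[keep]]
    rj <- model$sites$residue[sp$j[keep]]
    kk <- sp$k[keep]
    inter <- ri != rj
    for (s in which(inter)) {
      A[ri[s], rj[s]] <- A[ri[s], rj[s]] + kk[s]
      A[rj[s], ri[s]] <- A[rj[s], ri[s]] + kk[s]
    }
  } else {
    warning("empty spring selection for group=", group, ", subset=", subset,
            "; graph is all zeros")
  }
  structure(list(A = A, n = n, group = group, subset = subset,
                 window = window),
            class = "rigidity_graph")
}

#' Residue contact graph of a topology-only model
#'
#' Every retained spring counts with unit weight, so degrees are the integer
#' residue contact numbers m_II of CG-site pairs within the cutoff.
#'
#' @param model A `bsenm` (typically from [build_bsenm0()]).
#' @param subset Spring subset as in [residue_graph()]; default `"all"`.
#' @return A `rigidity_graph` with integer entries.
#' @export
contact_graph <- function(model, subset = "all") {
  stopifnot(inherits(model, "bsenm"))
  m <- model
  m$springs$k <- rep(1, nrow(m$springs))
  residue_graph(m, group = "ALL", subset = subset)
}

#' Degree vector, Laplacian and signless Laplacian
#'
#' @param graph A `rigidity_graph`.
#' @return `degree_vector()`: row sums of A (k_II). `laplacian()`: L = D - A.
#'   `signless_laplacian()`: K = D + A.
#' @export
degree_vector <- function(graph) {
  stopifnot(inherits(graph, "rigidity_graph"))
  rowSums(graph$A)
}

#' @rdname degree_vector
#' @export
laplacian <- function(graph) {
  diag(degree_vector(graph)) - graph$A
}

#' @rdname degree_vector
#' @export
signless_laplacian <- function(graph) {
  diag(degree_vector(graph)) + graph$A
}

#' Fraction of surviving springs per rest-length bin
#'
#' Histograms the spring rest lengths `l0` and reports, per bin, how many
#' candidate pairs exist and what fraction retained `k > 0` after fluctuation
#' matching — the sparsity profile of the mechanical coupling network.
#'
#' @param model A learned `bsenm` whose spring list still contains the
#'   `k = 0` springs (i.e. before trimming), or a model plus its trimmed
#'   springs appended.
#' @param bin_width Bin width in Angstrom (default 0.5).
#' @param subset Spring subset (default `"nonskeleton"`).
#' @return Data.frame with `lo`, `hi`, `mid`, `n_pairs`, `n_positive` and
#'   `fraction` (NA for empty bins).
#' @export
sparsity_profile <- function(model, bin_width = 0.5, subset = "nonskeleton") {
  stopifnot(inherits(model, "bsenm"), bin_width > 0)
  sp <- model$springs[.select_springs(model$springs, "ALL", subset), ]
  lo0 <- floor(min(sp$l0) / bin_width) * bin_width
  hi0 <- ceiling(max(sp$l0) / bin_width) * bin_width
  if (hi0 <= lo0) hi0 <- lo0 + bin_width
  breaks <- seq(lo0, hi0, by = bin_width)
  bin <- cut(sp$l0, breaks, include.lowest = TRUE, labels = FALSE)
  n_bin <- length(breaks) - 1L
  n_pairs <- tabulate(bin, nbins = n_bin)
  n_pos <- tabulate(bin[sp$k > 0], nbins = n_bin)
  data.frame(
    lo = breaks[-length(breaks)], hi = breaks[-1L],
    mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
    n_pairs = n_pairs, n_positive = n_pos,
    fraction = ifelse(n_pairs > 0L, n_pos / n_pairs, NA_real_)
  )
}

#' Backbone vs side-chain entry points of BS coupling per residue
#'
#' For every residue, splits its total non-skeleton BS spring strength into
#' the part entering through its backbone sites and the part through its
#' side-chain site. The two parts sum to the residue's BS degree.
#'
#' @param model A `bsenm`.
#' @return Data.frame with `residue`, `backbone`, `sidechain`.
#' @export
bs_contribution_ledger <- function(model) {
  stopifnot(inherits(model, "bsenm"))
  n <- max(model$sites$residue)
  sp <- model$springs
  keep <- sp$category == "nonskeleton" & sp$group == "BS"
  bb <- numeric(n)
  sc <- numeric(n)
  for (s in which(keep)) {
    for (end in c("i", "j")) {
      site <- sp[[end]][s]
      res <- model$sites$residue[site]
      other <- model$sites$residue[sp[[if (end == "i") "j" else "i"]][s]]
      if (res == other) next
      if (model$sites$site_class[site] == "backbone") {
        bb[res] <- bb[res] + sp$k[s]
      } else {
        sc[res] <- sc[res] + sp$k[s]
      }
    }
  }
  data.frame(residue = seq_len(n), backbone = bb, sidechain = sc)
}

#' Write a rigidity graph as a TSV edge list
#'
#' @param graph A `rigidity_graph`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_graph_edges <- function(graph, file) {
  stopifnot(inherits(graph, "rigidity_graph"))
  idx <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  edges <- data.frame(I = idx[, 1L], J = idx[, 2L],
                      k_IJ = graph$A[idx], group = graph$group)
  utils::write.table(edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @export
print.rigidity_graph <- function(x, ...) {
  cat(sprintf("Rigidity graph (%s, %s): %d residues, %d edges\n",
              x$group, x$subset, x$n, sum(x$A[upper.tri(x$A)] > 0)))
  invisible(x)
}
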