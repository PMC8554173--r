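# Synthetic reference networks and pseudo-trajectories. A reference bsENM with
# known spring constants plays the role of the (unavailable) all-atom
# trajectory: Gaussian configurations sampled from its harmonic ensemble give
# trajectories whose distance fluctuations have known analytic values, so
# every learning and analysis stage can be validated by parameter recovery.

#' Specification of a synthetic fixture
#'
#' Residues are laid out on a compact self-avoiding coil (3.8 Angstrom steps
#' confined to a sphere of protein-like density) plus positional jitter, each
#' residue carrying amide-N,
#' carbonyl-O and (except glycine) a side-chain site. Skeleton springs are
#' drawn strong; non-skeleton springs are heavy-tailed
#' (`k_floor + Lomax(shape, scale)`) with a zero probability that grows
#' linearly with rest length from `zero_onset` to the cutoff — emulating the
#' distance decay of specific packing interactions.
#'
#' @param n_residues Number of residues (>= 4; default 30).
#' @param lc Spring cutoff, Angstrom (default 7.8).
#' @param spacing Backbone lattice spacing, Angstrom (default 3.8).
#' @param jitter Uniform positional jitter amplitude, Angstrom (default 0.35).
#' @param shape,scale Lomax parameters of non-skeleton strengths
#'   (default 2.2, 1.0).
#' @param k_floor Additive stiffness floor for surviving non-skeleton springs,
#'   kcal mol-1 A-2 (default 0.05).
#' @param zero_max Maximum zero probability, reached at the cutoff
#'   (default 0.6).
#' @param zero_onset Rest length at which the zero probability starts rising,
#'   Angstrom (default 4).
#' @param k_skel1,k_skel2 Uniform stiffness ranges for skeleton-1 and
#'   skeleton-2 springs (defaults 40-80 and 10-30).
#' @param temperature Kelvin (default 300).
#' @param seed Integer seed; the fixture is a deterministic function of the
#'   spec including this seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 30L, lc = 7.8, spacing = 3.8,
                         jitter = 0.35, shape = 2.2, scale = 1.0,
                         k_floor = 0.05, zero_max = 0.6, zero_onset = 4,
                         k_skel1 = c(40, 80), k_skel2 = c(10, 30),
                         temperature = 300, seed = 1L) {
  stopifnot(n_residues >= 4L, lc > 0, spacing > 0)
  structure(
    list(n_residues = as.integer(n_residues), lc = lc, spacing = spacing,
         jitter = jitter, shape = shape, scale = scale, k_floor = k_floor,
         zero_max = zero_max, zero_onset = zero_onset, k_skel1 = k_skel1,
         k_skel2 = k_skel2, temperature = temperature, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Compact self-avoiding coil: a chain of fixed 3.8 A steps confined to a
# sphere of protein-like density (radius ~3.1 * n^(1/3) A), with an excluded
# volume keeping non-bonded residues >= min_sep apart. Irregular by
# construction, so the resulting networks have no symmetry-induced eigenvalue
# degeneracies; contact numbers come out protein-like (~10-16 residues within
# a 7.8 A cutoff). Deterministic given the caller's RNG state.
.coil_backbone <- function(n, spacing, min_sep = 4.6, max_restart = 50L) {
  radius <- 3.1 * n^(1 / 3)
  for (restart in seq_len(max_restart)) {
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- c(-radius / 2, 0, 0)
    i <- 1L
    fail <- FALSE
    while (i < n) {
      placed <- FALSE
      for (try in 1:60) {
        cand <- pos[i, ] + spacing * .runit()
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 1L) {
          d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        i <- i + 1L
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        # back up a couple of steps and retry from there
        i <- max(1L, i - 2L)
        if (stats::runif(1) < 0.02) {
          fail <- TRUE
          break
        }
      }
    }
    if (!fail && i == n) return(pos)
  }
  stop("could not grow a self-avoiding coil; relax min_sep or radius")
}

.fixture_residues <- c("ALA", "SER", "LEU", "GLY", "LYS", "PHE", "ASP",
                       "THR", "VAL", "GLU")

# Random unit vector from the current RNG stream.
.runit <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Build a synthetic reference bsENM with known spring constants
#'
#' @param spec A [fixture_spec()].
#' @param max_resample Resampling attempts if a draw disconnects the network.
#' @return Object of class `reference_enm`: list with `model` (a `bsenm`
#'   carrying the true k values; zero-strength springs are kept in the list),
#'   `targets` (analytic `fluctuation_targets` for every within-cutoff pair,
#'   computed from the model's own covariance), `cg` (the `cg_model`), and
#'   `spec`.
#' @export
make_reference_enm <- function(spec = fixture_spec(), max_resample = 20L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  bb <- .coil_backbone(n, spec$spacing)
  bb <- bb + matrix(stats::runif(3L * n, -spec$jitter, spec$jitter), n, 3L)

  resid <- rep(.fixture_residues, length.out = n)
  map <- default_mapping_table()
  rows <- list()
  xyz <- list()
  for (I in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      residue = I, chain = "A", resno = I, resid = resid[I],
      site_class = "backbone", source = "N", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- bb[I, ] + 0.95 * .runit()
    rows[[length(rows) + 1L]] <- data.frame(
      residue = I, chain = "A", resno = I, resid = resid[I],
      site_class = "backbone", source = "O", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- bb[I, ] + 1.25 * .runit()
    if (resid[I] != "GLY") {
      rule <- map$sidechain[resid[I]]
      rows[[length(rows) + 1L]] <- data.frame(
        residue = I, chain = "A", resno = I, resid = resid[I],
        site_class = "sidechain", source = unname(rule),
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- bb[I, ] + 1.9 * .runit()
    }
  }
  sites <- do.call(rbind, rows)
  sites <- cbind(site = seq_len(nrow(sites)), sites)
  cg <- structure(list(sites = sites, xyz = do.call(rbind, xyz)),
                  class = "cg_model")

  model <- build_initial_model(cg, lc = spec$lc, k0 = 1,
                               temperature = spec$temperature)
  sp <- model$springs
  ns <- sp$category == "nonskeleton"
  draw_k <- function() {
    k <- numeric(nrow(sp))
    k[sp$category == "skeleton1"] <- stats::runif(
      sum(sp$category == "skeleton1"), spec$k_skel1[1L], spec$k_skel1[2L])
    k[sp$category == "skeleton2"] <- stats::runif(
      sum(sp$category == "skeleton2"), spec$k_skel2[1L], spec$k_skel2[2L])
    p0 <- spec$zero_max *
      pmin(1, pmax(0, (sp$l0[ns] - spec$zero_onset) /
                        (spec$lc - spec$zero_onset)))
    zero <- stats::runif(sum(ns)) < p0
    kk <- spec$k_floor + rlomax(sum(ns), spec$shape, spec$scale)
    kk[zero] <- 0
    k[ns] <- kk
    k
  }
  for (attempt in seq_len(max_resample)) {
    model$springs$k <- draw_k()
    ok <- tryCatch({
      .enm_internal_modes(model)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    if (attempt == max_resample) {
      stop("could not draw a connected reference network in ", max_resample,
           " attempts")
    }
  }

  v <- enm_distance_fluctuations(model)
  targets <- structure(
    data.frame(i = model$springs$i, j = model$springs$j,
               l0 = model$springs$l0, var = v),
    class = c("fluctuation_targets", "data.frame")
  )
  structure(list(model = model, targets = targets, cg = cg, spec = spec),
            class = "reference_enm")
}

#' Sample a Gaussian pseudo-trajectory from a harmonic network
#'
#' Frames are drawn i.i.d. from the multivariate normal with mean at the
#' equilibrium coordinates and covariance `kB*T * H^+`; rigid-body modes get
#' zero variance so coordinates stay bounded while all distance statistics are
#' unaffected.
#'
#' @param model A `bsenm` (or `reference_enm`).
#' @param frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @return A `cg_trajectory`.
#' @export
sample_enm_trajectory <- function(model, frames, seed = 1L) {
  if (inherits(model, "reference_enm")) model <- model$model
  stopifnot(inherits(model, "bsenm"), .is_count(frames), frames >= 2L)
  modes <- .enm_internal_modes(model)
  set.seed(seed)
  sd <- sqrt(kBT(model$temperature) / modes$values)
  Z <- matrix(stats::rnorm(length(sd) * frames), length(sd), frames) * sd
  X <- as.vector(t(model$xyz)) + modes$vectors %*% Z   # 3N x frames
  n <- nrow(model$xyz)
  coords <- array(X, dim = c(3L, n, frames))
  coords <- aperm(coords, c(2L, 1L, 3L))
  structure(list(sites = model$sites, coords = coords),
            class = "cg_trajectory")
}

#' Generate a window series of fluctuating rigidity graphs with a planted edge
#'
#' Each window's spring constants are the reference values times i.i.d.
#' lognormal noise (meanlog 0, sdlog `perturbation`). One designated
#' non-skeleton residue edge — the pair with the largest sequence separation —
#' is overridden in every window with a constant, dominant weight (5x the 99th
#' percentile of the pooled window edge weights), so prominent-mode and
#' hotspot detection has a known answer.
#'
#' @param ref A `reference_enm` or `bsenm`.
#' @param n_windows Number of windows (>= 2; default 20).
#' @param perturbation Lognormal sdlog of the window noise (default 0.3).
#' @param seed Integer seed.
#' @param plant Logical: plant the dominant edge (default TRUE).
#' @return List with `graphs` (per-window non-skeleton `rigidity_graph`s),
#'   `planted` (residue pair, or NULL), `planted_weight`, and `k_windows`
#'   (springs x windows matrix of the noisy spring constants).
#' @export
make_window_series <- function(ref, n_windows = 20L, perturbation = 0.3,
                               seed = 1L, plant = TRUE) {
  model <- if (inherits(ref, "reference_enm")) ref$model else ref
  stopifnot(inherits(model, "bsenm"), .is_count(n_windows), n_windows >= 2L)
  set.seed(seed)
  ns <- nrow(model$springs)
  k_ref <- model$springs$k
  k_win <- matrix(stats::rlnorm(ns * n_windows, 0, perturbation),
                  ns, n_windows) * k_ref
  graphs <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    m <- model
    m$springs$k <- k_win[, w]
    graphs[[w]] <- residue_graph(m, group = "ALL", subset = "nonskeleton",
                                 window = w)
  }
  planted <- NULL
  planted_weight <- NA_real_
  if (isTRUE(plant)) {
    ref_graph <- residue_graph(model, group = "ALL", subset = "nonskeleton")
    idx <- which(upper.tri(ref_graph$A) & ref_graph$A > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("no non-skeleton edges to plant on")
    sep <- abs(idx[, 1L] - idx[, 2L])
    pick <- which.max(sep)
    planted <- c(idx[pick, 1L], idx[pick, 2L])
    pool <- unlist(lapply(graphs, function(g) {
      w <- g$A[upper.tri(g$A)]
      w[w > 0]
    }))
    planted_weight <- 5 * stats::quantile(pool, 0.99, type = 7, names = FALSE)
    for (w in seq_len(n_windows)) {
      graphs[[w]]$A[planted[1L], planted[2L]] <- planted_weight
      graphs[[w]]$A[planted[2L], planted[1L]] <- planted_weight
    }
  }
  list(graphs = graphs, planted = planted, planted_weight = planted_weight,
       k_windows = k_win)
}
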