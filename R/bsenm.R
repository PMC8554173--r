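# The backbone/side-chain elastic network model (bsENM): CG sites connected by
# harmonic springs E = sum 1/2 k (|xi - xj| - l0)^2. Spring constants are
# statistically learned by matching the model's inter-site distance-fluctuation
# variances to targets measured from an all-atom trajectory.

#' Construct a bsENM with uniform initial stiffness
#'
#' One spring is placed on every unordered site pair whose mean distance is
#' below the cutoff `lc`, each with stiffness `k0`. When fluctuation `targets`
#' are supplied, pair inclusion and rest lengths `l0` use the target window's
#' mean distances rather than the single equilibrium frame.
#'
#' @param cg A `cg_model` (equilibrium CG sites and coordinates).
#' @param lc Cutoff distance in Angstrom (default 7.8).
#' @param k0 Initial stiffness for every spring, kcal mol-1 A-2 (default 1).
#' @param targets Optional `fluctuation_targets` covering the candidate pairs.
#' @param temperature Temperature in Kelvin (default 300).
#' @return Object of class `bsenm`: list with `sites`, `xyz`, `springs`
#'   (data.frame `i`, `j`, `l0`, `k`, `category`, `group`) and `temperature`.
#' @export
build_initial_model <- function(cg, lc = 7.8, k0 = 1, targets = NULL,
                                temperature = 300) {
  stopifnot(inherits(cg, "cg_model"), lc > 0, k0 >= 0)
  if (is.null(targets)) {
    pr <- .all_pairs(nrow(cg$xyz))
    l0 <- .row_dist(cg$xyz[pr[, 1L], , drop = FALSE],
                    cg$xyz[pr[, 2L], , drop = FALSE])
    keep <- l0 < lc
    springs <- data.frame(i = pr[keep, 1L], j = pr[keep, 2L], l0 = l0[keep])
  } else {
    keep <- targets$l0 < lc
    springs <- data.frame(i = targets$i[keep], j = targets$j[keep],
                          l0 = targets$l0[keep])
  }
  if (nrow(springs) == 0L) {
    stop("no site pairs within cutoff lc = ", lc, " A")
  }
  springs$k <- rep(k0, nrow(springs))
  cls <- classify_springs(springs, cg$sites)
  springs$category <- cls$category
  springs$group <- cls$group
  structure(
    list(sites = cg$sites, xyz = cg$xyz, springs = springs,
         temperature = temperature),
    class = "bsenm"
  )
}

#' Topology-only reference model bsENM_0
#'
#' All springs within the cutoff receive unit stiffness; no learning. The
#' resulting inter-residue graph records residue contact numbers.
#'
#' @inheritParams build_initial_model
#' @return A `bsenm` with all `k = 1`.
#' @export
build_bsenm0 <- function(cg, lc = 7.8, temperature = 300) {
  build_initial_model(cg, lc = lc, k0 = 1, temperature = temperature)
}

# Expected rigid-body null-space dimension of the Hessian.
.expected_rigid_modes <- function(xyz) {
  if (nrow(xyz) == 1L) 3L else if (.is_collinear(xyz)) 5L else 6L
}

#' Hessian of a bsENM at its equilibrium coordinates
#'
#' For each spring with unit separation vector e, the off-diagonal 3x3 block
#' of sites (i, j) accumulates `-k e e^T` and the two diagonal blocks
#' `+k e e^T`. The result is symmetric positive semidefinite with the
#' rigid-body motions in its null space.
#'
#' @param model A `bsenm`.
#' @return A 3N x 3N symmetric matrix (kcal mol-1 A-2).
#' @export
enm_hessian <- function(model) {
  stopifnot(inherits(model, "bsenm"))
  xyz <- model$xyz
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 sites")
  H <- matrix(0, 3L * n, 3L * n)
  sp <- model$springs
  for (s in seq_len(nrow(sp))) {
    k <- sp$k[s]
    if (k == 0) next
    i <- sp$i[s]; j <- sp$j[s]
    dx <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(dx^2))
    if (r == 0) {
      stop(sprintf("spring (%d, %d) connects coincident sites", i, j))
    }
    e <- dx / r
    blk <- k * tcrossprod(e)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

# Eigendecomposition of the Hessian with rigid-body modes removed.
# Returns list(vectors, values) restricted to the internal modes. With
# strict = TRUE any zero mode beyond the rigid-body ones is an error
# (disconnected or degenerate network); with strict = FALSE exactly the
# rigid-body modes are dropped and remaining near-zero eigenvalues are floored,
# so soft modes yield huge (finite) variances — used inside fluctuation
# matching, where such variances drive the responsible springs back up.
.enm_internal_modes <- function(model, H = enm_hessian(model),
                                zero_tol = 1e-8, strict = TRUE) {
  eg <- eigen(H, symmetric = TRUE)
  lam <- eg$values
  lmax <- max(lam)
  if (lmax <= 0) stop("Hessian has no positive modes (all k zero?)")
  n_rigid <- .expected_rigid_modes(model$xyz)
  if (strict) {
    n_zero <- sum(lam < zero_tol * lmax)
    if (n_zero > n_rigid) {
      stop("Hessian rank deficiency: ", n_zero, " near-zero modes, expected ",
           n_rigid, " rigid-body modes (network disconnected or degenerate)")
    }
  }
  keep <- seq_len(length(lam) - n_rigid)
  list(vectors = eg$vectors[, keep, drop = FALSE],
       values = pmax(lam[keep], 1e-12 * lmax))
}

#' Model-predicted inter-site distance-fluctuation variances
#'
#' The site displacement covariance of the harmonic network is
#' `C = kB*T * H^+` (pseudo-inverse over the internal modes). The variance of
#' the distance between sites i and j is its first-order projection
#' `e^T (C_ii + C_jj - C_ij - C_ji) e` along the equilibrium unit vector e.
#'
#' @param model A `bsenm`.
#' @param pairs Two-column matrix of site pairs; defaults to the model's
#'   spring pairs.
#' @param strict Error when the network has zero modes beyond the rigid-body
#'   ones (default TRUE). Fluctuation matching relaxes this internally so
#'   transiently soft networks report huge variances instead of failing.
#' @return Numeric vector of variances in Angstrom^2, one per pair.
#' @export
enm_distance_fluctuations <- function(model, pairs = NULL, strict = TRUE) {
  stopifnot(inherits(model, "bsenm"))
  if (is.null(pairs)) pairs <- as.matrix(model$springs[, c("i", "j")])
  pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  modes <- .enm_internal_modes(model, strict = strict)
  n <- nrow(model$xyz)
  P <- nrow(pairs)
  U <- matrix(0, 3L * n, P)
  for (p in seq_len(P)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    dx <- model$xyz[j, ] - model$xyz[i, ]
    r <- sqrt(sum(dx^2))
    if (r == 0) stop("coincident sites in pair")
    e <- dx / r
    U[(3L * (i - 1L) + 1L):(3L * i), p] <- -e
    U[(3L * (j - 1L) + 1L):(3L * j), p] <- e
  }
  B <- crossprod(modes$vectors, U)        # modes x pairs
  kBT(model$temperature) * colSums(B^2 / modes$values)
}

# Distance-difference projection vectors for a set of site pairs: column p is
# the 3N-vector with +e at site j and -e at site i (e = equilibrium unit
# separation), so that var(l_p) = u_p^T C u_p for site covariance C.
.distance_projections <- function(model, pairs) {
  n <- nrow(model$xyz)
  U <- matrix(0, 3L * n, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    dx <- model$xyz[j, ] - model$xyz[i, ]
    r <- sqrt(sum(dx^2))
    if (r == 0) stop("coincident sites in pair")
    e <- dx / r
    U[(3L * (i - 1L) + 1L):(3L * i), p] <- -e
    U[(3L * (j - 1L) + 1L):(3L * j), p] <- e
  }
  U
}

# Site covariance kB*T * H^+ evaluated by Cholesky of the ridged Hessian.
# Distance projections are exactly orthogonal to the rigid-body modes, so the
# tiny ridge leaves projected variances unchanged, while genuinely soft modes
# (transiently under-connected sites during matching) yield huge finite
# variances that drive the responsible springs back up at the next update.
.site_covariance_chol <- function(model, H = enm_hessian(model)) {
  ridge <- 1e-10 * mean(diag(H))
  C <- tryCatch(chol2inv(chol(H + diag(ridge, nrow(H)))),
                error = function(e) NULL)
  if (is.null(C)) return(NULL)
  kBT(model$temperature) * C
}

#' Self-consistent fluctuation matching of bsENM spring constants
#'
#' Adjusts every spring constant so the model's predicted distance-fluctuation
#' variances match the targets. Springs whose targets are achievable without
#' them converge to `k = 0` and are kept in the list, flagged.
#'
#' Two solvers are available. `"newton"` (the default for networks up to
#' `newton_max_springs` springs) is a projected Gauss-Newton iteration on the
#' exact Jacobian of the variance map, `dvar_p/dk_q = -(u_p^T C u_q)^2 / kB*T`
#' (u_p = distance projection of pair p, C = site covariance), with a
#' backtracking line search on the worst relative mismatch and clamping at
#' `k = 0`. `"gradient"` is the classical damped per-spring update
#' `k <- max(0, k + alpha * kB*T * (1/var_target - 1/var_model))`, which uses
#' only the diagonal of that Jacobian (exact per spring, since `1/var` is
#' linear in the spring's own stiffness); it scales to large networks but
#' converges slowly when springs are strongly coupled, and carries a
#' divergence guard that backtracks to the best state reached and halves
#' `alpha` after `n_guard` non-improving iterations.
#'
#' @param model A `bsenm` whose springs all have targets.
#' @param targets A `fluctuation_targets` data.frame covering every spring
#'   pair (matched on unordered (i, j)); all target variances must be > 0.
#' @param method `"auto"` (newton when the spring count permits, else
#'   gradient), `"newton"`, or `"gradient"`.
#' @param alpha Dimensionless step size of the gradient update (default 0.5).
#' @param tol Convergence tolerance: max relative variance mismatch over
#'   springs with `k > 0` (default 1e-3).
#' @param max_iter Iteration cap (default: 50 for newton, 500 for gradient).
#' @param n_guard Consecutive non-improving iterations before backtracking
#'   (default 10; newton uses 5).
#' @param newton_max_springs Largest network `"auto"` solves with newton
#'   (default 4000; the Jacobian is springs x springs).
#' @return List with `model` (updated `bsenm`) and `report` (class
#'   `matching_report`): `iterations`, `converged`, `mismatch`, `n_zero`,
#'   `method`, `alpha_final`, and per-spring `k`, `predicted`, `target`.
#' @export
fluctuation_matching <- function(model, targets,
                                 method = c("auto", "newton", "gradient"),
                                 alpha = 0.5, tol = 1e-3, max_iter = NULL,
                                 n_guard = NULL, newton_max_springs = 4000L) {
  stopifnot(inherits(model, "bsenm"), alpha > 0, tol > 0)
  method <- match.arg(method)
  sp <- model$springs
  if (method == "auto") {
    method <- if (nrow(sp) <= newton_max_springs) "newton" else "gradient"
  }
  if (is.null(max_iter)) max_iter <- if (method == "newton") 50L else 500L
  if (is.null(n_guard)) n_guard <- if (method == "newton") 5L else 10L
  key_m <- .pair_key(sp$i, sp$j)
  key_t <- .pair_key(targets$i, targets$j)
  hit <- match(key_m, key_t)
  if (anyNA(hit)) {
    stop("missing fluctuation target for ", sum(is.na(hit)), " spring(s)")
  }
  v_t <- targets$var[hit]
  if (any(v_t <= 0)) stop("all target variances must be > 0")
  kT <- kBT(model$temperature)
  pairs <- as.matrix(sp[, c("i", "j")])
  U <- .distance_projections(model, pairs)

  variances <- function(k) {
    if (!any(k > 0)) return(rep(Inf, length(v_t)))
    model$springs$k <- k
    C <- .site_covariance_chol(model)
    if (is.null(C)) {
      model$springs$k <- k
      return(enm_distance_fluctuations(model, pairs, strict = FALSE))
    }
    colSums((C %*% U) * U)
  }
  worst <- function(k, v_m) {
    live <- k > 0
    if (any(live)) max(abs(v_m[live] - v_t[live]) / v_t[live]) else Inf
  }

  k <- sp$k
  best_k <- k
  best_mismatch <- Inf
  stall <- 0L
  converged <- FALSE
  iter <- 0L
  alpha0 <- alpha

  if (method == "newton") {
    # Levenberg-Marquardt least squares on the relative residuals
    # r_p = (var_model_p - var_target_p) / var_target_p, using the exact
    # Jacobian dvar_p/dk_q = -(u_p^T C u_q)^2 / kB*T. Noisy targets make the
    # system inconsistent; LM converges to the clamped least-squares fit.
    lm_lambda <- 1e-6
    best_obj <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      model$springs$k <- k
      C <- .site_covariance_chol(model)
      if (is.null(C)) {
        v_m <- variances(k)
        k <- pmax(0, k + alpha * kT * (1 / v_t - 1 / v_m))
        next
      }
      S <- crossprod(U, C %*% U)       # covariance of distance coordinates
      v_m <- diag(S)
      mismatch <- worst(k, v_m)
      r <- (v_m - v_t) / v_t
      obj <- sum(r^2)
      if (obj < best_obj * (1 - 1e-6)) {
        best_obj <- obj
        best_k <- k
        best_mismatch <- mismatch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= n_guard) break
      }
      if (mismatch <= tol) {
        converged <- TRUE
        break
      }
      Jrel <- -(S * S / kT) / v_t      # d r / d k
      N <- crossprod(Jrel)
      g <- crossprod(Jrel, r)
      dN <- diag(N)
      dN[dN <= 0] <- mean(dN[dN > 0])
      accepted <- FALSE
      for (try in 1:8) {
        delta <- tryCatch(
          solve(N + lm_lambda * diag(dN, nrow = nrow(N)), -g),
          error = function(e) NULL
        )
        if (is.null(delta)) {
          # singular normal equations (e.g. unreachable targets): fall back
          # to the damped per-spring gradient direction
          delta <- alpha * kT * (1 / v_t - 1 / v_m) / 2^(try - 1)
        }
        if (!is.null(delta)) {
          k_try <- pmax(0, k + drop(delta))
          v_try <- variances(k_try)
          if (sum(((v_try - v_t) / v_t)^2) < obj) {
            k <- k_try
            lm_lambda <- max(lm_lambda / 3, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lm_lambda <- lm_lambda * 10
      }
      if (!accepted) {
        stall <- stall + 1L
        if (stall >= n_guard) break
      }
    }
    if (worst(k, variances(k)) < best_mismatch) {
      best_k <- k
    }
  } else {
    while (iter < max_iter) {
      iter <- iter + 1L
      v_m <- variances(k)
      mismatch <- worst(k, v_m)
      if (mismatch <= tol) {
        converged <- TRUE
        best_k <- k
        best_mismatch <- mismatch
        break
      }
      if (mismatch < best_mismatch) {
        best_mismatch <- mismatch
        best_k <- k
        stall <- 0L
        alpha <- min(alpha0, alpha * 1.1)
      } else {
        stall <- stall + 1L
        if (stall >= n_guard) {
          alpha <- alpha / 2
          stall <- 0L
          if (alpha < 1e-8) break
          k <- best_k
          v_m <- variances(k)
        }
      }
      k <- pmax(0, k + alpha * kT * (1 / v_t - 1 / v_m))
    }
  }

  model$springs$k <- best_k
  v_m <- variances(best_k)
  report <- structure(
    list(iterations = iter, converged = converged,
         mismatch = worst(best_k, v_m), n_zero = sum(best_k == 0),
         method = method, alpha_final = alpha,
         springs = data.frame(i = sp$i, j = sp$j, k = best_k,
                              predicted = v_m, target = v_t)),
    class = "matching_report"
  )
  list(model = model, report = report)
}

#' Trim weak springs and refit
#'
#' Removes springs with `k < k_min` (skeleton-1 springs are exempt so chain
#' connectivity is never broken), verifies the trimmed network still has full
#' internal rank, and reruns [fluctuation_matching()] on the retained set.
#'
#' @param model A converged `bsenm`.
#' @param targets Fluctuation targets (as in [fluctuation_matching()]).
#' @param k_min Trim threshold, kcal mol-1 A-2 (default 1e-3).
#' @param ... Passed on to [fluctuation_matching()].
#' @return List with `model`, `report`, and `trimmed` (the removed springs).
#' @export
trim_and_refit <- function(model, targets, k_min = 1e-3, ...) {
  stopifnot(inherits(model, "bsenm"), k_min >= 0)
  sp <- model$springs
  drop <- sp$k < k_min & sp$category != "skeleton1"
  trimmed <- sp[drop, , drop = FALSE]
  model$springs <- sp[!drop, , drop = FALSE]
  ok <- tryCatch({
    .enm_internal_modes(model)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("trimming at k_min = ", k_min,
         " disconnects the network; try a lower k_min")
  }
  out <- fluctuation_matching(model, targets, ...)
  out$trimmed <- trimmed
  out
}

#' Write / read a bsENM spring table
#'
#' The spring list is stored as TSV (columns `i`, `j`, `residue_i`,
#' `residue_j`, `category`, `group`, `l0`, `k`) with a JSON metadata sidecar.
#'
#' @param model A `bsenm`.
#' @param file Output TSV path.
#' @param meta Optional named list of run metadata (cutoff, step, seed, ...).
#' @return Invisibly, the file path.
#' @export
write_bsenm <- function(model, file, meta = list()) {
  stopifnot(inherits(model, "bsenm"))
  sp <- model$springs
  out <- data.frame(
    i = sp$i, j = sp$j,
    residue_i = model$sites$residue[sp$i],
    residue_j = model$sites$residue[sp$j],
    category = sp$category, group = sp$group, l0 = sp$l0, k = sp$k
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta$temperature <- model$temperature
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE)
  invisible(file)
}

#' @export
print.bsenm <- function(x, ...) {
  cat("bsENM:", nrow(x$sites), "sites,", nrow(x$springs), "springs (",
      sum(x$springs$k > 0), "with k > 0 ), T =", x$temperature, "K\n")
  invisible(x)
}

#' @export
print.matching_report <- function(x, ...) {
  cat("Fluctuation matching:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(max rel. mismatch %.3g)", x$mismatch), "\n")
  cat("  springs at k = 0:", x$n_zero, "of", nrow(x$springs), "\n")
  invisible(x)
}
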