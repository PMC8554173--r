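test_that("cutoff controls spring construction", {
  m <- toy_pair_model(dist = 5)
  expect_equal(nrow(m$springs), 1L)

  cg8 <- structure(list(
    sites = data.frame(site = 1:2, residue = 1:2, chain = "A", resno = 1:2,
                       resid = "ALA", site_class = "backbone", source = "N"),
    xyz = rbind(c(0, 0, 0), c(8, 0, 0))), class = "cg_model")
  expect_error(build_initial_model(cg8, lc = 7.8), "no site pairs")

  cg3 <- structure(list(
    sites = data.frame(site = 1:3, residue = 1:3, chain = "A", resno = 1:3,
                       resid = "ALA", site_class = "backbone", source = "N"),
    xyz = rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))), class = "cg_model")
  m3 <- build_initial_model(cg3, lc = 5)
  expect_equal(nrow(m3$springs), 2L)
  expect_setequal(paste(m3$springs$i, m3$springs$j), c("1 2", "2 3"))

  m0 <- build_bsenm0(cg3, lc = 5)
  expect_true(all(m0$springs$k == 1))
})

test_that("the Hessian matches theory and numerical differentiation", {
  # single spring k = 1 along x: one internal mode of stiffness 2k
  m <- toy_pair_model(dist = 5, k = 1)
  H <- enm_hessian(m)
  expect_equal(H, t(H))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(rep(0, 5), 2), tolerance = 1e-12)

  m$springs$k <- 0
  expect_true(all(enm_hessian(m) == 0))

  # 4-site toy: Hessian equals the finite-difference second derivative of
  # E = sum 1/2 k (|xi-xj| - l0)^2 at equilibrium
  set.seed(5)
  xyz <- matrix(rnorm(12, sd = 3), 4, 3)
  springs <- data.frame(i = c(1, 1, 2, 3, 1), j = c(2, 3, 3, 4, 4),
                        k = c(1.5, 2, 0.7, 1.2, 0.4))
  m4 <- manual_bsenm(xyz, springs)
  H4 <- enm_hessian(m4)
  energy <- function(x) {
    p <- matrix(x, ncol = 3, byrow = FALSE)
    sp <- m4$springs
    d <- sqrt(rowSums((p[sp$i, , drop = FALSE] - p[sp$j, , drop = FALSE])^2))
    sum(0.5 * sp$k * (d - sp$l0)^2)
  }
  # x layout differs: Hessian blocks use site-major (x1 y1 z1 x2 ...)
  energy_flat <- function(v) {
    p <- matrix(v, ncol = 3, byrow = TRUE)
    sp <- m4$springs
    d <- sqrt(rowSums((p[sp$i, , drop = FALSE] - p[sp$j, , drop = FALSE])^2))
    sum(0.5 * sp$k * (d - sp$l0)^2)
  }
  x0 <- as.vector(t(xyz))
  h <- 1e-5
  Hnum <- matrix(0, 12, 12)
  for (a in 1:12) for (b in 1:12) {
    ea <- replace(numeric(12), a, h)
    eb <- replace(numeric(12), b, h)
    Hnum[a, b] <- (energy_flat(x0 + ea + eb) - energy_flat(x0 + ea) -
                     energy_flat(x0 + eb) + energy_flat(x0)) / h^2
  }
  expect_equal(H4, Hnum, tolerance = 1e-4)
})

test_that("an isolated pair fluctuates by kB*T/k", {
  m <- toy_pair_model(dist = 5, k = 1, temperature = 300)
  expect_equal(enm_distance_fluctuations(m), kBT(300), tolerance = 1e-12)
  expect_equal(kBT(300), 0.5961, tolerance = 1e-12)

  # doubling all k halves every variance
  ref <- ref_fixture()
  v1 <- enm_distance_fluctuations(ref$model)
  m2 <- ref$model
  m2$springs$k <- 2 * m2$springs$k
  expect_equal(enm_distance_fluctuations(m2), v1 / 2, tolerance = 1e-10)
})

test_that("predicted variances agree with Monte-Carlo sampling", {
  # well-separated sites (all pair distances > 4 A) keep sd(l)/l0 small
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5.5, 0), c(3, 2, 5.5),
               c(-2.5, 4, 3))
  pr <- t(utils::combn(5, 2))   # fully connected: full internal rank
  springs <- data.frame(i = pr[, 1], j = pr[, 2],
                        k = c(1.5, 2, 0.7, 1.2, 0.9, 0.6, 1.1, 0.8, 1.4, 0.5))
  # cold network: first-order projected variances are exact in the
  # small-fluctuation limit that the harmonic model assumes
  m5 <- manual_bsenm(xyz, springs, temperature = 30)
  v_analytic <- enm_distance_fluctuations(m5)
  n <- 1e5
  traj <- sample_enm_trajectory(m5, frames = n, seed = 10)
  v_mc <- compute_fluctuation_targets(
    traj, as.matrix(m5$springs[, c("i", "j")]))$var
  rel_se <- sqrt(2 / n)
  expect_lt(max(abs(v_mc - v_analytic) / v_analytic), 3 * rel_se + 0.01)
})

test_that("predicted variances are rigid-body invariant", {
  ref <- ref_fixture()
  v1 <- enm_distance_fluctuations(ref$model)
  m <- ref$model
  m$xyz <- rigid_transform(m$xyz, seed = 31)
  expect_equal(enm_distance_fluctuations(m), v1, tolerance = 1e-8)
})

test_that("rank deficiency beyond the rigid-body modes is an error", {
  # two disconnected pairs
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 20, 3), c(4, 21, 3))
  springs <- data.frame(i = c(1, 3), j = c(2, 4), k = c(1, 1))
  m <- manual_bsenm(xyz, springs)
  expect_error(enm_distance_fluctuations(m), "rank deficiency")
})

test_that("matching inverts an isolated pair from any start", {
  target <- data.frame(i = 1L, j = 2L, l0 = 5, var = kBT(300) / 2)
  class(target) <- c("fluctuation_targets", "data.frame")
  for (k0 in c(0.1, 1, 10)) {
    m <- toy_pair_model(dist = 5, k = k0)
    fit <- fluctuation_matching(m, target, tol = 1e-6)
    expect_true(fit$report$converged)
    expect_equal(fit$model$springs$k, 2, tolerance = 1e-5)
  }
})

test_that("matching is a fixed point of a model's own fluctuations", {
  ref <- ref_fixture()
  own <- ref$targets
  fit <- fluctuation_matching(ref$model, own, max_iter = 2L)
  expect_true(fit$report$converged)
  expect_equal(fit$model$springs$k, ref$model$springs$k, tolerance = 1e-6)
})

test_that("an unachievable target drives the redundant spring to zero", {
  # five fully connected sites carry 10 springs for 9 internal degrees of
  # freedom: one spring is redundant. Demand a variance on it far above what
  # the other nine allow
  set.seed(34)
  xyz <- matrix(rnorm(15, sd = 4), 5, 3)
  pr <- t(utils::combn(5, 2))
  springs <- data.frame(i = pr[, 1], j = pr[, 2], k = rep(1, 10))
  m <- manual_bsenm(xyz, springs)
  open_var <- local({
    m2 <- m
    m2$springs$k[10] <- 0
    enm_distance_fluctuations(m2)[10]   # still full rank without it
  })
  v_own <- enm_distance_fluctuations(m)
  tg <- data.frame(i = springs$i, j = springs$j, l0 = m$springs$l0,
                   var = c(v_own[1:9], 10 * open_var))
  fit <- fluctuation_matching(m, tg, tol = 1e-6, max_iter = 200)
  expect_equal(fit$model$springs$k[10], 0)
  # grid-search oracle: no k10 > 0 can reach the inflated target
  grid_v <- vapply(c(0.01, 0.1, 1, 10), function(k10) {
    m2 <- m
    m2$springs$k <- c(fit$model$springs$k[1:9], k10)
    enm_distance_fluctuations(m2)[10]
  }, numeric(1))
  expect_true(all(grid_v < 10 * open_var))
})

test_that("clamped springs with non-positive update stay at zero", {
  # gradient method: a spring at 0 whose target exceeds the achievable
  # variance keeps a non-positive update and never re-enters
  set.seed(35)
  xyz <- matrix(rnorm(15, sd = 4), 5, 3)
  pr <- t(utils::combn(5, 2))
  springs <- data.frame(i = pr[, 1], j = pr[, 2], k = c(rep(1, 9), 0))
  m <- manual_bsenm(xyz, springs)
  v0 <- enm_distance_fluctuations(m)
  tg <- data.frame(i = springs$i, j = springs$j, l0 = m$springs$l0,
                   var = c(v0[1:9], 5 * v0[10]))
  fit <- fluctuation_matching(m, tg, method = "gradient", max_iter = 50)
  expect_equal(fit$model$springs$k[10], 0)
})

test_that("spring constants are recovered from analytic targets", {
  spec <- fixture_spec(n_residues = 20L, seed = 13L)
  ref <- make_reference_enm(spec)
  init <- build_initial_model(ref$cg, lc = spec$lc, k0 = 1,
                              targets = ref$targets)
  fit <- fluctuation_matching(init, ref$targets, tol = 1e-6)
  k_ref <- ref$model$springs$k
  k_fit <- fit$model$springs$k
  big <- k_ref > 0.1
  expect_lt(max(abs(k_fit[big] - k_ref[big]) / k_ref[big]), 0.02)

  tr <- trim_and_refit(fit$model, ref$targets, tol = 1e-6)
  key <- function(s) paste(s$i, s$j)
  expect_setequal(key(tr$model$springs)[tr$model$springs$k > 0],
                  key(ref$model$springs)[k_ref > 0])
})

test_that("trimming respects the threshold and skeleton exemption", {
  # 5 fully connected sites: dropping one spring leaves exactly the 9 needed
  # for full internal rank
  set.seed(33)
  xyz <- matrix(rnorm(15, sd = 3), 5, 3)
  pr <- t(utils::combn(5, 2))
  springs <- data.frame(i = pr[, 1], j = pr[, 2],
                        k = c(rep(5, 9), 5e-4),
                        category = c(rep("skeleton1", 9), "nonskeleton"),
                        group = "BB")
  m <- manual_bsenm(xyz, springs)
  v <- enm_distance_fluctuations(m, strict = FALSE)
  tg <- data.frame(i = springs$i, j = springs$j, l0 = m$springs$l0, var = v)
  tr <- trim_and_refit(m, tg, k_min = 1e-3)
  expect_equal(nrow(tr$model$springs), 9L)
  expect_equal(nrow(tr$trimmed), 1L)

  # k_min = 0 keeps everything
  tr0 <- trim_and_refit(m, tg, k_min = 0)
  expect_equal(nrow(tr0$model$springs), 10L)

  # a weak skeleton1 spring is exempt from trimming
  m2 <- m
  m2$springs$k[2] <- 1e-5
  v2 <- enm_distance_fluctuations(m2, strict = FALSE)
  tg2 <- transform(tg, var = v2)
  tr2 <- trim_and_refit(m2, tg2, k_min = 1e-3)
  expect_true(paste(tr2$model$springs$i, tr2$model$springs$j)[2] == "1 3")
  expect_equal(nrow(tr2$model$springs), 9L)
})

test_that("the reference Hessian is symmetric positive semidefinite", {
  ref <- ref_fixture()
  H <- enm_hessian(ref$model)
  expect_equal(H, t(H), tolerance = 1e-12)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # exactly 6 rigid-body modes for a 3-D connected network
  expect_equal(sum(ev < 1e-8 * max(ev)), 6L)
})
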