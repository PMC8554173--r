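# A hand-built 4-mode spectrum used by several characteristic-mode tests.
toy_spectrum <- function(weights) {
  # weights: N x M matrix of squared weights per residue/mode (rows sum to 1)
  structure(list(values = rev(sort(colSums(weights))) * 0 + c(10, 7, 3, 1),
                 vectors = sqrt(weights), kind = "K"),
            class = "spectral_result")
}

test_that("characteristic modes follow the two-branch rule", {
  # residue 1: weight 0.6 in prominent mode 3 -> mode 3
  w <- rbind(c(0.2, 0.1, 0.6, 0.1),
             c(0.05, 0.05, 0.05, 0.85),
             c(0.4, 0.3, 0.2, 0.1))
  s <- structure(list(values = c(10, 7, 3, 1), vectors = t(sqrt(w)) * 0,
                      kind = "K"), class = "spectral_result")
  s$vectors <- matrix(0, 3, 4)
  s$vectors[] <- sqrt(w)
  expect_equal(characteristic_mode(1, s, prominent = c(2, 3)), 3L)
  # residue 2: below threshold in every prominent mode, heaviest elsewhere (4)
  expect_equal(characteristic_mode(2, s, prominent = c(2, 3)), 4L)
  # empty prominent set falls back over all modes
  expect_equal(characteristic_mode(2, s, prominent = integer(0)), 4L)
  # prominent covers everything and the residue fails the threshold
  expect_error(characteristic_mode(2, s, prominent = 1:4, nu_c2 = 0.9),
               "no non-prominent modes")
})

test_that("characteristic modes match an exhaustive two-branch search", {
  set.seed(18)
  n <- 4; m <- 6
  w <- matrix(rexp(n * m), n, m)
  w <- w / rowSums(w)
  s <- structure(list(values = sort(rexp(m, 0.2), decreasing = TRUE),
                      vectors = sqrt(w), kind = "K"),
                 class = "spectral_result")
  prominent <- c(1L, 4L)
  for (I in 1:n) {
    # brute force both branches
    wp <- w[I, prominent]
    pi_mode <- prominent[order(-wp)][1]
    expected <- if (w[I, pi_mode] >= 0.1) pi_mode else {
      rest <- setdiff(1:m, prominent)
      rest[order(-w[I, rest])][1]
    }
    expect_equal(characteristic_mode(I, s, prominent), expected)
  }
})

test_that("rigidity scores multiply strength by averaged content", {
  expect_equal(residue_score(2, lambda = c(1, 10, 3), c(0.5, 0.8, 0.9)), 8)
  expect_equal(residue_score(1, lambda = c(4, 1), c(0, 1)), 0)
})

test_that("backbone/side-chain combination respects BS participation", {
  out <- combine_scores(kappa_bb = 3, kappa_bs = 5, kappa_ss = 2,
                        bs_backbone = TRUE, bs_sidechain = FALSE,
                        glycine = FALSE)
  expect_equal(out$kappa_b, 5)
  expect_equal(out$kappa_s, 2)

  # side-chain-only participation: BS never competes for the backbone score
  out2 <- combine_scores(3, 5, 2, bs_backbone = FALSE, bs_sidechain = TRUE,
                         glycine = FALSE)
  expect_equal(out2$kappa_b, 3)
  expect_equal(out2$kappa_s, 5)

  # glycine gets the minimal placeholder side-chain score
  out3 <- combine_scores(3, 5, NA_real_, bs_backbone = TRUE,
                         bs_sidechain = FALSE, glycine = TRUE,
                         gly_placeholder = 0)
  expect_equal(out3$kappa_s, 0)
})

test_that("structural locations classify by element margins", {
  # 9-residue strand flanked by loops; margin 3
  ss <- c(rep("L", 3), rep("E", 9), rep("L", 6))
  loc <- classify_location(ss, margin = 3)
  # middle of the strand (position 5 of 9 -> index 8): interior
  expect_equal(loc[8], "interior")
  # positions within 3 of either strand end: periphery
  expect_equal(loc[4], "periphery")
  expect_equal(loc[12], "periphery")
  # loop residue 2 after the strand end: periphery
  expect_equal(loc[14], "periphery")
  # far loop residue: loop
  expect_equal(loc[18], "loop")
  # all-loop input has no peripheries
  expect_true(all(classify_location(rep("L", 10)) == "loop"))
  # labels can come from a file
  f <- tempfile()
  writeLines(paste(ss, collapse = ""), f)
  expect_equal(classify_location(f, margin = 3), loc)
  expect_error(classify_location(c("H", "X")), "labels must be")
})

test_that("hotspots of prominent modes occupy the high-score region", {
  ref <- ref_fixture()
  ws <- make_window_series(ref, 20, 0.3, seed = 5)
  st <- mean_mode_content(ws$graphs)
  pm <- select_prominent_modes(st$spectrum$values, st$content_mean, 0.75)
  expect_gt(length(pm$modes), 0L)
  hs <- sort(unique(unlist(lapply(
    pm$modes, function(m) hotspot_residues(st$spectrum$vectors[, m], 0.1)))))
  kap <- vapply(seq_len(ws$graphs[[1]]$n), function(I) {
    residue_score(characteristic_mode(I, st$spectrum, pm$modes, 0.1),
                  st$spectrum$values, st$content_mean)
  }, numeric(1))
  expect_gt(min(kap[hs]), median(kap[-hs]))
  # a hotspot's characteristic mode is always prominent
  for (I in hs) {
    expect_true(characteristic_mode(I, st$spectrum, pm$modes, 0.1) %in%
                  pm$modes)
  }
})

test_that("nu_c2 = 0 always takes the prominent branch", {
  ref <- ref_fixture()
  ws <- make_window_series(ref, 10, 0.3, seed = 6)
  st <- mean_mode_content(ws$graphs)
  pm <- select_prominent_modes(st$spectrum$values, st$content_mean, 0.75)
  for (I in seq_len(ws$graphs[[1]]$n)) {
    if (any(st$spectrum$vectors[I, pm$modes]^2 > 0)) {
      expect_true(characteristic_mode(I, st$spectrum, pm$modes, 0) %in%
                    pm$modes)
    }
  }
})

test_that("score tables are equivariant under residue relabelling", {
  ref <- ref_fixture()
  ws <- make_window_series(ref, 10, 0.3, seed = 44, plant = FALSE)
  st <- mean_mode_content(ws$graphs)
  pm <- select_prominent_modes(st$spectrum$values, st$content_mean, 0.75)
  n <- ws$graphs[[1]]$n
  kap <- vapply(seq_len(n), function(I) {
    residue_score(characteristic_mode(I, st$spectrum, pm$modes, 0.1),
                  st$spectrum$values, st$content_mean)
  }, numeric(1))

  set.seed(45)
  p <- sample(n)
  gperm <- lapply(ws$graphs, function(g) { g$A <- g$A[p, p]; g })
  stp <- mean_mode_content(gperm)
  pmp <- select_prominent_modes(stp$spectrum$values, stp$content_mean, 0.75)
  kapp <- vapply(seq_len(n), function(I) {
    residue_score(characteristic_mode(I, stp$spectrum, pmp$modes, 0.1),
                  stp$spectrum$values, stp$content_mean)
  }, numeric(1))
  expect_equal(kapp, kap[p], tolerance = 1e-8)
})

test_that("the full score table wires groups, hotspots and glycine", {
  ref <- ref_fixture()
  stats <- list()
  ws <- make_window_series(ref, 15, 0.3, seed = 46, plant = FALSE)
  for (grp in c("BB", "BS", "SS")) {
    graphs <- lapply(seq_len(ncol(ws$k_windows)), function(w) {
      m <- ref$model
      m$springs$k <- ws$k_windows[, w]
      residue_graph(m, group = grp, subset = "nonskeleton", window = w)
    })
    stats[[grp]] <- mean_mode_content(graphs)
  }
  tab <- residue_score_table(ref$model, stats)
  expect_equal(nrow(tab), 30L)
  expect_true(all(tab$kappa_bb >= 0))
  expect_true(all(is.na(tab$kappa_ss[tab$glycine])))
  expect_true(all(tab$kappa_s[tab$glycine] == 0))
  # kappa_b is at least the BB score (BS can only raise it)
  expect_true(all(tab$kappa_b >= tab$kappa_bb - 1e-12))
  # glycine every 10 residues in the fixture's repeating sequence
  expect_equal(which(tab$glycine), c(4L, 14L, 24L))
  f <- tempfile(fileext = ".tsv")
  write_score_table(tab, f)
  expect_equal(nrow(read.delim(f)), 30L)
})
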