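# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# Two CG sites a fixed distance apart on the x axis, joined by one spring.
toy_pair_model <- function(dist = 5, k = 1, temperature = 300) {
  cg <- structure(list(
    sites = data.frame(site = 1:2, residue = 1:2, chain = "A", resno = 1:2,
                       resid = "ALA", site_class = "backbone", source = "N"),
    xyz = rbind(c(0, 0, 0), c(dist, 0, 0))
  ), class = "cg_model")
  m <- build_initial_model(cg, lc = dist + 1, k0 = k,
                           temperature = temperature)
  m
}

# Hand-built bsenm from explicit coordinates and a spring table; categories
# and groups are taken as given (no classification).
manual_bsenm <- function(xyz, springs, site_class = NULL, resid = NULL,
                         residue = NULL, temperature = 300) {
  n <- nrow(xyz)
  if (is.null(site_class)) site_class <- rep("backbone", n)
  if (is.null(resid)) resid <- rep("ALA", n)
  if (is.null(residue)) residue <- seq_len(n)
  sites <- data.frame(site = seq_len(n), residue = residue, chain = "A",
                      resno = residue, resid = resid,
                      site_class = site_class, source = "N")
  springs$l0 <- sqrt(rowSums((xyz[springs$i, , drop = FALSE] -
                                xyz[springs$j, , drop = FALSE])^2))
  if (is.null(springs$category)) springs$category <- "nonskeleton"
  if (is.null(springs$group)) springs$group <- "BB"
  structure(list(sites = sites, xyz = xyz, springs = springs,
                 temperature = temperature),
            class = "bsenm")
}

# A small all-atom table (ALA-GLY dipeptide) for mapping tests.
ala_gly_atoms <- function() {
  data.frame(
    elety = c("N", "CA", "C", "O", "CB", "HB1",
              "N", "CA", "C", "O", "HA"),
    resid = c(rep("ALA", 6), rep("GLY", 5)),
    chain = "A",
    resno = c(rep(1L, 6), rep(2L, 5)),
    x = c(0, 1.4, 2.1, 2.2, 1.8, 1.9, 3.2, 4.5, 5.2, 5.4, 4.6),
    y = c(0, 0.5, 1.7, 2.9, -0.8, -1.7, 1.6, 1.9, 3.1, 4.3, 1.0),
    z = c(0, 0.1, 0, -0.2, 0.3, 0.4, 0.2, 0, -0.1, 0.1, 0.5)
  )
}

# Memoised standard reference fixture shared across test files.
ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_enm(fixture_spec(
      n_residues = 30L, seed = 7L))
    cache
  }
})

# Connected-component count of a weighted adjacency matrix (simple BFS).
count_components <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# Random rigid-body transform applied to an n x 3 coordinate matrix.
rigid_transform <- function(xyz, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 10)
  sweep(xyz %*% q, 2, -shift)
}
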