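# Atomic-to-coarse-grained mapping: every amino acid contributes two backbone
# sites (amide N, carbonyl O) and, except glycine, one side-chain site placed
# either at a representative interacting atom or at the centre of mass of the
# side-chain heavy atoms. Ions and other hetero residues become single-site
# residues of their own.

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP"
)

#' Default atomic-to-CG mapping table
#'
#' Polar and charged side chains are represented by the atom at which their
#' specific interactions (hydrogen bonds, salt bridges) form; hydrophobic side
#' chains by the centre of mass of their heavy atoms (`"COM"`). Glycine has no
#' side-chain site. Histidine CHARMM tautomer names (HSD/HSE/HSP) follow HIS.
#'
#' @return A list with components `sidechain` (named character vector:
#'   residue name -> atom name or `"COM"`; glycine maps to `NA`), `ions`
#'   (residue names treated as single-site residues), and `fallback_com`
#'   (logical; map unknown residues to a single heavy-atom COM site).
#' @seealso [read_mapping_config()] to load a user table, [map_structure()].
#' @export
default_mapping_table <- function() {
  sc <- c(
    ALA = "CB",  SER = "OG",  THR = "OG1", CYS = "SG",  TYR = "OH",
    ASP = "CG",  GLU = "CD",  ASN = "CG",  GLN = "CD",  HIS = "NE2",
    HSD = "NE2", HSE = "NE2", HSP = "NE2", LYS = "NZ",  ARG = "CZ",
    VAL = "COM", LEU = "COM", ILE = "COM", MET = "COM", PHE = "COM",
    TRP = "COM", PRO = "COM", GLY = NA_character_
  )
  list(
    sidechain = sc,
    ions = c("CA", "CAL", "ZN", "MG", "NA", "CL", "K", "SOD", "CLA", "POT"),
    fallback_com = FALSE
  )
}

#' Read a CG mapping configuration from a YAML file
#'
#' The file may define `sidechain:` (residue name -> atom name or COM),
#' `ions:` (list of residue names) and `fallback_com:` (logical). Entries
#' override the defaults of [default_mapping_table()].
#'
#' @param file Path to a YAML mapping file.
#' @return A mapping table list as in [default_mapping_table()].
#' @export
read_mapping_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  map <- default_mapping_table()
  if (!is.null(cfg$sidechain)) {
    sc <- vapply(cfg$sidechain, function(x) {
      if (is.null(x) || identical(x, "none")) NA_character_ else as.character(x)
    }, character(1L))
    map$sidechain[toupper(names(sc))] <- sc
  }
  if (!is.null(cfg$ions)) map$ions <- toupper(unlist(cfg$ions))
  if (!is.null(cfg$fallback_com)) map$fallback_com <- isTRUE(cfg$fallback_com)
  map
}

# Normalise atomic input (a bio3d pdb object or a plain atom data.frame with
# columns elety, resid, chain, resno, x, y, z) to one atom table.
.atom_table <- function(x) {
  if (inherits(x, "pdb")) {
    at <- x$atom
  } else if (is.data.frame(x)) {
    at <- x
  } else {
    stop("expected a bio3d 'pdb' object or an atom data.frame")
  }
  need <- c("elety", "resid", "resno", "x", "y", "z")
  missing <- setdiff(need, names(at))
  if (length(missing) > 0L) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(at$chain)) at$chain <- "A"
  at$chain[is.na(at$chain)] <- "A"
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  # element symbol; fall back to the first letter of the atom name
  if (is.null(at$elesy) || all(is.na(at$elesy))) {
    at$elesy <- substr(gsub("^[0-9]", "", at$elety), 1L, 1L)
  }
  at
}

# Per-residue CG site construction shared by map_structure/map_trajectory.
# Returns sites data.frame plus an n_sites x n_atoms weight matrix W so that
# site coordinates are W %*% atom_xyz for any frame.
.build_mapping <- function(atoms, mapping) {
  heavy <- toupper(atoms$elesy) != "H"
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  res_order <- unique(res_key)
  n_atoms <- nrow(atoms)

  sites <- list()
  w_rows <- list()
  add_site <- function(residue, chain, resno, resid, class, source, atom_idx,
                       weights) {
    sites[[length(sites) + 1L]] <<- data.frame(
      residue = residue, chain = chain, resno = resno, resid = resid,
      site_class = class, source = source, stringsAsFactors = FALSE
    )
    w <- numeric(n_atoms)
    w[atom_idx] <- weights
    w_rows[[length(w_rows) + 1L]] <<- w
  }

  for (ri in seq_along(res_order)) {
    sel <- which(res_key == res_order[ri])
    resid <- toupper(atoms$resid[sel[1L]])
    chain <- atoms$chain[sel[1L]]
    resno <- atoms$resno[sel[1L]]

    if (resid %in% .standard_aa) {
      for (bb in c("N", "O")) {
        hit <- sel[atoms$elety[sel] == bb]
        if (length(hit) == 0L) {
          stop(sprintf("residue %s%d (%s): required backbone atom %s missing",
                       chain, resno, resid, bb))
        }
        add_site(ri, chain, resno, resid, "backbone", bb, hit[1L], 1)
      }
      rule <- mapping$sidechain[resid]
      if (resid == "GLY" || is.na(rule)) next
      if (rule == "COM") {
        sc <- sel[heavy[sel] & !(atoms$elety[sel] %in% .backbone_atoms)]
        if (length(sc) == 0L) {
          stop(sprintf("residue %s%d (%s): no side-chain heavy atoms for COM",
                       chain, resno, resid))
        }
        add_site(ri, chain, resno, resid, "sidechain", "COM",
                 sc, rep(1 / length(sc), length(sc)))
      } else {
        hit <- sel[atoms$elety[sel] == rule]
        if (length(hit) == 0L) {
          stop(sprintf("residue %s%d (%s): side-chain atom %s missing",
                       chain, resno, resid, rule))
        }
        add_site(ri, chain, resno, resid, "sidechain", rule, hit[1L], 1)
      }
    } else if (resid %in% mapping$ions) {
      add_site(ri, chain, resno, resid, "sidechain", "ion", sel[1L], 1)
    } else if (isTRUE(mapping$fallback_com)) {
      sc <- sel[heavy[sel]]
      if (length(sc) == 0L) {
        stop(sprintf("residue %s%d (%s): no heavy atoms", chain, resno, resid))
      }
      add_site(ri, chain, resno, resid, "sidechain", "COM",
               sc, rep(1 / length(sc), length(sc)))
    } else {
      stop(sprintf(
        "residue %s%d (%s): no mapping rule (enable fallback_com or extend the table)",
        chain, resno, resid))
    }
  }

  sites <- do.call(rbind, sites)
  sites <- cbind(site = seq_len(nrow(sites)), sites)
  list(sites = sites, W = do.call(rbind, w_rows))
}

#' Map an atomic structure onto bsENM coarse-grained sites
#'
#' @param structure A bio3d `pdb` object (as from [bio3d::read.pdb()]) or a
#'   data.frame of atoms with columns `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z` (optionally `insert`, `elesy`).
#' @param mapping Mapping table, see [default_mapping_table()].
#' @return An object of class `cg_model`: list with `sites` (data.frame:
#'   `site`, `residue`, `chain`, `resno`, `resid`, `site_class`, `source`)
#'   and `xyz` (n_sites x 3 matrix, Angstrom).
#' @examples
#' ala <- data.frame(
#'   elety = c("N", "CA", "C", "O", "CB"), resid = "ALA", chain = "A",
#'   resno = 1, x = c(0, 1.4, 2.0, 2.2, 1.9), y = c(0, 0.4, 1.6, 2.8, -0.9),
#'   z = 0
#' )
#' map_structure(ala)$sites$site_class
#' @export
map_structure <- function(structure, mapping = default_mapping_table()) {
  atoms <- .atom_table(structure)
  m <- .build_mapping(atoms, mapping)
  xyz <- m$W %*% as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  structure(list(sites = m$sites, xyz = xyz), class = "cg_model")
}

#' Map an atomic trajectory onto a CG trajectory
#'
#' Applies the frame-local mapping of [map_structure()] to every frame.
#'
#' @inheritParams map_structure
#' @param xyz Frame coordinates: a numeric matrix with one row per frame and
#'   3 * n_atoms columns (bio3d `xyz` convention, e.g. from
#'   [bio3d::read.dcd()]), or `NULL` to use the coordinates stored in
#'   `structure` (multi-model PDBs give one frame per model).
#' @return An object of class `cg_trajectory`: list with `sites` and `coords`,
#'   an array of dimension (n_sites, 3, n_frames).
#' @export
map_trajectory <- function(structure, xyz = NULL,
                           mapping = default_mapping_table()) {
  atoms <- .atom_table(structure)
  if (is.null(xyz)) {
    if (inherits(structure, "pdb") && !is.null(structure$xyz)) {
      xyz <- matrix(structure$xyz, ncol = 3L * nrow(atoms), byrow = FALSE)
      if (is.matrix(structure$xyz)) xyz <- unclass(structure$xyz)
    } else {
      xyz <- matrix(c(t(as.matrix(atoms[, c("x", "y", "z")]))), nrow = 1L)
    }
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("frame/topology mismatch: xyz has ", ncol(xyz), " columns, expected ",
         3L * nrow(atoms))
  }
  m <- .build_mapping(atoms, mapping)
  n_frames <- nrow(xyz)
  n_sites <- nrow(m$sites)
  coords <- array(NA_real_, dim = c(n_sites, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[, , f] <- m$W %*% fr
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates after mapping")
  structure(list(sites = m$sites, coords = coords), class = "cg_trajectory")
}

#' Number of frames in a CG trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  dim(traj$coords)[3L]
}

#' Split a CG trajectory into consecutive analysis windows
#'
#' Windows are non-overlapping and equal-sized; a trailing partial window is
#' dropped so window statistics stay homogeneous.
#'
#' @param traj A `cg_trajectory`.
#' @param window_frames Frames per window (>= 2).
#' @return List of `cg_trajectory` windows.
#' @export
split_windows <- function(traj, window_frames) {
  stopifnot(inherits(traj, "cg_trajectory"), .is_count(window_frames),
            window_frames >= 2L)
  nf <- n_frames(traj)
  n_win <- nf %/% window_frames
  if (n_win < 1L) {
    stop("trajectory has ", nf, " frames, shorter than one window of ",
         window_frames)
  }
  lapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * window_frames + 1L):(w * window_frames)
    structure(list(sites = traj$sites,
                   coords = traj$coords[, , idx, drop = FALSE]),
              class = "cg_trajectory")
  })
}

#' Per-pair distance-fluctuation targets from a trajectory window
#'
#' For each requested site pair, the spring rest length `l0` is the mean
#' inter-site distance over frames and `var` the population variance of that
#' distance — the quantity fluctuation matching reproduces.
#'
#' @param window A `cg_trajectory` with >= 2 frames.
#' @param pairs Two-column matrix (or data.frame) of site index pairs; rows
#'   are unordered pairs i != j.
#' @return Object of class `fluctuation_targets`: data.frame with columns
#'   `i`, `j`, `l0` (Angstrom), `var` (Angstrom^2).
#' @export
compute_fluctuation_targets <- function(window, pairs) {
  stopifnot(inherits(window, "cg_trajectory"))
  if (n_frames(window) < 2L) stop("need at least 2 frames")
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "integer"
  ii <- pmin(pairs[, 1L], pairs[, 2L])
  jj <- pmax(pairs[, 1L], pairs[, 2L])
  if (any(ii == jj)) stop("pairs must have i != j")
  if (anyDuplicated(.pair_key(ii, jj)) > 0L) stop("duplicate pairs")
  co <- window$coords
  l0 <- numeric(length(ii))
  v <- numeric(length(ii))
  for (p in seq_along(ii)) {
    d <- sqrt(colSums((co[ii[p], , ] - co[jj[p], , ])^2))
    if (any(d == 0)) {
      stop(sprintf("zero inter-site distance for pair (%d, %d)", ii[p], jj[p]))
    }
    l0[p] <- mean(d)
    v[p] <- mean((d - l0[p])^2)
  }
  structure(
    data.frame(i = ii, j = jj, l0 = l0, var = v),
    class = c("fluctuation_targets", "data.frame")
  )
}

#' Write a CG trajectory as a multi-model PDB plus a site table
#'
#' @param traj A `cg_trajectory` or `cg_model`.
#' @param pdb_file Output PDB path (one MODEL per frame).
#' @param site_file Output TSV path for the site table (default: `pdb_file`
#'   with a `.sites.tsv` suffix).
#' @return Invisibly, the two file paths.
#' @export
write_cg_trajectory <- function(traj, pdb_file,
                                site_file = sub("\\.pdb$", "", pdb_file)) {
  if (inherits(traj, "cg_model")) {
    traj <- structure(
      list(sites = traj$sites,
           coords = array(traj$xyz, dim = c(nrow(traj$xyz), 3L, 1L))),
      class = "cg_trajectory"
    )
  }
  stopifnot(inherits(traj, "cg_trajectory"))
  s <- traj$sites
  nf <- n_frames(traj)
  xyz <- t(apply(traj$coords, 3L, function(fr) c(t(fr))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1L)
  elety <- ifelse(s$site_class == "backbone", s$source, "SC")
  bio3d::write.pdb(file = pdb_file, xyz = xyz, resno = s$resno,
                   resid = s$resid, chain = s$chain, elety = elety)
  site_path <- paste0(site_file, ".sites.tsv")
  utils::write.table(s, site_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pdb = pdb_file, sites = site_path))
}

#' @export
print.cg_model <- function(x, ...) {
  cat("CG model:", nrow(x$sites), "sites,",
      length(unique(x$sites$residue)), "residues\n")
  invisible(x)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("CG trajectory:", nrow(x$sites), "sites,", n_frames(x), "frames\n")
  invisible(x)
}
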