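# Residue rigidity scores. Each residue I gets a characteristic mode I' per
# rigidity graph: the prominent mode where it carries the most weight, if that
# weight is significant (nu_I^2 >= nu_c^2), otherwise the non-prominent mode
# where it is heaviest. The score kappa_I = <r_I'> * lambda_I' weights the
# mode's mechanical strength by its averaged content. BB/BS/SS scores combine
# into backbone (kappa^B) and side-chain (kappa^S) scores, counting the BS
# score only on the side (backbone or side chain) through which the residue
# actually couples in its BS characteristic mode.

#' Characteristic mode of a residue
#'
#' @param I Residue index.
#' @param spectrum A `spectral_result` of the mean graph.
#' @param prominent Integer indices of prominent modes (may be empty).
#' @param nu_c2 Significance threshold on squared eigenvector weight
#'   (default 0.1).
#' @return The mode index I'. Prefers the prominent mode with the residue's
#'   highest squared weight when that weight reaches `nu_c2`; otherwise the
#'   heaviest non-prominent mode. Argmax ties break towards the smaller mode
#'   index.
#' @export
characteristic_mode <- function(I, spectrum, prominent, nu_c2 = 0.1) {
  w <- spectrum$vectors[I, ]^2
  prominent <- as.integer(prominent)
  if (length(prominent) > 0L) {
    pi_mode <- prominent[which.max(w[prominent])]
    if (w[pi_mode] >= nu_c2) return(pi_mode)
  }
  rest <- setdiff(seq_along(w), prominent)
  if (length(rest) == 0L) {
    stop("residue ", I, " is below nu_c2 in every prominent mode and no ",
         "non-prominent modes remain")
  }
  rest[which.max(w[rest])]
}

#' Residue rigidity score kappa
#'
#' @param mode Characteristic mode index I'.
#' @param lambda Mode strengths.
#' @param content_mean Averaged mean-mode contents.
#' @return `content_mean[mode] * lambda[mode]` (>= 0).
#' @export
residue_score <- function(mode, lambda, content_mean) {
  content_mean[mode] * lambda[mode]
}

# Which side of residue I carries its BS coupling in a given mode: restrict to
# non-skeleton BS springs incident to I among the mode's hotspot residue
# pairs; when no such spring exists, fall back to all BS springs incident to
# I. Returns c(backbone = , sidechain = ) strengths.
.bs_mode_strength <- function(model, I, hotspots) {
  sp <- model$springs
  keep <- sp$category == "nonskeleton" & sp$group == "BS"
  ri <- model$sites$residue[sp$i]
  rj <- model$sites$residue[sp$j]
  inc <- keep & (ri == I | rj == I) & ri != rj
  restr <- inc & (I %in% hotspots) &
    ifelse(ri == I, rj %in% hotspots, ri %in% hotspots)
  sel <- if (any(restr)) restr else inc
  bb <- 0
  sc <- 0
  for (s in which(sel)) {
    site <- if (ri[s] == I) sp$i[s] else sp$j[s]
    if (model$sites$site_class[site] == "backbone") {
      bb <- bb + sp$k[s]
    } else {
      sc <- sc + sp$k[s]
    }
  }
  c(backbone = bb, sidechain = sc)
}

#' Combine per-graph scores into backbone and side-chain scores
#'
#' `kappa^B = max(kappa^BB, kappa^BS)` where the BS score competes only if the
#' residue contributes through its backbone in its BS characteristic mode;
#' `kappa^S = max(kappa^SS, kappa^BS)` with the analogous side-chain
#' condition. Glycine has no side-chain site: its `kappa^SS` is undefined and
#' `kappa^S` is reported as a configured minimal placeholder.
#'
#' @param kappa_bb,kappa_bs,kappa_ss Numeric vectors of per-residue scores
#'   (`kappa_ss` may contain NA for glycine).
#' @param bs_backbone,bs_sidechain Logical vectors: does the residue couple
#'   through its backbone / side chain in its BS characteristic mode?
#' @param glycine Logical vector flagging residues without a side-chain site.
#' @param gly_placeholder Minimal side-chain score assigned to glycine
#'   (default 0).
#' @return Data.frame with `kappa_b` and `kappa_s`.
#' @export
combine_scores <- function(kappa_bb, kappa_bs, kappa_ss, bs_backbone,
                           bs_sidechain, glycine,
                           gly_placeholder = 0) {
  kappa_b <- pmax(kappa_bb, ifelse(bs_backbone, kappa_bs, -Inf))
  kappa_s <- pmax(ifelse(is.na(kappa_ss), -Inf, kappa_ss),
                  ifelse(bs_sidechain, kappa_bs, -Inf))
  kappa_s[glycine] <- gly_placeholder
  kappa_s[!is.finite(kappa_s)] <- 0
  kappa_b[!is.finite(kappa_b)] <- 0
  data.frame(kappa_b = kappa_b, kappa_s = kappa_s)
}

#' Full residue rigidity score table
#'
#' Runs the scoring pipeline over the BB, BS and SS mean-mode statistics of a
#' window series: characteristic modes, per-graph scores, hotspot flags, and
#' the combined backbone/side-chain scores.
#'
#' @param model The `bsenm` the window graphs derive from (supplies the site
#'   table and the BS contribution split).
#' @param stats_by_group Named list with elements `BB`, `BS`, `SS`, each a
#'   `mean_mode_stats` (from [mean_mode_content()]).
#' @param content_quantile Named numeric vector of content quantiles per
#'   group; default `c(BB = 0.75, BS = 0.75, SS = 0.68)`.
#' @param nu_c2 Hotspot / significance threshold (default 0.1).
#' @param gly_placeholder Side-chain score placeholder for glycine.
#' @return Object of class `residue_score_table`: data.frame with per-residue
#'   characteristic modes and scores per group, `kappa_b`, `kappa_s`,
#'   `hotspot`, `glycine`. The prominent-mode sets are attached as attribute
#'   `"prominent"`.
#' @export
residue_score_table <- function(model, stats_by_group,
                                content_quantile = c(BB = 0.75, BS = 0.75,
                                                     SS = 0.68),
                                nu_c2 = 0.1, gly_placeholder = 0) {
  stopifnot(inherits(model, "bsenm"),
            all(c("BB", "BS", "SS") %in% names(stats_by_group)))
  n <- max(model$sites$residue)
  has_sc <- tapply(model$sites$site_class == "sidechain",
                   model$sites$residue, any)
  glycine <- !as.logical(has_sc[as.character(seq_len(n))])
  glycine[is.na(glycine)] <- TRUE

  res <- data.frame(residue = seq_len(n))
  prominent <- list()
  hotspot <- rep(FALSE, n)
  kappa <- list()
  mode_of <- list()
  for (grp in c("BB", "BS", "SS")) {
    st <- stats_by_group[[grp]]
    pm <- select_prominent_modes(st$spectrum$values, st$content_mean,
                                 content_quantile[[grp]])
    prominent[[grp]] <- pm
    for (m in pm$modes) {
      hotspot[hotspot_residues(st$spectrum$vectors[, m], nu_c2)] <- TRUE
    }
    modes <- vapply(seq_len(n), characteristic_mode, integer(1L),
                    spectrum = st$spectrum, prominent = pm$modes,
                    nu_c2 = nu_c2)
    kap <- vapply(modes, residue_score, numeric(1L),
                  lambda = st$spectrum$values,
                  content_mean = st$content_mean)
    mode_of[[grp]] <- modes
    kappa[[grp]] <- kap
  }
  kappa$SS[glycine] <- NA_real_

  # BS participation side, judged in each residue's BS characteristic mode
  bs_st <- stats_by_group$BS
  bs_backbone <- logical(n)
  bs_sidechain <- logical(n)
  for (I in seq_len(n)) {
    hs <- hotspot_residues(bs_st$spectrum$vectors[, mode_of$BS[I]], nu_c2)
    str <- .bs_mode_strength(model, I, hs)
    tot <- sum(str)
    if (tot > 0) {
      bs_backbone[I] <- str[["backbone"]] >= 0.5 * tot
      bs_sidechain[I] <- str[["sidechain"]] >= 0.5 * tot
    }
  }

  comb <- combine_scores(kappa$BB, kappa$BS, kappa$SS, bs_backbone,
                         bs_sidechain, glycine, gly_placeholder)
  out <- cbind(
    res,
    mode_bb = mode_of$BB, mode_bs = mode_of$BS, mode_ss = mode_of$SS,
    kappa_bb = kappa$BB, kappa_bs = kappa$BS, kappa_ss = kappa$SS,
    comb,
    bs_backbone = bs_backbone, bs_sidechain = bs_sidechain,
    hotspot = hotspot, glycine = glycine
  )
  attr(out, "prominent") <- prominent
  class(out) <- c("residue_score_table", "data.frame")
  out
}

#' Classify a residue's structural location
#'
#' Given per-residue secondary-structure labels (H = helix, E = strand,
#' L = loop), a residue is `interior` when it sits inside an element more than
#' `margin` residues from both ends, `periphery` when within `margin` residues
#' of an element boundary (on either side of it), and `loop` otherwise.
#'
#' @param ss Character vector of labels, one per residue (`H`/`E`/`L`), or a
#'   path to a plain-text file holding them (one per line, or one string).
#' @param margin Periphery width in residues (default 3).
#' @return Character vector: `interior`, `periphery`, `loop`.
#' @export
classify_location <- function(ss, margin = 3L) {
  if (length(ss) == 1L && file.exists(ss)) {
    txt <- readLines(ss, warn = FALSE)
    txt <- paste(txt, collapse = "")
    ss <- strsplit(gsub("[[:space:]]", "", txt), "")[[1L]]
  }
  ss <- toupper(ss)
  if (!all(ss %in% c("H", "E", "L", "C", "-"))) {
    stop("secondary-structure labels must be H, E or L")
  }
  ss[ss %in% c("C", "-")] <- "L"
  n <- length(ss)
  in_elem <- ss %in% c("H", "E")
  r <- rle(in_elem)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep("loop", n)
  bounds <- integer(0)
  for (e in which(r$values)) {
    s <- starts[e]; t <- ends[e]
    bounds <- c(bounds, s, t)
    for (p in s:t) {
      out[p] <- if (min(p - s, t - p) > margin) "interior" else "periphery"
    }
  }
  if (length(bounds) > 0L) {
    for (p in which(!in_elem)) {
      if (min(abs(p - bounds)) <= margin) out[p] <- "periphery"
    }
  }
  out
}

#' Write a residue score table as TSV
#'
#' @param table A `residue_score_table`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_score_table <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
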