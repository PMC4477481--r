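# Shrake-Rupley solvent-accessible surface area on a deterministic
# golden-spiral sphere lattice, relative solvent accessibility against the
# Miller extended Gly-X-Gly tripeptide scale, and buried/exposed
# classification of sites of interest (phosphorylation / ubiquitination
# residues of a signal-receiving domain).

#' Van der Waals radii and probe settings for SASA
#'
#' @param radii named numeric vector of per-element van der Waals radii,
#'   Angstrom.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, a water
#'   molecule).
#' @param n_sphere_points number of test points per atom on the deterministic
#'   golden-spiral lattice (default 960; at least 60).
#' @return object of class `radii_set`.
#' @export
radii_set <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                H = 1.20),
                      probe_radius = 1.4, n_sphere_points = 960L) {
  stopifnot(all(radii > 0), probe_radius >= 0, n_sphere_points >= 60L)
  structure(list(radii = radii, probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "radii_set")
}

# deterministic golden-spiral unit-sphere lattice (m x 3)
sphere_lattice <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Maximal accessible surface areas (Gly-X-Gly scale)
#'
#' Per-residue maximal SASA in the extended Gly-X-Gly tripeptide conformation
#' (Miller et al. 1987 tripeptide scale; Ser 122 and Lys 211 A^2), used to
#' normalise residue SASA into relative solvent accessibility.
#'
#' @return named numeric vector, Angstrom^2, all 20 standard residues.
#' @export
max_asa_gxg <- function() {
  c(ALA = 113, ARG = 241, ASN = 158, ASP = 151, CYS = 140,
    GLN = 189, GLU = 183, GLY = 85, HIS = 194, ILE = 182,
    LEU = 180, LYS = 211, MET = 204, PHE = 218, PRO = 143,
    SER = 122, THR = 146, TRP = 259, TYR = 229, VAL = 160)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per atom, the accessible fraction of a deterministic golden-spiral point
#' lattice on the expanded sphere of radius `r_vdw + probe`: a test point is
#' accessible when it lies outside every neighbouring atom's expanded
#' sphere. `SASA = 4 pi (r + probe)^2 x accessible fraction`.
#'
#' @inheritParams place_amide_hydrogens
#' @param radii a [radii_set()].
#' @return numeric vector of per-atom SASA, Angstrom^2.
#' @export
shrake_rupley <- function(frame, topology, radii = radii_set()) {
  frame <- as.matrix(frame)
  if (!all(is.finite(frame))) stop("coordinates must be finite")
  elem <- topology$atoms$element
  unknown <- setdiff(unique(elem), names(radii$radii))
  if (length(unknown) > 0) {
    bad <- which(elem %in% unknown)[1L]
    stop("no van der Waals radius for element '", elem[bad], "' (atom ",
         topology$atoms$name[bad], " ", topology$atoms$res_name[bad],
         topology$atoms$res_seq[bad], ")")
  }
  r_exp <- radii$radii[elem] + radii$probe_radius
  n <- nrow(frame)
  pts <- sphere_lattice(radii$n_sphere_points)
  m <- nrow(pts)
  out <- numeric(n)
  # neighbour lists from the pairwise distance matrix
  D <- cross_dist(frame, frame)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < r_exp[i] + r_exp & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * r_exp[i]^2
      next
    }
    P <- pts * r_exp[i]
    P <- sweep(P, 2L, frame[i, ], "+")
    # a point survives if outside every neighbour's expanded sphere
    acc <- rep(TRUE, m)
    d2 <- cross_dist2(P, frame[nb, , drop = FALSE])
    acc <- rowSums(d2 < matrix(r_exp[nb]^2, m, length(nb), byrow = TRUE)) == 0
    out[i] <- 4 * pi * r_exp[i]^2 * sum(acc) / m
  }
  out
}

#' Per-residue SASA
#'
#' Sums [shrake_rupley()] atom areas over each residue.
#' @inheritParams shrake_rupley
#' @return data frame `chain_id`, `res_seq`, `res_name`, `sasa` (A^2).
#' @export
residue_sasa <- function(frame, topology, radii = radii_set()) {
  atom_sasa <- shrake_rupley(frame, topology, radii)
  res <- residue_table(topology)
  ridx <- atom_residue_index(topology)
  res$sasa <- as.numeric(rowsum(atom_sasa, ridx)[as.character(res$res_index), 1L])
  res[, c("chain_id", "res_seq", "res_name", "sasa")]
}

#' Relative solvent accessibility
#'
#' `RSA = 100 x SASA / maxASA(residue)`, with maxASA from the extended
#' Gly-X-Gly tripeptide scale.
#'
#' @param residue_sasa residue SASA, Angstrom^2.
#' @param res_name 3-letter residue code(s).
#' @param scale named maxASA vector (default [max_asa_gxg()]).
#' @return RSA in percent.
#' @examples
#' rsa(61.2, "SER")  # 50.2 percent
#' @export
rsa <- function(residue_sasa, res_name, scale = max_asa_gxg()) {
  res_name <- toupper(res_name)
  if (!all(res_name %in% names(scale)))
    stop("no maxASA value for residue ",
         paste(setdiff(res_name, names(scale)), collapse = ", "))
  unname(100 * residue_sasa / scale[res_name])
}

#' Classify a residue as buried or exposed
#'
#' Buried iff RSA is strictly below the threshold (default 20 percent), so an
#' RSA of exactly 20 is exposed.
#'
#' @param rsa_percent RSA value(s), percent.
#' @param threshold burial threshold, percent (default 20).
#' @return character vector, `"buried"` or `"exposed"`.
#' @export
classify_burial <- function(rsa_percent, threshold = 20) {
  stopifnot(all(rsa_percent >= 0))
  ifelse(rsa_percent < threshold, "buried", "exposed")
}

#' Solvent-accessibility report for sites of interest
#'
#' Computes per-frame residue SASA for selected sites over an ensemble,
#' pools frames across replicas, and reports mean +/- sd SASA and RSA with a
#' buried/exposed label from the RSA mean.
#'
#' @inheritParams average_structure
#' @param sites data frame with columns `chain_id` and `res_seq`, or an
#'   integer vector of residue numbers (matched on any chain).
#' @param scale maxASA scale (default [max_asa_gxg()]).
#' @param radii a [radii_set()].
#' @param threshold burial threshold, percent.
#' @param state optional label (e.g. `"bound"`, `"free"`) attached to rows.
#' @return data frame with `chain_id`, `res_seq`, `res_name`, `sasa_mean`,
#'   `sasa_sd`, `rsa_mean`, `rsa_sd`, `label` and `state`; per-replica means
#'   in `attr(x, "per_replica")`.
#' @export
site_accessibility_report <- function(ensemble, sites, scale = max_asa_gxg(),
                                      radii = radii_set(), window = NULL,
                                      threshold = 20, state = NA_character_) {
  topo <- ensemble$topology
  res <- residue_table(topo)
  if (is.numeric(sites) && is.null(dim(sites))) {
    rows <- which(res$res_seq %in% sites)
    missing_sites <- setdiff(sites, res$res_seq)
  } else {
    key <- paste(res$chain_id, res$res_seq)
    want <- paste(sites$chain_id, sites$res_seq)
    rows <- match(want, key)
    missing_sites <- want[is.na(rows)]
    rows <- rows[!is.na(rows)]
  }
  if (length(missing_sites) > 0)
    stop("site(s) not in topology: ", paste(missing_sites, collapse = ", "))
  if (length(rows) == 0) stop("no sites selected")

  nrep <- length(ensemble$replicas)
  vals <- vector("list", nrep)   # frames x sites matrices
  for (r in seq_len(nrep)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    m <- matrix(0, length(idx), length(rows))
    for (k in seq_along(idx)) {
      rs <- residue_sasa(get_frame(ensemble, r, idx[k]), topo, radii)
      m[k, ] <- rs$sasa[rows]
    }
    vals[[r]] <- m
  }
  pooled <- do.call(rbind, vals)
  sasa_mean <- colMeans(pooled)
  sasa_sd <- apply(pooled, 2L, stats::sd)
  if (nrow(pooled) == 1L) sasa_sd <- rep(0, ncol(pooled))
  maxasa <- scale[res$res_name[rows]]
  if (anyNA(maxasa))
    stop("no maxASA value for residue ",
         paste(res$res_name[rows][is.na(maxasa)], collapse = ", "))
  rsa_all <- sweep(pooled, 2L, maxasa / 100, "/")
  rsa_mean <- colMeans(rsa_all)
  rsa_sd <- apply(rsa_all, 2L, stats::sd)
  if (nrow(pooled) == 1L) rsa_sd <- rep(0, ncol(pooled))
  out <- data.frame(chain_id = res$chain_id[rows], res_seq = res$res_seq[rows],
                    res_name = res$res_name[rows],
                    sasa_mean = sasa_mean, sasa_sd = sasa_sd,
                    rsa_mean = rsa_mean, rsa_sd = rsa_sd,
                    label = classify_burial(rsa_mean, threshold),
                    state = state, stringsAsFactors = FALSE)
  attr(out, "per_replica") <- lapply(vals, colMeans)
  attr(out, "settings") <- list(probe_radius = radii$probe_radius,
                                n_sphere_points = radii$n_sphere_points,
                                threshold = threshold)
  out
}

#' Write an accessibility report as TSV
#' @param x report(s) from [site_accessibility_report()]; several states can
#'   be passed as a list and are row-bound.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accessibility_tsv <- function(x, path) {
  settings <- attr(if (is.data.frame(x)) x else x[[1L]], "settings")
  df <- if (is.data.frame(x)) x else do.call(rbind, x)
  write_report_tsv(df, path, meta = settings)
}
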