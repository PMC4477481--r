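# Synthetic conformational ensembles with fully controlled ground truth:
# ideal-geometry peptides from internal coordinates (NeRF), helix/coil
# switching ensembles with designed per-segment helix occupancy and Gaussian
# positional noise, and two-chain complexes whose interface contacts follow
# exact deterministic occupancy schedules. These emulate the statistical
# structure of replica MD trajectories (stable helices at designed segments,
# variable conformations elsewhere, interface bonds present in a controlled
# fraction of frames) without any force-field dynamics.

# standard backbone geometry (Engh-Huber-like ideal values), Angstrom / deg
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, omega = 180)

PHI_PSI_PRESETS <- list(alpha = c(phi = -57, psi = -47),
                        extended = c(phi = -120, psi = 120))

# side-chain internal coordinates; "full" chains built bond by bond,
# everything else a single pseudo-atom at the CB position
SIDE_CHAINS <- list(
  SER = list(c("OG", "O", "CB", 1.417, 110.8, -60)),
  LYS = list(c("CG", "C", "CB", 1.520, 114.1, -60),
             c("CD", "C", "CG", 1.520, 111.3, 180),
             c("CE", "C", "CD", 1.520, 111.3, 180),
             c("NZ", "N", "CE", 1.489, 111.9, 180)),
  GLU = list(c("CG", "C", "CB", 1.520, 114.1, -60),
             c("CD", "C", "CG", 1.516, 112.6, 180),
             c("OE1", "O", "CD", 1.250, 118.4, 0),
             c("OE2", "O", "CD", 1.250, 118.4, 180)),
  ASP = list(c("CG", "C", "CB", 1.516, 112.6, -60),
             c("OD1", "O", "CG", 1.250, 118.4, 0),
             c("OD2", "O", "CG", 1.250, 118.4, 180)))

# atom layout for a sequence: one row per atom, with the internal-coordinate
# recipe resolved at build time
peptide_layout <- function(sequence, chain_id = "A", start_res = 1L) {
  letters1 <- split_states(toupper(sequence))
  if (!all(letters1 %in% names(AA3)))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[!letters1 %in% names(AA3)]), collapse = ", "))
  res3 <- AA3[letters1]
  rows <- list()
  for (i in seq_along(res3)) {
    rn <- res3[[i]]
    atoms <- c("N", "CA", "C", "O")
    elems <- c("N", "C", "C", "O")
    if (rn != "PRO" && i > 1L) { atoms <- c(atoms, "H"); elems <- c(elems, "H") }
    if (rn != "GLY") { atoms <- c(atoms, "CB"); elems <- c(elems, "C") }
    if (rn %in% names(SIDE_CHAINS)) {
      sc <- SIDE_CHAINS[[rn]]
      atoms <- c(atoms, vapply(sc, `[`, "", 1L))
      elems <- c(elems, vapply(sc, `[`, "", 2L))
    }
    rows[[i]] <- data.frame(name = atoms, element = elems, res_name = rn,
                            res_seq = start_res + i - 1L, chain_id = chain_id,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms[, c("serial", "name", "element", "res_name", "res_seq", "chain_id")]
}

# row lookup per residue: list of named integer vectors, computed once per
# layout and reused across frames
layout_index <- function(atoms) {
  ridx <- cumsum(!duplicated(atoms$res_seq))
  lapply(split(seq_len(nrow(atoms)), ridx), function(rows) {
    stats::setNames(rows, atoms$name[rows])
  })
}

# coordinates for a layout given per-residue phi/psi (degrees)
build_coords <- function(atoms, phi, psi, omega = BB_GEOM$omega,
                         index = layout_index(atoms)) {
  res_seqs <- unique(atoms$res_seq)
  nres <- length(res_seqs)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  g <- BB_GEOM
  xyz <- matrix(NA_real_, nrow(atoms), 3L)
  put <- function(i, name, p) {
    row <- index[[i]][[name]]
    if (!is.null(row)) xyz[row, ] <<- p
    p
  }
  res_names <- atoms$res_name[!duplicated(atoms$res_seq)]
  N_prev <- CA_prev <- C_prev <- O_prev <- NULL
  for (i in seq_len(nres)) {
    rn <- res_names[i]
    if (i == 1L) {
      N <- put(i, "N", c(0, 0, 0))
      CA <- put(i, "CA", c(g$n_ca, 0, 0))
      th <- deg2rad(180 - g$ang_n_ca_c)
      C <- put(i, "C", CA + g$ca_c * c(cos(th), sin(th), 0))
    } else {
      N <- put(i, "N", place_dihedral(N_prev, CA_prev, C_prev,
                                      g$c_n, g$ang_ca_c_n, psi[i - 1L]))
      CA <- put(i, "CA", place_dihedral(CA_prev, C_prev, N,
                                        g$n_ca, g$ang_c_n_ca, omega))
      C <- put(i, "C", place_dihedral(C_prev, N, CA,
                                      g$ca_c, g$ang_n_ca_c, phi[i]))
      if (rn != "PRO")
        put(i, "H", N + 1.01 * unit_vec(C_prev - O_prev))
    }
    O <- put(i, "O", place_dihedral(N, CA, C, g$c_o, g$ang_ca_c_o,
                                    psi[i] + 180))
    if (rn != "GLY") {
      CB <- put(i, "CB", place_dihedral(C, N, CA, 1.53, 110.5, 122.6))
      if (rn %in% names(SIDE_CHAINS)) {
        placed <- list(N = N, CA = CA, C = C, O = O, CB = CB)
        for (sc in SIDE_CHAINS[[rn]]) {
          nm <- sc[1L]
          # torsion frame: the three atoms preceding this one along the chain
          anchors <- switch(nm,
            OG = , CG = list(placed$N, placed$CA, placed$CB),
            CD = list(placed$CA, placed$CB, placed$CG),
            CE = list(placed$CB, placed$CG, placed$CD),
            NZ = list(placed$CG, placed$CD, placed$CE),
            OE1 = , OE2 = list(placed$CB, placed$CG, placed$CD),
            OD1 = , OD2 = list(placed$CA, placed$CB, placed$CG))
          p <- place_dihedral(anchors[[1L]], anchors[[2L]], anchors[[3L]],
                              as.numeric(sc[4L]), as.numeric(sc[5L]),
                              as.numeric(sc[6L]))
          placed[[nm]] <- put(i, nm, p)
        }
      }
    }
    N_prev <- N; CA_prev <- CA; C_prev <- C; O_prev <- O
  }
  xyz
}

#' Build an ideal-geometry peptide
#'
#' Constructs a peptide by sequential internal-coordinate (NeRF) placement
#' with standard bond lengths/angles (N-CA 1.458, CA-C 1.525, C-N 1.329 A,
#' omega 180 deg). Backbone atoms N/CA/C/O plus the amide hydrogen; side
#' chains are a single pseudo-atom at the CB position, except Ser (OG), Lys
#' (full side chain to NZ), and Glu/Asp (carboxylate oxygens), which carry
#' real chemistry so that accessibility and contact analyses are meaningful.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees, recycled over residues, or
#'   a preset name via `preset`. Defaults: alpha-helix (-57, -47).
#' @param preset `"alpha"` (phi -57, psi -47) or `"extended"`
#'   (phi -120, psi +120); overridden by explicit `phi`/`psi`.
#' @param chain_id,start_res chain identifier and first residue number.
#' @return a [pep_structure()].
#' @examples
#' helix <- build_peptide(strrep("A", 12))
#' table(assign_sse(helix$xyz, helix))
#' @export
build_peptide <- function(sequence, phi = NULL, psi = NULL, preset = "alpha",
                          chain_id = "A", start_res = 1L) {
  pp <- PHI_PSI_PRESETS[[match.arg(preset, names(PHI_PSI_PRESETS))]]
  if (is.null(phi)) phi <- pp[["phi"]]
  if (is.null(psi)) psi <- pp[["psi"]]
  atoms <- peptide_layout(sequence, chain_id, start_res)
  xyz <- build_coords(atoms, phi, psi)
  pep_structure(atoms, xyz)
}

draw_coil <- function(n, phi_range = c(-150, -60), psi_range = c(60, 170)) {
  list(phi = stats::runif(n, phi_range[1L], phi_range[2L]),
       psi = stats::runif(n, psi_range[1L], psi_range[2L]))
}

#' Helix/coil switching ensemble with designed occupancies
#'
#' Generates replica trajectories of a peptide in which each designated
#' segment independently adopts the ideal alpha-helix conformation with its
#' target probability in every frame, and the coil conformation (phi/psi
#' drawn uniformly from a broad coil basin, default phi in [-150, -60], psi
#' in [60, 170], chosen to avoid accidental helix assignment) otherwise.
#' Residues outside all segments are always coil. Iid Gaussian noise of sd
#' `noise_sigma` is added to every coordinate; for such noise the expected
#' RMSF of an otherwise rigid atom is `noise_sigma * sqrt(3)`.
#'
#' @param sequence one-letter amino-acid string.
#' @param segments data frame with columns `start`, `end` (1-based inclusive
#'   residue positions) and `occupancy` in `[0, 1]`; segments must not
#'   overlap.
#' @param n_replicas number of independent replicas (default 3, the usual
#'   replicate-simulation design).
#' @param n_frames frames per replica.
#' @param noise_sigma per-axis Gaussian noise, Angstrom (default 0.1).
#' @param seed mandatory RNG seed; replicas get independent substreams.
#' @param coil_phi,coil_psi coil-basin ranges, degrees.
#' @return a [replica_ensemble()] with attribute `manifest`: list holding the
#'   spec and the realised per-segment, per-replica helix-frame counts.
#' @export
helix_coil_ensemble <- function(sequence, segments, n_replicas = 3L,
                                n_frames = 100L, noise_sigma = 0.1, seed,
                                coil_phi = c(-150, -60),
                                coil_psi = c(60, 170)) {
  if (missing(seed)) stop("seed is mandatory (reproducibility)")
  stopifnot(n_frames >= 1L, n_replicas >= 1L, noise_sigma >= 0)
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "occupancy") %in% names(segments)))
  nres <- nchar(sequence)
  if (nrow(segments) > 0) {
    stopifnot(all(segments$start >= 1L), all(segments$end <= nres),
              all(segments$start <= segments$end),
              all(segments$occupancy >= 0), all(segments$occupancy <= 1))
    covered <- unlist(Map(seq.int, segments$start, segments$end))
    if (anyDuplicated(covered)) stop("segments overlap")
  }
  atoms <- peptide_layout(sequence)
  topo <- pep_structure(atoms, build_coords(atoms, -57, -47))
  alpha <- PHI_PSI_PRESETS$alpha

  set.seed(seed %% .Machine$integer.max)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  on_counts <- matrix(0L, nrow(segments), n_replicas)
  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    set.seed(rep_seeds[r])
    arr <- array(0, dim = c(nrow(atoms), 3L, n_frames))
    for (t in seq_len(n_frames)) {
      coil <- draw_coil(nres, coil_phi, coil_psi)
      phi <- coil$phi
      psi <- coil$psi
      if (nrow(segments) > 0) {
        on <- stats::runif(nrow(segments)) < segments$occupancy
        on_counts[, r] <- on_counts[, r] + as.integer(on)
        for (s in which(on)) {
          span <- seq.int(segments$start[s], segments$end[s])
          phi[span] <- alpha[["phi"]]
          psi[span] <- alpha[["psi"]]
        }
      }
      xyz <- build_coords(atoms, phi, psi)
      if (noise_sigma > 0)
        xyz <- xyz + stats::rnorm(length(xyz), 0, noise_sigma)
      arr[, , t] <- xyz
    }
    replicas[[r]] <- arr
  }
  ens <- replica_ensemble(topo, replicas)
  attr(ens, "manifest") <- list(
    sequence = sequence, segments = segments, n_replicas = n_replicas,
    n_frames = n_frames, noise_sigma = noise_sigma, seed = seed,
    helix_on_counts = on_counts)
  ens
}

# exact deterministic on/off schedule: `count` on-frames out of n, evenly
# interleaved (Bresenham), so occupancies are exact rationals
interleave_schedule <- function(fraction, n) {
  count <- round(fraction * n)
  t <- seq_len(n)
  floor(t * count / n) - floor((t - 1) * count / n) == 1
}

#' Two-chain complex ensemble with scheduled interface contacts
#'
#' Builds two extended peptide chains (A and B) and a set of designed
#' interface contacts, each switched on/off by an exact deterministic
#' interleaved schedule (not sampled), so persistence-filter outcomes are
#' analytic. In "on" frames the donor group sits at bonding geometry
#' (donor-acceptor 2.9 A, H-D-A angle 5 deg for hydrogen bonds; N-O 2.9 A for
#' salt bridges); in "off" frames it is displaced to 6 A along the same
#' direction. Hydrogen-bond contacts pair a chain-B backbone amide with a
#' chain-A backbone carbonyl; salt bridges pair a chain-B lysine NZ with a
#' chain-A glutamate carboxylate.
#'
#' @param occupancy numeric matrix, `n_contacts x n_replicas`: target
#'   occupancy of each contact in each replica, in `[0, 1]`.
#' @param n_frames frames per replica.
#' @param kind character vector over `"hbond"` / `"saltbridge"`, recycled to
#'   `n_contacts`.
#' @param d_on,d_off donor-acceptor distances in on/off frames, Angstrom.
#' @return a [replica_ensemble()] (chains A and B) with attribute `manifest`
#'   listing the designed contacts (`chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `kind`) and the exact per-replica on-frame counts.
#' @export
contact_complex_ensemble <- function(occupancy, n_frames, kind = "hbond",
                                     d_on = 2.9, d_off = 6.0) {
  occupancy <- as.matrix(occupancy)
  stopifnot(all(occupancy >= 0), all(occupancy <= 1), n_frames >= 1L)
  n_contacts <- nrow(occupancy)
  n_replicas <- ncol(occupancy)
  kind <- rep_len(kind, n_contacts)
  stopifnot(all(kind %in% c("hbond", "saltbridge")))

  # contact sites 4 residues apart: same backbone parity in the extended
  # conformation, so every donor amide points the same way
  pos <- 2L + 4L * (seq_len(n_contacts) - 1L)
  len <- max(pos) + 2L
  seq_a <- rep("A", len); seq_b <- rep("A", len)
  seq_a[pos[kind == "saltbridge"]] <- "E"
  seq_b[pos[kind == "saltbridge"]] <- "K"
  # fully extended (phi = psi = 180): exact two-residue backbone periodicity,
  # so all same-parity contact sites share one amide orientation
  pep_a <- build_peptide(paste(seq_a, collapse = ""), phi = 180, psi = 180,
                         chain_id = "A")
  pep_b <- build_peptide(paste(seq_b, collapse = ""), phi = 180, psi = 180,
                         chain_id = "B")
  find_in <- function(pep, res, name) {
    which(pep$atoms$res_seq == res & pep$atoms$name == name)
  }
  # carbonyl "outward" direction at the first acceptor site of chain A
  w <- unit_vec(pep_a$xyz[find_in(pep_a, pos[1L], "O"), ] -
                pep_a$xyz[find_in(pep_a, pos[1L], "C"), ])
  # rotate chain B so its contact-site amide N-H vectors point along -w:
  # donors then approach each carbonyl head-on from above it
  u <- unit_vec(pep_b$xyz[find_in(pep_b, pos[1L], "H"), ] -
                pep_b$xyz[find_in(pep_b, pos[1L], "N"), ])
  axis <- cross3(u, -w)
  R <- if (vec_norm(axis) < 1e-9) diag(3) else
    rotation_about_axis(axis, rad2deg(acos(max(-1, min(1, sum(u * -w))))))
  xyz_b <- pep_b$xyz %*% t(R)
  xyz_b <- sweep(xyz_b, 2L, c(0, 25, 0) - colMeans(xyz_b), "+")
  atoms <- rbind(pep_a$atoms, pep_b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  base <- rbind(pep_a$xyz, xyz_b)
  topo <- pep_structure(atoms, base)
  a <- topo$atoms

  find <- function(chain, res, name) {
    which(a$chain_id == chain & a$res_seq == res & a$name == name)
  }
  # per contact: atoms of the mobile chain-B residue, its anchor atom, the
  # fixed chain-A target atom, and the approach direction v (anchor is
  # placed at target - d * v)
  perp <- unit_vec(cross3(w, if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  moves <- vector("list", n_contacts)
  for (k in seq_len(n_contacts)) {
    b_rows <- which(a$chain_id == "B" & a$res_seq == pos[k])
    if (kind[k] == "hbond") {
      target <- base[find("A", pos[k], "O"), ]
      anchor <- find("B", pos[k], "N")
      # approach tilted 5 degrees off the carbonyl axis
      v <- -as.numeric(rotation_about_axis(perp, 5) %*% w)
    } else {
      cd <- base[find("A", pos[k], "CD"), ]
      target <- base[find("A", pos[k], "OE1"), ]
      anchor <- find("B", pos[k], "NZ")
      v <- -unit_vec(target - cd)  # outward continuation of the carboxylate
    }
    moves[[k]] <- list(rows = b_rows, anchor = anchor, target = target, v = v)
  }
  place_contact <- function(xyz, k, d) {
    mv <- moves[[k]]
    shift <- (mv$target - d * mv$v) - base[mv$anchor, ]
    xyz[mv$rows, ] <- base[mv$rows, , drop = FALSE] +
      matrix(shift, length(mv$rows), 3L, byrow = TRUE)
    xyz
  }

  replicas <- vector("list", n_replicas)
  on_counts <- matrix(0L, n_contacts, n_replicas)
  for (r in seq_len(n_replicas)) {
    sched <- vapply(seq_len(n_contacts), function(k) {
      interleave_schedule(occupancy[k, r], n_frames)
    }, logical(n_frames))
    sched <- matrix(sched, nrow = n_frames)
    on_counts[, r] <- colSums(sched)
    arr <- array(0, dim = c(nrow(a), 3L, n_frames))
    for (t in seq_len(n_frames)) {
      xyz <- base
      for (k in seq_len(n_contacts)) {
        xyz <- place_contact(xyz, k, if (sched[t, k]) d_on else d_off)
      }
      arr[, , t] <- xyz
    }
    replicas[[r]] <- arr
  }
  ens <- replica_ensemble(topo, replicas)
  attr(ens, "manifest") <- list(
    contacts = data.frame(chain_a = "A", res_a = pos, chain_b = "B",
                          res_b = pos, kind = kind,
                          stringsAsFactors = FALSE),
    occupancy = occupancy, n_frames = n_frames, on_counts = on_counts,
    d_on = d_on, d_off = d_off)
  ens
}

#' Write a synthetic ensemble to multi-model PDB files plus a JSON manifest
#'
#' @param ensemble a [replica_ensemble()] from [helix_coil_ensemble()] or
#'   [contact_complex_ensemble()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; replica `k` becomes
#'   `<prefix>_rep<k>.pdb`.
#' @return character vector of PDB paths written, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, dir, prefix = "traj") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ensemble$replicas))
  for (r in seq_along(ensemble$replicas)) {
    arr <- ensemble$replicas[[r]]
    frames <- lapply(seq_len(dim(arr)[3L]), function(t) arr[, , t])
    paths[r] <- file.path(dir, sprintf("%s_rep%d.pdb", prefix, r))
    write_multimodel_pdb(ensemble$topology, frames, paths[r])
  }
  manifest <- attr(ensemble, "manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest,
                         file.path(dir, paste0(prefix, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
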