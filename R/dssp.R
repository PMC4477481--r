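# Kabsch-Sander (DSSP-style) secondary-structure assignment: backbone
# hydrogen-bond energies from the classic electrostatic model, n-turn /
# bridge pattern rules, 8-state assignment, per-frame timelines and
# helix-formation probabilities across replicas.
#
# States: H alpha-helix, G 3_10-helix, I pi-helix, E extended strand,
# B isolated beta-bridge, T turn, S bend, C coil/loop.

SS8_STATES <- c("H", "G", "I", "E", "B", "T", "S", "C")

HBOND_Q <- 0.084 * 332       # kcal/mol * Angstrom (Kabsch-Sander constant)
HBOND_CUTOFF <- -0.5         # bond iff E < -0.5 kcal/mol
HBOND_EMIN <- -9.9           # clamp
CHAIN_BREAK_DIST <- 2.5      # Angstrom, C(i)-N(i+1) continuity limit
BEND_KAPPA <- 70             # degrees

# Per-residue backbone bookkeeping for one frame: atom indices of N/CA/C/O,
# amide-H coordinates, and contiguous-segment ids (chain change or C-N
# distance > 2.5 A starts a new segment). Following the original
# Kabsch-Sander convention, the hydrogen used for bond energies is always
# the idealised amide H = N + 1.01 * unit(C_prev - O_prev), regardless of
# any explicit hydrogen in the file (use_explicit_h recovers file H atoms
# where present, for callers that want them).
backbone_frame <- function(frame, topology, use_explicit_h = FALSE) {
  frame <- as.matrix(frame)
  res <- residue_table(topology)
  n <- nrow(res)
  a <- topology$atoms
  ridx <- atom_residue_index(topology)
  find_atom <- function(nm) {
    idx <- rep(NA_integer_, n)
    hit <- which(a$name == nm)
    idx[ridx[hit]] <- hit
    idx
  }
  iN <- find_atom("N"); iCA <- find_atom("CA"); iC <- find_atom("C")
  iO <- find_atom("O"); iH <- find_atom("H")
  coords <- function(idx) {
    m <- matrix(NA_real_, n, 3L)
    ok <- !is.na(idx)
    m[ok, ] <- frame[idx[ok], , drop = FALSE]
    m
  }
  N <- coords(iN); CA <- coords(iCA); C <- coords(iC); O <- coords(iO)
  H <- coords(iH)

  seg <- integer(n)
  seg[1L] <- 1L
  if (n > 1L) for (i in 2:n) {
    brk <- res$chain_id[i] != res$chain_id[i - 1L] ||
      is.na(iC[i - 1L]) || is.na(iN[i]) ||
      sqrt(sum((C[i - 1L, ] - N[i, ])^2)) > CHAIN_BREAK_DIST
    seg[i] <- seg[i - 1L] + as.integer(brk)
  }

  has_h <- use_explicit_h & !is.na(iH)
  if (!use_explicit_h) H[] <- NA_real_
  placeable <- !has_h & res$res_name != "PRO" & !is.na(iN)
  for (i in which(placeable)) {
    if (i == 1L || seg[i] != seg[i - 1L] ||
        is.na(iC[i - 1L]) || is.na(iO[i - 1L])) next
    u <- C[i - 1L, ] - O[i - 1L, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) next
    H[i, ] <- N[i, ] + 1.01 * u / nu
    has_h[i] <- TRUE
  }
  list(res = res, N = N, CA = CA, C = C, O = O, H = H,
       has_h = has_h, seg = seg,
       donor_ok = has_h & !is.na(iN),
       acceptor_ok = !is.na(iC) & !is.na(iO))
}

#' Place backbone amide hydrogens
#'
#' Adds a backbone amide hydrogen to every residue that lacks one, using the
#' standard DSSP construction `H = N + 1.01 A x unit(C_prev - O_prev)`
#' (anti to the preceding carbonyl). Prolines, segment-initial residues and
#' residues whose predecessor lacks C/O get no hydrogen; existing backbone
#' `H` atoms are left untouched.
#'
#' @param frame `n_atoms x 3` coordinate matrix conforming to `topology`.
#' @param topology a [pep_structure()].
#' @return list with updated `topology` and `frame` (new `H` atoms are
#'   inserted directly after each residue's `N`).
#' @export
place_amide_hydrogens <- function(frame, topology) {
  bb <- backbone_frame(frame, topology, use_explicit_h = TRUE)
  a <- topology$atoms
  ridx <- atom_residue_index(topology)
  existing_h <- a$name == "H"
  out_atoms <- list(); out_xyz <- list()
  frame <- as.matrix(frame)
  need <- bb$has_h & !(bb$res$res_index %in% ridx[existing_h])
  for (i in seq_len(nrow(a))) {
    out_atoms[[length(out_atoms) + 1L]] <- a[i, , drop = FALSE]
    out_xyz[[length(out_xyz) + 1L]] <- frame[i, , drop = FALSE]
    ri <- ridx[i]
    if (a$name[i] == "N" && need[ri]) {
      h <- a[i, , drop = FALSE]
      h$name <- "H"; h$element <- "H"; h$serial <- NA_integer_
      out_atoms[[length(out_atoms) + 1L]] <- h
      out_xyz[[length(out_xyz) + 1L]] <- matrix(bb$H[ri, ], 1L, 3L)
    }
  }
  atoms <- do.call(rbind, out_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  xyz <- do.call(rbind, out_xyz)
  list(topology = pep_structure(atoms, xyz), frame = xyz)
}

hbond_energy_from_dists <- function(d_on, d_ch, d_oh, d_cn) {
  e <- HBOND_Q * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
  e[d_on < 0.5 | d_ch < 0.5 | d_oh < 0.5 | d_cn < 0.5] <- HBOND_EMIN
  e[e < HBOND_EMIN] <- HBOND_EMIN
  e
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic H-bond energy between the amide group (N-H) of a donor
#' residue and the carbonyl group (C=O) of an acceptor residue:
#' `E = 0.084 x 332 x (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol, clamped
#' at -9.9; a hydrogen bond is declared when `E < -0.5` kcal/mol.
#'
#' @inheritParams place_amide_hydrogens
#' @param donor,acceptor residue indices (1-based rows of the residue table,
#'   i.e. file order across chains).
#' @return energy in kcal/mol, or `NA` if the donor lacks N/H (proline,
#'   chain start) or the acceptor lacks C/O.
#' @export
backbone_hbond_energy <- function(frame, topology, donor, acceptor) {
  bb <- backbone_frame(frame, topology)
  n <- nrow(bb$res)
  stopifnot(donor >= 1L, donor <= n, acceptor >= 1L, acceptor <= n,
            donor != acceptor)
  if (!bb$donor_ok[donor] || !bb$acceptor_ok[acceptor]) return(NA_real_)
  d <- function(p, q) sqrt(sum((p - q)^2))
  hbond_energy_from_dists(
    d(bb$O[acceptor, ], bb$N[donor, ]),
    d(bb$C[acceptor, ], bb$H[donor, ]),
    d(bb$O[acceptor, ], bb$H[donor, ]),
    d(bb$C[acceptor, ], bb$N[donor, ]))
}

# Full donor x acceptor hydrogen-bond boolean matrix for one frame.
hbond_matrix <- function(bb) {
  n <- nrow(bb$res)
  ok <- outer(bb$donor_ok, bb$acceptor_ok, "&")
  # sequence-separation eligibility: |i-j| >= 2 within a chain; inter-chain
  # pairs are always eligible
  rows <- seq_len(n)
  sep_ok <- abs(outer(rows, rows, "-")) >= 2L |
    outer(bb$res$chain_id, bb$res$chain_id, "!=")
  ok <- ok & sep_ok
  E <- matrix(0, n, n)
  if (any(ok)) {
    d_on <- cross_dist(bb$N, bb$O)
    d_cn <- cross_dist(bb$N, bb$C)
    d_ch <- cross_dist(bb$H, bb$C)
    d_oh <- cross_dist(bb$H, bb$O)
    E <- hbond_energy_from_dists(d_on, d_ch, d_oh, d_cn)
    E[!ok] <- 0
    E[is.na(E)] <- 0
  }
  E < HBOND_CUTOFF
}

# M[i + di, j + dj] aligned onto (i, j); out-of-range entries FALSE.
shift_mat <- function(M, di, dj) {
  n <- nrow(M)
  S <- matrix(FALSE, n, n)
  ri <- seq_len(n) + di
  cj <- seq_len(n) + dj
  ok_i <- ri >= 1L & ri <= n
  ok_j <- cj >= 1L & cj <= n
  S[ok_i, ok_j] <- M[ri[ok_i], cj[ok_j]]
  S
}

# core assignment given backbone bookkeeping for one frame
assign_sse_bb <- function(bb) {
  n <- nrow(bb$res)
  st <- rep("C", n)
  if (n < 3L) return(st)
  HB <- hbond_matrix(bb)   # HB[donor, acceptor]
  seg <- bb$seg

  same_seg_span <- function(i, k) {
    j <- i + k
    ok <- j >= 1L & j <= n
    out <- rep(FALSE, n)
    out[ok] <- seg[i[ok]] == seg[j[ok]]
    out
  }
  idx <- seq_len(n)

  # n-turns: turn_n[i] <- HBond from NH(i+n) to CO(i), within one segment
  turn <- list()
  for (k in 3:5) {
    t_k <- rep(FALSE, n)
    i <- idx[idx + k <= n]
    hit <- HB[cbind(i + k, i)] & seg[i] == seg[i + k]
    t_k[i] <- hit
    turn[[as.character(k)]] <- t_k
  }

  mark_helix <- function(t_k, k) {
    isx <- rep(FALSE, n)
    # two consecutive n-turns at i-1 and i start a minimal helix i..i+k-1
    i <- idx[idx >= 2L & idx + k - 1L <= n]
    starts <- i[t_k[i - 1L] & t_k[i]]
    for (s in starts) isx[s:(s + k - 1L)] <- TRUE
    isx
  }
  isH <- mark_helix(turn[["4"]], 4L)
  isG <- mark_helix(turn[["3"]], 3L)
  isI <- mark_helix(turn[["5"]], 5L)

  # bridges (Kabsch-Sander patterns); HBt[i, j] = HB[j, i]
  HBt <- t(HB)
  valid3 <- rep(FALSE, n)
  inner <- idx[idx >= 2L & idx <= n - 1L]
  valid3[inner] <- seg[inner - 1L] == seg[inner + 1L]
  P <- (shift_mat(HBt, -1L, 0L) & shift_mat(HB, 1L, 0L)) |
       (shift_mat(HB, 0L, -1L) & shift_mat(HBt, 0L, 1L))
  A <- (HBt & HB) |
       (shift_mat(HBt, -1L, 1L) & shift_mat(HB, 1L, -1L))
  sep3 <- abs(outer(idx, idx, "-")) > 2L |
    outer(bb$res$chain_id, bb$res$chain_id, "!=")
  mask <- outer(valid3, valid3, "&") & sep3
  P <- P & mask
  A <- A & mask

  # bridges -> ladders -> beta-bulge-linked sheets
  bp <- which(P & upper.tri(P), arr.ind = TRUE)
  ba <- which(A & upper.tri(A), arr.ind = TRUE)
  bridges <- rbind(
    if (nrow(bp) > 0) data.frame(i = bp[, 1L], j = bp[, 2L], type = "P"),
    if (nrow(ba) > 0) data.frame(i = ba[, 1L], j = ba[, 2L], type = "A"))
  isE <- rep(FALSE, n)
  isB <- rep(FALSE, n)
  if (!is.null(bridges) && nrow(bridges) > 0) {
    bridges <- bridges[order(bridges$type, bridges$i, bridges$j), , drop = FALSE]
    # chain bridges into ladders: parallel continues at (i+1, j+1),
    # antiparallel at (i+1, j-1)
    lad_of <- new.env(parent = emptyenv())
    lad_id <- integer(nrow(bridges))
    n_lad <- 0L
    for (b in seq_len(nrow(bridges))) {
      ty <- bridges$type[b]; i <- bridges$i[b]; j <- bridges$j[b]
      pred <- paste(ty, i - 1L, if (ty == "P") j - 1L else j + 1L)
      pid <- lad_of[[pred]]
      if (is.null(pid)) {
        n_lad <- n_lad + 1L
        pid <- n_lad
      }
      lad_id[b] <- pid
      lad_of[[paste(ty, i, j)]] <- pid
    }
    lad <- do.call(rbind, lapply(seq_len(n_lad), function(id) {
      sel <- lad_id == id
      data.frame(type = bridges$type[sel][1L],
                 i_min = min(bridges$i[sel]), i_max = max(bridges$i[sel]),
                 j_min = min(bridges$j[sel]), j_max = max(bridges$j[sel]),
                 n_bridges = sum(sel), stringsAsFactors = FALSE)
    }))
    # beta-bulge: two ladders of the same type separated by at most one
    # residue on one strand and at most four on the other
    parent <- seq_len(n_lad)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (n_lad > 1L) {
      ord <- order(lad$i_min)
      for (u in seq_len(n_lad - 1L)) for (v in (u + 1L):n_lad) {
        L1 <- lad[ord[u], ]; L2 <- lad[ord[v], ]
        if (L1$type != L2$type) next
        gi <- L2$i_min - L1$i_max - 1L
        gj <- if (L1$type == "P") L2$j_min - L1$j_max - 1L
              else L1$j_min - L2$j_max - 1L
        if (gi >= 0L && gj >= 0L &&
            ((gi <= 1L && gj <= 4L) || (gi <= 4L && gj <= 1L))) {
          ru <- find(ord[u]); rv <- find(ord[v])
          if (ru != rv) parent[rv] <- ru
        }
      }
    }
    groups <- split(seq_len(n_lad), vapply(seq_len(n_lad), find, integer(1)))
    for (g in groups) {
      total <- sum(lad$n_bridges[g])
      if (total >= 2L) {
        g <- g[order(lad$i_min[g])]
        for (k in seq_along(g)) {
          L <- lad[g[k], ]
          isE[L$i_min:L$i_max] <- TRUE
          isE[L$j_min:L$j_max] <- TRUE
          if (k > 1L) {  # bulge residues between linked ladders
            Lp <- lad[g[k - 1L], ]
            if (L$i_min - Lp$i_max > 1L)
              isE[(Lp$i_max + 1L):(L$i_min - 1L)] <- TRUE
            jgap <- if (L$type == "P") {
              if (L$j_min - Lp$j_max > 1L) (Lp$j_max + 1L):(L$j_min - 1L)
            } else {
              if (Lp$j_min - L$j_max > 1L) (L$j_max + 1L):(Lp$j_min - 1L)
            }
            if (!is.null(jgap)) isE[jgap] <- TRUE
          }
        }
      } else {
        L <- lad[g, ]
        isB[c(L$i_min, L$j_min)] <- TRUE
      }
    }
    isB <- isB & !isE
  }

  # T: interior of any n-turn
  isT <- rep(FALSE, n)
  for (k in 3:5) {
    t_k <- turn[[as.character(k)]]
    for (off in 1:(k - 1L)) {
      i <- idx[idx + off <= n]
      isT[i + off] <- isT[i + off] | t_k[i]
    }
  }

  # S: bend, kappa angle of CA(i-2), CA(i), CA(i+2) > 70 degrees
  isS <- rep(FALSE, n)
  i <- idx[idx >= 3L & idx <= n - 2L]
  i <- i[seg[i - 2L] == seg[i + 2L]]
  for (k in i) {
    u <- bb$CA[k, ] - bb$CA[k - 2L, ]
    v <- bb$CA[k + 2L, ] - bb$CA[k, ]
    if (anyNA(u) || anyNA(v)) next
    kappa <- bond_angle(bb$CA[k, ] + v, bb$CA[k, ], bb$CA[k, ] + u)
    isS[k] <- kappa > BEND_KAPPA
  }

  # overlap priority: H > B/E > G > I > T > S (assigned low to high)
  st[isS] <- "S"
  st[isT] <- "T"
  st[isI] <- "I"
  st[isG] <- "G"
  st[isB] <- "B"
  st[isE] <- "E"
  st[isH] <- "H"
  st
}

#' Assign 8-state secondary structure to one frame
#'
#' Kabsch-Sander pattern rules on backbone hydrogen bonds: n-turns (n = 3, 4,
#' 5) from `CO(i) -> NH(i+n)` bonds, minimal helices (G/H/I) from two
#' consecutive n-turns, parallel/antiparallel bridges (B) and ladders (E),
#' turn (T) for residues inside an n-turn, bend (S) where the
#' CA(i-2)/CA(i)/CA(i+2) kappa angle exceeds 70 degrees, and C otherwise.
#' Overlaps resolve with priority H > B/E > G > I > T > S. Chain breaks
#' (`C(i)-N(i+1)` > 2.5 A) terminate all pattern windows.
#'
#' @inheritParams place_amide_hydrogens
#' @return character vector, one of H/G/I/E/B/T/S/C per residue
#'   (residue-table order).
#' @export
assign_sse <- function(frame, topology) {
  assign_sse_bb(backbone_frame(frame, topology))
}

#' Reduce 8-state assignments to 3 states
#'
#' H/G/I become helix (H), E/B become strand (E), everything else coil (C).
#' @param state8 character vector of 8-state codes.
#' @return character vector over H/E/C.
#' @export
state8_to_state3 <- function(state8) {
  out <- rep("C", length(state8))
  out[state8 %in% c("H", "G", "I")] <- "H"
  out[state8 %in% c("E", "B")] <- "E"
  out
}

#' Secondary-structure timeline of an ensemble
#'
#' Runs [assign_sse()] on every frame of every replica.
#'
#' @inheritParams average_structure
#' @return list with one `n_residues x n_frames` character matrix per replica
#'   (rownames `chain:res_seq`), class `sse_timeline`.
#' @export
sse_timeline <- function(ensemble, window = NULL) {
  topo <- ensemble$topology
  res <- residue_table(topo)
  labs <- paste0(res$chain_id, ":", res$res_seq)
  out <- lapply(seq_along(ensemble$replicas), function(r) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    m <- vapply(idx, function(t) {
      assign_sse(get_frame(ensemble, r, t), topo)
    }, character(nrow(res)))
    m <- matrix(m, nrow = nrow(res), dimnames = list(labs, idx))
    m
  })
  class(out) <- "sse_timeline"
  out
}

#' Per-residue helix-formation probability
#'
#' Occupancy of helical states per residue: the fraction of frames whose
#' 8-state assignment falls in `helix_states`, per replica and pooled
#' (frame-weighted mean across replicas). The default counts alpha-helix (H)
#' only, treating 3_10- and pi-helical interludes as distinct states.
#'
#' @inheritParams average_structure
#' @param helix_states 8-state codes counted as helical (default `"H"`).
#' @param timeline optionally, a precomputed [sse_timeline()] to reuse.
#' @return object of class `helix_profile`: data frame with `chain_id`,
#'   `res_seq`, `res_name`, `occ_rep<k>` per replica, and `occ_pooled`.
#' @export
helix_probability <- function(ensemble, window = NULL, helix_states = "H",
                              timeline = NULL) {
  if (is.null(timeline)) timeline <- sse_timeline(ensemble, window)
  res <- residue_table(ensemble$topology)
  occ <- vapply(timeline, function(m) rowMeans(matrix(m %in% helix_states,
                                                      nrow = nrow(m))),
                numeric(nrow(res)))
  occ <- matrix(occ, nrow = nrow(res))
  nf <- vapply(timeline, ncol, integer(1))
  pooled <- as.numeric(occ %*% nf / sum(nf))
  out <- data.frame(chain_id = res$chain_id, res_seq = res$res_seq,
                    res_name = res$res_name, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(occ))) out[[paste0("occ_rep", r)]] <- occ[, r]
  out$occ_pooled <- pooled
  class(out) <- c("helix_profile", "data.frame")
  out
}

#' Write an SSE timeline as TSV (one file per replica)
#' @param timeline an [sse_timeline()].
#' @param dir output directory.
#' @param prefix file-name prefix (`<prefix>_rep<k>.tsv`).
#' @return character vector of the files written, invisibly.
#' @export
write_timeline_tsv <- function(timeline, dir, prefix = "sse_timeline") {
  paths <- character(length(timeline))
  for (r in seq_along(timeline)) {
    m <- timeline[[r]]
    df <- data.frame(residue = rownames(m), as.data.frame(m, optional = TRUE),
                     check.names = FALSE)
    names(df) <- c("residue", paste0("frame_", colnames(m)))
    paths[r] <- file.path(dir, sprintf("%s_rep%d.tsv", prefix, r))
    write_report_tsv(df, paths[r],
                     meta = list(replica = r, states = paste(SS8_STATES, collapse = "")))
  }
  invisible(paths)
}

#' Write a helix-probability profile as TSV
#' @param x a `helix_profile` from [helix_probability()].
#' @param path output path.
#' @param helix_states the states that were counted (echoed in the header).
#' @return `path`, invisibly.
#' @export
write_helix_profile_tsv <- function(x, path, helix_states = "H") {
  write_report_tsv(as.data.frame(x), path,
                   meta = list(helix_states = paste(helix_states, collapse = "")))
}
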