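# Superposition-based geometry statistics. All fits are least-squares rigid
# body superpositions (Kabsch, proper rotation); fluctuations are measured
# around the converged iterative average structure, matching the usual
# "RMSF around the average structure" convention of trajectory analysis.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over a selection,
#' via SVD of the cross-covariance with the determinant correction that
#' guarantees a proper rotation (no reflection).
#'
#' @param mobile,reference `n_atoms x 3` coordinate frames (Angstrom) with
#'   identical atom order.
#' @param selection integer atom indices to fit on (default: all atoms).
#'   At least 3 non-collinear atoms.
#' @return list with `rotation` (3 x 3, `det = +1`), `translation`
#'   (length-3), and `rmsd` (post-fit, Angstrom, over the selection). The
#'   transform maps mobile coordinates as `x %*% t(rotation) + translation`
#'   (see [apply_transform()]).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q))
    stop("selection cardinality differs between mobile and reference")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  # collinearity check: a line leaves the rotation about it undetermined
  sv_p <- svd(Pc, nu = 0L, nv = 0L)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1))
    stop("degenerate (collinear) selection geometry")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' Apply a rigid-body transform to a coordinate frame
#'
#' @param frame `n x 3` matrix.
#' @param transform list with `rotation` and `translation`, as returned by
#'   [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(frame, transform) {
  frame <- as.matrix(frame)
  out <- sweep(frame %*% t(transform$rotation), 2L, -transform$translation)
  dimnames(out) <- dimnames(frame)
  out
}

pooled_frames <- function(ensemble, window = NULL) {
  out <- list()
  for (r in seq_along(ensemble$replicas)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    for (t in idx) out[[length(out) + 1L]] <- get_frame(ensemble, r, t)
  }
  out
}

#' Iterative average structure of an ensemble
#'
#' Frames (pooled across replicas) are superposed onto the current mean over
#' the selection, the mean is recomputed, and the cycle repeats until the
#' mean moves less than `tol` (RMS over all atoms) or `max_iter` iterations.
#'
#' @param ensemble a [replica_ensemble()].
#' @param selection a [selection_spec()] used for fitting (default backbone
#'   C-alpha).
#' @param window optional inclusive frame range `c(first, last)` applied to
#'   every replica.
#' @param tol convergence threshold, Angstrom RMS (default 1e-6).
#' @param max_iter iteration cap (default 100; non-convergence warns and
#'   returns the last iterate).
#' @return `n_atoms x 3` matrix: the converged average coordinates.
#' @export
average_structure <- function(ensemble, selection = selection_spec("CA"),
                              window = NULL, tol = 1e-6, max_iter = 100L) {
  frames <- pooled_frames(ensemble, window)
  if (length(frames) < 1L) stop("ensemble has no frames in window")
  sel <- select_atoms(ensemble$topology, selection)
  avg <- frames[[1L]]
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, nrow(avg), 3L)
    for (f in frames) {
      tf <- kabsch_superpose(f, avg, sel)
      acc <- acc + apply_transform(f, tf)
    }
    new_avg <- acc / length(frames)
    shift <- sqrt(mean(rowSums((new_avg - avg)^2)))
    avg <- new_avg
    if (shift < tol) return(avg)
  }
  warning("average structure did not converge in ", max_iter, " iterations")
  avg
}

#' Per-residue root-mean-square fluctuations
#'
#' Each frame is superposed (over `selection`) onto the converged average
#' structure; RMSF of residue i is the root mean squared deviation of its
#' selected atoms from their average position, per replica, plus the mean
#' profile across replicas.
#'
#' @inheritParams average_structure
#' @param reference optional `n_atoms x 3` reference to fluctuate around;
#'   default: [average_structure()] of the windowed ensemble.
#' @param label window label stored with the profile (e.g. "first half").
#' @return object of class `flexibility_profile`: data frame with `chain_id`,
#'   `res_seq`, `res_name`, one `rmsf_rep<k>` column per replica and `rmsf_mean`
#'   (Angstrom); the window label is kept in `attr(x, "window")`.
#' @export
rmsf <- function(ensemble, selection = selection_spec("CA"), window = NULL,
                 reference = NULL, label = "full") {
  sel <- select_atoms(ensemble$topology, selection)
  if (is.null(reference))
    reference <- average_structure(ensemble, selection, window)
  res_idx <- atom_residue_index(ensemble$topology)[sel]
  res <- residue_table(ensemble$topology)
  nrep <- length(ensemble$replicas)
  prof <- matrix(NA_real_, length(unique(res_idx)), nrep)
  rows <- sort(unique(res_idx))
  for (r in seq_len(nrep)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    msf <- matrix(0, length(sel), 1L)
    for (t in idx) {
      f <- get_frame(ensemble, r, t)
      tf <- kabsch_superpose(f, reference, sel)
      dev <- apply_transform(f, tf)[sel, , drop = FALSE] -
        reference[sel, , drop = FALSE]
      msf <- msf + rowSums(dev^2)
    }
    msf <- msf / length(idx)
    # aggregate atoms to residues: RMSF over all selected atoms of a residue
    prof[, r] <- sqrt(vapply(rows, function(ri) mean(msf[res_idx == ri]),
                             numeric(1)))
  }
  out <- data.frame(chain_id = res$chain_id[rows], res_seq = res$res_seq[rows],
                    res_name = res$res_name[rows], stringsAsFactors = FALSE)
  for (r in seq_len(nrep)) out[[paste0("rmsf_rep", r)]] <- prof[, r]
  out$rmsf_mean <- rowMeans(prof)
  attr(out, "window") <- label
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Per-frame RMSD series
#'
#' RMSD of every frame from a reference after optimal superposition on the
#' selection, one series per replica. The default reference is each
#' replica's own first frame (displacement from the starting structure).
#'
#' @inheritParams average_structure
#' @param reference optional `n_atoms x 3` frame used for every replica.
#' @return data frame with columns `replica`, `frame`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference = NULL,
                        selection = selection_spec("CA"), window = NULL) {
  sel <- select_atoms(ensemble$topology, selection)
  out <- list()
  for (r in seq_along(ensemble$replicas)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    ref_r <- if (is.null(reference)) get_frame(ensemble, r, idx[1L]) else reference
    rmsds <- vapply(idx, function(t) {
      kabsch_superpose(get_frame(ensemble, r, t), ref_r, sel)$rmsd
    }, numeric(1))
    out[[r]] <- data.frame(replica = r, frame = idx, rmsd = rmsds)
  }
  do.call(rbind, out)
}

# block-minimum of a square atom-distance matrix over residue groups
block_min <- function(D, groups) {
  nres <- length(groups)
  stage1 <- matrix(0, nres, ncol(D))
  for (i in seq_len(nres)) {
    rows <- groups[[i]]
    stage1[i, ] <- if (length(rows) == 1L) D[rows, ]
    else do.call(pmin, lapply(rows, function(k) D[k, ]))
  }
  out <- matrix(0, nres, nres)
  for (j in seq_len(nres)) {
    cols <- groups[[j]]
    out[, j] <- if (length(cols) == 1L) stage1[, cols]
    else do.call(pmin, lapply(cols, function(k) stage1[, k]))
  }
  out
}

#' Time-averaged minimum inter-residue distance matrix
#'
#' Entry (i, j) is the mean over frames (pooled across replicas) of the
#' per-frame smallest heavy-atom distance between residues i and j; the
#' diagonal is zero. The time statistic (mean of per-frame minima) is stated
#' in the TSV header when written.
#'
#' @inheritParams average_structure
#' @param residue_range optional inclusive `c(first, last)` residue-number
#'   range (applied to `res_seq`).
#' @param chain_id optional single chain to restrict to.
#' @return symmetric numeric matrix with `res_seq` dimnames and attributes
#'   `residues` (the residue table used) and `statistic`.
#' @export
min_distance_matrix <- function(ensemble, residue_range = NULL,
                                chain_id = NULL, window = NULL) {
  topo <- ensemble$topology
  res <- residue_table(topo)
  keep <- rep(TRUE, nrow(res))
  if (!is.null(chain_id)) keep <- keep & res$chain_id %in% chain_id
  if (!is.null(residue_range))
    keep <- keep & res$res_seq >= residue_range[1L] &
      res$res_seq <= residue_range[2L]
  res <- res[keep, , drop = FALSE]
  if (nrow(res) < 1L) stop("no residues in range")
  heavy <- topo$atoms$element != "H"
  ridx <- atom_residue_index(topo)
  groups <- lapply(res$res_index, function(ri) which(ridx == ri & heavy))
  if (any(lengths(groups) == 0)) stop("a residue in range has no heavy atoms")
  atom_sel <- unlist(groups)
  # re-index groups into the subsetted coordinate block
  off <- c(0L, cumsum(lengths(groups)))
  groups_local <- lapply(seq_along(groups), function(i) {
    seq.int(off[i] + 1L, off[i + 1L])
  })
  acc <- matrix(0, nrow(res), nrow(res))
  count <- 0L
  for (r in seq_along(ensemble$replicas)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    for (t in idx) {
      xyz <- get_frame(ensemble, r, t)[atom_sel, , drop = FALSE]
      D <- cross_dist(xyz, xyz)
      acc <- acc + block_min(D, groups_local)
      count <- count + 1L
    }
  }
  M <- acc / count
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(res$res_seq, res$res_seq)
  attr(M, "residues") <- res
  attr(M, "statistic") <- "mean over frames of per-frame minimum heavy-atom distance"
  M
}

#' Write a flexibility profile as TSV
#' @param x a `flexibility_profile` from [rmsf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsf_tsv <- function(x, path) {
  write_report_tsv(as.data.frame(x), path,
                   meta = list(window = attr(x, "window"), units = "Angstrom"))
}
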