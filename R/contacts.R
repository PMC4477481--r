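# Geometric interface contacts: hydrogen bonds (donor-acceptor distance +
# H-D-A angle) and salt bridges (acidic O to basic N distance), per-frame
# detection, per-replica occupancy, and the persistence filter that keeps
# contacts intact for more than a minimum fraction of frames in a minimum
# number of replicas.

# side-chain donor heavy atoms (attached H required for the angle criterion)
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1")

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
BASIC_ATOMS_HIS <- c(BASIC_ATOMS, list(HIS = c("ND1", "NE2")))

# order residue pairs canonically by (chain, res_seq) for deduplication
canonical_pairs <- function(df) {
  swap <- df$chain_a > df$chain_b |
    (df$chain_a == df$chain_b & df$res_a > df$res_b)
  if (any(swap)) {
    tmp <- df[swap, c("chain_a", "res_a", "resname_a")]
    df[swap, c("chain_a", "res_a", "resname_a")] <-
      df[swap, c("chain_b", "res_b", "resname_b")]
    df[swap, c("chain_b", "res_b", "resname_b")] <- tmp
  }
  unique(df)
}

pair_frame <- function(atoms, ai, aj) {
  data.frame(chain_a = atoms$chain_id[ai], res_a = atoms$res_seq[ai],
             resname_a = atoms$res_name[ai],
             chain_b = atoms$chain_id[aj], res_b = atoms$res_seq[aj],
             resname_b = atoms$res_name[aj], stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' Atom-level criterion: donor-acceptor distance `<= d_da_max` and, when the
#' donor hydrogen is available, H-D-A angle `<= angle_max`. Donors are
#' backbone amide nitrogens (hydrogen placed by the DSSP rule when absent;
#' prolines excluded) and the standard side-chain donor atoms (Ser OG, Thr
#' OG1, Tyr OH, Lys NZ, Arg NE/NH1/NH2, Asn ND2, Gln NE2, His ND1/NE2, Trp
#' NE1); side-chain donors with no explicit hydrogen fall back to the
#' distance-only criterion and the output is flagged accordingly. Acceptors
#' are all N/O atoms. Residue-level contacts are the union of their
#' atom-level bonds; intra-residue pairs and backbone-backbone pairs of
#' sequence neighbours (i, i+-1) are excluded.
#'
#' @inheritParams place_amide_hydrogens
#' @param d_da_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_max H-D-A angle cutoff, degrees (default 30).
#' @return data frame of residue pairs (`chain_a`, `res_a`, `resname_a`,
#'   `chain_b`, `res_b`, `resname_b`), canonically ordered; attribute
#'   `distance_only_donors` names side-chain donor atoms that had no
#'   hydrogen.
#' @export
detect_hbonds <- function(frame, topology, d_da_max = 3.5, angle_max = 30) {
  frame <- as.matrix(frame)
  a <- topology$atoms
  ridx <- atom_residue_index(topology)

  is_bb_n <- a$name == "N" & a$res_name != "PRO"
  is_sc_donor <- rep(FALSE, nrow(a))
  for (rn in names(SIDECHAIN_DONORS)) {
    is_sc_donor <- is_sc_donor |
      (a$res_name == rn & a$name %in% SIDECHAIN_DONORS[[rn]])
  }
  don <- which(is_bb_n | is_sc_donor)
  acc <- which(a$element %in% c("N", "O"))
  if (length(don) == 0 || length(acc) == 0) {
    out <- pair_frame(a, integer(0), integer(0))
    attr(out, "distance_only_donors") <- character(0)
    return(out)
  }

  # attached hydrogens: explicit H in the same residue within 1.25 A,
  # or the DSSP-placed amide H for backbone N
  bb <- backbone_frame(frame, topology)
  h_idx <- which(a$element == "H")
  don_h <- vector("list", length(don))
  flagged <- character(0)
  for (k in seq_along(don)) {
    d <- don[k]
    hs <- h_idx[ridx[h_idx] == ridx[d]]
    if (length(hs) > 0) {
      dd <- sqrt(rowSums((frame[hs, , drop = FALSE] -
                            matrix(frame[d, ], length(hs), 3L, byrow = TRUE))^2))
      hs <- hs[dd <= 1.25]
    }
    if (length(hs) > 0) {
      don_h[[k]] <- frame[hs, , drop = FALSE]
    } else if (a$name[d] == "N") {
      ri <- ridx[d]
      if (bb$has_h[ri]) don_h[[k]] <- matrix(bb$H[ri, ], 1L, 3L)
    } else {
      flagged <- c(flagged, sprintf("%s%d:%s", a$res_name[d], a$res_seq[d],
                                    a$name[d]))
    }
  }

  D <- cross_dist(frame[don, , drop = FALSE], frame[acc, , drop = FALSE])
  hits <- which(D <= d_da_max, arr.ind = TRUE)
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    d <- don[hits[r, 1L]]
    ac <- acc[hits[r, 2L]]
    if (ridx[d] == ridx[ac]) next
    # backbone-backbone sequence neighbours are the peptide bond itself
    bbd <- a$name[d] %in% c("N", "O")
    bba <- a$name[ac] %in% c("N", "O", "C")
    if (bbd && bba && a$chain_id[d] == a$chain_id[ac] &&
        abs(ridx[d] - ridx[ac]) <= 1L) next
    H <- don_h[[hits[r, 1L]]]
    if (!is.null(H)) {
      angs <- apply(H, 1L, function(h) bond_angle(h, frame[d, ], frame[ac, ]))
      if (min(angs) > angle_max) next
    }
    keep[r] <- TRUE
  }
  hits <- hits[keep, , drop = FALSE]
  out <- canonical_pairs(pair_frame(a, don[hits[, 1L]], acc[hits[, 2L]]))
  rownames(out) <- NULL
  attr(out, "distance_only_donors") <- unique(flagged)
  out
}

#' Detect salt bridges in one frame
#'
#' A residue pair forms a salt bridge when any acidic carboxylate oxygen
#' (Asp OD1/OD2, Glu OE1/OE2) lies within `d_max` of a basic nitrogen
#' (Lys NZ, Arg NE/NH1/NH2; His ND1/NE2 optionally).
#'
#' @inheritParams detect_hbonds
#' @param d_max O-N distance cutoff, Angstrom (default 4.0, the
#'   Barlow-Thornton convention).
#' @param include_his include histidine in the basic set (default FALSE).
#' @return data frame of residue pairs as in [detect_hbonds()].
#' @export
detect_salt_bridges <- function(frame, topology, d_max = 4.0,
                                include_his = FALSE) {
  frame <- as.matrix(frame)
  a <- topology$atoms
  basic_tab <- if (include_his) BASIC_ATOMS_HIS else BASIC_ATOMS
  pick <- function(tab) {
    sel <- rep(FALSE, nrow(a))
    for (rn in names(tab)) sel <- sel | (a$res_name == rn & a$name %in% tab[[rn]])
    which(sel)
  }
  ai <- pick(ACIDIC_ATOMS)
  bi <- pick(basic_tab)
  if (length(ai) == 0 || length(bi) == 0)
    return(pair_frame(a, integer(0), integer(0)))
  D <- cross_dist(frame[ai, , drop = FALSE], frame[bi, , drop = FALSE])
  hits <- which(D <= d_max, arr.ind = TRUE)
  out <- canonical_pairs(pair_frame(a, ai[hits[, 1L]], bi[hits[, 2L]]))
  rownames(out) <- NULL
  out
}

#' Per-replica contact occupancy across an ensemble
#'
#' Runs a per-frame detector over every replica and reports, for each residue
#' pair ever observed, the fraction of frames in which the contact is present
#' in each replica. Pairs never observed are not materialised.
#'
#' @inheritParams average_structure
#' @param kind `"hbond"` or `"saltbridge"` (selects the detector), or a
#'   function `f(frame, topology, ...)` returning a pair data frame.
#' @param ... passed to the detector (e.g. `d_da_max`, `d_max`).
#' @return object of class `contact_records`: data frame with `kind`, the six
#'   pair-identity columns, and `occ_rep<k>` occupancies in `[0, 1]`;
#'   attribute `n_frames` holds the per-replica frame counts used.
#' @export
contact_occupancy <- function(ensemble, kind = c("hbond", "saltbridge"),
                              window = NULL, ...) {
  if (is.function(kind)) {
    detector <- kind
    kind_label <- "custom"
  } else {
    kind <- match.arg(kind)
    detector <- switch(kind, hbond = detect_hbonds,
                       saltbridge = detect_salt_bridges)
    kind_label <- kind
  }
  topo <- ensemble$topology
  nrep <- length(ensemble$replicas)
  counts <- list()
  nf <- integer(nrep)
  for (r in seq_len(nrep)) {
    idx <- resolve_window(window, n_frames(ensemble)[r])
    nf[r] <- length(idx)
    keys <- character(0)
    for (t in idx) {
      pairs <- detector(get_frame(ensemble, r, t), topo, ...)
      if (nrow(pairs) > 0)
        keys <- c(keys, do.call(paste, c(pairs, sep = "\t")))
    }
    counts[[r]] <- table(keys)
  }
  all_keys <- sort(unique(unlist(lapply(counts, names))))
  if (length(all_keys) == 0) {
    out <- data.frame(kind = character(0), chain_a = character(0),
                      res_a = integer(0), resname_a = character(0),
                      chain_b = character(0), res_b = integer(0),
                      resname_b = character(0), stringsAsFactors = FALSE)
    for (r in seq_len(nrep)) out[[paste0("occ_rep", r)]] <- numeric(0)
  } else {
    parts <- do.call(rbind, strsplit(all_keys, "\t", fixed = TRUE))
    out <- data.frame(kind = kind_label,
                      chain_a = parts[, 1L], res_a = as.integer(parts[, 2L]),
                      resname_a = parts[, 3L],
                      chain_b = parts[, 4L], res_b = as.integer(parts[, 5L]),
                      resname_b = parts[, 6L], stringsAsFactors = FALSE)
    for (r in seq_len(nrep)) {
      cnt <- counts[[r]][all_keys]
      cnt[is.na(cnt)] <- 0
      out[[paste0("occ_rep", r)]] <- as.numeric(cnt) / nf[r]
    }
    ord <- order(out$chain_a, out$res_a, out$chain_b, out$res_b)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_frames") <- nf
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Persistence criteria for interface contacts
#'
#' The filter keeps a contact when its occupancy exceeds `min_occupancy`
#' (strictly: "longer than" the fraction, so exactly 10 percent fails the
#' default) in at least `min_replicas` replicas.
#'
#' @param min_occupancy occupancy threshold in (0, 1], default 0.10.
#' @param min_replicas minimum number of passing replicas, default 2.
#' @return object of class `persistence_criteria`.
#' @export
persistence_criteria <- function(min_occupancy = 0.10, min_replicas = 2L) {
  stopifnot(min_occupancy > 0, min_occupancy <= 1, min_replicas >= 1L)
  structure(list(min_occupancy = min_occupancy,
                 min_replicas = as.integer(min_replicas)),
            class = "persistence_criteria")
}

#' Filter contacts by replica persistence
#'
#' @param records a `contact_records` data frame from [contact_occupancy()].
#' @param criteria a [persistence_criteria()].
#' @return the records that pass, with added columns `n_replicas_passing`
#'   and `persistent` (all `TRUE` in the returned subset). The full annotated
#'   table is available as `attr(result, "annotated")`.
#' @export
persistence_filter <- function(records, criteria = persistence_criteria()) {
  stopifnot(inherits(criteria, "persistence_criteria"))
  occ_cols <- grep("^occ_rep", names(records), value = TRUE)
  if (length(occ_cols) == 0) stop("records carry no occupancy columns")
  if (criteria$min_replicas > length(occ_cols))
    stop("min_replicas (", criteria$min_replicas,
         ") exceeds the replica count (", length(occ_cols), ")")
  occ <- as.matrix(records[, occ_cols, drop = FALSE])
  n_pass <- rowSums(occ > criteria$min_occupancy)   # strict inequality
  annotated <- records
  annotated$n_replicas_passing <- as.integer(n_pass)
  annotated$persistent <- n_pass >= criteria$min_replicas
  out <- annotated[annotated$persistent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotated") <- annotated
  attr(out, "criteria") <- criteria
  attr(out, "n_frames") <- attr(records, "n_frames")
  class(out) <- class(records)
  out
}

#' Interface contact table
#'
#' Restricts contact records to pairs spanning a given chain pair and renders
#' the residue-pair listing (labels like `GLU85`, kind, mean occupancy),
#' sorted by the first residue.
#'
#' @param records a `contact_records` data frame (filtered or raw).
#' @param chain_pair length-2 character vector, e.g. `c("A", "B")`.
#' @param known_chains optional character vector of valid chain identifiers
#'   (e.g. from the topology); defaults to the chains present in `records`.
#' @return data frame with `res_a`, `chain_a`, `res_b`, `chain_b`, `kind`,
#'   `occ_mean`.
#' @export
interface_table <- function(records, chain_pair, known_chains = NULL) {
  stopifnot(length(chain_pair) == 2L)
  if (is.null(known_chains))
    known_chains <- unique(c(records$chain_a, records$chain_b))
  if (length(known_chains) > 0 && !all(chain_pair %in% known_chains))
    stop("unknown chain: ",
         paste(setdiff(chain_pair, known_chains), collapse = ", "))
  occ_cols <- grep("^occ_rep", names(records), value = TRUE)
  span <- (records$chain_a == chain_pair[1L] & records$chain_b == chain_pair[2L]) |
          (records$chain_a == chain_pair[2L] & records$chain_b == chain_pair[1L])
  rec <- records[span, , drop = FALSE]
  # orient so res_a lies on chain_pair[1]
  flip <- rec$chain_a != chain_pair[1L]
  if (any(flip)) {
    tmp <- rec[flip, c("chain_a", "res_a", "resname_a")]
    rec[flip, c("chain_a", "res_a", "resname_a")] <-
      rec[flip, c("chain_b", "res_b", "resname_b")]
    rec[flip, c("chain_b", "res_b", "resname_b")] <- tmp
  }
  occ_mean <- if (nrow(rec) > 0)
    rowMeans(as.matrix(rec[, occ_cols, drop = FALSE])) else numeric(0)
  out <- data.frame(res_a = paste0(rec$resname_a, rec$res_a),
                    chain_a = rec$chain_a,
                    res_b = paste0(rec$resname_b, rec$res_b),
                    chain_b = rec$chain_b,
                    kind = rec$kind, occ_mean = occ_mean,
                    stringsAsFactors = FALSE)
  out <- out[order(rec$res_a, rec$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write contact records as TSV
#'
#' @param records a `contact_records` data frame (ideally the annotated table
#'   from [persistence_filter()]).
#' @param path output path.
#' @param criteria optional [persistence_criteria()] echoed in the header.
#' @param geometry optional named list of detector settings echoed in the
#'   header.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(records, path, criteria = NULL,
                               geometry = NULL) {
  full <- attr(records, "annotated")
  if (is.null(full)) full <- records
  if (is.null(criteria)) criteria <- attr(records, "criteria")
  meta <- list()
  if (!is.null(criteria))
    meta <- c(meta, list(min_occupancy = criteria$min_occupancy,
                         min_replicas = criteria$min_replicas))
  if (!is.null(geometry)) meta <- c(meta, geometry)
  df <- as.data.frame(full)
  if ("persistent" %in% names(df))
    df$persistent <- ifelse(df$persistent, "Y", "N")
  write_report_tsv(df, path, meta = meta)
}
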