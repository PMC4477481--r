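# Structure / trajectory containers and the multi-model PDB + predictor-file
# readers and writers. Coordinates are Angstrom throughout; residue numbers
# are taken verbatim from the file (no renumbering), so residue labels such
# as Ser32 or Lys22 keep their biological meaning.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

WATER_RES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC")

#' Construct a molecular structure
#'
#' A `pep_structure` couples an atom table (metadata: serial, name, element,
#' residue, chain) with one coordinate set. It is the topology of every
#' trajectory: all frames of a [replica_ensemble()] share the atom order of
#' their topology.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id`.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, Angstrom.
#' @param model_id integer model identifier.
#' @return object of class `pep_structure` with elements `atoms`, `xyz`,
#'   `model_id`.
#' @examples
#' pep <- build_peptide("AAAA")
#' pep
#' @export
pep_structure <- function(atoms, xyz, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "res_name", "res_seq", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be a numeric matrix with 3 columns and one row per atom")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$chain_id <- as.character(atoms$chain_id)
  # res_seq must not decrease within a chain (file order defines analysis order)
  for (ch in unique(atoms$chain_id)) {
    rs <- atoms$res_seq[atoms$chain_id == ch]
    if (is.unsorted(rs, strictly = FALSE))
      stop("res_seq decreases within chain ", ch)
  }
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom (chain, res_seq, name): ", key[duplicated(key)][1L])
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, model_id = as.integer(model_id)),
            class = "pep_structure")
}

#' @export
print.pep_structure <- function(x, ...) {
  a <- x$atoms
  chains <- unique(a$chain_id)
  cat("pep_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain_id, a$res_seq))), "residues,",
      length(chains), if (length(chains) == 1L) "chain" else "chains",
      paste0("(", paste(chains, collapse = ", "), ")\n"))
  invisible(x)
}

#' Bundle replica trajectories into an ensemble
#'
#' A `replica_ensemble` is the unit of every statistic in the package: a set
#' of independent trajectories (replicas) sharing a single topology, mirroring
#' the common design of running several replicate simulations of one system
#' from different initial velocities.
#'
#' @param topology a [pep_structure()]; its coordinates are ignored by
#'   analyses, its atom order defines the frame layout.
#' @param replicas list; each element one replica, either a list of
#'   `n_atoms x 3` frames or a `n_atoms x 3 x n_frames` array.
#' @param frame_spacing time per frame (metadata only; synthetic ensembles
#'   have no physical clock and use the default 1).
#' @return object of class `replica_ensemble` with elements `topology`,
#'   `replicas` (list of `n_atoms x 3 x n_frames` arrays), `frame_spacing`.
#' @export
replica_ensemble <- function(topology, replicas, frame_spacing = 1) {
  stopifnot(inherits(topology, "pep_structure"))
  if (!is.list(replicas) || length(replicas) < 1L)
    stop("need at least one replica")
  n_atoms <- nrow(topology$atoms)
  replicas <- lapply(seq_along(replicas), function(r) {
    rep_r <- replicas[[r]]
    if (is.array(rep_r) && length(dim(rep_r)) == 3L) {
      arr <- rep_r
    } else {
      if (is.matrix(rep_r)) rep_r <- list(rep_r)
      if (length(rep_r) < 1L) stop("replica ", r, " has no frames")
      arr <- array(0, dim = c(nrow(rep_r[[1L]]), 3L, length(rep_r)))
      for (t in seq_along(rep_r)) arr[, , t] <- as.matrix(rep_r[[t]])
    }
    if (dim(arr)[1L] != n_atoms || dim(arr)[2L] != 3L)
      stop("replica ", r, " frames do not match topology atom count (",
           dim(arr)[1L], " vs ", n_atoms, ")")
    if (!all(is.finite(arr))) stop("replica ", r, " has non-finite coordinates")
    arr
  })
  structure(list(topology = topology, replicas = replicas,
                 frame_spacing = frame_spacing),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(a) dim(a)[3L], integer(1))
  cat("replica_ensemble:", length(x$replicas), "replicas x",
      paste(nf, collapse = "/"), "frames,",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

n_frames <- function(ensemble) {
  vapply(ensemble$replicas, function(a) dim(a)[3L], integer(1))
}

get_frame <- function(ensemble, replica, frame) {
  ensemble$replicas[[replica]][, , frame, drop = TRUE]
}

# Resolve a window (frame-index range) against a replica's frame count.
# NULL or "full" means all frames; "first_half"/"second_half" split the
# trajectory in two (mirroring initial/final-period analyses); otherwise an
# inclusive c(first, last) 1-based range.
resolve_window <- function(window, nf) {
  if (is.null(window)) return(seq_len(nf))
  if (is.character(window)) {
    window <- switch(match.arg(window, c("full", "first_half", "second_half")),
                     full = c(1L, nf),
                     first_half = c(1L, max(1L, nf %/% 2L)),
                     second_half = c(min(nf, nf %/% 2L + 1L), nf))
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] < 1L || window[2L] > nf ||
      window[1L] > window[2L])
    stop("window must be c(first, last) within 1..", nf)
  seq.int(window[1L], window[2L])
}

pdb_num <- function(s, line_no, field) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("PDB format error at line %d: unparseable %s field '%s'",
                 line_no, field, trimws(s)), call. = FALSE)
  v
}

guess_element <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  if (nchar(s) == 0) return("X")
  toupper(substr(s, 1L, 1L))
}

#' Read a multi-model PDB file
#'
#' Parses a (possibly multi-model) PDB file into a topology and a list of
#' coordinate frames. MODEL/ENDMDL records delimit frames; a single-model file
#' yields one frame. HETATM records and waters/ions are skipped (analyses are
#' protein-only). Alternate locations keep the highest-occupancy copy (tie:
#' altloc "A"); insertion codes are rejected. Atom order must be identical in
#' every model.
#'
#' @param path file path. LF and CRLF line endings are both accepted.
#' @return list with `topology` (a [pep_structure()], coordinates of the first
#'   model) and `frames` (list of `n_atoms x 3` matrices, Angstrom).
#' @seealso [write_multimodel_pdb()]
#' @export
read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  "
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"

  # assign each ATOM line a model index
  model_idx <- cumsum(is_model)
  has_models <- any(is_model)
  if (!has_models) model_idx <- rep(1L, length(lines))
  model_idx[is_endmdl] <- NA  # markers only

  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0) stop("no ATOM records found in ", path)
  amodel <- model_idx[atom_lines]
  if (has_models && any(amodel == 0))
    stop("PDB format error: ATOM record before first MODEL at line ",
         atom_lines[amodel == 0][1L])

  parse_model <- function(idx) {
    ln <- lines[idx]
    res_name <- trimws(substr(ln, 18L, 20L))
    keep <- !(res_name %in% WATER_RES)
    ln <- ln[keep]; idx <- idx[keep]; res_name <- res_name[keep]
    icode <- substr(ln, 27L, 27L)
    if (any(icode != " "))
      stop("PDB format error at line ", idx[icode != " "][1L],
           ": insertion codes are not supported")
    n <- length(ln)
    x <- numeric(n); y <- numeric(n); z <- numeric(n); occ <- numeric(n)
    for (i in seq_len(n)) {
      x[i] <- pdb_num(substr(ln[i], 31L, 38L), idx[i], "x")
      y[i] <- pdb_num(substr(ln[i], 39L, 46L), idx[i], "y")
      z[i] <- pdb_num(substr(ln[i], 47L, 54L), idx[i], "z")
      o <- trimws(substr(ln[i], 55L, 60L))
      occ[i] <- if (nzchar(o)) suppressWarnings(as.numeric(o)) else 1
      if (is.na(occ[i])) occ[i] <- 1
    }
    elem <- trimws(substr(ln, 77L, 78L))
    name <- trimws(substr(ln, 13L, 16L))
    no_elem <- !nzchar(elem)
    if (any(no_elem)) elem[no_elem] <- vapply(name[no_elem], guess_element, "")
    df <- data.frame(
      serial = suppressWarnings(as.integer(trimws(substr(ln, 7L, 11L)))),
      name = name,
      altloc = substr(ln, 17L, 17L),
      element = toupper(elem),
      res_name = res_name,
      res_seq = suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L)))),
      chain_id = substr(ln, 22L, 22L),
      x = x, y = y, z = z, occ = occ,
      stringsAsFactors = FALSE
    )
    if (anyNA(df$res_seq))
      stop("PDB format error at line ", idx[is.na(df$res_seq)][1L],
           ": unparseable residue number")
    # altloc: keep the highest-occupancy copy; tie -> altloc 'A'
    if (any(df$altloc != " ")) {
      key <- paste(df$chain_id, df$res_seq, df$name)
      keep <- rep(TRUE, nrow(df))
      for (k in unique(key[df$altloc != " "])) {
        rows <- which(key == k)
        if (length(rows) > 1L) {
          best <- rows[order(-df$occ[rows], df$altloc[rows])][1L]
          keep[setdiff(rows, best)] <- FALSE
        }
      }
      df <- df[keep, , drop = FALSE]
    }
    df
  }

  models <- sort(unique(amodel))
  parsed <- lapply(models, function(m) parse_model(atom_lines[amodel == m]))
  ref <- parsed[[1L]]
  sig <- function(df) paste(df$chain_id, df$res_seq, df$name)
  ref_sig <- sig(ref)
  frames <- vector("list", length(parsed))
  for (m in seq_along(parsed)) {
    df <- parsed[[m]]
    if (nrow(df) != nrow(ref) || !identical(sig(df), ref_sig))
      stop("PDB format error: model ", m,
           " atom count/order differs from model 1")
    frames[[m]] <- cbind(x = df$x, y = df$y, z = df$z)
  }
  atoms <- ref[, c("serial", "name", "element", "res_name", "res_seq",
                   "chain_id")]
  rownames(atoms) <- NULL
  topo <- pep_structure(atoms, frames[[1L]], model_id = 1L)
  list(topology = topo, frames = frames)
}

#' Write a multi-model PDB file
#'
#' Renders a topology plus coordinate frames as a multi-model PDB file that
#' [read_multimodel_pdb()] reads back unchanged (coordinates `%8.3f`,
#' fixed-point to 0.001 Angstrom).
#'
#' @param topology a [pep_structure()].
#' @param frames a single `n_atoms x 3` matrix or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(topology, frames, path) {
  stopifnot(inherits(topology, "pep_structure"))
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < 1L) stop("need at least one frame")
  a <- topology$atoms
  for (f in frames) {
    f <- as.matrix(f)
    if (nrow(f) != nrow(a) || ncol(f) != 3L)
      stop("frame does not conform to topology (", nrow(f), " x ", ncol(f),
           " vs ", nrow(a), " atoms)")
    if (any(abs(f) >= 1000))
      stop("coordinate exceeds the PDB %8.3f field width")
  }
  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4L, sprintf("%-4s", substr(nm, 1L, 4L)),
           sprintf(" %-3s", nm))
  }
  names4 <- fmt_name(a$name)
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  out <- character(0)
  for (m in seq_along(frames)) {
    f <- as.matrix(frames[[m]])
    body <- sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    a$serial %% 100000L, names4, a$res_name, a$chain_id,
                    a$res_seq, f[, 1L], f[, 2L], f[, 3L], 1, 0,
                    sprintf("%2s", substr(a$element, 1L, 2L)))
    out <- c(out, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read an ensemble of replica trajectories from PDB files
#'
#' Convenience wrapper: reads one multi-model PDB per replica and checks that
#' all replicas share the topology of the first.
#'
#' @param paths character vector of multi-model PDB files, one per replica.
#' @param frame_spacing metadata passed to [replica_ensemble()].
#' @return a [replica_ensemble()].
#' @export
read_ensemble <- function(paths, frame_spacing = 1) {
  stopifnot(length(paths) >= 1L)
  first <- read_multimodel_pdb(paths[[1L]])
  sig <- function(a) paste(a$chain_id, a$res_seq, a$name)
  reps <- list(first$frames)
  for (p in paths[-1L]) {
    nxt <- read_multimodel_pdb(p)
    if (!identical(sig(nxt$topology$atoms), sig(first$topology$atoms)))
      stop("replica ", p, " topology differs from ", paths[[1L]])
    reps <- c(reps, list(nxt$frames))
  }
  replica_ensemble(first$topology, reps, frame_spacing)
}

#' Read 3-state secondary-structure predictions
#'
#' Parses a plain-text predictor file: each record is a `>`-prefixed label
#' line followed by one (or more, concatenated) lines of per-residue states
#' over the alphabet H/E/C. Eight-state predictor alphabets must be reduced to
#' 3 states upstream (G/I to the helix class, B to the strand class, the rest
#' to coil); this reader accepts only H, E and C.
#'
#' @param path file path; LF or CRLF.
#' @return named character vector, one equal-length H/E/C string per
#'   predictor.
#' @export
read_predictions <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty prediction file: ", path)
  is_label <- startsWith(lines, ">")
  if (!is_label[1L])
    stop("prediction format error: first line must be a '>' label")
  idx <- cumsum(is_label)
  labels <- trimws(sub("^>", "", lines[is_label]))
  preds <- vapply(seq_len(max(idx)), function(i) {
    paste(lines[idx == i & !is_label], collapse = "")
  }, character(1))
  if (any(!nzchar(preds)))
    stop("prediction format error: predictor '",
         labels[!nzchar(preds)][1L], "' has no state string")
  bad <- regexpr("[^HEC]", preds)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal state character '%s' at position %d of predictor '%s'",
                 substr(preds[i], bad[i], bad[i]), bad[i], labels[i]))
  }
  lens <- nchar(preds)
  if (length(unique(lens)) > 1L)
    stop("prediction strings have unequal lengths: ",
         paste(sprintf("%s=%d", labels, lens), collapse = ", "))
  stats::setNames(preds, labels)
}

#' Extract one-letter sequences per chain
#'
#' @param topology a [pep_structure()].
#' @return named character vector: one-letter amino-acid string per chain
#'   (unknown residue types become `X`).
#' @export
structure_sequence <- function(topology) {
  a <- topology$atoms
  res <- residue_table(topology)
  out <- vapply(split(res, res$chain_id), function(df) {
    aa <- AA1[df$res_name]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
  out[unique(a$chain_id)]
}

# One row per residue in file order: chain_id, res_seq, res_name plus the
# atom-index range. Used by every per-residue analysis.
residue_table <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain_id, a$res_seq)
  first <- !duplicated(key)
  res <- data.frame(chain_id = a$chain_id[first], res_seq = a$res_seq[first],
                    res_name = a$res_name[first], stringsAsFactors = FALSE)
  res$res_index <- seq_len(nrow(res))
  map <- match(key, key[first])
  res$atom_first <- match(seq_len(nrow(res)), map)
  res$atom_last <- length(map) - match(seq_len(nrow(res)), rev(map)) + 1L
  res
}

# Map each atom to its residue row in residue_table(topology).
atom_residue_index <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain_id, a$res_seq)
  match(key, unique(key))
}

#' Atom selection specification
#'
#' @param atom_names character vector of PDB atom names (default `"CA"`);
#'   `NULL` selects all atom names.
#' @param chain_ids optional chains to keep.
#' @param residue_range optional inclusive `c(first, last)` residue-number
#'   range.
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(atom_names = "CA", chain_ids = NULL,
                           residue_range = NULL) {
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L, residue_range[1L] <= residue_range[2L])
  }
  structure(list(atom_names = atom_names, chain_ids = chain_ids,
                 residue_range = residue_range), class = "selection_spec")
}

#' Resolve a selection against a topology
#'
#' @param topology a [pep_structure()].
#' @param spec a [selection_spec()].
#' @return integer atom indices (file order). Errors if the selection is
#'   empty.
#' @export
select_atoms <- function(topology, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$atom_names)) keep <- keep & a$name %in% spec$atom_names
  if (!is.null(spec$chain_ids)) keep <- keep & a$chain_id %in% spec$chain_ids
  if (!is.null(spec$residue_range))
    keep <- keep & a$res_seq >= spec$residue_range[1L] &
      a$res_seq <= spec$residue_range[2L]
  idx <- which(keep)
  if (length(idx) == 0) stop("selection matches no atoms")
  idx
}

# Write a data frame as TSV with '# key: value' metadata header lines.
write_report_tsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(format(x), collapse = " "), "")),
               con, sep = "\n")
  }
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) format(col, digits = 6, trim = TRUE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
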