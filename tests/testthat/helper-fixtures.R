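# Shared fixtures and independent oracles. Everything is generated in code;
# reference implementations (mdtraj via the bundled python scripts, bio3d)
# serve as independent cross-checks only.

# --- conformer fixtures -----------------------------------------------------

# beta-hairpin: two antiparallel strands joined by a two-residue turn
build_hairpin <- function(n = 14L) {
  phi <- rep(-139, n)
  psi <- rep(135, n)
  m <- n %/% 2L
  phi[m] <- 60; psi[m] <- -120
  phi[m + 1L] <- -80; psi[m + 1L] <- 0
  build_peptide(strrep("A", n), phi = phi, psi = psi)
}

conformer_battery <- function(n_variants = 50L, sigma = 0.15, seed = 1234L) {
  base <- list(
    helix = build_peptide(strrep("A", 14L)),
    helix310 = build_peptide(strrep("A", 12L), phi = -49, psi = -26),
    hairpin = build_hairpin(),
    coil = build_peptide(strrep("A", 14L), phi = -100, psi = 120))
  set.seed(seed)
  lapply(base, function(pep) {
    frames <- list(pep$xyz)
    for (k in seq_len(n_variants)) {
      frames[[k + 1L]] <- pep$xyz +
        matrix(stats::rnorm(length(pep$xyz), 0, sigma), ncol = 3L)
    }
    list(topology = pep, frames = frames)
  })
}

# small ad-hoc atom set (for SASA / geometry edge cases)
atom_cloud <- function(xyz, element = "C", res_seq = seq_len(nrow(xyz)),
                       res_name = "ALA", name = NULL, chain_id = "A") {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  if (is.null(name)) name <- sprintf("X%d", seq_len(n))
  pep_structure(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    element = rep_len(element, n), res_name = rep_len(res_name, n),
    res_seq = rep_len(res_seq, n), chain_id = rep_len(chain_id, n),
    stringsAsFactors = FALSE), xyz)
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4L)
    if (sum(q^2) > 1e-8) break
  }
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3L, 3L, byrow = TRUE)
}

rigid_move <- function(frame, R = random_rotation(), t = stats::rnorm(3L, 0, 5)) {
  sweep(frame %*% t(R), 2L, -t)
}

# --- independent numeric oracles --------------------------------------------

# brute-force rigid superposition: optimal translation is centroid matching;
# rotation minimised over Euler angles from many random restarts
brute_force_rmsd <- function(P, Q, n_starts = 40L) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  obj <- function(ang) {
    Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1]), 0,
                   0, 0, 1), 3L, 3L, byrow = TRUE)
    Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3L, 3L, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[3]), -sin(ang[3]),
                   0, sin(ang[3]), cos(ang[3])), 3L, 3L, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- stats::runif(3L, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# analytic accessible area of two intersecting spheres (expanded radii)
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(4 * pi * max(r1, r2)^2)
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  (4 * pi * r1^2 - 2 * pi * r1 * h1) + (4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# O(n^2) reference for the minimum-distance matrix on tiny systems
naive_min_dist <- function(ensemble, window = NULL) {
  topo <- ensemble$topology
  res <- pepdyn:::residue_table(topo)
  ridx <- pepdyn:::atom_residue_index(topo)
  heavy <- topo$atoms$element != "H"
  n <- nrow(res)
  acc <- matrix(0, n, n)
  count <- 0L
  for (r in seq_along(ensemble$replicas)) {
    arr <- ensemble$replicas[[r]]
    for (t in seq_len(dim(arr)[3L])) {
      f <- arr[, , t]
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        ai <- which(ridx == i & heavy)
        aj <- which(ridx == j & heavy)
        dmin <- Inf
        for (x in ai) for (y in aj) {
          dmin <- min(dmin, sqrt(sum((f[x, ] - f[y, ])^2)))
        }
        acc[i, j] <- acc[i, j] + dmin
      }
      count <- count + 1L
    }
  }
  acc / count
}

# brute-force segment scan oracle for extract_segments
scan_segments <- function(states, target, min_length) {
  s <- strsplit(states, "")[[1L]]
  out <- NULL
  i <- 1L
  while (i <= length(s)) {
    if (s[i] == target) {
      j <- i
      while (j < length(s) && s[j + 1L] == target) j <- j + 1L
      if (j - i + 1L >= min_length)
        out <- rbind(out, data.frame(state = target, start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) data.frame(state = character(0), start = integer(0),
                               end = integer(0)) else out
}

# --- reference implementations (python / mdtraj) ----------------------------

oracle_script <- function(name) {
  p <- system.file("oracle", name, package = "pepdyn")
  stopifnot(nzchar(p))
  p
}

run_dssp_oracle <- function(paths) {
  out <- system2("python", c(oracle_script("dssp_oracle.py"), paths),
                 stdout = TRUE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(path = vapply(parts, `[`, "", 1L),
             model = as.integer(vapply(parts, `[`, "", 2L)),
             states = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
}

run_sasa_oracle <- function(path, n_points = 960L) {
  out <- system2("python", c(oracle_script("sasa_oracle.py"), path, n_points),
                 stdout = TRUE)
  as.numeric(vapply(strsplit(out, "\t", fixed = TRUE), `[`, "", 2L))
}

# agreement of assign_sse with the reference DSSP over a conformer battery
dssp_battery_agreement <- function(battery) {
  tmp <- tempfile("dssp_battery")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  paths <- character(0)
  ours <- list()
  for (nm in names(battery)) {
    b <- battery[[nm]]
    p <- file.path(tmp, paste0(nm, ".pdb"))
    write_multimodel_pdb(b$topology, b$frames, p)
    paths <- c(paths, p)
    ours[[nm]] <- vapply(b$frames, function(f) {
      paste(assign_sse(f, b$topology), collapse = "")
    }, character(1))
  }
  ref <- run_dssp_oracle(paths)
  agree <- 0L
  total <- 0L
  for (nm in names(battery)) {
    rr <- ref[basename(ref$path) == paste0(nm, ".pdb"), ]
    for (m in seq_along(ours[[nm]])) {
      a <- strsplit(ours[[nm]][m], "")[[1L]]
      b <- strsplit(rr$states[rr$model == m], "")[[1L]]
      stopifnot(length(a) == length(b))
      agree <- agree + sum(a == b)
      total <- total + length(a)
    }
  }
  list(agreement = agree / total, n = total)
}
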