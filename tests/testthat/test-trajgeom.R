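make_ensemble <- function(topology, frames_per_rep) {
  replica_ensemble(topology, frames_per_rep)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  pep <- build_peptide("AKSAEG", phi = -70, psi = -40)
  f <- pep$xyz
  ident <- kabsch_superpose(f, f)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ident$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(ident$rmsd, 0, tolerance = 1e-10)

  # 90 degrees about z plus (1,2,3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(f %*% t(Rz), 2L, -c(1, 2, 3))
  tf <- kabsch_superpose(moved, f)
  expect_lt(tf$rmsd, 1e-8)
  expect_equal(tf$rotation %*% Rz, diag(3), tolerance = 1e-8)
  expect_equal(apply_transform(moved, tf), f, tolerance = 1e-8,
               ignore_attr = TRUE)

  set.seed(21)
  for (k in 1:5) {
    moved <- rigid_move(f)
    expect_lt(kabsch_superpose(moved, f)$rmsd, 1e-8)
  }
})

test_that("Kabsch RMSD matches a brute-force rotational minimizer on noisy points", {
  set.seed(8)
  for (k in 1:3) {
    P <- matrix(rnorm(30, 0, 3), 10, 3)
    Q <- rigid_move(P) + matrix(rnorm(30, 0, 0.1), 10, 3)
    ours <- kabsch_superpose(Q, P)$rmsd
    oracle <- brute_force_rmsd(Q, P)
    expect_lt(abs(ours - oracle), 1e-3)
    expect_lte(ours, oracle + 1e-9)  # ours is the true minimum
  }
})

test_that("degenerate superposition geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("average structure: fixed point, rigid-motion congruence, symmetry", {
  pep <- build_peptide("AKSAEGA", phi = -65, psi = -42)
  f <- pep$xyz

  # identical frames -> that frame
  ens <- make_ensemble(pep, list(list(f, f), list(f)))
  avg <- average_structure(ens)
  expect_equal(avg, f, tolerance = 1e-8, ignore_attr = TRUE)

  # frames that are rigid motions of one structure -> congruent average
  set.seed(2)
  ens2 <- make_ensemble(pep, list(list(f, rigid_move(f), rigid_move(f))))
  avg2 <- average_structure(ens2)
  expect_lt(kabsch_superpose(avg2, f, seq_len(nrow(f)))$rmsd, 1e-6)

  # symmetric +delta/-delta perturbations cancel (small delta: the opposed
  # superposition rotations cancel to first order)
  delta <- matrix(rnorm(length(f), 0, 1e-4), ncol = 3)
  ens3 <- make_ensemble(pep, list(list(f + delta, f - delta)))
  avg3 <- average_structure(ens3)
  expect_lt(kabsch_superpose(avg3, f, seq_len(nrow(f)))$rmsd, 1e-6)
})

test_that("RMSF is zero for static trajectories and sqrt(3)*sigma for iid noise", {
  pep <- build_peptide("AAAAAA", phi = -70, psi = -40)
  f <- pep$xyz
  ens <- make_ensemble(pep, list(list(f, f, f), list(f, f)))
  prof <- rmsf(ens)
  expect_true(all(prof$rmsf_mean < 1e-10))

  # one mobile atom near the centre of a large anchored shell: the fit
  # barely absorbs its motion, so RMSF ~ sigma * sqrt(3)
  set.seed(31)
  n_big <- 101L
  base <- rbind(c(0.5, 0, 0), pepdyn:::sphere_lattice(n_big - 1L) * 20)
  topo <- atom_cloud(base, element = "C", res_seq = seq_len(n_big),
                     name = "CA")
  sigma <- 0.4
  frames <- lapply(1:2000, function(t) {
    g <- base
    g[1L, ] <- g[1L, ] + rnorm(3, 0, sigma)
    g
  })
  ens2 <- make_ensemble(topo, list(frames))
  prof2 <- rmsf(ens2, selection_spec("CA"))
  expect_equal(prof2$rmsf_mean[1L], sigma * sqrt(3), tolerance = 0.05)
  expect_true(all(prof2$rmsf_mean[-1L] < 0.05))
})

test_that("windowed RMSF halves agree with the full window for stationary noise", {
  set.seed(12)
  pep <- build_peptide(strrep("A", 10), phi = -70, psi = -40)
  frames <- lapply(1:400, function(t) {
    pep$xyz + matrix(rnorm(length(pep$xyz), 0, 0.3), ncol = 3)
  })
  ens <- make_ensemble(pep, list(frames))
  full <- rmsf(ens)
  h1 <- rmsf(ens, window = "first_half", label = "first half")
  h2 <- rmsf(ens, window = "second_half", label = "second half")
  expect_equal(h1$rmsf_mean, full$rmsf_mean, tolerance = 0.15)
  expect_equal(h2$rmsf_mean, full$rmsf_mean, tolerance = 0.15)
  expect_identical(attr(h1, "window"), "first half")
})

test_that("RMSF ranks residues by their designed mobility", {
  set.seed(77)
  n <- 20L
  base <- cbind(5 * cos(seq_len(n)), 5 * sin(seq_len(n)), 2 * seq_len(n))
  topo <- atom_cloud(base, res_seq = seq_len(n), name = "CA")
  sigmas <- seq(0.05, 1.0, length.out = n)
  frames <- lapply(1:1000, function(t) {
    base + matrix(rnorm(3 * n, 0, rep(sigmas, 3)), n, 3)
  })
  ens <- make_ensemble(topo, list(frames))
  prof <- rmsf(ens)
  expect_gt(cor(prof$rmsf_mean, sigmas, method = "spearman"), 0.9)
})

test_that("RMSD series: zero references, monotone drift, rigid rotation", {
  pep <- build_peptide("AKSAEG", phi = -70, psi = -40)
  f <- pep$xyz
  static <- make_ensemble(pep, list(list(f, f, f)))
  s <- rmsd_series(static)
  expect_true(all(s$rmsd < 1e-10))

  # linear drift away from frame 1: monotone non-decreasing series
  set.seed(4)
  dir <- matrix(rnorm(length(f)), ncol = 3)
  drift <- lapply(0:10, function(k) f + 0.2 * k * dir)
  s2 <- rmsd_series(make_ensemble(pep, list(drift)))
  expect_true(all(diff(s2$rmsd) > -1e-9))

  # rigidly rotating body: superposition removes all motion
  rot <- lapply(seq(0, 150, by = 30), function(ang) {
    f %*% t(pepdyn:::rotation_about_axis(c(0, 0, 1), ang))
  })
  s3 <- rmsd_series(make_ensemble(pep, list(rot)))
  expect_true(all(s3$rmsd < 1e-8))
})

test_that("minimum-distance matrix matches the brute-force oracle", {
  set.seed(9)
  pep <- build_peptide("AKSDE", phi = -100, psi = 120)
  frames <- lapply(1:3, function(t) {
    pep$xyz + matrix(rnorm(length(pep$xyz), 0, 0.2), ncol = 3)
  })
  ens <- make_ensemble(pep, list(frames[1:2], frames[3]))
  M <- min_distance_matrix(ens)
  O <- naive_min_dist(ens)
  expect_equal(unname(diag(M)), rep(0, 5))
  expect_equal(M, t(M), ignore_attr = TRUE)
  expect_equal(M, O, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two residues fixed 5 A apart give a 5.0 entry", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 5))
  topo <- atom_cloud(xyz, res_seq = c(1L, 2L), name = c("CA", "CA"),
                     res_name = "GLY")
  ens <- make_ensemble(topo, list(list(xyz, xyz)))
  M <- min_distance_matrix(ens)
  expect_equal(M[1, 2], 5.0)
})

test_that("geometry statistics are invariant under global rigid motion", {
  set.seed(14)
  pep <- build_peptide("AKSAEGAK", phi = -70, psi = -40)
  frames <- lapply(1:6, function(t) {
    pep$xyz + matrix(rnorm(length(pep$xyz), 0, 0.25), ncol = 3)
  })
  R <- random_rotation()
  tr <- rnorm(3, 0, 8)
  moved <- lapply(frames, function(f) sweep(f %*% t(R), 2L, -tr))
  e1 <- make_ensemble(pep, list(frames))
  e2 <- make_ensemble(pep, list(moved))
  expect_equal(rmsf(e1)$rmsf_mean, rmsf(e2)$rmsf_mean, tolerance = 1e-6)
  expect_equal(min_distance_matrix(e1), min_distance_matrix(e2),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(rmsd_series(e1)$rmsd, rmsd_series(e2)$rmsd, tolerance = 1e-8)
})
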