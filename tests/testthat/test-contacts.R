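# a minimal two-atom-group fixture: one N-H donor group and one C=O acceptor
hbond_probe <- function(d_no, angle_dev = 0) {
  # donor N at origin with H toward +x; acceptor O at distance d on +x
  # (angle_dev tilts the O off the N-H axis)
  th <- angle_dev * pi / 180
  o <- c(d_no * cos(th), d_no * sin(th), 0)
  xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0), o, o + c(1.23, 0, 0))
  pep_structure(data.frame(
    serial = 1:4, name = c("N", "H", "O", "C"),
    element = c("N", "H", "O", "C"),
    res_name = c("ALA", "ALA", "GLY", "GLY"),
    res_seq = c(1L, 1L, 5L, 5L), chain_id = c("A", "A", "B", "B"),
    stringsAsFactors = FALSE), xyz)
}

test_that("hydrogen-bond geometry criterion: textbook hit and cutoffs", {
  hit <- hbond_probe(2.9)
  got <- detect_hbonds(hit$xyz, hit)
  expect_equal(nrow(got), 1L)
  expect_identical(got$chain_a, "A")
  expect_identical(got$chain_b, "B")

  # just beyond the distance cutoff
  miss <- hbond_probe(3.6)
  expect_equal(nrow(detect_hbonds(miss$xyz, miss)), 0L)
  # boundary: exactly 3.5 is within (<=)
  edge <- hbond_probe(3.5)
  expect_equal(nrow(detect_hbonds(edge$xyz, edge)), 1L)
  # angle beyond 30 degrees fails even at short distance
  bent <- hbond_probe(2.9, angle_dev = 40)
  expect_equal(nrow(detect_hbonds(bent$xyz, bent)), 0L)
})

test_that("designed interface fixture yields exactly its designed pairs", {
  ens <- contact_complex_ensemble(matrix(1, 4, 1),
                                  n_frames = 1L,
                                  kind = c("hbond", "hbond",
                                           "saltbridge", "saltbridge"))
  man <- attr(ens, "manifest")$contacts
  f <- ens$replicas[[1]][, , 1]
  hb <- detect_hbonds(f, ens$topology)
  # every designed pair is found, and nothing beyond the designed sites:
  # the lysine-glutamate pairs also satisfy the (distance-only) donor-
  # acceptor criterion, which is chemically correct
  expect_setequal(paste(hb$res_a, hb$res_b), paste(man$res_a, man$res_b))
  sb <- detect_salt_bridges(f, ens$topology)
  expect_equal(sb$res_a, man$res_a[man$kind == "saltbridge"])
  expect_identical(unique(sb$resname_a), "GLU")
  expect_identical(unique(sb$resname_b), "LYS")

  # an all-amide fixture yields exactly its designed donor-acceptor pairs
  ens4 <- contact_complex_ensemble(matrix(1, 4, 1), n_frames = 1L,
                                   kind = "hbond")
  man4 <- attr(ens4, "manifest")$contacts
  hb4 <- detect_hbonds(ens4$replicas[[1]][, , 1], ens4$topology)
  expect_equal(hb4$res_a, man4$res_a)
  expect_equal(hb4$res_b, man4$res_b)
  expect_equal(nrow(hb4), 4L)
})

test_that("salt bridges follow the acidic/basic chemistry and cutoff", {
  glu_lys <- function(d) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    pep_structure(data.frame(
      serial = 1:2, name = c("OE1", "NZ"), element = c("O", "N"),
      res_name = c("GLU", "LYS"), res_seq = c(1L, 9L),
      chain_id = c("A", "B"), stringsAsFactors = FALSE), xyz)
  }
  near <- glu_lys(3.0)
  got <- detect_salt_bridges(near$xyz, near)
  expect_equal(nrow(got), 1L)
  far <- glu_lys(4.5)
  expect_equal(nrow(detect_salt_bridges(far$xyz, far)), 0L)

  # every detected pair joins one acidic and one basic residue
  set.seed(10)
  occ <- matrix(runif(6), 2, 3)
  ens <- contact_complex_ensemble(occ, n_frames = 10L, kind = "saltbridge")
  for (t in 1:10) {
    sb <- detect_salt_bridges(ens$replicas[[1]][, , t], ens$topology)
    if (nrow(sb) > 0) {
      expect_true(all(sb$resname_a %in% c("ASP", "GLU")))
      expect_true(all(sb$resname_b %in% c("LYS", "ARG")))
    }
  }
})

test_that("occupancy counts frames exactly on deterministic schedules", {
  occ <- matrix(c(1.0, 0.15, 0.0), 3, 1)
  ens <- contact_complex_ensemble(occ, n_frames = 2000L, kind = "hbond")
  rec <- contact_occupancy(ens, "hbond")
  man <- attr(ens, "manifest")$contacts
  expect_equal(rec$occ_rep1[match(man$res_a[1], rec$res_a)], 1.0)
  expect_equal(rec$occ_rep1[match(man$res_a[2], rec$res_a)], 0.15)
  # never-present contact is not materialised
  expect_false(man$res_a[3] %in% rec$res_a)
})

test_that("persistence filter applies strict occupancy and replica rules", {
  mk <- function(occs) {
    df <- data.frame(kind = "hbond", chain_a = "A", res_a = 1L,
                     resname_a = "GLY", chain_b = "B", res_b = 2L,
                     resname_b = "GLY")
    for (r in seq_along(occs)) df[[paste0("occ_rep", r)]] <- occs[r]
    class(df) <- c("contact_records", "data.frame")
    df
  }
  expect_equal(nrow(persistence_filter(mk(c(0.15, 0.12, 0.02)))), 1L)
  expect_equal(nrow(persistence_filter(mk(c(0.10, 0.10, 0.10)))), 0L)
  expect_equal(nrow(persistence_filter(mk(c(0.90, 0.00, 0.00)))), 0L)
  expect_error(persistence_filter(mk(c(0.5, 0.5)),
                                  persistence_criteria(min_replicas = 3)),
               "replica count")
  expect_error(persistence_criteria(min_occupancy = 0))
})

test_that("raising the criteria never enlarges the persistent set", {
  set.seed(42)
  occ <- matrix(runif(30), 10, 3)
  df <- data.frame(kind = "hbond", chain_a = "A", res_a = 1:10,
                   resname_a = "GLY", chain_b = "B", res_b = 11:20,
                   resname_b = "GLY",
                   occ_rep1 = occ[, 1], occ_rep2 = occ[, 2],
                   occ_rep3 = occ[, 3])
  class(df) <- c("contact_records", "data.frame")
  for (mo in c(0.05, 0.1, 0.3, 0.6)) {
    prev <- nrow(persistence_filter(df, persistence_criteria(mo, 1)))
    for (mr in 2:3) {
      cur <- nrow(persistence_filter(df, persistence_criteria(mo, mr)))
      expect_lte(cur, prev)
      prev <- cur
    }
  }
  kept10 <- persistence_filter(df, persistence_criteria(0.1, 2))
  kept50 <- persistence_filter(df, persistence_criteria(0.5, 2))
  expect_true(all(kept50$res_a %in% kept10$res_a))
})

test_that("the persistent set on scheduled fixtures equals the analytic set", {
  occ <- matrix(c(0.15, 0.12, 0.02,
                  0.10, 0.10, 0.10,
                  0.90, 0.00, 0.00,
                  0.80, 0.80, 0.80), 4, 3, byrow = TRUE)
  ens <- contact_complex_ensemble(occ, n_frames = 200L,
                                  kind = c("hbond", "hbond", "hbond",
                                           "saltbridge"))
  man <- attr(ens, "manifest")$contacts
  hb <- contact_occupancy(ens, "hbond")
  sb <- contact_occupancy(ens, "saltbridge")
  kept_hb <- persistence_filter(hb)
  kept_sb <- persistence_filter(sb)
  # analytic expectation: contacts 1 and 4 survive, 2 (boundary) and 3 fail
  # (contact 4, a lysine-glutamate pair, passes both detectors)
  expect_setequal(kept_hb$res_a, man$res_a[c(1, 4)])
  expect_equal(kept_sb$res_a, man$res_a[4])
  i1 <- match(man$res_a[1], kept_hb$res_a)
  expect_equal(kept_hb$occ_rep1[i1], 0.15)
  expect_equal(kept_hb$occ_rep3[i1], 0.02)
})

test_that("detector outputs are invariant under rigid motion", {
  set.seed(33)
  ens <- contact_complex_ensemble(matrix(c(1, 0.5), 2, 1), n_frames = 4L,
                                  kind = c("hbond", "saltbridge"))
  for (t in 1:4) {
    f <- ens$replicas[[1]][, , t]
    g <- rigid_move(f)
    expect_identical(detect_hbonds(f, ens$topology)[, 1:6],
                     detect_hbonds(g, ens$topology)[, 1:6])
    expect_identical(detect_salt_bridges(f, ens$topology),
                     detect_salt_bridges(g, ens$topology))
  }
})

test_that("interface tables restrict to the chain pair and keep order", {
  df <- data.frame(kind = "hbond",
                   chain_a = c("A", "A", "B", "A", "A"),
                   res_a = c(10L, 20L, 5L, 7L, 30L),
                   resname_a = c("GLU", "ASP", "GLY", "ALA", "SER"),
                   chain_b = c("B", "B", "B", "A", "C"),
                   res_b = c(50L, 60L, 8L, 9L, 2L),
                   resname_b = c("LYS", "ARG", "GLY", "ALA", "GLY"),
                   occ_rep1 = seq(0.1, 0.5, 0.1),
                   occ_rep2 = seq(0.5, 0.1, -0.1))
  class(df) <- c("contact_records", "data.frame")
  tab <- interface_table(df, c("A", "B"))
  expect_equal(nrow(tab), 2L)  # only A-B spanning pairs
  expect_identical(tab$res_a, c("GLU10", "ASP20"))
  expect_identical(tab$res_b, c("LYS50", "ARG60"))
  expect_equal(tab$occ_mean[1], mean(c(0.1, 0.5)))
  expect_error(interface_table(df, c("A", "Z")), "unknown chain")
  empty <- df[0, ]
  class(empty) <- c("contact_records", "data.frame")
  expect_equal(nrow(interface_table(empty, c("A", "B"),
                                    known_chains = c("A", "B"))), 0L)
})

test_that("contact TSV output echoes the criteria", {
  occ <- matrix(c(0.8, 0.8, 0.8), 1, 3)
  ens <- contact_complex_ensemble(occ, n_frames = 10L)
  rec <- persistence_filter(contact_occupancy(ens, "hbond"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contacts_tsv(rec, p)
  lines <- readLines(p)
  expect_true(any(grepl("min_occupancy: 0.1", lines)))
  got <- read.delim(p, comment.char = "#")
  expect_identical(got$persistent, "Y")
})
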