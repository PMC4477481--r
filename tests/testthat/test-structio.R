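test_that("multi-model PDB round-trips coordinates to fixed-point precision", {
  pep <- build_peptide("AKSA", phi = -70, psi = -35)
  set.seed(3)
  frames <- list(pep$xyz,
                 pep$xyz + matrix(rnorm(length(pep$xyz), 0, 0.5), ncol = 3),
                 rigid_move(pep$xyz))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep, frames, p)
  expect_equal(sum(grepl("^MODEL", readLines(p))), 3L)

  back <- read_multimodel_pdb(p)
  expect_length(back$frames, 3L)
  expect_identical(back$topology$atoms$name, pep$atoms$name)
  expect_identical(back$topology$atoms$res_name, pep$atoms$res_name)
  expect_identical(back$topology$atoms$res_seq, pep$atoms$res_seq)
  for (m in 1:3) {
    expect_lt(max(abs(back$frames[[m]] - frames[[m]])), 0.001)
  }

  # write-read-write is byte-identical
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(back$topology, back$frames, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("single-model files yield one frame and CRLF is accepted", {
  pep <- build_peptide("AAA")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep, pep$xyz, p)
  crlf <- withr::local_tempfile(fileext = ".pdb")
  writeBin(charToRaw(paste0(paste(readLines(p), collapse = "\r\n"), "\r\n")),
           crlf)
  for (f in c(p, crlf)) {
    got <- read_multimodel_pdb(f)
    expect_length(got$frames, 1L)
    expect_equal(nrow(got$topology$atoms), nrow(pep$atoms))
  }
})

test_that("malformed multi-model input produces informative format errors", {
  pep <- build_peptide("AAAA")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep, list(pep$xyz, pep$xyz), p)
  lines <- readLines(p)

  # model 2 missing one atom
  atoms2 <- which(grepl("^ATOM", lines))
  mangled <- lines[-atoms2[length(atoms2)]]
  p_bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mangled, p_bad)
  expect_error(read_multimodel_pdb(p_bad), "model 2")

  # unparseable coordinate field with its line number
  bad <- lines
  ln <- atoms2[1L]
  substr(bad[ln], 31, 38) <- "  xx.xxx"
  p_bad2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, p_bad2)
  expect_error(read_multimodel_pdb(p_bad2), paste0("line ", ln))

  # insertion codes rejected
  bad2 <- lines
  substr(bad2[ln], 27, 27) <- "A"
  p_bad3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad2, p_bad3)
  expect_error(read_multimodel_pdb(p_bad3), "insertion")
})

test_that("coordinate overflow and frame mismatch are writer contract errors", {
  pep <- build_peptide("AA")
  big <- pep$xyz
  big[1, 1] <- 1234.5678
  expect_error(write_multimodel_pdb(pep, big, tempfile()), "field width")
  expect_error(write_multimodel_pdb(pep, pep$xyz[-1, ], tempfile()),
               "conform")
})

test_that("HETATM, waters and altlocs follow the reading policy", {
  pep <- build_peptide("AA")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep, pep$xyz, p)
  lines <- readLines(p)
  atom1 <- grep("^ATOM", lines)[1L]
  hetatm <- lines[atom1]
  substr(hetatm, 1, 6) <- "HETATM"
  water <- lines[atom1]
  substr(water, 18, 20) <- "HOH"
  substr(water, 23, 26) <- "  99"
  # altloc copies of atom 1: B with higher occupancy must win
  alt_a <- lines[atom1]; substr(alt_a, 17, 17) <- "A"
  substr(alt_a, 55, 60) <- "  0.40"
  alt_b <- lines[atom1]; substr(alt_b, 17, 17) <- "B"
  substr(alt_b, 55, 60) <- "  0.60"
  substr(alt_b, 31, 38) <- "  99.000"
  mang <- c(lines[1:(atom1 - 1)], alt_a, alt_b, hetatm, water,
            lines[(atom1 + 1):length(lines)])
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mang, p2)
  got <- read_multimodel_pdb(p2)
  expect_equal(nrow(got$topology$atoms), nrow(pep$atoms))  # extras dropped
  expect_equal(unname(got$frames[[1]][1, 1]), 99.0)        # altloc B kept
})

test_that("our PDB output is readable by an independent parser (bio3d)", {
  pep <- build_peptide("AKSE", phi = -80, psi = 60)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep, pep$xyz, p)
  bp <- suppressWarnings(bio3d::read.pdb(p))
  expect_equal(nrow(bp$atom), nrow(pep$atoms))
  expect_equal(as.numeric(bp$atom$x), unname(pep$xyz[, 1]), tolerance = 1e-3)
  expect_identical(bp$atom$resid[1], "ALA")
})

test_that("prediction files parse with strict alphabet and length checks", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("> predA", "HHHCCC", "> predB", "HHH", "ECC"), p)
  preds <- read_predictions(p)
  expect_identical(unname(preds), c("HHHCCC", "HHHECC"))
  expect_identical(names(preds), c("predA", "predB"))

  writeLines(c(">a", "HHHCCC", ">b", "HHHCCCE"), p)
  expect_error(read_predictions(p), "unequal lengths")
  writeLines(c(">a", "HHXCCC"), p)
  expect_error(read_predictions(p), "position 3")
  # CRLF
  writeBin(charToRaw(">a\r\nHEC\r\n>b\r\nCCC\r\n"), p)
  expect_identical(unname(read_predictions(p)), c("HEC", "CCC"))
})

test_that("sequences are extracted per chain and selections resolve", {
  pep <- build_peptide("AKSE")
  expect_identical(unname(structure_sequence(pep)), "AKSE")
  sel <- select_atoms(pep, selection_spec("CA"))
  expect_length(sel, 4L)
  expect_true(all(pep$atoms$name[sel] == "CA"))
  expect_error(select_atoms(pep, selection_spec("ZZ")), "no atoms")
  rng <- select_atoms(pep, selection_spec("CA", residue_range = c(2, 3)))
  expect_identical(pep$atoms$res_seq[rng], 2:3)
})

test_that("structure invariants are enforced", {
  df <- data.frame(serial = 1:2, name = c("CA", "CA"), element = "C",
                   res_name = "ALA", res_seq = c(2L, 1L), chain_id = "A")
  expect_error(pep_structure(df, matrix(0, 2, 3)), "decreases")
  df$res_seq <- c(1L, 1L)
  expect_error(pep_structure(df, matrix(0, 2, 3)), "duplicate")
  df$name <- c("CA", "CB")
  expect_error(pep_structure(df, matrix(c(0, Inf, 0, 0, 0, 0), 2, 3)),
               "finite")
})
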