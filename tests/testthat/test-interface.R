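test_that("interface membership is decided at exactly 6 A", {
  target <- rbind(c(0, 0, 20), c(0, 0, 5.9), c(0, 0, 6.1))
  partner <- rbind(c(0, 0, 0))
  e <- toy_entry(target, partner)
  patch <- interface_patch(chain_atoms(e, "A"), chain_atoms(e, "B"))
  # atom at 5.9 A included (6.0 inclusive), 6.1 A and 20 A excluded
  expect_equal(patch$atoms$resno, 2L)
})

test_that("interface patch equals a brute-force all-pairs scan", {
  set.seed(21)
  for (rep in 1:5) {
    a_xyz <- matrix(runif(30, 0, 15), ncol = 3)
    b_xyz <- matrix(runif(30, 0, 15), ncol = 3)
    e <- toy_entry(a_xyz, b_xyz)
    patch <- interface_patch(chain_atoms(e, "A"), chain_atoms(e, "B"))
    manual <- which(vapply(seq_len(nrow(a_xyz)), function(i) {
      any(sqrt(colSums((t(b_xyz) - a_xyz[i, ])^2)) <= 6)
    }, logical(1)))
    expect_equal(patch$atoms$resno, manual)
    # symmetry: an A atom is in patch(A,B) iff some B atom within 6 A,
    # and that B atom is in patch(B,A)
    rev <- interface_patch(chain_atoms(e, "B"), chain_atoms(e, "A"))
    for (i in patch$atoms$resno) {
      d <- sqrt(colSums((t(b_xyz) - a_xyz[i, ])^2))
      expect_true(any(which(d <= 6) %in% rev$atoms$resno))
    }
  }
})

test_that("ligand contact residues match a brute-force residue scan", {
  set.seed(22)
  prot <- matrix(runif(60, 0, 20), ncol = 3)
  e <- toy_entry(prot)
  lig <- toy_ligand(cbind(10 + cos(1:6), 10 + sin(1:6), 10))
  res <- ligand_interface_residues(chain_atoms(e, "A"), lig)
  lx <- pocketome:::.xyz(ligand_heavy_atoms(lig))
  manual <- which(vapply(seq_len(nrow(prot)), function(i) {
    any(sqrt(colSums((t(lx) - prot[i, ])^2)) <= 6)
  }, logical(1)))
  expect_equal(res$resno, manual)
  # ligand 20 A away contacts nothing
  far <- toy_ligand(cbind(100 + cos(1:6), sin(1:6), 0))
  expect_equal(nrow(ligand_interface_residues(chain_atoms(e, "A"), far)), 0L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_interface_residues(res, f)
  expect_length(readLines(f), nrow(res))
})

test_that("orthosteric test is a >= 50% fraction with inclusive boundary", {
  # 10 cavity points: exactly 5 within 6 A of the single partner atom
  pts <- data.frame(x = c(rep(0, 5), rep(50, 5)), y = 0, z = 1:10)
  cav <- cavity(pts)
  partner <- data.frame(x = 0, y = 0, z = 0, elesy = "C")
  expect_true(is_orthosteric(cav, partner))
  # 4 of 10 fails
  pts2 <- data.frame(x = c(rep(0, 4), rep(50, 6)), y = 0, z = 1:10)
  expect_false(is_orthosteric(cavity(pts2), partner))
  # opposite-face cavity: zero points qualify
  pts3 <- data.frame(x = 50, y = 50, z = 1:10)
  expect_false(is_orthosteric(cavity(pts3), partner))
})

test_that("ligand pocket classes follow the 1 A epitope criterion", {
  cav <- cavity(data.frame(x = 0:4, y = 0, z = 0))
  epi <- data.frame(x = 0, y = 0, z = 5, elesy = "C")
  # closest ligand atom 0.9 A below the epitope -> competitive
  lig09 <- toy_ligand(rbind(c(0, 0, 4.1), c(1, 0, 0), c(2, 0, 0),
                            c(3, 0, 0), c(4, 0, 0)))
  lig11 <- toy_ligand(rbind(c(0, 0, 3.9), c(1, 0, 0), c(2, 0, 0),
                            c(3, 0, 0), c(4, 0, 0)))
  expect_equal(classify_ligand_pocket(cav, lig09, epi, TRUE), "PLOC")
  expect_equal(classify_ligand_pocket(cav, lig11, epi, TRUE), "PLONC")
  # non-orthosteric pocket is allosteric no matter the distance
  expect_equal(classify_ligand_pocket(cav, lig09, epi, FALSE), "PLA")
  # a ligand that does not occupy the cavity is a usage error
  off <- toy_ligand(cbind(0:4 + 30, 0, 0))
  expect_error(classify_ligand_pocket(cav, off, epi, TRUE),
               "ligand/cavity mismatch")
})

test_that("classification is monotone in the competitive cutoff", {
  set.seed(30)
  cav <- cavity(data.frame(x = 0:4, y = 0, z = 0))
  epi <- data.frame(x = 0, y = 0, z = 5, elesy = "C")
  for (i in 1:20) {
    z <- runif(1, 2.5, 4.9)
    lig <- toy_ligand(rbind(c(0, 0, z), c(1, 0, 0), c(2, 0, 0),
                            c(3, 0, 0), c(4, 0, 0)))
    cls <- vapply(c(0.5, 1, 2, 4), function(ct)
      classify_ligand_pocket(cav, lig, epi, TRUE, cutoff = ct), character(1))
    # once PLOC, always PLOC as the cutoff grows
    first_ploc <- match("PLOC", cls)
    if (!is.na(first_ploc))
      expect_true(all(cls[first_ploc:length(cls)] == "PLOC"))
  }
})

test_that("superposition recovers rigid motions exactly", {
  set.seed(40)
  xyz <- matrix(rnorm(45, sd = 5), ncol = 3)
  hd <- toy_entry(xyz, matrix(rnorm(15) + 30, ncol = 3),
                  entry_id = "hd01", uniprot = c(A = "Q00987", B = "P1"))
  # self-superposition: zero RMSD, identity rotation
  pl <- toy_entry(xyz, entry_id = "pl01", uniprot = c(A = "Q00987"))
  fit <- superpose_pl_on_hd(pl, hd, "Q00987")
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # a 90-degree rotation plus shift is removed exactly
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- sweep(xyz %*% t(R90), 2, c(5, -3, 8), "+")
  pl2 <- toy_entry(moved, entry_id = "pl02", uniprot = c(A = "Q00987"))
  fit2 <- superpose_pl_on_hd(pl2, hd, "Q00987")
  expect_lt(fit2$rmsd, 1e-9)
  expect_lt(max(abs(pocketome:::.xyz(chain_atoms(fit2$pl, "A")) - xyz)), 1e-9)
})

test_that("noisy superposition RMSD matches the bio3d Kabsch oracle", {
  set.seed(41)
  xyz <- matrix(rnorm(60, sd = 5), ncol = 3)
  noisy <- xyz + matrix(rnorm(60, sd = 0.5), ncol = 3)
  R90 <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3)
  pl_xyz <- sweep(noisy %*% t(R90), 2, c(-2, 7, 1), "+")
  hd <- toy_entry(xyz, matrix(rnorm(15) + 40, ncol = 3),
                  entry_id = "hd02", uniprot = c(A = "Q00987", B = "P1"))
  pl <- toy_entry(pl_xyz, entry_id = "pl03", uniprot = c(A = "Q00987"))
  fit <- superpose_pl_on_hd(pl, hd, "Q00987")
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(xyz)),
                                         mobile = as.vector(t(pl_xyz))))
  oracle_rmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - xyz)^2)))
  expect_equal(fit$rmsd, oracle_rmsd, tolerance = 1e-6)
  # RMSD is invariant to an extra rigid pre-motion of the mobile entry
  Rz <- matrix(c(cos(1), sin(1), 0, -sin(1), cos(1), 0, 0, 0, 1), 3, 3)
  pl_pre <- toy_entry(sweep(pl_xyz %*% t(Rz), 2, c(11, -4, 2), "+"),
                      entry_id = "pl04", uniprot = c(A = "Q00987"))
  fit_pre <- superpose_pl_on_hd(pl_pre, hd, "Q00987")
  expect_equal(fit_pre$rmsd, fit$rmsd, tolerance = 1e-9)
})

test_that("superposition needs at least three common residues", {
  hd <- toy_entry(matrix(rnorm(9), 3), matrix(rnorm(9) + 20, 3),
                  entry_id = "hd03", uniprot = c(A = "Q1", B = "Q2"))
  pl <- toy_entry(matrix(rnorm(6), 2), entry_id = "pl05",
                  uniprot = c(A = "Q1"))
  expect_error(superpose_pl_on_hd(pl, hd, "Q1"), "common C-alpha")
  expect_error(superpose_pl_on_hd(pl, hd, "QX"), "no chain mapped")
})
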