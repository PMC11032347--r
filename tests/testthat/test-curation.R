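test_that("experimental-quality thresholds are inclusive at the boundary", {
  cfg <- curation_config()
  expect_equal(filter_structure_quality(
    meta_entry("a", "XRAY", 3.5, 0.07), cfg)$verdict, "ACCEPT")
  r <- filter_structure_quality(meta_entry("b", "XRAY", 3.6, 0.03), cfg)
  expect_equal(r$verdict, "REJECT")
  expect_true("resolution" %in% r$failed_rules)
  r <- filter_structure_quality(meta_entry("c", "XRAY", 3.0, 0.08), cfg)
  expect_true("r_free_minus_r_factor" %in% r$failed_rules)
  expect_equal(filter_structure_quality(
    meta_entry("d", "CRYOEM", 3.0, NA, fsc = 0.143), cfg)$verdict, "ACCEPT")
  r <- filter_structure_quality(meta_entry("e", "CRYOEM", 2.9, NA, fsc = 0.20), cfg)
  expect_true("fsc" %in% r$failed_rules)
  r <- filter_structure_quality(meta_entry("f", "CRYOEM", 3.1, NA, fsc = 0.10), cfg)
  expect_true("resolution" %in% r$failed_rules)
  # NMR bypasses the resolution tests; OTHER is rejected outright
  expect_equal(filter_structure_quality(
    meta_entry("g", "NMR", NA, NA), cfg)$verdict, "ACCEPT")
  expect_true("method" %in% filter_structure_quality(
    meta_entry("h", "OTHER", 1.0, 0.01), cfg)$failed_rules)
  # missing mandatory metadata is a rejection, not an exception
  r <- filter_structure_quality(meta_entry("i", "XRAY", NA, NA), cfg)
  expect_equal(r$verdict, "REJECT")
  expect_true("missing_metadata" %in% r$failed_rules)
})

test_that("heterodimer selection enforces chain count, identity and length", {
  mk <- function(id, up, n_res = c(10L, 10L), chains = c("A", "B")) {
    atoms <- do.call(rbind, lapply(seq_along(chains), function(i) {
      n <- n_res[i]
      data.frame(eleno = seq_len(n), elety = "CA", alt = "", resid = "ALA",
                 chain = chains[i], resno = seq_len(n),
                 x = rnorm(n), y = rnorm(n), z = rnorm(n) + 30 * i,
                 elesy = "C", hetero = FALSE)
    }))
    structure_entry(id, atoms, uniprot = up)
  }
  ok <- mk("ok1", c(A = "Q07817", B = "Q16611"))
  homo <- mk("hom", c(A = "Q07817", B = "Q07817"))
  short <- mk("sht", c(A = "Q07817", B = "Q16611"), n_res = c(10L, 3L))
  unmapped <- mk("unm", c(A = "Q07817"))
  three <- mk("tri", c(A = "P1", B = "P2", C = "P3"), n_res = c(5L, 5L, 5L),
              chains = c("A", "B", "C"))
  res <- select_heterodimers(list(ok, homo, short, unmapped, three))
  verdicts <- vapply(res$reports, `[[`, character(1), "verdict")
  expect_equal(verdicts, c("ACCEPT", "REJECT", "REJECT", "REJECT", "REJECT"))
  expect_true("homodimer" %in% res$reports[[2]]$failed_rules)
  expect_true("short_chain" %in% res$reports[[3]]$failed_rules)
  expect_true("unmapped_chain" %in% res$reports[[4]]$failed_rules)
  expect_true("chain_count" %in% res$reports[[5]]$failed_rules)
  # a chain with exactly 4 residues satisfies "more than three"
  four <- mk("fr4", c(A = "Q07817", B = "Q16611"), n_res = c(4L, 10L))
  expect_equal(select_heterodimers(list(four))$reports[[1]]$verdict, "ACCEPT")
})

test_that("ligand filter enforces heavy atoms, elements and exclusions", {
  cfg <- curation_config()
  hex <- toy_ligand(cbind(cos(1:6), sin(1:6), 0))
  expect_equal(filter_ligand(hex, cfg)$verdict, "ACCEPT")
  four <- toy_ligand(cbind(1:4, 0, 0))
  r <- filter_ligand(four, cfg)
  expect_true("min_heavy_atoms" %in% r$failed_rules)
  se <- toy_ligand(cbind(1:6, 0, 0), elements = c("C", "C", "C", "C", "C", "SE"))
  expect_true("element" %in% filter_ligand(se, cfg)$failed_rules)
  # hydrogens and deuteriums do not count as heavy atoms
  hd_lig <- toy_ligand(cbind(1:8, 0, 0),
                       elements = c("C", "C", "C", "C", "H", "H", "D", "D"))
  expect_true("min_heavy_atoms" %in% filter_ligand(hd_lig, cfg)$failed_rules)
  # hard exclusion list and occurrence exclusions
  cfg2 <- curation_config(exclusion_list = "LIG")
  expect_true("exclusion_list" %in% filter_ligand(hex, cfg2)$failed_rules)
  expect_true("occurrence" %in%
                filter_ligand(hex, cfg, occurrence_exclusions = "LIG")$failed_rules)
  # whitelist overrides the occurrence rule (curated visual inspection)
  cfg3 <- curation_config(whitelist = "LIG")
  expect_equal(filter_ligand(hex, cfg3,
                             occurrence_exclusions = "LIG")$verdict, "ACCEPT")
})

test_that("occurrence exclusion uses a strict < 10 rule", {
  cfg <- curation_config()
  expect_equal(build_occurrence_exclusions(c(LIG = 9, DIZ = 50), cfg), "LIG")
  expect_equal(build_occurrence_exclusions(c(DIZ = 10), cfg), character())
  expect_equal(build_occurrence_exclusions(integer(), cfg), character())
  expect_error(build_occurrence_exclusions(c(LIG = -1), cfg), "non-negative")
})

test_that("altloc rule is scoped to the interface", {
  a_xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(30, 0, 0))
  b_xyz <- rbind(c(0, 0, 3), c(1, 0, 3))
  e <- toy_entry(a_xyz, b_xyz)
  patch <- interface_patch(chain_atoms(e, "A"), chain_atoms(e, "B"))
  expect_equal(check_interface_altlocs(e, patch)$verdict, "ACCEPT")
  # altloc far from the interface is tolerated
  e$atoms$alt[3] <- "A"
  patch <- interface_patch(chain_atoms(e, "A"), chain_atoms(e, "B"))
  expect_equal(check_interface_altlocs(e, patch)$verdict, "ACCEPT")
  # altloc at the interface rejects
  e$atoms$alt[1] <- "B"
  patch <- interface_patch(chain_atoms(e, "A"), chain_atoms(e, "B"))
  r <- check_interface_altlocs(e, patch)
  expect_equal(r$verdict, "REJECT")
  expect_equal(r$failed_rules, "altloc")
})

test_that("PL cross-referencing requires one mapped chain shared with an HD", {
  hd <- toy_entry(matrix(rnorm(15), 5), matrix(rnorm(15) + 20, 5),
                  entry_id = "2mps", uniprot = c(A = "Q00987", B = "P12345"))
  pl_ok <- toy_entry(matrix(rnorm(15), 5), entry_id = "1t4e",
                     uniprot = c(A = "Q00987"))
  pl_orphan <- toy_entry(matrix(rnorm(15), 5), entry_id = "9xyz",
                         uniprot = c(A = "Q99999"))
  pl_dimer <- toy_entry(matrix(rnorm(15), 5), matrix(rnorm(15) + 20, 5),
                        entry_id = "2dim", uniprot = c(A = "Q00987", B = "P1"))
  res <- cross_reference_pl(list(pl_ok, pl_orphan, pl_dimer), list(hd))
  expect_length(res$accepted, 1L)
  expect_equal(res$accepted[[1]]$entry$entry_id, "1t4e")
  expect_equal(res$accepted[[1]]$linked_hd_ids, "2mps")
  expect_true("no_hd_match" %in% res$reports[[2]]$failed_rules)
  expect_true("monomer_rule" %in% res$reports[[3]]$failed_rules)
})

test_that("every rejection names at least one documented rule", {
  documented <- c("resolution", "r_free_minus_r_factor", "fsc", "method",
                  "missing_metadata", "chain_count", "unmapped_chain",
                  "homodimer", "short_chain", "min_heavy_atoms", "element",
                  "exclusion_list", "occurrence", "altloc", "monomer_rule",
                  "no_hd_match")
  reports <- list(
    filter_structure_quality(meta_entry("x", "XRAY", 9, 0.5)),
    filter_structure_quality(meta_entry("y", "OTHER", NA, NA)),
    filter_ligand(toy_ligand(cbind(1:3, 0, 0),
                             elements = c("C", "SE", "C"))))
  for (r in reports) {
    expect_equal(r$verdict, "REJECT")
    expect_gt(length(r$failed_rules), 0L)
    expect_true(all(r$failed_rules %in% documented))
  }
})

test_that("filters commute: any application order accepts the same entries", {
  set.seed(99)
  cfg <- curation_config()
  for (i in 1:200) {
    entries <- lapply(1:5, function(j) {
      method <- sample(c("XRAY", "CRYOEM", "NMR", "OTHER"), 1)
      up <- if (runif(1) < 0.8) c(A = "P1", B = sample(c("P1", "P2"), 1))
      else c(A = "P1")
      e <- toy_entry(matrix(rnorm(sample(c(9, 12, 30), 1)), ncol = 3),
                     matrix(rnorm(12) + 25, ncol = 3),
                     entry_id = paste0("e", j), uniprot = up)
      e$method <- method
      e$resolution <- sample(c(2, 3.6, NA), 1)
      e$r_free_minus_r_factor <- sample(c(0.02, 0.09), 1)
      e$fsc <- sample(c(0.1, 0.2), 1)
      e
    })
    pass_q <- vapply(entries, function(e)
      filter_structure_quality(e, cfg)$verdict == "ACCEPT", logical(1))
    pass_h <- vapply(seq_along(entries), function(k)
      select_heterodimers(entries[k])$reports[[1]]$verdict == "ACCEPT",
      logical(1))
    ids <- vapply(entries, `[[`, character(1), "entry_id")
    order1 <- ids[pass_q & pass_h]
    order2 <- ids[pass_h & pass_q]
    expect_identical(order1, order2)
  }
})

test_that("structure preparation strips waters always, heteroatoms for HD only", {
  a <- data.frame(eleno = 1:4, elety = c("CA", "C1", "O", "CA"), alt = "",
                  resid = c("ALA", "LIG", "HOH", "ALA"), chain = "A",
                  resno = c(1L, 90L, 91L, 2L),
                  x = c(0, 5, 8, 1), y = 0, z = 0, elesy = c("C", "C", "O", "C"),
                  hetero = c(FALSE, TRUE, TRUE, FALSE))
  e <- structure_entry("prep", a, uniprot = c(A = "P1"))
  hd <- prepare_structure(e, "HD")
  expect_equal(nrow(hd$atoms), 2L)
  expect_false(any(hd$atoms$hetero))
  pl <- prepare_structure(e, "PL")
  expect_equal(nrow(pl$atoms), 3L)
  expect_true("LIG" %in% pl$atoms$resid)
  expect_false("HOH" %in% pl$atoms$resid)
  # the prepare hook is pluggable and defaults to a no-op
  flipped <- prepare_structure(e, "PL", prepare_hook = function(x) {
    x$atoms$x <- -x$atoms$x; x
  })
  expect_equal(flipped$atoms$x, -pl$atoms$x)
})

test_that("rejection reports are written one file per rule", {
  reports <- list(filter_structure_quality(meta_entry("aaa1", "XRAY", 9, 0.5)),
                  filter_structure_quality(meta_entry("bbb2", "XRAY", 9, 0.01)))
  dir <- withr::local_tempdir()
  write_rejection_reports(reports, dir)
  res_file <- file.path(dir, "rejected_resolution.txt")
  expect_true(file.exists(res_file))
  expect_setequal(readLines(res_file), c("aaa1", "bbb2"))
  dr_file <- file.path(dir, "rejected_r_free_minus_r_factor.txt")
  expect_equal(readLines(dr_file), "aaa1")
})
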