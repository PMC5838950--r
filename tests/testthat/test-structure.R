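test_that("PDB reading keeps standard residues and resolves altLocs", {
  m <- read_structure(toy_pdb_text())
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 3)
  # altLoc A (occ 0.5) vs B (occ 0.6): keep B
  ala <- m$atoms[m$atoms$resno == 5, ]
  expect_equal(nrow(ala), 1)
  expect_equal(ala$x, 0.2)
  expect_error(read_structure("HEADER only\nEND"), "ATOM|parse")
  # writer round-trips
  lines <- write_structure(m)
  m2 <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(m2$residues, m$residues)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
})

test_that("mentions are matched by name, number and optional chain hint", {
  m <- read_structure(toy_pdb_text())
  hit <- match_mention(residue_mention("GLU", 67, "B"), m)
  expect_equal(hit$chain, "B")
  expect_equal(hit$resno, 67)
  # without chain hint any chain qualifies
  expect_false(is.null(match_mention(residue_mention("GLU", 67), m)))
  # wrong chain, wrong name, absent number
  expect_null(match_mention(residue_mention("GLU", 67, "A"), m))
  expect_null(match_mention(residue_mention("ALA", 67), m))
  expect_null(match_mention(residue_mention("GLU", 9999), m))
})

test_that("solvent accessibility: isolated residues are exposed, enclosed ones buried", {
  iso <- read_structure(paste(
    c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
      "END"), collapse = "\n"))
  expect_true(suppressWarnings(is_surface(list(chain = "A", resno = 1), iso)))
  expect_true(suppressWarnings(is_surface(list(chain = "A", resno = 1), iso,
                                          rsasa_threshold = 0)))
  # a residue enclosed in a tight synthetic shell of atoms is buried
  ang <- seq(0.15, pi - 0.15, length.out = 10)
  shell <- do.call(rbind, lapply(ang, function(ph) {
    th <- seq(0, 2 * pi, length.out = 16)[-16]
    cbind(3.2 * sin(ph) * cos(th), 3.2 * sin(ph) * sin(th), 3.2 * cos(ph))
  }))
  atoms <- data.frame(chain = "A", resno = c(1L, rep(2L, nrow(shell))),
                      insert = "", resid = "GLY",
                      elety = "CA", element = "C",
                      x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                      z = c(0, shell[, 3]), o = 1,
                      stringsAsFactors = FALSE)
  mm <- structure(list(atoms = atoms,
                       residues = atoms[!duplicated(atoms$resno),
                                        c("chain", "resno", "insert", "resid")]),
                  class = "structure_model")
  expect_false(suppressWarnings(is_surface(list(chain = "A", resno = 1), mm)))
  # threshold 0 marks everything surface
  expect_true(suppressWarnings(is_surface(list(chain = "A", resno = 1), mm,
                                          rsasa_threshold = 0)))
})

test_that("Shrake-Rupley areas agree with a dense-sampling oracle within 2%", {
  cx <- generate_toy_complex(n_res_receptor = 5, n_res_ligand = 3,
                             n_contacts = 3, seed = 17)
  m <- cx$bound_receptor
  got <- sasa_atoms(m)
  oracle <- brute_force_sasa(m)
  expect_lt(max(abs(got - oracle) / oracle), 0.02)
})

test_that("interface detection respects the cutoff, symmetry and monotonicity", {
  cx <- generate_toy_complex(n_res_receptor = 10, n_res_ligand = 6,
                             n_contacts = 3, seed = 4)
  ia <- interface_residues(cx$bound_receptor, cx$bound_ligand, cutoff = 6)
  expect_equal(sort(ia$receptor$resno), 1:3)
  expect_equal(sort(ia$ligand$resno), 1:3)
  # symmetry under swapping the partners
  ib <- interface_residues(cx$bound_ligand, cx$bound_receptor, cutoff = 6)
  expect_equal(ia$receptor, ib$ligand)
  expect_equal(ia$ligand, ib$receptor)
  # two atoms 5.9 A apart are interface; above the cutoff they are not
  mk <- function(y) read_structure(sprintf(
    "ATOM      1  CA  GLY A   1       0.000  %7.3f   0.000  1.00  0.00           C\nEND", y))
  near <- interface_residues(mk(0), mk(5.9), cutoff = 6)
  expect_equal(nrow(near$receptor), 1)
  expect_equal(nrow(near$ligand), 1)
  far <- interface_residues(mk(0), mk(6.1), cutoff = 6)
  expect_equal(nrow(far$receptor), 0)
  expect_equal(nrow(interface_residues(mk(0), mk(5.9), cutoff = 0)$receptor), 0)
  # monotone in the cutoff
  for (c1 in c(4, 6)) {
    s1 <- interface_residues(cx$bound_receptor, cx$bound_ligand, c1)$ligand$resno
    s2 <- interface_residues(cx$bound_receptor, cx$bound_ligand, c1 + 4)$ligand$resno
    expect_true(all(s1 %in% s2))
  }
})

test_that("unbound-to-bound mapping recovers numbering offsets and rejects unrelated chains", {
  cx <- generate_toy_complex(n_res_receptor = 12, n_res_ligand = 8,
                             n_contacts = 3, seed = 9, noise_sd = 0)
  mp <- map_unbound_to_bound(cx$unbound_ligand, cx$bound_ligand)
  expect_equal(nrow(mp), 8)
  expect_true(all(mp$unbound_resno - mp$bound_resno == cx$offset_ligand))
  # truncation: drop two N-terminal bound residues -> absent from map
  bl <- cx$bound_ligand
  keep <- bl$atoms$resno > 2
  bl$atoms <- bl$atoms[keep, ]
  bl$residues <- bl$residues[bl$residues$resno > 2, ]
  mp2 <- map_unbound_to_bound(cx$unbound_ligand, bl)
  expect_false(any(mp2$bound_resno %in% 1:2))
  expect_equal(nrow(mp2), 6)
  # unrelated sequences error out
  seqs <- list(rep("ALA", 10), rep("TRP", 10))
  mk_chain <- function(resnames, chain)
    tmdock:::toy_chain(chain, length(resnames), 0, resnames)
  expect_error(map_unbound_to_bound(mk_chain(seqs[[1]], "A"),
                                    mk_chain(seqs[[2]], "B")),
               "do not correspond")
})
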