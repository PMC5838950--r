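test_that("basic confidence is the capped provenance sum", {
  expect_equal(confidence_basic(rep("OR", 3)), 3)
  expect_equal(confidence_basic(rep("AND", 6)), 10)   # min(10, 12)
  expect_equal(confidence_basic(c("AND", "OR")), 3)
  expect_equal(confidence_basic("OR"), 1)
  expect_error(confidence_basic(character(0)), "empty")
  # monotone non-decreasing in the abstract multiset
  set.seed(7)
  for (rep in 1:30) {
    prov <- sample(c("AND", "OR"), sample(1:8, 1), replace = TRUE)
    f1 <- confidence_basic(prov)
    f2 <- confidence_basic(c(prov, sample(c("AND", "OR"), 1)))
    expect_gte(f2, f1)
    expect_gte(f1, 1); expect_lte(f1, 10)
  }
})

test_that("NLP confidence matches exhaustive enumeration of evidence patterns", {
  # hand truth: first matching clause of the precedence ladder
  truth <- function(prov, pass) {
    if (any(prov == "AND" & pass)) 10
    else if (any(prov == "AND")) 8
    else if (any(prov == "OR" & pass)) 6
    else min(10, max(5, length(prov)))
  }
  expect_equal(confidence_nlp("AND", TRUE), 10)
  expect_equal(confidence_nlp("OR", TRUE), 6)
  expect_equal(confidence_nlp(c("OR", "OR"), c(FALSE, FALSE)), 5)  # max(5, 2)
  # exhaustive: up to 6 abstracts, all AND/OR x pass/fail combinations
  for (n in 1:6) {
    combos <- expand.grid(rep(list(c("AND", "OR")), n), stringsAsFactors = FALSE)
    passes <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    for (i in seq_len(nrow(combos))) {
      prov <- unlist(combos[i, ], use.names = FALSE)
      for (j in seq_len(nrow(passes))) {
        pass <- unlist(passes[j, ], use.names = FALSE)
        f <- confidence_nlp(prov, pass)
        expect_equal(f, truth(prov, pass))
        expect_gte(f, 1); expect_lte(f, 10)
        # AND evidence never scores below the same pattern with OR evidence
        expect_gte(confidence_nlp(rep("AND", n), pass),
                   confidence_nlp(rep("OR", n), pass))
      }
    }
  }
})

test_that("constraint selection takes the top five with deterministic ties", {
  scored <- data.frame(
    chain = "A", resno = c(10, 20, 30, 40, 50, 60, 70),
    resname = "ALA", f = c(10, 8, 6, 6, 6, 2, 1),
    n_abstracts = c(5, 4, 2, 2, 1, 1, 1),
    has_and = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  sel <- select_constraints(scored, k = 5)
  expect_equal(nrow(sel), 5)
  # ties at f = 6: AND-derived first, then abstract count, then resno
  expect_equal(sel$resno, c(10, 20, 40, 30, 50))
  expect_equal(sel$protein_role, rep("receptor", 5))
  # fewer than k: no padding
  expect_equal(nrow(select_constraints(scored[1:3, ], k = 5)), 3)
  expect_equal(nrow(select_constraints(scored[0, ], k = 5)), 0)
})

test_that("reference constraints are the three closest interface pairs at f = 10", {
  cx <- generate_toy_complex(n_res_receptor = 15, n_res_ligand = 8,
                             n_contacts = 5, seed = 6)
  rc <- reference_constraints(cx$bound_receptor, cx$bound_ligand)
  expect_equal(nrow(rc$pairs), 3)
  expect_true(all(diff(rc$pairs$ca_distance) >= 0))
  expect_true(all(rc$constraints$f == 10))
  # all planted contacts share the CA distance: ties resolved by resno
  expect_equal(rc$pairs$receptor_resno, 1:3)
  # every selected pair satisfies the interface criterion
  ia <- interface_residues(cx$bound_receptor, cx$bound_ligand)
  expect_true(all(rc$pairs$receptor_resno %in% ia$receptor$resno))
  expect_true(all(rc$pairs$ligand_resno %in% ia$ligand$resno))
  # fewer pairs than requested: return what exists, with a warning
  cx2 <- generate_toy_complex(n_res_receptor = 6, n_res_ligand = 4,
                              n_contacts = 2, seed = 6)
  expect_warning(rc2 <- reference_constraints(cx2$bound_receptor,
                                              cx2$bound_ligand),
                 "interface pairs")
  expect_equal(nrow(rc2$pairs), 2)
  # no interface at all
  far <- cx2$bound_ligand
  far$atoms$y <- far$atoms$y + 100
  expect_warning(rc0 <- reference_constraints(cx2$bound_receptor, far),
                 "no interface")
  expect_equal(nrow(rc0$pairs), 0)
})

test_that("pose rescoring sums f over satisfied constraints with stable ties", {
  cx <- generate_toy_complex(n_res_receptor = 12, n_res_ligand = 8,
                             n_contacts = 4, seed = 2, noise_sd = 0,
                             offset_receptor = 0, offset_ligand = 0)
  # identity pose on the bound geometry: all contacts satisfied
  poses <- list(dock_pose("native", raw_score = 1, rank = 2),
                dock_pose("shifted", translation = c(0, 60, 0),
                          raw_score = 2, rank = 1))
  cons <- data.frame(protein_role = c("receptor", "ligand"),
                     chain = c("A", "B"), resno = c(1, 2), f = c(10, 6))
  rr <- rescore_poses(poses, cx$bound_receptor, cx$bound_ligand, cons)
  expect_equal(rr$pose_id, c("native", "shifted"))
  expect_equal(rr$constraint_score, c(16, 0))
  # empty constraints: original order kept, scores zero
  rr0 <- rescore_poses(poses, cx$bound_receptor, cx$bound_ligand, cons[0, ])
  expect_equal(rr0$pose_id, c("shifted", "native"))  # raw rank order
  expect_true(all(rr0$constraint_score == 0))
  # equal constraint scores: raw order preserved (stable tie-break)
  rr1 <- rescore_poses(list(dock_pose("p1", translation = c(0, 60, 0),
                                      raw_score = 5, rank = 1),
                            dock_pose("p2", translation = c(0, 70, 0),
                                      raw_score = 4, rank = 2)),
                       cx$bound_receptor, cx$bound_ligand, cons)
  expect_equal(rr1$pose_id, c("p1", "p2"))
})

test_that("i-RMSD is zero on the identity, additive under translation, rotation-invariant", {
  cx <- generate_toy_complex(n_res_receptor = 12, n_res_ligand = 8,
                             n_contacts = 4, seed = 5, noise_sd = 0)
  mp <- map_unbound_to_bound(cx$unbound_ligand, cx$bound_ligand)
  ref <- tmdock:::irmsd_reference(cx$bound_receptor, cx$bound_ligand,
                                  cx$unbound_ligand, mp)
  native <- dock_pose("nat", ref$superposition$rotation,
                      ref$superposition$translation)
  expect_equal(irmsd(native, cx$bound_receptor, cx$bound_ligand,
                     cx$unbound_ligand, mp), 0, tolerance = 1e-9)
  # pure translation of the native placement by 3 A -> exactly 3 A
  trans <- dock_pose("t3", ref$superposition$rotation,
                     ref$superposition$translation + c(0, 0, 3))
  expect_equal(irmsd(trans, cx$bound_receptor, cx$bound_ligand,
                     cx$unbound_ligand, mp), 3, tolerance = 1e-9)
  # invariance under a global rotation applied to both frames
  set.seed(19)
  for (rep in 1:5) {
    Q <- tmdock:::random_rotation()
    rot_model <- function(m) {
      xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(Q)
      m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
      m
    }
    pose <- dock_pose("p", tmdock:::small_rotation(0.3),
                      ref$superposition$translation + rnorm(3))
    v1 <- irmsd(pose, cx$bound_receptor, cx$bound_ligand,
                cx$unbound_ligand, mp)
    # rotate the bound frame globally; compose the pose accordingly
    pose_rot <- dock_pose("p", Q %*% pose$rotation,
                          as.numeric(Q %*% pose$translation))
    v2 <- irmsd(pose_rot, rot_model(cx$bound_receptor),
                rot_model(cx$bound_ligand), cx$unbound_ligand, mp)
    expect_equal(v1, v2, tolerance = 1e-6)
  }
})

test_that("success rate counts complexes with a near pose in the top ranks", {
  lists <- list(c(8, 4.9, 12), c(7, 9, 11))
  expect_equal(success_rate(lists, threshold = 5, top_n = 10), 0.5)
  # a hit below rank top_n only does not count
  expect_equal(success_rate(list(c(rep(10, 10), 1)), top_n = 10), 0)
  # exactly at the threshold counts (non-strict)
  expect_equal(success_rate(list(c(9, 5.0)), threshold = 5), 1)
  expect_error(success_rate(list()), "empty")
})
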