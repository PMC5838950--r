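test_that("corpus generation is a pure, validated function of the recipe", {
  expect_error(corpus_recipe(interface_mention_rate = 1.5), "probabilities")
  expect_error(corpus_recipe(p_and_query = -0.1), "probabilities")
  r <- corpus_recipe(n_complexes = 8, seed = 14)
  c1 <- generate_corpus(r)
  c2 <- generate_corpus(r)
  expect_identical(c1$gold, c2$gold)
  expect_identical(lapply(c1$abstracts, function(a)
    vapply(a$sentences, `[[`, "", "text")),
    lapply(c2$abstracts, function(a) vapply(a$sentences, `[[`, "", "text")))
  expect_equal(length(c1$abstracts), 8 * r$abstracts_per_complex)
})

test_that("no interface mentions are planted when the rate is zero", {
  corp <- generate_corpus(corpus_recipe(n_complexes = 5,
                                        interface_mention_rate = 0, seed = 2))
  expect_false(any(corp$gold$interface))
})

test_that("generated trees are parseable and their leaves match tokenization", {
  corp <- generate_corpus(corpus_recipe(n_complexes = 6, seed = 33))
  for (id in names(corp$abstracts)) {
    rec <- corp$abstracts[[id]]
    trs <- corp$trees[[id]]
    expect_equal(length(trs), length(rec$sentences))
    for (j in seq_along(trs))
      expect_identical(trs[[j]]$leaves, rec$sentences[[j]]$tokens)
  }
  # sidecar round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tree_sidecar(corp$trees, path)
  back <- read_tree_sidecar(path)
  expect_equal(names(back), names(corp$trees))
  for (id in names(back))
    expect_equal(lapply(back[[id]], `[[`, "leaves"),
                 lapply(corp$trees[[id]], `[[`, "leaves"))
})

test_that("extracted mentions equal the planted mentions exactly", {
  corp <- generate_corpus(corpus_recipe(n_complexes = 10, seed = 8))
  extracted <- do.call(rbind, lapply(names(corp$abstracts), function(id) {
    rec <- corp$abstracts[[id]]
    do.call(rbind, lapply(seq_along(rec$sentences), function(j) {
      ms <- rec$sentences[[j]]$mentions
      if (!length(ms)) return(NULL)
      data.frame(abstract_id = id, sentence_index = j - 1L,
                 residue_name = vapply(ms, `[[`, "", "residue_name"),
                 residue_number = vapply(ms, `[[`, integer(1), "residue_number"),
                 token_index = vapply(ms, `[[`, integer(1), "token_index"))
    }))
  }))
  gold <- corp$gold[, c("abstract_id", "sentence_index", "residue_name",
                        "residue_number", "token_index")]
  rownames(extracted) <- rownames(gold) <- NULL
  ord <- function(d) d[order(d$abstract_id, d$sentence_index), , drop = FALSE]
  expect_equal(ord(extracted), ord(gold), ignore_attr = TRUE)
})

test_that("with certain keyword placement Method 1 separates the labels perfectly", {
  corp <- generate_corpus(corpus_recipe(
    n_complexes = 30, p_keyword_near_interface = 1,
    p_negword_near_noninterface = 1, seed = 12))
  d <- default_dictionary()
  verdicts <- vapply(seq_len(nrow(corp$gold)), function(i) {
    g <- corp$gold[i, ]
    rec <- corp$abstracts[[g$abstract_id]]
    tr <- corp$trees[[g$abstract_id]][[g$sentence_index + 1]]
    method1_filter(tr, rec$sentences[[g$sentence_index + 1]]$mentions[[1]], d)
  }, character(1))
  expect_equal(verdicts == "keep", corp$gold$interface)
})

test_that("toy complexes plant the requested contact geometry", {
  cx <- generate_toy_complex(n_res_receptor = 14, n_res_ligand = 9,
                             n_contacts = 4, seed = 3)
  ia <- interface_residues(cx$bound_receptor, cx$bound_ligand)
  expect_equal(sort(ia$ligand$resno), 1:4)
  expect_equal(sort(ia$receptor$resno), 1:4)
  expect_error(generate_toy_complex(n_res_receptor = 5, n_res_ligand = 5,
                                    n_contacts = 7), "infeasible")
  # determinism
  cx2 <- generate_toy_complex(n_res_receptor = 14, n_res_ligand = 9,
                              n_contacts = 4, seed = 3)
  expect_identical(cx$bound_receptor$atoms, cx2$bound_receptor$atoms)
  expect_identical(cx$unbound_ligand$atoms, cx2$unbound_ligand$atoms)
  # zero noise: unbound-to-bound map is the identity modulo the offset
  cx0 <- generate_toy_complex(n_res_receptor = 10, n_res_ligand = 6,
                              n_contacts = 3, seed = 4, noise_sd = 0)
  mp <- map_unbound_to_bound(cx0$unbound_ligand, cx0$bound_ligand)
  expect_equal(mp$bound_resno, sort(cx0$bound_ligand$residues$resno))
  expect_true(all(mp$unbound_resno == mp$bound_resno + cx0$offset_ligand))
})

test_that("pose sets carry correct gold i-RMSD and respect the near-native fraction", {
  cx <- generate_toy_complex(n_res_receptor = 12, n_res_ligand = 8,
                             n_contacts = 4, seed = 2)
  mp <- map_unbound_to_bound(cx$unbound_ligand, cx$bound_ligand)
  ps <- generate_pose_set(cx, n_poses = 60, fraction_near_native = 0.1,
                          seed = 9)
  expect_length(ps$poses, 60)
  expect_equal(sum(ps$near_native), 6)
  # recorded gold matches an independent i-RMSD computation
  recomputed <- vapply(ps$poses, function(p)
    irmsd(p, cx$bound_receptor, cx$bound_ligand, cx$unbound_ligand, mp),
    numeric(1))
  expect_equal(recomputed, ps$gold_irmsd, tolerance = 1e-6)
  # no near-native poses -> no success at 5 A
  ps0 <- generate_pose_set(cx, n_poses = 40, fraction_near_native = 0,
                           seed = 9)
  expect_equal(success_rate(list(ps0$gold_irmsd), threshold = 5,
                            top_n = 40), 0)
  # determinism
  ps2 <- generate_pose_set(cx, n_poses = 60, fraction_near_native = 0.1,
                           seed = 9)
  expect_identical(ps$gold_irmsd, ps2$gold_irmsd)
})
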