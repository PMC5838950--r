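test_that("bracketed trees parse, serialize and reject malformed input", {
  t1 <- read_bracketed_tree("(S (NP (NN Glu67)) (VP (VBZ binds)))")
  expect_equal(t1$leaves, c("Glu67", "binds"))
  expect_equal(sum(t1$parent == 0), 1)
  t2 <- read_bracketed_tree("(X a)")
  expect_equal(t2$leaves, "a")
  expect_error(read_bracketed_tree("(("), "unbalanced")
  expect_error(read_bracketed_tree(""), "empty")
  expect_error(read_bracketed_tree("(S (NP a)) (S b)"), "single root")
  # round trip
  s <- "(S (NP (DT The) (NN pocket)) (VP (VBZ binds) (NP (NN Glu67))) (. .))"
  expect_equal(write_bracketed_tree(read_bracketed_tree(s)), s)
})

test_that("tree distances match a BFS oracle and form a metric on leaves", {
  expect_equal(tree_distance(read_bracketed_tree("(X a b)"), 1, 1), 0)
  expect_equal(tree_distance(read_bracketed_tree("(X a b)"), 1, 2), 2)
  expect_error(tree_distance(read_bracketed_tree("(X a b)"), 1, 3),
               "out of range")
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:15, 1)
    tr <- read_bracketed_tree(random_tree_string(paste0("w", seq_len(n))))
    d <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) tree_distance(tr, i, j)))
    bfs <- outer(seq_len(n), seq_len(n),
                 Vectorize(function(i, j) bfs_leaf_distance(tr, i, j)))
    expect_equal(d, bfs)
    # metric properties
    expect_true(all(diag(d) == 0))
    expect_true(all(d == t(d)))
    expect_true(all(d[upper.tri(d)] >= 2))
    for (k in seq_len(n))
      expect_true(all(d <= outer(d[, k], d[k, ], `+`) + 1e-9))
  }
})

test_that("the residue score follows the inverse-distance formula", {
  d <- default_dictionary()
  # one positive keyword at distance 4 -> 0.25
  t1 <- read_bracketed_tree("(S (NP (NN Glu67) (NN pocket)) (VP (VBZ sits)))")
  expect_equal(tree_distance(t1, 1, 2), 4)
  expect_equal(score_residue(t1, 1, d)$s_x, 0.25)
  # positives at 2 and 5, negative at 4: 0.5 + 0.2 - 0.25 = 0.45
  t2 <- read_bracketed_tree(
    "(S (NP Glu67 pocket (X (Y phosphorylation))) (VP (VBZ binds)))")
  expect_equal(tree_distance(t2, 1, 2), 2)
  expect_equal(tree_distance(t2, 1, 4), 5)
  expect_equal(tree_distance(t2, 1, 3), 4)
  sc <- score_residue(t2, 1, d)
  expect_equal(sc$s_x, 0.5 + 0.2 - 0.25)
  expect_equal(nrow(sc$positive_terms), 2)
  expect_equal(nrow(sc$negative_terms), 1)
  # no keywords -> 0
  t3 <- read_bracketed_tree("(S (NN Glu67) (VBZ sits))")
  expect_equal(score_residue(t3, 1, d)$s_x, 0)
  # residue leaves never count as keywords
  t4 <- read_bracketed_tree("(S (NN Glu67) (NN Arg45) (NN pocket))")
  sc4 <- score_residue(t4, 1, d)
  expect_equal(nrow(sc4$positive_terms), 1)  # pocket only, not Arg45
})

test_that("random-tree residue scores equal the brute-force oracle", {
  d <- default_dictionary()
  vocab <- c("pocket", "binding", "interface", "docks", "phosphorylation",
             "allosteric", "IgG1", "stable", "core", "the", "protein",
             "holds", "region")
  set.seed(23)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    leaves <- c("Glu67", sample(vocab, n - 1, replace = TRUE))
    leaves <- sample(leaves)
    tr <- read_bracketed_tree(random_tree_string(leaves))
    res_leaf <- match("Glu67", tr$leaves)
    expect_equal(score_residue(tr, res_leaf, d)$s_x,
                 brute_force_sx(tr, res_leaf, d), tolerance = 1e-12)
  }
})

test_that("the score is additive and monotone in positive keywords", {
  d <- default_dictionary()
  base <- "(S (NN Glu67) (NN stable) %s)"
  t_plain <- read_bracketed_tree(sprintf(base, "(NN core)"))
  t_plus <- read_bracketed_tree(sprintf(base, "(NN pocket)"))
  expect_gte(score_residue(t_plus, 1, d)$s_x, score_residue(t_plain, 1, d)$s_x)
  # each term is at most 1/2, so s_x <= n_positive / 2
  sc <- score_residue(t_plus, 1, d)
  expect_true(all(1 / sc$positive_terms$distance <= 0.5))
  expect_lte(sc$s_x, 0.5 * nrow(sc$positive_terms))
})

test_that("Method 1 thresholds strictly at 0.25 and abstains without a tree", {
  d <- default_dictionary()
  m <- residue_mention("GLU", 67, token_index = 1)
  t45 <- read_bracketed_tree(
    "(S (NP Glu67 pocket (X (Y phosphorylation))) (VP (VBZ binds)))")
  expect_equal(method1_filter(t45, m, d), "keep")            # s_x = 0.45
  t25 <- read_bracketed_tree("(S (NP (NN Glu67) (NN pocket)) (VP (VBZ sits)))")
  expect_equal(method1_filter(t25, m, d), "drop")            # s_x = 0.25 exactly
  tneg <- read_bracketed_tree("(S (NN Glu67) (NN phosphorylation))")
  expect_equal(method1_filter(tneg, m, d), "drop")
  expect_warning(v <- method1_filter(NULL, m, d), "no parse tree")
  expect_equal(v, "keep")
  expect_equal(method1_filter(NULL, m, d, strict = TRUE), "drop")
})

test_that("context spotting and Method 2 conjunction behave as specified", {
  d <- default_dictionary()
  rec <- abstract_record("a1", "OR", "c1", paste(
    "The docking study was careful.",
    "Glu67 and the hydrophobic pocket matter.",
    "Nothing else was seen."))
  expect_true(context_spot(rec, 1, d))     # "docking" precedes
  plainctx <- abstract_record("a4", "OR", "c1", paste(
    "The study was careful.", "Glu67 was measured.",
    "Nothing else was seen."))
  expect_false(context_spot(plainctx, 1, d))  # neighbors keyword-free
  solo <- abstract_record("a2", "OR", "c1", "Glu67 binds the pocket.")
  expect_false(context_spot(solo, 0, d))   # no neighbors at all

  m <- rec$sentences[[2]]$mentions[[1]]
  tr <- read_bracketed_tree(
    "(S (NP (NN Glu67) (CC and) (DT the) (JJ hydrophobic) (NN pocket)) (VP (VBZ matter)) (. .))")
  expect_equal(method2_filter(rec, 1, tr, m, d), "keep")
  # same sentence, no context keyword -> drop despite high s_x
  rec2 <- abstract_record("a3", "OR", "c1", paste(
    "The study was careful.",
    "Glu67 and the hydrophobic pocket matter.",
    "Nothing else was seen."))
  expect_equal(method2_filter(rec2, 1, tr, rec2$sentences[[2]]$mentions[[1]], d),
               "drop")
  # low s_x with context keyword -> drop
  tr_low <- read_bracketed_tree("(S (NN Glu67) (NN stuff))")
  expect_equal(method2_filter(rec, 1, tr_low, m, d), "drop")
  # conjunction: method2 keep-set is a subset of method1's
  expect_true(method2_filter(rec, 1, tr, m, d) == "drop" ||
                method1_filter(tr, m, d) == "keep")
})

test_that("the root-anchored context score sums inverse depths", {
  d <- default_dictionary()
  t1 <- read_bracketed_tree("(S (NP (NN (XX pocket))))")
  expect_equal(context_root_score(t1, d), 1 / 4)
  t2 <- read_bracketed_tree("(S (NN pocket) (NN phosphorylation))")
  expect_equal(context_root_score(t2, d), 1 / 2 - 1 / 2)
  expect_equal(context_root_score(read_bracketed_tree("(S (NN core))"), d), 0)
  expect_equal(context_root_score(NULL, d), 0)
  # oracle on random trees: depth enumeration
  set.seed(31)
  vocab <- c("pocket", "binding", "phosphorylation", "core", "the", "IgG1")
  for (rep in 1:20) {
    leaves <- sample(vocab, sample(3:10, 1), replace = TRUE)
    tr <- read_bracketed_tree(random_tree_string(leaves))
    manual <- 0
    for (j in seq_along(tr$leaves)) {
      dep <- tr$depth[tr$leaf_nodes[j]]
      if (nrow(spot_keywords(tr$leaves[j], d$ppi_positive))) manual <- manual + 1 / dep
      if (nrow(spot_keywords(tr$leaves[j], d$ppi_negative))) manual <- manual - 1 / dep
    }
    expect_equal(context_root_score(tr, d), manual, tolerance = 1e-12)
  }
})
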