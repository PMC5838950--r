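# Shared fixtures and independent oracles used across test files.

# --- random parse trees ---------------------------------------------------

# Build a random rooted ordered tree over the given leaf tokens by
# recursive partitioning; returns a bracketed string.
random_tree_string <- function(leaves, max_arity = 4) {
  build <- function(lv) {
    if (length(lv) == 1L)
      return(sprintf("(X %s)", lv))
    k <- sample(2:min(max_arity, length(lv)), 1)
    cuts <- sort(sample(seq_len(length(lv) - 1L), k - 1L))
    parts <- split(lv, cumsum(seq_along(lv) %in% (cuts + 1L)))
    paste0("(N", paste0(" ", vapply(parts, build, character(1)), collapse = ""), ")")
  }
  build(leaves)
}

# --- BFS distance oracle --------------------------------------------------

# Edge-count distance between two nodes by breadth-first search on the
# undirected parent/child graph; independent of the depth/LCA route.
bfs_leaf_distance <- function(tree, leaf_a, leaf_b) {
  n <- length(tree$parent)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p != 0L) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  src <- tree$leaf_nodes[leaf_a]; dst <- tree$leaf_nodes[leaf_b]
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == dst) return(dist[v])
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  stop("disconnected tree")
}

# All leaf distances from one source leaf, by a single BFS sweep.
bfs_distances_from <- function(tree, leaf_a) {
  n <- length(tree$parent)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p != 0L) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  src <- tree$leaf_nodes[leaf_a]
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist[tree$leaf_nodes]
}

# Brute-force residue score: enumerate every leaf, classify it against the
# dictionary by the lemma-matching rule, and sum inverse BFS distances.
brute_force_sx <- function(tree, res_leaf, dict) {
  s <- 0
  for (j in seq_along(tree$leaves)) {
    if (j == res_leaf) next
    tok <- tree$leaves[j]
    if (!is.null(tmdock:::match_mention_token(tok, one_letter = TRUE))) next
    is_pos <- nrow(spot_keywords(tok, dict$ppi_positive)) > 0
    is_neg <- nrow(spot_keywords(tok, dict$ppi_negative)) > 0
    if (!is_pos && !is_neg) next
    d <- bfs_leaf_distance(tree, res_leaf, j)
    if (is_pos) s <- s + 1 / d
    if (is_neg) s <- s - 1 / d
  }
  s
}

# --- dense-sampling SASA oracle -------------------------------------------

# Numeric SASA by dense random sphere sampling (independent point set and
# accounting from the Shrake-Rupley implementation under test).
brute_force_sasa <- function(model, probe = 1.4, n_points = 4000, seed = 99) {
  a <- model$atoms
  r <- tmdock:::VDW_RADII[a$element]
  r[is.na(r)] <- tmdock:::VDW_DEFAULT
  R <- unname(r) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  set.seed(seed)
  pts <- matrix(rnorm(3 * n_points), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      acc <- acc & (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  out
}

# --- tiny structure fixtures ----------------------------------------------

toy_pdb_text <- function() {
  paste(c(
    "HEADER    TOY",
    "ATOM      1  N   GLU B  67      10.000  10.000  10.000  1.00 10.00           N",
    "ATOM      2  CA  GLU B  67      11.000  10.000  10.000  1.00 10.00           C",
    "ATOM      3  CA AALA A   5       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   5       0.200   0.000   0.000  0.60 10.00           C",
    "ATOM      5  CA  GLY A   6       3.800   0.000   0.000  1.00 10.00           C",
    "TER",
    "END"), collapse = "\n")
}

# small labeled feature set with planted separation, for classifier tests
toy_feature_set <- function(n = 60, seed = 5) {
  set.seed(seed)
  pos <- cbind(rnorm(n, 0.5, 0.1), rnorm(n, 0.3, 0.1), rnorm(n, 0.3, 0.1),
               2, 1, 1)
  neg <- cbind(rnorm(n, -0.3, 0.1), rnorm(n, -0.2, 0.1), rnorm(n, -0.2, 0.1),
               0, 0, 0)
  list(x = rbind(pos, neg), y = rep(c(TRUE, FALSE), each = n))
}
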