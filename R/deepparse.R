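# Constituency parse trees, edge-count distances, the inverse-distance
# residue score and the rule-based context filters (Methods 1 and 2).

#' Read a bracketed (S-expression) parse tree
#'
#' Accepts Penn-Treebank-style bracketing, e.g.
#' `"(S (NP (NN Glu67)) (VP (VBZ binds)))"`. Leaves are the sentence
#' tokens in order.
#'
#' @param s Character scalar.
#' @return Object of class `parse_tree`: a flat node table with `label`,
#'   `parent` (0 for the root), `is_leaf`, `depth`, plus `leaves` (token
#'   strings) and `leaf_nodes` (node ids of the leaves in token order).
#' @export
read_bracketed_tree <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  if (!length(toks)) stop("empty parse-tree expression")
  label <- character(0); parent <- integer(0); is_leaf <- logical(0)
  stack <- integer(0)
  expecting_label <- FALSE
  for (k in seq_along(toks)) {
    t <- toks[k]
    if (t == "(") {
      label <- c(label, NA_character_)
      parent <- c(parent, if (length(stack)) stack[length(stack)] else 0L)
      is_leaf <- c(is_leaf, FALSE)
      stack <- c(stack, length(label))
      expecting_label <- TRUE
    } else if (t == ")") {
      if (!length(stack)) stop("unbalanced parse-tree expression at token ", k)
      stack <- stack[-length(stack)]
      expecting_label <- FALSE
    } else {
      if (!length(stack)) stop("token outside brackets at position ", k)
      if (expecting_label) {
        label[stack[length(stack)]] <- t
        expecting_label <- FALSE
      } else {
        label <- c(label, t)
        parent <- c(parent, stack[length(stack)])
        is_leaf <- c(is_leaf, TRUE)
      }
    }
  }
  if (length(stack)) stop("unbalanced parse-tree expression: ",
                          length(stack), " unclosed bracket(s)")
  if (sum(parent == 0L) != 1L) stop("parse tree must have a single root")
  # constituents with no children at all are leaves written as (X): reject
  depth <- integer(length(parent))
  for (i in seq_along(parent))
    depth[i] <- if (parent[i] == 0L) 0L else depth[parent[i]] + 1L
  leaf_nodes <- which(is_leaf)
  if (!length(leaf_nodes)) stop("parse tree has no leaves")
  structure(list(label = label, parent = parent, is_leaf = is_leaf,
                 depth = depth, leaves = label[leaf_nodes],
                 leaf_nodes = leaf_nodes),
            class = "parse_tree")
}

#' @export
print.parse_tree <- function(x, ...) {
  cat(sprintf("<parse tree: %d nodes, %d leaves: %s>\n", length(x$label),
              length(x$leaves), paste(x$leaves, collapse = " ")))
  invisible(x)
}

#' Serialize a parse tree back to bracketed form
#' @param tree A `parse_tree`.
#' @export
write_bracketed_tree <- function(tree) {
  children <- split(seq_along(tree$parent), tree$parent)
  rec <- function(i) {
    if (tree$is_leaf[i]) return(tree$label[i])
    kids <- children[[as.character(i)]]
    paste0("(", tree$label[i],
           paste0(" ", vapply(kids, rec, character(1)), collapse = ""), ")")
  }
  rec(which(tree$parent == 0L))
}

ancestors <- function(tree, node) {
  out <- node
  while (tree$parent[node] != 0L) {
    node <- tree$parent[node]
    out <- c(out, node)
  }
  out
}

#' Edge-count distance between two leaves of a parse tree
#'
#' The number of edges on the unique path between the leaves:
#' `depth(a) + depth(b) - 2 * depth(lca)`. Distinct leaves are at distance
#' >= 2 (they share at most a parent).
#'
#' @param tree A `parse_tree`.
#' @param leaf_a,leaf_b Leaf positions (1-based token indices).
#' @return Non-negative integer.
#' @export
tree_distance <- function(tree, leaf_a, leaf_b) {
  nl <- length(tree$leaf_nodes)
  if (leaf_a < 1L || leaf_a > nl || leaf_b < 1L || leaf_b > nl)
    stop("leaf index out of range")
  a <- tree$leaf_nodes[leaf_a]; b <- tree$leaf_nodes[leaf_b]
  if (a == b) return(0L)
  ca <- ancestors(tree, a)
  cb <- ancestors(tree, b)
  lca <- intersect(ca, cb)[1]
  (tree$depth[a] - tree$depth[lca]) + (tree$depth[b] - tree$depth[lca])
}

keyword_leaf_positions <- function(tree, lemmas, exclude = integer(0)) {
  hits <- spot_keywords(tree$leaves, lemmas)
  setdiff(unique(hits$token_index), exclude)
}

# leaves that are themselves residue mentions never count as keywords
mention_leaf_positions <- function(tree) {
  which(vapply(tree$leaves, function(t)
    !is.null(match_mention_token(t, one_letter = TRUE)), logical(1)))
}

#' Parse-tree proximity score of a residue mention
#'
#' The score of residue X in a sentence is the sum of inverse edge-count
#' distances to every occurrence of a positive (binding-site-relevant)
#' keyword leaf minus the same sum over negative keyword leaves:
#' `S_X = sum_i 1/d+_Xi - sum_j 1/d-_Xj`. Each occurrence of a lemma
#' contributes its own term; leaves that are themselves residue mentions
#' are never counted as keywords. A high positive score places the residue
#' grammatically close to binding-site vocabulary.
#'
#' @param tree A `parse_tree` whose leaves are the sentence tokens.
#' @param mention A [residue_mention()] (its `token_index` names the head
#'   leaf), or a bare leaf index.
#' @param dict A [keyword_dictionary()].
#' @return Object of class `residue_score`: list with `s_x`,
#'   `positive_terms` and `negative_terms` (data.frames lemma/leaf/distance).
#' @export
score_residue <- function(tree, mention, dict = default_dictionary()) {
  leaf <- if (inherits(mention, "residue_mention")) mention$token_index else mention
  if (is.na(leaf) || leaf < 1L || leaf > length(tree$leaf_nodes))
    stop("mention head token is not a leaf of the tree")
  excl <- union(mention_leaf_positions(tree), leaf)
  term_table <- function(lemmas) {
    pos <- keyword_leaf_positions(tree, lemmas, exclude = excl)
    if (!length(pos))
      return(data.frame(lemma = character(0), leaf = integer(0),
                        distance = integer(0)))
    hits <- spot_keywords(tree$leaves, lemmas)
    hits <- hits[hits$token_index %in% pos, , drop = FALSE]
    hits <- hits[!duplicated(hits$token_index), , drop = FALSE]  # one term per leaf
    data.frame(lemma = hits$lemma, leaf = hits$token_index,
               distance = vapply(hits$token_index, function(p)
                 tree_distance(tree, leaf, p), integer(1)))
  }
  pt <- term_table(dict$ppi_positive)
  nt <- term_table(dict$ppi_negative)
  s_x <- sum(1 / pt$distance) - sum(1 / nt$distance)
  structure(list(s_x = s_x, positive_terms = pt, negative_terms = nt),
            class = "residue_score")
}

#' @export
print.residue_score <- function(x, ...) {
  cat(sprintf("<residue score S_X = %.4f (%d positive, %d negative terms)>\n",
              x$s_x, nrow(x$positive_terms), nrow(x$negative_terms)))
  invisible(x)
}

#' Method 1: threshold the residue score of the residue-containing sentence
#'
#' A mention is kept iff its parse-tree score strictly exceeds the
#' threshold (default 0.25, the value separating interface from
#' non-interface residues).
#'
#' @param tree `parse_tree` for the sentence, or `NULL` if the parser
#'   failed on it.
#' @param mention A [residue_mention()].
#' @param dict A [keyword_dictionary()].
#' @param threshold The score threshold.
#' @param strict If the tree is missing: `FALSE` (default) lets the
#'   mention pass through with a warning (the filter abstains), `TRUE`
#'   drops it.
#' @return `"keep"` or `"drop"`.
#' @export
method1_filter <- function(tree, mention, dict = default_dictionary(),
                           threshold = 0.25, strict = FALSE) {
  if (is.null(tree)) {
    if (strict) return("drop")
    warning("no parse tree for sentence; mention passes through unfiltered")
    return("keep")
  }
  if (score_residue(tree, mention, dict)$s_x > threshold) "keep" else "drop"
}

#' Spot positive keywords in the context sentences
#'
#' Context sentences are the sentences immediately preceding and following
#' the residue-containing sentence; a missing neighbor contributes
#' nothing.
#'
#' @param abstract An [abstract_record()].
#' @param sentence_index 0-based index of the residue-containing sentence.
#' @param dict A [keyword_dictionary()].
#' @return Logical: was a positive lemma spotted in either neighbor?
#' @export
context_spot <- function(abstract, sentence_index, dict = default_dictionary()) {
  idx <- sentence_index + 1L  # list position
  for (j in c(idx - 1L, idx + 1L)) {
    if (j < 1L || j > length(abstract$sentences) || j == idx) next
    if (nrow(spot_keywords(abstract$sentences[[j]], dict$ppi_positive)) > 0L)
      return(TRUE)
  }
  FALSE
}

#' Method 2: residue score plus keyword spotting in the context
#'
#' A mention is kept iff Method 1 keeps it and a positive keyword is
#' spotted in a context sentence.
#'
#' @inheritParams method1_filter
#' @inheritParams context_spot
#' @return `"keep"` or `"drop"`.
#' @export
method2_filter <- function(abstract, sentence_index, tree, mention,
                           dict = default_dictionary(), threshold = 0.25,
                           strict = FALSE) {
  m1 <- method1_filter(tree, mention, dict, threshold, strict)
  if (m1 == "keep" && context_spot(abstract, sentence_index, dict)) "keep" else "drop"
}

#' Root-anchored keyword score of a context sentence
#'
#' The analogue of the residue score for sentences that contain no
#' residue: the sum of inverse edge-count distances between the sentence
#' root and each positive keyword leaf, minus the same sum over negative
#' keyword leaves. The root-to-leaf distance is the leaf depth.
#'
#' @param tree A `parse_tree`, or `NULL` (score 0).
#' @param dict A [keyword_dictionary()].
#' @return Numeric score.
#' @export
context_root_score <- function(tree, dict = default_dictionary()) {
  if (is.null(tree)) return(0)
  excl <- mention_leaf_positions(tree)
  s <- function(lemmas) {
    pos <- keyword_leaf_positions(tree, lemmas, exclude = excl)
    if (!length(pos)) return(0)
    d <- tree$depth[tree$leaf_nodes[pos]]
    sum(1 / d[d > 0])
  }
  s(dict$ppi_positive) - s(dict$ppi_negative)
}
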