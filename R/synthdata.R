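# Seeded generators of labeled corpora, parse trees, toy structures and
# pose sets. All generators are pure functions of (recipe, seed).

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Recipe for a synthetic labeled corpus
#'
#' The generator emulates the statistical structure the context filters
#' exploit: interface residues sit grammatically close to
#' binding-site-relevant keywords, non-interface residues close to
#' irrelevant keywords; context sentences and protein-name mentions carry
#' corroborating signal for interface residues. It does not emulate
#' realistic English prose or retrieval statistics.
#'
#' @param n_complexes Number of protein-protein complexes.
#' @param abstracts_per_complex Abstracts retrieved per complex.
#' @param interface_mention_rate Probability a planted mention is a true
#'   interface residue.
#' @param p_keyword_near_interface Probability an interface mention's
#'   sentence places positive keywords grammatically close to it.
#' @param p_negword_near_noninterface Probability a non-interface
#'   mention's sentence places negative keywords close to it (otherwise
#'   the sentence misleadingly contains positive keywords).
#' @param p_and_query Probability an abstract was retrieved by the
#'   AND-query.
#' @param p_names_interface,p_names_noninterface Probability the
#'   residue-containing sentence names both interacting proteins, for
#'   interface / non-interface mentions.
#' @param p_context_keyword_interface,p_context_keyword_noninterface
#'   Probability a context sentence carries a positive keyword.
#' @param seed Integer seed.
#' @return List of class `corpus_recipe`.
#' @export
corpus_recipe <- function(n_complexes = 200, abstracts_per_complex = 3,
                          interface_mention_rate = 0.5,
                          p_keyword_near_interface = 0.9,
                          p_negword_near_noninterface = 0.9,
                          p_and_query = 0.3,
                          p_names_interface = 0.8,
                          p_names_noninterface = 0.2,
                          p_context_keyword_interface = 0.8,
                          p_context_keyword_noninterface = 0.15,
                          seed = 1) {
  r <- as.list(environment())
  probs <- unlist(r[grepl("^p_|rate$", names(r))])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  stopifnot(n_complexes >= 1, abstracts_per_complex >= 1)
  structure(r, class = "corpus_recipe")
}

# Surface forms realizing dictionary lemmas; chosen so no filler word
# matches any lemma of the packaged dictionary.
POS_VERBS <- c("binds", "contacts", "docks", "interacts", "recognizes")
POS_NOUNS <- c("interface", "pocket", "groove", "receptor", "contact")
POS_ADJS  <- c("hydrophobic", "interfacial", "binding")
NEG_NOUNS <- c("phosphorylation", "dissociation", "glycosylation",
               "nucleotide", "epitope", "ubiquitin")
NEG_ADJS  <- c("allosteric", "polar")
PLAIN_VERBS <- c("stabilizes", "maintains", "supports", "alters")
PLAIN_NOUNS <- c("stability", "fold", "core", "structure", "region")
PLAIN_ADJS  <- c("buried", "conserved", "thermal", "structural")

# Sentence skeletons. Each returns a bracketed tree whose leaves are the
# sentence tokens; RES is the residue token, k* keyword surface forms,
# n1/n2 protein names (may be NULL). The strong skeletons keep two or
# three positive keywords within tree distance 4-6 of the residue, the
# negative skeletons do the same with negative keywords, the plain
# skeletons contain no dictionary words at all.
skeleton_strong <- list(
  function(res, kv, kn, ka, n1, n2)
    sprintf("(S (NP (NN %s) (CC and) (DT the) (JJ %s) (NN %s)) (VP (VBZ %s)%s) (. .))",
            res, ka, kn, kv,
            if (is.null(n2)) " (NP (DT the) (NN partner))"
            else sprintf(" (NP (NNP %s))", n2)),
  function(res, kv, kn, ka, n1, n2)
    sprintf("(S (NP (DT The) (NN %s) (NN %s)) (VP (VBZ %s) (NP (DT the) (JJ %s) (NN surface))) (. .))",
            kn, res, kv, ka),
  function(res, kv, kn, ka, n1, n2)
    sprintf("(S%s (VP (VBZ %s) (NP (NN %s) (IN at) (DT the) (JJ %s) (NN %s))) (. .))",
            if (is.null(n1)) " (NP (DT The) (NN protein))"
            else sprintf(" (NP (NNP %s))", n1),
            kv, res, ka, kn),
  function(res, kv, kn, ka, n1, n2)
    sprintf("(S (NP (NN %s) (DT the) (NN %s) (NN residue)) (VP (VBZ forms) (NP (DT a) (NN %s))) (. .))",
            res, kn, sample(POS_NOUNS, 1)))

skeleton_negative <- list(
  function(res, kn, ka, n1, n2)
    sprintf("(S (NP (NN %s) (CC and) (DT the) (JJ %s) (NN %s)) (VP (VBZ undergoes) (NP (NN modification))) (. .))",
            res, ka, kn),
  function(res, kn, ka, n1, n2)
    sprintf("(S (NP (DT The) (NN %s) (NN %s)) (VP (VBZ shows) (NP (DT a) (JJ %s) (NN effect))) (. .))",
            kn, res, ka),
  function(res, kn, ka, n1, n2)
    sprintf("(S (NP (NN %s) (NN %s) (NN site)) (VP (VBZ regulates) (NP (DT the) (NN enzyme))) (. .))",
            res, kn),
  function(res, kn, ka, n1, n2)
    sprintf("(S (NP (DT The) (NN residue) (NN %s)) (VP (VBZ controls) (NP (DT the) (NN %s) (NN state))) (. .))",
            res, kn))

skeleton_plain <- list(
  function(res, v, nn, jj, n1, n2)
    sprintf("(S (NP (NN %s) (CC and) (DT the) (JJ %s) (NN %s)) (VP (VBZ %s) (NP (DT the) (NN protein))) (. .))",
            res, jj, nn, v),
  function(res, v, nn, jj, n1, n2)
    sprintf("(S (NP (DT The) (NN %s) (NN %s)) (VP (VBZ %s) (NP (DT the) (JJ %s) (NN fold))) (. .))",
            nn, res, v, jj),
  function(res, v, nn, jj, n1, n2)
    sprintf("(S (NP (DT The) (JJ %s) (NN residue) (NN %s)) (VP (VBZ %s) (NP (DT the) (NN %s))) (. .))",
            jj, res, v, nn),
  function(res, v, nn, jj, n1, n2)
    sprintf("(S (NP (NN %s)) (VP (VBZ remains) (ADJP (JJ %s)) (PP (IN in) (NP (DT the) (NN %s)))) (. .))",
            res, jj, nn))

context_with_keyword <- function(kn, n1, n2) {
  tpl <- sample(2, 1)
  if (tpl == 1 && !is.null(n1))
    sprintf("(S (NP (NNP %s) (CC and) (NNP %s)) (VP (VBP form) (NP (DT a) (NN %s))) (. .))",
            n1, n2, kn)
  else
    sprintf("(S (NP (DT The) (NN %s)) (VP (VBZ matters) (PP (IN for) (NP (DT the) (NN assembly)))) (. .))",
            kn)
}

context_plain <- function(kind = c("neutral", "negative")) {
  kind <- match.arg(kind)
  if (kind == "negative")
    sprintf("(S (NP (DT The) (NN %s)) (VP (VBZ occurs) (PP (IN in) (NP (DT the) (NN cytoplasm)))) (. .))",
            sample(NEG_NOUNS, 1))
  else
    sprintf("(S (NP (DT The) (NN %s)) (VP (VBZ appears) (ADJP (JJ %s))) (. .))",
            sample(PLAIN_NOUNS, 1), sample(PLAIN_ADJS, 1))
}

make_protein_name <- function() {
  repeat {
    nm <- paste0(sample(LETTERS, 1), paste(sample(letters, 3), collapse = ""))
    bad <- vapply(c("bind", "interfac", "complex", "hydrophob", "recept",
                    "ligand", "contact", "recog", "dock", "groove", "pocket",
                    "pouch", "interact", "crystal", "latch", "catal"),
                  function(l) startsWith(tolower(nm), l), logical(1))
    if (!any(bad)) return(nm)
  }
}

residue_token <- function(resname, resno) {
  paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)), resno)
}

#' Generate a labeled synthetic corpus
#'
#' Builds abstracts from a fixed template grammar and emits the bracketed
#' parse of every sentence alongside, so the pipeline's parser-dependent
#' stages run deterministically. Each abstract has a context sentence, one
#' residue-containing sentence per planted mention, and a closing context
#' sentence. The gold per-mention interface label is returned.
#'
#' @param recipe A [corpus_recipe()].
#' @return List with `abstracts` (list of [abstract_record()]), `trees`
#'   (per abstract, list of `parse_tree` aligned with sentences), `gold`
#'   (data.frame: complex_id, abstract_id, query_type, sentence_index,
#'   residue_name, residue_number, token_index, interface),
#'   `protein_names` (per complex), and the `recipe`.
#' @export
generate_corpus <- function(recipe = corpus_recipe()) {
  stopifnot(inherits(recipe, "corpus_recipe"))
  local_seed(recipe$seed, {
    abstracts <- list(); trees <- list(); gold_rows <- list()
    protein_names <- list()
    for (cx in seq_len(recipe$n_complexes)) {
      complex_id <- sprintf("CPX%04d", cx)
      nms <- c(make_protein_name(), make_protein_name())
      protein_names[[complex_id]] <- nms
      resno_pool <- sample(10:400, recipe$abstracts_per_complex * 2)
      for (ab in seq_len(recipe$abstracts_per_complex)) {
        abstract_id <- sprintf("%s-A%02d", complex_id, ab)
        qt <- if (stats::runif(1) < recipe$p_and_query) "AND" else "OR"
        is_int <- stats::runif(1) < recipe$interface_mention_rate
        resname <- sample(names(AMINO1), 1)
        resname <- unname(AMINO1[resname])
        resno <- resno_pool[ab]
        res_tok <- residue_token(resname, resno)
        p_names <- if (is_int) recipe$p_names_interface else recipe$p_names_noninterface
        with_names <- stats::runif(1) < p_names
        n1 <- if (with_names) nms[1] else NULL
        n2 <- if (with_names) nms[2] else NULL
        res_tree_s <- if (is_int) {
          if (stats::runif(1) < recipe$p_keyword_near_interface)
            sample(skeleton_strong, 1)[[1]](res_tok, sample(POS_VERBS, 1),
                                            sample(POS_NOUNS, 1),
                                            sample(POS_ADJS, 1), n1, n2)
          else
            sample(skeleton_plain, 1)[[1]](res_tok, sample(PLAIN_VERBS, 1),
                                           sample(PLAIN_NOUNS, 1),
                                           sample(PLAIN_ADJS, 1), n1, n2)
        } else {
          if (stats::runif(1) < recipe$p_negword_near_noninterface)
            sample(skeleton_negative, 1)[[1]](res_tok, sample(NEG_NOUNS, 1),
                                              sample(NEG_ADJS, 1), n1, n2)
          else  # misleading: positive keywords near a non-interface residue
            sample(skeleton_strong, 1)[[1]](res_tok, sample(POS_VERBS, 1),
                                            sample(POS_NOUNS, 1),
                                            sample(POS_ADJS, 1), n1, n2)
        }
        p_ctx <- if (is_int) recipe$p_context_keyword_interface
        else recipe$p_context_keyword_noninterface
        ctx_of <- function() {
          if (stats::runif(1) < p_ctx)
            context_with_keyword(sample(POS_NOUNS, 1),
                                 if (with_names) nms[1] else NULL, nms[2])
          else if (!is_int && stats::runif(1) < 0.5)
            context_plain("negative")
          else context_plain("neutral")
        }
        tree_strings <- c(ctx_of(), res_tree_s, ctx_of())
        ptrees <- lapply(tree_strings, read_bracketed_tree)
        sent_texts <- vapply(ptrees, function(t)
          paste(t$leaves, collapse = " "), character(1))
        rec <- abstract_record(abstract_id, qt, complex_id,
                               paste(sent_texts, collapse = " "))
        stopifnot(length(rec$sentences) == length(ptrees))
        abstracts[[abstract_id]] <- rec
        trees[[abstract_id]] <- ptrees
        tok_idx <- match(res_tok, ptrees[[2]]$leaves)
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          complex_id = complex_id, abstract_id = abstract_id,
          query_type = qt, sentence_index = 1L,
          residue_name = resname, residue_number = resno,
          token_index = tok_idx, interface = is_int,
          stringsAsFactors = FALSE)
      }
    }
    list(abstracts = abstracts, trees = trees,
         gold = do.call(rbind, gold_rows),
         protein_names = protein_names, recipe = recipe)
  })
}

#' Write the bracketed-tree sidecar file
#'
#' One line per sentence: `abstract_id<TAB>sentence_index<TAB>s-expression`.
#'
#' @param trees Per-abstract list of `parse_tree` (as from
#'   [generate_corpus()]).
#' @param path Output path.
#' @export
write_tree_sidecar <- function(trees, path) {
  lines <- unlist(lapply(names(trees), function(id)
    vapply(seq_along(trees[[id]]), function(j)
      paste(id, j - 1L, write_bracketed_tree(trees[[id]][[j]]), sep = "\t"),
      character(1))), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tree_sidecar
#' @param lines Path or character vector of sidecar lines.
#' @return `read_tree_sidecar`: named list (abstract id) of lists of
#'   `parse_tree` in sentence order.
#' @export
read_tree_sidecar <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  out <- list()
  for (id in unique(ids)) {
    sel <- parts[ids == id]
    ord <- order(as.integer(vapply(sel, `[[`, "", 2L)))
    out[[id]] <- lapply(sel[ord], function(p) read_bracketed_tree(p[[3L]]))
  }
  out
}

# ---- toy structures ------------------------------------------------------

toy_chain <- function(chain, n_res, origin_y, resnames, flip_cb = FALSE) {
  rows <- list()
  for (i in seq_len(n_res)) {
    x <- 3.8 * i
    cb_y <- origin_y + if (flip_cb) -1.5 else 1.5
    rows[[i]] <- data.frame(
      chain = chain, resno = i, insert = "", resid = resnames[i],
      elety = c("CA", "CB"), element = "C",
      x = x, y = c(origin_y, cb_y), z = 0, o = 1,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  first <- !duplicated(paste(atoms$chain, atoms$resno))
  structure(list(atoms = atoms,
                 residues = atoms[first, c("chain", "resno", "insert", "resid")]),
            class = "structure_model")
}

#' Generate a toy bound complex with perturbed unbound monomers
#'
#' Builds C-alpha-plus-pseudo-side-chain chains: the receptor lies along
#' the x axis, and the first `n_contacts` ligand residues sit 5.5 A
#' across from their receptor counterparts (inside the 6 A interface
#' cutoff) while the rest of the ligand is far from the receptor, so the
#' bound complex has exactly `n_contacts` residue pairs in contact. The
#' unbound forms are the monomers with seeded isotropic Gaussian
#' coordinate noise, new chain identifiers and residue-numbering offsets.
#'
#' @param n_res_receptor,n_res_ligand Residue counts (>= 3).
#' @param n_contacts Number of interface residue pairs
#'   (`3 <= n_contacts <= min(n_res_receptor, n_res_ligand)`).
#' @param seed Integer seed.
#' @param noise_sd Unbound coordinate noise, A per coordinate.
#' @param offset_receptor,offset_ligand Residue-numbering offsets of the
#'   unbound forms.
#' @return List with `bound_receptor`, `bound_ligand`, `unbound_receptor`,
#'   `unbound_ligand` (`structure_model`s), `contacts` (data.frame of the
#'   planted pairs) and the parameters.
#' @export
generate_toy_complex <- function(n_res_receptor = 20, n_res_ligand = 10,
                                 n_contacts = 4, seed = 1, noise_sd = 0.5,
                                 offset_receptor = 5, offset_ligand = 10) {
  stopifnot(n_res_receptor >= 3, n_res_ligand >= 3, n_contacts >= 1)
  if (n_contacts > min(n_res_receptor, n_res_ligand))
    stop("infeasible geometry: more contacts than residues")
  local_seed(seed, {
    rn_rec <- sample(AMINO3, n_res_receptor, replace = TRUE)
    rn_lig <- sample(AMINO3, n_res_ligand, replace = TRUE)
    rec <- toy_chain("A", n_res_receptor, 0, rn_rec, flip_cb = TRUE)
    lig <- toy_chain("B", n_res_ligand, 5.5, rn_lig, flip_cb = FALSE)
    far <- lig$atoms$resno > n_contacts
    lig$atoms$y[far] <- lig$atoms$y[far] + 20
    perturb <- function(model, chain, offset) {
      m <- model
      m$atoms$chain <- chain
      m$atoms$resno <- m$atoms$resno + offset
      n <- nrow(m$atoms)
      m$atoms$x <- m$atoms$x + stats::rnorm(n, 0, noise_sd)
      m$atoms$y <- m$atoms$y + stats::rnorm(n, 0, noise_sd)
      m$atoms$z <- m$atoms$z + stats::rnorm(n, 0, noise_sd)
      first <- !duplicated(paste(m$atoms$chain, m$atoms$resno))
      m$residues <- m$atoms[first, c("chain", "resno", "insert", "resid")]
      rownames(m$residues) <- NULL
      m
    }
    contacts <- data.frame(receptor_resno = seq_len(n_contacts),
                           ligand_resno = seq_len(n_contacts),
                           distance = 5.5)
    list(bound_receptor = rec, bound_ligand = lig,
         unbound_receptor = perturb(rec, "C", offset_receptor),
         unbound_ligand = perturb(lig, "D", offset_ligand),
         contacts = contacts, seed = seed, noise_sd = noise_sd,
         offset_receptor = offset_receptor, offset_ligand = offset_ligand)
  })
}

random_rotation <- function() {
  # uniform random rotation from QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

small_rotation <- function(max_angle) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

#' Generate a synthetic docking pose set
#'
#' A desk-scale stand-in for a global rigid-body docking scan: a fraction
#' of poses are small rigid perturbations of the native placement of the
#' unbound ligand (obtained by superposition onto the bound ligand), the
#' rest are random rigid transforms scattering the ligand around the
#' receptor. Raw scores are uninformative draws, emulating a
#' low-resolution scan in which the near-native poses are present but not
#' top-ranked. The generator records each pose's ligand interface
#' C-alpha RMSD computed directly from the transformed coordinates.
#'
#' @param complex From [generate_toy_complex()].
#' @param n_poses Number of poses (>= 1).
#' @param fraction_near_native Fraction of near-native poses.
#' @param rmsd_spread Translation scale (A) of the near-native
#'   perturbations.
#' @param seed Integer seed.
#' @return List with `poses` (list of [dock_pose()] in raw-score rank
#'   order), `gold_irmsd` (aligned numeric vector) and `near_native`
#'   (aligned logical).
#' @export
generate_pose_set <- function(complex, n_poses = 500,
                              fraction_near_native = 0.02,
                              rmsd_spread = 1.5, seed = 1) {
  stopifnot(n_poses >= 1)
  local_seed(seed, {
    map <- map_unbound_to_bound(complex$unbound_ligand, complex$bound_ligand)
    ref <- irmsd_reference(complex$bound_receptor, complex$bound_ligand,
                           complex$unbound_ligand, residue_map = map)
    native_R <- ref$superposition$rotation
    native_t <- ref$superposition$translation
    rec_center <- colMeans(as.matrix(complex$bound_receptor$atoms[, c("x", "y", "z")]))
    lig_center_native <- colMeans(sweep(as.matrix(
      complex$unbound_ligand$atoms[, c("x", "y", "z")]) %*% t(native_R),
      2, native_t, `+`))
    n_near <- round(n_poses * fraction_near_native)
    is_near <- c(rep(TRUE, n_near), rep(FALSE, n_poses - n_near))
    poses <- vector("list", n_poses)
    for (i in seq_len(n_poses)) {
      if (is_near[i]) {
        # perturb about the native ligand centroid
        P <- small_rotation(max_angle = 0.08)
        shift <- stats::rnorm(3, 0, rmsd_spread / sqrt(3))
        R <- P %*% native_R
        t <- as.numeric(P %*% (native_t - lig_center_native)) +
          lig_center_native + shift
      } else {
        R <- random_rotation() %*% native_R
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        target <- rec_center + dir * stats::runif(1, 15, 45)
        # place the transformed ligand centroid at `target`
        t <- target - colMeans(as.matrix(
          complex$unbound_ligand$atoms[, c("x", "y", "z")]) %*% t(R))
      }
      poses[[i]] <- dock_pose(pose_id = sprintf("pose%04d", i),
                              rotation = R, translation = t,
                              raw_score = stats::rnorm(1), rank = NA)
    }
    gold <- vapply(poses, function(p) {
      docked <- sweep(ref$unbound_ca %*% t(p$rotation), 2, p$translation, `+`)
      sqrt(mean(rowSums((docked - ref$reference_ca)^2)))
    }, numeric(1))
    ord <- order(-vapply(poses, `[[`, numeric(1), "raw_score"))
    poses <- poses[ord]; gold <- gold[ord]; is_near <- is_near[ord]
    for (i in seq_along(poses)) poses[[i]]$rank <- i
    list(poses = poses, gold_irmsd = gold, near_native = is_near)
  })
}
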