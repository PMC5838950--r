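# Keyword dictionaries, lemma spotting and semantic-similarity filtering.

#' Construct a keyword dictionary
#'
#' A dictionary holds two disjoint lists of lemmas (stem words): lemmas
#' whose presence marks a sentence as relevant to the protein-protein
#' binding site (positive) and lemmas indicating information irrelevant to
#' the binding mode (negative: post-translational modifications,
#' immunoglobulin nomenclature, allostery, ...). All-lowercase lemmas are
#' stored lowercase; short or mixed-case forms (Fc, IgG1) keep their case
#' and are matched exactly.
#'
#' @param ppi_positive,ppi_negative Character vectors of lemmas.
#' @param name Dictionary label.
#' @return Object of class `keyword_dictionary`.
#' @export
keyword_dictionary <- function(ppi_positive, ppi_negative = character(0),
                               name = "user") {
  norm <- function(x) {
    x <- trimws(x)
    ifelse(x == tolower(x), tolower(x), x)
  }
  pos <- unique(norm(ppi_positive))
  neg <- unique(norm(ppi_negative))
  if (length(intersect(pos, neg)))
    stop("positive and negative lemma lists overlap: ",
         paste(intersect(pos, neg), collapse = ", "))
  structure(list(ppi_positive = pos, ppi_negative = neg, name = name),
            class = "keyword_dictionary")
}

#' @export
print.keyword_dictionary <- function(x, ...) {
  cat(sprintf("<keyword dictionary '%s': %d positive, %d negative lemmas>\n",
              x$name, length(x$ppi_positive), length(x$ppi_negative)))
  invisible(x)
}

#' Load a dictionary from a two-section file
#'
#' The file format has `[positive]` and `[negative]` section headers with
#' one lemma per line; `#` lines are comments. Third-party keyword lists
#' can be loaded in the same format (positive section only).
#'
#' @param path File path.
#' @param name Dictionary label; defaults to the file name.
#' @export
read_dictionary <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(lines %in% c("[positive]", "[negative]"))
  labels <- lines[lines %in% c("[positive]", "[negative]")]
  body <- split(lines[!lines %in% c("[positive]", "[negative]")],
                labels[sec[!lines %in% c("[positive]", "[negative]")]])
  keyword_dictionary(ppi_positive = body[["[positive]"]] %||% character(0),
                     ppi_negative = body[["[negative]"]] %||% character(0),
                     name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged binding-site keyword dictionary
#'
#' The in-house dictionary distinguishing lemmas relevant to protein
#' binding sites (16 positive stems: bind, interfac, complex, ...) from
#' lemmas that at most indicate the existence of an interaction or an
#' unrelated process (negative stems and short forms: phosphory, IgG1,
#' Fc, ...).
#'
#' @return A `keyword_dictionary`.
#' @export
default_dictionary <- function() {
  read_dictionary(system.file("extdata", "ppi_dictionary.txt",
                              package = "tmdock", mustWork = TRUE),
                  name = "in-house")
}

#' Spot dictionary lemmas in a tokenized sentence
#'
#' Matching rule: an all-lowercase lemma of length >= 4 matches
#' case-insensitively as a prefix anchored at the token start ("interfac"
#' matches "interface" and "interfacial", never "nonbinding" for "bind");
#' a lemma of length <= 3 or containing uppercase matches the whole token
#' case-sensitively (so "IgG1" matches only "IgG1"). Hyphenated lemmas
#' match hyphen-preserving tokens the same way.
#'
#' @param sentence Sentence object or character vector of tokens.
#' @param lemmas Character vector of lemmas.
#' @return data.frame with columns `token_index`, `token`, `lemma`, in
#'   token order (0 rows when nothing matches).
#' @export
spot_keywords <- function(sentence, lemmas) {
  toks <- if (is.character(sentence)) sentence else sentence$tokens
  out <- data.frame(token_index = integer(0), token = character(0),
                    lemma = character(0), stringsAsFactors = FALSE)
  if (!length(lemmas) || !length(toks)) return(out)
  for (i in seq_along(toks)) {
    for (lem in lemmas) {
      hit <- if (nchar(lem) >= 4L && lem == tolower(lem)) {
        startsWith(tolower(toks[i]), lem)
      } else {
        toks[i] == lem
      }
      if (hit) out[nrow(out) + 1L, ] <- list(i, toks[i], lem)
    }
  }
  out
}

#' Dictionary look-up filter for a residue-containing sentence
#'
#' Keeps every residue in the sentence when at least one positive lemma is
#' spotted; otherwise all residues in the sentence are dropped. Negative
#' lemmas play no role in this filter (they matter for parse-tree
#' scoring).
#'
#' @param sentence Sentence object (or token vector).
#' @param dict A [keyword_dictionary()].
#' @return `"keep"` or `"drop"`.
#' @export
dictionary_filter <- function(sentence, dict = default_dictionary()) {
  if (nrow(spot_keywords(sentence, dict$ppi_positive)) > 0L) "keep" else "drop"
}

# ---- semantic similarity -------------------------------------------------

LESK_STOPWORDS <- c("the", "a", "an", "of", "or", "and", "on", "in", "to",
                    "with", "by", "at", "is", "its", "for", "that", "where",
                    "something", "which", "from", "into", "as", "any")

#' Load the packaged similarity provider
#'
#' Builds a similarity provider from a small deterministic synset
#' taxonomy shipped with the package (a hand-built fixture of ~50 words
#' around the binding-site domain; it is not WordNet). Any lexical
#' database exported in the same JSON schema (synsets with `id`, `words`,
#' `hypernym`, `gloss`, `count`) can be loaded instead.
#'
#' @param path JSON lexicon path; default the packaged fixture.
#' @return Object of class `similarity_provider` with a
#'   `$score(word, concept_word, measure)` function returning a
#'   non-negative number, or `NA` when either word is out of lexicon.
#'   `measure` is one of `"lesk"`, `"lin"`, `"path"`.
#' @export
similarity_provider <- function(path = system.file("extdata", "similarity_lexicon.json",
                                                   package = "tmdock", mustWork = TRUE)) {
  lex <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  syn <- lex$synsets
  ids <- vapply(syn, `[[`, "", "id")
  names(syn) <- ids
  parent <- vapply(syn, function(s) s$hypernym %||% NA_character_, "")
  # word -> synset ids
  word2syn <- list()
  for (s in syn) for (w in s$words)
    word2syn[[tolower(w)]] <- c(word2syn[[tolower(w)]], s$id)
  # depth and ancestor chains
  chain <- lapply(ids, function(id) {
    path_up <- id
    while (!is.na(parent[[id]])) { id <- parent[[id]]; path_up <- c(path_up, id) }
    path_up
  })
  names(chain) <- ids
  # information content: p(s) = subtree count / total
  children <- split(ids, factor(parent[ids], levels = ids))
  subtree_count <- function(id) {
    s <- syn[[id]]$count
    for (ch in children[[id]]) s <- s + Recall(ch)
    s
  }
  counts <- vapply(ids, subtree_count, numeric(1))
  root <- ids[is.na(parent)][1]
  ic <- -log(counts / counts[[root]])
  gloss_tokens <- lapply(syn, function(s)
    strsplit(tolower(gsub("[^a-z ]", "", tolower(s$gloss))), " +")[[1]])
  ext_gloss <- lapply(ids, function(id) {
    nb <- c(id, parent[[id]], children[[id]])
    nb <- nb[!is.na(nb)]
    unlist(gloss_tokens[nb], use.names = FALSE)
  })
  names(ext_gloss) <- ids

  synset_path_sim <- function(a, b) {
    ca <- chain[[a]]; cb <- chain[[b]]
    common <- intersect(ca, cb)
    lca <- common[1]
    d <- (match(lca, ca) - 1L) + (match(lca, cb) - 1L)
    1 / (d + 1)
  }
  synset_lin <- function(a, b) {
    lca <- intersect(chain[[a]], chain[[b]])[1]
    denom <- ic[[a]] + ic[[b]]
    if (denom == 0) return(0)
    2 * ic[[lca]] / denom
  }
  synset_lesk <- function(a, b) lesk_overlap(ext_gloss[[a]], ext_gloss[[b]])

  score <- function(word, concept_word, measure = c("lesk", "lin", "path")) {
    measure <- match.arg(measure)
    sa <- word2syn[[tolower(word)]]
    sb <- word2syn[[tolower(concept_word)]]
    if (is.null(sa) || is.null(sb)) return(NA_real_)
    f <- switch(measure, path = synset_path_sim, lin = synset_lin,
                lesk = synset_lesk)
    max(vapply(sa, function(x)
      max(vapply(sb, function(y) f(x, y), numeric(1))), numeric(1)))
  }
  structure(list(score = score, words = names(word2syn), name = basename(path)),
            class = "similarity_provider")
}

# Extended gloss overlap: repeatedly remove the longest common contiguous
# phrase (containing at least one non-stopword) and add squared length.
lesk_overlap <- function(ta, tb) {
  score <- 0
  repeat {
    n <- length(ta); m <- length(tb)
    if (!n || !m) break
    best_len <- 0L; best_i <- 0L; best_j <- 0L
    # longest common substring by dynamic programming
    prev <- integer(m)
    for (i in seq_len(n)) {
      cur <- integer(m)
      for (j in seq_len(m)) {
        if (ta[i] == tb[j]) {
          cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
          if (cur[j] > best_len) { best_len <- cur[j]; best_i <- i; best_j <- j }
        }
      }
      prev <- cur
    }
    if (best_len == 0L) break
    phrase <- ta[(best_i - best_len + 1L):best_i]
    if (any(!phrase %in% LESK_STOPWORDS)) score <- score + best_len^2
    ta <- ta[-((best_i - best_len + 1L):best_i)]
    tb <- tb[-((best_j - best_len + 1L):best_j)]
  }
  score
}

#' Similarity-score thresholds
#'
#' Default thresholds for keeping a sentence under each measure: 20
#' (Lesk gloss overlap), 0.2 (Lin), 0.11 (Path). A sentence is kept when
#' some word strictly exceeds the measure's threshold against a concept
#' word.
#'
#' @param lesk,lin,path Positive numbers.
#' @export
similarity_thresholds <- function(lesk = 20, lin = 0.2, path = 0.11) {
  stopifnot(lesk > 0, lin > 0, path > 0)
  list(lesk = lesk, lin = lin, path = path)
}

#' Semantic-similarity filter for a residue-containing sentence
#'
#' Scores every word of the sentence against each generic concept word
#' (default "touch" and "site", the words designated as closest to the
#' binding-site concept) and keeps all residues in the sentence iff the
#' maximum score strictly exceeds the measure's threshold. Words absent
#' from the provider's lexicon contribute nothing, so a sentence of only
#' out-of-lexicon words is dropped.
#'
#' @param sentence Sentence object or token vector.
#' @param provider A [similarity_provider()].
#' @param measure `"lesk"`, `"lin"` or `"path"`.
#' @param concept_words Non-empty character vector.
#' @param thresholds From [similarity_thresholds()].
#' @param aggregate `"max"` (any qualifying pair suffices) or `"mean"`
#'   over concept words.
#' @return `"keep"` or `"drop"`.
#' @export
similarity_filter <- function(sentence, provider,
                              measure = c("lesk", "lin", "path"),
                              concept_words = c("touch", "site"),
                              thresholds = similarity_thresholds(),
                              aggregate = c("max", "mean")) {
  measure <- match.arg(measure)
  aggregate <- match.arg(aggregate)
  stopifnot(length(concept_words) >= 1L)
  toks <- if (is.character(sentence)) sentence else sentence$tokens
  toks <- unique(tolower(toks[grepl("^[A-Za-z]", toks)]))
  best <- -Inf
  for (w in toks) {
    sc <- vapply(concept_words, function(cw)
      tryCatch(provider$score(w, cw, measure),
               error = function(e) { warning(conditionMessage(e)); NA_real_ }),
      numeric(1))
    sc <- sc[!is.na(sc)]
    if (!length(sc)) next
    val <- if (aggregate == "max") max(sc) else mean(sc)
    best <- max(best, val)
  }
  if (is.finite(best) && best > thresholds[[measure]]) "keep" else "drop"
}
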