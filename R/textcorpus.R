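# Abstract ingestion, sentence segmentation/tokenization and residue
# mention recognition.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

AMINO1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AMINO_FULL <- c(alanine = "ALA", arginine = "ARG", asparagine = "ASN",
                aspartate = "ASP", aspartic = "ASP", cysteine = "CYS",
                glutamine = "GLN", glutamate = "GLU", glutamic = "GLU",
                glycine = "GLY", histidine = "HIS", isoleucine = "ILE",
                leucine = "LEU", lysine = "LYS", methionine = "MET",
                phenylalanine = "PHE", proline = "PRO", serine = "SER",
                threonine = "THR", tryptophan = "TRP", tyrosine = "TYR",
                valine = "VAL")

# Sentence-final punctuation is never split after these forms.
PROTECTED_ABBREV <- c("i.e.", "e.g.", "cf.", "vs.", "al.", "et al.",
                      "Fig.", "Figs.", "fig.", "Eq.", "Eqs.", "Ref.",
                      "Refs.", "No.", "Dr.", "ca.", "approx.", "resp.")

#' Construct a residue mention
#'
#' A residue mention is one textual occurrence of an amino-acid residue,
#' canonicalized to the 3-letter code plus the author residue number, with
#' an optional chain hint (a single uppercase letter directly appended to
#' the number, as in "Glu67B").
#'
#' @param residue_name Canonical 3-letter amino-acid code.
#' @param residue_number Positive integer author residue number.
#' @param chain_hint Optional single-letter chain identifier, or `NA`.
#' @param token_index Index (1-based) of the head token in the sentence.
#' @param source_form Verbatim matched text.
#' @return An object of class `residue_mention`.
#' @export
residue_mention <- function(residue_name, residue_number, chain_hint = NA_character_,
                            token_index = NA_integer_, source_form = "") {
  residue_name <- toupper(residue_name)
  stopifnot(residue_name %in% AMINO3, residue_number >= 1)
  structure(list(residue_name = residue_name,
                 residue_number = as.integer(residue_number),
                 chain_hint = as.character(chain_hint),
                 token_index = as.integer(token_index),
                 source_form = source_form),
            class = "residue_mention")
}

#' @export
print.residue_mention <- function(x, ...) {
  ch <- if (is.na(x$chain_hint)) "" else paste0(" chain ", x$chain_hint)
  cat(sprintf("<mention %s%d%s from \"%s\">\n", x$residue_name, x$residue_number,
              ch, x$source_form))
  invisible(x)
}

new_sentence <- function(index, text, tokens, mentions = list(), tree = NULL) {
  structure(list(index = index, text = text, tokens = tokens,
                 mentions = mentions, tree = tree),
            class = "tm_sentence")
}

#' Construct an abstract record
#'
#' @param abstract_id Opaque identifier (e.g. a PMID).
#' @param query_type `"AND"` (both protein names required at retrieval) or
#'   `"OR"` (either name).
#' @param complex_id Identifier of the protein-protein complex the query
#'   targeted.
#' @param text Abstract body; segmented and tokenized on construction.
#' @param one_letter Recognize 1-letter residue codes ("E67")? See
#'   [extract_residue_mentions()].
#' @return An object of class `abstract_record` with fields `abstract_id`,
#'   `query_type`, `complex_id` and `sentences`.
#' @export
abstract_record <- function(abstract_id, query_type, complex_id, text,
                            one_letter = TRUE) {
  query_type <- match.arg(query_type, c("AND", "OR"))
  if (!nzchar(trimws(text))) stop("empty abstract: ", abstract_id)
  sentences <- segment_and_tokenize(text)
  sentences <- lapply(sentences, function(s) {
    s$mentions <- extract_residue_mentions(s, one_letter = one_letter)
    s
  })
  structure(list(abstract_id = as.character(abstract_id),
                 query_type = query_type,
                 complex_id = as.character(complex_id),
                 sentences = sentences),
            class = "abstract_record")
}

#' @export
print.abstract_record <- function(x, ...) {
  nm <- sum(vapply(x$sentences, function(s) length(s$mentions), integer(1)))
  cat(sprintf("<abstract %s [%s-query, complex %s]: %d sentences, %d residue mentions>\n",
              x$abstract_id, x$query_type, x$complex_id, length(x$sentences), nm))
  invisible(x)
}

#' Read abstracts from a corpus file
#'
#' Two formats are supported. `"plain"`: blocks separated by blank lines;
#' the first line of a block is `#ID <abstract_id> <AND|OR> <complex_id>`
#' and the remaining lines are the abstract text. `"medline"`: MEDLINE
#' field format, read-only; `PMID-` supplies the identifier and `AB  -`
#' the body (continuation lines indented); query type defaults to OR and
#' the complex id to `NA` unless provided via the non-standard `QT  -` and
#' `CX  -` fields.
#'
#' @param path File path, or a character vector of lines.
#' @param format `"plain"` or `"medline"`.
#' @param one_letter Passed to [abstract_record()].
#' @return List of [abstract_record()] objects. A malformed block raises an
#'   error naming the block id and line; well-formed blocks are unaffected
#'   when `on_error = "skip"`.
#' @param on_error `"stop"` (default) or `"skip"` malformed records.
#' @export
read_abstracts <- function(path, format = c("plain", "medline"),
                           one_letter = TRUE, on_error = c("stop", "skip")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  if (format == "plain") read_abstracts_plain(lines, one_letter, on_error)
  else read_abstracts_medline(lines, one_letter, on_error)
}

read_abstracts_plain <- function(lines, one_letter, on_error) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(!blank) == 1) & !blank)
  grp[blank] <- 0L
  out <- list()
  for (g in setdiff(unique(grp), 0L)) {
    idx <- which(grp == g)
    block <- lines[idx]
    rec <- tryCatch({
      hdr <- strsplit(trimws(block[1]), "\\s+")[[1]]
      if (length(hdr) != 4L || hdr[1] != "#ID" || !hdr[3] %in% c("AND", "OR"))
        stop(sprintf("malformed header at line %d: %s", idx[1], block[1]))
      body <- paste(block[-1], collapse = " ")
      if (!nzchar(trimws(body)))
        stop(sprintf("empty abstract %s at line %d", hdr[2], idx[1]))
      abstract_record(hdr[2], hdr[3], hdr[4], body, one_letter = one_letter)
    }, error = function(e) if (on_error == "skip") {
      warning(conditionMessage(e)); NULL
    } else stop(e))
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

read_abstracts_medline <- function(lines, one_letter, on_error) {
  recs <- split(lines, cumsum(grepl("^PMID-", lines)))
  recs <- recs[names(recs) != "0"]
  out <- list()
  for (block in recs) {
    rec <- tryCatch({
      pmid <- trimws(sub("^PMID-", "", block[1]))
      field <- function(tag) {
        i <- grep(paste0("^", tag, " *-"), block)
        if (!length(i)) return("")
        j <- i[1] + 1L
        val <- sub("^[A-Z]+ *- *", "", block[i[1]])
        while (j <= length(block) && grepl("^\\s+", block[j])) {
          val <- paste(val, trimws(block[j])); j <- j + 1L
        }
        val
      }
      ab <- field("AB")
      if (!nzchar(trimws(ab))) stop("empty abstract ", pmid)
      qt <- field("QT"); cx <- field("CX")
      abstract_record(pmid, if (qt %in% c("AND", "OR")) qt else "OR",
                      if (nzchar(cx)) cx else NA_character_, ab,
                      one_letter = one_letter)
    }, error = function(e) if (on_error == "skip") {
      warning(conditionMessage(e)); NULL
    } else stop(e))
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  out
}

#' Write abstracts in the plain corpus format
#'
#' Inverse of [read_abstracts()] for `format = "plain"`; round-tripping
#' preserves the sentence and mention structure.
#'
#' @param records List of [abstract_record()].
#' @param path Output file path.
#' @export
write_abstracts <- function(records, path) {
  blocks <- vapply(records, function(r) {
    paste0("#ID ", r$abstract_id, " ", r$query_type, " ", r$complex_id, "\n",
           paste(vapply(r$sentences, `[[`, "", "text"), collapse = " "))
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Segment text into tokenized sentences
#'
#' Rule-based, deterministic segmentation: a sentence ends at `.`, `?` or
#' `!` followed by whitespace and an uppercase letter or digit, unless the
#' terminator belongs to a protected abbreviation ("i.e.", "et al.",
#' "Fig." ...) or to a decimal number. Tokens are maximal runs of
#' alphanumerics (internal hyphens, apostrophes and decimal points kept);
#' every other non-space character is its own token, so the tokens
#' concatenate back to the sentence text modulo whitespace.
#'
#' @param text Non-empty character scalar.
#' @return List of sentence objects with fields `index` (0-based), `text`
#'   and `tokens`.
#' @export
segment_and_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  text <- gsub("\\s+", " ", trimws(text))
  ends <- gregexpr("[.?!](?= [A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (ends[1] != -1L) {
    for (p in ends) {
      before <- substr(text, max(1L, p - 12L), p)
      if (any(vapply(PROTECTED_ABBREV, function(a)
        endsWith(before, a), logical(1)))) next
      # decimal like "3.5" never reaches here (no space after the dot)
      cuts <- c(cuts, p)
    }
  }
  starts <- c(1L, cuts + 2L)
  stops <- c(cuts, nchar(text))
  pieces <- trimws(substring(text, starts, stops))
  pieces <- pieces[nzchar(pieces)]
  lapply(seq_along(pieces), function(i) {
    new_sentence(index = i - 1L, text = pieces[i], tokens = tokenize(pieces[i]))
  })
}

tokenize <- function(sentence_text) {
  m <- gregexpr("[A-Za-z0-9]+(?:[-'.][A-Za-z0-9]+)*|[^A-Za-z0-9 ]",
                sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(sentence_text, list(m))[[1]]
  # a trailing sentence period glued into the last word token ("pocket.")
  # is split off so punctuation is always its own token
  unlist(lapply(toks, function(t) {
    if (grepl("[A-Za-z0-9]\\.$", t) && !grepl("\\d\\.\\d", t) &&
        !t %in% PROTECTED_ABBREV)
      c(sub("\\.$", "", t), ".")
    else t
  }), use.names = FALSE)
}

#' Extract residue mentions from a tokenized sentence
#'
#' The mention grammar recognizes, per token (or name + number token pair):
#' a 3-letter amino-acid code or full residue name, case-insensitive,
#' joined to the number directly, by a hyphen, or by a space ("Glu67",
#' "Glu-67", "Glu 67", "glutamate 67"); an uppercase 1-letter code
#' immediately followed by digits ("E67", disable with
#' `one_letter = FALSE`); mutation notation ("E67A", "Glu67Ala") yields the
#' wild-type residue only. A single uppercase letter directly appended to
#' the number of a 3-letter/full-name form is captured as a chain hint
#' ("Glu67B"). Extraction is per-sentence and idempotent.
#'
#' @param sentence A sentence from [segment_and_tokenize()], or a character
#'   scalar (tokenized internally).
#' @param one_letter Logical; recognize the 1-letter form.
#' @return List of [residue_mention()] (possibly empty).
#' @export
extract_residue_mentions <- function(sentence, one_letter = TRUE) {
  if (is.character(sentence))
    sentence <- segment_and_tokenize(sentence)[[1]]
  toks <- sentence$tokens
  out <- list()
  add <- function(m) out[[length(out) + 1L]] <<- m
  i <- 1L
  while (i <= length(toks)) {
    tok <- toks[i]
    m <- match_mention_token(tok, one_letter)
    if (!is.null(m)) {
      m$token_index <- i
      add(m)
    } else {
      nm <- canonical_residue_name(tok)
      # two-token form: name token then bare number token
      if (!is.na(nm) && i < length(toks) && grepl("^[0-9]+$", toks[i + 1L])) {
        num <- as.integer(toks[i + 1L])
        if (num >= 1L) {
          add(residue_mention(nm, num, NA_character_, i,
                              paste(tok, toks[i + 1L])))
          i <- i + 1L
        }
      }
    }
    i <- i + 1L
  }
  out
}

canonical_residue_name <- function(tok) {
  lt <- tolower(tok)
  if (nchar(tok) == 3L && toupper(tok) %in% AMINO3) return(toupper(tok))
  if (lt %in% names(AMINO_FULL)) return(unname(AMINO_FULL[lt]))
  NA_character_
}

match_mention_token <- function(tok, one_letter) {
  # 3-letter / full-name forms, optional hyphen, optional chain or mutation
  m <- regmatches(tok, regexec("^([A-Za-z]{3,})-?([0-9]+)([A-Za-z]*)$", tok))[[1]]
  if (length(m)) {
    nm <- canonical_residue_name(m[2])
    num <- as.integer(m[3])
    tail <- m[4]
    if (!is.na(nm) && num >= 1L) {
      if (tail == "")
        return(residue_mention(nm, num, NA_character_, NA, tok))
      if (nchar(tail) == 1L && tail == toupper(tail))  # chain hint "Glu67B"
        return(residue_mention(nm, num, tail, NA, tok))
      if (!is.na(canonical_residue_name(tail)))        # mutation "Glu67Ala"
        return(residue_mention(nm, num, NA_character_, NA, tok))
      return(NULL)
    }
  }
  if (!one_letter) return(NULL)
  m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z]?)$", tok))[[1]]
  if (length(m) && m[2] %in% names(AMINO1)) {
    num <- as.integer(m[3])
    if (num < 1L) return(NULL)
    nm <- unname(AMINO1[m[2]])
    if (m[4] == "")
      return(residue_mention(nm, num, NA_character_, NA, tok))
    if (m[4] %in% names(AMINO1))   # mutation "E67A": wild type only
      return(residue_mention(nm, num, NA_character_, NA, tok))
    return(residue_mention(nm, num, m[4], NA, tok))  # "E67B": chain hint
  }
  NULL
}
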