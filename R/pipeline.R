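# End-to-end orchestration: mention extraction -> structure filters ->
# advanced NLP filter -> evaluation -> constraints.

fnv1a <- function(x) {
  # tiny stable config hash for provenance stamping of reports
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 216613
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the residue-filtering pipeline over a corpus
#'
#' Stages, in order: residue-mention extraction (already on the abstract
#' records), structure correspondence and surface filtering (when
#' structures are supplied), then one advanced context filter. Every
#' mention is accounted for: the result's `mentions` table records for
#' each extracted mention whether it was retained or the stage and rule
#' that dropped it.
#'
#' @param abstracts List of [abstract_record()] (or a plain-corpus file
#'   path).
#' @param method One of `"basic"`, `"dictionary"`, `"similarity"`,
#'   `"method1"`, `"method2"`, `"method3"`.
#' @param trees Named per-abstract list of sentence `parse_tree`s (or a
#'   sidecar file path); required for methods 1-3.
#' @param dict A [keyword_dictionary()].
#' @param structures Optional named list: `complex_id -> list(receptor,
#'   ligand)` of `structure_model`s; enables the correspondence and
#'   surface stages.
#' @param interface_lookup Optional data.frame (`complex_id`,
#'   `residue_number`) of true interface residues used to flag retained
#'   mentions for evaluation (computed from `structures` at the 6 A
#'   cutoff when omitted but structures are present).
#' @param provider,measure,concept_words,thresholds For
#'   `method = "similarity"`; see [similarity_filter()].
#' @param svm_model,protein_names For `method = "method3"`; see
#'   [method3_filter()] and [s_prot()]. `protein_names` is a named list
#'   `complex_id -> c(name1, name2)`.
#' @param sx_threshold Residue-score threshold for methods 1-2.
#' @param strict Drop mentions whose sentence has no parse tree
#'   (otherwise they pass through with a warning).
#' @param rsasa_threshold Surface filter threshold.
#' @param seed Recorded in the report stamp.
#' @return List of class `tm_run`: `mentions` (full accounting table),
#'   `pools` (per-complex retained mentions for [ptm()]), `config_hash`,
#'   `method`.
#' @export
run_filtering <- function(abstracts, method = "basic", trees = NULL,
                          dict = default_dictionary(), structures = NULL,
                          interface_lookup = NULL, provider = NULL,
                          measure = "lesk", concept_words = c("touch", "site"),
                          thresholds = similarity_thresholds(),
                          svm_model = NULL, protein_names = NULL,
                          sx_threshold = 0.25, strict = FALSE,
                          rsasa_threshold = 0.05, seed = NA_integer_) {
  if (is.character(abstracts)) abstracts <- read_abstracts(abstracts)
  if (is.character(trees)) trees <- read_tree_sidecar(trees)
  method <- match.arg(method, c("basic", "dictionary", "similarity",
                                "method1", "method2", "method3"))
  if (method %in% c("method1", "method2", "method3") && is.null(trees))
    stop("parse trees are required for ", method)
  if (method == "similarity" && is.null(provider))
    stop("a similarity provider is required for method = 'similarity'")
  if (method == "method3" && (is.null(svm_model) || is.null(protein_names)))
    stop("method3 needs svm_model and protein_names")
  names(abstracts) <- vapply(abstracts, `[[`, "", "abstract_id")

  if (!is.null(structures) && is.null(interface_lookup)) {
    interface_lookup <- do.call(rbind, lapply(names(structures), function(cx) {
      ia <- interface_residues(structures[[cx]]$receptor,
                               structures[[cx]]$ligand)
      both <- rbind(ia$receptor, ia$ligand)
      data.frame(complex_id = cx, residue_number = both$resno)
    }))
  }
  surface_cache <- list()

  rows <- list()
  for (rec in abstracts) {
    atrees <- trees[[rec$abstract_id]]
    for (si in seq_along(rec$sentences)) {
      sent <- rec$sentences[[si]]
      tree <- if (!is.null(atrees) && si <= length(atrees)) atrees[[si]] else sent$tree
      for (m in sent$mentions) {
        action <- "retained"; stage <- ""; rule <- ""
        # stage: structure correspondence + surface
        if (!is.null(structures)) {
          st <- structures[[rec$complex_id]]
          if (is.null(st)) {
            action <- "dropped"; stage <- "structure"; rule <- "no-structure"
          } else {
            hit <- match_mention(m, st$receptor) %||% match_mention(m, st$ligand)
            if (is.null(hit)) {
              action <- "dropped"; stage <- "structure"; rule <- "no-correspondence"
            } else {
              model <- if (!is.null(match_mention(m, st$receptor))) st$receptor else st$ligand
              ckey <- paste(rec$complex_id, hit$chain[1])
              if (is.null(surface_cache[[ckey]]))
                surface_cache[[ckey]] <- residue_rsasa(model)
              if (!is_surface(hit[1, ], model, rsasa_threshold,
                              rsasa = surface_cache[[ckey]])) {
                action <- "dropped"; stage <- "surface"; rule <- "buried"
              }
            }
          }
        }
        # stage: advanced context filter
        if (action == "retained" && method != "basic") {
          verdict <- switch(
            method,
            dictionary = dictionary_filter(sent, dict),
            similarity = similarity_filter(sent, provider, measure,
                                           concept_words, thresholds),
            method1 = method1_filter(tree, m, dict, sx_threshold, strict),
            method2 = method2_filter(rec, si - 1L, tree, m, dict,
                                     sx_threshold, strict),
            method3 = {
              fv <- build_features(rec, si - 1L, m, dict,
                                   as.list(protein_names[[rec$complex_id]]),
                                   trees = atrees)
              method3_filter(svm_model, fv)
            })
          if (verdict == "drop") {
            action <- "dropped"; stage <- method; rule <- "context-filter"
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = rec$complex_id, abstract_id = rec$abstract_id,
          query_type = rec$query_type, sentence_index = si - 1L,
          residue_name = m$residue_name, residue_number = m$residue_number,
          token_index = m$token_index, action = action, stage = stage,
          rule = rule, stringsAsFactors = FALSE)
      }
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(0), abstract_id = character(0),
               query_type = character(0), sentence_index = integer(0),
               residue_name = character(0), residue_number = integer(0),
               token_index = integer(0), action = character(0),
               stage = character(0), rule = character(0))
  retained <- mentions[mentions$action == "retained", , drop = FALSE]
  if (!is.null(interface_lookup)) {
    key <- paste(interface_lookup$complex_id, interface_lookup$residue_number)
    retained$interface <- paste(retained$complex_id, retained$residue_number) %in% key
  }
  pools <- split(retained, retained$complex_id)
  cfg <- list(method = method, sx_threshold = sx_threshold,
              measure = measure, concept_words = concept_words,
              rsasa_threshold = rsasa_threshold, seed = seed)
  structure(list(mentions = mentions, pools = pools, method = method,
                 config_hash = fnv1a(cfg), seed = seed),
            class = "tm_run")
}

#' @export
print.tm_run <- function(x, ...) {
  cat(sprintf("<tm run [%s, cfg %s]: %d mentions, %d retained over %d complexes>\n",
              x$method, x$config_hash, nrow(x$mentions),
              sum(x$mentions$action == "retained"), length(x$pools)))
  invisible(x)
}

#' Evaluate a filtering run
#'
#' @param run A `tm_run` whose pools carry the `interface` flag.
#' @param total_complexes Total complexes attempted.
#' @return List: `distribution` ([ptm_distribution()]) and `stats`
#'   ([aggregate_stats()]).
#' @export
evaluate_run <- function(run, total_complexes = length(run$pools)) {
  if (!all(vapply(run$pools, function(p) "interface" %in% names(p), logical(1))))
    stop("pools lack interface flags; supply structures or interface_lookup")
  list(distribution = ptm_distribution(run$pools),
       stats = aggregate_stats(run$pools, total_complexes))
}

#' Generate docking constraints from a filtering run
#'
#' For `scheme = "basic"` the confidence of each retained residue is the
#' capped provenance sum (see [confidence_basic()]); for `"nlp"` the
#' re-ranked score of [confidence_nlp()], where an abstract "passes NLP"
#' when the advanced run retained the residue's mention from it. The top
#' five residues per complex become constraints. For
#' `scheme = "reference"` the bound complex supplies the three closest
#' interface pairs at confidence 10 (see [reference_constraints()]).
#'
#' @param basic_run `tm_run` from `method = "basic"`.
#' @param nlp_run Advanced-method `tm_run` (same corpus); required for
#'   `scheme = "nlp"`.
#' @param scheme `"basic"`, `"nlp"` or `"reference"`.
#' @param structures For `scheme = "reference"`: named list
#'   `complex_id -> list(receptor, ligand)` of bound models.
#' @param k Constraints per complex.
#' @return Named list (complex id) of constraint data.frames.
#' @export
run_constraints <- function(basic_run = NULL, nlp_run = NULL,
                            scheme = c("basic", "nlp", "reference"),
                            structures = NULL, k = 5) {
  scheme <- match.arg(scheme)
  if (scheme == "reference") {
    if (is.null(structures)) stop("scheme 'reference' needs bound structures")
    return(lapply(structures, function(st)
      reference_constraints(st$receptor, st$ligand)$constraints))
  }
  stopifnot(!is.null(basic_run))
  if (scheme == "nlp" && is.null(nlp_run))
    stop("scheme 'nlp' needs the advanced-filter run")
  ret <- basic_run$mentions[basic_run$mentions$action == "retained", , drop = FALSE]
  out <- list()
  for (cx in unique(ret$complex_id)) {
    sub <- ret[ret$complex_id == cx, , drop = FALSE]
    keykeep <- if (scheme == "nlp") {
      adv <- nlp_run$mentions[nlp_run$mentions$action == "retained" &
                                nlp_run$mentions$complex_id == cx, , drop = FALSE]
      paste(adv$abstract_id, adv$residue_number)
    } else character(0)
    res <- unique(sub[, c("residue_name", "residue_number")])
    scored <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
      ev <- sub[sub$residue_number == res$residue_number[i], , drop = FALSE]
      ev <- ev[!duplicated(ev$abstract_id), , drop = FALSE]
      f <- if (scheme == "basic") confidence_basic(ev$query_type)
      else confidence_nlp(ev$query_type,
                          paste(ev$abstract_id, ev$residue_number) %in% keykeep)
      data.frame(chain = NA_character_, resno = res$residue_number[i],
                 resname = res$residue_name[i], f = f,
                 n_abstracts = nrow(ev), has_and = any(ev$query_type == "AND"),
                 evidence = paste(ev$abstract_id, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    out[[cx]] <- select_constraints(scored, k = k)
  }
  out
}
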