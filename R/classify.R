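# SVM-based sentence classification (Method 3): feature construction from
# parse-tree scores and protein-name presence, training, and the usual
# precision/recall/accuracy/F metrics.

FEATURE_LAYOUT <- c("s_x", "s_ctx_prev", "s_ctx_next",
                    "s_prot_res", "s_prot_prev", "s_prot_next")

#' Protein-name presence score of a sentence
#'
#' 0 if neither interacting protein is named in the sentence, 1 if exactly
#' one is, 2 if both are. Each protein is given as a name with optional
#' synonyms; matching is case-insensitive on word boundaries, so
#' multi-word names are found in the raw sentence text.
#'
#' @param sentence Sentence object or character scalar.
#' @param protein_names List of two character vectors (name + synonyms per
#'   protein).
#' @return Integer 0, 1 or 2.
#' @export
s_prot <- function(sentence, protein_names) {
  stopifnot(length(protein_names) == 2L)
  text <- if (is.character(sentence)) sentence else sentence$text
  present <- vapply(protein_names, function(nms) {
    any(vapply(nms, function(nm)
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", nm), "\\b"),
            text, ignore.case = TRUE), logical(1)))
  }, logical(1))
  sum(present)
}

#' Build the 6-dimensional feature vector for a residue mention
#'
#' Features: the residue's parse-tree score in its sentence; the
#' root-anchored keyword scores of the preceding and following sentences;
#' and the protein-name presence score (0/1/2) of the residue-containing,
#' preceding and following sentences. A missing neighbor sentence
#' contributes 0 to its two slots.
#'
#' @param abstract An [abstract_record()].
#' @param sentence_index 0-based index of the residue-containing sentence.
#' @param mention A [residue_mention()] within that sentence.
#' @param dict A [keyword_dictionary()].
#' @param protein_names As in [s_prot()].
#' @param trees List of `parse_tree` (or `NULL`) aligned with the
#'   abstract's sentences; overrides any trees stored on the sentences.
#' @return Named numeric vector of length 6.
#' @export
build_features <- function(abstract, sentence_index, mention,
                           dict = default_dictionary(), protein_names,
                           trees = NULL) {
  idx <- sentence_index + 1L
  sent <- abstract$sentences[[idx]]
  tree_of <- function(j) {
    if (j < 1L || j > length(abstract$sentences)) return(NULL)
    if (!is.null(trees)) trees[[j]] else abstract$sentences[[j]]$tree
  }
  tree <- tree_of(idx)
  if (is.null(tree)) stop("no parse tree for the residue-containing sentence")
  fv <- c(
    s_x = score_residue(tree, mention, dict)$s_x,
    s_ctx_prev = context_root_score(tree_of(idx - 1L), dict),
    s_ctx_next = context_root_score(tree_of(idx + 1L), dict),
    s_prot_res = as.numeric(s_prot(sent, protein_names)),
    s_prot_prev = if (idx > 1L)
      as.numeric(s_prot(abstract$sentences[[idx - 1L]], protein_names)) else 0,
    s_prot_next = if (idx < length(abstract$sentences))
      as.numeric(s_prot(abstract$sentences[[idx + 1L]], protein_names)) else 0)
  fv
}

#' Train the sentence classifier
#'
#' Trains a kernel SVM (via \pkg{e1071}/libsvm) on labeled feature
#' vectors, after a stratified random split into training and validation
#' halves. The default kernel is RBF with gamma 16, the configuration
#' that performed best for this task; features are used unscaled (they
#' are already bounded and commensurate).
#'
#' @param features Numeric matrix (rows = sentences/mentions, 6 columns as
#'   in [build_features()]).
#' @param labels Logical or factor of two levels (`TRUE`/"positive" =
#'   contains an interface residue).
#' @param kernel `"radial"`, `"linear"` or `"polynomial"`.
#' @param gamma RBF kernel width.
#' @param cost Soft-margin cost C.
#' @param split_fraction Fraction of items in the training half.
#' @param seed Integer seed controlling the split.
#' @param scale Standardize features before training?
#' @return Object of class `svm_filter_model`: the fitted SVM plus the
#'   split indices, feature layout and validation metrics
#'   (see [praf()]).
#' @export
svm_train <- function(features, labels, kernel = "radial", gamma = 16,
                      cost = 1, split_fraction = 0.5, seed = 1,
                      scale = FALSE) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("empty training set")
  colnames(features) <- FEATURE_LAYOUT
  y <- factor(ifelse(as.logical(labels), "positive", "negative"),
              levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  idx_train <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    unlist(lapply(split(seq_along(y), y), function(i)
      sample(i, round(length(i) * split_fraction))), use.names = FALSE)
  })
  if (nlevels(droplevels(y[idx_train])) < 2L)
    stop("both classes must be present in the training half")
  fit <- e1071::svm(features[idx_train, , drop = FALSE], y[idx_train],
                    kernel = kernel, gamma = gamma, cost = cost,
                    scale = scale)
  model <- structure(list(fit = fit, layout = FEATURE_LAYOUT,
                          kernel = kernel, gamma = gamma, cost = cost,
                          seed = seed, train_idx = sort(idx_train)),
                     class = "svm_filter_model")
  if (length(idx_train) < length(y)) {
    val <- setdiff(seq_along(y), idx_train)
    pred <- predict(fit, features[val, , drop = FALSE])
    tp <- sum(pred == "positive" & y[val] == "positive")
    fp <- sum(pred == "positive" & y[val] == "negative")
    tn <- sum(pred == "negative" & y[val] == "negative")
    fn <- sum(pred == "negative" & y[val] == "positive")
    model$validation <- c(praf(tp, fp, tn, fn),
                          list(tp = tp, fp = fp, tn = tn, fn = fn,
                               n = length(val)))
  }
  model
}

#' @export
print.svm_filter_model <- function(x, ...) {
  cat(sprintf("<SVM sentence filter: %s kernel, gamma %g, cost %g, %d SVs>\n",
              x$kernel, x$gamma, x$cost, x$fit$tot.nSV))
  if (!is.null(x$validation))
    cat(sprintf("  validation (n=%d): P=%.3f R=%.3f A=%.3f F=%.3f\n",
                x$validation$n, x$validation$P, x$validation$R,
                x$validation$A, x$validation$F))
  invisible(x)
}

#' Method 3: SVM classification of a residue mention
#'
#' @param model A fitted `svm_filter_model`.
#' @param features Feature vector (length 6) or matrix with the layout of
#'   [build_features()].
#' @return `"keep"`/`"drop"` (vector for a matrix input).
#' @export
method3_filter <- function(model, features) {
  if (!inherits(model, "svm_filter_model")) stop("model absent or wrong class")
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(m) != length(model$layout)) stop("feature layout mismatch")
  colnames(m) <- model$layout
  ifelse(predict(model$fit, m) == "positive", "keep", "drop")
}

#' Save / load a sentence-filter model
#'
#' Serializes the model in a self-describing JSON envelope wrapping the
#' base-R serialization of the fitted SVM.
#'
#' @param model A `svm_filter_model`.
#' @param path File path.
#' @export
svm_save <- function(model, path) {
  payload <- list(format = "tmdock-svm/1", layout = model$layout,
                  kernel = model$kernel, gamma = model$gamma,
                  cost = model$cost, seed = model$seed,
                  fit = jsonlite::base64_enc(serialize(model$fit, NULL)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svm_save
#' @export
svm_load <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "tmdock-svm/1")) stop("unrecognized model file")
  structure(list(fit = unserialize(jsonlite::base64_dec(p$fit)),
                 layout = p$layout, kernel = p$kernel, gamma = p$gamma,
                 cost = p$cost, seed = p$seed),
            class = "svm_filter_model")
}

#' Precision, recall, accuracy and F-score
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `A = (TP+TN)/(TP+FP+TN+FN)`,
#' `F = 2PR/(P+R)`. Undefined ratios (0/0) are reported as `NA`, not 0.
#'
#' @param tp,fp,tn,fn Non-negative counts; their sum must be positive.
#' @return List with components `P`, `R`, `A`, `F`.
#' @export
praf <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all counts are zero")
  P <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  R <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  A <- (tp + tn) / total
  F <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R)
  else if (!is.na(P) && !is.na(R)) NA_real_ else NA_real_
  list(P = P, R = R, A = A, F = F)
}
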