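# Confidence-ranked docking constraints from mined residues, reference
# constraints from the bound complex, pose rescoring and i-RMSD
# evaluation.

#' Basic confidence score of a mined residue
#'
#' `f(R) = min(10, sum_i a_i)` over the abstracts mentioning residue R,
#' with `a_i = 1` for an abstract retrieved by the OR-query only and
#' `a_i = 2` for an AND-query abstract. The cap at 10 keeps the range
#' [1,10] and damps residue overrepresentation in the literature.
#'
#' @param provenance Character vector of `"AND"`/`"OR"`, one per abstract
#'   mentioning the residue.
#' @return Number in [1, 10].
#' @export
confidence_basic <- function(provenance) {
  if (!length(provenance)) stop("empty provenance list")
  stopifnot(all(provenance %in% c("AND", "OR")))
  min(10, sum(ifelse(provenance == "AND", 2, 1)))
}

#' NLP-re-ranked confidence score
#'
#' Re-ranking within the AND/OR categories using the outcome of the NLP
#' filter, keeping the range [1,10] and AND precedence over OR:
#' 10 if some AND-retrieved abstract passes the NLP filter; 8 if the
#' residue has an AND abstract (none passing); 6 if some OR abstract
#' passes the NLP filter; otherwise `max(5, number of abstracts)`, capped
#' at 10 to preserve the range.
#'
#' @param provenance As in [confidence_basic()].
#' @param nlp_pass Logical vector aligned with `provenance`: did the
#'   residue's mention in that abstract survive the NLP filter?
#' @return Number in [1, 10].
#' @export
confidence_nlp <- function(provenance, nlp_pass) {
  if (!length(provenance)) stop("empty provenance list")
  stopifnot(length(nlp_pass) == length(provenance),
            all(provenance %in% c("AND", "OR")))
  if (any(provenance == "AND" & nlp_pass)) return(10)
  if (any(provenance == "AND")) return(8)
  if (any(provenance == "OR" & nlp_pass)) return(6)
  min(10, max(5, length(provenance)))
}

#' Select the top-k constraints for one protein
#'
#' Ranks scored residues by confidence `f` (descending); at equal `f`,
#' residues with AND-query evidence outrank OR-only residues, then more
#' abstracts outrank fewer, then the lower residue number wins
#' (deterministic ties).
#'
#' @param scored data.frame with columns `chain`, `resno`, `resname`, `f`,
#'   `n_abstracts`, `has_and` (logical), and optionally `evidence`.
#' @param k Number of constraints (default 5, "top five residues").
#' @param protein_role `"receptor"` or `"ligand"`, recorded on the output.
#' @return data.frame of at most `k` rows, ordered by rank, with a
#'   `protein_role` column; fewer rows when fewer residues exist.
#' @export
select_constraints <- function(scored, k = 5, protein_role = "receptor") {
  if (is.null(scored) || !nrow(scored))
    return(cbind(scored[0, , drop = FALSE],
                 data.frame(protein_role = character(0))))
  ord <- order(-scored$f, -as.integer(scored$has_and),
               -scored$n_abstracts, scored$resno)
  out <- scored[ord, , drop = FALSE][seq_len(min(k, nrow(scored))), , drop = FALSE]
  out$protein_role <- protein_role
  rownames(out) <- NULL
  out
}

#' Reference constraints from the bound complex
#'
#' Interface residue pairs (any heavy-atom contact within `cutoff`) are
#' ranked by ascending C-alpha--C-alpha distance; the top `n_pairs`
#' (default three) are emitted, each side's residue as a constraint with
#' the maximum confidence 10. These reference constraints bound the
#' success rate attainable with perfect binding-site knowledge.
#'
#' @param receptor,ligand Bound-state `structure_model` partners.
#' @param cutoff Interface atom-atom cutoff (Angstrom).
#' @param n_pairs Number of pairs to keep.
#' @return List with `pairs` (data.frame: receptor_resno, ligand_resno,
#'   ca_distance) and `constraints` (data.frame as in
#'   [select_constraints()] with f = 10).
#' @export
reference_constraints <- function(receptor, ligand, cutoff = 6.0, n_pairs = 3) {
  ra <- receptor$atoms[receptor$atoms$element != "H", ]
  la <- ligand$atoms[ligand$atoms$element != "H", ]
  rx <- as.matrix(ra[, c("x", "y", "z")])
  lx <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), `+`) - 2 * rx %*% t(lx)
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  if (!nrow(hit)) {
    warning("no interface residue pairs within ", cutoff, " A")
    empty <- data.frame(receptor_resno = integer(0), ligand_resno = integer(0),
                        ca_distance = numeric(0))
    return(list(pairs = empty, constraints = empty[0, 0]))
  }
  pr <- unique(data.frame(
    receptor_chain = ra$chain[hit[, 1]], receptor_resno = ra$resno[hit[, 1]],
    ligand_chain = la$chain[hit[, 2]], ligand_resno = la$resno[hit[, 2]],
    stringsAsFactors = FALSE))
  ca_of <- function(m, chain, resno) {
    i <- which(m$atoms$chain == chain & m$atoms$resno == resno &
                 m$atoms$elety == "CA")[1]
    as.numeric(m$atoms[i, c("x", "y", "z")])
  }
  pr$ca_distance <- vapply(seq_len(nrow(pr)), function(i) {
    sqrt(sum((ca_of(receptor, pr$receptor_chain[i], pr$receptor_resno[i]) -
                ca_of(ligand, pr$ligand_chain[i], pr$ligand_resno[i]))^2))
  }, numeric(1))
  pr <- pr[order(pr$ca_distance, pr$receptor_resno, pr$ligand_resno), , drop = FALSE]
  if (nrow(pr) < n_pairs)
    warning("only ", nrow(pr), " interface pairs available (requested ",
            n_pairs, ")")
  pr <- pr[seq_len(min(n_pairs, nrow(pr))), , drop = FALSE]
  rownames(pr) <- NULL
  cons <- rbind(
    data.frame(protein_role = "receptor", chain = pr$receptor_chain,
               resno = pr$receptor_resno, f = 10, stringsAsFactors = FALSE),
    data.frame(protein_role = "ligand", chain = pr$ligand_chain,
               resno = pr$ligand_resno, f = 10, stringsAsFactors = FALSE))
  cons <- unique(cons)
  list(pairs = pr, constraints = cons)
}

#' Write constraints in the tab-separated exchange format
#'
#' Columns: role, chain, resnum, resname, f, evidence (semicolon-joined
#' abstract ids; empty when absent).
#'
#' @param constraints data.frame of constraints.
#' @param path Output path.
#' @export
write_constraints <- function(constraints, path) {
  df <- data.frame(role = constraints$protein_role, chain = constraints$chain,
                   resnum = constraints$resno,
                   resname = constraints$resname %||% "",
                   f = constraints$f,
                   evidence = constraints$evidence %||% "",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- poses and i-RMSD ----------------------------------------------------

#' Construct a rigid-body docking pose
#'
#' A pose is a rigid transform (rotation `R`, translation `t`) applied to
#' the ligand coordinates, with the raw docking-scan score and rank.
#'
#' @param pose_id Identifier.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector.
#' @param raw_score Raw docking score (higher is better).
#' @param rank Rank in the raw-scored list.
#' @export
dock_pose <- function(pose_id, rotation = diag(3), translation = c(0, 0, 0),
                      raw_score = 0, rank = NA_integer_) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  structure(list(pose_id = pose_id, rotation = rotation,
                 translation = as.numeric(translation),
                 raw_score = raw_score, rank = rank),
            class = "dock_pose")
}

apply_pose <- function(pose, xyz) {
  sweep(xyz %*% t(pose$rotation), 2, pose$translation, `+`)
}

transform_model <- function(model, pose) {
  xyz <- apply_pose(pose, as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Rescore docking poses with text-mining constraints
#'
#' The constraint score of a pose is the sum of the confidence values `f`
#' over all constraints whose residue lies at the pose's interface
#' (receptor-side constraints against the pose's receptor interface,
#' ligand-side against the ligand interface, same heavy-atom cutoff as
#' [interface_residues()]). Poses are re-ranked by constraint score
#' (descending) with the raw rank as a stable tie-break; with no
#' constraints every score is zero and the original order is preserved.
#'
#' @param poses List of [dock_pose()].
#' @param receptor `structure_model` kept fixed.
#' @param ligand `structure_model` the pose transforms apply to.
#' @param constraints data.frame with `protein_role`, `chain`, `resno`,
#'   `f` (possibly 0 rows).
#' @param cutoff Interface cutoff (Angstrom).
#' @return data.frame: pose_id, raw_score, raw_rank, constraint_score,
#'   new_rank, ordered by the new ranking.
#' @export
rescore_poses <- function(poses, receptor, ligand, constraints, cutoff = 6.0) {
  raw_rank <- vapply(poses, function(p)
    if (is.na(p$rank)) NA_integer_ else as.integer(p$rank), integer(1))
  if (any(is.na(raw_rank))) raw_rank <- seq_along(poses)
  score <- vapply(poses, function(p) {
    if (is.null(constraints) || !nrow(constraints)) return(0)
    iface <- interface_residues(receptor, transform_model(ligand, p), cutoff)
    s <- 0
    for (i in seq_len(nrow(constraints))) {
      side <- if (constraints$protein_role[i] == "receptor") iface$receptor else iface$ligand
      if (any(side$chain == constraints$chain[i] &
                side$resno == constraints$resno[i]))
        s <- s + constraints$f[i]
    }
    s
  }, numeric(1))
  ord <- order(-score, raw_rank)
  data.frame(pose_id = vapply(poses, function(p) as.character(p$pose_id), "")[ord],
             raw_score = vapply(poses, `[[`, numeric(1), "raw_score")[ord],
             raw_rank = raw_rank[ord],
             constraint_score = score[ord],
             new_rank = seq_along(poses),
             stringsAsFactors = FALSE)
}

#' Kabsch least-squares superposition
#'
#' Returns the rotation and translation minimizing the RMSD of `mobile`
#' onto `target` (proper rotation enforced).
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows.
#' @return List with `rotation`, `translation`, `rmsd`.
#' @export
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 3)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  list(rotation = R, translation = ct - as.numeric(R %*% cm),
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

#' Ligand interface C-alpha RMSD of a docking pose
#'
#' The reference placement is obtained by least-squares (Kabsch)
#' superposition of the unbound ligand onto the bound ligand over the
#' mapped C-alpha atoms; the i-RMSD of a pose is then the RMSD over the
#' ligand interface C-alpha atoms (interface defined on the bound
#' complex, carried to the unbound ligand through the residue map)
#' between the pose placement and the reference placement of the unbound
#' ligand.
#'
#' @param pose A [dock_pose()] acting on the unbound ligand coordinates.
#' @param bound_receptor,bound_ligand The co-crystallized complex.
#' @param unbound_ligand The separately solved ligand.
#' @param residue_map From [map_unbound_to_bound()] (unbound vs bound
#'   ligand); computed when `NULL`.
#' @param cutoff Interface cutoff on the bound complex (Angstrom).
#' @return i-RMSD in Angstrom.
#' @export
irmsd <- function(pose, bound_receptor, bound_ligand, unbound_ligand,
                  residue_map = NULL, cutoff = 6.0) {
  ref <- irmsd_reference(bound_receptor, bound_ligand, unbound_ligand,
                         residue_map, cutoff)
  docked <- apply_pose(pose, ref$unbound_ca)
  sqrt(mean(rowSums((docked - ref$reference_ca)^2)))
}

# shared precomputation: unbound interface CA coordinates and their
# reference (superposed-on-bound) placement
irmsd_reference <- function(bound_receptor, bound_ligand, unbound_ligand,
                            residue_map = NULL, cutoff = 6.0) {
  if (is.null(residue_map))
    residue_map <- map_unbound_to_bound(unbound_ligand, bound_ligand)
  iface <- interface_residues(bound_receptor, bound_ligand, cutoff)$ligand
  mp <- residue_map[residue_map$bound_resno %in% iface$resno, , drop = FALSE]
  ca <- function(model, resno_vec) {
    idx <- vapply(resno_vec, function(rn)
      which(model$atoms$resno == rn & model$atoms$elety == "CA")[1], integer(1))
    if (any(is.na(idx))) stop("missing C-alpha atoms for interface residues")
    as.matrix(model$atoms[idx, c("x", "y", "z")])
  }
  # superposition computed over all mapped CA, applied to interface CA
  all_u <- ca(unbound_ligand, residue_map$unbound_resno)
  all_b <- ca(bound_ligand, residue_map$bound_resno)
  fit <- kabsch(all_u, all_b)
  u_iface <- ca(unbound_ligand, mp$unbound_resno)
  if (nrow(u_iface) < 3) stop("fewer than 3 interface C-alpha correspondences")
  ref_ca <- sweep(u_iface %*% t(fit$rotation), 2, fit$translation, `+`)
  list(unbound_ca = u_iface, reference_ca = ref_ca, map = mp,
       superposition = fit)
}

#' Docking success rate over a set of complexes
#'
#' A complex is a success when at least one pose within the top `top_n` of
#' its ranked list has i-RMSD at or below `threshold` (non-strict, 5 A by
#' default).
#'
#' @param irmsd_by_complex List (one element per complex) of numeric
#'   i-RMSD vectors in rank order.
#' @param threshold Success threshold (Angstrom).
#' @param top_n Depth of the ranked list examined.
#' @return Fraction in [0, 1].
#' @export
success_rate <- function(irmsd_by_complex, threshold = 5, top_n = 10) {
  if (!length(irmsd_by_complex)) stop("empty input")
  mean(vapply(irmsd_by_complex, function(v)
    any(utils::head(v, top_n) <= threshold), logical(1)))
}
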