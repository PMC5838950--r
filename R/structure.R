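# PDB-format structure handling: mention-to-structure correspondence,
# surface filtering, interface definition, unbound/bound mapping.

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# van der Waals radii (A) by element; used for solvent accessibility
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

# Reference maximum accessible areas (A^2) of residue X in an extended
# Gly-X-Gly context (theoretical values of Tien et al. 2013), used to
# normalize absolute SASA to relative SASA.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Read a protein structure from PDB-format text
#'
#' Parses ATOM records of the first model, keeps standard amino-acid
#' residues only, and resolves alternate locations to the highest-occupancy
#' conformer (ties: first encountered). Reading is delegated to
#' \code{bio3d::read.pdb}.
#'
#' @param x Path to a PDB file, or a character scalar/vector of PDB-format
#'   text.
#' @return Object of class `structure_model`: a list with `atoms` (a
#'   data.frame with chain, resno, insert, resid, elety, element, x, y, z,
#'   o) and `residues` (one row per residue, keyed by chain/resno/insert).
#' @export
read_structure <- function(x) {
  path <- x
  if (length(x) > 1L || grepl("\n", x[1]) || !file.exists(x[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(x) > 1L) x else strsplit(x, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & toupper(at$resid) %in% names(AA3_TO_1), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records with standard amino-acid residues")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altLoc groups: keep highest occupancy, first on ties
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(idx) idx[which.max(at$o[idx])]),
                 use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z)))
    stop("non-finite coordinates")
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = toupper(at$resid), elety = at$elety,
                      element = substr(gsub("[0-9]", "", at$elety), 1, 1),
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      stringsAsFactors = FALSE)
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert)
  first <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                         insert = atoms$insert[first], resid = atoms$resid[first],
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure: %d chains (%s), %d residues, %d atoms>\n",
              length(unique(x$residues$chain)),
              paste(unique(x$residues$chain), collapse = ","),
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Write a structure model as PDB-format text
#'
#' Minimal ATOM-record writer for models produced by [read_structure()] or
#' the toy-complex generator.
#'
#' @param model A `structure_model`.
#' @param path Output path; if `NULL`, the lines are returned.
#' @export
write_structure <- function(model, path = NULL) {
  a <- model$atoms
  lines <- sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(a)),
                   ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
                   " ", a$resid, a$chain, a$resno,
                   ifelse(nzchar(a$insert), a$insert, " "),
                   a$x, a$y, a$z, a$o, 0, a$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Match a residue mention against a structure
#'
#' A mention matches iff some residue carries the identical author number
#' and 3-letter name; when the mention has a chain hint the search is
#' restricted to that chain.
#'
#' @param mention A [residue_mention()].
#' @param model A `structure_model`.
#' @return One-row data.frame (chain, resno, insert, resid) of the first
#'   matching residue, or `NULL`.
#' @export
match_mention <- function(mention, model) {
  r <- model$residues
  hit <- r$resno == mention$residue_number & r$resid == mention$residue_name
  if (!is.na(mention$chain_hint))
    hit <- hit & r$chain == mention$chain_hint
  if (!any(hit)) return(NULL)
  r[which(hit)[1], , drop = FALSE]
}

fib_sphere <- function(n) {
  # deterministic quasi-uniform points on the unit sphere (golden spiral)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley algorithm: each atom's sphere (vdW radius + probe) is
#' sampled with `n_points` deterministic quasi-uniform points; the
#' accessible area is the sphere area times the fraction of points not
#' buried inside any neighboring atom's expanded sphere.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sample points per atom.
#' @return Numeric vector of per-atom areas (A^2).
#' @export
sasa_atoms <- function(model, probe = 1.4, n_points = 960) {
  a <- model$atoms
  r <- VDW_RADII[a$element]
  r[is.na(r)] <- VDW_DEFAULT
  R <- unname(r) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- fib_sphere(n_points)
  n <- nrow(xyz)
  out <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  out
}

residue_rsasa <- function(model, probe = 1.4, n_points = 960) {
  area <- sasa_atoms(model, probe, n_points)
  key <- paste(model$atoms$chain, model$atoms$resno, model$atoms$insert)
  tot <- tapply(area, factor(key, levels = unique(key)), sum)
  rkey <- paste(model$residues$chain, model$residues$resno, model$residues$insert)
  ref <- MAX_ASA[model$residues$resid]
  unname(as.numeric(tot[rkey]) / ref)
}

#' Is a residue on the protein surface?
#'
#' A residue is on the surface iff its relative solvent-accessible area
#' (absolute SASA normalized by the extended-state reference area of the
#' residue type) is at least `rsasa_threshold`. Computed on the isolated
#' model as given; residues missing side-chain atoms are assessed on the
#' atoms present (with a warning).
#'
#' @param residue One-row data.frame (chain, resno) or list with `chain`
#'   and `resno` (optional `insert`).
#' @param model A `structure_model`.
#' @param rsasa_threshold Fraction in [0,1]; 0 marks every residue surface.
#' @param rsasa Optional precomputed vector from `residue_rsasa(model)` to
#'   avoid recomputation over many queries.
#' @return Logical.
#' @export
is_surface <- function(residue, model, rsasa_threshold = 0.05, rsasa = NULL) {
  if (is.null(rsasa)) rsasa <- residue_rsasa(model)
  ins <- residue$insert %||% ""
  idx <- which(model$residues$chain == residue$chain &
                 model$residues$resno == residue$resno &
                 model$residues$insert == ins)
  if (!length(idx)) stop("residue not in model")
  n_at <- sum(model$atoms$chain == residue$chain &
                model$atoms$resno == residue$resno &
                model$atoms$insert == ins)
  if (n_at < 2L && model$residues$resid[idx] != "GLY")
    warning("residue lacks side-chain atoms; rSASA computed on available atoms")
  rsasa[idx] >= rsasa_threshold
}

#' Interface residues of a two-chain complex
#'
#' A residue is at the interface iff any of its (heavy) atoms lies within
#' `cutoff` of any atom of the partner.
#'
#' @param receptor,ligand `structure_model` objects for the two partners.
#' @param cutoff Atom-atom distance cutoff in Angstrom.
#' @return List with `receptor` and `ligand`: data.frames (chain, resno,
#'   insert, resid) of interface residues, plus the `cutoff`.
#' @export
interface_residues <- function(receptor, ligand, cutoff = 6.0) {
  heavy <- function(m) m$atoms[m$atoms$element != "H", , drop = FALSE]
  ra <- heavy(receptor); la <- heavy(ligand)
  side <- function(a, b) {
    if (!nrow(a) || !nrow(b) || cutoff <= 0)
      return(a[0, c("chain", "resno", "insert", "resid")])
    ax <- as.matrix(a[, c("x", "y", "z")])
    bx <- as.matrix(b[, c("x", "y", "z")])
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), `+`) - 2 * ax %*% t(bx)
    close <- rowSums(d2 <= cutoff^2 + 1e-9) > 0
    key <- paste(a$chain, a$resno, a$insert)
    sel <- key %in% unique(key[close])
    unique(a[sel, c("chain", "resno", "insert", "resid")])
  }
  list(receptor = side(ra, la), ligand = side(la, ra), cutoff = cutoff)
}

chain_sequence <- function(model, chain) {
  r <- model$residues[model$residues$chain == chain, , drop = FALSE]
  list(seq = paste(AA3_TO_1[r$resid], collapse = ""), residues = r)
}

#' Map unbound-structure residues onto the bound structure
#'
#' Residue numbering and chain identifiers frequently differ between a
#' separately solved (unbound) monomer and the co-crystallized (bound)
#' complex. The correspondence is recovered by global sequence alignment
#' (identity scoring, affine gap penalties, via
#' \code{Biostrings::pairwiseAlignment}); aligned positions with identical
#' residues define the map, mismatched or unaligned positions are absent.
#'
#' @param unbound,bound `structure_model` objects.
#' @param unbound_chain,bound_chain Chain identifiers (defaults: first
#'   chain of each model).
#' @param min_identity Minimum alignment identity (fraction of the shorter
#'   sequence); below it the chains are declared non-corresponding.
#' @return data.frame with columns `unbound_resno`, `bound_resno`,
#'   `resid`.
#' @export
map_unbound_to_bound <- function(unbound, bound,
                                 unbound_chain = unbound$residues$chain[1],
                                 bound_chain = bound$residues$chain[1],
                                 min_identity = 0.30) {
  u <- chain_sequence(unbound, unbound_chain)
  b <- chain_sequence(bound, bound_chain)
  if (!nzchar(u$seq) || !nzchar(b$seq)) stop("empty chain sequence")
  letters20 <- unname(AA3_TO_1)
  submat <- matrix(-1, 20, 20, dimnames = list(letters20, letters20))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(u$seq), Biostrings::AAString(b$seq),
    type = "global", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ui <- cumsum(pa != "-")
  bi <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  ident <- both & pa == sa
  if (sum(ident) / min(nchar(u$seq), nchar(b$seq)) < min_identity)
    stop("chains do not correspond (alignment identity below ",
         min_identity * 100, "%)")
  data.frame(unbound_resno = u$residues$resno[ui[ident]],
             bound_resno = b$residues$resno[bi[ident]],
             resid = u$residues$resid[ui[ident]],
             stringsAsFactors = FALSE)
}
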