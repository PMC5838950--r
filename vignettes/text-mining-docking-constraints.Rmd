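---
title: "From literature abstracts to docking constraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From literature abstracts to docking constraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdock)
```

# The model

`tmdock` treats literature mining for docking as a cascade of filters
over residue mentions. A *mention* is a textual occurrence of an
amino-acid residue with an author residue number; a mention is *useful*
when that residue sits at the interface of the protein–protein complex
being modeled. The package's job is to keep useful mentions and purge
the rest, then convert what survives into weighted docking constraints.

The cascade and its assumptions:

* **Structure correspondence.** A mention must match a residue (same
  3-letter name and author number, optionally restricted by a chain
  hint) in the PDB-format structure of either partner, and must be
  solvent-exposed in the isolated monomer. The assumption is that
  authors use the deposited numbering — mentions using a different
  numbering scheme are lost here, which is a known source of false
  negatives.
* **Grammatical proximity carries evidence.** In a constituency parse
  tree of the sentence, a residue grammatically close to binding-site
  vocabulary (*bind*, *interfac*, *pocket*, ...) is likely an interface
  residue, and one close to vocabulary about unrelated processes
  (*phosphory*, *alloster*, *IgG1*, ...) likely is not. This is
  quantified by the inverse-distance score
  $S_X = \sum_i 1/d^{+}_{Xi} - \sum_j 1/d^{-}_{Xj}$ over all keyword
  occurrences among the leaves, with $d$ the edge count on the tree
  path. Two distinct leaves are never closer than 2 edges, so each term
  contributes at most 1/2; a leaf that is itself a residue mention never
  counts as a keyword.
* **Context sentences corroborate.** The sentences immediately before
  and after a residue-containing sentence often carry the binding-site
  message even when the residue sentence does not. Method 2 uses them as
  a hard conjunction (keyword presence required); Method 3 lets a
  classifier weigh them via root-anchored keyword scores (the $S_X$
  analogue measured from the sentence root) and protein-name presence
  scores $S_{prot} \in \{0, 1, 2\}$.
* **Provenance grades confidence.** An abstract retrieved by the
  AND-query (both protein names) ties the residue to *this* interaction
  more strongly than an OR-query abstract. The basic confidence ladder
  is $f(R) = \min(10, \sum_i a_i)$ with $a_i = 2$ for AND and 1 for OR;
  the NLP ladder re-ranks within categories (10 = AND and passes the
  NLP filter, 8 = AND, 6 = OR and passes, otherwise
  $\max(5, \text{abstract count})$). The cap keeps the range [1, 10] and
  damps residues that are merely famous.

# Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `rsasa_threshold` | 0.05 | fraction | relative SASA above which a residue counts as surface; permissive on purpose — the stage should discard only clearly buried residues |
| interface `cutoff` | 6.0 | Å | any heavy-atom pair within this distance marks both residues as interface |
| `sx_threshold` | 0.25 | — | strict inequality: $S_X > 0.25$ keeps; interface residues empirically concentrate above this value |
| similarity thresholds | 20 / 0.2 / 0.11 | — | Lesk / Lin / Path, strict; against the concept words "touch" and "site" |
| SVM | RBF, γ = 16, C = 1 | — | the kernel/width that performed best for this task; C is not tuned |
| `split_fraction` | 0.5 | — | stratified-by-label random train/validation split, seeded |
| constraints `k` | 5 | residues | top residues per protein used as constraints |
| reference pairs | 3 | pairs | closest interface pairs by Cα–Cα distance, each side at f = 10 |
| success | ≤ 5 Å in top 10 | — | i-RMSD criterion, non-strict at the boundary |

# Numerical and procedural choices

* **Mention grammar.** Case-insensitive 3-letter codes and full residue
  names, joined to the number directly or by a space/hyphen; uppercase
  1-letter codes followed by digits (disable with `one_letter = FALSE`
  if single-letter gene or strain symbols cause false hits); mutation
  notation yields the wild-type mention only; a single uppercase letter
  directly appended to the number of a 3-letter form is a chain hint.
  The grammar deliberately over-generates slightly ("His6" in
  "His6-tag" is excluded only because the hyphenated token does not
  match); the structure-correspondence stage absorbs such false hits.
* **Lemma matching.** Dictionary entries are stems: all-lowercase
  lemmas of length ≥ 4 match as case-insensitive prefixes anchored at
  the token start; shorter or mixed-case entries (Fc, IgG1) match whole
  tokens case-sensitively. This keeps "interfac" matching
  "interfacial" while preventing "Fc" from matching inside ordinary
  words.
* **Similarity provider.** The three measures (Lesk extended gloss
  overlap, Lin information content, Path) are computed over a pluggable
  lexical database. The packaged provider is a hand-built synthetic
  taxonomy of ~50 domain words (`inst/extdata/similarity_lexicon.json`)
  so that all three measures run deterministically offline; it is a
  fixture with the right *shape* (near-synonyms score high, cross-branch
  pairs score low), not a WordNet substitute, and any database exported
  in the same JSON schema can be swapped in. Aggregation across the two
  concept words is `max` — any qualifying score suffices — with `mean`
  available as an option.
* **Threshold strictness.** All keep/drop comparisons ($S_X$,
  similarity) are strict (`>`), so a score exactly at the threshold
  drops.
* **Surface criterion.** Shrake–Rupley with 960 deterministic
  quasi-uniform (golden-spiral) points per atom, probe 1.4 Å, vdW radii
  by element, normalized by extended-state reference areas (Tien et al.
  2013 theoretical values). Tests hold the implementation to within 2%
  of a dense random-sampling oracle.
* **Unbound↔bound mapping.** Global sequence alignment (identity
  scoring, affine gaps, via `Biostrings::pairwiseAlignment`); only
  aligned, identical positions enter the residue map, and alignments
  under 30% identity are rejected as non-corresponding chains.
* **Missing parse trees.** When the (pluggable) parser failed on a
  sentence, tree-based filters abstain and the mention passes through
  with a warning; `strict = TRUE` drops instead. Abstention avoids
  silently discarding data because a parser hiccupped.
* **Ties.** Constraint selection orders by f, then AND-evidence, then
  abstract count, then residue number; reference pairs tie-break on
  (receptor resno, ligand resno); pose re-ranking is a stable sort with
  the raw rank as tie-break, so an empty constraint set preserves the
  original order exactly.
* **Eq-ladder fallback cap.** The OR-category fallback
  $\max(5, \text{count})$ is additionally capped at 10 so that a heavily
  cited residue cannot outrank the AND + NLP tier and the stated [1, 10]
  range is preserved.
* **ΔN endpoints.** $\Delta N(0)$ and $\Delta N(1)$ count complexes with
  P_TM exactly 0 or exactly 1 (all false / all true positives);
  complexes whose every abstract was purged have undefined P_TM and are
  excluded on both sides. Histogram plots use ten equal right-closed
  bins.

# What the synthetic generator emulates — and what it does not

`generate_corpus()` builds abstracts from ~12 fixed sentence skeletons
whose bracketed parses are emitted alongside, so leaves always equal
tokens. It plants the statistical structure the filters exploit:

* interface mentions sit within tree distance 4–6 of two or three
  positive keywords (giving $S_X \approx 0.39$–0.7) with probability
  `p_keyword_near_interface`, and otherwise in keyword-free sentences
  ($S_X = 0$);
* non-interface mentions sit near negative keywords ($S_X < 0$) with
  probability `p_negword_near_noninterface`, and otherwise in
  misleadingly positive sentences — the hard cases that separate the
  SVM from the threshold rule;
* context sentences carry positive keywords and protein names more
  often around interface mentions (0.8 / 0.8 by default) than
  non-interface ones (0.15 / 0.2).

Defaults are 200 complexes, 3 abstracts each, one mention per abstract,
a 0.5 interface rate, 0.9 keyword-placement probabilities and a 0.3
AND-query rate — a regime in which roughly 10% of mentions are
misclassified by the $S_X$ threshold alone and recoverable from context,
mirroring the qualitative gap between the rule-based and learned
filters. What the generator does **not** emulate: realistic English
prose and parser noise, retrieval statistics, residue co-mention
correlations, numbering discrepancies between abstracts and structures,
or real lexical diversity. A green test suite therefore shows the
machinery is correct and the learned filter exploits context *when the
signal is present*; it does not certify performance on PubMed text.

`generate_toy_complex()` builds Cα + pseudo-side-chain chains with an
exactly known interface (contact pairs at 5.5 Å, next-nearest pairs at
6.7 Å, so the 6 Å cutoff is unambiguous), and unbound forms with
isotropic Gaussian coordinate noise (σ = 0.5 Å by default), shifted
numbering and renamed chains. `generate_pose_set()` scatters decoys
15–45 Å around the receptor and perturbs a small fraction of poses
near the native placement, with uninformative raw scores — emulating a
low-resolution scan where near-native poses exist but are not
top-ranked, which is exactly the situation constraints are meant to
rescue.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so a
full run completes in minutes on one CPU: 200-complex corpora (600
abstracts, ~1800 sentences) for the filter-recovery checks over five
seeds; 1000 random trees (≤ 25 leaves) for the score-oracle
equivalence; 10,000 random confusion matrices for the metric algebra;
500-pose sets over a 30-residue toy complex for the docking checks; and
12 toy complexes × 300 poses for the success-rate comparison. The
package itself has no scale-dependent logic — the same functions accept
corpora and structures of any size.

# Known limitations

* No live retrieval: abstracts are ingested from files; an E-utilities
  client is out of scope, as are full-text articles.
* No bundled constituency parser: parse trees come from a sidecar file
  or any external parser producing bracketed S-expressions; without
  trees only the dictionary and similarity filters are available.
* The packaged similarity lexicon is a small synthetic fixture; results
  with it characterize the mechanism, not WordNet behavior.
* Protein-name matching is list-based (names + synonyms, word-boundary,
  case-insensitive); no named-entity normalization is attempted.
* mmCIF, hetero-atoms, multi-model ensembles beyond the first model,
  and quaternary-assembly generation are out of scope on the structure
  side; the docking scan itself (e.g. FFT rigid-body search) is
  external — the package generates, re-ranks and evaluates constraints
  around it.
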