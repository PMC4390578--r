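# Ortholog quality assessment: head-to-head percent-identity comparison,
# normalized Robinson-Foulds tree concordance with a CDF-area summary,
# functional concordance, and positively-selected-site overlap.

#' Head-to-head comparison of two percent identities
#'
#' One method outperforms another on a given ortholog slot when its percent
#' identity to the reference exceeds the other's by at least `margin`
#' (default five percentage points); otherwise the two are tied.
#'
#' @param pid_a,pid_b Percent identities in `[0, 1]` (vectorized).
#' @param margin Winning margin (default 0.05); the boundary counts as a
#'   win.
#' @return Character vector over `{"A_WINS", "B_WINS", "TIE"}`.
#' @examples
#' head_to_head(0.90, 0.85)  # exactly at the margin: A wins
#' head_to_head(0.90, 0.87)  # TIE
#' @export
head_to_head <- function(pid_a, pid_b, margin = 0.05) {
  stopifnot(is.numeric(pid_a), is.numeric(pid_b),
            all(pid_a >= 0 & pid_a <= 1), all(pid_b >= 0 & pid_b <= 1),
            margin >= 0)
  # guard against binary floating point (0.90 - 0.85 must count as >= 0.05)
  tol <- 1e-9
  d <- pid_a - pid_b
  ifelse(d >= margin - tol, "A_WINS",
         ifelse(-d >= margin - tol, "B_WINS", "TIE"))
}

# Non-trivial bipartitions (splits) of an unrooted leaf-labeled tree, as
# canonical keys. Each internal edge splits the leaves in two; the side not
# containing the alphabetically first label is sorted and serialized.
.nontrivial_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(labs)[1L]
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1L))
  unique(keys[!is.na(keys)])
}

#' Normalized Robinson-Foulds distance between a gene tree and a species tree
#'
#' Both trees are treated as unrooted and first pruned to their shared leaf
#' set (at least four shared leaves are required for the distance to be
#' defined). The unweighted RF distance is the number of non-trivial splits
#' present in exactly one of the two trees; it is normalized by the sum of
#' the non-trivial split counts of the two pruned trees, giving a value in
#' `[0, 1]` (0 = identical topologies, 1 = no shared split). Larger values
#' mean worse agreement between the gene tree and the known species tree.
#'
#' @param gene_tree,species_tree [ape::phylo] trees with overlapping leaf
#'   label sets.
#' @return A number in `[0, 1]`. If neither pruned tree has any internal
#'   split (both are stars), the trees are trivially concordant and 0 is
#'   returned.
#' @examples
#' g <- ape::read.tree(text = "((a,b),(c,d));")
#' s <- ape::read.tree(text = "((a,c),(b,d));")
#' normalized_rf(g, s)  # 2 / (1 + 1) = 1
#' @export
normalized_rf <- function(gene_tree, species_tree) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (anyDuplicated(gene_tree$tip.label) ||
      anyDuplicated(species_tree$tip.label)) {
    stop("duplicate leaf labels", call. = FALSE)
  }
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4L) {
    stop("fewer than 4 shared leaves (", length(shared),
         "); RF distance undefined", call. = FALSE)
  }
  g <- ape::keep.tip(gene_tree, shared)
  s <- ape::keep.tip(species_tree, shared)
  sg <- .nontrivial_splits(g)
  ss <- .nontrivial_splits(s)
  denom <- length(sg) + length(ss)
  if (denom == 0L) return(0)
  rf <- length(setdiff(sg, ss)) + length(setdiff(ss, sg))
  rf / denom
}

#' Area under the empirical CDF of normalized RF distances
#'
#' Summarizes a genome-wide distribution of normalized RF distances by the
#' exact area under the right-continuous empirical CDF over `[0, limit)`
#' (default limit 0.4). Compared with the proportion of genes below a fixed
#' threshold, this up-weights small RF distances rather than weighting all
#' sub-threshold values equally. Higher values indicate better tree
#' concordance; the maximum is `limit` (every distance 0) and the minimum 0
#' (every distance at or beyond `limit`).
#'
#' @param values Numeric vector of normalized RF distances in `[0, 1]`.
#' @param limit Upper integration limit (default 0.4).
#' @return A number in `[0, limit]`.
#' @examples
#' rf_cdf_auc(c(0.1, 0.3))  # 0.5 * 0.2 + 1 * 0.1 = 0.2
#' @export
rf_cdf_auc <- function(values, limit = 0.4) {
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values),
            all(values >= 0), limit > 0)
  breaks <- c(0, sort(unique(values[values < limit])), limit)
  breaks <- unique(breaks)
  auc <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    auc <- auc + mean(values <= breaks[i]) * (breaks[i + 1L] - breaks[i])
  }
  auc
}

#' Functional concordance of two annotated sequences
#'
#' A binary agreement measure: a candidate ortholog is concordant with the
#' reference when both carry a top-scoring protein-family annotation and the
#' family labels are equal. If either sequence lacks a top hit the
#' comparison is undefined.
#'
#' @param annot Annotation `data.frame` from [read_annotations()] (columns
#'   `seq_id`, `family`).
#' @param ref_id,cand_id Sequence identifiers to compare.
#' @return One of `"CONCORDANT"`, `"DISCORDANT"`, `"UNDEFINED"`.
#' @export
functional_concordance <- function(annot, ref_id, cand_id) {
  stopifnot(is.data.frame(annot),
            all(c("seq_id", "family") %in% names(annot)))
  fam <- setNames(annot$family, annot$seq_id)
  a <- if (ref_id %in% names(fam)) fam[[ref_id]] else NA_character_
  b <- if (cand_id %in% names(fam)) fam[[cand_id]] else NA_character_
  if (is.na(a) || is.na(b)) return("UNDEFINED")
  if (a == b) "CONCORDANT" else "DISCORDANT"
}

#' Construct a set of positively selected sites
#'
#' @param gene Character vector of gene identifiers.
#' @param site Integer vector of 1-based ungapped reference site indices,
#'   same length.
#' @return A `data.frame` of class `pss_set` with one row per unique
#'   (gene, site) pair.
#' @export
pss_set <- function(gene = character(0), site = integer(0)) {
  stopifnot(length(gene) == length(site))
  if (length(site) > 0L) {
    stopifnot(!anyNA(site), all(site >= 1L), all(site == as.integer(site)))
  }
  out <- unique(data.frame(gene = as.character(gene),
                           site = as.integer(site),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("pss_set", "data.frame")
  out
}

#' Jaccard overlap of two sets of positively selected sites
#'
#' The size of the intersection of the two (gene, site) sets divided by the
#' size of their union. Undefined (an error) when both sets are empty.
#'
#' @param a,b [pss_set()] objects (or `data.frame`s with columns `gene`,
#'   `site`).
#' @return A number in `[0, 1]`.
#' @export
pss_overlap <- function(a, b) {
  ka <- unique(paste(a$gene, a$site, sep = "\r"))
  kb <- unique(paste(b$gene, b$site, sep = "\r"))
  union_n <- length(union(ka, kb))
  if (union_n == 0L) {
    stop("overlap undefined: both site sets are empty", call. = FALSE)
  }
  length(intersect(ka, kb)) / union_n
}
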