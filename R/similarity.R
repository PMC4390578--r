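# Pairwise alignment and reference-denominated similarity scoring.

#' Construct an aligned pair
#'
#' A reference sequence globally aligned to one candidate: two equal-length
#' strings over residues and `-`, with no column gapped in both rows. This
#' is the unit of similarity scoring.
#'
#' @param ref_aln Aligned reference string.
#' @param cand_aln Aligned candidate string, same length.
#' @return An object of class `aligned_pair`.
#' @examples
#' aligned_pair("AWVA-TFD", "-WVRYTFD")
#' @export
aligned_pair <- function(ref_aln, cand_aln) {
  stopifnot(is.character(ref_aln), length(ref_aln) == 1L,
            is.character(cand_aln), length(cand_aln) == 1L)
  ref_aln <- toupper(ref_aln)
  cand_aln <- toupper(cand_aln)
  if (nchar(ref_aln) != nchar(cand_aln)) {
    stop("aligned strings differ in length (", nchar(ref_aln), " vs ",
         nchar(cand_aln), ")", call. = FALSE)
  }
  if (nchar(ref_aln) == 0L) stop("empty alignment", call. = FALSE)
  r <- strsplit(ref_aln, "", fixed = TRUE)[[1L]]
  k <- strsplit(cand_aln, "", fixed = TRUE)[[1L]]
  ok <- c(.VALID_RESIDUES, "-")
  bad <- setdiff(unique(c(r, k)), ok)
  if (length(bad) > 0L) {
    stop("illegal character(s) in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(r == "-" & k == "-")) {
    stop("alignment contains a gap-vs-gap column", call. = FALSE)
  }
  structure(list(ref = ref_aln, cand = cand_aln), class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("ref : ", x$ref, "\ncand: ", x$cand, "\n", sep = "")
  invisible(x)
}

.score_columns <- function(ref_chars, cand_chars, context = "pair") {
  keep <- ref_chars != "-"
  n <- sum(keep)
  if (n == 0L) {
    stop("no scorable sites: reference row is all gaps (", context, ")",
         call. = FALSE)
  }
  matches <- sum(ref_chars[keep] == cand_chars[keep])
  structure(list(value = matches / n, n_ref_sites = n),
            class = "similarity_score")
}

#' Reference-denominated percent identity
#'
#' The fraction of reference residues whose aligned partner is the identical
#' residue. Columns where the reference row carries a gap (a deletion in the
#' reference, or an insertion in the candidate) are ignored; a candidate gap
#' opposite a reference residue counts as a mismatch. The score is therefore
#' asymmetric: it is always denominated in the reference sequence.
#'
#' @param pair An [aligned_pair()].
#' @return An object of class `similarity_score`: a list with `value` in
#'   `[0, 1]` and `n_ref_sites`, the number of reference residues scored.
#' @examples
#' # Two mismatches over the seven reference residues: 5/7, about 71%
#' percent_identity(aligned_pair("AWVA-TFD", "-WVRYTFD"))
#' @export
percent_identity <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  .score_columns(strsplit(pair$ref, "", fixed = TRUE)[[1L]],
                 strsplit(pair$cand, "", fixed = TRUE)[[1L]])
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("similarity %.4f over %d reference site(s)\n",
              x$value, x$n_ref_sites))
  invisible(x)
}

#' Global pairwise alignment parameters
#'
#' Defaults are a standard protein substitution matrix with affine gap
#' penalties (BLOSUM62, gap opening 10, gap extension 0.5). These are
#' configuration, not hard-coded into the alignment step.
#'
#' @param substitution_matrix Name of a substitution matrix known to
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_opening,gap_extension Non-negative affine gap penalties.
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  stopifnot(gap_opening >= 0, gap_extension >= 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "align_params")
}

.residues_of <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "residues" %in% names(x))
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' Globally align a reference sequence to a candidate
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment()])
#' of the two residue strings under the configured substitution matrix and
#' affine gap penalties. Deterministic for fixed parameters: the dynamic
#' program resolves ties by a fixed traceback rule.
#'
#' @param ref,cand Sequence records (one-row record `data.frame`s) or plain
#'   residue strings; both non-empty.
#' @param params An [align_params()] object.
#' @return An [aligned_pair()] (reference row first).
#' @examples
#' pr <- align_pair("AWVATFD", "AWVRTFD")
#' percent_identity(pr)  # 6/7
#' @export
align_pair <- function(ref, cand, params = align_params()) {
  r <- toupper(.residues_of(ref))
  k <- toupper(.residues_of(cand))
  stopifnot(nchar(r) > 0L, nchar(k) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(r), Biostrings::AAString(k), type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  aligned_pair(as.character(Biostrings::alignedPattern(pa)),
               as.character(Biostrings::alignedSubject(pa)))
}

#' Percent identity between two rows of a full MSA
#'
#' Applies the same column rule as [percent_identity()] to two rows exactly
#' as they stand in the multiple sequence alignment: no pairwise
#' realignment is performed, so the score reflects the quality of the MSA
#' itself. Columns gapped in both rows (induced by other sequences) carry no
#' information about the pair and are dropped before scoring.
#'
#' @param msa An [msa_confidence()] object (or any list with a named `rows`
#'   character vector of equal-length aligned strings).
#' @param ref_species Species name of the reference row (the denominator).
#' @param other_species Species name of the row scored against it.
#' @return A `similarity_score`.
#' @export
msa_percent_identity <- function(msa, ref_species, other_species) {
  rows <- msa$rows
  for (sp in c(ref_species, other_species)) {
    if (!sp %in% names(rows)) {
      stop("species '", sp, "' not present in alignment", call. = FALSE)
    }
  }
  r <- strsplit(toupper(rows[[ref_species]]), "", fixed = TRUE)[[1L]]
  k <- strsplit(toupper(rows[[other_species]]), "", fixed = TRUE)[[1L]]
  both_gap <- r == "-" & k == "-"
  .score_columns(r[!both_gap], k[!both_gap],
                 context = paste0(ref_species, " vs ", other_species))
}
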