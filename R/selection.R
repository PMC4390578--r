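# Post-processing around external site-level selection analyses:
# alignment-confidence masking, positively-selected-site calling, dN/dS
# outlier exclusion, and AIC model selection.

#' Mask alignment columns by confidence
#'
#' Keeps the alignment columns whose estimated alignment confidence is at
#' least `threshold` (default 0.95): sites aligned to less than 95%
#' confidence are filtered out before any site-level selection analysis.
#' When a reference species is given, the induced mapping from kept columns
#' to 1-based ungapped reference coordinates is returned as well (columns
#' where the reference row is gapped map to `NA`).
#'
#' @param msa An [msa_confidence()] object.
#' @param threshold Minimum confidence to keep a column; the boundary value
#'   is kept.
#' @param ref_species Optional reference species name for the coordinate
#'   map.
#' @return A list of class `column_mask`: `kept_columns` (1-based integer
#'   vector) and, when `ref_species` is given, `ref_site_map` (a
#'   `data.frame` with `column` and `ref_site`).
#' @examples
#' m <- msa_confidence(c(human = "AWD", chimp = "AWD"), c(1.0, 0.94, 0.95))
#' mask_low_confidence(m)$kept_columns  # columns 1 and 3
#' @export
mask_low_confidence <- function(msa, threshold = 0.95, ref_species = NULL) {
  stopifnot(inherits(msa, "msa_conf"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  kept <- which(msa$col_conf >= threshold)
  out <- list(kept_columns = kept)
  if (!is.null(ref_species)) {
    if (!ref_species %in% names(msa$rows)) {
      stop("species '", ref_species, "' not present in alignment",
           call. = FALSE)
    }
    chars <- strsplit(msa$rows[[ref_species]], "", fixed = TRUE)[[1L]]
    ungapped <- cumsum(chars != "-")
    ungapped[chars == "-"] <- NA_integer_
    out$ref_site_map <- data.frame(column = kept,
                                   ref_site = ungapped[kept])
  }
  structure(out, class = "column_mask")
}

#' Call positively selected sites
#'
#' A (gene, site) pair is called as a positively selected site (PSS) when
#' the site table flags it as positively selected, its estimate carries
#' confidence of at least `conf_threshold` (default 0.95), and -- if a site
#' mask is supplied -- the site falls in a kept, confidently aligned
#' position. Raising either threshold can only shrink the called set.
#'
#' @param table A site table (see [read_site_table()]).
#' @param conf_threshold Minimum estimate confidence; the boundary value is
#'   kept.
#' @param kept_sites Optional mask: either an integer vector of kept
#'   ungapped reference site indices (applied to every gene), a
#'   `data.frame` with columns `gene` and `site`, or a `column_mask` from
#'   [mask_low_confidence()] (its non-`NA` `ref_site_map$ref_site` values
#'   are used). `NULL` applies no positional mask.
#' @return A [pss_set()].
#' @export
call_pss <- function(table, conf_threshold = 0.95, kept_sites = NULL) {
  table <- validate_site_table(table)
  keep <- table$positively_selected & table$confidence >= conf_threshold
  out <- table[keep, c("gene", "site"), drop = FALSE]
  if (!is.null(kept_sites)) {
    if (inherits(kept_sites, "column_mask")) {
      if (is.null(kept_sites$ref_site_map)) {
        stop("column_mask lacks a reference site map; call ",
             "mask_low_confidence() with ref_species", call. = FALSE)
      }
      kept_sites <- kept_sites$ref_site_map$ref_site
      kept_sites <- kept_sites[!is.na(kept_sites)]
    }
    if (is.data.frame(kept_sites)) {
      ok <- paste(out$gene, out$site, sep = "\r") %in%
        paste(kept_sites$gene, kept_sites$site, sep = "\r")
    } else {
      ok <- out$site %in% as.integer(kept_sites)
    }
    out <- out[ok, , drop = FALSE]
  }
  pss_set(out$gene, out$site)
}

#' Exclude outlying gene-level dN/dS estimates
#'
#' Removes genes whose estimated dN/dS exceeds `cap` (default 3): external
#' codon-model fits occasionally concentrate very high selection on a tiny
#' portion of a sequence, inflating the gene-level average. Values strictly
#' greater than the cap are excluded; a value exactly at the cap is
#' retained. Retained rows are returned unaltered.
#'
#' @param values A `data.frame` with columns `gene` and `omega` (dN/dS,
#'   >= 0).
#' @param cap Exclusion threshold (default 3.0).
#' @return The filtered `data.frame`.
#' @export
exclude_dnds_outliers <- function(values, cap = 3.0) {
  stopifnot(is.data.frame(values),
            all(c("gene", "omega") %in% names(values)), cap >= 0)
  if (nrow(values) > 0L) {
    stopifnot(!anyNA(values$omega), all(values$omega >= 0))
  }
  out <- values[values$omega <= cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a model by the Akaike information criterion
#'
#' AIC = 2k - 2 log L, penalizing fit by the number of free parameters;
#' the fit minimizing AIC is returned. Exact ties go to the model with
#' fewer parameters (and then to the earlier row, for determinism). The
#' choice is invariant to input order up to that tie rule.
#'
#' @param fits A `data.frame` with columns `model_name`, `log_likelihood`,
#'   `k` (>= 1); at least one row.
#' @return The selected one-row `data.frame`, with an added `aic` column.
#' @examples
#' fits <- data.frame(model_name = c("neutral", "selection"),
#'                    log_likelihood = c(-100, -99), k = c(1, 3))
#' aic_select(fits)  # AIC 202 beats 204
#' @export
aic_select <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1L,
            all(c("model_name", "log_likelihood", "k") %in% names(fits)),
            all(fits$k >= 1L))
  fits$aic <- 2 * fits$k - 2 * fits$log_likelihood
  ord <- order(fits$aic, fits$k, fits$model_name)
  out <- fits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict two alignments to their shared species
#'
#' Utility for matched-species comparisons between two ortholog sets for the
#' same gene: each alignment is reduced to the species present in both, so
#' downstream model fits see identical taxon samples. The statistical
#' fitting itself stays external.
#'
#' @param msa_a,msa_b [msa_confidence()] objects.
#' @return A list with elements `a` and `b`, the species-matched `msa_conf`
#'   objects.
#' @export
match_species <- function(msa_a, msa_b) {
  stopifnot(inherits(msa_a, "msa_conf"), inherits(msa_b, "msa_conf"))
  shared <- intersect(names(msa_a$rows), names(msa_b$rows))
  if (length(shared) == 0L) {
    stop("the two alignments share no species", call. = FALSE)
  }
  list(a = msa_confidence(msa_a$rows[shared], msa_a$col_conf),
       b = msa_confidence(msa_b$rows[shared], msa_b$col_conf))
}
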