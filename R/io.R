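# Readers/writers for the external formats the toolkit touches.
# All parsers validate strictly and reject malformed input; nothing is
# silently repaired.

# 20 standard amino acids; X = unknown residue. Gaps are forbidden in
# unaligned sequence records.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.VALID_RESIDUES <- c(.AA20, "X")

.check_residues <- function(residues, id = "<sequence>") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      nchar(residues) == 0L) {
    stop("sequence '", id, "': residues must be a non-empty string",
         call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .VALID_RESIDUES)
  if (length(bad) > 0L) {
    stop("sequence '", id, "': illegal residue character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(residues)
}

#' Construct a sequence record
#'
#' A sequence record is one row of the canonical record table used across the
#' package: an identifier, the species it comes from, the ortholog-detection
#' method that proposed it, and its amino-acid residues (one-letter codes,
#' the 20 standard amino acids plus `X`; gaps are not allowed).
#'
#' @param seq_id Sequence identifier (unique within one FASTA source).
#' @param species Species label.
#' @param method Label of the ortholog-detection method that proposed the
#'   sequence (use `"ref"` for the reference sequence itself).
#' @param residues Amino-acid string; uppercased on input.
#' @return A one-row `data.frame` with columns `seq_id`, `species`, `method`,
#'   `residues`.
#' @examples
#' sequence_record("g1_chimp", "chimp", "BLAT", "AWVRTFD")
#' @export
sequence_record <- function(seq_id, species, method, residues) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L, nzchar(seq_id),
            is.character(species), length(species) == 1L, nzchar(species),
            is.character(method), length(method) == 1L, nzchar(method))
  residues <- toupper(residues)
  .check_residues(residues, seq_id)
  data.frame(seq_id = seq_id, species = species, method = method,
             residues = residues, stringsAsFactors = FALSE)
}

#' Read sequence records from FASTA
#'
#' Headers follow the fixed pipe-delimited dialect `>seqid|species|method`.
#' Residues are uppercased; anything outside the 20 amino acids plus `X`
#' (gaps included) is rejected, as are duplicate `seq_id`s within one file.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of records in file order (columns `seq_id`,
#'   `species`, `method`, `residues`); zero rows for an empty file.
#' @seealso [write_ortho_fasta()], [sequence_record()]
#' @export
read_ortho_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  empty <- data.frame(seq_id = character(0), species = character(0),
                      method = character(0), residues = character(0),
                      stringsAsFactors = FALSE)
  if (length(set) == 0L) return(empty)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 3L)) {
    bad <- headers[n_fields != 3L][1L]
    stop("malformed FASTA header (expected 'seqid|species|method'): '",
         bad, "' in ", path, call. = FALSE)
  }
  fields <- do.call(rbind, fields)
  if (any(!nzchar(fields))) {
    bad <- headers[apply(fields, 1L, function(f) any(!nzchar(f)))][1L]
    stop("FASTA header with empty field: '", bad, "' in ", path,
         call. = FALSE)
  }
  out <- data.frame(seq_id = fields[, 1L], species = fields[, 2L],
                    method = fields[, 3L],
                    residues = toupper(as.character(set)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$seq_id)) {
    stop("duplicate seq_id in ", path, ": ",
         out$seq_id[duplicated(out$seq_id)][1L], call. = FALSE)
  }
  for (i in seq_len(nrow(out))) .check_residues(out$residues[i], out$seq_id[i])
  rownames(out) <- NULL
  out
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_ortho_fasta()]; headers are `seqid|species|method`.
#'
#' @param records A record `data.frame` as returned by [read_ortho_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortho_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("seq_id", "species", "method", "residues") %in%
                  names(records)))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- paste(records$seq_id, records$species, records$method,
                      sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a proposal set
#'
#' A proposal set holds every candidate ortholog proposed for one reference
#' gene: the reference sequence itself plus at most one candidate per
#' (species, method) pair. The reference species never appears among the
#' candidates.
#'
#' @param ref_gene Reference gene identifier.
#' @param ref A one-row record `data.frame` for the reference sequence.
#' @param candidates A record `data.frame` of candidates (possibly zero
#'   rows).
#' @return An object of class `proposal_set`.
#' @export
proposal_set <- function(ref_gene, ref, candidates) {
  stopifnot(is.character(ref_gene), length(ref_gene) == 1L,
            is.data.frame(ref), nrow(ref) == 1L,
            is.data.frame(candidates))
  if (nrow(candidates) > 0L) {
    if (any(candidates$species == ref$species)) {
      stop("reference species '", ref$species,
           "' may not appear among candidates", call. = FALSE)
    }
    key <- paste(candidates$species, candidates$method, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- candidates[duplicated(key), , drop = FALSE][1L, ]
      stop("duplicate candidate for (", dup$species, ", ", dup$method,
           ") in gene ", ref_gene, call. = FALSE)
    }
  }
  structure(list(ref_gene = ref_gene, ref = ref, candidates = candidates),
            class = "proposal_set")
}

#' @export
print.proposal_set <- function(x, ...) {
  cat("Proposal set for gene ", x$ref_gene, " (reference: ", x$ref$species,
      ", ", nchar(x$ref$residues), " aa)\n", sep = "")
  cat("  ", nrow(x$candidates), " candidate(s) from ",
      length(unique(x$candidates$species)), " species / ",
      length(unique(x$candidates$method)), " method(s)\n", sep = "")
  invisible(x)
}

#' Read ortholog proposal tables
#'
#' The proposal TSV has exactly the columns `ref_gene`, `species`, `method`,
#' `seq_id`; every `seq_id` must resolve in the supplied FASTA sources. Rows
#' are grouped by `ref_gene` into one [proposal_set()] each, taking the row
#' whose species equals `ref_species` as the reference sequence.
#'
#' @param tsv_path Path to the proposal TSV.
#' @param fasta_paths Character vector of FASTA paths
#'   (see [read_ortho_fasta()]).
#' @param ref_species Name of the reference species (default `"human"`).
#' @return A named list of `proposal_set` objects, one per reference gene.
#' @export
read_proposals <- function(tsv_path, fasta_paths, ref_species = "human") {
  stopifnot(file.exists(tsv_path), length(fasta_paths) >= 1L)
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("ref_gene", "species", "method", "seq_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("proposal table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seqs <- do.call(rbind, lapply(fasta_paths, read_ortho_fasta))
  seqs <- seqs[!duplicated(seqs$seq_id), , drop = FALSE]
  lookup <- setNames(seqs$residues, seqs$seq_id)
  unresolved <- setdiff(tab$seq_id, names(lookup))
  if (length(unresolved) > 0L) {
    stop("seq_id(s) not found in FASTA sources: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  key <- paste(tab$ref_gene, tab$species, tab$method, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate proposal row for (", dup$ref_gene, ", ", dup$species,
         ", ", dup$method, ")", call. = FALSE)
  }
  out <- lapply(split(tab, tab$ref_gene), function(rows) {
    is_ref <- rows$species == ref_species
    if (sum(is_ref) == 0L) {
      stop("gene ", rows$ref_gene[1L], ": no row for reference species '",
           ref_species, "'", call. = FALSE)
    }
    if (sum(is_ref) > 1L) {
      stop("gene ", rows$ref_gene[1L],
           ": more than one reference-species row", call. = FALSE)
    }
    ref_row <- rows[is_ref, , drop = FALSE]
    cand_rows <- rows[!is_ref, , drop = FALSE]
    ref <- sequence_record(ref_row$seq_id, ref_row$species, ref_row$method,
                           lookup[[ref_row$seq_id]])
    candidates <- data.frame(seq_id = cand_rows$seq_id,
                             species = cand_rows$species,
                             method = cand_rows$method,
                             residues = unname(lookup[cand_rows$seq_id]),
                             stringsAsFactors = FALSE)
    rownames(candidates) <- NULL
    proposal_set(rows$ref_gene[1L], ref, candidates)
  })
  out[unique(tab$ref_gene)]
}

#' Read a multiple sequence alignment with per-column confidences
#'
#' The alignment is an aligned FASTA whose headers are species names; the
#' confidence sidecar is a plain-text file with one value per alignment
#' column, each in `[0, 1]`.
#'
#' @param aln_path Path to the aligned FASTA.
#' @param conf_path Path to the confidence sidecar.
#' @return An object of class `msa_conf`: a list with `rows` (named character
#'   vector, species to aligned string) and `col_conf` (numeric).
#' @export
read_msa_confidence <- function(aln_path, conf_path) {
  stopifnot(file.exists(aln_path), file.exists(conf_path))
  set <- Biostrings::readBStringSet(aln_path)
  rows <- setNames(toupper(as.character(set)), names(set))
  conf <- scan(conf_path, what = numeric(), quiet = TRUE)
  msa_confidence(rows, conf)
}

#' Construct an MSA-with-confidence object
#'
#' @param rows Named character vector: species name to aligned string
#'   (residues and `-`), all the same length.
#' @param col_conf Numeric vector of per-column alignment confidences in
#'   `[0, 1]`, one per alignment column.
#' @return An object of class `msa_conf`.
#' @export
msa_confidence <- function(rows, col_conf) {
  stopifnot(is.character(rows), length(rows) >= 1L,
            !is.null(names(rows)), all(nzchar(names(rows))))
  if (anyDuplicated(names(rows))) {
    stop("duplicate species in alignment: ",
         names(rows)[duplicated(names(rows))][1L], call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(col_conf) || length(col_conf) != widths[1L]) {
    stop("confidence sidecar has ", length(col_conf),
         " value(s) but alignment has ", widths[1L], " column(s)",
         call. = FALSE)
  }
  if (anyNA(col_conf) || any(col_conf < 0) || any(col_conf > 1)) {
    stop("column confidences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(rows = rows, col_conf = as.numeric(col_conf)),
            class = "msa_conf")
}

#' Write an MSA-with-confidence object
#'
#' @param msa An `msa_conf` object.
#' @param aln_path,conf_path Output paths for the aligned FASTA and the
#'   confidence sidecar.
#' @return `aln_path`, invisibly.
#' @export
write_msa_confidence <- function(msa, aln_path, conf_path) {
  stopifnot(inherits(msa, "msa_conf"))
  set <- Biostrings::BStringSet(msa$rows)
  names(set) <- names(msa$rows)
  Biostrings::writeXStringSet(set, aln_path)
  writeLines(format(msa$col_conf, trim = TRUE, scientific = FALSE),
             conf_path)
  invisible(aln_path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that additionally rejects duplicate
#' leaf labels, which would make split comparison ill-defined.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path,
                          call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree in ", path, call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s) in ", path, ": ",
         tree$tip.label[duplicated(tree$tip.label)][1L], call. = FALSE)
  }
  tree
}

#' Read or write a site-level selection table
#'
#' The TSV has columns `gene`, `site` (1-based index over the ungapped
#' reference sequence), `omega` (the dN/dS estimate, >= 0), `confidence`
#' (in `[0, 1]`), and `positively_selected` (logical). One row per
#' (gene, site).
#'
#' @param path Path to the TSV.
#' @return `read_site_table()`: a validated `data.frame` with the columns
#'   above. `write_site_table()`: `path`, invisibly.
#' @export
read_site_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "site", "omega", "confidence", "positively_selected")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("site table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$gene <- as.character(tab$gene)
  tab$positively_selected <- as.logical(tab$positively_selected)
  validate_site_table(tab[required])
}

validate_site_table <- function(tab) {
  if (nrow(tab) > 0L) {
    if (anyNA(tab$site) || any(tab$site < 1L) ||
        any(tab$site != as.integer(tab$site))) {
      stop("site indices must be integers >= 1", call. = FALSE)
    }
    if (anyNA(tab$omega) || any(tab$omega < 0)) {
      stop("omega (dN/dS) must be >= 0", call. = FALSE)
    }
    if (anyNA(tab$confidence) || any(tab$confidence < 0) ||
        any(tab$confidence > 1)) {
      stop("confidence must lie in [0, 1]", call. = FALSE)
    }
    if (anyNA(tab$positively_selected)) {
      stop("positively_selected must be TRUE/FALSE", call. = FALSE)
    }
    if (anyDuplicated(paste(tab$gene, tab$site, sep = "\r"))) {
      stop("duplicate (gene, site) row in site table", call. = FALSE)
    }
  }
  tab$site <- as.integer(tab$site)
  rownames(tab) <- NULL
  tab
}

#' @rdname read_site_table
#' @param tab A site table `data.frame`.
#' @export
write_site_table <- function(tab, path) {
  tab <- validate_site_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional annotation table
#'
#' TSV with columns `seq_id` and `family` (the top-scoring protein-family
#' hit, e.g. a Pfam accession). Rows with a blank or missing family are
#' treated as unannotated and dropped.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `seq_id`, `family`; one row per
#'   annotated sequence.
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(c("seq_id", "family"), names(tab))
  if (length(missing_cols) > 0L) {
    stop("annotation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[!is.na(tab$family) & nzchar(tab$family),
             c("seq_id", "family"), drop = FALSE]
  if (anyDuplicated(tab$seq_id)) {
    stop("duplicate seq_id in annotation table: ",
         tab$seq_id[duplicated(tab$seq_id)][1L], call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Read model-fit summaries
#'
#' TSV with columns `model_name`, `log_likelihood`, `k` (number of free
#' parameters, >= 1), as produced by external codon-model fitting; the rows
#' feed [aic_select()].
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame`.
#' @export
read_model_fits <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("model_name", "log_likelihood", "k")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("model-fit table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) > 0L && (anyNA(tab$k) || any(tab$k < 1L))) {
    stop("k (free parameters) must be >= 1", call. = FALSE)
  }
  tab[required]
}
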