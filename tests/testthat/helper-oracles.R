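# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# --- exhaustive global-alignment oracle (tiny strings only) ----------------

# Enumerate every global alignment of two residue strings as pairs of
# aligned rows (no gap-vs-gap columns).
enumerate_alignments <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ac) && j > length(bc)) {
      return(list(list(ref = "", cand = "")))
    }
    out <- list()
    if (i <= length(ac) && j <= length(bc)) {
      for (tail in rec(i + 1, j + 1)) {
        out[[length(out) + 1]] <- list(ref = paste0(ac[i], tail$ref),
                                       cand = paste0(bc[j], tail$cand))
      }
    }
    if (i <= length(ac)) {
      for (tail in rec(i + 1, j)) {
        out[[length(out) + 1]] <- list(ref = paste0(ac[i], tail$ref),
                                       cand = paste0("-", tail$cand))
      }
    }
    if (j <= length(bc)) {
      for (tail in rec(i, j + 1)) {
        out[[length(out) + 1]] <- list(ref = paste0("-", tail$ref),
                                       cand = paste0(bc[j], tail$cand))
      }
    }
    out
  }
  rec(1, 1)
}

# Score one alignment under a substitution matrix and affine gaps
# (each maximal gap run of length L costs opening + L * extension).
score_alignment <- function(ref_aln, cand_aln, submat,
                            gap_opening = 10, gap_extension = 0.5) {
  r <- strsplit(ref_aln, "")[[1]]
  k <- strsplit(cand_aln, "")[[1]]
  total <- 0
  in_gap_r <- FALSE
  in_gap_k <- FALSE
  for (i in seq_along(r)) {
    if (r[i] == "-") {
      total <- total - gap_extension - if (in_gap_r) 0 else gap_opening
      in_gap_r <- TRUE
      in_gap_k <- FALSE
    } else if (k[i] == "-") {
      total <- total - gap_extension - if (in_gap_k) 0 else gap_opening
      in_gap_k <- TRUE
      in_gap_r <- FALSE
    } else {
      total <- total + submat[r[i], k[i]]
      in_gap_r <- FALSE
      in_gap_k <- FALSE
    }
  }
  total
}

best_alignment_score <- function(a, b, submat,
                                 gap_opening = 10, gap_extension = 0.5) {
  max(vapply(enumerate_alignments(a, b), function(al) {
    score_alignment(al$ref, al$cand, submat, gap_opening, gap_extension)
  }, numeric(1)))
}

# --- brute-force cluster-selection oracle ----------------------------------

# Exhaustively enumerate one-node-per-species selections and return the
# maximal objective (and one maximizing selection).
brute_force_optimum <- function(graph, weights) {
  by_sp <- split(graph$nodes$node_id, graph$nodes$species)
  combos <- expand.grid(by_sp, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  best <- -Inf
  best_sel <- NULL
  for (r in seq_len(nrow(combos))) {
    sel <- unlist(combos[r, , drop = FALSE])
    obj <- objective_of(sel, graph, weights)
    if (obj > best) {
      best <- obj
      best_sel <- sel
    }
  }
  list(objective = best, chosen = best_sel)
}

# --- random-instance generator ---------------------------------------------

# A random proposal graph with all cross-species candidate edges present,
# suitable for any weight scheme.
random_graph <- function(n_species, n_methods, ref_species = "human") {
  species <- paste0("sp", seq_len(n_species))
  nodes <- expand.grid(species = species,
                       method = paste0("m", seq_len(n_methods)),
                       stringsAsFactors = FALSE)
  nodes$node_id <- paste(nodes$species, nodes$method, sep = ":")
  nodes$seq_id <- nodes$node_id
  nodes$sim_to_ref <- round(runif(nrow(nodes)), 3)
  edges <- NULL
  if (nrow(nodes) > 1) {
    idx <- utils::combn(nrow(nodes), 2)
    keep <- nodes$species[idx[1, ]] != nodes$species[idx[2, ]]
    if (any(keep)) {
      edges <- data.frame(node_a = nodes$node_id[idx[1, keep]],
                          node_b = nodes$node_id[idx[2, keep]],
                          sim = round(runif(sum(keep)), 3),
                          stringsAsFactors = FALSE)
    }
  }
  ref <- sequence_record(paste0("ref_", ref_species), ref_species, "ref",
                         "AWVATFDAWVATFDAWVATFD")
  proposal_graph(ref, nodes[c("node_id", "species", "method", "seq_id",
                              "sim_to_ref")], edges)
}
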