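# Core integration: build the proposal graph, filter it with species
# cutoffs, and select at most one ortholog per species by cyclic coordinate
# descent (CCD) with random restarts.

#' Species-pair weight scheme
#'
#' Weights let sequences from different species contribute unequally to the
#' cluster objective. `reference_only` gives weight 1 to every
#' reference-candidate pair and 0 to all candidate-candidate pairs, in which
#' case optimization reduces to taking, per species, the candidate most
#' similar to the reference. `uniform_pairwise` gives all cross-species
#' pairs weight 1 (maximizing total, hence average, pairwise similarity).
#' `custom` supplies explicit non-negative weights per unordered species
#' pair; unlisted pairs get 0.
#'
#' @param mode One of `"reference_only"`, `"uniform_pairwise"`, `"custom"`.
#' @param ref_species Reference species name.
#' @param pairs For `custom`: a `data.frame` with columns `species_a`,
#'   `species_b`, `weight` (>= 0).
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(mode = c("reference_only", "uniform_pairwise",
                                   "custom"),
                          ref_species = "human", pairs = NULL) {
  mode <- match.arg(mode)
  w <- NULL
  if (mode == "custom") {
    stopifnot(is.data.frame(pairs),
              all(c("species_a", "species_b", "weight") %in% names(pairs)),
              all(pairs$weight >= 0))
    key <- vapply(seq_len(nrow(pairs)), function(i) {
      paste(sort(c(pairs$species_a[i], pairs$species_b[i])), collapse = "\r")
    }, character(1L))
    if (anyDuplicated(key)) stop("duplicate species pair in custom weights",
                                 call. = FALSE)
    w <- setNames(pairs$weight, key)
  }
  structure(list(mode = mode, ref_species = ref_species, w = w),
            class = "weight_scheme")
}

#' Look up the weight of one species pair
#'
#' @param ws A [weight_scheme()].
#' @param sp_a,sp_b Species names (order irrelevant).
#' @return A non-negative weight.
#' @export
pair_weight <- function(ws, sp_a, sp_b) {
  stopifnot(inherits(ws, "weight_scheme"))
  if (sp_a == sp_b) return(0)
  switch(ws$mode,
         reference_only =
           if (sp_a == ws$ref_species || sp_b == ws$ref_species) 1 else 0,
         uniform_pairwise = 1,
         custom = {
           key <- paste(sort(c(sp_a, sp_b)), collapse = "\r")
           if (key %in% names(ws$w)) unname(ws$w[[key]]) else 0
         })
}

#' Species-specific similarity cutoff table
#'
#' Pre-integration filter thresholds on the pairwise similarity of each
#' candidate to the reference. The shipped defaults are percent-identity
#' cutoffs tuned for a human reference against its primate and mammal
#' relatives -- chimp 0.82, gorilla 0.77, orangutan 0.75, rhesus 0.73 -- with
#' 0.70 for any other species; all are overridable. A candidate is retained
#' when its similarity to the reference is greater than or equal to the
#' cutoff for its species.
#'
#' @param species Named numeric vector of per-species cutoffs in `[0, 1]`.
#' @param default Cutoff for species not listed.
#' @return An object of class `cutoff_table`.
#' @export
cutoff_table <- function(species = c(chimp = 0.82, gorilla = 0.77,
                                     orangutan = 0.75, rhesus = 0.73),
                         default = 0.70) {
  stopifnot(is.numeric(default), length(default) == 1L,
            default >= 0, default <= 1)
  if (length(species) > 0L) {
    stopifnot(is.numeric(species), !is.null(names(species)),
              all(nzchar(names(species))),
              all(species >= 0), all(species <= 1))
  }
  structure(list(species = species, default = default),
            class = "cutoff_table")
}

#' @rdname cutoff_table
#' @param cutoffs A `cutoff_table`.
#' @param sp Species name.
#' @export
species_cutoff <- function(cutoffs, sp) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  if (sp %in% names(cutoffs$species)) unname(cutoffs$species[[sp]])
  else cutoffs$default
}

.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Construct a proposal graph
#'
#' Low-level constructor, used directly in tests and by [build_graph()].
#' Nodes are surviving candidates (one per (species, method) proposal), each
#' carrying its similarity to the reference; edges between candidates of
#' different species carry pairwise similarities and are only required where
#' the weight scheme makes them contribute.
#'
#' @param ref One-row record `data.frame` for the reference sequence.
#' @param nodes `data.frame` with columns `node_id`, `species`, `method`,
#'   `seq_id`, `sim_to_ref` (and optionally `residues`).
#' @param edges `data.frame` with columns `node_a`, `node_b`, `sim`
#'   (candidate-candidate edges), or `NULL`.
#' @return An object of class `proposal_graph`.
#' @export
proposal_graph <- function(ref, nodes, edges = NULL) {
  stopifnot(is.data.frame(ref), nrow(ref) == 1L, is.data.frame(nodes))
  required <- c("node_id", "species", "method", "seq_id", "sim_to_ref")
  stopifnot(all(required %in% names(nodes)))
  if (nrow(nodes) > 0L) {
    stopifnot(!anyDuplicated(nodes$node_id),
              all(nodes$sim_to_ref >= 0), all(nodes$sim_to_ref <= 1),
              !any(nodes$species == ref$species))
  }
  edge_sim <- numeric(0)
  if (!is.null(edges) && nrow(edges) > 0L) {
    stopifnot(all(c("node_a", "node_b", "sim") %in% names(edges)),
              all(edges$sim >= 0), all(edges$sim <= 1))
    sp <- setNames(nodes$species, nodes$node_id)
    if (any(sp[edges$node_a] == sp[edges$node_b])) {
      stop("edge between two nodes of the same species", call. = FALSE)
    }
    edge_sim <- setNames(edges$sim, .edge_key(edges$node_a, edges$node_b))
    if (anyDuplicated(names(edge_sim))) {
      stop("duplicate candidate-candidate edge", call. = FALSE)
    }
  }
  rownames(nodes) <- NULL
  structure(list(ref = ref, nodes = nodes, edge_sim = edge_sim),
            class = "proposal_graph")
}

#' @export
print.proposal_graph <- function(x, ...) {
  cat("Proposal graph: reference ", x$ref$seq_id, " (", x$ref$species,
      "), ", nrow(x$nodes), " node(s) over ",
      length(unique(x$nodes$species)), " species, ",
      length(x$edge_sim), " candidate-candidate edge(s)\n", sep = "")
  invisible(x)
}

# similarity between two candidate sequences: a reference-denominated score
# is asymmetric, so candidate-candidate edges take the mean of the two
# directed scores (still in [0, 1]).
.cand_cand_sim <- function(score_fn, rec_a, rec_b, params) {
  pr <- align_pair(rec_a, rec_b, params)
  fwd <- .score_value(score_fn(pr))
  rev <- .score_value(score_fn(aligned_pair(pr$cand, pr$ref)))
  (fwd + rev) / 2
}

#' Build the proposal graph for one gene
#'
#' Scores every candidate of the proposal set against the reference sequence
#' (global pairwise alignment, then the configured scorer).
#' Candidate-candidate edges are computed only for species pairs the weight
#' scheme assigns nonzero weight -- under reference-only weighting no
#' candidate alignment is ever performed, which is what makes genome-scale
#' runs affordable. A candidate on which the scorer fails is dropped with a
#' warning rather than aborting the gene.
#'
#' @param pset A [proposal_set()] with at least one candidate.
#' @param scorer Scorer name or function (see [register_scorer()]).
#' @param weights A [weight_scheme()].
#' @param params An [align_params()] object.
#' @return A [proposal_graph()].
#' @export
build_graph <- function(pset, scorer = "perID",
                        weights = weight_scheme("reference_only",
                                                pset$ref$species),
                        params = align_params()) {
  stopifnot(inherits(pset, "proposal_set"))
  if (nrow(pset$candidates) == 0L) {
    stop("proposal set for gene ", pset$ref_gene, " has no candidates",
         call. = FALSE)
  }
  score_fn <- get_scorer(scorer)
  cand <- pset$candidates
  node_id <- paste(cand$species, cand$method, sep = ":")
  sim <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sim[i] <- tryCatch({
      pr <- align_pair(pset$ref$residues, cand$residues[i], params)
      .score_value(score_fn(pr))
    }, error = function(e) {
      warning("dropping node ", node_id[i], " (gene ", pset$ref_gene,
              "): ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  keep <- !is.na(sim)
  nodes <- data.frame(node_id = node_id[keep], species = cand$species[keep],
                      method = cand$method[keep], seq_id = cand$seq_id[keep],
                      sim_to_ref = sim[keep],
                      residues = cand$residues[keep],
                      stringsAsFactors = FALSE)
  edges <- NULL
  if (nrow(nodes) > 1L) {
    need <- which(outer(seq_len(nrow(nodes)), seq_len(nrow(nodes)),
                        function(i, j) i < j), arr.ind = TRUE)
    rows <- list()
    for (r in seq_len(nrow(need))) {
      i <- need[r, 1L]; j <- need[r, 2L]
      if (nodes$species[i] == nodes$species[j]) next
      if (pair_weight(weights, nodes$species[i], nodes$species[j]) <= 0) next
      s <- .cand_cand_sim(score_fn,
                          nodes$residues[i], nodes$residues[j], params)
      rows[[length(rows) + 1L]] <-
        data.frame(node_a = nodes$node_id[i], node_b = nodes$node_id[j],
                   sim = s, stringsAsFactors = FALSE)
    }
    if (length(rows) > 0L) edges <- do.call(rbind, rows)
  }
  proposal_graph(pset$ref, nodes, edges)
}

#' Apply pre-integration similarity cutoffs
#'
#' Removes every node whose similarity to the reference falls below the
#' cutoff for its species; a node exactly at the cutoff is retained. Species
#' may end up with no nodes at all, in which case they will simply be absent
#' from the integrated cluster.
#'
#' @param graph A [proposal_graph()].
#' @param cutoffs A [cutoff_table()].
#' @return The filtered `proposal_graph`.
#' @export
apply_cutoffs <- function(graph, cutoffs = cutoff_table()) {
  stopifnot(inherits(graph, "proposal_graph"),
            inherits(cutoffs, "cutoff_table"))
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) return(graph)
  thr <- vapply(nodes$species, function(sp) species_cutoff(cutoffs, sp),
                numeric(1L))
  keep <- nodes$sim_to_ref >= thr
  nodes <- nodes[keep, , drop = FALSE]
  edge_sim <- graph$edge_sim
  if (length(edge_sim) > 0L) {
    parts <- strsplit(names(edge_sim), "\r", fixed = TRUE)
    ok <- vapply(parts, function(p) all(p %in% nodes$node_id), logical(1L))
    edge_sim <- edge_sim[ok]
  }
  out <- graph
  out$nodes <- nodes
  rownames(out$nodes) <- NULL
  out$edge_sim <- edge_sim
  out
}

.lookup_edge <- function(graph, a, b) {
  key <- .edge_key(a, b)
  if (!key %in% names(graph$edge_sim)) {
    stop("no candidate-candidate edge between ", a, " and ", b,
         "; build the graph under a pairwise weight scheme", call. = FALSE)
  }
  unname(graph$edge_sim[[key]])
}

#' Cluster objective: weighted sum of pairwise similarities
#'
#' The objective of a selection is the sum, over unordered pairs of chosen
#' sequences (reference included), of the species-pair weight times the
#' pairwise similarity. Species without a chosen node contribute nothing.
#'
#' @param chosen Character vector of chosen `node_id`s (at most one per
#'   species; `NA`s are ignored).
#' @param graph A [proposal_graph()].
#' @param weights A [weight_scheme()].
#' @return A non-negative number.
#' @export
objective_of <- function(chosen, graph, weights) {
  stopifnot(inherits(graph, "proposal_graph"),
            inherits(weights, "weight_scheme"))
  chosen <- chosen[!is.na(chosen)]
  if (length(chosen) == 0L) return(0)
  nodes <- graph$nodes
  idx <- match(chosen, nodes$node_id)
  if (anyNA(idx)) stop("unknown node_id in 'chosen'", call. = FALSE)
  sp <- nodes$species[idx]
  if (anyDuplicated(sp)) stop("more than one chosen node for a species",
                              call. = FALSE)
  ref_sp <- graph$ref$species
  total <- sum(vapply(seq_along(chosen), function(i) {
    pair_weight(weights, ref_sp, sp[i]) * nodes$sim_to_ref[idx[i]]
  }, numeric(1L)))
  if (length(chosen) > 1L) {
    for (i in seq_len(length(chosen) - 1L)) {
      for (j in seq(i + 1L, length(chosen))) {
        w <- pair_weight(weights, sp[i], sp[j])
        if (w > 0) total <- total + w * .lookup_edge(graph, chosen[i],
                                                     chosen[j])
      }
    }
  }
  total
}

# deterministic tie-break rank: method priority first (position in the
# configured priority list; unlisted methods rank after listed ones,
# alphabetically), then lexicographic seq_id. Lower rank wins.
.node_rank <- function(nodes, method_priority = NULL) {
  pri <- match(nodes$method, method_priority)
  pri[is.na(pri)] <- length(method_priority) + 1L
  order(order(pri, nodes$method, nodes$seq_id))
}

#' Select one ortholog per species by cyclic coordinate descent
#'
#' Each restart draws a random initial choice of one node per species, then
#' sweeps through the species in a freshly drawn random order; for each
#' species in turn, the current choice is replaced by the node maximizing
#' the cluster objective given the choices for all other species. Sweeping
#' stops when a full pass changes nothing. Because every accepted move
#' strictly increases the objective and the state space is finite,
#' convergence is guaranteed; the best solution across restarts is returned.
#' A species whose nodes were all filtered out is simply absent. With a
#' fixed seed the result is bit-identical across runs.
#'
#' Ties between equal-objective candidates are broken deterministically:
#' first by the configured method-priority list, then by lexicographic
#' `seq_id`.
#'
#' @param graph A non-empty [proposal_graph()].
#' @param weights A [weight_scheme()].
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Optional integer seed for reproducibility.
#' @param method_priority Optional character vector ordering methods for
#'   tie-breaking.
#' @return An object of class `cluster_solution`: list with `chosen` (a
#'   `data.frame` of the selected node per species), `objective`,
#'   `n_restarts_used`, `converged`, and `traces` (the per-restart objective
#'   sequence, one value per coordinate update -- always non-decreasing).
#' @export
ccd_optimize <- function(graph, weights, n_restarts = 20, seed = NULL,
                         method_priority = NULL) {
  stopifnot(inherits(graph, "proposal_graph"),
            inherits(weights, "weight_scheme"), n_restarts >= 1L)
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) {
    stop("graph has no nodes; nothing to optimize", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- 1e-12
  rank <- .node_rank(nodes, method_priority)
  species <- unique(nodes$species)
  by_species <- split(seq_len(nrow(nodes)), nodes$species)

  best_chosen <- NULL
  best_obj <- -Inf
  traces <- vector("list", n_restarts)

  for (r in seq_len(n_restarts)) {
    chosen <- vapply(species, function(sp) {
      idx <- by_species[[sp]]
      nodes$node_id[idx[sample.int(length(idx), 1L)]]
    }, character(1L))
    obj <- objective_of(chosen, graph, weights)
    trace <- obj
    sweeps <- 0L
    repeat {
      sweeps <- sweeps + 1L
      # the objective strictly increases on every improving move and the
      # state space is finite, so this bound is unreachable in practice
      stopifnot(sweeps <= 10000L)
      changed <- FALSE
      for (sp in sample(species)) {
        idx <- by_species[[sp]]
        others <- chosen[names(chosen) != sp]
        gains <- vapply(idx, function(i) {
          g <- pair_weight(weights, graph$ref$species, sp) *
            nodes$sim_to_ref[i]
          for (u in others) {
            w <- pair_weight(weights, sp, nodes$species[match(u,
                                                              nodes$node_id)])
            if (w > 0) g <- g + w * .lookup_edge(graph, nodes$node_id[i], u)
          }
          g
        }, numeric(1L))
        top <- idx[gains >= max(gains) - eps]
        pick <- top[which.min(rank[top])]
        cur <- match(chosen[[sp]], nodes$node_id)
        gain_pick <- gains[match(pick, idx)]
        gain_cur <- gains[match(cur, idx)]
        # accept strictly improving moves; at (numerically) equal gain move
        # only toward the deterministic tie-break rank, so every species
        # settles on the documented tie-break winner
        if (pick != cur &&
            (gain_pick > gain_cur + eps ||
             (gain_pick >= gain_cur - eps && rank[pick] < rank[cur]))) {
          chosen[[sp]] <- nodes$node_id[pick]
          changed <- TRUE
          obj <- objective_of(chosen, graph, weights)
        }
        trace <- c(trace, obj)
      }
      if (!changed) break
    }
    stopifnot(all(diff(trace) >= -eps))  # CCD never decreases the objective
    traces[[r]] <- trace
    if (obj > best_obj + eps) {
      best_obj <- obj
      best_chosen <- chosen
    }
  }

  idx <- match(best_chosen, nodes$node_id)
  chosen_df <- data.frame(species = names(best_chosen),
                          node_id = best_chosen,
                          method = nodes$method[idx],
                          seq_id = nodes$seq_id[idx],
                          sim_to_ref = nodes$sim_to_ref[idx],
                          stringsAsFactors = FALSE)
  rownames(chosen_df) <- NULL
  structure(list(chosen = chosen_df,
                 objective = objective_of(best_chosen, graph, weights),
                 n_restarts_used = n_restarts,
                 converged = TRUE,
                 traces = traces),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution: ", nrow(x$chosen), " species, objective ",
      format(x$objective, digits = 6), " (", x$n_restarts_used,
      " restart(s))\n", sep = "")
  print(x$chosen[, c("species", "method", "seq_id", "sim_to_ref")],
        row.names = FALSE)
  invisible(x)
}

#' Size of the integrated-selection search space
#'
#' With `m` methods and `s` species there are up to `m^s` possible
#' integrated clusters, which is why exhaustive search is infeasible at
#' genome scale and cyclic coordinate descent is used instead.
#'
#' @param n_methods,n_species Positive integers.
#' @return `n_methods ^ n_species`, as a double.
#' @examples
#' search_space_size(4, 10)  # 1048576, over a million
#' @export
search_space_size <- function(n_methods, n_species) {
  stopifnot(n_methods >= 1L, n_species >= 1L)
  as.numeric(n_methods)^as.numeric(n_species)
}

#' Integrate one gene's ortholog proposals
#'
#' Full pipeline for one reference gene: build the proposal graph, apply the
#' species cutoffs, run the CCD optimizer, and collect the selected
#' sequences (reference first) ready for downstream multiple alignment,
#' together with a provenance table recording which method supplied the
#' winning candidate for each species. If every candidate of a species falls
#' below its cutoff the species is absent from the output; if no candidate
#' at all survives, the solution contains only the reference with objective
#' 0.
#'
#' @inheritParams build_graph
#' @inheritParams ccd_optimize
#' @param cutoffs A [cutoff_table()].
#' @param out_dir Optional directory; when given, writes
#'   `<gene>.selected.fasta` and `<gene>.provenance.tsv` there.
#' @return A list of class `integration_result`: `solution` (a
#'   `cluster_solution`, or `NULL` when nothing survived), `selected`
#'   (record `data.frame`, reference first), `provenance` (`data.frame`
#'   with `species`, `method`, `seq_id`, `sim_to_ref`), and `graph`
#'   (post-cutoff).
#' @export
integrate_proposals <- function(pset, scorer = "perID",
                                weights = weight_scheme("reference_only",
                                                        pset$ref$species),
                                cutoffs = cutoff_table(),
                                n_restarts = 20, seed = NULL,
                                method_priority = NULL, out_dir = NULL,
                                params = align_params()) {
  graph <- build_graph(pset, scorer, weights, params)
  graph <- apply_cutoffs(graph, cutoffs)
  ref_rec <- data.frame(seq_id = pset$ref$seq_id,
                        species = pset$ref$species, method = "ref",
                        residues = pset$ref$residues,
                        stringsAsFactors = FALSE)
  if (nrow(graph$nodes) == 0L) {
    solution <- NULL
    selected <- ref_rec
    provenance <- data.frame(species = character(0), method = character(0),
                             seq_id = character(0), sim_to_ref = numeric(0),
                             stringsAsFactors = FALSE)
  } else {
    solution <- ccd_optimize(graph, weights, n_restarts, seed,
                             method_priority)
    idx <- match(solution$chosen$node_id, graph$nodes$node_id)
    selected <- rbind(ref_rec,
                      data.frame(seq_id = solution$chosen$seq_id,
                                 species = solution$chosen$species,
                                 method = solution$chosen$method,
                                 residues = graph$nodes$residues[idx],
                                 stringsAsFactors = FALSE))
    provenance <- solution$chosen[, c("species", "method", "seq_id",
                                      "sim_to_ref")]
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ortho_fasta(selected,
                      file.path(out_dir,
                                paste0(pset$ref_gene, ".selected.fasta")))
    write.table(provenance,
                file.path(out_dir,
                          paste0(pset$ref_gene, ".provenance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(gene = pset$ref_gene, solution = solution,
                 selected = selected, provenance = provenance,
                 graph = graph),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat("Integration result for gene ", x$gene, ": ",
      nrow(x$selected) - 1L, " ortholog(s) selected\n", sep = "")
  if (!is.null(x$solution)) print(x$solution)
  invisible(x)
}
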