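make_pset <- function(ref_res = "AWVATFDKLM",
                      cands = list(c("chimp", "m1", "AWVRTFDKLM"))) {
  ref <- sequence_record("g1_human", "human", "ref", ref_res)
  rows <- do.call(rbind, lapply(seq_along(cands), function(i) {
    data.frame(seq_id = paste0("g1_", cands[[i]][1], "_", cands[[i]][2]),
               species = cands[[i]][1], method = cands[[i]][2],
               residues = cands[[i]][3], stringsAsFactors = FALSE)
  }))
  proposal_set("g1", ref, rows)
}

test_that("graph construction scores candidates against the reference", {
  ws <- weight_scheme("reference_only", "human")
  g <- build_graph(make_pset(), weights = ws)
  expect_equal(nrow(g$nodes), 1L)
  expect_length(g$edge_sim, 0L)
  expect_equal(g$nodes$sim_to_ref, 9 / 10)

  # 3 species x 2 methods under uniform weights: 6 nodes, and candidate
  # edges for every cross-species node pair (15 pairs - 3 same-species)
  cands <- list(c("chimp", "m1", "AWVRTFDKLM"), c("chimp", "m2", "AWVATFDKLA"),
                c("gorilla", "m1", "AWVATFDKAM"), c("gorilla", "m2", "AWVATADKLM"),
                c("cow", "m1", "KWVATFDKLM"), c("cow", "m2", "AWVATFDRRM"))
  g <- build_graph(make_pset(cands = cands),
                   weights = weight_scheme("uniform_pairwise", "human"))
  expect_equal(nrow(g$nodes), 6L)
  expect_length(g$edge_sim, 12L)

  # reference-only weighting skips all candidate-candidate alignments
  g2 <- build_graph(make_pset(cands = cands), weights = ws)
  expect_length(g2$edge_sim, 0L)

  empty <- proposal_set("g0",
                        sequence_record("g0_h", "human", "ref", "AWVATFD"),
                        data.frame(seq_id = character(0),
                                   species = character(0),
                                   method = character(0),
                                   residues = character(0)))
  expect_error(build_graph(empty, weights = ws), "no candidates")
})

test_that("a failing scorer drops the node with a warning, not a crash", {
  picky <- function(pair) {
    if (grepl("K", pair$cand, fixed = TRUE)) stop("cannot score")
    percent_identity(pair)$value
  }
  cands <- list(c("chimp", "m1", "AWVRTFDKLM"), c("cow", "m1", "AWVATFDRRM"))
  expect_warning(
    g <- build_graph(make_pset(cands = cands), scorer = picky,
                     weights = weight_scheme("reference_only", "human")),
    "dropping node")
  expect_equal(g$nodes$species, "cow")
})

test_that("cutoffs remove below-threshold nodes and keep the boundary", {
  ref <- sequence_record("g1_human", "human", "ref", "AWVATFD")
  nodes <- data.frame(
    node_id = c("chimp:m1", "gorilla:m1", "cow:m1"),
    species = c("chimp", "gorilla", "cow"),
    method = "m1",
    seq_id = c("c1", "g1", "w1"),
    sim_to_ref = c(0.80, 0.77, 0.71))
  g <- proposal_graph(ref, nodes)

  filtered <- apply_cutoffs(g, cutoff_table())
  # chimp at 0.80 is below its species cutoff 0.82 -> removed;
  # gorilla exactly at 0.77 is retained (>= rule);
  # cow falls back to the 0.70 default -> retained
  expect_setequal(filtered$nodes$species, c("gorilla", "cow"))

  # all nodes above their cutoffs: graph unchanged
  high <- g
  high$nodes$sim_to_ref <- c(0.99, 0.98, 0.97)
  expect_equal(apply_cutoffs(high, cutoff_table())$nodes, high$nodes)

  # candidate edges incident to a removed node disappear with it
  edges <- data.frame(node_a = c("chimp:m1", "gorilla:m1"),
                      node_b = c("gorilla:m1", "cow:m1"),
                      sim = c(0.9, 0.8))
  ge <- proposal_graph(ref, nodes, edges)
  expect_length(apply_cutoffs(ge, cutoff_table())$edge_sim, 1L)
})

test_that("the objective is the weighted sum over chosen pairs", {
  ref <- sequence_record("r", "human", "ref", "AWVATFD")
  nodes <- data.frame(node_id = c("a:m1", "b:m1", "c:m1"),
                      species = c("a", "b", "c"), method = "m1",
                      seq_id = c("a1", "b1", "c1"),
                      sim_to_ref = c(0.9, 0.8, 0.6))
  edges <- data.frame(node_a = c("a:m1", "a:m1", "b:m1"),
                      node_b = c("b:m1", "c:m1", "c:m1"),
                      sim = c(0.5, 0.4, 0.3))
  g <- proposal_graph(ref, nodes, edges)

  ref_only <- weight_scheme("reference_only", "human")
  expect_equal(objective_of(c("a:m1", "b:m1"), g, ref_only), 1.7)
  expect_equal(objective_of(character(0), g, ref_only), 0)

  uni <- weight_scheme("uniform_pairwise", "human")
  expect_equal(objective_of(c("a:m1", "b:m1", "c:m1"), g, uni),
               (0.9 + 0.8 + 0.6) + (0.5 + 0.4 + 0.3))

  custom <- weight_scheme("custom", "human",
                          pairs = data.frame(species_a = c("human", "a"),
                                             species_b = c("a", "b"),
                                             weight = c(2, 10)))
  expect_equal(objective_of(c("a:m1", "b:m1"), g, custom),
               2 * 0.9 + 10 * 0.5)
})

test_that("CCD with one node per species selects exactly those nodes", {
  set.seed(1)
  g <- random_graph(5, 1)
  ws <- weight_scheme("uniform_pairwise", "human")
  sol <- ccd_optimize(g, ws, n_restarts = 3, seed = 9)
  expect_setequal(sol$chosen$node_id, g$nodes$node_id)
})

test_that("reference-only CCD reduces to the per-species argmax", {
  for (s in 1:30) {
    set.seed(s)
    g <- random_graph(sample(2:6, 1), sample(1:4, 1))
    ws <- weight_scheme("reference_only", "human")
    sol <- ccd_optimize(g, ws, n_restarts = 5, seed = s * 13)
    expected <- vapply(split(seq_len(nrow(g$nodes)), g$nodes$species),
                       function(idx) {
                         best <- idx[g$nodes$sim_to_ref[idx] ==
                                       max(g$nodes$sim_to_ref[idx])]
                         # documented tie rule: method, then seq_id
                         best <- best[order(g$nodes$method[best],
                                            g$nodes$seq_id[best])][1]
                         g$nodes$node_id[best]
                       }, character(1))
    got <- setNames(sol$chosen$node_id, sol$chosen$species)
    expect_equal(got[sort(names(got))], expected[sort(names(expected))])
  }
})

test_that("best-of-restarts CCD attains the exhaustive optimum", {
  ws <- weight_scheme("uniform_pairwise", "human")
  for (s in 1:40) {
    set.seed(100 + s)
    g <- random_graph(sample(2:4, 1), sample(1:3, 1))
    oracle <- brute_force_optimum(g, ws)
    sol <- ccd_optimize(g, ws, n_restarts = 20, seed = s)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-12)
  }
})

test_that("every CCD trace is non-decreasing and solutions recompute", {
  ws <- weight_scheme("uniform_pairwise", "human")
  for (s in 1:10) {
    set.seed(300 + s)
    g <- random_graph(4, 3)
    sol <- ccd_optimize(g, ws, n_restarts = 10, seed = s)
    for (trace in sol$traces) expect_true(all(diff(trace) >= -1e-12))
    expect_equal(objective_of(sol$chosen$node_id, g, ws), sol$objective)
    expect_true(sol$converged)
  }
})

test_that("CCD is bit-identical under a fixed seed", {
  set.seed(55)
  g <- random_graph(4, 3)
  ws <- weight_scheme("uniform_pairwise", "human")
  a <- ccd_optimize(g, ws, n_restarts = 10, seed = 77)
  b <- ccd_optimize(g, ws, n_restarts = 10, seed = 77)
  expect_identical(a, b)
})

test_that("removing a node outside the optimum never changes the optimum", {
  ws <- weight_scheme("uniform_pairwise", "human")
  for (s in 1:15) {
    set.seed(500 + s)
    g <- random_graph(3, 3)
    oracle <- brute_force_optimum(g, ws)
    losers <- setdiff(g$nodes$node_id, oracle$chosen)
    if (length(losers) == 0) next
    drop_id <- losers[1]
    g2 <- g
    g2$nodes <- g$nodes[g$nodes$node_id != drop_id, , drop = FALSE]
    parts <- strsplit(names(g2$edge_sim), "\r", fixed = TRUE)
    g2$edge_sim <- g2$edge_sim[vapply(parts,
                                      function(p) !drop_id %in% p,
                                      logical(1))]
    expect_equal(brute_force_optimum(g2, ws)$objective, oracle$objective)
  }
})

test_that("pooling a dominated method never decreases the optimum", {
  # adding a method whose candidates are all strictly worse can only leave
  # the achievable objective unchanged or (for other instances) improve it
  ws <- weight_scheme("uniform_pairwise", "human")
  for (s in 1:10) {
    set.seed(700 + s)
    g <- random_graph(3, 2)
    before <- brute_force_optimum(g, ws)$objective
    extra <- data.frame(node_id = paste0("sp", 1:3, ":dom"),
                        species = paste0("sp", 1:3), method = "dom",
                        seq_id = paste0("sp", 1:3, ":dom"),
                        sim_to_ref = pmax(g$nodes$sim_to_ref[1:3] - 0.3, 0))
    nodes <- rbind(g$nodes, extra)
    idx <- utils::combn(nrow(nodes), 2)
    keep <- nodes$species[idx[1, ]] != nodes$species[idx[2, ]]
    edges <- data.frame(node_a = nodes$node_id[idx[1, keep]],
                        node_b = nodes$node_id[idx[2, keep]],
                        sim = 0)
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b), sep = "\r")
    old <- match(key, names(g$edge_sim))
    edges$sim <- ifelse(is.na(old), runif(nrow(edges)) * 0.1,
                        g$edge_sim[ifelse(is.na(old), 1, old)])
    g2 <- proposal_graph(g$ref, nodes, edges)
    after <- brute_force_optimum(g2, ws)$objective
    expect_gte(after, before - 1e-12)
  }
})

test_that("integration composes graph, cutoffs, and CCD with provenance", {
  cfg <- sim_config(seed = 21, p_decoy = 0, p_miss = 0.2)
  fam <- simulate_family(cfg, gene = "gX")
  res <- integrate_proposals(fam$pset, n_restarts = 5, seed = 4)
  expect_s3_class(res, "integration_result")
  # reference comes first in the emitted records
  expect_equal(res$selected$species[1], "human")
  # with no decoys planted, every selected sequence is the true ortholog
  sel <- setNames(res$provenance$seq_id, res$provenance$species)
  truth <- setNames(fam$truth$true_seq_id, fam$truth$species)
  expect_equal(sel, truth[names(sel)])

  out_dir <- withr::local_tempdir()
  integrate_proposals(fam$pset, n_restarts = 5, seed = 4,
                      out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "gX.selected.fasta")))
  prov <- read.delim(file.path(out_dir, "gX.provenance.tsv"))
  expect_equal(nrow(prov), nrow(res$provenance))
  fasta <- read_ortho_fasta(file.path(out_dir, "gX.selected.fasta"))
  expect_equal(fasta$residues, res$selected$residues)
})

test_that("when every candidate is filtered only the reference remains", {
  pset <- make_pset(ref_res = "AWVATFDKLMAWVATFDKLM",
                    cands = list(c("chimp", "m1",
                                   "KKKKKKKKKKKKKKKKKKKK")))
  res <- integrate_proposals(pset, n_restarts = 3, seed = 1)
  expect_null(res$solution)
  expect_equal(nrow(res$selected), 1L)
  expect_equal(res$selected$species, "human")
  expect_equal(nrow(res$provenance), 0L)
})

test_that("the search-space calculator is m^s", {
  expect_equal(search_space_size(4, 10), 1048576)
  expect_equal(search_space_size(1, 7), 1)
  expect_equal(search_space_size(3, 2), 9)
})
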