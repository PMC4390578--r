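test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 99)
  a <- simulate_family(cfg)
  b <- simulate_family(cfg)
  expect_identical(a, b)
  c2 <- simulate_family(sim_config(seed = 100))
  expect_false(identical(a$pset$candidates, c2$pset$candidates))
})

test_that("degenerate configurations behave as documented", {
  # zero divergence, no decoys: every candidate is identical to the ref
  cfg <- sim_config(seed = 3,
                    species = c(sp1 = 0, sp2 = 0), n_methods = 2,
                    p_miss = 0, p_decoy = 0, seq_length = 40)
  fam <- simulate_family(cfg)
  expect_true(all(fam$pset$candidates$residues == fam$pset$ref$residues))
  g <- build_graph(fam$pset,
                   weights = weight_scheme("reference_only", "human"))
  expect_true(all(g$nodes$sim_to_ref == 1))

  # p_miss = 1: a valid proposal set with no candidates at all
  none <- simulate_family(sim_config(seed = 3, p_miss = 1))
  expect_equal(nrow(none$pset$candidates), 0L)
  expect_s3_class(none$pset, "proposal_set")
})

test_that("realized identity tracks 1 - divergence at 1000 sites", {
  for (d in c(0.05, 0.2, 0.4)) {
    cfg <- sim_config(seed = round(1000 * d), species = c(spA = d),
                      n_methods = 1, p_miss = 0, p_decoy = 0,
                      seq_length = 1000)
    fam <- simulate_family(cfg)
    ref <- strsplit(fam$pset$ref$residues, "")[[1]]
    ort <- strsplit(fam$pset$candidates$residues[1], "")[[1]]
    identity <- mean(ref == ort)
    # binomial 3-sigma band around 1 - d
    expect_lt(abs(identity - (1 - d)), 3 * sqrt(d * (1 - d) / 1000) + 1e-9)
  }
})

test_that("a simulated cohort round-trips through the proposal reader", {
  cfg <- sim_config(seed = 31, species = c(chimp = 0.05, cow = 0.15),
                    n_methods = 2, seq_length = 50)
  fams <- lapply(1:3, function(i) {
    cfg$seed <- cfg$seed + i
    simulate_family(cfg, gene = paste0("g", i))
  })
  out <- withr::local_tempdir()
  write_simulated_cohort(fams, out)
  psets <- read_proposals(file.path(out, "proposals.tsv"),
                          file.path(out, "sequences.fasta"))
  expect_length(psets, 3L)
  expect_equal(psets$g2$candidates[order(psets$g2$candidates$seq_id,
                                         psets$g2$candidates$method), ],
               fams[[2]]$pset$candidates[
                 order(fams[[2]]$pset$candidates$seq_id,
                       fams[[2]]$pset$candidates$method), ],
               ignore_attr = TRUE)
})

test_that("indel mode produces alignable length-varying sequences", {
  cfg <- sim_config(seed = 13, species = c(spA = 0.1, spB = 0.2),
                    n_methods = 2, p_miss = 0, p_decoy = 0,
                    seq_length = 80, indel_rate = 0.05)
  fam <- simulate_family(cfg)
  lens <- nchar(fam$pset$candidates$residues)
  expect_true(any(lens != 80))
  g <- build_graph(fam$pset,
                   weights = weight_scheme("reference_only", "human"))
  expect_true(all(g$nodes$sim_to_ref > 0.5))
})

test_that("with no decoys the pipeline recovers every planted ortholog", {
  cfg <- sim_config(seed = 41, species = c(sp1 = 0.05, sp2 = 0.15),
                    n_methods = 2, p_miss = 0.2, p_decoy = 0,
                    seq_length = 60)
  r <- recovery_rate(10, cfg, n_restarts = 3)
  expect_equal(as.numeric(r), 1)
  expect_gt(attr(r, "n_eligible"), 0)
})

test_that("recovery is monotone in the decoy's extra divergence", {
  base <- function(extra) {
    sim_config(seed = 61,
               species = c(sp1 = 0.1, sp2 = 0.15, sp3 = 0.2),
               n_methods = 2, p_miss = 0.1, p_decoy = 0.4,
               decoy_extra_divergence = extra, seq_length = 80)
  }
  rates <- vapply(c(0, 0.1, 0.25),
                  function(extra) as.numeric(recovery_rate(40, base(extra),
                                                           n_restarts = 3)),
                  numeric(1))
  # same family seeds across the grid; allow slack for the decoys being
  # re-drawn rather than coupled
  expect_true(all(diff(rates) >= -0.03))
  expect_gt(rates[3], rates[1])
})

test_that("statistically identical decoys win about half their contests", {
  # with decoy_extra_divergence = 0 the true ortholog and the decoy follow
  # the same divergence distribution, so in slots where both compete the
  # selection is a coin flip; slots without a competing decoy are excluded
  # because the true ortholog trivially wins them
  cfg <- sim_config(seed = 71,
                    species = c(sp1 = 0.2, sp2 = 0.2, sp3 = 0.2,
                                sp4 = 0.2),
                    n_methods = 2, p_miss = 0, p_decoy = 0.5,
                    decoy_extra_divergence = 0, seq_length = 150)
  contested <- 0L
  won <- 0L
  for (i in 1:250) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    fam <- simulate_family(ci, gene = paste0("g", i))
    res <- integrate_proposals(fam$pset, n_restarts = 2,
                               seed = cfg$seed + i - 1L)
    for (r in seq_len(nrow(fam$truth))) {
      tr <- fam$truth[r, ]
      surviving <- res$graph$nodes$seq_id
      if (!tr$true_seq_id %in% surviving) next
      if (!tr$decoy_seq_id %in% surviving) next
      contested <- contested + 1L
      sel <- res$provenance$seq_id[res$provenance$species == tr$species]
      if (length(sel) == 1L && sel == tr$true_seq_id) won <- won + 1L
    }
  }
  expect_gt(contested, 400L)
  expect_lt(abs(won / contested - 0.5), 0.07)
})
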