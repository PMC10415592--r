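test_that("birth-death simulation honours conditioning and determinism", {
  two <- simulate_bd_tree(sim_config(seed = 3, n_taxa = 2))
  expect_equal(ape::Ntip(two$phy), 2L)
  expect_equal(two$phy$Nnode, 1L)

  pb <- simulate_bd_tree(sim_config(seed = 4, n_taxa = 8, death_rate = 0))
  expect_equal(ape::Ntip(pb$phy), 8L)
  expect_equal(pb$phy$Nnode, 7L)
  e <- pb$phy$edge
  expect_true(all(pb$ages[e[, 1L]] > pb$ages[e[, 2L]]))

  a <- simulate_bd_tree(sim_config(seed = 10, n_taxa = 6))
  b <- simulate_bd_tree(sim_config(seed = 10, n_taxa = 6))
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  c2 <- simulate_bd_tree(sim_config(seed = 11, n_taxa = 6))
  expect_false(identical(ape::write.tree(a$phy), ape::write.tree(c2$phy)))

  capped <- simulate_bd_tree(sim_config(seed = 12, n_taxa = 10,
                                        root_age_max = 2000))
  expect_lte(capped$root_age, 2000)
})

test_that("pure-birth root ages match an independent reference simulation", {
  n_rep <- 400L
  ours <- vapply(seq_len(n_rep), function(i) {
    simulate_bd_tree(sim_config(seed = 5000 + i, n_taxa = 6,
                                birth_rate = 1, death_rate = 0,
                                root_age_max = NULL))$root_age
  }, numeric(1L))
  withr::local_seed(123)
  ref <- vapply(seq_len(n_rep), function(i)
    indep_pure_birth_root_age(6L, 1), numeric(1L))
  se <- sqrt(stats::var(ours) / n_rep + stats::var(ref) / n_rep)
  expect_lt(abs(mean(ours) - mean(ref)), 3 * se)
})

test_that("jittered ensembles are valid chronograms centred on the truth", {
  cfg0 <- sim_config(seed = 21, n_taxa = 8, n_samples = 10, jitter_cv = 0)
  tr <- simulate_bd_tree(cfg0)
  e0 <- jitter_ensemble(tr, cfg0)
  for (s in e0$samples) expect_equal(s$ages, tr$ages)

  cfg <- sim_config(seed = 21, n_taxa = 8, n_samples = 50, jitter_cv = 0.2)
  ens <- jitter_ensemble(tr, cfg)
  for (s in ens$samples) {
    # every sample re-validates as an ultrametric chronogram
    expect_silent(as_chronogram(s$phy, tolerance = 1e-6))
  }
  # determinism
  ens2 <- jitter_ensemble(tr, cfg)
  expect_equal(ens$samples[[7L]]$ages, ens2$samples[[7L]]$ages)
})

test_that("planted transfers connect disjoint contemporaneous clades", {
  tr <- simulate_bd_tree(sim_config(seed = 42, n_taxa = 8))
  pl <- plant_transfers(tr, k = 10, seed = 9)
  expect_equal(nrow(pl), 10L)
  for (i in seq_len(nrow(pl))) {
    d <- hgtclock:::split_taxa(pl$donor_taxa[i])
    r <- hgtclock:::split_taxa(pl$recipient_taxa[i])
    expect_length(intersect(d, r), 0L)
    # both edges' intervals contain the event time
    for (node in c(pl$donor_node[i], pl$recipient_node[i])) {
      expect_lt(tr$ages[[node]], pl$time[i])
      expect_gt(tr$ages[[tr$parent[[node]]]], pl$time[i])
    }
    # crown_ok records the crown-age relation on the truth tree
    expect_equal(pl$crown_ok[i],
                 crown_age(tr, d, warn = FALSE) >
                   crown_age(tr, r, warn = FALSE))
  }
  # oriented constraints are all true on truth; their reversals all false
  oc <- oriented_constraints(pl)
  for (j in seq_len(nrow(oc))) {
    expect_true(is_compatible(tr, oc[j, , drop = FALSE]))
    expect_false(is_compatible(tr,
                               reverse_constraints(oc[j, , drop = FALSE])))
  }
})

test_that("gene trees under zero DTL rates are congruent with the species tree", {
  tr <- simulate_bd_tree(sim_config(seed = 42, n_taxa = 8))
  none <- sim_config(seed = 5, dtl_rates = c(duplication = 0, transfer = 0,
                                             loss = 0))
  sim <- simulate_dtl_gene_tree(tr, none)
  expect_true(sim$survived)
  expect_equal(ape::Ntip(sim$tree), 8L)
  expect_equal(reconcile(sim$tree, tr$phy, dtl_costs(1, 1, 1))$total_cost, 0)
})

test_that("zero loss keeps at least one gene copy per species tip", {
  tr <- simulate_bd_tree(sim_config(seed = 42, n_taxa = 8))
  cfg <- sim_config(seed = 6, dtl_rates = c(duplication = 1e-3,
                                            transfer = 0, loss = 0))
  sim <- simulate_dtl_gene_tree(tr, cfg)
  expect_true(sim$survived)
  expect_true(all(tr$phy$tip.label %in% sim$tree$tip.label))
  expect_gte(ape::Ntip(sim$tree), 8L)
})

test_that("recorded gene-family events carry feasible times and locations", {
  tr <- simulate_bd_tree(sim_config(seed = 42, n_taxa = 8))
  cfg <- sim_config(seed = 14, dtl_rates = c(duplication = 0.002,
                                             transfer = 0.004, loss = 0.002))
  sim <- simulate_dtl_gene_tree(tr, cfg)
  ev <- sim$events
  expect_true(all(ev$kind %in% c("speciation", "duplication", "transfer",
                                 "loss")))
  tx <- ev[ev$kind == "transfer", , drop = FALSE]
  for (i in seq_len(nrow(tx))) {
    expect_true(tx$species_node[i] != tx$recipient[i])
    expect_lt(tr$ages[[tx$recipient[i]]], tx$time[i])
    expect_gt(tr$ages[[tr$parent[[tx$recipient[i]]]]], tx$time[i])
  }
})

test_that("planted proteomes reclassify exactly per plan", {
  z <- synth_proteome(sim_config(seed = 1, motif_plan = list(c(3L, 0L))))
  expect_equal(sum(vapply(z$sequence, function(s)
    length(scan_heme_motifs(s)), integer(1L))), 0L)

  p22 <- synth_proteome(sim_config(seed = 2, motif_plan = list(c(2L, 2L))))
  s22 <- classify_proteome(p22, min_motifs = 2, genome_id = "g")
  expect_equal(s22$n_mhc, 2L)
  expect_equal(s22$n_motifs_in_mhc, 4L)

  mix <- synth_proteome(sim_config(seed = 3,
                                   motif_plan = list(c(5L, 1L), c(5L, 3L))))
  smix <- classify_proteome(mix, min_motifs = 2, genome_id = "g")
  expect_equal(smix$n_mhc, 5L)
  expect_equal(smix$n_motifs_in_mhc, 15L)
  # scanner recount agrees with the recorded plan, protein by protein
  expect_equal(vapply(mix$sequence, function(s)
    length(window_scan_oracle(s)), integer(1L), USE.NAMES = FALSE),
    as.integer(attr(mix, "planted")))
  # determinism
  again <- synth_proteome(sim_config(seed = 3,
                                     motif_plan = list(c(5L, 1L), c(5L, 3L))))
  expect_identical(mix$sequence, again$sequence)
})
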