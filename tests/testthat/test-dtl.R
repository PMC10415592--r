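test_that("congruent trees reconcile at zero cost with speciations only", {
  s <- parse_newick("((A:1,B:1):1,C:2);")
  r <- reconcile(s, s, dtl_costs(1, 1, 1))
  expect_equal(r$total_cost, 0)
  expect_equal(sum(r$events$kind == "speciation"), 2L)
  expect_equal(sum(r$events$kind %in%
                     c("duplication", "transfer", "speciation-loss")), 0L)
  expect_equal(brute_force_cost(s, s, dtl_costs(1, 1, 1)), 0)
})

test_that("the discordant three-taxon pair costs 1 under (1,1,1) and 3 under (1,3,1)", {
  g <- parse_newick("((A:1,C:1):1,B:2);")
  s <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(reconcile(g, s, dtl_costs(1, 1, 1))$total_cost, 1)
  expect_equal(reconcile(g, s, dtl_costs(1, 3, 1))$total_cost, 3)
  expect_equal(brute_force_cost(g, s, dtl_costs(1, 1, 1)), 1)
  expect_equal(brute_force_cost(g, s, dtl_costs(1, 3, 1)), 3)
  # scaling all costs doubles the brute-force optimum (linearity)
  expect_equal(brute_force_cost(g, s, dtl_costs(2, 2, 2)), 2)
  expect_equal(brute_force_cost(g, s, dtl_costs(2, 6, 2)), 6)
})

test_that("DP equals the enumeration oracle on all 3-4 leaf pairs", {
  labels <- c("A", "B", "C", "D")
  for (n in 3:4) {
    trees <- all_rooted_trees(labels[1:n])
    for (s in trees) {
      for (g in trees) {
        for (cv in list(c(1, 1, 1), c(1, 3, 1), c(2, 1, 3))) {
          expect_equal(reconcile(g, s, cv)$total_cost,
                       brute_force_cost(g, s, cv))
        }
      }
    }
  }
})

test_that("dead-lineage routing matches the oracle and never increases cost", {
  labels <- c("A", "B", "C", "D")
  for (n in 3:4) {
    trees <- all_rooted_trees(labels[1:n])
    for (s in trees) {
      for (g in trees) {
        for (cv in list(c(1, 1, 1), c(1, 3, 1))) {
          plain <- reconcile(g, s, cv)$total_cost
          dead <- reconcile(g, s, cv, dead_lineage = TRUE)$total_cost
          expect_equal(dead, brute_force_cost(g, s, cv, dead_lineage = TRUE))
          expect_lte(dead, plain)
        }
      }
    }
  }
})

test_that("cost is monotone in each event cost and the witness recomputes exactly", {
  cfg <- sim_config(seed = 42, n_taxa = 6)
  tr <- simulate_bd_tree(cfg)
  for (sd in c(2, 3, 5)) {
    gcfg <- sim_config(seed = sd, dtl_rates = c(duplication = 0.002,
                                                transfer = 0.005,
                                                loss = 0.002))
    sim <- simulate_dtl_gene_tree(tr, gcfg)
    if (!sim$survived || ape::Ntip(sim$tree) < 2L) next
    base <- reconcile(sim$tree, tr$phy, dtl_costs(1, 1, 1))
    expect_equal(event_list_cost(base), base$total_cost)
    for (bump in list(dtl_costs(2, 1, 1), dtl_costs(1, 2, 1),
                      dtl_costs(1, 1, 2))) {
      r <- reconcile(sim$tree, tr$phy, bump)
      expect_gte(r$total_cost, base$total_cost)
      expect_equal(event_list_cost(r), r$total_cost)
    }
    dead <- reconcile(sim$tree, tr$phy, dtl_costs(1, 3, 1),
                      dead_lineage = TRUE)
    expect_equal(event_list_cost(dead), dead$total_cost)
  }
})

test_that("invalid reconciliation inputs are rejected", {
  s <- parse_newick("((A:1,B:1):1,C:2);")
  poly <- parse_newick("((A:1,B:1,C:1):1,D:1);")
  expect_error(reconcile(poly, s), "binary")
  g_bad <- parse_newick("((A:1,Q:1):1,B:2);")
  expect_error(reconcile(g_bad, s), "Q")
  expect_error(brute_force_cost(g_bad, s), "Q")
  big <- parse_newick("(((((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5):1,G:6):1,H:7);")
  expect_error(brute_force_cost(big, big), "6")
})

test_that("transfer extraction yields the witnessed donor and recipient clades", {
  g <- parse_newick("((A:1,C:1):1,B:2);")
  s <- parse_newick("((A:1,B:1):1,C:2);")
  chron <- as_chronogram("((A:1,B:1):1,C:2);")
  r0 <- reconcile(s, s, dtl_costs(1, 1, 1))
  expect_equal(nrow(extract_transfers(r0, chron)), 0L)

  r1 <- reconcile(g, s, dtl_costs(1, 1, 1))
  tx <- extract_transfers(r1, chron)
  expect_equal(nrow(tx), 1L)
  expect_false(tx$untestable)
  expect_true(all(c(tx$donor_taxa, tx$recipient_taxa) %in% c("A", "C")))
  expect_true(tx$donor_taxa != tx$recipient_taxa)
})

test_that("planted transfers are recovered and chronologically consistent", {
  cfg <- sim_config(seed = 42, n_taxa = 8)
  tr <- simulate_bd_tree(cfg)
  planted <- plant_transfers(tr, k = 1, seed = 7)
  nodtl <- sim_config(seed = 5, dtl_rates = c(duplication = 0, transfer = 0,
                                              loss = 0))
  sim <- simulate_dtl_gene_tree(tr, nodtl, forced_transfers = planted)
  r <- reconcile(sim$tree, tr$phy, dtl_costs(1, 1, 1))
  expect_equal(r$total_cost, 1)
  tx <- extract_transfers(r, tr)
  expect_equal(nrow(tx), 1L)
  expect_setequal(c(tx$donor_taxa, tx$recipient_taxa),
                  c(planted$donor_taxa, planted$recipient_taxa))
  tc <- check_time_consistency(r, tr)
  expect_true(all(tc$consistent))
})

test_that("edge-interval overlap decides time consistency", {
  ch <- as_chronogram("(((A:1,B:1):1.5,C:2.5):1.5,(D:2,E:2):2);")
  g <- parse_newick("(((A:1,D:1):1.5,C:2.5):1.5,(B:2,E:2):2);")
  r <- reconcile(g, ch$phy, dtl_costs(1, 1, 1))
  tc <- check_time_consistency(r, ch)
  expect_true(all(!is.na(tc$consistent)))
  expect_true(all(tc$donor_lo <= tc$donor_hi))
  expect_true(all(tc$recipient_lo <= tc$recipient_hi))
  expect_equal(tc$consistent,
               tc$donor_lo <= tc$recipient_hi & tc$recipient_lo <= tc$donor_hi)
})
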