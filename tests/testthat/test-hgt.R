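test_that("compatibility of one chronogram follows donor-older-than-recipient", {
  ch <- fix4_chron()
  ok <- hgt_constraint("h1", c("C", "D"), c("A", "B"))   # crown 2 > crown 1
  expect_true(is_compatible(ch, ok))
  expect_false(is_compatible(ch, reverse_constraints(ok)))
  # exact age ties count as incompatible in both directions
  tie <- as_chronogram("((A:1,B:1):1,(C:1,D:1):1);")
  expect_false(is_compatible(tie, ok))
  expect_false(is_compatible(tie, reverse_constraints(ok)))
  expect_error(hgt_constraint("h2", c("A", "B"), c("B", "C")), "overlap")
})

test_that("stem modes pick the parent node on the requested side", {
  ch <- fix4_chron()
  # stem(C,D) = 3 > crown(A,B) = 1
  sc <- hgt_constraint("s1", c("C", "D"), c("A", "B"), mode = "stem-crown")
  expect_true(is_compatible(ch, sc))
  # stem-stem on the two cherries: both stems are the root -> tie -> FALSE
  ss <- hgt_constraint("s2", c("C", "D"), c("A", "B"), mode = "stem-stem")
  expect_false(is_compatible(ch, ss))
})

test_that("per-constraint and joint fractions match engineered ensembles", {
  # constraint 1 (crown CD > crown AB) true for samples 1..7;
  # constraint 2 (crown EF > crown AB) true for samples 4..10
  xs <- c(rep(2, 7), rep(0.5, 3))
  ys <- c(rep(0.5, 3), rep(2, 7))
  ens <- six_taxon_ensemble(xs, ys)
  cons <- rbind(hgt_constraint("c1", c("C", "D"), c("A", "B")),
                hgt_constraint("c2", c("E", "F"), c("A", "B")))
  res <- compatibility_fraction(ens, cons)
  expect_equal(unname(res$per_constraint), c(0.7, 0.7))
  expect_equal(res$joint_fraction, 0.4)
  expect_equal(res$compatible_indices, 4:7)

  one <- compatibility_fraction(ens, cons[1L, ])
  expect_equal(one$joint_fraction, 0.7)
  expect_equal(unname(one$per_constraint), 0.7)
})

test_that("fractions equal a naive per-sample recount on jittered ensembles", {
  cfg <- sim_config(seed = 404, n_taxa = 8, n_samples = 500,
                    jitter_cv = 0.05)
  tr <- simulate_bd_tree(cfg)
  ens <- jitter_ensemble(tr, cfg)
  cons <- oriented_constraints(plant_transfers(tr, k = 3, seed = 77))
  res <- compatibility_fraction(ens, cons)

  naive <- vapply(seq_len(nrow(cons)), function(j) {
    mean(vapply(ens$samples, function(s)
      is_compatible(s, cons[j, , drop = FALSE]), logical(1L)))
  }, numeric(1L))
  expect_equal(unname(res$per_constraint), naive)
  naive_joint <- mean(vapply(ens$samples, function(s)
    all(vapply(seq_len(nrow(cons)), function(j)
      is_compatible(s, cons[j, , drop = FALSE]), logical(1L))),
    logical(1L)))
  expect_equal(res$joint_fraction, naive_joint)
  expect_lte(res$joint_fraction, min(res$per_constraint))
  expect_true(all(res$per_constraint >= 0 & res$per_constraint <= 1))
})

test_that("filtering keeps exactly the jointly compatible samples, in order", {
  xs <- c(rep(2, 7), rep(0.5, 3))
  ys <- c(rep(0.5, 3), rep(2, 7))
  ens <- six_taxon_ensemble(xs, ys)
  cons <- rbind(hgt_constraint("c1", c("C", "D"), c("A", "B")),
                hgt_constraint("c2", c("E", "F"), c("A", "B")))
  filt <- filter_compatible(ens, cons)
  expect_length(filt$samples, 4L)
  # idempotent, and every fraction is 1 afterwards
  refilt <- filter_compatible(filt, cons)
  expect_length(refilt$samples, 4L)
  expect_equal(unname(compatibility_fraction(filt, cons)$per_constraint),
               c(1, 1))
  # all-compatible ensemble passes through unchanged
  allok <- six_taxon_ensemble(rep(2, 5), rep(2, 5))
  expect_length(filter_compatible(allok, cons)$samples, 5L)
  # no compatible samples -> advisory error
  none <- six_taxon_ensemble(rep(0.5, 5), rep(0.5, 5))
  expect_error(filter_compatible(none, cons), "relax")
})

test_that("constrained age summaries equal filter-then-summarize", {
  cfg <- sim_config(seed = 88, n_taxa = 8, n_samples = 300,
                    jitter_cv = 0.3)
  tr <- simulate_bd_tree(cfg)
  ens <- jitter_ensemble(tr, cfg)
  cons <- oriented_constraints(plant_transfers(tr, k = 2, seed = 1))
  clade <- hgtclock:::split_taxa(cons$donor_taxa[1L])
  got <- constrained_age_summary(ens, cons, clade, "crown")
  # independent recomputation: per-sample loop, then percentile summary
  keep <- vapply(ens$samples, function(s)
    all(vapply(seq_len(nrow(cons)), function(j)
      is_compatible(s, cons[j, , drop = FALSE]), logical(1L))),
    logical(1L))
  ages <- vapply(ens$samples[keep], crown_age, numeric(1L), taxa = clade,
                 warn = FALSE)
  expect_equal(got$n, sum(keep))
  expect_equal(got$mean, mean(ages))
  expect_equal(got$median, stats::median(ages))
  expect_equal(got$ci_low, unname(stats::quantile(ages, 0.025)))
  expect_equal(got$ci_high, unname(stats::quantile(ages, 0.975)))
  # vacuously true constraints leave the summary unconstrained
  allok <- six_taxon_ensemble(rep(2, 5), seq(1.5, 2.5, length.out = 5))
  vac <- hgt_constraint("v", c("C", "D"), c("A", "B"))
  expect_equal(constrained_age_summary(allok, vac, c("E", "F"), "crown"),
               summarize_ages(allok, c("E", "F"), "crown"))
})

test_that("model ranking sorts by joint fraction with alphabetical ties", {
  cons <- hgt_constraint("c1", c("C", "D"), c("A", "B"))
  mk <- function(n_true, n) {
    six_taxon_ensemble(c(rep(2, n_true), rep(0.5, n - n_true)), rep(1, n))
  }
  ensembles <- list("CIR+UNI" = mk(94, 100), "CIR+BD" = mk(93, 100),
                    "UGAM+BD" = mk(23, 100))
  tab <- rank_models(ensembles, cons)
  expect_equal(tab$label, c("CIR+UNI", "CIR+BD", "UGAM+BD"))
  expect_equal(tab$joint_fraction, c(0.94, 0.93, 0.23))
  # single ensemble -> single row
  expect_equal(nrow(rank_models(ensembles[1L], cons)), 1L)
  # identical ensembles tie and order alphabetically
  tie <- rank_models(list(beta = mk(50, 100), alpha = mk(50, 100)), cons)
  expect_equal(tie$label, c("alpha", "beta"))
})
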