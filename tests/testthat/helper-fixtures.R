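# Shared fixtures and independent oracles used across the suite.

# four-taxon reference chronogram: crown(A,B)=1, crown(C,D)=2, root=3
FIX4 <- "((A:1,B:1):2,(C:2,D:2):1);"

fix4_chron <- function() as_chronogram(FIX4)

# independent every-window motif oracle: checks each length-5 window with
# substring operations, no shared code with scan_heme_motifs()
window_scan_oracle <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  hits <- integer(0)
  if (n < 5L) return(hits)
  for (i in seq_len(n - 4L)) {
    w <- substr(s, i, i + 4L)
    cs <- strsplit(w, "")[[1L]]
    if (cs[1L] == "C" && cs[4L] == "C" && cs[5L] == "H" &&
        !any(cs %in% c("*", "-"))) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

# random amino-acid sequence incl. ambiguity/stop/gap symbols
random_aa <- function(n, alphabet = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                                      "X", "B", "Z", "*", "-")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent pure-birth reference: crown-conditioned, stop at the n-th
# lineage, then one further exponential stretch (same process definition as
# the generator, implemented separately)
indep_pure_birth_root_age <- function(n, birth) {
  k <- 2L
  t <- 0
  while (k < n) {
    t <- t + stats::rexp(1L, k * birth)
    k <- k + 1L
  }
  t + stats::rexp(1L, n * birth)
}

# parameterized 6-taxon ultrametric newick with adjustable cherry crown ages
# crown(A,B) = 1 fixed, crown(C,D) = x in (0,3), crown(E,F) = y in (0,4),
# node(ABCD) = 3, root = 4
six_taxon_tree <- function(x, y) {
  sprintf(
    "(((A:1,B:1):2,(C:%g,D:%g):%g):1,(E:%g,F:%g):%g);",
    x, x, 3 - x, y, y, 4 - y)
}

six_taxon_ensemble <- function(xs, ys, label = "engineered") {
  samples <- Map(function(x, y) as_chronogram(six_taxon_tree(x, y)), xs, ys)
  tree_ensemble(unname(samples), label = label)
}

# all rooted binary topologies on the given labels (phangorn enumeration);
# [[-indexing keeps per-tree tip labels intact
all_rooted_trees <- function(labels) {
  tl <- phangorn::allTrees(length(labels), rooted = TRUE,
                           tip.label = labels)
  lapply(seq_along(tl), function(i) tl[[i]])
}
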