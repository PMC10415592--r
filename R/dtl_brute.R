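## Exhaustive-enumeration oracle for DTL reconciliation cost.
##
## Independent of the dynamic program in dtl.R: every assignment of internal
## gene nodes to species nodes (plus, optionally, the dead lineage) is
## enumerated, the events and loss counts forced by each assignment are
## derived from local parent/child placements, and the minimum total cost is
## returned. Only practical on small trees; used as the testing oracle.

## Local cost table: dloc[m, m1, m2] is the cheapest way to resolve a gene
## node placed at species node m whose children are placed at m1 and m2.
## Index ns+1 denotes the dead lineage when dead_lineage is TRUE.
brute_local_table <- function(species_tree, costs, dead_lineage = FALSE) {
  costs <- as_dtl_costs(costs)
  delta <- costs[["delta"]]; tau <- costs[["tau"]]; lam <- costs[["lam"]]
  ntip <- ape::Ntip(species_tree)
  ns <- ntip + species_tree$Nnode
  kids <- children_list(species_tree)
  parent <- parent_vector(species_tree)

  ## descendant-or-equal and depth, computed by climbing parents (kept
  ## separate from the DP's postorder accumulation on purpose)
  nn <- if (dead_lineage) ns + 1L else ns
  descq <- matrix(FALSE, nn, nn)
  depth <- integer(nn)
  side <- matrix(0L, nn, nn)    # which child subtree of m holds t (1/2, 0 = none)
  for (t in seq_len(ns)) {
    v <- t
    d <- 0L
    repeat {
      descq[v, t] <- TRUE
      p <- parent[v]
      if (p == 0L) break
      side[p, t] <- match(v, kids[[p]])
      v <- p
      d <- d + 1L
    }
    depth[t] <- d
  }
  if (dead_lineage) descq[nn, nn] <- TRUE

  idx <- seq_len(nn)
  m  <- array(rep(idx, times = nn * nn), dim = c(nn, nn, nn))
  m1 <- array(rep(idx, each = nn, times = nn), dim = c(nn, nn, nn))
  m2 <- array(rep(idx, each = nn * nn), dim = c(nn, nn, nn))
  deq1 <- array(descq[cbind(c(m), c(m1))], dim = dim(m))   # m1 under-or-equal m
  deq2 <- array(descq[cbind(c(m), c(m2))], dim = dim(m))
  anc1 <- array(descq[cbind(c(m1), c(m))], dim = dim(m)) & !deq1
  anc2 <- array(descq[cbind(c(m2), c(m))], dim = dim(m)) & !deq2
  inc1 <- !deq1 & !anc1 & (m != m1)
  inc2 <- !deq2 & !anc2 & (m != m2)
  d_m  <- depth[m]; d_1 <- depth[m1]; d_2 <- depth[m2]

  inf <- Inf
  ## speciation: children on opposite child-sides of m, strictly below
  s1 <- array(side[cbind(c(m), c(m1))], dim = dim(m))
  s2 <- array(side[cbind(c(m), c(m2))], dim = dim(m))
  spec_ok <- s1 != 0L & s2 != 0L & s1 != s2
  cost_spec <- ifelse(spec_ok, lam * ((d_1 - d_m - 1L) + (d_2 - d_m - 1L)), inf)
  ## duplication: both children within the subtree of m (dead: both at dead)
  dup_ok <- deq1 & deq2
  cost_dup <- ifelse(dup_ok, delta + lam * ((d_1 - d_m) + (d_2 - d_m)), inf)
  ## transfer: one child leaves to an incomparable node, the other remains
  tr1_ok <- inc1 & deq2
  tr2_ok <- inc2 & deq1
  cost_tr <- pmin(ifelse(tr1_ok, tau + lam * (d_2 - d_m), inf),
                  ifelse(tr2_ok, tau + lam * (d_1 - d_m), inf))
  dloc <- pmin(cost_spec, cost_dup, cost_tr)
  if (dead_lineage) {
    ## at the dead lineage: persistence is free, losses impossible
    dloc[nn, , ] <- inf
    dloc[nn, nn, nn] <- delta                       # duplication in the dead
    dloc[nn, nn, seq_len(ns)] <- tau                # one child exits
    dloc[nn, seq_len(ns), nn] <- tau
  }
  dloc
}

#' Brute-force minimum DTL reconciliation cost
#'
#' Exhaustively enumerates every mapping of internal gene-tree nodes to
#' species-tree nodes (and, optionally, the dead lineage), derives the events
#' and loss counts forced by each mapping, and returns the minimum total
#' cost. This is the testing oracle for [reconcile()]; it is limited to gene
#' trees with at most six leaves.
#'
#' @inheritParams reconcile
#' @param max_leaves Size guard on the gene tree (default 6).
#' @return Minimum total cost (numeric).
#' @export
brute_force_cost <- function(gene_tree, species_tree, costs = dtl_costs(),
                             dead_lineage = FALSE, max_leaves = 6L) {
  check_binary_rooted(gene_tree, "gene_tree")
  check_binary_rooted(species_tree, "species_tree")
  gtip <- ape::Ntip(gene_tree)
  if (gtip > max_leaves) {
    stop("brute_force_cost is limited to gene trees with <= ", max_leaves,
         " leaves", call. = FALSE)
  }
  leaf_sp <- match(gene_tree$tip.label, species_tree$tip.label)
  if (anyNA(leaf_sp)) {
    stop("Gene leaf label(s) absent from species tree: ",
         paste(unique(gene_tree$tip.label[is.na(leaf_sp)]), collapse = ", "),
         call. = FALSE)
  }
  dloc <- brute_local_table(species_tree, costs, dead_lineage)
  brute_min_cost(gene_tree, leaf_sp, dloc,
                 ns = ape::Ntip(species_tree) + species_tree$Nnode,
                 dead_lineage = dead_lineage)
}

## Enumeration core, shared so sweeps can reuse one local table per species
## tree. leaf_sp maps gene tips to species tips.
brute_min_cost <- function(gene_tree, leaf_sp, dloc, ns,
                           dead_lineage = FALSE) {
  gtip <- ape::Ntip(gene_tree)
  gn <- gtip + gene_tree$Nnode
  internal <- (gtip + 1L):gn
  gkids <- children_list(gene_tree)
  dom <- if (dead_lineage) seq_len(ns + 1L) else seq_len(ns)
  grids <- rep(list(dom), length(internal))
  names(grids) <- as.character(internal)
  maps <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  nmap <- nrow(maps)
  place <- function(node) {
    if (node <= gtip) rep.int(leaf_sp[node], nmap)
    else maps[, as.character(node)]
  }
  total <- numeric(nmap)
  for (g in internal) {
    k <- gkids[[g]]
    total <- total + dloc[cbind(place(g), place(k[1L]), place(k[2L]))]
  }
  min(total)
}

#' Extract HGT constraints from a reconciliation's transfers
#'
#' Converts every transfer event in a reconciliation witness into an HGT
#' constraint: the donor clade is the leaf set under the donor species node
#' and the recipient clade the leaf set under the recipient node. Transfers
#' into or out of the dead lineage are reported but flagged untestable (no
#' extant clade represents the dead side).
#'
#' @param rec A `dtl_reconciliation`.
#' @param species_chronogram A `chronogram` whose leaf set matches the
#'   reconciled species tree, or `NULL` to skip the leaf-set check (the
#'   clades themselves come from the reconciled species tree).
#' @param mode Node-selection mode recorded on each constraint (default
#'   `"crown-crown"`).
#' @return Data frame with columns `constraint_id`, `donor_taxa`,
#'   `recipient_taxa` (semicolon-separated leaf labels), `mode` and
#'   `untestable`. Usable directly with [compatibility_fraction()] or
#'   written as a constraint TSV.
#' @export
extract_transfers <- function(rec, species_chronogram = NULL,
                              mode = "crown-crown") {
  stopifnot(inherits(rec, "dtl_reconciliation"))
  if (!is.null(species_chronogram)) {
    stopifnot(inherits(species_chronogram, "chronogram"))
    if (!setequal(rec$species_tree$tip.label,
                  species_chronogram$phy$tip.label)) {
      stop("Chronogram leaf set does not match the reconciled species tree",
           call. = FALSE)
    }
  }
  tr <- rec$events[rec$events$kind %in% c("transfer", "transfer-loss"), ,
                   drop = FALSE]
  if (nrow(tr) == 0L) {
    return(data.frame(constraint_id = character(), donor_taxa = character(),
                      recipient_taxa = character(), mode = character(),
                      untestable = logical()))
  }
  below <- tips_under(rec$species_tree)
  labs <- rec$species_tree$tip.label
  clade_str <- function(node) {
    if (node == DEAD) return(NA_character_)
    paste(sort(labs[below[[node]]]), collapse = ";")
  }
  donor <- vapply(tr$donor, clade_str, character(1L))
  recip <- vapply(tr$recipient, clade_str, character(1L))
  data.frame(
    constraint_id = sprintf("hgt%02d", seq_len(nrow(tr))),
    donor_taxa = donor,
    recipient_taxa = recip,
    mode = mode,
    untestable = is.na(donor) | is.na(recip),
    stringsAsFactors = FALSE
  )
}

#' Check transfers for chronological consistency on a dated species tree
#'
#' For each transfer event in a reconciliation, tests whether the donor
#' edge's time interval (from the donor node's age up to its parent's age)
#' overlaps the recipient edge's interval: a transfer requires the two
#' lineages to be contemporaneous. This interval check is more permissive
#' than the strict crown-age comparison used when scoring posterior
#' ensembles with [is_compatible()]; both views are informative.
#'
#' @inheritParams extract_transfers
#' @return Data frame with one row per transfer: `donor`, `recipient`
#'   (species node numbers, `0` = dead lineage), the four interval bounds,
#'   and `consistent` (`NA` for dead-lineage transfers).
#' @export
check_time_consistency <- function(rec, species_chronogram) {
  stopifnot(inherits(rec, "dtl_reconciliation"),
            inherits(species_chronogram, "chronogram"))
  if (!setequal(rec$species_tree$tip.label,
                species_chronogram$phy$tip.label)) {
    stop("Chronogram leaf set does not match the reconciled species tree",
         call. = FALSE)
  }
  tr <- rec$events[rec$events$kind %in% c("transfer", "transfer-loss"), ,
                   drop = FALSE]
  ## map species-tree nodes to chronogram nodes via shared tip labels
  below <- tips_under(rec$species_tree)
  labs <- rec$species_tree$tip.label
  edge_interval <- function(node) {
    if (node == DEAD) return(c(NA_real_, NA_real_))
    taxa <- labs[below[[node]]]
    cn <- mrca_node(species_chronogram, taxa, warn = FALSE)
    lo <- species_chronogram$ages[[cn]]
    p <- species_chronogram$parent[[cn]]
    hi <- if (p == 0L) Inf else species_chronogram$ages[[p]]
    c(lo, hi)
  }
  n <- nrow(tr)
  out <- data.frame(donor = tr$donor, recipient = tr$recipient,
                    donor_lo = numeric(n), donor_hi = numeric(n),
                    recipient_lo = numeric(n), recipient_hi = numeric(n),
                    consistent = logical(n))
  for (i in seq_len(n)) {
    di <- edge_interval(tr$donor[i])
    ri <- edge_interval(tr$recipient[i])
    out[i, c("donor_lo", "donor_hi")] <- di
    out[i, c("recipient_lo", "recipient_hi")] <- ri
    out$consistent[i] <- if (anyNA(c(di, ri))) NA else
      (di[1L] <= ri[2L] && ri[1L] <= di[2L])
  }
  out
}
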