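#' DTL event costs
#'
#' Constructs a validated Duplication-Transfer-Loss cost vector. Speciations
#' are free; a duplication costs `delta`, a transfer `tau`, and each loss
#' (including the loss component of speciation-loss) `lam`.
#'
#' @param delta,tau,lam Nonnegative event costs. The two classical settings
#'   are `(1, 1, 1)` and `(1, 3, 1)`.
#' @return Named numeric vector of class `dtl_costs`.
#' @export
dtl_costs <- function(delta = 1, tau = 1, lam = 1) {
  v <- c(delta = as.numeric(delta), tau = as.numeric(tau),
         lam = as.numeric(lam))
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("DTL costs must be finite and nonnegative", call. = FALSE)
  }
  class(v) <- "dtl_costs"
  v
}

as_dtl_costs <- function(costs) {
  if (inherits(costs, "dtl_costs")) return(costs)
  stopifnot(is.numeric(costs), length(costs) == 3L)
  dtl_costs(costs[[1L]], costs[[2L]], costs[[3L]])
}

## index used for the auxiliary dead/unsampled lineage in mappings and events
DEAD <- 0L

check_binary_rooted <- function(phy, what) {
  if (!inherits(phy, "phylo")) stop(what, " must be a phylo object",
                                    call. = FALSE)
  if (!ape::is.rooted(phy)) stop(what, " must be rooted", call. = FALSE)
  if (ape::Ntip(phy) >= 2L && !ape::is.binary(phy)) {
    stop(what, " must be binary (resolve polytomies first)", call. = FALSE)
  }
  invisible(phy)
}

## Relations on species nodes used by both the DP and the brute-force
## oracle's caller: descq[a, b] is TRUE iff b lies in the subtree of a
## (descendant-or-equal).
species_relations <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  kids <- children_list(phy)
  descq <- diag(n) > 0
  for (v in postorder_nodes(phy)) {
    for (k in kids[[v]]) descq[v, ] <- descq[v, ] | descq[k, ]
  }
  depth <- integer(n)  # node depth in edges from the root
  parent <- parent_vector(phy)
  for (v in rev(postorder_nodes(phy))) {
    if (parent[v] != 0L) depth[v] <- depth[parent[v]] + 1L
  }
  list(n = n, ntip = ntip, kids = kids, parent = parent, depth = depth,
       descq = descq, incomp = !descq & !t(descq),
       postorder = postorder_nodes(phy))
}

#' Minimum-cost DTL reconciliation of a gene tree with a species tree
#'
#' Finds a minimum-cost reconciliation of a rooted binary gene tree with a
#' rooted binary species tree under the undated
#' Duplication-Transfer-Loss parsimony model, by dynamic programming over
#' (gene node, species node) pairs. At every pair the cheapest of speciation
#' (the gene children separate into the two species subtrees), duplication
#' (cost `delta`, both children stay), and transfer (cost `tau`, one child
#' remains while the other maps to any species node neither ancestral nor
#' descendant) is taken, each combined with cheapest loss paths (`lam` per
#' loss) through intervening species nodes. The gene root may map to any
#' species node with no charge above it. Transfers are constrained only by
#' non-ancestry (no dates); chronological plausibility is assessed
#' downstream from dated trees.
#'
#' With `dead_lineage = TRUE` a single auxiliary unsampled lineage running
#' parallel to the whole species tree is available: a transfer may enter it
#' (`tau`) and later exit it (`tau`) and it persists for free, so gene
#' lineages may be routed through extinct or unsampled diversity.
#'
#' Ties are broken deterministically: events are preferred in the order
#' speciation, transfer, duplication, and remaining ties by species-node
#' postorder index, so one witness history is returned.
#'
#' @param gene_tree Rooted binary `phylo`; every tip label must name a
#'   species-tree tip (repeated labels denote multiple gene copies).
#' @param species_tree Rooted binary `phylo`.
#' @param costs A [dtl_costs()] vector or numeric `c(delta, tau, lam)`.
#' @param dead_lineage Allow routing through the unsampled lineage
#'   (default `FALSE`).
#' @return An object of class `dtl_reconciliation`: list with `total_cost`,
#'   `mapping` (species node per gene node; `0` denotes the dead lineage),
#'   `events` (data frame with columns `kind`, `gene_node`, `species_node`,
#'   `donor`, `recipient`), `cost_vector`, `dead_lineage_used`, and the two
#'   input trees.
#' @examples
#' g <- parse_newick("((A:1,C:1):1,B:2);")
#' s <- parse_newick("((A:1,B:1):1,C:2);")
#' reconcile(g, s, dtl_costs(1, 1, 1))$total_cost  # 1 (one transfer)
#' reconcile(g, s, dtl_costs(1, 3, 1))$total_cost  # 3
#' @export
reconcile <- function(gene_tree, species_tree, costs = dtl_costs(),
                      dead_lineage = FALSE) {
  costs <- as_dtl_costs(costs)
  check_binary_rooted(gene_tree, "gene_tree")
  check_binary_rooted(species_tree, "species_tree")
  delta <- costs[["delta"]]; tau <- costs[["tau"]]; lam <- costs[["lam"]]

  sp <- species_relations(species_tree)
  gtip <- ape::Ntip(gene_tree)
  gn <- gtip + gene_tree$Nnode
  gkids <- children_list(gene_tree)
  gpost <- postorder_nodes(gene_tree)

  leaf_sp <- match(gene_tree$tip.label, species_tree$tip.label)
  if (anyNA(leaf_sp)) {
    stop("Gene leaf label(s) absent from species tree: ",
         paste(unique(gene_tree$tip.label[is.na(leaf_sp)]), collapse = ", "),
         call. = FALSE)
  }

  ns <- sp$n
  nd <- ns + 1L                 # column nd holds the dead lineage, if used
  ncol_tot <- if (dead_lineage) nd else ns
  ## postorder rank over species columns; used for deterministic tie-breaks
  rank_of <- integer(ncol_tot)
  rank_of[sp$postorder] <- seq_len(ns)
  if (dead_lineage) rank_of[nd] <- ns + 1L
  col_order <- order(rank_of)

  C <- matrix(Inf, nrow = gn, ncol = ncol_tot)   # g mapped exactly at s
  IN <- matrix(Inf, nrow = gn, ncol = ncol_tot)  # g maps within subtree of s
  choice <- vector("list", gn)                   # backtracking records

  incomp_cols <- lapply(seq_len(ns), function(s) {
    cols <- which(sp$incomp[s, ])
    cols <- cols[order(rank_of[cols])]
    if (dead_lineage) c(cols, nd) else cols
  })
  if (dead_lineage) {
    incomp_cols[[nd]] <- sp$postorder   # everything is reachable from dead
  }

  ## minimum and deterministic argmin over a set of columns of a cost vector
  amin <- function(vals, cols) {
    if (length(cols) == 0L) return(list(cost = Inf, col = NA_integer_))
    v <- vals[cols]
    i <- which.min(v)                   # cols are pre-sorted by rank
    list(cost = v[[i]], col = cols[[i]])
  }

  for (g in gpost) {
    if (g <= gtip) {
      C[g, leaf_sp[g]] <- 0
    } else {
      g1 <- gkids[[g]][1L]; g2 <- gkids[[g]][2L]
      ch <- vector("list", ncol_tot)
      out1 <- lapply(seq_len(ncol_tot), function(s) amin(C[g1, ], incomp_cols[[s]]))
      out2 <- lapply(seq_len(ncol_tot), function(s) amin(C[g2, ], incomp_cols[[s]]))
      for (s in sp$postorder) {
        cand_cost <- numeric(0); cand <- list()
        if (s > sp$ntip) {
          a <- sp$kids[[s]][1L]; b <- sp$kids[[s]][2L]
          cand_cost <- c(cand_cost, IN[g1, a] + IN[g2, b],
                         IN[g1, b] + IN[g2, a])
          cand <- c(cand, list(list(ev = "speciation", a1 = a, a2 = b),
                               list(ev = "speciation", a1 = b, a2 = a)))
        }
        cand_cost <- c(cand_cost,
                       tau + IN[g1, s] + out2[[s]]$cost,
                       tau + IN[g2, s] + out1[[s]]$cost,
                       delta + IN[g1, s] + IN[g2, s])
        cand <- c(cand,
                  list(list(ev = "transfer", stay = g1, leave = g2,
                            to = out2[[s]]$col),
                       list(ev = "transfer", stay = g2, leave = g1,
                            to = out1[[s]]$col),
                       list(ev = "duplication")))
        best <- which.min(cand_cost)     # candidates listed in preference order
        C[g, s] <- cand_cost[[best]]
        ch[[s]] <- cand[[best]]
      }
      if (dead_lineage) {
        cand_cost <- c(tau + C[g1, nd] + amin(C[g2, ], sp$postorder)$cost,
                       tau + C[g2, nd] + amin(C[g1, ], sp$postorder)$cost,
                       delta + C[g1, nd] + C[g2, nd])
        cand <- list(list(ev = "transfer", stay = g1, leave = g2,
                          to = amin(C[g2, ], sp$postorder)$col, from_dead = TRUE),
                     list(ev = "transfer", stay = g2, leave = g1,
                          to = amin(C[g1, ], sp$postorder)$col, from_dead = TRUE),
                     list(ev = "duplication"))
        best <- which.min(cand_cost)
        C[g, nd] <- cand_cost[[best]]
        ch[[nd]] <- cand[[best]]
      }
      choice[[g]] <- ch
    }
    ## IN by postorder over species: speciation-loss descent
    for (s in sp$postorder) {
      v <- C[g, s]
      if (s > sp$ntip) {
        v <- min(v, lam + min(IN[g, sp$kids[[s]]]))
      }
      IN[g, s] <- v
    }
    if (dead_lineage) IN[g, nd] <- C[g, nd]
  }

  groot <- root_node(gene_tree)
  rt <- amin(C[groot, ], col_order)
  total <- rt$cost
  if (!is.finite(total)) stop("No finite reconciliation found", call. = FALSE)

  ## ---- backtracking: reconstruct one witness history ----
  events <- list()
  mapping <- rep(NA_integer_, gn)
  add_event <- function(kind, gene_node = NA_integer_,
                        species_node = NA_integer_,
                        donor = NA_integer_, recipient = NA_integer_) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, gene_node = gene_node, species_node = species_node,
      donor = donor, recipient = recipient)
  }
  ext <- function(s) if (dead_lineage && s == nd) DEAD else s

  resolve_at <- function(g, s) {
    mapping[g] <<- ext(s)
    if (g <= gtip) return(invisible())
    chs <- choice[[g]][[s]]
    g1 <- gkids[[g]][1L]; g2 <- gkids[[g]][2L]
    if (chs$ev == "speciation") {
      add_event("speciation", g, ext(s))
      resolve_in(g1, chs$a1)
      resolve_in(g2, chs$a2)
    } else if (chs$ev == "duplication") {
      add_event("duplication", g, ext(s))
      if (dead_lineage && s == nd) {
        resolve_at(g1, nd); resolve_at(g2, nd)
      } else {
        resolve_in(g1, s); resolve_in(g2, s)
      }
    } else {
      add_event("transfer", g, ext(s), donor = ext(s),
                recipient = ext(chs$to))
      if (dead_lineage && s == nd) {
        resolve_at(chs$stay, nd)
      } else {
        resolve_in(chs$stay, s)
      }
      resolve_at(chs$leave, chs$to)
    }
  }
  resolve_in <- function(g, s) {
    ## descend through speciation-losses until C is reached
    while (IN[g, s] < C[g, s]) {
      ks <- sp$kids[[s]]
      nxt <- ks[order(rank_of[ks])]
      picked <- FALSE
      for (k in nxt) {
        if (isTRUE(all.equal(IN[g, s], lam + IN[g, k])) ||
            IN[g, s] == lam + IN[g, k]) {
          add_event("speciation-loss", g, s)
          s <- k
          picked <- TRUE
          break
        }
      }
      if (!picked) break
    }
    resolve_at(g, s)
  }
  resolve_at(groot, rt$col)

  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(kind = character(), gene_node = integer(),
               species_node = integer(), donor = integer(),
               recipient = integer())
  res <- structure(list(
    total_cost = total,
    mapping = mapping,
    events = events,
    cost_vector = costs,
    dead_lineage_used = dead_lineage &&
      (any(mapping == DEAD, na.rm = TRUE)),
    gene_tree = gene_tree,
    species_tree = species_tree
  ), class = "dtl_reconciliation")
  res
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  tab <- table(x$events$kind)
  cat("DTL reconciliation: total cost", x$total_cost, "\n")
  cat("  costs (delta, tau, lam):",
      paste(unclass(x$cost_vector), collapse = ", "), "\n")
  if (length(tab) > 0L) {
    cat("  events:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  if (x$dead_lineage_used) cat("  (dead lineage used)\n")
  invisible(x)
}

#' Recompute a reconciliation's cost from its event list
#'
#' Sums `delta` per duplication, `tau` per transfer (including any
#' transfer-loss) and `lam` per loss (including the loss component of
#' compound events) over the witness event list. Used to check the witness
#' against `total_cost`.
#'
#' @param rec A `dtl_reconciliation`.
#' @return Numeric cost.
#' @export
event_list_cost <- function(rec) {
  stopifnot(inherits(rec, "dtl_reconciliation"))
  k <- rec$events$kind
  cv <- rec$cost_vector
  cv[["delta"]] * sum(k == "duplication") +
    cv[["tau"]] * sum(k %in% c("transfer", "transfer-loss")) +
    cv[["lam"]] * sum(k %in% c("loss", "speciation-loss")) +
    (cv[["lam"]]) * sum(k == "transfer-loss")
}
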