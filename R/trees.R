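#' Parse a rooted Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape` `phylo` object with topology, branch lengths and any internal node
#' labels preserved.
#'
#' @param text Newick string (exactly one tree).
#' @param allow_duplicates Permit repeated leaf labels (`FALSE` by default;
#'   gene trees use repeated labels for multiple copies in one species).
#' @return A `phylo` object.
#' @examples
#' parse_newick("((A:1,B:1):2,(C:2,D:2):1);")
#' @export
parse_newick <- function(text, allow_duplicates = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("Malformed Newick string: ", substr(text, 1L, 60L), call. = FALSE)
  }
  if (!allow_duplicates && anyDuplicated(phy$tip.label)) {
    stop("Duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  phy
}

## parent[i] = parent node of node i (0 for the root), from the edge matrix
parent_vector <- function(phy) {
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(n_nodes)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  parent
}

root_node <- function(phy) ape::Ntip(phy) + 1L

## children[[i]] = integer vector of children of node i
children_list <- function(phy) {
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n_nodes)))
}

## node indices in postorder (every child precedes its parent)
postorder_nodes <- function(phy) {
  ord <- ape::reorder.phylo(phy, "postorder")
  c(ord$edge[, 2L], root_node(phy))
}

## tip indices (1..Ntip) below each node, as a list over all nodes
tips_under <- function(phy) {
  ntip <- ape::Ntip(phy)
  kids <- children_list(phy)
  out <- vector("list", ntip + phy$Nnode)
  for (v in postorder_nodes(phy)) {
    if (v <= ntip) out[[v]] <- v
    else out[[v]] <- unlist(out[kids[[v]]], use.names = FALSE)
  }
  out
}

#' Convert a tree with branch lengths to a chronogram
#'
#' Computes node ages as maximum root-to-tip distance minus root-to-node
#' distance and validates ultrametricity: every tip must lie at the same
#' distance from the root within `tolerance` times the tree height. Tip ages
#' are snapped to exactly zero after validation, so all taxa are treated as
#' extant. Ages are in the branch-length unit (Ma throughout this package).
#'
#' @param phy A rooted `phylo` with branch lengths, or a Newick string.
#' @param tolerance Relative ultrametricity tolerance (default `1e-6`).
#' @return An object of class `chronogram`: a list with elements `phy`,
#'   `ages` (numeric vector indexed by node number), `parent` and `root_age`.
#' @examples
#' ch <- as_chronogram("((A:1,B:1):2,(C:2,D:2):1);")
#' ch$root_age  # 3
#' @export
as_chronogram <- function(phy, tolerance = 1e-6) {
  if (is.character(phy)) phy <- parse_newick(phy)
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop("Tree has no branch lengths; cannot build a chronogram",
         call. = FALSE)
  }
  ntip <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(ntip)])
  if (height <= 0) stop("Tree height must be positive", call. = FALSE)
  tip_depth <- depth[seq_len(ntip)]
  dev <- height - tip_depth
  if (max(dev) > tolerance * height) {
    worst <- which.max(dev)
    deepest <- which.max(tip_depth)
    stop(sprintf(paste0("Tree is not ultrametric: tip '%s' at depth %g vs ",
                        "tip '%s' at depth %g (tolerance %g x height)"),
                 phy$tip.label[worst], tip_depth[worst],
                 phy$tip.label[deepest], tip_depth[deepest], tolerance),
         call. = FALSE)
  }
  ages <- height - depth
  ages[seq_len(ntip)] <- 0
  parent <- parent_vector(phy)
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  kids_age_ok <- ages[phy$edge[, 1L]] > ages[phy$edge[, 2L]]
  if (!all(kids_age_ok)) {
    bad <- which(!kids_age_ok)[1L]
    stop(sprintf("Node ages not strictly decreasing along edge %d -> %d",
                 phy$edge[bad, 1L], phy$edge[bad, 2L]), call. = FALSE)
  }
  structure(list(phy = phy, ages = ages, parent = parent,
                 root_age = ages[root_node(phy)]),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("Chronogram with", ape::Ntip(x$phy), "tips; root age",
      format(x$root_age, digits = 6), "Ma\n")
  invisible(x)
}

#' Most recent common ancestor of a set of leaves
#'
#' Returns the node number of the MRCA of `taxa` on a chronogram. When the
#' taxa are not monophyletic in this tree the spanning MRCA is returned and,
#' unless `warn = FALSE`, a warning is raised (posterior samples may vary in
#' topology, so this is not an error).
#'
#' @param x A `chronogram`.
#' @param taxa Non-empty character vector of leaf labels.
#' @param warn Warn when the clade is non-monophyletic (default `TRUE`).
#' @return Node number, with attribute `monophyletic` (logical).
#' @export
mrca_node <- function(x, taxa, warn = TRUE) {
  stopifnot(inherits(x, "chronogram"), length(taxa) >= 1L)
  taxa <- unique(as.character(taxa))
  tips <- match(taxa, x$phy$tip.label)
  if (anyNA(tips)) {
    stop("Unknown leaf label(s): ", paste(taxa[is.na(tips)], collapse = ", "),
         call. = FALSE)
  }
  if (length(tips) == 1L) {
    return(structure(tips, monophyletic = TRUE))
  }
  # climb from the first tip to the root, then intersect the other paths
  path <- integer(0)
  v <- tips[[1L]]
  repeat {
    path <- c(path, v)
    if (x$parent[v] == 0L) break
    v <- x$parent[v]
  }
  pos <- 1L
  in_path <- match(seq_along(x$parent), path)  # node -> position in path
  for (t in tips[-1L]) {
    v <- t
    while (is.na(in_path[v])) v <- x$parent[v]
    pos <- max(pos, in_path[v])
  }
  node <- path[pos]
  n_desc <- n_tips_below(x, node)
  mono <- n_desc == length(tips)
  if (!mono && warn) {
    warning(sprintf("Taxa are not monophyletic here (%d extra tip%s under the spanning MRCA)",
                    n_desc - length(tips),
                    if (n_desc - length(tips) == 1L) "" else "s"),
            call. = FALSE)
  }
  structure(node, monophyletic = mono)
}

n_tips_below <- function(x, node) {
  ntip <- ape::Ntip(x$phy)
  if (node <= ntip) return(1L)
  kids <- children_list(x$phy)
  count <- function(v) {
    if (v <= ntip) return(1L)
    sum(vapply(kids[[v]], count, integer(1L)))
  }
  count(node)
}

#' Crown and stem ages of a clade
#'
#' The crown age is the age of the clade's MRCA; the stem age is the age of
#' that node's parent (the divergence from the sister lineage). For a clade
#' whose MRCA is the root, both equal the root age.
#'
#' @inheritParams mrca_node
#' @return Age in Ma.
#' @examples
#' ch <- as_chronogram("((A:1,B:1):2,(C:2,D:2):1);")
#' crown_age(ch, c("A", "B"))  # 1
#' stem_age(ch, c("A", "B"))   # 3
#' @export
crown_age <- function(x, taxa, warn = TRUE) {
  node <- mrca_node(x, taxa, warn = warn)
  x$ages[[node]]
}

#' @rdname crown_age
#' @export
stem_age <- function(x, taxa, warn = TRUE) {
  node <- mrca_node(x, taxa, warn = warn)
  p <- x$parent[[node]]
  if (p == 0L) x$ages[[node]] else x$ages[[p]]
}

#' Build a posterior chronogram ensemble from Newick tree lists
#'
#' Reads one or more tree-list files (one Newick tree per line, the format
#' written by Bayesian dating programs), discards the first
#' `floor(burn_in * n)` trees of each file as burn-in, retains every
#' `thin`-th of the remainder, and concatenates files in order (multiple
#' chains are merged after burn-in). All samples must share one leaf set.
#'
#' @param paths Character vector of tree-list file paths.
#' @param burn_in Fraction of each chain to discard (default 0.25; `0.2` is
#'   a common alternative -- both conventions occur in practice, so this is a
#'   parameter, never hard-coded).
#' @param thin Retain every `thin`-th post-burn-in tree (default 1).
#' @param label Ensemble tag, e.g. a rate-model/prior combination such as
#'   `"CIR+UNI"`.
#' @param tolerance Ultrametricity tolerance passed to [as_chronogram()].
#' @return A `tree_ensemble` object.
#' @export
load_ensemble <- function(paths, burn_in = 0.25, thin = 1L, label = "",
                          tolerance = 1e-6) {
  stopifnot(length(paths) >= 1L, burn_in >= 0, burn_in < 1, thin >= 1L)
  samples <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("Tree list not found: ", p, call. = FALSE)
    trees <- ape::read.tree(p)
    if (inherits(trees, "phylo")) trees <- list(trees)
    n <- length(trees)
    drop <- floor(burn_in * n)
    kept <- trees[drop + seq(thin, n - drop, by = thin)]
    samples <- c(samples, lapply(kept, as_chronogram, tolerance = tolerance))
  }
  tree_ensemble(samples, label = label)
}

#' Construct a tree ensemble from chronograms
#'
#' @param samples List of `chronogram` objects sharing one leaf set.
#' @param label Ensemble tag.
#' @return A `tree_ensemble`: list with `samples`, `label`, `leaves`.
#' @export
tree_ensemble <- function(samples, label = "") {
  stopifnot(is.list(samples), length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1L), "chronogram")))
  leaves <- sort(samples[[1L]]$phy$tip.label)
  for (i in seq_along(samples)) {
    li <- sort(samples[[i]]$phy$tip.label)
    if (!identical(li, leaves)) {
      diff <- c(setdiff(li, leaves), setdiff(leaves, li))
      stop("Leaf-set mismatch in ensemble sample ", i, ": ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(samples = samples, label = label, leaves = leaves),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("Tree ensemble", if (nzchar(x$label)) sQuote(x$label) else "",
      "with", length(x$samples), "samples,",
      length(x$leaves), "leaves\n")
  invisible(x)
}

#' @export
length.tree_ensemble <- function(x) length(x$samples)

#' Summarize clade ages over a posterior ensemble
#'
#' Computes the posterior mean, median and 95% equal-tailed credible interval
#' (2.5th and 97.5th percentiles, linear interpolation between order
#' statistics) of a clade's crown or stem age over every sample in the
#' ensemble.
#'
#' @param ensemble A `tree_ensemble`.
#' @param taxa Character vector of leaf labels defining the clade.
#' @param mode `"crown"` (MRCA age, default) or `"stem"` (age of the MRCA's
#'   parent).
#' @return One-row data frame with columns `n`, `mean`, `median`, `ci_low`,
#'   `ci_high` (Ma).
#' @export
summarize_ages <- function(ensemble, taxa, mode = c("crown", "stem")) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  mode <- match.arg(mode)
  if (length(ensemble$samples) == 0L) stop("Empty ensemble", call. = FALSE)
  agefun <- if (mode == "crown") crown_age else stem_age
  ages <- vapply(ensemble$samples, agefun, numeric(1L),
                 taxa = taxa, warn = FALSE)
  non_mono <- sum(!vapply(ensemble$samples, function(s)
    isTRUE(attr(mrca_node(s, taxa, warn = FALSE), "monophyletic")),
    logical(1L)))
  if (non_mono > 0L) {
    warning(sprintf("Clade non-monophyletic in %d of %d samples; spanning MRCA used",
                    non_mono, length(ages)), call. = FALSE)
  }
  ci <- stats::quantile(ages, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(n = length(ages), mean = mean(ages),
             median = stats::median(ages),
             ci_low = ci[[1L]], ci_high = ci[[2L]])
}
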