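# Distance-based phylogeny reconstruction with column-resampling bootstrap.
#
# Distances are p-distances (fraction of differing sites over columns where
# both rows are ungapped) or their Poisson correction -ln(1 - p); trees are
# built by classical neighbor joining (Saitou-Nei Q-criterion) with a
# deterministic lowest-index tie-break, returned as `ape` "phylo" objects
# so that Newick IO and downstream tree tooling come for free.

#' Pairwise evolutionary distances from an alignment
#'
#' For each pair of rows, the p-distance is computed over columns where
#' both rows are non-gap; \code{model = "poisson"} applies the multiple-hit
#' correction \eqn{-\ln(1 - p)}, capped at `max_dist` for saturated pairs
#' (\eqn{p \ge 0.95}).
#'
#' @param aln A \code{tbm_alignment} with at least 3 rows.
#' @param model \code{"poisson"} (default) or \code{"p"}.
#' @param max_dist Cap applied to saturated Poisson distances.
#' @return Symmetric numeric matrix with zero diagonal and row ids as
#'   dimnames.
#' @export
distance_from_alignment <- function(aln, model = c("poisson", "p"),
                                    max_dist = -log(0.05)) {
  stopifnot(inherits(aln, "tbm_alignment"))
  model <- match.arg(model)
  if (n_rows(aln) < 3L) stop("need at least 3 rows for a distance matrix")
  m <- as.matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- m[i, ] != GAP & m[j, ] != GAP
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns for pair ", aln$ids[i], " / ",
             aln$ids[j])
      p <- sum(m[i, comp] != m[j, comp]) / nc
      v <- if (model == "p") p
           else if (p >= 0.95) max_dist
           else -log(1 - p)
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Saitou--Nei): at each step the pair
#' minimizing \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} is joined, with ties
#' broken deterministically by the lowest pair of positions in the current
#' node ordering (original taxon order, newly created nodes appended).
#' Negative branch lengths are clamped to 0.  The result is an unrooted
#' binary tree; for additive input distances it reproduces the generating
#' tree exactly (topology and branch lengths).
#'
#' @param dm Symmetric distance matrix with taxon dimnames (as from
#'   \code{\link{distance_from_alignment}}).
#' @return An \pkg{ape} \code{phylo} object.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  if (any(!is.finite(dm)) || any(dm < 0))
    stop("distances must be finite and non-negative")

  D <- dm
  active <- seq_len(n)            # node ids of the active rows of D
  children <- list()              # internal id -> matrix (child id, length)
  next_id <- n
  while (length(active) > 3L) {
    r <- length(active)
    Rsum <- rowSums(D)
    Q <- (r - 2) * D - outer(Rsum, Rsum, `+`)
    diag(Q) <- Inf
    # lowest-index tie-break: scan i<j in current order
    best <- c(Inf, 0L, 0L)
    for (i in 1:(r - 1L)) for (j in (i + 1L):r) {
      if (Q[i, j] < best[1] - 1e-12) best <- c(Q[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    li <- D[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    next_id <- next_id + 1L
    children[[as.character(next_id)]] <-
      rbind(c(active[i], li), c(active[j], lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    active <- c(active[keep], next_id)
  }
  # final three-point join
  a <- 1L; b <- 2L; c_ <- 3L
  la <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
  lb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
  lc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
  next_id <- next_id + 1L
  children[[as.character(next_id)]] <-
    rbind(c(active[a], max(la, 0)),
          c(active[b], max(lb, 0)),
          c(active[c_], max(lc, 0)))
  .build_phylo(n, taxa, children, root_id = next_id)
}

# Convert the children map (internal ids > n) into an ape phylo object.
.build_phylo <- function(n, taxa, children, root_id) {
  n_internal <- length(children)
  # assign ape numbers: tips keep 1..n; internals renumbered in preorder
  ape_num <- integer(0)
  counter <- n
  edges <- matrix(0L, 0L, 2L)
  lengths <- numeric(0)
  assign_num <- function(id) {
    counter <<- counter + 1L
    ape_num[[as.character(id)]] <<- counter
    counter
  }
  walk <- function(id) {
    my <- ape_num[[as.character(id)]]
    ch <- children[[as.character(id)]]
    for (k in seq_len(nrow(ch))) {
      cid <- ch[k, 1]; len <- ch[k, 2]
      if (cid <= n) {
        edges <<- rbind(edges, c(my, as.integer(cid)))
        lengths <<- c(lengths, len)
      } else {
        cnum <- assign_num(cid)
        edges <<- rbind(edges, c(my, cnum))
        lengths <<- c(lengths, len)
        walk(cid)
      }
    }
  }
  assign_num(root_id)
  walk(root_id)
  tr <- structure(list(edge = edges, edge.length = lengths,
                       tip.label = taxa, Nnode = n_internal),
                  class = "phylo", order = "cladewise")
  tr
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys named by
# the internal node heading each edge.  Each internal edge splits the taxa
# in two; the key is the sorted side not containing the alphabetically
# first taxon, comma-joined.
.tree_splits <- function(tree) {
  anchor <- sort(tree$tip.label)[1]
  n <- length(tree$tip.label)
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- integer(0)
    for (k in kids) {
      if (k <= n) out <- c(out, k) else out <- c(out, desc(k))
    }
    out
  }
  root <- n + 1L
  nodes <- setdiff(tree$edge[tree$edge[, 2] > n, 2], root)  # non-root internals
  keys <- character(0)
  for (v in nodes) {
    side <- tree$tip.label[desc(v)]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys[[as.character(v)]] <- paste(sort(side), collapse = ",")
  }
  keys
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times; the support of each internal edge of
#' the full-data tree is the percentage of replicate trees containing the
#' same bipartition.  Supports are attached as internal node labels, so
#' \code{ape::write.tree} emits them in the conventional Newick position.
#' The procedure is fully reproducible: all resampling is driven by a
#' single generator seeded with `seed`, replicates drawn sequentially.
#'
#' @param aln A \code{tbm_alignment} (>= 3 rows).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (required; no wall-clock default).
#' @param model Distance model, see \code{\link{distance_from_alignment}}.
#' @return An \pkg{ape} \code{phylo} object whose \code{node.label} holds
#'   the support percentages ("" for the root).
#' @export
bootstrap_nj <- function(aln, n_replicates, seed, model = "poisson") {
  stopifnot(inherits(aln, "tbm_alignment"), n_replicates >= 1L)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  full <- neighbor_joining(distance_from_alignment(aln, model))
  keys <- .tree_splits(full)         # named by internal node number
  counts <- setNames(numeric(length(keys)), unname(keys))
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(aln$ncols, aln$ncols, replace = TRUE)
    rep_aln <- .subset_columns(aln, idx)
    rep_tree <- neighbor_joining(distance_from_alignment(rep_aln, model))
    rep_keys <- .tree_splits(rep_tree)
    hit <- unname(keys) %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_replicates
  n <- length(full$tip.label)
  labels <- character(full$Nnode)    # "" for the root and trivial edges
  for (k in seq_along(keys)) {
    node <- as.integer(names(keys)[k])
    labels[node - n] <- format(unname(supports[[keys[[k]]]]), trim = TRUE)
  }
  full$node.label <- labels
  full
}
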