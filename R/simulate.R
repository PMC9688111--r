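# Synthetic ortholog-family generator.
#
# Families are simulated down a species tree from a root protein built of
# ordered blocks: conserved domains (slow substitution, no indels) joined
# by fast-evolving linkers that accumulate indels -- the architecture the
# conservation and motif analyses assume.  TBMs can be planted in the root
# and inherited by a designated taxa subset; in all other taxa the motif
# arginine is ablated.  Every emitted family carries its TRUE alignment
# (indels are tracked by column identity, never re-aligned) and a truth
# table, so scanner, classifier, conservation and tree modules can all be
# tested against known ground truth with no external data.
#
# The substitution process is uniform exchange over the residue alphabet:
# a site hit by at least one Poisson event is redrawn uniformly, which is
# exact for this model and keeps background motif-hit rates analytically
# tractable.  Constrained motif positions (R; the G; position 4 of a
# canonical motif) are shielded from substitution and indels never touch a
# planted motif span; wildcard motif positions evolve freely.

#' Default domain/linker blueprint
#'
#' A miniature of a multi-domain protein: three conserved domains (low
#' substitution rate, no indels) separated by two fast linkers with
#' indels.  Rates are expected substitutions per site per unit branch
#' length; indel rates are expected indel events per linker site per unit
#' branch length.
#'
#' @return Data frame with columns \code{kind}, \code{length}, \code{rate},
#'   \code{indel_rate}.
#' @export
default_blueprint <- function() {
  data.frame(
    kind = c("domain", "linker", "domain", "linker", "domain"),
    length = c(60L, 30L, 60L, 30L, 80L),
    rate = c(0.1, 1.0, 0.1, 1.0, 0.1),
    indel_rate = c(0, 0.05, 0, 0.05, 0))
}

#' Build and validate a simulation configuration
#'
#' @param n_taxa Number of taxa (ignored for \code{tree = "fixed"}).
#' @param tree \code{"yule"} for a random birth tree (rescaled to
#'   \code{tree_depth}) or \code{"fixed"} for a user-supplied Newick.
#' @param newick Newick string with branch lengths (for
#'   \code{tree = "fixed"}); its tip labels become the taxa.
#' @param blocks Block blueprint, see \code{\link{default_blueprint}}.
#' @param motifs List of planted motifs, each a list with \code{block}
#'   (block index), \code{offset} (1-based within the block),
#'   \code{configuration} (\code{"canonical"}, \code{"rx4"} or
#'   \code{"rx5"}) and \code{taxa} (character subset carrying the motif).
#' @param seed Integer seed; the whole family is deterministic given the
#'   configuration.
#' @param alphabet Residue alphabet for the root draw and substitutions
#'   (default the 20 amino acids).
#' @param tree_depth Root-to-tip depth the Yule tree is rescaled to.
#' @return A validated list of class \code{tbm_simconfig} (adds
#'   \code{taxa}, the tip labels).
#' @export
simulation_config <- function(n_taxa = 6L, tree = c("yule", "fixed"),
                              newick = NULL, blocks = default_blueprint(),
                              motifs = list(), seed = 1L,
                              alphabet = AA20, tree_depth = 1) {
  tree <- match.arg(tree)
  stopifnot(is.data.frame(blocks),
            all(c("kind", "length", "rate", "indel_rate") %in% names(blocks)))
  if (any(!blocks$kind %in% c("domain", "linker")))
    stop("block kind must be 'domain' or 'linker'")
  if (any(blocks$length < 1L)) stop("block lengths must be >= 1")
  if (any(blocks$rate < 0) || any(blocks$indel_rate < 0))
    stop("rates must be >= 0")
  if (any(blocks$indel_rate > 0 & blocks$kind == "domain"))
    stop("indels are restricted to linker blocks")
  if (!all(alphabet %in% AA20)) stop("alphabet must be amino-acid letters")
  if (tree == "fixed") {
    if (is.null(newick)) stop("tree = 'fixed' requires a newick string")
    tr <- ape::read.tree(text = newick)
    if (is.null(tr$edge.length)) stop("fixed tree must have branch lengths")
    taxa <- tr$tip.label
  } else {
    if (n_taxa < 3L) stop("need at least 3 taxa")
    taxa <- sprintf("sp%02d", seq_len(n_taxa))
  }
  pat <- tbm_patterns()
  spans <- list()
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    if (!all(c("block", "offset", "configuration", "taxa") %in% names(m)))
      stop("motif ", k, ": needs block, offset, configuration, taxa")
    if (m$block < 1L || m$block > nrow(blocks))
      stop("motif ", k, ": block index out of range")
    if (!(m$configuration %in% names(pat)))
      stop("motif ", k, ": unknown configuration '", m$configuration, "'")
    len <- pat[[m$configuration]]$length
    if (m$offset < 1L || m$offset + len - 1L > blocks$length[m$block])
      stop("motif ", k, ": collides with block boundary (offset ", m$offset,
           ", length ", len, ", block length ", blocks$length[m$block], ")")
    bad <- setdiff(m$taxa, taxa)
    if (length(bad)) stop("motif ", k, ": unknown taxa ",
                          paste(bad, collapse = ", "))
    if (!("R" %in% alphabet))
      stop("planted motifs require 'R' in the alphabet")
    b0 <- c(0L, cumsum(blocks$length))[m$block]
    spans[[k]] <- c(b0 + m$offset, b0 + m$offset + len - 1L)
  }
  if (length(spans) > 1L) {
    for (i in 1:(length(spans) - 1L)) for (j in (i + 1L):length(spans)) {
      if (spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2])
        stop("planted motifs ", i, " and ", j, " overlap")
    }
  }
  structure(list(n_taxa = length(taxa), tree = tree, newick = newick,
                 blocks = blocks, motifs = motifs, seed = as.integer(seed),
                 alphabet = alphabet, tree_depth = tree_depth, taxa = taxa),
            class = "tbm_simconfig")
}

# Constrained positions of a planted configuration: named residue vector
# (position within window -> fixed residue); position 4 of a canonical
# motif is drawn once from [ACGP] at planting time.
.motif_constraints <- function(configuration, alphabet) {
  switch(configuration,
         canonical = c(`1` = "R",
                       `4` = sample(intersect(c("A", "C", "G", "P"),
                                              alphabet), 1L),
                       `6` = "G"),
         rx4 = c(`1` = "R", `6` = "G"),
         rx5 = c(`1` = "R", `7` = "G"))
}

#' Simulate one ortholog family
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @return A list of class \code{tbm_family}: \code{alignment} (the true
#'   \code{tbm_alignment}), \code{records} (unaligned
#'   \code{\link{seq_record}}s), \code{tree} (the generating \pkg{ape}
#'   \code{phylo}), \code{truth} (one row per taxon x planted motif:
#'   \code{taxon}, \code{motif}, \code{configuration}, \code{present},
#'   \code{residue_position}, \code{alignment_column}), \code{col_info}
#'   (alignment column -> block kind) and \code{config}.
#' @examples
#' cfg <- simulation_config(n_taxa = 4, seed = 7)
#' fam <- simulate_family(cfg)
#' fam$alignment
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "tbm_simconfig"))
  set.seed(cfg$seed)
  # --- species tree
  if (cfg$tree == "fixed") {
    tree <- ape::read.tree(text = cfg$newick)
  } else {
    tree <- ape::rphylo(cfg$n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * cfg$tree_depth / depth
    tree$tip.label <- cfg$taxa
  }
  ntip <- length(tree$tip.label)
  blocks <- cfg$blocks
  L <- sum(blocks$length)
  block_of <- rep(seq_len(nrow(blocks)), blocks$length)

  # --- root sequence with planted motifs
  residues <- sample(cfg$alphabet, L, replace = TRUE)
  motif_meta <- list()
  for (k in seq_along(cfg$motifs)) {
    m <- cfg$motifs[[k]]
    len <- tbm_patterns()[[m$configuration]]$length
    b0 <- c(0L, cumsum(blocks$length))[m$block]
    start <- b0 + m$offset
    cons <- .motif_constraints(m$configuration, cfg$alphabet)
    residues[start + as.integer(names(cons)) - 1L] <- cons
    motif_meta[[k]] <- list(index = k, configuration = m$configuration,
                            taxa = m$taxa,
                            r_id = start,
                            span_ids = start:(start + len - 1L),
                            constrained_ids = start + as.integer(names(cons)) - 1L,
                            key_lo = start, key_hi = start + len - 1L)
  }
  protected_sub <- unique(unlist(lapply(motif_meta, `[[`, "constrained_ids")))
  protected_span <- unique(unlist(lapply(motif_meta, `[[`, "span_ids")))
  if (is.null(protected_sub)) protected_sub <- integer(0)
  if (is.null(protected_span)) protected_span <- integer(0)
  span_int <- lapply(motif_meta, function(m) c(m$key_lo, m$key_hi))

  root_cols <- data.frame(id = seq_len(L), key = as.numeric(seq_len(L)),
                          block = block_of, residue = residues)
  ev <- new.env()
  ev$next_id <- L

  mutate <- function(cols, b) {
    # substitutions: a site hit by >= 1 Poisson event is redrawn uniformly
    rates <- blocks$rate[cols$block]
    hit <- runif(nrow(cols)) < (1 - exp(-rates * b))
    hit <- hit & !(cols$id %in% protected_sub)
    if (any(hit))
      cols$residue[hit] <- sample(cfg$alphabet, sum(hit), replace = TRUE)
    # indels, linker blocks only
    for (bk in which(blocks$indel_rate > 0)) {
      sites <- which(cols$block == bk)
      if (!length(sites)) next
      nev <- rpois(1L, blocks$indel_rate[bk] * b * length(sites))
      for (e in seq_len(nev)) {
        sites <- which(cols$block == bk)
        if (!length(sites)) break
        indel_len <- rgeom(1L, 0.5) + 1L
        if (runif(1) < 0.5) {
          # deletion: contiguous run from a uniform block site, truncated
          # at block boundaries and protected motif spans
          s <- sample(length(sites), 1L)
          del <- integer(0)
          r <- sites[s]
          while (length(del) < indel_len && r <= nrow(cols) &&
                 cols$block[r] == bk) {
            if (cols$id[r] %in% protected_span) break
            del <- c(del, r)
            r <- r + 1L
          }
          if (length(del)) cols <- cols[-del, , drop = FALSE]
        } else {
          # insertion: into a gap adjacent to a block site, never strictly
          # inside a planted motif span
          gaps <- unique(c(sites - 1L, sites))  # insert after row g (0 = front)
          keyat <- function(g) {
            kl <- if (g >= 1L) cols$key[g] else cols$key[1] - 1
            kr <- if (g < nrow(cols)) cols$key[g + 1L] else cols$key[nrow(cols)] + 1
            c(kl, kr)
          }
          ok <- vapply(gaps, function(g) {
            kk <- keyat(g)
            mid <- (kk[1] + kk[2]) / 2
            !any(vapply(span_int, function(si)
              mid > si[1] && mid < si[2], logical(1)))
          }, logical(1))
          gaps <- gaps[ok]
          if (!length(gaps)) next
          g <- gaps[sample(length(gaps), 1L)]
          kk <- keyat(g)
          newkeys <- kk[1] + seq_len(indel_len) * (kk[2] - kk[1]) /
            (indel_len + 1)
          newrows <- data.frame(
            id = ev$next_id + seq_len(indel_len),
            key = newkeys, block = bk,
            residue = sample(cfg$alphabet, indel_len, replace = TRUE))
          ev$next_id <- ev$next_id + indel_len
          cols <- rbind(
            if (g >= 1L) cols[seq_len(g), , drop = FALSE],
            newrows,
            if (g < nrow(cols)) cols[(g + 1L):nrow(cols), , drop = FALSE])
          rownames(cols) <- NULL
        }
      }
    }
    cols
  }

  tips <- vector("list", ntip)
  walk <- function(node, cols) {
    kids <- which(tree$edge[, 1] == node)
    for (k in kids) {
      child <- tree$edge[k, 2]
      ccols <- mutate(cols, tree$edge.length[k])
      if (child <= ntip) tips[[child]] <<- ccols
      else walk(child, ccols)
    }
  }
  walk(ntip + 1L, root_cols)
  names(tips) <- tree$tip.label

  # --- ablate the motif arginine in non-designated taxa
  non_r <- setdiff(cfg$alphabet, "R")
  for (m in motif_meta) {
    for (tx in setdiff(tree$tip.label, m$taxa)) {
      i <- match(m$r_id, tips[[tx]]$id)
      if (!is.na(i)) tips[[tx]]$residue[i] <- sample(non_r, 1L)
    }
  }

  # --- assemble the true alignment from column identities
  allcols <- unique(do.call(rbind, lapply(tips, function(tc)
    tc[, c("id", "key", "block")])))
  allcols <- allcols[order(allcols$key, allcols$id), , drop = FALSE]
  ncol_aln <- nrow(allcols)
  rows <- vapply(tree$tip.label, function(tx) {
    out <- rep(GAP, ncol_aln)
    idx <- match(tips[[tx]]$id, allcols$id)
    out[idx] <- tips[[tx]]$residue
    paste(out, collapse = "")
  }, character(1))
  aln <- new_alignment(tree$tip.label, unname(rows),
                       species = tree$tip.label)
  records <- lapply(tree$tip.label, function(tx)
    seq_record(tx, paste(tips[[tx]]$residue, collapse = ""),
               species = tx))
  names(records) <- tree$tip.label

  # --- truth table
  truth <- do.call(rbind, lapply(motif_meta, function(m) {
    do.call(rbind, lapply(tree$tip.label, function(tx) {
      i <- match(m$r_id, tips[[tx]]$id)
      data.frame(taxon = tx, motif = m$index,
                 configuration = m$configuration,
                 present = tx %in% m$taxa,
                 residue_position = if (is.na(i)) NA_integer_ else i,
                 alignment_column = match(m$r_id, allcols$id))
    }))
  }))
  if (is.null(truth))
    truth <- data.frame(taxon = character(0), motif = integer(0),
                        configuration = character(0), present = logical(0),
                        residue_position = integer(0),
                        alignment_column = integer(0))

  col_info <- data.frame(column = seq_len(ncol_aln),
                         col_id = allcols$id, key = allcols$key,
                         block = allcols$block,
                         kind = blocks$kind[allcols$block])

  structure(list(alignment = aln, records = records, tree = tree,
                 truth = truth, col_info = col_info, config = cfg),
            class = "tbm_family")
}

#' @export
print.tbm_family <- function(x, ...) {
  cat(sprintf("<tbm_family> %d taxa, %d alignment columns, %d planted motif(s)\n",
              length(x$records), x$alignment$ncols,
              length(x$config$motifs)))
  invisible(x)
}

#' Empirical background TBM hit rate
#'
#' Simulates `n_families` families from a motif-free configuration, scans
#' every (unaligned) tip sequence, and reports the chance hit rate per 100
#' residues for each motif configuration, with a normal-theory 95%
#' confidence interval over families.  Under the uniform substitution
#' model the per-window canonical probability is
#' \eqn{(1/20) \cdot (4/20) \cdot (1/20)} and rx4/rx5 each
#' \eqn{(1/20)^2}, which the observed rates can be checked against.
#'
#' @param cfg A \code{\link{simulation_config}} without planted motifs.
#' @param n_families Number of independent families to simulate.
#' @param seed Integer seed for the family seeds.
#' @return Data frame: \code{configuration}, \code{mean_rate},
#'   \code{sd_rate}, \code{ci_lo}, \code{ci_hi}, \code{n_families}
#'   (rates per 100 residues).
#' @export
background_scan_rate <- function(cfg, n_families, seed) {
  stopifnot(inherits(cfg, "tbm_simconfig"), n_families >= 2L)
  if (length(cfg$motifs))
    stop("background_scan_rate requires a configuration with no planted motifs")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_families)
  classes <- names(tbm_patterns())
  rates <- matrix(0, n_families, length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_len(n_families)) {
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    fam <- simulate_family(cfg_i)
    total <- sum(vapply(fam$records, function(r) nchar(r$residues), 0))
    hits <- do.call(rbind, lapply(fam$records, scan_tbm))
    for (cl in classes) {
      rates[i, cl] <- 100 * sum(hits$configuration == cl) / total
    }
  }
  mu <- colMeans(rates)
  sdv <- apply(rates, 2L, sd)
  half <- qt(0.975, n_families - 1L) * sdv / sqrt(n_families)
  data.frame(configuration = classes, mean_rate = unname(mu),
             sd_rate = unname(sdv),
             ci_lo = unname(mu - half), ci_hi = unname(mu + half),
             n_families = n_families)
}

#' Write a simulated family to disk
#'
#' Emits \code{family.afa} (true alignment), \code{family.fasta}
#' (unaligned sequences), \code{tree.nwk} and \code{truth.tsv} into a
#' directory.
#'
#' @param fam A \code{\link{simulate_family}} result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_family <- function(fam, dir) {
  stopifnot(inherits(fam, "tbm_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(fam$alignment, file.path(dir, "family.afa"))
  write_fasta(fam$records, file.path(dir, "family.fasta"))
  ape::write.tree(fam$tree, file.path(dir, "tree.nwk"))
  write.table(fam$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
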