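# Tankyrase-binding-motif (TBM) grammar, scanning and alignment-anchored
# presence/absence classification.
#
# Three motif configurations are recognized:
#   canonical  Rxx[ACGP]xGxx   length 8, most specific
#   rx4        Rx(4)Gxx        length 8 (4 wildcards between R and G)
#   rx5        Rx(5)Gxx        length 9 (5 wildcards between R and G)
# Every canonical match is also an rx4 match at the same start; a window is
# labeled with the most specific configuration of its length.  rx5 has a
# different length, so a start can yield both a length-8 and a length-9 hit.
# 'X' never satisfies a constrained position (R, G, position 4) but is
# accepted at wildcard positions.

#' TBM motif patterns
#'
#' Returns the three TBM configurations as a named list, each with its
#' window \code{length} and \code{constraints} (a named list mapping a
#' 1-based position in the window to the allowed residues).  Order encodes
#' specificity: \code{canonical} beats \code{rx4} beats \code{rx5}.
#'
#' @return Named list of pattern descriptors.
#' @export
tbm_patterns <- function() {
  list(
    canonical = list(length = 8L,
                     constraints = list(`1` = "R",
                                        `4` = c("A", "C", "G", "P"),
                                        `6` = "G")),
    rx4 = list(length = 8L,
               constraints = list(`1` = "R", `6` = "G")),
    rx5 = list(length = 9L,
               constraints = list(`1` = "R", `7` = "G"))
  )
}

.window_matches <- function(chars, start, pattern) {
  for (pos in names(pattern$constraints)) {
    if (!(chars[start + as.integer(pos) - 1L] %in% pattern$constraints[[pos]]))
      return(FALSE)
  }
  TRUE
}

#' Scan a sequence for TBM configurations
#'
#' Every window matching at least one pattern yields exactly one hit
#' labeled with the most specific matching configuration; overlapping
#' windows are all reported.  Hits are sorted by start position, then by
#' window length.
#'
#' @param seq A \code{\link{seq_record}} or residue string.
#' @param patterns Patterns to scan for; defaults to all three TBM
#'   configurations from \code{\link{tbm_patterns}}.
#' @return Data frame with columns \code{id}, \code{start}, \code{end},
#'   \code{length}, \code{configuration}, \code{matched_text}; zero rows
#'   when nothing matches.
#' @examples
#' scan_tbm("RGCADGRD")   # canonical (position 4 = A)
#' scan_tbm("RPPVPGEE")   # rx4 only (position 4 = V)
#' @export
scan_tbm <- function(seq, patterns = tbm_patterns()) {
  r <- .as_residues(seq)
  chars <- strsplit(r$residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  lens <- unique(vapply(patterns, `[[`, integer(1), "length"))
  for (len in sort(lens)) {
    pats <- patterns[vapply(patterns, function(p) p$length == len, logical(1))]
    if (n < len) next
    for (start in seq_len(n - len + 1L)) {
      if (chars[start] != "R") next   # all configurations require R first
      for (pname in names(pats)) {    # list order = specificity order
        if (.window_matches(chars, start, pats[[pname]])) {
          hits[[length(hits) + 1L]] <- data.frame(
            id = r$id, start = start, end = start + len - 1L,
            length = len, configuration = pname,
            matched_text = paste(chars[start:(start + len - 1L)],
                                 collapse = ""))
          break
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      configuration = character(0),
                      matched_text = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$length), , drop = FALSE]
}

#' Scan a whole protein for all possible TBMs
#'
#' Identical matching rules to \code{\link{scan_tbm}}, with no positional
#' filtering: every hit in the full-length sequence is returned.  This is
#' the whole-sequence mode used for proteins like RNF146 that carry many
#' TBMs at varying positions.
#'
#' @param seq A \code{\link{seq_record}} or residue string.
#' @return As \code{\link{scan_tbm}}.
#' @export
scan_all <- function(seq) {
  scan_tbm(seq, tbm_patterns())
}

# Verdict ordering, best first.
.VERDICTS <- c("canonical_aligned", "relaxed_aligned", "nearby_unaligned",
               "absent", "no_ortholog")

#' Classify TBM presence in one ortholog against the human reference site
#'
#' Let C be the alignment column of the reference TBM's arginine.  The
#' ortholog row is scanned (after removing its gaps) and each hit's
#' arginine is mapped to its alignment column.  A hit at exactly column C
#' gives \code{canonical_aligned} (canonical configuration) or
#' \code{relaxed_aligned} (rx4/rx5); otherwise a hit within
#' \code{nearby_window} columns of C gives \code{nearby_unaligned};
#' otherwise the verdict is \code{absent}.  When several hits qualify, the
#' best verdict wins (canonical_aligned > relaxed_aligned >
#' nearby_unaligned).
#'
#' The nearby-window rule is a column-distance approximation of the
#' "possible TBM in a nearby likely disordered region" annotation; no
#' disorder predictor is consulted and the window size is reported in the
#' output so the convention is explicit.
#'
#' @param ortholog_id Row id of the ortholog to classify.
#' @param aln Alignment containing both the ortholog and reference rows.
#' @param ref_id Row id of the human reference sequence.
#' @param ref_arg Residue number (1-based, in the reference sequence) of
#'   the TBM arginine.
#' @param nearby_window Column window for the \code{nearby_unaligned}
#'   verdict (default 30; 0 disables the nearby rule).
#' @param expected_tbm Optional expected reference motif text; a mismatch
#'   between it and the reference residues at \code{ref_arg} raises a
#'   warning (fixture self-check).
#' @return A list of class \code{tbm_presence_call}: \code{ortholog_id},
#'   \code{verdict}, \code{ref_column}, \code{nearby_window} and
#'   \code{hits} (the supporting hits with their mapped columns).
#' @export
classify_tbm <- function(ortholog_id, aln, ref_id, ref_arg,
                         nearby_window = 30L, expected_tbm = NULL) {
  stopifnot(inherits(aln, "tbm_alignment"))
  for (id in c(ortholog_id, ref_id)) {
    if (!(id %in% aln$ids)) stop("id '", id, "' not present in alignment")
  }
  rmap <- reference_map(aln, ref_id)
  hit_row <- match(ref_arg, rmap$residue)
  if (is.na(hit_row))
    stop("reference residue ", ref_arg, " outside reference sequence '",
         ref_id, "' (length ", nrow(rmap), ")")
  C <- rmap$column[hit_row]
  if (!is.null(expected_tbm)) {
    refres <- paste(strsplit(aln$seqs[[ref_id]], "",
                             fixed = TRUE)[[1]][
                      rmap$column[rmap$residue >= ref_arg &
                                  rmap$residue < ref_arg + nchar(expected_tbm)]],
                    collapse = "")
    if (!identical(refres, toupper(expected_tbm)))
      warning("reference residues at ", ref_arg, " are '", refres,
              "', expected '", expected_tbm, "'")
  }
  ortho_ch <- strsplit(aln$seqs[[ortholog_id]], "", fixed = TRUE)[[1]]
  ortho_cols <- which(ortho_ch != GAP)
  ortho_seq <- paste(ortho_ch[ortho_cols], collapse = "")
  hits <- scan_tbm(seq_record(ortholog_id, ortho_seq))
  verdict <- "absent"
  if (nrow(hits)) {
    hits$column <- ortho_cols[hits$start]
    hits$verdict <- ifelse(hits$column == C,
                           ifelse(hits$configuration == "canonical",
                                  "canonical_aligned", "relaxed_aligned"),
                           ifelse(abs(hits$column - C) <= nearby_window,
                                  "nearby_unaligned", NA_character_))
    hits <- hits[!is.na(hits$verdict), , drop = FALSE]
    if (nrow(hits))
      verdict <- .VERDICTS[min(match(hits$verdict, .VERDICTS))]
  } else {
    hits$column <- integer(0)
    hits$verdict <- character(0)
  }
  structure(list(ortholog_id = ortholog_id, verdict = verdict,
                 ref_column = C, nearby_window = as.integer(nearby_window),
                 hits = hits),
            class = "tbm_presence_call")
}

#' @export
print.tbm_presence_call <- function(x, ...) {
  cat(sprintf("<tbm_presence_call> %s: %s (reference column %d, window %d)\n",
              x$ortholog_id, x$verdict, x$ref_column, x$nearby_window))
  invisible(x)
}

#' Per-partner, per-species TBM presence/absence matrix
#'
#' Builds the presence/absence matrix of TBMs across ortholog sets: one
#' verdict per (TBM site, species).  Partners with several reference TBMs
#' contribute one sub-row per site.  A species without a row in a partner's
#' alignment is \code{no_ortholog}; a partner in the table with no supplied
#' alignment gets a full \code{no_ortholog} row with a warning.
#'
#' @param binders Binder table as from \code{\link{tbm_binders}} (columns
#'   \code{partner}, \code{tbm}, \code{arg_position}, \code{truncated}).
#' @param alignments Named list mapping partner name to a
#'   \code{tbm_alignment} of its orthologs (reference row included).
#' @param species Character vector of species tags defining the matrix
#'   columns; rows are matched by their species tag.
#' @param ref_species Species tag of the reference (human) rows.
#' @param nearby_window Column window passed to \code{\link{classify_tbm}}.
#' @return Data frame of class \code{tbm_presence_matrix} in long form:
#'   \code{partner}, \code{site} (arginine residue number), \code{species},
#'   \code{verdict}.  The window and verdict ordering are attached as
#'   attributes.
#' @export
presence_matrix <- function(binders, alignments, species,
                            ref_species = "Homo_sapiens",
                            nearby_window = 30L) {
  stopifnot(is.data.frame(binders), is.list(alignments))
  rows <- list()
  for (k in seq_len(nrow(binders))) {
    partner <- binders$partner[k]
    site <- binders$arg_position[k]
    aln <- alignments[[partner]]
    if (is.null(aln)) {
      warning("no alignment supplied for partner '", partner, "'")
      for (sp in species) {
        rows[[length(rows) + 1L]] <- data.frame(
          partner = partner, site = site, species = sp,
          verdict = "no_ortholog")
      }
      next
    }
    ref_id <- aln$ids[which(aln$species == ref_species)][1]
    if (is.na(ref_id))
      stop("partner '", partner, "': no row with reference species '",
           ref_species, "'")
    for (sp in species) {
      oid <- aln$ids[which(aln$species == sp)][1]
      v <- if (is.na(oid)) "no_ortholog" else {
        classify_tbm(oid, aln, ref_id, site,
                     nearby_window = nearby_window)$verdict
      }
      rows[[length(rows) + 1L]] <- data.frame(
        partner = partner, site = site, species = sp, verdict = v)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "nearby_window") <- as.integer(nearby_window)
  attr(out, "verdict_levels") <- .VERDICTS
  class(out) <- c("tbm_presence_matrix", "data.frame")
  out
}

#' Write a presence matrix as a wide TSV
#'
#' Pivots the long-form presence calls into the familiar matrix shape:
#' one row per (partner, site), one column per species.
#'
#' @param pm A \code{\link{presence_matrix}} result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_presence_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "tbm_presence_matrix"))
  key <- paste(pm$partner, pm$site, sep = "_")
  species <- unique(pm$species)
  keys <- unique(key)
  wide <- data.frame(site = keys, stringsAsFactors = FALSE)
  for (sp in species) {
    wide[[sp]] <- pm$verdict[match(paste(keys, sp),
                                   paste(key, pm$species))]
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
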