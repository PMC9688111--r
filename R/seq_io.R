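# Sequence and alignment IO.
#
# All downstream modules consume the two containers defined here:
# `tbm_seqrecord` (one ungapped protein sequence) and `tbm_alignment`
# (equal-length gapped rows).  Residue numbering is 1-based everywhere;
# alignment columns are 1-based.  The gap symbol is '-' internally; '.' is
# accepted on read only.

#' Construct a protein sequence record
#'
#' A sequence record holds one protein sequence over the 20 amino-acid
#' one-letter codes plus the ambiguity code \code{X}.  Input residues are
#' normalized: terminal/internal \code{*} stop symbols are stripped and
#' lowercase is raised to uppercase.  Gap characters are rejected: records
#' are always ungapped (gapped rows live in a \code{\link{read_alignment}}
#' result instead).
#'
#' The species tag is taken from a \code{species=} key in the description
#' when present, otherwise from the identifier prefix before the first
#' \code{|}, otherwise it is \code{NA}.
#'
#' @param id Unique identifier (non-empty, no whitespace).
#' @param residues Residue string.
#' @param description Free-text description (FASTA header remainder).
#' @param species Optional species tag; derived from the header when `NULL`.
#' @return An object of class \code{tbm_seqrecord} with fields \code{id},
#'   \code{description}, \code{species} and \code{residues}.
#' @examples
#' r <- seq_record("TNKS2_HUMAN|sample", "maarrrsg")
#' r$residues
#' r$species
#' @export
seq_record <- function(id, residues, description = "", species = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  if (grepl("\\s", id)) stop("sequence id must not contain whitespace: ", id)
  residues <- toupper(gsub("*", "", residues, fixed = TRUE))
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  .check_residues(residues, id, allow_gap = FALSE)
  if (is.null(species)) species <- .species_from_header(id, description)
  structure(list(id = id, description = description,
                 species = species, residues = residues),
            class = "tbm_seqrecord")
}

#' @export
print.tbm_seqrecord <- function(x, ...) {
  cat(sprintf("<tbm_seqrecord> %s (%d aa%s)\n", x$id, nchar(x$residues),
              if (is.na(x$species)) "" else paste0(", species ", x$species)))
  invisible(x)
}

.check_residues <- function(residues, id, allow_gap) {
  ok <- if (allow_gap) c(AAX, GAP) else AAX
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% ok))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d in record '%s'",
                 ch[bad[1]], bad[1], id))
  }
  invisible(TRUE)
}

# Headers carry the species tag as a "species=" key so that tags survive
# a write/read round trip.
.desc_with_species <- function(description, species) {
  if (!is.na(species) && !grepl("species=", description, fixed = TRUE))
    description <- trimws(paste(description, paste0("species=", species)))
  description
}

.species_from_header <- function(id, description) {
  m <- regmatches(description, regexpr("species=\\S+", description))
  if (length(m) && nzchar(m)) return(sub("^species=", "", m))
  if (grepl("|", id, fixed = TRUE)) return(sub("\\|.*$", "", id))
  NA_character_
}

# Split ">id desc" header into id / description.
.parse_header <- function(line) {
  h <- sub("^>", "", line)
  id <- sub("\\s.*$", "", h)
  desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
  list(id = id, description = desc)
}

# Core FASTA block parser shared by the unaligned and aligned readers.
.read_fasta_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^;", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L)
    stop("not a FASTA file (no leading '>'): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- lapply(seq_along(starts), function(i) {
    hd <- .parse_header(lines[starts[i]])
    seq <- if (ends[i] > starts[i]) {
      paste(gsub("\\s", "", lines[(starts[i] + 1L):ends[i]]), collapse = "")
    } else ""
    c(hd, list(seq = seq))
  })
  ids <- vapply(blocks, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  blocks
}

#' Read an unaligned FASTA file
#'
#' Sequence lines are concatenated, \code{*} stripped and lowercase raised
#' to uppercase.  Gap characters (\code{-} or \code{.}) are rejected: this
#' reader is for unaligned sequences (use \code{\link{read_alignment}} for
#' aligned input).  Duplicate ids and illegal characters are errors.
#'
#' @param path Path to a FASTA text file.
#' @return A list of \code{\link{seq_record}} objects.
#' @export
read_fasta <- function(path) {
  blocks <- .read_fasta_blocks(path)
  lapply(blocks, function(b) {
    if (grepl("[.-]", b$seq))
      stop("gap character in unaligned input for record '", b$id,
           "' (use read_alignment for aligned FASTA)")
    seq_record(b$id, b$seq, b$description)
  })
}

#' Write sequence records to FASTA
#'
#' @param records A list of \code{\link{seq_record}} objects (or a single
#'   record).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "tbm_seqrecord")) records <- list(records)
  out <- unlist(lapply(records, function(r) {
    desc <- .desc_with_species(r$description, r$species)
    hdr <- paste0(">", r$id, if (nzchar(desc)) paste0(" ", desc) else "")
    body <- substring(r$residues,
                      seq(1L, nchar(r$residues), by = width),
                      pmin(seq(1L, nchar(r$residues), by = width) + width - 1L,
                           nchar(r$residues)))
    c(hdr, body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Construct an alignment from gapped rows
#'
#' @param ids Character vector of unique row ids.
#' @param seqs Character vector of gapped residue strings (same length as
#'   `ids`).
#' @param descriptions Optional descriptions.
#' @param species Optional species tags; derived from headers when `NULL`.
#' @return An object of class \code{tbm_alignment} with fields \code{ids},
#'   \code{seqs} (named), \code{species} (named), \code{descriptions} and
#'   \code{ncols}.
#' @details Invariants enforced: at least 2 rows, all rows of equal length,
#'   residues restricted to the amino-acid alphabet plus \code{X} and
#'   \code{-}, and every column containing at least one non-gap symbol.
#' @export
new_alignment <- function(ids, seqs, descriptions = NULL, species = NULL) {
  stopifnot(is.character(ids), is.character(seqs),
            length(ids) == length(seqs))
  if (length(ids) < 2L) stop("an alignment needs at least 2 rows")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    ref_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- ids[lens != ref_len]
    stop("ragged alignment rows (length != ", ref_len, "): ",
         paste(bad, collapse = ", "))
  }
  for (i in seq_along(ids)) .check_residues(seqs[i], ids[i], allow_gap = TRUE)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  all_gap <- which(colSums(m != GAP) == 0L)
  if (length(all_gap))
    stop("all-gap column(s) in alignment: ",
         paste(head(all_gap, 5L), collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  if (is.null(species))
    species <- mapply(.species_from_header, ids, descriptions,
                      USE.NAMES = FALSE)
  structure(list(ids = ids,
                 seqs = setNames(seqs, ids),
                 species = setNames(species, ids),
                 descriptions = setNames(descriptions, ids),
                 ncols = unname(lens[1])),
            class = "tbm_alignment")
}

#' @export
print.tbm_alignment <- function(x, ...) {
  cat(sprintf("<tbm_alignment> %d rows x %d columns\n",
              length(x$ids), x$ncols))
  invisible(x)
}

#' @export
as.matrix.tbm_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  dimnames(m) <- list(x$ids, seq_len(x$ncols))
  m
}

#' Number of rows in an alignment
#' @param aln A \code{tbm_alignment}.
#' @return Integer row count.
#' @export
n_rows <- function(aln) {
  stopifnot(inherits(aln, "tbm_alignment"))
  length(aln$ids)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (`afa`) and Clustal (`clustal`) dialects.  The two
#' dialects yield identical alignment objects for the same underlying data.
#' \code{.} gap symbols are normalized to \code{-}; ragged rows are an error
#' listing the offending ids.
#'
#' @param path Path to the alignment file.
#' @param dialect One of \code{"afa"} or \code{"clustal"}.
#' @return A \code{\link{new_alignment}} object.
#' @export
read_alignment <- function(path, dialect = c("afa", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "afa") {
    blocks <- .read_fasta_blocks(path)
    new_alignment(vapply(blocks, `[[`, "", "id"),
                  vapply(blocks, function(b) toupper(gsub("*", "", b$seq,
                                                          fixed = TRUE)), ""),
                  vapply(blocks, `[[`, "", "description"))
  } else {
    .read_clustal(path)
  }
}

.read_clustal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty Clustal file: ", path)
  if (grepl("^(CLUSTAL|MUSCLE)", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  acc <- list()
  order <- character()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                       # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) < 3L) next
    id <- m[2]; chunk <- m[3]
    if (!(id %in% order)) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], chunk)
  }
  if (!length(order)) stop("no alignment rows found in Clustal file: ", path)
  new_alignment(order,
                vapply(order, function(id) toupper(gsub("*", "", acc[[id]],
                                                        fixed = TRUE)), ""))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A \code{tbm_alignment}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "tbm_alignment"))
  out <- unlist(lapply(aln$ids, function(id) {
    s <- aln$seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    desc <- .desc_with_species(aln$descriptions[[id]], aln$species[[id]])
    c(paste0(">", id, if (nzchar(desc)) paste0(" ", desc) else ""),
      substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

# Internal: subset alignment columns (used by the bootstrap).  `idx` may
# repeat columns; every source column has a non-gap symbol, so the result
# keeps the alignment invariants.
.subset_columns <- function(aln, idx) {
  m <- as.matrix(aln)[, idx, drop = FALSE]
  new_alignment(aln$ids, apply(m, 1L, paste, collapse = ""),
                unname(aln$descriptions), unname(aln$species))
}

#' Rewrite PDB B-factors with per-residue scores
#'
#' Replaces the B-factor column (columns 61--66) of every \code{ATOM} /
#' \code{HETATM} record in the given chain whose author residue number is a
#' key of `residue_scores`.  All other bytes of the file are preserved
#' exactly.  Residues carrying an insertion code are skipped (with a
#' warning) when the score map is keyed by plain residue numbers, since the
#' key would be ambiguous.
#'
#' Typical use is projecting a conservation grade or a strict-conservation
#' indicator onto a structure for molecular-graphics display.
#'
#' @param pdb_in Input PDB path (text, ATOM-record level).
#' @param chain Single chain identifier (e.g. \code{"A"}).
#' @param residue_scores Named numeric vector: names are author residue
#'   numbers, values the scores to write.
#' @param pdb_out Output path.
#' @return Number of distinct residues whose atoms were annotated.
#' @export
write_bfactor_pdb <- function(pdb_in, chain, residue_scores, pdb_out) {
  stopifnot(is.character(chain), length(chain) == 1L, nchar(chain) == 1L)
  if (!file.exists(pdb_in)) stop("file not found: ", pdb_in)
  lines <- readLines(pdb_in, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (any(is_atom)) {
    chains <- substr(lines[is_atom], 22L, 22L)
    if (!any(chains == chain))
      stop("chain '", chain, "' not present in ", pdb_in)
  } else {
    stop("no ATOM/HETATM records in ", pdb_in)
  }
  keys <- suppressWarnings(as.integer(names(residue_scores)))
  if (length(residue_scores) && anyNA(keys))
    stop("residue_scores must be keyed by integer residue numbers")
  touched <- integer(0)
  skipped_icode <- character(0)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (substr(ln, 22L, 22L) != chain) next
    resseq <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
    icode <- substr(ln, 27L, 27L)
    if (is.na(resseq) || !(resseq %in% keys)) next
    if (icode != " ") {
      skipped_icode <- union(skipped_icode, paste0(resseq, icode))
      next
    }
    score <- residue_scores[[match(resseq, keys)]]
    bf <- sprintf("%6.2f", score)
    if (nchar(bf) > 6L) bf <- sprintf("%6.1f", score)
    substr(ln, 61L, 66L) <- bf
    lines[i] <- ln
    touched <- union(touched, resseq)
  }
  if (length(skipped_icode))
    warning("skipped insertion-code residue(s) ",
            paste(skipped_icode, collapse = ", "),
            " (scores are keyed without insertion codes)")
  if (length(residue_scores) && !length(touched))
    warning("no residue matched the score map in chain '", chain, "'")
  writeLines(lines, pdb_out)
  length(touched)
}

#' Read a curated TBM binder table
#'
#' The table lists experimentally confirmed human TNKS interaction partners
#' with the TBM sequence(s) of the human ortholog and the residue number of
#' the motif arginine.  The packaged fixture (see \code{\link{tbm_binders}})
#' carries one row per TBM site; partners with two sites appear twice.
#'
#' @param path Path to a TSV with columns \code{partner}, \code{role},
#'   \code{tbm}, \code{arg_position} and \code{truncated}.
#' @return A data frame, one row per TBM site.
#' @details Validation: each TBM sequence is 7--9 residues, starts with
#'   \code{R}, and has arginine residue number >= 1.  A \code{truncated}
#'   flag marks sites printed shorter than the 8 positions the canonical
#'   grammar needs.
#' @export
read_binder_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("partner", "role", "tbm", "arg_position", "truncated")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("binder table missing column(s): ",
                         paste(miss, collapse = ", "))
  tb$tbm <- toupper(tb$tbm)
  tb$truncated <- as.logical(tb$truncated)
  bad_len <- which(nchar(tb$tbm) < 7L | nchar(tb$tbm) > 9L)
  if (length(bad_len)) stop("TBM length outside 7-9 for partner(s): ",
                            paste(tb$partner[bad_len], collapse = ", "))
  bad_r <- which(substr(tb$tbm, 1L, 1L) != "R")
  if (length(bad_r)) stop("TBM not starting with R for partner(s): ",
                          paste(tb$partner[bad_r], collapse = ", "))
  if (any(tb$arg_position < 1L)) stop("arg_position must be >= 1")
  tb
}

#' Packaged curated binder table
#'
#' Loads the curated table of human TNKS interaction partners and their TBM
#' sites shipped with the package.  One row per TBM site; the single
#' 7-residue site (USP25) is flagged \code{truncated} because the printed
#' sequence is one position short of the 8 the canonical grammar requires.
#'
#' @return A data frame, one row per TBM site.
#' @examples
#' tb <- tbm_binders()
#' nrow(tb)                  # TBM sites
#' length(unique(tb$partner))  # distinct partners
#' @export
tbm_binders <- function() {
  read_binder_table(system.file("extdata", "tbm_binders.tsv",
                                package = "tbmevo", mustWork = TRUE))
}
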