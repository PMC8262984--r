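# Per-column conservation over CZB alignments and seven-residue alpha-3
# motif logo matrices, anchored at the universally conserved cysteine.
# Alignments are consumed (externally produced, e.g. with MUSCLE/MAFFT),
# never built here.

#' Construct an amino-acid alignment
#'
#' Gapped sequences (gap character `-`) of equal length with unique ids.
#'
#' @param id character vector of row ids.
#' @param sequence character vector of gapped sequences.
#' @return object of class `"aa_alignment"`.
#' @export
aa_alignment <- function(id, sequence) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) stop("id/sequence length mismatch")
  if (length(id) < 2L) stop("alignment needs >= 2 rows")
  if (anyDuplicated(id)) stop("duplicate alignment row ids")
  w <- unique(nchar(sequence))
  if (length(w) != 1L) stop("alignment rows differ in length")
  ok <- vapply(sequence, function(s) {
    all(strsplit(s, "")[[1]] %in% c(AA_ALLOWED, "-"))
  }, logical(1))
  if (!all(ok)) stop("illegal characters in alignment row(s): ",
                     paste(id[!ok], collapse = ", "))
  structure(list(id = id, sequence = sequence, column_count = w),
            class = "aa_alignment")
}

#' Read an aligned FASTA file
#' @param path path to aligned FASTA (gaps as `-`).
#' @return an [aa_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file ", path)
  aa_alignment(sub("\\s.*$", "", names(set)), as.character(set))
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$sequence, ""))
}

#' Per-column conservation profile
#'
#' For each column: the modal residue and percent identity
#' `100 * count(modal) / non-gap rows`, with the gap fraction reported
#' separately.  All-gap columns have `NA` modal residue and identity.
#'
#' @param alignment an [aa_alignment()].
#' @return data.frame: column, modal_residue, identity (0-100),
#'   gap_fraction.
#' @export
column_conservation <- function(alignment) {
  mat <- alignment_matrix(alignment)
  nr <- nrow(mat)
  res <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    gaps <- col == "-"
    nong <- col[!gaps]
    if (length(nong) == 0L) {
      return(data.frame(column = j, modal_residue = NA_character_,
                        identity = NA_real_, gap_fraction = 1))
    }
    tab <- sort(table(nong), decreasing = TRUE)
    modal <- names(tab)[tab == max(tab)]
    modal <- sort(modal)[1]  # deterministic tie-break: alphabetical
    data.frame(column = j, modal_residue = modal,
               identity = 100 * max(tab) / length(nong),
               gap_fraction = sum(gaps) / nr)
  })
  do.call(rbind, res)
}

#' Locate the alignment column of a reference cysteine
#'
#' Maps an ungapped residue coordinate of a reference row (e.g. Cys52 of
#' DgcZ) to its alignment column.
#'
#' @param alignment an [aa_alignment()].
#' @param reference_id row id of the reference sequence.
#' @param reference_cys 1-based ungapped position of the conserved Cys in
#'   the reference.
#' @return integer alignment column.
#' @export
anchor_cys_column <- function(alignment, reference_id, reference_cys) {
  i <- match(reference_id, alignment$id)
  if (is.na(i)) stop("reference row not found: ", reference_id)
  chars <- strsplit(alignment$sequence[i], "")[[1]]
  ungapped <- cumsum(chars != "-")
  col <- match(reference_cys, ungapped)
  if (is.na(col)) stop("reference position ", reference_cys,
                       " outside ungapped reference length")
  if (chars[col] != "C") {
    stop("anchoring error: reference residue at position ", reference_cys,
         " is '", chars[col], "', not 'C'")
  }
  col
}

#' Motif logo matrix for the seven-residue alpha-3 motif
#'
#' Residue frequencies over non-gap rows for the seven alignment columns
#' starting at the anchored Cys column.  Frequencies are raw counts over
#' non-gap rows (no bit scaling, no redundancy weighting).
#'
#' @param alignment an [aa_alignment()].
#' @param anchor alignment column of the conserved Cys (position 1).
#' @return 7 x 20 numeric matrix (class `"motif_logo"`), rows `pos1` ..
#'   `pos7`, columns the canonical residues; rows sum to 1.  Attribute
#'   `anchor` records the anchor column.
#' @export
motif_logo <- function(alignment, anchor) {
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor + 6L > alignment$column_count) {
    stop("anchor + 6 columns must lie within the alignment")
  }
  mat <- alignment_matrix(alignment)
  logo <- matrix(0, nrow = 7, ncol = 20,
                 dimnames = list(paste0("pos", 1:7), AA_CANONICAL))
  for (p in 1:7) {
    col <- mat[, anchor + p - 1L]
    res <- col[col %in% AA_CANONICAL]
    if (length(res) == 0L) next
    cnt <- table(factor(res, levels = AA_CANONICAL))
    logo[p, ] <- as.numeric(cnt) / length(res)
  }
  structure(logo, anchor = anchor, class = c("motif_logo", "matrix",
                                             "array"))
}

#' Motif logos per architecture subgroup
#'
#' Computes one logo matrix per subgroup alignment (each anchored
#' independently) and a comparison of the top position-2 residue, the
#' motif position most variable between subgroups.
#'
#' @param alignments named list of [aa_alignment()] objects, one per
#'   subgroup.
#' @param anchors named integer vector of anchor columns (same names).
#' @return list with `logos` (named list of [motif_logo()] matrices) and
#'   `position2_top` (named character vector of top residues).  Subgroups
#'   with fewer than 2 rows are skipped with a warning.
#' @export
subgroup_logos <- function(alignments, anchors) {
  stopifnot(all(names(alignments) %in% names(anchors)))
  logos <- list()
  for (nm in names(alignments)) {
    aln <- alignments[[nm]]
    if (length(aln$id) < 2L) {
      warning("subgroup '", nm, "' has < 2 members; skipped")
      next
    }
    logos[[nm]] <- motif_logo(aln, anchors[[nm]])
  }
  pos2 <- vapply(logos, function(m) {
    names(which.max(m["pos2", ]))
  }, character(1))
  list(logos = logos, position2_top = pos2)
}

#' Write a logo matrix to TSV
#' @param logo a [motif_logo()] matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
  df <- data.frame(position = rownames(logo), as.data.frame(unclass(logo)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
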