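# Shared record model and readers/writers for the plain-text formats the
# pipeline consumes: FASTA (plain and aligned), TSV domain/taxonomy tables,
# and CSV dose-response tables.  Coordinates are 1-based inclusive
# throughout the package.

#' Construct a protein record collection
#'
#' A protein set is a plain `data.frame` with columns `id`, `species` and
#' `sequence`, carrying class `"protein_set"`.  Sequences may contain the
#' 20 canonical amino-acid letters plus `X` (unknown residue); anything
#' else is rejected so that motif-scanning semantics stay unambiguous.
#'
#' @param id character vector of unique accession ids.
#' @param sequence character vector of amino-acid sequences.
#' @param species optional character vector of species labels (free text,
#'   may be empty strings).
#' @return a `protein_set` data.frame.
#' @export
protein_set <- function(id, sequence, species = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (is.null(species)) species <- rep("", length(id))
  stopifnot(length(id) == length(sequence), length(species) == length(id))
  if (anyDuplicated(id)) {
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("zero-length sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- vapply(sequence, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA_ALLOWED)
  }, logical(1))
  if (any(bad)) {
    stop("illegal residue letter(s) in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, species = as.character(species),
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace becomes the record id; any
#' remainder is kept as the species label.  Gap characters are not allowed
#' here; use [read_alignment()] for aligned FASTA.
#'
#' @param path path to a FASTA file.
#' @return a [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: empty file ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  species <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), "")
  protein_set(id = id, sequence = as.character(set), species = species)
}

#' Write a protein set to FASTA
#'
#' @param proteins a [protein_set()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  headers <- ifelse(nzchar(proteins$species),
                    paste(proteins$id, proteins$species), proteins$id)
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Expects a TSV with columns `protein_id`, `domain_name`, `start`, `end`
#' (1-based inclusive residue coordinates), the same shape an InterPro
#' export is normalized to.  Unknown domain names are mapped to `"other"`
#' with a warning; coordinate violations are errors.
#'
#' @param path path to the TSV.
#' @param proteins optional [protein_set()]; when given, coordinates are
#'   validated against sequence lengths.
#' @return a data.frame of class `"domain_table"`.
#' @export
read_domain_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    tab <- data.frame(protein_id = character(), domain_name = character(),
                      start = integer(), end = integer())
    class(tab) <- c("domain_table", "data.frame")
    return(tab)
  }
  need <- c("protein_id", "domain_name", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("domain table must have columns ", paste(need, collapse = ", "))
  }
  tab <- tab[need]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  validate_domain_table(tab, proteins)
}

validate_domain_table <- function(tab, proteins = NULL) {
  unknown <- !(tab$domain_name %in% DOMAIN_NAMES)
  if (any(unknown)) {
    warning("unknown domain name(s) mapped to 'other': ",
            paste(unique(tab$domain_name[unknown]), collapse = ", "))
    tab$domain_name[unknown] <- "other"
  }
  bad <- tab$start < 1L | tab$end < tab$start
  if (any(bad)) {
    stop("coordinate error (need 1 <= start <= end) in row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (!is.null(proteins)) {
    len <- stats::setNames(nchar(proteins$sequence), proteins$id)
    known <- tab$protein_id %in% names(len)
    over <- known & tab$end > len[tab$protein_id]
    if (any(over)) {
      stop("annotation end exceeds sequence length for: ",
           paste(unique(tab$protein_id[over]), collapse = ", "))
    }
  }
  # same-name annotations on one protein must not nest
  by_key <- split(seq_len(nrow(tab)),
                  paste(tab$protein_id, tab$domain_name, sep = "\r"))
  for (idx in by_key) {
    if (length(idx) < 2L) next
    s <- tab$start[idx]; e <- tab$end[idx]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    for (i in seq_along(s)[-1]) {
      if (s[i] >= s[i - 1L] && e[i] <= e[i - 1L]) {
        stop("nested same-name annotations for protein ",
             tab$protein_id[idx[1]])
      }
    }
  }
  class(tab) <- unique(c("domain_table", class(tab)))
  tab
}

#' Write a domain table to TSV
#' @param tab a domain table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `protein_id`, `species`, `genus`, `phylum`,
#' `candidate_phylum_flag` (logical).
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "species", "phylum")
  if (!all(need %in% names(tab))) {
    stop("taxonomy table must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(tab$genus)) tab$genus <- sub("\\s.*$", "", tab$species)
  if (is.null(tab$candidate_phylum_flag)) tab$candidate_phylum_flag <- FALSE
  tab$candidate_phylum_flag <- as.logical(tab$candidate_phylum_flag)
  tab
}

#' Construct a dose-response dataset
#'
#' A long-format data.frame (`dose`, `response`) of class
#' `"dose_response"`, with one row per replicate measurement.  Doses are
#' in the units of the assay axis (micromolar throughout the package
#' defaults).
#'
#' @param dose numeric vector, nonnegative and finite.
#' @param response numeric vector of the same length.
#' @param label free-text dataset label.
#' @return a `dose_response` data.frame.
#' @export
dose_response <- function(dose, response, label = "") {
  stopifnot(length(dose) == length(response))
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("doses must be finite and nonnegative")
  }
  if (length(unique(dose)) < 3L) stop("need >= 3 distinct doses")
  o <- order(dose)
  out <- data.frame(dose = dose[o], response = response[o])
  attr(out, "label") <- label
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Read a dose-response CSV
#'
#' Expects columns `dose_uM`, `rep1` .. `repN`.  Lines starting with `#`
#' are treated as comments (the synthetic generator stores truth
#' parameters there).
#'
#' @param path path to the CSV.
#' @return a [dose_response()] dataset.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"dose_uM" %in% names(tab)) stop("missing dose_uM column in ", path)
  reps <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  if (length(reps) == 0L) stop("no rep<N> columns in ", path)
  dose <- rep(tab$dose_uM, times = length(reps))
  response <- unlist(tab[reps], use.names = FALSE)
  keep <- !is.na(response)
  dose_response(dose[keep], response[keep],
                label = tools::file_path_sans_ext(basename(path)))
}

#' Write a dose-response dataset to CSV (wide, rep1..repN)
#' @param dataset a [dose_response()] dataset.
#' @param path output path.
#' @param header_comments optional character vector written as `#` lines.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dataset, path, header_comments = NULL) {
  sp <- split(dataset$response, dataset$dose)
  nrep <- max(lengths(sp))
  wide <- t(vapply(sp, function(v) c(v, rep(NA_real_, nrep - length(v))),
                   numeric(nrep)))
  out <- data.frame(dose_uM = as.numeric(names(sp)), wide)
  names(out) <- c("dose_uM", paste0("rep", seq_len(nrep)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# restore the RNG state after running `expr` with a local seed; keeps
# generators and k-means deterministic without touching the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
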