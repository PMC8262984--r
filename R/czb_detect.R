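# CZB domain identification.  A CZB call rests on four attributes:
# (i) the 3His/1Cys zinc-binding core, (ii) the seven-residue
# CX(L/F)GXW(Y/L) alpha-3 motif, (iii) sequence coverage across the
# ~128-residue domain, and (iv) alignment to confirmed CZB sequences,
# scored against a position-frequency profile.

#' Scan a sequence for the CZB alpha-3 motif
#'
#' Reports every 7-residue window matching `CX(L/F)GXW(Y/L)` (X = any
#' canonical residue; the unknown residue letter `X` never satisfies a
#' motif position).  Overlapping hits are allowed and reported left to
#' right.
#'
#' @param record a single-row [protein_set()] or a list with `id` and
#'   `sequence`.
#' @return data.frame with columns `protein_id`, `cys_position` (1-based
#'   index of the motif Cys), `motif_seq`.
#' @export
scan_motif <- function(record) {
  seqc <- record$sequence[1]
  id <- record$id[1]
  # lookahead so overlapping matches are all reported
  pos <- gregexpr(paste0("(?=", MOTIF_REGEX, ")"), seqc, perl = TRUE)[[1]]
  if (pos[1] == -1L) {
    return(data.frame(protein_id = character(), cys_position = integer(),
                      motif_seq = character(), stringsAsFactors = FALSE))
  }
  pos <- as.integer(pos)
  data.frame(protein_id = id, cys_position = pos,
             motif_seq = substring(seqc, pos, pos + 6L),
             stringsAsFactors = FALSE)
}

#' Check the 3His/1Cys zinc-binding core around a motif hit
#'
#' True when at least three histidines lie within `window` residues of
#' the motif cysteine (both sides, clipped to the sequence bounds).
#'
#' @param record a single-row [protein_set()].
#' @param hit one row of [scan_motif()] output (or a list with
#'   `cys_position`).
#' @param window half-width in residues (default 45, spanning the
#'   His22/His79/His83 spread around Cys52 of the reference diguanylate
#'   cyclase DgcZ).
#' @return list with `core` (logical) and `his_positions` (ascending
#'   integer vector).
#' @export
check_zinc_core <- function(record, hit, window = 45L) {
  if (window < 1L) stop("window must be >= 1")
  seqc <- record$sequence[1]
  cys <- as.integer(hit$cys_position[1])
  if (cys < 1L || cys > nchar(seqc)) stop("hit outside record")
  lo <- max(1L, cys - as.integer(window))
  hi <- min(nchar(seqc), cys + as.integer(window))
  sub <- substring(seqc, lo, hi)
  rel <- gregexpr("H", sub, fixed = TRUE)[[1]]
  his <- if (rel[1] == -1L) integer(0) else as.integer(rel) + lo - 1L
  list(core = length(his) >= 3L, his_positions = his)
}

#' Build a position-frequency profile from a seed alignment
#'
#' Per-column residue frequencies over non-gap rows, with a symmetric
#' pseudocount, plus per-column gap fractions.  Scoring is log-odds
#' (base 2) against a background distribution (uniform by default).
#'
#' @param alignment an [aa_alignment()] of confirmed CZB domains.
#' @param pseudocount added per residue per column (default 0.5).
#' @param background length-20 named numeric summing to 1; default
#'   uniform.
#' @return object of class `"czb_profile"`.
#' @export
build_profile <- function(alignment, pseudocount = 0.5, background = NULL) {
  mat <- alignment_matrix(alignment)
  L <- ncol(mat)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL)
  }
  freq <- matrix(0, nrow = 20, ncol = L,
                 dimnames = list(AA_CANONICAL, NULL))
  gap_frac <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_frac[j] <- mean(col == "-")
    res <- col[col %in% AA_CANONICAL]
    cnt <- table(factor(res, levels = AA_CANONICAL))
    freq[, j] <- (as.numeric(cnt) + pseudocount) /
      (length(res) + 20 * pseudocount)
  }
  structure(list(freq = freq, gap_frac = gap_frac,
                 background = background, length = L,
                 pseudocount = pseudocount),
            class = "czb_profile")
}

#' Score a candidate region against a CZB profile
#'
#' Ungapped sum of per-column log-odds (base 2) of the observed residue
#' versus background, aligning the region start to profile column 1.
#' Profile columns not covered by the region contribute a fixed gap
#' penalty; `X` residues score as background (0).  A region shorter than
#' half the profile length is a coverage failure and scores `-Inf`.
#'
#' @param record a single-row [protein_set()].
#' @param region integer `c(start, end)`, 1-based inclusive.
#' @param profile a [build_profile()] object.
#' @param gap_penalty score for uncovered columns (default -2).
#' @return numeric log-odds score.
#' @export
score_against_profile <- function(record, region, profile,
                                  gap_penalty = -2) {
  start <- as.integer(region[1]); end <- as.integer(region[2])
  seqc <- record$sequence[1]
  stopifnot(start >= 1L, end <= nchar(seqc), start <= end)
  nres <- end - start + 1L
  if (nres < profile$length / 2) return(-Inf)
  res <- strsplit(substring(seqc, start, end), "")[[1]]
  score <- 0
  for (j in seq_len(profile$length)) {
    if (j > nres) { score <- score + gap_penalty; next }
    r <- res[j]
    if (r == "X") next  # background: log-odds 0
    score <- score + log2(profile$freq[r, j] / profile$background[[r]])
  }
  unname(score)
}

#' Configuration for CZB calling
#'
#' @param his_window half-width for [check_zinc_core()] (residues).
#' @param min_coverage minimum candidate-region length (residues) for the
#'   coverage attribute; default 100 of the canonical ~128-residue domain.
#' @param score_threshold minimum profile log-odds for the alignment
#'   attribute; default 0 (more CZB-like than background).
#' @param region_up,region_down residues taken upstream/downstream of the
#'   motif Cys to frame the candidate domain; defaults 51/76 mirror Cys52
#'   inside a 1-128 domain.
#' @param gap_penalty passed to [score_against_profile()].
#' @return a list of class `"czb_config"`.
#' @export
czb_config <- function(his_window = 45L, min_coverage = 100L,
                       score_threshold = 0, region_up = 51L,
                       region_down = 76L, gap_penalty = -2) {
  structure(list(his_window = as.integer(his_window),
                 min_coverage = as.integer(min_coverage),
                 score_threshold = score_threshold,
                 region_up = as.integer(region_up),
                 region_down = as.integer(region_down),
                 gap_penalty = gap_penalty),
            class = "czb_config")
}

#' Call a CZB domain in one protein
#'
#' Combines the four identification attributes.  When several motif hits
#' exist, the highest profile score wins, ties broken by the smallest
#' cysteine position.  A call exactly at the score threshold is accepted
#' but flagged for review.
#'
#' @param record a single-row [protein_set()].
#' @param profile a [build_profile()] object.
#' @param config a [czb_config()].
#' @return list of class `"czb_call"` with fields `protein_id`, `region`,
#'   `cys_position`, `his_positions`, `attributes` (named logical:
#'   core, motif, coverage, alignment), `profile_score`, `accepted`,
#'   `flagged`.
#' @export
call_czb <- function(record, profile, config = czb_config()) {
  hits <- scan_motif(record)
  n <- nchar(record$sequence[1])
  empty <- list(protein_id = record$id[1], region = c(NA_integer_, NA_integer_),
                cys_position = NA_integer_, his_positions = integer(0),
                attributes = c(core = FALSE, motif = FALSE,
                               coverage = FALSE, alignment = FALSE),
                profile_score = -Inf, accepted = FALSE, flagged = FALSE)
  class(empty) <- "czb_call"
  if (nrow(hits) == 0L) return(empty)
  regions <- cbind(pmax(1L, hits$cys_position - config$region_up),
                   pmin(n, hits$cys_position + config$region_down))
  scores <- vapply(seq_len(nrow(hits)), function(i) {
    score_against_profile(record, regions[i, ], profile,
                          gap_penalty = config$gap_penalty)
  }, numeric(1))
  best <- which(scores == max(scores))[1]  # ties: smallest cys (sorted)
  cys <- hits$cys_position[best]
  region <- regions[best, ]
  core <- check_zinc_core(record, hits[best, ], window = config$his_window)
  attributes <- c(
    core = core$core,
    motif = TRUE,
    coverage = (region[2] - region[1] + 1L) >= config$min_coverage,
    alignment = is.finite(scores[best]) &&
      scores[best] >= config$score_threshold
  )
  out <- list(protein_id = record$id[1], region = as.integer(region),
              cys_position = as.integer(cys),
              his_positions = core$his_positions,
              attributes = attributes,
              profile_score = scores[best],
              accepted = all(attributes),
              flagged = all(attributes) &&
                abs(scores[best] - config$score_threshold) <= 1e-9)
  class(out) <- "czb_call"
  out
}

#' Call CZB domains across a protein set
#'
#' @param proteins a [protein_set()].
#' @param profile a [build_profile()] object.
#' @param config a [czb_config()].
#' @return data.frame (class `"czb_call_table"`) with one row per
#'   protein: protein_id, start, end, cys_position, core, motif,
#'   coverage, alignment, score, accepted, flagged.
#' @export
call_czb_set <- function(proteins, profile, config = czb_config()) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    cl <- call_czb(proteins[i, ], profile, config)
    data.frame(protein_id = cl$protein_id,
               start = cl$region[1], end = cl$region[2],
               cys_position = cl$cys_position,
               core = cl$attributes[["core"]],
               motif = cl$attributes[["motif"]],
               coverage = cl$attributes[["coverage"]],
               alignment = cl$attributes[["alignment"]],
               score = cl$profile_score,
               accepted = cl$accepted, flagged = cl$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("czb_call_table", "data.frame")
  out
}

#' Naive shared k-mer search backend
#'
#' Returns a backend function mapping (query protein set, database
#' protein set) to candidate database ids sharing at least `min_shared`
#' distinct k-mers with any query.  A deliberately simple stand-in for a
#' BLAST-like search; no E-value statistics.
#'
#' @param k k-mer length.
#' @param min_shared minimum number of distinct shared k-mers.
#' @return function(queries, database) -> character vector of ids.
#' @export
kmer_backend <- function(k = 4L, min_shared = 8L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  function(queries, database) {
    qk <- unique(unlist(lapply(queries$sequence, kmers)))
    hit <- vapply(database$sequence, function(s) {
      sum(kmers(s) %in% qk) >= min_shared
    }, logical(1))
    database$id[hit]
  }
}

#' Iterative homology search to a fixed point
#'
#' Starting from seed ids, repeatedly asks the backend for candidates
#' similar to the accepted set and accepts those passing [call_czb()],
#' until no new sequences emerge.  The accepted set grows monotonically
#' and is bounded by the database, so termination is guaranteed.
#'
#' @param seeds character vector of seed protein ids (must be in
#'   `database`).
#' @param database a [protein_set()].
#' @param profile a [build_profile()] object.
#' @param backend a search function as from [kmer_backend()] (default).
#' @param config a [czb_config()].
#' @return list with `accepted` (sorted id vector) and `iterations`.
#' @export
iterative_search <- function(seeds, database, profile,
                             backend = kmer_backend(),
                             config = czb_config()) {
  stopifnot(all(seeds %in% database$id))
  accepted <- sort(unique(as.character(seeds)))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    queries <- database[database$id %in% accepted, , drop = FALSE]
    candidates <- setdiff(backend(queries, database), accepted)
    new_ok <- character(0)
    for (id in candidates) {
      cl <- call_czb(database[database$id == id, , drop = FALSE],
                     profile, config)
      if (cl$accepted) new_ok <- c(new_ok, id)
    }
    if (length(new_ok) == 0L) break
    accepted <- sort(union(accepted, new_ok))
  }
  list(accepted = accepted, iterations = iterations)
}
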