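# Architecture classification: each accepted CZB protein is assigned to
# one of seven subgroups, and N-terminal CZBs flanked by transmembrane
# helices in membrane-bound chemoreceptors are flagged as putative
# periplasmic domains.

#' Predict transmembrane regions by sliding-window hydropathy
#'
#' Kyte-Doolittle window means; maximal runs of window centers above the
#' threshold are merged when separated by fewer than 3 residues and
#' reported when at least `min_len` residues long.  A stand-in for an
#' external TM annotation.
#'
#' @param record a single-row [protein_set()].
#' @param window odd window width, >= 7 (default 19).
#' @param threshold hydropathy threshold (default 1.6).
#' @param min_len minimum run length in residues (default 15).
#' @return data.frame with columns `start`, `end`, `mean_hydropathy`
#'   (coordinates are window centers, 1-based inclusive).
#' @export
predict_tm <- function(record, window = 19L, threshold = 1.6,
                       min_len = 15L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 7L) stop("window must be odd and >= 7")
  res <- strsplit(record$sequence[1], "")[[1]]
  n <- length(res)
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = numeric())
  if (n < window) return(empty)
  h <- KD_SCALE[res]
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  wm <- vapply(centers, function(c) mean(h[(c - half):(c + half)]),
               numeric(1))
  above <- wm > threshold
  if (!any(above)) return(empty)
  pos <- centers[above]
  # merge runs separated by < 3 residues
  brk <- c(TRUE, diff(pos) >= 3L)
  grp <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_along(pos), grp), function(idx) {
    data.frame(start = pos[idx[1]], end = pos[idx[length(idx)]],
               mean_hydropathy = mean(wm[above][idx]))
  }))
  out <- out[out$end - out$start + 1L >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the domain architecture of a CZB-containing protein
#'
#' Decision rules in priority order: chemoreceptor (MCP) domains outrank
#' catalytic domains; membrane-bound vs soluble is decided by TM
#' presence; GGDEF+EAL, GGDEF-only, EAL-only and CheW-only come next;
#' anything else is CZB-only.  The CZB terminus is N when the domain
#' starts within the first 15% of the protein, C when it ends within the
#' last 15%, otherwise internal.
#'
#' @param record a single-row [protein_set()].
#' @param annotations a domain table restricted or not to this protein;
#'   only rows matching `record$id` are used.
#' @param czb_call an accepted [call_czb()] result for this protein.
#' @param tm_regions optional data.frame as from [predict_tm()]; TM rows
#'   in `annotations` are also honoured.
#' @return list of class `"architecture_call"`: `protein_id`, `subgroup`,
#'   `czb_terminus` ("N","C","internal"), `periplasmic`, `length`.
#' @export
classify_architecture <- function(record, annotations, czb_call,
                                  tm_regions = NULL) {
  if (!isTRUE(czb_call$accepted)) {
    stop("classification undefined: no accepted CZB call for ",
         record$id[1])
  }
  ann <- annotations[annotations$protein_id == record$id[1], , drop = FALSE]
  doms <- ann$domain_name
  tm_ann <- ann[doms == "TM", c("start", "end"), drop = FALSE]
  tms <- tm_ann
  if (!is.null(tm_regions) && nrow(tm_regions)) {
    tms <- rbind(tms, tm_regions[, c("start", "end"), drop = FALSE])
  }
  has <- function(d) d %in% doms
  has_tm <- nrow(tms) > 0L
  subgroup <-
    if (has("MCP") && has_tm) "membrane_chemoreceptor"
    else if (has("MCP")) "soluble_chemoreceptor"
    else if (has("GGDEF") && has("EAL")) "dgc_eal"
    else if (has("GGDEF")) "dgc"
    else if (has("EAL")) "eal_czb"
    else if (has("CheW")) "chew_czb"
    else "czb_only"
  if (subgroup == "czb_only" && any(doms == "other")) {
    message("protein ", record$id[1],
            ": only 'other' annotations besides CZB; classified czb_only")
  }
  n <- nchar(record$sequence[1])
  region <- czb_call$region
  czb_terminus <-
    if (region[1] <= 0.15 * n) "N"
    else if (region[2] >= 0.85 * n) "C"
    else "internal"
  out <- list(protein_id = record$id[1], subgroup = subgroup,
              czb_terminus = czb_terminus, periplasmic = FALSE,
              length = n)
  out$periplasmic <- flag_periplasmic(out, czb_call, tms)
  class(out) <- "architecture_call"
  out
}

#' Flag putative periplasmic CZB domains
#'
#' True only for membrane-bound chemoreceptors whose CZB region lies
#' strictly between two TM regions (one ending before it and one
#' starting after it).
#'
#' @param call an architecture call (list with `subgroup`).
#' @param czb_call the CZB call supplying `region`.
#' @param tm_regions data.frame with `start`, `end` columns.
#' @return logical.
#' @export
flag_periplasmic <- function(call, czb_call, tm_regions) {
  if (!identical(call$subgroup, "membrane_chemoreceptor")) return(FALSE)
  if (is.null(tm_regions) || nrow(tm_regions) == 0L) return(FALSE)
  region <- czb_call$region
  any(tm_regions$end < region[1]) && any(tm_regions$start > region[2])
}

#' Classify architectures across a protein set
#'
#' @param proteins a [protein_set()].
#' @param annotations a domain table.
#' @param calls a [call_czb_set()] table; only accepted rows are
#'   classified.
#' @param use_predicted_tm when TRUE and a protein has no TM annotation,
#'   [predict_tm()] supplies TM regions.
#' @return data.frame (class `"architecture_table"`): protein_id,
#'   subgroup, czb_terminus, periplasmic, length.
#' @export
classify_set <- function(proteins, annotations, calls,
                         use_predicted_tm = FALSE) {
  acc <- calls[calls$accepted, , drop = FALSE]
  rows <- lapply(seq_len(nrow(acc)), function(i) {
    id <- acc$protein_id[i]
    rec <- proteins[proteins$id == id, , drop = FALSE]
    cl <- list(accepted = TRUE,
               region = c(acc$start[i], acc$end[i]),
               cys_position = acc$cys_position[i])
    tm <- NULL
    if (use_predicted_tm &&
        !any(annotations$protein_id == id & annotations$domain_name == "TM")) {
      tm <- predict_tm(rec)
    }
    a <- classify_architecture(rec, annotations, cl, tm)
    data.frame(protein_id = a$protein_id, subgroup = a$subgroup,
               czb_terminus = a$czb_terminus, periplasmic = a$periplasmic,
               length = a$length, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), subgroup = character(),
               czb_terminus = character(), periplasmic = logical(),
               length = integer())
  class(out) <- c("architecture_table", "data.frame")
  out
}

#' Summarize subgroup composition
#'
#' @param calls an [classify_set()] architecture table.
#' @return data.frame with one row per subgroup (count, fraction), plus
#'   attributes `periplasmic_count` and `n`.
#' @export
summarize_subgroups <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- data.frame(subgroup = character(), count = integer(),
                      fraction = numeric())
    attr(out, "periplasmic_count") <- 0L
    attr(out, "n") <- 0L
    return(out)
  }
  cnt <- table(factor(calls$subgroup, levels = SUBGROUPS))
  out <- data.frame(subgroup = SUBGROUPS, count = as.integer(cnt),
                    fraction = as.numeric(cnt) / nrow(calls))
  attr(out, "periplasmic_count") <- sum(calls$periplasmic)
  attr(out, "n") <- nrow(calls)
  out
}
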