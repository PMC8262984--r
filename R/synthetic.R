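# Labeled synthetic inputs for every pipeline stage.  The generators are
# deterministic given a seed and always return ground-truth labels next
# to the data, so detection, classification, fitting and image
# quantification can all be verified offline.

#' Generator configuration
#'
#' Defaults state the emulated world: the subgroup mix follows the
#' published survey fractions (45.6% soluble chemoreceptors, 27.1%
#' CZB-only, 6.0% diguanylate cyclases split 3:1 between GGDEF-only and
#' GGDEF+EAL, 3.4% EAL-CZB, 1.4% CheW-CZB, remainder membrane-bound
#' chemoreceptors), replicate noise is 5% multiplicative, and decoys
#' mutate motif positions at rate 0.2.
#'
#' @param seed integer RNG seed (recorded in all outputs).
#' @param n_per_class default count per class for generators that need
#'   one.
#' @param noise_sd fractional (multiplicative) noise SD.
#' @param architecture_mix named fractions over the seven subgroups,
#'   summing to 1.
#' @param motif_mutation_rate per-position mutation probability used for
#'   decoy construction.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_per_class = 20L,
                             noise_sd = 0.05,
                             architecture_mix = c(
                               soluble_chemoreceptor = 0.456,
                               membrane_chemoreceptor = 0.165,
                               dgc = 0.045, dgc_eal = 0.015,
                               eal_czb = 0.034, chew_czb = 0.014,
                               czb_only = 0.271),
                             motif_mutation_rate = 0.2) {
  stopifnot(abs(sum(architecture_mix) - 1) < 1e-9,
            setequal(names(architecture_mix), SUBGROUPS))
  structure(list(seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 noise_sd = noise_sd,
                 architecture_mix = architecture_mix[SUBGROUPS],
                 motif_mutation_rate = motif_mutation_rate),
            class = "generator_config")
}

rand_aa <- function(n) paste(sample(AA_CANONICAL, n, replace = TRUE),
                             collapse = "")

# largest-remainder allocation of n among fractions (deterministic)
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# a CZB cassette: 128 residues, Cys52, His at 22/79/83, alpha-3 motif at
# 52..58.  `consensus` gives the family consensus; mutating it at
# `divergence` per position (motif and core positions held fixed) yields
# realistic within-family variation.
czb_consensus <- function(pos2_residue = "R") {
  cass <- strsplit(rand_aa(128), "")[[1]]
  cass[c(22, 79, 83)] <- "H"
  cass[52:58] <- c("C", pos2_residue, sample(c("L", "F"), 1), "G",
                   sample(setdiff(AA_CANONICAL, "H"), 1), "W",
                   sample(c("Y", "L"), 1))
  paste(cass, collapse = "")
}

mutate_cassette <- function(consensus, divergence = 0.15,
                            pos2_residue = NULL, pos2_enrichment = 0.6) {
  cass <- strsplit(consensus, "")[[1]]
  fixed <- c(22, 52, 55, 57, 79, 83)  # His core, Cys, Gly, Trp
  mut <- stats::runif(length(cass)) < divergence
  mut[fixed] <- FALSE
  cass[mut] <- sample(AA_CANONICAL, sum(mut), replace = TRUE)
  # re-impose motif constraints on the variable motif positions
  if (!is.null(pos2_residue) && stats::runif(1) < pos2_enrichment) {
    cass[53] <- pos2_residue
  } else if (!(cass[53] %in% setdiff(AA_CANONICAL, character(0)))) {
    cass[53] <- sample(AA_CANONICAL, 1)
  }
  if (!(cass[54] %in% c("L", "F"))) cass[54] <- sample(c("L", "F"), 1)
  if (cass[56] == "X") cass[56] <- sample(AA_CANONICAL, 1)
  if (!(cass[58] %in% c("Y", "L"))) cass[58] <- sample(c("Y", "L"), 1)
  paste(cass, collapse = "")
}

tm_segment <- function(n = 21L) {
  paste(sample(c("L", "I", "V", "F", "A"), n, replace = TRUE,
               prob = c(0.35, 0.2, 0.2, 0.15, 0.1)), collapse = "")
}

# remove any alpha-3 motif occurrences from a sequence (decoy scrubbing)
scrub_motif <- function(seqc) {
  repeat {
    hit <- regexpr(MOTIF_REGEX, seqc)
    if (hit == -1L) return(seqc)
    substr(seqc, hit, hit) <- "A"
  }
}

#' Generate labeled CZB-containing proteins and near-miss decoys
#'
#' Positives embed a 128-residue CZB cassette (Cys52, 3 His within the
#' default window, alpha-3 motif) into one of the seven architectures;
#' subgroup-defining cassettes carry literal GGDEF/EAL motifs and
#' hydrophobic TM stretches so both the annotation table and the naive
#' predictors agree with truth.  Decoys are near-misses, each designed to
#' fail exactly one attribute: `decoy_motif_only` (no His core),
#' `decoy_core_only` (motif scrubbed) and `decoy_truncated` (coverage
#' failure).  Half the membrane-bound chemoreceptors place the CZB
#' periplasmically between two TM helices.
#'
#' @param n_positive number of CZB-positive proteins.
#' @param n_decoy_per_type decoys per decoy type.
#' @param config a [generator_config()].
#' @param out_dir optional directory; when given, writes `proteins.fa`,
#'   `domains.tsv`, `truth.tsv`, `seed.aln` and `taxonomy.tsv`.
#' @return list: `proteins` ([protein_set()]), `domains` (domain table),
#'   `truth` (data.frame: protein_id, class, is_czb, subgroup, terminus,
#'   periplasmic), `seed_alignment` ([aa_alignment()] of positive
#'   cassettes), `taxonomy` (one synthetic species per protein).
#' @export
gen_czb_proteins <- function(n_positive = 280L, n_decoy_per_type = 40L,
                             config = generator_config(),
                             out_dir = NULL) {
  with_local_seed(config$seed, {
    counts <- allocate_counts(n_positive, config$architecture_mix)
    consensus <- czb_consensus()
    ids <- character(0); seqs <- character(0)
    dom <- list(); truth <- list(); seed_cass <- character(0)
    add_dom <- function(id, name, s, e) {
      dom[[length(dom) + 1L]] <<- data.frame(protein_id = id,
                                             domain_name = name,
                                             start = s, end = e)
    }
    k <- 0L
    for (sg in SUBGROUPS) {
      pos2 <- if (sg %in% c("soluble_chemoreceptor",
                            "membrane_chemoreceptor", "dgc", "dgc_eal",
                            "eal_czb")) "R" else "A"
      for (i in seq_len(counts[[sg]])) {
        k <- k + 1L
        id <- sprintf("POS%04d", k)
        cass <- mutate_cassette(consensus, pos2_residue = pos2)
        if (length(seed_cass) < 8L) seed_cass <- c(seed_cass, cass)
        periplasmic <- FALSE
        if (sg == "soluble_chemoreceptor") {
          seqc <- paste0(rand_aa(350), rand_aa(10), cass)
          add_dom(id, "MCP", 1L, 350L); add_dom(id, "CZB", 361L, 488L)
          terminus <- "C"
        } else if (sg == "membrane_chemoreceptor") {
          periplasmic <- i %% 2L == 1L
          if (periplasmic) {
            seqc <- paste0(rand_aa(4), tm_segment(21), rand_aa(14), cass,
                           rand_aa(12), tm_segment(21), rand_aa(10),
                           rand_aa(350))
            add_dom(id, "TM", 5L, 25L); add_dom(id, "CZB", 40L, 167L)
            add_dom(id, "TM", 180L, 200L); add_dom(id, "MCP", 211L, 560L)
            terminus <- "N"
          } else {
            seqc <- paste0(rand_aa(4), tm_segment(21), rand_aa(10),
                           rand_aa(365), rand_aa(10), cass)
            add_dom(id, "TM", 5L, 25L); add_dom(id, "MCP", 36L, 400L)
            add_dom(id, "CZB", 411L, 538L)
            terminus <- "C"
          }
        } else if (sg == "dgc") {
          seqc <- paste0(cass, rand_aa(60), "GGDEF", rand_aa(103))
          add_dom(id, "CZB", 1L, 128L); add_dom(id, "GGDEF", 129L, 296L)
          terminus <- "N"
        } else if (sg == "dgc_eal") {
          seqc <- paste0(cass, rand_aa(60), "GGDEF", rand_aa(103),
                         rand_aa(3), rand_aa(100), "EAL", rand_aa(138))
          add_dom(id, "CZB", 1L, 128L); add_dom(id, "GGDEF", 129L, 296L)
          add_dom(id, "EAL", 300L, 540L)
          terminus <- "N"
        } else if (sg == "eal_czb") {
          seqc <- paste0(rand_aa(100), "EAL", rand_aa(137), rand_aa(9),
                         cass)
          add_dom(id, "EAL", 1L, 240L); add_dom(id, "CZB", 250L, 377L)
          terminus <- "C"
        } else if (sg == "chew_czb") {
          seqc <- paste0(rand_aa(140), rand_aa(9), cass)
          add_dom(id, "CheW", 1L, 140L); add_dom(id, "CZB", 150L, 277L)
          terminus <- "C"
        } else {  # czb_only
          seqc <- cass
          add_dom(id, "CZB", 1L, 128L)
          terminus <- "N"
        }
        ids <- c(ids, id); seqs <- c(seqs, seqc)
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, class = sg, is_czb = TRUE, subgroup = sg,
          terminus = terminus, periplasmic = periplasmic)
      }
    }
    # near-miss decoys
    for (type in c("decoy_motif_only", "decoy_core_only",
                   "decoy_truncated")) {
      for (i in seq_len(n_decoy_per_type)) {
        k <- k + 1L
        id <- sprintf("DEC%04d", k)
        if (type == "decoy_motif_only") {
          cass <- strsplit(rand_aa(128), "")[[1]]
          cass[52:58] <- c("C", "A", "L", "G", "A", "W", "Y")
          cass[cass == "H"] <- "Q"  # no histidines anywhere near the Cys
          seqc <- paste(cass, collapse = "")
        } else if (type == "decoy_core_only") {
          seqc <- scrub_motif(mutate_cassette(consensus))
        } else {  # truncated: positive-like but only 90 residues long
          seqc <- substr(mutate_cassette(consensus), 1L, 90L)
        }
        ids <- c(ids, id); seqs <- c(seqs, seqc)
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, class = type, is_czb = FALSE,
          subgroup = NA_character_, terminus = NA_character_,
          periplasmic = FALSE)
      }
    }
    proteins <- protein_set(ids, seqs)
    domains <- validate_domain_table(do.call(rbind, dom), proteins)
    truth <- do.call(rbind, truth)
    seed_alignment <- aa_alignment(paste0("SEED", seq_along(seed_cass)),
                                   seed_cass)
    taxonomy <- data.frame(
      protein_id = ids,
      species = sprintf("Synthetica czb%04d", seq_along(ids)),
      genus = "Synthetica",
      phylum = "Proteobacteria", candidate_phylum_flag = FALSE)
    out <- list(proteins = proteins, domains = domains, truth = truth,
                seed_alignment = seed_alignment, taxonomy = taxonomy,
                seed = config$seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(proteins, file.path(out_dir, "proteins.fa"))
      write_domain_table(domains, file.path(out_dir, "domains.tsv"))
      utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      aln_set <- Biostrings::BStringSet(seed_alignment$sequence)
      names(aln_set) <- seed_alignment$id
      Biostrings::writeXStringSet(aln_set,
                                  file.path(out_dir, "seed.aln"))
    }
    out
  })
}

#' Generate a synthetic dose-response dataset
#'
#' Responses are `model(dose) * (1 + e)`, `e ~ N(0, noise_sd)`, truncated
#' at zero; truth parameters travel with the data (and into CSV header
#' comments when written).
#'
#' @param model one of "hill", "twostate", "linear".
#' @param params named list of model parameters: hill needs `K_half`,
#'   `n`, `A`; twostate needs `K_D`, `y_min`, `y_max`; linear needs
#'   `intercept`, `slope`.
#' @param doses numeric dose vector.
#' @param reps replicates per dose.
#' @param config a [generator_config()] (supplies seed and noise_sd).
#' @param path optional CSV output path.
#' @return a [dose_response()] dataset with attribute `truth`.
#' @export
gen_dose_response <- function(model = c("hill", "twostate", "linear"),
                              params, doses, reps = 3L,
                              config = generator_config(), path = NULL) {
  model <- match.arg(model)
  mu <- switch(model,
    hill = hill_response(doses, params$K_half,
                         n = params$n %||% 2, A = params$A %||% 1),
    twostate = tight_binding_y(doses, params$K_D, params$y_min,
                               params$y_max),
    linear = params$intercept + params$slope * doses)
  if (any(!is.finite(mu))) stop("invalid params for model ", model)
  with_local_seed(config$seed, {
    dose <- rep(doses, each = reps)
    base <- rep(mu, each = reps)
    response <- pmax(base * (1 + stats::rnorm(length(base),
                                              sd = config$noise_sd)), 0)
    ds <- dose_response(dose, response, label = model)
    attr(ds, "truth") <- c(list(model = model, seed = config$seed,
                                noise_sd = config$noise_sd), params)
    if (!is.null(path)) {
      write_dose_response(ds, path, header_comments = c(
        paste("model:", model), paste("seed:", config$seed),
        paste(names(params), unlist(params), sep = ": ")))
    }
    ds
  })
}

#' Generate a Congo red colony image with known red fraction
#'
#' A black border frames an interior whose pixels are red (hue ~8 on the
#' 0-255 wheel, inside the 1-14 gate) with the requested probability and
#' brown (hue ~45) otherwise; saturation/brightness jitter keeps hues
#' intact while giving k-means realistic spread.
#'
#' @param red_fraction requested fraction of red among colony pixels, in
#'   `[0, 1]`.
#' @param size `c(height, width)` in pixels.
#' @param border black border width in pixels.
#' @param config a [generator_config()].
#' @param path optional image output path (`.ppm`/`.png`).
#' @return list: `image` (H x W x 3 array), `red_fraction_requested`,
#'   `red_fraction_realized`, `seed`.
#' @export
gen_colony_image <- function(red_fraction, size = c(120L, 120L),
                             border = 10L, config = generator_config(),
                             path = NULL) {
  if (red_fraction < 0 || red_fraction > 1) {
    stop("red_fraction must be in [0, 1]")
  }
  with_local_seed(config$seed, {
    h <- size[1]; w <- size[2]
    img <- array(0, dim = c(h, w, 3))
    # background: near-black with tiny brightness jitter
    bg_v <- matrix(stats::runif(h * w, 0.01, 0.03), h, w)
    for (ch in 1:3) img[, , ch] <- bg_v
    rows <- (border + 1L):(h - border); cols <- (border + 1L):(w - border)
    n_in <- length(rows) * length(cols)
    is_red <- stats::runif(n_in) < red_fraction
    hue <- ifelse(is_red, 8, 45) / 255
    sat <- stats::runif(n_in, 0.75, 0.9)
    val <- ifelse(is_red, stats::runif(n_in, 0.75, 0.9),
                  stats::runif(n_in, 0.45, 0.6))
    rgb <- grDevices::col2rgb(grDevices::hsv(hue, sat, val)) / 255
    idx <- cbind(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))
    for (ch in 1:3) img[cbind(idx, ch)] <- rgb[ch, ]
    out <- list(image = img, red_fraction_requested = red_fraction,
                red_fraction_realized = mean(is_red), seed = config$seed)
    if (!is.null(path)) write_image(img, path)
    out
  })
}

#' Generate a crystal-violet tube image with a known pellicle band
#'
#' Light uniform background with a darker horizontal band over the given
#' 0-based row range; the stain-positive truth profile (1 - luma per
#' row) accompanies the image.  Deterministic (no pixel noise) so the
#' measured profile equals the truth exactly.
#'
#' @param pellicle_intensity stain intensity of the band above
#'   background, in `[0, 0.9]`.
#' @param band_rows 0-based `c(first, last)` row range of the band.
#' @param size `c(height, width)`.
#' @param background_value background gray level (default 0.9).
#' @param config a [generator_config()].
#' @param path optional image output path.
#' @return list: `image`, `truth_profile` (stain-positive, length H),
#'   `band_rows`, `seed`.
#' @export
gen_tube_image <- function(pellicle_intensity = 0.5,
                           band_rows = c(2000L, 2500L),
                           size = c(3000L, 40L),
                           background_value = 0.9,
                           config = generator_config(), path = NULL) {
  if (pellicle_intensity < 0 || pellicle_intensity > background_value) {
    stop("pellicle_intensity must be in [0, background_value]")
  }
  h <- size[1]; w <- size[2]
  if (band_rows[1] < 0 || band_rows[2] > h - 1 ||
      band_rows[1] > band_rows[2]) {
    stop("band outside image")
  }
  gray <- rep(background_value, h)
  gray[(band_rows[1]:band_rows[2]) + 1L] <-
    background_value - pellicle_intensity
  img <- array(rep(gray, times = 3L * w), dim = c(h, w, 3))
  out <- list(image = img, truth_profile = 1 - gray,
              band_rows = band_rows, seed = config$seed)
  if (!is.null(path)) write_image(img, path)
  out
}

#' Generate a species/taxonomy table with known co-occurrence categories
#'
#' Allocates species to the four co-occurrence categories by largest
#' remainder (so a (0.5, 0.5, 0, 0) mix over 100 species gives exactly
#' 50/50), assigns phyla cyclically, and emits the matching architecture
#' calls.
#'
#' @param mix named fractions over chemoreceptor_only / dgc_only / both /
#'   neither, summing to 1.
#' @param n_species number of species.
#' @param phyla character vector of phylum names to cycle through.
#' @param candidate_phyla subset of `phyla` flagged as candidate phyla.
#' @param config a [generator_config()].
#' @return list: `taxonomy` (protein-level), `arch_calls`
#'   (architecture-table shaped), `truth` (species, category, phylum).
#' @export
gen_species_table <- function(mix = c(chemoreceptor_only = 0.45,
                                      dgc_only = 0.35, both = 0.05,
                                      neither = 0.15),
                              n_species = 100L,
                              phyla = c("Proteobacteria", "Firmicutes",
                                        "Bacteroidetes", "Actinobacteria",
                                        "Spirochaetes",
                                        "Candidatus Saccharibacteria"),
                              candidate_phyla =
                                "Candidatus Saccharibacteria",
                              config = generator_config()) {
  stopifnot(abs(sum(mix) - 1) < 1e-9)
  with_local_seed(config$seed, {
    counts <- allocate_counts(n_species,
                              mix[c("chemoreceptor_only", "dgc_only",
                                    "both", "neither")])
    category <- rep(names(counts), counts)
    species <- sprintf("Synthetica species%03d", seq_len(n_species))
    phylum <- rep_len(phyla, n_species)
    tax <- list(); calls <- list()
    pid <- 0L
    for (i in seq_len(n_species)) {
      subs <- switch(category[i],
        chemoreceptor_only = sample(CHEMO_SUBGROUPS, 1),
        dgc_only = sample(DGC_SUBGROUPS, 1),
        both = c(sample(CHEMO_SUBGROUPS, 1), sample(DGC_SUBGROUPS, 1)),
        neither = sample(c("czb_only", "eal_czb", "chew_czb"), 1))
      for (sg in subs) {
        pid <- pid + 1L
        id <- sprintf("SP%05d", pid)
        tax[[pid]] <- data.frame(
          protein_id = id, species = species[i],
          genus = "Synthetica", phylum = phylum[i],
          candidate_phylum_flag = phylum[i] %in% candidate_phyla)
        calls[[pid]] <- data.frame(
          protein_id = id, subgroup = sg, czb_terminus = "N",
          periplasmic = FALSE, length = 300L)
      }
    }
    list(taxonomy = do.call(rbind, tax),
         arch_calls = do.call(rbind, calls),
         truth = data.frame(species = species, category = category,
                            phylum = phylum,
                            candidate_phylum = phylum %in% candidate_phyla),
         seed = config$seed)
  })
}
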