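test_that("scan_motif reports matching windows left to right", {
  hits <- scan_motif(make_protein("AACALGAWLAA"))
  expect_equal(hits$cys_position, 3L)
  expect_equal(hits$motif_seq, "CALGAWL")

  # position 3 must be L or F
  expect_equal(nrow(scan_motif(make_protein("CAAGAWL"))), 0L)
  # X never satisfies a motif position, even a wildcard one
  expect_equal(nrow(scan_motif(make_protein("CXLGAWL"))), 0L)
  # overlapping hits are all reported (Cys at 5 sits inside the first
  # window as its wildcard position 5)
  hits <- scan_motif(make_protein("CALGCWLGAWY"))
  expect_equal(hits$cys_position, c(1L, 5L))
})

test_that("scan_motif equals exhaustive window enumeration", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    seqc <- paste(sample(AA20, n, TRUE), collapse = "")
    # plant a motif in some sequences so matches are exercised
    if (i %% 2 == 0) {
      at <- sample(n - 6, 1)
      substr(seqc, at, at + 6) <- "CRFGIWY"
    }
    expect_equal(scan_motif(make_protein(seqc))$cys_position,
                 oracle_scan_motif(seqc), info = paste("case", i))
  }
  # one long sequence
  seqc <- paste(sample(AA20, 10000, TRUE), collapse = "")
  expect_equal(scan_motif(make_protein(seqc))$cys_position,
               oracle_scan_motif(seqc))
})

test_that("check_zinc_core counts His within the clipped window", {
  # DgcZ-like spacing: His at cys-30, cys-27, cys+31
  chars <- rep("A", 120)
  cys <- 60
  chars[c(cys - 30, cys - 27, cys + 31)] <- "H"
  chars[cys] <- "C"
  rec <- make_protein(paste(chars, collapse = ""))
  res <- check_zinc_core(rec, list(cys_position = cys), window = 45)
  expect_true(res$core)
  expect_equal(res$his_positions, c(30L, 33L, 91L))

  chars[cys + 31] <- "A"
  res <- check_zinc_core(make_protein(paste(chars, collapse = "")),
                         list(cys_position = cys), window = 45)
  expect_false(res$core)
  expect_length(res$his_positions, 2L)

  expect_error(check_zinc_core(rec, list(cys_position = cys), window = 0),
               "window")
})

test_that("check_zinc_core equals the exhaustive count oracle", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(60:300, 1)
    seqc <- paste(sample(AA20, n, TRUE), collapse = "")
    cys <- sample(n, 1)
    w <- sample(c(10, 45, 80), 1)
    oracle <- oracle_his_in_window(seqc, cys, w)
    got <- check_zinc_core(make_protein(seqc),
                           list(cys_position = cys), window = w)
    expect_equal(got$his_positions, oracle)
    expect_equal(got$core, length(oracle) >= 3)
  }
})

test_that("profile scoring: uniform profile scores 0, toy profile by hand", {
  # uniform profile: every column equiprobable -> log-odds identically 0
  uni <- aa_alignment(paste0("U", 1:20), AA20)  # one residue per row
  prof <- build_profile(uni)
  expect_true(all(abs(prof$freq - 1 / 20) < 1e-12))
  rec <- make_protein("MKHLR")
  expect_equal(score_against_profile(rec, c(1, 5), prof), 0)

  # 5-column toy profile, hand-computed log-odds
  aln <- aa_alignment(c("S1", "S2", "S3", "S4"),
                      c("CAGDE", "CAGDE", "CAGDF", "CAGDE"))
  prof <- build_profile(aln, pseudocount = 0.5)
  # per column, p(res) = (count + 0.5) / (4 + 10); background 1/20
  p4 <- (4 + 0.5) / 14; p3 <- (3 + 0.5) / 14
  expected <- 4 * log2(p4 / 0.05) + log2(p3 / 0.05)  # scoring "CAGDE"
  expect_equal(score_against_profile(make_protein("CAGDE"), c(1, 5), prof),
               expected, tolerance = 1e-12)

  # a seed scores at least as high as any of its single-point mutants
  seed_score <- score_against_profile(make_protein("CAGDE"), c(1, 5), prof)
  for (pos in 1:5) for (r in c("W", "K")) {
    mut <- "CAGDE"
    substr(mut, pos, pos) <- r
    expect_lte(score_against_profile(make_protein(mut), c(1, 5), prof),
               seed_score)
  }

  # X scores as background (0 contribution)
  expect_equal(score_against_profile(make_protein("XAGDE"), c(1, 5), prof),
               expected - log2(p4 / 0.05), tolerance = 1e-12)

  # region shorter than half the profile -> -Inf coverage sentinel
  expect_identical(score_against_profile(make_protein("CA"), c(1, 2), prof),
                   -Inf)
})

test_that("call_czb combines the four attributes", {
  sim <- gen_czb_proteins(n_positive = 10, n_decoy_per_type = 5,
                          config = generator_config(seed = 31))
  profile <- build_profile(sim$seed_alignment)
  config <- czb_config()

  pos <- sim$proteins[sim$proteins$id == "POS0001", ]
  call <- call_czb(pos, profile, config)
  expect_true(call$accepted)
  expect_true(all(call$attributes))
  expect_gte(length(call$his_positions), 3L)
  expect_true(call$cys_position >= call$region[1] &&
              call$cys_position <= call$region[2])

  # motif-only decoy: core fails, motif/coverage pass
  dec <- sim$proteins[sim$truth$class == "decoy_motif_only", ][1, ]
  call <- call_czb(dec, profile, config)
  expect_false(call$accepted)
  expect_false(call$attributes[["core"]])
  expect_true(call$attributes[["motif"]])
  expect_true(call$attributes[["coverage"]])

  # no motif at all: empty call
  call <- call_czb(make_protein(strrep("A", 200)), profile, config)
  expect_false(call$accepted)
  expect_false(call$attributes[["motif"]])

  # a call exactly at the threshold is accepted and flagged
  rec <- sim$proteins[1, ]
  sc <- call_czb(rec, profile, config)$profile_score
  at <- call_czb(rec, profile, czb_config(score_threshold = sc))
  expect_true(at$accepted)
  expect_true(at$flagged)
})

test_that("call_czb_set is deterministic and permutation-invariant", {
  sim <- gen_czb_proteins(n_positive = 20, n_decoy_per_type = 5,
                          config = generator_config(seed = 32))
  profile <- build_profile(sim$seed_alignment)
  a <- call_czb_set(sim$proteins, profile)
  b <- call_czb_set(sim$proteins, profile)
  expect_identical(a, b)
  perm <- sample(nrow(sim$proteins))
  shuffled <- sim$proteins[perm, ]
  class(shuffled) <- class(sim$proteins)
  c2 <- call_czb_set(shuffled, profile)
  c2 <- c2[match(a$protein_id, c2$protein_id), ]
  rownames(c2) <- NULL
  expect_equal(a, c2, ignore_attr = TRUE)
})

test_that("iterative_search reaches a fixed point", {
  sim <- gen_czb_proteins(n_positive = 6, n_decoy_per_type = 0,
                          config = generator_config(seed = 33))
  profile <- build_profile(sim$seed_alignment)
  seeds <- sim$proteins$id
  res <- iterative_search(seeds, sim$proteins, profile)
  expect_equal(res$accepted, sort(seeds))
  expect_equal(res$iterations, 1L)
})

test_that("iterative_search finds a 2-hop homolog via an intermediate", {
  set.seed(44)
  cass <- function() {
    x <- sample(AA20, 128, TRUE)
    x[c(22, 79, 83)] <- "H"
    x[52:58] <- c("C", "R", "L", "G", "I", "W", "Y")
    paste(x, collapse = "")
  }
  link <- function(n = 30) paste(sample(AA20, n, TRUE), collapse = "")
  l_ab <- link(); l_bc <- link(); pad <- link
  a <- paste0(cass(), l_ab, pad())
  b <- paste0(cass(), l_ab, l_bc)
  cc <- paste0(cass(), pad(), l_bc)
  db <- protein_set(c("A", "B", "C"), c(a, b, cc))
  profile <- build_profile(aa_alignment(
    c("s1", "s2", "s3"),
    c(substr(a, 1, 128), substr(b, 1, 128), substr(cc, 1, 128))))
  backend <- kmer_backend(k = 4, min_shared = 20)
  # sanity: C is not directly reachable from A
  expect_false("C" %in% backend(db[db$id == "A", ], db))
  res <- iterative_search("A", db, profile, backend = backend)
  expect_setequal(res$accepted, c("A", "B", "C"))
  expect_gte(res$iterations, 2L)
  # output invariant to seed ordering
  res2 <- iterative_search(c("B", "A"), db, profile, backend = backend)
  expect_equal(sort(res2$accepted), sort(union(res$accepted, "B")))
})
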