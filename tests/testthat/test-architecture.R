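test_that("predict_tm finds hydrophobic stretches and nothing else", {
  rec <- make_protein(paste0(strrep("S", 30), strrep("L", 25),
                             strrep("S", 30)))
  tm <- predict_tm(rec)
  expect_equal(nrow(tm), 1L)
  # run of qualifying window centers covers the Leu stretch
  expect_equal(c(tm$start, tm$end), c(31, 55))
  expect_gt(tm$mean_hydropathy, 1.6)

  expect_equal(nrow(predict_tm(make_protein(strrep("S", 100)))), 0L)
  # sequence shorter than the window -> empty
  expect_equal(nrow(predict_tm(make_protein("MKHLLVV"))), 0L)
  expect_error(predict_tm(rec, window = 18), "odd")
})

test_that("predict_tm equals direct re-evaluation of the rule", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(80:400, 1)
    x <- sample(AA20, n, TRUE)
    if (i %% 2 == 0) {  # plant a hydrophobic stretch
      at <- sample(n - 24, 1)
      x[at:(at + 23)] <- sample(c("L", "I", "V", "F"), 24, TRUE)
    }
    seqc <- paste(x, collapse = "")
    got <- predict_tm(make_protein(seqc))
    want <- oracle_tm_regions(seqc)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, info = paste("case", i))
    } else {
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(want), info = paste("case", i))
    }
  }
})

make_arch_case <- function(seqc, anns, czb_region) {
  rec <- make_protein(seqc)
  ann <- do.call(rbind, lapply(anns, function(a) {
    data.frame(protein_id = "P1", domain_name = a[[1]],
               start = as.integer(a[[2]]), end = as.integer(a[[3]]))
  }))
  call <- list(accepted = TRUE, region = czb_region,
               cys_position = czb_region[1] + 51L)
  list(rec = rec, ann = ann, call = call)
}

test_that("classification follows the priority rules", {
  rand <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
  set.seed(7)
  # DgcZ-style: N-terminal CZB + GGDEF, no TM
  cs <- make_arch_case(rand(296),
                       list(list("CZB", 1, 128), list("GGDEF", 129, 296)),
                       c(1L, 128L))
  a <- classify_architecture(cs$rec, cs$ann, cs$call)
  expect_equal(a$subgroup, "dgc")
  expect_equal(a$czb_terminus, "N")
  expect_false(a$periplasmic)

  # TlpD-style: MCP + C-terminal CZB, no TM
  cs <- make_arch_case(rand(488),
                       list(list("MCP", 1, 350), list("CZB", 361, 488)),
                       c(361L, 488L))
  a <- classify_architecture(cs$rec, cs$ann, cs$call)
  expect_equal(a$subgroup, "soluble_chemoreceptor")
  expect_equal(a$czb_terminus, "C")

  # MCP outranks catalytic domains
  cs <- make_arch_case(rand(600),
                       list(list("MCP", 1, 300), list("GGDEF", 310, 470),
                            list("CZB", 473, 600)),
                       c(473L, 600L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$subgroup,
               "soluble_chemoreceptor")

  # GGDEF + EAL -> dgc_eal; EAL only; CheW only; CZB only
  cs <- make_arch_case(rand(540),
                       list(list("CZB", 1, 128), list("GGDEF", 129, 296),
                            list("EAL", 300, 540)), c(1L, 128L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$subgroup,
               "dgc_eal")
  cs <- make_arch_case(rand(377),
                       list(list("EAL", 1, 240), list("CZB", 250, 377)),
                       c(250L, 377L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$subgroup,
               "eal_czb")
  cs <- make_arch_case(rand(277),
                       list(list("CheW", 1, 140), list("CZB", 150, 277)),
                       c(150L, 277L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$subgroup,
               "chew_czb")
  cs <- make_arch_case(rand(128), list(list("CZB", 1, 128)), c(1L, 128L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$subgroup,
               "czb_only")

  # internal CZB terminus
  cs <- make_arch_case(rand(400), list(list("CZB", 130, 257)),
                       c(130L, 257L))
  expect_equal(classify_architecture(cs$rec, cs$ann, cs$call)$czb_terminus,
               "internal")

  # unaccepted CZB call is an error
  cs <- make_arch_case(rand(128), list(list("CZB", 1, 128)), c(1L, 128L))
  cs$call$accepted <- FALSE
  expect_error(classify_architecture(cs$rec, cs$ann, cs$call),
               "undefined")
})

test_that("periplasmic flag requires a TM on each side of the CZB", {
  tm2 <- data.frame(start = c(5L, 170L), end = c(25L, 190L))
  call <- list(subgroup = "membrane_chemoreceptor")
  czb <- list(region = c(40L, 160L))
  expect_true(flag_periplasmic(call, czb, tm2))

  # no TM after the CZB (cytoplasmic C-terminal CZB)
  tm1 <- data.frame(start = 5L, end = 25L)
  expect_false(flag_periplasmic(call, list(region = c(40L, 160L)), tm1))

  # soluble chemoreceptors are never periplasmic, whatever the coordinates
  expect_false(flag_periplasmic(list(subgroup = "soluble_chemoreceptor"),
                                czb, tm2))
})

test_that("subgroup summaries normalize correctly", {
  calls <- data.frame(
    protein_id = paste0("P", 1:10),
    subgroup = c(rep("soluble_chemoreceptor", 4), rep("dgc", 3),
                 rep("czb_only", 3)),
    czb_terminus = "N", periplasmic = FALSE, length = 300L)
  s <- summarize_subgroups(calls)
  expect_equal(s$fraction[s$subgroup == "soluble_chemoreceptor"], 0.4)
  expect_equal(sum(s$fraction), 1.0)
  expect_equal(sum(s$count), 10L)

  empty <- summarize_subgroups(calls[0, ])
  expect_equal(nrow(empty), 0L)
})
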