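test_that("interaction datasets enforce their structural contracts", {
  ds <- toyDataset()
  expect_s4_class(ds, "InteractionDataset")
  expect_equal(nPairs(ds), 4L)
  recs <- records(ds)
  # duplicate pair within a label class
  expect_error(interactionDataset(rbind(recs, recs[1, ]),
                                  sequenceStore(ds), idpIds(ds)),
               "duplicate")
  # same pair as both positive and negative
  flip <- recs[1, ]; flip$label <- "negative"
  expect_error(interactionDataset(rbind(recs, flip), sequenceStore(ds),
                                  idpIds(ds)), "IDP component|both")
  # unresolved sequence id
  ghost <- recs; ghost$partnerId[1] <- "missing"
  expect_error(interactionDataset(ghost, sequenceStore(ds), idpIds(ds)),
               "unresolved")
  # negatives must keep exactly one IDP component
  negIdp <- recs[1, ]; negIdp$label <- "negative"
  negIdp$partnerId <- idpIds(ds)[2]
  expect_error(interactionDataset(rbind(recs, negIdp),
                                  sequenceStore(ds), idpIds(ds)),
               "exactly one IDP")
  # dedupe mode drops duplicates with a warning instead
  expect_warning(d2 <- interactionDataset(rbind(recs, recs[1, ]),
                                          sequenceStore(ds), idpIds(ds),
                                          dedupe = TRUE), "duplicated")
  expect_equal(nPairs(d2), 4L)
})

test_that("pair lists round-trip through the tab-separated format", {
  ds <- toyDataset()
  path <- tempfile(fileext = ".tsv")
  writePairList(ds, path)
  back <- readPairList(path)
  expect_equal(back$idpId, records(ds)$idpId)
  expect_equal(back$label, records(ds)$label)
  # comment lines and missing label column
  writeLines(c("# provenance comment", "idp_id\tpartner_id",
               "idp1\tprt1", "idp2\tprt2"), path)
  bare <- readPairList(path)
  expect_equal(nrow(bare), 2L)
  expect_true(all(bare$label == "positive"))
  expect_error(readPairList(tempfile("nope")), "not found")
})

test_that("length and name-word filters remove exactly the flagged sequences", {
  store <- Biostrings::AAStringSet(c(s49 = strrep("A", 49),
                                     s50 = strrep("A", 50),
                                     s51 = strrep("A", 51),
                                     bad1 = strrep("A", 80),
                                     bad2 = strrep("A", 80),
                                     ok = strrep("A", 80)))
  S4Vectors::mcols(store)$description <-
    c("", "", "", "Putative kinase", "potential transporter fragment",
      "well characterized enzyme")
  expect_message(out <- filterSequences(store),
                 "removed 1 short .* and 2 banned-word")
  expect_setequal(names(out), c("s50", "s51", "ok"))
  # monotone: output ids are a subset of input ids
  expect_true(all(names(out) %in% names(store)))
  expect_warning(filterSequences(store, minLength = 1000, verbose = FALSE),
                 "all sequences")
})

test_that("record tables resynchronize after sequence filtering", {
  ds <- toyDataset()
  store <- sequenceStore(ds)[-1]  # drop idp1
  expect_message(recs <- restrictRecords(records(ds), store), "dropped 2")
  expect_false("idp1" %in% recs$idpId)
})

test_that("greedy identity clustering keeps one representative per cluster", {
  base <- randomSeq(80)
  mutate <- function(res, k) {
    chars <- strsplit(res, "")[[1]]
    idx <- sample(length(chars), k)
    chars[idx] <- sample(AA, k, replace = TRUE)
    paste(chars, collapse = "")
  }
  withr::with_seed(17, {
    near <- mutate(base, 8)        # ~90% identical to base
    far1 <- randomSeq(80)          # unrelated
    far2 <- randomSeq(75)
    store <- Biostrings::AAStringSet(c(a = base, b = near, c = far1,
                                       d = far2))
    out <- reduceRedundancy(store, identityThreshold = 0.40)
    # base/near collapse to one representative; unrelated sequences survive
    expect_equal(sum(c("a", "b") %in% names(out)), 1L)
    expect_true(all(c("c", "d") %in% names(out)))
    expect_true(all(names(out) %in% names(store)))
    # identical sequences always collapse
    twin <- Biostrings::AAStringSet(c(x = base, y = base))
    expect_equal(length(reduceRedundancy(twin)), 1L)
  })
  expect_error(reduceRedundancy(Biostrings::AAStringSet(c(a = base)),
                                identityThreshold = 1.2), "identityThreshold")
})

test_that("CD-HIT cluster files substitute for internal alignment", {
  clstr <- tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0",
               "0\t80aa, >seqA... *",
               "1\t78aa, >seqB... at 92.31%",
               ">Cluster 1",
               "0\t60aa, >seqC... *"), clstr)
  parsed <- readClstr(clstr)
  expect_equal(parsed$representatives, c("seqA", "seqC"))
  expect_equal(parsed$clusters[[1]], c("seqA", "seqB"))
  store <- Biostrings::AAStringSet(c(seqA = strrep("A", 60),
                                     seqB = strrep("A", 60),
                                     seqC = strrep("C", 60)))
  out <- reduceRedundancy(store, clstrFile = clstr)
  expect_setequal(names(out), c("seqA", "seqC"))
})
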