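cfg <- paacConfig()

test_that("dipeptide composition counts ordered residue pairs", {
  v <- dipeptideComposition("AAA")
  expect_length(v, 400L)
  expect_equal(unname(v[["AA"]]), 1.0)
  expect_equal(sum(v != 0), 1L)
  v2 <- dipeptideComposition("ACAC")
  expect_equal(unname(v2[["AC"]]), 2 / 3)
  expect_equal(unname(v2[["CA"]]), 1 / 3)
  expect_equal(sum(v2), 1)
  expect_error(dipeptideComposition("A", id = "tiny"), "tiny")
})

test_that("dipeptide schema order is lexicographic", {
  nms <- names(dipeptideComposition("ACDE"))
  expect_equal(nms[1:3], c("AA", "AC", "AD"))
  expect_equal(nms[400], "YY")
  expect_equal(nms, sort(nms))
})

test_that("a 51-residue homopolymer collapses PAAC to one component", {
  v <- paacComposition(strrep("A", 51), cfg)
  expect_length(v, 70L)
  expect_equal(unname(v[["A"]]), 1.0)
  expect_equal(sum(v != 0), 1L)
})

test_that("PAAC enforces the lambda + 1 minimum length", {
  expect_error(paacComposition(strrep("A", 50), cfg, id = "short51"),
               "length >= 51")
  expect_silent(paacComposition(strrep("AC", 26), cfg))
})

test_that("PAAC and dipeptide blocks are simplexes for random sequences", {
  withr::with_seed(7, {
    for (i in 1:20) {
      res <- randomSeq(sample(51:200, 1))
      p <- paacComposition(res, cfg)
      d <- dipeptideComposition(res)
      expect_true(all(p >= 0 & p <= 1))
      expect_true(all(d >= 0 & d <= 1))
      expect_lt(abs(sum(p) - 1), 1e-9)
      expect_lt(abs(sum(d) - 1), 1e-9)
    }
  })
})

test_that("residue order moves the correlation tiers but not the frequencies", {
  withr::with_seed(11, {
    res <- randomSeq(120)
    shuf <- paste(sample(strsplit(res, "")[[1]]), collapse = "")
    a <- paacComposition(res, cfg)
    b <- paacComposition(shuf, cfg)
    # raw frequency ratios are order-invariant (denominators differ)
    expect_equal(a[1:20] / sum(a[1:20]), b[1:20] / sum(b[1:20]),
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(a[21:70], b[21:70])))
    expect_false(isTRUE(all.equal(dipeptideComposition(res),
                                  dipeptideComposition(shuf))))
  })
})

test_that("paacComposition matches the brute-force oracle", {
  raw <- rawDefaultScales()
  withr::with_seed(3, {
    for (i in 1:5) {
      res <- randomSeq(sample(51:120, 1))
      expect_equal(unname(paacComposition(res, cfg)),
                   paacOracle(res, raw, 50L, 0.05), tolerance = 1e-12)
    }
  })
})

test_that("single-sequence encoding concatenates PAAC then dipeptides", {
  v <- encodeSequence(strrep("A", 51), cfg)
  expect_length(v, 470L)
  expect_equal(sum(v != 0), 2L)
  expect_equal(unname(v[["paac.A"]]), 1.0)
  expect_equal(unname(v[["dpc.AA"]]), 1.0)
  expect_equal(names(v), featureSchema(cfg))
  expect_error(encodeSequence("", cfg), "empty")
})

test_that("pair encoding is an ordered 940-dimensional concatenation", {
  withr::with_seed(5, {
    a <- randomSeq(80)
    b <- randomSeq(90)
    v <- encodePair(a, b, cfg, idpId = "ida", partnerId = "idb")
    expect_length(v, 940L)
    expect_equal(attr(v, "idpId"), "ida")
    expect_equal(attr(v, "partnerId"), "idb")
    expect_equal(unname(v[1:470]), unname(encodeSequence(a, cfg)))
    expect_equal(unname(v[471:940]), unname(encodeSequence(b, cfg)))
    expect_false(isTRUE(all.equal(unname(encodePair(a, b, cfg)),
                                  unname(encodePair(b, a, cfg)))))
    same <- encodePair(a, a, cfg)
    expect_equal(unname(same[1:470]), unname(same[471:940]))
  })
})

test_that("nonstandard residues follow the configured policy", {
  expect_warning(v <- dipeptideComposition(paste0(strrep("A", 60), "X")),
                 "deleted 1 nonstandard")
  expect_equal(unname(v[["AA"]]), 1.0)
  # more than 5% nonstandard letters is an error under the delete policy
  expect_error(suppressWarnings(
    dipeptideComposition(paste0(strrep("A", 10), "XXX"), id = "junky")),
    "junky")
  strict <- paacConfig(nonstandard = "error")
  expect_error(paacComposition(paste0(strrep("A", 60), "U"), strict),
               "nonstandard")
})

test_that("store encoding matches per-sequence encoding row by row", {
  withr::with_seed(9, {
    store <- Biostrings::AAStringSet(c(s1 = randomSeq(70), s2 = randomSeq(95)))
    mat <- encodeStore(store, cfg)
    expect_equal(dim(mat), c(2L, 470L))
    expect_equal(mat["s2", ], encodeSequence(as.character(store[["s2"]]), cfg))
    recs <- data.frame(idpId = "s1", partnerId = "s2")
    X <- disoPPI:::pairFeatureMatrix(recs, store, cfg)
    expect_equal(as.numeric(X[1, ]),
                 as.numeric(encodePair(as.character(store[["s1"]]),
                                       as.character(store[["s2"]]), cfg)))
  })
})

test_that("feature tables export with ids first and a full header", {
  withr::with_seed(13, {
    store <- Biostrings::AAStringSet(c(a = randomSeq(60), b = randomSeq(60)))
    path <- tempfile(fileext = ".tsv")
    writeFeatureTable(encodeStore(store, cfg), path)
    tab <- read.delim(path, check.names = FALSE)
    expect_equal(dim(tab), c(2L, 471L))
    expect_equal(names(tab)[1], "id")
    expect_equal(names(tab)[-1], featureSchema(cfg))
  })
})
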