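# virtual screening: filter chain, library prediction, decoys, enrichment

test_that("filter chain rejects with cumulative reasons and keeps order", {
  lib <- c(
    ok = "CCN1CCCCC1",
    big = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCN1CCCCC1",
    noN = "CCOc1ccccc1",
    threeN = "NCCN(CCN)CCN",
    racemic = "CC(c1ccccc1)N1CCCCC1",
    salt = "[Na+].[Cl-]",
    bad = "C1CC("
  )
  out <- filter_library(lib)
  expect_equal(out$kept$id, "ok")
  expect_equal(out$rejected$id, setdiff(names(lib), "ok"))
  reason <- function(id) out$rejected$reasons[out$rejected$id == id]
  expect_match(reason("big"), "ro5_mw")
  expect_match(reason("noN"), "no_basic_N")
  expect_match(reason("threeN"), "positive_groups")
  expect_match(reason("racemic"), "unspecified_stereo")
  expect_match(reason("salt"), "element")
  expect_equal(reason("bad"), "parse_error")
})

test_that("a relaxed RO5 tolerates one violation", {
  lib <- c(greasy = "CCCCCCCCCCCCCCCCCCCCN1CCCCC1")  # logP > 5, MW fine
  strict <- filter_library(lib)
  relaxed <- filter_library(lib, ro5_allowed_violations = 1)
  expect_match(strict$rejected$reasons, "ro5_logp")
  expect_equal(relaxed$kept$id, "greasy")
})

test_that("library prediction sorts, applies the inclusive cutoff, and matches hand dot products", {
  m <- published_model()
  nm <- names(m$coefficients)
  X <- matrix(0, 3, 5, dimnames = list(c("z1", "z2", "z3"), nm))
  hits <- predict_library(m, X, cutoff = 5.5)
  expect_true(all(hits$predicted_pki == 11.29))
  expect_true(all(hits$passed))

  set.seed(3)
  X10 <- matrix(rnorm(50, sd = 5), 10, 5, dimnames = list(sprintf("r%02d", 1:10), nm))
  hits10 <- predict_library(m, X10, cutoff = 5.5)
  hand <- m$intercept + drop(X10 %*% m$coefficients)
  expect_equal(hits10$predicted_pki[match(names(hand), hits10$id)], unname(hand),
               tolerance = 1e-12)
  expect_false(is.unsorted(rev(hits10$predicted_pki)))
  # boundary: exactly at the cutoff passes, just under fails
  at_cutoff <- predict_library(qsar_model(5.5, setNames(rep(0, 5), nm)),
                               matrix(0, 1, 5, dimnames = list("b", nm)))
  expect_true(at_cutoff$passed)
  just_under <- predict_library(qsar_model(5.49, setNames(rep(0, 5), nm)),
                                matrix(0, 1, 5, dimnames = list("b", nm)))
  expect_false(just_under$passed)
  expect_error(predict_library(m, X10[, 1:3]), "missing")
})

test_that("decoy selection keeps the most dissimilar floor(fraction*n), ties by id", {
  cand <- data.frame(id = sprintf("c%02d", 1:8),
                     max_tc = c(.9, .1, .5, .3, .8, .2, .7, .6))
  sel <- select_decoys(cand, 0.25)
  expect_equal(sel$id, c("c02", "c06"))  # two lowest max_tc
  # all-tied: first floor(n/4) by id
  tied <- data.frame(id = sprintf("t%02d", 8:1), max_tc = 0.5)
  expect_equal(select_decoys(tied, 0.25)$id, c("t01", "t02"))
  expect_error(select_decoys(cand[0, ], 0.25), "empty")
  # size property over n and fraction
  for (n in c(1, 5, 8, 13)) for (f in c(0.1, 0.25, 0.5, 1)) {
    cc <- data.frame(id = sprintf("x%02d", 1:n), max_tc = runif(n))
    expect_equal(nrow(select_decoys(cc, f)), floor(f * n))
  }
})

test_that("maximum Tanimoto against the actives orders candidates sensibly", {
  act <- c(a1 = "CCN1CCCCC1", a2 = "CCCN1CCCCC1")
  cand <- c(self = "CCN1CCCCC1", aryl = "c1ccc2ccccc2c1", diol = "OCCO")
  mt <- max_tanimoto(cand, act)
  expect_equal(mt$max_tc[mt$id == "self"], 1)
  expect_lt(mt$max_tc[mt$id == "aryl"], 0.2)
  expect_true(all(mt$max_tc >= 0 & mt$max_tc <= 1))
})

test_that("hand-computed Tanimoto on tiny fingerprints matches the sort", {
  # 4-bit fingerprints written out by hand: tc = |a&b| / |a|b|
  fp_act <- c(1, 1, 0, 0)
  cands <- list(c1 = c(1, 1, 0, 0), c2 = c(1, 0, 0, 1), c3 = c(0, 0, 1, 1))
  tc_hand <- vapply(cands, function(f) {
    sum(f & fp_act) / sum(f | fp_act)
  }, numeric(1))
  expect_equal(unname(tc_hand), c(1, 1 / 3, 0))
  sel <- select_decoys(data.frame(id = names(tc_hand), max_tc = tc_hand), 1 / 3)
  expect_equal(sel$id, "c3")
})

test_that("screening-set assembly counts actives and decoys", {
  p3 <- assemble_screening_set(sprintf("a%03d", 1:191), sprintf("d%05d", 1:12148))
  expect_equal(nrow(p3), 12339)
  expect_equal(attr(p3, "counts")$A, 191)
  expect_error(assemble_screening_set(c("x"), c("x")), "share ids")
})

test_that("enrichment counts, identities, and endpoint cases", {
  db <- c(sprintf("a%02d", 1:10), sprintf("d%02d", 1:90))
  act <- sprintf("a%02d", 1:10)
  # perfect screen: Ht = A, TP = A, EF = D/A
  perfect <- evaluate_enrichment(act, act, db)
  expect_equal(perfect$ef, 10)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # random screen with TP/Ht = A/D exactly: EF = 1
  rand <- evaluate_enrichment(c(act[1], sprintf("d%02d", 1:9)), act, db)
  expect_equal(rand$ef, 1)
  # identities on randomized screens
  set.seed(8)
  for (i in 1:25) {
    hits <- sample(db, sample(0:100, 1))
    er <- evaluate_enrichment(hits, act, db)
    expect_equal(er$TP + er$FN, er$A)
    expect_equal(er$TP + er$FP, er$Ht)
    expect_equal(er$TP + er$TN + er$FP + er$FN, er$D)
    if (er$Ht > 0) expect_equal(er$ef, (er$TP / er$Ht) / (er$A / er$D))
    if (er$A > 0) expect_equal(er$sensitivity, er$TP / (er$TP + er$FN))
  }
  # empty hit list: EF flagged undefined
  none <- evaluate_enrichment(character(0), act, db)
  expect_true(is.na(none$ef))
  expect_match(none$ef_note, "undefined")
  expect_error(evaluate_enrichment("zz", act, db), "subset")
})

test_that("EF is invariant to uniform duplication of the database", {
  db <- c(sprintf("a%02d", 1:5), sprintf("d%02d", 1:45))
  act <- sprintf("a%02d", 1:5)
  hits <- c("a01", "a02", "d01", "d02", "d03")
  base <- evaluate_enrichment(hits, act, db)
  dup <- function(x) c(x, paste0(x, "_copy"))
  doubled <- evaluate_enrichment(dup(hits), dup(act), dup(db))
  expect_equal(doubled$ef, base$ef)
  expect_equal(doubled$sensitivity, base$sensitivity)
  expect_equal(doubled$specificity, base$specificity)
})

test_that("top-fraction evaluation truncates the ranked list", {
  db <- sprintf("x%03d", 1:200)
  act <- db[1:20]
  ranked <- c(act[1:5], setdiff(db, act))  # actives ranked first
  er <- evaluate_enrichment(ranked, act, db, top_fraction = 0.01)
  expect_equal(er$Ht, 1)  # floor(0.01 * 185) = 1
  expect_equal(er$TP, 1)
  expect_equal(er$ef, (1 / 1) / (20 / 200))
})
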