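test_that("AAC matches hand counts and sums to one", {
  v <- encodeAAC("ACDE")
  expect_equal(length(v), 20L)
  expect_equal(unname(v[c("AAC_A", "AAC_C", "AAC_D", "AAC_E")]), rep(0.25, 4))
  expect_equal(sum(v), 1)
  expect_equal(unname(encodeAAC("AAAA")["AAC_A"]), 1)
  v <- encodeAAC("KLKLLLLLKLK")
  expect_equal(unname(v["AAC_K"]), 4 / 11)
  expect_equal(unname(v["AAC_L"]), 7 / 11)
  expect_error(encodeAAC("ACXDE"), "X")
})

test_that("DPC enumerates overlapping dipeptides", {
  v <- encodeDPC("AAA")
  expect_equal(length(v), 400L)
  expect_equal(unname(v["DPC_AA"]), 1)
  v <- encodeDPC("ACAC")
  expect_equal(unname(v["DPC_AC"]), 2 / 3)
  expect_equal(unname(v["DPC_CA"]), 1 / 3)
  expect_error(encodeDPC("A"), "length")
  # constant-denominator convention rescales uniformly
  vc <- encodeDPC("ACAC", denominator = "constant")
  expect_equal(unname(vc["DPC_AC"]), 2 / 400)
})

test_that("AAI weights composition by the averaged normalized indices", {
  # independent recomputation of the averaged profile from seqinr
  env <- new.env(); utils::data("aaindex", package = "seqinr", envir = env)
  idx <- get("aaindex", env)
  acc <- c("BLAM930101", "BIOV880101", "MAXF760101", "TSAJ990101",
           "NAKH920108", "CEDJ970104", "LIFS790101", "MIYS990104")
  three <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu")
  avg <- vapply(names(three), function(a1) {
    mean(vapply(acc, function(id) {
      v <- idx[[id]]$I
      (v[[three[[a1]]]] - min(v)) / (max(v) - min(v))
    }, numeric(1)))
  }, numeric(1))
  v <- encodeAAI("ACDE")
  expect_equal(unname(v[paste0("AAI_", names(three))]),
               unname(0.25 * avg), tolerance = 1e-12)
  # composition acts as an indicator
  v <- encodeAAI("AAAA")
  expect_equal(unname(v["AAI_A"]), unname(aaiProfile()["A"]))
  expect_equal(sum(v[names(v) != "AAI_A"]), 0)
})

test_that("CTD descriptor blocks follow their definitions", {
  v <- encodeCTD("AAAAAAAA")
  expect_equal(length(v), 147L)
  for (prop in names(aipkit:::CTD_SCHEMES)) {
    g <- which(vapply(aipkit:::CTD_SCHEMES[[prop]],
                      function(set) "A" %in% set, logical(1)))
    comp <- v[paste0("CTD_", prop, "_C_", 1:3)]
    expect_equal(unname(comp[g]), 100)
    expect_equal(sum(comp), 100)
    expect_equal(sum(v[paste0("CTD_", prop, c("_T_12", "_T_13", "_T_23"))]), 0)
    dvals <- v[paste0("CTD_", prop, "_D_", g, "_",
                      c("first", "q25", "q50", "q75", "q100"))]
    expect_equal(unname(dvals), c(1, 2, 4, 6, 8) / 8 * 100)
    other <- setdiff(1:3, g)
    expect_equal(sum(v[grep(paste0("CTD_", prop, "_D_[", paste(other,
      collapse = ""), "]"), names(v))]), 0)
  }
  # alternating two-group sequence: every adjacent pair is a transition
  v <- encodeCTD("ARARARARAR")  # charge: A neutral (g2), R positive (g1)
  expect_equal(unname(v["CTD_charge_T_12"]), 100)
  expect_error(encodeCTD("A"), "length")
})

test_that("PCP descriptors reproduce the printed formulas", {
  v <- encodePCP("AAAA")
  expect_equal(length(v), 9L)
  expect_equal(unname(v["PCP_aliphatic_index"]), 1)
  expect_equal(unname(v["PCP_hydrophobic_fraction"]), 1)
  expect_equal(unname(v["PCP_abs_charge"]), 0)
  expect_equal(unname(encodePCP("KKDD")["PCP_abs_charge"]), 0)
  expect_equal(unname(encodePCP("VVLL")["PCP_aliphatic_index"]),
               (2.9 * 2 + 3.9 * 2) / 4)
  # per-residue molecular weight: masses plus one water, over n
  m <- aipkit:::RESIDUE_MASS
  expect_equal(unname(encodePCP("ACDE")["PCP_mol_weight"]),
               (sum(m[c("A", "C", "D", "E")]) + 18.015) / 4)
})

test_that("hybrid concatenation respects block order and lengths", {
  s <- "KLKLLLLLKLK"
  expect_identical(encodeHybrid(s, parts = "aac"), encodeAAC(s))
  expect_equal(length(encodeHybrid(s)), 596L)
  v <- encodeHybrid(s, parts = c("dpc", "aac"))  # order is fixed, not given
  expect_equal(length(v), 420L)
  expect_identical(names(v)[1:20], names(encodeAAC(s)))
  expect_error(encodeHybrid(s, parts = character(0)), "non-empty")
  expect_error(encodeHybrid(s, parts = "xyz"), "unknown")
})

test_that("dataset encoding is consistent, deterministic and equivariant", {
  set.seed(403)
  ps <- randomPeptideSet(12)
  m <- encodeDataset(ps, "dpc")
  expect_equal(dim(m), c(12L, 400L))
  expect_identical(m, encodeDataset(ps, "dpc"))
  i <- 7L
  expect_equal(m[i, ], encodeDPC(as.character(peptides(ps))[[i]]))
  # shuffling rows shuffles outputs identically
  perm <- sample(length(ps))
  expect_identical(encodeDataset(ps[perm], "ctd"),
                   encodeDataset(ps, "ctd")[perm, ])
})

test_that("random peptides obey the normalization invariants", {
  set.seed(404)
  for (i in 1:60) {
    s <- randomPeptide(sample(5:30, 1))
    expect_equal(sum(encodeAAC(s)), 1, tolerance = 1e-12)
    expect_equal(sum(encodeDPC(s)), 1, tolerance = 1e-12)
    v <- encodeCTD(s)
    for (prop in names(aipkit:::CTD_SCHEMES)) {
      expect_equal(sum(v[paste0("CTD_", prop, "_C_", 1:3)]), 100,
                   tolerance = 1e-9)
      expect_lte(sum(v[paste0("CTD_", prop, c("_T_12", "_T_13", "_T_23"))]),
                 100 + 1e-9)
    }
    d <- v[grep("_D_", names(v))]
    expect_true(all(d >= 0 & d <= 100))
    # reversal leaves a homopolymer's encodings unchanged
  }
  h <- paste(rep("K", 9), collapse = "")
  expect_identical(encodeHybrid(h), encodeHybrid(paste(rev(strsplit(h,
    "")[[1]]), collapse = "")))
})

test_that("feature matrix TSV round-trips", {
  set.seed(405)
  ps <- randomPeptideSet(4)
  m <- encodeDataset(ps, "pcp")
  f <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(m, f, header = "test")
  back <- readFeatureMatrix(f)
  expect_equal(back, m, tolerance = 1e-12)
})
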