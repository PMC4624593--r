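test_that("identity symbol mapping leaves the matrix unchanged", {
  m <- pm("RNASEQ", mat_named(1:6, c("A", "B"), c("s1", "s2", "s3")))
  out <- update_symbols(m, data.frame(old = character(0), new = character(0)))
  expect_identical(out$values, m$values)
  expect_length(attr(out, "removed"), 0)
})

test_that("mapped symbols are renamed and obsolete ones dropped", {
  m <- pm("RNASEQ", mat_named(1:9, c("OLD1", "OLD2", "KEEP"), paste0("s", 1:3)))
  map <- data.frame(old = c("OLD1", "OLD2"), new = c("NEW1", NA),
                    status = c("updated", "obsolete"))
  out <- update_symbols(m, map)
  expect_setequal(features_of(out), c("NEW1", "KEEP"))
  expect_identical(unname(out$values["NEW1", ]), unname(m$values["OLD1", ]))
  expect_identical(attr(out, "removed"), "OLD2")
})

test_that("symbol collisions keep the feature with fewer missing values", {
  v <- mat_named(c(1, NA, 3, 4, 5, 6), c("A1", "A2"), paste0("s", 1:3))
  m <- pm("RNASEQ", v)
  map <- data.frame(old = c("A1", "A2"), new = c("A", "A"))
  out <- update_symbols(m, map)
  expect_identical(features_of(out), "A")
  expect_identical(unname(out$values["A", "s1"]), 4)  # A2 kept: 0 missing
  expect_identical(attr(out, "collisions")$dropped, "A1")
  # exact tie: lexicographically smallest original id wins
  v2 <- mat_named(1:6, c("B2", "B1"), paste0("s", 1:3))
  out2 <- update_symbols(pm("RNASEQ", v2),
                         data.frame(old = c("B1", "B2"), new = c("B", "B")))
  expect_identical(attr(out2, "collisions")$kept, "B1")
})

test_that("mutation matrix flags non-silent records only", {
  rec <- data.frame(
    Hugo_Symbol = c("G1", "G1", "G2", "G3"),
    Tumor_Sample_Barcode = c("s1", "s2", "s1", "s2"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation", "3'UTR"),
    stringsAsFactors = FALSE)
  m <- mutation_matrix_from_maf(rec, c("s1", "s2", "s3"))
  expect_identical(m$values["G1", "s1"], 1)  # missense counts
  expect_identical(m$values["G1", "s2"], 0)  # only silent
  expect_identical(m$values["G3", "s2"], 0)  # UTR excluded
  expect_identical(unname(m$values[, "s3"]), c(0, 0, 0))  # no records
})

test_that("MAF records for unknown samples are rejected and logged", {
  rec <- data.frame(Hugo_Symbol = "G1", Tumor_Sample_Barcode = "sX",
                    Variant_Classification = "Missense_Mutation")
  m <- mutation_matrix_from_maf(rec, c("s1", "s2"))
  expect_identical(nrow(attr(m, "rejected")), 1L)
  expect_identical(dim(m$values), c(0L, 2L))
})

test_that("methylation harmonization takes common probes, union of samples", {
  hm27 <- pm("METH", mat_named(c(1, 2, 3, 4), c("p1", "p2"), c("sA", "sB")))
  hm450 <- pm("METH", mat_named(c(10, 20, 30, 40), c("p2", "p3"), c("sB", "sC")))
  out <- harmonize_methylation(hm27, hm450, "common-probes")
  expect_identical(features_of(out), "p2")
  expect_setequal(samples_of(out), c("sA", "sB", "sC"))
  expect_identical(out$values["p2", "sB"], 10)  # both platforms: HM450 wins
  expect_identical(out$values["p2", "sA"], 3)   # HM27 only
  expect_identical(harmonize_methylation(hm27, hm450, "hm450-only"), hm450)
  disjoint <- pm("METH", mat_named(1:2, c("q1", "q2"), "sA"))
  expect_error(harmonize_methylation(disjoint, hm450, "common-probes"),
               "empty probe intersection")
})

test_that("sample intersection restricts all matrices to shared columns", {
  m1 <- pm("RNASEQ", mat_named(1:6, c("A", "B"), c("s1", "s2", "s3")))
  m2 <- pm("METH", mat_named(1:6, c("p1", "p2"), c("s2", "s3", "s4")))
  out <- intersect_samples(list(m1, m2))
  expect_identical(samples_of(out[[1]]), c("s2", "s3"))
  expect_identical(samples_of(out[[2]]), c("s2", "s3"))
  expect_identical(intersect_samples(list(m1))[[1]]$values, m1$values)
  m3 <- pm("RPPA", mat_named(1:2, c("r1", "r2"), "s9"))
  expect_error(intersect_samples(list(m1, m3)), "no samples")
})

test_that("the missingness filter drops at >= 3% and imputes below it", {
  set.seed(42)
  v <- matrix(rnorm(300), 3, 100,
              dimnames = list(c("drop3", "keep2", "full"), sprintf("s%03d", 1:100)))
  v["drop3", 1:3] <- NA   # 3/100 -> dropped at the default threshold
  v["keep2", 1:2] <- NA   # 2/100 -> imputed
  out <- filter_and_impute(pm("RNASEQ", v))
  expect_identical(attr(out, "dropped"), "drop3")
  expect_false(anyNA(out$values))
  med <- median(v["keep2", -(1:2)])
  expect_identical(unname(out$values["keep2", 1:2]), rep(med, 2))
  # imputation never changes the feature median
  expect_identical(median(out$values["keep2", ]), med)
  # identity when nothing is missing
  clean <- pm("RNASEQ", v[3, , drop = FALSE])
  expect_identical(filter_and_impute(clean)$values, clean$values)
  all_na <- pm("RNASEQ", matrix(NA_real_, 1, 4,
                                dimnames = list("x", paste0("s", 1:4))))
  expect_error(filter_and_impute(all_na), "all features dropped")
})

test_that("normalization divides by feature sd plus the sd 10th percentile", {
  # two features with sds {2, 20}: linear-interpolation percentile gives
  # sd10 = 2 + 0.1*(20-2) = 3.8, so feature 1 divides by 5.8
  s1 <- c(-2, 0, 2) / sd(c(-2, 0, 2)) * 2       # sd exactly 2
  s2 <- c(-2, 0, 2) / sd(c(-2, 0, 2)) * 20      # sd exactly 20
  m <- pm("RNASEQ", mat_named(c(s1, s2), c("f1", "f2"), paste0("s", 1:3)))
  out <- normalize_features(m)
  expect_equal(attr(out, "sd10"), 3.8, tolerance = 1e-12)
  expect_equal(unname(out$values["f1", ]), s1 / (2 + 3.8), tolerance = 1e-12)
  expect_equal(unname(out$values["f2", ]), s2 / (20 + 3.8), tolerance = 1e-12)
})

test_that("homogeneous-scale matrices divide by exactly twice the sd", {
  base <- c(-1, 0, 1)
  s <- sd(base)
  v <- mat_named(rep(base, each = 1), "f1", paste0("s", 1:3))
  v <- rbind(v, f2 = base + 5, f3 = base - 2)
  rownames(v) <- c("f1", "f2", "f3")
  out <- normalize_features(pm("RNASEQ", v))
  expect_equal(out$values, v / (2 * s), tolerance = 1e-12,
               ignore_attr = FALSE)
})

test_that("normalized feature sds satisfy sd/(sd + sd10) exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(40 * 25, sd = rep(exp(runif(40, log(0.5), log(20))), 25)),
                40, 25, dimnames = list(sprintf("f%02d", 1:40),
                                        sprintf("s%02d", 1:25)))
    m <- pm("RNASEQ", v)
    out <- normalize_features(m)
    sds <- apply(v, 1, sd)
    sd10 <- attr(out, "sd10")
    expect_equal(unname(apply(out$values, 1, sd)),
                 unname(sds / (sds + sd10)), tolerance = 1e-12)
    expect_true(all(apply(out$values, 1, sd) < 1))
  }
})

test_that("an all-constant matrix cannot be normalized", {
  v <- mat_named(rep(1, 6), c("a", "b"), paste0("s", 1:3))
  expect_error(normalize_features(pm("RNASEQ", v)), "sds are zero")
})

test_that("integration filters the gene group by the target list and tags rows", {
  m1 <- pm("CNV", mat_named(c(1, 0, -1, 0, 1, 1), c("G1", "G2"), paste0("s", 1:3)))
  m2 <- pm("RNASEQ", mat_named(rnorm(9), c("G1", "G2", "G3"), paste0("s", 1:3)))
  tg <- target_list(c("G1", "G3"), c("COSMIC", "MutSig"))
  X <- integrate_platforms(list(m1, m2), "gene", tg)
  expect_false("G2" %in% X$entity)
  expect_setequal(rownames(X$values), c("G1|CNV", "G1|RNASEQ", "G3|RNASEQ"))
  # miR group keeps everything
  m3 <- pm("MIRSEQ", mat_named(rnorm(6), c("M1", "M2"), paste0("s", 1:3)))
  Xm <- integrate_platforms(list(m3), "miR")
  expect_identical(nrow(Xm$values), 2L)
})

test_that("block concatenation preserves row counts and platform scaling recovers", {
  set.seed(1)
  m1 <- pm("RNASEQ", mat_named(rnorm(5 * 6), sprintf("a%d", 1:5), sprintf("s%d", 1:6)))
  m2 <- pm("METH", mat_named(rnorm(7 * 6, sd = 4), sprintf("b%d", 1:7),
                             sprintf("s%d", 1:6)))
  X <- integrate_platforms(list(m1, m2), "miR")
  expect_identical(nrow(X$values), 12L)
  expect_identical(X$platform, c(rep("RNASEQ", 5), rep("METH", 7)))
  # each block's mean per-feature sd is 1 after its scalar
  for (tag in c("RNASEQ", "METH")) {
    blk <- X$values[X$platform == tag, , drop = FALSE]
    expect_equal(mean(apply(blk, 1, sd)), 1, tolerance = 1e-12)
  }
  # original values recoverable from the recorded scalars
  rec <- X$values[X$platform == "METH", ] / X$platform_scale["METH"]
  expect_equal(unname(rec), unname(m2$values), tolerance = 1e-12)
  # already unit-mean-sd block gets scale factor 1
  u <- m1$values / mean(apply(m1$values, 1, sd))
  Xu <- integrate_platforms(list(pm("RNASEQ", u)), "miR")
  expect_equal(unname(Xu$platform_scale["RNASEQ"]), 1, tolerance = 1e-12)
})

test_that("integration rejects inconsistent inputs", {
  m1 <- pm("RNASEQ", mat_named(rnorm(4), c("A", "B"), c("s1", "s2")))
  m2 <- pm("METH", mat_named(rnorm(4), c("p", "q"), c("s2", "s1")))
  expect_error(integrate_platforms(list(m1, m2), "miR"),
               "identical sample order")
  expect_error(integrate_platforms(list(m1), "gene"), "target list")
  withna <- mat_named(c(NA, 1, 2, 3), c("A", "B"), c("s1", "s2"))
  expect_error(integrate_platforms(list(pm("RNASEQ", withna)), "miR"),
               "complete data")
})

test_that("duplicate-free target union counts unique ids across provenances", {
  ids <- c(sprintf("C%03d", 1:40),          # literature-curated
           sprintf("C%03d", 21:40),         # drug targets overlapping 20
           sprintf("M%03d", 1:30),          # recurrent mutations
           sprintf("A%03d", 1:15),          # amplification peaks
           sprintf("M%03d", 16:30))         # deletion peaks overlapping 15
  prov <- c(rep("COSMIC", 40), rep("TARGET", 20), rep("MutSig", 30),
            rep("CN-AmpPeak", 15), rep("CN-DelPeak", 15))
  tg <- target_list(ids, prov)
  # oracle: independent unique count on the raw id vector
  expect_identical(nrow(tg), length(unique(ids)))
  expect_identical(nrow(tg), 85L)
  expect_false(anyDuplicated(tg$id) > 0)
  # round trip through the TSV reader
  dir <- withr::local_tempdir()
  path <- file.path(dir, "targets.tsv")
  write.table(data.frame(id = ids, provenance = prov), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_identical(nrow(read_target_list(path)), 85L)
})
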