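variant_table <- function() {
  data.frame(
    subject_id = c("s1", "s1", "s2", "s3", "s3", "s4", "s5"),
    gene = c("G1", "G1", "G1", "G1", "G2", "G1", "G1"),
    allele_count = c(1L, 1L, 1L, 2L, 1L, 1L, 1L),
    population_af = c(NA, 5e-5, 5e-4, 0, NA, 2e-3, NA),
    consequence_class = c("protein_altering", "stop_gain",
                          "protein_altering", "frameshift",
                          "protein_altering", "protein_altering", "other"),
    stringsAsFactors = FALSE)
}

test_that("variant filtering applies mode-specific AF and consequence rules", {
  v <- variant_table()
  dom <- filter_variants(v, "dominant")
  # AF 5e-4 >= 1/10,000 removed under dominant; missing AF kept
  expect_false("s2" %in% dom$subject_id)
  expect_true(all(c("s1", "s3") %in% dom$subject_id))
  rec <- filter_variants(v, "recessive")
  # 5e-4 < 1/1,000 kept under recessive
  expect_true("s2" %in% rec$subject_id)
  expect_false("s4" %in% rec$subject_id)   # 2e-3 too common even recessive
  hi <- filter_variants(v, "high_impact_dominant")
  expect_setequal(unique(hi$subject_id), c("s1", "s3"))
  expect_true(all(hi$consequence_class %in%
                    c("splice_aberration", "frameshift", "start_loss",
                      "stop_gain")))
  # consequence "other" never passes
  expect_false("s5" %in% dom$subject_id)
  v$population_af[1] <- -0.1
  expect_error(filter_variants(v, "dominant"), "negative")
})

test_that("genotype encoding thresholds allele counts by inheritance mode", {
  subjects <- paste0("s", 1:6)
  v <- variant_table()
  ydom <- encode_genotypes(filter_variants(v, "dominant"), subjects, "G1",
                           "dominant")
  yrec <- encode_genotypes(filter_variants(v, "recessive"), subjects, "G1",
                           "recessive")
  # one het rare variant: dominant 1, recessive 0
  expect_equal(unname(ydom["s2"]), 0L)       # filtered out under dominant
  expect_equal(unname(yrec["s2"]), 0L)       # single allele, needs two
  # two het records in the same gene count as two alleles
  expect_equal(unname(yrec["s1"]), 1L)
  # homozygous (allele_count 2) satisfies recessive
  expect_equal(unname(yrec["s3"]), 1L)
  # subject with no records gets 0
  expect_equal(unname(ydom["s6"]), 0L)
  expect_equal(names(ydom), subjects)
  # recessive genotype implies dominant genotype on identical filtered input
  frec <- filter_variants(v, "recessive")
  y1 <- encode_genotypes(frec, subjects, "G1", "dominant")
  y2 <- encode_genotypes(frec, subjects, "G1", "recessive")
  expect_true(all(y1[y2 == 1L] == 1L))
  expect_warning(encode_genotypes(v, c("s1", "s2"), "G1", "dominant"),
                 "skipped")
})

test_that("offsets are centred batch-level logit rates", {
  ym <- matrix(c(1, 0, 0, 0,
                 0, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, 0, 0), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
  # batch A: subjects 1-2, mean rate 0.125; batch B: subjects 3-4, 0.125
  h <- estimate_offsets(ym, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_equal(unname(h), rep(0, 4))
  # rates 0.02 vs 0.01: offset difference = logit(0.02) - logit(0.01)
  ym2 <- matrix(0, nrow = 4, ncol = 100,
                dimnames = list(paste0("s", 1:4), NULL))
  ym2[1, 1:4] <- 1   # batch A mean rate (4/200) = 0.02
  ym2[3, 1:2] <- 1   # batch B mean rate 0.01
  h2 <- estimate_offsets(ym2, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_equal(unname(h2["s1"] - h2["s3"]), qlogis(0.02) - qlogis(0.01),
               tolerance = 1e-10)
  expect_equal(mean(h2), 0)
  # all-zero batch is clipped to a finite offset
  ym3 <- ym2; ym3[3, ] <- 0; ym3[4, ] <- 0
  h3 <- estimate_offsets(ym3, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_true(all(is.finite(h3)))
  # single batch -> zero offsets; single gene -> error
  expect_equal(unname(estimate_offsets(ym, c(s1 = "A", s2 = "A", s3 = "A",
                                             s4 = "A"))), rep(0, 4))
  expect_error(estimate_offsets(ym[, 1, drop = FALSE],
                                c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")),
               "2 genes")
})

test_that("the thin VCF reader reshapes calls into the variant table", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", "PASS",
          "GENE=G1;AF=0.00005;CSQ=stop_gain", "GT", "0/1", "0/0", sep = "\t"),
    paste("1", "200", ".", "C", "G", ".", "PASS",
          "GENE=G1;CSQ=protein_altering", "GT", "1/1", "0/1", sep = "\t"))
  path <- withr::local_tempfile(lines = vcf, fileext = ".vcf")
  v <- read_vcf_variants(path)
  expect_setequal(names(v), c("subject_id", "gene", "allele_count",
                              "population_af", "consequence_class"))
  s1 <- v[v$subject_id == "s1", ]
  expect_equal(sort(s1$allele_count), c(1L, 2L))   # het + hom
  expect_true(is.na(v$population_af[v$subject_id == "s2"]))  # AF key absent
  y <- encode_genotypes(filter_variants(v, "recessive"), c("s1", "s2"),
                        "G1", "recessive")
  expect_equal(unname(y), c(1L, 0L))
})
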