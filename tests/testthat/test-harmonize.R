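rec <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.2, beta = 0.1,
                se = 0.02) {
  list(snp_id = id, effect_allele = ea, other_allele = oa, eaf = eaf,
       beta = beta, se = se)
}

test_that("palindromic detection covers complement pairs only", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("T", "A"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("C", "T"))
  expect_equal(isPalindromic(c("a", "c"), c("t", "a")), c(TRUE, FALSE))
})

test_that("alignRecord keeps, flips, strand-corrects and drops as specified", {
  # identical orientation
  r <- alignRecord(rec(), rec(beta = 0.05))
  expect_equal(r$action, "kept")
  expect_equal(r$by, 0.05)

  # swapped alleles: sign and frequency flip
  r <- alignRecord(rec(), rec(ea = "G", oa = "A", beta = 0.05, eaf = 0.3))
  expect_equal(r$action, "flipped")
  expect_equal(r$by, -0.05)
  expect_equal(r$eaf_y, 0.7)

  # other strand, same orientation after complement
  r <- alignRecord(rec(), rec(ea = "T", oa = "C", beta = 0.05))
  expect_equal(r$action, "kept")
  # other strand, swapped after complement
  r <- alignRecord(rec(), rec(ea = "C", oa = "T", beta = 0.05, eaf = 0.3))
  expect_equal(r$action, "flipped")

  # palindromic, ambiguous frequency: dropped
  r <- alignRecord(rec(ea = "A", oa = "T", eaf = 0.5),
                   rec(ea = "A", oa = "T", eaf = 0.5))
  expect_equal(r$action, "dropped_palindromic")
  # palindromic with missing frequency: dropped
  r <- alignRecord(rec(ea = "C", oa = "G", eaf = NA),
                   rec(ea = "C", oa = "G", eaf = 0.1))
  expect_equal(r$action, "dropped_palindromic")
  # palindromic, clear matching minor alleles: resolvable
  r <- alignRecord(rec(ea = "A", oa = "T", eaf = 0.1),
                   rec(ea = "A", oa = "T", eaf = 0.12, beta = 0.05))
  expect_equal(r$action, "kept")
  # palindromic, frequencies on opposite sides: flipped
  r <- alignRecord(rec(ea = "A", oa = "T", eaf = 0.1),
                   rec(ea = "A", oa = "T", eaf = 0.88, beta = 0.05))
  expect_equal(r$action, "flipped")
  expect_equal(r$by, -0.05)

  # irreconcilable allele sets
  r <- alignRecord(rec(), rec(ea = "A", oa = "C"))
  expect_equal(r$action, "dropped_mismatch")

  expect_error(alignRecord(rec(id = "rs1"), rec(id = "rs2")), "different SNPs")
})

test_that("harmonizeTables intersects tables, logs exclusions and conserves SNP count", {
  exp <- make_stats(n = 5, snp_id = sprintf("rs%d", 1:5), trait = "exp")
  out <- make_stats(n = 4, snp_id = sprintf("rs%d", 1:4), beta = 0.05,
                    trait = "out")
  h <- harmonizeTables(exp, out)
  expect_equal(nPairs(h), 4L)
  expect_equal(exclusionLog(h)$snp_id, "rs5")
  expect_equal(exclusionLog(h)$action, "dropped_absent")
  # conservation invariant
  expect_equal(nPairs(h) + nrow(exclusionLog(h)), nVariants(exp))
})

test_that("an all-ambiguous-palindromic exposure raises the empty-instrument error", {
  exp <- make_stats(n = 3, effect_allele = "A", other_allele = "T", eaf = 0.5)
  out <- make_stats(n = 3, effect_allele = "A", other_allele = "T", eaf = 0.5)
  expect_error(harmonizeTables(exp, out), "empty instrument")
})

test_that("double flip is the identity and harmonization is idempotent", {
  exp <- make_stats(n = 4, effect_allele = c("A", "C", "G", "T"),
                    other_allele = c("G", "A", "T", "C"),
                    beta = c(0.1, -0.2, 0.15, 0.08), trait = "exp")
  out_v <- variant_df(4, effect_allele = c("A", "C", "G", "T"),
                      other_allele = c("G", "A", "T", "C"),
                      beta = c(0.05, -0.1, 0.02, 0.04), eaf = 0.3)
  out <- summaryStats(out_v, "out")
  h1 <- harmonizedPairs(harmonizeTables(exp, out))

  # swap outcome alleles and negate its effects: alignment must recover h1
  sw <- out_v
  sw$effect_allele <- out_v$other_allele
  sw$other_allele <- out_v$effect_allele
  sw$beta <- -out_v$beta
  sw$eaf <- 1 - out_v$eaf
  h2 <- harmonizedPairs(harmonizeTables(exp, summaryStats(sw, "out")))
  expect_equal(h1$by, h2$by)
  expect_equal(h1$eaf_y, h2$eaf_y)

  # idempotence: re-harmonizing against an outcome built from the
  # harmonized output changes nothing
  back <- variant_df(4, effect_allele = variants(exp)$effect_allele,
                     other_allele = variants(exp)$other_allele,
                     beta = h1$by, eaf = h1$eaf_y)
  h3 <- harmonizedPairs(harmonizeTables(exp, summaryStats(back, "out")))
  expect_equal(h3$by, h1$by)
  expect_true(all(h3$action == "kept"))
})

test_that("generator tables with matched alleles harmonize to the full instrument count", {
  st <- simulateStudy(simulationConfig(J = 12, JMed = 0, seed = 31))
  h <- harmonizeTables(st@exposure, st@outcome)
  expect_equal(nPairs(h), 12L)
  expect_equal(nrow(exclusionLog(h)), 0L)
})

test_that("harmonized output and exclusion log write as TSV", {
  exp <- make_stats(n = 3, trait = "exp")
  out <- make_stats(n = 2, beta = 0.04, trait = "out")
  h <- harmonizeTables(exp, out)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeHarmonized(h, p1, p2)
  back <- utils::read.table(p1, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nPairs(h))
  expect_equal(nrow(utils::read.table(p2, header = TRUE, sep = "\t")), 1L)
})
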