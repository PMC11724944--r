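test_that("classifier thresholds must be ordered and positive", {
  expect_error(classifier_config(0, 1000), "sv_min_delta")
  expect_error(classifier_config(1000, 1000), "sv_min_delta")
  expect_silent(classifier_config(50, 1000))
})

test_that("length rules assign snv/mnv/indel/insertion/deletion classes", {
  # pure substitution
  snv <- classify_allele("A", "T")
  expect_equal(snv$variant_class, "snv")
  expect_equal(snv$delta, 0L)
  expect_false(snv$is_sv)
  # equal-length multi-base substitution
  expect_equal(classify_allele("ACG", "TGA")$variant_class, "mnv")
  # 119 bp contraction: SV by size, indel by the 1 kb categorization
  big_del <- classify_allele(strrep("A", 120), "A")
  expect_true(big_del$is_sv)
  expect_equal(big_del$variant_class, "indel")
  expect_equal(big_del$delta, -119L)
  # 1500 bp expansion: insertion proper
  ins <- classify_allele("A", paste0("A", strrep("GT", 750)))
  expect_true(ins$is_sv)
  expect_equal(ins$variant_class, "insertion")
  # 20 bp expansion: not an SV, still an indel
  small <- classify_allele("A", paste0("A", strrep("C", 20)))
  expect_false(small$is_sv)
  expect_equal(small$variant_class, "indel")
})

test_that("SV and indel boundaries are inclusive at 50 and exclusive below", {
  del_of <- function(n) classify_allele(paste0("A", strrep("C", n)), "A")
  ins_of <- function(n) classify_allele("A", paste0("A", strrep("C", n)))
  for (f in list(del_of, ins_of)) {
    expect_false(f(49)$is_sv)
    expect_true(f(50)$is_sv)
    expect_equal(f(999)$variant_class, "indel")
    expect_equal(f(1000)$variant_class,
                 if (f(1000)$delta > 0) "insertion" else "deletion")
  }
})

test_that("length change entangled with substitution is complex", {
  # anchor-trimming leaves >1 bp on both sides
  cx <- classify_allele("ATTTTG", "ACACACACACG")
  expect_equal(cx$variant_class, "complex")
  # but a clean anchored insertion stays pure
  expect_equal(classify_allele("AG", "ACCCG")$variant_class, "indel")
})

test_that("symbolic or non-nucleotide alleles are rejected", {
  expect_error(classify_allele("A", "<DEL>"), "ACGTN")
  expect_error(classify_allele("A", "A]chr1:123]"), "ACGTN")
})

test_that("per-sample extraction keeps carried records and trims alleles", {
  vcf <- write_text_vcf(c(
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t20\t.\tA\tT,ACCT\t.\tPASS\t.\tGT\t0/2\t1/1",
    "chr1\t30\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t0|1",
    "chr1\t40\t.\tT\tA,TGGG\t.\tPASS\t.\tGT\t1/2\t0/0"),
    samples = c("KLC", "OTHER"))

  klc <- extract_sample_variants(vcf, "KLC")
  expect_equal(klc$pos, c(20L, 40L))
  # 0/2 against ALT=[T,ACCT] trims to ALT=[ACCT] with genotype 0/1
  expect_equal(klc$alt[[1]], "ACCT")
  expect_equal(klc$gt[1], "0/1")
  # 1/2 keeps both alleles
  expect_equal(klc$alt[[2]], c("A", "TGGG"))
  expect_equal(klc$gt[2], "1/2")

  other <- extract_sample_variants(vcf, "OTHER")
  # homozygous reference and missing-only genotypes are dropped; phased kept
  expect_equal(other$pos, c(10L, 20L, 30L))
  expect_equal(other$gt[other$pos == 30L], "0|1")
})

test_that("unknown samples and malformed genotypes are handled loudly", {
  vcf <- write_text_vcf("chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\tbogus",
                        samples = "S1")
  expect_error(extract_sample_variants(vcf, "nope"), "S1")
  expect_warning(out <- extract_sample_variants(vcf, "S1"), "unparseable")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("exclusive mode keeps only variants private to the sample", {
  vcf <- write_text_vcf(c(
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t20\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0"),
    samples = c("KLC", "OTHER"))
  expect_equal(extract_sample_variants(vcf, "KLC")$pos, c(10L, 20L))
  expect_equal(extract_sample_variants(vcf, "KLC", exclusive = TRUE)$pos, 20L)
})

test_that("each carried allele yields exactly one classification", {
  vcf <- write_text_vcf(c(
    "chr1\t10\t.\tA\tT,ATTTT\t.\tPASS\t.\tGT\t1/2",
    sprintf("chr2\t5\t.\tA\t%s\t.\tPASS\t.\tGT\t0/1",
            paste0("A", strrep("G", 1200)))),
    samples = "S1")
  cls <- sv_classify_sample(vcf, "S1")
  expect_equal(nrow(cls), 3)
  expect_equal(sort(cls$variant_class), c("indel", "insertion", "snv"))

  # classifying the trimmed record equals classifying its carried allele
  rec <- extract_sample_variants(vcf, "S1")
  direct <- classify_allele(rec$ref[2], rec$alt[[2]])
  expect_equal(cls$variant_class[cls$chrom == "chr2"], direct$variant_class)
})

test_that("tallies partition variants by class and chromosome", {
  empty <- sv_tally(classify_sample_variants(
    structure(tibble::tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = list(),
                             gt = character()))))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_total"), 0L)

  classified <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    pos = 1:3, ref = "A", alt = "T",
    ref_len = 1L, alt_len = 1L, delta = 0L,
    variant_class = c("insertion", "insertion", "deletion"),
    is_sv = TRUE)
  t <- sv_tally(classified)
  g <- glance(t)
  expect_equal(g$insertion, 2)
  expect_equal(g$deletion, 1)
  expect_equal(sum(t$n), nrow(classified))
  expect_equal(t$n[t$chrom == "chr1" & t$variant_class == "insertion"], 2)
})

test_that("planted classes at the 49/50/999/1000 boundaries are recovered", {
  for (len in c(49L, 50L, 999L, 1000L)) {
    p <- sim_params(n_samples = 3, core_segment_count = 12,
                    unique_insertions_per_sample = 1,
                    unique_insertion_len = c(len, len),
                    shared_variant_count = 1, deletion_count = 1,
                    deletion_len = c(len, len), snv_count = 1,
                    seed = 100L + len)
    b <- generate_pangenome(p, withr::local_tempdir())
    pv <- b$truth$planted_variants
    for (s in c("S1", "S2")) {
      cls <- sv_classify_sample(b$vcf, s)
      carried <- pv[purrr::map_lgl(pv$carriers, ~ s %in% .x), ]
      expect_equal(nrow(cls), nrow(carried))
      expect_equal(sort(table(cls$variant_class)),
                   sort(table(carried$expected_class)))
      expect_equal(sum(cls$is_sv), sum(carried$expected_is_sv))
    }
  }
})
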