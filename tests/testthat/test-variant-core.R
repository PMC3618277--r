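test_that("classify_variant_type types every allele pair exactly once", {
  expect_identical(classify_variant_type("A", "G"), "snp")
  expect_identical(classify_variant_type("", "ACG"), "insertion")
  expect_identical(classify_variant_type("AC", ""), "deletion")
  expect_identical(classify_variant_type("ACGT", "TGCA"),
                   "block_substitution")
  ## shared affixes are ignored: CAG->CTG is a SNP, not a block
  expect_identical(classify_variant_type("CAG", "CTG"), "snp")
  expect_error(classify_variant_type("A", "N"), "invalid allele")
  expect_error(classify_variant_type("A", "A"), "identical")
  expect_error(classify_variant_type("", ""), "empty")

  set.seed(1)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    r <- paste(sample(bases, sample(0:4, 1L), replace = TRUE), collapse = "")
    a <- paste(sample(bases, sample(0:4, 1L), replace = TRUE), collapse = "")
    if (r == a || (nchar(r) + nchar(a)) == 0L) next
    vt <- classify_variant_type(r, a)
    expect_length(vt, 1L)
    expect_true(vt %in% c("snp", "insertion", "deletion",
                          "block_substitution"))
  }
})

test_that("is_transition distinguishes transitions from transversions", {
  expect_true(is_transition("A", "G"))
  expect_true(is_transition("C", "T"))
  expect_false(is_transition("A", "C"))
  expect_identical(is_transition(c("G", "T", "T"), c("A", "C", "G")),
                   c(TRUE, TRUE, FALSE))
  expect_error(is_transition("AC", "A"), "SNP")
})

test_that("normalization trims, left-aligns and is idempotent", {
  ref <- c(c1 = "CCAAAACC")
  v <- variant_table("c1", 5L, "A", "")
  n1 <- normalize_variants(v, ref)
  expect_identical(n1$start, 2L)        # homopolymer left shift
  expect_identical(n1$ref, "A")

  v2 <- variant_table("c1", 2L, "AAA", "ATA", vtype = "snp")
  n2 <- normalize_variants(v2, ref)
  expect_identical(n2$start, 3L)        # prefix/suffix trim
  expect_identical(n2$ref, "A")
  expect_identical(n2$alt, "T")

  expect_error(normalize_variants(variant_table("c1", 0L, "GG", "T"), ref),
               "reference-consistency")

  ## idempotence + haplotype preservation on random fixtures
  set.seed(2)
  for (i in 1:100) {
    fx <- random_cluster_fixture()
    ref_i <- c(c = fx$seq)
    one <- fx$calls[sample(nrow(fx$calls), 1L)]
    one[, variant_id := 1L]
    n1 <- normalize_variants(one, ref_i)
    n2 <- normalize_variants(n1, ref_i)
    expect_identical(n1[, .(start, ref, alt)], n2[, .(start, ref, alt)])
    expect_identical(
      oracle_apply(fx$seq, one$start, one$ref, one$alt),
      oracle_apply(fx$seq, n1$start, n1$ref, n1$alt))
  }
})

test_that("group_into_blocks follows the <2-reference-base rule", {
  ref <- c(c1 = "ACGTACGT")
  ## SNPs at 2 and 4 (one base between) merge into one block
  v <- variant_table("c1", c(2L, 4L), c("G", "A"), c("T", "G"))
  m <- group_into_blocks(v, ref)
  expect_identical(nrow(m), 1L)
  expect_identical(m$vtype, "block_substitution")
  expect_identical(m$ref, "GTA")
  expect_identical(m$alt, "TTG")
  expect_identical(m$n_block, 2L)

  ## SNPs at 2 and 5 (two bases between) stay separate
  v2 <- variant_table("c1", c(2L, 5L), c("G", "C"), c("T", "G"))
  m2 <- group_into_blocks(v2, ref)
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$vtype, c("snp", "snp"))

  ## SNP immediately followed by a 1-bp deletion: length-changing block
  v3 <- variant_table("c1", c(2L, 3L), c("G", "T"), c("T", ""))
  m3 <- group_into_blocks(v3, ref)
  expect_identical(nrow(m3), 1L)
  expect_identical(m3$ref, "GT")
  expect_identical(m3$alt, "T")
  expect_identical(m3$length_change, -1L)

  ## overlapping input is a conflict
  v4 <- variant_table("c1", c(2L, 3L), c("GTA", "T"), c("T", "A"))
  expect_error(group_into_blocks(v4, ref), "conflict")
})

test_that("block merging agrees with the brute-force scanner", {
  set.seed(3)
  for (i in 1:200) {
    fx <- random_cluster_fixture()
    ref <- c(c = fx$seq)
    m <- group_into_blocks(fx$calls, ref)
    o <- oracle_merge(as.data.frame(fx$calls), fx$seq)
    expect_identical(m$start, o$start)
    expect_identical(m$ref, o$ref)
    expect_identical(m$alt, o$alt)
    expect_identical(m$n_block, as.integer(o$n))
    ## lossless partition: same haplotype sequence, same primitive count
    expect_identical(
      oracle_apply(fx$seq, m$start, m$ref, m$alt),
      oracle_apply(fx$seq, fx$calls$start, fx$calls$ref, fx$calls$alt))
    expect_identical(sum(m$n_block), nrow(fx$calls))
  }
})

test_that("tstv_ratio counts transitions over transversions", {
  v <- variant_table("c", c(1L, 2L, 3L), c("A", "C", "A"),
                     c("G", "T", "C"))
  expect_equal(tstv_ratio(v), 2)
  expect_warning(r <- tstv_ratio(v[0]), "undefined")
  expect_true(is.na(r))
  all_ts <- variant_table("c", 1:2, c("A", "C"), c("G", "T"))
  expect_warning(r2 <- tstv_ratio(all_ts), "undefined")
  expect_true(is.na(r2))
})

test_that("tstv_ratio recovers a simulated transition probability", {
  set.seed(4)
  p <- 2.13 / 3.13
  n <- 10000L
  is_ts <- rbinom(n, 1L, p) == 1L
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  tsmap <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- ifelse(is_ts, tsmap[ref],
                vapply(ref, function(r)
                  sample(setdiff(c("A", "C", "G", "T"),
                                 c(r, tsmap[[r]])), 1L), character(1L)))
  v <- variant_table("c", seq_len(n), ref, alt)
  r <- tstv_ratio(v)
  ## 3-sigma binomial interval mapped through p/(1-p)
  se <- 3 * sqrt(p * (1 - p) / n)
  expect_gt(r, (p - se) / (1 - p + se))
  expect_lt(r, (p + se) / (1 - p - se))
})

test_that("het_hom_ratio handles the worked examples and edge cases", {
  g <- data.table(zygosity = c("het", "het", "hom"))
  expect_equal(het_hom_ratio(g), 2)
  expect_equal(het_hom_ratio(data.table(zygosity = c("hom", "hom"))), 0)
  expect_warning(r <- het_hom_ratio(data.table(zygosity = "het")),
                 "undefined")
  expect_true(is.na(r))
  ## hemizygous excluded
  expect_equal(het_hom_ratio(data.table(
    zygosity = c("het", "hom", "hemi", "hemi"))), 1)
})

test_that("maf_spectrum bins called-allele frequencies on (0, 0.5]", {
  v <- variant_table("c1", 1L, "A", "G")
  ## het in 1 of 4 diploid individuals: MAF 1/8 = 0.125
  g <- data.table(variant_id = 1L, individual = "i1", h1 = 1L, h2 = 0L)
  fake_inds <- data.table(individual = paste0("i", 1:4),
                          sex = "female")
  sp <- maf_spectrum(g, v, bin_edges = 0.05, individuals = fake_inds,
                     haploid_male_contigs = character(),
                     haploid_contigs = character())
  expect_identical(sp$count, c(0L, 1L))
  expect_equal(attr(sp, "maf"), 0.125)
  ## hom in every individual: monomorphic in practice, MAF 0, excluded
  g2 <- data.table(variant_id = 1L, individual = paste0("i", 1:4),
                   h1 = 1L, h2 = 1L)
  sp2 <- maf_spectrum(g2, v, bin_edges = 0.05, individuals = fake_inds,
                      haploid_male_contigs = character(),
                      haploid_contigs = character())
  expect_identical(sum(sp2$count), 0L)
  expect_error(maf_spectrum(g[0], v), "empty-input")
})

test_that("variant type counts partition every callset", {
  sim <- small_sim()
  expect_identical(
    sum(sim$truth$vtype == "snp") +
      sum(sim$truth$vtype %in% c("insertion", "deletion")) +
      sum(sim$truth$vtype == "block_substitution"),
    nrow(sim$truth))
})
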