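## a one-exon gene with CDS ATG GAA TAA, 5-bp UTRs on both sides
tiny_gene <- function(code = "1", cds = "ATGGAATAA") {
  seq <- paste0("TTTTT", cds, "GGGGG")
  list(
    reference = c(c1 = seq),
    tx = transcript_models("gA", "tA", "c1", "+",
                           list(0L), list(nchar(seq)),
                           5L, 5L + nchar(cds), code = code)
  )
}

test_that("locate_variants applies the region hierarchy over transcripts", {
  ## transcript A: single exon fully coding at [20, 40);
  ## transcript B: exons [0,12) and [60,80), so [12,60) is its intron
  seq <- paste(rep("ACGT", 25), collapse = "")
  ref <- c(c1 = seq)
  tx <- transcript_models(
    c("gA", "gB"), c("tA", "tB"), "c1", "+",
    list(c(20L), c(0L, 60L)), list(c(40L), c(12L, 80L)),
    c(20L, 0L), c(40L, 80L))
  pos <- c(25L, 13L, 58L, 30L, 95L)
  refs <- substring(seq, pos + 1L, pos + 1L)
  alts <- ifelse(refs == "A", "G", "A")
  v <- variant_table("c1", pos, refs, alts)
  loc <- locate_variants(v, tx)
  ## 25: cds of A beats intron of B
  expect_identical(loc$region_class[1L], "cds")
  ## 13: first two intronic bases of B's intron = splice donor (+ strand)
  expect_identical(loc$region_class[2L], "splice_donor")
  ## 58: last two intronic bases = splice acceptor
  expect_identical(loc$region_class[3L], "splice_acceptor")
  ## 30: cds of A beats intron of B
  expect_identical(loc$region_class[4L], "cds")
  ## 95: outside every transcript
  expect_identical(loc$region_class[5L], "intergenic")

  ## hierarchy idempotence: an added transcript contributing only a
  ## lower class at each position never changes the class; here gC's
  ## long intron [2, 98) underlies all four genic positions
  tx_extra <- rbind(tx, transcript_models(
    "gC", "tC", "c1", "+", list(c(0L, 98L)), list(c(2L, 100L)),
    0L, 100L), fill = TRUE)
  loc2 <- locate_variants(v, tx_extra)
  expect_identical(loc$region_class[1:4], loc2$region_class[1:4])
  ## ... while a previously intergenic position is lifted to intron
  expect_identical(loc2$region_class[5L], "intron")
})

test_that("coding_effect translates SNPs through the genetic code", {
  g <- tiny_gene()
  eff <- function(pos, ref, alt) {
    coding_effect(variant_table("c1", pos, ref, alt), g$tx, g$reference)
  }
  expect_identical(eff(8L, "G", "A"), "missense")   # GAA -> AAA (E -> K)
  expect_identical(eff(8L, "G", "T"), "nonsense")   # GAA -> TAA
  expect_identical(eff(11L, "T", "C"), "nonstop")   # TAA -> CAA
  expect_identical(eff(10L, "A", "G"), "synonymous")# GAA -> GAG (E -> E)
})

test_that("coding indels follow the 3n frameshift rule", {
  g <- tiny_gene(cds = "ATGGAAGAAGAATAA")
  del2 <- variant_table("c1", 8L, substr(g$reference, 9L, 10L), "",
                        vtype = "deletion")
  del3 <- variant_table("c1", 8L, substr(g$reference, 9L, 11L), "",
                        vtype = "deletion")
  expect_identical(coding_effect(del2, g$tx, g$reference), "frameshift")
  expect_identical(coding_effect(del3, g$tx, g$reference),
                   "frameshift_preserving")
  ins1 <- variant_table("c1", 9L, "", "T")
  expect_identical(coding_effect(ins1, g$tx, g$reference), "frameshift")
})

test_that("length-conserving blocks are translated codon-wise", {
  g <- tiny_gene(cds = "ATGCTAGAATAA")   # codon2 CTA (Leu)
  ## CTA -> TTG: two mismatching columns, still Leu
  blk <- variant_table("c1", 8L, "CTA", "TTG")
  expect_identical(blk$vtype, "block_substitution")
  expect_identical(coding_effect(blk, g$tx, g$reference), "synonymous")
  ## CTA -> TAA would be nonsense but shares no 2-mismatch need; use GAA
  blk2 <- variant_table("c1", 8L, "CTA", "AGA")  # Leu -> Arg
  expect_identical(coding_effect(blk2, g$tx, g$reference), "missense")
})

test_that("minus-strand annotation equals the mirrored plus-strand one", {
  g <- tiny_gene(cds = "ATGGAACTAGGGTAA")
  L <- nchar(g$reference[["c1"]])
  refM <- c(c1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      g$reference[["c1"]]))))
  cds_len <- 15L
  txM <- transcript_models("gA", "tA", "c1", "-",
                           list(0L), list(L),
                           L - 5L - cds_len, L - 5L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(5)
  for (i in 1:20) {
    p <- sample(5:(5L + cds_len - 1L), 1L)
    r <- substr(g$reference[["c1"]], p + 1L, p + 1L)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    e_plus <- coding_effect(variant_table("c1", p, r, a), g$tx,
                            g$reference)
    pm <- L - 1L - p
    e_minus <- coding_effect(
      variant_table("c1", pm, comp[[r]], comp[[a]]), txM, refM)
    expect_identical(e_minus, e_plus)
  }
})

test_that("the mitochondrial code changes stop-codon calls", {
  ## codon2 TGG (Trp); G->A gives TGA: stop in the nuclear code,
  ## tryptophan in the vertebrate mitochondrial code
  gn <- tiny_gene(code = "1", cds = "ATGTGGTAA")
  gm <- tiny_gene(code = "2", cds = "ATGTGGTAA")
  v <- variant_table("c1", 10L, "G", "A")
  expect_identical(coding_effect(v, gn$tx, gn$reference), "nonsense")
  expect_identical(coding_effect(v, gm$tx, gm$reference), "synonymous")
})

test_that("is_lof covers stop gain/loss, frameshift and splice sites", {
  expect_true(is_lof("cds", "nonsense"))
  expect_true(is_lof("cds", "nonstop"))
  expect_true(is_lof("cds", "frameshift"))
  expect_true(is_lof("splice_donor", "none"))
  expect_true(is_lof("splice_acceptor", "none"))
  expect_false(is_lof("cds", "synonymous"))
  expect_false(is_lof("cds", "missense"))
  expect_false(is_lof("cds", "frameshift_preserving"))
  expect_false(is_lof("intron", "none"))
})

test_that("annotate_cohort partitions match the taxonomy structure", {
  sim <- small_sim()
  v <- data.table::copy(sim$truth)[, variant_id := tvid]
  g <- data.table::copy(sim$truth_genotypes)
  data.table::setnames(g, "tvid", "variant_id")
  ann <- annotate_cohort(v, g, sim$transcripts, sim$reference)
  s <- ann$summary
  get <- function(cl, cat) s[variant_class == cl & category == cat,
                             n_distinct]
  ## region partition: total = intergenic + intragenic
  for (cl in c("snp", "indel", "block_substitution")) {
    expect_equal(get(cl, "total"),
                 get(cl, "intergenic") + get(cl, "intragenic"))
    expect_equal(get(cl, "intragenic"),
                 get(cl, "intron") + get(cl, "utr") + get(cl, "coding") +
                   get(cl, "splice_donor") + get(cl, "splice_acceptor"))
  }
  ## coding SNP effects partition the coding SNP count
  expect_equal(get("snp", "coding"),
               get("snp", "synonymous") + get("snp", "non_synonymous"))
  expect_equal(get("snp", "non_synonymous"),
               get("snp", "missense") + get("snp", "nonsense") +
                 get("snp", "nonstop"))
  ## coding indels split into frameshift vs frameshift-preserving
  expect_equal(get("indel", "coding"),
               get("indel", "frameshift") +
                 get("indel", "frameshift_preserving"))
  ## single-genome worked example: 3 SNPs, one cds one intron one
  ## intergenic -> intragenic 2, total 3
  expect_gte(get("snp", "coding"), 1)
})
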