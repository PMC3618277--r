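test_that("lof_burden counts total and homozygous LoF per genome", {
  ann <- data.table(variant_id = 1:4,
                    is_lof = c(TRUE, TRUE, TRUE, FALSE))
  g <- data.table(
    variant_id = c(1L, 2L, 3L, 4L, 1L),
    individual = c("a", "a", "a", "a", "b"),
    zygosity = c("het", "hom", "hom", "hom", "hemi"))
  b <- lof_burden(ann, g)
  expect_identical(b$per_genome[individual == "a", n_lof], 3L)
  expect_identical(b$per_genome[individual == "a", n_hom_lof], 2L)
  ## hemizygous counts as homozygous for knockout logic
  expect_identical(b$per_genome[individual == "b", n_hom_lof], 1L)
  expect_equal(b$mean_lof, 2)
  g0 <- data.table(variant_id = 4L, individual = "c", zygosity = "het")
  expect_identical(lof_burden(ann, g0)$per_genome$n_lof, 0L)
})

test_that("knockout_spectrum requires homozygous or hemizygous LoF", {
  ge <- data.table(variant_id = c(1L, 2L, 3L),
                   gene_id = c("G", "G", "H"),
                   region_class = "cds",
                   coding_effect = c("nonsense", "nonsense", "frameshift"),
                   vtype = "snp",
                   is_lof = TRUE)
  g <- data.table(
    variant_id = c(1L, 1L, 2L, 3L),
    individual = c("i1", "i2", "i3", "i1"),
    zygosity = c("hom", "hom", "het", "hemi"))
  ko <- knockout_spectrum(ge, g, n_individuals = 3L)
  expect_identical(ko$genes[gene_id == "G", n_genomes], 2L)
  ## het-only carrier i3 does not knock out G
  expect_identical(nrow(ko$genes), 2L)
  ## hemizygous male X call counts
  expect_identical(ko$genes[gene_id == "H", n_genomes], 1L)
  ## histogram total = number of distinct knocked-out genes
  expect_identical(sum(ko$histogram$n_genes), nrow(ko$genes))
  expect_identical(ko$histogram[occurrence == 2L, n_genes], 1L)

  ## monotonicity: adding a genome never decreases a count
  g2 <- rbind(g, data.table(variant_id = 2L, individual = "i4",
                            zygosity = "hom"))
  ko2 <- knockout_spectrum(ge, g2, n_individuals = 4L)
  m <- merge(ko$genes, ko2$genes, by = "gene_id")
  expect_true(all(m$n_genomes.y >= m$n_genomes.x))

  expect_identical(nrow(common_knockouts(ko, 0.3)), 2L)
  expect_identical(nrow(common_knockouts(ko, 0.65)), 1L)  # 2/3 > 0.65
  expect_identical(nrow(common_knockouts(ko, 0.7)), 0L)
})

test_that("gene ranking uses density, then count, then CDS length", {
  ## gene Y (3/600 = 0.005) outranks X (4/1000 = 0.004)
  mk_tx <- function(genes, lens) {
    transcript_models(genes, paste0("t_", genes), "c1", "+",
                      lapply(seq_along(lens), function(i)
                        (i - 1L) * 5000L),
                      lapply(seq_along(lens), function(i)
                        (i - 1L) * 5000L + lens[i]),
                      (seq_along(lens) - 1L) * 5000L,
                      (seq_along(lens) - 1L) * 5000L + lens)
  }
  ge <- data.table(
    variant_id = 1:7,
    gene_id = c(rep("X", 4L), rep("Y", 3L)),
    region_class = "cds",
    coding_effect = "missense",
    vtype = "snp",
    is_lof = FALSE)
  tx <- mk_tx(c("X", "Y"), c(1000L, 600L))
  r <- rank_genes_by_deleterious_density(ge, tx)
  expect_identical(r$gene_id, c("Y", "X"))

  ## equal density: higher count first
  ge2 <- data.table(variant_id = 1:15,
                    gene_id = c(rep("A", 10L), rep("B", 5L)),
                    region_class = "cds", coding_effect = "missense",
                    vtype = "snp", is_lof = FALSE)
  tx2 <- mk_tx(c("A", "B"), c(2000L, 1000L))
  r2 <- rank_genes_by_deleterious_density(ge2, tx2)
  expect_identical(r2$gene_id, c("A", "B"))

  ## only amino-acid-changing variants count: synonymous and
  ## frameshift-preserving are ignored, frameshift indels included
  ge3 <- data.table(variant_id = 1:4, gene_id = "A",
                    region_class = "cds",
                    coding_effect = c("synonymous", "missense",
                                      "frameshift_preserving",
                                      "frameshift"),
                    vtype = c("snp", "snp", "deletion", "deletion"),
                    is_lof = c(FALSE, FALSE, FALSE, TRUE))
  r3 <- rank_genes_by_deleterious_density(ge3, mk_tx("A", 999L))
  expect_identical(r3$deleterious, 2L)
})

test_that("ranking matches an independent three-key sort on random genes", {
  set.seed(6)
  n <- 500L
  lens <- sample(c(300L, 600L, 900L), n, replace = TRUE)
  counts <- sample(0:6, n, replace = TRUE)
  genes <- sprintf("g%04d", sample(n))
  tx <- transcript_models(genes, paste0("t", genes), "c1", "+",
                          as.list((seq_len(n) - 1L) * 2000L),
                          as.list((seq_len(n) - 1L) * 2000L + lens),
                          (seq_len(n) - 1L) * 2000L,
                          (seq_len(n) - 1L) * 2000L + lens)
  ge <- data.table(
    variant_id = seq_len(sum(counts)),
    gene_id = rep(genes, counts),
    region_class = "cds", coding_effect = "missense", vtype = "snp",
    is_lof = FALSE)
  r <- rank_genes_by_deleterious_density(ge, tx)
  o <- oracle_rank(data.frame(gene_id = genes, deleterious = counts,
                              cds_len = lens,
                              density = counts / lens))
  expect_identical(r$gene_id, o$gene_id)
})

test_that("array_concordance stratifies by array zygosity", {
  arr <- data.table(contig = "c1", start = 1:4, ref = "A", alt = "G",
                    dosage = c(2L, 1L, 1L, 0L))
  seq_gt <- data.table(contig = "c1", start = 1:3, ref = "A", alt = "G",
                       dosage = c(2L, 1L, 0L))
  r <- array_concordance(seq_gt, arr)
  expect_equal(r$call_rate, 0.75)
  expect_equal(r$concordance_hom, 1)
  expect_equal(r$concordance_het, 0.5)

  ## identity
  r2 <- array_concordance(arr, arr)
  expect_equal(unlist(r2[c("call_rate", "concordance_hom",
                           "concordance_het")]),
               c(call_rate = 1, concordance_hom = 1, concordance_het = 1))

  ## swapped alleles are flipped, foreign alleles audited out
  arr3 <- data.table(contig = "c1", start = 1:2,
                     ref = c("G", "T"), alt = c("A", "C"),
                     dosage = c(0L, 1L))
  seq3 <- data.table(contig = "c1", start = 1:2,
                     ref = c("A", "A"), alt = c("G", "G"),
                     dosage = c(2L, 1L))
  r3 <- array_concordance(seq3, arr3)
  expect_equal(r3$concordance_hom, 1)   # site 1: swapped, 2 -> 0 matches
  expect_identical(r3$n_excluded, 1L)   # site 2: incompatible alleles
})

test_that("planted array discordance is recovered", {
  sim <- small_sim()
  ar <- simulate_array(sim, "ind01", n_sites = 400L,
                       het_discordance = 0.05, hom_discordance = 0,
                       miss_rate = 0.02, seed = 9L)
  r <- array_concordance(ar$seq_gt, ar$array_gt)
  expect_gt(r$call_rate, 0.9)
  expect_equal(r$concordance_hom, 1)
  n_het <- sum(ar$array_gt$dosage == 1L)
  expect_lt(abs(r$concordance_het - 0.95),
            3 * sqrt(0.05 * 0.95 / max(n_het, 1L)) + 0.02)
})
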