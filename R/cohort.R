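## per-genome and cross-genome gene-level analyses

#' Per-genome loss-of-function burden
#'
#' Counts, per individual, the carried LoF variants in total and those in
#' homozygous (or hemizygous) state, plus cohort means.
#'
#' @param annotations annotated variant table (with `is_lof`).
#' @param genotypes long genotype table (`variant_id`, `individual`,
#'   `zygosity`).
#' @return list with `per_genome` (`individual`, `n_lof`, `n_hom_lof`)
#'   and `mean_lof` / `mean_hom_lof`.
#' @export
lof_burden <- function(annotations, genotypes) {
  lofv <- annotations[is_lof == TRUE, variant_id]
  g <- genotypes[zygosity != "ref"]
  per <- g[, .(
    n_lof = sum(variant_id %in% lofv),
    n_hom_lof = sum(variant_id %in% lofv & zygosity %in% c("hom", "hemi"))
  ), by = individual]
  list(per_genome = per[order(individual)],
       mean_lof = mean(per$n_lof),
       mean_hom_lof = mean(per$n_hom_lof))
}

#' Knocked-out genes across a cohort
#'
#' A gene is knocked out in an individual when that individual carries at
#' least one homozygous (or hemizygous) LoF variant in the gene;
#' heterozygous LoF, including compound heterozygotes, does not count.
#'
#' @param gene_effects per-(variant, gene) effect table (attribute of
#'   [annotate_variants()]).
#' @param genotypes long genotype table.
#' @param n_individuals cohort size (for the occurrence histogram).
#' @return object of class `knockout_report`: `genes`
#'   (`gene_id`, `n_genomes`), `histogram` (occurrence count 1..N ->
#'   number of genes), `n_individuals`.
#' @export
knockout_spectrum <- function(gene_effects, genotypes, n_individuals) {
  lofg <- gene_effects[is_lof == TRUE, .(variant_id, gene_id)]
  hom <- genotypes[zygosity %in% c("hom", "hemi"),
                   .(variant_id, individual)]
  ko <- unique(merge(lofg, hom, by = "variant_id",
                     allow.cartesian = TRUE)[, .(gene_id, individual)])
  genes <- ko[, .(n_genomes = .N), by = gene_id][order(-n_genomes, gene_id)]
  histogram <- data.table(occurrence = seq_len(n_individuals),
                          n_genes = tabulate(genes$n_genomes,
                                             nbins = n_individuals))
  structure(list(genes = genes, histogram = histogram,
                 n_individuals = n_individuals),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("knockout report:", nrow(x$genes), "genes knocked out in >=1 of",
      x$n_individuals, "genomes\n")
  print(head(x$genes, 10L))
  invisible(x)
}

#' Genes knocked out in more than a given fraction of the cohort
#'
#' @param report a [knockout_spectrum()] result.
#' @param threshold cohort fraction (default 0.30).
#' @return subset of `report$genes`.
#' @export
common_knockouts <- function(report, threshold = 0.30) {
  report$genes[n_genomes > threshold * report$n_individuals]
}

#' Rank genes by deleterious-variant density
#'
#' Deleterious variants are amino-acid-changing: non-synonymous SNPs
#' (missense, nonsense, nonstop) and frameshift indels/block
#' substitutions.  Density is the number of distinct deleterious variants
#' in a gene divided by the summed CDS length of its transcripts.  Genes
#' are sorted by descending density, then descending count, then
#' descending CDS length, then gene id (deterministic).
#'
#' @param gene_effects per-(variant, gene) effect table.
#' @param transcripts transcript-model table.
#' @return `data.table` (`gene_id`, `deleterious`, `cds_len`, `density`),
#'   ranked; genes with zero CDS length are dropped with a warning.
#' @export
rank_genes_by_deleterious_density <- function(gene_effects, transcripts) {
  del <- gene_effects[
    (vtype == "snp" &
       coding_effect %in% c("missense", "nonsense", "nonstop")) |
      coding_effect == "frameshift",
    .(deleterious = uniqueN(variant_id)), by = gene_id]
  lens <- gene_cds_lengths(transcripts)
  g <- merge(lens, del, by = "gene_id", all.x = TRUE)
  g[is.na(deleterious), deleterious := 0L]
  if (any(g$cds_len == 0L)) {
    warning(sum(g$cds_len == 0L), " genes with zero CDS length excluded")
    g <- g[cds_len > 0L]
  }
  g[, density := deleterious / cds_len]
  setorder(g, -density, -deleterious, -cds_len, gene_id)
  setcolorder(g, c("gene_id", "deleterious", "cds_len", "density"))
  g[]
}

#' Sequencing vs array genotype concordance
#'
#' Sites are matched on contig+position.  A site with identical ref/alt
#' alleles is compared directly; with swapped alleles the array dosage is
#' flipped; any other allele combination (e.g. strand mismatch) is
#' excluded and counted in the audit.  Dosage is the alternate-allele
#' count (0/1/2).
#'
#' @param seq_gt sequencing genotypes: `contig`, `start`, `ref`, `alt`,
#'   `dosage` (`NA` = not called).
#' @param array_gt array genotypes, same columns.
#' @return list with `call_rate`, `concordance_hom`, `concordance_het`,
#'   `n_excluded`.
#' @export
array_concordance <- function(seq_gt, array_gt) {
  m <- merge(array_gt, seq_gt, by = c("contig", "start"),
             suffixes = c("_arr", "_seq"), all.x = TRUE)
  called <- !is.na(m$dosage_seq)
  same <- called & m$ref_arr == m$ref_seq & m$alt_arr == m$alt_seq
  swapped <- called & m$ref_arr == m$alt_seq & m$alt_arr == m$ref_seq
  excluded <- called & !(same | swapped)
  d_arr <- m$dosage_arr
  d_seq <- fifelse(swapped, 2L - m$dosage_seq, m$dosage_seq)
  use <- (same | swapped)
  hom <- use & d_arr %in% c(0L, 2L)
  het <- use & d_arr == 1L
  list(call_rate = mean(called),
       concordance_hom = if (any(hom)) mean(d_seq[hom] == d_arr[hom])
                         else NA_real_,
       concordance_het = if (any(het)) mean(d_seq[het] == d_arr[het])
                         else NA_real_,
       n_excluded = sum(excluded))
}
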