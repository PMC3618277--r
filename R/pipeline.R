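## end-to-end cohort pipeline: read -> normalize -> merge -> annotate

#' Read per-individual VCFs into a cohort
#'
#' @param paths named character vector of VCF paths (names = individual
#'   ids; unnamed paths use the file stem).
#' @return list with `variants` (distinct calls) and `genotypes` (long,
#'   per individual).
#' @export
read_cohort_vcfs <- function(paths) {
  ids <- names(paths) %||% rep("", length(paths))
  ids[ids == ""] <- sub("\\.vcf$", "", basename(paths[ids == ""]))
  per <- lapply(seq_along(paths), function(i) {
    v <- read_vcf(paths[[i]])
    v[, individual := ids[i]]
    v
  })
  all <- rbindlist(per, fill = TRUE)
  distinct <- unique(all[, .(contig, start, ref, alt, vtype, length_change,
                             n_block)])
  setorder(distinct, contig, start, ref, alt)
  distinct[, variant_id := .I]
  setcolorder(distinct, "variant_id")
  g <- merge(all[, .(contig, start, ref, alt, individual, h1, h2,
                     zygosity, phased)],
             distinct[, .(variant_id, contig, start, ref, alt)],
             by = c("contig", "start", "ref", "alt"))
  list(variants = distinct,
       genotypes = g[, .(variant_id, individual, h1, h2, zygosity, phased)])
}

## re-key a cohort after variant coordinates changed (normalization/merging)
rekey_cohort <- function(variants, genotypes, map) {
  ## map: old variant_id -> (contig, start, ref, alt, ...) new rows
  distinct <- unique(map[, .(contig, start, ref, alt, vtype, length_change,
                             n_block)])
  setorder(distinct, contig, start, ref, alt)
  distinct[, variant_id := .I]
  g <- merge(genotypes, map[, .(old_id, contig, start, ref, alt)],
             by.x = "variant_id", by.y = "old_id")
  g <- merge(g, distinct[, .(variant_id, contig, start, ref, alt)],
             by = c("contig", "start", "ref", "alt"),
             suffixes = c("_old", ""))
  list(variants = distinct[],
       genotypes = g[, .(variant_id, individual, h1, h2, zygosity, phased)])
}

#' Merge proximal variants into block substitutions across a cohort
#'
#' Applies the <2-reference-base merging rule per individual and per
#' haplotype.  Heterozygous variants without phase are left unmerged
#' with a warning (merging across unknown phase would fabricate
#' haplotypes); homozygous clusters always merge.
#'
#' @param variants distinct normalized variant table.
#' @param genotypes long genotype table (`h1`, `h2`, `phased`).
#' @param reference named character vector of contig sequences.
#' @return list with merged `variants` and `genotypes`.
#' @export
merge_cohort_blocks <- function(variants, genotypes, reference) {
  if (!"phased" %in% names(genotypes)) genotypes[, phased := TRUE]
  unph <- genotypes[phased == FALSE & zygosity == "het"]
  if (nrow(unph)) {
    warning(nrow(unph), " unphased heterozygous calls left unmerged")
  }
  g <- merge(genotypes,
             variants[, .(variant_id, contig, start, ref, alt, vtype,
                          n_block)],
             by = "variant_id")
  out_rows <- list()
  for (ind in unique(g$individual)) {
    gi <- g[individual == ind]
    mergeable <- gi$phased | gi$zygosity %in% c("hom", "hemi")
    hap_calls <- list()
    for (hap in 1:2) {
      carried <- if (hap == 1L) gi$h1 == 1L else (!is.na(gi$h2) & gi$h2 == 1L)
      hk <- gi[carried & mergeable]
      if (!nrow(hk)) {
        hap_calls[[hap]] <- data.table()
        next
      }
      m <- group_into_blocks(
        hk[, .(contig, start, ref, alt, vtype, n_block)], reference)
      m[, hap := hap]
      hap_calls[[hap]] <- m
    }
    hc <- rbindlist(hap_calls, fill = TRUE)
    keep_sep <- gi[!mergeable]
    if (nrow(hc)) {
      combined <- hc[, .(h1 = as.integer(any(hap == 1L)),
                         h2raw = as.integer(any(hap == 2L)),
                         vtype = vtype[1L], n_block = max(n_block)),
                     by = .(contig, start, ref, alt)]
      ## restore NA second haplotype on haploid loci
      hap2_known <- gi[, any(!is.na(h2)), by = contig]
      combined <- merge(combined, hap2_known, by = "contig")
      combined[, h2 := fifelse(V1, h2raw, NA_integer_)]
      combined[, h2raw := NULL]
      combined[, individual := ind]
      out_rows[[length(out_rows) + 1L]] <- combined
    }
    if (nrow(keep_sep)) {
      out_rows[[length(out_rows) + 1L]] <-
        keep_sep[, .(contig, start, ref, alt, vtype, n_block, h1, h2,
                     individual)]
    }
  }
  longd <- rbindlist(out_rows, fill = TRUE, use.names = TRUE)
  longd[, length_change := nchar(alt) - nchar(ref)]
  distinct <- unique(longd[, .(contig, start, ref, alt, vtype,
                               length_change)])
  nb <- longd[, .(n_block = max(n_block)), by = .(contig, start, ref, alt)]
  distinct <- merge(distinct, nb, by = c("contig", "start", "ref", "alt"))
  setorder(distinct, contig, start, ref, alt)
  distinct[, variant_id := .I]
  setcolorder(distinct, "variant_id")
  gout <- merge(longd, distinct[, .(variant_id, contig, start, ref, alt)],
                by = c("contig", "start", "ref", "alt"))
  gout[, zygosity := zygosity_of(h1, h2)]
  gout[, phased := TRUE]
  list(variants = distinct[],
       genotypes = gout[, .(variant_id, individual, h1, h2, zygosity,
                            phased)])
}

#' Characterize a cohort end-to-end
#'
#' Normalizes the calls, merges proximal variants per haplotype into
#' block substitutions, annotates against the transcript models and
#' summarizes: taxonomy table, Ts/Tv, het/hom, MAF spectrum, LoF burden,
#' knockout spectrum and deleterious-density gene ranking; optionally a
#' catalog Venn partition.
#'
#' @param cohort list with `variants` and `genotypes`
#'   (e.g. [read_cohort_vcfs()]).
#' @param transcripts transcript-model table.
#' @param reference named character vector of contig sequences.
#' @param catalogs optional named list of two [build_catalog()] objects
#'   for the Venn partition.
#' @param window indel match window for catalogs (bp).
#' @return list of results (class `cohort_report`).
#' @export
characterize_cohort <- function(cohort, transcripts, reference,
                                catalogs = NULL, window = 25L) {
  ## trim anchors/shared bases first, merge haplotype-wise, and only then
  ## left-align: shifting before merging can slide an indel into a
  ## neighbour it belongs with
  v <- normalize_variants(cohort$variants, reference, shift = FALSE)
  map <- copy(v)[, old_id := cohort$variants$variant_id]
  ck <- rekey_cohort(v, cohort$genotypes, map)
  merged0 <- merge_cohort_blocks(ck$variants, ck$genotypes, reference)
  v2 <- normalize_variants(merged0$variants, reference)
  map2 <- copy(v2)[, old_id := merged0$variants$variant_id]
  merged <- rekey_cohort(v2, merged0$genotypes, map2)
  ann <- annotate_cohort(merged$variants, merged$genotypes, transcripts,
                         reference)
  burden <- lof_burden(ann$annotations, merged$genotypes)
  ko <- knockout_spectrum(ann$gene_effects, merged$genotypes,
                          length(unique(merged$genotypes$individual)))
  ranked <- rank_genes_by_deleterious_density(ann$gene_effects, transcripts)
  venn <- if (!is.null(catalogs)) {
    venn_partition(merged$variants, catalogs[[1L]], catalogs[[2L]], window)
  }
  structure(list(
    variants = merged$variants,
    genotypes = merged$genotypes,
    annotation = ann,
    tstv = tstv_ratio(merged$variants[variant_id %in%
      merged$genotypes$variant_id]),
    het_hom = het_hom_ratio(merged$genotypes),
    maf = maf_spectrum(merged$genotypes, merged$variants),
    lof = burden,
    knockouts = ko,
    ranked_genes = ranked,
    venn = venn
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort report:", nrow(x$variants), "distinct variants\n")
  cat(sprintf("  Ts/Tv %.3f | het/hom %.3f | mean LoF/genome %.1f (hom %.1f)\n",
              x$tstv, x$het_hom, x$lof$mean_lof, x$lof$mean_hom_lof))
  cat(" ", nrow(x$knockouts$genes), "knocked-out genes\n")
  invisible(x)
}
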