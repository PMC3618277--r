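## hierarchical functional annotation and coding-effect prediction

variant_span <- function(variants) {
  ## insertions occupy the base to the right of the insertion point
  v <- copy(variants)
  v[, `:=`(fs = start, fe = start + pmax(nchar(ref), 1L))]
  v[]
}

#' Locate variants in the region hierarchy
#'
#' Each variant receives the single highest region class it touches over
#' all overlapping transcripts, under the hierarchy
#' CDS > UTR > splice site > intron > intergenic.  Variants overlapping no
#' transcript are `intergenic`.
#'
#' @param variants variant table.
#' @param transcripts transcript-model table.
#' @return `data.table` with `variant_id`, `region_class` and a
#'   `gene_hits` attribute: per (variant, gene) best class.
#' @export
locate_variants <- function(variants, transcripts) {
  feats <- feature_table(transcripts)
  v <- variant_span(variants)[, .(variant_id, contig, fs, fe)]
  setkey(feats, contig, fs, fe)
  ov <- foverlaps(setkey(copy(v), contig, fs, fe), feats,
                  type = "any", nomatch = NULL)
  ## half-open intervals: discard touch-only overlaps kept by foverlaps
  ov <- ov[i.fs < fe & fs < i.fe]
  best <- ov[, .(priority = max(priority)), by = variant_id]
  out <- data.table(variant_id = variants$variant_id)
  out <- merge(out, best, by = "variant_id", all.x = TRUE)
  out[is.na(priority), priority := 0L]
  prio_class <- setNames(names(REGION_PRIORITY), REGION_PRIORITY)
  out[, region_class := prio_class[as.character(priority)]]
  out[, priority := NULL]
  gene_hits <- ov[, .(priority = max(priority)),
                  by = .(variant_id, gene_id)]
  gene_hits[, region_class := prio_class[as.character(priority)]]
  setattr(out, "gene_hits", gene_hits[])
  out[]
}

## coding effect of one variant against one transcript.
## `map` is cds_map(transcript, reference).
coding_effect_one <- function(variant, transcript, map) {
  lc <- nchar(variant$alt) - nchar(variant$ref)
  if (lc != 0L) {
    return(if (abs(lc) %% 3L != 0L) "frameshift" else "frameshift_preserving")
  }
  plus <- transcript$strand == "+"
  positions <- seq(variant$start, variant$start + nchar(variant$ref) - 1L)
  idx <- match(positions, map$pos)
  if (anyNA(idx)) {
    ## length-conserving variant partially outside the CDS: treated as a
    ## coding disruption without frame change
    return("missense")
  }
  a <- strsplit(variant$alt, "", fixed = TRUE)[[1L]]
  if (!plus) a <- complement_base(a)
  new_bases <- map$bases
  new_bases[idx] <- a
  cod <- sort(unique((idx - 1L) %/% 3L))
  old_aa <- translate_codons(vapply(cod, function(c0)
    paste(map$bases[c0 * 3L + 1:3], collapse = ""), character(1L)),
    transcript$code)
  new_aa <- translate_codons(vapply(cod, function(c0)
    paste(new_bases[c0 * 3L + 1:3], collapse = ""), character(1L)),
    transcript$code)
  if (any(new_aa == "*" & old_aa != "*")) "nonsense"
  else if (any(old_aa == "*" & new_aa != "*")) "nonstop"
  else if (any(old_aa != new_aa)) "missense"
  else "synonymous"
}

#' Coding effect of a variant in one transcript
#'
#' SNPs and length-conserving block substitutions are applied to the
#' spliced CDS and translated (minus-strand transcripts on the reverse
#' complement); indels and length-changing blocks follow the 3n rule:
#' `frameshift` iff `|length_change| %% 3 != 0`, else
#' `frameshift_preserving`.
#'
#' @param variant one-row variant table (must be coding in `transcript`).
#' @param transcript one-row transcript-model table.
#' @param reference named character vector of contig sequences.
#' @return one of the coding-effect labels.
#' @export
coding_effect <- function(variant, transcript, reference) {
  coding_effect_one(variant, transcript, cds_map(transcript, reference))
}

#' Loss-of-function predicate
#'
#' A variant is LoF when it creates or disrupts a stop codon (`nonsense`,
#' `nonstop`), shifts the reading frame (`frameshift`), or falls in a
#' splice donor/acceptor site.
#'
#' @param region_class,coding_effect annotation labels (vectorized).
#' @return logical vector.
#' @export
is_lof <- function(region_class, coding_effect) {
  coding_effect %in% c("nonsense", "nonstop", "frameshift") |
    region_class %in% c("splice_donor", "splice_acceptor")
}

#' Annotate variants against transcript models
#'
#' Combines [locate_variants()] with per-transcript coding effects.  When
#' a variant is coding in several transcripts, the most severe effect is
#' kept (frameshift > nonsense > nonstop > missense >
#' frameshift_preserving > synonymous).
#'
#' @param variants variant table.
#' @param transcripts transcript-model table.
#' @param reference named character vector of contig sequences.
#' @return annotated variant table (adds `region_class`, `coding_effect`,
#'   `genes`, `is_lof`) with attribute `"gene_effects"`: one row per
#'   (variant, gene) with that gene's own class/effect/LoF call.
#' @export
annotate_variants <- function(variants, transcripts, reference) {
  variants <- copy(variants)
  stale <- intersect(names(variants),
                     c("region_class", "coding_effect", "genes", "is_lof"))
  if (length(stale)) variants[, (stale) := NULL]
  loc <- locate_variants(variants, transcripts)
  gene_hits <- attr(loc, "gene_hits")
  ann <- merge(copy(variants), loc, by = "variant_id")
  maps <- lapply(seq_len(nrow(transcripts)),
                 function(i) cds_map(transcripts[i], reference))
  names(maps) <- transcripts$transcript_id

  feats <- feature_table(transcripts)
  cds_tx <- feats[class == "cds"]
  vsp <- variant_span(variants)
  setkey(cds_tx, contig, fs, fe)
  ovc <- foverlaps(setkey(copy(vsp[, .(variant_id, contig, fs, fe)]),
                          contig, fs, fe),
                   cds_tx, type = "any", nomatch = NULL)
  ovc <- ovc[i.fs < fe & fs < i.fe]
  pairs <- unique(ovc[, .(variant_id, gene_id, transcript_id)])

  eff <- if (nrow(pairs)) {
    vix <- setNames(seq_len(nrow(variants)), variants$variant_id)
    tix <- setNames(seq_len(nrow(transcripts)), transcripts$transcript_id)
    vi <- unname(vix[as.character(pairs$variant_id)])
    ti <- unname(tix[pairs$transcript_id])
    pairs[, effect := vapply(seq_len(.N), function(k) {
      coding_effect_one(variants[vi[k]], transcripts[ti[k]],
                        maps[[ti[k]]])
    }, character(1L))]
    pairs
  } else {
    data.table(variant_id = integer(), gene_id = character(),
               transcript_id = character(), effect = character())
  }

  ## per-variant effect: most severe over coding transcripts
  veff <- eff[, .(coding_effect = .SD$effect[
    which.max(EFFECT_SEVERITY[.SD$effect])]), by = variant_id]
  ann <- merge(ann, veff, by = "variant_id", all.x = TRUE)
  ann[is.na(coding_effect) | region_class != "cds", coding_effect := "none"]
  gl <- gene_hits[, .(genes = paste(sort(unique(gene_id)), collapse = ",")),
                  by = variant_id]
  ann <- merge(ann, gl, by = "variant_id", all.x = TRUE)
  ann[is.na(genes), genes := ""]
  ann[, is_lof := is_lof(region_class, coding_effect)]

  ## per-gene records for knockout / ranking analyses
  geff <- eff[, .(coding_effect = .SD$effect[
    which.max(EFFECT_SEVERITY[.SD$effect])]), by = .(variant_id, gene_id)]
  ge <- merge(gene_hits[, .(variant_id, gene_id, region_class)], geff,
              by = c("variant_id", "gene_id"), all.x = TRUE)
  ge[is.na(coding_effect) | region_class != "cds", coding_effect := "none"]
  ge[, is_lof := is_lof(region_class, coding_effect)]
  ge <- merge(ge, variants[, .(variant_id, vtype)], by = "variant_id")
  setattr(ann, "gene_effects", ge[])
  setorder(ann, variant_id)
  ann[]
}

#' Cohort annotation summary (distinct counts and per-genome means)
#'
#' Produces the taxonomy of a cohort variant table: per variant class
#' (SNP / indel / block substitution) the distinct-variant counts and
#' per-genome averages for each region class and coding effect, with the
#' derived rows `total`, `intragenic` (= total - intergenic), `coding`
#' and `non_synonymous` (= missense + nonsense + nonstop).
#'
#' @param variants distinct (post-merge) variant table.
#' @param genotypes long genotype table (`variant_id`, `individual`,
#'   `zygosity`); only non-reference rows count as carried.
#' @param transcripts transcript-model table.
#' @param reference named character vector of contig sequences.
#' @return list with `annotations`, `gene_effects`, `summary`
#'   (class `cohort_annotation`).
#' @export
annotate_cohort <- function(variants, genotypes, transcripts, reference) {
  ann <- annotate_variants(variants, transcripts, reference)
  n_ind <- length(unique(genotypes$individual))
  carried <- genotypes[zygosity != "ref",
                       .(variant_id, individual)]
  carried <- merge(carried,
                   ann[, .(variant_id, vtype, region_class, coding_effect)],
                   by = "variant_id")

  summarize <- function(dt, weight = 1) {
    ## dt: one row per (variant[, individual]) with vtype/region/effect
    cls <- function(sub, category) {
      data.table(variant_class = c("snp", "indel", "block_substitution"),
                 category = category,
                 n = c(sum(sub$vtype == "snp") / weight,
                       sum(sub$vtype %in% c("insertion", "deletion")) / weight,
                       sum(sub$vtype == "block_substitution") / weight))
    }
    parts <- list(cls(dt, "total"))
    for (rc in REGION_CLASSES) {
      parts[[length(parts) + 1L]] <-
        cls(dt[region_class == rc], if (rc == "cds") "coding" else rc)
    }
    for (ef in setdiff(CODING_EFFECTS, "none")) {
      parts[[length(parts) + 1L]] <- cls(dt[coding_effect == ef], ef)
    }
    parts[[length(parts) + 1L]] <-
      cls(dt[coding_effect %in% c("missense", "nonsense", "nonstop")],
          "non_synonymous")
    out <- rbindlist(parts)
    ## intragenic = total - intergenic (mirrors the published taxonomy)
    wide <- dcast(out, variant_class ~ category, value.var = "n")
    out <- rbind(out,
                 data.table(variant_class = wide$variant_class,
                            category = "intragenic",
                            n = wide$total - wide$intergenic))
    out
  }
  ## distinct counts
  dsum <- summarize(ann)
  ## per-genome means: counts over carried rows divided by cohort size
  gsum <- summarize(carried, weight = n_ind)
  setnames(dsum, "n", "n_distinct")
  setnames(gsum, "n", "mean_per_genome")
  s <- merge(dsum, gsum, by = c("variant_class", "category"), sort = FALSE)
  res <- structure(list(annotations = ann,
                        gene_effects = attr(ann, "gene_effects"),
                        summary = s,
                        n_individuals = n_ind),
                   class = "cohort_annotation")
  res
}

#' @export
print.cohort_annotation <- function(x, ...) {
  cat("cohort annotation:", nrow(x$annotations), "distinct variants,",
      x$n_individuals, "genomes\n")
  print(x$summary)
  invisible(x)
}
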