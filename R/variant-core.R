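## variant data model, typing, normalization, block merging, summary stats

#' Build a variant table
#'
#' Assembles distinct variant calls into the package's canonical
#' `data.table` representation.  Coordinates are 0-based half-open; `ref`
#' and `alt` are uppercase DNA strings, possibly empty for pure
#' insertions/deletions.  `vtype` and `length_change` are derived unless
#' supplied.
#'
#' @param contig character vector of contig names.
#' @param start integer vector of 0-based start offsets.
#' @param ref,alt reference and alternate allele strings.
#' @param vtype optional variant types; classified from the alleles when
#'   `NULL`.
#' @param n_block number of primitive variants merged into each call
#'   (1 for unmerged calls).
#' @return a `data.table` with columns `variant_id`, `contig`, `start`,
#'   `ref`, `alt`, `vtype`, `length_change`, `n_block`.
#' @export
variant_table <- function(contig, start, ref, alt, vtype = NULL,
                          n_block = 1L) {
  check_dna(ref, alt)
  if (is.null(vtype)) vtype <- classify_variant_type(ref, alt)
  dt <- data.table(
    contig = as.character(contig),
    start = as.integer(start),
    ref = as.character(ref),
    alt = as.character(alt),
    vtype = vtype,
    length_change = nchar(alt) - nchar(ref),
    n_block = as.integer(n_block)
  )
  dt[, variant_id := .I]
  setcolorder(dt, "variant_id")
  dt[]
}

trim_alleles <- function(start, ref, alt) {
  ## shared suffix then shared prefix; start advances with the prefix
  nr <- nchar(ref); na <- nchar(alt)
  while (nr > 0L && na > 0L &&
         substr(ref, nr, nr) == substr(alt, na, na)) {
    ref <- substr(ref, 1L, nr - 1L); alt <- substr(alt, 1L, na - 1L)
    nr <- nr - 1L; na <- na - 1L
  }
  while (nr > 0L && na > 0L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nr); alt <- substr(alt, 2L, na)
    nr <- nr - 1L; na <- na - 1L
    start <- start + 1L
  }
  list(start = as.integer(start), ref = ref, alt = alt)
}

#' Classify an allele pair into a variant type
#'
#' Shared prefix/suffix bases are ignored, then the pair is typed as
#' `snp` (single-base replacement), `insertion` (no reference bases
#' consumed), `deletion` (no alternate bases) or `block_substitution`
#' (everything else: length-conserving multi-base replacements and
#' composite replacements).
#'
#' @param ref,alt allele strings (vectorized).
#' @return character vector of types.
#' @export
classify_variant_type <- function(ref, alt) {
  check_dna(ref, alt)
  if (any(nchar(ref) + nchar(alt) == 0L)) stop("both alleles empty")
  if (any(ref == alt)) stop("ref and alt alleles are identical")
  mapply(function(r, a) {
    t <- trim_alleles(0L, r, a)
    nr <- nchar(t$ref); na <- nchar(t$alt)
    if (nr == 1L && na == 1L) "snp"
    else if (nr == 0L) "insertion"
    else if (na == 0L) "deletion"
    else "block_substitution"
  }, ref, alt, USE.NAMES = FALSE)
}

#' Is a SNP a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' exchanges; everything else is a transversion.
#'
#' @param ref,alt single-base allele vectors.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L | ref == alt)) {
    stop("is_transition() expects SNP alleles (single differing bases)")
  }
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

normalize_one <- function(seq, start, ref, alt, shift = TRUE) {
  if (nchar(ref) > 0L &&
      substr(seq, start + 1L, start + nchar(ref)) != ref) {
    stop("reference-consistency error: ref allele does not match reference",
         call. = FALSE)
  }
  t <- trim_alleles(start, ref, alt)
  start <- t$start; ref <- t$ref; alt <- t$alt
  if (shift && xor(nchar(ref) == 0L, nchar(alt) == 0L)) {
    s <- if (nchar(ref) == 0L) alt else ref
    L <- nchar(s)
    while (start > 0L && substr(seq, start, start) == substr(s, L, L)) {
      s <- paste0(substr(seq, start, start), substr(s, 1L, L - 1L))
      start <- start - 1L
    }
    if (nchar(ref) == 0L) alt <- s else ref <- s
  }
  list(start = start, ref = ref, alt = alt)
}

#' Normalize variants against a reference
#'
#' Trims shared prefix/suffix bases and left-aligns pure indels
#' (parsimonious, left-most representation).  Idempotent.  Block
#' substitutions keep their type and are trimmed but never shifted.
#'
#' @param variants a variant table (see [variant_table()]).
#' @param reference named character vector of contig sequences.
#' @param shift left-align pure indels (default).  `shift = FALSE` trims
#'   shared bases only, which is the right mode before haplotype-wise
#'   block merging (a left-shifted indel may otherwise collide with an
#'   upstream variant it should have been merged with).
#' @return the normalized variant table (new object).
#' @export
normalize_variants <- function(variants, reference, shift = TRUE) {
  v <- copy(variants)
  res <- mapply(function(ctg, s, r, a, vt) {
    normalize_one(reference[[ctg]], s, r, a,
                  shift = shift && !identical(vt, "block_substitution"))
  }, v$contig, v$start, v$ref, v$alt, v$vtype, SIMPLIFY = FALSE)
  v[, start := vapply(res, `[[`, integer(1L), "start")]
  v[, ref := vapply(res, `[[`, character(1L), "ref")]
  v[, alt := vapply(res, `[[`, character(1L), "alt")]
  v[, length_change := nchar(alt) - nchar(ref)]
  v[vtype != "block_substitution", vtype := classify_variant_type(ref, alt)]
  v[]
}

#' Merge proximal variants on one haplotype into block substitutions
#'
#' Consecutive variant sequences on a haplotype separated by fewer than two
#' reference bases are merged into a single block substitution whose
#' ref/alt alleles spell the full local reference and alternate sequences.
#' Variants separated by at least two reference bases stay separate.  The
#' output partitions the input: `sum(n_block)` equals the number of input
#' primitives.
#'
#' @param calls variant table for one haplotype of one individual, sorted
#'   by contig and start.  Overlapping calls raise a conflict error.
#' @param reference named character vector of contig sequences.
#' @return merged variant table.
#' @export
group_into_blocks <- function(calls, reference) {
  if (nrow(calls) == 0L) return(copy(calls))
  v <- copy(calls)
  if (!"n_block" %in% names(v)) v[, n_block := 1L]
  setorder(v, contig, start)
  v[, end := start + nchar(ref)]
  v[, gap := start - shift(end), by = contig]
  if (any(v$gap < 0L, na.rm = TRUE)) {
    stop("conflict error: overlapping variants on one haplotype")
  }
  v[, grp := cumsum(is.na(gap) | gap >= 2L)]
  merged <- v[, {
    if (.N == 1L) {
      list(start = start, ref = ref, alt = alt, vtype = vtype,
           n_block = n_block)
    } else {
      s0 <- start[1L]
      between <- c(vapply(seq_len(.N - 1L), function(i) {
        seq_sub(reference, contig[1L], end[i], start[i + 1L])
      }, character(1L)), "")
      list(start = s0,
           ref = seq_sub(reference, contig[1L], s0, end[.N]),
           alt = paste0(paste0(alt, between), collapse = ""),
           vtype = "block_substitution",
           n_block = sum(n_block))
    }
  }, by = .(contig, grp)]
  merged[, grp := NULL]
  merged[, length_change := nchar(alt) - nchar(ref)]
  merged[, variant_id := .I]
  setcolorder(merged,
              c("variant_id", "contig", "start", "ref", "alt", "vtype",
                "length_change", "n_block"))
  merged[]
}

#' Apply variants to a reference sequence
#'
#' Reconstructs the haplotype sequence implied by a set of non-overlapping
#' variants on one contig.  Used for lossless-merge checks.
#'
#' @param seq contig sequence (single string).
#' @param calls variant table restricted to that contig (one haplotype).
#' @return the edited sequence.
#' @export
apply_variants <- function(seq, calls) {
  if (nrow(calls) == 0L) return(seq)
  v <- calls[order(start)]
  out <- character(0L)
  cur <- 0L
  for (i in seq_len(nrow(v))) {
    if (v$start[i] < cur) stop("conflict error: overlapping variants")
    out <- c(out, substr(seq, cur + 1L, v$start[i]), v$alt[i])
    cur <- v$start[i] + nchar(v$ref[i])
  }
  paste0(paste(out, collapse = ""), substr(seq, cur + 1L, nchar(seq)))
}

#' Transition/transversion ratio
#'
#' @param variants variant table; only `vtype == "snp"` rows are used.
#' @return transitions/transversions, or `NA` (with a warning) when no
#'   transversion is present.
#' @export
tstv_ratio <- function(variants) {
  s <- variants[vtype == "snp"]
  if (nrow(s) == 0L) {
    warning("no SNPs: Ts/Tv undefined")
    return(NA_real_)
  }
  ts <- sum(is_transition(s$ref, s$alt))
  tv <- nrow(s) - ts
  if (tv == 0L) {
    warning("zero transversions: Ts/Tv undefined")
    return(NA_real_)
  }
  ts / tv
}

#' Heterozygote/homozygote ratio
#'
#' Hemizygous calls (haploid contigs) are excluded.
#'
#' @param genotypes data.table with a `zygosity` column
#'   (`"het"`/`"hom"`/`"hemi"`).
#' @return het/hom ratio, or `NA` (with a warning) when no homozygous
#'   call is present.
#' @export
het_hom_ratio <- function(genotypes) {
  het <- sum(genotypes$zygosity == "het")
  hom <- sum(genotypes$zygosity == "hom")
  if (hom == 0L) {
    warning("zero homozygous calls: het/hom undefined")
    return(NA_real_)
  }
  het / hom
}

#' Minor-allele-frequency spectrum of a cohort
#'
#' Frequencies are computed from called alleles only (haploid genotypes
#' contribute one allele).  Monomorphic sites (MAF 0) are excluded; bins
#' are right-closed and partition (0, 0.5].
#'
#' @param genotypes long genotype table of carriers (`variant_id`,
#'   `individual`, `h1`, `h2`; `NA` for absent haplotypes).
#' @param variants variant table giving each variant's contig.
#' @param bin_edges interior bin edges in (0, 0.5); 0 and 0.5 are added.
#' @param individuals optional table (`individual`, `sex`); inferred
#'   from hemizygous calls when `NULL`.
#' @param haploid_male_contigs,haploid_contigs contigs haploid in males
#'   / in everyone.
#' @return a `data.table` with `lo`, `hi`, `count`, and the per-variant
#'   MAF vector as attribute `"maf"`.
#' @export
maf_spectrum <- function(genotypes, variants,
                         bin_edges = c(0.05, 0.1, 0.2, 0.3, 0.4),
                         individuals = NULL,
                         haploid_male_contigs = "ctgX",
                         haploid_contigs = "ctgM") {
  if (nrow(genotypes) == 0L) stop("empty-input error: no genotypes")
  f <- cohort_allele_freq(genotypes, variants, individuals,
                          haploid_male_contigs, haploid_contigs)
  m <- pmin(f$p, 1 - f$p)
  m <- m[m > 0]
  breaks <- sort(unique(c(0, bin_edges, 0.5)))
  cnt <- tabulate(findInterval(m, breaks, left.open = TRUE,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  out <- data.table(lo = head(breaks, -1L), hi = tail(breaks, -1L),
                    count = cnt)
  setattr(out, "maf", m)
  out[]
}

#' Realized alternate-allele frequencies of a cohort
#'
#' Frequencies are computed over all called alleles: individuals absent
#' from the carrier table are homozygous reference, and the per-variant
#' allele denominator follows the contig's ploidy (haploid-male contigs
#' contribute one allele per male, fully haploid contigs one per
#' individual).
#'
#' @param genotypes long carrier genotype table (`variant_id`,
#'   `individual`, `h1`, `h2`).
#' @param variants variant table with `variant_id`, `contig`.
#' @param individuals optional table (`individual`, `sex`); when `NULL`,
#'   the cohort is the set of individuals seen in `genotypes` and an
#'   individual is called male iff it carries a hemizygous call outside
#'   the fully haploid contigs.
#' @param haploid_male_contigs,haploid_contigs ploidy configuration.
#' @return `data.table` with `variant_id`, `alt_count`, `n_alleles`, `p`.
#' @export
cohort_allele_freq <- function(genotypes, variants, individuals = NULL,
                               haploid_male_contigs = "ctgX",
                               haploid_contigs = "ctgM") {
  g <- merge(genotypes, variants[, .(variant_id, contig)],
             by = "variant_id")
  if (is.null(individuals)) {
    ids <- sort(unique(g$individual))
    males <- unique(g[is.na(h2) & !contig %in% haploid_contigs, individual])
    individuals <- data.table(individual = ids,
                              sex = fifelse(ids %in% males, "male",
                                            "female"))
  }
  n_m <- sum(individuals$sex == "male")
  n_tot <- nrow(individuals)
  alt <- g[, .(alt_count = sum(h1 == 1L, na.rm = TRUE) +
                 sum(h2 == 1L, na.rm = TRUE)), by = variant_id]
  out <- merge(variants[, .(variant_id, contig)], alt,
               by = "variant_id", all.x = TRUE)
  out[is.na(alt_count), alt_count := 0L]
  out[, n_alleles := fifelse(contig %in% haploid_contigs, n_tot,
                      fifelse(contig %in% haploid_male_contigs,
                              n_m + 2L * (n_tot - n_m), 2L * n_tot))]
  out[, p := alt_count / n_alleles]
  out[, contig := NULL]
  out[]
}

#' Derive zygosity from haplotype alleles
#'
#' @param h1,h2 allele indicators (0/1), `h2 = NA` on haploid contigs.
#' @return `"het"`, `"hom"`, `"hemi"` or `"ref"`.
#' @export
zygosity_of <- function(h1, h2) {
  fifelse(is.na(h2), fifelse(h1 == 1L, "hemi", "ref"),
          fifelse(h1 == 1L & h2 == 1L, "hom",
                  fifelse(h1 + h2 == 1L, "het", "ref")))
}
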