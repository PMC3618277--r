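## deterministic synthetic-cohort generator with recorded ground truth

#' Simulation configuration
#'
#' Defaults describe the emulated study design: a 44-genome diploid cohort
#' (half male), a rare-skewed site-frequency spectrum (MAF ~ Beta(0.2, 2)
#' truncated to (0, 0.5]), genome-wide variant densities matching the
#' published distinct-site densities (~3.8 SNPs, ~0.47 insertions and
#' ~0.51 deletions per kb), a cluster rate sized so that merged block
#' substitutions are ~3.6% of SNP sites, and two partial catalogs whose
#' inclusion probability depends on whether a site is common (MAF > 5%).
#' Planted coding-class quotas guarantee that every row of the annotation
#' taxonomy is exercised at desk scale.
#'
#' @param seed master RNG seed (fixes every downstream byte).
#' @param n_individuals cohort size.
#' @param contig_lengths named contig lengths; `ctgX` is haploid in males
#'   (non-PAR model), `ctgM` is haploid in everyone and uses the
#'   vertebrate mitochondrial code.
#' @param gc GC fraction of the simulated reference.
#' @param n_genes number of non-overlapping genes.
#' @param snp_rate,ins_rate,del_rate distinct background sites per bp.
#' @param transition_prob probability that a background SNP is a
#'   transition (default 2.13/3.13, i.e. a genome-wide Ts/Tv of 2.13).
#' @param cluster_rate fraction of SNP sites that spawn an in-phase
#'   neighbor within <2 reference bases (exercises block merging).
#' @param max_ins_len,max_del_len background indel length caps.
#' @param sfs_shape1,sfs_shape2 Beta parameters of the MAF spectrum.
#' @param coding_quota named planted-site counts per coding class.
#' @param n_knockout_genes genes given a high-frequency nonsense SNP so
#'   that homozygous knockouts are common.
#' @param knockout_freq_range alt-allele frequency range for those sites.
#' @param catalog_a,catalog_b inclusion probabilities
#'   (`common`, `rare`) for each catalog.
#' @param common_maf MAF threshold separating common from rare.
#' @param catalog_indel_jitter max placement shift (bp) applied to
#'   catalog copies of indels (emulates cross-dataset placement
#'   differences; must stay below the 25-bp match window).
#' @param n_decoys catalog-only variants absent from the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 44L,
                       contig_lengths = c(ctg1 = 1700000L, ctgX = 280000L,
                                          ctgM = 20000L),
                       gc = 0.41,
                       n_genes = 50L,
                       snp_rate = 3.8e-3,
                       ins_rate = 4.7e-4,
                       del_rate = 5.1e-4,
                       transition_prob = 2.13 / 3.13,
                       cluster_rate = 0.036,
                       max_ins_len = 20L,
                       max_del_len = 30L,
                       sfs_shape1 = 0.2,
                       sfs_shape2 = 2,
                       coding_quota = c(synonymous = 40L, missense = 60L,
                                        nonsense = 15L, nonstop = 5L,
                                        splice_donor = 10L,
                                        splice_acceptor = 10L,
                                        indel_frameshift = 20L,
                                        indel_inframe = 12L,
                                        block_missense = 10L,
                                        block_synonymous = 4L,
                                        block_nonsense = 3L,
                                        block_nonstop = 1L,
                                        block_frameshift = 4L),
                       n_knockout_genes = 8L,
                       knockout_freq_range = c(0.85, 0.98),
                       catalog_a = c(common = 0.95, rare = 0.30),
                       catalog_b = c(common = 0.98, rare = 0.45),
                       common_maf = 0.05,
                       catalog_indel_jitter = 10L,
                       n_decoys = 2000L) {
  cfg <- as.list(environment())
  probs <- c(cfg$catalog_a, cfg$catalog_b, cfg$cluster_rate, cfg$gc,
             cfg$transition_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$contig_lengths <= 0L)) stop("contig lengths must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome
#'
#' @param config a [sim_config()].
#' @return named character vector of contig sequences (GC within ~2% of
#'   target on contigs of at least 10 kb).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  setNames(
    vapply(config$contig_lengths, random_dna, character(1L), gc = config$gc),
    names(config$contig_lengths)
  )
}

split_len <- function(total, k, min_part = 20L) {
  if (k == 1L) return(total)
  if (total < k * (min_part + 2L)) {
    stop("cannot split ", total, " into ", k, " parts of >= ", min_part)
  }
  repeat {
    cuts <- sort(sample(seq_len(total - 1L), k - 1L))
    parts <- diff(c(0L, cuts, total))
    if (all(parts >= min_part)) return(parts)
  }
}

## one gene: sense-strand layout built first, then mirrored for "-" genes.
## Returns locus sequence, relative exon/cds coordinates and the
## transcription-order relative CDS positions.
build_gene_locus <- function(mito, gc, code) {
  n_exons <- if (mito) 1L else sample(1:10, 1L)
  n_codons <- if (mito) sample(60:150, 1L) else sample(60:350, 1L)
  cds_len <- 3L * n_codons
  ## short CDS cannot honour the 20-bp-per-exon minimum over many exons
  n_exons <- min(n_exons, max(1L, cds_len %/% 30L))
  utr5 <- sample(40:150, 1L)
  utr3 <- sample(60:250, 1L)
  parts <- split_len(cds_len, n_exons)
  introns <- if (n_exons > 1L) sample(60:400, n_exons - 1L, replace = TRUE)
             else integer()
  tbl <- Biostrings::getGeneticCode(code)
  stops <- names(tbl)[tbl == "*"]
  nonstops <- setdiff(names(tbl), stops)
  cds_seq <- paste0("ATG",
                    paste(sample(nonstops, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1L))
  ## sense-relative layout
  exon_lens <- parts
  exon_lens[1L] <- exon_lens[1L] + utr5
  exon_lens[n_exons] <- exon_lens[n_exons] + utr3
  es <- integer(n_exons); ee <- integer(n_exons)
  cur <- 0L
  pieces <- character(0L)
  cds_rel <- integer(0L)
  cds_cursor <- 0L
  for (i in seq_len(n_exons)) {
    es[i] <- cur
    exon_seq <- ""
    if (i == 1L) {
      exon_seq <- random_dna(utr5, gc)
      cur <- cur + utr5
    }
    seg <- substr(cds_seq, cds_cursor + 1L, cds_cursor + parts[i])
    cds_rel <- c(cds_rel, seq(cur, cur + parts[i] - 1L))
    cds_cursor <- cds_cursor + parts[i]
    exon_seq <- paste0(exon_seq, seg)
    cur <- cur + parts[i]
    if (i == n_exons) {
      exon_seq <- paste0(exon_seq, random_dna(utr3, gc))
      cur <- cur + utr3
    }
    ee[i] <- cur
    pieces <- c(pieces, exon_seq)
    if (i < n_exons) {
      pieces <- c(pieces, random_dna(introns[i], gc))
      cur <- cur + introns[i]
    }
  }
  list(seq = paste(pieces, collapse = ""), len = cur,
       exon_starts = es, exon_ends = ee,
       cds_rel = cds_rel, cds_seq = cds_seq)
}

#' Simulate transcript models (and write their loci into the reference)
#'
#' Places non-overlapping genes (1-10 exons, CDS of length 3n starting
#' ATG and ending in a stop codon, flanking UTRs, both strands) on every
#' contig; `ctgM` genes are single-exon and use the vertebrate
#' mitochondrial code.  The gene loci are spliced into the reference.
#'
#' @param reference named character vector from [simulate_reference()].
#' @param config a [sim_config()].
#' @return list with the modified `reference` and `transcripts` (a
#'   transcript-model table carrying generator-truth columns `cds_pos`
#'   and `cds_seq`).
#' @export
simulate_transcripts <- function(reference, config) {
  set.seed(config$seed + 1L)
  lens <- config$contig_lengths
  mito <- names(lens) %in% "ctgM"
  n_alloc <- integer(length(lens))
  n_alloc[mito] <- pmin(2L, config$n_genes)
  rest <- config$n_genes - sum(n_alloc)
  w <- as.numeric(lens[!mito]) / sum(as.numeric(lens[!mito]))
  n_alloc[!mito] <- round(rest * w)
  n_alloc[!mito][1L] <- rest - sum(n_alloc[!mito][-1L])
  rows <- list()
  gi <- 0L
  for (ci in seq_along(lens)) {
    ctg <- names(lens)[ci]
    cursor <- 600L
    for (k in seq_len(n_alloc[ci])) {
      g <- build_gene_locus(mito[ci], config$gc,
                            if (mito[ci]) "2" else "1")
      offset <- cursor + sample(800:4000, 1L)
      if (offset + g$len > lens[ci] - 600L) break
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      if (strand == "+") {
        locus_seq <- g$seq
        es <- g$exon_starts; ee <- g$exon_ends
        cds_rel <- g$cds_rel
      } else {
        locus_seq <- revcomp(g$seq)
        es <- rev(g$len - g$exon_ends); ee <- rev(g$len - g$exon_starts)
        cds_rel <- g$len - 1L - g$cds_rel   # transcription order kept
      }
      substr(reference[[ctg]], offset + 1L, offset + g$len) <- locus_seq
      rows[[gi]] <- list(
        gene_id = sprintf("g%03d", gi),
        transcript_id = sprintf("t%03d", gi),
        contig = ctg, strand = strand,
        exon_starts = list(es + offset), exon_ends = list(ee + offset),
        cds_start = min(cds_rel) + offset,
        cds_end = max(cds_rel) + offset + 1L,
        code = if (mito[ci]) "2" else "1",
        cds_pos = list(cds_rel + offset),
        cds_seq = g$cds_seq
      )
      cursor <- offset + g$len
    }
  }
  extra <- rbindlist(rows)
  tx <- transcript_models(extra$gene_id, extra$transcript_id, extra$contig,
                          extra$strand, extra$exon_starts, extra$exon_ends,
                          extra$cds_start, extra$cds_end, extra$code)
  tx[, cds_pos := extra$cds_pos]
  tx[, cds_seq := extra$cds_seq]
  list(reference = reference, transcripts = tx)
}

## generator-truth region classes via a painted per-base priority mask
## (mechanism deliberately different from the annotator's interval joins)
build_region_mask <- function(transcripts, contig_lengths) {
  masks <- lapply(contig_lengths, function(L) integer(L))
  paint <- function(ctg, fs, fe, p) {
    if (length(fs) == 0L) return()
    for (k in seq_along(fs)) {
      if (fe[k] > fs[k]) {
        i <- (fs[k] + 1L):fe[k]
        masks[[ctg]][i] <<- pmax(masks[[ctg]][i], p)
      }
    }
  }
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i]
    es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
    cs <- t$cds_start; ce <- t$cds_end
    if (length(es) > 1L) {
      is_ <- head(ee, -1L); ie_ <- tail(es, -1L)
      paint(t$contig, is_, ie_, REGION_PRIORITY[["intron"]])
      if (t$strand == "+") {
        paint(t$contig, is_, is_ + 2L, REGION_PRIORITY[["splice_donor"]])
        paint(t$contig, ie_ - 2L, ie_, REGION_PRIORITY[["splice_acceptor"]])
      } else {
        paint(t$contig, ie_ - 2L, ie_, REGION_PRIORITY[["splice_donor"]])
        paint(t$contig, is_, is_ + 2L, REGION_PRIORITY[["splice_acceptor"]])
      }
    }
    paint(t$contig, es, pmin(ee, cs), REGION_PRIORITY[["utr"]])
    paint(t$contig, pmax(es, ce), ee, REGION_PRIORITY[["utr"]])
    paint(t$contig, pmax(es, cs), pmin(ee, ce), REGION_PRIORITY[["cds"]])
  }
  masks
}

mask_class <- function(masks, contig, start, end) {
  prio_class <- setNames(names(REGION_PRIORITY), REGION_PRIORITY)
  vapply(seq_along(start), function(k) {
    p <- max(masks[[contig[k]]][(start[k] + 1L):end[k]])
    prio_class[[as.character(p)]]
  }, character(1L))
}

## effect of a sense-strand single-base change at CDS index `ci` (1-based)
truth_snp_effect <- function(cds_seq, code, ci, new_base) {
  c0 <- (ci - 1L) %/% 3L
  old <- substr(cds_seq, c0 * 3L + 1L, c0 * 3L + 3L)
  new <- old
  substr(new, ci - c0 * 3L, ci - c0 * 3L) <- new_base
  ao <- translate_codons(old, code); an <- translate_codons(new, code)
  if (an == "*" && ao != "*") "nonsense"
  else if (ao == "*" && an != "*") "nonstop"
  else if (ao != an) "missense"
  else "synonymous"
}

## search a replacement codon meeting a target outcome
find_codon_change <- function(codon, target, code, min_diff = 1L) {
  tbl <- Biostrings::getGeneticCode(code)
  aa0 <- unname(tbl[codon])
  cands <- names(tbl)[names(tbl) != codon]
  diffs <- vapply(cands, function(c2)
    sum(strsplit(codon, "")[[1L]] != strsplit(c2, "")[[1L]]), integer(1L))
  aa <- unname(tbl[cands])
  ok <- switch(target,
    synonymous = aa == aa0 & aa0 != "*",
    missense   = aa != aa0 & aa != "*" & aa0 != "*",
    nonsense   = aa == "*" & aa0 != "*",
    nonstop    = aa != "*" & aa0 == "*")
  ok <- ok & diffs >= min_diff & (min_diff > 1L | diffs == 1L)
  if (!any(ok)) return(NULL)
  sample(cands[ok], 1L)
}

## ---- cohort simulation ----------------------------------------------------

draw_maf <- function(n, shape1, shape2) {
  f <- rbeta(n, shape1, shape2)
  bad <- f <= 1e-6 | f > 0.5
  while (any(bad)) {
    f[bad] <- rbeta(sum(bad), shape1, shape2)
    bad <- f <= 1e-6 | f > 0.5
  }
  f
}

## greedy thinning: keep sorted positions at least `gap` apart
thin_positions <- function(pos, gap) {
  pos <- sort(pos)
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= gap) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  pos[keep]
}

## pick L transcription-consecutive CDS indices whose genome positions are
## contiguous (inside one exon), away from the CDS ends
pick_cds_run <- function(pos, L, margin = 10L) {
  n <- length(pos)
  if (n < 2L * margin + L + 3L) return(NULL)
  for (k in 1:40) {
    i <- sample(seq(margin, n - margin - L), 1L)
    idx <- i:(i + L - 1L)
    d <- diff(pos[idx])
    if (L == 1L || all(d == 1L) || all(d == -1L)) return(idx)
  }
  NULL
}

#' Simulate a diploid cohort with recorded ground truth
#'
#' Plants the configured coding-class quotas at known CDS/splice
#' positions, scatters background SNPs/indels genome-wide with a minimum
#' spacing that prevents unintended block merging, spawns in-phase
#' clustered variants that the pipeline must merge, and draws
#' Hardy-Weinberg genotypes from the configured site-frequency spectrum
#' (males hemizygous on `ctgX`, everyone haploid on `ctgM`).  Every
#' emitted variant has exactly one truth record; truth is stated at the
#' post-merge level (cluster pairs appear as one expected block
#' substitution).
#'
#' @param reference modified reference from [simulate_transcripts()].
#' @param transcripts transcript table from [simulate_transcripts()].
#' @param config a [sim_config()].
#' @return list with `individuals`, `primitives` (emitted calls),
#'   `genotypes` (primitive-level carriers), `truth` (post-merge distinct
#'   variants with classes/effects/frequencies), `truth_genotypes`, and
#'   an `audit` list.
#' @export
simulate_cohort <- function(reference, transcripts, config) {
  set.seed(config$seed + 2L)
  lens <- config$contig_lengths
  masks <- build_region_mask(transcripts, lens)
  guard <- config$max_del_len + 45L
  bases <- c("A", "C", "G", "T")
  planted <- list()
  add_site <- function(contig, start, ref, alt, vtype, region, effect,
                       freq = NA_real_, knockout = FALSE) {
    t <- trim_alleles(start, ref, alt)
    planted[[length(planted) + 1L]] <<- data.table(
      contig = contig, start = t$start, ref = t$ref, alt = t$alt,
      vtype = vtype, region_class = region, coding_effect = effect,
      freq_override = freq, knockout = knockout)
  }
  ref_at <- function(ctg, s, e) seq_sub(reference, ctg, s, e)

  ## --- planted coding-class quotas -----------------------------------------
  q <- config$coding_quota
  tx_multi <- which(vapply(transcripts$exon_starts, length, integer(1L)) > 1L)
  snp_targets <- c(rep("synonymous", q[["synonymous"]]),
                   rep("missense", q[["missense"]]),
                   rep("nonsense", q[["nonsense"]]),
                   rep("nonstop", q[["nonstop"]]))
  plant_codon_snp <- function(target, freq = NA_real_, knockout = FALSE) {
    for (try in 1:80) {
      ti <- sample(nrow(transcripts), 1L)
      t <- transcripts[ti]
      pos <- t$cds_pos[[1L]]
      ncod <- length(pos) %/% 3L
      c0 <- if (target == "nonstop") ncod else sample(2:(ncod - 1L), 1L)
      old <- substr(t$cds_seq, (c0 - 1L) * 3L + 1L, c0 * 3L)
      new <- find_codon_change(old, target, t$code, min_diff = 1L)
      if (is.null(new)) next
      j <- which(strsplit(old, "")[[1L]] != strsplit(new, "")[[1L]])
      ci <- (c0 - 1L) * 3L + j
      gpos <- pos[ci]
      sense_new <- substr(new, j, j)
      galt <- if (t$strand == "+") sense_new else complement_base(sense_new)
      gref <- ref_at(t$contig, gpos, gpos + 1L)
      if (gref == galt) next
      if (!site_free(t$contig, gpos, gpos + 1L, 12L)) next
      add_site(t$contig, gpos, gref, galt, "snp", "cds", target,
               freq = freq, knockout = knockout)
      return(TRUE)
    }
    FALSE
  }
  plant_splice_snp <- function(side) {
    for (try in 1:80) {
      ti <- sample(tx_multi, 1L)
      t <- transcripts[ti]
      es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
      is_ <- head(ee, -1L); ie_ <- tail(es, -1L)
      k <- sample(length(is_), 1L)
      donor_plus <- t$strand == "+"
      span <- if ((side == "splice_donor") == donor_plus)
        c(is_[k], is_[k] + 2L) else c(ie_[k] - 2L, ie_[k])
      gpos <- span[1L] + sample(0:1, 1L)
      gref <- ref_at(t$contig, gpos, gpos + 1L)
      galt <- sample(setdiff(bases, gref), 1L)
      if (!site_free(t$contig, gpos, gpos + 1L, 12L)) next
      add_site(t$contig, gpos, gref, galt, "snp", side, "none")
      return(TRUE)
    }
    FALSE
  }
  plant_coding_indel <- function(inframe) {
    for (try in 1:80) {
      ti <- sample(nrow(transcripts), 1L)
      t <- transcripts[ti]
      pos <- t$cds_pos[[1L]]
      L <- if (inframe) 3L else sample(c(1L, 2L, 4L), 1L)
      insertion <- runif(1L) < 0.5
      idx <- pick_cds_run(pos, if (insertion) 1L else L)
      if (is.null(idx)) next
      s <- min(pos[idx]); e <- max(pos[idx]) + 1L
      if (insertion) {
        ref <- ""; alt <- random_dna(L, config$gc); e <- s
      } else {
        ref <- ref_at(t$contig, s, e); alt <- ""
      }
      nm <- normalize_one(reference[[t$contig]], s, ref, alt)
      if (nm$start != s || nm$ref != ref || nm$alt != alt) next
      if (!site_free(t$contig, s, max(e, s + 1L), 12L)) next
      add_site(t$contig, s, ref, alt, if (insertion) "insertion" else
               "deletion", "cds",
               if (inframe) "frameshift_preserving" else "frameshift")
      return(TRUE)
    }
    FALSE
  }
  plant_coding_block <- function(target) {
    for (try in 1:120) {
      ti <- sample(nrow(transcripts), 1L)
      t <- transcripts[ti]
      pos <- t$cds_pos[[1L]]
      ncod <- length(pos) %/% 3L
      if (target == "frameshift") {
        idx <- pick_cds_run(pos, 2L)
        if (is.null(idx)) next
        s <- min(pos[idx]); e <- max(pos[idx]) + 1L
        ref <- ref_at(t$contig, s, e)
        cand <- setdiff(bases, strsplit(ref, "")[[1L]])
        if (!length(cand)) next
        alt <- sample(cand, 1L)
        if (!site_free(t$contig, s, e, 12L)) next
        add_site(t$contig, s, ref, alt, "block_substitution", "cds",
                 "frameshift")
        return(TRUE)
      }
      c0 <- if (target == "nonstop") ncod else sample(2:(ncod - 1L), 1L)
      i0 <- (c0 - 1L) * 3L + 1L
      idx <- i0:(i0 + 2L)
      d <- diff(pos[idx])
      if (!(all(d == 1L) | all(d == -1L))) next
      old <- substr(t$cds_seq, i0, i0 + 2L)
      new <- find_codon_change(old, target, t$code, min_diff = 2L)
      if (is.null(new)) next
      s <- min(pos[idx]); e <- max(pos[idx]) + 1L
      ref <- ref_at(t$contig, s, e)
      alt <- if (t$strand == "+") new else revcomp(new)
      if (!site_free(t$contig, s, e, 12L)) next
      add_site(t$contig, s, ref, alt, "block_substitution", "cds", target)
      return(TRUE)
    }
    FALSE
  }

  ## registry of already-planted spans (small; linear scan is fine)
  site_free <- function(ctg, s, e, gap) {
    if (!length(planted)) return(TRUE)
    p <- rbindlist(planted)[contig == ctg]
    if (!nrow(p)) return(TRUE)
    !any(p$start - gap < e & s - gap < p$start + pmax(nchar(p$ref), 1L))
  }

  for (target in snp_targets) plant_codon_snp(target)
  for (k in seq_len(q[["splice_donor"]])) plant_splice_snp("splice_donor")
  for (k in seq_len(q[["splice_acceptor"]]))
    plant_splice_snp("splice_acceptor")
  for (k in seq_len(q[["indel_frameshift"]])) plant_coding_indel(FALSE)
  for (k in seq_len(q[["indel_inframe"]])) plant_coding_indel(TRUE)
  for (target in c(rep("missense", q[["block_missense"]]),
                   rep("synonymous", q[["block_synonymous"]]),
                   rep("nonsense", q[["block_nonsense"]]),
                   rep("nonstop", q[["block_nonstop"]]),
                   rep("frameshift", q[["block_frameshift"]]))) {
    plant_coding_block(target)
  }
  ## common knockout sites: high-frequency nonsense SNPs in random genes
  for (k in seq_len(config$n_knockout_genes)) {
    plant_codon_snp("nonsense",
                    freq = runif(1L, config$knockout_freq_range[1L],
                                 config$knockout_freq_range[2L]),
                    knockout = TRUE)
  }
  quota <- if (length(planted)) rbindlist(planted) else
    data.table(contig = character(), start = integer(), ref = character(),
               alt = character(), vtype = character(),
               region_class = character(), coding_effect = character(),
               freq_override = numeric(), knockout = logical())

  ## --- background sites ----------------------------------------------------
  total_len <- sum(as.numeric(lens))
  n_bg <- round(c(snp = config$snp_rate, ins = config$ins_rate,
                  del = config$del_rate) * total_len)
  bg <- list()
  for (ctg in names(lens)) {
    L <- lens[[ctg]]
    n_ctg <- round(sum(n_bg) * L / total_len)
    cand <- sample(200:(L - 300L), min(3L * n_ctg, L %/% 10L))
    cand <- thin_positions(cand, guard)
    qp <- quota[contig == ctg, start]
    if (length(qp)) {
      near <- vapply(cand, function(p) any(abs(p - qp) < guard), logical(1L))
      cand <- cand[!near]
    }
    if (length(cand) > n_ctg) cand <- sort(sample(cand, n_ctg))
    bg[[ctg]] <- data.table(contig = ctg, start = cand)
  }
  bg <- rbindlist(bg)
  type_pool <- sample(rep(c("snp", "insertion", "deletion"),
                          times = ceiling(nrow(bg) * n_bg / sum(n_bg)))[
                            seq_len(nrow(bg))])
  bg[, vtype := type_pool]
  ilen <- function(n, cap) pmin(1L + stats::rgeom(n, 0.35), cap)
  bg[, ref := ""]
  bg[, alt := ""]
  bg[vtype == "snp", ref := vapply(seq_len(.N), function(i)
    ref_at(contig[i], start[i], start[i] + 1L), character(1L))]
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  bg[vtype == "snp", alt := vapply(ref, function(r) {
    if (runif(1L) < config$transition_prob) transition_of[[r]]
    else sample(setdiff(bases, c(r, transition_of[[r]])), 1L)
  }, character(1L))]
  bg[vtype == "insertion", alt := vapply(ilen(.N, config$max_ins_len),
                                         random_dna, character(1L),
                                         gc = config$gc)]
  bg[vtype == "deletion", ref := {
    Ls <- ilen(.N, config$max_del_len)
    vapply(seq_len(.N), function(i)
      ref_at(contig[i], start[i], start[i] + Ls[i]), character(1L))
  }]
  ## drop indels that are not already left-normalized at their position
  stable <- vapply(seq_len(nrow(bg)), function(i) {
    if (bg$vtype[i] == "snp") return(TRUE)
    nm <- normalize_one(reference[[bg$contig[i]]], bg$start[i],
                        bg$ref[i], bg$alt[i])
    nm$start == bg$start[i] && nm$ref == bg$ref[i] && nm$alt == bg$alt[i]
  }, logical(1L))
  n_dropped_norm <- sum(!stable)
  bg <- bg[stable]
  bg[, end := start + pmax(nchar(ref), 1L)]
  bg[, region_class := mask_class(masks, contig, start, end)]
  bg[, end := NULL]

  ## background coding effects from the constructor's own CDS records
  cmap <- rbindlist(lapply(seq_len(nrow(transcripts)), function(i) {
    data.table(contig = transcripts$contig[i],
               pos = transcripts$cds_pos[[i]],
               txi = i, ci = seq_along(transcripts$cds_pos[[i]]))
  }))
  bg[, coding_effect := "none"]
  csnp <- which(bg$vtype == "snp" & bg$region_class == "cds")
  if (length(csnp)) {
    hit <- cmap[bg[csnp, .(contig, pos = start)],
                on = c("contig", "pos"), mult = "first"]
    eff <- vapply(seq_along(csnp), function(k) {
      t <- transcripts[hit$txi[k]]
      sense <- if (t$strand == "+") bg$alt[csnp[k]] else
        complement_base(bg$alt[csnp[k]])
      truth_snp_effect(t$cds_seq, t$code, hit$ci[k], sense)
    }, character(1L))
    bg[csnp, coding_effect := eff]
  }
  bg[vtype != "snp" & region_class == "cds",
     coding_effect := fifelse(abs(nchar(alt) - nchar(ref)) %% 3L != 0L,
                              "frameshift", "frameshift_preserving")]
  bg[, `:=`(freq_override = NA_real_, knockout = FALSE)]

  ## --- in-phase clustered variants (exercise block merging) ----------------
  safe_parent <- vapply(seq_len(nrow(bg)), function(i) {
    bg$vtype[i] == "snp" &&
      bg$region_class[i] %in% c("intergenic", "intron") &&
      max(masks[[bg$contig[i]]][(bg$start[i] + 1L):(bg$start[i] + 7L)]) <=
        REGION_PRIORITY[["intron"]]
  }, logical(1L))
  n_clu <- min(round(config$cluster_rate * sum(bg$vtype == "snp")),
               sum(safe_parent))
  parent_idx <- sample(which(safe_parent), n_clu)
  bg[, cluster_id := NA_integer_]
  partners <- list()
  for (k in seq_along(parent_idx)) {
    i <- parent_idx[k]
    bg[i, cluster_id := k]
    p <- bg$start[i]; ctg <- bg$contig[i]
    pat <- k %% 3L
    if (pat == 1L) {            # SNP . SNP (one reference base between)
      s2 <- p + 2L
      r2 <- ref_at(ctg, s2, s2 + 1L)
      a2 <- sample(setdiff(bases, r2), 1L)
      part <- data.table(contig = ctg, start = s2, ref = r2, alt = a2,
                         vtype = "snp")
    } else if (pat == 2L) {     # adjacent SNPs
      s2 <- p + 1L
      r2 <- ref_at(ctg, s2, s2 + 1L)
      a2 <- sample(setdiff(bases, r2), 1L)
      part <- data.table(contig = ctg, start = s2, ref = r2, alt = a2,
                         vtype = "snp")
    } else {                    # SNP immediately followed by a 1-bp deletion
      s2 <- p + 1L
      r2 <- ref_at(ctg, s2, s2 + 1L)
      if (r2 == bg$ref[i]) {
        ## deleting a base equal to its left neighbour would not be
        ## left-normalized as a standalone call; use adjacent SNPs instead
        a2 <- sample(setdiff(bases, r2), 1L)
        part <- data.table(contig = ctg, start = s2, ref = r2, alt = a2,
                           vtype = "snp")
      } else {
        part <- data.table(contig = ctg, start = s2, ref = r2, alt = "",
                           vtype = "deletion")
        ## keep the parent SNP alt distinct from the deleted base so the
        ## merged allele does not trim to a plain deletion
        cand <- setdiff(bases, c(bg$ref[i], r2))
        if (length(cand)) bg[i, alt := sample(cand, 1L)]
      }
    }
    part[, `:=`(region_class = NA_character_, coding_effect = "none",
                freq_override = NA_real_, knockout = FALSE,
                cluster_id = k)]
    partners[[k]] <- part
  }
  partners <- rbindlist(partners)

  sites <- rbind(
    quota[, .(contig, start, ref, alt, vtype, region_class, coding_effect,
              freq_override, knockout, cluster_id = NA_integer_)],
    bg[, .(contig, start, ref, alt, vtype, region_class, coding_effect,
           freq_override, knockout, cluster_id)],
    if (nrow(partners)) partners[, .(contig, start, ref, alt, vtype,
                                     region_class, coding_effect,
                                     freq_override, knockout, cluster_id)]
  )
  setorder(sites, contig, start)
  sites[, variant_id := .I]
  sites[, length_change := nchar(alt) - nchar(ref)]
  sites[, n_block := 1L]

  ## --- frequencies and Hardy-Weinberg genotypes ----------------------------
  N <- config$n_individuals
  individuals <- data.table(
    individual = sprintf("ind%02d", seq_len(N)),
    sex = rep_len(c("male", "female"), N))
  is_partner <- !is.na(sites$cluster_id) &
    duplicated(sites$cluster_id) | (!is.na(sites$cluster_id) &
      sites$variant_id %in%
        sites[!is.na(cluster_id)][duplicated(cluster_id), variant_id])
  ## partner rows are the second member of each cluster
  sites[, is_partner := FALSE]
  sites[!is.na(cluster_id), is_partner := seq_len(.N) > 1L, by = cluster_id]
  own <- which(!sites$is_partner)
  f <- draw_maf(length(own), config$sfs_shape1, config$sfs_shape2)
  ov <- sites$freq_override[own]
  f[!is.na(ov)] <- ov[!is.na(ov)]
  sites[, alt_freq := NA_real_]
  sites[own, alt_freq := f]

  male <- individuals$sex == "male"
  gt_rows <- vector("list", length(own))
  n_forced <- 0L
  for (k in seq_along(own)) {
    i <- own[k]
    ctg <- sites$contig[i]
    fk <- sites$alt_freq[i]
    for (try in 1:100) {
      h1 <- rbinom(N, 1L, fk)
      h2 <- rbinom(N, 1L, fk)
      if (ctg == "ctgM") h2[] <- NA_integer_
      if (ctg == "ctgX") h2[male] <- NA_integer_
      if (sum(h1, na.rm = TRUE) + sum(h2, na.rm = TRUE) > 0L) break
    }
    if (sum(h1, na.rm = TRUE) + sum(h2, na.rm = TRUE) == 0L) {
      h1[sample(N, 1L)] <- 1L
      n_forced <- n_forced + 1L
    }
    carrier <- which(h1 == 1L | (!is.na(h2) & h2 == 1L))
    gt_rows[[k]] <- data.table(
      variant_id = sites$variant_id[i],
      individual = individuals$individual[carrier],
      h1 = h1[carrier], h2 = h2[carrier],
      n_alleles = sum(!is.na(h1)) + sum(!is.na(h2)),
      alt_count = sum(h1, na.rm = TRUE) + sum(h2, na.rm = TRUE))
  }
  genotypes <- rbindlist(gt_rows)
  freq <- unique(genotypes[, .(variant_id, alt_count, n_alleles)])
  genotypes[, c("alt_count", "n_alleles") := NULL]
  ## cluster partners share the parent's haplotypes exactly (in phase)
  pmap <- sites[!is.na(cluster_id),
                .(parent = variant_id[1L], partner = variant_id[-1L]),
                by = cluster_id]
  if (nrow(pmap)) {
    extra <- merge(genotypes, pmap, by.x = "variant_id", by.y = "parent",
                   allow.cartesian = TRUE)
    extra <- extra[, .(variant_id = partner, individual, h1, h2)]
    genotypes <- rbind(genotypes, extra)
    pf <- merge(pmap, freq, by.x = "parent", by.y = "variant_id")
    freq <- rbind(freq, pf[, .(variant_id = partner, alt_count, n_alleles)])
  }
  genotypes[, zygosity := zygosity_of(h1, h2)]
  genotypes[, phased := TRUE]
  setorder(genotypes, variant_id, individual)

  sites <- merge(sites, freq, by = "variant_id", all.x = TRUE)
  sites[, p_real := alt_count / n_alleles]

  ## --- post-merge truth ----------------------------------------------------
  singles <- sites[is.na(cluster_id)]
  truth_rows <- singles[, .(contig, start, ref, alt, vtype, length_change,
                            n_block, region_class, coding_effect,
                            knockout, p_real, src = variant_id)]
  if (nrow(pmap)) {
    merged <- sites[!is.na(cluster_id)][order(start), .(
      mstart = start[1L],
      mref = seq_sub(reference, contig[1L], start[1L],
                     start[.N] + nchar(ref[.N])),
      malt = {
        between <- seq_sub(reference, contig[1L],
                           start[1L] + nchar(ref[1L]), start[2L])
        paste0(alt[1L], between, alt[2L])
      },
      contig = contig[1L],
      p_real = p_real[1L],
      src = variant_id[1L]
    ), by = cluster_id]
    tr <- lapply(seq_len(nrow(merged)), function(k) {
      t <- trim_alleles(merged$mstart[k], merged$mref[k], merged$malt[k])
      e <- t$start + max(nchar(t$ref), 1L)
      data.table(contig = merged$contig[k], start = t$start, ref = t$ref,
                 alt = t$alt, vtype = "block_substitution",
                 length_change = nchar(t$alt) - nchar(t$ref), n_block = 2L,
                 region_class = mask_class(masks, merged$contig[k],
                                           t$start, e),
                 coding_effect = "none", knockout = FALSE,
                 p_real = merged$p_real[k], src = merged$src[k])
    })
    truth_rows <- rbind(truth_rows, rbindlist(tr))
  }
  setorder(truth_rows, contig, start)
  truth_rows[, tvid := .I]
  truth_rows[, is_lof := is_lof(region_class, coding_effect)]
  truth_gt <- merge(genotypes,
                    truth_rows[, .(src, tvid)],
                    by.x = "variant_id", by.y = "src")
  truth_gt <- truth_gt[, .(tvid, individual, h1, h2, zygosity, phased)]
  setorder(truth_gt, tvid, individual)

  list(individuals = individuals,
       primitives = sites[, .(variant_id, contig, start, ref, alt, vtype,
                              length_change, n_block, cluster_id)],
       genotypes = genotypes,
       truth = truth_rows,
       truth_genotypes = truth_gt,
       audit = list(n_dropped_norm = n_dropped_norm,
                    n_forced_segregating = n_forced,
                    n_clusters = nrow(pmap)))
}

## ---- catalogs -------------------------------------------------------------

#' Simulate partial reference catalogs
#'
#' Each truth SNP/indel enters catalog A/B with a probability depending
#' on whether its realized MAF exceeds `common_maf`; catalog copies of
#' indels are re-placed within `catalog_indel_jitter` bp (emulating
#' cross-dataset placement differences resolved by windowed matching).
#' Decoy variants absent from the cohort are added.  Block substitutions
#' are never catalogued.
#'
#' @param sim result of [simulate_cohort()] (truth is updated in place
#'   with `in_a`/`in_b`).
#' @param reference the simulated reference.
#' @param config a [sim_config()].
#' @return list with updated `truth`, `catalog_a`, `catalog_b`
#'   (variant tables).
#' @export
simulate_catalogs <- function(sim, reference, config) {
  set.seed(config$seed + 3L)
  truth <- copy(sim$truth)
  maf <- pmin(truth$p_real, 1 - truth$p_real)
  eligible <- truth$vtype %in% c("snp", "insertion", "deletion")
  common <- maf > config$common_maf
  p_a <- fifelse(common, config$catalog_a[["common"]],
                 config$catalog_a[["rare"]])
  p_b <- fifelse(common, config$catalog_b[["common"]],
                 config$catalog_b[["rare"]])
  truth[, in_a := eligible & rbinom(.N, 1L, p_a) == 1L]
  truth[, in_b := eligible & rbinom(.N, 1L, p_b) == 1L]

  jitter_copy <- function(rows) {
    out <- copy(rows)
    ind <- which(out$vtype %in% c("insertion", "deletion"))
    if (length(ind)) {
      J <- config$catalog_indel_jitter
      sh <- sample(seq(-J, J), length(ind), replace = TRUE)
      out[ind, start := pmax(50L, start + sh)]
      del <- ind[out$vtype[ind] == "deletion"]
      out[del, ref := vapply(seq_len(.N), function(k)
        seq_sub(reference, contig[k], start[k], start[k] + nchar(ref[k])),
        character(1L))]
    }
    out[, .(contig, start, ref, alt, vtype,
            length_change = nchar(alt) - nchar(ref))]
  }
  cat_a <- jitter_copy(truth[in_a == TRUE])
  cat_b <- jitter_copy(truth[in_b == TRUE])

  ## decoys: catalogued variants the cohort does not carry, placed away
  ## from every cohort site so windowed matching cannot fire by accident
  if (config$n_decoys > 0L) {
    occ <- split(truth$start, truth$contig)
    dec <- list()
    lens <- config$contig_lengths
    per_ctg <- round(config$n_decoys * as.numeric(lens) / sum(lens))
    for (ci in seq_along(lens)) {
      ctg <- names(lens)[ci]
      cand <- sample(100:(lens[[ci]] - 150L), 3L * per_ctg[ci])
      o <- sort(occ[[ctg]] %||% integer())
      if (length(o)) {
        iv <- findInterval(cand, o)
        dl <- cand - c(-Inf, o)[iv + 1L]
        dr <- c(o, Inf)[iv + 1L] - cand
        cand <- cand[pmin(dl, dr) > 40L]
      }
      cand <- head(unique(cand), per_ctg[ci])
      if (!length(cand)) next
      vt <- sample(c("snp", "insertion", "deletion"), length(cand),
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
      rows <- data.table(contig = ctg, start = cand, vtype = vt)
      rows[, ref := ""]
      rows[, alt := ""]
      rows[vtype == "snp", ref := vapply(start, function(s)
        seq_sub(reference, ctg, s, s + 1L), character(1L))]
      rows[vtype == "snp", alt := vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))]
      rows[vtype == "insertion", alt := vapply(
        sample(1:6, sum(vtype == "insertion"), replace = TRUE),
        random_dna, character(1L), gc = config$gc)]
      rows[vtype == "deletion", ref := {
        Ls <- sample(1:6, .N, replace = TRUE)
        vapply(seq_len(.N), function(k)
          seq_sub(reference, ctg, start[k], start[k] + Ls[k]),
          character(1L))
      }]
      dec[[ctg]] <- rows
    }
    dec <- rbindlist(dec)
    if (nrow(dec)) {
      dec[, length_change := nchar(alt) - nchar(ref)]
      cell <- sample(c("a", "b", "ab"), nrow(dec), replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
      cat_a <- rbind(cat_a, dec[cell %in% c("a", "ab"),
                                .(contig, start, ref, alt, vtype,
                                  length_change)])
      cat_b <- rbind(cat_b, dec[cell %in% c("b", "ab"),
                                .(contig, start, ref, alt, vtype,
                                  length_change)])
    }
  }
  for (d in list(cat_a, cat_b)) {
    d[, variant_id := .I]
    d[, n_block := 1L]
  }
  list(truth = truth, catalog_a = cat_a, catalog_b = cat_b)
}

## ---- orchestration --------------------------------------------------------

#' Run the full simulation
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_sim` bundling the reference,
#'   transcripts, individuals, emitted primitive calls with genotypes,
#'   post-merge truth (with catalog memberships), and the catalogs.
#' @export
simulate_study <- function(config = sim_config()) {
  ref0 <- simulate_reference(config)
  txr <- simulate_transcripts(ref0, config)
  coh <- simulate_cohort(txr$reference, txr$transcripts, config)
  cats <- simulate_catalogs(coh, txr$reference, config)
  structure(list(config = config,
                 reference = txr$reference,
                 transcripts = txr$transcripts,
                 individuals = coh$individuals,
                 primitives = coh$primitives,
                 genotypes = coh$genotypes,
                 truth = cats$truth,
                 truth_genotypes = coh$truth_genotypes,
                 catalog_a = cats$catalog_a,
                 catalog_b = cats$catalog_b,
                 audit = coh$audit),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$individuals), "genomes,",
      nrow(x$truth), "distinct variants (truth),",
      nrow(x$transcripts), "transcripts\n")
  invisible(x)
}

#' Write a simulation to standard files
#'
#' Emits `reference.fa` (+ `.fai`), `genome.txt`, `genes.gff3`,
#' per-individual VCFs under `vcf/`, `catalog_a.vcf` / `catalog_b.vcf`,
#' `truth.tsv` and `config.json`.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_genome_file(sim$reference, file.path(dir, "genome.txt"))
  write_gff3(sim$transcripts, file.path(dir, "genes.gff3"))
  for (ind in sim$individuals$individual) {
    g <- sim$genotypes[individual == ind]
    v <- sim$primitives[variant_id %in% g$variant_id]
    write_vcf(v, g, sim$reference,
              file.path(dir, "vcf", paste0(ind, ".vcf")), sample_name = ind)
  }
  write_sites_vcf(sim$catalog_a, sim$reference,
                  file.path(dir, "catalog_a.vcf"))
  write_sites_vcf(sim$catalog_b, sim$reference,
                  file.path(dir, "catalog_b.vcf"))
  fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- sim$config
  cfg$contig_lengths <- as.list(cfg$contig_lengths)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate array genotypes for concordance checks
#'
#' Samples SNP sites from the truth set and builds, for one individual,
#' the sequencing dosage (from the recorded genotypes) and an array
#' dosage with planted discordance and missingness.
#'
#' @param sim a [simulate_study()] result.
#' @param individual individual id.
#' @param n_sites number of array sites.
#' @param het_discordance,hom_discordance planted error rates by array
#'   zygosity.
#' @param miss_rate fraction of array sites the sequencing side fails to
#'   call.
#' @param seed RNG seed.
#' @return list with `seq_gt` and `array_gt` tables for
#'   [array_concordance()].
#' @export
simulate_array <- function(sim, individual, n_sites = 500L,
                           het_discordance = 0.01, hom_discordance = 0.002,
                           miss_rate = 0.015, seed = 1L) {
  set.seed(seed)
  snps <- sim$truth[vtype == "snp"]
  pick <- snps[sample(.N, min(n_sites, .N))]
  ind <- individual
  g <- sim$truth_genotypes[individual == ind & tvid %in% pick$tvid]
  d <- merge(pick[, .(tvid, contig, start, ref, alt)],
             g[, .(tvid, h1, h2)], by = "tvid", all.x = TRUE)
  d[, dosage := fifelse(is.na(h1), 0L,
                        fifelse(is.na(h2), h1, h1 + h2))]
  arr <- d[, .(contig, start, ref, alt, dosage)]
  ## discordance is planted on the sequencing side, stratified by the
  ## array zygosity, so the array strata stay clean
  flip <- function(dos, rate) {
    do_flip <- runif(length(dos)) < rate
    fifelse(do_flip, fifelse(dos == 1L, sample(c(0L, 2L), length(dos),
                                               replace = TRUE), 1L), dos)
  }
  seq_gt <- d[, .(contig, start, ref, alt, dosage)]
  het <- arr$dosage == 1L
  seq_gt[het == TRUE, dosage := flip(dosage, het_discordance)]
  seq_gt[het == FALSE, dosage := flip(dosage, hom_discordance)]
  seq_gt[runif(.N) < miss_rate, dosage := NA_integer_]
  list(seq_gt = seq_gt, array_gt = arr)
}
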