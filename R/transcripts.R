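## transcript models: construction, GFF3 I/O, derived feature intervals

#' Build a transcript-model table
#'
#' One row per transcript.  Exon intervals are 0-based half-open, ordered,
#' non-overlapping; the CDS span `[cds_start, cds_end)` lies within the
#' exonic footprint.  `code` is the NCBI genetic-code id used for
#' translation ("1" standard nuclear, "2" vertebrate mitochondrial).
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig,strand location (`strand` is `"+"` or `"-"`).
#' @param exon_starts,exon_ends lists of integer vectors.
#' @param cds_start,cds_end genomic CDS span.
#' @param code genetic-code id per transcript.
#' @return a `data.table` of transcript models.
#' @export
transcript_models <- function(gene_id, transcript_id, contig, strand,
                              exon_starts, exon_ends, cds_start, cds_end,
                              code = "1") {
  tx <- data.table(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    contig = as.character(contig),
    strand = as.character(strand),
    exon_starts = as.list(exon_starts),
    exon_ends = as.list(exon_ends),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    code = rep_len(as.character(code), length(gene_id))
  )
  tx[, tx_start := vapply(exon_starts, min, integer(1L))]
  tx[, tx_end := vapply(exon_ends, max, integer(1L))]
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    if (is.unsorted(es) || any(ee <= es) || any(head(ee, -1L) > tail(es, -1L)))
      stop("exons must be ordered and non-overlapping")
  }
  tx[]
}

#' CDS length of each gene (sum over its transcripts)
#'
#' @param transcripts transcript-model table.
#' @return `data.table` with `gene_id`, `cds_len`.
#' @export
gene_cds_lengths <- function(transcripts) {
  len1 <- vapply(seq_len(nrow(transcripts)), function(i) {
    es <- transcripts$exon_starts[[i]]; ee <- transcripts$exon_ends[[i]]
    sum(pmax(0L, pmin(ee, transcripts$cds_end[i]) -
                 pmax(es, transcripts$cds_start[i])))
  }, integer(1L))
  data.table(gene_id = transcripts$gene_id,
             cds_len = len1)[, .(cds_len = sum(cds_len)), by = gene_id]
}

## flatten transcript models into typed feature intervals with hierarchy
## priorities; splice sites are the two intronic bases at each intron end
## (donor at the transcription-wise 5' end of the intron).
feature_table <- function(transcripts) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i]
    es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
    cs <- t$cds_start; ce <- t$cds_end
    feats <- list()
    add <- function(fs, fe, cls) {
      keep <- fe > fs
      if (any(keep)) {
        feats[[length(feats) + 1L]] <<- data.table(fs = fs[keep],
                                                   fe = fe[keep], class = cls)
      }
    }
    add(pmax(es, cs), pmin(ee, ce), "cds")
    add(es, pmin(ee, cs), "utr")
    add(pmax(es, ce), ee, "utr")
    if (length(es) > 1L) {
      is_ <- head(ee, -1L); ie_ <- tail(es, -1L)   # introns [is_, ie_)
      add(is_, ie_, "intron")
      if (t$strand == "+") {
        add(is_, is_ + 2L, "splice_donor")
        add(ie_ - 2L, ie_, "splice_acceptor")
      } else {
        add(ie_ - 2L, ie_, "splice_donor")
        add(is_, is_ + 2L, "splice_acceptor")
      }
    }
    f <- rbindlist(feats)
    f[, `:=`(contig = t$contig, gene_id = t$gene_id,
             transcript_id = t$transcript_id)]
    f
  })
  f <- rbindlist(rows)
  f[, priority := REGION_PRIORITY[class]]
  f[]
}

#' Write transcript models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with `ID`/`Parent` attributes via
#' rtracklayer (1-based inclusive coordinates; CDS phase computed in
#' transcription order).
#'
#' @param transcripts transcript-model table.
#' @param path output file.
#' @export
write_gff3 <- function(transcripts, path) {
  recs <- list()
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i]
    es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
    cs <- pmax(es, t$cds_start); ce <- pmin(ee, t$cds_end)
    keep <- ce > cs
    cs <- cs[keep]; ce <- ce[keep]
    lens <- ce - cs
    ord <- if (t$strand == "+") seq_along(cs) else rev(seq_along(cs))
    phase <- integer(length(cs))
    cum <- 0L
    for (j in ord) {
      phase[j] <- (3L - cum %% 3L) %% 3L
      cum <- cum + lens[j]
    }
    recs[[i]] <- data.table(
      contig = t$contig,
      type = c("gene", "mRNA", rep("exon", length(es)),
               rep("CDS", length(cs))),
      fs = c(t$tx_start, t$tx_start, es, cs),
      fe = c(t$tx_end, t$tx_end, ee, ce),
      strand = t$strand,
      phase = c(NA_integer_, NA_integer_, rep(NA_integer_, length(es)),
                phase),
      ID = c(t$gene_id, t$transcript_id,
             rep(NA_character_, length(es) + length(cs))),
      Parent = c(NA_character_, t$gene_id,
                 rep(t$transcript_id, length(es) + length(cs))),
      gene_id = t$gene_id,
      code = t$code
    )
  }
  d <- rbindlist(recs)
  gr <- GenomicRanges::GRanges(
    seqnames = d$contig,
    ranges = IRanges::IRanges(start = d$fs + 1L, end = d$fe),
    strand = d$strand
  )
  S4Vectors::mcols(gr)$source <- "varcohort"
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$phase <- d$phase
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$Parent <- d$Parent
  S4Vectors::mcols(gr)$gene_id <- d$gene_id
  S4Vectors::mcols(gr)$genetic_code <- d$code
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features linked by `ID`/`Parent` (the layout
#' written by [write_gff3()]; plain Ensembl-style GFF3 with one mRNA level
#' also works).  An optional `genetic_code` attribute selects the
#' translation table (default "1").
#'
#' @param path GFF3 file.
#' @return transcript-model table.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  m <- S4Vectors::mcols(gr)
  parent <- vapply(as.list(m$Parent), function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1L))
  d <- data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    fs = GenomicRanges::start(gr) - 1L,
    fe = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(m$type),
    id = as.character(m$ID),
    parent = parent,
    code = if ("genetic_code" %in% names(m))
      as.character(m$genetic_code) else "1"
  )
  mrna <- d[type == "mRNA"]
  out <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$id[i]
    ex <- d[type == "exon" & parent == tid][order(fs)]
    cds <- d[type == "CDS" & parent == tid]
    list(gene_id = mrna$parent[i], transcript_id = tid,
         contig = mrna$contig[i], strand = mrna$strand[i],
         exon_starts = list(ex$fs), exon_ends = list(ex$fe),
         cds_start = min(cds$fs), cds_end = max(cds$fe),
         code = mrna$code[i] %||% "1")
  })
  tx <- rbindlist(out)
  transcript_models(tx$gene_id, tx$transcript_id, tx$contig, tx$strand,
                    tx$exon_starts, tx$exon_ends, tx$cds_start, tx$cds_end,
                    tx$code)
}

## genome positions (0-based, transcription order) and sense-strand bases
## of a transcript's CDS
cds_map <- function(transcript, reference) {
  t <- transcript
  es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
  cs <- pmax(es, t$cds_start); ce <- pmin(ee, t$cds_end)
  keep <- ce > cs
  pos <- unlist(lapply(which(keep), function(j) seq(cs[j], ce[j] - 1L)))
  seq <- strsplit(seq_sub(reference, t$contig, t$tx_start, t$tx_end),
                  "", fixed = TRUE)[[1L]]
  bases <- seq[pos - t$tx_start + 1L]
  if (t$strand == "-") {
    pos <- rev(pos)
    bases <- complement_base(rev(bases))
  }
  list(pos = pos, bases = bases)
}
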