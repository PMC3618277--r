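## file I/O: FASTA (Biostrings), VCF v4.2 (light reader/writer), TSV

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a reference to FASTA (with .fai index)
#'
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path, width = 70L)
  ## samtools-style index: name, length, offset, linebases, linewidth
  len <- nchar(reference)
  seq_bytes <- len + ceiling(len / 70)
  rec_bytes <- 1L + nchar(names(reference)) + 1L + seq_bytes
  rec_start <- cumsum(c(0L, head(rec_bytes, -1L)))
  fai <- data.table(name = names(reference), len = len,
                    offset = rec_start + 1L + nchar(names(reference)) + 1L,
                    linebases = 70L, linewidth = 71L)
  fwrite(fai, paste0(path, ".fai"), sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a samtools-style genome file (contig, length)
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @export
write_genome_file <- function(reference, path) {
  fwrite(data.table(contig = names(reference), len = nchar(reference)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## VCF representation: internal empty-allele indels gain the preceding
## reference base as anchor (POS moves left by one); everything else is
## written verbatim at POS = start + 1.
vcf_alleles <- function(reference, contig, start, ref, alt) {
  need_anchor <- nchar(ref) == 0L | nchar(alt) == 0L
  anchor <- character(length(start))
  anchor[need_anchor] <- mapply(function(ctg, s) {
    if (s == 0L) stop("cannot anchor an indel at contig start")
    seq_sub(reference, ctg, s - 1L, s)
  }, contig[need_anchor], start[need_anchor])
  list(pos = ifelse(need_anchor, start, start + 1L),   # 1-based POS
       ref = ifelse(need_anchor, paste0(anchor, ref), ref),
       alt = ifelse(need_anchor, paste0(anchor, alt), alt))
}

#' Write one individual's calls to VCF v4.2
#'
#' Emits single-sample records with a phased GT field; block
#' substitutions carry `INFO/BLOCK` (number of merged primitives) and all
#' records carry `INFO/VT` (variant type).  Empty-allele indels are
#' anchored on the preceding reference base as usual in VCF.
#'
#' @param variants variant table (rows carried by this individual).
#' @param genotypes genotype rows for this individual (`variant_id`,
#'   `h1`, `h2`).
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(variants, genotypes, reference, path,
                      sample_name = "sample") {
  v <- merge(variants, genotypes[, .(variant_id, h1, h2)],
             by = "variant_id")
  setorder(v, contig, start)
  al <- vcf_alleles(reference, v$contig, v$start, v$ref, v$alt)
  gt <- ifelse(is.na(v$h2), as.character(v$h1),
               paste0(v$h1, "|", v$h2))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(reference),
           ",length=", nchar(reference), ">"),
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
    paste0("##INFO=<ID=BLOCK,Number=1,Type=Integer,Description=",
           "\"Number of merged primitive variants\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- paste(v$contig, al$pos, ".", al$ref, al$alt, ".", "PASS",
                paste0("VT=", v$vtype, ";BLOCK=", v$n_block),
                "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a catalog (sites-only) VCF
#'
#' @param variants variant table.
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @export
write_sites_vcf <- function(variants, reference, path) {
  v <- copy(variants)
  setorder(v, contig, start)
  al <- vcf_alleles(reference, v$contig, v$start, v$ref, v$alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(reference),
           ",length=", nchar(reference), ">"),
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- paste(v$contig, al$pos, ".", al$ref, al$alt, ".", "PASS",
                paste0("VT=", v$vtype), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file
#'
#' Light reader for the single-allele records this package writes (and
#' any VCF restricted to one ALT per record).  Returns 0-based variants;
#' anchor bases are not trimmed here — run [normalize_variants()] after
#' reading.  If a sample column is present, `h1`/`h2`/`zygosity`/`phased`
#' are parsed from GT.
#'
#' @param path VCF file (uncompressed).
#' @return variant table; genotype columns attached when present.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  cols <- strsplit(sub("^#", "", header), "\t")[[1L]]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(variant_table(character(), integer(), character(), character()))
  }
  d <- fread(text = body, sep = "\t", header = FALSE, col.names = cols,
             colClasses = "character")
  d[, POS := as.integer(POS)]
  info <- d$INFO
  vt <- sub(".*VT=([a-z_]+).*", "\\1", info)
  vt[!grepl("VT=", info)] <- NA_character_
  blk <- suppressWarnings(as.integer(sub(".*BLOCK=([0-9]+).*", "\\1", info)))
  blk[is.na(blk)] <- 1L
  v <- data.table(contig = d$CHROM, start = d$POS - 1L,
                  ref = toupper(d$REF), alt = toupper(d$ALT),
                  n_block = blk)
  v[, vtype := ifelse(is.na(vt), classify_variant_type(ref, alt), vt)]
  v[, length_change := nchar(alt) - nchar(ref)]
  v[, variant_id := .I]
  if (length(cols) >= 10L) {
    gtcol <- d[[cols[10L]]]
    gt <- sub(":.*$", "", gtcol)
    v[, phased := grepl("|", gt, fixed = TRUE) | !grepl("/", gt, fixed = TRUE)]
    parts <- strsplit(gt, "[|/]")
    v[, h1 := as.integer(vapply(parts, `[`, character(1L), 1L))]
    v[, h2 := as.integer(vapply(parts, function(p)
      if (length(p) > 1L) p[2L] else NA_character_, character(1L)))]
    v[, zygosity := zygosity_of(h1, h2)]
  }
  setcolorder(v, c("variant_id", "contig", "start", "ref", "alt", "vtype",
                   "length_change", "n_block"))
  v[]
}
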