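## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x) grepl("^[ACGT]*$", x)

check_dna <- function(...) {
  for (x in list(...)) {
    bad <- !is_dna(x)
    if (any(bad)) {
      stop("invalid allele: non-ACGT characters in ", sQuote(x[bad][1L]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## substring of a contig in 0-based half-open coordinates
seq_sub <- function(reference, contig, start0, end0) {
  substr(reference[[contig]], start0 + 1L, end0)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

## translate a character vector of codons under an NCBI genetic code id
translate_codons <- function(codons, code = "1") {
  tbl <- Biostrings::getGeneticCode(code)
  aa <- unname(tbl[codons])
  if (anyNA(aa)) stop("cannot translate codon ", sQuote(codons[is.na(aa)][1L]))
  aa
}

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

variant_key <- function(dt) {
  paste(dt$contig, dt$start, dt$ref, dt$alt, sep = ":")
}
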