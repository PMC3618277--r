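## independent oracles used by the property/acceptance tests.  These are
## deliberately naive re-implementations (string surgery, full
## enumeration, plain sorts) that never call the code paths they check.

library(data.table)

## apply variants to a sequence by plain string surgery (left to right)
oracle_apply <- function(seq, starts, refs, alts) {
  ord <- order(starts)
  starts <- starts[ord]; refs <- refs[ord]; alts <- alts[ord]
  out <- ""
  cur <- 0L
  for (i in seq_along(starts)) {
    out <- paste0(out, substr(seq, cur + 1L, starts[i]), alts[i])
    cur <- starts[i] + nchar(refs[i])
  }
  paste0(out, substr(seq, cur + 1L, nchar(seq)))
}

## brute-force block scanner: group by the <2-reference-base rule, then
## spell each group's ref/alt by cutting the reference and applying the
## members to the local substring
oracle_merge <- function(calls, seq) {
  calls <- calls[order(calls$start), ]
  ends <- calls$start + nchar(calls$ref)
  grp <- cumsum(c(TRUE, calls$start[-1] - ends[-length(ends)] >= 2L))
  rows <- lapply(split(seq_len(nrow(calls)), grp), function(ix) {
    s0 <- calls$start[ix[1L]]
    e1 <- max(ends[ix])
    sub <- substr(seq, s0 + 1L, e1)
    data.frame(
      start = s0,
      ref = sub,
      alt = oracle_apply(sub, calls$start[ix] - s0, calls$ref[ix],
                         calls$alt[ix]),
      n = length(ix),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## random clustered-variant fixture on one haplotype: a fresh reference
## plus 2-6 primitives with random small gaps (some < 2, forcing merges)
random_cluster_fixture <- function() {
  seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  n <- sample(2:6, 1L)
  starts <- integer(n); refs <- character(n); alts <- character(n)
  cur <- sample(3:6, 1L)
  for (i in seq_len(n)) {
    type <- sample(c("snp", "ins", "del"), 1L)
    if (type == "snp") {
      refs[i] <- substr(seq, cur + 1L, cur + 1L)
      alts[i] <- sample(setdiff(c("A", "C", "G", "T"), refs[i]), 1L)
    } else if (type == "ins") {
      refs[i] <- ""
      alts[i] <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                              replace = TRUE), collapse = "")
    } else {
      L <- sample(1:3, 1L)
      refs[i] <- substr(seq, cur + 1L, cur + L)
      alts[i] <- ""
    }
    starts[i] <- cur
    gap <- sample(0:4, 1L)   # gaps 0/1 force merging, >=2 keep separate
    cur <- cur + nchar(refs[i]) + gap
    if (i < n && type == "ins" && gap == 0L) cur <- cur + 1L  # avoid stacking
  }
  list(seq = seq,
       calls = data.table(contig = "c", start = starts, ref = refs,
                          alt = alts,
                          vtype = classify_variant_type(refs, alts)))
}

## exact discovery-curve means by full enumeration of genome orderings,
## using plain set arithmetic on variant labels (exact matching)
oracle_discovery <- function(genome_sets, catalog_set) {
  n <- length(genome_sets)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  acc <- matrix(0, nrow(perms), n)
  for (r in seq_len(nrow(perms))) {
    seen <- catalog_set
    for (k in seq_len(n)) {
      g <- genome_sets[[perms[r, k]]]
      acc[r, k] <- length(setdiff(g, seen))
      seen <- union(seen, g)
    }
  }
  colMeans(acc)
}

## three-key descending sort with lexicographic gene tie-break
oracle_rank <- function(df) {
  df[order(-df$density, -df$deleterious, -df$cds_len, df$gene_id), ]
}

## one small simulated study reused across test files (seed-fixed)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_individuals = 8L,
                        contig_lengths = c(ctg1 = 400000L, ctgX = 80000L,
                                           ctgM = 16000L),
                        n_genes = 14L, n_decoys = 400L)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})
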