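## cross-catalog membership, Venn partitioning, discovery curves

#' Build a variant catalog
#'
#' Catalogs support exact lookup for SNPs and block substitutions
#' (contig + position + alleles) and windowed lookup for indels (contig,
#' event type, signed length change, position within a window).
#' Duplicate entries are collapsed.
#'
#' @param variants variant table of catalog content.
#' @param name catalog label.
#' @return object of class `variant_catalog`.
#' @export
build_catalog <- function(variants, name = "catalog") {
  exact <- unique(variants[vtype %in% c("snp", "block_substitution"),
                           .(contig, start, ref, alt)])
  indels <- unique(variants[vtype %in% c("insertion", "deletion"),
                            .(contig, vtype, length_change, start)])
  setkey(exact, contig, start, ref, alt)
  structure(list(name = name, exact = exact, indels = indels),
            class = "variant_catalog")
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat("catalog", sQuote(x$name), ":", nrow(x$exact), "exact entries,",
      nrow(x$indels), "indels\n")
  invisible(x)
}

#' Exact SNP catalog membership
#'
#' @param snps variant table of normalized SNPs.
#' @param catalog a [build_catalog()] object.
#' @return logical vector (same contig, position and allele pair).
#' @export
snp_in_catalog <- function(snps, catalog) {
  !is.na(catalog$exact[snps[, .(contig, start, ref, alt)],
                       on = c("contig", "start", "ref", "alt"),
                       which = TRUE, mult = "first"])
}

#' Windowed indel match
#'
#' Two normalized indels match when they share contig, event type and
#' signed length change, and their start offsets differ by at most
#' `window` bp (an insertion never matches a deletion).  Symmetric.
#'
#' @param a,b one-row variant tables (or equal-length tables, compared
#'   row-wise).
#' @param window maximum start distance in bp (default 25).
#' @return logical vector.
#' @export
indel_match <- function(a, b, window = 25L) {
  a$contig == b$contig & a$vtype == b$vtype &
    a$vtype %in% c("insertion", "deletion") &
    (nchar(a$alt) - nchar(a$ref)) == (nchar(b$alt) - nchar(b$ref)) &
    abs(a$start - b$start) <= window
}

## vectorized catalog membership for a mixed variant table
variant_in_catalog <- function(variants, catalog, window = 25L) {
  out <- logical(nrow(variants))
  ex <- variants$vtype %in% c("snp", "block_substitution")
  if (any(ex)) out[ex] <- snp_in_catalog(variants[which(ex)], catalog)
  ind <- which(!ex)
  if (length(ind) && nrow(catalog$indels)) {
    q <- variants[ind, .(contig, vtype, length_change, start)]
    q[, `:=`(lo = start - window, hi = start + window)]
    hit <- catalog$indels[q,
      on = .(contig, vtype, length_change, start >= lo, start <= hi),
      which = TRUE, mult = "first"]
    out[ind] <- !is.na(hit)
  }
  out
}

#' Catalog Venn partition of a cohort's distinct variants
#'
#' Each distinct variant is assigned to one of the four membership cells
#' (A only, B only, both, neither) per variant class; SNPs/blocks use
#' exact matching, indels windowed matching.
#'
#' @param variants distinct normalized variant table.
#' @param catalog_a,catalog_b [build_catalog()] objects.
#' @param window indel match window (bp).
#' @return `data.table` with `variant_class`, `cell`, `n`, `pct` plus an
#'   attribute `"membership"` (`variant_id`, `in_a`, `in_b`).
#' @export
venn_partition <- function(variants, catalog_a, catalog_b, window = 25L) {
  mem <- data.table(variant_id = variants$variant_id,
                    in_a = variant_in_catalog(variants, catalog_a, window),
                    in_b = variant_in_catalog(variants, catalog_b, window))
  cl <- fifelse(variants$vtype == "snp", "snp",
                fifelse(variants$vtype == "block_substitution",
                        "block_substitution", "indel"))
  cells <- data.table(variant_class = cl,
                      cell = fifelse(mem$in_a & mem$in_b, "both",
                             fifelse(mem$in_a, "A_only",
                             fifelse(mem$in_b, "B_only", "neither"))))
  out <- cells[, .(n = .N), by = .(variant_class, cell)]
  grid <- CJ(variant_class = unique(cl),
             cell = c("A_only", "B_only", "both", "neither"))
  out <- merge(grid, out, by = c("variant_class", "cell"), all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, pct := 100 * n / sum(n), by = variant_class]
  setattr(out, "membership", mem)
  out[]
}

#' Catalog-overlap percentages from cell counts
#'
#' The report helper behind Venn summaries: given the number of distinct
#' variants, the counts found in catalog A, in catalog B and in neither,
#' returns the corresponding percentages of the total.
#'
#' @param n_total,n_in_a,n_in_b,n_neither counts.
#' @return named numeric: `pct_in_a`, `pct_in_b`, `pct_novel`.
#' @export
overlap_percentages <- function(n_total, n_in_a, n_in_b, n_neither) {
  if (n_total <= 0) stop("n_total must be positive")
  c(pct_in_a = 100 * n_in_a / n_total,
    pct_in_b = 100 * n_in_b / n_total,
    pct_novel = 100 * n_neither / n_total)
}

#' Fraction of a variant class mapped to coding sequence
#'
#' @param n_coding,n_total counts.
#' @return percentage of the total mapped to CDS.
#' @export
coding_fraction <- function(n_coding, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * n_coding / n_total
}

## membership structures for the discovery walk:
## exact: per-variant integer vector of genomes carrying the variant;
## match: per-variant genomes carrying any variant matching it (exact for
## SNPs/blocks, windowed for indels).
discovery_membership <- function(variants, genotypes, window = 25L) {
  ids <- variants$variant_id
  inds <- sort(unique(genotypes$individual))
  n <- length(inds)
  g <- genotypes[zygosity != "ref"]
  g[, j := match(individual, inds)]
  exact <- split(g$j, factor(g$variant_id, levels = ids))
  exact <- lapply(exact, function(x) sort(unique(x)))
  match_l <- exact
  ind_idx <- which(variants$vtype %in% c("insertion", "deletion"))
  if (length(ind_idx) > 1L) {
    q <- variants[ind_idx, .(variant_id, contig, vtype, length_change, start)]
    q2 <- copy(q)[, `:=`(lo = start - window, hi = start + window)]
    pairs <- q[q2, on = .(contig, vtype, length_change,
                          start >= lo, start <= hi),
               .(vid = i.variant_id, uid = x.variant_id), nomatch = NULL]
    pairs <- pairs[vid != uid]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- as.character(pairs$vid[k]); b <- as.character(pairs$uid[k])
        match_l[[a]] <- sort(unique(c(match_l[[a]], exact[[b]])))
      }
    }
  }
  list(ids = ids, individuals = inds, n = n,
       exact = exact, match = match_l)
}

#' Permutation discovery-saturation curve
#'
#' Permutes the order of the genomes `n_permutations` times; for each
#' order, walks the genomes accumulating seen variants (catalogs
#' pre-seeded) and counts, at each step k, the variants of genome k
#' matching neither the catalogs nor any previously walked genome.
#' SNP/block matching is exact, indel matching windowed.
#'
#' @param variants distinct normalized cohort variant table.
#' @param genotypes long genotype table.
#' @param catalogs list of [build_catalog()] objects (may be empty).
#' @param n_permutations number of random orders (>= 1).
#' @param seed master RNG seed; permutations are drawn up-front from this
#'   seed, making the curve reproducible.
#' @param window indel match window (bp).
#' @return object of class `discovery_curve`: `data.table`
#'   (`step`, `mean_new`, `sd_new`) with attributes `n_permutations`,
#'   `seed`.
#' @export
discovery_curve <- function(variants, genotypes, catalogs = list(),
                            n_permutations = 1000L, seed = 1L,
                            window = 25L) {
  if (n_permutations < 1L) stop("parameter error: n_permutations < 1")
  mem <- discovery_membership(variants, genotypes, window)
  if (mem$n < 2L) stop("need >= 2 genomes")
  in_cat <- rep(FALSE, nrow(variants))
  for (cat_ in catalogs) {
    in_cat <- in_cat | variant_in_catalog(variants, cat_, window)
  }
  keep <- !in_cat & lengths(mem$exact) > 0L
  exact <- mem$exact[keep]
  matchl <- mem$match[keep]
  N <- mem$n
  set.seed(seed)
  perms <- replicate(n_permutations, sample.int(N), simplify = FALSE)
  counts <- matrix(0L, nrow = n_permutations, ncol = N)
  for (p in seq_along(perms)) {
    pos <- integer(N)
    pos[perms[[p]]] <- seq_len(N)
    se <- vapply(exact, function(j) min(pos[j]), numeric(1L))
    sm <- vapply(matchl, function(j) min(pos[j]), numeric(1L))
    counts[p, ] <- tabulate(se[sm >= se], nbins = N)
  }
  out <- data.table(step = seq_len(N),
                    mean_new = colMeans(counts),
                    sd_new = apply(counts, 2L, sd))
  setattr(out, "n_permutations", n_permutations)
  setattr(out, "seed", seed)
  setattr(out, "class", c("discovery_curve", class(out)))
  out[]
}

#' Fit a decay trendline to a discovery curve
#'
#' Least-squares fit of a power law with offset,
#' `y = a * k^(-b) + c`, via [stats::nls()] with multiple data-driven
#' starting values.
#'
#' @param curve a [discovery_curve()] result or a `data.table` with
#'   `step` and `mean_new`.
#' @param family currently only `"power"`.
#' @return list with `ok`, parameters `a`, `b`, `c`, `sse`, `r_squared`
#'   and the fitted values; `ok = FALSE` (fit-failure signal) for
#'   degenerate (constant) curves.
#' @export
fit_trendline <- function(curve, family = "power") {
  stopifnot(family == "power")
  k <- curve$step
  y <- curve$mean_new
  if (length(k) < 3L) stop("curve length must be >= 3")
  if (sd(y) == 0) {
    return(list(ok = FALSE, a = 0, b = NA_real_, c = y[1L],
                sse = 0, r_squared = NA_real_, fitted = y))
  }
  best <- NULL
  for (frac in c(0, 0.5, 0.9, 0.99)) {
    c0 <- frac * min(y)
    z <- y - c0
    if (any(z <= 0)) next
    lm0 <- stats::lm(log(z) ~ log(k))
    start <- list(a = exp(coef(lm0)[[1L]]), b = -coef(lm0)[[2L]], c = c0)
    fit <- tryCatch(
      suppressWarnings(
        nls(y ~ a * k^(-b) + c, start = start,
            control = stats::nls.control(maxiter = 200L, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- coef(fit)
      best <- list(ok = TRUE, a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                   sse = sse,
                   r_squared = 1 - sse / sum((y - mean(y))^2),
                   fitted = as.numeric(predict(fit)))
    }
  }
  if (is.null(best)) {
    return(list(ok = FALSE, a = NA_real_, b = NA_real_, c = NA_real_,
                sse = NA_real_, r_squared = NA_real_, fitted = NULL))
  }
  best
}
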