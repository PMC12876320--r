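# The GWAS -> LD -> eQTL -> enhancer integration cascade: sentinel
# selection, r-squared LD expansion, eGene intersection, genomic-region
# annotation, super/typical-enhancer colocalization with McNemar's exact
# test, position-weight-matrix allele scoring, and expression correlation.
#
# Coordinate conventions: variant/GWAS/eQTL positions are 1-based (VCF
# convention); BED enhancer intervals are 0-based half-open; all internal
# interval logic is done through IRanges with conversion at the boundary.

#' Select sentinel variants from a GWAS association table
#'
#' Keeps associations with `p < p_max` and deduplicates by rsID, keeping
#' the smallest p per variant.
#'
#' @param gwas data frame with at least `rsid` and `p` (association
#'   p-value in (0, 1]); typically also chrom, pos, ref, alt, trait.
#' @param p_max sentinel threshold (default 1e-5, strict `<`).
#' @return the sentinel rows of `gwas`, one per rsID, with
#'   `source = "index"`.
#' @export
select_sentinels <- function(gwas, p_max = 1e-5) {
  if (!all(c("rsid", "p") %in% names(gwas)))
    stop("gwas table needs `rsid` and `p` columns")
  p <- gwas$p
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1))
    stop("malformed p-values: must be numeric in (0, 1]")
  hit <- gwas[p < p_max, , drop = FALSE]
  if (!nrow(hit)) {
    hit$source <- character(0)
    return(hit)
  }
  hit <- hit[order(hit$p), , drop = FALSE]
  hit <- hit[!duplicated(hit$rsid), , drop = FALSE]
  hit$source <- "index"
  rownames(hit) <- NULL
  hit
}

#' Pairwise linkage disequilibrium r-squared from haplotype counts
#'
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)} with
#' \eqn{D = p_{AB} - p_A p_B}.  Undefined (NA) when either locus is
#' monomorphic — any marginal allele frequency of zero.
#'
#' @param n_AB,n_Ab,n_aB,n_ab counts of the four two-locus haplotypes.
#' @return r-squared in [0, 1], or NA for a monomorphic locus.
#' @export
compute_r2 <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- c(n_AB, n_Ab, n_aB, n_ab)
  if (any(n < 0)) stop("haplotype counts must be non-negative")
  tot <- sum(n)
  if (tot == 0) stop("haplotype counts sum to zero")
  pAB <- n_AB / tot
  pA <- (n_AB + n_Ab) / tot
  pB <- (n_AB + n_aB) / tot
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' LD expansion of sentinel variants
#'
#' Retains proxies in high LD (`r2 > r2_min`, strict) with a sentinel
#' within a symmetric window.  The LD source is either a pair table
#' (`rsid_a`, `rsid_b`, `r2`) or a haplotype panel (0/1 matrix with rsID
#' columns), in which case r-squared is computed from the panel by
#' [compute_r2()].  Positions come from `loci`.
#'
#' @param sentinels data frame from [select_sentinels()] (needs `rsid`).
#' @param ld LD pair table or haplotype panel matrix.
#' @param loci data frame `rsid`, `chrom`, `pos` covering sentinels and
#'   candidate proxies.
#' @param r2_min LD threshold (default 0.8, strict `>`).
#' @param window_bp symmetric window around the sentinel (default 5e5).
#' @return data frame of the union of sentinels (`source = "index"`) and
#'   proxies (`source = "proxy"`, with `parent_rsid` and `r2`),
#'   deduplicated by rsID with index records taking precedence.
#' @export
ld_expand <- function(sentinels, ld, loci, r2_min = 0.8, window_bp = 5e5) {
  stopifnot(all(c("rsid", "chrom", "pos") %in% names(loci)))
  pos_of <- setNames(loci$pos, loci$rsid)
  chrom_of <- setNames(loci$chrom, loci$rsid)
  pair_r2 <- function(sent) {
    if (is.matrix(ld)) {
      if (!sent %in% colnames(ld)) return(NULL)
      others <- setdiff(colnames(ld), sent)
      r2 <- vapply(others, function(o)
        r2_from_haplotypes(ld[, sent], ld[, o]), numeric(1))
      data.frame(rsid = others, r2 = unname(r2), stringsAsFactors = FALSE)
    } else {
      hit <- ld$rsid_a == sent | ld$rsid_b == sent
      if (!any(hit)) return(NULL)
      sub <- ld[hit, , drop = FALSE]
      data.frame(rsid = ifelse(sub$rsid_a == sent, sub$rsid_b, sub$rsid_a),
                 r2 = sub$r2, stringsAsFactors = FALSE)
    }
  }
  proxies <- list()
  for (sent in sentinels$rsid) {
    pr <- pair_r2(sent)
    if (is.null(pr)) {
      warning("sentinel absent from LD source, skipped: ", sent)
      next
    }
    pr <- pr[!is.na(pr$r2) & pr$r2 > r2_min, , drop = FALSE]
    if (!nrow(pr)) next
    keep <- !is.na(pos_of[pr$rsid]) &
      chrom_of[pr$rsid] == chrom_of[[sent]] &
      abs(pos_of[pr$rsid] - pos_of[[sent]]) <= window_bp
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr)) {
      pr$parent_rsid <- sent
      proxies[[sent]] <- pr
    }
  }
  idx <- data.frame(rsid = sentinels$rsid,
                    chrom = chrom_of[sentinels$rsid],
                    pos = pos_of[sentinels$rsid],
                    source = "index", parent_rsid = NA_character_,
                    r2 = NA_real_, stringsAsFactors = FALSE)
  if (length(proxies)) {
    px <- do.call(rbind, proxies)
    px <- data.frame(rsid = px$rsid, chrom = chrom_of[px$rsid],
                     pos = pos_of[px$rsid], source = "proxy",
                     parent_rsid = px$parent_rsid, r2 = px$r2,
                     stringsAsFactors = FALSE)
    px <- px[order(-px$r2), , drop = FALSE]
    px <- px[!duplicated(px$rsid), , drop = FALSE]
    out <- rbind(idx, px[!px$rsid %in% idx$rsid, , drop = FALSE])
  } else out <- idx
  rownames(out) <- NULL
  out
}

#' Intersect variants with a cis-eQTL table
#'
#' Inner join on rsID (with an optional chrom+pos fallback requiring
#' allele consistency), deduplicated on (rsid, gene, tissue); the eGene
#' set collapses hits to distinct genes.
#'
#' @param variants data frame with `rsid` (and `chrom`, `pos`, `ref`,
#'   `alt` for the fallback join).
#' @param eqtl data frame `rsid`, `gene_id`, `tissue`, `slope`, `p`.
#' @return list: `hits` (snp-gene-tissue rows), `egenes` (character
#'   vector of distinct gene IDs), `per_tissue` (named hit counts).
#' @export
intersect_eqtl <- function(variants, eqtl) {
  stopifnot(all(c("rsid", "gene_id", "tissue") %in% names(eqtl)))
  hits <- merge(variants["rsid"], eqtl, by = "rsid")
  if (all(c("chrom", "pos") %in% names(variants)) &&
      all(c("chrom", "pos") %in% names(eqtl))) {
    rest <- variants[!variants$rsid %in% hits$rsid, , drop = FALSE]
    fb <- merge(rest[c("rsid", "chrom", "pos", "ref", "alt")],
                eqtl[setdiff(names(eqtl), "rsid")],
                by = c("chrom", "pos"))
    if (nrow(fb) && all(c("ref", "alt") %in% names(eqtl))) {
      ok <- fb$ref.x == fb$ref.y & fb$alt.x == fb$alt.y
      if (any(!ok)) message(sum(!ok), " positional join(s) excluded: allele mismatch")
      fb <- fb[ok, , drop = FALSE]
    }
    if (nrow(fb))
      hits <- rbind(hits, fb[intersect(names(hits), names(fb))])
  }
  hits <- hits[!duplicated(hits[c("rsid", "gene_id", "tissue")]), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       egenes = sort(unique(hits$gene_id)),
       per_tissue = if (nrow(hits)) table(hits$tissue) else table(character()))
}

#' Classify variants into genomic regions against a gene model
#'
#' Precedence: exonic > UTR > intronic > upstream/downstream (within
#' `flank_bp` of the gene start/end, strand-respecting) > intergenic.
#' When the gene model provides no UTR features, UTR positions are part of
#' the exonic class.  GFF3 input (1-based closed) is handled natively by
#' rtracklayer; variant positions are 1-based.
#'
#' @param variants data frame with `rsid`, `chrom`, `pos` (1-based).
#' @param gene_model path to a GFF3 file, or a `GRanges` with a `type`
#'   metadata column (feature types: gene, exon, five_prime_UTR,
#'   three_prime_UTR...).
#' @param flank_bp upstream/downstream span (default 2000).
#' @return `variants` with an added `region` factor; levels exonic, UTR,
#'   intronic, upstream, downstream, intergenic (a partition: one class
#'   per variant).
#' @export
annotate_region <- function(variants, gene_model, flank_bp = 2000) {
  gr <- if (is.character(gene_model))
    rtracklayer::import(gene_model, format = "gff3")
  else gene_model
  if (!"type" %in% names(GenomicRanges::mcols(gr)))
    stop("gene model must carry a `type` column")
  type <- as.character(gr$type)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1))
  hit <- function(set) {
    if (!length(set)) return(rep(FALSE, length(vr)))
    IRanges::overlapsAny(vr, set)
  }
  exons <- gr[type %in% c("exon", "CDS")]
  utrs <- gr[grepl("utr", type, ignore.case = TRUE)]
  genes <- gr[type %in% c("gene", "mRNA", "transcript")]
  if (!length(genes)) genes <- range(exons)

  in_utr <- hit(utrs)
  in_exon <- if (length(utrs) && any(type == "CDS"))
    hit(gr[type == "CDS"]) else hit(exons)
  in_gene <- hit(genes)

  up <- GenomicRanges::flank(genes, flank_bp, start = TRUE)
  dn <- GenomicRanges::flank(genes, flank_bp, start = FALSE)
  in_up <- hit(up)
  in_dn <- hit(dn)

  region <- rep("intergenic", length(vr))
  region[in_dn] <- "downstream"
  region[in_up] <- "upstream"
  region[in_gene] <- "intronic"
  region[in_utr] <- "UTR"
  region[in_exon] <- "exonic"
  variants$region <- factor(region, levels = c("exonic", "UTR", "intronic",
                                               "upstream", "downstream",
                                               "intergenic"))
  variants
}

#' Exact two-sided McNemar p-value from discordant counts
#'
#' \eqn{p = \min(1, 2\,P(X \le \min(b, c)))} with
#' \eqn{X \sim \mathrm{Binomial}(b + c, 1/2)}.
#'
#' @param b,c discordant pair counts.
#' @return exact two-sided p-value (1 when b + c = 0).
#' @export
mcnemar_exact_p <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Colocalize variants with super- and typical-enhancer intervals
#'
#' Tests each variant position (1-based, converted to 0-based) against
#' the half-open enhancer intervals, then compares SE-only versus TE-only
#' occupancy by McNemar's exact test on the discordant counts.
#'
#' @param variants data frame with `rsid`, `chrom`, `pos` (non-empty).
#' @param enhancers data frame `chrom`, `start`, `end` (0-based
#'   half-open), `kind` in {SE, TE}; or a BED6 path with the kind in the
#'   name column.
#' @return list: `flags` (per-variant in_SE/in_TE), `summary`
#'   (n_se_only, n_te_only, n_both, n_neither, their percentages of
#'   n_total to 1 decimal), `mcnemar_p`.
#' @export
enhancer_colocalize <- function(variants, enhancers) {
  if (!nrow(variants)) stop("empty variant set")
  if (is.character(enhancers)) {
    bed <- rtracklayer::import(enhancers, format = "bed")
    enhancers <- data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
                            start = GenomicRanges::start(bed) - 1L,
                            end = GenomicRanges::end(bed),
                            kind = bed$name, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "kind") %in% names(enhancers)))
  if (any(enhancers$start >= enhancers$end))
    stop("enhancer intervals must satisfy start < end (0-based half-open)")
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1))
  as_gr <- function(kind) {
    sub <- enhancers[enhancers$kind == kind, , drop = FALSE]
    # half-open [start, end) in 0-based = [start+1, end] in 1-based closed
    GenomicRanges::GRanges(sub$chrom,
                           IRanges::IRanges(sub$start + 1L, sub$end))
  }
  in_se <- IRanges::overlapsAny(vr, as_gr("SE"))
  in_te <- IRanges::overlapsAny(vr, as_gr("TE"))
  n <- nrow(variants)
  b <- sum(in_se & !in_te)
  cc <- sum(in_te & !in_se)
  both <- sum(in_se & in_te)
  neither <- sum(!in_se & !in_te)
  pct <- function(x) round(100 * x / n, 1)
  list(
    flags = data.frame(rsid = variants$rsid, in_SE = in_se, in_TE = in_te,
                       stringsAsFactors = FALSE),
    summary = data.frame(n_total = n, n_se_only = b, n_te_only = cc,
                         n_both = both, n_neither = neither,
                         pct_se_only = pct(b), pct_te_only = pct(cc),
                         pct_both = pct(both), pct_neither = pct(neither)),
    mcnemar_p = mcnemar_exact_p(b, cc)
  )
}

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR text format: a `>` header line then four rows
#' `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of per-position
#' counts or frequencies.
#'
#' @param path matrix file path.
#' @param pseudocount added to every cell before column normalization
#'   (default 0.01).
#' @param background length-4 background probabilities (default uniform).
#' @return list of class `pwm`: `id`, `freq` (4 x L column-stochastic
#'   matrix, rows ACGT), `background`, `pseudocount`.
#' @export
read_pwm_jaspar <- function(path, pseudocount = 0.01,
                            background = rep(0.25, 4)) {
  lines <- readLines(path)
  hdr <- grep("^>", lines, value = TRUE)
  id <- if (length(hdr)) sub("^>\\s*", "", hdr[1]) else basename(path)
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    ln <- grep(paste0("^\\s*", b, "\\b"), lines, value = TRUE)
    if (!length(ln)) stop("missing ", b, " row in PWM file")
    vals <- gsub("[][]", " ", sub("^\\s*[ACGT]", "", ln[1]))
    toks <- strsplit(trimws(vals), "\\s+")[[1]]
    as.numeric(toks[toks != ""])
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- c("A", "C", "G", "T")
  pwm_from_counts(mat, id = id, pseudocount = pseudocount,
                  background = background)
}

#' Build a PWM from a count/frequency matrix
#'
#' @param mat 4 x L numeric matrix, rows named A, C, G, T.
#' @param id motif identifier.
#' @param pseudocount per-cell pseudocount.
#' @param background length-4 background probabilities.
#' @return `pwm` object with column-normalized frequencies.
#' @export
pwm_from_counts <- function(mat, id = "motif", pseudocount = 0.01,
                            background = rep(0.25, 4)) {
  stopifnot(nrow(mat) == 4)
  if (is.null(rownames(mat))) rownames(mat) <- c("A", "C", "G", "T")
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  f <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  structure(list(id = id, freq = f, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# log2-odds score of the motif at a fixed placement in a sequence
pwm_score_at <- function(pwm, seq_chars) {
  L <- ncol(pwm$freq)
  stopifnot(length(seq_chars) == L)
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(-Inf)
  sum(log2(pwm$freq[cbind(idx, seq_len(L))] / pwm$background[idx]))
}

#' Allele effect of a variant on a motif match
#'
#' Scans every placement of the motif covering the variant, on both
#' strands, scores the reference window in log2-odds bits, keeps the
#' best-scoring placement, and rescores it with the alternate allele
#' substituted.  `delta = score_alt - score_ref` at that placement; a
#' negative delta means the alternate allele weakens the predicted
#' binding.
#'
#' @param pwm a [pwm_from_counts()]/[read_pwm_jaspar()] object.
#' @param window reference sequence (A/C/G/T string) around the variant,
#'   at least as long as the motif.
#' @param variant_offset 1-based position of the variant within `window`.
#' @param ref,alt single-base alleles; `ref` must match the window.
#' @return list: `score_ref`, `score_alt`, `delta`, `offset` (1-based
#'   start of the best placement), `strand`.
#' @export
pwm_allele_score <- function(pwm, window, variant_offset, ref, alt) {
  stopifnot(inherits(pwm, "pwm"))
  window <- toupper(window)
  chars <- strsplit(window, "")[[1]]
  L <- ncol(pwm$freq)
  if (length(chars) < L) stop("window shorter than motif")
  if (variant_offset < 1 || variant_offset > length(chars))
    stop("variant offset outside window")
  if (chars[variant_offset] != toupper(ref))
    stop(sprintf("ref allele %s disagrees with window base %s at offset %d",
                 ref, chars[variant_offset], variant_offset))
  alt_chars <- chars
  alt_chars[variant_offset] <- toupper(alt)

  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    fwd <- if (strand == "+") chars else strsplit(revcomp(window), "")[[1]]
    voff <- if (strand == "+") variant_offset
            else length(chars) - variant_offset + 1L
    for (start in seq_len(length(fwd) - L + 1L)) {
      if (voff < start || voff > start + L - 1L) next  # must cover variant
      sc <- pwm_score_at(pwm, fwd[start:(start + L - 1L)])
      if (sc > best$score)
        best <- list(score = sc, start = start, strand = strand)
    }
  }
  if (!is.finite(best$score) && is.null(best$start))
    stop("no motif placement covers the variant")
  alt_fwd <- if (best$strand == "+") alt_chars
             else strsplit(revcomp(paste(alt_chars, collapse = "")), "")[[1]]
  sc_alt <- pwm_score_at(pwm, alt_fwd[best$start:(best$start + L - 1L)])
  off <- if (best$strand == "+") best$start
         else length(chars) - (best$start + L - 1L) + 1L
  list(score_ref = best$score, score_alt = sc_alt,
       delta = sc_alt - best$score, offset = off, strand = best$strand)
}

#' Correlation between two expression vectors
#'
#' Spearman by default (midranks for ties; exact p for n <= 9 without
#' ties, t-approximation otherwise, as in [stats::cor.test()]).
#'
#' @param x,y numeric vectors, length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `rho`, `p`, `n`, `flag`.
#' @export
correlate_expression <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                flag = "constant_vector"))
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), flag = "")
}

#' Intersect an eGene set with differential expression events
#'
#' A DEG event is one (gene, contrast) pair passing the nominal
#' thresholds `p < p_max` and `|log2fc| >= log2(fc_min)` in any contrast.
#' Returns the eGenes with at least one event, plus event counts by
#' contrast family.
#'
#' @param egenes character vector of eGene IDs.
#' @param results list of contrast tables (with [fit_contrast()]
#'   attributes) containing `gene_id`, `log2fc`, `p`.
#' @param p_max nominal p threshold (default 0.05).
#' @param fc_min linear fold-change threshold (default 1.5; applied as
#'   `|log2fc| >= log2(fc_min)`).
#' @return list: `genes` (overlapping gene IDs), `n_genes`, `events`
#'   (data frame gene_id, family, area_a, area_b), `events_by_family`.
#' @export
intersect_degs <- function(egenes, results, p_max = 0.05, fc_min = 1.5) {
  lfc_min <- log2(fc_min)
  ev <- lapply(results, function(r) {
    hit <- r$gene_id %in% egenes & r$p < p_max & abs(r$log2fc) >= lfc_min
    if (!any(hit)) return(NULL)
    data.frame(gene_id = r$gene_id[hit],
               family = attr(r, "family"),
               area_a = attr(r, "area_a"), area_b = attr(r, "area_b"),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(gene_id = character(), family = character(),
                     area_a = character(), area_b = character())
  fam_counts <- setNames(integer(3), c("LR", "WH_L", "WH_R"))
  if (nrow(ev)) {
    tb <- table(ev$family)
    fam_counts[names(tb)] <- as.integer(tb)
  }
  list(genes = sort(unique(ev$gene_id)),
       n_genes = length(unique(ev$gene_id)),
       events = ev, events_by_family = fam_counts)
}
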