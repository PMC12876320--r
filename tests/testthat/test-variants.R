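# Variant cascade: sentinels, LD, eQTL intersection, region annotation,
# enhancer colocalization, PWM scoring, correlation, DEG events.

test_that("sentinel selection thresholds strictly and deduplicates by min p", {
  gwas <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs3"),
                     p = c(1e-4, 9e-6, 1e-6, 1e-8))
  out <- select_sentinels(gwas)
  expect_equal(sort(out$rsid), c("rs2", "rs3"))
  expect_equal(out$p[out$rsid == "rs3"], 1e-8)
  expect_true(all(out$source == "index"))

  none <- select_sentinels(data.frame(rsid = c("a", "b"), p = c(1e-4, 1e-4)))
  expect_equal(nrow(none), 0)
  expect_error(select_sentinels(data.frame(rsid = "a", p = 0)), "malformed")
  expect_error(select_sentinels(data.frame(rsid = "a", p = 2)), "malformed")
})

test_that("r2 matches hand-computed haplotype tables", {
  expect_equal(compute_r2(50, 0, 0, 50), 1)
  expect_equal(compute_r2(25, 25, 25, 25), 0)
  expect_equal(compute_r2(40, 10, 10, 40), 0.36)  # D = 0.15, denom 0.0625
  expect_true(is.na(compute_r2(50, 50, 0, 0)))    # monomorphic B
  expect_true(is.na(compute_r2(50, 0, 50, 0)))    # monomorphic A
  expect_error(compute_r2(-1, 1, 1, 1), "non-negative")

  # symmetry under locus exchange and allele relabeling, and range
  set.seed(61)
  for (i in 1:40) {
    n <- sample(1:50, 4, replace = TRUE)
    r <- compute_r2(n[1], n[2], n[3], n[4])
    if (is.na(r)) next
    expect_gte(r, 0); expect_lte(r, 1 + 1e-12)
    expect_equal(r, compute_r2(n[1], n[3], n[2], n[4]))  # swap loci
    expect_equal(r, compute_r2(n[4], n[3], n[2], n[1]))  # relabel alleles
  }
})

test_that("LD expansion honors the strict r2 and window boundaries", {
  loci <- data.frame(rsid = c("s", "p1", "p2", "p3", "far"),
                     chrom = "chr17",
                     pos = c(1e6, 1e6 + 1000, 1e6 + 2000, 1e6 + 3000,
                             1e6 + 5e5 + 1))
  ld <- data.frame(rsid_a = "s", rsid_b = c("p1", "p2", "p3", "far"),
                   r2 = c(0.9, 0.8, 0.79, 0.95))
  sent <- data.frame(rsid = "s", p = 1e-8)
  out <- ld_expand(sent, ld, loci)
  # r2 = 0.8 exactly and the +1 bp window overflow are both excluded
  expect_equal(out$rsid[out$source == "proxy"], "p1")
  expect_equal(out$parent_rsid[out$source == "proxy"], "s")

  # sentinel absent from the LD source: warning, skipped
  sent2 <- data.frame(rsid = c("s", "ghost"), p = 1e-8)
  loci2 <- rbind(loci, data.frame(rsid = "ghost", chrom = "chr17", pos = 2e6))
  expect_warning(out2 <- ld_expand(sent2, ld, loci2), "ghost")
  expect_equal(sum(out2$source == "proxy"), 1)

  # haplotype-panel source: one constructed r2 > 0.8 pair gives one proxy
  hap <- simulate_haplotypes(variant_sim_spec(
    n_snps = 6, haplotype_panel_size = 400,
    ld_blocks = data.frame(n_loci = 2, target_r2 = 1), seed = 62))
  sent3 <- data.frame(rsid = hap$loci$rsid[1], p = 1e-9)
  out3 <- ld_expand(sent3, hap$panel, hap$loci)
  expect_equal(out3$rsid[out3$source == "proxy"], hap$loci$rsid[2])
})

test_that("eQTL intersection joins, deduplicates, and collapses eGenes", {
  eqtl <- data.frame(rsid = c("rs1", "rs1", "rs1", "rs1", "rs9"),
                     gene_id = c("G1", "G1", "G1", "G1", "G9"),
                     tissue = c("cortex", "cerebellum", "putamen",
                                "cortex", "cortex"),
                     slope = 0.5, p = 1e-8)
  vars <- data.frame(rsid = c("rs1", "rs2"))
  out <- intersect_eqtl(vars, eqtl)
  expect_equal(nrow(out$hits), 3)  # duplicate (rs1, G1, cortex) removed
  expect_equal(out$egenes, "G1")
  expect_equal(as.integer(out$per_tissue["cortex"]), 1)

  none <- intersect_eqtl(data.frame(rsid = "rsX"), eqtl)
  expect_equal(nrow(none$hits), 0)
  expect_equal(length(none$egenes), 0)
})

test_that("genomic-region annotation applies the precedence rules", {
  gff <- write_toy_gff3()
  vars <- data.frame(
    rsid = paste0("v", 1:7),
    chrom = "chr1",
    pos = c(1200,   # CDS of geneA -> exonic
            1050,   # five_prime_UTR -> UTR
            2000,   # between exons, inside geneA -> intronic
            500,    # 500 bp upstream of geneA (+) -> upstream
            3500,   # 500 bp after geneA end (+) -> downstream
            12500,  # 500 bp beyond geneB end; geneB is '-' -> upstream
            6000))  # > 2 kb from both genes -> intergenic
  out <- annotate_region(vars, gff)
  expect_equal(as.character(out$region),
               c("exonic", "UTR", "intronic", "upstream", "downstream",
                 "upstream", "intergenic"))
  # the classes partition the set
  expect_false(anyNA(out$region))
  unlink(gff)
})

test_that("intronic beats upstream when a variant is in a gene and near another", {
  # variant inside geneA's intron, 1 kb upstream of a nearby gene
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1000\t5000\t.\t+\t.\tID=geneA",
    "chr1\ttoy\texon\t1000\t1500\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\texon\t4500\t5000\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\tgene\t4800\t7000\t.\t+\t.\tID=geneB",
    "chr1\ttoy\texon\t4800\t7000\t.\t+\t.\tParent=geneB"), path)
  out <- annotate_region(data.frame(rsid = "v", chrom = "chr1", pos = 4000),
                         path)
  expect_equal(as.character(out$region), "intronic")
  unlink(path)
})

test_that("McNemar exact p matches binomial enumeration for all b+c <= 20", {
  expect_equal(mcnemar_exact_p(5, 0), 0.0625)
  expect_equal(mcnemar_exact_p(1, 1), 1)
  for (n in 0:20)
    for (b in 0:n)
      expect_equal(mcnemar_exact_p(b, n - b), mcnemar_oracle(b, n - b),
                   tolerance = 1e-12)
})

test_that("enhancer colocalization counts partition and use half-open intervals", {
  enh <- data.frame(chrom = "chr1",
                    start = c(100, 300), end = c(200, 400),
                    kind = c("SE", "TE"))
  vars <- data.frame(rsid = paste0("v", 1:6), chrom = "chr1",
                     # 1-based positions: 101 is the first base inside
                     # [100,200); 200 is the last; 201 is outside
                     pos = c(101, 200, 201, 301, 150, 500))
  out <- enhancer_colocalize(vars, enh)
  expect_equal(out$flags$in_SE, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$flags$in_TE, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  s <- out$summary
  expect_equal(s$n_se_only + s$n_te_only + s$n_both + s$n_neither,
               s$n_total)
  expect_equal(out$mcnemar_p, mcnemar_exact_p(3, 1))
  expect_error(enhancer_colocalize(vars[0, ], enh), "empty")
})

test_that("PWM allele scoring matches arithmetic and strand symmetry", {
  # uniform PWM: any substitution has delta 0
  uni <- pwm_from_counts(matrix(0.25, 4, 3), pseudocount = 0)
  res <- pwm_allele_score(uni, "ACGTACG", 4, "T", "G")
  expect_equal(res$delta, 0)

  # 1-position PWM, f(G) = 0.97 vs f(A) = 0.01: delta = log2(0.01/0.97)
  m1 <- matrix(c(0.01, 0.01, 0.97, 0.01), 4, 1,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  p1 <- pwm_from_counts(m1, pseudocount = 0)
  r1 <- pwm_allele_score(p1, "G", 1, "G", "A")
  expect_equal(r1$delta, log2(0.01 / 0.97), tolerance = 1e-6)

  # reverse-complement of the window gives identical scores
  set.seed(63)
  counts <- matrix(rpois(4 * 6, 20) + 1, 4, 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(counts)
  win <- "TTACGTGACCA"
  off <- 5
  ref <- substr(win, off, off)
  fwd <- pwm_allele_score(pwm, win, off, ref, "A")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(win, "")[[1]]),
                                     collapse = ""))
  rc_off <- nchar(win) - off + 1
  rc_ref <- substr(rc, rc_off, rc_off)
  rev_res <- pwm_allele_score(pwm, rc, rc_off, rc_ref, "T")
  expect_equal(fwd$score_ref, rev_res$score_ref, tolerance = 1e-12)
  expect_equal(fwd$delta, rev_res$delta, tolerance = 1e-12)

  expect_error(pwm_allele_score(pwm, win, 5, "C", "A"), "disagrees")
})

test_that("JASPAR matrix files parse into normalized frequencies", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0000.1 TOY",
    "A [ 10  0  5 ]",
    "C [  0 20  5 ]",
    "G [ 10  0  5 ]",
    "T [  0  0  5 ]"), path)
  pwm <- read_pwm_jaspar(path, pseudocount = 0)
  expect_equal(dim(pwm$freq), c(4L, 3L))
  expect_equal(colSums(pwm$freq), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unname(pwm$freq["C", 2]), 1)
  expect_equal(pwm$id, "MA0000.1 TOY")
  unlink(path)
})

test_that("Spearman correlation matches known rank arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_expression(x, x)$rho, 1)
  expect_equal(correlate_expression(x, -x)$rho, -1)
  # rank displacement d = (-1, 1, -1, 1, 0): rho = 1 - 6*4/(5*24) = 0.8
  r <- correlate_expression(x, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))
  const <- correlate_expression(x, rep(1, 5))
  expect_true(is.na(const$rho))
  expect_equal(const$flag, "constant_vector")
  expect_error(correlate_expression(1:2, 1:2), "at least 3")
})

test_that("DEG-event intersection counts events by family with boundaries", {
  mk <- function(genes, lfc, p, family, a, b) {
    tab <- data.frame(gene_id = genes, log2fc = lfc, p = p)
    attr(tab, "family") <- family
    attr(tab, "area_a") <- a
    attr(tab, "area_b") <- b
    tab
  }
  res <- list(
    mk("G1", log2(1.5), 0.01, "WH_L", "BA22", "BA44"),   # boundary: kept
    mk("G1", 2, 0.01, "WH_L", "BA22", "BA41"),
    mk("G1", 2, 0.2, "WH_R", "BA22", "BA44"),            # p too large
    mk("G2", 0.3, 0.01, "LR", "BA44", "BA44"),           # fc too small
    mk("G3", -2, 0.01, "LR", "BA44", "BA44"))
  out <- intersect_degs(c("G1", "G2", "G3"), res)
  expect_equal(out$n_genes, 2)
  expect_equal(sort(out$genes), c("G1", "G3"))
  expect_equal(unname(out$events_by_family["WH_L"]), 2L)
  expect_equal(unname(out$events_by_family["WH_R"]), 0L)
  expect_equal(unname(out$events_by_family["LR"]), 1L)

  none <- intersect_degs("G9", res)
  expect_equal(none$n_genes, 0)
})
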