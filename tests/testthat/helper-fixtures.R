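# Shared synthetic fixtures, built in code at test time.

# small bilateral cohort with optional injected lateralization
make_cohort <- function(n_genes = 300, n_donors = 5,
                        areas = c("BA44", "BA22"), dispersion = 0.05,
                        lateralized = NULL, seed = 1, ...) {
  simulate_expression(expression_sim_spec(
    n_genes = n_genes, n_donors = n_donors, areas = areas,
    dispersion = dispersion, lateralized_genes = lateralized,
    seed = seed, ...))
}

# the 20-syllable USV fixture: alternating 50 kHz tones and gentle
# 40 -> 47.5 kHz chirps (0.5 kHz/ms, below one frequency bin per analysis
# window), 15 ms calls, 70 ms separation, ~37 dB SNR
usv_fixture_spec <- function(seed = 11) {
  n <- 20
  usv_sim_spec(
    syllables = data.frame(
      onset = 0.06 + (seq_len(n) - 1) * 0.085,
      duration = 0.015,
      type = rep(c("tone", "chirp"), n / 2),
      f_start = rep(c(50e3, 40e3), n / 2),
      f_end = rep(c(50e3, 47.5e3), n / 2),
      amplitude = 0.5),
    noise_floor = 0.005, ramp_s = 0.00025, seed = seed)
}

# match detected segments to ground-truth syllables by onset proximity
match_segments <- function(segments, truth, tol_s = 0.01) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- abs(segments$onset - truth$onset[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) j else NA_integer_
  }, integer(1))
}

# tiny GFF3 gene model written to a temp file: one +strand gene with two
# exons (UTR annotated), one -strand single-exon gene
write_toy_gff3 <- function() {
  path <- tempfile(fileext = ".gff3")
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1000\t3000\t.\t+\t.\tID=geneA",
    "chr1\ttoy\tmRNA\t1000\t3000\t.\t+\t.\tID=mrnaA;Parent=geneA",
    "chr1\ttoy\texon\t1000\t1500\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\texon\t2500\t3000\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\tfive_prime_UTR\t1000\t1099\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\tCDS\t1100\t1500\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\tCDS\t2500\t2900\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\tthree_prime_UTR\t2901\t3000\t.\t+\t.\tParent=mrnaA",
    "chr1\ttoy\tgene\t10000\t12000\t.\t-\t.\tID=geneB",
    "chr1\ttoy\tmRNA\t10000\t12000\t.\t-\t.\tID=mrnaB;Parent=geneB",
    "chr1\ttoy\texon\t10000\t12000\t.\t-\t.\tParent=mrnaB",
    "chr1\ttoy\tCDS\t10000\t12000\t.\t-\t.\tParent=mrnaB")
  writeLines(lines, path)
  path
}
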