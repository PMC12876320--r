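# Donor-paired differential expression: contrast construction, filtering,
# engines, and the multi-level FDR.

test_that("contrast construction keeps paired donors and ledgers covariates", {
  sim <- make_cohort(n_genes = 50, n_donors = 5,
                     areas = c("BA44", "BA41"), seed = 21)
  cs <- build_contrast(sim$meta, "LR", "BA44")
  expect_equal(length(cs$donors_used), 5)
  expect_equal(levels(cs$condition), c("L", "R"))

  # a donor missing right BA41 is dropped for LR-BA41
  meta2 <- sim$meta[!(sim$meta$donor == "donor01" &
                        sim$meta$hemisphere == "R" &
                        sim$meta$area == "BA41"), ]
  cs2 <- build_contrast(meta2, "LR", "BA41")
  expect_false("donor01" %in% cs2$donors_used)
  expect_true("donor01" %in% cs2$donors_dropped)

  # constant covariate excluded with reason "constant"
  meta3 <- sim$meta
  meta3$sex <- "M"
  cs3 <- build_contrast(meta3, "LR", "BA44")
  expect_false(cs3$ledger$sex$included)
  expect_equal(cs3$ledger$sex$reason, "constant")

  # fewer than two paired donors is an informative error
  meta4 <- sim$meta[sim$meta$donor %in% c("donor01", "donor02"), ]
  meta4 <- meta4[!(meta4$donor == "donor02" & meta4$hemisphere == "R"), ]
  expect_error(build_contrast(meta4, "LR", "BA44"), "at least 2")

  expect_error(build_contrast(sim$meta, "LR", "BA99"), "BA99")
  expect_error(build_contrast(sim$meta, "WH_L", "BA44", "BA44"),
               "two different areas")
})

test_that("the expression filter implements the total/nonzero rule", {
  counts <- rbind(
    a = c(10L, 0L, 0L, 0L),   # nonzero in 1 sample: dropped
    b = c(3L, 3L, 3L, 1L),    # total 10, nonzero 4: retained
    c = c(9L, 0L, 0L, 0L),    # total 9: dropped
    d = c(2L, 3L, 3L, 1L),    # total 9: dropped
    e = c(4L, 3L, 3L, 0L))    # total 10, nonzero 3: retained
  colnames(counts) <- paste0("s", 1:4)
  expect_equal(filter_genes(counts, colnames(counts)), c("b", "e"))
})

test_that("moderated t recovers injected effects and respects sign symmetry", {
  # a 10% lateralized fraction keeps the most-genes-unchanged assumption
  # behind TMM normalization realistic
  lat <- data.frame(gene = sprintf("gene%05d", 1:100), area = "BA44",
                    log2fc = 2)
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 1000, n_donors = 5, areas = "BA44", dispersion = 0.05,
    lateralized_genes = lat, seed = 22))
  cs <- build_contrast(sim$meta, "LR", "BA44")
  fit <- suppressMessages(fit_contrast(sim$counts, cs))
  est <- mean(fit$log2fc[fit$gene_id %in% lat$gene])
  expect_true(abs(est - 2) < 0.3)

  # swapping condition labels negates log2fc and statistic, keeps p
  cs_sw <- cs
  cs_sw$condition <- factor(ifelse(cs$condition == "L", "R", "L"),
                            levels = c("L", "R"))
  fit_sw <- suppressMessages(fit_contrast(sim$counts, cs_sw))
  expect_equal(fit_sw$log2fc, -fit$log2fc, tolerance = 1e-10)
  expect_equal(fit_sw$statistic, -fit$statistic, tolerance = 1e-10)
  expect_equal(fit_sw$p, fit$p, tolerance = 1e-10)
})

test_that("a zero-variance gene is flagged with p = 1", {
  sim <- make_cohort(n_genes = 40, n_donors = 4, areas = "BA44",
                     libsize_sd = 0, seed = 23)
  sim$counts[3, ] <- 50L  # constant across samples
  cs <- build_contrast(sim$meta, "LR", "BA44")
  fit <- suppressMessages(fit_contrast(sim$counts, cs))
  row <- fit[fit$gene_id == rownames(sim$counts)[3], ]
  expect_equal(row$flag, "zero_variance")
  expect_equal(row$p, 1)
  expect_true(is.na(row$statistic))
})

test_that("with zero prior df the moderated t reduces to the paired t-test", {
  sim <- make_cohort(n_genes = 60, n_donors = 5, areas = "BA44", seed = 24)
  cs <- build_contrast(sim$meta, "LR", "BA44")
  fit <- suppressMessages(
    fit_contrast(sim$counts, cs, prior_df = 0, trend = FALSE))
  # independent route: ordinary paired t-test on the same log-CPM
  sub <- sim$counts[filter_genes(sim$counts, cs), cs$sample_ids]
  lc <- log_cpm(sub, tmm_factors(sub))$values
  for (g in sample(rownames(lc), 10)) {
    d <- vapply(levels(cs$donor), function(dn) {
      l <- cs$sample_ids[cs$donor == dn & cs$condition == "L"]
      r <- cs$sample_ids[cs$donor == dn & cs$condition == "R"]
      lc[g, r] - lc[g, l]
    }, numeric(1))
    tt <- t.test(d)
    row <- fit[fit$gene_id == g, ]
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("the unmoderated fit agrees with limma's ordinary statistics", {
  skip_if_not_installed("limma")
  sim <- make_cohort(n_genes = 80, n_donors = 5, areas = "BA44", seed = 25)
  cs <- build_contrast(sim$meta, "LR", "BA44")
  fit <- suppressMessages(
    fit_contrast(sim$counts, cs, prior_df = 0, trend = FALSE))
  sub <- sim$counts[filter_genes(sim$counts, cs), cs$sample_ids]
  lc <- log_cpm(sub, tmm_factors(sub))$values
  X <- model.matrix(~cs$donor + cs$condition)
  lf <- limma::lmFit(lc, X)
  ord_t <- lf$coefficients[, ncol(X)] /
    (lf$stdev.unscaled[, ncol(X)] * lf$sigma)
  expect_equal(fit$log2fc, unname(lf$coefficients[, ncol(X)]),
               tolerance = 1e-8)
  expect_equal(fit$statistic, unname(ord_t), tolerance = 1e-8)
})

test_that("the negative-binomial Wald engine recovers injected effects", {
  skip_if_not_installed("DESeq2")
  lat <- data.frame(gene = sprintf("gene%05d", 1:20), area = "BA44",
                    log2fc = 2)
  sim <- simulate_expression(expression_sim_spec(
    n_genes = 100, n_donors = 5, areas = "BA44", dispersion = 0.05,
    lateralized_genes = lat, seed = 26))
  cs <- build_contrast(sim$meta, "LR", "BA44")
  fit <- suppressWarnings(suppressMessages(
    fit_contrast(sim$counts, cs, engine = "nb_wald")))
  est <- mean(fit$log2fc[fit$gene_id %in% lat$gene])
  expect_true(abs(est - 2) < 0.4)
  expect_true(all(fit$p[fit$flag == ""] >= 0 & fit$p[fit$flag == ""] <= 1))
})

test_that("aliased donor-level covariates are dropped (or error on request)", {
  sim <- make_cohort(n_genes = 40, n_donors = 5, areas = "BA44", seed = 27)
  cs <- build_contrast(sim$meta, "LR", "BA44")
  # donor-level covariates are collinear with donor blocks by design
  if (length(cs$covariate_data)) {
    expect_message(fit_contrast(sim$counts, cs), "aliased")
    expect_error(fit_contrast(sim$counts, cs, on_aliased = "error"),
                 "aliased")
  } else succeed()
})

test_that("multi-level adjustment collapses, pools, and labels modules", {
  sim <- make_cohort(n_genes = 60, n_donors = 5,
                     areas = c("BA44", "BA45", "BA22"), seed = 28)
  f1 <- suppressMessages(
    fit_contrast(sim$counts, build_contrast(sim$meta, "LR", "BA44")))

  # single contrast: all pooled levels equal the within-contrast BH
  adj1 <- adjust_multilevel(list(f1))[[1]]
  expect_equal(adj1$q_contrast, adj1$q_global)
  expect_equal(adj1$q_contrast, adj1$q_family)
  expect_equal(adj1$module_label[1], "Broca")
  expect_equal(adj1$q_contrast, adj1$q_module)

  # WH pair spanning Broca and Wernicke is mixed, no module-level q
  f2 <- suppressMessages(
    fit_contrast(sim$counts, build_contrast(sim$meta, "WH_L", "BA44", "BA22")))
  f3 <- suppressMessages(
    fit_contrast(sim$counts, build_contrast(sim$meta, "WH_L", "BA44", "BA45")))
  adj <- adjust_multilevel(list(lr = f1, mixed = f2, broca = f3))
  expect_equal(unique(adj$mixed$module_label), "mixed")
  expect_true(all(is.na(adj$mixed$q_module)))
  expect_equal(unique(adj$broca$module_label), "Broca")
  expect_false(anyNA(adj$broca$q_module))
  expect_error(adjust_multilevel(list(f1), module_map = c(BA45 = "Broca")),
               "BA44")
})

test_that("BH agrees with the step-up oracle on short vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(31)
  for (n in 1:12) {
    for (rep in 1:10) {
      p <- round(runif(n), 3)
      expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("BH q-values are monotone under the step-up ordering", {
  set.seed(32)
  p <- runif(50)
  q <- p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p.adjust(p, "BH")))  # self-consistency floor
})
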