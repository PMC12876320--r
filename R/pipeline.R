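# End-to-end orchestration: a single YAML config drives synthetic-cohort
# simulation, donor-paired DE, lateralization summaries, handedness
# inference, the variant cascade and the USV pipeline, writing TSV outputs
# and a provenance manifest.  A fixed config and seed give byte-identical
# outputs; the global seed expands to per-stage seeds by a counter scheme
# (stage_seed = (seed * 101 + stage_counter) mod 2^31 - 1).

PIPELINE_STAGES <- c("simulate", "de", "laterality", "handedness",
                     "variants", "usv")

#' Default pipeline configuration
#'
#' The built-in demo: a five-donor bilateral cohort over one language
#' (BA44), one auditory (BA41), one Wernicke (BA22) and one motor (BA4)
#' area with a dozen injected lateralized genes, a toy variant resource
#' bundle, and a short synthetic USV bout.
#'
#' @return nested named list of all stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "results/pipeline",
    stages = PIPELINE_STAGES,
    simulate = list(
      n_genes = 300L, n_donors = 5L,
      areas = c("BA44", "BA22", "BA41", "BA4"),
      baseline_mean = 100, dispersion = 0.05,
      n_lateralized = 12L, lateral_log2fc = 2,
      lateral_area = "BA44",
      donor_sd = 0.2, gene_sd = 1, libsize_sd = 0.2
    ),
    de = list(engine = "moderated_t", alpha = 0.05),
    laterality = list(q_field = "q_contrast", alpha = 0.05),
    handedness = list(prior = 0.9, normalization = "cosine"),
    variants = list(
      n_snps = 60L, panel_size = 200L,
      block_loci = 10L, block_r2 = 0.95,
      p_max = 1e-5, r2_min = 0.8, window_bp = 5e5,
      n_se = 6L, n_te = 6L
    ),
    usv = list(
      n_syllables = 12L, noise_floor = 0.002, amplitude = 0.5,
      k = 2L
    )
  )
}

#' Validate a pipeline configuration
#'
#' Reads YAML (or takes a list), fills defaults, rejects unknown keys,
#' and type-checks the filled values.
#'
#' @param config path to a YAML file or a nested list.
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML mapping")
  def <- default_config()
  collector <- new.env()
  collector$collected <- character()
  merged <- merge_config(config, def, path = "", errors = collector)
  errors <- collector$collected
  if (!is.null(merged$stages)) {
    if (identical(merged$stages, "all")) merged$stages <- PIPELINE_STAGES
    bad <- setdiff(merged$stages, PIPELINE_STAGES)
    if (length(bad))
      errors <- c(errors, paste0("unknown stage(s): ",
                                 paste(bad, collapse = ", ")))
  }
  if (!is.numeric(merged$seed) || merged$seed != floor(merged$seed))
    errors <- c(errors, "seed must be an integer")
  if (length(errors))
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  merged$seed <- as.integer(merged$seed)
  class(merged) <- "run_config"
  merged
}

# recursive default fill + unknown-key detection; collects error strings
# in the `errors` environment
merge_config <- function(user, def, path, errors) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    errors$collected <- c(errors$collected,
                          paste0("unknown key(s)", if (nzchar(path))
                            paste0(" in ", path), ": ",
                            paste(unknown, collapse = ", ")))
  out <- def
  for (k in intersect(names(user), names(def))) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      out[[k]] <- merge_config(as.list(user[[k]]), def[[k]],
                               paste0(path, if (nzchar(path)) ".", k),
                               errors)
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order, writes each
#' stage's tables under `outdir`, and finishes with `manifest.tsv`
#' recording the package version, the global and per-stage seeds, and an
#' MD5 digest of every output file.  Identical config and inputs give
#' identical outputs.
#'
#' @param config a [validate_config()] result, a path, or a list.
#' @param outdir override for the configured output directory.
#' @return invisibly, a list: `status` (0 on success), `manifest`
#'   (data frame), `outputs` (named list of in-memory stage results).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env()
  files <- character()
  seeds <- integer()
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% config$stages) next
    counter <- match(stage, PIPELINE_STAGES)
    sseed <- stage_seed(config$seed, counter)
    seeds[stage] <- sseed
    fn <- get(paste0("stage_", stage), mode = "function")
    files <- c(files, tryCatch(fn(config, env, sseed),
                               error = function(e)
                                 stop("stage '", stage, "' failed: ",
                                      conditionMessage(e), call. = FALSE)))
  }
  manifest <- data.frame(
    file = c("_package_version", "_global_seed",
             if (length(seeds)) paste0("_seed_", names(seeds)),
             files),
    value = c(as.character(utils::packageVersion("hemivox")),
              as.character(config$seed),
              if (length(seeds)) as.character(seeds),
              unname(tools::md5sum(file.path(config$outdir, files)))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  invisible(list(status = 0L, manifest = manifest,
                 outputs = as.list(env)))
}

stage_simulate <- function(config, env, seed) {
  p <- config$simulate
  lat <- NULL
  if (p$n_lateralized > 0) {
    lat <- data.frame(
      gene = sprintf("gene%05d", seq_len(p$n_lateralized)),
      area = p$lateral_area,
      log2fc = p$lateral_log2fc
    )
  }
  spec <- expression_sim_spec(
    n_genes = p$n_genes, n_donors = p$n_donors, areas = p$areas,
    baseline_mean = p$baseline_mean, dispersion = p$dispersion,
    lateralized_genes = lat, donor_sd = p$donor_sd, gene_sd = p$gene_sd,
    libsize_sd = p$libsize_sd, seed = seed)
  env$cohort <- simulate_expression(spec)
  write_counts(env$cohort$counts, env$cohort$meta,
               file.path(config$outdir, "counts.tsv"),
               file.path(config$outdir, "meta.tsv"))
  write_tsv(env$cohort$truth, file.path(config$outdir, "truth.tsv"))
  c("counts.tsv", "meta.tsv", "truth.tsv")
}

stage_de <- function(config, env, seed) {
  if (is.null(env$cohort)) stop("requires the simulate stage")
  counts <- env$cohort$counts
  meta <- env$cohort$meta
  areas <- unique(meta$area)
  specs <- list()
  for (a in areas)
    specs[[paste0("LR_", a)]] <- build_contrast(meta, "LR", a)
  if (length(areas) > 1) {
    pairs <- utils::combn(sort(areas), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      specs[[paste0("WH_L_", a, "_", b)]] <-
        build_contrast(meta, "WH_L", a, b)
      specs[[paste0("WH_R_", a, "_", b)]] <-
        build_contrast(meta, "WH_R", a, b)
    }
  }
  fits <- lapply(specs, function(s)
    suppressMessages(fit_contrast(counts, s, engine = config$de$engine)))
  mm <- default_module_map()
  extra <- setdiff(unique(meta$area), names(mm))
  if (length(extra)) mm[extra] <- "other"
  env$de <- adjust_multilevel(fits, module_map = mm)
  files <- character()
  for (nm in names(env$de)) {
    f <- paste0("de_", sanitize_id(nm), ".tsv")
    write_tsv(env$de[[nm]], file.path(config$outdir, f))
    files <- c(files, f)
  }
  files
}

stage_laterality <- function(config, env, seed) {
  if (is.null(env$de)) stop("requires the de stage")
  fams <- vapply(env$de, function(r) attr(r, "family"), character(1))
  counts <- count_significant(env$de, q_field = config$laterality$q_field,
                              alpha = config$laterality$alpha)
  count_tab <- data.frame(contrast = names(env$de), family = fams,
                          n_significant = as.integer(counts),
                          log10_n_plus_1 = log_count_map(as.integer(counts)))
  env$dumbbell <- dumbbell_table(env$de[fams == "WH_L"],
                                 env$de[fams == "WH_R"],
                                 q_field = config$laterality$q_field,
                                 alpha = config$laterality$alpha)
  write_tsv(count_tab, file.path(config$outdir, "significant_counts.tsv"))
  write_tsv(env$dumbbell, file.path(config$outdir, "dumbbell.tsv"))
  c("significant_counts.tsv", "dumbbell.tsv")
}

stage_handedness <- function(config, env, seed) {
  if (is.null(env$cohort)) stop("requires the simulate stage")
  areas <- unique(env$cohort$meta$area)
  lang <- intersect(default_region_sets()$language, areas)
  mot <- intersect(default_region_sets()$motor, areas)
  if (!length(lang) || !length(mot))
    stop("cohort lacks language or motor areas for handedness inference")
  env$handedness <- suppressMessages(
    lodo_run(env$cohort$counts, env$cohort$meta,
             language_regions = lang, motor_regions = mot,
             prior = config$handedness$prior,
             normalization = config$handedness$normalization))
  write_tsv(env$handedness, file.path(config$outdir, "handedness.tsv"))
  "handedness.tsv"
}

stage_variants <- function(config, env, seed) {
  p <- config$variants
  spec <- variant_sim_spec(
    n_snps = p$n_snps, haplotype_panel_size = p$panel_size,
    ld_blocks = data.frame(n_loci = p$block_loci, target_r2 = p$block_r2),
    seed = seed)
  res <- suppressWarnings(
    simulate_variant_resources(spec, n_se = p$n_se, n_te = p$n_te))
  sent <- select_sentinels(res$gwas, p_max = p$p_max)
  expanded <- suppressWarnings(
    ld_expand(sent, res$panel, res$loci, r2_min = p$r2_min,
              window_bp = p$window_bp))
  eq <- intersect_eqtl(expanded, res$eqtl)
  coloc <- enhancer_colocalize(expanded, res$enhancers)
  env$variants <- list(sentinels = sent, expanded = expanded,
                       eqtl = eq, coloc = coloc)
  write_tsv(sent, file.path(config$outdir, "sentinels.tsv"))
  write_tsv(expanded, file.path(config$outdir, "ld_expanded.tsv"))
  write_tsv(eq$hits, file.path(config$outdir, "eqtl_hits.tsv"))
  coloc_tab <- cbind(coloc$summary, mcnemar_p = coloc$mcnemar_p)
  write_tsv(coloc_tab, file.path(config$outdir, "enhancer_coloc.tsv"))
  c("sentinels.tsv", "ld_expanded.tsv", "eqtl_hits.tsv",
    "enhancer_coloc.tsv")
}

stage_usv <- function(config, env, seed) {
  p <- config$usv
  n <- p$n_syllables
  # alternating flat tones and rising chirps, well separated
  onsets <- 0.05 + (seq_len(n) - 1) * 0.08
  syl <- data.frame(
    onset = onsets, duration = 0.02,
    type = rep(c("tone", "chirp"), length.out = n),
    f_start = rep(c(50e3, 40e3), length.out = n),
    f_end = rep(c(50e3, 80e3), length.out = n),
    amplitude = p$amplitude
  )
  audio <- simulate_usv_audio(usv_sim_spec(syllables = syl,
                                           noise_floor = p$noise_floor,
                                           seed = seed))
  spec <- usv_spectrogram(audio$waveform, audio$sample_rate)
  segs <- detect_segments(spec)
  feats <- extract_features(spec, segs)
  contours <- lapply(seq_len(nrow(segs)), function(i)
    extract_contour(spec, segs[i, ]))
  cl <- if (nrow(segs) >= 2)
    cluster_syllables(contours, k = p$k, seed = seed)
  else NULL
  env$usv <- list(truth = audio$truth, segments = segs, features = feats,
                  clusters = cl)
  write_tsv(audio$truth, file.path(config$outdir, "usv_truth.tsv"))
  write_tsv(segs, file.path(config$outdir, "usv_segments.tsv"))
  write_tsv(feats, file.path(config$outdir, "usv_features.tsv"))
  files <- c("usv_truth.tsv", "usv_segments.tsv", "usv_features.tsv")
  if (!is.null(cl)) {
    write_tsv(data.frame(segment = seq_along(cl$assignments),
                         cluster = cl$assignments),
              file.path(config$outdir, "usv_clusters.tsv"))
    files <- c(files, "usv_clusters.tsv")
  }
  files
}
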