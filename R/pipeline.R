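# End-to-end orchestration: call (variant + histone) -> merge -> score ->
# select -> associate/classify -> metagene/entropy. Intermediate artifacts
# are plain TSV/BED files so each stage can be audited and re-run on its
# own; every output starts with a header recording the package version,
# a config hash and the seed.

#' Pipeline configuration
#'
#' @param variant,histone,igg,input paths to the four channel bedGraphs.
#' @param annotation path to the GFF3 feature annotation.
#' @param expression path to the gene x condition expression TSV.
#' @param outdir output directory.
#' @param caller a [caller_params()].
#' @param scoring a [scoring_params()].
#' @param association an [association_params()].
#' @param flank,bin_size,n_body_bins,n_expression_bins metagene settings.
#' @param seed integer seed recorded in all outputs and used for the
#'   resampling stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(variant, histone, igg, input, annotation,
                            expression, outdir,
                            caller = caller_params(),
                            scoring = scoring_params(),
                            association = association_params(seed = seed),
                            flank = 3000, bin_size = 50, n_body_bins = 100,
                            n_expression_bins = 4, seed = 1) {
  structure(list(variant = variant, histone = histone, igg = igg,
                 input = input, annotation = annotation,
                 expression = expression, outdir = outdir,
                 caller = caller, scoring = scoring,
                 association = association, flank = flank,
                 bin_size = bin_size, n_body_bins = n_body_bins,
                 n_expression_bins = n_expression_bins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# polynomial rolling hash over the serialized analytic configuration
# (the output directory does not affect the results and is excluded)
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run summary (also written as `summary.json`):
#'   per-stage counts, gene-category counts, the fitted mixture parameters
#'   and the protein-coding enrichment versus random resampling.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (ch in c("variant", "histone", "igg", "input", "annotation",
               "expression"))
    if (!file.exists(config[[ch]]))
      stop("missing input for channel/file '", ch, "': ", config[[ch]])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("varnuc ", as.character(utils::packageVersion("varnuc"))),
           paste0("config_hash=", .config_hash(config)),
           paste0("seed=", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  trk <- stage("read_tracks", lapply(
    config[c("variant", "histone", "igg", "input")], read_probe_track))
  genes <- stage("read_annotation", read_annotation(config$annotation))
  expr <- stage("read_expression",
                read_expression_table(config$expression))

  calls_v <- stage("call_variant",
                   call_nucleosomes(trk$variant, config$caller, "variant"))
  calls_h <- stage("call_histone",
                   call_nucleosomes(trk$histone, config$caller, "histone"))
  calls <- stage("merge", merge_calls(calls_v, calls_h,
                                      config$caller$merge_distance))
  scored <- stage("score", score_nucleosomes(calls, trk$variant,
                                             trk$histone, trk$igg,
                                             config$scoring))
  scored <- stage("select",
                  select_variant_nucleosomes(scored,
                                             params = config$scoring))
  mix <- attr(scored, "mixture")
  write_nucleosome_calls(scored, file.path(config$outdir, "nucleosomes.bed"),
                         header = hdr)

  sel <- scored[selected == TRUE]
  assoc <- stage("associate", nearest_feature(
    sel, genes, config$association$max_distance))
  classified <- stage("classify", classify_positions(
    sel, genes[feature_type == "protein_coding"], config$association))
  categories <- stage("categories", gene_h33_categories(genes, classified))
  comp <- stage("composition", feature_composition(assoc))
  enr <- stage("enrichment_vs_random", enrichment_vs_random(
    sel$id, scored, genes, params = config$association))
  .write_tsv(assoc, file.path(config$outdir, "associations.tsv"), hdr)
  .write_tsv(classified, file.path(config$outdir, "position_classes.tsv"),
             hdr)
  .write_tsv(categories, file.path(config$outdir, "gene_categories.tsv"),
             hdr)
  .write_tsv(comp, file.path(config$outdir, "feature_composition.tsv"), hdr)

  # metagene of variant/histone log2 ratio by expression bin
  ratio <- stage("ratio_track", {
    m <- match(paste(trk$variant$chrom, trk$variant$pos),
               paste(trk$histone$chrom, trk$histone$pos))
    keep <- !is.na(m)
    probe_track(trk$variant$chrom[keep], trk$variant$pos[keep],
                trk$variant$value[keep] - trk$histone$value[m[keep]])
  })
  ebins <- stage("expression_bins",
                 bin_by_expression(expr, n_bins = config$n_expression_bins))
  profs <- stage("metagene", suppressWarnings(grouped_profiles(
    ratio, genes[feature_type == "protein_coding"],
    setNames(paste0("bin", ebins$assignment), names(ebins$assignment)),
    flank = config$flank, bin_size = config$bin_size,
    n_body_bins = config$n_body_bins)))
  prof_dt <- rbindlist(lapply(names(profs), function(g) {
    p <- profs[[g]]
    data.table(group = g,
               segment = rep(c("upstream", "body", "downstream"),
                             c(length(p$upstream_bins),
                               length(p$body_bins),
                               length(p$downstream_bins))),
               bin = c(seq_along(p$upstream_bins), seq_along(p$body_bins),
                       seq_along(p$downstream_bins)),
               mean = c(p$upstream_bins, p$body_bins, p$downstream_bins),
               n = c(p$upstream_n, p$body_n, p$downstream_n))
  }))
  .write_tsv(prof_dt, file.path(config$outdir, "metagene_profiles.tsv"),
             hdr)

  ent <- stage("entropy", entropy_table(expr))
  .write_tsv(ent, file.path(config$outdir, "expression_entropy.tsv"), hdr)
  report <- stage("report", group_comparison_report(
    setNames(ent$entropy, ent$gene_id), categories))
  .write_tsv(report, file.path(config$outdir, "entropy_report.tsv"), hdr)

  cat_counts <- attr(categories, "counts")
  summary <- list(
    version = as.character(utils::packageVersion("varnuc")),
    config_hash = .config_hash(config), seed = config$seed,
    n_positioned = nrow(scored),
    n_variant_calls = nrow(calls_v), n_histone_calls = nrow(calls_h),
    n_selected = nrow(sel),
    n_associated = sum(!is.na(assoc$feature_id)),
    association_rate_pct = percent(sum(!is.na(assoc$feature_id)),
                                   max(nrow(sel), 1)),
    n_promoter = sum(classified$position_class == "promoter"),
    n_tts = sum(classified$position_class == "TTS"),
    gene_categories = as.list(cat_counts),
    mixture = list(weights = mix$weights, means = mix$means,
                   variances = mix$variances),
    protein_coding_fold = enr$fold, protein_coding_p = enr$p_value)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
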