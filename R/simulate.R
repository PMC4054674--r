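# Synthetic tiling-array data with planted nucleosome footprints.
#
# The generator emulates normalized log2-scale probe signal over a tiled
# genome: a bulk-histone ChIP channel carrying a smooth kernel at every
# planted nucleosome, a variant (H3.3) channel carrying kernel mass only at
# variant-bearing nucleosomes, an IgG channel of pure noise and a flat input
# channel. Gene models carry strand, TSS/TTS, a core-promoter class and a
# multi-condition expression vector, so feature association, metagene
# profiles, expression bins and entropy all have planted ground truth.

#' Simulation configuration
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param probe_spacing bp between probe centers (default 10; denser than a
#'   real tiling array so grid artifacts do not dominate).
#' @param n_genes total gene count across the genome.
#' @param nucleosome_footprint bp protected by one nucleosome (default 147).
#' @param h33_fraction fraction of planted nucleosomes carrying the variant.
#' @param promoter_class_probs named probabilities over TATA/GA/coreless,
#'   summing to 1 (assigned to protein-coding genes; other feature types
#'   get class `"unknown"`).
#' @param feature_type_probs named probabilities over the feature-type
#'   vocabulary, summing to 1 (default: mostly protein-coding with a
#'   minority of TE genes, pseudogenes and ncRNAs, roughly the proportions
#'   of a euchromatic plant chromosome arm).
#' @param noise_sd SD of additive Gaussian noise on the log2 signal, per
#'   probe per channel.
#' @param n_conditions number of expression conditions.
#' @param n_nucleosomes exact number of nucleosomes to plant per chromosome
#'   (NULL = derive from `nucleosome_spacing`).
#' @param nucleosome_spacing mean center-to-center spacing, bp, used when
#'   `n_nucleosomes` is NULL.
#' @param kernel_height mean peak amplitude of a planted nucleosome on the
#'   log2 scale (default 2, i.e. ~4-fold ChIP enrichment at the dyad).
#' @param expression_zero_prob probability that a gene has no detectable
#'   transcripts (all-zero expression vector).
#' @param seed integer RNG seed.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 2e6,
                              n_chromosomes = 1,
                              probe_spacing = 10,
                              n_genes = 400,
                              nucleosome_footprint = 147,
                              h33_fraction = 0.3,
                              promoter_class_probs = c(TATA = 0.3, GA = 0.2,
                                                       coreless = 0.5),
                              feature_type_probs = c(protein_coding = 0.8,
                                                     TE_gene = 0.1,
                                                     pseudogene = 0.05,
                                                     ncRNA = 0.05),
                              noise_sd = 0.3,
                              n_conditions = 8,
                              n_nucleosomes = NULL,
                              nucleosome_spacing = 400,
                              kernel_height = 2,
                              expression_zero_prob = 0.1,
                              seed = 1) {
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              probe_spacing = probe_spacing, n_genes = n_genes,
              nucleosome_footprint = nucleosome_footprint,
              h33_fraction = h33_fraction,
              promoter_class_probs = promoter_class_probs,
              feature_type_probs = feature_type_probs,
              noise_sd = noise_sd, n_conditions = n_conditions,
              n_nucleosomes = n_nucleosomes,
              nucleosome_spacing = nucleosome_spacing,
              kernel_height = kernel_height,
              expression_zero_prob = expression_zero_prob,
              seed = as.integer(seed))
  with(cfg, {
    if (genome_length <= 0 || n_chromosomes <= 0 || probe_spacing <= 0 ||
        n_genes <= 0 || nucleosome_footprint <= 0 || n_conditions <= 0 ||
        nucleosome_spacing <= 0)
      stop("all lengths and counts must be positive")
    if (h33_fraction < 0 || h33_fraction > 1)
      stop("h33_fraction must be in [0, 1]")
    if (abs(sum(promoter_class_probs) - 1) > 1e-9)
      stop("promoter_class_probs must sum to 1")
    if (abs(sum(feature_type_probs) - 1) > 1e-9)
      stop("feature_type_probs must sum to 1")
    if (!all(names(feature_type_probs) %in% FEATURE_TYPES))
      stop("feature_type_probs names must come from the feature vocabulary")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate gene models and planted nucleosomes
#'
#' Genes are laid out in non-overlapping slots (so no two genes on the same
#' strand overlap), assigned a promoter class and a multi-condition
#' expression vector (log-normal, zero-inflated; GA-class genes get a
#' condition-specific, low-entropy profile). Nucleosomes are planted as a
#' quasi-regular background plus anchored nucleosomes just upstream of
#' GA-class promoters (independent of expression) and around the TTS of
#' high-expression genes. Variant flags are assigned by weighted sampling so
#' that the overall variant fraction equals `h33_fraction` while variant
#' nucleosomes concentrate at GA promoters and high-expression TTSs.
#'
#' @param config a [simulation_config()].
#' @return list of class `genome_truth` with elements `genes` (data.table:
#'   id, chrom, strand, TSS, TTS, feature_type, promoter_class),
#'   `expression` (gene x condition matrix), `nucleosomes` (data.table:
#'   chrom, center, occupancy, has_variant, anchor), `condition_labels`,
#'   and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  fp <- config$nucleosome_footprint

  genes_per_chrom <- diff(round(seq(0, config$n_genes,
                                    length.out = config$n_chromosomes + 1)))
  gene_list <- vector("list", config$n_chromosomes)
  nuc_list <- vector("list", config$n_chromosomes)

  for (ci in seq_len(config$n_chromosomes)) {
    ng <- genes_per_chrom[ci]
    # --- genes in non-overlapping slots ---
    slot <- L / ng
    if (slot < 1500)
      stop("gene density too high: need >= 1500 bp per gene slot")
    len <- pmin(pmax(round(rlnorm(ng, log(2000), 0.5)), 300),
                floor(slot) - 600)
    start <- round((seq_len(ng) - 1) * slot +
                     runif(ng, 300, pmax(301, slot - len - 300)))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    ftype <- sample(names(config$feature_type_probs), ng, replace = TRUE,
                    prob = config$feature_type_probs)
    pclass <- ifelse(
      ftype == "protein_coding",
      sample(names(config$promoter_class_probs), ng, replace = TRUE,
             prob = config$promoter_class_probs),
      "unknown")
    genes <- data.table(
      id = sprintf("%s_g%04d", chroms[ci], seq_len(ng)),
      chrom = chroms[ci], strand = strand,
      TSS = ifelse(strand == "+", start, start + len),
      TTS = ifelse(strand == "+", start + len, start),
      feature_type = ftype, promoter_class = pclass)
    gene_list[[ci]] <- genes

    # --- anchored nucleosomes (protein-coding genes only) ---
    sgn <- ifelse(strand == "+", 1, -1)
    prom_centers <- round(genes$TSS - sgn * 150 + runif(ng, -20, 20))
    tts_centers <- round(genes$TTS + sgn * 50 + runif(ng, -30, 30))
    pc <- ftype == "protein_coding"
    anchored <- rbind(
      data.table(center = prom_centers[pclass == "GA"], anchor = "promoter",
                 gene = genes$id[pclass == "GA"]),
      data.table(center = tts_centers[pc], anchor = "TTS",
                 gene = genes$id[pc]))
    anchored <- anchored[center >= fp & center < L - fp]

    # --- quasi-regular background filling to the target count ---
    n_target <- if (!is.null(config$n_nucleosomes)) config$n_nucleosomes
      else round(L / config$nucleosome_spacing)
    n_bg <- max(0L, n_target - nrow(anchored))
    sp <- L / (n_bg + 1)
    bg <- round(seq_len(n_bg) * sp + runif(n_bg, -sp / 5, sp / 5))
    bg <- bg[bg >= fp & bg < L - fp]
    occupied <- sort(anchored$center)
    near <- findInterval(bg, occupied)
    d_lo <- bg - c(-Inf, occupied)[near + 1]
    d_hi <- c(occupied, Inf)[near + 1] - bg
    bg <- bg[pmin(d_lo, d_hi) > fp + 10]
    # top up one-by-one by rejection so the planted count is exact
    all_c <- sort(c(occupied, bg))
    while (length(bg) < n_bg) {
      cand <- round(runif(1, fp, L - fp))
      i <- findInterval(cand, all_c)
      if (min(cand - c(-Inf, all_c)[i + 1],
              c(all_c, Inf)[i + 1] - cand) > fp + 10) {
        bg <- c(bg, cand)
        all_c <- sort(c(all_c, cand))
      }
    }
    nucs <- rbind(
      data.table(center = as.numeric(anchored$center),
                 anchor = anchored$anchor, gene = anchored$gene),
      data.table(center = as.numeric(bg), anchor = "background",
                 gene = NA_character_))
    nucs[, chrom := chroms[ci]]
    nuc_list[[ci]] <- nucs
  }

  genes <- rbindlist(gene_list)
  nucs <- rbindlist(nuc_list)
  setorder(nucs, chrom, center)

  # --- expression: log-normal, zero-inflated; GA genes condition-specific ---
  nc <- config$n_conditions
  cond <- sprintf("cond%02d", seq_len(nc))
  level <- rlnorm(nrow(genes), log(100), 1.2)
  prof <- matrix(rlnorm(nrow(genes) * nc, 0, 0.3), ncol = nc)
  ga <- genes$promoter_class == "GA"
  if (any(ga)) {
    dom <- sample(nc, sum(ga), replace = TRUE)
    conc <- matrix(0.15, sum(ga), nc)
    conc[cbind(seq_len(sum(ga)), dom)] <- nc - 0.15 * (nc - 1)
    prof[ga, ] <- conc * matrix(rlnorm(sum(ga) * nc, 0, 0.2), ncol = nc)
  }
  expr <- prof / rowMeans(prof) * level
  expr[runif(nrow(genes)) < config$expression_zero_prob, ] <- 0
  dimnames(expr) <- list(genes$id, cond)

  # --- variant assignment: exact fraction, weighted to planted targets ---
  n_var <- round(config$h33_fraction * nrow(nucs))
  hi_expr <- rownames(expr)[rowMeans(expr) >=
                              quantile(rowMeans(expr), 0.75)]
  w <- rep(1, nrow(nucs))
  w[nucs$anchor == "promoter"] <- 400
  w[nucs$anchor == "TTS" & nucs$gene %in% hi_expr] <- 400
  has_variant <- rep(FALSE, nrow(nucs))
  if (n_var > 0)
    has_variant[sample.int(nrow(nucs), n_var, prob = w)] <- TRUE
  nucs[, has_variant := has_variant]
  nucs[, occupancy := rlnorm(.N, log(config$kernel_height), 0.15)]

  structure(list(genes = genes, expression = expr,
                 nucleosomes = nucs[, .(chrom, center, occupancy,
                                        has_variant, anchor, gene)],
                 condition_labels = cond, config = config),
            class = "genome_truth")
}

#' Raised-cosine nucleosome kernel
#'
#' `0.5 * (1 + cos(pi * x / w))` on `|x| <= w`: compactly supported and
#' twice differentiable, with full width at half maximum — and inflection
#' point separation — equal to `w`, the nucleosome footprint. The caller's
#' second-derivative support width of an isolated planted nucleosome is
#' therefore the footprint itself.
#'
#' @param x offset from the nucleosome center, bp.
#' @param w footprint, bp.
#' @return kernel value in [0, 1].
#' @export
nucleosome_kernel <- function(x, w) {
  ifelse(abs(x) <= w, 0.5 * (1 + cos(pi * x / w)), 0)
}

#' Simulate four-channel probe tracks from planted truth
#'
#' Probes sit on a regular grid of `probe_spacing`. The histone channel is
#' the sum of occupancy-weighted [nucleosome_kernel()]s over all planted
#' nucleosomes; the variant channel carries kernel mass only at
#' variant-bearing nucleosomes; IgG is a noise-only baseline and input is
#' flat. Gaussian noise of SD `noise_sd` is added i.i.d. per probe per
#' channel on the log2 scale.
#'
#' @param truth a `genome_truth` from [simulate_genome()].
#' @param config the matching [simulation_config()].
#' @return named list of [probe_track()]s:
#'   `variant`, `histone`, `igg`, `input`.
#' @export
simulate_probe_tracks <- function(truth, config) {
  stopifnot(inherits(truth, "genome_truth"))
  if (nrow(truth$nucleosomes) == 0) stop("truth contains no nucleosomes")
  set.seed(config$seed + 1L)
  fp <- config$nucleosome_footprint
  per_chrom <- function(cc) {
    pos <- seq(0, config$genome_length - 1, by = config$probe_spacing)
    nuc <- truth$nucleosomes[chrom == cc]
    base_h <- numeric(length(pos))
    base_v <- numeric(length(pos))
    for (i in seq_len(nrow(nuc))) {
      lo <- findInterval(nuc$center[i] - fp, pos) + 1
      hi <- findInterval(nuc$center[i] + fp, pos)
      if (hi < lo) next
      idx <- lo:hi
      k <- nuc$occupancy[i] * nucleosome_kernel(pos[idx] - nuc$center[i], fp)
      base_h[idx] <- base_h[idx] + k
      if (nuc$has_variant[i]) base_v[idx] <- base_v[idx] + k
    }
    list(pos = pos, histone = base_h, variant = base_v)
  }
  chroms <- unique(truth$nucleosomes$chrom)
  parts <- lapply(chroms, per_chrom)
  pos <- unlist(lapply(parts, `[[`, "pos"))
  cc <- rep(chroms, vapply(parts, function(p) length(p$pos), 1L))
  hist_sig <- unlist(lapply(parts, `[[`, "histone"))
  var_sig <- unlist(lapply(parts, `[[`, "variant"))
  n <- length(pos)
  noise <- function() if (config$noise_sd > 0)
    rnorm(n, 0, config$noise_sd) else numeric(n)
  list(variant = probe_track(cc, pos, var_sig + noise()),
       histone = probe_track(cc, pos, hist_sig + noise()),
       igg = probe_track(cc, pos, noise()),
       input = probe_track(cc, pos, noise()))
}

#' Write a complete synthetic data set to disk
#'
#' Writes one bedGraph per channel, a GFF3 of gene models, a BED6 of the
#' planted-nucleosome truth, a TSV expression matrix and a YAML-style
#' key-value config file.
#'
#' @param truth a `genome_truth`.
#' @param tracks output of [simulate_probe_tracks()].
#' @param dir output directory (created if missing).
#' @return invisibly, named vector of file paths.
#' @export
write_simulation <- function(truth, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variant = file.path(dir, "variant.bedGraph"),
             histone = file.path(dir, "histone.bedGraph"),
             igg = file.path(dir, "igg.bedGraph"),
             input = file.path(dir, "input.bedGraph"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "nucleosomes_truth.bed"),
             expression = file.path(dir, "expression.tsv"),
             config = file.path(dir, "config.yaml"))
  for (ch in names(tracks)) write_bedgraph(tracks[[ch]], paths[[ch]])
  write_gff3(truth$genes, paths[["genes"]])
  nuc <- truth$nucleosomes
  bed <- data.table(nuc$chrom, pmax(as.integer(nuc$center) - 73L, 0L),
                    as.integer(nuc$center) + 74L,
                    paste0("truth", seq_len(nrow(nuc))),
                    round(nuc$occupancy, 4),
                    ifelse(nuc$has_variant, "+", "."))
  fwrite(bed, paths[["truth"]], sep = "\t", col.names = FALSE)
  write_expression_table(truth$expression, paths[["expression"]])
  cfg <- truth$config
  scalar <- vapply(cfg, function(x) length(x) == 1 && !is.null(x), TRUE)
  writeLines(c(paste0(names(cfg)[scalar], ": ",
                      unlist(cfg[scalar], use.names = FALSE)),
               paste0("promoter_class_probs: ",
                      paste(names(cfg$promoter_class_probs),
                            cfg$promoter_class_probs,
                            sep = "=", collapse = " "))),
             paths[["config"]])
  invisible(paths)
}
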