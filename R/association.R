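# Nearest-feature association, promoter/TTS classification and the
# resampling null for feature-type enrichment.
#
# Association distance is measured to the nearest feature edge (features
# include non-gene types, which have no meaningful TSS); promoter/TTS
# classification then uses strand-aware gene anchors. "Unequivocal"
# classification means the center falls in exactly one qualifying window of
# exactly one gene.

#' Association parameters
#'
#' @param max_distance bp; a nucleosome farther than this from every
#'   feature edge stays unassociated (default 2000, boundary inclusive).
#' @param promoter_window bp upstream of the TSS counted as promoter
#'   (default 2000).
#' @param tts_window_up,tts_window_down bp upstream/downstream of the TTS
#'   counted as TTS-proximal (defaults 500 and 2000).
#' @param n_resamples random subsets drawn for the enrichment null
#'   (default 1000).
#' @param seed RNG seed for the resampling.
#' @return a validated list of class `association_params`.
#' @export
association_params <- function(max_distance = 2000, promoter_window = 2000,
                               tts_window_up = 500, tts_window_down = 2000,
                               n_resamples = 1000, seed = 1) {
  if (max_distance <= 0 || promoter_window <= 0 || tts_window_up <= 0 ||
      tts_window_down <= 0)
    stop("all windows must be positive")
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  structure(list(max_distance = max_distance,
                 promoter_window = promoter_window,
                 tts_window_up = tts_window_up,
                 tts_window_down = tts_window_down,
                 n_resamples = n_resamples, seed = as.integer(seed)),
            class = "association_params")
}

.features_gr <- function(annotation) {
  GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = pmin(annotation$TSS, annotation$TTS) + 1,
                     end = pmax(annotation$TSS, annotation$TTS)))
}

#' Associate nucleosome centers with the nearest feature
#'
#' Distance is 0 when the center lies inside the feature, otherwise the gap
#' in bp to the nearest covered base; the nearest feature wins and the
#' association is dropped when the distance exceeds `max_distance`
#' (boundary inclusive). The reported `distance` is signed relative to the
#' feature's strand: negative upstream of the TSS, positive downstream of
#' the TTS, 0 inside.
#'
#' @param calls table with `chrom` and `center` (and optionally `id`).
#' @param annotation gene-model table ([read_annotation()] /
#'   [simulate_genome()]).
#' @param max_distance bp (default 2000).
#' @return data.table: `id`, `chrom`, `center`, `feature_id`,
#'   `feature_type`, `distance` (unsigned NA when unassociated),
#'   `signed_distance`.
#' @export
nearest_feature <- function(calls, annotation, max_distance = 2000) {
  calls <- as.data.table(calls)
  out <- data.table(
    id = if ("id" %in% names(calls)) calls$id else
      paste0("nuc", seq_len(nrow(calls))),
    chrom = calls$chrom, center = calls$center,
    feature_id = NA_character_, feature_type = NA_character_,
    distance = NA_real_, signed_distance = NA_real_)
  if (nrow(calls) == 0 || nrow(annotation) == 0) return(out)
  known <- out$chrom %in% unique(annotation$chrom)
  if (any(!known))
    warning(sum(!known), " nucleosome(s) on chromosomes absent from the ",
            "annotation")
  if (!any(known)) return(out)
  qi <- which(known)
  q <- GenomicRanges::GRanges(out$chrom[qi],
                              IRanges::IRanges(out$center[qi] + 1, width = 1))
  subj <- .features_gr(annotation)
  hits <- GenomicRanges::distanceToNearest(q, subj, select = "arbitrary")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # GRanges distance counts the gap; our convention counts center-to-edge
  d <- S4Vectors::mcols(hits)$distance
  d <- ifelse(d > 0, d + 1, 0)
  keep <- d <= max_distance
  rows <- qi[qh[keep]]
  feat <- sh[keep]
  out$feature_id[rows] <- annotation$id[feat]
  out$feature_type[rows] <- annotation$feature_type[feat]
  out$distance[rows] <- d[keep]
  # sign: upstream of the 5' anchor on the feature strand is negative
  sgn <- ifelse(annotation$strand[feat] == "+", 1, -1)
  lo <- pmin(annotation$TSS[feat], annotation$TTS[feat])
  hi <- pmax(annotation$TSS[feat], annotation$TTS[feat])
  ctr <- out$center[rows]
  side <- ifelse(ctr < lo, -1, ifelse(ctr >= hi, 1, 0))
  out$signed_distance[rows] <- d[keep] * side * sgn
  out[]
}

#' Classify nucleosome positions as promoter / TTS / body / ambiguous
#'
#' Strand-aware windows: promoter = `[TSS - promoter_window, TSS)` on the
#' gene's strand; TTS = `[TTS - tts_window_up, TTS + tts_window_down]`;
#' body = inside the gene but in neither window. A center qualifying for
#' windows of two or more genes, or for both windows of one gene, is
#' `ambiguous`; a center qualifying nowhere (and not inside a gene) is
#' `none`.
#'
#' @param calls table with `chrom` and `center` (and optionally `id`).
#' @param genes gene-model table (gene-type features only are used).
#' @param params an [association_params()].
#' @return data.table: `id`, `chrom`, `center`, `position_class`,
#'   `gene_id` (the single qualifying gene for promoter/TTS/body, else NA).
#' @export
classify_positions <- function(calls, genes, params = association_params()) {
  calls <- as.data.table(calls)
  genes <- as.data.table(genes)
  out <- data.table(
    id = if ("id" %in% names(calls)) calls$id else
      paste0("nuc", seq_len(nrow(calls))),
    chrom = calls$chrom, center = calls$center,
    position_class = "none", gene_id = NA_character_)
  if (nrow(calls) == 0 || nrow(genes) == 0) return(out)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  win <- function(a, b) {  # strand-aware [a, b] -> genomic [lo, hi]
    data.table(lo = pmin(a, b), hi = pmax(a, b))
  }
  # promoter: strand-aware [TSS - pw, TSS) => genomic bounds
  pw <- win(genes$TSS - sgn * params$promoter_window,
            genes$TSS - sgn)                       # exclusive at the TSS
  tw <- win(genes$TTS - sgn * params$tts_window_up,
            genes$TTS + sgn * params$tts_window_down)
  bw <- win(genes$TSS, genes$TTS - sgn)            # gene body [TSS, TTS)
  q <- GenomicRanges::GRanges(out$chrom,
                              IRanges::IRanges(out$center + 1, width = 1))
  ov <- function(w) {
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(w$lo + 1, w$hi + 1))
    h <- GenomicRanges::findOverlaps(q, gr)
    data.table(nuc = S4Vectors::queryHits(h),
               gene = S4Vectors::subjectHits(h))
  }
  ph <- ov(pw); th <- ov(tw); bh <- ov(bw)
  hits <- rbind(ph[, class := "promoter"], th[, class := "TTS"])
  if (nrow(hits)) {
    counts <- hits[, .N, by = nuc]
    single <- counts[N == 1, nuc]
    multi <- counts[N > 1, nuc]
    h1 <- hits[nuc %in% single]
    out$position_class[h1$nuc] <- h1$class
    out$gene_id[h1$nuc] <- genes$id[h1$gene]
    out$position_class[multi] <- "ambiguous"
  }
  # body: inside a gene and not already classified
  if (nrow(bh)) {
    bh <- bh[out$position_class[nuc] == "none"]
    if (nrow(bh)) {
      bcount <- bh[, .(n = .N, gene = gene[1]), by = nuc]
      out$position_class[bcount$nuc] <- ifelse(bcount$n > 1, "ambiguous",
                                               "body")
      out$gene_id[bcount[n == 1, nuc]] <- genes$id[bcount[n == 1, gene]]
    }
  }
  out[]
}

#' Feature-type composition of an association set
#'
#' @param associations output of [nearest_feature()].
#' @return data.table: per `feature_type`, counts over distinct associated
#'   features (`n_features`) and over nucleosomes (`n_nucleosomes`), with
#'   fractions over the associated set.
#' @export
feature_composition <- function(associations) {
  a <- as.data.table(associations)[!is.na(feature_id)]
  base <- data.table(feature_type = FEATURE_TYPES)
  if (nrow(a) == 0)
    return(base[, `:=`(n_features = 0L, n_nucleosomes = 0L,
                       frac_features = 0, frac_nucleosomes = 0)][])
  byt <- a[, .(n_features = length(unique(feature_id)),
               n_nucleosomes = .N), by = feature_type]
  out <- byt[base, on = "feature_type"]
  out[is.na(n_features), `:=`(n_features = 0L, n_nucleosomes = 0L)]
  out[, frac_features := n_features / sum(n_features)]
  out[, frac_nucleosomes := n_nucleosomes / sum(n_nucleosomes)]
  out[]
}

#' Feature-type enrichment of a selected set against random resampling
#'
#' Draws `n_resamples` random subsets of the same size as the selected set
#' from all positioned nucleosomes, recomputes the queried feature-type
#' fraction for each, and reports `fold` = observed / mean(resampled) and
#' the two-tailed one-sample t-test of the resampled fractions against the
#' observed value.
#'
#' @param selected_ids ids of the selected nucleosomes (subset of
#'   `all_calls$id`).
#' @param all_calls all positioned nucleosomes (the resampling population).
#' @param annotation feature table.
#' @param feature unit of the fraction: `"features"` (distinct associated
#'   features, as in the study) or `"nucleosomes"`.
#' @param type queried feature type (default `"protein_coding"`).
#' @param params an [association_params()] (uses `max_distance`,
#'   `n_resamples`, `seed`).
#' @return list: `observed`, `expected` (mean resampled), `fold`,
#'   `p_value`, `resampled` (vector).
#' @export
enrichment_vs_random <- function(selected_ids, all_calls, annotation,
                                 feature = c("features", "nucleosomes"),
                                 type = "protein_coding",
                                 params = association_params()) {
  feature <- match.arg(feature)
  all_calls <- copy(as.data.table(all_calls))
  if (!"id" %in% names(all_calls))
    all_calls[, id := paste0("nuc", .I)]
  if (length(selected_ids) > nrow(all_calls))
    stop("selected set larger than the resampling population")
  assoc <- nearest_feature(all_calls, annotation, params$max_distance)
  pre <- assoc[!is.na(feature_id)]
  frac_of <- function(ids) {
    mi <- match(ids, pre$id)
    mi <- mi[!is.na(mi)]
    if (!length(mi)) return(NA_real_)
    if (feature == "features") {
      k <- !duplicated(pre$feature_id[mi])
      mean(pre$feature_type[mi][k] == type)
    } else mean(pre$feature_type[mi] == type)
  }
  observed <- frac_of(selected_ids)
  set.seed(params$seed)
  k <- length(selected_ids)
  resampled <- vapply(seq_len(params$n_resamples), function(i)
    frac_of(sample(all_calls$id, k)), 0)
  expected <- mean(resampled, na.rm = TRUE)
  fold <- observed / expected
  p <- if (all(resampled == observed, na.rm = TRUE)) 1 else
    tryCatch(t.test(resampled, mu = observed)$p.value,
             error = function(e) 1)
  list(observed = observed, expected = expected, fold = fold,
       p_value = p, resampled = resampled)
}

#' Per-gene variant-nucleosome categories
#'
#' From the unambiguous promoter/TTS classifications of the selected
#' nucleosomes, each gene is categorized as `promoter-only`, `TTS-only`,
#' `both`, or `none` (body-only associations do not count).
#'
#' @param genes gene-model table.
#' @param classified output of [classify_positions()] for the selected
#'   nucleosomes.
#' @return data.table: `gene_id`, `category`; attribute `"counts"` holds
#'   the per-category totals.
#' @export
gene_h33_categories <- function(genes, classified) {
  cl <- as.data.table(classified)[position_class %in% c("promoter", "TTS")]
  per <- cl[, .(has_prom = any(position_class == "promoter"),
                has_tts = any(position_class == "TTS")), by = gene_id]
  out <- data.table(gene_id = genes$id, category = "none")
  m <- match(per$gene_id, out$gene_id)
  ok <- !is.na(m)
  out$category[m[ok]] <- ifelse(per$has_prom[ok] & per$has_tts[ok], "both",
                                ifelse(per$has_prom[ok], "promoter-only",
                                       "TTS-only"))
  counts <- table(factor(out$category,
                         c("promoter-only", "TTS-only", "both", "none")))
  setattr(out, "counts", counts)
  out[]
}

#' Overlap fraction of two gene sets
#'
#' `|A intersect B| / |A|`.
#'
#' @param gene_set_a,gene_set_b character vectors of gene ids.
#' @return numeric fraction.
#' @export
overlap_fraction <- function(gene_set_a, gene_set_b) {
  a <- unique(gene_set_a)
  if (!length(a)) stop("first gene set is empty")
  length(intersect(a, unique(gene_set_b))) / length(a)
}
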