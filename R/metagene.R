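# Strand-aware anchored signal profiles.
#
# A metagene profile averages signal over many genes after anchoring the
# flanks in fixed bp and rescaling each gene body to percentages, so genes
# of different lengths align. Probes are averaged into bins per gene first
# (a gene with no probe in a bin contributes nothing to that bin), then
# averaged across genes.

#' Metagene profile with fixed flanks and a percentage-scaled body
#'
#' @param track a [probe_track()].
#' @param genes gene-model table with `chrom`, `strand`, `TSS`, `TTS`.
#' @param flank bp of upstream/downstream flank (default 3000).
#' @param bin_size bp per flank bin (default 50).
#' @param n_body_bins percent bins across the gene body (default 100).
#' @return list of class `metagene_profile`: `upstream_bins`, `body_bins`,
#'   `downstream_bins` (per-bin mean across genes), matching `*_n` gene
#'   counts per bin, `n_genes`, `bin_size`, `n_body_bins`, `flank`.
#' @export
metagene_profile <- function(track, genes, flank = 3000, bin_size = 50,
                             n_body_bins = 100) {
  genes <- as.data.table(genes)
  n_fl <- as.integer(flank / bin_size)
  per_gene <- .per_gene_bins(track, genes, flank, bin_size, n_body_bins)
  if (length(per_gene) == 0) stop("no gene contributed to the profile")
  agg <- function(part, nb) {
    m <- vapply(per_gene, function(pg) {
      v <- rep(NA_real_, nb)
      rows <- pg[[part]]
      if (nrow(rows)) v[rows$bin] <- rows$mean
      v
    }, numeric(nb))
    list(mean = rowMeans(m, na.rm = TRUE), n = rowSums(!is.na(m)))
  }
  up <- agg("up", n_fl); body <- agg("body", n_body_bins)
  down <- agg("down", n_fl)
  structure(list(upstream_bins = up$mean, body_bins = body$mean,
                 downstream_bins = down$mean,
                 upstream_n = up$n, body_n = body$n, downstream_n = down$n,
                 n_genes = length(per_gene), bin_size = bin_size,
                 n_body_bins = n_body_bins, flank = flank),
            class = "metagene_profile")
}

# binary-search slice of a per-chromosome track list on [lo, hi]
.slice_track <- function(trk_by, cc, lo, hi) {
  t <- trk_by[[cc]]
  if (is.null(t)) return(NULL)
  i1 <- findInterval(lo - 1e-9, t$pos) + 1L
  i2 <- findInterval(hi, t$pos)
  if (i2 < i1) return(NULL)
  t[i1:i2]
}

# per-gene binned means: upstream [-flank,0) of TSS, body [TSS,TTS] in
# percent bins, downstream (0,flank] of TTS, all on the gene's strand
.per_gene_bins <- function(track, genes, flank, bin_size, n_body_bins) {
  trk_by <- split(as.data.table(track), by = "chrom")
  out <- vector("list", nrow(genes))
  kept <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    len <- abs(g$TTS - g$TSS)
    if (len < n_body_bins) {
      warning("gene ", g$id, " shorter than one bp per body bin; skipped")
      next
    }
    s <- if (g$strand == "+") 1 else -1
    lo <- min(g$TSS, g$TTS) - flank
    hi <- max(g$TSS, g$TTS) + flank
    sub <- .slice_track(trk_by, g$chrom, lo, hi)
    if (is.null(sub)) next
    rel_tss <- (sub$pos - g$TSS) * s
    rel_tts <- (sub$pos - g$TTS) * s
    up_i <- rel_tss >= -flank & rel_tss < 0
    body_i <- rel_tss >= 0 & rel_tts <= 0
    down_i <- rel_tts > 0 & rel_tts <= flank
    bins <- function(sel, b) {
      if (!any(sel)) return(data.table(bin = integer(0), mean = numeric(0)))
      dt <- data.table(bin = b[sel], value = sub$value[sel])
      dt[, .(mean = mean(value)), by = bin]
    }
    out[[i]] <- list(
      up = bins(up_i, pmin(floor((rel_tss + flank) / bin_size) + 1L,
                           as.integer(flank / bin_size))),
      body = bins(body_i, pmin(floor(rel_tss / len * n_body_bins) + 1L,
                               n_body_bins)),
      down = bins(down_i, pmin(ceiling(rel_tts / bin_size),
                               as.integer(flank / bin_size))))
    kept[i] <- TRUE
  }
  out[kept]
}

#' Metagene profiles per gene group
#'
#' @param track a [probe_track()].
#' @param genes gene-model table.
#' @param grouping named vector or list mapping gene id -> group label
#'   (genes absent from the grouping are ignored).
#' @param ... passed to [metagene_profile()].
#' @return named list of [metagene_profile()]s, one per non-empty group,
#'   with attribute `"group_sizes"`.
#' @export
grouped_profiles <- function(track, genes, grouping, ...) {
  genes <- as.data.table(genes)
  grouping <- unlist(grouping)
  labels <- unique(grouping)
  out <- list()
  sizes <- integer(0)
  for (lab in labels) {
    ids <- names(grouping)[grouping == lab]
    sub <- genes[id %in% ids]
    if (nrow(sub) == 0) {
      warning("group ", lab, " is empty; omitted")
      next
    }
    out[[as.character(lab)]] <- metagene_profile(track, sub, ...)
    sizes[as.character(lab)] <- nrow(sub)
  }
  setattr(out, "group_sizes", sizes)
  out
}

#' Point-anchored profile with a 95% confidence band
#'
#' Stacks the signal around a set of anchor points (for example nucleosome
#' centers) in `[-half_width, +half_width]` and reports the per-bin mean
#' across points with a normal-approximation 95% band
#' (`mean +/- 1.96 * SE`).
#'
#' @param track a [probe_track()].
#' @param points table with `chrom` and `center`.
#' @param half_width bp (default 600).
#' @param bin_size bp per bin (default 25).
#' @return data.table: `offset` (bin center, bp), `mean`, `n`, `ci_lo`,
#'   `ci_hi`.
#' @export
point_profile <- function(track, points, half_width = 600, bin_size = 25) {
  points <- as.data.table(points)
  if (nrow(points) == 0) stop("no anchor points supplied")
  trk_by <- split(as.data.table(track), by = "chrom")
  n_bins <- as.integer(2 * half_width / bin_size)
  acc <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    sub <- .slice_track(trk_by, points$chrom[i],
                        points$center[i] - half_width,
                        points$center[i] + half_width)
    if (is.null(sub)) next
    rel <- sub$pos - points$center[i]
    b <- pmin(floor((rel + half_width) / bin_size) + 1L, n_bins)
    acc[[i]] <- data.table(point = i, bin = b, value = sub$value)[
      , .(mean = mean(value)), by = .(point, bin)]
  }
  all <- rbindlist(acc)
  if (nrow(all) == 0) stop("no probes around any anchor point")
  res <- all[, .(mean = mean(mean), n = .N,
                 se = if (.N > 1) sd(mean) / sqrt(.N) else 0), by = bin]
  setorder(res, bin)
  res[, `:=`(offset = -half_width + (bin - 0.5) * bin_size,
             ci_lo = mean - 1.96 * se, ci_hi = mean + 1.96 * se)]
  res[, .(offset, mean, n, ci_lo, ci_hi)]
}

#' TSS-to-TTS signal matrix ordered by gene body length
#'
#' One row per (sampled) gene: binned signal from the TSS along the gene
#' body up to `max_body` bp, then `downstream` bp past the TTS. Bodies
#' longer than `max_body` are truncated; cells beyond a shorter gene's TTS
#' are `NA`. Rows are ordered by increasing body length.
#'
#' @param track a [probe_track()].
#' @param genes gene-model table.
#' @param max_body bp of gene body shown (default 5000).
#' @param downstream bp past the TTS (default 1000).
#' @param bin_size bp per column (default 50).
#' @param n_sample genes sampled (default all; sampling uses `seed`).
#' @param seed RNG seed for sampling.
#' @return numeric matrix (genes x bins) with gene ids as rownames, body
#'   columns first; attribute `"body_length"` holds the per-row lengths.
#' @export
tss_tts_matrix <- function(track, genes, max_body = 5000, downstream = 1000,
                           bin_size = 50, n_sample = NULL, seed = 1) {
  genes <- copy(as.data.table(genes))
  if (!is.null(n_sample) && n_sample < nrow(genes)) {
    set.seed(seed)
    genes <- genes[sample(.N, n_sample)]
  }
  genes[, body_len := abs(TTS - TSS)]
  setorder(genes, body_len)
  trk_by <- split(as.data.table(track), by = "chrom")
  nb_body <- as.integer(max_body / bin_size)
  nb_down <- as.integer(downstream / bin_size)
  m <- matrix(NA_real_, nrow(genes), nb_body + nb_down,
              dimnames = list(genes$id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    s <- if (g$strand == "+") 1 else -1
    lo <- min(g$TSS, g$TTS) - downstream
    hi <- max(g$TSS, g$TTS) + downstream
    sub <- .slice_track(trk_by, g$chrom, lo, hi)
    if (is.null(sub)) next
    rel_tss <- (sub$pos - g$TSS) * s
    rel_tts <- (sub$pos - g$TTS) * s
    body_i <- rel_tss >= 0 & rel_tts <= 0 & rel_tss < max_body
    down_i <- rel_tts > 0 & rel_tts <= downstream
    b <- c(floor(rel_tss[body_i] / bin_size) + 1L,
           nb_body + pmin(ceiling(rel_tts[down_i] / bin_size), nb_down))
    v <- c(sub$value[body_i], sub$value[down_i])
    if (length(b)) {
      agg <- data.table(b = b, v = v)[, .(mean = mean(v)), by = b]
      m[i, agg$b] <- agg$mean
    }
  }
  setattr(m, "body_length", genes$body_len)
  m
}

#' Quantile expression bins
#'
#' Assigns genes to `n_bins` quantile bins of an expression summary
#' (default: mean across conditions), bin 1 = lowest. Ties are broken by
#' gene id order so the assignment is deterministic and invariant to any
#' strictly monotone transform of the values.
#'
#' @param expression gene x condition matrix (rownames = gene ids), or a
#'   named numeric vector of summary values.
#' @param summary function collapsing a gene's conditions (default
#'   `mean`); ignored when `expression` is a vector.
#' @param n_bins number of bins (default 4).
#' @return list of class `expression_bins`: `assignment` (named integer
#'   vector), `n_bins`, `boundaries` (value quantiles at bin edges).
#' @export
bin_by_expression <- function(expression, summary = mean, n_bins = 4) {
  vals <- if (is.matrix(expression)) apply(expression, 1, summary)
    else expression
  if (is.null(names(vals))) stop("expression values must be named by gene")
  if (max(vals) - min(vals) < .Machine$double.eps)
    stop("all expression values equal: bins undefined")
  ord <- order(vals, names(vals))
  n <- length(vals)
  bin_sorted <- ceiling(seq_len(n) * n_bins / n)
  assignment <- integer(n)
  assignment[ord] <- bin_sorted
  names(assignment) <- names(vals)
  bounds <- vapply(seq_len(n_bins - 1), function(k)
    vals[ord][max(which(bin_sorted == k))], 0)
  structure(list(assignment = assignment, n_bins = n_bins,
                 boundaries = unname(bounds)),
            class = "expression_bins")
}
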