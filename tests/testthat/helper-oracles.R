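# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately naive: loops and full scans.

# nearest feature by scanning every feature edge
brute_nearest <- function(chrom, center, annotation, max_distance) {
  best_d <- Inf; best_i <- NA
  for (i in seq_len(nrow(annotation))) {
    if (annotation$chrom[i] != chrom) next
    lo <- min(annotation$TSS[i], annotation$TTS[i])
    hi <- max(annotation$TSS[i], annotation$TTS[i])   # half-open end
    d <- if (center >= lo && center < hi) 0
      else if (center < lo) lo - center else center - hi + 1
    if (d < best_d) { best_d <- d; best_i <- i }
  }
  if (!is.finite(best_d) || best_d > max_distance)
    return(list(feature = NA_character_, distance = NA_real_))
  list(feature = annotation$id[best_i], distance = best_d)
}

# window-median ratio by direct enumeration of every probe
brute_median_ratio <- function(num_pos, num_val, den_pos, den_val,
                               center, window) {
  ratios <- c()
  for (i in seq_along(num_pos)) {
    p <- num_pos[i]
    if (p >= center - window / 2 && p < center + window / 2) {
      j <- which(den_pos == p)
      if (length(j) == 1) ratios <- c(ratios, num_val[i] - den_val[j])
    }
  }
  if (!length(ratios)) NA_real_ else median(ratios)
}

# parabola fit by grid search over (a, c, h) minimizing SSE
grid_search_parabola <- function(x, y, a_grid, c_grid, h_grid) {
  best <- list(sse = Inf)
  for (a in a_grid) for (cc in c_grid) for (h in h_grid) {
    sse <- sum((a * (x - cc)^2 + h - y)^2)
    if (sse < best$sse) best <- list(a = a, center = cc, height = h,
                                     sse = sse)
  }
  best
}

# one-tail rank-sum p-value by exhaustive enumeration of group labelings
enum_wilcoxon_less <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); k <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(k)])
  combos <- utils::combn(n, k)
  stats <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mean(stats <= obs)
}

# all-pairs channel merging oracle: variant call absorbed by any histone
# call within d; histone calls with at least one absorbed partner -> "both"
brute_merge <- function(cv, ch, d) {
  keep_v <- rep(TRUE, nrow(cv))
  both_h <- rep(FALSE, nrow(ch))
  for (i in seq_len(nrow(cv))) for (j in seq_len(nrow(ch))) {
    if (cv$chrom[i] == ch$chrom[j] &&
        abs(cv$center[i] - ch$center[j]) <= d) {
      keep_v[i] <- FALSE
      if (j == which.min(ifelse(ch$chrom == cv$chrom[i],
                                abs(ch$center - cv$center[i]), Inf)))
        both_h[j] <- TRUE
    }
  }
  list(variant_kept = cv$center[keep_v], histone_both = ch$center[both_h])
}

# per-point linear interpolation oracle
brute_interp <- function(px, py, x) {
  sapply(x, function(xx) {
    i <- max(which(px <= xx))
    if (px[i] == xx) return(py[i])
    py[i] + (py[i + 1] - py[i]) * (xx - px[i]) / (px[i + 1] - px[i])
  })
}

# small shared simulation for cross-module tests
small_sim <- function(seed = 7, ...) {
  cfg <- simulation_config(genome_length = 4e5, n_genes = 80,
                           n_nucleosomes = 1000, noise_sd = 0.3,
                           seed = seed, ...)
  truth <- simulate_genome(cfg)
  list(cfg = cfg, truth = truth,
       tracks = simulate_probe_tracks(truth, cfg))
}
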