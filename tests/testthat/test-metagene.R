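dense_track <- function(L = 60000, step = 10, value = NULL, seed = 1) {
  pos <- seq(0, L, step)
  set.seed(seed)
  v <- if (is.null(value)) rnorm(length(pos)) else rep(value, length(pos))
  probe_track("chr1", pos, v)
}

plus_gene <- function(id, start, end) data.table::data.table(
  id = id, chrom = "chr1", strand = "+", TSS = start, TTS = end,
  feature_type = "protein_coding", promoter_class = "unknown")

test_that("a constant track gives constant metagene bins", {
  trk <- dense_track(value = 3.5)
  genes <- rbind(plus_gene("a", 10000, 14000), plus_gene("b", 30000, 36000))
  p <- metagene_profile(trk, genes, flank = 3000, bin_size = 50,
                        n_body_bins = 100)
  expect_true(all(abs(p$upstream_bins - 3.5) < 1e-12))
  expect_true(all(abs(p$body_bins - 3.5) < 1e-12))
  expect_true(all(abs(p$downstream_bins - 3.5) < 1e-12))
  expect_equal(p$n_genes, 2)
})

test_that("a minus-strand gene mirrors its plus-strand image", {
  pos <- seq(0, 40000, 10)
  set.seed(2)
  v <- rnorm(length(pos))
  trk_f <- probe_track("chr1", pos, v)
  # mirrored track: value at pos x becomes value at 40000 - x
  trk_r <- probe_track("chr1", sort(40000 - pos), rev(v))
  gf <- plus_gene("f", 15000, 22000)
  gr <- data.table::data.table(id = "r", chrom = "chr1", strand = "-",
                               TSS = 40000 - 15000, TTS = 40000 - 22000,
                               feature_type = "protein_coding",
                               promoter_class = "unknown")
  pf <- metagene_profile(trk_f, gf)
  pr <- metagene_profile(trk_r, gr)
  expect_equal(pr$upstream_bins, pf$upstream_bins, tolerance = 1e-12)
  expect_equal(pr$body_bins, pf$body_bins, tolerance = 1e-12)
  expect_equal(pr$downstream_bins, pf$downstream_bins, tolerance = 1e-12)
})

test_that("metagene bins equal brute-force per-gene averaging", {
  trk <- dense_track(seed = 3)
  set.seed(4)
  genes <- data.table::rbindlist(lapply(1:10, function(i) {
    start <- 3200 + (i - 1) * 5500
    plus_gene(paste0("g", i), start, start + sample(2000:4000, 1))
  }))
  flank <- 3000; bs <- 50; nb <- 100
  p <- metagene_profile(trk, genes, flank, bs, nb)
  # independent direct averaging
  up <- matrix(NA_real_, 10, flank / bs)
  body <- matrix(NA_real_, 10, nb)
  down <- matrix(NA_real_, 10, flank / bs)
  tdt <- data.table::as.data.table(trk)
  for (i in 1:10) {
    g <- genes[i]
    len <- g$TTS - g$TSS
    for (b in seq_len(flank / bs)) {
      lo <- g$TSS - flank + (b - 1) * bs
      sel <- tdt[pos >= lo & pos < lo + bs & pos < g$TSS]
      if (nrow(sel)) up[i, b] <- mean(sel$value)
      lo2 <- g$TTS + (b - 1) * bs
      sel2 <- tdt[pos > g$TTS & pos > lo2 & pos <= lo2 + bs]
      if (nrow(sel2)) down[i, b] <- mean(sel2$value)
    }
    for (b in seq_len(nb)) {
      sel <- tdt[pos >= g$TSS & pos <= g$TTS &
                   pmin(floor((pos - g$TSS) / len * nb) + 1, nb) == b]
      if (nrow(sel)) body[i, b] <- mean(sel$value)
    }
  }
  expect_lt(max(abs(p$upstream_bins - colMeans(up, na.rm = TRUE))), 1e-12)
  expect_lt(max(abs(p$body_bins - colMeans(body, na.rm = TRUE))), 1e-12)
  expect_lt(max(abs(p$downstream_bins - colMeans(down, na.rm = TRUE))),
            1e-12)
})

test_that("metagene commutes with affine transforms and gene order", {
  trk <- dense_track(seed = 5)
  genes <- rbind(plus_gene("a", 10000, 14000), plus_gene("b", 30000, 35000),
                 plus_gene("c", 44000, 48000))
  p1 <- metagene_profile(trk, genes)
  aff <- probe_track(trk$chrom, trk$pos, 2 * trk$value - 1)
  p2 <- metagene_profile(aff, genes)
  expect_equal(p2$body_bins, 2 * p1$body_bins - 1, tolerance = 1e-12)
  p3 <- metagene_profile(trk, genes[c(3, 1, 2)])
  expect_equal(p3$body_bins, p1$body_bins)
})

test_that("grouped profiles split and match the single-group case", {
  trk <- dense_track(seed = 6)
  genes <- rbind(plus_gene("a", 10000, 14000), plus_gene("b", 30000, 35000))
  single <- grouped_profiles(trk, genes, c(a = "all", b = "all"))
  expect_equal(single$all$body_bins, metagene_profile(trk, genes)$body_bins)
  expect_warning(
    grouped_profiles(trk, genes, c(a = "g1", b = "g1", zz = "empty")),
    "empty")
})

test_that("grouped profiles see planted TTS signal ordering", {
  s <- small_sim(seed = 41)
  # log2 variant/histone ratio track
  v <- s$tracks$variant; h <- s$tracks$histone
  ratio <- probe_track(v$chrom, v$pos, v$value - h$value)
  genes <- s$truth$genes[feature_type == "protein_coding"]
  ebins <- bin_by_expression(s$truth$expression[genes$id, ])
  grouping <- setNames(paste0("q", ebins$assignment), names(ebins$assignment))
  profs <- suppressWarnings(grouped_profiles(ratio, genes, grouping))
  # variant was planted at TTSs of high-expression genes: the top quartile
  # must exceed the bottom quartile at the TTS-proximal bins
  tts_zone <- function(p) mean(p$downstream_bins[1:4])
  expect_gt(tts_zone(profs$q4), tts_zone(profs$q1))
})

test_that("point profiles stack windows around anchors", {
  trk <- dense_track(value = 2)
  pts <- data.table::data.table(chrom = "chr1", center = c(10000, 20000))
  pp <- point_profile(trk, pts, half_width = 600, bin_size = 25)
  expect_true(all(abs(pp$mean - 2) < 1e-12))
  expect_true(all(pp$ci_hi - pp$ci_lo < 1e-12))
  expect_equal(nrow(pp), 2 * 600 / 25)

  # single point: profile equals that point's local signal
  trk2 <- dense_track(seed = 7)
  one <- point_profile(trk2, pts[1], half_width = 100, bin_size = 25)
  tdt <- data.table::as.data.table(trk2)
  nb <- nrow(one)
  bin_sel <- function(ctr, hw, bs, k, nb) {
    # half-open bins, the window's right edge folded into the last bin
    lo <- ctr - hw + (k - 1) * bs
    tdt[pos >= lo & (pos < lo + bs | (k == nb & pos == ctr + hw))]
  }
  for (k in seq_len(nb)) {
    expect_equal(one$mean[k],
                 mean(bin_sel(10000, 100, 25, k, nb)$value))
  }

  # random anchors against brute-force stacking
  set.seed(8)
  pts3 <- data.table::data.table(chrom = "chr1",
                                 center = sample(5000:50000, 15))
  pp3 <- point_profile(trk2, pts3, half_width = 200, bin_size = 50)
  for (k in c(1, 4, 8)) {
    per_point <- sapply(pts3$center, function(ctr) {
      sel <- bin_sel(ctr, 200, 50, k, 8)
      if (nrow(sel)) mean(sel$value) else NA_real_
    })
    expect_equal(pp3$mean[k], mean(per_point, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("TSS-TTS matrix is length-ordered with correct cells", {
  trk <- dense_track(value = 1.25)
  set.seed(9)
  genes <- data.table::rbindlist(lapply(1:8, function(i) {
    start <- 2000 + (i - 1) * 7000
    plus_gene(paste0("g", i), start, start + sample(1500:6500, 1))
  }))
  m <- tss_tts_matrix(trk, genes, max_body = 5000, downstream = 1000,
                      bin_size = 50)
  expect_true(all(diff(attr(m, "body_length")) >= 0))
  expect_true(all(abs(m[!is.na(m)] - 1.25) < 1e-12))

  # spot-check cells on a random track
  trk2 <- dense_track(seed = 10)
  m2 <- tss_tts_matrix(trk2, genes, max_body = 5000, downstream = 1000,
                       bin_size = 50)
  tdt <- data.table::as.data.table(trk2)
  for (ri in c(2, 5)) {
    g <- genes[id == rownames(m2)[ri]]
    for (b in c(1, 10)) {
      lo <- g$TSS + (b - 1) * 50
      sel <- tdt[pos >= lo & pos < lo + 50 & pos <= g$TTS]
      expect_equal(unname(m2[ri, b]), mean(sel$value), tolerance = 1e-12)
    }
  }
})

test_that("expression bins are equal-sized quantile groups", {
  vals <- setNames(c(5, 1, 9, 3, 7, 2, 8, 4), paste0("g", 1:8))
  b <- bin_by_expression(vals, n_bins = 4)
  expect_equal(as.integer(table(b$assignment)), rep(2L, 4))
  # lowest two values in bin 1
  expect_equal(sort(names(b$assignment)[b$assignment == 1]),
               c("g2", "g6"))

  # rank invariance under monotone transforms
  b2 <- bin_by_expression(exp(vals), n_bins = 4)
  expect_identical(b$assignment, b2$assignment)

  # sorting-based oracle on random values
  set.seed(11)
  v <- setNames(runif(37), paste0("x", 1:37))
  b3 <- bin_by_expression(v, n_bins = 4)
  ord <- order(v, names(v))
  oracle <- integer(37)
  oracle[ord] <- ceiling(seq_len(37) * 4 / 37)
  expect_identical(unname(b3$assignment), oracle)
  # sizes within one of each other
  expect_lte(diff(range(table(b3$assignment))), 1)

  expect_error(bin_by_expression(setNames(rep(1, 5), letters[1:5])),
               "equal")
})
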