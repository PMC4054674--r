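mk_genes <- function(...) {
  g <- data.table::rbindlist(list(...))
  g[, promoter_class := "unknown"]
  g[]
}

gene_row <- function(id, chrom, strand, start, end,
                     feature_type = "protein_coding") {
  data.table::data.table(
    id = id, chrom = chrom, strand = strand,
    TSS = if (strand == "+") start else end,
    TTS = if (strand == "+") end else start,
    feature_type = feature_type)
}

test_that("association distance is edge-based and boundary-inclusive", {
  genes <- mk_genes(gene_row("g1", "chr1", "+", 10000, 12000))
  calls <- data.table::data.table(
    id = c("inside", "at2000", "at2001"), chrom = "chr1",
    center = c(11000, 8000, 7999))
  a <- nearest_feature(calls, genes, max_distance = 2000)
  expect_equal(a[id == "inside", distance], 0)
  expect_equal(a[id == "at2000", distance], 2000)   # "did not exceed"
  expect_equal(a[id == "at2000", feature_id], "g1")
  expect_true(is.na(a[id == "at2001", feature_id])) # 2001 bp: dropped
  # signed distance: upstream of a + gene is negative
  expect_equal(a[id == "at2000", signed_distance], -2000)
})

test_that("nearest feature matches the brute-force scan", {
  set.seed(9)
  genes <- data.table::rbindlist(lapply(1:30, function(i) {
    start <- sample(0:95000, 1)
    gene_row(paste0("g", i), sample(c("chr1", "chr2"), 1),
             sample(c("+", "-"), 1), start, start + sample(500:3000, 1))
  }))
  genes$promoter_class <- "unknown"
  calls <- data.table::data.table(
    id = paste0("n", 1:80), chrom = sample(c("chr1", "chr2"), 80, TRUE),
    center = sample(0:100000, 80))
  a <- nearest_feature(calls, genes, 2000)
  for (i in seq_len(nrow(calls))) {
    o <- brute_nearest(calls$chrom[i], calls$center[i], genes, 2000)
    expect_equal(a$distance[i], o$distance, info = paste("call", i))
    if (!is.na(o$distance))   # ties may pick either feature; distance agrees
      expect_equal(a$distance[i],
                   abs(a$distance[i]))
  }
})

test_that("association is invariant under a genome-wide shift", {
  set.seed(10)
  genes <- mk_genes(gene_row("g1", "chr1", "+", 10000, 13000),
                    gene_row("g2", "chr1", "-", 20000, 22000))
  calls <- data.table::data.table(id = paste0("n", 1:20), chrom = "chr1",
                                  center = sample(5000:30000, 20))
  a1 <- nearest_feature(calls, genes, 2000)
  sh <- 5000
  g2 <- data.table::copy(genes)[, `:=`(TSS = TSS + sh, TTS = TTS + sh)]
  c2 <- data.table::copy(calls)[, center := center + sh]
  a2 <- nearest_feature(c2, g2, 2000)
  expect_equal(a1$feature_id, a2$feature_id)
  expect_equal(a1$distance, a2$distance)
})

test_that("position classes follow strand-aware windows", {
  genes <- mk_genes(gene_row("g1", "chr1", "+", 10000, 15000))
  p <- association_params()
  cl <- classify_positions(data.table::data.table(
    id = c("prom", "tts_at", "body", "far"), chrom = "chr1",
    center = c(9700, 15000, 12000, 40000)), genes, p)
  expect_equal(cl[id == "prom", position_class], "promoter")
  expect_equal(cl[id == "tts_at", position_class], "TTS")  # offset 0 counts
  expect_equal(cl[id == "body", position_class], "body")
  expect_equal(cl[id == "far", position_class], "none")

  # minus-strand gene: promoter is genomically downstream of its TSS
  gm <- mk_genes(gene_row("g2", "chr1", "-", 10000, 15000))
  clm <- classify_positions(data.table::data.table(
    id = "promM", chrom = "chr1", center = 15300), gm, p)
  expect_equal(clm$position_class, "promoter")

  # overlapping qualifying windows of two genes: ambiguous
  g2 <- mk_genes(gene_row("ga", "chr1", "+", 10000, 15000),
                 gene_row("gb", "chr1", "+", 16500, 20000))
  cla <- classify_positions(data.table::data.table(
    id = "amb", chrom = "chr1", center = 15500), g2, p)
  expect_equal(cla$position_class, "ambiguous")
})

test_that("feature composition tallies by hand agree", {
  set.seed(11)
  assoc <- data.table::data.table(
    id = paste0("n", 1:50),
    feature_id = sample(paste0("f", 1:12), 50, replace = TRUE),
    feature_type = NA_character_)
  type_of <- setNames(sample(c("protein_coding", "TE", "tRNA"), 12, TRUE),
                      paste0("f", 1:12))
  assoc[, feature_type := type_of[feature_id]]
  comp <- feature_composition(assoc)
  for (tt in c("protein_coding", "TE", "tRNA")) {
    expect_equal(comp[feature_type == tt, n_nucleosomes],
                 sum(assoc$feature_type == tt))
    expect_equal(comp[feature_type == tt, n_features],
                 length(unique(assoc[feature_type == tt, feature_id])))
  }
  expect_equal(sum(comp$frac_features), 1)
  expect_equal(sum(comp$frac_nucleosomes), 1)

  # all one type
  one <- feature_composition(data.table::data.table(
    id = "a", feature_id = "f", feature_type = "protein_coding"))
  expect_equal(one[feature_type == "protein_coding", frac_features], 1)
  # empty set
  empty <- feature_composition(data.table::data.table(
    id = character(), feature_id = character(),
    feature_type = character()))
  expect_true(all(empty$n_features == 0))
})

test_that("resampling enrichment is null for a random subset", {
  set.seed(12)
  genes <- data.table::rbindlist(lapply(1:40, function(i) {
    start <- i * 2500
    gene_row(paste0("g", i), "chr1", "+", start, start + 1200,
             feature_type = sample(c("protein_coding", "TE"), 1,
                                   prob = c(0.7, 0.3)))
  }))
  genes$promoter_class <- "unknown"
  calls <- data.table::data.table(id = paste0("n", 1:500), chrom = "chr1",
                                  center = sample(0:100000, 500))
  sel <- sample(calls$id, 100)
  r <- enrichment_vs_random(sel, calls, genes,
                            params = association_params(n_resamples = 500,
                                                        seed = 1))
  se <- sd(r$resampled) / sqrt(length(r$resampled))
  expect_lt(abs(r$fold - 1), 2 * sd(r$resampled) / r$expected)

  # whole population as the selection: fold exactly 1
  rall <- enrichment_vs_random(calls$id, calls, genes,
                               params = association_params(
                                 n_resamples = 200, seed = 1))
  expect_equal(rall$fold, 1)
  expect_equal(rall$p_value, 1)

  expect_error(enrichment_vs_random(c(calls$id, "extra"), calls, genes),
               "larger")
})

test_that("small-instance resampling agrees with exhaustive enumeration", {
  genes <- data.table::rbindlist(lapply(1:5, function(i)
    gene_row(paste0("g", i), "chr1", "+", i * 4000, i * 4000 + 1000,
             feature_type = c("protein_coding", "protein_coding", "TE",
                              "TE", "TE")[i])))
  genes$promoter_class <- "unknown"
  calls <- data.table::data.table(id = paste0("n", 1:20), chrom = "chr1",
                                  center = rep(seq(4100, 20100, 4000), 4))
  assoc <- nearest_feature(calls, genes, 2000)
  sel <- calls$id[1:6]
  r <- enrichment_vs_random(sel, calls, genes, feature = "nucleosomes",
                            params = association_params(n_resamples = 2000,
                                                        seed = 3))
  # exhaustive mean over all C(20,6) subsets of the protein-coding fraction
  type_by_id <- setNames(assoc$feature_type, assoc$id)
  combos <- utils::combn(20, 6)
  fracs <- apply(combos, 2, function(ix)
    mean(type_by_id[calls$id[ix]] == "protein_coding", na.rm = TRUE))
  expect_lt(abs(r$expected - mean(fracs)), 3 * sd(fracs) / sqrt(2000))
})

test_that("gene categories partition the gene set", {
  genes <- mk_genes(gene_row("g1", "chr1", "+", 1000, 4000),
                    gene_row("g2", "chr1", "+", 10000, 14000),
                    gene_row("g3", "chr1", "+", 20000, 24000),
                    gene_row("g4", "chr1", "+", 30000, 34000))
  cl <- data.table::data.table(
    id = paste0("n", 1:4), chrom = "chr1",
    center = c(500, 4100, 13900, 22000),
    position_class = c("promoter", "TTS", "TTS", "body"),
    gene_id = c("g1", "g1", "g2", "g3"))
  cats <- gene_h33_categories(genes, cl)
  expect_equal(cats[gene_id == "g1", category], "both")
  expect_equal(cats[gene_id == "g2", category], "TTS-only")
  expect_equal(cats[gene_id == "g3", category], "none")  # body only
  expect_equal(cats[gene_id == "g4", category], "none")
  counts <- attr(cats, "counts")
  expect_equal(sum(counts), nrow(genes))
})

test_that("overlap fraction is a plain set ratio", {
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(overlap_fraction(c("a", "b"), c("x", "y")), 0)
  set.seed(13)
  a <- sample(letters, 10); b <- sample(letters, 12)
  expect_equal(overlap_fraction(a, b),
               sum(!is.na(match(unique(a), b))) / length(unique(a)))
  expect_error(overlap_fraction(character(), "a"), "empty")
})
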