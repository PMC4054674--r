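# Readers/writers for the formats the pipeline touches.
# Coordinate conventions, used everywhere:
#   internal positions  0-based (probe centers, nucleosome centers, TSS/TTS)
#   bedGraph / BED      0-based half-open
#   GFF3                1-based closed
# TSS/TTS are strand-aware: TSS is the 5' end on the feature's strand, so on
# the minus strand TSS > TTS.

FEATURE_TYPES <- c("protein_coding", "pseudogene", "TE_gene", "TE",
                   "miRNA", "tRNA", "ncRNA")
PROMOTER_CLASSES <- c("TATA", "GA", "coreless", "unknown")

# GFF3 `type` column <-> internal feature_type vocabulary
.gff_type_of <- c(protein_coding = "gene",
                  pseudogene = "pseudogene",
                  TE_gene = "transposable_element_gene",
                  TE = "transposable_element",
                  miRNA = "miRNA",
                  tRNA = "tRNA",
                  ncRNA = "ncRNA")

#' Construct a probe track
#'
#' A probe track holds per-chromosome sorted probe center positions (0-based
#' bp) with one signal value each, for a single channel.
#'
#' @param chrom chromosome name per probe (recycled if length 1).
#' @param pos integer probe centers, strictly increasing within chromosome.
#' @param value numeric signal (log2-like scale), no NAs.
#' @return a `data.table` of class `probe_track` with columns
#'   `chrom`, `pos`, `value`, keyed by chromosome and position.
#' @export
probe_track <- function(chrom, pos, value) {
  dt <- data.table(chrom = as.character(chrom), pos = as.numeric(pos),
                   value = as.numeric(value))
  if (anyNA(dt$value) || anyNA(dt$pos))
    stop("probe track must not contain NA positions or values")
  setorder(dt, chrom, pos)
  if (dt[, any(diff(pos) <= 0), by = chrom][, any(V1)])
    stop("probe positions must be strictly increasing within a chromosome")
  setattr(dt, "class", c("probe_track", class(dt)))
  dt[]
}

.strip_track_class <- function(dt) {
  setattr(dt, "class", setdiff(class(dt), "probe_track"))
  dt
}

#' Read a probe track from bedGraph or wig
#'
#' Intervals are converted to probe centers at the interval midpoint
#' (`(start + end) %/% 2` in 0-based half-open coordinates). Rows with
#' missing values are dropped with a warning; unsorted or overlapping
#' intervals are a format error naming the offending line.
#'
#' @param path bedGraph (`.bedGraph`/`.bdg`) or wig file.
#' @param chromosome_filter optional character vector of chromosomes to keep.
#' @param format `"auto"` (from extension), `"bedGraph"` or `"wig"`.
#' @return a [probe_track()].
#' @export
read_probe_track <- function(path, chromosome_filter = NULL,
                             format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  if (format == "wig") {
    gr <- rtracklayer::import(path, format = "wig")
    dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr),
                     value = gr$score,
                     line = seq_along(gr))
  } else {
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    if (!any(keep))
      return(probe_track(character(), numeric(), numeric()))
    dt <- fread(text = lines[keep], header = FALSE,
                col.names = c("chrom", "start", "end", "value"),
                colClasses = list(character = 1))
    dt[, line := which(keep)]
  }
  if (anyNA(dt$value)) {
    warning(sum(is.na(dt$value)), " probes with missing values dropped")
    dt <- dt[!is.na(value)]
  }
  if (!is.null(chromosome_filter)) dt <- dt[chrom %in% chromosome_filter]
  if (nrow(dt) == 0) return(probe_track(character(), numeric(), numeric()))
  # validate sortedness/overlap per chromosome in file order
  for (cc in unique(dt$chrom)) {
    sub <- dt[chrom == cc]
    bad <- which(sub$start[-1] < sub$end[-nrow(sub)])
    if (length(bad))
      stop("unsorted or overlapping intervals at line ", sub$line[bad[1] + 1],
           " of ", path)
  }
  probe_track(dt$chrom, (dt$start + dt$end) %/% 2, dt$value)
}

#' Write a probe track as bedGraph
#'
#' Each probe is written as a width-1 interval `[pos, pos + 1)` so that the
#' midpoint convention of [read_probe_track()] round-trips exactly.
#'
#' @param track a [probe_track()].
#' @param path output file.
#' @param header optional character vector written first as `#` comments.
#' @export
write_bedgraph <- function(track, path, header = NULL) {
  out <- data.table(chrom = track$chrom, start = as.integer(track$pos),
                    end = as.integer(track$pos) + 1L, value = track$value)
  con <- file(path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  close(con)
  fwrite(.fmt_num(out), path, sep = "\t", col.names = FALSE,
         append = !is.null(header))
  invisible(path)
}

#' Read gene/feature models from GFF3
#'
#' Converts GFF3 1-based closed coordinates to internal 0-based, assigning
#' TSS/TTS strand-aware (TSS = 5' end on the feature's strand). The
#' `feature_type` is taken from a `feature_type` attribute when present,
#' otherwise mapped from the GFF3 `type` column; `promoter_class` from the
#' attribute of the same name, defaulting to `"unknown"`.
#'
#' @param path GFF3 file.
#' @return a `data.table` with columns `id`, `chrom`, `strand`, `TSS`,
#'   `TTS`, `feature_type`, `promoter_class`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  keep <- strand %in% c("+", "-")
  if (any(!keep)) {
    warning(sum(!keep), " records without strand rejected")
    gr <- gr[keep]; mc <- mc[keep, , drop = FALSE]; strand <- strand[keep]
  }
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0("feat", seq_along(gr))
  if (anyDuplicated(id)) stop("duplicate feature IDs in ", path)
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)   # half-open end
  ftype <- if ("feature_type" %in% names(mc)) as.character(mc$feature_type)
    else names(.gff_type_of)[match(as.character(mc$type), .gff_type_of)]
  ftype[is.na(ftype)] <- "protein_coding"
  if (!all(ftype %in% FEATURE_TYPES))
    stop("feature_type outside vocabulary: ",
         paste(setdiff(ftype, FEATURE_TYPES), collapse = ", "))
  pclass <- if ("promoter_class" %in% names(mc))
    as.character(mc$promoter_class) else rep("unknown", length(gr))
  pclass[is.na(pclass) | !pclass %in% PROMOTER_CLASSES] <- "unknown"
  data.table(id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             TSS = ifelse(strand == "+", start0, end0),
             TTS = ifelse(strand == "+", end0, start0),
             feature_type = ftype,
             promoter_class = pclass)
}

#' Write gene/feature models as GFF3
#'
#' @param genes a gene-model table as returned by [read_annotation()] or
#'   [simulate_genome()].
#' @param path output file.
#' @param header optional `#` comment lines after the version pragma.
#' @export
write_gff3 <- function(genes, path, header = NULL) {
  start0 <- pmin(genes$TSS, genes$TTS)
  end0 <- pmax(genes$TSS, genes$TTS)
  attrs <- sprintf("ID=%s;feature_type=%s;promoter_class=%s",
                   genes$id, genes$feature_type, genes$promoter_class)
  out <- data.table(genes$chrom, "varnuc",
                    .gff_type_of[genes$feature_type],
                    start0 + 1L, end0, ".", genes$strand, ".", attrs)
  writeLines(c("##gff-version 3",
               if (!is.null(header)) paste0("# ", header)), path)
  fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE,
         quote = FALSE)
  invisible(path)
}

#' Write nucleosome calls as BED6 with a full TSV sidecar
#'
#' The BED interval is the 147-bp footprint centered on the call
#' (`start = center - 73`, `end = center + 74`), the score column carries
#' the enrichment score when present (0 otherwise) and the strand is `"."`
#' (intergenic nucleosomes have no strand; orientation comes from the
#' associated gene at analysis time). All call columns are written to a
#' `.tsv` sidecar next to the BED file.
#'
#' @param calls a call table ([call_nucleosomes()] or scored calls).
#' @param path BED output path; the sidecar replaces the extension by `.tsv`.
#' @param header optional `#` comment lines.
#' @return invisibly, `c(bed = path, tsv = sidecar)`.
#' @export
write_nucleosome_calls <- function(calls, path, header = NULL) {
  center <- as.integer(round(calls$center))
  start <- center - 73L
  if (any(start < 0)) {
    warning(sum(start < 0), " call(s) clamped to chromosome start")
    start <- pmax(start, 0L)
  }
  score <- if ("enrichment" %in% names(calls)) calls$enrichment else 0
  bed <- data.table(calls$chrom, start, center + 74L,
                    if ("id" %in% names(calls)) calls$id else
                      paste0("nuc", seq_len(nrow(calls))),
                    score, ".")
  con <- file(path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  close(con)
  fwrite(bed, path, sep = "\t", col.names = FALSE, append = !is.null(header))
  tsv <- paste0(sub("\\.[^.]+$", "", path), ".tsv")
  .write_tsv(calls, tsv, header)
  invisible(c(bed = path, tsv = tsv))
}

#' Read a nucleosome-call TSV sidecar
#' @param path TSV written by [write_nucleosome_calls()].
#' @return a `data.table` of calls.
#' @export
read_nucleosome_calls <- function(path) {
  fread(path, sep = "\t", skip = .n_comment_lines(path))
}

#' Read a gene x condition expression matrix from TSV
#'
#' First column = gene id, remaining columns = condition labels.
#'
#' @param path TSV file.
#' @return numeric matrix, rownames gene ids, colnames condition labels.
#' @export
read_expression_table <- function(path) {
  dt <- fread(path, sep = "\t", skip = .n_comment_lines(path))
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Write a gene x condition expression matrix as TSV
#' @param mat numeric matrix with gene rownames and condition colnames.
#' @param path output file.
#' @param header optional `#` comment lines.
#' @export
write_expression_table <- function(mat, path, header = NULL) {
  dt <- data.table(gene_id = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  .write_tsv(dt, path, header)
  invisible(path)
}

# format double columns with 17 significant digits so fread round-trips
# them bit-exactly (fwrite's default 15 digits does not)
.fmt_num <- function(dt) {
  out <- copy(as.data.table(dt))
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           sprintf("%.17g", out[[col]]))
  out
}

.write_tsv <- function(dt, path, header = NULL) {
  con <- file(path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  close(con)
  fwrite(.fmt_num(dt), path, sep = "\t", append = !is.null(header),
         col.names = TRUE)
  invisible(path)
}

.n_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (!length(l) || !startsWith(l, "#")) break
    n <- n + 1L
  }
  n
}
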