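#' Binned genome coverage track
#'
#' A fixed-bin coverage signal: one integer vector of read counts per
#' chromosome, a shared bin size, and the library's total mapped reads.
#'
#' @param counts Named list, chromosome -> numeric vector of per-bin
#'   read counts (bin i covers bases `[(i-1)*bin_size, i*bin_size)`,
#'   0-based).
#' @param bin_size Bin width in bp.
#' @param total_mapped_reads Total mapped reads in the library; defaults
#'   to the sum of the binned counts.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(counts, bin_size,
                           total_mapped_reads = sum(unlist(counts))) {
  stopifnot(is.list(counts), !is.null(names(counts)),
            bin_size >= 1, total_mapped_reads > 0)
  if (any(unlist(counts) < 0)) stop("coverage counts must be >= 0")
  structure(list(counts = counts, bin_size = as.integer(bin_size),
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "Coverage track: %d chrom(s), bin %d bp, %.4g mapped reads\n",
    length(x$counts), x$bin_size, x$total_mapped_reads))
  invisible(x)
}

.same_grid <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$counts), names(b$counts)) &&
    all(lengths(a$counts) == lengths(b$counts))
}

#' Read a fixed-bin bedGraph into a coverage track
#'
#' The file must tile each chromosome with constant-width intervals
#' (the last bin may be short).
#'
#' @param path bedGraph file path.
#' @param total_mapped_reads Library size; defaults to the sum of scores.
#' @return A [coverage_track()].
#' @export
read_bedgraph_track <- function(path, total_mapped_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  w <- BiocGenerics::width(gr)
  bin <- as.integer(max(w))
  if (any(w > bin)) stop("bedGraph bins exceed the inferred bin size")
  chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  counts <- lapply(chroms, function(ch) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    g <- g[BiocGenerics::order(g)]
    starts0 <- BiocGenerics::start(g) - 1L
    if (any(starts0 %% bin != 0L))
      stop("bedGraph intervals are not aligned to a fixed bin grid")
    n <- max(starts0) %/% bin + 1L
    v <- numeric(n)
    v[starts0 %/% bin + 1L] <- S4Vectors::mcols(g)$score
    v
  })
  names(counts) <- chroms
  if (is.null(total_mapped_reads)) total_mapped_reads <- sum(unlist(counts))
  coverage_track(counts, bin, total_mapped_reads)
}

#' Write a coverage track as bedGraph
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @export
write_bedgraph_track <- function(track, path) {
  rows <- lapply(names(track$counts), function(ch) {
    v <- track$counts[[ch]]
    data.frame(chrom = ch,
               start = (seq_along(v) - 1L) * track$bin_size,
               end = seq_along(v) * track$bin_size,
               score = signif(v, 6))
  })
  df <- do.call(rbind, rows)
  df <- df[df$score != 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Gene annotations with TSS/TES and optional gene class
#'
#' @param df A data.frame with columns `gene_id`, `chrom`, `tss`, `tes`,
#'   `strand` (+/-), and optionally `class_label`. Coordinates are
#'   0-based; on the minus strand `tss > tes`.
#' @return The validated data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("gene_annotation missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$tss == df$tes)) stop("tss must differ from tes")
  plus_bad <- df$strand == "+" & df$tss > df$tes
  minus_bad <- df$strand == "-" & df$tss < df$tes
  if (any(plus_bad | minus_bad))
    stop("orientation violated: need tss < tes on '+', tss > tes on '-'")
  if (is.null(df$class_label)) df$class_label <- "other"
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotations from BED6
#'
#' BED intervals (0-based, half-open) are oriented by strand: the TSS is
#' the 5' end and the TES the 3' end of each interval. An optional class
#' table (TSV with columns `gene_id`, `class_label`) attaches gene
#' classes, e.g. well-translated class I versus granule-localized
#' class II starvation-induced genes.
#'
#' @param path BED6 file path.
#' @param class_table Optional path to a gene-class TSV.
#' @return A [gene_annotation()].
#' @export
read_bed6_annotation <- function(path, class_table = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) stop("BED6 annotations must carry a strand")
  start0 <- BiocGenerics::start(gr) - 1L   # back to 0-based
  end0 <- BiocGenerics::end(gr)
  df <- data.frame(
    gene_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(st == "+", start0, end0),
    tes = ifelse(st == "+", end0, start0),
    strand = st, stringsAsFactors = FALSE)
  if (!is.null(class_table)) {
    cls <- utils::read.delim(class_table, stringsAsFactors = FALSE)
    df$class_label <- cls$class_label[match(df$gene_id, cls$gene_id)]
    df$class_label[is.na(df$class_label)] <- "other"
  }
  gene_annotation(df)
}

#' Write gene annotations as BED6
#'
#' @param ann A [gene_annotation()].
#' @param path Output path.
#' @export
write_bed6_annotation <- function(ann, path) {
  start0 <- ifelse(ann$strand == "+", ann$tss, ann$tes)
  end0 <- ifelse(ann$strand == "+", ann$tes, ann$tss)
  df <- data.frame(ann$chrom, start0, end0, ann$gene_id, 0L, ann$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# per-bp coverage density over 0-based half-open [start, end) on one
# chromosome, pro-rating partial bins; clips to chromosome bounds
.track_density <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  bs <- track$bin_size
  chrom_len <- length(v) * bs
  s <- max(0L, start)
  e <- min(chrom_len, end)
  if (e <= s) return(list(density = numeric(0), clipped = TRUE))
  pos <- seq.int(s, e - 1L)
  dens <- v[pos %/% bs + 1L] / bs
  list(density = dens, clipped = (s > start || e < end))
}

.track_reads <- function(track, chrom, start, end) {
  d <- .track_density(track, chrom, start, end)
  list(reads = sum(d$density), clipped = d$clipped)
}

#' Reads per kilobase per million mapped reads over an interval
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; clipped to the
#'   chromosome with a warning if out of bounds.
#' @return RPKM = reads * 1e9 / (interval length * total mapped reads).
#' @export
rpkm <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  r <- .track_reads(track, chrom, start, end)
  if (r$clipped) warning("interval clipped to chromosome bounds")
  len <- end - start
  if (len <= 0) stop("interval length must be positive")
  r$reads * 1e9 / (len * track$total_mapped_reads)
}

#' ChIP-over-input normalized density
#'
#' The ratio of immunoprecipitate to input RPKM over an interval,
#' with a pseudocount guarding against empty input windows:
#' `(RPKM_chip + pseudocount) / (RPKM_input + pseudocount)`.
#'
#' @param chip,input_ [coverage_track()]s on the same bin grid.
#' @param chrom,start,end Interval (0-based, half-open).
#' @param pseudocount Added to both RPKM values; default 0.
#' @return A list: `ratio`, `rpkm_chip`, `rpkm_input`, `degenerate`
#'   (TRUE when the raw input RPKM is zero).
#' @export
normalized_density <- function(chip, input_, chrom, start, end,
                               pseudocount = 0) {
  stopifnot(inherits(chip, "coverage_track"),
            inherits(input_, "coverage_track"))
  if (!.same_grid(chip, input_))
    stop("chip and input tracks are on different bin grids")
  rc <- rpkm(chip, chrom, start, end)
  ri <- rpkm(input_, chrom, start, end)
  if (ri == 0 && pseudocount == 0)
    stop("zero input coverage and no pseudocount: ratio undefined")
  list(ratio = (rc + pseudocount) / (ri + pseudocount),
       rpkm_chip = rc, rpkm_input = ri, degenerate = ri == 0)
}

# per-gene scaled profile axis: upstream flank (fixed bins), body
# (mean-pooled to body_bins), downstream flank
.gene_profile <- function(track, gene, upstream_bp, downstream_bp,
                          body_bins, flank_bin_bp) {
  ch <- gene$chrom
  minus <- gene$strand == "-"
  if (!minus) {
    up <- .track_density(track, ch, gene$tss - upstream_bp, gene$tss)$density
    body <- .track_density(track, ch, gene$tss, gene$tes)$density
    down <- .track_density(track, ch, gene$tes, gene$tes + downstream_bp)$density
  } else {
    up <- rev(.track_density(track, ch, gene$tss, gene$tss + upstream_bp)$density)
    body <- rev(.track_density(track, ch, gene$tes, gene$tss)$density)
    down <- rev(.track_density(track, ch, gene$tes - downstream_bp,
                               gene$tes)$density)
  }
  pad <- function(v, n) { length(v) <- n; v }  # NA-pad clipped flanks
  up <- pad(rev(pad(rev(up), upstream_bp)), upstream_bp)
  down <- pad(down, downstream_bp)
  pool <- function(v, width) {
    idx <- ceiling(seq_along(v) / width)
    as.numeric(tapply(v, idx, mean, na.rm = TRUE))
  }
  body_pooled <- as.numeric(tapply(
    body, ceiling(seq_along(body) / (length(body) / body_bins)), mean))
  length(body_pooled) <- body_bins
  c(pool(up, flank_bin_bp), body_pooled, pool(down, flank_bin_bp))
}

#' Strand-aware scaled metagene profile
#'
#' For each gene, coverage density is laid out on a normalized axis:
#' an unscaled upstream flank (default 500 bp before the TSS, binned at
#' `flank_bin_bp`), the gene body rescaled to `body_bins` bins by mean
#' pooling, and an unscaled downstream flank past the TES. Minus-strand
#' genes are reversed so the axis always runs promoter to terminator.
#' When a control track is given, the per-bin value is the ratio of
#' depth-normalized target to control density (with pseudocount), the
#' form used to profile a specific factor over a nonspecific IP control.
#'
#' @param target A [coverage_track()] for the factor of interest.
#' @param control Optional [coverage_track()] (e.g. a nonspecific IP)
#'   on the same bin grid.
#' @param annotations A [gene_annotation()].
#' @param upstream_bp,downstream_bp Flank sizes in bp.
#' @param body_bins Number of scaled gene-body bins.
#' @param flank_bin_bp Flank bin width in bp.
#' @param pseudocount Added to both depth-normalized densities in ratio
#'   mode.
#' @return A `metagene_profile`: `positions` (axis labels), `matrix`
#'   (genes x positions), `summary` (per-position mean and 95% CI),
#'   `segments` (bin counts per segment), `n_excluded`.
#' @export
metagene <- function(target, control = NULL, annotations,
                     upstream_bp = 500, downstream_bp = 500,
                     body_bins = 100, flank_bin_bp = 10,
                     pseudocount = 0.5) {
  stopifnot(inherits(target, "coverage_track"),
            inherits(annotations, "gene_annotation"))
  if (nrow(annotations) == 0L) stop("no genes in annotation")
  if (!is.null(control) && !.same_grid(target, control))
    stop("target and control tracks are on different bin grids")
  glen <- abs(annotations$tes - annotations$tss)
  keep <- glen >= body_bins
  if (sum(!keep) > 0L)
    warning(sum(!keep), " gene(s) shorter than one body bin excluded")
  ann <- annotations[keep, , drop = FALSE]
  if (nrow(ann) == 0L) stop("all genes were filtered out")

  scale_t <- 1e9 / target$total_mapped_reads
  scale_c <- if (!is.null(control)) 1e9 / control$total_mapped_reads else NA
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    pt <- .gene_profile(target, g, upstream_bp, downstream_bp,
                        body_bins, flank_bin_bp) * scale_t
    if (is.null(control)) return(pt)
    pc <- .gene_profile(control, g, upstream_bp, downstream_bp,
                        body_bins, flank_bin_bp) * scale_c
    (pt + pseudocount) / (pc + pseudocount)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- ann$gene_id
  n_up <- ceiling(upstream_bp / flank_bin_bp)
  n_down <- ceiling(downstream_bp / flank_bin_bp)
  positions <- c(sprintf("up%03d", seq_len(n_up)),
                 sprintf("body%03d", seq_len(body_bins)),
                 sprintf("down%03d", seq_len(n_down)))
  colnames(mat) <- positions
  mu <- colMeans(mat, na.rm = TRUE)
  se <- apply(mat, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  structure(
    list(positions = positions, matrix = mat,
         summary = data.frame(position = positions, mean = mu,
                              lo = mu - 1.96 * se, hi = mu + 1.96 * se,
                              row.names = NULL),
         segments = c(upstream = n_up, body = body_bins,
                      downstream = n_down),
         n_excluded = sum(!keep)),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "Metagene profile: %d genes x %d positions (%d up / %d body / %d down)\n",
    nrow(x$matrix), ncol(x$matrix), x$segments["upstream"],
    x$segments["body"], x$segments["downstream"]))
  invisible(x)
}

#' Promoter-window enrichment of a target over a control IP
#'
#' Raw read counts in the strand-aware promoter window
#' `[TSS - upstream_bp, TSS)` (sense orientation) are compared between
#' the target and a control IP after scaling the control counts to the
#' target library depth:
#' `log2((target + pc) / (control_scaled + pc))`. Window length is
#' constant across genes, so counts rather than RPKM are used.
#'
#' @param target,control [coverage_track()]s on the same bin grid.
#' @param annotations A [gene_annotation()].
#' @param pseudocount Added to both counts; default 0.5 reads.
#' @param upstream_bp Promoter window size; default 500.
#' @return A data.frame of class `window_enrichment`: `gene_id`,
#'   `target_reads`, `control_reads` (depth-scaled), `log2_ratio`,
#'   `class_label`, `clipped`.
#' @export
promoter_enrichment <- function(target, control, annotations,
                                pseudocount = 0.5, upstream_bp = 500) {
  stopifnot(inherits(target, "coverage_track"),
            inherits(control, "coverage_track"),
            inherits(annotations, "gene_annotation"))
  if (!.same_grid(target, control))
    stop("target and control tracks are on different bin grids")
  if (nrow(annotations) == 0L) stop("no genes in annotation")
  depth_scale <- target$total_mapped_reads / control$total_mapped_reads
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    g <- annotations[i, ]
    win <- if (g$strand == "+") c(g$tss - upstream_bp, g$tss)
    else c(g$tss, g$tss + upstream_bp)
    rt <- .track_reads(target, g$chrom, win[1L], win[2L])
    rc <- .track_reads(control, g$chrom, win[1L], win[2L])
    ctrl_scaled <- rc$reads * depth_scale
    data.frame(gene_id = g$gene_id,
               target_reads = rt$reads,
               control_reads = ctrl_scaled,
               log2_ratio = log2((rt$reads + pseudocount) /
                                   (ctrl_scaled + pseudocount)),
               class_label = g$class_label,
               clipped = rt$clipped || rc$clipped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_enrichment", "data.frame")
  out
}

#' Compare promoter enrichment between two gene classes
#'
#' Welch two-sample t-test on per-gene log2 enrichment ratios between
#' two gene classes, with class means and empirical CDF coordinates for
#' cumulative-distribution plots.
#'
#' @param enrichments A [promoter_enrichment()] result.
#' @param class_a,class_b Class labels to compare (>= 2 genes each).
#' @return A list: `p_value`, `mean_a`, `mean_b`, `difference`
#'   (a minus b), `t_statistic`, `df`, `n_a`, `n_b`, and `ecdf`
#'   (data.frame of sorted log2 ratios with cumulative fractions).
#' @export
class_compare <- function(enrichments, class_a, class_b) {
  stopifnot(inherits(enrichments, "window_enrichment") ||
              is.data.frame(enrichments))
  xa <- enrichments$log2_ratio[enrichments$class_label == class_a]
  xb <- enrichments$log2_ratio[enrichments$class_label == class_b]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each compared class needs >= 2 genes")
  ht <- stats::t.test(xa, xb)
  ecdf_df <- function(x, lab) {
    x <- sort(x)
    data.frame(class_label = lab, log2_ratio = x,
               cum_fraction = seq_along(x) / length(x))
  }
  list(p_value = unname(ht$p.value),
       mean_a = mean(xa), mean_b = mean(xb),
       difference = mean(xa) - mean(xb),
       t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       n_a = length(xa), n_b = length(xb),
       ecdf = rbind(ecdf_df(xa, class_a), ecdf_df(xb, class_b)))
}
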