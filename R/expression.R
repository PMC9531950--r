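#' Reporter protein-synthesis rate from paired luciferase wells
#'
#' Nanoluciferase signal accumulated over a short window reports the
#' protein-synthesis rate once the translation-independent background is
#' removed: each well's luminescence is divided by its OD660, and the
#' OD-normalized reading of a paired well treated with cycloheximide
#' (translation halted a few minutes earlier) is subtracted.
#'
#' @param records A data.frame with columns `strain`, `condition`,
#'   `chx` (logical), `luminescence`, `od660`.
#' @param strain,condition The pair of wells to evaluate.
#' @return A list: `rate` (arbitrary units per OD), `normalized_lum`,
#'   `normalized_chx`, `qc_flag` (`"negative_rate"` when the CHX
#'   baseline exceeds the signal, else `"ok"`).
#' @export
protein_rate <- function(records, strain, condition) {
  need <- c("strain", "condition", "chx", "luminescence", "od660")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("luciferase records missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(records$od660 <= 0)) stop("od660 must be > 0")
  if (any(records$luminescence < 0)) stop("luminescence must be >= 0")
  sub <- records[records$strain == strain &
                   records$condition == condition, , drop = FALSE]
  sig <- sub[!sub$chx, , drop = FALSE]
  bg <- sub[sub$chx, , drop = FALSE]
  if (nrow(sig) == 0L || nrow(bg) == 0L)
    stop(sprintf("strain %s / condition %s lacks a CHX or non-CHX well",
                 strain, condition))
  lum <- mean(sig$luminescence / sig$od660)
  chx <- mean(bg$luminescence / bg$od660)
  rate <- lum - chx
  list(rate = rate, normalized_lum = lum, normalized_chx = chx,
       qc_flag = if (rate < 0) "negative_rate" else "ok")
}

#' Translatability from relative protein and mRNA levels
#'
#' Translatability (a translational-efficiency proxy) is the log2
#' relative protein-synthesis rate minus the log2 relative mRNA
#' abundance, both expressed as fold over the same control. Protein
#' down while mRNA is up therefore yields a negative translatability.
#'
#' @param protein_rel Protein synthesis fold over control (> 0).
#' @param mrna_rel mRNA abundance fold over control (> 0).
#' @param strain Optional label carried through.
#' @return A `translatability_result`: `strain`, `protein_rel`,
#'   `mrna_rel`, `translatability_log2`, `translatability_fold`.
#' @export
translatability <- function(protein_rel, mrna_rel, strain = NA_character_) {
  stopifnot(is.numeric(protein_rel), is.numeric(mrna_rel))
  if (any(protein_rel <= 0) || any(mrna_rel <= 0))
    stop("protein and mRNA folds must be strictly positive")
  tl <- log2(protein_rel) - log2(mrna_rel)
  structure(list(strain = strain, protein_rel = protein_rel,
                 mrna_rel = mrna_rel, translatability_log2 = tl,
                 translatability_fold = 2^tl),
            class = "translatability_result")
}

#' @export
print.translatability_result <- function(x, ...) {
  cat(sprintf(
    "Translatability: protein %.3gx, mRNA %.3gx -> log2 TE = %.3g (%.3g-fold)\n",
    x$protein_rel, x$mrna_rel, x$translatability_log2,
    x$translatability_fold))
  invisible(x)
}

#' Ribosome occupancy from region read counts
#'
#' Occupancy is the ribosome-footprint density over the mRNA density in
#' the ORF region downstream of the initiation zone (120 nt after the
#' AUG to the ORF end), each normalized to library depth in reads per
#' million: `(ribo/ribo_total * 1e6) / (rna/rna_total * 1e6)`.
#'
#' @param ribo_reads,rna_reads Footprint and mRNA read counts in the
#'   downstream region.
#' @param ribo_total,rna_total Library-wide aligned read totals (> 0).
#' @param orf_length_nt Optional ORF length; an ORF of 120 nt or
#'   shorter has no downstream region and is an error.
#' @return A list: `occupancy` (NA sentinel with `qc_flag =
#'   "no_rna_reads"` when `rna_reads == 0`), `ribo_rpm`, `rna_rpm`,
#'   `qc_flag`.
#' @export
ribosome_occupancy <- function(ribo_reads, rna_reads, ribo_total,
                               rna_total, orf_length_nt = NULL) {
  stopifnot(ribo_reads >= 0, rna_reads >= 0)
  if (ribo_total <= 0 || rna_total <= 0)
    stop("library totals must be > 0")
  if (!is.null(orf_length_nt) && orf_length_nt <= 120)
    stop("ORF of <= 120 nt has no downstream region")
  ribo_rpm <- ribo_reads / ribo_total * 1e6
  rna_rpm <- rna_reads / rna_total * 1e6
  if (rna_reads == 0)
    return(list(occupancy = NA_real_, ribo_rpm = ribo_rpm,
                rna_rpm = rna_rpm, qc_flag = "no_rna_reads"))
  list(occupancy = ribo_rpm / rna_rpm, ribo_rpm = ribo_rpm,
       rna_rpm = rna_rpm, qc_flag = "ok")
}

#' Per-base ribosome occupancy along an mRNA
#'
#' Divides the ribosome read count at each base by the gene's average
#' mRNA reads per base.
#'
#' @param ribo_per_base Numeric vector of footprint counts per base.
#' @param rna_mean_per_base Scalar average mRNA reads per base (> 0).
#' @return Numeric vector of per-base occupancy.
#' @export
positional_occupancy <- function(ribo_per_base, rna_mean_per_base) {
  stopifnot(is.numeric(ribo_per_base))
  if (length(rna_mean_per_base) != 1L || rna_mean_per_base <= 0)
    stop("rna_mean_per_base must be a single positive value")
  if (any(ribo_per_base < 0)) stop("negative footprint counts")
  ribo_per_base / rna_mean_per_base
}

#' Fraction of cells with mRNA-containing granule foci
#'
#' @param n_foci Number of cells with visible reporter-mRNA foci.
#' @param n_cells Number of cells scored (> 0).
#' @return The proportion `n_foci / n_cells`.
#' @export
foci_fraction <- function(n_foci, n_cells) {
  stopifnot(length(n_foci) == length(n_cells))
  if (any(n_cells <= 0)) stop("n_cells must be > 0")
  if (any(n_foci < 0) || any(n_foci > n_cells))
    stop("n_foci must lie in [0, n_cells]")
  n_foci / n_cells
}

#' Compare foci fractions between two groups
#'
#' Two-sample comparison of the proportion of cells with mRNA foci:
#' either a t-test on per-replicate fractions (default) or a pooled
#' two-proportion test.
#'
#' @param foci_a,cells_a Replicate foci and cell counts, group A.
#' @param foci_b,cells_b Replicate foci and cell counts, group B.
#' @param method `"t"` (t-test on replicate fractions) or `"prop"`
#'   (two-proportion test on pooled counts).
#' @return A list: `fraction_a`, `fraction_b` (pooled), `p_value`,
#'   `method`.
#' @export
compare_foci <- function(foci_a, cells_a, foci_b, cells_b,
                         method = c("t", "prop")) {
  method <- match.arg(method)
  fa <- foci_fraction(foci_a, cells_a)
  fb <- foci_fraction(foci_b, cells_b)
  pooled_a <- sum(foci_a) / sum(cells_a)
  pooled_b <- sum(foci_b) / sum(cells_b)
  if (method == "t") {
    if (length(fa) < 2L || length(fb) < 2L)
      stop("t-test mode needs >= 2 replicate fractions per group")
    if (stats::sd(c(fa, fb)) == 0) {
      p <- 1  # identical fractions everywhere: no evidence of difference
    } else {
      p <- stats::t.test(fa, fb)$p.value
    }
  } else {
    ht <- suppressWarnings(
      stats::prop.test(c(sum(foci_a), sum(foci_b)),
                       c(sum(cells_a), sum(cells_b))))
    p <- ht$p.value
  }
  list(fraction_a = pooled_a, fraction_b = pooled_b,
       p_value = unname(p), method = method)
}
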