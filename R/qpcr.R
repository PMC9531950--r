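#' Structured qPCR cycle-threshold table
#'
#' Validates a long-format table of Ct records. Columns: `sample`,
#' `fraction` (one of `"IP"`, `"input"`, `"total"`), `strain`, `target`,
#' `replicate`, `ct` (cycles, in (0, 45)).
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `ct_table`.
#' @export
ct_table <- function(df) {
  need <- c("sample", "fraction", "strain", "target", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("ct_table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$fraction %in% c("IP", "input", "total")))
    stop("'fraction' must be one of IP, input, total")
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0 | df$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from TSV
#'
#' @param path Path to a tab-separated file with header columns
#'   sample, fraction, strain, target, replicate, ct.
#' @param exclude Optional path to an exclusion list (one
#'   `sample<TAB>target` pair per line, header allowed) of records to
#'   drop before analysis, mirroring manual removal of flagged samples.
#' @return A [ct_table()].
#' @export
read_ct_tsv <- function(path, exclude = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(exclude)) {
    ex <- utils::read.delim(exclude, stringsAsFactors = FALSE)
    drop <- paste(df$sample, df$target) %in% paste(ex$sample, ex$target)
    df <- df[!drop, , drop = FALSE]
  }
  ct_table(df)
}

# replicate-mean Ct and variance for one (sample, target) cell,
# optionally restricted to a fraction/strain
.ct_cell <- function(tab, sample = NULL, target = NULL, fraction = NULL,
                     strain = NULL) {
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(sample)) keep <- keep & tab$sample == sample
  if (!is.null(target)) keep <- keep & tab$target == target
  if (!is.null(fraction)) keep <- keep & tab$fraction == fraction
  if (!is.null(strain)) keep <- keep & tab$strain == strain
  ct <- tab$ct[keep]
  if (length(ct) == 0L) {
    lab <- paste(c(sample, target, fraction, strain), collapse = " / ")
    stop("no Ct records for combination: ", lab)
  }
  list(mean = mean(ct), var = stats::var(ct), n = length(ct))
}

.cell_se2 <- function(cell) {
  if (cell$n < 2L || is.na(cell$var)) 0 else cell$var / cell$n
}

#' Fold change by the delta-delta-Ct method
#'
#' Computes \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} within each
#' sample (replicate-mean Ct), \eqn{\Delta\Delta Ct = \Delta Ct_{test} -
#' \Delta Ct_{calibrator}}, and the fold change \eqn{2^{-\Delta\Delta Ct}}
#' assuming perfect doubling per cycle. The standard error is propagated
#' from replicate variances on the Ct (log2) scale.
#'
#' @param table A [ct_table()].
#' @param target Target gene label.
#' @param reference_gene Reference (normalizer) gene, e.g. ACT1.
#' @param test_sample,calibrator_sample Sample labels.
#' @return A list: `fold`, `log2_fold`, `ddct`, `se_log2`.
#' @export
delta_delta_ct <- function(table, target, reference_gene,
                           test_sample, calibrator_sample) {
  stopifnot(inherits(table, "ct_table"))
  tt <- .ct_cell(table, sample = test_sample, target = target)
  tr <- .ct_cell(table, sample = test_sample, target = reference_gene)
  ct <- .ct_cell(table, sample = calibrator_sample, target = target)
  cr <- .ct_cell(table, sample = calibrator_sample, target = reference_gene)
  ddct <- (tt$mean - tr$mean) - (ct$mean - cr$mean)
  se <- sqrt(.cell_se2(tt) + .cell_se2(tr) + .cell_se2(ct) + .cell_se2(cr))
  list(fold = 2^(-ddct), log2_fold = -ddct, ddct = ddct, se_log2 = se)
}

#' RIP enrichment with the three-stage normalization cascade
#'
#' RNA-immunoprecipitation enrichment of a target mRNA: Ct values are
#' first normalized to the reference gene within each (strain, fraction),
#' then the IP fraction is normalized to the input fraction within each
#' strain, and finally the tagged-strain enrichment is normalized to the
#' untagged wild-type IP control. When wild-type records are absent the
#' two-stage (IP-over-input) enrichment is returned with
#' `wt_normalized = FALSE` and a warning, never silently.
#'
#' @param table A [ct_table()] containing IP and input fractions.
#' @param target Target gene label.
#' @param reference_gene Reference gene, e.g. ACT1.
#' @param ip_strain Strain carrying the tagged protein.
#' @param wt_strain Untagged control strain, or `NULL` for two-stage mode.
#' @param input_fraction Fraction of lysate used as input (e.g. 0.01 for
#'   a 1% input). The correction is a constant log2 offset that cancels
#'   in three-stage mode; the default 1.0 applies no correction.
#' @return An `enrichment_result`: `target`, `strain`, `enrichment`,
#'   `log2_enrichment`, `se_log2`, `wt_normalized`.
#' @export
rip_enrichment <- function(table, target, reference_gene, ip_strain,
                           wt_strain = NULL, input_fraction = 1.0) {
  stopifnot(inherits(table, "ct_table"))
  stage12 <- function(strain) {
    ip_t <- .ct_cell(table, target = target, fraction = "IP", strain = strain)
    ip_r <- .ct_cell(table, target = reference_gene, fraction = "IP",
                     strain = strain)
    in_t <- .ct_cell(table, target = target, fraction = "input",
                     strain = strain)
    in_r <- .ct_cell(table, target = reference_gene, fraction = "input",
                     strain = strain)
    list(ddct = (ip_t$mean - ip_r$mean) - (in_t$mean - in_r$mean),
         se2 = .cell_se2(ip_t) + .cell_se2(ip_r) +
           .cell_se2(in_t) + .cell_se2(in_r))
  }
  ip <- stage12(ip_strain)
  wt <- NULL
  if (!is.null(wt_strain)) {
    wt <- tryCatch(stage12(wt_strain), error = function(e) NULL)
    if (is.null(wt))
      warning("wild-type control records absent; ",
              "returning two-stage (IP/input) enrichment")
  }
  if (!is.null(wt)) {
    log2_enr <- -(ip$ddct - wt$ddct)
    se <- sqrt(ip$se2 + wt$se2)
    wt_norm <- TRUE
  } else {
    log2_enr <- -ip$ddct + log2(input_fraction)
    se <- sqrt(ip$se2)
    wt_norm <- FALSE
  }
  structure(list(target = target, strain = ip_strain,
                 enrichment = 2^log2_enr, log2_enrichment = log2_enr,
                 se_log2 = se, wt_normalized = wt_norm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("RIP enrichment of %s in %s: %.3g-fold (log2 = %.3g +/- %.2g)%s\n",
              x$target, x$strain, x$enrichment, x$log2_enrichment, x$se_log2,
              if (x$wt_normalized) "" else " [no WT normalization]"))
  invisible(x)
}

#' Build a fold-induction time course from a Ct table
#'
#' For each time-point sample, the fold over the baseline (pre-stress)
#' sample is computed per replicate via the delta-delta-Ct method; the
#' result feeds the kinetics module as a fold-scale [time_course()].
#'
#' @param table A [ct_table()].
#' @param target Target gene label.
#' @param reference_gene Reference gene.
#' @param timepoint_samples Either a named numeric vector
#'   (sample label -> time in minutes) or a character vector of sample
#'   labels whose trailing integer encodes the time (e.g. `"starve_15"`).
#' @param baseline_sample The t = 0 calibrator sample label.
#' @param condition Condition label for the returned course.
#' @return A [time_course()] with `scale = "fold_over_t0"`.
#' @export
induction_series <- function(table, target, reference_gene,
                             timepoint_samples, baseline_sample,
                             condition = target) {
  stopifnot(inherits(table, "ct_table"))
  if (is.null(names(timepoint_samples))) {
    labs <- as.character(timepoint_samples)
    times <- suppressWarnings(as.numeric(sub(".*?([0-9]+(\\.[0-9]+)?)$",
                                             "\\1", labs)))
    if (any(is.na(times)))
      stop("cannot parse a time from sample label(s): ",
           paste(labs[is.na(times)], collapse = ", "))
    timepoint_samples <- stats::setNames(times, labs)
  }
  ord <- order(timepoint_samples)
  samples <- names(timepoint_samples)[ord]
  times <- unname(timepoint_samples[ord])

  base_t <- .ct_cell(table, sample = baseline_sample, target = target)
  base_r <- .ct_cell(table, sample = baseline_sample,
                     target = reference_gene)
  base_dct <- base_t$mean - base_r$mean

  fold_reps <- lapply(samples, function(s) {
    sub <- table[table$sample == s & table$target %in%
                   c(target, reference_gene), , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    vapply(reps, function(r) {
      ct_t <- sub$ct[sub$target == target & sub$replicate == r]
      ct_r <- sub$ct[sub$target == reference_gene & sub$replicate == r]
      if (length(ct_t) == 0L || length(ct_r) == 0L)
        stop(sprintf("sample %s replicate %s lacks target or reference Ct",
                     s, r))
      2^(-((mean(ct_t) - mean(ct_r)) - base_dct))
    }, numeric(1L))
  })
  nrep <- max(vapply(fold_reps, length, integer(1L)))
  mat <- t(vapply(fold_reps, function(v) {
    length(v) <- nrep  # pad ragged replicates with NA
    v
  }, numeric(nrep)))
  if (nrep == 1L) mat <- matrix(unlist(fold_reps), ncol = 1L)
  time_course(condition, times, mat, scale = "fold_over_t0")
}
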