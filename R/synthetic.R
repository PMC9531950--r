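#' Configuration for the synthetic-data generators
#'
#' One global seed deterministically expands into per-generator
#' substreams (a fixed offset per generator), so adding one generator
#' never perturbs another's output.
#'
#' @param seed Integer seed fixing all generator output.
#' @param noise_cv Coefficient of variation of multiplicative
#'   (lognormal) measurement noise; 0 gives exact noiseless output.
#' @param n_replicates Replicates per measurement.
#' @param time_grid Time grid in minutes for time-course generators.
#' @param genome_spec List: `n_chroms`, `n_genes`, `gene_length`
#'   (min, max bp), `class_props` (named proportions over
#'   `class_I`, `class_II`, `other`), `bin_size` (bp).
#' @param depth Expected total reads per coverage track.
#' @return A `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             noise_cv = 0.05,
                             n_replicates = 4L,
                             time_grid = c(0, 5, 10, 15, 30, 45),
                             genome_spec = list(
                               n_chroms = 2L, n_genes = 60L,
                               gene_length = c(600L, 3000L),
                               class_props = c(class_I = 0.25,
                                               class_II = 0.25,
                                               other = 0.5),
                               bin_size = 10L),
                             depth = 1e6) {
  stopifnot(is.numeric(seed), length(seed) == 1L, noise_cv >= 0,
            n_replicates >= 1L, length(time_grid) >= 1L, depth > 0)
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 time_grid = as.numeric(time_grid),
                 genome_spec = genome_spec, depth = depth),
            class = "generator_config")
}

# fixed substream offsets, one per generator
.substream <- c(timecourse = 101L, ct = 211L, genome = 307L,
                luciferase = 401L, counts = 503L)

.with_substream <- function(cfg, which, code) {
  withr::with_seed((cfg$seed + .substream[[which]]) %% .Machine$integer.max,
                   code)
}

# lognormal multiplicative noise with unit mean and given CV
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate a noisy replicated time course
#'
#' The closed-form induction or decay trajectory multiplied by
#' lognormal noise with unit mean and coefficient of variation
#' `cfg$noise_cv`, `cfg$n_replicates` replicates per time point.
#'
#' @param cfg A [generator_config()].
#' @param model An [induction_model()].
#' @param mode `"induction"` or `"decay"`.
#' @param scale `"absolute"` or `"fold_over_t0"` (fold requires
#'   `model$x0 > 0` in induction mode).
#' @param condition Condition label.
#' @return A [time_course()].
#' @export
gen_timecourse <- function(cfg, model,
                           mode = c("induction", "decay"),
                           scale = c("absolute", "fold_over_t0"),
                           condition = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(model, "induction_model"))
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  times <- cfg$time_grid
  if (length(times) == 0L) stop("empty time grid")
  base <- if (mode == "induction") {
    induction_solution(times, model$alpha, model$beta, model$x0)
  } else {
    if (model$x0 <= 0) stop("decay mode requires x0 > 0")
    model$x0 * exp(-model$alpha * times)
  }
  if (scale == "fold_over_t0") {
    if (base[1L] <= 0)
      stop("fold scale requires a positive abundance at t = 0")
    base <- base / base[1L]
  }
  vals <- .with_substream(cfg, "timecourse", {
    matrix(base, nrow = length(times), ncol = cfg$n_replicates) *
      matrix(.lognoise(length(times) * cfg$n_replicates, cfg$noise_cv),
             nrow = length(times))
  })
  time_course(condition, times, vals, scale = scale)
}

#' Generate a qPCR Ct table from true abundances
#'
#' Emulates the inverse log2-linear response of cycle thresholds to
#' template abundance: `Ct = c0 - log2(abundance) + N(0, sigma_ct)`.
#' The reference gene is held at constant abundance in every sample.
#'
#' @param cfg A [generator_config()].
#' @param abundances Named list or matrix: `abundances[[sample]][target]`
#'   strictly positive true abundances, or a matrix with samples as
#'   rows and targets as columns.
#' @param reference_gene Reference gene label (constant abundance
#'   `ref_abundance` in every sample).
#' @param c0 Ct of one abundance unit; default 30.
#' @param sigma_ct Gaussian Ct noise SD in cycles; default 0.
#' @param ref_abundance Reference-gene abundance; default 1.
#' @param fraction,strain Constant labels applied to all records.
#' @return A [ct_table()].
#' @export
gen_ct_table <- function(cfg, abundances, reference_gene = "ACT1",
                         c0 = 30, sigma_ct = 0, ref_abundance = 1,
                         fraction = "total", strain = "wt") {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.matrix(abundances)) {
    ab <- lapply(seq_len(nrow(abundances)), function(i) abundances[i, ])
    names(ab) <- rownames(abundances)
    abundances <- ab
  }
  if (any(unlist(abundances) <= 0))
    stop("abundances must be strictly positive")
  rows <- list()
  for (s in names(abundances)) {
    targ <- c(abundances[[s]],
              stats::setNames(ref_abundance, reference_gene))
    for (g in names(targ)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, fraction = fraction, strain = strain, target = g,
        replicate = seq_len(cfg$n_replicates),
        ct_true = c0 - log2(targ[[g]]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$ct <- .with_substream(cfg, "ct", {
    df$ct_true + stats::rnorm(nrow(df), 0, sigma_ct)
  })
  df$ct_true <- NULL
  ct_table(df)
}

#' Generate a synthetic genome with class-structured ChIP coverage
#'
#' Lays out non-overlapping genes with random strands on a small
#' genome, assigns gene classes by the configured proportions, and
#' draws Poisson bin counts for three tracks: a target IP with
#' promoter-window enrichment (mean multiplied by the class fold in
#' `[TSS - 500, TSS)`, strand-aware), plus background-only control IP
#' and input tracks. Background means are set so each track totals
#' about `cfg$depth` reads.
#'
#' @param cfg A [generator_config()].
#' @param class_enrichment Named numeric vector of promoter fold
#'   enrichment per class label, e.g. `c(class_II = 8)`; classes
#'   absent from the vector get fold 1.
#' @param promoter_bp Enriched promoter window size; default 500.
#' @return A list: `annotations` ([gene_annotation()]), `target`,
#'   `control`, `input` ([coverage_track()]s), and `truth` (the
#'   per-gene true promoter fold).
#' @export
gen_genome_coverage <- function(cfg, class_enrichment = c(class_II = 8),
                                promoter_bp = 500) {
  stopifnot(inherits(cfg, "generator_config"))
  if (any(class_enrichment <= 0)) stop("enrichment folds must be > 0")
  gs <- cfg$genome_spec
  .with_substream(cfg, "genome", {
    per_chrom <- ceiling(gs$n_genes / gs$n_chroms)
    genes <- list()
    chrom_len <- integer(gs$n_chroms)
    gid <- 0L
    for (ci in seq_len(gs$n_chroms)) {
      pos <- 600L  # room for the first upstream window
      for (k in seq_len(per_chrom)) {
        if (gid >= gs$n_genes) break
        gid <- gid + 1L
        len <- sample(seq(gs$gene_length[1L], gs$gene_length[2L]), 1L)
        strand <- sample(c("+", "-"), 1L)
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene%03d", gid),
          chrom = sprintf("chr%d", ci),
          tss = if (strand == "+") pos else pos + len,
          tes = if (strand == "+") pos + len else pos,
          strand = strand, stringsAsFactors = FALSE)
        pos <- pos + len + sample(1000:1600, 1L)
      }
      chrom_len[ci] <- pos + 600L
    }
    ann <- do.call(rbind, genes)
    props <- gs$class_props
    cls <- sample(names(props), nrow(ann), replace = TRUE, prob = props)
    ann$class_label <- cls
    ann <- gene_annotation(ann)

    bin <- gs$bin_size
    nbins <- ceiling(chrom_len / bin)
    lambda0 <- cfg$depth / sum(nbins)
    draw_track <- function(promoter_fold_by_gene) {
      counts <- lapply(seq_len(gs$n_chroms), function(ci) {
        lam <- rep(lambda0, nbins[ci])
        sub <- ann[ann$chrom == sprintf("chr%d", ci), , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
          f <- promoter_fold_by_gene[[sub$gene_id[i]]]
          if (is.null(f) || f == 1) next
          win <- if (sub$strand[i] == "+")
            c(sub$tss[i] - promoter_bp, sub$tss[i])
          else c(sub$tss[i], sub$tss[i] + promoter_bp)
          b1 <- max(1L, win[1L] %/% bin + 1L)
          b2 <- min(nbins[ci], (win[2L] - 1L) %/% bin + 1L)
          lam[b1:b2] <- lam[b1:b2] * f
        }
        stats::rpois(nbins[ci], lam)
      })
      names(counts) <- sprintf("chr%d", seq_len(gs$n_chroms))
      # libraries are sequenced to a set depth: record the nominal
      # library size, not the realized binned sum, as the track total
      coverage_track(counts, bin, total_mapped_reads = cfg$depth)
    }
    truth <- stats::setNames(
      ifelse(ann$class_label %in% names(class_enrichment),
             class_enrichment[ann$class_label], 1),
      ann$gene_id)
    target <- draw_track(as.list(truth))
    control <- draw_track(list())
    input <- draw_track(list())
    list(annotations = ann, target = target, control = control,
         input = input, truth = truth)
  })
}

#' Generate paired CHX/non-CHX luciferase wells
#'
#' Each strain/condition gets a non-CHX well with signal
#' `(rate + background) * od * gain` and a paired CHX well carrying
#' only the translation-independent background `background * od *
#' gain`, both multiplied by lognormal noise of CV `cfg$noise_cv`.
#'
#' @param cfg A [generator_config()].
#' @param true_rates Data.frame with columns `strain`, `condition`,
#'   `rate` (>= 0).
#' @param background_rate CHX-resistant background signal rate.
#' @param od OD660 of every well; default 0.4.
#' @param gain Plate-reader gain multiplier; default 1.
#' @return A data.frame of luciferase records (`strain`, `condition`,
#'   `chx`, `luminescence`, `od660`).
#' @export
gen_luciferase <- function(cfg, true_rates, background_rate = 0,
                           od = 0.4, gain = 1) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("strain", "condition", "rate") %in% names(true_rates)))
  if (any(true_rates$rate < 0)) stop("rates must be >= 0")
  if (background_rate < 0) stop("background rate must be >= 0")
  .with_substream(cfg, "luciferase", {
    rows <- lapply(seq_len(nrow(true_rates)), function(i) {
      r <- true_rates[i, ]
      sig <- (r$rate + background_rate) * od * gain *
        .lognoise(1L, cfg$noise_cv)
      bg <- background_rate * od * gain * .lognoise(1L, cfg$noise_cv)
      data.frame(strain = rep(r$strain, 2L),
                 condition = rep(r$condition, 2L),
                 chx = c(FALSE, TRUE),
                 luminescence = c(sig, bg),
                 od660 = od, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate count data around known truths
#'
#' Poisson draws (region read counts) or negative-binomial draws
#' (spectral counts, with configurable dispersion) around true means;
#' `noiseless = TRUE` returns the rounded means themselves.
#'
#' @param cfg A [generator_config()].
#' @param truths Numeric vector of true mean counts (>= 0).
#' @param type `"poisson"` or `"nb"`.
#' @param dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed); default 5.
#' @param noiseless Return the means without sampling.
#' @return Numeric vector of counts, same length and names as `truths`.
#' @export
gen_counts <- function(cfg, truths, type = c("poisson", "nb"),
                       dispersion = 5, noiseless = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  type <- match.arg(type)
  if (any(truths < 0)) stop("truths must be >= 0")
  if (noiseless) return(truths)
  .with_substream(cfg, "counts", {
    out <- if (type == "poisson") stats::rpois(length(truths), truths)
    else stats::rnbinom(length(truths), size = dispersion, mu = truths)
    stats::setNames(as.numeric(out), names(truths))
  })
}
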