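#' Read a long-format time-course TSV
#'
#' Expects header columns `condition`, `time_min`, `replicate`,
#' `value`; one [time_course()] is returned per condition.
#'
#' @param path TSV file path.
#' @param scale Measurement scale of the values.
#' @return A named list of [time_course()] objects, one per condition.
#' @export
read_timecourse_tsv <- function(path,
                                scale = c("absolute", "fold_over_t0")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_min", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("time-course TSV missing column(s): ",
         paste(miss, collapse = ", "))
  df$time_min <- as.numeric(df$time_min)
  out <- lapply(split(df, df$condition), function(sub) {
    times <- sort(unique(sub$time_min))
    reps <- sort(unique(sub$replicate))
    mat <- matrix(NA_real_, length(times), length(reps))
    mat[cbind(match(sub$time_min, times), match(sub$replicate, reps))] <-
      sub$value
    time_course(sub$condition[1L], times, mat, scale = scale)
  })
  out[order(names(out))]
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  data.frame(
    condition = x$condition,
    time_min = rep(x$times, times = ncol(x$values)),
    replicate = rep(seq_len(ncol(x$values)), each = length(x$times)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' Write a time course as long-format TSV
#'
#' @param tc A [time_course()] (or list of them, concatenated).
#' @param path Output path.
#' @export
write_timecourse_tsv <- function(tc, path) {
  if (inherits(tc, "time_course")) tc <- list(tc)
  df <- do.call(rbind, lapply(tc, as.data.frame))
  df$value <- signif(df$value, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
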