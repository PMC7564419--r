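#' Segmentation parameters
#'
#' The three printed tuning parameters of the genomic-segmentation step plus
#' the diploid window used for three-state calling: a candidate breakpoint is
#' accepted only when its two-sample p-value falls below
#' \code{split_p_threshold}, both flanks hold at least \code{min_markers}
#' markers, and the mean difference is at least \code{signal_to_noise} pooled
#' standard deviations. Copy-number values between \code{diploid_low} and
#' \code{diploid_high} (inclusive) are called normal.
#'
#' @param min_markers Minimum markers per segment (default 10).
#' @param split_p_threshold Breakpoint p-value threshold (default 0.001).
#' @param signal_to_noise Minimum |mean difference| / pooled SD (default 0.3).
#' @param diploid_low,diploid_high Diploid copy-number window
#'   (defaults 1.72 and 2.78, linear scale).
#' @return A list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(min_markers = 10, split_p_threshold = 0.001,
                                signal_to_noise = 0.3,
                                diploid_low = 1.72, diploid_high = 2.78) {
  stopifnot(min_markers >= 2,
            split_p_threshold > 0, split_p_threshold < 1,
            signal_to_noise >= 0,
            diploid_low < 2, diploid_high > 2)
  structure(list(min_markers = min_markers,
                 split_p_threshold = split_p_threshold,
                 signal_to_noise = signal_to_noise,
                 diploid_low = diploid_low, diploid_high = diploid_high),
            class = "segmentation_params")
}

# Welch t statistic and p for splitting x at every admissible breakpoint.
# Returns the best breakpoint (index of last marker on the left) or NULL.
best_split <- function(x, params) {
  n <- length(x)
  mm <- params$min_markers
  if (n < 2 * mm) return(NULL)
  ks <- mm:(n - mm)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  nl <- ks; nr <- n - ks
  ml <- cs[ks] / nl
  mr <- (cs[n] - cs[ks]) / nr
  # unbiased variances of the flanks; the cumulative-sum shortcut suffers
  # catastrophic cancellation on exactly constant data, so snap values
  # indistinguishable from zero (relative to the data scale) to zero
  eps <- 1e-9 * max(abs(x), 1)
  vl <- pmax((cs2[ks] - nl * ml^2) / (nl - 1), 0)
  vr <- pmax((cs2[n] - cs2[ks] - nr * mr^2) / (nr - 1), 0)
  vl[vl < eps^2] <- 0
  vr[vr < eps^2] <- 0
  diff <- ml - mr
  diff[abs(diff) < eps] <- 0
  se2 <- vl / nl + vr / nr
  tstat <- ifelse(se2 > 0, abs(diff) / sqrt(se2),
                  ifelse(abs(diff) > 0, Inf, 0))
  # Welch-Satterthwaite df; irrelevant when t is 0 or Inf
  df <- ifelse(se2 > 0,
               se2^2 / (pmax((vl / nl)^2 / (nl - 1), 0) +
                        pmax((vr / nr)^2 / (nr - 1), 0)),
               1)
  df[!is.finite(df) | df <= 0] <- 1
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(tstat, df, lower.tail = FALSE))
  best <- which.max(tstat)
  if (length(best) == 0) return(NULL)
  # pooled SD of the whole candidate split for the signal-to-noise gate
  pooled <- sqrt(((nl[best] - 1) * vl[best] + (nr[best] - 1) * vr[best]) /
                   max(n - 2, 1))
  snr <- if (pooled > 0) abs(diff[best]) / pooled else
    ifelse(abs(diff[best]) > 0, Inf, 0)
  if (p[best] < params$split_p_threshold && snr >= params$signal_to_noise) {
    ks[best]
  } else {
    NULL
  }
}

recursive_split <- function(x, params) {
  k <- best_split(x, params)
  if (is.null(k)) return(length(x))
  c(recursive_split(x[1:k], params),
    recursive_split(x[(k + 1):length(x)], params))
}

#' Segment a marker-level copy-number track
#'
#' Recursive binary splitting: within each chromosome, every admissible
#' breakpoint is scored by a two-sample Welch t statistic between the flanks;
#' the strongest split is accepted when its p-value, flank sizes, and
#' signal-to-noise ratio all pass [segmentation_params()], and both sides are
#' then segmented recursively. The resulting segments tile the markers
#' exactly. This is a transparent stand-in for proprietary genomic
#' segmentation engines that honours the same three tuning parameters; it is
#' validated on synthetic tracks with known breakpoints.
#'
#' @param track A \code{marker_track} (see [read_marker_track()]).
#' @param params A [segmentation_params()].
#' @return A data.frame of class \code{segment_table}: sample, chromosome,
#'   \code{start_pos}/\code{end_pos} (1-based inclusive marker positions),
#'   \code{n_markers}, \code{mean_copy_number}, ordered within each
#'   sample/chromosome.
#' @export
segment_track <- function(track, params = segmentation_params()) {
  if (nrow(track) == 0) stop("empty marker track")
  track <- as_marker_track(as.data.frame(track))
  out <- list()
  for (sid in unique(track$sample)) {
    sub_s <- track[track$sample == sid, , drop = FALSE]
    for (chrom in unique(sub_s$chromosome)) {
      sub <- sub_s[sub_s$chromosome == chrom, , drop = FALSE]
      lens <- recursive_split(sub$copy_number, params)
      ends <- cumsum(lens)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      out[[paste(sid, chrom)]] <- data.frame(
        sample = sid, chromosome = chrom,
        start_pos = sub$position[starts],
        end_pos = sub$position[ends],
        n_markers = lens,
        mean_copy_number = vapply(seq_along(lens), function(i) {
          mean(sub$copy_number[starts[i]:ends[i]])
        }, numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("segment_table", "data.frame")
  res
}

#' Map segments to per-gene continuous copy number
#'
#' Each gene takes the mean copy number of the segment with the largest
#' base-pair overlap with the gene interval; an exact overlap tie goes to the
#' upstream (lower-coordinate) segment. Genes with no overlapping segment are
#' absent from the matrix and listed in attribute \code{absent_genes}.
#' Gene intervals are 0-based half-open (BED); segment marker positions are
#' 1-based, so a segment spans \code{[start_pos - 1, end_pos)} in BED space.
#'
#' @param segments A \code{segment_table} from [segment_track()].
#' @param annotation A \code{gene_annotation} from [read_annotation_bed()].
#' @return A continuous copy-number matrix (genes x samples) with attribute
#'   \code{absent_genes}.
#' @export
gene_copy_number <- function(segments, annotation) {
  samples <- unique(segments$sample)
  # reject overlapping segments within a sample/chromosome
  for (sid in samples) {
    sub_s <- segments[segments$sample == sid, , drop = FALSE]
    for (chrom in unique(sub_s$chromosome)) {
      sub <- sub_s[sub_s$chromosome == chrom, , drop = FALSE]
      sub <- sub[order(sub$start_pos), , drop = FALSE]
      if (nrow(sub) > 1 &&
          any(sub$start_pos[-1] <= sub$end_pos[-nrow(sub)])) {
        stop("overlapping segments for sample ", sid, " on ", chrom)
      }
    }
  }
  mat <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$symbol, samples))
  for (sid in samples) {
    sub_s <- segments[segments$sample == sid, , drop = FALSE]
    for (i in seq_len(nrow(annotation))) {
      seg <- sub_s[sub_s$chromosome == annotation$chromosome[i], , drop = FALSE]
      if (nrow(seg) == 0) next
      ov <- pmin(seg$end_pos, annotation$end[i]) -
        pmax(seg$start_pos - 1L, annotation$start[i])
      if (all(ov <= 0)) next
      best <- order(-ov, seg$start_pos)[1]  # tie -> upstream segment
      mat[i, sid] <- seg$mean_copy_number[best]
    }
  }
  absent <- rownames(mat)[apply(mat, 1, function(r) all(is.na(r)))]
  mat <- mat[!rownames(mat) %in% absent, , drop = FALSE]
  attr(mat, "kind") <- "copy_number_continuous"
  attr(mat, "absent_genes") <- absent
  mat
}

#' Three-state copy-number calling
#'
#' Linear-scale copy number below \code{diploid_low} is a deletion (-1),
#' above \code{diploid_high} a gain (+1), and the closed interval between
#' them is normal (0); the boundaries 1.72 and 2.78 themselves are normal.
#'
#' @param x Positive numeric vector or matrix of continuous copy number.
#' @param params A [segmentation_params()] supplying the diploid window.
#' @return Integer calls in \{-1, 0, +1\}, same shape as \code{x}. Matrices
#'   gain attribute \code{kind = "copy_number_categorical"}.
#' @export
categorize_copy_number <- function(x, params = segmentation_params()) {
  vals <- x[!is.na(x)]
  if (any(vals <= 0)) stop("copy number must be positive")
  out <- ifelse(x < params$diploid_low, -1L,
                ifelse(x > params$diploid_high, 1L, 0L))
  if (is.matrix(x)) {
    dimnames(out) <- dimnames(x)
    attr(out, "kind") <- "copy_number_categorical"
  }
  out
}
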