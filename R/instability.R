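#' CNA-based genomic instability score
#'
#' A modified large-scale-transition score over one sample's
#' copy-number segments. Segments are first split at arm boundaries
#' (centromere-spanning segments are divided, with a message). A
#' segment contributes only when it is a copy-number alteration
#' (|CN - 2| >= `neutral_band`) and is longer than `min_len` (strict).
#' Arm-level alterations (covering at least `arm_frac` of their arm)
#' contribute |CN - 2|; shorter ones contribute a binary 1.
#'
#' @param segments One sample's segments: `data.frame(chrom, start,
#'   end, copy_number)` (a `sample` column, if present, must be
#'   constant).
#' @param arms Arm definitions: `data.frame(chrom, start, end, name)`.
#' @param min_len Minimum alteration length, bp (default 10 Mb,
#'   strict `>`).
#' @param neutral_cn Neutral copy number (2).
#' @param neutral_band |CN - neutral| below this is treated as no CNA
#'   (default 0.3).
#' @param arm_frac Arm-level call threshold on covered arm fraction
#'   (default 0.9).
#' @return List of class `instability_score`: `score`, `n_arm_terms`,
#'   `n_subarm_terms`, `terms` (per-segment audit table).
#' @export
instability_score <- function(segments, arms, min_len = 10e6,
                              neutral_cn = 2, neutral_band = 0.3,
                              arm_frac = 0.9) {
  if ("sample" %in% names(segments)) {
    stop_if(length(unique(segments$sample)) > 1,
            "instability_score() takes one sample; see instability_scores()")
  }
  arms <- data.table::as.data.table(arms)
  segs <- data.table::as.data.table(segments)
  pieces <- list()
  for (i in seq_len(nrow(segs))) {
    ov <- arms[chrom == segs$chrom[i] & start < segs$end[i] &
                 end > segs$start[i]]
    if (nrow(ov) == 0) next
    if (nrow(ov) > 1) message("segment ", segs$chrom[i], ":",
                              segs$start[i], "-", segs$end[i],
                              " spans an arm boundary; split")
    for (k in seq_len(nrow(ov))) {
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        chrom = segs$chrom[i],
        start = max(segs$start[i], ov$start[k]),
        end = min(segs$end[i], ov$end[k]),
        copy_number = segs$copy_number[i],
        arm = ov$name[k], arm_len = ov$end[k] - ov$start[k])
    }
  }
  if (length(pieces) == 0) {
    return(structure(list(score = 0, n_arm_terms = 0L,
                          n_subarm_terms = 0L, terms = NULL),
                     class = "instability_score"))
  }
  terms <- data.table::rbindlist(pieces)
  terms[, len := end - start]
  terms[, dev := abs(copy_number - neutral_cn)]
  terms[, is_cna := dev >= neutral_band]
  terms[, arm_level := is_cna & len > min_len & len >= arm_frac * arm_len]
  terms[, subarm := is_cna & len > min_len & !arm_level]
  terms[, contribution := ifelse(arm_level, dev, ifelse(subarm, 1, 0))]
  structure(list(score = sum(terms$contribution),
                 n_arm_terms = sum(terms$arm_level),
                 n_subarm_terms = sum(terms$subarm),
                 terms = terms[]),
            class = "instability_score")
}

#' Instability scores for every sample in a SEG table
#'
#' @param seg Multi-sample SEG-like table (`sample`, `chrom`, `start`,
#'   `end`, `copy_number`).
#' @param arms Arm definitions.
#' @param ... Passed to [instability_score()].
#' @return `data.frame(sample, score, n_arm_terms, n_subarm_terms)`.
#' @export
instability_scores <- function(seg, arms, ...) {
  seg <- data.table::as.data.table(seg)
  out <- lapply(split(seg, seg$sample), function(s) {
    sc <- instability_score(s[, -"sample"], arms, ...)
    data.frame(sample = s$sample[1], score = sc$score,
               n_arm_terms = sc$n_arm_terms,
               n_subarm_terms = sc$n_subarm_terms)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between methylation and genomic instability
#'
#' Pearson correlation (two-sided t-based p) between per-sample
#' methylation levels and instability scores, with per-group means.
#'
#' @param meth Named per-sample methylation fractions (e.g. cancer
#'   cell-specific methylation or global methylation).
#' @param inst `data.frame(sample, score)` or named score vector.
#' @param labels Optional named group labels for per-group means.
#' @return List: `pearson_r`, `p`, `n`, `group_means` (data.frame or
#'   NULL).
#' @export
methylation_instability_correlation <- function(meth, inst,
                                                labels = NULL) {
  if (is.data.frame(inst)) inst <- stats::setNames(inst$score, inst$sample)
  shared <- intersect(names(meth), names(inst))
  stop_if(length(shared) < 3, "need >= 3 paired samples")
  m <- meth[shared]; s <- inst[shared]
  stop_if(stats::sd(m) == 0 || stats::sd(s) == 0,
          "zero variance in methylation or instability")
  ct <- stats::cor.test(m, s, method = "pearson")
  gm <- NULL
  if (!is.null(labels)) {
    lb <- labels[shared]
    gm <- data.frame(group = names(tapply(m, lb, mean)),
                     mean_meth = as.numeric(tapply(m, lb, mean)),
                     mean_instability = as.numeric(tapply(s, lb, mean)))
  }
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       n = length(shared), group_means = gm)
}
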