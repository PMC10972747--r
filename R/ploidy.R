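# Genome-ploidy classification and whole-genome-doubling calls from
# allele-specific copy number.

#' Call genome ploidy class and whole-genome doubling for a sample
#'
#' High ploidy is a mean copy number of 2.8 or above (inclusive). Among
#' high-ploidy genomes, doubling is distinguished from successive
#' independent gains via the genome LOH fraction: a doubled genome carries
#' its pre-doubling LOH at even copy numbers and needs relatively little
#' LOH to reach high ploidy, so the default rule calls WGD when
#' `ploidy > wgd_intercept - wgd_slope * loh_fraction` (defaults 2.9 and
#' 2). The LOH fraction is the length-weighted fraction of the autosomal
#' genome with minor allele copy number 0 (sex chromosomes excluded).
#'
#' @param segments segment table of one sample (`chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`).
#' @param ploidy the sample's mean copy number estimate.
#' @param sample sample id for the report.
#' @param ploidy_gate high-ploidy threshold (default 2.8, inclusive).
#' @param wgd_intercept,wgd_slope WGD decision boundary parameters.
#' @return data.frame (class `ploidy_call`) with `sample`, `ploidy`,
#'   `loh_fraction`, `high_ploidy`, `wgd`.
#' @export
call_ploidy <- function(segments, ploidy, sample = "S1", ploidy_gate = 2.8,
                        wgd_intercept = 2.9, wgd_slope = 2) {
  if (is.null(segments) || nrow(segments) == 0) stop("empty segmentation")
  auto <- !segments$chrom %in% c("chrX", "chrY", "X", "Y")
  seg <- segments[auto, , drop = FALSE]
  if (!nrow(seg)) stop("no autosomal segments")
  len <- seg$end - seg$start + 1
  loh <- sum(len[seg$minor_cn == 0]) / sum(len)
  high <- ploidy >= ploidy_gate
  wgd <- high && ploidy > wgd_intercept - wgd_slope * loh
  out <- data.frame(sample = sample, ploidy = ploidy, loh_fraction = loh,
                    high_ploidy = high, wgd = wgd, stringsAsFactors = FALSE)
  class(out) <- c("ploidy_call", class(out))
  out
}

#' Acquired whole-genome doubling between longitudinal samples
#'
#' TRUE iff the later sample is WGD-called and the earlier one is not
#' (loss of a doubling is not modelled).
#'
#' @param pre,post `ploidy_call` rows in temporal order.
#' @return Logical.
#' @export
acquired_wgd <- function(pre, post) {
  isTRUE(post$wgd) && !isTRUE(pre$wgd)
}
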