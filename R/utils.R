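`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default pipeline configuration
#'
#' Returns the full threshold namespace used across the pipeline. Every
#' tunable appears exactly once here; stage functions take their defaults
#' from this list so a single config object drives a whole run.
#'
#' @param ... named overrides of individual thresholds.
#' @return A named list with elements:
#' \describe{
#'   \item{rc}{read-count product threshold of the low-AF power gate (10).}
#'   \item{fr_threshold}{forward-reverse score cutoff (0.2).}
#'   \item{af_gate}{allele-fraction ceiling below which artifact filters
#'     apply (0.2).}
#'   \item{indel_window}{bp distance under which SNMs near indels fail (10).}
#'   \item{tail_fraction}{chromosome-tail fraction flagged (0.015).}
#'   \item{mapq_fraction}{maximum tolerated fraction of low-MAPQ reads (0.10).}
#'   \item{z}{power-trim z-score (1.96, the 2.5\% per-tail normal quantile).}
#'   \item{alpha}{BH level of the private-mutation test (0.05).}
#'   \item{min_cluster}{minimum mutations per CCF cluster (4).}
#'   \item{min_sig_cases}{cohort-prevalence minimum for a signature (5).}
#'   \item{min_subclonal_mut}{strict lower bound for subclonal signature
#'     fits (20).}
#'   \item{min_clonal_mut}{strict lower bound for clonal signature fits (300).}
#'   \item{ploidy_gate}{high-ploidy threshold (2.8, inclusive).}
#'   \item{bin_width, ccf_max}{CCF histogram geometry (0.05, 1.5).}
#'   \item{peak_floor}{peak floor as a fraction of the surface maximum (0.01).}
#'   \item{lambda}{smoothing parameter; NULL selects it by GCV.}
#'   \item{eps}{CCF tolerance for clonality/ancestry/sum-rule checks (0.1).}
#'   \item{normal_cn}{copy number of the matched normal (2).}
#'   \item{detect_k}{minimum variant reads counting as detection in the
#'     binomial private test (1).}
#'   \item{backward_threshold}{tolerated relative cost increase of backward
#'     signature selection (0.02).}
#'   \item{inframe_damaging}{whether in-frame indels of >= 3 codons count as
#'     gene damaging (TRUE).}
#'   \item{wgd_intercept, wgd_slope}{WGD rule: ploidy > intercept -
#'     slope * loh_fraction (2.9, 2).}
#' }
#' @export
default_config <- function(...) {
  cfg <- list(
    rc = 10, fr_threshold = 0.2, af_gate = 0.2, indel_window = 10,
    tail_fraction = 0.015, mapq_fraction = 0.10, z = 1.96, alpha = 0.05,
    min_cluster = 4, min_sig_cases = 5, min_subclonal_mut = 20,
    min_clonal_mut = 300, ploidy_gate = 2.8,
    bin_width = 0.05, ccf_max = 1.5, peak_floor = 0.01, lambda = NULL,
    eps = 0.1, normal_cn = 2, detect_k = 1, backward_threshold = 0.02,
    inframe_damaging = TRUE, wgd_intercept = 2.9, wgd_slope = 2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected so typos in threshold names fail loudly.
#'
#' @param path YAML file with a subset of the keys of [default_config()].
#' @return A complete config list (file values over defaults).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals %||% list())
}

#' hg19 chromosome lengths
#'
#' Lengths of the autosomes and sex chromosomes of the GRCh37/hg19
#' reference assembly, 1-based.
#'
#' @return Named integer vector of chromosome lengths.
#' @export
hg19_chrom_lengths <- function() {
  path <- system.file("extdata", "hg19_chrom_lengths.tsv", package = "clonearch")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

#' hg19 centromere intervals
#'
#' Centromeric intervals of GRCh37/hg19 (UCSC gap track), 1-based inclusive.
#'
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
hg19_centromeres <- function() {
  path <- system.file("extdata", "hg19_centromeres.tsv", package = "clonearch")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
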