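# Cancer-cell-fraction model: expected allele fractions under clonality and
# per-mutation CCFs with multiplicity enumeration on polyploid segments.

#' Expected variant allele fraction under clonality
#'
#' The allele fraction a mutation would show if every tumour cell carried
#' `multiplicity` mutated copies, given tumour purity and local total copy
#' number:
#' \deqn{E[v] = \frac{m\,p}{p\,CN_t + (1-p)\,CN_n}}
#'
#' @param purity tumour purity in (0, 1].
#' @param total_cn local total copy number of the tumour (positive integer).
#' @param multiplicity number of mutated copies per tumour cell
#'   (1..`total_cn`).
#' @param normal_cn copy number of the contaminating normal cells (2 for
#'   autosomes; 1 for male sex chromosomes).
#' @return Expected VAF in (0, 1]. Vectorised over all arguments.
#' @examples
#' expected_vaf(1, 2, 1)      # 0.5
#' expected_vaf(0.5, 2, 1)    # 0.25
#' expected_vaf(0.85, 3, 2)   # ~0.596
#' @export
expected_vaf <- function(purity, total_cn, multiplicity, normal_cn = 2) {
  n <- max(length(purity), length(total_cn), length(multiplicity), length(normal_cn))
  purity <- rep_len(purity, n); total_cn <- rep_len(total_cn, n)
  multiplicity <- rep_len(multiplicity, n); normal_cn <- rep_len(normal_cn, n)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(total_cn < 1)) stop("total_cn must be a positive integer")
  if (any(multiplicity < 1)) stop("multiplicity must be a positive integer")
  if (any(multiplicity > total_cn))
    stop("multiplicity may not exceed total copy number")
  multiplicity * purity / (purity * total_cn + (1 - purity) * normal_cn)
}

#' Feasible mutation multiplicities of a segment
#'
#' On a segment with major allele copy number `major_cn` a mutation can sit
#' on 1..`major_cn` copies. A homozygous deletion (major 0) admits none: the
#' empty result carries an `loh_loss` attribute so callers can flag the
#' mutation rather than drop it silently.
#'
#' @param major_cn major allele copy number (non-negative integer), or a
#'   one-row segment data.frame with a `major_cn` column.
#' @return Integer vector of feasible multiplicities (possibly empty).
#' @export
enumerate_multiplicities <- function(major_cn) {
  if (is.data.frame(major_cn)) major_cn <- major_cn$major_cn
  stopifnot(length(major_cn) == 1L, major_cn >= 0)
  if (major_cn == 0) {
    out <- integer(0)
    attr(out, "loh_loss") <- TRUE
    return(out)
  }
  seq_len(major_cn)
}

# Map each mutation x sample to the index of its covering segment
# (segments: unified, per-sample states). Returns integer index into `segments`
# rows, NA when uncovered.
locate_segment <- function(chrom, pos, sample, segments) {
  idx <- rep(NA_integer_, length(chrom))
  key <- paste(sample, chrom)
  skey <- paste(segments$sample, segments$chrom)
  for (k in unique(key)) {
    mi <- which(key == k)
    si <- which(skey == k)
    if (!length(si)) next
    hit <- findInterval(pos[mi], segments$start[si])
    ok <- hit >= 1 & pos[mi] <= segments$end[si][pmax(hit, 1L)]
    idx[mi[ok]] <- si[hit[ok]]
  }
  idx
}

#' Compute per-mutation, per-sample cancer cell fractions
#'
#' For every mutation/sample pair, the observed VAF is divided by the
#' expected VAF under clonality. The mutation multiplicity defaults to the
#' value in 1..major_cn that brings the CCF closest to 1 (clonality
#' assumption); the chosen multiplicity is recorded. CCFs above 1 are
#' preserved (clustering needs them).
#'
#' Flags: `unevaluable` (depth 0), `no_segment` (no covering segment),
#' `loh_deleted` (major copy number 0), `subclonal_cn` (segment carries a
#' within-sample subclonal copy number state), `ok` otherwise.
#'
#' @param mutations long-format mutation table with columns `mutation_id`,
#'   `chrom`, `pos`, `sample`, `depth`, `alt_reads`.
#' @param segments segment table with columns `sample`, `chrom`, `start`,
#'   `end`, `major_cn`, `minor_cn` and optional `subclonal_cn`.
#' @param purity data.frame with columns `sample`, `purity`.
#' @param normal_cn normal copy number (default 2).
#' @param multiplicity optional integer vector (length `nrow(mutations)`)
#'   forcing the multiplicity instead of the argmin rule.
#' @return data.frame with one row per mutation/sample: `mutation_id`,
#'   `sample`, `depth`, `alt_reads`, `vaf`, `expected_vaf`, `multiplicity`,
#'   `ccf`, `flag`.
#' @export
compute_ccf <- function(mutations, segments, purity, normal_cn = 2,
                        multiplicity = NULL) {
  stopifnot(all(c("mutation_id", "chrom", "pos", "sample", "depth",
                  "alt_reads") %in% names(mutations)))
  p <- stats::setNames(purity$purity, purity$sample)
  if (any(!mutations$sample %in% names(p)))
    stop("purity missing for sample(s): ",
         paste(setdiff(unique(mutations$sample), names(p)), collapse = ", "))
  if (is.null(segments$subclonal_cn)) segments$subclonal_cn <- FALSE

  seg_i <- locate_segment(mutations$chrom, mutations$pos, mutations$sample,
                          segments)
  n <- nrow(mutations)
  out <- data.frame(
    mutation_id = mutations$mutation_id, sample = mutations$sample,
    depth = mutations$depth, alt_reads = mutations$alt_reads,
    vaf = NA_real_, expected_vaf = NA_real_,
    multiplicity = NA_integer_, ccf = NA_real_, flag = "ok",
    stringsAsFactors = FALSE
  )
  out$vaf <- ifelse(mutations$depth > 0,
                    mutations$alt_reads / mutations$depth, NA_real_)
  out$flag[mutations$depth == 0] <- "unevaluable"
  out$flag[is.na(seg_i) & out$flag == "ok"] <- "no_segment"

  ok <- which(out$flag == "ok")
  for (i in ok) {
    si <- seg_i[i]
    major <- segments$major_cn[si]
    total <- major + segments$minor_cn[si]
    if (major == 0) { out$flag[i] <- "loh_deleted"; next }
    pur <- p[[mutations$sample[i]]]
    ms <- if (!is.null(multiplicity) && !is.na(multiplicity[i])) {
      multiplicity[i]
    } else {
      enumerate_multiplicities(major)
    }
    ev <- expected_vaf(pur, total, ms, normal_cn)
    ccfs <- out$vaf[i] / ev
    j <- which.min(abs(ccfs - 1))
    out$multiplicity[i] <- ms[j]
    out$expected_vaf[i] <- ev[j]
    out$ccf[i] <- ccfs[j]
    if (segments$subclonal_cn[si]) out$flag[i] <- "subclonal_cn"
  }
  out
}

# Wide CCF matrix helper: rows = mutation ids, one column set per sample.
ccf_wide <- function(ccf_tab, samples = NULL) {
  samples <- samples %||% unique(ccf_tab$sample)
  ids <- unique(ccf_tab$mutation_id)
  w <- list(mutation_id = ids)
  for (s in samples) {
    sub <- ccf_tab[ccf_tab$sample == s, ]
    m <- match(ids, sub$mutation_id)
    w[[paste0("ccf_", s)]] <- sub$ccf[m]
    w[[paste0("alt_", s)]] <- sub$alt_reads[m]
    w[[paste0("depth_", s)]] <- sub$depth[m]
    w[[paste0("evaf_", s)]] <- sub$expected_vaf[m]
    w[[paste0("flag_", s)]] <- sub$flag[m]
  }
  as.data.frame(w, stringsAsFactors = FALSE)
}
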