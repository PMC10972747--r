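# Mutation-filter battery and shared/private statistical tests applied
# before CCF clustering. Filters only annotate/partition; read counts are
# never modified. Fixed order: artifact filters -> unification/rescue ->
# LOH/positional -> power trim -> private test.

#' Forward-reverse strand balance score
#'
#' 1 at perfect balance of variant reads over the two read orientations, 0
#' when all variant reads share one orientation:
#' `1 - |forward - reverse| / (forward + reverse)`.
#'
#' @param forward_alt,reverse_alt variant read counts per orientation.
#' @return Score in \[0, 1\]; NA when there are no variant reads
#'   (unevaluable).
#' @export
forward_reverse_score <- function(forward_alt, reverse_alt) {
  alt <- forward_alt + reverse_alt
  ifelse(alt >= 1, 1 - abs(forward_alt - reverse_alt) / alt, NA_real_)
}

#' Low-allele-fraction power gate
#'
#' Mutations with VAF below `af_gate` are kept only when coverage is high
#' enough that the call is powered: fail iff
#' `min(depth_tumour, depth_normal) * vaf < rc`. Calls at VAF >= `af_gate`
#' always pass.
#'
#' @param vaf observed variant allele fraction.
#' @param depth_tumour,depth_normal coverage in the tumour and matched
#'   normal at the locus.
#' @param rc read-count product threshold (default 10).
#' @param af_gate AF below which the gate is active (default 0.2).
#' @return Logical: TRUE = pass.
#' @export
low_af_power_gate <- function(vaf, depth_tumour, depth_normal = depth_tumour,
                              rc = 10, af_gate = 0.2) {
  vaf >= af_gate | pmin(depth_tumour, depth_normal) * vaf >= rc
}

#' Filter SNMs adjacent to indel calls
#'
#' Single-nucleotide mutations within `window` bp (strict) of any insertion
#' or deletion call on the same chromosome are failed; indels themselves are
#' unaffected.
#'
#' @param mutations table with `mutation_id`, `chrom`, `pos`, `kind`
#'   (`SNM`/`insertion`/`deletion`); typically the unified per-patient list.
#' @param window bp distance threshold (default 10, strict `<`).
#' @return Logical vector (per row of `mutations`): TRUE = pass.
#' @export
indel_proximity_filter <- function(mutations, window = 10) {
  pass <- rep(TRUE, nrow(mutations))
  is_indel <- mutations$kind %in% c("insertion", "deletion")
  is_snm <- mutations$kind == "SNM"
  for (chr in unique(mutations$chrom[is_indel])) {
    ipos <- unique(mutations$pos[is_indel & mutations$chrom == chr])
    si <- which(is_snm & mutations$chrom == chr)
    if (!length(si)) next
    d <- vapply(mutations$pos[si],
                function(p) min(abs(p - ipos)), numeric(1))
    pass[si[d < window]] <- FALSE
  }
  pass
}

#' Positional and mapping-quality region filters
#'
#' Flags mutations near chromosome tails (outer `tail_fraction` of the
#' chromosome length), inside centromeric intervals (where copy number
#' estimation is error prone), and in regions where more than
#' `mapq_fraction` of uniquely mapped reads had low mapping quality.
#'
#' @param mutations table with `chrom`, `pos` and optional
#'   `fraction_lowmapq`.
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   hg19.
#' @param centromeres data.frame `chrom`,`start`,`end` (1-based inclusive);
#'   defaults to the packaged hg19 table.
#' @param tail_fraction fraction of the chromosome length treated as tail
#'   (default 0.015).
#' @param mapq_fraction maximum tolerated low-MAPQ read fraction (default
#'   0.10).
#' @return Character vector per row: `"ok"`, `"tail"`, `"centromere"` or
#'   `"lowmapq"` (first rule that fires).
#' @export
positional_region_filters <- function(mutations,
                                      chrom_lengths = hg19_chrom_lengths(),
                                      centromeres = hg19_centromeres(),
                                      tail_fraction = 0.015,
                                      mapq_fraction = 0.10) {
  unknown <- setdiff(unique(mutations$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  L <- chrom_lengths[mutations$chrom]
  flag <- rep("ok", nrow(mutations))
  flag[mutations$pos <= tail_fraction * L |
         mutations$pos >= (1 - tail_fraction) * L] <- "tail"
  if (!is.null(centromeres) && nrow(centromeres)) {
    for (i in seq_len(nrow(centromeres))) {
      hit <- mutations$chrom == centromeres$chrom[i] &
        mutations$pos >= centromeres$start[i] &
        mutations$pos <= centromeres$end[i] & flag == "ok"
      flag[hit] <- "centromere"
    }
  }
  fl <- mutations$fraction_lowmapq %||% rep(0, nrow(mutations))
  flag[flag == "ok" & fl > mapq_fraction] <- "lowmapq"
  flag
}

#' Unify per-sample copy number segmentations
#'
#' Output breakpoints are the per-chromosome union of all samples'
#' breakpoints; every unified segment carries each sample's (major, minor)
#' state, so each mutation maps to exactly one unified segment per sample.
#'
#' @param segments per-sample segment table (`sample`, `chrom`, `start`,
#'   `end`, `major_cn`, `minor_cn`, optional `subclonal_cn`).
#' @return Segment table in the same layout on the unified breakpoints.
#' @export
unify_segmentation <- function(segments) {
  if (is.null(segments$subclonal_cn)) segments$subclonal_cn <- FALSE
  samples <- unique(segments$sample)
  out <- list()
  for (chr in unique(segments$chrom)) {
    seg_c <- segments[segments$chrom == chr, ]
    for (s in samples) {
      ss <- seg_c[seg_c$sample == s, ]
      if (nrow(ss) > 1) {
        o <- order(ss$start)
        if (any(ss$start[o][-1] <= ss$end[o][-nrow(ss)]))
          stop("overlapping segments within sample ", s, " on ", chr)
      }
    }
    cuts <- sort(unique(c(seg_c$start, seg_c$end + 1L)))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1L] - 1L
    for (s in samples) {
      ss <- seg_c[seg_c$sample == s, ]
      hit <- findInterval(starts, ss$start)
      cov <- hit >= 1 & ends <= ss$end[pmax(hit, 1L)]
      keep <- which(cov)
      if (!length(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = chr, start = starts[keep], end = ends[keep],
        major_cn = ss$major_cn[hit[keep]], minor_cn = ss$minor_cn[hit[keep]],
        subclonal_cn = ss$subclonal_cn[hit[keep]],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$sample, res$chrom, res$start), , drop = FALSE]
}

#' Rescue low-AF calls shared with a stringent call elsewhere
#'
#' Multiregion rescue: a mutation passing all stringent filters in at least
#' one sample is re-probed in every other sample with relaxed criteria
#' (>= `min_alt` variant reads), and marked present there at its observed
#' VAF. Never removes an existing call; idempotent.
#'
#' @param call_status logical matrix mutations x samples of stringent call
#'   status.
#' @param alt_reads integer matrix (same shape) of variant read counts.
#' @param min_alt relaxed detection threshold (default 1 read).
#' @return Logical matrix of augmented call status.
#' @export
rescue_shared_lowaf <- function(call_status, alt_reads, min_alt = 1) {
  stopifnot(identical(dim(call_status), dim(alt_reads)))
  anywhere <- rowSums(call_status) >= 1
  call_status | (anywhere & alt_reads >= min_alt)
}

#' LOH conflict filter
#'
#' A mutation on a segment that undergoes LOH (minor copy number 0) in at
#' least one but not all samples cannot be phylogenetically placed when it
#' is private (or near-private, CCF < `af_gate`) to a sample lacking the
#' LOH event: absence in the LOH sample may reflect the copy number loss
#' rather than subclonal acquisition. Such mutations are excluded as
#' ambiguous. Mutations on segments where a within-sample subclonal copy
#' number state involves LOH are excluded likewise.
#'
#' @param ccf_tab long CCF table (from [compute_ccf()]).
#' @param segments unified segmentation (all samples share breakpoints).
#' @param mutations mutation table giving `mutation_id`, `chrom`, `pos`.
#' @param near_private_ccf CCF below which a call counts as near-private in
#'   an LOH sample (default 0.2).
#' @return Character vector over unique mutation ids: `"retained"` or
#'   `"excluded_ambiguous"`.
#' @export
loh_conflict_filter <- function(ccf_tab, segments, mutations,
                                near_private_ccf = 0.2) {
  samples <- unique(segments$sample)
  mu <- mutations[!duplicated(mutations$mutation_id),
                  c("mutation_id", "chrom", "pos")]
  verdict <- stats::setNames(rep("retained", nrow(mu)), mu$mutation_id)
  for (i in seq_len(nrow(mu))) {
    loh <- logical(length(samples)); subcl_loh <- FALSE
    for (j in seq_along(samples)) {
      si <- locate_segment(mu$chrom[i], mu$pos[i], samples[j], segments)
      if (is.na(si)) next
      loh[j] <- segments$minor_cn[si] == 0
      if (isTRUE(segments$subclonal_cn[si]) && segments$minor_cn[si] == 0)
        subcl_loh <- TRUE
    }
    if (subcl_loh) { verdict[i] <- "excluded_ambiguous"; next }
    if (!any(loh) || all(loh)) next
    cc <- ccf_tab[ccf_tab$mutation_id == mu$mutation_id[i], ]
    ccf_s <- stats::setNames(cc$ccf[match(samples, cc$sample)], samples)
    low_in_loh <- all(is.na(ccf_s[loh]) | ccf_s[loh] < near_private_ccf)
    called_nonloh <- any(!is.na(ccf_s[!loh]) &
                           ccf_s[!loh] >= near_private_ccf)
    if (low_in_loh && called_nonloh) verdict[i] <- "excluded_ambiguous"
  }
  verdict
}

#' Detection-power trim of CCF records
#'
#' Per sample, the contribution of one mutated read to a mutation's CCF is
#' `score = (1/depth) / expected_vaf`. The per-sample score distribution is
#' modelled as log-normal and its two `pnorm(z)` tails are cut off,
#' removing over- and underpowered mutations; with `z = 1.96` that trims
#' the 2.5\% per-tail extremes. A mutation is dropped when trimmed in
#' either sample of the pair. Degenerate (constant-score) samples trim
#' nothing. Fewer than `min_n` scored mutations per sample skips the trim
#' with a warning.
#'
#' @param ccf_tab long CCF table of one sample pair.
#' @param z trim z-score (default 1.96).
#' @param min_n minimum mutations per sample (default 10).
#' @return Character vector over unique mutation ids: `"retained"` or
#'   `"power_trimmed"`.
#' @export
power_trim <- function(ccf_tab, z = 1.96, min_n = 10) {
  ids <- unique(ccf_tab$mutation_id)
  verdict <- stats::setNames(rep("retained", length(ids)), ids)
  for (s in unique(ccf_tab$sample)) {
    sub <- ccf_tab[ccf_tab$sample == s & !is.na(ccf_tab$expected_vaf) &
                     ccf_tab$depth > 0, ]
    if (nrow(sub) < min_n) {
      warning("power_trim: fewer than ", min_n, " scored mutations in ",
              s, "; skipped")
      next
    }
    score <- (1 / sub$depth) / sub$expected_vaf
    if (any(score <= 0)) stop("non-positive power score")
    ls <- log(score)
    sdv <- stats::sd(ls)
    if (!is.finite(sdv) || sdv == 0) next
    out <- abs(ls - mean(ls)) > z * sdv
    verdict[sub$mutation_id[out]] <- "power_trimmed"
  }
  verdict
}

#' Binomial test for truly private mutations
#'
#' For a mutation called in exactly one sample of a pair: under the null
#' that it is shared with allelic fraction at least as high as observed in
#' the carrier, the probability of seeing fewer than `detect_k` variant
#' reads among `D` reads in the other sample is
#' `p = P(Binom(D, v) < detect_k)` (with `detect_k = 1`, `(1 - v)^D`).
#' Benjamini-Hochberg control at `alpha` across all private candidates of
#' the pair; rejected candidates are truly private, the rest are excluded
#' as ambiguous (underpowered). Zero coverage in the other sample is
#' excluded with provenance.
#'
#' @param vaf_carrier observed VAF in the carrier sample.
#' @param depth_other coverage at the locus in the other sample.
#' @param alpha BH level (default 0.05).
#' @param detect_k minimum variant reads counting as detection (default 1).
#' @return data.frame with `p`, `q` and `status` in
#'   `truly_private` / `excluded_ambiguous` / `excluded_zero_coverage`.
#' @export
private_mutation_test <- function(vaf_carrier, depth_other, alpha = 0.05,
                                  detect_k = 1) {
  n <- length(vaf_carrier)
  stopifnot(length(depth_other) == n)
  p <- stats::pbinom(detect_k - 1, depth_other, vaf_carrier)
  p[depth_other == 0] <- NA_real_
  q <- rep(NA_real_, n)
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  status <- rep("excluded_ambiguous", n)
  status[!ok] <- "excluded_zero_coverage"
  status[ok & q <= alpha] <- "truly_private"
  data.frame(p = p, q = q, status = status, stringsAsFactors = FALSE)
}

#' Run the full filter battery on a sample pair
#'
#' Applies, in fixed order: per-sample artifact filters (strand balance +
#' low-AF power gate below the AF gate, indel proximity, positional/MAPQ
#' regions), cross-sample rescue of the unified mutation list, CCF
#' computation on the unified segmentation, LOH-conflict and subclonal-CN
#' exclusion, detection-power trim, and the binomial private/shared test
#' with BH control. Filters annotate; read counts are untouched.
#'
#' @param mutations long mutation table covering the two samples (columns
#'   `mutation_id`, `chrom`, `pos`, `ref`, `alt`, `kind`, `sample`, `depth`,
#'   `alt_reads`, `forward_alt`, `reverse_alt`, optional `normal_depth`,
#'   `fraction_lowmapq`).
#' @param segments per-sample segment table (unified internally).
#' @param purity data.frame `sample`, `purity`.
#' @param samples character(2): the pair, in order.
#' @param config threshold namespace from [default_config()].
#' @param chrom_lengths,centromeres positional-filter references (hg19
#'   defaults).
#' @return list with `ccf` (wide CCF table of retained mutations), `status`
#'   (named vector `shared` / `private_<sample>` per retained id),
#'   `verdicts` (per-mutation filter provenance), `segments` (unified).
#' @export
apply_filters <- function(mutations, segments, purity, samples,
                          config = default_config(),
                          chrom_lengths = hg19_chrom_lengths(),
                          centromeres = hg19_centromeres()) {
  stopifnot(length(samples) == 2L)
  mut <- mutations[mutations$sample %in% samples, , drop = FALSE]
  useg <- unify_segmentation(segments[segments$sample %in% samples, ,
                                      drop = FALSE])

  ids <- unique(mut$mutation_id)
  meta <- mut[!duplicated(mut$mutation_id), ]
  meta <- meta[match(ids, meta$mutation_id), ]

  # --- per-sample stringent artifact filters ------------------------------
  vaf <- ifelse(mut$depth > 0, mut$alt_reads / mut$depth, 0)
  frs <- forward_reverse_score(mut$forward_alt %||% mut$alt_reads,
                               mut$reverse_alt %||% rep(0, nrow(mut)))
  low <- vaf < config$af_gate
  fr_fail <- low & !is.na(frs) & frs < config$fr_threshold
  nd <- mut$normal_depth %||% mut$depth
  gate_fail <- !low_af_power_gate(vaf, mut$depth, nd,
                                  rc = config$rc, af_gate = config$af_gate)
  called <- mut$alt_reads >= 1
  stringent <- called & !fr_fail & !gate_fail

  # unified-list filters (apply to the mutation across samples)
  indel_pass <- indel_proximity_filter(meta, window = config$indel_window)
  pos_flag <- positional_region_filters(meta, chrom_lengths, centromeres,
                                        tail_fraction = config$tail_fraction,
                                        mapq_fraction = config$mapq_fraction)
  site_pass <- stats::setNames(indel_pass & pos_flag == "ok", ids)

  to_mat <- function(x, default = 0) {
    m <- matrix(default, length(ids), 2, dimnames = list(ids, samples))
    m[cbind(match(mut$mutation_id, ids), match(mut$sample, samples))] <- x
    m
  }
  call_m <- to_mat(stringent & site_pass[mut$mutation_id], FALSE)
  alt_m <- to_mat(mut$alt_reads)
  rescued <- rescue_shared_lowaf(call_m, alt_m, min_alt = 1)

  verdict <- stats::setNames(rep("pass", length(ids)), ids)
  verdict[!site_pass & !indel_pass] <- "fail_indel_proximity"
  verdict[pos_flag != "ok"] <- paste0("fail_", pos_flag[pos_flag != "ok"])
  none <- rowSums(rescued) == 0
  both_artifact <- verdict == "pass" & none
  verdict[both_artifact] <- "fail_artifact"
  keep <- names(verdict)[verdict == "pass"]

  # --- CCFs on the unified segmentation -----------------------------------
  mut_k <- mut[mut$mutation_id %in% keep, , drop = FALSE]
  ccf_tab <- compute_ccf(mut_k, useg, purity, normal_cn = config$normal_cn)
  bad <- unique(ccf_tab$mutation_id[ccf_tab$flag %in%
                                      c("no_segment", "loh_deleted")])
  verdict[bad] <- "fail_no_cn_state"
  subcl <- unique(ccf_tab$mutation_id[ccf_tab$flag == "subclonal_cn"])
  verdict[setdiff(subcl, bad)] <- "excluded_subclonal_cn"
  ccf_tab <- ccf_tab[!ccf_tab$mutation_id %in% c(bad, subcl), , drop = FALSE]

  # --- LOH conflict --------------------------------------------------------
  lohv <- loh_conflict_filter(ccf_tab, useg, meta,
                              near_private_ccf = config$af_gate)
  amb <- names(lohv)[lohv == "excluded_ambiguous"]
  amb <- intersect(amb, unique(ccf_tab$mutation_id))
  verdict[amb] <- "excluded_loh_conflict"
  ccf_tab <- ccf_tab[!ccf_tab$mutation_id %in% amb, , drop = FALSE]

  # --- power trim ----------------------------------------------------------
  ptv <- power_trim(ccf_tab, z = config$z)
  trimmed <- names(ptv)[ptv == "power_trimmed"]
  verdict[trimmed] <- "power_trimmed"
  ccf_tab <- ccf_tab[!ccf_tab$mutation_id %in% trimmed, , drop = FALSE]

  # --- shared/private assignment + binomial test --------------------------
  w <- ccf_wide(ccf_tab, samples)
  pres <- cbind(rescued[w$mutation_id, 1] & !is.na(w[[paste0("ccf_", samples[1])]]),
                rescued[w$mutation_id, 2] & !is.na(w[[paste0("ccf_", samples[2])]]))
  status <- stats::setNames(rep(NA_character_, nrow(w)), w$mutation_id)
  status[pres[, 1] & pres[, 2]] <- "shared"
  cand1 <- which(pres[, 1] & !pres[, 2])
  cand2 <- which(pres[, 2] & !pres[, 1])
  cand <- c(cand1, cand2)
  if (length(cand)) {
    carrier <- c(rep(samples[1], length(cand1)), rep(samples[2], length(cand2)))
    other <- c(rep(samples[2], length(cand1)), rep(samples[1], length(cand2)))
    v <- mapply(function(i, s) {
      a <- w[[paste0("alt_", s)]][i]; d <- w[[paste0("depth_", s)]][i]
      if (is.na(d) || d == 0) 0 else a / d
    }, cand, carrier)
    D <- mapply(function(i, s) {
      d <- w[[paste0("depth_", s)]][i]
      if (is.na(d)) 0 else d
    }, cand, other)
    pt <- private_mutation_test(v, D, alpha = config$alpha,
                                detect_k = config$detect_k)
    priv_ok <- pt$status == "truly_private"
    status[cand[priv_ok]] <- paste0("private_", carrier[priv_ok])
    verdict[w$mutation_id[cand[!priv_ok]]] <-
      paste0("excluded_", sub("^excluded_", "", pt$status[!priv_ok]))
  }
  drop_na <- names(status)[is.na(status)]
  verdict[drop_na[verdict[drop_na] == "pass"]] <- "excluded_uncalled"
  retained <- names(status)[!is.na(status)]
  w <- w[w$mutation_id %in% retained, , drop = FALSE]
  # absent side of a private mutation contributes CCF 0 to clustering
  for (k in 1:2) {
    col <- paste0("ccf_", samples[k])
    w[[col]][is.na(w[[col]])] <- 0
    pr <- status[w$mutation_id] == paste0("private_", samples[3 - k])
    w[[col]][pr] <- 0
  }

  list(ccf = w, status = status[retained],
       verdicts = data.frame(mutation_id = ids, verdict = verdict[ids],
                             stringsAsFactors = FALSE),
       segments = useg)
}
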