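# SBS mutational-signature refitting: 96-channel catalogues, non-negative
# least-squares exposures, backward selection, cohort prevalence subset,
# eligibility rules, and radiation-associated indel ratios.

#' The 96 SBS trinucleotide channels
#'
#' Standard pyrimidine-strand convention and ordering: substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G; within each, the 16 flanking contexts in
#' alphabetical order. Channel names follow the `A[C>A]A` convention.
#'
#' @return Character vector of 96 channel names.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(COMPLEMENT[ch])), collapse = ""), character(1))
}

#' Build a 96-channel mutation catalogue
#'
#' Counts single-nucleotide mutations by substitution class and
#' trinucleotide context under the pyrimidine-strand convention: mutations
#' with a purine reference are reverse-complemented. Non-SNM calls are
#' skipped and counted in the `skipped` attribute.
#'
#' @param mutations table with columns `ref`, `alt`, `kind` and `context`
#'   (the reference trinucleotide around the site).
#' @param subset optional logical/integer index restricting the rows used.
#' @return Named integer vector over [sbs_channels()] summing to the number
#'   of usable SNMs; attribute `skipped` counts rejected rows.
#' @export
build_catalogue <- function(mutations, subset = NULL) {
  if (!is.null(subset)) mutations <- mutations[subset, , drop = FALSE]
  ch <- sbs_channels()
  counts <- stats::setNames(integer(96), ch)
  skipped <- 0L
  snm <- mutations$kind == "SNM" & nchar(mutations$ref) == 1 &
    nchar(mutations$alt) == 1
  skipped <- skipped + sum(!snm)
  mutations <- mutations[snm, , drop = FALSE]
  for (i in seq_len(nrow(mutations))) {
    ref <- mutations$ref[i]; alt <- mutations$alt[i]
    ctx <- toupper(mutations$context[i])
    if (is.na(ctx) || nchar(ctx) != 3 || substr(ctx, 2, 2) != ref) {
      skipped <- skipped + 1L; next
    }
    if (ref %in% c("A", "G")) {
      ctx <- revcomp(ctx); ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
    }
    key <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                  substr(ctx, 3, 3))
    if (!key %in% ch) { skipped <- skipped + 1L; next }
    counts[key] <- counts[key] + 1L
  }
  attr(counts, "skipped") <- skipped
  counts
}

#' Read a COSMIC-format signature matrix
#'
#' Tab-separated, first column the 96 channel names (`Type` header or
#' unnamed), remaining columns one signature each; columns are normalised
#' to sum to 1 and re-ordered to the canonical channel order.
#'
#' @param path TSV path.
#' @return Numeric matrix 96 x signatures.
#' @export
read_signature_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ch <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ch
  miss <- setdiff(sbs_channels(), ch)
  if (length(miss)) stop("signature file missing channels: ", miss[1], " ...")
  m <- m[sbs_channels(), , drop = FALSE]
  sweep(m, 2, colSums(m), `/`)
}

#' Synthetic SBS signature catalogue
#'
#' A deterministic, synthetic stand-in for a reduced COSMIC-style SBS
#' catalogue, for examples and tests: 15 signature profiles carrying
#' COSMIC-style names (the prevalent set SBS1-SBS92 plus the platinum
#' signatures SBS31/SBS35) whose shapes are loosely modelled on the
#' characteristic channels of their namesakes but are NOT the COSMIC
#' profiles. Real analyses should load a genuine catalogue with
#' [read_signature_catalog()].
#'
#' @return Numeric matrix 96 x 15, columns summing to 1.
#' @export
synthetic_sbs_catalogue <- function() {
  ch <- sbs_channels()
  base <- function() stats::setNames(rep(1, 96), ch)
  peak <- function(v, pattern, w) {
    hit <- grepl(pattern, names(v))
    v[hit] <- v[hit] + w
    v
  }
  defs <- list(
    SBS1  = peak(base(), "\\[C>T\\]G", 60),
    SBS2  = peak(base(), "^T\\[C>[AT]\\]", 50),
    SBS3  = base() + stats::setNames(rep(c(0.6, 0.2), 48), ch),
    SBS4  = peak(base(), "\\[C>A\\]", 12),
    SBS5  = peak(base(), "\\[T>C\\]", 6),
    SBS13 = peak(base(), "^T\\[C>G\\]", 55),
    SBS15 = peak(peak(base(), "^[AG]\\[C>T\\]", 20), "T$", 4),
    SBS16 = peak(base(), "^A\\[T>C\\]", 45),
    SBS24 = peak(base(), "^[CG]\\[C>A\\]G", 50),
    SBS29 = peak(base(), "\\[C>A\\]A", 28),
    SBS39 = peak(base(), "\\[C>G\\]", 14),
    SBS40 = peak(base(), "\\[T>A\\]", 8),
    SBS92 = peak(base(), "^[CT]\\[T>G\\]", 35),
    SBS31 = peak(base(), "^C\\[C>T\\]", 45),
    SBS35 = peak(peak(base(), "\\[C>A\\]C", 25), "^G\\[C>T\\]", 20)
  )
  m <- do.call(cbind, defs)
  rownames(m) <- ch
  sweep(m, 2, colSums(m), `/`)
}

fit_cost <- function(catalogue, sigs, exposures) {
  sqrt(sum((catalogue - as.vector(sigs %*% exposures))^2))
}

#' Fit signature exposures by non-negative least squares
#'
#' Minimises the L2 reconstruction error of the 96-channel catalogue over
#' non-negative exposures (count space: exposures scale to mutation
#' counts).
#'
#' @param catalogue 96-channel count vector.
#' @param sigs signature matrix 96 x k (columns sum to 1).
#' @return list of class `exposure_fit`: `exposures` (named, >= 0), `cost`
#'   (L2 residual norm), `fitted` (reconstructed catalogue).
#' @export
fit_exposures <- function(catalogue, sigs) {
  if (is.null(dim(sigs)) || ncol(sigs) == 0) stop("empty signature subset")
  if (sum(catalogue) <= 0) stop("catalogue total must be positive")
  sol <- pracma::lsqnonneg(as.matrix(sigs), as.numeric(catalogue))
  expo <- stats::setNames(sol$x, colnames(sigs))
  structure(list(
    exposures = expo,
    cost = fit_cost(as.numeric(catalogue), as.matrix(sigs), sol$x),
    fitted = as.vector(as.matrix(sigs) %*% sol$x)
  ), class = "exposure_fit")
}

#' Backward selection of signatures
#'
#' Starting from the full non-negative fit, iteratively removes the
#' signature whose removal increases the cost least, as long as the cost
#' stays within `threshold` (relative) of the full-model cost — i.e. only
#' signatures that markedly reduce the model cost are kept. With
#' `threshold = 0` only exactly redundant signatures are removed.
#'
#' @param catalogue 96-channel count vector.
#' @param sigs signature matrix 96 x k.
#' @param threshold tolerated relative cost increase over the full fit
#'   (default 0.02).
#' @return list: `selected` (signature names), `fit` (`exposure_fit` on the
#'   selected subset), `full_cost`.
#' @export
backward_select <- function(catalogue, sigs, threshold = 0.02) {
  full <- fit_exposures(catalogue, sigs)
  budget <- full$cost * (1 + threshold) + 1e-9
  keep <- colnames(sigs)
  fit <- full
  repeat {
    if (length(keep) == 1) break
    costs <- vapply(keep, function(drop) {
      fit_exposures(catalogue, sigs[, setdiff(keep, drop), drop = FALSE])$cost
    }, numeric(1))
    cand <- names(which.min(costs))
    if (costs[[cand]] > budget) break
    keep <- setdiff(keep, cand)
    fit <- fit_exposures(catalogue, sigs[, keep, drop = FALSE])
  }
  list(selected = keep, fit = fit, full_cost = full$cost)
}

#' Cohort-prevalent signature subset
#'
#' Signatures with non-zero exposure in at least `min_cases` cases. For
#' post-treatment subclonal fits the platinum signatures SBS31 and SBS35
#' are force-included regardless of prevalence.
#'
#' @param exposure_matrix cases x signatures matrix of fitted exposures.
#' @param min_cases prevalence threshold (default 5).
#' @param post_treatment logical; force-include platinum signatures
#'   (default FALSE).
#' @param platinum names of the platinum signatures.
#' @return Character vector of signature names.
#' @export
cohort_subset <- function(exposure_matrix, min_cases = 5,
                          post_treatment = FALSE,
                          platinum = c("SBS31", "SBS35")) {
  if (is.null(dim(exposure_matrix)) || nrow(exposure_matrix) == 0)
    stop("empty cohort")
  prev <- colSums(exposure_matrix > 0)
  sel <- names(prev)[prev >= min_cases]
  if (post_treatment)
    sel <- union(sel, intersect(platinum, colnames(exposure_matrix)))
  sel
}

#' Eligibility of a mutation subset for signature fitting
#'
#' Clonal fits require more than `min_clonal` mutations; subclonal fits
#' require more than `min_subclonal` (strict inequalities). Skipped
#' subsets are reported, not dropped silently.
#'
#' @param n_mutations subset size.
#' @param kind `"clonal"` or `"subclonal"`.
#' @param min_clonal,min_subclonal strict lower bounds (300, 20).
#' @return list `fit` (logical), `reason`.
#' @export
eligibility <- function(n_mutations, kind = c("clonal", "subclonal"),
                        min_clonal = 300, min_subclonal = 20) {
  kind <- match.arg(kind)
  lim <- if (kind == "clonal") min_clonal else min_subclonal
  if (n_mutations > lim) list(fit = TRUE, reason = "eligible")
  else list(fit = FALSE,
            reason = sprintf("%s subset of %d mutations (needs > %d)",
                             kind, n_mutations, lim))
}

#' Radiation-associated indel ratios
#'
#' The indel-to-substitution burden ratio and the deletion-to-insertion
#' ratio of a call set. Undefined denominators are reported as missing
#' (NA), never as 0.
#'
#' @param kind character vector of call types
#'   (`SNM`/`insertion`/`deletion`).
#' @return list `indel_substitution`, `deletion_insertion`.
#' @export
radiation_ratios <- function(kind) {
  n_snm <- sum(kind == "SNM")
  n_ins <- sum(kind == "insertion")
  n_del <- sum(kind == "deletion")
  list(
    indel_substitution = if (n_snm > 0) (n_ins + n_del) / n_snm else NA_real_,
    deletion_insertion = if (n_ins > 0) n_del / n_ins else NA_real_
  )
}

#' Sample a mutation catalogue from known exposures
#'
#' Draws `n` mutations from the channel distribution implied by mixing the
#' given signatures, for recovery experiments.
#'
#' @param sigs signature matrix 96 x k.
#' @param exposures non-negative mixing weights (length k).
#' @param n number of mutations.
#' @return Named 96-channel count vector.
#' @export
simulate_catalogue <- function(sigs, exposures, n) {
  p <- as.vector(as.matrix(sigs) %*% (exposures / sum(exposures)))
  counts <- stats::rmultinom(1, n, p)[, 1]
  stats::setNames(counts, rownames(sigs))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
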