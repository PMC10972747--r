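# Two-dimensional CCF clustering of a sample pair: histogram, smoothed
# surface, peak detection, constrained nearest-centre assignment.

#' Bin paired CCFs into a two-dimensional histogram
#'
#' Grid over `[0, ccf_max]^2` with the given bin width. CCFs above
#' `ccf_max` are clamped into the last bin so noisy values slightly above 1
#' remain visible. Private mutations (CCF 0 in one sample) accumulate along
#' the axes. Counts sum to the number of mutations.
#'
#' @param ccf1,ccf2 CCFs of each mutation in the two samples (0 allowed).
#' @param bin_width bin width (default 0.05).
#' @param ccf_max upper edge of the grid (default 1.5).
#' @return Object of class `ccf_histogram`: list with `counts` (matrix),
#'   `mids` (bin midpoints), `bin_width`, `bin1`, `bin2` (per-mutation bin
#'   indices).
#' @export
build_histogram <- function(ccf1, ccf2, bin_width = 0.05, ccf_max = 1.5) {
  stopifnot(length(ccf1) == length(ccf2))
  if (!length(ccf1)) stop("empty CCF input")
  if (any(!is.finite(ccf1)) || any(!is.finite(ccf2)))
    stop("non-finite CCF values")
  nb <- ceiling(ccf_max / bin_width)
  bin_of <- function(x) pmin(pmax(floor(x / bin_width) + 1L, 1L), nb)
  b1 <- bin_of(ccf1); b2 <- bin_of(ccf2)
  counts <- matrix(0L, nb, nb)
  for (i in seq_along(b1)) counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1L
  mids <- (seq_len(nb) - 0.5) * bin_width
  structure(list(counts = counts, mids = mids, bin_width = bin_width,
                 bin1 = b1, bin2 = b2), class = "ccf_histogram")
}

#' Fit a smooth surface to the CCF histogram
#'
#' Tensor-product smoothing-spline (B-spline bases) fit to the bin counts
#' under a Poisson count model, with a single smoothing parameter shared
#' by both axes. With `lambda = NULL` the common parameter is chosen by
#' the generalised cross-validation (UBRE) score over a log-spaced grid.
#' The count model is what deconvolutes bin-level sampling jitter: surface
#' maxima are insensitive to Poisson noise on individual bins. Fitted
#' values are clipped at 0.
#'
#' @param hist `ccf_histogram` from [build_histogram()].
#' @param lambda optional fixed smoothing parameter.
#' @param k basis dimension per axis (default 10).
#' @return Object of class `ccf_surface`: list with `z` (fitted matrix),
#'   `mids`, `lambda`.
#' @export
fit_surface <- function(hist, lambda = NULL, k = 10) {
  stopifnot(inherits(hist, "ccf_histogram"))
  nb <- length(hist$mids)
  if (nb < 4) stop("grid must be at least 4x4")
  dat <- data.frame(
    n = as.vector(hist$counts),
    x = rep(hist$mids, times = nb),
    y = rep(hist$mids, each = nb)
  )
  if (any(!is.finite(dat$n))) stop("non-finite grid values")
  fit_at <- function(sp) mgcv::gam(n ~ te(x, y, bs = "ps", k = c(k, k)),
                                   data = dat, family = stats::poisson(),
                                   sp = c(sp, sp))
  if (is.null(lambda)) {
    grid <- 10^seq(-3, 3, length.out = 9)
    fits <- lapply(grid, fit_at)
    scores <- vapply(fits, function(f) f$gcv.ubre, numeric(1))
    best <- which.min(scores)
    lambda <- grid[best]
    g <- fits[[best]]
  } else {
    g <- fit_at(lambda)
  }
  z <- matrix(pmax(stats::fitted(g), 0), nb, nb)
  structure(list(z = z, mids = hist$mids, lambda = lambda),
            class = "ccf_surface")
}

#' Identify surface peaks as cluster centres
#'
#' Strict local maxima of the fitted surface under the 8-neighbour rule,
#' above a floor of `floor_frac` of the surface maximum (suppressing
#' ripple). Centres take the bin-midpoint coordinates; a coordinate in the
#' first bin (which contains CCF 0) is reported as 0, marking a private
#' (axis) centre. If no peak qualifies, the single grid argmax is returned
#' as fallback.
#'
#' @param surface `ccf_surface` from [fit_surface()].
#' @param floor_frac peak floor as a fraction of the maximum (default 0.01).
#' @return data.frame with columns `x`, `y` (centre CCFs) and `kind`
#'   (`shared`, `private_s1`, `private_s2`).
#' @export
find_peaks <- function(surface, floor_frac = 0.01) {
  z <- surface$z
  nb <- nrow(z)
  floorv <- floor_frac * max(z)
  eqtol <- 1e-6 * max(z)  # numerically flat neighbourhoods are not peaks
  peaks <- list()
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    v <- z[i, j]
    if (v <= floorv || v <= 0) next
    ni <- max(1, i - 1):min(nb, i + 1)
    nj <- max(1, j - 1):min(nb, j + 1)
    nbh <- z[ni, nj, drop = FALSE]
    if (sum(nbh >= v - eqtol) == 1 && all(nbh <= v))
      peaks[[length(peaks) + 1L]] <- c(i, j)
  }
  if (!length(peaks)) {
    am <- which(z == max(z), arr.ind = TRUE)[1, ]
    peaks <- list(c(am[[1]], am[[2]]))
  }
  pk <- do.call(rbind, peaks)
  x <- ifelse(pk[, 1] == 1L, 0, surface$mids[pk[, 1]])
  y <- ifelse(pk[, 2] == 1L, 0, surface$mids[pk[, 2]])
  kind <- ifelse(x > 0 & y > 0, "shared",
                 ifelse(y == 0 & x > 0, "private_s1",
                        ifelse(x == 0 & y > 0, "private_s2", "origin")))
  out <- data.frame(x = x, y = y, kind = kind, stringsAsFactors = FALSE)
  out <- out[out$kind != "origin", , drop = FALSE]
  if (!nrow(out)) {
    am <- which(z == max(z), arr.ind = TRUE)[1, ]
    out <- data.frame(x = surface$mids[am[[1]]], y = surface$mids[am[[2]]],
                      kind = "shared", stringsAsFactors = FALSE)
  }
  out[order(-(out$x + out$y)), , drop = FALSE]
}

#' Assign mutations to cluster centres
#'
#' Nearest-centre assignment by Euclidean distance under the kind
#' constraint: shared mutations only to shared centres, private mutations
#' only to private centres of their side. Ties break toward the centre
#' with larger summed CCF, then lexicographic label. A private mutation
#' with no centre on its side founds a new axis centre at the mean CCF of
#' such mutations when at least `min_members` exist, and is otherwise
#' excluded as ambiguous. After assignment, centres holding fewer than
#' `min_members` mutations are deleted and their members re-assigned to
#' the nearest surviving compatible centre.
#'
#' @param ccf1,ccf2 per-mutation CCFs (named by mutation id).
#' @param status per-mutation `shared` / `private_s1` / `private_s2`.
#' @param centres data.frame from [find_peaks()].
#' @param min_members minimum cluster size (default 4).
#' @return list with `assignments` (data.frame `mutation_id`, `cluster`,
#'   `kind`) and `centres` (data.frame `cluster`, `x`, `y`, `kind`, `n`);
#'   excluded mutations carry cluster `NA`.
#' @export
assign_mutations <- function(ccf1, ccf2, status, centres, min_members = 4) {
  ids <- names(ccf1) %||% as.character(seq_along(ccf1))
  stopifnot(length(ccf2) == length(ccf1), length(status) == length(ccf1))
  cen <- centres
  # found missing-side private centres where needed
  for (side in c("private_s1", "private_s2")) {
    if (any(status == side) && !any(cen$kind == side)) {
      sel <- status == side
      if (sum(sel) >= min_members) {
        cen <- rbind(cen, data.frame(
          x = if (side == "private_s1") mean(ccf1[sel]) else 0,
          y = if (side == "private_s2") mean(ccf2[sel]) else 0,
          kind = side, stringsAsFactors = FALSE))
      }
    }
  }
  cen$cluster <- sprintf("K%02d", seq_len(nrow(cen)))

  assign_once <- function(cen) {
    cl <- rep(NA_character_, length(ids))
    for (i in seq_along(ids)) {
      ok <- which(cen$kind == status[i])
      if (!length(ok)) next
      d <- sqrt((ccf1[i] - cen$x[ok])^2 + (ccf2[i] - cen$y[ok])^2)
      best <- ok[d == min(d)]
      if (length(best) > 1) {
        ssum <- cen$x[best] + cen$y[best]
        best <- best[ssum == max(ssum)]
        best <- best[order(cen$cluster[best])][1]
      }
      cl[i] <- cen$cluster[best]
    }
    cl
  }
  cl <- assign_once(cen)
  repeat {
    sizes <- table(factor(cl, levels = cen$cluster))
    small <- names(sizes)[sizes < min_members]
    if (!length(small)) break
    # delete the weakest peak first, then re-assign
    drop <- small[which.min(sizes[small])]
    cen <- cen[cen$cluster != drop, , drop = FALSE]
    if (!nrow(cen)) break
    cl <- assign_once(cen)
  }
  cen$n <- as.integer(table(factor(cl, levels = cen$cluster)))
  list(
    assignments = data.frame(mutation_id = ids, cluster = cl,
                             kind = status, stringsAsFactors = FALSE),
    centres = cen[, c("cluster", "x", "y", "kind", "n")]
  )
}

#' Cluster a sample pair in CCF space
#'
#' Orchestrates histogram, surface fit, peak detection and constrained
#' assignment for one pair. Deterministic for fixed input and smoothing
#' parameter.
#'
#' @param ccf_pair wide CCF table from [apply_filters()] (`$ccf`).
#' @param status shared/private status vector from [apply_filters()].
#' @param samples character(2) sample names.
#' @param config threshold namespace.
#' @return list with `assignments`, `centres` (coordinates named after the
#'   two samples), `surface`, `histogram`.
#' @export
cluster_pair <- function(ccf_pair, status, samples,
                         config = default_config()) {
  c1 <- ccf_pair[[paste0("ccf_", samples[1])]]
  c2 <- ccf_pair[[paste0("ccf_", samples[2])]]
  names(c1) <- names(c2) <- ccf_pair$mutation_id
  st <- status[ccf_pair$mutation_id]
  st <- ifelse(st == paste0("private_", samples[1]), "private_s1",
               ifelse(st == paste0("private_", samples[2]), "private_s2",
                      "shared"))
  # the grid cannot distinguish coordinates within the first bin from the
  # axis, so rescued trace-level detections (shared, but CCF inside the
  # axis bin in exactly one sample) follow the axis-bin convention and are
  # assigned as near-private to the carrier side
  near1 <- st == "shared" & c2 < config$bin_width & c1 >= config$bin_width
  near2 <- st == "shared" & c1 < config$bin_width & c2 >= config$bin_width
  st[near1] <- "private_s1"
  st[near2] <- "private_s2"
  h <- build_histogram(c1, c2, config$bin_width, config$ccf_max)
  surf <- fit_surface(h, lambda = config$lambda)
  pk <- find_peaks(surf, floor_frac = config$peak_floor)
  res <- assign_mutations(c1, c2, st, pk, min_members = config$min_cluster)
  res$surface <- surf
  res$histogram <- h
  res$samples <- samples
  res
}
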