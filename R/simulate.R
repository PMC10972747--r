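# Synthetic multiregion/longitudinal patient generator with known ground
# truth (clone tree, per-sample CCFs, copy number, purity, read counts).
# Defaults emulate the study conditions of the emulated cohort: 2-3
# exome-sequenced samples per patient at ~127x coverage, purity ~0.85,
# genome ploidy ~2.5, hundreds of clonal and tens-to-hundreds of subclonal
# mutations.

CLASS_MIN_CLONES <- c(A = 1L, B = 2L, C = 3L, D = 4L, E = 3L, F = 5L)

# Topology (parent index vector, root = 0) realising a phylogeny class with
# n_clones nodes. Extra clones extend chains below existing leaves so the
# branching count is unchanged.
class_topology <- function(target_class, n_clones) {
  need <- CLASS_MIN_CLONES[[target_class]]
  if (n_clones < need)
    stop("infeasible target_class ", target_class, " with ", n_clones,
         " clones (needs >= ", need, ")")
  if (target_class == "A" && n_clones != 1L)
    stop("infeasible target_class A: needs exactly 1 clone")
  if (target_class == "B" && n_clones != 2L)
    stop("infeasible target_class B: needs exactly 2 clones")
  parent <- switch(target_class,
    A = integer(0),
    B = 1L,
    C = seq_len(n_clones - 1L),          # chain
    D = c(1L, 2L, 2L),                   # C0 -> C1 -> {x, y}
    E = c(1L, 1L),                       # C0 -> {x, y}
    F = c(1L, 1L, 2L, 2L)                # C0 -> {a, b}; a -> {c, d}
  )
  # pad by chain extension below the last node (never adds a branching)
  while (length(parent) + 1L < n_clones) {
    tips <- setdiff(seq_len(length(parent) + 1L), parent)
    # extend a tip that is a branch child (keeps D/E/F class stable)
    parent <- c(parent, max(tips))
  }
  parent
}

random_topology <- function(n_clones) {
  if (n_clones == 1L) return(integer(0))
  vapply(seq_len(n_clones - 1L) + 1L,
         function(i) sample.int(i - 1L, 1L), integer(1))
}

count_branchings <- function(parent) {
  if (!length(parent)) return(0L)
  sum(table(parent) >= 2L)
}

# Minimum number of samples needed to give every clone below `node` a
# distinct "home" sample pattern: sibling subtrees need disjoint sample
# sets for their CCF vectors to cross.
req_width <- function(children, node) {
  kids <- children[[as.character(node)]]
  if (is.null(kids)) return(1L)
  reqs <- vapply(kids, function(k) req_width(children, k), integer(1))
  if (length(kids) == 1L) reqs else sum(reqs)
}

# Draw a clone x sample CCF matrix for a topology by recursive
# stick-breaking: children receive fractions of the parent's CCF, so the
# sum rule holds by construction. At each branching the parent's active
# samples are partitioned among the children (respecting the width each
# subtree needs), so sibling clones peak in disjoint samples and their
# CCF vectors cross, making the branching identifiable.
draw_ccfs <- function(parent, n_samples, strict = TRUE) {
  n <- length(parent) + 1L
  ccf <- matrix(0, n, n_samples)
  ccf[1L, ] <- 1
  children <- split(seq_len(n)[-1L], parent)
  active <- vector("list", n)
  active[[1L]] <- seq_len(n_samples)
  for (v in seq_len(n)) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) next
    k <- length(kids)
    if (k == 1L) {
      frac <- stats::runif(1, 0.5, 0.75)
      ccf[kids, ] <- frac * ccf[v, ]
      active[[kids]] <- active[[v]]
      next
    }
    av <- active[[v]]
    reqs <- vapply(kids, function(x) req_width(children, x), integer(1))
    if (strict && sum(reqs) > length(av))
      stop("infeasible: branching needs ", sum(reqs),
           " samples but only ", length(av), " are active")
    groups <- vector("list", k)
    pool <- sample(av)
    if (sum(reqs) <= length(pool)) {
      off <- 0L
      for (j in seq_len(k)) {
        groups[[j]] <- pool[off + seq_len(reqs[j])]
        off <- off + reqs[j]
      }
      for (s in pool[seq_len(length(pool) - off) + off]) {
        j <- sample.int(k, 1)
        groups[[j]] <- c(groups[[j]], s)
      }
    } else {
      for (j in seq_len(k))
        groups[[j]] <- pool[(j - 1L) %% length(pool) + 1L]
    }
    for (j in seq_len(k)) {
      hi <- stats::runif(1, 0.55, 0.8)
      lo <- stats::runif(n_samples, 0, 0.15) / (k - 1)
      f <- ifelse(seq_len(n_samples) %in% groups[[j]], hi, lo)
      ccf[kids[j], ] <- f * ccf[v, ]
      active[[kids[j]]] <- groups[[j]]
    }
    tot <- colSums(ccf[kids, , drop = FALSE])
    over <- tot > 0.95 * ccf[v, ]
    if (any(over)) {
      sc <- ifelse(over, 0.95 * ccf[v, ] / tot, 1)
      ccf[kids, ] <- sweep(ccf[kids, , drop = FALSE], 2, sc, `*`)
    }
  }
  ccf
}

# Ancestor-relation helper on a parent-index vector.
is_ancestor <- function(parent, a, b) {
  while (b != 0L) {
    b <- if (b == 1L) 0L else parent[b - 1L]
    if (b == a) return(TRUE)
  }
  FALSE
}

ccfs_valid <- function(parent, ccf, min_sep, delta = 0.15,
                       require_crossing = TRUE) {
  n <- nrow(ccf)
  if (n == 1L) return(TRUE)
  d <- as.matrix(stats::dist(ccf))
  if (min(d[upper.tri(d)]) < min_sep) return(FALSE)
  if (!require_crossing) return(TRUE)
  # unrelated clone pairs must cross (neither dominates everywhere), so the
  # emitted topology is the unique minimal-branching admissible tree
  for (a in 2:n) for (b in 2:n) {
    if (a >= b) next
    if (is_ancestor(parent, a, b) || is_ancestor(parent, b, a)) next
    if (all(ccf[a, ] >= ccf[b, ] - delta) || all(ccf[b, ] >= ccf[a, ] - delta))
      return(FALSE)
  }
  TRUE
}

#' Sample a ground-truth clone tree with per-sample CCFs
#'
#' Draws a clone topology (optionally realising a requested phylogeny
#' class) and a clone-by-sample CCF matrix by recursive stick-breaking
#' from the root, so the sum rule holds by construction and the root (C0)
#' has CCF 1 in every sample. Sibling clones are given crossing CCF
#' patterns across samples so the branching structure is identifiable from
#' the data.
#'
#' @param n_clones total number of clones including the ancestor (>= 1).
#' @param n_samples number of samples (>= 1).
#' @param target_class optional phylogeny class `"A"`..`"F"`; an
#'   infeasibility error is raised when `n_clones`/`n_samples` cannot
#'   realise it (e.g. class F needs >= 5 clones).
#' @param seed integer seed; fixing it fixes the emitted object.
#' @param min_sep minimum Euclidean separation between clone CCF vectors
#'   (default 0.25).
#' @param mut_clonal,mut_subclonal integer bounds (log-uniform) for the
#'   mutation count of the ancestral and of each subclone.
#' @return Object of class `ground_truth`: list with `parent` (named clone
#'   labels), `ccf` (clone x sample matrix), `n_mutations` (per clone),
#'   `class`, `samples`, `seed`.
#' @export
sample_clone_tree <- function(n_clones, n_samples, target_class = NULL,
                              seed = NULL, min_sep = 0.25,
                              mut_clonal = c(50, 500),
                              mut_subclonal = c(10, 200)) {
  stopifnot(n_clones >= 1, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  strict <- !is.null(target_class)
  if (strict) {
    target_class <- match.arg(target_class, c("A", "B", "C", "D", "E", "F"))
    parent <- class_topology(target_class, n_clones)
    ch <- split(seq_len(n_clones)[-1L], parent)
    need <- req_width(ch, 1L)
    if (need > n_samples)
      stop("infeasible target_class ", target_class, ": its branchings need ",
           need, " samples for identifiable CCF patterns, got ", n_samples)
  } else {
    parent <- random_topology(n_clones)
  }
  for (try in seq_len(500)) {
    ccf <- draw_ccfs(parent, n_samples, strict = strict)
    ok <- ccfs_valid(parent, ccf, min_sep, require_crossing = strict)
    if (ok && strict) {
      # identifiability: the noiseless configuration must reconstruct to the
      # requested class even at a stricter tolerance, so that maximum
      # parsimony cannot flatten the branching structure
      rec <- try(reconstruct_tree(ccf, eps = 0.15), silent = TRUE)
      ok <- !inherits(rec, "try-error") && rec$class == target_class
    }
    if (ok) break
    if (try == 500) stop("could not draw separated CCFs; lower min_sep")
  }
  labels <- paste0("C", seq_len(n_clones) - 1L)
  rownames(ccf) <- labels
  samples <- paste0("S", seq_len(n_samples))
  colnames(ccf) <- samples
  logu <- function(b) round(exp(stats::runif(1, log(b[1]), log(b[2]))))
  n_mut <- c(logu(mut_clonal),
             if (n_clones > 1) replicate(n_clones - 1L, logu(mut_subclonal)))
  gt <- structure(list(
    parent = stats::setNames(c(NA_character_, labels[parent]), labels),
    ccf = ccf, n_mutations = stats::setNames(as.integer(n_mut), labels),
    class = classify_parent_map(parent),
    samples = samples, seed = seed
  ), class = "ground_truth")
  gt
}

# classification on a raw parent-index vector (shared with phylo module)
classify_parent_map <- function(parent) {
  n <- length(parent) + 1L
  b <- count_branchings(parent)
  if (b == 0L) {
    if (n == 1L) return("A")
    if (n == 2L) return("B")
    return("C")
  }
  if (b >= 2L) return("F")
  branch_node <- as.integer(names(which(table(parent) >= 2L)))
  if (branch_node == 1L) "E" else "D"
}

# Simulate an exome-scale allele-specific segmentation. States are drawn
# per segment to give a length-weighted mean copy number near the target
# ploidy; an loh_fraction of the genome is forced to minor copy 0.
simulate_segments <- function(samples, target_ploidy = 2.5, loh_fraction = 0,
                              n_seg_per_chrom = 2L,
                              chrom_lengths = hg19_chrom_lengths()) {
  chroms <- names(chrom_lengths)[1:22]
  states <- list(c(1L, 1L), c(2L, 1L), c(2L, 2L), c(3L, 1L), c(1L, 0L))
  totals <- vapply(states, sum, integer(1))
  # weights chosen so the expected total CN matches target_ploidy
  base_w <- c(0.45, 0.30, 0.10, 0.10, 0.05)
  adj <- (target_ploidy - sum(base_w * totals)) / (4 - 2)
  w <- base_w + c(-adj, 0, adj, 0, 0)
  w <- pmax(w, 0.01); w <- w / sum(w)
  segs <- list()
  for (chr in chroms) {
    L <- chrom_lengths[[chr]]
    cuts <- sort(sample.int(L - 2L, n_seg_per_chrom - 1L) + 1L)
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, L)
    st <- sample(seq_along(states), n_seg_per_chrom, replace = TRUE, prob = w)
    if (loh_fraction > 0) {
      make_loh <- stats::runif(n_seg_per_chrom) < loh_fraction
      st[make_loh] <- 5L
    } else {
      st[st == 5L] <- 2L
    }
    segs[[chr]] <- data.frame(
      chrom = chr, start = starts, end = ends,
      major_cn = vapply(states[st], `[`, integer(1), 1),
      minor_cn = vapply(states[st], `[`, integer(1), 2),
      stringsAsFactors = FALSE
    )
  }
  one <- do.call(rbind, segs)
  out <- do.call(rbind, lapply(samples, function(s)
    cbind(sample = s, one, stringsAsFactors = FALSE)))
  out$subclonal_cn <- FALSE
  rownames(out) <- NULL
  out
}

#' Emit read-count observations from a ground truth
#'
#' Places each clone's mutations uniformly on the simulated segments and
#' draws, per mutation and sample, a Poisson depth around `mean_depth` and
#' binomial variant reads with success probability
#' `expected_vaf(purity, CN, m) * CCF(clone, sample)`; strand counts split
#' binomially at 0.5. Optional artifact channels inject FFPE-like low-AF
#' noise variants, indel calls adjacent to SNMs, and LOH-deleted segments,
#' for filter testing; all default off.
#'
#' @param gt `ground_truth` from [sample_clone_tree()].
#' @param mean_depth mean sequencing depth (default 127, exome-like).
#' @param purity per-sample purity (recycled; default 0.85).
#' @param target_ploidy genome mean copy number aimed for (default 2.5).
#' @param seed integer seed.
#' @param noise_rate expected count of artifact low-AF strand-biased
#'   variants per sample (default 0 = off).
#' @param indel_rate expected count of indel calls, half of them placed
#'   within 10 bp of an SNM call (default 0 = off).
#' @param loh_fraction fraction of segments forced to LOH (default 0).
#' @return A `patient_bundle`: list with `mutations` (long table),
#'   `segments`, `purity` (sample/purity/ploidy), `truth` (the ground
#'   truth plus `mutation_assignment`).
#' @export
emit_reads <- function(gt, mean_depth = 127, purity = 0.85,
                       target_ploidy = 2.5, seed = NULL,
                       noise_rate = 0, indel_rate = 0, loh_fraction = 0) {
  stopifnot(inherits(gt, "ground_truth"), mean_depth > 0)
  if (!is.null(seed)) set.seed(seed)
  samples <- gt$samples
  purity <- rep_len(purity, length(samples))
  segs <- simulate_segments(samples, target_ploidy, loh_fraction)
  one <- segs[segs$sample == samples[1], ]
  seg_len <- one$end - one$start + 1
  ploidy <- vapply(samples, function(s) {
    ss <- segs[segs$sample == s, ]
    sum((ss$major_cn + ss$minor_cn) * (ss$end - ss$start + 1)) /
      sum(ss$end - ss$start + 1)
  }, numeric(1))

  clones <- rownames(gt$ccf)
  n_tot <- sum(gt$n_mutations)
  clone_of <- rep(clones, gt$n_mutations[clones])
  seg_pick <- sample.int(nrow(one), n_tot, replace = TRUE, prob = seg_len)
  pos <- one$start[seg_pick] +
    floor(stats::runif(n_tot) * (seg_len[seg_pick] - 1))
  ids <- sprintf("m%05d", seq_len(n_tot))
  major <- one$major_cn[seg_pick]
  total <- major + one$minor_cn[seg_pick]
  # true multiplicity: clonal mutations predate gains with prob 0.25
  m_true <- ifelse(clone_of == "C0" & major >= 2 & stats::runif(n_tot) < 0.25,
                   major, 1L)
  m_true[major == 0] <- 0L

  rows <- list()
  for (k in seq_along(samples)) {
    s <- samples[k]
    ccf_s <- gt$ccf[clone_of, s]
    depth <- stats::rpois(n_tot, mean_depth)
    ev <- ifelse(m_true >= 1,
                 expected_vaf(purity[k], pmax(total, 1), pmax(m_true, 1)), 0)
    palt <- pmin(ev * ccf_s, 1)
    alt <- stats::rbinom(n_tot, depth, palt)
    fwd <- stats::rbinom(n_tot, alt, 0.5)
    rows[[k]] <- data.frame(
      mutation_id = ids, chrom = one$chrom[seg_pick], pos = pos,
      ref = "C", alt = "T", kind = "SNM", sample = s,
      depth = depth, alt_reads = alt, forward_alt = fwd,
      reverse_alt = alt - fwd, fraction_lowmapq = 0,
      stringsAsFactors = FALSE
    )
  }
  mut <- do.call(rbind, rows)

  # artifact channels ------------------------------------------------------
  extra <- list()
  if (noise_rate > 0) {
    for (k in seq_along(samples)) {
      nn <- stats::rpois(1, noise_rate)
      if (!nn) next
      sp <- sample.int(nrow(one), nn, replace = TRUE, prob = seg_len)
      np <- one$start[sp] + floor(stats::runif(nn) * (seg_len[sp] - 1))
      d <- stats::rpois(nn, mean_depth)
      a <- pmax(1L, stats::rbinom(nn, d, 0.03))
      extra[[length(extra) + 1L]] <- data.frame(
        mutation_id = sprintf("noise_%s_%04d", samples[k], seq_len(nn)),
        chrom = one$chrom[sp], pos = np, ref = "C", alt = "A", kind = "SNM",
        sample = samples[k], depth = d, alt_reads = a,
        forward_alt = a, reverse_alt = 0L,  # strand-biased artifact
        fraction_lowmapq = 0, stringsAsFactors = FALSE
      )
    }
  }
  if (indel_rate > 0) {
    nn <- stats::rpois(1, indel_rate)
    if (nn > 0) {
      near <- sample(seq_len(n_tot), ceiling(nn / 2))
      ip <- c(pos[near] + sample(c(-9L:-1L, 1L:9L), length(near), TRUE),
              sample.int(1e8, nn - length(near)) + 1e6)
      ic <- c(one$chrom[seg_pick][near],
              sample(one$chrom, nn - length(near), TRUE))
      for (k in seq_along(samples)) {
        d <- stats::rpois(nn, mean_depth)
        a <- stats::rbinom(nn, d, 0.4)
        f <- stats::rbinom(nn, a, 0.5)
        extra[[length(extra) + 1L]] <- data.frame(
          mutation_id = sprintf("indel_%04d", seq_len(nn)),
          chrom = ic, pos = ip, ref = "CT", alt = "C", kind = "deletion",
          sample = samples[k], depth = d, alt_reads = a,
          forward_alt = f, reverse_alt = a - f,
          fraction_lowmapq = 0, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(extra)) mut <- rbind(mut, do.call(rbind, extra))
  rownames(mut) <- NULL

  truth <- gt
  truth$mutation_assignment <- stats::setNames(clone_of, ids)
  truth$multiplicity <- stats::setNames(m_true, ids)
  structure(list(
    patient = "SIM", mutations = mut, segments = segs,
    purity = data.frame(sample = samples, purity = purity, ploidy = ploidy,
                        stringsAsFactors = FALSE),
    truth = truth
  ), class = "patient_bundle")
}

#' Simulate a complete synthetic patient
#'
#' Convenience wrapper: [sample_clone_tree()] + [emit_reads()] under one
#' seed.
#'
#' @inheritParams sample_clone_tree
#' @inheritParams emit_reads
#' @return A `patient_bundle` with ground truth attached.
#' @export
simulate_patient <- function(n_clones, n_samples, target_class = NULL,
                             seed = NULL, mean_depth = 127, purity = 0.85,
                             min_sep = 0.25,
                             mut_clonal = c(50, 500),
                             mut_subclonal = c(10, 200), ...) {
  gt <- sample_clone_tree(n_clones, n_samples, target_class, seed = seed,
                          min_sep = min_sep, mut_clonal = mut_clonal,
                          mut_subclonal = mut_subclonal)
  emit_reads(gt, mean_depth = mean_depth, purity = purity, ...)
}
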