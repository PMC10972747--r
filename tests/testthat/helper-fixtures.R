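# Fixture builders shared across the suite; everything generated in code.

# minimal per-sample segment table: one whole-chromosome segment per sample
make_segments <- function(samples, chrom = "chr1", major = 1, minor = 1,
                          start = 1, end = 249250621, subclonal = FALSE) {
  do.call(rbind, lapply(samples, function(s) data.frame(
    sample = s, chrom = chrom, start = start, end = end,
    major_cn = major, minor_cn = minor, subclonal_cn = subclonal,
    stringsAsFactors = FALSE)))
}

# long-format mutation rows with sensible defaults
make_mut <- function(mutation_id, sample, depth, alt, chrom = "chr1",
                     pos = 1e6, kind = "SNM", fwd = NULL,
                     fraction_lowmapq = 0) {
  n <- max(length(mutation_id), length(sample), length(depth), length(alt),
           length(pos))
  mutation_id <- rep_len(mutation_id, n); sample <- rep_len(sample, n)
  depth <- rep_len(depth, n); alt <- rep_len(alt, n)
  pos <- rep_len(pos, n); chrom <- rep_len(chrom, n)
  kind <- rep_len(kind, n)
  if (is.null(fwd)) fwd <- floor(alt / 2) else fwd <- rep_len(fwd, n)
  data.frame(
    mutation_id = mutation_id, chrom = chrom, pos = pos, ref = "C",
    alt = "T", kind = kind, sample = sample, depth = depth,
    alt_reads = alt, forward_alt = fwd, reverse_alt = alt - fwd,
    fraction_lowmapq = rep_len(fraction_lowmapq, n),
    stringsAsFactors = FALSE
  )
}

make_purity <- function(samples, purity = 1, ploidy = 2) {
  data.frame(sample = samples, purity = rep_len(purity, length(samples)),
             ploidy = rep_len(ploidy, length(samples)),
             stringsAsFactors = FALSE)
}

# hand-built clone tree (bypasses reconstruction)
make_tree <- function(parent, ccf, n_mut = NULL) {
  if (is.null(n_mut))
    n_mut <- stats::setNames(rep(10L, nrow(ccf)), rownames(ccf))
  tr <- clonearch:::new_clone_tree(parent, ccf, n_mut)
  tr$class <- classify(tr)
  tr
}

# independent brute-force tree oracle: enumerate every parent assignment,
# keep those satisfying monotonicity + sum rule, report minimal branching
brute_force_trees <- function(centres, eps = 0.1) {
  stopifnot(all(abs(centres[1, ] - 1) <= eps))  # row 1 is the root
  n <- nrow(centres)
  if (n == 1) return(list(min_branch = 0L, parents = list(integer(0))))
  choices <- rep(list(seq_len(n)), n - 1)
  grid <- as.matrix(expand.grid(choices))
  ok_parents <- list()
  for (r in seq_len(nrow(grid))) {
    par <- c(0L, grid[r, ])
    if (any(par[-1] == seq(2, n))) next  # self-parenting
    # acyclicity: walk up from each node
    cyc <- FALSE
    for (v in 2:n) {
      seen <- integer(0); u <- v
      while (u != 1L) {
        if (u %in% seen) { cyc <- TRUE; break }
        seen <- c(seen, u); u <- par[u]
        if (u == 0L) break
      }
      if (cyc) break
    }
    if (cyc) next
    mono <- all(vapply(2:n, function(v)
      all(centres[v, ] <= centres[par[v], ] + eps), logical(1)))
    if (!mono) next
    sums_ok <- TRUE
    for (p in seq_len(n)) {
      kids <- which(par == p)
      if (!length(kids)) next
      if (any(colSums(centres[kids, , drop = FALSE]) > centres[p, ] + eps)) {
        sums_ok <- FALSE; break
      }
    }
    if (!sums_ok) next
    ok_parents[[length(ok_parents) + 1L]] <- par
  }
  if (!length(ok_parents)) return(list(min_branch = NA, parents = list()))
  branch <- vapply(ok_parents, function(par)
    sum(table(par[-1]) >= 2L), integer(1))
  list(min_branch = min(branch), parents = ok_parents, branch = branch)
}

N_CLONES_OF <- c(A = 1L, B = 2L, C = 3L, D = 4L, E = 3L, F = 5L)
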