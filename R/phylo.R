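# Clone-tree reconstruction under the infinite-sites assumption and the
# CCF sum rule; phylogeny classes; per-sample clonal composition.

new_clone_tree <- function(parent, ccf, n_mutations, flags = character(0)) {
  labels <- rownames(ccf)
  b <- if (length(parent) <= 1) 0L else
    sum(table(parent[!is.na(parent)]) >= 2L)
  structure(list(
    labels = labels, parent = parent, ccf = ccf,
    n_mutations = n_mutations, n_branching = as.integer(b),
    class = NA_character_, flags = flags
  ), class = "clone_tree")
}

tree_children <- function(tree, node) {
  names(tree$parent)[!is.na(tree$parent) & tree$parent == node]
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", length(x$labels), "clones,",
      x$n_branching, "branching event(s), class",
      x$class %||% "?", "\n")
  for (l in x$labels) {
    p <- x$parent[[l]]
    cat(sprintf("  %s <- %s  [%s]  n=%d\n", l,
                ifelse(is.na(p), "root", p),
                paste(sprintf("%.2f", x$ccf[l, ]), collapse = ", "),
                x$n_mutations[[l]] %||% NA_integer_))
  }
  invisible(x)
}

#' Reconstruct the clone tree from CCF cluster centres
#'
#' Searches rooted trees over the clusters satisfying (i) ancestry
#' monotonicity (child CCF <= parent CCF + `eps` in every sample) and (ii)
#' the sum rule (sibling CCFs sum to <= parent CCF + `eps` in every
#' sample), and returns the tree minimising the number of branching events
#' (maximum parsimony: linear evolution preferred over branched). Remaining
#' ties attach each clone to the admissible parent with the smallest CCF
#' (deepest attachment), then break lexicographically.
#'
#' The root C0 is the cluster with every centre coordinate within `eps` of
#' 1; multiple qualifying clusters are indistinguishable at tolerance and
#' are merged; if none qualifies the highest shared cluster is promoted
#' with a warning flag. Clone labels C0, C1, ... follow depth-first order
#' with larger-CCF children first.
#'
#' @param centres matrix clusters x samples of centre CCFs (rownames are
#'   cluster ids), or the `centres` data.frame of [cluster_pair()].
#' @param n_mutations integer vector of cluster sizes (named like the
#'   centre rows).
#' @param eps CCF tolerance (default 0.1).
#' @param samples optional sample names for the columns.
#' @return A `clone_tree`; on failure an error of class
#'   `clonearch_conflict` listing the violated constraints.
#' @export
reconstruct_tree <- function(centres, n_mutations = NULL, eps = 0.1,
                             samples = NULL) {
  if (is.data.frame(centres)) {
    m <- as.matrix(centres[, intersect(c("x", "y"), names(centres)),
                           drop = FALSE])
    rownames(m) <- centres$cluster
    if (is.null(n_mutations) && !is.null(centres$n))
      n_mutations <- stats::setNames(centres$n, centres$cluster)
    centres <- m
  }
  if (is.null(rownames(centres)))
    rownames(centres) <- sprintf("K%02d", seq_len(nrow(centres)))
  if (!is.null(samples)) colnames(centres) <- samples
  if (is.null(colnames(centres)))
    colnames(centres) <- paste0("S", seq_len(ncol(centres)))
  if (is.null(n_mutations)) {
    n_mutations <- stats::setNames(rep(1L, nrow(centres)), rownames(centres))
  } else if (is.null(names(n_mutations)) ||
             !all(rownames(centres) %in% names(n_mutations))) {
    stopifnot(length(n_mutations) == nrow(centres))
    n_mutations <- stats::setNames(n_mutations, rownames(centres))
  }
  flags <- character(0)

  # --- root identification ------------------------------------------------
  # clonal means >= 1 - eps in every sample; coordinates above 1 are noise
  # or multiplicity error and do not disqualify a cluster from C0
  is_c0 <- apply(centres, 1, function(r) all(r >= 1 - eps))
  if (sum(is_c0) == 0) {
    shared <- apply(centres, 1, function(r) all(r > 0))
    if (!any(shared))
      stop(structure(class = c("clonearch_conflict", "error", "condition"),
                     list(message = "no cluster qualifies as ancestral C0",
                          call = sys.call())))
    root_id <- names(which.max(rowSums(centres[shared, , drop = FALSE])))
    flags <- c(flags, "promoted_root")
  } else if (sum(is_c0) > 1) {
    ids <- names(which(is_c0))
    w <- n_mutations[ids]
    merged <- colSums(centres[ids, , drop = FALSE] * w) / sum(w)
    centres <- centres[!rownames(centres) %in% ids, , drop = FALSE]
    centres <- rbind(merged, centres)
    rownames(centres)[1] <- ids[1]
    n_mutations <- c(stats::setNames(sum(w), ids[1]),
                     n_mutations[setdiff(names(n_mutations), ids)])
    root_id <- ids[1]
    flags <- c(flags, "merged_root")
  } else {
    root_id <- names(which(is_c0))
  }

  ids <- rownames(centres)
  others <- setdiff(ids, root_id)
  # order by decreasing total CCF (ties by label): parents precede children,
  # which also guarantees acyclicity of the searched assignments
  others <- others[order(-rowSums(centres[others, , drop = FALSE]), others)]
  ord <- c(root_id, others)
  n <- length(ord)
  cc <- centres[ord, , drop = FALSE]

  if (n == 1) {
    tree <- new_clone_tree(stats::setNames(NA_character_, "C0"),
                           matrix(cc[1, ], 1, ncol(cc),
                                  dimnames = list("C0", colnames(cc))),
                           stats::setNames(n_mutations[root_id], "C0"), flags)
    tree$class <- classify(tree)
    return(tree)
  }

  # admissible parents per cluster (monotonicity + earlier in order)
  adm <- lapply(seq_len(n), function(i) {
    if (i == 1) return(integer(0))
    cand <- seq_len(i - 1)
    cand[vapply(cand, function(j) all(cc[i, ] <= cc[j, ] + eps), logical(1))]
  })
  if (any(vapply(adm[-1], length, integer(1)) == 0)) {
    bad <- ord[-1][vapply(adm[-1], length, integer(1)) == 0]
    stop(structure(class = c("clonearch_conflict", "error", "condition"),
                   list(message = paste0(
                     "no admissible parent for cluster(s) ",
                     paste(bad, collapse = ", "),
                     " (ancestry monotonicity violated at eps=", eps, ")"),
                     call = sys.call())))
  }

  best <- new.env()
  best$parent <- NULL; best$score <- NULL
  child_sum <- matrix(0, n, ncol(cc))
  assign_par <- integer(n)

  score_of <- function(parent_idx) {
    b <- sum(table(parent_idx[-1]) >= 2L)
    depth_pen <- sum(rowSums(cc)[parent_idx[-1]])
    lex <- paste(ord[parent_idx[-1]], collapse = "|")
    list(b = b, depth = depth_pen, lex = lex)
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$b != b$b) return(a$b < b$b)
    if (a$depth != b$depth) return(a$depth < b$depth)
    a$lex < b$lex
  }
  dfs <- function(i) {
    if (i > n) {
      sc <- score_of(assign_par)
      if (better(sc, best$score)) {
        best$score <- sc
        best$parent <- assign_par
      }
      return(invisible(NULL))
    }
    for (j in adm[[i]]) {
      new_sum <- child_sum[j, ] + cc[i, ]
      if (all(new_sum <= cc[j, ] + eps)) {
        child_sum[j, ] <<- new_sum
        assign_par[i] <<- j
        dfs(i + 1)
        child_sum[j, ] <<- child_sum[j, ] - cc[i, ]
      }
    }
    invisible(NULL)
  }
  dfs(2L)
  if (is.null(best$parent))
    stop(structure(class = c("clonearch_conflict", "error", "condition"),
                   list(message = paste0(
                     "no admissible tree: the CCF sum rule cannot be ",
                     "satisfied for any parent assignment at eps=", eps),
                     call = sys.call())))

  # relabel C0, C1, ... depth-first, larger-CCF children first
  par_idx <- best$parent
  kids <- split(seq_len(n)[-1], par_idx[-1])
  lab <- character(n)
  counter <- 0L
  walk <- function(i) {
    lab[i] <<- paste0("C", counter); counter <<- counter + 1L
    ks <- kids[[as.character(i)]]
    if (!is.null(ks)) {
      ks <- ks[order(-rowSums(cc[ks, , drop = FALSE]))]
      for (k2 in ks) walk(k2)
    }
  }
  walk(1L)
  o <- order(as.integer(sub("C", "", lab)))
  ccf <- cc[o, , drop = FALSE]
  rownames(ccf) <- lab[o]
  parent <- stats::setNames(
    c(NA_character_, lab[par_idx[o[-1]]]), lab[o])
  nm <- stats::setNames(as.integer(n_mutations[ord[o]]), lab[o])
  tree <- new_clone_tree(parent, ccf, nm, flags)
  tree$cluster_map <- stats::setNames(lab[o], ord[o])
  tree$class <- classify(tree)
  tree
}

#' Classify a clone tree into phylogeny classes A-F
#'
#' A: no subclones; B: linear with one subclone; C: linear with at least
#' two subclones; D: exactly one branching event from a C1-or-deeper
#' subclone; E: exactly one branching event from the ancestral clone C0;
#' F: at least two branching events. A branching event is a node with two
#' or more children.
#'
#' @param tree a `clone_tree`.
#' @return One of `"A"`..`"F"`.
#' @export
classify <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  parent <- tree$parent
  n <- length(parent)
  tab <- table(parent[!is.na(parent)])
  b <- sum(tab >= 2L)
  if (b == 0L) return(if (n == 1L) "A" else if (n == 2L) "B" else "C")
  if (b >= 2L) return("F")
  root <- names(parent)[is.na(parent)]
  if (names(which(tab >= 2L)) == root) "E" else "D"
}

#' Per-sample clonal composition
#'
#' Reports each clone's CCF in a sample plus the derived terminal fraction:
#' the fraction of cells whose most derived clone is that node
#' (node CCF minus the summed CCF of its children, floored at 0).
#'
#' @param tree a `clone_tree`.
#' @param sample sample name (a column of the tree's CCF matrix).
#' @return data.frame with `clone`, `ccf`, `terminal_fraction`.
#' @export
clone_composition <- function(tree, sample) {
  stopifnot(inherits(tree, "clone_tree"), sample %in% colnames(tree$ccf))
  ccf <- stats::setNames(tree$ccf[, sample], rownames(tree$ccf))
  term <- vapply(tree$labels, function(l) {
    kids <- tree_children(tree, l)
    max(ccf[[l]] - sum(ccf[kids]), 0)
  }, numeric(1))
  data.frame(clone = tree$labels, ccf = unname(ccf[tree$labels]),
             terminal_fraction = unname(term[tree$labels]),
             stringsAsFactors = FALSE)
}

#' Ancestral clone seeding a relapse sample
#'
#' The clones making up the later sample are those with a terminal cell
#' fraction above `eps` there; the seed is the deepest common ancestor of
#' all of them that is present (CCF > `eps`) in both the earlier and the
#' later sample. C0 always qualifies, so the function is total.
#'
#' @param tree a `clone_tree`.
#' @param pre,post sample names in temporal order.
#' @param eps presence threshold (default 0.1).
#' @return Clone label.
#' @export
relapse_seed <- function(tree, pre, post, eps = 0.1) {
  stopifnot(inherits(tree, "clone_tree"))
  comp <- clone_composition(tree, post)
  post_clones <- comp$clone[comp$terminal_fraction > eps]
  if (!length(post_clones))
    post_clones <- comp$clone[which.max(comp$terminal_fraction)]
  ancestors <- function(l) {
    out <- l
    while (!is.na(tree$parent[[l]])) { l <- tree$parent[[l]]; out <- c(out, l) }
    out
  }
  common <- Reduce(intersect, lapply(post_clones, ancestors))
  cand <- common[tree$ccf[common, pre] > eps & tree$ccf[common, post] > eps]
  if (!length(cand)) cand <- tree$labels[is.na(tree$parent)]
  depth <- vapply(cand, function(l) length(ancestors(l)), integer(1))
  cand[which.max(depth)]
}

#' Choose the representative sample pair of a patient
#'
#' Evaluates every pair's subclonal complexity and returns the pair
#' maximising the number of subclones, then the number of subclonal
#' mutations; deterministic tie-break by sample-id order.
#'
#' @param pair_summaries data.frame with columns `sample1`, `sample2`,
#'   `n_subclones`, `n_subclonal_mutations` (one row per evaluated pair).
#' @return The selected row of `pair_summaries`.
#' @export
downscale_pairs <- function(pair_summaries) {
  if (nrow(pair_summaries) < 1) stop("at least one sample pair required")
  o <- order(-pair_summaries$n_subclones,
             -pair_summaries$n_subclonal_mutations,
             pair_summaries$sample1, pair_summaries$sample2)
  pair_summaries[o[1], , drop = FALSE]
}

#' Rescale cluster centres that conflict with clonality
#'
#' Clusters whose centre exceeds CCF 1 + `eps` in some sample reject the
#' multiplicity-1 clonality assumption; re-evaluating their mutations at a
#' higher multiplicity divides the CCF accordingly. The centre is rescaled
#' by the feasible integer multiplicity bringing its largest coordinate
#' closest to 1.
#'
#' @param centres matrix clusters x samples.
#' @param eps tolerance (default 0.1).
#' @param max_m largest multiplicity considered (default 4).
#' @return list `centres` (rescaled), `rescaled` (named multiplicities).
#' @export
rescale_conflicting_clusters <- function(centres, eps = 0.1, max_m = 4) {
  resc <- integer(0)
  for (i in seq_len(nrow(centres))) {
    top <- max(centres[i, ])
    if (top > 1 + eps) {
      ms <- 2:max_m
      m <- ms[which.min(abs(top / ms - 1))]
      centres[i, ] <- centres[i, ] / m
      resc[rownames(centres)[i]] <- m
    }
  }
  list(centres = centres, rescaled = resc)
}

#' Export a clone tree as a Newick string
#'
#' Branch lengths are the mean CCF drop from parent to child across
#' samples (floored at 0).
#'
#' @param tree a `clone_tree`.
#' @return Newick string terminated by `;`.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  mean_ccf <- rowMeans(tree$ccf)
  rec <- function(l) {
    kids <- tree_children(tree, l)
    bl <- if (is.na(tree$parent[[l]])) 0 else
      max(mean_ccf[[tree$parent[[l]]]] - mean_ccf[[l]], 0)
    if (!length(kids)) return(sprintf("%s:%.4f", l, bl))
    sprintf("(%s)%s:%.4f", paste(vapply(kids, rec, character(1)),
                                 collapse = ","), l, bl)
  }
  paste0(rec(tree$labels[is.na(tree$parent)]), ";")
}

#' Serialise a clone tree to JSON
#'
#' @param tree a `clone_tree`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(
    nodes = tree$labels,
    parent = as.list(tree$parent),
    ccf = apply(tree$ccf, 1, as.list),
    n_mutations = as.list(tree$n_mutations),
    n_branching = tree$n_branching,
    class = tree$class,
    flags = tree$flags
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
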