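# Formats and per-patient pipeline orchestration. Coordinates are 1-based
# inclusive throughout; VCF ingestion converts accordingly.

MUTATION_COLS <- c("mutation_id", "chrom", "pos", "ref", "alt", "kind",
                   "sample", "depth", "alt_reads", "forward_alt",
                   "reverse_alt")
SEGMENT_COLS <- c("sample", "chrom", "start", "end", "major_cn", "minor_cn")

check_schema <- function(tab, cols, what, path) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(what, " table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a mutation table (TSV)
#'
#' Long format, one row per mutation/sample, columns as documented in
#' [read_inputs()]. Schema violations name the offending lines.
#'
#' @param path TSV file.
#' @return Mutation data.frame.
#' @export
read_mutation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mutation_id = "character",
                                          chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          kind = "character",
                                          sample = "character"))
  check_schema(tab, MUTATION_COLS, "mutation", path)
  bad <- which(tab$alt_reads > tab$depth | tab$alt_reads < 0)
  if (length(bad))
    stop("mutation table ", path, ": alt_reads outside [0, depth] at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  bad <- which(tab$forward_alt + tab$reverse_alt != tab$alt_reads)
  if (length(bad))
    stop("mutation table ", path,
         ": strand counts do not sum to alt_reads at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  tab
}

#' Read somatic mutations from a VCF
#'
#' Minimal VCF 4.x ingestion via the vcfR package (one sample per file):
#' uses per-genotype `DP` and `AD` fields for depth and variant reads and,
#' when present, `ADF`/`ADR` for strand counts (otherwise split evenly).
#'
#' @param path VCF file.
#' @param sample sample id to record.
#' @return Mutation data.frame in the package's long format.
#' @export
read_mutation_vcf <- function(path, sample) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  alt_reads <- as.integer(vapply(strsplit(ad, ","), `[`, character(1), 2))
  kind <- ifelse(nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1, "SNM",
                 ifelse(nchar(fix[, "REF"]) < nchar(fix[, "ALT"]),
                        "insertion", "deletion"))
  fwd <- tryCatch({
    adf <- vcfR::extract.gt(v, "ADF")[, 1]
    as.integer(vapply(strsplit(adf, ","), `[`, character(1), 2))
  }, error = function(e) floor(alt_reads / 2))
  if (all(is.na(fwd))) fwd <- floor(alt_reads / 2)
  data.frame(
    mutation_id = paste0(fix[, "CHROM"], ":", fix[, "POS"], "_",
                         fix[, "REF"], ">", fix[, "ALT"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], kind = kind, sample = sample,
    depth = dp, alt_reads = alt_reads, forward_alt = fwd,
    reverse_alt = alt_reads - fwd, fraction_lowmapq = 0,
    stringsAsFactors = FALSE
  )
}

#' Read an allele-specific segment table (SEG)
#'
#' Tab-separated with columns `sample`, `chrom`, `start`, `end`,
#' `major_cn`, `minor_cn` (1-based inclusive); overlap within a sample is
#' a validation error naming the lines.
#'
#' @param path TSV file.
#' @return Segment data.frame.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_schema(tab, SEGMENT_COLS, "segment", path)
  if (any(tab$major_cn < tab$minor_cn))
    stop("segment table ", path, ": major_cn < minor_cn")
  for (s in unique(tab$sample)) for (chr in unique(tab$chrom)) {
    ss <- tab[tab$sample == s & tab$chrom == chr, ]
    if (nrow(ss) < 2) next
    o <- order(ss$start)
    ov <- which(ss$start[o][-1] <= ss$end[o][-nrow(ss)])
    if (length(ov))
      stop("segment table ", path, ": overlapping segments for ", s, " on ",
           chr, " near line ", which(tab$sample == s & tab$chrom == chr)[o][ov[1] + 1] + 1L)
  }
  if (is.null(tab$subclonal_cn)) tab$subclonal_cn <- FALSE
  tab
}

#' Assemble a patient bundle from files
#'
#' @param mutation_path mutation TSV (long format; columns `mutation_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `kind`, `sample`, `depth`, `alt_reads`,
#'   `forward_alt`, `reverse_alt`, optional `normal_depth`,
#'   `fraction_lowmapq`, `context`, `gene`, `effect`).
#' @param segment_path SEG table.
#' @param purity_path TSV with `sample`, `purity`, `ploidy`.
#' @param patient patient id.
#' @param config threshold namespace.
#' @return A `patient_bundle`.
#' @export
read_inputs <- function(mutation_path, segment_path, purity_path,
                        patient = "patient", config = default_config()) {
  mut <- read_mutation_tsv(mutation_path)
  seg <- read_seg(segment_path)
  pur <- utils::read.delim(purity_path, stringsAsFactors = FALSE)
  check_schema(pur, c("sample", "purity"), "purity", purity_path)
  samples <- unique(mut$sample)
  miss <- setdiff(samples, pur$sample)
  if (length(miss)) stop("purity missing for sample(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(samples, unique(seg$sample))
  if (length(miss)) stop("segments missing for sample(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pur$sample)) stop("duplicate sample ids in purity table")
  structure(list(patient = patient, mutations = mut, segments = seg,
                 purity = pur, config = config),
            class = "patient_bundle")
}

#' Write a patient bundle to a directory
#'
#' Emits the same mutation TSV and SEG formats the pipeline reads, plus a
#' ground-truth JSON (tree, assignments, parameters) when the bundle came
#' from the simulator.
#'
#' @param bundle a `patient_bundle`.
#' @param dir output directory (created).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$purity, file.path(dir, "purity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(list(
      parent = as.list(tr$parent), ccf = apply(tr$ccf, 1, as.list),
      n_mutations = as.list(tr$n_mutations),
      mutation_assignment = as.list(tr$mutation_assignment),
      class = tr$class, samples = tr$samples, seed = tr$seed
    ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  }
  invisible(dir)
}

#' Read a bundle previously written by [write_bundle()]
#'
#' @param dir directory holding `mutations.tsv`, `segments.tsv`,
#'   `purity.tsv`.
#' @param patient patient id.
#' @param config threshold namespace.
#' @return A `patient_bundle` (ground truth, if present, is re-attached).
#' @export
read_bundle <- function(dir, patient = basename(dir),
                        config = default_config()) {
  b <- read_inputs(file.path(dir, "mutations.tsv"),
                   file.path(dir, "segments.tsv"),
                   file.path(dir, "purity.tsv"), patient, config)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    js <- jsonlite::read_json(gt_path)
    ccf <- do.call(rbind, lapply(js$ccf, function(r) unlist(r)))
    rownames(ccf) <- names(js$ccf)
    b$truth <- structure(list(
      parent = unlist(lapply(js$parent, function(x) x %||% NA_character_)),
      ccf = ccf,
      n_mutations = unlist(js$n_mutations),
      mutation_assignment = unlist(js$mutation_assignment),
      class = js$class, samples = unlist(js$samples), seed = js$seed
    ), class = "ground_truth")
  }
  b
}

# Consensus clustering across >2 samples: every pair is clustered in 2D;
# mutations are grouped by their tuple of per-pair cluster labels ("-"
# where a pair dropped the mutation, e.g. when it is absent from both of
# that pair's samples); groups of >= min_cluster mutations become clones
# with centre = per-sample mean CCF over the pairs carrying a value.
# Groups whose centres are indistinguishable at tolerance are merged.
cluster_consensus <- function(bundle, samples, config) {
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  pair_res <- lapply(pairs, function(pr) {
    flt <- apply_filters(bundle$mutations, bundle$segments, bundle$purity,
                         pr, config)
    cl <- cluster_pair(flt$ccf, flt$status, pr, config)
    list(pair = pr, filters = flt, clusters = cl)
  })
  lab_list <- lapply(pair_res, function(r) {
    a <- r$clusters$assignments
    stats::setNames(a$cluster, a$mutation_id)
  })
  ids <- sort(unique(unlist(lapply(lab_list, names))))

  # per-sample CCF per mutation, averaged over the pairs carrying a value
  ccf_env <- lapply(samples, function(s) {
    acc <- list()
    for (r in pair_res) {
      if (!s %in% r$pair) next
      col <- paste0("ccf_", s)
      acc[[length(acc) + 1L]] <- stats::setNames(r$filters$ccf[[col]],
                                                 r$filters$ccf$mutation_id)
    }
    acc
  })
  names(ccf_env) <- samples
  ccf_of <- function(id, s) {
    vals <- unlist(lapply(ccf_env[[s]], function(v) unname(v[id])))
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }
  ccf_mat <- vapply(samples, function(s)
    vapply(ids, ccf_of, numeric(1), s = s), numeric(length(ids)))
  dimnames(ccf_mat) <- list(ids, samples)
  # a mutation whose CCF is unknown in some sample (dropped from every pair
  # covering it) cannot be placed in k-dimensional CCF space
  complete <- rowSums(is.na(ccf_mat)) == 0
  ids <- ids[complete]
  ccf_mat <- ccf_mat[complete, , drop = FALSE]

  tuple <- vapply(ids, function(i) {
    paste(vapply(lab_list, function(l) {
      v <- l[i]
      if (is.na(names(v)) || is.na(v)) "-" else unname(v)
    }, character(1)), collapse = "/")
  }, character(1))
  groups <- split(ids, tuple)
  groups <- groups[vapply(groups, length, integer(1)) >= config$min_cluster]
  if (!length(groups)) stop("no consensus cluster reaches the size minimum")
  centres <- t(vapply(groups, function(g)
    colMeans(ccf_mat[g, , drop = FALSE]), numeric(length(samples))))

  # merge groups indistinguishable at tolerance
  merge_r <- config$eps * 1.5
  repeat {
    if (nrow(centres) < 2) break
    d <- as.matrix(stats::dist(centres))
    diag(d) <- Inf
    mn <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[mn[1], mn[2]] >= merge_r) break
    i <- mn[1]; j <- mn[2]
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    centres[i, ] <- (centres[i, ] * ni + centres[j, ] * nj) / (ni + nj)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups <- groups[-j]
    centres <- centres[-j, , drop = FALSE]
  }

  rownames(centres) <- sprintf("K%02d", seq_along(groups))
  colnames(centres) <- samples
  n_mut <- stats::setNames(vapply(groups, length, integer(1)),
                           rownames(centres))
  assignments <- data.frame(
    mutation_id = unlist(groups),
    cluster = rep(rownames(centres), vapply(groups, length, integer(1))),
    stringsAsFactors = FALSE
  )
  list(centres = centres, n_mutations = n_mut, assignments = assignments,
       pair_res = pair_res)
}

#' Run the full per-patient pipeline
#'
#' Filters, clusters and reconstructs the clone tree for a patient bundle.
#' Two samples are analysed by paired 2D clustering; more samples by
#' consensus over all pairs. Cluster centres conflicting with clonality
#' (CCF > 1 + eps) are re-evaluated at alternative mutation multiplicities
#' before reconstruction fails. Per-sample ploidy/WGD calls are always
#' reported; signature exposures are fitted when the mutation table
#' carries a `context` column and the subset sizes are eligible.
#'
#' @param bundle a `patient_bundle`.
#' @param config threshold namespace (defaults to the bundle's, else
#'   [default_config()]).
#' @param sigs optional signature matrix for exposure fitting (default:
#'   the synthetic bundled catalogue).
#' @return list of class `patient_result`: `tree`, `class`, `clusters`,
#'   `ccf`, `filter_report`, `ploidy`, `exposures`, `newick`, `pair` (the
#'   samples used), `summary` (one row: n_subclones,
#'   n_subclonal_mutations, class).
#' @export
run_patient <- function(bundle, config = NULL, sigs = NULL) {
  stopifnot(inherits(bundle, "patient_bundle"))
  config <- config %||% bundle$config %||% default_config()
  samples <- unique(bundle$mutations$sample)
  if (length(samples) < 2) stop("at least 2 samples required")

  if (length(samples) == 2) {
    flt <- apply_filters(bundle$mutations, bundle$segments, bundle$purity,
                         samples, config)
    cl <- cluster_pair(flt$ccf, flt$status, samples, config)
    centres <- as.matrix(cl$centres[, c("x", "y")])
    rownames(centres) <- cl$centres$cluster
    colnames(centres) <- samples
    n_mut <- stats::setNames(cl$centres$n, cl$centres$cluster)
    assignments <- cl$assignments
    filter_report <- flt$verdicts
    ccf_tab <- flt$ccf
  } else {
    cons <- cluster_consensus(bundle, samples, config)
    centres <- cons$centres
    colnames(centres) <- samples
    n_mut <- cons$n_mutations
    assignments <- cons$assignments
    filter_report <- do.call(rbind, lapply(cons$pair_res, function(r)
      cbind(pair = paste(r$pair, collapse = "-"), r$filters$verdicts)))
    ccf_tab <- NULL
    cl <- NULL
  }

  try_tree <- function(cen, nm) tryCatch(
    reconstruct_tree(cen, nm, eps = config$eps, samples = samples),
    clonearch_conflict = function(e) e
  )
  tree <- try_tree(centres, n_mut)
  if (inherits(tree, "clonearch_conflict")) {
    fix <- rescale_conflicting_clusters(centres, eps = config$eps)
    if (length(fix$rescaled)) {
      tree <- try_tree(fix$centres, n_mut)
      if (inherits(tree, "clone_tree"))
        tree$flags <- c(tree$flags, "multiplicity_reevaluated")
      centres <- fix$centres
    }
  }
  dropped <- character(0)
  while (inherits(tree, "clonearch_conflict") && nrow(centres) > 1) {
    # assignment debris: discard the smallest cluster and retry
    worst <- names(which.min(n_mut[rownames(centres)]))
    dropped <- c(dropped, worst)
    centres <- centres[rownames(centres) != worst, , drop = FALSE]
    n_mut <- n_mut[rownames(centres)]
    tree <- try_tree(centres, n_mut)
  }
  if (inherits(tree, "clonearch_conflict")) stop(tree)
  if (length(dropped))
    tree$flags <- c(tree$flags,
                    paste0("dropped_unplaceable:", paste(dropped, collapse = "+")))

  ploidy_tab <- do.call(rbind, lapply(samples, function(s) {
    call_ploidy(bundle$segments[bundle$segments$sample == s, ],
                bundle$purity$ploidy[bundle$purity$sample == s] %||% NA_real_,
                sample = s, ploidy_gate = config$ploidy_gate,
                wgd_intercept = config$wgd_intercept,
                wgd_slope = config$wgd_slope)
  }))

  exposures <- NULL
  if ("context" %in% names(bundle$mutations)) {
    sigs <- sigs %||% synthetic_sbs_catalogue()
    ok <- !is.na(assignments$cluster) &
      assignments$cluster %in% names(tree$cluster_map)
    clone_of <- stats::setNames(tree$cluster_map[assignments$cluster[ok]],
                                assignments$mutation_id[ok])
    meta <- bundle$mutations[!duplicated(bundle$mutations$mutation_id), ]
    meta <- meta[meta$mutation_id %in% names(clone_of), ]
    clonal_ids <- names(clone_of)[clone_of == "C0"]
    sub_ids <- setdiff(names(clone_of), clonal_ids)
    exposures <- list()
    for (part in list(list("clonal_C0", clonal_ids, "clonal"),
                      list("subclonal", sub_ids, "subclonal"))) {
      el <- eligibility(length(part[[2]]), part[[3]],
                        min_clonal = config$min_clonal_mut,
                        min_subclonal = config$min_subclonal_mut)
      if (el$fit) {
        cat96 <- build_catalogue(meta[meta$mutation_id %in% part[[2]], ])
        exposures[[part[[1]]]] <- fit_exposures(cat96, sigs)
      } else {
        exposures[[part[[1]]]] <- el$reason
      }
    }
  }

  n_sub <- length(tree$labels) - 1L
  n_sub_mut <- sum(tree$n_mutations[setdiff(tree$labels, "C0")])
  structure(list(
    patient = bundle$patient, pair = samples, tree = tree,
    class = tree$class, clusters = cl, assignments = assignments,
    ccf = ccf_tab, filter_report = filter_report, ploidy = ploidy_tab,
    exposures = exposures, newick = as_newick(tree),
    summary = data.frame(patient = bundle$patient,
                         n_subclones = n_sub,
                         n_subclonal_mutations = n_sub_mut,
                         class = tree$class, stringsAsFactors = FALSE)
  ), class = "patient_result")
}

#' Persist the results of a patient run
#'
#' Writes the CCF table, filter report, cluster assignments, tree (JSON
#' and Newick), ploidy report and exposure tables under `dir`.
#'
#' @param res a `patient_result`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_patient_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$ccf)) wt(res$ccf, "ccf.tsv")
  wt(res$filter_report, "filter_report.tsv")
  wt(res$assignments, "clusters.tsv")
  wt(res$ploidy, "ploidy.tsv")
  wt(res$summary, "summary.tsv")
  tree_to_json(res$tree, file.path(dir, "tree.json"))
  writeLines(res$newick, file.path(dir, "tree.nwk"))
  if (is.list(res$exposures)) {
    for (nm in names(res$exposures)) {
      e <- res$exposures[[nm]]
      if (inherits(e, "exposure_fit"))
        wt(data.frame(signature = names(e$exposures),
                      exposure = unname(e$exposures)),
           paste0("exposures_", nm, ".tsv"))
    }
  }
  invisible(dir)
}
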