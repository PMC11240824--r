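#' Agglomerative clustering of core features
#'
#' Hierarchical clustering of the core feature vectors with Euclidean
#' distance and Ward's linkage (`stats::hclust`, method `"ward.D2"`, whose
#' internal tie-break is deterministic across platforms). The full
#' agglomeration record (n - 1 merges with non-decreasing heights) is the
#' substrate for the merge-level / NML computation.
#'
#' @param fm A [feature_matrix()] with at least two rows.
#' @return Object of class `merge_tree`: the `hclust` fit plus aligned
#'   `core_id` / `patient_id` vectors and per-node `size` (leaf count) and
#'   `depth` (generations above the deepest leaf) tables.
#' @export
cluster_cores <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$features)
  if (n < 2) stop("clustering needs at least two cores")
  if (!all(is.finite(fm$features))) stop("non-finite feature values")
  hc <- stats::hclust(stats::dist(fm$features), method = "ward.D2")
  m <- hc$merge
  size <- integer(n - 1)
  depth <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    ch <- m[s, ]
    sz <- ifelse(ch < 0, 1L, size[pmax(ch, 1L)])
    dp <- ifelse(ch < 0, 0L, depth[pmax(ch, 1L)])
    size[s] <- sum(sz)
    depth[s] <- 1L + max(dp)
  }
  structure(list(hclust = hc, core_id = fm$core_id,
                 patient_id = fm$patient_id, variant = fm$variant,
                 size = size, depth = depth),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree %d leaves (%d patients), variant=%s>\n",
              length(x$core_id), length(unique(x$patient_id)), x$variant))
  invisible(x)
}

#' Linkage-record table of a merge tree
#'
#' One row per agglomeration step: children are coded hclust-style
#' (negative = leaf index into `tree$core_id`, positive = earlier step).
#'
#' @param tree A [cluster_cores()] result.
#' @return data.frame with columns step, child_a, child_b, height, size.
#' @export
as_linkage_table <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  data.frame(step = seq_along(tree$hclust$height),
             child_a = tree$hclust$merge[, 1],
             child_b = tree$hclust$merge[, 2],
             height = tree$hclust$height,
             size = tree$size)
}

#' Export a merge tree as Newick
#'
#' @param tree A `merge_tree`.
#' @param path Optional file path; when given the tree is written there.
#' @return Newick string (invisibly when written to file).
#' @export
export_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "merge_tree"))
  hc <- tree$hclust
  hc$labels <- tree$core_id
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut the dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; the study design sets `k` to the number
#' of patients to view the visual-ITH cluster structure. Labels follow
#' `stats::cutree`'s stable convention (order of appearance in the data).
#'
#' @param tree A `merge_tree`.
#' @param k_clusters Number of clusters, between 1 and the leaf count.
#' @return Named integer vector of cluster labels, names are core ids.
#' @export
cut_tree <- function(tree, k_clusters) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- length(tree$core_id)
  if (k_clusters < 1 || k_clusters > n) {
    stop("k_clusters must lie in [1, ", n, "]")
  }
  cl <- stats::cutree(tree$hclust, k = k_clusters)
  names(cl) <- tree$core_id
  cl
}

# ancestor chain of a leaf: ordered vector of step indices up to the root
ancestor_chain <- function(parent_leaf, parent_step, leaf) {
  s <- parent_leaf[leaf]
  chain <- integer(0)
  while (!is.na(s)) {
    chain <- c(chain, s)
    s <- parent_step[s]
  }
  chain
}

#' Merge level of a patient's cores
#'
#' Locates the lowest dendrogram node whose member set contains all of the
#' patient's cores (the containing node) by intersecting the leaves'
#' ancestor chains, and reports, per `definition`:
#' \describe{
#'   \item{`leaf_count`}{(default) the number of leaves under the
#'     containing node, so the level is at least the core count and a
#'     patient whose cores form a pure subtree scores the minimum;}
#'   \item{`step_index`}{the agglomeration step creating the node;}
#'   \item{`depth`}{the node's generation depth above its deepest leaf.}
#' }
#'
#' @param tree A `merge_tree`.
#' @param cores Character vector (>= 2) of the patient's core ids.
#' @param definition Merge-level definition; see above.
#' @return Single positive number.
#' @export
merge_level <- function(tree, cores,
                        definition = c("leaf_count", "step_index", "depth")) {
  stopifnot(inherits(tree, "merge_tree"))
  definition <- match.arg(definition)
  idx <- match(cores, tree$core_id)
  if (anyNA(idx)) {
    stop("unknown core_id: ", paste(cores[is.na(idx)], collapse = ", "))
  }
  if (length(idx) < 2) stop("merge level needs at least two cores")
  m <- tree$hclust$merge
  n <- length(tree$core_id)
  parent_leaf <- rep(NA_integer_, n)
  parent_step <- rep(NA_integer_, n - 1)
  for (s in seq_len(n - 1)) {
    for (ch in m[s, ]) {
      if (ch < 0) parent_leaf[-ch] <- s else parent_step[ch] <- s
    }
  }
  common <- ancestor_chain(parent_leaf, parent_step, idx[1])
  for (leaf in idx[-1]) {
    common <- intersect(common, ancestor_chain(parent_leaf, parent_step, leaf))
  }
  node <- min(common)  # lowest containing node (chains are step-increasing)
  switch(definition,
         leaf_count = tree$size[node],
         step_index = node,
         depth = tree$depth[node])
}

#' Normalized Merge Level
#'
#' The merge level divided by the patient's core count. Under the default
#' `leaf_count` merge-level definition NML >= 1, with equality exactly
#' when the patient's cores form a pure subtree (perfect visual
#' homogeneity); large values mean the cores only co-cluster inside a
#' much larger mixed group (visual heterogeneity).
#'
#' @param level Merge level (positive).
#' @param k Patient core count (>= 2).
#' @return `level / k`.
#' @export
nml_score <- function(level, k) {
  if (any(k < 2)) stop("NML is undefined for patients with fewer than 2 cores")
  if (any(!is.finite(level)) || any(level <= 0)) stop("invalid merge level")
  level / k
}

#' Per-patient NML table
#'
#' Computes merge level and NML for every patient represented in the tree.
#'
#' @param tree A `merge_tree`.
#' @param definition Merge-level definition, see [merge_level()].
#' @return data.frame: patient_id, k, merge_level, nml, variant.
#' @export
patient_nml <- function(tree, definition = "leaf_count") {
  stopifnot(inherits(tree, "merge_tree"))
  split_cores <- split(tree$core_id, tree$patient_id)
  split_cores <- split_cores[vapply(split_cores, length, integer(1)) >= 2]
  lev <- vapply(split_cores, function(cs) merge_level(tree, cs, definition),
                numeric(1))
  k <- vapply(split_cores, length, integer(1))
  data.frame(patient_id = names(split_cores), k = as.integer(k),
             merge_level = as.numeric(lev), nml = nml_score(lev, k),
             variant = tree$variant, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select the homogeneous/heterogeneous NML cutoff
#'
#' Estimates the NML density with a Gaussian kernel (Silverman's
#' rule-of-thumb bandwidth) and looks for an obvious bimodal pattern: at
#' least two local maxima whose height above the valley between the two
#' most prominent modes is at least `prominence` times the maximum
#' density. If found, the cutoff is the antimode (density minimum between
#' the two modes); otherwise it falls back to the sample median.
#'
#' @param nml_values Numeric vector of NML scores (>= 10 values).
#' @param method `"auto"` (default), or force `"antimode"` / `"median"`.
#' @param prominence Relative prominence threshold for a mode (default
#'   0.1).
#' @param bw Bandwidth rule passed to [stats::density()].
#' @return Object of class `ith_cutoff`: `method` (one actually used),
#'   `value`, and `diagnostics` (mode locations, bandwidth, valley).
#' @export
select_cutoff <- function(nml_values, method = c("auto", "antimode", "median"),
                          prominence = 0.1, bw = "nrd0") {
  method <- match.arg(method)
  nml_values <- nml_values[is.finite(nml_values)]
  if (length(nml_values) < 10) stop("cutoff selection needs >= 10 NML values")
  med <- stats::median(nml_values)
  if (stats::sd(nml_values) == 0) {
    warning("constant NML values; returning the (degenerate) median cutoff")
    return(structure(list(method = "median", value = med,
                          diagnostics = list(modes = med, bandwidth = NA_real_,
                                             valley = NA_real_)),
                     class = "ith_cutoff"))
  }
  den <- stats::density(nml_values, bw = bw)
  y <- den$y; x <- den$x
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k], FALSE)
  peaks <- which(is_max)
  diag_modes <- x[peaks]
  chosen <- "median"; value <- med; valley <- NA_real_
  if (method != "median" && length(peaks) >= 2) {
    top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
    lo <- min(top2); hi <- max(top2)
    between <- lo:hi
    v_idx <- between[which(y[between] == min(y[between]))]
    v_idx <- v_idx[ceiling(length(v_idx) / 2)]
    valley <- x[v_idx]
    prom <- (y[c(lo, hi)] - y[v_idx]) / max(y)
    if (all(prom >= prominence) || method == "antimode") {
      chosen <- "antimode"; value <- valley
    }
  } else if (method == "antimode") {
    warning("no second mode found; falling back to the median cutoff")
  }
  rng <- range(nml_values)
  value <- min(max(value, rng[1]), rng[2])
  structure(list(method = chosen, value = value,
                 diagnostics = list(modes = diag_modes, bandwidth = den$bw,
                                    valley = valley)),
            class = "ith_cutoff")
}

#' @export
print.ith_cutoff <- function(x, ...) {
  cat(sprintf("<ith_cutoff %s = %.4g (bw %.3g, %d mode(s))>\n", x$method,
              x$value, x$diagnostics$bandwidth, length(x$diagnostics$modes)))
  invisible(x)
}

#' Assign binary visual-ITH groups
#'
#' Patients with NML at or below the cutoff are labelled homogeneous (low
#' visual ITH); those above it heterogeneous (high visual ITH). A score
#' exactly at the cutoff is homogeneous: the low-ITH group is defined by
#' low scores and the boundary must be deterministic. The factor's first
#' level is "heterogeneous", the referent group of every downstream model.
#'
#' @param nml A [patient_nml()] table (or data.frame with `patient_id`,
#'   `nml`).
#' @param cutoff An [select_cutoff()] result or a plain number.
#' @return data.frame: patient_id, nml, ith_group (factor, levels
#'   heterogeneous < homogeneous).
#' @export
assign_groups <- function(nml, cutoff) {
  value <- if (inherits(cutoff, "ith_cutoff")) cutoff$value else as.numeric(cutoff)
  stopifnot(is.data.frame(nml), all(c("patient_id", "nml") %in% names(nml)))
  grp <- ifelse(nml$nml <= value, "homogeneous", "heterogeneous")
  data.frame(patient_id = nml$patient_id, nml = nml$nml,
             ith_group = factor(grp, levels = c("heterogeneous", "homogeneous")),
             stringsAsFactors = FALSE)
}
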