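# Independent oracles used across the suite.

# Brute-force merge level: scan the agglomeration records in order,
# materializing every cluster's member-leaf set, and stop at the first
# step whose member set contains all of the patient's cores. Independent
# of the ancestor-chain walk used by merge_level().
oracle_merge_level <- function(tree, cores,
                               definition = c("leaf_count", "step_index", "depth")) {
  definition <- match.arg(definition)
  m <- tree$hclust$merge
  n <- length(tree$core_id)
  idx <- match(cores, tree$core_id)
  stopifnot(!anyNA(idx))
  members <- vector("list", n - 1)
  depths <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    mem <- lapply(m[s, ], function(ch) if (ch < 0) -ch else members[[ch]])
    dps <- vapply(m[s, ], function(ch) if (ch < 0) 0L else depths[ch], integer(1))
    members[[s]] <- c(mem[[1]], mem[[2]])
    depths[s] <- 1L + max(dps)
    if (all(idx %in% members[[s]])) {
      return(switch(definition,
                    leaf_count = length(members[[s]]),
                    step_index = s,
                    depth = depths[s]))
    }
  }
  stop("containing node not found (corrupt tree)")
}

# Naive O(n^3) Ward agglomeration: at each step merge the pair of active
# clusters with the smallest increase in within-cluster sum of squares.
# Returns the sequence of merged member sets (sorted), for comparison
# with the hclust-based tree.
naive_ward_member_sequence <- function(X) {
  ess <- function(ids) {
    M <- X[ids, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  seqs <- list()
  while (length(clusters) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in 2:length(clusters)) {
      for (j in 1:(i - 1)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        dd <- ess(c(a, b)) - ess(a) - ess(b)
        if (dd < bestd) { bestd <- dd; best <- c(j, i) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    seqs[[length(seqs) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  seqs
}

# member sets of each hclust merge step (sorted leaf indices)
hclust_member_sequence <- function(hc) {
  m <- hc$merge
  members <- vector("list", nrow(m))
  for (s in seq_len(nrow(m))) {
    mem <- lapply(m[s, ], function(ch) if (ch < 0) -ch else members[[ch]])
    members[[s]] <- sort(c(mem[[1]], mem[[2]]))
  }
  members
}

# random feature matrix with random patient sizes (all >= 2)
random_feature_set <- function(n_patients, dim = 4, sizes = 2:4,
                               sd_within = 1, sd_between = 1) {
  k <- if (length(sizes) == 1) rep(sizes, n_patients) else
    sample(sizes, n_patients, replace = TRUE)
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), k)
  cid <- paste0(pid, "_C", unlist(lapply(k, seq_len)))
  centers <- matrix(rnorm(n_patients * dim, sd = sd_between), n_patients, dim)
  X <- centers[rep(seq_len(n_patients), k), , drop = FALSE] +
    matrix(rnorm(length(pid) * dim, sd = sd_within), length(pid), dim)
  feature_matrix(X, pid, cid)
}

# textured fake patch for filter/feature tests (never triggers detectors)
fake_patch <- function(bg_fraction = 0, side = 40, seed = NULL,
                       core_id = "T_C1") {
  if (!is.null(seed)) set.seed(seed)
  structure(list(patient_id = "T", core_id = core_id, variant = "original",
                 row0 = 0, col0 = 0,
                 pixels = array(runif(side * side * 3), c(side, side, 3)),
                 background_fraction = bg_fraction,
                 artifact_flags = character(0)),
            class = "core_patch")
}
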