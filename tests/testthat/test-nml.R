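# two tight, well-separated triplets: merge order is forced
two_triplets <- function(eps = 0.05) {
  X <- rbind(c(0, 0), c(eps, 0), c(0, eps),
             c(10, 10), c(10 + eps, 10), c(10, 10 + eps))
  feature_matrix(X, rep(c("PA", "PB"), each = 3),
                 c("PA_C1", "PA_C2", "PA_C3", "PB_C1", "PB_C2", "PB_C3"))
}

test_that("two cores merge in a single step", {
  fm <- feature_matrix(rbind(c(0, 0), c(1, 1)), c("P1", "P1"),
                       c("P1_C1", "P1_C2"))
  tree <- cluster_cores(fm)
  expect_equal(nrow(tree$hclust$merge), 1)
  expect_equal(merge_level(tree, c("P1_C1", "P1_C2")), 2)
  expect_equal(nml_score(2, 2), 1)
})

test_that("well-separated triplets agree with the naive Ward oracle", {
  fm <- two_triplets()
  tree <- cluster_cores(fm)
  members <- hclust_member_sequence(tree$hclust)
  # first four merges stay within a triplet
  for (s in 1:4) {
    expect_true(all(members[[s]] <= 3) || all(members[[s]] >= 4))
  }
  # full merge sequence equals the brute-force Ward agglomeration
  set.seed(20)
  for (rep in 1:5) {
    X <- matrix(rnorm(16), 8, 2)
    fmr <- feature_matrix(X, rep(sprintf("P%d", 1:4), each = 2),
                          sprintf("P%d_C%d", rep(1:4, each = 2), 1:2))
    hc <- cluster_cores(fmr)$hclust
    expect_identical(hclust_member_sequence(hc), naive_ward_member_sequence(X))
  }
  # duplicated rows merge at height zero
  dupfm <- feature_matrix(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)),
                          c("P1", "P1", "P2", "P2"),
                          sprintf("C%d", 1:4))
  expect_equal(min(cluster_cores(dupfm)$hclust$height), 0)
})

test_that("tree cuts behave at the extremes and refine monotonically", {
  set.seed(21)
  fm <- random_feature_set(6)
  tree <- cluster_cores(fm)
  n <- length(tree$core_id)
  expect_equal(length(unique(cut_tree(tree, n))), n)   # every core alone
  expect_equal(length(unique(cut_tree(tree, 1))), 1)   # one big cluster
  expect_error(cut_tree(tree, 0), "k_clusters")
  expect_error(cut_tree(tree, n + 1), "k_clusters")
  fm2 <- two_triplets()
  expect_equal(as.vector(sort(table(cut_tree(cluster_cores(fm2), 2)))),
               c(3L, 3L))
  # cut at k refines the cut at k-1
  k0 <- length(unique(fm$patient_id))
  for (k in c(k0, k0 + 1)) {
    fine <- cut_tree(tree, k)
    coarse <- cut_tree(tree, k - 1)
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
})

test_that("merge level matches the record-scan oracle on random trees", {
  set.seed(22)
  for (rep in 1:25) {
    fm <- random_feature_set(sample(3:8, 1), dim = 3)
    tree <- cluster_cores(fm)
    for (p in unique(fm$patient_id)) {
      cores <- fm$core_id[fm$patient_id == p]
      for (defn in c("leaf_count", "step_index", "depth")) {
        expect_equal(merge_level(tree, cores, defn),
                     oracle_merge_level(tree, cores, defn),
                     info = paste(rep, p, defn))
      }
    }
  }
  tree <- cluster_cores(two_triplets())
  expect_error(merge_level(tree, c("PA_C1", "nope")), "unknown core_id")
  expect_error(merge_level(tree, "PA_C1"), "at least two")
})

test_that("NML attains its extremes at pure subtrees and the root", {
  fm <- two_triplets()
  tree <- cluster_cores(fm)
  # pure subtree: merge level = k, NML = 1
  expect_equal(merge_level(tree, c("PA_C1", "PA_C2", "PA_C3")), 3)
  expect_equal(nml_score(3, 3), 1)
  # cores meeting only at the root: merge level = n leaves
  expect_equal(merge_level(tree, c("PA_C1", "PB_C1")), 6)
  expect_equal(nml_score(6, 3), 2)
  expect_error(nml_score(4, 1), "fewer than 2")
})

test_that("NML >= 1 with equality iff pure subtree; permutation invariant", {
  set.seed(23)
  for (rep in 1:10) {
    fm <- random_feature_set(6, dim = 4)
    # plant one patient as a tight remote cluster: must be a pure subtree
    planted <- fm$patient_id == "P001"
    fm$features[planted, ] <- matrix(rnorm(sum(planted) * 4, mean = 50,
                                           sd = 0.01), ncol = 4)
    tree <- cluster_cores(fm)
    tab <- patient_nml(tree)
    expect_true(all(tab$nml >= 1))
    expect_equal(tab$nml[tab$patient_id == "P001"], 1)
    # permutation invariance (distances almost surely distinct)
    perm <- sample(nrow(fm$features))
    fmp <- feature_matrix(fm$features[perm, ], fm$patient_id[perm],
                          fm$core_id[perm])
    tabp <- patient_nml(cluster_cores(fmp))
    expect_equal(tab[order(tab$patient_id), c("patient_id", "nml")],
                 tabp[order(tabp$patient_id), c("patient_id", "nml")],
                 ignore_attr = TRUE)
  }
})

test_that("raising one patient's spread does not lower their NML", {
  for (s in 1:3) {
    set.seed(30 + s)
    base <- random_feature_set(8, dim = 6, sd_within = 0.3, sd_between = 1)
    target <- "P004"
    rows <- base$patient_id == target
    centre <- colMeans(base$features[rows, , drop = FALSE])
    nml_at <- function(scale) {
      f <- base$features
      dev <- sweep(f[rows, , drop = FALSE], 2, centre)
      f[rows, ] <- sweep(dev * scale, 2, centre, `+`)
      tab <- patient_nml(cluster_cores(
        feature_matrix(f, base$patient_id, base$core_id)))
      tab$nml[tab$patient_id == target]
    }
    expect_gte(nml_at(8), nml_at(1))
  }
})

test_that("cutoff selection separates bimodal scores, else uses the median", {
  set.seed(24)
  for (rep in 1:5) {
    bim <- c(rnorm(100, 1, 0.1), rnorm(100, 5, 0.1))
    cut <- select_cutoff(bim)
    expect_equal(cut$method, "antimode")
    expect_gt(cut$value, 2)
    expect_lt(cut$value, 4)
    uni <- rnorm(200, 3, 0.5)
    cutu <- select_cutoff(uni)
    expect_equal(cutu$method, "median")
    expect_equal(cutu$value, median(uni))
  }
  expect_error(select_cutoff(rnorm(5)), ">= 10")
  expect_warning(cutc <- select_cutoff(rep(2, 20)), "constant")
  expect_equal(cutc$value, 2)
})

test_that("group assignment uses the documented boundary rule", {
  nml <- data.frame(patient_id = c("A", "B", "C"), nml = c(1.0, 3.75, 3.76))
  g <- assign_groups(nml, 3.75)
  expect_equal(as.character(g$ith_group),
               c("homogeneous", "homogeneous", "heterogeneous"))
  expect_equal(levels(g$ith_group), c("heterogeneous", "homogeneous"))
  # all below cutoff: everyone homogeneous
  g2 <- assign_groups(nml, 10)
  expect_true(all(g2$ith_group == "homogeneous"))
})

test_that("planted regimes are recovered at tenfold variance separation", {
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    cfg <- synthetic_config(n_patients = 60, feature_dim = 256,
                            sigma_within_low = 1, sigma_within_high = 10,
                            sigma_between = 1, seed = 40 + s)
    gf <- gen_features(cfg)
    tree <- cluster_cores(gf$features)
    tab <- patient_nml(tree)
    grp <- assign_groups(tab, select_cutoff(tab$nml))
    m <- merge(grp, gf$truth)
    hits <- hits + sum(as.character(m$ith_group) == m$regime)
    total <- total + nrow(m)
    # stochastic dominance of the heterogeneous regime's NML
    expect_gt(mean(m$nml[m$regime == "heterogeneous"]),
              mean(m$nml[m$regime == "homogeneous"]))
  }
  expect_gte(hits / total, 0.9)
})

test_that("merge trees serialize to linkage tables and Newick", {
  fm <- two_triplets()
  tree <- cluster_cores(fm)
  lt <- as_linkage_table(tree)
  expect_equal(nrow(lt), 5)
  expect_equal(lt$size[5], 6)
  expect_true(all(diff(lt$height) >= 0))
  nwk <- export_newick(tree)
  expect_match(nwk, "PA_C1")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, fm$core_id)
})
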