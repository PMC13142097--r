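make_test_ensemble <- function(n_members, n_res = 12, noise = 0.3, seed = 1) {
  set.seed(seed)
  base <- cbind(3.8 * seq_len(n_res), 0, 0) +
    matrix(rnorm(n_res * 3, 0, 0.2), ncol = 3)
  inst <- lapply(seq_len(n_members), function(i) {
    make_instance(seq_len(n_res),
                  base + matrix(rnorm(n_res * 3, 0, noise), ncol = 3),
                  id = sprintf("s%02d", i))
  })
  build_ensemble(inst)
}

test_that("identical members give a zero matrix; rigid copies stay at zero", {
  xyz <- cbind(3.8 * (1:10), 0, 0) + matrix(rnorm(30, 0, 0.3), ncol = 3)
  same <- lapply(1:3, function(i) make_instance(1:10, xyz, id = paste0("s", i)))
  m <- pairwise_rmsd_matrix(build_ensemble(same))
  expect_equal(m$values, matrix(0, 3, 3), ignore_attr = TRUE)

  moved <- make_instance(1:10, apply_rigid(xyz, rotation_about(c(1, 1, 0), 0.7),
                                           c(5, 5, 5)), id = "mv")
  pert <- make_instance(1:10, xyz + matrix(rnorm(30, 0, 0.5), ncol = 3),
                        id = "pt")
  m2 <- pairwise_rmsd_matrix(build_ensemble(list(same[[1]], moved, pert)))
  expect_lt(m2$values[1, 2], 1e-8)
  expect_gt(m2$values[1, 3], 0.1)
  expect_lt(abs(m2$values[1, 3] - m2$values[2, 3]), 1e-6)
})

test_that("matrix structure matches the all-pairs definition", {
  ens <- make_test_ensemble(20)
  m <- pairwise_rmsd_matrix(ens)
  expect_equal(sum(upper.tri(m$values)), 190L)  # 20 * 19 / 2
  expect_equal(m$values, t(m$values))
  expect_equal(diag(m$values), rep(0, 20), ignore_attr = TRUE)
  expect_equal(nrow(tidy(m)), 190L)
})

test_that("matrix rows/columns permute with member relabeling; profiles do not", {
  ens <- make_test_ensemble(6)
  m <- pairwise_rmsd_matrix(ens)
  p <- per_residue_avg_rmsd(ens)
  perm <- c(4, 2, 6, 1, 3, 5)
  ens2 <- build_ensemble(ens$members[perm])
  m2 <- pairwise_rmsd_matrix(ens2)
  expect_equal(m2$values, m$values[perm, perm], tolerance = 1e-12)
  p2 <- per_residue_avg_rmsd(ens2)
  expect_equal(p2$value, p$value, tolerance = 1e-12)
})

test_that("pair rmsd^2 is the residue-mean of squared per-pair deviations", {
  ens <- make_test_ensemble(4)
  m <- pairwise_rmsd_matrix(ens)
  for (pair in list(c(1, 2), c(2, 4), c(3, 4))) {
    f <- kabsch_superpose(ens$coords[, , pair[1]], ens$coords[, , pair[2]])
    expect_equal(m$values[pair[1], pair[2]]^2, mean(f$per_site_deviation^2),
                 tolerance = 1e-10)
  }
})

test_that("UPGMA reproduces the hand-computed 3-member merge history", {
  v <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- hierarchical_cluster(v, linkage = "average")
  expect_equal(sort(tree$hclust$height), c(1, 4))  # (4 + 4) / 2 = 4
  merges <- tidy(tree)
  expect_equal(nrow(merges), 2L)
  expect_equal(merges$members_a[1], "a")
  expect_equal(merges$members_b[1], "b")
  expect_true(all(diff(merges$height) >= 0))  # average linkage is monotone
})

test_that("clustering produces n-1 merges and valid flat cuts", {
  ens <- make_test_ensemble(8)
  tree <- hierarchical_cluster(pairwise_rmsd_matrix(ens))
  expect_equal(length(tree$hclust$height), 7L)
  expect_equal(length(unique(flat_clusters(tree, 1))), 1L)
  expect_equal(length(unique(flat_clusters(tree, 8))), 8L)
  expect_error(flat_clusters(tree, 0), class = "conflex_range_error")
  expect_error(flat_clusters(tree, 9), class = "conflex_range_error")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(hierarchical_cluster(bad), class = "conflex_invalid_distance")
})

test_that("two-block matrices are recovered exactly at k = 2", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 10
    truth <- rep(1:2, each = n / 2)
    v <- matrix(5 + rnorm(n * n, 0, 0.2), n, n)
    v[truth == 1, truth == 1] <- abs(rnorm(sum(truth == 1)^2, 0, 0.1))
    v[truth == 2, truth == 2] <- abs(rnorm(sum(truth == 2)^2, 0, 0.1))
    v <- (v + t(v)) / 2
    diag(v) <- 0
    dimnames(v) <- list(paste0("m", 1:n), paste0("m", 1:n))
    tree <- hierarchical_cluster(v)
    k2 <- flat_clusters(tree, 2)
    expect_equal(ari_oracle(k2[paste0("m", 1:n)], truth), 1.0)
  }
})

test_that("flat cuts are stable under input permutation up to relabeling", {
  ens <- make_test_ensemble(10, seed = 7)
  m <- pairwise_rmsd_matrix(ens)
  k3 <- flat_clusters(hierarchical_cluster(m), 3)
  perm <- sample(1:10)
  m2 <- pairwise_rmsd_matrix(build_ensemble(ens$members[perm]))
  k3b <- flat_clusters(hierarchical_cluster(m2), 3)
  expect_equal(ari_oracle(k3[sort(names(k3))], k3b[sort(names(k3b))]), 1.0)
})

test_that("inter-cluster distances aggregate cross-pair RMSDs", {
  labs <- c("a", "b", "c", "d")
  v <- matrix(0, 4, 4, dimnames = list(labs, labs))
  v["a", "c"] <- v["c", "a"] <- 4
  v["a", "d"] <- v["d", "a"] <- 6
  v["b", "c"] <- v["c", "b"] <- 4
  v["b", "d"] <- v["d", "b"] <- 6
  v["a", "b"] <- v["b", "a"] <- 0.1
  v["c", "d"] <- v["d", "c"] <- 0.1
  m <- structure(list(labels = labs, values = v), class = "rmsd_matrix")
  cl <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  icd <- inter_cluster_distance(m, cl)
  expect_equal(icd$distance, 5)  # mean of {4, 6, 4, 6}
  # two singletons: the pair distance itself
  m2 <- structure(list(labels = c("a", "b"),
                       values = matrix(c(0, 3, 3, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
                  class = "rmsd_matrix")
  expect_equal(inter_cluster_distance(m2, c(a = 1L, b = 2L))$distance, 3)
  expect_error(inter_cluster_distance(m, c(a = 1L, b = 1L, c = 1L, d = 1L)),
               class = "conflex_needs_two_clusters")
})

test_that("per-residue profile localizes a single displaced residue", {
  # identical 20-residue rigid core + one residue displaced by 2.0 A
  set.seed(11)
  core <- cbind(3.8 * (1:20), 0, 0) + matrix(rnorm(60, 0, 0.2), ncol = 3)
  xyz_a <- rbind(core, c(10, 10, 10))
  xyz_b <- rbind(core, c(10, 10, 12))  # +2.0 A in z at residue 21
  a <- make_instance(1:21, xyz_a, id = "a")
  b <- make_instance(1:21, xyz_b, id = "b")
  ens <- build_ensemble(list(a, b))
  prof <- per_residue_avg_rmsd(ens, fit_selection = 1:20)
  expect_equal(prof$value[21], 2.0, tolerance = 1e-8)
  expect_equal(prof$value[1:20], rep(0, 20), tolerance = 1e-8)
  # identical members -> all-zero profile
  ens0 <- build_ensemble(list(a, a))
  expect_equal(per_residue_avg_rmsd(ens0)$value, rep(0, 21), tolerance = 1e-10)
})

test_that("loop residues dominate the profile of a two-sigma ensemble", {
  set.seed(13)
  n_res <- 40
  base <- cbind(3.8 * seq_len(n_res), 0, 0)
  loop <- 15:21
  sigma <- ifelse(seq_len(n_res) %in% loop, 1.5, 0.05)
  inst <- lapply(1:8, function(i) {
    make_instance(seq_len(n_res),
                  base + matrix(rnorm(n_res * 3), ncol = 3) * sigma,
                  id = sprintf("s%02d", i))
  })
  prof <- per_residue_avg_rmsd(build_ensemble(inst))
  expect_gt(mean(prof$value[loop]), 5 * mean(prof$value[-loop]))
})

test_that("region calling follows strict thresholds, gaps and min_length", {
  prof <- new_residue_profile(c(115:130), rep(0.2, 16))
  prof$value[prof$resno %in% 119:125] <- 1.5
  regs <- call_regions(prof, 1.0)
  expect_equal(nrow(regs), 1L)
  expect_equal(c(regs$first, regs$last), c(119L, 125L))
  expect_equal(regs$peak, 1.5)

  # all below threshold -> empty
  expect_equal(nrow(call_regions(new_residue_profile(1:10, rep(0.5, 10)), 1.0)), 0L)

  # single-residue spikes respect min_length
  spike <- new_residue_profile(1:10, c(0, 0, 2, 0, 0, 2, 0, 0, 0, 0))
  expect_equal(nrow(call_regions(spike, 1.0, min_length = 2)), 0L)
  expect_equal(nrow(call_regions(spike, 1.0, min_length = 1)), 2L)

  # numbering gap breaks a run
  gap <- new_residue_profile(c(1:5, 8:12), rep(2, 10))
  regs2 <- call_regions(gap, 1.0)
  expect_equal(nrow(regs2), 2L)
  expect_equal(regs2$first, c(1L, 8L))

  # boundary equality is excluded (strict >)
  eq <- new_residue_profile(1:5, rep(1.0, 5))
  expect_equal(nrow(call_regions(eq, 1.0)), 0L)
  expect_error(call_regions(eq, -1), class = "conflex_bad_input")
})

test_that("mixing restrained and free members reproduces chain asymmetry", {
  spec <- synthetic_ensemble_spec(seed = 21)
  cs <- make_crystal_set(spec)
  res <- run_diversity(cs$structures, quiet = TRUE)
  labs <- res$matrix$labels
  a_members <- labs[grepl("_A_", labs)]
  b_members <- labs[grepl("_B_", labs)]
  within <- function(g) mean(res$matrix$values[g, g][upper.tri(diag(length(g)))])
  expect_gt(within(b_members), within(a_members))
})

test_that("Newick export preserves the tree topology", {
  ens <- make_test_ensemble(6)
  tree <- hierarchical_cluster(pairwise_rmsd_matrix(ens))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tree$labels)
  expect_equal(suppressWarnings(ape::dist.topo(phy, ape::as.phylo(tree$hclust))),
               0, ignore_attr = TRUE)
})
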