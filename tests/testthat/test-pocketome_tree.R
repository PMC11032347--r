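test_that("tiny instances give the textbook trees", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- minimum_spanning_tree(mst_from_matrix(d))
  expect_equal(nrow(tr$edges), 2L)
  expect_equal(tr$total_weight, 3)
  expect_setequal(paste(tr$edges$from, tr$edges$to),
                  c("a b", "a c"))
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- minimum_spanning_tree(mst_from_matrix(d2))
  expect_equal(nrow(tr2$edges), 1L)
  expect_equal(tr2$total_weight, 4)
})

test_that("tree weight matches igraph and beats random spanning trees", {
  set.seed(80)
  trees7 <- oracle_all_trees(7L)
  for (s in 1:10) {
    d <- random_distance_matrix(7, 8000 + s)
    tr <- minimum_spanning_tree(mst_from_matrix(d))
    expect_equal(nrow(tr$edges), 6L)
    ig <- igraph::mst(igraph::graph_from_adjacency_matrix(
      d, mode = "undirected", weighted = TRUE), algorithm = "prim")
    expect_equal(tr$total_weight, sum(igraph::E(ig)$weight), tolerance = 1e-9)
    # no random spanning tree does better
    some <- sample(length(trees7), 1000L)
    rand_w <- vapply(trees7[some], function(e) sum(d[e]), numeric(1))
    expect_true(all(tr$total_weight <= rand_w + 1e-12))
  }
})

test_that("the tree is invariant to row permutation up to relabeling", {
  set.seed(81)
  x <- matrix(rnorm(12 * 5), 12,
              dimnames = list(paste0("pk", 1:12), NULL))
  tr <- minimum_spanning_tree(pairwise_distances(x))
  perm <- sample(12)
  tr2 <- minimum_spanning_tree(pairwise_distances(x[perm, ]))
  expect_equal(tr2$total_weight, tr$total_weight, tolerance = 1e-12)
  key <- function(t) sort(paste(pmin(t$edges$from, t$edges$to),
                                pmax(t$edges$from, t$edges$to)))
  expect_identical(key(tr2), key(tr))
  # every edge's PSI is the kernel of its distance
  expect_equal(tr$edges$psi, psi(tr$edges$distance, tr$sigma),
               tolerance = 1e-12)
  bad <- mst_from_matrix(matrix(c(0, Inf, Inf, 0), 2))
  expect_error(minimum_spanning_tree(bad), "non-finite")
})

test_that("annotations attach verbatim, with NA for allowed missing nodes", {
  set.seed(82)
  x <- matrix(rnorm(10 * 4), 10, dimnames = list(paste0("pk", 1:10), NULL))
  tr <- minimum_spanning_tree(pairwise_distances(x))
  ann <- data.frame(pocket_id = paste0("pk", 1:9),
                    pfam_name = c("Bcl-2", rep("Pkinase", 8)),
                    volume = seq(100, 900, by = 100))
  expect_error(annotate_tree(tr, ann), "missing annotation")
  tr2 <- annotate_tree(tr, ann, allow_missing = TRUE)
  expect_equal(tr2$annotations$pfam_name[tr2$annotations$pocket_id == "pk1"],
               "Bcl-2")
  expect_true(is.na(tr2$annotations$pfam_name[
    tr2$annotations$pocket_id == "pk10"]))
  dup <- rbind(ann, ann[1, ])
  expect_error(annotate_tree(tr, dup, allow_missing = TRUE), "duplicate")
})

test_that("branch homogeneity counts same-label edges", {
  # path a-b-c-d constructed from collinear points
  x <- cbind(c(0, 1, 2, 3), 0)
  rownames(x) <- letters[1:4]
  tr <- minimum_spanning_tree(pairwise_distances(x))
  same <- annotate_tree(tr, data.frame(pocket_id = letters[1:4],
                                       grp = "one"))
  expect_equal(branch_homogeneity(same, "grp"), 1.0)
  alt <- annotate_tree(tr, data.frame(pocket_id = letters[1:4],
                                      grp = c("one", "two", "one", "two")))
  expect_equal(branch_homogeneity(alt, "grp"), 0.0)
  expect_error(branch_homogeneity(alt, "nope"), "not found")
  # planted clusters: recount the matching edges by hand
  ds <- make_descriptor_sample(descriptor_sample_spec(seed = 83))
  pp <- descriptor_pipeline(ds$matrix)
  trc <- minimum_spanning_tree(pairwise_distances(pp$matrix))
  trc <- annotate_tree(trc, data.frame(pocket_id = rownames(ds$matrix),
                                       cluster = ds$labels))
  lab <- setNames(ds$labels, rownames(ds$matrix))
  manual <- mean(lab[trc$edges$from] == lab[trc$edges$to])
  expect_equal(branch_homogeneity(trc, "cluster"), manual)
})

test_that("homogeneity does not decrease with cluster separation", {
  h <- vapply(c(0, 2, 4, 6), function(sep) {
    ds <- make_descriptor_sample(descriptor_sample_spec(
      n_pockets = 60, n_descriptors = 10, n_clusters = 2,
      cluster_separation = sep, noise_sd = 1, seed = 84))
    pp <- descriptor_pipeline(ds$matrix)
    tr <- minimum_spanning_tree(pairwise_distances(pp$matrix))
    tr <- annotate_tree(tr, data.frame(pocket_id = rownames(ds$matrix),
                                       cluster = ds$labels))
    branch_homogeneity(tr, "cluster")
  }, numeric(1))
  expect_true(all(diff(h) >= -1e-12))
})

test_that("GraphML export round trips structure and annotations", {
  set.seed(85)
  x <- matrix(rnorm(10 * 4), 10, dimnames = list(paste0("pk", 1:10), NULL))
  tr <- minimum_spanning_tree(pairwise_distances(x))
  tr <- annotate_tree(tr, data.frame(pocket_id = paste0("pk", 1:10),
                                     subset = rep(c("HD", "PLOC"), 5),
                                     volume = 1:10 * 10))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_tree(tr, f, "graphml")
  tr2 <- read_tree_graphml(f)
  expect_setequal(tr2$nodes, tr$nodes)
  expect_equal(nrow(tr2$edges), 9L)
  expect_equal(tr2$total_weight, tr$total_weight, tolerance = 1e-6)
  key <- function(t) sort(paste(pmin(t$edges$from, t$edges$to),
                                pmax(t$edges$from, t$edges$to)))
  expect_identical(key(tr2), key(tr))
  ann2 <- tr2$annotations[match(tr$annotations$pocket_id,
                                tr2$annotations$pocket_id), ]
  expect_equal(ann2$subset, tr$annotations$subset)
  expect_equal(ann2$volume, tr$annotations$volume, tolerance = 1e-6)
  expect_error(export_tree(tr, f, "dot"), "arg")
})

test_that("HTML export is self-contained", {
  set.seed(86)
  x <- matrix(rnorm(8 * 3), 8, dimnames = list(paste0("pk", 1:8), NULL))
  tr <- minimum_spanning_tree(pairwise_distances(x))
  tr <- annotate_tree(tr, data.frame(pocket_id = paste0("pk", 1:8),
                                     subset = "HD", volume = 1:8))
  f <- withr::local_tempfile(fileext = ".html")
  export_tree(tr, f, "html")
  html <- readLines(f)
  expect_true(any(grepl("pocket_id", html)))
  # no external fetches: no src/href pointing at a URL
  expect_false(any(grepl("(src|href)\\s*=\\s*[\"']https?://", html)))
  expect_false(any(grepl("<script[^>]+src", html)))
  expect_false(any(grepl("<link", html)))
})
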