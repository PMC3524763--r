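chain_sweep <- function() {
  as_kmodes_sweep(list(
    as_kmodes_config(list(c(1, 3), 5, 7), k = 4),
    as_kmodes_config(list(c(1, 3, 5), 7), k = 3),
    as_kmodes_config(list(c(1, 3, 5, 7)), k = 2)))
}

merge_sweep <- function() {
  # two disjoint chains converging at one node
  as_kmodes_sweep(list(
    as_kmodes_config(list(c(1, 2), c(5, 6), 3, 7), k = 4),
    as_kmodes_config(list(c(1, 2, 3), c(5, 6, 7)), k = 3),
    as_kmodes_config(list(c(1, 2, 3, 5, 6, 7)), k = 2)))
}

test_that("nested clusters form a single three-cluster branch", {
  tree <- build_cluster_tree(chain_sweep())
  expect_length(tree$branches, 1)
  chain_orders <- tree$nodes$order[match(tree$branches[[1]],
                                         tree$nodes$node)]
  expect_equal(chain_orders, c(2, 3, 4))
  expect_equal(nrow(tree$edges), 2)
  expect_equal(tree$branch_types$type, "I")
})

test_that("two disjoint chains merging produce one node and one module", {
  tree <- build_cluster_tree(merge_sweep())
  expect_length(tree$branches, 2)
  shared <- intersect(tree$branches[[1]], tree$branches[[2]])
  expect_length(shared, 1)   # the merged order-6 cluster
  expect_equal(tree$nodes$order[tree$nodes$node == shared], 6)
  expect_equal(tree$modules$module, c(1, 1))
  expect_equal(unique(tree$modules$kind), "converging")
  # convergence alone is not interlacing
  expect_equal(tree$branch_types$type, c("I", "I"))
})

test_that("branches sharing sites without converging are Type II", {
  sweep <- as_kmodes_sweep(list(
    as_kmodes_config(list(c(1, 2), c(3, 4), 5), k = 3),
    as_kmodes_config(list(c(1, 2, 3), c(4, 5)), k = 2)))
  tree <- build_cluster_tree(sweep)
  # every chain's exclusive clusters share site 3 or 4 with another chain
  expect_true(all(tree$branch_types$type == "II"))
  expect_gte(length(tree$branches), 2)
})

test_that("mutually interlacing chains with no common parent form a declared module", {
  sweep <- as_kmodes_sweep(list(
    as_kmodes_config(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)), k = 3),
    as_kmodes_config(list(c(1, 2, 3, 4, 5), c(6, 7, 8, 9), c(2, 3, 10, 11)),
                     k = 30)))
  # three order-3 roots, each straddling another's higher-order cluster
  tree <- build_cluster_tree(sweep)
  expect_gte(sum(tree$branch_types$type == "II"), 2)
  expect_equal(nrow(tree$edges), 0)   # nothing converges
  grouped <- tree$modules[!is.na(tree$modules$module), ]
  expect_gte(nrow(grouped), 2)
  expect_true(all(grouped$kind == "interlaced"))
})

test_that("independent chains yield no multi-branch modules", {
  sweep <- as_kmodes_sweep(list(
    as_kmodes_config(list(c(1, 2), c(5, 6)), k = 3),
    as_kmodes_config(list(c(1, 2, 3), c(5, 6, 7)), k = 2)))
  tree <- build_cluster_tree(sweep)
  expect_true(all(is.na(tree$modules$module)))
  expect_equal(tree$branch_types$type, c("I", "I"))
})

test_that("every nesting edge satisfies the majority-containment rule", {
  sim <- simulate_msa(100, 14, blocks = list(1:4, 5:8, 9:12), rho = 0.85,
                      hierarchy = list(c(1, 2)), rho2 = 0.5, seed = 55)
  rm <- redundancy_matrix(sim$aln)
  sw <- sweep_k(rm, seed = 9, restarts = 2)
  tree <- build_cluster_tree(sw)
  ks <- sort(sw$k_values, decreasing = TRUE)
  for (i in seq_len(nrow(tree$edges))) {
    child <- tree$nodes[tree$nodes$node == tree$edges$child[i], ]
    parent <- tree$nodes[tree$nodes$node == tree$edges$parent[i], ]
    ov <- length(intersect(child$sites[[1]], parent$sites[[1]]))
    expect_gt(ov, child$order / 2)
    expect_gt(parent$order, child$order)
    # parent lives in the configuration at the next k below the child's last
    k_next <- ks[ks < child$k_last][1]
    cfg <- sw$configs[[as.character(k_next)]]
    expect_true(any(sapply(cfg$clusters, function(cl) {
      setequal(cl, parent$sites[[1]])
    })))
    # and has maximal overlap there among qualifying clusters
    ovs <- sapply(cfg$clusters, function(cl) {
      length(intersect(child$sites[[1]], cl))
    })
    expect_equal(ov, max(ovs))
  }
  # acyclic by construction: orders strictly increase along edges; and every
  # distinct cluster of the sweep appears exactly once as a node
  keys <- unique(unlist(lapply(sw$configs, function(cfg) {
    sapply(cfg$clusters, function(cl) paste(sort(cl), collapse = ","))
  })))
  expect_equal(sort(tree$nodes$key), sort(keys))
})

test_that("a planted merge schedule is recovered edge for edge", {
  sim <- simulate_msa(50, 12, blocks = list(1:3, 4:6, 7:9, 10:12),
                      hierarchy = list(c(1, 2), c(3, 4)), seed = 6)
  sweep <- truth_sweep(sim$truth)
  tree <- build_cluster_tree(sweep)
  find_node <- function(sites) {
    tree$nodes$node[sapply(tree$nodes$sites, setequal, sites)]
  }
  expected_edges <- list(list(child = 1:3, parent = 1:6),
                         list(child = 4:6, parent = 1:6),
                         list(child = 7:9, parent = 7:12),
                         list(child = 10:12, parent = 7:12))
  for (e in expected_edges) {
    expect_true(any(tree$edges$child == find_node(e$child) &
                      tree$edges$parent == find_node(e$parent)))
  }
  expect_equal(nrow(tree$edges), 4)
})

test_that("representative selection prefers higher order only within tolerance", {
  nodes <- tibble::tibble(
    node = 1:5,
    sites = list(c(1, 2, 3, 4), c(1, 2, 3, 4, 5, 6), c(7, 8, 9),
                 c(7, 8, 9, 10, 11), c(20, 21)),
    order = c(4, 6, 3, 5, 2),
    mode = c(1, 1, 7, 7, 20),
    sr_mode = c(0.26, 0.20, 0.25, 0.245, 0.4))
  tree <- structure(list(nodes = nodes,
                         branches = list(c(1, 2), c(3, 4), 5),
                         rep_tolerance = 0.05),
                    class = "cluster_tree")
  reps <- select_representative(tree, tolerance = 0.05)
  # 0.20 is >5% below 0.26: the order-4 cluster wins
  expect_equal(reps$node[reps$branch == 1], 1)
  # 0.245 is within 5% of 0.25: the order-5 cluster wins
  expect_equal(reps$node[reps$branch == 2], 4)
  # single-cluster branch: that cluster
  expect_equal(reps$node[reps$branch == 3], 5)
})

test_that("tree tidiers and DOT export cover all clusters", {
  tree <- build_cluster_tree(merge_sweep())
  td <- tidy(tree)
  expect_equal(nrow(td), nrow(tree$nodes))
  expect_true(all(c("order", "branch", "representative") %in% names(td)))
  gl <- glance(tree)
  expect_equal(gl$n_branches, 2)
  path <- withr::local_tempfile(fileext = ".dot")
  export_tree_dot(tree, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("label=", lines)), nrow(tree$nodes))
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), nrow(tree$edges))
})
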