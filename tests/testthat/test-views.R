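test_that("the initial view is the root alone with no edges", {
  ex <- running_example()
  v0 <- initial_view(ex$tree, ex$idx)
  expect_equal(v0$meta_nodes, "root")
  expect_length(v0$atomic_nodes, 0L)
  expect_equal(nrow(v0$edges), 0L)
  expect_frontier_partition(v0, ex$tree, ex$net)
})

test_that("expanding the root shows the level-1 communities", {
  ex <- running_example()
  v1 <- level1_view(ex$tree, ex$idx, ex$ic, ex$net)
  expect_setequal(v1$meta_nodes, c("C1", "C4"))
  expect_equal(v1$edges$family, "cc")
  expect_equal(nrow(v1$edges), 1L)
  expect_frontier_partition(v1, ex$tree, ex$net)
})

test_that("expanding C4 reveals exactly the relations C5-C1, C7-C1, C5-C6", {
  ex <- running_example()
  v1 <- level1_view(ex$tree, ex$idx, ex$ic, ex$net)
  v2 <- zoom_in(v1, "C4", ex$tree, ex$idx, ex$ic, ex$net)
  expect_setequal(v2$meta_nodes, c("C1", "C5", "C6", "C7"))
  got <- sort(paste(v2$edges$u, v2$edges$v))
  expect_equal(v2$edges$family, rep("cc", 3L))
  expect_setequal(paste(v2$edges$u, v2$edges$v),
                  c("C1 C5", "C1 C7", "C5 C6"))
})

test_that("expanding the leaf C7 yields atomic proteins with mixed edge families", {
  ex <- running_example()
  v1 <- level1_view(ex$tree, ex$idx, ex$ic, ex$net)
  v2 <- zoom_in(v1, "C4", ex$tree, ex$idx, ex$ic, ex$net)
  v3 <- zoom_in(v2, "C7", ex$tree, ex$idx, ex$ic, ex$net)
  expect_setequal(v3$atomic_nodes, c("DET1", "SOC1", "SPY"))
  expect_setequal(v3$meta_nodes, c("C1", "C5", "C6"))
  pp <- v3$edges[v3$edges$family == "pp", ]
  expect_setequal(paste(pp$u, pp$v), c("DET1 SOC1", "SOC1 SPY"))
  pc <- v3$edges[v3$edges$family == "pc", ]
  expect_equal(paste(pc$u, pc$v), "DET1 C1")
  expect_equal(v3$edges, oracle_view_edges(v3, ex$tree, ex$idx, ex$net))
})

test_that("zooming out on a protein or sibling community walks back up", {
  ex <- running_example()
  v1 <- level1_view(ex$tree, ex$idx, ex$ic, ex$net)
  v2 <- zoom_in(v1, "C4", ex$tree, ex$idx, ex$ic, ex$net)
  v3 <- zoom_in(v2, "C7", ex$tree, ex$idx, ex$ic, ex$net)
  back2 <- zoom_out(v3, "SOC1", ex$tree, ex$idx)
  expect_equal(back2, v2, ignore_attr = TRUE)
  for (c in c("C5", "C6", "C7")) {
    expect_equal(zoom_out(v2, c, ex$tree, ex$idx), v1, ignore_attr = TRUE)
  }
})

test_that("zoom preconditions are enforced", {
  ex <- running_example()
  v1 <- level1_view(ex$tree, ex$idx, ex$ic, ex$net)
  expect_error(zoom_in(v1, "C7", ex$tree, ex$idx, ex$ic, ex$net),
               "not a meta-node")
  expect_error(zoom_out(v1, "root", ex$tree, ex$idx), "root")
  expect_error(zoom_out(v1, "ghost", ex$tree, ex$idx), "not present")
  # collapsing a community whose sibling is expanded must be refused
  v2 <- zoom_in(v1, "C4", ex$tree, ex$idx, ex$ic, ex$net)
  v3 <- zoom_in(v2, "C7", ex$tree, ex$idx, ex$ic, ex$net)
  expect_error(zoom_out(v3, "C5", ex$tree, ex$idx), "collapse them first")
})

test_that("the root-to-leaf path of a protein lists its nested communities", {
  ex <- running_example()
  expect_equal(path_to_node("DET1", ex$tree, ex$idx), c("root", "C4", "C7"))
  expect_equal(path_to_node("A1", ex$tree, ex$idx), c("root", "C1"))
  p <- path_to_node("M2", ex$tree, ex$idx)
  expect_equal(p[1], ex$tree$root)
  expect_equal(p[length(p)], class_of("M2", ex$idx))
  for (i in seq_len(length(p) - 1L)) {
    expect_equal(parent_of(p[i + 1L], ex$tree), p[i])
  }
  expect_error(path_to_node("ghost", ex$tree, ex$idx), "unknown node")
})

test_that("meta-edge statistics summarize the underlying weight multiset", {
  idxnet <- list()
  tree <- community_tree_from_list(list(
    id = "r",
    children = list(list(id = "L1", members = c("a", "b", "c")),
                    list(id = "L2", members = c("x", "y", "z")))
  ))
  idx <- assign_tree_indexes(tree)
  net <- protein_network(data.frame(
    u = c("a", "b", "c", "a"),
    v = c("x", "y", "z", "b"),
    w = c(0.2, 0.4, 0.6, 1)
  ))
  ic <- build_relation_index(tree, idx, net)
  v1 <- level1_view(tree, idx, ic, net)
  s <- meta_edge_stats(v1, "L1", "L2", tree, idx, net)
  expect_equal(s$count, 3L)
  expect_equal(s$min_w, 0.2)
  expect_equal(s$max_w, 0.6)
  expect_equal(s$mean_w, 0.4)
  # protein-protein edge: singleton multiset
  v2 <- zoom_in(v1, "L1", tree, idx, ic, net)
  sp <- meta_edge_stats(v2, "a", "b", tree, idx, net)
  expect_equal(sp$count, 1L)
  expect_equal(sp$min_w, 1)
  expect_equal(sp$mean_w, 1)
  expect_error(meta_edge_stats(v2, "a", "c", tree, idx, net), "absent")
})

test_that("edge counts are conserved when a meta-node is expanded", {
  for (s in 1:5) {
    inst <- random_instance(n = 30L, p = 0.2, max_levels = 3L, seed = s + 40L)
    v1 <- level1_view(inst$tree, inst$idx, inst$ic, inst$net)
    total_under <- function(view) {
      hidden <- sum(vapply(view$meta_nodes, function(m) {
        network_size(induced_subnetwork(inst$net,
                                        community_members(inst$tree, m)))
      }, numeric(1)))
      shown <- 0L
      if (nrow(view$edges)) {
        shown <- sum(vapply(seq_len(nrow(view$edges)), function(i) {
          meta_edge_stats(view, view$edges$u[i], view$edges$v[i],
                          inst$tree, inst$idx, inst$net)$count
        }, numeric(1)))
      }
      hidden + shown
    }
    expect_equal(total_under(v1), network_size(inst$net))
    expandable <- v1$meta_nodes[vapply(v1$meta_nodes, function(m)
      length(community_children(inst$tree, m)) > 0, logical(1))]
    if (length(expandable)) {
      v2 <- zoom_in(v1, expandable[1], inst$tree, inst$idx, inst$ic, inst$net)
      expect_equal(total_under(v2), network_size(inst$net))
    }
  }
})

test_that("zoom_in inspects each underlying edge at most once", {
  inst <- random_instance(n = 30L, p = 0.25, max_levels = 3L, seed = 123L)
  v1 <- level1_view(inst$tree, inst$idx, inst$ic, inst$net)
  expect_lte(attr(v1, "edges_inspected"), network_size(inst$net))
  for (m in v1$meta_nodes) {
    v2 <- zoom_in(v1, m, inst$tree, inst$idx, inst$ic, inst$net)
    expect_lte(attr(v2, "edges_inspected"), network_size(inst$net))
  }
})

test_that("view JSON is deterministic and carries sizes, leaves and stats", {
  ex <- running_example()
  v1 <- zoom_in(level1_view(ex$tree, ex$idx, ex$ic, ex$net), "C4",
                ex$tree, ex$idx, ex$ic, ex$net)
  v2 <- zoom_in(v1, "C7", ex$tree, ex$idx, ex$ic, ex$net)
  j1 <- view_to_json(v2, ex$tree, ex$idx, net = ex$net,
                     scores = c(DET1 = 0.9))
  j2 <- view_to_json(v2, ex$tree, ex$idx, net = ex$net,
                     scores = c(DET1 = 0.9))
  expect_identical(as.character(j1), as.character(j2))
  parsed <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  expect_equal(parsed$meta_nodes[[1]]$id, "C1")
  atom_ids <- vapply(parsed$atomic_nodes, `[[`, character(1), "id")
  expect_true("DET1" %in% atom_ids)
  det <- parsed$atomic_nodes[[which(atom_ids == "DET1")]]
  expect_equal(det$leaf, "C7")
  expect_equal(det$score, 0.9)
  expect_true(all(vapply(parsed$edges, function(e) e$stats$count >= 1,
                         logical(1))))
})
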