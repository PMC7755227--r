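toy_tree <- function() {
  community_tree_from_list(list(
    id = "root",
    children = list(
      list(id = "A", children = list(
        list(id = "A1", members = c("u1", "u2")),
        list(id = "A2", members = c("u3"))
      )),
      list(id = "B", members = c("u4", "u5"))
    )
  ))
}

test_that("pre/post labels follow the depth-first visit in stored child order", {
  idx <- assign_tree_indexes(toy_tree())
  expect_equal(idx$pre[c("root", "A", "A1", "A2", "B")],
               c(root = 1L, A = 2L, A1 = 3L, A2 = 4L, B = 5L))
  expect_equal(idx$post[c("A1", "A2", "A", "B", "root")],
               c(A1 = 1L, A2 = 2L, A = 3L, B = 4L, root = 5L))
  expect_equal(sort(unname(idx$pre)), 1:5)
  expect_equal(sort(unname(idx$post)), 1:5)
})

test_that("a root-only tree gets pre = post = 1", {
  tree <- community_tree_from_list(list(id = "solo", members = c("x")))
  idx <- assign_tree_indexes(tree)
  expect_equal(unname(idx$pre["solo"]), 1L)
  expect_equal(unname(idx$post["solo"]), 1L)
  expect_equal(class_of("x", idx), "solo")
})

test_that("sorting by pre is a topological order (parents before children)", {
  set.seed(20)
  for (rep in 1:10) {
    tree <- random_tree(sprintf("n%02d", 1:30), max_levels = 4L)
    idx <- assign_tree_indexes(tree)
    for (id in names(tree$communities)) {
      p <- parent_of(id, tree)
      if (!is.na(p)) expect_lt(idx$pre[p], idx$pre[id])
    }
  }
})

test_that("interval predicates match path-walking and set oracles exhaustively", {
  set.seed(77)
  sizes <- c(40L, 120L, 200L)
  for (target in sizes) {
    # grow node sets until the tree is reasonably large, capped by target
    nodes <- sprintf("n%04d", seq_len(target * 2L))
    tree <- random_tree(nodes, max_levels = 5L)
    idx <- assign_tree_indexes(tree)
    ids <- names(tree$communities)
    anc <- lapply(setNames(ids, ids), function(c) c(c, tree_ancestors(tree, c)))
    mem <- lapply(setNames(ids, ids),
                  function(c) tree$communities[[c]]$members)
    for (c1 in ids) {
      for (c2 in ids) {
        expect_identical(is_descendant(c1, c2, idx), c2 %in% anc[[c1]])
        if (c1 < c2) {
          expect_identical(are_disjoint(c1, c2, idx),
                           length(intersect(mem[[c1]], mem[[c2]])) == 0L)
        }
      }
    }
    # membership predicate against explicit member lookup, sampled nodes
    some_nodes <- sample(nodes, 12L)
    for (v in some_nodes) {
      for (c2 in ids) {
        expect_identical(member_of(v, c2, idx), v %in% mem[[c2]])
      }
    }
    expect_true(all(vapply(nodes, function(v) {
      v %in% mem[[class_of(v, idx)]]
    }, logical(1))))
  }
})

test_that("descendant is reflexive and unknown ids are rejected", {
  idx <- assign_tree_indexes(toy_tree())
  expect_true(is_descendant("A", "A", idx))
  expect_true(is_descendant("A1", "A", idx))
  expect_false(is_descendant("A", "A1", idx))
  expect_false(is_descendant("A", "B", idx))
  expect_true(are_disjoint("A", "B", idx))
  expect_false(are_disjoint("A1", "A", idx))
  expect_error(is_descendant("A", "nope", idx), "unknown community")
  expect_error(class_of("ghost", idx), "unknown node")
})

test_that("parent_of walks up and the leaf class sits below every containing community", {
  tree <- toy_tree()
  idx <- assign_tree_indexes(tree)
  expect_equal(parent_of("A1", tree), "A")
  expect_true(is.na(parent_of("root", tree)))
  for (v in c("u1", "u3", "u4")) {
    cls <- class_of(v, idx)
    p <- parent_of(cls, tree)
    while (!is.na(p)) {
      expect_true(member_of(v, p, idx))
      p <- parent_of(p, tree)
    }
  }
})

test_that("relation index keeps only edge-witnessed disjoint pairs (running example)", {
  ex <- running_example()
  keys <- relation_index_keys(ex$ic)
  has <- function(a, b) paste(sort(c(a, b)), collapse = "\r") %in%
    c(keys$leaf, keys$upper)
  expect_true(has("C5", "C1"))
  expect_true(has("C7", "C1"))
  expect_true(has("C5", "C6"))
  expect_false(has("C6", "C1"))
  expect_false(has("C6", "C7"))
  expect_false(has("C5", "C7"))
  # the ancestor pair C4--C1 is witnessed through its children
  expect_true(has("C4", "C1"))
})

test_that("edges internal to leaves contribute nothing to the relation index", {
  tree <- toy_tree()
  idx <- assign_tree_indexes(tree)
  net <- protein_network(data.frame(u = c("u1", "u4"), v = c("u2", "u5"), w = 1),
                         nodes = paste0("u", 1:5))
  ic <- build_relation_index(tree, idx, net)
  expect_equal(nrow(ic$leaf_edges), 0L)
  expect_equal(nrow(ic$upper_edges), 0L)
})

test_that("relation index equals the brute-force index on random instances", {
  for (s in 1:25) {
    inst <- random_instance(n = 25L, p = 0.15, max_levels = 3L, seed = s)
    got <- relation_index_keys(inst$ic)
    want <- oracle_relation_index(inst$tree, inst$net)
    expect_identical(got$leaf, want$leaf)
    expect_identical(got$upper, want$upper)
  }
})

test_that("index construction respects the O(|E| + |V_C|^2) inspection budget", {
  inst <- random_instance(n = 40L, p = 0.2, max_levels = 4L, seed = 99L)
  expect_identical(inst$ic$edge_inspections, nrow(inst$net$edges))
  expect_lte(inst$ic$pair_inspections, length(inst$tree$communities)^2)
})

test_that("index JSON dump carries labels and relation edges", {
  ex <- running_example()
  txt <- index_to_json(ex$idx, ex$ic)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_equal(parsed$communities$root$pre, 1L)
  expect_true(length(parsed$leaf_edges) > 0)
})
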