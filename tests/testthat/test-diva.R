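test_that("a cherry with tips {A} and {B} reconstructs root {AB} at cost 0", {
  tr <- parse_newick("(a:1,b:1);")
  areas <- area_table_fixture(list(a = "A", b = "B"))
  rec <- diva_reconstruct(tr, areas)
  expect_equal(rec$total_cost, 0L)
  expect_equal(rec$node_states[["3"]], "AB")
  expect_equal(unname(rec$multiplicity), 1L)
})

test_that("uniform tip ranges reconstruct for free", {
  tr <- simulate_yule(12, 0.3, seed = 4)
  areas <- area_table_fixture(setNames(as.list(rep("A", 12)), tr$tip.label))
  rec <- diva_reconstruct(tr, areas)
  expect_equal(rec$total_cost, 0L)
  for (st in rec$node_states) expect_equal(st, "A")
})

test_that("the DP matches exhaustive enumeration on random instances", {
  set.seed(88)
  alphabet3 <- c("A", "B", "C")
  for (rep in 1:60) {
    nt <- sample(3:5, 1)
    tr <- simulate_yule(nt, 0.4, seed = sample.int(1e7, 1))
    areas <- random_area_table(tr$tip.label, alphabet3)
    rec <- diva_reconstruct(tr, areas)
    oracle <- diva_oracle(tr, areas, alphabet3)
    expect_equal(rec$total_cost, oracle$cost)
    for (nd in names(rec$node_states))
      expect_setequal(rec$node_states[[nd]], oracle$node_states[[nd]])
  }
})

test_that("total cost is invariant under tip and area relabeling", {
  set.seed(5)
  for (i in 1:10) {
    tr <- simulate_yule(8, 0.3, seed = 60 + i)
    areas <- random_area_table(tr$tip.label, c("A", "B", "C", "D"))
    base <- diva_reconstruct(tr, areas)$total_cost
    ## permute tip labels (carrying ranges along)
    perm <- sample(tr$tip.label)
    tr2 <- tr; tr2$tip.label <- perm
    areas2 <- structure(setNames(unclass(areas)[tr$tip.label], perm),
                        class = "area_table",
                        alphabet = attr(areas, "alphabet"))
    expect_equal(diva_reconstruct(as_chronogram(tr2), areas2)$total_cost, base)
    ## relabel the area alphabet by a fixed permutation
    amap <- setNames(c("D", "C", "B", "A"), c("A", "B", "C", "D"))
    areas3 <- structure(lapply(unclass(areas), function(r) sort(unname(amap[r]))),
                        class = "area_table", alphabet = c("A", "B", "C", "D"))
    expect_equal(diva_reconstruct(tr, areas3)$total_cost, base)
  }
})

test_that("maxareas constrains ancestral ranges and validates tips", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  areas <- area_table_fixture(list(a = "A", b = "B", c = "C"))
  rec <- diva_reconstruct(tr, areas, maxareas = 2)
  for (st in unlist(rec$node_states)) expect_lte(nchar(st), 2L)
  expect_gte(rec$total_cost, diva_reconstruct(tr, areas)$total_cost)
  wide <- area_table_fixture(list(a = "ABC", b = "B", c = "C"))
  expect_error(diva_reconstruct(tr, wide, maxareas = 2), "larger than maxareas")
  expect_error(diva_reconstruct(tr, area_table_fixture(list(a = "A", b = "B"))),
               "missing from the area table")
})

test_that("sdiva over a degenerate sample gives uniform optimal-state pies", {
  tr <- simulate_yule(8, 0.3, seed = 21)
  areas <- random_area_table(tr$tip.label, c("A", "B", "C"),
                             max_size = 2)
  rec <- diva_reconstruct(tr, areas)
  prof <- sdiva(list(tr, tr, tr, tr), tr, areas)
  for (nd in names(rec$node_states)) {
    p <- prof$nodes[[nd]]
    expect_equal(p$coverage, 1)
    expect_equal(sum(p$freqs), 1, tolerance = 1e-9)
    m <- length(rec$node_states[[nd]])
    expect_setequal(names(p$freqs), rec$node_states[[nd]])
    expect_equal(unname(p$freqs), rep(1 / m, m))
  }
})

test_that("sdiva coverage counts the trees containing each clade", {
  ## two topologies for tips a..d: ((a,b),(c,d)) twice and (((a,c),b),d) twice
  t1 <- parse_newick("((a:1,b:1):2,(c:1,d:1):2);")
  t2 <- parse_newick("(((a:1,c:1):1,b:2):1,d:3);")
  areas <- area_table_fixture(list(a = "A", b = "A", c = "B", d = "B"))
  prof <- sdiva(list(t1, t1, t2, t2), t1, areas)
  keys <- clade_key_strings(t1)
  nd_ab <- names(keys)[keys == "a|b"]
  nd_cd <- names(keys)[keys == "c|d"]
  root <- names(keys)[keys == "a|b|c|d"]
  expect_equal(prof$nodes[[nd_ab]]$coverage, 0.5)
  expect_equal(prof$nodes[[nd_cd]]$coverage, 0.5)
  expect_equal(prof$nodes[[root]]$coverage, 1)
  ## hand count: in t1 the {a,b} node is optimally {A} (tips a,b both A)
  expect_equal(prof$nodes[[nd_ab]]$freqs, c(A = 1))
  expect_equal(sum(prof$nodes[[root]]$freqs), 1, tolerance = 1e-9)
})

test_that("count_dispersals counts area gains and validates chosen states", {
  fx <- dispersal_fixture()
  rec <- diva_reconstruct(fx$tree, fx$areas)
  chosen <- vapply(rec$node_states, `[[`, character(1), 1L)
  expect_equal(count_dispersals(fx$tree, rec, chosen, "A", "B"), 2L)
  expect_equal(count_dispersals(fx$tree, rec, chosen, "B", "A"), 0L)
  bad <- chosen; bad[[1]] <- "B"
  expect_error(count_dispersals(fx$tree, rec, bad, "A", "B"),
               "not among the optimal")
  ## all-A tips: no dispersals anywhere
  tr <- simulate_yule(6, 0.3, seed = 9)
  areasA <- area_table_fixture(setNames(as.list(rep("A", 6)), tr$tip.label))
  recA <- diva_reconstruct(tr, areasA)
  chA <- vapply(recA$node_states, `[[`, character(1), 1L)
  for (to in c("B", "C", "D"))
    expect_equal(count_dispersals(tr, recA, chA, "A", to), 0L)
})

test_that("the true root range is recovered at low event rates", {
  hits <- 0L; reps <- 200L
  for (r in seq_len(reps)) {
    sc <- scenario(simulation_spec(16, 0.25, seed = substream_seed(4000, r)),
                   n_pruned = 0L, root_range = "A",
                   dispersal_rate = 0.02, extinction_rate = 0.01,
                   seed = substream_seed(4000, r))
    st <- generate_study(sc)
    rec <- diva_reconstruct(st$pruned_tree, st$areas)
    root <- as.character(n_tips(st$pruned_tree) + 1L)
    if ("A" %in% rec$node_states[[root]]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})
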