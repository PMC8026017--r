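# Frozen expected values below were computed by hand enumeration and by the
# brute-force oracles in helper-oracles.R before the implementation existed.

test_that("graph construction records nodes and edge multiplicities", {
  g <- speech_graph(c("a", "b", "c", "a", "b", "d"))
  expect_equal(length(g$nodes), 4)
  expect_equal(sum(g$edges$count), 5)
  expect_setequal(g$nodes, c("a", "b", "c", "d"))
  # a->b appears twice, every other transition once
  ab <- g$edges$count[g$edges$from == "a" & g$edges$to == "b"]
  expect_equal(ab, 2L)

  expect_equal(speech_graph("w")$token_count, 1)
  expect_equal(nrow(speech_graph("w")$edges), 0)

  gx <- speech_graph(c("x", "x"))
  expect_equal(length(gx$nodes), 1)
  expect_equal(gx$edges$count, 1L)
  expect_true(gx$edges$from == gx$edges$to)

  expect_error(speech_graph(character(0)), "empty token window")
})

test_that("recurrence and loop counts match hand enumeration", {
  g1 <- speech_graph(c("a", "b", "a", "b", "a"))  # a->b x2, b->a x2
  expect_equal(recurrence_counts(g1), c(RE = 2, PE = 1))
  expect_equal(loop_counts(g1)[["L2"]], 1)
  expect_equal(recurrence_counts(g1, re_mode = "all")[["RE"]], 4)

  g2 <- speech_graph(c("a", "b", "c", "a", "b", "d"))
  expect_equal(recurrence_counts(g2), c(RE = 1, PE = 0))
  expect_equal(loop_counts(g2), c(L1 = 0, L2 = 0, L3 = 1))

  g3 <- speech_graph(letters[1:6])
  expect_equal(recurrence_counts(g3), c(RE = 0, PE = 0))
  expect_equal(loop_counts(g3), c(L1 = 0, L2 = 0, L3 = 0))

  expect_equal(loop_counts(speech_graph(c("x", "x", "x")))[["L1"]], 2)
  expect_equal(loop_counts(speech_graph(c("a", "b", "c", "a")))[["L3"]], 1)
  expect_equal(loop_counts(speech_graph(c("a", "b", "a")))[["L2"]], 1)

  # both orientations of a triangle are distinct cyclic classes
  g4 <- speech_graph(c("a", "b", "c", "a", "c", "b", "a"))
  expect_equal(loop_counts(g4)[["L3"]], 2)
})

test_that("strongly and weakly connected components match hand derivation", {
  g <- speech_graph(c("a", "b", "c", "a", "b", "d"))
  expect_equal(largest_strongly_connected(g), 3)  # {a,b,c}; d has no way back
  expect_equal(largest_weakly_connected(g), 4)

  expect_equal(largest_strongly_connected(speech_graph(letters[1:8])), 1)
  expect_equal(largest_strongly_connected(speech_graph(c("a","b","a","b","a"))), 2)
  expect_equal(largest_weakly_connected(speech_graph("w")), 1)

  gu <- union_speech_graph(c("a", "b", "c"), c("p", "q", "r", "s", "p"))
  expect_equal(largest_weakly_connected(gu), 4)
  expect_equal(oracle_lcc(c("a", "b", "c")), 3)  # oracle sanity on one piece
})

test_that("global measures match hand-computed small cases", {
  path4 <- compute_attributes(letters[1:4])
  expect_equal(path4[["D"]], 3 / 12)
  expect_equal(path4[["DI"]], 3)
  expect_equal(path4[["ASP"]], 10 / 6)
  expect_equal(path4[["CC"]], 0)
  expect_equal(path4[["ATD"]], 1.5)

  two <- compute_attributes(c("a", "b", "a", "b", "a"))
  expect_equal(two[["D"]], 1)
  expect_equal(two[["DI"]], 1)
  expect_equal(two[["ASP"]], 1)
  expect_equal(two[["ATD"]], 4)

  one <- compute_attributes("w")
  expect_equal(unname(one[c("D", "DI", "ASP", "CC")]), c(0, 0, 0, 0))

  # triangle plus a pendant: CC = (1 + 1 + 1/3 + 0)/4, hand-computed
  tri <- compute_attributes(c("a", "b", "c", "a", "d"))
  expect_equal(tri[["CC"]], (1 + 1 + 1 / 3 + 0) / 4)
})

test_that("full attribute vector assembles the per-operation results", {
  at <- compute_attributes(c("a", "b", "c", "a", "b", "d"))
  expect_equal(unname(at[c("N", "E", "WC", "RE", "PE", "L1", "L2", "L3",
                            "LCC", "LSC")]),
               c(4, 5, 6, 1, 0, 0, 0, 1, 4, 3))

  konst <- compute_attributes(rep("x", 30))
  expect_equal(unname(konst[c("N", "E", "WC", "L1", "RE", "LSC")]),
               c(1, 29, 30, 29, 28, 1))

  set.seed(4)
  dist30 <- compute_attributes(replicate(30, paste(sample(letters, 6),
                                                   collapse = "")))
  expect_equal(unname(dist30[c("N", "E", "RE", "PE", "L1", "L2", "L3",
                                "LCC", "LSC", "DI")]),
               c(30, 29, 0, 0, 0, 0, 0, 30, 1, 29))
  expect_equal(dist30[["ASP"]], 31 / 3)
})

test_that("structural invariants hold on random sequences", {
  set.seed(11)
  for (i in 1:60) {
    k <- sample(1:40, 1)
    toks <- random_tokens(k, vocab = letters[1:sample(2:8, 1)])
    g <- speech_graph(toks)
    at <- compute_attributes(toks)
    expect_equal(at[["E"]], k - 1)
    expect_lte(at[["N"]], k)
    expect_equal(at[["LCC"]], at[["N"]])  # single-sequence graphs are weakly connected
    expect_gte(at[["LSC"]], 1)
    expect_lte(at[["LSC"]], at[["LCC"]])
    expect_equal(at[["RE"]], at[["E"]] - nrow(g$edges))
    expect_gte(at[["D"]], 0); expect_lte(at[["D"]], 1)
    expect_gte(at[["CC"]], 0); expect_lte(at[["CC"]], 1)
    if (at[["N"]] >= 2) expect_lte(at[["ASP"]], at[["DI"]])

  }

  # appending a token that re-traverses an existing transition out of the
  # final token increments RE by exactly 1 and leaves N unchanged
  for (i in 1:20) {
    toks <- random_tokens(sample(4:20, 1), vocab = letters[1:3])
    k <- length(toks)
    j <- which(toks[-k] == toks[k])
    if (length(j) == 0) next
    nxt <- toks[j[1] + 1]  # (toks[k], nxt) already occurs in the graph
    base <- compute_attributes(toks)
    more <- compute_attributes(c(toks, nxt))
    expect_equal(more[["N"]], base[["N"]])
    expect_equal(more[["RE"]], base[["RE"]] + 1)
  }
})

test_that("attributes are invariant under sequence reversal and relabeling", {
  set.seed(23)
  stable <- c("N", "E", "WC", "L1", "L2", "LCC", "LSC", "D", "DI", "ASP", "CC")
  for (i in 1:40) {
    toks <- random_tokens(sample(2:30, 1), vocab = letters[1:5])
    at_f <- compute_attributes(toks)
    at_r <- compute_attributes(rev(toks))
    expect_equal(at_f[stable], at_r[stable])

    relab <- setNames(LETTERS[1:5], letters[1:5])
    at_m <- compute_attributes(unname(relab[toks]))
    expect_equal(unclass(at_m), unclass(at_f), ignore_attr = TRUE)
  }
})

test_that("LSC/LCC/DI/ASP agree with brute-force oracles on random graphs", {
  set.seed(101)
  for (i in 1:200) {
    toks <- random_tokens(sample(2:12, 1), vocab = letters[1:sample(2:6, 1)])
    g <- speech_graph(toks)
    expect_equal(largest_strongly_connected(g), oracle_lsc(toks))
    expect_equal(largest_weakly_connected(g), oracle_lcc(toks))
    fw <- oracle_di_asp(toks)
    glob <- global_measures(g)
    expect_equal(glob[["DI"]], fw[["DI"]])
    expect_equal(glob[["ASP"]], fw[["ASP"]])
  }
})

test_that("directed-distance variant stays within the strongly connected core", {
  g <- speech_graph(c("a", "b", "c", "a", "b", "d"))
  glob <- global_measures(g, distances = "directed_lsc")
  # SCC {a,b,c}: directed distances a->b 1, b->c 1, c->a 1, b->a 2, ...
  expect_equal(glob[["DI"]], 2)
  expect_equal(glob[["ASP"]], 1.5)
  # acyclic graph: single-node SCC, distances collapse to the convention
  glob2 <- global_measures(speech_graph(letters[1:5]),
                           distances = "directed_lsc")
  expect_equal(glob2[["DI"]], 0)
})

test_that("edge-list export round-trips multiplicities", {
  g <- speech_graph(c("a", "b", "a", "b", "a"))
  el <- edge_list(g)
  expect_equal(sort(el$multiplicity), c(2L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  edge_list(g, path)
  back <- read.delim(path)
  expect_equal(sum(back$multiplicity), 4)
})

test_that("dense attribute path agrees with the igraph-backed operations", {
  set.seed(137)
  for (i in 1:50) {
    toks <- random_tokens(sample(2:35, 1), vocab = letters[1:sample(2:9, 1)])
    at <- compute_attributes(toks)
    g <- speech_graph(toks)
    ops <- c(recurrence_counts(g), loop_counts(g),
             LCC = largest_weakly_connected(g),
             LSC = largest_strongly_connected(g),
             global_measures(g))
    for (nm in names(ops)) expect_equal(at[[nm]], unname(ops[[nm]]))
  }
})
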