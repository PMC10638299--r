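test_that("graph construction follows consecutive-lemma adjacency", {
  g1 <- buildGraph(lemseq("casa"))
  expect_equal(graphNodes(g1), "casa")
  expect_equal(nrow(graphEdges(g1)), 0L)

  g2 <- buildGraph(lemseq(c("ver", "casa", "ver")))
  expect_setequal(graphNodes(g2), c("ver", "casa"))
  expect_equal(graphEdges(g2),
               cbind(c("ver", "casa"), c("casa", "ver")))

  g3 <- buildGraph(lemseq(c("a", "b", "a", "b", "a")))
  expect_equal(length(graphNodes(g3)), 2L)
  expect_equal(nrow(graphEdges(g3)), 4L)
  key <- paste(graphEdges(g3)[, 1], graphEdges(g3)[, 2])
  expect_equal(sort(table(key)), sort(c("a b" = 2L, "b a" = 2L)),
               ignore_attr = TRUE)

  expect_error(buildGraph(lemseq(character(0), id = "empty")),
               class = "dreamgraphs_skip_record")
})

test_that("loop counts match trace formulas on hand-derived fixtures", {
  # trace convention: a self-loop of multiplicity 1 contributes
  # trace(A^2)/2 = 1/2 and trace(A^3)/3 = 1/3 (fractional by design)
  expect_equal(cycleCounts(buildGraph(lemseq(c("a", "a")))),
               c(L1 = 1, L2 = 1 / 2, L3 = 1 / 3))
  expect_equal(cycleCounts(buildGraph(lemseq(c("a", "b", "a")))),
               c(L1 = 0, L2 = 1, L3 = 0))
  expect_equal(cycleCounts(buildGraph(lemseq(c("a", "b", "c", "a")))),
               c(L1 = 0, L2 = 0, L3 = 1))
})

test_that("parallel edges count repeated adjacencies beyond the first", {
  expect_equal(parallelEdgeCount(buildGraph(lemseq(c("a", "b", "c")))), 0)
  expect_equal(parallelEdgeCount(buildGraph(lemseq(c("a", "b", "a", "b",
                                                     "a")))), 2)
})

test_that("LSC is the largest strongly connected component", {
  expect_equal(lscSize(buildGraph(lemseq(c("a", "b", "c")))), 1)
  expect_equal(lscSize(buildGraph(lemseq(c("a", "b", "c", "a")))), 3)
  g <- methods::new("SpeechGraph", reportId = "t",
                    nodes = c("a", "b", "c"),
                    edges = rbind(c("a", "b"), c("b", "a"), c("a", "c")))
  expect_equal(lscSize(g), 2)
})

test_that("path statistics use finite ordered pairs only", {
  expect_equal(pathStats(buildGraph(lemseq(c("a", "b", "c", "a")))),
               c(diameter = 2, ASP = 1.5))
  expect_equal(pathStats(buildGraph(lemseq(c("a", "b")))),
               c(diameter = 1, ASP = 1))
  expect_equal(pathStats(buildGraph(lemseq("a"))),
               c(diameter = 0, ASP = 0))
})

test_that("clustering, betweenness and neighbor degree match hand values", {
  expect_equal(meanClustering(buildGraph(lemseq(c("a", "b", "c", "a")))), 1)
  expect_equal(meanClustering(buildGraph(lemseq(c("a", "b", "c")))), 0)
  # one triangle plus a pendant: c(a)=c(b)=1, c(c)=1/3 (neighbors a,b,d;
  # only pair a-b connected), c(d)=0 -> mean 7/12
  pend <- methods::new("SpeechGraph", reportId = "t",
                       nodes = c("a", "b", "c", "d"),
                       edges = rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                     c("c", "d")))
  expect_equal(meanClustering(pend), (1 + 1 + 1 / 3 + 0) / 4)

  # path a -> b -> c: dependency of b is 1, normalized by
  # (N-1)(N-2) = 2, so mean over nodes is (0 + 1/2 + 0)/3
  expect_equal(meanBetweenness(buildGraph(lemseq(c("a", "b", "c")))), 1 / 6)
  triad <- methods::new("SpeechGraph", reportId = "t",
                        nodes = c("a", "b", "c"),
                        edges = rbind(c("a", "b"), c("b", "a"), c("b", "c"),
                                      c("c", "b"), c("a", "c"), c("c", "a")))
  expect_equal(meanBetweenness(triad), 0)
  expect_equal(meanBetweenness(buildGraph(lemseq(c("a", "b")))), 0)

  expect_equal(avgNeighborDegreeMean(buildGraph(lemseq(c("a", "b")))), 1)
  star <- methods::new("SpeechGraph", reportId = "t",
                       nodes = c("h", "x", "y", "z"),
                       edges = rbind(c("h", "x"), c("h", "y"), c("h", "z")))
  expect_equal(avgNeighborDegreeMean(star), (3 + 3 + 3 + 1) / 4)
  lonely <- methods::new("SpeechGraph", reportId = "t", nodes = c("a", "b"),
                         edges = matrix(character(), 0, 2))
  expect_equal(avgNeighborDegreeMean(lonely), 0)
})

test_that("the two-node cycle report has the full hand-derived profile", {
  a <- computeAttributes(buildGraph(lemseq(c("a", "b", "a"))))
  expect_equal(a$N, 2)
  expect_equal(a$E, 2)
  expect_equal(a$PE, 0)
  expect_equal(a$L1, 0)
  expect_equal(a$L2, 1)
  expect_equal(a$L3, 0)
  expect_equal(a$LSC, 2)
  expect_equal(a$ATD, 2)
  expect_equal(a$density, 1)
  expect_equal(a$diameter, 1)
  expect_equal(a$ASP, 1)
  expect_equal(a$CC, 0)
  expect_equal(a$mean_betweenness, 0)
  expect_equal(a$avg_neighbor_degree, 1)
})

test_that("degenerate single-node graphs stay finite", {
  a <- computeAttributes(buildGraph(lemseq("a")))
  expect_equal(a$N, 1)
  expect_equal(a$E, 0)
  expect_equal(a$density, 0)
  expect_equal(a$diameter, 0)
  expect_equal(a$ASP, 0)
  expect_equal(a$mean_betweenness, 0)
  expect_equal(a$CC, 0)
  expect_equal(a$avg_neighbor_degree, 0)
})

test_that("attributes are invariant to lemma renaming", {
  for (s in c(3L, 17L, 29L)) {
    base <- withr::with_seed(s, sample(letters[1:6], 30, replace = TRUE))
    ren <- stats::setNames(paste0("X", seq_len(6)), letters[1:6])
    a1 <- computeAttributes(buildGraph(lemseq(base)))
    a2 <- computeAttributes(buildGraph(lemseq(unname(ren[base]))))
    expect_equal(a1, a2)
  }
})

test_that("self-concatenation compacts the graph", {
  # repeating a narrative adds recurrence: density never decreases and
  # the diameter never increases
  for (s in c(5L, 11L, 23L, 41L)) {
    lem <- withr::with_seed(s, sample(letters[1:8], 15, replace = TRUE))
    a1 <- computeAttributes(buildGraph(lemseq(lem)))
    a2 <- computeAttributes(buildGraph(lemseq(c(lem, lem))))
    expect_gte(a2$density, a1$density)
    expect_lte(a2$diameter, a1$diameter)
  }
})

test_that("attributes agree with the brute-force oracle on random multigraphs", {
  for (s in seq(1001L, 1030L)) {
    g <- random_speech_graph(s)
    expect_equal(computeAttributes(g), oracle_attributes(g),
                 tolerance = 1e-12)
  }
})
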