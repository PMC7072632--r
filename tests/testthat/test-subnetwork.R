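test_that("subnetwork assembly is the induced basal subgraph", {
  basal <- basalNetwork(letters[1:4],
                        parent = c("a", "b", "b", "c"),
                        child = c("b", "c", "d", "d"))
  # only the endpoints of extracted edges become nodes
  ex1 <- data.frame(parent = "a", child = "b", stringsAsFactors = FALSE)
  sn1 <- buildSubnetwork(basal, ex1)
  expect_setequal(sn1@nodes, c("a", "b"))
  expect_equal(nrow(sn1@edges), 1L)

  # a basal connection between extracted nodes is filled in and tagged
  ex2 <- data.frame(parent = c("a", "c"), child = c("b", "d"),
                    line1 = c(1.4, 1.2), stringsAsFactors = FALSE)
  sn2 <- buildSubnetwork(basal, ex2)
  expect_setequal(sn2@nodes, c("a", "b", "c", "d"))
  e2 <- sn2@edges
  expect_setequal(paste(e2$parent, e2$child),
                  c("a b", "c d", "b c", "b d"))
  expect_equal(sum(e2$origin == "delta_extracted"), 2L)
  expect_equal(sum(e2$origin == "basal_fill"), 2L)
  expect_gte(nrow(e2), nrow(ex2))
  # annotations survive on extracted edges, are NA on fill edges
  expect_equal(sort(e2$line1[e2$origin == "delta_extracted"]), c(1.2, 1.4))
  expect_true(all(is.na(e2$line1[e2$origin == "basal_fill"])))

  ghost <- data.frame(parent = "d", child = "a", stringsAsFactors = FALSE)
  expect_error(buildSubnetwork(basal, ghost), "consistency error")

  sn3 <- buildSubnetwork(basal, ex2)
  expect_identical(sn3@edges, sn2@edges)
})

test_that("hub ranking follows total degree with tie extension", {
  # star: center must rank first
  star <- basalNetwork(c("hub", paste0("n", 1:9)),
                       parent = rep("hub", 9), child = paste0("n", 1:9))
  expect_identical(hubNodes(star, 0.05)$gene[1], "hub")

  # 150 nodes, no tie at the cutoff: ceiling(0.05 * 150) = 8 nodes
  hubs9 <- sprintf("h%d", 1:9)
  leaves <- sprintf("l%03d", seq_len(sum(17:9)))
  genes150 <- c(hubs9, leaves, sprintf("iso%02d", 1:24))
  net150 <- basalNetwork(genes150, parent = rep(hubs9, times = 17:9),
                         child = leaves)
  hn <- hubNodes(net150, 0.05)
  expect_equal(nrow(hn), 8L)
  expect_identical(hn$gene, hubs9[1:8])

  # all degrees equal: the tie rule returns every node
  ring <- basalNetwork(c("a", "b", "c"), parent = c("a", "b", "c"),
                       child = c("b", "c", "a"))
  expect_equal(nrow(hubNodes(ring, 0.05)), 3L)

  empty <- new("Subnetwork", nodes = character(),
               edges = data.frame(parent = character(), child = character(),
                                  origin = character(),
                                  stringsAsFactors = FALSE))
  expect_equal(nrow(hubNodes(empty)), 0L)
  expect_error(hubNodes(ring, 0), "fraction")
})

test_that("weakly connected components come largest first", {
  two <- basalNetwork(letters[1:4], parent = c("a", "c"),
                      child = c("b", "d"))
  comps <- networkComponents(two)
  expect_length(comps, 2L)
  expect_true(all(lengths(comps) == 2L))

  empty <- new("Subnetwork", nodes = character(),
               edges = data.frame(parent = character(), child = character(),
                                  origin = character(),
                                  stringsAsFactors = FALSE))
  expect_length(networkComponents(empty), 0L)

  chain <- basalNetwork(letters[1:5], parent = letters[1:4],
                        child = letters[2:5])
  comps2 <- networkComponents(chain)
  expect_length(comps2, 1L)
  expect_length(comps2[[1]], 5L)

  mixed <- basalNetwork(letters[1:5], parent = c("a", "b", "d"),
                        child = c("b", "c", "e"))
  comps3 <- networkComponents(mixed)
  expect_equal(lengths(comps3), c(3L, 2L), ignore_attr = TRUE)
})

test_that("subnetwork writers produce parseable files", {
  basal <- basalNetwork(letters[1:4],
                        parent = c("a", "b", "b"), child = c("b", "c", "d"))
  ex <- data.frame(parent = c("a", "b"), child = c("b", "c"),
                   line1 = c(1.5, 1.1), stringsAsFactors = FALSE)
  sn <- buildSubnetwork(basal, ex)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSubnetworkTsv(sn, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(back$origin, sn@edges$origin)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeNetworkSif(sn, sif)
  expect_length(readLines(sif), nrow(sn@edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  writeSubnetworkGraphml(sn, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(sn@nodes))
  expect_equal(igraph::gsize(g), nrow(sn@edges))
  expect_true("origin" %in% igraph::edge_attr_names(g))
  expect_true(all(c("degree", "hub") %in% igraph::vertex_attr_names(g)))
})
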