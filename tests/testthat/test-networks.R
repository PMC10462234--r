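test_that("lr_database deduplicates and preserves order", {
  df <- data.frame(ligand = c("a", "b", "a", "c", "d", "e"),
                   receptor = c("r1", "r2", "r1", "r3", "r4", "r5"))
  lr <- lr_database(df)
  expect_equal(nrow(lr), 5)
  expect_equal(lr$ligand, c("a", "b", "c", "d", "e"))
  # empty table with header is valid and scores to an empty table
  empty <- lr_database(data.frame(ligand = character(),
                                  receptor = character()))
  expect_equal(nrow(empty), 0)
  expect_error(lr_database(data.frame(gene = "x")), "columns")
})

test_that("signaling_graph validates edge kinds and rejects self-loops", {
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      kind = c("signaling", "regulatory"))
  g <- signaling_graph(edges)
  expect_equal(igraph::ecount(g), 2)
  expect_error(signaling_graph(data.frame(source = "a", target = "a",
                                          kind = "signaling")),
               "self-loops")
  expect_error(signaling_graph(data.frame(source = "a", target = "b",
                                          kind = "inhibition")),
               "unknown edge kind")
})

test_that("active_subgraph keeps edges iff both endpoints pass detection", {
  # 6 genes with controlled detection in one type: g1..g3 always on,
  # g4 on in half the cells, g5, g6 never
  counts <- matrix(0, 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  counts[1:3, ] <- 1
  counts[4, 1:5] <- 1
  m <- toy_matrix(counts, "T")
  edges <- data.frame(source = c("g1", "g2", "g3", "g4", "g5"),
                      target = c("g2", "g3", "g4", "g5", "g6"),
                      kind = "signaling")
  g <- signaling_graph(edges)
  sub <- active_subgraph(g, m, "T", detect_min = 0.5)
  got <- igraph::as_data_frame(sub)[, c("from", "to")]
  # brute-force per-edge check
  det <- apply(counts > 0, 1, mean)
  want <- edges[det[edges$source] >= 0.5 & det[edges$target] >= 0.5, ]
  expect_setequal(paste(got$from, got$to), paste(want$source, want$target))
  # detect_min = 0 keeps the full graph
  expect_equal(igraph::ecount(active_subgraph(g, m, "T", 0)),
               igraph::ecount(g))
  # monotone: raising detect_min never adds edges
  e_lo <- igraph::ecount(active_subgraph(g, m, "T", 0.3))
  e_hi <- igraph::ecount(active_subgraph(g, m, "T", 0.8))
  expect_lte(e_hi, e_lo)
  expect_error(active_subgraph(g, m, "NoSuchType", 0.1), "unknown cell")
})

test_that("the canonical distress-loop example is recovered", {
  # forward Bdnf-Ntrk2 (RGC -> astrocyte-like receiver); receiver relays
  # Ntrk2 -> TFx -> Vegfa, and the back receptor Flt1 sits on the sender
  lr <- lr_database(data.frame(ligand = c("Bdnf", "Vegfa"),
                               receptor = c("Ntrk2", "Flt1")))
  g_receiver <- signaling_graph(data.frame(
    source = c("Ntrk2", "TFx"), target = c("TFx", "Vegfa"),
    kind = c("signaling", "regulatory")))
  loops <- find_feedback_loops(
    list(ligand = "Bdnf", receptor = "Ntrk2",
         sender = "RGC", receiver = "Astrocyte"),
    lr, g_receiver, max_path_len = 4)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$back_ligand, "Vegfa")
  expect_equal(loops$back_receptor, "Flt1")
  expect_equal(loops$path_receiver, "Ntrk2>TFx>Vegfa")
  # empty receiver graph: no loops
  g_empty <- signaling_graph(data.frame(source = "x", target = "y",
                                        kind = "signaling"))
  expect_equal(nrow(find_feedback_loops(
    list(ligand = "Bdnf", receptor = "Ntrk2", sender = "RGC",
         receiver = "Astrocyte"), lr, g_empty)), 0)
})

test_that("loop detection equals exhaustive DFS enumeration on random
           graphs", {
  set.seed(202)
  for (rep in 1:40) {
    n_nodes <- sample(4:8, 1)
    edges <- random_edges(n_nodes, p_edge = 0.3)
    if (!nrow(edges)) next
    nodes <- paste0("n", seq_len(n_nodes))
    lr <- lr_database(data.frame(
      ligand = sample(nodes, 4, replace = TRUE),
      receptor = sample(nodes, 4, replace = TRUE)))
    r1 <- sample(nodes, 1)
    max_len <- sample(2:4, 1)
    g <- signaling_graph(cbind(edges, kind = "signaling"))
    got <- find_feedback_loops(
      list(ligand = "L0", receptor = r1, sender = "S", receiver = "R"),
      lr, g, max_path_len = max_len)
    want <- loops_bruteforce(r1, as.data.frame(lr), edges, max_len)
    expect_setequal(paste(got$back_ligand, got$back_receptor),
                    paste(want$ligand, want$receptor))
  }
})

test_that("loop sets are invariant to edge insertion order", {
  set.seed(7)
  edges <- random_edges(7, 0.35)
  lr <- lr_database(data.frame(ligand = paste0("n", 1:7),
                               receptor = paste0("n", 7:1)))
  fw <- list(ligand = "L0", receptor = "n1", sender = "S", receiver = "R")
  g1 <- signaling_graph(cbind(edges, kind = "signaling"))
  g2 <- signaling_graph(cbind(edges[rev(seq_len(nrow(edges))), ],
                              kind = "signaling"))
  l1 <- find_feedback_loops(fw, lr, g1, max_path_len = 3)
  l2 <- find_feedback_loops(fw, lr, g2, max_path_len = 3)
  expect_equal(paste(l1$back_ligand, l1$back_receptor),
               paste(l2$back_ligand, l2$back_receptor))
})

test_that("back receptors must be detected in the sender when expression is
           supplied", {
  counts <- matrix(0, 4, 10,
                   dimnames = list(c("R1", "L2", "R2", "R3"),
                                   paste0("c", 1:10)))
  counts[c("R1", "L2"), ] <- 1
  counts["R2", 1:5] <- 1          # detected in sender at 0.5
  m <- toy_matrix(counts, "S")
  lr <- lr_database(data.frame(ligand = c("L2", "L2"),
                               receptor = c("R2", "R3")))
  g <- signaling_graph(data.frame(source = "R1", target = "L2",
                                  kind = "signaling"))
  fw <- list(ligand = "L1", receptor = "R1", sender = "S", receiver = "R")
  loops <- find_feedback_loops(fw, lr, g, m = m, detect_min = 0.1)
  # R3 is never expressed in the sender, so only the R2 loop survives
  expect_equal(loops$back_receptor, "R2")
})
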