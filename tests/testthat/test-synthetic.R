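test_that("identical config and seed give byte-identical atlases", {
  cfg <- synthetic_config(cells_per_type_per_timepoint = 20,
                          n_sender_types = 3, n_genes = 260, seed = 7)
  a <- generate_atlas(cfg)
  b <- generate_atlas(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$matrix$cell_meta, b$matrix$cell_meta)
  expect_identical(a$truth$lr_pairs, b$truth$lr_pairs)
  c <- generate_atlas(synthetic_config(cells_per_type_per_timepoint = 20,
                                       n_sender_types = 3, n_genes = 260,
                                       seed = 8))
  expect_false(identical(as.matrix(a$matrix$counts),
                         as.matrix(c$matrix$counts)))
})

test_that("planted boost shows up as ~effect_size-fold ligand expression in
           the sender", {
  cfg <- synthetic_config(seed = 13)
  atlas <- generate_atlas(cfg)
  pp <- cfg$planted_pairs[cfg$planted_pairs$dynamics == "preset", ][1, ]
  counts <- as.matrix(atlas$matrix$counts)
  meta <- atlas$matrix$cell_meta
  in_sender <- atlas$truth$labels == pp$sender
  # independent per-cell average of raw ligand counts
  boosted_mean <- mean(counts[pp$ligand, in_sender])
  other_senders <- meta$cell_type %in% cfg$sender_types &
    !in_sender
  baseline_mean <- mean(counts[pp$ligand, other_senders])
  expect_equal(boosted_mean / baseline_mean, pp$effect_size,
               tolerance = 0.25)
  # and against the configured absolute baseline
  expect_equal(boosted_mean, cfg$nb_mean * pp$effect_size,
               tolerance = 0.25 * cfg$nb_mean * pp$effect_size)
})

test_that("effect_size 1 plants no differential signal", {
  cfg0 <- synthetic_config(seed = 31)
  cfg0$planted_pairs$effect_size <- 1
  atlas <- generate_atlas(cfg0)
  m <- atlas$matrix
  lr <- lr_database(atlas$truth$lr_pairs)
  tab <- score_interactions(m, lr, senders = cfg0$sender_types,
                            receivers = cfg0$receiver_subclasses$name)
  dparams <- differential_params(
    cfg0$receiver_subclasses$name[
      cfg0$receiver_subclasses$survival_class == "high"],
    cfg0$receiver_subclasses$name[
      cfg0$receiver_subclasses$survival_class == "low"])
  recs <- protective_table(tab, dparams)
  key <- paste(recs$ligand, recs$receptor)
  planted <- key %in% paste(cfg0$planted_pairs$ligand,
                            cfg0$planted_pairs$receptor)
  # null-effect planted pairs behave like decoys: no protective calls and
  # differential scores within the decoy range
  expect_true(all(recs$call[planted] == "neutral"))
  expect_lte(max(abs(recs$dslr[planted])),
             max(abs(recs$dslr[!planted])) + 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(cells_per_type_per_timepoint = 10))
  expect_error(synthetic_config(receiver_subclasses = data.frame(
    name = c("a", "b"), survival_class = c("high", "high"))),
    "both survival classes")
  expect_error(synthetic_config(planted_pairs = data.frame(
    ligand = "not_a_gene", receptor = "g0001", sender = "MullerGlia",
    target_survival_class = "high", effect_size = 4,
    dynamics = "preset")), "absent from the gene universe")
})

test_that("planted-effect recovery: boosted group mean exceeds baseline in
           >= 95% of seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(cells_per_type_per_timepoint = 25,
                            n_sender_types = 3, n_genes = 260,
                            seed = 100 + s)
    cfg$planted_pairs <- cfg$planted_pairs[1, ]
    cfg$planted_pairs$effect_size <- 3
    cfg$planted_loops <- cfg$planted_loops[0, ]
    atlas <- generate_atlas(cfg)
    pp <- cfg$planted_pairs
    counts <- as.matrix(atlas$matrix$counts)
    in_sender <- atlas$truth$labels == pp$sender
    other <- atlas$matrix$cell_meta$cell_type %in% cfg$sender_types &
      !in_sender
    if (mean(counts[pp$ligand, in_sender]) >
        mean(counts[pp$ligand, other])) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("dot images honour their closed-form structure", {
  # zero dots: pure background
  img0 <- generate_dot_image(0, background_level = 3, seed = 1)
  expect_true(all(img0$field$intensity == 3))
  # zero background: total intensity is n * dot_intensity * area
  img <- generate_dot_image(10, dot_intensity = 40, dot_area_px = 9,
                            background_level = 0, seed = 2)
  expect_equal(sum(img$field$intensity), 10 * 40 * 9)
  # determinism
  img2 <- generate_dot_image(10, dot_intensity = 40, dot_area_px = 9,
                             background_level = 0, seed = 2)
  expect_identical(img$field$intensity, img2$field$intensity)
  # impossible placements error out
  expect_error(generate_dot_image(200, dot_area_px = 25,
                                  image_shape = c(30, 30), seed = 1),
               "could not place")
})

test_that("atlas files round-trip through the documented formats", {
  atlas <- small_atlas(seed = 9)
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  lr <- load_lr_database(file.path(dir, "lr_pairs.tsv"))
  expect_equal(nrow(lr), nrow(atlas$truth$lr_pairs))
  net <- load_signaling_graph(file.path(dir, "network.tsv"))
  expect_equal(igraph::ecount(net), nrow(atlas$truth$network))
  mk <- load_markers(file.path(dir, "markers.json"))
  expect_identical(mk, atlas$truth$markers)
})
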