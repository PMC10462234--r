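# fixture with controlled group means: 3 labels x 2 timepoints, one ligand
# and one receptor gene whose per-group expression is set by construction
scoring_fixture <- function() {
  groups <- expand.grid(label = c("A", "B", "C"), tp = c("t1", "t2"),
                        stringsAsFactors = FALSE)
  per <- 10
  lig_level <- c(A_t1 = 0, A_t2 = 8, B_t1 = 2, B_t2 = 2,
                 C_t1 = 4, C_t2 = 6)
  rec_level <- c(A_t1 = 1, A_t2 = 1, B_t1 = 0, B_t2 = 10,
                 C_t1 = 5, C_t2 = 5)
  counts <- NULL
  meta_label <- meta_tp <- character(0)
  for (i in seq_len(nrow(groups))) {
    key <- paste(groups$label[i], groups$tp[i], sep = "_")
    block <- rbind(lig = rep(lig_level[key], per),
                   rec = rep(rec_level[key], per),
                   filler = rep(3, per))
    counts <- cbind(counts, block)
    meta_label <- c(meta_label, rep(groups$label[i], per))
    meta_tp <- c(meta_tp, rep(groups$tp[i], per))
  }
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  rownames(counts) <- c("lig", "rec", "filler")
  toy_matrix(counts, meta_label, timepoint = meta_tp)
}

# independent recomputation of the scaled geometric-mean score
oracle_s0 <- function(m, ligand, receptor, sender, receiver, timepoint) {
  counts <- as.matrix(m$counts)
  norm <- apply(counts, 2, function(v)
    if (sum(v) > 0) log1p(v / sum(v) * 1e4) else v)
  rownames(norm) <- rownames(counts)
  grp <- paste(m$cell_meta$cell_type, m$cell_meta$timepoint)
  gmean <- function(gene)
    tapply(norm[gene, ], grp, mean)
  scale01 <- function(v) {
    if (max(v) == min(v)) return(v * 0)
    (v - min(v)) / (max(v) - min(v))
  }
  l <- scale01(gmean(ligand))[paste(sender, timepoint)]
  r <- scale01(gmean(receptor))[paste(receiver, timepoint)]
  sqrt(l * r)
}

test_that("base scores equal the hand-computed scaled geometric mean", {
  m <- scoring_fixture()
  lr <- lr_database(data.frame(ligand = "lig", receptor = "rec"))
  tab <- score_interactions(m, lr, receiver_level = "cell_type")
  for (i in sample(nrow(tab), 8)) {
    expect_equal(tab$s0[i],
                 unname(oracle_s0(m, "lig", "rec", tab$sender[i],
                                  tab$receiver[i], tab$timepoint[i])),
                 tolerance = 1e-10,
                 info = paste(tab$sender[i], tab$receiver[i],
                              tab$timepoint[i]))
  }
  # ligand absent from sender at all timepoints scales to 0
  row <- tab[tab$sender == "A" & tab$timepoint == "t1", ][1, ]
  expect_equal(row$s0, 0)
  # both genes at their own maximum group: score 1
  row <- tab[tab$sender == "A" & tab$receiver == "B" &
             tab$timepoint == "t2", ]
  expect_equal(row$s0, 1)
  # scores always within [0, 1]
  expect_true(all(tab$s0 >= 0 & tab$s0 <= 1))
})

test_that("genes with no between-group contrast score 0", {
  # identical cells everywhere: every group mean coincides, so min-max
  # scaling maps both genes to 0
  counts <- matrix(5, 2, 20, dimnames = list(c("flat1", "flat2"),
                                             sprintf("c%02d", 1:20)))
  m <- toy_matrix(counts, rep(c("A", "B"), each = 10),
                  timepoint = rep(c("t1", "t2"), 10))
  lr <- lr_database(data.frame(ligand = "flat1", receptor = "flat2"))
  tab <- score_interactions(m, lr, receiver_level = "cell_type")
  expect_true(all(tab$s0 == 0))
})

test_that("loop adjustment follows its closed form and saturates", {
  expect_equal(loop_adjusted_score(0.4, numeric(), 0.5), 0.4)
  expect_equal(loop_adjusted_score(0.4, 1.0, 0.5), 0.6)
  expect_equal(loop_adjusted_score(0.9, 1.0, 0.5), 1.0)
  expect_equal(loop_adjusted_score(0.4, c(0.2, 0.8), 0.5),
               0.4 * (1 + 0.5 * 0.8))
  expect_equal(loop_adjusted_score(0.4, c(0.2, 0.8), 0.5,
                                   loop_combine = "sum"),
               0.4 * (1 + 0.5 * 1.0))
  # monotone in beta and in back scores
  expect_gte(loop_adjusted_score(0.4, 0.9, 0.8),
             loop_adjusted_score(0.4, 0.9, 0.5))
  expect_gte(loop_adjusted_score(0.4, 0.9, 0.5),
             loop_adjusted_score(0.4, 0.5, 0.5))
})

test_that("filter_pairs applies detection and score rules with inclusive
           boundaries", {
  base <- expand.grid(timepoint = c("sham", "12h", "24h", "48h"),
                      stringsAsFactors = FALSE)
  mk <- function(lig, scores, det_l, det_r)
    data.frame(sender = "S", receiver = "R", ligand = lig,
               receptor = paste0(lig, "r"), timepoint = base$timepoint,
               s0 = scores, S_LR = scores, det_ligand = det_l,
               det_receptor = det_r, stringsAsFactors = FALSE)
  tab <- as_score_table(rbind(
    mk("exactly_half", c(0.1, 0.2, 0.5, 0.3), 0.5, 0.5),
    mk("low_det_lig", c(0.9, 0.9, 0.9, 0.9), 0.09, 0.5),
    mk("low_det_rec", c(0.9, 0.9, 0.9, 0.9), 0.5, 0.09),
    mk("weak", c(0.1, 0.2, 0.3, 0.49), 0.5, 0.5)))
  kept <- filter_pairs(tab, scoring_params())
  # max exactly 0.5 is kept ("no less than"), detection 0.09 excludes
  expect_setequal(unique(kept$ligand), "exactly_half")
  expect_equal(nrow(kept), 4)  # all timepoints of the surviving key
  # idempotent
  expect_equal(as.data.frame(filter_pairs(kept, scoring_params())),
               as.data.frame(kept))
})

test_that("filter_pairs agrees with a brute-force per-key rule check", {
  set.seed(33)
  keys <- expand.grid(sender = c("S1", "S2"), receiver = c("R1", "R2"),
                      pair = 1:10, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    data.frame(sender = keys$sender[i], receiver = keys$receiver[i],
               ligand = paste0("L", keys$pair[i]),
               receptor = paste0("R", keys$pair[i]),
               timepoint = c("sham", "12h"),
               S_LR = round(runif(2), 2),
               det_ligand = round(runif(2), 2),
               det_receptor = round(runif(2), 2),
               stringsAsFactors = FALSE)
  }))
  tab <- as_score_table(rows)
  kept <- filter_pairs(tab, scoring_params(detect_min = 0.3,
                                           score_min = 0.6))
  key_of <- function(d) paste(d$sender, d$receiver, d$ligand, d$receptor)
  want <- character(0)
  for (k in unique(key_of(rows))) {
    d <- rows[key_of(rows) == k, ]
    if (max(d$det_ligand) >= 0.3 && max(d$det_receptor) >= 0.3 &&
        max(d$S_LR) >= 0.6) want <- c(want, k)
  }
  expect_setequal(unique(key_of(kept)), want)
})

test_that("overall_score sums surviving pairs and is monotone", {
  tab <- as_score_table(data.frame(
    sender = "S", receiver = "R",
    ligand = c("a", "b", "c"), receptor = c("ar", "br", "cr"),
    timepoint = "12h", S_LR = c(0.5, 0.6, 0.7),
    stringsAsFactors = FALSE))
  expect_equal(overall_score(tab, "S", "R", "12h"), 1.8)
  expect_equal(overall_score(tab, "S", "R", "sham"), 0)
  bigger <- as_score_table(rbind(as.data.frame(tab), data.frame(
    sender = "S", receiver = "R", ligand = "d", receptor = "dr",
    timepoint = "12h", S_LR = 0.2, s0 = 0.2, det_ligand = 1,
    det_receptor = 1)))
  expect_gte(overall_score(bigger, "S", "R", "12h"),
             overall_score(tab, "S", "R", "12h"))
})

test_that("with beta 0 loop adjustment reduces to base scores", {
  atlas <- small_atlas(seed = 14)
  m <- atlas$matrix
  lr <- lr_database(atlas$truth$lr_pairs)
  net <- signaling_graph(atlas$truth$network)
  cfg <- atlas$truth$config
  tab <- score_interactions(m, lr, senders = cfg$sender_types,
                            receivers = cfg$receiver_subclasses$name,
                            params = scoring_params(beta = 0))
  adj <- add_loop_adjustment(tab, m, lr, net,
                             scoring_params(beta = 0))
  expect_equal(adj$S_LR, adj$s0)
  # with positive beta, scores never decrease and stay within [0, 1]
  adj2 <- add_loop_adjustment(tab, m, lr, net,
                              scoring_params(beta = 0.5))
  expect_true(all(adj2$S_LR >= adj2$s0 - 1e-12))
  expect_true(all(adj2$S_LR <= 1))
  # pairs with planted loops actually received a bonus opportunity
  looped <- paste(adj2$ligand, adj2$receptor) %in%
    paste(cfg$planted_loops$ligand, cfg$planted_loops$receptor)
  expect_true(all(adj2$n_loops[looped] >= 1))
})

test_that("empty inputs give empty score tables", {
  atlas <- small_atlas(seed = 2)
  empty_lr <- lr_database(data.frame(ligand = character(),
                                     receptor = character()))
  tab <- score_interactions(atlas$matrix, empty_lr)
  expect_s3_class(tab, "score_table")
  expect_equal(nrow(tab), 0)
  expect_equal(nrow(filter_pairs(tab, scoring_params())), 0)
})
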