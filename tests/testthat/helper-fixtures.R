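# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately written with plain loops / recursion, independent of the
# package's implementation path.

# tiny cell_matrix with explicit counts and group annotation
toy_matrix <- function(counts, cell_type, timepoint = "sham",
                       subclass = NA_character_,
                       survival_class = NA_character_) {
  meta <- data.frame(cell_id = colnames(counts), cell_type = cell_type,
                     subclass = subclass, survival_class = survival_class,
                     timepoint = timepoint, condition = "sham",
                     stringsAsFactors = FALSE)
  cell_matrix(counts, meta)
}

# wrap a long data.frame as a score_table (for fixtures with hand-set
# scores)
as_score_table <- function(df, timepoints = NULL) {
  if (!"S_LR" %in% names(df)) df$S_LR <- df$s0
  if (!"s0" %in% names(df)) df$s0 <- df$S_LR
  for (col in c("det_ligand", "det_receptor"))
    if (!col %in% names(df)) df[[col]] <- 1
  if (is.null(timepoints)) timepoints <- unique(df$timepoint)
  attr(df, "timepoints") <- timepoints
  attr(df, "receiver_level") <- "subclass"
  class(df) <- c("score_table", "data.frame")
  df
}

# --- QC oracle: literal per-cell evaluation of the five printed rules ----
qc_survivors_bruteforce <- function(counts, thresholds, mito_prefix = "mt-") {
  counts <- as.matrix(counts)
  keep <- character(0)
  for (cell in colnames(counts)) {
    v <- counts[, cell]
    numi <- sum(v)
    ngene <- sum(v > 0)
    mito <- sum(v[startsWith(tolower(names(v)), tolower(mito_prefix))])
    mito_rate <- if (numi > 0) mito / numi else NA
    lgpu <- if (numi > 1 && ngene > 0) log10(ngene) / log10(numi) else NA
    removed <- is.na(mito_rate) || is.na(lgpu) ||
      numi < thresholds$numi_min || numi > thresholds$numi_max ||
      ngene < thresholds$ngene_min || ngene > thresholds$ngene_max ||
      mito_rate > thresholds$mito_max || lgpu < thresholds$lgpu_min
    if (!removed) keep <- c(keep, cell)
  }
  keep
}

# --- simple-path enumeration oracle (recursive DFS, no igraph) ----------
# edges: data.frame(source, target). Returns TRUE when a simple directed
# path with 1..max_len edges exists from `from` to `to`.
path_exists_bruteforce <- function(edges, from, to, max_len) {
  if (from == to) return(FALSE)  # a simple path cannot revisit its start
  adj <- split(edges$target, edges$source)
  found <- FALSE
  walk <- function(node, visited, depth) {
    if (found || depth > max_len) return()
    for (nxt in adj[[node]]) {
      if (nxt == to) { found <<- TRUE; return() }
      if (!(nxt %in% visited))
        walk(nxt, c(visited, nxt), depth + 1)
    }
  }
  if (from %in% names(adj)) walk(from, from, 1)
  found
}

# loop oracle: every lr pair whose back ligand is reachable from the
# forward receptor within max_len edges
loops_bruteforce <- function(receptor, lr, edges, max_len) {
  hit <- logical(nrow(lr))
  for (i in seq_len(nrow(lr)))
    hit[i] <- path_exists_bruteforce(edges, receptor, lr$ligand[i],
                                     max_len)
  lr[hit, , drop = FALSE]
}

# --- 8-connected component labelling oracle (recursive flood fill) ------
label_components_bruteforce <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  current <- 0L
  fill <- function(r, c) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
        next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <<- current
      for (dr in -1:1) for (dc in -1:1)
        if (dr != 0L || dc != 0L)
          stack[[length(stack) + 1L]] <- c(p[1] + dr, p[2] + dc)
    }
  }
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c] && lab[r, c] == 0L) {
      current <- current + 1L
      fill(r, c)
    }
  lab
}

# random directed graph edge table over <= n_nodes labelled nodes
random_edges <- function(n_nodes, p_edge = 0.25) {
  nodes <- paste0("n", seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid[stats::runif(nrow(grid)) < p_edge, , drop = FALSE]
}

# small atlas used by several tests (kept modest so suites stay fast)
small_atlas <- function(seed = 11, ...) {
  generate_atlas(synthetic_config(
    cells_per_type_per_timepoint = 20, n_sender_types = 3,
    n_genes = 260, n_decoy_pairs = 15, seed = seed, ...))
}
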