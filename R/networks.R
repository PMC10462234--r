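#' Ligand-receptor pair database
#'
#' A deduplicated table of (ligand, receptor) gene pairs. Pairs with the
#' same gene on both sides are permitted. Order of first appearance is
#' preserved.
#'
#' @param pairs data.frame with \code{ligand} and \code{receptor} columns.
#' @return an \code{lr_database} (a data.frame subclass).
#' @export
lr_database <- function(pairs) {
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stop("pair table needs 'ligand' and 'receptor' columns")
  pairs <- pairs[, c("ligand", "receptor"), drop = FALSE]
  pairs$ligand <- as.character(pairs$ligand)
  pairs$receptor <- as.character(pairs$receptor)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stop("empty gene labels in pair table")
  pairs <- pairs[!duplicated(paste(pairs$ligand, pairs$receptor,
                                   sep = "\r")), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("lr_database", "data.frame")
  pairs
}

#' Read a ligand-receptor pair table from TSV
#'
#' @param path TSV file with \code{ligand} and \code{receptor} columns.
#' @return an \code{lr_database}.
#' @export
load_lr_database <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lr_database(df)
}

#' Directed gene-level signalling/regulatory network
#'
#' Builds an igraph directed graph from an edge table with \code{source},
#' \code{target} and \code{kind} columns; \code{kind} must be
#' \code{"signaling"} or \code{"regulatory"}. Self-loops are rejected.
#'
#' @param edges data.frame of directed edges.
#' @return an igraph object with a \code{kind} edge attribute.
#' @export
signaling_graph <- function(edges) {
  if (!all(c("source", "target") %in% names(edges)))
    stop("network table needs 'source' and 'target' columns")
  if (!"kind" %in% names(edges)) edges$kind <- "signaling"
  bad_kind <- setdiff(unique(edges$kind), c("signaling", "regulatory"))
  if (length(bad_kind))
    stop("unknown edge kind(s): ", paste(bad_kind, collapse = ", "))
  if (any(edges$source == edges$target))
    stop("self-loops are not allowed in the signalling graph")
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "kind")], directed = TRUE)
  g
}

#' Read a network TSV
#'
#' @param path TSV with \code{source}, \code{target} and optional
#'   \code{kind} columns.
#' @return an igraph directed graph.
#' @export
load_signaling_graph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  signaling_graph(df)
}

#' Per-gene detection rate within a cell group
#'
#' Fraction of a group's cells with a nonzero count for each gene. Genes
#' absent from the matrix get detection 0.
#'
#' @param m a \code{cell_matrix}.
#' @param genes character vector of gene ids.
#' @param cell_type group label (matched against \code{cell_type}, or the
#'   subclass label when present).
#' @return named numeric vector of detection rates in [0, 1].
#' @export
detection_rate <- function(m, genes, cell_type) {
  labels <- cell_labels(m, "subclass")
  in_group <- labels == cell_type | m$cell_meta$cell_type == cell_type
  in_group[is.na(in_group)] <- FALSE
  if (!any(in_group)) stop("unknown cell type: ", cell_type)
  sub <- m$counts[, in_group, drop = FALSE]
  out <- stats::setNames(numeric(length(genes)), genes)
  present <- intersect(genes, rownames(sub))
  if (length(present))
    out[present] <- Matrix::rowSums(sub[present, , drop = FALSE] > 0) /
      ncol(sub)
  out
}

#' Cell-type-specific active subgraph
#'
#' Keeps the edges of a signalling graph whose both endpoint genes are
#' detected in at least a fraction \code{detect_min} of the given cell
#' type's cells. Raising \code{detect_min} can only remove edges.
#'
#' @param g an igraph directed graph.
#' @param m a \code{cell_matrix}.
#' @param cell_type group label to evaluate detection in.
#' @param detect_min minimum detection rate for both endpoints.
#' @return the induced igraph subgraph (nodes with no surviving edges are
#'   kept as isolated vertices only if they pass detection).
#' @export
active_subgraph <- function(g, m, cell_type, detect_min = 0.10) {
  nodes <- igraph::V(g)$name
  det <- detection_rate(m, nodes, cell_type)
  keep_node <- det >= detect_min
  igraph::induced_subgraph(g, which(keep_node))
}

#' Find sender-receiver feedback loops for a forward interaction
#'
#' A forward ligand-receptor pair (L1 from the sender, R1 on the receiver)
#' participates in a feedback loop with a back pair (L2, R2) when receptor
#' signalling in the receiver can reach the back ligand -- a directed path
#' R1 -> ... -> L2 of at most \code{max_path_len} edges exists in the
#' receiver's active subgraph -- and the back receptor R2 is expressed on
#' the original sender. A directed path R2 -> ... -> L1 in the sender's
#' subgraph is recorded as supporting evidence when present, but is not
#' required. A back ligand identical to the forward receptor is never
#' reported: the relay path must be a non-empty simple path, which cannot
#' revisit its start.
#'
#' @param forward list with \code{ligand}, \code{receptor}, \code{sender},
#'   \code{receiver}.
#' @param lr an \code{lr_database} of candidate back pairs.
#' @param g_receiver receiver-side active subgraph (igraph).
#' @param g_sender optional sender-side active subgraph, used only for the
#'   optional return-path evidence.
#' @param m optional \code{cell_matrix}; when given, back receptors must
#'   have detection rate >= \code{detect_min} in the sender. When NULL the
#'   detection check is skipped.
#' @param detect_min detection threshold for the back receptor.
#' @param max_path_len maximum number of edges in the receiver-side path
#'   (default 4: receptor -> signalling -> TF -> ligand).
#' @return data.frame with one row per loop: back ligand/receptor, the
#'   witness receiver path (shortest, ties broken lexicographically) and
#'   the sender return path when one exists ("" otherwise).
#' @export
find_feedback_loops <- function(forward, lr, g_receiver, g_sender = NULL,
                                m = NULL, detect_min = 0.10,
                                max_path_len = 4) {
  stopifnot(all(c("ligand", "receptor", "sender", "receiver") %in%
                names(forward)))
  empty <- data.frame(ligand = character(), receptor = character(),
                      back_ligand = character(), back_receptor = character(),
                      path_receiver = character(), path_sender = character(),
                      stringsAsFactors = FALSE)
  r1 <- forward$receptor
  if (!r1 %in% igraph::V(g_receiver)$name) return(empty)

  cand <- as.data.frame(lr)
  if (!is.null(m)) {
    det <- detection_rate(m, unique(cand$receptor), forward$sender)
    cand <- cand[det[cand$receptor] >= detect_min, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  dists <- igraph::distances(g_receiver, v = r1, mode = "out")[1, ]
  loops <- list()
  for (i in seq_len(nrow(cand))) {
    l2 <- cand$ligand[i]
    r2 <- cand$receptor[i]
    if (!l2 %in% names(dists)) next
    d <- dists[[l2]]
    if (!is.finite(d) || d < 1 || d > max_path_len) next
    wit <- witness_path(g_receiver, r1, l2)
    back_path <- ""
    if (!is.null(g_sender) &&
        all(c(r2, forward$ligand) %in% igraph::V(g_sender)$name)) {
      ds <- igraph::distances(g_sender, v = r2, to = forward$ligand,
                              mode = "out")[1, 1]
      if (is.finite(ds) && ds >= 1 && ds <= max_path_len)
        back_path <- paste(witness_path(g_sender, r2, forward$ligand),
                           collapse = ">")
    }
    loops[[length(loops) + 1L]] <- data.frame(
      ligand = forward$ligand, receptor = r1,
      back_ligand = l2, back_receptor = r2,
      path_receiver = paste(wit, collapse = ">"),
      path_sender = back_path, stringsAsFactors = FALSE)
  }
  if (!length(loops)) return(empty)
  out <- do.call(rbind, loops)
  out[order(out$back_ligand, out$back_receptor), , drop = FALSE]
}

# Shortest directed path from -> to; among equally short paths the
# lexicographically smallest node sequence is returned (determinism).
witness_path <- function(g, from, to) {
  asp <- igraph::all_shortest_paths(g, from = from, to = to,
                                    mode = "out")$res
  paths <- lapply(asp, function(p) igraph::V(g)$name[as.integer(p)])
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[[order(keys)[1]]]
}
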