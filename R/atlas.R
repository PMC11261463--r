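#' Synthetic brain parcellation table
#'
#' Builds a 246-node atlas table emulating a whole-brain parcellation with
#' 210 cortical and 36 subcortical subregions, organised into 7 lobes and
#' 24 gyri/nuclei, with a 7-network functional assignment. Labels are
#' synthetic analogs (same closed vocabularies and block structure as the
#' common 246-region template), sufficient for edge bookkeeping and
#' region-level summaries; no anatomical coordinates are implied.
#'
#' Within each gyrus block, nodes alternate left/right hemisphere (even
#' offset = L, odd offset = R). For `n_nodes` other than 246 the labels
#' are cycled deterministically so every node still carries valid
#' lobe/gyrus/network values.
#'
#' @param n_nodes number of nodes (default 246).
#' @return data.frame with columns `node_index` (0-based, contiguous),
#'   `name`, `hemisphere`, `lobe`, `gyrus`, `network`.
#' @export
synthetic_atlas <- function(n_nodes = 246) {
  gy <- data.frame(
    gyrus = c("SFG", "MFG", "IFG", "OrG", "PrG", "PCL",
              "STG", "MTG", "ITG", "FuG", "PhG", "pSTS",
              "SPL", "IPL", "PCun", "PoG",
              "INS", "CG", "MVOcC", "LOcC",
              "Amyg", "Hipp", "BG", "Tha"),
    lobe = c(rep("Frontal", 6), rep("Temporal", 6), rep("Parietal", 4),
             "Insular", "Limbic", rep("Occipital", 2),
             rep("Subcortical", 4)),
    n = c(14, 14, 12, 12, 12, 4,
          12, 8, 12, 8, 12, 4,
          10, 12, 8, 8,
          12, 14, 10, 12,
          4, 4, 12, 16),
    stringsAsFactors = FALSE
  )
  networks <- c("Visual", "Somatomotor", "DorsalAttention",
                "VentralAttention", "Limbic", "Frontoparietal", "Default")
  gy$network <- networks[(seq_len(nrow(gy)) - 1L) %% length(networks) + 1L]

  gyrus <- rep(gy$gyrus, gy$n)
  lobe <- rep(gy$lobe, gy$n)
  network <- rep(gy$network, gy$n)
  offset <- unlist(lapply(gy$n, seq_len)) - 1L
  if (n_nodes != sum(gy$n)) {
    idx <- (seq_len(n_nodes) - 1L) %% sum(gy$n) + 1L
    gyrus <- gyrus[idx]; lobe <- lobe[idx]
    network <- network[idx]; offset <- offset[idx]
  }
  hemi <- ifelse(offset %% 2L == 0L, "L", "R")
  data.frame(
    node_index = seq_len(n_nodes) - 1L,
    name = sprintf("%s_%s_%d", gyrus, hemi, offset %/% 2L + 1L),
    hemisphere = hemi,
    lobe = lobe,
    gyrus = gyrus,
    network = network,
    stringsAsFactors = FALSE
  )
}

assert_atlas <- function(atlas, n_nodes = NULL) {
  need <- c("node_index", "name", "hemisphere", "lobe", "gyrus", "network")
  miss <- setdiff(need, names(atlas))
  if (length(miss))
    stop("atlas is missing column(s): ", paste(miss, collapse = ", "))
  if (!identical(as.integer(atlas$node_index),
                 seq_len(nrow(atlas)) - 1L))
    stop("atlas node_index must be 0-based, unique and contiguous")
  if (!is.null(n_nodes) && nrow(atlas) != n_nodes)
    stop(sprintf("atlas covers %d nodes; %d required", nrow(atlas), n_nodes))
  invisible(atlas)
}
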