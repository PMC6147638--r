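# Text serialization of supra-networks: a dense matrix with a JSON header
# naming layers and node order, plus a tab-separated edge list. Both are
# bit-identical across runs at a fixed seed.

#' Write a supra-network to text files
#'
#' Writes `<prefix>.mat.tsv` (dense `lN x lN` supra-adjacency,
#' tab-separated), `<prefix>.json` (layers, node count, node ordering,
#' coupling structures and any pipeline metadata) and
#' `<prefix>.edges.tsv` (columns `layer_i`, `node_i`, `layer_j`,
#' `node_j`, `weight`; each undirected edge once, `(i, layer_i)` ordered
#' before `(j, layer_j)`).
#'
#' @param net A [supra_network()].
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @seealso [read_supra_network()]
#' @export
write_supra_network <- function(net, prefix) {
  stopifnot(inherits(net, "supra_network"))
  M <- supra_adjacency(net)
  mat_path <- paste0(prefix, ".mat.tsv")
  json_path <- paste0(prefix, ".json")
  edge_path <- paste0(prefix, ".edges.tsv")
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     mat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(n_nodes = net$n_nodes, layers = names(net$layers),
         node_order = "node n of layer l has index n + (l-1)*N",
         coupling_structure = lapply(net$couplings, `[[`, "structure"),
         meta = net$meta),
    json_path, auto_unbox = TRUE, digits = NA)
  N <- net$n_nodes
  l <- net$n_layers
  gi <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  edges <- data.frame(
    layer_i = names(net$layers)[(gi[, 1L] - 1L) %/% N + 1L],
    node_i = (gi[, 1L] - 1L) %% N + 1L,
    layer_j = names(net$layers)[(gi[, 2L] - 1L) %/% N + 1L],
    node_j = (gi[, 2L] - 1L) %% N + 1L,
    weight = format(M[gi], digits = 17, trim = TRUE, scientific = TRUE))
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mat_path, json_path, edge_path))
}

#' Read a supra-network written by [write_supra_network()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [supra_network()].
#' @export
read_supra_network <- function(prefix) {
  mat_path <- paste0(prefix, ".mat.tsv")
  json_path <- paste0(prefix, ".json")
  if (!file.exists(mat_path) || !file.exists(json_path))
    stopf("missing %s or %s", mat_path, json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(mat_path, sep = "\t", header = FALSE))
  dimnames(M) <- NULL
  net <- slice_supra_matrix(M, meta$n_nodes, meta$layers,
                            meta = as.list(meta$meta))
  net
}
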