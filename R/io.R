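#' Read a gene network from disk
#'
#' Accepts a whitespace/tab-separated edge list (two columns of node
#' identifiers, `#` comments allowed) or a GraphML file (by extension or
#' `format`). Self-loops are dropped and duplicate edges collapsed, with
#' a message reporting the counts.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension), `"edgelist"` or
#'   `"graphml"`.
#' @return a [GeneGraph-class].
#' @export
readNetwork <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    return(GeneGraph(ig))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineNo <- which(keep)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop(sprintf("unparsable edge at line %d: '%s'", lineNo[bad[1]], lines[bad[1]]))
  em <- do.call(rbind, lapply(parts, function(x) x[1:2]))
  GeneGraph(em)
}

#' Read a labeled drug-gene interaction table
#'
#' TSV with header columns `drug_id`, `gene_id`, `label` (0/1; anything
#' else is an error). An empty file with a header yields an empty
#' dataset.
#'
#' @param path file path.
#' @return data.frame with character ids and integer labels.
#' @export
readInteractions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", colClasses = NA)
  need <- c("drug_id", "gene_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) && !all(df$label %in% c(0, 1)))
    stop("interaction labels must be 0 or 1")
  df$drug_id <- as.character(df$drug_id)
  df$gene_id <- as.character(df$gene_id)
  df$label <- as.integer(df$label)
  df
}

## Provenance header written at the top of every output table.
.provenanceHeader <- function(seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("GraphDTI")),
                  error = function(e) "dev")
  c(sprintf("# GraphDTI %s", ver),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(seed)) sprintf("# seed: %s", seed))
}

#' Write a data.frame as a TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return invisibly, the path.
#' @export
writeTsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Write / read screening prediction records
#'
#' Round-trip stable TSV of [screenLibrary()] records (after
#' [normalizeScores()]); reading restores every column with its type.
#'
#' @param records prediction records.
#' @param path file path.
#' @param seed optional seed for the provenance header.
#' @return `writePredictions`: the path, invisibly; `readPredictions`:
#'   the records data.frame.
#' @export
writePredictions <- function(records, path, seed = NULL) {
  writeTsv(records, path, seed)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  for (cn in intersect(c("drug_id", "gene_id", "cluster", "targets"), names(df)))
    df[[cn]] <- as.character(df[[cn]])
  df
}

#' Write the centrality + FCI table
#'
#' One row per node: node id, the ten raw metrics, and (when given) the
#' composite FCI.
#'
#' @param ct a [CentralityTable-class].
#' @param fr optional [FCIResult-class] with computed scores.
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @return invisibly, the path.
#' @export
writeCentralityTable <- function(ct, path, fr = NULL, seed = NULL) {
  df <- data.frame(node = rownames(ct@metrics), ct@metrics,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(fr)) df$fci <- fciScores(fr)[df$node]
  writeTsv(df, path, seed)
}

#' Write / read a cluster assignment table
#'
#' TSV with columns `gene` and `cluster`.
#'
#' @param p a [Partition-class].
#' @param path file path.
#' @param seed optional seed for the provenance header.
#' @param g optional [GeneGraph-class] used to recompute Q when reading.
#' @return `writeClusters`: the path, invisibly; `readClusters`: a
#'   [Partition-class].
#' @export
writeClusters <- function(p, path, seed = NULL) {
  df <- data.frame(gene = names(p@membership), cluster = p@membership,
                   stringsAsFactors = FALSE)
  writeTsv(df, path, seed)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path, g = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("gene", "cluster") %in% names(df)))
    stop("cluster table needs columns 'gene' and 'cluster'")
  mem <- setNames(as.integer(df$cluster), as.character(df$gene))
  Q <- if (is.null(g)) 0 else modularityQ(g, mem)
  new("Partition", membership = mem, Q = Q)
}

#' Save / load a trained model
#'
#' Plain-text JSON checkpoint embedding the configuration, gene universe,
#' edges, cluster one-hot and every parameter tensor.
#'
#' @param model a [DTIModel-class].
#' @param path file path (`.json`).
#' @return `saveDTIModel`: the path, invisibly; `loadDTIModel`: the
#'   restored [DTIModel-class].
#' @export
saveDTIModel <- function(model, path) {
  obj <- list(
    config = model@config[setdiff(names(model@config), character(0))],
    genes = model@genes, edges = model@edges,
    clusterOneHot = model@clusterOneHot,
    params = lapply(model@params, function(x)
      if (is.matrix(x)) list(dim = dim(x), x = as.numeric(x))
      else list(dim = NULL, x = as.numeric(x))),
    meta = list(seed = model@meta$seed)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveDTIModel
#' @export
loadDTIModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(e) {
    if (!is.null(e$dim) && length(e$dim)) matrix(e$x, e$dim[1], e$dim[2])
    else as.numeric(e$x)
  })
  cfg <- obj$config
  C <- as.matrix(obj$clusterOneHot)
  rownames(C) <- obj$genes
  edges <- as.matrix(obj$edges)
  storage.mode(edges) <- "integer"
  new("DTIModel", params = params, config = cfg, genes = obj$genes,
      edges = edges, clusterOneHot = C,
      meta = list(seed = obj$meta$seed))
}
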