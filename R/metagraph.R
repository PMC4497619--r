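#' @include AllGenerics.R
NULL

#' Build a metagraph from metanode and metaedge declarations
#'
#' @param metanodes data.frame (or list of lists) with columns `identifier`
#'   and `abbreviation`.
#' @param metaedges data.frame (or list of lists) with columns `source`,
#'   `target`, `kind`, `abbreviation` and optionally `direction`
#'   (default `"undirected"`). Endpoints name declared metanodes.
#' @return a validated [MetaGraph-class]. Each metaedge receives the id
#'   `<sourceAbbrev><kindAbbrev><targetAbbrev>`, e.g. `DaG`.
#' @examples
#' mg <- buildMetaGraph(
#'   metanodes = data.frame(identifier = c("Gene", "Disease"),
#'                          abbreviation = c("G", "D")),
#'   metaedges = data.frame(source = "Disease", target = "Gene",
#'                          kind = "association", abbreviation = "a"))
#' metaEdges(mg)$id  # "DaG"
#' @export
buildMetaGraph <- function(metanodes, metaedges = NULL) {
  toDf <- function(x, cols) {
    if (is.null(x)) return(stats::setNames(
      as.data.frame(replicate(length(cols), character(0), simplify = FALSE)), cols))
    if (!is.data.frame(x))
      x <- do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    x
  }
  mn <- toDf(metanodes, c("identifier", "abbreviation"))
  if (!all(c("identifier", "abbreviation") %in% names(mn)))
    stopf("metanodes need columns 'identifier' and 'abbreviation'")
  mn <- data.frame(identifier = as.character(mn$identifier),
                   abbreviation = as.character(mn$abbreviation),
                   stringsAsFactors = FALSE)
  me <- toDf(metaedges, c("source", "target", "kind", "abbreviation"))
  if (nrow(me) > 0) {
    if (!all(c("source", "target", "kind", "abbreviation") %in% names(me)))
      stopf("metaedges need columns 'source', 'target', 'kind', 'abbreviation'")
    if (is.null(me$direction)) me$direction <- "undirected"
    unknown <- setdiff(c(me$source, me$target), mn$identifier)
    if (length(unknown))
      stopf("metaedge endpoint not a declared metanode: %s",
            paste(unique(unknown), collapse = ", "))
    ab <- stats::setNames(mn$abbreviation, mn$identifier)
    me <- data.frame(source = as.character(me$source),
                     target = as.character(me$target),
                     kind = as.character(me$kind),
                     direction = as.character(me$direction),
                     abbreviation = as.character(me$abbreviation),
                     stringsAsFactors = FALSE)
    me$id <- paste0(ab[me$source], me$abbreviation, ab[me$target])
  } else {
    me <- data.frame(source = character(0), target = character(0),
                     kind = character(0), direction = character(0),
                     abbreviation = character(0), id = character(0),
                     stringsAsFactors = FALSE)
  }
  new("MetaGraph", metanodes = mn, metaedges = me)
}

#' Read or write a metagraph schema file
#'
#' The schema file is YAML with two top-level lists, `metanodes` and
#' `metaedges`, mirroring the columns of [buildMetaGraph()].
#'
#' @param path file path.
#' @return `readMetaGraph()` a [MetaGraph-class]; `writeMetaGraph()` the path,
#'   invisibly.
#' @export
readMetaGraph <- function(path) {
  spec <- yaml::read_yaml(path)
  buildMetaGraph(spec$metanodes, spec$metaedges)
}

#' @rdname readMetaGraph
#' @param metagraph a [MetaGraph-class].
#' @export
writeMetaGraph <- function(metagraph, path) {
  me <- metagraph@metaedges
  spec <- list(
    metanodes = unname(apply(metagraph@metanodes, 1, as.list)),
    metaedges = unname(lapply(seq_len(nrow(me)), function(i)
      as.list(me[i, c("source", "target", "kind", "direction", "abbreviation")])))
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' The bundled gene-disease metagraph
#'
#' The 18-metanode / 19-metaedge schema used for GWAS-based gene-disease
#' association prediction: Gene, Disease, Tissue, Pathophysiology, and 14
#' gene-set collections, connected by association, localization, expression,
#' interaction and membership metaedges (all undirected).
#'
#' @return a [MetaGraph-class].
#' @examples
#' mg <- bundledMetaGraph()
#' nrow(metaNodes(mg))  # 18
#' nrow(metaEdges(mg))  # 19
#' @export
bundledMetaGraph <- function() {
  readMetaGraph(system.file("extdata", "gene-disease-metagraph.yml",
                            package = "hetpath", mustWork = TRUE))
}

#' @rdname accessors
#' @export
setMethod("metaNodes", "MetaGraph", function(x) x@metanodes)

#' @rdname accessors
#' @export
setMethod("metaEdges", "MetaGraph", function(x) x@metaedges)

# Metaedges traversable from a metanode, with the metanode reached by each.
# Undirected metaedges are traversable from either endpoint; directed ones
# only source -> target.
incidentMetaEdges <- function(metagraph, metanode) {
  me <- metagraph@metaedges
  if (nrow(me) == 0)
    return(data.frame(id = character(0), next_metanode = character(0)))
  fwd <- me$source == metanode
  rev <- me$target == metanode & me$direction == "undirected" & me$source != me$target
  data.frame(id = c(me$id[fwd], me$id[rev]),
             next_metanode = c(me$target[fwd], me$source[rev]),
             stringsAsFactors = FALSE)
}

metanodeAbbrev <- function(metagraph, metanode) {
  mn <- metagraph@metanodes
  mn$abbreviation[match(metanode, mn$identifier)]
}

setMethod("show", "MetaGraph", function(object) {
  cat(sprintf("MetaGraph with %d metanodes and %d metaedges\n",
              nrow(object@metanodes), nrow(object@metaedges)))
  if (nrow(object@metanodes))
    cat("  metanodes:", paste(object@metanodes$identifier, collapse = ", "), "\n")
  if (nrow(object@metaedges))
    cat("  metaedges:", paste(object@metaedges$id, collapse = ", "), "\n")
})
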