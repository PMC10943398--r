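# Plain-text readers and writers for the pipeline's exchange formats:
# expression TSV (genes x samples) + sample metadata TSV, GMT gene sets,
# interaction TSV, fraction TSV, and GraphML for networks.

stop_parse <- function(path, line, why) {
  stop(sprintf("parse error in %s at line %d: %s", path, line, why),
       call. = FALSE)
}

#' Write / read an expression matrix as TSV
#'
#' Expression is written genes-in-rows, samples-in-columns with a leading
#' `gene` column and a header row of sample ids; sample metadata
#' (`sample_id`, `group`, `batch`, optional `subcluster`) goes to a second
#' TSV.
#'
#' @param em An [expression_matrix].
#' @param expr_path,meta_path File paths for the two TSVs.
#' @return `write_expression` returns the paths invisibly; `read_expression`
#'   returns an [expression_matrix].
#' @export
write_expression <- function(em, expr_path, meta_path) {
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, meta_path) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") stop_parse(expr_path, 1, "first column must be 'gene'")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(meta)))
    stop_parse(meta_path, 1, "need columns sample_id, group, batch")
  if (!identical(colnames(values), meta$sample_id))
    stop("expression columns and metadata sample_id disagree")
  expression_matrix(values, group = meta$group, batch = meta$batch,
                    subcluster = meta$subcluster)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description strings.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_parse(path, i, "GMT line needs name, description and >=1 gene")
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    d <- if (is.null(descriptions)) "na" else descriptions[i]
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene panel from GMT or a plain one-symbol-per-line list
#'
#' @param path File path; files whose first line contains tabs are parsed as
#'   GMT (union of all sets), otherwise as a plain list.
#' @return Character vector of gene symbols.
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) unique(unlist(read_gmt(path), use.names = FALSE))
  else {
    x <- trimws(readLines(path))
    unique(x[nzchar(x)])
  }
}

#' Read / write miRNA interaction tables
#'
#' TSV with columns `mirna_id`, `target_id`, `target_kind`.
#'
#' @param tab Data.frame with those columns.
#' @param path File path.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id")
  if (!all(need %in% names(tab)))
    stop_parse(path, 1, "need columns mirna_id, target_id")
  tab
}

#' Read / write immune-fraction tables
#'
#' TSV with a leading `sample_id` column, one column per cell type, and a
#' trailing `deconv_p` column.
#'
#' @param fractions Data.frame with sample rownames and a `deconv_p` column.
#' @param path File path.
#' @export
write_fractions <- function(fractions, path) {
  tab <- data.frame(sample_id = rownames(fractions), fractions,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fractions
#' @export
read_fractions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id" || !"deconv_p" %in% names(tab))
    stop_parse(path, 1, "need sample_id first column and a deconv_p column")
  out <- tab[, -1, drop = FALSE]
  rownames(out) <- tab$sample_id
  out
}

#' Write / read a ceRNA network as GraphML
#'
#' @param network A `cerna_network`.
#' @param path File path.
#' @return `read_network_graphml` returns a `cerna_network` rebuilt from the
#'   file (degree and betweenness recomputed).
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    id = igraph::V(g)$name,
    type = igraph::V(g)$type,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                 normalized = FALSE)),
    stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes), class = "cerna_network")
}
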