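#' Validate (and coerce) a sample-by-taxon count table
#'
#' The package represents community count tables as plain integer matrices
#' with taxa as rows and samples as columns, labelled on both axes — the
#' layout in which OTU tables are usually exported.  All downstream
#' operations align tables, trees and distance matrices by identifier,
#' never by position.
#'
#' @param x matrix (or object coercible to one) of nonnegative integer
#'   counts; rows = taxa, columns = samples, both axes named.
#' @return the validated integer matrix, invisibly classed as produced.
#' @export
count_table <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have taxon rownames and sample colnames", call. = FALSE)
  dup_t <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_t))
    stop("duplicated taxon id(s): ", paste(dup_t, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (!is.numeric(x) || anyNA(x))
    stop("count table must be numeric with no missing values", call. = FALSE)
  if (any(x < 0))
    stop("negative counts are not allowed", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8))
    stop("non-integer counts are not allowed", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

#' Read a delimited count table
#'
#' @param path TSV file; first column holds taxon ids (default orientation)
#'   or sample ids, header row gives the other axis.
#' @param taxa_as_rows logical; set \code{FALSE} for samples-as-rows files.
#' @param sep field separator, tab by default.
#' @return validated integer matrix, taxa as rows.
#' @export
read_count_table <- function(path, taxa_as_rows = TRUE, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty count table file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2 || nrow(df) < 1)
    stop("count table file must have an id column and at least one data column", call. = FALSE)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ", if (taxa_as_rows) "taxon" else "sample",
         " id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) stop("non-numeric cell(s) in count table: ", path, call. = FALSE)
  rownames(m) <- ids
  if (!taxa_as_rows) m <- t(m)
  count_table(m)
}

#' Write a count table as TSV (taxa as rows)
#' @param x count table matrix
#' @param path output file
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, group, covariates) from TSV
#' @param path TSV with a header; must contain \code{sample_id} and
#'   \code{group} columns.
#' @return data.frame with character sample_id and group.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata needs 'sample_id' and 'group' columns", call. = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "), call. = FALSE)
  df
}

#' Look up group labels for a set of samples
#' @param metadata data.frame from \code{read_sample_metadata} (or equivalent)
#' @param sample_ids samples that must all carry a group label
#' @return character vector of group labels, named by sample.
#' @export
sample_groups <- function(metadata, sample_ids) {
  idx <- match(sample_ids, metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  stats::setNames(as.character(metadata$group[idx]), sample_ids)
}

#' Read a rooted Newick phylogeny with branch lengths
#'
#' Trees without branch lengths are rejected outright: the nearest-taxon
#' null model consumes patristic distances, and silently defaulting absent
#' lengths to zero would corrupt them.
#'
#' @param path Newick file
#' @return an \code{ape} \code{phylo} object with >= 2 uniquely labelled tips.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick: ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("unparseable Newick file: ", path, call. = FALSE)
  validate_tree(tr)
}

#' Validate a phylogeny for pairwise phylogenetic operations
#' @param tr \code{phylo} object
#' @return the tree, invisibly usable downstream.
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object", call. = FALSE)
  if (length(tr$tip.label) < 2)
    stop("tree has fewer than 2 tips; pairwise distances undefined", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicated tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree is missing branch lengths; they are required, not defaulted to 0",
         call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) in tree", call. = FALSE)
  tr
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree validated \code{phylo}
#' @param taxa optional taxon ids to restrict/reorder the matrix to; all
#'   must be tips of the tree.
#' @return symmetric labelled matrix of patristic distances, zero diagonal.
#' @export
patristic_distances <- function(tree, taxa = NULL) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(d))
    if (length(missing))
      stop("taxa missing from tree: ", paste(missing, collapse = ", "), call. = FALSE)
    d <- d[taxa, taxa, drop = FALSE]
  }
  diag(d) <- 0
  d
}

#' Validate a labelled distance (or signed score) matrix
#' @param x square matrix with matching dimnames
#' @param signed if TRUE (e.g. a betaNTI matrix) negative entries are
#'   allowed; plain distances must be nonnegative with an exactly zero
#'   diagonal.
#' @return the matrix.
#' @export
validate_distance_matrix <- function(x, signed = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(x)) || !identical(rownames(x), colnames(x)))
    stop("distance matrix needs identical row/column labels", call. = FALSE)
  if (max(abs(x - t(x))) > 1e-12)
    stop("distance matrix not symmetric within 1e-12", call. = FALSE)
  if (!signed) {
    if (any(diag(x) != 0)) stop("distance matrix diagonal must be exactly 0", call. = FALSE)
    if (any(x < 0)) stop("negative entries in distance matrix", call. = FALSE)
  }
  x
}

#' Write / read a labelled distance matrix as TSV
#' @param x labelled square matrix
#' @param path TSV path
#' @export
write_distance_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param signed passed to \code{validate_distance_matrix}
#' @export
read_distance_matrix <- function(path, signed = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  # symmetrize away write/parse rounding at the last digit
  m <- (m + t(m)) / 2
  validate_distance_matrix(m, signed = signed)
}

#' Gene abundance table with lengths and library sizes (for RPKM)
#'
#' @param counts gene x sample read-count matrix, labelled on both axes
#' @param gene_lengths bp per gene, named by gene or in row order
#' @param total_mapped per-sample total mapped reads, named by sample or in
#'   column order; must be at least the column sums of \code{counts}.
#' @return list with elements \code{counts}, \code{gene_lengths},
#'   \code{total_mapped}, aligned by identifier.
#' @export
gene_table <- function(counts, gene_lengths, total_mapped) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("gene table needs gene rownames and sample colnames", call. = FALSE)
  if (!is.null(names(gene_lengths))) gene_lengths <- gene_lengths[rownames(counts)]
  if (!is.null(names(total_mapped))) total_mapped <- total_mapped[colnames(counts)]
  if (length(gene_lengths) != nrow(counts) || anyNA(gene_lengths))
    stop("gene_lengths must cover every gene", call. = FALSE)
  if (length(total_mapped) != ncol(counts) || anyNA(total_mapped))
    stop("total_mapped must cover every sample", call. = FALSE)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(total_mapped < colSums(counts)))
    stop("total mapped reads below column sums", call. = FALSE)
  list(counts = counts, gene_lengths = as.numeric(gene_lengths),
       total_mapped = as.numeric(total_mapped))
}

#' Export a co-occurrence network as GraphML
#'
#' Node attributes: taxon id, degree and (if supplied at build time) a
#' free-text taxonomic label; edge attributes: correlation weight and sign.
#' The file loads directly into Gephi or igraph.
#'
#' @param network a \code{NetworkModel} from \code{\link{build_network}}
#' @param path output .graphml path
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "network_model"))
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
  igraph::V(g)$name <- network$nodes
  igraph::V(g)$degree <- as.integer(network$degree[network$nodes])
  if (!is.null(network$taxonomy))
    igraph::V(g)$taxonomy <- as.character(network$taxonomy[network$nodes])
  if (nrow(network$edges)) {
    idx <- rbind(match(network$edges$taxon_i, network$nodes),
                 match(network$edges$taxon_j, network$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    igraph::E(g)$weight <- network$edges$r
    igraph::E(g)$sign <- ifelse(network$edges$r >= 0, "positive", "negative")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
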