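#' Ordered disease-stage levels
#'
#' The baseline condition is non-malignant adjacent urothelium (NAU),
#' followed by the pathologic tumor stages in order of spread.
#'
#' @format Character vector of length 6: `NAU < Ta < T1 < T2 < T3 < T4`.
#' @export
STAGE_LEVELS <- c("NAU", "Ta", "T1", "T2", "T3", "T4")

#' Tumor stages (the five non-baseline conditions)
#' @rdname STAGE_LEVELS
#' @export
TUMOR_STAGES <- c("Ta", "T1", "T2", "T3", "T4")

#' Validate a gene x sample expression matrix
#'
#' Expression values are on the log2 intensity scale throughout the
#' pipeline (the deconvolution module, which needs linear-scale input,
#' exponentiates explicitly). The container is a plain numeric matrix
#' with gene symbols as rownames and sample IDs as colnames.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  values
}

#' Construct and validate a per-sample annotation table
#'
#' @param df Data frame with columns `sample_id`, `stage` (levels among
#'   `NAU, Ta, T1, T2, T3, T4`), `batch`, and optionally `age`, `sex`,
#'   `time` (survival months) and `event` (0/1). `event` must be present
#'   iff `time` is present.
#' @return Data frame with `stage` as an ordered factor and `batch` as a
#'   factor.
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "stage", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample table")
  bad <- setdiff(unique(as.character(df$stage)), STAGE_LEVELS)
  if (length(bad)) stop("unknown stage labels: ", paste(bad, collapse = ", "))
  df$stage <- factor(as.character(df$stage), levels = STAGE_LEVELS, ordered = TRUE)
  df$batch <- factor(df$batch)
  has_time <- "time" %in% names(df)
  has_event <- "event" %in% names(df)
  if (has_time != has_event)
    stop("survival columns must come as a pair: 'event' present iff 'time' present")
  if (has_time) {
    if (any(df$time < 0, na.rm = TRUE)) stop("negative survival time")
    if (!all(df$event %in% c(0, 1, NA))) stop("event must be 0/1")
  }
  df
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample IDs and
#' whose first column holds gene symbols. Duplicate gene rows are
#' collapsed by their mean on the log scale (each collapse is reported
#' via `message()`); duplicate sample IDs are an error.
#'
#' @param path Path to the TSV file.
#' @param missing_policy Either `"fail"` (default; any missing cell is an
#'   error) or `"drop_gene"` (rows containing missing values are removed
#'   with a warning naming each dropped gene).
#' @return Numeric matrix (genes x samples), see [expression_matrix()].
#' @export
read_expression_matrix <- function(path, missing_policy = c("fail", "drop_gene")) {
  missing_policy <- match.arg(missing_policy)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus >=1 sample column")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop("duplicate sample ID in header: ", paste(dup, collapse = ", "))
  }
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, samples)))
  # cells that fail numeric coercion but are not declared missing
  na_in <- is.na(vals) | vals == "" | vals == "NaN"
  na_in[is.na(na_in)] <- TRUE
  bad <- which(is.na(num) & !na_in, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyNA(num)) {
    if (missing_policy == "fail") {
      i <- which(apply(is.na(num), 1, any))
      stop("missing values in genes: ", paste(unique(genes[i]), collapse = ", "),
           " (use missing_policy = 'drop_gene' to remove them)")
    }
    drop <- apply(is.na(num), 1, any)
    warning("dropping ", sum(drop), " gene row(s) with missing values: ",
            paste(unique(genes[drop]), collapse = ", "))
    num <- num[!drop, , drop = FALSE]
    genes <- genes[!drop]
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing duplicate gene rows by mean: ", paste(dup, collapse = ", "))
    counts <- as.vector(rowsum(rep(1, length(genes)), group = genes, reorder = FALSE))
    num <- rowsum(num, group = genes, reorder = FALSE) / counts
    genes <- rownames(num)
  }
  rownames(num) <- genes
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric gene x sample matrix.
#' @param path Output path.
#' @param gene_col Name of the first (gene) column.
#' @export
write_expression_matrix <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. A sign-suffix dialect is supported for regulons:
#' members written `GENE|+1` or `GENE|-1` carry the sign of regulation.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors), `desc` (named character) and `signs` (named list
#'   of +1/-1 vectors, or `NULL` entries for unsigned sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(); signs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member", i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    sgn <- rep(NA_real_, length(members))
    has_sfx <- grepl("\\|[+-]?1$", members)
    if (any(has_sfx)) {
      if (!all(has_sfx))
        stop("set '", nm, "': signed and unsigned members mixed; signs must cover every member")
      sgn <- ifelse(grepl("\\|\\+?1$", members), 1, -1)
      members <- sub("\\|[+-]?1$", "", members)
    }
    if (anyDuplicated(members)) stop("set '", nm, "' lists a member twice")
    sets[[nm]] <- members
    desc[nm] <- f[2]
    signs[[nm]] <- if (any(has_sfx)) stats::setNames(sgn, members) else NULL
  }
  gene_set_collection(sets, desc, signs)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set members).
#' @param desc Optional named character of descriptions.
#' @param signs Optional named list; each entry `NULL` or a named numeric
#'   vector of +1/-1 covering every member of the set.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, desc = NULL, signs = NULL) {
  if (length(sets) == 0) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) || anyDuplicated(names(sets)))
    stop("gene-set names must be unique and non-empty")
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  # canonicalize: one (possibly NULL) signs entry per set, in set order
  norm <- stats::setNames(vector("list", length(sets)), names(sets))
  if (!is.null(signs))
    for (nm in intersect(names(signs), names(sets)))
      if (!is.null(signs[[nm]])) norm[[nm]] <- signs[[nm]]
  signs <- norm
  for (nm in names(sets)) {
    s <- signs[[nm]]
    if (!is.null(s)) {
      if (!setequal(names(s), sets[[nm]]) || !all(s %in% c(-1, 1)))
        stop("signs for set '", nm, "' must cover every member with +1/-1")
    }
  }
  structure(list(sets = sets, desc = desc, signs = signs),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets; sizes",
      paste(range(lengths(x$sets)), collapse = "-"),
      "; signed:", sum(!vapply(x$signs, is.null, logical(1))), "\n")
  invisible(x)
}

#' Write a gene-set collection in GMT format
#'
#' Signed sets use the `GENE|+1` / `GENE|-1` suffix dialect that
#' [read_gmt()] parses back.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    s <- collection$signs[[nm]]
    if (!is.null(s))
      members <- paste0(members, "|", ifelse(s[members] > 0, "+1", "-1"))
    paste(c(nm, collection$desc[[nm]], members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a stage co-expression network to disk
#'
#' Produces two files: `<prefix>_edges.tsv` with columns `gene_a`,
#' `gene_b`, `weight`, `spearman_rho`, and `<prefix>.graphml` carrying
#' the Louvain community ID and betweenness centrality as node
#' attributes. An empty graph writes a header-only edge list.
#'
#' @param network A `stage_network` (see [build_stage_network()]) or a
#'   bare igraph graph with `weight` and `spearman_rho` edge attributes.
#' @param path_prefix Path prefix for the two output files.
#' @return Invisibly, the two paths written.
#' @export
write_network <- function(network, path_prefix) {
  g <- if (inherits(network, "stage_network")) network$graph else network
  stopifnot(inherits(g, "igraph"))
  edge_path <- paste0(path_prefix, "_edges.tsv")
  gml_path <- paste0(path_prefix, ".graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   weight = igraph::E(g)$weight,
                   spearman_rho = igraph::E(g)$spearman_rho)
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(network, "stage_network")) {
    igraph::V(g)$community <- network$membership[igraph::V(g)$name]
    igraph::V(g)$betweenness <- network$betweenness[igraph::V(g)$name]
  }
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = gml_path))
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to the `*_edges.tsv` file.
#' @return Undirected igraph graph with `weight` and `spearman_rho` edge
#'   attributes; reading back a written network reproduces the graph
#'   exactly.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (nrow(df) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(df[, c("gene_a", "gene_b")], directed = FALSE)
  igraph::E(g)$weight <- df$weight
  igraph::E(g)$spearman_rho <- df$spearman_rho
  g
}
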