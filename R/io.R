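#' Read a gene expression matrix
#'
#' Reads a delimited text file (TAB or comma, auto-detected) with gene
#' identifiers in the first column and sample identifiers in the header row.
#' Values are expected to be log-scale intensities; missing or non-numeric
#' cells are rejected with their coordinates.
#'
#' @param path Path to the file.
#' @param group_map Optional named character vector mapping sample IDs to
#'   group labels, which must be `"case"` or `"control"`. When supplied, the
#'   labels are attached as the `"group"` attribute of the returned matrix.
#' @return A numeric matrix (genes x samples) with gene IDs as row names and
#'   sample IDs as column names, in file order.
#' @export
read_expression <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("malformed header: expected gene ID column plus >= 1 sample column")
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1L])
  }
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID: ", gene_ids[duplicated(gene_ids)][1L])
  }
  values <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  if (!is.null(group_map)) {
    if (is.null(names(group_map))) stop("group_map must be named by sample ID")
    missing <- setdiff(sample_ids, names(group_map))
    if (length(missing)) stop("no group label for sample(s): ",
                              paste(missing, collapse = ", "))
    labels <- unname(group_map[sample_ids])
    unknown <- setdiff(unique(labels), c("case", "control"))
    if (length(unknown)) stop("unknown group label: ",
                              paste(unknown, collapse = ", "))
    attr(values, "group") <- stats::setNames(labels, sample_ids)
  }
  values
}

#' Split a combined expression matrix into case and control matrices
#'
#' @param x Matrix returned by [read_expression()] with a `"group"` attribute.
#' @return A list with elements `case` and `control`.
#' @export
split_groups <- function(x) {
  group <- attr(x, "group")
  if (is.null(group)) stop("matrix carries no 'group' attribute")
  list(case = x[, names(group)[group == "case"], drop = FALSE],
       control = x[, names(group)[group == "control"], drop = FALSE])
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, TAB-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed. Pathways with fewer than `min_genes` unique genes are
#' dropped (the number dropped is reported via a message).
#'
#' @param path Path to the GMT file.
#' @param min_genes Minimum unique gene-set size retained (default 6).
#' @param on_duplicate What to do when two lines share a pathway name:
#'   `"error"` (default) or `"first"` (keep the first, warn).
#' @return A named list of character vectors (gene sets) with a
#'   `"description"` attribute (named character vector).
#' @export
read_gmt <- function(path, min_genes = 6L, on_duplicate = c("error", "first")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    if (on_duplicate == "error") {
      stop("duplicate pathway name: ", paste(dup, collapse = ", "))
    }
    warning("duplicate pathway name(s) kept-first: ", paste(dup, collapse = ", "))
    keep <- !duplicated(ids)
    ids <- ids[keep]; desc <- desc[keep]; sets <- sets[keep]
  }
  sizes <- lengths(sets)
  dropped <- sum(sizes < min_genes)
  if (dropped > 0L) {
    message(dropped, " pathway(s) dropped with fewer than ", min_genes, " genes")
  }
  keep <- sizes >= min_genes
  out <- stats::setNames(sets[keep], ids[keep])
  attr(out, "description") <- stats::setNames(desc[keep], ids[keep])
  out
}

#' Drop redundant pathway terms, keeping the largest gene set
#'
#' Optional deduplication pass over a pathway collection: among pathways with
#' identical gene sets (`key = "genes"`) or identical names after
#' case/whitespace normalization (`key = "name"`), only the one with the
#' largest gene set is retained.
#'
#' @param pathways Named list of gene sets, as from [read_gmt()].
#' @param key `"genes"` or `"name"`.
#' @return The filtered collection.
#' @export
dedup_pathways <- function(pathways, key = c("genes", "name")) {
  key <- match.arg(key)
  k <- if (key == "genes") {
    vapply(pathways, function(g) paste(sort(g), collapse = "\r"), character(1L))
  } else {
    gsub("[[:space:]_-]+", " ", tolower(names(pathways)))
  }
  ord <- order(-lengths(pathways))
  keep_idx <- ord[!duplicated(k[ord])]
  out <- pathways[sort(keep_idx)]
  attr(out, "description") <- attr(pathways, "description")[names(out)]
  out
}

#' Read a TF-to-target regulatory edge list
#'
#' Delimited text (TAB or comma, auto-detected, no header) with at least two
#' columns: TF identifier, target-gene identifier, and an optional source
#' tag. Duplicate (TF, TG) pairs are collapsed and self-pairs dropped with a
#' warning.
#'
#' @param path Path to the edge-list file.
#' @return A data.frame with columns `tf`, `tg`, and `source` (`NA` when the
#'   file has two columns). The number of rows read is reported via a message.
#' @export
read_regulatory_network <- function(path) {
  if (!file.exists(path)) stop("regulatory network file not found: ", path)
  sep <- tryCatch(detect_delimiter(path), error = function(e)
    stop("regulatory network file must have >= 2 columns: ", path, call. = FALSE))
  raw <- utils::read.table(path, header = FALSE, sep = sep, quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", fill = TRUE)
  if (ncol(raw) < 2L) stop("regulatory network file must have >= 2 columns")
  if (ncol(raw) >= 3L) raw[[3L]][!nzchar(raw[[3L]])] <- NA_character_
  message(nrow(raw), " regulatory interactions read")
  edges <- data.frame(tf = raw[[1L]], tg = raw[[2L]],
                      source = if (ncol(raw) >= 3L) raw[[3L]] else NA_character_,
                      stringsAsFactors = FALSE)
  loops <- edges$tf == edges$tg
  if (any(loops)) {
    warning(sum(loops), " self-pair(s) dropped from regulatory network")
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- edges[!duplicated(edges[c("tf", "tg")]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path Path to the file.
#' @return Character vector of unique, non-empty identifiers in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) stop("gene list is empty: ", path)
  ids
}

#' Write pipeline results to a directory
#'
#' Writes `edges.tsv` (per rewired edge), `pathways.tsv` (per pathway),
#' `genes.tsv` (per gene), and `run.json` (parameters, seed, package
#' version). An empty result set yields headers-only files.
#'
#' @param results A `pathrewire_result` object from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, out_dir) {
  if (!inherits(results, "pathrewire_result")) {
    stop("results must be a 'pathrewire_result' object")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(edges = file.path(out_dir, "edges.tsv"),
             pathways = file.path(out_dir, "pathways.tsv"),
             genes = file.path(out_dir, "genes.tsv"),
             run = file.path(out_dir, "run.json"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_tsv(results$edges_table, paths[["edges"]])
  write_tsv(results$pathways_table, paths[["pathways"]])
  write_tsv(results$genes_table, paths[["genes"]])
  run_info <- c(results$params,
                list(package_version = as.character(utils::packageVersion("pathrewire")),
                     r_version = as.character(getRversion())))
  jsonlite::write_json(run_info, paths[["run"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

# Delimiter auto-detection among TAB and comma; TAB wins ties.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) stop("malformed header: empty first line in ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_tab == 0L && n_com == 0L) {
    stop("malformed header: no TAB or comma delimiter found in ", path)
  }
  if (n_tab >= n_com) "\t" else ","
}
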